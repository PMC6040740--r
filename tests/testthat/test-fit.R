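test_that("noise-free plate is interpolated exactly", {
  theta <- list(A = log(c(100, 40, 150, 20)), B = log(c(80, 30, 120, 15)))
  beta <- list(A = c(0.1, -0.05, -0.05), B = c(0.2, -0.2))
  m <- exact_plate(theta, beta)
  fit <- fit_log_linear(m)
  for (b in names(theta)) {
    est <- fit$theta$theta[fit$theta$biosample == b]
    expect_equal(est, theta[[b]], tolerance = 1e-10)
    est_b <- fit$beta$beta[fit$beta$biosample == b]
    expect_equal(sort(est_b), sort(beta[[b]]), tolerance = 1e-10)
  }
  expect_lt(max(abs(fit$data$deviation - rep(unlist(beta),
                                             each = 12L))), 1e-10)
  expect_lt(max(abs(fit$data$residual)), 1e-10)
})

test_that("estimates match the pseudoinverse design-matrix oracle", {
  for (s in 1:25) {
    m <- rand_plate(s, n_bios = 1L + s %% 3L, wells = 2L + s %% 3L,
                    tpp = 1L + s %% 3L)
    fit <- fit_log_linear(m)
    orc <- oracle_fit(m)
    key <- paste(fit$theta$biosample, fit$theta$interval, sep = ":")
    expect_equal(fit$theta$theta, unname(orc$theta[key]), tolerance = 1e-10)
    expect_equal(fit$beta$beta, unname(orc$beta[fit$beta$well]),
                 tolerance = 1e-10)
    expect_equal(fit$data$fitted, orc$fitted, tolerance = 1e-10)
  }
})

test_that("fitted values are invariant to the identifiability constraint", {
  for (s in 1:10) {
    m <- rand_plate(100 + s, n_bios = 2L, wells = 4L, tpp = 3L)
    fit <- fit_log_linear(m)
    expect_lt(max(abs(fit$data$fitted - reference_coding_fitted(m))), 1e-8)
  }
})

test_that("well effects are zero-sum per biosample and over the plate", {
  m <- rand_plate(7, n_bios = 3L, wells = 5L, tpp = 3L)
  fit <- fit_log_linear(m)
  sums <- tapply(fit$beta$beta, fit$beta$biosample, sum)
  expect_true(all(abs(sums) < 1e-10))
  expect_lt(abs(mean(fit$beta$beta)), 1e-10)
})

test_that("residuals are orthogonal to the intercept", {
  m <- rand_plate(8, n_bios = 2L, wells = 4L, tpp = 3L)
  fit <- fit_log_linear(m)
  expect_lt(abs(sum(fit$data$residual)), 1e-9)
})

test_that("adding a constant shifts theta, leaves beta unchanged", {
  m <- rand_plate(9, n_bios = 2L, wells = 3L, tpp = 3L)
  fit0 <- fit_log_linear(m)
  m2 <- m
  m2$ocr <- m2$ocr * exp(0.7)
  fit1 <- fit_log_linear(m2)
  expect_equal(fit1$theta$theta, fit0$theta$theta + 0.7, tolerance = 1e-10)
  expect_equal(fit1$beta$beta, fit0$beta$beta, tolerance = 1e-10)
})

test_that("deviations keep the well effect, residuals do not", {
  m <- rand_plate(10, n_bios = 2L, wells = 4L, tpp = 2L)
  fit <- fit_log_linear(m)
  beta_of <- fit$beta$beta[match(fit$data$well, fit$beta$well)]
  expect_equal(fit$data$deviation, fit$data$residual + beta_of,
               tolerance = 1e-12)
  d <- compute_deviations(fit)
  expect_equal(d$deviation, fit$data$deviation)
})

test_that("offsets are subtracted before fitting", {
  m <- rand_plate(11, n_bios = 2L, wells = 3L, tpp = 3L)
  off <- data.frame(interval = 1:4, offset = c(0.3, -0.1, 0, 0.2))
  fit0 <- fit_log_linear(m)
  fit1 <- fit_log_linear(m, offsets = off)
  expect_equal(fit1$theta$theta,
               fit0$theta$theta - off$offset[fit1$theta$interval],
               tolerance = 1e-10)
  expect_equal(fit1$beta$beta, fit0$beta$beta, tolerance = 1e-10)
})

test_that("cell-count offset normalises by seeded cell number", {
  m <- rand_plate(12, n_bios = 1L, wells = 3L, tpp = 3L)
  counts <- c(15000, 20000, 30000)
  m$cell_count <- counts[match(m$well, unique(m$well))]
  fit <- fit_log_linear(m, cell_count_offset = TRUE)
  # equivalent to fitting OCR / cell_count
  m2 <- m
  m2$ocr <- m2$ocr / m2$cell_count
  fit2 <- fit_log_linear(m2)
  expect_equal(fit$theta$theta, fit2$theta$theta, tolerance = 1e-10)
  expect_equal(fit$beta$beta, fit2$beta$beta, tolerance = 1e-10)

  m$cell_count <- NA_real_
  expect_error(fit_log_linear(m, cell_count_offset = TRUE), "cell_count")
})

test_that("degenerate and invalid inputs are handled as contracted", {
  # single-well biosample: allowed, beta forced to 0 and flagged
  theta <- list(A = log(c(100, 40, 150, 20)))
  m <- exact_plate(theta)
  solo <- m[m$well == "A_w1", ]
  solo$biosample <- "solo"
  solo$well <- "S1"
  solo$ocr <- solo$ocr * 1.3
  fit <- fit_log_linear(rbind(m, solo))
  expect_true(fit$beta$singleton[fit$beta$well == "S1"])
  expect_equal(fit$beta$beta[fit$beta$well == "S1"], 0)

  # empty (biosample, interval) cell is an error naming the cell
  m2 <- rand_plate(13, n_bios = 2L, wells = 3L, tpp = 2L)
  m2 <- m2[!(m2$biosample == "bio2" & m2$interval == 3L), ]
  expect_error(fit_log_linear(m2), "bio2 x interval 3")

  # two plates at once is a misuse
  m3 <- rand_plate(14)
  m4 <- m3
  m4$plate_id <- "p2"
  expect_error(fit_log_linear(rbind(m3, m4)), "one plate")
})

test_that("theta RMSE decreases with more wells per biosample", {
  rmse <- sapply(c(4L, 16L), function(nw) {
    errs <- sapply(1:20, function(s) {
      sim <- simulate_plates(
        sim_config(n_plates = 1, biosamples = paste0("S", 1:4),
                   wells_per_biosample = nw, sigma_plate_interval = 0),
        seed = s)
      fit <- fit_log_linear(sim$plates$measurements)
      tr <- sim$truth$theta
      est <- fit$theta$theta[match(paste(tr$biosample, tr$interval),
                                   paste(fit$theta$biosample,
                                         fit$theta$interval))]
      sqrt(mean((est - tr$theta)^2))
    })
    mean(errs)
  })
  expect_lt(rmse[2], rmse[1])
})
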