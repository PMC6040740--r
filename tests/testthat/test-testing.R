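test_that("ddtheta matches hand arithmetic and degenerate cases", {
  theta <- list(NHDF = log(c(100, 40, 150, 40)),
                b = log(c(100, 40, 150, 20)))
  fit <- fit_log_linear(exact_plate(theta))
  dd <- compute_ddtheta(fit, control = "NHDF")
  expect_equal(dd$ddtheta[dd$metric == "MEi"], log(2), tolerance = 1e-10)
  expect_equal(dd$ddtheta[dd$metric == "EI"], log(100 / 20) - log(100 / 40),
               tolerance = 1e-10)
  expect_equal(dd$ddtheta[dd$metric == "AI"], 0, tolerance = 1e-10)
  expect_equal(dd$ddtheta[dd$metric == "MI"], 0, tolerance = 1e-10)
  expect_equal(dd$ddtheta[dd$metric == "EAi"], log(40 / 20) - log(40 / 40),
               tolerance = 1e-10)

  # biosample identical to control: all differences vanish
  theta2 <- list(NHDF = log(c(100, 40, 150, 20)),
                 b = log(c(100, 40, 150, 20)))
  dd2 <- compute_ddtheta(fit_log_linear(exact_plate(theta2)), "NHDF")
  expect_lt(max(abs(dd2$ddtheta)), 1e-10)

  # a plate without the control is skipped with a message
  expect_message(
    dd3 <- compute_ddtheta(fit_log_linear(exact_plate(theta["b"])), "NHDF"),
    "no control")
  expect_null(dd3)
})

test_that("ddtheta is invariant to per-(plate, interval) additive shifts", {
  sim <- simulate_plates(sim_config(n_plates = 2), seed = 70)
  m <- sim$plates$measurements[!sim$plates$measurements$is_blank, ]
  dd0 <- compute_ddtheta(lapply(split(m, m$plate_id), fit_log_linear), "NHDF")
  m2 <- m
  shifts <- expand.grid(plate_id = unique(m$plate_id), interval = 1:4)
  set.seed(1)
  shifts$c <- rnorm(nrow(shifts), 0, 0.5)
  for (r in seq_len(nrow(shifts))) {
    idx <- m2$plate_id == shifts$plate_id[r] & m2$interval == shifts$interval[r]
    m2$ocr[idx] <- m2$ocr[idx] * exp(shifts$c[r])
  }
  dd1 <- compute_ddtheta(lapply(split(m2, m2$plate_id), fit_log_linear), "NHDF")
  expect_equal(dd1$ddtheta, dd0$ddtheta, tolerance = 1e-10)
})

test_that("pooled test equals the closed form and an lm oracle", {
  set.seed(80)
  dd <- rand_ddtheta(mu = c(0, 0.2, -0.15, 0.05), n_plates = 4, sigma = 0.1)
  res <- test_biosamples(dd)

  # closed form
  mu <- tapply(dd$ddtheta, dd$biosample, mean)
  expect_equal(res$mu_hat, as.vector(mu[res$biosample]), tolerance = 1e-12)
  resid <- dd$ddtheta - mu[dd$biosample]
  s2 <- sum(resid^2) / (nrow(dd) - length(mu))
  expect_equal(unique(res$se), sqrt(s2 / 4), tolerance = 1e-12)

  # lm oracle: one-way fixed effects without intercept
  fit <- lm(ddtheta ~ 0 + biosample, data = dd)
  sm <- summary(fit)$coefficients
  rownames(sm) <- sub("^biosample", "", rownames(sm))
  expect_equal(res$mu_hat, unname(sm[res$biosample, "Estimate"]),
               tolerance = 1e-10)
  expect_equal(res$se, unname(sm[res$biosample, "Std. Error"]),
               tolerance = 1e-10)
  expect_equal(res$t, unname(sm[res$biosample, "t value"]), tolerance = 1e-10)
  expect_equal(res$p_value, unname(sm[res$biosample, "Pr(>|t|)"]),
               tolerance = 1e-10)

  # CI contains the estimate; ratio is exp(mu)
  expect_true(all(res$ci_low <= res$mu_hat & res$mu_hat <= res$ci_high))
  expect_equal(res$ratio, exp(res$mu_hat), tolerance = 1e-12)
})

test_that("constant ddtheta values give mu_hat exactly and pooled variance", {
  dd <- rbind(
    data.frame(biosample = "a", plate_id = paste0("p", 1:3), metric = "MEi",
               ddtheta = 0.3),
    data.frame(biosample = "b", plate_id = paste0("p", 1:3), metric = "MEi",
               ddtheta = c(-0.1, 0, 0.1)))
  res <- test_biosamples(dd)
  expect_equal(res$mu_hat[res$biosample == "a"], 0.3, tolerance = 1e-12)
  expect_gt(res$se[res$biosample == "a"], 0)  # variance pooled from b
})

test_that("a single-plate biosample is testable through pooled variance", {
  set.seed(81)
  dd <- rand_ddtheta(mu = c(0, 0.1, 0.3), n_plates = 3, sigma = 0.05)
  dd <- rbind(dd, data.frame(biosample = "solo", plate_id = "p1",
                             metric = "MEi", ddtheta = 0.4))
  res <- test_biosamples(dd)
  solo <- res[res$biosample == "solo", ]
  expect_equal(solo$n_plates, 1L)
  expect_true(is.finite(solo$p_value))
  # too few residual df is an error
  tiny <- rand_ddtheta(mu = 0, n_plates = 2, sigma = 0.1)
  expect_error(test_biosamples(tiny), "degrees of freedom")
})

test_that("sign coherence: negative mu means fold-change ratio below 1", {
  set.seed(82)
  for (s in 1:10) {
    dd <- rand_ddtheta(mu = rnorm(5, 0, 0.3), n_plates = 3, sigma = 0.1)
    res <- test_biosamples(dd)
    gm <- exp(tapply(dd$ddtheta, dd$biosample, mean))
    expect_equal(res$mu_hat < 0,
                 as.vector(gm[res$biosample] < 1))
  }
})

test_that("alternative and BH adjustment options behave", {
  set.seed(83)
  dd <- rand_ddtheta(mu = c(-0.3, 0, 0, 0), n_plates = 4, sigma = 0.08)
  two <- test_biosamples(dd)
  less <- test_biosamples(dd, alternative = "less")
  b1 <- two$biosample[two$mu_hat < 0][1]
  expect_lt(less$p_value[less$biosample == b1],
            two$p_value[two$biosample == b1])
  bh <- test_biosamples(dd, p_adjust = "BH")
  expect_true(all(bh$p_value >= two$p_value - 1e-12))
})

test_that("qq pairs are antisymmetric for symmetric input, flat for constants", {
  r <- c(-3, -2, -1, 1, 2, 3)
  qq <- qq_residuals(r)
  expect_equal(qq$observed, -rev(qq$observed), tolerance = 1e-12)
  expect_equal(qq$theoretical, -rev(qq$theoretical), tolerance = 1e-12)

  qq0 <- qq_residuals(rep(0.5, 10))
  expect_equal(qq0$observed, rep(0, 10))

  set.seed(84)
  qqn <- qq_residuals(rnorm(200))
  expect_lt(max(abs(qqn$observed - qqn$theoretical)), 0.35)
})
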