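canonical_fit <- function() {
  theta <- list(A = log(c(100, 40, 150, 20)))
  fit_log_linear(exact_plate(theta, beta = list(A = c(0.1, -0.1))))
}

test_that("ratio metrics match hand arithmetic on the canonical profile", {
  rm <- compute_ratio_metrics(canonical_fit())
  expect_equal(rm$EI_prop, 0.8, tolerance = 1e-10)
  expect_equal(rm$AI_prop, 0.6, tolerance = 1e-10)
  expect_equal(rm$EAi_prop, 0.5, tolerance = 1e-10)
  expect_equal(rm$MI_fold, 1.5, tolerance = 1e-10)
  expect_equal(rm$MEi_fold, 7.5, tolerance = 1e-10)

  # theta_M = theta_I means no spare capacity
  f2 <- fit_log_linear(exact_plate(list(A = log(c(100, 40, 100, 20)))))
  expect_equal(compute_ratio_metrics(f2)$MI_fold, 1, tolerance = 1e-10)
})

test_that("bioenergetic measures match hand arithmetic and identities", {
  bm <- compute_bioenergetic_measures(canonical_fit())
  expect_equal(bm$basal, 80, tolerance = 1e-8)
  expect_equal(bm$atp_linked, 60, tolerance = 1e-8)
  expect_equal(bm$proton_leak, 20, tolerance = 1e-8)
  expect_equal(bm$spare, 50, tolerance = 1e-8)
  expect_equal(bm$maximal, 130, tolerance = 1e-8)
  expect_equal(bm$nonmito, 20, tolerance = 1e-8)

  # all-equal theta: every difference-based measure is 0
  f0 <- fit_log_linear(exact_plate(list(A = rep(log(50), 4))))
  bm0 <- compute_bioenergetic_measures(f0)
  expect_equal(unlist(bm0[, c("basal", "atp_linked", "proton_leak",
                              "spare", "maximal")]),
               rep(0, 5), tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(bm0$nonmito, 50, tolerance = 1e-8)
})

test_that("ratio/measure duality holds on arbitrary fits", {
  for (s in 1:10) {
    fit <- fit_log_linear(rand_plate(200 + s, n_bios = 2L, wells = 3L))
    mm <- ocr_metrics(fit)
    o1 <- mm$basal + mm$nonmito                      # = OCR1
    expect_equal(mm$basal / o1, mm$EI_prop, tolerance = 1e-10)
    expect_equal(mm$maximal / mm$nonmito, mm$MEi_fold - 1, tolerance = 1e-10)
  }
})

test_that("ratio metrics are invariant to a constant shift of all theta", {
  m <- rand_plate(31, n_bios = 2L, wells = 3L)
  fit1 <- fit_log_linear(m)
  m2 <- m
  m2$ocr <- m2$ocr * exp(0.4)                       # shifts every theta by 0.4
  fit2 <- fit_log_linear(m2)
  expect_equal(compute_ratio_metrics(fit2)[, -(1:2)],
               compute_ratio_metrics(fit1)[, -(1:2)], tolerance = 1e-10)
})

test_that("log-sd to CV conversion reproduces printed per-interval values", {
  sig <- c(0.10, 0.13, 0.12, 0.16)
  expect_equal(round(100 * log_sd_to_cv(sig)), c(11, 14, 13, 17))
  expect_equal(log_sd_to_cv(0), 0)
})

test_that("within-plate CV recovers the generating log-scale sd", {
  # lognormal simulation: median sigma_hat should sit near sigma_noise
  sims <- lapply(1:20, function(s) {
    simulate_plates(sim_config(n_plates = 1, biosamples = character(0),
                               sigma_noise = 0.2, sigma_well = 0,
                               sigma_plate_interval = 0),
                    seed = 400 + s)$plates$measurements
  })
  for (i in seq_along(sims)) sims[[i]]$plate_id <- sprintf("p%02d", i)
  m <- do.call(rbind, sims)
  cv <- within_plate_cv(m, biosample = "NHDF")
  expect_equal(nrow(cv), 4L)
  expect_true(all(abs(cv$sigma_median - 0.2) < 0.03))
  expect_equal(cv$cv, exp(cv$sigma_median) - 1)
})

test_that("across-plate CV matches hand arithmetic and contracts", {
  mx <- data.frame(plate_id = c("p1", "p2"), biosample = "A",
                   basal = c(80, 120))
  cv <- across_plate_cv(mx, measures = "basal")
  expect_equal(cv$cv, sd(c(80, 120)) / 100, tolerance = 1e-12)
  expect_equal(cv$cv, 0.2828427, tolerance = 1e-6)

  # identical values across plates: CV = 0
  cv0 <- across_plate_cv(data.frame(plate_id = c("p1", "p2"),
                                    biosample = "A", basal = c(90, 90)),
                         measures = "basal")
  expect_equal(cv0$cv, 0)

  # non-positive mean: undefined
  cvn <- across_plate_cv(data.frame(plate_id = c("p1", "p2"),
                                    biosample = "A", spare = c(-5, 3)),
                         measures = "spare")
  expect_true(is.na(cvn$cv))
})

test_that("uniformly lower CVs yield a significant one-sided Wilcoxon", {
  set.seed(5)
  bios <- paste0("b", 1:8)
  cv_b <- data.frame(biosample = bios, measure = "basal",
                     n_plates = 3L, cv = runif(8, 0.2, 0.4))
  cv_a <- cv_b
  cv_a$cv <- cv_b$cv * 0.6
  res <- compare_cv(cv_a, cv_b)
  expect_lt(res$p_value, 0.05)
  res_rev <- compare_cv(cv_b, cv_a)
  expect_gt(res_rev$p_value, 0.5)
})

test_that("positional diagnostics recover injected edge effects", {
  # full-plate single biosample so the interval effect absorbs the same
  # mean everywhere and row/column contrasts are interpretable
  full_cfg <- sim_config(n_plates = 1, biosamples = character(0),
                         wells_per_biosample = 92L)

  # null: no positional structure; medians pooled over plates stay small
  fits <- lapply(1:20, function(s) {
    fit_log_linear(simulate_plates(full_cfg, seed = 500 + s)$plates$measurements)
  })
  pd0 <- positional_diagnostics(fits)
  expect_lt(max(abs(c(pd0$rows$median_deviation,
                      pd0$cols$median_deviation))), 0.02)

  # edge rows scaled by e^-0.13 sit ~0.13 below the plate middle
  sim <- simulate_plates(full_cfg, seed = 42)
  m <- sim$plates$measurements
  edge <- grepl("^(A|H)", m$well) & !m$is_blank
  m$ocr[edge] <- m$ocr[edge] * exp(-0.13)
  pd <- positional_diagnostics(fit_log_linear(m))
  a_row <- pd$rows$median_deviation[pd$rows$level == "A"]
  mid <- median(pd$rows$median_deviation[pd$rows$level %in% c("C", "D", "E", "F")])
  expect_lt(abs((a_row - mid) - (-0.13)), 0.04)
  # an interval-consistent edge effect cancels in the log-ratio metrics
  a_metric <- pd$metric_rows$median_deviation[pd$metric_rows$level == "A"]
  expect_lt(max(abs(a_metric)), 0.06)

  # single-row plate: column summary informative, row summary degenerate
  sim5 <- simulate_plates(sim_config(n_plates = 1), seed = 43)
  one_row <- sim5$plates$measurements
  one_row <- one_row[grepl("^B", one_row$well), ]
  pd1 <- positional_diagnostics(fit_log_linear(one_row))
  expect_equal(nrow(pd1$rows), 1L)
  expect_gt(nrow(pd1$cols), 1L)
})
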