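#' Per-plate log-ratio differences versus the plate-matched control
#'
#' The unit of cross-plate testing is the double difference
#' \eqn{\Delta\Delta\theta_{b,p}}: the difference of a log OCR ratio
#' between biosample `b` and the control `c` on the same plate `p`.
#' Because both terms come from the same plate, any additive
#' (plate, interval) shift common to all wells cancels exactly. The five
#' tested differences, one per ratio metric, are:
#' \itemize{
#'   \item `EI`:  (theta_I,b - theta_Ei,b) - (theta_I,c - theta_Ei,c)
#'   \item `AI`:  (theta_I,b - theta_Ai,b) - (theta_I,c - theta_Ai,c)
#'   \item `EAi`: (theta_Ai,b - theta_Ei,b) - (theta_Ai,c - theta_Ei,c)
#'   \item `MI`:  (theta_M,b - theta_I,b) - (theta_M,c - theta_I,c)
#'   \item `MEi`: (theta_M,b - theta_Ei,b) - (theta_M,c - theta_Ei,c)
#' }
#'
#' @param fits an `ocr_fit` or list of per-plate fits (outlier-cleaned).
#' @param control control biosample name.
#' @return data.frame `biosample`, `plate_id`, `metric`, `ddtheta`.
#'   Plates lacking the control contribute nothing (with a message).
#' @export
compute_ddtheta <- function(fits, control) {
  if (inherits(fits, "ocr_fit")) fits <- list(fits)
  out <- list()
  for (f in fits) {
    th <- theta_wide(f)
    ci <- which(th$biosample == control)
    if (!length(ci)) {
      message("plate ", f$plate_id, " has no control '", control,
              "'; skipped for testing")
      next
    }
    ctl <- th[ci, , drop = FALSE]
    ratio <- function(r, int_a, int_b) {
      r[[paste0("th", int_a)]] - r[[paste0("th", int_b)]]
    }
    for (bi in setdiff(seq_len(nrow(th)), ci)) {
      b <- th[bi, , drop = FALSE]
      vals <- c(
        EI  = ratio(b, 1, 4) - ratio(ctl, 1, 4),
        AI  = ratio(b, 1, 2) - ratio(ctl, 1, 2),
        EAi = ratio(b, 2, 4) - ratio(ctl, 2, 4),
        MI  = ratio(b, 3, 1) - ratio(ctl, 3, 1),
        MEi = ratio(b, 3, 4) - ratio(ctl, 3, 4))
      out[[length(out) + 1L]] <- data.frame(
        biosample = b$biosample, plate_id = f$plate_id,
        metric = names(vals), ddtheta = unname(vals),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cross-plate statistical test of biosamples versus control
#'
#' For each ratio metric, fits the fixed-effects model
#' \eqn{\Delta\Delta\theta_{b,p} = \mu_b + \epsilon_{b,p}} jointly over
#' all biosamples by least squares (equivalently, \eqn{\hat\mu_b} is the
#' across-plate mean and the error variance is pooled over the complete
#' data set: \eqn{\hat\sigma^2 = \sum_{b,p} (\Delta\Delta\theta_{b,p} -
#' \hat\mu_b)^2 / (N - B)}). Pooling gives a robust variance estimate even
#' for biosamples seeded on few plates. Each \eqn{\mu_b} is tested against
#' 0 with a Student t test on \eqn{N - B} degrees of freedom, and a
#' confidence interval is formed on the same pooled scale.
#'
#' @param ddtheta output of [compute_ddtheta()].
#' @param conf_level confidence level for the intervals (default 0.95).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @param p_adjust multiple-testing adjustment across biosamples within a
#'   metric, passed to [stats::p.adjust()]; default `"none"` (raw
#'   p-values), `"BH"` available.
#' @return data.frame with one row per (metric, biosample): `mu_hat`,
#'   `ratio` (`exp(mu_hat)`, the natural-scale fold-change ratio vs
#'   control), `se`, `t`, `df`, `p_value`, `ci_low`, `ci_high`,
#'   `n_plates`. The per-observation residuals are attached as
#'   `attr(, "residuals")`.
#' @examples
#' sim <- simulate_plates(sim_config(n_plates = 3), seed = 1)
#' fits <- lapply(split(sim$plates$measurements,
#'                      sim$plates$measurements$plate_id), fit_log_linear)
#' dd <- compute_ddtheta(fits, control = "NHDF")
#' head(test_biosamples(dd))
#' @export
test_biosamples <- function(ddtheta, conf_level = 0.95,
                            alternative = c("two.sided", "less", "greater"),
                            p_adjust = "none") {
  alternative <- match.arg(alternative)
  ddtheta <- as.data.frame(ddtheta)
  out <- list()
  resid_out <- list()
  for (mt in unique(ddtheta$metric)) {
    d <- ddtheta[ddtheta$metric == mt, , drop = FALSE]
    mu <- tapply(d$ddtheta, d$biosample, mean)
    n <- tapply(d$ddtheta, d$biosample, length)
    N <- nrow(d)
    B <- length(mu)
    df <- N - B
    if (df < 2L) {
      stop("fewer than 2 residual degrees of freedom for metric ", mt,
           "; seed biosamples on more plates", call. = FALSE)
    }
    res <- d$ddtheta - mu[d$biosample]
    sigma2 <- sum(res^2) / df
    se <- sqrt(sigma2 / n)
    tval <- as.numeric(mu) / se
    p <- switch(alternative,
                two.sided = 2 * stats::pt(-abs(tval), df),
                less = stats::pt(tval, df),
                greater = stats::pt(tval, df, lower.tail = FALSE))
    p <- stats::p.adjust(p, method = p_adjust)
    q <- stats::qt(1 - (1 - conf_level) / 2, df)
    out[[length(out) + 1L]] <- data.frame(
      metric = mt, biosample = names(mu),
      mu_hat = as.numeric(mu), ratio = exp(as.numeric(mu)),
      se = as.numeric(se), t = tval, df = df, p_value = p,
      ci_low = as.numeric(mu) - q * as.numeric(se),
      ci_high = as.numeric(mu) + q * as.numeric(se),
      n_plates = as.integer(n),
      stringsAsFactors = FALSE)
    resid_out[[length(resid_out) + 1L]] <- data.frame(
      metric = mt, biosample = d$biosample, plate_id = d$plate_id,
      residual = res, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "residuals") <- do.call(rbind, resid_out)
  class(res) <- c("ocr_test_result", class(res))
  res
}

#' QQ pairs of standardized test residuals
#'
#' Produces (theoretical, observed) standard-normal quantile pairs of the
#' standardized residuals \eqn{\epsilon_{b,p}} of the cross-plate model,
#' the diagnostic for its normality assumption.
#'
#' @param residuals numeric vector, or the data.frame attached to a
#'   [test_biosamples()] result (column `residual` is used).
#' @return data.frame `theoretical`, `observed`, in increasing order.
#' @export
qq_residuals <- function(residuals) {
  if (is.data.frame(residuals)) residuals <- residuals$residual
  r <- residuals[is.finite(residuals)]
  n <- length(r)
  s <- stats::sd(r)
  z <- if (is.na(s) || s == 0) rep(0, n) else (r - mean(r)) / s
  data.frame(theoretical = stats::qnorm(stats::ppoints(n)),
             observed = sort(z))
}
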