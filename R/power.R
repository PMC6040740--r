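#' Minimal detectable relative difference
#'
#' Converts the standard deviation of the cross-plate test residuals
#' \eqn{\epsilon_{b,p}} into the smallest relative (natural-scale)
#' difference detectable at the given significance level with `n_plates`
#' plate replicates:
#' \deqn{mde = \exp\!\left(z \cdot \frac{sd(\epsilon)}{\sqrt{n}}\right) - 1,}
#' with `z = 1.96`, the (approximate) 97.5th standard-normal percentile for
#' a two-sided 5% level. Set `exact_t = TRUE` to use the Student-t
#' quantile on `df` degrees of freedom instead.
#'
#' @param sd_resid standard deviation of the log-ratio residuals
#'   (log scale, >= 0).
#' @param n_plates number of plate replicates per comparison (default 3).
#' @param z normal quantile (default 1.96).
#' @param exact_t use `qt(1 - alpha/2, df)` in place of `z`.
#' @param alpha significance level (used only with `exact_t`).
#' @param df degrees of freedom for the t quantile.
#' @return minimal detectable relative difference (unitless fraction).
#' @examples
#' minimal_detectable_effect(0.0786, n_plates = 3)  # ~0.093
#' @export
minimal_detectable_effect <- function(sd_resid, n_plates = 3L, z = 1.96,
                                      exact_t = FALSE, alpha = 0.05,
                                      df = NULL) {
  if (any(n_plates < 1L)) stop("n_plates must be >= 1", call. = FALSE)
  if (any(sd_resid < 0)) stop("sd_resid must be >= 0", call. = FALSE)
  if (exact_t) {
    if (is.null(df)) stop("df required when exact_t = TRUE", call. = FALSE)
    z <- stats::qt(1 - alpha / 2, df)
  }
  exp(z * sd_resid / sqrt(n_plates)) - 1
}

#' Residual-sd power curve by well subsampling
#'
#' Emulates reducing the number of replicate wells seeded per biosample:
#' for each count in `wells_grid` and each of `reps` random subsamples
#' (without replacement) of that many wells per (plate, biosample), the
#' full estimation pipeline (outlier removal, per-plate fits, log-ratio
#' differences vs control, pooled cross-plate model) is re-run and the
#' pooled residual sd per metric recorded, together with the minimal
#' detectable effect at `n_plates` plates.
#'
#' @param plates an `ocr_plateset` with the control and repeated
#'   biosamples.
#' @param wells_grid well counts to subsample to (default 4..16 by 2).
#' @param reps random subsamples per count (default 10).
#' @param seed RNG seed; the same seed reproduces the curve exactly.
#' @param n_plates plate count for the minimal-detectable-effect mapping
#'   (default 3).
#' @param outlier_removal run the two outlier passes on each subsample
#'   (default TRUE).
#' @return data.frame of class `ocr_power_curve`: `wells`, `rep`,
#'   `metric`, `sd_resid`, `mde`.
#' @export
subsample_power_curve <- function(plates,
                                  wells_grid = c(4L, 6L, 8L, 10L, 12L, 14L, 16L),
                                  reps = 10L, seed = NULL, n_plates = 3L,
                                  outlier_removal = TRUE) {
  stopifnot(inherits(plates, "ocr_plateset"))
  if (!is.null(seed)) set.seed(seed)
  m <- plates$measurements[!plates$measurements$is_blank, , drop = FALSE]
  control <- plates$control
  out <- list()
  for (nw in wells_grid) {
    for (r in seq_len(reps)) {
      keep_keys <- character(0)
      pb <- unique(m[, c("plate_id", "biosample")])
      for (i in seq_len(nrow(pb))) {
        ws <- unique(m$well[m$plate_id == pb$plate_id[i] &
                              m$biosample == pb$biosample[i]])
        take <- if (length(ws) > nw) sample(ws, nw) else ws
        keep_keys <- c(keep_keys, paste(pb$plate_id[i], take))
      }
      sub <- m[paste(m$plate_id, m$well) %in% keep_keys, , drop = FALSE]
      fits <- lapply(split(sub, sub$plate_id), function(pm) {
        if (outlier_removal) remove_outliers(pm)$fit else fit_log_linear(pm)
      })
      dd <- compute_ddtheta(fits, control = control)
      tst <- test_biosamples(dd)
      res <- attr(tst, "residuals")
      for (mt in unique(res$metric)) {
        df_mt <- unique(tst$df[tst$metric == mt])
        sdr <- sqrt(sum(res$residual[res$metric == mt]^2) / df_mt)
        out[[length(out) + 1L]] <- data.frame(
          wells = nw, rep = r, metric = mt, sd_resid = sdr,
          mde = minimal_detectable_effect(sdr, n_plates = n_plates),
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("ocr_power_curve", class(res))
  res
}
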