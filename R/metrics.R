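#' Ratio-based OCR metrics from a within-plate fit
#'
#' Because noise and systematic effects on OCR are multiplicative,
#' comparisons are best made on ratios, i.e. differences of the log-scale
#' interval effects. With \eqn{\theta_I, \theta_{Ai}, \theta_M, \theta_{Ei}}
#' the interval-1..4 effects of a biosample:
#' \itemize{
#'   \item `EI_prop`  = 1 - exp(theta_Ei - theta_I): ETC-dependent OCR
#'     proportion (ratio analogue of basal respiration);
#'   \item `AI_prop`  = 1 - exp(theta_Ai - theta_I): ATPase-dependent OCR
#'     proportion (ATP-linked respiration);
#'   \item `EAi_prop` = 1 - exp(theta_Ei - theta_Ai): ETC-dependent
#'     proportion of ATPase-independent OCR (proton leak);
#'   \item `MI_fold`  = exp(theta_M - theta_I): maximal over initial fold
#'     change (spare capacity);
#'   \item `MEi_fold` = exp(theta_M - theta_Ei): maximal over
#'     ETC-independent fold change (maximal respiration).
#' }
#'
#' @param fit an `ocr_fit`.
#' @return data.frame with one row per biosample on the plate.
#' @export
compute_ratio_metrics <- function(fit) {
  th <- theta_wide(fit)
  data.frame(
    plate_id = th$plate_id,
    biosample = th$biosample,
    EI_prop = 1 - exp(th$th4 - th$th1),
    AI_prop = 1 - exp(th$th2 - th$th1),
    EAi_prop = 1 - exp(th$th4 - th$th2),
    MI_fold = exp(th$th3 - th$th1),
    MEi_fold = exp(th$th3 - th$th4),
    stringsAsFactors = FALSE)
}

#' Natural-scale bioenergetic measures from a within-plate fit
#'
#' Scaling the interval effects back to the natural scale,
#' \eqn{OCR_i = exp(\hat\theta_i)}, gives the six classical bioenergetic
#' measures in pmol/min: basal respiration (OCR1 - OCR4), ATP-linked
#' respiration (OCR1 - OCR2), proton leak (OCR2 - OCR4), spare capacity
#' (OCR3 - OCR1), maximal respiration (OCR3 - OCR4) and non-mitochondrial
#' respiration (OCR4).
#'
#' @param fit an `ocr_fit`.
#' @return data.frame with one row per biosample on the plate.
#' @export
compute_bioenergetic_measures <- function(fit) {
  th <- theta_wide(fit)
  o1 <- exp(th$th1); o2 <- exp(th$th2); o3 <- exp(th$th3); o4 <- exp(th$th4)
  data.frame(
    plate_id = th$plate_id,
    biosample = th$biosample,
    basal = o1 - o4,
    atp_linked = o1 - o2,
    proton_leak = o2 - o4,
    spare = o3 - o1,
    maximal = o3 - o4,
    nonmito = o4,
    stringsAsFactors = FALSE)
}

#' Combined metric table (ratios + natural-scale measures)
#'
#' @param fit an `ocr_fit`, or a list of them (one per plate).
#' @return data.frame `plate_id`, `biosample`, the five ratio metrics and
#'   the six bioenergetic measures.
#' @export
ocr_metrics <- function(fit) {
  if (inherits(fit, "ocr_fit")) fit <- list(fit)
  out <- lapply(fit, function(f) {
    merge(compute_ratio_metrics(f), compute_bioenergetic_measures(f),
          by = c("plate_id", "biosample"), sort = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

theta_wide <- function(fit) {
  stopifnot(inherits(fit, "ocr_fit"))
  th <- fit$theta
  bs <- unique(th$biosample)
  out <- data.frame(plate_id = fit$plate_id, biosample = bs,
                    stringsAsFactors = FALSE)
  for (i in 1:4) {
    v <- th$theta[match(paste(bs, i), paste(th$biosample, th$interval))]
    if (any(is.na(v))) {
      stop("missing interval effect for (",
           paste(bs[is.na(v)], collapse = ", "), ", interval ", i, ")",
           call. = FALSE)
    }
    out[[paste0("th", i)]] <- v
  }
  out
}

#' Natural-scale CV from a log-scale standard deviation
#'
#' For small-to-moderate log-scale spread the coefficient of variation on
#' the natural scale is approximated by `exp(sigma) - 1`.
#'
#' @param sigma standard deviation of log OCR.
#' @return approximate natural-scale CV (unitless fraction).
#' @examples
#' log_sd_to_cv(0.16)  # ~0.17
#' @export
log_sd_to_cv <- function(sigma) {
  stopifnot(all(sigma >= 0))
  exp(sigma) - 1
}

#' Within-plate coefficient of variation between wells
#'
#' For each plate and interval, the standard deviation
#' \eqn{\sigma_{p,i}} of log OCR across all included observations of a
#' biosample is computed; the median across plates gives one
#' \eqn{\bar\sigma_i} per interval, converted to a natural-scale CV via
#' [log_sd_to_cv()]. Plates on which the biosample has fewer than two
#' wells are skipped.
#'
#' @param plates an `ocr_plateset` or a measurements data.frame (typically
#'   outlier-cleaned).
#' @param biosample which biosample to summarise (default: the plate set's
#'   control).
#' @return data.frame `interval`, `n_plates`, `sigma_median`, `cv`.
#' @export
within_plate_cv <- function(plates, biosample = NULL) {
  if (inherits(plates, "ocr_plateset")) {
    if (is.null(biosample)) biosample <- plates$control
    m <- plates$measurements
  } else {
    m <- as.data.frame(plates)
    if (is.null(biosample)) stop("biosample must be given", call. = FALSE)
  }
  m <- drop_blank(m)
  m <- m[m$biosample == biosample, , drop = FALSE]
  if (!nrow(m)) stop("biosample ", biosample, " not present", call. = FALSE)
  out <- lapply(sort(unique(m$interval)), function(i) {
    mi <- m[m$interval == i, , drop = FALSE]
    sig <- vapply(split(mi, mi$plate_id), function(p) {
      if (length(unique(p$well)) < 2L) return(NA_real_)
      stats::sd(log(p$ocr))
    }, numeric(1))
    sig <- sig[!is.na(sig)]
    data.frame(interval = i, n_plates = length(sig),
               sigma_median = stats::median(sig),
               cv = log_sd_to_cv(stats::median(sig)))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Across-plate coefficient of variation of bioenergetic measures
#'
#' CV = sd/mean of each natural-scale measure across the plates on which a
#' biosample was repeated. Used to benchmark estimation methods (Extreme
#' Differences vs log-linear vs full outlier-removed vs plate-corrected).
#'
#' @param metrics a metric table from [ocr_metrics()] (or the ED summary in
#'   the same schema), with one row per (plate, biosample).
#' @param measures which measure columns to summarise.
#' @return long data.frame `biosample`, `measure`, `n_plates`, `cv`;
#'   `cv` is `NA` when the across-plate mean is not positive.
#' @export
across_plate_cv <- function(metrics,
                            measures = c("basal", "atp_linked", "proton_leak",
                                         "spare", "maximal", "nonmito")) {
  metrics <- as.data.frame(metrics)
  out <- list()
  for (b in unique(metrics$biosample)) {
    mb <- metrics[metrics$biosample == b, , drop = FALSE]
    if (nrow(mb) < 2L) next
    for (ms in measures) {
      v <- mb[[ms]]
      cv <- if (mean(v) > 0) stats::sd(v) / mean(v) else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        biosample = b, measure = ms, n_plates = nrow(mb), cv = cv,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Paired one-sided comparison of across-plate CVs between two methods
#'
#' Tests whether method A yields systematically lower across-plate CVs
#' than method B with a one-sided paired Wilcoxon signed-rank test over
#' biosamples, per measure.
#'
#' @param cv_a,cv_b outputs of [across_plate_cv()] for the two methods.
#' @return data.frame `measure`, `n`, `p_value` (alternative: A < B).
#' @export
compare_cv <- function(cv_a, cv_b) {
  out <- list()
  for (ms in unique(cv_a$measure)) {
    a <- cv_a[cv_a$measure == ms, ]
    b <- cv_b[cv_b$measure == ms, ]
    common <- intersect(a$biosample, b$biosample)
    va <- a$cv[match(common, a$biosample)]
    vb <- b$cv[match(common, b$biosample)]
    ok <- !is.na(va) & !is.na(vb)
    p <- if (sum(ok) >= 2L) {
      stats::wilcox.test(va[ok], vb[ok], paired = TRUE,
                         alternative = "less", exact = FALSE)$p.value
    } else NA_real_
    out[[length(out) + 1L]] <- data.frame(measure = ms, n = sum(ok),
                                          p_value = p)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Positional (edge-effect) diagnostics
#'
#' Summarises the log-OCR deviations `y - theta_hat` by plate row and
#' column, pooled over plates and intervals, to reveal positional effects
#' (measurements tend to run lower at plate edges). Because the ratio
#' metrics are differences of log OCR within a well, a positional effect
#' that is consistent across intervals cancels in them; the `metric_rows` /
#' `metric_cols` summaries check this on the per-well interval-mean
#' deviations (e.g. `MI` column = mean deviation in interval 3 minus
#' interval 1 for that well).
#'
#' @param fits an `ocr_fit` or list of fits.
#' @return list with `rows`, `cols` (median deviation by plate row /
#'   column) and `metric_rows`, `metric_cols` (median per-well log-ratio
#'   deviation by row / column).
#' @export
positional_diagnostics <- function(fits) {
  if (inherits(fits, "ocr_fit")) fits <- list(fits)
  d <- do.call(rbind, lapply(fits, function(f) f$data))
  d$row <- well_row(d$well)
  d$col <- well_col(d$well)

  med_by <- function(x, g) {
    v <- tapply(x, g, stats::median)
    data.frame(level = names(v), median_deviation = as.numeric(v),
               stringsAsFactors = FALSE)
  }
  rows <- med_by(d$deviation, d$row)
  cols <- med_by(d$deviation, d$col)
  cols <- cols[order(as.integer(cols$level)), ]
  rownames(cols) <- NULL

  # per-well mean deviation per interval, then log-ratio contrasts
  agg <- stats::aggregate(
    list(dbar = d$deviation),
    by = list(plate_id = d$plate_id, well = d$well, row = d$row,
              col = d$col, interval = d$interval),
    FUN = mean)
  wkey <- paste(agg$plate_id, agg$well)
  wide <- data.frame(key = unique(wkey), stringsAsFactors = FALSE)
  for (i in 1:4) {
    ai <- agg[agg$interval == i, ]
    wide[[paste0("d", i)]] <- ai$dbar[match(wide$key, paste(ai$plate_id, ai$well))]
  }
  first <- agg[!duplicated(wkey), ]
  wide$row <- first$row[match(wide$key, paste(first$plate_id, first$well))]
  wide$col <- first$col[match(wide$key, paste(first$plate_id, first$well))]
  wide$EI <- wide$d1 - wide$d4
  wide$AI <- wide$d1 - wide$d2
  wide$EAi <- wide$d2 - wide$d4
  wide$MI <- wide$d3 - wide$d1
  wide$MEi <- wide$d3 - wide$d4

  metric_summ <- function(g) {
    out <- NULL
    for (mc in c("EI", "AI", "EAi", "MI", "MEi")) {
      v <- tapply(wide[[mc]], wide[[g]], stats::median, na.rm = TRUE)
      df <- data.frame(level = names(v), metric = mc,
                       median_deviation = as.numeric(v),
                       stringsAsFactors = FALSE)
      out <- rbind(out, df)
    }
    out
  }
  list(rows = rows, cols = cols,
       metric_rows = metric_summ("row"), metric_cols = metric_summ("col"))
}
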