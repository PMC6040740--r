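#' Extreme Differences (vendor-default) bioenergetic measures
#'
#' The vendor-style baseline estimator works per well on the raw OCR time
#' series: in interval 1 it takes the OCR of the last measurement, in
#' intervals 2 and 4 the minimum, and in interval 3 the maximum; the six
#' bioenergetic measures are then natural-scale differences of these
#' extremes. Per (plate, biosample) it reports the mean across wells with
#' sd and sem. It is defined on raw (pre-outlier-removal) data; by default
#' QC-filtered wells are used for benchmark parity, pass the unfiltered
#' plate set to change that.
#'
#' @param plates an `ocr_plateset` or measurements data.frame.
#' @return list of class `ocr_ed` with `wells` (per-well extremes and
#'   measures), `summary` (long data.frame `plate_id`, `biosample`,
#'   `measure`, `mean`, `sd`, `sem`, `n_wells`), and `skipped` (wells
#'   lacking an interval).
#' @export
ed_measures <- function(plates) {
  m <- if (inherits(plates, "ocr_plateset")) plates$measurements else
    as.data.frame(plates)
  m <- drop_blank(m)
  wells <- unique(m[, c("plate_id", "well", "biosample")])
  rows <- list()
  skipped <- list()
  for (i in seq_len(nrow(wells))) {
    wi <- m[m$plate_id == wells$plate_id[i] & m$well == wells$well[i], ]
    if (length(unique(wi$interval)) < 4L) {
      skipped[[length(skipped) + 1L]] <- wells[i, c("plate_id", "well")]
      next
    }
    i1 <- wi[wi$interval == 1L, ]
    e1 <- i1$ocr[which.max(i1$time_point)]   # last measurement of interval 1
    e2 <- min(wi$ocr[wi$interval == 2L])
    e3 <- max(wi$ocr[wi$interval == 3L])
    e4 <- min(wi$ocr[wi$interval == 4L])
    rows[[length(rows) + 1L]] <- data.frame(
      plate_id = wells$plate_id[i], well = wells$well[i],
      biosample = wells$biosample[i],
      e1 = e1, e2 = e2, e3 = e3, e4 = e4,
      basal = e1 - e4, atp_linked = e1 - e2, proton_leak = e2 - e4,
      spare = e3 - e1, maximal = e3 - e4, nonmito = e4,
      stringsAsFactors = FALSE)
  }
  wtab <- do.call(rbind, rows)
  rownames(wtab) <- NULL
  measures <- c("basal", "atp_linked", "proton_leak", "spare", "maximal",
                "nonmito")
  summ <- list()
  for (key in unique(paste(wtab$plate_id, wtab$biosample, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1L]]
    wb <- wtab[wtab$plate_id == parts[1L] & wtab$biosample == parts[2L], ]
    for (ms in measures) {
      v <- wb[[ms]]
      summ[[length(summ) + 1L]] <- data.frame(
        plate_id = parts[1L], biosample = parts[2L], measure = ms,
        mean = mean(v), sd = stats::sd(v),
        sem = stats::sd(v) / sqrt(length(v)), n_wells = length(v),
        stringsAsFactors = FALSE)
    }
  }
  summary <- do.call(rbind, summ)
  rownames(summary) <- NULL
  structure(list(wells = wtab, summary = summary,
                 skipped = if (length(skipped)) do.call(rbind, skipped) else NULL),
            class = "ocr_ed")
}

#' Metric table from Extreme Differences summaries
#'
#' Reshapes the per-(plate, biosample) ED means into the wide schema of
#' [ocr_metrics()] (measure columns only; ratio columns are not defined
#' for this estimator).
#'
#' @param ed an `ocr_ed` from [ed_measures()].
#' @return data.frame `plate_id`, `biosample`, six measure columns.
#' @export
ed_metric_table <- function(ed) {
  stopifnot(inherits(ed, "ocr_ed"))
  s <- ed$summary
  keys <- unique(s[, c("plate_id", "biosample")])
  out <- keys
  for (ms in unique(s$measure)) {
    si <- s[s$measure == ms, ]
    out[[ms]] <- si$mean[match(paste(keys$plate_id, keys$biosample),
                               paste(si$plate_id, si$biosample))]
  }
  rownames(out) <- NULL
  out
}

#' Within-plate Wilcoxon test on per-well ED measures
#'
#' Two-sided Wilcoxon rank-sum test comparing the per-well values of one
#' bioenergetic measure between a biosample and the control, separately on
#' each plate where both are present. This is the vendor-style
#' single-plate test; conclusions from it can disagree across plates.
#'
#' @param ed an `ocr_ed`.
#' @param biosample,control the two groups to compare.
#' @param measure which measure column (default `"maximal"`).
#' @return data.frame `plate_id`, `n_biosample`, `n_control`, `p_value`
#'   (`NA` when either group has fewer than 2 wells on the plate).
#' @export
ed_within_plate_test <- function(ed, biosample, control,
                                 measure = "maximal") {
  stopifnot(inherits(ed, "ocr_ed"))
  w <- ed$wells
  out <- list()
  for (p in unique(w$plate_id[w$biosample == biosample])) {
    vb <- w[w$plate_id == p & w$biosample == biosample, measure]
    vc <- w[w$plate_id == p & w$biosample == control, measure]
    pv <- if (length(vb) >= 2L && length(vc) >= 2L) {
      suppressWarnings(stats::wilcox.test(vb, vc)$p.value)
    } else NA_real_
    out[[length(out) + 1L]] <- data.frame(
      plate_id = p, n_biosample = length(vb), n_control = length(vc),
      p_value = pv, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Across-plate Wilcoxon test on plate-averaged ED measures
#'
#' The multi-plate averaging baseline: per-plate means of a measure for
#' biosample and control are paired by plate and compared with an exact
#' two-sided Wilcoxon signed-rank test. With fewer than 5 plates the
#' exact two-sided signed-rank test cannot reach p < 0.05 (its floor at
#' n = 4 is 0.125), so such results are flagged underpowered.
#'
#' @inheritParams ed_within_plate_test
#' @param alternative passed to [stats::wilcox.test()].
#' @return list with `p_value`, `n_plates`, `underpowered` (TRUE when
#'   `n_plates < 5`), and `plate_means` (the paired values).
#' @export
ed_across_plate_test <- function(ed, biosample, control,
                                 measure = "maximal",
                                 alternative = "two.sided") {
  stopifnot(inherits(ed, "ocr_ed"))
  s <- ed$summary[ed$summary$measure == measure, ]
  sb <- s[s$biosample == biosample, ]
  sc <- s[s$biosample == control, ]
  common <- intersect(sb$plate_id, sc$plate_id)
  if (length(common) < 2L) {
    stop("biosample and control share fewer than 2 plates", call. = FALSE)
  }
  vb <- sb$mean[match(common, sb$plate_id)]
  vc <- sc$mean[match(common, sc$plate_id)]
  pv <- if (all(vb == vc)) 1 else suppressWarnings(
    stats::wilcox.test(vb, vc, paired = TRUE,
                       alternative = alternative)$p.value)
  list(p_value = pv, n_plates = length(common),
       underpowered = length(common) < 5L,
       plate_means = data.frame(plate_id = common, biosample = vb,
                                control = vc, stringsAsFactors = FALSE))
}
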