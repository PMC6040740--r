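#' Run the full OCR estimation and testing pipeline
#'
#' Chains the whole analysis: interval-ordering QC, per-plate log-linear
#' fits with two-level outlier removal, optional control-anchored
#' plate-interval correction, metric tables, and cross-plate testing of
#' every biosample against the plate-matched control.
#'
#' Method variants:
#' \describe{
#'   \item{`"OCR-Stats"`}{log-linear fit + well and point outlier removal
#'     (the default).}
#'   \item{`"OCR-PE"`}{OCR-Stats plus plate-interval correction; the
#'     control is excluded from metric/CV output (it anchors the
#'     correction).}
#'   \item{`"LL"`}{log-linear fit only, no outlier removal.}
#'   \item{`"ED"`}{the Extreme Differences baseline; produces the measure
#'     table in the same schema (no ratio columns, no model test).}
#' }
#'
#' @param plates an `ocr_plateset`.
#' @param method one of `"OCR-Stats"`, `"OCR-PE"`, `"LL"`, `"ED"`.
#' @param manual_exclusions optional data.frame `plate_id`, `well` for
#'   manual (microscope) exclusions, see [qc_filter_wells()].
#' @param qc apply the interval-ordering QC filter first (default TRUE).
#' @param well_mad_mult,point_mad_mult,grouping,min_wells outlier-removal
#'   settings, see [remove_outliers()].
#' @param cell_count_offset include `log(cell_count)` as a per-well
#'   offset in the fits.
#' @param conf_level,alternative,p_adjust testing settings, see
#'   [test_biosamples()].
#' @return list of class `ocr_run` with elements `method`, `qc_report`,
#'   `fits` (per-plate `ocr_fit`; `NULL` for ED), `outlier_reports`,
#'   `plate_effects` (OCR-PE only), `metrics` (with a `method` column),
#'   and `tests` (`NULL` for ED).
#' @examples
#' sim <- simulate_plates(sim_config(n_plates = 2), seed = 7)
#' run <- run_ocr_stats(sim$plates)
#' head(run$tests)
#' @export
run_ocr_stats <- function(plates,
                          method = c("OCR-Stats", "OCR-PE", "LL", "ED"),
                          manual_exclusions = NULL, qc = TRUE,
                          well_mad_mult = 5, point_mad_mult = 7,
                          grouping = "biosample", min_wells = 3L,
                          cell_count_offset = FALSE,
                          conf_level = 0.95, alternative = "two.sided",
                          p_adjust = "none") {
  stopifnot(inherits(plates, "ocr_plateset"))
  method <- match.arg(method)
  control <- plates$control

  qc_report <- NULL
  if (qc) {
    q <- qc_filter_wells(plates, manual_exclusions = manual_exclusions)
    plates <- q$plates
    qc_report <- q$report
  }
  m <- plates$measurements[!plates$measurements$is_blank, , drop = FALSE]

  if (method == "ED") {
    ed <- ed_measures(m)
    metrics <- ed_metric_table(ed)
    metrics$method <- "ED"
    out <- list(method = method, qc_report = qc_report, fits = NULL,
                outlier_reports = NULL, plate_effects = NULL,
                ed = ed, metrics = metrics, tests = NULL)
    class(out) <- "ocr_run"
    return(out)
  }

  outlier_reports <- NULL
  if (method == "LL") {
    fits <- lapply(split(m, m$plate_id), function(pm) {
      fit_log_linear(pm, cell_count_offset = cell_count_offset)
    })
    cleaned <- m
  } else {
    per_plate <- lapply(split(m, m$plate_id), function(pm) {
      remove_outliers(pm, well_mad_mult = well_mad_mult,
                      point_mad_mult = point_mad_mult,
                      grouping = grouping, min_wells = min_wells,
                      cell_count_offset = cell_count_offset)
    })
    fits <- lapply(per_plate, `[[`, "fit")
    cleaned <- do.call(rbind, lapply(per_plate, `[[`, "data"))
    outlier_reports <- lapply(per_plate, `[[`, "report")
  }

  plate_effects <- NULL
  if (method == "OCR-PE") {
    plate_effects <- estimate_plate_interval_effects(cleaned,
                                                     control = control)
    fits <- apply_plate_correction(cleaned, plate_effects,
                                   cell_count_offset = cell_count_offset)
  }

  metrics <- ocr_metrics(fits)
  if (method == "OCR-PE") {
    metrics <- metrics[metrics$biosample != control, , drop = FALSE]
  }
  metrics$method <- method

  tests <- NULL
  dd <- compute_ddtheta(fits, control = control)
  if (!is.null(dd) && nrow(dd)) {
    n_per <- table(dd$biosample[dd$metric == dd$metric[1L]])
    if (sum(n_per) - length(n_per) >= 2L) {
      tests <- test_biosamples(dd, conf_level = conf_level,
                               alternative = alternative,
                               p_adjust = p_adjust)
    }
  }

  out <- list(method = method, qc_report = qc_report, fits = fits,
              outlier_reports = outlier_reports,
              plate_effects = plate_effects,
              metrics = metrics, tests = tests, ddtheta = dd)
  class(out) <- "ocr_run"
  out
}

#' @export
print.ocr_run <- function(x, ...) {
  cat("<ocr_run> method ", x$method, "\n", sep = "")
  cat("  metrics rows: ", nrow(x$metrics), "\n", sep = "")
  if (!is.null(x$tests)) {
    sig <- sum(x$tests$p_value < 0.05)
    cat("  tests: ", nrow(x$tests), " (", sig, " with p < 0.05)\n", sep = "")
  }
  invisible(x)
}
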