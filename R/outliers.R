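#' Iterative well-level outlier detection
#'
#' Alternates model fitting and robust flagging until no further well is
#' removed. At each iteration the plate is refitted with
#' [fit_log_linear()], the mean squared log-OCR deviation per well
#' \eqn{s_w = mean_t(d_{w,t}^2)} is computed, and wells with
#' \eqn{s_w > median(s) + k \cdot mad(s)} (strict inequality, default
#' `mad_mult = 5`, MAD scaled by 1.4826) are dropped. The median and MAD
#' are taken over the wells of the same biological sample on the plate
#' (`grouping = "biosample"`) or over all wells (`grouping = "plate"`).
#'
#' As a safety floor, a biosample is never reduced below `min_wells`
#' wells; if the flagged set would do so, only the most deviant wells are
#' removed down to the floor, with a warning.
#'
#' @param data measurements of a single plate (see [fit_log_linear()]).
#' @param mad_mult MAD multiplier of the threshold (default 5).
#' @param grouping `"biosample"` (default) or `"plate"`: the pool over
#'   which the robust location/scale of `s` is computed.
#' @param min_wells minimum wells retained per biosample (default 3).
#' @param offsets,cell_count_offset passed to [fit_log_linear()].
#' @return list with `fit` (final `ocr_fit` on the cleaned wells), `data`
#'   (measurements minus flagged wells), and `report` (data.frame
#'   `plate_id`, `well`, `biosample`, `iteration`, `s_w`).
#' @export
detect_well_outliers <- function(data, mad_mult = 5,
                                 grouping = c("biosample", "plate"),
                                 min_wells = 3L,
                                 offsets = NULL, cell_count_offset = FALSE) {
  grouping <- match.arg(grouping)
  data <- as.data.frame(data)
  if ("is_blank" %in% names(data)) data <- data[!data$is_blank, , drop = FALSE]

  flagged <- data.frame(plate_id = character(0), well = character(0),
                        biosample = character(0), iteration = integer(0),
                        s_w = numeric(0), stringsAsFactors = FALSE)
  frozen <- character(0)  # biosamples at the floor: no further removal
  iter <- 0L
  n_wells_total <- length(unique(data$well))
  repeat {
    iter <- iter + 1L
    if (iter > n_wells_total + 1L) {
      stop("well-outlier iteration failed to terminate", call. = FALSE)
    }
    fit <- fit_log_linear(data, offsets = offsets,
                          cell_count_offset = cell_count_offset)
    d <- fit$data
    s <- stats::aggregate(list(s_w = d$deviation^2),
                          by = list(well = d$well, biosample = d$biosample),
                          FUN = mean)
    s$group <- if (grouping == "biosample") s$biosample else "plate"
    removed_any <- FALSE
    for (g in unique(s$group)) {
      sg <- s[s$group == g, , drop = FALSE]
      thr <- stats::median(sg$s_w) + mad_mult * stats::mad(sg$s_w)
      # strict exceedance with a numerical guard so that exact-fit rounding
      # residue (~1e-30) is never flagged in degenerate zero-mad groups
      hit <- sg[sg$s_w > thr + 1e-10, , drop = FALSE]
      if (!nrow(hit)) next
      hit <- hit[order(-hit$s_w), , drop = FALSE]
      # enforce the per-biosample floor
      for (b in unique(hit$biosample)) {
        if (b %in% frozen) {
          hit <- hit[hit$biosample != b, , drop = FALSE]
          next
        }
        n_rem <- sum(s$biosample == b)
        allowance <- max(0L, n_rem - min_wells)
        hb <- which(hit$biosample == b)
        if (length(hb) > allowance) {
          warning("well-outlier removal for biosample ", b, " on plate ",
                  fit$plate_id, " halted at the ", min_wells,
                  "-well floor", call. = FALSE)
          drop_idx <- if (allowance > 0L) hb[-seq_len(allowance)] else hb
          hit <- hit[-drop_idx, , drop = FALSE]
          frozen <- c(frozen, b)
        }
      }
      if (!nrow(hit)) next
      removed_any <- TRUE
      flagged <- rbind(flagged, data.frame(
        plate_id = fit$plate_id, well = hit$well, biosample = hit$biosample,
        iteration = iter, s_w = hit$s_w, stringsAsFactors = FALSE))
      data <- data[!data$well %in% hit$well, , drop = FALSE]
    }
    if (!removed_any) break
  }
  list(fit = fit, data = data,
       report = flagged, n_iterations = iter,
       fraction = nrow(flagged) / max(n_wells_total, 1L))
}

#' Iterative single-point outlier detection
#'
#' Run after [detect_well_outliers()] on the well-cleaned data. At each
#' iteration the plate is refitted and single observations with squared
#' deviation \eqn{d_{w,t}^2 > median(d^2) + k \cdot mad(d^2)} (strict,
#' default `mad_mult = 7`) are dropped, the robust statistics being pooled
#' over all remaining points of the same biological sample on the plate
#' (or the whole plate with `grouping = "plate"`). Iterates until no point
#' is flagged. The last remaining point of a (biosample, interval) cell is
#' never removed, so every interval effect stays estimable.
#'
#' @inheritParams detect_well_outliers
#' @param mad_mult MAD multiplier of the threshold (default 7).
#' @return list with `fit`, `data`, `report` (data.frame `plate_id`,
#'   `well`, `biosample`, `time_point`, `iteration`, `d2`).
#' @export
detect_point_outliers <- function(data, mad_mult = 7,
                                  grouping = c("biosample", "plate"),
                                  offsets = NULL, cell_count_offset = FALSE) {
  grouping <- match.arg(grouping)
  data <- as.data.frame(data)
  if ("is_blank" %in% names(data)) data <- data[!data$is_blank, , drop = FALSE]

  flagged <- data.frame(plate_id = character(0), well = character(0),
                        biosample = character(0), time_point = integer(0),
                        iteration = integer(0), d2 = numeric(0),
                        stringsAsFactors = FALSE)
  n_points_total <- nrow(data)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > n_points_total + 1L) {
      stop("point-outlier iteration failed to terminate", call. = FALSE)
    }
    fit <- fit_log_linear(data, offsets = offsets,
                          cell_count_offset = cell_count_offset)
    d <- fit$data
    d$d2 <- d$deviation^2
    d$group <- if (grouping == "biosample") d$biosample else "plate"
    removed_any <- FALSE
    for (g in unique(d$group)) {
      dg <- d[d$group == g, , drop = FALSE]
      thr <- stats::median(dg$d2) + mad_mult * stats::mad(dg$d2)
      hit <- dg[dg$d2 > thr + 1e-10, , drop = FALSE]
      if (!nrow(hit)) next
      hit <- hit[order(-hit$d2), , drop = FALSE]
      # floor: keep at least one point per (biosample, interval) cell
      cell_n <- table(paste(dg$biosample, dg$interval))
      keep_row <- rep(TRUE, nrow(hit))
      removed_per_cell <- integer(0)
      for (r in seq_len(nrow(hit))) {
        cl <- paste(hit$biosample[r], hit$interval[r])
        already <- if (cl %in% names(removed_per_cell)) removed_per_cell[[cl]] else 0L
        if (cell_n[[cl]] - already <= 1L) {
          keep_row[r] <- FALSE
          warning("point-outlier removal halted: last remaining point of ",
                  cl, " on plate ", fit$plate_id, call. = FALSE)
        } else {
          removed_per_cell[cl] <- already + 1L
        }
      }
      hit <- hit[keep_row, , drop = FALSE]
      if (!nrow(hit)) next
      removed_any <- TRUE
      flagged <- rbind(flagged, data.frame(
        plate_id = fit$plate_id, well = hit$well, biosample = hit$biosample,
        time_point = hit$time_point, iteration = iter, d2 = hit$d2,
        stringsAsFactors = FALSE))
      drop_key <- paste(hit$well, hit$time_point)
      data <- data[!paste(data$well, data$time_point) %in% drop_key, , drop = FALSE]
    }
    if (!removed_any) break
  }
  list(fit = fit, data = data, report = flagged, n_iterations = iter,
       fraction = nrow(flagged) / max(n_points_total, 1L))
}

#' Full two-level outlier removal for one plate
#'
#' Runs the well-level pass then the single-point pass and returns the
#' final fit together with a combined outlier report.
#'
#' @inheritParams detect_well_outliers
#' @param well_mad_mult,point_mad_mult MAD multipliers for the two passes
#'   (defaults 5 and 7).
#' @return list with `fit` (final `ocr_fit`), `data` (cleaned
#'   measurements), and `report` (class `ocr_outlier_report`): rows
#'   `plate_id`, `well`, `time_point` (`NA` for well-level), `level`,
#'   `iteration`; plus iteration counts and flagged fractions.
#' @examples
#' sim <- simulate_plates(sim_config(n_plates = 1), seed = 1)
#' res <- remove_outliers(sim$plates$measurements)
#' res$report
#' @export
remove_outliers <- function(data, well_mad_mult = 5, point_mad_mult = 7,
                            grouping = c("biosample", "plate"),
                            min_wells = 3L,
                            offsets = NULL, cell_count_offset = FALSE) {
  grouping <- match.arg(grouping)
  wl <- detect_well_outliers(data, mad_mult = well_mad_mult,
                             grouping = grouping, min_wells = min_wells,
                             offsets = offsets,
                             cell_count_offset = cell_count_offset)
  pt <- detect_point_outliers(wl$data, mad_mult = point_mad_mult,
                              grouping = grouping, offsets = offsets,
                              cell_count_offset = cell_count_offset)
  rep_w <- if (nrow(wl$report)) data.frame(
    plate_id = wl$report$plate_id, well = wl$report$well,
    biosample = wl$report$biosample, time_point = NA_integer_,
    level = "well", iteration = wl$report$iteration,
    stringsAsFactors = FALSE) else NULL
  rep_p <- if (nrow(pt$report)) data.frame(
    plate_id = pt$report$plate_id, well = pt$report$well,
    biosample = pt$report$biosample, time_point = pt$report$time_point,
    level = "point", iteration = pt$report$iteration,
    stringsAsFactors = FALSE) else NULL
  outliers <- rbind(rep_w, rep_p)
  if (is.null(outliers)) {
    outliers <- data.frame(plate_id = character(0), well = character(0),
                           biosample = character(0),
                           time_point = integer(0), level = character(0),
                           iteration = integer(0), stringsAsFactors = FALSE)
  }
  report <- structure(
    list(outliers = outliers,
         n_iterations_well = wl$n_iterations,
         n_iterations_point = pt$n_iterations,
         fraction_wells = wl$fraction,
         fraction_points = pt$fraction),
    class = "ocr_outlier_report")
  list(fit = pt$fit, data = pt$data, report = report)
}

#' @export
print.ocr_outlier_report <- function(x, ...) {
  o <- x$outliers
  cat("<ocr_outlier_report>\n")
  cat(sprintf("  well outliers:  %d (%.1f%% of wells, %d iteration(s))\n",
              sum(o$level == "well"), 100 * x$fraction_wells,
              x$n_iterations_well))
  cat(sprintf("  point outliers: %d (%.1f%% of points, %d iteration(s))\n",
              sum(o$level == "point"), 100 * x$fraction_points,
              x$n_iterations_point))
  invisible(x)
}
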