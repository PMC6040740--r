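#' Assemble a plate set from long-format measurements
#'
#' A plate set is the central data container: one row per
#' (plate, well, time point) carrying the biosample seeded in the well, the
#' measurement interval delimited by the oligomycin / FCCP / rotenone
#' injections, and the oxygen consumption rate (OCR) in pmol/min.
#'
#' @param measurements data.frame with columns `plate_id`, `well`,
#'   `biosample`, `time_point`, `interval`, `ocr`, and optionally
#'   `cell_count` and `is_blank`. Wells are named by row letter and 1-based
#'   column number (e.g. `"C6"`). `is_blank` marks media-only background
#'   wells (typically the four plate corners); blank wells are carried in
#'   the container but never enter any model fit.
#' @param control name of the control biosample (the cell line seeded on
#'   every plate, e.g. `"NHDF"`). Used by cross-plate testing and the
#'   plate-interval correction.
#' @param layout integer vector `c(rows, cols)` of the plate format.
#'   Defaults to a 96-well plate (8 x 12).
#'
#' @return An object of class `ocr_plateset`: a list with elements
#'   `measurements` (the validated data.frame), `control`, and `layout`.
#' @examples
#' sim <- simulate_plates(sim_config(n_plates = 1), seed = 1)
#' ps <- sim$plates
#' ps
#' @export
plate_set <- function(measurements, control = "NHDF", layout = c(8L, 12L)) {
  measurements <- as.data.frame(measurements)
  required <- c("plate_id", "well", "biosample", "time_point", "interval", "ocr")
  missing_cols <- setdiff(required, names(measurements))
  if (length(missing_cols)) {
    stop("measurements is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"is_blank" %in% names(measurements)) measurements$is_blank <- FALSE
  if (!"cell_count" %in% names(measurements)) measurements$cell_count <- NA_real_
  measurements$plate_id <- as.character(measurements$plate_id)
  measurements$well <- as.character(measurements$well)
  measurements$biosample <- as.character(measurements$biosample)
  measurements$time_point <- as.integer(measurements$time_point)
  measurements$interval <- as.integer(measurements$interval)
  measurements$ocr <- as.numeric(measurements$ocr)
  measurements$is_blank <- as.logical(measurements$is_blank)

  validate_measurements(measurements)
  structure(
    list(measurements = measurements,
         control = as.character(control),
         layout = as.integer(layout)),
    class = "ocr_plateset"
  )
}

validate_measurements <- function(m) {
  if (any(!is.finite(m$ocr[!m$is_blank])) || any(m$ocr[!m$is_blank] <= 0)) {
    stop("non-positive or non-finite OCR in non-blank wells; the log-linear ",
         "model requires OCR > 0. Use read_plates() to drop and report such rows.",
         call. = FALSE)
  }
  if (any(!m$interval %in% 1:4)) {
    stop("interval must be in 1..4", call. = FALSE)
  }
  # each well maps to exactly one biosample within a plate
  wb <- unique(m[, c("plate_id", "well", "biosample")])
  if (anyDuplicated(wb[, c("plate_id", "well")])) {
    stop("a well maps to more than one biosample on the same plate", call. = FALSE)
  }
  # interval must be a non-decreasing step function of time point
  key <- paste(m$plate_id, m$well)
  for (k in unique(key)) {
    rows <- m[key == k, ]
    rows <- rows[order(rows$time_point), ]
    if (is.unsorted(rows$interval)) {
      stop("interval is not non-decreasing in time_point for well ",
           rows$well[1L], " on plate ", rows$plate_id[1L], call. = FALSE)
    }
  }
  invisible(m)
}

#' @export
print.ocr_plateset <- function(x, ...) {
  m <- x$measurements
  cat("<ocr_plateset>\n")
  cat("  plates:     ", length(unique(m$plate_id)), "\n", sep = "")
  cat("  biosamples: ", length(unique(m$biosample[!m$is_blank])),
      " (control: ", x$control, ")\n", sep = "")
  cat("  wells:      ", nrow(unique(m[!m$is_blank, c("plate_id", "well")])),
      " assayed, ", nrow(unique(m[m$is_blank, c("plate_id", "well")])),
      " blank\n", sep = "")
  cat("  time points:", paste(range(m$time_point), collapse = ".."),
      " in intervals ", paste(range(m$interval), collapse = ".."), "\n", sep = "")
  invisible(x)
}

#' Default time-point to interval mapping
#'
#' The standard mitochondrial stress test has 12 time points in 4 intervals
#' of 3 (Int 1 before any treatment, Int 2 after oligomycin, Int 3 after
#' FCCP, Int 4 after rotenone).
#'
#' @param points_per_interval number of measurement cycles per interval.
#' @return integer vector mapping time point index to interval 1..4.
#' @export
default_interval_map <- function(points_per_interval = 3L) {
  rep(1:4, each = points_per_interval)
}

#' Read a plate set from a long-format CSV file
#'
#' The canonical on-disk format is a plain CSV with one row per
#' (plate, well, time point) and columns `plate_id`, `well`, `biosample`,
#' `time_point`, `interval`, `ocr`, optionally `cell_count` and `is_blank`.
#' If `interval` is absent it is assigned from `time_point` via
#' `interval_map`; if present it is checked against that mapping.
#'
#' Rows with non-positive OCR in non-blank wells cannot enter the log-linear
#' model; they are dropped with a warning and listed in the `load_report`
#' attribute of the result.
#'
#' @param path path to the CSV file.
#' @param control control biosample name.
#' @param interval_map integer vector mapping time points to intervals
#'   (default: 12 points, 3 per interval).
#' @param layout plate dimensions `c(rows, cols)`.
#' @return `ocr_plateset` with attribute `load_report` (data.frame of
#'   dropped rows, possibly empty).
#' @seealso [write_plates()]
#' @export
read_plates <- function(path, control = "NHDF",
                        interval_map = default_interval_map(),
                        layout = c(8L, 12L)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("plate_id", "well", "biosample", "time_point", "ocr")
  missing_cols <- setdiff(required, names(m))
  if (length(missing_cols)) {
    stop("input file is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  m$time_point <- as.integer(m$time_point)
  if (any(is.na(m$time_point)) ||
      any(m$time_point < 1L | m$time_point > length(interval_map))) {
    stop("time_point outside 1..", length(interval_map), call. = FALSE)
  }
  mapped <- as.integer(interval_map[m$time_point])
  if ("interval" %in% names(m)) {
    if (any(as.integer(m$interval) != mapped)) {
      bad <- which(as.integer(m$interval) != mapped)[1L]
      stop("interval column inconsistent with time_point mapping at row ", bad,
           " (time_point ", m$time_point[bad], " maps to interval ",
           mapped[bad], ", file says ", m$interval[bad], ")", call. = FALSE)
    }
  }
  m$interval <- mapped
  if (!"is_blank" %in% names(m)) m$is_blank <- FALSE
  m$is_blank <- as.logical(m$is_blank)

  bad <- !m$is_blank & (!is.finite(m$ocr) | m$ocr <= 0)
  report <- m[bad, c("plate_id", "well", "time_point", "ocr"), drop = FALSE]
  if (nrow(report)) {
    warning(nrow(report), " row(s) with non-positive OCR in non-blank wells ",
            "dropped; see attr(, 'load_report')", call. = FALSE)
    m <- m[!bad, , drop = FALSE]
  }
  ps <- plate_set(m, control = control, layout = layout)
  attr(ps, "load_report") <- report
  ps
}

#' Write a plate set to a long-format CSV file
#'
#' @param plates an `ocr_plateset`.
#' @param path output path.
#' @return `path`, invisibly.
#' @seealso [read_plates()]
#' @export
write_plates <- function(plates, path) {
  stopifnot(inherits(plates, "ocr_plateset"))
  cols <- c("plate_id", "well", "biosample", "time_point", "interval",
            "ocr", "cell_count", "is_blank")
  utils::write.csv(plates$measurements[, cols], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Quality-control filter on well interval ordering
#'
#' A well that responded to the three injections as expected shows a strict
#' ordering of its per-interval median OCR:
#' `median(Int3) > median(Int1) > median(Int2) > median(Int4)`
#' (maximal/uncoupled above basal, basal above ATPase-independent, rotenone
#' lowest). Wells violating this ordering (ties count as violations) did not
#' respond to the treatments and are removed before model fitting. A
#' user-supplied exclusion list stands in for manual microscope inspection
#' (contamination, detached cells).
#'
#' @param plates an `ocr_plateset`.
#' @param manual_exclusions optional data.frame with columns `plate_id`,
#'   `well` of wells to exclude regardless of ordering.
#' @return list with `plates` (filtered `ocr_plateset`) and `report`
#'   (class `ocr_qc_report`): the discarded wells by category and the
#'   discarded fractions relative to all assayed (non-blank) wells.
#' @examples
#' sim <- simulate_plates(sim_config(n_plates = 1), seed = 1)
#' qc <- qc_filter_wells(sim$plates)
#' qc$report
#' @export
qc_filter_wells <- function(plates, manual_exclusions = NULL) {
  stopifnot(inherits(plates, "ocr_plateset"))
  m <- plates$measurements
  live <- m[!m$is_blank, , drop = FALSE]
  wells <- unique(live[, c("plate_id", "well", "biosample")])

  manual_key <- character(0)
  if (!is.null(manual_exclusions) && nrow(as.data.frame(manual_exclusions))) {
    manual_exclusions <- as.data.frame(manual_exclusions)
    stopifnot(all(c("plate_id", "well") %in% names(manual_exclusions)))
    manual_key <- paste(manual_exclusions$plate_id, manual_exclusions$well)
  }

  key <- paste(live$plate_id, live$well)
  wkey <- paste(wells$plate_id, wells$well)
  is_manual <- wkey %in% manual_key

  med <- stats::aggregate(ocr ~ plate_id + well + interval, data = live,
                          FUN = stats::median)
  ord_ok <- vapply(seq_len(nrow(wells)), function(i) {
    if (is_manual[i]) return(TRUE)   # judged on the manual list instead
    mi <- med[med$plate_id == wells$plate_id[i] & med$well == wells$well[i], ]
    v <- mi$ocr[match(1:4, mi$interval)]
    if (any(is.na(v))) return(FALSE) # missing interval: cannot satisfy ordering
    v[3] > v[1] && v[1] > v[2] && v[2] > v[4]
  }, logical(1))

  discard_order <- wells[!ord_ok & !is_manual, c("plate_id", "well")]
  discard_manual <- wells[is_manual, c("plate_id", "well")]
  drop_key <- c(paste(discard_order$plate_id, discard_order$well),
                paste(discard_manual$plate_id, discard_manual$well))

  keep <- m$is_blank | !(paste(m$plate_id, m$well) %in% drop_key)
  out <- plates
  out$measurements <- m[keep, , drop = FALSE]

  # a (plate, biosample) stripped of all wells is unusable downstream
  before <- unique(wells[, c("plate_id", "biosample")])
  after <- out$measurements[!out$measurements$is_blank, , drop = FALSE]
  after_pb <- unique(after[, c("plate_id", "biosample")])
  lost <- before[!paste(before$plate_id, before$biosample) %in%
                   paste(after_pb$plate_id, after_pb$biosample), , drop = FALSE]
  if (nrow(lost)) {
    warning("biosample(s) lost all wells on a plate after QC: ",
            paste(paste0(lost$biosample, "@", lost$plate_id), collapse = ", "),
            call. = FALSE)
  }

  n_total <- nrow(wells)
  report <- structure(
    list(discarded_order_violation = discard_order,
         discarded_manual = discard_manual,
         lost_plate_biosamples = lost,
         n_wells_total = n_total,
         fractions = c(
           order_violation = nrow(discard_order) / max(n_total, 1L),
           manual = nrow(discard_manual) / max(n_total, 1L))),
    class = "ocr_qc_report")
  list(plates = out, report = report)
}

#' @export
print.ocr_qc_report <- function(x, ...) {
  cat("<ocr_qc_report>\n")
  cat(sprintf("  assayed wells:        %d\n", x$n_wells_total))
  cat(sprintf("  order violations:     %d (%.2f%%)\n",
              nrow(x$discarded_order_violation),
              100 * x$fractions[["order_violation"]]))
  cat(sprintf("  manual exclusions:    %d (%.2f%%)\n",
              nrow(x$discarded_manual), 100 * x$fractions[["manual"]]))
  invisible(x)
}

# well-name helpers: "C6" -> row "C", column 6
well_row <- function(well) sub("^([A-Za-z]+).*$", "\\1", well)
well_col <- function(well) as.integer(sub("^[A-Za-z]+", "", well))

# drop blank wells from a measurements frame that may lack the column
drop_blank <- function(m) {
  if ("is_blank" %in% names(m)) m[!m$is_blank, , drop = FALSE] else m
}
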