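#' Estimate plate-interval effects from the control biosample
#'
#' Treatment efficiency and instrument conditions can shift whole
#' plate-intervals (e.g. a rotenone batch affecting interval 4 of one
#' plate only). Anchoring on the control biosample seeded on every plate,
#' the model
#' \deqn{y_{control,t,p} = \theta_{control,\,interv(t)} + \beta_{interv(t),p} + \varepsilon_{t,p}}
#' is solved by least squares over all control observations, with the
#' plate effects constrained to mean zero over plates within each interval
#' (only contrasts between plates are identified). Because the per-plate
#' one-way layout is saturated, the solution is closed-form: the fitted
#' level of (plate, interval) is the plate-interval mean of control log
#' OCR, and \eqn{\hat\beta_{i,p}} its deviation from the unweighted
#' across-plate mean.
#'
#' @param plates an `ocr_plateset` or measurements data.frame; control
#'   observations should already be outlier-cleaned.
#' @param control control biosample name (default: the plate set's).
#' @return object of class `ocr_plate_effects`: list with `beta`
#'   (data.frame `plate_id`, `interval`, `offset`), `theta_control`
#'   (data.frame `interval`, `theta`), `control`, and `missing_plates`
#'   (plates without control, which receive no offset).
#' @seealso [apply_plate_correction()]
#' @export
estimate_plate_interval_effects <- function(plates, control = NULL) {
  if (inherits(plates, "ocr_plateset")) {
    if (is.null(control)) control <- plates$control
    m <- plates$measurements
  } else {
    m <- as.data.frame(plates)
    if (is.null(control)) stop("control must be given", call. = FALSE)
  }
  all_plates <- unique(m$plate_id)
  m <- drop_blank(m)
  m <- m[m$biosample == control, , drop = FALSE]
  if (!nrow(m)) stop("control biosample ", control, " not found", call. = FALSE)
  missing_plates <- setdiff(all_plates, unique(m$plate_id))
  if (length(missing_plates)) {
    warning("control absent on plate(s): ",
            paste(missing_plates, collapse = ", "),
            "; they receive no plate-interval offset", call. = FALSE)
  }
  m$y <- log(m$ocr)
  beta <- NULL
  theta <- NULL
  for (i in sort(unique(m$interval))) {
    mi <- m[m$interval == i, , drop = FALSE]
    ybar <- tapply(mi$y, mi$plate_id, mean)
    th <- mean(ybar)                      # unweighted mean over plates
    b <- as.numeric(ybar) - th
    beta <- rbind(beta, data.frame(plate_id = names(ybar), interval = i,
                                   offset = b, stringsAsFactors = FALSE))
    theta <- rbind(theta, data.frame(interval = i, theta = th))
  }
  rownames(beta) <- rownames(theta) <- NULL
  structure(list(beta = beta, theta_control = theta, control = control,
                 missing_plates = missing_plates),
            class = "ocr_plate_effects")
}

#' @export
print.ocr_plate_effects <- function(x, ...) {
  cat("<ocr_plate_effects> anchored on control ", x$control, "\n", sep = "")
  cat("  ", length(unique(x$beta$plate_id)), " plate(s), offsets sd = ",
      signif(stats::sd(x$beta$offset), 3), " (log scale)\n", sep = "")
  if (length(x$missing_plates)) {
    cat("  no control on:", paste(x$missing_plates, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Refit plates with plate-interval offsets (plate-effect correction)
#'
#' Refits the within-plate log-linear model on each plate with the
#' estimated plate-interval effects subtracted from log OCR as known
#' offsets, so that interval effects (and hence the natural-scale
#' bioenergetic measures) are comparable across plates. A plate without a
#' control receives a zero offset.
#'
#' @param plates an `ocr_plateset` or measurements data.frame (typically
#'   the outlier-cleaned data).
#' @param effects an `ocr_plate_effects` from
#'   [estimate_plate_interval_effects()].
#' @param cell_count_offset passed to [fit_log_linear()].
#' @return named list of `ocr_fit`, one per plate.
#' @export
apply_plate_correction <- function(plates, effects, cell_count_offset = FALSE) {
  stopifnot(inherits(effects, "ocr_plate_effects"))
  m <- if (inherits(plates, "ocr_plateset")) plates$measurements else
    as.data.frame(plates)
  m <- drop_blank(m)
  fits <- lapply(split(m, m$plate_id), function(pm) {
    fit_log_linear(pm, offsets = effects$beta,
                   cell_count_offset = cell_count_offset)
  })
  fits
}
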