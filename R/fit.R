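#' Fit the within-plate log-linear OCR model
#'
#' Models the natural log of OCR of well `w` at time point `t` on one plate
#' as
#' \deqn{y_{w,t} = \theta_{biosample(w),\,interv(t)} + \beta_w + \varepsilon_{w,t},}
#' i.e. a sum of a time-interval effect per (biosample, interval), a
#' systematic well effect, and multiplicative (log-additive) noise. The
#' model is fitted by exact linear least squares over all wells of the
#' plate jointly, minimising
#' \eqn{\sum_w \sum_t (y_{w,t} - \theta - \beta_w - o_{w,t})^2}
#' where \eqn{o_{w,t}} is an optional known offset.
#'
#' Well effects are only identified up to a constant per biosample (a shift
#' of \eqn{\beta} over one biosample's wells can be absorbed into that
#' biosample's four \eqn{\theta}); they are therefore constrained to sum to
#' zero within each biosample, which makes the mean of \eqn{\hat\beta} over
#' all included wells of the plate exactly zero and leaves fitted values,
#' metrics and all downstream tests invariant to the choice. Under this
#' constraint the log OCR well deviation reduces to
#' \eqn{d_{w,t} = y_{w,t} - \hat\theta}.
#'
#' @param data data.frame of measurements from a single plate (columns
#'   `well`, `biosample`, `time_point`, `interval`, `ocr`, optionally
#'   `plate_id`, `cell_count`, `is_blank`). Blank wells are ignored.
#' @param offsets optional data.frame of known log-scale offsets with
#'   columns `interval` and `offset` (optionally `plate_id`), e.g. the
#'   plate-interval effects from [estimate_plate_interval_effects()].
#'   Offsets are subtracted from the log OCR before fitting.
#' @param cell_count_offset if `TRUE`, add `log(cell_count)` per well to
#'   the offset, normalising for seeded cell number by design.
#' @return An object of class `ocr_fit` with elements:
#'   \describe{
#'     \item{theta}{data.frame `biosample`, `interval`, `theta` — interval
#'       effects \eqn{\hat\theta} (log scale; intervals 1..4 are the
#'       initial, ATPase-independent, maximal and ETC-independent levels).}
#'     \item{beta}{data.frame `well`, `biosample`, `beta`, `singleton` —
#'       well effects, zero-sum per biosample; wells that are their
#'       biosample's only well have `beta` forced to 0 and are flagged.}
#'     \item{data}{per-observation frame with `y` (offset-adjusted log
#'       OCR), `fitted`, `deviation` (\eqn{d_{w,t} = y - \hat\theta}) and
#'       `residual` (\eqn{y - \hat\theta - \hat\beta}).}
#'     \item{n_obs}{number of observations used.}
#'   }
#' @examples
#' sim <- simulate_plates(sim_config(n_plates = 1), seed = 1)
#' fit <- fit_log_linear(sim$plates$measurements)
#' head(fit$theta)
#' @export
fit_log_linear <- function(data, offsets = NULL, cell_count_offset = FALSE) {
  data <- as.data.frame(data)
  req <- c("well", "biosample", "interval", "ocr")
  if (!all(req %in% names(data))) {
    stop("data must have columns ", paste(req, collapse = ", "), call. = FALSE)
  }
  if ("is_blank" %in% names(data)) data <- data[!data$is_blank, , drop = FALSE]
  plate <- if ("plate_id" %in% names(data)) unique(data$plate_id) else NA_character_
  if (length(plate) != 1L) {
    stop("fit_log_linear() fits one plate at a time; got plates: ",
         paste(plate, collapse = ", "), call. = FALSE)
  }
  if (!nrow(data)) stop("no observations to fit", call. = FALSE)
  if (any(!is.finite(data$ocr)) || any(data$ocr <= 0)) {
    stop("OCR must be positive and finite for the log-linear model", call. = FALSE)
  }

  off <- numeric(nrow(data))
  if (!is.null(offsets)) {
    offsets <- as.data.frame(offsets)
    if ("plate_id" %in% names(offsets) && !is.na(plate)) {
      offsets <- offsets[offsets$plate_id == plate, , drop = FALSE]
    }
    o <- offsets$offset[match(data$interval, offsets$interval)]
    o[is.na(o)] <- 0
    off <- off + o
  }
  if (isTRUE(cell_count_offset)) {
    cc <- data$cell_count
    if (is.null(cc) || any(is.na(cc)) || any(cc <= 0)) {
      stop("cell_count_offset = TRUE requires a positive cell_count on every row",
           call. = FALSE)
    }
    off <- off + log(cc)
  }
  y <- log(data$ocr) - off

  bios <- as.character(data$biosample)
  intv <- as.integer(data$interval)
  wells <- as.character(data$well)

  cells <- table(bios, intv)
  empty <- which(cells == 0, arr.ind = TRUE)
  if (nrow(empty)) {
    stop("no observations for (biosample, interval) cell(s): ",
         paste(paste0(rownames(cells)[empty[, 1]], " x interval ",
                      colnames(cells)[empty[, 2]]), collapse = ", "),
         call. = FALSE)
  }

  cell_f <- factor(paste(bios, intv, sep = "\r"))
  Xt <- stats::model.matrix(~ 0 + cell_f)
  wc <- well_contrast_matrix(wells, bios)
  X <- cbind(Xt, wc$X)

  ls <- stats::lm.fit(X, y)
  if (any(is.na(ls$coefficients))) {
    stop("rank-deficient design: check that every well has observations and ",
         "each well maps to one biosample", call. = FALSE)
  }
  coefs <- ls$coefficients
  n_theta <- ncol(Xt)

  cell_levels <- levels(cell_f)
  parts <- strsplit(cell_levels, "\r", fixed = TRUE)
  theta <- data.frame(
    plate_id = plate,
    biosample = vapply(parts, `[[`, "", 1L),
    interval = as.integer(vapply(parts, `[[`, "", 2L)),
    theta = unname(coefs[seq_len(n_theta)]),
    stringsAsFactors = FALSE)
  theta <- theta[order(theta$biosample, theta$interval), ]
  rownames(theta) <- NULL

  beta <- reconstruct_beta(coefs[-seq_len(n_theta)], wc)
  beta$plate_id <- plate
  beta <- beta[, c("plate_id", "well", "biosample", "beta", "singleton")]

  th_map <- theta$theta[match(paste(bios, intv), paste(theta$biosample, theta$interval))]
  be_map <- beta$beta[match(wells, beta$well)]
  obs <- data.frame(
    plate_id = plate,
    well = wells,
    biosample = bios,
    time_point = if ("time_point" %in% names(data)) as.integer(data$time_point) else NA_integer_,
    interval = intv,
    y = y,
    offset = off,
    fitted = th_map + be_map,
    deviation = y - th_map,
    residual = y - th_map - be_map,
    stringsAsFactors = FALSE)

  structure(
    list(plate_id = plate, theta = theta, beta = beta, data = obs,
         n_obs = nrow(obs),
         cell_count_offset = isTRUE(cell_count_offset),
         has_offsets = !is.null(offsets)),
    class = "ocr_fit")
}

# per-biosample sum-to-zero contrast columns for well effects:
# a biosample with wells w1..wk contributes k-1 columns
# (+1 on wj, -1 on wk); a single-well biosample contributes none
# (its beta is 0 by the constraint).
well_contrast_matrix <- function(wells, bios) {
  wb <- unique(data.frame(well = wells, biosample = bios,
                          stringsAsFactors = FALSE))
  if (anyDuplicated(wb$well)) {
    stop("each well must map to exactly one biosample", call. = FALSE)
  }
  wb <- wb[order(wb$biosample, wb$well), ]
  cols <- list()
  nms <- character(0)
  for (b in unique(wb$biosample)) {
    ws <- wb$well[wb$biosample == b]
    k <- length(ws)
    if (k < 2L) next
    for (j in seq_len(k - 1L)) {
      cols[[length(cols) + 1L]] <-
        (wells == ws[j]) - (wells == ws[k])
      nms <- c(nms, paste0("w\r", ws[j]))
    }
  }
  X <- if (length(cols)) do.call(cbind, cols) else
    matrix(0, nrow = length(wells), ncol = 0)
  colnames(X) <- nms
  list(X = X, map = wb)
}

reconstruct_beta <- function(coefs, wc) {
  wb <- wc$map
  beta <- numeric(nrow(wb))
  names(beta) <- wb$well
  singleton <- logical(nrow(wb))
  for (b in unique(wb$biosample)) {
    idx <- which(wb$biosample == b)
    ws <- wb$well[idx]
    k <- length(ws)
    if (k < 2L) {
      singleton[idx] <- TRUE
      next
    }
    cj <- coefs[paste0("w\r", ws[-k])]
    beta[idx] <- c(cj, -sum(cj))
  }
  data.frame(well = wb$well, biosample = wb$biosample,
             beta = unname(beta), singleton = singleton,
             stringsAsFactors = FALSE)
}

#' Log OCR well deviations of a fitted plate
#'
#' Deviations \eqn{d_{w,t} = y_{w,t} - \hat\theta_{biosample(w),interv(t)}
#' - \bar{\hat\beta}} drive both levels of outlier detection. Because well
#' effects are zero-sum over the plate's included wells, the mean-beta term
#' vanishes and \eqn{d_{w,t} = y_{w,t} - \hat\theta}. Note that the well
#' effect is deliberately *not* subtracted: a whole-well shift shows up in
#' `d` and can be flagged at the well level.
#'
#' @param fit an `ocr_fit`.
#' @return data.frame with `plate_id`, `well`, `biosample`, `time_point`,
#'   `interval`, `deviation`.
#' @export
compute_deviations <- function(fit) {
  stopifnot(inherits(fit, "ocr_fit"))
  fit$data[, c("plate_id", "well", "biosample", "time_point", "interval",
               "deviation")]
}

#' @export
print.ocr_fit <- function(x, ...) {
  cat("<ocr_fit> plate ", x$plate_id, "\n", sep = "")
  cat("  biosamples: ", length(unique(x$theta$biosample)),
      ", wells: ", nrow(x$beta), ", observations: ", x$n_obs, "\n", sep = "")
  cat("  residual sd: ", signif(stats::sd(x$data$residual), 4), "\n", sep = "")
  if (any(x$beta$singleton)) {
    cat("  note: ", sum(x$beta$singleton),
        " single-well biosample(s); their well effect is fixed at 0\n", sep = "")
  }
  invisible(x)
}

#' @export
fitted.ocr_fit <- function(object, ...) object$data$fitted

#' @export
residuals.ocr_fit <- function(object, ...) object$data$residual
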