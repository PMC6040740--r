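#' Configuration for the synthetic plate simulator
#'
#' Describes the generative model the estimation method assumes: log OCR
#' is a sum of (biosample, interval) effects, zero-sum well effects,
#' plate-interval effects and Gaussian noise, all on the log scale
#' (multiplicative on the natural scale), plus explicitly injected
#' outliers and non-responder wells.
#'
#' @param n_plates number of plates (default 3; a control is seeded on
#'   every plate).
#' @param biosamples names of the non-control biosamples per plate
#'   (default 4, matching a typical layout of 3-7 samples per plate).
#' @param control control biosample name (default `"NHDF"`).
#' @param wells_per_biosample replicate wells per biosample per plate
#'   (default 12, the recommended minimum).
#' @param points_per_interval measurement cycles per interval (default 3;
#'   4 intervals, so 12 time points).
#' @param theta named list/matrix of 4 log-scale interval effects per
#'   biosample, or `NULL` for the canonical mitochondrial stress-test
#'   profile `log(c(100, 40, 150, 20))` (interval ordering
#'   Int3 > Int1 > Int2 > Int4) for every biosample. With a shared
#'   profile every true log-ratio difference vs control is 0.
#' @param sigma_noise sd of the log-scale measurement noise (default 0.1).
#' @param sigma_well sd of the well effects (default 0.1; centered within
#'   each (plate, biosample)).
#' @param sigma_plate_interval sd of the plate-interval effects (default
#'   0.15, larger than the within-plate components, as observed between
#'   plates; centered per interval across plates).
#' @param outlier_well_rate probability that a well is an injected
#'   well-level outlier (all its points shifted by
#'   `+/- outlier_magnitude` on the log scale; default 0).
#' @param outlier_point_rate probability that a single point (in a
#'   non-outlier well) is shifted (default 0).
#' @param outlier_magnitude log-scale shift of injected outliers
#'   (default 1).
#' @param non_responder_rate probability that a well ignores the
#'   treatments (flat at its interval-1 level; default 0). Such wells
#'   exercise the interval-ordering QC filter.
#' @param layout plate dimensions (default 96-well, 8 x 12; the four
#'   corners are blank).
#' @return list of class `ocr_sim_config`.
#' @export
sim_config <- function(n_plates = 3L,
                       biosamples = paste0("SAMPLE_", 1:4),
                       control = "NHDF",
                       wells_per_biosample = 12L,
                       points_per_interval = 3L,
                       theta = NULL,
                       sigma_noise = 0.1,
                       sigma_well = 0.1,
                       sigma_plate_interval = 0.15,
                       outlier_well_rate = 0,
                       outlier_point_rate = 0,
                       outlier_magnitude = 1,
                       non_responder_rate = 0,
                       layout = c(8L, 12L)) {
  groups <- c(control, biosamples)
  if (is.null(theta)) {
    theta <- matrix(rep(log(c(100, 40, 150, 20)), each = length(groups)),
                    nrow = length(groups),
                    dimnames = list(groups, NULL))
  } else {
    theta <- do.call(rbind, as.list(theta))
    if (is.null(rownames(theta)) || !all(groups %in% rownames(theta))) {
      stop("theta must be named with one 4-vector per biosample ",
           "(including the control)", call. = FALSE)
    }
    theta <- theta[groups, , drop = FALSE]
  }
  stopifnot(ncol(theta) == 4L,
            all(c(sigma_noise, sigma_well, sigma_plate_interval) >= 0),
            all(c(outlier_well_rate, outlier_point_rate,
                  non_responder_rate) >= 0),
            all(c(outlier_well_rate, outlier_point_rate,
                  non_responder_rate) <= 1))
  capacity <- prod(layout) - 4L  # blank corners
  if (length(groups) * wells_per_biosample > capacity) {
    stop("layout holds ", capacity, " assay wells; ",
         length(groups), " x ", wells_per_biosample, " requested",
         call. = FALSE)
  }
  structure(list(
    n_plates = as.integer(n_plates), biosamples = biosamples,
    control = control, wells_per_biosample = as.integer(wells_per_biosample),
    points_per_interval = as.integer(points_per_interval), theta = theta,
    sigma_noise = sigma_noise, sigma_well = sigma_well,
    sigma_plate_interval = sigma_plate_interval,
    outlier_well_rate = outlier_well_rate,
    outlier_point_rate = outlier_point_rate,
    outlier_magnitude = outlier_magnitude,
    non_responder_rate = non_responder_rate,
    layout = as.integer(layout)), class = "ocr_sim_config")
}

#' Simulate mitochondrial stress-test plates with ground truth
#'
#' Generates a plate set under the log-additive generative model of
#' [sim_config()] together with the full ground truth (interval effects,
#' well effects, plate-interval effects, outlier masks and true log-ratio
#' differences vs control), so that estimation, outlier recovery and test
#' calibration can be checked against the truth.
#'
#' @param config an `ocr_sim_config`.
#' @param seed integer RNG seed; the same seed reproduces the output
#'   bit-exactly.
#' @return list with `plates` (an [plate_set()]) and `truth`, a list with
#'   `theta` (biosample x interval log levels), `beta` (well effects,
#'   zero-sum per (plate, biosample)), `plate_interval` (zero-mean per
#'   interval), `well_outliers`, `point_outliers`, `non_responders`
#'   (masks), and `mu` (true cross-plate log-ratio differences vs
#'   control, per metric).
#' @examples
#' sim <- simulate_plates(sim_config(n_plates = 2), seed = 42)
#' sim$plates
#' head(sim$truth$theta)
#' @export
simulate_plates <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "ocr_sim_config"))
  set.seed(as.integer(seed))
  cf <- config
  groups <- rownames(cf$theta)
  n_int <- 4L
  tpp <- cf$points_per_interval
  n_tp <- n_int * tpp
  interval_of <- rep(1:n_int, each = tpp)

  rows <- LETTERS[seq_len(cf$layout[1L])]
  cols <- seq_len(cf$layout[2L])
  all_wells <- as.vector(outer(rows, cols, paste0))
  corners <- c(paste0(rows[1L], cols[1L]), paste0(rows[1L], max(cols)),
               paste0(rows[length(rows)], cols[1L]),
               paste0(rows[length(rows)], max(cols)))
  assay_wells <- setdiff(all_wells, corners)

  plate_ids <- sprintf("plate_%02d", seq_len(cf$n_plates))

  # plate-interval effects, zero-mean per interval across plates
  gamma <- matrix(stats::rnorm(cf$n_plates * n_int, 0, cf$sigma_plate_interval),
                  nrow = cf$n_plates,
                  dimnames = list(plate_ids, NULL))
  if (cf$n_plates > 1L) {
    gamma <- sweep(gamma, 2L, colMeans(gamma))
  } else {
    gamma[] <- 0
  }

  meas <- list()
  beta_truth <- list()
  well_out <- list()
  point_out <- list()
  nonresp <- list()

  for (p in seq_len(cf$n_plates)) {
    pid <- plate_ids[p]
    n_assigned <- length(groups) * cf$wells_per_biosample
    wells_used <- assay_wells[seq_len(n_assigned)]
    well_group <- rep(groups, each = cf$wells_per_biosample)

    beta <- stats::rnorm(n_assigned, 0, cf$sigma_well)
    for (g in groups) {  # zero-sum within (plate, biosample)
      idx <- well_group == g
      beta[idx] <- beta[idx] - mean(beta[idx])
    }
    is_wout <- stats::runif(n_assigned) < cf$outlier_well_rate
    wout_sign <- sample(c(-1, 1), n_assigned, replace = TRUE)
    is_nonresp <- !is_wout & stats::runif(n_assigned) < cf$non_responder_rate

    for (w in seq_len(n_assigned)) {
      g <- well_group[w]
      th <- cf$theta[g, interval_of]
      if (is_nonresp[w]) th <- rep(cf$theta[g, 1L], n_tp)
      mu_log <- th + beta[w] + gamma[p, interval_of]
      eps <- stats::rnorm(n_tp, 0, cf$sigma_noise)
      shift <- numeric(n_tp)
      pt_mask <- rep(FALSE, n_tp)
      if (is_wout[w]) {
        shift <- shift + wout_sign[w] * cf$outlier_magnitude
      } else if (cf$outlier_point_rate > 0) {
        pt_mask <- stats::runif(n_tp) < cf$outlier_point_rate
        shift[pt_mask] <- sample(c(-1, 1), sum(pt_mask), replace = TRUE) *
          cf$outlier_magnitude
      }
      ocr <- exp(mu_log + eps + shift)
      meas[[length(meas) + 1L]] <- data.frame(
        plate_id = pid, well = wells_used[w], biosample = g,
        time_point = seq_len(n_tp), interval = interval_of, ocr = ocr,
        cell_count = round(20000 * exp(beta[w] +
                                         stats::rnorm(1L, 0, 0.05))),
        is_blank = FALSE, stringsAsFactors = FALSE)
      if (any(pt_mask)) {
        point_out[[length(point_out) + 1L]] <- data.frame(
          plate_id = pid, well = wells_used[w],
          time_point = which(pt_mask), stringsAsFactors = FALSE)
      }
    }
    beta_truth[[p]] <- data.frame(plate_id = pid, well = wells_used,
                                  biosample = well_group, beta = beta,
                                  stringsAsFactors = FALSE)
    if (any(is_wout)) {
      well_out[[length(well_out) + 1L]] <- data.frame(
        plate_id = pid, well = wells_used[is_wout],
        stringsAsFactors = FALSE)
    }
    if (any(is_nonresp)) {
      nonresp[[length(nonresp) + 1L]] <- data.frame(
        plate_id = pid, well = wells_used[is_nonresp],
        stringsAsFactors = FALSE)
    }
    # blank corner wells: media-only background level
    for (cw in corners) {
      meas[[length(meas) + 1L]] <- data.frame(
        plate_id = pid, well = cw, biosample = "BLANK",
        time_point = seq_len(n_tp), interval = interval_of,
        ocr = exp(stats::rnorm(n_tp, log(5), 0.3)),
        cell_count = NA_real_, is_blank = TRUE, stringsAsFactors = FALSE)
    }
  }

  m <- do.call(rbind, meas)
  plates <- plate_set(m, control = cf$control, layout = cf$layout)

  theta_df <- data.frame(
    biosample = rep(groups, times = n_int),
    interval = rep(1:n_int, each = length(groups)),
    theta = as.vector(cf$theta), stringsAsFactors = FALSE)
  gamma_df <- data.frame(
    plate_id = rep(plate_ids, times = n_int),
    interval = rep(1:n_int, each = cf$n_plates),
    gamma = as.vector(gamma), stringsAsFactors = FALSE)

  # true cross-plate log-ratio differences vs control, per metric
  ctl <- cf$theta[cf$control, ]
  mu <- list()
  for (g in cf$biosamples) {
    th <- cf$theta[g, ]
    vals <- c(EI = (th[1] - th[4]) - (ctl[1] - ctl[4]),
              AI = (th[1] - th[2]) - (ctl[1] - ctl[2]),
              EAi = (th[2] - th[4]) - (ctl[2] - ctl[4]),
              MI = (th[3] - th[1]) - (ctl[3] - ctl[1]),
              MEi = (th[3] - th[4]) - (ctl[3] - ctl[4]))
    mu[[length(mu) + 1L]] <- data.frame(
      biosample = g, metric = names(vals), mu = unname(vals),
      stringsAsFactors = FALSE)
  }

  empty_mask <- data.frame(plate_id = character(0), well = character(0),
                           stringsAsFactors = FALSE)
  truth <- list(
    theta = theta_df,
    beta = do.call(rbind, beta_truth),
    plate_interval = gamma_df,
    well_outliers = if (length(well_out)) do.call(rbind, well_out) else empty_mask,
    point_outliers = if (length(point_out)) do.call(rbind, point_out) else
      cbind(empty_mask, time_point = integer(0)),
    non_responders = if (length(nonresp)) do.call(rbind, nonresp) else empty_mask,
    mu = do.call(rbind, mu))
  list(plates = plates, truth = truth, config = cf, seed = as.integer(seed))
}
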