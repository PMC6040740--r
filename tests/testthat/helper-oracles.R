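# Independent least-squares oracles and tiny data builders shared by the
# tests. The oracles deliberately use a different solution path (full dummy
# design + SVD pseudoinverse / reference-well coding + QR) than the package.

# Minimum-norm LS solution on the full (rank-deficient) dummy design,
# re-expressed under the per-biosample zero-sum well-effect convention.
oracle_fit <- function(data) {
  y <- log(data$ocr)
  cell <- paste(data$biosample, data$interval, sep = ":")
  cells <- sort(unique(cell))
  wells <- sort(unique(data$well))
  X <- cbind(1 * outer(cell, cells, "=="), 1 * outer(data$well, wells, "=="))
  sv <- svd(X)
  pos <- sv$d > max(sv$d) * 1e-10
  coef <- sv$v[, pos, drop = FALSE] %*%
    ((t(sv$u[, pos, drop = FALSE]) %*% y) / sv$d[pos])
  theta <- coef[seq_along(cells)]
  beta <- coef[-seq_along(cells)]
  names(theta) <- cells
  names(beta) <- wells
  wb <- unique(data[, c("well", "biosample")])
  for (b in unique(wb$biosample)) {
    ws <- wb$well[wb$biosample == b]
    mb <- mean(beta[ws])
    beta[ws] <- beta[ws] - mb
    ints <- sort(unique(data$interval[data$biosample == b]))
    theta[paste(b, ints, sep = ":")] <- theta[paste(b, ints, sep = ":")] + mb
  }
  list(theta = theta, beta = beta, fitted = as.numeric(X %*% coef))
}

# Fitted values under reference-well coding: the beta of each biosample's
# first well is fixed at zero and the reduced design solved by QR.
reference_coding_fitted <- function(data) {
  y <- log(data$ocr)
  cell <- paste(data$biosample, data$interval, sep = ":")
  cells <- sort(unique(cell))
  wb <- unique(data[, c("well", "biosample")])
  free_wells <- unlist(lapply(split(wb$well, wb$biosample),
                              function(w) sort(w)[-1]))
  X <- cbind(1 * outer(cell, cells, "=="),
             1 * outer(data$well, free_wells, "=="))
  as.numeric(X %*% qr.coef(qr(X), y))
}

# Small random plate: n_bios biosamples x wells wells, 4 intervals of tpp
# points, lognormal noise around a per-biosample level profile.
rand_plate <- function(seed, n_bios = 2L, wells = 3L, tpp = 2L,
                       sigma = 0.15) {
  set.seed(seed)
  rows <- list()
  profile <- log(c(100, 40, 150, 20))
  for (b in seq_len(n_bios)) {
    th <- profile + rnorm(4, 0, 0.2)
    for (w in seq_len(wells)) {
      bw <- rnorm(1, 0, 0.1)
      tp <- seq_len(4L * tpp)
      iv <- rep(1:4, each = tpp)
      rows[[length(rows) + 1L]] <- data.frame(
        plate_id = "p1",
        well = paste0(LETTERS[b], w),
        biosample = paste0("bio", b),
        time_point = tp, interval = iv,
        ocr = exp(th[iv] + bw + rnorm(length(tp), 0, sigma)),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Noise-free plate at exact log levels: theta is a list biosample -> 4-vector,
# beta a list biosample -> per-well effects (zero-sum to match the fit).
exact_plate <- function(theta, beta = NULL, tpp = 3L, plate_id = "p1") {
  rows <- list()
  for (b in names(theta)) {
    nb <- if (is.null(beta)) 2L else length(beta[[b]])
    bv <- if (is.null(beta)) rep(0, nb) else beta[[b]]
    for (w in seq_len(nb)) {
      tp <- seq_len(4L * tpp)
      iv <- rep(1:4, each = tpp)
      rows[[length(rows) + 1L]] <- data.frame(
        plate_id = plate_id, well = paste0(b, "_w", w), biosample = b,
        time_point = tp, interval = iv,
        ocr = exp(theta[[b]][iv] + bv[w]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# ddtheta frame drawn directly from the cross-plate error model.
rand_ddtheta <- function(mu, n_plates, sigma, metric = "MEi") {
  B <- length(mu)
  data.frame(
    biosample = rep(sprintf("b%02d", seq_len(B)), each = n_plates),
    plate_id = rep(sprintf("p%d", seq_len(n_plates)), B),
    metric = metric,
    ddtheta = rep(mu, each = n_plates) + rnorm(B * n_plates, 0, sigma),
    stringsAsFactors = FALSE)
}
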