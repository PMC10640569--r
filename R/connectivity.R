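#' Discrete prolate spheroidal (Slepian) sequences
#'
#' Computes the first `k` Slepian tapers of length `n` with time-half-bandwidth
#' product `nw`, as eigenvectors of the standard symmetric tridiagonal matrix
#' whose top eigenvectors are maximally concentrated in the band
#' \[-nw/n, nw/n\] (in cycles per sample). Tapers are returned with unit
#' energy (columns of an `n` by `k` matrix, ordered by decreasing
#' concentration).
#'
#' @param n taper length in samples.
#' @param nw time-half-bandwidth product (`duration * half_bandwidth` in
#'   seconds times Hz).
#' @param k number of tapers; defaults to the usual `2*nw - 1` rule.
#' @return matrix `n` x `k` of tapers, unit sum of squares per column.
#' @export
dpss_tapers <- function(n, nw, k = max(1L, round(2 * nw - 1))) {
  if (n < 2) stop("taper length must be at least 2")
  if (nw <= 0 || nw >= n / 2) stop("need 0 < nw < n/2")
  if (k < 1 || k > n) stop("invalid number of tapers")
  w <- nw / n
  t <- 0:(n - 1)
  A <- matrix(0, n, n)
  diag(A) <- ((n - 1 - 2 * t) / 2)^2 * cos(2 * pi * w)
  off <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  A[cbind(1:(n - 1), 2:n)] <- off
  A[cbind(2:n, 1:(n - 1))] <- off
  e <- eigen(A, symmetric = TRUE)
  tapers <- e$vectors[, seq_len(k), drop = FALSE]
  # unit energy; sign irrelevant for cross-spectra (taper enters both channels)
  sweep(tapers, 2, sqrt(colSums(tapers^2)), "/")
}

#' Multichannel trial-wise recording
#'
#' Container for node-level oscillatory time series: a `trials x nodes x
#' samples` array with sampling rate and node coordinates in mm.
#'
#' @param data numeric array, trials x nodes x samples; all values finite.
#' @param fs sampling rate in Hz.
#' @param node_coords nodes x 3 matrix of coordinates (mm), optional.
#' @param subject_id identifier string.
#' @return an object of class `node_timeseries`.
#' @export
node_timeseries <- function(data, fs, node_coords = NULL, subject_id = "s1") {
  if (length(dim(data)) != 3) stop("data must be a trials x nodes x samples array")
  if (!all(is.finite(data))) stop("all samples must be finite")
  if (fs <= 0) stop("fs must be positive")
  if (!is.null(node_coords)) {
    node_coords <- as.matrix(node_coords)
    if (nrow(node_coords) != dim(data)[2] || ncol(node_coords) != 3)
      stop("node_coords must be nodes x 3")
  }
  structure(list(data = data, fs = fs, node_coords = node_coords,
                 subject_id = subject_id),
            class = "node_timeseries")
}

#' Multitaper cross-spectra on a fixed frequency grid
#'
#' Per trial and Slepian taper, one complex Fourier coefficient per node per
#' frequency bin; cross-spectra are formed on demand as `X_i * Conj(X_j)`.
#' Each trial is demeaned per channel before tapering; the FFT is zero-padded
#' so that bin centers fall exactly on the `fstep` grid.
#'
#' @param ts a [node_timeseries()].
#' @param fmin,fmax,fstep frequency grid in Hz (default 0.5-100 in 0.5 Hz
#'   steps, 200 bins).
#' @param half_bandwidth spectral smoothing half-bandwidth in Hz (default 2);
#'   with 2 s trials this gives NW = 4 and 7 tapers.
#' @param n_tapers number of tapers; default `2*NW - 1`.
#' @return object of class `cross_spectra` holding the complex coefficient
#'   array `bins x nodes x (trials*tapers)`.
#' @export
multitaper_cross_spectra <- function(ts, fmin = 0.5, fmax = 100, fstep = 0.5,
                                     half_bandwidth = 2, n_tapers = NULL) {
  stopifnot(inherits(ts, "node_timeseries"))
  fs <- ts$fs
  if (fmax >= fs / 2) stop("fmax must be below the Nyquist frequency")
  if (fstep <= 0) stop("fstep must be positive")
  dims <- dim(ts$data)
  n_trials <- dims[1]; n_nodes <- dims[2]; n_samp <- dims[3]
  if (n_trials < 2) stop("need at least 2 trials (expectation undefined)")
  duration <- n_samp / fs
  nw <- duration * half_bandwidth
  if (nw < 1) stop("half_bandwidth * duration must be >= 1")
  k <- n_tapers %||% max(1L, round(2 * nw - 1))
  tapers <- dpss_tapers(n_samp, nw, k)

  # zero-pad so fs/nfft divides fstep exactly (bin centers on the grid)
  base_nfft <- round(fs / fstep)
  if (abs(fs / fstep - base_nfft) > 1e-8)
    stop("fs must be an integer multiple of fstep")
  nfft <- base_nfft * max(1L, ceiling(n_samp / base_nfft))
  freqs <- seq(fmin, fmax, by = fstep)
  bin_idx <- round(freqs * nfft / fs) + 1L
  if (any(abs(freqs - (bin_idx - 1L) * fs / nfft) > 1e-6))
    stop("frequency grid does not align with FFT bins")

  coefs <- array(complex(real = 0), dim = c(length(freqs), n_nodes, n_trials * k))
  pad <- matrix(0, nfft - n_samp, n_nodes)
  obs <- 0L
  for (tr in seq_len(n_trials)) {
    x <- t(ts$data[tr, , , drop = TRUE])          # samples x nodes
    if (n_nodes == 1) x <- matrix(ts$data[tr, 1, ], ncol = 1)
    x <- sweep(x, 2, colMeans(x))
    for (tp in seq_len(k)) {
      X <- stats::mvfft(rbind(x * tapers[, tp], pad))
      obs <- obs + 1L
      coefs[, , obs] <- X[bin_idx, , drop = FALSE]
    }
  }
  structure(list(coef = coefs, freqs = freqs, fs = fs,
                 n_trials = n_trials, n_tapers = k,
                 half_bandwidth = half_bandwidth,
                 node_coords = ts$node_coords,
                 subject_id = ts$subject_id),
            class = "cross_spectra")
}

#' Cross-spectral observations for one node pair
#'
#' Returns the per-observation (trial x taper) complex cross-spectrum
#' `S_ij(f) = X_i(f) * Conj(X_j(f))` as a bins x observations matrix.
#'
#' @param cs a `cross_spectra` object.
#' @param i,j node indices.
#' @return complex matrix, bins x observations.
#' @export
cross_spectrum <- function(cs, i, j) {
  stopifnot(inherits(cs, "cross_spectra"))
  cs$coef[, i, , drop = TRUE] * Conj(cs$coef[, j, , drop = TRUE])
}

#' Auto-spectrum (mean over trials and tapers)
#'
#' @param cs a `cross_spectra` object.
#' @param i node index.
#' @return numeric vector of mean power per frequency bin.
#' @export
auto_spectrum <- function(cs, i) {
  rowMeans(Mod(cs$coef[, i, , drop = TRUE])^2)
}

#' Weighted phase lag index per frequency bin
#'
#' For each node pair and bin, `wPLI = |E[Im S_ij]| / E[|Im S_ij|]`, the
#' expectation taken over pooled trial-by-taper observations. When the
#' denominator is zero (zero-lag or identical signals) the value is defined
#' as 0: zero-lag coupling is exactly what wPLI is designed to discount.
#'
#' @param cs a `cross_spectra` object.
#' @return object of class `spectral_connectivity`: array bins x nodes x
#'   nodes with entries in \[0, 1\], symmetric, zero diagonal.
#' @export
wpli <- function(cs) {
  stopifnot(inherits(cs, "cross_spectra"))
  n_nodes <- dim(cs$coef)[2]
  n_bins <- dim(cs$coef)[1]
  if (dim(cs$coef)[3] < 2) stop("need >= 2 observations per bin")
  w <- array(0, dim = c(n_bins, n_nodes, n_nodes))
  for (i in seq_len(n_nodes - 1)) {
    Xi <- cs$coef[, i, , drop = TRUE]
    if (n_bins == 1) Xi <- matrix(Xi, nrow = 1)
    for (j in (i + 1):n_nodes) {
      Xj <- cs$coef[, j, , drop = TRUE]
      if (n_bins == 1) Xj <- matrix(Xj, nrow = 1)
      im <- Im(Xi * Conj(Xj))
      num <- abs(rowMeans(im))
      den <- rowMeans(abs(im))
      v <- ifelse(den > 0, num / den, 0)
      w[, i, j] <- v
      w[, j, i] <- v
    }
  }
  structure(list(wpli = w, freqs = cs$freqs, node_coords = cs$node_coords,
                 subject_id = cs$subject_id),
            class = "spectral_connectivity")
}

#' Aggregate narrowband connectivity across bins in the L2 norm
#'
#' `W_ij = sqrt(sum_f wPLI_ij(f)^2)`, estimating total coupling across the
#' spectrum; entries are bounded by `sqrt(n_bins)`.
#'
#' @param sc a `spectral_connectivity` object.
#' @return a [connectome()].
#' @export
aggregate_l2 <- function(sc) {
  stopifnot(inherits(sc, "spectral_connectivity"))
  W <- sqrt(apply(sc$wpli^2, c(2, 3), sum))
  diag(W) <- 0
  connectome(W, node_coords = sc$node_coords,
             subject_id = sc$subject_id %||% "s1",
             n_bins_aggregated = length(sc$freqs))
}

#' Weighted connectome
#'
#' Symmetric, zero-diagonal, nonnegative weighted adjacency with optional
#' node coordinates (mm); the object that attack simulations operate on.
#'
#' @param W nodes x nodes numeric matrix.
#' @param node_coords nodes x 3 matrix (mm), optional.
#' @param subject_id identifier.
#' @param n_bins_aggregated number of frequency bins aggregated into `W`
#'   (`NA` when `W` was supplied directly).
#' @return object of class `connectome` with fields `W`, `node_coords`,
#'   `mean_distance`, `n_bins_aggregated`.
#' @export
connectome <- function(W, node_coords = NULL, subject_id = "s1",
                       n_bins_aggregated = NA_integer_) {
  W <- as.matrix(W)
  if (nrow(W) != ncol(W)) stop("W must be square")
  if (max(abs(W - t(W))) > 1e-8) stop("W must be symmetric")
  if (any(W < 0)) stop("W must be nonnegative")
  if (any(diag(W) != 0)) stop("W must have a zero diagonal")
  md <- if (!is.null(node_coords)) mean_node_distance(node_coords) else NA_real_
  structure(list(W = W, node_coords = node_coords, mean_distance = md,
                 n_bins_aggregated = n_bins_aggregated,
                 subject_id = subject_id),
            class = "connectome")
}

#' Mean Euclidean distance over all node pairs
#'
#' Used as a nuisance covariate: field-spread-like effects scale with
#' inter-node distance, which differs between small and large heads.
#'
#' @param coords nodes x 3 numeric matrix (mm).
#' @return mean of the Euclidean distances over all unordered node pairs (mm).
#' @export
mean_node_distance <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 2) stop("need at least 2 nodes")
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  mean(stats::dist(coords))
}

#' Write / read a connectome as TSV matrix + JSON sidecar
#'
#' @param conn a `connectome`.
#' @param path output TSV path; the sidecar is written as `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_connectome <- function(conn, path) {
  utils::write.table(conn$W, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  meta <- list(subject_id = conn$subject_id,
               mean_distance = conn$mean_distance,
               n_bins_aggregated = conn$n_bins_aggregated)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_connectome
#' @param coords_path optional TSV (node, x, y, z) with node coordinates.
#' @export
read_connectome <- function(path, coords_path = NULL) {
  W <- as.matrix(utils::read.table(path, sep = "\t"))
  dimnames(W) <- NULL
  coords <- NULL
  if (!is.null(coords_path)) {
    cc <- utils::read.table(coords_path, sep = "\t", header = TRUE)
    coords <- as.matrix(cc[, c("x", "y", "z")])
  }
  meta_path <- paste0(path, ".json")
  sid <- "s1"; nb <- NA_integer_
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    sid <- meta$subject_id %||% "s1"
    nb <- meta$n_bins_aggregated %||% NA_integer_
  }
  connectome(W, node_coords = coords, subject_id = sid, n_bins_aggregated = nb)
}
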