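#' Functional sample of percolation-point-by-density curves
#'
#' The functional domain follows the thresholding sweep from dense to
#' sparse: grid points are stored in descending density order, so the
#' curves decline from their high-density plateau toward the static sparse
#' range, the "last" value is the sparsest density (where the percolation
#' point is least stable), and domain trimming keeps an initial segment of
#' the sweep. An ascending grid is accepted and reversed.
#'
#' @param densities common density grid (strictly monotone).
#' @param Y subjects x densities matrix of percolation points.
#' @param ids subject identifiers (rownames of `Y` by default).
#' @return object of class `functional_sample` with fields `densities`
#'   (descending), `Y`, `ids`, `retained` (logical mask, all TRUE
#'   initially) and `trim` (indices of the retained sub-grid).
#' @export
functional_sample <- function(densities, Y, ids = rownames(Y)) {
  Y <- as.matrix(Y)
  if (length(densities) != ncol(Y))
    stop("ncol(Y) must match the density grid length")
  if (all(diff(densities) > 0)) {
    densities <- rev(densities)
    Y <- Y[, rev(seq_len(ncol(Y))), drop = FALSE]
  } else if (!all(diff(densities) < 0)) {
    stop("densities must be strictly monotone")
  }
  if (is.null(ids)) ids <- sprintf("sub%03d", seq_len(nrow(Y)))
  # densities where thresholding failed for any subject are dropped up front
  ok <- colSums(is.na(Y)) == 0
  structure(list(densities = densities[ok], Y = Y[, ok, drop = FALSE],
                 ids = ids, retained = rep(TRUE, nrow(Y)),
                 trim = seq_len(sum(ok))),
            class = "functional_sample")
}

#' Assemble a functional sample from attack results
#'
#' @param pfs list of `percolation_function` objects on a common grid.
#' @return a [functional_sample()].
#' @export
functional_sample_from_attacks <- function(pfs) {
  Y <- do.call(rbind, lapply(pfs, function(pf) pf$p))
  rownames(Y) <- vapply(pfs, function(pf) pf$subject_id, character(1))
  functional_sample(pfs[[1]]$densities, Y)
}

# Active (retained x trimmed) view of the sample.
fs_active <- function(fs) {
  list(densities = fs$densities[fs$trim],
       Y = fs$Y[fs$retained, fs$trim, drop = FALSE],
       ids = fs$ids[fs$retained])
}

#' Drop subjects with a terminal percolation-point spike
#'
#' The percolation point is unstable at the sparsest thresholds (very few
#' edges survive), producing spikes at the end of the dense-to-sparse sweep
#' for some subjects. The last value of each subject's function (the
#' sparsest density) is extracted, z-scored across subjects (once, no
#' iteration), and subjects with z > `z_thresh` are dropped. A
#' zero-variance column leaves everyone in.
#'
#' @param fs a [functional_sample()].
#' @param z_thresh z-score threshold (default 2).
#' @return the updated `functional_sample` (mask tightened).
#' @export
drop_terminal_spike_outliers <- function(fs, z_thresh = 2) {
  act <- fs_active(fs)
  if (nrow(act$Y) < 3) stop("need at least 3 retained subjects")
  v <- act$Y[, ncol(act$Y)]
  s <- sd(v)
  z <- if (s > 0) (v - mean(v)) / s else rep(0, length(v))
  drop <- z > z_thresh
  if (all(drop)) stop("terminal-spike rule would drop all subjects")
  keep_ids <- act$ids[!drop]
  fs$retained <- fs$retained & (fs$ids %in% keep_ids)
  fs
}

#' Trim the static dense plateau off the functional domain
#'
#' Percolation-point curves are static near full density (graphs there are
#' robust whatever the threshold), then fall precipitously toward the
#' sparse end of the sweep. This computes the group-mean function over
#' retained subjects and its first finite-difference derivative (velocity)
#' along the dense-to-sparse sweep (central differences inside, one-sided
#' at the ends, per unit of density swept), locates the first grid point
#' (searched from the second) at which the mean velocity drops to
#' `<= -tol` — the onset of the decline — and retains the domain from the
#' point just before that onset through the sparse end. If no decline is
#' found the full domain is kept, with a warning. The across-subject SD of
#' the velocity over the retained domain is attached for transparency
#' (attribute `"deriv_sd"`).
#'
#' @param fs a [functional_sample()].
#' @param tol decline-onset tolerance on the velocity (default 1e-6).
#' @param relative if TRUE, `tol` is interpreted as a fraction of the peak
#'   absolute velocity of the mean function, so the onset is judged
#'   relative to the size of the decline (appropriate for noisy empirical
#'   curves whose plateau is never exactly flat).
#' @return the updated `functional_sample` with `trim` set.
#' @export
trim_domain <- function(fs, tol = 1e-6, relative = FALSE) {
  act <- fs_active(fs)
  d <- act$densities
  M <- length(d)
  if (M < 2) stop("need at least 2 grid points")
  xs <- cumsum(c(0, abs(diff(d))))  # position along the sweep
  mu <- colMeans(act$Y)
  dmu <- finite_diff(mu, xs)
  if (relative) tol <- tol * max(abs(dmu))
  dsub <- t(apply(act$Y, 1, finite_diff, x = xs))
  deriv_sd <- apply(dsub, 2, sd)
  idx <- which(dmu[-1] <= -tol)
  if (length(idx) == 0) {
    warning("no decline found in the mean function; keeping the full domain")
    dstar <- 2L
  } else {
    dstar <- idx[1] + 1L
  }
  keep <- (dstar - 1L):M
  if (length(keep) < 10)
    warning(sprintf("trimmed domain has only %d grid points", length(keep)))
  fs$trim <- fs$trim[keep]
  attr(fs, "deriv_sd") <- deriv_sd[keep]
  fs
}

finite_diff <- function(y, x) {
  M <- length(y)
  d <- numeric(M)
  d[1] <- (y[2] - y[1]) / (x[2] - x[1])
  d[M] <- (y[M] - y[M - 1]) / (x[M] - x[M - 1])
  if (M > 2) {
    i <- 2:(M - 1)
    d[i] <- (y[i + 1] - y[i - 1]) / (x[i + 1] - x[i - 1])
  }
  d
}

# Order-4 B-spline basis with knots at the grid points: interior knots at
# d_2..d_{M-1} plus 4-fold boundary knots give M + 2 basis functions.
bspline_basis <- function(d, order = 4L) {
  M <- length(d)
  knots <- c(rep(d[1], order), d[seq(2, M - 1)], rep(d[M], order))
  list(knots = knots, order = order, n_basis = length(knots) - order)
}

eval_basis <- function(basis, x, derivs = 0L) {
  splines::splineDesign(basis$knots, x, ord = basis$order,
                        derivs = rep(derivs, length(x)),
                        outer.ok = FALSE)
}

# Exact Gram matrix of second derivatives: for order-4 splines B'' is
# piecewise linear, so Simpson's rule per knot interval is exact.
roughness_matrix <- function(basis, d) {
  nb <- basis$n_basis
  R <- matrix(0, nb, nb)
  for (m in seq_len(length(d) - 1)) {
    a <- d[m]; b <- d[m + 1]; h <- b - a
    if (h <= 0) next
    pts <- c(a, (a + b) / 2, b)
    B2 <- eval_basis(basis, pts, derivs = 2L)
    R <- R + (h / 6) * (outer(B2[1, ], B2[1, ]) +
                        4 * outer(B2[2, ], B2[2, ]) +
                        outer(B2[3, ], B2[3, ]))
  }
  R
}

#' Penalized B-spline smoothing with GCV-selected roughness penalty
#'
#' Fits an order-4 B-spline expansion with `M + 2` basis functions (knots at
#' the density grid points) by penalized least squares, the penalty being
#' `lambda` times the integrated squared second derivative. `lambda` is
#' chosen from `lambda_grid` (default `e^k`, integer `k` in -5..12) by
#' minimizing `GCV = M * SSR / (M - edf)^2`.
#'
#' @param y function values on the grid.
#' @param d density grid (strictly increasing, length >= 4).
#' @param lambda_grid candidate penalty weights (> 0).
#' @return object of class `smoothed_function`: `coef`, `lambda`, `gcv`,
#'   `ssr`, `edf`, `fitted`, `basis`.
#' @export
smooth_gcv <- function(y, d, lambda_grid = exp(-5:12)) {
  if (length(lambda_grid) == 0) stop("lambda_grid must be non-empty")
  if (any(lambda_grid <= 0)) stop("lambda must be positive")
  M <- length(d)
  if (length(y) != M) stop("y and d lengths differ")
  if (M < 4) stop("need at least 4 grid points for an order-4 basis")
  basis <- bspline_basis(d)
  B <- eval_basis(basis, d)
  R <- roughness_matrix(basis, d)
  BtB <- crossprod(B)
  Bty <- crossprod(B, y)
  best <- NULL
  for (lam in sort(lambda_grid)) {
    K <- BtB + lam * R
    Kinv <- tryCatch(chol2inv(chol(K)), error = function(e) solve(K))
    cf <- Kinv %*% Bty
    fit <- as.numeric(B %*% cf)
    ssr <- sum((y - fit)^2)
    edf <- sum(diag(B %*% Kinv %*% t(B)))
    gcv <- M * ssr / (M - edf)^2
    if (is.null(best) || gcv < best$gcv)
      best <- list(coef = as.numeric(cf), lambda = lam, gcv = gcv,
                   ssr = ssr, edf = edf, fitted = fit)
  }
  structure(c(best, list(basis = basis, densities = d)),
            class = "smoothed_function")
}

#' Smooth every retained subject and flag poor fits by SSR
#'
#' Each retained function is smoothed with [smooth_gcv()]; the per-subject
#' sums of squared residuals are z-scored across subjects and subjects with
#' z > `z_thresh` are dropped as ill-fitting (mirroring the terminal-spike
#' rule; `z_thresh = Inf` keeps everyone).
#'
#' Densities are taken to percent units for smoothing: the default
#' `e^-5 .. e^12` penalty grid has its intended resolution when grid
#' spacing is of order one (0.25-1 percent steps), whereas on a
#' fraction-unit domain the roughness matrix grows as the fourth power of
#' the inverse spacing and every candidate would oversmooth.
#'
#' @param fs a [functional_sample()] (trimmed).
#' @param z_thresh SSR z-score threshold (default 2).
#' @param lambda_grid passed to [smooth_gcv()].
#' @return list with `fs` (mask tightened), `fits` (per-subject
#'   `smoothed_function`s) and `table` (id, lambda, gcv, ssr).
#' @export
drop_ssr_outliers <- function(fs, z_thresh = 2, lambda_grid = exp(-5:12)) {
  act <- fs_active(fs)
  if (nrow(act$Y) < 3) stop("need at least 3 retained subjects")
  ord <- order(act$densities)  # splines need an ascending abscissa
  fits <- lapply(seq_len(nrow(act$Y)),
                 function(i) smooth_gcv(act$Y[i, ord],
                                        100 * act$densities[ord],
                                        lambda_grid))
  ssr <- vapply(fits, function(f) f$ssr, numeric(1))
  s <- sd(ssr)
  z <- if (s > 0) (ssr - mean(ssr)) / s else rep(0, length(ssr))
  keep_ids <- act$ids[z <= z_thresh]
  fs$retained <- fs$retained & (fs$ids %in% keep_ids)
  tab <- data.frame(id = act$ids,
                    lambda = vapply(fits, function(f) f$lambda, numeric(1)),
                    gcv = vapply(fits, function(f) f$gcv, numeric(1)),
                    ssr = ssr, dropped = z > z_thresh,
                    stringsAsFactors = FALSE)
  list(fs = fs, fits = fits, table = tab)
}

#' @export
print.smoothed_function <- function(x, ...) {
  cat(sprintf("Penalized B-spline fit: %d basis functions, lambda = %.4g\n",
              x$basis$n_basis, x$lambda))
  cat(sprintf("  SSR = %.4g, edf = %.2f, GCV = %.4g\n", x$ssr, x$edf, x$gcv))
  invisible(x)
}
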