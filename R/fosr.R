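#' Penalized function-on-scalar regression
#'
#' Fits the varying-coefficient model
#' \deqn{y_i(d) = \beta_0(d) + \sum_j x_{ij} \beta_j(d) + \epsilon_i(d)}
#' to a sample of percolation-point-by-density functions, with each
#' coefficient function expanded in 5 cubic B-splines carrying a
#' first-order difference penalty (P-splines), smoothing weights selected
#' by REML on the stacked (subject x density) system. Estimation treats
#' grid points as working-independent; dependence along the domain is
#' handled at inference time by the case bootstrap ([confint.fosr()]).
#'
#' Two overall tests are computed from unpenalized companion fits (see
#' [lr_overall_test()]): a model test (full fit vs the
#' functional-intercept-only fit) that gates [significance_summary()], and
#' a constant-vs-functional comparison (covariate coefficients constrained
#' to scalars, functional intercept retained). Per-covariate tests
#' come from the penalized fit's approximate F statistics. Functional
#' R-squared (variance explained beyond the functional intercept, adjusted
#' for effective degrees of freedom) and semi-partial correlations
#' (square root of the drop in adjusted R-squared when a regressor is
#' removed) are computed at fit time.
#'
#' @param formula model formula; the left side names a subjects x densities
#'   matrix or a [functional_sample()], the right side scalar covariates
#'   found in `data`.
#' @param data data.frame of subject-level covariates, rows aligned with
#'   the response.
#' @param argvals density grid (required when the response is a matrix;
#'   taken from the object when it is a `functional_sample`).
#' @param k basis dimension per coefficient function (default 5 cubic
#'   B-splines).
#' @param method smoothing-parameter criterion passed to [mgcv::gam()]
#'   (default "REML").
#' @param sp optional fixed smoothing parameters (length `1 + p`) bypassing
#'   REML selection, e.g. in resampling loops.
#' @param light if TRUE, skip the extra refits behind the functional
#'   R-squared family and semi-partial correlations (they are returned as
#'   `NA`); the estimate, the overall test and the per-covariate tests are
#'   unaffected.
#' @return an object of class `fosr`; see [coef.fosr()], [summary.fosr()],
#'   [confint.fosr()], [significance_summary()].
#' @examples
#' d <- seq(0.01, 0.3, length.out = 20)
#' n <- 40
#' age <- runif(n, 4, 19)
#' Y <- outer(rep(1, n), 0.5 - d) - 0.01 * age + matrix(rnorm(n * 20, 0, 0.02), n)
#' fit <- fosr(Y ~ age, data = data.frame(age = age), argvals = d)
#' coef(fit)[1:3, ]
#' @export
fosr <- function(formula, data, argvals = NULL, k = 5, method = "REML",
                 sp = NULL, light = FALSE) {
  resp <- eval(formula[[2]], data, environment(formula))
  if (inherits(resp, "functional_sample")) {
    act <- fs_active(resp)
    Y <- act$Y
    argvals <- act$densities
    ids <- act$ids
  } else {
    Y <- as.matrix(resp)
    ids <- rownames(Y) %||% sprintf("sub%03d", seq_len(nrow(Y)))
    if (is.null(argvals)) stop("argvals required when the response is a matrix")
  }
  n <- nrow(Y); M <- ncol(Y)
  if (M < 10) stop("trimmed grid must have at least 10 points")
  rhs <- stats::delete.response(stats::terms(formula, data = data))
  mf <- stats::model.frame(rhs, data)
  X <- stats::model.matrix(rhs, mf)
  if (!"(Intercept)" %in% colnames(X)) stop("model must include an intercept")
  X <- X[, setdiff(colnames(X), "(Intercept)"), drop = FALSE]
  if (nrow(X) != n) stop("covariate rows must align with response rows")
  if (any(is.na(X))) stop("missing values in covariates")
  p <- ncol(X)
  qrX <- qr(cbind(1, X))
  if (qrX$rank < p + 1) {
    bad <- colnames(X)[qrX$pivot[seq(qrX$rank + 1, p + 1)] - 1]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  labels <- colnames(X)
  xnames <- sprintf(".x%d", seq_len(p))

  df <- data.frame(y = as.vector(t(Y)), d = rep(argvals, n))
  for (j in seq_len(p)) df[[xnames[j]]] <- rep(X[, j], each = M)

  sterm <- sprintf('s(d, bs = "ps", k = %d, m = c(2, 1))', k)
  byterms <- sprintf('s(d, by = %s, bs = "ps", k = %d, m = c(2, 1))',
                     xnames, k)
  fml_full <- stats::as.formula(paste("y ~", paste(c(sterm, byterms),
                                                   collapse = " + ")))
  fml_const <- stats::as.formula(paste("y ~", paste(c(sterm, xnames),
                                                    collapse = " + ")))
  fml_int <- stats::as.formula(paste("y ~", sterm))

  # REML breaks down on (near-)noiseless responses; fall back to the
  # unpenalized fit, which is exact there.
  gam_safe <- function(fml, n_smooth, sp0 = NULL) {
    tryCatch(mgcv::gam(fml, data = df, method = method, sp = sp0),
             error = function(e) mgcv::gam(fml, data = df,
                                           sp = rep(0, n_smooth)))
  }
  fit_full <- gam_safe(fml_full, p + 1, sp)
  fit_const <- gam_safe(fml_const, 1, if (!is.null(sp)) sp[1])
  fit_int <- gam_safe(fml_int, 1, if (!is.null(sp)) sp[1])

  rss <- function(b) sum(residuals(b)^2)
  edf_tot <- function(b) sum(b$edf)
  nM <- n * M
  RSS_f <- rss(fit_full); edf_f <- edf_tot(fit_full)
  RSS_c <- rss(fit_const); edf_c <- edf_tot(fit_const)
  RSS_0 <- rss(fit_int); edf_0 <- edf_tot(fit_int)

  # Overall tests from unpenalized companion fits: F tests based on
  # differences of *shrunken* effective df are anticonservative, whereas
  # with the penalties off the comparisons are plain nested linear fits and
  # the F reference distribution applies. Two comparisons are kept:
  #  - "model": full fit vs the functional-intercept-only fit (are the
  #    covariates associated with the response at all?) — the gate used by
  #    significance_summary(); powered against constant effects too.
  #  - "constant": full fit vs scalar covariate coefficients (do the
  #    effects vary over density?).
  fit_full_u <- mgcv::gam(fml_full, data = df, sp = rep(0, p + 1))
  fit_const_u <- mgcv::gam(fml_const, data = df, sp = 0)
  fit_int_u <- mgcv::gam(fml_int, data = df, sp = 0)
  RSS_fu <- rss(fit_full_u); edf_fu <- edf_tot(fit_full_u)
  RSS_cu <- rss(fit_const_u); edf_cu <- edf_tot(fit_const_u)
  RSS_0u <- rss(fit_int_u); edf_0u <- edf_tot(fit_int_u)
  if (edf_fu <= edf_cu)
    stop("penalties collapsed the functional terms (edf_full <= edf_constant)")
  ftest <- function(RSS_r, edf_r) {
    Fv <- ((RSS_r - RSS_fu) / (edf_fu - edf_r)) / (RSS_fu / (nM - edf_fu))
    c(F = Fv, p = pf(Fv, edf_fu - edf_r, nM - edf_fu, lower.tail = FALSE),
      df1 = edf_fu - edf_r, df2 = nM - edf_fu)
  }
  overall_model <- ftest(RSS_0u, edf_0u)
  overall_const <- ftest(RSS_cu, edf_cu)

  st <- summary(fit_full)$s.table
  cov_rows <- match(sprintf("s(d):%s", xnames), rownames(st))
  cov_tests <- data.frame(term = labels,
                          F = st[cov_rows, "F"],
                          p = st[cov_rows, "p-value"],
                          row.names = NULL)

  tss <- sum((df$y - mean(df$y))^2)
  adj_r2 <- function(RSS, edf) 1 - (RSS / (nM - edf)) / (tss / (nM - 1))
  fun_r2 <- function(RSS, edf)
    1 - (RSS / (nM - edf)) / (RSS_0 / (nM - edf_0))

  r2_adj_full <- adj_r2(RSS_f, edf_f)
  fr2_overall <- fun_r2(RSS_f, edf_f)
  fr2_per <- rep(NA_real_, p)
  sp_r <- rep(NA_real_, p)
  if (p > 0 && !light) {
    for (j in seq_len(p)) {
      fml_j <- stats::as.formula(paste("y ~", paste(c(sterm, byterms[j]),
                                                    collapse = " + ")))
      bj <- mgcv::gam(fml_j, data = df, method = method)
      fr2_per[j] <- fun_r2(rss(bj), edf_tot(bj))
      if (p > 1) {
        fml_mj <- stats::as.formula(paste("y ~",
          paste(c(sterm, byterms[-j]), collapse = " + ")))
        bmj <- mgcv::gam(fml_mj, data = df, method = method)
        r2_mj <- adj_r2(rss(bmj), edf_tot(bmj))
      } else {
        r2_mj <- adj_r2(RSS_0, edf_0)
      }
      sp_r[j] <- sqrt(max(0, r2_adj_full - r2_mj))
    }
  }

  obj <- structure(list(gam = fit_full, X = X, labels = labels,
                        xnames = xnames, argvals = argvals, Y = Y, ids = ids,
                        n = n, M = M, k = k, method = method,
                        RSS = RSS_f, edf = edf_f,
                        overall = overall_model,
                        overall_constant = overall_const,
                        cov_tests = cov_tests,
                        r_squared = r2_adj_full,
                        functional_r2 = list(overall = fr2_overall,
                                             per_covariate =
                                               setNames(fr2_per, labels)),
                        semipartial = setNames(sp_r, labels),
                        sigma2 = RSS_f / (nM - edf_f),
                        sp = fit_full$sp),
                   class = "fosr")
  obj
}

# Coefficient functions evaluated on a grid from a fitted mgcv model.
eval_beta <- function(gamfit, xnames, argvals) {
  nd <- data.frame(d = argvals)
  for (nm in xnames) nd[[nm]] <- 1
  tm <- predict(gamfit, newdata = nd, type = "terms")
  const <- attr(tm, "constant") %||% coef(gamfit)[["(Intercept)"]]
  beta <- cbind(`(Intercept)` = const + tm[, "s(d)"])
  for (nm in xnames) beta <- cbind(beta, tm[, sprintf("s(d):%s", nm)])
  beta
}

#' Coefficient functions of a fitted fosr model
#'
#' @param object a `fosr` fit.
#' @param ... unused.
#' @return data.frame: `density`, then one column per model term with the
#'   estimated coefficient function evaluated on the fitting grid.
#' @export
coef.fosr <- function(object, ...) {
  beta <- eval_beta(object$gam, object$xnames, object$argvals)
  colnames(beta) <- c("(Intercept)", object$labels)
  data.frame(density = object$argvals, beta, check.names = FALSE)
}

#' @export
fitted.fosr <- function(object, ...) {
  matrix(fitted(object$gam), object$n, object$M, byrow = TRUE,
         dimnames = list(object$ids, NULL))
}

#' @export
residuals.fosr <- function(object, ...) {
  object$Y - fitted(object)
}

#' Predict functional responses for new subjects
#'
#' @param object a `fosr` fit.
#' @param newdata data.frame of covariates (same terms as the fit); when
#'   omitted, fitted functions for the estimation sample are returned.
#' @param ... unused.
#' @return matrix, subjects x densities.
#' @export
predict.fosr <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(fitted(object))
  beta <- eval_beta(object$gam, object$xnames, object$argvals)
  Xn <- matrix(1, nrow(newdata), 1)
  for (lb in object$labels) {
    if (!lb %in% names(newdata)) {
      # reconstruct model-matrix columns (e.g. factor indicators)
      stop("newdata must contain numeric columns named exactly: ",
           paste(object$labels, collapse = ", "))
    }
    Xn <- cbind(Xn, newdata[[lb]])
  }
  out <- Xn %*% t(beta)
  rownames(out) <- rownames(newdata)
  out
}

#' Simulate functional responses from a fitted fosr model
#'
#' Parametric simulation: fitted functions plus i.i.d. Gaussian residuals
#' at the model's residual variance.
#'
#' @param object a `fosr` fit.
#' @param nsim number of replicate response matrices.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return list of `nsim` subjects x densities matrices.
#' @export
simulate.fosr <- function(object, nsim = 1, seed = NULL, ...) {
  code <- function() {
    mu <- fitted(object)
    lapply(seq_len(nsim), function(i)
      mu + matrix(rnorm(length(mu), 0, sqrt(object$sigma2)),
                  nrow(mu), ncol(mu)))
  }
  if (is.null(seed)) code() else with_seed(seed, code())
}

#' Overall likelihood-ratio-type F tests
#'
#' Both comparisons are computed from unpenalized companion fits of the
#' model formulas (classical nested F tests; shrunken-edf comparisons are
#' anticonservative). `type = "model"` (the default, and the gate used by
#' [significance_summary()]) compares the full fit against the
#' functional-intercept-only fit: do the covariates explain the response
#' at all? It retains power when effects are constant over density.
#' `type = "constant"` compares the full fit against scalar covariate
#' coefficients (functional intercept retained): do the effects vary over
#' density?
#'
#' @param object a `fosr` fit.
#' @param type which comparison to return.
#' @return named vector `F`, `p`, `df1`, `df2`.
#' @export
lr_overall_test <- function(object, type = c("model", "constant")) {
  stopifnot(inherits(object, "fosr"))
  type <- match.arg(type)
  if (type == "model") object$overall else object$overall_constant
}

#' Functional R-squared
#'
#' Variance explained beyond the functional-intercept-only model, adjusted
#' for effective degrees of freedom: overall (full model) and per covariate
#' (intercept plus one regressor).
#'
#' @param object a `fosr` fit.
#' @return list with `overall` and `per_covariate`.
#' @export
functional_r2 <- function(object) {
  stopifnot(inherits(object, "fosr"))
  object$functional_r2
}

#' Semi-partial correlations
#'
#' Square root of the (clamped-at-zero) drop in adjusted R-squared when
#' each regressor is removed from the full model.
#'
#' @param object a `fosr` fit.
#' @return named numeric vector, one entry per covariate.
#' @export
semipartial_r <- function(object) {
  stopifnot(inherits(object, "fosr"))
  object$semipartial
}

#' Case-bootstrap pointwise confidence bands for coefficient functions
#'
#' Resamples subjects with replacement, refits the model with smoothing
#' parameters fixed at the original REML estimates, and takes pointwise
#' percentiles of the coefficient-function draws. Rank-deficient resamples
#' are redrawn (count reported in attribute `"n_redraws"`).
#'
#' @param object a `fosr` fit.
#' @param parm unused (all coefficient functions are returned).
#' @param level confidence level (default 0.95).
#' @param n_boot bootstrap replicates (default 1000; >= 100 required).
#' @param seed integer seed (deterministic bands for a given seed).
#' @param ... unused.
#' @return object of class `fosr_ci`: list with `density` grid and, per
#'   term, a matrix with columns `lo`, `hi`.
#' @export
confint.fosr <- function(object, parm = NULL, level = 0.95, n_boot = 1000,
                         seed = 1L, ...) {
  if (n_boot < 100) stop("n_boot must be >= 100")
  n <- object$n; M <- object$M; p <- ncol(object$X)
  argvals <- object$argvals
  terms_all <- c("(Intercept)", object$labels)
  draws <- array(NA_real_, c(n_boot, M, p + 1))
  sterm <- sprintf('s(d, bs = "ps", k = %d, m = c(2, 1))', object$k)
  byterms <- sprintf('s(d, by = %s, bs = "ps", k = %d, m = c(2, 1))',
                     object$xnames, object$k)
  fml <- stats::as.formula(paste("y ~", paste(c(sterm, byterms),
                                              collapse = " + ")))
  n_redraws <- 0L
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, replace = TRUE)
        if (qr(cbind(1, object$X[idx, , drop = FALSE]))$rank == p + 1) break
        n_redraws <- n_redraws + 1L
        if (n_redraws > 1000L) stop("too many degenerate bootstrap resamples")
      }
      df <- data.frame(y = as.vector(t(object$Y[idx, , drop = FALSE])),
                       d = rep(argvals, n))
      for (j in seq_len(p))
        df[[object$xnames[j]]] <- rep(object$X[idx, j], each = M)
      bfit <- mgcv::gam(fml, data = df, sp = object$sp)
      draws[b, , ] <- eval_beta(bfit, object$xnames, argvals)
    }
  })
  alpha <- (1 - level) / 2
  out <- lapply(seq_len(p + 1), function(j) {
    lo <- apply(draws[, , j, drop = FALSE], 2, quantile, probs = alpha)
    hi <- apply(draws[, , j, drop = FALSE], 2, quantile, probs = 1 - alpha)
    cbind(lo = lo, hi = hi)
  })
  names(out) <- terms_all
  structure(list(density = argvals, bands = out, level = level,
                 n_boot = n_boot),
            class = "fosr_ci", n_redraws = n_redraws)
}

#' Three-condition significance summary
#'
#' A covariate is marked significant over exactly those contiguous density
#' ranges where (1) the overall constant-coefficient test is significant at
#' `alpha`, (2) the covariate's test in the full model is significant at
#' `alpha`, and (3) the pointwise bootstrap confidence band excludes zero.
#'
#' @param object a `fosr` fit.
#' @param ci a `fosr_ci` from [confint.fosr()].
#' @param alpha significance level for conditions (1) and (2); default
#'   0.001, the conservative threshold appropriate to the large effective
#'   degrees of freedom of stacked functional fits.
#' @return data.frame: `term`, `significant` (any range at all), `d_lo`,
#'   `d_hi`, `sign` (sign of the estimate over the range); one row per
#'   contiguous range, or a single all-NA-range row for covariates with no
#'   significant range.
#' @export
significance_summary <- function(object, ci, alpha = 0.001) {
  stopifnot(inherits(object, "fosr"), inherits(ci, "fosr_ci"))
  d <- object$argvals
  beta <- coef(object)
  overall_ok <- object$overall[["p"]] <= alpha
  out <- list()
  for (j in seq_along(object$labels)) {
    lb <- object$labels[j]
    cov_ok <- object$cov_tests$p[j] <= alpha
    band <- ci$bands[[lb]]
    excl <- band[, "lo"] > 0 | band[, "hi"] < 0
    sig <- overall_ok & cov_ok & excl
    if (!any(sig)) {
      out[[length(out) + 1]] <- data.frame(term = lb, significant = FALSE,
                                           d_lo = NA_real_, d_hi = NA_real_,
                                           sign = NA_real_)
      next
    }
    r <- rle(sig)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (i in which(r$values)) {
      est <- beta[[lb]][starts[i]:ends[i]]
      dd <- d[starts[i]:ends[i]]
      out[[length(out) + 1]] <- data.frame(term = lb, significant = TRUE,
                                           d_lo = min(dd), d_hi = max(dd),
                                           sign = sign(mean(est)))
    }
  }
  do.call(rbind, out)
}

#' @export
print.fosr <- function(x, ...) {
  cat("Function-on-scalar regression (penalized, cubic P-splines, k =",
      x$k, ")\n")
  cat(sprintf("  %d subjects x %d densities on [%.4g, %.4g]\n",
              x$n, x$M, min(x$argvals), max(x$argvals)))
  cat(sprintf("  Overall model test: F = %.3f, p = %.3g\n",
              x$overall[["F"]], x$overall[["p"]]))
  cat(sprintf("  Constant-vs-functional coefficients: F = %.3f, p = %.3g\n",
              x$overall_constant[["F"]], x$overall_constant[["p"]]))
  cat(sprintf("  Adjusted R-squared = %.3f; functional R-squared = %.3g\n",
              x$r_squared, x$functional_r2$overall))
  invisible(x)
}

#' @export
summary.fosr <- function(object, ...) {
  structure(list(fit = object), class = "summary.fosr")
}

#' @export
print.summary.fosr <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nPer-covariate tests (full model):\n")
  tab <- f$cov_tests
  tab$functional_r2 <- f$functional_r2$per_covariate[tab$term]
  tab$semipartial_r <- f$semipartial[tab$term]
  print(tab, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Plot coefficient functions with optional bootstrap bands
#'
#' @param x a `fosr` fit.
#' @param ci optional `fosr_ci` for shaded pointwise bands.
#' @param terms which terms to plot (default all covariates).
#' @param ... passed to [graphics::plot()].
#' @export
plot.fosr <- function(x, ci = NULL, terms = x$labels, ...) {
  beta <- coef(x)
  old <- graphics::par(mfrow = c(1, length(terms)))
  on.exit(graphics::par(old))
  for (lb in terms) {
    est <- beta[[lb]]
    ylim <- range(est, 0)
    if (!is.null(ci)) ylim <- range(ylim, ci$bands[[lb]])
    plot(x$argvals, est, type = "l", lwd = 2, ylim = ylim,
         xlab = "initial network density", ylab = bquote(beta(d)),
         main = lb, ...)
    if (!is.null(ci)) {
      b <- ci$bands[[lb]]
      graphics::polygon(c(x$argvals, rev(x$argvals)),
                        c(b[, "lo"], rev(b[, "hi"])),
                        col = grDevices::adjustcolor("steelblue", 0.3),
                        border = NA)
      graphics::lines(x$argvals, est, lwd = 2)
    }
    graphics::abline(h = 0, lty = 2)
  }
  invisible(x)
}
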