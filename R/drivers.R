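#' Climate anomaly layer (past minus present)
#'
#' Environmental layers are named numeric vectors keyed by cell id. The
#' anomaly convention throughout is past minus present (and, for projections,
#' future minus present), so a positive temperature anomaly means the other
#' period was warmer than today.
#'
#' @param past,present named numeric layers over the same cell set.
#' @return named numeric anomaly layer.
#' @export
compute_anomaly <- function(past, present) {
  if (is.null(names(past)) || is.null(names(present)))
    stopf("layers must be named by cell id")
  if (!setequal(names(past), names(present)) ||
      length(past) != length(present))
    stopf("cell sets of the two layers differ")
  present <- present[names(past)]
  past - present
}

#' Elevation range per cell
#'
#' Topographic heterogeneity proxy: the absolute difference between the
#' maximum and minimum elevation sample within each cell. Cells with a single
#' sample get 0.
#'
#' @param samples data.frame with columns `cell` and `elevation` (>= 1 row
#'   per cell).
#' @return named numeric layer of per-cell elevation range.
#' @export
elevation_range <- function(samples) {
  samples <- as.data.frame(samples)
  if (!all(c("cell", "elevation") %in% names(samples)))
    stopf("`samples` must have columns cell and elevation")
  if (nrow(samples) == 0L) stopf("no elevation samples supplied")
  if (anyNA(samples$elevation)) stopf("missing elevation values")
  rng <- tapply(samples$elevation, as.character(samples$cell),
                function(v) max(v) - min(v))
  out <- as.numeric(rng)
  names(out) <- names(rng)
  out
}

#' Z-standardize predictor columns
#'
#' Centres every column to mean 0 and scales to standard deviation 1
#' (denominator n - 1), so fitted slopes are comparable across predictors.
#' The centre/scale parameters are attached for inverse mapping.
#'
#' @param x data.frame or matrix of numeric predictors.
#' @return data.frame of standardized columns with attributes `center` and
#'   `scale`.
#' @export
standardize <- function(x) {
  x <- as.data.frame(x)
  if (ncol(x) == 0L) stopf("no columns to standardize")
  ctr <- vapply(x, mean, numeric(1))
  scl <- vapply(x, stats::sd, numeric(1))
  bad <- names(scl)[!is.finite(scl) | scl <= 0]
  if (length(bad))
    stopf("constant (or non-finite) column(s): %s", paste(bad, collapse = ", "))
  out <- as.data.frame(Map(function(col, m, s) (col - m) / s, x, ctr, scl))
  names(out) <- names(x)
  attr(out, "center") <- ctr
  attr(out, "scale") <- scl
  out
}

#' Assemble the per-cell driver table
#'
#' Joins the endemism response with environmental predictor layers over the
#' analysed cells, log10-transforms the response, and z-standardizes every
#' predictor. Cells with a zero response are excluded (log undefined; such
#' cells cannot carry endemism signal).
#'
#' @param pe named per-cell response (e.g. scaled PE), positive where used.
#' @param layers named list of environmental layers (named numeric vectors).
#' @param cells data.frame of grid cells (`id`, `x`, `y`) supplying
#'   coordinates.
#' @param log10_response log10-transform the response?
#' @return object of class `driver_table`: data.frame with `cell`, `x`, `y`,
#'   `response`, and one standardized column per predictor; standardization
#'   parameters in attributes.
#' @export
build_driver_table <- function(pe, layers, cells, log10_response = TRUE) {
  if (is.null(names(pe))) stopf("`pe` must be named by cell id")
  if (!length(layers) || is.null(names(layers)))
    stopf("`layers` must be a named list of layers")
  cells$id <- as.character(cells$id)
  ids <- names(pe)
  keep <- rep(TRUE, length(ids))
  if (log10_response) {
    keep <- pe > 0
    if (!all(keep))
      message(sprintf("dropping %d cell(s) with zero response before log10",
                      sum(!keep)))
  }
  ids <- ids[keep]
  if (!length(ids)) stopf("no cells left after dropping zero responses")
  for (nm in names(layers)) {
    lay <- layers[[nm]]
    if (!all(ids %in% names(lay)))
      stopf("layer '%s' is missing cells present in the response", nm)
  }
  if (!all(ids %in% cells$id)) stopf("response cells missing from `cells`")
  pred <- as.data.frame(lapply(layers, function(lay) as.numeric(lay[ids])))
  names(pred) <- names(layers)
  if (anyNA(pred)) stopf("missing predictor values on analysed cells")
  std <- standardize(pred)
  resp <- if (log10_response) log10(pe[ids]) else pe[ids]
  ci <- match(ids, cells$id)
  out <- cbind(data.frame(cell = ids, x = cells$x[ci], y = cells$y[ci],
                          response = as.numeric(resp)),
               std)
  attr(out, "center") <- attr(std, "center")
  attr(out, "scale") <- attr(std, "scale")
  attr(out, "log10_response") <- log10_response
  class(out) <- c("driver_table", "data.frame")
  out
}

#' Variance inflation factors
#'
#' VIF of predictor j is 1 / (1 - R^2_j) from regressing column j on all the
#' others; values above ~4 flag collinearity worth acting on. Perfectly
#' collinear columns are reported as `Inf` rather than raising an error.
#'
#' @param predictors data.frame or matrix with >= 2 numeric columns and more
#'   rows than columns.
#' @return named numeric vector of VIFs.
#' @export
vif <- function(predictors) {
  x <- as.matrix(as.data.frame(predictors))
  if (ncol(x) < 2L) stopf("need at least two predictors")
  if (nrow(x) <= ncol(x)) stopf("need more rows than predictors")
  out <- vapply(seq_len(ncol(x)), function(j) {
    fit <- stats::lm.fit(cbind(1, x[, -j, drop = FALSE]), x[, j])
    ssr <- sum(fit$residuals^2)
    sst <- sum((x[, j] - mean(x[, j]))^2)
    if (sst <= 0) return(Inf)
    r2 <- 1 - ssr / sst
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  stats::setNames(out, colnames(x))
}

#' Ordinary least squares fit with information criteria
#'
#' Thin wrapper around `stats::lm()` returning the pieces the model
#' comparison and diagnostics need: a coefficient table with 95% confidence
#' intervals, adjusted R^2, Gaussian log-likelihood, AIC and BIC.
#'
#' @param response numeric response vector.
#' @param predictors data.frame or matrix of predictors (no intercept
#'   column; one is added).
#' @return object of class `ols_fit`.
#' @export
fit_ols <- function(response, predictors) {
  X <- as.data.frame(predictors)
  if (anyNA(response) || anyNA(X)) stopf("missing values in model data")
  dat <- cbind(data.frame(.y = response), X)
  fit <- stats::lm(.y ~ ., data = dat)
  if (any(is.na(stats::coef(fit))))
    stopf("rank-deficient design: %s",
          paste(names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", "))
  ll <- as.numeric(stats::logLik(fit))
  cf <- summary(fit)$coefficients
  ci <- stats::confint(fit)
  coefs <- data.frame(term = rownames(cf),
                      estimate = cf[, 1], se = cf[, 2],
                      statistic = cf[, 3], p_value = cf[, 4],
                      ci_low = ci[, 1], ci_high = ci[, 2],
                      row.names = NULL)
  structure(list(
    model = "OLS",
    coefficients = coefs,
    adj_r_squared = summary(fit)$adj.r.squared,
    r_squared = summary(fit)$r.squared,
    logLik = ll,
    n_par = length(stats::coef(fit)) + 1,  # + sigma^2
    AIC = stats::AIC(fit),
    BIC = stats::BIC(fit),
    residuals = as.numeric(stats::residuals(fit)),
    fitted = as.numeric(stats::fitted(fit)),
    response = as.numeric(response),
    lm = fit
  ), class = "ols_fit")
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf("<ols_fit> n=%d, adjR2=%.3f, AIC=%.1f, BIC=%.1f\n",
              length(x$response), x$adj_r_squared, x$AIC, x$BIC))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' k-nearest-neighbour spatial weights
#'
#' Links every site to its k nearest neighbours by planar Euclidean distance
#' and (by default) row-standardizes the weights so each row sums to one.
#' The neighbour relation need not be symmetric. Distance ties are resolved
#' by stable site order and reported via a message.
#'
#' @param coords two-column matrix or data.frame of planar coordinates.
#' @param k number of neighbours (1 <= k < n).
#' @param row_standardize divide each row by its sum?
#' @return object of class `spatial_weights`: list with the sparse matrix
#'   `W`, `neighbours` (list of integer indices), `k`, `row_standardized`.
#' @export
knn_weights <- function(coords, k, row_standardize = TRUE) {
  xy <- as.matrix(coords)
  if (ncol(xy) != 2L) stopf("`coords` must have two columns")
  n <- nrow(xy)
  if (k < 1 || k >= n) stopf("need 1 <= k < n")
  d <- as.matrix(stats::dist(xy))
  diag(d) <- Inf
  had_tie <- FALSE
  nb <- vector("list", n)
  for (i in seq_len(n)) {
    ord <- order(d[i, ], seq_len(n))  # stable: index breaks distance ties
    sel <- ord[seq_len(k)]
    cut <- d[i, sel[k]]
    if (sum(d[i, ] <= cut + 1e-12) > k) had_tie <- TRUE
    nb[[i]] <- sort(sel)
  }
  if (had_tie)
    message("distance ties at the k-th neighbour resolved by stable site order")
  i_idx <- rep(seq_len(n), each = k)
  j_idx <- unlist(nb)
  w <- rep(if (row_standardize) 1 / k else 1, n * k)
  W <- Matrix::sparseMatrix(i = i_idx, j = j_idx, x = w, dims = c(n, n))
  structure(list(W = W, neighbours = nb, k = k,
                 row_standardized = row_standardize, coords = xy),
            class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat(sprintf("<spatial_weights> n=%d, k=%d, %srow-standardized\n",
              nrow(x$W), x$k, if (x$row_standardized) "" else "not "))
  invisible(x)
}

# Eigenvalues of W for the SAR log-determinant; cached on the weights object.
weights_eigenvalues <- function(W) {
  if (inherits(W, "spatial_weights")) {
    if (!is.null(W$eigenvalues)) return(W$eigenvalues)
    return(eigen(as.matrix(W$W), only.values = TRUE)$values)
  }
  eigen(as.matrix(W), only.values = TRUE)$values
}

#' Precompute spatial-weights eigenvalues
#'
#' The SAR-error likelihood needs the eigenvalues of W for its
#' log-determinant term; computing them once and storing them on the weights
#' object makes repeated fits on the same lattice cheap.
#'
#' @param weights a [knn_weights()] object.
#' @return the same object with an `eigenvalues` element.
#' @export
precompute_eigen <- function(weights) {
  stopifnot(inherits(weights, "spatial_weights"))
  weights$eigenvalues <- weights_eigenvalues(weights)
  weights
}

#' Maximum-likelihood SAR error model
#'
#' Fits y = X beta + u with spatially autocorrelated errors u = lambda W u +
#' eps, eps iid Gaussian, by profile maximum likelihood over the spatial
#' parameter lambda. The Jacobian log|I - lambda W| is computed exactly from
#' the eigenvalues of W (complex pairs handled via moduli), which is the
#' appropriate method at desk-scale n. For each candidate lambda, beta and
#' sigma^2 are the GLS estimates on the whitened system (I - lambda W) y.
#'
#' When `coords` and `k_scan` are given instead of a single `weights`
#' object, one model is fitted per k and the best by AIC is returned (the
#' scan is reported in `$scan`).
#'
#' @param response numeric response vector.
#' @param predictors data.frame/matrix of predictors (intercept added).
#' @param weights a [knn_weights()] object (row-standardized).
#' @param coords,k_scan alternative to `weights`: site coordinates plus a
#'   vector of neighbour counts to scan.
#' @param lambda_fixed optional: skip the profile optimization and evaluate
#'   at this lambda (0 reduces the model to OLS).
#' @return object of class `sar_fit`: coefficient table with asymptotic 95%
#'   confidence intervals, `lambda`, `logLik`, `AIC`, `BIC`,
#'   `nagelkerke_r2` (against the intercept-only non-spatial model),
#'   whitened residuals (`residuals`), raw residuals (`residuals_raw`), and
#'   the admissible lambda `interval`.
#' @export
fit_sar_error <- function(response, predictors, weights = NULL,
                          coords = NULL, k_scan = NULL,
                          lambda_fixed = NULL) {
  if (is.null(weights)) {
    if (is.null(coords) || is.null(k_scan))
      stopf("supply `weights`, or `coords` plus `k_scan`")
    fits <- lapply(k_scan, function(k)
      fit_sar_error(response, predictors, knn_weights(coords, k)))
    aics <- vapply(fits, function(f) f$AIC, numeric(1))
    best <- fits[[which.min(aics)]]
    best$scan <- data.frame(k = k_scan, AIC = aics,
                            logLik = vapply(fits, function(f) f$logLik, numeric(1)),
                            lambda = vapply(fits, function(f) f$lambda, numeric(1)))
    return(best)
  }
  stopifnot(inherits(weights, "spatial_weights"))
  if (!weights$row_standardized)
    stopf("SAR error fit expects row-standardized weights")
  y <- as.numeric(response)
  X <- cbind(`(Intercept)` = 1, as.matrix(as.data.frame(predictors)))
  n <- length(y)
  if (nrow(X) != n) stopf("response/predictor length mismatch")
  if (anyNA(y) || anyNA(X)) stopf("missing values in model data")
  W <- weights$W
  ev <- weights_eigenvalues(weights)
  re <- Re(ev)
  ev_max <- max(re)
  ev_min <- min(re)
  lo <- if (ev_min < 0) 1 / ev_min + 1e-6 else -0.9999
  hi <- if (ev_max > 0) 1 / ev_max - 1e-6 else 0.9999
  if (!(lo < 0 && hi > 0))
    stopf("degenerate admissible interval for lambda: (%.3f, %.3f)", lo, hi)

  Wy <- as.numeric(W %*% y)
  WX <- as.matrix(W %*% X)

  profile <- function(lambda) {
    ys <- y - lambda * Wy
    Xs <- X - lambda * WX
    fit <- stats::lm.fit(Xs, ys)
    rss <- sum(fit$residuals^2)
    sigma2 <- rss / n
    ldet <- sum(log(Mod(1 - lambda * ev)))
    ll <- -n / 2 * (log(2 * pi) + log(sigma2) + 1) + ldet
    list(ll = ll, fit = fit, sigma2 = sigma2)
  }
  lambda <- if (!is.null(lambda_fixed)) {
    if (lambda_fixed <= lo || lambda_fixed >= hi)
      stopf("lambda_fixed outside the admissible interval (%.3f, %.3f)", lo, hi)
    lambda_fixed
  } else {
    stats::optimize(function(l) profile(l)$ll, c(lo, hi),
                    maximum = TRUE, tol = .Machine$double.eps^0.4)$maximum
  }
  prof <- profile(lambda)
  if (!is.finite(prof$ll))
    stopf("SAR likelihood did not converge; lambda profile degenerate near %.3f", lambda)
  beta <- prof$fit$coefficients
  Xs <- X - lambda * WX
  XtX <- crossprod(Xs)
  vcov_beta <- prof$sigma2 * solve(XtX)
  se <- sqrt(diag(vcov_beta))
  z <- beta / se
  coefs <- data.frame(term = colnames(X),
                      estimate = as.numeric(beta), se = se,
                      statistic = z,
                      p_value = 2 * stats::pnorm(-abs(z)),
                      ci_low = beta - stats::qnorm(0.975) * se,
                      ci_high = beta + stats::qnorm(0.975) * se,
                      row.names = NULL)
  n_par <- ncol(X) + 2  # beta, lambda, sigma^2
  ll <- prof$ll
  ll_null <- as.numeric(stats::logLik(stats::lm(y ~ 1)))
  resid_raw <- y - as.numeric(X %*% beta)
  resid_white <- resid_raw - lambda * as.numeric(W %*% resid_raw)
  structure(list(
    model = "SAR_error",
    coefficients = coefs,
    lambda = lambda,
    sigma2 = prof$sigma2,
    logLik = ll,
    n_par = n_par,
    AIC = -2 * ll + 2 * n_par,
    BIC = -2 * ll + log(n) * n_par,
    nagelkerke_r2 = 1 - exp(2 / n * (ll_null - ll)),
    residuals = resid_white,
    residuals_raw = resid_raw,
    fitted = y - resid_white,
    response = y,
    interval = c(lo, hi),
    k = weights$k
  ), class = "sar_fit")
}

#' @export
print.sar_fit <- function(x, ...) {
  cat(sprintf("<sar_fit> n=%d, lambda=%.3f, NagelkerkeR2=%.3f, AIC=%.1f, BIC=%.1f\n",
              length(x$response), x$lambda, x$nagelkerke_r2, x$AIC, x$BIC))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Moran's I test for spatial autocorrelation
#'
#' I = (n / S0) * (z' W z) / (z' z) with z the centred values. The expected
#' value under no autocorrelation is -1/(n-1). The analytic p-value uses, by
#' default, the randomization-assumption variance (the permutation-null
#' moments, involving the sample kurtosis); `assumption = "normality"`
#' switches to the Gaussian-sampling variance. `n_perm > 0` adds an actual
#' permutation p-value.
#'
#' @param values numeric vector (non-constant).
#' @param weights a [knn_weights()] object or a (sparse) weights matrix with
#'   zero diagonal.
#' @param alternative "two.sided", "greater" (positive SAC), or "less".
#' @param assumption "randomization" (default) or "normality" variance.
#' @param n_perm optional number of random permutations.
#' @param seed optional seed for the permutation p-value.
#' @return list with `I`, `expected`, `variance`, `sd`, `p_value`, and
#'   optionally `p_perm`.
#' @export
moran_test <- function(values, weights, alternative = "two.sided",
                       assumption = c("randomization", "normality"),
                       n_perm = 0, seed = NULL) {
  assumption <- match.arg(assumption)
  W <- if (inherits(weights, "spatial_weights")) weights$W else
    Matrix::Matrix(weights, sparse = TRUE)
  x <- as.numeric(values)
  n <- length(x)
  if (n < 3L) stopf("need at least 3 observations")
  if (stats::sd(x) == 0) stopf("`values` are constant")
  z <- x - mean(x)
  S0 <- sum(W)
  moran_I <- function(z) (n / S0) * as.numeric(crossprod(z, W %*% z)) / sum(z^2)
  I <- moran_I(z)
  Wt <- Matrix::t(W)
  S1 <- sum((W + Wt)^2) / 2
  rs <- Matrix::rowSums(W)
  cs <- Matrix::colSums(W)
  S2 <- sum((rs + cs)^2)
  EI <- -1 / (n - 1)
  if (assumption == "normality") {
    VI <- (n^2 * S1 - n * S2 + 3 * S0^2) / (S0^2 * (n^2 - 1)) - EI^2
  } else {
    b2 <- n * sum(z^4) / sum(z^2)^2   # sample kurtosis
    VI <- (n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * S0^2) -
             b2 * ((n^2 - n) * S1 - 2 * n * S2 + 6 * S0^2)) /
      ((n - 1) * (n - 2) * (n - 3) * S0^2) - EI^2
  }
  zscore <- (I - EI) / sqrt(VI)
  p <- switch(alternative,
              two.sided = 2 * stats::pnorm(-abs(zscore)),
              greater = stats::pnorm(zscore, lower.tail = FALSE),
              less = stats::pnorm(zscore),
              stopf("unknown alternative '%s'", alternative))
  out <- list(I = I, expected = EI, variance = VI, sd = sqrt(VI),
              statistic = zscore, p_value = p, alternative = alternative)
  if (n_perm > 0) {
    perm <- with_seed(seed,
      vapply(seq_len(n_perm), function(i) moran_I(sample(z)), numeric(1)))
    out$p_perm <- switch(alternative,
      two.sided = (1 + sum(abs(perm - EI) >= abs(I - EI) - 1e-12)) / (n_perm + 1),
      greater = (1 + sum(perm >= I - 1e-12)) / (n_perm + 1),
      less = (1 + sum(perm <= I + 1e-12)) / (n_perm + 1))
  }
  out
}

#' Moran's I correlogram over distance bins
#'
#' Splits site pairs into distance classes and computes Moran's I per class
#' using binary within-bin weights, the standard visual check that a model's
#' residuals carry no autocorrelation at any lag.
#'
#' @param values numeric vector.
#' @param coords two-column coordinates.
#' @param breaks numeric vector of distance-class boundaries, or a single
#'   integer number of equal-width bins.
#' @return data.frame with `lag_low`, `lag_high`, `lag_mid`, `n_pairs`, `I`,
#'   `p_value` per bin (bins with no pairs are dropped).
#' @export
moran_correlogram <- function(values, coords, breaks = 8) {
  xy <- as.matrix(coords)
  d <- as.matrix(stats::dist(xy))
  if (length(breaks) == 1L)
    breaks <- seq(0, max(d), length.out = breaks + 1L)
  out <- lapply(seq_len(length(breaks) - 1L), function(b) {
    lo <- breaks[b]; hi <- breaks[b + 1L]
    M <- (d > lo & d <= hi) * 1
    diag(M) <- 0
    if (sum(M) == 0) return(NULL)
    mt <- moran_test(values, M)
    data.frame(lag_low = lo, lag_high = hi, lag_mid = (lo + hi) / 2,
               n_pairs = sum(M) / 2, I = mt$I, p_value = mt$p_value)
  })
  do.call(rbind, out)
}

#' Rank fitted models by information criteria
#'
#' @param fits named list of `ols_fit` / `sar_fit` objects sharing the same
#'   response vector.
#' @return data.frame sorted by AIC with `delta_AIC` and `delta_BIC`.
#' @export
model_selection <- function(fits) {
  if (!length(fits)) stopf("no fits supplied")
  if (is.null(names(fits)))
    names(fits) <- paste0("model", seq_along(fits))
  y0 <- fits[[1]]$response
  same <- vapply(fits, function(f) isTRUE(all.equal(f$response, y0)), logical(1))
  if (!all(same)) stopf("fits do not share the same response vector")
  tab <- data.frame(
    model = names(fits),
    type = vapply(fits, function(f) f$model, character(1)),
    logLik = vapply(fits, function(f) f$logLik, numeric(1)),
    n_par = vapply(fits, function(f) f$n_par, numeric(1)),
    AIC = vapply(fits, function(f) f$AIC, numeric(1)),
    BIC = vapply(fits, function(f) f$BIC, numeric(1)),
    row.names = NULL
  )
  tab <- tab[order(tab$AIC), ]
  tab$delta_AIC <- tab$AIC - min(tab$AIC)
  tab$delta_BIC <- tab$BIC - min(tab$BIC)
  rownames(tab) <- NULL
  tab
}
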