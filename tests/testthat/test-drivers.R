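test_that("anomalies are element-wise past minus present", {
  ids <- sprintf("c%d", 1:6)
  present <- setNames(rnorm(6), ids)
  expect_equal(compute_anomaly(present, present),
               setNames(rep(0, 6), ids))
  expect_equal(unname(compute_anomaly(setNames(10, "a"), setNames(4, "a"))), 6)
  set.seed(2)
  past <- setNames(rnorm(6), ids)
  expect_equal(compute_anomaly(past, present), past - present)
  # order-insensitive join on cell ids
  expect_equal(compute_anomaly(past, present[rev(ids)]), past - present)
  expect_error(compute_anomaly(past, present[1:5]), "differ")
})

test_that("elevation range is max minus min per cell", {
  s <- data.frame(cell = c("a", "a", "a", "b", "b", "c"),
                  elevation = c(100, 350, 80, 5, 5, 42))
  er <- elevation_range(s)
  expect_equal(er[["a"]], 270)
  expect_equal(er[["b"]], 0)
  expect_equal(er[["c"]], 0)
  set.seed(4)
  r <- data.frame(cell = sample(letters[1:4], 40, replace = TRUE),
                  elevation = runif(40, 0, 1000))
  er2 <- elevation_range(r)
  for (cc in names(er2))
    expect_equal(er2[[cc]], diff(range(r$elevation[r$cell == cc])))
})

test_that("standardization gives exact z-scores with the n-1 denominator", {
  z <- standardize(data.frame(v = c(1, 2, 3)))
  expect_equal(z$v, c(-1, 0, 1))
  expect_equal(attr(z, "center")[["v"]], 2)
  expect_equal(attr(z, "scale")[["v"]], 1)
  # idempotent on already-standardized input
  z2 <- standardize(z)
  expect_equal(z2$v, z$v, tolerance = 1e-12)
  expect_error(standardize(data.frame(ok = 1:3, flat = rep(7, 3))), "flat")
})

test_that("VIF matches the two-predictor closed form and flags collinearity", {
  set.seed(10)
  n <- 400
  x1 <- rnorm(n)
  x2 <- 0.6 * x1 + sqrt(1 - 0.36) * rnorm(n)
  v <- vif(data.frame(x1 = x1, x2 = x2))
  r <- cor(x1, x2)
  expect_equal(unname(v), rep(1 / (1 - r^2), 2), tolerance = 1e-9)

  orth <- qr.Q(qr(matrix(rnorm(n * 3), n, 3)))
  orth <- scale(orth, center = TRUE, scale = FALSE)   # centre, keep near-orthogonality
  colnames(orth) <- c("a", "b", "c")
  expect_equal(unname(vif(orth)), rep(1, 3), tolerance = 0.02)

  dup <- data.frame(a = x1, b = x1)
  expect_true(all(is.infinite(vif(dup))))
})

test_that("OLS reproduces the normal-equation solution and degenerate cases", {
  x <- c(1, 2, 3, 4, 5)
  y_exact <- 2 + 3 * x
  f <- suppressWarnings(fit_ols(y_exact, data.frame(x = x)))  # exact fit
  expect_equal(f$coefficients$estimate, c(2, 3), tolerance = 1e-10)
  expect_equal(f$r_squared, 1)
  expect_equal(f$residuals, rep(0, 5), tolerance = 1e-10)

  set.seed(12)
  X <- matrix(rnorm(60 * 2), 60, 2, dimnames = list(NULL, c("a", "b")))
  y <- rnorm(60)
  f2 <- fit_ols(y, as.data.frame(X))
  beta_hat <- solve(crossprod(cbind(1, X)), crossprod(cbind(1, X), y))
  expect_equal(f2$coefficients$estimate, as.numeric(beta_hat), tolerance = 1e-10)
  expect_lt(abs(f2$adj_r_squared), 0.1)  # pure-noise response

  expect_error(fit_ols(y, data.frame(a = X[, 1], b = X[, 1])), "rank")
})

test_that("kNN weights link true nearest neighbours and row-standardize", {
  # 3 collinear points: the middle one links to the nearer endpoint
  co <- cbind(c(0, 1, 3), c(0, 0, 0))
  w <- knn_weights(co, 1)
  expect_equal(w$neighbours[[2]], 1L)
  expect_equal(w$neighbours[[3]], 2L)
  expect_equal(unname(Matrix::rowSums(w$W)), rep(1, 3))

  set.seed(14)
  pts <- cbind(runif(40), runif(40))
  w3 <- knn_weights(pts, 3)
  d <- as.matrix(dist(pts)); diag(d) <- Inf
  for (i in 1:40)
    expect_setequal(w3$neighbours[[i]], order(d[i, ])[1:3])
  expect_equal(unname(Matrix::rowSums(w3$W)), rep(1, 40))
  expect_true(all(Matrix::diag(w3$W) == 0))
  expect_error(knn_weights(pts, 40), "k < n")
})

test_that("SAR error with lambda fixed at 0 reproduces OLS", {
  set.seed(15)
  co <- as.matrix(expand.grid(x = 1:8, y = 1:8))
  n <- nrow(co)
  X <- data.frame(a = rnorm(n), b = rnorm(n))
  y <- 1 + 0.5 * X$a - 0.7 * X$b + rnorm(n)
  w <- suppressMessages(knn_weights(co, 4))
  sar0 <- fit_sar_error(y, X, w, lambda_fixed = 0)
  ols <- fit_ols(y, X)
  expect_equal(sar0$coefficients$estimate, ols$coefficients$estimate,
               tolerance = 1e-6)
  expect_equal(sar0$logLik, ols$logLik, tolerance = 1e-8)
})

test_that("SAR error recovers a zero and a strong spatial signal", {
  set.seed(16)
  co <- as.matrix(expand.grid(x = 1:12, y = 1:12))
  n <- nrow(co)
  w <- suppressMessages(precompute_eigen(knn_weights(co, 4)))
  X <- data.frame(a = rnorm(n), b = rnorm(n))
  Xm <- cbind(1, as.matrix(X))
  beta <- c(1, 2, -1.5)

  # lambda = 0: fitted lambda near zero, beta inside OLS confidence bands
  y0 <- as.numeric(Xm %*% beta) + rnorm(n)
  f0 <- fit_sar_error(y0, X, w)
  expect_lt(abs(f0$lambda), 0.35)  # sampling sd of lambda-hat ~0.12 at n=144
  ols0 <- fit_ols(y0, X)
  expect_true(all(f0$coefficients$estimate > ols0$coefficients$ci_low &
                  f0$coefficients$estimate < ols0$coefficients$ci_high))

  # lambda = 0.7: recovered within a sensible band, SAR preferred by AIC
  A <- diag(n) - 0.7 * as.matrix(w$W)
  y1 <- as.numeric(Xm %*% beta) + as.numeric(solve(A, rnorm(n)))
  f1 <- fit_sar_error(y1, X, w)
  expect_lt(abs(f1$lambda - 0.7), 0.2)
  sel <- model_selection(list(OLS = fit_ols(y1, X), SAR = f1))
  expect_equal(sel$model[1], "SAR")
  expect_true(all(diff(sel$AIC) >= 0))
  expect_equal(sel$delta_AIC[1], 0)
  # lambda within the admissible interval from the weights eigenvalues
  expect_gt(f1$lambda, f1$interval[1])
  expect_lt(f1$lambda, f1$interval[2])
})

test_that("k-scan picks a weight structure by AIC and reports the scan", {
  set.seed(18)
  co <- as.matrix(expand.grid(x = 1:9, y = 1:9))
  n <- nrow(co)
  X <- data.frame(a = rnorm(n))
  w4 <- suppressMessages(knn_weights(co, 4))
  A <- diag(n) - 0.6 * as.matrix(w4$W)
  y <- 1 + 2 * X$a + as.numeric(solve(A, rnorm(n)))
  f <- suppressMessages(fit_sar_error(y, X, coords = co, k_scan = c(2, 4, 6)))
  expect_s3_class(f, "sar_fit")
  expect_equal(nrow(f$scan), 3L)
  expect_equal(f$AIC, min(f$scan$AIC))
  expect_true(f$k %in% c(2, 4, 6))
})

test_that("Moran's I matches hand values and the independent ape oracle", {
  # perfect checkerboard under rook weights: I = -1
  co <- expand.grid(x = 1:4, y = 1:4)
  vals <- (-1)^(co$x + co$y)
  d <- as.matrix(dist(co))
  Wrook <- (abs(d - 1) < 1e-9) * 1
  m <- moran_test(vals, Wrook)
  expect_equal(m$I, -1, tolerance = 1e-12)
  expect_equal(m$expected, -1 / 15)

  set.seed(20)
  x <- rnorm(30)
  pts <- cbind(runif(30), runif(30))
  w <- knn_weights(pts, 4)
  m2 <- moran_test(x, w)
  # independent implementation used as cross-check only
  orc <- ape::Moran.I(x, as.matrix(w$W))
  expect_equal(m2$I, orc$observed, tolerance = 1e-10)
  expect_equal(m2$expected, orc$expected, tolerance = 1e-12)
  expect_equal(m2$sd, orc$sd, tolerance = 1e-10)
  expect_equal(m2$p_value, orc$p.value, tolerance = 1e-8)

  # permutation p agrees with the analytic approximation
  m3 <- moran_test(x, w, n_perm = 2000, seed = 6)
  expect_lt(abs(m3$p_perm - m3$p_value),
            3 * sqrt(0.25 / 2000) + 0.02)
  expect_error(moran_test(rep(1, 30), w), "constant")
})

test_that("the correlogram decays for an autocorrelated field", {
  set.seed(22)
  spec <- scenario_spec(nx = 15, ny = 15)
  layers <- simulate_env_layers(spec, seed = 3)
  cells <- lattice_cells(15, 15)
  cg <- moran_correlogram(unname(layers$MAT), cells[, c("x", "y")],
                          breaks = c(0, 1.5, 3, 6, 10))
  expect_gt(cg$I[1], cg$I[3])
  expect_gt(cg$I[1], 0.2)  # strong short-range autocorrelation
})

test_that("driver table assembly standardizes predictors and logs the response", {
  ids <- sprintf("c%d", 1:50)
  cells <- data.frame(id = ids, x = seq_along(ids), y = 0)
  set.seed(24)
  pe <- setNames(c(0, runif(49, 0.001, 0.1)), ids)  # one zero-PE cell
  layers <- list(MAT = setNames(rnorm(50), ids),
                 AP = setNames(rnorm(50), ids))
  expect_message(tab <- build_driver_table(pe, layers, cells), "zero response")
  expect_equal(nrow(tab), 49L)
  expect_equal(mean(tab$MAT), 0, tolerance = 1e-9)
  expect_equal(sd(tab$MAT), 1, tolerance = 1e-9)
  expect_equal(tab$response, unname(log10(pe[pe > 0])))
  expect_error(build_driver_table(pe, list(MAT = layers$MAT[1:10]), cells),
               "missing cells")
})

test_that("model selection validates shared responses", {
  set.seed(26)
  y <- rnorm(40)
  X <- data.frame(a = rnorm(40))
  f1 <- fit_ols(y, X)
  f2 <- fit_ols(y, data.frame(a = X$a, junk = rnorm(40)))
  sel <- model_selection(list(base = f1, noisy = f2))
  expect_equal(sort(sel$model), c("base", "noisy"))
  f3 <- fit_ols(rnorm(40), X)
  expect_error(model_selection(list(f1, f3)), "same response")
  # identical fits tie at delta 0
  sel2 <- model_selection(list(a = f1, b = f1))
  expect_equal(sel2$delta_AIC, c(0, 0))
})
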