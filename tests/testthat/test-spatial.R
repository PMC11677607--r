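grid_coords <- function(side) {
  as.matrix(expand.grid(x = seq_len(side), y = seq_len(side)))
}

test_that("knn weights link rook neighbours on a regular grid", {
  xy <- grid_coords(5)
  w <- knn_weights(xy, k = 4, longlat = FALSE)
  expect_equal(rowSums(w$W), rep(1, 25), ignore_attr = TRUE)
  expect_true(all(diag(w$W) == 0))
  # interior site (3,3) is row 13: neighbours are the 4 rook-adjacent cells
  i <- which(xy[, 1] == 3 & xy[, 2] == 3)
  nb <- which(w$W[i, ] > 0)
  expected <- which((abs(xy[, 1] - 3) + abs(xy[, 2] - 3)) == 1)
  expect_setequal(nb, expected)
  # brute-force distance sort agrees for every site
  D <- as.matrix(dist(xy))
  for (s in c(1, 7, 13, 25)) {
    d <- D[s, ]; d[s] <- Inf
    expect_setequal(which(w$W[s, ] > 0), order(d)[1:4])
  }
  expect_error(knn_weights(xy[1:3, ], k = 4), "k \\+ 1")
  expect_warning(knn_weights(rbind(xy, xy[1, ]), k = 2, longlat = FALSE),
                 "duplicate")
})

test_that("weights triplets round-trip the nonzero entries", {
  w <- knn_weights(grid_coords(3), k = 2, longlat = FALSE)
  tri <- weights_triplets(w)
  expect_equal(nrow(tri), sum(w$W != 0))
  expect_equal(tri$w, w$W[cbind(tri$i, tri$j)])
})

test_that("morans_i matches ape and its permutation moments", {
  set.seed(14)
  xy <- matrix(runif(60), 30, 2)
  w <- knn_weights(xy, k = 4, longlat = FALSE)
  x <- rnorm(30)
  ours <- morans_i(x, w)
  ref <- ape::Moran.I(x, w$W)
  expect_equal(ours$I, ref$observed, tolerance = 1e-12)
  expect_equal(ours$expected, ref$expected, tolerance = 1e-12)
  expect_equal(ours$expected, -1 / 29)

  # permutation oracle for the randomization sd
  perm <- replicate(4000, morans_i(sample(x), w)$I)
  expect_lt(abs(mean(perm) - ours$expected), 3 * sd(perm) / sqrt(4000))
  expect_lt(abs(sd(perm) - ours$sd), 0.05 * ours$sd)

  expect_error(morans_i(rep(1, 30), w), "constant")
})

test_that("morans_i detects checkerboard repulsion and smooth surfaces", {
  xy <- grid_coords(6)
  w <- knn_weights(xy, k = 4, longlat = FALSE)
  checker <- (-1)^(xy[, 1] + xy[, 2])
  expect_lt(morans_i(checker, w)$I, -0.5)
  smooth <- xy[, 1] + xy[, 2]
  res <- morans_i(smooth, w)
  expect_gt(res$I, 0.5)
  expect_lt(res$p_value, 0.01)
})

test_that("SAR lag fit reduces to OLS when autocorrelation is absent", {
  # degenerate all-zero weights: equality is exact
  set.seed(41)
  n <- 60
  X <- cbind(a = rnorm(n), b = rnorm(n))
  y <- 1 + X %*% c(2, -1) + rnorm(n)
  f0 <- fit_sar_lag(y, X, matrix(0, n, n))
  expect_equal(f0$rho, 0)
  expect_equal(unname(f0$coefficients), unname(coef(lm(y ~ X))),
               tolerance = 1e-10)

  # simulated rho = 0 on real weights: rho_hat near 0, betas near OLS
  land <- simulate_landscape(landscape_scenario(n_sites = 150, rho_true = 0,
                                                seed = 1))
  fit <- fit_sar_lag(land$y, land$X, land$weights)
  expect_lt(abs(fit$rho), 0.1)
  bols <- coef(lm(land$y ~ land$X))[-1]
  expect_equal(unname(fit$coefficients[-1]), unname(bols), tolerance = 0.02)
})

test_that("SAR profile likelihood is maximized and rho stays in bounds", {
  land <- simulate_landscape(landscape_scenario(n_sites = 100, rho_true = 0.6,
                                                seed = 21))
  fit <- fit_sar_lag(land$y, land$X, land$weights)
  expect_gt(fit$rho, fit$rho_interval[1])
  expect_lt(fit$rho, fit$rho_interval[2])
  # logLik at rho_hat >= logLik of the rho = 0 (OLS) profile point
  ols <- lm(land$y ~ land$X)
  n <- length(land$y)
  s2 <- sum(residuals(ols)^2) / n
  ll0 <- -n / 2 * (log(2 * pi * s2) + 1)
  expect_gte(fit$logLik, ll0)
  expect_equal(fit$aic, 2 * fit$k - 2 * fit$logLik)
})

test_that("SAR residuals lose the autocorrelation OLS residuals retain", {
  closer_sar <- 0; closer_ols <- 0
  for (s in 1:20) {
    land <- simulate_landscape(landscape_scenario(n_sites = 100,
                                                  rho_true = 0.7, seed = 300 + s))
    fit <- fit_sar_lag(land$y, land$X, land$weights)
    e_ols <- residuals(lm(land$y ~ land$X))
    i_sar <- morans_i(fit$residuals, land$weights)
    i_ols <- morans_i(e_ols, land$weights)
    d_sar <- abs(i_sar$I - i_sar$expected)
    d_ols <- abs(i_ols$I - i_ols$expected)
    if (d_sar < d_ols) closer_sar <- closer_sar + 1 else closer_ols <- closer_ols + 1
  }
  expect_gt(closer_sar, closer_ols)
})

test_that("spatial error variant fits and agrees with lag under rho = 0", {
  land <- simulate_landscape(landscape_scenario(n_sites = 120, rho_true = 0,
                                                seed = 77))
  flag <- fit_sar_lag(land$y, land$X, land$weights, variant = "lag")
  ferr <- fit_sar_lag(land$y, land$X, land$weights, variant = "error")
  expect_equal(unname(flag$coefficients[-1]), unname(ferr$coefficients[-1]),
               tolerance = 0.05)
  expect_lt(abs(ferr$rho), 0.25)
})

test_that("pseudo-R2 behaves like a fraction of explained variation", {
  set.seed(9)
  n <- 100
  xy <- matrix(runif(2 * n), n, 2)
  w <- knn_weights(xy, k = 4, longlat = FALSE)
  x <- rnorm(n)
  # near-noiseless data: pseudo-R2 approaches 1
  y1 <- 3 * x + rnorm(n, 0, 0.01)
  f1 <- fit_sar_lag(y1, cbind(x = x), w)
  expect_gt(pseudo_r2(f1, y1), 0.99)
  # intercept-only model vs itself: 0
  y0 <- rnorm(n)
  f0 <- fit_sar_lag(y0, NULL, matrix(0, n, n))
  r20 <- suppressWarnings(pseudo_r2(f0, y0))  # clamp warning expected at exactly 0
  expect_equal(r20, 0, tolerance = 1e-10)
  # monotone in the fitted log-likelihood
  y2 <- 3 * x + rnorm(n, 0, 1)
  f2 <- fit_sar_lag(y2, cbind(x = x), w)
  expect_lt(pseudo_r2(f2, y2), pseudo_r2(f1, y1))
  expect_gte(pseudo_r2(f2, y2), 0)
  expect_lte(pseudo_r2(f2, y2), 1)
  # squared observed-fitted correlation variant
  expect_gt(pseudo_r2(f1, y1, method = "cor"), 0.99)
})
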