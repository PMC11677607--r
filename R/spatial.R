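#' k-nearest-neighbour spatial weights
#'
#' Links each site to its `k` nearest neighbours, by great-circle distance
#' for lon/lat coordinates (WGS84 spherical approximation) or Euclidean
#' distance for planar ones. Whether coordinates are geographic is
#' auto-detected from their value range and can be overridden. Distance
#' ties (including exactly duplicated coordinates, which trigger a warning)
#' are broken by site order. Rows are standardized to sum to 1 by default.
#'
#' @param coords two-column matrix or data frame of site coordinates
#'   (lon/lat or planar x/y), optionally with rownames as site ids.
#' @param k number of neighbours (default 4); requires `n >= k + 1`.
#' @param row_standardize divide each row by its sum (default TRUE).
#' @param longlat TRUE for great-circle, FALSE for Euclidean, NULL to
#'   auto-detect.
#' @return a list of class `"spatial_weights"`: `W` (n x n matrix),
#'   `ids`, `k`, `scheme`, `row_standardized`, `longlat`.
#' @export
knn_weights <- function(coords, k = 4L, row_standardize = TRUE,
                        longlat = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 2L) stop("coords must have two columns")
  n <- nrow(coords)
  if (n < k + 1L) stop("need at least k + 1 sites")
  if (is.null(longlat)) {
    longlat <- all(abs(coords[, 1]) <= 180) && all(abs(coords[, 2]) <= 90)
  }
  if (anyDuplicated(coords)) {
    warning("duplicate coordinates: neighbour ties broken by site order")
  }
  D <- if (longlat) geosphere::distm(coords) else as.matrix(stats::dist(coords))
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    d <- D[i, ]
    d[i] <- Inf
    nb <- order(d)[seq_len(k)]  # order() is stable: ties fall to site order
    W[i, nb] <- 1
  }
  if (row_standardize) W <- W / rowSums(W)
  ids <- rownames(coords)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  dimnames(W) <- list(ids, ids)
  structure(
    list(W = W, ids = ids, k = as.integer(k), scheme = "knn",
         row_standardized = row_standardize, longlat = longlat),
    class = "spatial_weights"
  )
}

as_weights_matrix <- function(w) {
  if (inherits(w, "spatial_weights")) w$W else as.matrix(w)
}

#' Export spatial weights as a sparse triplet table
#'
#' @param w a `"spatial_weights"` object.
#' @return data frame with columns `i`, `j`, `w` for the nonzero entries.
#' @export
weights_triplets <- function(w) {
  W <- as_weights_matrix(w)
  nz <- which(W != 0, arr.ind = TRUE)
  data.frame(i = nz[, 1], j = nz[, 2], w = W[nz])
}

#' Moran's I with randomization moments
#'
#' Global spatial autocorrelation of a site-level variable (typically
#' regression residuals): `I = (n / S0) * sum_ij W_ij z_i z_j / sum_i z_i^2`
#' with `z` the centred variable. Under random permutation of values over
#' sites the expectation is `-1/(n-1)`; the variance uses the standard
#' randomization moments and the p-value a two-sided normal approximation.
#'
#' @param x numeric vector with positive variance.
#' @param w a `"spatial_weights"` object or weights matrix with at least
#'   one nonzero entry.
#' @return list with `I`, `expected`, `sd`, `p_value`, `n`.
#' @export
morans_i <- function(x, w) {
  W <- as_weights_matrix(w)
  n <- length(x)
  if (nrow(W) != n) stop("weights and data differ in size")
  if (stats::var(x) == 0) stop("Moran's I undefined for a constant vector")
  S0 <- sum(W)
  if (S0 == 0) stop("weights matrix has no nonzero entries")
  z <- x - mean(x)
  I <- (n / S0) * as.numeric(t(z) %*% W %*% z) / sum(z^2)
  EI <- -1 / (n - 1)
  S1 <- 0.5 * sum((W + t(W))^2)
  S2 <- sum((rowSums(W) + colSums(W))^2)
  b2 <- n * sum(z^4) / sum(z^2)^2
  varI <- (n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * S0^2) -
           b2 * ((n^2 - n) * S1 - 2 * n * S2 + 6 * S0^2)) /
          ((n - 1) * (n - 2) * (n - 3) * S0^2) - EI^2
  sdI <- sqrt(varI)
  p <- 2 * stats::pnorm(-abs((I - EI) / sdI))
  list(I = I, expected = EI, sd = sdI, p_value = p, n = n)
}

# log|I - rho W| from the (possibly complex) eigenvalues of W; complex
# eigenvalues come in conjugate pairs so the sum is real
.log_det_factory <- function(W) {
  ev <- eigen(W, only.values = TRUE)$values
  re <- Re(ev)
  if (max(re) <= 0 || min(re) >= 0) {
    stop("degenerate weights: rho search interval is empty")
  }
  list(
    logdet = function(rho) Re(sum(log(1 - rho * ev))),
    interval = c(1 / min(re), 1 / max(re))
  )
}

#' Maximum-likelihood spatial autoregressive model
#'
#' Fits the spatial-lag model `y = rho * W y + X beta + eps` (default) or
#' the spatial-error model `y = X beta + u, u = lambda * W u + eps` by
#' maximum likelihood. The likelihood is concentrated over the
#' autoregressive coefficient, with `log|I - rho W|` evaluated from the
#' eigenvalues of `W`; the search is confined to `(1/lambda_min,
#' 1/lambda_max)` of those eigenvalues. Coefficient standard errors come
#' from the inverse observed information (numerical Hessian) over
#' `(rho, beta, log sigma^2)`, tested by asymptotic z. AIC counts all
#' estimated parameters including rho and the error variance. The residual
#' Moran's I of the fit is reported alongside.
#'
#' With an all-zero weights matrix the model degenerates to OLS exactly
#' (rho fixed at 0).
#'
#' @param y numeric response.
#' @param X model matrix or data frame of predictors (an intercept column
#'   is added unless `add_intercept = FALSE`).
#' @param w a `"spatial_weights"` object (row-standardized) or matrix.
#' @param variant `"lag"` (default) or `"error"`.
#' @param add_intercept prepend an intercept column (default TRUE).
#' @return a list of class `"spatial_fit"`: `rho`, `coefficients`,
#'   `table` (estimate, se, z, p, stars), `sigma2`, `logLik`, `aic`,
#'   `pseudo_r2` (Nagelkerke, against the intercept-only OLS null),
#'   `moran_residual`, `residuals`, `fitted`, `rho_interval`, `variant`, `n`.
#' @export
fit_sar_lag <- function(y, X, w, variant = c("lag", "error"),
                        add_intercept = TRUE) {
  variant <- match.arg(variant)
  W <- as_weights_matrix(w)
  y <- as.numeric(y)
  n <- length(y)
  if (nrow(W) != n) stop("weights and response differ in size")
  X <- if (is.null(X)) matrix(numeric(0), n, 0) else as.matrix(X)
  if (!is.numeric(X)) stop("X must be numeric; expand factors to dummies first")
  if (add_intercept) {
    X <- cbind(`(Intercept)` = 1, X)
  }
  p <- ncol(X)
  if (qr(X)$rank < p) stop("X is rank-deficient")

  if (all(W == 0)) {
    fit <- stats::lm.fit(X, y)
    e <- fit$residuals
    s2 <- sum(e^2) / n
    ll <- -n / 2 * (log(2 * pi * s2) + 1)
    rho <- 0
    beta <- fit$coefficients
    se <- sqrt(diag(s2 * solve(crossprod(X))) * n / (n - p))
    se_rho <- NA_real_
    interval <- c(NA_real_, NA_real_)
    fitted <- as.numeric(X %*% beta)
  } else {
    ld <- .log_det_factory(W)
    eps <- 1e-6 * diff(ld$interval)
    interval <- ld$interval + c(eps, -eps)
    Wy <- as.numeric(W %*% y)
    if (variant == "lag") {
      f0 <- stats::lm.fit(X, y)
      fd <- stats::lm.fit(X, Wy)
      e0 <- f0$residuals
      ed <- fd$residuals
      cll <- function(rho) {
        e <- e0 - rho * ed
        s2 <- sum(e^2) / n
        -n / 2 * (log(2 * pi * s2) + 1) + ld$logdet(rho)
      }
      opt <- stats::optimize(cll, interval, maximum = TRUE, tol = 1e-9)
      rho <- opt$maximum
      beta <- f0$coefficients - rho * fd$coefficients
      e <- e0 - rho * ed
      s2 <- sum(e^2) / n
      ll <- opt$objective
      fitted <- rho * Wy + as.numeric(X %*% beta)
      nll <- function(th) {
        r <- th[1]; b <- th[2:(p + 1)]; sig2 <- exp(th[p + 2])
        if (r <= interval[1] || r >= interval[2]) return(1e10)
        res <- y - r * Wy - as.numeric(X %*% b)
        -(-n / 2 * log(2 * pi * sig2) - sum(res^2) / (2 * sig2) + ld$logdet(r))
      }
    } else {
      WX <- W %*% X
      cll <- function(lam) {
        yt <- y - lam * Wy
        Xt <- X - lam * WX
        ft <- stats::lm.fit(Xt, yt)
        s2 <- sum(ft$residuals^2) / n
        -n / 2 * (log(2 * pi * s2) + 1) + ld$logdet(lam)
      }
      opt <- stats::optimize(cll, interval, maximum = TRUE, tol = 1e-9)
      rho <- opt$maximum
      yt <- y - rho * Wy
      Xt <- X - rho * WX
      ft <- stats::lm.fit(Xt, yt)
      beta <- ft$coefficients
      e <- ft$residuals
      s2 <- sum(e^2) / n
      ll <- opt$objective
      fitted <- as.numeric(X %*% beta)
      nll <- function(th) {
        r <- th[1]; b <- th[2:(p + 1)]; sig2 <- exp(th[p + 2])
        if (r <= interval[1] || r >= interval[2]) return(1e10)
        u <- y - as.numeric(X %*% b)
        res <- u - r * as.numeric(W %*% u)
        -(-n / 2 * log(2 * pi * sig2) - sum(res^2) / (2 * sig2) + ld$logdet(r))
      }
    }
    vc <- tryCatch({
      H <- stats::optimHess(c(rho, beta, log(s2)), nll)
      solve(H)
    }, error = function(e) NULL)
    if (!is.null(vc) && all(is.finite(diag(vc))) && all(diag(vc) > 0)) {
      se_rho <- sqrt(vc[1, 1])
      se <- sqrt(diag(vc)[2:(p + 1)])
    } else {
      # fall back on the conditional (given rho) covariance
      se_rho <- NA_real_
      se <- sqrt(diag(s2 * solve(crossprod(X))))
    }
  }

  z <- beta / se
  pvals <- 2 * stats::pnorm(-abs(z))
  tab <- data.frame(term = colnames(X), estimate = unname(beta),
                    se = unname(se), z = unname(z), p_value = unname(pvals),
                    stars = significance_stars(unname(pvals)),
                    stringsAsFactors = FALSE)
  if (is.finite(se_rho)) {
    zr <- rho / se_rho
    tab <- rbind(data.frame(term = "rho", estimate = rho, se = se_rho,
                            z = zr, p_value = 2 * stats::pnorm(-abs(zr)),
                            stars = significance_stars(2 * stats::pnorm(-abs(zr))),
                            stringsAsFactors = FALSE), tab)
  }
  k <- p + 2  # betas + rho + sigma^2
  ll0 <- as.numeric(stats::logLik(stats::lm(y ~ 1)))
  moran <- if (stats::var(e) > 0 && any(W != 0)) morans_i(e, W) else NULL
  structure(
    list(rho = rho, coefficients = stats::setNames(beta, colnames(X)),
         table = tab, sigma2 = s2, logLik = ll, aic = 2 * k - 2 * ll,
         k = k, logLik_null = ll0,
         pseudo_r2 = .nagelkerke(ll0, ll, n, warn = FALSE),
         moran_residual = moran, residuals = as.numeric(e),
         fitted = as.numeric(fitted), rho_interval = interval,
         variant = variant, n = n),
    class = "spatial_fit"
  )
}

.nagelkerke <- function(ll0, ll1, n, warn = TRUE) {
  r2 <- 1 - exp((2 / n) * (ll0 - ll1))
  if (r2 < 0) {
    if (warn) warning("fitted log-likelihood below null; pseudo-R2 clamped to 0")
    r2 <- 0
  }
  min(r2, 1)
}

#' Fraction of variation explained by a spatial fit
#'
#' Nagelkerke pseudo-R-squared `1 - exp((2/n) (logL0 - logL1))` against the
#' intercept-only OLS null (the convention used to report "% of variation
#' explained"), clamped to \[0, 1\]. The squared correlation between
#' observed and fitted values is available as an alternative.
#'
#' @param fit a `"spatial_fit"` object.
#' @param y the response the model was fitted to.
#' @param method `"nagelkerke"` (default) or `"cor"`.
#' @return numeric in \[0, 1\].
#' @export
pseudo_r2 <- function(fit, y, method = c("nagelkerke", "cor")) {
  method <- match.arg(method)
  stopifnot(inherits(fit, "spatial_fit"))
  if (method == "cor") {
    return(stats::cor(as.numeric(y), fit$fitted)^2)
  }
  ll0 <- as.numeric(stats::logLik(stats::lm(as.numeric(y) ~ 1)))
  .nagelkerke(ll0, fit$logLik, fit$n)
}

#' @export
print.spatial_fit <- function(x, ...) {
  cat(sprintf("Spatial %s model (ML): rho = %.4f, logLik = %.2f, AIC = %.2f, pseudo-R2 = %.4f\n",
              x$variant, x$rho, x$logLik, x$aic, x$pseudo_r2))
  if (!is.null(x$moran_residual)) {
    cat(sprintf("Residual Moran's I = %.4f (p = %.3f)\n",
                x$moran_residual$I, x$moran_residual$p_value))
  }
  print(x$table, digits = 4)
  invisible(x)
}
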