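#' Welch two-sample contrast between site groups
#'
#' Unequal-variance t-test (Welch-Satterthwaite degrees of freedom) between
#' two groups of site-level values, e.g. species richness on two bedrock
#' types. A pooled-variance test is available by flag. The degenerate case
#' of two constant, equal-valued samples returns t = 0, p = 1 rather than
#' an error.
#'
#' @param x,y numeric samples, each of length >= 2.
#' @param group_a,group_b labels for the two groups.
#' @param pooled use the pooled-variance (classic) t-test instead of Welch.
#' @return a list of class `"group_contrast"`: `group_a`, `group_b`,
#'   `t_stat`, `df`, `p_value`, `stars`.
#' @export
welch_t <- function(x, y, group_a = "A", group_b = "B", pooled = FALSE) {
  if (length(x) < 2L || length(y) < 2L) stop("each group needs n >= 2")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) {
      res <- list(t_stat = 0, df = length(x) + length(y) - 2, p_value = 1)
    } else {
      stop("both groups constant with different means: t undefined")
    }
  } else {
    ht <- stats::t.test(x, y, var.equal = pooled)
    res <- list(t_stat = unname(ht$statistic), df = unname(ht$parameter),
                p_value = ht$p.value)
  }
  structure(
    list(group_a = group_a, group_b = group_b, t_stat = res$t_stat,
         df = res$df, p_value = res$p_value,
         stars = significance_stars(res$p_value)),
    class = "group_contrast"
  )
}

#' All pairwise group contrasts of a site-level metric
#'
#' @param value numeric vector of site values.
#' @param group factor of group membership (same length).
#' @param metric name recorded in the output.
#' @param pooled see [welch_t()].
#' @return data frame with one row per unordered group pair having n >= 2
#'   in both groups.
#' @export
pairwise_contrasts <- function(value, group, metric = "value", pooled = FALSE) {
  group <- as.factor(group)
  keep <- !is.na(value)
  value <- value[keep]; group <- droplevels(group[keep])
  lev <- levels(group)
  rows <- list()
  for (a in seq_along(lev)) {
    for (b in seq_along(lev)) {
      if (b <= a) next
      xa <- value[group == lev[a]]
      xb <- value[group == lev[b]]
      if (length(xa) < 2L || length(xb) < 2L) next
      ct <- welch_t(xa, xb, lev[a], lev[b], pooled = pooled)
      rows[[length(rows) + 1L]] <- data.frame(
        metric = metric, group_a = lev[a], group_b = lev[b],
        mean_a = mean(xa), mean_b = mean(xb), t_stat = ct$t_stat,
        df = ct$df, p_value = ct$p_value, stars = ct$stars,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Simple least-squares regression on one covariate
#'
#' Ordinary least squares of a response on a single predictor, reporting
#' slope, intercept, R-squared and the two-sided slope p-value — the
#' elevation-gradient regressions of the analysis.
#'
#' @param y numeric response.
#' @param x numeric covariate with positive variance.
#' @param response,predictor names recorded in the output.
#' @return a list of class `"model_fit"` with `coefficients`, `r2`,
#'   `slope_p`, `logLik`, `aic`.
#' @export
ols_r2 <- function(y, x, response = "y", predictor = "x") {
  if (length(y) != length(x)) stop("y and x differ in length")
  if (length(y) < 3L) stop("need n >= 3")
  if (stats::var(x) == 0) stop("constant covariate: slope undefined")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  structure(
    list(response = response, predictors = predictor,
         coefficients = c(intercept = unname(stats::coef(fit)[1]),
                          slope = unname(stats::coef(fit)[2])),
         r2 = sm$r.squared, slope_p = sm$coefficients[2, 4],
         logLik = as.numeric(stats::logLik(fit)), aic = stats::AIC(fit),
         n = length(y)),
    class = "model_fit"
  )
}

#' Stepwise Gaussian GLM selected by AIC
#'
#' Fits a Gaussian (identity-link) GLM of `y` on the candidate predictors
#' and selects terms by stepwise search (both directions by default),
#' at each step taking the single addition or removal that most lowers the
#' AIC, stopping at a local minimum. Factor candidates (e.g. the bedrock
#' type) enter and leave as a block of dummies; set the factor's first
#' level to choose the reference. Perfectly collinear candidates (aliased
#' in the full fit) are excluded with a warning before the search.
#'
#' @param y numeric response.
#' @param data data frame of candidate predictors (numeric or factor).
#' @param direction `"both"`, `"forward"` or `"backward"`.
#' @param response name recorded in the output.
#' @return a list of class `"model_fit"` with the selected `terms`, a
#'   coefficient `table` (estimate, se, p, stars), `aic`, `logLik`, `r2`
#'   (proportion of deviance explained) and the fitted `model`.
#' @export
stepwise_glm_aic <- function(y, data, direction = c("both", "forward", "backward"),
                             response = "y") {
  direction <- match.arg(direction)
  data <- as.data.frame(data)
  if (nrow(data) != length(y)) stop("response and predictors differ in length")
  if (nrow(data) <= ncol(data)) stop("need more observations than candidates")
  dat <- cbind(.y = y, data)
  full <- stats::glm(.y ~ ., data = dat, family = stats::gaussian())
  aliased <- is.na(stats::coef(full))
  if (any(aliased)) {
    bad_coef <- names(stats::coef(full))[aliased]
    # map aliased dummy coefficients back to candidate columns
    bad <- names(data)[vapply(names(data), function(v)
      any(startsWith(bad_coef, v)), logical(1))]
    warning("perfectly collinear candidate(s) excluded: ",
            paste(bad, collapse = ", "))
    data <- data[setdiff(names(data), bad)]
    dat <- cbind(.y = y, data)
    full <- stats::glm(.y ~ ., data = dat, family = stats::gaussian())
  }
  null <- stats::glm(.y ~ 1, data = dat, family = stats::gaussian())
  scope <- list(lower = stats::formula(null), upper = stats::formula(full))
  start <- if (direction == "forward") null else full
  sel <- stats::step(start, scope = scope, direction = direction, trace = 0)
  sm <- summary(sel)
  tab <- data.frame(term = rownames(sm$coefficients),
                    estimate = sm$coefficients[, 1],
                    se = sm$coefficients[, 2],
                    p_value = sm$coefficients[, 4],
                    stars = significance_stars(sm$coefficients[, 4]),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(
    list(response = response,
         terms = attr(stats::terms(sel), "term.labels"),
         table = tab, coefficients = stats::coef(sel),
         aic = stats::AIC(sel), logLik = as.numeric(stats::logLik(sel)),
         r2 = 1 - sel$deviance / sel$null.deviance,
         n = length(y), model = sel),
    class = "model_fit"
  )
}
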