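#' Hellinger transformation of a community matrix
#'
#' Each entry becomes the square root of its row-relative abundance:
#' `sqrt(x[s, j] / rowsum_s)`. Transformed rows have unit Euclidean norm,
#' which makes community composition amenable to Euclidean-based methods.
#' Species richness is always taken from the raw matrix (row sums of
#' presence/absence), never from the transformed one.
#'
#' @param M numeric matrix or data frame, sites x species, values >= 0.
#' @return numeric matrix of the same shape.
#' @examples
#' hellinger_transform(rbind(a = c(1, 0, 3)))  # 0.5, 0, 0.866
#' @export
hellinger_transform <- function(M) {
  M <- as.matrix(M)
  if (!is.numeric(M)) stop("community matrix must be numeric")
  if (any(M < 0)) stop("community matrix has negative entries")
  rs <- rowSums(M)
  if (any(rs == 0)) {
    empty <- rownames(M)[rs == 0]
    if (is.null(empty)) empty <- which(rs == 0)
    stop("empty site(s) with zero row sum: ", paste(empty, collapse = ", "))
  }
  sqrt(sweep(M, 1L, rs, "/"))
}

#' Range (min-max) normalization to [0, 1]
#'
#' `(x - min) / (max - min)`: the minimum maps to 0, the maximum to 1,
#' affinely in between. Idempotent on its own output.
#'
#' @param x numeric vector with `max(x) > min(x)`.
#' @return numeric vector in \[0, 1\].
#' @export
range_normalize <- function(x) {
  if (!is.numeric(x)) stop("x must be numeric")
  if (anyNA(x)) stop("x contains missing values")
  rng <- range(x)
  if (rng[2] <= rng[1]) {
    stop("range normalization undefined for a constant vector")
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Greedy collinearity screen on a block of predictors
#'
#' Scans columns in their declared order; a column whose correlation with
#' any already-retained column exceeds the threshold is dropped, and every
#' decision is logged. By default the screen uses |r| so strong negative
#' collinearity is caught too; set `absolute = FALSE` for a signed
#' `r > threshold` rule. Zero-variance columns are dropped with a warning
#' before any correlation is computed.
#'
#' @param X numeric matrix or data frame of candidate columns (>= 2 columns,
#'   >= 3 rows).
#' @param threshold correlation cutoff (default 0.95).
#' @param absolute use |r| (default) rather than signed r.
#' @return list with `retained` (column names), `data` (retained columns),
#'   and `log` (a data frame recording each dropped column, the retained
#'   column that triggered it, and the offending correlation).
#' @export
drop_collinear <- function(X, threshold = 0.95, absolute = TRUE) {
  X <- as.data.frame(X)
  if (ncol(X) < 2L) stop("need at least 2 columns")
  if (nrow(X) < 3L) stop("need at least 3 rows")
  if (!all(vapply(X, is.numeric, logical(1)))) stop("all columns must be numeric")
  nm <- names(X)
  log <- data.frame(dropped = character(0), against = character(0),
                    r = numeric(0), reason = character(0),
                    stringsAsFactors = FALSE)
  variances <- vapply(X, stats::var, numeric(1))
  if (any(variances == 0)) {
    zv <- nm[variances == 0]
    warning("zero-variance column(s) dropped: ", paste(zv, collapse = ", "))
    log <- rbind(log, data.frame(dropped = zv, against = NA_character_,
                                 r = NA_real_, reason = "zero variance"))
    nm <- setdiff(nm, zv)
  }
  keep <- character(0)
  for (j in nm) {
    offender <- NULL
    for (i in keep) {
      r <- stats::cor(X[[i]], X[[j]])
      rr <- if (absolute) abs(r) else r
      if (rr > threshold) {
        offender <- list(i = i, r = r)
        break
      }
    }
    if (is.null(offender)) {
      keep <- c(keep, j)
    } else {
      log <- rbind(log, data.frame(dropped = j, against = offender$i,
                                   r = offender$r, reason = "collinear"))
    }
  }
  list(retained = keep, data = X[keep], log = log)
}
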