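#' Null distribution of a diversity metric under taxa-label randomization
#'
#' Draws `n_null` random assemblages of the same richness as the observed
#' community from the species pool (the taxa-label shuffle null: richness is
#' preserved, identities randomized) and recomputes the metric on each.
#'
#' @param metric one of `"PD"`, `"MPD"`, `"MNTD"`.
#' @param tree a `"phylo"` object or [phylo_context()].
#' @param taxa observed community: character vector of tip labels.
#' @param pool species pool to draw from; defaults to all tree tips.
#' @param n_null number of randomizations (default 999).
#' @param null_model randomization scheme; only `"taxa_labels"` is provided.
#' @param seed integer seed; fixing it fixes the whole null vector.
#' @param include_root PD convention flag, see [faith_pd()].
#' @return numeric vector of `n_null` null metric values.
#' @export
null_distribution <- function(metric = c("PD", "MPD", "MNTD"), tree, taxa,
                              pool = NULL, n_null = 999L,
                              null_model = "taxa_labels", seed = NULL,
                              include_root = TRUE) {
  metric <- match.arg(metric)
  if (!identical(null_model, "taxa_labels")) {
    stop("unknown null model: ", null_model)
  }
  ctx <- as_phylo_context(tree)
  if (is.null(pool)) pool <- ctx$tip_labels
  pool_idx <- match_taxa(pool, ctx$tip_labels)
  obs_idx <- match_taxa(taxa, ctx$tip_labels)
  if (!all(obs_idx %in% pool_idx)) stop("community taxa must lie in the pool")
  if (n_null < 1L) stop("n_null must be >= 1")
  r <- length(obs_idx)
  fun <- switch(metric,
    PD   = function(idx) .faith_pd_idx(ctx, idx, include_root),
    MPD  = function(idx) .mpd_idx(ctx$D, idx),
    MNTD = function(idx) .mntd_idx(ctx$D, idx)
  )
  with_seed(seed, {
    vapply(seq_len(n_null),
           function(i) fun(sample(pool_idx, r)),
           numeric(1))
  })
}

.new_ses_result <- function(metric_name, observed, null, sign, n_null, seed) {
  null_mean <- mean(null)
  null_sd <- stats::sd(null)
  undefined <- !is.finite(null_sd) || null_sd < 1e-12
  ses <- if (undefined) NA_real_ else sign * (observed - null_mean) / null_sd
  structure(
    list(metric_name = metric_name, observed = observed,
         null_mean = null_mean, null_sd = null_sd, ses = ses,
         rank_p = mean(null <= observed), n_null = length(null),
         seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
         undefined = undefined),
    class = "ses_result"
  )
}

#' @export
print.ses_result <- function(x, ...) {
  cat(sprintf("%s: observed = %.4f, null mean = %.4f (sd %.4f), SES = %s, rank p = %.3f [n_null = %d]\n",
              x$metric_name, x$observed, x$null_mean, x$null_sd,
              if (x$undefined) "undefined" else sprintf("%.3f", x$ses),
              x$rank_p, x$n_null))
  invisible(x)
}

# shared engine: one set of null assemblages feeds all requested metrics,
# so PDI/NRI/NTI for a site are computed on identical randomizations
.ses_engine <- function(ctx, taxa, pool, n_null, seed, include_root,
                        metrics = c("PDI", "NRI", "NTI")) {
  pool_idx <- match_taxa(pool, ctx$tip_labels)
  obs_idx <- match_taxa(taxa, ctx$tip_labels)
  if (length(obs_idx) < 2L) stop("SES indices need site richness >= 2")
  r <- length(obs_idx)
  draws <- with_seed(seed, {
    lapply(seq_len(n_null), function(i) sample(pool_idx, r))
  })
  out <- list()
  if ("PDI" %in% metrics) {
    obs <- .faith_pd_idx(ctx, obs_idx, include_root)
    null <- vapply(draws, function(s) .faith_pd_idx(ctx, s, include_root),
                   numeric(1))
    out$PDI <- .new_ses_result("PDI", obs, null, +1, n_null, seed)
  }
  if ("NRI" %in% metrics) {
    obs <- .mpd_idx(ctx$D, obs_idx)
    null <- vapply(draws, function(s) .mpd_idx(ctx$D, s), numeric(1))
    out$NRI <- .new_ses_result("NRI", obs, null, -1, n_null, seed)
  }
  if ("NTI" %in% metrics) {
    obs <- .mntd_idx(ctx$D, obs_idx)
    null <- vapply(draws, function(s) .mntd_idx(ctx$D, s), numeric(1))
    out$NTI <- .new_ses_result("NTI", obs, null, -1, n_null, seed)
  }
  out
}

#' Phylogenetic Diversity Index (SES of Faith's PD)
#'
#' `PDI = (PD_obs - mean(PD_null)) / sd(PD_null)`: positive values mean the
#' community carries more phylogenetic diversity than richness-matched
#' random draws from the pool. When the null has zero spread (e.g. the
#' community equals the whole pool) the SES is flagged undefined rather
#' than reported as infinite.
#'
#' @inheritParams null_distribution
#' @return an object of class `"ses_result"`.
#' @export
pdi <- function(tree, taxa, pool = NULL, n_null = 999L, seed = NULL,
                include_root = TRUE) {
  ctx <- as_phylo_context(tree)
  if (is.null(pool)) pool <- ctx$tip_labels
  .ses_engine(ctx, taxa, pool, n_null, seed, include_root, "PDI")$PDI
}

#' Net Relatedness Index (negated SES of MPD)
#'
#' `NRI = -(MPD_obs - mean(MPD_null)) / sd(MPD_null)`. The leading minus
#' makes positive values indicate phylogenetic clustering (co-occurring
#' species more related than expected) and negative values overdispersion.
#'
#' @inheritParams pdi
#' @return an object of class `"ses_result"`.
#' @export
nri <- function(tree, taxa, pool = NULL, n_null = 999L, seed = NULL) {
  ctx <- as_phylo_context(tree)
  if (is.null(pool)) pool <- ctx$tip_labels
  .ses_engine(ctx, taxa, pool, n_null, seed, TRUE, "NRI")$NRI
}

#' Nearest Taxon Index (negated SES of MNTD)
#'
#' Same sign convention as [nri()], applied to the mean nearest-taxon
#' distance: positive = clustering at the tree's shallow (terminal) depths.
#'
#' @inheritParams pdi
#' @return an object of class `"ses_result"`.
#' @export
nti <- function(tree, taxa, pool = NULL, n_null = 999L, seed = NULL) {
  ctx <- as_phylo_context(tree)
  if (is.null(pool)) pool <- ctx$tip_labels
  .ses_engine(ctx, taxa, pool, n_null, seed, TRUE, "NTI")$NTI
}

#' All three SES indices for one community, on shared nulls
#'
#' Computes PDI, NRI and NTI against the same `n_null` random assemblages,
#' which is both faster and internally consistent for per-site reporting.
#'
#' @inheritParams pdi
#' @return named list of `"ses_result"` objects (`PDI`, `NRI`, `NTI`).
#' @export
ses_indices <- function(tree, taxa, pool = NULL, n_null = 999L, seed = NULL,
                        include_root = TRUE) {
  ctx <- as_phylo_context(tree)
  if (is.null(pool)) pool <- ctx$tip_labels
  .ses_engine(ctx, taxa, pool, n_null, seed, include_root)
}

#' Classify community phylogenetic structure from an SES index
#'
#' For the clustering-positive indices (NRI, NTI) a positive value is
#' `"clustered"` and a negative one `"overdispersed"`; for PDI the sign is
#' inverted (low diversity relative to null = clustering). An undefined SES
#' (zero null spread) or an SES of exactly zero is `"indeterminate"`.
#'
#' @param ses an `"ses_result"` object.
#' @return one of `"clustered"`, `"overdispersed"`, `"indeterminate"`.
#' @export
classify_structure <- function(ses) {
  stopifnot(inherits(ses, "ses_result"))
  if (ses$undefined || is.na(ses$ses) || ses$ses == 0) return("indeterminate")
  clustering_positive <- ses$metric_name %in% c("NRI", "NTI")
  value <- if (clustering_positive) ses$ses else -ses$ses
  if (value > 0) "clustered" else "overdispersed"
}

#' Flatten SES results into a one-row data frame
#'
#' @param ses an `"ses_result"` object.
#' @param site_id optional site identifier prepended as a column.
#' @return a one-row data frame matching the SES CSV layout.
#' @export
ses_as_row <- function(ses, site_id = NA) {
  data.frame(site_id = site_id, metric = ses$metric_name,
             observed = ses$observed, null_mean = ses$null_mean,
             null_sd = ses$null_sd, ses = ses$ses, rank_p = ses$rank_p,
             n_null = ses$n_null, seed = ses$seed,
             stringsAsFactors = FALSE)
}
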