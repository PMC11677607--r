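#' Read a site x species community table
#'
#' CSV with first column `site_id` and one column per species; numeric
#' values (abundance or presence/absence). Lines starting with `#`
#' (metadata headers written by this package) are skipped.
#'
#' @param path CSV file path.
#' @return numeric matrix with site rownames and species colnames.
#' @export
read_community_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, comment.char = "#")
  if (names(df)[1] != "site_id") stop("first column must be 'site_id'")
  M <- as.matrix(df[, -1, drop = FALSE])
  rownames(M) <- df$site_id
  storage.mode(M) <- "numeric"
  if (any(M < 0)) stop("negative community entries")
  M
}

#' Read a site-level environment table
#'
#' @param path CSV with `site_id`, topography, `bedrock` and climate columns.
#' @param bedrock_levels factor levels for the bedrock column (first level
#'   is the regression reference).
#' @return data frame with `bedrock` as a factor.
#' @export
read_environment_csv <- function(path,
                                 bedrock_levels = c("granite", "rhyolite",
                                                    "pyroclastic rock",
                                                    "pyroclastic lava",
                                                    "quartz sandstone")) {
  df <- utils::read.csv(path, check.names = FALSE, comment.char = "#",
                        stringsAsFactors = FALSE)
  if (!"site_id" %in% names(df)) stop("environment table needs 'site_id'")
  if ("bedrock" %in% names(df)) {
    bad <- setdiff(unique(df$bedrock), bedrock_levels)
    if (length(bad)) stop("unknown bedrock level(s): ", paste(bad, collapse = ", "))
    df$bedrock <- factor(df$bedrock, levels = bedrock_levels)
  }
  df
}

#' Read site coordinates
#'
#' @param path CSV with columns `site_id` and either `lon`,`lat` or `x`,`y`.
#' @return data frame `site_id`, `lon`, `lat` (planar coords keep x->lon,
#'   y->lat naming; [knn_weights()] auto-detects which metric to use).
#' @export
read_coordinates_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, comment.char = "#",
                        stringsAsFactors = FALSE)
  if (!"site_id" %in% names(df)) stop("coordinates table needs 'site_id'")
  if (all(c("x", "y") %in% names(df))) {
    df <- data.frame(site_id = df$site_id, lon = df$x, lat = df$y)
  }
  if (!all(c("lon", "lat") %in% names(df))) {
    stop("coordinates table needs lon/lat or x/y columns")
  }
  df[c("site_id", "lon", "lat")]
}

#' Write a result table with a reproducibility metadata header
#'
#' Prepends `# key: value` comment lines (seed, n_null, weights scheme,
#' package version, ...) so every output records how to regenerate it.
#'
#' @param df data frame to write.
#' @param path output CSV path.
#' @param meta named list of metadata values.
#' @return `path`, invisibly.
#' @export
write_result_csv <- function(df, path, meta = list()) {
  meta <- c(list(package = paste0("phylospat ",
                                  as.character(utils::packageVersion("phylospat")))),
            meta)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta)) {
    writeLines(sprintf("# %s: %s", k, paste(meta[[k]], collapse = " ")), con)
  }
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Validate and cross-reference pipeline inputs
#'
#' Checks that community species are tips of the tree (or drops the
#' missing ones when `drop_missing = TRUE`, logging them), that site ids
#' align across community, environment and coordinate tables, and that
#' every analyzed site has richness >= 2. Inputs may be given as objects
#' or file paths.
#'
#' @param tree `"phylo"` object or newick file path.
#' @param community matrix or community CSV path.
#' @param env data frame or environment CSV path.
#' @param coords data frame or coordinates CSV path.
#' @param drop_missing drop community species absent from the tree instead
#'   of erroring.
#' @return list of class `"dataset_bundle"`: `tree`, `community`, `env`,
#'   `coords`, `dropped_species`.
#' @export
validate_inputs <- function(tree, community, env, coords,
                            drop_missing = FALSE) {
  if (is.character(tree)) tree <- parse_newick(paste(readLines(tree), collapse = ""))
  validate_phylogeny(tree)
  if (is.character(community)) community <- read_community_csv(community)
  if (is.character(env)) env <- read_environment_csv(env)
  if (is.character(coords)) coords <- read_coordinates_csv(coords)

  missing_sp <- setdiff(colnames(community), tree$tip.label)
  if (length(missing_sp) && !drop_missing) {
    stop("species missing from tree: ", paste(missing_sp, collapse = ", "),
         " (use drop_missing = TRUE to drop them)")
  }
  if (length(missing_sp)) {
    message("dropping ", length(missing_sp), " species absent from the tree: ",
            paste(missing_sp, collapse = ", "))
    community <- community[, setdiff(colnames(community), missing_sp),
                           drop = FALSE]
  }
  sites <- rownames(community)
  if (!setequal(sites, env$site_id) || !setequal(sites, coords$site_id)) {
    stop("site ids do not align across community/environment/coordinates")
  }
  env <- env[match(sites, env$site_id), , drop = FALSE]
  coords <- coords[match(sites, coords$site_id), , drop = FALSE]
  richness <- rowSums(community > 0)
  if (any(richness < 2L)) {
    stop("site(s) with richness < 2: ",
         paste(sites[richness < 2L], collapse = ", "))
  }
  structure(list(tree = tree, community = community, env = env,
                 coords = coords, dropped_species = missing_sp),
            class = "dataset_bundle")
}

#' Run the full diversity / regression / spatial pipeline
#'
#' End-to-end analysis of a validated dataset: per-site species richness
#' and SES indices (PDI, NRI, NTI on shared taxa-label nulls), pairwise
#' bedrock contrasts for all four metrics, the richness-elevation OLS,
#' range normalization and the collinearity screen of the climate block,
#' stepwise-AIC Gaussian GLMs, and maximum-likelihood spatial-lag models
#' (with residual Moran's I and Nagelkerke pseudo-R-squared) for each
#' response on the predictors its GLM selected. Deterministic given
#' `seed`; per-site null streams are derived from the seed and the site
#' index.
#'
#' @param bundle a `"dataset_bundle"` from [validate_inputs()].
#' @param n_null null randomizations per site (default 999).
#' @param seed master seed (default 1).
#' @param collinearity_threshold screen cutoff (default 0.95).
#' @param k neighbours for the spatial weights (default 4).
#' @param sar_variant `"lag"` (default) or `"error"`.
#' @param pseudo_r2_method `"nagelkerke"` (default) or `"cor"`.
#' @param climate_cols names of climate columns in `bundle$env`; defaults
#'   to every numeric column except site_id/elevation/slope/aspect.
#' @param out_dir if non-NULL, write every result table there as CSV with
#'   metadata headers.
#' @return list of class `"pipeline_result"`: `sites` (per-site metrics),
#'   `contrasts`, `elevation_ols`, `collinearity`, `glm_fits`, `sar_fits`,
#'   `model_table`, `weights`, `config`.
#' @export
run_pipeline <- function(bundle, n_null = 999L, seed = 1L,
                         collinearity_threshold = 0.95, k = 4L,
                         sar_variant = "lag",
                         pseudo_r2_method = "nagelkerke",
                         climate_cols = NULL, out_dir = NULL) {
  stopifnot(inherits(bundle, "dataset_bundle"))
  if (n_null < 99L) stop("n_null must be >= 99")
  ctx <- phylo_context(bundle$tree)
  M <- bundle$community
  sites <- rownames(M)
  pool <- colnames(M)[colSums(M > 0) > 0]  # pool = union over analyzed sites
  richness <- rowSums(M > 0)

  # --- per-site SES indices on shared nulls ---------------------------------
  ses_rows <- vector("list", length(sites))
  site_tab <- data.frame(site_id = sites, SR = richness,
                         PDI = NA_real_, NRI = NA_real_, NTI = NA_real_,
                         stringsAsFactors = FALSE)
  for (s in seq_along(sites)) {
    taxa <- colnames(M)[M[s, ] > 0]
    res <- ses_indices(ctx, taxa, pool = pool, n_null = n_null,
                       seed = derive_seed(seed, s))
    site_tab$PDI[s] <- res$PDI$ses
    site_tab$NRI[s] <- res$NRI$ses
    site_tab$NTI[s] <- res$NTI$ses
    ses_rows[[s]] <- do.call(rbind, lapply(res, ses_as_row, site_id = sites[s]))
  }
  ses_table <- do.call(rbind, ses_rows)
  rownames(ses_table) <- NULL

  env <- bundle$env
  # --- bedrock group contrasts ----------------------------------------------
  contrasts <- do.call(rbind, lapply(c("SR", "PDI", "NRI", "NTI"), function(m)
    pairwise_contrasts(site_tab[[m]], env$bedrock, metric = m)))

  # --- elevation OLS ---------------------------------------------------------
  elev_ols <- ols_r2(site_tab$SR, env$elevation,
                     response = "SR", predictor = "elevation")

  # --- normalization + collinearity screen ----------------------------------
  if (is.null(climate_cols)) {
    num <- names(env)[vapply(env, is.numeric, logical(1))]
    climate_cols <- setdiff(num, c("elevation", "slope", "aspect"))
  }
  screen <- drop_collinear(env[climate_cols],
                           threshold = collinearity_threshold)
  predictors <- data.frame(
    elevation = range_normalize(env$elevation),
    slope = range_normalize(env$slope),
    aspect = range_normalize(env$aspect),
    lapply(screen$data, range_normalize),
    check.names = FALSE)
  predictors$bedrock <- droplevels(env$bedrock)

  # --- stepwise GLM + SAR per response --------------------------------------
  w <- knn_weights(as.matrix(bundle$coords[, c("lon", "lat")]), k = k)
  glm_fits <- list(); sar_fits <- list(); model_rows <- list()
  for (resp in c("SR", "NRI", "NTI", "PDI")) {
    y <- site_tab[[resp]]
    ok <- is.finite(y)  # undefined SES propagate as missing
    preds_ok <- droplevels(predictors[ok, , drop = FALSE])
    fit <- stepwise_glm_aic(y[ok], preds_ok, response = resp)
    glm_fits[[resp]] <- fit
    Xsel <- stats::model.matrix(
      stats::reformulate(if (length(fit$terms)) fit$terms else "1"),
      data = preds_ok)[, -1, drop = FALSE]
    wsub <- if (all(ok)) w else
      knn_weights(as.matrix(bundle$coords[ok, c("lon", "lat")]), k = k)
    sfit <- fit_sar_lag(y[ok], Xsel, wsub, variant = sar_variant)
    sfit$pseudo_r2 <- pseudo_r2(sfit, y[ok], method = pseudo_r2_method)
    sar_fits[[resp]] <- sfit
    glm_moran <- morans_i(stats::residuals(fit$model), wsub)
    model_rows[[resp]] <- data.frame(
      response = resp, sfit$table,
      aic = sfit$aic, pseudo_r2 = sfit$pseudo_r2,
      moran_glm_resid = glm_moran$I, moran_glm_p = glm_moran$p_value,
      moran_sar_resid = sfit$moran_residual$I,
      moran_sar_p = sfit$moran_residual$p_value,
      stringsAsFactors = FALSE)
  }
  model_table <- do.call(rbind, model_rows)
  rownames(model_table) <- NULL

  config <- list(seed = seed, n_null = n_null,
                 collinearity_threshold = collinearity_threshold,
                 weights_scheme = sprintf("knn k=%d row-standardized", k),
                 sar_variant = sar_variant,
                 pseudo_r2_method = pseudo_r2_method,
                 null_model = "taxa_labels")
  out <- structure(
    list(sites = site_tab, ses_table = ses_table, contrasts = contrasts,
         elevation_ols = elev_ols, collinearity = screen,
         glm_fits = glm_fits, sar_fits = sar_fits,
         model_table = model_table, weights = w, config = config),
    class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_results(out, out_dir)
  out
}

#' Write every pipeline result table to a directory
#'
#' @param result a `"pipeline_result"`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_results <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  meta <- result$config
  write_result_csv(result$sites, file.path(out_dir, "site_metrics.csv"), meta)
  write_result_csv(result$ses_table, file.path(out_dir, "ses_results.csv"), meta)
  write_result_csv(result$contrasts, file.path(out_dir, "bedrock_contrasts.csv"), meta)
  write_result_csv(result$model_table, file.path(out_dir, "sar_models.csv"), meta)
  write_result_csv(result$collinearity$log,
                   file.path(out_dir, "collinearity_log.csv"), meta)
  write_result_csv(weights_triplets(result$weights),
                   file.path(out_dir, "spatial_weights.csv"), meta)
  elev <- result$elevation_ols
  write_result_csv(data.frame(response = elev$response,
                              predictor = elev$predictors,
                              slope = elev$coefficients["slope"],
                              intercept = elev$coefficients["intercept"],
                              r2 = elev$r2, p_value = elev$slope_p),
                   file.path(out_dir, "elevation_ols.csv"), meta)
  invisible(out_dir)
}
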