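#!/usr/bin/env Rscript
# Stage 3: non-spatial statistics. Pairwise Welch contrasts of each metric
# between bedrock types, the richness-elevation regression, range
# normalization and the |r| > 0.95 collinearity screen of the climate
# block, and stepwise-AIC Gaussian GLMs for SR / NRI / NTI / PDI.

library(phylospat)

data_dir <- "results/data"
out <- "results"
env <- read_environment_csv(file.path(data_dir, "environment.csv"))
site_tab <- read.csv(file.path(out, "site_metrics.csv"), comment.char = "#")
stopifnot(identical(site_tab$site_id, env$site_id))

## bedrock contrasts --------------------------------------------------------
contrasts <- do.call(rbind, lapply(c("SR", "PDI", "NRI", "NTI"), function(m)
  pairwise_contrasts(site_tab[[m]], env$bedrock, metric = m)))
write_result_csv(contrasts, file.path(out, "bedrock_contrasts.csv"))
sig <- contrasts[contrasts$p_value < 0.05, ]
message("significant bedrock contrasts (p < 0.05):")
for (i in seq_len(nrow(sig))) {
  message(sprintf("  %-4s %s vs %s: t = %.2f, p = %.4f %s", sig$metric[i],
                  sig$group_a[i], sig$group_b[i], sig$t_stat[i],
                  sig$p_value[i], sig$stars[i]))
}

## elevation gradient -------------------------------------------------------
elev <- ols_r2(site_tab$SR, env$elevation, "SR", "elevation")
message(sprintf("SR ~ elevation: R2 = %.2f, slope p = %.2g",
                elev$r2, elev$slope_p))
write_result_csv(data.frame(response = "SR", predictor = "elevation",
                            slope = elev$coefficients["slope"],
                            intercept = elev$coefficients["intercept"],
                            r2 = elev$r2, p_value = elev$slope_p),
                 file.path(out, "elevation_ols.csv"))

## collinearity screen + normalized predictors ------------------------------
climate_cols <- setdiff(names(env)[vapply(env, is.numeric, logical(1))],
                        c("elevation", "slope", "aspect"))
screen <- drop_collinear(env[climate_cols], threshold = 0.95)
message("climate screen dropped: ",
        paste(screen$log$dropped, collapse = ", "))
write_result_csv(screen$log, file.path(out, "collinearity_log.csv"))

predictors <- data.frame(elevation = range_normalize(env$elevation),
                         slope = range_normalize(env$slope),
                         aspect = range_normalize(env$aspect),
                         lapply(screen$data, range_normalize),
                         bedrock = droplevels(env$bedrock),
                         check.names = FALSE)

## stepwise GLMs ------------------------------------------------------------
glm_rows <- list()
for (resp in c("SR", "NRI", "NTI", "PDI")) {
  fit <- stepwise_glm_aic(site_tab[[resp]], predictors, response = resp)
  message(sprintf("%s GLM: AIC = %.2f, R2 = %.2f, terms: %s", resp, fit$aic,
                  fit$r2, paste(fit$terms, collapse = " + ")))
  glm_rows[[resp]] <- data.frame(response = resp, fit$table,
                                 aic = fit$aic, r2 = fit$r2)
}
write_result_csv(do.call(rbind, glm_rows), file.path(out, "glm_models.csv"))
message("tables written to ", out)
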