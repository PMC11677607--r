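test_that("null distribution degenerates when randomization cannot vary", {
  tr <- simulate_yule_tree(8, seed = 5)
  # community = whole pool: every richness-preserving draw is the pool itself
  null <- null_distribution("PD", tr, tr$tip.label, n_null = 25, seed = 1)
  expect_equal(stats::sd(null), 0)
  expect_equal(null[1], faith_pd(tr, tr$tip.label))
  res <- pdi(tr, tr$tip.label, n_null = 25, seed = 1)
  expect_true(res$undefined)
  expect_true(is.na(res$ses))
  expect_equal(classify_structure(res), "indeterminate")

  # star tree: MPD identical for every subset of given size
  star <- parse_newick("(A:2,B:2,C:2,D:2,E:2);")
  nullm <- null_distribution("MPD", star, c("A", "B", "C"), n_null = 20, seed = 2)
  expect_equal(stats::sd(nullm), 0)
  expect_true(all(nullm == 4))

  expect_error(
    null_distribution("MPD", tr, tr$tip.label[1:3], null_model = "swap"),
    "unknown null model")
})

test_that("null mean matches exhaustive subset enumeration on an 8-tip tree", {
  tr <- simulate_yule_tree(8, seed = 17)
  ctx <- phylo_context(tr)
  subsets <- utils::combn(tr$tip.label, 4, simplify = FALSE)  # all C(8,4)=70
  for (metric in c("PD", "MPD", "MNTD")) {
    f <- switch(metric,
                PD = function(s) faith_pd(ctx, s),
                MPD = function(s) mpd(ctx$D, s),
                MNTD = function(s) mntd(ctx$D, s))
    exact <- vapply(subsets, f, numeric(1))
    null <- null_distribution(metric, ctx, tr$tip.label[1:4],
                              n_null = 999, seed = 3)
    se <- stats::sd(exact) / sqrt(999)
    expect_lt(abs(mean(null) - mean(exact)), 3 * se)
  }
})

test_that("fixing the seed fixes the whole null vector bit for bit", {
  tr <- simulate_yule_tree(20, seed = 9)
  taxa <- tr$tip.label[1:6]
  a <- null_distribution("MPD", tr, taxa, n_null = 50, seed = 42)
  b <- null_distribution("MPD", tr, taxa, n_null = 50, seed = 42)
  expect_identical(a, b)
  r1 <- ses_indices(tr, taxa, n_null = 50, seed = 42)
  r2 <- ses_indices(tr, taxa, n_null = 50, seed = 42)
  expect_identical(r1, r2)
  # and the shared-null engine agrees with the per-index wrappers
  expect_equal(r1$NRI$ses, nri(tr, taxa, n_null = 50, seed = 42)$ses)
  expect_equal(r1$NTI$ses, nti(tr, taxa, n_null = 50, seed = 42)$ses)
  expect_equal(r1$PDI$ses, pdi(tr, taxa, n_null = 50, seed = 42)$ses)
})

test_that("sign conventions: NRI/NTI positive means clustering", {
  # hand-built SES results exercise the conventions directly
  mk <- function(metric, obs, nm, nsd) {
    phylospat:::.new_ses_result(metric, obs, c(nm - nsd, nm, nm + nsd),
                                if (metric == "PDI") +1 else -1, 3, 1)
  }
  # observed MPD below null mean -> NRI > 0 -> clustered
  r <- mk("NRI", obs = 1, nm = 2, nsd = 0.5)
  expect_gt(r$ses, 0)
  expect_equal(classify_structure(r), "clustered")
  # observed MNTD above null mean -> NTI < 0 -> overdispersed
  r <- mk("NTI", obs = 3, nm = 2, nsd = 0.5)
  expect_lt(r$ses, 0)
  expect_equal(classify_structure(r), "overdispersed")
  # PDI: observed equals null mean -> SES 0 -> indeterminate
  r <- mk("PDI", obs = 2, nm = 2, nsd = 0.5)
  expect_equal(r$ses, 0)
  expect_equal(classify_structure(r), "indeterminate")
  # PDI below null mean = less diversity than expected = clustering
  r <- mk("PDI", obs = 1, nm = 2, nsd = 0.5)
  expect_equal(classify_structure(r), "clustered")
})

test_that("SES engine matches an independent picante computation statistically", {
  tr <- simulate_yule_tree(40, seed = 31)
  taxa <- sort(sample(tr$tip.label, 10))
  taxa2 <- sort(sample(tr$tip.label, 14))
  samp <- rbind(s1 = as.integer(tr$tip.label %in% taxa),
                s2 = as.integer(tr$tip.label %in% taxa2))
  colnames(samp) <- tr$tip.label
  ours <- nri(tr, taxa, n_null = 999, seed = 77)
  ref <- picante::ses.mpd(samp, cophenetic_matrix(tr),
                          null.model = "taxa.labels", runs = 999)
  # same observed value exactly; same null moments up to Monte Carlo error
  expect_equal(ours$observed, ref$mpd.obs[1], tolerance = 1e-9)
  expect_lt(abs(ours$null_mean - ref$mpd.rand.mean[1]),
            4 * ref$mpd.rand.sd[1] / sqrt(999))
  expect_lt(abs(-ours$ses - ref$mpd.obs.z[1]), 0.35)
})

test_that("SES of uniform-random communities is approximately standard normal", {
  tr <- simulate_yule_tree(64, seed = 3)
  ctx <- phylo_context(tr)
  sc <- assembly_scenario("neutral", richness = 12, n_sites = 120, seed = 8)
  M <- simulate_assembly(ctx, sc)
  z <- t(vapply(seq_len(nrow(M)), function(s) {
    r <- ses_indices(ctx, colnames(M)[M[s, ] > 0], n_null = 199,
                     seed = derive_seed(8, 1000 + s))
    c(r$PDI$ses, r$NRI$ses, r$NTI$ses)
  }, numeric(3)))
  # looser than the headline calibration (fewer sites/nulls here)
  expect_true(all(abs(colMeans(z)) < 0.3))
  expect_true(all(apply(z, 2, stats::sd) > 0.7 & apply(z, 2, stats::sd) < 1.3))
})
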