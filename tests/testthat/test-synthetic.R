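test_that("yule trees satisfy pure-birth identities", {
  # two tips: a single cherry with equal depths
  tr2 <- simulate_yule_tree(2, seed = 1)
  expect_equal(length(tr2$tip.label), 2)
  depths <- ape::node.depth.edgelength(tr2)[1:2]
  expect_equal(depths[1], depths[2])

  # binary-tree combinatorics: n tips always mean n - 1 internal nodes
  nn <- vapply(1:30, function(s) simulate_yule_tree(17, seed = s)$Nnode,
               numeric(1))
  expect_true(all(nn == 16))

  # reproducibility is bit-for-bit under a fixed seed
  expect_identical(write_newick(simulate_yule_tree(25, 2, seed = 99)),
                   write_newick(simulate_yule_tree(25, 2, seed = 99)))
  expect_error(simulate_yule_tree(1), "n_tips")
  expect_error(simulate_yule_tree(5, birth_rate = 0), "birth_rate")
})

test_that("yule branch-length totals follow the closed-form expectations", {
  # E[total length] = (n-1)/lambda; E[height] = (H_n - 1)/lambda
  lambda <- 2
  set.seed(12)
  for (n in c(6, 12)) {
    tot <- vapply(1:150, function(s)
      sum(simulate_yule_tree(n, lambda, seed = 5000 + 100 * n + s)$edge.length),
      numeric(1))
    exp_tot <- (n - 1) / lambda
    se <- sd(tot) / sqrt(length(tot))
    expect_lt(abs(mean(tot) - exp_tot), 3 * se)
  }
  hts <- vapply(1:150, function(s) {
    tr <- simulate_yule_tree(10, lambda, seed = 9000 + s)
    max(ape::node.depth.edgelength(tr))
  }, numeric(1))
  exp_ht <- (sum(1 / (2:10))) / lambda
  expect_lt(abs(mean(hts) - exp_ht), 3 * sd(hts) / sqrt(150))
})

test_that("assembly regimes produce the expected phylogenetic signatures", {
  tr <- simulate_yule_tree(64, seed = 2)
  ctx <- phylo_context(tr)
  mean_nri <- function(mode, tau, n_sites, seed) {
    sc <- assembly_scenario(mode, richness = 12, n_sites = n_sites,
                            tau = tau, seed = seed)
    M <- simulate_assembly(ctx, sc)
    vapply(seq_len(n_sites), function(s) {
      r <- ses_indices(ctx, colnames(M)[M[s, ] > 0], n_null = 99,
                       seed = derive_seed(seed, 500 + s))
      c(r$NRI$ses, r$NTI$ses)
    }, numeric(2))
  }
  dbar <- mean(ctx$D[upper.tri(ctx$D)])
  filt <- mean_nri("filtering", tau = 0.2 * dbar, n_sites = 60, seed = 3)
  expect_lt(t.test(filt[1, ], alternative = "greater")$p.value, 0.01)  # NRI > 0
  expect_lt(t.test(filt[2, ], alternative = "greater")$p.value, 0.01)  # NTI > 0
  rep_ <- mean_nri("repulsion", tau = dbar, n_sites = 60, seed = 4)
  expect_lt(t.test(rep_[1, ], alternative = "less")$p.value, 0.01)     # NRI < 0
  expect_error(assembly_scenario("filtering", tau = 0), "tau")
  expect_error(
    simulate_assembly(ctx, assembly_scenario("neutral", richness = 100,
                                             n_sites = 1)),
    "pool")
})

test_that("assembly is reproducible and respects richness", {
  tr <- simulate_yule_tree(40, seed = 6)
  sc <- assembly_scenario("filtering", richness = c(5, 9, 13), n_sites = 3,
                          tau = 0.5, seed = 10)
  M1 <- simulate_assembly(tr, sc)
  M2 <- simulate_assembly(tr, sc)
  expect_identical(M1, M2)
  expect_equal(unname(rowSums(M1)), c(5, 9, 13))
})

test_that("landscapes carry the advertised structure", {
  land <- simulate_landscape(landscape_scenario(seed = 5))
  env <- land$env
  expect_equal(nrow(env), 75)
  expect_equal(range(env$elevation), c(0, 869.7))
  expect_equal(length(levels(env$bedrock)), 5)
  # climate block contains a near-duplicated pair by construction
  clim <- env[, c("MAT", "MTWQ", "Isoth", "MDR", "TAR", "PWM", "PDM", "PS")]
  C <- abs(cor(clim))
  expect_gt(max(C[upper.tri(C)]), 0.95)
  expect_gte(nrow(drop_collinear(clim)$log), 1)
  # reproducible given the seed
  land2 <- simulate_landscape(landscape_scenario(seed = 5))
  expect_identical(land$y, land2$y)
  expect_error(landscape_scenario(rho_true = 1.2), "rho_true")
})

test_that("OLS recovers landscape effects when rho_true = 0", {
  hits <- 0L; total <- 0L
  for (s in 1:30) {
    land <- simulate_landscape(landscape_scenario(rho_true = 0, seed = 600 + s))
    fit <- lm(land$y ~ land$X)
    est <- coef(fit)[-1]
    se <- sqrt(diag(vcov(fit)))[-1]
    hits <- hits + sum(abs(est - land$beta_true) <= 2 * se)
    total <- total + length(est)
  }
  expect_gte(hits / total, 0.9)
})

test_that("the full study bundle feeds the pipeline formats", {
  st <- simulate_study(n_sites = 20, n_species = 80, seed = 44)
  expect_s3_class(st$tree, "phylo")
  expect_equal(dim(st$community), c(20, 80))
  expect_true(all(rowSums(st$community) >= 2))
  expect_setequal(rownames(st$community), st$env$site_id)
  # round-trips through the file formats the analysis modules read
  td <- withr::local_tempdir()
  ape::write.tree(st$tree, file.path(td, "tree.nwk"))
  write.csv(data.frame(site_id = rownames(st$community), st$community,
                       check.names = FALSE),
            file.path(td, "community.csv"), row.names = FALSE)
  write.csv(st$env, file.path(td, "env.csv"), row.names = FALSE)
  write.csv(st$coords, file.path(td, "coords.csv"), row.names = FALSE)
  bundle <- validate_inputs(file.path(td, "tree.nwk"),
                            file.path(td, "community.csv"),
                            file.path(td, "env.csv"),
                            file.path(td, "coords.csv"))
  expect_s3_class(bundle, "dataset_bundle")
})
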