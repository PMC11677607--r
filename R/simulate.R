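#' Simulate a pure-birth (Yule) phylogeny
#'
#' Lineages split at rate `birth_rate` each; epoch durations are
#' exponential with rate `k * birth_rate` while `k` lineages are extant,
#' and the lineage that splits is chosen uniformly. After the pool reaches
#' `n_tips` lineages one final exponential epoch is drawn before the
#' present, so terminal branches are strictly positive and the tree is
#' ultrametric. Under this construction the expected total branch length
#' is `(n - 1) / birth_rate` and the expected height is
#' `(H_n - 1) / birth_rate` with `H_n` the n-th harmonic number.
#'
#' @param n_tips number of tips (>= 2).
#' @param birth_rate speciation rate (> 0), in 1/time units.
#' @param seed integer seed; the tree is bit-reproducible given the seed.
#' @return an [ape] `"phylo"` tree with tip labels `t1..tn`.
#' @export
simulate_yule_tree <- function(n_tips, birth_rate = 1, seed = NULL) {
  n <- as.integer(n_tips)
  if (n < 2L) stop("need n_tips >= 2")
  if (birth_rate <= 0) stop("birth_rate must be > 0")
  with_seed(seed, {
    root <- n + 1L
    next_internal <- n + 2L
    open_par <- c(root, root)   # parent node of each open lineage
    open_birth <- c(0, 0)       # birth time of each open lineage
    edge_parent <- integer(0)
    edge_child <- integer(0)
    edge_len <- numeric(0)
    t <- 0
    while (length(open_par) < n) {
      k <- length(open_par)
      t <- t + stats::rexp(1L, k * birth_rate)
      i <- sample.int(k, 1L)
      node <- next_internal
      next_internal <- next_internal + 1L
      edge_parent <- c(edge_parent, open_par[i])
      edge_child <- c(edge_child, node)
      edge_len <- c(edge_len, t - open_birth[i])
      open_par <- c(open_par[-i], node, node)
      open_birth <- c(open_birth[-i], t, t)
    }
    t <- t + stats::rexp(1L, n * birth_rate)
    edge_parent <- c(edge_parent, open_par)
    edge_child <- c(edge_child, seq_len(n))
    edge_len <- c(edge_len, t - open_birth)
    tree <- list(edge = cbind(edge_parent, edge_child, deparse.level = 0),
                 edge.length = edge_len, Nnode = n - 1L,
                 tip.label = paste0("t", seq_len(n)))
    class(tree) <- "phylo"
    tree <- ape::reorder.phylo(tree, "cladewise")
    validate_phylogeny(tree)
    tree
  })
}

#' Describe a community-assembly scenario
#'
#' @param mode `"neutral"` (uniform richness-matched subsets),
#'   `"filtering"` (species near a random focal lineage are favoured:
#'   inclusion weight `exp(-d / tau)` in cophenetic distance `d`) or
#'   `"repulsion"` (species far from those already selected are favoured:
#'   weight proportional to the minimum distance to the selected set).
#' @param richness species per site (scalar or one value per site).
#' @param n_sites number of sites.
#' @param tau kernel scale in branch-length units (> 0); small `tau` means
#'   strong filtering.
#' @param seed master seed; each site draws from its own derived stream.
#' @return a list of class `"assembly_scenario"`.
#' @export
assembly_scenario <- function(mode = c("neutral", "filtering", "repulsion"),
                              richness = 20L, n_sites = 75L, tau = 1,
                              seed = NULL) {
  mode <- match.arg(mode)
  if (tau <= 0) stop("tau must be > 0")
  if (any(richness < 2L)) stop("richness must be >= 2")
  structure(list(mode = mode, richness = richness, n_sites = as.integer(n_sites),
                 tau = tau, seed = seed),
            class = "assembly_scenario")
}

#' Assemble communities on a phylogeny
#'
#' Draws `n_sites` species assemblages from the tree's tip pool under the
#' scenario's assembly regime. Filtering produces phylogenetically
#' clustered communities (expected NRI/NTI > 0), repulsion overdispersed
#' ones, and neutral assemblages calibrate the null (expected SES ~ 0).
#' Each site uses a seed derived from the master seed and the site index,
#' so results do not depend on evaluation order.
#'
#' @param tree a `"phylo"` object or [phylo_context()].
#' @param scenario an [assembly_scenario()].
#' @return a binary site x species matrix; rownames `site_1..site_n`,
#'   colnames the tree's tip labels.
#' @export
simulate_assembly <- function(tree, scenario) {
  stopifnot(inherits(scenario, "assembly_scenario"))
  ctx <- as_phylo_context(tree)
  n <- ctx$ntip
  richness <- rep_len(scenario$richness, scenario$n_sites)
  if (any(richness > n)) stop("richness exceeds the species pool")
  M <- matrix(0L, scenario$n_sites, n,
              dimnames = list(paste0("site_", seq_len(scenario$n_sites)),
                              ctx$tip_labels))
  for (s in seq_len(scenario$n_sites)) {
    site_seed <- if (is.null(scenario$seed)) NULL else
      derive_seed(scenario$seed, s)
    idx <- with_seed(site_seed,
      .draw_assemblage(ctx$D, richness[s], scenario$mode, scenario$tau))
    M[s, idx] <- 1L
  }
  M
}

.draw_assemblage <- function(D, r, mode, tau) {
  n <- nrow(D)
  if (mode == "neutral") {
    return(sample.int(n, r))
  }
  if (mode == "filtering") {
    focal <- sample.int(n, 1L)
    others <- setdiff(seq_len(n), focal)
    wts <- exp(-D[focal, others] / tau)
    wts[wts <= 0 | !is.finite(wts)] <- .Machine$double.xmin
    return(c(focal, sample(others, r - 1L, prob = wts)))
  }
  # repulsion: sequential, favouring tips distant from the selected set
  sel <- sample.int(n, 1L)
  while (length(sel) < r) {
    cand <- setdiff(seq_len(n), sel)
    dmin <- apply(D[cand, sel, drop = FALSE], 1L, min)
    if (all(dmin == 0)) dmin[] <- 1
    sel <- c(sel, if (length(cand) == 1L) cand else
      sample(cand, 1L, prob = dmin))
  }
  sel
}

#' Describe a synthetic landscape
#'
#' Defaults emulate the scale and structure of a volcanic coastal mountain
#' survey: 75 sites in a ~10 x 7 km lon/lat window around 22.5 N, 114.5 E,
#' an elevation gradient from sea level to 869.7 m, a mosaic of five
#' bedrock types in spatially contiguous patches, a block of correlated
#' bioclimatic variables containing at least one nearly duplicated pair
#' (|r| > 0.95, so the collinearity screen always has work to do), and a
#' response with spatial autocorrelation `rho_true` on k-nearest-neighbour
#' weights.
#'
#' @param n_sites number of sites (default 75).
#' @param elevation_range numeric length-2, metres (default c(0, 869.7)).
#' @param bedrock_levels character vector of bedrock classes.
#' @param rho_true spatial-lag coefficient in (-1, 1) (default 0.4).
#' @param noise_sd sd of the response noise (default 1).
#' @param k neighbours for the weights used to generate the response.
#' @param seed integer seed.
#' @return a list of class `"landscape_scenario"`.
#' @export
landscape_scenario <- function(n_sites = 75L,
                               elevation_range = c(0, 869.7),
                               bedrock_levels = c("granite", "rhyolite",
                                                  "pyroclastic rock",
                                                  "pyroclastic lava",
                                                  "quartz sandstone"),
                               rho_true = 0.4, noise_sd = 1, k = 4L,
                               seed = NULL) {
  if (abs(rho_true) >= 1) stop("rho_true must lie in (-1, 1)")
  structure(list(n_sites = as.integer(n_sites),
                 elevation_range = elevation_range,
                 bedrock_levels = bedrock_levels, rho_true = rho_true,
                 noise_sd = noise_sd, k = as.integer(k), seed = seed),
            class = "landscape_scenario")
}

#' Simulate a spatial landscape: coordinates, environment, response
#'
#' Generates site coordinates, a smooth elevation surface, slope and
#' aspect, contiguous bedrock patches (nearest of five random patch
#' centres), a bioclimatic block driven by shared temperature and
#' precipitation factors (with a built-in near-duplicate pair, MAT/MTWQ),
#' and a response `y = (I - rho W)^{-1} (X beta_true + eps)` on the
#' k-nearest-neighbour weights of the coordinates.
#'
#' @param scenario a [landscape_scenario()].
#' @return list with `coords` (data frame: site_id, lon, lat), `env`
#'   (EnvironmentTable data frame), `y` (response vector), `X` (design
#'   used to generate `y`), `beta_true`, `rho_true`, `weights`.
#' @export
simulate_landscape <- function(scenario = landscape_scenario()) {
  stopifnot(inherits(scenario, "landscape_scenario"))
  n <- scenario$n_sites
  with_seed(scenario$seed, {
    lon <- stats::runif(n, 114.52, 114.62)
    lat <- stats::runif(n, 22.49, 22.56)
    u <- (lon - 114.52) / 0.10
    v <- (lat - 22.49) / 0.07
    # dome-shaped massif: high in the window centre, falling to the coast
    dome <- 1 - ((u - 0.5)^2 + (v - 0.5)^2) / 0.5
    elev_raw <- dome + stats::rnorm(n, 0, 0.15)
    er <- scenario$elevation_range
    elevation <- er[1] + (er[2] - er[1]) * range_normalize(elev_raw)
    slope <- pmin(pmax(stats::rnorm(n, 22, 8), 1), 55)
    aspect <- stats::runif(n, 0, 360)
    centres <- cbind(stats::runif(5, 0, 1), stats::runif(5, 0, 1))
    d2 <- outer(u, centres[, 1], "-")^2 + outer(v, centres[, 2], "-")^2
    bedrock <- factor(scenario$bedrock_levels[max.col(-d2)],
                      levels = scenario$bedrock_levels)
    # shared latent factors give the climate block its collinearity
    temp_f <- -elevation / er[2] + 0.2 * stats::rnorm(n)
    prec_f <- v + 0.3 * stats::rnorm(n)
    climate <- data.frame(
      MAT   = 220 + 30 * temp_f,
      MTWQ  = 280 + 30 * temp_f + stats::rnorm(n, 0, 1.5),  # near-copy of MAT
      Isoth = 45 + 5 * temp_f + 3 * stats::rnorm(n),
      MDR   = 60 - 8 * temp_f + 4 * stats::rnorm(n),
      TAR   = 160 - 20 * temp_f + 8 * stats::rnorm(n),
      PWM   = 350 + 60 * prec_f + 25 * stats::rnorm(n),
      PDM   = 30 + 10 * prec_f + 4 * stats::rnorm(n),
      PS    = 70 + 12 * prec_f + 6 * stats::rnorm(n)
    )
    coords <- data.frame(site_id = paste0("site_", seq_len(n)),
                         lon = lon, lat = lat)
    env <- data.frame(site_id = coords$site_id, elevation = elevation,
                      slope = slope, aspect = aspect, bedrock = bedrock,
                      climate, stringsAsFactors = FALSE)
    w <- knn_weights(cbind(lon, lat), k = scenario$k)
    X <- cbind(elevation = range_normalize(elevation),
               Isoth = range_normalize(climate$Isoth),
               PS = range_normalize(climate$PS),
               pyroclastic_lava = as.numeric(bedrock == "pyroclastic lava"))
    beta_true <- c(elevation = 3, Isoth = -2, PS = 2, pyroclastic_lava = 1.5)
    eta <- as.numeric(X %*% beta_true) +
      stats::rnorm(n, 0, scenario$noise_sd)
    A <- diag(n) - scenario$rho_true * w$W
    y <- as.numeric(solve(A, eta))
    list(coords = coords, env = env, y = y, X = X, beta_true = beta_true,
         rho_true = scenario$rho_true, weights = w)
  })
}

#' Simulate a complete study system
#'
#' Bundles everything the pipeline consumes: a Yule species-pool tree, a
#' landscape (coordinates, environment, latent richness surface) and
#' communities assembled on the tree with richness following the spatial
#' surface. Assembly is environmental filtering whose kernel scale varies
#' with elevation (stronger filtering upslope), so phylogenetic structure
#' co-varies with the environment as in a montane filtering regime.
#'
#' @param n_sites number of sites (default 75).
#' @param n_species species-pool size (default 594).
#' @param richness_range site richness limits mapped onto the latent
#'   surface (default c(10, 60)).
#' @param mode assembly regime passed through to [simulate_assembly()].
#' @param rho_true spatial autocorrelation of the latent surface.
#' @param seed master seed.
#' @return list with `tree`, `community`, `env`, `coords`, `landscape`.
#' @export
simulate_study <- function(n_sites = 75L, n_species = 594L,
                           richness_range = c(10L, 60L),
                           mode = "filtering", rho_true = 0.4, seed = 1L) {
  tree <- simulate_yule_tree(n_species, birth_rate = 1,
                             seed = derive_seed(seed, 1L))
  land <- simulate_landscape(landscape_scenario(
    n_sites = n_sites, rho_true = rho_true, seed = derive_seed(seed, 2L)))
  richness <- round(richness_range[1] +
                    (richness_range[2] - richness_range[1]) *
                    range_normalize(land$y))
  ctx <- phylo_context(tree)
  # filtering strength tightens with elevation: tau spans ~ (0.15, 1) x
  # mean pairwise depth, giving upslope communities stronger clustering
  dbar <- mean(ctx$D[upper.tri(ctx$D)])
  elev01 <- range_normalize(land$env$elevation)
  M <- matrix(0L, n_sites, ctx$ntip,
              dimnames = list(land$env$site_id, ctx$tip_labels))
  for (s in seq_len(n_sites)) {
    tau_s <- dbar * (1 - 0.85 * elev01[s])
    sc <- assembly_scenario(mode = mode, richness = richness[s],
                            n_sites = 1L, tau = tau_s,
                            seed = derive_seed(seed, 100L + s))
    M[s, ] <- simulate_assembly(ctx, sc)[1L, ]
  }
  list(tree = tree, community = M, env = land$env, coords = land$coords,
       landscape = land)
}
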