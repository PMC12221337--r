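# The synthetic-data generator: trees, traits, environment, regimes, KO
# tables, and seed determinism.

test_that("Yule tree simulation produces labelled binary trees deterministically", {
  t2 <- simulate_tree(2, seed = 1)
  expect_equal(length(t2$tip.label), 2)
  expect_equal(t2$Nnode, 1)

  t64a <- simulate_tree(64, seed = 1)
  t64b <- simulate_tree(64, seed = 1)
  expect_identical(ape::write.tree(t64a), ape::write.tree(t64b))
  expect_setequal(t64a$tip.label, paste0("OTU_", 1:64))

  depths <- ape::node.depth.edgelength(t64a)[seq_len(64)]
  expect_true(all(depths > 0))
  expect_true(all(t64a$edge.length > 0))

  expect_error(simulate_tree(1), class = "sedcomm_invalid_argument")
})

test_that("Brownian traits respect the tree: sisters diverge less than distant tips", {
  tree <- ape::read.tree(text = "((A:0.01,B:0.01):1.99,(C:0.01,D:0.01):1.99);")
  sis <- numeric(100); far <- numeric(100)
  for (s in 1:100) {
    tr <- simulate_traits(tree, sigma = 1, seed = s)
    sis[s] <- abs(tr["A"] - tr["B"])
    far[s] <- abs(tr["A"] - tr["C"])
  }
  expect_lt(mean(sis), mean(far) / 3)

  tr1 <- simulate_traits(tree, sigma = 1, seed = 5)
  tr2 <- simulate_traits(tree, sigma = 1, seed = 5)
  expect_identical(tr1, tr2)

  tiny <- simulate_traits(tree, sigma = 1e-12, seed = 1)
  expect_true(all(abs(tiny) < 1e-9))

  expect_error(simulate_traits(tree, sigma = 0), class = "sedcomm_invalid_argument")
})

test_that("transect environment has the 5/5/5 design, monotone salinity and even spacing", {
  ec <- simulate_environment(15, c(0.12, 35.8), transect_km = 300, seed = 2)
  expect_equal(as.vector(table(ec$env$group)), c(5L, 5L, 5L))
  expect_true(all(ec$env$MC >= 0 & ec$env$MC <= 100))

  ec0 <- simulate_environment(15, c(0.12, 35.8), seed = 2, noise_sd = 0)
  expect_equal(cor(ec0$env$salinity, seq_len(15), method = "spearman"), 1)

  ec4 <- simulate_environment(4, c(0.12, 35.8), transect_km = 300, seed = 1)
  g <- geo_distances(ec4$coords)
  gaps <- c(g[1, 2], g[2, 3], g[3, 4])
  expect_true(all(abs(gaps - 100) < 1))

  expect_error(simulate_environment(15, c(10, 10)),
               class = "sedcomm_invalid_argument")
})

test_that("community rows sum to depth and the narrow-niche limit is filtered", {
  for (regime in c("selection", "dispersal_limitation", "drift", "homogenizing")) {
    ds <- small_dataset(regime = regime, seed = 3)
    expect_true(all(rowSums(ds$community) == ds$config$depth), info = regime)
  }

  cfg <- simulation_config(n_taxa = 40, n_samples = 9, depth = 2000,
                           regime = "selection", niche_width = 1e-3, seed = 4)
  tree <- simulate_tree(cfg$n_taxa, derive_seed(cfg$seed, "tree"))
  traits <- simulate_traits(tree, 1, derive_seed(cfg$seed, "traits"),
                            root = mean(cfg$salinity_range))
  ec <- simulate_environment(cfg$n_samples, cfg$salinity_range, seed = cfg$seed)
  comm <- simulate_communities(tree, traits, ec$env, ec$coords, cfg)
  for (s in seq_len(nrow(comm))) {
    modal <- names(which.max(comm[s, ]))
    gaps <- abs(traits - ec$env$salinity[s])
    expect_equal(unname(gaps[modal]), min(gaps), tolerance = 1e-12)
  }

  expect_error(simulation_config(regime = "neutral"))
})

test_that("drift communities are more similar than niche-filtered ones", {
  bc_mean <- function(regime, seed) {
    ds <- simulate_dataset(simulation_config(
      n_taxa = 60, n_samples = 15, depth = 1e4, regime = regime,
      niche_width = 2, seed = seed))
    bc <- bray_curtis(ds$community)
    mean(bc[upper.tri(bc)])
  }
  drift <- vapply(1:50, function(s) bc_mean("drift", s), numeric(1))
  selec <- vapply(1:50, function(s) bc_mean("selection", s), numeric(1))
  expect_lt(mean(drift), mean(selec))
})

test_that("null KO tables give nominal Kruskal-Wallis rejection rates", {
  groups <- factor(rep(c("low", "mid", "high"), each = 5),
                   levels = c("low", "mid", "high"))
  ko <- simulate_ko_table(200, groups, n_affected = 0, effect = 1, seed = 9)
  expect_false(any(ko$affected))
  kw <- kruskal_wallis_groups(rpkm_normalize(ko), groups = groups)
  rate <- mean(kw$p < 0.05)
  expect_gte(rate, 0.01)
  expect_lte(rate, 0.10)

  ko2 <- simulate_ko_table(200, groups, n_affected = 0, effect = 1, seed = 9)
  expect_identical(ko$counts, ko2$counts)
  expect_identical(ko$gene_length, ko2$gene_length)

  expect_error(simulate_ko_table(10, factor(character(0))),
               class = "sedcomm_invalid_argument")
  expect_error(simulate_ko_table(10, groups, n_affected = 20),
               class = "sedcomm_invalid_argument")
})

test_that("whole datasets are reproducible from config + seed", {
  a <- small_dataset(seed = 12)
  b <- small_dataset(seed = 12)
  expect_identical(a$community, b$community)
  expect_identical(ape::write.tree(a$tree), ape::write.tree(b$tree))
  expect_identical(a$env, b$env)
  expect_identical(a$ko$counts, b$ko$counts)
  expect_true(all(colnames(a$community) %in% a$tree$tip.label))
  expect_identical(rownames(a$community), a$env$sample)
  expect_identical(a$env$sample, a$coords$sample)
})
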