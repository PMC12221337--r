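# beta-MNTD, the tip-shuffle betaNTI null, RCbray, and the five-process
# classification.

sym_from_upper <- function(vals, n, ids = paste0("S", seq_len(n))) {
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  m[upper.tri(m)] <- vals
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

test_that("beta-MNTD matches hand values and vanishes for identical communities", {
  tree <- balanced_tree4()
  comm <- toy_comm(rbind(c(1L, 1L, 0L, 0L), c(0L, 0L, 1L, 1L)),
                   otus = c("A", "B", "C", "D"))
  bm <- beta_mntd(comm, tree)
  expect_equal(bm[1, 2], 4)   # all cross patristic distances are 4
  expect_equal(diag(bm), setNames(c(0, 0), rownames(comm)))

  same <- toy_comm(rbind(c(3L, 1L, 2L, 0L), c(3L, 1L, 2L, 0L)),
                   otus = c("A", "B", "C", "D"))
  expect_equal(beta_mntd(same, tree)[1, 2], 0)

  missing <- toy_comm(cbind(comm, X = c(1L, 0L)),
                      otus = c("A", "B", "C", "D", "X"))
  expect_error(beta_mntd(missing, tree), class = "sedcomm_alignment_error")
})

test_that("beta-MNTD equals independent brute-force and picante oracles", {
  for (seed in 1:20) {
    inst <- random_instance(8, 4, seed)
    ours <- beta_mntd(inst$comm, inst$tree, abundance_weighted = TRUE)
    expect_lt(max(abs(ours - bmntd_brute(inst$comm, inst$tree, TRUE))), 1e-10)
  }
  inst <- random_instance(12, 5, 99)
  for (weighted in c(TRUE, FALSE)) {
    ours <- beta_mntd(inst$comm, inst$tree, abundance_weighted = weighted)
    pic <- as.matrix(picante::comdistnt(inst$comm, cophenetic(inst$tree),
                                        abundance.weighted = weighted))
    expect_lt(max(abs(ours - pic[rownames(ours), colnames(ours)])), 1e-10)
  }
})

test_that("beta-MNTD is symmetric and scales linearly with branch lengths", {
  inst <- random_instance(10, 5, 3)
  bm <- beta_mntd(inst$comm, inst$tree)
  expect_equal(bm, t(bm))
  scaled <- inst$tree
  scaled$edge.length <- scaled$edge.length * 3.5
  expect_equal(beta_mntd(inst$comm, scaled), 3.5 * bm, tolerance = 1e-12)
})

test_that("betaNTI is seed-deterministic and flags degenerate pairs", {
  ds <- small_dataset(seed = 4)
  cfg <- null_model_config(n_reps = 49, seed = 11)
  a <- beta_nti(ds$community, ds$tree, cfg)
  b <- beta_nti(ds$community, ds$tree, cfg)
  expect_identical(a$bnti, b$bnti)
  expect_true(all(a$null_sd[upper.tri(a$null_sd)] >= 0))

  # identical communities: observed beta-MNTD 0, no null can be smaller
  tree <- balanced_tree4()
  same <- toy_comm(rbind(c(2L, 1L, 1L, 0L), c(2L, 1L, 1L, 0L)),
                   otus = c("A", "B", "C", "D"))
  z <- beta_nti(same, tree, null_model_config(n_reps = 99, seed = 1))
  expect_equal(z$bmntd_obs[1, 2], 0)
  expect_true(is.na(z$bnti[1, 2]) || z$bnti[1, 2] <= 0)

  expect_error(null_model_config(n_reps = 0), class = "sedcomm_invalid_argument")
})

test_that("RCbray stays in [-1, 1] with 1/n_reps granularity and resolves extremes", {
  cfg <- null_model_config(n_reps = 199, seed = 2)

  same <- toy_comm(rbind(c(5L, 3L, 2L), c(5L, 3L, 2L)))
  rc_same <- raup_crick_bray(same, cfg)[1, 2]
  expect_lte(rc_same, -0.9)

  # two samples sharing no taxa, drawn from a large common pool
  set.seed(1)
  pool <- t(rmultinom(6, 300, runif(100)))
  a <- integer(100); b <- integer(100)
  a[1:40] <- 5L; b[61:100] <- 5L
  comm <- rbind(pool, a, b)
  rownames(comm) <- paste0("S", 1:8)
  colnames(comm) <- paste0("OTU_", 1:100)
  rc <- raup_crick_bray(comm, null_model_config(n_reps = 999, seed = 3))
  expect_gt(rc["S7", "S8"], 0.9)

  vals <- rc[upper.tri(rc)]
  expect_true(all(abs(vals) <= 1))
  grains <- (vals + 1) * 999   # must be multiples of 1 (half-ties give 1)
  expect_true(all(abs(grains - round(grains)) < 1e-6))

  expect_identical(raup_crick_bray(same, cfg), raup_crick_bray(same, cfg))
})

test_that("process classification applies the betaNTI / RCbray decision rule", {
  cfg <- null_model_config()
  b <- sym_from_upper(c(2.5, -2.5, 0.5, 0.1, 0.5, 1.9, -1.2, 0.3, 0, 0.2),
                      5)
  r <- sym_from_upper(c(0.99, 0.2, 0.97, 0.2, -0.97, 0.99, -0.99, 0.5, 0, 0),
                      5)
  res <- classify_assembly(b, r, cfg)
  p <- setNames(res$pairs$process,
                paste(res$pairs$sample_i, res$pairs$sample_j))
  expect_equal(unname(p["S1 S2"]), "heterogeneous_selection")  # bnti 2.5
  expect_equal(unname(p["S1 S3"]), "homogeneous_selection")    # bnti -2.5
  expect_equal(unname(p["S2 S3"]), "dispersal_limitation")     # 0.5 / 0.97
  expect_equal(unname(p["S1 S4"]), "drift")                    # 0.1 / 0.2
  expect_equal(unname(p["S2 S4"]), "homogenizing_dispersal")   # 0.5 / -0.97
  expect_equal(unname(p["S3 S4"]), "dispersal_limitation")     # 1.9 / 0.99
})

test_that("partition fractions reproduce the printed-percentage arithmetic", {
  # 28 pairs: 2 deterministic, 26 stochastic split 15 / 1 / 10
  bvals <- c(rep(3, 2), rep(0, 26))
  rvals <- c(rep(0, 2), rep(0.99, 15), rep(-0.99, 1), rep(0, 10))
  b <- sym_from_upper(bvals, 8)
  r <- sym_from_upper(rvals, 8)
  res <- classify_assembly(b, r, null_model_config())
  tot <- res$partition[res$partition$group == "total", ]
  expect_equal(round(tot$pct_dispersal_limitation, 2), 57.69)
  expect_equal(round(tot$pct_drift, 2), 38.46)
  expect_equal(round(tot$pct_homogenizing_dispersal, 2), 3.85)
  expect_equal(tot$pct_deterministic + tot$pct_stochastic, 100)
  expect_equal(tot$pct_dispersal_limitation + tot$pct_drift +
                 tot$pct_homogenizing_dispersal, 100)

  # undefined betaNTI pairs are excluded and tallied
  b[1, 2] <- b[2, 1] <- NA
  res2 <- classify_assembly(b, r, null_model_config())
  expect_equal(res2$n_excluded, 1)
  expect_equal(res2$partition[res2$partition$group == "total", "n_pairs"], 27)
})

test_that("group partitions use within-group pairs only", {
  ds <- small_dataset(seed = 5)
  cfg <- null_model_config(n_reps = 49, seed = 1)
  bn <- beta_nti(ds$community, ds$tree, cfg)
  rc <- raup_crick_bray(ds$community, cfg)
  res <- classify_assembly(bn, rc, cfg, groups = setNames(ds$env$group,
                                                          ds$env$sample))
  part <- res$partition
  counts <- table(ds$env$group)
  for (g in c("low", "mid", "high")) {
    expected_pairs <- choose(counts[[g]], 2)
    expect_lte(part[part$group == g, "n_pairs"], expected_pairs)
  }
  expect_lte(part[part$group == "total", "n_pairs"], choose(nrow(ds$community), 2))
})
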