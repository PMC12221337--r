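# PCoA, NMDS, UPGMA, ANOSIM, Mantel, haversine distances, PCNM,
# constrained ordination and variation partitioning.

test_that("PCoA reproduces a planar configuration from its Euclidean distances", {
  set.seed(4)
  pts <- matrix(rnorm(8), 4, 2)
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(paste0("S", 1:4), paste0("S", 1:4))
  ord <- pcoa(d, k = 2)
  # Procrustes: distances among recovered points equal the originals
  expect_lt(max(abs(as.matrix(dist(ord$points)) - unname(d))), 1e-8)
  # eigenvalue sum equals the trace of the centred matrix
  g <- -0.5 * scale(t(scale(t(d^2), scale = FALSE)), scale = FALSE)
  expect_equal(sum(ord$eigenvalues), sum(diag(g)), tolerance = 1e-9)

  zero <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_warning(z <- pcoa(zero, k = 2))
  expect_true(all(z$points == 0))
})

test_that("NMDS embeds collinear points with near-zero stress, deterministically", {
  pts <- cbind(seq_len(8) * 2)
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(paste0("S", 1:8), paste0("S", 1:8))
  fit <- suppressWarnings(nmds(d, k = 1, n_starts = 5, seed = 3))
  expect_lt(fit$stress, 0.01)
  fit2 <- suppressWarnings(nmds(d, k = 1, n_starts = 5, seed = 3))
  expect_identical(fit$points, fit2$points)
  expect_identical(fit$stress, fit2$stress)
  expect_error(nmds(d[1:2, 1:2], k = 1), class = "sedcomm_invalid_argument")
})

test_that("UPGMA joins the closest pair first at half its distance, ultrametrically", {
  d <- matrix(c(0, 1, 4,
                1, 0, 4,
                4, 4, 0), 3, dimnames = list(c("A", "B", "C"),
                                             c("A", "B", "C")))
  tr <- upgma_dendrogram(d)
  expect_setequal(tr$tip.label, c("A", "B", "C"))
  cp <- cophenetic(tr)
  expect_equal(cp["A", "B"], 1)        # joined at height 0.5
  expect_equal(cp["A", "C"], 4)
  expect_true(ape::is.ultrametric(tr, tol = 1e-9))

  ds <- small_dataset(seed = 19)
  bc <- bray_curtis(ds$community)
  tr2 <- upgma_dendrogram(bc)
  nwk <- ape::write.tree(tr2)
  back <- ape::read.tree(text = nwk)
  expect_true(ape::is.ultrametric(back, tol = 1e-6))
  expect_error(upgma_dendrogram(d[1, 1, drop = FALSE]),
               class = "sedcomm_invalid_argument")
})

test_that("ANOSIM yields R = 1 for perfectly separated groups and respects the permutation bound", {
  pts <- c(0, 0.1, 0.2, 10, 10.1, 10.2)
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(paste0("S", 1:6), paste0("S", 1:6))
  grp <- rep(c("a", "b"), each = 3)
  res <- anosim_test(d, grp, n_perm = 199, seed = 1)
  expect_equal(res$R, 1)
  expect_gte(res$p, 1 / 200)
  expect_error(anosim_test(d, rep("a", 6)), class = "sedcomm_invalid_argument")
})

test_that("Mantel r is exact under identity and scaling", {
  ds <- small_dataset(seed = 23)
  bc <- bray_curtis(ds$community)
  expect_equal(mantel_test(bc, bc, n_perm = 99, seed = 1)$r, 1)
  expect_equal(mantel_test(bc, 2 * bc, method = "pearson", n_perm = 99,
                           seed = 1)$r, 1)
  cst <- matrix(1, 5, 5) - diag(5)
  dimnames(cst) <- list(paste0("S", 1:5), paste0("S", 1:5))
  expect_error(mantel_test(cst, cst, n_perm = 99),
               class = "sedcomm_invalid_argument")
})

test_that("haversine distances hit the one-degree benchmark and are metric", {
  co <- data.frame(sample = c("p", "q"), lat = c(0, 0), lon = c(0, 1))
  g <- geo_distances(co)
  expect_lt(abs(g["p", "q"] - 111.19), 0.01)
  expect_equal(g["p", "p"], 0)

  set.seed(8)
  co2 <- data.frame(sample = paste0("S", 1:12),
                    lat = runif(12, -60, 60), lon = runif(12, -170, 170))
  g2 <- geo_distances(co2)
  expect_equal(g2, t(g2))
  for (i in 1:100) {
    trio <- sample(12, 3)
    expect_lte(g2[trio[1], trio[2]],
               g2[trio[1], trio[3]] + g2[trio[3], trio[2]] + 1e-9)
  }
  expect_error(geo_distances(data.frame(sample = "x", lat = 95, lon = 0)),
               class = "sedcomm_invalid_argument")
})

test_that("PCNM truncates at the longest MST edge and yields sinusoidal eigenvectors", {
  co <- data.frame(sample = paste0("S", 1:10), lat = rep(0, 10),
                   lon = seq(0, 0.9, by = 0.1))
  g <- geo_distances(co)
  spacing <- g[1, 2]
  pb <- pcnm_basis(g)
  expect_equal(pb$threshold, spacing, tolerance = 1e-9)

  V <- pb$vectors
  expect_lt(max(abs(colMeans(V))), 1e-9)
  gram <- crossprod(V)
  expect_lt(max(abs(gram - diag(diag(gram)))), 1e-8)

  sign_changes <- function(v) sum(diff(sign(v[v != 0])) != 0)
  expect_lt(sign_changes(V[, 1]), sign_changes(V[, 2]))

  all0 <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_error(pcnm_basis(all0), class = "sedcomm_invalid_argument")
})

test_that("RDA recovers a noiseless linear gradient on the first axis", {
  set.seed(11)
  n <- 12
  x <- seq_len(n)
  Y <- outer(x, seq_len(6)) + matrix(rnorm(n * 6, sd = 1e-3), n, 6)
  comm <- matrix(Y, n, 6, dimnames = list(paste0("S", 1:n),
                                          paste0("OTU_", 1:6)))
  res <- constrained_ordination(comm, data.frame(x = x), mode = "rda",
                                n_perm = 99, seed = 1, hellinger = FALSE)
  expect_gt(res$explained[1], 0.99)
  expect_lt(res$term_p["x"], 0.05)
})

test_that("constrained ordination is invariant to joint sample relabelling", {
  ds <- small_dataset(seed = 31, n_samples = 12)
  env <- ds$env[c("salinity", "TOC", "MC")]
  r1 <- constrained_ordination(ds$community, env, mode = "cca", n_perm = 49,
                               seed = 1)
  perm <- sample(nrow(ds$community))
  r2 <- constrained_ordination(ds$community[perm, ], env[perm, ],
                               mode = "cca", n_perm = 49, seed = 1)
  expect_equal(r1$explained, r2$explained, tolerance = 1e-9)

  too_many <- as.data.frame(matrix(rnorm(12 * 15), 12, 15))
  expect_error(constrained_ordination(ds$community, too_many, mode = "rda"),
               class = "sedcomm_invalid_argument")
})

test_that("variation partitioning obeys the decomposition identity and matches vegan", {
  ds <- small_dataset(seed = 13, n_samples = 12)
  env <- ds$env[c("salinity", "NH4_N", "TOC")]
  pb <- pcnm_basis(geo_distances(ds$coords))
  space <- pb$vectors[, 1:3]
  v <- variation_partitioning(ds$community, env, space)
  expect_equal(v$pure_env + v$shared + v$pure_space + v$unexplained, 1,
               tolerance = 1e-9)

  Y <- vegan::decostand(ds$community, "hellinger")
  vp <- vegan::varpart(Y, scale(as.matrix(env)), space)
  # vegan rows: [a] = X1|X2 (pure env), [b] = X2|X1 (pure space), [c] shared
  ind <- vp$part$indfract$Adj.R.square
  expect_equal(v$pure_env, ind[1], tolerance = 1e-6)
  expect_equal(v$pure_space, ind[2], tolerance = 1e-6)
  expect_equal(v$shared, ind[3], tolerance = 1e-6)
})

test_that("orthogonal predictor blocks leave no shared fraction", {
  set.seed(21)
  n <- 30
  env_driver <- rnorm(n)
  Y <- outer(env_driver, rnorm(8)) + matrix(rnorm(n * 8, sd = 0.01), n, 8)
  Y <- Y - min(Y) + 0.1
  comm <- matrix(Y, n, 8, dimnames = list(paste0("S", 1:n), paste0("OTU_", 1:8)))
  junk <- matrix(rnorm(n * 2), n, 2, dimnames = list(rownames(comm),
                                                     c("PCNM1", "PCNM2")))
  v <- variation_partitioning(comm, data.frame(env = env_driver), junk,
                              hellinger = FALSE)
  expect_lt(abs(v$pure_space), 0.05)
  expect_lt(abs(v$shared), 0.05)
  expect_gt(v$pure_env, 0.9)
})

test_that("composed printed fractions total as reported", {
  v <- vpa_compose(8.6, 30.0, 1.6)
  expect_equal(v$total_explained, 40.2)
  expect_equal(v$unexplained, 59.8)
})
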