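# Fixture builders and independent brute-force oracles used across the
# suite. The oracles deliberately share no code with the package
# internals they check.

toy_comm <- function(m, samples = NULL, otus = NULL) {
  m <- as.matrix(m)
  rownames(m) <- samples %||% paste0("S", seq_len(nrow(m)))
  colnames(m) <- otus %||% paste0("OTU_", seq_len(ncol(m)))
  storage.mode(m) <- "integer"
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

balanced_tree4 <- function() ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")

random_instance <- function(n_taxa, n_samples, seed, depth = 200) {
  set.seed(seed)
  tree <- ape::rtree(n_taxa)
  tree$tip.label <- paste0("OTU_", seq_len(n_taxa))
  comm <- t(rmultinom(n_samples, depth,
                      prob = runif(n_taxa, 0.2, 1)))
  dimnames(comm) <- list(paste0("S", seq_len(n_samples)), tree$tip.label)
  list(tree = tree, comm = comm)
}

# Exhaustive nearest-taxon beta-MNTD: plain nested loops over taxa.
bmntd_brute <- function(comm, tree, weighted = TRUE) {
  D <- cophenetic(tree)[colnames(comm), colnames(comm)]
  S <- nrow(comm)
  out <- matrix(0, S, S, dimnames = list(rownames(comm), rownames(comm)))
  for (k in seq_len(S - 1)) {
    for (m in (k + 1):S) {
      A <- which(comm[k, ] > 0)
      B <- which(comm[m, ] > 0)
      fA <- if (weighted) comm[k, A] / sum(comm[k, A]) else rep(1 / length(A), length(A))
      fB <- if (weighted) comm[m, B] / sum(comm[m, B]) else rep(1 / length(B), length(B))
      s1 <- 0
      for (a in seq_along(A)) {
        best <- Inf
        for (b in seq_along(B)) best <- min(best, D[A[a], B[b]])
        s1 <- s1 + fA[a] * best
      }
      s2 <- 0
      for (b in seq_along(B)) {
        best <- Inf
        for (a in seq_along(A)) best <- min(best, D[A[a], B[b]])
        s2 <- s2 + fB[b] * best
      }
      out[k, m] <- out[m, k] <- 0.5 * (s1 + s2)
    }
  }
  out
}

# Independent Spearman edge set: midrank-transform columns, Pearson
# correlation of the ranks, two-sided t-approximation p-value.
spearman_edges_brute <- function(comm, rho_min = 0.6, p_max = 0.01) {
  rel <- comm / rowSums(comm)
  n <- nrow(rel)
  ranks <- apply(rel, 2, rank)
  edges <- character(0)
  for (i in seq_len(ncol(rel) - 1)) {
    for (j in (i + 1):ncol(rel)) {
      r <- suppressWarnings(cor(ranks[, i], ranks[, j], method = "pearson"))
      if (is.na(r)) next
      tt <- r * sqrt((n - 2) / max(1 - r^2, 1e-300))
      p <- 2 * pt(-abs(tt), n - 2)
      if (r > rho_min && p < p_max)
        edges <- c(edges, paste(sort(c(colnames(rel)[i], colnames(rel)[j])),
                                collapse = "|"))
    }
  }
  sort(edges)
}

edge_keys <- function(net) {
  ed <- igraph::as_data_frame(net$graph, what = "edges")
  if (nrow(ed) == 0) return(character(0))
  sort(apply(cbind(ed$from, ed$to), 1,
             function(x) paste(sort(x), collapse = "|")))
}

# Labelled Euclidean distance matrix from a point configuration.
as_d <- function(pts) {
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(paste0("S", seq_len(nrow(d))), paste0("S", seq_len(nrow(d))))
  d
}

# Small deterministic study-shaped dataset shared by several tests.
small_dataset <- function(regime = "selection", seed = 7, n_taxa = 40,
                          n_samples = 9, depth = 1000) {
  simulate_dataset(simulation_config(n_taxa = n_taxa, n_samples = n_samples,
                                     depth = depth, regime = regime,
                                     seed = seed))
}
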