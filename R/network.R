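# Thresholded Spearman co-occurrence network on dominant OTUs, and the
# topology metrics used to describe it (average degree, path length,
# diameter, clustering, modularity).

#' Network configuration
#'
#' @param top_n number of dominant OTUs retained (study default 100).
#' @param rho_min Spearman coefficient threshold (default 0.6; edges
#'   require `rho > rho_min`).
#' @param p_max two-sided significance threshold (default 0.01); the
#'   rho and p conditions are conjunctive.
#' @param absolute admit negative correlations via `|rho| > rho_min`
#'   (off by default: the literal rule keeps positive correlations only).
#' @param adjust_p apply Benjamini-Hochberg correction to the pairwise
#'   p-values before thresholding (off by default; the study states
#'   uncorrected thresholds).
#' @param module_seed seed for module detection.
#' @return A list of class `"network_config"`.
#' @export
network_config <- function(top_n = 100, rho_min = 0.6, p_max = 0.01,
                           absolute = FALSE, adjust_p = FALSE,
                           module_seed = 1) {
  if (rho_min <= 0 || rho_min >= 1) stop_invalid("rho_min must be in (0, 1)")
  if (p_max <= 0 || p_max >= 1) stop_invalid("p_max must be in (0, 1)")
  structure(list(top_n = as.integer(top_n), rho_min = rho_min, p_max = p_max,
                 absolute = isTRUE(absolute), adjust_p = isTRUE(adjust_p),
                 module_seed = as.integer(module_seed)),
            class = "network_config")
}

#' Select the most abundant OTUs
#'
#' Ranks OTUs by the sum over samples of their per-sample relative
#' abundance, descending; ties are broken by lexicographic OTU id so
#' the selection is deterministic.
#'
#' @param comm samples x OTUs count matrix.
#' @param top_n number of OTUs to keep (<= total OTUs).
#' @return The community table restricted to the selected columns, in
#'   rank order.
#' @export
select_top_otus <- function(comm, top_n = 100) {
  if (top_n <= 0) stop_invalid("top_n must be > 0")
  if (top_n > ncol(comm)) stop_invalid("top_n exceeds the number of OTUs")
  score <- colSums(relative_abundance(comm))
  ord <- order(-score, colnames(comm))
  keep <- colnames(comm)[ord[seq_len(top_n)]]
  out <- comm[, keep, drop = FALSE]
  if (!is.null(attr(comm, "taxonomy")))
    attr(out, "taxonomy") <- attr(comm, "taxonomy")[keep]
  out
}

# Two-sided p for Spearman rho via the t approximation.
spearman_p <- function(rho, n) {
  t <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  2 * pt(-abs(t), df = n - 2)
}

#' Build a Spearman co-occurrence network
#'
#' Pairwise Spearman correlations (midrank ties) of OTU relative
#' abundances across samples; two-sided p-values from the t
#' approximation; an edge is kept when `rho > rho_min` and `p < p_max`
#' (or `|rho| > rho_min` with `absolute = TRUE`).  Isolated nodes stay
#' in the node set.  Pairs involving a constant OTU vector have
#' undefined rho and are skipped (tallied in `skipped_pairs`).
#'
#' @param comm samples x OTUs count matrix (typically after
#'   [select_top_otus()]); needs >= 4 samples.
#' @param config a [network_config()].
#' @param taxonomy optional named OTU -> phylum vector for node colours.
#' @return List of class `"cooccurrence_network"`: `graph` (igraph with
#'   node attributes `abundance`, `phylum`, `module` and edge
#'   attributes `rho`, `p`), `config`, `skipped_pairs`.
#' @export
build_network <- function(comm, config = network_config(),
                          taxonomy = attr(comm, "taxonomy")) {
  if (nrow(comm) < 4) stop_invalid("need >= 4 samples for Spearman p-values")
  rel <- relative_abundance(comm)
  n <- nrow(rel)
  rho <- suppressWarnings(cor(rel, method = "spearman"))
  p <- spearman_p(rho, n)
  ut <- upper.tri(rho)
  if (config$adjust_p) p[ut] <- p.adjust(p[ut], method = "BH")
  keep_rho <- if (config$absolute) abs(rho) > config$rho_min
              else rho > config$rho_min
  skipped <- sum(is.na(rho[ut]))
  sel <- ut & !is.na(rho) & keep_rho & p < config$p_max
  idx <- which(sel, arr.ind = TRUE)
  otus <- colnames(rel)
  edges <- data.frame(from = otus[idx[, 1]], to = otus[idx[, 2]],
                      rho = rho[sel], p = p[sel], stringsAsFactors = FALSE)
  phylum <- if (is.null(taxonomy)) rep(NA_character_, length(otus))
            else unname(taxonomy[otus])
  nodes <- data.frame(name = otus, abundance = colMeans(rel), phylum = phylum,
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
  memb <- detect_modules(g, config$module_seed)
  igraph::V(g)$module <- memb
  structure(list(graph = g, config = config, skipped_pairs = skipped),
            class = "cooccurrence_network")
}

# Greedy modularity maximization; singleton components keep their own
# module ids. Seeded for reproducibility even though the greedy
# agglomeration is deterministic.
detect_modules <- function(g, seed = 1) {
  if (igraph::vcount(g) == 0) return(integer(0))
  with_seed(seed, {
    cl <- igraph::cluster_fast_greedy(igraph::simplify(g))
    as.integer(igraph::membership(cl))
  })
}

#' Topology metrics of a co-occurrence network
#'
#' Average degree `2E / V`; average path length over connected node
#' pairs only; diameter within the largest connected component; mean
#' local clustering coefficient with nodes of degree < 2 contributing
#' 0; modules by greedy modularity maximization (fixed seed) and the
#' Newman Q of that partition.
#'
#' @param net a `cooccurrence_network` or an igraph graph.
#' @param module_seed seed for module detection.
#' @return A one-row data frame of class `"network_metrics"`:
#'   `n_nodes`, `n_edges`, `avg_degree`, `apl`, `diameter`,
#'   `clustering`, `modularity`, `n_modules`.
#' @export
network_metrics <- function(net, module_seed = 1) {
  g <- if (inherits(net, "cooccurrence_network")) net$graph else net
  V <- igraph::vcount(g); E <- igraph::ecount(g)
  if (V == 0) {
    warning("empty graph: returning zeroed metrics")
    out <- data.frame(n_nodes = 0L, n_edges = 0L, avg_degree = 0, apl = 0,
                      diameter = 0, clustering = 0, modularity = 0,
                      n_modules = 0L)
    class(out) <- c("network_metrics", "data.frame")
    return(out)
  }
  avg_degree <- 2 * E / V
  if (E == 0) {
    apl <- 0; diam <- 0
  } else {
    apl <- igraph::mean_distance(g, directed = FALSE, unconnected = TRUE)
    comp <- igraph::components(g)
    big <- igraph::induced_subgraph(g, which(comp$membership ==
                                             which.max(comp$csize)))
    diam <- igraph::diameter(big, directed = FALSE, weights = NA)
  }
  local_cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  clustering <- mean(local_cc)
  memb <- if (inherits(net, "cooccurrence_network") &&
              !is.null(igraph::V(g)$module)) igraph::V(g)$module
          else detect_modules(g, module_seed)
  mod <- if (E == 0) 0 else igraph::modularity(g, memb)
  out <- data.frame(n_nodes = as.integer(V), n_edges = as.integer(E),
                    avg_degree = avg_degree, apl = apl, diameter = diam,
                    clustering = clustering, modularity = mod,
                    n_modules = length(unique(memb)))
  class(out) <- c("network_metrics", "data.frame")
  out
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  g <- x$graph
  cat(sprintf("Co-occurrence network: %d nodes, %d edges", igraph::vcount(g),
              igraph::ecount(g)))
  if (!is.null(x$config))
    cat(sprintf(" (rho > %.2f, p < %.2g)", x$config$rho_min, x$config$p_max))
  cat("\n")
  if (!is.na(x$skipped_pairs) && x$skipped_pairs > 0)
    cat(sprintf("  %d pair(s) skipped (constant OTU vectors)\n",
                x$skipped_pairs))
  invisible(x)
}
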