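# End-to-end pipeline: load or simulate -> rarefy -> diversity ->
# ordination + clustering -> ANOSIM/Mantel -> spatial eigenfunctions ->
# constrained ordination + variation partitioning -> assembly null
# models -> co-occurrence network -> nitrogen profile. Every stage seed
# derives deterministically from one master seed.

#' Pipeline configuration
#'
#' Either `simulate` (a [simulation_config()]) or `paths` (named list
#' with `community`, `tree`, `env`, `coords`, optionally `ko`) must be
#' given.
#'
#' @param simulate optional [simulation_config()] for a self-contained
#'   synthetic run.
#' @param paths optional named list of input file paths.
#' @param rarefaction_depth reads per sample for rarefaction (study
#'   default 3581).
#' @param null_model a [null_model_config()].
#' @param network a [network_config()].
#' @param env_vars environmental predictor columns used in constrained
#'   ordination and variation partitioning.
#' @param max_pcnm cap on the number of (broadest-scale) PCNM vectors
#'   used as spatial predictors, keeping the joint model estimable on
#'   small designs.
#' @param n_perm permutations for ANOSIM/Mantel/ordination tests.
#' @param nmds_starts random starts for NMDS.
#' @param out_dir output directory (created if missing).
#' @param seed master seed; per-stage seeds derive from it via
#'   [derive_seed()].
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(simulate = NULL, paths = NULL,
                            rarefaction_depth = 3581,
                            null_model = null_model_config(),
                            network = network_config(),
                            env_vars = c("salinity", "NO2_N", "NH4_N",
                                         "Fe3", "TOC", "MC"),
                            max_pcnm = 5, n_perm = 999, nmds_starts = 20,
                            out_dir = tempfile("sedcomm_run_"), seed = 1) {
  if (is.null(simulate) && is.null(paths))
    stop_invalid("either 'simulate' or 'paths' must be provided")
  if (!is.null(paths)) {
    need <- c("community", "env", "coords")
    miss <- setdiff(need, names(paths))
    if (length(miss))
      stop_invalid("paths missing: ", paste(miss, collapse = ", "))
    gone <- unlist(paths)[!file.exists(unlist(paths))]
    if (length(gone))
      stop_invalid("input file(s) not found: ", paste(gone, collapse = ", "))
    if (is.null(paths$tree))
      stop_invalid("assembly analysis requires a tree path")
  }
  structure(list(simulate = simulate, paths = paths,
                 rarefaction_depth = as.integer(rarefaction_depth),
                 null_model = null_model, network = network,
                 env_vars = env_vars, max_pcnm = as.integer(max_pcnm),
                 n_perm = as.integer(n_perm),
                 nmds_starts = as.integer(nmds_starts),
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

write_tsv <- function(df, dir, name) {
  path <- file.path(dir, name)
  write.table(format(df, digits = 12, trim = TRUE, scientific = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes every stage in the study's analysis order, writes
#' per-stage TSV outputs plus a JSON report to the configured output
#' directory, and returns the report invisibly as a list.  Identical
#' config and seed reproduce all numeric outputs exactly.
#'
#' @param config a [pipeline_config()].
#' @return List of class `"pipeline_report"` (also written as
#'   `report.json`).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config"))
    stop_invalid("config must be a pipeline_config")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- character(0)
  seeds <- list()
  stage_seed <- function(stage) {
    s <- derive_seed(config$seed, stage)
    seeds[[stage]] <<- s
    s
  }

  # -- load or simulate ------------------------------------------------
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    sim$seed <- config$seed
    ds <- simulate_dataset(sim)
    comm <- ds$community; tree <- ds$tree
    env <- ds$env; coords <- ds$coords; ko <- ds$ko
  } else {
    comm <- load_community_table(config$paths$community)
    tree <- load_tree(config$paths$tree)
    md <- load_sample_metadata(config$paths$env, config$paths$coords)
    env <- md$env; coords <- md$coords
    ko <- if (!is.null(config$paths$ko)) load_ko_table(config$paths$ko)
          else NULL
    al <- align_samples(comm, env, coords)
    comm <- al$comm; env <- al$env; coords <- al$coords
  }
  groups <- setNames(env$group, env$sample)
  manifest <- c(manifest, write_community_table(comm, file.path(config$out_dir,
                                                                "community.tsv")))
  manifest <- c(manifest, write_tree(tree, file.path(config$out_dir, "tree.nwk")))

  # -- rarefaction + diversity -----------------------------------------
  depth <- min(config$rarefaction_depth, min(rowSums(comm)))
  rare <- rarefy_table(comm, depth, seed = stage_seed("rarefy"))
  groups <- groups[rownames(rare)]
  env <- env[match(rownames(rare), env$sample), , drop = FALSE]
  coords <- coords[match(rownames(rare), coords$sample), , drop = FALSE]
  alpha <- alpha_diversity_table(rare)
  bc <- bray_curtis(rare)
  manifest <- c(manifest, write_tsv(alpha, config$out_dir, "alpha_diversity.tsv"))
  manifest <- c(manifest, write_distance_matrix(bc, file.path(config$out_dir,
                                                              "bray_curtis.tsv")))

  # -- ordination + clustering -----------------------------------------
  ord_pcoa <- pcoa(bc, k = 2)
  ord_nmds <- nmds(bc, k = 2, n_starts = config$nmds_starts,
                   seed = stage_seed("nmds"))
  dendro <- upgma_dendrogram(bc)
  manifest <- c(manifest,
                write_tsv(data.frame(sample = rownames(ord_pcoa$points),
                                     ord_pcoa$points), config$out_dir, "pcoa.tsv"),
                write_tsv(data.frame(sample = rownames(ord_nmds$points),
                                     ord_nmds$points), config$out_dir, "nmds.tsv"),
                write_tree(dendro, file.path(config$out_dir, "upgma.nwk")))

  # -- group and matrix tests ------------------------------------------
  env_num <- env[, intersect(config$env_vars, names(env)), drop = FALSE]
  env_dist <- as_distmat(dist(scale(as.matrix(env_num))),
                         ids = rownames(rare))
  anosim_res <- anosim_test(bc, groups, n_perm = config$n_perm,
                            seed = stage_seed("anosim"))
  mantel_res <- mantel_test(bc, env_dist, n_perm = config$n_perm,
                            seed = stage_seed("mantel"))

  # -- space: geographic distances + PCNM ------------------------------
  geo <- geo_distances(coords)
  pb <- pcnm_basis(geo)
  # Keep the joint env + space model estimable: n - p - 1 must stay > 0.
  n_space <- min(config$max_pcnm, ncol(pb$vectors),
                 nrow(rare) - ncol(env_num) - 2)
  if (n_space < 1)
    stop_invalid("too few samples for the configured predictor blocks")
  space <- pb$vectors[, seq_len(n_space), drop = FALSE]
  manifest <- c(manifest,
                write_distance_matrix(geo, file.path(config$out_dir, "geo_km.tsv")),
                write_tsv(data.frame(sample = rownames(space), space),
                          config$out_dir, "pcnm.tsv"))

  # -- constrained ordination + VPA ------------------------------------
  cca_res <- constrained_ordination(rare, cbind(env_num, space), mode = "cca",
                                    n_perm = config$n_perm,
                                    seed = stage_seed("cca"))
  vpa <- variation_partitioning(rare, env_num, space)

  # -- assembly null models --------------------------------------------
  nm <- config$null_model
  nm$seed <- stage_seed("assembly")
  bnti <- beta_nti(rare, tree, nm)
  rc <- raup_crick_bray(rare, nm)
  part <- classify_assembly(bnti, rc, nm, groups = groups)
  manifest <- c(manifest,
                write_tsv(part$pairs, config$out_dir, "assembly_pairs.tsv"),
                write_tsv(part$partition, config$out_dir, "assembly_partition.tsv"))

  # -- co-occurrence network -------------------------------------------
  nc <- config$network
  nc$module_seed <- stage_seed("network")
  top <- select_top_otus(rare, min(nc$top_n, ncol(rare)))
  net <- build_network(top, nc)
  metrics <- network_metrics(net)
  manifest <- c(manifest, {
    export_network(net, file.path(config$out_dir, "network"), format = "tsv")
    file.path(config$out_dir, c("network.nodes.tsv", "network.edges.tsv"))
  })
  manifest <- c(manifest, write_tsv(metrics, config$out_dir,
                                    "network_metrics.tsv"))

  # -- nitrogen profile -------------------------------------------------
  nitrogen <- NULL
  if (!is.null(ko)) {
    rpkm <- rpkm_normalize(ko)
    prof <- aggregate_nitrogen_pathways(rpkm, groups = groups)
    kw <- kruskal_wallis_groups(prof, groups = groups, level = "family")
    manifest <- c(manifest,
                  write_tsv(data.frame(sample = rownames(prof$families),
                                       prof$families, check.names = FALSE),
                            config$out_dir, "nitrogen_families.tsv"),
                  write_tsv(kw, config$out_dir, "nitrogen_kw.tsv"))
    nitrogen <- list(families = colnames(prof$families),
                     n_significant = sum(kw$p < 0.05),
                     kw = kw)
  }

  report <- structure(list(
    version = as.character(utils::packageVersion("sedcomm")),
    seed = config$seed, stage_seeds = seeds,
    rarefaction_depth = depth,
    n_samples = nrow(rare), n_otus = ncol(rare),
    alpha = alpha,
    anosim = anosim_res, mantel = mantel_res,
    pcoa_prop_axis12 = sum(ord_pcoa$proportion[1:2]),
    nmds_stress = ord_nmds$stress,
    cca_cum_axis12_pct = cca_res$cum_axis12_pct,
    cca_term_p = as.list(cca_res$term_p),
    vpa = vpa[c("pure_env", "shared", "pure_space", "unexplained",
                "total_explained")],
    assembly = list(partition = part$partition, n_excluded = part$n_excluded),
    network = as.list(metrics),
    nitrogen = nitrogen,
    manifest = basename(manifest)), class = "pipeline_report")
  jsonlite::write_json(report[setdiff(names(report), c("alpha"))],
                       file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       pretty = TRUE)
  invisible(report)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("sedcomm pipeline report (seed ", x$seed, ")\n", sep = "")
  cat(sprintf("  %d samples x %d OTUs rarefied to %d reads\n", x$n_samples,
              x$n_otus, x$rarefaction_depth))
  cat(sprintf("  ANOSIM R = %.4f (p = %.4g); Mantel r = %.4f (p = %.4g)\n",
              x$anosim$R, x$anosim$p, x$mantel$r, x$mantel$p))
  cat(sprintf("  CCA axes 1-2: %.2f%%; VPA total explained: %.3f\n",
              x$cca_cum_axis12_pct, x$vpa$total_explained))
  cat(sprintf("  network: %d nodes, %d edges, avg degree %.2f, modularity %.3f\n",
              x$network$n_nodes, x$network$n_edges, x$network$avg_degree,
              x$network$modularity))
  cat("  assembly partition:\n")
  print(format(x$assembly$partition, digits = 4), row.names = FALSE)
  invisible(x)
}
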