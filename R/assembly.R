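# Phylogenetic and taxonomic null models partitioning community assembly
# into deterministic and stochastic processes: beta-MNTD, the tip-shuffle
# beta-nearest taxon index (betaNTI), Raup-Crick on Bray-Curtis (RCbray),
# and the five-process classification.

#' Null-model configuration
#'
#' @param n_reps number of randomizations (study default 999).
#' @param seed integer seed.
#' @param abundance_weighted weight nearest-taxon distances by relative
#'   abundance (the cited framework's default).
#' @param bnti_threshold |betaNTI| cut separating deterministic from
#'   stochastic turnover (the -2..2 band; default 2).
#' @param rc_threshold |RCbray| cut separating dispersal processes from
#'   drift (default 0.95).
#' @return A list of class `"null_model_config"`.
#' @export
null_model_config <- function(n_reps = 999, seed = 1, abundance_weighted = TRUE,
                              bnti_threshold = 2, rc_threshold = 0.95) {
  if (n_reps < 1) stop_invalid("n_reps must be >= 1")
  if (bnti_threshold <= 0 || rc_threshold <= 0)
    stop_invalid("thresholds must be > 0")
  structure(list(n_reps = as.integer(n_reps), seed = as.integer(seed),
                 abundance_weighted = isTRUE(abundance_weighted),
                 bnti_threshold = bnti_threshold, rc_threshold = rc_threshold),
            class = "null_model_config")
}

# Patristic distance matrix aligned to the community's OTU columns.
aligned_cophenetic <- function(comm, tree) {
  otus <- colnames(comm)
  missing <- setdiff(otus[colSums(comm) > 0], tree$tip.label)
  if (length(missing))
    stop_alignment("OTUs absent from the tree: ",
                   paste(head(missing), collapse = ", "),
                   if (length(missing) > 6) " ..." else "")
  D <- cophenetic(tree)
  D[otus, otus, drop = FALSE]
}

#' Between-community mean nearest taxon distance (beta-MNTD)
#'
#' For a sample pair (k, m):
#' `0.5 * (sum_i f_ik min_j d_ij + sum_j f_jm min_i d_ij)` where the
#' sums run over taxa present in each sample, `f` are within-sample
#' relative abundances (uniform if unweighted) and `d` is the patristic
#' distance.
#'
#' @param comm samples x OTUs count matrix.
#' @param tree phylogeny containing every OTU with positive counts.
#' @param abundance_weighted logical.
#' @return Square symmetric matrix of beta-MNTD values.
#' @export
beta_mntd <- function(comm, tree, abundance_weighted = TRUE) {
  D <- aligned_cophenetic(comm, tree)
  m <- bmntd_all_cpp(comm, D, abundance_weighted)
  dimnames(m) <- list(rownames(comm), rownames(comm))
  m
}

#' Beta-nearest taxon index (betaNTI)
#'
#' Null beta-MNTD distributions are generated by shuffling tip labels
#' across the whole tree (taxa shuffle) and recomputing beta-MNTD for
#' every pair, `n_reps` times; betaNTI is the per-pair z-score
#' `(observed - null mean) / null sd`.  Pairs with zero null standard
#' deviation are flagged `NA` (undefined) and excluded from downstream
#' partitions.
#'
#' @param comm samples x OTUs count matrix (conventionally rarefied).
#' @param tree phylogeny.
#' @param config a [null_model_config()].
#' @return List of class `"beta_nti"`: matrices `bnti`, `bmntd_obs`,
#'   `null_mean`, `null_sd`, plus `n_reps` and `n_undefined`.
#' @export
beta_nti <- function(comm, tree, config = null_model_config()) {
  if (nrow(comm) < 2) stop_invalid("need >= 2 samples")
  D <- aligned_cophenetic(comm, tree)
  obs <- bmntd_all_cpp(comm, D, config$abundance_weighted)
  nt <- ncol(D)
  sum1 <- matrix(0, nrow(comm), nrow(comm))
  sum2 <- matrix(0, nrow(comm), nrow(comm))
  with_seed(config$seed, {
    for (r in seq_len(config$n_reps)) {
      p <- sample.int(nt)
      null <- bmntd_all_cpp(comm, D[p, p], config$abundance_weighted)
      sum1 <- sum1 + null
      sum2 <- sum2 + null^2
    }
  })
  null_mean <- sum1 / config$n_reps
  null_var <- pmax(sum2 / config$n_reps - null_mean^2, 0) *
    config$n_reps / max(config$n_reps - 1, 1)
  null_sd <- sqrt(null_var)
  bnti <- (obs - null_mean) / null_sd
  bnti[null_sd == 0] <- NA_real_
  diag(bnti) <- NA_real_
  ids <- rownames(comm)
  dimnames(obs) <- dimnames(null_mean) <- dimnames(null_sd) <-
    dimnames(bnti) <- list(ids, ids)
  structure(list(bnti = bnti, bmntd_obs = obs, null_mean = null_mean,
                 null_sd = null_sd, n_reps = config$n_reps,
                 n_undefined = sum(is.na(bnti[upper.tri(bnti)]))),
            class = "beta_nti")
}

#' Raup-Crick metric on Bray-Curtis (RCbray)
#'
#' For each sample pair, `n_reps` null community pairs are assembled
#' preserving each sample's observed richness and read total: taxa are
#' drawn without replacement with probability proportional to occupancy
#' (number of samples containing the taxon), each drawn taxon is seeded
#' with one read, and the remaining reads are allotted multinomially
#' with probability proportional to metacommunity relative abundance.
#' `RCbray = 2 * [#(null BC < obs) + 0.5 #(null BC = obs)] / n_reps - 1`,
#' bounded in `[-1, 1]` with granularity `1 / n_reps`.
#'
#' @param comm samples x OTUs count matrix.
#' @param config a [null_model_config()].
#' @return Square symmetric matrix of RCbray values (diagonal `NA`).
#' @export
raup_crick_bray <- function(comm, config = null_model_config()) {
  check_community(comm)
  if (nrow(comm) < 2) stop_invalid("need >= 2 samples")
  nt <- ncol(comm)
  occ <- colSums(comm > 0)
  meta <- colSums(comm) / sum(comm)
  rich <- rowSums(comm > 0)
  depth <- rowSums(comm)
  if (any(rich > sum(occ > 0)))
    stop_invalid("sample richness exceeds the occupied taxon pool")
  obs_bc <- as.matrix(vegan::vegdist(comm, method = "bray"))
  S <- nrow(comm)
  rc <- matrix(NA_real_, S, S, dimnames = list(rownames(comm), rownames(comm)))
  draw_null <- function(n_taxa, n_reads) {
    taxa <- sample.int(nt, n_taxa, prob = occ)
    x <- numeric(nt)
    x[taxa] <- 1
    if (n_reads > n_taxa)
      x[taxa] <- x[taxa] + rmultinom(1, n_reads - n_taxa, meta[taxa])[, 1]
    x
  }
  with_seed(config$seed, {
    for (k in seq_len(S - 1)) {
      for (m in (k + 1):S) {
        obs <- obs_bc[k, m]
        less <- 0; equal <- 0
        for (r in seq_len(config$n_reps)) {
          xa <- draw_null(rich[k], depth[k])
          xb <- draw_null(rich[m], depth[m])
          bc <- sum(abs(xa - xb)) / (depth[k] + depth[m])
          if (abs(bc - obs) <= 1e-12) equal <- equal + 1
          else if (bc < obs) less <- less + 1
        }
        rc[k, m] <- rc[m, k] <- 2 * (less + 0.5 * equal) / config$n_reps - 1
      }
    }
  })
  rc
}

#' Classify sample pairs into assembly processes
#'
#' Applies the framework's decision rule: `betaNTI > +t` heterogeneous
#' selection, `betaNTI < -t` homogeneous selection (deterministic);
#' among the remaining (stochastic) pairs, `RC > +u` dispersal
#' limitation, `RC < -u` homogenizing dispersal, else drift
#' (`t`, `u` from the config, defaults 2 and 0.95).  Partitions are
#' computed over within-group pairs for each group plus all pairs
#' (total); pairs with undefined betaNTI are excluded and tallied.
#'
#' @param bnti betaNTI matrix (or a `"beta_nti"` object).
#' @param rc RCbray matrix.
#' @param config a [null_model_config()].
#' @param groups optional factor of per-sample group labels, named by or
#'   ordered as the matrix ids.
#' @return List of class `"assembly_partition"`: `pairs` (long data
#'   frame with betaNTI, RC and process per pair), `partition` (one row
#'   per group and total with percent deterministic and the stochastic
#'   sub-fractions), `n_excluded`.
#' @export
classify_assembly <- function(bnti, rc, config = null_model_config(),
                              groups = NULL) {
  if (inherits(bnti, "beta_nti")) bnti <- bnti$bnti
  if (!identical(dim(bnti), dim(rc)))
    stop_invalid("betaNTI and RC matrices must share dimensions")
  ids <- rownames(bnti)
  S <- nrow(bnti)
  idx <- which(upper.tri(bnti), arr.ind = TRUE)
  b <- bnti[upper.tri(bnti)]
  r <- rc[upper.tri(rc)]
  t_b <- config$bnti_threshold; t_r <- config$rc_threshold
  process <- ifelse(is.na(b), NA_character_,
             ifelse(b > t_b, "heterogeneous_selection",
             ifelse(b < -t_b, "homogeneous_selection",
             ifelse(r > t_r, "dispersal_limitation",
             ifelse(r < -t_r, "homogenizing_dispersal", "drift")))))
  pairs <- data.frame(sample_i = ids[idx[, 1]], sample_j = ids[idx[, 2]],
                      bnti = b, rc = r, process = process,
                      stringsAsFactors = FALSE)
  if (!is.null(groups)) {
    if (!is.null(names(groups))) groups <- groups[ids]
    gi <- as.character(groups[idx[, 1]])
    gj <- as.character(groups[idx[, 2]])
    pairs$group <- ifelse(gi == gj, gi, NA_character_)
  }
  partition_of <- function(sub, label) {
    sub <- sub[!is.na(sub$process), , drop = FALSE]
    n <- nrow(sub)
    if (n == 0)
      return(data.frame(group = label, n_pairs = 0, pct_deterministic = NA,
                        pct_stochastic = NA, pct_dispersal_limitation = NA,
                        pct_homogenizing_dispersal = NA, pct_drift = NA))
    det <- sub$process %in% c("heterogeneous_selection", "homogeneous_selection")
    sto <- sub[!det, , drop = FALSE]
    ns <- nrow(sto)
    frac <- function(p) if (ns == 0) NA else 100 * mean(sto$process == p)
    data.frame(group = label, n_pairs = n,
               pct_deterministic = 100 * mean(det),
               pct_stochastic = 100 * mean(!det),
               pct_dispersal_limitation = frac("dispersal_limitation"),
               pct_homogenizing_dispersal = frac("homogenizing_dispersal"),
               pct_drift = frac("drift"))
  }
  parts <- list()
  if (!is.null(groups)) {
    for (g in levels(factor(groups)))
      parts[[g]] <- partition_of(pairs[!is.na(pairs$group) & pairs$group == g, ],
                                 g)
  }
  parts$total <- partition_of(pairs, "total")
  structure(list(pairs = pairs, partition = do.call(rbind, parts),
                 n_excluded = sum(is.na(process)), config = config),
            class = "assembly_partition")
}

#' @export
print.assembly_partition <- function(x, ...) {
  cat("Community assembly partition (", nrow(x$pairs), " pairs, ",
      x$n_excluded, " excluded)\n", sep = "")
  print(format(x$partition, digits = 4), row.names = FALSE)
  invisible(x)
}

#' @export
print.beta_nti <- function(x, ...) {
  v <- x$bnti[upper.tri(x$bnti)]
  cat("betaNTI over", length(v), "sample pairs (", x$n_reps, "randomizations )\n")
  cat(sprintf("  range %.3f .. %.3f; %d pair(s) undefined\n",
              min(v, na.rm = TRUE), max(v, na.rm = TRUE), x$n_undefined))
  cat(sprintf("  %.1f%% of pairs deterministic (|betaNTI| > 2)\n",
              100 * mean(abs(v) > 2, na.rm = TRUE)))
  invisible(x)
}
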