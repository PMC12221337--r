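# Rarefaction, alpha-diversity estimators and Bray-Curtis dissimilarity.

#' Rarefy a community table to even depth
#'
#' Subsamples each sample's reads without replacement to exactly `depth`
#' reads (one draw, no averaging).  Samples with fewer reads than
#' `depth` are dropped with a warning.  Deterministic given `seed`.
#'
#' @param comm samples x OTUs count matrix.
#' @param depth target reads per sample (e.g. 3581, the study's
#'   minimum-sample normalization depth).
#' @param seed integer seed.
#' @return Rarefied count matrix; every retained row sums to `depth`.
#' @export
rarefy_table <- function(comm, depth, seed = 1) {
  check_community(comm)
  if (depth <= 0) stop_invalid("depth must be > 0")
  totals <- rowSums(comm)
  keep <- totals >= depth
  if (!all(keep))
    warning(sum(!keep), " sample(s) below depth ", depth, " dropped: ",
            paste(rownames(comm)[!keep], collapse = ", "))
  comm <- comm[keep, , drop = FALSE]
  with_seed(seed, {
    out <- t(apply(comm, 1, function(x) {
      if (sum(x) == depth) return(as.integer(x))
      reads <- sample(rep.int(seq_along(x), x), depth)
      tabulate(reads, nbins = length(x))
    }))
    dimnames(out) <- dimnames(comm)
    storage.mode(out) <- "integer"
    out
  })
}

#' Alpha-diversity estimators for one sample
#'
#' Computes the classical index set: observed richness (Sobs), Shannon
#' entropy in nats, Simpson dominance (sum of squared proportions),
#' Chao1 (classic form, `Sobs + F1^2 / (2 F2)`, falling back to
#' `F1 (F1 - 1) / 2` when there are no doubletons), ACE with the
#' standard rare/abundant split at 10 reads and coefficient-of-variation
#' term, and Good's coverage `1 - F1 / N`.
#'
#' @param counts non-negative integer count vector for one sample.
#' @return A one-row data frame: `sobs`, `shannon`, `simpson`, `chao1`,
#'   `ace`, `coverage`.
#' @export
alpha_diversity <- function(counts) {
  counts <- counts[counts > 0]
  if (length(counts) == 0) stop_invalid("all-zero count vector")
  if (any(counts != round(counts))) stop_invalid("counts must be integers")
  n <- sum(counts)
  p <- counts / n
  sobs <- length(counts)
  shannon <- -sum(p * log(p))
  simpson <- sum(p^2)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  chao1 <- if (f2 > 0) sobs + f1^2 / (2 * f2) else sobs + f1 * (f1 - 1) / 2
  # ACE: rare species are those with <= 10 reads.
  rare <- counts[counts <= 10]
  abund <- counts[counts > 10]
  s_rare <- length(rare); s_abund <- length(abund)
  n_rare <- sum(rare)
  if (s_rare == 0) {
    ace <- sobs
  } else if (n_rare == f1) {
    # All rare reads are singletons: ACE sample coverage is 0; fall back
    # to Chao1 as is conventional.
    ace <- chao1
  } else {
    c_ace <- 1 - f1 / n_rare
    fi <- tabulate(rare, nbins = 10)
    g2 <- max(s_rare / c_ace * sum(seq_len(10) * (seq_len(10) - 1) * fi) /
                (n_rare * (n_rare - 1)) - 1, 0)
    ace <- s_abund + s_rare / c_ace + f1 / c_ace * g2
  }
  coverage <- 1 - f1 / n
  data.frame(sobs = sobs, shannon = shannon, simpson = simpson,
             chao1 = chao1, ace = ace, coverage = coverage)
}

#' Alpha-diversity table for all samples
#'
#' @param comm samples x OTUs count matrix.
#' @return Data frame with one row per sample and a `sample` column.
#' @export
alpha_diversity_table <- function(comm) {
  check_community(comm)
  res <- do.call(rbind, lapply(rownames(comm),
                               function(s) alpha_diversity(comm[s, ])))
  cbind(data.frame(sample = rownames(comm), stringsAsFactors = FALSE), res)
}

#' Bray-Curtis dissimilarity between samples
#'
#' `d(k, m) = sum |x_k - x_m| / sum (x_k + x_m)`, in `[0, 1]`.
#'
#' @param comm samples x OTUs matrix (counts or relative abundances).
#' @return Square symmetric distance matrix with sample ids.
#' @export
bray_curtis <- function(comm) {
  if (nrow(comm) < 2) stop_invalid("need >= 2 samples")
  if (any(rowSums(comm) == 0)) stop_invalid("zero-sum sample in table")
  as_distmat(vegan::vegdist(comm, method = "bray"), ids = rownames(comm))
}

#' Relative abundances
#'
#' @param comm samples x OTUs count matrix.
#' @return Matrix of per-sample proportions; every row sums to 1.
#' @export
relative_abundance <- function(comm) {
  rs <- rowSums(comm)
  if (any(rs == 0)) stop_invalid("zero-sum sample in table")
  comm / rs
}
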