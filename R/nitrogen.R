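# Nitrogen-cycle functional profiling: RPKM normalization of KO read
# counts, aggregation into gene families and pathway modules, and
# group comparison by Kruskal-Wallis.

#' Load a KO -> gene family -> pathway module map
#'
#' TSV with columns `ko`, `family`, `module`.  Each KO must map to
#' exactly one family, and each family to exactly one module.  Without
#' a path, the packaged representative nitrogen-cycle map is used; it
#' covers denitrification (narG/H, napA/B, nirS/K, norB/C, nosZ),
#' dissimilatory and assimilatory nitrate reduction, nitrification
#' (amoA/B/C-pmoA/B/C, hao), nitrogen fixation (nifD/H/K) and anammox
#' (hzsA/B/C, hdh) with representative K numbers, and can be overridden
#' by any file in the same layout.
#'
#' @param path optional TSV path.
#' @return Data frame of class `"pathway_map"`.
#' @export
load_pathway_map <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "nitrogen_ko_map.tsv", package = "sedcomm")
  map <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("ko", "family", "module") %in% names(map)))
    stop_format("pathway map needs 'ko', 'family', 'module' columns")
  if (anyDuplicated(map$ko))
    stop_format("KO mapped to more than one family: ",
                paste(unique(map$ko[duplicated(map$ko)]), collapse = ", "))
  fam_mod <- unique(map[c("family", "module")])
  if (anyDuplicated(fam_mod$family))
    stop_format("gene family mapped to more than one module")
  class(map) <- c("pathway_map", "data.frame")
  map
}

#' RPKM normalization
#'
#' Reads per kilobase of gene per million mapped reads:
#' `RPKM = reads / (length_kb * total_mapped_millions)`.  Invariant to
#' uniform sequencing-depth rescaling.
#'
#' @param ko a `ko_table` (counts, gene lengths, per-sample totals).
#' @return Numeric matrix, samples x KOs, of RPKM values.
#' @export
rpkm_normalize <- function(ko) {
  if (any(ko$gene_length <= 0)) stop_invalid("gene lengths must be > 0")
  if (any(ko$total_reads <= 0))
    stop_invalid("zero total mapped reads for sample(s): ",
                 paste(names(ko$total_reads)[ko$total_reads <= 0],
                       collapse = ", "))
  len_kb <- ko$gene_length[colnames(ko$counts)] / 1000
  mil <- ko$total_reads / 1e6
  sweep(sweep(ko$counts, 2, len_kb, "/"), 1, mil, "/")
}

#' Aggregate KO abundances into nitrogen gene families and modules
#'
#' Family value = sum of member-KO RPKM; module value = sum of member
#' families.  KOs absent from the map are excluded (tallied).
#'
#' @param rpkm samples x KO RPKM matrix.
#' @param map a `pathway_map` (default: packaged nitrogen map).
#' @param groups optional per-sample group labels.
#' @return List of class `"functional_profile"`: `families`, `modules`
#'   (samples x feature matrices), `groups`, `n_unmapped`.
#' @export
aggregate_nitrogen_pathways <- function(rpkm, map = load_pathway_map(),
                                        groups = NULL) {
  if (nrow(map) == 0) stop_invalid("pathway map is empty")
  mapped <- intersect(colnames(rpkm), map$ko)
  n_unmapped <- ncol(rpkm) - length(mapped)
  if (n_unmapped > 0)
    message(n_unmapped, " KO(s) not in the pathway map; excluded")
  sub <- rpkm[, mapped, drop = FALSE]
  fam_of <- setNames(map$family, map$ko)[mapped]
  fams <- sort(unique(fam_of))
  families <- vapply(fams, function(f)
    rowSums(sub[, fam_of == f, drop = FALSE]), numeric(nrow(sub)))
  if (nrow(sub) == 1) families <- matrix(families, nrow = 1,
                                         dimnames = list(rownames(sub), fams))
  mod_of_fam <- setNames(map$module, map$family)[fams]
  mods <- sort(unique(mod_of_fam))
  modules <- vapply(mods, function(m)
    rowSums(families[, mod_of_fam == m, drop = FALSE]), numeric(nrow(sub)))
  if (nrow(sub) == 1) modules <- matrix(modules, nrow = 1,
                                        dimnames = list(rownames(sub), mods))
  structure(list(families = families, modules = modules, groups = groups,
                 n_unmapped = n_unmapped),
            class = "functional_profile")
}

#' Kruskal-Wallis comparison of features across groups
#'
#' Per-feature Kruskal-Wallis H (midrank tie correction, chi-square
#' approximation with k-1 df) across the sample groups, with a
#' Benjamini-Hochberg column.  Features constant across all samples
#' get `p = 1` and are flagged degenerate.
#'
#' @param profile a `functional_profile`, or a samples x features
#'   matrix.
#' @param groups per-sample labels (needed when `profile` is a matrix
#'   or carries none); >= 2 groups with >= 2 samples each.
#' @param level `"family"` or `"module"` when `profile` is a
#'   `functional_profile`.
#' @return Data frame: `feature`, `H`, `p`, `p_bh`, `degenerate`.
#' @export
kruskal_wallis_groups <- function(profile, groups = NULL,
                                  level = c("family", "module")) {
  if (inherits(profile, "functional_profile")) {
    level <- match.arg(level)
    groups <- groups %||% profile$groups
    mat <- if (level == "family") profile$families else profile$modules
  } else mat <- as.matrix(profile)
  if (is.null(groups)) stop_invalid("group labels are required")
  groups <- factor(groups)
  if (nlevels(groups) < 2 || any(table(groups) < 2))
    stop_invalid("need >= 2 groups with >= 2 samples each")
  res <- lapply(colnames(mat), function(f) {
    x <- mat[, f]
    if (var(x) == 0)
      return(data.frame(feature = f, H = 0, p = 1, degenerate = TRUE))
    kw <- kruskal.test(x, groups)
    data.frame(feature = f, H = unname(kw$statistic), p = kw$p.value,
               degenerate = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_bh <- p.adjust(out$p, method = "BH")
  out[c("feature", "H", "p", "p_bh", "degenerate")]
}

#' @export
print.functional_profile <- function(x, ...) {
  cat(sprintf("Functional profile: %d samples, %d gene families, %d modules",
              nrow(x$families), ncol(x$families), ncol(x$modules)))
  if (x$n_unmapped > 0) cat(sprintf(" (%d unmapped KOs)", x$n_unmapped))
  cat("\n")
  invisible(x)
}
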