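# Readers and writers for the formats the pipeline touches: OTU count
# tables (TSV, OTUs as rows on disk, samples as rows in memory), newick
# trees, sample metadata (CSV), square distance matrices (TSV), KO
# tables (TSV) and co-occurrence networks (GraphML / TSV pair).
# Loaders reject malformed records rather than repairing them.

#' Read an OTU count table
#'
#' File layout follows the sequencing convention: first column `otu`,
#' one column per sample with integer counts, optional final `taxonomy`
#' column.  In memory the table follows the ecology convention: samples
#' as rows, OTUs as columns.  Any taxonomy strings are attached as a
#' named character attribute `"taxonomy"`.
#'
#' @param path TSV file path.
#' @return Integer matrix (samples x OTUs), possibly with a `taxonomy`
#'   attribute.
#' @export
load_community_table <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop_format("community table needs an otu column and >= 1 sample")
  otus <- as.character(df[[1]])
  if (anyDuplicated(otus)) stop_format("duplicate OTU ids in ", path)
  tax <- NULL
  if (tolower(names(df)[ncol(df)]) == "taxonomy") {
    tax <- setNames(as.character(df[[ncol(df)]]), otus)
    df <- df[-ncol(df)]
  }
  samples <- names(df)[-1]
  if (anyDuplicated(samples)) stop_format("duplicate sample ids in ", path)
  m <- matrix(0L, length(samples), length(otus), dimnames = list(samples, otus))
  for (j in seq_along(samples)) {
    col <- df[[j + 1]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) | num < 0 | num != round(num))
    if (length(bad))
      stop_format("invalid count '", col[bad[1]], "' at OTU '", otus[bad[1]],
                  "', sample '", samples[j], "'")
    m[j, ] <- as.integer(num)
  }
  check_community(m)
  if (!is.null(tax)) attr(m, "taxonomy") <- tax
  m
}

#' Write an OTU count table
#'
#' Inverse of [load_community_table()]: OTUs become rows on disk.
#'
#' @param comm samples x OTUs count matrix.
#' @param path output TSV path.
#' @param taxonomy optional named character vector (OTU -> lineage).
#' @export
write_community_table <- function(comm, path, taxonomy = attr(comm, "taxonomy")) {
  check_community(comm, require_integer = FALSE)
  df <- data.frame(otu = colnames(comm), t(comm), check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!is.null(taxonomy)) df$taxonomy <- unname(taxonomy[colnames(comm)])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a rooted phylogeny with branch lengths
#'
#' Zero-length terminal branches are replaced by a small epsilon (with a
#' warning) so that nearest-taxon distances stay positive; trees without
#' branch lengths are rejected.
#'
#' @param path newick file path.
#' @param epsilon replacement for zero-length terminal branches.
#' @return An [ape::phylo] object.
#' @export
load_tree <- function(path, epsilon = 1e-8) {
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop_format("unparseable newick: ",
                                                   conditionMessage(e)))
  if (is.null(tree)) stop_format("unparseable newick file: ", path)
  if (is.null(tree$edge.length)) stop_format("tree has no branch lengths: ", path)
  term <- tree$edge[, 2] <= length(tree$tip.label)
  zero_term <- term & tree$edge.length == 0
  if (any(zero_term)) {
    warning(sum(zero_term), " zero-length terminal branch(es) replaced by ",
            epsilon)
    tree$edge.length[zero_term] <- epsilon
  }
  tree
}

#' Write a phylogeny to newick
#'
#' @param tree an [ape::phylo] object.
#' @param path output path.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

#' Read sample metadata and coordinates
#'
#' Both files are CSV with a header and a sample id column named
#' `sample`.  Environmental variables are coerced to numbers; a missing
#' `group` column is derived from salinity cut-points (defaults 1.0 and
#' 30.0 ppt, the low/mid and mid/high boundaries of the study design).
#' Coordinates must be decimal degrees within range.
#'
#' @param env_path CSV with sediment variables (must include `salinity`).
#' @param coords_path CSV with `lat` and `lon` columns.
#' @param cuts numeric length-2 salinity cut-points for group labels.
#' @return A list with data frames `env` and `coords`.
#' @export
load_sample_metadata <- function(env_path, coords_path, cuts = c(1.0, 30.0)) {
  env <- utils::read.csv(env_path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample" %in% names(env)) stop_format("env file needs a 'sample' column")
  if (anyDuplicated(env$sample)) stop_format("duplicate sample ids in ", env_path)
  has_group <- "group" %in% names(env)
  for (nm in setdiff(names(env), c("sample", "group"))) {
    num <- suppressWarnings(as.numeric(env[[nm]]))
    bad <- which(is.na(num) & !is.na(env[[nm]]))
    if (length(bad))
      stop_format("non-numeric value '", env[[nm]][bad[1]], "' in column '",
                  nm, "', sample '", env$sample[bad[1]], "'")
    env[[nm]] <- num
  }
  if ("MC" %in% names(env) && any(env$MC < 0 | env$MC > 100, na.rm = TRUE))
    stop_format("MC (moisture content, %) must lie in [0, 100]")
  if (!has_group) {
    if (!"salinity" %in% names(env))
      stop_format("env file needs 'salinity' to derive group labels")
    env$group <- salinity_groups(env$salinity, cuts = cuts)
  } else {
    env$group <- factor(env$group, levels = c("low", "mid", "high"))
  }
  coords <- utils::read.csv(coords_path, check.names = FALSE,
                            stringsAsFactors = FALSE)
  if (!all(c("sample", "lat", "lon") %in% names(coords)))
    stop_format("coords file needs 'sample', 'lat', 'lon' columns")
  coords$lat <- suppressWarnings(as.numeric(coords$lat))
  coords$lon <- suppressWarnings(as.numeric(coords$lon))
  if (any(is.na(coords$lat)) || any(abs(coords$lat) > 90))
    stop_format("latitudes must be numeric within [-90, 90]")
  if (any(is.na(coords$lon)) || any(abs(coords$lon) > 180))
    stop_format("longitudes must be numeric within [-180, 180]")
  list(env = env, coords = coords)
}

#' Align community, environment and coordinates by sample id
#'
#' Intersects sample ids and returns all three objects in one shared
#' ordering (the community table's order restricted to the
#' intersection).  Fewer than 3 shared samples is a hard error.
#'
#' @param comm samples x OTUs matrix.
#' @param env,coords metadata data frames with a `sample` column.
#' @return List with aligned `comm`, `env`, `coords`.
#' @export
align_samples <- function(comm, env, coords) {
  ids <- intersect(rownames(comm), env$sample)
  if (!is.null(coords)) ids <- intersect(ids, coords$sample)
  if (length(ids) < 3)
    stop_alignment("fewer than 3 samples shared across tables (", length(ids), ")")
  list(comm = comm[ids, , drop = FALSE],
       env = env[match(ids, env$sample), , drop = FALSE],
       coords = if (is.null(coords)) NULL
                else coords[match(ids, coords$sample), , drop = FALSE])
}

#' Read / write a square distance matrix as TSV
#'
#' Square layout with ids as both the header row and first column.
#'
#' @param d distance matrix (or `dist`).
#' @param path file path.
#' @return `load_distance_matrix` returns a validated symmetric matrix.
#' @export
write_distance_matrix <- function(d, path) {
  m <- as_distmat(d)
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
load_distance_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[-1])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  as_distmat(m)
}

#' Read / write a KO read-count table
#'
#' TSV with columns `ko`, `length`, then one column per sample; a final
#' comment-free row is not required.  Total mapped reads per sample are
#' stored in a companion one-row header line `#total_reads` when
#' writing, and read back from it.
#'
#' @param ko a `ko_table` (see [simulate_ko_table()]).
#' @param path file path.
#' @export
write_ko_table <- function(ko, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#total_reads\t\t",
                    paste(ko$total_reads, collapse = "\t")), con)
  df <- data.frame(ko = colnames(ko$counts),
                   length = unname(ko$gene_length[colnames(ko$counts)]),
                   t(ko$counts), check.names = FALSE)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}

#' @rdname write_ko_table
#' @export
load_ko_table <- function(path) {
  first <- readLines(path, n = 1)
  totals <- NULL
  skip <- 0
  if (startsWith(first, "#total_reads")) {
    totals <- as.numeric(strsplit(first, "\t")[[1]][-(1:2)])
    skip <- 1
  }
  df <- read.delim(path, skip = skip, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!all(c("ko", "length") %in% names(df)))
    stop_format("KO table needs 'ko' and 'length' columns")
  lens <- setNames(as.numeric(df$length), df$ko)
  if (any(lens <= 0)) stop_format("gene lengths must be > 0")
  samples <- setdiff(names(df), c("ko", "length"))
  counts <- t(as.matrix(df[samples]))
  colnames(counts) <- df$ko
  storage.mode(counts) <- "integer"
  if (any(counts < 0)) stop_format("negative KO counts")
  if (is.null(totals)) totals <- rowSums(counts)
  names(totals) <- samples
  if (any(totals < rowSums(counts)))
    stop_format("total mapped reads below the KO column sums")
  structure(list(counts = counts, gene_length = lens, total_reads = totals,
                 groups = NULL, affected = NULL), class = "ko_table")
}

#' Export a co-occurrence network
#'
#' GraphML (node attributes: OTU id, mean relative abundance, phylum,
#' module id; edge attribute: Spearman rho) or a node/edge TSV pair
#' (`<path>.nodes.tsv`, `<path>.edges.tsv`).  An empty network produces
#' valid empty files with a warning.
#'
#' @param net a `cooccurrence_network` (see [build_network()]).
#' @param path output path (GraphML file, or TSV basename).
#' @param format `"graphml"` or `"tsv"`.
#' @export
export_network <- function(net, path, format = c("graphml", "tsv")) {
  format <- match.arg(format)
  g <- net$graph
  if (igraph::vcount(g) == 0) warning("exporting an empty network")
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
    return(invisible(path))
  }
  nodes <- data.frame(otu = igraph::V(g)$name,
                      abundance = round(igraph::V(g)$abundance, 6),
                      phylum = igraph::V(g)$phylum,
                      module = igraph::V(g)$module)
  ed <- igraph::as_data_frame(g, what = "edges")
  edges <- data.frame(from = ed$from, to = ed$to,
                      rho = round(ed$rho, 6), p = signif(ed$p, 6))
  write.table(nodes, paste0(path, ".nodes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(edges, paste0(path, ".edges.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname export_network
#' @export
import_network_tsv <- function(path) {
  nodes <- read.delim(paste0(path, ".nodes.tsv"), stringsAsFactors = FALSE,
                      colClasses = c(otu = "character"))
  edges <- read.delim(paste0(path, ".edges.tsv"), stringsAsFactors = FALSE,
                      colClasses = c(from = "character", to = "character"))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes[c("otu", setdiff(names(nodes), "otu"))])
  structure(list(graph = g, config = NULL, skipped_pairs = NA_integer_),
            class = "cooccurrence_network")
}
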