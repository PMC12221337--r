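# Geographic distances and spatial eigenfunctions (PCNM).

# Haversine great-circle distances (km) on a sphere of radius 6371 km.
haversine_matrix <- function(lat, lon, radius = 6371.0) {
  phi <- lat * pi / 180
  lam <- lon * pi / 180
  n <- length(lat)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    j <- (i + 1):n
    a <- sin((phi[j] - phi[i]) / 2)^2 +
      cos(phi[i]) * cos(phi[j]) * sin((lam[j] - lam[i]) / 2)^2
    d[i, j] <- d[j, i] <- 2 * radius * asin(pmin(sqrt(a), 1))
  }
  d
}

#' Great-circle distances between samples
#'
#' Haversine formula on a sphere of radius 6371.0 km.
#'
#' @param coords data frame with `sample`, `lat`, `lon` (decimal
#'   degrees).
#' @return Square symmetric matrix of distances in km.
#' @export
geo_distances <- function(coords) {
  if (any(abs(coords$lat) > 90) || any(abs(coords$lon) > 180))
    stop_invalid("coordinates out of range")
  d <- haversine_matrix(coords$lat, coords$lon)
  dimnames(d) <- list(coords$sample, coords$sample)
  d
}

#' Spatial eigenfunctions (PCNM)
#'
#' Principal coordinates of neighbour matrices: the geographic distance
#' matrix is truncated at the longest edge of its minimum spanning tree
#' (distances beyond the threshold replaced by four times the
#' threshold), then subjected to principal coordinates analysis;
#' eigenvectors with eigenvalues above `1e-8` times the largest are
#' retained as multiscale spatial predictors.
#'
#' @param geo square geographic distance matrix (km).
#' @param threshold optional truncation distance; defaults to the
#'   longest minimum-spanning-tree edge.
#' @return List of class `"pcnm_basis"`: `vectors` (samples x m, columns
#'   `PCNM1..m`), `values` (eigenvalues), `threshold`.
#' @export
pcnm_basis <- function(geo, threshold = NULL) {
  geo <- as_distmat(geo)
  if (nrow(geo) < 3) stop_invalid("need >= 3 sites")
  if (max(geo) == 0) stop_invalid("all sites coincident")
  d <- stats::as.dist(geo)
  res <- if (is.null(threshold)) vegan::pcnm(d) else vegan::pcnm(d, threshold = threshold)
  vec <- as.matrix(res$vectors)
  vals <- res$values[seq_len(ncol(vec))]
  keep <- vals > 1e-8 * max(vals)
  vec <- vec[, keep, drop = FALSE]
  colnames(vec) <- paste0("PCNM", seq_len(ncol(vec)))
  rownames(vec) <- rownames(geo)
  structure(list(vectors = vec, values = vals[keep],
                 threshold = res$threshold), class = "pcnm_basis")
}

#' @export
print.pcnm_basis <- function(x, ...) {
  cat(sprintf("PCNM basis: %d spatial eigenvector(s), truncation %.3f km\n",
              ncol(x$vectors), x$threshold))
  invisible(x)
}
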