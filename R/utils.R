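# Shared validation helpers and small utilities.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) {
  stop(structure(class = c("sedcomm_invalid_argument", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_format <- function(...) {
  stop(structure(class = c("sedcomm_format_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_alignment <- function(...) {
  stop(structure(class = c("sedcomm_alignment_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' Derive a stage-specific seed from a master seed
#'
#' Mixes a master seed with a stage name so that pipeline stages use
#' decorrelated random streams while remaining reproducible from one
#' integer.  The result is always a valid 32-bit R integer seed.
#'
#' @param master integer master seed.
#' @param stage character stage name.
#' @return A single integer in `[0, 2^31 - 1]`.
#' @export
derive_seed <- function(master, stage) {
  h <- as.double(master) %% 2147483647
  for (code in utf8ToInt(as.character(stage))) {
    h <- (h * 131 + code) %% 2147483647
  }
  as.integer(h)
}

# Validate a community matrix: samples x OTUs, non-negative integer counts.
check_community <- function(x, require_integer = TRUE) {
  if (!is.matrix(x) || !is.numeric(x))
    stop_invalid("community table must be a numeric matrix (samples x OTUs)")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop_invalid("community table must have sample row names and OTU column names")
  if (anyDuplicated(rownames(x)))
    stop_format("duplicate sample ids in community table")
  if (anyDuplicated(colnames(x)))
    stop_format("duplicate OTU ids in community table")
  if (any(x < 0))
    stop_format("negative counts in community table")
  if (require_integer && any(x != round(x)))
    stop_format("non-integer counts in community table")
  invisible(x)
}

# Coerce a dist or matrix into a validated square symmetric matrix with ids.
as_distmat <- function(d, ids = NULL) {
  m <- if (inherits(d, "dist")) as.matrix(d) else as.matrix(d)
  if (nrow(m) != ncol(m)) stop_invalid("distance matrix must be square")
  if (!is.null(ids)) dimnames(m) <- list(ids, ids)
  if (is.null(rownames(m))) {
    ids <- paste0("S", seq_len(nrow(m)))
    dimnames(m) <- list(ids, ids)
  }
  if (max(abs(m - t(m))) > 1e-12) stop_invalid("distance matrix must be symmetric")
  if (any(diag(m) != 0)) stop_invalid("distance matrix diagonal must be zero")
  if (any(m < 0)) stop_invalid("distance matrix must be non-negative")
  m
}

# Upper-triangle values of a square matrix, in column-major order.
upper_tri_vals <- function(m) m[upper.tri(m)]

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
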