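# Unconstrained and constrained ordination, matrix-correlation tests,
# clustering, and adjusted-R2 variation partitioning.

#' Principal coordinates analysis (classical scaling)
#'
#' Double-centres `-0.5 * D^2`, eigendecomposes, and scales the
#' eigenvectors by the square root of their eigenvalues.  Negative
#' eigenvalues are reported but excluded from the explained
#' proportions.
#'
#' @param d square distance matrix.
#' @param k number of axes (truncated with a warning if it exceeds the
#'   number of positive eigenvalues).
#' @return List of class `"ordination"`: `points` (samples x k),
#'   `eigenvalues` (all, decreasing), `proportion` (per returned axis),
#'   `method = "pcoa"`.
#' @export
pcoa <- function(d, k = 2) {
  d <- as_distmat(d)
  n <- nrow(d)
  res <- suppressWarnings(cmdscale(stats::as.dist(d), k = min(k, n - 1),
                                   eig = TRUE))
  eig <- res$eig
  pos <- sum(eig > sqrt(.Machine$double.eps) * max(abs(eig), 1))
  if (k > pos) {
    warning("only ", pos, " positive eigenvalue(s); axes truncated")
    k <- max(pos, 1)
  }
  pts <- res$points
  if (ncol(pts) == 0) pts <- matrix(0, n, k, dimnames = list(rownames(d), NULL))
  pts <- pts[, seq_len(min(k, ncol(pts))), drop = FALSE]
  colnames(pts) <- paste0("PCoA", seq_len(ncol(pts)))
  prop <- if (pos == 0) rep(0, ncol(pts))
          else pmax(eig[seq_len(ncol(pts))], 0) / sum(eig[eig > 0])
  structure(list(points = pts, eigenvalues = eig, proportion = prop,
                 method = "pcoa"), class = "ordination")
}

#' Non-metric multidimensional scaling
#'
#' Kruskal stress-1 minimized by iterative majorization with monotone
#' regression, best of `n_starts` random starts; deterministic given
#' `seed`.
#'
#' @param d square distance matrix.
#' @param k dimensions (default 2).
#' @param n_starts random starts (default 20).
#' @param seed integer seed.
#' @param max_iter,tol iteration cap and stress convergence tolerance.
#' @return List of class `"ordination"`: `points`, `stress` (0-1 scale),
#'   `converged`, `method = "nmds"`.
#' @export
nmds <- function(d, k = 2, n_starts = 20, seed = 1, max_iter = 300,
                 tol = 1e-7) {
  d <- as_distmat(d)
  if (nrow(d) < k + 2) stop_invalid("need >= k + 2 samples")
  fit <- with_seed(seed,
    vegan::metaMDS(stats::as.dist(d), k = k, try = n_starts,
                   trymax = n_starts, maxit = max_iter, sfgrmin = tol,
                   trace = 0, autotransform = FALSE, wascores = FALSE))
  pts <- fit$points
  colnames(pts) <- paste0("NMDS", seq_len(ncol(pts)))
  structure(list(points = pts, stress = fit$stress,
                 converged = fit$converged > 0, method = "nmds"),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat(toupper(x$method), "ordination:", nrow(x$points), "samples,",
      ncol(x$points), "axes\n")
  if (x$method == "pcoa")
    cat("  proportion explained:", paste(sprintf("%.3f", x$proportion),
                                         collapse = " "), "\n")
  else cat(sprintf("  stress: %.4f\n", x$stress))
  invisible(x)
}

#' @export
plot.ordination <- function(x, groups = NULL, ...) {
  col <- if (is.null(groups)) "black" else as.integer(factor(groups)) + 1
  plot(x$points[, 1], x$points[, 2], col = col, pch = 19,
       xlab = colnames(x$points)[1], ylab = colnames(x$points)[2], ...)
  invisible(x)
}

#' UPGMA dendrogram
#'
#' Average-linkage agglomerative clustering of a distance matrix; the
#' result is ultrametric, with each join placed at half the average
#' between-cluster distance.
#'
#' @param d square distance matrix.
#' @return An [ape::phylo] ultrametric tree with the sample ids as tips.
#' @export
upgma_dendrogram <- function(d) {
  d <- as_distmat(d)
  if (nrow(d) < 2) stop_invalid("need >= 2 samples")
  ape::as.phylo(hclust(stats::as.dist(d), method = "average"))
}

#' Analysis of similarities (ANOSIM)
#'
#' `R = (mean between-group rank - mean within-group rank) / (n(n-1)/4)`
#' on the ranked dissimilarities; p by group-label permutation with the
#' add-one rule.
#'
#' @param d square distance matrix.
#' @param groups per-sample labels (>= 2 groups of >= 2).
#' @param n_perm permutations (default 999).
#' @param seed integer seed.
#' @return List with `R` and `p`.
#' @export
anosim_test <- function(d, groups, n_perm = 999, seed = 1) {
  d <- as_distmat(d)
  groups <- factor(groups)
  if (nlevels(groups) < 2 || any(table(groups) < 2))
    stop_invalid("need >= 2 groups with >= 2 members each")
  fit <- with_seed(seed, vegan::anosim(stats::as.dist(d), groups,
                                       permutations = n_perm))
  list(R = unname(fit$statistic), p = fit$signif)
}

#' Mantel test between two distance matrices
#'
#' Correlation of the off-diagonal upper triangles; p by permutation of
#' one matrix's rows and columns, one-sided (greater), add-one rule.
#'
#' @param d1,d2 square distance matrices with matching ids.
#' @param method `"pearson"` or `"spearman"`.
#' @param n_perm permutations (default 999).
#' @param seed integer seed.
#' @return List with `r` and `p`.
#' @export
mantel_test <- function(d1, d2, method = c("pearson", "spearman"),
                        n_perm = 999, seed = 1) {
  method <- match.arg(method)
  d1 <- as_distmat(d1); d2 <- as_distmat(d2)
  if (!identical(rownames(d1), rownames(d2)))
    stop_alignment("distance matrices have mismatched ids")
  if (sd(upper_tri_vals(d1)) == 0 || sd(upper_tri_vals(d2)) == 0)
    stop_invalid("constant distance triangle: correlation undefined")
  fit <- with_seed(seed, vegan::mantel(stats::as.dist(d1), stats::as.dist(d2),
                                       method = method, permutations = n_perm))
  list(r = unname(fit$statistic), p = fit$signif)
}

# Standardize predictor columns and drop collinear ones (QR pivoting).
prepare_predictors <- function(X) {
  X <- as.data.frame(X)
  num <- vapply(X, is.numeric, logical(1))
  X <- X[num]
  has_na <- vapply(X, anyNA, logical(1))
  if (any(has_na)) {
    message("dropping predictor(s) with missing values: ",
            paste(names(X)[has_na], collapse = ", "))
    X <- X[!has_na]
  }
  keep <- vapply(X, function(x) sd(x) > 0, logical(1))
  if (any(!keep))
    message("dropping constant predictor(s): ",
            paste(names(X)[!keep], collapse = ", "))
  X <- X[keep]
  Xs <- as.data.frame(scale(as.matrix(X)))
  q <- qr(cbind(1, as.matrix(Xs)))
  if (q$rank < ncol(Xs) + 1) {
    drop <- setdiff(seq_len(ncol(Xs)) + 1, q$pivot[seq_len(q$rank)]) - 1
    message("dropping collinear predictor(s): ",
            paste(names(Xs)[drop], collapse = ", "))
    Xs <- Xs[-drop]
  }
  Xs
}

#' Constrained ordination (RDA / CCA)
#'
#' RDA regresses the Hellinger-transformed community on standardized
#' predictors and eigen-analyses the fitted values; CCA uses the
#' chi-square-transformed community with row/column weighting.
#' Per-variable significance comes from marginal permutation tests
#' (each variable tested with the others retained).
#'
#' @param comm samples x OTUs count matrix.
#' @param predictors data frame (or matrix) of predictor columns;
#'   combine environmental variables and PCNM vectors with `cbind`.
#' @param mode `"rda"` or `"cca"`.
#' @param n_perm permutations for the marginal tests (default 999).
#' @param seed integer seed.
#' @param hellinger Hellinger-transform the response before RDA.
#' @return List of class `"constrained_ordination"`: `mode`, `sites`
#'   (site scores), `biplot` (variable scores), `explained` (per
#'   constrained axis, fraction of total inertia), `cum_axis12_pct`,
#'   `total_explained`, `term_p` (named per-variable p-values), `model`.
#' @export
constrained_ordination <- function(comm, predictors, mode = c("rda", "cca"),
                                   n_perm = 999, seed = 1, hellinger = TRUE) {
  mode <- match.arg(mode)
  n <- nrow(comm)
  n_raw <- sum(vapply(as.data.frame(predictors), is.numeric, logical(1)))
  if (n_raw > n - 1)
    stop_invalid("more predictors (", n_raw, ") than samples - 1 (", n - 1,
                 "); select fewer variables")
  X <- prepare_predictors(predictors)
  Y <- if (mode == "rda" && hellinger)
    vegan::decostand(comm, method = "hellinger") else comm
  dat <- X
  mod <- if (mode == "rda") vegan::rda(Y ~ ., data = dat)
         else vegan::cca(Y ~ ., data = dat)
  eig <- mod$CCA$eig
  total <- mod$tot.chi
  explained <- eig / total
  perm_p <- with_seed(seed, {
    an <- stats::anova(mod, by = "margin", permutations = n_perm)
    setNames(an[["Pr(>F)"]][seq_len(ncol(X))], rownames(an)[seq_len(ncol(X))])
  })
  sc <- vegan::scores(mod, display = c("sites", "bp"), choices = seq_along(eig))
  structure(list(mode = mode, sites = sc$sites, biplot = sc$biplot,
                 explained = explained,
                 cum_axis12_pct = 100 * sum(explained[seq_len(min(2, length(explained)))]),
                 total_explained = sum(explained), term_p = perm_p,
                 model = mod),
            class = "constrained_ordination")
}

#' @export
print.constrained_ordination <- function(x, ...) {
  cat(toupper(x$mode), ": first two constrained axes explain ",
      sprintf("%.2f%%", x$cum_axis12_pct), " of total inertia\n", sep = "")
  cat("  marginal permutation p-values:\n")
  for (nm in names(x$term_p))
    cat(sprintf("    %-10s %.4g\n", nm, x$term_p[[nm]]))
  invisible(x)
}

# Ezekiel-adjusted R2 of an RDA of Y on X.
rda_adj_r2 <- function(Y, X) {
  n <- nrow(Y); p <- ncol(X)
  if (n - p - 1 <= 0)
    stop_invalid("n - p - 1 <= 0: too many predictors (", p, ") for ", n,
                 " samples")
  mod <- vegan::rda(Y ~ ., data = as.data.frame(X))
  r2 <- mod$CCA$tot.chi / mod$tot.chi
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

#' Variation partitioning between environment and space
#'
#' Partitions the (Hellinger-transformed) community variance explained
#' by two predictor blocks using Ezekiel-adjusted R2:
#' `a = adjR2(joint) - adjR2(space)` (pure environment),
#' `c = adjR2(joint) - adjR2(env)` (pure space),
#' `b = adjR2(env) + adjR2(space) - adjR2(joint)` (shared),
#' `d = 1 - adjR2(joint)` (unexplained).  Adjusted fractions may be
#' slightly negative; they are not clamped.
#'
#' @param comm samples x OTUs count matrix.
#' @param env data frame of environmental predictor columns.
#' @param space a `pcnm_basis` or matrix of spatial predictors.
#' @param hellinger Hellinger-transform the response first.
#' @return List of class `"vpa_result"` with `pure_env`, `shared`,
#'   `pure_space`, `unexplained`, `total_explained` and the three
#'   adjusted R2 values.
#' @export
variation_partitioning <- function(comm, env, space, hellinger = TRUE) {
  if (inherits(space, "pcnm_basis")) space <- space$vectors
  Xe <- prepare_predictors(env)
  Xs <- prepare_predictors(space)
  if (ncol(Xe) == 0 || ncol(Xs) == 0)
    stop_invalid("both predictor blocks must be non-empty")
  Y <- if (hellinger) vegan::decostand(comm, method = "hellinger") else comm
  r2_env <- rda_adj_r2(Y, Xe)
  r2_spa <- rda_adj_r2(Y, Xs)
  r2_all <- rda_adj_r2(Y, cbind(Xe, Xs))
  a <- r2_all - r2_spa
  c_ <- r2_all - r2_env
  b <- r2_env + r2_spa - r2_all
  structure(list(pure_env = a, shared = b, pure_space = c_,
                 unexplained = 1 - r2_all, total_explained = r2_all,
                 adj_r2 = c(env = r2_env, space = r2_spa, joint = r2_all)),
            class = "vpa_result")
}

#' Compose a variation-partitioning result from printed fractions
#'
#' Utility for working with reported adjusted fractions: given pure
#' environment, shared and pure space (all on the same scale, e.g.
#' percent), returns the composition with the total explained fraction
#' `a + b + c` and the complementary unexplained fraction.
#'
#' @param pure_env,shared,pure_space adjusted fractions.
#' @param scale the scale total (100 for percentages, 1 for fractions).
#' @return A list of class `"vpa_result"`.
#' @export
vpa_compose <- function(pure_env, shared, pure_space, scale = 100) {
  total <- pure_env + shared + pure_space
  structure(list(pure_env = pure_env, shared = shared,
                 pure_space = pure_space, unexplained = scale - total,
                 total_explained = total, adj_r2 = NULL),
            class = "vpa_result")
}

#' @export
print.vpa_result <- function(x, ...) {
  cat("Variation partitioning (adjusted R2 fractions)\n")
  cat(sprintf("  pure environment: %.4g\n", x$pure_env))
  cat(sprintf("  shared:           %.4g\n", x$shared))
  cat(sprintf("  pure space:       %.4g\n", x$pure_space))
  cat(sprintf("  total explained:  %.4g\n", x$total_explained))
  cat(sprintf("  unexplained:      %.4g\n", x$unexplained))
  invisible(x)
}
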