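preprocess_matrix <- function(X, scaling, centring) {
  X <- as.matrix(X)
  if (centring) X <- sweep(X, 2, colMeans(X))
  if (scaling == "unit-variance") {
    s <- apply(X, 2, stats::sd)
    if (any(s == 0)) stop("constant column under unit-variance scaling")
    X <- sweep(X, 2, s, "/")
  } else if (scaling == "pareto") {
    s <- sqrt(apply(X, 2, stats::sd))
    if (any(s == 0)) stop("constant column under pareto scaling")
    X <- sweep(X, 2, s, "/")
  }
  X
}

# One NIPALS component on a (preprocessed) matrix; returns scores t and
# unit-norm loadings p. Converges on the relative change of the score
# vector, which is stricter than the eigenvalue change when neighbouring
# eigenvalues are close.
nipals_component <- function(E, tol = 1e-24, max_iter = 10000) {
  j <- which.max(colSums(E^2))
  t_vec <- E[, j]
  if (all(t_vec == 0)) t_vec <- E[, which(colSums(abs(E)) > 0)[1]]
  for (i in seq_len(max_iter)) {
    p <- drop(crossprod(E, t_vec)) / sum(t_vec^2)
    p <- p / sqrt(sum(p^2))
    t_new <- drop(E %*% p)
    delta <- sum((t_new - t_vec)^2) / sum(t_new^2)
    t_vec <- t_new
    if (delta < tol) break
  }
  list(t = t_vec, p = p)
}

#' Principal component analysis by NIPALS
#'
#' Mean-centred (optionally unit-variance or pareto scaled) PCA extracted
#' component-by-component with the NIPALS algorithm and deflation. R2 per
#' component is the fraction of the preprocessed matrix's total sum of
#' squares explained by that component.
#'
#' @param X samples x features numeric matrix.
#' @param ncomp number of components A; must satisfy
#'   A <= min(samples - 1, features).
#' @param scaling `"unit-variance"` (default), `"pareto"` or `"none"`.
#' @param centring mean-centre columns (default TRUE).
#' @return list of class `PCAModel`: `scores` (samples x A), `loadings`
#'   (features x A, column-orthonormal), `r2` (per component), `r2cum`,
#'   `scaling`, `centring`, `ncomp`.
#' @export
fit_pca <- function(X, ncomp, scaling = c("unit-variance", "pareto", "none"),
                    centring = TRUE) {
  scaling <- match.arg(scaling)
  X <- as.matrix(X)
  if (ncomp > min(nrow(X) - 1L, ncol(X))) {
    stop("ncomp exceeds min(samples - 1, features)")
  }
  if (ncomp < 0) stop("ncomp must be >= 0")
  E <- preprocess_matrix(X, scaling, centring)
  ss0 <- sum(E^2)
  scores <- matrix(0, nrow(X), ncomp)
  loadings <- matrix(0, ncol(X), ncomp)
  r2 <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    cmp <- nipals_component(E)
    scores[, a] <- cmp$t
    loadings[, a] <- cmp$p
    r2[a] <- sum(cmp$t^2) / ss0
    E <- E - tcrossprod(cmp$t, cmp$p)
  }
  rownames(scores) <- rownames(X)
  rownames(loadings) <- colnames(X)
  structure(list(scores = scores, loadings = loadings,
                 r2 = r2, r2cum = cumsum(r2),
                 scaling = scaling, centring = centring, ncomp = ncomp),
            class = "PCAModel")
}

#' @export
print.PCAModel <- function(x, ...) {
  cat(sprintf("PCAModel: %d component(s), R2cum = %.3f\n",
              x$ncomp, if (x$ncomp > 0) x$r2cum[x$ncomp] else 0))
  invisible(x)
}

#' Cross-validated predictive fraction Q2 of a PCA model
#'
#' Rows are assigned to folds round-robin after a seeded shuffle. For each
#' component a (on the residual matrix after a-1 full-data components),
#' every fold is held out in turn, a one-component NIPALS model is fitted to
#' the remaining rows, and the held-out rows are predicted from its
#' loadings; PRESS_a is the pooled squared prediction error. Then
#' Q2_a = 1 - PRESS_a / SS_(a-1) and Q2cum = 1 - prod_a(PRESS_a / SS_(a-1)).
#'
#' @param X samples x features matrix.
#' @param ncomp number of components.
#' @param folds cross-validation folds (default 7).
#' @param scaling,centring as in [fit_pca()]; applied once to the full
#'   matrix before cross-validation.
#' @param seed integer seed for the row shuffle.
#' @return list with per-component `q2`, `q2cum`, and `press`.
#' @export
q2_crossval <- function(X, ncomp, folds = 7, scaling = "unit-variance",
                        centring = TRUE, seed = 1) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (folds < 2L) stop("folds must be >= 2")
  if (folds > n) stop("fold count exceeds the number of rows")
  if (ncomp > min(n - 2L, ncol(X))) {
    stop("ncomp too large for cross-validation")
  }
  E <- preprocess_matrix(X, match.arg(scaling, c("unit-variance", "pareto", "none")),
                         centring)
  set.seed(seed)
  fold_of <- integer(n)
  fold_of[sample.int(n)] <- rep_len(seq_len(folds), n)
  q2 <- press <- ss_prev <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    ss_prev[a] <- sum(E^2)
    pr <- 0
    for (f in seq_len(folds)) {
      hold <- fold_of == f
      cmp <- nipals_component(E[!hold, , drop = FALSE])
      t_hat <- E[hold, , drop = FALSE] %*% cmp$p
      pr <- pr + sum((E[hold, , drop = FALSE] - tcrossprod(t_hat, cmp$p))^2)
    }
    press[a] <- pr
    q2[a] <- 1 - pr / ss_prev[a]
    cmp_full <- nipals_component(E)
    E <- E - tcrossprod(cmp_full$t, cmp_full$p)
  }
  list(q2 = q2, q2cum = 1 - prod(press / ss_prev), press = press)
}

#' Hierarchical clustering of metabolite fold-change trajectories
#'
#' Agglomerative clustering of metabolites by their log2 fold-change
#' trajectories over the time course, as used to order the rows of a
#' regulation heat map. Default: Euclidean distance, average linkage.
#'
#' @param log2fc_matrix metabolites x time points matrix of finite log2
#'   fold changes (rownames = metabolite labels).
#' @param linkage agglomeration method passed to [stats::hclust()].
#' @param metric distance metric passed to [stats::dist()].
#' @return object of class `ClusterTree` wrapping the `hclust` result:
#'   `merge`, `height`, `order`, `labels`, `hclust`.
#' @export
cluster_metabolites <- function(log2fc_matrix, linkage = "average",
                                metric = "euclidean") {
  m <- as.matrix(log2fc_matrix)
  if (nrow(m) < 2L) stop("clustering requires >= 2 metabolites")
  if (any(!is.finite(m))) stop("log2 fold-change matrix contains non-finite values")
  hc <- stats::hclust(stats::dist(m, method = metric), method = linkage)
  structure(list(merge = hc$merge, height = hc$height, order = hc$order,
                 labels = hc$labels, hclust = hc),
            class = "ClusterTree")
}
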