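# Varimax-rotated PCA of the feature table: eigendecomposition of the
# correlation matrix, eigenvalue > 1 retention, Kaiser-normalized varimax.

#' Varimax-rotated principal components of a feature table
#'
#' Columns are z-scored internally, so components come from the
#' correlation matrix (features have heterogeneous units). Components
#' with eigenvalue > 1 are retained and rotated with varimax under Kaiser
#' normalization; each rotated component's sign is fixed so its
#' largest-|loading| entry is positive. Communalities (row sums of squared
#' loadings) are invariant under the rotation.
#'
#' @param t a [feature_table()] or plain data.frame/matrix of features.
#' @param n_components override the eigenvalue > 1 retention rule.
#' @return A `pca_result` list: `eigenvalues`, `n_retained`, `loadings`
#'   (feature x component, rotated), `explained_pct`, `communalities`,
#'   `unrotated_loadings`, `scores`.
#' @export
pca_varimax <- function(t, n_components = NULL) {
  X <- as.matrix(if (inherits(t, "feature_table")) t[feature_names()] else t)
  storage.mode(X) <- "double"
  ok <- rowSums(!is.finite(X)) == 0L   # listwise exclusion of undefined rows
  if (any(!ok)) message(sum(!ok), " row(s) with undefined features excluded")
  X <- X[ok, , drop = FALSE]
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("need more rows than feature columns")
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) stop("constant feature column: ",
                          paste(colnames(X)[sds == 0], collapse = ", "))
  Z <- scale(X)
  eg <- eigen(cor(X), symmetric = TRUE)
  ev <- eg$values
  k <- if (is.null(n_components)) sum(ev > 1) else as.integer(n_components)
  if (k < 1L) stop("no component retained")
  if (n < 3L * k) stop("need at least 3x more rows than retained components")
  L <- eg$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(ev[seq_len(k)]), k)
  rownames(L) <- colnames(X)
  rot <- if (k > 1L) {
    vm <- varimax(L, normalize = TRUE)
    Lr <- unclass(vm$loadings)
    attributes(Lr) <- attributes(Lr)[c("dim", "dimnames")]
    Lr
  } else L
  # sign convention: dominant loading of each component positive
  for (j in seq_len(k)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  colnames(rot) <- paste0("PC", seq_len(k))
  expl <- colSums(rot^2) / p * 100
  # component scores via least squares on the z-scored data
  scores <- Z %*% rot %*% solve(crossprod(rot))
  structure(list(eigenvalues = ev, n_retained = k, loadings = rot,
                 explained_pct = expl, communalities = rowSums(rot^2),
                 unrotated_loadings = L, scores = scores),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d components retained (eigenvalue > 1)\n",
              x$n_retained))
  cat("explained variance (%):",
      paste(sprintf("%.1f", x$explained_pct), collapse = ", "), "\n")
  invisible(x)
}
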