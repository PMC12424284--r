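# Partial least squares correlation: SVD of the cross-correlation matrix
# between two z-scored blocks, with permutation inference on the singular
# values and bootstrap confidence intervals on the saliences.

zscore_block <- function(M, label) {
  M <- as.matrix(M)
  storage.mode(M) <- "double"
  sds <- apply(M, 2, sd)
  if (any(sds == 0))
    stop("constant column in ", label, " block")
  scale(M)
}

#' Fit a partial least squares correlation model
#'
#' Both blocks are z-scored column-wise, the cross-block matrix
#' R = X'Y/(n-1) (a correlation matrix) is decomposed with an SVD
#' R = U S V', and each latent variable's effect size is the proportion
#' of cross-block covariance it explains, s_i^2 / sum_j s_j^2. Saliences
#' (columns of U and V) are the variable weights on each LV; latent
#' scores are the projections of the z-scored blocks onto them.
#'
#' @param X n x p predictor block (e.g. the 16 breathing features).
#' @param Y n x q outcome block (e.g. BAI items or per-load efficiency).
#' @return A `plsc_result` list: `singular_values`, `covexp`,
#'   `x_saliences`, `y_saliences`, `x_scores`, `y_scores`, `n`.
#' @export
plsc_fit <- function(X, Y) {
  Xz <- zscore_block(X, "X"); Yz <- zscore_block(Y, "Y")
  n <- nrow(Xz)
  if (n < 3L) stop("need n >= 3")
  if (nrow(Yz) != n) stop("X and Y must have the same rows")
  R <- crossprod(Xz, Yz) / (n - 1)
  k <- min(ncol(Xz), ncol(Yz))
  sv <- svd(R, nu = k, nv = k)
  s <- sv$d[seq_len(k)]
  U <- sv$u; V <- sv$v
  rownames(U) <- colnames(Xz); rownames(V) <- colnames(Yz)
  colnames(U) <- colnames(V) <- paste0("LV", seq_len(k))
  structure(list(singular_values = s, covexp = s^2 / sum(s^2),
                 x_saliences = U, y_saliences = V,
                 x_scores = Xz %*% U, y_scores = Yz %*% V,
                 n = n, Xz = Xz, Yz = Yz),
            class = "plsc_result")
}

#' @export
print.plsc_result <- function(x, ...) {
  k <- length(x$singular_values)
  cat(sprintf("<plsc_result> %d LVs, n = %d\n", k, x$n))
  cat("covariance explained (%):",
      paste(sprintf("%.1f", 100 * x$covexp), collapse = ", "), "\n")
  if (!is.null(x$perm_p))
    cat("permutation p:", paste(signif(x$perm_p, 3), collapse = ", "), "\n")
  invisible(x)
}

# singular values of the cross-correlation of two already-z-scored blocks
cross_singvals <- function(Xz, Yz, k) {
  svd(crossprod(Xz, Yz) / (nrow(Xz) - 1), nu = 0, nv = 0)$d[seq_len(k)]
}

#' Permutation test for PLSC latent variables
#'
#' Rows of Y are permuted uniformly at random in each replicate and the
#' singular values recomputed; the p-value for LV i is
#' (1 + #\{permuted s_i >= observed s_i\}) / (n_perm + 1), compared
#' LV-by-LV without re-rotation.
#'
#' @param fit a `plsc_result`.
#' @param n_perm number of permutations.
#' @param seed RNG seed for reproducibility.
#' @return The fit with `perm_p` and `n_perm` added.
#' @export
plsc_permutation <- function(fit, n_perm = 1000, seed = 1) {
  stopifnot(inherits(fit, "plsc_result"))
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (n_perm < 100) warning("n_perm < 100 gives coarse p-values")
  k <- length(fit$singular_values)
  n <- fit$n
  set.seed(seed)
  exceed <- numeric(k)
  for (b in seq_len(n_perm)) {
    sp <- cross_singvals(fit$Xz, fit$Yz[sample.int(n), , drop = FALSE], k)
    exceed <- exceed + (sp >= fit$singular_values)
  }
  fit$perm_p <- (1 + exceed) / (n_perm + 1)
  fit$n_perm <- n_perm
  fit
}

# least-squares orthogonal Procrustes rotation of B onto A
procrustes_rotation <- function(A, B) {
  sv <- svd(crossprod(B, A))
  sv$u %*% t(sv$v)
}

#' Bootstrap confidence intervals for PLSC saliences
#'
#' Subjects (rows of X and Y jointly) are resampled with replacement;
#' each replicate's saliences are aligned to the original axes with an
#' orthogonal Procrustes rotation of U (the same rotation is applied to
#' V) to prevent sign and order flips. Percentile 2.5/97.5 intervals are
#' reported and a salience is flagged reliable when its interval excludes
#' zero. Replicates producing a constant column are redrawn and counted.
#'
#' @param fit a `plsc_result` with n >= 10.
#' @param n_boot number of bootstrap replicates.
#' @param seed RNG seed.
#' @return The fit with `x_ci_lo`, `x_ci_hi`, `y_ci_lo`, `y_ci_hi`,
#'   `x_reliable`, `y_reliable`, `n_boot`, `n_redrawn` added.
#' @export
plsc_bootstrap <- function(fit, n_boot = 1000, seed = 1) {
  stopifnot(inherits(fit, "plsc_result"))
  if (n_boot < 1) stop("n_boot must be >= 1")
  n <- fit$n
  if (n < 10L) stop("bootstrap needs n >= 10")
  k <- length(fit$singular_values)
  p <- nrow(fit$x_saliences); q <- nrow(fit$y_saliences)
  set.seed(seed)
  Ub <- array(NA_real_, c(p, k, n_boot))
  Vb <- array(NA_real_, c(q, k, n_boot))
  n_redrawn <- 0L
  # resample on the original-scale blocks so each replicate re-z-scores
  X0 <- sweep(sweep(fit$Xz, 2, attr(fit$Xz, "scaled:scale"), "*"),
              2, attr(fit$Xz, "scaled:center"), "+")
  Y0 <- sweep(sweep(fit$Yz, 2, attr(fit$Yz, "scaled:scale"), "*"),
              2, attr(fit$Yz, "scaled:center"), "+")
  for (b in seq_len(n_boot)) {
    repeat {
      i <- sample.int(n, replace = TRUE)
      Xb <- X0[i, , drop = FALSE]; Yb <- Y0[i, , drop = FALSE]
      if (all(apply(Xb, 2, sd) > 0) && all(apply(Yb, 2, sd) > 0)) break
      n_redrawn <- n_redrawn + 1L
    }
    sv <- svd(crossprod(scale(Xb), scale(Yb)) / (n - 1), nu = k, nv = k)
    Q <- procrustes_rotation(fit$x_saliences, sv$u)
    Ub[, , b] <- sv$u %*% Q
    Vb[, , b] <- sv$v %*% Q
  }
  ci <- function(arr) {
    lo <- apply(arr, c(1, 2), quantile, probs = 0.025)
    hi <- apply(arr, c(1, 2), quantile, probs = 0.975)
    list(lo = lo, hi = hi)
  }
  cx <- ci(Ub); cy <- ci(Vb)
  dimnames(cx$lo) <- dimnames(cx$hi) <- dimnames(fit$x_saliences)
  dimnames(cy$lo) <- dimnames(cy$hi) <- dimnames(fit$y_saliences)
  fit$x_ci_lo <- cx$lo; fit$x_ci_hi <- cx$hi
  fit$y_ci_lo <- cy$lo; fit$y_ci_hi <- cy$hi
  fit$x_reliable <- cx$lo > 0 | cx$hi < 0
  fit$y_reliable <- cy$lo > 0 | cy$hi < 0
  fit$n_boot <- n_boot
  fit$n_redrawn <- n_redrawn
  fit
}
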