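# Rest-vs-task paired comparisons across the 16 features with BH FDR.

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin wrapper over the standard step-up procedure: adjusted p at rank i
#' is min over j >= i of p_(j) * m / j, capped at 1.
#'
#' @param p vector of p-values in \[0, 1\].
#' @return Adjusted p-values in the original order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values outside [0, 1]")
  p.adjust(p, method = "BH")
}

#' Paired rest-vs-task comparison of every feature
#'
#' Two-sided paired t-tests per feature on the difference rest - task
#' (so a task increase yields a negative t), with Cohen's d =
#' mean(diff)/SD(diff) and BH adjustment across the 16 features. The
#' identity d = t/sqrt(n) holds exactly under this definition.
#'
#' @param rest,task [feature_table()]s covering the same subjects.
#' @return data.frame: `feature`, `t`, `df`, `p_raw`, `p_adjusted`,
#'   `cohens_d`, `n`.
#' @export
paired_compare <- function(rest, task) {
  stopifnot(inherits(rest, "feature_table"), inherits(task, "feature_table"))
  subs <- sort(unique(rest$subject))
  if (!setequal(subs, unique(task$subject)))
    stop("rest and task tables cover different subjects")
  n <- length(subs)
  if (n < 3L) stop("need at least 3 paired subjects")
  r <- as.matrix(rest[match(subs, rest$subject), feature_names()])
  k <- as.matrix(task[match(subs, task$subject), feature_names()])
  res <- lapply(feature_names(), function(fn) {
    d <- r[, fn] - k[, fn]
    d <- d[is.finite(d)]     # complete pairs only (undefined features drop)
    m <- length(d)
    if (m < 3L) stop("fewer than 3 complete pairs for ", fn)
    if (all(d == 0))          # no change at all: null result by convention
      return(data.frame(feature = fn, t = 0, df = m - 1L, p_raw = 1,
                        cohens_d = 0, n = m))
    if (sd(d) <= 1e-10 * max(abs(d)))
      stop("zero-variance differences for ", fn)
    tt <- t.test(d)
    data.frame(feature = fn, t = unname(tt$statistic), df = m - 1L,
               p_raw = tt$p.value, cohens_d = mean(d) / sd(d), n = m)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- bh_adjust(out$p_raw)
  out[c("feature", "t", "df", "p_raw", "p_adjusted", "cohens_d", "n")]
}
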