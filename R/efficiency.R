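# Working-memory efficiency: accuracy / mean reaction time per subject
# and N-back load, speeds pooled.

#' Working-memory efficiency per subject and load
#'
#' Accuracy is the proportion of correct trials; mean RT is taken over
#' correct trials by default (inverse-efficiency convention) or over all
#' responded trials. Efficiency = accuracy / mean RT (1/s): higher is
#' both faster and more accurate. Fast/slow presentation speeds are
#' pooled within load.
#'
#' @param trials behavioral data.frame from [read_behavior_table()].
#' @param rt_trials `"correct"` (default) or `"all"`.
#' @return data.frame: `subject`, `load`, `accuracy`, `mean_rt`,
#'   `efficiency`.
#' @export
wm_efficiency <- function(trials, rt_trials = c("correct", "all")) {
  rt_trials <- match.arg(rt_trials)
  if (nrow(trials) == 0L) stop("no trials")
  groups <- split(trials, list(trials$subject, trials$load), drop = TRUE)
  out <- lapply(groups, function(g) {
    acc <- mean(g$correct)
    sel <- if (rt_trials == "correct") g$correct == 1 else is.finite(g$rt)
    rts <- g$rt[sel & is.finite(g$rt) & g$rt > 0]
    mrt <- if (length(rts)) mean(rts) else NA_real_
    eff <- if (acc == 0) 0
           else if (is.na(mrt) || mrt == 0) stop("mean RT unavailable for ",
                                                 g$subject[1], " load ",
                                                 g$load[1])
           else acc / mrt
    data.frame(subject = g$subject[1], load = g$load[1],
               accuracy = acc, mean_rt = mrt, efficiency = eff)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$subject, out$load), ]
}

#' Wide efficiency block for PLSC
#'
#' @param eff output of [wm_efficiency()].
#' @return matrix with one row per subject and columns
#'   `eff_1back, eff_2back, eff_3back` (subjects as rownames).
#' @export
efficiency_block <- function(eff) {
  subs <- sort(unique(eff$subject))
  loads <- sort(unique(eff$load))
  M <- matrix(NA_real_, length(subs), length(loads),
              dimnames = list(subs, paste0("eff_", loads, "back")))
  for (i in seq_len(nrow(eff)))
    M[eff$subject[i], paste0("eff_", eff$load[i], "back")] <- eff$efficiency[i]
  if (anyNA(M)) stop("missing subject x load efficiency cells")
  M
}
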