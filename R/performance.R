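#' Segment counts for the three performance measures
#'
#' Correct/total classified-segment counts per condition, the raw material
#' of the three neurofeedback performance measures. Baseline counts are
#' kept separately for left-hand and right-hand trials so the baseline
#' denominator of each Base classifier can be restricted to its own side
#' (the default) or pooled.
#'
#' @param c_b_left,t_b_left correct/total baseline segments from left-hand
#'   trials (classified by BaseL).
#' @param c_b_right,t_b_right correct/total baseline segments from
#'   right-hand trials (classified by BaseR).
#' @param c_mi_left,t_mi_left correct/total left-MI segments.
#' @param c_mi_right,t_mi_right correct/total right-MI segments.
#' @return object of class `"minfa_counts"`.
#' @export
segment_counts <- function(c_b_left, t_b_left, c_b_right, t_b_right,
                           c_mi_left, t_mi_left, c_mi_right, t_mi_right) {
  v <- c(c_b_left, t_b_left, c_b_right, t_b_right,
         c_mi_left, t_mi_left, c_mi_right, t_mi_right)
  if (any(v < 0) || any(v != round(v))) stop("counts must be non-negative integers")
  if (c_b_left > t_b_left || c_b_right > t_b_right ||
      c_mi_left > t_mi_left || c_mi_right > t_mi_right) {
    stop("correct count exceeds total count")
  }
  structure(list(c_b_left = c_b_left, t_b_left = t_b_left,
                 c_b_right = c_b_right, t_b_right = t_b_right,
                 c_mi_left = c_mi_left, t_mi_left = t_mi_left,
                 c_mi_right = c_mi_right, t_mi_right = t_mi_right),
            class = "minfa_counts")
}

#' Neurofeedback performance from segment counts
#'
#' The three raw performance measures, as percentages:
#' \deqn{BaseL = 100 (C_B + C_{MILeft}) / (T_B + T_{MILeft})}
#' \deqn{BaseR = 100 (C_B + C_{MIRight}) / (T_B + T_{MIRight})}
#' \deqn{LR = 100 (C_{MILeft} + C_{MIRight}) / (T_{MILeft} + T_{MIRight})}
#' plus the per-subject maximum over the three and the identity of the
#' best classifier (ties broken in the order BaseL, BaseR, LR).
#'
#' @param counts a [segment_counts()].
#' @param baseline_scope `"matched"` (default): the baseline counts in
#'   BaseL/BaseR come from the matching side's trials only; `"pooled"`:
#'   both sides' baseline segments enter both denominators.
#' @return object of class `"minfa_performance"`: `baseL`, `baseR`, `lr`,
#'   `max_perf`, `best_classifier`.
#' @export
classifier_performance <- function(counts, baseline_scope = c("matched", "pooled")) {
  baseline_scope <- match.arg(baseline_scope)
  if (baseline_scope == "pooled") {
    cbl <- cbr <- counts$c_b_left + counts$c_b_right
    tbl <- tbr <- counts$t_b_left + counts$t_b_right
  } else {
    cbl <- counts$c_b_left; tbl <- counts$t_b_left
    cbr <- counts$c_b_right; tbr <- counts$t_b_right
  }
  if (tbl + counts$t_mi_left == 0 || tbr + counts$t_mi_right == 0 ||
      counts$t_mi_left + counts$t_mi_right == 0) {
    stop("zero total segments for a performance measure")
  }
  baseL <- 100 * (cbl + counts$c_mi_left) / (tbl + counts$t_mi_left)
  baseR <- 100 * (cbr + counts$c_mi_right) / (tbr + counts$t_mi_right)
  lr <- 100 * (counts$c_mi_left + counts$c_mi_right) /
    (counts$t_mi_left + counts$t_mi_right)
  perf <- c(BaseL = baseL, BaseR = baseR, LR = lr)
  best <- names(perf)[which.max(perf)]  # which.max takes the first tie
  structure(list(baseL = baseL, baseR = baseR, lr = lr,
                 max_perf = unname(max(perf)), best_classifier = best),
            class = "minfa_performance")
}

#' @export
print.minfa_performance <- function(x, ...) {
  cat(sprintf("BaseL %.1f%%  BaseR %.1f%%  LR %.1f%%  ->  max %.1f%% (%s)\n",
              x$baseL, x$baseR, x$lr, x$max_perf, x$best_classifier))
  invisible(x)
}

#' Median split into low and high performers
#'
#' Dichotomizes per-subject maximum performance at the sample median:
#' scores strictly above the median are labelled `"high"`, scores at or
#' below it `"low"`. With an odd n of distinct scores this yields the
#' (n+1)/2 low / (n-1)/2 high split (e.g. 11/10 at n = 21). Identical
#' scores throughout give all-low with a warning.
#'
#' @param scores numeric vector of per-subject maximum performance.
#' @return factor with levels `c("low", "high")`.
#' @export
median_split <- function(scores) {
  if (length(scores) < 2) stop("need at least 2 subjects")
  if (length(unique(scores)) == 1) {
    warning("all scores identical; all subjects labelled low")
    return(factor(rep("low", length(scores)), levels = c("low", "high")))
  }
  m <- stats::median(scores)
  factor(ifelse(scores > m, "high", "low"), levels = c("low", "high"))
}

#' Performance from per-segment decision tables
#'
#' Tallies the per-bin decisions of the three classifiers on a feedback
#' block and evaluates the three performance equations. Each classifier
#' contributes its own correct/total counts: BaseL is scored on
#' baseline-of-left-trial and left-MI segments, BaseR on the right-side
#' analogues, LR on left- and right-MI segments. This is the decision-level
#' route the equation arithmetic of [classifier_performance()] must agree
#' with on any shared counting scheme.
#'
#' @param base_l decisions (from [classify_segments()]) of the BaseL
#'   classifier; must carry a `label` column in `c("baseline", "left")`.
#' @param base_r same for BaseR (`"baseline"`/`"right"`).
#' @param lr decisions of the LR classifier (`label` in
#'   `c("left", "right")`).
#' @return a `"minfa_performance"` (see [classifier_performance()]).
#' @export
tally_performance <- function(base_l, base_r, lr) {
  cnt <- function(df, lab) {
    sel <- df$label == lab
    c(correct = sum(sel & df$decision == lab), total = sum(sel))
  }
  bl_b <- cnt(base_l, "baseline"); bl_m <- cnt(base_l, "left")
  br_b <- cnt(base_r, "baseline"); br_m <- cnt(base_r, "right")
  lr_l <- cnt(lr, "left"); lr_r <- cnt(lr, "right")
  ratio <- function(c1, t1, c2, t2) unname(100 * (c1 + c2) / (t1 + t2))
  perf <- c(
    BaseL = ratio(bl_b["correct"], bl_b["total"], bl_m["correct"], bl_m["total"]),
    BaseR = ratio(br_b["correct"], br_b["total"], br_m["correct"], br_m["total"]),
    LR = ratio(lr_l["correct"], lr_l["total"], lr_r["correct"], lr_r["total"]))
  best <- names(perf)[which.max(perf)]
  structure(list(baseL = unname(perf["BaseL"]), baseR = unname(perf["BaseR"]),
                 lr = unname(perf["LR"]), max_perf = unname(max(perf)),
                 best_classifier = best),
            class = "minfa_performance")
}
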