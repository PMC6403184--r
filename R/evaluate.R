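#' Repeated stratified cross-validated SLDA accuracy
#'
#' Ten repeats (by default) of stratified fivefold cross-validation.
#' Within every training split, CAT-score variable selection
#' ([crossval_select()], itself five-fold within the split so no label
#' ever leaks into selection) is followed by an SLDA fit on the selected
#' features; the held-out subjects are then predicted. Overall accuracy
#' is the percentage correct over all repeats and subjects.
#'
#' @param table a cohort data.frame (e.g. from [generate_fa_cohort()] or
#'   [build_feature_table()]).
#' @param candidate_columns character vector of predictor columns;
#'   non-numeric columns are coded as integer factors.
#' @param outcome name of the binary outcome column (default `"label"`).
#' @param folds outer folds (default 5; reduced with a warning if a class
#'   is smaller).
#' @param repeats outer repeats, fresh folds each (default 10).
#' @param select run CAT selection inside each training split (default
#'   `TRUE`); `FALSE` uses all candidates ("variables selected: all").
#' @param threshold CAT inclusion threshold (default 4).
#' @param seed integer seed for fold assignment.
#' @return object of class `"minfa_cv"`: `accuracy` (%), `fold_acc`
#'   (repeat x fold matrix, %), `selected` (list of per-split selected
#'   column names), `config`.
#' @export
repeated_cv <- function(table, candidate_columns, outcome = "label",
                        folds = 5, repeats = 10, select = TRUE,
                        threshold = 4, seed = 1) {
  x <- encode_candidates(table, candidate_columns)
  y <- droplevels(as.factor(table[[outcome]]))
  if (nlevels(y) != 2) stop("outcome must be binary")
  set.seed(seed)
  # folds are assigned in a canonical (content-based) row order, so the
  # accuracy at a fixed seed is invariant to row permutations of the table
  can <- do.call(order, c(unname(as.data.frame(x)), list(as.integer(y))))
  fold_acc <- matrix(NA_real_, repeats, folds)
  selected_sets <- list()
  n_correct <- 0; n_total <- 0
  for (rep in seq_len(repeats)) {
    fid <- integer(length(y))
    fid[can] <- stratified_folds(y[can], folds)
    for (f in sort(unique(fid))) {
      tr <- fid != f
      sel <- if (select) {
        crossval_select(x[tr, , drop = FALSE], y[tr], folds = 5,
                        threshold = threshold)$included
      } else {
        seq_len(ncol(x))
      }
      model <- fit_slda(x[tr, , drop = FALSE], y[tr], sel)
      pred <- predict_slda(model, x[!tr, , drop = FALSE])
      hits <- pred$class == as.character(y[!tr])
      n_correct <- n_correct + sum(hits)
      n_total <- n_total + length(hits)
      fold_acc[rep, f] <- 100 * mean(hits)
      selected_sets[[length(selected_sets) + 1]] <- candidate_columns[sel]
    }
  }
  structure(list(accuracy = 100 * n_correct / n_total, fold_acc = fold_acc,
                 selected = selected_sets,
                 config = list(folds = folds, repeats = repeats,
                               select = select, threshold = threshold,
                               seed = seed)),
            class = "minfa_cv")
}

#' @export
print.minfa_cv <- function(x, ...) {
  cat(sprintf("<minfa_cv> accuracy %.1f%% over %d repeats x %d folds\n",
              x$accuracy, x$config$repeats, x$config$folds))
  invisible(x)
}

# Candidate columns as a numeric matrix; character/factor columns become
# integer codes.
encode_candidates <- function(table, cols) {
  missing <- setdiff(cols, names(table))
  if (length(missing) > 0) {
    stop("unknown candidate column(s): ", paste(missing, collapse = ", "))
  }
  x <- sapply(cols, function(cn) {
    v <- table[[cn]]
    if (is.numeric(v)) v else as.numeric(as.factor(v))
  })
  x <- matrix(x, nrow = nrow(table), dimnames = list(NULL, cols))
  if (anyNA(x)) {
    keep <- !apply(is.na(x), 2, any)
    warning(sprintf("%d candidate column(s) dropped for missing values",
                    sum(!keep)))
    x <- x[, keep, drop = FALSE]
  }
  x
}

#' Monte-Carlo permutation test of cross-validation accuracy
#'
#' Shuffles the group labels across all subjects and reruns the entire
#' repeated-CV pipeline — including variable selection inside every
#' training split — for each permutation. The p-value is the plain
#' proportion of permutations with accuracy greater than or equal to the
#' observed accuracy; a zero proportion is reported as 0 and flagged as
#' "< 1/n_perm" when printed.
#'
#' @inheritParams repeated_cv
#' @param n_perm number of permutations (default 10000; < 100 warns).
#' @return object of class `"minfa_perm"`: `observed` (%), `null`
#'   (length `n_perm`), `p`, `n_perm`, `seed`.
#' @export
permutation_test <- function(table, candidate_columns, outcome = "label",
                             folds = 5, repeats = 10, select = TRUE,
                             threshold = 4, n_perm = 10000, seed = 1) {
  if (n_perm < 100) warning("fewer than 100 permutations; p-value is unstable")
  obs <- repeated_cv(table, candidate_columns, outcome, folds, repeats,
                     select, threshold, seed = child_seed(seed, 0))
  null_acc <- numeric(n_perm)
  perm_table <- table
  for (b in seq_len(n_perm)) {
    set.seed(child_seed(seed, 2 * b - 1))
    perm_table[[outcome]] <- sample(table[[outcome]])
    null_acc[b] <- repeated_cv(perm_table, candidate_columns, outcome, folds,
                               repeats, select, threshold,
                               seed = child_seed(seed, 2 * b))$accuracy
  }
  structure(list(observed = obs$accuracy, null = null_acc,
                 p = mean(null_acc >= obs$accuracy), n_perm = n_perm,
                 seed = seed, cv = obs),
            class = "minfa_perm")
}

#' @export
print.minfa_perm <- function(x, ...) {
  p_txt <- if (x$p == 0) sprintf("< %g", 1 / x$n_perm) else sprintf("%.4g", x$p)
  cat(sprintf("<minfa_perm> observed %.1f%%, p = %s (%d permutations)\n",
              x$observed, p_txt, x$n_perm))
  invisible(x)
}

#' Exact binomial tail probability
#'
#' One-sided exact test of k successes in n trials against success
#' probability `p0`: `P(X >= k)` for `X ~ Binomial(n, p0)`. The
#' two-sided variant doubles the smaller tail (capped at 1).
#'
#' @param k successes (0..n).
#' @param n trials.
#' @param p0 null success probability (default 0.5).
#' @param one_sided default `TRUE` (upper tail).
#' @return the p-value.
#' @export
binomial_test <- function(k, n, p0 = 0.5, one_sided = TRUE) {
  if (k < 0 || k > n) stop("k must be in 0..n")
  upper <- stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
  if (one_sided) return(upper)
  lower <- stats::pbinom(k, n, p0)
  min(1, 2 * min(upper, lower))
}

#' Pearson correlation with t-based p-value
#'
#' Sample Pearson correlation and its two-sided p-value from
#' `t = r sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors, length >= 3, finite, non-constant.
#' @return list with `r` and `p`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) < 3 || length(x) != length(y)) stop("need n >= 3 paired values")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance")
  r <- stats::cor(x, y)
  n <- length(x)
  tstat <- r * sqrt((n - 2) / max(1 - r^2, 1e-15))
  list(r = r, p = 2 * stats::pt(-abs(tstat), n - 2))
}

#' Run a suite of SLDA analyses
#'
#' Reproduces the structure of a multi-analysis report: each analysis
#' names an outcome column, a candidate set, and whether CAT selection is
#' applied (fixed-subset analyses use every listed variable, "All"). For
#' each analysis the repeated-CV accuracy and its permutation p-value are
#' computed; the reported selected variables come from CAT selection on
#' the full table (or "All" when selection is off).
#'
#' @param table a cohort data.frame.
#' @param analyses list of analysis specs: each a list with `id`,
#'   `outcome`, `candidates` (column names), and `select` (logical).
#' @param n_perm permutations per analysis.
#' @param repeats CV repeats.
#' @param seed master seed.
#' @return data.frame with one row per analysis: `analysis`, `outcome`,
#'   `n_candidates`, `selected`, `accuracy`, `p`.
#' @export
run_analysis_suite <- function(table, analyses, n_perm = 10000, repeats = 10,
                               seed = 1) {
  rows <- lapply(seq_along(analyses), function(i) {
    an <- analyses[[i]]
    pt <- permutation_test(table, an$candidates, outcome = an$outcome,
                           repeats = repeats, select = an$select,
                           n_perm = n_perm, seed = child_seed(seed, i))
    sel_txt <- if (an$select) {
      x <- encode_candidates(table, an$candidates)
      y <- droplevels(as.factor(table[[an$outcome]]))
      set.seed(child_seed(seed, 1000 + i))
      sel <- crossval_select(x, y, folds = 5, repeats = repeats)$included
      if (length(sel) == 0) "(none)" else paste(an$candidates[sel], collapse = "; ")
    } else "All"
    data.frame(analysis = an$id %||% i, outcome = an$outcome,
               n_candidates = length(an$candidates), selected = sel_txt,
               accuracy = pt$observed, p = pt$p)
  })
  do.call(rbind, rows)
}
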