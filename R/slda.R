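#' Shrinkage moments for two-class discriminant analysis
#'
#' Class means plus James-Stein-type shrinkage estimates of the pooled
#' feature variances and the feature correlation matrix, usable when
#' features outnumber samples. Correlations are shrunk toward the
#' identity and variances toward their median, each with the analytic
#' MSE-minimizing intensity estimated from the data (Schafer-Strimmer
#' family), clipped to \[0, 1\]:
#' \deqn{P^* = (1 - \lambda_{corr}) R + \lambda_{corr} I}
#' \deqn{v^*_j = \lambda_{var}\,median(v) + (1 - \lambda_{var}) v_j}
#'
#' @param x numeric matrix, samples x features.
#' @param y binary labels (factor/character); level order fixes the sign
#'   of mean differences.
#' @param lambda_corr,lambda_var optional forced intensities in \[0, 1\]
#'   (used by equivalence tests; `NULL` = estimate).
#' @return list with `means` (2 x p), `n` (per-class counts),
#'   `variances` (shrunk, length p), `corr` (P*, p x p),
#'   `lambda = c(corr, var)`, `classes`.
#' @export
shrink_moments <- function(x, y, lambda_corr = NULL, lambda_var = NULL) {
  x <- as.matrix(x)
  y <- as.factor(y)
  if (nlevels(y) != 2) stop("two classes required")
  n <- nrow(x); p <- ncol(x)
  if (n < 4) stop("need at least 4 samples")
  cls <- levels(y)
  n1 <- sum(y == cls[1]); n2 <- n - n1
  if (n1 == 0 || n2 == 0) stop("both classes must be present")
  m1 <- colMeans(x[y == cls[1], , drop = FALSE])
  m2 <- colMeans(x[y == cls[2], , drop = FALSE])
  xc <- x
  xc[y == cls[1], ] <- sweep(x[y == cls[1], , drop = FALSE], 2, m1)
  xc[y == cls[2], ] <- sweep(x[y == cls[2], , drop = FALSE], 2, m2)
  df <- n - 2

  v <- colSums(xc^2) / df
  const <- which(v <= 1e-12)
  if (length(const) > 0) {
    warning(sprintf("%d constant feature(s); variance floored", length(const)))
    v[const] <- 1e-12
  }

  # variance shrinkage toward the median
  if (is.null(lambda_var)) {
    w <- xc^2
    wbar <- colMeans(w)
    var_v <- n / (n - 1)^3 * colSums(sweep(w, 2, wbar)^2) * (n / df)^2
    denom <- sum((v - stats::median(v))^2)
    lambda_var <- if (denom > 0) min(1, max(0, sum(var_v) / denom)) else 0
  }
  v_star <- lambda_var * stats::median(v) + (1 - lambda_var) * v

  # correlation shrinkage toward the identity
  xs <- sweep(xc, 2, sqrt(v), `/`)
  r <- crossprod(xs) / df
  diag(r) <- 1
  if (p == 1) {
    lambda_corr <- lambda_corr %||% 0
    p_star <- matrix(1, 1, 1)
  } else {
    if (is.null(lambda_corr)) {
      s2 <- crossprod(xs^2)              # sum_k w_kij^2
      wbar <- (df / n) * r               # mean_k w_kij
      var_r <- n / (n - 1)^3 * (s2 - n * wbar^2)
      diag(var_r) <- 0
      off <- r; diag(off) <- 0
      denom <- sum(off^2)
      lambda_corr <- if (denom > 0) min(1, max(0, sum(var_r) / denom)) else 0
    }
    p_star <- (1 - lambda_corr) * r
    diag(p_star) <- 1
  }

  list(means = rbind(m1, m2), n = c(n1, n2), variances = v_star,
       corr = p_star, lambda = c(corr = lambda_corr, var = lambda_var),
       classes = cls)
}

#' Correlation-adjusted t-scores
#'
#' Decorrelated two-class t-scores: the ordinary (shrunk-variance)
#' t-score vector multiplied by the inverse square root of the shrunk
#' correlation matrix,
#' \deqn{\tau = (P^*)^{-1/2} t, \quad
#'       t_j = (m_{1j} - m_{2j}) / (s^*_j \sqrt{1/n_1 + 1/n_2}).}
#' Under an identity correlation \eqn{\tau = t} exactly; correlated
#' informative features share their discriminative mass.
#'
#' @param moments output of [shrink_moments()].
#' @return numeric vector of CAT scores, one per feature, with the plain
#'   t-scores in `attr(, "t")`.
#' @export
cat_scores <- function(moments) {
  se <- sqrt(moments$variances) * sqrt(1 / moments$n[1] + 1 / moments$n[2])
  t_scores <- (moments$means[1, ] - moments$means[2, ]) / se
  p <- length(t_scores)
  if (p == 1) {
    tau <- t_scores
  } else {
    eg <- eigen(moments$corr, symmetric = TRUE)
    if (min(eg$values) <= 0) stop("shrunk correlation matrix is not positive-definite")
    inv_sqrt <- eg$vectors %*% (t(eg$vectors) / sqrt(eg$values))
    tau <- drop(inv_sqrt %*% t_scores)
  }
  names(tau) <- colnames(moments$means) %||% names(t_scores)
  attr(tau, "t") <- t_scores
  tau
}

#' Cross-validated CAT-score variable selection
#'
#' Within each training fold the CAT scores of all candidate features are
#' computed; a feature is included when its mean absolute CAT score over
#' all folds and repeats exceeds `threshold` (default 4). The threshold
#' is applied to |tau| so that negative-effect features remain eligible.
#'
#' @param x samples x features matrix.
#' @param y binary labels.
#' @param folds number of stratified folds (default 5).
#' @param repeats fold-structure repeats (default 1).
#' @param threshold inclusion threshold on mean |tau| (default 4).
#' @return list (`"minfa_selection"`): `mean_abs_tau` per feature,
#'   `included` (integer indices), `inclusion_freq` (fraction of folds
#'   with |tau| > threshold).
#' @export
crossval_select <- function(x, y, folds = 5, repeats = 1, threshold = 4) {
  x <- as.matrix(x)
  y <- as.factor(y)
  p <- ncol(x)
  acc <- numeric(p); hits <- numeric(p); n_folds <- 0
  for (rep in seq_len(repeats)) {
    fid <- stratified_folds(y, folds)
    for (f in sort(unique(fid))) {
      tr <- fid != f
      tau <- abs(cat_scores(shrink_moments(x[tr, , drop = FALSE], y[tr])))
      acc <- acc + tau
      hits <- hits + (tau > threshold)
      n_folds <- n_folds + 1
    }
  }
  mean_abs_tau <- acc / n_folds
  names(mean_abs_tau) <- colnames(x)
  structure(list(mean_abs_tau = mean_abs_tau,
                 included = which(mean_abs_tau > threshold),
                 inclusion_freq = hits / n_folds,
                 threshold = threshold),
            class = "minfa_selection")
}

#' Fit a shrinkage linear discriminant model
#'
#' LDA on the selected features with the shrunk covariance
#' \eqn{\Sigma^* = D^{1/2} P^* D^{1/2}} (D = diagonal of shrunk
#' variances). Discriminant for class k:
#' \deqn{\delta_k(x) = \mu_k' \Sigma^{*-1} x - \tfrac12 \mu_k' \Sigma^{*-1} \mu_k + \log \pi_k}
#' with empirical class frequencies as priors. An empty selection yields
#' a majority-class model (every prediction is the larger training
#' class), so permutation reruns remain well-defined.
#'
#' @param x samples x features matrix (all candidates).
#' @param y binary labels.
#' @param selected integer indices of selected features (possibly empty).
#' @param lambda_corr,lambda_var optional forced shrinkage intensities.
#' @return object of class `"minfa_slda"`.
#' @export
fit_slda <- function(x, y, selected, lambda_corr = NULL, lambda_var = NULL) {
  x <- as.matrix(x)
  y <- as.factor(y)
  cls <- levels(y)
  priors <- as.numeric(table(y)[cls]) / length(y)
  if (length(selected) == 0) {
    maj <- cls[which.max(priors)]
    return(structure(list(empty = TRUE, majority = maj, classes = cls,
                          priors = priors, selected = integer(0)),
                     class = "minfa_slda"))
  }
  xs <- x[, selected, drop = FALSE]
  mom <- shrink_moments(xs, y, lambda_corr = lambda_corr,
                        lambda_var = lambda_var)
  d_half <- sqrt(mom$variances)
  sigma <- sweep(sweep(mom$corr, 1, d_half, `*`), 2, d_half, `*`)
  omega <- solve(sigma)
  structure(list(empty = FALSE, moments = mom, omega = omega,
                 classes = cls, priors = priors, selected = selected),
            class = "minfa_slda")
}

#' @rdname fit_slda
#' @param model a `"minfa_slda"`.
#' @param newx matrix (or vector) of observations over the same candidate
#'   columns the model was fitted with.
#' @return `predict_slda`: data.frame with `class` and the posterior
#'   probability of each class.
#' @export
predict_slda <- function(model, newx) {
  newx <- rbind(newx)
  if (model$empty) {
    post <- matrix(rep(model$priors, each = nrow(newx)), nrow(newx))
    colnames(post) <- model$classes
    return(data.frame(class = rep(model$majority, nrow(newx)), post,
                      check.names = FALSE))
  }
  if (max(model$selected) > ncol(newx)) stop("feature mismatch at predict time")
  xs <- newx[, model$selected, drop = FALSE]
  mu <- model$moments$means
  delta <- sapply(1:2, function(k) {
    drop(xs %*% (model$omega %*% mu[k, ])) -
      0.5 * drop(mu[k, ] %*% model$omega %*% mu[k, ]) + log(model$priors[k])
  })
  delta <- rbind(delta)
  post <- exp(delta - apply(delta, 1, max))
  post <- post / rowSums(post)
  colnames(post) <- model$classes
  data.frame(class = model$classes[max.col(delta, ties.method = "first")],
             post, check.names = FALSE)
}

#' Partial correlations of selected features with a continuous outcome
#'
#' For each selected feature, the Pearson correlation between the
#' feature's residuals and the outcome's residuals after regressing both
#' (with intercept) on the remaining selected features. The p-value uses
#' a t reference with `n - 2 - (k - 1)` degrees of freedom, k = number of
#' selected features. With a single selected feature this reduces to the
#' plain Pearson correlation.
#'
#' @param x_selected matrix of the selected features (samples x k).
#' @param score continuous outcome vector.
#' @return data.frame with `feature`, `partial_r`, `p`.
#' @export
partial_correlations <- function(x_selected, score) {
  x_selected <- as.matrix(x_selected)
  n <- nrow(x_selected); k <- ncol(x_selected)
  if (n != length(score)) stop("outcome length mismatch")
  out <- data.frame(feature = colnames(x_selected) %||% paste0("f", seq_len(k)),
                    partial_r = NA_real_, p = NA_real_)
  for (j in seq_len(k)) {
    ctrl <- cbind(1, x_selected[, -j, drop = FALSE])
    qr_c <- qr(ctrl)
    if (qr_c$rank < ncol(ctrl)) stop("collinear control variables")
    res_f <- qr.resid(qr_c, x_selected[, j])
    res_s <- qr.resid(qr_c, score)
    r <- stats::cor(res_f, res_s)
    df <- n - 2 - (k - 1)
    if (df < 1) stop("not enough observations for partial correlation")
    tstat <- r * sqrt(df / max(1 - r^2, 1e-15))
    out$partial_r[j] <- r
    out$p[j] <- 2 * stats::pt(-abs(tstat), df)
  }
  out
}

#' Serialize / restore an SLDA model as JSON
#' @param model a `"minfa_slda"`.
#' @param path JSON file path.
#' @return `path` invisibly; `read_slda_json` returns the model.
#' @export
write_slda_json <- function(model, path) {
  obj <- unclass(model)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_slda_json
#' @export
read_slda_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_mat <- function(m, nr) {
    if (is.matrix(m)) m else matrix(unlist(m), nrow = nr, byrow = TRUE)
  }
  if (!obj$empty) {
    k <- length(obj$selected)
    obj$omega <- as_mat(obj$omega, k)
    obj$moments$means <- as_mat(obj$moments$means, 2)
    obj$moments$corr <- as_mat(obj$moments$corr, k)
  }
  structure(obj, class = "minfa_slda")
}
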