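test_that("shrunk correlations approach identity for abundant independent data", {
  set.seed(1)
  devs <- vapply(1:5, function(i) {
    x <- matrix(rnorm(2000 * 5), 2000, 5)
    y <- rep(c("a", "b"), 1000)
    mom <- shrink_moments(x, y)
    max(abs(mom$corr - diag(5)))
  }, 0)
  expect_true(all(devs < 0.1))
  # with genuine correlation and abundant data the intensity vanishes,
  # so the shrunk matrix tracks the sample correlation
  f <- rnorm(2000)
  xc <- cbind(f + rnorm(2000, sd = 0.5), f + rnorm(2000, sd = 0.5),
              rnorm(2000))
  momc <- shrink_moments(xc, rep(c("a", "b"), 1000))
  expect_lt(momc$lambda["corr"], 0.1)
  expect_gt(momc$corr[1, 2], 0.7)
})

test_that("shrinkage pulls perfect correlation off one and handles degenerate input", {
  set.seed(2)
  base <- rnorm(8)
  x <- cbind(base, base) + 0  # two perfectly correlated features
  y <- rep(c("a", "b"), 4)
  mom <- shrink_moments(x, y)
  expect_lt(mom$corr[1, 2], 1)
  expect_gte(mom$lambda["corr"], 0)

  mom1 <- shrink_moments(matrix(rnorm(12), 12, 1), rep(c("a", "b"), 6))
  expect_equal(mom1$corr, matrix(1, 1, 1))
  expect_equal(unname(mom1$lambda["corr"]), 0)

  expect_warning(shrink_moments(cbind(rnorm(8), rep(5, 8)), rep(c("a", "b"), 4)),
                 "constant")
  expect_error(shrink_moments(matrix(rnorm(8), 2), c("a", "b")), "4 samples")
})

test_that("CAT scores equal t-scores under identity correlation", {
  set.seed(3)
  x <- matrix(rnorm(40 * 6), 40, 6)
  x[1:20, 2] <- x[1:20, 2] + 1.5
  y <- rep(c("a", "b"), each = 20)
  mom <- shrink_moments(x, y, lambda_corr = 1)  # P* = I
  tau <- cat_scores(mom)
  expect_equal(as.numeric(tau), as.numeric(attr(tau, "t")), tolerance = 1e-12)
  expect_equal(unname(sign(tau[2])),
               unname(sign(mom$means[1, 2] - mom$means[2, 2])))
})

test_that("correlated duplicate features share CAT mass, matching the closed form", {
  set.seed(4)
  n <- 30
  base <- rnorm(n) + rep(c(1, 0), each = n / 2)
  x <- cbind(base + rnorm(n, sd = 0.05), base + rnorm(n, sd = 0.05))
  y <- rep(c("a", "b"), each = n / 2)
  mom <- shrink_moments(x, y)
  tau <- cat_scores(mom)
  t_sc <- attr(tau, "t")
  expect_true(all(abs(tau) < abs(t_sc)))
  # 2x2 closed-form inverse square root of P* = [[1, r], [r, 1]]
  r <- mom$corr[1, 2]
  al <- (1 / sqrt(1 + r) + 1 / sqrt(1 - r)) / 2
  be <- (1 / sqrt(1 + r) - 1 / sqrt(1 - r)) / 2
  oracle <- c(al * t_sc[1] + be * t_sc[2], be * t_sc[1] + al * t_sc[2])
  expect_equal(as.numeric(tau), oracle, tolerance = 1e-9)
})

test_that("CAT scores are affine-invariant up to the variance-shrinkage target", {
  set.seed(5)
  x <- matrix(rnorm(30 * 4), 30, 4)
  x[1:15, 1] <- x[1:15, 1] + 2
  y <- rep(c("a", "b"), each = 15)
  # common affine rescaling never changes tau
  tau1 <- cat_scores(shrink_moments(x, y))
  tau_c <- cat_scores(shrink_moments(2.5 * x + 7, y))
  expect_equal(as.numeric(tau1), as.numeric(tau_c), tolerance = 1e-9)
  # per-feature rescaling is invariant once the (scale-sensitive)
  # median-target variance shrinkage is held fixed
  x2 <- sweep(sweep(x, 2, c(3, 0.2, 10, 1), `*`), 2, c(-5, 2, 0, 100), `+`)
  tau_a <- cat_scores(shrink_moments(x, y, lambda_var = 0))
  tau_b <- cat_scores(shrink_moments(x2, y, lambda_var = 0))
  expect_equal(as.numeric(tau_a), as.numeric(tau_b), tolerance = 1e-9)
})

test_that("label swap negates CAT scores and swaps discriminant predictions", {
  set.seed(6)
  x <- matrix(rnorm(24 * 3), 24, 3)
  x[1:12, 1] <- x[1:12, 1] + 2
  y <- rep(c("a", "b"), each = 12)
  y_sw <- ifelse(y == "a", "b", "a")
  tau <- cat_scores(shrink_moments(x, y))
  tau_sw <- cat_scores(shrink_moments(x, y_sw))
  expect_equal(as.numeric(tau), -as.numeric(tau_sw), tolerance = 1e-12)
  m <- fit_slda(x, y, 1:3)
  m_sw <- fit_slda(x, y_sw, 1:3)
  expect_equal(predict_slda(m, x)$class,
               unname(c(a = "b", b = "a")[predict_slda(m_sw, x)$class]))
})

test_that("selection stays empty on noise, fires on a strong feature, and obeys limits", {
  hits_null <- vapply(1:20, function(s) {
    set.seed(s)
    x <- matrix(rnorm(40 * 48), 40, 48)
    y <- rep(c("a", "b"), 20)
    length(crossval_select(x, y)$included) == 0
  }, TRUE)
  expect_gte(mean(hits_null), 0.9)

  hits_sig <- vapply(1:20, function(s) {
    set.seed(100 + s)
    x <- matrix(rnorm(40 * 10), 40, 10)
    y <- rep(c("a", "b"), each = 20)
    x[y == "a", 4] <- x[y == "a", 4] + 3
    4 %in% crossval_select(x, y)$included
  }, TRUE)
  expect_gte(mean(hits_sig), 0.95)

  set.seed(7)
  x <- matrix(rnorm(40 * 6), 40, 6)
  sel0 <- crossval_select(x, rep(c("a", "b"), 20), threshold = 0)
  expect_equal(sel0$included, 1:6)
})

test_that("SLDA with zero shrinkage equals classical pooled-covariance LDA", {
  set.seed(8)
  x <- matrix(rnorm(60 * 4), 60, 4)
  x[1:30, 1:2] <- x[1:30, 1:2] + 1
  y <- rep(c("a", "b"), each = 30)
  m <- fit_slda(x, y, 1:4, lambda_corr = 0, lambda_var = 0)
  pred <- predict_slda(m, x)$class
  # independent classical-LDA oracle from pooled-covariance algebra
  m1 <- colMeans(x[y == "a", ]); m2 <- colMeans(x[y == "b", ])
  xc <- rbind(sweep(x[y == "a", ], 2, m1), sweep(x[y == "b", ], 2, m2))
  sp <- crossprod(xc) / (60 - 2)
  w <- solve(sp, m1 - m2)
  scores <- drop(x %*% w) - sum(w * (m1 + m2)) / 2
  oracle <- ifelse(scores > 0, "a", "b")
  expect_equal(pred, oracle)
})

test_that("SLDA with full correlation shrinkage equals diagonal discriminant analysis", {
  set.seed(9)
  x <- matrix(rnorm(50 * 5), 50, 5)
  x[1:25, 3] <- x[1:25, 3] + 1.2
  y <- rep(c("a", "b"), each = 25)
  m <- fit_slda(x, y, 1:5, lambda_corr = 1)
  pred <- predict_slda(m, x)$class
  # diagonal oracle with the model's own shrunk variances
  v <- m$moments$variances
  m1 <- m$moments$means[1, ]; m2 <- m$moments$means[2, ]
  d1 <- colSums((t(x) - m1)^2 / v); d2 <- colSums((t(x) - m2)^2 / v)
  oracle <- ifelse(d1 < d2, "a", "b")
  expect_equal(pred, oracle)
})

test_that("prediction at a class mean returns that class with posterior above half", {
  set.seed(10)
  x <- matrix(rnorm(40 * 3), 40, 3)
  x[1:20, ] <- x[1:20, ] + 1
  y <- rep(c("a", "b"), each = 20)
  m <- fit_slda(x, y, 1:3)
  pr <- predict_slda(m, rbind(m$moments$means[1, ]))
  expect_equal(pr$class, "a")
  expect_gt(pr$a, 0.5)
  expect_error(predict_slda(m, matrix(1, 1, 2)), "mismatch")
})

test_that("empty selection falls back to the training majority class", {
  set.seed(11)
  x <- matrix(rnorm(21 * 5), 21, 5)
  y <- c(rep("low", 11), rep("high", 10))
  m <- fit_slda(x, y, integer(0))
  expect_true(m$empty)
  expect_true(all(predict_slda(m, x)$class == "low"))
})

test_that("two informative regions carry the top CAT ranks in most cohorts", {
  info <- c("Genu of corpus callosum" = 1.5, "Tapetum L" = 1.5)
  hit <- vapply(1:25, function(s) {
    ch <- generate_fa_cohort(cohort_sim_config(
      n_subjects = 40, informative_regions = info, seed = 700 + s))
    regions <- attr(ch, "region_names")
    set.seed(800 + s)
    sel <- crossval_select(as.matrix(ch[, regions]), ch$label, folds = 5)
    ranked <- names(sort(sel$mean_abs_tau, decreasing = TRUE))
    all(names(info) %in% ranked[1:2])
  }, TRUE)
  expect_gte(mean(hit), 0.80)
})

test_that("partial correlations reduce to Pearson and match a normal-equations oracle", {
  set.seed(12)
  x1 <- matrix(rnorm(30), 30, 1, dimnames = list(NULL, "f1"))
  s <- rnorm(30)
  pc <- partial_correlations(x1, s)
  expect_equal(pc$partial_r, cor(x1[, 1], s), tolerance = 1e-12)
  expect_equal(pc$p, pearson_cor(x1[, 1], s)$p, tolerance = 1e-9)

  expect_equal(partial_correlations(x1, x1[, 1])$partial_r, 1)

  # 3-variable toy: residuals solved by explicit normal equations
  x <- cbind(f1 = rnorm(25), f2 = rnorm(25))
  sc <- 0.5 * x[, 1] - 0.3 * x[, 2] + rnorm(25)
  pc2 <- partial_correlations(x, sc)
  for (j in 1:2) {
    ctrl <- cbind(1, x[, -j])
    beta_f <- solve(t(ctrl) %*% ctrl, t(ctrl) %*% x[, j])
    beta_s <- solve(t(ctrl) %*% ctrl, t(ctrl) %*% sc)
    r_manual <- cor(x[, j] - ctrl %*% beta_f, sc - ctrl %*% beta_s)
    expect_equal(pc2$partial_r[j], as.numeric(r_manual), tolerance = 1e-9)
  }
  dup <- cbind(f1 = x[, 1], f2 = x[, 1], f3 = x[, 2])
  expect_error(partial_correlations(dup, sc), "collinear")
})

test_that("SLDA models survive a JSON round trip", {
  set.seed(13)
  x <- matrix(rnorm(30 * 4), 30, 4)
  x[1:15, 2] <- x[1:15, 2] + 2
  y <- rep(c("a", "b"), each = 15)
  m <- fit_slda(x, y, c(2L, 4L))
  path <- tempfile(fileext = ".json")
  write_slda_json(m, path)
  m2 <- read_slda_json(path)
  expect_equal(predict_slda(m2, x)$class, predict_slda(m, x)$class)
  unlink(path)
})
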