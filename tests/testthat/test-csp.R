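# Average trace-normalized class covariance, recomputed independently of
# the package internals for oracle use.
oracle_class_cov <- function(ep) {
  n_ch <- dim(ep$data)[2]
  acc <- matrix(0, n_ch, n_ch)
  for (i in seq_len(dim(ep$data)[1])) {
    x <- ep$data[i, , ]
    x <- x - rowMeans(x)
    cc <- x %*% t(x)
    acc <- acc + cc / sum(diag(cc))
  }
  acc / dim(ep$data)[1]
}

test_that("CSP solves the separable two-channel construction", {
  set.seed(1)
  n <- 20; n_samp <- 200
  left <- array(0, dim = c(n, 2, n_samp))
  right <- array(0, dim = c(n, 2, n_samp))
  left[, 1, ] <- rnorm(n * n_samp)   # class-left variance only on ch1
  right[, 2, ] <- rnorm(n * n_samp)  # class-right variance only on ch2
  # tiny jitter keeps per-epoch covariances full-rank
  left <- left + array(rnorm(length(left), sd = 1e-4), dim = dim(left))
  right <- right + array(rnorm(length(right), sd = 1e-4), dim = dim(right))
  m <- fit_csp(make_epochs(left, rep("left", n), 100),
               make_epochs(right, rep("right", n), 100))
  expect_equal(m$eigenvalues, c(1, 0), tolerance = 1e-3)
  # top filter ~ e1, bottom ~ e2 (up to scale)
  top <- abs(m$filters[1, ]) / max(abs(m$filters[1, ]))
  bot <- abs(m$filters[2, ]) / max(abs(m$filters[2, ]))
  expect_lt(top[2], 0.05)
  expect_lt(bot[1], 0.05)
})

test_that("identical class covariances give eigenvalues of one half", {
  set.seed(2)
  dat <- array(rnorm(12 * 3 * 150), dim = c(12, 3, 150))
  ep_l <- make_epochs(dat, rep("left", 12), 100)
  ep_r <- make_epochs(dat, rep("right", 12), 100)
  m <- fit_csp(ep_l, ep_r)
  expect_equal(m$eigenvalues, rep(0.5, 3), tolerance = 1e-6)
})

test_that("CSP eigenvalues match a brute-force characteristic-polynomial oracle", {
  set.seed(3)
  for (case in 1:5) {
    mk <- function() {
      a <- matrix(rnorm(16), 4)
      dat <- array(0, dim = c(10, 4, 120))
      for (i in 1:10) dat[i, , ] <- a %*% matrix(rnorm(4 * 120), 4)
      make_epochs(dat, rep("left", 10), 100)
    }
    l <- mk(); r <- mk()
    m <- fit_csp(l, r)
    # independent oracle: roots of det(S_l - lambda * (S_l + S_r)) = 0,
    # coefficients recovered by evaluating the determinant at 5 points
    s_l <- oracle_class_cov(l); s_p <- s_l + oracle_class_cov(r)
    pts <- seq(-0.2, 1.2, length.out = 5)
    dets <- vapply(pts, function(lm) det(s_l - lm * s_p), 0)
    coef <- solve(outer(pts, 0:4, `^`), dets)
    roots <- sort(Re(polyroot(coef)), decreasing = TRUE)
    expect_equal(m$eigenvalues, roots, tolerance = 1e-6)
  }
})

test_that("CSP is scale invariant and lambda pairs sum to one across class swap", {
  set.seed(4)
  mk <- function(a, scl = 1) {
    dat <- array(0, dim = c(8, 3, 100))
    for (i in 1:8) dat[i, , ] <- scl * (a %*% matrix(rnorm(300), 3))
    make_epochs(dat, rep("left", 8), 100)
  }
  a1 <- matrix(rnorm(9), 3); a2 <- matrix(rnorm(9), 3)
  set.seed(5); l <- mk(a1); set.seed(6); r <- mk(a2)
  set.seed(5); l5 <- mk(a1, 5); set.seed(6); r5 <- mk(a2, 5)
  m <- fit_csp(l, r)
  m5 <- fit_csp(l5, r5)
  expect_equal(m$eigenvalues, m5$eigenvalues, tolerance = 1e-9)
  # filters equal up to sign/scale
  for (k in 1:3) {
    cosang <- abs(sum(m$filters[k, ] * m5$filters[k, ])) /
      sqrt(sum(m$filters[k, ]^2) * sum(m5$filters[k, ]^2))
    expect_equal(cosang, 1, tolerance = 1e-6)
  }
  swapped <- fit_csp(r, l)
  expect_equal(swapped$eigenvalues, rev(1 - m$eigenvalues), tolerance = 1e-6)
})

test_that("filter selection honors candidates, plausibility and degenerate fallbacks", {
  set.seed(8)
  dat <- array(rnorm(10 * 8 * 100), dim = c(10, 8, 100))
  l <- make_epochs(dat, rep("left", 10), 100)
  dat2 <- array(rnorm(10 * 8 * 100), dim = c(10, 8, 100))
  r <- make_epochs(dat2, rep("right", 10), 100)
  m <- fit_csp(l, r)
  sel <- select_filters(m)
  expect_equal(sel$left, 1)
  expect_equal(sel$right, 8)
  sel2 <- select_filters(m, motor_channels = 1:8)
  expect_true(sel2$left %in% 1:3)
  expect_true(sel2$right %in% 6:8)

  dat3 <- array(rnorm(10 * 2 * 100), dim = c(10, 2, 100))
  m2 <- fit_csp(make_epochs(dat3, rep("left", 10), 100),
                make_epochs(dat3 + array(rnorm(2000, sd = 0.5), dim = dim(dat3)),
                            rep("right", 10), 100))
  expect_warning(sel3 <- select_filters(m2), "fewer components")
  expect_equal(sort(c(sel3$left, sel3$right)), c(1, 2))
})

test_that("selected patterns recover the true lateralized mixing columns", {
  cfg <- eeg_sim_config(n_channels = 16, seed = 5)
  rec <- generate_eeg_session(cfg)
  mix <- attr(rec, "mixing")
  rec_f <- butter_bandpass(rec, 8, 30)
  m <- fit_csp(epoch(rec_f, c(0.5, 4.5), "left"),
               epoch(rec_f, c(0.5, 4.5), "right"))
  sel <- select_filters(m)
  expect_gt(abs(cor(m$patterns[, sel$left], mix[, 1])), 0.9)
  expect_gt(abs(cor(m$patterns[, sel$right], mix[, 2])), 0.9)
})

test_that("apply_csp projects onto filters and reproduces the lambda variance ratio", {
  set.seed(10)
  dat <- array(rnorm(6 * 3 * 80), dim = c(6, 3, 80))
  ep <- make_epochs(dat, rep("left", 6), 100)
  onehot <- apply_csp(ep, matrix(c(0, 1, 0), 1))
  expect_equal(onehot$data[, 1, ], ep$data[, 2, ])
  expect_equal(max(abs(apply_csp(ep, matrix(0, 1, 3))$data)), 0)
  expect_error(apply_csp(ep, matrix(1, 1, 5)), "mismatch")

  # variance ratio of the top virtual channel ~ lambda / (1 - lambda)
  mkcov <- function(a, n) {
    dat <- array(0, dim = c(n, 4, 400))
    for (i in seq_len(n)) dat[i, , ] <- a %*% matrix(rnorm(4 * 400), 4)
    make_epochs(dat, rep("left", n), 100)
  }
  set.seed(11)
  l <- mkcov(diag(c(2, 1, 1, 1)), 40)
  r <- mkcov(diag(c(1, 1, 1, 2)), 40)
  m <- fit_csp(l, r)
  v_l <- mean(apply(apply_csp(l, m$filters[1, , drop = FALSE])$data[, 1, ], 1, var))
  v_r <- mean(apply(apply_csp(r, m$filters[1, , drop = FALSE])$data[, 1, ], 1, var))
  lam <- m$eigenvalues[1]
  expect_equal(v_l / v_r, lam / (1 - lam), tolerance = 0.1)
})
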