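test_that("Wald ratio is the outcome-exposure effect ratio", {
  h <- make_h(beta_exp = 0.5, se_exp = 0.05, beta_out = 0.1, se_out = 0.05)
  r <- mr_wald_ratio(h)
  expect_equal(r$beta, 0.2)
  expect_equal(r$se, 0.1)
  expect_equal(r$method, "wald")
  h0 <- make_h(0.5, 0.05, 0, 0.05)
  r0 <- mr_wald_ratio(h0)
  expect_equal(r0$beta, 0)
  expect_equal(r0$pvalue, 1)
  expect_error(mr_wald_ratio(make_h(0, 0.05, 0.1, 0.05)), "degenerate")
})

test_that("second-order Wald SE tracks the Monte-Carlo SD of the ratio", {
  bx <- 0.5; sx <- 0.05; by <- 0.1; sy <- 0.05
  r <- mr_wald_ratio(make_h(bx, sx, by, sy), second_order = TRUE)
  set.seed(41)
  draws <- rnorm(1e5, by, sy) / rnorm(1e5, bx, sx)
  expect_equal(r$se, sd(draws), tolerance = 0.05)
  # and the second-order SE strictly exceeds the first-order one
  expect_gt(r$se, mr_wald_ratio(make_h(bx, sx, by, sy))$se)
})

test_that("IVW equals the closed-form normal-equations solution", {
  set.seed(42)
  k <- 8
  h <- make_h(beta_exp = rnorm(k, 0.3, 0.1), se_exp = 0.03,
              beta_out = rnorm(k, 0.1, 0.05),
              se_out = runif(k, 0.01, 0.05))
  h$data$se_out <- runif(k, 0.01, 0.05)
  r <- mr_ivw(h)
  # independent brute-force accumulation
  num <- 0; den <- 0
  for (j in seq_len(k)) {
    num <- num + h$data$beta_exp[j] * h$data$beta_out[j] / h$data$se_out[j]^2
    den <- den + h$data$beta_exp[j]^2 / h$data$se_out[j]^2
  }
  expect_equal(r$beta, num / den, tolerance = 1e-12)
  expect_equal(r$n_snps, k)
  expect_true(r$q_df == k - 1)
})

test_that("IVW with two symmetric instruments averages their ratios", {
  h <- make_h(c(1, 1), 0.03, c(0.2, 0.4), c(0.1, 0.1))
  expect_equal(mr_ivw(h)$beta, 0.3)
})

test_that("IVW at k = 1 delegates exactly to the Wald ratio", {
  h <- make_h(0.4, 0.05, 0.12, 0.02)
  expect_equal(mr_ivw(h), mr_wald_ratio(h))
})

test_that("correlated IVW with identity LD reproduces plain IVW", {
  set.seed(43)
  k <- 6
  h <- make_h(rnorm(k, 0.3, 0.1), 0.03, rnorm(k, 0.1, 0.05), 0.02,
              ld = diag(k))
  h$data$se_out <- runif(k, 0.01, 0.05)
  a <- mr_ivw_correlated(h)
  h$ld <- NULL
  b <- mr_ivw(h)
  expect_equal(a$beta, b$beta, tolerance = 1e-12)
  expect_equal(a$se, b$se, tolerance = 1e-12)
  expect_equal(a$q_stat, b$q_stat, tolerance = 1e-10)
})

test_that("correlated IVW matches an explicit GLS solve under AR(1) LD", {
  set.seed(44)
  k <- 5
  R <- simulate_ld(k, 0.6)
  h <- make_h(rnorm(k, 0.3, 0.1), 0.03, rnorm(k, 0.1, 0.05), 0.02, ld = R)
  sy <- runif(k, 0.01, 0.05)
  h$data$se_out <- sy
  r <- mr_ivw_correlated(h)
  Sigma <- diag(sy) %*% R %*% diag(sy)
  Si <- solve(Sigma)
  x <- h$data$beta_exp; y <- h$data$beta_out
  beta <- drop((t(x) %*% Si %*% y) / (t(x) %*% Si %*% x))
  se_fixed <- drop(sqrt(1 / (t(x) %*% Si %*% x)))
  resid <- y - beta * x
  Q <- drop(t(resid) %*% Si %*% resid)
  expect_equal(r$beta, beta, tolerance = 1e-10)
  expect_equal(r$se, se_fixed * sqrt(Q / (k - 1)), tolerance = 1e-10)
})

test_that("duplicated instruments collapse to the single-instrument answer", {
  bx <- 0.4; sy <- 0.02
  R <- matrix(1, 2, 2)
  # same instrument entered twice (outcome betas jittered within noise)
  h <- make_h(c(bx, bx), 0.03, c(0.12, 0.121), c(sy, sy), ld = R)
  r <- mr_ivw_correlated(h)
  wald <- mr_wald_ratio(make_h(bx, 0.03, 0.1205, sy))
  expect_equal(r$beta, wald$beta, tolerance = 1e-3)
  # two copies of one instrument must not manufacture precision
  expect_gte(r$se, wald$se * (1 - 1e-3))
})

test_that("near-singular LD escalates the ridge instead of failing", {
  k <- 3
  R <- matrix(0.999999, k, k); diag(R) <- 1
  h <- make_h(c(0.3, 0.31, 0.29), 0.03, c(0.1, 0.1, 0.09), 0.02, ld = R)
  expect_s3_class(mr_ivw_correlated(h), "tbl_df")
})

test_that("Egger recovers an exact linear relationship", {
  bx <- c(0.2, 0.3, 0.5, 0.7)
  a <- 0.05; b <- 0.4
  h <- make_h(bx, 0.03, a + b * bx, 0.02)
  r <- mr_egger(h)
  expect_equal(r$beta, b, tolerance = 1e-10)
  expect_equal(r$egger_intercept, a, tolerance = 1e-10)
  expect_equal(r$se, 0, tolerance = 1e-8)
})

test_that("Egger equals an independent weighted-least-squares solve", {
  set.seed(45)
  k <- 7
  bx <- abs(rnorm(k, 0.3, 0.1))
  by <- 0.02 + 0.5 * bx + rnorm(k, 0, 0.02)
  sy <- runif(k, 0.01, 0.05)
  h <- make_h(bx, 0.03, by, sy)
  r <- mr_egger(h)
  W <- diag(1 / sy^2)
  X <- cbind(1, bx)
  coefs <- solve(t(X) %*% W %*% X, t(X) %*% W %*% by)
  rss <- sum((by - X %*% coefs)^2 / sy^2)
  covm <- solve(t(X) %*% W %*% X) * rss / (k - 2)
  expect_equal(r$egger_intercept, coefs[1], tolerance = 1e-10)
  expect_equal(r$beta, coefs[2], tolerance = 1e-10)
  expect_equal(r$se, sqrt(covm[2, 2]), tolerance = 1e-10)
  expect_equal(r$egger_intercept_se, sqrt(covm[1, 1]), tolerance = 1e-10)
})

test_that("Egger orients instruments before fitting", {
  set.seed(46)
  k <- 6
  bx <- rnorm(k, 0.3, 0.2)  # mixed signs
  by <- 0.01 + 0.5 * bx + rnorm(k, 0, 0.01)
  sy <- rep(0.02, k)
  h <- make_h(bx, 0.03, by, sy)
  h_flipped <- make_h(-bx, 0.03, -by, sy)
  expect_equal(mr_egger(h)$beta, mr_egger(h_flipped)$beta)
})

test_that("Egger intercept is unbiased under no pleiotropy", {
  set.seed(47)
  hits <- 0
  for (i in 1:500) {
    k <- 10
    bx_true <- runif(k, 0.2, 0.5)
    bx <- bx_true + rnorm(k, 0, 0.01)
    by <- 0.4 * bx_true + rnorm(k, 0, 0.02)
    r <- mr_egger(make_h(bx, 0.01, by, 0.02))
    if (abs(r$egger_intercept) < 3 * r$egger_intercept_se) hits <- hits + 1
  }
  expect_gte(hits / 500, 0.95)
})

test_that("weighted median interpolates the weighted ratio CDF", {
  # all ratios equal
  h <- make_h(c(0.2, 0.4, 0.5), 0.03, c(0.1, 0.2, 0.25), 0.02)
  r <- mr_weighted_median(h, n_boot = 50, seed = 1)
  expect_equal(r$beta, 0.5, tolerance = 1e-12)
  # equal weights: plain median of (0.1, 0.2, 0.9)
  h2 <- make_h(c(1, 1, 1), 0.03, c(0.1, 0.2, 0.9), c(0.1, 0.1, 0.1))
  expect_equal(mr_weighted_median(h2, n_boot = 50, seed = 1)$beta, 0.2)
  expect_error(mr_weighted_median(h2, n_boot = 50), "seed")
})

test_that("weighted median matches the breakpoint-scan oracle", {
  set.seed(48)
  for (rep in 1:20) {
    k <- sample(3:9, 1)
    bx <- rnorm(k, 0.4, 0.15)
    bx[bx == 0] <- 0.1
    by <- rnorm(k, 0.15, 0.1)
    sy <- runif(k, 0.01, 0.08)
    h <- make_h(bx, 0.03, by, sy)
    r <- mr_weighted_median(h, n_boot = 10, seed = rep)
    expect_equal(r$beta,
                 oracle_weighted_median(by / bx, bx^2 / sy^2),
                 tolerance = 1e-10)
  }
})

test_that("weighted median bootstrap is reproducible under a fixed seed", {
  h <- make_h(c(0.2, 0.3, 0.5, 0.6), 0.03,
              c(0.1, 0.1, 0.2, 0.25), c(0.02, 0.03, 0.02, 0.04))
  a <- mr_weighted_median(h, n_boot = 200, seed = 99)
  b <- mr_weighted_median(h, n_boot = 200, seed = 99)
  expect_identical(a$se, b$se)
})

test_that("Steiger keeps instruments explaining more exposure variance", {
  # dominant exposure signal passes
  h <- make_h(1, 0.1, 0.05, 0.05, n_exp = 1000, n_out = 1000)
  st <- steiger_filter(h)
  expect_true(all(st$report$pass))
  # exact tie fails the strict inequality
  h2 <- make_h(0.5, 0.05, 0.5, 0.05, n_exp = 1000, n_out = 1000)
  st2 <- steiger_filter(h2)
  expect_false(any(st2$report$pass))
  expect_equal(st2$status, "all_removed")
  expect_equal(nrow(st2$harmonized$data), 0L)
  expect_error(steiger_filter(h, n_exp = 5), "at least 10")
})

test_that("Steiger r-squared follows the z-based variance decomposition", {
  h <- make_h(0.3, 0.03, 0.01, 0.004, n_exp = 982, n_out = 50000)
  st <- steiger_filter(h)
  z_exp <- 0.3 / 0.03; z_out <- 0.01 / 0.004
  expect_equal(st$report$r2_exp, z_exp^2 / (z_exp^2 + 980))
  expect_equal(st$report$r2_out, z_out^2 / (z_out^2 + 49998))
})

test_that("tiers follow the two-level thresholds", {
  expect_equal(assign_tier(1e-4), "global")
  expect_equal(assign_tier(0.001), "potential")
  expect_equal(assign_tier(0.01), "nonsignificant")
  expect_equal(assign_tier(3e-4), "potential")  # boundary: 0.0003 <= p
  expect_equal(assign_tier(0.003), "nonsignificant")  # boundary: p >= 0.003
  expect_error(assign_tier(0), "0, 1")
  expect_error(assign_tier(1.2), "0, 1")
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(0.02), 0.02)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(49)
  for (rep in 1:10) {
    p <- runif(sample(3:20, 1))
    expect_equal(bh_adjust(p), oracle_bh(p))
  }
  # grouped adjustment is the per-group application
  p <- c(0.01, 0.04, 0.02, 0.5)
  g <- c("a", "a", "b", "b")
  expect_equal(bh_adjust(p, g),
               c(oracle_bh(p[1:2]), oracle_bh(p[3:4])))
})

test_that("causal estimates are scale- and sign-equivariant", {
  set.seed(50)
  k <- 6
  h <- make_h(rnorm(k, 0.3, 0.1), 0.03, rnorm(k, 0.12, 0.05), 0.02)
  base <- mr_ivw(h)
  scaled <- h
  scaled$data$beta_exp <- h$data$beta_exp * 3
  scaled$data$se_exp <- h$data$se_exp * 3
  expect_equal(mr_ivw(scaled)$beta, base$beta / 3)
  negated <- h
  negated$data$beta_out <- -h$data$beta_out
  expect_equal(mr_ivw(negated)$beta, -base$beta)
  expect_equal(mr_ivw(negated)$se, base$se)
})
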