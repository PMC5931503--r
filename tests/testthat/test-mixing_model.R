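src2 <- source_spec(c("A", "B"), mu13C = c(-20, -26), sd13C = c(0, 0),
                    mu15N = c(5, 5), sd15N = c(0, 0))
tef0 <- tef_spec(0, 0, 0, 0)

test_that("log posterior: degenerate mixture puts the likelihood mean on source 1", {
  src <- default_sources(); tef <- default_tef()
  x_at_1 <- c(src$mu13C[1] + tef$mu13C, src$mu15N[1] + tef$mu15N)
  f_deg <- c(30, 0, 0, 0, 0) # softmax ~ (1, 0, 0, 0, 0)
  lp_at <- mixing_log_posterior(f_deg, c(-2, -2), x_at_1, src, tef)
  lp_off <- mixing_log_posterior(f_deg, c(-2, -2), x_at_1 + c(3, 3), src, tef)
  expect_gt(lp_at, lp_off)
  # symmetry: identical zero-spread sources make the likelihood
  # invariant in f (with spread, the p^2-weighted variance still varies)
  same <- source_spec(letters[1:3], mu13C = rep(-23, 3), sd13C = rep(0, 3),
                      mu15N = rep(6, 3), sd15N = rep(0, 3))
  x <- c(-22, 9)
  base <- mixing_log_posterior(c(0, 0, 0), c(0, 0), x, same, tef0)
  shuf <- mixing_log_posterior(c(1, -1, 0), c(0, 0), x, same, tef0)
  prior_diff <- sum(dnorm(c(1, -1, 0), log = TRUE)) -
    sum(dnorm(c(0, 0, 0), log = TRUE))
  expect_equal(shuf - base, prior_diff, tolerance = 1e-10)
})

test_that("R reference log posterior agrees with the compiled core", {
  src <- default_sources(); tef <- default_tef()
  mu <- cbind(src$mu13C, src$mu15N)
  sd2 <- cbind(src$sd13C^2 + tef$sd13C^2, src$sd15N^2 + tef$sd15N^2)
  set.seed(99)
  for (i in 1:25) {
    f <- rnorm(5); ls <- rnorm(2); x <- c(rnorm(1, -22, 2), rnorm(1, 10, 2))
    expect_equal(
      vulturediet:::.cpp_log_posterior(f, ls, x, mu, sd2,
                                       c(tef$mu13C, tef$mu15N)),
      mixing_log_posterior(f, ls, x, src, tef), tolerance = 1e-12)
  }
})

test_that("gelman_rubin behaves at its reference points", {
  expect_equal(gelman_rubin(matrix(0.3, 100, 4)), 1)
  set.seed(1)
  iid <- matrix(rnorm(20000), 5000, 4)
  expect_lt(gelman_rubin(iid), 1.01)
  sep <- cbind(rnorm(500, 0), rnorm(500, 10))
  expect_gt(gelman_rubin(sep), 1.5)
  expect_error(gelman_rubin(matrix(rnorm(100), 100, 1)), "chains")
  expect_error(gelman_rubin(matrix(rnorm(8), 4, 2)), "draws")
})

test_that("summarize_posterior reproduces order-statistics and analytic oracles", {
  cons <- data.frame(territory_id = "A", year = 2012,
                     mean_delta13C = -22, mean_delta15N = 10, n_siblings = 1)
  # constant draws
  const <- array(0.3, c(2, 500, 2))
  post <- fake_posterior(list(const), cons, c("s1", "s2"))
  s <- summarize_posterior(post)
  expect_equal(s$mean, rep(0.3, 2))
  expect_equal(s$q2.5, rep(0.3, 2))
  expect_equal(s$q97.5, rep(0.3, 2))
  expect_equal(s$sd, rep(0, 2))
  # uniform draws: 95% CI ~ (0.025, 0.975); beta(2,2) mean ~ 0.5
  set.seed(3)
  n <- 20000
  arr <- array(NA_real_, c(2, n / 2, 2))
  arr[, , 1] <- runif(n)
  arr[, , 2] <- rbeta(n, 2, 2)
  post <- fake_posterior(list(arr), cons, c("unif", "beta"))
  s <- summarize_posterior(post)
  expect_lt(abs(s$q2.5[s$source == "unif"] - 0.025), 0.005)
  expect_lt(abs(s$q97.5[s$source == "unif"] - 0.975), 0.005)
  expect_equal(s$mean[s$source == "beta"], 0.5,
               tolerance = 3 * sqrt(0.05 / n))
})

test_that("sampler is deterministic given the seed and draws stay on the simplex", {
  cons <- data.frame(territory_id = c("A", "B"), year = 2012,
                     mean_delta13C = c(-22, -23), mean_delta15N = c(10, 8),
                     n_siblings = 1)
  p1 <- small_fit(cons, seed = 5, n_iter = 400, n_burnin = 100)
  p2 <- small_fit(cons, seed = 5, n_iter = 400, n_burnin = 100)
  expect_identical(p1$draws, p2$draws)
  p3 <- small_fit(cons, seed = 6, n_iter = 400, n_burnin = 100)
  expect_false(identical(p1$draws, p3$draws))
  for (arr in p1$draws) {
    sums <- apply(arr, c(1, 2), sum)
    expect_lt(max(abs(sums - 1)), 1e-10)
    expect_true(all(arr > 0 & arr < 1))
  }
  expect_true(all(unlist(p1$sigma) > 0))
})

test_that("two-source noiseless fit matches the linear-inversion oracle", {
  for (p1_true in c(0.25, 0.6)) {
    x1 <- p1_true * (-20) + (1 - p1_true) * (-26)
    cons <- data.frame(territory_id = "T1", year = 2012,
                       mean_delta13C = x1, mean_delta15N = 5, n_siblings = 1)
    spec <- mixing_model_spec(src2, tef0, cons, n_chains = 4, n_iter = 3000,
                              n_burnin = 1000, seed = 3,
                              residual_sd = c(0.01, 0.01))
    fs <- summarize_posterior(sample_posterior(spec))
    expect_equal(fs$mean[fs$source == "A"], p1_true, tolerance = 0.02)
  }
})

test_that("consumer at the TEF-shifted centroid of symmetric sources gets ~1/K", {
  # equilateral source triangle: the 120-degree symmetry permutes sources,
  # so the centroid consumer must load each equally
  ang <- c(90, 210, 330) * pi / 180
  src <- source_spec(c("a", "b", "c"),
                     mu13C = -23 + 2 * cos(ang), sd13C = rep(1, 3),
                     mu15N = 7 + 2 * sin(ang), sd15N = rep(1, 3))
  tef <- tef_spec(1, 0.5, 2, 0.5)
  cons <- data.frame(territory_id = "T", year = 2012,
                     mean_delta13C = mean(src$mu13C) + 1,
                     mean_delta15N = mean(src$mu15N) + 2, n_siblings = 1)
  spec <- mixing_model_spec(src, tef, cons, n_chains = 4, n_iter = 3000,
                            n_burnin = 1000, seed = 9)
  fs <- summarize_posterior(sample_posterior(spec))
  expect_equal(fs$mean, rep(1 / 3, 3), tolerance = 0.08)
})

test_that("prior-only run (huge fixed residual SD) recovers the prior mean", {
  cons <- data.frame(territory_id = "T", year = 2012,
                     mean_delta13C = -22, mean_delta15N = 10, n_siblings = 1)
  spec <- mixing_model_spec(default_sources(), default_tef(), cons,
                            n_chains = 4, n_iter = 3000, n_burnin = 1000,
                            seed = 5, residual_sd = c(1e4, 1e4))
  fs <- summarize_posterior(sample_posterior(spec))
  expect_equal(fs$mean, rep(0.2, 5), tolerance = 0.05)
})

test_that("permuting the source list permutes posterior summaries", {
  src <- default_sources()
  cons <- data.frame(territory_id = "T", year = 2012,
                     mean_delta13C = -22, mean_delta15N = 10, n_siblings = 1)
  perm <- c(3, 1, 5, 2, 4)
  fs1 <- summarize_posterior(sample_posterior(
    mixing_model_spec(src, default_tef(), cons, n_chains = 4,
                      n_iter = 3000, n_burnin = 1000, seed = 2)))
  fs2 <- summarize_posterior(sample_posterior(
    mixing_model_spec(src[perm, ], default_tef(), cons, n_chains = 4,
                      n_iter = 3000, n_burnin = 1000, seed = 12)))
  m1 <- setNames(fs1$mean, fs1$source)
  m2 <- setNames(fs2$mean, fs2$source)
  expect_equal(m2[names(m1)], m1, tolerance = 0.05)
})

test_that("population_diet_summary is the mean/SD of per-consumer means", {
  fs <- data.frame(source = rep("landfill", 2), mean = c(0.2, 0.4))
  out <- population_diet_summary(fs)
  expect_equal(out$mean_pct, 30)
  expect_equal(out$sd_pct, 100 * sd(c(0.2, 0.4)))
  one <- population_diet_summary(data.frame(source = "x", mean = 0.3))
  expect_equal(one$mean_pct, 30)
  expect_equal(one$sd_pct, 0)
  set.seed(4)
  many <- data.frame(source = rep(c("a", "b"), each = 20),
                     mean = runif(40, 0, 0.5))
  out <- population_diet_summary(many)
  expect_equal(out$mean_pct[out$source == "a"],
               100 * mean(many$mean[many$source == "a"]))
  expect_equal(out$sd_pct[out$source == "b"],
               100 * sd(many$mean[many$source == "b"]))
})

test_that("spec validation catches bad settings", {
  cons <- data.frame(territory_id = "T", year = 2012,
                     mean_delta13C = -22, mean_delta15N = 10, n_siblings = 1)
  expect_error(mixing_model_spec(default_sources()[1, ], tef0, cons), "K >= 2")
  expect_error(mixing_model_spec(default_sources(), tef0, cons,
                                 n_iter = 100, n_burnin = 100), "n_iter")
  expect_error(mixing_model_spec(default_sources(), tef0, cons,
                                 residual_sd = c(-1, 1)), "positive")
})
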