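# Stochastic engine: exactness oracles, determinism, LNA validation and the
# noise-buffering machinery.

test_that("birth-death stationary law is Poisson (mean k/g, Fano 1)", {
  s <- birth_death_system(k = 5, g = 0.1) # mean 50
  set.seed(11)
  m <- stationary_moments(s, "ensemble", n_trials = 12000)
  se_mean <- m$se_mean[["x"]]
  expect_lt(abs(m$mean[["x"]] - 50), 3 * se_mean)
  fano <- m$sd[["x"]]^2 / m$mean[["x"]]
  # var(s^2) for Poisson ~ 2 mu^2 + mu; SE of Fano ~ sqrt(2/n) at mu >> 1
  expect_lt(abs(fano - 1), 3 * sqrt(2 / m$n_samples))
  # LNA is exact for this linear system
  l <- lna_moments(s)
  expect_equal(l$mean[["x"]], 50)
  expect_equal(l$cv[["x"]], sqrt(0.1 / 5), tolerance = 1e-12)
})

test_that("fixed seed reproduces the event sequence bit for bit", {
  p <- preset("fig5")$params
  sys <- reaction_system(p)
  for (meth in c("first", "direct")) {
    set.seed(99)
    e1 <- gillespie_events(sys, n_events = 2000, method = meth)
    set.seed(99)
    e2 <- gillespie_events(sys, n_events = 2000, method = meth)
    expect_identical(e1, e2)
  }
})

test_that("first-reaction and direct methods agree distributionally", {
  s <- birth_death_system(k = 2, g = 0.05) # mean 40
  set.seed(21)
  m1 <- stationary_moments(s, "ensemble", n_trials = 4000, engine = "first")
  set.seed(22)
  m2 <- stationary_moments(s, "ensemble", n_trials = 4000, engine = "direct")
  se <- sqrt(m1$se_mean[["x"]]^2 + m2$se_mean[["x"]]^2)
  expect_lt(abs(m1$mean[["x"]] - m2$mean[["x"]]), 3 * se)
  expect_lt(abs(m1$cv[["x"]] - m2$cv[["x"]]),
            3 * sqrt(m1$se_cv[["x"]]^2 + m2$se_cv[["x"]]^2))
})

test_that("two-stage TF noise matches the closed form (LNA exactly, Gillespie within error)", {
  p <- preset("fig5")$params
  cf <- cv_two_stage(p$k_w, p$k_q, p$g_w, p$g_q)
  sys <- tf_reaction_system(p)
  l <- lna_moments(sys)
  expect_equal(l$cv[["q"]], cf$cv_q, tolerance = 1e-10)
  expect_equal(l$mean[["q"]], cf$mean_q, tolerance = 1e-8)
  set.seed(31)
  m <- stationary_moments(sys, "time_average", t_sample = 4e6)
  expect_lt(abs(m$cv[["q"]] - cf$cv_q), 4 * m$se_cv[["q"]] + 0.01)
})

test_that("Gillespie means agree with deterministic steady states for all presets", {
  set.seed(41)
  p5 <- preset("fig5")$params
  qbar <- tf_mean(p5)
  for (top in c("iMSL", "sTF", "tSL")) {
    par <- p5
    par$topology <- top
    par$h_r <- qbar # sensitive regime
    if (top != "sTF") par <- calibrate_repression(par, 0.5, q = qbar)
    sys <- reaction_system(par)
    det <- meanfield_fixed_point(sys)
    m <- stationary_moments(sys, "time_average", t_sample = 1.5e6)
    for (sp in c("r", "p")) {
      tol <- 3 * m$se_mean[[sp]] + 0.02 * det[[sp]] # allowance for nonlinearity
      expect_lt(abs(m$mean[[sp]] - det[[sp]]), tol)
    }
  }
})

test_that("ensemble and time-average designs give consistent moments", {
  p <- preset("fig5")$params
  sys <- tf_reaction_system(p)
  set.seed(51)
  me <- stationary_moments(sys, "ensemble", n_trials = 1500)
  mt <- stationary_moments(sys, "time_average", t_sample = 3e6)
  se <- sqrt(me$se_mean[["q"]]^2 + mt$se_mean[["q"]]^2)
  expect_lt(abs(me$mean[["q"]] - mt$mean[["q"]]), 3.5 * se)
})

test_that("LNA protein noise tracks Gillespie for the full iMSL", {
  set.seed(61)
  p <- preset("fig5")$params
  qbar <- tf_mean(p)
  for (draw in 1:4) {
    par <- p
    par$h_r <- qbar / runif(1, 0.3, 3)
    par <- calibrate_repression(par, runif(1, 0.15, 0.7), q = qbar)
    sys <- reaction_system(par)
    l <- lna_moments(sys)
    m <- stationary_moments(sys, "time_average", t_sample = 2e6)
    expect_lt(abs(l$cv[["p"]] - m$cv[["p"]]) / m$cv[["p"]], 0.15)
  }
})

test_that("TF-rate inversion hits a feasible noise target and rejects the floor", {
  p <- preset("fig5")$params
  p2 <- tf_params_for_cv(p, mean_q = 1000, cv_q = 0.1)
  cf <- cv_two_stage(p2$k_w, p2$k_q, p2$g_w, p2$g_q)
  expect_equal(cf$mean_q, 1000, tolerance = 1e-12)
  expect_equal(cf$cv_q, 0.1, tolerance = 1e-12)
  # CV 10% at mean 40 sits below the Poisson floor 1/sqrt(40)
  expect_error(tf_params_for_cv(p, mean_q = 40, cv_q = 0.1), "Poisson floor")
})

test_that("gamma overlay matches moment algebra and the sTF histogram", {
  expect_equal(gamma_overlay(7, 7), list(shape = 7, scale = 1))
  expect_equal(gamma_overlay(100, 400), list(shape = 25, scale = 4))
  expect_error(gamma_overlay(-1, 2), "positive")
  # KS distance between the empirical stationary law and the moment-matched
  # gamma for a matched sTF at the noise-setting rates
  p <- preset("fig5")$params
  qbar <- tf_mean(p)
  p$h_r <- qbar
  p <- calibrate_repression(p, 0.2, q = qbar)
  stf <- calibrate_matched(p, "sTF", q_op = qbar)
  sys <- reaction_system(stf)
  set.seed(71)
  t_burn <- burn_in_time(sys)
  path <- gillespie_simulate(sys, t_end = t_burn + 2e6,
                             times = seq(t_burn, t_burn + 2e6, by = 2000),
                             method = "direct")
  x <- path$p
  g <- gamma_overlay(mean(x), stats::var(x))
  ks <- suppressWarnings(stats::ks.test(x, stats::pgamma, shape = g$shape,
                                        scale = g$scale))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("co-transcription coupling matters: decoupled option changes correlations", {
  p <- preset("fig5")$params
  qbar <- tf_mean(p)
  p$h_r <- qbar
  p <- calibrate_repression(p, 0.3, q = qbar)
  sys_co <- reaction_system(p, cotranscribed = TRUE)
  sys_de <- reaction_system(p, cotranscribed = FALSE)
  expect_equal(nrow(sys_de$rx), nrow(sys_co$rx) + 1)
  # same mean field
  expect_equal(meanfield_fixed_point(sys_de), meanfield_fixed_point(sys_co),
               tolerance = 1e-8)
  # r-s correlation is weaker without co-transcription (LNA covariances)
  corr <- function(sys) {
    l <- lna_moments(sys)
    i <- match("r", sys$species); j <- match("s", sys$species)
    l$cov[i, j] / sqrt(l$cov[i, i] * l$cov[j, j])
  }
  expect_gt(corr(sys_co), corr(sys_de))
})

test_that("iMSL protein noise is U-shaped in repression with an interior minimum", {
  p <- preset("fig5")$params
  qbar <- tf_mean(p)
  p$h_r <- qbar
  reps <- c(0.05, 0.1, 0.2, 0.3, 0.5, 0.7, 0.9)
  cvs <- vapply(reps, function(rho) {
    par <- calibrate_repression(p, rho, q = qbar)
    lna_moments(reaction_system(par))$cv[["p"]]
  }, numeric(1))
  i_min <- which.min(cvs)
  expect_gt(i_min, 1)
  expect_lt(i_min, length(reps))
  expect_lt(cvs[i_min], cvs[1])
  expect_lt(cvs[i_min], cvs[length(reps)])
})

test_that("iMSL buffers upstream noise over a wider region than the tSL", {
  p <- preset("fig5")$params
  acts <- c(0.3, 1, 3); reps <- c(0.2, 0.5)
  mi <- noise_reduction_map(p, acts, reps, "iMSL", "lna")
  mt <- noise_reduction_map(p, acts, reps, "tSL", "lna")
  expect_true(all(is.na(mi$error)))
  expect_true(all(is.na(mt$error)))
  # point-wise: the iMSL ratio is below the tSL ratio on >= 90% of the grid
  expect_gte(mean(mi$ratio <= mt$ratio), 0.9)
  # and its buffering region (ratio < 1) is at least as large
  expect_gte(sum(mi$ratio < 1), sum(mt$ratio < 1))
})

test_that("LNA converges to Gillespie as copy numbers scale up", {
  # scale all counts by x10 twice via h, h_r, k_w at fixed rates
  p <- preset("fig5")$params
  qbar <- tf_mean(p)
  discrepancy <- sapply(c(0.1, 1, 10), function(scale) {
    par <- p
    par$k_w <- p$k_w * scale
    par$h_r <- qbar * scale # keep <q>/h_r = 1
    par <- calibrate_repression(par, 0.4, q = qbar * scale)
    sys <- reaction_system(par)
    l <- lna_moments(sys)
    set.seed(81)
    m <- stationary_moments(sys, "time_average", t_sample = 2e6)
    abs(l$cv[["p"]] - m$cv[["p"]]) / m$cv[["p"]]
  })
  expect_lt(discrepancy[3], 0.1)
  expect_lt(discrepancy[3], discrepancy[1])
})

test_that("noise map edge case: repression 1 gives ratio 1 (identical circuits)", {
  p <- preset("fig5")$params
  m <- noise_reduction_map(p, 1, 1, "iMSL", "lna")
  expect_equal(m$ratio, 1, tolerance = 1e-6)
})
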