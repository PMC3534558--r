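# Rate laws, half-life conversions, steady states and matched calibration.

test_that("activation rate has the Michaelis-Menten anchor points", {
  expect_equal(activation_rate(0, 1, 10), 0)
  expect_equal(activation_rate(10, 0.7, 10), 0.35)
  # at saturating TF the rate approaches the maximal transcription rate
  expect_equal(activation_rate(1e6 * 5, 0.212819, 5), 0.212819,
               tolerance = 1e-4)
  # Hill generalisation keeps the half-saturation point at q = h_r
  expect_equal(activation_rate(10, 1, 10, n = 4), 0.5)
  expect_error(activation_rate(-1, 1, 10), "non-negative")
  expect_error(activation_rate(1, -1, 10), "positive")
})

test_that("repression factor follows 1/(1 + s/h)", {
  expect_equal(repression_factor(0, 100), 1)
  expect_equal(repression_factor(100, 100), 0.5)
  expect_equal(repression_factor(300, 100), 0.25)
  expect_equal(repression_factor(1e9, Inf), 1)
  expect_error(repression_factor(-1, 10), "non-negative")
})

test_that("rate laws are monotone in their first argument", {
  q <- 10^seq(-3, 6, length.out = 50)
  expect_true(all(diff(activation_rate(q, 0.3, 40)) >= 0))
  expect_true(all(diff(activation_rate(q, 0.3, 40, n = 2)) >= 0))
  expect_true(all(diff(repression_factor(q, 1000)) <= 0))
  expect_true(all(activation_rate(q, 0.3, 40) <= 0.3))
})

test_that("half-life conversions and round trips", {
  expect_equal(halflife_to_rate(1800), log(2) / 1800)
  expect_equal(halflife_to_rate(8 * 3600, "one_over_tau"), 1 / 28800)
  for (conv in c("ln2_over_tau", "one_over_tau")) {
    tau <- c(60, 1800, 28800)
    expect_equal(rate_to_halflife(halflife_to_rate(tau, conv), conv), tau,
                 tolerance = 1e-12)
  }
  expect_error(halflife_to_rate(0), "positive")
  expect_error(halflife_to_rate(-5), "positive")
})

test_that("durations with unit suffixes parse to seconds", {
  expect_equal(parse_duration("30 min"), 1800)
  expect_equal(parse_duration(c("8 h", "90s", "1 day")), c(28800, 90, 86400))
  expect_equal(parse_duration(42), 42)
  expect_error(parse_duration("1 fortnight"), "unknown time unit")
})

test_that("iMSL steady state matches its closed form and limits", {
  p <- fast_imsl()
  q <- 500
  ss <- steady_state(p, q)
  krq <- activation_rate(q, p$k_r, p$h_r)
  expect_equal(ss$state[["r"]], krq / p$g_r)
  expect_equal(ss$state[["s"]], krq / p$g_s)
  expect_equal(ss$state[["p"]],
               p$k_p * krq / p$g_r / (p$g_p * (1 + krq / p$g_s / p$h)))
  expect_equal(ss$p0, p$k_p * krq / (p$g_r * p$g_p))
  # no repression: p_ss = p0, repression level 1
  p_inf <- fast_imsl(h = Inf)
  ss_inf <- steady_state(p_inf, q)
  expect_equal(ss_inf$repression, 1)
  expect_equal(ss_inf$state[["p"]], ss_inf$p0)
  # no input: empty circuit
  expect_equal(unname(steady_state(p, 0)$state[c("r", "s", "p")]), c(0, 0, 0))
})

test_that("strong repression makes the protein steady state input-independent", {
  p <- fast_imsl()
  # drive s_ss/h to ~1e3 at the base input
  q <- 1e4 * p$h_r
  s_ss <- activation_rate(q, p$k_r, p$h_r) / p$g_s
  p$h <- s_ss / 1e3
  p1 <- steady_state(p, q)$state[["p"]]
  p4 <- steady_state(p, 4 * q)$state[["p"]]
  expect_lt(abs(p4 - p1) / p1, 0.002)
  # and both sit near the analytic strong-repression plateau k_p h g_s/(g_r g_p)
  plateau <- p$k_p * p$h * p$g_s / (p$g_r * p$g_p)
  expect_equal(p1, plateau, tolerance = 5e-3)
  # oracle: long-time integration of the rate equations at both inputs
  for (qq in c(q, 4 * q)) {
    tr <- integrate_circuit(p, input_protocol(Inf, qq, "tf_level"),
                            t_end = 100 / p$g_p)
    expect_equal(tr$p[nrow(tr)], steady_state(p, qq)$state[["p"]],
                 tolerance = 1e-4)
  }
})

test_that("tSL steady state solves the self-consistency equation", {
  p <- fast_imsl(topology = "tSL", h = Inf, h_fb = 200)
  q <- 300
  ss <- steady_state(p, q)
  pss <- ss$state[["p"]]
  # bracketed bisection oracle on [0, p0]
  krq <- activation_rate(q, p$k_r, p$h_r)
  p0 <- p$k_p * krq / (p$g_r * p$g_p)
  root <- uniroot(function(x) x * (1 + x / p$h_fb) - p0, c(0, p0),
                  tol = 1e-12 * p0)$root
  expect_equal(pss, root, tolerance = 1e-9)
  expect_lt(ss$repression, 1)
  expect_gt(ss$repression, 0)
})

test_that("closed-form steady states agree with ODE integration for random draws", {
  set.seed(101)
  for (k in 1:20) {
    top <- sample(c("iMSL", "sTF", "tSL"), 1)
    p <- circuit_params(top,
                        k_r = runif(1, 0.01, 0.5), k_p = runif(1, 0.005, 0.1),
                        g_r = 1 / runif(1, 100, 2000),
                        g_s = 1 / runif(1, 100, 2000),
                        g_p = 1 / runif(1, 500, 5000),
                        h = exp(runif(1, 1, 6)), h_r = exp(runif(1, 2, 6)),
                        h_fb = exp(runif(1, 3, 8)))
    q <- exp(runif(1, 2, 8))
    ss <- steady_state(p, q)$state
    tr <- integrate_circuit(p, input_protocol(Inf, q, "tf_level"),
                            t_end = 60 / p$g_p)
    fin <- unlist(tr[nrow(tr), -1])
    for (sp in names(fin)) {
      expect_equal(fin[[sp]], ss[[sp]], tolerance = 1e-3)
    }
  }
})

test_that("p_ss never increases with repression strength 1/h", {
  p <- fast_imsl()
  q <- 200
  hgrid <- 10^seq(-2, 6, length.out = 30)
  pss <- vapply(hgrid, function(h) {
    p$h <- h
    steady_state(p, q)$state[["p"]]
  }, numeric(1))
  # h increasing = repression weakening, so p_ss must be non-decreasing in h
  expect_true(all(diff(pss) >= 0))
})

test_that("matched sTF calibration preserves the protein steady state", {
  p <- fast_imsl()
  q <- 800
  # s_ss = h gives k_p2 = k_p / 2 exactly
  p$h <- activation_rate(q, p$k_r, p$h_r) / p$g_s
  m <- calibrate_matched(p, "sTF", q_op = q)
  expect_equal(m$k_p2, p$k_p / 2)
  expect_equal(steady_state(m, q)$state[["p"]], steady_state(p, q)$state[["p"]],
               tolerance = 1e-6)
  # unrepressed reference: nothing to match
  p_inf <- fast_imsl(h = Inf)
  expect_equal(calibrate_matched(p_inf, "sTF", q_op = q)$k_p2, p_inf$k_p)
})

test_that("matched tSL calibration hits the iMSL steady state", {
  p <- fast_imsl()
  q <- 600
  p <- calibrate_repression(p, 0.2, q = q)
  expect_equal(steady_state(p, q)$repression, 0.2, tolerance = 1e-9)
  m <- calibrate_matched(p, "tSL", q_op = q)
  expect_equal(m$topology, "tSL")
  pi <- steady_state(p, q)$state[["p"]]
  pt <- steady_state(m, q)$state[["p"]]
  expect_lt(abs(pt - pi) / pi, 1e-6)
  # bisection oracle over h_fb reproduces the closed-form constant
  p0 <- steady_state(p, q)$p0
  f <- function(hfb) {
    m2 <- m; m2$h_fb <- hfb
    steady_state(m2, q)$state[["p"]] - pi
  }
  hfb_or <- uniroot(f, c(1e-6 * p0, 1e6 * p0), tol = 1e-10)$root
  expect_equal(m$h_fb, hfb_or, tolerance = 1e-4)
})

test_that("repression calibration solves h for iMSL and h_fb for tSL", {
  for (top in c("iMSL", "tSL")) {
    p <- fast_imsl(topology = top)
    for (rho in c(0.1, 0.5, 0.9, 1)) {
      pc <- calibrate_repression(p, rho, q = 1e6 * p$h_r)
      expect_equal(steady_state(pc, 1e6 * p$h_r)$repression, rho,
                   tolerance = 1e-8)
    }
  }
  expect_error(calibrate_repression(fast_imsl(topology = "sTF"), 0.5, q = 1),
               "no repression")
})

test_that("parameter validation rejects non-positive constants", {
  expect_error(fast_imsl(k_r = -1), "positive")
  expect_error(fast_imsl(g_p = 0), "positive")
  expect_error(fast_imsl(n = 0.5), "Hill")
  expect_error(circuit_params("iMSL", k_r = 1, k_p = 1, g_r = 1, g_p = 1,
                              h_r = 1), "g_s")
})
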