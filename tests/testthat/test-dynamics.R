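# Deterministic dynamics: integration correctness, response times and the
# ON-state robustness distance.

test_that("a circuit started at its steady state stays there", {
  for (top in c("iMSL", "sTF", "tSL")) {
    p <- fast_imsl(topology = top, h_fb = 300)
    q <- 400
    ss <- steady_state(p, q)$state
    init <- ss[intersect(names(ss), names(mirloop:::state_template(p)))]
    tr <- integrate_circuit(p, input_protocol(Inf, q, "tf_level"),
                            init = init, t_end = 10 / p$g_p)
    for (sp in names(init)) {
      expect_equal(tr[[sp]] / init[[sp]], rep(1, nrow(tr)), tolerance = 1e-6)
    }
  }
})

test_that("sTF switch-on follows the two-stage cascade closed form", {
  p <- fast_imsl(topology = "sTF")
  tr <- integrate_circuit(p, make_protocol("step_on"), t_end = 6 / p$g_p,
                          n_grid = 600)
  pss <- steady_state(p, 1e6 * p$h_r)$state[["p"]]
  gr <- p$g_r; gp <- p$g_p
  expected <- 1 - (gp * exp(-gr * tr$time) - gr * exp(-gp * tr$time)) / (gp - gr)
  expect_equal(tr$p / pss, expected, tolerance = 1e-4)
})

test_that("iMSL with repression disabled reproduces the sTF response time", {
  p_off <- fast_imsl(h = Inf)
  p_stf <- fast_imsl(topology = "sTF", h = Inf)
  expect_equal(response_time(p_off, "on")$time,
               response_time(p_stf, "on")$time, tolerance = 1e-3)
})

test_that("self-loops accelerate switch-on and the iMSL delays switch-off", {
  p <- fast_imsl()
  sw <- sweep_response_times(p, repressions = c(0.2, 0.5), ratios = 1)
  on <- sw[sw$direction == "on", ]
  expect_true(all(on$normalized < 1))
  off_imsl <- sw[sw$direction == "off" & sw$topology == "iMSL", ]
  expect_true(all(off_imsl$normalized > 1))
  # no repression row: all normalized times are 1
  sw1 <- sweep_response_times(p, repressions = 1, ratios = 1)
  expect_equal(sw1$normalized, rep(1, nrow(sw1)), tolerance = 1e-3)
})

test_that("iMSL speed-up grows as mRNA turnover outpaces the miRNA one", {
  p <- fast_imsl()
  sw <- sweep_response_times(p, repressions = 0.2, ratios = c(0.2, 1, 5),
                             topologies = "iMSL", directions = "on")
  ord <- order(sw$tau_ratio)
  expect_true(all(diff(sw$normalized[ord]) > 0))
})

test_that("tSL response times barely depend on the miRNA half-life ratio", {
  p <- fast_imsl()
  sw <- sweep_response_times(p, repressions = 0.2, ratios = c(0.2, 1, 5),
                             directions = "on")
  spread <- function(x) diff(range(x))
  sp_tsl <- spread(sw$normalized[sw$topology == "tSL"])
  sp_imsl <- spread(sw$normalized[sw$topology == "iMSL"])
  expect_lt(sp_tsl, 1e-6)
  expect_gt(sp_imsl, 0.1)
})

test_that("switch-off uses the last downward crossing under the transient boost", {
  # short-lived miRNA: translation de-repression can push p above its ON level
  p <- fast_imsl(g_s = 5 / 300)
  p <- calibrate_repression(p, 0.2, q = 1e6 * p$h_r)
  rt <- response_time(p, "off")
  tr <- rt$trajectory
  expect_gt(max(tr$p) / rt$p_ref, 1)       # transient boost happened
  expect_gt(rt$time, 0)
  # after the located crossing, p stays below threshold
  after <- tr$p[tr$time > rt$time * 1.001]
  expect_true(all(after < 0.5 * rt$p_ref * (1 + 1e-6)))
})

test_that("response times are stable under tighter integrator tolerance", {
  p <- fast_imsl()
  p <- calibrate_repression(p, 0.3, q = 1e6 * p$h_r)
  t1 <- response_time(p, "on")$time
  # halving tolerances via a denser base grid changes T_on by < 0.1%
  t2 <- with_grid <- response_time(p, "on", horizon = 300)$time
  expect_equal(t1, t2, tolerance = 1e-3)
})

test_that("robustness distance is 0 at T* = 0, grows with T*, saturates at 1", {
  p <- fast_imsl()
  p <- calibrate_repression(p, 0.3, q = 1e6 * p$h_r)
  expect_equal(robustness_distance(p, 0)$d, 0)
  tp <- log(2) / p$g_p
  Ts <- c(0.5, 1, 2, 4, 8) * tp
  d <- vapply(Ts, function(t) robustness_distance(p, t)$d, numeric(1))
  expect_true(all(diff(d) > 0))
  expect_gt(robustness_distance(p, 50 * tp)$d, 0.999)
})

test_that("the iMSL ON-state outlasts the matched sTF under equal drops", {
  p <- fast_imsl()
  q_sat <- 1e6 * p$h_r
  p <- calibrate_repression(p, 0.2, q = q_sat)
  stf <- calibrate_matched(p, "sTF", q_op = q_sat)
  tp <- log(2) / p$g_p
  for (Ts in c(1, 2) * tp) {
    expect_lt(robustness_distance(p, Ts)$d, robustness_distance(stf, Ts)$d)
  }
})

test_that("circuits return to the ON steady state after the drop (no hysteresis)", {
  for (top in c("iMSL", "sTF", "tSL")) {
    p <- fast_imsl(topology = top, h_fb = 300)
    q_sat <- 1e6 * p$h_r
    ss <- steady_state(p, q_sat)$state[["p"]]
    r <- robustness_distance(p, 2 * log(2) / p$g_p, recovery = 40)
    fin <- r$trajectory$p[nrow(r$trajectory)]
    expect_equal(fin, ss, tolerance = 1e-4)
  }
})

test_that("protocol constructors and levels behave as specified", {
  pr <- make_protocol("transient_drop", T_star = 100, q_sat = 7)
  expect_equal(protocol_level(pr, c(0, 50, 99.9)), c(0, 0, 0))
  expect_equal(protocol_level(pr, c(100.1, 1e6)), c(7, 7))
  two <- make_protocol("two_step", q0 = 40, F_change = 4, gap = 1000)
  expect_equal(two$levels, c(160, 640))
  expect_error(input_protocol(c(Inf, 10), c(1, 1)), "infinite")
  expect_error(input_protocol(10, -1), "non-negative")
})
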