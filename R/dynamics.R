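# Deterministic dynamics: piecewise ODE integration of the three circuits
# under time-varying input, and the dynamical observables T_ON, T_OFF and the
# ON-state robustness distance d.

circuit_derivs <- function(params) {
  top <- params$topology
  force(params)
  function(t, y, input) {
    # input: list(q = level or NA, kr_scale = multiplier)
    q <- input$q
    krq <- if (q == 0) 0 else {
      activation_rate(q, params$k_r, params$h_r, params$n)
    }
    krq <- krq * input$kr_scale
    r <- y[["r"]]; p <- y[["p"]]
    if (top == "iMSL") {
      s <- y[["s"]]
      dr <- krq - params$g_r * r
      ds <- krq - params$g_s * s
      dp <- params$k_p * repression_factor(max(s, 0), params$h) * r - params$g_p * p
      list(c(dr, ds, dp))
    } else if (top == "sTF") {
      dr <- krq - params$g_r * r
      dp <- params$k_p2 * r - params$g_p * p
      list(c(dr, dp))
    } else { # tSL
      dr <- krq / (1 + max(p, 0) / params$h_fb) - params$g_r * r
      dp <- params$k_p * r - params$g_p * p
      list(c(dr, dp))
    }
  }
}

state_template <- function(params) {
  if (params$topology == "iMSL") c(r = 0, s = 0, p = 0) else c(r = 0, p = 0)
}

#' Integrate a circuit under a piecewise-constant input protocol
#'
#' Solves the circuit ODEs segment by segment with `deSolve::lsoda` (stiff-
#' capable, adaptive), carrying the state continuously across segment
#' boundaries.  For `"tf_level"` protocols the segment level is the TF
#' concentration `q`; for `"transcription_switch"` protocols the maximal
#' transcription rate is multiplied by the segment level (0/1 for the on/off
#' switch experiments), which stops host-mRNA and intronic-miRNA production
#' together.
#'
#' @param params a [circuit_params()] object.
#' @param protocol an [input_protocol()].
#' @param init named initial state (`r`, `s`, `p` as applicable); defaults to
#'   all-zero.
#' @param t_end integration horizon (s).
#' @param q_fixed TF level to use in `"transcription_switch"` mode (default:
#'   saturating, `1e6 * h_r`).
#' @param n_grid number of output points per segment (dense output for event
#'   location).
#' @param rtol,atol integrator tolerances.
#' @return a `data.frame` of class `trajectory` with columns `time`, `r`,
#'   (`s`,) `p` and attributes `params`, `protocol`.
#' @export
integrate_circuit <- function(params, protocol, init = NULL, t_end,
                              q_fixed = NULL, n_grid = 400,
                              rtol = 1e-8, atol = 1e-8) {
  stopifnot(inherits(params, "circuit_params"), inherits(protocol, "input_protocol"))
  if (t_end <= 0) stop("t_end must be positive")
  if (is.null(init)) init <- state_template(params)
  if (any(init < 0)) stop("initial state must be non-negative")
  if (is.null(q_fixed)) q_fixed <- 1e6 * params$h_r
  derivs <- circuit_derivs(params)
  bounds <- pmin(cumsum(protocol$durations), t_end)
  starts <- c(0, utils::head(bounds, -1))
  keep <- starts < t_end
  bounds <- pmin(bounds[keep], t_end); starts <- starts[keep]
  if (bounds[length(bounds)] < t_end) bounds[length(bounds)] <- t_end
  levels <- protocol$levels[keep]
  out <- NULL
  y <- init
  for (k in seq_along(starts)) {
    input <- if (protocol$mode == "tf_level") {
      list(q = levels[k], kr_scale = 1)
    } else {
      list(q = q_fixed, kr_scale = levels[k])
    }
    seg_len <- bounds[k] - starts[k]
    npt <- max(20, ceiling(n_grid * min(1, seg_len / t_end)))
    times <- starts[k] + seg_len * seq(0, 1, length.out = npt)
    sol <- deSolve::lsoda(y, times, function(t, y, parms) derivs(t, y, input),
                          parms = NULL, rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1] < 0) {
      stop("integration failed in protocol segment ", k)
    }
    sol <- as.data.frame(sol)
    names(sol)[1] <- "time"
    y <- unlist(sol[nrow(sol), -1])
    out <- if (is.null(out)) sol else rbind(out, sol[-1, ])
  }
  structure(out, class = c("trajectory", "data.frame"),
            params = params, protocol = protocol)
}

# locate threshold crossings of p(t) by monotone cubic interpolation on the
# dense output, optionally the last downward crossing (switch-off responses
# can transiently boost p above the starting level before decaying)
crossing_time <- function(times, p, threshold, last_downward = FALSE) {
  below <- p < threshold
  idx <- which(diff(below) != 0)
  if (length(idx) == 0) return(NA_real_)
  if (last_downward) {
    down <- idx[!below[idx] & below[idx + 1]]
    if (length(down) == 0) return(NA_real_)
    i <- down[length(down)]
  } else {
    i <- idx[1]
  }
  lo <- max(1, i - 2); hi <- min(length(times), i + 3)
  f <- stats::splinefun(times[lo:hi], p[lo:hi] - threshold, method = "natural")
  stats::uniroot(f, lower = times[i], upper = times[i + 1],
                 tol = 1e-9 * max(times[i + 1], 1))$root
}

#' Switch-on / switch-off response time
#'
#' `T_ON` is the time for the protein to first reach half of its final steady
#' state after a sudden saturating activation from the empty state
#' (`r = s = p = 0`); `T_OFF` is the time to fall to half of the initial
#' steady state after transcription is switched off from the fully activated
#' steady state.  Because the iMSL switch-off can transiently boost `p` above
#' its starting level, the off-time is the last downward crossing of the
#' threshold.  The dense grid is doubled until the located time is stable to
#' 0.1%.
#'
#' @param params a [circuit_params()] object.
#' @param direction `"on"` or `"off"`.
#' @param threshold crossing fraction of the reference steady state (0.5).
#' @param horizon integration horizon in protein half-lives (default 200).
#' @return list with `time` (s), `p_ref` (reference steady state), `overshoot`
#'   (max p(t) / final p_ss, on-direction only) and the `trajectory`.
#' @export
response_time <- function(params, direction = c("on", "off"), threshold = 0.5,
                          horizon = 200) {
  direction <- match.arg(direction)
  q_sat <- 1e6 * params$h_r
  ss <- steady_state(params, q_sat)
  p_ss <- ss$state[["p"]]
  if (p_ss <= 0) stop("activated steady state is zero; nothing to cross")
  t_end <- horizon * log(2) / params$g_p
  if (direction == "on") {
    protocol <- make_protocol("step_on")
    init <- state_template(params)
  } else {
    protocol <- make_protocol("step_off")
    init <- ss$state[intersect(names(ss$state), names(state_template(params)))]
  }
  thr <- threshold * p_ss
  n_grid <- 800
  t_prev <- NA_real_
  for (iter in 1:6) {
    tr <- integrate_circuit(params, protocol, init = init, t_end = t_end,
                            q_fixed = q_sat, n_grid = n_grid)
    tcross <- crossing_time(tr$time, tr$p, thr,
                            last_downward = direction == "off")
    if (!is.na(tcross) && !is.na(t_prev) &&
        abs(tcross - t_prev) <= 1e-3 * tcross) break
    t_prev <- tcross
    n_grid <- n_grid * 2
  }
  if (is.na(tcross)) {
    stop("p(t) never crossed ", threshold, " x steady state within the horizon")
  }
  list(time = tcross, p_ref = p_ss,
       overshoot = if (direction == "on") max(tr$p) / p_ss else NA_real_,
       trajectory = tr)
}

#' Robustness of the ON-state to a transient input drop
#'
#' Starting from the fully activated (ON) steady state, the TF input is
#' removed for `T_star` seconds and then restored.  The distance
#' `d = (p_ss - min_t p(t)) / p_ss` measures how far the protein falls from
#' the ON level: d = 0 means the drop is not felt, d = 1 means the protein
#' reached zero.
#'
#' @param params a [circuit_params()] object.
#' @param T_star drop duration (s), >= 0.
#' @param recovery extra integration time after the drop, in protein
#'   half-lives (the trajectory is also checked to return to the ON state).
#' @return list with `d`, `p_min`, `p_ss` and the `trajectory`.
#' @export
robustness_distance <- function(params, T_star, recovery = 30) {
  if (T_star < 0) stop("T_star must be >= 0")
  q_sat <- 1e6 * params$h_r
  ss <- steady_state(params, q_sat)
  p_ss <- ss$state[["p"]]
  if (T_star == 0) {
    return(list(d = 0, p_min = p_ss, p_ss = p_ss, trajectory = NULL))
  }
  protocol <- make_protocol("transient_drop", T_star = T_star, q_sat = q_sat)
  init <- ss$state[intersect(names(ss$state), names(state_template(params)))]
  t_end <- T_star + recovery * log(2) / params$g_p
  tr <- integrate_circuit(params, protocol, init = init, t_end = t_end,
                          n_grid = 1200)
  p_min <- min(tr$p)
  d <- max(0, min(1, (p_ss - p_min) / p_ss))
  list(d = d, p_min = p_min, p_ss = p_ss, trajectory = tr)
}

#' Sweep normalized response times over repression levels and half-life ratios
#'
#' For each combination of repression level and mRNA/miRNA half-life ratio
#' `tau_r/tau_s` (achieved holding `g_r`, `g_p` fixed and varying `g_s`), the
#' repression constant (`h` for the iMSL, `h_fb` for the tSL) is calibrated to
#' the requested steady-state repression at full activation, and the switch-on
#' and switch-off times are computed and normalized by the matched sTF time of
#' the same direction (`T_0`).
#'
#' @param base_params an iMSL [circuit_params()] object supplying the shared
#'   rates.
#' @param repressions repression levels `p_ss/p0` in (0, 1].
#' @param ratios values of `tau_r/tau_s`.
#' @param topologies subset of `c("iMSL", "tSL")`.
#' @param directions subset of `c("on", "off")`.
#' @return a tidy `data.frame` with columns `topology`, `repression`,
#'   `tau_ratio`, `direction`, `T`, `T0`, `normalized`.
#' @export
sweep_response_times <- function(base_params, repressions, ratios,
                                 topologies = c("iMSL", "tSL"),
                                 directions = c("on", "off")) {
  stopifnot(all(repressions > 0 & repressions <= 1), all(ratios > 0))
  q_sat <- 1e6 * base_params$h_r
  rows <- list()
  for (ratio in ratios) {
    par_r <- base_params
    par_r$g_s <- base_params$g_r * ratio # tau_s = tau_r / ratio
    stf <- par_r; stf$topology <- "sTF"; stf$h <- Inf
    T0 <- vapply(directions, function(d) response_time(stf, d)$time, numeric(1))
    names(T0) <- directions
    for (top in topologies) {
      for (rho in repressions) {
        par_t <- par_r
        par_t$topology <- top
        par_t <- calibrate_repression(par_t, rho, q = q_sat)
        for (d in directions) {
          Tt <- response_time(par_t, d)$time
          rows[[length(rows) + 1]] <- data.frame(
            topology = top, repression = rho, tau_ratio = ratio,
            direction = d, T = Tt, T0 = T0[[d]], normalized = Tt / T0[[d]])
        }
      }
    }
  }
  do.call(rbind, rows)
}
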