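# Adaptation and Weber's-law quantification: precision P, sensitivity S,
# fold-change-detection error E, and the region classification over the
# (q/h_r, 1/h) parameter plane.

P_CAP <- 1e6 # sentinel for perfect adaptation (p1 == p0 to machine precision)

equilibration_gap <- function(params) {
  gs <- if (is.null(params$g_s) || !is.finite(params$g_s)) params$g_p else params$g_s
  max(20 / params$g_p, 20 / gs)
}

step_response <- function(params, q_from, q_to, window, init = NULL,
                          n_grid = 1200) {
  protocol <- input_protocol(Inf, q_to, mode = "tf_level")
  if (is.null(init)) {
    ss0 <- steady_state(params, q_from)
    init <- ss0$state[intersect(names(ss0$state), names(state_template(params)))]
  }
  integrate_circuit(params, protocol, init = init, t_end = window,
                    n_grid = n_grid)
}

# refine the trajectory maximum by spline interpolation around the grid peak
peak_value <- function(times, p) {
  i <- which.max(p)
  lo <- max(1, i - 3); hi <- min(length(p), i + 3)
  if (hi - lo < 3) return(p[i])
  f <- stats::splinefun(times[lo:hi], p[lo:hi], method = "natural")
  opt <- stats::optimize(f, range(times[lo:hi]), maximum = TRUE)
  max(p[i], opt$objective)
}

#' Adaptation metrics for a single input step
#'
#' Applies a step of the TF level from `q0` to `F q0` to a circuit
#' pre-equilibrated at `q0` and computes the adaptation indexes
#' \deqn{P = \left|\frac{(p_1-p_0)/p_0}{(q_1-q_0)/q_0}\right|^{-1}, \qquad
#'       S = \frac{p_{max}-p_0}{p_0},}
#' where `p0`, `p1` are the pre- and post-step steady states and `p_max` the
#' transient peak.  High `P` means the steady state returns close to its
#' pre-step value relative to the input change (adaptation); `S` measures
#' whether the transient is a recognisable signal.  `P` is capped at `1e6`
#' when `p1 = p0` to machine precision (perfect adaptation).
#'
#' @param params a [circuit_params()] object.
#' @param q0 background TF level (> 0).
#' @param F_change fold change (> 1): the step goes to `F_change * q0`.
#' @return list with `p0`, `p1`, `p_max`, `P`, `S`.
#' @export
step_metrics <- function(params, q0, F_change) {
  if (q0 <= 0) stop("q0 must be positive")
  if (F_change == 1) stop("undefined step: q1 equals q0")
  q1 <- F_change * q0
  p0 <- steady_state(params, q0)$state[["p"]]
  p1 <- steady_state(params, q1)$state[["p"]]
  if (p0 <= 0) stop("pre-step steady state is zero")
  window <- equilibration_gap(params)
  tr <- step_response(params, q0, q1, window)
  p_max <- peak_value(tr$time, tr$p)
  rel_p <- abs(p1 - p0) / p0
  rel_q <- abs(q1 - q0) / q0
  P <- if (rel_p < .Machine$double.eps^0.75 * rel_q) P_CAP else {
    min(P_CAP, rel_q / rel_p)
  }
  S <- (p_max - p0) / p0
  list(p0 = p0, p1 = p1, p_max = p_max, P = P, S = S)
}

#' Fold-change-detection (Weber) error for two consecutive steps
#'
#' Applies two consecutive steps of equal fold change on different
#' backgrounds (`q0 -> F q0 -> F^2 q0`), waiting for re-equilibration between
#' them (return to within 1% of the intermediate steady state; a protocol
#' error otherwise).  The error in fold-change recognition is
#' \deqn{E = |p_{max,2} - p_{max,1}| / p_{max,1},}
#' with each peak measured relative to its own pre-step baseline.  `E = 0`
#' means the response depends only on the input fold change (Weber's law).
#'
#' @param params a [circuit_params()] object.
#' @param q0 background TF level.
#' @param F_change fold change per step (> 1; `F_change = 1` returns 0).
#' @param gap re-equilibration window between the steps (s); defaults to
#'   `max(20/g_p, 20/g_s)`.
#' @return list with `peak1`, `peak2`, `E`.
#' @export
weber_error <- function(params, q0, F_change, gap = equilibration_gap(params)) {
  if (q0 <= 0) stop("q0 must be positive")
  if (F_change == 1) return(list(peak1 = 0, peak2 = 0, E = 0))
  if (F_change < 1) stop("F_change must be >= 1")
  q1 <- q0 * F_change
  q2 <- q0 * F_change^2
  p0 <- steady_state(params, q0)$state[["p"]]
  p1 <- steady_state(params, q1)$state[["p"]]
  tr1 <- step_response(params, q0, q1, gap)
  peak1 <- peak_value(tr1$time, tr1$p) - p0
  end1 <- unlist(tr1[nrow(tr1), -1])
  if (abs(end1[["p"]] - p1) > 0.01 * p1) {
    stop("protocol error: no re-equilibration within the gap (p = ",
         signif(end1[["p"]], 6), ", target ", signif(p1, 6), ")")
  }
  tr2 <- step_response(params, q1, q2, gap, init = end1)
  peak2 <- peak_value(tr2$time, tr2$p) - p1
  if (peak1 <= 0) stop("first step produced no positive peak")
  list(peak1 = peak1, peak2 = peak2, E = abs(peak2 - peak1) / peak1)
}

#' Steady-state protein noise used for the sensitivity threshold
#'
#' The sensitivity threshold compares the response peak to the steady-state
#' protein noise `CV_p` in presence of input noise `CV_q` (10% by default).
#' The two-stage TF gene has a Poisson floor `CV_q^2 >= 1/<q>`, so an
#' arbitrary input CV cannot always be imposed by tuning TF rates; instead the
#' input noise is treated as a quasi-static modulation of `q` and combined
#' with the intrinsic fluctuations of the `r`, `s`, `p` subsystem (fixed-q
#' linear noise approximation):
#' \deqn{CV_p^2 = CV_{p,int}^2 + \left(\frac{d\ln p_{ss}}{d\ln q}\right)^2 CV_q^2.}
#'
#' @param params a [circuit_params()] object.
#' @param q0 operating TF level.
#' @param cv_q input noise level (default 0.1).
#' @return `CV_p` (dimensionless).
#' @export
protein_cv_at <- function(params, q0, cv_q = 0.1) {
  sys <- reaction_system(params, fixed_q = q0)
  cv_int <- lna_moments(sys)$cv[["p"]]
  # logarithmic gain of the steady state to the input
  eps <- 1e-4
  pa <- steady_state(params, q0 * (1 + eps))$state[["p"]]
  pb <- steady_state(params, q0 * (1 - eps))$state[["p"]]
  gain <- (log(pa) - log(pb)) / (2 * eps)
  sqrt(cv_int^2 + gain^2 * cv_q^2)
}

#' Classify a parameter point by its adaptation behaviour
#'
#' Threshold logic: a circuit is `insensitive` if its response peak is below
#' the noise level (`S < 2 CV_p`); otherwise it is `adaptive` if `P > 10`,
#' and `weber` if additionally `E < 0.1`; else `non_adaptive`.
#'
#' @param P,S,E adaptation metrics (see [step_metrics()], [weber_error()]).
#' @param cv_p steady-state protein noise at the operating point.
#' @param P_min,S_factor,E_max thresholds (defaults 10, 2, 0.1).
#' @return one of `"insensitive"`, `"non_adaptive"`, `"adaptive"`, `"weber"`.
#' @export
classify_response <- function(P, S, E, cv_p, P_min = 10, S_factor = 2,
                              E_max = 0.1) {
  if (S < S_factor * cv_p) return("insensitive")
  if (P <= P_min) return("non_adaptive")
  if (!is.na(E) && E < E_max) "weber" else "adaptive"
}

#' Map adaptation and Weber's-law performance over the parameter plane
#'
#' Sweeps the effective activation `q0/h_r` (by varying `h_r` at fixed `q0`)
#' and the repression strength `1/h`, computing `P`, `S`, `E`, the noise
#' `CV_p` and the region label at each grid point.  Per-point failures are
#' recorded in the `error` column rather than aborting the sweep.
#'
#' @param base_params a [circuit_params()] iMSL object; its `h_r` and `h` are
#'   overridden point-wise.
#' @param q_over_hr numeric vector of effective activations (log-spaced grids
#'   spanning decades are typical).
#' @param inv_h numeric vector of repression strengths `1/h`.
#' @param q0 background TF level of the step protocol.
#' @param F_change fold change per step.
#' @param cv_q input noise for the sensitivity threshold.
#' @return a tidy `data.frame` with one row per grid point: `q_over_hr`,
#'   `inv_h`, `P`, `S`, `E`, `CVp`, `label`, `error`.
#' @export
function_map <- function(base_params, q_over_hr, inv_h, q0 = 40, F_change = 4,
                         cv_q = 0.1) {
  rows <- list()
  for (a in q_over_hr) for (ih in inv_h) {
    par <- base_params
    par$h_r <- q0 / a
    par$h <- 1 / ih
    row <- data.frame(q_over_hr = a, inv_h = ih, P = NA_real_, S = NA_real_,
                      E = NA_real_, CVp = NA_real_, label = NA_character_,
                      error = NA_character_)
    res <- try({
      sm <- step_metrics(par, q0, F_change)
      we <- try(weber_error(par, q0, F_change), silent = TRUE)
      cvp <- protein_cv_at(par, q0, cv_q)
      row$P <- sm$P; row$S <- sm$S
      row$E <- if (inherits(we, "try-error")) NA_real_ else we$E
      row$CVp <- cvp
      row$label <- classify_response(sm$P, sm$S, row$E, cvp)
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      row$error <- conditionMessage(attr(res, "condition"))
    }
    rows[[length(rows) + 1]] <- row
  }
  do.call(rbind, rows)
}
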