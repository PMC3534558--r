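#' Deterministic steady state of a circuit at constant TF level
#'
#' Solves the rate equations at stationarity.  For the iMSL the closed form is
#' `r_ss = k_r(q)/g_r`, `s_ss = k_r(q)/g_s`,
#' `p_ss = k_p r_ss / (g_p (1 + s_ss/h))`; for the sTF
#' `p_ss = k_p2 k_r(q) / (g_r g_p)`; for the tSL the transcription rate is
#' `k_r(q) / (1 + p/h_fb)`, so `p_ss` solves `p (1 + p/h_fb) = p0`, a
#' quadratic with exactly one positive root, taken in closed form and verified
#' by residual.  Also reports `p0`, the protein level of the matched circuit
#' with the negative regulation removed, and the repression level
#' `p_ss/p0 \in (0, 1]` (1 means no repression).
#'
#' @param params a [circuit_params()] object.
#' @param q constant TF protein level (molecules), >= 0.
#' @return a list of class `steady_state` with elements `state` (named vector
#'   `w`, `q`, `r`, `s`, `p`; `w` is `NA` unless TF-gene rates are present),
#'   `p0` and `repression`.
#' @export
steady_state <- function(params, q = tf_mean(params)) {
  stopifnot(inherits(params, "circuit_params"))
  if (q < 0) stop("q must be non-negative")
  krq <- if (q == 0) 0 else activation_rate(q, params$k_r, params$h_r, params$n)
  w <- if (has_tf_gene(params)) params$k_w / params$g_w else NA_real_
  top <- params$topology
  if (top == "iMSL") {
    r <- krq / params$g_r
    s <- krq / params$g_s
    p0 <- params$k_p * r / params$g_p
    p <- p0 / (1 + s / params$h)
  } else if (top == "sTF") {
    r <- krq / params$g_r
    s <- NA_real_
    p <- params$k_p2 * r / params$g_p
    p0 <- p
  } else { # tSL
    s <- NA_real_
    p0 <- params$k_p * krq / (params$g_r * params$g_p)
    if (!is.finite(params$h_fb)) {
      p <- p0
    } else if (p0 == 0) {
      p <- 0
    } else {
      hfb <- params$h_fb
      p <- hfb * (-1 + sqrt(1 + 4 * p0 / hfb)) / 2
      resid <- p * (1 + p / hfb) - p0
      if (abs(resid) > 1e-8 * max(p0, 1)) {
        p <- stats::uniroot(function(x) x * (1 + x / hfb) - p0,
                            lower = 0, upper = p0, tol = 1e-12 * p0)$root
      }
    }
    r <- if (p0 == 0) 0 else krq / (params$g_r * (1 + p / params$h_fb))
  }
  repression <- if (p0 == 0) 1 else p / p0
  structure(list(state = c(w = w, q = q, r = r, s = s, p = p),
                 p0 = p0, repression = repression),
            class = "steady_state")
}

#' Steady-state mean of the upstream TF protein
#'
#' For the constitutive two-stage TF gene (mRNA `w`, protein `q`):
#' `<w> = k_w/g_w`, `<q> = k_q <w> / g_q`.
#'
#' @param params a [circuit_params()] object carrying TF-gene rates.
#' @return mean TF protein level (molecules).
#' @export
tf_mean <- function(params) {
  if (!has_tf_gene(params)) {
    stop("no TF-gene rates in params; pass q explicitly")
  }
  params$k_q * params$k_w / (params$g_w * params$g_q)
}

#' Calibrate the repression constant to a target repression level
#'
#' Solves for `h` (iMSL) or `h_fb` (tSL) so that the steady-state repression
#' `p_ss/p0` at operating TF level `q` equals `repression`.  Both solutions
#' are closed-form for these rate laws: `h = s_ss rho/(1-rho)` and
#' `h_fb = rho^2 p0/(1-rho)`.
#'
#' @param params a [circuit_params()] object (iMSL or tSL).
#' @param repression target `p_ss/p0` in (0, 1].
#' @param q operating TF level.
#' @return a `circuit_params` object with `h` (or `h_fb`) replaced.
#' @export
calibrate_repression <- function(params, repression, q = tf_mean(params)) {
  stopifnot(inherits(params, "circuit_params"))
  if (repression <= 0 || repression > 1) stop("repression must be in (0, 1]")
  if (repression == 1) {
    if (params$topology == "iMSL") params$h <- Inf else params$h_fb <- Inf
    return(params)
  }
  krq <- activation_rate(q, params$k_r, params$h_r, params$n)
  if (params$topology == "iMSL") {
    s_ss <- krq / params$g_s
    params$h <- s_ss * repression / (1 - repression)
  } else if (params$topology == "tSL") {
    p0 <- params$k_p * krq / (params$g_r * params$g_p)
    params$h_fb <- repression^2 * p0 / (1 - repression)
  } else {
    stop("sTF has no repression to calibrate")
  }
  ach <- steady_state(params, q)$repression
  if (abs(ach - repression) > 1e-8) {
    stop("repression calibration failed: achieved ", ach)
  }
  params
}

#' Mathematically controlled comparison: derive a matched circuit
#'
#' Starting from an iMSL reference, produces an sTF or tSL parameter set with
#' all shared parameters equal and the topology-specific constant constrained
#' so that the protein steady state at the operating TF level `q_op` matches
#' the reference: `k_p2 = k_p/(1 + s_ss/h)` for the sTF, and
#' `h_fb = p_ss^2/(p0 - p_ss)` for the tSL (exact for this feedback form; the
#' result is verified to 1e-6 relative).
#'
#' @param reference an iMSL [circuit_params()] object.
#' @param target `"sTF"` or `"tSL"`.
#' @param q_op operating TF level.
#' @return a `circuit_params` object of the target topology.
#' @export
calibrate_matched <- function(reference, target = c("sTF", "tSL"),
                              q_op = tf_mean(reference)) {
  stopifnot(inherits(reference, "circuit_params"))
  if (reference$topology != "iMSL") stop("reference must be an iMSL")
  target <- match.arg(target)
  ss <- steady_state(reference, q_op)
  out <- reference
  out$topology <- target
  if (target == "sTF") {
    out$k_p2 <- reference$k_p * ss$repression
    out$h <- Inf
  } else {
    out$h <- Inf
    p <- ss$state[["p"]]
    p0 <- ss$p0
    out$h_fb <- if (p >= p0) Inf else p^2 / (p0 - p)
  }
  ach <- steady_state(out, q_op)$state[["p"]]
  want <- ss$state[["p"]]
  if (want > 0 && abs(ach - want) / want > 1e-6) {
    stop("matched calibration failed: target p_ss ", want, ", achieved ", ach)
  }
  out
}
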