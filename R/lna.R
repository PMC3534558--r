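#' Linear noise approximation of stationary fluctuations
#'
#' Gaussian approximation to the master-equation fluctuations around the
#' deterministic fixed point: with drift Jacobian `A` and diffusion matrix
#' `D = sum_j nu_j nu_j' a_j(x*)`, the stationary covariance `C` solves the
#' Lyapunov equation `A C + C A' + D = 0` (solved via vectorisation).  Exact
#' for linear systems (e.g. birth-death, the two-stage TF gene); an
#' approximation for the nonlinear circuits, validated against Gillespie
#' simulation in the test suite.
#'
#' @param system a [reaction_system()].
#' @param fixed_point optional precomputed fixed point (named vector).
#' @return an object of class `noise_summary` with `mean`, `sd`, `cv`, the
#'   full covariance matrix `cov`, and `method = "lna"`.
#' @export
lna_moments <- function(system, fixed_point = NULL) {
  x <- if (is.null(fixed_point)) meanfield_fixed_point(system) else fixed_point
  A <- meanfield_jacobian(system, x)
  ev <- eigen(A, only.values = TRUE)$values
  if (any(Re(ev) >= 0)) {
    stop("deterministic fixed point is not stable; LNA undefined")
  }
  a <- propensities(system, x)
  S <- system$stoich
  D <- S %*% diag(a, nrow = length(a)) %*% t(S)
  n <- length(x)
  I <- diag(n)
  C <- matrix(solve(kronecker(I, A) + kronecker(A, I), -as.vector(D)), n, n)
  sdev <- sqrt(pmax(diag(C), 0))
  sp <- system$species
  out <- list(mean = stats::setNames(as.numeric(x), sp),
              sd = stats::setNames(sdev, sp),
              cv = stats::setNames(sdev / as.numeric(x), sp),
              cov = C, method = "lna", n_samples = NA_integer_)
  class(out) <- "noise_summary"
  out
}

#' Closed-form protein noise of the two-stage expression model
#'
#' For constitutive two-stage expression (mRNA `w`: birth `k_w`, death `g_w`;
#' protein `q`: birth `k_q w`, death `g_q`), the stationary protein noise is
#' \deqn{CV_q^2 = \frac{1}{\langle q\rangle} +
#'       \frac{1}{\langle w\rangle}\,\frac{g_q}{g_q+g_w}.}
#'
#' @param k_w,k_q,g_w,g_q rates (1/s).
#' @return list with `mean_w`, `mean_q`, `cv_q`.
#' @export
cv_two_stage <- function(k_w, k_q, g_w, g_q) {
  mean_w <- k_w / g_w
  mean_q <- k_q * mean_w / g_q
  cv2 <- 1 / mean_q + (1 / mean_w) * g_q / (g_q + g_w)
  list(mean_w = mean_w, mean_q = mean_q, cv_q = sqrt(cv2))
}

#' Tune TF-gene rates to a target protein mean and noise
#'
#' Inverts the two-stage closed form at fixed lifetimes: scales `k_w` (burst
#' frequency) and `k_q` (burst size) so that the TF protein has mean `mean_q`
#' and coefficient of variation `cv_q`.  Infeasible targets below the Poisson
#' floor (`cv_q^2 <= 1/mean_q`) raise an error.
#'
#' @param params a [circuit_params()] object with TF-gene rates (`g_w`, `g_q`
#'   are kept).
#' @param mean_q target mean TF protein level.
#' @param cv_q target coefficient of variation of the TF protein.
#' @return `params` with `k_w`, `k_q` replaced.
#' @export
tf_params_for_cv <- function(params, mean_q, cv_q) {
  stopifnot(inherits(params, "circuit_params"))
  if (is.null(params$g_w) || is.null(params$g_q)) {
    stop("params carry no TF-gene degradation rates")
  }
  extr <- cv_q^2 - 1 / mean_q
  if (extr <= 0) {
    stop("target cv_q below the Poisson floor 1/sqrt(mean_q) = ",
         signif(1 / sqrt(mean_q), 4))
  }
  mean_w <- (params$g_q / (params$g_q + params$g_w)) / extr
  params$k_w <- params$g_w * mean_w
  params$k_q <- params$g_q * mean_q / mean_w
  params
}
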