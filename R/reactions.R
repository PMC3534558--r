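# Master-equation representation of the circuits: species, stoichiometries and
# propensity functions, in a small tabular encoding shared by the C++ Gillespie
# engine, the mean-field ODE integrator and the linear noise approximation.
#
# Propensity types (parameters k, i, n, h, j, h2):
#   0 constant            a = k
#   1 linear              a = k x_i
#   2 Hill activation     a = k x_i^n / (h^n + x_i^n)
#   3 linear x repression a = k x_i / (1 + x_j/h2)
#   4 activation x repr.  a = k (x_i^n/(h^n+x_i^n)) / (1 + x_j/h2)
#   5 constant x repr.    a = k / (1 + x_j/h2)

new_reaction_system <- function(species, stoich, rx) {
  stopifnot(nrow(stoich) == length(species), ncol(stoich) == nrow(rx))
  rownames(stoich) <- species
  structure(list(species = species, stoich = stoich, rx = rx),
            class = "reaction_system")
}

rx_row <- function(type, k, i = 1, n = 1, h = Inf, j = 1, h2 = Inf) {
  data.frame(type = type, k = k, i = i, n = n, h = h, j = j, h2 = h2)
}

#' @export
print.reaction_system <- function(x, ...) {
  cat("<reaction_system>", length(x$species), "species:",
      paste(x$species, collapse = ", "), "|", nrow(x$rx), "reactions\n")
  invisible(x)
}

#' Build the master-equation model of a circuit
#'
#' Constructs the jump-process representation whose mean-field limit is the
#' deterministic rate-equation model.  Reactions: TF transcription (`k_w`),
#' TF translation (`k_q w`), TF mRNA/protein degradation; host transcription
#' with the full nonlinear activation (and, for the tSL, protein repression);
#' for the iMSL a single transcription firing produces the mRNA `r` and the
#' intronic miRNA `s` together (perfect co-transcription; set
#' `cotranscribed = FALSE` to decouple them into two reactions with equal
#' rates); translation with the full nonlinear miRNA repression; first-order
#' degradation of every species.
#'
#' @param params a [circuit_params()] object.
#' @param fixed_q if non-`NULL`, the TF level is clamped to this constant and
#'   the TF gene is not simulated (species `r`, `s`, `p` only).
#' @param cotranscribed logical; see above (iMSL only).
#' @return a `reaction_system` object.
#' @export
reaction_system <- function(params, fixed_q = NULL, cotranscribed = TRUE) {
  stopifnot(inherits(params, "circuit_params"))
  top <- params$topology
  species <- c(if (is.null(fixed_q)) c("w", "q"),
               "r", if (top == "iMSL") "s", "p")
  if (is.null(fixed_q) && !has_tf_gene(params)) {
    stop("TF-gene rates (k_w, k_q, g_w, g_q) required unless fixed_q is given")
  }
  idx <- function(sp) match(sp, species)
  st <- function(...) {
    v <- integer(length(species)); names(v) <- species
    args <- list(...)
    v[names(args)] <- unlist(args)
    v
  }
  stoich <- list(); rx <- list()
  add <- function(s, r) {
    stoich[[length(stoich) + 1]] <<- s
    rx[[length(rx) + 1]] <<- r
  }
  if (is.null(fixed_q)) {
    add(st(w = 1), rx_row(0, params$k_w))
    add(st(q = 1), rx_row(1, params$k_q, i = idx("w")))
    add(st(w = -1), rx_row(1, params$g_w, i = idx("w")))
    add(st(q = -1), rx_row(1, params$g_q, i = idx("q")))
  }
  # transcription
  transc_rx <- if (is.null(fixed_q)) {
    if (top == "tSL") {
      rx_row(4, params$k_r, i = idx("q"), n = params$n, h = params$h_r,
             j = idx("p"), h2 = params$h_fb)
    } else {
      rx_row(2, params$k_r, i = idx("q"), n = params$n, h = params$h_r)
    }
  } else {
    krq <- if (fixed_q == 0) 0 else {
      activation_rate(fixed_q, params$k_r, params$h_r, params$n)
    }
    if (top == "tSL") {
      rx_row(5, krq, j = idx("p"), h2 = params$h_fb)
    } else {
      rx_row(0, krq)
    }
  }
  if (top == "iMSL" && cotranscribed) {
    add(st(r = 1, s = 1), transc_rx)
  } else if (top == "iMSL") {
    add(st(r = 1), transc_rx)
    add(st(s = 1), transc_rx)
  } else {
    add(st(r = 1), transc_rx)
  }
  add(st(r = -1), rx_row(1, params$g_r, i = idx("r")))
  if (top == "iMSL") {
    add(st(s = -1), rx_row(1, params$g_s, i = idx("s")))
    add(st(p = 1), rx_row(3, params$k_p, i = idx("r"), j = idx("s"),
                          h2 = params$h))
  } else if (top == "sTF") {
    add(st(p = 1), rx_row(1, params$k_p2, i = idx("r")))
  } else {
    add(st(p = 1), rx_row(1, params$k_p, i = idx("r")))
  }
  add(st(p = -1), rx_row(1, params$g_p, i = idx("p")))
  new_reaction_system(species, do.call(cbind, stoich), do.call(rbind, rx))
}

#' The upstream TF gene module alone
#'
#' Two-stage constitutive expression: mRNA `w` born at `k_w` and degraded at
#' `g_w w`; protein `q` born at `k_q w` and degraded at `g_q q`.
#'
#' @param k_w,k_q,g_w,g_q rates (1/s); by default taken from `params`.
#' @param params optionally, a [circuit_params()] object carrying the rates.
#' @return a `reaction_system` with species `w`, `q`.
#' @export
tf_reaction_system <- function(params = NULL, k_w = params$k_w,
                               k_q = params$k_q, g_w = params$g_w,
                               g_q = params$g_q) {
  species <- c("w", "q")
  stoich <- cbind(c(1L, 0L), c(0L, 1L), c(-1L, 0L), c(0L, -1L))
  rx <- rbind(rx_row(0, k_w), rx_row(1, k_q, i = 1),
              rx_row(1, g_w, i = 1), rx_row(1, g_q, i = 2))
  new_reaction_system(species, stoich, rx)
}

#' A one-species birth-death process
#'
#' Birth at constant rate `k`, death at `g x`; the stationary law is Poisson
#' with mean `k/g` (used as an exact oracle for the stochastic engine).
#'
#' @param k birth rate (molecules/s).
#' @param g death rate (1/s).
#' @return a `reaction_system` with one species `x`.
#' @export
birth_death_system <- function(k, g) {
  new_reaction_system("x", cbind(1L, -1L),
                      rbind(rx_row(0, k), rx_row(1, g, i = 1)))
}

# propensities and their gradients at a state (used by the mean-field ODE and
# the LNA); x is a named or plain numeric vector in species order
propensities <- function(system, x) {
  rx <- system$rx
  a <- numeric(nrow(rx))
  for (k in seq_len(nrow(rx))) {
    t <- rx$type[k]; kk <- rx$k[k]
    if (t == 0) a[k] <- kk
    else if (t == 1) a[k] <- kk * x[rx$i[k]]
    else if (t == 2) {
      xi <- x[rx$i[k]]; n <- rx$n[k]; h <- rx$h[k]
      a[k] <- if (!is.finite(h) || xi <= 0) 0 else kk * xi^n / (h^n + xi^n)
    } else if (t == 3) {
      a[k] <- kk * x[rx$i[k]] / (1 + x[rx$j[k]] / rx$h2[k])
    } else if (t == 4) {
      xi <- x[rx$i[k]]; n <- rx$n[k]; h <- rx$h[k]
      act <- if (!is.finite(h) || xi <= 0) 0 else xi^n / (h^n + xi^n)
      a[k] <- kk * act / (1 + x[rx$j[k]] / rx$h2[k])
    } else if (t == 5) {
      a[k] <- kk / (1 + x[rx$j[k]] / rx$h2[k])
    }
  }
  a
}

propensity_grads <- function(system, x) {
  rx <- system$rx
  n_sp <- length(system$species)
  G <- matrix(0, nrow(rx), n_sp)
  for (k in seq_len(nrow(rx))) {
    t <- rx$type[k]; kk <- rx$k[k]
    if (t == 1) {
      G[k, rx$i[k]] <- kk
    } else if (t == 2) {
      xi <- x[rx$i[k]]; n <- rx$n[k]; h <- rx$h[k]
      if (is.finite(h) && xi > 0) {
        G[k, rx$i[k]] <- kk * n * h^n * xi^(n - 1) / (h^n + xi^n)^2
      }
    } else if (t == 3) {
      xi <- x[rx$i[k]]; xj <- x[rx$j[k]]; h2 <- rx$h2[k]
      f <- 1 / (1 + xj / h2)
      G[k, rx$i[k]] <- kk * f
      if (is.finite(h2)) G[k, rx$j[k]] <- G[k, rx$j[k]] - kk * xi * f^2 / h2
    } else if (t == 4) {
      xi <- x[rx$i[k]]; n <- rx$n[k]; h <- rx$h[k]
      xj <- x[rx$j[k]]; h2 <- rx$h2[k]
      act <- if (!is.finite(h) || xi <= 0) 0 else xi^n / (h^n + xi^n)
      f <- 1 / (1 + xj / h2)
      if (is.finite(h) && xi > 0) {
        G[k, rx$i[k]] <- kk * f * n * h^n * xi^(n - 1) / (h^n + xi^n)^2
      }
      if (is.finite(h2)) G[k, rx$j[k]] <- G[k, rx$j[k]] - kk * act * f^2 / h2
    } else if (t == 5) {
      xj <- x[rx$j[k]]; h2 <- rx$h2[k]
      if (is.finite(h2)) G[k, rx$j[k]] <- -kk / h2 / (1 + xj / h2)^2
    }
  }
  G
}

# drift (mean-field right-hand side) and its Jacobian
meanfield_drift <- function(system, x) {
  as.numeric(system$stoich %*% propensities(system, x))
}
meanfield_jacobian <- function(system, x) {
  system$stoich %*% propensity_grads(system, x)
}

#' Deterministic fixed point of a reaction system
#'
#' Integrates the mean-field rate equations to long times and polishes the
#' result with damped Newton iterations.
#'
#' @param system a `reaction_system`.
#' @param init initial state (default zero).
#' @return named numeric vector of steady-state means.
#' @export
meanfield_fixed_point <- function(system, init = NULL) {
  n <- length(system$species)
  if (is.null(init)) init <- stats::setNames(numeric(n), system$species)
  lin <- system$rx$type == 1 & system$stoich[cbind(system$rx$i, seq_len(nrow(system$rx)))] < 0
  degr <- system$rx$k[lin]
  t_end <- if (length(degr)) 60 / min(degr) else 1e6
  sol <- deSolve::lsoda(init, c(0, t_end),
                        function(t, y, p) list(meanfield_drift(system, pmax(y, 0))),
                        parms = NULL, rtol = 1e-10, atol = 1e-10)
  x <- pmax(as.numeric(sol[nrow(sol), -1]), 0)
  for (it in 1:50) {
    f <- meanfield_drift(system, x)
    if (max(abs(f)) < 1e-13 * max(1, max(x))) break
    J <- meanfield_jacobian(system, x)
    dx <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(dx)) break
    step <- 1
    while (any(x + step * dx < 0) && step > 1e-6) step <- step / 2
    x <- x + step * dx
  }
  stats::setNames(x, system$species)
}

#' Mean-field (deterministic) trajectory of a reaction system
#'
#' @param system a `reaction_system`.
#' @param init initial state.
#' @param times output time grid (s).
#' @return data.frame with `time` and one column per species.
#' @export
meanfield_trajectory <- function(system, init, times) {
  sol <- deSolve::lsoda(init, times,
                        function(t, y, p) list(meanfield_drift(system, pmax(y, 0))),
                        parms = NULL, rtol = 1e-10, atol = 1e-10)
  out <- as.data.frame(sol)
  names(out) <- c("time", system$species)
  out
}
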