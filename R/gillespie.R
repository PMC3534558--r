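# Exact stochastic simulation (Gillespie) and stationary-moment estimation.

rxpar_matrix <- function(system) {
  rx <- system$rx
  # one column per reaction (the engine reads each reaction's parameters as a
  # contiguous column)
  rbind(rx$type, rx$k, rx$i - 1, rx$n, rx$h, rx$j - 1, rx$h2)
}

check_init <- function(system, init) {
  if (is.null(init)) init <- stats::setNames(numeric(length(system$species)),
                                             system$species)
  if (length(init) != length(system$species)) stop("init has wrong length")
  if (any(init < 0) || any(init != floor(init))) {
    stop("init must be non-negative integers")
  }
  as.numeric(init)
}

#' Simulate one exact sample path of a reaction system
#'
#' Gillespie's stochastic simulation with the full nonlinear propensities;
#' `method = "first"` is the first-reaction scheme, `method = "direct"` the
#' direct scheme (statistically identical, faster).  All randomness comes
#' from R's RNG, so `set.seed()` makes paths bit-reproducible.
#'
#' @param system a [reaction_system()].
#' @param init non-negative integer initial state (default zero).
#' @param t_end simulated time horizon (s).
#' @param times recording grid (default 500 evenly spaced points); the state
#'   recorded at each grid time is the piecewise-constant path value.
#' @param method `"first"` or `"direct"`.
#' @return a `data.frame` with `time` and one column per species.
#' @export
gillespie_simulate <- function(system, init = NULL, t_end,
                               times = NULL, method = c("first", "direct")) {
  method <- match.arg(method)
  init <- check_init(system, init)
  if (t_end <= 0) stop("t_end must be positive")
  if (is.null(times)) times <- seq(0, t_end, length.out = 500)
  m <- .ssa_path(system$stoich, rxpar_matrix(system), init, times,
                 as.integer(method == "first"))
  out <- data.frame(time = times)
  out[system$species] <- as.data.frame(m)
  out
}

#' Record an exact event sequence (jump times and states)
#'
#' @param system a [reaction_system()].
#' @param init initial state.
#' @param n_events number of reaction events to record.
#' @param method `"first"` or `"direct"`.
#' @return list with `times` and a `states` matrix (one row per event).
#' @export
gillespie_events <- function(system, init = NULL, n_events = 1000,
                             method = c("first", "direct")) {
  method <- match.arg(method)
  init <- check_init(system, init)
  .ssa_events(system$stoich, rxpar_matrix(system), init,
              as.integer(n_events), as.integer(method == "first"))
}

#' Burn-in time from the deterministic convergence criterion
#'
#' The stationary state is assumed reached when the mean-field (deterministic)
#' trajectory started from `init` is within a fraction `frac` (default 0.05%)
#' of its asymptotic value for every species with a non-zero asymptote.
#'
#' @param system a [reaction_system()].
#' @param init initial state (default zero).
#' @param frac relative distance defining convergence (default `5e-4`).
#' @return burn-in time (s).
#' @export
burn_in_time <- function(system, init = NULL, frac = 5e-4) {
  n <- length(system$species)
  if (is.null(init)) init <- numeric(n)
  xstar <- meanfield_fixed_point(system, init = init)
  lin <- system$rx$type == 1 &
    system$stoich[cbind(system$rx$i, seq_len(nrow(system$rx)))] < 0
  tmax <- 200 / min(system$rx$k[lin])
  times <- seq(0, tmax, length.out = 4000)
  tr <- meanfield_trajectory(system, init, times)
  keep <- xstar > 1e-12
  rel <- abs(sweep(as.matrix(tr[, -1, drop = FALSE])[, keep, drop = FALSE], 2,
                   xstar[keep])) / rep(xstar[keep], each = nrow(tr))
  ok <- apply(rel <= frac, 1, all)
  # earliest time after which the criterion holds for good
  bad <- which(!ok)
  if (length(bad) == nrow(tr)) stop("no convergence within ", tmax, " s")
  if (length(bad) == 0) return(times[2])
  t_conv <- times[min(nrow(tr), max(bad) + 1)]
  t_conv
}

#' Stationary moments of a reaction system by stochastic simulation
#'
#' Two sampling designs:
#' \describe{
#'   \item{ensemble}{`n_trials` independent trials, each run from `init` for
#'     the burn-in time given by the deterministic 0.05% convergence
#'     criterion (see [burn_in_time()]), recording one state per trial.}
#'   \item{time_average}{one long path; after burn-in, time-weighted first and
#'     second moments are accumulated over `t_sample` seconds, with
#'     batch-means standard errors (`n_batches` batches).  This is the
#'     scaled-down design used for parameter scans.}
#' }
#'
#' @param system a [reaction_system()].
#' @param method `"time_average"` or `"ensemble"`.
#' @param init initial state (default zero; ensemble trials all start there).
#' @param n_trials ensemble size (default 2000).
#' @param t_sample sampling time for the time-average design (s).
#' @param n_batches number of batches for batch-means errors.
#' @param t_burn burn-in override (s; default from [burn_in_time()]).
#' @param engine `"direct"` (default here, for speed) or `"first"`.
#' @return an object of class `noise_summary`: list with `mean`, `sd`, `cv`,
#'   `se_mean`, `se_cv` (named by species), `method`, `n_samples` (trials or
#'   effective batch count) and `t_burn`.
#' @export
stationary_moments <- function(system, method = c("time_average", "ensemble"),
                               init = NULL, n_trials = 2000,
                               t_sample = NULL, n_batches = 40,
                               t_burn = NULL, engine = c("direct", "first")) {
  method <- match.arg(method)
  engine <- match.arg(engine)
  init <- check_init(system, init)
  if (is.null(t_burn)) t_burn <- burn_in_time(system, init)
  eng <- as.integer(engine == "first")
  sp <- system$species
  if (method == "ensemble") {
    m <- .ssa_final(system$stoich, rxpar_matrix(system), init, t_burn,
                    as.integer(n_trials), eng)
    mu <- colMeans(m)
    sdev <- apply(m, 2, stats::sd)
    cv <- sdev / mu
    se_mean <- sdev / sqrt(n_trials)
    se_cv <- cv * sqrt((1 + 2 * cv^2) / (2 * n_trials))
    out <- list(mean = stats::setNames(mu, sp), sd = stats::setNames(sdev, sp),
                cv = stats::setNames(cv, sp),
                se_mean = stats::setNames(se_mean, sp),
                se_cv = stats::setNames(se_cv, sp),
                method = "gillespie_ensemble", n_samples = n_trials,
                t_burn = t_burn)
  } else {
    if (is.null(t_sample)) {
      lin <- system$rx$type == 1 &
        system$stoich[cbind(system$rx$i, seq_len(nrow(system$rx)))] < 0
      t_sample <- 2000 / min(system$rx$k[lin]) # ~2000 slowest lifetimes
    }
    res <- .ssa_timeavg(system$stoich, rxpar_matrix(system), init, t_burn,
                        t_sample, as.integer(n_batches), eng)
    mu <- as.numeric(res$mean)
    varx <- pmax(as.numeric(res$m2) - mu^2, 0)
    sdev <- sqrt(varx)
    cv <- sdev / mu
    bmu <- res$batch_mean
    bvar <- pmax(res$batch_m2 - bmu^2, 0)
    bcv <- sqrt(bvar) / bmu
    se_mean <- apply(bmu, 2, stats::sd) / sqrt(n_batches)
    se_cv <- apply(bcv, 2, stats::sd) / sqrt(n_batches)
    out <- list(mean = stats::setNames(mu, sp), sd = stats::setNames(sdev, sp),
                cv = stats::setNames(cv, sp),
                se_mean = stats::setNames(se_mean, sp),
                se_cv = stats::setNames(se_cv, sp),
                method = "gillespie_time_average", n_samples = n_batches,
                t_burn = t_burn, t_sample = t_sample,
                n_events = res$n_events)
  }
  class(out) <- "noise_summary"
  out
}

#' @export
print.noise_summary <- function(x, ...) {
  cat("<noise_summary>", x$method, "\n")
  print(round(rbind(mean = x$mean, cv = x$cv), 4))
  invisible(x)
}
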