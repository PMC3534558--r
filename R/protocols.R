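#' Piecewise-constant input protocols
#'
#' An input protocol is an ordered list of segments, each a duration (seconds;
#' only the last may be `Inf`) and an input level.  Two modes are supported:
#' `"tf_level"` sets the TF protein level `q(t)` directly, and
#' `"transcription_switch"` multiplies the maximal transcription rate by the
#' segment level (used for the full-saturation switch on/off experiments where
#' host and intronic miRNA transcription stop together).
#'
#' @param durations numeric vector of segment durations (s); the last may be
#'   `Inf`.
#' @param levels numeric vector of input levels (same length), non-negative.
#' @param mode `"tf_level"` or `"transcription_switch"`.
#' @return an object of class `input_protocol`.
#' @export
input_protocol <- function(durations, levels,
                           mode = c("tf_level", "transcription_switch")) {
  mode <- match.arg(mode)
  if (length(durations) != length(levels)) stop("durations/levels length mismatch")
  if (any(levels < 0)) stop("levels must be non-negative")
  if (any(durations <= 0)) stop("durations must be positive")
  if (any(!is.finite(durations[-length(durations)]))) {
    stop("only the last segment may have infinite duration")
  }
  structure(list(durations = durations, levels = levels, mode = mode),
            class = "input_protocol")
}

#' @export
print.input_protocol <- function(x, ...) {
  cat("<input_protocol> mode:", x$mode, "\n")
  cat(paste(sprintf("  %s s @ level %g", format(x$durations), x$levels),
            collapse = "\n"), "\n")
  invisible(x)
}

#' Input level at given times
#'
#' @param protocol an [input_protocol()].
#' @param t times (s).
#' @return input level at each time.
#' @export
protocol_level <- function(protocol, t) {
  bounds <- cumsum(protocol$durations)
  idx <- findInterval(t, c(0, utils::head(bounds, -1)), left.open = FALSE)
  idx[idx < 1] <- 1
  idx[idx > length(protocol$levels)] <- length(protocol$levels)
  protocol$levels[idx]
}

#' Named protocol constructors
#'
#' Builders for the input time courses used throughout the analyses:
#' \describe{
#'   \item{step_on}{transcription switched from 0 to maximal at t = 0 (a
#'     sudden saturating activation).}
#'   \item{step_off}{transcription switched from maximal to 0 at t = 0.}
#'   \item{transient_drop}{saturating input, then 0 for `T_star` seconds, then
#'     saturating again.}
#'   \item{two_step}{TF level `q0`, one step to `F q0` and, after a
#'     re-equilibration gap, a second step to `F^2 q0` (equal fold-changes on
#'     different backgrounds).}
#' }
#'
#' @param kind one of `"step_on"`, `"step_off"`, `"transient_drop"`,
#'   `"two_step"`.
#' @param T_star drop duration (s), for `transient_drop`.
#' @param q0 background TF level, for `two_step`.
#' @param F_change fold change per step (> 1), for `two_step`.
#' @param gap re-equilibration time between the two steps (s).
#' @param q_sat saturating TF level used by `transient_drop`.
#' @return an [input_protocol()].
#' @export
make_protocol <- function(kind = c("step_on", "step_off", "transient_drop", "two_step"),
                          T_star = NULL, q0 = NULL, F_change = NULL,
                          gap = NULL, q_sat = NULL) {
  kind <- match.arg(kind)
  switch(kind,
    step_on = input_protocol(Inf, 1, mode = "transcription_switch"),
    step_off = input_protocol(Inf, 0, mode = "transcription_switch"),
    transient_drop = {
      if (is.null(T_star) || T_star < 0) stop("T_star must be >= 0")
      if (is.null(q_sat)) q_sat <- 1
      if (T_star == 0) {
        input_protocol(Inf, q_sat, mode = "tf_level")
      } else {
        input_protocol(c(T_star, Inf), c(0, q_sat), mode = "tf_level")
      }
    },
    two_step = {
      if (is.null(q0) || q0 <= 0) stop("q0 must be positive")
      if (is.null(F_change) || F_change <= 1) stop("F_change must be > 1")
      if (is.null(gap) || gap <= 0) stop("gap must be positive")
      input_protocol(c(gap, Inf), c(q0 * F_change, q0 * F_change^2),
                     mode = "tf_level")
    })
}
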