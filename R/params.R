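#' Convert a molecular half-life to a first-order degradation rate
#'
#' Figure-style parameter sets quote half-lives (tau) while the rate equations
#' use first-order degradation rates (g).  Two conventions are supported:
#' `"ln2_over_tau"` treats tau as a true half-life (g = ln(2)/tau), while
#' `"one_over_tau"` treats tau as a mean lifetime (g = 1/tau).  Both appear in
#' the modeling literature, and the difference matters for absolute copy
#' numbers, so every parameter set records which convention it uses.
#'
#' @param tau half-life (or lifetime), seconds; must be positive.
#' @param convention `"ln2_over_tau"` (default) or `"one_over_tau"`.
#' @return degradation rate in 1/s.
#' @seealso [rate_to_halflife()] for the inverse.
#' @export
halflife_to_rate <- function(tau, convention = c("ln2_over_tau", "one_over_tau")) {
  convention <- match.arg(convention)
  if (any(!is.finite(tau)) || any(tau <= 0)) {
    stop("half-life must be positive and finite")
  }
  if (convention == "ln2_over_tau") log(2) / tau else 1 / tau
}

#' @rdname halflife_to_rate
#' @param g degradation rate, 1/s; must be positive.
#' @export
rate_to_halflife <- function(g, convention = c("ln2_over_tau", "one_over_tau")) {
  convention <- match.arg(convention)
  if (any(!is.finite(g)) || any(g <= 0)) stop("rate must be positive and finite")
  if (convention == "ln2_over_tau") log(2) / g else 1 / g
}

#' Parse a duration with a unit suffix into seconds
#'
#' Accepts bare numbers (seconds) or strings like `"30 min"`, `"8 h"`,
#' `"90s"`.  Recognised units: s, sec, min, h, hr, hour(s), d, day(s).
#'
#' @param x numeric or character scalar/vector.
#' @return numeric seconds.
#' @export
parse_duration <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  unit_s <- c(s = 1, sec = 1, secs = 1, second = 1, seconds = 1,
              min = 60, mins = 60, minute = 60, minutes = 60,
              h = 3600, hr = 3600, hrs = 3600, hour = 3600, hours = 3600,
              d = 86400, day = 86400, days = 86400)
  vapply(as.character(x), function(s) {
    s <- trimws(s)
    m <- regmatches(s, regexec("^([0-9.eE+-]+)\\s*([A-Za-z]*)$", s))[[1]]
    if (length(m) != 3 || m[2] == "") stop("cannot parse duration: ", s)
    val <- as.numeric(m[2])
    if (is.na(val)) stop("cannot parse duration: ", s)
    if (m[3] == "") return(val)
    u <- tolower(m[3])
    if (!u %in% names(unit_s)) stop("unknown time unit: ", m[3])
    val * unit_s[[u]]
  }, numeric(1), USE.NAMES = FALSE)
}

#' Kinetic parameter set for one circuit instance
#'
#' Bundles all rate constants and dissociation constants of one of the three
#' circuit topologies:
#' \describe{
#'   \item{iMSL}{host gene repressed post-transcriptionally by its own
#'     co-transcribed intronic miRNA (translation rate divided by `1 + s/h`).}
#'   \item{sTF}{simple TF-activated transcription unit, constant translation
#'     rate `k_p2`; the normalisation baseline.}
#'   \item{tSL}{transcriptional self-loop: the protein represses its own
#'     transcription through the factor `1/(1 + p/h_fb)`.}
#' }
#' Rates may be given directly (`g_r`, ...) or as half-lives (`tau_r`, ...,
#' seconds or strings with units) which are converted using
#' `halflife_convention`.  The upstream TF gene's own expression parameters
#' (`k_w`, `k_q`, `g_w`/`tau_w`, `g_q`/`tau_q`) are optional and only needed
#' when the TF is modeled explicitly (stochastic analyses).
#'
#' @param topology `"iMSL"`, `"sTF"` or `"tSL"`.
#' @param k_r maximal transcription rate of the host gene, molecules/s.
#' @param k_p maximal translation rate per mRNA, 1/s.
#' @param k_p2 constant translation rate for the sTF (defaults to `k_p`).
#' @param g_r,g_s,g_p degradation rates of mRNA, miRNA and protein, 1/s.
#' @param tau_r,tau_s,tau_p alternatively, half-lives (seconds or unit strings).
#' @param h miRNA repression dissociation constant, molecules; `Inf` disables
#'   repression (iMSL only).
#' @param h_r TF activation dissociation constant, molecules.
#' @param n Hill coefficient of activation (default 1).
#' @param h_fb protein feedback dissociation constant, molecules (tSL only);
#'   `Inf` disables the feedback.
#' @param k_w,k_q,g_w,g_q,tau_w,tau_q upstream TF gene parameters (optional).
#' @param halflife_convention see [halflife_to_rate()].
#' @return an object of class `circuit_params` (a validated named list).
#' @examples
#' p <- circuit_params("iMSL", k_r = 0.212819, k_p = 0.0048,
#'                     tau_r = "30 min", tau_s = "30 min", tau_p = "8 h",
#'                     h = 1000, h_r = 1000)
#' @export
circuit_params <- function(topology = c("iMSL", "sTF", "tSL"),
                           k_r, k_p, k_p2 = NULL,
                           g_r = NULL, g_s = NULL, g_p = NULL,
                           tau_r = NULL, tau_s = NULL, tau_p = NULL,
                           h = Inf, h_r, n = 1, h_fb = Inf,
                           k_w = NULL, k_q = NULL,
                           g_w = NULL, g_q = NULL,
                           tau_w = NULL, tau_q = NULL,
                           halflife_convention = c("ln2_over_tau", "one_over_tau")) {
  topology <- match.arg(topology)
  halflife_convention <- match.arg(halflife_convention)
  cvt <- function(g, tau, what, required = TRUE) {
    if (!is.null(g)) return(g)
    if (!is.null(tau)) return(halflife_to_rate(parse_duration(tau), halflife_convention))
    if (required) stop("either g_", what, " or tau_", what, " must be given")
    NULL
  }
  g_r <- cvt(g_r, tau_r, "r")
  g_p <- cvt(g_p, tau_p, "p")
  g_s <- cvt(g_s, tau_s, "s", required = topology == "iMSL")
  g_w <- cvt(g_w, tau_w, "w", required = FALSE)
  g_q <- cvt(g_q, tau_q, "q", required = FALSE)
  if (is.null(k_p2)) k_p2 <- k_p
  p <- structure(list(topology = topology, k_r = k_r, k_p = k_p, k_p2 = k_p2,
                      g_r = g_r, g_s = g_s, g_p = g_p, h = h, h_r = h_r,
                      n = n, h_fb = h_fb, k_w = k_w, k_q = k_q,
                      g_w = g_w, g_q = g_q,
                      halflife_convention = halflife_convention),
                 class = "circuit_params")
  validate_circuit_params(p)
  p
}

validate_circuit_params <- function(p) {
  pos <- function(x, nm, allow_inf = FALSE) {
    if (is.null(x)) return(invisible())
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x <= 0) {
      stop(nm, " must be a positive scalar")
    }
    if (!allow_inf && !is.finite(x)) stop(nm, " must be finite")
  }
  pos(p$k_r, "k_r"); pos(p$k_p, "k_p"); pos(p$k_p2, "k_p2")
  pos(p$g_r, "g_r"); pos(p$g_p, "g_p"); pos(p$h_r, "h_r")
  pos(p$h, "h", allow_inf = TRUE); pos(p$h_fb, "h_fb", allow_inf = TRUE)
  if (p$topology == "iMSL") pos(p$g_s, "g_s")
  pos(p$k_w, "k_w"); pos(p$k_q, "k_q"); pos(p$g_w, "g_w"); pos(p$g_q, "g_q")
  if (p$n < 1) stop("Hill coefficient n must be >= 1")
  invisible(p)
}

has_tf_gene <- function(p) {
  !is.null(p$k_w) && !is.null(p$k_q) && !is.null(p$g_w) && !is.null(p$g_q)
}

#' @export
print.circuit_params <- function(x, ...) {
  cat("<circuit_params> topology:", x$topology,
      " (half-life convention:", x$halflife_convention, ")\n")
  flds <- x[!vapply(x, is.null, logical(1))]
  flds$topology <- NULL; flds$halflife_convention <- NULL
  cat(paste0("  ", names(flds), " = ", vapply(flds, format, character(1)),
             collapse = "\n"), "\n")
  invisible(x)
}

#' Transcriptional activation rate (Michaelis-Menten / Hill)
#'
#' Transcription rate of the host gene as a function of the activating TF
#' level: `k_r * q^n / (h_r^n + q^n)`.  With the default `n = 1` this is the
#' Michaelis-Menten form; `h_r` is the TF level at which transcription runs at
#' half its maximal rate.
#'
#' @param q TF protein level (molecules), non-negative.
#' @param k_r maximal transcription rate, molecules/s.
#' @param h_r activation dissociation constant, molecules.
#' @param n Hill coefficient, >= 1.
#' @return transcription rate, bounded above by `k_r`.
#' @export
activation_rate <- function(q, k_r, h_r, n = 1) {
  if (any(q < 0)) stop("TF level q must be non-negative")
  if (k_r <= 0 || h_r <= 0 || !is.finite(k_r) || !is.finite(h_r)) {
    stop("k_r and h_r must be positive and finite")
  }
  if (n < 1) stop("Hill coefficient n must be >= 1")
  qn <- q^n
  k_r * qn / (h_r^n + qn)
}

#' miRNA repression factor on translation
#'
#' Dimensionless factor `1/(1 + s/h)` multiplying the maximal translation
#' rate; `h` is the miRNA level halving translation.  `h = Inf` means no
#' repression (factor 1).
#'
#' @param s miRNA level (molecules), non-negative.
#' @param h repression dissociation constant, molecules (may be `Inf`).
#' @return factor in (0, 1].
#' @export
repression_factor <- function(s, h) {
  if (any(s < 0)) stop("miRNA level s must be non-negative")
  if (h <= 0) stop("h must be positive (possibly Inf)")
  1 / (1 + s / h)
}
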