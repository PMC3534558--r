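# Synthetic inputs: named parameter presets and generated regulatory
# networks with a controllable planted excess of miRNA -> own-host links.

#' Named circuit parameter presets
#'
#' Bundled parameter settings used throughout the analyses, with half-lives
#' converted to rates under the convention each preset records:
#' \describe{
#'   \item{fig2 / fig3}{response-time setting: tau_p = 8 h, tau_r = 30 min,
#'     tau_s = 30 min (the tau_r/tau_s = 1 example; sweeps vary g_s),
#'     h = 1000, k_r = 0.212819 1/s, k_p = 0.0048 1/s; ln2/tau convention.}
#'   \item{fig4}{adaptation setting: same half-lives but tau_s = 8 h,
#'     k_r = 2.12819 1/s, k_p = 0.048 1/s, with the two-step input
#'     q0 = 40, F = 4; h_r defaults to 40 (q0/h_r = 1); ln2/tau convention.}
#'   \item{fig5}{noise setting with the explicit TF gene:
#'     tau_r = tau_w = 30 min, tau_p = tau_q = 1.5 h,
#'     k_w = 3.4e-3 1/s, k_q = 8.7e-3 1/s, k_r = 0.155 1/s,
#'     k_p = 4.8e-3 1/s; 1/tau convention (giving the upstream noise level
#'     CV_q ~ 0.2 the noise analyses use); tau_s = 30 min (miRNA turnover
#'     comparable to the mRNA one, a modeling choice documented in the
#'     vignette).}
#' }
#' `h_r` and `h` are operating-point parameters; presets carry the defaults
#' noted above and analyses override them via [calibrate_repression()] etc.
#'
#' @param name `"fig2"`, `"fig3"`, `"fig4"` or `"fig5"`.
#' @return list of class `parameter_preset` with elements `name`, `params`
#'   (a [circuit_params()] object), `protocol` (for fig4: `q0`, `F_change`)
#'   and `notes`.
#' @export
preset <- function(name = c("fig2", "fig3", "fig4", "fig5")) {
  name <- match.arg(name)
  out <- switch(name,
    fig2 = ,
    fig3 = list(
      name = name,
      params = circuit_params("iMSL", k_r = 0.212819, k_p = 0.0048,
                              tau_r = "30 min", tau_s = "30 min",
                              tau_p = "8 h", h = 1000, h_r = 1000,
                              halflife_convention = "ln2_over_tau"),
      protocol = NULL,
      notes = "response-time setting; saturating-input switch experiments"),
    fig4 = list(
      name = "fig4",
      params = circuit_params("iMSL", k_r = 2.12819, k_p = 0.048,
                              tau_r = "30 min", tau_s = "8 h", tau_p = "8 h",
                              h = 1000, h_r = 40,
                              halflife_convention = "ln2_over_tau"),
      protocol = list(q0 = 40, F_change = 4),
      notes = "adaptation/Weber setting; two-step input q0 = 40, F = 4"),
    fig5 = list(
      name = "fig5",
      params = circuit_params("iMSL", k_r = 0.155, k_p = 4.8e-3,
                              tau_r = "30 min", tau_s = "30 min",
                              tau_p = "1.5 h", h = 1000, h_r = 100,
                              k_w = 3.4e-3, k_q = 8.7e-3,
                              tau_w = "30 min", tau_q = "1.5 h",
                              halflife_convention = "one_over_tau"),
      protocol = NULL,
      notes = paste("noise setting with explicit TF gene; 1/tau convention",
                    "(reproduces CV_q ~ 0.2); tau_s = tau_r modeling choice")))
  class(out) <- "parameter_preset"
  out
}

#' @export
print.parameter_preset <- function(x, ...) {
  cat("<parameter_preset>", x$name, "-", x$notes, "\n")
  print(x$params)
  invisible(x)
}

#' Specification of a synthetic regulatory-network generator
#'
#' Describes how to generate an annotation table plus per-algorithm target
#' predictions emulating a genome-scale miRNA/host-gene dataset: miRNA
#' genomic-context fractions, background target probability `pi` per
#' algorithm, and a planted self-target excess `epsilon` (the probability
#' that a same-strand intronic miRNA targets its own host becomes
#' `min(1, pi + epsilon)` in the designated planted algorithm(s)).
#'
#' @param n_genes,n_mirnas positive counts (defaults 2000 / 300: large enough
#'   for a stable null, small enough for seconds-scale permutation tests).
#' @param fraction_intragenic probability that a miRNA is intragenic.
#' @param fraction_intronic_given_intragenic P(intronic | intragenic).
#' @param fraction_same_strand P(same strand | intragenic).
#' @param algorithms character vector of algorithm names.
#' @param pi background probability that a given (miRNA, gene) pair is
#'   predicted by a given algorithm.
#' @param epsilon planted self-target excess, >= 0.
#' @param planted_algorithms which algorithms carry the excess (default the
#'   first; set to all names for the multi-algorithm excess mode).
#' @return list of class `network_generator_spec`.
#' @export
network_generator_spec <- function(n_genes = 2000, n_mirnas = 300,
                                   fraction_intragenic = 0.5,
                                   fraction_intronic_given_intragenic = 0.8,
                                   fraction_same_strand = 0.7,
                                   algorithms = paste0("alg", 1:8),
                                   pi = 0.01, epsilon = 0,
                                   planted_algorithms = algorithms[1]) {
  probs <- c(fraction_intragenic, fraction_intronic_given_intragenic,
             fraction_same_strand, pi)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (epsilon < 0) stop("epsilon must be >= 0")
  if (n_genes < 1 || n_mirnas < 1) stop("counts must be positive")
  if (!all(planted_algorithms %in% algorithms)) {
    stop("planted_algorithms must be a subset of algorithms")
  }
  structure(list(n_genes = n_genes, n_mirnas = n_mirnas,
                 fraction_intragenic = fraction_intragenic,
                 fraction_intronic_given_intragenic =
                   fraction_intronic_given_intragenic,
                 fraction_same_strand = fraction_same_strand,
                 algorithms = algorithms, pi = pi, epsilon = epsilon,
                 planted_algorithms = planted_algorithms),
            class = "network_generator_spec")
}

#' Generate a synthetic regulatory network
#'
#' Draws miRNA genomic contexts and host assignments from the spec's
#' fractions, then fills each algorithm's prediction set: every (miRNA, gene)
#' pair enters independently with probability `pi`, except the (same-strand
#' intronic miRNA, own host) pairs, which enter the planted algorithm(s) with
#' probability `min(1, pi + epsilon)`.  Uses R's RNG; call `set.seed()` for
#' reproducible networks.
#'
#' @param spec a [network_generator_spec()].
#' @return a [regulatory_network()].
#' @export
generate_network <- function(spec) {
  stopifnot(inherits(spec, "network_generator_spec"))
  genes <- sprintf("g%04d", seq_len(spec$n_genes))
  ids <- sprintf("mir%04d", seq_len(spec$n_mirnas))
  intra <- stats::runif(spec$n_mirnas) < spec$fraction_intragenic
  context <- ifelse(!intra, "intergenic",
                    ifelse(stats::runif(spec$n_mirnas) <
                             spec$fraction_intronic_given_intragenic,
                           "intronic", "exonic"))
  strand <- ifelse(!intra, NA_character_,
                   ifelse(stats::runif(spec$n_mirnas) <
                            spec$fraction_same_strand, "same", "opposite"))
  host <- ifelse(intra, sample(genes, spec$n_mirnas, replace = TRUE),
                 NA_character_)
  mirnas <- data.frame(mirna_id = ids, context = context,
                       strand_relation = strand, host_gene = host,
                       stringsAsFactors = FALSE)
  self_pair <- context == "intronic" & strand %in% "same"
  preds <- list()
  for (alg in spec$algorithms) {
    planted <- alg %in% spec$planted_algorithms
    rows <- lapply(seq_len(spec$n_mirnas), function(m) {
      hit <- which(stats::runif(spec$n_genes) < spec$pi)
      tg <- genes[hit]
      if (self_pair[m] && planted) {
        tg <- setdiff(tg, host[m])
        if (stats::runif(1) < min(1, spec$pi + spec$epsilon)) {
          tg <- c(tg, host[m])
        }
      }
      if (length(tg) == 0) return(NULL)
      data.frame(algorithm = alg, mirna_id = ids[m], target_gene = tg,
                 stringsAsFactors = FALSE)
    })
    preds[[alg]] <- do.call(rbind, rows)
  }
  regulatory_network(genes, mirnas, do.call(rbind, preds))
}
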