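# Regulatory-network container and the intronic-miRNA self-loop (iMSL)
# enrichment analysis: motif counting, genomic-context classification and the
# permutation tests with their Z score.

#' Annotation + target-prediction network
#'
#' @param genes character vector of gene IDs.
#' @param mirnas data.frame with columns `mirna_id`, `context` (one of
#'   `"intergenic"`, `"exonic"`, `"intronic"`), `strand_relation` (`"same"`,
#'   `"opposite"`, or `NA` for intergenic miRNAs) and `host_gene` (gene ID,
#'   or `NA` for intergenic miRNAs).
#' @param predictions data.frame with columns `algorithm`, `mirna_id`,
#'   `target_gene`: the per-algorithm miRNA -> target predictions (duplicates
#'   within one algorithm are dropped on construction).
#' @return an object of class `regulatory_network`.
#' @export
regulatory_network <- function(genes, mirnas, predictions) {
  genes <- as.character(genes)
  mirnas <- as.data.frame(mirnas, stringsAsFactors = FALSE)
  need <- c("mirna_id", "context", "strand_relation", "host_gene")
  if (!all(need %in% names(mirnas))) {
    stop("mirnas must have columns ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(mirnas$mirna_id)) stop("duplicated miRNA IDs")
  bad <- !mirnas$context %in% c("intergenic", "exonic", "intronic")
  if (any(bad)) stop("unknown context: ", mirnas$context[bad][1])
  inter <- mirnas$context == "intergenic"
  if (any(inter & !is.na(mirnas$host_gene))) {
    stop("intergenic miRNAs must not have a host gene")
  }
  if (any(!inter & is.na(mirnas$host_gene))) {
    stop("intragenic miRNAs must have a host gene")
  }
  if (any(!inter & !mirnas$strand_relation %in% c("same", "opposite"))) {
    stop("intragenic miRNAs need strand_relation same/opposite")
  }
  if (any(!is.na(mirnas$host_gene) & !mirnas$host_gene %in% genes)) {
    stop("host gene not in gene set")
  }
  mirnas$strand_relation[inter] <- NA_character_
  if (is.null(predictions) || nrow(predictions) == 0) {
    predictions <- data.frame(algorithm = character(), mirna_id = character(),
                              target_gene = character(),
                              stringsAsFactors = FALSE)
  } else {
    predictions <- as.data.frame(predictions, stringsAsFactors = FALSE)
    if (!all(c("algorithm", "mirna_id", "target_gene") %in% names(predictions))) {
      stop("predictions must have columns algorithm, mirna_id, target_gene")
    }
    predictions <- unique(predictions[c("algorithm", "mirna_id", "target_gene")])
    if (any(!predictions$mirna_id %in% mirnas$mirna_id)) {
      stop("prediction references unknown miRNA")
    }
    if (any(!predictions$target_gene %in% genes)) {
      stop("prediction references unknown gene")
    }
  }
  structure(list(genes = genes, mirnas = mirnas, predictions = predictions,
                 algorithms = sort(unique(predictions$algorithm))),
            class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat("<regulatory_network>", length(x$genes), "genes,", nrow(x$mirnas),
      "miRNAs,", nrow(x$predictions), "predictions from",
      length(x$algorithms), "algorithms\n")
  invisible(x)
}

#' Classify miRNAs by genomic context and strand
#'
#' Tallies intergenic vs intragenic miRNAs and, within the intragenic class,
#' exonic vs intronic and same- vs opposite-strand, with percentages relative
#' to the stated denominator.
#'
#' @param network a [regulatory_network()].
#' @return a `data.frame` with columns `class`, `count`, `denominator`,
#'   `percent`.
#' @export
classify_mirnas <- function(network) {
  m <- network$mirnas
  n <- nrow(m)
  n_inter <- sum(m$context == "intergenic")
  n_intra <- n - n_inter
  pct <- function(x, d) if (d == 0) 0 else 100 * x / d
  rows <- data.frame(
    class = c("intergenic", "intragenic",
              "exonic", "intronic",
              "exonic_same", "exonic_opposite",
              "intronic_same", "intronic_opposite"),
    count = c(n_inter, n_intra,
              sum(m$context == "exonic"), sum(m$context == "intronic"),
              sum(m$context == "exonic" & m$strand_relation %in% "same"),
              sum(m$context == "exonic" & m$strand_relation %in% "opposite"),
              sum(m$context == "intronic" & m$strand_relation %in% "same"),
              sum(m$context == "intronic" & m$strand_relation %in% "opposite")),
    denominator = c("all", "all", "intragenic", "intragenic",
                    "exonic", "exonic", "intronic", "intronic"),
    stringsAsFactors = FALSE)
  dens <- c(all = n, intragenic = n_intra,
            exonic = sum(m$context == "exonic"),
            intronic = sum(m$context == "intronic"))
  rows$percent <- mapply(pct, rows$count, dens[rows$denominator])
  rows
}

# union-of-algorithms support table: one row per (mirna, target) with the
# number of algorithms agreeing
prediction_support <- function(network) {
  pr <- network$predictions
  if (nrow(pr) == 0) {
    return(data.frame(mirna_id = character(), target_gene = character(),
                      support = integer(), stringsAsFactors = FALSE))
  }
  # predictions are de-duplicated per algorithm on construction, so the
  # union support is the multiplicity of each (mirna, target) key
  key <- paste(pr$mirna_id, pr$target_gene, sep = "\r")
  tt <- table(key)
  first <- !duplicated(key)
  data.frame(mirna_id = pr$mirna_id[first],
             target_gene = pr$target_gene[first],
             support = as.integer(tt[key[first]]),
             stringsAsFactors = FALSE)
}

#' Count intronic-miRNA-mediated self-loops
#'
#' An iMSL is a same-strand intronic miRNA predicted to target its own host
#' gene by at least `min_support` algorithms.  Each (miRNA, host) pair is
#' counted once; the table of loops carries the per-loop support (number of
#' agreeing algorithms), the confidence measure used to rank candidates.
#'
#' @param network a [regulatory_network()].
#' @param min_support minimum number of agreeing algorithms (>= 1).
#' @return list with `count` and `loops` (data.frame `mirna_id`, `host_gene`,
#'   `support`).
#' @export
count_imsl <- function(network, min_support = 1) {
  if (min_support < 1) stop("min_support must be >= 1")
  if (length(network$algorithms) && min_support > length(network$algorithms)) {
    stop("min_support exceeds the number of algorithms")
  }
  m <- network$mirnas
  cand <- m[m$context == "intronic" & m$strand_relation %in% "same", ]
  sup <- prediction_support(network)
  key <- paste(sup$mirna_id, sup$target_gene, sep = "\r")
  hit <- match(paste(cand$mirna_id, cand$host_gene, sep = "\r"), key)
  loops <- data.frame(mirna_id = cand$mirna_id, host_gene = cand$host_gene,
                      support = ifelse(is.na(hit), 0L, sup$support[hit]),
                      stringsAsFactors = FALSE)
  loops <- loops[loops$support >= min_support, , drop = FALSE]
  rownames(loops) <- NULL
  list(count = nrow(loops), loops = loops)
}

#' Randomize the network under one of two reshuffling strategies
#'
#' \describe{
#'   \item{host_reshuffle}{host-gene assignments of the intronic miRNAs are
#'     permuted uniformly among themselves; predictions are untouched.}
#'   \item{target_reshuffle}{the union-of-algorithms edge set is rewired by
#'     permuting the target-gene column across edges (each miRNA keeps its
#'     number of union targets); host assignments are untouched and every
#'     permuted edge carries support 1.}
#' }
#' Both strategies preserve their stated marginals exactly.
#'
#' @param network a [regulatory_network()].
#' @param strategy `"host_reshuffle"` or `"target_reshuffle"`.
#' @return a `regulatory_network` (for `target_reshuffle` the predictions are
#'   collapsed to a single pseudo-algorithm `"union"`).
#' @export
permute_network <- function(network,
                            strategy = c("host_reshuffle", "target_reshuffle")) {
  strategy <- match.arg(strategy)
  out <- network
  if (strategy == "host_reshuffle") {
    idx <- which(network$mirnas$context == "intronic")
    if (length(idx) >= 2) {
      out$mirnas$host_gene[idx] <-
        network$mirnas$host_gene[idx][sample.int(length(idx))]
    }
  } else {
    sup <- prediction_support(network)
    if (nrow(sup) >= 2) {
      perm <- data.frame(algorithm = "union",
                         mirna_id = sup$mirna_id,
                         target_gene = sup$target_gene[sample.int(nrow(sup))],
                         stringsAsFactors = FALSE)
      # keep the multiset of edges (duplicates after rewiring still count as
      # presence at support 1)
      out$predictions <- perm
      out$algorithms <- "union"
    }
  }
  out
}

#' Permutation test for iMSL over-representation
#'
#' The observed count `x` of iMSLs confirmed by at least one algorithm is
#' compared with its null distribution over `n_perm` independently reshuffled
#' networks (see [permute_network()]), summarised by
#' \deqn{Z = (x - \langle x\rangle_r)/\sigma_r.}
#'
#' @param network a [regulatory_network()].
#' @param strategy `"host_reshuffle"` or `"target_reshuffle"`.
#' @param n_perm number of permutations (>= 100 for a reported Z).
#' @return an object of class `enrichment_result`: list with `x`,
#'   `null_counts`, `mean_null`, `sd_null`, `Z` (NA with a warning if the
#'   null is degenerate), `strategy`, `n_perm`.
#' @export
enrichment_test <- function(network,
                            strategy = c("host_reshuffle", "target_reshuffle"),
                            n_perm = 1000) {
  strategy <- match.arg(strategy)
  if (n_perm < 1) stop("n_perm must be >= 1")
  x <- count_imsl(network, min_support = 1)$count
  # fast permutation path: the union support table and the candidate list are
  # invariant across draws, so each draw only needs membership counting on
  # integer-encoded (miRNA, gene) keys.  permute_network() implements the
  # identical reshuffles one network at a time and is cross-checked against
  # this path in the tests.
  m <- network$mirnas
  sup <- prediction_support(network)
  mir_lev <- m$mirna_id
  gene_lev <- network$genes
  enc <- function(mir, gene) {
    (match(mir, mir_lev) - 1) * (length(gene_lev) + 1) + match(gene, gene_lev)
  }
  edge_key <- enc(sup$mirna_id, sup$target_gene)
  intronic <- which(m$context == "intronic")
  same <- m$context == "intronic" & m$strand_relation %in% "same"
  null_counts <- if (strategy == "host_reshuffle") {
    hosts <- m$host_gene[intronic]
    same_pos <- which(same[intronic])
    mir_same <- m$mirna_id[intronic][same_pos]
    vapply(seq_len(n_perm), function(i) {
      h <- hosts[sample.int(length(hosts))]
      sum(enc(mir_same, h[same_pos]) %in% edge_key)
    }, numeric(1))
  } else {
    cand_mir <- m$mirna_id[same]
    cand_host <- m$host_gene[same]
    mir_of_edge <- sup$mirna_id
    vapply(seq_len(n_perm), function(i) {
      tg <- sup$target_gene[sample.int(nrow(sup))]
      sum(enc(cand_mir, cand_host) %in% enc(mir_of_edge, tg))
    }, numeric(1))
  }
  mu <- mean(null_counts)
  sdev <- stats::sd(null_counts)
  Z <- if (is.na(sdev) || sdev == 0) {
    warning("degenerate null distribution: Z undefined")
    NA_real_
  } else (x - mu) / sdev
  structure(list(x = x, null_counts = null_counts, mean_null = mu,
                 sd_null = sdev, Z = Z, strategy = strategy, n_perm = n_perm),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("<enrichment_result>", x$strategy, "| x =", x$x,
      sprintf("| null %.2f +/- %.2f over %d permutations | Z = %.2f\n",
              x$mean_null, x$sd_null, x$n_perm, x$Z))
  invisible(x)
}

#' Exact null expectation of the iMSL count under host reshuffling
#'
#' Complete enumeration over the host multiset: for each same-strand intronic
#' miRNA, the probability that a uniformly reassigned host is one of its
#' union targets is (number of hosts in the multiset that are targets)/(number
#' of hosts), and the expected count is the sum over miRNAs.  Used as an
#' independent oracle for the Monte-Carlo null.
#'
#' @param network a [regulatory_network()].
#' @return expected iMSL count under the host-reshuffle null.
#' @export
expected_imsl_host_null <- function(network) {
  m <- network$mirnas
  intronic <- m[m$context == "intronic", ]
  hosts <- intronic$host_gene
  if (length(hosts) == 0) return(0)
  sup <- prediction_support(network)
  same <- intronic[intronic$strand_relation %in% "same", ]
  tot <- 0
  for (k in seq_len(nrow(same))) {
    targets <- sup$target_gene[sup$mirna_id == same$mirna_id[k]]
    tot <- tot + sum(hosts %in% targets) / length(hosts)
  }
  tot
}
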