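# Interchange formats: annotation tables (TSV / GFF3), per-algorithm
# prediction tables, network directories, and flat key-value parameter
# configs with unit-suffixed half-lives.

#' Read a miRNA annotation table
#'
#' Two formats:
#' \describe{
#'   \item{tsv}{tab-separated columns `mirna_id`, `context`,
#'     `strand_relation`, `host_gene` (empty host/strand for intergenic
#'     miRNAs), plus optionally a first block of gene IDs via the companion
#'     `genes` argument.}
#'   \item{gff3}{`gene` features (with `ID`) and `miRNA` features carrying
#'     `ID`, and for intragenic miRNAs a `host` attribute plus a `context`
#'     attribute (`exonic`/`intronic`); `strand_relation` is derived by
#'     comparing the miRNA strand with its host gene's strand.  Coordinates
#'     are 1-based inclusive per GFF3.}
#' }
#'
#' @param path file path.
#' @param format `"tsv"` or `"gff3"`.
#' @param genes optional character vector of gene IDs (tsv format; defaults
#'   to the hosts present plus any `genes` column values).
#' @return list with `genes` and `mirnas` (the annotation part of a
#'   [regulatory_network()]).
#' @export
read_annotation <- function(path, format = c("tsv", "gff3"), genes = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "tsv") {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             na.strings = c("NA", ""))
    need <- c("mirna_id", "context", "strand_relation", "host_gene")
    miss <- setdiff(need, names(tab))
    if (length(miss)) stop("annotation TSV lacks columns: ",
                           paste(miss, collapse = ", "))
    if (is.null(genes)) {
      genes <- sort(unique(stats::na.omit(tab$host_gene)))
    }
    list(genes = genes, mirnas = tab[need])
  } else {
    gr <- rtracklayer::import(path, format = "gff3")
    md <- S4Vectors::mcols(gr)
    is_gene <- md$type == "gene"
    gene_ids <- as.character(md$ID[is_gene])
    gene_strand <- as.character(BiocGenerics::strand(gr)[is_gene])
    names(gene_strand) <- gene_ids
    is_mir <- md$type == "miRNA"
    if (!any(is_mir)) stop("no miRNA features in ", path)
    mir_id <- as.character(md$ID[is_mir])
    host <- if ("host" %in% names(md)) as.character(md$host[is_mir]) else {
      rep(NA_character_, sum(is_mir))
    }
    context <- if ("context" %in% names(md)) {
      as.character(md$context[is_mir])
    } else rep(NA_character_, sum(is_mir))
    context[is.na(context) & is.na(host)] <- "intergenic"
    unknown_host <- !is.na(host) & !host %in% gene_ids
    if (any(unknown_host)) {
      stop("miRNA references unknown host gene: ", host[unknown_host][1])
    }
    mir_strand <- as.character(BiocGenerics::strand(gr)[is_mir])
    strand_relation <- ifelse(is.na(host), NA_character_,
                              ifelse(mir_strand == gene_strand[host],
                                     "same", "opposite"))
    mirnas <- data.frame(mirna_id = mir_id, context = context,
                         strand_relation = strand_relation, host_gene = host,
                         stringsAsFactors = FALSE)
    if (is.null(genes)) genes <- gene_ids
    list(genes = genes, mirnas = mirnas)
  }
}

#' Write a miRNA annotation table as TSV
#'
#' @param network a [regulatory_network()] (or a list with `mirnas`).
#' @param path output file.
#' @export
write_annotation <- function(network, path) {
  utils::write.table(network$mirnas, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read per-algorithm target-prediction tables
#'
#' Each file is a TSV with columns `mirna_id`, `target_gene`; the algorithm
#' name is the file name without extension (or the names of the vector).
#'
#' @param paths named or unnamed character vector of file paths.
#' @return data.frame with columns `algorithm`, `mirna_id`, `target_gene`.
#' @export
read_predictions <- function(paths) {
  nm <- names(paths)
  if (is.null(nm)) nm <- sub("\\.[^.]*$", "", basename(paths))
  out <- lapply(seq_along(paths), function(k) {
    tab <- utils::read.delim(paths[k], stringsAsFactors = FALSE)
    if (!all(c("mirna_id", "target_gene") %in% names(tab))) {
      stop("prediction table lacks mirna_id/target_gene: ", paths[k])
    }
    data.frame(algorithm = nm[k], mirna_id = tab$mirna_id,
               target_gene = tab$target_gene, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write a network to a directory of plain-text tables
#'
#' Writes `genes.txt` (one ID per line), `annotation.tsv` and one
#' `predictions_<algorithm>.tsv` per algorithm; [read_network()] reverses it.
#'
#' @param network a [regulatory_network()].
#' @param dir output directory (created if needed).
#' @export
write_network <- function(network, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(network$genes, file.path(dir, "genes.txt"))
  write_annotation(network, file.path(dir, "annotation.tsv"))
  for (alg in network$algorithms) {
    pr <- network$predictions[network$predictions$algorithm == alg,
                              c("mirna_id", "target_gene")]
    utils::write.table(pr, file.path(dir, paste0("predictions_", alg, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_network
#' @export
read_network <- function(dir) {
  genes <- readLines(file.path(dir, "genes.txt"))
  ann <- read_annotation(file.path(dir, "annotation.tsv"), "tsv",
                         genes = genes)
  pfiles <- list.files(dir, pattern = "^predictions_.*\\.tsv$",
                       full.names = TRUE)
  names(pfiles) <- sub("^predictions_(.*)\\.tsv$", "\\1", basename(pfiles))
  preds <- if (length(pfiles)) read_predictions(pfiles) else NULL
  regulatory_network(genes, ann$mirnas, preds)
}

#' Serialize circuit parameters to a flat key-value config
#'
#' Writes a YAML file with the field names of [circuit_params()]; half-lives
#' are written as rates (1/s) under `g_*` keys.  [read_config()] also accepts
#' `tau_*` keys with unit suffixes (`"30 min"`, `"8 h"`), converted on load
#' with the file's `halflife_convention`.  Unknown keys are rejected.
#'
#' @param params a [circuit_params()] object.
#' @param path output file.
#' @export
write_config <- function(params, path) {
  stopifnot(inherits(params, "circuit_params"))
  flds <- params[!vapply(params, is.null, logical(1))]
  flds <- lapply(flds, function(v) if (is.numeric(v) && !is.finite(v)) ".inf" else v)
  yaml::write_yaml(flds, path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("topology", "k_r", "k_p", "k_p2", "g_r", "g_s", "g_p", "h",
             "h_r", "n", "h_fb", "k_w", "k_q", "g_w", "g_q",
             "tau_r", "tau_s", "tau_p", "tau_w", "tau_q",
             "halflife_convention")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) stop("unknown config keys: ",
                            paste(unknown, collapse = ", "))
  raw <- lapply(raw, function(v) if (identical(v, ".inf")) Inf else v)
  do.call(circuit_params, raw)
}
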