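# Shared fixtures: small parameter sets and toy networks built in code.

# fast, well-conditioned iMSL used where the figure presets would be
# needlessly slow (minutes-scale half-lives instead of hours)
fast_imsl <- function(...) {
  args <- utils::modifyList(
    list(topology = "iMSL", k_r = 0.2, k_p = 0.05, g_r = 1 / 300,
         g_s = 1 / 300, g_p = 1 / 900, h = 50, h_r = 100),
    list(...))
  do.call(circuit_params, args)
}

# toy annotation network: 5 genes, miRNA m1 is a same-strand intronic miRNA
# hosted in g1 with two algorithms agreeing on the self-link; m2 is an
# opposite-strand intronic miRNA predicted by all three algorithms
toy_network <- function() {
  genes <- paste0("g", 1:5)
  mirnas <- data.frame(
    mirna_id = c("m1", "m2", "m3"),
    context = c("intronic", "intronic", "intergenic"),
    strand_relation = c("same", "opposite", NA),
    host_gene = c("g1", "g2", NA),
    stringsAsFactors = FALSE)
  predictions <- data.frame(
    algorithm = c("A", "B", "A", "B", "C", "C"),
    mirna_id = c("m1", "m1", "m2", "m2", "m2", "m3"),
    target_gene = c("g1", "g1", "g2", "g2", "g2", "g4"),
    stringsAsFactors = FALSE)
  regulatory_network(genes, mirnas, predictions)
}
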