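# Self-loop counting, context classification and the permutation test.

test_that("miRNA context classification tallies counts and percentages", {
  genes <- paste0("g", 1:10)
  mirnas <- data.frame(
    mirna_id = paste0("m", 1:10),
    context = c(rep("intergenic", 5), rep("intronic", 3), rep("exonic", 2)),
    strand_relation = c(rep(NA, 5), "same", "same", "same",
                        "opposite", "opposite"),
    host_gene = c(rep(NA, 5), "g1", "g2", "g3", "g4", "g5"),
    stringsAsFactors = FALSE)
  net <- regulatory_network(genes, mirnas, NULL)
  tab <- classify_mirnas(net)
  get <- function(cl) tab$percent[tab$class == cl]
  expect_equal(get("intergenic"), 50)
  expect_equal(get("intragenic"), 50)
  expect_equal(get("exonic"), 40)
  expect_equal(get("intronic"), 60)
  expect_equal(get("intronic_same"), 100)
  expect_equal(get("exonic_opposite"), 100)
  # percentages at each level sum to 100
  expect_equal(get("intergenic") + get("intragenic"), 100)
  expect_equal(get("exonic") + get("intronic"), 100)
})

test_that("degenerate networks classify without division by zero", {
  genes <- "g1"
  all_inter <- data.frame(mirna_id = c("m1", "m2"), context = "intergenic",
                          strand_relation = NA, host_gene = NA,
                          stringsAsFactors = FALSE)
  tab <- classify_mirnas(regulatory_network(genes, all_inter, NULL))
  expect_equal(tab$percent[tab$class == "intergenic"], 100)
  expect_equal(tab$percent[tab$class == "intragenic"], 0)
  expect_true(all(is.finite(tab$percent)))
  empty <- regulatory_network(genes, all_inter[0, ], NULL)
  tab0 <- classify_mirnas(empty)
  expect_true(all(tab0$count == 0))
  expect_true(all(is.finite(tab0$percent)))
})

test_that("iMSL counting honours strand, support and min_support monotonicity", {
  net <- toy_network()
  # m1: same-strand intronic, self-link supported by algorithms A and B
  expect_equal(count_imsl(net, 1)$count, 1)
  expect_equal(count_imsl(net, 2)$count, 1)
  expect_equal(count_imsl(net, 3)$count, 0)
  expect_equal(count_imsl(net, 1)$loops$support, 2)
  # m2 targets its host with full support but is opposite strand: not counted
  expect_false("m2" %in% count_imsl(net, 1)$loops$mirna_id)
  # counts are non-increasing in min_support
  counts <- vapply(1:3, function(k) count_imsl(net, k)$count, numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_error(count_imsl(net, 4), "exceeds")
  # no predictions: zero loops
  net0 <- regulatory_network(net$genes, net$mirnas, NULL)
  expect_equal(count_imsl(net0, 1)$count, 0)
})

test_that("permutations preserve their stated marginals", {
  set.seed(202)
  net <- generate_network(network_generator_spec(n_genes = 60, n_mirnas = 25,
                                                 pi = 0.05))
  for (k in 1:20) {
    ph <- permute_network(net, "host_reshuffle")
    # predictions untouched, host multiset preserved
    expect_identical(ph$predictions, net$predictions)
    expect_equal(sort(ph$mirnas$host_gene[ph$mirnas$context == "intronic"]),
                 sort(net$mirnas$host_gene[net$mirnas$context == "intronic"]))
    pt <- permute_network(net, "target_reshuffle")
    # per-miRNA union out-degree preserved, hosts untouched
    sup <- mirloop:::prediction_support(net)
    expect_equal(table(pt$predictions$mirna_id), table(sup$mirna_id))
    expect_identical(pt$mirnas, net$mirnas)
  }
})

test_that("Monte-Carlo host-reshuffle null matches the enumerated expectation", {
  set.seed(303)
  net <- generate_network(network_generator_spec(n_genes = 50, n_mirnas = 20,
                                                 pi = 0.05, epsilon = 0))
  exact <- expected_imsl_host_null(net)
  er <- enrichment_test(net, "host_reshuffle", n_perm = 1000)
  expect_equal(er$mean_null, exact,
               tolerance = 3 * er$sd_null / sqrt(1000) / max(exact, 1))
  # the x of the unpermuted network is itself reproduced by count_imsl
  expect_equal(er$x, count_imsl(net, 1)$count)
})

test_that("enrichment_test fast path agrees with permute_network + count_imsl", {
  set.seed(404)
  net <- generate_network(network_generator_spec(n_genes = 40, n_mirnas = 15,
                                                 pi = 0.08))
  for (strat in c("host_reshuffle", "target_reshuffle")) {
    er <- enrichment_test(net, strat, n_perm = 300)
    slow <- vapply(1:300, function(i) {
      count_imsl(permute_network(net, strat), 1)$count
    }, numeric(1))
    # same null distribution (compare means within combined MC error)
    se <- sqrt(er$sd_null^2 / 300 + stats::var(slow) / 300)
    expect_lt(abs(er$mean_null - mean(slow)), 4 * se)
  }
})

test_that("Z is invariant under relabeling of gene and miRNA IDs", {
  set.seed(505)
  net <- generate_network(network_generator_spec(n_genes = 40, n_mirnas = 15,
                                                 pi = 0.08, epsilon = 0.5))
  relabel <- function(net) {
    gmap <- stats::setNames(paste0("X", rev(seq_along(net$genes))), net$genes)
    mmap <- stats::setNames(paste0("Y", rev(seq_len(nrow(net$mirnas)))),
                            net$mirnas$mirna_id)
    m <- net$mirnas
    m$mirna_id <- unname(mmap[m$mirna_id])
    m$host_gene <- ifelse(is.na(m$host_gene), NA, unname(gmap[m$host_gene]))
    pr <- net$predictions
    pr$mirna_id <- unname(mmap[pr$mirna_id])
    pr$target_gene <- unname(gmap[pr$target_gene])
    regulatory_network(unname(gmap[net$genes]), m, pr)
  }
  net2 <- relabel(net)
  expect_equal(count_imsl(net2, 1)$count, count_imsl(net, 1)$count)
  set.seed(1); z1 <- enrichment_test(net, "host_reshuffle", n_perm = 400)$Z
  set.seed(1); z2 <- enrichment_test(net2, "host_reshuffle", n_perm = 400)$Z
  expect_equal(z1, z2)
})

test_that("degenerate null yields a flagged, undefined Z", {
  genes <- c("g1", "g2")
  mirnas <- data.frame(mirna_id = "m1", context = "intronic",
                       strand_relation = "same", host_gene = "g1",
                       stringsAsFactors = FALSE)
  net <- regulatory_network(genes, mirnas, NULL)
  expect_warning(er <- enrichment_test(net, "host_reshuffle", n_perm = 50),
                 "degenerate")
  expect_true(is.na(er$Z))
})
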