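toy_net <- function() {
  induce_subgroup_network(toy_kb(), toy_items(), toy_patterns())
}

test_that("MGF is the mean per-type connectivity fraction in the network", {
  net <- toy_net()
  # network: genes {g1..g5}, pathways {pw1,pw2,pw3}, BPs {bp1,bp2}
  expect_equal(mgf(net, "g1"), (1/5 + 2/3 + 1/2 + 0 + 0) / 5,
               tolerance = 1e-12)
  expect_equal(mgf(net, "g2"), (1/5 + 1/3 + 0 + 0 + 0) / 5,
               tolerance = 1e-12)
  expect_equal(mgf(net, "g3"), (1/5 + 1/3 + 1/2 + 0 + 0) / 5,
               tolerance = 1e-12)
  expect_error(mgf(net, "g6"), "not in the subgroup network")
})

test_that("a gene linked to 2 of 10 pathways and 1 of 5 processes scores 0.08", {
  net <- mgf_toy_net()
  expect_equal(mgf(net, "x1"), 0.08, tolerance = 1e-12)
  # entity tallies behind the fraction: 10 pathways, 5 processes, 2 genes
  expect_length(net$entity_sets$Pathway, 10)
  expect_length(net$entity_sets$BiologicalProcess, 5)
})

test_that("an isolated gene has zero weight and weights never exceed one", {
  nodes <- data.frame(node_id = c("solo", "other"), node_type = "Gene")
  kb <- knowledge_graph(nodes, data.frame(
    source_id = character(0), source_type = character(0),
    relation = character(0), target_id = character(0),
    target_type = character(0), direction = character(0)))
  net <- induce_subgroup_network(kb, data.frame(gene = "solo",
                                                direction = "UP"))
  expect_equal(mgf(net, "solo"), 0)
  case <- simulated_case(13, small_sim_control())
  items <- attr(case$cohort$items, "item_info")[1:5, ]
  simnet <- induce_subgroup_network(case$kb, items)
  for (g in simnet$gene_items$gene) {
    w <- mgf(simnet, g)
    expect_gte(w, 0); expect_lte(w, 1)
  }
})

test_that("the scoring cascade matches hand computation on the toy network", {
  kb <- toy_kb()
  net <- toy_net()
  w_g1 <- (1/5 + 2/3 + 1/2) / 5
  w_g2 <- (1/5 + 1/3) / 5
  w_g3 <- (1/5 + 1/3 + 1/2) / 5

  expect_equal(agf(net, "dA"), w_g1 + w_g3, tolerance = 1e-9)
  expect_equal(agf(net, "dB"), w_g2, tolerance = 1e-9)
  expect_equal(pa(net, "dA"), 1.0)
  expect_equal(pa(net, "dB"), 0.5)
  expect_equal(pa(net, "dA", mode = "all"), 0.5)
  expect_equal(pa(net, "dB", mode = "all"), 0.0)
  expect_equal(osm(0.5, 0.2), 0.7)
  expect_equal(gp(net, "dA"), 2/3, tolerance = 1e-12)
  expect_equal(gp(net, "dB"), 1/3, tolerance = 1e-12)
  # six genes in the toy knowledge base; dA perturbs 3, dB perturbs 2
  expect_equal(idf(kb, "dA"), log10(6/3), tolerance = 1e-12)
  expect_equal(idf(kb, "dB"), log10(6/2), tolerance = 1e-12)
  expect_equal(idf(kb, "dA", net, scope = "subgroup"), log10(6/2),
               tolerance = 1e-12)

  rk <- rank_drugs(net, kb)
  expect_equal(rk$drug_id, c("dA", "dB"))
  expect_equal(rk$rank, c(1L, 2L))
  expect_equal(rk$dscore[1], (1 + w_g1 + w_g3) * log10(2) * (2/3),
               tolerance = 1e-9)
  expect_equal(rk$dscore[2], (0.5 + w_g2) * log10(3) * (1/3),
               tolerance = 1e-9)
  expect_equal(rk$reversed_genes, c("g1;g3", "g2"))
})

test_that("IDF follows the inverse-frequency arithmetic and rejects unscorable drugs", {
  genes <- sprintf("gene%04d", 1:1000)
  nodes <- rbind(data.frame(node_id = genes, node_type = "Gene"),
                 data.frame(node_id = c("dx", "dy", "dz", "d0"),
                            node_type = "Drug"))
  e <- function(d, g) data.frame(source_id = d, source_type = "Drug",
                                 relation = "regulates", target_id = g,
                                 target_type = "Gene", direction = "up")
  kb <- knowledge_graph(nodes, rbind(e("dx", genes[1:10]),
                                     e("dy", genes[1]),
                                     e("dz", genes)))
  expect_equal(idf(kb, "dx"), 2.0, tolerance = 1e-12)
  expect_equal(idf(kb, "dy"), 3.0, tolerance = 1e-12)
  expect_equal(idf(kb, "dz"), 0.0, tolerance = 1e-12)
  expect_error(idf(kb, "d0"), "cannot be scored")
  # strictly decreasing in the number of perturbed genes
  expect_true(idf(kb, "dy") > idf(kb, "dx"))
  expect_true(idf(kb, "dx") > idf(kb, "dz"))
})

test_that("DScore is weakly monotone when a drug gains a reversed gene", {
  net <- toy_net()
  bigger <- net
  bigger$drug_items$dB <- sort(c(bigger$drug_items$dB, "g3:DOWN"))
  bigger$drug_targets$dB <- sort(c(bigger$drug_targets$dB, "g3"))
  for (fun in list(pa, agf, gp))
    expect_gte(fun(bigger, "dB"), fun(net, "dB"))
  fixed_idf <- 1.7
  d_before <- osm(pa(net, "dB"), agf(net, "dB")) * fixed_idf * gp(net, "dB")
  d_after <- osm(pa(bigger, "dB"), agf(bigger, "dB")) * fixed_idf *
    gp(bigger, "dB")
  expect_gte(d_after, d_before)
})

test_that("rankings satisfy the cascade identities and ignore drug input order", {
  case <- simulated_case(17)
  pats <- mine_contrast_patterns(case$cohort$items,
                                 case$truth$patient_ids)
  net <- induce_subgroup_network(case$kb, pattern_gene_items(pats), pats)
  rk <- rank_drugs(net, case$kb)
  expect_gt(nrow(rk), 0)
  expect_equal(rk$osm, rk$pa + rk$agf, tolerance = 1e-9)
  expect_equal(rk$dscore, rk$osm * rk$idf * rk$gp, tolerance = 1e-9)
  expect_equal(rk$rank, seq_len(nrow(rk)))
  expect_true(all(diff(rk$dscore) <= 1e-12))
  expect_true(all(rk$pa >= 0 & rk$pa <= 1))
  expect_true(all(rk$gp >= 0 & rk$gp <= 1))

  shuffled <- net
  perm <- rev(seq_along(net$drug_items))
  shuffled$drug_items <- net$drug_items[perm]
  shuffled$drug_targets <- net$drug_targets[perm]
  expect_equal(rank_drugs(shuffled, case$kb), rk)
})

test_that("a network without drugs yields an empty ranking with a warning", {
  nodes <- data.frame(node_id = c("a", "b"), node_type = "Gene")
  kb <- knowledge_graph(nodes, data.frame(
    source_id = "a", source_type = "Gene", relation = "interacts_with",
    target_id = "b", target_type = "Gene", direction = "."))
  net <- induce_subgroup_network(kb, data.frame(gene = "a",
                                                direction = "UP"),
                                 toy_patterns())
  expect_warning(rk <- rank_drugs(net, kb), "no drug")
  expect_equal(nrow(rk), 0)
})
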