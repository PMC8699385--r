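# Independent oracles and small fixture builders shared across tests.

# Brute-force contrast-pattern oracle: enumerate every itemset up to
# max_len by exhaustive combination, score it by direct row scans, and
# apply the thresholds. Independent of the level-wise miner.
oracle_mine <- function(items, sg_ids, control = mining_control(),
                        max_len = control$max_pattern_len) {
  cols <- colnames(items)
  in_sg <- rownames(items) %in% sg_ids
  out <- list()
  for (k in seq_len(min(max_len, length(cols)))) {
    cmb <- utils::combn(cols, k)
    for (j in seq_len(ncol(cmb))) {
      set <- sort(cmb[, j])
      carr <- rowSums(items[, set, drop = FALSE]) == k
      s1 <- mean(carr[in_sg]); s2 <- mean(carr[!in_sg])
      if (s1 <= control$support_min) next
      g <- if (min(s1, s2) == 0) control$growth_cap else
        max(s1, s2) / min(s1, s2)
      conf <- sum(carr[in_sg]) / sum(carr)
      if (g > control$growth_min && conf >= control$confidence_min)
        out[[length(out) + 1L]] <- data.frame(
          items = paste(set, collapse = ";"), length = k,
          s1 = s1, s2 = s2, growth = g, confidence = conf,
          stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out) > 0) do.call(rbind, out) else
    data.frame(items = character(0), length = integer(0), s1 = numeric(0),
               s2 = numeric(0), growth = numeric(0),
               confidence = numeric(0))
  res <- res[order(res$length, res$items), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Random boolean item matrix with per-item carriage probabilities drawn
# wide enough to produce frequent itemsets.
random_item_matrix <- function(n_patients, n_items) {
  p <- runif(n_items, 0.1, 0.95)
  m <- sapply(p, function(pi) runif(n_patients) < pi)
  rownames(m) <- sprintf("P%02d", seq_len(n_patients))
  # one item per gene, so the one-direction-per-gene invariant holds
  colnames(m) <- paste0("G", sprintf("%02d", seq_len(n_items)),
                        ifelse(seq_len(n_items) %% 2 == 0, ":DOWN", ":UP"))
  m
}

# Exhaustive subgroup-search oracle: evaluate every nonempty conjunction
# of clinical predicates (one value per variable, all variable subsets)
# and return the best SPCScore among viable subgroups clearing spc_min.
oracle_best_spc <- function(cohort, kb, control) {
  reference <- reference_subgroups(
    cohort$clinical, cohort$items, control$mining,
    R = control$jvalue$n_random_subgroups, seed = control$seed,
    jorg_stat = control$jvalue$jorg_stat,
    na_category = cohort$na_category)
  vars <- setdiff(names(cohort$clinical), "patient_id")
  vals <- lapply(vars, function(v)
    setdiff(sort(unique(cohort$clinical[[v]])), cohort$na_category))
  names(vals) <- vars
  best <- -Inf; n_conj <- 0L
  for (k in seq_along(vars)) {
    for (vs in utils::combn(vars, k, simplify = FALSE)) {
      grid <- expand.grid(vals[vs], stringsAsFactors = FALSE)
      for (i in seq_len(nrow(grid))) {
        defn <- stats::setNames(as.character(grid[i, ]), vs)
        n_conj <- n_conj + 1L
        r <- evaluate_subgroup(defn, cohort, kb, control, reference)
        if (isTRUE(r$viable) && r$spc_score > control$spc_min)
          best <- max(best, r$spc_score)
      }
    }
  }
  list(best = best, n_conjunctions = n_conj)
}

# Small planted simulation used by several tests.
small_sim_control <- function(...) {
  simulation_control(
    n_patients = 60L, n_planted = 15L,
    clinical_vars = c(v1 = 2L, v2 = 3L, v3 = 2L),
    planted_definition = c(v1 = "v1_1", v2 = "v2_1"),
    n_genes = 30L, n_deg_decoys = 7L,
    kb = list(n_pathways = 8L, n_bp = 5L, n_cc = 4L, n_mf = 4L,
              n_diseases = 3L, n_drugs = 12L, membership_rate = 0.1,
              gg_rate = 0.03, disease_rate = 0.05),
    ...)
}

simulated_case <- function(seed, cfg = simulation_control()) {
  sim <- simulate_cohort(cfg, seed)
  kb <- simulate_kb(cfg, sim$truth, seed + 1000L)
  cohort <- build_cohort(sim$clinical, sim$expression, sim$deg_stats)
  list(sim = sim, kb = kb, cohort = cohort, truth = sim$truth)
}

# Hand-built toy knowledge graph used by the scoring-cascade tests:
# six genes, three pathways, two biological processes, two drugs.
toy_kb <- function() {
  nodes <- rbind(
    data.frame(node_id = paste0("g", 1:6), node_type = "Gene"),
    data.frame(node_id = paste0("pw", 1:3), node_type = "Pathway"),
    data.frame(node_id = paste0("bp", 1:2),
               node_type = "BiologicalProcess"),
    data.frame(node_id = c("dA", "dB"), node_type = "Drug"))
  e <- function(s, st, rel, t, tt, dir = ".")
    data.frame(source_id = s, source_type = st, relation = rel,
               target_id = t, target_type = tt, direction = dir,
               stringsAsFactors = FALSE)
  edges <- rbind(
    e("g1", "Gene", "member_of", "pw1", "Pathway"),
    e("g1", "Gene", "member_of", "pw2", "Pathway"),
    e("g2", "Gene", "member_of", "pw2", "Pathway"),
    e("g3", "Gene", "member_of", "pw3", "Pathway"),
    e("g1", "Gene", "member_of", "bp1", "BiologicalProcess"),
    e("g3", "Gene", "member_of", "bp2", "BiologicalProcess"),
    e("g1", "Gene", "interacts_with", "g4", "Gene"),
    e("g2", "Gene", "interacts_with", "g4", "Gene"),
    e("g3", "Gene", "interacts_with", "g5", "Gene"),
    e("g5", "Gene", "interacts_with", "g6", "Gene"),
    e("dA", "Drug", "regulates", "g1", "Gene", "down"),
    e("dA", "Drug", "regulates", "g3", "Gene", "up"),
    e("dA", "Drug", "regulates", "g6", "Gene", "up"),
    e("dB", "Drug", "regulates", "g2", "Gene", "down"),
    e("dB", "Drug", "regulates", "g1", "Gene", "up"))
  knowledge_graph(nodes, edges)
}

toy_items <- function() {
  data.frame(gene = c("g1", "g2", "g3"),
             direction = c("UP", "UP", "DOWN"),
             stringsAsFactors = FALSE)
}

# Two-gene network in which gene x1 touches 2 of 10 pathways and 1 of 5
# biological processes and nothing else: its MGF is (0.2 + 0.2)/5 = 0.08.
mgf_toy_net <- function() {
  nodes <- rbind(
    data.frame(node_id = c("x1", "x2"), node_type = "Gene"),
    data.frame(node_id = sprintf("pw%02d", 1:10), node_type = "Pathway"),
    data.frame(node_id = paste0("bp", 1:5),
               node_type = "BiologicalProcess"))
  e <- function(g, t, tt) data.frame(source_id = g, source_type = "Gene",
                                     relation = "member_of", target_id = t,
                                     target_type = tt, direction = ".")
  edges <- rbind(e("x1", c("pw01", "pw02"), "Pathway"),
                 e("x2", sprintf("pw%02d", 1:10), "Pathway"),
                 e("x1", "bp1", "BiologicalProcess"),
                 e("x2", paste0("bp", 1:5), "BiologicalProcess"))
  induce_subgroup_network(
    knowledge_graph(nodes, edges),
    data.frame(gene = c("x1", "x2"), direction = "UP"))
}

toy_patterns <- function() {
  structure(data.frame(
    items = c("g1:UP;g2:UP", "g3:DOWN"),
    length = c(2L, 1L), s1 = c(0.8, 0.9), s2 = c(0, 0),
    growth = c(100, 100), confidence = c(1, 1),
    stringsAsFactors = FALSE),
    class = c("contrast_patterns", "data.frame"))
}
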