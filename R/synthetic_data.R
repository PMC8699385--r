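#' Configuration of the synthetic cohort and knowledge-graph generator
#'
#' The generator emulates the statistical structure the subgroup-discovery
#' method assumes: a clinically defined patient subgroup carrying planted,
#' co-occurring dysregulated gene items, embedded in a cohort with
#' independent background noise, plus a knowledge graph containing one
#' planted drug that reverses the planted signature and decoy drugs that do
#' not.
#'
#' Dysregulation is modeled as a switch to a distinct expression level:
#' a carrier's log-expression sits at `baseline +/- effect_size` with small
#' dispersion `dysreg_sd`, while biological variability is expressed in
#' whether the switch occurs at all (`penetrance`). Background dysregulation
#' flips any differential gene in any other patient at
#' `background_item_rate`, with a random direction.
#'
#' @param n_patients Cohort size.
#' @param n_planted Number of patients carrying the planted subgroup
#'   signature.
#' @param clinical_vars Named integer vector: categorical clinical
#'   variables and their category counts. Categories of variable `v` are
#'   labeled `v_1 ... v_k`.
#' @param planted_definition Named character vector of
#'   `variable = category` predicates defining the planted subgroup.
#' @param exclusive_definition When `TRUE` (default) the planted categories
#'   of the definition variables occur only in planted patients, so the
#'   definition delineates the subgroup exactly; when `FALSE` non-planted
#'   patients may share single predicates (full accidental matches are
#'   re-drawn either way).
#' @param n_genes Size of the gene universe (`G001 ...`).
#' @param planted_items Data.frame (`gene`, `direction`) of the planted
#'   co-regulated items.
#' @param n_deg_decoys Differentially expressed decoy genes that pass the
#'   DEG thresholds without carrying subgroup structure.
#' @param effect_size Log-scale shift of a dysregulated value, in units of
#'   the unit-variance background noise.
#' @param penetrance Probability that a planted item appears in a planted
#'   patient.
#' @param background_item_rate Per-cell probability of background
#'   dysregulation outside the planted cells.
#' @param dysreg_sd Dispersion of the dysregulated expression level.
#' @param kb List of knowledge-graph sizes: `n_pathways`, `n_bp`, `n_cc`,
#'   `n_mf`, `n_diseases`, `n_drugs` (planted drug included),
#'   `membership_rate`, `gg_rate` (gene-gene edge probability),
#'   `disease_rate`.
#' @param planted_drug_fidelity Share of planted items reversed by the
#'   planted drug.
#' @return A list of class `simulation_control`.
#' @export
simulation_control <- function(
    n_patients = 120L, n_planted = 30L,
    clinical_vars = c(subtype = 3L, histology = 3L, race = 3L,
                      age_group = 2L),
    planted_definition = c(subtype = "subtype_1", histology = "histology_1"),
    exclusive_definition = TRUE,
    n_genes = 60L,
    planted_items = data.frame(gene = c("G001", "G002", "G003"),
                               direction = c("UP", "UP", "DOWN"),
                               stringsAsFactors = FALSE),
    n_deg_decoys = 17L,
    effect_size = 2.5, penetrance = 0.9, background_item_rate = 0.05,
    dysreg_sd = 0.1,
    kb = list(n_pathways = 15L, n_bp = 10L, n_cc = 8L, n_mf = 8L,
              n_diseases = 5L, n_drugs = 12L, membership_rate = 0.08,
              gg_rate = 0.02, disease_rate = 0.03),
    planted_drug_fidelity = 1.0) {
  genes <- sprintf("G%03d", seq_len(n_genes))
  if (!all(names(planted_definition) %in% names(clinical_vars)))
    stop("planted definition uses unknown clinical variables")
  for (v in names(planted_definition)) {
    vals <- paste0(v, "_", seq_len(clinical_vars[[v]]))
    if (!planted_definition[[v]] %in% vals)
      stop("planted category '", planted_definition[[v]],
           "' is not a category of variable '", v, "'")
    if (clinical_vars[[v]] < 2)
      stop("definition variable '", v, "' needs at least two categories")
  }
  if (!all(planted_items$gene %in% genes))
    stop("planted item genes outside the gene universe")
  if (!all(planted_items$direction %in% c("UP", "DOWN")))
    stop("planted item directions must be UP or DOWN")
  rates <- c(penetrance, background_item_rate, planted_drug_fidelity,
             kb$membership_rate, kb$gg_rate, kb$disease_rate)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  if (n_planted < 2 || n_planted > n_patients - 2)
    stop("the planted subgroup must select between 2 and n_patients - 2 patients")
  if (n_deg_decoys + length(unique(planted_items$gene)) > n_genes)
    stop("more DEG genes requested than the gene universe holds")
  structure(list(n_patients = as.integer(n_patients),
                 n_planted = as.integer(n_planted),
                 clinical_vars = clinical_vars,
                 planted_definition = planted_definition,
                 exclusive_definition = isTRUE(exclusive_definition),
                 n_genes = as.integer(n_genes), genes = genes,
                 planted_items = planted_items,
                 n_deg_decoys = as.integer(n_deg_decoys),
                 effect_size = effect_size, penetrance = penetrance,
                 background_item_rate = background_item_rate,
                 dysreg_sd = dysreg_sd, kb = kb,
                 planted_drug_fidelity = planted_drug_fidelity),
            class = "simulation_control")
}

#' Simulate a cohort with a planted subgroup
#'
#' Generates the clinical table, the expression matrix (raw scale; apply
#' [normalize_log2()] downstream), per-gene differential statistics under
#' which exactly the planted and decoy DEG genes pass the default
#' thresholds, and the planted ground truth. Identical seeds give
#' identical output.
#'
#' @param cfg A [simulation_control()].
#' @param seed Integer seed.
#' @return List with `clinical`, `expression`, `deg_stats`, `truth`; the
#'   truth holds the planted patient ids, definition, items, the planted
#'   drug id and the decoy drug ids.
#' @export
simulate_cohort <- function(cfg = simulation_control(), seed = 1L) {
  with_seed(seed, {
    n <- cfg$n_patients
    patients <- sprintf("P%03d", seq_len(n))
    planted <- sort(sample.int(n, cfg$n_planted))
    is_planted <- seq_len(n) %in% planted

    clinical <- data.frame(patient_id = patients,
                           stringsAsFactors = FALSE)
    for (v in names(cfg$clinical_vars)) {
      vals <- paste0(v, "_", seq_len(cfg$clinical_vars[[v]]))
      x <- sample(vals, n, replace = TRUE)
      if (v %in% names(cfg$planted_definition)) {
        pv <- cfg$planted_definition[[v]]
        x[is_planted] <- pv
        if (cfg$exclusive_definition) {
          other <- setdiff(vals, pv)
          x[!is_planted] <- sample(other, sum(!is_planted), replace = TRUE)
        }
      }
      clinical[[v]] <- x
    }
    if (!cfg$exclusive_definition) {
      # redraw non-planted patients that accidentally satisfy the full
      # definition, so the definition selects exactly the planted subgroup
      full <- rep(TRUE, n)
      for (v in names(cfg$planted_definition))
        full <- full & clinical[[v]] == cfg$planted_definition[[v]]
      for (i in which(full & !is_planted)) {
        v <- names(cfg$planted_definition)[1L]
        vals <- paste0(v, "_", seq_len(cfg$clinical_vars[[v]]))
        clinical[i, v] <- sample(setdiff(vals, cfg$planted_definition[[v]]), 1L)
      }
    }
    attr(clinical, "na_category") <- "missing"

    g <- cfg$n_genes
    baseline <- stats::runif(g, 6, 10)
    L <- baseline + matrix(stats::rnorm(g * n), nrow = g, ncol = n,
                           dimnames = list(cfg$genes, patients))
    planted_cells <- matrix(FALSE, g, n, dimnames = dimnames(L))
    for (i in seq_len(nrow(cfg$planted_items))) {
      gi <- cfg$planted_items$gene[i]
      s <- if (cfg$planted_items$direction[i] == "UP") 1 else -1
      carrier <- planted[stats::runif(cfg$n_planted) < cfg$penetrance]
      planted_cells[gi, planted] <- TRUE
      if (length(carrier) > 0)
        L[gi, carrier] <- baseline[match(gi, cfg$genes)] +
          s * cfg$effect_size +
          stats::rnorm(length(carrier), 0, cfg$dysreg_sd)
    }
    planted_genes <- unique(cfg$planted_items$gene)
    decoy_genes <- setdiff(cfg$genes, planted_genes)[
      seq_len(cfg$n_deg_decoys)]
    deg_genes <- sort(c(planted_genes, decoy_genes))
    for (gi in deg_genes) {
      eligible <- which(!planted_cells[gi, ])
      flip <- eligible[stats::runif(length(eligible)) <
                         cfg$background_item_rate]
      if (length(flip) > 0) {
        s <- sample(c(-1, 1), length(flip), replace = TRUE)
        L[gi, flip] <- baseline[match(gi, cfg$genes)] +
          s * cfg$effect_size +
          stats::rnorm(length(flip), 0, cfg$dysreg_sd)
      }
    }
    expression <- pmax(2^L - 1, 0)

    is_deg <- cfg$genes %in% deg_genes
    lfc_sign <- stats::setNames(sample(c(-1, 1), g, replace = TRUE),
                                cfg$genes)
    for (i in seq_len(nrow(cfg$planted_items)))
      lfc_sign[cfg$planted_items$gene[i]] <-
        if (cfg$planted_items$direction[i] == "UP") 1 else -1
    deg_stats <- data.frame(
      gene_id = cfg$genes,
      log2fc = ifelse(is_deg,
                      lfc_sign * stats::runif(g, 2.2, 4.0),
                      stats::runif(g, -1.5, 1.5)),
      pvalue = ifelse(is_deg,
                      stats::runif(g, 1e-6, 0.01),
                      stats::runif(g, 0.2, 0.95)),
      stringsAsFactors = FALSE)

    n_drugs <- cfg$kb$n_drugs
    truth <- list(patient_ids = patients[planted],
                  definition = cfg$planted_definition,
                  items = cfg$planted_items,
                  planted_drug = "D001",
                  decoy_drugs = sprintf("D%03d", seq_len(n_drugs)[-1L]))
    list(clinical = clinical, expression = expression,
         deg_stats = deg_stats, truth = truth)
  })
}

#' Simulate a knowledge graph with a planted reversing drug
#'
#' Builds a gene-centric graph over the configured gene universe: random
#' memberships into pathways and GO domains, sparse gene-gene
#' interactions, gene-disease associations, one planted drug whose edges
#' reverse the planted items (opposite direction), and decoy drugs of
#' three kinds cycling by index: same-direction binders of the planted
#' genes (never reversal-matched), partial reversers that reverse a single
#' planted item while also perturbing several unrelated genes, and
#' promiscuous drugs touching only unrelated genes.
#'
#' @param cfg A [simulation_control()].
#' @param truth The `truth` element returned by [simulate_cohort()].
#' @param seed Integer seed.
#' @return A validated `knowledge_graph`.
#' @export
simulate_kb <- function(cfg = simulation_control(), truth, seed = 1L) {
  with_seed(seed, {
    genes <- cfg$genes
    ann <- list(Pathway = sprintf("PW%03d", seq_len(cfg$kb$n_pathways)),
                BiologicalProcess = sprintf("BP%03d", seq_len(cfg$kb$n_bp)),
                CellularComponent = sprintf("CC%03d", seq_len(cfg$kb$n_cc)),
                MolecularFunction = sprintf("MF%03d", seq_len(cfg$kb$n_mf)),
                Disease = sprintf("DIS%03d", seq_len(cfg$kb$n_diseases)))
    drugs <- sprintf("D%03d", seq_len(cfg$kb$n_drugs))
    nodes <- rbind(
      data.frame(node_id = genes, node_type = "Gene"),
      do.call(rbind, lapply(names(ann), function(t)
        data.frame(node_id = ann[[t]], node_type = t))),
      data.frame(node_id = drugs, node_type = "Drug"))

    edge_row <- function(s, st, rel, t, tt, dir = ".") {
      data.frame(source_id = s, source_type = st, relation = rel,
                 target_id = t, target_type = tt, direction = dir,
                 stringsAsFactors = FALSE)
    }
    edges <- list()
    for (t in c("Pathway", "BiologicalProcess", "CellularComponent",
                "MolecularFunction")) {
      grid <- expand.grid(gene = genes, node = ann[[t]],
                          stringsAsFactors = FALSE)
      hit <- grid[stats::runif(nrow(grid)) < cfg$kb$membership_rate, ]
      if (nrow(hit) > 0)
        edges[[length(edges) + 1L]] <-
          edge_row(hit$gene, "Gene", "member_of", hit$node, t)
    }
    grid <- expand.grid(gene = genes, node = ann$Disease,
                        stringsAsFactors = FALSE)
    hit <- grid[stats::runif(nrow(grid)) < cfg$kb$disease_rate, ]
    if (nrow(hit) > 0)
      edges[[length(edges) + 1L]] <-
        edge_row(hit$gene, "Gene", "associated_with", hit$node, "Disease")
    pairs <- utils::combn(genes, 2)
    keep <- stats::runif(ncol(pairs)) < cfg$kb$gg_rate
    if (any(keep))
      edges[[length(edges) + 1L]] <-
        edge_row(pairs[1, keep], "Gene", "interacts_with",
                 pairs[2, keep], "Gene")

    opp <- c(UP = "down", DOWN = "up")
    same <- c(UP = "up", DOWN = "down")
    items <- truth$items
    items <- items[order(items$gene), , drop = FALSE]
    planted_genes <- unique(items$gene)
    other_genes <- setdiff(genes, planted_genes)

    k_rev <- max(1L, round(cfg$planted_drug_fidelity * nrow(items)))
    rev_items <- items[seq_len(k_rev), , drop = FALSE]
    edges[[length(edges) + 1L]] <-
      edge_row(truth$planted_drug, "Drug", "regulates",
               rev_items$gene, "Gene", opp[rev_items$direction])

    kinds <- rep(c("same_direction", "partial", "promiscuous"),
                 length.out = length(truth$decoy_drugs))
    for (i in seq_along(truth$decoy_drugs)) {
      d <- truth$decoy_drugs[i]
      if (kinds[i] == "same_direction") {
        edges[[length(edges) + 1L]] <-
          edge_row(d, "Drug", "regulates", items$gene, "Gene",
                   same[items$direction])
      } else if (kinds[i] == "partial") {
        it <- items[1L + ((i %/% 3L) %% nrow(items)), , drop = FALSE]
        extra <- sample(other_genes, 4L)
        edges[[length(edges) + 1L]] <- rbind(
          edge_row(d, "Drug", "regulates", it$gene, "Gene",
                   opp[it$direction]),
          edge_row(d, "Drug", "regulates", extra, "Gene",
                   sample(c("up", "down"), 4L, replace = TRUE)))
      } else {
        extra <- sample(other_genes, 8L)
        edges[[length(edges) + 1L]] <-
          edge_row(d, "Drug", "regulates", extra, "Gene",
                   sample(c("up", "down"), 8L, replace = TRUE))
      }
    }
    knowledge_graph(nodes, do.call(rbind, edges))
  })
}
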