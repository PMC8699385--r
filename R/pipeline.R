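#' Write a simulated cohort and knowledge graph to disk
#'
#' Emits the TSV dialects consumed by the loaders plus the planted ground
#' truth: `clinical.tsv`, `expression.tsv`, `deg_stats.tsv`,
#' `kb_nodes.tsv`, `kb_edges.tsv`, `truth.json`.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed; the knowledge graph uses `seed + 1`.
#' @param control A [simulation_control()].
#' @return Invisibly, a named vector of the six file paths.
#' @export
run_simulate <- function(out_dir, seed = 1L,
                         control = simulation_control()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_cohort(control, seed)
  kb <- simulate_kb(control, sim$truth, seed + 1L)
  paths <- c(clinical = file.path(out_dir, "clinical.tsv"),
             expression = file.path(out_dir, "expression.tsv"),
             deg_stats = file.path(out_dir, "deg_stats.tsv"),
             kb_nodes = file.path(out_dir, "kb_nodes.tsv"),
             kb_edges = file.path(out_dir, "kb_edges.tsv"),
             truth = file.path(out_dir, "truth.json"))
  utils::write.table(sim$clinical, paths["clinical"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  expr <- data.frame(gene_id = rownames(sim$expression),
                     sim$expression, check.names = FALSE)
  utils::write.table(format(expr, digits = 15, trim = TRUE),
                     paths["expression"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(format(sim$deg_stats, digits = 15, trim = TRUE),
                     paths["deg_stats"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_kb(kb, paths["kb_nodes"], paths["kb_edges"])
  truth <- sim$truth
  truth$definition <- as.list(truth$definition)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

load_inputs <- function(clinical, expression, deg_stats,
                        kb_nodes, kb_edges, normalize = TRUE, ...) {
  cl <- read_clinical(clinical)
  ex <- read_expression(expression)
  dg <- read_deg_stats(deg_stats)
  cohort <- build_cohort(cl, ex, dg, normalize = normalize, ...)
  kb <- read_kb(kb_nodes, kb_edges)
  list(cohort = cohort, kb = kb)
}

subgroup_set_to_list <- function(sgs) {
  list(
    subgroups = lapply(seq_along(sgs$results), function(i) {
      r <- sgs$results[[i]]
      list(id = paste0("sg", i),
           predicates = as.list(r$definition),
           patient_ids = r$patient_ids,
           n_patients = length(r$patient_ids),
           jorg = r$jorg, j_value = r$j_value, ncs = r$ncs,
           spc_score = r$spc_score,
           patterns = r$patterns[, c("items", "s1", "s2", "growth",
                                     "confidence")])
    }),
    reference = list(javg = mean(sgs$reference$jorgs),
                     M = sgs$reference$M),
    parameters = list(
      beam_width = sgs$control$beam_width,
      max_depth = sgs$control$max_depth,
      min_patients = sgs$control$min_patients,
      spc_min = sgs$control$spc_min,
      support_min = sgs$control$mining$support_min,
      growth_min = sgs$control$mining$growth_min,
      confidence_min = sgs$control$mining$confidence_min,
      max_pattern_len = sgs$control$mining$max_pattern_len,
      growth_cap = sgs$control$mining$growth_cap,
      n_random_subgroups = sgs$control$jvalue$n_random_subgroups,
      seed = sgs$control$seed),
    trajectory = sgs$trajectory)
}

#' Stratify a cohort from files
#'
#' End-to-end subgroup discovery on TSV inputs; writes the retained
#' subgroups, their patterns and the beam trajectory as JSON. An empty DEG
#' list yields an empty (but valid) result file.
#'
#' @param clinical,expression,deg_stats,kb_nodes,kb_edges Input paths.
#' @param out Output JSON path.
#' @param control A [search_control()].
#' @param normalize Apply log2 normalization to the expression input?
#' @param ... Further arguments to [build_cohort()].
#' @return Invisibly, the `subgroup_set`.
#' @export
run_stratify <- function(clinical, expression, deg_stats,
                         kb_nodes, kb_edges, out,
                         control = search_control(), normalize = TRUE,
                         ...) {
  inp <- load_inputs(clinical, expression, deg_stats, kb_nodes, kb_edges,
                     normalize = normalize, ...)
  sgs <- discover_subgroups(inp$cohort, inp$kb, control)
  dir.create(dirname(out), showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(subgroup_set_to_list(sgs), out, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, dataframe = "rows")
  invisible(sgs)
}

#' Rank drugs for stratified subgroups
#'
#' Re-evaluates the subgroup definitions recorded in a stratification JSON
#' (deterministic given the same inputs and seed) and writes one ranking
#' TSV per selected subgroup (`ranking_<id>.tsv`).
#'
#' @param clinical,expression,deg_stats,kb_nodes,kb_edges Input paths.
#' @param stratify_json Output of [run_stratify()].
#' @param out_dir Directory for the ranking TSVs.
#' @param subgroups Character vector of subgroup ids (`"sg1"`, ...);
#'   `NULL` ranks all.
#' @param control The [search_control()] used for stratification.
#' @param idf_scope,pa_mode Passed to [rank_drugs()].
#' @param normalize Apply log2 normalization to the expression input?
#' @param ... Further arguments to [build_cohort()].
#' @return Invisibly, a named list of `drug_ranking` tables.
#' @export
run_rank <- function(clinical, expression, deg_stats, kb_nodes, kb_edges,
                     stratify_json, out_dir, subgroups = NULL,
                     control = search_control(),
                     idf_scope = "kb_wide", pa_mode = "any",
                     normalize = TRUE, ...) {
  res <- jsonlite::read_json(stratify_json, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  ids <- vapply(res$subgroups, `[[`, "", "id")
  if (is.null(subgroups)) subgroups <- ids
  unknown <- setdiff(subgroups, ids)
  if (length(unknown) > 0)
    stop("unknown subgroup id: ", paste(unknown, collapse = ", "))
  if (length(subgroups) == 0) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    return(invisible(list()))
  }
  inp <- load_inputs(clinical, expression, deg_stats, kb_nodes, kb_edges,
                     normalize = normalize, ...)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rankings <- list()
  for (id in subgroups) {
    sg <- res$subgroups[[match(id, ids)]]
    defn <- unlist(sg$predicates)
    r <- evaluate_subgroup(defn, inp$cohort, inp$kb, control)
    path <- file.path(out_dir, paste0("ranking_", id, ".tsv"))
    if (isTRUE(r$viable) && length(r$network$drug_targets) > 0) {
      rk <- rank_drugs(r$network, inp$kb, idf_scope, pa_mode)
    } else {
      rk <- suppressWarnings(rank_drugs(empty_subgroup_network(), inp$kb))
    }
    write_ranking(rk, path)
    rankings[[id]] <- rk
  }
  invisible(rankings)
}

#' Run the full pipeline on synthetic data
#'
#' Simulate, stratify and rank in one call; all outputs land in
#' `out_dir` (`subgroups.json`, `ranking_sg*.tsv`, plus the simulated
#' inputs).
#'
#' @param out_dir Output directory.
#' @param seed Integer seed for all stages.
#' @param sim_control A [simulation_control()].
#' @param search A [search_control()]; its seed is overridden by `seed`.
#' @param idf_scope,pa_mode Passed to [rank_drugs()].
#' @return Invisibly, a list with the `subgroup_set`, the rankings and the
#'   planted truth.
#' @export
run_all <- function(out_dir, seed = 1L,
                    sim_control = simulation_control(),
                    search = search_control(),
                    idf_scope = "kb_wide", pa_mode = "any") {
  search$seed <- as.integer(seed)
  paths <- run_simulate(out_dir, seed, sim_control)
  sgs <- run_stratify(paths["clinical"], paths["expression"],
                      paths["deg_stats"], paths["kb_nodes"],
                      paths["kb_edges"],
                      out = file.path(out_dir, "subgroups.json"),
                      control = search)
  rankings <- run_rank(paths["clinical"], paths["expression"],
                       paths["deg_stats"], paths["kb_nodes"],
                       paths["kb_edges"],
                       stratify_json = file.path(out_dir, "subgroups.json"),
                       out_dir = out_dir, control = search,
                       idf_scope = idf_scope, pa_mode = pa_mode)
  truth <- jsonlite::read_json(paths["truth"], simplifyVector = TRUE)
  invisible(list(subgroups = sgs, rankings = rankings, truth = truth))
}

#' Did the search recover the planted subgroup?
#'
#' With exclusive contrast patterns (confidence 1) adding a predicate that
#' does not change the selected patients cannot strictly raise the
#' SPCScore, so the search reports the most parsimonious definition of a
#' patient set. Recovery is therefore assessed on the selected patients: a
#' top-`k` result recovers the planted truth when its patient set equals
#' the planted patient set and its predicates are a subset of the planted
#' definition.
#'
#' @param sgs A `subgroup_set`.
#' @param truth Planted truth from [simulate_cohort()] (or read from
#'   `truth.json`).
#' @param top Number of leading results to inspect.
#' @return `TRUE` or `FALSE`.
#' @export
truth_recovered <- function(sgs, truth, top = 5L) {
  defn <- unlist(truth$definition)
  target <- sort(unlist(truth$patient_ids))
  for (r in utils::head(sgs$results, top)) {
    if (identical(sort(r$patient_ids), target) &&
        all(names(r$definition) %in% names(defn)) &&
        all(r$definition == defn[names(r$definition)]))
      return(TRUE)
  }
  FALSE
}
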