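#' Mean gene frequency (MGF)
#'
#' A gene's weight in the subgroup network: the mean, over the five
#' gene-annotation entity types (Gene, Pathway, BiologicalProcess,
#' CellularComponent, MolecularFunction), of the fraction of that type's
#' network entities in direct interaction with the gene. The gene-gene term
#' excludes the gene from its own numerator; a type with no entities in the
#' network contributes 0. Hub genes therefore weigh more than peripheral
#' ones.
#'
#' @param sgnw A `subgroup_network`.
#' @param gene A gene id present in the network's gene entity set.
#' @return A number in `[0, 1]`.
#' @export
mgf <- function(sgnw, gene) {
  if (!gene %in% sgnw$entity_sets[["Gene"]])
    stop("gene '", gene, "' is not in the subgroup network")
  ed <- sgnw$edges
  terms <- vapply(MGF_TYPES, function(t) {
    NE <- length(sgnw$entity_sets[[t]])
    if (NE == 0) return(0)
    if (t == "Gene") {
      gg <- ed[ed$source_type == "Gene" & ed$target_type == "Gene", ]
      nb <- unique(c(gg$target_id[gg$source_id == gene],
                     gg$source_id[gg$target_id == gene]))
      nb <- intersect(setdiff(nb, gene), sgnw$entity_sets[["Gene"]])
      length(nb) / NE
    } else {
      adj <- ed[ed$source_id == gene & ed$target_type == t, ]
      length(intersect(unique(adj$target_id), sgnw$entity_sets[[t]])) / NE
    }
  }, numeric(1))
  mean(terms)
}

#' Accumulative gene frequency (AGF)
#'
#' Sum of the MGF weights of the genes whose expression the drug reverses
#' in the subgroup.
#'
#' @param sgnw A `subgroup_network`.
#' @param drug A drug id present in the network.
#' @param weights Optional named vector of precomputed MGF weights.
#' @return A non-negative number.
#' @export
agf <- function(sgnw, drug, weights = NULL) {
  genes <- sgnw$drug_targets[[drug]]
  if (is.null(genes)) stop("drug '", drug, "' is not in the subgroup network")
  if (length(genes) == 0) return(0)
  if (is.null(weights))
    weights <- vapply(genes, function(g) mgf(sgnw, g), numeric(1))
  sum(weights[genes])
}

#' Percentage of patterns targeted by a drug (PA)
#'
#' The fraction of the subgroup's contrast patterns the drug targets.
#' Under `mode = "any"` (default) a pattern counts as targeted when the
#' drug reverses at least one of its items; under `"all"` every item must
#' be reversed.
#'
#' @param sgnw A `subgroup_network` whose `patterns` table is nonempty.
#' @param drug A drug id present in the network.
#' @param mode `"any"` or `"all"`.
#' @return A fraction in `[0, 1]`.
#' @export
pa <- function(sgnw, drug, mode = c("any", "all")) {
  mode <- match.arg(mode)
  if (is.null(sgnw$patterns) || nrow(sgnw$patterns) == 0)
    stop("the subgroup network has no patterns")
  hit_items <- sgnw$drug_items[[drug]]
  if (is.null(hit_items))
    stop("drug '", drug, "' is not in the subgroup network")
  sets <- pattern_item_sets(sgnw$patterns)
  hits <- vapply(sets, function(s) {
    if (mode == "any") any(s %in% hit_items) else all(s %in% hit_items)
  }, logical(1))
  mean(hits)
}

#' Overlap score measure (OSM)
#'
#' `OSM = PA + AGF`: the drug's pattern-level and gene-level importance
#' combined.
#'
#' @param pa Pattern fraction from [pa()].
#' @param agf Accumulated gene weight from [agf()].
#' @return The sum.
#' @export
osm <- function(pa, agf) pa + agf

#' Gene percentage of a drug (GP)
#'
#' Fraction of the subgroup's dysregulated genes whose expression the drug
#' reverses.
#'
#' @param sgnw A `subgroup_network`.
#' @param drug A drug id present in the network.
#' @return A fraction in `[0, 1]`.
#' @export
gp <- function(sgnw, drug) {
  genes <- sgnw$drug_targets[[drug]]
  if (is.null(genes)) stop("drug '", drug, "' is not in the subgroup network")
  NG <- length(unique(sgnw$gene_items$gene))
  if (NG == 0) stop("the subgroup has no dysregulated genes")
  length(genes) / NG
}

#' Inverse drug frequency (IDF)
#'
#' `IDF = log10(Ns / nSj)`, where `Ns` is the total number of genes in the
#' knowledge base. Under the default `scope = "kb_wide"`, `nSj` counts all
#' genes the drug perturbs anywhere in the knowledge base (edges with or
#' without a direction label), so drugs that broadly perturb human cells
#' are down-weighted and subgroup-specific drugs gain score. Under
#' `scope = "subgroup"`, `nSj` counts only the reversal-matched genes in
#' the subgroup network (the literal per-network reading).
#'
#' @param kb A `knowledge_graph`.
#' @param drug A drug id.
#' @param sgnw A `subgroup_network`; required for `scope = "subgroup"`.
#' @param scope `"kb_wide"` (default) or `"subgroup"`.
#' @return A non-negative number.
#' @export
idf <- function(kb, drug, sgnw = NULL, scope = c("kb_wide", "subgroup")) {
  scope <- match.arg(scope)
  Ns <- sum(kb$nodes$node_type == "Gene")
  if (scope == "kb_wide") {
    ed <- normalize_edges(kb$edges)
    dg <- ed[ed$source_type == "Drug" & ed$source_id == drug &
               ed$target_type == "Gene", ]
    nS <- length(unique(dg$target_id))
  } else {
    if (is.null(sgnw)) stop("scope = 'subgroup' needs a subgroup network")
    nS <- length(sgnw$drug_targets[[drug]] %||% character(0))
  }
  if (nS == 0)
    stop("drug '", drug, "' perturbs no gene in the chosen scope; ",
         "it cannot be scored")
  log10(Ns / nS)
}

#' Rank every drug of a subgroup network by DScore
#'
#' Runs the full scoring cascade for each drug in the network:
#' `OSM = PA + AGF`, `DScore = OSM * IDF * GP`, and ranks drugs by
#' descending DScore (ties broken by drug id). Higher scores mark drugs
#' whose reversal signature matches the subgroup more completely, touches
#' more of its co-regulation patterns and weightier genes, and perturbs
#' fewer genes elsewhere.
#'
#' @param sgnw A `subgroup_network` with a nonempty pattern table.
#' @param kb The `knowledge_graph` the network was induced from.
#' @param idf_scope Passed to [idf()].
#' @param pa_mode Passed to [pa()].
#' @return A data.frame of class `drug_ranking` with columns `rank`,
#'   `drug_id`, `pa`, `agf`, `osm`, `gp`, `idf`, `dscore`,
#'   `reversed_genes`. Empty (with a warning) when the network holds no
#'   drug.
#' @export
rank_drugs <- function(sgnw, kb, idf_scope = c("kb_wide", "subgroup"),
                       pa_mode = c("any", "all")) {
  idf_scope <- match.arg(idf_scope)
  pa_mode <- match.arg(pa_mode)
  drugs <- sort(names(sgnw$drug_targets))
  empty <- data.frame(rank = integer(0), drug_id = character(0),
                      pa = numeric(0), agf = numeric(0), osm = numeric(0),
                      gp = numeric(0), idf = numeric(0), dscore = numeric(0),
                      reversed_genes = character(0),
                      stringsAsFactors = FALSE)
  if (length(drugs) == 0) {
    warning("the subgroup network contains no drug")
    class(empty) <- c("drug_ranking", "data.frame")
    return(empty)
  }
  target_genes <- sort(unique(unlist(sgnw$drug_targets)))
  weights <- vapply(target_genes, function(g) mgf(sgnw, g), numeric(1))
  rows <- lapply(drugs, function(d) {
    pav <- pa(sgnw, d, pa_mode)
    agfv <- agf(sgnw, d, weights)
    idfv <- idf(kb, d, sgnw, idf_scope)
    gpv <- gp(sgnw, d)
    data.frame(drug_id = d, pa = pav, agf = agfv, osm = osm(pav, agfv),
               gp = gpv, idf = idfv,
               dscore = osm(pav, agfv) * idfv * gpv,
               reversed_genes = paste(sgnw$drug_targets[[d]],
                                      collapse = ";"),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res <- res[order(-res$dscore, res$drug_id), , drop = FALSE]
  res <- cbind(rank = seq_len(nrow(res)), res)
  rownames(res) <- NULL
  class(res) <- c("drug_ranking", "data.frame")
  res
}

#' @export
print.drug_ranking <- function(x, digits = 4, ...) {
  cat("Drug ranking:", nrow(x), "drug(s)\n")
  if (nrow(x) > 0) {
    y <- x
    for (col in c("pa", "agf", "osm", "gp", "idf", "dscore"))
      y[[col]] <- signif(y[[col]], digits)
    print.data.frame(utils::head(y, 20), row.names = FALSE)
    if (nrow(x) > 20) cat("  ...", nrow(x) - 20, "more\n")
  }
  invisible(x)
}

#' Write a drug ranking to TSV
#'
#' @param ranking A `drug_ranking` data.frame.
#' @param path Output path.
#' @export
write_ranking <- function(ranking, path) {
  utils::write.table(ranking, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
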