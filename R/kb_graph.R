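#' Construct a gene-centric heterogeneous knowledge graph
#'
#' The graph holds typed nodes (`Gene`, `Pathway`, `BiologicalProcess`,
#' `CellularComponent`, `MolecularFunction`, `Disease`, `Drug`) and typed
#' edges. The schema is gene-centric: every edge must touch at least one
#' `Gene` node. Drug-to-gene edges carry a regulation direction (`up` or
#' `down`, the drug's effect on the gene's expression); a `.` direction
#' marks an unlabeled drug edge, which is never matched for signature
#' reversal but still counts toward a drug's knowledge-base-wide target
#' tally. All other edges must have direction `.`.
#'
#' @param nodes Data.frame with columns `node_id`, `node_type`.
#' @param edges Data.frame with columns `source_id`, `source_type`,
#'   `relation`, `target_id`, `target_type`, `direction`.
#' @return An object of class `knowledge_graph`.
#' @export
knowledge_graph <- function(nodes, edges) {
  need_n <- c("node_id", "node_type")
  need_e <- c("source_id", "source_type", "relation",
              "target_id", "target_type", "direction")
  if (!all(need_n %in% names(nodes)))
    stop("node table must have columns: ", paste(need_n, collapse = ", "))
  if (!all(need_e %in% names(edges)))
    stop("edge table must have columns: ", paste(need_e, collapse = ", "))
  nodes <- data.frame(lapply(nodes[need_n], as.character),
                      stringsAsFactors = FALSE)
  edges <- data.frame(lapply(edges[need_e], as.character),
                      stringsAsFactors = FALSE)

  bad <- which(!nodes$node_type %in% KB_NODE_TYPES)
  if (length(bad) > 0)
    stop(sprintf("unknown node type '%s' (node table line %d)",
                 nodes$node_type[bad[1L]], bad[1L] + 1L))
  key <- paste(nodes$node_type, nodes$node_id)
  if (anyDuplicated(key))
    stop("duplicated node id within type: ", key[duplicated(key)][1L])

  bad <- which(!edges$source_type %in% KB_NODE_TYPES |
                 !edges$target_type %in% KB_NODE_TYPES)
  if (length(bad) > 0)
    stop(sprintf("unknown node type on edge (edge table line %d)",
                 bad[1L] + 1L))
  ek1 <- paste(edges$source_type, edges$source_id)
  ek2 <- paste(edges$target_type, edges$target_id)
  bad <- which(!(ek1 %in% key))
  if (length(bad) > 0)
    stop(sprintf("dangling edge source '%s' (edge table line %d)",
                 edges$source_id[bad[1L]], bad[1L] + 1L))
  bad <- which(!(ek2 %in% key))
  if (length(bad) > 0)
    stop(sprintf("dangling edge target '%s' (edge table line %d)",
                 edges$target_id[bad[1L]], bad[1L] + 1L))
  bad <- which(edges$source_type != "Gene" & edges$target_type != "Gene")
  if (length(bad) > 0)
    stop(sprintf(
      "edge between two non-Gene nodes violates the gene-centric schema (edge table line %d)",
      bad[1L] + 1L))
  bad <- which(edges$source_type == "Gene" & edges$target_type == "Gene" &
                 edges$source_id == edges$target_id)
  if (length(bad) > 0)
    stop(sprintf("self-loop gene-gene edge (edge table line %d)",
                 bad[1L] + 1L))
  bad <- which(!edges$direction %in% c("up", "down", "."))
  if (length(bad) > 0)
    stop(sprintf("direction must be one of up/down/. (edge table line %d)",
                 bad[1L] + 1L))
  is_drug <- edges$source_type == "Drug" | edges$target_type == "Drug"
  bad <- which(!is_drug & edges$direction != ".")
  if (length(bad) > 0)
    stop(sprintf("only drug-gene edges may carry a direction (edge table line %d)",
                 bad[1L] + 1L))

  structure(list(nodes = nodes, edges = edges), class = "knowledge_graph")
}

#' Load a knowledge graph from typed TSV edge lists
#'
#' @param nodes_path TSV with columns `node_id`, `node_type`.
#' @param edges_path TSV with columns `source_id`, `source_type`,
#'   `relation`, `target_id`, `target_type`, `direction`.
#' @return A validated `knowledge_graph`.
#' @export
read_kb <- function(nodes_path, edges_path) {
  nodes <- utils::read.delim(nodes_path, sep = "\t", header = TRUE,
                             colClasses = "character")
  edges <- utils::read.delim(edges_path, sep = "\t", header = TRUE,
                             colClasses = "character")
  knowledge_graph(nodes, edges)
}

#' Write a knowledge graph to TSV edge lists
#'
#' Inverse of [read_kb()]: `read_kb` after `write_kb` reproduces the graph.
#'
#' @param kb A `knowledge_graph`.
#' @param nodes_path,edges_path Output paths.
#' @export
write_kb <- function(kb, nodes_path, edges_path) {
  utils::write.table(kb$nodes, nodes_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(kb$edges, edges_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(nodes_path, edges_path))
}

#' @export
print.knowledge_graph <- function(x, ...) {
  tab <- table(factor(x$nodes$node_type, levels = KB_NODE_TYPES))
  cat("Knowledge graph:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  for (t in KB_NODE_TYPES) cat(sprintf("  %-18s %d\n", t, tab[[t]]))
  invisible(x)
}

# Normalize drug edges so the Drug node is the source, and gene-annotation
# edges so the Gene node is the source. Gene-gene edges are untouched.
normalize_edges <- function(edges) {
  flip <- edges$target_type == "Drug" |
    (edges$source_type != "Gene" & edges$target_type == "Gene" &
       edges$source_type != "Drug")
  if (any(flip)) {
    tmp <- edges[flip, ]
    edges[flip, c("source_id", "source_type")] <-
      tmp[, c("target_id", "target_type")]
    edges[flip, c("target_id", "target_type")] <-
      tmp[, c("source_id", "source_type")]
  }
  edges
}

empty_subgroup_network <- function() {
  es <- stats::setNames(rep(list(character(0)), length(KB_NODE_TYPES)),
                        KB_NODE_TYPES)
  structure(list(gene_items = data.frame(gene = character(0),
                                         direction = character(0)),
                 entity_sets = es,
                 patterns = NULL,
                 drug_items = list(), drug_targets = list(),
                 edges = NULL, n_missing_genes = 0L),
            class = "subgroup_network")
}

#' Induce a subgroup network from the knowledge graph
#'
#' Maps a subgroup's dysregulated gene items onto the knowledge graph. The
#' induced heterogeneous network contains: the item genes plus their direct
#' gene-gene interaction neighbors; every pathway, GO-domain and disease
#' node adjacent to an item gene; and every drug with at least one
#' direction-labeled edge to an item gene whose direction is opposite to
#' the item's dysregulation (signature reversal). `drug_targets` records,
#' per included drug, exactly the reversal-matched item genes.
#'
#' @param kb A `knowledge_graph`.
#' @param items Data.frame with columns `gene`, `direction`
#'   (`UP`/`DOWN`), the subgroup's dysregulated gene items. Genes absent
#'   from the graph are dropped with a warning.
#' @param patterns Optional `contrast_patterns` table carried along for
#'   drug scoring.
#' @param reversal `"opposite"` (default) admits a drug edge only when its
#'   direction opposes the item's; `"any"` admits any labeled direction
#'   (sensitivity analysis).
#' @param annotate_from `"items"` (default) collects non-gene entities from
#'   the item genes only; `"all_genes"` also collects them from interaction
#'   neighbors.
#' @return An object of class `subgroup_network`.
#' @export
induce_subgroup_network <- function(kb, items, patterns = NULL,
                                    reversal = c("opposite", "any"),
                                    annotate_from = c("items", "all_genes")) {
  reversal <- match.arg(reversal)
  annotate_from <- match.arg(annotate_from)
  if (is.null(items) || nrow(items) == 0) stop("empty gene-item set")
  items <- unique(items[, c("gene", "direction")])
  items <- items[order(items$gene, items$direction), , drop = FALSE]
  rownames(items) <- NULL

  kb_genes <- kb$nodes$node_id[kb$nodes$node_type == "Gene"]
  missing <- setdiff(unique(items$gene), kb_genes)
  if (length(missing) > 0) {
    warning(length(missing), " item gene(s) absent from the knowledge graph")
    items <- items[!items$gene %in% missing, , drop = FALSE]
  }
  if (nrow(items) == 0) stop("no item gene present in the knowledge graph")
  item_genes <- unique(items$gene)

  ed <- normalize_edges(kb$edges)
  gg <- ed[ed$source_type == "Gene" & ed$target_type == "Gene", ]
  gg_hit <- gg$source_id %in% item_genes | gg$target_id %in% item_genes
  gg <- gg[gg_hit, , drop = FALSE]
  neighbors <- setdiff(unique(c(gg$source_id, gg$target_id)), item_genes)
  net_genes <- sort(unique(c(item_genes, neighbors)))

  ann_src <- if (annotate_from == "items") item_genes else net_genes
  ann <- ed[ed$source_type == "Gene" & ed$target_type != "Gene" &
              ed$source_id %in% ann_src, , drop = FALSE]

  entity_sets <- stats::setNames(rep(list(character(0)),
                                     length(KB_NODE_TYPES)), KB_NODE_TYPES)
  entity_sets[["Gene"]] <- net_genes
  for (t in c("Pathway", "BiologicalProcess", "CellularComponent",
              "MolecularFunction", "Disease")) {
    entity_sets[[t]] <- sort(unique(ann$target_id[ann$target_type == t]))
  }

  dg <- ed[ed$source_type == "Drug" & ed$target_type == "Gene" &
             ed$target_id %in% item_genes & ed$direction != ".", ,
           drop = FALSE]
  drug_items <- list()
  if (nrow(dg) > 0) {
    opp <- c(UP = "down", DOWN = "up")
    for (i in seq_len(nrow(items))) {
      g <- items$gene[i]; d <- items$direction[i]
      hit <- dg$target_id == g &
        (if (reversal == "opposite") dg$direction == opp[[d]]
         else dg$direction %in% c("up", "down"))
      for (drug in unique(dg$source_id[hit])) {
        drug_items[[drug]] <- c(drug_items[[drug]], item_id(g, d))
      }
    }
  }
  drug_items <- lapply(drug_items, function(x) sort(unique(x)))
  if (length(drug_items) > 0)
    drug_items <- drug_items[order(names(drug_items))]
  drug_targets <- lapply(drug_items,
                         function(x) sort(unique(split_item_ids(x)$gene)))
  entity_sets[["Drug"]] <- as.character(names(drug_items))

  matched_drug_edges <- dg[paste(dg$source_id, dg$target_id) %in%
                             unlist(lapply(names(drug_targets), function(d)
                               paste(d, drug_targets[[d]]))), , drop = FALSE]
  net_edges <- rbind(gg, ann, matched_drug_edges)
  rownames(net_edges) <- NULL

  structure(list(gene_items = items, entity_sets = entity_sets,
                 patterns = patterns, drug_items = drug_items,
                 drug_targets = drug_targets, edges = net_edges,
                 n_missing_genes = length(missing)),
            class = "subgroup_network")
}

#' @export
print.subgroup_network <- function(x, ...) {
  cat("Subgroup network:", nrow(x$gene_items), "gene items\n")
  for (t in KB_NODE_TYPES)
    cat(sprintf("  %-18s %d\n", t, length(x$entity_sets[[t]])))
  if (!is.null(x$patterns)) cat("  patterns:", nrow(x$patterns), "\n")
  invisible(x)
}

#' Export a subgroup network as property-graph CSV files
#'
#' Writes `nodes.csv` (`id:ID`, `label:LABEL`) and
#' `relationships.csv` (`:START_ID`, `:END_ID`, `:TYPE`, `direction`) in
#' the CSV dialect accepted by common property-graph bulk importers.
#'
#' @param sgnw A `subgroup_network`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
export_property_graph <- function(sgnw, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nodes <- do.call(rbind, lapply(KB_NODE_TYPES, function(t) {
    ids <- sgnw$entity_sets[[t]]
    if (length(ids) == 0) return(NULL)
    data.frame(`id:ID` = ids, `label:LABEL` = t, check.names = FALSE)
  }))
  rel <- sgnw$edges
  rels <- data.frame(`:START_ID` = rel$source_id, `:END_ID` = rel$target_id,
                     `:TYPE` = toupper(rel$relation),
                     direction = rel$direction, check.names = FALSE)
  np <- file.path(dir, "nodes.csv"); rp <- file.path(dir, "relationships.csv")
  utils::write.csv(nodes, np, row.names = FALSE, quote = FALSE)
  utils::write.csv(rels, rp, row.names = FALSE, quote = FALSE)
  invisible(c(np, rp))
}
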