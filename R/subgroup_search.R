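#' Search configuration for path-expansion subgroup discovery
#'
#' @param beam_width Number of paths retained at each search depth.
#' @param max_depth Maximum number of clinical predicates per subgroup.
#' @param min_patients Minimum subgroup size to be considered viable.
#' @param spc_min Exclusive lower bound on the subgroup contrast score of
#'   reported subgroups (the published retention rule is `SPCScore > 0`).
#' @param mining A [mining_control()].
#' @param jvalue A [jvalue_control()].
#' @param ncs_types Entity types entering the network contrast score;
#'   defaults to all seven.
#' @param seed Integer seed driving the reference-subgroup draw.
#' @return A list of class `search_control`.
#' @export
search_control <- function(beam_width = 5L, max_depth = 4L,
                           min_patients = 20L, spc_min = 0,
                           mining = mining_control(),
                           jvalue = jvalue_control(),
                           ncs_types = KB_NODE_TYPES, seed = 1L) {
  stopifnot(beam_width >= 1, max_depth >= 1, min_patients >= 1,
            all(ncs_types %in% KB_NODE_TYPES))
  structure(list(beam_width = as.integer(beam_width),
                 max_depth = as.integer(max_depth),
                 min_patients = as.integer(min_patients),
                 spc_min = spc_min, mining = mining, jvalue = jvalue,
                 ncs_types = ncs_types, seed = as.integer(seed)),
            class = "search_control")
}

#' Patients selected by a subgroup definition
#'
#' @param clinical Clinical data.frame.
#' @param definition Named character vector of
#'   `variable = category` predicates (conjunction).
#' @return Character vector of matching patient ids.
#' @export
match_patients <- function(clinical, definition) {
  if (length(definition) == 0) stop("empty subgroup definition")
  if (anyDuplicated(names(definition)))
    stop("a clinical variable may appear only once in a definition")
  if (!all(names(definition) %in% names(clinical)))
    stop("unknown clinical variable: ",
         setdiff(names(definition), names(clinical))[1L])
  sel <- rep(TRUE, nrow(clinical))
  for (v in names(definition)) sel <- sel & clinical[[v]] == definition[[v]]
  clinical$patient_id[sel]
}

definition_label <- function(definition) {
  paste(paste0(names(definition), "=", unname(definition)), collapse = " & ")
}

#' Network contrast score
#'
#' `NCS = 1 - mean_i Jaccard(E_i_focus, E_i_outer)` over the entity types,
#' comparing the focus subgroup's induced network with the outer
#' population's network. Types empty in both networks are skipped; if every
#' type is skipped the score is 0 (no network evidence of contrast).
#'
#' @param focus,outer `subgroup_network` objects (`NULL` means an empty
#'   network).
#' @param types Entity types to compare.
#' @return A number in `[0, 1]`.
#' @export
ncs <- function(focus, outer, types = KB_NODE_TYPES) {
  stopifnot(length(types) >= 1)
  if (is.null(focus)) focus <- empty_subgroup_network()
  if (is.null(outer)) outer <- empty_subgroup_network()
  jac <- numeric(0)
  for (t in types) {
    a <- focus$entity_sets[[t]]; b <- outer$entity_sets[[t]]
    if (length(a) == 0 && length(b) == 0) next
    jac <- c(jac, length(intersect(a, b)) / length(union(a, b)))
  }
  if (length(jac) == 0) return(0)
  1 - mean(jac)
}

#' Subgroup contrast score
#'
#' The product of the J-value and the network contrast score; a subgroup
#' with `SPCScore = 0` is indistinguishable from the outer population.
#'
#' @param j J-value of the subgroup.
#' @param ncs Network contrast score in `[0, 1]`.
#' @return The product.
#' @export
spc_score <- function(j, ncs) {
  stopifnot(j >= 0, ncs >= 0, ncs <= 1)
  j * ncs
}

nonviable <- function(definition, reason) {
  structure(list(definition = definition,
                 label = definition_label(definition),
                 viable = FALSE, reason = reason),
            class = "subgroup_result")
}

#' Evaluate one candidate subgroup
#'
#' Mines contrast patterns of the subgroup against the outer population,
#' induces the two heterogeneous networks (the outer network is built from
#' the patterns mined with the two roles swapped), and computes the
#' J-value, NCS and SPCScore. Too-small subgroups, subgroups covering the
#' whole cohort, and subgroups without retained patterns are reported as
#' non-viable results, not errors.
#'
#' @param definition Named character vector of predicates.
#' @param cohort A `dr_cohort`.
#' @param kb A `knowledge_graph`.
#' @param control A [search_control()].
#' @param reference Reference-subgroup statistics from
#'   [reference_subgroups()]; computed from `control$seed` when `NULL`.
#' @return A `subgroup_result`; check its `viable` field.
#' @export
evaluate_subgroup <- function(definition, cohort, kb,
                              control = search_control(),
                              reference = NULL) {
  ids <- match_patients(cohort$clinical, definition)
  n <- nrow(cohort$clinical)
  if (length(ids) < control$min_patients)
    return(nonviable(definition, "fewer patients than min_patients"))
  if (length(ids) >= n)
    return(nonviable(definition, "empty outer population"))
  if (ncol(cohort$items) == 0)
    return(nonviable(definition, "no candidate items (no DEGs)"))
  if (is.null(reference)) {
    reference <- reference_subgroups(
      cohort$clinical, cohort$items, control$mining,
      R = control$jvalue$n_random_subgroups, seed = control$seed,
      jorg_stat = control$jvalue$jorg_stat,
      na_category = cohort$na_category)
  }

  pats_f <- mine_contrast_patterns(cohort$items, ids, control$mining)
  if (nrow(pats_f) == 0)
    return(nonviable(definition, "no retained contrast pattern"))
  net_f <- induce_subgroup_network(kb, pattern_gene_items(pats_f), pats_f)

  outer_ids <- setdiff(cohort$clinical$patient_id, ids)
  pats_o <- mine_contrast_patterns(cohort$items, outer_ids, control$mining)
  net_o <- if (nrow(pats_o) > 0)
    induce_subgroup_network(kb, pattern_gene_items(pats_o), pats_o)
  else empty_subgroup_network()

  Tw <- control$jvalue$T %||% length(ids)
  jorg <- pattern_jorg(pats_f, control$jvalue$jorg_stat)
  j <- j_value(pats_f, reference$jorgs, Tw, reference$M,
               control$jvalue$jorg_stat)
  ncs_v <- ncs(net_f, net_o, control$ncs_types)
  structure(list(definition = definition,
                 label = definition_label(definition),
                 patient_ids = sort(ids), patterns = pats_f,
                 network = net_f, jorg = jorg, j_value = j,
                 ncs = ncs_v, spc_score = spc_score(j, ncs_v),
                 viable = TRUE, reason = NULL),
            class = "subgroup_result")
}

#' @export
print.subgroup_result <- function(x, ...) {
  cat("Subgroup:", x$label, "\n")
  if (!isTRUE(x$viable)) {
    cat("  non-viable:", x$reason, "\n")
    return(invisible(x))
  }
  cat(sprintf("  %d patients, %d patterns | Jorg %.3f, J %.3f, NCS %.3f, SPCScore %.3f\n",
              length(x$patient_ids), nrow(x$patterns), x$jorg,
              x$j_value, x$ncs, x$spc_score))
  invisible(x)
}

candidate_predicates <- function(clinical, na_category) {
  vars <- setdiff(names(clinical), "patient_id")
  out <- list()
  for (v in vars) {
    for (val in setdiff(sort(unique(clinical[[v]])), na_category)) {
      out[[length(out) + 1L]] <- stats::setNames(val, v)
    }
  }
  out
}

#' Discover subgroups by path-expansion beam search
#'
#' The three-level search: paths start from every single
#' `variable = category` predicate (path expansion), each depth re-ranks
#' all live paths and keeps the `beam_width` best viable subgroups by
#' SPCScore (floating selection), and a path is extended by a further
#' predicate only when the refined subgroup is viable and strictly
#' improves the SPCScore (inclusion/exclusion). All subgroups that ever
#' entered the beam are collected, filtered to `SPCScore > spc_min`,
#' de-duplicated by patient set (keeping the most parsimonious, then
#' lexicographically smallest definition) and returned sorted by
#' descending SPCScore.
#'
#' @param cohort A `dr_cohort`.
#' @param kb A `knowledge_graph`.
#' @param control A [search_control()].
#' @return An object of class `subgroup_set`.
#' @export
discover_subgroups <- function(cohort, kb, control = search_control()) {
  reference <- if (ncol(cohort$items) > 0) {
    reference_subgroups(
      cohort$clinical, cohort$items, control$mining,
      R = control$jvalue$n_random_subgroups, seed = control$seed,
      jorg_stat = control$jvalue$jorg_stat,
      na_category = cohort$na_category)
  } else list(jorgs = 1, M = 0, sizes = numeric(0))

  rank_beam <- function(results) {
    if (length(results) == 0) return(results)
    ord <- order(-vapply(results, `[[`, 0, "spc_score"),
                 vapply(results, `[[`, "", "label"))
    results[ord[seq_len(min(control$beam_width, length(ord)))]]
  }

  preds <- candidate_predicates(cohort$clinical, cohort$na_category)
  evals <- lapply(preds, evaluate_subgroup, cohort = cohort, kb = kb,
                  control = control, reference = reference)
  beam <- rank_beam(Filter(function(r) isTRUE(r$viable), evals))
  retained <- beam
  trajectory <- list(list(depth = 1L, beam = vapply(beam, `[[`, "", "label")))

  depth <- 1L
  while (depth < control$max_depth && length(beam) > 0) {
    depth <- depth + 1L
    children <- list()
    for (parent in beam) {
      for (pred in preds) {
        v <- names(pred)
        if (v %in% names(parent$definition)) next
        child_def <- c(parent$definition, pred)
        child <- evaluate_subgroup(child_def, cohort, kb, control, reference)
        if (isTRUE(child$viable) && child$spc_score > parent$spc_score)
          children[[length(children) + 1L]] <- child
      }
    }
    beam <- rank_beam(children)
    retained <- c(retained, beam)
    trajectory[[length(trajectory) + 1L]] <-
      list(depth = depth, beam = vapply(beam, `[[`, "", "label"))
  }

  retained <- Filter(function(r) r$spc_score > control$spc_min, retained)
  if (length(retained) > 0) {
    keys <- vapply(retained, function(r)
      paste(r$patient_ids, collapse = ","), "")
    ord <- order(keys,
                 vapply(retained, function(r) length(r$definition), 0L),
                 vapply(retained, `[[`, "", "label"))
    retained <- retained[ord][!duplicated(keys[ord])]
    ord <- order(-vapply(retained, `[[`, 0, "spc_score"),
                 vapply(retained, `[[`, "", "label"))
    retained <- retained[ord]
  }
  structure(list(results = retained, control = control,
                 reference = reference, trajectory = trajectory,
                 n_patients = nrow(cohort$clinical)),
            class = "subgroup_set")
}

#' @rdname discover_subgroups
#' @export
path_expansion_search <- discover_subgroups

#' @export
print.subgroup_set <- function(x, ...) {
  cat("Path-expansion subgroup search:", length(x$results),
      "subgroup(s) retained of", x$n_patients, "patients\n")
  if (length(x$results) > 0) print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' @export
summary.subgroup_set <- function(object, ...) {
  df <- as.data.frame(object)
  cat("Subgroups retained:", nrow(df), "\n")
  cat("Reference prior: Javg =", format(mean(object$reference$jorgs)),
      ", M =", format(object$reference$M), "\n")
  if (nrow(df) > 0) print(df, row.names = FALSE)
  invisible(df)
}

#' @export
as.data.frame.subgroup_set <- function(x, ...) {
  if (length(x$results) == 0)
    return(data.frame(definition = character(0), n_patients = integer(0),
                      n_patterns = integer(0), jorg = numeric(0),
                      j_value = numeric(0), ncs = numeric(0),
                      spc_score = numeric(0)))
  data.frame(
    definition = vapply(x$results, `[[`, "", "label"),
    n_patients = vapply(x$results, function(r) length(r$patient_ids), 0L),
    n_patterns = vapply(x$results, function(r) nrow(r$patterns), 0L),
    jorg = vapply(x$results, `[[`, 0, "jorg"),
    j_value = vapply(x$results, `[[`, 0, "j_value"),
    ncs = vapply(x$results, `[[`, 0, "ncs"),
    spc_score = vapply(x$results, `[[`, 0, "spc_score"),
    stringsAsFactors = FALSE)
}

#' @export
plot.subgroup_set <- function(x, ...) {
  df <- as.data.frame(x)
  if (nrow(df) == 0) {
    plot.new(); title("No subgroup retained")
    return(invisible(x))
  }
  op <- graphics::par(mar = c(4, 12, 2, 1)); on.exit(graphics::par(op))
  graphics::barplot(rev(df$spc_score), names.arg = rev(df$definition),
                    horiz = TRUE, las = 1, xlab = "SPCScore",
                    main = "Subgroup contrast scores", ...)
  invisible(x)
}
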