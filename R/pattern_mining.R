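#' Mining thresholds for contrast patterns
#'
#' Defaults follow the published filter settings: pattern support in the
#' focus subgroup strictly greater than 70%, growth rate strictly greater
#' than 1.5, and confidence of at least 1 (patterns exclusive to the
#' subgroup). Growth is undefined when the pattern is absent outside the
#' subgroup, so it is capped at `growth_cap`; the cap exceeds any sensible
#' `growth_min`, so filtering is unaffected, and it keeps J-value means
#' finite.
#'
#' @param support_min Strict lower bound on focus-subgroup support.
#' @param growth_min Strict lower bound on the growth rate.
#' @param confidence_min Inclusive lower bound on rule confidence
#'   (pattern implies subgroup membership).
#' @param max_pattern_len Maximum number of items per pattern.
#' @param growth_cap Growth value substituted when the outer support is 0.
#' @param filter `"all"` returns every itemset passing the thresholds
#'   (default); `"closed"` drops patterns that have a frequent strict
#'   superset with an identical supporting-patient set; `"maximal"` keeps
#'   only patterns with no retained strict superset.
#' @return A list of class `mining_control`.
#' @export
mining_control <- function(support_min = 0.70, growth_min = 1.5,
                           confidence_min = 1.0, max_pattern_len = 3L,
                           growth_cap = 100,
                           filter = c("all", "closed", "maximal")) {
  filter <- match.arg(filter)
  stopifnot(support_min > 0, support_min <= 1,
            growth_min >= 1, max_pattern_len >= 1, growth_cap > growth_min)
  structure(list(support_min = support_min, growth_min = growth_min,
                 confidence_min = confidence_min,
                 max_pattern_len = as.integer(max_pattern_len),
                 growth_cap = growth_cap, filter = filter),
            class = "mining_control")
}

#' J-value configuration
#'
#' @param T Population-size preference weight of the Bayesian average.
#'   `NULL` (default) means "use the focus subgroup's patient count".
#' @param n_random_subgroups Number of randomly drawn single-predicate
#'   subgroups used to estimate the cohort-wide average pattern quality and
#'   the average subgroup size M.
#' @param jorg_stat Location statistic of capped pattern growth defining a
#'   subgroup's raw quality Jorg: `"mean"` (default) or `"sum"`.
#' @return A list of class `jvalue_control`.
#' @export
jvalue_control <- function(T = NULL, n_random_subgroups = 30L,
                           jorg_stat = c("mean", "sum")) {
  jorg_stat <- match.arg(jorg_stat)
  stopifnot(is.null(T) || T >= 0, n_random_subgroups >= 1)
  structure(list(T = T, n_random_subgroups = as.integer(n_random_subgroups),
                 jorg_stat = jorg_stat),
            class = "jvalue_control")
}

# Logical vector: which rows of the item matrix carry every item of the set.
carriers <- function(items, itemset) {
  idx <- match(itemset, colnames(items))
  if (anyNA(idx)) stop("unknown item: ",
                       itemset[is.na(idx)][1L])
  rowSums(items[, idx, drop = FALSE]) == length(idx)
}

#' Pattern support
#'
#' Fraction of patients carrying every item of the pattern.
#'
#' @param items Logical item matrix (patients x items).
#' @param itemset Character vector of item ids (`gene:UP` / `gene:DOWN`).
#' @return A fraction in `[0, 1]`.
#' @export
pattern_support <- function(items, itemset) {
  if (nrow(items) == 0) stop("empty patient set")
  mean(carriers(items, itemset))
}

#' Growth rate of a contrast pattern
#'
#' `max(s1, s2) / min(s1, s2)`, the contrast between a pattern's supports
#' in the focus subgroup and the outer population. When one support is 0
#' the ratio is undefined and `cap` is returned.
#'
#' @param s1,s2 Supports in the two populations.
#' @param cap Value returned when `min(s1, s2) == 0`.
#' @return Growth rate, `>= 1`.
#' @export
growth_rate <- function(s1, s2, cap = 100) {
  stopifnot(s1 >= 0, s1 <= 1, s2 >= 0, s2 <= 1)
  if (s1 == 0 && s2 == 0) stop("pattern occurs nowhere: growth undefined")
  if (min(s1, s2) == 0) return(cap)
  max(s1, s2) / min(s1, s2)
}

#' Confidence of the rule pattern => subgroup
#'
#' The fraction of all pattern-bearing patients that lie inside the
#' subgroup; 1 means the pattern is exclusive to the subgroup.
#'
#' @param items Logical item matrix over all patients.
#' @param itemset Character vector of item ids.
#' @param sg_ids Patient ids (row names) of the focus subgroup.
#' @return A fraction in `[0, 1]`.
#' @export
pattern_confidence <- function(items, itemset, sg_ids) {
  carr <- carriers(items, itemset)
  if (!any(carr)) stop("pattern absent from every patient")
  sum(carr[rownames(items) %in% sg_ids]) / sum(carr)
}

#' Mine contrast patterns of a subgroup against the outer population
#'
#' Level-wise enumeration of itemsets up to `max_pattern_len`, pruned by
#' the anti-monotone focus-support bound. An itemset is reported when its
#' focus support exceeds `support_min`, its (capped) growth exceeds
#' `growth_min`, and its confidence reaches `confidence_min`. Output order
#' is deterministic: by pattern length, then lexicographically on the
#' joined item ids.
#'
#' @param items Logical item matrix (patients x items) with patient row
#'   names.
#' @param sg_ids Patient ids of the focus subgroup; must be a nonempty
#'   strict subset of all patients.
#' @param control A [mining_control()] list.
#' @return A data.frame of class `contrast_patterns` with columns `items`
#'   (semicolon-joined ids), `length`, `s1`, `s2`, `growth`, `confidence`.
#' @export
mine_contrast_patterns <- function(items, sg_ids,
                                   control = mining_control()) {
  pats <- rownames(items)
  sg_ids <- unique(sg_ids)
  if (length(sg_ids) == 0) stop("empty focus subgroup")
  if (!all(sg_ids %in% pats)) stop("unknown patient id in subgroup")
  if (length(sg_ids) >= length(pats))
    stop("focus subgroup must be a strict subset of the cohort")
  in_sg <- pats %in% sg_ids
  n1 <- sum(in_sg); n2 <- sum(!in_sg)
  m1 <- items[in_sg, , drop = FALSE]
  m2 <- items[!in_sg, , drop = FALSE]

  cols <- colnames(items)
  out <- list()
  explored <- list()  # per frequent candidate: indices + total carrier count

  # level 1
  c1 <- colSums(m1); c2 <- colSums(m2)
  frontier <- lapply(which(c1 / n1 > control$support_min), identity)
  for (lev in seq_len(control$max_pattern_len)) {
    if (length(frontier) == 0) break
    keep <- logical(length(frontier))
    for (i in seq_along(frontier)) {
      idx <- frontier[[i]]
      if (lev == 1L) {
        k1 <- c1[[idx]]; k2 <- c2[[idx]]
      } else {
        k1 <- sum(rowSums(m1[, idx, drop = FALSE]) == lev)
        k2 <- sum(rowSums(m2[, idx, drop = FALSE]) == lev)
      }
      s1 <- k1 / n1
      if (s1 <= control$support_min) next
      keep[i] <- TRUE
      s2 <- k2 / n2
      ids <- sort(cols[idx])
      explored[[length(explored) + 1L]] <-
        list(idx = sort(idx), count = k1 + k2)
      gr <- growth_rate(s1, s2, control$growth_cap)
      conf <- k1 / (k1 + k2)
      if (gr > control$growth_min && conf >= control$confidence_min) {
        out[[length(out) + 1L]] <- data.frame(
          items = paste(ids, collapse = ";"), length = lev,
          s1 = s1, s2 = s2, growth = gr, confidence = conf,
          stringsAsFactors = FALSE)
      }
    }
    frontier <- frontier[keep]
    if (lev == control$max_pattern_len) break
    # apriori join: extend each frequent set with a larger item index
    nxt <- list()
    for (f in frontier) {
      top <- max(f)
      for (j in seq_along(cols)) {
        if (j > top) nxt[[length(nxt) + 1L]] <- c(f, j)
      }
    }
    frontier <- nxt
  }

  res <- if (length(out) > 0) do.call(rbind, out) else
    data.frame(items = character(0), length = integer(0),
               s1 = numeric(0), s2 = numeric(0),
               growth = numeric(0), confidence = numeric(0))
  res <- res[order(res$length, res$items), , drop = FALSE]
  rownames(res) <- NULL

  if (nrow(res) > 0 && control$filter != "all") {
    sets <- strsplit(res$items, ";", fixed = TRUE)
    if (control$filter == "closed") {
      # a pattern is closed unless a frequent strict superset (within the
      # length bound) has the identical supporting-patient set; supersets
      # have subset carriers, so equal carrier counts imply equal sets
      cnt <- vapply(sets, function(s)
        sum(carriers(items, s)), numeric(1))
      drop <- vapply(seq_along(sets), function(i) {
        si <- match(sets[[i]], cols)
        any(vapply(explored, function(e)
          length(e$idx) > length(si) && all(si %in% e$idx) &&
            e$count == cnt[i], logical(1)))
      }, logical(1))
    } else {
      drop <- vapply(seq_along(sets), function(i) {
        any(vapply(seq_along(sets), function(j)
          j != i && length(sets[[j]]) > length(sets[[i]]) &&
            all(sets[[i]] %in% sets[[j]]), logical(1)))
      }, logical(1))
    }
    res <- res[!drop, , drop = FALSE]
    rownames(res) <- NULL
  }
  class(res) <- c("contrast_patterns", "data.frame")
  res
}

#' Item sets of a pattern table
#'
#' @param patterns A `contrast_patterns` data.frame.
#' @return List of character vectors of item ids.
#' @export
pattern_item_sets <- function(patterns) {
  strsplit(patterns$items, ";", fixed = TRUE)
}

#' Unique gene items of a pattern table
#'
#' @param patterns A `contrast_patterns` data.frame.
#' @return Data.frame with columns `gene`, `direction`.
#' @export
pattern_gene_items <- function(patterns) {
  ids <- sort(unique(unlist(pattern_item_sets(patterns))))
  split_item_ids(ids)
}

#' Raw pattern-quality index Jorg of a subgroup
#'
#' The location statistic (mean by default) of the capped growth rates of
#' the subgroup's retained contrast patterns.
#'
#' @param patterns Nonempty `contrast_patterns` data.frame.
#' @param stat `"mean"` or `"sum"`.
#' @return A non-negative number.
#' @export
pattern_jorg <- function(patterns, stat = c("mean", "sum")) {
  stat <- match.arg(stat)
  if (is.null(patterns) || nrow(patterns) == 0)
    stop("J-value undefined: the subgroup retains no contrast pattern")
  if (stat == "mean") mean(patterns$growth) else sum(patterns$growth)
}

#' Bayesian-average J-value of a subgroup
#'
#' Blends the subgroup's raw pattern quality `Jorg` with the average raw
#' quality of randomly drawn subgroups:
#' `J = (T * Jorg + M * Javg) / (T + M)`, where `T` expresses the
#' population-size preference and `M` is the average size of the random
#' subgroups. The result always lies between `Jorg` and `Javg`.
#'
#' @param patterns Nonempty `contrast_patterns` table of the subgroup.
#' @param random_jorgs Numeric vector of raw qualities of the random
#'   reference subgroups (pattern-less subgroups contribute 1).
#' @param T Size-preference weight (non-negative).
#' @param M Average reference-subgroup size.
#' @param stat Passed to [pattern_jorg()].
#' @return The blended J-value.
#' @export
j_value <- function(patterns, random_jorgs, T, M, stat = "mean") {
  stopifnot(T >= 0, M >= 0, T + M > 0, length(random_jorgs) >= 1)
  jorg <- pattern_jorg(patterns, stat)
  javg <- mean(random_jorgs)
  (T * jorg + M * javg) / (T + M)
}

#' Reference subgroups for the J-value prior
#'
#' Draws `R` single-predicate subgroups by picking a clinical
#' (variable, category) pair uniformly at random (the missing-value
#' sentinel is never drawn), mines each against its complement, and
#' records its raw quality Jorg (1 when no pattern is retained) and its
#' size. Their mean size is the Bayesian-average weight `M`.
#'
#' @param clinical Clinical data.frame.
#' @param items Logical item matrix.
#' @param control A [mining_control()].
#' @param R Number of reference subgroups.
#' @param seed Integer seed making the draw reproducible.
#' @param jorg_stat Passed to [pattern_jorg()].
#' @param na_category Sentinel category excluded from the draw.
#' @return List with `jorgs` (length `R`), `M`, and `sizes`.
#' @export
reference_subgroups <- function(clinical, items, control = mining_control(),
                                R = 30L, seed = 1L, jorg_stat = "mean",
                                na_category = "missing") {
  vars <- setdiff(names(clinical), "patient_id")
  pool <- do.call(rbind, lapply(vars, function(v) {
    vals <- setdiff(sort(unique(clinical[[v]])), na_category)
    if (length(vals) == 0) return(NULL)
    data.frame(variable = v, value = vals, stringsAsFactors = FALSE)
  }))
  if (is.null(pool) || nrow(pool) == 0)
    stop("no usable clinical predicate")
  draw <- with_seed(seed, sample.int(nrow(pool), R, replace = TRUE))
  jorgs <- numeric(R); sizes <- numeric(R)
  n <- nrow(clinical)
  for (r in seq_len(R)) {
    v <- pool$variable[draw[r]]; val <- pool$value[draw[r]]
    ids <- clinical$patient_id[clinical[[v]] == val]
    sizes[r] <- length(ids)
    jorgs[r] <- 1
    if (length(ids) >= 1 && length(ids) < n && ncol(items) > 0) {
      pats <- mine_contrast_patterns(items, ids, control)
      if (nrow(pats) > 0) jorgs[r] <- pattern_jorg(pats, jorg_stat)
    }
  }
  list(jorgs = jorgs, M = mean(sizes), sizes = sizes)
}

#' Write a pattern table to TSV
#'
#' @param patterns A `contrast_patterns` data.frame.
#' @param path Output path.
#' @export
write_patterns <- function(patterns, path) {
  utils::write.table(
    patterns[, c("items", "s1", "s2", "growth", "confidence")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
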