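#' Read a clinical table
#'
#' Reads a tab-separated clinical table with a `patient_id` column followed
#' by one column per categorical clinical variable. Missing values (`NA` or
#' empty strings) are recoded to a single sentinel category so that they can
#' be carried along but never used as subgroup predicates.
#'
#' @param path Path to a TSV file with header
#'   `patient_id<TAB>var1<TAB>...`.
#' @param na_category Sentinel category used for missing values.
#' @return A data.frame of character columns with attribute `na_category`.
#' @export
read_clinical <- function(path, na_category = "missing") {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE)
  if (!"patient_id" %in% names(df))
    stop("clinical table must contain a 'patient_id' column")
  if (anyDuplicated(df$patient_id))
    stop("duplicated patient_id in clinical table: ",
         df$patient_id[duplicated(df$patient_id)][1L])
  for (v in setdiff(names(df), "patient_id")) {
    x <- df[[v]]
    x[is.na(x) | x == ""] <- na_category
    df[[v]] <- x
  }
  attr(df, "na_category") <- na_category
  df
}

#' Read an expression matrix
#'
#' Reads a genes-by-patients TSV. The first column holds gene identifiers;
#' the header row holds patient identifiers.
#'
#' @param path Path to the TSV file.
#' @return A numeric matrix, genes in rows, patients in columns.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE)
  genes <- as.character(df[[1L]])
  if (anyDuplicated(genes))
    stop("duplicated gene_id in expression matrix: ",
         genes[duplicated(genes)][1L])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  m
}

#' Read per-gene differential-expression statistics
#'
#' @param path TSV with columns `gene_id`, `log2fc`, `pvalue` (one row per
#'   gene), typically the output of an external differential-expression
#'   analysis of tumor versus normal samples.
#' @return A data.frame with those three columns.
#' @export
read_deg_stats <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE)
  need <- c("gene_id", "log2fc", "pvalue")
  if (!all(need %in% names(df)))
    stop("DEG statistics must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$gene_id))
    stop("duplicated gene_id in DEG statistics")
  if (any(df$pvalue < 0 | df$pvalue > 1, na.rm = TRUE))
    stop("pvalue outside [0, 1]")
  df$gene_id <- as.character(df$gene_id)
  df[need]
}

#' Log2-normalize an expression matrix
#'
#' Replaces each value `v` by `log2(v + pseudocount)`.
#'
#' @param expr Numeric matrix of non-negative expression values,
#'   genes x patients.
#' @param pseudocount Positive offset added before taking logs.
#' @return Matrix of the same shape.
#' @export
normalize_log2 <- function(expr, pseudocount = 1) {
  stopifnot(is.matrix(expr), is.numeric(expr))
  if (pseudocount <= 0) stop("pseudocount must be positive")
  bad <- which(expr < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("negative expression value for gene '%s', patient '%s'",
                 rownames(expr)[bad[1L, 1L]] %||% bad[1L, 1L],
                 colnames(expr)[bad[1L, 2L]] %||% bad[1L, 2L]))
  }
  log2(expr + pseudocount)
}

#' Per-gene z-scores across patients
#'
#' @param expr Log-normalized matrix, genes x patients.
#' @param sd_method `"sample"` uses the n-1 denominator, `"population"`
#'   uses n.
#' @return Matrix of z-scores; rows with zero variance become all-`NA`.
#' @export
gene_zscores <- function(expr, sd_method = c("sample", "population")) {
  sd_method <- match.arg(sd_method)
  mu <- rowMeans(expr)
  n <- ncol(expr)
  ss <- rowSums((expr - mu)^2)
  sdv <- sqrt(ss / if (sd_method == "sample") n - 1 else n)
  z <- (expr - mu) / sdv
  z[sdv == 0, ] <- NA_real_
  z
}

#' Trichotomize expression into regulation states
#'
#' Computes per-gene z-scores across all patients and assigns each
#' (patient, gene) cell to `UP` (z strictly above `up_thresh`), `DOWN`
#' (z strictly below `down_thresh`) or `NORMAL` (boundary values included).
#' Genes with zero variance are `NORMAL` everywhere.
#'
#' @param expr Log-normalized matrix, genes x patients.
#' @param up_thresh,down_thresh Strict z-score cut points; defaults +1/-1.
#' @param sd_method See [gene_zscores()].
#' @return A patients x genes character matrix of states
#'   (the regulation matrix).
#' @export
zscore_categorize <- function(expr, up_thresh = 1, down_thresh = -1,
                              sd_method = c("sample", "population")) {
  if (up_thresh <= down_thresh)
    stop("up_thresh must be strictly greater than down_thresh")
  z <- gene_zscores(expr, sd_method)
  st <- matrix("NORMAL", nrow = nrow(expr), ncol = ncol(expr),
               dimnames = dimnames(expr))
  st[!is.na(z) & z > up_thresh] <- "UP"
  st[!is.na(z) & z < down_thresh] <- "DOWN"
  t(st)
}

#' Select differentially expressed genes
#'
#' Retains genes with `pvalue < p_max` and `|log2fc| > lfc_min`
#' (strict inequalities on both sides).
#'
#' @param stats Data.frame with `gene_id`, `log2fc`, `pvalue`.
#' @param p_max P-value bound (default 0.05).
#' @param lfc_min Absolute log2 fold-change bound (default 2).
#' @return Sorted character vector of retained gene ids.
#' @export
select_degs <- function(stats, p_max = 0.05, lfc_min = 2) {
  keep <- stats$pvalue < p_max &
    (stats$log2fc > lfc_min | stats$log2fc < -lfc_min)
  sort(unique(stats$gene_id[keep & !is.na(keep)]))
}

#' Encode a regulation matrix as a boolean item matrix
#'
#' Each selected gene contributes two candidate items, `gene:UP` and
#' `gene:DOWN`; `NORMAL` states yield no item. At most one of a gene's two
#' items is true for any patient.
#'
#' @param reg Patients x genes character state matrix from
#'   [zscore_categorize()].
#' @param degs Nonempty character vector of gene ids (a subset of the
#'   regulation matrix's genes).
#' @return Logical matrix, patients x items, with item-id column names and
#'   an `item_info` attribute mapping items to (gene, direction).
#' @export
build_item_matrix <- function(reg, degs) {
  if (length(degs) == 0) stop("empty DEG set")
  if (!all(degs %in% colnames(reg)))
    stop("DEG genes absent from regulation matrix: ",
         paste(utils::head(setdiff(degs, colnames(reg)), 3), collapse = ", "))
  degs <- sort(unique(degs))
  sub <- reg[, degs, drop = FALSE]
  up <- sub == "UP"
  dn <- sub == "DOWN"
  colnames(up) <- item_id(degs, "UP")
  colnames(dn) <- item_id(degs, "DOWN")
  m <- cbind(up, dn)
  m <- m[, order(colnames(m)), drop = FALSE]
  attr(m, "item_info") <- split_item_ids(colnames(m))
  m
}

#' Assemble a cohort object
#'
#' Runs the preprocessing chain: optional log2 normalization, DEG selection
#' from external differential statistics, z-score trichotomization (by
#' default restricted to the selected DEGs), and item encoding for contrast
#' mining.
#'
#' @param clinical Clinical data.frame (see [read_clinical()]).
#' @param expr Expression matrix, genes x patients; raw non-negative values
#'   if `normalize = TRUE`, otherwise already on log scale.
#' @param deg_stats Data.frame of per-gene differential statistics.
#' @param normalize Apply [normalize_log2()] first?
#' @param pseudocount Pseudocount for log2 normalization.
#' @param p_max,lfc_min DEG thresholds, see [select_degs()].
#' @param up_thresh,down_thresh z-score cut points, see
#'   [zscore_categorize()].
#' @param sd_method Standard-deviation denominator, see [gene_zscores()].
#' @param zscore_on `"degs"` computes z-scores after restricting to the
#'   selected DEGs (default); `"all"` standardizes over all genes first.
#'   Both give identical states because standardization is per gene; the
#'   flag controls which genes are materialized in the regulation matrix.
#' @return An object of class `dr_cohort`.
#' @export
build_cohort <- function(clinical, expr, deg_stats,
                         normalize = TRUE, pseudocount = 1,
                         p_max = 0.05, lfc_min = 2,
                         up_thresh = 1, down_thresh = -1,
                         sd_method = "sample",
                         zscore_on = c("degs", "all")) {
  zscore_on <- match.arg(zscore_on)
  if (!setequal(colnames(expr), clinical$patient_id))
    stop("expression patient ids do not match the clinical table")
  expr <- expr[, clinical$patient_id, drop = FALSE]
  if (normalize) expr <- normalize_log2(expr, pseudocount)
  degs <- select_degs(deg_stats, p_max, lfc_min)
  degs <- intersect(degs, rownames(expr))
  zin <- if (zscore_on == "degs") expr[degs, , drop = FALSE] else expr
  if (length(degs) > 0 && nrow(zin) > 0) {
    reg <- zscore_categorize(zin, up_thresh, down_thresh, sd_method)
    items <- build_item_matrix(reg, degs)
  } else {
    reg <- matrix(character(0), nrow = ncol(expr), ncol = 0,
                  dimnames = list(colnames(expr), NULL))
    items <- matrix(logical(0), nrow = ncol(expr), ncol = 0,
                    dimnames = list(colnames(expr), NULL))
  }
  structure(list(clinical = clinical, expr = expr, deg_stats = deg_stats,
                 degs = degs, regulation = reg, items = items,
                 na_category = attr(clinical, "na_category") %||% "missing",
                 params = list(p_max = p_max, lfc_min = lfc_min,
                               up_thresh = up_thresh,
                               down_thresh = down_thresh,
                               sd_method = sd_method,
                               zscore_on = zscore_on)),
            class = "dr_cohort")
}

#' @export
print.dr_cohort <- function(x, ...) {
  cat("Cohort:", nrow(x$clinical), "patients,",
      ncol(x$clinical) - 1L, "clinical variables\n")
  cat("  expression:", nrow(x$expr), "genes;",
      length(x$degs), "selected DEGs ->", ncol(x$items),
      "candidate items\n")
  invisible(x)
}
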