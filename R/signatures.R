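# Single-sample gene-signature scoring primitives. Gene identifiers are
# matched by exact string comparison after upper-casing.

match_set_genes <- function(expression, geneset) {
  genes <- toupper(rownames(expression))
  set <- toupper(geneset$genes)
  idx <- which(genes %in% set)
  missing <- setdiff(set, genes)
  if (length(missing) > 0) {
    warning("gene set '", geneset$name, "': ", length(missing),
            " gene(s) absent from the expression matrix")
  }
  if (length(idx) == 0) {
    icibench_error("icibench_value_error", paste0(
      "no gene of set '", geneset$name, "' is present in the matrix"))
  }
  idx
}

#' Per-gene z-scoring, optionally within patient strata
#'
#' Centers and scales each gene row to mean 0 and unit sample standard
#' deviation, separately within each stratum when `strata` is given (e.g.
#' squamous vs non-squamous histology). Zero-variance genes map to
#' all-zero rows.
#'
#' @param expression genes-by-patients numeric matrix.
#' @param strata optional vector of length `ncol(expression)` assigning
#'   each patient to a stratum; every stratum needs at least 2 patients.
#' @return matrix of the same shape.
#' @export
zscore_genes <- function(expression, strata = NULL) {
  expression <- as.matrix(expression)
  if (is.null(strata)) strata <- rep("all", ncol(expression))
  if (length(strata) != ncol(expression)) {
    icibench_error("icibench_value_error",
                   "strata length must equal the number of patients")
  }
  out <- expression
  for (s in unique(strata)) {
    cols <- which(strata == s)
    if (length(cols) < 2) {
      icibench_error("icibench_value_error", paste0(
        "stratum '", s, "' has fewer than 2 patients"))
    }
    block <- expression[, cols, drop = FALSE]
    mu <- rowMeans(block)
    sd <- apply(block, 1, stats::sd)
    z <- (block - mu) / ifelse(sd > 0, sd, 1)
    z[sd == 0, ] <- 0
    out[, cols] <- z
  }
  out
}

#' Mean of scaled expression over a gene set
#'
#' @param scaled_expression output of [zscore_genes()] (or any matrix).
#' @param geneset a [gene_set]; genes absent from the matrix are ignored
#'   with a warning.
#' @return object of class `signature_score` with per-patient means.
#' @export
signature_mean_score <- function(scaled_expression, geneset) {
  idx <- match_set_genes(scaled_expression, geneset)
  values <- colMeans(scaled_expression[idx, , drop = FALSE])
  signature_score(geneset$name, values)
}

#' Signature score container
#' @param signature_name string.
#' @param values named numeric vector (patient id -> score), finite.
#' @return object of class `signature_score`.
#' @export
signature_score <- function(signature_name, values) {
  if (any(!is.finite(values))) {
    icibench_error("icibench_value_error",
                   "signature scores must be finite")
  }
  structure(list(signature_name = signature_name, values = values),
            class = "signature_score")
}

#' @export
print.signature_score <- function(x, ...) {
  cat("signature_score:", x$signature_name, "(", length(x$values),
      "patients )\n")
  invisible(x)
}

#' Competitive mean-rank enrichment score
#'
#' For each patient all genes are ranked ascending by expression
#' (mid-ranks for ties) and the set's mean rank is standardized by its
#' null moments under exchangeability: with `G` genes and `m` set genes,
#' `score = (meanrank_set - (G+1)/2) / sqrt((G+1)*(G-m)/(12*m))` -- the
#' standardized Mann-Whitney mean-rank statistic. Positive scores mean the
#' set genes sit among the patient's most highly expressed genes. The
#' statistic depends on expression only through ranks, so it is invariant
#' under any strictly monotone transform.
#'
#' @param expression genes-by-patients matrix.
#' @param geneset a [gene_set]; both the set and its complement must be
#'   non-empty within the matrix.
#' @return a [signature_score].
#' @export
rank_enrichment_score <- function(expression, geneset) {
  idx <- match_set_genes(expression, geneset)
  G <- nrow(expression)
  m <- length(idx)
  if (m == G) {
    icibench_error("icibench_value_error",
                   "gene set covers the whole matrix; complement is empty")
  }
  denom <- sqrt((G + 1) * (G - m) / (12 * m))
  values <- apply(expression, 2, function(x) {
    r <- rank(x, ties.method = "average")
    (mean(r[idx]) - (G + 1) / 2) / denom
  })
  signature_score(geneset$name, values)
}

#' Weighted random-walk enrichment score
#'
#' Single-sample Kolmogorov-Smirnov-style walk: genes are ordered by
#' decreasing expression; stepping through that list the walk rises by the
#' gene's rank weight raised to `weight_exponent` (normalized over the
#' set) at set genes and falls by `1/(G - m)` elsewhere. The score is the
#' maximum positive deviation minus the maximum negative deviation of the
#' walk (the "difference" convention), so sets concentrated at the top of
#' the profile score positive and sets at the bottom score negative.
#'
#' @inheritParams rank_enrichment_score
#' @param weight_exponent exponent on the rank weights (default 1).
#' @return a [signature_score].
#' @export
walk_enrichment_score <- function(expression, geneset, weight_exponent = 1) {
  idx <- match_set_genes(expression, geneset)
  G <- nrow(expression)
  m <- length(idx)
  if (m == G) {
    icibench_error("icibench_value_error",
                   "gene set covers the whole matrix; complement is empty")
  }
  in_set <- logical(G)
  in_set[idx] <- TRUE
  values <- apply(expression, 2, function(x) {
    ord <- order(x, decreasing = TRUE)
    r <- rank(x, ties.method = "average")
    w <- abs(r[ord])^weight_exponent
    set_ord <- in_set[ord]
    steps <- ifelse(set_ord, w / sum(w[set_ord]), -1 / (G - m))
    walk <- cumsum(steps)
    max(walk, 0) + min(walk, 0)
  })
  signature_score(geneset$name, values)
}

#' Empirical quantile threshold
#'
#' Linear-interpolation (type 7) empirical quantile of the non-missing
#' values; used for cohort tertiles, medians and 67th percentiles. At
#' least 3 non-missing values are required.
#'
#' @param values numeric vector, may contain `NA`.
#' @param q quantile level in \[0, 1\].
#' @return the threshold value.
#' @export
quantile_threshold <- function(values, q) {
  v <- values[!is.na(values)]
  if (length(v) == 0) {
    icibench_error("icibench_value_error", "all values are missing")
  }
  if (length(v) < 3) {
    icibench_error("icibench_value_error",
                   "need at least 3 non-missing values for a quantile")
  }
  unname(stats::quantile(v, probs = q, type = 7))
}
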