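# Genome-wide five-sector partition from expression data: fractional
# normalization, per-nutrient SVD, loading-based calls, and aggregation.

#' Fractional (log10 parts-per-million) expression
#'
#' Converts a nonnegative signal matrix to fractional expression,
#' `f_i = log10(1e6 * g_i / sum_j g_j)` per sample, so that
#' `sum_i 10^f_i = 1e6` in every sample.  The result measures the share of
#' the cell's expression resources each gene receives, and is invariant to
#' per-sample scaling of the raw signal.
#'
#' @param raw Nonnegative numeric matrix, genes x samples, with rownames.
#' @return Matrix of the same shape.  Zero signals map to `-Inf`; affected
#'   genes are recorded in attribute `"flagged_genes"`.
#' @export
fractional_expression <- function(raw) {
  raw <- as.matrix(raw)
  if (any(raw < 0, na.rm = TRUE)) stop("negative signal values")
  tot <- colSums(raw)
  if (any(tot <= 0)) stop("degenerate sample: all-zero signal column")
  f <- log10(sweep(raw, 2, tot / 1e6, "/"))
  flagged <- rownames(raw)[apply(!is.finite(f), 1, any)]
  attr(f, "flagged_genes") <- flagged
  f
}

#' Per-nutrient SVD of fractional expression
#'
#' Computes the top two right-singular directions of one nutrient's
#' genes x growth-rates fractional-expression matrix.  The first direction
#' `v1` captures the baseline (growth-rate-independent) fractional
#' expression, the second `v2` the monotone response to growth; each gene's
#' profile is approximated by `a_i * v1 + b_i * v2`.  Sign indeterminacy is
#' resolved by the conventions `sum(v1) > 0` and `cor(v2, growth_rate) > 0`.
#'
#' @param frac Fractional-expression matrix (genes x samples) restricted to
#'   one nutrient, samples ordered by increasing growth rate.
#' @param growth_rates Growth rate per sample (strictly increasing).
#' @param nutrient Optional nutrient label carried into the result.
#' @return An object of class `nutrient_svd`: list with `nutrient`, `v1`,
#'   `v2` (unit norm), `a`, `b` (named per-gene loadings), `var_explained`
#'   (fraction of variance per retained component), `growth_rates`, and
#'   `dropped` (genes removed for non-finite values).
#' @export
nutrient_svd <- function(frac, growth_rates, nutrient = NA_character_) {
  frac <- as.matrix(frac)
  if (ncol(frac) < 2L) stop("rank error: need at least 2 samples per nutrient")
  stopifnot(length(growth_rates) == ncol(frac))
  if (is.unsorted(growth_rates, strictly = TRUE))
    stop("growth rates must be strictly increasing")
  ok <- apply(is.finite(frac), 1, all)
  dropped <- rownames(frac)[!ok]
  x <- frac[ok, , drop = FALSE]
  sv <- svd(x, nu = 0, nv = 2)
  v1 <- sv$v[, 1]
  v2 <- sv$v[, 2]
  if (sum(v1) < 0) v1 <- -v1
  r2 <- suppressWarnings(stats::cor(v2, growth_rates))
  if (is.na(r2)) r2 <- sum(v2)
  if (r2 < 0) v2 <- -v2
  a <- drop(x %*% v1)
  b <- drop(x %*% v2)
  names(a) <- names(b) <- rownames(x)
  structure(list(nutrient = nutrient,
                 v1 = v1, v2 = v2, a = a, b = b,
                 var_explained = sv$d^2 / sum(sv$d^2),
                 growth_rates = growth_rates,
                 dropped = dropped),
            class = "nutrient_svd")
}

#' @export
print.nutrient_svd <- function(x, ...) {
  cat(sprintf("nutrient_svd: %s, %d genes x %d rates; var explained %.4f + %.4f\n",
              x$nutrient, length(x$a), length(x$growth_rates),
              x$var_explained[1], x$var_explained[2]))
  invisible(x)
}

#' Pairwise baseline-specificity call between two nutrients
#'
#' A gene is *specific* between two nutrient conditions when its baseline
#' loading shifts by more than `k_sd` standard deviations of the shifts of
#' all genes; otherwise it is *nonspecific*.
#'
#' @param a_low,a_high Named baseline loadings (`a_i`) for the two nutrients
#'   over the same gene set.
#' @param k_sd Threshold in standard-deviation units (default 3).
#' @param sd_mode `"signed"` uses the standard deviation of the signed
#'   differences (default); `"absolute"` uses the standard deviation of the
#'   absolute differences.
#' @return Character vector per gene in
#'   `{"nonspecific", "specific_up", "specific_down"}` (up means the loading
#'   increases from the first to the second nutrient).
#' @export
pairwise_specificity <- function(a_low, a_high, k_sd = 3,
                                 sd_mode = c("signed", "absolute")) {
  sd_mode <- match.arg(sd_mode)
  stopifnot(length(a_low) == length(a_high))
  if (!is.null(names(a_low)) && !is.null(names(a_high)))
    stopifnot(identical(names(a_low), names(a_high)))
  d <- a_high - a_low
  s <- if (sd_mode == "signed") stats::sd(d) else stats::sd(abs(d))
  out <- rep("nonspecific", length(d))
  if (is.na(s) || s == 0) {
    if (any(d != 0)) warning("zero variance of loading differences; all genes nonspecific")
  } else {
    spec <- abs(d) > k_sd * s
    out[spec & d > 0] <- "specific_up"
    out[spec & d < 0] <- "specific_down"
  }
  names(out) <- names(d)
  out
}

#' Growth-response class from the second loading
#'
#' Ranks genes by `|b_i|` and labels the `n_invariant` smallest as invariant;
#' the rest are positive or negative by the sign of `b_i`.  Ties are broken
#' by gene identifier (lexicographic) for determinism.
#'
#' @param b Named numeric vector of second-component loadings.
#' @param n_invariant Size of the invariant quota (default 2500, the
#'   genome-scale value; scale it to the instance at hand).
#' @return Character vector per gene in `{"negative", "invariant",
#'   "positive"}`.  If fewer genes than `n_invariant` are supplied, all are
#'   invariant (with a warning).  Genes with `b == 0` beyond the quota are
#'   labelled invariant and flagged via attribute `"degenerate"`.
#' @export
growth_response_class <- function(b, n_invariant = 2500) {
  ids <- names(b)
  if (is.null(ids)) ids <- sprintf("g%06d", seq_along(b))
  if (length(b) < n_invariant) {
    warning("fewer genes than the invariant quota; all genes invariant")
    out <- rep("invariant", length(b))
    names(out) <- ids
    return(out)
  }
  ord <- order(abs(b), ids)
  out <- rep(NA_character_, length(b))
  inv_idx <- ord[seq_len(n_invariant)]
  out[inv_idx] <- "invariant"
  rest <- ord[-seq_len(n_invariant)]
  out[rest] <- ifelse(b[rest] > 0, "positive",
                      ifelse(b[rest] < 0, "negative", "invariant"))
  degenerate <- any(b[rest] == 0)
  if (degenerate)
    warning("zero loadings beyond the invariant quota; labelled invariant (degenerate)")
  names(out) <- ids
  attr(out, "degenerate") <- degenerate
  out
}

#' Aggregate pairwise and per-nutrient calls into the five-sector partition
#'
#' A gene is nonspecific when it is called nonspecific in at least
#' `nonspecific_min` of the pairwise nutrient comparisons.  Nonspecific genes
#' invariant in at least `invariant_min` nutrients are invariant; remaining
#' nonspecific genes are positive or negative by majority vote of their
#' per-nutrient classes.  Specific genes are activated or repressed by the
#' same vote.  Exact vote ties are resolved by the sign of the summed second
#' loadings (supplied via `b_by_nutrient`), positive winning at zero.
#'
#' @param pair_calls Character matrix genes x pairs with entries in
#'   `{"nonspecific", "specific_up", "specific_down"}`.
#' @param nutrient_classes Character matrix genes x nutrients with entries in
#'   `{"negative", "invariant", "positive"}`.
#' @param nonspecific_min Minimum nonspecific pair count (default 9 of 15,
#'   i.e. strictly more than half; use 8 for the "at least half" reading).
#' @param invariant_min Minimum invariant nutrient count (default 4 of 6).
#' @param b_by_nutrient Optional numeric matrix genes x nutrients of second
#'   loadings used only to break exact positive/negative vote ties.
#' @return An object of class `sector_partition`: a data.frame with
#'   `gene_id`, `sector`, `n_nonspecific_pairs`, `n_invariant_nutrients`,
#'   `n_pos`, `n_neg`, with the thresholds stored as attributes.
#' @export
aggregate_partition <- function(pair_calls, nutrient_classes,
                                nonspecific_min = 9, invariant_min = 4,
                                b_by_nutrient = NULL) {
  pair_calls <- as.matrix(pair_calls)
  nutrient_classes <- as.matrix(nutrient_classes)
  stopifnot(nrow(pair_calls) == nrow(nutrient_classes))
  if (any(is.na(pair_calls)) || any(is.na(nutrient_classes)))
    stop("incomplete evidence: missing pairwise or per-nutrient calls")
  ids <- rownames(pair_calls)
  if (is.null(ids)) ids <- sprintf("g%06d", seq_len(nrow(pair_calls)))

  n_ns <- rowSums(pair_calls == "nonspecific")
  n_inv <- rowSums(nutrient_classes == "invariant")
  n_pos <- rowSums(nutrient_classes == "positive")
  n_neg <- rowSums(nutrient_classes == "negative")

  tie_sign <- if (is.null(b_by_nutrient)) rep(1, length(ids)) else {
    s <- rowSums(as.matrix(b_by_nutrient))
    ifelse(s > 0, 1, -1)  # zero aggregate loading falls to negative
  }
  vote <- ifelse(n_pos > n_neg, 1, ifelse(n_neg > n_pos, -1, tie_sign))

  nonspecific <- n_ns >= nonspecific_min
  sector <- ifelse(nonspecific,
                   ifelse(n_inv >= invariant_min, "invariant",
                          ifelse(vote > 0, "positive", "negative")),
                   ifelse(vote > 0, "activated", "repressed"))
  out <- data.frame(gene_id = ids,
                    sector = sector,
                    n_nonspecific_pairs = as.integer(n_ns),
                    n_invariant_nutrients = as.integer(n_inv),
                    n_pos = as.integer(n_pos),
                    n_neg = as.integer(n_neg),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out,
            nonspecific_min = nonspecific_min,
            invariant_min = invariant_min,
            class = c("sector_partition", "data.frame"))
}

#' @export
print.sector_partition <- function(x, ...) {
  cat("sector_partition:", nrow(x), "genes\n")
  print(table(factor(x$sector, levels = sector_levels())))
  invisible(x)
}

#' Sector labels in canonical order
#' @return Character vector of the five sector labels.
#' @export
sector_levels <- function()
  c("repressed", "negative", "invariant", "positive", "activated")

#' Per-nutrient growth classes for all genes
#'
#' Applies [growth_response_class()] to every nutrient independently,
#' ignoring the specific/nonspecific split (used for the TF-class and
#' coherence analyses, where all genes are classified by their second
#' loading only).
#'
#' @param svds List of `nutrient_svd` objects sharing a common gene set.
#' @param n_invariant Invariant quota per nutrient.
#' @return Character matrix genes x nutrients.
#' @export
per_nutrient_allgene_class <- function(svds, n_invariant = 2500) {
  genes <- Reduce(intersect, lapply(svds, function(s) names(s$b)))
  cls <- vapply(svds, function(s)
    growth_response_class(s$b[genes], n_invariant = n_invariant),
    character(length(genes)))
  rownames(cls) <- genes
  colnames(cls) <- vapply(svds, function(s) as.character(s$nutrient), character(1))
  cls
}

#' Full SVD five-sector partition pipeline
#'
#' Runs the genome-wide partition end to end: fractional normalization,
#' per-nutrient SVD, pairwise baseline-specificity calls over all nutrient
#' pairs, per-nutrient growth classes, and aggregation into the five-sector
#' partition.  Genes with zero signal in any sample are excluded (no
#' imputation) and reported.
#'
#' @param raw Nonnegative signal matrix, genes x samples (or an already
#'   fractional matrix when `fractional = TRUE`).
#' @param meta Sample metadata data.frame with columns `sample_id`,
#'   `nutrient`, `growth_rate`; `sample_id` must match `colnames(raw)`.
#' @param n_invariant Invariant quota per nutrient (default 2500).
#' @param k_sd Pairwise-specificity threshold in SD units (default 3).
#' @param nonspecific_min,invariant_min Aggregation thresholds, see
#'   [aggregate_partition()].
#' @param sd_mode Passed to [pairwise_specificity()].
#' @param fractional Set `TRUE` if `raw` is already on the fractional
#'   log10-ppm scale.
#' @return An object of class `svd_partition`: list with `partition`
#'   (a `sector_partition`), `svd` (list of `nutrient_svd`), `pair_calls`,
#'   `nutrient_classes`, `excluded` (genes dropped for zero signal), and
#'   `params`.
#' @export
partition_expression <- function(raw, meta, n_invariant = 2500, k_sd = 3,
                                 nonspecific_min = 9, invariant_min = 4,
                                 sd_mode = "signed", fractional = FALSE) {
  stopifnot(all(c("sample_id", "nutrient", "growth_rate") %in% names(meta)))
  raw <- as.matrix(raw)
  stopifnot(all(meta$sample_id %in% colnames(raw)))
  frac <- if (fractional) raw else fractional_expression(raw)
  nutrients <- unique(meta$nutrient)

  svds <- lapply(nutrients, function(nu) {
    m <- meta[meta$nutrient == nu, , drop = FALSE]
    m <- m[order(m$growth_rate), , drop = FALSE]
    nutrient_svd(frac[, m$sample_id, drop = FALSE], m$growth_rate, nutrient = nu)
  })
  names(svds) <- nutrients

  genes <- Reduce(intersect, lapply(svds, function(s) names(s$a)))
  excluded <- setdiff(rownames(raw), genes)
  if (length(excluded))
    message(length(excluded), " gene(s) excluded for zero signal in >=1 sample")

  pairs <- utils::combn(nutrients, 2, simplify = FALSE)
  pair_calls <- vapply(pairs, function(p)
    pairwise_specificity(svds[[p[1]]]$a[genes], svds[[p[2]]]$a[genes],
                         k_sd = k_sd, sd_mode = sd_mode),
    character(length(genes)))
  rownames(pair_calls) <- genes
  colnames(pair_calls) <- vapply(pairs, paste, character(1), collapse = ":")

  nutrient_classes <- per_nutrient_allgene_class(svds, n_invariant = n_invariant)
  nutrient_classes <- nutrient_classes[genes, , drop = FALSE]
  b_mat <- vapply(svds, function(s) s$b[genes], numeric(length(genes)))
  rownames(b_mat) <- genes

  part <- aggregate_partition(pair_calls, nutrient_classes,
                              nonspecific_min = nonspecific_min,
                              invariant_min = invariant_min,
                              b_by_nutrient = b_mat)
  structure(list(partition = part,
                 svd = svds,
                 pair_calls = pair_calls,
                 nutrient_classes = nutrient_classes,
                 excluded = excluded,
                 params = list(n_invariant = n_invariant, k_sd = k_sd,
                               nonspecific_min = nonspecific_min,
                               invariant_min = invariant_min,
                               sd_mode = sd_mode)),
            class = "svd_partition")
}

#' @export
print.svd_partition <- function(x, ...) {
  cat("svd_partition over", length(x$svd), "nutrients\n")
  ve <- vapply(x$svd, function(s) sum(s$var_explained[1:2]), numeric(1))
  cat("variance explained by two components:",
      paste(sprintf("%s %.3f", names(ve), ve), collapse = ", "), "\n")
  print(x$partition)
  invisible(x)
}
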