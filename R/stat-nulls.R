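# Shared statistical machinery: class-randomization nulls, permutation null
# samples, hypergeometric enrichment with Holm correction, KS comparisons.

#' Randomization null for per-class summaries
#'
#' Compares a per-class summary statistic (by default the class mean) of a
#' per-gene quantity against a null obtained by randomly reassigning genes to
#' classes while preserving class sizes.  This is the engine behind all
#' "z-score with respect to a null by randomization" summaries in the package
#' (regulators per sector, score tracks, promoter features, modifier effects).
#'
#' @param values Named numeric vector of per-gene values.
#' @param labels Class label per gene (character or factor), aligned with
#'   `values` (recycled by name when `values` is named and `labels` is too).
#' @param statistic Function summarizing the values of one class.  The mean is
#'   special-cased to a fast path; any other function is applied per class and
#'   per randomization.
#' @param n Number of randomizations (ignored when `exact = TRUE`).
#' @param seed Integer seed for the randomization stream.
#' @param exact If `TRUE`, enumerate *all* distinct label assignments instead
#'   of sampling.  Only feasible for very small instances; the null mean and
#'   standard deviation are then population moments over the enumeration
#'   (denominator `N`), whereas sampled mode uses the sample standard
#'   deviation.
#'
#' @return A data.frame with one row per class: `class`, `n_genes`,
#'   `observed`, `null_mean`, `null_sd`, `z`, `n_randomizations`, `seed`.
#'   When `null_sd` is zero, `z` is reported as `0` if the observed value
#'   equals the null mean and as signed `Inf` otherwise (never `NaN`), so
#'   downstream thresholding is total.
#' @export
sector_randomization_null <- function(values, labels, statistic = mean,
                                      n = 10000, seed = NULL, exact = FALSE) {
  stopifnot(length(values) == length(labels))
  keep <- !is.na(values) & !is.na(labels)
  values <- as.numeric(values[keep])
  labels <- as.character(labels)[keep]
  if (length(values) == 0L) stop("no usable gene values")
  classes <- sort(unique(labels))
  sizes <- table(labels)[classes]
  if (any(sizes == 0L)) {
    warning("classes of size zero skipped: ",
            paste(classes[sizes == 0L], collapse = ", "))
    classes <- classes[sizes > 0L]
  }
  observed <- vapply(classes, function(k) statistic(values[labels == k]),
                     numeric(1))

  if (exact) {
    nulls <- .enumerate_class_stats(values, labels, classes, statistic)
    null_mean <- colMeans(nulls)
    nn <- nrow(nulls)
    null_sd <- sqrt(colMeans(sweep(nulls, 2, null_mean)^2))
    n_used <- nn
  } else {
    nulls <- .sample_class_stats(values, labels, classes, statistic, n, seed)
    null_mean <- colMeans(nulls)
    null_sd <- apply(nulls, 2, stats::sd)
    n_used <- n
  }
  z <- .safe_z(observed, null_mean, null_sd)
  data.frame(class = classes,
             n_genes = as.integer(table(labels)[classes]),
             observed = observed,
             null_mean = null_mean,
             null_sd = null_sd,
             z = z,
             n_randomizations = n_used,
             seed = if (is.null(seed)) NA_integer_ else seed,
             row.names = NULL,
             stringsAsFactors = FALSE)
}

# z with total semantics: sd 0 -> 0 when obs == mean, signed Inf otherwise
.safe_z <- function(observed, null_mean, null_sd) {
  z <- (observed - null_mean) / null_sd
  degen <- !is.na(null_sd) & null_sd == 0
  z[degen] <- ifelse(observed[degen] == null_mean[degen], 0,
                     sign(observed[degen] - null_mean[degen]) * Inf)
  z
}

# Sampled null: permuting values against fixed labels is equivalent to
# permuting labels against fixed values, and lets the mean use rowsum().
.sample_class_stats <- function(values, labels, classes, statistic, n, seed) {
  if (!is.null(seed)) set.seed(seed)
  m <- length(values)
  fast_mean <- identical(statistic, mean)
  counts <- as.numeric(table(labels)[classes])
  out <- matrix(NA_real_, n, length(classes), dimnames = list(NULL, classes))
  for (i in seq_len(n)) {
    perm <- values[sample.int(m)]
    if (fast_mean) {
      s <- rowsum(perm, labels)
      out[i, ] <- s[classes, 1] / counts
    } else {
      out[i, ] <- vapply(classes, function(k) statistic(perm[labels == k]),
                         numeric(1))
    }
  }
  out
}

# Exhaustive null: every distinct assignment of the label multiset.
.enumerate_class_stats <- function(values, labels, classes, statistic) {
  assigns <- .multiset_permutations(labels)
  t(apply(assigns, 1, function(lab)
    vapply(classes, function(k) statistic(values[lab == k]), numeric(1))))
}

.multiset_permutations <- function(x) {
  n <- length(x)
  if (n == 1L) return(matrix(x, 1L, 1L))
  ux <- unique(x)
  out <- vector("list", length(ux))
  for (j in seq_along(ux)) {
    rest <- x[-match(ux[j], x)]
    sub <- .multiset_permutations(rest)
    out[[j]] <- cbind(rep(ux[j], nrow(sub)), sub, deparse.level = 0)
  }
  do.call(rbind, out)
}

#' Null sample of per-class statistics under label randomization
#'
#' Like [sector_randomization_null()] but returns the full null sample of
#' per-class statistics (one column per class, one row per randomization),
#' e.g. for kernel-density display of the null alongside observed modifier
#' effects.
#'
#' @inheritParams sector_randomization_null
#' @return A numeric matrix `n x classes` with the observed per-class
#'   statistics attached as attribute `"observed"`.
#' @export
permutation_effect_density <- function(values, labels, statistic = mean,
                                       n = 1000, seed = NULL) {
  stopifnot(length(values) == length(labels))
  keep <- !is.na(values) & !is.na(labels)
  values <- as.numeric(values[keep])
  labels <- as.character(labels)[keep]
  classes <- sort(unique(labels))
  nulls <- .sample_class_stats(values, labels, classes, statistic, n, seed)
  attr(nulls, "observed") <- vapply(classes, function(k)
    statistic(values[labels == k]), numeric(1))
  nulls
}

#' Upper-tail hypergeometric enrichment p-value
#'
#' Probability of observing at least `overlap` category members inside a
#' group of size `group_size` drawn without replacement from a population of
#' `population` genes containing `category_size` category members.
#'
#' @param overlap Observed overlap count.
#' @param group_size Size of the selected group.
#' @param category_size Number of category members in the population.
#' @param population Population size.
#' @return `P[X >= overlap]` under the hypergeometric distribution.
#' @export
hypergeom_enrichment <- function(overlap, group_size, category_size, population) {
  if (any(c(overlap, group_size, category_size, population) < 0) ||
      overlap > min(group_size, category_size) ||
      group_size > population || category_size > population)
    stop("inconsistent hypergeometric counts")
  stats::phyper(overlap - 1, category_size, population - category_size,
                group_size, lower.tail = FALSE)
}

#' Holm step-down adjustment
#'
#' Thin wrapper over `stats::p.adjust(method = "holm")` returning the
#' adjusted p-values together with the rejection set at a given level.
#'
#' @param pvalues Numeric vector of raw p-values in `[0, 1]`.
#' @param alpha Significance level for the rejection set.
#' @return List with `adjusted` (same order as input, capped at 1) and
#'   `reject` (logical).  Empty input yields empty results.
#' @export
holm_bonferroni <- function(pvalues, alpha = 0.05) {
  if (length(pvalues) == 0L)
    return(list(adjusted = numeric(0), reject = logical(0)))
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(pvalues, method = "holm")
  list(adjusted = adj, reject = !is.na(adj) & adj <= alpha)
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' @param x,y Numeric samples (both nonempty).
#' @param alternative Passed to `stats::ks.test`.
#' @param exact `NULL` (asymptotic for the sample sizes used here) or logical.
#' @return List with `D` (sup-distance between the ECDFs) and `p`.
#' @export
ks_two_sample <- function(x, y, alternative = "two.sided", exact = NULL) {
  if (length(x) == 0L || length(y) == 0L) stop("empty sample")
  res <- suppressWarnings(stats::ks.test(x, y, alternative = alternative,
                                         exact = exact))
  list(D = unname(res$statistic), p = res$p.value)
}
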