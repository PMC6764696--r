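# Five-sector classification of promoter-activity (PA) data per pairwise
# growth transition, the typical-class summary, and per-class scaling fits.

#' Fractional promoter activity
#'
#' Converts a nonnegative PA matrix (reporter production rate per OD per
#' second) to fractional activity per condition: the share of summed promoter
#' activity each gene receives, `fPA_i = PA_i / sum_j PA_j`.
#'
#' @param pa Nonnegative numeric matrix, genes x conditions, with rownames.
#' @return Matrix of per-condition fractions (columns sum to 1).
#' @export
fractional_pa <- function(pa) {
  pa <- as.matrix(pa)
  if (any(pa < 0, na.rm = TRUE)) stop("negative promoter activities")
  tot <- colSums(pa)
  if (any(tot <= 0)) stop("degenerate condition: all-zero activity column")
  sweep(pa, 2, tot, "/")
}

#' Classify one growth transition into the five sectors
#'
#' Given fractional activities at a low- and a high-growth condition, genes
#' with activity at or below `activity_floor` in both conditions are set
#' aside as `low_activity`.  The rest are ranked by the distance of their
#' fPA ratio to 1: the `n_invariant` closest are invariant; among the
#' remainder the `n_specific` with the largest distance and ratio above 1
#' are activated, the `n_specific` largest with ratio below 1 repressed, and
#' the rest are positive (ratio above 1) or negative (below 1).
#'
#' @param fpa_low,fpa_high Named fraction vectors over the same genes,
#'   ordered low to high growth rate.
#' @param n_invariant Invariant quota (default 350).
#' @param n_specific Activated and repressed quota (default 50 each).
#' @param activity_floor Fraction below which a promoter counts as inactive
#'   (default `1e-4`).
#' @param distance `"log"` ranks by `|log(ratio)|` (symmetric in up/down,
#'   the default); `"linear"` ranks by `|ratio - 1|`.
#' @param transition Optional label (e.g. `"glycerol:glucose"`).
#' @param rate_low,rate_high Optional growth rates of the two conditions,
#'   carried along for the typical-class tie-break.
#' @return Data.frame with `gene_id`, `label`, `ratio`, `distance` and the
#'   transition metadata as columns.  A gene with zero low-growth fraction
#'   but high-growth fraction above the floor gets ratio `Inf` and ranks
#'   first among activated.  Ranking ties are broken by gene identifier.
#' @export
classify_transition <- function(fpa_low, fpa_high, n_invariant = 350,
                                n_specific = 50, activity_floor = 1e-4,
                                distance = c("log", "linear"),
                                transition = NA_character_,
                                rate_low = NA_real_, rate_high = NA_real_) {
  distance <- match.arg(distance)
  stopifnot(length(fpa_low) == length(fpa_high))
  ids <- names(fpa_low)
  if (is.null(ids)) ids <- sprintf("g%06d", seq_along(fpa_low))

  low_act <- fpa_low <= activity_floor & fpa_high <= activity_floor
  ratio <- fpa_high / fpa_low            # 0/0 -> NaN (low_activity anyway)
  dist <- if (distance == "log") abs(log(ratio)) else abs(ratio - 1)

  rankable <- which(!low_act)
  if (length(rankable) < n_invariant + 2L * n_specific)
    stop("insufficient rankable genes for the requested quotas")

  label <- rep(NA_character_, length(ids))
  label[low_act] <- "low_activity"

  ord <- rankable[order(dist[rankable], ids[rankable])]
  inv <- ord[seq_len(n_invariant)]
  label[inv] <- "invariant"
  rest <- ord[-seq_len(n_invariant)]

  up <- rest[ratio[rest] > 1]
  down <- rest[ratio[rest] < 1]
  flat <- rest[ratio[rest] == 1]
  if (length(flat)) {
    warning("exact unit ratios beyond the invariant quota; labelled invariant (degenerate)")
    label[flat] <- "invariant"
  }
  take <- function(idx, k) {
    k <- min(k, length(idx))
    idx[order(-dist[idx], ids[idx])][seq_len(k)]
  }
  act <- take(up, n_specific)
  rep_ <- take(down, n_specific)
  if (length(act) < n_specific || length(rep_) < n_specific)
    warning("fewer genes than the specific quota in one direction")
  label[act] <- "activated"
  label[rep_] <- "repressed"
  label[setdiff(up, act)] <- "positive"
  label[setdiff(down, rep_)] <- "negative"

  data.frame(gene_id = ids, label = label, ratio = ratio, distance = dist,
             transition = transition, rate_low = rate_low,
             rate_high = rate_high, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Typical (modal) class of a gene across transitions
#'
#' The most frequently occurring label a gene presents across all pairwise
#' growth transitions.  `low_activity` calls are excluded from the vote
#' unless every call is `low_activity`.  Ties are broken by the label of the
#' tied call whose transition has the highest high-growth rate (then the
#' highest low-growth rate); any remaining ambiguity falls to the fixed
#' order repressed < negative < invariant < positive < activated (larger
#' wins).
#'
#' @param calls Data.frame of per-transition calls as produced by
#'   [classify_transition()] (columns `gene_id`, `label`, optionally
#'   `rate_low`, `rate_high`), rows from one or more transitions.
#' @return Data.frame `gene_id`, `typical_class`.
#' @export
typical_class <- function(calls) {
  stopifnot(all(c("gene_id", "label") %in% names(calls)))
  if (!"rate_high" %in% names(calls)) calls$rate_high <- NA_real_
  if (!"rate_low" %in% names(calls)) calls$rate_low <- NA_real_
  order_levels <- c("repressed", "negative", "invariant", "positive",
                    "activated", "low_activity")
  one <- function(df) {
    lab <- df$label
    use <- lab != "low_activity"
    if (!any(use)) return("low_activity")
    df <- df[use, , drop = FALSE]
    tab <- table(df$label)
    winners <- names(tab)[tab == max(tab)]
    if (length(winners) == 1L) return(winners)
    cand <- df[df$label %in% winners, , drop = FALSE]
    ord <- order(-ifelse(is.na(cand$rate_high), -Inf, cand$rate_high),
                 -ifelse(is.na(cand$rate_low), -Inf, cand$rate_low),
                 -match(cand$label, order_levels))
    cand$label[ord[1L]]
  }
  res <- vapply(split(calls, calls$gene_id), one, character(1))
  data.frame(gene_id = names(res), typical_class = unname(res),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Proportional-scaling fit for a gene class
#'
#' Least-squares slope through the origin of high-growth versus low-growth
#' fractional activities restricted to one gene set, with the uncentered
#' R-squared, reported alongside the growth-rate-ratio null (the scaling a
#' purely passive proportional response would give).
#'
#' @param fpa_low,fpa_high Named fraction vectors.
#' @param members Gene identifiers of the class.
#' @param rate_low,rate_high Optional growth rates; their ratio is the null
#'   scaling.
#' @return List with `slope`, `r_squared`, `n`, `null_ratio`.
#' @export
class_scaling <- function(fpa_low, fpa_high, members,
                          rate_low = NA_real_, rate_high = NA_real_) {
  x <- fpa_low[members]
  y <- fpa_high[members]
  if (any(is.na(x)) || any(is.na(y))) stop("members missing from fractions")
  if (all(x == 0)) stop("degenerate fit: all member fractions are zero")
  slope <- sum(x * y) / sum(x * x)
  r2 <- 1 - sum((y - slope * x)^2) / sum(y^2)
  list(slope = slope, r_squared = r2, n = length(x),
       null_ratio = rate_high / rate_low)
}

#' PA five-sector pipeline over all transitions
#'
#' Computes fractional activities, classifies every ordered pair of
#' conditions with increasing growth rate (all pairs by default, or only
#' consecutive ones), and summarizes each gene by its typical class.
#'
#' @param pa Nonnegative PA matrix, genes x conditions.
#' @param growth_rates Named (by condition) or positional growth rates.
#' @param pairs `"all"` ordered increasing-rate pairs or `"consecutive"`.
#' @inheritParams classify_transition
#' @return List with `fractional`, `calls` (long data.frame over
#'   transitions), and `typical` (per-gene modal class).
#' @export
partition_pa <- function(pa, growth_rates, pairs = c("all", "consecutive"),
                         n_invariant = 350, n_specific = 50,
                         activity_floor = 1e-4, distance = "log") {
  pairs <- match.arg(pairs)
  pa <- as.matrix(pa)
  stopifnot(length(growth_rates) == ncol(pa))
  ord <- order(growth_rates)
  pa <- pa[, ord, drop = FALSE]
  growth_rates <- growth_rates[ord]
  frac <- fractional_pa(pa)
  conds <- colnames(pa)
  if (is.null(conds)) conds <- sprintf("c%02d", seq_along(growth_rates))

  idx <- if (pairs == "all") utils::combn(seq_along(conds), 2, simplify = FALSE)
         else lapply(seq_len(length(conds) - 1L), function(i) c(i, i + 1L))
  calls <- do.call(rbind, lapply(idx, function(p)
    classify_transition(frac[, p[1]], frac[, p[2]],
                        n_invariant = n_invariant, n_specific = n_specific,
                        activity_floor = activity_floor, distance = distance,
                        transition = paste(conds[p[1]], conds[p[2]], sep = ":"),
                        rate_low = growth_rates[p[1]],
                        rate_high = growth_rates[p[2]])))
  list(fractional = frac, calls = calls, typical = typical_class(calls))
}
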