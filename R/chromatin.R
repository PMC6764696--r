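# Epigenetic analyses: GTF fraction, per-sector score and feature
# enrichments, chromatin-modifier strength and signed-effect analysis, and
# slow-growth-signature removal.

#' Mean fraction of general transcription factors per sector
#'
#' For every gene with at least one regulator, the fraction of its
#' regulators belonging to the general-transcription-factor set, then the
#' per-sector mean with a sector-randomization z-score.
#'
#' @param network A `regulatory_network`.
#' @param partition A `sector_partition`.
#' @param gtf_set Identifiers of the general TFs.  The canonical yeast set
#'   is Rap1, Abf1, Reb1, Cbf1 and Mcm1; pass whatever identifiers your
#'   network uses.
#' @param n,seed Randomization parameters.
#' @return List with `per_gene` (named fractions) and `by_sector`
#'   (randomization summary data.frame).
#' @export
gtf_fraction <- function(network, partition, gtf_set, n = 10000, seed = NULL) {
  if (length(gtf_set) == 0L) stop("empty GTF set")
  e <- network$edges
  e <- e[e$target %in% partition$gene_id, , drop = FALSE]
  tot <- table(e$target)
  gtf <- table(e$target[e$tf %in% gtf_set])
  frac <- rep(0, length(tot))
  names(frac) <- names(tot)
  frac[names(gtf)] <- as.numeric(gtf) / as.numeric(tot[names(gtf)])
  lab <- partition$sector[match(names(frac), partition$gene_id)]
  list(per_gene = frac,
       by_sector = sector_randomization_null(frac, lab, n = n, seed = seed))
}

#' Per-sector summary of a continuous gene score
#'
#' Mean of a continuous per-gene score (nucleosome fragility, cis/trans
#' variability, expression level, noise, ...) within each sector, with a
#' sector-randomization z-score.  Genes missing from the track are excluded.
#'
#' @param track Named numeric vector (gene scores).
#' @param partition A `sector_partition`.
#' @param n,seed Randomization parameters.
#' @return Data.frame as returned by [sector_randomization_null()].
#' @export
sector_score_summary <- function(track, partition, n = 10000, seed = NULL) {
  common <- intersect(names(track), partition$gene_id)
  if (!length(common)) stop("track shares no genes with the partition")
  lab <- partition$sector[match(common, partition$gene_id)]
  sector_randomization_null(track[common], lab, n = n, seed = seed)
}

#' Per-sector enrichment of a binary promoter feature
#'
#' Same engine as [sector_score_summary()] with the statistic being the
#' within-sector feature fraction.  The feature may be given as a named 0/1
#' vector or as a character vector of member genes (interpreted against the
#' partition universe).
#'
#' @param feature Named 0/1 vector or character vector of gene identifiers.
#' @param partition A `sector_partition`.
#' @param n,seed Randomization parameters.
#' @return Data.frame as returned by [sector_randomization_null()].
#' @export
binary_feature_enrichment <- function(feature, partition, n = 10000, seed = NULL) {
  if (is.character(feature)) {
    v <- as.numeric(partition$gene_id %in% feature)
    names(v) <- partition$gene_id
    feature <- v
  }
  if (!all(feature %in% c(0, 1))) stop("binary feature must take values 0/1")
  sector_score_summary(feature, partition, n = n, seed = seed)
}

#' Chromatin-modifier compendium container
#'
#' @param profiles Numeric matrix mutants x genes of log2 expression ratios.
#' @param mutants Data.frame with columns `modifier` (matching rownames of
#'   `profiles`) and `family` (modifier class: TAF, HAT, HDAC,
#'   methyltransferase, remodeler, silencing, other, ...).
#' @return Object of class `modifier_compendium`.
#' @export
modifier_compendium <- function(profiles, mutants) {
  profiles <- as.matrix(profiles)
  stopifnot(all(c("modifier", "family") %in% names(mutants)),
            all(rownames(profiles) %in% mutants$modifier))
  structure(list(profiles = profiles,
                 mutants = mutants[match(rownames(profiles), mutants$modifier), ,
                                   drop = FALSE],
                 normalized = FALSE),
            class = "modifier_compendium")
}

#' @export
print.modifier_compendium <- function(x, ...) {
  cat(sprintf("modifier_compendium: %d mutants x %d genes (%snormalized)\n",
              nrow(x$profiles), ncol(x$profiles),
              if (x$normalized) "" else "not "))
  invisible(x)
}

#' Normalize each mutant profile to unit variance
#'
#' Divides every mutant's log2-ratio profile by its standard deviation (the
#' mean is untouched).  Zero-variance profiles are dropped with a warning.
#' Idempotent.
#'
#' @param comp A `modifier_compendium`.
#' @return The compendium with `normalized = TRUE`.
#' @export
normalize_compendium <- function(comp) {
  stopifnot(inherits(comp, "modifier_compendium"))
  s <- apply(comp$profiles, 1, stats::sd)
  drop <- s == 0 | is.na(s)
  if (any(drop)) {
    warning(sum(drop), " zero-variance profile(s) dropped")
    comp$profiles <- comp$profiles[!drop, , drop = FALSE]
    comp$mutants <- comp$mutants[!drop, , drop = FALSE]
    s <- s[!drop]
  }
  comp$profiles <- comp$profiles / s
  comp$normalized <- TRUE
  comp
}

#' Chromatin-regulatory-effect strength on specific vs nonspecific genes
#'
#' For each modifier, the mean absolute (unit-variance normalized) log2
#' ratio over the specific (repressed + activated) and nonspecific gene
#' groups, with z-scores from gene-label randomization.  A modifier is
#' called stronger in specific genes when the specific-group z exceeds 2.
#'
#' @param comp A normalized `modifier_compendium`.
#' @param partition A `sector_partition`.
#' @param n,seed Randomization parameters.
#' @return Data.frame per modifier: group means, z-scores, and the
#'   `stronger_in_specific` flag.
#' @export
cre_strength <- function(comp, partition, n = 10000, seed = NULL) {
  stopifnot(inherits(comp, "modifier_compendium"))
  if (!comp$normalized) warning("compendium is not unit-variance normalized")
  genes <- intersect(colnames(comp$profiles), partition$gene_id)
  if (!length(genes)) stop("no partitioned genes in the compendium")
  lab <- ifelse(partition$sector[match(genes, partition$gene_id)] %in%
                  c("repressed", "activated"), "specific", "nonspecific")
  a <- abs(comp$profiles[, genes, drop = FALSE])
  if (!is.null(seed)) set.seed(seed)
  idx_spec <- which(lab == "specific")
  idx_ns <- which(lab == "nonspecific")
  if (!length(idx_spec) || !length(idx_ns))
    stop("both specific and nonspecific genes are required")
  obs_s <- rowMeans(a[, idx_spec, drop = FALSE])
  obs_n <- rowMeans(a[, idx_ns, drop = FALSE])
  m <- length(genes)
  k <- length(idx_spec)
  s1s <- s2s <- s1n <- s2n <- numeric(nrow(a))
  for (it in seq_len(n)) {
    p <- sample.int(m)
    ms <- rowMeans(a[, p[seq_len(k)], drop = FALSE])
    mn <- rowMeans(a[, p[-seq_len(k)], drop = FALSE])
    s1s <- s1s + ms; s2s <- s2s + ms^2
    s1n <- s1n + mn; s2n <- s2n + mn^2
  }
  mu_s <- s1s / n; sd_s <- sqrt(pmax(0, (s2s - n * mu_s^2) / (n - 1)))
  mu_n <- s1n / n; sd_n <- sqrt(pmax(0, (s2n - n * mu_n^2) / (n - 1)))
  z_s <- .safe_z(obs_s, mu_s, sd_s)
  z_n <- .safe_z(obs_n, mu_n, sd_n)
  data.frame(modifier = rownames(a),
             family = comp$mutants$family,
             mean_specific = obs_s, mean_nonspecific = obs_n,
             z_specific = z_s, z_nonspecific = z_n,
             stronger_in_specific = z_s > 2,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Signed modifier effects on the nonspecific sectors, with classification
#'
#' For each modifier, the mean signed effect on the genes of the negative,
#' invariant and positive sectors is assessed against a sector-label
#' permutation null (labels randomized among the nonspecific genes).  The
#' permutation sample provides the per-sector scale; by default
#' (`center = "zero"`) an effect is significant when the observed mean lies
#' more than two permutation SDs (corrected for finite-population
#' shrinkage) away from zero, the no-effect point of log2 ratios.  With
#' `center = "null_mean"` the band is the literal null mean +/- 2 SD of the
#' permutation sample; note that this band is centered on the modifier's
#' own grand mean, so globally uncentered effects read as their deviation
#' pattern only.  `band = "quantile"` replaces the 2-SD band by the central
#' 95.45% of the (re-centered) null sample.
#'
#' Modifiers are then classified: *dual* when the positive-sector mean is
#' significantly negative and the invariant or negative mean significantly
#' positive; *activator* when both the invariant and positive means are
#' significantly negative and no sector is significantly positive;
#' *repressor* when the negative-sector mean is significantly positive and
#' no sector is significantly negative; otherwise unclassified.
#'
#' @param comp A normalized `modifier_compendium`.
#' @param partition A `sector_partition`.
#' @param n,seed Randomization parameters.
#' @param band `"sd"` (+/- 2 SD, default) or `"quantile"` (central 95.45%).
#' @param center `"zero"` (default) or `"null_mean"`, see above.
#' @return List with `effects` (long data.frame modifier x sector: mean,
#'   null mean/sd, z, significance direction) and `classification`
#'   (data.frame `modifier`, `family`, `class`).
#' @export
modifier_signed_effects <- function(comp, partition, n = 10000, seed = NULL,
                                    band = c("sd", "quantile"),
                                    center = c("zero", "null_mean")) {
  band <- match.arg(band)
  center <- match.arg(center)
  stopifnot(inherits(comp, "modifier_compendium"))
  if (!comp$normalized) warning("compendium is not unit-variance normalized")
  sectors <- c("negative", "invariant", "positive")
  keep <- partition$sector %in% sectors
  genes <- intersect(colnames(comp$profiles), partition$gene_id[keep])
  if (!length(genes)) stop("no nonspecific genes in the compendium")
  lab <- partition$sector[match(genes, partition$gene_id)]
  x <- comp$profiles[, genes, drop = FALSE]
  idx <- lapply(sectors, function(s) which(lab == s))
  names(idx) <- sectors
  counts <- lengths(idx)
  obs <- vapply(sectors, function(s) rowMeans(x[, idx[[s]], drop = FALSE]),
                numeric(nrow(x)))
  if (!is.null(seed)) set.seed(seed)
  m <- length(genes)
  nm <- nrow(x)
  bounds <- cumsum(counts)
  # running moments keep memory flat; the full null sample is only kept
  # when the quantile band needs it
  keep_sample <- band == "quantile"
  s1 <- s2 <- matrix(0, nm, 3L)
  null_arr <- if (keep_sample) array(NA_real_, c(n, nm, 3L)) else NULL
  for (it in seq_len(n)) {
    p <- sample.int(m)
    nm1 <- rowMeans(x[, p[seq_len(bounds[1])], drop = FALSE])
    nm2 <- rowMeans(x[, p[(bounds[1] + 1):bounds[2]], drop = FALSE])
    nm3 <- rowMeans(x[, p[(bounds[2] + 1):bounds[3]], drop = FALSE])
    s1 <- s1 + cbind(nm1, nm2, nm3)
    s2 <- s2 + cbind(nm1^2, nm2^2, nm3^2)
    if (keep_sample) {
      null_arr[it, , 1L] <- nm1; null_arr[it, , 2L] <- nm2
      null_arr[it, , 3L] <- nm3
    }
  }
  out <- vector("list", 3L)
  sig <- matrix("none", nm, 3L, dimnames = list(rownames(x), sectors))
  for (j in 1:3) {
    mu <- s1[, j] / n
    sdv <- sqrt(pmax(0, (s2[, j] - n * mu^2) / (n - 1)))
    # permutation SD estimates the finite-population sampling scale; for
    # the zero-centered test undo the (1 - n_s/m) shrinkage
    if (center == "zero") {
      ctr <- 0
      scale_j <- sdv / sqrt(1 - counts[j] / m)
    } else {
      ctr <- mu
      scale_j <- sdv
    }
    if (band == "sd") {
      lo <- ctr - 2 * scale_j
      hi <- ctr + 2 * scale_j
    } else {
      nu <- null_arr[, , j, drop = TRUE]
      if (is.null(dim(nu))) nu <- matrix(nu, ncol = 1L)
      q <- apply(nu - rep(mu, each = nrow(nu)), 2, stats::quantile,
                 probs = c(0.02275, 0.97725))
      if (center == "zero") {
        fpc <- sqrt(1 - counts[j] / m)
        lo <- q[1, ] / fpc; hi <- q[2, ] / fpc
      } else {
        lo <- mu + q[1, ]; hi <- mu + q[2, ]
      }
    }
    sig[obs[, j] < lo, j] <- "negative"
    sig[obs[, j] > hi, j] <- "positive"
    out[[j]] <- data.frame(modifier = rownames(x), sector = sectors[j],
                           mean_effect = obs[, j], null_mean = mu,
                           null_sd = sdv, z = .safe_z(obs[, j], ctr, scale_j),
                           significance = sig[, j],
                           row.names = NULL, stringsAsFactors = FALSE)
  }
  effects <- do.call(rbind, out)
  cls <- apply(sig, 1, function(s) {
    any_pos <- any(s == "positive")
    any_neg <- any(s == "negative")
    if (s["positive"] == "negative" &&
        (s["invariant"] == "positive" || s["negative"] == "positive"))
      "dual"
    else if (s["invariant"] == "negative" && s["positive"] == "negative" &&
             !any_pos)
      "activator"
    else if (s["negative"] == "positive" && !any_neg)
      "repressor"
    else "unclassified"
  })
  list(effects = effects,
       classification = data.frame(modifier = rownames(x),
                                   family = comp$mutants$family,
                                   class = unname(cls),
                                   row.names = NULL, stringsAsFactors = FALSE))
}

#' Slow-growth signature from a reference expression matrix
#'
#' The rank-1 SVD approximation of the reference genes x conditions matrix
#' is computed; the column of that approximation with the largest Euclidean
#' norm is taken as the slow-growth profile and normalized to unit norm.
#'
#' @param ref Numeric matrix genes x conditions (>= 2 columns), rownames
#'   identifying genes.
#' @return Object of class `slow_growth_signature`: list with `signature`
#'   (named unit-norm vector over genes) and `norm` (pre-normalization
#'   Euclidean norm of the chosen column).
#' @export
slow_growth_signature <- function(ref) {
  ref <- as.matrix(ref)
  if (ncol(ref) < 2L) stop("need at least 2 reference conditions")
  if (all(ref == 0)) stop("degenerate reference: all zeros")
  sv <- svd(ref, nu = 1, nv = ncol(ref))
  j <- which.max(abs(sv$v[, 1]))
  col_norm <- sv$d[1] * abs(sv$v[j, 1])
  s <- sign(sv$v[j, 1]) * sv$u[, 1]
  names(s) <- rownames(ref)
  structure(list(signature = s, norm = col_norm),
            class = "slow_growth_signature")
}

#' Remove the slow-growth signature from a compendium
#'
#' Projects every mutant profile onto the orthogonal complement of the
#' normalized slow-growth profile (Gram-Schmidt step
#' `p - (p . s) s`), so that corrected profiles are exactly orthogonal to
#' the signature.  Gene sets are aligned by intersection (dropped counts
#' recorded in attribute `"n_dropped_genes"`).
#'
#' @param comp A `modifier_compendium`.
#' @param signature A `slow_growth_signature` (or named unit-norm vector).
#' @return The corrected compendium, restricted to the shared genes.
#' @export
remove_slow_growth <- function(comp, signature) {
  stopifnot(inherits(comp, "modifier_compendium"))
  s <- if (inherits(signature, "slow_growth_signature")) signature$signature
       else signature
  genes <- intersect(colnames(comp$profiles), names(s))
  if (!length(genes)) stop("no shared genes between compendium and signature")
  dropped <- ncol(comp$profiles) - length(genes)
  s <- s[genes]
  s <- s / sqrt(sum(s^2))        # renormalize after restriction
  x <- comp$profiles[, genes, drop = FALSE]
  proj <- x %*% s
  comp$profiles <- x - proj %*% t(s)
  attr(comp, "n_dropped_genes") <- dropped
  comp
}

#' Overlap of ESR gene sets with the partition sectors
#'
#' Counts, per sector, the overlap with the stress-induced and
#' stress-repressed environmental-stress-response gene sets, with
#' upper-tail hypergeometric enrichment p-values (Holm-adjusted across all
#' sector x set tests).
#'
#' @param esr_induced,esr_repressed Character vectors of gene identifiers.
#' @param partition A `sector_partition`.
#' @return Data.frame: `sector`, `esr_set`, `sector_size`, `esr_size`,
#'   `overlap`, `p`, `p_holm`.
#' @export
esr_overlap <- function(esr_induced, esr_repressed, partition) {
  universe <- partition$gene_id
  sets <- list(induced = intersect(esr_induced, universe),
               repressed = intersect(esr_repressed, universe))
  levs <- intersect(sector_levels(), unique(partition$sector))
  rows <- list()
  for (sn in names(sets)) {
    for (sec in levs) {
      members <- universe[partition$sector == sec]
      ov <- length(intersect(members, sets[[sn]]))
      p <- if (length(sets[[sn]]) == 0L) 1 else
        hypergeom_enrichment(ov, length(members), length(sets[[sn]]),
                             length(universe))
      rows[[length(rows) + 1L]] <-
        data.frame(sector = sec, esr_set = sn,
                   sector_size = length(members),
                   esr_size = length(sets[[sn]]), overlap = ov, p = p,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_holm <- holm_bonferroni(out$p)$adjusted
  out
}
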