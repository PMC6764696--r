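# Synthetic-data generators with planted ground truth: expression with
# rank-2 per-nutrient structure and specific baseline shifts, a regulatory
# network with coherent TFs, a chromatin-modifier compendium with planted
# effect classes, promoter-activity tables, score tracks, and a reference
# matrix carrying a slow-growth signature.

#' Simulation configuration
#'
#' Bundles and validates every knob of the synthetic-data generators.  The
#' defaults emulate the chemostat design the pipeline was built for: six
#' limiting nutrients, six dilution rates each (0.05-0.30/h), and a sector
#' composition matching a genome dominated by nonspecific genes with a
#' small specific fringe.
#'
#' @param n_genes Number of genes.
#' @param n_tfs Number of TF genes (sampled from the gene set).
#' @param nutrients Nutrient labels.
#' @param rates_per_nutrient Growth rates per nutrient (>= 2).
#' @param growth_rates Either one increasing vector reused for every
#'   nutrient or a named list per nutrient.
#' @param sector_proportions Simplex over the five sectors in the order
#'   repressed, negative, invariant, positive, activated.  Note that the
#'   pairwise 3-SD specificity rule is scale-free in the shift size: when
#'   the specific fraction `q` satisfies `3 * sqrt(q * (1 - q)) >= 1`
#'   (roughly `q > 0.127`) no equal-magnitude shift can ever exceed the
#'   threshold, so such compositions are rejected with a warning.
#' @param baseline_shift_sd Per-nutrient baseline displacement unit (in
#'   first-loading units) of specific genes.
#' @param growth_slope_scale Magnitude of the second loading for
#'   positive/negative (and activated/repressed) genes.
#' @param noise_sd Additive Gaussian noise on the fractional-log scale.
#' @param baseline_sd Gene-to-gene spread of baseline fractional expression
#'   (log10 units).
#' @param coherent_fraction Probability that a network edge is built
#'   coherent (the TF drawn from the target's growth class).
#' @param regulators_mu Mean in-degrees, named `specific`, `growth`
#'   (nonspecific positive/negative) and `invariant`.
#' @param modifier_classes Named map modifier -> planted behaviour in
#'   `{activator, dual, repressor}`.
#' @param modifier_effect Planted mean effect size (log2 units before unit
#'   -variance normalization).
#' @param compendium_noise_sd Per-gene noise of compendium profiles.
#' @param cre_specific_factor Noise-magnitude multiplier on specific genes
#'   (makes modifier effects stronger there).
#' @param slow_growth_lambda Amplitude of the slow-growth contamination
#'   added to every compendium profile (0 = clean).
#' @param pa_noise_sd Multiplicative (log) noise of the promoter-activity
#'   generator.
#' @param specificity_mode `"full"` plants specific genes apart in all 15
#'   pairwise comparisons; `"marginal"` plants a pattern that separates
#'   them in only part of the comparisons, to exercise the aggregation
#'   threshold.
#' @param seed Integer master seed; each generator derives its own stream
#'   from it, so partial runs are reproducible.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 5000,
                       n_tfs = 130,
                       nutrients = c("glucose", "ammonium", "phosphate",
                                     "sulfate", "leucine", "uracil"),
                       rates_per_nutrient = 6,
                       growth_rates = seq(0.05, 0.30, by = 0.05),
                       sector_proportions = c(repressed = 0.011,
                                              negative = 0.400,
                                              invariant = 0.280,
                                              positive = 0.306,
                                              activated = 0.003),
                       baseline_shift_sd = 1,
                       growth_slope_scale = 0.5,
                       noise_sd = 0.025,
                       baseline_sd = 0.5,
                       coherent_fraction = 0.5,
                       regulators_mu = c(specific = 5.06, growth = 3.3,
                                         invariant = 2.56),
                       modifier_classes = NULL,
                       modifier_effect = 0.3,
                       compendium_noise_sd = 1,
                       cre_specific_factor = 2,
                       slow_growth_lambda = 0,
                       pa_noise_sd = 0.01,
                       specificity_mode = c("full", "marginal"),
                       seed = 1) {
  specificity_mode <- match.arg(specificity_mode)
  if (rates_per_nutrient < 2L)
    stop("invalid design: SVD needs at least 2 growth rates per nutrient")
  if (!is.list(growth_rates))
    growth_rates <- stats::setNames(rep(list(growth_rates), length(nutrients)),
                                    nutrients)
  stopifnot(length(growth_rates) == length(nutrients))
  for (g in growth_rates) {
    if (length(g) != rates_per_nutrient)
      stop("invalid design: growth_rates length must equal rates_per_nutrient")
    if (any(g <= 0) || is.unsorted(g, strictly = TRUE))
      stop("invalid design: growth rates must be positive and strictly increasing")
  }
  levs <- sector_levels()
  if (is.null(names(sector_proportions))) names(sector_proportions) <- levs
  sector_proportions <- sector_proportions[levs]
  if (any(is.na(sector_proportions)) ||
      abs(sum(sector_proportions) - 1) > 1e-8 || any(sector_proportions < 0))
    stop("sector_proportions must be a simplex over the five sectors")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  q <- sum(sector_proportions[c("repressed", "activated")])
  if (3 * sqrt(q * (1 - q)) >= 1)
    warning("specific fraction too large: the 3-SD specificity rule can never ",
            "flag equal-magnitude shifts when 3*sqrt(q*(1-q)) >= 1")
  if (is.null(modifier_classes))
    modifier_classes <- stats::setNames(
      rep(c("activator", "dual", "repressor"), times = c(60, 55, 55)),
      sprintf("%s%03d", rep(c("act", "dual", "rep"), times = c(60, 55, 55)),
              c(1:60, 1:55, 1:55)))
  if (!all(modifier_classes %in% c("activator", "dual", "repressor")))
    stop("invalid design: unknown modifier class label")
  structure(list(n_genes = n_genes, n_tfs = n_tfs, nutrients = nutrients,
                 rates_per_nutrient = rates_per_nutrient,
                 growth_rates = growth_rates,
                 sector_proportions = sector_proportions,
                 baseline_shift_sd = baseline_shift_sd,
                 growth_slope_scale = growth_slope_scale,
                 noise_sd = noise_sd, baseline_sd = baseline_sd,
                 coherent_fraction = coherent_fraction,
                 regulators_mu = regulators_mu,
                 modifier_classes = modifier_classes,
                 modifier_effect = modifier_effect,
                 compendium_noise_sd = compendium_noise_sd,
                 cre_specific_factor = cre_specific_factor,
                 slow_growth_lambda = slow_growth_lambda,
                 pa_noise_sd = pa_noise_sd,
                 specificity_mode = specificity_mode,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# largest-remainder apportionment of n among proportions p
.apportion <- function(n, p) {
  raw <- p * n
  k <- floor(raw)
  short <- n - sum(k)
  if (short > 0) {
    add <- order(raw - k, decreasing = TRUE)[seq_len(short)]
    k[add] <- k[add] + 1
  }
  as.integer(k)
}

# per-generator seed streams derived from the master seed
.sim_seed <- function(config, offset) (config$seed %% 100000L) * 10L + offset

#' Generate a synthetic expression dataset with planted sectors
#'
#' Per nutrient, each gene's fractional-log profile over growth rates is a
#' linear combination `a_i * v1 + b_i * v2` of a flat unit-norm baseline
#' `v1` and a centered, linearly increasing unit-norm growth direction `v2`
#' (built from the nutrient's growth rates), plus Gaussian noise.  Planted
#' invariant genes have `b_i = 0`, positive/activated `+growth_slope_scale`,
#' negative/repressed `-growth_slope_scale`.  Specific (repressed/activated)
#' genes additionally receive a staircase of baseline shifts across
#' nutrients so that their first loading differs between conditions by at
#' least `baseline_shift_sd` (and multiples of it), enough to exceed the
#' 3-SD pairwise test by construction under a feasible sector composition.
#' The profiles are renormalized so that fractions sum exactly to one per
#' sample and returned on the raw positive scale with arbitrary per-sample
#' scale factors, so the normalization stage is exercised downstream.
#'
#' Exact fraction normalization and exact rank-2 log-scale structure are
#' mutually exclusive: the sum-to-one constraint is nonlinear on the log
#' scale and adds a small per-sample shift (a variance leak of order 1e-5).
#' With `normalize_fractions = FALSE` the planted matrix is returned
#' exactly rank 2 per nutrient (fractions then sum to one only
#' approximately), which is the right input for rank-closure and
#' loading-recovery checks.
#'
#' @param config A [sim_config()].
#' @param normalize_fractions Renormalize each sample so fractions sum
#'   exactly to one (default `TRUE`; see above).
#' @return Object of class `sim_expression`: list with `raw` (genes x
#'   samples), `fractional` (log10-ppm scale), `meta` (`sample_id`,
#'   `nutrient`, `growth_rate`), and `truth` (class `truth_labels`: per-gene
#'   `sector`, `per_nutrient_class`, and the planted pre-normalization
#'   loadings `a` and `b`).
#' @export
generate_expression <- function(config, normalize_fractions = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.sim_seed(config, 1L))
  n <- config$n_genes
  nutr <- config$nutrients
  tt <- config$rates_per_nutrient
  genes <- sprintf("g%05d", seq_len(n))

  counts <- .apportion(n, config$sector_proportions)
  sector <- sample(rep(sector_levels(), counts))
  names(sector) <- genes

  b <- numeric(n)
  b[sector %in% c("positive", "activated")] <- config$growth_slope_scale
  b[sector %in% c("negative", "repressed")] <- -config$growth_slope_scale
  names(b) <- genes

  specific <- sector %in% c("repressed", "activated")
  shift_sign <- ifelse(specific, sample(c(-1, 1), n, replace = TRUE), 0)
  stair <- seq_along(nutr) - (length(nutr) + 1) / 2
  shift <- outer(shift_sign * config$baseline_shift_sd, stair)
  marginal <- rep(FALSE, n)
  if (config$specificity_mode == "marginal") {
    if (length(nutr) != 6L)
      stop("marginal specificity mode requires 6 nutrients")
    # a small cohort whose baseline pattern clears the per-pair 3-SD
    # threshold (set by the full-staircase majority, ~3*sqrt(q)*sep) in
    # exactly 7 of the 15 nutrient pairs; pattern units are
    # threshold-per-unit-separation, see the methods vignette
    idx_spec <- which(specific)
    n_marg <- max(2L, round(0.1 * length(idx_spec)))
    idx_marg <- sort(sample(idx_spec, min(n_marg, length(idx_spec))))
    marginal[idx_marg] <- TRUE
    q_full <- (length(idx_spec) - length(idx_marg)) / n
    cpred <- 3 * sqrt(q_full * (1 - q_full))
    w <- c(0, 0, 0, 2.65, 3.25, 4.45)
    shift[idx_marg, ] <- outer(shift_sign[idx_marg] *
                                 config$baseline_shift_sd * cpred, w)
    # a reduced growth loading keeps these genes clear of the invariant
    # quota while avoiding the baseline contamination that the global
    # correlation between the two loading vectors induces
    b[idx_marg] <- 0.1 * b[idx_marg]
  }

  a0 <- sqrt(tt) * stats::rnorm(n, log10(1e6 / n), config$baseline_sd)
  a_mat <- matrix(a0, n, length(nutr), dimnames = list(genes, nutr))
  a_mat <- a_mat + shift

  frac <- NULL
  meta <- NULL
  for (k in seq_along(nutr)) {
    r <- config$growth_rates[[k]]
    v1 <- rep(1 / sqrt(tt), tt)
    v2 <- (r - mean(r)) / sqrt(sum((r - mean(r))^2))
    f <- outer(a_mat[, k], v1) + outer(b, v2)
    if (config$noise_sd > 0)
      f <- f + matrix(stats::rnorm(n * tt, 0, config$noise_sd), n, tt)
    if (normalize_fractions)
      f <- sweep(f, 2, 6 - log10(colSums(10^f)), "+") # fractions sum to 1
    ids <- sprintf("%s_r%d", nutr[k], seq_len(tt))
    colnames(f) <- ids
    frac <- cbind(frac, f)
    meta <- rbind(meta, data.frame(sample_id = ids, nutrient = nutr[k],
                                   growth_rate = r, stringsAsFactors = FALSE))
  }
  rownames(frac) <- genes
  raw <- sweep(10^frac, 2, stats::runif(ncol(frac), 0.5, 2), "*")

  growth_class <- ifelse(b > 0, "positive", ifelse(b < 0, "negative", "invariant"))
  per_nutrient_class <- matrix(growth_class, n, length(nutr),
                               dimnames = list(genes, nutr))
  names(marginal) <- genes
  truth <- structure(list(gene_id = genes,
                          sector = sector,
                          per_nutrient_class = per_nutrient_class,
                          marginal = marginal,
                          a = a_mat, b = b,
                          is_coherent_target = NULL,
                          regulating_tfs = NULL),
                     class = "truth_labels")
  structure(list(raw = raw, fractional = frac, meta = meta, truth = truth),
            class = "sim_expression")
}

#' Generate a regulatory network with planted coherent edges
#'
#' Targets draw their number of regulators from Poisson means that mirror
#' the observed ordering (specific genes most regulated, invariant genes
#' least).  Each edge is built *coherent* with probability
#' `coherent_fraction`: its TF is drawn from the TFs sharing the target's
#' growth class, so TF and target profiles correlate positively across
#' growth rates.  Other edges draw a TF uniformly.  A target is a planted
#' coherent target when it is non-invariant, has at least one regulator,
#' and all its edges were built coherent.
#'
#' @param config A [sim_config()].
#' @param truth The `truth_labels` from [generate_expression()] under the
#'   same config.
#' @return A `regulatory_network` with extra fields `coherent_targets`
#'   (character) and `tf_class` (named growth classes of the TFs).
#' @export
generate_network <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "truth_labels"))
  if (config$n_tfs == 0L && config$coherent_fraction > 0)
    stop("invalid design: coherent edges require at least one TF")
  set.seed(.sim_seed(config, 2L))
  genes <- truth$gene_id
  gclass <- ifelse(truth$b > 0, "positive",
                   ifelse(truth$b < 0, "negative", "invariant"))
  tfs <- sort(sample(genes, config$n_tfs))
  tf_class <- gclass[tfs]
  pool <- split(tfs, tf_class[tfs])

  mu <- ifelse(truth$sector %in% c("repressed", "activated"),
               config$regulators_mu[["specific"]],
               ifelse(truth$sector == "invariant",
                      config$regulators_mu[["invariant"]],
                      config$regulators_mu[["growth"]]))
  kk <- pmin(stats::rpois(length(genes), mu), length(tfs))

  edge_tf <- vector("list", length(genes))
  coherent <- logical(length(genes))
  for (i in seq_along(genes)) {
    k <- kk[i]
    if (k == 0L) next
    n_coh <- stats::rbinom(1L, k, config$coherent_fraction)
    match_pool <- setdiff(pool[[gclass[i]]], genes[i])
    if (gclass[i] == "invariant" || is.null(match_pool)) match_pool <- character(0)
    coh_tfs <- if (n_coh > 0 && length(match_pool))
      sample(match_pool, min(n_coh, length(match_pool))) else character(0)
    rest_pool <- setdiff(tfs, c(coh_tfs, genes[i]))
    n_rest <- min(k - length(coh_tfs), length(rest_pool))
    rest_tfs <- if (n_rest > 0) sample(rest_pool, n_rest) else character(0)
    edge_tf[[i]] <- c(coh_tfs, rest_tfs)
    coherent[i] <- gclass[i] != "invariant" &&
      length(coh_tfs) == length(edge_tf[[i]]) && length(edge_tf[[i]]) > 0L
  }
  nn <- lengths(edge_tf)
  edges <- data.frame(tf = unlist(edge_tf),
                      target = rep(genes, nn),
                      stringsAsFactors = FALSE)
  net <- regulatory_network(edges, tfs = tfs)
  net$coherent_targets <- genes[coherent]
  net$tf_class <- tf_class
  net
}

# Unnormalized slow-growth profile shared by the compendium contamination
# and the reference-matrix generator: a sector-tilted pattern (stress-like
# induction of negative genes, repression of positive genes) plus
# gene-level variation, scaled to unit RMS.
.slow_signature_raw <- function(config, truth) {
  set.seed(.sim_seed(config, 6L))
  tilt <- ifelse(truth$sector %in% c("negative", "repressed"), 1,
                 ifelse(truth$sector %in% c("positive", "activated"), -1, 0))
  s <- 0.5 * tilt + stats::rnorm(length(tilt))
  s <- s / sqrt(mean(s^2))
  names(s) <- truth$gene_id
  s
}

#' Generate a chromatin-modifier compendium with planted effect classes
#'
#' Each modifier's per-gene log2 ratios are Gaussian around a planted
#' sector-dependent mean given by its behaviour class: *activators* lower
#' invariant and positive genes upon mutation, *dual* modifiers raise
#' negative genes and lower positive ones, *repressors* raise negative
#' genes.  Specific genes receive noise of larger magnitude (stronger
#' chromatin-regulatory effect).  With `slow_growth_lambda > 0` every
#' profile is additionally contaminated by a multiple of the shared
#' slow-growth profile, to exercise the signature-removal stage.
#'
#' @param config A [sim_config()].
#' @param truth The matching `truth_labels`.
#' @return A `modifier_compendium` whose `mutants` table carries the planted
#'   `behaviour` next to the `family` metadata; the unnormalized slow-growth
#'   profile used for contamination is attached as attribute
#'   `"slow_signature_raw"`.
#' @export
generate_compendium <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "truth_labels"))
  sraw <- .slow_signature_raw(config, truth)
  set.seed(.sim_seed(config, 3L))
  beh <- config$modifier_classes
  mods <- names(beh)
  genes <- truth$gene_id
  sec <- truth$sector
  e <- config$modifier_effect
  mu_for <- function(cl) {
    m <- numeric(length(genes))
    if (cl == "activator") m[sec %in% c("invariant", "positive")] <- -e
    if (cl == "dual") { m[sec == "negative"] <- e; m[sec == "positive"] <- -e }
    if (cl == "repressor") m[sec == "negative"] <- e
    m
  }
  sd_gene <- config$compendium_noise_sd *
    ifelse(sec %in% c("repressed", "activated"), config$cre_specific_factor, 1)
  x <- t(vapply(mods, function(m)
    mu_for(beh[[m]]) + stats::rnorm(length(genes), 0, sd_gene),
    numeric(length(genes))))
  if (config$slow_growth_lambda > 0) {
    lam <- config$slow_growth_lambda * stats::runif(length(mods), 0.5, 1.5)
    x <- x + outer(lam, sraw)
  }
  dimnames(x) <- list(mods, genes)
  fam_pool <- list(activator = c("TAF", "HAT", "methyltransferase"),
                   dual = c("remodeler", "other"),
                   repressor = "silencing")
  family <- vapply(seq_along(beh), function(i) {
    p <- fam_pool[[beh[[i]]]]
    p[1 + (i - 1) %% length(p)]
  }, character(1))
  comp <- modifier_compendium(x, data.frame(modifier = mods,
                                            behaviour = unname(beh),
                                            family = family,
                                            stringsAsFactors = FALSE))
  attr(comp, "slow_signature_raw") <- sraw
  comp
}

#' Generate a reference matrix carrying the slow-growth signature
#'
#' A near-rank-1 genes x conditions matrix whose first SVD mode is the
#' shared slow-growth profile, with column norms increasing so the
#' largest-norm column of the rank-1 approximation recovers the profile.
#'
#' @param config A [sim_config()].
#' @param truth The matching `truth_labels`.
#' @param n_conditions Number of reference conditions.
#' @return Numeric matrix genes x conditions.
#' @export
generate_reference <- function(config, truth, n_conditions = 8) {
  sraw <- .slow_signature_raw(config, truth)
  set.seed(.sim_seed(config, 7L))
  s_unit <- sraw / sqrt(sum(sraw^2))
  w <- seq(10, 40, length.out = n_conditions)
  ref <- outer(s_unit, w) +
    matrix(stats::rnorm(length(sraw) * n_conditions, 0, 0.005),
           length(sraw), n_conditions)
  dimnames(ref) <- list(truth$gene_id, sprintf("ref%02d", seq_len(n_conditions)))
  ref
}

#' Generate a promoter-activity table with planted transition classes
#'
#' Builds fractional activities of the form
#' `fPA_i(c) = p_i * (1 + gamma_i * x_c)` with `x_c` the relative deviation
#' of the growth rate from its mean, using mirrored gene pairs so fractions
#' sum exactly to one in every condition.  Planted tiers of `|gamma|`
#' (invariant 0, positive/negative moderate, activated/repressed large)
#' make the transition ranking recover the quotas; a handful of genes sit
#' below the activity floor in every condition.  Raw PA is fractional
#' activity times a condition-dependent total that rises with growth rate.
#'
#' @param config A [sim_config()] (only the seed and `pa_noise_sd` are
#'   used; the PA library has its own canonical size).
#' @param n_genes Number of promoters (default 900).
#' @param growth_rates Increasing growth rates of the conditions.
#' @return Object of class `sim_pa`: list with `pa` (raw activities,
#'   genes x conditions), `growth_rates`, and `truth` (data.frame
#'   `gene_id`, `class`).
#' @export
generate_pa <- function(config,
                        n_genes = 900,
                        growth_rates = c(0.05, 0.09, 0.13, 0.17, 0.21,
                                         0.26, 0.31, 0.37, 0.43, 0.50)) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.sim_seed(config, 4L))
  n_low <- 20L; n_inv <- 350L; n_act <- 50L; n_rep <- 50L
  n_pair <- (n_genes - n_low - n_inv - n_act - n_rep) %/% 2L
  n_use <- n_low + n_inv + n_act + n_rep + 2L * n_pair
  cls <- c(rep("low_activity", n_low), rep("invariant", n_inv),
           rep("activated", n_act), rep("repressed", n_rep),
           rep("positive", n_pair), rep("negative", n_pair))
  genes <- sprintf("p%04d", seq_len(n_use))
  ord <- sample(n_use)                   # interleave classes over ids
  cls <- cls[order(ord)]

  gamma <- numeric(n_use)
  base <- numeric(n_use)
  i_pos <- which(cls == "positive"); i_neg <- which(cls == "negative")
  i_act <- which(cls == "activated"); i_rep <- which(cls == "repressed")
  g_pos <- 0.35 + stats::runif(n_pair, -0.05, 0.05)
  g_act <- 0.65 + stats::runif(n_act, -0.05, 0.05)
  gamma[i_pos] <- g_pos; gamma[i_neg] <- -g_pos
  gamma[i_act] <- g_act; gamma[i_rep] <- -g_act
  # bounded baseline spreads keep every active promoter above the activity
  # floor in all conditions (specific promoters sit lowest: half baseline,
  # narrow spread)
  p_raw <- 10^stats::runif(n_use, -0.6, 0.6)
  p_raw[i_neg] <- p_raw[i_pos]           # mirrored pairs keep sums exact
  p_raw[i_act] <- 0.5 * 10^stats::runif(n_act, -0.15, 0.15)
  p_raw[i_rep] <- p_raw[i_act]
  low <- cls == "low_activity"
  p_raw[low] <- 0
  p <- p_raw / sum(p_raw) * (1 - n_low * 3e-5)
  p[low] <- 3e-5
  gamma[low] <- 0

  x <- (growth_rates - mean(growth_rates)) / mean(growth_rates)
  fpa <- (p %o% rep(1, length(x))) * (1 + gamma %o% x)
  if (config$pa_noise_sd > 0) {
    fpa <- fpa * exp(matrix(stats::rnorm(length(fpa), 0, config$pa_noise_sd),
                            nrow(fpa)))
    fpa <- sweep(fpa, 2, colSums(fpa), "/")
  }
  pa <- sweep(fpa, 2, 5e3 * growth_rates, "*")
  dimnames(pa) <- list(genes, sprintf("cond%02d", seq_along(growth_rates)))
  structure(list(pa = pa, growth_rates = growth_rates,
                 truth = data.frame(gene_id = genes, class = cls,
                                    stringsAsFactors = FALSE)),
            class = "sim_pa")
}

#' Generate per-gene score tracks and annotated gene sets
#'
#' Continuous tracks (nucleosome fragility, cis/trans variability,
#' expression level, expression noise) and binary promoter features (TATA
#' box, TFIID dominance, short nucleosome-free region) with planted
#' sector-dependent enrichments mirroring the patterns the epigenetic
#' analyses are meant to detect, plus stress-response-like gene sets
#' (induced within negative/repressed genes, repressed within positive
#' genes).
#'
#' @param config A [sim_config()].
#' @param truth The matching `truth_labels`.
#' @return List with `continuous` (named numeric vectors), `binary`
#'   (named 0/1 vectors), and `esr` (`induced`/`repressed` gene sets).
#' @export
generate_tracks <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "truth_labels"))
  set.seed(.sim_seed(config, 5L))
  genes <- truth$gene_id
  sec <- truth$sector
  n <- length(genes)
  cont <- list(
    fragility = stats::rnorm(n) + 1.2 * (sec == "positive"),
    trans_variability = stats::rnorm(n) + 1.0 * (sec == "positive"),
    cis_variability = stats::rnorm(n) + 0.5 * (sec == "negative"),
    expression = stats::rnorm(n) + 1.0 * (sec == "positive") +
      0.5 * (sec == "invariant"),
    noise = stats::rnorm(n) - 0.8 * (sec == "positive") +
      0.6 * (sec == "negative"))
  cont <- lapply(cont, function(v) { names(v) <- genes; v })
  p_tata <- ifelse(sec %in% c("negative", "repressed"), 0.35, 0.12)
  p_tfiid <- ifelse(sec %in% c("positive", "invariant"), 0.70,
                    ifelse(sec == "negative", 0.30, 0.40))
  p_shnfr <- ifelse(sec == "positive", 0.60, 0.25)
  bin <- list(tata = stats::rbinom(n, 1, p_tata),
              tfiid = stats::rbinom(n, 1, p_tfiid),
              shnfr = stats::rbinom(n, 1, p_shnfr))
  bin <- lapply(bin, function(v) { names(v) <- genes; v })
  ind_pool <- genes[sec %in% c("negative", "repressed")]
  rep_pool <- genes[sec == "positive"]
  esr <- list(induced = sort(sample(ind_pool, round(0.12 * length(ind_pool)))),
              repressed = sort(sample(rep_pool, round(0.25 * length(rep_pool)))))
  list(continuous = cont, binary = bin, esr = esr)
}

#' Run every generator under one configuration
#'
#' Convenience wrapper producing a fully consistent synthetic study:
#' expression, network (with `regulating_tfs` and `is_coherent_target`
#' folded back into the truth), compendium, reference matrix, PA table and
#' score tracks.
#'
#' @param config A [sim_config()].
#' @return Object of class `sector5_sim` with elements `config`,
#'   `expression`, `truth`, `network`, `compendium`, `reference`, `pa`,
#'   `tracks`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  ex <- generate_expression(config)
  truth <- ex$truth
  net <- generate_network(config, truth)
  truth$regulating_tfs <- split(net$edges$tf, factor(net$edges$target,
                                                     levels = truth$gene_id))
  truth$is_coherent_target <- stats::setNames(
    truth$gene_id %in% net$coherent_targets, truth$gene_id)
  comp <- generate_compendium(config, truth)
  ref <- generate_reference(config, truth)
  pa <- generate_pa(config)
  tracks <- generate_tracks(config, truth)
  structure(list(config = config,
                 expression = ex[c("raw", "fractional", "meta")],
                 truth = truth, network = net, compendium = comp,
                 reference = ref, pa = pa, tracks = tracks),
            class = "sector5_sim")
}
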