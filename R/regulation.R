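# TF-network analyses: regulators per sector, TF self-classification,
# TF-class fractions on targets, regulatory coherence with permutation
# nulls, TF-sector enrichment among coherent genes, and network hierarchy.

#' Construct a regulatory network from a directed edge list
#'
#' @param edges Data.frame (or matrix) with columns `tf`, `target`.
#'   Duplicate edges are dropped (count recorded in attribute
#'   `"n_duplicates"`).
#' @param tfs Optional character vector of TF identifiers; defaults to the
#'   TFs appearing in the edge list.
#' @return Object of class `regulatory_network`: list with `edges`, `tfs`.
#' @export
regulatory_network <- function(edges, tfs = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  stopifnot(all(c("tf", "target") %in% names(edges)))
  edges$tf <- as.character(edges$tf)
  edges$target <- as.character(edges$target)
  key <- paste(edges$tf, edges$target, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) message(sum(dup), " duplicate edge(s) dropped")
  edges <- edges[!dup, c("tf", "target"), drop = FALSE]
  rownames(edges) <- NULL
  if (is.null(tfs)) tfs <- sort(unique(edges$tf)) else
    stopifnot(all(unique(edges$tf) %in% tfs))
  structure(list(edges = edges, tfs = tfs), class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat(sprintf("regulatory_network: %d interactions, %d TFs, %d targets\n",
              nrow(x$edges), length(x$tfs), length(unique(x$edges$target))))
  invisible(x)
}

#' In-degree (number of regulating TFs) per gene
#'
#' @param network A `regulatory_network`.
#' @param genes Gene universe; genes absent from the network count 0.
#' @return Named integer vector over `genes`.
#' @export
regulator_count <- function(network, genes) {
  tab <- table(network$edges$target)
  out <- integer(length(genes))
  names(out) <- genes
  hit <- intersect(genes, names(tab))
  out[hit] <- as.integer(tab[hit])
  out
}

#' Mean number of regulators per sector, with randomization null
#'
#' Computes the mean TF in-degree of the genes in each sector, a z-score
#' against the sector-randomization null, and the pairwise two-sample KS
#' comparisons of the in-degree distributions, plus the coarse group
#' contrasts (specific vs nonspecific; invariant vs nonspecific
#' non-invariant).
#'
#' @param network A `regulatory_network`.
#' @param partition A `sector_partition`.
#' @param n Number of randomizations.
#' @param seed Seed for the null.
#' @return List with `by_sector` (data.frame of [sector_randomization_null()]
#'   summaries), `ks_pairs` (data.frame of pairwise KS results), and
#'   `groups` (specific/nonspecific and invariant/non-invariant means with
#'   KS p-values).
#' @export
regulators_per_sector <- function(network, partition, n = 10000, seed = NULL) {
  indeg <- regulator_count(network, partition$gene_id)
  sect <- partition$sector
  by_sector <- sector_randomization_null(indeg, sect, n = n, seed = seed)

  levs <- intersect(sector_levels(), unique(sect))
  prs <- utils::combn(levs, 2, simplify = FALSE)
  ks_pairs <- do.call(rbind, lapply(prs, function(p) {
    r <- ks_two_sample(indeg[sect == p[1]], indeg[sect == p[2]])
    data.frame(class_a = p[1], class_b = p[2], D = r$D, p = r$p,
               stringsAsFactors = FALSE)
  }))

  specific <- sect %in% c("repressed", "activated")
  noninv_ns <- !specific & sect != "invariant"
  inv <- sect == "invariant"
  g <- function(name, a, b) {
    if (!any(a) || !any(b))
      return(data.frame(comparison = name, mean_a = NA_real_,
                        mean_b = NA_real_, D = NA_real_, p = NA_real_,
                        stringsAsFactors = FALSE))
    r <- ks_two_sample(indeg[a], indeg[b])
    data.frame(comparison = name,
               mean_a = mean(indeg[a]), mean_b = mean(indeg[b]),
               D = r$D, p = r$p, stringsAsFactors = FALSE)
  }
  groups <- rbind(
    g("nonspecific_vs_specific", !specific, specific),
    g("invariant_vs_nonspecific_noninvariant", inv, noninv_ns))
  list(by_sector = by_sector, ks_pairs = ks_pairs, groups = groups)
}

#' Classify the TFs of the network within the partition framework
#'
#' Looks the TF genes up in a fitted [partition_expression()] result and
#' summarizes how the regulators themselves respond to growth: the fraction
#' that is nonspecific, and among nonspecific TFs the fractions invariant in
#' more than half the nutrients, mostly negative, and mostly positive.
#'
#' @param network A `regulatory_network`.
#' @param fit An `svd_partition` object.
#' @return List with `per_tf` (data.frame: nonspecific flag, invariant
#'   nutrient count, positive/negative vote counts, category), `summary`
#'   (fractions over nonspecific TFs), `missing` (TFs without expression),
#'   and `all_condition_invariant` (TFs invariant in every nutrient).
#' @export
classify_tfs <- function(network, fit) {
  part <- fit$partition
  have <- intersect(network$tfs, part$gene_id)
  missing <- setdiff(network$tfs, have)
  if (length(missing))
    message(length(missing), " TF(s) without expression excluded")
  i <- match(have, part$gene_id)
  nsmin <- attr(part, "nonspecific_min")
  invmin <- attr(part, "invariant_min")
  nonspecific <- part$n_nonspecific_pairs[i] >= nsmin
  n_inv <- part$n_invariant_nutrients[i]
  n_pos <- part$n_pos[i]
  n_neg <- part$n_neg[i]
  n_nutr <- ncol(fit$nutrient_classes)
  category <- ifelse(n_inv >= invmin, "invariant",
                     ifelse(n_neg > n_pos, "mostly_negative",
                            ifelse(n_pos > n_neg, "mostly_positive", "tied")))
  per_tf <- data.frame(tf = have, nonspecific = nonspecific,
                       n_invariant_nutrients = n_inv,
                       n_pos = n_pos, n_neg = n_neg, category = category,
                       stringsAsFactors = FALSE)
  ns <- per_tf[per_tf$nonspecific, , drop = FALSE]
  summary <- data.frame(
    n_tfs = length(network$tfs),
    n_with_expression = length(have),
    n_nonspecific = nrow(ns),
    frac_invariant = mean(ns$category == "invariant"),
    frac_mostly_negative = mean(ns$category == "mostly_negative"),
    frac_mostly_positive = mean(ns$category == "mostly_positive"))
  list(per_tf = per_tf, summary = summary, missing = missing,
       all_condition_invariant = have[n_inv == n_nutr])
}

#' Per-target fractions of regulator growth classes
#'
#' For every target gene with at least one classified regulator in a given
#' nutrient, computes the fraction of its regulators behaving as negative,
#' invariant, or positive with growth rate (TF_neg, TF_inv, TF_pos), then
#' aggregates the means by the target's own class and compares, per TF
#' class, the fraction distribution on each target class against all other
#' targets (two-sided KS).
#'
#' @param network A `regulatory_network`.
#' @param nutrient_classes Character matrix genes x nutrients (all-gene
#'   growth classes, see [per_nutrient_allgene_class()]).
#' @param nutrient Column of `nutrient_classes` to use.
#' @return List with `fractions` (per-target data.frame; the three fractions
#'   sum to 1), `class_means` (3 x 3 matrix, target class x TF class), and
#'   `ks_p` (same shape, KS p-values of class-vs-rest contrasts).
#' @export
tf_class_fractions <- function(network, nutrient_classes, nutrient) {
  cls <- nutrient_classes[, nutrient]
  names(cls) <- rownames(nutrient_classes)
  e <- network$edges
  e <- e[e$tf %in% names(cls) & e$target %in% names(cls), , drop = FALSE]
  if (!nrow(e)) stop("no edges with classified TFs and targets")
  tf_cls <- cls[e$tf]
  counts <- table(factor(e$target), factor(tf_cls, levels = c("negative", "invariant", "positive")))
  tot <- rowSums(counts)
  keep <- tot > 0
  fr <- sweep(counts[keep, , drop = FALSE], 1, tot[keep], "/")
  fractions <- data.frame(gene_id = rownames(fr),
                          target_class = unname(cls[rownames(fr)]),
                          n_regulators = as.integer(tot[keep]),
                          TF_neg = fr[, "negative"],
                          TF_inv = fr[, "invariant"],
                          TF_pos = fr[, "positive"],
                          row.names = NULL, stringsAsFactors = FALSE)
  tclasses <- c("negative", "invariant", "positive")
  class_means <- matrix(NA_real_, 3, 3, dimnames = list(target = tclasses, tf = tclasses))
  ks_p <- class_means
  cols <- c(negative = "TF_neg", invariant = "TF_inv", positive = "TF_pos")
  for (tc in tclasses) {
    inx <- fractions$target_class == tc
    for (fc in tclasses) {
      v <- fractions[[cols[fc]]]
      class_means[tc, fc] <- mean(v[inx])
      if (any(inx) && any(!inx))
        ks_p[tc, fc] <- ks_two_sample(v[inx], v[!inx])$p
    }
  }
  list(fractions = fractions, class_means = class_means, ks_p = ks_p)
}

# Row-standardize profiles so that the edge dot product is the Pearson r
# across growth rates.  Constant profiles become NA rows.
.standardize_profiles <- function(x) {
  x <- as.matrix(x)
  mu <- rowMeans(x)
  xc <- x - mu
  s <- sqrt(rowSums(xc^2))
  z <- xc / s
  z[s == 0, ] <- NA_real_
  z
}

#' Regulatory coherence of targets within one nutrient
#'
#' The regulatory coherence of a gene is the mean Pearson correlation,
#' across growth rates within one nutrient, between the gene's expression
#' profile and the profiles of the TFs that regulate it.  Constant profiles
#' have undefined correlation and are excluded; a target with no usable
#' regulator gets `NA`.
#'
#' @param expr Expression (fractional) matrix genes x growth-rate samples
#'   for one nutrient, rownames covering targets and TFs.
#' @param network A `regulatory_network`.
#' @return Data.frame `gene_id`, `n_tfs` (usable regulators), `coherence`.
#' @export
regulatory_coherence <- function(expr, network) {
  if (ncol(expr) < 2L) stop("need at least 2 growth-rate points")
  z <- .standardize_profiles(expr)
  e <- network$edges
  e <- e[e$tf %in% rownames(z) & e$target %in% rownames(z), , drop = FALSE]
  usable <- rowSums(is.na(z)) == 0
  e <- e[usable[e$tf] & usable[e$target], , drop = FALSE]
  targets <- sort(unique(network$edges$target[network$edges$target %in% rownames(z)]))
  r <- rowSums(z[e$target, , drop = FALSE] * z[e$tf, , drop = FALSE])
  s <- rowsum(r, e$target)
  n_tf <- table(e$target)
  coh <- rep(NA_real_, length(targets))
  names(coh) <- targets
  coh[rownames(s)] <- s[, 1] / as.numeric(n_tf[rownames(s)])
  ntf <- integer(length(targets))
  names(ntf) <- targets
  ntf[names(n_tf)] <- as.integer(n_tf)
  data.frame(gene_id = targets, n_tfs = unname(ntf),
             coherence = unname(coh), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Regulatory coherence with a profile-permutation null
#'
#' Recomputes every target's coherence after independently permuting each
#' gene's profile across the growth-rate positions of the nutrient
#' (`mode = "within_gene"`, the default: each gene keeps its value
#' distribution but loses its growth alignment) or after swapping whole
#' profiles between genes (`mode = "across_gene"`).  The observed coherence
#' is standardized against the null sample; genes with `z > 2` (one-sided)
#' are called significantly coherent.
#'
#' @inheritParams regulatory_coherence
#' @param n Number of permutations (default 1000).
#' @param seed Seed.
#' @param mode Null construction, see above.
#' @return Data.frame `gene_id`, `n_tfs`, `coherence`, `null_mean`,
#'   `null_sd`, `z`, `significant`.  Degenerate nulls (`null_sd == 0`) get
#'   the total-z sentinel of [sector_randomization_null()].
#' @export
coherence_null <- function(expr, network, n = 1000, seed = NULL,
                           mode = c("within_gene", "across_gene")) {
  mode <- match.arg(mode)
  obs <- regulatory_coherence(expr, network)
  z <- .standardize_profiles(expr)
  usable <- rowSums(is.na(z)) == 0
  z <- z[usable, , drop = FALSE]
  e <- network$edges
  e <- e[e$tf %in% rownames(z) & e$target %in% rownames(z), , drop = FALSE]
  if (!is.null(seed)) set.seed(seed)
  m <- nrow(z)
  tt <- ncol(z)
  ti <- match(e$target, rownames(z))
  fi <- match(e$tf, rownames(z))
  n_tf <- as.numeric(table(e$target)[sort(unique(e$target))])
  tgt_f <- factor(e$target)
  tgt_levels <- levels(tgt_f)
  sums <- numeric(length(tgt_levels))
  sqs <- numeric(length(tgt_levels))
  zt <- t(z)                      # rates x genes, column-major per gene
  gene_block <- rep(seq_len(m), each = tt)
  for (it in seq_len(n)) {
    if (mode == "within_gene") {
      idx <- order(gene_block, stats::runif(m * tt))
      zp <- matrix(zt[idx], nrow = tt)
    } else {
      zp <- zt[, sample.int(m), drop = FALSE]
    }
    r <- colSums(zp[, ti, drop = FALSE] * zp[, fi, drop = FALSE])
    coh <- rowsum(r, tgt_f) / n_tf
    sums <- sums + coh[, 1]
    sqs <- sqs + coh[, 1]^2
  }
  null_mean <- sums / n
  null_sd <- sqrt(pmax(0, (sqs - n * null_mean^2) / (n - 1)))
  i <- match(obs$gene_id, tgt_levels)
  obs$null_mean <- null_mean[i]
  obs$null_sd <- null_sd[i]
  obs$z <- .safe_z(obs$coherence, obs$null_mean, obs$null_sd)
  obs$significant <- !is.na(obs$z) & obs$z > 2
  obs
}

#' Coherence across all nutrients
#'
#' Runs [coherence_null()] for each nutrient and adds the cross-nutrient
#' aggregate used downstream: a gene counts as coherent when it is
#' significantly coherent in at least one nutrient condition.
#'
#' @param expr Full fractional-expression matrix genes x samples.
#' @param meta Sample metadata (`sample_id`, `nutrient`, `growth_rate`).
#' @param network A `regulatory_network`.
#' @inheritParams coherence_null
#' @return List with `per_nutrient` (long data.frame with a `nutrient`
#'   column) and `coherent_genes` (character vector, significant in >= 1
#'   nutrient).
#' @export
coherence_all <- function(expr, meta, network, n = 1000, seed = NULL,
                          mode = "within_gene") {
  nutrients <- unique(meta$nutrient)
  out <- vector("list", length(nutrients))
  for (k in seq_along(nutrients)) {
    m <- meta[meta$nutrient == nutrients[k], , drop = FALSE]
    m <- m[order(m$growth_rate), , drop = FALSE]
    res <- coherence_null(expr[, m$sample_id, drop = FALSE], network,
                          n = n,
                          seed = if (is.null(seed)) NULL else seed + k,
                          mode = mode)
    res$nutrient <- nutrients[k]
    out[[k]] <- res
  }
  per_nutrient <- do.call(rbind, out)
  coherent <- sort(unique(per_nutrient$gene_id[per_nutrient$significant]))
  list(per_nutrient = per_nutrient, coherent_genes = coherent)
}

#' TF-by-sector enrichment among coherent genes
#'
#' For each TF, the proportions of its significantly coherent targets that
#' fall in each of the five sectors are compared, per sector, against a
#' null obtained by randomizing the partition labels (preserving sector
#' sizes).  Positive z denotes enrichment, negative depletion.  TFs with no
#' coherent target get a row of zeros (sentinel) and are listed in the
#' `"no_coherent_targets"` attribute.
#'
#' @param coherent_genes Character vector of significantly coherent genes.
#' @param network A `regulatory_network`.
#' @param partition A `sector_partition`.
#' @param n Number of randomizations (default 10000).
#' @param seed Seed.
#' @return Numeric matrix TFs x sectors of z-scores.
#' @export
tf_sector_enrichment <- function(coherent_genes, network, partition,
                                 n = 10000, seed = NULL) {
  levs <- sector_levels()
  lab <- factor(partition$sector, levels = levs)
  genes <- partition$gene_id
  e <- network$edges
  e <- e[e$target %in% intersect(coherent_genes, genes), , drop = FALSE]
  tfs <- network$tfs
  zmat <- matrix(0, length(tfs), length(levs), dimnames = list(tfs, levs))
  if (!nrow(e)) {
    attr(zmat, "no_coherent_targets") <- tfs
    return(zmat)
  }
  tf_i <- match(e$tf, tfs)
  g_i <- match(e$target, genes)
  ntf <- length(tfs)
  tot <- tabulate(tf_i, ntf)
  cell <- function(lab_vec) {
    li <- as.integer(lab_vec)[g_i]
    cnt <- matrix(tabulate(tf_i + ntf * (li - 1L), ntf * length(levs)),
                  nrow = ntf)
    cnt / ifelse(tot == 0, 1, tot)
  }
  obs <- cell(lab)
  if (!is.null(seed)) set.seed(seed)
  s1 <- matrix(0, ntf, length(levs))
  s2 <- matrix(0, ntf, length(levs))
  for (it in seq_len(n)) {
    p <- cell(lab[sample.int(length(lab))])
    s1 <- s1 + p
    s2 <- s2 + p^2
  }
  mu <- s1 / n
  sdv <- sqrt(pmax(0, (s2 - n * mu^2) / (n - 1)))
  z <- .safe_z(obs, mu, sdv)
  z[tot == 0, ] <- 0
  dimnames(z) <- dimnames(zmat)
  attr(z, "no_coherent_targets") <- tfs[tot == 0]
  attr(z, "observed_proportions") <- obs
  z
}

#' Vertex-sort hierarchy of a directed network
#'
#' Condenses the strongly connected components of the graph, then
#' iteratively strips sink components: the first stripped layer is level 1
#' (bottom), and the last remaining layer is the top.  Nodes of one
#' strongly connected component share a level, and every edge between
#' distinct levels points downwards (from a higher to a lower level).
#'
#' @param network A `regulatory_network`, or a data.frame of `tf`/`target`
#'   edges.
#' @param nodes Optional additional isolated nodes to include.
#' @return Data.frame `node`, `component`, `level` (integer, 1 = bottom).
#'   Empty input yields an empty data.frame.
#' @export
network_hierarchy <- function(network, nodes = NULL) {
  edges <- if (inherits(network, "regulatory_network")) network$edges else
    as.data.frame(network, stringsAsFactors = FALSE)
  verts <- unique(c(edges$tf, edges$target, nodes))
  if (length(verts) == 0L)
    return(data.frame(node = character(0), component = integer(0),
                      level = integer(0), stringsAsFactors = FALSE))
  g <- igraph::graph_from_data_frame(
    edges[, c("tf", "target"), drop = FALSE], directed = TRUE,
    vertices = data.frame(name = verts))
  comp <- igraph::components(g, mode = "strong")$membership
  # condensation: one vertex per strongly connected component
  ce <- unique(data.frame(from = comp[edges$tf], to = comp[edges$target]))
  ce <- ce[ce$from != ce$to, , drop = FALSE]
  ncomp <- max(comp)
  level <- integer(ncomp)
  alive <- rep(TRUE, ncomp)
  lev <- 0L
  while (any(alive)) {
    lev <- lev + 1L
    act <- ce[alive[ce$from] & alive[ce$to], , drop = FALSE]
    sinks <- alive & !(seq_len(ncomp) %in% act$from)
    if (!any(sinks)) sinks <- alive   # safety; cannot occur in a DAG
    level[sinks] <- lev
    alive[sinks] <- FALSE
  }
  data.frame(node = verts, component = unname(comp[verts]),
             level = unname(level[comp[verts]]),
             row.names = NULL, stringsAsFactors = FALSE)
}
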