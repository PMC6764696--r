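# Epigenetic analyses: feature enrichments, modifier effects, slow-growth
# signature removal, ESR overlaps.

mk_partition <- function(genes, sectors) {
  structure(data.frame(gene_id = genes, sector = sectors,
                       stringsAsFactors = FALSE),
            nonspecific_min = 9, invariant_min = 4,
            class = c("sector_partition", "data.frame"))
}

test_that("GTF fraction is the regulator-share of the general factors", {
  part <- mk_partition(c("g1", "g2", "g3"),
                       c("positive", "negative", "invariant"))
  edges <- rbind(data.frame(tf = c("Rap1", "X", "Y", "Z"), target = "g1"),
                 data.frame(tf = c("Rap1", "Abf1"), target = "g2"),
                 data.frame(tf = "Q", target = "g3"))
  net <- regulatory_network(edges)
  res <- gtf_fraction(net, part, gtf_set = c("Rap1", "Abf1", "Reb1"),
                      n = 50, seed = 1)
  expect_equal(unname(res$per_gene[c("g1", "g2", "g3")]), c(0.25, 1, 0))
  expect_error(gtf_fraction(net, part, gtf_set = character(0)), "empty")
})

test_that("sector score summaries reuse the randomization engine correctly", {
  genes <- sprintf("g%02d", 1:10)
  part <- mk_partition(genes, rep(c("positive", "negative"), each = 5))
  const <- setNames(rep(1, 10), genes)
  res <- sector_score_summary(const, part, n = 50, seed = 1)
  expect_equal(res$z, c(0, 0))
  ind <- setNames(c(rep(1, 5), rep(0, 5)), genes)
  res2 <- sector_score_summary(ind, part, n = 2000, seed = 2)
  zpos <- res2$z[res2$class == "positive"]
  expect_true(zpos > 2 || is.infinite(zpos))
  # z agrees with the exhaustive oracle on the same statistic
  zex <- sector_randomization_null(ind, part$sector, exact = TRUE)
  zo <- oracle_exact_null_z(unname(ind), part$sector)
  expect_equal(zex$z, unname(zo[zex$class]), tolerance = 1e-12)
})

test_that("binary feature enrichment accepts gene sets and flags membership", {
  genes <- sprintf("g%02d", 1:12)
  part <- mk_partition(genes, rep(c("positive", "negative", "invariant"), 4))
  all_on <- setNames(rep(1, 12), genes)
  expect_equal(binary_feature_enrichment(all_on, part, n = 50, seed = 1)$z,
               rep(0, 3))
  members <- genes[part$sector == "positive"]
  res <- binary_feature_enrichment(members, part, n = 500, seed = 3)
  expect_true(all(res$observed[res$class == "positive"] == 1))
  expect_true(res$z[res$class == "positive"] > 2 ||
                is.infinite(res$z[res$class == "positive"]))
  expect_equal(binary_feature_enrichment(character(0), part, n = 20,
                                         seed = 1)$z, rep(0, 3))
  expect_error(binary_feature_enrichment(setNames(c(1, 2, rep(0, 10)), genes),
                                         part), "0/1")
})

test_that("compendium normalization is unit-variance, idempotent, mean-preserving", {
  x <- rbind(m1 = rnorm(50, 1, 2), m2 = rnorm(50, -1, 1))
  comp <- modifier_compendium(x, data.frame(modifier = c("m1", "m2"),
                                            family = c("HAT", "HDAC")))
  nc <- normalize_compendium(comp)
  expect_equal(unname(apply(nc$profiles, 1, sd)), c(1, 1))
  expect_equal(unname(nc$profiles[1, ]), unname(x[1, ] / sd(x[1, ])))
  nc2 <- normalize_compendium(nc)
  expect_equal(nc$profiles, nc2$profiles)
  x0 <- rbind(x, m3 = rep(2, 50))
  comp0 <- modifier_compendium(x0, data.frame(modifier = c("m1", "m2", "m3"),
                                              family = c("HAT", "HDAC", "other")))
  expect_warning(n0 <- normalize_compendium(comp0), "zero-variance")
  expect_equal(nrow(n0$profiles), 2)
})

test_that("CRE strength contrasts specific vs nonspecific genes", {
  # enough specific genes for the group contrast to have power
  cfg <- sim_config(n_genes = 3000, n_tfs = 50, noise_sd = 0.02, seed = 301)
  sim <- simulate_dataset(cfg)
  fit <- partition_expression(sim$expression$raw, sim$expression$meta,
                              n_invariant = sum(sim$truth$sector == "invariant"))
  comp <- normalize_compendium(sim$compendium)
  res <- cre_strength(comp, fit$partition, n = 300, seed = 4)
  # the generator plants larger-magnitude effects on specific genes
  expect_gt(mean(res$stronger_in_specific), 0.9)
  expect_gt(mean(res$mean_specific > res$mean_nonspecific), 0.99)
  # sign flips do not change strength
  comp2 <- comp
  comp2$profiles <- -comp2$profiles
  res2 <- cre_strength(comp2, fit$partition, n = 300, seed = 4)
  expect_equal(res2$mean_specific, res$mean_specific)
})

test_that("signed effects classify planted modifier behaviours", {
  sim <- small_sim()
  fit <- small_fit()
  comp <- normalize_compendium(sim$compendium)
  res <- modifier_signed_effects(comp, fit$partition, n = 400, seed = 6)
  conf <- table(planted = sim$compendium$mutants$behaviour,
                called = res$classification$class)
  acc <- mean(res$classification$class == sim$compendium$mutants$behaviour)
  expect_gt(acc, 0.9)
  # pure-noise compendium: almost everything unclassified
  cfg0 <- small_config(modifier_effect = 0, seed = 202)
  sim0 <- simulate_dataset(cfg0)
  comp0 <- normalize_compendium(sim0$compendium)
  res0 <- modifier_signed_effects(comp0, fit$partition, n = 1500, seed = 6)
  expect_lte(mean(res0$classification$class != "unclassified"), 0.05)
})

test_that("the quantile band behaves like the SD band on Gaussian nulls", {
  sim <- small_sim()
  fit <- small_fit()
  comp <- normalize_compendium(sim$compendium)
  rsd <- modifier_signed_effects(comp, fit$partition, n = 600, seed = 8)
  rq <- modifier_signed_effects(comp, fit$partition, n = 600, seed = 8,
                                band = "quantile")
  agree <- mean(rsd$classification$class == rq$classification$class)
  expect_gt(agree, 0.9)
})

test_that("slow-growth signature equals the dominant mode of the reference", {
  # exact rank-1 input
  u <- rnorm(30)
  w <- c(1, 3, 2)
  m <- outer(u, w)
  rownames(m) <- sprintf("g%02d", 1:30)
  sig <- slow_growth_signature(m)
  expect_equal(abs(cor(sig$signature, u)), 1, tolerance = 1e-12)
  expect_equal(sqrt(sum(sig$signature^2)), 1)
  expect_equal(sig$norm, sqrt(sum((u * 3)^2)))
  # the chosen column has the largest norm: its sign is preserved
  expect_gt(cor(sig$signature, u * sign(1)), 0.99)
  # adding a zero column changes nothing
  sig2 <- slow_growth_signature(cbind(m, 0))
  expect_equal(sig2$signature, sig$signature)
  # power-iteration oracle on a random matrix
  set.seed(10)
  m2 <- matrix(rnorm(100), 20, 5, dimnames = list(sprintf("g%02d", 1:20), NULL))
  sig3 <- slow_growth_signature(m2)
  po <- oracle_power_iteration(m2)
  expect_equal(abs(sum(sig3$signature * po)), 1, tolerance = 1e-8)
  expect_error(slow_growth_signature(matrix(0, 3, 3)), "degenerate")
})

test_that("signature removal is an exact orthogonal projection", {
  genes <- sprintf("g%02d", 1:40)
  s <- rnorm(40)
  s <- setNames(s / sqrt(sum(s^2)), genes)
  x <- rbind(pure = 3 * s,
             orth = {v <- rnorm(40); v - sum(v * s) * s},
             mixed = rnorm(40))
  colnames(x) <- genes
  comp <- modifier_compendium(x, data.frame(modifier = rownames(x),
                                            family = "other"))
  out <- remove_slow_growth(comp, s)
  expect_equal(max(abs(out$profiles["pure", ])), 0, tolerance = 1e-12)
  expect_equal(out$profiles["orth", ], x["orth", ], tolerance = 1e-12)
  expect_true(max(abs(out$profiles %*% s)) < 1e-10)
  # idempotence
  out2 <- remove_slow_growth(out, s)
  expect_equal(out2$profiles, out$profiles, tolerance = 1e-12)
})

test_that("ESR overlaps count exactly and carry Holm-adjusted enrichment", {
  genes <- sprintf("g%02d", 1:10)
  part <- mk_partition(genes, c(rep("negative", 4), rep("positive", 4),
                                rep("invariant", 2)))
  res <- esr_overlap(esr_induced = genes[1:4], esr_repressed = "g99", part)
  ind <- res[res$esr_set == "induced", ]
  expect_equal(ind$overlap[ind$sector == "negative"], 4)
  expect_equal(ind$overlap[ind$sector == "positive"], 0)
  # the full-sector overlap is the minimal-p cell
  expect_equal(which.min(ind$p), which(ind$sector == "negative"))
  rep_ <- res[res$esr_set == "repressed", ]
  expect_true(all(rep_$overlap == 0))
  expect_true(all(rep_$p == 1))
  expect_true(all(res$p_holm >= res$p))
  # hand enumeration: hypergeometric p for the negative/induced cell
  expect_equal(ind$p[ind$sector == "negative"],
               choose(4, 4) * choose(6, 0) / choose(10, 4))
})
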