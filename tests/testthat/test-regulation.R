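# TF-network integration: regulators per sector, coherence, enrichment,
# hierarchy.

test_that("network container deduplicates edges and keeps isolated TFs", {
  net <- suppressMessages(regulatory_network(
    data.frame(tf = c("T1", "T1", "T2"), target = c("a", "a", "b")),
    tfs = c("T1", "T2", "T3")))
  expect_equal(nrow(net$edges), 2)
  expect_true("T3" %in% net$tfs)   # out-degree 0 allowed
  expect_equal(regulator_count(net, c("a", "b", "c")),
               c(a = 1L, b = 1L, c = 0L))
})

test_that("regulators per sector: uniform in-degree gives flat means, z = 0", {
  genes <- sprintf("g%02d", 1:30)
  part <- structure(
    data.frame(gene_id = genes,
               sector = rep(c("negative", "invariant", "positive"), 10),
               stringsAsFactors = FALSE),
    nonspecific_min = 9, invariant_min = 4,
    class = c("sector_partition", "data.frame"))
  edges <- data.frame(tf = rep(c("T1", "T2", "T3"), 30),
                      target = rep(genes, each = 3))
  net <- regulatory_network(edges)
  res <- regulators_per_sector(net, part, n = 100, seed = 1)
  expect_equal(res$by_sector$observed, rep(3, 3))
  expect_equal(res$by_sector$z, rep(0, 3))
})

test_that("planted in-degree gradient is detected", {
  sim <- small_sim()
  fit <- small_fit()
  res <- regulators_per_sector(sim$network, fit$partition, n = 500, seed = 2)
  g <- res$groups
  expect_gt(g$mean_b[g$comparison == "nonspecific_vs_specific"],
            g$mean_a[g$comparison == "nonspecific_vs_specific"])
  expect_lt(g$mean_a[g$comparison == "invariant_vs_nonspecific_noninvariant"],
            g$mean_b[g$comparison == "invariant_vs_nonspecific_noninvariant"])
  expect_lt(g$p[g$comparison == "nonspecific_vs_specific"], 0.05)
})

test_that("TF self-classification mirrors the planted growth classes", {
  sim <- small_sim()
  fit <- small_fit()
  res <- classify_tfs(sim$network, fit)
  expect_equal(res$summary$n_with_expression, length(sim$network$tfs))
  per <- res$per_tf
  planted <- sim$truth$sector[per$tf]
  expect_true(all(per$category[planted == "invariant"] == "invariant"))
  expect_true(all(per$category[planted == "positive"] == "mostly_positive"))
  # invariant TFs in all six nutrients are reported
  expect_setequal(res$all_condition_invariant,
                  per$tf[per$n_invariant_nutrients == 6])
  # a TF absent from the expression table is excluded but counted
  net2 <- sim$network
  net2$tfs <- c(net2$tfs, "ghost")
  res2 <- suppressMessages(classify_tfs(net2, fit))
  expect_equal(res2$missing, "ghost")
})

test_that("per-target TF-class fractions sum to one and show diagonal dominance", {
  cls <- matrix(c("negative", "negative", "positive", "invariant"), 4, 1,
                dimnames = list(c("T1", "T2", "T3", "t"), "glucose"))
  net <- regulatory_network(data.frame(tf = c("T1", "T2", "T3"),
                                       target = c("t", "t", "t")))
  res <- tf_class_fractions(net, cls, "glucose")
  expect_equal(res$fractions$TF_neg, 2 / 3)
  expect_equal(res$fractions$TF_inv, 0)
  expect_equal(res$fractions$TF_pos, 1 / 3)
  # planted coherent network: same-class TFs dominate each target class
  cfgc <- sim_config(n_genes = 700, n_tfs = 80, coherent_fraction = 1,
                     noise_sd = 0.02, seed = 55)
  simc <- simulate_dataset(cfgc)
  fitc <- partition_expression(simc$expression$raw, simc$expression$meta,
                               n_invariant = sum(simc$truth$sector == "invariant"))
  ninv <- sum(simc$truth$sector == "invariant")
  allcls <- per_nutrient_allgene_class(fitc$svd, n_invariant = ninv)
  resc <- tf_class_fractions(simc$network, allcls, "glucose")
  expect_true(all(rowSums(resc$fractions[, c("TF_neg", "TF_inv", "TF_pos")]) - 1
                  < 1e-12))
  cm <- resc$class_means
  expect_gt(cm["negative", "negative"], cm["positive", "negative"])
  expect_gt(cm["positive", "positive"], cm["negative", "positive"])
})

test_that("regulatory coherence is the mean Pearson r over usable regulators", {
  expr <- rbind(t1 = c(1, 2, 3, 4),
                T_same = c(2, 4, 6, 8),
                T_rev = c(4, 3, 2, 1),
                T_flat = c(5, 5, 5, 5))
  net1 <- regulatory_network(data.frame(tf = "T_same", target = "t1"))
  expect_equal(regulatory_coherence(expr, net1)$coherence, 1)
  net2 <- regulatory_network(data.frame(tf = c("T_same", "T_rev"),
                                        target = c("t1", "t1")))
  expect_equal(regulatory_coherence(expr, net2)$coherence, 0)
  # longhand Pearson oracle on irregular profiles
  set.seed(6)
  prof <- matrix(rnorm(16), 4, 4,
                 dimnames = list(c("t", "A", "B", "C"), NULL))
  net3 <- regulatory_network(data.frame(tf = c("A", "B", "C"),
                                        target = c("t", "t", "t")))
  want <- mean(c(oracle_pearson(prof["t", ], prof["A", ]),
                 oracle_pearson(prof["t", ], prof["B", ]),
                 oracle_pearson(prof["t", ], prof["C", ])))
  expect_equal(regulatory_coherence(prof, net3)$coherence, want)
  # constant profiles are excluded from the mean
  net4 <- regulatory_network(data.frame(tf = c("T_same", "T_flat"),
                                        target = c("t1", "t1")))
  res4 <- regulatory_coherence(expr, net4)
  expect_equal(res4$coherence, 1)
  expect_equal(res4$n_tfs, 1)
})

test_that("coherence null flags planted targets and is seed-stable", {
  sim <- small_sim()
  m <- sim$expression$meta
  m1 <- m[m$nutrient == "glucose", ]
  expr <- sim$expression$fractional[, m1$sample_id]
  r1 <- coherence_null(expr, sim$network, n = 300, seed = 5)
  r2 <- coherence_null(expr, sim$network, n = 300, seed = 5)
  expect_identical(r1, r2)
  planted <- intersect(sim$network$coherent_targets, r1$gene_id)
  sens <- mean(r1$significant[match(planted, r1$gene_id)])
  expect_gt(sens, 0.9)
  expect_true(all(r1$significant == (!is.na(r1$z) & r1$z > 2)))
})

test_that("TF-sector enrichment highlights planted structure and calibrates", {
  sim <- small_sim()
  fit <- small_fit()
  part <- fit$partition
  # a TF acting only on coherent positive-sector genes
  pos <- part$gene_id[part$sector == "positive"][1:10]
  edges <- rbind(data.frame(tf = "TFpos", target = pos),
                 data.frame(tf = "TFmix",
                            target = part$gene_id[seq(1, 200, by = 10)]))
  net <- regulatory_network(edges)
  z <- tf_sector_enrichment(c(pos, part$gene_id[seq(1, 200, by = 10)]),
                            net, part, n = 500, seed = 3)
  expect_gt(z["TFpos", "positive"], 2)
  expect_lt(z["TFpos", "negative"], 0)
  # empty coherent set: all-zero sentinel
  z0 <- tf_sector_enrichment(character(0), net, part, n = 10, seed = 1)
  expect_true(all(z0 == 0))
  expect_setequal(attr(z0, "no_coherent_targets"), c("TFpos", "TFmix"))
  # label-shuffled input: few cells beyond the 2-SD band
  set.seed(9)
  shuf <- part
  shuf$sector <- sample(shuf$sector)
  zs <- tf_sector_enrichment(sample(part$gene_id, 150), sim$network, shuf,
                             n = 400, seed = 11)
  zf <- zs[is.finite(zs)]
  expect_gt(mean(abs(zf) < 2), 0.9)
})

test_that("vertex-sort hierarchy levels condense cycles and point downward", {
  h <- network_hierarchy(data.frame(tf = c("A", "B"), target = c("B", "C")))
  expect_equal(h$level[match(c("A", "B", "C"), h$node)], c(3, 2, 1))
  # 2-cycle above a sink: two levels, the cycle shares one
  h2 <- network_hierarchy(data.frame(tf = c("A", "B", "A"),
                                     target = c("B", "A", "C")))
  expect_equal(h2$level[match(c("A", "B", "C"), h2$node)], c(2, 2, 1))
  expect_equal(h2$component[h2$node == "A"], h2$component[h2$node == "B"])
  # edgeless graph: every node at the single level
  h3 <- network_hierarchy(data.frame(tf = character(0), target = character(0)),
                          nodes = c("x", "y"))
  expect_equal(h3$level, c(1, 1))
  expect_equal(nrow(network_hierarchy(data.frame(tf = character(0),
                                                 target = character(0)))), 0)
  # property: edges never point upward across components
  set.seed(14)
  for (i in 1:10) {
    nn <- sample(4:8, 1)
    e <- unique(data.frame(tf = sample(LETTERS[1:nn], 12, TRUE),
                           target = sample(LETTERS[1:nn], 12, TRUE)))
    e <- e[e$tf != e$target | TRUE, ]
    h <- network_hierarchy(e)
    lv <- setNames(h$level, h$node)
    cp <- setNames(h$component, h$node)
    same <- cp[e$tf] == cp[e$target]
    expect_true(all(lv[e$tf][!same] > lv[e$target][!same]))
    expect_true(all(lv[e$tf][same] == lv[e$target][same]))
  }
})
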