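test_that("group mean SEP pools genes x accessions with t intervals", {
  pd <- sim_planted()
  genes <- valid_genes(pd$profiles)[1:14]
  gm <- group_mean_sep(pd$profiles, genes, "D")
  expect_equal(gm$n, rep(84, 7))  # 14 genes x 6 D accessions
  expect_equal(mean(gm$mean), 0, tolerance = 1e-12)
  expect_true(all(gm$lower <= gm$mean & gm$mean <= gm$upper))
  # averaging contracts the norm: population sd of the mean curve <= 1
  expect_lte(sqrt(mean(gm$mean^2)), 1 + 1e-12)

  gw <- group_mean_sep(pd$profiles, genes, "W")
  expect_equal(gw$n, rep(56, 7))
  expect_error(group_mean_sep(pd$profiles, character(0), "D"), "empty")
})

test_that("a single pooled profile has no confidence interval", {
  toy_design <- data.frame(
    library = paste0("L", 1:8),
    accession = rep(c("A", "B"), each = 4),
    group = c(rep("D", 4), rep("W", 4)),
    time = rep(c(0, 0, 10, 10), 2),
    replicate = rep(1:2, 4), stringsAsFactors = FALSE)
  counts <- matrix(rpois(16, 50) + 1L, 2, 8,
                   dimnames = list(c("g1", "g2"), toy_design$library))
  prof <- compute_profiles(counts, toy_design)
  expect_warning(gm <- group_mean_sep(prof, "g1", "D"), "single profile")
  expect_true(all(is.na(gm$lower)))
  expect_equal(gm$mean, unname(prof$sep["g1", , "A"]))
})

test_that("pointwise group tests behave under identity and label swap", {
  pd <- sim_planted()
  gene <- valid_genes(pd$profiles)[1]
  res <- pointwise_group_test(pd$profiles, gene)
  expect_equal(nrow(res), 7)

  # swapping group labels flips the t sign and keeps the p-value
  swapped <- pd$profiles
  swapped$accessions$group <- ifelse(swapped$accessions$group == "D",
                                     "W", "D")
  res2 <- pointwise_group_test(swapped, gene)
  expect_equal(res2$statistic, -res$statistic, tolerance = 1e-12)
  expect_equal(res2$p, res$p, tolerance = 1e-12)

  # identical standardized values in both groups: t = 0, p = 1
  ident <- pd$profiles
  ident$sep[gene, , ] <- matrix(rep(standardize_profile(1:7), 10), 7, 10)
  res3 <- pointwise_group_test(ident, gene)
  expect_equal(res3$statistic, rep(0, 7))
  expect_equal(res3$p, rep(1, 7))
})

test_that("a planted one-time group offset is found by the pointwise test", {
  pd <- sim_planted()
  shift <- intersect(pd$truth$table$gene[pd$truth$table$archetype ==
                                           "shift"],
                     valid_genes(pd$profiles))
  min_p <- vapply(shift, function(g) {
    min(pointwise_group_test(pd$profiles, g)$p)
  }, numeric(1))
  expect_gte(mean(min_p < 0.01), 0.9)
})

test_that("vectorised Welch matches stats::t.test", {
  set.seed(7)
  x <- matrix(rnorm(60), 10, 6)
  y <- matrix(rnorm(40, sd = 2), 10, 4)
  ours <- septime:::.welch_rows(x, y)
  for (i in 1:10) {
    ref <- stats::t.test(x[i, ], y[i, ])
    expect_equal(ours$statistic[i], unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$p[i], ref$p.value, tolerance = 1e-12)
    expect_equal(ours$df[i], unname(ref$parameter), tolerance = 1e-12)
    expect_equal(c(ours$lower[i], ours$upper[i]),
                 as.numeric(ref$conf.int), tolerance = 1e-12)
  }
})

test_that("divergence classification is FDR-calibrated and sensitive", {
  nd <- sim_null()
  div_null <- classify_divergence(nd$profiles, fdr = 0.01)
  n <- nrow(div_null$calls)
  expect_lte(mean(div_null$calls$call == "distinct"),
             0.01 + 3 * sqrt(0.01 * 0.99 / n))

  pd <- sim_planted()
  div <- classify_divergence(pd$profiles, fdr = 0.01)
  planted <- pd$truth$table$gene[pd$truth$table$archetype == "d10w30"]
  planted <- intersect(planted, div$calls$gene)
  hits <- div$calls$call[div$calls$gene %in% planted] == "distinct"
  expect_gte(mean(hits), 0.95)

  # realized per-test cutoff is below the FDR level, and q is monotone in p
  expect_lte(div$p_cutoff, 0.01)
  ord <- order(div$p)
  expect_true(all(diff(div$q[ord]) >= -1e-15))

  # fdr = 0 calls nothing
  div0 <- classify_divergence(pd$profiles, fdr = 0)
  expect_equal(sum(div0$calls$call == "distinct"), 0)
})

test_that("accession distances are metric-like and split the groups", {
  pd <- sim_planted()
  ad <- accession_distance_matrix(pd$profiles)
  expect_equal(ad$dist, t(ad$dist))
  expect_true(all(diag(ad$dist) == 0))

  # gene order and accession relabeling do not change the distances
  g <- valid_genes(pd$profiles)
  ad2 <- accession_distance_matrix(pd$profiles, genes = rev(g))
  expect_equal(ad$dist, ad2$dist, tolerance = 1e-12)

  # planted D/W divergence: the top split separates D from W
  top <- stats::cutree(ad$hclust, k = 2)
  grp <- pd$profiles$accessions$group[match(names(top),
                                            pd$profiles$accessions$accession)]
  expect_equal(length(unique(top[grp == "D"])), 1)
  expect_equal(length(unique(top[grp == "W"])), 1)
  expect_false(top[grp == "D"][1] == top[grp == "W"][1])

  # two accessions with identical counts are at distance 0, merged first
  design <- pd$design[pd$design$accession %in% c("D1", "D2", "W1", "W2"), ]
  counts <- pd$counts[1:50, design$library]
  counts[, design$accession == "D2"] <- counts[, design$accession == "D1"]
  prof <- compute_profiles(counts, design)
  ad3 <- accession_distance_matrix(prof)
  expect_equal(ad3$dist["D1", "D2"], 0)
  expect_setequal(ad3$hclust$labels[abs(ad3$hclust$merge[1, ])],
                  c("D1", "D2"))

  # newick export round-trips the topology
  path <- withr::local_tempfile(fileext = ".nwk")
  write_dendrogram(ad, path)
  tree <- ape::read.tree(path)
  expect_setequal(tree$tip.label, pd$profiles$accessions$accession)
})

test_that("between-group distances exceed within-group ones when planted", {
  pd <- sim_planted()
  res <- distance_group_test(pd$profiles)
  expect_gt(res$mean_between, res$mean_within)
  expect_lt(res$p, 1e-6)

  # under the null the two pools are indistinguishable
  nd <- sim_null()
  res0 <- distance_group_test(nd$profiles)
  expect_lt(abs(res0$mean_between / res0$mean_within - 1), 0.01)
  expect_gt(res0$p, 0.001)

  # single accession per group: the within pool is empty
  sub <- pd$design[pd$design$accession %in% c("D1", "W1"), ]
  prof <- compute_profiles(pd$counts[1:50, sub$library], sub)
  expect_error(distance_group_test(prof), "at least 2 accessions")
})

test_that("peak-time summaries recover the planted -20 DAA lag", {
  pd <- sim_planted()
  planted <- intersect(
    pd$truth$table$gene[pd$truth$table$archetype == "d10w30"],
    valid_genes(pd$profiles))
  pk <- peak_time_summary(pd$profiles, planted)
  expect_true(all(pk$per_gene$peak_time %in% pd$profiles$times))
  expect_lt(abs(pk$difference - (-20)), 2)
  expect_lt(abs(pk$mean_d - 10), 2)
  expect_lt(abs(pk$mean_w - 30), 2)
})

test_that("argmax ties break toward the earlier time", {
  pd <- sim_planted()
  prof <- pd$profiles
  g <- valid_genes(prof)[1]
  tied <- standardize_profile(c(1, 5, 1, 5, 1, 1, 1))
  for (a in seq_len(nrow(prof$accessions))) prof$sep[g, , a] <- tied
  pk <- peak_time_summary(prof, g)
  expect_true(all(pk$per_gene$peak_time == 10))
})

test_that("diversity test detects wider wild-group spread", {
  # W group simulated with doubled between-accession spread: scale each W
  # accession's expression by an accession-specific factor
  # gene-level accession random effects, twice the log-sd in W than in D
  nd <- sim_null()
  counts <- nd$counts
  set.seed(1)
  accs <- unique(nd$design$accession)
  for (a in accs) {
    sd_a <- if (grepl("^W", a)) 0.6 else 0.05
    fac <- exp(stats::rnorm(nrow(counts), 0, sd_a))
    libs <- nd$design$library[nd$design$accession == a]
    counts[, libs] <- round(counts[, libs] * fac)
  }
  res <- diversity_test(normalize_cpm(counts), nd$design)
  expect_equal(res$direction, "D < W")
  expect_lt(res$p, 0.01)

  # identical groups: no systematic CV difference
  res0 <- diversity_test(normalize_cpm(nd$counts), nd$design)
  expect_lt(abs(res0$mean_log_ratio), 0.1)
})
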