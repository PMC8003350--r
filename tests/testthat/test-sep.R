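toy_counts <- function() {
  design <- data.frame(
    library = paste0("L", 1:8),
    accession = rep(c("A", "B"), each = 4),
    group = rep(c("D", "W"), each = 4),
    time = rep(c(0, 0, 10, 10), 2),
    replicate = rep(c(1, 2), 4),
    stringsAsFactors = FALSE
  )
  counts <- rbind(
    g1 = c(4, 6, 10, 14, 3, 5, 7, 9),
    g2 = c(0, 0, 0, 0, 1, 2, 3, 4),   # silent in accession A
    g3 = c(5, 0, 0, 7, 2, 0, 3, 0)    # exactly 2 positives per accession
  )
  colnames(counts) <- design$library
  list(counts = counts, design = design)
}

test_that("consistent-expression filter keeps and drops the right genes", {
  toy <- toy_counts()
  flt <- filter_consistent_genes(toy$counts, toy$design, min_positive = 2)
  expect_setequal(flt$keep, c("g1", "g3"))
  expect_equal(flt$dropped$gene, "g2")
  expect_equal(flt$dropped$accession, "A")
  expect_equal(flt$dropped$n_positive, 0)

  # boundary: raising the threshold drops the 2-positive gene too
  flt3 <- filter_consistent_genes(toy$counts, toy$design, min_positive = 3)
  expect_setequal(flt3$keep, "g1")
})

test_that("CPM normalization rescales columns to one million", {
  m <- matrix(c(1, 9, 2, 18), 2, 2, dimnames = list(c("a", "b"),
                                                    c("l1", "l2")))
  cpm <- normalize_cpm(m)
  expect_equal(unname(cpm[1, ]), c(1e5, 1e5))
  expect_equal(unname(colSums(cpm)), c(1e6, 1e6), tolerance = 1e-9)

  # scaling one library's counts uniformly leaves its CPM column unchanged
  m2 <- m
  m2[, 2] <- m2[, 2] * 7
  expect_equal(normalize_cpm(m2)[, 2], cpm[, 2])

  m3 <- m
  m3[, 1] <- 0
  expect_error(normalize_cpm(m3), "l1")
})

test_that("profile means average replicates per accession and time", {
  toy <- toy_counts()
  cpm <- normalize_cpm(toy$counts)
  pm <- profile_means(cpm, toy$design)
  expect_equal(dim(pm), c(3, 2, 2))
  # brute-force check over every cell of the 2x2 design
  for (a in c("A", "B")) {
    for (t in c(0, 10)) {
      libs <- toy$design$library[toy$design$accession == a &
                                   toy$design$time == t]
      expect_equal(pm[, as.character(t), a],
                   rowMeans(cpm[, libs]))
    }
  }
  # permuting replicate labels within a cell changes nothing
  perm <- toy$design
  perm$replicate[1:2] <- perm$replicate[2:1]
  perm$library <- perm$library  # ids unchanged, replicate labels swapped
  expect_equal(profile_means(cpm, perm), pm)
})

test_that("standardization gives mean-0 sd-1 profiles, pop convention", {
  expect_equal(standardize_profile(1:7), seq(-1.5, 1.5, by = 0.5))
  expect_null(standardize_profile(rep(5, 7)))
  x <- standardize_profile(stats::rexp(7))
  expect_equal(mean(x), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(x^2)), 1, tolerance = 1e-12)
  # sample convention on request
  y <- standardize_profile(1:7, sd_convention = "sample")
  expect_equal(stats::sd(y), 1, tolerance = 1e-12)
})

test_that("distance and correlation are tied for population SEPs", {
  set.seed(42)
  n <- 7
  for (i in 1:50) {
    x <- random_sep(n)
    y <- random_sep(n)
    expect_equal(sum((x - y)^2), 2 * n * (1 - stats::cor(x, y)),
                 tolerance = 1e-9)
  }
})

test_that("profile sets flag degenerate genes and respect the shared grid", {
  toy <- toy_counts()
  prof <- compute_profiles(toy$counts, toy$design)
  expect_s3_class(prof, "profile_set")
  expect_setequal(rownames(prof$sep), c("g1", "g3"))
  expect_true(all(abs(apply(prof$sep[valid_genes(prof), , ], c(1, 3),
                            mean)) < 1e-9))

  # a gene whose CPM is constant over time is invalid and excluded from the
  # cross-accession gene list: give it counts proportional to the library
  # totals
  g1 <- toy$counts["g1", ]
  g2 <- g1 + 3L  # positive everywhere, non-constant CPM
  counts <- rbind(g1 = g1, g2 = g2, g3 = g1 + g2)  # g3 = half of every total
  prof2 <- compute_profiles(counts, toy$design, min_positive = 2)
  expect_false(any(prof2$valid["g3", ]))
  expect_false("g3" %in% valid_genes(prof2))

  # a time absent from one accession drops off the shared grid
  d2 <- toy$design
  d2$time[d2$library %in% c("L7", "L8")] <- 20
  expect_equal(as.numeric(dimnames(profile_means(
    normalize_cpm(toy$counts), d2))[[2]]), 0)
})

test_that("tendency classes follow the planted direction", {
  toy <- toy_counts()
  tend <- classify_tendencies(toy$counts, toy$design, alpha = 0.5)
  expect_setequal(unique(tend$interval), "0-10")
  expect_equal(nrow(tend), 6)

  # identical counts at both times are steady at any level
  design <- toy$design[toy$design$accession == "A", ]
  counts <- matrix(rep(c(5L, 8L), each = 4), 2, 4, byrow = TRUE,
                   dimnames = list(c("gA", "gB"), design$library))
  tend2 <- classify_tendencies(counts, design, alpha = 0.5)
  expect_true(all(tend2$class == "steady"))
})

test_that("planted strong increases are detected at alpha 0.01", {
  spec <- sim_spec(n_genes = 300,
                   archetypes = plant_archetypes(300, n_shift = 100,
                                                 shift_time = 10),
                   shift_fold = 16, dispersion = 0.02, seed = 31)
  design <- build_design(spec)
  counts <- simulate_counts(design, make_archetype_curves(spec), spec)
  tend <- classify_tendencies(counts, design)
  planted <- spec$archetypes$gene[spec$archetypes$archetype == "shift"]
  w_up <- tend[tend$gene %in% planted & tend$interval == "0-10" &
                 grepl("^W", tend$accession), ]
  expect_gte(mean(w_up$class == "increasing"), 0.95)
  # and the same change is absent in D, where nothing was planted
  d_cells <- tend[tend$gene %in% planted & tend$interval == "0-10" &
                    grepl("^D", tend$accession), ]
  expect_lt(mean(d_cells$class != "steady"), 0.05)
})

test_that("time contrasts control the null and recover planted changes", {
  nd <- sim_null()
  ct <- contrast_times(nd$counts, nd$design, unique(nd$design$accession),
                       0, 10, fdr = 0.01)
  expect_equal(sum(ct$de), 0)

  spec <- sim_spec(n_genes = 1000,
                   archetypes = plant_archetypes(1000, n_shift = 50,
                                                 shift_time = 60),
                   shift_fold = 8, dispersion = 0.05, seed = 47)
  design <- build_design(spec)
  counts <- simulate_counts(design, make_archetype_curves(spec), spec)
  planted <- spec$archetypes$gene[spec$archetypes$archetype == "shift"]
  ct2 <- contrast_times(counts, design, c("W1", "W2", "W3", "W4"),
                        50, 60, fdr = 0.01)
  expect_gte(sum(ct2$de[ct2$gene %in% planted]), 45)
  false_calls <- sum(ct2$de[!ct2$gene %in% planted])
  expect_lte(false_calls, 0.01 * sum(ct2$de) + 3 * sqrt(0.01 * 950))

  expect_error(contrast_times(nd$counts, nd$design, character(0), 0, 10),
               "empty accession subset")
  expect_error(contrast_times(nd$counts, nd$design, "D1", 10, 10),
               "must differ")
})

test_that("contrast ranking agrees with edgeR's exact test", {
  spec <- sim_spec(n_genes = 400,
                   archetypes = plant_archetypes(400, n_shift = 20,
                                                 shift_time = 60),
                   shift_fold = 8, dispersion = 0.05, seed = 53)
  design <- build_design(spec)
  counts <- simulate_counts(design, make_archetype_curves(spec), spec)
  sub <- design[design$group == "W" & design$time %in% c(50, 60), ]
  ours <- contrast_times(counts, design, c("W1", "W2", "W3", "W4"),
                         50, 60, fdr = 0.01)

  y <- edgeR::DGEList(counts = counts[, sub$library],
                      group = factor(sub$time))
  y <- edgeR::calcNormFactors(y)
  y <- suppressMessages(edgeR::estimateDisp(y))
  et <- edgeR::exactTest(y)
  q_edger <- stats::p.adjust(et$table$PValue, "BH")
  planted <- spec$archetypes$gene[spec$archetypes$archetype == "shift"]
  # both routes recover essentially the same planted set
  expect_gte(sum(ours$de[ours$gene %in% planted]), 18)
  expect_gte(sum(q_edger[rownames(et$table) %in% planted] <= 0.01), 18)
  agree <- table(ours = ours$de, edger = q_edger <= 0.01)
  expect_gte(sum(diag(agree)) / sum(agree), 0.95)
})
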