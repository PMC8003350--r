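# Shared simulated datasets, built once per test run and memoised.
# All fixtures are generated in code from fixed seeds; nothing is stored on
# disk.

.fixture_cache <- new.env(parent = emptyenv())

.memo <- function(key, build) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, build(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Reference-scale design (6 D + 4 W x 7 times x 2 reps) with planted peak-shift
# and group-shift signal plus flat background.
sim_planted <- function() {
  .memo("planted", function() {
    spec <- sim_spec(
      n_genes = 1200,
      archetypes = plant_archetypes(1200, n_d10w30 = 120, n_shift = 40,
                                    shift_time = 50),
      seed = 421L)
    design <- build_design(spec)
    truth <- make_archetype_curves(spec)
    counts <- simulate_counts(design, truth, spec)
    profiles <- compute_profiles(counts, design)
    list(spec = spec, design = design, truth = truth, counts = counts,
         profiles = profiles)
  })
}

# Pure-null dataset: every gene flat, identical latent curves in D and W.
sim_null <- function() {
  .memo("null", function() {
    spec <- sim_spec(n_genes = 800, seed = 99L)
    design <- build_design(spec)
    truth <- make_archetype_curves(spec)
    counts <- simulate_counts(design, truth, spec)
    profiles <- compute_profiles(counts, design)
    list(spec = spec, design = design, truth = truth, counts = counts,
         profiles = profiles)
  })
}

# Low-noise network dataset: one 14-gene module, 8 TFs tied to its genes,
# 11 unrelated independently peaked genes, flat background.
sim_network <- function() {
  .memo("network", function() {
    arch <- plant_archetypes(600, module_sizes = 14, n_tfs = 8)
    # 11 unrelated candidates: independently peaked, distinct peak pairs
    combos <- subset(expand.grid(peak_d = seq(0, 60, 10),
                                 peak_w = seq(0, 60, 10)),
                     !(peak_d == 10 & peak_w == 30))
    idx <- which(arch$archetype == "flat")[1:11]
    pick <- combos[seq(1, 44, 4), ][1:11, ]
    arch$archetype[idx] <- "d10w30"
    arch$peak_d[idx] <- pick$peak_d
    arch$peak_w[idx] <- pick$peak_w
    spec <- sim_spec(n_genes = 600, archetypes = arch, dispersion = 0.01,
                     seed = 77L)
    design <- build_design(spec)
    truth <- make_archetype_curves(spec)
    counts <- simulate_counts(design, truth, spec)
    profiles <- compute_profiles(counts, design)
    module <- arch$gene[!is.na(arch$module)]
    tfs <- arch$gene[arch$archetype == "tf"]
    list(spec = spec, design = design, truth = truth, counts = counts,
         profiles = profiles, module = module, tfs = tfs,
         unrelated = arch$gene[idx])
  })
}

# Random population-standardized profile (pop-sd convention).
random_sep <- function(n = 7) {
  x <- stats::rnorm(n)
  (x - mean(x)) / sqrt(sum((x - mean(x))^2) / n)
}

# Independent hypergeometric tail oracle for a 2x2 enrichment table, by
# direct enumeration over all tables with fixed margins.
hypergeom_tail_oracle <- function(a, b, c_, d) {
  n_set <- a + b
  n_term <- a + c_
  n_tot <- a + b + c_ + d
  ks <- max(0, n_set + n_term - n_tot):min(n_set, n_term)
  logp <- lchoose(n_term, ks) + lchoose(n_tot - n_term, n_set - ks) -
    lchoose(n_tot, n_set)
  sum(exp(logp[ks >= a])) / sum(exp(logp))
}
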