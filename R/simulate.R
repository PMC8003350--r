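#' Specification for a synthetic two-group time-course experiment
#'
#' Bundles the design factors (accessions, time grid, replication) with the
#' nuisance parameters of the count model (negative-binomial dispersion,
#' library-size range, baseline expression) and the archetype assignment that
#' plants known expression signals.  The defaults mirror a factorial fruit
#' development study: 6 domesticated (D) and 4 wild (W) accessions sampled at
#' 0--60 days after anthesis (DAA) in steps of 10 with 2 replicate libraries
#' per accession and time, i.e. 7 x 10 x 2 = 140 libraries.
#'
#' @param n_domesticated Number of D accessions (>= 1).
#' @param n_wild Number of W accessions (>= 1).
#' @param time_points Strictly increasing vector of sampling times in DAA.
#' @param replicates Libraries per accession x time cell (>= 1).
#' @param n_genes Total number of simulated genes.
#' @param archetypes Archetype assignment, a data frame as produced by
#'   [plant_archetypes()]; one row per gene.  `NULL` assigns every gene the
#'   `flat` archetype (pure null).
#' @param dispersion Negative-binomial dispersion phi (variance
#'   \eqn{\mu + \phi \mu^2}); a single value or one per gene.  Use 0 for the
#'   Poisson limit.
#' @param baseline_cpm_range Range from which per-gene baseline expression
#'   (CPM) is drawn log-uniformly.
#' @param lib_size_range Range from which expected library totals are drawn
#'   log-uniformly; the default 10--24 million reads matches typical
#'   per-library depths of a NovaSeq fruit-development experiment.
#' @param peak_fold Peak/baseline fold change of peaked archetypes.
#' @param shift_fold Fold change planted at `shift_time` (W group) for the
#'   `shift` archetype.
#' @param module_sd Standard deviation (log2 scale) of the per-gene jitter
#'   around a network module's shared latent curve.
#' @param seed Master integer seed; all stages draw from streams derived
#'   from it.
#'
#' @return An object of class `sim_spec`.
#' @seealso [build_design()], [make_archetype_curves()], [simulate_counts()]
#' @export
sim_spec <- function(n_domesticated = 6, n_wild = 4,
                     time_points = seq(0, 60, by = 10),
                     replicates = 2,
                     n_genes = 2000,
                     archetypes = NULL,
                     dispersion = 0.1,
                     baseline_cpm_range = c(20, 200),
                     lib_size_range = c(10e6, 24e6),
                     peak_fold = 8,
                     shift_fold = 3,
                     module_sd = 0.1,
                     seed = 1L) {
  if (!.is_count(n_domesticated)) stop("invalid 'n_domesticated': must be a count >= 1")
  if (!.is_count(n_wild)) stop("invalid 'n_wild': must be a count >= 1")
  if (!.is_count(replicates)) stop("invalid 'replicates': must be a count >= 1")
  if (!.is_count(n_genes)) stop("invalid 'n_genes': must be a count >= 1")
  if (length(time_points) < 1L || any(!is.finite(time_points)) ||
      is.unsorted(time_points, strictly = TRUE)) {
    stop("invalid 'time_points': must be strictly increasing and finite")
  }
  if (!(length(dispersion) %in% c(1L, n_genes)) || any(dispersion < 0)) {
    stop("invalid 'dispersion': must be >= 0, length 1 or n_genes")
  }
  if (length(lib_size_range) != 2L || any(lib_size_range <= 0) ||
      lib_size_range[1] > lib_size_range[2]) {
    stop("invalid 'lib_size_range'")
  }
  if (length(baseline_cpm_range) != 2L || any(baseline_cpm_range <= 0) ||
      baseline_cpm_range[1] > baseline_cpm_range[2]) {
    stop("invalid 'baseline_cpm_range'")
  }
  if (module_sd < 0) stop("invalid 'module_sd': must be >= 0")
  if (length(seed) != 1L || !is.finite(seed) || seed != round(seed)) {
    stop("invalid 'seed': must be a single integer")
  }
  if (is.null(archetypes)) {
    archetypes <- plant_archetypes(n_genes)
  }
  archetypes <- .validate_archetypes(archetypes, n_genes, time_points)
  structure(list(
    n_domesticated = as.integer(n_domesticated),
    n_wild = as.integer(n_wild),
    time_points = as.numeric(time_points),
    replicates = as.integer(replicates),
    n_genes = as.integer(n_genes),
    archetypes = archetypes,
    dispersion = as.numeric(dispersion),
    baseline_cpm_range = as.numeric(baseline_cpm_range),
    lib_size_range = as.numeric(lib_size_range),
    peak_fold = as.numeric(peak_fold),
    shift_fold = as.numeric(shift_fold),
    module_sd = as.numeric(module_sd),
    seed = as.integer(seed)
  ), class = "sim_spec")
}

#' @export
print.sim_spec <- function(x, ...) {
  cat("Simulation spec:", x$n_domesticated, "D +", x$n_wild, "W accessions,",
      length(x$time_points), "time points,", x$replicates,
      "replicate(s):", (x$n_domesticated + x$n_wild) *
        length(x$time_points) * x$replicates, "libraries\n")
  cat("  genes:", x$n_genes, " archetypes:",
      paste(sprintf("%s=%d", names(table(x$archetypes$archetype)),
                    table(x$archetypes$archetype)), collapse = ", "), "\n")
  cat("  dispersion:", paste(format(unique(x$dispersion)), collapse = ","),
      " lib sizes:", paste(format(x$lib_size_range, big.mark = ","),
                           collapse = "-"), "\n")
  invisible(x)
}

#' Build an archetype assignment table
#'
#' Lays out the planted ground truth of a simulation: which genes carry a
#' peak-shift ("D10W30"-style) signal, a single-time group shift, membership
#' in a co-regulated network module, or a transcription-factor profile tied
#' to a target gene; all remaining genes are `flat` (identical constant
#' latent curve in both groups, i.e. true nulls).
#'
#' @param n_genes Total genes; must accommodate all planted classes.
#' @param n_d10w30 Number of peak-shift genes (peak at `peak_d` in D,
#'   `peak_w` in W).
#' @param peak_d,peak_w Peak times (DAA) of the peak-shift archetype.
#' @param n_shift Number of group-shift genes (W expression multiplied at
#'   `shift_time` only).
#' @param shift_time Time (DAA) at which the shift archetype diverges.
#' @param module_sizes Integer vector; one co-regulated module per entry,
#'   each sharing a single peak-shift latent curve per group.
#' @param n_tfs Number of TF genes; TF i copies the latent curve of the i-th
#'   gene (cycled) of the first module (or of the peak-shift set when no
#'   module is requested).
#'
#' @return A data frame with columns `gene`, `archetype` (one of `flat`,
#'   `d10w30`, `shift`, `module`, `tf`), `peak_d`, `peak_w`, `shift_time`,
#'   `module` (module id) and `target` (TF target gene).
#' @export
plant_archetypes <- function(n_genes, n_d10w30 = 0, peak_d = 10, peak_w = 30,
                             n_shift = 0, shift_time = 30,
                             module_sizes = integer(0), n_tfs = 0) {
  n_module <- sum(module_sizes)
  n_special <- n_d10w30 + n_shift + n_module + n_tfs
  if (n_special > n_genes) {
    stop("planted archetypes (", n_special, ") exceed n_genes (", n_genes, ")")
  }
  if (n_tfs > 0 && n_module == 0 && n_d10w30 == 0) {
    stop("TF archetypes need a module or a d10w30 set to supply targets")
  }
  gene <- sprintf("g%05d", seq_len(n_genes))
  out <- data.frame(gene = gene, archetype = "flat",
                    peak_d = NA_real_, peak_w = NA_real_,
                    shift_time = NA_real_, module = NA_integer_,
                    target = NA_character_, stringsAsFactors = FALSE)
  i <- 0L
  take <- function(n) {
    idx <- i + seq_len(n)
    i <<- i + n
    idx
  }
  if (n_d10w30 > 0) {
    idx <- take(n_d10w30)
    out$archetype[idx] <- "d10w30"
    out$peak_d[idx] <- peak_d
    out$peak_w[idx] <- peak_w
  }
  if (n_shift > 0) {
    idx <- take(n_shift)
    out$archetype[idx] <- "shift"
    out$shift_time[idx] <- shift_time
  }
  for (m in seq_along(module_sizes)) {
    idx <- take(module_sizes[m])
    out$archetype[idx] <- "module"
    out$module[idx] <- m
    out$peak_d[idx] <- peak_d
    out$peak_w[idx] <- peak_w
  }
  if (n_tfs > 0) {
    idx <- take(n_tfs)
    targets <- if (n_module > 0) out$gene[out$module %in% 1L] else
      out$gene[out$archetype == "d10w30"]
    out$archetype[idx] <- "tf"
    out$target[idx] <- rep_len(targets, n_tfs)
  }
  out
}

.validate_archetypes <- function(a, n_genes, time_points) {
  need <- c("gene", "archetype")
  if (!is.data.frame(a) || !all(need %in% names(a))) {
    stop("invalid 'archetypes': need a data frame with columns gene, archetype")
  }
  for (col in c("peak_d", "peak_w", "shift_time", "module", "target")) {
    if (!col %in% names(a)) a[[col]] <- NA
  }
  if (nrow(a) != n_genes) {
    stop("invalid 'archetypes': ", nrow(a), " rows for ", n_genes, " genes")
  }
  if (anyDuplicated(a$gene)) {
    stop("invalid 'archetypes': duplicated gene ids")
  }
  bad <- setdiff(unique(a$archetype), c("flat", "d10w30", "shift", "module", "tf"))
  if (length(bad)) stop("invalid 'archetypes': unknown archetype ", bad[1])
  peaked <- a$archetype %in% c("d10w30", "module")
  if (any(peaked & (!a$peak_d %in% time_points | !a$peak_w %in% time_points))) {
    stop("invalid 'archetypes': peak_d/peak_w must lie on the time grid")
  }
  shifted <- a$archetype == "shift"
  if (any(shifted & !a$shift_time %in% time_points)) {
    stop("invalid 'archetypes': shift_time must lie on the time grid")
  }
  tfs <- a$archetype == "tf"
  if (any(tfs & !(a$target %in% a$gene[!tfs]))) {
    stop("invalid 'archetypes': every tf needs a non-tf target gene")
  }
  a
}

#' Build the library design table of a simulation
#'
#' One row per RNA-seq library of the full factorial (accession x time x
#' replicate).  Accessions are keyed `D1..Dn` and `W1..Wn`.  Late-maturation
#' libraries that extend the grid for a subset of accessions can be appended
#' through `extra`.
#'
#' @param spec A [sim_spec()].
#' @param extra Optional data frame with columns `accession` and `time`; each
#'   row adds `spec$replicates` libraries for that accession at that time
#'   (used for accessions whose maturation extends past the shared grid).
#' @return A design data frame with columns `library`, `accession`, `group`
#'   (`"D"`/`"W"`), `time` and `replicate`.
#' @export
build_design <- function(spec, extra = NULL) {
  stopifnot(inherits(spec, "sim_spec"))
  accession <- c(paste0("D", seq_len(spec$n_domesticated)),
                 paste0("W", seq_len(spec$n_wild)))
  group <- rep(c("D", "W"), c(spec$n_domesticated, spec$n_wild))
  grid <- expand.grid(replicate = seq_len(spec$replicates),
                      time = spec$time_points,
                      accession = accession,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (!is.null(extra)) {
    if (!is.data.frame(extra) || !all(c("accession", "time") %in% names(extra))) {
      stop("invalid 'extra': need columns accession, time")
    }
    if (!all(extra$accession %in% accession)) {
      stop("invalid 'extra': unknown accession ",
           setdiff(extra$accession, accession)[1])
    }
    add <- extra[rep(seq_len(nrow(extra)), each = spec$replicates), , drop = FALSE]
    add$replicate <- rep(seq_len(spec$replicates), nrow(extra))
    grid <- rbind(grid[c("replicate", "time", "accession")],
                  add[c("replicate", "time", "accession")])
  }
  design <- data.frame(
    library = sprintf("%s_t%02d_r%d", grid$accession, grid$time, grid$replicate),
    accession = grid$accession,
    group = group[match(grid$accession, accession)],
    time = grid$time,
    replicate = grid$replicate,
    stringsAsFactors = FALSE
  )
  rownames(design) <- NULL
  validate_design(design)
  design
}

#' Latent per-group expression curves for every gene
#'
#' Translates the archetype assignment of a [sim_spec()] into latent
#' mean-expression curves (CPM units) per gene, time point and group.
#' Curves are piecewise-linear through anchors at the grid times: peaked
#' archetypes place `peak_fold` x baseline at the peak time with shoulders at
#' the flanking grid points, so the curve's argmax is unique at the planted
#' peak; `flat` genes are constant; `shift` genes are flat except for a
#' single W time point; `module` genes share one latent curve per group up to
#' log-normal jitter of sd `module_sd`; `tf` genes inherit their target's
#' curve shape rescaled to their own baseline.
#'
#' @param spec A [sim_spec()].
#' @return An object of class `truth_table`: a list with `curves` (gene x
#'   time x group array, CPM), `table` (the archetype assignment with the
#'   drawn baselines) and `time_points`.
#' @export
make_archetype_curves <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  tp <- spec$time_points
  nt <- length(tp)
  a <- spec$archetypes
  n <- spec$n_genes
  set.seed(.derive_seed(spec$seed, "curves"))
  baseline <- exp(stats::runif(n, log(spec$baseline_cpm_range[1]),
                               log(spec$baseline_cpm_range[2])))
  curves <- array(0, dim = c(n, nt, 2),
                  dimnames = list(a$gene, as.character(tp), c("D", "W")))

  # Peak value peak_fold x baseline; flanking grid points get a shoulder at
  # 25% of the excess so the argmax is unique and the rise/fall is gradual.
  bump <- function(b, peak, fold) {
    v <- rep(b, nt)
    i <- match(peak, tp)
    v[i] <- b * fold
    for (j in c(i - 1L, i + 1L)) {
      if (j >= 1L && j <= nt) v[j] <- b * (1 + 0.25 * (fold - 1))
    }
    v
  }

  module_base <- numeric(0)
  if (any(a$archetype == "module")) {
    ids <- sort(unique(a$module[a$archetype == "module"]))
    module_base <- stats::setNames(
      exp(stats::runif(length(ids), log(spec$baseline_cpm_range[1]),
                       log(spec$baseline_cpm_range[2]))), ids)
  }
  set.seed(.derive_seed(spec$seed, "jitter"))
  for (g in seq_len(n)) {
    b <- baseline[g]
    switch(a$archetype[g],
      flat = {
        curves[g, , "D"] <- b
        curves[g, , "W"] <- b
      },
      d10w30 = {
        curves[g, , "D"] <- bump(b, a$peak_d[g], spec$peak_fold)
        curves[g, , "W"] <- bump(b, a$peak_w[g], spec$peak_fold)
      },
      shift = {
        curves[g, , "D"] <- b
        w <- rep(b, nt)
        w[match(a$shift_time[g], tp)] <- b * spec$shift_fold
        curves[g, , "W"] <- w
      },
      module = {
        mb <- module_base[[as.character(a$module[g])]]
        jit <- matrix(2^stats::rnorm(2 * nt, 0, spec$module_sd), nt, 2)
        curves[g, , "D"] <- bump(mb, a$peak_d[g], spec$peak_fold) * jit[, 1]
        curves[g, , "W"] <- bump(mb, a$peak_w[g], spec$peak_fold) * jit[, 2]
      },
      tf = NULL # second pass, after all targets exist
    )
  }
  for (g in which(a$archetype == "tf")) {
    t_idx <- match(a$target[g], a$gene)
    for (grp in c("D", "W")) {
      shape <- curves[t_idx, , grp]
      curves[g, , grp] <- shape * baseline[g] / mean(shape)
    }
  }
  a$baseline <- baseline
  structure(list(curves = curves, table = a, time_points = tp),
            class = "truth_table")
}

#' @export
print.truth_table <- function(x, ...) {
  cat("Latent truth:", dim(x$curves)[1], "genes x", dim(x$curves)[2],
      "time points x 2 groups\n")
  invisible(x)
}

#' Simulate a negative-binomial count matrix
#'
#' Draws one expected library size per library (log-uniform within
#' `spec$lib_size_range`) and then a negative-binomial count for every gene
#' and library with mean `lib_size * curve(gene, group, time) / 1e6` and
#' variance \eqn{\mu + \phi \mu^2}.  `dispersion = 0` gives Poisson counts.
#' Output is reproducible: the same spec (and hence master seed) yields an
#' identical matrix.
#'
#' @param design Design table from [build_design()]; all its times must lie
#'   on the spec's grid.
#' @param truth Latent curves from [make_archetype_curves()].
#' @param spec The originating [sim_spec()].
#' @return Integer matrix of counts, genes x libraries, with dimnames.
#' @export
simulate_counts <- function(design, truth, spec) {
  stopifnot(inherits(spec, "sim_spec"), inherits(truth, "truth_table"))
  validate_design(design)
  tp <- truth$time_points
  if (!all(design$time %in% tp)) {
    stop("design contains times absent from the simulated grid: ",
         paste(setdiff(design$time, tp), collapse = ", "))
  }
  n <- dim(truth$curves)[1]
  nlib <- nrow(design)
  set.seed(.derive_seed(spec$seed, "libsize"))
  lib_size <- exp(stats::runif(nlib, log(spec$lib_size_range[1]),
                               log(spec$lib_size_range[2])))
  t_idx <- match(design$time, tp)
  g_idx <- match(design$group, c("D", "W"))
  mu <- matrix(0, n, nlib)
  for (j in seq_len(nlib)) {
    mu[, j] <- lib_size[j] * truth$curves[, t_idx[j], g_idx[j]] / 1e6
  }
  if (any(mu > 2^30)) {
    stop("expected counts exceed the integer range; reduce library size or CPM")
  }
  phi <- rep_len(spec$dispersion, n)
  set.seed(.derive_seed(spec$seed, "counts"))
  counts <- matrix(0L, n, nlib,
                   dimnames = list(rownames(truth$curves), design$library))
  pois <- phi == 0
  if (any(pois)) {
    counts[pois, ] <- stats::rpois(sum(pois) * nlib, mu[pois, ])
  }
  if (any(!pois)) {
    counts[!pois, ] <- stats::rnbinom(sum(!pois) * nlib,
                                      mu = mu[!pois, ],
                                      size = 1 / phi[!pois])
  }
  storage.mode(counts) <- "integer"
  counts
}
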