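#' Filter genes consistently expressed in every accession
#'
#' Keeps a gene only if, within every accession, at least `min_positive` of
#' that accession's libraries have a raw count above zero.  This removes
#' genes with very low or inconsistent expression before profile
#' estimation.
#'
#' @param counts Integer count matrix, genes x libraries.
#' @param design Design table covering the count columns.
#' @param min_positive Minimum number of positive libraries required per
#'   accession (default 2).
#' @return List with `keep` (character vector of retained gene ids) and
#'   `dropped` (data frame `gene`, `accession`, `n_positive` naming, for
#'   each rejected gene, the accession with the fewest positive libraries).
#' @export
filter_consistent_genes <- function(counts, design, min_positive = 2) {
  validate_design(design)
  if (!.is_count(min_positive)) {
    stop("invalid 'min_positive': must be a count >= 1")
  }
  counts <- counts[, design$library, drop = FALSE]
  accs <- unique(design$accession)
  npos <- vapply(accs, function(a) {
    rowSums(counts[, design$library[design$accession == a], drop = FALSE] > 0)
  }, numeric(nrow(counts)))
  worst <- apply(npos, 1, which.min)
  keep <- rowSums(npos >= min_positive) == length(accs)
  dropped <- data.frame(
    gene = rownames(counts)[!keep],
    accession = accs[worst[!keep]],
    n_positive = npos[cbind(which(!keep), worst[!keep])],
    stringsAsFactors = FALSE
  )
  rownames(dropped) <- NULL
  list(keep = rownames(counts)[keep], dropped = dropped)
}

#' Counts-per-million normalization
#'
#' @param counts Count matrix, genes x libraries; every library total must
#'   be positive.
#' @return Numeric matrix of the same shape; each column sums to 1e6.
#' @export
normalize_cpm <- function(counts) {
  tot <- colSums(counts)
  if (any(tot == 0)) {
    stop("library with zero total counts: ",
         colnames(counts)[tot == 0][1])
  }
  sweep(counts, 2, tot, `/`) * 1e6
}

#' Per-accession time-point mean expression
#'
#' Averages normalized expression over the replicate libraries of every
#' (accession, time) cell, over the time grid shared by all accessions.
#' Times absent from any accession (e.g. late-maturation extensions) are
#' excluded from the grid.
#'
#' @param norm Normalized matrix from [normalize_cpm()].
#' @param design Design table.
#' @return 3-d array genes x times x accessions of mean expression.
#' @export
profile_means <- function(norm, design) {
  validate_design(design)
  norm <- norm[, design$library, drop = FALSE]
  accs <- unique(design$accession)
  times <- sort(unique(design$time))
  shared <- times[vapply(times, function(t) {
    all(vapply(accs, function(a) {
      any(design$accession == a & design$time == t)
    }, logical(1)))
  }, logical(1))]
  if (length(shared) == 0L) {
    stop("no time point is present in all accessions")
  }
  out <- array(NA_real_, dim = c(nrow(norm), length(shared), length(accs)),
               dimnames = list(rownames(norm), as.character(shared), accs))
  for (a in accs) {
    for (ti in seq_along(shared)) {
      libs <- design$library[design$accession == a & design$time == shared[ti]]
      if (length(libs) == 0L) {
        stop("missing libraries for accession ", a, " at time ", shared[ti])
      }
      out[, ti, a] <- rowMeans(norm[, libs, drop = FALSE])
    }
  }
  out
}

#' Standardize a time-mean expression vector
#'
#' Rescales a gene's time-point mean vector to mean 0 and standard deviation
#' 1 across the grid: the standardized expression profile (SEP).  With the
#' default population convention (`sd_convention = "pop"`, divide-by-n
#' standard deviation) every SEP has squared norm equal to the number of
#' time points, which ties Euclidean SEP distance to Pearson correlation
#' exactly: \eqn{\|x-y\|^2 = 2n(1-r)}.
#'
#' @param x Numeric vector of time-point means.
#' @param sd_convention `"pop"` (default) or `"sample"`.
#' @return Standardized vector, or `NULL` when `x` is constant (no valid
#'   SEP exists for such a gene).
#' @export
standardize_profile <- function(x, sd_convention = c("pop", "sample")) {
  sd_convention <- match.arg(sd_convention)
  n <- length(x)
  m <- mean(x)
  ss <- sum((x - m)^2)
  if (ss == 0) {
    return(NULL)
  }
  s <- if (sd_convention == "pop") sqrt(ss / n) else sqrt(ss / (n - 1))
  (x - m) / s
}

#' Estimate standardized expression profiles for every gene and accession
#'
#' Runs the profile pipeline: consistent-expression filtering, CPM
#' normalization, per-(accession, time) means over the shared grid, and
#' per-gene standardization within each accession.  Genes whose mean vector
#' is constant in some accession carry no profile there and are flagged
#' invalid; cross-accession analyses use only genes valid everywhere.
#'
#' @param counts Raw count matrix, genes x libraries.
#' @param design Design table.
#' @param min_positive Filter threshold, see [filter_consistent_genes()].
#' @param sd_convention Standardization convention, see
#'   [standardize_profile()].
#' @return Object of class `profile_set`: list with `sep` and `means`
#'   (gene x time x accession arrays), `valid` (gene x accession logical
#'   matrix), `genes`, `times`, `accessions` (data frame `accession`,
#'   `group`), `sd_convention` and `dropped` (the filter's rejection table).
#' @export
compute_profiles <- function(counts, design, min_positive = 2,
                             sd_convention = c("pop", "sample")) {
  sd_convention <- match.arg(sd_convention)
  validate_design(design)
  flt <- filter_consistent_genes(counts, design, min_positive)
  counts <- counts[flt$keep, design$library, drop = FALSE]
  means <- profile_means(normalize_cpm(counts), design)
  ng <- dim(means)[1]
  na <- dim(means)[3]
  sep <- array(NA_real_, dim = dim(means), dimnames = dimnames(means))
  valid <- matrix(TRUE, ng, na,
                  dimnames = dimnames(means)[c(1, 3)])
  for (a in seq_len(na)) {
    x <- means[, , a]
    m <- rowMeans(x)
    ss <- rowSums((x - m)^2)
    ok <- ss > 0
    denom <- if (sd_convention == "pop") {
      sqrt(ss / ncol(x))
    } else {
      sqrt(ss / (ncol(x) - 1))
    }
    sep[ok, , a] <- (x[ok, , drop = FALSE] - m[ok]) / denom[ok]
    valid[, a] <- ok
  }
  acc <- unique(design[c("accession", "group")])
  acc <- acc[match(dimnames(means)[[3]], acc$accession), ]
  rownames(acc) <- NULL
  structure(list(
    sep = sep, means = means, valid = valid,
    genes = dimnames(means)[[1]],
    times = as.numeric(dimnames(means)[[2]]),
    accessions = acc,
    sd_convention = sd_convention,
    dropped = flt$dropped
  ), class = "profile_set")
}

#' @export
print.profile_set <- function(x, ...) {
  cat("Profile set:", length(x$genes), "genes x", length(x$times),
      "time points x", nrow(x$accessions), "accessions (",
      sum(x$accessions$group == "D"), "D /",
      sum(x$accessions$group == "W"), "W )\n")
  cat("  valid in all accessions:", sum(rowSums(!x$valid) == 0),
      " filtered out upstream:", nrow(x$dropped), "\n")
  invisible(x)
}

#' Genes with a valid SEP in every accession
#'
#' @param profiles A `profile_set`.
#' @return Character vector of gene ids.
#' @export
valid_genes <- function(profiles) {
  stopifnot(inherits(profiles, "profile_set"))
  profiles$genes[rowSums(!profiles$valid) == 0]
}

# Accession indices of one group.
.group_idx <- function(profiles, group) {
  which(profiles$accessions$group == group)
}

# genes x times matrix of a group's mean SEP (average over that group's
# accessions) for the given genes.
.group_mean_sep_matrix <- function(profiles, genes, group) {
  idx <- .group_idx(profiles, group)
  m <- profiles$sep[genes, , idx, drop = FALSE]
  rowMeans(m, dims = 2)
}

#' Classify per-interval expression tendencies
#'
#' For every gene, accession and pair of neighboring time points, tests for
#' a change in abundance with a negative-binomial quasi-likelihood-ratio
#' test (median-of-ratios effective library sizes as offsets, so that a few
#' strongly changing genes cannot masquerade as shifts in the rest;
#' per-gene method-of-moments dispersion pooled
#' over all of the accession's replicated time cells, shrunk toward the
#' across-gene mean, F reference accounting for the estimated dispersion)
#' and classifies the interval as `increasing`, `decreasing`, or `steady`
#' at Type-I level `alpha`.
#'
#' @param counts Raw count matrix, genes x libraries.
#' @param design Design table; every (accession, time) cell needs at least 2
#'   replicates for dispersion estimation.
#' @param alpha Type-I error level (default 0.01).
#' @param shrink Weight of the across-gene median in the dispersion shrinkage
#'   (default 0.5).
#' @return Data frame with one row per gene x accession x interval:
#'   `gene`, `accession`, `interval` (e.g. `"0-10"`), `time_from`, `time_to`,
#'   `p`, `lfc` (log2 fold change, later over earlier), `class`.
#' @export
classify_tendencies <- function(counts, design, alpha = 0.01, shrink = 0.5) {
  validate_design(design)
  if (alpha <= 0 || alpha >= 1) stop("invalid 'alpha'")
  counts <- counts[, design$library, drop = FALSE]
  accs <- unique(design$accession)
  out <- vector("list", 0)
  for (a in accs) {
    times <- sort(unique(design$time[design$accession == a]))
    acc_libs <- design$library[design$accession == a]
    lib_sizes <- stats::setNames(
      .effective_lib_sizes(counts[, acc_libs, drop = FALSE]), acc_libs)
    libs_at <- lapply(times, function(t) {
      design$library[design$accession == a & design$time == t]
    })
    replicated <- vapply(libs_at, length, integer(1)) >= 2L
    disp <- NULL
    if (any(replicated)) {
      disp <- .estimate_dispersion(
        lapply(libs_at[replicated], function(l) counts[, l, drop = FALSE]),
        lapply(libs_at[replicated], function(l) lib_sizes[l]),
        shrink = shrink)
    }
    for (i in seq_len(length(times) - 1L)) {
      t1 <- times[i]
      t2 <- times[i + 1L]
      l1 <- libs_at[[i]]
      l2 <- libs_at[[i + 1L]]
      iv <- paste0(t1, "-", t2)
      if (length(l1) < 2L || length(l2) < 2L) {
        out[[length(out) + 1L]] <- data.frame(
          gene = rownames(counts), accession = a, interval = iv,
          time_from = t1, time_to = t2, p = NA_real_, lfc = NA_real_,
          class = "untestable", stringsAsFactors = FALSE)
        next
      }
      y1 <- counts[, l1, drop = FALSE]
      y2 <- counts[, l2, drop = FALSE]
      res <- .nb_lrt(y1, y2, lib_sizes[l1], lib_sizes[l2], disp)
      cls <- ifelse(res$p < alpha & res$lfc > 0, "increasing",
                    ifelse(res$p < alpha & res$lfc < 0, "decreasing",
                           "steady"))
      out[[length(out) + 1L]] <- data.frame(
        gene = rownames(counts), accession = a, interval = iv,
        time_from = t1, time_to = t2, p = res$p, lfc = res$lfc,
        class = cls, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Differential-expression contrast between two time points
#'
#' Pools the libraries of the chosen accessions at each of two times and
#' applies the same negative-binomial quasi-likelihood-ratio test as
#' [classify_tendencies()] (dispersion pooled over every replicated cell of
#' the contrast), followed by Benjamini-Hochberg correction across
#' genes.  Used e.g. for late-maturation contrasts (60 vs 70 DAA) in the
#' accessions that extend past the shared grid.
#'
#' @param counts Raw count matrix.
#' @param design Design table.
#' @param accessions Accession keys to include (nonempty).
#' @param time_a,time_b The two times to contrast (must differ and be
#'   present in the subset).
#' @param fdr FDR threshold for the DE call (default 0.01).
#' @param shrink Dispersion shrinkage weight, see [classify_tendencies()].
#' @return Data frame `gene`, `p`, `q`, `lfc` (log2 `time_b` over `time_a`),
#'   `de` (logical, `q <= fdr`).
#' @export
contrast_times <- function(counts, design, accessions, time_a, time_b,
                           fdr = 0.01, shrink = 0.5) {
  validate_design(design)
  if (length(accessions) == 0L) stop("empty accession subset")
  if (!all(accessions %in% design$accession)) {
    stop("unknown accession: ",
         setdiff(accessions, design$accession)[1])
  }
  if (time_a == time_b) stop("time_a and time_b must differ")
  counts <- counts[, design$library, drop = FALSE]
  sub <- design[design$accession %in% accessions, ]
  l_a <- sub$library[sub$time == time_a]
  l_b <- sub$library[sub$time == time_b]
  if (length(l_a) == 0L || length(l_b) == 0L) {
    stop("time ", if (length(l_a) == 0L) time_a else time_b,
         " has no libraries in the accession subset")
  }
  lib_sizes <- stats::setNames(
    .effective_lib_sizes(counts[, c(l_a, l_b), drop = FALSE]), c(l_a, l_b))
  y_a <- counts[, l_a, drop = FALSE]
  y_b <- counts[, l_b, drop = FALSE]
  # dispersion from every (accession, time) cell of the contrast
  cells <- list()
  sizes <- list()
  for (a in accessions) {
    for (t in c(time_a, time_b)) {
      libs <- sub$library[sub$accession == a & sub$time == t]
      if (length(libs) >= 2L) {
        cells[[length(cells) + 1L]] <- counts[, libs, drop = FALSE]
        sizes[[length(sizes) + 1L]] <- lib_sizes[libs]
      }
    }
  }
  if (length(cells) == 0L) {
    cells <- list(y_a, y_b)
    sizes <- list(lib_sizes[l_a], lib_sizes[l_b])
  }
  disp <- .estimate_dispersion(cells, sizes, shrink = shrink)
  res <- .nb_lrt(y_a, y_b, lib_sizes[l_a], lib_sizes[l_b], disp)
  q <- stats::p.adjust(res$p, method = "BH")
  data.frame(gene = rownames(counts), p = res$p, q = q, lfc = res$lfc,
             de = q <= fdr, stringsAsFactors = FALSE)
}
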