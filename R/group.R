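#' Mean standardized profile of a gene set within one group
#'
#' Pools the SEPs of the chosen genes across all accessions of a group
#' (n = genes x group accessions profiles) and returns the pointwise mean
#' with a t-based 95% confidence interval at every time point.  Because each
#' SEP has time-mean zero, the pooled mean curve has time-mean exactly zero.
#'
#' @param profiles A `profile_set` from [compute_profiles()].
#' @param genes Gene ids (default: all genes valid in every accession).
#' @param group `"D"` or `"W"`.
#' @param conf.level Confidence level of the pointwise interval.
#' @return Data frame `time`, `mean`, `lower`, `upper`, `n`; with a single
#'   pooled profile the interval is undefined (`NA`) and a warning is
#'   raised.
#' @export
group_mean_sep <- function(profiles, genes = NULL, group = c("D", "W"),
                           conf.level = 0.95) {
  stopifnot(inherits(profiles, "profile_set"))
  group <- match.arg(group)
  if (is.null(genes)) genes <- valid_genes(profiles)
  if (length(genes) == 0L) stop("empty gene set")
  if (!all(genes %in% profiles$genes)) {
    stop("unknown gene: ", setdiff(genes, profiles$genes)[1])
  }
  idx <- .group_idx(profiles, group)
  if (length(idx) == 0L) stop("no accessions in group ", group)
  m <- profiles$sep[genes, , idx, drop = FALSE]
  pooled <- matrix(aperm(m, c(1, 3, 2)), ncol = length(profiles$times))
  pooled <- pooled[stats::complete.cases(pooled), , drop = FALSE]
  n <- nrow(pooled)
  if (n == 0L) stop("no valid profiles in the pool")
  mean_curve <- colMeans(pooled)
  if (n == 1L) {
    warning("single profile in the pool: confidence interval undefined")
    lower <- upper <- rep(NA_real_, length(mean_curve))
  } else {
    se <- sqrt(apply(pooled, 2, stats::var) / n)
    hw <- stats::qt(1 - (1 - conf.level) / 2, n - 1) * se
    lower <- mean_curve - hw
    upper <- mean_curve + hw
  }
  data.frame(time = profiles$times, mean = mean_curve, lower = lower,
             upper = upper, n = n)
}

#' Pointwise D-versus-W test for one gene
#'
#' At every time point, compares the gene's standardized values across the D
#' accessions with those across the W accessions using Welch's two-sample
#' t-test, and reports the 95% confidence interval for the difference in
#' means (D minus W).
#'
#' @param profiles A `profile_set`.
#' @param gene A single gene id, valid in all accessions.
#' @return Data frame `time`, `mean_d`, `mean_w`, `statistic`, `df`, `p`,
#'   `lower`, `upper`.
#' @export
pointwise_group_test <- function(profiles, gene) {
  stopifnot(inherits(profiles, "profile_set"), length(gene) == 1L)
  if (!gene %in% profiles$genes) stop("unknown gene: ", gene)
  if (!gene %in% valid_genes(profiles)) {
    stop("gene ", gene, " has no valid SEP in some accession")
  }
  d_idx <- .group_idx(profiles, "D")
  w_idx <- .group_idx(profiles, "W")
  if (length(d_idx) < 2L || length(w_idx) < 2L) {
    stop("each group needs at least 2 accessions")
  }
  x <- t(profiles$sep[gene, , d_idx])  # accessions x times
  y <- t(profiles$sep[gene, , w_idx])
  res <- .welch_rows(t(x), t(y))
  data.frame(time = profiles$times, mean_d = res$mean_x,
             mean_w = res$mean_y, statistic = res$statistic, df = res$df,
             p = res$p, lower = res$lower, upper = res$upper)
}

#' Classify genes as having equal or distinct profiles in D and W
#'
#' Runs the pointwise Welch test at every time point for every gene, pools
#' all gene x time p-values into a single Benjamini-Hochberg correction, and
#' calls a gene `distinct` when any of its time points reaches `q <= fdr`.
#' The realized per-test p cutoff implied by the FDR threshold is reported.
#'
#' @param profiles A `profile_set`.
#' @param fdr FDR level (default 0.01).
#' @param genes Gene ids to classify (default: all genes valid everywhere).
#' @return List with `calls` (data frame `gene`, `min_q`, `call`), `p` and
#'   `q` (gene x time matrices) and `p_cutoff` (largest p-value still
#'   significant after correction; 0 when nothing is).
#' @export
classify_divergence <- function(profiles, fdr = 0.01, genes = NULL) {
  stopifnot(inherits(profiles, "profile_set"))
  if (fdr < 0 || fdr > 1) stop("invalid 'fdr'")
  if (is.null(genes)) genes <- valid_genes(profiles)
  if (length(genes) == 0L) stop("empty gene set")
  d_idx <- .group_idx(profiles, "D")
  w_idx <- .group_idx(profiles, "W")
  if (length(d_idx) < 2L || length(w_idx) < 2L) {
    stop("each group needs at least 2 accessions")
  }
  nt <- length(profiles$times)
  p <- matrix(NA_real_, length(genes), nt,
              dimnames = list(genes, as.character(profiles$times)))
  for (ti in seq_len(nt)) {
    x <- profiles$sep[genes, ti, d_idx, drop = TRUE]
    y <- profiles$sep[genes, ti, w_idx, drop = TRUE]
    if (length(genes) == 1L) {
      x <- matrix(x, nrow = 1)
      y <- matrix(y, nrow = 1)
    }
    p[, ti] <- .welch_rows(x, y)$p
  }
  q <- matrix(stats::p.adjust(p, method = "BH"), nrow(p), ncol(p),
              dimnames = dimnames(p))
  sig <- q <= fdr
  p_cutoff <- if (any(sig, na.rm = TRUE)) max(p[sig], na.rm = TRUE) else 0
  min_q <- apply(q, 1, min)
  calls <- data.frame(gene = genes, min_q = min_q,
                      call = ifelse(min_q <= fdr, "distinct", "equal"),
                      stringsAsFactors = FALSE)
  rownames(calls) <- NULL
  list(calls = calls, p = p, q = q, p_cutoff = p_cutoff)
}

#' Mean SEP distances between accessions, with clustering
#'
#' The dissimilarity between two accessions is the mean, over genes, of the
#' Euclidean distance between their SEPs.  Accessions are then clustered
#' agglomeratively on this matrix (average linkage by default).
#'
#' @param profiles A `profile_set` with at least 2 accessions.
#' @param genes Gene ids to use (default: all genes valid everywhere).
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @return Object of class `accession_distances`: list with `dist`
#'   (symmetric matrix), `hclust` and `linkage`.
#' @export
accession_distance_matrix <- function(profiles, genes = NULL,
                                      linkage = c("average", "complete",
                                                  "single")) {
  stopifnot(inherits(profiles, "profile_set"))
  linkage <- match.arg(linkage)
  if (is.null(genes)) genes <- valid_genes(profiles)
  if (length(genes) == 0L) stop("empty gene set")
  accs <- profiles$accessions$accession
  if (length(accs) < 2L) stop("need at least 2 accessions")
  d <- matrix(0, length(accs), length(accs), dimnames = list(accs, accs))
  for (i in seq_along(accs)) {
    for (j in seq_len(i - 1L)) {
      di <- profiles$sep[genes, , i, drop = TRUE] -
        profiles$sep[genes, , j, drop = TRUE]
      if (length(genes) == 1L) di <- matrix(di, nrow = 1)
      d[i, j] <- d[j, i] <- mean(sqrt(rowSums(di^2)))
    }
  }
  hc <- stats::hclust(stats::as.dist(d), method = linkage)
  structure(list(dist = d, hclust = hc, linkage = linkage),
            class = "accession_distances")
}

#' @export
print.accession_distances <- function(x, ...) {
  cat("Accession distance matrix (", nrow(x$dist), " accessions, ",
      x$linkage, " linkage)\n", sep = "")
  print(round(x$dist, 3))
  invisible(x)
}

#' Export an accession dendrogram in Newick format
#'
#' @param distances An `accession_distances` object.
#' @param path Output file.
#' @export
write_dendrogram <- function(distances, path) {
  stopifnot(inherits(distances, "accession_distances"))
  ape::write.tree(ape::as.phylo(distances$hclust), file = path)
  invisible(path)
}

#' Test whether between-group SEP distances exceed within-group distances
#'
#' For every gene, computes the mean Euclidean distance between SEPs of
#' accessions in different groups and the mean distance between SEPs of
#' accessions in the same group, then applies a paired t-test across genes.
#'
#' @param profiles A `profile_set`; both groups need at least 2 accessions
#'   so the within pool is nonempty.
#' @param genes Gene ids (default: all genes valid everywhere).
#' @return List with `statistic`, `df`, `p` (two-sided),
#'   `mean_between`, `mean_within` and `per_gene` (data frame `gene`,
#'   `between`, `within`).
#' @export
distance_group_test <- function(profiles, genes = NULL) {
  stopifnot(inherits(profiles, "profile_set"))
  if (is.null(genes)) genes <- valid_genes(profiles)
  if (length(genes) == 0L) stop("empty gene set")
  grp <- profiles$accessions$group
  if (sum(grp == "D") < 2L || sum(grp == "W") < 2L) {
    stop("each group needs at least 2 accessions for within-group distances")
  }
  na <- length(grp)
  pairs <- utils::combn(na, 2)
  bsum <- wsum <- rep(0, length(genes))
  nb <- nw <- 0L
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]
    j <- pairs[2, k]
    di <- profiles$sep[genes, , i, drop = TRUE] -
      profiles$sep[genes, , j, drop = TRUE]
    if (length(genes) == 1L) di <- matrix(di, nrow = 1)
    dd <- sqrt(rowSums(di^2))
    if (grp[i] == grp[j]) {
      wsum <- wsum + dd
      nw <- nw + 1L
    } else {
      bsum <- bsum + dd
      nb <- nb + 1L
    }
  }
  per_gene <- data.frame(gene = genes, between = bsum / nb,
                         within = wsum / nw, stringsAsFactors = FALSE)
  tt <- stats::t.test(per_gene$between, per_gene$within, paired = TRUE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_between = mean(per_gene$between),
       mean_within = mean(per_gene$within), per_gene = per_gene)
}

#' Per-group average peak times of a gene set
#'
#' For every gene and accession, the peak time is the grid time at which the
#' SEP attains its maximum (ties broken toward the earlier time).  Peak
#' times are averaged within each group over all genes and accessions, and
#' the difference D minus W is reported.
#'
#' @param profiles A `profile_set`.
#' @param genes Gene ids (default: all genes valid everywhere).
#' @return List with `per_gene` (data frame `gene`, `accession`, `group`,
#'   `peak_time`), `mean_d`, `mean_w` and `difference` (`mean_d - mean_w`,
#'   in DAA).
#' @export
peak_time_summary <- function(profiles, genes = NULL) {
  stopifnot(inherits(profiles, "profile_set"))
  if (is.null(genes)) genes <- valid_genes(profiles)
  if (length(genes) == 0L) stop("empty gene set")
  accs <- profiles$accessions$accession
  rows <- vector("list", length(accs))
  for (a in seq_along(accs)) {
    m <- profiles$sep[genes, , a, drop = TRUE]
    if (length(genes) == 1L) m <- matrix(m, nrow = 1)
    peak <- profiles$times[apply(m, 1, which.max)]
    rows[[a]] <- data.frame(gene = genes, accession = accs[a],
                            group = profiles$accessions$group[a],
                            peak_time = peak, stringsAsFactors = FALSE)
  }
  per_gene <- do.call(rbind, rows)
  mean_d <- mean(per_gene$peak_time[per_gene$group == "D"])
  mean_w <- mean(per_gene$peak_time[per_gene$group == "W"])
  list(per_gene = per_gene, mean_d = mean_d, mean_w = mean_w,
       difference = mean_d - mean_w)
}

#' Compare expression diversity between groups
#'
#' Expression diversity of a gene within a group is the coefficient of
#' variation (sd/mean) of the gene's accession-level mean expression, with
#' accession means taken over all of that accession's libraries (all times
#' pooled).  The per-gene difference `log(CV_D) - log(CV_W)` is tested with
#' a paired two-sided t-test across genes; genes with a zero group mean or a
#' zero CV are excluded (and counted).
#'
#' @param norm Normalized matrix from [normalize_cpm()].
#' @param design Design table; each group needs at least 2 accessions.
#' @return List with `statistic`, `df`, `p`, `mean_log_ratio` (mean of
#'   `log(CV_D) - log(CV_W)`), `direction` (`"D < W"` or `"D > W"`),
#'   `n_used`, `n_excluded` and `per_gene` (data frame `gene`, `cv_d`,
#'   `cv_w`).
#' @export
diversity_test <- function(norm, design) {
  validate_design(design)
  norm <- norm[, design$library, drop = FALSE]
  acc <- unique(design[c("accession", "group")])
  if (sum(acc$group == "D") < 2L || sum(acc$group == "W") < 2L) {
    stop("each group needs at least 2 accessions")
  }
  acc_means <- vapply(acc$accession, function(a) {
    rowMeans(norm[, design$library[design$accession == a], drop = FALSE])
  }, numeric(nrow(norm)))
  cv_group <- function(grp) {
    m <- acc_means[, acc$group == grp, drop = FALSE]
    mu <- rowMeans(m)
    sdv <- sqrt(.row_vars(m))
    ifelse(mu > 0, sdv / mu, NA_real_)
  }
  cv_d <- cv_group("D")
  cv_w <- cv_group("W")
  ok <- !is.na(cv_d) & !is.na(cv_w) & cv_d > 0 & cv_w > 0
  if (sum(ok) < 2L) stop("fewer than 2 usable genes for the diversity test")
  lr <- log(cv_d[ok]) - log(cv_w[ok])
  tt <- stats::t.test(lr)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_log_ratio = mean(lr),
       direction = if (mean(lr) < 0) "D < W" else "D > W",
       n_used = sum(ok), n_excluded = sum(!ok),
       per_gene = data.frame(gene = rownames(norm)[ok], cv_d = cv_d[ok],
                             cv_w = cv_w[ok], stringsAsFactors = FALSE))
}
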