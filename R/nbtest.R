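# Self-contained negative-binomial two-sample machinery used by the
# tendency classifier and the time-contrast test.  Counts y_ij for library j
# are modelled as NB with mean N_j * q (N_j = library size, q = relative
# abundance) and variance mu + phi mu^2.  The statistic is the likelihood
# ratio for equal q in the two compared cells, with q estimated by the
# library-size-weighted proportion (the quasi-likelihood estimator, exact
# MLE in the Poisson limit and for equal library sizes).
#
# Dispersion is estimated per gene by the method of moments pooled over all
# replicated cells of the tested unit and shrunk toward the across-gene
# mean; because phi is estimated, the statistic is referred to an
# F(1, d/(1 - shrink)) distribution rather than chi-squared(1), where d is
# the per-gene residual df of the moment estimator and the df inflation
# d -> d/(1 - shrink) is the usual empirical-Bayes accounting for the
# information contributed by the across-gene pool (a shrink weight w
# corresponds to a prior with d * w/(1 - w) df, so posterior df
# = d + d * w/(1 - w)).  Calibration of the resulting test at the design
# scale is asserted by the null-simulation tests.

# Median-of-ratios effective library sizes (size factor x count scale) for
# the libraries of one tested unit.  Robust to composition shifts: a handful
# of strongly changing genes inflates a library's total but not its median
# ratio to the per-gene geometric mean.  Genes with a zero count in any
# library are excluded from the reference; with fewer than 20 such genes the
# raw totals are returned.
.effective_lib_sizes <- function(y) {
  tot <- colSums(y)
  pos <- rowSums(y == 0) == 0
  if (sum(pos) < 20) {
    return(tot)
  }
  lg <- log(y[pos, , drop = FALSE])
  ref <- rowMeans(lg)
  sf <- exp(apply(lg - ref, 2, stats::median))
  sf / mean(sf) * mean(tot)
}

# Method-of-moments dispersion for one cell: counts are rescaled to the mean
# library size, where Var(z) ~ m + phi m^2; returns one (possibly negative)
# estimate per gene.  y: genes x replicates, N: library sizes.
.mom_dispersion_cell <- function(y, N) {
  z <- sweep(y, 2, mean(N) / N, `*`)
  m <- rowMeans(z)
  v <- .row_vars(z)
  (v - m) / m^2
}

# Per-gene dispersion across a list of replicated cells, shrunk toward the
# across-gene mean.  Returns the per-gene estimate and the reference df of
# the downstream F test.
.estimate_dispersion <- function(cells, lib_sizes, shrink = 0.5,
                                 floor = 1e-8) {
  stopifnot(length(cells) >= 1L, shrink >= 0, shrink < 1)
  ests <- vapply(seq_along(cells),
                 function(i) .mom_dispersion_cell(cells[[i]], lib_sizes[[i]]),
                 numeric(nrow(cells[[1]])))
  if (is.null(dim(ests))) ests <- matrix(ests, nrow = 1)
  phi <- rowMeans(ests, na.rm = TRUE)
  phi[!is.finite(phi)] <- 0
  phi <- pmax(phi, 0)
  phi <- pmax((1 - shrink) * phi + shrink * mean(phi), floor)
  d <- sum(vapply(cells, function(y) ncol(y) - 1L, integer(1)))
  list(phi = phi, df = d / (1 - shrink))
}

# NB log-likelihood of counts y (genes x libs) at abundance q (per gene)
# given library sizes N and dispersion phi (per gene).
.nb_loglik <- function(y, N, q, phi) {
  ll <- numeric(nrow(y))
  size <- 1 / phi
  for (j in seq_len(ncol(y))) {
    mu <- N[j] * q
    d <- stats::dnbinom(y[, j], size = size, mu = mu, log = TRUE)
    # q = 0 gives mu = 0: the distribution is degenerate at 0
    d[mu == 0] <- ifelse(y[mu == 0, j] == 0, 0, -Inf)
    ll <- ll + d
  }
  ll
}

# Quasi-likelihood-ratio test of equal abundance in cells a and b.
# y_a, y_b: genes x replicates count matrices; N_a, N_b: library sizes;
# disp: result of .estimate_dispersion().  Returns per-gene p (F reference),
# log2 fold change (b over a, half-count floor on the abundances) and the
# LR statistic.
.nb_lrt <- function(y_a, y_b, N_a, N_b, disp) {
  phi <- disp$phi
  q_a <- rowSums(y_a) / sum(N_a)
  q_b <- rowSums(y_b) / sum(N_b)
  q_0 <- (rowSums(y_a) + rowSums(y_b)) / (sum(N_a) + sum(N_b))
  ll1 <- .nb_loglik(y_a, N_a, q_a, phi) + .nb_loglik(y_b, N_b, q_b, phi)
  ll0 <- .nb_loglik(y_a, N_a, q_0, phi) + .nb_loglik(y_b, N_b, q_0, phi)
  stat <- pmax(2 * (ll1 - ll0), 0)
  p <- stats::pf(stat, 1, disp$df, lower.tail = FALSE)
  eps_a <- 0.5 / sum(N_a)
  eps_b <- 0.5 / sum(N_b)
  lfc <- log2((q_b + eps_b) / (q_a + eps_a))
  list(p = p, lfc = lfc, stat = stat)
}
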