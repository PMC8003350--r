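# Internal helpers shared across modules.

# Derive a per-stage RNG seed from the master seed so that partial reruns
# (e.g. regenerating library sizes without redrawing counts) are reproducible.
.derive_seed <- function(seed, stage) {
  offsets <- c(curves = 11L, jitter = 23L, libsize = 37L, counts = 53L,
               perm = 71L)
  if (!stage %in% names(offsets)) {
    stop("unknown RNG stage: ", stage)
  }
  (as.integer(seed) %% 2000000000L) + offsets[[stage]]
}

.is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

# Row-wise sample variance of a numeric matrix (denominator n - 1).
.row_vars <- function(x) {
  n <- ncol(x)
  if (n < 2L) {
    return(rep(NA_real_, nrow(x)))
  }
  m <- rowMeans(x)
  rowSums((x - m)^2) / (n - 1)
}

# Vectorised Welch two-sample t-test over the rows of two matrices.
# Returns the statistic, Welch-Satterthwaite df, two-sided p and the 95% CI
# for the difference in means (row of x minus row of y).  Degenerate rows
# (zero pooled variance) get t = 0, p = 1 when the means agree and p = 0
# otherwise, mirroring the limit of the test.
.welch_rows <- function(x, y, conf.level = 0.95) {
  nx <- ncol(x)
  ny <- ncol(y)
  if (nx < 2L || ny < 2L) {
    stop("Welch test needs at least 2 observations per group")
  }
  mx <- rowMeans(x)
  my <- rowMeans(y)
  vx <- .row_vars(x)
  vy <- .row_vars(y)
  se2 <- vx / nx + vy / ny
  diff <- mx - my
  tt <- diff / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  zero <- !is.na(se2) & se2 == 0
  if (any(zero)) {
    tt[zero] <- ifelse(diff[zero] == 0, 0, sign(diff[zero]) * Inf)
    p[zero] <- ifelse(diff[zero] == 0, 1, 0)
    df[zero] <- nx + ny - 2
  }
  hw <- stats::qt(1 - (1 - conf.level) / 2, df) * sqrt(se2)
  data.frame(mean_x = mx, mean_y = my, diff = diff, statistic = tt,
             df = df, p = p, lower = diff - hw, upper = diff + hw)
}

# p-value for a Pearson correlation through the exact t transform with
# df = n - 2 (n = number of paired observations).
.cor_pvalue <- function(r, n, alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  df <- n - 2
  r <- pmin(1, pmax(-1, r))
  tt <- r * sqrt(df) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  if (alternative == "greater") {
    stats::pt(tt, df, lower.tail = FALSE)
  } else {
    2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  }
}
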