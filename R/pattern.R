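#' Define a peak-shift expression pattern
#'
#' A peak pattern names the time at which a gene's profile should peak in
#' each group, e.g. peak at 10 DAA in the domesticated group and 30 DAA in
#' the wild group ("D10W30").
#'
#' @param peak_d Peak time (DAA) required in the D group.
#' @param peak_w Peak time (DAA) required in the W group.
#' @param mode `"group-mean"`: the argmax condition applies to each group's
#'   mean SEP; `"per-accession-strict"`: it must hold in every accession of
#'   each group individually.
#' @return Object of class `peak_pattern`.
#' @export
peak_pattern <- function(peak_d = 10, peak_w = 30,
                         mode = c("group-mean", "per-accession-strict")) {
  mode <- match.arg(mode)
  stopifnot(length(peak_d) == 1L, length(peak_w) == 1L,
            is.finite(peak_d), is.finite(peak_w))
  structure(list(peak_d = peak_d, peak_w = peak_w, mode = mode),
            class = "peak_pattern")
}

#' Detect genes matching a peak-shift pattern
#'
#' In `group-mean` mode a gene matches when the argmax of its D-group mean
#' SEP falls at `peak_d` and the argmax of its W-group mean SEP at `peak_w`
#' (ties broken toward the earlier time).  In `per-accession-strict` mode
#' the argmax condition must hold in every single accession of each group.
#'
#' @param profiles A `profile_set`.
#' @param pattern A [peak_pattern()]; both peak times must lie on the
#'   profile grid.
#' @param genes Candidate gene ids (default: all genes valid everywhere).
#' @return Character vector of matching gene ids.
#' @export
detect_peak_pattern <- function(profiles, pattern = peak_pattern(),
                                genes = NULL) {
  stopifnot(inherits(profiles, "profile_set"),
            inherits(pattern, "peak_pattern"))
  if (!pattern$peak_d %in% profiles$times ||
      !pattern$peak_w %in% profiles$times) {
    stop("pattern peak times must lie on the time grid (",
         paste(profiles$times, collapse = ", "), ")")
  }
  if (is.null(genes)) genes <- valid_genes(profiles)
  if (length(genes) == 0L) return(character(0))
  argmax_time <- function(m) profiles$times[apply(m, 1, which.max)]
  if (pattern$mode == "group-mean") {
    pd <- argmax_time(.group_mean_sep_matrix(profiles, genes, "D"))
    pw <- argmax_time(.group_mean_sep_matrix(profiles, genes, "W"))
    hit <- pd == pattern$peak_d & pw == pattern$peak_w
  } else {
    hit <- rep(TRUE, length(genes))
    for (a in seq_len(nrow(profiles$accessions))) {
      m <- profiles$sep[genes, , a, drop = TRUE]
      if (length(genes) == 1L) m <- matrix(m, nrow = 1)
      want <- if (profiles$accessions$group[a] == "D") pattern$peak_d else
        pattern$peak_w
      hit <- hit & argmax_time(m) == want
    }
  }
  genes[hit]
}

#' GO biological-process enrichment by Fisher's exact test
#'
#' For every term annotated in the universe, builds the 2x2 table of gene
#' set membership against term membership (genes without any annotation
#' count in the "neither" margins), computes the one-sided (enrichment
#' direction) Fisher exact p-value and the conditional maximum-likelihood
#' odds ratio, and corrects across terms with Benjamini-Hochberg.
#'
#' @param genes Gene set (must be contained in `universe`, nonempty).
#' @param universe All genes considered (e.g. every consistently expressed
#'   gene).
#' @param annotations An `annotation_set` from [read_annotations()], or any
#'   list with a `go` data frame (`gene`, `term`) and optional `term_names`.
#' @param fdr FDR threshold recorded in the `enriched` column.
#' @param or_method `"cmle"` (conditional MLE, Fisher-test convention) or
#'   `"sample"` (ad/bc) for the odds ratio.
#' @return Data frame sorted by `q`: `term`, `name`, `set_in_term`,
#'   `set_not_term`, `term_not_set`, `neither`, `odds_ratio`, `p`, `q`,
#'   `enriched`.  Degenerate tables give an infinite odds ratio.
#' @export
enrich_go <- function(genes, universe, annotations, fdr = 0.05,
                      or_method = c("cmle", "sample")) {
  or_method <- match.arg(or_method)
  if (length(genes) == 0L) stop("empty gene set")
  if (length(universe) == 0L) stop("empty universe")
  genes <- unique(genes)
  universe <- unique(universe)
  if (!all(genes %in% universe)) {
    stop("gene set must be contained in the universe (offender: ",
         setdiff(genes, universe)[1], ")")
  }
  go <- annotations$go
  go <- go[go$gene %in% universe, , drop = FALSE]
  terms <- unique(go$term)
  if (length(terms) == 0L) stop("no annotated universe gene")
  n_univ <- length(universe)
  n_set <- length(genes)
  rows <- lapply(terms, function(tm) {
    in_term <- unique(go$gene[go$term == tm])
    a <- sum(genes %in% in_term)
    b <- n_set - a
    c_ <- length(in_term) - a
    d <- n_univ - a - b - c_
    tab <- matrix(c(a, b, c_, d), 2, 2)
    ft <- stats::fisher.test(tab, alternative = "greater")
    or <- if (or_method == "cmle") unname(ft$estimate) else {
      if (b * c_ == 0) Inf else (a * d) / (b * c_)
    }
    data.frame(term = tm, set_in_term = a, set_not_term = b,
               term_not_set = c_, neither = d, odds_ratio = or,
               p = ft$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$enriched <- out$q <= fdr
  nm <- annotations$term_names
  out$name <- if (length(nm)) unname(nm[out$term]) else NA_character_
  out <- out[order(out$q, out$p), c("term", "name", "set_in_term",
                                    "set_not_term", "term_not_set",
                                    "neither", "odds_ratio", "p", "q",
                                    "enriched")]
  rownames(out) <- NULL
  out
}
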