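#' Thresholds for gene-network estimation
#'
#' Bundles the thresholds of the network pipeline: candidate edges are gene
#' pairs whose mean SEPs lie within `distance_threshold` standardized units;
#' an edge is validated when the two genes' group-mean SEPs are strongly and
#' significantly positively correlated within both groups
#' (`r > within_r_min`, one-sided p < `within_p_max`) while the cross-group
#' correlation is weak and non-significant (`r < between_r_max`, one-sided
#' p > `between_p_min`).  TF imputation demands a per-accession correlation
#' of at least `tf_concordance_min` in every accession; `epsilon` is the
#' nominal per-accession selection error feeding
#' [repeated_error_probability()].
#'
#' @param distance_threshold Mean-SEP Euclidean distance cutoff (default 1).
#' @param within_r_min Minimum within-group correlation (default 0.96).
#' @param within_p_max Maximum within-group correlation p (default 1e-4).
#' @param between_r_max Maximum between-group correlation (default 0.4).
#' @param between_p_min Minimum between-group correlation p (default 0.5).
#' @param tf_concordance_min Per-accession TF-target correlation threshold
#'   (default 0.95).
#' @param epsilon Per-accession error probability (default 0.1).
#' @param distance_mode `"pooled"`: candidate distance uses the mean SEP
#'   over all accessions; `"per-group"`: a pair qualifies when the distance
#'   criterion holds for both group-mean SEPs.
#' @param between_mode `"cross-mean"`: between-group correlation is the mean
#'   of r(D_i, W_j) and r(W_i, D_j); `"direct"`: mean of r(D_i, W_i) and
#'   r(D_j, W_j).
#' @return Object of class `network_config`.
#' @export
network_config <- function(distance_threshold = 1,
                           within_r_min = 0.96, within_p_max = 1e-4,
                           between_r_max = 0.4, between_p_min = 0.5,
                           tf_concordance_min = 0.95,
                           epsilon = 0.1,
                           distance_mode = c("pooled", "per-group"),
                           between_mode = c("cross-mean", "direct")) {
  if (distance_threshold <= 0) stop("invalid 'distance_threshold': must be > 0")
  for (r in c(within_r_min, between_r_max, tf_concordance_min)) {
    if (r < -1 || r > 1) stop("correlation thresholds must lie in [-1, 1]")
  }
  if (epsilon < 0 || epsilon > 1) stop("invalid 'epsilon': must be in [0, 1]")
  structure(list(distance_threshold = distance_threshold,
                 within_r_min = within_r_min, within_p_max = within_p_max,
                 between_r_max = between_r_max,
                 between_p_min = between_p_min,
                 tf_concordance_min = tf_concordance_min,
                 epsilon = epsilon,
                 distance_mode = match.arg(distance_mode),
                 between_mode = match.arg(between_mode)),
            class = "network_config")
}

#' Enumerate candidate structural edges by mean-SEP distance
#'
#' Enumerates all unordered pairs of the candidate genes and computes the
#' Euclidean distance between their mean SEPs (the average of the
#' per-accession SEPs over all accessions, or per group under
#' `distance_mode = "per-group"`).  A pair is selected when the distance
#' falls below `cfg$distance_threshold`.
#'
#' @param profiles A `profile_set`.
#' @param candidates At least 2 gene ids with valid SEPs in all accessions.
#' @param cfg A [network_config()].
#' @return Data frame with one row per pair: `gene1`, `gene2`, `distance`
#'   (pooled mode) or `distance_d`/`distance_w`, and `selected`.
#' @export
select_structural_edges <- function(profiles, candidates,
                                    cfg = network_config()) {
  stopifnot(inherits(profiles, "profile_set"),
            inherits(cfg, "network_config"))
  if (length(candidates) < 2L) stop("need at least 2 candidate genes")
  bad <- setdiff(candidates, valid_genes(profiles))
  if (length(bad)) {
    stop("candidate without valid SEPs in all accessions: ", bad[1])
  }
  pairs <- utils::combn(candidates, 2)
  out <- data.frame(gene1 = pairs[1, ], gene2 = pairs[2, ],
                    stringsAsFactors = FALSE)
  if (cfg$distance_mode == "pooled") {
    msep <- rowMeans(profiles$sep[candidates, , , drop = FALSE], dims = 2)
    d <- sqrt(rowSums((msep[out$gene1, , drop = FALSE] -
                         msep[out$gene2, , drop = FALSE])^2))
    out$distance <- d
    out$selected <- d < cfg$distance_threshold
  } else {
    md <- .group_mean_sep_matrix(profiles, candidates, "D")
    mw <- .group_mean_sep_matrix(profiles, candidates, "W")
    dd <- sqrt(rowSums((md[out$gene1, , drop = FALSE] -
                          md[out$gene2, , drop = FALSE])^2))
    dw <- sqrt(rowSums((mw[out$gene1, , drop = FALSE] -
                          mw[out$gene2, , drop = FALSE])^2))
    out$distance_d <- dd
    out$distance_w <- dw
    out$selected <- dd < cfg$distance_threshold & dw < cfg$distance_threshold
  }
  out
}

#' Validate candidate edges by within- and between-group correlation
#'
#' For every selected candidate pair, computes the Pearson correlation of
#' the two genes' group-mean SEPs within the D group and within the W group
#' (one-sided p, t transform with df = time points - 2), and the
#' between-group correlation (mean of the two cross-pairings).  All p-values
#' test the positive-association direction: an edge needs strong evidence of
#' positive coordination within each group and no such evidence across
#' groups.  An edge is retained when both within-group correlations exceed
#' `cfg$within_r_min` with p below `cfg$within_p_max` and the between-group
#' correlation stays below `cfg$between_r_max` with p above
#' `cfg$between_p_min`.  Pairs with a constant group-mean SEP are untestable
#' and dropped.
#'
#' @param edges Candidate edges from [select_structural_edges()]; only rows
#'   with `selected == TRUE` are considered.
#' @param profiles A `profile_set`.
#' @param cfg A [network_config()].
#' @return Object of class `gene_network` with structural nodes and the
#'   validated edges (evidence columns: distance, r/p within D and W, r/p
#'   between).  The number of untestable (degenerate) pairs is stored in
#'   `n_untestable`.
#' @export
validate_edges <- function(edges, profiles, cfg = network_config()) {
  stopifnot(inherits(profiles, "profile_set"),
            inherits(cfg, "network_config"), is.data.frame(edges))
  cand <- edges[edges$selected, , drop = FALSE]
  genes <- unique(c(cand$gene1, cand$gene2))
  nt <- length(profiles$times)
  md <- .group_mean_sep_matrix(profiles, genes, "D")
  mw <- .group_mean_sep_matrix(profiles, genes, "W")
  rows <- vector("list", nrow(cand))
  n_untestable <- 0L
  for (k in seq_len(nrow(cand))) {
    g1 <- cand$gene1[k]
    g2 <- cand$gene2[k]
    if (stats::sd(md[g1, ]) == 0 || stats::sd(md[g2, ]) == 0 ||
        stats::sd(mw[g1, ]) == 0 || stats::sd(mw[g2, ]) == 0) {
      n_untestable <- n_untestable + 1L
      next
    }
    r_d <- stats::cor(md[g1, ], md[g2, ])
    r_w <- stats::cor(mw[g1, ], mw[g2, ])
    r_between <- if (cfg$between_mode == "cross-mean") {
      mean(c(stats::cor(md[g1, ], mw[g2, ]), stats::cor(mw[g1, ], md[g2, ])))
    } else {
      mean(c(stats::cor(md[g1, ], mw[g1, ]), stats::cor(md[g2, ], mw[g2, ])))
    }
    p_d <- .cor_pvalue(r_d, nt, "greater")
    p_w <- .cor_pvalue(r_w, nt, "greater")
    p_b <- .cor_pvalue(r_between, nt, "greater")
    keep <- min(r_d, r_w) > cfg$within_r_min &&
      max(p_d, p_w) < cfg$within_p_max &&
      r_between < cfg$between_r_max && p_b > cfg$between_p_min
    rows[[k]] <- data.frame(
      gene1 = g1, gene2 = g2,
      distance = if ("distance" %in% names(cand)) cand$distance[k] else
        NA_real_,
      r_within_d = r_d, p_within_d = p_d,
      r_within_w = r_w, p_within_w = p_w,
      r_between = r_between, p_between = p_b,
      retained = keep, stringsAsFactors = FALSE)
  }
  evidence <- do.call(rbind, rows)
  if (is.null(evidence)) {
    evidence <- data.frame(gene1 = character(0), gene2 = character(0),
                           distance = numeric(0), r_within_d = numeric(0),
                           p_within_d = numeric(0), r_within_w = numeric(0),
                           p_within_w = numeric(0), r_between = numeric(0),
                           p_between = numeric(0), retained = logical(0))
  }
  kept <- evidence[evidence$retained, setdiff(names(evidence), "retained"),
                   drop = FALSE]
  rownames(kept) <- NULL
  nodes <- data.frame(gene = genes, role = rep("structural", length(genes)),
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = kept, tf_edges = NULL,
                 candidates = evidence, n_untestable = n_untestable,
                 config = cfg),
            class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat("Gene network:", nrow(x$nodes), "nodes (",
      sum(x$nodes$role == "structural"), "structural,",
      sum(x$nodes$role == "TF"), "TF ),", nrow(x$edges),
      "structural edges")
  if (!is.null(x$tf_edges)) cat(",", nrow(x$tf_edges), "TF-target edges")
  cat("\n")
  invisible(x)
}

#' Impute transcription factors for structural target genes
#'
#' A TF is imputed as a putative regulator of a target gene when their SEPs
#' are concordant in every accession independently:
#' `cor(SEP_tf, SEP_target) >= cfg$tf_concordance_min` in each of the A
#' accessions.  Because the accessions are independent datasets, the chance
#' probability of a spurious imputation is approximately `p_pass^A`, where
#' `p_pass` is the probability that a random expressed gene passes the
#' per-accession criterion; `p_pass` is estimated empirically by drawing
#' random (gene, accession) combinations.
#'
#' @param profiles A `profile_set`.
#' @param targets Structural target gene ids.
#' @param tf_list Candidate TF gene ids (nonempty); TFs without valid SEPs
#'   in every accession are skipped and counted.
#' @param cfg A [network_config()].
#' @param n_perm Random draws for the `p_pass` estimate (default 1000).
#' @param seed Optional seed for the permutation draws.
#' @return List with `edges` (data frame `tf`, `target`, `r_min`, `r_mean`,
#'   `p_pass`, `p_chance`, `imputed`), `r` (TF x target x accession array of
#'   correlations), `p_pass` (named per target), `n_accessions` and
#'   `n_skipped`.
#' @export
impute_tfs <- function(profiles, targets, tf_list, cfg = network_config(),
                       n_perm = 1000, seed = NULL) {
  stopifnot(inherits(profiles, "profile_set"),
            inherits(cfg, "network_config"))
  if (length(tf_list) == 0L) stop("empty tf_list")
  if (length(targets) == 0L) stop("no target genes")
  ok <- valid_genes(profiles)
  bad_t <- setdiff(targets, ok)
  if (length(bad_t)) stop("target without valid SEPs: ", bad_t[1])
  skipped <- setdiff(tf_list, ok)
  tfs <- intersect(tf_list, ok)
  if (length(tfs) == 0L) stop("no TF candidate has valid SEPs everywhere")
  accs <- profiles$accessions$accession
  na <- length(accs)
  r <- array(NA_real_, dim = c(length(tfs), length(targets), na),
             dimnames = list(tfs, targets, accs))
  for (a in seq_len(na)) {
    m <- profiles$sep[, , a]
    r[, , a] <- stats::cor(t(m[tfs, , drop = FALSE]),
                           t(m[targets, , drop = FALSE]))
  }
  if (!is.null(seed)) set.seed(.derive_seed(seed, "perm"))
  pool <- setdiff(ok, targets)
  draw_g <- sample(pool, n_perm, replace = TRUE)
  draw_a <- sample(na, n_perm, replace = TRUE)
  p_pass <- vapply(targets, function(s) {
    pass <- vapply(seq_len(n_perm), function(i) {
      stats::cor(profiles$sep[draw_g[i], , draw_a[i]],
                 profiles$sep[s, , draw_a[i]]) >= cfg$tf_concordance_min
    }, logical(1))
    mean(pass)
  }, numeric(1))
  grid <- expand.grid(tf = tfs, target = targets, stringsAsFactors = FALSE)
  r_min <- mapply(function(t_, s_) min(r[t_, s_, ]), grid$tf, grid$target)
  r_mean <- mapply(function(t_, s_) mean(r[t_, s_, ]), grid$tf, grid$target)
  edges <- data.frame(
    tf = grid$tf, target = grid$target,
    r_min = unname(r_min), r_mean = unname(r_mean),
    p_pass = unname(p_pass[grid$target]),
    p_chance = unname(p_pass[grid$target])^na,
    imputed = unname(r_min) >= cfg$tf_concordance_min,
    stringsAsFactors = FALSE)
  list(edges = edges, r = r, p_pass = p_pass, n_accessions = na,
       n_skipped = length(skipped))
}

#' Attach imputed TF edges to a gene network
#'
#' @param net A `gene_network` from [validate_edges()].
#' @param imputation Result of [impute_tfs()]; only imputed edges are kept.
#' @return The network with TF nodes and TF-target edges added.
#' @export
add_tf_edges <- function(net, imputation) {
  stopifnot(inherits(net, "gene_network"))
  hits <- imputation$edges[imputation$edges$imputed, , drop = FALSE]
  rownames(hits) <- NULL
  tf_nodes <- data.frame(gene = setdiff(unique(hits$tf), net$nodes$gene),
                         role = "TF", stringsAsFactors = FALSE)
  net$nodes <- rbind(net$nodes, tf_nodes)
  net$tf_edges <- hits
  net
}

#' Probability of repeating a selection error in every accession
#'
#' With independent per-accession error probability `epsilon`, the
#' probability of erroneously selecting a gene in all `n_accessions`
#' independent accessions is `epsilon^n_accessions` — e.g. 1e-10 for
#' `epsilon = 0.1` over 10 accessions.
#'
#' @param epsilon Per-accession error probability, in `[0, 1]`.
#' @param n_accessions Number of independent accessions (>= 1).
#' @return The repeated-error probability `epsilon^n_accessions`.
#' @export
repeated_error_probability <- function(epsilon, n_accessions) {
  if (length(epsilon) != 1L || !is.finite(epsilon) || epsilon < 0 ||
      epsilon > 1) {
    stop("invalid 'epsilon': must lie in [0, 1]")
  }
  if (!.is_count(n_accessions)) {
    stop("invalid 'n_accessions': must be a count >= 1")
  }
  epsilon^n_accessions
}

#' Export a gene network to GraphML and a TSV edge list
#'
#' @param net A `gene_network`.
#' @param graphml_path Output GraphML file.
#' @param tsv_path Optional output TSV edge list with all evidence columns.
#' @return `graphml_path`, invisibly.
#' @export
export_network <- function(net, graphml_path, tsv_path = NULL) {
  stopifnot(inherits(net, "gene_network"))
  edges <- net$edges
  all_edges <- data.frame(
    from = edges$gene1, to = edges$gene2, kind = rep("structural-structural",
                                                     nrow(edges)),
    distance = edges$distance,
    r_within_d = edges$r_within_d, r_within_w = edges$r_within_w,
    r_between = edges$r_between, stringsAsFactors = FALSE)
  if (!is.null(net$tf_edges) && nrow(net$tf_edges)) {
    all_edges <- rbind(all_edges, data.frame(
      from = net$tf_edges$tf, to = net$tf_edges$target, kind = "TF-target",
      distance = NA_real_, r_within_d = NA_real_, r_within_w = NA_real_,
      r_between = NA_real_, stringsAsFactors = FALSE))
  }
  g <- igraph::graph_from_data_frame(all_edges, directed = FALSE,
                                     vertices = net$nodes)
  igraph::write_graph(g, graphml_path, format = "graphml")
  if (!is.null(tsv_path)) {
    utils::write.table(all_edges, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(graphml_path)
}

#' Read a network written by [export_network()]
#'
#' @param graphml_path GraphML file.
#' @return List with `nodes` (data frame `gene`, `role`) and `edges` (data
#'   frame `from`, `to`, `kind`, evidence columns).
#' @export
read_network <- function(graphml_path) {
  g <- igraph::read_graph(graphml_path, format = "graphml")
  nodes <- data.frame(gene = igraph::vertex_attr(g, "name"),
                      role = igraph::vertex_attr(g, "role"),
                      stringsAsFactors = FALSE)
  el <- igraph::as_data_frame(g, what = "edges")
  list(nodes = nodes, edges = el)
}
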