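#' Validate a library design table
#'
#' Checks the invariants every design table must satisfy: required columns,
#' unique (accession, time, replicate) combinations, one group label per
#' accession, and group labels restricted to `"D"` and `"W"`.
#'
#' @param design Data frame with columns `library`, `accession`, `group`,
#'   `time`, `replicate`.
#' @return The design, invisibly, after validation.
#' @export
validate_design <- function(design) {
  need <- c("library", "accession", "group", "time", "replicate")
  if (!is.data.frame(design) || !all(need %in% names(design))) {
    stop("design must be a data frame with columns ",
         paste(need, collapse = ", "))
  }
  if (anyDuplicated(design$library)) {
    stop("design: duplicated library id ",
         design$library[duplicated(design$library)][1])
  }
  key <- paste(design$accession, design$time, design$replicate)
  if (anyDuplicated(key)) {
    stop("design: duplicated (accession, time, replicate): ",
         key[duplicated(key)][1])
  }
  if (!all(design$group %in% c("D", "W"))) {
    stop("design: group labels must be 'D' or 'W'")
  }
  grp <- tapply(design$group, design$accession,
                function(g) length(unique(g)))
  if (any(grp > 1)) {
    stop("design: accession ", names(grp)[grp > 1][1],
         " carries more than one group label")
  }
  if (!is.numeric(design$time) || any(!is.finite(design$time))) {
    stop("design: time must be numeric and finite")
  }
  invisible(design)
}

#' Read a library design table
#'
#' @param path Tab-separated file with header columns `library`, `accession`,
#'   `group`, `time`, `replicate`.
#' @return Validated design data frame.
#' @export
read_design <- function(path) {
  design <- utils::read.delim(path, stringsAsFactors = FALSE)
  design$time <- as.numeric(design$time)
  design$replicate <- as.integer(design$replicate)
  validate_design(design)
  design
}

#' @rdname read_design
#' @param design Design table to write.
#' @export
write_design <- function(design, path) {
  validate_design(design)
  utils::write.table(design, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a raw count matrix and align it to a design
#'
#' Reads a tab-separated genes-in-rows count file (first column: gene id;
#' remaining columns: one per library, named in the header) and returns an
#' integer matrix whose columns are reordered to match the design.  Parsing
#' is strict: duplicated gene ids, libraries missing from the file, and
#' non-integer cells are errors that name the offending gene/library.
#'
#' @param path Tab-separated count file.
#' @param design Design table ([validate_design()]) listing the expected
#'   libraries.
#' @return Integer matrix, genes x libraries (design order).
#' @export
read_counts <- function(path, design) {
  validate_design(design)
  raw <- utils::read.delim(path, check.names = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 2L) stop("count file ", path, " has no library columns")
  gene <- raw[[1]]
  if (anyDuplicated(gene)) {
    stop("duplicate gene id in ", path, ": ", gene[duplicated(gene)][1])
  }
  libs <- colnames(raw)[-1]
  missing <- setdiff(design$library, libs)
  if (length(missing)) {
    stop("count file is missing design librar",
         if (length(missing) > 1) "ies: " else "y: ",
         paste(missing, collapse = ", "))
  }
  mat <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(mat), nrow(mat), ncol(mat)))
  bad <- which(is.na(num) | num != round(num) | num < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-integer count '", mat[bad[1, 1], bad[1, 2]], "' for gene ",
         gene[bad[1, 1]], " in library ", libs[bad[1, 2]])
  }
  storage.mode(num) <- "integer"
  dimnames(num) <- list(gene, libs)
  num[, design$library, drop = FALSE]
}

#' @rdname read_counts
#' @param counts Integer matrix (genes x libraries, dimnames set) to write.
#' @export
write_counts <- function(counts, path) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)))
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the latent truth of a simulation for test harnesses
#'
#' @param truth A `truth_table` from [make_archetype_curves()].
#' @param path Output TSV path; one row per gene x group with the archetype
#'   and the latent CPM at every time point.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "truth_table"))
  tp <- truth$time_points
  flat <- do.call(rbind, lapply(c("D", "W"), function(grp) {
    m <- truth$curves[, , grp, drop = FALSE]
    data.frame(gene = rownames(truth$curves), group = grp,
               archetype = truth$table$archetype,
               matrix(m, dim(m)[1], dim(m)[2],
                      dimnames = list(NULL, paste0("cpm_", tp))),
               stringsAsFactors = FALSE, check.names = FALSE)
  }))
  utils::write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene annotations: GO biological-process map and TF list
#'
#' @param go_path Tab-separated file with header whose first two columns are
#'   gene id and GO term id; an optional third column carries the term
#'   label.  Duplicate gene-term pairs are collapsed.
#' @param tf_path Tab-separated file with header whose first column lists
#'   transcription-factor gene ids.
#' @return An object of class `annotation_set`: list with `go` (data frame
#'   `gene`, `term`), `term_names` (named character, possibly empty) and
#'   `tfs` (character vector).
#' @export
read_annotations <- function(go_path, tf_path) {
  go <- utils::read.delim(go_path, stringsAsFactors = FALSE)
  if (nrow(go) == 0L) stop("empty annotation file: ", go_path)
  if (ncol(go) < 2L) stop("GO map ", go_path, " needs gene and term columns")
  map <- data.frame(gene = as.character(go[[1]]), term = as.character(go[[2]]),
                    stringsAsFactors = FALSE)
  if (any(!nzchar(map$term))) stop("empty GO term id in ", go_path)
  term_names <- character(0)
  if (ncol(go) >= 3L) {
    keep <- !duplicated(map$term)
    term_names <- stats::setNames(as.character(go[[3]])[keep], map$term[keep])
  }
  map <- map[!duplicated(paste(map$gene, map$term)), , drop = FALSE]
  rownames(map) <- NULL
  tf <- utils::read.delim(tf_path, stringsAsFactors = FALSE)
  if (nrow(tf) == 0L) stop("empty TF list: ", tf_path)
  tfs <- unique(as.character(tf[[1]]))
  structure(list(go = map, term_names = term_names, tfs = tfs),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("Annotation set:", nrow(x$go), "gene-term pairs,",
      length(unique(x$go$term)), "terms,", length(x$tfs), "TFs\n")
  invisible(x)
}
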