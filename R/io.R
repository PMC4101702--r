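#' Read a gene expression matrix from a tab-separated file
#'
#' The expected layout is the usual "wide" expression table: the first row
#' holds sample identifiers, the first column gene identifiers, and the body
#' is numeric (log-ratio scale or any other analysis-ready unit).  Rows with
#' any missing value are dropped with a warning (the downstream PCA assumes
#' complete data), and duplicated gene rows are collapsed by keeping the
#' first occurrence.
#'
#' @param path Path to a TSV file.
#' @return A numeric matrix with gene identifiers as row names and sample
#'   identifiers as column names.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, header = TRUE, row.names = NULL,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L)
    stop("expression table must have at least 2 sample columns")
  genes <- as.character(df[[1L]])
  body <- df[, -1L, drop = FALSE]
  vals <- as.matrix(body)
  if (!is.numeric(vals))
    stop("non-numeric expression values in ", path)
  storage.mode(vals) <- "double"
  dup <- duplicated(genes)
  if (any(dup)) {
    warning(sum(dup), " duplicated gene row(s) collapsed, keeping the first")
    vals <- vals[!dup, , drop = FALSE]
    genes <- genes[!dup]
  }
  rownames(vals) <- genes
  incomplete <- rowSums(is.na(vals)) > 0L
  if (any(incomplete)) {
    warning(sum(incomplete), " gene row(s) with missing values dropped")
    vals <- vals[!incomplete, , drop = FALSE]
  }
  if (nrow(vals) < 1L) stop("no complete gene rows left after filtering")
  if (anyDuplicated(colnames(vals))) stop("duplicated sample identifiers")
  vals
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression()]; the first column is named `gene_id`.
#'
#' @param x Numeric matrix with row and column names.
#' @param path Output path.
#' @export
write_expression <- function(x, path) {
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read pathway gene sets in GMT format
#'
#' Standard GMT: one pathway per line, `id TAB description TAB gene1 TAB
#' gene2 ...`.  Duplicate genes within a line are removed.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors (gene sets); the `description`
#'   attribute carries the second GMT field per pathway.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(fields, length, 1L) < 3L
  if (any(bad))
    stop("GMT line(s) with fewer than 3 fields: ", which(bad)[1L])
  ids <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(ids)) stop("duplicated pathway identifiers in GMT")
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- ids
  attr(sets, "description") <- stats::setNames(vapply(fields, `[[`, "", 2L), ids)
  sets
}

#' Write pathway gene sets in GMT format
#'
#' @param annotation Named list of character vectors.
#' @param path Output path.
#' @param description Optional character vector of per-pathway descriptions;
#'   defaults to the `description` attribute or the pathway id.
#' @export
write_gmt <- function(annotation, path, description = NULL) {
  ids <- names(annotation)
  if (is.null(description)) description <- attr(annotation, "description")
  if (is.null(description)) description <- stats::setNames(ids, ids)
  lines <- vapply(ids, function(id) {
    paste(c(id, description[[id]], annotation[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene-pair association-score table
#'
#' Three tab-separated columns: `geneA`, `geneB`, `score` (nonnegative).
#' The table is symmetric by construction; if an unordered pair appears
#' more than once the maximum score is kept (with a warning).  Lookups of
#' absent pairs return 0.
#'
#' @param path Path to a 3-column TSV (header optional; a header row is
#'   detected by a non-numeric third field).
#' @return An object of class `score_table`.
#' @export
read_scores <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) != 3L) stop("score table must have exactly 3 columns")
  if (is.character(df[[3L]])) {  # header row present
    df <- df[-1L, , drop = FALSE]
    df[[3L]] <- suppressWarnings(as.numeric(df[[3L]]))
  }
  if (anyNA(df[[3L]])) stop("malformed (non-numeric) score value")
  if (any(df[[3L]] < 0)) stop("negative association score")
  score_table(df[[1L]], df[[2L]], df[[3L]])
}

#' Build an association-score table from vectors
#'
#' @param gene_a,gene_b Character vectors of gene identifiers.
#' @param score Nonnegative numeric scores.
#' @return An object of class `score_table`: an environment hashing the
#'   unordered pair key to its score.
#' @export
score_table <- function(gene_a, gene_b, score) {
  stopifnot(length(gene_a) == length(gene_b),
            length(gene_a) == length(score))
  if (any(score < 0)) stop("negative association score")
  key <- pair_key(gene_a, gene_b)
  env <- new.env(parent = emptyenv(), size = max(length(key), 29L))
  dups <- 0L
  for (i in seq_along(key)) {
    k <- key[[i]]
    old <- env[[k]]
    if (is.null(old)) env[[k]] <- score[[i]]
    else {
      dups <- dups + 1L
      env[[k]] <- max(old, score[[i]])
    }
  }
  if (dups > 0L)
    warning(dups, " duplicated gene pair(s); maximum score kept")
  genes <- unique(c(as.character(gene_a), as.character(gene_b)))
  structure(list(env = env, genes = genes), class = "score_table")
}

pair_key <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Look up gene-pair association scores
#'
#' @param scores A `score_table`.
#' @param gene_a,gene_b Gene identifier vectors (recycled to equal length).
#' @return Numeric vector of scores; absent pairs give 0.
#' @export
lookup_score <- function(scores, gene_a, gene_b) {
  stopifnot(inherits(scores, "score_table"))
  key <- pair_key(gene_a, gene_b)
  vapply(key, function(k) {
    v <- scores$env[[k]]
    if (is.null(v)) 0 else v
  }, 0, USE.NAMES = FALSE)
}

#' @export
print.score_table <- function(x, ...) {
  cat("score_table:", length(ls(x$env)), "unique gene pairs over",
      length(x$genes), "genes\n")
  invisible(x)
}

#' @export
length.score_table <- function(x) length(ls(x$env))

#' Write an association-score table as 3-column TSV
#'
#' @param scores A `score_table`.
#' @param path Output path.
#' @export
write_scores <- function(scores, path) {
  keys <- ls(scores$env)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  df <- data.frame(geneA = vapply(parts, `[[`, "", 1L),
                   geneB = vapply(parts, `[[`, "", 2L),
                   score = vapply(keys, function(k) scores$env[[k]], 0),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Restrict a pathway annotation to genes present in an expression matrix
#'
#' Annotation genes not measured in the matrix are dropped (once, with a
#' message); the pathway size used throughout the package counts measured
#' genes only.
#'
#' @param annotation Named list of gene-id vectors.
#' @param x Expression matrix.
#' @param min_genes Drop pathways left with fewer genes than this.
#' @return Filtered annotation list.
#' @export
match_annotation <- function(annotation, x, min_genes = 1L) {
  measured <- rownames(x)
  out <- lapply(annotation, function(g) g[g %in% measured])
  lost <- sum(lengths(annotation)) - sum(lengths(out))
  if (lost > 0L)
    message(lost, " annotated gene(s) not measured in the expression matrix; ignored")
  out <- out[lengths(out) >= min_genes]
  attr(out, "description") <- attr(annotation, "description")
  out
}

#' Extract a pathway's expression submatrix
#'
#' Row subset of the expression matrix for the pathway's measured genes;
#' sample (column) order is preserved.
#'
#' @param x Expression matrix.
#' @param genes Character vector of gene ids.
#' @return Numeric matrix (genes x samples).
#' @export
pathway_submatrix <- function(x, genes) {
  x[intersect(genes, rownames(x)), , drop = FALSE]
}
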