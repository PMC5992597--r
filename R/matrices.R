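# Tabular containers used throughout the pipeline.
#
# An expression table is a tibble whose first column (`gene`) holds unique
# gene identifiers and whose remaining columns are numeric log2 expression
# values, one per sample.  A discrete table has the same layout with values
# restricted to the three states {0, 1, 2}.  A p-value table is long:
# one row per gene x contrast with columns `gene`, `contrast`, `p` and
# optionally `lfc`.

#' Coerce an expression table to a numeric matrix
#'
#' Internal helper: takes a tibble/data frame whose first column is the gene
#' id and returns a numeric matrix with gene row names, validating shape.
#'
#' @param x data frame, first column gene ids.
#' @param kind one of `"expression"` or `"discrete"`; discrete tables are
#'   checked to contain only the states 0, 1 and 2.
#' @return numeric (or integer) matrix with gene ids as row names.
#' @keywords internal
as_gene_matrix <- function(x, kind = c("expression", "discrete")) {
  kind <- match.arg(kind)
  if (is.matrix(x)) {
    if (is.null(rownames(x))) abort("matrix input must carry gene row names")
    m <- x
  } else {
    if (!is.data.frame(x) || ncol(x) < 2) {
      abort("expected a data frame with a gene id column plus sample columns")
    }
    genes <- as.character(x[[1]])
    m <- as.matrix(x[, -1, drop = FALSE])
    rownames(m) <- genes
  }
  if (anyDuplicated(rownames(m))) {
    dup <- unique(rownames(m)[duplicated(rownames(m))])
    abort(paste0("duplicate gene ids: ", paste(head(dup, 5L), collapse = ", ")))
  }
  storage.mode(m) <- if (kind == "discrete") "integer" else "double"
  if (kind == "discrete") {
    bad <- which(!(m %in% c(0L, 1L, 2L)) | is.na(m))
    if (length(bad)) {
      rc <- arrayInd(bad[1L], dim(m))
      abort(sprintf("discrete value outside {0,1,2} at gene '%s', sample '%s'",
                    rownames(m)[rc[1L]], colnames(m)[rc[2L]]))
    }
  } else if (any(!is.finite(m))) {
    rc <- arrayInd(which(!is.finite(m))[1L], dim(m))
    abort(sprintf("non-finite expression value at gene '%s', sample '%s'",
                  rownames(m)[rc[1L]], colnames(m)[rc[2L]]))
  }
  m
}

#' Convert a gene matrix back to a tibble
#' @param m matrix with gene row names.
#' @return tibble with first column `gene`.
#' @keywords internal
gene_matrix_tbl <- function(m) {
  out <- as_tibble(m, .name_repair = "minimal")
  dplyr::bind_cols(tibble(gene = rownames(m)), out)
}

#' Read an expression, discrete or p-value table from TSV
#'
#' TSV with a header row; the first column holds gene ids.  For
#' `kind = "pvalue"` the file is the long format written by
#' [write_pvalue_table()] with columns `gene`, `contrast`, `p` and
#' optionally `lfc`.  Invariants are enforced on read: discrete values must
#' lie in \{0,1,2\}, p-values in (0,1], and gene ids must not repeat
#' (per contrast for p-value tables).
#'
#' @param path file path.
#' @param kind `"expression"`, `"discrete"` or `"pvalue"`.
#' @return a tibble (see package container conventions).
#' @export
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' write_matrix(tibble::tibble(gene = c("a", "b"), s1 = c(0, 1), s2 = c(2, 0)), f)
#' read_matrix(f, "expression")
read_matrix <- function(path, kind = c("expression", "discrete", "pvalue")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (kind == "pvalue") {
    need <- c("gene", "contrast", "p")
    if (!all(need %in% names(raw))) {
      abort("p-value table needs columns gene, contrast, p")
    }
    tbl <- as_tibble(raw)
    validate_pvalue_table(tbl)
    return(tbl)
  }
  m <- as_gene_matrix(raw, kind)
  gene_matrix_tbl(m)
}

#' Write an expression or discrete table as TSV
#'
#' Genes as rows, first column `gene`, header row of sample ids.  UTF-8,
#' tab-separated, no quoting; row order is preserved so writes are
#' deterministic.
#'
#' @param x tibble or matrix (gene ids as row names).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path) {
  if (is.matrix(x)) x <- gene_matrix_tbl(x)
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a long p-value table
#' @param tbl tibble with `gene`, `contrast`, `p`, optionally `lfc`.
#' @keywords internal
validate_pvalue_table <- function(tbl) {
  if (any(!is.finite(tbl$p)) || any(tbl$p <= 0) || any(tbl$p > 1)) {
    abort("p-values must lie in (0, 1]")
  }
  dup <- dplyr::count(tbl, .data$gene, .data$contrast) |> dplyr::filter(.data$n > 1L)
  if (nrow(dup)) {
    abort(paste0("duplicate gene/contrast rows, e.g. ",
                 dup$gene[1L], " / ", dup$contrast[1L]))
  }
  invisible(tbl)
}

#' Write a long p-value table as TSV
#' @param tbl p-value tibble (`gene`, `contrast`, `p`, optional `lfc`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pvalue_table <- function(tbl, path) {
  validate_pvalue_table(tbl)
  write.table(tbl, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then member genes.
#'
#' @param path GMT file.
#' @return named list of character vectors of member genes.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) strsplit(l, "\t", fixed = TRUE)[[1L]])
  nm <- vapply(sets, `[`, character(1L), 1L)
  members <- lapply(sets, function(f) unique(f[-(1:2)]))
  setNames(members, nm)
}
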