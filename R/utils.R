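#' @importFrom rlang abort warn .data
#' @importFrom stats cor sd var median quantile setNames
NULL

# Internal helpers shared across modules: conversion between the wide
# (gene_id + one column per sample) tibble layout used at the interface and
# the plain numeric matrix layout used for linear algebra.

#' Convert a wide expression tibble to a numeric matrix
#'
#' The first column must be `gene_id`; every other column is a sample.
#'
#' @param tbl A tibble with a `gene_id` column and one numeric column per sample.
#' @return A numeric matrix with genes as rows (rownames = gene ids) and
#'   samples as columns.
#' @export
as_expr_matrix <- function(tbl) {
  stopifnot(is.data.frame(tbl))
  if (!"gene_id" %in% names(tbl)) {
    abort("expression table must have a 'gene_id' column")
  }
  ids <- as.character(tbl$gene_id)
  if (anyDuplicated(ids)) abort("gene ids must be unique")
  m <- as.matrix(tbl[setdiff(names(tbl), "gene_id")])
  if (!is.numeric(m)) abort("sample columns must be numeric")
  rownames(m) <- ids
  m
}

#' Convert a gene-by-sample matrix to the wide expression tibble layout
#'
#' @param m A numeric matrix with gene rownames and sample colnames.
#' @param unit Optional unit tag stored in the `"unit"` attribute
#'   (`"count"`, `"fpkm"` or `"log_fpkm"`).
#' @return A tibble with `gene_id` first, one column per sample.
#' @export
expr_tibble <- function(m, unit = NULL) {
  out <- tibble::as_tibble(m, rownames = "gene_id")
  if (!is.null(unit)) attr(out, "unit") <- unit
  out
}

expr_unit <- function(tbl) attr(tbl, "unit", exact = TRUE)

check_unit <- function(tbl, expected, fn) {
  u <- expr_unit(tbl)
  if (!is.null(u) && !identical(u, expected)) {
    abort(sprintf("%s expects a matrix in '%s' units, got '%s'", fn, expected, u))
  }
  invisible(TRUE)
}

# Library sizes may arrive as a named numeric vector or a two-column tibble
# (sample_id, fragments); normalise to a named vector aligned to `samples`.
resolve_library_sizes <- function(library_sizes, samples) {
  if (is.data.frame(library_sizes)) {
    ls <- setNames(library_sizes[[2]], as.character(library_sizes[[1]]))
  } else {
    ls <- library_sizes
  }
  if (is.null(names(ls))) {
    if (length(ls) != length(samples)) {
      abort("unnamed library sizes must match the number of samples")
    }
    names(ls) <- samples
  }
  missing <- setdiff(samples, names(ls))
  if (length(missing)) {
    abort(paste0("missing library sizes for: ", paste(missing, collapse = ", ")))
  }
  ls <- ls[samples]
  if (any(!is.finite(ls)) || any(ls <= 0)) abort("library sizes must be positive")
  ls
}

resolve_gene_lengths <- function(gene_lengths, genes) {
  if (is.data.frame(gene_lengths)) {
    gl <- setNames(gene_lengths[[2]], as.character(gene_lengths[[1]]))
  } else {
    gl <- gene_lengths
  }
  missing <- setdiff(genes, names(gl))
  if (length(missing)) {
    abort(paste0("missing lengths for genes: ",
                 paste(utils::head(missing, 5), collapse = ", ")))
  }
  gl <- gl[genes]
  if (any(!is.finite(gl)) || any(gl <= 0)) abort("gene lengths must be positive")
  gl
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("'%s' must be a finite numeric scalar", name))
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    abort(sprintf("'%s' = %g is outside its allowed range", name, x))
  }
  invisible(TRUE)
}

# Round half away from zero (half-up), the presentation convention used in
# the report percentages; base round() rounds half to even.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
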