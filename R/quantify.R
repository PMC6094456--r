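#' Compute FPKM from fragment counts
#'
#' FPKM (fragments per kilobase of transcript per million mapped fragments)
#' is computed per gene and sample as
#' `count * 1e9 / (length_bp * library_size)`. Library sizes default to the
#' column sums of the count matrix; callers counting paired-end fragments
#' are responsible for supplying fragment (not read) totals.
#'
#' @param counts Wide tibble of non-negative integer counts
#'   (`gene_id` + one column per sample).
#' @param gene_lengths Tibble (`gene_id`, `length_bp`) or named vector of
#'   positive transcript lengths in bp; required for every gene in `counts`.
#' @param library_sizes Optional per-sample fragment totals (tibble
#'   `sample_id`, `fragments`, or named vector). Defaults to column sums.
#' @return Wide tibble of FPKM values with unit attribute `"fpkm"`.
#' @examples
#' counts <- tibble::tibble(gene_id = "g1", s1 = 10)
#' compute_fpkm(counts, c(g1 = 1000), c(s1 = 1e6))  # FPKM = 10
#' @export
compute_fpkm <- function(counts, gene_lengths, library_sizes = NULL) {
  m <- as_expr_matrix(counts)
  if (any(m < 0)) abort("counts must be non-negative")
  len <- resolve_gene_lengths(gene_lengths, rownames(m))
  if (is.null(library_sizes)) library_sizes <- colSums(m)
  lib <- resolve_library_sizes(library_sizes, colnames(m))
  fpkm <- m * 1e9 / outer(len, lib)
  expr_tibble(fpkm, unit = "fpkm")
}

#' Remove genes with low expression across most samples
#'
#' A gene is removed when its FPKM falls below `tau` in at least `max_low`
#' samples — with the defaults, below 0.3 in at least eight of ten tissues —
#' so genes expressed in even a few tissues are retained. Sample order and
#' the relative order of surviving genes are preserved.
#'
#' @param fpkm Wide FPKM tibble.
#' @param tau Low-expression threshold (FPKM), default 0.3.
#' @param max_low Minimum number of below-threshold samples that triggers
#'   removal, default 8.
#' @return Filtered FPKM tibble (a subset of the input rows).
#' @export
filter_low_expression <- function(fpkm, tau = 0.3, max_low = 8) {
  check_unit(fpkm, "fpkm", "filter_low_expression")
  check_scalar(tau, "tau", lower = 0)
  m <- as_expr_matrix(fpkm)
  if (max_low < 0 || max_low > ncol(m)) {
    abort("max_low must be between 0 and the number of samples")
  }
  n_low <- rowSums(m < tau)
  out <- fpkm[n_low < max_low, , drop = FALSE]
  attr(out, "unit") <- "fpkm"
  out
}

#' Count expressed genes per sample
#'
#' A gene counts as expressed in a sample when its FPKM is at least `tau`
#' (inclusive boundary: FPKM exactly `tau` is expressed).
#'
#' @param fpkm Wide FPKM tibble.
#' @param tau Expression threshold, default 0.3.
#' @return A tibble (`sample_id`, `n_expressed`, `mean_fpkm`) with one row
#'   per sample; `mean_fpkm` averages over all genes. The grand mean FPKM
#'   over the whole matrix is attached as attribute `"mean_fpkm"`.
#' @export
flag_expressed <- function(fpkm, tau = 0.3) {
  check_unit(fpkm, "fpkm", "flag_expressed")
  check_scalar(tau, "tau", lower = 0)
  m <- as_expr_matrix(fpkm)
  out <- tibble::tibble(
    sample_id = colnames(m),
    n_expressed = unname(colSums(m >= tau)),
    mean_fpkm = unname(colMeans(m))
  )
  attr(out, "mean_fpkm") <- mean(m)
  out
}

#' Log-transform an FPKM matrix
#'
#' Returns `log10(FPKM + pseudocount)`, the expression scale used for sample
#' clustering and network construction. Strictly monotone in FPKM.
#'
#' @param fpkm Wide FPKM tibble.
#' @param pseudocount Positive offset added before taking log10; default 1,
#'   so an FPKM of 0 maps to 0.
#' @return Wide tibble with unit attribute `"log_fpkm"`.
#' @export
log_transform <- function(fpkm, pseudocount = 1) {
  check_unit(fpkm, "fpkm", "log_transform")
  check_scalar(pseudocount, "pseudocount", lower = 0, strict_lower = TRUE)
  m <- as_expr_matrix(fpkm)
  if (any(m < 0)) abort("FPKM values must be non-negative")
  expr_tibble(log10(m + pseudocount), unit = "log_fpkm")
}
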