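#' Audic-Claverie exact p-value for two fragment counts
#'
#' Compares one gene's fragment count between two pooled libraries of known
#' total sizes. Given a count `x` in library 1, the conditional distribution
#' of the count `y` in library 2 has kernel
#' `p(k | x) = (N2/N1)^k (x+k)! / (x! k! (1 + N2/N1)^(x+k+1))`,
#' which is a negative binomial with `size = x + 1` and success probability
#' `N1 / (N1 + N2)`; tails are therefore evaluated through the stable
#' log-space negative-binomial CDF. The two-sided p-value doubles the
#' smaller inclusive tail and caps at 1, so `p` is in (0, 1]. Because the
#' kernel conditions on the first library's count, exchanging the libraries
#' can shift the p-value by one point mass of the discrete kernel; the
#' difference vanishes as counts grow.
#'
#' All arguments are vectorised and recycled.
#'
#' @param x,y Non-negative integer fragment counts in libraries 1 and 2.
#' @param n1,n2 Positive library totals (total mapped fragments).
#' @return Two-sided p-values in (0, 1].
#' @examples
#' audic_claverie_p(16, 0, 1e6, 1e6)
#' audic_claverie_p(5, 5, 1e6, 1e6)  # 1: y sits at the centre
#' @export
audic_claverie_p <- function(x, y, n1, n2) {
  n <- max(length(x), length(y), length(n1), length(n2))
  x <- rep_len(x, n); y <- rep_len(y, n)
  n1 <- rep_len(n1, n); n2 <- rep_len(n2, n)
  if (any(x < 0) || any(y < 0) || any(x != floor(x)) || any(y != floor(y))) {
    abort("counts must be non-negative integers")
  }
  if (any(n1 <= 0) || any(n2 <= 0)) abort("library sizes must be positive")
  q <- n1 / (n1 + n2)
  lower <- stats::pnbinom(y, size = x + 1, prob = q)
  upper <- ifelse(y == 0, 1,
                  stats::pnbinom(y - 1, size = x + 1, prob = q,
                                 lower.tail = FALSE))
  pmin(1, 2 * pmin(lower, upper))
}

#' Library-size-normalised log2 expression ratio
#'
#' `log2(((x + pseudocount) / n1) / ((y + pseudocount) / n2))`. The
#' pseudocount keeps the ratio finite for zero counts; the function is
#' antisymmetric under exchange of the two libraries.
#'
#' @inheritParams audic_claverie_p
#' @param pseudocount Positive offset added to both counts, default 1.
#' @return Vector of log2 ratios.
#' @export
log2_ratio <- function(x, y, n1, n2, pseudocount = 1) {
  check_scalar(pseudocount, "pseudocount", lower = 0, strict_lower = TRUE)
  log2(((x + pseudocount) / n1) / ((y + pseudocount) / n2))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment: with sorted p-values,
#' `q_(i) = min_(j >= i) (p_(j) * m / j)` capped at 1, returned in the
#' original order. Delegates to [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Call differentially expressed genes across pairwise library comparisons
#'
#' For each unordered sample pair, computes per gene the library-normalised
#' log2 ratio and the Audic-Claverie two-sided p, adjusts p within the
#' comparison by Benjamini-Hochberg, and flags genes with
#' `|log2 ratio| >= ratio_min` and `q < fdr_max` as differentially
#' expressed. The union across comparisons (genes differential in at least
#' one pair) is the gene set carried into network construction.
#'
#' @param counts Wide tibble of non-negative integer counts.
#' @param library_sizes Optional per-sample fragment totals; defaults to
#'   column sums of `counts`.
#' @param pairs Optional two-column data frame (`sample_a`, `sample_b`)
#'   restricting the comparisons; default all unordered pairs.
#' @param ratio_min Minimum absolute log2 ratio, default 1.
#' @param fdr_max FDR threshold (strict), default 0.05.
#' @param pseudocount Pseudocount for the log2 ratio, default 1.
#' @return A list with:
#'   \describe{
#'     \item{calls}{tibble with one row per (comparison, gene):
#'       `sample_a`, `sample_b`, `gene_id`, `x`, `y`, `log2_ratio`,
#'       `p`, `q`, `is_deg`.}
#'     \item{union}{character vector of genes differential in >= 1 comparison,
#'       in input gene order.}
#'   }
#' @export
call_degs <- function(counts, library_sizes = NULL, pairs = NULL,
                      ratio_min = 1, fdr_max = 0.05, pseudocount = 1) {
  m <- as_expr_matrix(counts)
  check_scalar(ratio_min, "ratio_min", lower = 0)
  check_scalar(fdr_max, "fdr_max", lower = 0, upper = 1, strict_lower = TRUE)
  if (is.null(library_sizes)) library_sizes <- colSums(m)
  lib <- resolve_library_sizes(library_sizes, colnames(m))
  samples <- colnames(m)
  if (is.null(pairs)) {
    idx <- utils::combn(samples, 2)
    pairs <- tibble::tibble(sample_a = idx[1, ], sample_b = idx[2, ])
  } else {
    pairs <- tibble::as_tibble(pairs)
    names(pairs)[1:2] <- c("sample_a", "sample_b")
    bad <- setdiff(c(pairs$sample_a, pairs$sample_b), samples)
    if (length(bad)) abort(paste("unknown samples in pairs:", paste(bad, collapse = ", ")))
  }
  if (nrow(pairs) < 1) abort("at least one comparison is required")

  calls <- purrr::pmap(pairs, function(sample_a, sample_b) {
    x <- m[, sample_a]; y <- m[, sample_b]
    n1 <- lib[[sample_a]]; n2 <- lib[[sample_b]]
    p <- audic_claverie_p(x, y, n1, n2)
    lr <- log2_ratio(x, y, n1, n2, pseudocount)
    q <- bh_fdr(p)
    tibble::tibble(
      sample_a = sample_a, sample_b = sample_b,
      gene_id = rownames(m), x = x, y = y,
      log2_ratio = lr, p = p, q = q,
      is_deg = abs(lr) >= ratio_min & q < fdr_max
    )
  }) |> dplyr::bind_rows()

  deg_genes <- unique(calls$gene_id[calls$is_deg])
  list(calls = calls,
       union = rownames(m)[rownames(m) %in% deg_genes])
}
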