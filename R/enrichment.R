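#' Hypergeometric upper-tail p-value for over-representation
#'
#' Probability of observing at least `k` annotated genes when drawing `n`
#' genes from a universe of `N` containing `K` annotated ones:
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`. Evaluated through the
#' stable log-space hypergeometric CDF (the `phyper` upper tail of
#' `k - 1`), so the inclusive-tail convention is explicit.
#'
#' @param k Observed overlap (module genes carrying the pathway).
#' @param K Universe genes carrying the pathway.
#' @param n Module genes in the universe.
#' @param N Universe size.
#' @return Upper-tail p-value(s) in (0, 1].
#' @examples
#' hypergeom_upper_p(5, 5, 5, 20)  # 1 / choose(20, 5)
#' @export
hypergeom_upper_p <- function(k, K, n, N) {
  len <- max(length(k), length(K), length(n), length(N))
  k <- rep_len(k, len); K <- rep_len(K, len)
  n <- rep_len(n, len); N <- rep_len(N, len)
  if (any(k < 0) || any(K > N) || any(n > N) || any(k > pmin(n, K))) {
    abort("inconsistent hypergeometric counts")
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Build a gene annotation object
#'
#' Normalises a two-column (gene, pathway) table into the structure used by
#' [enrich_modules()], checking that annotated genes fall inside the chosen
#' universe.
#'
#' @param annotation Two-column data frame: gene id, pathway id.
#' @param universe Optional character vector of background genes; defaults
#'   to all annotated genes.
#' @return A list of class `gene_annotation`: `table` (tibble `gene_id`,
#'   `pathway`), `universe`.
#' @export
gene_annotation <- function(annotation, universe = NULL) {
  annotation <- tibble::as_tibble(annotation)
  if (ncol(annotation) < 2) abort("annotation needs two columns: gene, pathway")
  names(annotation)[1:2] <- c("gene_id", "pathway")
  annotation <- dplyr::distinct(annotation[, c("gene_id", "pathway")])
  if (nrow(annotation) == 0) abort("annotation is empty")
  if (is.null(universe)) universe <- unique(annotation$gene_id)
  outside <- setdiff(annotation$gene_id, universe)
  if (length(outside)) annotation <- annotation[annotation$gene_id %in% universe, ]
  structure(list(table = annotation, universe = universe),
            class = "gene_annotation")
}

#' Test modules for pathway over-representation
#'
#' For every (module, pathway) pair with at least one overlapping gene,
#' computes the hypergeometric upper-tail p-value of the overlap against
#' the background universe, adjusts by Benjamini-Hochberg (pooled across
#' all tests by default, or within each module), and flags rows with
#' `q < q_max`. The `"unassigned"` pool is never tested.
#'
#' @param partition Partition tibble (`gene_id`, `module`).
#' @param annotation A `gene_annotation` object or a two-column (gene,
#'   pathway) data frame.
#' @param q_max FDR threshold (strict), default 0.05.
#' @param universe `"network"` (default): background = annotated genes that
#'   entered the network; `"annotation"`: all annotated genes.
#' @param family `"pooled"` (default) or `"per-module"` BH family.
#' @return A tibble (`module`, `pathway`, `k`, `n`, `K`, `N`, `p`, `q`,
#'   `significant`) sorted by `q` then `p`.
#' @export
enrich_modules <- function(partition, annotation, q_max = 0.05,
                           universe = c("network", "annotation"),
                           family = c("pooled", "per-module")) {
  universe <- match.arg(universe)
  family <- match.arg(family)
  check_scalar(q_max, "q_max", lower = 0, upper = 1, strict_lower = TRUE)
  if (!inherits(annotation, "gene_annotation")) {
    annotation <- gene_annotation(annotation)
  }
  ann <- annotation$table
  bg <- switch(universe,
               network = intersect(annotation$universe, partition$gene_id),
               annotation = annotation$universe)
  if (length(bg) == 0) abort("empty background universe")
  ann <- ann[ann$gene_id %in% bg, ]
  N <- length(bg)
  path_sizes <- table(ann$pathway)

  mods <- setdiff(unique(partition$module), "unassigned")
  rows <- purrr::map(mods, function(mod) {
    mod_genes <- intersect(partition$gene_id[partition$module == mod], bg)
    n <- length(mod_genes)
    if (n == 0) return(NULL)
    overlap <- table(ann$pathway[ann$gene_id %in% mod_genes])
    if (length(overlap) == 0) return(NULL)
    tibble::tibble(
      module = mod,
      pathway = names(overlap),
      k = as.integer(overlap),
      n = n,
      K = as.integer(path_sizes[names(overlap)]),
      N = N
    )
  }) |> dplyr::bind_rows()
  if (nrow(rows) == 0) abort("no module/pathway overlaps to test")
  rows$p <- hypergeom_upper_p(rows$k, rows$K, rows$n, rows$N)
  rows <- if (family == "pooled") {
    dplyr::mutate(rows, q = bh_fdr(.data$p))
  } else {
    rows |> dplyr::group_by(.data$module) |>
      dplyr::mutate(q = bh_fdr(.data$p)) |> dplyr::ungroup()
  }
  rows |>
    dplyr::mutate(significant = .data$q < q_max) |>
    dplyr::arrange(.data$q, .data$p, .data$module, .data$pathway)
}
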