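#' Fit a weighted gene co-expression network
#'
#' One-call wrapper over the network stage: correlation, soft-thresholded
#' adjacency, topological overlap, average-linkage gene clustering, static
#' module cut with size filter, eigengene-based module merging, eigengene
#' computation, intramodular connectivity and hub selection.
#'
#' @param log_expr Wide tibble of log10(FPKM + 1) values
#'   (`gene_id` + samples), typically the differential genes.
#' @param power Soft threshold, default 30.
#' @param mode `"unsigned"` or `"signed"` network.
#' @param min_module_size Minimum module size, default 30.
#' @param merge_cut Eigengene dissimilarity below which modules merge,
#'   default 0.25.
#' @param cut_fraction Dendrogram cut height as a fraction of the maximum
#'   merge height, default 0.99.
#' @param top_fraction Hub fraction per module, default 0.02.
#' @return An object of class `coexpression_fit`: a list with `partition`,
#'   `eigengenes` (the [module_eigengenes()] list), `connectivity`, `hubs`,
#'   `adjacency`, `tom`, `dendrogram`, `sample_ids` and the parameters.
#' @seealso [tidy.coexpression_fit()], [glance.coexpression_fit()]
#' @export
fit_coexpression <- function(log_expr, power = 30,
                             mode = c("unsigned", "signed"),
                             min_module_size = 30, merge_cut = 0.25,
                             cut_fraction = 0.99, top_fraction = 0.02) {
  mode <- match.arg(mode)
  corr <- gene_correlation(log_expr)
  kept <- rownames(corr)
  log_expr <- log_expr[match(kept, log_expr$gene_id), ]
  adj <- adjacency_matrix(corr, power = power, mode = mode)
  tom <- tom_similarity(adj)
  dendro <- cluster_genes(1 - tom)
  part <- cut_modules(dendro, min_module_size = min_module_size,
                      cut_fraction = cut_fraction)
  part <- merge_close_modules(log_expr, part, merge_cut = merge_cut)
  eig <- module_eigengenes(log_expr, part)
  conn <- intramodular_connectivity(adj, part)
  hubs <- select_hubs(conn, top_fraction = top_fraction)
  structure(list(
    partition = part, eigengenes = eig, connectivity = conn, hubs = hubs,
    adjacency = adj, tom = tom, dendrogram = dendro,
    sample_ids = setdiff(names(log_expr), "gene_id"),
    params = list(power = power, mode = mode,
                  min_module_size = min_module_size, merge_cut = merge_cut,
                  cut_fraction = cut_fraction, top_fraction = top_fraction)
  ), class = "coexpression_fit")
}

#' @export
print.coexpression_fit <- function(x, ...) {
  g <- glance(x)
  cat("Weighted gene co-expression network\n")
  cat(sprintf("  %d genes x %d samples, power = %g (%s)\n",
              g$n_genes, g$n_samples, x$params$power, x$params$mode))
  cat(sprintf("  %d modules (sizes %d..%d), %d unassigned (%.2f%% assigned)\n",
              g$n_modules, g$min_module_size, g$max_module_size,
              g$n_unassigned, g$pct_assigned))
  invisible(x)
}

#' Tidy a co-expression fit into a per-gene tibble
#'
#' @param x A `coexpression_fit`.
#' @param ... Unused.
#' @return A tibble (`gene_id`, `module`, `k_within`, `rank`, `is_hub`).
#' @export
tidy.coexpression_fit <- function(x, ...) {
  hubs <- paste(x$hubs$module, x$hubs$gene_id)
  x$connectivity |>
    dplyr::mutate(is_hub = paste(.data$module, .data$gene_id) %in% hubs)
}

#' One-row summary of a co-expression fit
#'
#' @param x A `coexpression_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `n_genes`, `n_samples`, `n_modules`,
#'   `min_module_size`, `max_module_size`, `n_unassigned`, `pct_assigned`
#'   (half-up to 2 decimals), `n_hubs`.
#' @export
glance.coexpression_fit <- function(x, ...) {
  sizes <- table(x$partition$module[x$partition$module != "unassigned"])
  n_un <- sum(x$partition$module == "unassigned")
  n_tot <- nrow(x$partition)
  tibble::tibble(
    n_genes = n_tot,
    n_samples = length(x$sample_ids),
    n_modules = length(sizes),
    min_module_size = if (length(sizes)) min(sizes) else NA_integer_,
    max_module_size = if (length(sizes)) max(sizes) else NA_integer_,
    n_unassigned = n_un,
    pct_assigned = round_half_up(100 * (n_tot - n_un) / n_tot, 2),
    n_hubs = nrow(x$hubs)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
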