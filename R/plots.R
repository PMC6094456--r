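#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_text geom_point
#'   geom_line geom_col geom_hline scale_fill_gradient2 labs theme_minimal
#'   facet_wrap element_text theme
NULL

#' Heatmap of module-trait correlations
#'
#' The module-trait relationship grid: one tile per (module, trait) cell,
#' coloured by the correlation coefficient and annotated with `r` and its
#' p-value.
#'
#' @param object A `module_trait_result` from [relate_modules()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.module_trait_result <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$label <- sprintf("%.2f\n(%.0e)", df$r, df$p)
  ggplot(df, aes(x = .data$trait, y = .data$module, fill = .data$r)) +
    geom_tile(colour = "grey70") +
    geom_text(aes(label = .data$label), size = 2.6) +
    scale_fill_gradient2(low = "#3b4cc0", mid = "white", high = "#b40426",
                         limits = c(-1, 1)) +
    labs(x = "metabolite trait", y = "module", fill = "r",
         title = "Module-trait relationships") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}

#' Soft-threshold diagnostics plot
#'
#' Signed scale-free R-squared and mean connectivity against candidate
#' powers, as produced by [pick_soft_threshold()].
#'
#' @param diagnostics The `diagnostics` tibble from [pick_soft_threshold()].
#' @param r2_min Reference line for the R-squared requirement, default 0.8.
#' @return A ggplot object.
#' @export
plot_soft_threshold <- function(diagnostics, r2_min = 0.8) {
  df <- diagnostics |>
    tidyr::pivot_longer(c("r_squared", "mean_k"),
                        names_to = "metric", values_to = "value") |>
    dplyr::mutate(metric = dplyr::recode(.data$metric,
                                         r_squared = "signed scale-free R²",
                                         mean_k = "mean connectivity"))
  ref <- tibble::tibble(metric = "signed scale-free R²", y = r2_min)
  ggplot(df, aes(x = .data$power, y = .data$value)) +
    geom_point() + geom_line() +
    geom_hline(data = ref, aes(yintercept = .data$y), linetype = 2) +
    facet_wrap(~metric, scales = "free_y") +
    labs(x = "soft threshold (power)", y = NULL,
         title = "Scale-free topology scan") +
    theme_minimal()
}

#' Module overview plot for a co-expression fit
#'
#' Bar chart of module sizes (hub counts overlaid) for a fitted network.
#'
#' @param object A `coexpression_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coexpression_fit <- function(object, ...) {
  sizes <- object$partition |>
    dplyr::count(.data$module, name = "n_genes") |>
    dplyr::left_join(dplyr::count(object$hubs, .data$module, name = "n_hubs"),
                     by = "module") |>
    dplyr::mutate(n_hubs = dplyr::coalesce(.data$n_hubs, 0L))
  ggplot(sizes, aes(x = stats::reorder(.data$module, -.data$n_genes),
                    y = .data$n_genes)) +
    geom_col(fill = "grey65") +
    geom_text(aes(label = .data$n_hubs), vjust = -0.3, size = 3) +
    labs(x = "module", y = "genes",
         title = "Module sizes (hub counts above bars)") +
    theme_minimal()
}

#' Eigengene profiles across samples
#'
#' Line plot of each module eigengene across the samples, the summary
#' profile that is correlated with the metabolite traits.
#'
#' @param fit A `coexpression_fit` or the list from [module_eigengenes()].
#' @return A ggplot object.
#' @export
plot_eigengenes <- function(fit) {
  me <- if (inherits(fit, "coexpression_fit")) fit$eigengenes$eigengenes
        else fit$eigengenes
  df <- expr_tibble(me) |>
    dplyr::rename(module = "gene_id") |>
    tidyr::pivot_longer(-"module", names_to = "sample_id", values_to = "eigengene")
  df$sample_id <- factor(df$sample_id, levels = colnames(me))
  ggplot(df, aes(x = .data$sample_id, y = .data$eigengene,
                 group = .data$module, colour = .data$module)) +
    geom_line() + geom_point(size = 1) +
    labs(x = "sample", y = "eigengene", colour = "module",
         title = "Module eigengene profiles") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
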