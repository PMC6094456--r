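#' Pearson product-moment correlation
#'
#' Thin, validated wrapper around [stats::cor()] for two sample vectors.
#'
#' @param a,b Numeric vectors of equal length >= 3 with nonzero variance.
#' @return The correlation coefficient in \[-1, 1\].
#' @export
pearson_r <- function(a, b) {
  if (length(a) != length(b)) abort("vectors must have equal length")
  if (length(a) < 3) abort("correlation needs at least 3 observations")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) abort("zero-variance input")
  stats::cor(a, b)
}

#' Two-sided p-value for a Pearson correlation (Student-t form)
#'
#' Tests the null of zero correlation with
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` degrees of freedom.
#' `|r| = 1` returns 0 by convention (with a warning), since the t statistic
#' diverges.
#'
#' @param r Correlation coefficient(s) in \[-1, 1\].
#' @param n Number of paired samples (>= 3).
#' @return Two-sided p-value(s).
#' @examples
#' correlation_p_student(0.98275, 10)  # ~3.8e-7
#' @export
correlation_p_student <- function(r, n) {
  if (any(n < 3)) abort("n must be >= 3")
  if (any(abs(r) > 1)) abort("|r| must be <= 1")
  p <- rep(0, length(r))
  ok <- abs(r) < 1
  if (any(!ok)) warn("|r| = 1: returning p = 0 by convention")
  t <- r[ok] * sqrt(n - 2) / sqrt(1 - r[ok]^2)
  p[ok] <- 2 * stats::pt(abs(t), df = n - 2, lower.tail = FALSE)
  p
}

#' Fisher-Z asymptotic confidence interval for a correlation
#'
#' `z = atanh(r)` has approximate standard error `1 / sqrt(n - 3)`; the
#' interval `tanh(z +/- z_crit / sqrt(n - 3))` always lies inside (-1, 1).
#'
#' @param r Correlation coefficient with `|r| < 1`.
#' @param n Number of paired samples (>= 4).
#' @param level Confidence level, default 0.95.
#' @return Named numeric vector `c(ci_low, ci_high)`.
#' @export
fisher_z_interval <- function(r, n, level = 0.95) {
  if (n < 4) abort("the Fisher-Z interval needs n >= 4")
  if (abs(r) >= 1) abort("|r| must be < 1")
  check_scalar(level, "level", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  z <- atanh(r)
  hw <- stats::qnorm(1 - (1 - level) / 2) / sqrt(n - 3)
  c(ci_low = tanh(z - hw), ci_high = tanh(z + hw))
}

#' Correlate module eigengenes with metabolite traits
#'
#' Produces the full module x trait grid of Pearson correlations with
#' Student-t p-values, Benjamini-Hochberg q per trait, and Fisher-Z 95%
#' confidence bounds — the module-trait relationship table.
#'
#' @param eigengenes Module x sample eigengene matrix (rows named by module),
#'   or the list returned by [module_eigengenes()].
#' @param traits Tibble with `sample_id` first and one numeric column per
#'   trait; samples must match the eigengene columns.
#' @param level Confidence level for the Fisher-Z interval, default 0.95.
#' @return A tibble of class `module_trait_result` with columns `module`,
#'   `trait`, `r`, `p`, `q`, `ci_low`, `ci_high` and attribute `n` (sample
#'   count). Zero-variance traits are skipped with a warning.
#' @export
relate_modules <- function(eigengenes, traits, level = 0.95) {
  if (is.list(eigengenes) && !is.matrix(eigengenes)) {
    eigengenes <- eigengenes$eigengenes
  }
  traits <- tibble::as_tibble(traits)
  if (!"sample_id" %in% names(traits)) abort("traits must have a 'sample_id' column")
  if (!setequal(traits$sample_id, colnames(eigengenes))) {
    abort("samples differ between eigengenes and traits")
  }
  tm <- as.matrix(traits[match(colnames(eigengenes), traits$sample_id),
                         setdiff(names(traits), "sample_id")])
  keep <- apply(tm, 2, stats::sd) > 0
  if (any(!keep)) {
    warn(paste("skipping zero-variance trait(s):",
               paste(colnames(tm)[!keep], collapse = ", ")))
    tm <- tm[, keep, drop = FALSE]
  }
  n <- ncol(eigengenes)
  grid <- tidyr::expand_grid(module = rownames(eigengenes),
                             trait = colnames(tm))
  res <- purrr::pmap(grid, function(module, trait) {
    r <- stats::cor(eigengenes[module, ], tm[, trait])
    ci <- if (abs(r) < 1) fisher_z_interval(r, n, level) else c(r, r)
    tibble::tibble(module = module, trait = trait, r = r,
                   p = correlation_p_student(r, n),
                   ci_low = ci[[1]], ci_high = ci[[2]])
  }) |> dplyr::bind_rows()
  res <- res |>
    dplyr::group_by(.data$trait) |>
    dplyr::mutate(q = bh_fdr(.data$p)) |>
    dplyr::ungroup() |>
    dplyr::select("module", "trait", "r", "p", "q", "ci_low", "ci_high")
  attr(res, "n") <- n
  class(res) <- c("module_trait_result", class(res))
  res
}

#' Classify content-related and highly significant modules
#'
#' A module is *content-related* when its eigengene correlates with at least
#' one trait at raw `p < alpha`; it is *highly significant* when
#' additionally `|r| >= strong_r` for such a trait. Highly significant
#' modules are by construction a subset of content-related ones. Both
#' inequalities on p are strict.
#'
#' @param result A `module_trait_result` from [relate_modules()].
#' @param alpha Significance level, default 0.05.
#' @param strong_r Minimum absolute correlation for the highly significant
#'   class, default 0.8.
#' @return A list: `content_related` and `highly_significant` (character
#'   vectors of module labels) plus `table`, a per-module summary tibble
#'   (`module`, `best_trait`, `best_r`, `best_p`, `content_related`,
#'   `highly_significant`).
#' @export
classify_modules <- function(result, alpha = 0.05, strong_r = 0.8) {
  check_scalar(alpha, "alpha", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  check_scalar(strong_r, "strong_r", lower = 0, upper = 1)
  tab <- result |>
    dplyr::group_by(.data$module) |>
    dplyr::summarise(
      best_trait = .data$trait[which.min(.data$p)][1],
      best_r = .data$r[which.min(.data$p)][1],
      best_p = min(.data$p),
      content_related = any(.data$p < alpha),
      highly_significant = any(.data$p < alpha & abs(.data$r) >= strong_r),
      .groups = "drop"
    )
  list(content_related = tab$module[tab$content_related],
       highly_significant = tab$module[tab$highly_significant],
       table = tab)
}

#' Gene-level trait correlations
#'
#' Correlates the expression profiles of selected genes (typically hubs)
#' with each trait — the per-gene analogue of the module-trait grid.
#'
#' @param log_expr Wide tibble of log10(FPKM + 1) values.
#' @param genes Character vector of gene ids present in `log_expr`.
#' @param traits Tibble with `sample_id` first and one column per trait.
#' @return A tibble (`gene_id`, `trait`, `r`, `p`); gene/trait pairs where
#'   either profile has zero variance are skipped with a warning.
#' @export
gene_trait_significance <- function(log_expr, genes, traits) {
  m <- as_expr_matrix(log_expr)
  unknown <- setdiff(genes, rownames(m))
  if (length(unknown)) {
    abort(paste("unknown gene ids:", paste(utils::head(unknown, 5), collapse = ", ")))
  }
  traits <- tibble::as_tibble(traits)
  tm <- as.matrix(traits[match(colnames(m), traits$sample_id),
                         setdiff(names(traits), "sample_id")])
  n <- ncol(m)
  grid <- tidyr::expand_grid(gene_id = genes, trait = colnames(tm))
  skipped <- 0L
  out <- purrr::pmap(grid, function(gene_id, trait) {
    x <- m[gene_id, ]; y <- tm[, trait]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      skipped <<- skipped + 1L
      return(NULL)
    }
    r <- stats::cor(x, y)
    tibble::tibble(gene_id = gene_id, trait = trait, r = r,
                   p = correlation_p_student(r, n))
  }) |> dplyr::bind_rows()
  if (skipped > 0) warn(sprintf("skipped %d zero-variance gene/trait pair(s)", skipped))
  out
}
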