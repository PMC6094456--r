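pipeline_defaults <- function() {
  list(
    tau = 0.3, max_low = 8, pseudocount = 1,
    ratio_min = 1, fdr_max = 0.05,
    power = 30, mode = "unsigned", min_module_size = 30, merge_cut = 0.25,
    cut_fraction = 0.99, top_fraction = 0.02,
    alpha = 0.05, strong_r = 0.8,
    q_max = 0.05, universe = "network", family = "pooled",
    edge_min = 0.15,
    seed = 1L
  )
}

#' Pipeline configuration
#'
#' Collects every stage parameter with its default (FPKM filter tau = 0.3
#' below in >= 8 samples; DEG thresholds |log2 ratio| >= 1 and FDR < 0.05;
#' soft threshold 30; minimum module size 30; eigengene merge cut 0.25;
#' module-trait alpha 0.05 and strong-correlation bound 0.8; top 2% hubs;
#' enrichment q < 0.05) plus the seed. Unknown keys are rejected.
#'
#' @param ... Named overrides of the defaults listed above.
#' @param sim Optional [sim_config()]; when supplied (or when no input
#'   tables are given to [run_pipeline()]) the pipeline simulates its
#'   inputs. Its seed is kept in sync with `seed` unless set explicitly.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(..., sim = NULL) {
  cfg <- pipeline_defaults()
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    abort(paste("unknown configuration keys:", paste(unknown, collapse = ", ")))
  }
  cfg[names(over)] <- over
  check_scalar(cfg$tau, "tau", lower = 0)
  check_scalar(cfg$fdr_max, "fdr_max", lower = 0, upper = 1, strict_lower = TRUE)
  check_scalar(cfg$power, "power", lower = 1)
  check_scalar(cfg$merge_cut, "merge_cut", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  check_scalar(cfg$alpha, "alpha", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  check_scalar(cfg$top_fraction, "top_fraction", lower = 0, upper = 1,
               strict_lower = TRUE)
  check_scalar(cfg$edge_min, "edge_min", lower = 0, upper = 1)
  if (is.null(sim)) sim <- sim_config(seed = cfg$seed)
  cfg$sim <- sim
  structure(cfg, class = "pipeline_config")
}

#' Percentage summary table for annotation counts
#'
#' Report arithmetic for assembly/annotation summaries: each category is
#' expressed as `100 * count / total`, rounded half-up to two decimals.
#' When `total_bases` is supplied the mean sequence length
#' `total_bases / total`, rounded half-up to the nearest integer, is
#' attached as attribute `"mean_length"`.
#'
#' @param counts Named integer vector (or single count) per category.
#' @param total Positive total used as the denominator.
#' @param total_bases Optional total base count for the mean-length summary.
#' @return A tibble (`item`, `count`, `percentage`).
#' @examples
#' summarize_annotation(c(annotated = 63464), 87319)  # 72.68%
#' @export
summarize_annotation <- function(counts, total, total_bases = NULL) {
  if (total <= 0) abort("total must be positive")
  if (any(counts < 0) || any(counts > total)) {
    abort("category counts must lie in [0, total]")
  }
  items <- if (is.null(names(counts))) as.character(seq_along(counts)) else names(counts)
  out <- tibble::tibble(
    item = items,
    count = as.vector(counts),
    percentage = round_half_up(100 * as.vector(counts) / total, 2)
  )
  if (!is.null(total_bases)) {
    attr(out, "mean_length") <- round_half_up(total_bases / total, 0)
  }
  out
}

#' Export the weighted network as edge lists
#'
#' Writes every undirected gene pair with `TOM >= edge_min` once
#' (`gene_a < gene_b` lexicographically) both as a TSV
#' (`gene_a`, `gene_b`, `weight`, `same_module`) and as SIF lines
#' (`gene_a co gene_b`) for network-visualisation tools.
#'
#' @param tom TOM matrix.
#' @param partition Partition tibble (`gene_id`, `module`).
#' @param edge_min Minimum TOM weight in \[0, 1\].
#' @param path Output path prefix; writes `<path>.tsv` and `<path>.sif`.
#'   `NULL` (default) writes nothing.
#' @return The edge tibble, invisibly when `path` is given.
#' @export
export_edges <- function(tom, partition, edge_min, path = NULL) {
  check_scalar(edge_min, "edge_min", lower = 0, upper = 1)
  genes <- rownames(tom)
  ord <- order(genes)
  tom <- tom[ord, ord]
  genes <- genes[ord]
  keep <- which(upper.tri(tom) & tom >= edge_min, arr.ind = TRUE)
  mod <- setNames(partition$module, partition$gene_id)
  edges <- tibble::tibble(
    gene_a = genes[keep[, 1]],
    gene_b = genes[keep[, 2]],
    weight = tom[keep],
    same_module = mod[genes[keep[, 1]]] == mod[genes[keep[, 2]]]
  ) |> dplyr::arrange(.data$gene_a, .data$gene_b)
  if (!is.null(path)) {
    readr::write_tsv(edges, paste0(path, ".tsv"))
    writeLines(sprintf("%s co %s", edges$gene_a, edges$gene_b),
               paste0(path, ".sif"))
    return(invisible(edges))
  }
  edges
}

read_wide_tsv <- function(path, unit = NULL) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  names(tbl)[1] <- "gene_id"
  if (!is.null(unit)) attr(tbl, "unit") <- unit
  tbl
}

#' Run the full metabolite-module pipeline
#'
#' Executes the stages in order — simulate (when no inputs are supplied),
#' quantify (FPKM, low-expression filter, log10 transform), differential
#' expression (all pairwise Audic-Claverie comparisons, DEG union), network
#' (co-expression fit on the DEG union), module-trait correlation and
#' classification, pathway enrichment — writing every stage artifact as TSV
#' under `out_dir` and returning a run report.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param counts,gene_lengths,library_sizes,traits,annotation Optional input
#'   tables (tibbles) or TSV paths; when all are `NULL` the synthetic
#'   generator supplies them from `config$sim`.
#' @return A list of class `pipeline_report`: per-stage counts (genes in,
#'   genes after filtering, DEG union size, module count and size range,
#'   unassigned count, percent of DEGs assigned to modules, content-related
#'   and highly significant module counts, hub count, significant enrichment
#'   rows), the parameter echo, and per-stage wall times (seconds).
#' @export
run_pipeline <- function(config, out_dir,
                         counts = NULL, gene_lengths = NULL,
                         library_sizes = NULL, traits = NULL,
                         annotation = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  report <- list(params = unclass(config)[setdiff(names(config), "sim")])

  # -- simulate ---------------------------------------------------------
  t0 <- tic()
  if (is.null(counts)) {
    sim <- simulate_dataset(config$sim)
    counts <- sim$counts
    gene_lengths <- sim$gene_lengths
    library_sizes <- sim$library_sizes
    traits <- sim$traits
    annotation <- sim$annotation
    readr::write_tsv(sim$truth$gene_module, file.path(out_dir, "truth_modules.tsv"))
    readr::write_tsv(counts, file.path(out_dir, "counts.tsv"))
    readr::write_tsv(gene_lengths, file.path(out_dir, "gene_lengths.tsv"))
    readr::write_tsv(library_sizes, file.path(out_dir, "library_sizes.tsv"))
    readr::write_tsv(traits, file.path(out_dir, "traits.tsv"))
    readr::write_tsv(annotation, file.path(out_dir, "annotation.tsv"))
  } else {
    if (is.character(counts)) counts <- read_wide_tsv(counts, unit = "count")
    if (is.character(gene_lengths)) {
      gene_lengths <- readr::read_tsv(gene_lengths, show_col_types = FALSE)
    }
    if (is.character(library_sizes)) {
      library_sizes <- readr::read_tsv(library_sizes, show_col_types = FALSE)
    }
    if (is.character(traits)) traits <- readr::read_tsv(traits, show_col_types = FALSE)
    if (is.character(annotation)) {
      annotation <- readr::read_tsv(annotation, show_col_types = FALSE)
    }
  }
  timings["simulate"] <- tic() - t0
  report$n_genes_in <- nrow(counts)
  report$n_samples <- ncol(counts) - 1L

  # -- quantify ---------------------------------------------------------
  t0 <- tic()
  fpkm <- compute_fpkm(counts, gene_lengths, library_sizes)
  fpkm_f <- filter_low_expression(fpkm, tau = config$tau, max_low = config$max_low)
  expressed <- flag_expressed(fpkm_f, tau = config$tau)
  log_expr <- log_transform(fpkm_f, pseudocount = config$pseudocount)
  readr::write_tsv(fpkm_f, file.path(out_dir, "fpkm_filtered.tsv"))
  readr::write_tsv(expressed, file.path(out_dir, "expressed_per_sample.tsv"))
  readr::write_tsv(log_expr, file.path(out_dir, "log_fpkm.tsv"))
  timings["quantify"] <- tic() - t0
  report$n_genes_filtered <- nrow(fpkm_f)

  # -- differential expression -----------------------------------------
  t0 <- tic()
  keep <- counts$gene_id %in% fpkm_f$gene_id
  degs <- call_degs(counts[keep, ], library_sizes = library_sizes,
                    ratio_min = config$ratio_min, fdr_max = config$fdr_max,
                    pseudocount = config$pseudocount)
  readr::write_tsv(degs$calls, file.path(out_dir, "deg_calls.tsv"))
  readr::write_tsv(tibble::tibble(gene_id = degs$union),
                   file.path(out_dir, "deg_union.tsv"))
  timings["deg"] <- tic() - t0
  report$n_deg_union <- length(degs$union)
  if (length(degs$union) < 3) abort("fewer than 3 differential genes; cannot build a network")

  # -- network ----------------------------------------------------------
  t0 <- tic()
  net_expr <- log_expr[log_expr$gene_id %in% degs$union, ]
  fit <- fit_coexpression(net_expr, power = config$power, mode = config$mode,
                          min_module_size = config$min_module_size,
                          merge_cut = config$merge_cut,
                          cut_fraction = config$cut_fraction,
                          top_fraction = config$top_fraction)
  readr::write_tsv(tidy(fit), file.path(out_dir, "partition.tsv"))
  readr::write_tsv(expr_tibble(fit$eigengenes$eigengenes) |>
                     dplyr::rename(module = "gene_id"),
                   file.path(out_dir, "eigengenes.tsv"))
  export_edges(fit$tom, fit$partition, config$edge_min,
               path = file.path(out_dir, "edges"))
  timings["network"] <- tic() - t0
  g <- glance(fit)
  report$n_modules <- g$n_modules
  report$module_size_range <- c(g$min_module_size, g$max_module_size)
  report$n_unassigned <- g$n_unassigned
  report$pct_deg_assigned <- g$pct_assigned
  report$n_hubs <- g$n_hubs

  # -- module-trait relationships --------------------------------------
  t0 <- tic()
  mt <- relate_modules(fit$eigengenes, traits)
  cls <- classify_modules(mt, alpha = config$alpha, strong_r = config$strong_r)
  hub_tr <- gene_trait_significance(net_expr, fit$hubs$gene_id, traits)
  readr::write_tsv(mt, file.path(out_dir, "module_trait.tsv"))
  readr::write_tsv(cls$table, file.path(out_dir, "module_classification.tsv"))
  readr::write_tsv(hub_tr, file.path(out_dir, "hub_trait.tsv"))
  timings["relate"] <- tic() - t0
  report$n_content_related <- length(cls$content_related)
  report$n_highly_significant <- length(cls$highly_significant)

  # -- enrichment -------------------------------------------------------
  t0 <- tic()
  enr <- enrich_modules(fit$partition, annotation, q_max = config$q_max,
                        universe = config$universe, family = config$family)
  readr::write_tsv(enr, file.path(out_dir, "enrichment.tsv"))
  timings["enrich"] <- tic() - t0
  report$n_enriched <- sum(enr$significant)

  report$timings <- timings
  # consistency: module sizes + unassigned must account for every network gene
  stopifnot(sum(table(fit$partition$module)) == nrow(fit$partition))
  report_tbl <- tibble::tibble(
    key = c("n_genes_in", "n_genes_filtered", "n_deg_union", "n_modules",
            "min_module_size", "max_module_size", "n_unassigned",
            "pct_deg_assigned", "n_content_related", "n_highly_significant",
            "n_hubs", "n_enriched"),
    value = c(report$n_genes_in, report$n_genes_filtered, report$n_deg_union,
              report$n_modules, report$module_size_range[1],
              report$module_size_range[2], report$n_unassigned,
              report$pct_deg_assigned, report$n_content_related,
              report$n_highly_significant, report$n_hubs, report$n_enriched)
  )
  readr::write_tsv(report_tbl, file.path(out_dir, "report.tsv"))
  structure(report, class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline run report\n")
  cat(sprintf("  genes in: %d; after low-expression filter: %d\n",
              x$n_genes_in, x$n_genes_filtered))
  cat(sprintf("  DEG union: %d; modules: %d (sizes %d..%d); unassigned: %d (%.2f%% assigned)\n",
              x$n_deg_union, x$n_modules, x$module_size_range[1],
              x$module_size_range[2], x$n_unassigned, x$pct_deg_assigned))
  cat(sprintf("  content-related modules: %d; highly significant: %d; hubs: %d; enriched pathways: %d\n",
              x$n_content_related, x$n_highly_significant, x$n_hubs, x$n_enriched))
  invisible(x)
}
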