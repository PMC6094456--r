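#' Configuration for the synthetic tissue-expression generator
#'
#' Builds and validates the configuration object consumed by
#' [simulate_expression()], [simulate_traits()] and [simulate_annotation()].
#' The generator emulates the design of a pooled-library tissue panel: one
#' sequencing library per tissue (default 10 tissues), thousands of genes,
#' planted co-expression modules driven by latent per-module sample profiles
#' ("eigengenes"), metabolite traits generated as noisy linear functions of
#' chosen eigengenes, and pathway labels enriched in chosen modules.
#'
#' @param n_genes Total number of genes.
#' @param n_samples Number of samples (tissues); defaults to 10.
#' @param module_sizes Integer vector of genes per planted module; genes not
#'   covered are unstructured background. `sum(module_sizes) <= n_genes`.
#' @param within_module_cor Target absolute gene-eigengene correlation in
#'   (0, 1]. Loadings are scaled so the expected |correlation| of a module
#'   gene with its latent eigengene equals this value.
#' @param noise_sd Log-scale residual standard deviation (>= 0).
#' @param trait_couplings Data frame with columns `trait`, `module`,
#'   `coupling`, `noise_sd`: each trait is `coupling * eigengene + noise`,
#'   shifted to be non-negative. Defaults to eight metabolite traits
#'   (C, GC, EC, EGC, ECG, EGCG, theanine, caffeine) coupled to the planted
#'   modules, two of them with negative sign.
#' @param n_pathways Number of pathway labels.
#' @param pathway_base_prob Baseline per-gene probability of carrying any
#'   given pathway label.
#' @param enriched_pairs Data frame with columns `module`, `pathway`, `odds`:
#'   genes of `module` carry `pathway` with their membership odds multiplied
#'   by `odds`. Defaults to pathway i enriched in module i with odds 10.
#' @param library_sizes Per-sample total fragment counts (positive).
#' @param length_range Two-element vector: min and max transcript length (bp).
#' @param baseline_log_mean,baseline_log_sd Mean and SD of the per-gene
#'   baseline natural-log FPKM, giving a realistic spread of expression levels.
#' @param seed Integer seed; all generator output is deterministic given the
#'   full configuration including the seed.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_genes = 300, module_sizes = c(60, 60), seed = 1)
#' sim <- simulate_expression(cfg)
#' dim(as_expr_matrix(sim$counts))
#' @export
sim_config <- function(n_genes = 1200,
                       n_samples = 10,
                       module_sizes = rep(150L, 6),
                       within_module_cor = 0.95,
                       noise_sd = 0.5,
                       trait_couplings = default_trait_couplings(length(module_sizes)),
                       n_pathways = 20,
                       pathway_base_prob = 0.05,
                       enriched_pairs = default_enriched_pairs(length(module_sizes)),
                       library_sizes = rep(2e7, n_samples),
                       length_range = c(300, 3000),
                       baseline_log_mean = log(20),
                       baseline_log_sd = 1,
                       seed = 1L) {
  check_scalar(n_genes, "n_genes", lower = 1)
  check_scalar(n_samples, "n_samples", lower = 3)
  if (length(module_sizes) < 1 || any(module_sizes < 1) ||
      any(!is.finite(module_sizes))) {
    abort("module_sizes must be positive integers")
  }
  if (sum(module_sizes) > n_genes) {
    abort("sum(module_sizes) must not exceed n_genes")
  }
  check_scalar(within_module_cor, "within_module_cor",
               lower = 0, upper = 1, strict_lower = TRUE)
  check_scalar(noise_sd, "noise_sd", lower = 0)
  check_scalar(n_pathways, "n_pathways", lower = 1)
  check_scalar(pathway_base_prob, "pathway_base_prob",
               lower = 0, upper = 1, strict_lower = TRUE, strict_upper = TRUE)
  if (length(library_sizes) != n_samples) {
    abort("library_sizes must have one entry per sample")
  }
  if (any(!is.finite(library_sizes)) || any(library_sizes <= 0)) {
    abort("library_sizes must be positive")
  }
  if (length(length_range) != 2 || any(length_range <= 0) ||
      length_range[1] > length_range[2]) {
    abort("length_range must be (min, max) with 0 < min <= max")
  }
  trait_couplings <- tibble::as_tibble(trait_couplings)
  needed <- c("trait", "module", "coupling", "noise_sd")
  if (!all(needed %in% names(trait_couplings))) {
    abort("trait_couplings needs columns trait, module, coupling, noise_sd")
  }
  if (any(trait_couplings$module > length(module_sizes)) ||
      any(trait_couplings$module < 1)) {
    abort("trait_couplings reference a module that is not planted")
  }
  if (any(trait_couplings$noise_sd < 0)) abort("trait noise SDs must be >= 0")
  enriched_pairs <- tibble::as_tibble(enriched_pairs)
  if (!all(c("module", "pathway", "odds") %in% names(enriched_pairs))) {
    abort("enriched_pairs needs columns module, pathway, odds")
  }
  if (nrow(enriched_pairs) > 0 && any(enriched_pairs$odds <= 0)) {
    abort("enrichment odds must be positive")
  }
  if (nrow(enriched_pairs) > 0 &&
      (any(enriched_pairs$module > length(module_sizes)) ||
       any(enriched_pairs$pathway > n_pathways))) {
    abort("enriched_pairs reference an absent module or pathway")
  }
  structure(list(
    n_genes = as.integer(n_genes), n_samples = as.integer(n_samples),
    module_sizes = as.integer(module_sizes),
    within_module_cor = within_module_cor, noise_sd = noise_sd,
    trait_couplings = trait_couplings, n_pathways = as.integer(n_pathways),
    pathway_base_prob = pathway_base_prob, enriched_pairs = enriched_pairs,
    library_sizes = library_sizes, length_range = length_range,
    baseline_log_mean = baseline_log_mean, baseline_log_sd = baseline_log_sd,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Default metabolite-trait couplings
#'
#' Eight traits named after the tea metabolites measured across tissues
#' (catechin C, GC, EC, EGC, ECG, EGCG, theanine, caffeine), assigned
#' round-robin to the planted modules with coupling 0.95 and trait noise SD
#' 0.1; the last two couplings are negative to exercise sign handling.
#'
#' @param n_modules Number of planted modules available for coupling.
#' @return A tibble with columns trait, module, coupling, noise_sd.
#' @export
default_trait_couplings <- function(n_modules) {
  traits <- c("C", "GC", "EC", "EGC", "ECG", "EGCG", "theanine", "caffeine")
  k <- length(traits)
  sgn <- c(rep(1, k - 2), -1, -1)
  tibble::tibble(
    trait = traits,
    module = rep_len(seq_len(n_modules), k),
    coupling = 0.95 * sgn,
    noise_sd = 0.1
  )
}

#' Default planted pathway enrichments
#'
#' Pathway i is enriched in module i with membership odds multiplied by 10.
#'
#' @param n_modules Number of planted modules.
#' @return A tibble with columns module, pathway, odds.
#' @export
default_enriched_pairs <- function(n_modules) {
  tibble::tibble(module = seq_len(n_modules),
                 pathway = seq_len(n_modules),
                 odds = 10)
}

module_labels <- function(n) sprintf("M%d", seq_len(n))

#' Simulate a fragment-count expression matrix with planted modules
#'
#' Draws one standardized latent eigengene profile per planted module, builds
#' each module gene's log expression as `loading * eigengene + noise` with the
#' loading magnitude chosen so the expected absolute gene-eigengene
#' correlation equals `within_module_cor` (loading signs are +/- with equal
#' probability), exponentiates to an expected FPKM around a per-gene baseline,
#' and draws fragment counts as Poisson with mean
#' `FPKM * length * library_size / 1e9`. Background genes are independent
#' noise. Fully deterministic given the configuration seed.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements:
#'   \describe{
#'     \item{counts}{wide tibble of integer counts (`gene_id` + samples).}
#'     \item{gene_lengths}{tibble `gene_id`, `length_bp`.}
#'     \item{library_sizes}{tibble `sample_id`, `fragments`.}
#'     \item{truth}{a `sim_truth` list: `gene_module` tibble (gene_id,
#'       module with `"background"` for unstructured genes), `eigengenes`
#'       (module x sample matrix), `loadings`, `expected_fpkm`, and the
#'       trait/pathway ground truth filled in by the companion generators.}
#'   }
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_g <- config$n_genes
  n_s <- config$n_samples
  mods <- config$module_sizes
  n_m <- length(mods)
  samples <- sprintf("tissue%02d", seq_len(n_s))
  genes <- sprintf("gene%05d", seq_len(n_g))

  # latent eigengenes: one standardized profile per module
  eig <- matrix(stats::rnorm(n_m * n_s), n_m, n_s,
                dimnames = list(module_labels(n_m), samples))
  eig <- t(scale(t(eig)))  # row mean 0, sd 1

  assignment <- rep("background", n_g)
  idx <- 1L
  for (m in seq_len(n_m)) {
    assignment[idx:(idx + mods[m] - 1L)] <- module_labels(n_m)[m]
    idx <- idx + mods[m]
  }

  rho <- config$within_module_cor
  sigma <- config$noise_sd
  # loading magnitude lambda with lambda/sqrt(lambda^2+sigma^2) = rho
  lambda <- if (sigma == 0 || rho == 1) 1 else sigma * rho / sqrt(1 - rho^2)

  signs <- sample(c(-1, 1), n_g, replace = TRUE)
  baseline <- stats::rnorm(n_g, config$baseline_log_mean, config$baseline_log_sd)
  noise <- matrix(stats::rnorm(n_g * n_s, sd = sigma), n_g, n_s)

  logexpr <- matrix(0, n_g, n_s, dimnames = list(genes, samples))
  loadings <- numeric(n_g)
  for (g in seq_len(n_g)) {
    if (assignment[g] == "background") {
      loadings[g] <- 0
      logexpr[g, ] <- baseline[g] + noise[g, ]
    } else {
      loadings[g] <- signs[g] * lambda
      logexpr[g, ] <- baseline[g] + loadings[g] * eig[assignment[g], ] + noise[g, ]
    }
  }
  expected_fpkm <- exp(logexpr)

  lengths <- round(stats::runif(n_g, config$length_range[1], config$length_range[2]))
  lib <- config$library_sizes
  mu <- expected_fpkm * outer(lengths, lib) / 1e9
  counts <- matrix(stats::rpois(n_g * n_s, mu), n_g, n_s,
                   dimnames = list(genes, samples))

  truth <- structure(list(
    gene_module = tibble::tibble(gene_id = genes, module = assignment),
    eigengenes = eig,
    loadings = tibble::tibble(gene_id = genes, loading = loadings),
    expected_fpkm = expected_fpkm,
    config = config
  ), class = "sim_truth")

  list(
    counts = expr_tibble(counts, unit = "count"),
    gene_lengths = tibble::tibble(gene_id = genes, length_bp = lengths),
    library_sizes = tibble::tibble(sample_id = samples, fragments = lib),
    truth = truth
  )
}

#' Simulate metabolite trait contents coupled to planted modules
#'
#' Each trait is `coupling * eigengene + Gaussian(0, noise_sd)`, then shifted
#' by its minimum so contents are non-negative (an affine map, leaving all
#' correlations untouched). Deterministic given the configuration seed.
#'
#' @param truth The `sim_truth` object from [simulate_expression()].
#' @param config The same [sim_config()] used to generate `truth`.
#' @return A tibble with `sample_id` first and one non-negative column per trait.
#' @export
simulate_traits <- function(truth, config) {
  stopifnot(inherits(truth, "sim_truth"), inherits(config, "sim_config"))
  tc <- config$trait_couplings
  labels <- rownames(truth$eigengenes)
  if (any(!module_labels(length(config$module_sizes))[tc$module] %in% labels)) {
    abort("trait_couplings reference modules absent from the truth object")
  }
  set.seed(config$seed + 1L)
  n_s <- config$n_samples
  vals <- purrr::pmap(tc, function(trait, module, coupling, noise_sd) {
    e <- truth$eigengenes[module_labels(length(config$module_sizes))[module], ]
    x <- coupling * e + stats::rnorm(n_s, sd = noise_sd)
    x - min(x)
  })
  out <- tibble::as_tibble(setNames(vals, tc$trait))
  dplyr::bind_cols(tibble::tibble(sample_id = colnames(truth$eigengenes)), out)
}

#' Simulate a gene-to-pathway annotation with planted enrichments
#'
#' Every gene carries each pathway independently with probability
#' `pathway_base_prob`; for each planted (module, pathway, odds) pair the
#' membership odds of that pathway are multiplied by `odds` for genes of that
#' module (probability capped at 1 as odds grow). Deterministic given the
#' configuration seed.
#'
#' @param truth The `sim_truth` object from [simulate_expression()].
#' @param config The same [sim_config()] used to generate `truth`.
#' @return A two-column tibble (`gene_id`, `pathway`), one row per membership.
#' @export
simulate_annotation <- function(truth, config) {
  stopifnot(inherits(truth, "sim_truth"), inherits(config, "sim_config"))
  if (nrow(config$enriched_pairs) > 0 && any(config$enriched_pairs$odds <= 0)) {
    abort("enrichment odds must be positive")
  }
  set.seed(config$seed + 2L)
  genes <- truth$gene_module$gene_id
  modules <- truth$gene_module$module
  n_g <- length(genes)
  n_p <- config$n_pathways
  p0 <- config$pathway_base_prob
  odds0 <- p0 / (1 - p0)
  pathways <- sprintf("pw%02d", seq_len(n_p))

  prob <- matrix(p0, n_g, n_p)
  ep <- config$enriched_pairs
  if (nrow(ep) > 0) {
    for (i in seq_len(nrow(ep))) {
      in_mod <- modules == module_labels(length(config$module_sizes))[ep$module[i]]
      o <- odds0 * ep$odds[i]
      prob[in_mod, ep$pathway[i]] <- o / (1 + o)
    }
  }
  member <- matrix(stats::runif(n_g * n_p) < prob, n_g, n_p)
  idx <- which(member, arr.ind = TRUE)
  tibble::tibble(gene_id = genes[idx[, 1]], pathway = pathways[idx[, 2]]) |>
    dplyr::arrange(.data$gene_id, .data$pathway)
}

#' Generate a complete synthetic data set
#'
#' Convenience wrapper running [simulate_expression()], [simulate_traits()]
#' and [simulate_annotation()] off one configuration.
#'
#' @param config A [sim_config()] object.
#' @return A list: `counts`, `gene_lengths`, `library_sizes`, `traits`,
#'   `annotation`, `truth`.
#' @export
simulate_dataset <- function(config) {
  sim <- simulate_expression(config)
  sim$traits <- simulate_traits(sim$truth, config)
  sim$annotation <- simulate_annotation(sim$truth, config)
  sim
}
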