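#' Hierarchically cluster samples and flag outliers
#'
#' Average-linkage clustering of samples on Euclidean distances between
#' their expression profiles, used to screen for outlying tissues before
#' network construction. A sample is flagged when the height at which its
#' leaf first merges into the tree exceeds `outlier_cut`.
#'
#' @param log_expr Wide tibble of log10(FPKM + 1) values.
#' @param outlier_cut Height threshold for flagging; default `Inf` (no flags).
#' @return A list: `hclust` (the sample dendrogram), `merge_height` (named
#'   vector, first-merge height per sample), `outliers` (character vector).
#' @export
cluster_samples <- function(log_expr, outlier_cut = Inf) {
  m <- as_expr_matrix(log_expr)
  if (ncol(m) < 3) abort("sample clustering needs at least 3 samples")
  d <- stats::dist(t(m))
  hc <- stats::hclust(d, method = "average")
  # first merge height per leaf
  h <- setNames(numeric(ncol(m)), hc$labels)
  for (i in seq_len(nrow(hc$merge))) {
    for (leaf in hc$merge[i, ]) {
      if (leaf < 0) h[hc$labels[-leaf]] <- hc$height[i]
    }
  }
  list(hclust = hc, merge_height = h, outliers = names(h)[h > outlier_cut])
}

#' Gene-gene Pearson correlation matrix
#'
#' Correlates every pair of gene expression profiles across samples.
#' Zero-variance genes cannot be correlated and are removed with a warning.
#'
#' @param log_expr Wide tibble of log10(FPKM + 1) values (>= 3 samples).
#' @return A symmetric gene x gene correlation matrix with unit diagonal.
#' @export
gene_correlation <- function(log_expr) {
  m <- as_expr_matrix(log_expr)
  if (ncol(m) < 3) abort("correlation needs at least 3 samples")
  v <- apply(m, 1, stats::var)
  if (any(v == 0)) {
    warn(sprintf("removing %d zero-variance gene(s) before correlation",
                 sum(v == 0)))
    m <- m[v > 0, , drop = FALSE]
  }
  stats::cor(t(m))
}

#' Soft-thresholded adjacency matrix
#'
#' Raises the correlation-derived similarity to the power `power` (the soft
#' threshold beta), keeping a weighted network instead of a hard cutoff:
#' unsigned `a_ij = |r_ij|^power`, signed `a_ij = ((1 + r_ij)/2)^power`.
#' The diagonal is forced to 1.
#'
#' @param corr Gene correlation matrix from [gene_correlation()].
#' @param power Soft threshold, >= 1; default 30.
#' @param mode `"unsigned"` (default) or `"signed"`.
#' @return Symmetric adjacency matrix in \[0, 1\] of class `matrix`, with
#'   attributes `power` and `mode`.
#' @export
adjacency_matrix <- function(corr, power = 30, mode = c("unsigned", "signed")) {
  mode <- match.arg(mode)
  check_scalar(power, "power", lower = 1)
  a <- switch(mode,
              unsigned = abs(corr)^power,
              signed = ((1 + corr) / 2)^power)
  diag(a) <- 1
  attr(a, "power") <- power
  attr(a, "mode") <- mode
  a
}

#' Scale-free topology fit of a weighted network
#'
#' Node connectivity is `k_i = sum_(j != i) a_ij`. Connectivities are
#' discretised into `n_bins` equal-width bins, the per-bin frequency
#' `p(k)` regressed as `log10 p(k) ~ log10 (mean k in bin)` over non-empty
#' bins, and the fit reported as a signed R-squared
#' (`-sign(slope) * R^2`), positive when frequency decays with connectivity
#' as in a scale-free degree distribution.
#'
#' @param adj Adjacency matrix, or a numeric vector of node connectivities.
#' @param n_bins Number of connectivity bins; default 10.
#' @return A list: `r_squared` (signed), `slope`, `mean_k`.
#' @export
scale_free_fit <- function(adj, n_bins = 10) {
  k <- if (is.matrix(adj)) rowSums(adj) - diag(adj) else adj
  if (length(unique(k)) < 2) abort("all connectivities are equal; no fit possible")
  breaks <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  freq <- tapply(k, bin, length) / length(k)
  kmean <- tapply(k, bin, mean)
  keep <- !is.na(freq) & freq > 0 & kmean > 0
  lf <- log10(freq[keep]); lk <- log10(kmean[keep])
  if (length(lf) < 2) abort("too few occupied bins for a scale-free fit")
  fit <- stats::lm(lf ~ lk)
  slope <- unname(stats::coef(fit)[2])
  r2 <- summary(fit)$r.squared
  list(r_squared = -sign(slope) * r2, slope = slope, mean_k = mean(k))
}

#' Choose the soft-threshold power by the scale-free topology criterion
#'
#' Scans candidate powers and returns the smallest whose signed scale-free
#' R-squared reaches `r2_min`; if none qualifies, falls back to
#' `default_power`.
#'
#' @param corr Gene correlation matrix.
#' @param candidates Candidate powers, default 1..30.
#' @param r2_min Required signed R-squared, default 0.8.
#' @param default_power Fallback power, default 30.
#' @param mode Network mode passed to [adjacency_matrix()].
#' @return A list: `power` (chosen), `diagnostics` (tibble with one row per
#'   candidate: `power`, `r_squared`, `slope`, `mean_k`).
#' @export
pick_soft_threshold <- function(corr, candidates = 1:30, r2_min = 0.8,
                                default_power = 30,
                                mode = c("unsigned", "signed")) {
  mode <- match.arg(mode)
  if (length(candidates) < 1) abort("candidate power list must not be empty")
  diag_tbl <- purrr::map(candidates, function(p) {
    f <- scale_free_fit(adjacency_matrix(corr, power = p, mode = mode))
    tibble::tibble(power = p, r_squared = f$r_squared,
                   slope = f$slope, mean_k = f$mean_k)
  }) |> dplyr::bind_rows()
  ok <- diag_tbl$power[diag_tbl$r_squared >= r2_min]
  list(power = if (length(ok)) min(ok) else default_power,
       diagnostics = diag_tbl)
}

#' Topological overlap matrix
#'
#' Combines direct adjacency with shared-neighbour structure: for
#' `i != j`, with `l_ij = sum_(u != i,j) a_iu a_uj` and
#' `k_i = sum_(u != i) a_iu`,
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)`; the diagonal is 1.
#' `1 - TOM` is the dissimilarity used for gene clustering.
#'
#' @param adj Symmetric adjacency matrix with unit diagonal.
#' @return Symmetric TOM matrix in \[0, 1\] with unit diagonal.
#' @export
tom_similarity <- function(adj) {
  if (!isSymmetric(unname(adj), tol = 1e-8)) abort("adjacency must be symmetric")
  a <- adj
  diag(a) <- 1
  aa <- a %*% a
  # (A^2)_ij includes u = i and u = j terms a_ii a_ij + a_ij a_jj = 2 a_ij
  l <- aa - 2 * a
  k <- rowSums(a) - 1
  kmin <- outer(k, k, pmin)
  tom <- (l + a) / (kmin + 1 - a)
  diag(tom) <- 1
  tom[kmin + 1 - a == 0] <- 0  # isolated pair guard (k = 0, a = 0)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adj)
  tom
}

#' Hierarchically cluster genes on a dissimilarity matrix
#'
#' Average-linkage agglomerative clustering, normally applied to
#' `1 - TOM`.
#'
#' @param dissim Symmetric dissimilarity matrix with zero diagonal.
#' @return An [stats::hclust] dendrogram.
#' @export
cluster_genes <- function(dissim) {
  if (any(!is.finite(dissim))) abort("dissimilarity contains non-finite values")
  if (!isSymmetric(unname(dissim), tol = 1e-8)) abort("dissimilarity must be symmetric")
  stats::hclust(stats::as.dist(dissim), method = "average")
}

#' Cut a gene dendrogram into modules
#'
#' Static cut at `cut_fraction` times the maximum merge height; candidate
#' clusters smaller than `min_module_size` are pooled into the reserved
#' `"unassigned"` label, and the surviving clusters are labelled `M1`,
#' `M2`, ... by decreasing size.
#'
#' @param dendro An [stats::hclust] gene dendrogram.
#' @param min_module_size Minimum genes per module, default 30.
#' @param cut_fraction Fraction of the maximum merge height at which to cut,
#'   in (0, 1\]; default 0.99.
#' @return A partition tibble (`gene_id`, `module`) in dendrogram label order.
#' @export
cut_modules <- function(dendro, min_module_size = 30, cut_fraction = 0.99) {
  if (min_module_size < 1) abort("min_module_size must be >= 1")
  check_scalar(cut_fraction, "cut_fraction", lower = 0, upper = 1,
               strict_lower = TRUE)
  # average linkage is monotone; ties can leave float-level height inversions
  # that cutree rejects, so clamp them (and only them) to non-decreasing
  h <- dendro$height
  if (any(diff(h) < -1e-8 * max(abs(h)))) {
    abort("dendrogram merge heights decrease; not an average-linkage tree?")
  }
  dendro$height <- cummax(h)
  cl <- stats::cutree(dendro, h = cut_fraction * max(dendro$height))
  relabel_partition(tibble::tibble(gene_id = names(cl),
                                   module = as.character(cl)),
                    min_module_size)
}

# Pool clusters below the size threshold into "unassigned" and relabel the
# rest M1, M2, ... by decreasing size (ties broken by first gene id).
relabel_partition <- function(partition, min_module_size = 1) {
  sizes <- table(partition$module[partition$module != "unassigned"])
  keep <- names(sizes)[sizes >= min_module_size]
  partition$module[!partition$module %in% keep] <- "unassigned"
  sizes <- sizes[keep]
  first_gene <- vapply(keep, function(l) {
    min(partition$gene_id[partition$module == l])
  }, character(1))
  ord <- keep[order(-as.integer(sizes[keep]), first_gene)]
  map <- setNames(sprintf("M%d", seq_along(ord)), ord)
  partition$module <- ifelse(partition$module == "unassigned", "unassigned",
                             unname(map[partition$module]))
  partition
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of its
#' standardized gene x sample submatrix: each member gene is z-scored
#' across samples, the leading right singular vector gives the per-sample
#' scores, which are restandardized to zero mean and unit variance and
#' sign-aligned so the eigengene correlates non-negatively with the module's
#' mean standardized profile. Variance explained is the leading eigenvalue's
#' share of the total.
#'
#' @param log_expr Wide tibble of log10(FPKM + 1) values.
#' @param partition Partition tibble (`gene_id`, `module`); the
#'   `"unassigned"` pool gets no eigengene.
#' @return A list: `eigengenes` (module x sample matrix, rows are
#'   standardized profiles) and `variance_explained` (tibble `module`,
#'   `variance_explained`, `n_genes`).
#' @export
module_eigengenes <- function(log_expr, partition) {
  m <- as_expr_matrix(log_expr)
  mods <- setdiff(unique(partition$module), "unassigned")
  mods <- mods[order(match(mods, partition$module))]
  if (!all(partition$gene_id %in% rownames(m))) {
    abort("partition contains genes absent from the expression matrix")
  }
  me <- matrix(NA_real_, length(mods), ncol(m),
               dimnames = list(mods, colnames(m)))
  ve <- numeric(length(mods))
  ng <- integer(length(mods))
  for (i in seq_along(mods)) {
    genes <- partition$gene_id[partition$module == mods[i]]
    sub <- m[genes, , drop = FALSE]
    sds <- apply(sub, 1, stats::sd)
    if (all(sds == 0)) abort(sprintf("module %s has only zero-variance genes", mods[i]))
    sub <- sub[sds > 0, , drop = FALSE]
    z <- t(scale(t(sub)))
    sv <- svd(z)
    e <- sv$v[, 1]
    e <- (e - mean(e)) / stats::sd(e)
    mean_profile <- colMeans(z)
    al <- stats::cor(e, mean_profile)
    if (!is.na(al) && al < 0) e <- -e
    me[i, ] <- e
    ve[i] <- sv$d[1]^2 / sum(sv$d^2)
    ng[i] <- nrow(z)
  }
  list(eigengenes = me,
       variance_explained = tibble::tibble(module = mods,
                                           variance_explained = ve,
                                           n_genes = ng))
}

#' Merge modules with similar eigengenes
#'
#' Iteratively merges the module pair with the smallest eigengene
#' dissimilarity `d = 1 - cor(ME_a, ME_b)` while `d < merge_cut`,
#' recomputing eigengenes after every merge; stops when no pair qualifies.
#' Surviving modules are relabelled by decreasing size.
#'
#' @param log_expr Wide tibble of log10(FPKM + 1) values.
#' @param partition Partition tibble (`gene_id`, `module`).
#' @param merge_cut Eigengene dissimilarity below which modules merge,
#'   in (0, 1); default 0.25.
#' @return The merged partition tibble.
#' @export
merge_close_modules <- function(log_expr, partition, merge_cut = 0.25) {
  check_scalar(merge_cut, "merge_cut", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  part <- partition
  repeat {
    mods <- setdiff(unique(part$module), "unassigned")
    if (length(mods) < 2) break
    me <- module_eigengenes(log_expr, part)$eigengenes
    cc <- stats::cor(t(me))
    d <- 1 - cc
    diag(d) <- Inf
    if (min(d) >= merge_cut) break
    ij <- which(d == min(d), arr.ind = TRUE)[1, ]
    a <- rownames(d)[ij[1]]; b <- colnames(d)[ij[2]]
    sizes <- table(part$module)
    into <- if (sizes[[a]] >= sizes[[b]]) a else b
    from <- setdiff(c(a, b), into)
    part$module[part$module == from] <- into
  }
  relabel_partition(part)
}

#' Intramodular connectivity
#'
#' For each assigned gene, `k_within` sums the adjacency weights of its
#' edges to the other genes of its module ("the weights across all edges of
#' a node"). Genes in the `"unassigned"` pool receive `NA`. Within each
#' module genes are ranked by decreasing `k_within` (rank 1 = most
#' connected; ties broken by gene id).
#'
#' @param adj Adjacency matrix covering all partition genes.
#' @param partition Partition tibble (`gene_id`, `module`).
#' @return A tibble (`gene_id`, `module`, `k_within`, `rank`).
#' @export
intramodular_connectivity <- function(adj, partition) {
  if (!all(partition$gene_id %in% rownames(adj))) {
    abort("partition contains genes absent from the adjacency matrix")
  }
  out <- partition
  out$k_within <- NA_real_
  out$rank <- NA_integer_
  for (mod in setdiff(unique(partition$module), "unassigned")) {
    genes <- partition$gene_id[partition$module == mod]
    sub <- adj[genes, genes, drop = FALSE]
    kw <- rowSums(sub) - diag(sub)
    idx <- match(genes, out$gene_id)
    out$k_within[idx] <- kw
    ord <- order(-kw, genes)
    out$rank[idx[ord]] <- seq_along(genes)
  }
  out
}

#' Select module hub genes
#'
#' The hubs of a module are its most connected members: the top
#' `top_fraction` of genes by intramodular connectivity, with count
#' `max(1, ceiling(top_fraction * module size))` (so a 100-gene module at
#' the default 2% yields 2 hubs). Ties are broken by gene id.
#'
#' @param conn Connectivity tibble from [intramodular_connectivity()].
#' @param top_fraction Fraction of module genes taken as hubs, in (0, 1\];
#'   default 0.02.
#' @return A tibble (`module`, `gene_id`, `k_within`, `rank`) of hub genes,
#'   ordered by module then rank.
#' @export
select_hubs <- function(conn, top_fraction = 0.02) {
  check_scalar(top_fraction, "top_fraction", lower = 0, upper = 1,
               strict_lower = TRUE)
  conn |>
    dplyr::filter(.data$module != "unassigned") |>
    dplyr::group_by(.data$module) |>
    dplyr::arrange(.data$rank, .by_group = TRUE) |>
    dplyr::filter(.data$rank <= max(1L, ceiling(top_fraction * dplyr::n()))) |>
    dplyr::ungroup() |>
    dplyr::select("module", "gene_id", "k_within", "rank")
}
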