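le_tbl <- function(m) expr_tibble(m, unit = "log_fpkm")

test_that("sample clustering detects duplicates and constructed outliers", {
  set.seed(1)
  base <- matrix(rnorm(40), 10, 4,
                 dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
  m <- cbind(base, s5 = base[, "s1"])            # duplicated sample
  cs <- cluster_samples(le_tbl(m))
  expect_equal(min(cs$hclust$height), 0)
  expect_equal(unname(cs$merge_height[c("s1", "s5")]), c(0, 0))

  m2 <- cbind(base, out = base[, 1] + 50)        # gross offset outlier
  d_direct <- sqrt(sum((m2[, "out"] - m2[, "s1"])^2))
  cs2 <- cluster_samples(le_tbl(m2), outlier_cut = d_direct / 2)
  expect_true("out" %in% cs2$outliers)

  perm <- m[, c(3, 1, 5, 2, 4)]
  expect_equal(sort(cluster_samples(le_tbl(perm))$hclust$height),
               sort(cs$hclust$height))
  expect_error(cluster_samples(le_tbl(base[, 1:2])), "3 samples")
})

test_that("gene correlation matches a brute-force Pearson oracle", {
  m <- matrix(c(1, 2, 4, 3,
                2, 1, 5, 2,
                9, 7, 3, 1), 3, 4, byrow = TRUE,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  cc <- gene_correlation(le_tbl(m))
  for (i in 1:3) for (j in 1:3) {
    expect_equal(cc[i, j], oracle_pearson(m[i, ], m[j, ]), tolerance = 1e-12)
  }
  dup <- rbind(m, g4 = m[1, ], g5 = -m[1, ])
  cc2 <- gene_correlation(le_tbl(dup))
  expect_equal(cc2["g1", "g4"], 1)
  expect_equal(cc2["g1", "g5"], -1)
  withflat <- rbind(m, flat = rep(2, 4))
  expect_warning(cc3 <- gene_correlation(le_tbl(withflat)), "zero-variance")
  expect_false("flat" %in% rownames(cc3))
})

test_that("adjacency is the soft-thresholded similarity", {
  r <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0, -0.9, 0, 1), 3, 3)
  a <- adjacency_matrix(r, power = 30)
  expect_equal(a[1, 2], 0.9^30)
  expect_equal(a[1, 2], a[1, 3])       # unsigned is even in r
  expect_equal(diag(a), rep(1, 3))
  expect_equal(adjacency_matrix(matrix(1, 2, 2), power = 7),
               matrix(1, 2, 2), ignore_attr = TRUE)
  s <- adjacency_matrix(r, power = 2, mode = "signed")
  expect_equal(s[1, 2], ((1 + 0.9) / 2)^2)
  expect_error(adjacency_matrix(r, power = 0.5), "range")
})

test_that("adjacency decreases with power for |r| < 1", {
  set.seed(4)
  r <- cor(matrix(rnorm(80), 8, 10))
  a5 <- adjacency_matrix(r, power = 5)
  a9 <- adjacency_matrix(r, power = 9)
  off <- upper.tri(r)
  expect_true(all(a9[off] <= a5[off]))
  f5 <- scale_free_fit(a5); f9 <- scale_free_fit(a9)
  expect_gt(f5$mean_k, f9$mean_k)
})

test_that("scale-free fit is exact on a power law and poor on uniform noise", {
  gamma <- 2
  # counts exactly proportional to k^-2 (36/k^2 is integral for these k)
  ks <- c(1, 2, 3, 6)
  k <- rep(ks, times = 10 * 36 / ks^gamma)
  fit <- suppressWarnings(scale_free_fit(k))  # lm notes the perfect fit
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_equal(fit$slope, -gamma, tolerance = 1e-10)
  set.seed(11)
  worse <- replicate(5, {
    a <- matrix(runif(400), 20, 20); a <- (a + t(a)) / 2; diag(a) <- 1
    scale_free_fit(a)$r_squared
  })
  expect_true(all(worse < 0.9))
  expect_error(scale_free_fit(rep(3, 10)), "equal")
})

test_that("soft-threshold picker honours its contract", {
  sim <- small_sim(seed = 13, n_genes = 120, module_sizes = 100L)
  corr <- gene_correlation(log_expr_of(sim))
  cand <- c(2, 6, 12, 20, 30)
  ps <- pick_soft_threshold(corr, candidates = cand)
  expect_lte(ps$power, 30)
  expect_identical(ps$diagnostics$power, cand)
  expect_true(all(abs(ps$diagnostics$r_squared) <= 1 + 1e-12))
  # degenerate threshold (any signed R-squared passes): smallest candidate wins
  expect_equal(pick_soft_threshold(corr, candidates = cand, r2_min = -1)$power, 2)
  # unattainable threshold: falls back to the configured default
  expect_equal(pick_soft_threshold(corr, candidates = cand, r2_min = 0.999,
                                   default_power = 30)$power, 30)
  expect_error(pick_soft_threshold(corr, candidates = numeric(0)), "empty")
})

test_that("TOM matches its formula, by hand and against the double-loop oracle", {
  full <- matrix(1, 3, 3)
  expect_equal(tom_similarity(full), matrix(1, 3, 3), ignore_attr = TRUE)

  a <- diag(3)
  a[1, 2] <- a[2, 1] <- 0.5
  a[1, 3] <- a[3, 1] <- 0.2
  a[2, 3] <- a[3, 2] <- 0.1
  tom <- tom_similarity(a)
  expect_equal(tom[1, 2], (0.2 * 0.1 + 0.5) / (min(0.7, 0.6) + 1 - 0.5),
               tolerance = 1e-12)

  iso <- diag(4)
  iso[1, 2] <- iso[2, 1] <- 0.8
  ti <- tom_similarity(iso)
  expect_equal(ti[3, 1:2], c(0, 0))  # isolated gene overlaps nothing
  expect_equal(ti[3, 4], 0)

  set.seed(5)
  for (i in 1:5) {
    a <- matrix(runif(400), 20, 20); a <- (a + t(a)) / 2; diag(a) <- 1
    expect_lt(max(abs(tom_similarity(a) - oracle_tom(a))), 1e-10)
  }
  bad <- matrix(runif(9), 3, 3)
  expect_error(tom_similarity(bad), "symmetric")
})

test_that("TOM is a similarity: symmetric, in [0,1], unit diagonal", {
  set.seed(6)
  a <- matrix(runif(225), 15, 15); a <- (a + t(a)) / 2; diag(a) <- 1
  tom <- tom_similarity(a)
  expect_true(isSymmetric(tom, tol = 1e-12))
  expect_true(all(tom >= -1e-12 & tom <= 1 + 1e-12))
  expect_equal(diag(tom), rep(1, 15))
})

test_that("gene clustering reproduces a hand-executed average-linkage trace", {
  d <- matrix(0.9, 4, 4, dimnames = list(paste0("g", 1:4), paste0("g", 1:4)))
  diag(d) <- 0
  d[1, 2] <- d[2, 1] <- 0.1
  d[3, 4] <- d[4, 3] <- 0.2
  hc <- cluster_genes(d)
  expect_equal(sort(hc$height), c(0.1, 0.2, 0.9))
  # two zero-dissimilarity blocks separated by 1 merge finally at 1
  b <- matrix(1, 6, 6, dimnames = list(paste0("g", 1:6), paste0("g", 1:6)))
  b[1:3, 1:3] <- 0; b[4:6, 4:6] <- 0; diag(b) <- 0
  hb <- cluster_genes(b)
  expect_equal(max(hb$height), 1)
  # permutation invariance of the merge heights
  perm <- sample(4)
  hp <- cluster_genes(d[perm, perm])
  expect_equal(sort(hp$height), sort(hc$height))
  dn <- d; dn[1, 2] <- NaN
  expect_error(cluster_genes(dn), "non-finite")
})

test_that("module cutting separates planted blocks and pools small clusters", {
  set.seed(8)
  d <- matrix(1, 80, 80, dimnames = list(sprintf("g%02d", 1:80),
                                         sprintf("g%02d", 1:80)))
  d[1:40, 1:40] <- 0.05; d[41:80, 41:80] <- 0.05; diag(d) <- 0
  part <- cut_modules(cluster_genes(d), min_module_size = 30)
  expect_equal(sort(unique(part$module)), c("M1", "M2"))
  expect_equal(unname(table(part$module)), c(40L, 40L), ignore_attr = TRUE)

  # no structure: everything below the size threshold, hence unassigned
  u <- matrix(1, 10, 10, dimnames = list(paste0("g", 1:10), paste0("g", 1:10)))
  diag(u) <- 0
  part_u <- cut_modules(cluster_genes(u), min_module_size = 3)
  expect_true(all(part_u$module == "unassigned"))
  # degenerate threshold keeps every singleton
  part_1 <- cut_modules(cluster_genes(u), min_module_size = 1)
  expect_false(any(part_1$module == "unassigned"))
  expect_error(cut_modules(cluster_genes(u), min_module_size = 0), ">= 1")
})

test_that("module labels are ordered by decreasing size", {
  d <- matrix(1, 50, 50, dimnames = list(sprintf("g%02d", 1:50),
                                         sprintf("g%02d", 1:50)))
  d[1:15, 1:15] <- 0.05; d[16:50, 16:50] <- 0.05; diag(d) <- 0
  part <- cut_modules(cluster_genes(d), min_module_size = 10)
  sizes <- table(part$module)
  expect_gt(sizes[["M1"]], sizes[["M2"]])
})

test_that("eigengenes are the leading principal axis, standardized and aligned", {
  set.seed(12)
  # rank-one module: identical genes
  prof <- rnorm(6)
  m <- matrix(rep(prof, each = 5), 5, 6,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:6)))
  m <- m + matrix(rnorm(30, sd = 1e-9), 5, 6)
  part <- tibble::tibble(gene_id = rownames(m), module = "M1")
  me <- module_eigengenes(le_tbl(m), part)
  expect_equal(me$variance_explained$variance_explained, 1, tolerance = 1e-6)
  expect_equal(abs(cor(me$eigengenes["M1", ], m[1, ])), 1, tolerance = 1e-6)
  expect_equal(mean(me$eigengenes["M1", ]), 0, tolerance = 1e-12)
  expect_equal(sd(me$eigengenes["M1", ]), 1, tolerance = 1e-12)

  # brute-force eigendecomposition oracle for variance explained
  m2 <- matrix(rnorm(48), 8, 6,
               dimnames = list(paste0("g", 1:8), paste0("s", 1:6)))
  part2 <- tibble::tibble(gene_id = rownames(m2), module = "M1")
  me2 <- module_eigengenes(le_tbl(m2), part2)
  z <- t(scale(t(m2)))
  ev <- eigen(t(z) %*% z, symmetric = TRUE)$values
  expect_equal(me2$variance_explained$variance_explained,
               ev[1] / sum(ev), tolerance = 1e-10)

  # sign convention survives flipping every member gene
  me3 <- module_eigengenes(le_tbl(-m2), part2)
  zf <- t(scale(t(-m2)))
  expect_gte(cor(me3$eigengenes["M1", ], colMeans(zf)), 0)

  flat <- matrix(3, 4, 6, dimnames = list(paste0("g", 1:4), paste0("s", 1:6)))
  expect_error(module_eigengenes(le_tbl(flat),
               tibble::tibble(gene_id = rownames(flat), module = "M1")),
               "zero-variance")
})

test_that("eigengene variance explained beats random unit combinations", {
  set.seed(14)
  m <- matrix(rnorm(60), 10, 6,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  part <- tibble::tibble(gene_id = rownames(m), module = "M1")
  ve <- module_eigengenes(le_tbl(m), part)$variance_explained$variance_explained
  z <- t(scale(t(m)))
  tot <- sum(z^2)
  rand_ve <- replicate(1000, {
    w <- rnorm(nrow(z)); w <- w / sqrt(sum(w^2))
    sum((crossprod(z, w))^2) / tot
  })
  expect_gte(ve, max(rand_ve) - 1e-12)
})

test_that("modules from one latent profile merge; orthogonal ones do not", {
  set.seed(15)
  e1 <- scale(rnorm(10))[, 1]
  e2 <- stats::residuals(lm(rnorm(10) ~ e1))
  e2 <- (e2 - mean(e2)) / sd(e2)         # exactly orthogonal to e1
  mk <- function(e, n, label) {
    m <- t(sapply(seq_len(n), function(i) e + rnorm(10, sd = 1e-6)))
    rownames(m) <- paste0(label, seq_len(n))
    m
  }
  m <- rbind(mk(e1, 5, "a"), mk(e1, 4, "b"), mk(e2, 5, "c"))
  colnames(m) <- paste0("s", 1:10)
  part <- tibble::tibble(gene_id = rownames(m),
                         module = rep(c("M1", "M2", "M3"), c(5, 4, 5)))
  merged <- merge_close_modules(le_tbl(m), part, merge_cut = 0.25)
  expect_equal(length(unique(merged$module)), 2)  # a+b merged, c kept apart
  szs <- table(merged$module)
  expect_equal(unname(sort(szs)), c(5L, 9L), ignore_attr = TRUE)
  # vanishing merge cut leaves the partition unchanged once eigengene
  # dissimilarities are bounded away from zero
  mn <- rbind(mk(e1, 5, "a"), mk(e2, 4, "b")) +
    matrix(rnorm(90, sd = 0.05), 9, 10)
  colnames(mn) <- paste0("s", 1:10)
  partn <- tibble::tibble(gene_id = rownames(mn),
                          module = rep(c("M1", "M2"), c(5, 4)))
  tiny <- merge_close_modules(le_tbl(mn), partn, merge_cut = 1e-9)
  expect_equal(sort(unname(table(tiny$module))), c(4L, 5L), ignore_attr = TRUE)
  expect_error(merge_close_modules(le_tbl(m), part, merge_cut = 0), "range")
})

test_that("intramodular connectivity sums within-module edge weights", {
  genes <- paste0("g", 1:6)
  a <- diag(6); dimnames(a) <- list(genes, genes)
  a[1:4, 1:4] <- matrix(c(1, .5, .4, .3,
                          .5, 1, .2, .1,
                          .4, .2, 1, .6,
                          .3, .1, .6, 1), 4, 4)
  a[5, 6] <- a[6, 5] <- 0.9
  part <- tibble::tibble(gene_id = genes,
                         module = c(rep("M1", 4), "M2", "unassigned"))
  conn <- intramodular_connectivity(a, part)
  expect_equal(conn$k_within[1:4], c(.5 + .4 + .3, .5 + .2 + .1,
                                     .4 + .2 + .6, .3 + .1 + .6))
  expect_equal(conn$k_within[5], 0)        # singleton module
  expect_true(is.na(conn$k_within[6]))     # unassigned: no rank
  expect_equal(sort(conn$rank[1:4]), 1:4)
  # complete module: k_within = size - 1 for every member
  full <- matrix(1, 5, 5, dimnames = list(paste0("h", 1:5), paste0("h", 1:5)))
  pf <- tibble::tibble(gene_id = paste0("h", 1:5), module = "M1")
  expect_equal(intramodular_connectivity(full, pf)$k_within, rep(4, 5))
})

test_that("hub selection takes the ceiling of the top fraction, at least one", {
  mk_conn <- function(n, label) {
    tibble::tibble(gene_id = sprintf("%s_%05d", label, seq_len(n)),
                   module = label, k_within = rev(seq_len(n)),
                   rank = seq_len(n))
  }
  conn <- dplyr::bind_rows(mk_conn(100, "M1"), mk_conn(55, "M2"),
                           mk_conn(9041, "M3"), mk_conn(10, "M4"))
  hubs <- select_hubs(conn, top_fraction = 0.02)
  counts <- table(hubs$module)
  expect_equal(counts[["M1"]], 2L)      # 2% of 100
  expect_equal(counts[["M2"]], 2L)      # ceil(1.1)
  expect_equal(counts[["M3"]], 181L)    # ceil(180.82)
  expect_equal(counts[["M4"]], 1L)      # max(1, .)
  # hubs are the highest-connectivity members
  expect_equal(hubs$rank[hubs$module == "M1"], 1:2)
  all_hubs <- select_hubs(mk_conn(10, "M1"), top_fraction = 1)
  expect_equal(nrow(all_hubs), 10)
  expect_error(select_hubs(conn, top_fraction = 0), "range")
})
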