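# Normalization, marker genes, modules, signatures, surface proteins and
# embedding-density diffusion.

test_that("log CPM normalization matches a scalar-loop oracle and preserves ranks", {
  set.seed(1)
  counts <- matrix(rpois(60, 4), 10, 6,
                   dimnames = list(paste0("g", 1:10), paste0("c", 1:6)))
  X <- normalize_log_cpm(counts)
  # independent scalar loop
  for (j in 1:6) {
    tot <- sum(counts[, j])
    for (i in 1:10) {
      expect_equal(X[i, j], log(1 + 1e6 * counts[i, j] / tot),
                   tolerance = 1e-10)
    }
  }
  expect_equal(X[counts == 0], rep(0, sum(counts == 0)))
  # single-gene cell
  one <- matrix(c(5), 1, 1, dimnames = list("g1", "c1"))
  expect_equal(unname(normalize_log_cpm(one)[1, 1]), log(1 + 1e6))
  # within-cell rank order preserved
  for (j in 1:6) expect_equal(rank(X[, j]), rank(counts[, j]))
  # sparse input agrees with dense and zero-total cells are dropped
  counts2 <- cbind(counts, c0 = 0)
  expect_warning(Xs <- normalize_log_cpm(Matrix::Matrix(counts2,
                                                        sparse = TRUE)),
                 "zero total")
  expect_equal(as.matrix(Xs), X, ignore_attr = TRUE)
})

test_that("marker gene test gives the exact enumerated p on the 3-vs-3 toy", {
  X <- matrix(c(1, 2, 3, 10, 11, 12), 1, 6,
              dimnames = list("g1", paste0("c", 1:6)))
  labels <- rep(c("lo", "hi"), each = 3)
  res <- rank_marker_genes(X, labels)
  # oracle: enumerate all C(6,3) label assignments of the rank sum
  vals <- c(1, 2, 3, 10, 11, 12)
  combos <- utils::combn(6, 3)
  U_all <- apply(combos, 2, function(idx) {
    sum(rank(vals)[idx]) - 3 * 4 / 2
  })
  U_obs <- res$lo$U[1]
  p_exact <- mean(U_all <= min(U_obs, 9 - U_obs) |
                  U_all >= max(U_obs, 9 - U_obs))
  expect_equal(U_obs, 0)
  expect_equal(p_exact, 2 / 20)
  expect_equal(res$lo$p[1], p_exact)
  expect_equal(res$hi$U[1], 9)  # mirrored one-vs-rest
})

test_that("constant genes give p = 1 and p-values are rank-invariant", {
  set.seed(2)
  X <- rbind(flat = rep(1, 40), sig = c(rnorm(20), rnorm(20, 3)),
             noise = rnorm(40))
  colnames(X) <- paste0("c", 1:40)
  labels <- rep(c("a", "b"), each = 20)
  res <- rank_marker_genes(X, labels)
  expect_equal(res$a[res$a$gene == "flat", "p"], 1)
  # monotone per-gene transformation leaves p unchanged
  res2 <- rank_marker_genes(exp(X), labels)
  expect_equal(res$a[order(res$a$gene), "p"],
               res2$a[order(res2$a$gene), "p"])
  # label permutation permutes results
  perm <- c(21:40, 1:20)
  res3 <- rank_marker_genes(X[, perm], labels[perm])
  expect_equal(res3$a, res$a)
})

test_that("module discovery recovers planted anti-correlated blocks exactly", {
  set.seed(3)
  base <- rnorm(100)
  X <- rbind(matrix(rep(base, 4), 4, byrow = TRUE) +
               matrix(rnorm(400, sd = 0.05), 4),
             matrix(rep(-base, 4), 4, byrow = TRUE) +
               matrix(rnorm(400, sd = 0.05), 4))
  rownames(X) <- paste0("g", 1:8)
  markers <- list(one = data.frame(gene = rownames(X)))
  mod <- discover_modules(X, markers, top_n = 8, k_range = 2:3)
  expect_equal(mod$k, 2)
  got <- split(names(mod$assignment), mod$assignment)
  expect_setequal(vapply(got, paste, collapse = ",", ""),
                  c("g1,g2,g3,g4", "g5,g6,g7,g8"))
  # gene order permutation does not change the partition
  perm <- c(5, 1, 7, 3, 8, 2, 6, 4)
  mod2 <- discover_modules(X[perm, ], list(one = data.frame(
    gene = rownames(X)[perm])), top_n = 8, k_range = 2:3)
  same <- outer(mod$assignment[rownames(X)], mod$assignment[rownames(X)],
                "==")
  same2 <- outer(mod2$assignment[rownames(X)], mod2$assignment[rownames(X)],
                 "==")
  expect_equal(same, same2)
})

test_that("degenerate all-correlated geometry falls back to k = min with a warning", {
  base <- seq_len(50)
  X <- rbind(g1 = base, g2 = 2 * base, g3 = base + 100, g4 = 3 * base,
             g5 = base / 2, g6 = base * 1.5)
  markers <- list(one = data.frame(gene = rownames(X)))
  expect_warning(mod <- discover_modules(X, markers, top_n = 6,
                                         k_range = 2:3),
                 "degenerate|silhouette")
  expect_equal(mod$k, 2)
})

test_that("signature scores equal the mean of member genes", {
  set.seed(4)
  counts <- matrix(rpois(200, 5), 20, 10,
                   dimnames = list(paste0("g", 1:20), paste0("c", 1:10)))
  X <- normalize_log_cpm(counts)
  sc <- score_signature(X, c("g1", "g5", "g9"))
  for (j in 1:10) {
    expect_equal(unname(sc[j]), mean(X[c("g1", "g5", "g9"), j]),
                 tolerance = 1e-10)
  }
  expect_equal(unname(score_signature(X, "g3")), unname(X["g3", ]),
               ignore_attr = TRUE)
  # uniform cell: signature over all genes equals the common value
  u <- matrix(2, 5, 1, dimnames = list(paste0("g", 1:5), "c1"))
  Xu <- normalize_log_cpm(u)
  expect_equal(unname(score_signature(Xu, rownames(u))), unname(Xu[1, 1]),
               ignore_attr = TRUE)
  expect_warning(score_signature(X, c("g1", "nope")), "missing")
  expect_error(score_signature(X, "absent"), "none of the signature genes")
})

test_that("per-batch standardization removes additive batch shifts", {
  set.seed(5)
  S <- matrix(rnorm(60), 30, 2)
  batch <- rep(c("b1", "b2"), each = 15)
  S[batch == "b2", ] <- S[batch == "b2", ] + 5
  out <- batch_standardize_signatures(S, batch)
  expect_lt(max(abs(colMeans(out[batch == "b1", ]) -
                    colMeans(out[batch == "b2", ]))), 1e-10)
  # one batch == global z-scoring
  one <- batch_standardize_signatures(S, rep("b", 30))
  expect_equal(one, scale(S), ignore_attr = TRUE)
  expect_warning(batch_standardize_signatures(S[1:3, ], c("a", "a", "b")),
                 "single cell")
})

test_that("batch correction reduces batch separability on generated cohorts", {
  drops <- vapply(1:4, function(s) {
    sim <- simulate_cohort(small_config(seed = s, n_batches = 2,
                                        batch_sd = 0.8))
    X <- normalize_log_cpm(sim$counts)
    gp <- sim$truth$gene_program
    sigs <- vapply(unique(gp[!is.na(gp)]), function(p) {
      score_signature(X, names(gp)[!is.na(gp) & gp == p])
    }, numeric(ncol(X)))
    batch <- sim$cells$batch[match(colnames(X), sim$cells$cell_id)]
    corr <- batch_standardize_signatures(sigs, batch)
    sil <- function(M) {
      mean(cluster::silhouette(as.integer(factor(batch)),
                               stats::dist(M))[, "sil_width"])
    }
    sil(sigs) - sil(corr)
  }, numeric(1))
  expect_true(all(drops > 0))
})

test_that("surface protein z-scores are background-relative per cell", {
  P <- matrix(c(10, 5, 3, 3,
                8, 2, 4, 4), 4, 2,
              dimnames = list(c("cd57", "other", "iso1", "iso2"),
                              c("c1", "c2")))
  expect_warning(out <- normalize_surface_proteins(P, c("iso1", "iso2")),
                 "zero background SD")
  # backgrounds identical within each cell -> sd 0 -> flagged, zeros
  expect_setequal(out$flagged, c("c1", "c2"))
  expect_true(all(out$z == 0))

  set.seed(6)
  P2 <- matrix(rpois(50, 6) + 1, 5, 10,
               dimnames = list(c("a", "b", "iso1", "iso2", "iso3"),
                               paste0("c", 1:10)))
  out2 <- normalize_surface_proteins(P2, c("iso1", "iso2", "iso3"))
  for (j in 1:10) {
    l <- log1p(P2[, j])
    mu <- mean(l[3:5]); sdv <- stats::sd(l[3:5])
    expect_equal(unname(out2$z[1, j]), unname((l[1] - mu) / sdv),
                 tolerance = 1e-10)
  }
  # a protein equal to the cell background mean scores 0
  P3 <- rbind(P2, at_bg = round(expm1(colMeans(log1p(P2[3:5, ])))))
  l3 <- log1p(P3)
  z3 <- normalize_surface_proteins(P3, c("iso1", "iso2", "iso3"))$z
  manual <- (l3["at_bg", ] - colMeans(l3[3:5, ])) /
    apply(l3[3:5, ], 2, stats::sd)
  expect_equal(z3["at_bg", ], manual, tolerance = 1e-10)
})

test_that("program-linked surface proteins are highest in their cluster", {
  sim <- simulate_cohort(small_config(seed = 9))
  z <- normalize_surface_proteins(sim$surface,
                                  sim$truth$background_proteins)$z
  cl <- sim$truth$true_cluster[sim$cells$clonotype_id]
  # cluster 0 drives the naive program; its mean sp_naive z must be maximal
  means <- tapply(z["sp_naive", sim$cells$cell_id], cl, mean)
  expect_equal(unname(which.max(means)), 1)
})

test_that("density diffusion conserves mass and respects geometry", {
  set.seed(7)
  coords <- cbind(rnorm(60), rnorm(60))
  rownames(coords) <- paste0("c", 1:60)
  members <- seq_len(60) %in% 1:12
  dens <- diffuse_embedding_density(coords, members, k = 5, iterations = 5)
  expect_true(all(is.finite(dens)) && all(dens >= 0))

  # conservation: recompute the pre-diffusion density and compare totals
  d0 <- diffuse_embedding_density(coords, members, k = 5, iterations = 0)
  expect_equal(sum(dens), sum(d0), tolerance = 1e-8)

  # oracle: 5-step matrix power of the row-normalized adjacency
  dd <- as.matrix(dist(coords))
  nn <- t(apply(dd, 1, function(r) order(r)[2:6]))
  A <- matrix(0, 60, 60)
  A[cbind(rep(1:60, each = 5), as.vector(t(nn)))] <- 1
  diag(A) <- 1
  A <- A / rowSums(A)
  x <- d0
  for (i in 1:5) x <- as.vector(t(A) %*% x)
  expect_equal(unname(dens), unname(x), tolerance = 1e-10)

  # single far member: after mass-conserving diffusion the density is
  # concentrated around that member -- decreasing with distance from it
  far <- rbind(coords, far = c(30, 30))
  dens1 <- diffuse_embedding_density(far, c(rep(FALSE, 60), TRUE), k = 5)
  dist_to_far <- sqrt(rowSums(sweep(far, 2, far["far", ], "-")^2))
  expect_lt(stats::cor(dens1, dist_to_far, method = "spearman"), -0.5)

  # all members on a symmetric ring: constant density is a fixed point
  theta <- seq(0, 2 * pi, length.out = 9)[-9]
  ring <- cbind(cos(theta), sin(theta))
  rownames(ring) <- paste0("r", 1:8)
  dring <- diffuse_embedding_density(ring, rep(TRUE, 8), k = 2)
  expect_lt(diff(range(dring)), 1e-8)

  expect_warning(z <- diffuse_embedding_density(coords, rep(FALSE, 60)),
                 "no member")
  expect_equal(unname(z), rep(0, 60))
})
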