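# Autoencoder latents, phenotype dimensions, significance counting, the
# equal-importance chi-square and the protein/PC intersection analysis.

test_that("the autoencoder is deterministic with a non-increasing loss", {
  set.seed(1)
  X <- scale(matrix(rnorm(40 * 12), 40, 12))
  f1 <- clonoscope:::mlp_autoencoder(X, max_iter = 15, seed = 3)
  f2 <- clonoscope:::mlp_autoencoder(X, max_iter = 15, seed = 3)
  expect_identical(f1$latent, f2$latent)
  expect_true(all(diff(f1$loss) <= 1e-8))
  f3 <- clonoscope:::mlp_autoencoder(X, max_iter = 15, seed = 4)
  expect_false(identical(f1$latent, f3$latent))
})

test_that("training on rank-2 data beats an under-ranked linear baseline", {
  set.seed(2)
  n <- 60; d <- 20
  U <- matrix(rnorm(n * 2), n, 2)
  V <- matrix(rnorm(2 * d), 2, d)
  X <- scale(U %*% V)
  fit <- clonoscope:::mlp_autoencoder(X, max_iter = 25, seed = 1)
  # truncated-SVD oracle: best rank-1 linear reconstruction error
  sv <- svd(X)
  rank1 <- sv$u[, 1, drop = FALSE] %*% diag(sv$d[1], 1) %*%
    t(sv$v[, 1, drop = FALSE])
  baseline <- mean((X - rank1)^2)
  expect_lt(fit$final_loss, baseline)
  expect_lt(utils::tail(fit$loss, 1), utils::head(fit$loss, 1))
})

test_that("encode_omic validates input and returns 50 finite latents per unit", {
  set.seed(3)
  M <- matrix(rnorm(30 * 8), 30, 8,
              dimnames = list(sprintf("u%02d", 1:30), paste0("f", 1:8)))
  lb <- encode_omic(omic_block("plasma", M, "patient_timepoint"), seed = 1)
  expect_s3_class(lb, "latent_block")
  expect_equal(dim(lb$latent), c(30, 50))
  expect_true(all(is.finite(lb$latent)))
  # constant features are dropped; an all-constant matrix errors
  M2 <- cbind(M, const = 1)
  lb2 <- encode_omic(omic_block("plasma", M2, "patient_timepoint"), seed = 1)
  expect_equal(lb2$dropped_features, "const")
  M3 <- matrix(1, 10, 3, dimnames = list(paste0("u", 1:10), paste0("f", 1:3)))
  expect_error(encode_omic(omic_block("hla", M3, "patient")),
               "zero variance")
  expect_error(encode_omic(omic_block("hla", M[1:2, ], "patient")),
               "units", class = "simpleError")
})

test_that("phenotype PCs are orthogonal with non-increasing variance", {
  sim <- simulate_cohort(small_config(seed = 5))
  X <- normalize_log_cpm(sim$counts)
  expect_warning(phen <- derive_phenotype_dims(X, "pcs", n_pcs = 2000),
                 "clipped")
  G <- crossprod(scale(phen, scale = FALSE))
  expect_lt(max(abs(G[upper.tri(G)])), 1e-6)
  v <- apply(phen, 2, stats::var)
  expect_true(all(diff(v) <= 1e-10))
  # signature mode passes through the 4 program columns
  gp <- sim$truth$gene_program
  sigs <- vapply(unique(gp[!is.na(gp)]), function(p) {
    score_signature(X, names(gp)[!is.na(gp) & gp == p])
  }, numeric(ncol(X)))
  phen2 <- derive_phenotype_dims(X, "signatures", signatures = sigs)
  expect_equal(ncol(phen2), 4)
})

test_that("count_significant matches a direct binomial-style oracle and its identity", {
  set.seed(6)
  n <- 400
  cells <- sprintf("c%03d", 1:n)
  phen <- matrix(rnorm(n * 10), n, 10, dimnames = list(cells, NULL))
  lat <- function(om, U) {
    L <- matrix(rnorm(U * 50), U, 50,
                dimnames = list(sprintf("%s%02d", om, 1:U), NULL))
    structure(list(omic = om, units = rownames(L), latent = L,
                   loss = 1, dropped_features = character(0)),
              class = "latent_block")
  }
  blocks <- list(lat("a", n), lat("b", n))
  maps <- list(a = setNames(sprintf("a%02d", 1:n), cells),
               b = setNames(sprintf("b%02d", 1:n), cells))
  imp <- count_significant(blocks, phen, maps)
  # oracle: direct correlation p-value count for omic "a"
  p_or <- clonoscope:::cor_pvals(stats::cor(blocks[[1]]$latent, phen), n)
  expect_equal(imp$observed[1], sum(p_or < 0.05))
  expect_equal(imp$expected, rep(50 * 10 * 0.05, 2))
  # identity: sum(observed - expected) == total - sum(expected) exactly
  expect_equal(sum(imp$obs_minus_exp),
               attr(imp, "total_observed") - sum(imp$expected))
  # chi-square expected count is 25% of the total for 4 omics
  blocks4 <- list(lat("a", n), lat("b", n), lat("c", n), lat("d", n))
  maps4 <- c(maps, list(c = maps$a, d = maps$b))
  names(maps4) <- c("a", "b", "c", "d")
  maps4 <- lapply(maps4, function(m) m)
  maps4$c <- setNames(sub("a", "c", maps$a), cells)
  maps4$d <- setNames(sub("b", "d", maps$b), cells)
  imp4 <- count_significant(blocks4, phen, maps4)
  expect_equal(attr(imp4, "chi_expected"), attr(imp4, "total_observed") / 4)
})

test_that("equal observed counts give chi-square 0 and the test is calibrated under independence", {
  n <- 200
  cells <- sprintf("c%03d", 1:n)
  mklat <- function(om, L) {
    rownames(L) <- cells
    structure(list(omic = om, units = cells, latent = L, loss = 1,
                   dropped_features = character(0)), class = "latent_block")
  }
  id_map <- setNames(cells, cells)
  # construct omics with identical latents -> identical observed counts
  set.seed(7)
  L <- matrix(rnorm(n * 20), n, 20)
  phen <- matrix(rnorm(n * 5), n, 5, dimnames = list(cells, NULL))
  blocks <- lapply(c("a", "b", "c", "d"), mklat, L = L)
  maps <- setNames(rep(list(id_map), 4), c("a", "b", "c", "d"))
  imp <- count_significant(blocks, phen, maps)
  expect_equal(attr(imp, "chisq"), 0)
  expect_equal(attr(imp, "p"), 1)

  # calibration: with independent full-rank latents the rejection rate at
  # alpha = 0.05 stays near alpha
  set.seed(8)
  rej <- replicate(200, {
    blocks <- lapply(c("a", "b", "c", "d"), function(om) {
      mklat(om, matrix(rnorm(n * 20), n, 20))
    })
    phen <- matrix(rnorm(n * 5), n, 5, dimnames = list(cells, NULL))
    attr(count_significant(blocks, phen, maps), "p") < 0.05
  })
  expect_lte(mean(rej), 0.10)
})

test_that("latents constant after broadcast are skipped with adjusted expectation", {
  n <- 100
  cells <- sprintf("c%03d", 1:n)
  L <- cbind(rnorm(2), c(1, 1), rnorm(2))  # unit-level: one constant dim
  rownames(L) <- c("u1", "u2")
  lb <- structure(list(omic = "x", units = c("u1", "u2"), latent = L,
                       loss = 1, dropped_features = character(0)),
                  class = "latent_block")
  phen <- matrix(rnorm(n * 4), n, 4, dimnames = list(cells, NULL))
  maps <- list(x = setNames(rep(c("u1", "u2"), length.out = n), cells))
  expect_message(imp <- count_significant(list(lb), phen, maps),
                 "constant after broadcast")
  expect_equal(imp$n_latents, 2)
  expect_equal(imp$expected, 2 * 4 * 0.05)
})

test_that("planted correlation blocks are recovered by the intersection analysis", {
  set.seed(9)
  n_samp <- 40; n_cells <- 400
  samples <- sprintf("s%02d", 1:n_samp)
  cells <- sprintf("c%03d", 1:n_cells)
  cell_samples <- setNames(sample(samples, n_cells, replace = TRUE), cells)
  # two planted factors: proteins 1-4 and PCs 1-2 share factor 1;
  # proteins 5-8 and PCs 3-4 share factor 2
  f1 <- rnorm(n_samp); f2 <- rnorm(n_samp)
  plasma <- cbind(sapply(1:4, function(i) f1 + rnorm(n_samp, sd = 0.2)),
                  sapply(1:4, function(i) f2 + rnorm(n_samp, sd = 0.2)))
  dimnames(plasma) <- list(samples, paste0("p", 1:8))
  pc_cells <- cbind(sapply(1:2, function(i) f1[match(cell_samples, samples)] +
                             rnorm(n_cells, sd = 0.2)),
                    sapply(1:2, function(i) f2[match(cell_samples, samples)] +
                             rnorm(n_cells, sd = 0.2)))
  dimnames(pc_cells) <- list(cells, paste0("PC", 1:4))
  out <- protein_pc_intersections(plasma, pc_cells, cell_samples,
                                  k_range = 2:3)
  expect_equal(out$k_proteins, 2)
  expect_equal(out$k_pcs, 2)
  expect_equal(length(unique(out$protein_clusters[1:4])), 1)
  expect_equal(length(unique(out$protein_clusters[5:8])), 1)
  expect_false(out$protein_clusters[1] == out$protein_clusters[5])
  # protein score of a single-protein cluster equals its standardized level
  one <- protein_pc_intersections(plasma, pc_cells, cell_samples,
                                  k_range = 2:3, protein_cluster =
                                    out$protein_clusters[[1]],
                                  pc_cluster = out$pc_clusters[[1]])
  expect_true(all(one$sig_proteins %in% paste0("p", 1:4)))
  # scores from a coupled block correlate positively
  ps <- one$protein_score
  ms <- tapply(one$mrna_score, cell_samples[names(one$mrna_score)], mean)
  ct <- stats::cor.test(ps[names(ms)], as.numeric(ms))
  expect_gt(ct$estimate, 0.5)
  expect_lt(ct$p.value, 0.05)
})

test_that("an inflammatory plasma block coupled to effector programs is recovered end to end", {
  hits <- vapply(1:6, function(s) {
    w <- c(w_tcr = 0.3, w_plasma = 0.5, w_hla = 0.1, w_cdc = 0.1,
           w_noise = 0)
    sim <- simulate_cohort(small_config(seed = 50 + s, effect_weights = w))
    X <- normalize_log_cpm(sim$counts)
    phen <- derive_phenotype_dims(X, "pcs", n_pcs = 10)
    samp <- setNames(paste(sim$cells$patient_id, sim$cells$timepoint,
                           sep = "_"), sim$cells$cell_id)
    out <- try(protein_pc_intersections(sim$plasma,
                                        phen[sim$cells$cell_id, ],
                                        samp, k_range = 3:5), silent = TRUE)
    if (inherits(out, "try-error")) return(FALSE)
    ps <- out$protein_score
    ms <- tapply(out$mrna_score, samp[names(out$mrna_score)], mean)
    ct <- stats::cor.test(ps[names(ms)], as.numeric(ms))
    abs(ct$estimate) > 0.3 && ct$p.value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 5 / 6)
})

test_that("feature scaling leaves significance counts essentially unchanged", {
  diffs <- vapply(1:5, function(s) {
    set.seed(s + 60)
    M <- matrix(rnorm(40 * 10), 40, 10,
                dimnames = list(sprintf("u%02d", 1:40), paste0("f", 1:10)))
    n <- 300
    cells <- sprintf("c%03d", 1:n)
    maps <- list(x = setNames(sample(rownames(M), n, replace = TRUE), cells))
    phen <- matrix(rnorm(n * 10), n, 10, dimnames = list(cells, NULL))
    l1 <- encode_omic(omic_block("x", M, "patient"), seed = s)
    l2 <- encode_omic(omic_block("x", 2 * M, "patient"), seed = s)
    o1 <- count_significant(list(l1), phen, maps)$observed
    o2 <- count_significant(list(l2), phen, maps)$observed
    abs(o1 - o2)
  }, numeric(1))
  # standardization makes the encodings scale-invariant, so counts agree
  expect_true(all(diffs <= 0.1 * 50 * 10 * 0.05 + 3))
})
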