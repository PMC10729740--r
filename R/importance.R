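# Factor-importance framework: per-omic autoencoder latents, significant
# latent-phenotype correlation counting against an alpha-budgeted
# expectation, and the equal-importance chi-square test.

#' Construct an omic block
#'
#' A labeled unit-by-feature matrix at the omic's native unit level:
#' clonotype for TCR features, patient-timepoint for plasma, patient for HLA
#' and dendritic-cell features.
#'
#' @param omic Omic name (e.g. `"tcr"`, `"plasma"`, `"hla"`, `"cdc"`).
#' @param features Unit x feature numeric matrix with unit rownames.
#' @param level Unit level: `"clonotype"`, `"patient_timepoint"` or
#'   `"patient"`.
#' @return Object of class `omic_block`.
#' @export
omic_block <- function(omic, features,
                       level = c("clonotype", "patient_timepoint", "patient")) {
  level <- match.arg(level)
  features <- as.matrix(features)
  if (nrow(features) < 2) stop("omic block needs >= 2 units", call. = FALSE)
  if (anyNA(features)) stop("omic block contains missing values", call. = FALSE)
  if (is.null(rownames(features))) {
    stop("omic feature matrix needs unit rownames", call. = FALSE)
  }
  structure(list(omic = omic, level = level, units = rownames(features),
                 features = features),
            class = "omic_block")
}

#' TCR sequence features per clonotype
#'
#' Default TCR omic featurization: one-hot V/J usage for both chains,
#' CDR3 length per chain, and per-chain amino-acid composition (20
#' frequencies each).
#'
#' @param clonotypes Clonotype table.
#' @return An `omic_block` at clonotype level.
#' @export
tcr_omic_features <- function(clonotypes) {
  onehot <- function(x, prefix) {
    lv <- sort(unique(x))
    m <- outer(x, lv, "==") * 1
    colnames(m) <- paste0(prefix, "_", lv)
    m
  }
  composition <- function(seqs, prefix) {
    m <- t(vapply(seqs, function(s) {
      ch <- strsplit(s, "")[[1]]
      as.numeric(table(factor(ch, AA_ALPHABET))) / length(ch)
    }, numeric(20)))
    colnames(m) <- paste0(prefix, "_", AA_ALPHABET)
    m
  }
  f <- cbind(onehot(clonotypes$va, "va"), onehot(clonotypes$ja, "ja"),
             onehot(clonotypes$vb, "vb"), onehot(clonotypes$jb, "jb"),
             len_a = nchar(clonotypes$cdr3a), len_b = nchar(clonotypes$cdr3b),
             composition(clonotypes$cdr3a, "aa_a"),
             composition(clonotypes$cdr3b, "aa_b"))
  rownames(f) <- clonotypes$clonotype_id
  omic_block("tcr", f, level = "clonotype")
}

#' Encode an omic block into 50 autoencoder latent dimensions
#'
#' Standardizes features (dropping constants), trains a fully connected
#' autoencoder with layer widths 200-100-50-100-200, ReLU activations and an
#' Adam optimizer for at most `max_iter` epochs (squared-error objective,
#' early stop on relative loss change < 1e-4), and returns the 50-unit
#' bottleneck activations per unit. Deterministic given `seed`.
#'
#' @param block An `omic_block`.
#' @param seed Integer seed for weight initialization.
#' @param max_iter Maximum training epochs (default 25).
#' @return Object of class `latent_block`: list with `omic`, `units`,
#'   `latent` (unit x 50), `loss` (per-epoch trajectory), `dropped_features`.
#' @export
encode_omic <- function(block, seed = 1, max_iter = 25) {
  stopifnot(inherits(block, "omic_block"))
  X <- block$features
  if (nrow(X) < 3) {
    stop("cannot train an autoencoder on fewer than 3 units", call. = FALSE)
  }
  sds <- apply(X, 2, stats::sd)
  dropped <- colnames(X)[sds == 0]
  if (length(dropped) == ncol(X)) {
    stop(sprintf("all %d features have zero variance and were dropped; %s",
                 length(dropped), "nothing left to encode"), call. = FALSE)
  }
  Xs <- scale(X[, sds > 0, drop = FALSE])
  fit <- mlp_autoencoder(Xs, max_iter = max_iter, seed = seed)
  latent <- fit$latent
  rownames(latent) <- block$units
  colnames(latent) <- paste0("L", seq_len(ncol(latent)))
  structure(list(omic = block$omic, level = block$level, units = block$units,
                 latent = latent, loss = fit$loss,
                 final_loss = fit$final_loss, dropped_features = dropped),
            class = "latent_block")
}

#' Phenotype dimensions per cell
#'
#' Unbiased principal components of the cell x normalized-gene matrix and/or
#' supplied signature score columns.
#'
#' @param X Normalized gene x cell matrix.
#' @param mode `"pcs"`, `"signatures"` or `"both"`.
#' @param n_pcs Number of PCs (clipped to the matrix rank with a warning).
#' @param signatures Cell x signature matrix (required for modes involving
#'   signatures).
#' @return Cell x dimension numeric matrix.
#' @export
derive_phenotype_dims <- function(X, mode = c("pcs", "signatures", "both"),
                                  n_pcs = 50, signatures = NULL) {
  mode <- match.arg(mode)
  out <- NULL
  if (mode %in% c("pcs", "both")) {
    Xc <- t(as.matrix(X))
    max_pcs <- min(nrow(Xc) - 1, ncol(Xc))
    if (n_pcs > max_pcs) {
      warning(sprintf("n_pcs = %d exceeds the matrix rank; clipped to %d",
                      n_pcs, max_pcs), call. = FALSE)
      n_pcs <- max_pcs
    }
    pcs <- stats::prcomp(Xc, center = TRUE, scale. = FALSE, rank. = n_pcs)$x
    rownames(pcs) <- colnames(X)
    out <- pcs
  }
  if (mode %in% c("signatures", "both")) {
    if (is.null(signatures)) {
      stop("signatures matrix required for mode = ", mode, call. = FALSE)
    }
    sig <- as.matrix(signatures)
    out <- if (is.null(out)) sig else cbind(out, sig[rownames(out), ,
                                                     drop = FALSE])
  }
  out
}

#' Count significant latent-phenotype correlations per omic
#'
#' Broadcasts each omic's unit-level latents to cells, computes the Pearson
#' correlation of every (latent dim, phenotype dim) pair across cells, and
#' counts pairs with two-sided p < `alpha`. The expected count per omic is
#' `n_valid_latents * n_phenotype_dims * alpha` (alpha-budgeted null);
#' latents constant after broadcast are skipped with the expectation adjusted
#' accordingly. The equal-importance chi-square test compares the observed
#' counts across omics against `total_observed / n_omics` each
#' (df = n_omics - 1).
#'
#' @param latents List of `latent_block` objects.
#' @param phenotype Cell x dimension matrix from [derive_phenotype_dims()].
#' @param maps Named list (per omic) of character vectors mapping each cell
#'   (names) to its unit in that omic.
#' @param alpha Significance level (default 0.05).
#' @return Data.frame (class `importance_table`) with one row per omic:
#'   `omic`, `n_latents`, `n_phenotype_dims`, `observed`, `expected`,
#'   `obs_minus_exp`; attributes `chisq`, `df`, `p`, `chi_expected`,
#'   `total_observed`.
#' @export
count_significant <- function(latents, phenotype, maps, alpha = 0.05) {
  phenotype <- as.matrix(phenotype)
  cells <- rownames(phenotype)
  n <- nrow(phenotype)
  rows <- NULL
  for (lb in latents) {
    stopifnot(inherits(lb, "latent_block"))
    map <- maps[[lb$omic]]
    if (is.null(map)) stop("no cell-to-unit map for omic ", lb$omic,
                           call. = FALSE)
    units <- map[cells]
    if (anyNA(units) || !all(units %in% lb$units)) {
      stop("every cell must map to a unit of omic ", lb$omic, call. = FALSE)
    }
    Lb <- lb$latent[units, , drop = FALSE]
    sds <- apply(Lb, 2, stats::sd)
    valid <- sds > 0
    n_skip <- sum(!valid)
    if (n_skip > 0) {
      message(sprintf("omic %s: %d latent dim(s) constant after broadcast; %s",
                      lb$omic, n_skip, "skipped and expectation adjusted"))
    }
    Lb <- Lb[, valid, drop = FALSE]
    r <- suppressWarnings(stats::cor(Lb, phenotype))
    p <- cor_pvals(r, n)
    observed <- sum(p < alpha, na.rm = TRUE)
    expected <- ncol(Lb) * ncol(phenotype) * alpha
    rows <- rbind(rows, data.frame(
      omic = lb$omic, n_latents = ncol(Lb),
      n_phenotype_dims = ncol(phenotype),
      observed = observed, expected = expected,
      obs_minus_exp = observed - expected, stringsAsFactors = FALSE))
  }
  total <- sum(rows$observed)
  k <- nrow(rows)
  chi_expected <- total / k
  chisq <- if (total == 0) 0 else
    sum((rows$observed - chi_expected)^2 / chi_expected)
  structure(rows, class = c("importance_table", "data.frame"),
            chisq = chisq, df = k - 1,
            p = stats::pchisq(chisq, df = k - 1, lower.tail = FALSE),
            chi_expected = chi_expected, total_observed = total,
            alpha = alpha)
}

#' @export
print.importance_table <- function(x, ...) {
  cat("Factor importance (significant latent-phenotype correlations)\n")
  print.data.frame(x, row.names = FALSE, ...)
  cat(sprintf("equal-importance chi-square = %.3f (df = %d, p = %.3g); %s\n",
              attr(x, "chisq"), attr(x, "df"), attr(x, "p"),
              sprintf("expected %.1f per omic", attr(x, "chi_expected"))))
  invisible(x)
}

#' Full factor-importance analysis of a simulated cohort
#'
#' Convenience pipeline: builds the four omic blocks (TCR sequence features
#' per clonotype, plasma per patient-timepoint, HLA and cDC per patient),
#' encodes each into autoencoder latents, derives phenotype dimensions from
#' the normalized expression matrix, and counts significant
#' latent-phenotype correlations per omic.
#'
#' @param sim Output of [simulate_cohort()].
#' @param seed Seed for the autoencoder initializations.
#' @param mode,n_pcs Passed to [derive_phenotype_dims()]; signature mode uses
#'   the four program module scores.
#' @param alpha Significance level (default 0.05).
#' @return An `importance_table` (see [count_significant()]).
#' @export
omic_importance <- function(sim, seed = 1, mode = "pcs", n_pcs = 50,
                            alpha = 0.05) {
  X <- normalize_log_cpm(sim$counts)
  signatures <- NULL
  if (mode %in% c("signatures", "both")) {
    gp <- sim$truth$gene_program
    signatures <- vapply(PROGRAMS, function(p) {
      score_signature(X, names(gp)[!is.na(gp) & gp == p])
    }, numeric(ncol(X)))
  }
  phen <- derive_phenotype_dims(X, mode = mode, n_pcs = n_pcs,
                                signatures = signatures)
  blocks <- list(tcr_omic_features(sim$clonotypes),
                 omic_block("plasma", sim$plasma, "patient_timepoint"),
                 omic_block("hla", sim$hla, "patient"),
                 omic_block("cdc", sim$cdc, "patient"))
  latents <- lapply(seq_along(blocks), function(i) {
    encode_omic(blocks[[i]], seed = seed + i)
  })
  cells <- sim$cells
  maps <- list(
    tcr = setNames(cells$clonotype_id, cells$cell_id),
    plasma = setNames(paste(cells$patient_id, cells$timepoint, sep = "_"),
                      cells$cell_id),
    hla = setNames(cells$patient_id, cells$cell_id),
    cdc = setNames(cells$patient_id, cells$cell_id))
  count_significant(latents, phen[cells$cell_id, , drop = FALSE], maps,
                    alpha = alpha)
}

#' Plasma-protein / transcriptomic-PC intersection analysis
#'
#' Correlates individual plasma protein levels (per patient-timepoint) with
#' phenotype PCs aggregated to patient-timepoint means, clusters the rows
#' (proteins) and columns (PCs) of the correlation matrix separately with
#' Ward's method (cluster count by maximum silhouette over `k_range`), and
#' derives scores for a chosen (protein cluster, PC cluster) intersection:
#' the protein score is the mean standardized level of the significantly
#' correlated proteins per patient-timepoint, and the mRNA score is the mean
#' over the significantly correlated PCs per cell.
#'
#' @param plasma Patient-timepoint x protein matrix (rownames = sample ids).
#' @param pc_cells Cell x PC matrix.
#' @param cell_samples Named character vector mapping cell -> sample id.
#' @param k_range Candidate cluster counts (default `3:10`).
#' @param protein_cluster,pc_cluster Intersection to score (defaults: the
#'   protein cluster and PC cluster pair with the strongest mean absolute
#'   correlation).
#' @param alpha Significance level for membership in the scores (default
#'   0.05).
#' @return List with `correlation` (protein x PC r matrix), `p_values`,
#'   `protein_clusters`, `pc_clusters`, `k_proteins`, `k_pcs`,
#'   `protein_score` (per sample), `mrna_score` (per cell),
#'   `selected` (the scored intersection), `sig_proteins`, `sig_pcs`.
#' @export
protein_pc_intersections <- function(plasma, pc_cells, cell_samples,
                                     k_range = 3:10, protein_cluster = NULL,
                                     pc_cluster = NULL, alpha = 0.05) {
  plasma <- as.matrix(plasma)
  pc_cells <- as.matrix(pc_cells)
  if (ncol(plasma) < max(k_range) + 1) {
    stop(sprintf("need more than max(k_range) = %d proteins", max(k_range)),
         call. = FALSE)
  }
  if (ncol(pc_cells) < 3) stop("need >= 3 phenotype PCs", call. = FALSE)
  samples <- rownames(plasma)
  # aggregate PCs to patient-timepoint means
  pc_samp <- apply(pc_cells, 2, function(v) {
    tapply(v, cell_samples[rownames(pc_cells)], mean)
  })
  common <- intersect(samples, rownames(pc_samp))
  if (length(common) < 3) stop("fewer than 3 shared samples", call. = FALSE)
  R <- stats::cor(plasma[common, , drop = FALSE],
                  pc_samp[common, , drop = FALSE])
  P <- cor_pvals(R, length(common))

  ward_k <- function(M, k_range) {
    d <- stats::dist(M)
    hc <- stats::hclust(d, method = "ward.D2")
    ks <- k_range[k_range < nrow(M)]
    sil <- vapply(ks, function(k) {
      cl <- stats::cutree(hc, k)
      if (length(unique(cl)) < 2) return(NA_real_)
      mean(cluster::silhouette(cl, d)[, "sil_width"])
    }, numeric(1))
    k <- if (all(is.na(sil))) min(ks) else ks[which.max(round(sil, 12))]
    stats::cutree(hc, k)
  }
  prot_cl <- ward_k(R, k_range)
  pc_cl <- ward_k(t(R), k_range)

  if (is.null(protein_cluster) || is.null(pc_cluster)) {
    best <- c(NA, NA); best_val <- -Inf
    for (a in unique(prot_cl)) {
      for (b in unique(pc_cl)) {
        v <- mean(abs(R[prot_cl == a, pc_cl == b, drop = FALSE]))
        if (v > best_val) { best_val <- v; best <- c(a, b) }
      }
    }
    if (is.null(protein_cluster)) protein_cluster <- best[1]
    if (is.null(pc_cluster)) pc_cluster <- best[2]
  }
  prots <- names(prot_cl)[prot_cl == protein_cluster]
  pcs <- names(pc_cl)[pc_cl == pc_cluster]
  if (length(prots) == 0 || length(pcs) == 0) {
    stop("empty intersection: no proteins or PCs in the chosen clusters",
         call. = FALSE)
  }
  sub_p <- P[prots, pcs, drop = FALSE]
  sig_prots <- prots[apply(sub_p < alpha, 1, any)]
  sig_pcs <- pcs[apply(sub_p < alpha, 2, any)]
  if (length(sig_prots) == 0 || length(sig_pcs) == 0) {
    stop("empty intersection: no significant correlations at alpha = ",
         alpha, call. = FALSE)
  }
  prot_score <- rowMeans(scale(plasma)[, sig_prots, drop = FALSE])
  mrna_score <- rowMeans(pc_cells[, sig_pcs, drop = FALSE])
  list(correlation = R, p_values = P, protein_clusters = prot_cl,
       pc_clusters = pc_cl,
       k_proteins = length(unique(prot_cl)), k_pcs = length(unique(pc_cl)),
       protein_score = prot_score, mrna_score = mrna_score,
       selected = c(protein_cluster = protein_cluster,
                    pc_cluster = pc_cluster),
       sig_proteins = sig_prots, sig_pcs = sig_pcs)
}
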