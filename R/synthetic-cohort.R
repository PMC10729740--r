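# Synthetic cohort generator.
#
# Emulates the statistical structure the analysis assumes: clonotypes fall
# into sequence-similar TCR clusters with cluster-specific V/J usage and CDR3
# motifs; each clonotype belongs to one patient and contributes cells at
# three blood draws (T1/T2 acute, T3 convalescent) whose counts follow a
# per-cluster contraction profile; each cell's transcriptional program
# activity is a weighted mixture of its TCR cluster's program loading and
# patient-level environment latents (plasma proteome, HLA genotype,
# dendritic-cell phenotype) plus noise; gene counts are negative-binomial
# with exp-linear means in the program activities.

PROGRAMS <- c("naive", "memory", "interferon", "cytotoxic")

#' Cohort simulation configuration
#'
#' Collects and validates every knob of the synthetic cohort. The defaults
#' define the package's reference simulation: 25 patients, 5 TCR clusters of
#' 25 clonotypes (125 clonotypes, 5 per patient, every cluster represented
#' exactly once per patient), 8 cells per clonotype per timepoint (about
#' 3,000 cells), 300 genes with 15 module genes per program plus 10
#' cluster-private genes per cluster, and effect weights putting 0.7 on TCR
#' cluster identity and 0.1 on each environment block.
#'
#' @param n_patients,n_tcr_clusters,clonotypes_per_cluster Cohort shape.
#' @param cells_per_clonotype_per_timepoint Mean (Poisson) cells per
#'   clonotype per acute timepoint.
#' @param n_genes,n_module_genes Gene panel size and module genes per
#'   program (4 programs: naive, memory, interferon, cytotoxic).
#' @param n_proteins_plasma,n_surface_proteins,n_cdc_features,n_hla_alleles_pool
#'   Environment block sizes.
#' @param effect_weights Named nonnegative weights `w_tcr`, `w_plasma`,
#'   `w_hla`, `w_cdc`, `w_noise` summing to 1.
#' @param contraction_profile Per-cluster target contraction strength in
#'   log10 units (length `n_tcr_clusters`; negative = contraction).
#' @param repertoire_size Total CD8 cells counted per patient-timepoint (the
#'   percentage denominator; antigen-specific cells plus an untracked
#'   background pool).
#' @param motif_divergence Probability that a CDR3 middle residue is drawn
#'   from the cluster's preferred residue set rather than uniformly.
#' @param tcr_clonotype_sd SD of an optional per-clonotype private offset in
#'   program space (0 by default: phenotype depends on the TCR only through
#'   its cluster).
#' @param n_private_genes_per_cluster Genes expressed as a cluster-private
#'   signature per TCR cluster (default 10).
#' @param nb_dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2; default 0.5).
#' @param n_batches,batch_sd Number of sequencing batches (patients are
#'   nested in batches) and SD of per-gene log-scale batch offsets.
#' @param seed Integer seed making the whole cohort reproducible.
#' @return Validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 25,
                          n_tcr_clusters = 5,
                          clonotypes_per_cluster = 25,
                          cells_per_clonotype_per_timepoint = 8,
                          n_genes = 300,
                          n_module_genes = 15,
                          n_proteins_plasma = 40,
                          n_surface_proteins = 20,
                          n_cdc_features = 30,
                          n_hla_alleles_pool = 30,
                          effect_weights = c(w_tcr = 0.7, w_plasma = 0.1,
                                             w_hla = 0.1, w_cdc = 0.1,
                                             w_noise = 0),
                          contraction_profile = NULL,
                          repertoire_size = 250,
                          motif_divergence = 0.6,
                          tcr_clonotype_sd = 0,
                          nb_dispersion = 0.5,
                          n_private_genes_per_cluster = 10,
                          n_batches = 1,
                          batch_sd = 0.3,
                          seed = 1) {
  counts <- list(n_patients = n_patients, n_tcr_clusters = n_tcr_clusters,
                 clonotypes_per_cluster = clonotypes_per_cluster,
                 cells_per_clonotype_per_timepoint =
                   cells_per_clonotype_per_timepoint,
                 n_genes = n_genes, n_module_genes = n_module_genes,
                 n_proteins_plasma = n_proteins_plasma,
                 n_surface_proteins = n_surface_proteins,
                 n_cdc_features = n_cdc_features,
                 n_hla_alleles_pool = n_hla_alleles_pool,
                 repertoire_size = repertoire_size, n_batches = n_batches)
  for (nm in names(counts)) {
    v <- counts[[nm]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 1) {
      stop_config(nm, "must be a count >= 1")
    }
  }
  wn <- c("w_tcr", "w_plasma", "w_hla", "w_cdc", "w_noise")
  if (!all(wn %in% names(effect_weights))) {
    stop_config("effect_weights",
                paste("must be named", paste(wn, collapse = ", ")))
  }
  effect_weights <- effect_weights[wn]
  if (any(effect_weights < 0)) {
    stop_config("effect_weights", "weights must be nonnegative")
  }
  if (abs(sum(effect_weights) - 1) > 1e-9) {
    stop_config("effect_weights", "weights must sum to 1")
  }
  if (is.null(contraction_profile)) {
    contraction_profile <- seq(-0.45, 0, length.out = n_tcr_clusters)
  }
  if (length(contraction_profile) != n_tcr_clusters) {
    stop_config("contraction_profile",
                sprintf("length must equal n_tcr_clusters (%d)",
                        n_tcr_clusters))
  }
  if (n_private_genes_per_cluster < 0) {
    stop_config("n_private_genes_per_cluster", "must be nonnegative")
  }
  if (n_genes < 4 * n_module_genes +
      n_tcr_clusters * n_private_genes_per_cluster) {
    stop_config("n_genes", paste("must cover 4 * n_module_genes plus",
                                 "n_tcr_clusters *",
                                 "n_private_genes_per_cluster"))
  }
  if (motif_divergence < 0 || motif_divergence > 1) {
    stop_config("motif_divergence", "must lie in [0, 1]")
  }
  if (nb_dispersion <= 0) stop_config("nb_dispersion", "must be positive")
  if (tcr_clonotype_sd < 0) stop_config("tcr_clonotype_sd",
                                        "must be nonnegative")
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop_config("seed", "must be a single integer")
  }
  structure(c(counts,
              list(n_private_genes_per_cluster = n_private_genes_per_cluster,
                   effect_weights = effect_weights,
                   contraction_profile = contraction_profile,
                   motif_divergence = motif_divergence,
                   tcr_clonotype_sd = tcr_clonotype_sd,
                   nb_dispersion = nb_dispersion, batch_sd = batch_sd,
                   seed = as.integer(seed))),
            class = "cohort_config")
}

random_cdr3 <- function(len, start3, end3, pref, divergence) {
  mid_len <- len - 6
  use_pref <- stats::runif(mid_len) < divergence
  mid <- ifelse(use_pref, sample(pref, mid_len, replace = TRUE),
                sample(AA_ALPHABET, mid_len, replace = TRUE))
  paste(c(start3, mid, end3), collapse = "")
}

#' Generate clonotypes with cluster-structured sequences and gene usage
#'
#' Each TCR cluster draws V/J genes from a cluster-specific categorical
#' distribution (one dominant gene per call at probability 0.8) and CDR3s
#' from a cluster-specific motif: fixed first-3 and last-3 anchor residues,
#' a preferred middle-residue set used with probability `motif_divergence`,
#' and tight cluster-specific lengths within 10-18. Clonotypes are assigned
#' to patients in balanced fashion; output is deterministic given the config
#' seed.
#'
#' @param config A [cohort_config()].
#' @return List with `clonotypes` (data.frame: `clonotype_id`, `patient_id`,
#'   `cdr3a`, `cdr3b`, `va`, `ja`, `vb`, `jb`, `antigen`) and `truth`
#'   (list with `true_cluster` -- 0-based labels named by clonotype id --
#'   and the per-cluster motif/gene parameters).
#' @export
generate_clonotypes <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  K <- config$n_tcr_clusters
  nc <- config$clonotypes_per_cluster
  n <- K * nc
  with_local_seed(config$seed, {
    pool_n <- max(12, 3 * K)
    pools <- list(va = paste0("TRAV", seq_len(pool_n)),
                  ja = paste0("TRAJ", seq_len(pool_n)),
                  vb = paste0("TRBV", seq_len(pool_n)),
                  jb = paste0("TRBJ", seq_len(pool_n)))
    dominant <- lapply(pools, function(p) sample(p, K))
    cluster_motif <- lapply(seq_len(K), function(k) {
      list(a_start = c("C", sample(AA_ALPHABET, 2, replace = TRUE)),
           a_end = c(sample(AA_ALPHABET, 2, replace = TRUE), "F"),
           b_start = c("C", sample(AA_ALPHABET, 2, replace = TRUE)),
           b_end = c(sample(AA_ALPHABET, 2, replace = TRUE), "F"),
           a_pref = sample(AA_ALPHABET, 5),
           b_pref = sample(AA_ALPHABET, 5),
           a_len = sample(12:16, 1),
           b_len = sample(12:16, 1))
    })
    draw_gene <- function(pool, dom) {
      if (stats::runif(1) < 0.8) dom else sample(pool, 1)
    }
    rows <- vector("list", n)
    true_cluster <- integer(n)
    i <- 0
    for (k in seq_len(K)) {
      mot <- cluster_motif[[k]]
      for (j in seq_len(nc)) {
        i <- i + 1
        true_cluster[i] <- k - 1L
        la <- min(max(mot$a_len + sample(-1:1, 1), 10), 18)
        lb <- min(max(mot$b_len + sample(-1:1, 1), 10), 18)
        rows[[i]] <- data.frame(
          clonotype_id = sprintf("ct%04d", i),
          cdr3a = random_cdr3(la, mot$a_start, mot$a_end, mot$a_pref,
                              config$motif_divergence),
          cdr3b = random_cdr3(lb, mot$b_start, mot$b_end, mot$b_pref,
                              config$motif_divergence),
          va = draw_gene(pools$va, dominant$va[k]),
          ja = draw_gene(pools$ja, dominant$ja[k]),
          vb = draw_gene(pools$vb, dominant$vb[k]),
          jb = draw_gene(pools$jb, dominant$jb[k]),
          antigen = "SYN-ANT", stringsAsFactors = FALSE)
      }
    }
    clonotypes <- do.call(rbind, rows)
    patients <- sprintf("P%02d", seq_len(config$n_patients))
    # stratified assignment: every cluster is spread evenly over patients
    # (public-response style), so patient repertoire composition is not
    # confounded with TCR cluster identity
    pat <- character(n)
    for (k in seq_len(K)) {
      idx <- which(true_cluster == k - 1L)
      pat[idx] <- sample(rep_len(sample(patients), length(idx)))
    }
    clonotypes$patient_id <- pat
    names(true_cluster) <- clonotypes$clonotype_id
    list(clonotypes = clonotypes,
         truth = list(true_cluster = true_cluster,
                      dominant_genes = dominant,
                      cluster_motif = cluster_motif))
  })
}

#' Generate cells, expression and environment omics for a clonotype set
#'
#' Builds the full multi-omic layer on top of [generate_clonotypes()]:
#' per-cell program activities as the weighted mixture
#' `w_tcr * cluster loading + w_plasma * plasma latent + w_hla * HLA latent +
#' w_cdc * cDC latent + w_noise * noise`; negative-binomial gene counts with
#' exp-linear means in the activities (module genes only); per-cluster cell
#' counts across timepoints following the contraction profile against the
#' configured repertoire size; low-rank-plus-noise plasma and cDC matrices;
#' an HLA presence/absence table; and background-driven surface proteins.
#'
#' @param clono Output of [generate_clonotypes()].
#' @param config The same [cohort_config()].
#' @return List with `cells` (data.frame: `cell_id`, `clonotype_id`,
#'   `patient_id`, `timepoint`, `batch`), `counts` (sparse gene x cell),
#'   `surface` (protein x cell), `plasma` (patient-timepoint x protein),
#'   `hla` (patient x allele 0/1), `cdc` (patient x feature), `totals`
#'   (percentage denominators per patient-timepoint), and `truth`
#'   (program loadings, environment latents, gene programs, per-cell
#'   activities, per-cluster T3 rate multipliers).
#' @export
generate_cells_and_omics <- function(clono, config) {
  stopifnot(inherits(config, "cohort_config"))
  clonotypes <- clono$clonotypes
  if (nrow(clonotypes) == 0) stop("clonotypes must be nonempty", call. = FALSE)
  true_cluster <- clono$truth$true_cluster
  K <- config$n_tcr_clusters
  m <- config$cells_per_clonotype_per_timepoint
  w <- config$effect_weights
  patients <- sprintf("P%02d", seq_len(config$n_patients))
  timepoints <- c("T1", "T2", "T3")

  with_local_seed(config$seed + 1L, {
    # cluster -> program loading: each cluster drives one program strongly
    load_raw <- matrix(0, K, 4, dimnames = list(NULL, PROGRAMS))
    for (k in seq_len(K)) load_raw[k, (k - 1) %% 4 + 1] <- 1
    loading <- (load_raw - 0.25) * 2  # spread across clusters, mean ~0

    # environment latents ------------------------------------------------
    samples <- as.vector(outer(patients, timepoints, paste, sep = "_"))
    S <- length(samples)
    # plasma: low-rank (5 factors) + noise; only factor 1 couples to the
    # T cell programs and it loads an "inflammatory" protein block (the
    # first fifth of the panel); the remaining factors are nuisance axes of
    # plasma variation
    P <- config$n_proteins_plasma
    n_fac <- 5
    Fmat <- matrix(stats::rnorm(S * n_fac), S, n_fac)
    Wl <- matrix(stats::rnorm(n_fac * P, sd = 0.1), n_fac, P)
    blocks <- split(seq_len(P), cut(seq_len(P), n_fac, labels = FALSE))
    for (f in seq_len(n_fac)) Wl[f, blocks[[f]]] <- 1
    plasma <- Fmat %*% Wl + matrix(stats::rnorm(S * P, sd = 0.3), S, P)
    dimnames(plasma) <- list(samples, sprintf("prot%03d", seq_len(P)))
    z_plasma <- setNames(Fmat[, 1], samples)

    # HLA: presence/absence over the allele pool, 6 alleles per patient
    A <- config$n_hla_alleles_pool
    hla <- matrix(0L, config$n_patients, A,
                  dimnames = list(patients, sprintf("HLA%03d", seq_len(A))))
    for (p in seq_len(config$n_patients)) {
      hla[p, sample(A, min(6, A))] <- 1L
    }
    allele_wt <- stats::rnorm(A)
    z_hla <- as.vector(hla %*% allele_wt)
    z_hla <- setNames(as.vector(scale(z_hla)), patients)
    if (anyNA(z_hla)) z_hla[] <- 0  # all patients identical: no HLA signal

    # cDC: rank-3 + noise per patient; only the first factor couples to the
    # T cell programs
    D <- config$n_cdc_features
    G <- matrix(stats::rnorm(config$n_patients * 3), config$n_patients, 3)
    V <- matrix(stats::rnorm(3 * D, sd = 0.8), 3, D)
    cdc <- G %*% V + matrix(stats::rnorm(config$n_patients * D, sd = 0.3),
                            config$n_patients, D)
    dimnames(cdc) <- list(patients, sprintf("cdc%03d", seq_len(D)))
    z_cdc <- setNames(G[, 1], patients)

    # direction of each environment latent in program space; plasma factor 1
    # (inflammatory) pushes toward interferon/cytotoxic, away from
    # naive/memory
    u_plasma <- c(-0.5, -0.5, 0.5, 0.5)
    u_hla <- sample(c(-0.5, 0.5), 4, replace = TRUE)
    u_cdc <- sample(c(-0.5, 0.5), 4, replace = TRUE)

    # contraction: per-cluster T3 rate multiplier hitting the target profile
    p_acute <- 100 * m / config$repertoire_size
    target_conv <- (p_acute + 1) * 10^config$contraction_profile - 1
    infeasible <- target_conv < 0
    if (any(infeasible)) {
      warning(sprintf(paste0("contraction target(s) %s below the achievable ",
                             "floor -log10(1 + %.3g); clamped to full ",
                             "contraction"),
                      paste(config$contraction_profile[infeasible],
                            collapse = ", "), p_acute), call. = FALSE)
      target_conv[infeasible] <- 0
    }
    t3_rate <- target_conv / p_acute

    # cells ---------------------------------------------------------------
    n_ct <- nrow(clonotypes)
    ct_cluster <- true_cluster[clonotypes$clonotype_id] + 1L
    cell_rows <- vector("list", n_ct * 3)
    r <- 0
    for (i in seq_len(n_ct)) {
      for (tp in timepoints) {
        mu_cells <- if (tp == "T3") m * t3_rate[ct_cluster[i]] else m
        nci <- stats::rpois(1, mu_cells)
        r <- r + 1
        if (nci == 0) next
        cell_rows[[r]] <- data.frame(
          clonotype_id = clonotypes$clonotype_id[i],
          patient_id = clonotypes$patient_id[i],
          timepoint = tp, stringsAsFactors = FALSE)[rep(1, nci), ]
      }
    }
    cells <- do.call(rbind, cell_rows)
    rownames(cells) <- NULL
    cells$cell_id <- sprintf("c%06d", seq_len(nrow(cells)))
    batch_of_patient <- setNames(
      paste0("B", (seq_len(config$n_patients) - 1) %% config$n_batches + 1),
      patients)
    cells$batch <- batch_of_patient[cells$patient_id]
    cells <- cells[, c("cell_id", "clonotype_id", "patient_id", "timepoint",
                       "batch")]

    # per-cell program activity -------------------------------------------
    # beyond its cluster's loading, each clonotype carries a small private
    # offset in program space: phenotype tracks the TCR continuously, not
    # only through cluster membership
    ncell <- nrow(cells)
    ct_offset <- matrix(stats::rnorm(n_ct * 4, sd = config$tcr_clonotype_sd),
                        n_ct, 4, dimnames = list(clonotypes$clonotype_id,
                                                 PROGRAMS))
    i_of_cell <- match(cells$clonotype_id, clonotypes$clonotype_id)
    k_of_cell <- ct_cluster[i_of_cell]
    samp_of_cell <- paste(cells$patient_id, cells$timepoint, sep = "_")
    activity <- w[["w_tcr"]] * (loading[k_of_cell, , drop = FALSE] +
                                ct_offset[i_of_cell, , drop = FALSE]) +
      w[["w_plasma"]] * outer(z_plasma[samp_of_cell], u_plasma) +
      w[["w_hla"]] * outer(z_hla[cells$patient_id], u_hla) +
      w[["w_cdc"]] * outer(z_cdc[cells$patient_id], u_cdc) +
      w[["w_noise"]] * matrix(stats::rnorm(ncell * 4), ncell, 4)
    dimnames(activity) <- list(cells$cell_id, PROGRAMS)

    # cluster-private program activity: beyond the 4 shared programs, each
    # TCR cluster carries its own small transcriptional signature (rank-K
    # TCR effect, mirroring the cluster-unique marker genes of real
    # repertoires); under pure noise the same variance comes from the
    # noise term so gene-level variance is weight-invariant
    private_act <- w[["w_tcr"]] *
      2 * (outer(k_of_cell, seq_len(K), "==") - 1 / K) +
      w[["w_noise"]] * matrix(stats::rnorm(ncell * K), ncell, K)

    # gene counts ----------------------------------------------------------
    ng <- config$n_genes
    genes <- sprintf("g%04d", seq_len(ng))
    gene_program <- rep(NA_character_, ng)
    gene_program[seq_len(4 * config$n_module_genes)] <-
      rep(PROGRAMS, each = config$n_module_genes)
    npv <- config$n_private_genes_per_cluster
    gene_private <- rep(NA_integer_, ng)
    if (npv > 0) {
      gene_private[4 * config$n_module_genes + seq_len(K * npv)] <-
        rep(seq_len(K) - 1L, each = npv)
    }
    b0 <- stats::rnorm(ng, mean = log(1.5), sd = 0.5)
    batch_offset <- matrix(stats::rnorm(ng * config$n_batches,
                                        sd = config$batch_sd),
                           ng, config$n_batches,
                           dimnames = list(genes,
                                           paste0("B",
                                                  seq_len(config$n_batches))))
    logmu <- matrix(rep(b0, ncell), ng, ncell)
    for (p in seq_along(PROGRAMS)) {
      idx <- which(gene_program == PROGRAMS[p])
      logmu[idx, ] <- logmu[idx, ] +
        matrix(rep(activity[, p], each = length(idx)), length(idx), ncell)
    }
    for (k in seq_len(K)) {
      idx <- which(gene_private == k - 1L)
      if (length(idx) > 0) {
        logmu[idx, ] <- logmu[idx, ] +
          matrix(rep(private_act[, k], each = length(idx)), length(idx),
                 ncell)
      }
    }
    logmu <- logmu + batch_offset[, match(cells$batch,
                                          colnames(batch_offset))]
    size <- 1 / config$nb_dispersion
    counts <- matrix(stats::rnbinom(ng * ncell, mu = exp(logmu), size = size),
                     ng, ncell, dimnames = list(genes, cells$cell_id))
    counts <- Matrix::Matrix(counts, sparse = TRUE)

    # surface proteins ------------------------------------------------------
    np <- config$n_surface_proteins
    n_bg <- min(4, max(2, np - 4))
    prog_prot <- paste0("sp_", PROGRAMS)[seq_len(min(4, np - n_bg))]
    other_n <- np - length(prog_prot) - n_bg
    prot_names <- c(prog_prot,
                    if (other_n > 0) sprintf("sp%02d", seq_len(other_n)),
                    paste0("iso", seq_len(n_bg)))
    logmu_p <- matrix(log(3), np, ncell, dimnames = list(prot_names, NULL))
    for (p in seq_along(prog_prot)) {
      logmu_p[p, ] <- log(10) + 0.8 * activity[, p]
    }
    if (other_n > 0) {
      logmu_p[length(prog_prot) + seq_len(other_n), ] <-
        stats::rnorm(other_n, log(5), 0.3)
    }
    surface <- matrix(stats::rnbinom(np * ncell, mu = exp(logmu_p), size = 2),
                      np, ncell, dimnames = list(prot_names, cells$cell_id))

    totals <- expand.grid(patient_id = patients, timepoint = timepoints,
                          stringsAsFactors = FALSE)
    totals$total_cells <- config$repertoire_size

    truth <- c(clono$truth,
               list(loading = loading,
                    z_plasma = z_plasma, z_hla = z_hla, z_cdc = z_cdc,
                    u_plasma = u_plasma, u_hla = u_hla, u_cdc = u_cdc,
                    plasma_blocks = blocks,
                    gene_program = setNames(gene_program, genes),
                    gene_private = setNames(gene_private, genes),
                    activity = activity,
                    t3_rate = t3_rate,
                    background_proteins = paste0("iso", seq_len(n_bg)),
                    batch_offset = batch_offset))
    list(cells = cells, counts = counts, surface = surface, plasma = plasma,
         hla = hla, cdc = cdc, totals = totals, truth = truth)
  })
}

#' Simulate a full labeled cohort
#'
#' Convenience wrapper running [generate_clonotypes()] and
#' [generate_cells_and_omics()] with one config.
#'
#' @param config A [cohort_config()].
#' @return List with `clonotypes`, `cells`, `counts`, `surface`, `plasma`,
#'   `hla`, `cdc`, `totals`, `truth` and `config`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  clono <- generate_clonotypes(config)
  omics <- generate_cells_and_omics(clono, config)
  c(list(clonotypes = clono$clonotypes, config = config), omics)
}

#' Planted TRAV-usage contraction fixture
#'
#' Generates clusters whose contraction strength is exactly linear in the
#' realized usage percentage of one focal TRAV gene plus Gaussian noise:
#' `C_k = slope * usage_pct_k + intercept + eps`, for testing coefficient
#' recovery of [fit_trav_model()].
#'
#' @param n_clusters Number of clusters (default 12).
#' @param clonotypes_per_cluster Clonotypes per cluster (default 20).
#' @param slope,intercept Planted linear relation on the percent scale.
#' @param sigma Noise SD on contraction strength (default 0.05).
#' @param focal_gene Focal TRAV gene (default `"TRAV9"`).
#' @param seed Integer seed.
#' @return List with `clonotypes`, `clusters` (named assignment),
#'   `contraction` (data.frame usable by [fit_trav_model()]), `usage_pct`
#'   (realized focal usage per cluster), `slope`, `intercept`.
#' @export
simulate_trav_contraction <- function(n_clusters = 12,
                                      clonotypes_per_cluster = 20,
                                      slope = -0.01, intercept = -0.2,
                                      sigma = 0.05, focal_gene = "TRAV9",
                                      seed = 1) {
  with_local_seed(seed, {
    other <- setdiff(paste0("TRAV", 1:16), focal_gene)
    frac <- seq(0.05, 0.95, length.out = n_clusters)
    rows <- NULL
    clusters <- character(0)
    i <- 0
    for (k in seq_len(n_clusters)) {
      for (j in seq_len(clonotypes_per_cluster)) {
        i <- i + 1
        va <- if (stats::runif(1) < frac[k]) focal_gene else sample(other, 1)
        rows <- rbind(rows, data.frame(clonotype_id = sprintf("tc%04d", i),
                                       va = va, stringsAsFactors = FALSE))
        clusters <- c(clusters, setNames(as.character(k - 1),
                                         sprintf("tc%04d", i)))
      }
    }
    usage_pct <- vapply(seq_len(n_clusters), function(k) {
      ids <- names(clusters)[clusters == as.character(k - 1)]
      100 * mean(rows$va[match(ids, rows$clonotype_id)] == focal_gene)
    }, numeric(1))
    C <- slope * usage_pct + intercept + stats::rnorm(n_clusters, sd = sigma)
    contraction <- data.frame(cluster = as.character(seq_len(n_clusters) - 1),
                              contraction_strength = C,
                              stringsAsFactors = FALSE)
    list(clonotypes = rows, clusters = clusters, contraction = contraction,
         usage_pct = usage_pct, slope = slope, intercept = intercept)
  })
}
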