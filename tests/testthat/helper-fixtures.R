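# Shared fixtures built in code.

# A small cohort configuration for fast unit tests.
small_config <- function(seed = 11, contraction_profile = c(-0.3, -0.15, 0),
                         ...) {
  cohort_config(n_patients = 6, n_tcr_clusters = 3,
                clonotypes_per_cluster = 6,
                cells_per_clonotype_per_timepoint = 5,
                n_genes = 80, n_module_genes = 8,
                n_private_genes_per_cluster = 4,
                n_proteins_plasma = 12, n_surface_proteins = 10,
                n_cdc_features = 8, n_hla_alleles_pool = 12,
                contraction_profile = contraction_profile,
                repertoire_size = 120, seed = seed, ...)
}

# Hand-built clonotype records with controllable sequences.
make_clonotypes <- function(cdr3a, cdr3b, va = NULL, ja = NULL, vb = NULL,
                            jb = NULL, patient = "P01") {
  n <- length(cdr3a)
  data.frame(clonotype_id = sprintf("x%03d", seq_len(n)),
             patient_id = rep_len(patient, n),
             cdr3a = cdr3a, cdr3b = cdr3b,
             va = if (is.null(va)) rep("TRAV1", n) else va,
             ja = if (is.null(ja)) rep("TRAJ1", n) else ja,
             vb = if (is.null(vb)) rep("TRBV1", n) else vb,
             jb = if (is.null(jb)) rep("TRBJ1", n) else jb,
             antigen = "SYN-ANT", stringsAsFactors = FALSE)
}

random_clonotypes <- function(n, seed = 1, len_range = 10:18) {
  set.seed(seed)
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  rand_seq <- function() {
    paste(sample(aa, sample(len_range, 1), replace = TRUE), collapse = "")
  }
  make_clonotypes(cdr3a = replicate(n, rand_seq()),
                  cdr3b = replicate(n, rand_seq()),
                  va = sample(paste0("TRAV", 1:6), n, replace = TRUE),
                  ja = sample(paste0("TRAJ", 1:6), n, replace = TRUE),
                  vb = sample(paste0("TRBV", 1:6), n, replace = TRUE),
                  jb = sample(paste0("TRBJ", 1:6), n, replace = TRUE))
}

# A tcr_graph built from explicit 2-D coordinates (Euclidean distances).
graph_from_points <- function(xy, n_neighbors, graph_pcs = 2) {
  D <- as.matrix(stats::dist(xy))
  rownames(D) <- colnames(D) <- sprintf("p%03d", seq_len(nrow(xy)))
  build_tcr_graph(D, n_pcs = min(10, nrow(xy) - 1),
                  n_neighbors = n_neighbors, graph_pcs = graph_pcs)
}

# Two well-separated blocks: within-block distance ~small, between ~large.
two_block_distance <- function(n_per_block = 20, gap = 50, seed = 3) {
  set.seed(seed)
  xy <- rbind(cbind(rnorm(n_per_block), rnorm(n_per_block)),
              cbind(rnorm(n_per_block) + gap, rnorm(n_per_block)))
  D <- as.matrix(stats::dist(xy))
  rownames(D) <- colnames(D) <- sprintf("n%03d", seq_len(2 * n_per_block))
  D
}
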