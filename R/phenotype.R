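# Expression normalization, marker genes, co-expression modules, signature
# scoring, surface-protein normalization and embedding-density diffusion.

#' Log CPM normalization
#'
#' `x = ln(1 + 1e6 * count / cell_total)` per gene and cell. Cells with zero
#' total counts are excluded with a warning.
#'
#' @param counts Gene x cell count matrix (dense or `Matrix` sparse),
#'   nonnegative.
#' @return Normalized matrix of the same class (genes x cells), possibly with
#'   zero-total cells dropped.
#' @export
normalize_log_cpm <- function(counts) {
  totals <- Matrix::colSums(counts)
  if (any(totals == 0)) {
    warning(sprintf("excluding %d cell(s) with zero total counts",
                    sum(totals == 0)), call. = FALSE)
    counts <- counts[, totals > 0, drop = FALSE]
    totals <- totals[totals > 0]
  }
  if (inherits(counts, "sparseMatrix")) {
    cpm <- counts %*% Matrix::Diagonal(x = 1e6 / totals)
    colnames(cpm) <- colnames(counts)
    log1p(cpm)
  } else {
    log1p(sweep(counts, 2, 1e6 / totals, "*"))
  }
}

# Vectorized tie-corrected one-vs-rest Mann-Whitney U over the rows of X.
# Exact p-values (via wilcox.test) are used for small untied problems.
mwu_one_vs_rest <- function(X, in_group) {
  X <- as.matrix(X)
  n <- ncol(X)
  n1 <- sum(in_group)
  n2 <- n - n1
  rk <- t(apply(X, 1, rank))
  R1 <- rowSums(rk[, in_group, drop = FALSE])
  U <- R1 - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  # tie correction per gene
  tie_term <- apply(X, 1, function(v) {
    t <- table(v)
    sum(t^3 - t)
  })
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (n <= 30) {
    p <- vapply(seq_len(nrow(X)), function(g) {
      suppressWarnings(stats::wilcox.test(X[g, in_group], X[g, !in_group],
                                          exact = (tie_term[g] == 0))$p.value)
    }, numeric(1))
  } else {
    z <- ifelse(sigma2 > 0, (U - mu) / sqrt(sigma2), 0)
    p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
    p <- pmin(p, 1)
  }
  p[sigma2 == 0] <- 1  # gene constant across all cells: no separation
  list(U = U, p = p)
}

#' One-vs-rest marker genes per label (Mann-Whitney U)
#'
#' For each label, each gene is tested with a two-sided Mann-Whitney U test
#' of the label's cells against all other cells on normalized expression;
#' p-values are Benjamini-Hochberg adjusted across genes within each label.
#' The log-fold-change column is the difference of mean normalized (ln CPM)
#' expression, label minus rest.
#'
#' @param X Normalized gene x cell matrix (see [normalize_log_cpm()]).
#' @param labels Per-cell label vector (>= 2 labels, each with >= 3 cells).
#' @return Named list (one per label) of data.frames with columns `gene`,
#'   `U`, `p`, `p_adj`, `log_fold_change`, ordered by increasing p.
#' @export
rank_marker_genes <- function(X, labels) {
  labels <- as.character(labels)
  if (length(labels) != ncol(X)) {
    stop("labels must have one entry per cell", call. = FALSE)
  }
  tab <- table(labels)
  if (length(tab) < 2 || any(tab < 3)) {
    stop("need >= 2 labels with >= 3 cells each", call. = FALSE)
  }
  genes <- rownames(X)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(X)))
  out <- list()
  Xd <- as.matrix(X)
  for (lab in names(tab)) {
    in_group <- labels == lab
    res <- mwu_one_vs_rest(Xd, in_group)
    lfc <- rowMeans(Xd[, in_group, drop = FALSE]) -
      rowMeans(Xd[, !in_group, drop = FALSE])
    df <- data.frame(gene = genes, U = res$U, p = res$p,
                     p_adj = stats::p.adjust(res$p, "BH"),
                     log_fold_change = lfc, stringsAsFactors = FALSE,
                     row.names = NULL)
    out[[lab]] <- df[order(df$p, -abs(df$log_fold_change)), ]
  }
  out
}

#' Co-expression modules from top marker genes
#'
#' Takes the union of the `top_n` marker genes per label, computes the
#' gene-gene Pearson correlation on normalized expression, clusters genes by
#' Ward's method on distance `1 - r`, and picks the cluster count in
#' `k_range` maximizing the mean silhouette width (ties: smallest k).
#' Constant genes are dropped with a warning before correlation.
#'
#' @param X Normalized gene x cell matrix.
#' @param markers Output of [rank_marker_genes()].
#' @param top_n Markers per label to pool (default 25).
#' @param k_range Candidate module counts (default `10:20`).
#' @return List with `modules` (module id -> gene vector), `k`,
#'   `silhouette` (per candidate k), and `assignment` (gene -> module id).
#' @export
discover_modules <- function(X, markers, top_n = 25, k_range = 10:20) {
  genes <- unique(unlist(lapply(markers, function(df) {
    utils::head(df$gene, top_n)
  })))
  Xg <- as.matrix(X[genes, , drop = FALSE])
  const <- apply(Xg, 1, stats::sd) == 0
  if (any(const)) {
    warning(sprintf("dropping %d constant gene(s) before correlation",
                    sum(const)), call. = FALSE)
    Xg <- Xg[!const, , drop = FALSE]
    genes <- genes[!const]
  }
  if (length(genes) < max(k_range) + 1) {
    stop(sprintf("only %d usable genes; need more than max(k_range) = %d",
                 length(genes), max(k_range)), call. = FALSE)
  }
  C <- stats::cor(t(Xg))
  d <- stats::as.dist(1 - C)
  if (max(d) < 1e-12) {
    warning("all genes are mutually perfectly correlated; silhouette is ",
            "undefined for k > 1, returning k = min(k_range)", call. = FALSE)
    k <- min(k_range)
    cl <- stats::cutree(stats::hclust(d, method = "ward.D2"), k = k)
    return(list(modules = split(genes, cl), k = k,
                silhouette = setNames(rep(NA_real_, length(k_range)),
                                      k_range),
                assignment = setNames(cl, genes)))
  }
  hc <- stats::hclust(d, method = "ward.D2")
  sil <- setNames(rep(NA_real_, length(k_range)), k_range)
  for (k in k_range) {
    cl <- stats::cutree(hc, k = k)
    if (length(unique(cl)) < 2) next
    sw <- try(cluster::silhouette(cl, d), silent = TRUE)
    if (!inherits(sw, "try-error")) {
      m <- mean(sw[, "sil_width"])
      if (is.finite(m)) sil[as.character(k)] <- m
    }
  }
  if (all(is.na(sil))) {
    warning("silhouette undefined for every candidate k (degenerate ",
            "geometry); returning k = min(k_range)", call. = FALSE)
    k_best <- min(k_range)
  } else {
    k_best <- k_range[which.max(round(sil, 12))]  # ties -> smallest k
  }
  cl <- stats::cutree(hc, k = k_best)
  list(modules = split(genes, cl), k = k_best, silhouette = sil,
       assignment = setNames(cl, genes))
}

#' Mean-expression signature score per cell
#'
#' Mean of normalized (ln CPM) expression over the signature genes present in
#' the matrix. Missing genes are reported via a warning and the
#' `missing_genes` attribute.
#'
#' @param X Normalized gene x cell matrix.
#' @param genes Signature gene vector.
#' @return Named numeric vector of per-cell scores.
#' @export
score_signature <- function(X, genes) {
  present <- intersect(genes, rownames(X))
  missing <- setdiff(genes, rownames(X))
  if (length(present) == 0) {
    stop("none of the signature genes are present in the matrix",
         call. = FALSE)
  }
  if (length(missing) > 0) {
    warning(sprintf("%d signature gene(s) missing from the matrix: %s",
                    length(missing),
                    paste(utils::head(missing, 5), collapse = ", ")),
            call. = FALSE)
  }
  out <- Matrix::colMeans(X[present, , drop = FALSE])
  attr(out, "missing_genes") <- missing
  out
}

#' Per-batch standardization of a signature matrix
#'
#' Within each batch, every signature column is centered and scaled to unit
#' variance (zero-variance columns become 0). A defined, deterministic
#' correction for additive batch effects in signature space. Singleton
#' batches are left uncentered with a warning.
#'
#' @param S Cell x signature numeric matrix.
#' @param batch Per-cell batch id vector.
#' @return Corrected matrix of the same shape.
#' @export
batch_standardize_signatures <- function(S, batch) {
  S <- as.matrix(S)
  if (length(batch) != nrow(S)) {
    stop("batch must have one entry per cell (row of S)", call. = FALSE)
  }
  out <- S
  for (b in unique(batch)) {
    idx <- which(batch == b)
    if (length(idx) < 2) {
      warning(sprintf("batch '%s' has a single cell; left uncentered", b),
              call. = FALSE)
      next
    }
    block <- scale(S[idx, , drop = FALSE])
    block[, attr(block, "scaled:scale") == 0] <- 0
    out[idx, ] <- block
  }
  out
}

#' Background-relative surface protein normalization
#'
#' CITE-seq style normalization: per cell, each protein's `ln(1 + count)` is
#' z-scored against that cell's mean and SD over the designated background
#' (isotype-like) proteins. Cells whose background SD is zero are flagged and
#' set to 0.
#'
#' @param P Protein x cell count matrix.
#' @param background Character vector of background protein row names
#'   (>= 2 required).
#' @return List with `z` (protein x cell z-score matrix) and `flagged`
#'   (cell names with zero background SD).
#' @export
normalize_surface_proteins <- function(P, background) {
  P <- as.matrix(P)
  if (length(background) < 2) {
    stop("need at least 2 background proteins", call. = FALSE)
  }
  if (!all(background %in% rownames(P))) {
    stop("background protein(s) not found: ",
         paste(setdiff(background, rownames(P)), collapse = ", "),
         call. = FALSE)
  }
  L <- log1p(P)
  mu <- colMeans(L[background, , drop = FALSE])
  sdv <- apply(L[background, , drop = FALSE], 2, stats::sd)
  flagged <- colnames(P)[sdv == 0]
  if (length(flagged) > 0) {
    warning(sprintf("%d cell(s) have zero background SD; z set to 0",
                    length(flagged)), call. = FALSE)
  }
  sdv[sdv == 0] <- Inf  # z -> 0 for flagged cells
  z <- sweep(sweep(L, 2, mu, "-"), 2, sdv, "/")
  list(z = z, flagged = flagged)
}

#' Gaussian embedding density with kNN diffusion
#'
#' Computes a Gaussian kernel density estimate of the member cells over the
#' 2-D embedding, min-max scales it to `[0, 1]`, then diffuses mass for
#' `iterations` steps: `x <- t(A) %*% x`, where `A` is the row-normalized
#' k-nearest-neighbor adjacency with self-loops. Because each cell
#' redistributes its mass over a row summing to one, the total density is
#' conserved across iterations.
#'
#' @param coords Cell x 2 embedding coordinates.
#' @param members Logical vector flagging the cells whose density is
#'   estimated.
#' @param k Neighborhood size for diffusion (default 5).
#' @param iterations Number of diffusion steps (default 5).
#' @return Named numeric density vector over all cells.
#' @export
diffuse_embedding_density <- function(coords, members, k = 5, iterations = 5) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < k + 1) {
    stop(sprintf("need at least k + 1 = %d cells, got %d", k + 1, n),
         call. = FALSE)
  }
  if (length(members) != n) {
    stop("members must flag every cell", call. = FALSE)
  }
  ids <- rownames(coords)
  if (!any(members)) {
    warning("no member cells; returning zero density", call. = FALSE)
    return(setNames(numeric(n), ids))
  }
  mc <- coords[members, , drop = FALSE]
  m <- nrow(mc)
  # Scott's rule bandwidth per dimension (2-D KDE)
  h <- apply(mc, 2, stats::sd) * m^(-1 / 6)
  bad <- h == 0 | !is.finite(h)
  if (any(bad)) {
    # degenerate member spread (e.g. a single member): fall back to the
    # spread of the whole embedding
    fallback <- pmax(apply(coords, 2, stats::sd) * n^(-1 / 6), 1e-8)
    h[bad] <- fallback[bad]
  }
  d1 <- outer(coords[, 1], mc[, 1], "-") / h[1]
  d2 <- outer(coords[, 2], mc[, 2], "-") / h[2]
  dens <- rowMeans(exp(-(d1^2 + d2^2) / 2)) / (2 * pi * h[1] * h[2])
  rng <- range(dens)
  # an (effectively) uniform density stays uniform rather than having
  # numerical noise blown up to [0, 1]
  dens <- if (diff(rng) <= 1e-10 * max(abs(rng), 1e-300)) rep(1, n) else
    (dens - rng[1]) / diff(rng)

  dd <- as.matrix(stats::dist(coords))
  nn <- knn_indices(dd, k)
  A <- matrix(0, n, n)
  A[cbind(rep(seq_len(n), each = k), as.vector(t(nn)))] <- 1
  diag(A) <- 1
  A <- A / rowSums(A)
  x <- dens
  for (i in seq_len(iterations)) x <- as.vector(crossprod(A, x))
  setNames(x, ids)
}
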