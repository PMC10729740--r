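# Diffusion components, pseudotime and the cluster sequence-similarity metric.
#
# The similarity metric compares a clonotype's diffusion-space distance to two
# TCR clusters: s(i) = mean over roots in B of dpt(i, root) minus the same
# mean over roots in A, so s > 0 means closer in sequence space to cluster A.

#' Diffusion components of the clonotype neighbor graph
#'
#' Standard diffusion-map construction: the kernel (graph adjacency) is
#' row-normalized to a transition matrix; its symmetric conjugate
#' `D^{-1/2} K D^{-1/2}` is eigendecomposed; the trivial constant eigenpair
#' is dropped and the top `n_dcs` nontrivial pairs are returned together with
#' scaled coordinates `phi_k = (lambda_k / (1 - lambda_k)) * psi_k`.
#' Disconnected graphs are decomposed per connected component (with a
#' warning); diffusion distances across components are infinite.
#'
#' @param graph A `tcr_graph`.
#' @param n_dcs Number of nontrivial diffusion components (default 15).
#' @return Object of class `diffusion_space`: list with `ids`, `evals`
#'   (per component), `phi` (clonotype x DC scaled coordinates), `psi`,
#'   and `component` (integer component id per clonotype).
#' @export
diffusion_components <- function(graph, n_dcs = 15) {
  stopifnot(inherits(graph, "tcr_graph"))
  A <- as.matrix(graph$adjacency)
  n <- nrow(A)
  g <- igraph::graph_from_adjacency_matrix(graph$adjacency,
                                           mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  comp <- igraph::components(g)$membership
  if (max(comp) > 1) {
    warning(sprintf("graph has %d connected components; ", max(comp)),
            "diffusion components computed per component and cross-component ",
            "pseudotime is infinite", call. = FALSE)
  }
  phi <- matrix(0, n, n_dcs, dimnames = list(graph$ids,
                                             paste0("DC", seq_len(n_dcs))))
  psi <- phi
  evals <- vector("list", max(comp))
  for (cid in seq_len(max(comp))) {
    idx <- which(comp == cid)
    m <- length(idx)
    if (m == 1) { evals[[cid]] <- numeric(0); next }
    K <- A[idx, idx, drop = FALSE]
    d <- rowSums(K)
    d[d == 0] <- .Machine$double.eps
    S <- K / sqrt(d %o% d)
    eig <- eigen((S + t(S)) / 2, symmetric = TRUE)
    # first eigenpair (lambda = 1, psi constant) is trivial; keep the next
    # n_dcs with positive eigenvalue
    keep <- seq(2, m)
    keep <- keep[eig$values[keep] > 1e-12]
    keep <- utils::head(keep, n_dcs)
    lam <- eig$values[keep]
    v <- eig$vectors[, keep, drop = FALSE]
    ps <- v / sqrt(d)
    # normalize each psi to unit norm for scale stability
    ps <- sweep(ps, 2, sqrt(colSums(ps^2)), "/")
    lam <- pmin(lam, 1 - 1e-12)
    if (length(keep) > 0) {
      psi[idx, seq_along(keep)] <- ps
      phi[idx, seq_along(keep)] <- sweep(ps, 2, lam / (1 - lam), "*")
    }
    evals[[cid]] <- lam
  }
  structure(list(ids = graph$ids, evals = evals, phi = phi, psi = psi,
                 component = comp),
            class = "diffusion_space")
}

#' Diffusion pseudotime from a root clonotype
#'
#' `dpt(i, root)` is the Euclidean norm of `phi(i) - phi(root)` in scaled
#' diffusion coordinates (infinite across graph components).
#'
#' @param space A `diffusion_space`.
#' @param root Clonotype id used as root.
#' @return Named nonnegative numeric vector over all clonotypes.
#' @export
pseudotime_from_root <- function(space, root) {
  stopifnot(inherits(space, "diffusion_space"))
  r <- match(root, space$ids)
  if (is.na(r)) stop(sprintf("unknown root clonotype '%s'", root), call. = FALSE)
  d <- sqrt(rowSums(sweep(space$phi, 2, space$phi[r, ], "-")^2))
  d[space$component != space$component[r]] <- Inf
  setNames(d, space$ids)
}

resolve_members <- function(spec_ids, clusters, space, what) {
  if (length(spec_ids) == 1 && !is.null(clusters) &&
      any(clusters == spec_ids)) {
    members <- names(clusters)[clusters == spec_ids]
  } else {
    members <- as.character(spec_ids)
  }
  if (length(members) == 0) {
    stop(sprintf("cluster %s is empty", what), call. = FALSE)
  }
  bad <- setdiff(members, space$ids)
  if (length(bad) > 0) {
    stop(sprintf("cluster %s contains unknown clonotype(s): %s", what,
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  members
}

#' Sequence-similarity score of every clonotype toward cluster A vs cluster B
#'
#' Averages diffusion pseudotime over all roots in cluster B, subtracts the
#' average over all roots in cluster A: positive scores mean the clonotype is
#' closer (more similar in TCR sequence) to cluster A; negative scores mean
#' closer to cluster B. Swapping A and B negates the score exactly.
#'
#' @param space A `diffusion_space`.
#' @param clusters Named cluster assignment (e.g. from
#'   [cluster_resolution_search()]`$assignment`); may be `NULL` when `A` and
#'   `B` are given as explicit id vectors.
#' @param A,B Cluster labels (single values looked up in `clusters`) or
#'   character vectors of clonotype ids. Must not denote the same single label.
#' @return Data.frame with columns `clonotype_id`, `score`, and attributes
#'   `clusterA`, `clusterB`.
#' @export
pairwise_cluster_similarity <- function(space, clusters, A, B) {
  stopifnot(inherits(space, "diffusion_space"))
  if (length(A) == 1 && length(B) == 1 && identical(A, B)) {
    stop("clusters A and B must differ", call. = FALSE)
  }
  mA <- resolve_members(A, clusters, space, "A")
  mB <- resolve_members(B, clusters, space, "B")
  iA <- match(mA, space$ids)
  iB <- match(mB, space$ids)
  # pairwise diffusion distances to all roots at once
  dist_to <- function(rows) {
    phi <- space$phi
    out <- matrix(0, nrow(phi), length(rows))
    for (k in seq_along(rows)) {
      r <- rows[k]
      d <- sqrt(rowSums(sweep(phi, 2, phi[r, ], "-")^2))
      d[space$component != space$component[r]] <- Inf
      out[, k] <- d
    }
    out
  }
  s <- rowMeans(dist_to(iB)) - rowMeans(dist_to(iA))
  out <- data.frame(clonotype_id = space$ids, score = s,
                    stringsAsFactors = FALSE)
  attr(out, "clusterA") <- A
  attr(out, "clusterB") <- B
  out
}

#' Binned association between a similarity score and a clonotype variable
#'
#' Bins the score axis into `n_bins` equal-width bins, drops empty bins, and
#' reports the Pearson correlation (with two-sided p) between the bin-mean
#' score and the bin-mean variable. (Bin means rather than geometric bin
#' centers are used on the score axis so that a variable identical to the
#' score correlates exactly 1.)
#'
#' @param score Data.frame from [pairwise_cluster_similarity()] or a named
#'   numeric vector of scores.
#' @param variable Named numeric vector (per clonotype) or numeric vector
#'   aligned with `score`.
#' @param n_bins Number of equal-width bins (default 25).
#' @return List with `r`, `p`, `n_bins_used` and the per-bin `table`.
#' @export
binned_association <- function(score, variable, n_bins = 25) {
  if (is.data.frame(score)) {
    s <- setNames(score$score, score$clonotype_id)
  } else s <- score
  if (!is.null(names(variable)) && !is.null(names(s))) {
    variable <- variable[names(s)]
  }
  keep <- is.finite(s) & is.finite(variable)
  s <- s[keep]; variable <- variable[keep]
  if (length(s) < n_bins) {
    stop(sprintf("need at least n_bins = %d scored clonotypes, got %d",
                 n_bins, length(s)), call. = FALSE)
  }
  brk <- seq(min(s), max(s), length.out = n_bins + 1)
  bin <- cut(s, breaks = brk, include.lowest = TRUE)
  score_means <- tapply(s, bin, mean)
  means <- tapply(variable, bin, mean)
  nonempty <- !is.na(means)
  if (sum(nonempty) < 3) {
    stop("fewer than 3 nonempty bins; cannot correlate", call. = FALSE)
  }
  ct <- stats::cor.test(as.numeric(score_means[nonempty]),
                        as.numeric(means[nonempty]))
  list(r = unname(ct$estimate), p = ct$p.value, n_bins_used = sum(nonempty),
       table = data.frame(score = as.numeric(score_means[nonempty]),
                          mean = as.numeric(means[nonempty]),
                          n = as.integer(table(bin)[nonempty])))
}

#' Cluster-level connectivity from a diffusion-space kNN graph
#'
#' Builds a k-nearest-neighbor graph in diffusion coordinates and scores each
#' cluster pair by observed inter-cluster edge count divided by the count
#' expected when edges are placed proportionally to cluster degree sums
#' (configuration-model expectation `deg_A * deg_B / (2E)`), clipped to
#' `[0, 1]`.
#'
#' @param space A `diffusion_space`.
#' @param clusters Named cluster assignment over the clonotypes.
#' @param k Neighborhood size (default 20).
#' @return Data.frame edge list with columns `clusterA`, `clusterB`,
#'   `observed`, `expected`, `weight`; symmetric by construction.
#' @export
cluster_connectivity <- function(space, clusters, k = 20) {
  stopifnot(inherits(space, "diffusion_space"))
  n <- length(space$ids)
  if (n < k + 1) {
    stop(sprintf("need at least k + 1 = %d clonotypes, got %d", k + 1, n),
         call. = FALSE)
  }
  clusters <- clusters[space$ids]
  dd <- as.matrix(stats::dist(space$phi))
  dd[outer(space$component, space$component, "!=")] <- Inf
  nn <- knn_indices(dd, k)
  from <- rep(seq_len(n), each = k)
  to <- as.vector(t(nn))
  # drop infinite (cross-component) pseudo-neighbors, then take the
  # undirected union edge set
  keep <- is.finite(dd[cbind(from, to)])
  e <- unique(t(apply(cbind(from, to)[keep, , drop = FALSE], 1, sort)))
  labs <- sort(unique(clusters))
  deg <- setNames(numeric(length(labs)), labs)
  for (l in labs) deg[as.character(l)] <- sum(clusters[e[, 1]] == l) +
    sum(clusters[e[, 2]] == l)
  E <- nrow(e)
  out <- NULL
  for (i in seq_along(labs)) {
    for (j in seq_along(labs)) {
      if (j <= i) next
      a <- labs[i]; b <- labs[j]
      obs <- sum((clusters[e[, 1]] == a & clusters[e[, 2]] == b) |
                 (clusters[e[, 1]] == b & clusters[e[, 2]] == a))
      expd <- deg[as.character(a)] * deg[as.character(b)] / (2 * E)
      w <- if (expd > 0) min(1, obs / expd) else 0
      out <- rbind(out, data.frame(clusterA = a, clusterB = b,
                                   observed = obs, expected = unname(expd),
                                   weight = unname(w)))
    }
  }
  out
}
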