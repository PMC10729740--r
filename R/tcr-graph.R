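# Neighbor graph, Leiden clustering and 2-D embedding of clonotype distances.

#' Build a kNN graph from a clonotype distance matrix
#'
#' The distance matrix rows (distances-to-all-clonotypes) are treated as a
#' feature matrix, centered and reduced by PCA; the k-nearest-neighbor graph
#' is computed in the leading `graph_pcs` principal components with Euclidean
#' metric. Edge weights come from a locally adaptive Gaussian kernel
#' `exp(-d^2 / (sigma_i * sigma_j))`, where `sigma_i` is clonotype i's
#' distance to its k-th neighbor, symmetrized over the union of directed
#' neighborhoods (equivalent to taking the max of the two directed weights).
#'
#' @param D Symmetric clonotype distance matrix with id dimnames
#'   (see [compute_tcrdist()]).
#' @param n_pcs Number of principal components to retain (default 50).
#' @param n_neighbors Neighborhood size k (default 30).
#' @param graph_pcs Number of leading PCs used for the kNN search (default 20).
#' @param method `"rows"` (default) performs PCA on the centered rows of `D`;
#'   `"mds"` uses classical multidimensional scaling of `D` instead.
#' @return An object of class `tcr_graph`: list with elements `ids`, `pcs`
#'   (clonotype x PC coordinates), `adjacency` (sparse symmetric weight
#'   matrix), `knn` (index matrix of neighbors), and `params`.
#' @export
build_tcr_graph <- function(D, n_pcs = 50, n_neighbors = 30, graph_pcs = 20,
                            method = c("rows", "mds")) {
  method <- match.arg(method)
  n <- nrow(D)
  ids <- rownames(D)
  if (is.null(ids)) ids <- paste0("ct", seq_len(n))
  if (n < n_neighbors + 1) {
    stop(sprintf(paste0("only %d clonotypes but n_neighbors = %d; ",
                        "use a smaller k (at most %d)"),
                 n, n_neighbors, n - 1), call. = FALSE)
  }
  n_pcs <- min(n_pcs, n - 1, ncol(D))
  if (method == "rows") {
    pcs <- stats::prcomp(D, center = TRUE, scale. = FALSE, rank. = n_pcs)$x
  } else {
    pcs <- stats::cmdscale(stats::as.dist(D), k = n_pcs)
    colnames(pcs) <- paste0("PC", seq_len(ncol(pcs)))
  }
  rownames(pcs) <- ids
  graph_pcs <- min(graph_pcs, ncol(pcs))
  emb <- pcs[, seq_len(graph_pcs), drop = FALSE]

  dd <- as.matrix(stats::dist(emb))
  nn_idx <- knn_indices(dd, n_neighbors)
  sigma <- vapply(seq_len(n), function(i) dd[i, nn_idx[i, n_neighbors]],
                  numeric(1))
  sigma <- pmax(sigma, .Machine$double.eps)

  from <- rep(seq_len(n), each = n_neighbors)
  to <- as.vector(t(nn_idx))
  w <- exp(-dd[cbind(from, to)]^2 / (sigma[from] * sigma[to]))
  A <- Matrix::sparseMatrix(i = from, j = to, x = w, dims = c(n, n),
                            dimnames = list(ids, ids))
  # symmetrize over the union of directed neighborhoods (weights already
  # symmetric in i,j, so union == elementwise max)
  At <- Matrix::t(A)
  A <- (A + At + abs(A - At)) / 2

  structure(list(ids = ids, pcs = pcs, adjacency = A, knn = nn_idx,
                 params = list(n_pcs = n_pcs, n_neighbors = n_neighbors,
                               graph_pcs = graph_pcs, method = method)),
            class = "tcr_graph")
}

#' Leiden clustering with a resolution search
#'
#' Runs Leiden community detection (modularity objective) on the weighted
#' neighbor graph at resolutions `start, start + step, ..., max_res` and
#' returns the partition at the highest resolution at which no cluster falls
#' below `min_cluster_size` members -- the operational definition of "not
#' over-clustered". Cluster labels are contiguous integers from 0, ordered by
#' decreasing cluster size.
#'
#' @param graph A `tcr_graph`.
#' @param start,step,max_res Resolution grid (defaults 0.5, 0.01, 2.0).
#' @param min_cluster_size Smallest admissible cluster (default 5).
#' @param seed Integer seed controlling the Leiden refinement RNG.
#' @return List with `assignment` (named integer vector of 0-based labels),
#'   `resolution` (the selected resolution), `search` (data.frame of the
#'   resolution path with cluster counts and minimum sizes), and `warning`
#'   (TRUE when no resolution satisfied the size requirement and the start-resolution
#'   partition was returned).
#' @export
cluster_resolution_search <- function(graph, start = 0.5, step = 0.01,
                                      max_res = 2.0, min_cluster_size = 5,
                                      seed = 1) {
  stopifnot(inherits(graph, "tcr_graph"))
  g <- igraph::graph_from_adjacency_matrix(graph$adjacency, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  resolutions <- seq(start, max_res, by = step)
  partitions <- vector("list", length(resolutions))
  n_clusters <- integer(length(resolutions))
  min_sizes <- integer(length(resolutions))
  for (i in seq_along(resolutions)) {
    memb <- with_local_seed(seed, {
      igraph::membership(igraph::cluster_leiden(
        g, objective_function = "modularity",
        resolution = resolutions[i], n_iterations = 3))
    })
    partitions[[i]] <- as.integer(memb)
    sizes <- tabulate(memb)
    n_clusters[i] <- length(sizes)
    min_sizes[i] <- min(sizes)
  }
  ok <- min_sizes >= min_cluster_size
  warn <- !any(ok)
  pick <- if (warn) 1L else max(which(ok))
  if (warn) {
    warning("no resolution satisfied the minimum cluster size; ",
            "returning the start-resolution partition", call. = FALSE)
  }
  memb <- partitions[[pick]]
  # relabel 0-based by decreasing size (ties broken by first occurrence)
  sizes <- table(memb)
  new_lab <- setNames(seq_along(sizes) - 1L,
                      names(sort(sizes, decreasing = TRUE)))
  assignment <- setNames(as.integer(new_lab[as.character(memb)]), graph$ids)
  list(assignment = assignment,
       resolution = resolutions[pick],
       search = data.frame(resolution = resolutions, n_clusters = n_clusters,
                           min_size = min_sizes, admissible = ok),
       warning = warn)
}

#' 2-D embedding of the clonotype graph
#'
#' UMAP embedding of the PC coordinates underlying the neighbor graph,
#' deterministic given `seed`. For fewer than 5 clonotypes (where a UMAP
#' neighborhood is undefined) classical MDS of the PC distances is used
#' instead, which is exact for such degenerate inputs.
#'
#' @param graph A `tcr_graph`.
#' @param seed Integer seed.
#' @return Numeric matrix (clonotypes x 2) with id rownames.
#' @export
embed_graph_2d <- function(graph, seed = 1) {
  stopifnot(inherits(graph, "tcr_graph"))
  emb_in <- graph$pcs[, seq_len(graph$params$graph_pcs), drop = FALSE]
  n <- nrow(emb_in)
  if (n < 5) {
    xy <- stats::cmdscale(stats::dist(emb_in), k = min(2, n - 1))
    while (ncol(xy) < 2) xy <- cbind(xy, seq_len(n) * 1e-6)
  } else {
    k <- min(graph$params$n_neighbors, n - 1)
    xy <- with_local_seed(seed, {
      uwot::umap(emb_in, n_neighbors = k, n_threads = 1, n_sgd_threads = 0)
    })
  }
  dimnames(xy) <- list(graph$ids, c("UMAP1", "UMAP2"))
  xy
}
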