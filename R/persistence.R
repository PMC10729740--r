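# Longitudinal clonotype tracking: repertoire percentages, contraction
# strength, feature correlation, TRAV-usage regression, reference-based
# contraction prediction and survival splits.

#' Per-clonotype repertoire percentages per patient and timepoint
#'
#' `pct = 100 * n_clonotype_cells / n_total_cells` within each
#' (patient, timepoint) sample. Totals default to the number of cells
#' observed in the cell table (in which case percentages sum to 100 within
#' every sample); pass `totals` to use external denominators such as total
#' high-quality CD8 counts per blood draw. A clonotype absent from one of its
#' patient's sampled timepoints gets 0 there.
#'
#' @param cells Data.frame with columns `clonotype_id`, `patient_id`,
#'   `timepoint`.
#' @param totals Optional data.frame with columns `patient_id`, `timepoint`,
#'   `total_cells`.
#' @return Long data.frame with columns `clonotype_id`, `patient_id`,
#'   `timepoint`, `n_cells`, `total_cells`, `pct`.
#' @export
clonotype_frequencies <- function(cells, totals = NULL) {
  need <- c("clonotype_id", "patient_id", "timepoint")
  if (!all(need %in% names(cells))) {
    stop("cells must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  counts <- aggregate(list(n_cells = rep(1L, nrow(cells))),
                      cells[, need], FUN = sum)
  if (is.null(totals)) {
    totals <- aggregate(list(total_cells = rep(1L, nrow(cells))),
                        cells[, c("patient_id", "timepoint")], FUN = sum)
  }
  totals <- totals[totals$total_cells > 0, , drop = FALSE]
  # expand each clonotype over all sampled timepoints of its own patient
  ct_pat <- unique(cells[, c("clonotype_id", "patient_id")])
  grid <- merge(ct_pat, totals[, c("patient_id", "timepoint", "total_cells")],
                by = "patient_id")
  out <- merge(grid, counts, by = need, all.x = TRUE)
  out$n_cells[is.na(out$n_cells)] <- 0L
  out$pct <- 100 * out$n_cells / out$total_cells
  out[order(out$clonotype_id, out$timepoint),
      c("clonotype_id", "patient_id", "timepoint", "n_cells", "total_cells",
        "pct")]
}

#' Per-cluster contraction strength between acute and convalescent draws
#'
#' For each TCR cluster, pools its clonotypes' repertoire percentages over
#' the acute timepoints (T1/T2) and the convalescent timepoint (T3) and
#' computes `C = log10(mean_conv + 1) - log10(mean_acute + 1)` (log10 units;
#' negative values mean contraction), together with a Welch two-sided t test
#' between the acute and convalescent percentage vectors.
#'
#' @param freq Output of [clonotype_frequencies()].
#' @param clusters Named cluster assignment, clonotype id -> label.
#' @param acute,convalescent Timepoint labels pooled on each side
#'   (defaults `c("T1", "T2")` and `"T3"`).
#' @return Data.frame with one row per cluster: `cluster`, `n_clonotypes`,
#'   `mean_acute_pct`, `mean_conv_pct`, `contraction_strength`, `t`, `p`.
#' @export
contraction_strength <- function(freq, clusters, acute = c("T1", "T2"),
                                 convalescent = "T3") {
  labs <- sort(unique(clusters))
  out <- NULL
  for (l in labs) {
    ids <- names(clusters)[clusters == l]
    f <- freq[freq$clonotype_id %in% ids, , drop = FALSE]
    a <- f$pct[f$timepoint %in% acute]
    v <- f$pct[f$timepoint %in% convalescent]
    if (length(a) == 0 || length(v) == 0) {
      stop(sprintf("cluster %s has no %s observations", l,
                   if (length(a) == 0) "acute" else "convalescent"),
           call. = FALSE)
    }
    C <- log10(mean(v) + 1) - log10(mean(a) + 1)
    tt <- if (length(a) > 1 && length(v) > 1 &&
              (stats::sd(a) > 0 || stats::sd(v) > 0)) {
      stats::t.test(v, a, var.equal = FALSE)
    } else NULL
    out <- rbind(out, data.frame(
      cluster = l, n_clonotypes = length(ids),
      mean_acute_pct = mean(a), mean_conv_pct = mean(v),
      contraction_strength = C,
      t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
      p = if (is.null(tt)) NA_real_ else tt$p.value))
  }
  out
}

#' Correlate per-cluster contraction with per-cluster feature means
#'
#' Pearson correlation (two-sided p) of contraction strength against each
#' feature column; constant features are dropped with a note. Feature means
#' are expected to be computed on acute-timepoint cells (see
#' [cluster_feature_means()]).
#'
#' @param contraction Data.frame from [contraction_strength()] (>= 3 rows).
#' @param features Cluster x feature numeric matrix, rows aligned with
#'   `contraction$cluster`.
#' @return Data.frame with columns `feature`, `r`, `p`.
#' @export
correlate_contraction_features <- function(contraction, features) {
  features <- as.matrix(features)
  if (nrow(contraction) < 3) stop("need >= 3 clusters", call. = FALSE)
  if (nrow(features) != nrow(contraction)) {
    stop("features must have one row per cluster", call. = FALSE)
  }
  C <- contraction$contraction_strength
  out <- NULL
  dropped <- character(0)
  for (j in seq_len(ncol(features))) {
    f <- features[, j]
    nm <- colnames(features)[j]
    if (is.null(nm)) nm <- paste0("feature", j)
    if (stats::sd(f) == 0 || stats::sd(C) == 0) {
      dropped <- c(dropped, nm)
      next
    }
    ct <- stats::cor.test(C, f)
    out <- rbind(out, data.frame(feature = nm, r = unname(ct$estimate),
                                 p = ct$p.value))
  }
  if (length(dropped) > 0) {
    message("dropped constant feature(s): ", paste(dropped, collapse = ", "))
  }
  attr(out, "dropped") <- dropped
  out
}

#' Mean feature score per TCR cluster over acute-timepoint cells
#'
#' @param cells Cell table with `clonotype_id` and `timepoint`.
#' @param scores Cell x feature matrix (rownames = cell ids) or a named
#'   vector.
#' @param clusters Named clonotype -> cluster assignment.
#' @param timepoints Timepoints retained (default acute: T1, T2).
#' @return Cluster x feature matrix of means, rows sorted by cluster label.
#' @export
cluster_feature_means <- function(cells, scores, clusters,
                                  timepoints = c("T1", "T2")) {
  if (is.null(dim(scores))) scores <- cbind(score = scores)
  keep <- cells$timepoint %in% timepoints
  cl <- clusters[cells$clonotype_id[keep]]
  sc <- scores[cells$cell_id[keep], , drop = FALSE]
  labs <- sort(unique(clusters))
  out <- matrix(NA_real_, length(labs), ncol(scores),
                dimnames = list(labs, colnames(scores)))
  for (l in labs) {
    idx <- which(cl == l)
    if (length(idx) > 0) out[as.character(l), ] <-
        colMeans(sc[idx, , drop = FALSE])
  }
  out
}

#' TRAV-usage linear model of cluster contraction
#'
#' Screens every TRAV (V-alpha) gene by the Pearson correlation of its
#' per-cluster usage percentage with contraction strength, keeps genes with
#' p < `alpha`, and fits an ordinary least squares model of contraction on
#' the kept usage columns plus an intercept at the cluster level. Collinear
#' designs are reduced by dropping columns in screen p-value order until full
#' rank.
#'
#' @param clonotypes Clonotype table with `clonotype_id` and `va`.
#' @param clusters Named clonotype -> cluster assignment.
#' @param contraction Data.frame from [contraction_strength()].
#' @param alpha Screen significance level (default 0.05).
#' @return List with `genes`, `coefficients` (incl. `(Intercept)`),
#'   `p_values`, `predicted` (per cluster), `usage` (cluster x gene %),
#'   `dropped` (genes removed for rank), and the `lm` fit.
#' @export
fit_trav_model <- function(clonotypes, clusters, contraction, alpha = 0.05) {
  labs <- as.character(contraction$cluster)
  if (length(labs) < 2) stop("need >= 2 clusters", call. = FALSE)
  cl <- clusters[clonotypes$clonotype_id]
  genes <- sort(unique(clonotypes$va))
  usage <- matrix(0, length(labs), length(genes),
                  dimnames = list(labs, genes))
  for (l in labs) {
    va <- clonotypes$va[cl == l]
    if (length(va) > 0) usage[l, ] <- 100 * table(factor(va, genes)) / length(va)
  }
  C <- contraction$contraction_strength
  if (stats::sd(C) == 0) {
    stop("contraction strength is constant across clusters; ",
         "no TRAV gene can pass the correlation screen", call. = FALSE)
  }
  screen_p <- vapply(genes, function(g) {
    u <- usage[, g]
    if (stats::sd(u) == 0) return(NA_real_)
    stats::cor.test(C, u)$p.value
  }, numeric(1))
  kept <- genes[!is.na(screen_p) & screen_p < alpha]
  if (length(kept) == 0) {
    stop(sprintf("no TRAV gene passes the screen at alpha = %g", alpha),
         call. = FALSE)
  }
  kept <- kept[order(screen_p[kept])]
  # reduce to a full-rank design, dropping worst-screened genes first
  dropped <- character(0)
  repeat {
    Xd <- cbind(1, usage[, kept, drop = FALSE])
    if (qr(Xd)$rank == ncol(Xd) || length(kept) == 1) break
    dropped <- c(dropped, kept[length(kept)])
    kept <- kept[-length(kept)]
  }
  df <- data.frame(C = C, usage[, kept, drop = FALSE], check.names = FALSE)
  fit <- stats::lm(C ~ ., data = df)
  sm <- suppressWarnings(summary(fit))  # perfect fits are legitimate here
  list(genes = kept,
       coefficients = stats::coef(fit),
       p_values = sm$coefficients[, "Pr(>|t|)"],
       predicted = setNames(unname(stats::fitted(fit)), labs),
       usage = usage,
       dropped = dropped,
       fit = fit)
}

#' Reference-based contraction prediction
#'
#' Predicts contraction of each study clonotype from its sequence proximity
#' to a reference set of known contracting clonotypes. The neighbor threshold
#' is the mean of all within-study pairwise alpha-chain distances; a study
#' clonotype's raw score is the number of reference clonotypes closer than
#' that threshold (duplicated reference entries each count), and predictions
#' are the min-max scaled scores in `[0, 1]` (all 0 when constant).
#'
#' @param study Study clonotype table (`clonotype_id`, `cdr3a`, `va`, `ja`).
#' @param reference Reference clonotype table, same alpha-chain columns.
#' @param chains Chains used for distances (default `"alpha"`, matching the
#'   stronger alpha-chain association with contraction).
#' @param ... Passed to [compute_tcrdist()].
#' @return Data.frame with `clonotype_id`, `n_neighbors`,
#'   `predicted_contraction`, plus attribute `threshold`.
#' @export
predict_contraction_from_reference <- function(study, reference,
                                               chains = "alpha", ...) {
  if (nrow(study) < 2) {
    stop("need >= 2 study clonotypes to define the distance threshold",
         call. = FALSE)
  }
  if (nrow(reference) < 1) stop("reference set is empty", call. = FALSE)
  D <- compute_tcrdist(study, chains = chains, ...)
  dbar <- mean(D[upper.tri(D)])
  Dx <- compute_tcrdist(study, reference = reference, chains = chains, ...)
  n_nb <- rowSums(Dx < dbar)
  rng <- range(n_nb)
  pred <- if (rng[1] == rng[2]) rep(0, length(n_nb)) else
    (n_nb - rng[1]) / diff(rng)
  out <- data.frame(clonotype_id = study$clonotype_id,
                    n_neighbors = as.integer(n_nb),
                    predicted_contraction = pred, stringsAsFactors = FALSE)
  attr(out, "threshold") <- dbar
  out
}

#' Kaplan-Meier split by a patient score threshold with a chi-square test
#'
#' Splits patients into high/low arms at `threshold`, fits product-limit
#' survival curves per arm, and tests the 2x2 contingency of survival status
#' against arm with a 1-df chi-square statistic (no continuity correction).
#'
#' @param scores Named numeric vector of per-patient scores.
#' @param threshold Split value (high: score > threshold).
#' @param surv Data.frame with `patient_id`, `time`, `event` (1 = death).
#' @return List with `fit` (a `survfit` object), `table` (2x2 contingency),
#'   `chisq`, `df`, `p`, `groups`.
#' @export
survival_split_test <- function(scores, threshold, surv) {
  surv <- surv[surv$patient_id %in% names(scores), , drop = FALSE]
  grp <- ifelse(scores[surv$patient_id] > threshold, "high", "low")
  if (min(table(grp)) < 2 || length(unique(grp)) < 2) {
    stop("need >= 2 patients in each arm", call. = FALSE)
  }
  fit <- survival::survfit(survival::Surv(surv$time, surv$event) ~ grp)
  survived <- factor(surv$event == 0, levels = c(TRUE, FALSE),
                     labels = c("survived", "died"))
  tab <- table(group = grp, status = survived)
  expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  # a zero margin (e.g. no deaths at all) carries no information: stat 0
  chisq <- if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) 0 else
    sum((tab - expd)^2 / expd)
  list(fit = fit, table = tab, chisq = chisq, df = 1,
       p = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
       groups = setNames(grp, surv$patient_id))
}
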