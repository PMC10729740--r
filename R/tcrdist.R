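# Paired-chain TCRdist-style clonotype distances.
#
# The distance between two clonotypes is a sum over CDR loops of per-position
# substitution penalties derived from BLOSUM62:
#   penalty(a, b) = min(4, 4 - BLOSUM62(a, b)),  penalty(a, a) = 0.
# Germline-encoded loops (CDR1, CDR2, CDR2.5 of each V gene) carry weight 1;
# the CDR3 of each chain, trimmed of 3 N-terminal and 2 C-terminal residues,
# carries weight 3. Unequal-length loops are aligned by inserting a central
# gap block in the shorter sequence; each gapped position costs
# gap_penalty * weight. The result is a symmetric semimetric (triangle
# inequality is not guaranteed and not asserted anywhere).

.blosum_env <- new.env(parent = emptyenv())

# 20x20 per-position penalty matrix: min(4, 4 - BLOSUM62), zero diagonal.
blosum62_penalty <- function() {
  if (!is.null(.blosum_env$penalty)) return(.blosum_env$penalty)
  b62 <- NULL
  # Biostrings ships the canonical BLOSUM62 substitution matrix.
  utils::data("BLOSUM62", package = "Biostrings", envir = environment())
  b62 <- get("BLOSUM62", envir = environment())
  b <- b62[AA_ALPHABET, AA_ALPHABET]
  pen <- pmin(4 - b, 4)  # attribute-preserving order: result stays a matrix
  diag(pen) <- 0
  dimnames(pen) <- list(AA_ALPHABET, AA_ALPHABET)
  .blosum_env$penalty <- pen
  pen
}

#' Bundled germline CDR loop table for simulated gene names
#'
#' Supplies CDR1 (5 aa), CDR2 (6 aa) and CDR2.5 (4 aa) loop sequences for
#' simulated V gene names of the form `TRAV<k>` / `TRBV<k>`. Loops are drawn
#' deterministically from the gene name so the table is reproducible without
#' shipping data files. Real IMGT-style gene names (e.g. `TRAV12-1`) are not
#' covered; distance computation falls back to CDR3-only mode for them.
#'
#' @param genes Character vector of V gene names to tabulate.
#' @return A data.frame with columns `gene`, `cdr1`, `cdr2`, `cdr2_5`.
#' @export
simulated_germline_table <- function(genes) {
  genes <- unique(as.character(genes))
  covered <- grepl("^TR[AB]V[0-9]+$", genes)
  genes <- genes[covered]
  rows <- lapply(genes, function(g) {
    seed <- sum(utf8ToInt(g) * seq_along(utf8ToInt(g))) %% .Machine$integer.max
    with_local_seed(seed, {
      data.frame(
        gene = g,
        cdr1 = paste(sample(AA_ALPHABET, 5, replace = TRUE), collapse = ""),
        cdr2 = paste(sample(AA_ALPHABET, 6, replace = TRUE), collapse = ""),
        cdr2_5 = paste(sample(AA_ALPHABET, 4, replace = TRUE), collapse = ""),
        stringsAsFactors = FALSE
      )
    })
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

# Encode an amino-acid string as integer indices into AA_ALPHABET, with
# position-level error reporting.
encode_aa <- function(s, what, id) {
  chars <- strsplit(s, "")[[1]]
  idx <- match(chars, AA_ALPHABET)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    stop(sprintf("unknown amino acid '%s' at position %d of %s for clonotype %s",
                 chars[bad], bad, what, id), call. = FALSE)
  }
  idx
}

# Central-gap alignment index pairs for two loop lengths. The shorter loop
# keeps its N-terminal ceiling(n/2) residues aligned at the start and the rest
# aligned at the end; the length difference is bridged by a gap block.
central_gap_align <- function(n1, n2) {
  if (n1 > n2) {
    al <- central_gap_align(n2, n1)
    return(list(i = al$j, j = al$i, gaps = al$gaps))
  }
  if (n1 == 0L) return(list(i = integer(0), j = integer(0), gaps = n2))
  lead <- ceiling(n1 / 2)
  tail_len <- n1 - lead
  j <- c(seq_len(lead), if (tail_len > 0) (n2 - tail_len + 1):n2 else integer(0))
  list(i = seq_len(n1), j = j, gaps = n2 - n1)
}

# Weighted penalty between two encoded loops under the central-gap alignment.
loop_distance <- function(e1, e2, pen, weight, gap_penalty) {
  n1 <- length(e1); n2 <- length(e2)
  if (n1 == n2) {
    sub <- if (n1 > 0) sum(pen[cbind(e1, e2)]) else 0
    return(weight * sub)
  }
  al <- central_gap_align(n1, n2)
  sub <- if (length(al$i) > 0) sum(pen[cbind(e1[al$i], e2[al$j])]) else 0
  weight * (sub + al$gaps * gap_penalty)
}

# Precompute pairwise germline-loop distances for a set of V genes
# (sum over CDR1 + CDR2 + CDR2.5, weight 1 per loop).
germline_gene_dist <- function(genes, germline, pen, gap_penalty) {
  ug <- unique(genes)
  missing <- setdiff(ug, germline$gene)
  if (length(missing) > 0) {
    stop(sprintf("unknown V gene(s) in germline mode: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  rows <- germline[match(ug, germline$gene), ]
  loops <- lapply(seq_along(ug), function(i) {
    list(encode_aa(rows$cdr1[i], "cdr1", ug[i]),
         encode_aa(rows$cdr2[i], "cdr2", ug[i]),
         encode_aa(rows$cdr2_5[i], "cdr2.5", ug[i]))
  })
  m <- matrix(0, length(ug), length(ug), dimnames = list(ug, ug))
  if (length(ug) > 1) {
    for (i in 1:(length(ug) - 1)) {
      for (j in (i + 1):length(ug)) {
        d <- sum(vapply(1:3, function(l) {
          loop_distance(loops[[i]][[l]], loops[[j]][[l]], pen, 1, gap_penalty)
        }, numeric(1)))
        m[i, j] <- m[j, i] <- d
      }
    }
  }
  m
}

check_clonotype_table <- function(x, chains) {
  need <- c("clonotype_id",
            if ("alpha" %in% chains) c("cdr3a", "va", "ja"),
            if ("beta" %in% chains) c("cdr3b", "vb", "jb"))
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    stop("clonotype table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (col in intersect(c("cdr3a", "cdr3b"), need)) {
    if (any(!nzchar(x[[col]]))) {
      stop(sprintf("empty %s sequence for clonotype %s", col,
                   x$clonotype_id[which(!nzchar(x[[col]]))[1]]), call. = FALSE)
    }
  }
  invisible(x)
}

#' Paired-chain TCRdist-style distance matrix
#'
#' Computes the clonotype-by-clonotype distance used throughout the package:
#' BLOSUM62-derived per-position substitution penalties, capped at 4, summed
#' over the germline CDR1/CDR2/CDR2.5 loops of each V gene (weight 1) and over
#' the trimmed CDR3 of each chain (weight `cdr3_weight`). Unequal-length CDR3s
#' are aligned with a central gap block costing `gap_penalty * weight` per
#' gapped position.
#'
#' @param clonotypes Data.frame of clonotype records with columns
#'   `clonotype_id`, `cdr3a`, `cdr3b`, `va`, `ja`, `vb`, `jb` (only the
#'   columns for the requested `chains` are required).
#' @param reference Optional second clonotype table; if supplied, the result is
#'   the rectangular cross-distance matrix (rows = `clonotypes`,
#'   columns = `reference`) instead of the symmetric within-set matrix.
#' @param chains Chains to include: `"alpha"`, `"beta"` or both (default).
#' @param mode `"germline"` scores CDR1/CDR2/CDR2.5 from a germline table and
#'   errors on unknown V genes; `"cdr3"` scores trimmed CDR3 loops only;
#'   `"auto"` (default) uses germline when every V gene is covered by the
#'   table and otherwise falls back to CDR3-only with a warning.
#' @param germline Germline loop table (see [simulated_germline_table()]);
#'   defaults to the bundled simulated-gene table.
#' @param cdr3_weight Weight of the CDR3 loop terms (default 3).
#' @param gap_penalty Penalty per gapped position before weighting (default 4,
#'   the substitution-penalty cap).
#' @param trim_n,trim_c Number of N-/C-terminal CDR3 residues trimmed before
#'   scoring (defaults 3 and 2).
#' @return A numeric distance matrix with clonotype ids as dimnames. Symmetric
#'   with zero diagonal when `reference` is `NULL`.
#' @export
compute_tcrdist <- function(clonotypes, reference = NULL,
                            chains = c("alpha", "beta"),
                            mode = c("auto", "germline", "cdr3"),
                            germline = NULL,
                            cdr3_weight = 3, gap_penalty = 4,
                            trim_n = 3, trim_c = 2) {
  mode <- match.arg(mode)
  chains <- match.arg(chains, c("alpha", "beta"), several.ok = TRUE)
  check_clonotype_table(clonotypes, chains)
  if (!is.null(reference)) check_clonotype_table(reference, chains)
  all_rec <- if (is.null(reference)) clonotypes else rbind(
    clonotypes[, intersect(names(clonotypes), names(reference)), drop = FALSE],
    reference[, intersect(names(clonotypes), names(reference)), drop = FALSE])

  vcols <- c(alpha = "va", beta = "vb")[chains]
  if (is.null(germline)) {
    germline <- simulated_germline_table(unlist(all_rec[vcols], use.names = FALSE))
  }
  if (mode == "auto") {
    covered <- all(unlist(all_rec[vcols], use.names = FALSE) %in% germline$gene)
    if (!covered) {
      warning("V gene(s) not covered by the germline table; ",
              "falling back to CDR3-only distances", call. = FALSE)
    }
    mode <- if (covered) "germline" else "cdr3"
  }

  pen <- blosum62_penalty()
  trim_cdr3 <- function(s) {
    n <- nchar(s)
    ifelse(n > trim_n + trim_c, substr(s, trim_n + 1, n - trim_c), "")
  }
  encode_set <- function(tab) {
    out <- list()
    for (ch in chains) {
      col <- c(alpha = "cdr3a", beta = "cdr3b")[[ch]]
      trimmed <- trim_cdr3(tab[[col]])
      # validate the full, untrimmed sequence so position errors are exact
      invisible(mapply(encode_aa, tab[[col]], col, tab$clonotype_id))
      out[[ch]] <- lapply(seq_len(nrow(tab)), function(i) {
        if (nzchar(trimmed[i])) match(strsplit(trimmed[i], "")[[1]], AA_ALPHABET)
        else integer(0)
      })
    }
    out
  }

  gdist <- list()
  if (mode == "germline") {
    for (ch in chains) {
      gdist[[ch]] <- germline_gene_dist(all_rec[[vcols[[ch]]]], germline, pen,
                                        gap_penalty)
    }
  }

  x <- clonotypes
  y <- if (is.null(reference)) clonotypes else reference
  ex <- encode_set(x)
  ey <- if (is.null(reference)) ex else encode_set(y)
  nx <- nrow(x); ny <- nrow(y)
  D <- matrix(0, nx, ny, dimnames = list(x$clonotype_id, y$clonotype_id))

  pair_dist <- function(i, j) {
    d <- 0
    for (ch in chains) {
      d <- d + loop_distance(ex[[ch]][[i]], ey[[ch]][[j]], pen, cdr3_weight,
                             gap_penalty)
      if (mode == "germline") {
        vc <- vcols[[ch]]
        d <- d + gdist[[ch]][x[[vc]][i], y[[vc]][j]]
      }
    }
    d
  }

  if (is.null(reference)) {
    if (nx > 1) {
      for (i in 1:(nx - 1)) {
        for (j in (i + 1):nx) {
          D[i, j] <- D[j, i] <- pair_dist(i, j)
        }
      }
    }
  } else {
    for (i in seq_len(nx)) {
      for (j in seq_len(ny)) D[i, j] <- pair_dist(i, j)
    }
  }
  attr(D, "chains") <- chains
  attr(D, "mode") <- mode
  D
}
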