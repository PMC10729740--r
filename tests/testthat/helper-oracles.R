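# Independent oracles shared by unit and acceptance tests.

# Independent position-by-position scorer used as the oracle. Reimplements
# the scoring contract directly from its definition with plain loops.
oracle_pair_distance <- function(rec1, rec2, germline) {
  b62 <- local({
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    get("BLOSUM62", envir = e)
  })
  pen <- function(a, b) if (a == b) 0 else min(4, 4 - b62[a, b])
  score_loop <- function(s1, s2, weight) {
    c1 <- strsplit(s1, "")[[1]]
    c2 <- strsplit(s2, "")[[1]]
    if (length(c1) > length(c2)) { tmp <- c1; c1 <- c2; c2 <- tmp }
    n1 <- length(c1); n2 <- length(c2)
    total <- (n2 - n1) * 4 * weight
    if (n1 == 0) return(total)
    lead <- ceiling(n1 / 2)
    for (i in seq_len(n1)) {
      j <- if (i <= lead) i else n2 - (n1 - i)
      total <- total + weight * pen(c1[i], c2[j])
    }
    total
  }
  trim <- function(s) {
    n <- nchar(s)
    if (n <= 5) "" else substr(s, 4, n - 2)
  }
  d <- score_loop(trim(rec1$cdr3a), trim(rec2$cdr3a), 3) +
    score_loop(trim(rec1$cdr3b), trim(rec2$cdr3b), 3)
  for (col in c("va", "vb")) {
    g1 <- germline[germline$gene == rec1[[col]], ]
    g2 <- germline[germline$gene == rec2[[col]], ]
    for (loop in c("cdr1", "cdr2", "cdr2_5")) {
      d <- d + score_loop(g1[[loop]], g2[[loop]], 1)
    }
  }
  d
}

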