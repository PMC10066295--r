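# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (and its C++ kernels) wherever they check one.

# Exhaustive transition-graph classification of a small threshold network:
# enumerate all 2^n states in {-1,+1}^n, follow the deterministic update
# map from `initial`, and report whether a fixed point is reached.
oracle_fixed_point <- function(initial, w, max_iters = 100) {
  step <- function(s) {
    z <- as.vector(w %*% s)
    out <- ifelse(z < 0, -1L, 1L)
    out[s == 0] <- 0L
    out
  }
  cur <- as.integer(initial)
  for (t in 0:(max_iters - 1)) {
    nxt <- step(cur)
    if (identical(nxt, cur)) {
      return(list(converged = TRUE, equilibrium = cur, steps = t))
    }
    cur <- nxt
  }
  list(converged = FALSE, equilibrium = NULL, steps = max_iters)
}

# Naive cubic-time affine Smith-Waterman: best[i][j] over alignments ending
# at (i, j), scanning all gap lengths explicitly.
oracle_sw_affine <- function(q, s, sub, gap_open, gap_extend) {
  m <- length(q); n <- length(s)
  H <- matrix(0, m + 1, n + 1)
  best <- 0
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      sc <- H[i, j] + sub[q[i], s[j]]
      for (g in seq_len(j - 1)) {           # gap in query of length g
        sc <- max(sc, H[i, j - g] + sub[q[i], s[j]] -
                        (gap_open + g * gap_extend))
      }
      for (g in seq_len(i - 1)) {           # gap in subject of length g
        sc <- max(sc, H[i - g, j] + sub[q[i], s[j]] -
                        (gap_open + g * gap_extend))
      }
      H[i + 1, j + 1] <- max(0, sc)
      best <- max(best, H[i + 1, j + 1])
    }
  }
  best
}

random_protein <- function(n) {
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V"), n, TRUE),
        collapse = "")
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
}

revcomp_str <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Brute-force clade check: is `subset` exactly the tip set of one node
# (or a single tip) of the rooted tree?
oracle_is_clade <- function(tree, subset) {
  subset <- sort(subset)
  if (length(subset) == 0) return(TRUE)
  if (length(subset) == 1) return(subset %in% tree$tip.label)
  n_tip <- length(tree$tip.label)
  for (node in (n_tip + 1):(n_tip + tree$Nnode)) {
    tips <- sort(ape::extract.clade(tree, node)$tip.label)
    if (identical(tips, subset)) return(TRUE)
  }
  FALSE
}

blosum62 <- function() {
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}
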