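# Independent oracles used across the suite. These deliberately share no
# code with the package: the motif oracle is a per-position window loop, the
# alignment oracle enumerates every global alignment, the NJ oracle builds
# additive matrices by path sums on random trees.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

rand_seq <- function(len, alphabet = AA20) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# exhaustive window matcher over a compiled MotifDefinition
oracle_scan <- function(seq, def, region) {
  sv <- strsplit(seq, "")[[1]]
  w <- length(def@positions)
  hits <- integer(0)
  if (length(sv) < w) return(hits)
  for (i in seq_len(length(sv) - w + 1L)) {
    if (i < region[1] || i + w - 1L > region[2]) next
    ok <- TRUE
    for (k in seq_len(w)) {
      allowed <- def@positions[[k]]
      if (length(allowed) && !(sv[i + k - 1L] %in% allowed)) {
        ok <- FALSE
        break
      }
    }
    if (ok) hits <- c(hits, i)
  }
  hits
}

# brute-force optimal global alignment score under affine gaps
# (gap of length L costs open + ext * L, end gaps included)
brute_align_score <- function(a, b, S, open, ext) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  na <- length(av); nb <- length(bv)
  best <- -Inf
  score_moves <- function(moves) {
    sc <- 0; i <- 0L; j <- 0L; prev <- 0L
    for (m in moves) {
      if (m == 1L) {
        i <- i + 1L; j <- j + 1L
        sc <- sc + S[av[i], bv[j]]
      } else if (m == 2L) {          # gap in a, consumes b
        j <- j + 1L
        sc <- sc - ext - if (prev != 2L) open else 0
      } else {                       # gap in b, consumes a
        i <- i + 1L
        sc <- sc - ext - if (prev != 3L) open else 0
      }
      prev <- m
    }
    sc
  }
  rec <- function(i, j, moves) {
    if (i > na && j > nb) {
      best <<- max(best, score_moves(moves))
      return(invisible(NULL))
    }
    if (i <= na && j <= nb) rec(i + 1L, j + 1L, c(moves, 1L))
    if (j <= nb) rec(i, j + 1L, c(moves, 2L))
    if (i <= na) rec(i + 1L, j, c(moves, 3L))
  }
  rec(1L, 1L, integer(0))
  best
}

# random unrooted binary tree with positive branch lengths and its
# path-sum (additive) distance matrix
additive_case <- function(n) {
  tr <- ape::unroot(ape::rtree(n, br = NULL))
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.2, 3)
  list(tree = tr, D = ape::cophenetic.phylo(tr))
}

# a valid 22-column domtblout data line with the given fields
domtbl_line <- function(target, acc, ievalue, env_start, env_end,
                        full_e = 1e-20) {
  paste(target, "-", 900, "profile", acc, 240, full_e, 100, 1, 1, 2,
        ievalue / 10, ievalue, 50, 1, 1, 240, env_start - 1, env_end - 1,
        env_start, env_end, 0.9, "fixture row")
}
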