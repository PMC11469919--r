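# Alignment machinery: affine-gap global pairwise alignment (and its
# profile-profile generalization) over a packaged BLOSUM62 matrix, a
# deterministic progressive MSA with a 3-mer guide tree, and
# Poisson-corrected distances.

.pkg_cache <- new.env(parent = emptyenv())

#' Packaged BLOSUM62 substitution matrix
#'
#' The standard BLOSUM62 matrix shipped with Biostrings, restricted to the
#' 20 standard residues plus `X` (half-bit scale).
#'
#' @return A 21 x 21 integer matrix.
#' @export
blosum62 <- function() {
  if (is.null(.pkg_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pkg_cache$blosum62 <- e$BLOSUM62[.AA21, .AA21]
  }
  .pkg_cache$blosum62
}

#' Global pairwise alignment with affine gaps
#'
#' Optimal global (Needleman-Wunsch) alignment under affine gap costs: a gap
#' of length L costs `gap_open + gap_extend * L`, end gaps included.
#' Traceback ties are broken deterministically, preferring match/mismatch
#' over a gap in `a` over a gap in `b`.
#'
#' @param a,b Non-empty sequences (character scalars or `AAString`s).
#' @param submat Substitution matrix (default [blosum62()]).
#' @param gap_open,gap_extend Gap opening / extension penalties (defaults
#'   10 and 0.5, half-bit scale).
#' @return `list(alignment = AAStringSet of the two gapped rows, score)`.
#' @examples
#' pairwiseAlign("MKTDIDD", "MKTDID")$score
#' @export
pairwiseAlign <- function(a, b, submat = blosum62(), gap_open = 10,
                          gap_extend = 0.5) {
  an <- if (!is.null(names(a))) names(a)[1] else "a"
  bn <- if (!is.null(names(b))) names(b)[1] else "b"
  a <- .single_seq(unname(a)); b <- .single_seq(unname(b))
  if (!nchar(a) || !nchar(b)) stop("sequences must be non-empty")
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  if (!all(av %in% rownames(submat)) || !all(bv %in% rownames(submat)))
    stop("sequence contains residues absent from the substitution matrix")
  C <- submat[av, bv, drop = FALSE]
  r <- .affine_dp(C, gap_open, gap_extend)
  ga <- gb <- character(length(r$path))
  i <- j <- 0L
  for (k in seq_along(r$path)) {
    mv <- r$path[k]
    if (mv == 1L) { i <- i + 1L; j <- j + 1L; ga[k] <- av[i]; gb[k] <- bv[j] }
    else if (mv == 2L) { j <- j + 1L; ga[k] <- "-"; gb[k] <- bv[j] }
    else { i <- i + 1L; ga[k] <- av[i]; gb[k] <- "-" }
  }
  aln <- Biostrings::AAStringSet(stats::setNames(
    c(paste(ga, collapse = ""), paste(gb, collapse = "")), c(an, bn)))
  list(alignment = aln, score = r$score)
}

# frequency profile of a group alignment (character vector of gapped rows)
.profile_of <- function(rows) {
  m <- do.call(rbind, strsplit(rows, ""))
  L <- ncol(m)
  P <- matrix(0, nrow = length(.AA21), ncol = L,
              dimnames = list(.AA21, NULL))
  for (aa in .AA21) P[aa, ] <- colSums(m == aa)
  P / length(rows)
}

# align two group alignments profile-to-profile; returns merged gapped rows
.merge_alignments <- function(rowsA, rowsB, submat, gap_open, gap_extend) {
  PA <- .profile_of(rowsA)
  PB <- .profile_of(rowsB)
  S <- submat[.AA21, .AA21]
  C <- t(PA) %*% S %*% PB
  r <- .affine_dp(C, gap_open, gap_extend)
  mA <- do.call(rbind, strsplit(rowsA, ""))
  mB <- do.call(rbind, strsplit(rowsB, ""))
  outA <- matrix("-", nrow = nrow(mA), ncol = length(r$path))
  outB <- matrix("-", nrow = nrow(mB), ncol = length(r$path))
  i <- j <- 0L
  for (k in seq_along(r$path)) {
    mv <- r$path[k]
    if (mv != 2L) { i <- i + 1L; outA[, k] <- mA[, i] }
    if (mv != 3L) { j <- j + 1L; outB[, k] <- mB[, j] }
  }
  c(stats::setNames(apply(outA, 1L, paste, collapse = ""), names(rowsA)),
    stats::setNames(apply(outB, 1L, paste, collapse = ""), names(rowsB)))
}

#' 3-mer composition distance
#'
#' Cosine distance between overlapping 3-mer count vectors; the guide
#' distance of the progressive MSA and the default relatedness measure of
#' [closerToGroup()].
#'
#' @param x Sequences (named character vector or [Biostrings::AAStringSet]).
#' @param k Word size (default 3).
#' @return Symmetric distance matrix with zero diagonal.
#' @export
kmerDistance <- function(x, k = 3L) {
  x <- .as_aastringset(x)
  seqs <- as.character(x)
  counts <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(table(character(0)))
    table(substring(s, 1:(n - k + 1L), k:n))
  })
  words <- sort(unique(unlist(lapply(counts, names))))
  M <- vapply(counts, function(ct) {
    v <- stats::setNames(numeric(length(words)), words)
    v[names(ct)] <- as.numeric(ct)
    v
  }, numeric(length(words)))
  if (!is.matrix(M)) M <- matrix(M, ncol = length(seqs))
  nrm <- sqrt(colSums(M^2))
  D <- matrix(1, length(seqs), length(seqs),
              dimnames = list(names(x), names(x)))
  ok <- nrm > 0
  cs <- crossprod(M[, ok, drop = FALSE]) / outer(nrm[ok], nrm[ok])
  D[ok, ok] <- 1 - pmin(pmax(cs, 0), 1)
  diag(D) <- 0
  D
}

#' Progressive multiple sequence alignment
#'
#' Deterministic progressive MSA: a guide tree is built by neighbor joining
#' on 3-mer cosine distances, then group profiles are merged in guide-tree
#' order by profile-profile global alignment under the same affine scoring
#' as [pairwiseAlign()]. A stand-in for external aligners at desk scale, not
#' an emulation of them.
#'
#' @param x At least two uniquely named sequences.
#' @param submat,gap_open,gap_extend Scoring, as in [pairwiseAlign()].
#' @return An [Biostrings::AAStringSet] of equal-width gapped rows in input
#'   order; removing gaps restores each input exactly.
#' @export
progressiveMsa <- function(x, submat = blosum62(), gap_open = 10,
                           gap_extend = 0.5) {
  x <- .as_aastringset(x)
  if (length(x) < 2L) stop("need at least 2 sequences")
  ids <- names(x)
  if (is.null(ids) || anyDuplicated(ids))
    stop("sequences must carry unique ids")
  seqs <- stats::setNames(as.character(x), ids)
  if (length(x) == 2L) {
    rows <- .merge_alignments(seqs[1], seqs[2], submat, gap_open, gap_extend)
    return(Biostrings::AAStringSet(rows[ids]))
  }
  guide <- neighborJoining(kmerDistance(x))
  rows_of <- function(node) {
    kids <- guide$edge[guide$edge[, 1] == node, 2]
    if (!length(kids)) return(seqs[guide$tip.label[node]])
    acc <- rows_of(kids[1])
    for (kid in kids[-1])
      acc <- .merge_alignments(acc, rows_of(kid), submat, gap_open,
                               gap_extend)
    acc
  }
  root <- length(guide$tip.label) + 1L
  rows <- rows_of(root)
  Biostrings::AAStringSet(rows[ids])
}

#' Poisson-corrected protein distance
#'
#' For each sequence pair, the fraction `p` of mismatching residues over
#' pairwise-complete columns (columns where either row is gapped are
#' dropped per pair) is corrected as `d = -ln(1 - p)`, capped at `cap`
#' (default 5) when `p >= 1 - exp(-cap)`.
#'
#' @param aln Equal-width gapped rows ([Biostrings::AAStringSet] or named
#'   character vector).
#' @param cap Maximum distance (default 5).
#' @return Symmetric distance matrix, zero diagonal.
#' @export
poissonDistance <- function(aln, cap = 5) {
  aln <- .as_aastringset(aln)
  if (length(unique(Biostrings::width(aln))) != 1L)
    stop("alignment rows must have equal width")
  m <- do.call(rbind, strsplit(as.character(aln), ""))
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(names(aln), names(aln)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- m[i, ] != "-" & m[j, ] != "-"
      if (!any(ok))
        stop(sprintf("no comparable columns between %s and %s",
                     names(aln)[i], names(aln)[j]))
      p <- sum(m[i, ok] != m[j, ok]) / sum(ok)
      d <- if (p >= 1 - exp(-cap)) cap else -log(1 - p)
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}
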