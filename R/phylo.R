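# Distance-based phylogenetics: neighbor joining with deterministic
# tie-breaks, column-bootstrap supports, bipartition queries, and the
# relatedness filter that removes SHC-like didomain proteins.

#' Neighbor-joining tree
#'
#' Standard NJ agglomeration (Q-matrix minimization) on a symmetric distance
#' matrix, exact on additive distances. Ties in the Q matrix are broken by
#' the lexicographically smallest pair of cluster labels (a cluster is
#' labeled by its smallest leaf); negative branch-length estimates are
#' clamped to 0. The result is unrooted with a basal trifurcation.
#'
#' @param D Symmetric distance matrix with unique row/column labels, zero
#'   diagonal, n >= 3.
#' @return An `ape::phylo` tree.
#' @examples
#' D <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' neighborJoining(D)
#' @export
neighborJoining <- function(D) {
  D <- as.matrix(D)
  labels <- rownames(D)
  n <- nrow(D)
  if (is.null(labels) || anyDuplicated(labels))
    stop("distance matrix must carry unique labels")
  if (n < 3L) stop("neighbor joining needs n >= 3")
  if (max(abs(D - t(D))) > 1e-12 || any(diag(D) != 0) || any(D < 0) ||
      any(!is.finite(D)))
    stop("not a valid distance matrix")
  nwk <- stats::setNames(labels, labels)      # newick fragment per cluster
  rep_lab <- stats::setNames(labels, labels)  # smallest leaf label
  act <- labels
  d <- D
  fmt <- function(x) sprintf("%.15g", max(x, 0))
  while (length(act) > 3L) {
    r <- length(act)
    R <- rowSums(d)
    Q <- (r - 2) * d - outer(R, R, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    keys <- apply(cand, 1L, function(ij) {
      pr <- sort(c(rep_lab[act[ij[1]]], rep_lab[act[ij[2]]]))
      paste(pr, collapse = "\r")
    })
    pick <- cand[order(keys)[1L], ]
    i <- pick[1]; j <- pick[2]
    li <- d[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    lj <- d[i, j] - li
    new_lab <- paste0("(", act[i], ",", act[j], ")")
    new_nwk <- paste0("(", nwk[act[i]], ":", fmt(li), ",",
                      nwk[act[j]], ":", fmt(lj), ")")
    du <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], du[keep]),
                c(du[keep], 0))
    act2 <- c(act[keep], new_lab)
    dimnames(d2) <- list(act2, act2)
    nwk[new_lab] <- new_nwk
    rep_lab[new_lab] <- min(rep_lab[act[i]], rep_lab[act[j]])
    act <- act2
    d <- d2
  }
  a <- act[1]; b <- act[2]; c_ <- act[3]
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  txt <- paste0("(", nwk[a], ":", fmt(la), ",", nwk[b], ":", fmt(lb), ",",
                nwk[c_], ":", fmt(lc), ");")
  ape::read.tree(text = txt)
}

# non-trivial bipartitions of an unrooted tree as canonical keys:
# for each internal edge, the tip set below it, flipped so the key side
# never contains the alphabetically smallest tip
.bipartitions <- function(tree, trivial = FALSE) {
  tips <- tree$tip.label
  n <- length(tips)
  sides <- list()
  below <- function(node) {
    if (node <= n) return(tips[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, below))
  }
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    if (child <= n && !trivial) next
    sides[[length(sides) + 1L]] <- below(child)
  }
  keys <- vapply(sides, function(s) .bip_key(s, tips), "")
  unique(keys[nzchar(keys)])
}

.bip_key <- function(side, tips) {
  if (length(side) < 1L || length(side) >= length(tips)) return("")
  if (min(tips) %in% side) side <- setdiff(tips, side)
  paste(sort(side), collapse = "\r")
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Builds the reference tree (Poisson distance + NJ) from the full
#' alignment, then resamples alignment columns with replacement
#' `replicates` times, rebuilds a tree per replicate, and labels each
#' internal edge of the reference tree with the count of replicates whose
#' tree contains the same bipartition. Deterministic given `seed`.
#' Replicates in which some pair has no comparable columns are counted as
#' supporting no bipartition.
#'
#' @param aln Alignment as in [poissonDistance()], n >= 3 rows.
#' @param replicates Number of bootstrap replicates (>= 1).
#' @param seed RNG seed.
#' @return The reference `ape::phylo` tree with integer supports as
#'   `node.label` (empty at the basal node).
#' @export
bootstrapSupport <- function(aln, replicates = 100L, seed = 1L) {
  stopifnot(replicates >= 1L)
  aln <- .as_aastringset(aln)
  ref <- neighborJoining(poissonDistance(aln))
  m <- do.call(rbind, strsplit(as.character(aln), ""))
  rownames(m) <- names(aln)
  counts <- stats::setNames(
    integer(length(.bipartitions(ref))), .bipartitions(ref))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(seed)
  for (b in seq_len(replicates)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    rs <- apply(m[, cols, drop = FALSE], 1L, paste, collapse = "")
    rep_tree <- tryCatch(
      neighborJoining(poissonDistance(
        Biostrings::AAStringSet(stats::setNames(rs, rownames(m))))),
      error = function(e) NULL)
    if (is.null(rep_tree)) next
    hit <- intersect(names(counts), .bipartitions(rep_tree))
    counts[hit] <- counts[hit] + 1L
  }
  # attach supports: internal non-basal nodes carry their edge's count
  tips <- ref$tip.label
  n <- length(tips)
  labs <- character(ref$Nnode)
  below <- function(node) {
    if (node <= n) return(tips[node])
    kids <- ref$edge[ref$edge[, 1] == node, 2]
    unlist(lapply(kids, below))
  }
  for (node in (n + 2L):(n + ref$Nnode)) {
    key <- .bip_key(below(node), tips)
    if (nzchar(key) && key %in% names(counts))
      labs[node - n] <- as.character(counts[[key]])
  }
  ref$node.label <- labs
  ref
}

#' Test monophyly of a label set
#'
#' True iff some edge of the unrooted tree induces exactly `labels` on one
#' side (singletons are always monophyletic; the result is invariant under
#' complementation).
#'
#' @param tree An `ape::phylo`.
#' @param labels Subset of the tip labels, `1 <= |labels| < n`.
#' @return Logical scalar.
#' @export
isMonophyletic <- function(tree, labels) {
  tips <- tree$tip.label
  bad <- setdiff(labels, tips)
  if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "))
  labels <- unique(labels)
  if (length(labels) < 1L || length(labels) >= length(tips))
    stop("label set must be a proper non-empty subset of the leaves")
  if (length(labels) == 1L || length(labels) == length(tips) - 1L)
    return(TRUE)  # a leaf edge induces every singleton and its complement
  key <- .bip_key(labels, tips)
  key %in% .bipartitions(tree)
}

#' Relatedness filter: DTC-like or SHC-like?
#'
#' Classifies a didomain query by mean distance to two reference groups:
#' `DTC_LIKE` iff the mean distance to the diterpene-cyclase references is
#' strictly smaller than to the squalene-hopene-cyclase references; ties are
#' resolved `SHC_LIKE` (conservative removal from the DTC dataset).
#'
#' @param query A single sequence.
#' @param dtc_refs,shc_refs Non-empty reference sequence sets.
#' @param distance_fn `function(a, b)` returning a distance between two
#'   sequences; default is 3-mer cosine distance.
#' @return `"DTC_LIKE"` or `"SHC_LIKE"`.
#' @export
closerToGroup <- function(query, dtc_refs, shc_refs, distance_fn = NULL) {
  q <- .single_seq(query)
  dtc <- as.character(.as_aastringset(.auto_name(dtc_refs)))
  shc <- as.character(.as_aastringset(.auto_name(shc_refs)))
  if (!length(dtc) || !length(shc)) stop("reference sets must be non-empty")
  if (is.null(distance_fn))
    distance_fn <- function(a, b)
      kmerDistance(c(q1 = a, q2 = b))["q1", "q2"]
  md <- mean(vapply(dtc, function(r) distance_fn(q, r), 0))
  ms <- mean(vapply(shc, function(r) distance_fn(q, r), 0))
  if (md < ms) "DTC_LIKE" else "SHC_LIKE"
}

.auto_name <- function(x) {
  if (is.character(x) && is.null(names(x)))
    names(x) <- sprintf("s%03d", seq_along(x))
  x
}
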