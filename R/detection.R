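# Domain detection: turns ingested HMMER rows or an internal
# position-probability profile scan into merged per-protein domain hits, and
# assembles the two screening datasets whose intersection is the
# fusion-candidate pool.

.emptyHits <- function() {
  S4Vectors::DataFrame(protein_id = character(0), class = character(0),
                       start = integer(0), end = integer(0),
                       score = numeric(0), provider = character(0))
}

# merge sorted-by-start intervals with gap <= merge_gap; score = max
.merge_intervals <- function(start, end, score, merge_gap) {
  o <- order(start, end)
  start <- start[o]; end <- end[o]; score <- score[o]
  ms <- me <- integer(0); msc <- numeric(0)
  for (i in seq_along(start)) {
    if (length(ms) && start[i] <= me[length(me)] + merge_gap + 1L) {
      me[length(me)] <- max(me[length(me)], end[i])
      msc[length(msc)] <- max(msc[length(msc)], score[i])
    } else {
      ms <- c(ms, start[i]); me <- c(me, end[i]); msc <- c(msc, score[i])
    }
  }
  list(start = ms, end = me, score = msc)
}

#' Domain hits from ingested HMMER rows
#'
#' Applies the per-domain e-value cutoffs, merges overlapping or adjacent
#' (gap at most `merge_gap`) intervals per protein and class, and emits
#' didomain (`GB_DTC`) hits only for proteins carrying both flavors of
#' didomain evidence (C-terminal- and N-terminal-domain profiles), spanning
#' their combined extent. Scores are `-log10` of the domain i-e-value (max on
#' merge).
#'
#' @param rows A table from [readDomtblout()].
#' @param config A [ScreenConfig-class].
#' @return Domain hits: a [S4Vectors::DataFrame] with columns `protein_id`,
#'   `class` (`ALPHA_TS`, `GB_DTC`, `SHC_LIKE`), `start`, `end`, `score`,
#'   `provider` (`"external"`).
#' @export
hitsFromRows <- function(rows, config = ScreenConfig()) {
  rows <- S4Vectors::DataFrame(rows)
  if (!nrow(rows)) return(.emptyHits())
  cutoff <- ifelse(rows$domain_class == "ALPHA_TS",
                   config@alpha_evalue_cutoff, config@gb_evalue_cutoff)
  rows <- rows[rows$domain_ievalue <= cutoff, , drop = FALSE]
  if (!nrow(rows)) return(.emptyHits())
  out <- list()
  for (pid in unique(rows$target_id)) {
    r <- rows[rows$target_id == pid, , drop = FALSE]
    a <- r[r$domain_class == "ALPHA_TS", , drop = FALSE]
    if (nrow(a)) {
      m <- .merge_intervals(a$env_start, a$env_end,
                            -log10(a$domain_ievalue), config@merge_gap)
      out[[length(out) + 1L]] <- S4Vectors::DataFrame(
        protein_id = pid, class = "ALPHA_TS", start = m$start, end = m$end,
        score = m$score, provider = "external")
    }
    g <- r[r$domain_class %in% c("GB_CTERM", "GB_NTERM"), , drop = FALSE]
    if (nrow(g) && all(c("GB_CTERM", "GB_NTERM") %in% g$domain_class)) {
      out[[length(out) + 1L]] <- S4Vectors::DataFrame(
        protein_id = pid, class = "GB_DTC",
        start = min(g$env_start), end = max(g$env_end),
        score = max(-log10(g$domain_ievalue)), provider = "external")
    }
  }
  if (!length(out)) return(.emptyHits())
  res <- do.call(rbind, out)
  res[order(res$protein_id, res$class, res$start), , drop = FALSE]
}

#' Packaged position-probability profiles
#'
#' Builds the internal scanner's profiles from the three packaged templates
#' with pseudocount 1/20: per column the template residue has probability
#' 1.05/2 and every other residue 0.05/2; scores are
#' `log2(p / (1/20))` half-bit log-odds. The self-match score (sum of the
#' template-residue column scores) is attached as attribute `self_score`.
#'
#' @return Named list (`ALPHA_TS`, `GB_DTC`, `SHC_LIKE`) of 20 x width score
#'   matrices (rows = residues).
#' @export
buildProfiles <- function() {
  one <- function(template) {
    sv <- strsplit(template, "")[[1]]
    w <- length(sv)
    p <- matrix(0.05 / 2, nrow = 20L, ncol = w, dimnames = list(.AA20, NULL))
    p[cbind(match(sv, .AA20), seq_len(w))] <- 1.05 / 2
    m <- log2(p / (1 / 20))
    attr(m, "self_score") <- sum(m[cbind(match(sv, .AA20), seq_len(w))])
    m
  }
  list(ALPHA_TS = one(ALPHA_TEMPLATE), GB_DTC = one(GB_TEMPLATE),
       SHC_LIKE = one(SHC_TEMPLATE))
}

.scan_one <- function(s, profile, threshold, merge_gap) {
  w <- ncol(profile)
  L <- nchar(s)
  if (L < w) return(NULL)
  res <- match(strsplit(s, "")[[1]], .AA20)  # X / unknown -> NA
  n_off <- L - w + 1L
  sc <- numeric(n_off)
  # X scores as the flat log-odds of a residue drawn blind, i.e. 0 - penalty;
  # use the column minimum so unknowns never inflate a window
  colmin <- apply(profile, 2L, min)
  for (k in seq_len(w)) {
    v <- unname(profile[res[k:(k + n_off - 1L)], k])
    v[is.na(v)] <- colmin[k]
    sc <- sc + v
  }
  hit <- which(sc >= threshold)
  if (!length(hit)) return(NULL)
  m <- .merge_intervals(hit, hit + w - 1L, sc[hit], merge_gap)
  m
}

#' Internal heuristic domain scan
#'
#' Desk-scale stand-in for external profile searches: slides each packaged
#' position-probability profile over every sequence at stride 1, scoring each
#' window as the summed half-bit log-odds, and keeps windows scoring at least
#' the class threshold (default 60% of the profile self-match score, a level
#' calibrated to yield no hits on random sequences); qualifying windows are
#' merged like external sub-hits. Deterministic.
#'
#' @param x Sequences ([Biostrings::AAStringSet] or named character vector).
#' @param profiles From [buildProfiles()].
#' @param config A [ScreenConfig-class]; `internal_score_threshold` entries
#'   that are `NA` use the 60% default.
#' @return Domain hits as in [hitsFromRows()], with `provider = "internal"`.
#' @export
scanInternal <- function(x, profiles = buildProfiles(),
                         config = ScreenConfig()) {
  x <- .as_aastringset(x)
  seqs <- as.character(x)
  out <- list()
  thr <- vapply(names(profiles), function(cls) {
    t <- config@internal_score_threshold[cls]
    if (is.null(t) || is.na(t)) 0.6 * attr(profiles[[cls]], "self_score")
    else unname(t)
  }, 0)
  for (i in seq_along(seqs)) {
    for (cls in names(profiles)) {
      m <- .scan_one(seqs[i], profiles[[cls]], thr[[cls]], config@merge_gap)
      if (is.null(m)) next
      out[[length(out) + 1L]] <- S4Vectors::DataFrame(
        protein_id = names(seqs)[i], class = cls, start = m$start,
        end = m$end, score = m$score, provider = "internal")
    }
  }
  if (!length(out)) return(.emptyHits())
  res <- do.call(rbind, out)
  res[order(match(res$protein_id, names(seqs)), res$start), , drop = FALSE]
}

#' Assemble the TS and DTC screening datasets
#'
#' The TS set holds every protein with at least one alpha-domain hit; the
#' DTC set every protein with at least one didomain hit not flagged
#' SHC-like. The sets may overlap: the overlap is the fusion-candidate pool.
#'
#' @param hits Domain hits from [hitsFromRows()] or [scanInternal()].
#' @param shc_ids Protein ids whose didomain evidence is SHC-like and must be
#'   excluded from the DTC set. Default `NULL` derives the flag from the
#'   hits themselves: a protein whose best `SHC_LIKE` score is at least its
#'   best `GB_DTC` score (or that has only `SHC_LIKE` didomain evidence) is
#'   flagged. Pass ids from [closerToGroup()] for external evidence.
#' @return `list(ts_set, dtc_set, overlap)` of protein id character vectors.
#' @export
buildDatasets <- function(hits, shc_ids = NULL) {
  hits <- S4Vectors::DataFrame(hits)
  if (is.null(shc_ids)) shc_ids <- .shc_flagged(hits)
  ts <- unique(hits$protein_id[hits$class == "ALPHA_TS"])
  dtc_all <- unique(hits$protein_id[hits$class == "GB_DTC"])
  dtc <- setdiff(dtc_all, shc_ids)
  list(ts_set = ts, dtc_set = dtc, overlap = intersect(ts, dtc))
}

# proteins whose SHC-like didomain evidence dominates their DTC evidence
.shc_flagged <- function(hits) {
  ids <- unique(hits$protein_id[hits$class == "SHC_LIKE"])
  vapply(ids, function(pid) {
    shc <- max(hits$score[hits$protein_id == pid & hits$class == "SHC_LIKE"])
    gb <- hits$score[hits$protein_id == pid & hits$class == "GB_DTC"]
    !length(gb) || shc >= max(gb)
  }, TRUE) -> keep
  ids[keep]
}
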