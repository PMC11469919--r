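# Per-protein architecture calls: the central screen. A fusion candidate
# needs didomain evidence strictly N-terminal to alpha-domain evidence
# (gamma-beta-alpha order); predicted bifunctionality additionally requires
# intact Class I and Class II motif sets.

.CALLS <- c("DCS_CANDIDATE", "DCS_ATYPICAL_ORDER", "TS_ONLY", "DTC_ONLY",
            "SHC_LIKE", "NONE")

#' Call the domain architecture of one protein
#'
#' Uses the most N-terminal didomain hit and the most C-terminal alpha hit
#' for the order test (conservative gamma-beta-alpha check): both classes
#' with didomain end before alpha start give `DCS_CANDIDATE`; both classes
#' otherwise `DCS_ATYPICAL_ORDER`; alpha only `TS_ONLY`; didomain only
#' `DTC_ONLY` (or `SHC_LIKE` when the didomain evidence is SHC-flagged); no
#' hits `NONE`. `predicted_bifunctional` is true only for candidates whose
#' Class I and Class II motif sets are both intact.
#'
#' @param protein_id Protein id; `hits` rows must all carry it.
#' @param length Protein length (residues).
#' @param hits Domain hits for this protein ([scanInternal()] /
#'   [hitsFromRows()] rows).
#' @param motif_status A [MotifStatus-class] from [classifyMotifStatus()].
#' @param shc_flagged Whether the didomain evidence is SHC-like (see
#'   [buildDatasets()]).
#' @param min_total_length Candidates shorter than this are demoted to
#'   `NONE` (default 0: no gate).
#' @return One-row [S4Vectors::DataFrame]: `protein_id`, `call`, `gb_start`,
#'   `gb_end`, `alpha_start`, `alpha_end`, `classII`, `classI`,
#'   `predicted_bifunctional`.
#' @export
callArchitecture <- function(protein_id, length, hits, motif_status,
                             shc_flagged = FALSE, min_total_length = 0) {
  hits <- S4Vectors::DataFrame(hits)
  if (nrow(hits) && any(hits$protein_id != protein_id))
    stop("hits carry a different protein_id than ", protein_id)
  gb <- hits[hits$class == "GB_DTC", , drop = FALSE]
  al <- hits[hits$class == "ALPHA_TS", , drop = FALSE]
  has_gb <- nrow(gb) > 0 && !shc_flagged
  has_al <- nrow(al) > 0
  gb_sel <- if (nrow(gb)) gb[which.min(gb$start), ] else NULL
  al_sel <- if (nrow(al)) al[which.max(al$end), ] else NULL
  call <- if (has_gb && has_al) {
    if (gb_sel$end < al_sel$start) "DCS_CANDIDATE" else "DCS_ATYPICAL_ORDER"
  } else if (has_al) "TS_ONLY"
  else if (nrow(gb) || shc_flagged) {
    if (shc_flagged) "SHC_LIKE" else "DTC_ONLY"
  } else if (any(hits$class == "SHC_LIKE")) "SHC_LIKE"
  else "NONE"
  if (call == "DCS_CANDIDATE" && length < min_total_length) call <- "NONE"
  bifunctional <- call == "DCS_CANDIDATE" &&
    motif_status@classI == "INTACT" && motif_status@classII == "INTACT"
  S4Vectors::DataFrame(
    protein_id = protein_id, call = call,
    gb_start = if (has_gb) gb_sel$start else NA_integer_,
    gb_end = if (has_gb) gb_sel$end else NA_integer_,
    alpha_start = if (has_al) al_sel$start else NA_integer_,
    alpha_end = if (has_al) al_sel$end else NA_integer_,
    classII = motif_status@classII, classI = motif_status@classI,
    predicted_bifunctional = bifunctional)
}

#' Render an architecture report
#'
#' Produces, per protein, an ASCII track of the detected domain intervals
#' and a TSV-ready table (one row per protein, sorted by id) with the call,
#' intervals, motif statuses and predicted activity.
#'
#' @param calls Call table (rbound rows of [callArchitecture()]).
#' @param width Track width in characters (default 70).
#' @param lengths Optional named integer vector of protein lengths used to
#'   scale the tracks; defaults to each protein's maximum hit end.
#' @return `list(table = DataFrame, tracks = named character vector)`.
#' @export
renderArchitecture <- function(calls, width = 70L, lengths = NULL) {
  calls <- S4Vectors::DataFrame(calls)
  if (nrow(calls)) calls <- calls[order(calls$protein_id), , drop = FALSE]
  tracks <- character(0)
  for (i in seq_len(nrow(calls))) {
    r <- calls[i, ]
    L <- if (!is.null(lengths) && r$protein_id %in% names(lengths))
      lengths[[r$protein_id]]
    else max(r$gb_end, r$alpha_end, 1L, na.rm = TRUE)
    tr <- rep(".", width)
    put <- function(tr, s, e, ch) {
      if (is.na(s)) return(tr)
      a <- max(1L, ceiling(s / L * width)); b <- max(a, ceiling(e / L * width))
      tr[a:b] <- ch
      tr
    }
    tr <- put(tr, r$gb_start, r$gb_end, "G")
    tr <- put(tr, r$alpha_start, r$alpha_end, "A")
    tracks[r$protein_id] <- sprintf("%-12s %s %s", r$protein_id,
                                    paste(tr, collapse = ""), r$call)
  }
  list(table = calls, tracks = tracks)
}
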