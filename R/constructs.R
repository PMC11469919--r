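# Splitting fusion candidates into independently testable cyclase and
# synthase constructs, and anchored in-silico point mutagenesis.

#' Split a fusion candidate into didomain and alpha constructs
#'
#' Cuts the parent after a boundary residue chosen by rule: `"GB_END"`
#' (default; end of the detected didomain hit), `"MIDLINKER"` (midpoint of
#' the inter-domain gap) or `"EXPLICIT:n"` (a stated boundary, as used for
#' characterized fusions whose published didomain ends, e.g. residues 540
#' and 506, are not derivable from hit coordinates). Concatenating the two
#' parts restores the parent exactly.
#'
#' @param x The parent sequence (length-1 [Biostrings::AAStringSet], named
#'   character scalar, or `AAString` with the id given by `names`).
#' @param call A one-row call table from [callArchitecture()] with call
#'   `DCS_CANDIDATE`.
#' @param boundary_rule `"GB_END"`, `"MIDLINKER"` or `"EXPLICIT:n"`.
#' @return An [Biostrings::AAStringSet] of the two constructs, named
#'   `<parent>:NTERM_GB` and `<parent>:CTERM_ALPHA`, with `mcols` columns
#'   `parent_id`, `part`, `boundary`.
#' @examples
#' \dontrun{splitDcs(seq, call, "EXPLICIT:540")}
#' @export
splitDcs <- function(x, call, boundary_rule = "GB_END") {
  s <- .single_seq(x)
  L <- nchar(s)
  call <- S4Vectors::DataFrame(call)
  stopifnot(nrow(call) == 1L)
  if (call$call != "DCS_CANDIDATE")
    stop("can only split a DCS_CANDIDATE (got ", call$call, ")")
  gb_end <- call$gb_end
  alpha_start <- call$alpha_start
  boundary <- if (boundary_rule == "GB_END") {
    gb_end
  } else if (boundary_rule == "MIDLINKER") {
    gb_end + (alpha_start - gb_end) %/% 2L
  } else if (startsWith(boundary_rule, "EXPLICIT:")) {
    n <- as.integer(sub("^EXPLICIT:", "", boundary_rule))
    if (is.na(n) || n < gb_end - 20L || n > alpha_start - 1L)
      stop(sprintf(
        "explicit boundary %s outside [%d, %d] (didomain end - 20, alpha start - 1)",
        sub("^EXPLICIT:", "", boundary_rule), gb_end - 20L, alpha_start - 1L))
    n
  } else stop("unknown boundary_rule: ", boundary_rule)
  pid <- call$protein_id
  out <- Biostrings::AAStringSet(c(
    substr(s, 1L, boundary), substr(s, boundary + 1L, L)))
  names(out) <- paste0(pid, c(":NTERM_GB", ":CTERM_ALPHA"))
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    parent_id = pid, part = c("NTERM_GB", "CTERM_ALPHA"),
    boundary = as.integer(boundary))
  out
}

#' Apply an anchored point mutation
#'
#' Anchors a substitution on a motif occurrence rather than a raw
#' coordinate: the target residue is `offset` (1-based) within the
#' `occurrence`-th region-constrained hit of `anchor_motif`, so the same
#' mutation definition transfers across homologs. The mutant label records
#' the absolute position in the field's `D610A` style.
#'
#' @param x The sequence to mutate (length-1 set or named character; the
#'   name is the record id).
#' @param anchor_motif Name of a motif in `motifs` (e.g. `"DDxxD"`,
#'   `"LHS"`).
#' @param offset 1-based offset of the mutated residue within the motif.
#' @param replacement Replacement residue.
#' @param occurrence Which region-constrained hit to anchor on (default 1,
#'   most N-terminal).
#' @param region_intervals Passed to [scanMotifs()].
#' @param motifs Motif set (default [builtinMotifs()]).
#' @return A length-1 [Biostrings::AAStringSet] named `<id>:<label>` with
#'   `mcols` columns `parent_id`, `label`, `position`, `from`, `to`,
#'   `anchor_motif`, `offset`. The input is not modified.
#' @examples
#' applyMutation(c(p = "AAADDTTDAAAAA"), "DDxxD", offset = 1,
#'               replacement = "A",
#'               region_intervals = list(alpha = c(1, 13), gb = NULL))
#' @export
applyMutation <- function(x, anchor_motif, offset, replacement,
                          occurrence = 1L, region_intervals = NULL,
                          motifs = builtinMotifs()) {
  s <- .single_seq(x)
  pid <- if (methods::is(x, "AAStringSet")) names(x) else names(x)
  if (is.null(pid)) pid <- "query"
  if (!anchor_motif %in% names(motifs))
    stop("unknown anchor motif: ", anchor_motif)
  def <- motifs[[anchor_motif]]
  if (offset < 1L || offset > length(def@positions))
    stop("offset outside motif ", anchor_motif)
  hits <- scanMotifs(s, motifs[anchor_motif], region_intervals)
  if (nrow(hits) < occurrence)
    stop(sprintf("motif %s has %d region-constrained hit(s); occurrence %d requested",
                 anchor_motif, nrow(hits), occurrence))
  pos <- hits$start[occurrence] + offset - 1L
  from <- substr(s, pos, pos)
  allowed <- def@positions[[offset]]
  if (length(allowed) && !from %in% allowed)
    stop(sprintf("anchored residue mismatch at %d: expected one of {%s}, found %s",
                 pos, paste(allowed, collapse = ","), from))
  if (!replacement %in% .AA20) stop("replacement must be a standard residue")
  mutated <- s
  substr(mutated, pos, pos) <- replacement
  label <- sprintf("%s%d%s", from, pos, replacement)
  out <- Biostrings::AAStringSet(stats::setNames(mutated,
                                                 paste0(pid, ":", label)))
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    parent_id = pid, label = label, position = pos, from = from,
    to = replacement, anchor_motif = anchor_motif, offset = as.integer(offset))
  out
}
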