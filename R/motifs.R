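# Degenerate catalytic-motif engine: grammar compiler, region-constrained
# overlapping scanner, Class I / Class II status classification.
#
# Grammar: an uppercase letter is an exact residue, 'x' the wildcard
# (matches any residue including the unknown X), "(A/B/C)" a residue set.

#' Compile a degenerate motif pattern
#'
#' @param pattern_text Pattern under the grammar above, e.g.
#'   `"(N/D)Dxx(S/T/G)xxx(E/D)"`.
#' @param name Motif name (defaults to the pattern text).
#' @param region Region constraint: `"GB_REGION"`, `"ALPHA_REGION"` or
#'   `"ANY"`.
#' @return A [MotifDefinition-class].
#' @examples
#' compileMotif("DxDD", region = "GB_REGION")
#' @export
compileMotif <- function(pattern_text, name = pattern_text, region = "ANY") {
  if (!nchar(pattern_text)) stop("empty motif pattern")
  positions <- list()
  i <- 1L
  n <- nchar(pattern_text)
  while (i <= n) {
    ch <- substr(pattern_text, i, i)
    if (ch == "x") {
      positions[[length(positions) + 1L]] <- character(0)  # wildcard
      i <- i + 1L
    } else if (ch == "(") {
      close <- regexpr(")", substr(pattern_text, i, n), fixed = TRUE)
      if (close < 0)
        stop(sprintf("motif parse error at column %d: unbalanced '('", i))
      inner <- substr(pattern_text, i + 1L, i + close - 2L)
      alts <- strsplit(inner, "/", fixed = TRUE)[[1]]
      if (!length(alts) || any(nchar(alts) != 1L) || !all(alts %in% .AA20))
        stop(sprintf("motif parse error at column %d: bad alternative set '%s'",
                     i, inner))
      positions[[length(positions) + 1L]] <- alts
      i <- i + close
    } else if (ch %in% .AA20) {
      positions[[length(positions) + 1L]] <- ch
      i <- i + 1L
    } else {
      stop(sprintf("motif parse error at column %d: illegal character '%s'",
                   i, ch))
    }
  }
  methods::new("MotifDefinition", name = name, pattern = pattern_text,
               positions = positions, region = region)
}

#' Built-in catalytic motif set
#'
#' The aspartate-rich catalytic motifs of the two terpene-synthase classes
#' and their aberrant variants, plus the active-site context motifs:
#' `DxDD` (Class II catalytic acid, didomain region), `DDxxD` and `NSE` =
#' `(N/D)Dxx(S/T/G)xxx(E/D)` (Class I magnesium binding, alpha region),
#' `ABERRANT_DD` = `DDxxx(D/E)` and `NSE_VARIANT` = `NGxxSxxxE` (aberrant
#' Class I variants), and the contexts `LHS`, `PNV` (catalytic dyad,
#' didomain region) and `PIx` (plant-type key isoleucine, alpha region).
#'
#' @return Named list of [MotifDefinition-class] objects.
#' @export
builtinMotifs <- function() {
  defs <- list(
    DxDD = compileMotif("DxDD", "DxDD", "GB_REGION"),
    DDxxD = compileMotif("DDxxD", "DDxxD", "ALPHA_REGION"),
    NSE = compileMotif("(N/D)Dxx(S/T/G)xxx(E/D)", "NSE", "ALPHA_REGION"),
    ABERRANT_DD = compileMotif("DDxxx(D/E)", "ABERRANT_DD", "ALPHA_REGION"),
    NSE_VARIANT = compileMotif("NGxxSxxxE", "NSE_VARIANT", "ALPHA_REGION"),
    LHS = compileMotif("LHS", "LHS", "GB_REGION"),
    PNV = compileMotif("PNV", "PNV", "GB_REGION"),
    PIx = compileMotif("PIx", "PIx", "ALPHA_REGION")
  )
  defs
}

.motif_regex <- function(def) {
  paste(vapply(def@positions, function(p) {
    if (!length(p)) "."
    else if (length(p) == 1L) p
    else paste0("[", paste(p, collapse = ""), "]")
  }, ""), collapse = "")
}

.default_regions <- function(L) {
  half <- as.integer(ceiling(L / 2))
  list(gb = c(1L, half), alpha = c(half + 1L, L))
}

#' Scan a sequence for degenerate motifs
#'
#' Reports every (possibly overlapping) match of each definition whose full
#' span lies inside the motif's constrained region, in ascending start
#' order. When `region_intervals` is `NULL` the didomain region defaults to
#' the N-terminal half `[1, ceiling(L/2)]` and the alpha region to the
#' C-terminal half; a region explicitly set to `NULL` inside
#' `region_intervals` yields no matches for motifs constrained to it.
#'
#' @param x A single sequence (character scalar, `AAString`, or a length-1
#'   `AAStringSet`).
#' @param definitions List of [MotifDefinition-class] (default
#'   [builtinMotifs()]).
#' @param region_intervals Optional `list(gb =, alpha =)` of 1-based
#'   inclusive `c(start, end)` pairs, normally the detected domain
#'   intervals.
#' @return A [S4Vectors::DataFrame] with columns `motif_name`, `start`,
#'   `end`, `matched`.
#' @examples
#' scanMotifs("AAADIDDAAA", builtinMotifs()["DxDD"],
#'            region_intervals = list(gb = c(1, 10), alpha = NULL))
#' @export
scanMotifs <- function(x, definitions = builtinMotifs(),
                       region_intervals = NULL) {
  s <- .single_seq(x)
  L <- nchar(s)
  if (is.null(region_intervals)) region_intervals <- .default_regions(L)
  out <- list()
  for (def in definitions) {
    w <- length(def@positions)
    reg <- switch(def@region,
                  GB_REGION = region_intervals$gb,
                  ALPHA_REGION = region_intervals$alpha,
                  ANY = c(1L, L))
    if (is.null(reg) || L < w) next
    m <- gregexpr(sprintf("(?=%s)", .motif_regex(def)), s, perl = TRUE)[[1]]
    if (m[1] < 0) next
    starts <- as.integer(m)
    ends <- starts + w - 1L
    keep <- starts >= reg[1] & ends <= min(reg[2], L)
    if (!any(keep)) next
    out[[length(out) + 1L]] <- S4Vectors::DataFrame(
      motif_name = def@name, start = starts[keep], end = ends[keep],
      matched = substring(s, starts[keep], ends[keep]))
  }
  if (!length(out)) {
    return(S4Vectors::DataFrame(motif_name = character(0), start = integer(0),
                                end = integer(0), matched = character(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$start, res$motif_name), , drop = FALSE]
}

#' Classify Class I / Class II motif status
#'
#' Class II is `INTACT` iff at least one DxDD hit lies in the didomain
#' region. Class I is `INTACT` iff DDxxD and NSE hits both occur in the
#' alpha region with some DDxxD upstream of some NSE at a start separation
#' inside `spacing`; `ABERRANT` iff not intact but an aberrant variant
#' (DDxxx(D/E) or NGxxSxxxE) is present, or both canonical motifs are
#' present with out-of-window spacing; else `ABSENT`. When canonical and
#' aberrant motifs co-occur with valid spacing, canonical wins.
#'
#' @param hits Motif hits for one protein, from [scanMotifs()] (order
#'   irrelevant).
#' @param spacing Allowed DDxxD-to-NSE start separation, default
#'   `c(80, 220)` residues.
#' @return A [MotifStatus-class].
#' @export
classifyMotifStatus <- function(hits, spacing = c(80, 220)) {
  starts <- function(nm) hits$start[hits$motif_name == nm]
  classII <- if (length(starts("DxDD"))) "INTACT" else "ABSENT"
  dd <- starts("DDxxD")
  nse <- starts("NSE")
  sep_ok <- FALSE
  pair_present <- length(dd) > 0 && length(nse) > 0
  if (pair_present) {
    seps <- outer(nse, dd, "-")  # NSE start minus DDxxD start
    sep_ok <- any(seps >= spacing[1] & seps <= spacing[2])
  }
  classI <- if (sep_ok) "INTACT"
  else if (length(starts("ABERRANT_DD")) || length(starts("NSE_VARIANT")) ||
           pair_present) "ABERRANT"
  else "ABSENT"
  methods::new("MotifStatus", classI = classI, classII = classII,
               hits = S4Vectors::DataFrame(hits))
}

.single_seq <- function(x) {
  if (methods::is(x, "AAStringSet")) {
    stopifnot(length(x) == 1L)
    return(as.character(x)[[1]])
  }
  if (methods::is(x, "AAString")) return(as.character(x))
  stopifnot(is.character(x), length(x) == 1L)
  x
}
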