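#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
NULL

setClassUnion("DataFrameOrNULL", c("DFrame", "NULL"))

#' Screen configuration
#'
#' Holds the thresholds and profile identifiers of the intersection screen:
#' the Pfam profile sets used to collect alpha-domain terpene-synthase (TS)
#' and gamma-beta-didomain diterpene-cyclase (DTC) evidence, the e-value
#' cutoffs applied to ingested HMMER rows, the internal profile-scanner score
#' thresholds, interval-merge gap and the Class I motif spacing window.
#'
#' `cdd_evalue_cutoff`, `gb_blast_evalue_cutoff` and `reference_dtc_id`
#' record the confirmation steps of the external-tool workflow (conserved
#' domain database confirmation; blastp against a characterized CPS) and are
#' metadata only: no web or blast queries are run.
#'
#' @param alpha_profile_ids,gb_profile_ids Pfam accessions (version suffix
#'   ignored) recognized as alpha-domain / didomain evidence.
#' @param alpha_evalue_cutoff,gb_evalue_cutoff Per-domain independent e-value
#'   cutoffs for ingested rows (defaults 1e-3).
#' @param cdd_evalue_cutoff,gb_blast_evalue_cutoff,reference_dtc_id Metadata.
#' @param internal_score_threshold Named numeric, log2-odds half-bit score
#'   thresholds for the internal scanner per domain class; `NA` means 60\% of
#'   the profile's self-match score.
#' @param merge_gap Maximum residue gap between sub-hits merged into one
#'   domain interval (default 30).
#' @param class1_spacing Allowed DDxxD-to-NSE start separation (residues) for
#'   an intact Class I motif pair, default `c(80, 220)`.
#' @param min_total_length Minimum candidate protein length (default 0: no
#'   length gate).
#' @return A `ScreenConfig` object.
#' @export ScreenConfig
#' @exportClass ScreenConfig
ScreenConfig <- setClass("ScreenConfig", slots = c(
  alpha_profile_ids = "character",
  gb_profile_ids = "character",
  alpha_evalue_cutoff = "numeric",
  gb_evalue_cutoff = "numeric",
  cdd_evalue_cutoff = "numeric",
  gb_blast_evalue_cutoff = "numeric",
  reference_dtc_id = "character",
  internal_score_threshold = "numeric",
  merge_gap = "numeric",
  class1_spacing = "numeric",
  min_total_length = "numeric"
))

setValidity("ScreenConfig", function(object) {
  cuts <- c(object@alpha_evalue_cutoff, object@gb_evalue_cutoff,
            object@cdd_evalue_cutoff, object@gb_blast_evalue_cutoff)
  if (any(!is.finite(cuts)) || any(cuts <= 0))
    return("e-value cutoffs must be positive")
  if (length(object@class1_spacing) != 2 ||
      object@class1_spacing[1] > object@class1_spacing[2])
    return("class1_spacing must be an ordered pair")
  if (object@merge_gap < 0) return("merge_gap must be >= 0")
  TRUE
})

setMethod("initialize", "ScreenConfig", function(.Object, ...,
    alpha_profile_ids = c("PF03936", "PF19086", "PF06330"),
    gb_profile_ids = c("PF13243", "PF13249"),
    alpha_evalue_cutoff = 1e-3,
    gb_evalue_cutoff = 1e-3,
    cdd_evalue_cutoff = 1e-2,
    gb_blast_evalue_cutoff = 1e-4,
    reference_dtc_id = "BAC47414.1",
    internal_score_threshold = c(ALPHA_TS = NA_real_, GB_DTC = NA_real_,
                                 SHC_LIKE = NA_real_),
    merge_gap = 30,
    class1_spacing = c(80, 220),
    min_total_length = 0) {
  callNextMethod(.Object,
    alpha_profile_ids = alpha_profile_ids, gb_profile_ids = gb_profile_ids,
    alpha_evalue_cutoff = alpha_evalue_cutoff,
    gb_evalue_cutoff = gb_evalue_cutoff,
    cdd_evalue_cutoff = cdd_evalue_cutoff,
    gb_blast_evalue_cutoff = gb_blast_evalue_cutoff,
    reference_dtc_id = reference_dtc_id,
    internal_score_threshold = internal_score_threshold,
    merge_gap = merge_gap, class1_spacing = class1_spacing,
    min_total_length = min_total_length, ...)
})

setMethod("show", "ScreenConfig", function(object) {
  cat("ScreenConfig\n")
  cat("  alpha profiles:", paste(object@alpha_profile_ids, collapse = ", "),
      sprintf("(e-value <= %g)\n", object@alpha_evalue_cutoff))
  cat("  gamma-beta profiles:", paste(object@gb_profile_ids, collapse = ", "),
      sprintf("(e-value <= %g)\n", object@gb_evalue_cutoff))
  cat(sprintf("  merge gap: %g aa; Class I spacing window: [%g, %g]\n",
              object@merge_gap, object@class1_spacing[1],
              object@class1_spacing[2]))
})

.SYNTH_CLASSES <- c("DCS_INTACT", "DCS_ABERRANT", "TS_ONLY", "DTC_ONLY",
                    "SHC_DECOY", "BACKGROUND")

#' Synthetic proteome specification
#'
#' Describes a labeled synthetic proteome: how many proteins to plant per
#' architecture class, how far instances diverge from the packaged templates,
#' linker and background length ranges, and the seed. Defaults are the
#' 50-protein desk-scale study condition used throughout the test suite
#' (5 intact fusions, 2 aberrant fusions, 10 alpha-only TSs, 10 didomain-only
#' DTCs, 3 SHC-like decoys, 20 background proteins; template identity 0.9).
#'
#' @param counts Named non-negative integers over the six classes
#'   `DCS_INTACT`, `DCS_ABERRANT`, `TS_ONLY`, `DTC_ONLY`, `SHC_DECOY`,
#'   `BACKGROUND`.
#' @param background_length_range Ordered pair, residues.
#' @param template_identity Fraction in (0, 1]; planted instances match their
#'   template at this expected identity outside mutation-locked motif spans.
#' @param seed Integer RNG seed.
#' @param linker_length_range Ordered pair of non-negative integers, residues
#'   between the didomain and alpha parts of a fusion.
#' @return A `SyntheticSpec` object.
#' @export SyntheticSpec
#' @exportClass SyntheticSpec
SyntheticSpec <- setClass("SyntheticSpec", slots = c(
  counts = "integer",
  background_length_range = "integer",
  template_identity = "numeric",
  seed = "integer",
  linker_length_range = "integer"
))

setValidity("SyntheticSpec", function(object) {
  if (!setequal(names(object@counts), .SYNTH_CLASSES))
    return("counts must be named by the six synthetic classes")
  if (any(object@counts < 0)) return("counts must be non-negative")
  if (object@template_identity <= 0 || object@template_identity > 1)
    return("template_identity must lie in (0, 1]")
  if (diff(object@background_length_range) < 0 ||
      any(object@background_length_range < 1))
    return("background_length_range must be an ordered pair of positives")
  if (diff(object@linker_length_range) < 0 ||
      any(object@linker_length_range < 0))
    return("linker_length_range must be an ordered non-negative pair")
  TRUE
})

setMethod("initialize", "SyntheticSpec", function(.Object, ...,
    counts = c(DCS_INTACT = 5L, DCS_ABERRANT = 2L, TS_ONLY = 10L,
               DTC_ONLY = 10L, SHC_DECOY = 3L, BACKGROUND = 20L),
    background_length_range = c(200L, 600L),
    template_identity = 0.9,
    seed = 42L,
    linker_length_range = c(5L, 25L)) {
  full <- stats::setNames(integer(length(.SYNTH_CLASSES)), .SYNTH_CLASSES)
  counts <- as.integer(counts)[match(.SYNTH_CLASSES, names(counts))]
  counts[is.na(counts)] <- 0L
  names(counts) <- .SYNTH_CLASSES
  callNextMethod(.Object, counts = counts,
    background_length_range = as.integer(background_length_range),
    template_identity = template_identity, seed = as.integer(seed),
    linker_length_range = as.integer(linker_length_range), ...)
})

setMethod("show", "SyntheticSpec", function(object) {
  cat("SyntheticSpec:",
      paste(sprintf("%s=%d", names(object@counts), object@counts),
            collapse = " "), "\n")
  cat(sprintf("  template identity %.2f, seed %d\n",
              object@template_identity, object@seed))
})

#' Degenerate catalytic motif definition
#'
#' A compiled degenerate motif: one entry per position, each either an exact
#' residue, a residue set, or the wildcard (stored as `character(0)`), plus
#' the region the motif is constrained to (`GB_REGION`, `ALPHA_REGION` or
#' `ANY`). Build with [compileMotif()].
#'
#' @seealso [compileMotif()], [builtinMotifs()], [scanMotifs()]
#' @exportClass MotifDefinition
setClass("MotifDefinition", slots = c(
  name = "character",
  pattern = "character",
  positions = "list",
  region = "character"
))

setValidity("MotifDefinition", function(object) {
  if (length(object@positions) < 3)
    return("motif must have length >= 3")
  if (!object@region %in% c("GB_REGION", "ALPHA_REGION", "ANY"))
    return("region must be GB_REGION, ALPHA_REGION or ANY")
  for (p in object@positions) {
    if (length(p) && !all(p %in% .AA20))
      return("position sets must be subsets of the 20 residues")
  }
  TRUE
})

setMethod("show", "MotifDefinition", function(object) {
  cat(sprintf("MotifDefinition %s: %s [%s]\n", object@name, object@pattern,
              object@region))
})

#' Class I / Class II motif status of one protein
#'
#' `classII` is `INTACT` when a DxDD hit lies in the didomain region, else
#' `ABSENT`. `classI` is `INTACT` when DDxxD and NSE both occur in the alpha
#' region with DDxxD upstream at an in-window spacing, `ABERRANT` when only
#' aberrant variants (DDxxx(D/E), NGxxSxxxE) or an out-of-window canonical
#' pair occur, else `ABSENT`.
#'
#' @seealso [classifyMotifStatus()]
#' @exportClass MotifStatus
setClass("MotifStatus", slots = c(
  classI = "character",
  classII = "character",
  hits = "DFrame"
))

setMethod("show", "MotifStatus", function(object) {
  cat(sprintf("MotifStatus: classII %s, classI %s (%d supporting hits)\n",
              object@classII, object@classI, nrow(object@hits)))
})

#' Active-site residue profile
#'
#' Positions (1-based, query coordinates) of the Class II catalytic
#' histidine-asparagine dyad (inside LHS / PNV contexts) and of the Class I
#' plant-type key isoleucine (inside PIx) together with the bacterial-type
#' position one helical turn (4 residues) before it. `NA` marks a site absent
#' from the query (gapped in the alignment to the annotated reference).
#'
#' @seealso [locateSites()], [predictProduct()]
#' @exportClass ActiveSiteProfile
setClass("ActiveSiteProfile", slots = c(
  positions = "integer",
  residues = "character",
  context_ok = "logical"
))

setValidity("ActiveSiteProfile", function(object) {
  roles <- c("dyad_his", "dyad_asn", "ile_bact", "ile_plant")
  if (!identical(names(object@positions), roles))
    return("positions must be named dyad_his, dyad_asn, ile_bact, ile_plant")
  p <- object@positions
  if (!is.na(p["ile_bact"]) && !is.na(p["ile_plant"]) &&
      p["ile_bact"] != p["ile_plant"] - 4L)
    return("bacterial-type position must be plant-type position - 4")
  TRUE
})

setMethod("show", "ActiveSiteProfile", function(object) {
  cat("ActiveSiteProfile\n")
  for (r in names(object@positions)) {
    cat(sprintf("  %-9s %s%s %s\n", r,
                ifelse(is.na(object@residues[r]), "-", object@residues[r]),
                ifelse(is.na(object@positions[r]), "",
                       object@positions[r]),
                ifelse(isTRUE(object@context_ok[r]), "",
                       "(context_mismatch)")))
  }
})

#' Screen report
#'
#' Result container of [runScreen()]: the per-stage funnel counts, prevalence
#' summaries, per-protein architecture calls, the TS / DTC datasets and their
#' intersection (the fusion-candidate pool), the candidate table, split
#' constructs, optional neighbor-joining trees of the alpha and didomain
#' parts, and paths of emitted artifacts.
#'
#' @seealso [runScreen()], [funnelCounts()], [candidateTable()]
#' @exportClass ScreenReport
setClass("ScreenReport", slots = c(
  funnel = "integer",
  prevalence = "character",
  calls = "DFrame",
  datasets = "list",
  candidates = "DFrame",
  splits = "list",
  trees = "list",
  lineage = "DataFrameOrNULL",
  paths = "character"
))

setMethod("show", "ScreenReport", function(object) {
  cat("ScreenReport\n")
  f <- object@funnel
  for (k in names(f)) cat(sprintf("  %-22s %d\n", k, f[k]))
  if (length(object@prevalence))
    cat("  DCS species prevalence:", object@prevalence, "\n")
})

#' Accessors for ScreenReport
#'
#' `funnelCounts` returns the named per-stage counts of the screening funnel;
#' `candidateTable` the fusion-candidate table; `datasetIds` the TS set, DTC
#' set and their intersection; `screenCalls` the full per-protein call table.
#'
#' @param object A [ScreenReport-class] object.
#' @return See details above.
#' @export
setGeneric("funnelCounts", function(object) standardGeneric("funnelCounts"))

#' @rdname funnelCounts
#' @export
setGeneric("candidateTable", function(object) standardGeneric("candidateTable"))

#' @rdname funnelCounts
#' @export
setGeneric("datasetIds", function(object) standardGeneric("datasetIds"))

#' @rdname funnelCounts
#' @export
setGeneric("screenCalls", function(object) standardGeneric("screenCalls"))

#' @rdname funnelCounts
setMethod("funnelCounts", "ScreenReport", function(object) object@funnel)

#' @rdname funnelCounts
setMethod("candidateTable", "ScreenReport", function(object) object@candidates)

#' @rdname funnelCounts
setMethod("datasetIds", "ScreenReport", function(object) object@datasets)

#' @rdname funnelCounts
setMethod("screenCalls", "ScreenReport", function(object) object@calls)
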