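# Active-site residue mapping by annotation transfer, and the product-outcome
# rule table for the CPS-KS (ent-kaurene) lineage of fused cyclase/synthases.

#' Annotated synthetic CPS-KS-like reference
#'
#' A synthetic full-length fusion built from the packaged templates (didomain
#' + 10-residue linker + alpha domain, template identity 1) whose annotated
#' active-site positions reproduce the numbering of the characterized
#' cyanobacterial CPS-KS: catalytic dyad His 187 (LHS context) and Asn 253
#' (PNV context) in the gamma domain, and the Class I key isoleucines at 726
#' (bacterial-type position, one helical turn before) and 730 (plant-type,
#' PIx context) in the alpha domain. This is a synthetic stand-in
#' constructed in code, not a deposited sequence; the same record ships as
#' `inst/extdata/csedcs_like_synthetic.fasta` with a sidecar TSV of the
#' annotations.
#'
#' @return `list(sequence = named character scalar, annotations = DataFrame
#'   with columns role, position, residue, context_motif)`.
#' @export
annotatedReference <- function() {
  linker <- "GSGSGSGSGS"
  s <- paste0(GB_TEMPLATE, linker, ALPHA_TEMPLATE)
  off <- nchar(GB_TEMPLATE) + nchar(linker)
  info <- .TEMPLATE_INFO
  ann <- S4Vectors::DataFrame(
    role = c("dyad_his", "dyad_asn", "ile_bact", "ile_plant"),
    position = c(info$gb$dyad_his, info$gb$dyad_asn,
                 off + info$alpha$ile_bact, off + info$alpha$ile_plant),
    residue = c("H", "N", "I", "I"),
    context_motif = c("LHS", "PNV", "PIx-4", "PIx"))
  list(sequence = c(CPSKS_REF_SYNTHETIC = s), annotations = ann)
}

.SITE_ROLES <- c("dyad_his", "dyad_asn", "ile_bact", "ile_plant")

#' Locate active-site residues by annotation transfer
#'
#' Globally aligns the query to an annotated reference and maps each
#' annotated reference position onto the query. A site whose reference
#' column is deleted in the query is reported absent (`NA`). Local context
#' is verified around each mapped site (dyad His inside an LHS match, Asn
#' inside PNV, plant-type Ile inside PIx, bacterial-type position exactly
#' four residues before the plant-type one); failures are flagged
#' `context_mismatch` rather than dropped.
#'
#' @param query Query sequence (named character scalar or length-1 set).
#' @param reference Result of [annotatedReference()] or a compatible
#'   `list(sequence, annotations)`.
#' @param submat,gap_open,gap_extend Alignment scoring, as in
#'   [pairwiseAlign()].
#' @return An [ActiveSiteProfile-class].
#' @export
locateSites <- function(query, reference = annotatedReference(),
                        submat = blosum62(), gap_open = 10,
                        gap_extend = 0.5) {
  ann <- reference$annotations
  if (is.null(ann) || !all(.SITE_ROLES %in% ann$role))
    stop("reference lacks the required active-site annotations")
  q <- .single_seq(query)
  pa <- pairwiseAlign(c(q = q), reference$sequence, submat = submat,
                      gap_open = gap_open, gap_extend = gap_extend)
  rows <- as.character(pa$alignment)
  qa <- strsplit(rows[1], "")[[1]]
  ra <- strsplit(rows[2], "")[[1]]
  # reference position -> query position (NA where the query is gapped)
  rpos <- cumsum(ra != "-")
  qpos <- cumsum(qa != "-")
  map <- rep(NA_integer_, nchar(reference$sequence[[1]]))
  filled <- ra != "-" & qa != "-"
  map[rpos[filled]] <- qpos[filled]
  positions <- stats::setNames(rep(NA_integer_, 4L), .SITE_ROLES)
  residues <- stats::setNames(rep(NA_character_, 4L), .SITE_ROLES)
  context <- stats::setNames(rep(NA, 4L), .SITE_ROLES)
  for (r in .SITE_ROLES) {
    refp <- ann$position[ann$role == r]
    p <- map[refp]
    if (is.na(p)) next
    positions[r] <- p
    residues[r] <- substr(q, p, p)
  }
  has <- function(r) !is.na(positions[r])
  at <- function(p) if (p >= 1 && p <= nchar(q)) substr(q, p, p) else ""
  if (has("dyad_his"))
    context["dyad_his"] <- at(positions["dyad_his"] - 1L) == "L" &&
      at(positions["dyad_his"] + 1L) == "S"
  if (has("dyad_asn"))
    context["dyad_asn"] <- at(positions["dyad_asn"] - 1L) == "P" &&
      at(positions["dyad_asn"] + 1L) == "V"
  if (has("ile_plant"))
    context["ile_plant"] <- at(positions["ile_plant"] - 1L) == "P"
  if (has("ile_bact"))
    context["ile_bact"] <- has("ile_plant") &&
      positions["ile_bact"] == positions["ile_plant"] - 4L
  methods::new("ActiveSiteProfile", positions = positions,
               residues = residues, context_ok = context)
}

# classify a set of applied mutations against the profile's anchored sites
.mutation_states <- function(profile, motif_status, mutations) {
  st <- c(knockout = FALSE, his = FALSE, asn = FALSE, ile_bact = FALSE,
          ile_plant = FALSE, other = FALSE)
  if (is.null(mutations) || !NROW(mutations)) return(st)
  mutations <- S4Vectors::DataFrame(mutations)
  dd <- motif_status@hits
  dd_start <- dd$start[dd$motif_name == "DDxxD"]
  for (i in seq_len(nrow(mutations))) {
    pos <- mutations$position[i]
    to <- mutations$to[i]
    p <- profile@positions
    if (length(dd_start) && pos == dd_start[1] && to == "A")
      st["knockout"] <- TRUE
    else if (!is.na(p["dyad_his"]) && pos == p["dyad_his"] && to == "A")
      st["his"] <- TRUE
    else if (!is.na(p["dyad_asn"]) && pos == p["dyad_asn"] && to == "A")
      st["asn"] <- TRUE
    else if (!is.na(p["ile_bact"]) && pos == p["ile_bact"] && to == "T")
      st["ile_bact"] <- TRUE
    else if (!is.na(p["ile_plant"]) && pos == p["ile_plant"] && to == "T")
      st["ile_plant"] <- TRUE
    else st["other"] <- TRUE
  }
  st
}

#' Predict product outcome of wild type and anchored mutants
#'
#' Applies the shipped rule table for the CPS-KS lineage top-down; the rules
#' encode observed product outcomes (major product first), not a mechanistic
#' model, and the table is defined only for Class II-intact proteins.
#' Rules: wild type with intact Class I motifs gives ent-kaurene; a Class I
#' knockout (first aspartate of DDxxD to alanine) alone stalls at the Class
#' II product ent-CPP; dyad His-to-Ala alone gives ent-13-epi-manoyl oxide,
#' dyad Asn-to-Ala the same with residual ent-kaurene; a dyad substitution
#' combined with the Class I knockout yields ent-LPP; threonine at the
#' bacterial-type key position switches the outcome to
#' ent-pimara-8(14),15-diene, and at the plant-type isoleucine to
#' 8a-hydroxy-ent-pimar-15-ene with residual ent-kaurene. Inputs matched by
#' no rule return `"none"` with `no_rule = TRUE`.
#'
#' @param profile An [ActiveSiteProfile-class] from [locateSites()].
#' @param motif_status A [MotifStatus-class] for the same protein; must be
#'   Class II-intact.
#' @param mutations `NULL` (wild type) or mutation metadata with columns
#'   `position` and `to` (e.g. rbound `mcols` of [applyMutation()] results).
#' @return `list(products = ordered character vector, rule = integer or NA,
#'   no_rule = logical)`.
#' @export
predictProduct <- function(profile, motif_status, mutations = NULL) {
  stopifnot(methods::is(profile, "ActiveSiteProfile"),
            methods::is(motif_status, "MotifStatus"))
  if (motif_status@classII != "INTACT")
    stop("product rules are defined only for Class II-intact proteins")
  st <- .mutation_states(profile, motif_status, mutations)
  none_of <- function(...) !any(st[c(...)])
  rule <- NA_integer_
  products <- "none"
  if (!any(st) && motif_status@classI == "INTACT") {
    rule <- 1L; products <- "ent-kaurene"
  } else if (st["knockout"] && none_of("his", "asn", "ile_bact",
                                       "ile_plant", "other")) {
    rule <- 2L; products <- "ent-CPP"
  } else if (st["his"] && none_of("knockout", "asn", "ile_bact",
                                  "ile_plant", "other") &&
             motif_status@classI == "INTACT") {
    rule <- 3L; products <- "ent-13-epi-manoyl oxide"
  } else if (st["asn"] && none_of("knockout", "his", "ile_bact",
                                  "ile_plant", "other") &&
             motif_status@classI == "INTACT") {
    rule <- 4L; products <- c("ent-13-epi-manoyl oxide", "ent-kaurene")
  } else if (st["knockout"] && xor(st["his"], st["asn"]) &&
             none_of("ile_bact", "ile_plant", "other")) {
    rule <- 5L; products <- "ent-LPP"
  } else if (st["ile_bact"] && none_of("knockout", "his", "asn",
                                       "ile_plant", "other")) {
    rule <- 6L; products <- "ent-pimara-8(14),15-diene"
  } else if (st["ile_plant"] && none_of("knockout", "his", "asn",
                                        "ile_bact", "other")) {
    rule <- 7L; products <- c("8a-hydroxy-ent-pimar-15-ene", "ent-kaurene")
  }
  list(products = products, rule = rule, no_rule = is.na(rule))
}
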