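# Synthetic-proteome generator: plants the six architecture classes the
# screen must distinguish (intact and aberrant gamma-beta-alpha fusions,
# alpha-only TSs, didomain-only DTCs, SHC-like decoys, background) and
# records ground truth for recovery evaluation.

# uniform draw from an inclusive integer range (safe for degenerate ranges)
.sample_range <- function(range) {
  range[1] + sample.int(range[2] - range[1] + 1L, 1L) - 1L
}

.mutate_template <- function(template, identity, locked) {
  sv <- strsplit(template, "")[[1]]
  idx <- setdiff(seq_along(sv), locked)
  if (identity < 1 && length(idx)) {
    hit <- idx[stats::runif(length(idx)) < (1 - identity)]
    for (i in hit) sv[i] <- sample(setdiff(.AA20, sv[i]), 1L)
  }
  paste(sv, collapse = "")
}

.stamp <- function(template, at, txt) {
  paste0(substr(template, 1L, at - 1L), txt,
         substr(template, at + nchar(txt), nchar(template)))
}

.alpha_variant <- function(aberrant) {
  s <- ALPHA_TEMPLATE
  if (aberrant)
    for (st in .TEMPLATE_INFO$alpha$aberrant) s <- .stamp(s, st$at, st$txt)
  s
}

#' Generate a labeled synthetic proteome
#'
#' Emits one protein per planted instance: fusions are a didomain-template
#' instance, a random linker and an alpha-template instance (gamma-beta
#' strictly before alpha); aberrant fusions carry DDxxx(D/E) in place of
#' DDxxD and NGxxSxxxE in place of NSE; decoys derive from the
#' SHC-like template; background proteins are uniform over the 20 residues.
#' Template instances are mutated at non-motif positions to the requested
#' identity, so planted motif positions always rescan. Deterministic given
#' the seed in `spec`.
#'
#' @param spec A [SyntheticSpec-class].
#' @return `list(proteins = AAStringSet, truth = DataFrame)`. `truth` has one
#'   row per protein: `protein_id`, `true_class`, `species`, the planted
#'   domain intervals (`gb_start`/`gb_end`, `alpha_start`/`alpha_end`, `NA`
#'   when absent) and planted motif start positions (`dxdd`, `lhs`, `pnv`,
#'   `ddxxd`, `nse`, `aberrant_dd`, `nse_variant`).
#' @examples
#' sim <- generateProteome(SyntheticSpec(counts = c(DCS_INTACT = 1L)))
#' width(sim$proteins)
#' @export
generateProteome <- function(spec) {
  stopifnot(methods::is(spec, "SyntheticSpec"))
  methods::validObject(spec)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec@seed)

  info <- .TEMPLATE_INFO
  id <- spec@template_identity
  seqs <- character(0)
  truth <- list()
  tags <- c(DCS_INTACT = "DCSI", DCS_ABERRANT = "DCSA", TS_ONLY = "TS",
            DTC_ONLY = "DTC", SHC_DECOY = "SHC", BACKGROUND = "BG")

  # alpha domains of intact fusions descend from one shared proteome-level
  # ancestor (itself a template instance), so they carry common derived
  # states and cluster together among alpha sequences; didomain parts and
  # aberrant fusions draw straight from the templates and do not.
  alpha_intact_ancestor <- .mutate_template(ALPHA_TEMPLATE, id,
                                            info$alpha$locked)

  blank <- function(pid, cls) {
    list(protein_id = pid, true_class = cls,
         species = paste0("sp_", tolower(pid)),
         gb_start = NA_integer_, gb_end = NA_integer_,
         alpha_start = NA_integer_, alpha_end = NA_integer_,
         dxdd = NA_integer_, lhs = NA_integer_, pnv = NA_integer_,
         ddxxd = NA_integer_, nse = NA_integer_,
         aberrant_dd = NA_integer_, nse_variant = NA_integer_)
  }

  for (cls in .SYNTH_CLASSES) {
    for (i in seq_len(spec@counts[[cls]])) {
      pid <- sprintf("%s_%02d", tags[[cls]], i)
      tr <- blank(pid, cls)
      if (cls %in% c("DCS_INTACT", "DCS_ABERRANT")) {
        gb <- .mutate_template(GB_TEMPLATE, id, info$gb$locked)
        ll <- .sample_range(spec@linker_length_range)
        linker <- paste(sample(.AA20, ll, replace = TRUE), collapse = "")
        al <- .mutate_template(
          if (cls == "DCS_INTACT") alpha_intact_ancestor
          else .alpha_variant(TRUE), id, info$alpha$locked)
        s <- paste0(gb, linker, al)
        a0 <- nchar(gb) + ll  # alpha part starts at a0 + 1
        tr$gb_start <- 1L; tr$gb_end <- nchar(gb)
        tr$alpha_start <- a0 + 1L; tr$alpha_end <- nchar(s)
        tr$dxdd <- info$gb$dxdd; tr$lhs <- info$gb$lhs; tr$pnv <- info$gb$pnv
        if (cls == "DCS_INTACT") {
          tr$ddxxd <- a0 + info$alpha$ddxxd
          tr$nse <- a0 + info$alpha$nse
        } else {
          tr$aberrant_dd <- a0 + info$alpha$ddxxd
          tr$nse_variant <- a0 + info$alpha$nse
        }
      } else if (cls == "TS_ONLY") {
        s <- .mutate_template(ALPHA_TEMPLATE, id, info$alpha$locked)
        tr$alpha_start <- 1L; tr$alpha_end <- nchar(s)
        tr$ddxxd <- info$alpha$ddxxd; tr$nse <- info$alpha$nse
      } else if (cls == "DTC_ONLY") {
        s <- .mutate_template(GB_TEMPLATE, id, info$gb$locked)
        tr$gb_start <- 1L; tr$gb_end <- nchar(s)
        tr$dxdd <- info$gb$dxdd; tr$lhs <- info$gb$lhs; tr$pnv <- info$gb$pnv
      } else if (cls == "SHC_DECOY") {
        s <- .mutate_template(SHC_TEMPLATE, id, info$shc$locked)
        tr$gb_start <- 1L; tr$gb_end <- nchar(s)
        tr$dxdd <- info$shc$dxdd
      } else {
        len <- .sample_range(spec@background_length_range)
        s <- paste(sample(.AA20, len, replace = TRUE), collapse = "")
      }
      seqs[pid] <- s
      truth[[pid]] <- tr
    }
  }

  if (!length(seqs)) {
    proteins <- Biostrings::AAStringSet()
    S4Vectors::mcols(proteins) <- S4Vectors::DataFrame(
      species = character(0), description = character(0))
    return(list(proteins = proteins,
                truth = S4Vectors::DataFrame(
                  protein_id = character(0), true_class = character(0),
                  species = character(0))))
  }
  proteins <- Biostrings::AAStringSet(seqs)
  truth_df <- do.call(rbind, lapply(truth, function(tr)
    S4Vectors::DataFrame(tr)))
  rownames(truth_df) <- NULL
  S4Vectors::mcols(proteins) <- S4Vectors::DataFrame(
    species = truth_df$species,
    description = paste0("species=", truth_df$species))
  list(proteins = proteins, truth = truth_df)
}

#' Write a synthetic proteome and its truth table
#'
#' @param sim Result of [generateProteome()].
#' @param dir Output directory (created if needed).
#' @return Paths of the FASTA and truth TSV, invisibly.
#' @export
writeSyntheticProteome <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fa <- file.path(dir, "synthetic_proteome.fasta")
  tsv <- file.path(dir, "synthetic_truth.tsv")
  writeProteinFasta(sim$proteins, fa)
  writeTsv(sim$truth, tsv)
  invisible(c(fasta = fa, truth = tsv))
}

#' Evaluate screen calls against planted truth
#'
#' Computes per-class sensitivity and precision for the fusion-candidate,
#' alpha-only and didomain-only calls plus a full confusion table. Planted
#' `DCS_INTACT` and `DCS_ABERRANT` proteins are both expected to be called
#' `DCS_CANDIDATE`; decoys `SHC_LIKE`; background `NONE`.
#'
#' @param calls A table with columns `protein_id` and `call` (for example
#'   `screenCalls(report)`).
#' @param truth The truth table from [generateProteome()].
#' @return `list(metrics, confusion)`: `metrics` is a DataFrame with columns
#'   `class`, `tp`, `fn`, `fp`, `sensitivity`, `precision` (precision `NA`
#'   when nothing was called); `confusion` a true-class x call count table.
#' @export
evaluateScreen <- function(calls, truth) {
  calls <- as.data.frame(calls)
  truth <- as.data.frame(truth)
  miss <- setdiff(truth$protein_id, calls$protein_id)
  extra <- setdiff(calls$protein_id, truth$protein_id)
  if (length(miss) || length(extra))
    stop("protein id universes differ; missing from calls: [",
         paste(miss, collapse = ", "), "]; absent from truth: [",
         paste(extra, collapse = ", "), "]")
  expected <- c(DCS_INTACT = "DCS_CANDIDATE", DCS_ABERRANT = "DCS_CANDIDATE",
                TS_ONLY = "TS_ONLY", DTC_ONLY = "DTC_ONLY",
                SHC_DECOY = "SHC_LIKE", BACKGROUND = "NONE")
  truth$expected <- unname(expected[truth$true_class])
  m <- merge(truth[, c("protein_id", "true_class", "expected")],
             calls[, c("protein_id", "call")], by = "protein_id")
  metrics <- do.call(rbind, lapply(
    c("DCS_CANDIDATE", "TS_ONLY", "DTC_ONLY"), function(cls) {
      pos <- m$expected == cls
      called <- m$call == cls
      tp <- sum(pos & called)
      data.frame(class = cls, tp = tp, fn = sum(pos & !called),
                 fp = sum(!pos & called),
                 sensitivity = if (sum(pos)) tp / sum(pos) else NA_real_,
                 precision = if (sum(called)) tp / sum(called) else NA_real_)
    }))
  list(metrics = S4Vectors::DataFrame(metrics),
       confusion = table(true_class = m$true_class, call = m$call))
}
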