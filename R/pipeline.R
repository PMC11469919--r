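# Orchestration: proteomes -> hits -> datasets -> intersection -> motifs ->
# calls -> splits -> trees -> report, plus lineage tabulation and prevalence
# arithmetic.

#' Run the full intersection screen
#'
#' Executes, in order: domain detection (either ingesting an external HMMER
#' per-domain table or running the internal profile scan), dataset assembly
#' and intersection, per-protein motif scanning and classification (using
#' detected domain intervals as motif regions), architecture calls, splits
#' of every fusion candidate, and (optionally) neighbor-joining trees of all
#' alpha parts and all didomain parts — the split-and-compare dataset
#' treatments used to place fusion domains among their single-domain
#' relatives. Every stage logs one structured line
#' (`stage in=... out=... dropped=...`) via `message()`.
#'
#' @param proteins Proteome FASTA path(s), or an [Biostrings::AAStringSet]
#'   from [readProteinFasta()] / [generateProteome()].
#' @param hits Optional external evidence: a domtblout path or a row table
#'   from [readDomtblout()]. Mutually exclusive with the internal scan
#'   (`internal = TRUE`).
#' @param config A [ScreenConfig-class].
#' @param lineage_map Optional species-to-lineage map (named character
#'   vector or data.frame with columns `species`, `lineage`) for the
#'   lineage table.
#' @param internal Use the internal profile scanner (default: `TRUE` when
#'   `hits` is `NULL`).
#' @param trees Build NJ trees of the alpha and didomain parts (default
#'   TRUE; needs >= 3 members in a part set).
#' @param out_dir Optional directory; when given, report TSVs, candidate
#'   FASTAs and Newick trees are written there.
#' @param seed Seed forwarded to any stochastic stage (reserved; the screen
#'   itself is deterministic).
#' @return A [ScreenReport-class].
#' @examples
#' sim <- generateProteome(SyntheticSpec(counts = c(DCS_INTACT = 2L,
#'                                                  TS_ONLY = 3L)))
#' rep <- runScreen(sim$proteins, trees = FALSE)
#' funnelCounts(rep)
#' @export
runScreen <- function(proteins, hits = NULL, config = ScreenConfig(),
                      lineage_map = NULL, internal = is.null(hits),
                      trees = TRUE, out_dir = NULL, seed = 1L) {
  if (is.character(proteins)) {
    sets <- lapply(proteins, readProteinFasta)
    proteins <- do.call(c, sets)
    if (anyDuplicated(names(proteins)))
      stop("duplicate protein ids across proteome files")
  }
  proteins <- .as_aastringset(proteins)
  if (!length(proteins)) stop("no proteins parsed")
  if (!is.null(hits) && internal)
    stop("supply external hits or enable internal scanning, not both")
  species <- .meta_col(proteins, "species")
  n_species <- length(unique(species[nzchar(species)]))
  if (!n_species) { species <- names(proteins); n_species <- length(proteins) }
  message(sprintf("stage=input in=%d out=%d dropped=0 species=%d",
                  length(proteins), length(proteins), n_species))

  if (!is.null(hits)) {
    rows <- if (is.character(hits)) readDomtblout(hits) else
      S4Vectors::DataFrame(hits)
    unknown <- setdiff(unique(rows$target_id), names(proteins))
    if (length(unknown))
      stop("hits refer to protein(s) absent from the proteome: ",
           paste(unknown, collapse = ", "))
    hit_df <- hitsFromRows(rows, config)
    # external evidence carries no SHC profile: apply the relatedness filter
    gb_ids <- unique(hit_df$protein_id[hit_df$class == "GB_DTC"])
    shc_ids <- gb_ids[vapply(gb_ids, function(pid) {
      r <- hit_df[hit_df$protein_id == pid & hit_df$class == "GB_DTC", ][1, ]
      reg <- substr(as.character(proteins[[pid]]), r$start, r$end)
      closerToGroup(reg, c(ref = GB_TEMPLATE),
                    c(ref = SHC_TEMPLATE)) == "SHC_LIKE"
    }, TRUE)]
  } else {
    hit_df <- scanInternal(proteins, config = config)
    shc_ids <- .shc_flagged(hit_df)
  }
  message(sprintf("stage=detection in=%d out=%d dropped=%d",
                  length(proteins), nrow(hit_df),
                  length(proteins) - length(unique(hit_df$protein_id))))

  ds <- buildDatasets(hit_df, shc_ids = shc_ids)
  message(sprintf("stage=datasets in=%d out=%d dropped=%d ts=%d dtc=%d overlap=%d",
                  nrow(hit_df), length(ds$ts_set) + length(ds$dtc_set),
                  length(shc_ids), length(ds$ts_set), length(ds$dtc_set),
                  length(ds$overlap)))

  calls <- NULL
  statuses <- list()
  for (i in seq_along(proteins)) {
    pid <- names(proteins)[i]
    s <- as.character(proteins[[i]])
    h <- hit_df[hit_df$protein_id == pid, , drop = FALSE]
    gb <- h[h$class == "GB_DTC", , drop = FALSE]
    al <- h[h$class == "ALPHA_TS", , drop = FALSE]
    regions <- list(
      gb = if (nrow(gb)) c(min(gb$start), max(gb$end)),
      alpha = if (nrow(al)) c(min(al$start), max(al$end)))
    if (!nrow(gb) && !nrow(al)) regions <- NULL
    mh <- scanMotifs(s, builtinMotifs(), region_intervals = regions)
    st <- classifyMotifStatus(mh, spacing = config@class1_spacing)
    statuses[[pid]] <- st
    row <- callArchitecture(pid, nchar(s), h, st,
                            shc_flagged = pid %in% shc_ids,
                            min_total_length = config@min_total_length)
    calls <- if (is.null(calls)) row else rbind(calls, row)
  }
  calls$species <- species
  message(sprintf("stage=calls in=%d out=%d dropped=0 candidates=%d",
                  length(proteins), nrow(calls),
                  sum(calls$call == "DCS_CANDIDATE")))

  cand <- calls[calls$call == "DCS_CANDIDATE", , drop = FALSE]
  splits <- list()
  for (i in seq_len(nrow(cand))) {
    pid <- cand$protein_id[i]
    splits[[pid]] <- splitDcs(proteins[pid], cand[i, ], "GB_END")
  }

  tree_list <- list()
  if (trees) {
    alpha_parts <- c(
      lapply(splits, function(sp) as.character(sp)[[2]]),
      as.list(stats::setNames(
        as.character(proteins[calls$protein_id[calls$call == "TS_ONLY"]]),
        calls$protein_id[calls$call == "TS_ONLY"])))
    gb_parts <- c(
      lapply(splits, function(sp) as.character(sp)[[1]]),
      as.list(stats::setNames(
        as.character(proteins[calls$protein_id[calls$call == "DTC_ONLY"]]),
        calls$protein_id[calls$call == "DTC_ONLY"])))
    for (nm in c("alpha", "gb")) {
      parts <- if (nm == "alpha") alpha_parts else gb_parts
      if (length(parts) >= 3L) {
        aln <- progressiveMsa(unlist(parts))
        tree_list[[nm]] <- neighborJoining(poissonDistance(aln))
      }
    }
    message(sprintf("stage=trees in=%d out=%d dropped=0",
                    length(alpha_parts) + length(gb_parts),
                    length(tree_list)))
  }

  funnel <- c(
    species_in = n_species,
    proteins_in = length(proteins),
    ts_genes = length(ds$ts_set),
    dtc_genes = length(ds$dtc_set),
    shc_removed = length(shc_ids),
    ts_only = sum(calls$call == "TS_ONLY"),
    dtc_only = sum(calls$call == "DTC_ONLY"),
    dcs_candidates = sum(calls$call == "DCS_CANDIDATE"),
    dcs_atypical = sum(calls$call == "DCS_ATYPICAL_ORDER"),
    predicted_bifunctional = sum(calls$predicted_bifunctional))
  hit_species <- unique(calls$species[calls$call == "DCS_CANDIDATE"])
  prevalence <- summarizePrevalence(length(hit_species), n_species)

  lineage <- if (!is.null(lineage_map)) tabulateLineages(calls, lineage_map)

  paths <- character(0)
  report <- methods::new("ScreenReport", funnel = funnel,
                         prevalence = prevalence, calls = calls,
                         datasets = ds, candidates = cand, splits = splits,
                         trees = tree_list, lineage = lineage, paths = paths)
  if (!is.null(out_dir)) report <- writeScreenReport(report, out_dir)
  report
}

#' Write report artifacts
#'
#' Emits the call table, candidate table, funnel counts and (if present)
#' lineage table as TSV, split constructs as FASTA, and trees as Newick
#' under `dir`. Output is byte-deterministic given identical inputs.
#'
#' @param report A [ScreenReport-class].
#' @param dir Output directory (created if needed).
#' @return The report with `@paths` filled in.
#' @export
writeScreenReport <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(calls = file.path(dir, "calls.tsv"),
             candidates = file.path(dir, "candidates.tsv"),
             funnel = file.path(dir, "funnel.tsv"))
  writeTsv(report@calls, paths[["calls"]])
  writeTsv(report@candidates, paths[["candidates"]])
  writeTsv(data.frame(stage = names(report@funnel),
                      count = unname(report@funnel)), paths[["funnel"]])
  if (!is.null(report@lineage)) {
    paths[["lineage"]] <- file.path(dir, "lineage.tsv")
    writeTsv(report@lineage, paths[["lineage"]])
  }
  if (length(report@splits)) {
    paths[["constructs"]] <- file.path(dir, "constructs.fasta")
    writeProteinFasta(do.call(c, unname(report@splits)),
                      paths[["constructs"]])
  }
  for (nm in names(report@trees)) {
    key <- paste0("tree_", nm)
    paths[[key]] <- file.path(dir, paste0(nm, "_parts.nwk"))
    writeNewickTree(report@trees[[nm]], paths[[key]])
  }
  report@paths <- paths
  report
}

#' Tabulate screen results by lineage
#'
#' Per lineage: number of species carrying at least one fusion candidate, at
#' least one alpha-domain-containing gene (fusions included), at least one
#' didomain-containing gene (fusions included), and total species. Species
#' missing from the map fall into lineage `"unassigned"`; species present in
#' the map but absent from the calls still count toward totals.
#'
#' @param calls Call table with `species` column (see [screenCalls()]).
#' @param lineage_map Named character vector (species -> lineage) or a
#'   data.frame with columns `species` and `lineage`.
#' @return [S4Vectors::DataFrame] with columns `lineage`, `n_DCS`,
#'   `n_TS_species`, `n_DTC_species`, `n_species`.
#' @export
tabulateLineages <- function(calls, lineage_map) {
  calls <- as.data.frame(calls)
  if (is.data.frame(lineage_map))
    lineage_map <- stats::setNames(lineage_map$lineage, lineage_map$species)
  all_species <- union(names(lineage_map), unique(calls$species))
  lin <- lineage_map[all_species]
  lin[is.na(lin)] <- "unassigned"
  names(lin) <- all_species
  ts_calls <- c("TS_ONLY", "DCS_CANDIDATE", "DCS_ATYPICAL_ORDER")
  dtc_calls <- c("DTC_ONLY", "DCS_CANDIDATE", "DCS_ATYPICAL_ORDER")
  rows <- lapply(sort(unique(lin)), function(l) {
    sp <- names(lin)[lin == l]
    sub <- calls[calls$species %in% sp, , drop = FALSE]
    S4Vectors::DataFrame(
      lineage = l,
      n_DCS = length(unique(sub$species[sub$call == "DCS_CANDIDATE"])),
      n_TS_species = length(unique(sub$species[sub$call %in% ts_calls])),
      n_DTC_species = length(unique(sub$species[sub$call %in% dtc_calls])),
      n_species = length(sp))
  })
  do.call(rbind, rows)
}

#' Prevalence percentage, report style
#'
#' Formats `100 * n_hit / n_total` rounded half-up to two decimals, with
#' trailing zeros trimmed for values of one percent or more (`10%`, `3%`)
#' and both decimals kept below one percent (`0.03%`).
#'
#' @param n_hit,n_total Species counts, `0 <= n_hit <= n_total`,
#'   `n_total > 0`.
#' @return Character scalar like `"0.03%"`.
#' @examples
#' summarizePrevalence(5, 15498)
#' @export
summarizePrevalence <- function(n_hit, n_total) {
  if (n_total <= 0) stop("n_total must be positive")
  if (n_hit < 0 || n_hit > n_total) stop("need 0 <= n_hit <= n_total")
  pct <- floor(100 * n_hit / n_total * 100 + 0.5) / 100  # round half-up
  s <- sprintf("%.2f", pct)
  if (pct >= 1) {
    s <- sub("0+$", "", s)   # always has a decimal point here
    s <- sub("\\.$", "", s)
  }
  paste0(s, "%")
}
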