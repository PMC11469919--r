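# Readers and writers for the external formats: protein FASTA, HMMER3
# per-domain tables (domtblout), Newick trees, TSV reports and YAML config.
# All coordinates are 1-based inclusive throughout the package.

#' Read a protein FASTA file
#'
#' Wraps [Biostrings::readAAStringSet()] with the validation the screen
#' needs: wrapped sequence lines are concatenated, lowercase residues are
#' upfolded, a single trailing stop (`*`) is stripped, and the species tag is
#' parsed from a configurable header token. The record id is the first
#' whitespace-delimited header token and must be unique; residues must come
#' from the 20 standard amino acids plus `X`.
#'
#' @param path Path to a (possibly CRLF) FASTA text file. An empty file
#'   yields an empty set.
#' @param species_token Header token introducing the species tag (default
#'   `"species="`); absent token gives an empty species.
#' @return An [Biostrings::AAStringSet] named by record id, with `mcols`
#'   columns `species` and `description`.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 species=S1", "MKT", "DIDD"), f)
#' readProteinFasta(f)
#' @export
readProteinFasta <- function(path, species_token = "species=") {
  stopifnot(file.exists(path))
  raw <- readLines(path, warn = FALSE)
  raw <- sub("\r$", "", raw)
  if (!length(raw) || !any(startsWith(raw, ">"))) {
    if (any(nzchar(trimws(raw))))
      stop("not a FASTA file (no '>' header): ", path)
    out <- Biostrings::AAStringSet()
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(species = character(0),
                                                  description = character(0))
    return(out)
  }
  tmp <- tempfile(fileext = ".fasta")
  on.exit(unlink(tmp))
  writeLines(raw, tmp)
  set <- Biostrings::readAAStringSet(tmp)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate record id: ", paste(unique(dup), collapse = ", "))
  seqs <- toupper(as.character(set))
  seqs <- sub("\\*$", "", seqs)
  ok <- paste(.AA21, collapse = "")
  for (i in seq_along(seqs)) {
    if (!nchar(seqs[i])) stop("empty sequence for record ", ids[i])
    bad <- regexpr(sprintf("[^%s]", ok), seqs[i])
    if (bad > 0)
      stop(sprintf("illegal residue '%s' at position %d of record %s",
                   substr(seqs[i], bad, bad), bad, ids[i]))
  }
  species <- vapply(desc, function(d) {
    m <- regmatches(d, regexpr(paste0(species_token, "\\S+"), d))
    if (length(m)) substring(m, nchar(species_token) + 1L) else ""
  }, "", USE.NAMES = FALSE)
  out <- Biostrings::AAStringSet(seqs)
  names(out) <- ids
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(species = species,
                                                description = desc)
  out
}

#' Write a protein FASTA file
#'
#' Inverse of [readProteinFasta()]: headers are `id description`, sequences
#' wrapped at `width` columns. Round-tripping preserves records exactly.
#'
#' @param x An [Biostrings::AAStringSet] (or named character vector), with
#'   optional `mcols` columns `species` / `description`.
#' @param path Output path.
#' @param width Line-wrap width (default 60).
#' @return `path`, invisibly.
#' @export
writeProteinFasta <- function(x, path, width = 60L) {
  x <- .as_aastringset(x)
  desc <- .meta_col(x, "description")
  headers <- ifelse(nzchar(desc), paste(names(x), desc), names(x))
  out <- character(0)
  seqs <- as.character(x)
  for (i in seq_along(seqs)) {
    s <- seqs[i]
    starts <- seq(1L, nchar(s), by = width)
    out <- c(out, paste0(">", headers[i]),
             substring(s, starts, pmin(starts + width - 1L, nchar(s))))
  }
  writeLines(out, path)
  invisible(path)
}

#' Default Pfam profile-to-domain-class map
#'
#' Maps the alpha-domain profiles (PF03936, PF19086, PF06330) to `ALPHA_TS`
#' and the squalene-hopene-cyclase C-/N-terminal domain profiles (PF13243,
#' PF13249) to `GB_CTERM` / `GB_NTERM`; both flavors of didomain evidence
#' must co-occur on a protein before a didomain hit is emitted.
#'
#' @param config A [ScreenConfig-class] supplying the profile id sets.
#' @return Named character vector, accession -> domain class.
#' @export
defaultProfileMap <- function(config = ScreenConfig()) {
  map <- c(stats::setNames(rep("ALPHA_TS", length(config@alpha_profile_ids)),
                           config@alpha_profile_ids),
           stats::setNames(c("GB_CTERM", "GB_NTERM"),
                           c("PF13243", "PF13249")))
  extra <- setdiff(config@gb_profile_ids, names(map))
  if (length(extra)) map[extra] <- "GB_CTERM"
  map
}

# documented HMMER3 per-domain table layout (22 fixed columns + description)
.DOMTBL_MIN_COLS <- 22L

#' Read an HMMER3 per-domain table (domtblout)
#'
#' Parses the whitespace-delimited per-domain output of `hmmsearch
#' --domtblout`: one row per reported domain, using the envelope coordinate
#' columns. Profile accessions have any version suffix (e.g. `.8`) stripped
#' before lookup in `profile_map`; rows whose accession is unmapped are
#' dropped and the dropped count reported via `message()`.
#'
#' @param path Path to the table; `#` lines are comments.
#' @param profile_map Named character vector mapping profile accession to a
#'   domain class, see [defaultProfileMap()].
#' @return A [S4Vectors::DataFrame] with columns `target_id`,
#'   `query_profile_id`, `domain_class`, `full_seq_evalue`, `domain_ievalue`,
#'   `env_start`, `env_end`.
#' @export
readDomtblout <- function(path, profile_map = defaultProfileMap()) {
  stopifnot(file.exists(path))
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  rows <- which(keep)
  out <- vector("list", length(rows))
  for (k in seq_along(rows)) {
    i <- rows[k]
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < .DOMTBL_MIN_COLS)
      stop(sprintf("domtblout parse error at line %d: %d columns (expected >= %d)",
                   i, length(f), .DOMTBL_MIN_COLS))
    acc <- if (f[5] != "-") f[5] else f[4]
    acc <- sub("\\.\\d+$", "", acc)
    out[[k]] <- list(target_id = f[1], query_profile_id = acc,
                     full_seq_evalue = as.numeric(f[7]),
                     domain_ievalue = as.numeric(f[13]),
                     env_start = as.integer(f[20]),
                     env_end = as.integer(f[21]))
  }
  if (!length(out)) {
    return(S4Vectors::DataFrame(
      target_id = character(0), query_profile_id = character(0),
      domain_class = character(0), full_seq_evalue = numeric(0),
      domain_ievalue = numeric(0), env_start = integer(0),
      env_end = integer(0)))
  }
  df <- S4Vectors::DataFrame(
    target_id = vapply(out, `[[`, "", "target_id"),
    query_profile_id = vapply(out, `[[`, "", "query_profile_id"),
    full_seq_evalue = vapply(out, `[[`, 0, "full_seq_evalue"),
    domain_ievalue = vapply(out, `[[`, 0, "domain_ievalue"),
    env_start = vapply(out, `[[`, 0L, "env_start"),
    env_end = vapply(out, `[[`, 0L, "env_end"))
  if (any(df$env_start < 1L) || any(df$env_start > df$env_end))
    stop("invalid envelope coordinates (env_start must be in [1, env_end])")
  if (any(df$full_seq_evalue <= 0) || any(df$domain_ievalue <= 0))
    stop("e-values must be positive")
  mapped <- profile_map[df$query_profile_id]
  drop <- is.na(mapped)
  if (any(drop))
    message(sum(drop), " domtblout row(s) with unmapped profile dropped")
  df <- df[!drop, , drop = FALSE]
  df$domain_class <- unname(profile_map[df$query_profile_id])
  df[, c("target_id", "query_profile_id", "domain_class", "full_seq_evalue",
         "domain_ievalue", "env_start", "env_end")]
}

#' Write a tree in Newick format
#'
#' Serializes an unrooted tree (an [ape::phylo] object) as standard Newick
#' with branch lengths rounded to 6 significant digits and any integer
#' bootstrap supports carried as internal node labels; the string is
#' whitespace-free and `;`-terminated.
#'
#' @param tree An `ape::phylo` with unique, non-empty leaf labels.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeNewickTree <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  if (anyNA(tree$tip.label) || any(!nzchar(tree$tip.label)))
    stop("unnamed leaf: every tip must carry a non-empty label")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf labels")
  if (!is.null(tree$edge.length))
    tree$edge.length <- signif(tree$edge.length, 6)
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a Newick tree
#'
#' @param path Path to a Newick file.
#' @return An `ape::phylo` object.
#' @export
readNewickTree <- function(path) {
  stopifnot(file.exists(path))
  ape::read.tree(path)
}

#' Read/write tab-separated report tables
#'
#' All report tables are UTF-8 TSV with a header row and no quoting.
#'
#' @param df A data.frame-like table.
#' @param path File path.
#' @return `writeTsv` returns `path` invisibly; `readTsv` a `data.frame`.
#' @export
writeTsv <- function(df, path) {
  utils::write.table(as.data.frame(df), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname writeTsv
#' @export
readTsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

#' Read screen configuration from YAML
#'
#' Reads a config file with an optional `screen:` mapping (keys matching
#' [ScreenConfig()] arguments) and an optional `motifs:` list of
#' `name`/`pattern`/`region` entries appended to the built-in motif set.
#'
#' @param path Path to a YAML file.
#' @return `list(config = ScreenConfig, motifs = list of MotifDefinition)`.
#' @export
readScreenConfig <- function(path) {
  stopifnot(file.exists(path))
  y <- yaml::read_yaml(path)
  args <- y$screen
  if (is.null(args)) args <- list()
  config <- do.call(ScreenConfig, args)
  motifs <- builtinMotifs()
  for (m in y$motifs) {
    def <- compileMotif(m$pattern, name = m$name,
                        region = if (is.null(m$region)) "ANY" else m$region)
    motifs[[def@name]] <- def
  }
  list(config = config, motifs = motifs)
}

# ---- small shared helpers ----

.as_aastringset <- function(x) {
  if (is.character(x)) {
    if (is.null(names(x))) stop("sequences must be named")
    x <- Biostrings::AAStringSet(x)
  }
  stopifnot(methods::is(x, "AAStringSet"))
  x
}

.meta_col <- function(x, col) {
  mc <- S4Vectors::mcols(x)
  if (!is.null(mc) && col %in% colnames(mc)) as.character(mc[[col]])
  else rep("", length(x))
}
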