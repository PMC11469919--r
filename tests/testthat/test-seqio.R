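test_that("FASTA reading concatenates wrapped lines and parses species", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1 species=S1 extra note", "MKT", "DID", "D"), f)
  recs <- readProteinFasta(f)
  expect_equal(length(recs), 1L)
  expect_equal(names(recs), "p1")
  expect_equal(as.character(recs)[[1]], "MKTDIDD")
  expect_equal(S4Vectors::mcols(recs)$species, "S1")
})

test_that("FASTA reading upfolds case, strips a trailing stop, rejects bad input", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1", "mktd*"), f)
  expect_equal(as.character(readProteinFasta(f))[[1]], "MKTD")

  writeLines(c(">p1", "MKT", ">p1", "AAA"), f)
  expect_error(readProteinFasta(f), "duplicate.*p1")

  writeLines(c(">p1", "MKTJ"), f)
  expect_error(readProteinFasta(f), "illegal residue 'J' at position 4")

  # empty file is an empty set, not an error
  writeLines(character(0), f)
  expect_equal(length(readProteinFasta(f)), 0L)
})

test_that("FASTA round trip restores records exactly (LF and CRLF)", {
  set.seed(11)
  seqs <- setNames(vapply(c(5, 80, 133), rand_seq, ""), c("a1", "b2", "c3"))
  x <- Biostrings::AAStringSet(seqs)
  S4Vectors::mcols(x) <- S4Vectors::DataFrame(
    species = c("S1", "", "S3"),
    description = c("species=S1", "", "species=S3 strain x"))
  f <- withr::local_tempfile(fileext = ".fasta")
  writeProteinFasta(x, f)
  back <- readProteinFasta(f)
  expect_equal(as.character(back), as.character(x))
  expect_equal(S4Vectors::mcols(back)$species, S4Vectors::mcols(x)$species)

  # CRLF line endings are accepted
  crlf <- withr::local_tempfile(fileext = ".fasta")
  writeBin(charToRaw(paste0(paste(readLines(f), collapse = "\r\n"), "\r\n")),
           crlf)
  expect_equal(as.character(readProteinFasta(crlf)), as.character(x))
})

test_that("domtblout rows use envelope coordinates and drop unmapped profiles", {
  f <- withr::local_tempfile(fileext = ".tbl")
  writeLines(c("# comment", "#", domtbl_line("protA", "PF13243.8", 5e-20, 12, 350)), f)
  rows <- readDomtblout(f)
  expect_equal(nrow(rows), 1L)
  expect_equal(rows$query_profile_id, "PF13243")  # version suffix stripped
  expect_equal(rows$env_start, 12L)
  expect_equal(rows$env_end, 350L)
  expect_equal(rows$domain_ievalue, 5e-20)
  expect_true(all(rows$env_start <= rows$env_end))

  # comment-only file
  writeLines(c("# only", "# comments"), f)
  expect_equal(nrow(readDomtblout(f)), 0L)

  # unmapped profile dropped with a logged count
  writeLines(c(domtbl_line("protA", "PF99999.1", 1e-10, 5, 90),
               domtbl_line("protA", "PF03936.12", 1e-10, 5, 90)), f)
  expect_message(rows <- readDomtblout(f), "1.*unmapped")
  expect_equal(rows$query_profile_id, "PF03936")

  # truncated data line errors with the line number
  writeLines(c("# head", "protA - 900 too short"), f)
  expect_error(readDomtblout(f), "line 2")
})

test_that("Newick writing is canonical and round-trips", {
  two <- ape::read.tree(text = "(A:1,B:2);")
  f <- withr::local_tempfile(fileext = ".nwk")
  writeNewickTree(two, f)
  expect_equal(readLines(f), "(A:1,B:2);")

  set.seed(5)
  tr <- ape::rtree(6)
  # serialization carries 6 significant digits; lengths at that precision
  # round-trip losslessly
  tr$edge.length <- signif(tr$edge.length, 6)
  writeNewickTree(tr, f)
  back <- readNewickTree(f)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), ape::unroot(back))), 0)
  expect_lt(max(abs(ape::cophenetic.phylo(back)[tr$tip.label, tr$tip.label] -
                    ape::cophenetic.phylo(tr))), 1e-9)

  # support labels survive
  sup <- ape::read.tree(text = "((A:1,B:1)87:1,C:1,D:1);")
  writeNewickTree(sup, f)
  expect_match(readLines(f), "\\)87:")

  tr$tip.label[2] <- ""
  expect_error(writeNewickTree(tr, f), "unnamed leaf")
})

test_that("YAML config overrides screen keys and extends the motif set", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("screen:",
               "  alpha_evalue_cutoff: 1.0e-5",
               "  merge_gap: 10",
               "motifs:",
               "  - name: QW",
               "    pattern: QWx(A/G)",
               "    region: ANY"), f)
  cfg <- readScreenConfig(f)
  expect_s4_class(cfg$config, "ScreenConfig")
  expect_equal(cfg$config@alpha_evalue_cutoff, 1e-5)
  expect_equal(cfg$config@merge_gap, 10)
  expect_true("QW" %in% names(cfg$motifs))
  expect_equal(length(cfg$motifs$QW@positions), 4L)
})
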