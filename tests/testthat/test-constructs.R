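dcs_fixture <- function(seed = 13L, identity = 0.9) {
  sim <- generateProteome(SyntheticSpec(counts = c(DCS_INTACT = 1L),
                                        seed = seed,
                                        template_identity = identity))
  hits <- scanInternal(sim$proteins)
  s <- as.character(sim$proteins)[[1]]
  regions <- list(gb = c(min(hits$start[hits$class == "GB_DTC"]),
                         max(hits$end[hits$class == "GB_DTC"])),
                  alpha = c(min(hits$start[hits$class == "ALPHA_TS"]),
                            max(hits$end[hits$class == "ALPHA_TS"])))
  st <- classifyMotifStatus(scanMotifs(s, region_intervals = regions))
  call <- callArchitecture(sim$truth$protein_id, nchar(s), hits, st)
  list(seq = sim$proteins, s = s, call = call, regions = regions, st = st)
}

test_that("split rules put the boundary where stated and restore the parent", {
  fx <- dcs_fixture()
  L <- nchar(fx$s)
  for (rule in c("GB_END", "MIDLINKER",
                 sprintf("EXPLICIT:%d", fx$call$gb_end))) {
    parts <- splitDcs(fx$seq, fx$call, rule)
    expect_equal(length(parts), 2L)
    expect_equal(S4Vectors::mcols(parts)$part, c("NTERM_GB", "CTERM_ALPHA"))
    expect_equal(paste0(as.character(parts)[[1]], as.character(parts)[[2]]),
                 fx$s)
  }
  gbe <- splitDcs(fx$seq, fx$call, "GB_END")
  expect_equal(S4Vectors::mcols(gbe)$boundary[1], fx$call$gb_end)
  expect_equal(nchar(as.character(gbe)[[1]]), fx$call$gb_end)

  mid <- splitDcs(fx$seq, fx$call, "MIDLINKER")
  expect_equal(S4Vectors::mcols(mid)$boundary[1],
               fx$call$gb_end + (fx$call$alpha_start - fx$call$gb_end) %/% 2L)

  # published-style explicit boundaries are honored verbatim
  expl <- splitDcs(fx$seq, fx$call, sprintf("EXPLICIT:%d", fx$call$gb_end - 5L))
  expect_equal(nchar(as.character(expl)[[1]]), fx$call$gb_end - 5L)

  expect_error(splitDcs(fx$seq, fx$call,
                        sprintf("EXPLICIT:%d", fx$call$gb_end - 30L)),
               "outside")
  expect_error(splitDcs(fx$seq, fx$call,
                        sprintf("EXPLICIT:%d", fx$call$alpha_start)),
               "outside")
})

test_that("only fusion candidates are splittable", {
  fx <- dcs_fixture()
  bad <- fx$call
  bad$call <- "TS_ONLY"
  expect_error(splitDcs(fx$seq, bad, "GB_END"), "DCS_CANDIDATE")
})

test_that("anchored mutation changes exactly one residue and labels it", {
  toy <- c(p = "AAAAAAAAADDTTDAAAAAAA")
  mut <- applyMutation(toy, "DDxxD", offset = 1, replacement = "A",
                       region_intervals = list(alpha = c(1L, 21L), gb = NULL))
  mc <- S4Vectors::mcols(mut)
  expect_equal(mc$label, "D10A")
  expect_equal(names(mut), "p:D10A")
  a <- strsplit(toy[[1]], "")[[1]]
  b <- strsplit(as.character(mut)[[1]], "")[[1]]
  expect_equal(sum(a != b), 1L)
  expect_equal(b[10], "A")
  expect_error(applyMutation(toy, "DDxxD", offset = 1, replacement = "A",
                             occurrence = 2L,
                             region_intervals = list(alpha = c(1L, 21L),
                                                     gb = NULL)),
               "occurrence 2")
})

test_that("dyad mutations on the didomain template mirror the field's labels", {
  gb <- c(ref = gbTemplate())
  reg <- list(gb = c(1L, 500L), alpha = NULL)
  his <- applyMutation(gb, "LHS", offset = 2, replacement = "A",
                       region_intervals = reg)
  expect_equal(S4Vectors::mcols(his)$label, "H187A")
  asn <- applyMutation(gb, "PNV", offset = 2, replacement = "A",
                       region_intervals = reg)
  expect_equal(S4Vectors::mcols(asn)$label, "N253A")
})

test_that("Class I knockout flips motif status on every planted fusion", {
  sim <- generateProteome(SyntheticSpec(counts = c(DCS_INTACT = 3L),
                                        seed = 5L))
  tr <- as.data.frame(sim$truth)
  for (i in seq_len(nrow(tr))) {
    s <- setNames(as.character(sim$proteins)[i], tr$protein_id[i])
    regions <- list(gb = c(tr$gb_start[i], tr$gb_end[i]),
                    alpha = c(tr$alpha_start[i], tr$alpha_end[i]))
    before <- classifyMotifStatus(scanMotifs(s[[1]],
                                             region_intervals = regions))
    expect_equal(before@classI, "INTACT")
    ko <- applyMutation(s, "DDxxD", offset = 1, replacement = "A",
                        region_intervals = regions)
    expect_equal(S4Vectors::mcols(ko)$position, tr$ddxxd[i])
    after <- classifyMotifStatus(scanMotifs(as.character(ko)[[1]],
                                            region_intervals = regions))
    expect_false(after@classI == "INTACT")
  }
})
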