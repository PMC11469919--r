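wt_fixture <- function() {
  # identity-1 fusion: the annotated positions transfer exactly
  sim <- generateProteome(SyntheticSpec(counts = c(DCS_INTACT = 1L),
                                        template_identity = 1,
                                        linker_length_range = c(10L, 10L)))
  s <- as.character(sim$proteins)[[1]]
  regions <- list(gb = c(1L, 500L), alpha = c(511L, 810L))
  st <- classifyMotifStatus(scanMotifs(s, region_intervals = regions))
  prof <- locateSites(c(q = s))
  list(s = s, st = st, prof = prof, regions = regions)
}

test_that("the annotated reference maps onto itself unchanged", {
  ref <- annotatedReference()
  prof <- locateSites(ref$sequence, ref)
  expect_equal(unname(prof@positions),
               c(187L, 253L, 726L, 730L))
  expect_equal(unname(prof@residues), c("H", "N", "I", "I"))
  expect_true(all(prof@context_ok))
})

test_that("position mapping shifts with indels and reports deletions as absent", {
  ref <- annotatedReference()
  ext <- paste0("GSGSGSGSGS", ref$sequence[[1]])
  prof <- locateSites(c(q = ext), ref)
  expect_equal(unname(prof@positions), c(187L, 253L, 726L, 730L) + 10L)
  expect_true(all(prof@context_ok))

  # delete the dyad histidine
  s <- ref$sequence[[1]]
  del <- paste0(substr(s, 1, 186), substr(s, 188, nchar(s)))
  prof2 <- locateSites(c(q = del), ref)
  expect_true(is.na(prof2@positions["dyad_his"]))
  expect_false(is.na(prof2@positions["dyad_asn"]))
})

test_that("context mismatches are flagged, not dropped", {
  ref <- annotatedReference()
  s <- ref$sequence[[1]]
  substr(s, 186, 186) <- "A"  # LHS -> AHS around the mapped histidine
  prof <- locateSites(c(q = s), ref)
  expect_equal(unname(prof@positions["dyad_his"]), 187L)
  expect_false(prof@context_ok[["dyad_his"]])
  expect_true(prof@context_ok[["dyad_asn"]])
})

test_that("reference-query-reference mapping is inverse-consistent when gap-free", {
  ref <- annotatedReference()
  prof <- locateSites(ref$sequence, ref)
  back_ref <- list(sequence = c(r = ref$sequence[[1]]),
                   annotations = S4Vectors::DataFrame(
                     role = names(prof@positions),
                     position = unname(prof@positions),
                     residue = unname(prof@residues),
                     context_motif = ""))
  round2 <- locateSites(ref$sequence, back_ref)
  expect_equal(round2@positions, prof@positions)
})

test_that("the product rule table reproduces every characterized outcome", {
  fx <- wt_fixture()
  mut <- function(...) do.call(rbind, lapply(list(...), function(m)
    S4Vectors::DataFrame(position = m[[1]], to = m[[2]])))
  p <- fx$prof@positions
  dd <- 610L  # first aspartate of the alpha-domain DDxxD

  expect_equal(predictProduct(fx$prof, fx$st)$products, "ent-kaurene")
  expect_equal(predictProduct(fx$prof, fx$st, mut(list(dd, "A")))$products,
               "ent-CPP")
  expect_equal(predictProduct(fx$prof, fx$st,
                              mut(list(p[["dyad_his"]], "A")))$products,
               "ent-13-epi-manoyl oxide")
  expect_equal(predictProduct(fx$prof, fx$st,
                              mut(list(p[["dyad_asn"]], "A")))$products,
               c("ent-13-epi-manoyl oxide", "ent-kaurene"))
  expect_equal(predictProduct(fx$prof, fx$st,
                              mut(list(p[["dyad_his"]], "A"),
                                  list(dd, "A")))$products,
               "ent-LPP")
  expect_equal(predictProduct(fx$prof, fx$st,
                              mut(list(p[["ile_bact"]], "T")))$products,
               "ent-pimara-8(14),15-diene")
  expect_equal(predictProduct(fx$prof, fx$st,
                              mut(list(p[["ile_plant"]], "T")))$products,
               c("8a-hydroxy-ent-pimar-15-ene", "ent-kaurene"))

  # anchored mutations produced by applyMutation drive the same rules
  ko <- applyMutation(c(DCS = fx$s), "DDxxD", offset = 1, replacement = "A",
                      region_intervals = fx$regions)
  expect_equal(predictProduct(fx$prof, fx$st,
                              S4Vectors::mcols(ko))$products, "ent-CPP")

  # the table is defined only for Class II-intact proteins
  absent <- methods::new("MotifStatus", classI = "INTACT", classII = "ABSENT",
                         hits = fx$st@hits)
  expect_error(predictProduct(fx$prof, absent), "Class II")
})

test_that("no mutation-state combination matches more than one rule", {
  fx <- wt_fixture()
  p <- fx$prof@positions
  dd <- 610L
  site_pos <- c(knockout = dd, his = unname(p[["dyad_his"]]),
                asn = unname(p[["dyad_asn"]]),
                ile_bact = unname(p[["ile_bact"]]),
                ile_plant = unname(p[["ile_plant"]]))
  site_to <- c(knockout = "A", his = "A", asn = "A", ile_bact = "T",
               ile_plant = "T")
  rules <- vapply(0:31, function(mask) {
    on <- names(site_pos)[bitwAnd(mask, 2^(0:4)) > 0]
    muts <- if (length(on))
      S4Vectors::DataFrame(position = site_pos[on], to = site_to[on])
    res <- predictProduct(fx$prof, fx$st, muts)
    expect_true(is.na(res$rule) || res$rule %in% 1:7)
    expect_equal(res$no_rule, is.na(res$rule))
    if (is.na(res$rule)) expect_equal(res$products, "none")
    if (is.na(res$rule)) NA_integer_ else res$rule
  }, 1L)
  # each combination fires at most one rule; the designed coverage is:
  # wild type, the five single-site states, and knockout + either dyad site
  expect_equal(unname(rules[1]), 1L)
  expect_equal(sum(!is.na(rules)), 8L)
  expect_equal(as.integer(table(rules)), c(1L, 1L, 1L, 1L, 2L, 1L, 1L))
})
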