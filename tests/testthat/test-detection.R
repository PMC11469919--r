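rows_df <- function(...) {
  r <- list(...)
  S4Vectors::DataFrame(
    target_id = vapply(r, `[[`, "", 1),
    query_profile_id = vapply(r, `[[`, "", 2),
    domain_class = vapply(r, `[[`, "", 3),
    full_seq_evalue = 1e-20,
    domain_ievalue = vapply(r, function(x) as.numeric(x[[4]]), 0),
    env_start = vapply(r, function(x) as.integer(x[[5]]), 0L),
    env_end = vapply(r, function(x) as.integer(x[[6]]), 0L))
}

test_that("external rows respect the per-class e-value cutoff", {
  hits <- hitsFromRows(rows_df(
    list("p1", "PF03936", "ALPHA_TS", 5e-4, 600, 850)))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$class, "ALPHA_TS")
  expect_equal(c(hits$start, hits$end), c(600L, 850L))

  none <- hitsFromRows(rows_df(
    list("p1", "PF03936", "ALPHA_TS", 2e-3, 600, 850)))
  expect_equal(nrow(none), 0L)
})

test_that("didomain evidence needs both profile flavors and spans their union", {
  both <- hitsFromRows(rows_df(
    list("p1", "PF13249", "GB_NTERM", 1e-10, 10, 240),
    list("p1", "PF13243", "GB_CTERM", 1e-12, 250, 500)))
  expect_equal(nrow(both), 1L)
  expect_equal(both$class, "GB_DTC")
  expect_equal(c(both$start, both$end), c(10L, 500L))
  expect_equal(both$score, -log10(1e-12))

  onesided <- hitsFromRows(rows_df(
    list("p1", "PF13243", "GB_CTERM", 1e-12, 250, 500)))
  expect_equal(nrow(onesided), 0L)
})

test_that("interval merging joins gaps up to 30 aa, is idempotent, stays sorted", {
  hits <- hitsFromRows(rows_df(
    list("p1", "PF03936", "ALPHA_TS", 1e-6, 100, 200),
    list("p1", "PF03936", "ALPHA_TS", 1e-9, 220, 300),   # gap 19 -> merge
    list("p1", "PF19086", "ALPHA_TS", 1e-4, 340, 400)))  # gap 39 -> separate
  expect_equal(nrow(hits), 2L)
  expect_equal(hits$start, c(100L, 340L))
  expect_equal(hits$end, c(300L, 400L))
  expect_equal(hits$score[1], -log10(1e-9))
  expect_true(all(diff(hits$start) > 0))
  expect_true(all(hits$end[-nrow(hits)] < hits$start[-1]))
  # feeding merged hits back through the merger changes nothing
  m <- dcsminer:::.merge_intervals(hits$start, hits$end, hits$score, 30)
  expect_equal(m$start, hits$start)
  expect_equal(m$end, hits$end)
})

test_that("internal scan finds templates, is silent on random sequences", {
  profiles <- buildProfiles()
  self <- scanInternal(c(tpl = alphaTemplate()), profiles)
  expect_equal(self$class, "ALPHA_TS")
  expect_equal(c(self$start, self$end), c(1L, 300L))

  set.seed(99)
  rand <- Biostrings::AAStringSet(
    setNames(vapply(rep(300, 100), rand_seq, ""), sprintf("r%03d", 1:100)))
  expect_equal(nrow(scanInternal(rand, profiles)), 0L)

  # sequences shorter than every profile yield no hits, not an error
  expect_equal(nrow(scanInternal(c(short = "MKTDIDD"), profiles)), 0L)
})

test_that("internal scan on a fusion reports didomain strictly before alpha", {
  sim <- generateProteome(SyntheticSpec(counts = c(DCS_INTACT = 1L),
                                        seed = 21L))
  hits <- scanInternal(sim$proteins)
  gb <- hits[hits$class == "GB_DTC", ]
  al <- hits[hits$class == "ALPHA_TS", ]
  expect_equal(nrow(gb), 1L)
  expect_equal(nrow(al), 1L)
  expect_lt(gb$end, al$start)
  tr <- as.data.frame(sim$truth)
  expect_equal(c(gb$start, gb$end), c(tr$gb_start, tr$gb_end))
  expect_equal(c(al$start, al$end), c(tr$alpha_start, tr$alpha_end))
})

test_that("dataset assembly is set algebra with SHC exclusion", {
  hits <- S4Vectors::DataFrame(
    protein_id = c("A", "B", "C", "C", "S"),
    class = c("ALPHA_TS", "GB_DTC", "ALPHA_TS", "GB_DTC", "GB_DTC"),
    start = 1L, end = 100L, score = 10, provider = "external")
  ds <- buildDatasets(hits, shc_ids = "S")
  expect_setequal(ds$ts_set, c("A", "C"))
  expect_setequal(ds$dtc_set, c("B", "C"))
  expect_equal(ds$overlap, "C")

  empty <- buildDatasets(hits[0, ])
  expect_length(empty$ts_set, 0L)
  expect_length(empty$dtc_set, 0L)

  # internal evidence: an SHC-dominated protein drops out of the DTC set
  hits2 <- S4Vectors::DataFrame(
    protein_id = c("S", "S"), class = c("GB_DTC", "SHC_LIKE"),
    start = 1L, end = 500L, score = c(300, 700), provider = "internal")
  expect_length(buildDatasets(hits2)$dtc_set, 0L)
})

test_that("synthetic dataset overlap equals exactly the planted fusion ids", {
  sim <- generateProteome(SyntheticSpec())
  ds <- buildDatasets(scanInternal(sim$proteins))
  planted <- sim$truth$protein_id[
    sim$truth$true_class %in% c("DCS_INTACT", "DCS_ABERRANT")]
  expect_setequal(ds$overlap, planted)
})
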