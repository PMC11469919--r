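test_that("motif grammar compiles exact residues, wildcards and sets", {
  d <- compileMotif("DxDD")
  expect_equal(length(d@positions), 4L)
  expect_equal(d@positions[[1]], "D")
  expect_length(d@positions[[2]], 0L)  # wildcard

  nse <- compileMotif("(N/D)Dxx(S/T/G)xxx(E/D)")
  expect_equal(length(nse@positions), 9L)
  expect_setequal(nse@positions[[1]], c("N", "D"))
  expect_setequal(nse@positions[[5]], c("S", "T", "G"))
  expect_setequal(nse@positions[[9]], c("E", "D"))

  expect_error(compileMotif("D(x"), "column 2")
  expect_error(compileMotif("DxD9"), "column 4")
})

test_that("scanner reports all overlapping in-region matches in order", {
  hits <- scanMotifs("AAADIDDAAA", list(compileMotif("DxDD")))
  expect_equal(hits$start, 4L)
  expect_equal(hits$matched, "DIDD")

  # brute-force over all 5-windows of DDFFDDFFD: windows 1 and 5 both read
  # DDFFD, overlapping matches are all reported
  d <- builtinMotifs()$DDxxD
  expect_equal(oracle_scan("DDFFDDFFD", d, c(1L, 9L)), c(1L, 5L))
  hits2 <- scanMotifs("DDFFDDFFD", list(d),
                      region_intervals = list(alpha = c(1L, 9L), gb = NULL))
  expect_equal(hits2$start, c(1L, 5L))
  expect_equal(hits2$matched, c("DDFFD", "DDFFD"))

  # a DxDD instance outside the didomain region is not reported
  s <- paste0(strrep("A", 699), "DIDD", strrep("A", 197))
  expect_equal(nchar(s), 900L)
  out <- scanMotifs(s, builtinMotifs()["DxDD"],
                    region_intervals = list(gb = c(1L, 540L), alpha = NULL))
  expect_equal(nrow(out), 0L)
})

test_that("wildcards match the unknown residue X but exact positions do not", {
  hits <- scanMotifs("DXDD", builtinMotifs()["DxDD"],
                     region_intervals = list(gb = c(1L, 4L), alpha = NULL))
  expect_equal(hits$start, 1L)
  none <- scanMotifs("XIDD", builtinMotifs()["DxDD"],
                     region_intervals = list(gb = c(1L, 4L), alpha = NULL))
  expect_equal(nrow(none), 0L)
})

test_that("scanner agrees with the exhaustive window oracle on random sequences", {
  motifs <- builtinMotifs()
  set.seed(424)
  for (rep in seq_len(200)) {
    s <- rand_seq(60, c(AA20, "D", "D", "N", "S", "E"))  # enrich motif letters
    L <- nchar(s)
    half <- as.integer(ceiling(L / 2))
    regions <- list(GB_REGION = c(1L, half), ALPHA_REGION = c(half + 1L, L),
                    ANY = c(1L, L))
    got <- scanMotifs(s, motifs)
    for (d in motifs) {
      expect_equal(got$start[got$motif_name == d@name],
                   oracle_scan(s, d, regions[[d@region]]),
                   label = paste(d@name, s))
    }
  }
})

test_that("motif status follows the Class I / Class II rules", {
  h <- function(...) {
    x <- list(...)
    S4Vectors::DataFrame(motif_name = vapply(x, `[[`, "", 1),
                         start = vapply(x, function(r) as.integer(r[[2]]), 0L),
                         end = integer(length(x)),
                         matched = character(length(x)))
  }
  # intact fusion: DxDD in didomain, DDxxD then NSE 140 apart in alpha
  st <- classifyMotifStatus(h(list("DxDD", 100), list("DDxxD", 610),
                              list("NSE", 750)))
  expect_equal(st@classII, "INTACT")
  expect_equal(st@classI, "INTACT")

  # aberrant variants only
  st2 <- classifyMotifStatus(h(list("DxDD", 100), list("ABERRANT_DD", 600),
                               list("NSE_VARIANT", 740)))
  expect_equal(st2@classII, "INTACT")
  expect_equal(st2@classI, "ABERRANT")

  # canonical pair at out-of-window spacing is aberrant, not intact
  st3 <- classifyMotifStatus(h(list("DDxxD", 610), list("NSE", 660)))
  expect_equal(st3@classI, "ABERRANT")

  # canonical wins when aberrant variants co-occur with a valid pair
  st4 <- classifyMotifStatus(h(list("DDxxD", 610), list("NSE", 750),
                               list("ABERRANT_DD", 620)))
  expect_equal(st4@classI, "INTACT")

  st5 <- classifyMotifStatus(h()[0, ])
  expect_equal(st5@classII, "ABSENT")
  expect_equal(st5@classI, "ABSENT")
})

test_that("motif status is invariant to hit order", {
  hits <- S4Vectors::DataFrame(
    motif_name = c("NSE", "DxDD", "DDxxD"),
    start = c(750L, 100L, 610L), end = 0L, matched = "")
  set.seed(2)
  for (i in 1:5) {
    p <- sample(nrow(hits))
    st <- classifyMotifStatus(hits[p, ])
    expect_equal(st@classI, "INTACT")
    expect_equal(st@classII, "INTACT")
  }
})
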