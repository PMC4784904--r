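nt_hit <- function(contig, start, end, bitscore, evalue = 1e-30, id = "h1") {
  data.frame(query_id = contig, subject_id = id, percent_identity = 0.9,
             align_length = end - start, q_start = start, q_end = end,
             evalue = evalue, bitscore = bitscore, stringsAsFactors = FALSE)
}
no_hits <- function() nt_hit("x", 0L, 1L, 1)[0, ]

test_that("the entropy masker flags homopolymers and passes complex sequence", {
  m <- mask_low_complexity(strrep("A", 200))
  expect_equal(nrow(m), 1L)
  expect_equal(m$start, 0L)
  expect_equal(m$end, 200L)

  # maximum mononucleotide entropy: never masked
  expect_equal(nrow(mask_low_complexity(strrep("ACGT", 100))), 0L)

  # seeded uniform-random sequence stays above 1.5 bits
  set.seed(5)
  rnd <- paste(sample(c("A", "C", "G", "T"), 5000, replace = TRUE), collapse = "")
  expect_equal(nrow(mask_low_complexity(rnd)), 0L)
})

test_that("windows partition each contig exactly once", {
  w <- make_windows(2500L, 1000L)
  expect_equal(w$start, c(0L, 1000L, 2000L))
  expect_equal(w$end, c(1000L, 2000L, 2500L))
  expect_equal(sum(w$end - w$start), 2500L)

  w <- make_windows(999L, 1000L)
  expect_equal(nrow(w), 1L)
  expect_equal(w$end, 999L)

  w <- make_windows(2500L, 1000L, data.frame(start = 0L, end = 500L))
  expect_equal(w$masked_fraction, c(0.5, 0, 0))

  # property: random lengths still tile exactly
  set.seed(8)
  for (len in sample.int(10000, 10)) {
    w <- make_windows(len, 1000L)
    expect_equal(sum(w$end - w$start), len)
    expect_true(all(w$start[-1] == w$end[-nrow(w)]))
  }
})

test_that("window scoring applies the strict bit-score comparison and e-value cutoff", {
  w <- make_windows(3000L, 1000L)
  prok <- nt_hit("c", 100L, 400L, bitscore = 120)
  euk <- nt_hit("c", 200L, 500L, bitscore = 80)
  s <- score_windows(w, prok, euk, 3000L)
  expect_true(s$harvested[1])
  expect_false(any(s$harvested[-1]))

  # equal scores: strict > means not harvested
  s <- score_windows(w, nt_hit("c", 100L, 400L, 80), euk, 3000L)
  expect_false(any(s$harvested))

  # prokaryotic hit above the e-value threshold is ignored
  s <- score_windows(w, nt_hit("c", 100L, 400L, 120, evalue = 1e-3), no_hits(), 3000L)
  expect_false(any(s$harvested))

  # heavily masked windows are never harvested
  wm <- make_windows(3000L, 1000L, data.frame(start = 0L, end = 600L))
  s <- score_windows(wm, prok, no_hits(), 3000L)
  expect_false(s$harvested[1])

  expect_error(score_windows(w, nt_hit("c", 100L, 4000L, 120), no_hits(), 3000L),
               "outside contig")
})

test_that("a 150 bp prokaryotic alignment at bit 120 vs 80 flags one region on a 60 kb contig and none on 40 kb", {
  prok <- nt_hit("c", 10000L, 10150L, bitscore = 120)
  euk <- nt_hit("c", 10000L, 10150L, bitscore = 80, id = "e1")
  for (clen in c(60000L, 40000L)) {
    w <- score_windows(make_windows(clen, 1000L), prok, euk, clen)
    mf <- merge_and_flag(w, prok, "c", clen,
                         data.frame(gene_id = character(), contig_id = character(),
                                    start = numeric(), end = numeric()))
    if (clen > 50000L) {
      expect_equal(sum(mf$regions$flagged_nt), 1L)
      expect_equal(mf$regions$prok_similarity_length[mf$regions$flagged_nt], 150L)
      expect_equal(mf$regions$bitscore_diff[mf$regions$flagged_nt], 40)
    } else {
      expect_equal(sum(mf$regions$flagged_nt), 0L)
    }
  }
})

test_that("prokaryotic similarity length is an interval union and split hits do not change the flag", {
  clen <- 60000L
  whole <- nt_hit("c", 0L, 130L, bitscore = 120)
  split2 <- rbind(nt_hit("c", 0L, 80L, bitscore = 120, id = "a"),
                  nt_hit("c", 40L, 130L, bitscore = 120, id = "b"))
  for (hits in list(whole, split2)) {
    w <- score_windows(make_windows(clen, 1000L), hits, no_hits(), clen)
    mf <- merge_and_flag(w, hits, "c", clen,
                         data.frame(gene_id = character(), contig_id = character(),
                                    start = numeric(), end = numeric()))
    expect_equal(mf$regions$prok_similarity_length, 130L)
    expect_equal(sum(mf$regions$flagged_nt), 1L)  # euk absent: diff = 120 > 25
  }
})

test_that("adjacent harvested windows merge and overlapping genes are flagged", {
  clen <- 60000L
  hits <- nt_hit("c", 500L, 2500L, bitscore = 200)
  genes <- data.frame(gene_id = c("gIn", "gOut"), contig_id = "c",
                      start = c(2400, 30000), end = c(3400, 31000))
  w <- score_windows(make_windows(clen, 1000L), hits, no_hits(), clen)
  mf <- merge_and_flag(w, hits, "c", clen, genes)
  expect_equal(nrow(mf$regions), 1L)
  expect_equal(mf$regions$start, 0L)
  expect_equal(mf$regions$end, 3000L)
  expect_equal(mf$flagged_genes, "gIn")
})

test_that("on synthetic data the screen recovers recent transfers and never flags host or symbiont genes", {
  sim <- default_sim()
  res <- default_result()
  truth <- sim$genome$truth
  flagged <- res$candidates$gene_id[res$candidates$flag_nt]
  cls <- stats::setNames(truth$class, truth$gene_id)
  recent <- truth$gene_id[truth$class == "recent_hgt"]
  expect_gte(mean(recent %in% flagged), 0.95)
  expect_true(all(cls[flagged] == "recent_hgt"))
})
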