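test_that("Alien Index matches direct evaluation of the definition", {
  cfg <- pipeline_config()
  # equal best e-values on both sides: symmetric, AI = 0
  h <- rbind(hit_frame(subject = "m1", evalue = 1e-40, bitscore = 150, superkingdom = "Metazoa"),
             hit_frame(subject = "b1", evalue = 1e-40, bitscore = 150, superkingdom = "Bacteria"))
  r <- compute_alien_index("g1", h, cfg)
  expect_equal(r$ai, 0)
  expect_false(r$flagged_ai45)

  # no metazoan hit: AI = ln(1 + eps) - ln(1e-30 + eps)
  h <- hit_frame(subject = "b1", evalue = 1e-30, bitscore = 140, superkingdom = "Bacteria")
  r <- compute_alien_index("g1", h, cfg)
  expect_equal(r$ai, log(1 + 1e-200) - log(1e-30 + 1e-200), tolerance = 1e-12)
  expect_equal(r$ai, 69.0776, tolerance = 1e-4)
  expect_true(r$flagged_ai45)

  # both present, modest contrast: below the threshold
  h <- rbind(hit_frame(subject = "m1", evalue = 1e-50, bitscore = 180, superkingdom = "Metazoa"),
             hit_frame(subject = "b1", evalue = 1e-60, bitscore = 220, superkingdom = "Bacteria"))
  r <- compute_alien_index("g1", h, cfg)
  expect_equal(r$ai, 23.02585, tolerance = 1e-4)
  expect_false(r$flagged_ai45)

  # no hits at all: both categories default to e = 1
  r <- compute_alien_index("g1", h[0, ], cfg)
  expect_equal(r$ai, 0)
  expect_false(r$flagged_ai45)

  expect_error(compute_alien_index("g1",
    hit_frame(subject = "b1", evalue = -1, bitscore = 10, superkingdom = "Bacteria"), cfg),
    "negative")
})

test_that("a strong non-metazoan eukaryote best hit blocks the flag", {
  cfg <- pipeline_config()
  h <- rbind(hit_frame(subject = "f1", evalue = 1e-60, bitscore = 220,
                       superkingdom = "Eukaryota", phylum = "Ascomycota",
                       is_metazoan = FALSE),
             hit_frame(subject = "b1", evalue = 1e-50, bitscore = 180,
                       superkingdom = "Bacteria"))
  r <- compute_alien_index("g1", h, cfg)
  expect_true(r$ai >= 45)              # fungus drives the non-metazoan e-value
  expect_false(r$best_overall_hit_is_prokaryotic)
  expect_false(r$flagged_ai45)         # ...but also vetoes the flag
})

test_that("self-hits are removed before scoring when a self-id set is given", {
  cfg <- pipeline_config()
  h <- rbind(hit_frame(subject = "SELF_1", evalue = 0, bitscore = 999,
                       superkingdom = "Metazoa"),
             hit_frame(subject = "b1", evalue = 1e-30, bitscore = 140,
                       superkingdom = "Bacteria"))
  with_self <- compute_alien_index("g1", h, cfg, self_ids = "SELF_1")
  without <- compute_alien_index("g1", h, cfg)
  expect_true(with_self$flagged_ai45)
  expect_false(without$flagged_ai45)
})

test_that("compute_alien_index agrees with a brute-force oracle on 1000 random tables", {
  cfg <- pipeline_config()
  set.seed(42)
  for (i in 1:1000) {
    h <- random_hit_table(sample.int(12, 1))
    got <- compute_alien_index("g1", h, cfg)
    want <- ai_oracle(h)
    expect_lt(abs(got$ai - want$ai), 1e-9)
    expect_identical(got$flagged_ai45, want$flagged)
  }
})

test_that("AI is antisymmetric and monotone in the metazoan e-value", {
  cfg <- pipeline_config()
  set.seed(43)
  for (i in 1:50) {
    em <- 10^stats::runif(1, -100, 0); en <- 10^stats::runif(1, -100, 0)
    h1 <- rbind(hit_frame(subject = "m", evalue = em, bitscore = 100, superkingdom = "Metazoa"),
                hit_frame(subject = "b", evalue = en, bitscore = 100, superkingdom = "Bacteria"))
    h2 <- rbind(hit_frame(subject = "m", evalue = en, bitscore = 100, superkingdom = "Metazoa"),
                hit_frame(subject = "b", evalue = em, bitscore = 100, superkingdom = "Bacteria"))
    expect_equal(compute_alien_index("g1", h1, cfg)$ai,
                 -compute_alien_index("g1", h2, cfg)$ai, tolerance = 1e-12)
    # improving the metazoan e-value can only lower AI
    h3 <- h1; h3$evalue[1] <- h3$evalue[1] / 100
    expect_lte(compute_alien_index("g1", h3, cfg)$ai,
               compute_alien_index("g1", h1, cfg)$ai)
  }
})

test_that("ai45_candidates returns exactly the flagged genes", {
  cfg <- pipeline_config()
  hits <- rbind(
    hit_frame(query = "gA", subject = "b1", evalue = 1e-30, bitscore = 140,
              superkingdom = "Bacteria"),
    hit_frame(query = "gB", subject = "m1", evalue = 1e-40, bitscore = 150,
              superkingdom = "Metazoa"),
    hit_frame(query = "gC", subject = "f1", evalue = 1e-50, bitscore = 200,
              superkingdom = "Eukaryota", phylum = "Ascomycota", is_metazoan = FALSE))
  tab <- alien_index_table(hits, c("gA", "gB", "gC", "gD"), cfg)
  expect_equal(ai45_candidates(tab), "gA")
  expect_equal(tab$ai[tab$gene_id == "gD"], 0)
})
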