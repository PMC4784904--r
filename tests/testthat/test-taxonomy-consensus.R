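mk_hits <- function(phyla, evalues, bitscores = NULL, sks = NULL, mets = NULL) {
  n <- length(phyla)
  if (is.null(bitscores)) bitscores <- rep(100, n)
  if (n == 0L) return(hit_frame(subject = "s", evalue = 1, bitscore = 1,
                                superkingdom = "Bacteria")[0, ])
  if (is.null(sks)) sks <- ifelse(phyla %in% c("Chordata", "Porifera"),
                                  "Eukaryota", "Bacteria")
  if (is.null(mets)) mets <- phyla %in% c("Chordata", "Porifera")
  data.frame(query_id = "g1", subject_id = sprintf("s%02d", seq_len(n)),
             percent_identity = 0.8, align_length = 100L,
             q_start = 0L, q_end = 100L,
             evalue = evalues, bitscore = bitscores,
             superkingdom = sks, phylum = phyla, is_metazoan = mets,
             stringsAsFactors = FALSE)
}

test_that("top_k_hits filters, sorts and truncates with the stated tie-breaks", {
  h <- mk_hits(rep("Proteobacteria", 12), evalues = 10^-(30:19))
  expect_equal(nrow(top_k_hits(h, 10, 1e-5)), 10L)
  expect_equal(top_k_hits(h, 10, 1e-5)$evalue[1], 1e-30)

  h <- mk_hits(rep("Proteobacteria", 3), evalues = c(1e-2, 1e-3, 1e-4))
  expect_equal(nrow(top_k_hits(h, 10, 1e-5)), 0L)

  h <- mk_hits(rep("Proteobacteria", 2), evalues = c(1e-10, 1e-10),
               bitscores = c(80, 95))
  expect_equal(top_k_hits(h, 10, 1e-5)$bitscore[1], 95)
})

test_that("consensus phylum is the majority, ties go to the best-ranked tied phylum", {
  h <- mk_hits(c(rep("Proteobacteria", 6), rep("Chordata", 4)),
               evalues = 10^-(40:31))
  expect_equal(consensus_phylum(top_k_hits(h, 10, 1e-5))$phylum, "Proteobacteria")

  # 5-5 tie; best-ranked hit belongs to B
  h <- mk_hits(c("B", rep(c("A", "B"), c(5, 4))), evalues = 10^-(40:31),
               sks = "Bacteria", mets = FALSE)
  expect_equal(consensus_phylum(top_k_hits(h, 10, 1e-5))$phylum, "B")

  expect_equal(consensus_phylum(mk_hits(character(), numeric()))$phylum, "unassigned")
})

test_that("the exclusivity rule excludes genes with any qualifying eukaryotic hit", {
  gene_ids <- "g1"
  # consensus Bacteria but one metazoan hit at 1e-8: excluded
  h <- mk_hits(c(rep("Proteobacteria", 5), "Chordata"),
               evalues = c(10^-(40:36), 1e-8))
  a <- consensus_assignments(h, gene_ids)
  expect_equal(a$consensus_superkingdom, "Bacteria")
  expect_false(a$flagged_blast)

  # eukaryotic similarity only above the threshold: included
  h$evalue[6] <- 0.01
  a <- consensus_assignments(h, gene_ids)
  expect_true(a$flagged_blast)
  expect_equal(blast_candidates(a), "g1")

  # no qualifying hits at all: unassigned, excluded
  h <- mk_hits(rep("Proteobacteria", 3), evalues = rep(0.5, 3))
  a <- consensus_assignments(h, gene_ids)
  expect_equal(a$consensus_phylum, "unassigned")
  expect_false(a$flagged_blast)
})

test_that("assignments are invariant to permutation of the input hit order", {
  set.seed(99)
  h <- random_hit_table(15)
  a1 <- consensus_assignments(h, "g1")
  a2 <- consensus_assignments(h[sample.int(nrow(h)), ], "g1")
  expect_equal(a1, a2)
})

test_that("flagged genes always have at least one prokaryotic hit and, on synthetic data, no host gene is flagged", {
  sim <- default_sim()
  res <- default_result()
  flagged <- blast_candidates(res$assignments)
  prok_genes <- unique(sim$inputs$protein_hits$query_id[
    sim$inputs$protein_hits$superkingdom %in% c("Bacteria", "Archaea")])
  expect_true(all(flagged %in% prok_genes))
  hosts <- sim$genome$truth$gene_id[sim$genome$truth$class == "host"]
  expect_length(intersect(flagged, hosts), 0L)
})
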