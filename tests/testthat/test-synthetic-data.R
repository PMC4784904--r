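test_that("a fixed seed reproduces the simulation byte for byte", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_simulation(simulate_all(small_params(seed = 77)), d1)
  write_simulation(simulate_all(small_params(seed = 77)), d2)
  files <- list.files(d1)
  expect_setequal(files, list.files(d2))
  for (f in files)
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  # a different seed changes the data
  d3 <- withr::local_tempdir()
  write_simulation(simulate_all(small_params(seed = 78)), d3)
  expect_false(identical(readLines(file.path(d1, "contigs.fasta")),
                         readLines(file.path(d3, "contigs.fasta"))))
})

test_that("gene models satisfy their structural invariants", {
  sim <- default_sim()
  g <- sim$genome$genes
  expect_true(all(nchar(g$cds) %% 3L == 0L))
  expect_equal(nchar(g$peptide), nchar(g$cds) / 3L - 1L)  # terminal stop removed
  for (i in seq_len(nrow(g))) {
    ex <- g$exons[[i]]
    expect_true(all(diff(ex$start) > 0))
    expect_true(all(ex$end > ex$start))
    expect_true(all(utils::head(ex$end, -1) <= utils::tail(ex$start, -1)))
    expect_equal(sum(ex$end - ex$start), nchar(g$cds[i]))
  }
  # every gene appears exactly once in the truth table
  expect_setequal(sim$genome$truth$gene_id, g$gene_id)
  expect_false(anyDuplicated(sim$genome$truth$gene_id) > 0)
  # single-exon classes and intron-bearing classes
  cls <- stats::setNames(sim$genome$truth$class, sim$genome$truth$gene_id)
  expect_true(all(g$exon_count[cls[g$gene_id] %in% c("recent_hgt", "symbiont")] == 1L))
})

test_that("class placement and composition follow the study design", {
  sim <- default_sim()
  g <- sim$genome$genes
  cls <- stats::setNames(sim$genome$truth$class, sim$genome$truth$gene_id)
  clen <- stats::setNames(Biostrings::width(sim$genome$contigs),
                          names(sim$genome$contigs))
  # symbionts on short contigs, everything else on long contigs
  expect_true(all(clen[g$contig_id[cls[g$gene_id] == "symbiont"]] < 50000))
  expect_true(all(clen[g$contig_id[cls[g$gene_id] != "symbiont"]] >= 50000))

  # host GC3 close to its target
  cc <- codon_count_matrix(stats::setNames(g$cds, g$gene_id))
  third_gc <- substr(colnames(cc), 3, 3) %in% c("G", "C")
  gc3 <- rowSums(cc[, third_gc]) / rowSums(cc)
  expect_lt(abs(mean(gc3[cls[rownames(cc)] == "host"]) - 0.45), 0.02)
  expect_gt(mean(gc3[cls[rownames(cc)] == "symbiont"]),
            mean(gc3[cls[rownames(cc)] == "host"]) + 0.1)

  # with no symbionts, no gene sits on a short contig
  sim0 <- simulate_genome(small_params(seed = 55, n_symbiont = 0L))
  clen0 <- stats::setNames(Biostrings::width(sim0$contigs), names(sim0$contigs))
  expect_true(all(clen0[sim0$genes$contig_id] >= 50000))
})

test_that("hit profiles give host genes low and transfer genes high Alien Index", {
  sim <- default_sim()
  res <- default_result()
  cls <- stats::setNames(sim$genome$truth$class, sim$genome$truth$gene_id)
  ai <- stats::setNames(res$ai$ai, res$ai$gene_id)
  expect_gte(mean(ai[names(cls)[cls == "host"]] < 45), 0.99)
  expect_true(all(ai[names(cls)[cls %in% c("ancient_hgt", "recent_hgt")]] >= 45))
  # the no-metazoan-hit bound: prok e <= 1e-20 forces AI above the threshold
  h <- hit_frame(subject = "b", evalue = 1e-20, bitscore = 70,
                 superkingdom = "Bacteria")
  expect_gte(compute_alien_index("g", h)$ai, 45)

  # symbiont nucleotide hits fall only on short contigs
  nt <- sim$hit_tables$nt_prok_hits
  sym_contigs <- unique(sim$genome$genes$contig_id[
    cls[sim$genome$genes$gene_id] == "symbiont"])
  expect_true(all(startsWith(sym_contigs, "contig_short")))
  expect_length(intersect(res$candidates$gene_id[res$candidates$flag_nt],
                          names(cls)[cls == "symbiont"]), 0L)
})

test_that("expression and auxiliary tables carry the intended class signal", {
  sim <- default_sim()
  cls <- stats::setNames(sim$genome$truth$class, sim$genome$truth$gene_id)
  avg <- average_rpkm(sim$tables$expression, sim$genome$truth$gene_id)
  expect_gte(mean(avg[names(cls)[cls == "symbiont"]] < 10), 0.95)
  expect_gte(mean(avg[names(cls)[cls == "host"]] >= 10), 0.8)
  # external gene-family flags only on ancient transfers
  ev <- sim$tables$evolmap_flags
  expect_true(all(cls[names(ev)[ev]] == "ancient_hgt"))
  # with the external route silenced no gene can reach full support
  rec <- default_result()$candidates
  expect_true(all(rec$n_supporting[!rec$flag_evolmap] <= 3L))
})

test_that("a null GO simulation yields no strong enrichment and odds create it", {
  sim0 <- simulate_all(small_params(seed = 91, enrichment_odds = 1))
  res0 <- suppressMessages(run_pipeline(sim0$inputs))
  ann0 <- annotate_genes(sim0$inputs$protein_hits, sim0$tables$go_map, 1e-4)
  cand0 <- res0$candidates$gene_id[res0$candidates$final_candidate]
  enr0 <- fisher_enrichment(intersect(cand0, names(ann0)), names(ann0), ann0)
  expect_lte(mean(enr0$q_value < 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / nrow(enr0)))

  sim1 <- default_sim()
  res1 <- default_result()
  ann1 <- annotate_genes(sim1$inputs$protein_hits, sim1$tables$go_map, 1e-4)
  cand1 <- res1$candidates$gene_id[res1$candidates$final_candidate]
  enr1 <- fisher_enrichment(intersect(cand1, names(ann1)), names(ann1), ann1)
  expect_equal(enr1$term_id[1], sim1$tables$enriched_term)
  expect_lt(enr1$q_value[1], 0.05)
})

test_that("widening the compositional gap increases the codon-usage separation", {
  seps <- vapply(c(0.50, 0.65, 0.80), function(gc3) {
    sim <- simulate_genome(small_params(seed = 66, alien_gc3_mean = gc3))
    cc <- codon_count_matrix(stats::setNames(sim$genes$cds, sim$genes$gene_id))
    ca <- correspondence_analysis(cc)
    cls <- stats::setNames(sim$truth$class, sim$truth$gene_id)[rownames(cc)]
    abs(mean(ca$axis1[cls == "symbiont"]) - mean(ca$axis1[cls == "host"]))
  }, numeric(1))
  expect_true(all(diff(seps) > 0))
})
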