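test_that("GC and GC13 percentages follow their definitions", {
  expect_equal(gc_percent(c("GGCC", "ATAT", "ATGC")), c(100, 0, 50))
  expect_equal(gc_percent("GGNNCC"), 100)  # Ns excluded from both counts
  expect_warning(expect_true(is.na(gc_percent("NNNN"))), "unambiguous")

  expect_equal(gc13_percent("ATGGCA"), 50)   # pos-1/3 bases A,G,G,A
  expect_equal(gc13_percent("GCGGCG"), 100)
  expect_equal(gc13_percent("ATATAT"), 0)
  expect_error(gc13_percent("ATGGC"), "divisible")
})

test_that("GC13 of a concatenation is the count-weighted mean of the parts", {
  set.seed(12)
  for (i in 1:20) {
    a <- paste(sample(c("GCA", "ATT", "CGG", "TTA"), sample(5:30, 1), TRUE), collapse = "")
    b <- paste(sample(c("GGC", "AAT", "TCG"), sample(5:30, 1), TRUE), collapse = "")
    wa <- 2 * nchar(a) / 3; wb <- 2 * nchar(b) / 3
    expect_equal(gc13_percent(paste0(a, b)),
                 (gc13_percent(a) * wa + gc13_percent(b) * wb) / (wa + wb),
                 tolerance = 1e-9)
  }
})

test_that("codon counts cover the 59 informative codons and exclude start/stop", {
  expect_length(informative_codons(), 59L)
  m <- codon_count_matrix(c(gA = "ATGTAA", gB = "ATGGCAGCATAA"))
  expect_equal(sum(m["gA", ]), 0L)
  expect_equal(unname(m["gB", "GCA"]), 2L)
  expect_equal(sum(m["gB", ]), 2L)
  expect_true(all(c("gA", "gB") %in% attr(m, "low_information")))
  m2 <- codon_count_matrix(stats::setNames(rep("ATGGCAGCATAA", 3), c("a", "b", "c")))
  expect_true(all(m2 == m2[rep(1, 3), ]))
})

test_that("CA total inertia equals chi-square over grand total on random tables", {
  set.seed(21)
  for (i in 1:20) {
    m <- matrix(stats::rpois(25, 8) + 1L, 5, 5,
                dimnames = list(paste0("r", 1:5), paste0("c", 1:5)))
    ca <- correspondence_analysis(m)
    chi2 <- suppressWarnings(stats::chisq.test(m)$statistic)
    expect_lt(abs(ca$total_inertia - unname(chi2) / sum(m)), 1e-9)
    expect_true(all(diff(ca$inertia_per_axis) <= 1e-12))
    expect_equal(sum(ca$inertia_per_axis), ca$total_inertia, tolerance = 1e-12)
  }
})

test_that("CA singular values agree with an independent implementation", {
  skip_if_not_installed("MASS")
  set.seed(22)
  m <- matrix(stats::rpois(42, 10) + 1L, 6, 7,
              dimnames = list(paste0("r", 1:6), paste0("c", 1:7)))
  ca <- correspondence_analysis(m)
  ref <- MASS::corresp(m, nf = 3)
  expect_equal(sqrt(ca$inertia_per_axis[1:3]), unname(ref$cor[1:3]), tolerance = 1e-8)
  # principal row coordinates match up to the fixed sign convention
  for (a in 1:3)
    expect_equal(abs(ca$row_coords[, a]),
                 abs(ref$rscore[, a] * ref$cor[a]), tolerance = 1e-8,
                 ignore_attr = TRUE)
})

test_that("degenerate and structured tables behave as CA theory predicts", {
  # homogeneous table: zero inertia, all coordinates zero
  m <- matrix(5L, 4, 6, dimnames = list(paste0("r", 1:4), paste0("c", 1:6)))
  ca <- correspondence_analysis(m)
  expect_equal(ca$total_inertia, 0)
  expect_true(all(ca$row_coords == 0))

  # uniform scaling of the whole table leaves coordinates unchanged
  set.seed(23)
  m <- matrix(stats::rpois(30, 6) + 1L, 6, 5,
              dimnames = list(paste0("r", 1:6), paste0("c", 1:5)))
  expect_equal(correspondence_analysis(m)$row_coords,
               correspondence_analysis(m * 7L)$row_coords, tolerance = 1e-10)

  # a duplicated profile lands on the same coordinate
  m2 <- rbind(m, r_dup = m[2, ] * 3L)
  ca2 <- correspondence_analysis(m2)
  expect_equal(unname(ca2$row_coords["r_dup", ]), unname(ca2$row_coords["r2", ]),
               tolerance = 1e-9)

  # two-block matrix: axis 1 separates the blocks by sign
  blockA <- matrix(rep(c(10L, 8L, 0L, 0L), each = 3), 3, 4)
  blockB <- matrix(rep(c(0L, 0L, 9L, 11L), each = 3), 3, 4)
  m <- rbind(blockA, blockB)
  dimnames(m) <- list(paste0("g", 1:6), c("AAA", "AAC", "GGG", "GGC"))
  ca <- correspondence_analysis(m)
  s <- sign(ca$row_coords[, 1])
  expect_true(all(s[1:3] == s[1]) && all(s[4:6] == -s[1]))

  # all-zero rows are dropped and reported
  m[2, ] <- 0L
  ca <- correspondence_analysis(m)
  expect_equal(ca$dropped_rows, "g2")
  expect_equal(unname(ca$axis1["g2"]), 0)
})

test_that("axis-1 sign follows GC3", {
  set.seed(24)
  # rows preferring GC-ending codons must get positive axis-1 coordinates
  m <- rbind(matrix(rep(c(12L, 10L, 1L, 1L), each = 4), 4, 4),
             matrix(rep(c(1L, 1L, 12L, 10L), each = 4), 4, 4))
  dimnames(m) <- list(paste0("g", 1:8), c("GCT", "AAT", "GCG", "AAC"))
  ca <- correspondence_analysis(m)
  gc3 <- rowSums(m[, c("GCG", "AAC")]) / rowSums(m)
  expect_gt(stats::cor(ca$row_coords[, 1], gc3), 0)
})

test_that("host bands flag GC13 outliers and the minority codon cluster", {
  # identical composition: SD 0, everyone in band and in the host cluster
  prof <- data.frame(gene_id = sprintf("g%02d", 1:12),
                     gc13_percent = 45, ca_axis1 = 0)
  hb <- host_bands(prof)
  expect_equal(hb$gc13_sd, 0)
  expect_true(all(hb$membership$in_host_gc_band))
  expect_true(all(hb$membership$in_host_codon_cluster))

  expect_error(host_bands(prof[1:5, ]), "fewer than 10")

  # a gene at mean + 3 SD falls out of the band
  set.seed(31)
  g13 <- c(stats::rnorm(50, 45, 2), NA)
  g13[51] <- mean(g13[1:50]) + 3 * stats::sd(g13[1:50])
  g13 <- c(g13[1:51])
  prof <- data.frame(gene_id = sprintf("g%02d", 1:51),
                     gc13_percent = g13, ca_axis1 = stats::rnorm(51, 0, 0.1))
  hb <- host_bands(prof)
  expect_false(hb$membership$in_host_gc_band[51])

  # 90/10 mixture with an axis-1 gap: the implanted 10% form the non-host cluster
  prof <- data.frame(gene_id = sprintf("g%03d", 1:100),
                     gc13_percent = 45,
                     ca_axis1 = c(stats::rnorm(90, 0, 0.1), stats::rnorm(10, 2, 0.1)))
  hb <- host_bands(prof)
  expect_equal(which(!hb$membership$in_host_codon_cluster), 91:100)
})

test_that("composition profiles separate the alien minority on synthetic data", {
  sim <- default_sim()
  res <- default_result()
  prof <- res$composition$profiles
  cls <- stats::setNames(sim$genome$truth$class, sim$genome$truth$gene_id)[prof$gene_id]
  # symbiont genes sit outside the host codon cluster and above the GC13 band
  expect_gt(mean(!prof$in_host_codon_cluster[cls == "symbiont"]), 0.9)
  expect_gt(mean(prof$gc13_percent[cls == "symbiont"]),
            mean(prof$gc13_percent[cls == "host"]))
  # host genes overwhelmingly in band and cluster
  expect_gt(mean(prof$in_host_gc_band[cls == "host"]), 0.95)
  expect_gt(mean(prof$in_host_codon_cluster[cls == "host"]), 0.95)
})
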