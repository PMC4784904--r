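# Seeded synthetic-data generator. Emits a host-like genome with implanted
# transfers plus every table the screen consumes, and a truth table for
# recovery testing. Gene classes:
#   host        - vertically inherited, host composition, strong metazoan hits
#   ancient_hgt - old transfer: host composition and introns, prokaryotic
#                 protein hits, homologs in related sponges
#   recent_hgt  - young transfer surviving the contamination filters:
#                 partially ameliorated GC3, single exon, prokaryotic protein
#                 AND nucleotide hits, on long contigs
#   symbiont    - co-assembled contaminant: alien composition, single exon,
#                 lone gene on a short contig, negligible expression

#' Parameters of the synthetic study
#'
#' Defaults define the simulated study conditions: 500 host genes, 30
#' ancient and 20 recent transfers on long (60-200 kb) contigs, 40
#' symbiont genes on short (5-40 kb) contigs; host GC3 0.45 (SD 0.05),
#' fully alien GC3 0.65 (SD 0.05) for symbionts, partially ameliorated
#' GC3 0.50 for recent transfers; exon counts 1 + Poisson(4) for host and
#' ancient genes, single-exon for recent and symbiont genes; log-normal
#' expression with symbiont mean rpkm below 1; class-conditional
#' homology-search e-value ranges chosen non-overlapping so the detection
#' signal is sharp; homolog-presence probabilities 0.9 (ancient), 0.2
#' (recent), 0.05 (symbiont) per comparison transcriptome. Bit scores
#' follow bitscore = a * (-log10 e) + b with a = 2, b = 30.
#'
#' @param n_host_genes,n_ancient_hgt,n_recent_hgt,n_symbiont class sizes.
#' @param host_gc3_mean,host_gc3_sd,alien_gc3_mean,alien_gc3_sd,recent_gc3_mean,recent_gc3_sd
#'   per-gene GC3 target distributions.
#' @param codon_pref_concentration Dirichlet concentration for the
#'   class-specific synonymous-codon preferences.
#' @param long_contig_range,short_contig_range contig length ranges (bp).
#' @param exon_lambda Poisson mean for extra exons of host/ancient genes.
#' @param intron_range,n_codons_range,intergenic_range structural ranges.
#' @param expression named list of `c(meanlog, sdlog)` per class.
#' @param n_samples expression samples.
#' @param homolog_prob named list of `c(haliclona, ephydatia)` presence
#'   probabilities per class.
#' @param evolmap_fraction fraction of ancient transfers carrying the
#'   external gene-family flag.
#' @param enrichment_odds multiplier on the enriched GO term's baseline
#'   probability (0.05) for subjects best-hit by transfer/symbiont genes;
#'   1 gives a null (no enrichment) dataset.
#' @param hit_profile class-conditional log10 e-value ranges and hit
#'   counts; see defaults.
#' @param bitscore_a,bitscore_b linear map from -log10(e) to bit score.
#' @param seed integer RNG seed; every emitted byte is a deterministic
#'   function of the parameters and this seed.
#' @return a `simulation_params` list.
#' @export
simulation_params <- function(n_host_genes = 500L, n_ancient_hgt = 30L,
                              n_recent_hgt = 20L, n_symbiont = 40L,
                              host_gc3_mean = 0.45, host_gc3_sd = 0.05,
                              alien_gc3_mean = 0.65, alien_gc3_sd = 0.05,
                              recent_gc3_mean = 0.50, recent_gc3_sd = 0.05,
                              codon_pref_concentration = 2,
                              long_contig_range = c(60000L, 200000L),
                              short_contig_range = c(5000L, 40000L),
                              exon_lambda = 4,
                              intron_range = c(80L, 400L),
                              n_codons_range = c(150L, 400L),
                              intergenic_range = c(1500L, 4000L),
                              expression = list(
                                host = c(meanlog = log(30), sdlog = 0.8),
                                ancient_hgt = c(meanlog = log(60), sdlog = 0.8),
                                recent_hgt = c(meanlog = log(40), sdlog = 0.8),
                                symbiont = c(meanlog = log(0.3), sdlog = 1.0)),
                              n_samples = 4L,
                              homolog_prob = list(
                                host = c(0.95, 0.95),
                                ancient_hgt = c(0.9, 0.9),
                                recent_hgt = c(0.2, 0.2),
                                symbiont = c(0.05, 0.05)),
                              evolmap_fraction = 0.5,
                              enrichment_odds = 10,
                              hit_profile = list(
                                host = list(met_n = c(3L, 8L), met_log10e = c(-180, -80),
                                            prok_n = c(1L, 3L), prok_log10e = c(-30, -6),
                                            fungal_prob = 0.3, fungal_log10e = c(-60, -30)),
                                alien = list(prok_n = c(3L, 8L), prok_log10e = c(-150, -60),
                                             met_prob = 0.3, met_log10e = c(-4, -2)),
                                nt = list(prok_log10e = c(-185, -85),
                                          euk_log10e = c(-60, -20),
                                          euk_tile_step = 2000L, euk_tile_len = 500L,
                                          euk_tile_prob = 0.7)),
                              bitscore_a = 2, bitscore_b = 30,
                              seed = 1L) {
  p <- as.list(environment())
  counts <- c(p$n_host_genes, p$n_ancient_hgt, p$n_recent_hgt, p$n_symbiont)
  if (any(counts < 0)) stopf("class sizes must be >= 0")
  probs <- unlist(p$homolog_prob)
  if (any(probs < 0 | probs > 1)) stopf("homolog probabilities must lie in [0, 1]")
  structure(p, class = c("simulation_params", "list"))
}

gene_classes <- c("host", "ancient_hgt", "recent_hgt", "symbiont")

# --- sequence machinery ------------------------------------------------------

sample_seq <- function(n, gc) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Class-level synonymous-codon preferences: one Dirichlet draw per amino
# acid (multi-codon amino acids only), split into GC-ending and AT-ending
# thirds so a per-gene GC3 target can be imposed at sampling time.
codon_preferences <- function(concentration) {
  code <- Biostrings::GENETIC_CODE
  codons <- setdiff(names(code)[code != "*"], c("ATG", "TGG"))
  by_aa <- split(codons, code[codons])
  lapply(by_aa, function(cs) {
    w <- stats::rgamma(length(cs), shape = concentration)
    w <- w / sum(w)
    third_gc <- substr(cs, 3, 3) %in% c("G", "C")
    list(codons = cs, weights = w, third_gc = third_gc)
  })
}

# One CDS: ATG + n codons drawn from the class preferences at the gene's
# GC3 target + TAA. Amino acids uniform over the 18 multi-codon ones.
sample_cds <- function(n_codons, prefs, gc3_target) {
  aas <- names(prefs)
  aa_draw <- sample(aas, n_codons, replace = TRUE)
  use_gc <- stats::runif(n_codons) < gc3_target
  out <- character(n_codons)
  for (aa in aas) {
    pr <- prefs[[aa]]
    for (gcflag in c(TRUE, FALSE)) {
      ix <- which(aa_draw == aa & use_gc == gcflag)
      if (!length(ix)) next
      sel <- pr$third_gc == gcflag
      if (!any(sel)) sel <- !logical(length(pr$codons))
      out[ix] <- sample(pr$codons[sel], length(ix), replace = TRUE,
                        prob = pr$weights[sel])
    }
  }
  paste0("ATG", paste(out, collapse = ""), "TAA")
}

# Genomic layout of one gene: exon/intron structure around a CDS.
build_gene_body <- function(cds, exon_count, intron_range, intron_gc) {
  L <- nchar(cds)
  n_cod <- L / 3L
  if (exon_count == 1L) {
    return(list(seq = cds, exon_start = 0L, exon_end = L))
  }
  # cut the CDS at codon boundaries into exon_count pieces
  cuts <- sort(sample(seq_len(n_cod - 1L), exon_count - 1L)) * 3L
  starts <- c(0L, cuts); ends <- c(cuts, L)
  introns <- vapply(seq_len(exon_count - 1L), function(i)
    sample_seq(sample(seq(intron_range[1], intron_range[2]), 1L), intron_gc),
    character(1))
  parts <- character(0); exon_start <- integer(exon_count); exon_end <- integer(exon_count)
  pos <- 0L
  for (i in seq_len(exon_count)) {
    ex <- substring(cds, starts[i] + 1L, ends[i])
    exon_start[i] <- pos; exon_end[i] <- pos + nchar(ex)
    parts <- c(parts, ex)
    pos <- pos + nchar(ex)
    if (i < exon_count) {
      parts <- c(parts, introns[i])
      pos <- pos + nchar(introns[i])
    }
  }
  list(seq = paste(parts, collapse = ""), exon_start = exon_start, exon_end = exon_end)
}

# --- genome ------------------------------------------------------------------

#' Simulate the genome: contigs, gene models, truth table
#'
#' Host, ancient and recent genes are interleaved on long contigs with
#' host genes anchoring both contig ends (a genuine transfer sits inside
#' a host gene neighbourhood); each symbiont gene sits alone on a short
#' contig. Coding sequence is sampled codon-by-codon from class-specific
#' synonymous preferences under a per-gene GC3 target. Deterministic
#' given the seed.
#'
#' @param params a [simulation_params()].
#' @return list: `contigs` ([Biostrings::DNAStringSet]), `genes`
#'   (gene-model data.frame as in [read_gff3_genes()]), `truth`
#'   (data.frame `gene_id`, `class`).
#' @export
simulate_genome <- function(params = simulation_params()) {
  set.seed(params$seed)
  host_prefs <- codon_preferences(params$codon_pref_concentration)
  alien_prefs <- codon_preferences(params$codon_pref_concentration)

  gc3_for <- function(class) {
    m <- switch(class, host = , ancient_hgt = params$host_gc3_mean,
                recent_hgt = params$recent_gc3_mean, symbiont = params$alien_gc3_mean)
    s <- switch(class, host = , ancient_hgt = params$host_gc3_sd,
                recent_hgt = params$recent_gc3_sd, symbiont = params$alien_gc3_sd)
    min(max(stats::rnorm(1, m, s), 0.05), 0.95)
  }
  prefs_for <- function(class) if (class == "symbiont") alien_prefs else host_prefs
  exons_for <- function(class)
    if (class %in% c("host", "ancient_hgt")) 1L + stats::rpois(1, params$exon_lambda) else 1L

  make_gene <- function(class, intron_gc) {
    n_cod <- sample(seq(params$n_codons_range[1], params$n_codons_range[2]), 1L)
    cds <- sample_cds(n_cod, prefs_for(class), gc3_for(class))
    body <- build_gene_body(cds, exons_for(class), params$intron_range, intron_gc)
    c(body, list(cds = cds, class = class,
                 strand = sample(c("+", "-"), 1L)))
  }

  long_min <- params$long_contig_range[1]
  max_gene_len <- params$n_codons_range[2] * 3L + 6L +
    30L * params$intron_range[2]  # generous bound on a gene body
  if (max_gene_len + 2L * params$intergenic_range[2] > long_min &&
      params$n_host_genes + params$n_ancient_hgt + params$n_recent_hgt > 0L)
    stopf("long contigs too short for the configured gene sizes")

  # shuffled pools of genes for the long contigs
  host_pool <- rep("host", params$n_host_genes)
  impl_pool <- sample(c(rep("ancient_hgt", params$n_ancient_hgt),
                        rep("recent_hgt", params$n_recent_hgt)))
  host_gc <- 0.40; alien_gc <- 0.62

  contigs <- list(); gene_rows <- list(); truth <- list()
  gi <- 0L; li <- 0L
  add_gene <- function(class, contig_id, pos, intron_gc) {
    g <- make_gene(class, intron_gc)
    gi <<- gi + 1L
    glen <- nchar(g$seq)
    seq_fwd <- if (g$strand == "-") revcomp(g$seq) else g$seq
    if (g$strand == "-") {
      es <- glen - rev(g$exon_end); ee <- glen - rev(g$exon_start)
    } else {
      es <- g$exon_start; ee <- g$exon_end
    }
    gene_rows[[gi]] <<- list(contig_id = contig_id, strand = g$strand,
                             offset = pos, exon_start = es, exon_end = ee,
                             cds = g$cds, class = g$class, len = glen,
                             seq = seq_fwd)
    glen
  }

  while (length(host_pool) + length(impl_pool) > 0L) {
    li <- li + 1L
    cid <- sprintf("contig_long_%03d", li)
    target <- round(stats::runif(1, long_min, params$long_contig_range[2]))
    parts <- character(0); pos <- 0L
    placed_classes <- character(0)
    repeat {
      gap <- round(stats::runif(1, params$intergenic_range[1], params$intergenic_range[2]))
      # choose the next class; implanted genes never open or close a contig
      n_h <- length(host_pool); n_i <- length(impl_pool)
      if (n_h + n_i == 0L) break
      room_after <- target - pos - gap - max_gene_len
      take_impl <- n_i > 0L && length(placed_classes) > 0L && n_h > 0L &&
        stats::runif(1) < n_i / (n_h + n_i) * 3 &&
        room_after > max_gene_len + params$intergenic_range[2]
      class <- if (take_impl) impl_pool[1] else if (n_h > 0L) host_pool[1] else impl_pool[1]
      # stop if even this gene will not fit before the end margin
      g_est <- max_gene_len
      if (pos + gap + g_est > target - params$intergenic_range[1] &&
          length(placed_classes) > 0L) break
      gseq <- sample_seq(gap, host_gc)
      glen <- add_gene(class, cid, pos + gap, host_gc)
      parts <- c(parts, gseq, gene_rows[[gi]]$seq)
      pos <- pos + gap + glen
      placed_classes <- c(placed_classes, class)
      if (take_impl) impl_pool <- impl_pool[-1] else if (n_h > 0L) host_pool <- host_pool[-1] else impl_pool <- impl_pool[-1]
    }
    # close the contig with a host gene if an implanted gene is last
    if (length(placed_classes) && utils::tail(placed_classes, 1) != "host" &&
        length(host_pool) > 0L) {
      gap <- round(stats::runif(1, params$intergenic_range[1], params$intergenic_range[2]))
      gseq <- sample_seq(gap, host_gc)
      glen <- add_gene("host", cid, pos + gap, host_gc)
      parts <- c(parts, gseq, gene_rows[[gi]]$seq)
      pos <- pos + gap + glen
      host_pool <- host_pool[-1]
    }
    pad <- max(target - pos, params$intergenic_range[1])
    parts <- c(parts, sample_seq(pad, host_gc))
    contigs[[cid]] <- paste(parts, collapse = "")
    if (li > 10000L) stopf("contig placement failed to terminate")
  }

  max_sym_len <- params$n_codons_range[2] * 3L + 6L  # single exon, no introns
  for (si in seq_len(params$n_symbiont)) {
    cid <- sprintf("contig_short_%03d", si)
    target <- round(stats::runif(1, params$short_contig_range[1],
                                 params$short_contig_range[2]))
    lead <- round(stats::runif(1, 200, max(201, target - max_sym_len - 200)))
    glen <- add_gene("symbiont", cid, lead, alien_gc)
    tail_len <- max(target - lead - glen, 200L)
    contigs[[cid]] <- paste0(sample_seq(lead, alien_gc),
                             gene_rows[[gi]]$seq,
                             sample_seq(tail_len, alien_gc))
  }

  # stable ids in (contig, position) order
  ord <- order_c(vapply(gene_rows, `[[`, character(1), "contig_id"),
                 vapply(gene_rows, function(g) g$offset, numeric(1)))
  genes <- lapply(seq_along(ord), function(i) {
    g <- gene_rows[[ord[i]]]
    id <- sprintf("g%04d", i)
    es <- g$offset + g$exon_start; ee <- g$offset + g$exon_end
    list(gene_id = id, contig_id = g$contig_id, strand = g$strand,
         start = min(es), end = max(ee), exon_count = length(es),
         exons = data.frame(start = es, end = ee),
         cds = g$cds, class = g$class)
  })
  peptides <- sub("\\*$", "", as.character(
    Biostrings::translate(Biostrings::DNAStringSet(
      vapply(genes, `[[`, character(1), "cds")))))
  gdf <- data.frame(
    gene_id = vapply(genes, `[[`, character(1), "gene_id"),
    contig_id = vapply(genes, `[[`, character(1), "contig_id"),
    strand = vapply(genes, `[[`, character(1), "strand"),
    start = vapply(genes, `[[`, numeric(1), "start"),
    end = vapply(genes, `[[`, numeric(1), "end"),
    exon_count = vapply(genes, `[[`, integer(1), "exon_count"),
    cds = vapply(genes, `[[`, character(1), "cds"),
    peptide = peptides,
    cds_ok = TRUE,
    stringsAsFactors = FALSE
  )
  gdf$exons <- lapply(genes, `[[`, "exons")
  truth <- data.frame(gene_id = gdf$gene_id,
                      class = vapply(genes, `[[`, character(1), "class"),
                      stringsAsFactors = FALSE)
  cs <- Biostrings::DNAStringSet(unlist(contigs))
  list(contigs = cs, genes = gdf, truth = truth)
}

# --- hit tables --------------------------------------------------------------

log10e_to_bits <- function(l10e, params) params$bitscore_a * (-l10e) + params$bitscore_b

draw_evalue <- function(n, range) 10^stats::runif(n, range[1], range[2])

#' Simulate homology-search result tables from the truth table
#'
#' Hit tables are generated parametrically from the true class of each
#' gene (the screen's contract is over tabular search results): host
#' genes receive strong metazoan plus weaker prokaryotic protein hits;
#' transfer and symbiont genes receive strong prokaryotic hits with at
#' most weak (above-threshold) metazoan ones; recent transfers and
#' symbionts additionally receive strong prokaryotic nucleotide hits over
#' their genomic loci, and long contigs carry a background tiling of
#' eukaryotic nucleotide hits. E-values are drawn log-uniformly within
#' class ranges; bit scores follow the documented linear map.
#'
#' @param genome list from [simulate_genome()].
#' @param params a [simulation_params()].
#' @return list: `protein_hits` (taxon-labelled), `nt_prok_hits`,
#'   `nt_euk_hits`, `sponge_hits` (list `haliclona`, `ephydatia`),
#'   `taxon_map` (subject lineage data.frame with `taxon_key`).
#' @export
simulate_hit_tables <- function(genome, params = simulation_params()) {
  set.seed(params$seed + 1L)
  genes <- genome$genes
  cls <- stats::setNames(genome$truth$class, genome$truth$gene_id)

  met_phyla <- c("Porifera", "Cnidaria", "Chordata")
  prok_phyla <- c(Bacteria = "Proteobacteria", Bacteria = "Firmicutes",
                  Bacteria = "Actinobacteria", Bacteria = "Bacteroidetes",
                  Archaea = "Euryarchaeota")
  subjects <- rbind(
    data.frame(subject_id = sprintf("MET_%03d", 1:120),
               superkingdom = "Eukaryota",
               phylum = rep(met_phyla, length.out = 120),
               is_metazoan = TRUE, stringsAsFactors = FALSE),
    data.frame(subject_id = sprintf("PROK_%03d", 1:150),
               superkingdom = rep(names(prok_phyla), length.out = 150),
               phylum = rep(unname(prok_phyla), length.out = 150),
               is_metazoan = FALSE, stringsAsFactors = FALSE),
    data.frame(subject_id = sprintf("FUNG_%03d", 1:40),
               superkingdom = "Eukaryota", phylum = "Ascomycota",
               is_metazoan = FALSE, stringsAsFactors = FALSE)
  )
  subjects$taxon_key <- sprintf("t%04d", seq_len(nrow(subjects)))
  pool <- function(prefix) subjects$subject_id[startsWith(subjects$subject_id, prefix)]

  hp <- params$hit_profile
  mk_hits <- function(gid, sids, l10e, plen) {
    n <- length(sids)
    if (!n) return(NULL)
    alen <- pmax(30L, round(plen * stats::runif(n, 0.5, 0.95)))
    qs <- pmax(0L, round(stats::runif(n, 0, plen - alen)))
    data.frame(query_id = gid, subject_id = sids,
               percent_identity = stats::runif(n, 0.35, 0.95),
               align_length = alen, q_start = qs, q_end = qs + alen,
               evalue = 10^l10e, bitscore = log10e_to_bits(l10e, params),
               stringsAsFactors = FALSE)
  }

  prot <- list()
  for (i in seq_len(nrow(genes))) {
    gid <- genes$gene_id[i]
    plen <- nchar(genes$peptide[i])
    if (cls[gid] == "host") {
      nm <- sample(seq(hp$host$met_n[1], hp$host$met_n[2]), 1L)
      np <- sample(seq(hp$host$prok_n[1], hp$host$prok_n[2]), 1L)
      h <- rbind(
        mk_hits(gid, sample(pool("MET"), nm), stats::runif(nm, hp$host$met_log10e[1], hp$host$met_log10e[2]), plen),
        mk_hits(gid, sample(pool("PROK"), np), stats::runif(np, hp$host$prok_log10e[1], hp$host$prok_log10e[2]), plen),
        if (stats::runif(1) < hp$host$fungal_prob)
          mk_hits(gid, sample(pool("FUNG"), 1L), stats::runif(1, hp$host$fungal_log10e[1], hp$host$fungal_log10e[2]), plen)
      )
    } else {
      np <- sample(seq(hp$alien$prok_n[1], hp$alien$prok_n[2]), 1L)
      h <- rbind(
        mk_hits(gid, sample(pool("PROK"), np), stats::runif(np, hp$alien$prok_log10e[1], hp$alien$prok_log10e[2]), plen),
        if (cls[gid] != "symbiont" && stats::runif(1) < hp$alien$met_prob)
          mk_hits(gid, sample(pool("MET"), 1L), stats::runif(1, hp$alien$met_log10e[1], hp$alien$met_log10e[2]), plen)
      )
    }
    prot[[gid]] <- h
  }
  protein_hits <- do.call(rbind, c(prot, list(make.row.names = FALSE)))
  idx <- match(protein_hits$subject_id, subjects$subject_id)
  protein_hits$superkingdom <- subjects$superkingdom[idx]
  protein_hits$phylum <- subjects$phylum[idx]
  protein_hits$is_metazoan <- subjects$is_metazoan[idx]

  # nucleotide hits: query ids are contig ids, coordinates on the contig
  nt_prok <- list()
  nt_targets <- genes[cls[genes$gene_id] %in% c("recent_hgt", "symbiont"), , drop = FALSE]
  for (i in seq_len(nrow(nt_targets))) {
    g <- nt_targets[i, ]
    l10e <- stats::runif(1, hp$nt$prok_log10e[1], hp$nt$prok_log10e[2])
    span <- as.integer(g$end - g$start)
    rows <- data.frame(query_id = g$contig_id,
                       subject_id = sprintf("NTP_%04d", i),
                       percent_identity = stats::runif(1, 0.7, 0.95),
                       align_length = span,
                       q_start = as.integer(g$start), q_end = as.integer(g$end),
                       evalue = 10^l10e, bitscore = log10e_to_bits(l10e, params),
                       stringsAsFactors = FALSE)
    if (stats::runif(1) < 0.5 && span > 200L) {
      sub_len <- round(span * stats::runif(1, 0.3, 0.6))
      ss <- as.integer(g$start) + sample.int(span - sub_len, 1L)
      l2 <- stats::runif(1, hp$nt$prok_log10e[1], hp$nt$prok_log10e[2])
      rows <- rbind(rows, data.frame(query_id = g$contig_id,
                                     subject_id = sprintf("NTP_%04d_b", i),
                                     percent_identity = stats::runif(1, 0.7, 0.95),
                                     align_length = sub_len,
                                     q_start = ss, q_end = ss + sub_len,
                                     evalue = 10^l2, bitscore = log10e_to_bits(l2, params),
                                     stringsAsFactors = FALSE))
    }
    nt_prok[[i]] <- rows
  }
  nt_prok_hits <- if (length(nt_prok)) do.call(rbind, c(nt_prok, list(make.row.names = FALSE)))
                  else empty_hit_frame(FALSE)

  nt_euk <- list()
  long_ids <- names(genome$contigs)[startsWith(names(genome$contigs), "contig_long")]
  for (cid in long_ids) {
    clen <- Biostrings::width(genome$contigs[cid])
    starts <- seq.int(0L, max(0L, clen - hp$nt$euk_tile_len), by = hp$nt$euk_tile_step)
    keep <- stats::runif(length(starts)) < hp$nt$euk_tile_prob
    starts <- starts[keep]
    if (!length(starts)) next
    l10e <- stats::runif(length(starts), hp$nt$euk_log10e[1], hp$nt$euk_log10e[2])
    nt_euk[[cid]] <- data.frame(query_id = cid,
                                subject_id = sprintf("NTE_%s_%04d", cid, seq_along(starts)),
                                percent_identity = stats::runif(length(starts), 0.6, 0.9),
                                align_length = hp$nt$euk_tile_len,
                                q_start = starts, q_end = starts + hp$nt$euk_tile_len,
                                evalue = 10^l10e, bitscore = log10e_to_bits(l10e, params),
                                stringsAsFactors = FALSE)
  }
  nt_euk_hits <- if (length(nt_euk)) do.call(rbind, c(nt_euk, list(make.row.names = FALSE)))
                 else empty_hit_frame(FALSE)

  sponge <- function(which_col, prefix) {
    pr <- vapply(params$homolog_prob, `[`, numeric(1), which_col)
    present <- stats::runif(nrow(genes)) < pr[cls[genes$gene_id]]
    gid <- genes$gene_id[present]
    if (!length(gid)) return(empty_hit_frame(FALSE))
    l10e <- stats::runif(length(gid), -50, -10)
    plen <- nchar(genes$peptide)[present]
    alen <- pmax(30L, round(plen * stats::runif(length(gid), 0.5, 0.9)))
    data.frame(query_id = gid,
               subject_id = sprintf("%s_%04d", prefix, seq_along(gid)),
               percent_identity = stats::runif(length(gid), 0.4, 0.9),
               align_length = alen, q_start = 0L, q_end = alen,
               evalue = 10^l10e, bitscore = log10e_to_bits(l10e, params),
               stringsAsFactors = FALSE)
  }
  sponge_hits <- list(haliclona = sponge(1L, "HAMB"),
                      ephydatia = sponge(2L, "EMUE"))

  list(protein_hits = protein_hits, nt_prok_hits = nt_prok_hits,
       nt_euk_hits = nt_euk_hits, sponge_hits = sponge_hits,
       taxon_map = subjects)
}

# --- auxiliary tables --------------------------------------------------------

#' Simulate expression, GO annotations and external gene-family flags
#'
#' Expression is class-conditional log-normal (symbiont genes essentially
#' silent). GO terms are attached to homology-search subjects so the
#' screen's best-hit annotation transfer is exercised end-to-end: every
#' best-hit subject carries two background terms, and one designated term
#' is enriched among subjects matched by transfer/symbiont genes at
#' `enrichment_odds` times its 0.05 baseline probability. The external
#' gene-family route flags a parameterized fraction of ancient
#' transfers.
#'
#' @param genome list from [simulate_genome()].
#' @param hit_tables list from [simulate_hit_tables()].
#' @param params a [simulation_params()].
#' @return list: `expression` (data.frame), `go_map` (named list,
#'   subject id -> terms), `evolmap_flags` (named logical vector),
#'   `enriched_term` (the designated term id).
#' @export
simulate_tables <- function(genome, hit_tables, params = simulation_params()) {
  set.seed(params$seed + 2L)
  truth <- genome$truth
  cls <- stats::setNames(truth$class, truth$gene_id)

  samples <- c(sprintf("larva_%d", seq_len(ceiling(params$n_samples / 2))),
               sprintf("adult_%d", seq_len(floor(params$n_samples / 2))))
  expr <- data.frame(gene_id = truth$gene_id, stringsAsFactors = FALSE)
  for (s in samples) {
    ml <- vapply(params$expression, `[`, numeric(1), 1L)[cls[truth$gene_id]]
    sl <- vapply(params$expression, `[`, numeric(1), 2L)[cls[truth$gene_id]]
    expr[[s]] <- stats::rlnorm(nrow(truth), meanlog = ml, sdlog = sl)
  }

  # best-hit subject per gene, same tie-break as the annotation transfer
  h <- hit_tables$protein_hits
  h <- h[order_c(h$evalue, -h$bitscore, h$subject_id), , drop = FALSE]
  best <- h[!duplicated(h$query_id), c("query_id", "subject_id")]
  enriched_term <- "GO:9990001"
  background_terms <- sprintf("GO:%07d", 1:15)
  p_base <- 0.05
  go_map <- list()
  for (i in seq_len(nrow(best))) {
    gid <- best$query_id[i]; sid <- best$subject_id[i]
    if (!is.null(go_map[[sid]])) next
    terms <- sample(background_terms, 2L)
    p_enr <- if (cls[gid] == "host") p_base else min(1, p_base * params$enrichment_odds)
    if (stats::runif(1) < p_enr) terms <- c(terms, enriched_term)
    go_map[[sid]] <- sort(terms)
  }

  anc <- truth$gene_id[truth$class == "ancient_hgt"]
  flagged <- anc[stats::runif(length(anc)) < params$evolmap_fraction]
  evolmap <- stats::setNames(truth$gene_id %in% flagged, truth$gene_id)

  list(expression = expr, go_map = go_map, evolmap_flags = evolmap,
       enriched_term = enriched_term)
}

#' Simulate the complete study
#'
#' @param params a [simulation_params()].
#' @return list with `genome`, `hit_tables`, `tables`, and `inputs` — the
#'   latter ready to pass to [run_pipeline()].
#' @export
simulate_all <- function(params = simulation_params()) {
  genome <- simulate_genome(params)
  hit_tables <- simulate_hit_tables(genome, params)
  tables <- simulate_tables(genome, hit_tables, params)
  inputs <- list(contigs = genome$contigs, genes = genome$genes,
                 protein_hits = hit_tables$protein_hits,
                 nt_prok_hits = hit_tables$nt_prok_hits,
                 nt_euk_hits = hit_tables$nt_euk_hits,
                 expression = tables$expression,
                 sponge_hits = hit_tables$sponge_hits,
                 evolmap_flags = tables$evolmap_flags)
  list(genome = genome, hit_tables = hit_tables, tables = tables,
       inputs = inputs)
}

#' Write a simulated study to disk in the screen's external formats
#'
#' Emits contig/CDS/peptide FASTA, gene-model GFF3, the 12-column hit
#' tables, the two-file taxon map, expression/GO/flag TSVs, the truth
#' table, and the run configuration. Output is byte-deterministic given
#' the parameters.
#'
#' @param sim list from [simulate_all()].
#' @param dir output directory (created if needed).
#' @param config a [pipeline_config()] to write alongside.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir, config = pipeline_config()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  g <- sim$genome
  write_fasta(g$contigs, p("contigs.fasta"))
  write_fasta(stats::setNames(g$genes$cds, g$genes$gene_id), p("cds.fasta"))
  write_fasta(stats::setNames(g$genes$peptide, g$genes$gene_id), p("peptides.fasta"))
  write_gff3_genes(g$genes, p("genes.gff3"))
  write_hit_table(sim$hit_tables$protein_hits, p("protein_hits.tsv"))
  write_hit_table(sim$hit_tables$nt_prok_hits, p("nt_prok_hits.tsv"))
  write_hit_table(sim$hit_tables$nt_euk_hits, p("nt_euk_hits.tsv"))
  write_hit_table(sim$hit_tables$sponge_hits$haliclona, p("sponge_haliclona.tsv"))
  write_hit_table(sim$hit_tables$sponge_hits$ephydatia, p("sponge_ephydatia.tsv"))
  tm <- sim$hit_tables$taxon_map
  utils::write.table(tm[, c("subject_id", "taxon_key")], p("taxon_subjects.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(unique(tm[, c("taxon_key", "superkingdom", "phylum", "is_metazoan")]),
                     p("taxon_lineage.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  ex <- sim$tables$expression
  num <- vapply(ex, is.numeric, logical(1))
  for (j in which(num)) ex[[j]] <- signif(ex[[j]], 6)
  utils::write.table(ex, p("expression.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  gm <- sim$tables$go_map
  go_df <- data.frame(id = rep(names(gm), lengths(gm)),
                      term_id = unlist(gm, use.names = FALSE))
  go_df <- go_df[order_c(go_df$id, go_df$term_id), ]
  utils::write.table(go_df, p("go_map.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  ev <- data.frame(gene_id = names(sim$tables$evolmap_flags),
                   flag = unname(sim$tables$evolmap_flags))
  utils::write.table(ev, p("evolmap_flags.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$genome$truth, p("truth.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write_config(config, p("config.yaml"))
  invisible(dir)
}

#' Load a simulated study written by [write_simulation()]
#'
#' @param dir directory written by [write_simulation()].
#' @return list of pipeline inputs (see [run_pipeline()]) plus `truth`
#'   and `config`.
#' @export
load_simulation <- function(dir) {
  p <- function(f) file.path(dir, f)
  contigs <- read_fasta(p("contigs.fasta"))
  genes <- read_gff3_genes(p("genes.gff3"), contigs)
  tmap <- read_taxon_map(p("taxon_subjects.tsv"), p("taxon_lineage.tsv"))
  truth <- utils::read.delim(p("truth.tsv"), stringsAsFactors = FALSE)
  config <- read_config(p("config.yaml"))
  list(contigs = contigs, genes = genes,
       protein_hits = read_hit_table(p("protein_hits.tsv"), tmap),
       nt_prok_hits = read_hit_table(p("nt_prok_hits.tsv")),
       nt_euk_hits = read_hit_table(p("nt_euk_hits.tsv")),
       expression = read_expression(p("expression.tsv")),
       sponge_hits = list(haliclona = read_hit_table(p("sponge_haliclona.tsv")),
                          ephydatia = read_hit_table(p("sponge_ephydatia.tsv"))),
       evolmap_flags = read_flag_table(p("evolmap_flags.tsv"), genes$gene_id),
       go_map = read_term_map(p("go_map.tsv")),
       truth = truth, config = config)
}
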