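#' Read gene models from a GFF3 file
#'
#' Parses gene/mRNA/exon/CDS features (via \pkg{rtracklayer}), converts the
#' on-disk 1-based inclusive coordinates to the package's internal 0-based
#' half-open convention, and splices each model's CDS from the supplied
#' contigs, reverse-complementing minus-strand models. Models whose CDS
#' length is not divisible by 3 are kept and flagged (`cds_ok = FALSE`)
#' rather than dropped; their peptide is `NA`.
#'
#' @param path GFF3 file.
#' @param contigs named [Biostrings::DNAStringSet] (or character vector) of
#'   the contig sequences the models refer to.
#' @return a data.frame with one row per gene: `gene_id`, `contig_id`,
#'   `strand`, `start`, `end` (0-based half-open span), `exon_count`,
#'   `exons` (list column of data.frames with 0-based half-open
#'   `start`/`end`), `cds`, `peptide`, `cds_ok`.
#' @export
read_gff3_genes <- function(path, contigs) {
  if (!file.exists(path)) stopf("GFF3 file not found: %s", path)
  if (is.character(contigs)) contigs <- Biostrings::DNAStringSet(contigs)
  gr <- rtracklayer::import(path, format = "gff3")
  typ <- as.character(gr$type)
  ids <- as.character(gr$ID)
  parent <- vapply(gr$Parent, function(p) if (length(p)) p[[1]] else NA_character_,
                   character(1))

  # Map each CDS segment up to its gene id (CDS -> mRNA -> gene, or CDS -> gene).
  feat_parent <- stats::setNames(parent, ids)
  gene_ids <- ids[typ == "gene"]
  to_gene <- function(p) {
    while (!is.na(p) && !(p %in% gene_ids) && p %in% names(feat_parent))
      p <- feat_parent[[p]]
    p
  }
  cds_idx <- which(typ == "CDS")
  if (!length(cds_idx)) stopf("no CDS features in %s", path)
  cds_gene <- vapply(parent[cds_idx], to_gene, character(1))
  if (anyNA(cds_gene)) stopf("CDS feature without a resolvable gene parent in %s", path)

  clens <- stats::setNames(Biostrings::width(contigs), names(contigs))
  rows <- lapply(split(cds_idx, cds_gene), function(ix) {
    g <- gr[ix]
    contig <- as.character(GenomicRanges::seqnames(g))[1]
    strand <- as.character(GenomicRanges::strand(g))[1]
    if (!(contig %in% names(clens)))
      stopf("gene %s refers to unknown contig %s", cds_gene[[as.character(ix[1])]] %||% "?", contig)
    s0 <- GenomicRanges::start(g) - 1L   # to 0-based half-open
    e0 <- GenomicRanges::end(g)
    o <- order_c(s0)
    s0 <- s0[o]; e0 <- e0[o]
    gid <- to_gene(parent[ix[1]])
    if (any(s0 < 0L) || any(e0 > clens[[contig]]))
      stopf("gene %s has exons outside the bounds of contig %s", gid, contig)
    if (any(utils::head(e0, -1) > utils::tail(s0, -1)))
      stopf("gene %s has overlapping exons", gid)
    parts <- substring(as.character(contigs[[contig]]), s0 + 1L, e0)
    cds <- paste0(parts, collapse = "")
    if (strand == "-") cds <- revcomp(cds)
    list(gene_id = gid, contig_id = contig, strand = strand,
         start = min(s0), end = max(e0), exon_count = length(s0),
         exons = data.frame(start = s0, end = e0),
         cds = cds, cds_ok = nchar(cds) %% 3L == 0L)
  })
  rows <- rows[order_c(vapply(rows, `[[`, character(1), "gene_id"))]
  cds_all <- vapply(rows, `[[`, character(1), "cds")
  ok_all <- vapply(rows, `[[`, logical(1), "cds_ok") & nchar(cds_all) > 0L
  peptides <- rep(NA_character_, length(rows))
  if (any(ok_all))
    peptides[ok_all] <- sub("\\*$", "", as.character(
      Biostrings::translate(Biostrings::DNAStringSet(cds_all[ok_all]),
                            if.fuzzy.codon = "X")))
  out <- data.frame(
    gene_id = vapply(rows, `[[`, character(1), "gene_id"),
    contig_id = vapply(rows, `[[`, character(1), "contig_id"),
    strand = vapply(rows, `[[`, character(1), "strand"),
    start = vapply(rows, `[[`, numeric(1), "start"),
    end = vapply(rows, `[[`, numeric(1), "end"),
    exon_count = vapply(rows, `[[`, integer(1), "exon_count"),
    cds = cds_all,
    peptide = peptides,
    cds_ok = vapply(rows, `[[`, logical(1), "cds_ok"),
    stringsAsFactors = FALSE
  )
  out$exons <- lapply(rows, `[[`, "exons")
  rownames(out) <- NULL
  if (any(!out$cds_ok))
    warnf("%d gene model(s) have CDS length not divisible by 3 (flagged, kept)",
          sum(!out$cds_ok))
  out
}

#' Write gene models to GFF3
#'
#' Inverse of [read_gff3_genes()]: internal 0-based half-open exon intervals
#' are emitted as 1-based inclusive gene/mRNA/exon/CDS features.
#'
#' @param genes gene-model data.frame as returned by [read_gff3_genes()] or
#'   [simulate_genome()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_gff3_genes <- function(genes, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  o <- order_c(genes$contig_id, genes$start)
  for (i in o) {
    g <- genes[i, ]
    ex <- g$exons[[1]]
    line <- function(type, s0, e0, phase, attrs)
      sprintf("%s\talienscreen\t%s\t%d\t%d\t.\t%s\t%s\t%s",
              g$contig_id, type, as.integer(s0) + 1L, as.integer(e0),
              g$strand, phase, attrs)
    writeLines(line("gene", g$start, g$end, ".", sprintf("ID=%s", g$gene_id)), con)
    mid <- sprintf("%s.t1", g$gene_id)
    writeLines(line("mRNA", g$start, g$end, ".",
                    sprintf("ID=%s;Parent=%s", mid, g$gene_id)), con)
    # phase: bases of preceding CDS, in translation order
    n <- nrow(ex)
    tr <- if (g$strand == "-") rev(seq_len(n)) else seq_len(n)
    cum <- cumsum(c(0L, (ex$end - ex$start)[tr]))[seq_len(n)]
    phase <- (3L - cum %% 3L) %% 3L
    phase_by_row <- integer(n); phase_by_row[tr] <- phase
    for (j in seq_len(n)) {
      writeLines(line("exon", ex$start[j], ex$end[j], ".",
                      sprintf("ID=%s.e%d;Parent=%s", g$gene_id, j, mid)), con)
      writeLines(line("CDS", ex$start[j], ex$end[j],
                      as.character(phase_by_row[j]),
                      sprintf("ID=%s.c%d;Parent=%s", g$gene_id, j, mid)), con)
    }
  }
  invisible(path)
}
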