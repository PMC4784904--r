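#' Mask low-complexity sequence by windowed entropy
#'
#' Slides a window along the sequence (stride 1) and masks every window
#' whose Shannon entropy over mononucleotide frequencies falls below the
#' threshold; overlapping masked windows are merged. Non-ACGT characters
#' are excluded from the frequency tally; a window with no unambiguous
#' bases is masked. Sequences shorter than the window are assessed as a
#' single window.
#'
#' @param sequence DNA string.
#' @param window window length in bp.
#' @param entropy_threshold minimum entropy in bits to stay unmasked.
#' @return data.frame of merged masked intervals `start`, `end`
#'   (0-based half-open); zero rows when nothing is masked.
#' @export
mask_low_complexity <- function(sequence, window = 64L, entropy_threshold = 1.5) {
  n <- nchar(sequence)
  if (n == 0L) return(data.frame(start = integer(), end = integer()))
  w <- min(as.integer(window), n)
  x <- Biostrings::DNAString(sequence)
  # per-position indicators -> windowed counts via lagged cumulative sums
  v <- strsplit(as.character(x), "", fixed = TRUE)[[1]]
  ent <- windowed_entropy(v, w)
  low <- which(ent < entropy_threshold)
  if (!length(low)) return(data.frame(start = integer(), end = integer()))
  ir <- IRanges::reduce(IRanges::IRanges(start = low, width = w))
  data.frame(start = IRanges::start(ir) - 1L,
             end = pmin(IRanges::end(ir), n))
}

windowed_entropy <- function(bases, w) {
  n <- length(bases)
  counts <- vapply(c("A", "C", "G", "T"), function(b) {
    cs <- cumsum(bases == b)
    cs[w:n] - c(0, cs)[seq_len(n - w + 1L)]
  }, numeric(n - w + 1L))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1L)
  tot <- rowSums(counts)
  xlx <- counts * log2(pmax(counts, 1))
  ifelse(tot > 0, log2(tot) - rowSums(xlx) / tot, 0)
}

#' Partition a contig into consecutive windows
#'
#' Non-overlapping `[i*w, (i+1)*w)` windows covering the contig exactly
#' once, the last window truncated, each annotated with the fraction of
#' its length covered by mask intervals.
#'
#' @param contig_length contig length in bp (> 0).
#' @param window_size window width in bp.
#' @param mask_intervals data.frame from [mask_low_complexity()] (may have
#'   zero rows).
#' @return data.frame `start`, `end` (0-based half-open),
#'   `masked_fraction`.
#' @export
make_windows <- function(contig_length, window_size = 1000L, mask_intervals = NULL) {
  if (contig_length <= 0L) stopf("contig length must be > 0")
  starts <- seq.int(0L, contig_length - 1L, by = window_size)
  ends <- pmin(starts + window_size, contig_length)
  mf <- numeric(length(starts))
  if (!is.null(mask_intervals) && nrow(mask_intervals)) {
    wir <- IRanges::IRanges(start = starts + 1L, end = ends)
    mir <- IRanges::reduce(IRanges::IRanges(start = mask_intervals$start + 1L,
                                            end = mask_intervals$end))
    ov <- IRanges::findOverlaps(wir, mir)
    if (length(ov)) {
      inter <- IRanges::pintersect(wir[S4Vectors::queryHits(ov)],
                                   mir[S4Vectors::subjectHits(ov)])
      cov <- tapply(IRanges::width(inter), S4Vectors::queryHits(ov), sum)
      mf[as.integer(names(cov))] <- as.numeric(cov)
    }
  }
  data.frame(start = starts, end = ends,
             masked_fraction = mf / (ends - starts))
}

#' Score windows with the best prokaryotic and eukaryotic nucleotide hits
#'
#' Each hit at or below the significance threshold is assigned to every
#' window it overlaps by at least 1 bp; a window's score on each side is
#' the maximum bit score among its hits. A window is harvested when it has
#' a prokaryotic hit whose bit score strictly exceeds the eukaryotic score
#' (absent eukaryotic hit counts as no competition), unless more than half
#' the window is masked.
#'
#' @param windows data.frame from [make_windows()].
#' @param prok_hits,euk_hits hit data.frames with `q_start`/`q_end` on the
#'   contig (0-based half-open), `evalue`, `bitscore`.
#' @param contig_length contig length, for coordinate validation.
#' @param evalue_threshold nucleotide-search significance cutoff.
#' @return `windows` with `best_prok`, `best_euk` (NA when absent) and
#'   `harvested` added.
#' @export
score_windows <- function(windows, prok_hits, euk_hits, contig_length,
                          evalue_threshold = 1e-5) {
  for (h in list(prok_hits, euk_hits))
    if (nrow(h) && (any(h$q_start < 0) || any(h$q_end > contig_length)))
      stopf("hit coordinates outside contig bounds")
  best_side <- function(hits) {
    best <- rep(NA_real_, nrow(windows))
    hits <- hits[hits$evalue <= evalue_threshold, , drop = FALSE]
    if (!nrow(hits)) return(best)
    wir <- IRanges::IRanges(start = windows$start + 1L, end = windows$end)
    hir <- IRanges::IRanges(start = hits$q_start + 1L, end = hits$q_end)
    ov <- IRanges::findOverlaps(wir, hir)
    if (length(ov)) {
      mx <- tapply(hits$bitscore[S4Vectors::subjectHits(ov)],
                   S4Vectors::queryHits(ov), max)
      best[as.integer(names(mx))] <- as.numeric(mx)
    }
    best
  }
  windows$best_prok <- best_side(prok_hits)
  windows$best_euk <- best_side(euk_hits)
  windows$harvested <- !is.na(windows$best_prok) &
    (is.na(windows$best_euk) | windows$best_prok > windows$best_euk) &
    windows$masked_fraction <= 0.5
  windows
}

#' Merge harvested windows into candidate regions and flag genes
#'
#' Maximal runs of consecutive harvested windows become candidate regions.
#' A region's prokaryotic-similarity length is the length of the union of
#' qualifying prokaryotic alignment intervals clipped to the region; its
#' bit-score difference is the maximum over member windows of
#' best_prok - best_euk (missing eukaryotic score treated as 0). A region
#' is flagged when similarity length > `min_region_length`, difference >
#' `min_bitscore_diff`, and the contig is longer than
#' `min_contig_length`. A gene is flagged when it overlaps a flagged
#' region by at least 1 bp.
#'
#' @param scored data.frame from [score_windows()] for one contig.
#' @param prok_hits prokaryotic hit data.frame for the same contig.
#' @param contig_id,contig_length contig identity and length.
#' @param genes gene-model data.frame (only rows on this contig are used).
#' @param config a [pipeline_config()].
#' @return list: `regions` data.frame (`contig_id`, `start`, `end`,
#'   `prok_similarity_length`, `bitscore_diff`, `gene_ids`
#'   comma-separated, `flagged_nt`) and `flagged_genes` character vector.
#' @export
merge_and_flag <- function(scored, prok_hits, contig_id, contig_length,
                           genes, config = pipeline_config()) {
  empty <- list(regions = data.frame(contig_id = character(), start = integer(),
                                     end = integer(), prok_similarity_length = integer(),
                                     bitscore_diff = numeric(), gene_ids = character(),
                                     flagged_nt = logical(), stringsAsFactors = FALSE),
                flagged_genes = character())
  hv <- which(scored$harvested)
  if (!length(hv)) return(empty)
  runs <- split(hv, cumsum(c(1L, diff(hv) != 1L)))
  q <- prok_hits[prok_hits$evalue <= config$evalue_threshold_protein, , drop = FALSE]
  g_here <- genes[genes$contig_id == contig_id, , drop = FALSE]
  rows <- lapply(runs, function(ix) {
    rs <- scored$start[ix[1]]; re <- scored$end[ix[length(ix)]]
    cl <- clip_intervals(q$q_start, q$q_end, rs, re)
    psl <- interval_union_length(cl$start, cl$end)
    diffs <- scored$best_prok[ix] - ifelse(is.na(scored$best_euk[ix]), 0, scored$best_euk[ix])
    bsd <- max(diffs)
    flag <- psl > config$min_region_length && bsd > config$min_bitscore_diff &&
      contig_length > config$min_contig_length
    gids <- g_here$gene_id[g_here$start < re & g_here$end > rs]
    data.frame(contig_id = contig_id, start = rs, end = re,
               prok_similarity_length = psl, bitscore_diff = bsd,
               gene_ids = paste(sort(gids), collapse = ","),
               flagged_nt = flag, stringsAsFactors = FALSE)
  })
  regions <- do.call(rbind, rows)
  rownames(regions) <- NULL
  flagged <- unlist(strsplit(regions$gene_ids[regions$flagged_nt], ",", fixed = TRUE))
  list(regions = regions, flagged_genes = sort(unique(flagged[flagged != ""])))
}

#' Run the windowed nucleotide screen over a whole assembly
#'
#' For each contig: mask low-complexity sequence, partition into windows,
#' score the windows with the prokaryotic and eukaryotic nucleotide hit
#' tables (query ids are contig ids), merge harvested windows into
#' regions, and flag overlapping genes.
#'
#' @param contigs named [Biostrings::DNAStringSet].
#' @param prok_hits,euk_hits nucleotide hit data.frames with
#'   `query_id` = contig id.
#' @param genes gene-model data.frame.
#' @param config a [pipeline_config()].
#' @return list: `regions` (all contigs), `flagged_genes`, `windows`
#'   (scored windows, one data.frame with a `contig_id` column).
#' @export
nucleotide_screen <- function(contigs, prok_hits, euk_hits, genes,
                              config = pipeline_config()) {
  all_regions <- list(); all_flagged <- character(); all_windows <- list()
  for (cid in names(contigs)) {
    seqc <- as.character(contigs[[cid]])
    clen <- nchar(seqc)
    mask <- mask_low_complexity(seqc)
    win <- make_windows(clen, config$window_size, mask)
    ph <- prok_hits[prok_hits$query_id == cid, , drop = FALSE]
    eh <- euk_hits[euk_hits$query_id == cid, , drop = FALSE]
    scored <- score_windows(win, ph, eh, clen, config$evalue_threshold_protein)
    mf <- merge_and_flag(scored, ph, cid, clen, genes, config)
    scored$contig_id <- cid
    all_windows[[cid]] <- scored
    all_regions[[cid]] <- mf$regions
    all_flagged <- c(all_flagged, mf$flagged_genes)
  }
  list(regions = do.call(rbind, c(all_regions, list(make.row.names = FALSE))),
       flagged_genes = sort(unique(all_flagged)),
       windows = do.call(rbind, c(all_windows, list(make.row.names = FALSE))))
}

#' Write nucleotide-screen regions as BED
#'
#' BED uses the same 0-based half-open convention as the package's
#' internal coordinates, so intervals are written as-is. The score column
#' carries the bit-score difference.
#'
#' @param regions data.frame from [nucleotide_screen()].
#' @param path destination BED file.
#' @param flagged_only write only flagged regions (default TRUE).
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path, flagged_only = TRUE) {
  r <- if (flagged_only) regions[regions$flagged_nt, , drop = FALSE] else regions
  lines <- sprintf("%s\t%d\t%d\tnt_region\t%.1f\t.",
                   r$contig_id, as.integer(r$start), as.integer(r$end),
                   r$bitscore_diff)
  writeLines(lines, path)
  invisible(path)
}
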