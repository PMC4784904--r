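# Route combination, contamination post-filters, candidate classification,
# and the end-to-end driver.

#' Homolog presence in comparison transcriptomes
#'
#' A gene has a detectable homolog in a transcriptome when at least one
#' hit is strictly below the e-value threshold.
#'
#' @param gene_ids genes to report.
#' @param sponge_hits named list of hit data.frames (`query_id` = gene id),
#'   one per comparison transcriptome.
#' @param evalue_threshold strict upper bound on the e-value.
#' @return logical matrix, genes x transcriptomes.
#' @export
homolog_presence <- function(gene_ids, sponge_hits, evalue_threshold = 1e-5) {
  out <- sapply(sponge_hits, function(h) {
    present <- unique(h$query_id[h$evalue < evalue_threshold])
    gene_ids %in% present
  })
  if (is.null(dim(out))) out <- matrix(out, nrow = length(gene_ids),
                                       dimnames = list(NULL, names(sponge_hits)))
  rownames(out) <- gene_ids
  out
}

#' Contamination post-filters
#'
#' The four symbiont-contamination filters applied to every gene:
#' \describe{
#'   \item{gc13_band}{GC13 within `gc13_sd_multiplier` SD of the
#'     assembly-wide mean (from [host_bands()]).}
#'   \item{contig_length}{gene's contig at least `min_contig_length` bp —
#'     only genes on contigs shorter than the cutoff are eliminated, so a
#'     contig of exactly the cutoff length passes.}
#'   \item{expression}{mean rpkm across samples at least `min_avg_rpkm`;
#'     genes absent from the expression table count as 0 and fail.}
#'   \item{flanking}{at least one non-candidate gene (flagged by no
#'     detection route) on each side on the same contig; genes at contig
#'     ends fail.}
#' }
#'
#' @param genes gene-model data.frame.
#' @param membership data.frame from [host_bands()] (`membership`).
#' @param avg_rpkm named numeric vector from [average_rpkm()].
#' @param contig_lengths named integer vector of contig lengths.
#' @param route_flagged named logical vector: gene flagged by any route.
#' @param config a [pipeline_config()].
#' @return data.frame: `gene_id`, `pass_gc13_band`, `pass_contig_length`,
#'   `pass_expression`, `pass_flanking`, `contig_length`, `avg_rpkm`.
#' @export
apply_post_filters <- function(genes, membership, avg_rpkm, contig_lengths,
                               route_flagged, config = pipeline_config()) {
  if (!all(genes$contig_id %in% names(contig_lengths)))
    stopf("gene(s) on unknown contig: %s",
          paste(utils::head(setdiff(genes$contig_id, names(contig_lengths)), 3),
                collapse = ", "))
  idx <- match(genes$gene_id, membership$gene_id)
  clen <- contig_lengths[genes$contig_id]
  rpkm <- avg_rpkm[genes$gene_id]
  rpkm[is.na(rpkm)] <- 0
  pass_flank <- rep(FALSE, nrow(genes))
  flagged <- route_flagged[genes$gene_id]
  flagged[is.na(flagged)] <- FALSE
  for (cid in unique(genes$contig_id)) {
    on_c <- which(genes$contig_id == cid)
    o <- on_c[order_c(genes$start[on_c])]
    ok <- !flagged[o]
    left <- cumsum(ok) - ok          # non-candidate genes strictly before
    right <- rev(cumsum(rev(ok)) - rev(ok))  # strictly after
    pass_flank[o] <- left > 0L & right > 0L
  }
  data.frame(gene_id = genes$gene_id,
             pass_gc13_band = membership$in_host_gc_band[idx],
             pass_contig_length = unname(clen >= config$min_contig_length),
             pass_expression = unname(rpkm >= config$min_avg_rpkm),
             pass_flanking = pass_flank,
             contig_length = unname(clen),
             avg_rpkm = unname(rpkm),
             stringsAsFactors = FALSE)
}

#' Classify candidates by supporting methods and host-like features
#'
#' `n_supporting` is the number of independent detection routes flagging
#' the gene (Alien Index, consensus taxonomy, external gene-family
#' evidence, nucleotide screen; maximum 4). `n_hostlike` is the number of
#' host-like features: GC13 within the host band, membership in the host
#' codon-usage cluster, multiple exons, and a detectable homolog in each
#' of the two comparison transcriptomes (maximum 5). A gene is a final
#' candidate when at least one route flags it and it passes all four
#' post-filters.
#'
#' @param records data.frame carrying the flag, filter, feature columns
#'   (`flag_*`, `pass_*`, `in_host_*`, `exon_count`, `homolog_*`).
#' @return `records` with `n_supporting`, `n_hostlike`,
#'   `final_candidate` added.
#' @export
classify <- function(records) {
  records$n_supporting <- with(records,
    as.integer(flag_ai45) + as.integer(flag_blast) +
    as.integer(flag_evolmap) + as.integer(flag_nt))
  records$n_hostlike <- with(records,
    as.integer(in_host_gc_band) + as.integer(in_host_codon_cluster) +
    as.integer(exon_count >= 2L) + as.integer(homolog_haliclona) +
    as.integer(homolog_ephydatia))
  records$final_candidate <- with(records,
    n_supporting >= 1L & pass_gc13_band & pass_contig_length &
    pass_expression & pass_flanking)
  records
}

#' Run the full screen
#'
#' Executes the four detection routes, the compositional analysis, the
#' contamination post-filters and the classification, and assembles the
#' per-gene candidate table plus a method-overlap summary and the
#' scatter data used for compositional diagnostics.
#'
#' @param inputs list with components `contigs` (named DNAStringSet),
#'   `genes` (gene-model data.frame), `protein_hits` (taxon-labelled hit
#'   data.frame), `nt_prok_hits`, `nt_euk_hits` (nucleotide hit
#'   data.frames, query = contig), `expression` (data.frame),
#'   `sponge_hits` (named list of two hit data.frames, `haliclona` and
#'   `ephydatia`), `evolmap_flags` (named logical vector, optional),
#'   `self_ids` (optional).
#' @param config a [pipeline_config()].
#' @return list of class `alienscreen_result`: `candidates` (per-gene
#'   table), `summary` (per-route and overlap counts), `regions`
#'   (nucleotide-screen regions), `scatter` (axis-1 vs GC%, contig
#'   length, rpkm), `ai` (Alien Index table), `assignments`
#'   (consensus-taxonomy table), `composition` (profiles and CA).
#' @export
run_pipeline <- function(inputs, config = pipeline_config()) {
  genes <- inputs$genes
  gene_ids <- genes$gene_id
  contig_lengths <- stats::setNames(Biostrings::width(inputs$contigs),
                                    names(inputs$contigs))

  message(sprintf("[routes] scoring %d genes", length(gene_ids)))
  ai <- alien_index_table(inputs$protein_hits, gene_ids, config, inputs$self_ids)
  assign <- consensus_assignments(inputs$protein_hits, gene_ids, config)
  nt <- nucleotide_screen(inputs$contigs, inputs$nt_prok_hits,
                          inputs$nt_euk_hits, genes, config)
  evolmap <- inputs$evolmap_flags %||% stats::setNames(rep(FALSE, length(gene_ids)), gene_ids)

  flag_ai45 <- gene_ids %in% ai45_candidates(ai)
  flag_blast <- gene_ids %in% blast_candidates(assign)
  flag_nt <- gene_ids %in% nt$flagged_genes
  flag_evolmap <- unname(evolmap[gene_ids]); flag_evolmap[is.na(flag_evolmap)] <- FALSE
  route_flagged <- stats::setNames(flag_ai45 | flag_blast | flag_nt | flag_evolmap,
                                   gene_ids)
  message(sprintf("[routes] AI45 %d, consensus %d, external %d, nucleotide %d, union %d",
                  sum(flag_ai45), sum(flag_blast), sum(flag_evolmap), sum(flag_nt),
                  sum(route_flagged)))

  message("[composition] GC, codon usage, correspondence analysis")
  comp <- composition_profiles(genes, config)

  rpkm <- average_rpkm(inputs$expression, gene_ids)
  filt <- apply_post_filters(genes, comp$profiles, rpkm, contig_lengths,
                             route_flagged, config)
  hom <- homolog_presence(gene_ids, inputs$sponge_hits, config$evalue_threshold_protein)

  records <- data.frame(
    gene_id = gene_ids,
    flag_ai45 = flag_ai45, flag_blast = flag_blast,
    flag_evolmap = flag_evolmap, flag_nt = flag_nt,
    pass_gc13_band = filt$pass_gc13_band,
    pass_contig_length = filt$pass_contig_length,
    pass_expression = filt$pass_expression,
    pass_flanking = filt$pass_flanking,
    gc_percent = comp$profiles$gc_percent,
    gc13_percent = comp$profiles$gc13_percent,
    ca_axis1 = comp$profiles$ca_axis1,
    contig_length = filt$contig_length,
    avg_rpkm = filt$avg_rpkm,
    exon_count = genes$exon_count,
    in_host_gc_band = comp$profiles$in_host_gc_band,
    in_host_codon_cluster = comp$profiles$in_host_codon_cluster,
    homolog_haliclona = unname(hom[, "haliclona"]),
    homolog_ephydatia = unname(hom[, "ephydatia"]),
    stringsAsFactors = FALSE
  )
  records <- classify(records)
  records <- records[order_c(records$gene_id), , drop = FALSE]
  rownames(records) <- NULL
  message(sprintf("[filters] %d/%d route-flagged genes pass all four post-filters",
                  sum(records$final_candidate), sum(route_flagged)))

  routes <- list(ai45 = flag_ai45, blast = flag_blast,
                 evolmap = flag_evolmap, nt = flag_nt)
  pairs <- utils::combn(names(routes), 2)
  overlap <- stats::setNames(
    lapply(seq_len(ncol(pairs)), function(j)
      sum(routes[[pairs[1, j]]] & routes[[pairs[2, j]]])),
    apply(pairs, 2, paste, collapse = "_and_"))
  summary <- c(list(n_genes = length(gene_ids),
                    n_ai45 = sum(flag_ai45), n_blast = sum(flag_blast),
                    n_evolmap = sum(flag_evolmap), n_nt = sum(flag_nt),
                    n_union = sum(route_flagged),
                    n_final_candidates = sum(records$final_candidate)),
               overlap)

  scatter <- data.frame(gene_id = gene_ids,
                        ca_axis1 = comp$profiles$ca_axis1,
                        gc_percent = comp$profiles$gc_percent,
                        contig_length = filt$contig_length,
                        avg_rpkm = filt$avg_rpkm,
                        final_candidate = records$final_candidate[
                          match(gene_ids, records$gene_id)],
                        stringsAsFactors = FALSE)

  structure(list(candidates = records, summary = summary, regions = nt$regions,
                 scatter = scatter, ai = ai, assignments = assign,
                 composition = comp),
            class = "alienscreen_result")
}

#' @export
print.alienscreen_result <- function(x, ...) {
  s <- x$summary
  cat("Horizontal-gene-transfer screen\n")
  cat(sprintf("  genes screened       : %d\n", s$n_genes))
  cat(sprintf("  routes (AI45/consensus/external/nucleotide): %d / %d / %d / %d\n",
              s$n_ai45, s$n_blast, s$n_evolmap, s$n_nt))
  cat(sprintf("  union of routes      : %d\n", s$n_union))
  cat(sprintf("  final candidates     : %d\n", s$n_final_candidates))
  invisible(x)
}
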