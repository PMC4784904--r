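#' Top-k qualifying hits of a gene
#'
#' Hits at or below the significance threshold, sorted by ascending
#' e-value with ties broken by descending bit score then subject id, and
#' truncated to the top `k`.
#'
#' @param hits hit data.frame for one gene.
#' @param k number of hits to keep.
#' @param evalue_threshold significance cutoff (hits with `evalue <=`
#'   threshold qualify).
#' @return the ordered, truncated hit data.frame.
#' @export
top_k_hits <- function(hits, k = 10L, evalue_threshold = 1e-5) {
  q <- hits[hits$evalue <= evalue_threshold, , drop = FALSE]
  q <- q[order_c(q$evalue, -q$bitscore, q$subject_id), , drop = FALSE]
  utils::head(q, k)
}

#' Consensus phylum of an ordered top-hit list
#'
#' The most frequent phylum among the top hits; ties go to the phylum of
#' the best-ranked hit among the tied phyla. An empty list is
#' "unassigned". The consensus superkingdom is that of the best-ranked hit
#' belonging to the consensus phylum.
#'
#' @param top_hits data.frame from [top_k_hits()].
#' @return list with `phylum` and `superkingdom` (both "unassigned" when
#'   there are no hits).
#' @export
consensus_phylum <- function(top_hits) {
  if (!nrow(top_hits)) return(list(phylum = "unassigned", superkingdom = "unassigned"))
  tab <- table(top_hits$phylum)
  tied <- names(tab)[tab == max(tab)]
  best_rank <- vapply(tied, function(p) min(which(top_hits$phylum == p)), integer(1))
  phy <- tied[which.min(best_rank)]
  sk <- top_hits$superkingdom[which(top_hits$phylum == phy)[1]]
  list(phylum = phy, superkingdom = sk)
}

#' Consensus-taxonomy assignment for all genes
#'
#' Assigns each gene the consensus phylum of its top
#' `config$top_hits_for_consensus` qualifying hits and records whether any
#' eukaryotic hit anywhere in the gene's table reaches the significance
#' threshold. A gene is flagged by this route (`flagged_blast`) when its
#' consensus superkingdom is prokaryotic and it has no qualifying
#' eukaryotic hit at all — a mechanical version of "matched exclusively to
#' prokaryotic sequences".
#'
#' @param hits full protein hit data.frame with taxon columns.
#' @param gene_ids all genes to assign.
#' @param config a [pipeline_config()].
#' @return data.frame: `gene_id`, `consensus_phylum`,
#'   `consensus_superkingdom`, `n_top_hits`, `n_euk_hits`,
#'   `has_eukaryotic_hit`, `flagged_blast`.
#' @export
consensus_assignments <- function(hits, gene_ids, config = pipeline_config()) {
  thr <- config$evalue_threshold_protein
  by_gene <- split(seq_len(nrow(hits)), factor(hits$query_id, levels = sort(gene_ids)))
  rows <- lapply(sort(gene_ids), function(g) {
    h <- hits[by_gene[[g]], , drop = FALSE]
    top <- top_k_hits(h, config$top_hits_for_consensus, thr)
    cons <- consensus_phylum(top)
    n_euk <- sum(h$superkingdom == "Eukaryota" & h$evalue <= thr)
    data.frame(gene_id = g,
               consensus_phylum = cons$phylum,
               consensus_superkingdom = cons$superkingdom,
               n_top_hits = nrow(top),
               n_euk_hits = n_euk,
               has_eukaryotic_hit = n_euk > 0L,
               flagged_blast = cons$superkingdom %in% c("Bacteria", "Archaea") && n_euk == 0L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Genes flagged by the consensus-taxonomy route
#'
#' @param assignments data.frame from [consensus_assignments()].
#' @return character vector of flagged gene ids.
#' @export
blast_candidates <- function(assignments) {
  sort(assignments$gene_id[assignments$flagged_blast])
}
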