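#' Alien Index of one gene
#'
#' The Alien Index (AI) contrasts a gene's best protein-search e-value
#' against metazoan subjects with its best e-value against non-metazoan
#' subjects:
#'
#'   AI = ln(best_metazoan_e + eps) - ln(best_nonmetazoan_e + eps)
#'
#' with `eps = config$pseudo_evalue` (default 1e-200) guarding zero
#' e-values. A category with no hit contributes e = 1, the conventional
#' "no detectable homology" value, and e-values above 1 are capped at 1, so
#' AI is bounded and AI = 0 when neither category has a hit. Large positive
#' AI means much stronger affinity outside Metazoa.
#'
#' A gene is AI-flagged (`flagged_ai45`) when AI is at or above
#' `config$ai_threshold` (default 45) *and* its best overall hit — minimum
#' e-value, ties broken by higher bit score then lexicographic subject id —
#' is prokaryotic (Bacteria or Archaea). Hits to non-metazoan eukaryotes
#' lower the non-metazoan e-value but veto the flag when they are the best
#' overall hit.
#'
#' @param gene_id gene identifier.
#' @param hits hit data.frame (rows for this gene only) with taxon columns.
#' @param config a [pipeline_config()].
#' @param self_ids optional character vector of subject ids that are the
#'   host's own proteins; matching hits are removed first.
#' @return one-row data.frame: `gene_id`, `best_metazoan_evalue`,
#'   `best_nonmetazoan_evalue`, `ai`, `best_overall_hit_is_prokaryotic`,
#'   `flagged_ai45`.
#' @export
compute_alien_index <- function(gene_id, hits, config = pipeline_config(),
                                self_ids = NULL) {
  if (nrow(hits) && any(hits$evalue < 0)) stopf("negative e-value for gene %s", gene_id)
  if (!is.null(self_ids) && nrow(hits))
    hits <- hits[!(hits$subject_id %in% self_ids), , drop = FALSE]
  e <- pmin(hits$evalue, 1)
  met <- hits$is_metazoan
  best_met <- if (any(met)) min(e[met]) else NA_real_
  best_non <- if (any(!met)) min(e[!met]) else NA_real_
  eps <- config$pseudo_evalue
  em <- if (is.na(best_met)) 1 else best_met
  en <- if (is.na(best_non)) 1 else best_non
  ai <- log(em + eps) - log(en + eps)
  prok_best <- FALSE
  if (nrow(hits)) {
    o <- order_c(e, -hits$bitscore, hits$subject_id)[1]
    prok_best <- hits$superkingdom[o] %in% c("Bacteria", "Archaea")
  }
  data.frame(gene_id = gene_id,
             best_metazoan_evalue = best_met,
             best_nonmetazoan_evalue = best_non,
             ai = ai,
             best_overall_hit_is_prokaryotic = prok_best,
             flagged_ai45 = ai >= config$ai_threshold && prok_best,
             stringsAsFactors = FALSE)
}

#' Alien Index table for all genes
#'
#' @param hits full protein hit data.frame (`query_id` = gene id).
#' @param gene_ids all genes to score; genes without hits get AI 0.
#' @param config a [pipeline_config()].
#' @param self_ids see [compute_alien_index()].
#' @return data.frame with one row per gene, sorted by gene id.
#' @export
alien_index_table <- function(hits, gene_ids, config = pipeline_config(),
                              self_ids = NULL) {
  by_gene <- split(seq_len(nrow(hits)), factor(hits$query_id, levels = sort(gene_ids)))
  out <- do.call(rbind, lapply(sort(gene_ids), function(g)
    compute_alien_index(g, hits[by_gene[[g]], , drop = FALSE], config, self_ids)))
  rownames(out) <- NULL
  out
}

#' Genes flagged by the Alien Index route
#'
#' @param results data.frame from [alien_index_table()].
#' @return character vector of flagged gene ids.
#' @export
ai45_candidates <- function(results) {
  sort(results$gene_id[results$flagged_ai45])
}
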