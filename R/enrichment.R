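# Functional over-representation of the candidate set: best-hit GO
# inheritance, one-sided Fisher's exact tests, Benjamini-Hochberg FDR.

#' Inherit GO annotations from each gene's best qualifying hit
#'
#' Each gene takes the terms of its best hit — minimum e-value, ties
#' broken by higher bit score then lexicographic subject id — provided
#' that hit's e-value is at or below the cutoff. Genes with no qualifying
#' hit, or whose best hit has no terms, are unannotated.
#'
#' @param hits hit data.frame (`query_id` = gene id).
#' @param go_map named list from [read_term_map()]: subject id -> terms.
#' @param evalue_cutoff annotation-transfer cutoff.
#' @return named list: gene id -> character vector of terms.
#' @export
annotate_genes <- function(hits, go_map, evalue_cutoff = 1e-4) {
  q <- hits[hits$evalue <= evalue_cutoff, , drop = FALSE]
  if (!nrow(q)) return(stats::setNames(list(), character()))
  q <- q[order_c(q$evalue, -q$bitscore, q$subject_id), , drop = FALSE]
  best <- q[!duplicated(q$query_id), , drop = FALSE]
  terms <- lapply(best$subject_id, function(s) unique(go_map[[s]] %||% character()))
  names(terms) <- best$query_id
  terms[lengths(terms) > 0]
}

#' One-sided Fisher over-representation of terms in a candidate set
#'
#' For every term annotating at least one background gene, the
#' probability of observing at least the candidate count under the
#' hypergeometric null (Fisher's exact test, over-representation tail).
#' The background is restricted to annotated genes; the candidate count
#' `n` is likewise the number of annotated candidates. Results are
#' sorted by p-value and carry Benjamini-Hochberg q-values.
#'
#' @param candidates character vector of candidate gene ids (must be a
#'   subset of `background`).
#' @param background character vector of background gene ids.
#' @param annotations named list: gene id -> terms (from
#'   [annotate_genes()] or a direct gene-to-term map).
#' @return data.frame: `term_id`, `k` (candidates with term), `n`
#'   (annotated candidates), `K` (background genes with term), `N`
#'   (annotated background), `p_value`, `q_value`.
#' @export
fisher_enrichment <- function(candidates, background, annotations) {
  if (!all(candidates %in% background))
    stopf("candidate gene(s) not in background: %s",
          paste(utils::head(setdiff(candidates, background), 3), collapse = ", "))
  ann <- annotations[intersect(names(annotations), background)]
  ann <- ann[lengths(ann) > 0]
  N_genes <- names(ann)
  N <- length(N_genes)
  cand <- intersect(candidates, N_genes)
  n <- length(cand)
  if (N == 0L)
    return(data.frame(term_id = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), p_value = numeric(),
                      q_value = numeric(), stringsAsFactors = FALSE))
  long <- data.frame(gene = rep(N_genes, lengths(ann)),
                     term = unlist(ann, use.names = FALSE),
                     stringsAsFactors = FALSE)
  K_tab <- table(long$term)
  k_tab <- table(long$term[long$gene %in% cand])
  terms <- sort(names(K_tab))
  K <- as.integer(K_tab[terms])
  k <- integer(length(terms))
  k[match(names(k_tab), terms)] <- as.integer(k_tab)
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(term_id = terms, k = k, n = n, K = K, N = N,
                    p_value = p, stringsAsFactors = FALSE)
  out <- out[order_c(out$p_value, out$term_id), , drop = FALSE]
  out$q_value <- benjamini_hochberg(out$p_value)
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg step-up q-values
#'
#' `q_(i) = min_(j >= i) p_(j) * m / j` over the sorted p-values,
#' returned in the input order.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return q-values, same length and order as `p`.
#' @export
benjamini_hochberg <- function(p) {
  if (!length(p)) return(numeric())
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    stopf("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Write an enrichment table
#'
#' @param results data.frame from [fisher_enrichment()].
#' @param path destination TSV.
#' @return `path`, invisibly.
#' @export
write_enrichment_table <- function(results, path) {
  x <- results
  x$p_value <- signif(x$p_value, 6)
  x$q_value <- signif(x$q_value, 6)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
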