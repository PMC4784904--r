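#' Read an expression table
#'
#' TSV with a `gene_id` column and one numeric rpkm column per sample.
#' Genes absent from the table are treated downstream as expression 0.
#'
#' @param path TSV file.
#' @return data.frame with `gene_id` and sample columns; negative values
#'   are rejected.
#' @export
read_expression <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!("gene_id" %in% names(x))) stopf("expression table needs a gene_id column")
  vals <- x[setdiff(names(x), "gene_id")]
  if (any(vapply(vals, function(v) any(v < 0, na.rm = TRUE), logical(1))))
    stopf("negative rpkm values in %s", path)
  x
}

#' Mean expression per gene
#'
#' @param expression data.frame from [read_expression()].
#' @param gene_ids genes to report; genes missing from the table get 0.
#' @return named numeric vector of mean rpkm.
#' @export
average_rpkm <- function(expression, gene_ids) {
  vals <- as.matrix(expression[setdiff(names(expression), "gene_id")])
  avg <- rowMeans(vals)
  out <- stats::setNames(rep(0, length(gene_ids)), gene_ids)
  idx <- match(expression$gene_id, gene_ids)
  out[idx[!is.na(idx)]] <- avg[!is.na(idx)]
  out
}

#' Read a gene/term or subject/term annotation map
#'
#' Two-column TSV, one row per (id, term) pair, with header
#' `id<TAB>term_id` (any first-column name is accepted).
#'
#' @param path TSV file.
#' @return named list: id -> character vector of terms.
#' @export
read_term_map <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(x) < 2L) stopf("term map %s needs two columns", path)
  split(x[[2]], x[[1]])
}

#' Read per-gene boolean flags (external gene-family evidence)
#'
#' TSV with header `gene_id<TAB>flag`. Used for the externally computed
#' gene-family route: the screen consumes its per-gene verdicts as input.
#'
#' @param path TSV file, or `NULL`/missing file for "no external evidence"
#'   (all genes unflagged).
#' @param gene_ids genes to report.
#' @return named logical vector over `gene_ids`.
#' @export
read_flag_table <- function(path, gene_ids) {
  out <- stats::setNames(rep(FALSE, length(gene_ids)), gene_ids)
  if (is.null(path) || !file.exists(path %||% "")) return(out)
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "flag") %in% names(x)))
    stopf("flag table %s needs gene_id and flag columns", path)
  idx <- match(x$gene_id, gene_ids)
  out[idx[!is.na(idx)]] <- as.logical(x$flag)[!is.na(idx)]
  out
}

candidate_columns <- c(
  "gene_id", "flag_ai45", "flag_blast", "flag_evolmap", "flag_nt",
  "pass_gc13_band", "pass_contig_length", "pass_expression", "pass_flanking",
  "gc_percent", "gc13_percent", "ca_axis1", "contig_length", "avg_rpkm",
  "exon_count", "in_host_gc_band", "in_host_codon_cluster",
  "homolog_haliclona", "homolog_ephydatia",
  "n_supporting", "n_hostlike", "final_candidate"
)

#' Write the per-gene candidate report
#'
#' One row per gene, deterministic column order, rows sorted by gene id,
#' floats printed with 6 significant digits. Round-trips through
#' [read_candidate_table()].
#'
#' @param records candidate data.frame from [run_pipeline()].
#' @param path destination TSV.
#' @return `path`, invisibly.
#' @export
write_candidate_table <- function(records, path) {
  miss <- setdiff(candidate_columns, names(records))
  if (length(miss)) stopf("candidate table missing columns: %s", paste(miss, collapse = ", "))
  x <- records[order_c(records$gene_id), candidate_columns, drop = FALSE]
  num <- vapply(x, is.numeric, logical(1))
  for (j in which(num)) x[[j]] <- signif(x[[j]], 6)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a candidate report written by [write_candidate_table()]
#'
#' @param path TSV file.
#' @return candidate data.frame.
#' @export
read_candidate_table <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (cc in grep("^(flag_|pass_|in_host_|homolog_|final_)", candidate_columns, value = TRUE))
    if (cc %in% names(x)) x[[cc]] <- as.logical(x[[cc]])
  x
}
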