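#' Read the two-file taxon map
#'
#' Taxonomic labels for homology-search subjects come from two plain TSV
#' files: one mapping subject id to a taxon key, and one mapping taxon key
#' to superkingdom, phylum and a metazoan flag. This mirrors the usual
#' accession-to-taxid plus taxid-to-lineage lookup without any online
#' taxonomy service.
#'
#' @param subject_path TSV with header `subject_id<TAB>taxon_key`.
#' @param lineage_path TSV with header
#'   `taxon_key<TAB>superkingdom<TAB>phylum<TAB>is_metazoan`.
#' @return data.frame `subject_id`, `superkingdom`, `phylum`, `is_metazoan`.
#' @export
read_taxon_map <- function(subject_path, lineage_path) {
  s <- utils::read.delim(subject_path, stringsAsFactors = FALSE)
  l <- utils::read.delim(lineage_path, stringsAsFactors = FALSE)
  need_s <- c("subject_id", "taxon_key")
  need_l <- c("taxon_key", "superkingdom", "phylum", "is_metazoan")
  if (!all(need_s %in% names(s))) stopf("subject map needs columns: %s", paste(need_s, collapse = ", "))
  if (!all(need_l %in% names(l))) stopf("lineage map needs columns: %s", paste(need_l, collapse = ", "))
  m <- merge(s, l, by = "taxon_key")
  bad <- !(m$superkingdom %in% c("Bacteria", "Archaea", "Eukaryota"))
  if (any(bad)) stopf("unknown superkingdom(s): %s", paste(unique(m$superkingdom[bad]), collapse = ", "))
  m$is_metazoan <- as.logical(m$is_metazoan)
  if (any(m$is_metazoan & m$superkingdom != "Eukaryota"))
    stopf("metazoan subjects must be Eukaryota")
  out <- m[order_c(m$subject_id), c("subject_id", "superkingdom", "phylum", "is_metazoan")]
  rownames(out) <- NULL
  out
}

#' Read a 12-column tabular homology-search result
#'
#' The dialect is the standard 12-column tab-separated layout
#' (qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore), without a header. Query coordinates are converted to
#' 0-based half-open with `qstart < qend`; percent identity is converted to
#' a fraction. Subjects are joined to the taxon map; rows whose subject is
#' not in the map are dropped with a warning (default) or raise an error.
#'
#' @param path hit-table file.
#' @param taxon_map data.frame from [read_taxon_map()], or `NULL` to skip
#'   taxon labelling (nucleotide screens, transcriptome presence checks).
#' @param on_missing "drop" (default) or "error" for unmapped subjects.
#' @return data.frame of hit records: `query_id`, `subject_id`,
#'   `percent_identity` (fraction), `align_length`, `q_start`, `q_end`
#'   (0-based half-open), `evalue`, `bitscore`, and, when a map is given,
#'   `superkingdom`, `phylum`, `is_metazoan`. The number of dropped rows is
#'   in `attr(, "n_dropped")`.
#' @export
read_hit_table <- function(path, taxon_map = NULL,
                           on_missing = c("drop", "error")) {
  on_missing <- match.arg(on_missing)
  if (!file.exists(path)) stopf("hit table not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines) & !startsWith(lines, "#")]
  if (!length(lines)) {
    out <- empty_hit_frame(!is.null(taxon_map))
    attr(out, "n_dropped") <- 0L
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(parts)
  if (any(ncols != 12L))
    stopf("hit-table parse error in %s: row %d has %d columns (expected 12)",
          path, which(ncols != 12L)[1], ncols[which(ncols != 12L)[1]])
  m <- matrix(unlist(parts), ncol = 12L, byrow = TRUE)
  qs <- as.numeric(m[, 7]); qe <- as.numeric(m[, 8])
  # tabular convention: 1-based inclusive, qstart may exceed qend on reverse
  lo <- pmin(qs, qe); hi <- pmax(qs, qe)
  out <- data.frame(
    query_id = m[, 1], subject_id = m[, 2],
    percent_identity = as.numeric(m[, 3]) / 100,
    align_length = as.integer(m[, 4]),
    q_start = as.integer(lo) - 1L, q_end = as.integer(hi),
    evalue = as.numeric(m[, 11]), bitscore = as.numeric(m[, 12]),
    stringsAsFactors = FALSE
  )
  if (any(is.na(out$evalue)) || any(out$evalue < 0))
    stopf("hit-table parse error in %s: invalid e-value at row %d",
          path, which(is.na(out$evalue) | out$evalue < 0)[1])
  n_dropped <- 0L
  if (!is.null(taxon_map)) {
    idx <- match(out$subject_id, taxon_map$subject_id)
    if (anyNA(idx)) {
      missing_ids <- unique(out$subject_id[is.na(idx)])
      if (on_missing == "error")
        stopf("subjects missing from taxon map: %s",
              paste(utils::head(missing_ids, 5), collapse = ", "))
      n_dropped <- sum(is.na(idx))
      warnf("dropped %d hit(s) with subjects missing from the taxon map", n_dropped)
      out <- out[!is.na(idx), , drop = FALSE]
      idx <- idx[!is.na(idx)]
    }
    out$superkingdom <- taxon_map$superkingdom[idx]
    out$phylum <- taxon_map$phylum[idx]
    out$is_metazoan <- taxon_map$is_metazoan[idx]
    rownames(out) <- NULL
  }
  attr(out, "n_dropped") <- n_dropped
  out
}

empty_hit_frame <- function(with_taxa) {
  out <- data.frame(query_id = character(), subject_id = character(),
                    percent_identity = numeric(), align_length = integer(),
                    q_start = integer(), q_end = integer(),
                    evalue = numeric(), bitscore = numeric(),
                    stringsAsFactors = FALSE)
  if (with_taxa) {
    out$superkingdom <- character(); out$phylum <- character()
    out$is_metazoan <- logical()
  }
  out
}

#' Write hits in the 12-column tabular dialect
#'
#' Inverse of [read_hit_table()] for the coordinate and identity
#' conventions (0-based half-open back to 1-based inclusive, fraction back
#' to percent). Taxon columns are not written; they live in the taxon map.
#'
#' @param hits hit data.frame.
#' @param path destination.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  lines <- sprintf("%s\t%s\t%.2f\t%d\t0\t0\t%d\t%d\t1\t%d\t%s\t%.1f",
                   hits$query_id, hits$subject_id,
                   hits$percent_identity * 100, as.integer(hits$align_length),
                   as.integer(hits$q_start) + 1L, as.integer(hits$q_end),
                   as.integer(hits$align_length),
                   format(hits$evalue, scientific = TRUE, digits = 3),
                   hits$bitscore)
  writeLines(lines, path)
  invisible(path)
}
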