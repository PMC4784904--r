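#' Read a FASTA file
#'
#' Sequences are uppercased; in nucleotide mode U is mapped to T so RNA-style
#' input is accepted. Record ids are the header tokens up to the first
#' whitespace and must be unique.
#'
#' @param path FASTA file.
#' @param type "DNA" or "AA".
#' @return a [Biostrings::DNAStringSet] (or `AAStringSet`) named by record id.
#'   An empty file yields an empty set with a warning.
#' @export
read_fasta <- function(path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  blank <- grepl("^\\s*$", lines)
  make <- if (type == "DNA") Biostrings::DNAStringSet else Biostrings::AAStringSet
  if (all(blank)) {
    warnf("FASTA file %s is empty", path)
    return(make())
  }
  lines <- lines[!blank]
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1])
    stopf("FASTA parse error at line 1 of %s: sequence before any header", path)
  hdr_line_no <- which(is_hdr)
  ids <- sub("^>\\s*", "", lines[is_hdr])
  ids <- sub("\\s.*$", "", ids)
  if (any(ids == "")) {
    bad <- hdr_line_no[ids == ""][1]
    stopf("FASTA parse error at line %d of %s: empty header", bad, path)
  }
  if (anyDuplicated(ids))
    stopf("duplicate FASTA ids in %s: %s", path,
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  rec <- cumsum(is_hdr)
  seqs <- vapply(split(lines[!is_hdr], factor(rec[!is_hdr], levels = seq_along(ids))),
                 paste0, character(1), collapse = "")
  if (any(seqs == "")) {
    bad <- hdr_line_no[seqs == ""][1]
    stopf("FASTA parse error at line %d of %s: record '%s' has empty sequence",
          bad, path, ids[seqs == ""][1])
  }
  seqs <- toupper(seqs)
  if (type == "DNA") seqs <- chartr("U", "T", seqs)
  out <- make(seqs)
  names(out) <- ids
  out
}

#' Write sequences to FASTA
#'
#' @param seqs an `XStringSet` or named character vector.
#' @param path destination.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.character(seqs)) seqs <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path, width = width)
  invisible(path)
}
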