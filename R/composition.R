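# Compositional amelioration analysis: GC metrics, codon-usage matrix,
# correspondence analysis, and the host band/cluster rules used by the
# contamination filters.

#' GC content of a sequence, in percent
#'
#' Ambiguous bases (anything outside A/C/G/T) are excluded from both the
#' numerator and the denominator.
#'
#' @param x character vector of DNA sequences.
#' @return numeric vector in `[0, 100]`; `NA` (with a warning) for
#'   sequences with no unambiguous base.
#' @export
gc_percent <- function(x) {
  ss <- Biostrings::DNAStringSet(x)
  fr <- Biostrings::letterFrequency(ss, c("A", "C", "G", "T"))
  tot <- rowSums(fr)
  if (any(tot == 0)) warnf("%d sequence(s) have no unambiguous bases; GC undefined", sum(tot == 0))
  ifelse(tot > 0, 100 * (fr[, "G"] + fr[, "C"]) / tot, NA_real_)
}

#' GC content at codon positions 1 and 3, in percent
#'
#' The GC fraction over the pooled multiset of bases at the first and
#' third position of every codon. Ambiguous bases are excluded.
#'
#' @param cds character vector of coding sequences, each with length
#'   divisible by 3.
#' @return numeric vector in `[0, 100]`.
#' @export
gc13_percent <- function(cds) {
  n <- nchar(cds)
  if (any(n %% 3L != 0L))
    stopf("CDS length not divisible by 3 for %d sequence(s)", sum(n %% 3L != 0L))
  vapply(cds, function(s) {
    b <- strsplit(s, "", fixed = TRUE)[[1]]
    pos <- (seq_along(b) - 1L) %% 3L
    keep <- b %in% c("A", "C", "G", "T") & pos != 1L
    if (!any(keep)) return(NA_real_)
    100 * mean(b[keep] %in% c("G", "C"))
  }, numeric(1), USE.NAMES = FALSE)
}

#' The 59 informative sense codons
#'
#' All 61 sense codons of the standard code minus the two without
#' synonymous alternatives (ATG and TGG), whose usage carries no bias
#' information.
#'
#' @return character vector of 59 codons.
#' @export
informative_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  sort(setdiff(names(gc)[gc != "*"], c("ATG", "TGG")))
}

#' Codon-count matrix over the informative codons
#'
#' @param cds named character vector of coding sequences (names = gene
#'   ids), each divisible by 3.
#' @param min_codons genes whose counted codons total less than this are
#'   flagged low-information in `attr(, "low_information")`.
#' @return integer matrix, genes x 59 codons.
#' @export
codon_count_matrix <- function(cds, min_codons = 30L) {
  if (is.null(names(cds))) stopf("cds must be named by gene id")
  n <- nchar(cds)
  if (any(n %% 3L != 0L)) stopf("CDS length not divisible by 3")
  counts <- Biostrings::oligonucleotideFrequency(Biostrings::DNAStringSet(cds),
                                                 width = 3L, step = 3L)
  m <- counts[, informative_codons(), drop = FALSE]
  rownames(m) <- names(cds)
  attr(m, "low_information") <- rownames(m)[rowSums(m) < min_codons]
  m
}

#' Correspondence analysis of a codon-count table
#'
#' Standard CA: the table is scaled to relative frequencies, the
#' chi-square standardized residuals of the independence model are
#' decomposed by SVD, and row/column coordinates are returned in
#' principal scaling (coordinates scaled by their singular value), so the
#' per-axis inertias are the squared singular values and sum to the
#' table's chi-square statistic divided by its grand total. Rows with a
#' zero sum are excluded and reported via `dropped_rows`. The sign of
#' axis 1 is fixed so that it correlates positively with the rows' GC3
#' (fraction of counted codons ending in G or C), making coordinates
#' reproducible across linear-algebra backends; remaining axes are
#' anchored by forcing their largest-magnitude row coordinate positive.
#'
#' @param m non-negative count matrix (genes x codons) with rownames.
#' @return list of class `ca_result`: `row_coords`, `col_coords`,
#'   `inertia_per_axis`, `total_inertia`, `dropped_rows`, and `axis1`
#'   (named vector over all input rows, 0 for dropped rows).
#' @export
correspondence_analysis <- function(m) {
  m <- as.matrix(m)
  if (any(m < 0)) stopf("count matrix must be non-negative")
  if (is.null(rownames(m))) rownames(m) <- as.character(seq_len(nrow(m)))
  zero_rows <- rownames(m)[rowSums(m) == 0]
  keep <- rowSums(m) > 0
  mk <- m[keep, colSums(m) > 0, drop = FALSE]
  n_r <- nrow(mk)
  if (n_r < 2L) stopf("correspondence analysis needs at least 2 rows with counts")
  total <- sum(mk)
  P <- mk / total
  r <- rowSums(P); cc <- colSums(P)
  S <- (P - outer(r, cc)) / sqrt(outer(r, cc))
  sv <- La.svd(S)
  tol <- max(dim(S)) * max(sv$d, 0) * .Machine$double.eps * 100
  nax <- min(sum(sv$d > tol), min(dim(mk)) - 1L)
  gc3 <- row_gc3(mk)
  if (nax == 0L) {
    row_coords <- matrix(0, n_r, 1L, dimnames = list(rownames(mk), "axis1"))
    col_coords <- matrix(0, ncol(mk), 1L, dimnames = list(colnames(mk), "axis1"))
    inertia <- 0
  } else {
    d <- sv$d[seq_len(nax)]
    U <- sv$u[, seq_len(nax), drop = FALSE]
    V <- t(sv$vt)[, seq_len(nax), drop = FALSE]
    row_coords <- sweep(U, 2, d, `*`) / sqrt(r)
    col_coords <- sweep(V, 2, d, `*`) / sqrt(cc)
    for (a in seq_len(nax)) {
      s <- if (a == 1L && stats::sd(gc3) > 0 && stats::sd(row_coords[, 1]) > 0)
        sign(stats::cor(row_coords[, 1], gc3))
      else sign(row_coords[which.max(abs(row_coords[, a])), a])
      if (!is.na(s) && s < 0) {
        row_coords[, a] <- -row_coords[, a]
        col_coords[, a] <- -col_coords[, a]
      }
    }
    dimnames(row_coords) <- list(rownames(mk), paste0("axis", seq_len(nax)))
    dimnames(col_coords) <- list(colnames(mk), paste0("axis", seq_len(nax)))
    inertia <- d^2
  }
  axis1 <- stats::setNames(rep(0, nrow(m)), rownames(m))
  axis1[rownames(row_coords)] <- row_coords[, 1]
  structure(list(row_coords = row_coords, col_coords = col_coords,
                 inertia_per_axis = inertia, total_inertia = sum(inertia),
                 dropped_rows = zero_rows, axis1 = axis1),
            class = "ca_result")
}

# GC3 per row of a codon-count matrix: count-weighted fraction of codons
# whose third base is G or C.
row_gc3 <- function(m) {
  third <- substr(colnames(m), 3L, 3L)
  gc_cols <- third %in% c("G", "C")
  rowSums(m[, gc_cols, drop = FALSE]) / pmax(rowSums(m), 1)
}

#' Host compositional bands: GC13 z-band and codon-usage cluster
#'
#' Estimates the host GC13 band as mean +/- k SD over all genes with a
#' defined GC13 (k = `config$gc13_sd_multiplier`), and splits the
#' primary codon-usage axis into two groups by deterministic 2-means
#' (initial centers at the 10th and 90th percentiles, Lloyd iterations
#' capped at 100); the larger group is the host cluster. When the axis is
#' degenerate (no spread, or an empty cluster), all genes are host. Genes
#' with undefined GC13 fall outside the band.
#'
#' @param profiles data.frame with `gene_id`, `gc13_percent`, `ca_axis1`.
#' @param config a [pipeline_config()].
#' @return list: `gc13_mean`, `gc13_sd`, and `membership` data.frame
#'   (`gene_id`, `in_host_gc_band`, `in_host_codon_cluster`).
#' @export
host_bands <- function(profiles, config = pipeline_config()) {
  if (nrow(profiles) < 10L)
    stopf("refusing to estimate host bands from fewer than 10 genes")
  g13 <- profiles$gc13_percent
  mu <- mean(g13, na.rm = TRUE)
  sdv <- stats::sd(g13, na.rm = TRUE)
  in_band <- !is.na(g13) & abs(g13 - mu) <= config$gc13_sd_multiplier * sdv
  x <- profiles$ca_axis1
  host_cluster <- rep(TRUE, length(x))
  ctr <- stats::quantile(x, c(0.1, 0.9), names = FALSE, type = 7)
  if (diff(ctr) > .Machine$double.eps^0.5) {
    km <- tryCatch(
      stats::kmeans(x, centers = matrix(ctr, ncol = 1), iter.max = 100L,
                    algorithm = "Lloyd"),
      error = function(e) NULL, warning = function(w) {
        suppressWarnings(stats::kmeans(x, centers = matrix(ctr, ncol = 1),
                                       iter.max = 100L, algorithm = "Lloyd"))
      })
    if (!is.null(km) && all(km$size > 0L)) {
      host_k <- if (km$size[1] != km$size[2]) which.max(km$size)
                else which.min(abs(km$centers - stats::median(x)))
      host_cluster <- km$cluster == host_k
    }
  }
  list(gc13_mean = mu, gc13_sd = sdv,
       membership = data.frame(gene_id = profiles$gene_id,
                               in_host_gc_band = in_band,
                               in_host_codon_cluster = host_cluster,
                               stringsAsFactors = FALSE))
}

#' Compositional profiles for a set of gene models
#'
#' Computes per-gene GC%, GC13%, the informative-codon count matrix, the
#' correspondence analysis, and the host band/cluster memberships.
#'
#' @param genes gene-model data.frame with `gene_id` and `cds`.
#' @param config a [pipeline_config()].
#' @return list: `profiles` data.frame (`gene_id`, `gc_percent`,
#'   `gc13_percent`, `n_codons`, `low_information`, `ca_axis1`,
#'   `in_host_gc_band`, `in_host_codon_cluster`), `ca` the full
#'   `ca_result`, `codon_counts` the count matrix, `gc13_mean`,
#'   `gc13_sd`.
#' @export
composition_profiles <- function(genes, config = pipeline_config()) {
  cds <- stats::setNames(genes$cds, genes$gene_id)
  cc <- codon_count_matrix(cds)
  ca <- correspondence_analysis(cc)
  prof <- data.frame(gene_id = genes$gene_id,
                     gc_percent = gc_percent(genes$cds),
                     gc13_percent = gc13_percent(genes$cds),
                     n_codons = rowSums(cc),
                     low_information = genes$gene_id %in% attr(cc, "low_information"),
                     ca_axis1 = unname(ca$axis1[genes$gene_id]),
                     stringsAsFactors = FALSE)
  hb <- host_bands(prof, config)
  prof$in_host_gc_band <- hb$membership$in_host_gc_band
  prof$in_host_codon_cluster <- hb$membership$in_host_codon_cluster
  list(profiles = prof, ca = ca, codon_counts = cc,
       gc13_mean = hb$gc13_mean, gc13_sd = hb$gc13_sd)
}
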