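#' Pipeline configuration
#'
#' Collects every tunable threshold of the screen in one object. Defaults are
#' the values used throughout: Alien Index cutoff 45 with a prokaryotic best
#' hit, protein-search significance 1e-5, GO-annotation cutoff 1e-4, 1 kb
#' genome windows, a 50 kb minimum contig length, 100 bp minimum prokaryotic
#' similarity per region, a prokaryote-vs-eukaryote bit-score margin of 25,
#' a two-standard-deviation GC13 band, a 10 rpkm expression floor, top-10
#' hits for the taxonomy consensus, and a 1e-200 pseudocount added to
#' e-values before taking logs.
#'
#' @param ai_threshold Alien Index above which a gene is considered alien.
#' @param evalue_threshold_protein significance cutoff for protein hits.
#' @param evalue_threshold_go cutoff for inheriting GO annotations.
#' @param window_size genome window size in bp for the nucleotide screen.
#' @param min_contig_length contigs shorter than this are treated as
#'   untrustworthy assembly (symbiont-like) context, in bp.
#' @param min_region_length minimum prokaryotic-similarity length (bp) for a
#'   nucleotide-screen region to be reported.
#' @param min_bitscore_diff minimum prokaryote-minus-eukaryote bit-score
#'   difference for a region.
#' @param gc13_sd_multiplier half-width of the host GC13 band in SD units.
#' @param min_avg_rpkm minimum mean expression across samples.
#' @param top_hits_for_consensus number of top hits voting in the taxonomy
#'   consensus.
#' @param pseudo_evalue pseudocount added to e-values inside the log.
#' @param seed integer seed for any stochastic step.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(ai_threshold = 45,
                            evalue_threshold_protein = 1e-5,
                            evalue_threshold_go = 1e-4,
                            window_size = 1000L,
                            min_contig_length = 50000L,
                            min_region_length = 100L,
                            min_bitscore_diff = 25,
                            gc13_sd_multiplier = 2,
                            min_avg_rpkm = 10,
                            top_hits_for_consensus = 10L,
                            pseudo_evalue = 1e-200,
                            seed = 1L) {
  cfg <- list(
    ai_threshold = ai_threshold,
    evalue_threshold_protein = evalue_threshold_protein,
    evalue_threshold_go = evalue_threshold_go,
    window_size = as.integer(window_size),
    min_contig_length = as.integer(min_contig_length),
    min_region_length = as.integer(min_region_length),
    min_bitscore_diff = min_bitscore_diff,
    gc13_sd_multiplier = gc13_sd_multiplier,
    min_avg_rpkm = min_avg_rpkm,
    top_hits_for_consensus = as.integer(top_hits_for_consensus),
    pseudo_evalue = pseudo_evalue,
    seed = as.integer(seed)
  )
  num <- vapply(cfg, is.numeric, logical(1))
  if (any(vapply(cfg[num], function(x) any(x < 0), logical(1)) &
          names(cfg)[num] != "seed"))
    stopf("all configuration thresholds must be >= 0")
  if (cfg$window_size <= 0L) stopf("window_size must be > 0")
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Unknown keys are rejected; missing keys take their defaults.
#'
#' @param path file ending in .yaml/.yml or .json.
#' @return a `pipeline_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  vals <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
          else jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stopf("unknown config keys: %s", paste(bad, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' Write a pipeline configuration
#'
#' @param config a `pipeline_config`.
#' @param path destination path, .yaml/.yml or .json.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(x, path)
  else jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
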