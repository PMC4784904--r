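# Shared fixtures. The full default simulation and its pipeline run are
# computed once per test session and reused.

.fixture_cache <- new.env(parent = emptyenv())

default_sim <- function() {
  if (is.null(.fixture_cache$sim))
    .fixture_cache$sim <- simulate_all(simulation_params(seed = 1))
  .fixture_cache$sim
}

default_result <- function() {
  if (is.null(.fixture_cache$res))
    .fixture_cache$res <- suppressMessages(run_pipeline(default_sim()$inputs))
  .fixture_cache$res
}

# Down-scaled study for tests that need several independent runs.
small_params <- function(seed = 202, ...) {
  args <- list(n_host_genes = 60L, n_ancient_hgt = 6L,
               n_recent_hgt = 4L, n_symbiont = 6L, seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(simulation_params, args)
}

# Minimal taxon-labelled hit frame builder.
hit_frame <- function(query = "g1", subject, evalue, bitscore,
                      superkingdom, phylum = superkingdom,
                      is_metazoan = superkingdom == "Metazoa",
                      q_start = 0L, q_end = 100L) {
  sk <- ifelse(superkingdom == "Metazoa", "Eukaryota", superkingdom)
  data.frame(query_id = query, subject_id = subject,
             percent_identity = 0.8, align_length = q_end - q_start,
             q_start = q_start, q_end = q_end,
             evalue = evalue, bitscore = bitscore,
             superkingdom = sk, phylum = phylum,
             is_metazoan = is_metazoan, stringsAsFactors = FALSE)
}

# Random taxon-labelled hit table for fuzzing, deterministic per call site.
random_hit_table <- function(n_hits) {
  sk <- sample(c("Bacteria", "Archaea", "Eukaryota"), n_hits, replace = TRUE)
  met <- sk == "Eukaryota" & stats::runif(n_hits) < 0.6
  data.frame(query_id = "g1",
             subject_id = sprintf("s%03d", sample.int(500, n_hits)),
             percent_identity = stats::runif(n_hits),
             align_length = 100L, q_start = 0L, q_end = 100L,
             evalue = 10^stats::runif(n_hits, -120, 1),
             bitscore = round(stats::runif(n_hits, 30, 500), 1),
             superkingdom = sk,
             phylum = sample(c("Proteobacteria", "Firmicutes", "Chordata",
                               "Porifera", "Ascomycota"), n_hits, replace = TRUE),
             is_metazoan = met, stringsAsFactors = FALSE)
}

# Independent brute-force Alien Index oracle: explicit scan over hits,
# no shared code with compute_alien_index.
ai_oracle <- function(hits, eps = 1e-200, threshold = 45) {
  best_met <- 1; best_non <- 1; seen_met <- FALSE; seen_non <- FALSE
  best_e <- Inf; best_bit <- -Inf; best_sid <- NULL; best_sk <- NA_character_
  for (i in seq_len(nrow(hits))) {
    e <- min(hits$evalue[i], 1)
    if (hits$is_metazoan[i]) {
      seen_met <- TRUE
      if (e < best_met) best_met <- e
    } else {
      seen_non <- TRUE
      if (e < best_non) best_non <- e
    }
    better <- e < best_e ||
      (e == best_e && hits$bitscore[i] > best_bit) ||
      (e == best_e && hits$bitscore[i] == best_bit &&
         !is.null(best_sid) && hits$subject_id[i] < best_sid)
    if (better) {
      best_e <- e; best_bit <- hits$bitscore[i]
      best_sid <- hits$subject_id[i]; best_sk <- hits$superkingdom[i]
    }
  }
  ai <- log(best_met + eps) - log(best_non + eps)
  list(ai = ai,
       flagged = ai >= threshold && isTRUE(best_sk %in% c("Bacteria", "Archaea")))
}

# Hypergeometric upper-tail oracle from binomial coefficients only.
hyper_tail_oracle <- function(k, K, N, n) {
  ks <- seq(max(k, max(0, n - (N - K))), min(K, n))
  if (!length(ks)) return(0)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}
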