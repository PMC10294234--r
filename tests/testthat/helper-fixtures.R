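# Shared, memoized fixtures. Heavy objects (references, pipeline runs) are
# built once per test session.

.fx_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fx_env[[name]])) .fx_env[[name]] <- builder()
  .fx_env[[name]]
}

# Convert an in-memory simulated trio to the layout filter_and_classify
# expects (read_vcf normally adds distance_to_exon).
trio_from_sim <- function(trio_sim, exons) {
  stages <- lapply(trio_sim$records, function(calls) {
    calls$distance_to_exon <- exon_distance(calls$chrom, calls$pos, exons)
    calls
  })
  c(stages, list(drug = trio_sim$drug, replicate = trio_sim$replicate))
}

# Full default pipeline run (the most expensive fixture; ~1 min).
fx_pipeline <- function() {
  fixture("pipeline", function() {
    dir <- file.path(tempdir(), "fx_pipeline")
    res <- run_full_pipeline(sim_config(seed = 1L), dir)
    list(dir = dir, res = res)
  })
}

# Small reference + context index shared by generator/IO tests.
fx_small_ref <- function() {
  fixture("small_ref", function() {
    cfg <- sim_config(seed = 5L, n_genes = 20L,
                      planted_drivers = default_planted_drivers()[0, ])
    re <- simulate_reference(cfg)
    list(cfg = cfg, re = re,
         ctx = tkiclonal:::context_index(re$reference, re$exons))
  })
}

# Large reference supporting 20,000 background variants per trio.
fx_big_ref <- function() {
  fixture("big_ref", function() {
    cfg <- big_sim_config(c(SIG1 = 0.6, SIG2 = 0.4))
    re <- simulate_reference(cfg)
    list(re = re, ctx = tkiclonal:::context_index(re$reference, re$exons))
  })
}

big_sim_config <- function(mix, seed = 11L) {
  sim_config(seed = seed, replicates = c(imatinib = 1L),
             n_genes = 100L, contig_length = 20000L,
             n_background_variants = 20000L,
             signature_mix = mix, n_signatures = 3L,
             planted_drivers = default_planted_drivers()[0, ],
             n_hitchhikers_per_driver = 0L,
             background_profile = c(germline = 0, acquired_high = 1,
                                    shared = 0, low_only = 0,
                                    subthreshold = 0))
}

# Two-drug, two-community configuration whose propagation profiles separate
# exactly by drug: imatinib drivers fill PPI community 1, nilotinib drivers
# community 2 (gene order in planted_drivers fixes the block assignment).
ari_sim_config <- function(seed = 3L) {
  im_genes <- paste0("IMG", 1:8)
  n_genes <- paste0("NG", 1:8)
  rows <- list()
  for (r in 1:2) {
    for (g in im_genes)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, drug = "imatinib", replicate = r,
        vaf_sensitive = NA_real_, vaf_low = 0.5, vaf_high = 0.5,
        consequence = "missense", context = NA_character_,
        clinvar_id = NA_character_, stringsAsFactors = FALSE)
    for (g in n_genes)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, drug = "nilotinib", replicate = r,
        vaf_sensitive = NA_real_, vaf_low = 0.5, vaf_high = 0.5,
        consequence = "missense", context = NA_character_,
        clinvar_id = NA_character_, stringsAsFactors = FALSE)
  }
  sim_config(seed = seed, replicates = c(imatinib = 2L, nilotinib = 2L),
             depth_mean = 10000, n_genes = 16L,
             n_background_variants = 0L, n_hitchhikers_per_driver = 0L,
             ppi_communities = 2L, ppi_p_within = 0.5, ppi_p_between = 0.01,
             planted_drivers = do.call(rbind, rows))
}

# 20,000-variant trio drawn from a 0.6/0.4 two-signature mixture.
fx_big_trio <- function() {
  fixture("big_trio", function() {
    fx <- fx_big_ref()
    mix <- c(SIG1 = 0.6, SIG2 = 0.4)
    cfg <- big_sim_config(mix)
    sigmat <- make_signature_matrix(cfg$n_signatures, seed = cfg$seed)
    trio <- simulate_subline_trio(cfg, fx$re, 1L, "imatinib",
                                  sigmat = sigmat, ctx = fx$ctx)
    list(trio = trio, sigmat = sigmat, mix = mix, re = fx$re)
  })
}

# High-depth default-layout run for parameter-recovery checks.
fx_hidepth <- function() {
  fixture("hidepth", function() {
    cfg <- sim_config(seed = 2L, depth_mean = 10000,
                      n_background_variants = 100L)
    re <- simulate_reference(cfg)
    ctx <- tkiclonal:::context_index(re$reference, re$exons)
    trios <- list()
    for (drug in names(cfg$replicates)) {
      for (r in seq_len(cfg$replicates[[drug]])) {
        trios[[paste0(drug, "-R", r)]] <-
          simulate_subline_trio(cfg, re, r, drug, ctx = ctx)
      }
    }
    list(cfg = cfg, re = re, trios = trios)
  })
}
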