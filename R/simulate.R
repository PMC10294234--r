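#' Simulation configuration for the synthetic TKI-resistance study
#'
#' Builds and validates the configuration that drives every synthetic input:
#' reference and exon geometry, subline trio layout, read-depth model,
#' background mutation load and its signature mixture, PPI community
#' structure, and the planted driver variants whose trajectories the filter
#' cascade must recover.
#'
#' The default layout mirrors the in vitro study design: four imatinib
#' replicates (low 0.5 / high 2 uM) and two nilotinib replicates (low 0.05 /
#' high 0.1 uM), each with a TKI-sensitive parent, sequenced at a mean depth
#' of 60 reads.
#'
#' @param seed Single integer; all randomness flows from it (see Details).
#' @param replicates Named integer vector, replicates per drug.
#' @param depth_mean Mean sequencing depth (reads); per-site depths are
#'   Poisson(depth_mean) floored at 1.
#' @param n_genes Number of genes (one contig per gene).
#' @param contig_length Bases per contig.
#' @param exon_fraction Fraction of each contig covered by exons.
#' @param exons_per_gene Exons per contig.
#' @param n_background_variants Background variants per subline trio.
#' @param signature_mix Named non-negative weights over signature ids,
#'   summing to 1; background trinucleotide contexts are drawn from the
#'   mixture spectrum.
#' @param n_signatures Number of columns in the synthetic signature matrix
#'   (must cover all names in `signature_mix`).
#' @param ppi_communities Number of planted PPI communities.
#' @param ppi_p_within,ppi_p_between Edge probabilities inside/between
#'   communities.
#' @param deep_intronic_fraction Fraction of background variants placed
#'   farther than `deep_intronic_distance` from any exon.
#' @param deep_intronic_distance Distance threshold (bases) defining "deep"
#'   intronic placement; matches the filter module default so the removal
#'   rule is exercised by construction.
#' @param n_hitchhikers_per_driver Passenger variants co-segregating with
#'   each planted driver (same trajectory shape, VAF jittered).
#' @param vaf_jitter Half-width of the uniform jitter on hitchhiker VAFs.
#' @param planted_drivers Data frame of planted variants; see
#'   [default_planted_drivers()].
#' @param background_profile Named probabilities over background trajectory
#'   categories (germline, acquired_high, shared, low_only, subthreshold).
#'
#' @details All randomness is drawn from R's default generator, seeded once
#' per public `simulate_*` entry point with a value derived from `seed` (and,
#' for trios, from the drug index and replicate number), so each trio is
#' reproducible in isolation. Within a trio the stream order is: planted
#' positions, hitchhiker genes/positions/jitter, background categories/
#' contexts/positions/VAFs, then read depths and alt counts stage by stage
#' (sensitive, low, high).
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       replicates = c(imatinib = 4L, nilotinib = 2L),
                       depth_mean = 60,
                       n_genes = 60L,
                       contig_length = 3000L,
                       exon_fraction = 0.5,
                       exons_per_gene = 4L,
                       n_background_variants = 400L,
                       signature_mix = c(SIG1 = 0.6, SIG2 = 0.4),
                       n_signatures = 3L,
                       ppi_communities = 2L,
                       ppi_p_within = 0.2,
                       ppi_p_between = 0.01,
                       deep_intronic_fraction = 0.05,
                       deep_intronic_distance = 20L,
                       n_hitchhikers_per_driver = 2L,
                       vaf_jitter = 0.05,
                       planted_drivers = default_planted_drivers(),
                       background_profile = c(germline = 0.35,
                                              acquired_high = 0.25,
                                              shared = 0.20,
                                              low_only = 0.08,
                                              subthreshold = 0.12)) {
  cfg <- list(seed = as.integer(seed), replicates = replicates,
              depth_mean = depth_mean, n_genes = as.integer(n_genes),
              contig_length = as.integer(contig_length),
              exon_fraction = exon_fraction,
              exons_per_gene = as.integer(exons_per_gene),
              n_background_variants = as.integer(n_background_variants),
              signature_mix = signature_mix,
              n_signatures = as.integer(n_signatures),
              ppi_communities = as.integer(ppi_communities),
              ppi_p_within = ppi_p_within, ppi_p_between = ppi_p_between,
              deep_intronic_fraction = deep_intronic_fraction,
              deep_intronic_distance = as.integer(deep_intronic_distance),
              n_hitchhikers_per_driver = as.integer(n_hitchhikers_per_driver),
              vaf_jitter = vaf_jitter,
              planted_drivers = planted_drivers,
              background_profile = background_profile)
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

#' @keywords internal
validate_sim_config <- function(cfg) {
  if (length(cfg$seed) != 1L || is.na(cfg$seed))
    stop("configuration error: seed must be a single integer")
  if (cfg$depth_mean <= 0)
    stop("configuration error: depth_mean must be > 0")
  fr <- c(cfg$exon_fraction, cfg$deep_intronic_fraction)
  if (any(fr < 0 | fr > 1))
    stop("configuration error: fractions must lie in [0, 1]")
  if (any(cfg$signature_mix < 0))
    stop("configuration error: signature_mix weights must be >= 0")
  if (abs(sum(cfg$signature_mix) - 1) > 1e-9)
    stop("configuration error: signature_mix weights must sum to 1")
  if (length(cfg$signature_mix) > cfg$n_signatures)
    stop("configuration error: signature_mix names more signatures than ",
         "n_signatures provides")
  if (cfg$ppi_communities < 1L || cfg$n_genes < cfg$ppi_communities)
    stop("configuration error: need n_genes >= ppi_communities >= 1")
  pd <- cfg$planted_drivers
  if (nrow(pd) > 0) {
    vaf_cols <- as.matrix(pd[, c("vaf_sensitive", "vaf_low", "vaf_high")])
    if (any(rowSums(!is.na(vaf_cols)) == 0))
      stop("configuration error: planted variant with all stages ABSENT")
    if (any(vaf_cols < 0 | vaf_cols > 1, na.rm = TRUE))
      stop("configuration error: planted VAFs must lie in [0, 1]")
    bad <- !pd$drug %in% names(cfg$replicates)
    if (any(bad)) stop("input error: unknown drug label: ",
                       paste(unique(pd$drug[bad]), collapse = ", "))
  }
  invisible(cfg)
}

#' Default planted driver variants
#'
#' A set of acquired driver trajectories modelled on the variants recurrently
#' observed in imatinib- and nilotinib-resistant K-562 sublines: late gains in
#' the high-dose line (e.g. PTPN11, PDGFRB, KRAS G12D-like trajectories),
#' early gains retained at constant VAF (NRAS-like), a two-variant gene in
#' one subline (LRP1B-like multihit), a truncating variant (MCM3AP-like) and
#' low-dose-only clones. `NA` stage VAFs encode absence (zero alternate
#' reads), not missing data. The `context` column is the full SBS channel the
#' variant is planted into (`NA` for non-SNVs, which get a random exonic
#' placement).
#'
#' @return Data frame with columns gene, drug, replicate, vaf_sensitive,
#'   vaf_low, vaf_high, consequence, context, clinvar_id.
#' @export
default_planted_drivers <- function() {
  d <- function(gene, drug, rep, vs, vl, vh, csq, ctx, cv = NA_character_)
    data.frame(gene = gene, drug = drug, replicate = rep,
               vaf_sensitive = vs, vaf_low = vl, vaf_high = vh,
               consequence = csq, context = ctx, clinvar_id = cv,
               stringsAsFactors = FALSE)
  rbind(
    d("LRP1B",   "imatinib", 1L, NA, NA,     0.3881, "missense",  "T[C>A]T"),
    d("LRP1B",   "imatinib", 1L, NA, NA,     0.3040, "missense",  "C[C>G]A"),
    d("SALL4",   "imatinib", 1L, NA, NA,     0.4322, "missense",  "A[C>T]G"),
    d("MCM3AP",  "imatinib", 1L, NA, 0.25,   0.25,   "stop_gain", "A[C>T]A"),
    d("PTPN11",  "imatinib", 2L, NA, NA,     0.6929, "missense",  "T[T>C]A",
      "13328"),
    d("PDGFRB",  "imatinib", 2L, NA, NA,     0.2830, "missense",  "G[C>G]C"),
    d("RELA",    "imatinib", 2L, NA, 0.2828, 0.2923, "missense",  "A[T>A]T"),
    d("TNC",     "imatinib", 2L, NA, 0.2,    0.2222, "missense",  "C[T>C]C"),
    d("KRAS",    "imatinib", 3L, 0,  0.087,  0.6667, "missense",  "G[C>T]A",
      "12581"),
    d("KMT2D",   "imatinib", 3L, 0,  0.09,   0.3710, "missense",  "C[C>T]G",
      "449928"),
    d("KRAS",    "imatinib", 4L, NA, NA,     0.2927, "missense",  "C[C>T]A",
      "12582"),
    d("CACNA1D", "imatinib", 4L, NA, 0.4444, NA,     "missense",  "T[C>A]C"),
    d("ABL1",    "nilotinib", 1L, NA, 0.2648, NA,    "missense",  "A[C>A]G"),
    d("CREBBP",  "nilotinib", 1L, NA, 0.4066, NA,    "missense",  "T[T>G]T"),
    d("MYH9",    "nilotinib", 1L, NA, NA,     0.3810, "missense", "G[C>A]T"),
    d("NRAS",    "nilotinib", 2L, 0,  0.2917, 0.3333, "missense", "G[C>A]A",
      "73058"),
    d("TRRAP",   "nilotinib", 2L, NA, 0.2993, 0.2685, "missense", "A[T>C]C"),
    d("PDE4DIP", "nilotinib", 2L, NA, 0.3,    0.1961, "missense", "T[C>T]C")
  )
}

#' Gene universe implied by a configuration
#'
#' Planted driver genes first, padded with synthetic background genes up to
#' `n_genes`.
#'
#' @param cfg A [sim_config()].
#' @return Character vector of gene symbols (one contig each).
#' @export
sim_genes <- function(cfg) {
  drivers <- unique(cfg$planted_drivers$gene)
  n_pad <- cfg$n_genes - length(drivers)
  if (n_pad < 0)
    stop("configuration error: n_genes smaller than planted driver genes")
  c(drivers, sprintf("GENE%03d", seq_len(n_pad)))
}

#' Simulate a reference genome and exon annotation
#'
#' One contig per gene (the synthetic convention: a variant's gene is its
#' contig), with `exons_per_gene` exons per contig covering roughly
#' `exon_fraction` of the bases. Exon intervals are stored 1-based inclusive
#' in the returned `GRanges` and written 0-based half-open when exported to
#' BED.
#'
#' @param cfg A [sim_config()].
#' @return List with `reference` (named [Biostrings::DNAStringSet]) and
#'   `exons` ([GenomicRanges::GRanges]).
#' @export
simulate_reference <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  genes <- sim_genes(cfg)
  L <- cfg$contig_length
  n_ex <- cfg$exons_per_gene
  seqs <- character(length(genes))
  ex_list <- vector("list", length(genes))
  seg <- L %/% n_ex
  exon_len <- max(1L, round(cfg$exon_fraction * L / n_ex))
  for (i in seq_along(genes)) {
    seqs[i] <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                     collapse = "")
    off <- sample.int(max(1L, seg - exon_len), n_ex, replace = TRUE)
    start <- (seq_len(n_ex) - 1L) * seg + off
    end <- pmin(start + exon_len - 1L, L)
    ex_list[[i]] <- data.frame(gene = genes[i], start = start, end = end)
  }
  ref <- Biostrings::DNAStringSet(seqs)
  names(ref) <- genes
  ex <- do.call(rbind, ex_list)
  exons <- GenomicRanges::GRanges(
    seqnames = ex$gene,
    ranges = IRanges::IRanges(start = ex$start, end = ex$end),
    seqlengths = stats::setNames(rep(L, length(genes)), genes))
  list(reference = ref, exons = exons)
}

#' Index every internal reference position by its pyrimidine-centred triplet
#'
#' @param reference Named DNAStringSet.
#' @param exons Exon GRanges (1-based inclusive).
#' @return Data frame gene, pos, triplet (pyrimidine-normalized), exonic,
#'   dist (distance to nearest exon boundary; 0 if exonic).
#' @keywords internal
context_index <- function(reference, exons) {
  pyr <- c("C", "T")
  out <- vector("list", length(reference))
  exdf <- as.data.frame(exons)
  for (i in seq_along(reference)) {
    g <- names(reference)[i]
    s <- as.character(reference[[i]])
    n <- nchar(s)
    pos <- 2:(n - 1L)
    trip <- substring(s, pos - 1L, pos + 1L)
    center <- substring(s, pos, pos)
    flip <- !center %in% pyr
    trip[flip] <- revcomp(trip[flip])
    ge <- exdf[exdf$seqnames == g, , drop = FALSE]
    dist <- rep(Inf, length(pos))
    for (j in seq_len(nrow(ge)))
      dist <- pmin(dist, pmax(ge$start[j] - pos, pos - ge$end[j], 0))
    out[[i]] <- data.frame(gene = g, pos = pos, triplet = trip,
                           exonic = dist == 0, dist = dist,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' @keywords internal
parse_channel <- function(channel) {
  # "A[C>T]G" -> list(triplet="ACG", ref="C", alt="T")
  f <- substring(channel, 1, 1)
  r <- substring(channel, 3, 3)
  a <- substring(channel, 5, 5)
  t3 <- substring(channel, 7, 7)
  list(triplet = paste0(f, r, t3), ref = r, alt = a)
}

# Sample one unused position matching a pyrimidine-normalized triplet and
# placement ("exonic", "intronic", "deep_intronic", "any"), optionally within
# one gene. Returns a one-row slice of the index.
#' @keywords internal
sample_position <- function(ctx, triplet, placement, deep_dist, used,
                            gene = NULL) {
  pool <- ctx$triplet == triplet
  if (!is.null(gene)) pool <- pool & ctx$gene == gene
  pool <- pool & switch(placement,
                        exonic = ctx$exonic,
                        intronic = !ctx$exonic,
                        deep_intronic = ctx$dist > deep_dist,
                        any = rep(TRUE, nrow(ctx)))
  idx <- which(pool)
  if (length(idx) == 0)
    stop("configuration error: no reference position available for triplet ",
         triplet, " (", placement,
         if (!is.null(gene)) paste0(", gene ", gene) else "", ")")
  for (k in seq_len(50L)) {
    i <- idx[sample.int(length(idx), 1L)]
    key <- paste0(ctx$gene[i], ":", ctx$pos[i])
    if (is.null(used[[key]])) {
      used[[key]] <- TRUE
      return(ctx[i, , drop = FALSE])
    }
  }
  stop("configuration error: exhausted positions for triplet ", triplet)
}

#' @keywords internal
actual_ref_alt <- function(reference, gene, pos, channel) {
  p <- parse_channel(channel)
  base <- as.character(Biostrings::subseq(reference[[gene]], pos, pos))
  if (base %in% c("C", "T")) list(ref = p$ref, alt = p$alt)
  else list(ref = base, alt = revcomp(p$alt))
}

#' @keywords internal
classify_vafs <- function(vs, vl, vh, delta_min = 0.15) {
  vs0 <- ifelse(is.na(vs), 0, vs); vl0 <- ifelse(is.na(vl), 0, vl)
  vh0 <- ifelse(is.na(vh), 0, vh)
  dl <- vl0 - vs0; dh <- vh0 - vs0
  ifelse(pmax(dl, dh) <= delta_min, "NONE",
  ifelse(dh > delta_min & dl <= delta_min, "ACQUIRED_HIGH",
  ifelse(dl > delta_min & dh <= delta_min, "LOW_ONLY",
  ifelse(vl0 - vh0 > delta_min, "SHARED_REDUCED_HIGH", "SHARED_CONSTANT"))))
}

#' Simulate one subline trio (sensitive, low, high) with ground truth
#'
#' Plants the configured driver variants for this replicate, attaches
#' co-segregating hitchhikers (same trajectory shape, jittered VAF), and adds
#' background variants whose trajectory category is drawn from
#' `background_profile` and whose trinucleotide context is drawn from the
#' signature-mixture spectrum. Per variant and stage, total depth is
#' Poisson(`depth_mean`) floored at 1 and alternate depth is
#' Binomial(depth, true VAF); a stage with true VAF `NA` (ABSENT) emits zero
#' alternate reads, and records with zero alternate reads are not written.
#'
#' @param cfg A [sim_config()].
#' @param ref_exons Output of [simulate_reference()].
#' @param replicate Replicate number.
#' @param drug "imatinib" or "nilotinib".
#' @param sigmat Signature matrix (96 x k); defaults to
#'   [make_signature_matrix()] under the configured seed.
#' @param ctx Optional precomputed [context_index()] (recomputed if NULL).
#' @return List with `records` (per-stage call tables, names sensitive/low/
#'   high), `truth` (one row per emitted variant: key, gene, consequence,
#'   context channel, kind, stage VAFs, true class), `labels` (subline
#'   labels), `drug`, `replicate`.
#' @export
simulate_subline_trio <- function(cfg, ref_exons, replicate, drug,
                                  sigmat = NULL, ctx = NULL) {
  validate_sim_config(cfg)
  if (!drug %in% names(cfg$replicates))
    stop("input error: unknown drug label: ", drug)
  reference <- ref_exons$reference
  if (is.null(ctx)) ctx <- context_index(reference, ref_exons$exons)
  if (is.null(sigmat))
    sigmat <- make_signature_matrix(cfg$n_signatures, seed = cfg$seed)
  drug_idx <- match(drug, names(cfg$replicates))
  set.seed((cfg$seed %% 100000L) * 10000L + drug_idx * 100L +
             as.integer(replicate))
  used <- new.env(parent = emptyenv())
  deep <- cfg$deep_intronic_distance

  place <- function(gene, consequence, channel) {
    placement <- if (consequence == "intronic") "deep_intronic" else "exonic"
    if (is.na(channel)) {
      row <- NULL
      pool <- which(ctx$gene == gene &
                      (if (placement == "exonic") ctx$exonic
                       else ctx$dist > deep))
      i <- pool[sample.int(length(pool), 1L)]
      row <- ctx[i, , drop = FALSE]
      used[[paste0(row$gene, ":", row$pos)]] <- TRUE
      base <- as.character(
        Biostrings::subseq(reference[[gene]], row$pos, row$pos))
      alt <- if (consequence == "frameshift")
        paste0(base, sample(c("A", "C", "G", "T"), 1L))
      else sample(setdiff(c("A", "C", "G", "T"), base), 1L)
      list(gene = gene, pos = row$pos, ref = base, alt = alt)
    } else {
      p <- parse_channel(channel)
      row <- sample_position(ctx, p$triplet, placement, deep, used,
                             gene = gene)
      ra <- actual_ref_alt(reference, row$gene, row$pos, channel)
      list(gene = row$gene, pos = row$pos, ref = ra$ref, alt = ra$alt)
    }
  }

  # --- planted drivers -------------------------------------------------
  pd <- cfg$planted_drivers
  pd <- pd[pd$drug == drug & pd$replicate == replicate, , drop = FALSE]
  rows <- list()
  add_row <- function(loc, csq, channel, kind, vs, vl, vh,
                      cv = NA_character_) {
    data.frame(chrom = loc$gene, pos = loc$pos, ref = loc$ref, alt = loc$alt,
               gene = loc$gene, consequence = csq,
               context = if (is.na(channel)) NA_character_ else channel,
               kind = kind, vaf_sensitive = vs, vaf_low = vl, vaf_high = vh,
               clinvar_id = cv, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(pd))) {
    loc <- place(pd$gene[i], pd$consequence[i], pd$context[i])
    rows[[length(rows) + 1L]] <-
      add_row(loc, pd$consequence[i], pd$context[i], "driver",
              pd$vaf_sensitive[i], pd$vaf_low[i], pd$vaf_high[i],
              pd$clinvar_id[i])
  }

  # --- hitchhikers ------------------------------------------------------
  genes <- sim_genes(cfg)
  bg_genes <- setdiff(genes, unique(cfg$planted_drivers$gene))
  mix_p <- as.vector(sigmat[, names(cfg$signature_mix), drop = FALSE] %*%
                       cfg$signature_mix)
  channels <- sbs96_channels()
  jitter1 <- function(v) {
    ifelse(is.na(v), NA_real_,
           pmin(1, pmax(0.01, v + stats::runif(length(v), -cfg$vaf_jitter,
                                               cfg$vaf_jitter))))
  }
  for (i in seq_len(nrow(pd))) {
    for (h in seq_len(cfg$n_hitchhikers_per_driver)) {
      g <- sample(bg_genes, 1L)
      ch <- sample(channels, 1L, prob = mix_p)
      loc <- place(g, "missense", ch)
      rows[[length(rows) + 1L]] <-
        add_row(loc, "missense", ch, "hitchhiker",
                jitter1(pd$vaf_sensitive[i]), jitter1(pd$vaf_low[i]),
                jitter1(pd$vaf_high[i]))
    }
  }

  # --- background (vectorized; placement grouped by triplet) -----------
  nb <- cfg$n_background_variants
  bg <- NULL
  if (nb > 0) {
    cats <- sample(names(cfg$background_profile), nb, replace = TRUE,
                   prob = cfg$background_profile)
    chs <- sample(channels, nb, replace = TRUE, prob = mix_p)
    is_deep <- stats::runif(nb) < cfg$deep_intronic_fraction
    csq <- ifelse(is_deep, "intronic",
                  sample(c("missense", "synonymous", "stop_gain"), nb,
                         replace = TRUE, prob = c(0.75, 0.2, 0.05)))
    trip <- paste0(substring(chs, 1, 1), substring(chs, 3, 3),
                   substring(chs, 7, 7))
    placement <- ifelse(csq == "intronic", "deep_intronic", "exonic")
    used_keys <- ls(used)
    idx <- integer(nb)
    for (grp in split(seq_len(nb), paste(trip, placement))) {
      t1 <- trip[grp[1]]; pl <- placement[grp[1]]
      pool <- which(ctx$triplet == t1 &
                      (if (pl == "exonic") ctx$exonic else ctx$dist > deep))
      if (length(used_keys) > 0)
        pool <- pool[!paste0(ctx$gene[pool], ":", ctx$pos[pool]) %in%
                       used_keys]
      if (length(pool) < length(grp))
        stop("configuration error: not enough reference positions for ",
             "triplet ", t1, " (", pl, "); enlarge the reference")
      idx[grp] <- pool[sample.int(length(pool), length(grp))]
    }
    seq_str <- stats::setNames(as.character(reference), names(reference))
    gene_bg <- ctx$gene[idx]
    pos_bg <- ctx$pos[idx]
    base <- substring(seq_str[gene_bg], pos_bg, pos_bg)
    alt_py <- substring(chs, 5, 5)
    on_pyr <- base %in% c("C", "T")
    ref_bg <- base  # matched triplet center: equals the channel ref on the
                    # pyrimidine strand, its complement otherwise
    alt_bg <- ifelse(on_pyr, alt_py, chartr("ACGT", "TGCA", alt_py))
    u1 <- stats::runif(nb); u2 <- stats::runif(nb)
    vs <- numeric(nb); vl <- numeric(nb); vh <- numeric(nb)
    i <- cats == "germline"
    vs[i] <- vl[i] <- vh[i] <- 0.3 + 0.3 * u1[i]
    i <- cats == "acquired_high"
    vl[i] <- 0.05 * u1[i]; vh[i] <- 0.2 + 0.4 * u2[i]
    i <- cats == "shared"
    vl[i] <- 0.2 + 0.3 * u1[i]
    vh[i] <- pmin(1, vl[i] + (u2[i] - 0.5) * 0.1)
    i <- cats == "low_only"
    vl[i] <- 0.2 + 0.3 * u1[i]; vh[i] <- NA_real_
    i <- cats == "subthreshold"
    vl[i] <- 0.12 * u1[i]; vh[i] <- 0.12 * u2[i]
    bg <- data.frame(chrom = gene_bg, pos = pos_bg, ref = ref_bg,
                     alt = alt_bg, gene = gene_bg, consequence = csq,
                     context = chs, kind = paste0("background_", cats),
                     vaf_sensitive = vs, vaf_low = vl, vaf_high = vh,
                     clinvar_id = NA_character_, stringsAsFactors = FALSE)
  }
  truth <- rbind(do.call(rbind, rows), bg)
  truth$true_class <- classify_vafs(truth$vaf_sensitive, truth$vaf_low,
                                    truth$vaf_high)

  # --- read sampling ----------------------------------------------------
  stages <- c(sensitive = "vaf_sensitive", low = "vaf_low", high = "vaf_high")
  records <- list()
  for (st in names(stages)) {
    vaf <- truth[[stages[[st]]]]
    n <- nrow(truth)
    depth <- pmax(1L, stats::rpois(n, cfg$depth_mean))
    alt <- integer(n)
    present <- !is.na(vaf) & vaf > 0
    alt[present] <- stats::rbinom(sum(present), depth[present], vaf[present])
    keep <- alt > 0L
    records[[st]] <- data.frame(
      chrom = truth$chrom[keep], pos = truth$pos[keep],
      ref = truth$ref[keep], alt = truth$alt[keep],
      gene = truth$gene[keep], consequence = truth$consequence[keep],
      depth = depth[keep], alt_depth = alt[keep],
      stringsAsFactors = FALSE)
  }
  labels <- c(sensitive = paste0("sens", c(imatinib = "IM",
                                           nilotinib = "N")[[drug]],
                                 "-R", replicate),
              low = subline_label(drug, "low", replicate),
              high = subline_label(drug, "high", replicate))
  list(records = records, truth = truth, labels = labels,
       drug = drug, replicate = as.integer(replicate))
}

#' Synthetic reference signature matrix
#'
#' Draws `n` sparse, well-separated 96-channel signature profiles
#' (normalized gamma draws, i.e. Dirichlet with small concentration), named
#' SIG1..SIGn. Synthetic stand-ins for a COSMIC-style reference; the fitting
#' code treats any matrix in this layout as opaque input.
#'
#' @param n Number of signatures.
#' @param seed Integer seed.
#' @param concentration Dirichlet concentration (smaller = peakier).
#' @return 96 x n matrix, rownames the canonical channels, columns sum to 1.
#' @export
make_signature_matrix <- function(n = 3L, seed = 1L, concentration = 0.15) {
  set.seed(as.integer(seed) + 424243L)
  m <- matrix(stats::rgamma(96L * n, shape = concentration), nrow = 96L)
  m <- sweep(m, 2, colSums(m), "/")
  rownames(m) <- sbs96_channels()
  colnames(m) <- paste0("SIG", seq_len(n))
  m
}

#' Simulate a PPI network with planted communities
#'
#' Stochastic block model over the configured gene universe: genes are
#' assigned to `ppi_communities` contiguous blocks, edges drawn with
#' probability `ppi_p_within` inside and `ppi_p_between` between blocks.
#' Undirected, simple, no self-loops; every gene is a node (possibly
#' isolated).
#'
#' @param cfg A [sim_config()].
#' @return An [igraph] graph with vertex attribute `community`.
#' @export
simulate_ppi <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed + 777L)
  genes <- sim_genes(cfg)
  n <- length(genes)
  k <- cfg$ppi_communities
  sizes <- rep(n %/% k, k)
  sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1L
  pm <- matrix(cfg$ppi_p_between, k, k)
  diag(pm) <- cfg$ppi_p_within
  g <- igraph::sample_sbm(n, pref.matrix = pm, block.sizes = sizes)
  igraph::V(g)$name <- genes
  comm <- rep(seq_len(k), times = sizes)
  igraph::V(g)$community <- comm
  g <- igraph::simplify(g)
  # tether isolated genes to a same-community partner so the graph survives
  # an edge-list round trip (the format cannot carry degree-0 nodes)
  iso <- which(igraph::degree(g) == 0)
  for (v in iso) {
    pool <- setdiff(which(comm == comm[v]), v)
    if (length(pool) == 0) pool <- setdiff(seq_len(n), v)
    g <- igraph::add_edges(g, c(v, pool[sample.int(length(pool), 1L)]))
  }
  g
}

#' Simulate gene sets over the PPI communities
#'
#' One set per planted community (its exact membership) plus `n_random`
#' random sets, so set-level propagation scores have known structure.
#'
#' @param cfg A [sim_config()].
#' @param graph Output of [simulate_ppi()].
#' @param n_random Number of additional random sets.
#' @param random_size Size of each random set.
#' @return Named list of gene vectors.
#' @export
simulate_gene_sets <- function(cfg, graph, n_random = 5L, random_size = 15L) {
  set.seed(cfg$seed + 778L)
  genes <- igraph::V(graph)$name
  comm <- igraph::V(graph)$community
  sets <- lapply(sort(unique(comm)), function(k) genes[comm == k])
  names(sets) <- paste0("COMMUNITY_", sort(unique(comm)))
  for (i in seq_len(n_random)) {
    sets[[paste0("RANDOM_", i)]] <-
      sample(genes, min(random_size, length(genes)))
  }
  sets
}

#' Simulate a driver-gene catalogue
#'
#' All planted driver genes plus a configurable fraction of decoy background
#' genes, with a nominal role column.
#'
#' @param cfg A [sim_config()].
#' @param decoy_fraction Fraction of non-driver genes included as decoys.
#' @return Data frame with columns gene, role.
#' @export
simulate_driver_catalogue <- function(cfg, decoy_fraction = 0.3) {
  set.seed(cfg$seed + 779L)
  drivers <- unique(cfg$planted_drivers$gene)
  others <- setdiff(sim_genes(cfg), drivers)
  decoys <- sample(others, round(decoy_fraction * length(others)))
  data.frame(gene = c(drivers, decoys),
             role = sample(c("oncogene", "tsg"),
                           length(drivers) + length(decoys), replace = TRUE),
             stringsAsFactors = FALSE)
}
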