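# The staged VAF filter cascade and trajectory classification across the
# sensitive -> low-dose -> high-dose resistant trio. Thresholds follow the
# study design: drop variants already present in the sensitive parent
# (VAF >= 0.05), drop deep-intronic variants, and keep variants whose VAF
# rises by more than 0.15 in at least one resistant stage. All threshold
# comparisons are strict where the rule says "greater than", so ties at the
# exact threshold fail.

#' Filter cascade configuration
#'
#' @param min_depth Minimum read depth (default 10): a variant passes the
#'   coverage gate if at least one sample where it is called reaches this
#'   depth.
#' @param sensitive_vaf_max Variants with sensitive-stage VAF at or above
#'   this fraction are considered pre-existing and removed (default 0.05).
#' @param delta_vaf_min Minimum VAF gain over the sensitive stage, strict
#'   (default 0.15).
#' @param deep_intronic_distance Intronic variants farther than this many
#'   bases from any exon boundary are removed (default 20, the conventional
#'   splice-region bound).
#' @return List of class `filter_config`.
#' @export
filter_config <- function(min_depth = 10L, sensitive_vaf_max = 0.05,
                          delta_vaf_min = 0.15,
                          deep_intronic_distance = 20L) {
  if (min_depth < 0 || sensitive_vaf_max < 0 || delta_vaf_min < 0 ||
      deep_intronic_distance < 0)
    stop("configuration error: thresholds must be >= 0")
  if (sensitive_vaf_max >= 1 || delta_vaf_min > 1)
    stop("configuration error: VAF thresholds out of range")
  structure(list(min_depth = min_depth,
                 sensitive_vaf_max = sensitive_vaf_max,
                 delta_vaf_min = delta_vaf_min,
                 deep_intronic_distance = deep_intronic_distance),
            class = "filter_config")
}

#' Variant allele frequency of calls
#'
#' `alt_depth / depth` at full precision; `NA` (undefined) at zero depth,
#' which downstream treatment maps to a coverage failure. Percentage
#' rendering for reports is a separate concern ([render_vaf_pct()]).
#'
#' @param calls Data frame with `alt_depth` and `depth` columns (e.g. the
#'   `calls` of a `subline_sample`).
#' @return Numeric vector of fractions.
#' @export
compute_vaf <- function(calls) {
  ifelse(calls$depth > 0, calls$alt_depth / calls$depth, NA_real_)
}

#' Filter and classify variant trajectories across a subline trio
#'
#' Takes the union of variant keys across the three stages; a key absent
#' from a stage has VAF `NA` (ABSENT), treated as 0 when computing deltas.
#' The cascade, in order:
#' 1. `FAIL_depth` unless at least one sample where the variant is called
#'    has depth >= `min_depth` (zero-depth calls are undefined-VAF and count
#'    as uncovered);
#' 2. `FAIL_sensitive` if the sensitive-stage VAF >= `sensitive_vaf_max`;
#' 3. `FAIL_intronic` if the consequence is intronic and the distance to the
#'    nearest exon exceeds `deep_intronic_distance`;
#' 4. `FAIL_delta` unless `max(delta_low, delta_high) > delta_vaf_min`.
#'
#' Passing variants are classified: `ACQUIRED_HIGH` (gained only in the
#' high-dose line), `LOW_ONLY` (gained only in the low-dose line),
#' `SHARED_REDUCED_HIGH` (gained in both but dropping by more than
#' `delta_vaf_min` from low to high), else `SHARED_CONSTANT`.
#'
#' @param trio A `subline_trio` from [read_trio()], or a plain list with
#'   `sensitive`, `low`, `high` elements each carrying a `calls` data frame,
#'   plus optional `drug` / `replicate`.
#' @param cfg A [filter_config()].
#' @return Data frame, one row per variant key: key columns, gene,
#'   consequence, stage VAFs (`NA` = ABSENT), deltas, `verdict`,
#'   `clonal_class` (`NONE` unless PASS), and `pass_low` / `pass_high`
#'   flags marking in which resistant subline(s) the gain exceeds the
#'   threshold.
#' @export
filter_and_classify <- function(trio, cfg = filter_config()) {
  stages <- c("sensitive", "low", "high")
  if (!all(stages %in% names(trio)))
    stop("input error: trio must have sensitive, low and high samples")
  tabs <- lapply(stages, function(st) {
    s <- trio[[st]]
    calls <- if (is.data.frame(s)) s else s$calls
    calls$key <- variant_key(calls$chrom, calls$pos, calls$ref, calls$alt)
    calls
  })
  names(tabs) <- stages
  keys <- unique(unlist(lapply(tabs, `[[`, "key"), use.names = FALSE))
  if (length(keys) == 0) {
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      gene = character(), consequence = character(),
                      vaf_sensitive = numeric(), vaf_low = numeric(),
                      vaf_high = numeric(), delta_low = numeric(),
                      delta_high = numeric(), verdict = character(),
                      clonal_class = character(), pass_low = logical(),
                      pass_high = logical(), drug = character(),
                      replicate = integer(), stringsAsFactors = FALSE))
  }
  base <- do.call(rbind, lapply(tabs, function(t)
    t[, c("key", "chrom", "pos", "ref", "alt", "gene", "consequence",
          "distance_to_exon")]))
  base <- base[!duplicated(base$key), , drop = FALSE]
  base <- base[match(keys, base$key), , drop = FALSE]

  stage_col <- function(st, col) {
    t <- tabs[[st]]
    t[[col]][match(keys, t$key)]
  }
  depth <- sapply(stages, function(st) stage_col(st, "depth"))
  altd <- sapply(stages, function(st) stage_col(st, "alt_depth"))
  if (length(keys) == 1L) { depth <- t(depth); altd <- t(altd) }
  vaf <- ifelse(!is.na(depth) & depth > 0, altd / depth, NA_real_)
  called <- !is.na(depth)

  vs0 <- ifelse(is.na(vaf[, 1]), 0, vaf[, 1])
  vl0 <- ifelse(is.na(vaf[, 2]), 0, vaf[, 2])
  vh0 <- ifelse(is.na(vaf[, 3]), 0, vaf[, 3])
  delta_low <- vl0 - vs0
  delta_high <- vh0 - vs0
  t_min <- cfg$delta_vaf_min

  # zero-depth calls have undefined VAF and never satisfy the coverage gate
  depth_ok <- rowSums(called & !is.na(depth) & depth > 0 &
                        depth >= cfg$min_depth, na.rm = TRUE) > 0
  verdict <- rep("PASS", length(keys))
  verdict[!(pmax(delta_low, delta_high) > t_min)] <- "FAIL_delta"
  verdict[base$consequence == "intronic" &
            base$distance_to_exon > cfg$deep_intronic_distance] <-
    "FAIL_intronic"
  verdict[vs0 >= cfg$sensitive_vaf_max] <- "FAIL_sensitive"
  verdict[!depth_ok] <- "FAIL_depth"

  clonal_class <- rep("NONE", length(keys))
  p <- verdict == "PASS"
  clonal_class[p & delta_high > t_min & delta_low <= t_min] <- "ACQUIRED_HIGH"
  clonal_class[p & delta_low > t_min & delta_high <= t_min] <- "LOW_ONLY"
  shared <- p & clonal_class == "NONE"
  clonal_class[shared & (vl0 - vh0 > t_min)] <- "SHARED_REDUCED_HIGH"
  clonal_class[shared & !(vl0 - vh0 > t_min)] <- "SHARED_CONSTANT"

  data.frame(chrom = base$chrom, pos = base$pos, ref = base$ref,
             alt = base$alt, gene = base$gene,
             consequence = base$consequence,
             vaf_sensitive = vaf[, 1], vaf_low = vaf[, 2],
             vaf_high = vaf[, 3],
             delta_low = delta_low, delta_high = delta_high,
             verdict = verdict, clonal_class = clonal_class,
             pass_low = p & delta_low > t_min,
             pass_high = p & delta_high > t_min,
             drug = trio$drug %||% NA_character_,
             replicate = trio$replicate %||% NA_integer_,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-subline mutation burden
#'
#' One row per resistant subline: the count of PASS variants whose VAF gain
#' in that subline exceeds the threshold (the per-stage count), the class
#' breakdown, and the trio's total of unique PASS variants (both counting
#' conventions are reported).
#'
#' @param trajectories A trajectory data frame from [filter_and_classify()],
#'   or a list of them (one per trio).
#' @return Data frame with subline, drug, replicate, level, n_pass,
#'   per-class counts, and n_pass_unique_trio.
#' @export
burden_table <- function(trajectories) {
  if (is.data.frame(trajectories)) trajectories <- list(trajectories)
  classes <- c("ACQUIRED_HIGH", "SHARED_REDUCED_HIGH", "SHARED_CONSTANT",
               "LOW_ONLY")
  rows <- list()
  for (tr in trajectories) {
    for (level in c("low", "high")) {
      in_sub <- tr[[paste0("pass_", level)]]
      cls <- table(factor(tr$clonal_class[in_sub], levels = classes))
      drug <- tr$drug[1]
      rep_id <- tr$replicate[1]
      rows[[length(rows) + 1L]] <- data.frame(
        subline = if (!is.na(drug)) subline_label(drug, level, rep_id)
                  else paste0(level, "-NA"),
        drug = drug, replicate = rep_id, level = level,
        n_pass = sum(in_sub),
        as.list(cls),
        n_pass_unique_trio = sum(tr$verdict == "PASS"),
        stringsAsFactors = FALSE, check.names = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(subline = character(), drug = character(),
                      replicate = integer(), level = character(),
                      n_pass = integer())
  rownames(out) <- NULL
  out
}
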