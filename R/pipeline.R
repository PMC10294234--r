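# Stage orchestration: each run_* step reads its inputs from a directory,
# writes its module's outputs plus a run-metadata JSON, and fails with an
# actionable error naming any missing upstream file. The thin command-line
# wrapper in inst/cli/tkiclonal.R maps subcommands onto these functions.

#' @keywords internal
config_hash <- function(cfg) {
  tf <- tempfile()
  on.exit(unlink(tf))
  jsonlite::write_json(cfg, tf, auto_unbox = TRUE, digits = NA,
                       force = TRUE, na = "null")
  unname(tools::md5sum(tf))
}

#' @keywords internal
write_metadata <- function(dir, step, cfg, extra = list()) {
  meta <- c(list(step = step,
                 package = "tkiclonal",
                 version = as.character(utils::packageVersion("tkiclonal")),
                 config = cfg,
                 config_hash = config_hash(cfg)),
            extra)
  jsonlite::write_json(meta, file.path(dir, paste0(step, "_metadata.json")),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       na = "null")
  invisible(meta)
}

#' @keywords internal
require_files <- function(paths, step) {
  missing <- paths[!file.exists(unlist(paths))]
  if (length(missing) > 0)
    stop("input error: `", step, "` requires missing file(s): ",
         paste(unlist(missing), collapse = ", "),
         " (run the upstream step first)")
  invisible(TRUE)
}

#' Generate all synthetic inputs (simulate step)
#'
#' @param cfg A [sim_config()].
#' @param out_dir Output directory.
#' @return Invisibly, the manifest from [write_synthetic_inputs()].
#' @export
run_simulate <- function(cfg, out_dir) {
  man <- write_synthetic_inputs(cfg, out_dir)
  trios <- lapply(man$trios, function(tr)
    list(drug = tr$drug, replicate = tr$replicate,
         labels = as.list(tr$labels), paths = lapply(tr$paths, basename)))
  jsonlite::write_json(list(trios = trios, paths = lapply(man$paths,
                                                          basename)),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, na = "null")
  cfg_plain <- unclass(cfg)
  cfg_plain$replicates <- as.list(cfg_plain$replicates)
  cfg_plain$signature_mix <- as.list(cfg_plain$signature_mix)
  cfg_plain$background_profile <- as.list(cfg_plain$background_profile)
  write_metadata(out_dir, "simulate", cfg_plain,
                 list(seed = cfg$seed))
  invisible(man)
}

#' @keywords internal
read_manifest <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  require_files(list(manifest = mf), "pipeline")
  jsonlite::fromJSON(mf, simplifyVector = FALSE)
}

#' Run the filter cascade on every trio (filter step)
#'
#' Reads the VCF trios named in `<in_dir>/manifest.json`, applies
#' [filter_and_classify()] and writes `trajectories.tsv` (one row per
#' variant key per trio) and `burden.tsv`.
#'
#' @param in_dir Directory holding the simulate outputs.
#' @param out_dir Output directory (defaults to `in_dir`).
#' @param cfg A [filter_config()].
#' @return Invisibly, the combined trajectory data frame.
#' @export
run_filter <- function(in_dir, out_dir = in_dir, cfg = filter_config()) {
  man <- read_manifest(in_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  exons_path <- file.path(in_dir, man$paths$exons)
  require_files(list(exons = exons_path), "filter")
  exons <- read_exons_bed(exons_path)
  all_tr <- list()
  for (tr in man$trios) {
    paths <- lapply(tr$paths, function(p) file.path(in_dir, p))
    require_files(paths, "filter")
    trio <- read_trio(paths, exons, tr$drug, tr$replicate)
    all_tr[[paste0(tr$drug, "-R", tr$replicate)]] <-
      filter_and_classify(trio, cfg)
  }
  combined <- do.call(rbind, all_tr)
  rownames(combined) <- NULL
  utils::write.table(combined, file.path(out_dir, "trajectories.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(burden_table(all_tr), file.path(out_dir, "burden.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_metadata(out_dir, "filter", unclass(cfg))
  invisible(combined)
}

#' @keywords internal
read_trajectories <- function(dir) {
  path <- file.path(dir, "trajectories.tsv")
  require_files(list(trajectories = path), "downstream")
  tr <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(ref = "character",
                                         alt = "character"))
  split(tr, paste0(tr$drug, "-R", tr$replicate))
}

#' Driver annotation and oncoplot (drivers step)
#'
#' @param in_dir Directory with simulate + filter outputs.
#' @param out_dir Output directory (defaults to `in_dir`).
#' @return Invisibly, list with `hits` and `oncoplot`.
#' @export
run_drivers <- function(in_dir, out_dir = in_dir) {
  man <- read_manifest(in_dir)
  trs <- read_trajectories(in_dir)
  cat_path <- file.path(in_dir, man$paths$catalogue)
  cv_path <- file.path(in_dir, man$paths$clinvar)
  require_files(list(catalogue = cat_path, clinvar = cv_path), "drivers")
  catalogue <- read_driver_catalogue(cat_path)
  clinvar <- read_clinvar_lookup(cv_path)
  hits <- annotate_drivers(do.call(rbind, trs), catalogue, clinvar)
  onc <- build_oncoplot(hits[hits$in_catalogue, , drop = FALSE])
  utils::write.table(hits, file.path(out_dir, "driver_hits.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(gene = rownames(onc), onc,
                                check.names = FALSE),
                     file.path(out_dir, "oncoplot.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_metadata(out_dir, "drivers", list())
  invisible(list(hits = hits, oncoplot = onc))
}

#' Mutational-signature spectra and exposures (signatures step)
#'
#' @param in_dir Directory with simulate + filter outputs.
#' @param out_dir Output directory (defaults to `in_dir`).
#' @return Invisibly, the [subline_signatures()] result.
#' @export
run_signatures <- function(in_dir, out_dir = in_dir) {
  man <- read_manifest(in_dir)
  trs <- read_trajectories(in_dir)
  ref_path <- file.path(in_dir, man$paths$reference)
  sig_path <- file.path(in_dir, man$paths$signatures)
  require_files(list(reference = ref_path, signatures = sig_path),
                "signatures")
  reference <- Biostrings::readDNAStringSet(ref_path)
  names(reference) <- sub(" .*", "", names(reference))
  sigmat <- read_signature_matrix(sig_path)
  res <- subline_signatures(trs, reference, sigmat)
  utils::write.table(data.frame(Type = rownames(res$spectra), res$spectra,
                                check.names = FALSE),
                     file.path(out_dir, "spectra.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(subline = rownames(res$exposures),
                                res$exposures, check.names = FALSE),
                     file.path(out_dir, "exposures.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(as.list(res$dominant),
                       file.path(out_dir, "dominant_signatures.json"),
                       auto_unbox = TRUE)
  write_metadata(out_dir, "signatures", list())
  invisible(res)
}

#' Network propagation, gene-set scoring and clustering (propagate step)
#'
#' @param in_dir Directory with simulate + filter outputs.
#' @param out_dir Output directory (defaults to `in_dir`).
#' @param cfg A [propagation_config()].
#' @param k_sublines,k_genesets Cluster counts (NULL = silhouette-automatic).
#' @param enrichment_path Optional TSV of a precomputed expression-enrichment
#'   matrix to compare against.
#' @return Invisibly, list with scores, geneset scores, partitions and (if
#'   requested) the enrichment comparison.
#' @export
run_propagate <- function(in_dir, out_dir = in_dir,
                          cfg = propagation_config(),
                          k_sublines = NULL, k_genesets = NULL,
                          enrichment_path = NULL) {
  man <- read_manifest(in_dir)
  trs <- read_trajectories(in_dir)
  edge_path <- file.path(in_dir, man$paths$edges)
  gmt_path <- file.path(in_dir, man$paths$gene_sets)
  require_files(list(edges = edge_path, gene_sets = gmt_path), "propagate")
  graph <- read_graph(edge_path)
  sets <- read_gmt(gmt_path)
  prop <- propagate_sublines(trs, graph, cfg)
  gs <- score_genesets(prop$scores, sets)
  subline_clusters <- cluster_profiles(prop$scores, k = k_sublines)
  ok <- rowSums(is.na(gs$scaled)) == 0
  geneset_clusters <- cluster_profiles(t(gs$scaled[ok, , drop = FALSE]),
                                       k = k_genesets)
  utils::write.table(data.frame(gene = rownames(prop$scores), prop$scores,
                                check.names = FALSE),
                     file.path(out_dir, "propagation_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(gene_set = rownames(gs$scaled), gs$scaled,
                                check.names = FALSE),
                     file.path(out_dir, "geneset_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  clus <- rbind(data.frame(item = names(subline_clusters), kind = "subline",
                           cluster = as.integer(subline_clusters)),
                data.frame(item = names(geneset_clusters), kind = "gene_set",
                           cluster = as.integer(geneset_clusters)))
  utils::write.table(clus, file.path(out_dir, "clusters.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  comparison <- NULL
  if (!is.null(enrichment_path)) {
    require_files(list(enrichment = enrichment_path), "propagate")
    enr <- read_enrichment_matrix(enrichment_path)
    comparison <- compare_matrices(gs$scaled, enr)
    jsonlite::write_json(comparison, file.path(out_dir, "comparison.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  write_metadata(out_dir, "propagate", unclass(cfg),
                 list(k_sublines = attr(subline_clusters, "k"),
                      k_genesets = attr(geneset_clusters, "k")))
  invisible(list(propagation = prop, geneset_scores = gs,
                 subline_clusters = subline_clusters,
                 geneset_clusters = geneset_clusters,
                 comparison = comparison))
}

#' Join all stage outputs into one summary (report step)
#'
#' @param dir Directory holding the outputs of the previous steps.
#' @return Invisibly, the report list (also written as `report.json`).
#' @export
run_report <- function(dir) {
  need <- list(burden = file.path(dir, "burden.tsv"),
               hits = file.path(dir, "driver_hits.tsv"),
               dominant = file.path(dir, "dominant_signatures.json"),
               clusters = file.path(dir, "clusters.tsv"))
  require_files(need, "report")
  burden <- utils::read.delim(need$burden, stringsAsFactors = FALSE)
  hits <- utils::read.delim(need$hits, stringsAsFactors = FALSE,
                            colClasses = c(ref = "character",
                                           alt = "character"))
  dominant <- jsonlite::fromJSON(need$dominant)
  clusters <- utils::read.delim(need$clusters, stringsAsFactors = FALSE)
  driver_table <- hits[hits$in_catalogue, , drop = FALSE]
  report <- list(burden = burden,
                 driver_table = driver_table,
                 dominant_signatures = dominant,
                 clusters = clusters)
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       na = "null")
  write_metadata(dir, "report", list())
  invisible(report)
}

#' Run the whole pipeline on synthetic inputs
#'
#' Convenience wrapper: simulate, filter, drivers, signatures, propagate,
#' report, all into one directory.
#'
#' @param sim A [sim_config()].
#' @param dir Output directory.
#' @param filter A [filter_config()].
#' @param prop A [propagation_config()].
#' @param k_sublines,k_genesets Cluster counts (NULL = automatic).
#' @return Invisibly, list with the manifest, trajectories, driver results,
#'   signature results, propagation results and the report.
#' @export
run_full_pipeline <- function(sim = sim_config(), dir,
                              filter = filter_config(),
                              prop = propagation_config(),
                              k_sublines = NULL, k_genesets = NULL) {
  man <- run_simulate(sim, dir)
  traj <- run_filter(dir, dir, filter)
  drv <- run_drivers(dir, dir)
  sig <- run_signatures(dir, dir)
  net <- run_propagate(dir, dir, prop, k_sublines = k_sublines,
                       k_genesets = k_genesets)
  rep <- run_report(dir)
  invisible(list(manifest = man, trajectories = traj, drivers = drv,
                 signatures = sig, propagation = net, report = rep))
}
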