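# Writers for the synthetic inputs. Readers (the pipeline-facing side) live
# in io.R; every format written here is read back through those readers in
# the round-trip tests.

#' Write a per-subline VCF (v4.2, single sample, DP/AD FORMAT)
#'
#' Records carry `GENE` and `CSQ` INFO fields (the synthetic gene/consequence
#' convention) and per-sample GT, DP and AD (`AD = ref,alt`).
#'
#' @param calls Data frame with chrom, pos, ref, alt, gene, consequence,
#'   depth, alt_depth.
#' @param sample_name Sample column name.
#' @param path Output path.
#' @param contig_lengths Named integer vector of contig lengths.
#' @return `path`, invisibly.
#' @export
write_subline_vcf <- function(calls, sample_name, path, contig_lengths) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
            as.integer(contig_lengths)),
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    paste0("##INFO=<ID=CSQ,Number=1,Type=String,",
           "Description=\"Consequence class\">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
           "Description=\"Allelic depths (ref,alt)\">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_name), collapse = "\t"))
  o <- order(calls$chrom, calls$pos, calls$alt)
  calls <- calls[o, , drop = FALSE]
  body <- if (nrow(calls) == 0) character(0) else
    paste(calls$chrom, calls$pos, ".", calls$ref, calls$alt, ".", "PASS",
          paste0("GENE=", calls$gene, ";CSQ=", calls$consequence),
          "GT:DP:AD",
          paste0("0/1:", calls$depth, ":",
                 calls$depth - calls$alt_depth, ",", calls$alt_depth),
          sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write gene sets in GMT format
#'
#' @param sets Named list of gene vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "synthetic", sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Write a PPI edge list as TSV
#'
#' @param graph igraph graph.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  el <- igraph::as_edgelist(graph)
  df <- data.frame(gene_a = el[, 1], gene_b = el[, 2])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a signature matrix in COSMIC-style TSV layout
#'
#' First column `Type` holds the channel labels; one column per signature.
#'
#' @param sigmat 96 x k matrix with channel rownames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signature_matrix <- function(sigmat, path) {
  df <- data.frame(Type = rownames(sigmat), sigmat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Generate and write every pipeline input to a directory
#'
#' Runs the full synthetic generator under the configuration's seed and
#' writes: reference FASTA, exon BED (0-based half-open), one VCF per subline
#' (sensitive, low, high per replicate), signature matrix TSV, driver
#' catalogue TSV, ClinVar-style lookup TSV, PPI edge-list TSV, gene sets GMT,
#' and the ground truth JSON.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a manifest list: file paths (`paths`), trio metadata
#'   (`trios`), and the in-memory `truth`, `graph`, `sigmat`, `gene_sets`.
#' @export
write_synthetic_inputs <- function(cfg, dir) {
  validate_sim_config(cfg)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  re <- simulate_reference(cfg)
  sigmat <- make_signature_matrix(cfg$n_signatures, seed = cfg$seed)
  ctx <- context_index(re$reference, re$exons)
  graph <- simulate_ppi(cfg)
  sets <- simulate_gene_sets(cfg, graph)
  catalogue <- simulate_driver_catalogue(cfg)

  p <- list(reference = file.path(dir, "reference.fa"),
            exons = file.path(dir, "exons.bed"),
            signatures = file.path(dir, "signatures.tsv"),
            catalogue = file.path(dir, "driver_catalogue.tsv"),
            clinvar = file.path(dir, "clinvar_lookup.tsv"),
            edges = file.path(dir, "ppi_edges.tsv"),
            gene_sets = file.path(dir, "gene_sets.gmt"),
            truth = file.path(dir, "ground_truth.json"))
  Biostrings::writeXStringSet(re$reference, p$reference)
  rtracklayer::export(re$exons, p$exons, format = "BED")
  write_signature_matrix(sigmat, p$signatures)
  utils::write.table(catalogue, p$catalogue, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_edge_list(graph, p$edges)
  write_gmt(sets, p$gene_sets)

  contig_lengths <- stats::setNames(Biostrings::width(re$reference),
                                    names(re$reference))
  trios <- list()
  truth_all <- list()
  vcf_paths <- list()
  for (drug in names(cfg$replicates)) {
    for (r in seq_len(cfg$replicates[[drug]])) {
      trio <- simulate_subline_trio(cfg, re, r, drug, sigmat = sigmat,
                                    ctx = ctx)
      tp <- list()
      for (st in names(trio$records)) {
        lbl <- trio$labels[[st]]
        tp[[st]] <- file.path(dir, paste0(lbl, ".vcf"))
        write_subline_vcf(trio$records[[st]], lbl, tp[[st]], contig_lengths)
      }
      key <- paste0(drug, "-R", r)
      trios[[key]] <- list(drug = drug, replicate = r,
                           labels = trio$labels, paths = tp)
      t <- trio$truth
      t$drug <- drug
      t$replicate <- r
      truth_all[[key]] <- t
      vcf_paths[[key]] <- tp
    }
  }
  truth <- do.call(rbind, truth_all)
  rownames(truth) <- NULL

  cv <- truth[truth$kind == "driver" & !is.na(truth$clinvar_id),
              c("chrom", "pos", "ref", "alt", "clinvar_id"), drop = FALSE]
  cv$significance <- rep("Pathogenic", nrow(cv))
  utils::write.table(unique(cv), p$clinvar, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  truth_json <- list(
    variants = truth,
    exposures = lapply(trios, function(tr) as.list(cfg$signature_mix)),
    communities = stats::setNames(as.list(igraph::V(graph)$community),
                                  igraph::V(graph)$name))
  jsonlite::write_json(truth_json, p$truth, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, na = "null")

  invisible(list(paths = p, trios = trios, truth = truth, graph = graph,
                 sigmat = sigmat, gene_sets = sets, reference = re))
}
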