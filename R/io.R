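# Pipeline-facing readers. Coordinate conventions: VCF positions are 1-based
# inclusive; BED is 0-based half-open and converted to 1-based GRanges once,
# at read time (rtracklayer); everything downstream is 1-based.

#' Read exon intervals from BED
#'
#' @param path BED file (0-based half-open).
#' @return [GenomicRanges::GRanges], 1-based inclusive.
#' @export
read_exons_bed <- function(path) {
  rtracklayer::import(path, format = "BED")
}

#' Distance from positions to the nearest exon boundary
#'
#' 0 for positions inside an exon; otherwise the minimum over exons of the
#' distance to the nearer boundary (a position one base past an exon end has
#' distance 1). `Inf` for contigs without exons.
#'
#' @param chrom,pos Parallel vectors of contig and 1-based position.
#' @param exons Exon GRanges (1-based inclusive).
#' @return Numeric vector of distances.
#' @export
exon_distance <- function(chrom, pos, exons) {
  exdf <- data.frame(chrom = as.character(GenomicRanges::seqnames(exons)),
                     start = GenomicRanges::start(exons),
                     end = GenomicRanges::end(exons))
  out <- rep(Inf, length(pos))
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    e <- exdf[exdf$chrom == ch, , drop = FALSE]
    if (nrow(e) == 0) next
    d <- rep(Inf, length(i))
    for (j in seq_len(nrow(e)))
      d <- pmin(d, pmax(e$start[j] - pos[i], pos[i] - e$end[j], 0))
    out[i] <- d
  }
  out
}

#' Read one subline's variant calls from VCF
#'
#' Requires per-sample `DP` and `AD` FORMAT fields; VAF is always recomputed
#' as `alt_depth / depth` (an AF tag is never trusted). Multi-allelic records
#' are split into one call per alternate allele. Gene symbols come from a
#' `GENE` INFO field when present, else from the contig name (the synthetic
#' one-contig-per-gene convention); consequence from a `CSQ` INFO field, else
#' `"other"`. Calls with zero depth are retained with undefined VAF (they are
#' removed later by the coverage filter).
#'
#' @param path VCF file.
#' @param exons Exon GRanges from [read_exons_bed()].
#' @param sample_meta List with `drug` ("imatinib", "nilotinib" or "none"),
#'   `level` ("sensitive", "low", "high"), `replicate`.
#' @return A `subline_sample`: list with drug, level, replicate and a `calls`
#'   data frame (chrom, pos, ref, alt, gene, depth, alt_depth, consequence,
#'   distance_to_exon, snv).
#' @export
read_vcf <- function(path, exons, sample_meta) {
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  g <- VariantAnnotation::geno(vcf)
  if (!all(c("DP", "AD") %in% names(g)))
    stop("format error: VCF ", path, " lacks DP and/or AD FORMAT fields")
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt_list <- as.list(VariantAnnotation::alt(vcf))
  dp <- as.vector(g$DP[, 1])
  ad <- g$AD
  ad_of <- function(i) {
    x <- if (is.list(ad)) ad[[i, 1]] else ad[i, 1, ]
    as.integer(x)
  }
  inf <- VariantAnnotation::info(vcf)
  gene <- if ("GENE" %in% names(inf)) as.character(inf$GENE) else chrom
  csq <- if ("CSQ" %in% names(inf)) as.character(inf$CSQ)
         else rep("other", length(chrom))
  gene[is.na(gene)] <- chrom[is.na(gene)]
  csq[is.na(csq)] <- "other"

  rows <- vector("list", length(chrom))
  for (i in seq_along(chrom)) {
    alts <- as.character(alt_list[[i]])
    adi <- ad_of(i)
    if (is.na(dp[i]) || anyNA(adi) || length(adi) < length(alts) + 1L)
      stop("format error: missing DP/AD at record ", chrom[i], ":", pos[i])
    rows[[i]] <- data.frame(
      chrom = chrom[i], pos = pos[i], ref = ref[i], alt = alts,
      gene = gene[i], depth = dp[i], alt_depth = adi[-1L][seq_along(alts)],
      consequence = csq[i], stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, rows)
  if (is.null(calls))
    calls <- data.frame(chrom = character(), pos = integer(),
                        ref = character(), alt = character(),
                        gene = character(), depth = integer(),
                        alt_depth = integer(), consequence = character(),
                        stringsAsFactors = FALSE)
  bad <- calls$alt_depth > calls$depth | calls$pos < 1
  if (any(bad))
    stop("format error: alt_depth > depth at record ",
         calls$chrom[bad][1], ":", calls$pos[bad][1])
  calls$distance_to_exon <- exon_distance(calls$chrom, calls$pos, exons)
  calls$snv <- is_snv(calls$ref, calls$alt)
  structure(list(drug = sample_meta$drug, level = sample_meta$level,
                 replicate = sample_meta$replicate, calls = calls),
            class = "subline_sample")
}

#' Read the sensitive/low/high VCFs of one replicate as a trio
#'
#' @param paths Named list/vector with elements `sensitive`, `low`, `high`.
#' @param exons Exon GRanges.
#' @param drug Drug of the resistant sublines.
#' @param replicate Replicate id.
#' @return A `subline_trio`: list with sensitive, low, high
#'   `subline_sample`s plus drug and replicate.
#' @export
read_trio <- function(paths, exons, drug, replicate) {
  need <- c("sensitive", "low", "high")
  if (!all(need %in% names(paths)))
    stop("input error: trio needs sensitive, low and high VCF paths")
  samples <- lapply(need, function(st) {
    read_vcf(paths[[st]], exons,
             list(drug = if (st == "sensitive") "none" else drug,
                  level = st, replicate = replicate))
  })
  names(samples) <- need
  structure(c(samples, list(drug = drug, replicate = replicate)),
            class = "subline_trio")
}

#' Read a COSMIC-layout signature matrix
#'
#' TSV with a `Type` column of channel labels (`"A[C>A]A"`) and one column
#' per signature. Rows are reordered to the canonical channel order, so the
#' result is invariant to input row order. Columns whose sum is within 1e-3
#' of 1 are renormalized to exactly 1; anything else is an error, as are
#' negative weights or a context set other than the canonical 96.
#'
#' @param path TSV file.
#' @return 96 x k numeric matrix, rownames the canonical channels.
#' @export
read_signature_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  if (!"Type" %in% names(df))
    stop("format error: signature matrix needs a Type column")
  channels <- sbs96_channels()
  if (nrow(df) != 96L || !setequal(df$Type, channels))
    stop("format error: signature matrix must have exactly the 96 canonical ",
         "contexts (got ", nrow(df), " rows)")
  m <- as.matrix(df[match(channels, df$Type), setdiff(names(df), "Type"),
                    drop = FALSE])
  rownames(m) <- channels
  if (any(m < 0)) stop("format error: negative signature weights")
  cs <- colSums(m)
  if (any(abs(cs - 1) > 1e-3))
    stop("format error: signature columns must sum to 1 (max deviation ",
         format(max(abs(cs - 1))), ")")
  sweep(m, 2, cs, "/")
}

#' Read a PPI edge list
#'
#' Two-column TSV (header `gene_a`, `gene_b`). The graph is undirected,
#' deduplicated (A-B and B-A collapse), self-loops dropped, symbols
#' upper-cased.
#'
#' @param path TSV file.
#' @return igraph graph.
#' @export
read_graph <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2)
    stop("format error: edge list needs two columns")
  df[[1]] <- toupper(df[[1]]); df[[2]] <- toupper(df[[2]])
  g <- igraph::graph_from_data_frame(df[, 1:2], directed = FALSE)
  igraph::simplify(g)
}

#' Read gene sets from GMT
#'
#' @param path GMT file (set name, description, then genes, tab-separated).
#' @return Named list of upper-cased gene vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("format error: malformed GMT line ", i, " (need >= 3 fields)")
    sets[[f[1]]] <- toupper(f[-(1:2)])
  }
  sets
}

#' Read a driver-gene catalogue
#'
#' TSV with a `gene` column (or first column). Symbols are upper-cased and
#' deduplicated; matching downstream is case-insensitive and invariant to
#' row order.
#'
#' @param path TSV file.
#' @return Character vector of gene symbols.
#' @export
read_driver_catalogue <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  col <- if ("gene" %in% names(df)) df$gene else df[[1]]
  unique(toupper(col))
}

#' Read a ClinVar-style variant lookup
#'
#' @param path TSV with columns chrom, pos, ref, alt, clinvar_id and
#'   optionally significance.
#' @return Data frame keyed by (chrom, pos, ref, alt).
#' @export
read_clinvar_lookup <- function(path) {
  hdr <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  need <- c("chrom", "pos", "ref", "alt", "clinvar_id")
  if (!all(need %in% hdr))
    stop("format error: ClinVar lookup needs columns ",
         paste(need, collapse = ", "))
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(ref = "character",
                                         alt = "character"))
  df$clinvar_id <- as.character(df$clinvar_id)
  df
}

#' Read a precomputed expression-enrichment matrix
#'
#' Rows are gene sets, columns sublines (as written by e.g. a GSVA run).
#'
#' @param path TSV file with row names in the first column.
#' @return Numeric matrix.
#' @export
read_enrichment_matrix <- function(path) {
  df <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  as.matrix(df)
}
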