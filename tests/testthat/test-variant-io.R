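# Readers and writers: VCF round trip, coordinate conventions, format
# validation of signature matrices, edge lists, GMT and lookup tables.

simple_exons <- function() {
  GenomicRanges::GRanges("GENEA",
                         IRanges::IRanges(start = 101, end = 200))
}

write_raw_vcf <- function(body, path,
                          format = "GT:DP:AD",
                          contig = "##contig=<ID=GENEA,length=1000>") {
  hdr <- c(
    "##fileformat=VCFv4.2", contig,
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"g\">",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"c\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"dp\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"ad\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", "S1"), collapse = "\t"))
  writeLines(c(hdr, body), path)
  path
}

test_that("subline VCFs round-trip through write and read", {
  cfg <- sim_config(seed = 9L, replicates = c(imatinib = 1L), n_genes = 20L,
                    n_background_variants = 50L,
                    planted_drivers = default_planted_drivers()[0, ],
                    n_hitchhikers_per_driver = 0L)
  re <- simulate_reference(cfg)
  trio <- simulate_subline_trio(cfg, re, 1L, "imatinib")
  calls <- trio$records$high
  path <- tempfile(fileext = ".vcf")
  lens <- stats::setNames(Biostrings::width(re$reference),
                          names(re$reference))
  write_subline_vcf(calls, "highIM-R1", path, lens)
  exons <- re$exons
  got <- read_vcf(path, exons,
                  list(drug = "imatinib", level = "high", replicate = 1L))
  expect_s3_class(got, "subline_sample")
  cols <- c("chrom", "pos", "ref", "alt", "gene", "depth", "alt_depth",
            "consequence")
  want <- calls[order(calls$chrom, calls$pos, calls$alt), cols]
  have <- got$calls[order(got$calls$chrom, got$calls$pos, got$calls$alt),
                    cols]
  rownames(want) <- rownames(have) <- NULL
  expect_equal(have, want)
  # distance_to_exon is attached and zero inside exons
  exdf <- as.data.frame(exons)
  inside <- mapply(function(ch, p) {
    any(exdf$seqnames == ch & exdf$start <= p & p <= exdf$end)
  }, got$calls$chrom, got$calls$pos)
  expect_identical(unname(got$calls$distance_to_exon == 0), unname(inside))
})

test_that("multi-allelic records split into one call per alternate", {
  path <- write_raw_vcf(paste("GENEA", 150, ".", "A", "C,G", ".", "PASS",
                              "GENE=GENEA;CSQ=missense", "GT:DP:AD",
                              "0/1:72:10,48,24", sep = "\t"),
                        tempfile(fileext = ".vcf"))
  s <- read_vcf(path, simple_exons(),
                list(drug = "imatinib", level = "low", replicate = 1L))
  expect_equal(nrow(s$calls), 2L)
  expect_equal(s$calls$alt, c("C", "G"))
  expect_equal(s$calls$depth, c(72L, 72L))
  expect_equal(s$calls$alt_depth, c(48L, 24L))
})

test_that("a VCF without AD is a format error", {
  hdr <- c("##fileformat=VCFv4.2",
           "##contig=<ID=GENEA,length=1000>",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"dp\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", "S1"), collapse = "\t"),
           paste("GENEA", 150, ".", "A", "C", ".", "PASS", ".",
                 "GT:DP", "0/1:50", sep = "\t"))
  path <- tempfile(fileext = ".vcf")
  writeLines(hdr, path)
  expect_error(read_vcf(path, simple_exons(),
                        list(drug = "imatinib", level = "low",
                             replicate = 1L)),
               "format error")
})

test_that("zero-depth calls are retained with undefined VAF", {
  path <- write_raw_vcf(paste("GENEA", 150, ".", "A", "C", ".", "PASS",
                              "GENE=GENEA;CSQ=missense", "GT:DP:AD",
                              "0/1:0:0,0", sep = "\t"),
                        tempfile(fileext = ".vcf"))
  s <- read_vcf(path, simple_exons(),
                list(drug = "imatinib", level = "low", replicate = 1L))
  expect_equal(nrow(s$calls), 1L)
  expect_equal(s$calls$depth, 0L)
  expect_true(is.na(compute_vaf(s$calls)))
})

test_that("exon_distance follows the boundary convention", {
  # BED interval [100, 200) is 1-based [101, 200]
  bed <- tempfile(fileext = ".bed")
  writeLines("GENEA\t100\t200", bed)
  exons <- read_exons_bed(bed)
  expect_equal(GenomicRanges::start(exons), 101)
  expect_equal(GenomicRanges::end(exons), 200)
  expect_equal(exon_distance("GENEA", 150, exons), 0)
  expect_equal(exon_distance("GENEA", 250, exons), 50)
  expect_equal(exon_distance("GENEA", 201, exons), 1)
  expect_equal(exon_distance("GENEA", 100, exons), 1)
  expect_equal(exon_distance("GENEB", 150, exons), Inf)
  # brute force over many positions and a multi-exon annotation
  ex2 <- GenomicRanges::GRanges(
    rep("G", 3), IRanges::IRanges(start = c(10, 50, 300),
                                  end = c(20, 80, 400)))
  pos <- 1:450
  got <- exon_distance(rep("G", length(pos)), pos, ex2)
  brute <- vapply(pos, function(p) {
    min(vapply(seq_len(3), function(j) {
      s <- GenomicRanges::start(ex2)[j]; e <- GenomicRanges::end(ex2)[j]
      if (p >= s && p <= e) 0 else min(abs(p - s), abs(p - e))
    }, 0))
  }, 0)
  expect_equal(got, brute)
})

test_that("signature matrix reading is order-invariant and validated", {
  m <- make_signature_matrix(3L, seed = 4L)
  path <- tempfile(fileext = ".tsv")
  write_signature_matrix(m, path)
  got <- read_signature_matrix(path)
  expect_equal(got, m, tolerance = 1e-12)
  # shuffled rows read back identically
  df <- utils::read.delim(path, check.names = FALSE)
  set.seed(1); df <- df[sample(nrow(df)), ]
  shuf <- tempfile(fileext = ".tsv")
  utils::write.table(df, shuf, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_signature_matrix(shuf), m, tolerance = 1e-12)
  # 95 rows
  utils::write.table(df[-1, ], shuf, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(read_signature_matrix(shuf), "96")
  # negative weight
  df2 <- utils::read.delim(path, check.names = FALSE)
  df2$SIG1[1] <- -df2$SIG1[1] - 0.001
  utils::write.table(df2, shuf, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_signature_matrix(shuf), "negative")
  # near-1 column sums renormalize to exactly 1
  df3 <- utils::read.delim(path, check.names = FALSE)
  df3$SIG1 <- df3$SIG1 * 1.0005
  utils::write.table(df3, shuf, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(unname(colSums(read_signature_matrix(shuf))), rep(1, 3))
  # far-from-1 column sums are an error
  df3$SIG1 <- df3$SIG1 * 2
  utils::write.table(df3, shuf, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_signature_matrix(shuf), "sum to 1")
})

test_that("edge lists deduplicate, drop self-loops and upper-case", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("gene_a\tgene_b", "abl1\tKRAS", "KRAS\tABL1", "NRAS\tNRAS",
               "NRAS\tKRAS"), path)
  g <- read_graph(path)
  expect_setequal(igraph::V(g)$name, c("ABL1", "KRAS", "NRAS"))
  expect_equal(igraph::ecount(g), 2)
  expect_true(igraph::are_adjacent(g, "ABL1", "KRAS"))
  expect_false(igraph::is_directed(g))
})

test_that("GMT reading validates line structure", {
  path <- tempfile(fileext = ".gmt")
  writeLines(c("SET_A\tdesc\tkras\tNRAS", "SET_B\tdesc\tABL1"), path)
  sets <- read_gmt(path)
  expect_equal(sets$SET_A, c("KRAS", "NRAS"))
  expect_equal(sets$SET_B, "ABL1")
  writeLines(c("SET_A\tdesc\tKRAS", "SET_B\tdesc"), path)
  expect_error(read_gmt(path), "line 2")
})

test_that("driver catalogue and ClinVar lookups validate and normalize", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("gene", "kras", "KRAS", "Nras"), path)
  expect_equal(read_driver_catalogue(path), c("KRAS", "NRAS"))
  cv <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tref\talt\tclinvar_id",
               "KRAS\t25\tT\tT\t12581"), cv)
  lk <- read_clinvar_lookup(cv)
  expect_identical(lk$ref, "T")   # all-T columns must stay character
  expect_identical(lk$clinvar_id, "12581")
  writeLines("chrom\tpos\tref", cv)
  expect_error(read_clinvar_lookup(cv), "format error")
})
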