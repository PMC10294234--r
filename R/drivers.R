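# Driver-gene catalogue intersection, ClinVar flags, multihit detection and
# the gene x subline oncoplot matrix.

#' Annotate PASS trajectories against a driver catalogue
#'
#' Only PASS trajectories are considered. Consequence classes: `TRUNCATING`
#' for stop-gain or frameshift, `MISSENSE` for missense, else `OTHER`.
#' ClinVar ids attach on exact (chrom, pos, ref, alt) match. One output row
#' per variant x resistant subline in which the variant's VAF gain passed
#' the threshold (so a variant shared by low and high of a replicate marks
#' both subline columns). Catalogue matching is case-insensitive.
#'
#' @param trajectories Trajectory data frame from [filter_and_classify()]
#'   (or several rbind-ed together, with `drug` / `replicate` columns).
#' @param catalogue Character vector of driver genes
#'   ([read_driver_catalogue()]).
#' @param clinvar_lookup Optional data frame from [read_clinvar_lookup()].
#' @return Data frame of driver hits: key columns, gene, subline, vaf (in
#'   that subline), consequence_class, in_catalogue, clinvar_id,
#'   clonal_class.
#' @export
annotate_drivers <- function(trajectories, catalogue,
                             clinvar_lookup = NULL) {
  tr <- trajectories[trajectories$verdict == "PASS", , drop = FALSE]
  rows <- list()
  for (level in c("low", "high")) {
    sub <- tr[tr[[paste0("pass_", level)]], , drop = FALSE]
    if (nrow(sub) == 0) next
    sub$subline <- subline_label(sub$drug, level, sub$replicate)
    sub$vaf <- sub[[paste0("vaf_", level)]]
    rows[[level]] <- sub
  }
  hits <- do.call(rbind, rows)
  if (is.null(hits) || nrow(hits) == 0)
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      gene = character(), subline = character(),
                      vaf = numeric(), consequence_class = character(),
                      in_catalogue = logical(), clinvar_id = character(),
                      clonal_class = character(), stringsAsFactors = FALSE))
  hits$consequence_class <- ifelse(
    hits$consequence %in% c("stop_gain", "frameshift"), "TRUNCATING",
    ifelse(hits$consequence == "missense", "MISSENSE", "OTHER"))
  hits$in_catalogue <- toupper(hits$gene) %in% toupper(catalogue)
  hits$clinvar_id <- NA_character_
  if (!is.null(clinvar_lookup) && nrow(clinvar_lookup) > 0) {
    k <- variant_key(hits$chrom, hits$pos, hits$ref, hits$alt)
    lk <- variant_key(clinvar_lookup$chrom, clinvar_lookup$pos,
                      clinvar_lookup$ref, clinvar_lookup$alt)
    m <- match(k, lk)
    hits$clinvar_id <- as.character(clinvar_lookup$clinvar_id[m])
  }
  rownames(hits) <- NULL
  hits[, c("chrom", "pos", "ref", "alt", "gene", "subline", "vaf",
           "consequence_class", "in_catalogue", "clinvar_id",
           "clonal_class")]
}

#' Build the oncoplot matrix from driver hits
#'
#' Gene x subline categorical matrix over catalogue hits. Each cell holds a
#' comma-joined subset of `MISSENSE`, `TRUNCATING`, `CLINVAR`, `MULTIHIT`
#' (empty string = NONE). `MULTIHIT` means at least two distinct variants of
#' the gene in that one subline; `CLINVAR` means at least one variant in the
#' cell has a lookup hit. Rows are ordered by the number of mutated sublines
#' (descending), ties alphabetical.
#'
#' @param hits Data frame from [annotate_drivers()] (or any data frame with
#'   gene, subline, chrom/pos/ref/alt, consequence_class, clinvar_id and
#'   optionally in_catalogue columns).
#' @param sublines Optional character vector fixing the column set/order;
#'   defaults to the sublines present in `hits`.
#' @return Character matrix with attributes `gene_counts` (named vector:
#'   distinct catalogue driver genes per subline), `variant_counts`
#'   (distinct driver variants per subline) and `recurrence` (data frame of
#'   genes hit in more than one replicate).
#' @export
build_oncoplot <- function(hits, sublines = NULL) {
  if ("in_catalogue" %in% names(hits))
    hits <- hits[hits$in_catalogue, , drop = FALSE]
  hits$gene <- toupper(hits$gene)
  if (is.null(sublines)) sublines <- sort(unique(hits$subline))
  genes <- sort(unique(hits$gene))
  m <- matrix("", nrow = length(genes), ncol = length(sublines),
              dimnames = list(genes, sublines))
  if (nrow(hits) > 0) {
    hits$vkey <- variant_key(hits$chrom, hits$pos, hits$ref, hits$alt)
    cells <- split(hits, paste(hits$gene, hits$subline, sep = "\r"))
    for (cell in cells) {
      g <- cell$gene[1]; s <- cell$subline[1]
      if (!s %in% sublines) next
      lab <- character(0)
      if (any(cell$consequence_class == "MISSENSE")) lab <- c(lab, "MISSENSE")
      if (any(cell$consequence_class == "TRUNCATING"))
        lab <- c(lab, "TRUNCATING")
      if (any(!is.na(cell$clinvar_id))) lab <- c(lab, "CLINVAR")
      if (length(unique(cell$vkey)) >= 2L) lab <- c(lab, "MULTIHIT")
      m[g, s] <- paste(lab, collapse = ",")
    }
  }
  n_mut <- rowSums(m != "")
  m <- m[order(-n_mut, rownames(m)), , drop = FALSE]
  gene_counts <- vapply(sublines, function(s)
    length(unique(hits$gene[hits$subline == s])), 0L)
  variant_counts <- vapply(sublines, function(s)
    length(unique(hits$vkey[hits$subline == s])), 0L)
  # recurrence across replicates (distinct from within-subline MULTIHIT)
  rep_of <- sub("^(low|high)", "", hits$subline)
  rec <- table(unique(data.frame(gene = hits$gene, rep = rep_of))$gene)
  recurrence <- data.frame(gene = names(rec), n_replicates = as.integer(rec),
                           stringsAsFactors = FALSE)
  recurrence <- recurrence[recurrence$n_replicates > 1, , drop = FALSE]
  attr(m, "gene_counts") <- gene_counts
  attr(m, "variant_counts") <- variant_counts
  attr(m, "recurrence") <- recurrence
  m
}

#' Convert a Table-1-style driver-hit table to the hits layout
#'
#' Accepts a plain table with one row per variant x subline (columns gene,
#' chrom, pos, ref, alt, consequence, subline, clinvar_id, vaf) — e.g. a
#' published driver-variant table encoded as TSV — and maps it onto the
#' format [build_oncoplot()] expects.
#'
#' @param df Data frame as described.
#' @return Driver-hits data frame.
#' @export
driver_hits_from_table <- function(df) {
  need <- c("gene", "chrom", "pos", "ref", "alt", "consequence", "subline")
  if (!all(need %in% names(df)))
    stop("format error: driver table needs columns ",
         paste(need, collapse = ", "))
  df$consequence_class <- ifelse(
    df$consequence %in% c("stop_gain", "frameshift"), "TRUNCATING",
    ifelse(df$consequence == "missense", "MISSENSE", "OTHER"))
  df$in_catalogue <- TRUE
  if (!"clinvar_id" %in% names(df)) df$clinvar_id <- NA_character_
  df$clinvar_id <- as.character(df$clinvar_id)
  df$clinvar_id[!is.na(df$clinvar_id) & df$clinvar_id == ""] <- NA_character_
  if (!"vaf" %in% names(df)) df$vaf <- NA_real_
  df$gene <- toupper(df$gene)
  df
}
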