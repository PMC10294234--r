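#' Canonical 96-channel single-base-substitution context labels
#'
#' Channel labels follow the standard SBS convention: six pyrimidine-centred
#' substitution types (C>A, C>G, C>T, T>A, T>C, T>G), each flanked by the 16
#' combinations of 5' and 3' bases, formatted `"A[C>A]A"`. The order is fixed:
#' substitution type outermost, then 5' flank (A, C, G, T), then 3' flank.
#'
#' @return Character vector of length 96.
#' @export
sbs96_channels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s) {
    as.vector(t(outer(bases, bases, function(f, t3)
      paste0(f, "[", s, "]", t3))))
  }), use.names = FALSE)
}

#' Reverse complement of a base string
#'
#' @param x Character vector of DNA strings (ACGT alphabet).
#' @return Character vector of reverse complements.
#' @keywords internal
revcomp <- function(x) {
  comp <- chartr("ACGTacgt", "TGCAtgca", x)
  vapply(strsplit(comp, ""), function(b) paste(rev(b), collapse = ""), "")
}

#' Render a VAF as a percentage string
#'
#' Reporting-only helper: multiplies by 100 and rounds half-up to `digits`
#' decimal places (so 0.2917 renders as "29.2%" and 0.6929 as "69%" at
#' integer rendering). The underlying fractions are never rounded in the
#' pipeline itself.
#'
#' @param vaf Numeric vector of allele fractions in \[0, 1\].
#' @param digits Decimal places of the percentage (default 1).
#' @return Character vector like `"33.3%"`.
#' @examples
#' render_vaf_pct(24 / 72)       # "33.3%"
#' render_vaf_pct(88 / 127, 0)   # "69%"
#' @export
render_vaf_pct <- function(vaf, digits = 1) {
  pct <- vaf * 100
  f <- 10^digits
  out <- floor(pct * f + 0.5) / f
  paste0(formatC(out, format = "f", digits = digits), "%")
}

#' Subline label in the low/high + drug + replicate convention
#'
#' Labels follow the `{low|high}{IM|N}-R{n}` convention used for
#' TKI-resistance replicates (e.g. `highIM-R2`, `lowN-R1`).
#'
#' @param drug "imatinib" or "nilotinib".
#' @param level "low" or "high".
#' @param replicate Integer replicate number.
#' @return Character label.
#' @export
subline_label <- function(drug, level, replicate) {
  abbr <- c(imatinib = "IM", nilotinib = "N")[drug]
  if (anyNA(abbr)) stop("unknown drug label: ", paste(drug, collapse = ", "))
  paste0(level, abbr, "-R", replicate)
}

#' @keywords internal
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

#' @keywords internal
is_snv <- function(ref, alt) {
  nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
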