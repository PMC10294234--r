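# 96-channel trinucleotide spectra of acquired SNVs and their decomposition
# against a reference signature matrix by non-negative least squares.

#' Trinucleotide context channel of SNVs
#'
#' Looks up the reference triplet around each variant and normalizes to the
#' pyrimidine strand: if the reference base is a purine, triplet and alleles
#' are reverse-complemented so the central base is C or T. Non-SNVs get `NA`
#' (they are skipped, not an error), as do positions lacking a flanking base
#' (with a warning).
#'
#' @param calls Data frame with chrom, pos, ref, alt.
#' @param reference Named [Biostrings::DNAStringSet] (contig per gene).
#' @return Character vector of channel labels like `"A[C>A]A"` (`NA` where
#'   undefined).
#' @export
contexts_of <- function(calls, reference) {
  n <- nrow(calls)
  out <- rep(NA_character_, n)
  if (n == 0) return(out)
  snv <- is_snv(calls$ref, calls$alt)
  seq_str <- stats::setNames(as.character(reference), names(reference))
  lens <- nchar(seq_str)
  known <- snv & calls$chrom %in% names(seq_str)
  pos <- calls$pos
  inb <- known & pos >= 2L & pos <= lens[calls$chrom] - 1L
  inb[is.na(inb)] <- FALSE
  if (any(known & !inb))
    warning(sum(known & !inb), " variant(s) lack a flanking base; ",
            "excluded from spectrum")
  idx <- which(inb)
  if (length(idx) == 0) return(out)
  trip <- substring(seq_str[calls$chrom[idx]], pos[idx] - 1L, pos[idx] + 1L)
  ref <- calls$ref[idx]; alt <- calls$alt[idx]
  match_ok <- substring(trip, 2, 2) == ref
  if (any(!match_ok))
    warning(sum(!match_ok), " variant(s) mismatch the reference base; ",
            "excluded from spectrum")
  pur <- ref %in% c("A", "G")
  trip[pur] <- revcomp(trip[pur])
  ref[pur] <- chartr("ACGT", "TGCA", ref[pur])
  alt[pur] <- chartr("ACGT", "TGCA", alt[pur])
  lab <- paste0(substring(trip, 1, 1), "[", ref, ">", alt, "]",
                substring(trip, 3, 3))
  lab[!match_ok] <- NA_character_
  out[idx] <- lab
  out
}

#' 96-channel spectrum of a subline's acquired SNVs
#'
#' Counts PASS SNVs only (indels and non-PASS variants are ignored); the
#' result is independent of input order. An empty PASS set yields the
#' all-zero spectrum with `n_snvs = 0`.
#'
#' @param calls Data frame of calls (chrom, pos, ref, alt).
#' @param pass_keys Character vector of passing variant keys
#'   (`chrom:pos:ref:alt`, see [variant_key()]); `NULL` means all calls.
#' @param reference Named DNAStringSet.
#' @return Object of class `spectrum96`: named integer vector of length 96
#'   with attribute `n_snvs`.
#' @export
spectrum96 <- function(calls, pass_keys = NULL, reference) {
  channels <- sbs96_channels()
  if (!is.null(pass_keys)) {
    k <- variant_key(calls$chrom, calls$pos, calls$ref, calls$alt)
    calls <- calls[k %in% pass_keys, , drop = FALSE]
  }
  ctx <- contexts_of(calls, reference)
  ctx <- ctx[!is.na(ctx)]
  counts <- table(factor(ctx, levels = channels))
  out <- stats::setNames(as.integer(counts), channels)
  structure(out, n_snvs = sum(out), class = "spectrum96")
}

#' Fit signature exposures by non-negative least squares
#'
#' Solves `min || S x - p ||_2` subject to `x >= 0`, where `p` is the
#' spectrum normalized to sum 1 and `S` the 96 x k signature matrix
#' (columns sum 1). Exposures are `x / sum(x)`; the residual is the
#' Euclidean norm of `S x - p` on the normalized scale. The dominant
#' signature is the argmax exposure (ties resolve to the lexicographically
#' first id and are flagged).
#'
#' @param spectrum A [spectrum96()] (or any non-negative 96-vector in
#'   canonical channel order).
#' @param sigmat Signature matrix from [read_signature_matrix()] or
#'   [make_signature_matrix()].
#' @return List of class `exposure_fit`: `exposures` (named, sums to 1),
#'   `residual`, `dominant`, `tied` (logical).
#' @export
fit_exposures <- function(spectrum, sigmat) {
  counts <- as.numeric(spectrum)
  if (length(counts) != 96L)
    stop("input error: spectrum must have 96 channels")
  n <- sum(counts)
  if (n <= 0)
    stop("fit error: cannot fit exposures to an empty spectrum (n_snvs = 0)")
  p <- counts / n
  if (qr(sigmat)$rank < ncol(sigmat))
    warning("signature matrix is rank-deficient; exposures are not unique")
  x <- pracma::lsqnonneg(sigmat, p)$x
  resid <- sqrt(sum((as.vector(sigmat %*% x) - p)^2))
  if (sum(x) == 0) {
    exposures <- stats::setNames(rep(1 / ncol(sigmat), ncol(sigmat)),
                                 colnames(sigmat))
  } else {
    exposures <- stats::setNames(x / sum(x), colnames(sigmat))
  }
  ord <- order(names(exposures))
  mx <- max(exposures)
  tied <- sum(exposures == mx) > 1L
  dominant <- names(exposures)[ord][which.max(exposures[ord])]
  structure(list(exposures = exposures, residual = resid,
                 dominant = dominant, tied = tied),
            class = "exposure_fit")
}

#' Per-subline spectra and exposures for a set of trajectories
#'
#' Builds, for each resistant subline, the spectrum of its passing SNVs and
#' fits exposures against the signature matrix.
#'
#' @param trajectories Trajectory data frame(s) from [filter_and_classify()].
#' @param reference Named DNAStringSet.
#' @param sigmat Signature matrix.
#' @return List with `spectra` (96 x sublines matrix), `exposures`
#'   (sublines x signatures matrix), `dominant` (named character vector).
#' @export
subline_signatures <- function(trajectories, reference, sigmat) {
  if (is.data.frame(trajectories)) trajectories <- list(trajectories)
  spectra <- list(); expo <- list(); dominant <- character(0)
  for (tr in trajectories) {
    for (level in c("low", "high")) {
      sub <- tr[tr[[paste0("pass_", level)]], , drop = FALSE]
      lbl <- subline_label(tr$drug[1], level, tr$replicate[1])
      sp <- spectrum96(sub, NULL, reference)
      spectra[[lbl]] <- as.integer(sp)
      if (attr(sp, "n_snvs") > 0) {
        fit <- fit_exposures(sp, sigmat)
        expo[[lbl]] <- fit$exposures
        dominant[lbl] <- fit$dominant
      }
    }
  }
  spec_m <- do.call(cbind, spectra)
  rownames(spec_m) <- sbs96_channels()
  expo_m <- do.call(rbind, expo)
  list(spectra = spec_m, exposures = expo_m, dominant = dominant)
}
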