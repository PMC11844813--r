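#' Build a DNA fingerprint over a core panel
#'
#' Restricts the genotype matrix to the panel loci (in panel order) and
#' attaches the rendering class of every call for fingerprint display:
#' homozygotes are classed by base (the conventional colour scheme being
#' C/C yellow, A/A green, T/T blue, G/G purple), every heterozygote
#' collapses to a single HET class (white) and missing calls to MISSING
#' (gray). The underlying two-allele call is kept: the rendering loses
#' information that the barcode payload must retain.
#'
#' @param g a `geno_matrix`.
#' @param panel locus ids (must all be present in `g`).
#' @return List of class `fingerprint`: `samples`, `panel`, `calls`
#'   (samples x panel character matrix), `classes` (same shape, values in
#'   AA/CC/GG/TT/HET/MISSING), `panel_hash` (version hash of the panel
#'   definition).
#' @export
build_fingerprint <- function(g, panel) {
  idx <- match(panel, g$loci$id)
  if (anyNA(idx)) {
    stop("panel loci absent from matrix: ",
         paste(panel[is.na(idx)], collapse = ", "))
  }
  sub <- g[, idx]
  calls <- sub$calls
  classes <- matrix("MISSING", nrow(calls), ncol(calls),
                    dimnames = dimnames(calls))
  hom <- c("A/A" = "AA", "C/C" = "CC", "G/G" = "GG", "T/T" = "TT")
  is_call <- !is.na(calls)
  classes[is_call] <- ifelse(calls[is_call] %in% names(hom),
                             hom[calls[is_call]], "HET")
  structure(list(samples = sub$samples, panel = sub$loci$id,
                 loci = sub$loci, calls = calls, classes = classes,
                 panel_hash = panel_hash(sub$loci)),
            class = "fingerprint")
}

# short deterministic hash of the panel definition (id:chrom:pos:ref:alt)
panel_hash <- function(loci) {
  key <- paste(loci$id, loci$chrom, loci$pos, loci$ref, loci$alt,
               sep = ":", collapse = ";")
  ints <- utf8ToInt(key)
  h <- 5381
  for (v in ints) h <- (h * 33 + v) %% 2147483647
  sprintf("%08x", h)
}

#' @export
print.fingerprint <- function(x, ...) {
  cat("fingerprint:", length(x$samples), "samples x", length(x$panel),
      "panel loci (panel hash", x$panel_hash, ")\n")
  invisible(x)
}

#' Pairwise distinguishability of fingerprints
#'
#' Counts, for every pair of samples, the panel loci at which their calls
#' differ among loci called in both. Pairs with zero mismatches are
#' indistinguishable; pairs with no shared called locus are flagged
#' uncomparable rather than identical.
#'
#' @param fp a `fingerprint`.
#' @return List: `mismatches` (symmetric count matrix, `NA` where
#'   uncomparable), `shared` (compared-locus counts),
#'   `indistinguishable` (data.frame of sample pairs with 0 mismatches),
#'   `uncomparable` (data.frame of pairs with no shared calls).
#' @export
pairwise_distinguishability <- function(fp) {
  n <- length(fp$samples)
  stopifnot(n >= 2)
  mm <- matrix(0L, n, n, dimnames = list(fp$samples, fp$samples))
  sh <- matrix(0L, n, n, dimnames = list(fp$samples, fp$samples))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      both <- !is.na(fp$calls[i, ]) & !is.na(fp$calls[j, ])
      sh[i, j] <- sh[j, i] <- sum(both)
      mm[i, j] <- mm[j, i] <-
        if (any(both)) sum(fp$calls[i, both] != fp$calls[j, both]) else NA_integer_
    }
  }
  pairs <- which(upper.tri(mm), arr.ind = TRUE)
  zero <- pairs[!is.na(mm[pairs]) & mm[pairs] == 0L, , drop = FALSE]
  unc <- pairs[sh[pairs] == 0L, , drop = FALSE]
  list(
    mismatches = mm, shared = sh,
    indistinguishable = data.frame(sample_a = fp$samples[zero[, 1]],
                                   sample_b = fp$samples[zero[, 2]],
                                   stringsAsFactors = FALSE),
    uncomparable = data.frame(sample_a = fp$samples[unc[, 1]],
                              sample_b = fp$samples[unc[, 2]],
                              stringsAsFactors = FALSE)
  )
}

#' 2D-barcode text payload for one sample
#'
#' Deterministic plain-text payload carrying the full genotype of a sample
#' over the fingerprint panel: a header with the sample label and panel
#' version hash, then one `locus_id=call` pair per panel locus in panel
#' order (missing calls rendered `./.`). Any external QR encoder can consume
#' the text; [parse_barcode_payload()] round-trips it.
#'
#' @param fp a `fingerprint`.
#' @param sample sample label.
#' @return Single character string.
#' @export
barcode_payload <- function(fp, sample) {
  i <- match(sample, fp$samples)
  if (is.na(i)) stop("unknown sample: ", sample)
  calls <- fp$calls[i, ]
  calls[is.na(calls)] <- "./."
  paste(c(paste0("FP;sample=", sample, ";panel=", fp$panel_hash,
                 ";n=", length(fp$panel)),
          paste0(fp$panel, "=", calls)),
        collapse = "\n")
}

#' Parse a barcode payload back into calls
#'
#' @param payload string produced by [barcode_payload()].
#' @return List with `sample`, `panel_hash`, and `calls` (named character
#'   vector, `NA` for missing).
#' @export
parse_barcode_payload <- function(payload) {
  lines <- strsplit(payload, "\n", fixed = TRUE)[[1]]
  hdr <- lines[1]
  if (!startsWith(hdr, "FP;")) stop("not a fingerprint payload")
  fields <- strsplit(sub("^FP;", "", hdr), ";", fixed = TRUE)[[1]]
  kv <- strsplit(fields, "=", fixed = TRUE)
  hdr_map <- stats::setNames(vapply(kv, `[`, character(1), 2),
                             vapply(kv, `[`, character(1), 1))
  body <- strsplit(lines[-1], "=", fixed = TRUE)
  calls <- vapply(body, `[`, character(1), 2)
  names(calls) <- vapply(body, `[`, character(1), 1)
  calls[calls == "./."] <- NA_character_
  if (length(calls) != as.integer(hdr_map[["n"]])) {
    stop("payload truncated: header declares ", hdr_map[["n"]],
         " loci, found ", length(calls))
  }
  list(sample = hdr_map[["sample"]], panel_hash = hdr_map[["panel"]],
       calls = calls)
}

#' Write a fingerprint table
#'
#' Tab-separated fingerprint matrix oriented as in conventional fingerprint
#' figures: rows are panel SNP markers, columns are samples.
#'
#' @param fp a `fingerprint`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fingerprint <- function(fp, path) {
  m <- t(fp$calls)
  m[is.na(m)] <- "./."
  df <- data.frame(locus = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
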