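#' Genotype matrix container
#'
#' The central object of the pipeline: unordered biallelic allele-pair calls
#' for a set of samples at a set of SNP loci. Calls are stored as "X/Y"
#' strings with alleles in alphabetical order ("A/G", never "G/A"), so that
#' unphased "0/1" and "1/0" collapse to the same call; missing calls are
#' `NA`.
#'
#' @param samples character vector of unique sample labels.
#' @param loci data.frame with columns `id`, `chrom`, `pos`, `ref`, `alt`.
#'   `ref` and `alt` must be single distinct bases from A/C/G/T and `pos`
#'   1-based.
#' @param calls character matrix (samples x loci) of sorted "X/Y" calls or
#'   `NA`; alleles at each locus must be drawn from that locus' ref/alt.
#'
#' @return An object of class `geno_matrix`: a list with elements `samples`,
#'   `loci` and `calls`.
#' @export
geno_matrix <- function(samples, loci, calls) {
  samples <- as.character(samples)
  stopifnot(is.data.frame(loci), is.matrix(calls))
  required <- c("id", "chrom", "pos", "ref", "alt")
  if (!all(required %in% names(loci))) {
    stop("loci must have columns: ", paste(required, collapse = ", "))
  }
  if (anyDuplicated(samples)) stop("sample labels must be unique")
  if (anyDuplicated(loci$id)) stop("locus ids must be unique")
  loci$chrom <- as.character(loci$chrom)
  loci$id <- as.character(loci$id)
  loci$ref <- as.character(loci$ref)
  loci$alt <- as.character(loci$alt)
  loci$pos <- as.integer(loci$pos)
  bases <- c("A", "C", "G", "T")
  if (!all(loci$ref %in% bases) || !all(loci$alt %in% bases)) {
    stop("ref and alt alleles must be single bases in {A,C,G,T}")
  }
  if (any(loci$ref == loci$alt)) stop("ref and alt must differ at every locus")
  if (any(loci$pos < 1L)) stop("positions are 1-based and must be >= 1")
  if (nrow(calls) != length(samples) || ncol(calls) != nrow(loci)) {
    stop("calls must be a ", length(samples), " x ", nrow(loci), " matrix")
  }
  dimnames(calls) <- list(samples, loci$id)
  g <- structure(list(samples = samples, loci = loci, calls = calls),
                 class = "geno_matrix")
  validate_calls(g)
  g
}

validate_calls <- function(g) {
  for (j in seq_len(n_loci(g))) {
    ok <- sort_call(g$loci$ref[j], g$loci$alt[j])
    cj <- g$calls[, j]
    bad <- !is.na(cj) & !(cj %in% ok)
    if (any(bad)) {
      stop("invalid call(s) at locus ", g$loci$id[j], ": ",
           paste(unique(cj[bad]), collapse = ", "))
    }
  }
  invisible(g)
}

# the three legal sorted calls at a ref/alt locus: hom-ref, het, hom-alt
sort_call <- function(ref, alt) {
  het <- paste(sort(c(ref, alt)), collapse = "/")
  c(paste(ref, ref, sep = "/"), het, paste(alt, alt, sep = "/"))
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("geno_matrix:", n_samples(x), "samples x", n_loci(x), "loci\n")
  cat("  chromosomes:", length(unique(x$loci$chrom)), "\n")
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @rdname geno_matrix
#' @param g a `geno_matrix`.
#' @export
n_samples <- function(g) length(g$samples)

#' @rdname geno_matrix
#' @export
n_loci <- function(g) nrow(g$loci)

#' Subset a genotype matrix
#'
#' @param x a `geno_matrix`.
#' @param i sample index (integer, logical or character).
#' @param j locus index (integer, logical or locus id).
#' @param ... unused.
#' @return A `geno_matrix` restricted to the requested samples/loci.
#' @export
`[.geno_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(n_samples(x))
  if (missing(j)) j <- seq_len(n_loci(x))
  if (is.character(i)) i <- match(i, x$samples)
  if (is.character(j)) j <- match(j, x$loci$id)
  if (anyNA(i)) stop("unknown sample label(s)")
  if (anyNA(j)) stop("unknown locus id(s)")
  geno_matrix(x$samples[i], x$loci[j, , drop = FALSE],
              x$calls[i, j, drop = FALSE])
}

#' Alt-allele dosage matrix
#'
#' Codes every call as the number of alternate alleles it carries:
#' hom-ref = 0, het = 1, hom-alt = 2. Missing calls stay `NA` (the missing
#' mask). This is the numeric representation consumed by PCA and by the
#' core-collection optimizer.
#'
#' @param g a `geno_matrix`.
#' @return Integer matrix (samples x loci) in \{0, 1, 2, NA\}.
#' @export
dosage_matrix <- function(g) {
  d <- matrix(NA_integer_, n_samples(g), n_loci(g),
              dimnames = dimnames(g$calls))
  for (j in seq_len(n_loci(g))) {
    lv <- sort_call(g$loci$ref[j], g$loci$alt[j])
    d[, j] <- match(g$calls[, j], lv) - 1L
  }
  d
}
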