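#' Exact Hardy-Weinberg equilibrium test
#'
#' Levene-Haldane exact conditional test for a biallelic locus. Conditional
#' on the observed allele counts, the probability of seeing `h` heterozygotes
#' among `n` individuals is
#' \deqn{P(h) = \frac{n!}{n_{AA}! \, h! \, n_{aa}!} 2^h
#'       \frac{n_A! \, n_a!}{(2n)!}}
#' and the p-value is the total probability of all heterozygote counts whose
#' probability does not exceed that of the observed count (same allele
#' counts force the same parity of `h`).
#'
#' @param n_homref,n_het,n_homalt genotype counts (non-negative integers,
#'   total >= 1).
#' @return p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_homref, n_het, n_homalt) {
  counts <- c(n_homref, n_het, n_homalt)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("genotype counts must be non-negative integers")
  }
  n <- sum(counts)
  if (n < 1) stop("at least one genotyped individual required")
  n_a1 <- 2 * n_homref + n_het
  n_a2 <- 2 * n_homalt + n_het
  n_minor <- min(n_a1, n_a2)
  if (n_minor == 0) return(1)           # monomorphic: single outcome
  # heterozygote counts compatible with the fixed allele counts
  hs <- seq(n_minor %% 2, n_minor, by = 2)
  log_p <- vapply(hs, function(h) {
    hom1 <- (n_a1 - h) / 2
    hom2 <- (n_a2 - h) / 2
    lgamma(n + 1) - lgamma(hom1 + 1) - lgamma(h + 1) - lgamma(hom2 + 1) +
      h * log(2) + lgamma(n_a1 + 1) + lgamma(n_a2 + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  p <- exp(log_p - max(log_p))
  p <- p / sum(p)
  p_obs <- p[match(n_het, hs)]
  sum(p[p <= p_obs * (1 + 1e-9)])
}

#' Per-locus diversity statistics
#'
#' Computes, for each locus, allele frequencies over called samples, minor
#' allele frequency, observed heterozygosity (fraction of het calls),
#' expected heterozygosity / Nei's gene diversity `1 - sum(p^2)` (plain,
#' uncorrected form, ceiling 0.5 for biallelic loci), the Shannon-Wiener
#' index `-sum(p * log(p))` over allele frequencies (natural log, ceiling
#' log 2), the Botstein polymorphism information content restricted to two
#' alleles `1 - sum(p^2) - 2 p^2 q^2` (ceiling 0.375), the exact
#' Hardy-Weinberg p-value, and the missing-call rate. Missing calls are
#' dropped locus-wise (complete cases per locus).
#'
#' @param g a `geno_matrix`.
#' @param loci optional locus indices or ids; default all.
#' @return data.frame with one row per locus: `id`, `chrom`, `pos`,
#'   `n_called`, `p_ref`, `p_alt`, `maf`, `ho`, `he`, `nei`, `shannon`,
#'   `pic`, `hwe_p`, `missing_rate`. (`nei` duplicates `he`: for biallelic
#'   loci Nei's gene diversity is the same `1 - sum(p^2)`; the column is kept
#'   for report parity with standard diversity tables.)
#' @export
locus_stats <- function(g, loci = NULL) {
  if (is.null(loci)) loci <- seq_len(n_loci(g))
  if (is.character(loci)) loci <- match(loci, g$loci$id)
  out <- lapply(loci, function(j) {
    lv <- sort_call(g$loci$ref[j], g$loci$alt[j])
    cj <- g$calls[, j]
    called <- !is.na(cj)
    n <- sum(called)
    if (n == 0) stop("locus ", g$loci$id[j], " has no called samples")
    counts <- c(sum(cj == lv[1], na.rm = TRUE),
                sum(cj == lv[2], na.rm = TRUE),
                sum(cj == lv[3], na.rm = TRUE))
    p_ref <- (2 * counts[1] + counts[2]) / (2 * n)
    p_alt <- 1 - p_ref
    p <- c(p_ref, p_alt)
    he <- 1 - sum(p^2)
    pz <- p[p > 0]
    data.frame(
      id = g$loci$id[j], chrom = g$loci$chrom[j], pos = g$loci$pos[j],
      n_called = n, p_ref = p_ref, p_alt = p_alt,
      maf = min(p), ho = counts[2] / n, he = he, nei = he,
      shannon = -sum(pz * log(pz)),
      pic = he - 2 * p_ref^2 * p_alt^2,
      hwe_p = hwe_exact_test(counts[1], counts[2], counts[3]),
      missing_rate = 1 - n / n_samples(g),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Minor-allele-frequency spectrum
#'
#' Histogram of per-locus MAF values as relative frequencies.
#'
#' @param maf numeric vector of MAF values (e.g. `locus_stats(g)$maf`).
#' @param breaks bin edges covering `[0, 0.5]`; default width-0.05 bins.
#' @return data.frame with `bin` labels and `freq` summing to 1.
#' @export
maf_spectrum <- function(maf, breaks = seq(0, 0.5, by = 0.05)) {
  if (length(maf) == 0) stop("no MAF values supplied")
  stopifnot(min(breaks) <= 0, max(breaks) >= 0.5)
  h <- hist(maf, breaks = breaks, plot = FALSE, right = FALSE,
            include.lowest = TRUE)
  data.frame(
    bin = sprintf("[%.2f,%.2f)", h$breaks[-length(h$breaks)], h$breaks[-1]),
    freq = h$counts / sum(h$counts), stringsAsFactors = FALSE
  )
}

#' Ten-class genotype spectrum
#'
#' Relative frequency of calls in each of the ten unordered genotype classes
#' that four nucleotides admit: 4 homozygous (AA, CC, GG, TT) plus
#' choose(4,2) = 6 heterozygous (AC, AG, AT, CG, CT, GT). Missing calls are
#' excluded from the normalization.
#'
#' @param g a `geno_matrix`.
#' @return Named numeric vector of length 10 summing to 1 (all zero if every
#'   call is missing).
#' @export
genotype_spectrum <- function(g) {
  classes <- c("A/A", "C/C", "G/G", "T/T",
               "A/C", "A/G", "A/T", "C/G", "C/T", "G/T")
  tab <- table(factor(g$calls[!is.na(g$calls)], levels = classes))
  n <- sum(tab)
  freq <- if (n > 0) as.numeric(tab) / n else as.numeric(tab)
  names(freq) <- classes
  freq
}

#' Concordance between two genotype spectra
#'
#' Coefficient of determination (R squared) of the least-squares line fitted
#' between two spectra over the same genotype classes, used to compare a
#' core collection's genotype distribution against the full collection's.
#'
#' @param spec_a,spec_b numeric vectors of equal length (class frequencies).
#' @return R squared in `[0, 1]`.
#' @export
spectrum_concordance <- function(spec_a, spec_b) {
  stopifnot(length(spec_a) == length(spec_b), length(spec_a) >= 2)
  # identical spectra fit perfectly; lm's "perfect fit" warning is expected
  suppressWarnings(summary(stats::lm(spec_b ~ spec_a))$r.squared)
}
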