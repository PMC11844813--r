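#' Screening configuration for the marker cascade
#'
#' Thresholds for the five-criterion candidate-marker cascade: flank
#' specificity, completeness (missing rate), minor allele frequency,
#' polymorphism information content, exact Hardy-Weinberg test, and
#' physical isolation from neighbouring variants.
#'
#' @param flank specificity window half-width in bp (window = 2*flank+1;
#'   default 200, i.e. a 401 bp window).
#' @param max_missing maximum per-locus missing-call rate (default 0: no
#'   missing data tolerated).
#' @param min_maf minimum minor allele frequency (default 0.2).
#' @param min_pic minimum polymorphism information content (default 0.35).
#' @param hwe_alpha loci are retained when the exact HWE p-value is
#'   strictly greater than this (default 0.01).
#' @param isolation no other variant within this many bp, closed interval
#'   (default 100: a neighbour exactly 100 bp away fails the criterion).
#' @param require_specificity run the flank-uniqueness criterion (default
#'   `TRUE`); turning it off yields the larger specificity-free panel
#'   variant.
#' @return List of class `screen_config`.
#' @export
screen_config <- function(flank = 200L, max_missing = 0, min_maf = 0.2,
                          min_pic = 0.35, hwe_alpha = 0.01,
                          isolation = 100L, require_specificity = TRUE) {
  stopifnot(flank >= 1L, max_missing >= 0, max_missing <= 1,
            min_maf >= 0, min_maf <= 0.5, min_pic >= 0, min_pic <= 0.375,
            hwe_alpha >= 0, hwe_alpha <= 1, isolation >= 0,
            flank >= isolation)
  structure(list(flank = as.integer(flank), max_missing = max_missing,
                 min_maf = min_maf, min_pic = min_pic,
                 hwe_alpha = hwe_alpha, isolation = as.integer(isolation),
                 require_specificity = isTRUE(require_specificity)),
            class = "screen_config")
}

#' Flank-window uniqueness (specificity criterion)
#'
#' A locus is specific when its `2*flank+1` bp window occurs exactly once in
#' the whole genome, counting both strands. A window that cannot be fully
#' extracted (locus too close to a contig end) fails with reason "edge".
#'
#' @param genome a `DNAStringSet`.
#' @param chrom,pos locus coordinates (1-based).
#' @param flank half-window in bp.
#' @return `TRUE`/`FALSE`; attribute `reason` set to `"edge"` or
#'   `"multi_hit"` on failure.
#' @export
flank_uniqueness <- function(genome, chrom, pos, flank = 200L) {
  w <- extract_flanks(genome, chrom, pos, flank)
  if (w$truncated) return(structure(FALSE, reason = "edge"))
  n <- count_genome_hits(genome, w$seq)
  if (n == 1L) TRUE else structure(FALSE, reason = "multi_hit")
}

# occurrences of `pattern` in the genome, forward + reverse-complement.
# A palindromic window would double-count; irrelevant for odd-length windows
# with a unique center base, but guarded anyway.
count_genome_hits <- function(genome, pattern) {
  pat <- Biostrings::DNAString(pattern)
  rc <- Biostrings::reverseComplement(pat)
  fwd <- sum(Biostrings::vcountPattern(pat, genome))
  if (as.character(rc) == as.character(pat)) return(fwd)
  fwd + sum(Biostrings::vcountPattern(rc, genome))
}

# batch specificity over many loci using a PDict for speed
flank_uniqueness_batch <- function(genome, loci, flank = 200L) {
  n <- nrow(loci)
  verdict <- logical(n)
  reason <- rep(NA_character_, n)
  wins <- character(n)
  full <- logical(n)
  for (k in seq_len(n)) {
    w <- extract_flanks(genome, loci$chrom[k], loci$pos[k], flank)
    full[k] <- !w$truncated
    wins[k] <- w$seq
    if (w$truncated) reason[k] <- "edge"
  }
  idx <- which(full)
  if (length(idx)) {
    pats <- Biostrings::DNAStringSet(wins[idx])
    pd <- Biostrings::PDict(pats)
    rc <- Biostrings::reverseComplement(pats)
    pdr <- Biostrings::PDict(rc)
    hits <- rep(0L, length(idx))
    for (chr in seq_along(genome)) {
      hits <- hits + Biostrings::countPDict(pd, genome[[chr]]) +
        Biostrings::countPDict(pdr, genome[[chr]])
    }
    palin <- as.character(rc) == as.character(pats)
    hits[palin] <- hits[palin] %/% 2L
    verdict[idx] <- hits == 1L
    reason[idx][hits != 1L] <- "multi_hit"
  }
  list(verdict = verdict, reason = reason)
}

#' Physical isolation of loci
#'
#' For each locus, `TRUE` iff no other variant lies within `isolation` bp on
#' the same chromosome (closed interval: a neighbour at exactly `isolation`
#' bp fails).
#'
#' @param loci data.frame with `chrom` and `pos`, sorted by (chrom, pos).
#' @param isolation distance in bp.
#' @return Logical vector, one per locus.
#' @export
isolation_filter <- function(loci, isolation = 100L) {
  ord <- order(loci$chrom, loci$pos)
  if (!identical(ord, seq_len(nrow(loci)))) {
    stop("loci must be sorted by (chrom, pos)")
  }
  n <- nrow(loci)
  ok <- rep(TRUE, n)
  if (n < 2) return(ok)
  same_prev <- c(FALSE, loci$chrom[-1] == loci$chrom[-n])
  gap_prev <- c(NA, diff(loci$pos))
  near_prev <- same_prev & gap_prev <= isolation
  ok[near_prev] <- FALSE
  ok[which(near_prev) - 1L] <- FALSE
  ok
}

#' Run the five-criterion screening cascade
#'
#' Evaluates every locus against each criterion independently (specificity,
#' completeness, MAF, PIC, HWE, isolation) and reports per-criterion
#' verdicts plus the surviving candidate panel (loci passing all applied
#' criteria), in genome order.
#'
#' @param g a `geno_matrix` with loci sorted by (chrom, pos).
#' @param genome a `DNAStringSet`; may be `NULL` when
#'   `cfg$require_specificity` is `FALSE`.
#' @param cfg a [screen_config()].
#' @return List of class `screen_report`: `verdicts` (data.frame of logical
#'   columns `specificity`, `missing`, `maf`, `pic`, `hwe`, `isolation`,
#'   `overall`), `stats` (the [locus_stats()] table), `survivors` (locus
#'   ids), `config`.
#' @export
screen_cascade <- function(g, genome = NULL, cfg = screen_config()) {
  stats <- locus_stats(g)
  if (cfg$require_specificity) {
    if (is.null(genome)) stop("specificity criterion needs a reference genome")
    spec <- flank_uniqueness_batch(genome, g$loci, cfg$flank)$verdict
  } else {
    spec <- rep(TRUE, n_loci(g))
  }
  verdicts <- data.frame(
    id = g$loci$id,
    specificity = spec,
    missing = stats$missing_rate <= cfg$max_missing,
    maf = stats$maf >= cfg$min_maf,
    pic = stats$pic >= cfg$min_pic,
    hwe = stats$hwe_p > cfg$hwe_alpha,
    isolation = isolation_filter(g$loci, cfg$isolation),
    stringsAsFactors = FALSE
  )
  verdicts$overall <- verdicts$specificity & verdicts$missing &
    verdicts$maf & verdicts$pic & verdicts$hwe & verdicts$isolation
  structure(list(verdicts = verdicts, stats = stats,
                 survivors = g$loci$id[verdicts$overall], config = cfg),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat("screen_report:", nrow(x$verdicts), "loci screened,",
      length(x$survivors), "survivors\n")
  fails <- vapply(c("specificity", "missing", "maf", "pic", "hwe",
                    "isolation"),
                  function(cr) sum(!x$verdicts[[cr]]), integer(1))
  for (cr in names(fails)) cat(sprintf("  %-12s failed: %d\n", cr, fails[cr]))
  invisible(x)
}

#' Chromosome-balanced core-panel selection
#'
#' Reduces a candidate panel to a core panel of `target` loci spread evenly
#' across chromosomes: each chromosome gets a quota of
#' `floor(target / n_chrom)`, the remainder going to the chromosomes with
#' the most surviving candidates; within a chromosome loci are ranked by
#' (PIC, MAF, id) descending and the quota taken from the top. When a
#' chromosome has fewer survivors than its quota the shortfall is
#' redistributed to the remaining chromosomes (with a warning). Fully
#' deterministic.
#'
#' @param report a `screen_report`.
#' @param target core panel size (<= number of survivors).
#' @param chromosomes chromosome set over which to balance; defaults to the
#'   chromosomes present in the screened loci.
#' @return Character vector of core-panel locus ids in genome order.
#' @export
chromosome_balanced_select <- function(report, target,
                                       chromosomes = NULL) {
  surv <- report$stats[report$stats$id %in% report$survivors, , drop = FALSE]
  if (target > nrow(surv)) {
    stop("target (", target, ") exceeds survivor count (", nrow(surv), ")")
  }
  if (is.null(chromosomes)) chromosomes <- unique(report$stats$chrom)
  n_chrom <- length(chromosomes)
  avail <- vapply(chromosomes, function(ch) sum(surv$chrom == ch), integer(1))
  quota <- rep(target %/% n_chrom, n_chrom)
  rem <- target %% n_chrom
  if (rem > 0) {
    extra <- order(-avail, chromosomes)[seq_len(rem)]
    quota[extra] <- quota[extra] + 1L
  }
  short <- pmax(quota - avail, 0L)
  if (any(short > 0)) {
    warning(sum(short), " quota slot(s) redistributed from chromosome(s) ",
            paste(chromosomes[short > 0], collapse = ", "),
            " with too few survivors")
    quota <- pmin(quota, avail)
    deficit <- target - sum(quota)
    while (deficit > 0) {
      room <- avail - quota
      k <- order(-room, chromosomes)[1]
      if (room[k] <= 0) stop("cannot fill target from available survivors")
      quota[k] <- quota[k] + 1L
      deficit <- deficit - 1L
    }
  }
  chosen <- character(0)
  for (i in seq_len(n_chrom)) {
    ci <- surv[surv$chrom == chromosomes[i], , drop = FALSE]
    ci <- ci[order(-ci$pic, -ci$maf, ci$id), , drop = FALSE]
    chosen <- c(chosen, ci$id[seq_len(quota[i])])
  }
  # return in genome order
  report$stats$id[report$stats$id %in% chosen]
}
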