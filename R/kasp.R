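#' KASP design configuration
#'
#' Constraint set for kompetitive allele-specific PCR assay design: two
#' tailed allele-specific forward primers (FAM/VIC) whose 3' base is the
#' targeted SNP allele, plus one common reverse primer on the opposite
#' strand, with the amplicon kept short.
#'
#' @param flank flanking sequence available on each side of the SNP
#'   (default 200 bp).
#' @param primer_len_range candidate genomic-segment lengths for both the
#'   allele-specific and common primers (default 18:25).
#' @param gc_range allowed GC percentage (default c(30, 60); the
#'   conventional optimum is 45).
#' @param tm_range allowed melting temperature in Celsius (default
#'   c(55, 61)).
#' @param max_product maximum PCR product size in bp (default 120).
#' @return List of class `kasp_config`.
#' @export
kasp_config <- function(flank = 200L, primer_len_range = 18:25,
                        gc_range = c(30, 60), tm_range = c(55, 61),
                        max_product = 120L) {
  structure(list(flank = as.integer(flank),
                 primer_len_range = as.integer(primer_len_range),
                 gc_range = gc_range, tm_range = tm_range,
                 max_product = as.integer(max_product)),
            class = "kasp_config")
}

#' Standard KASP fluorophore tails
#'
#' The universal FAM and VIC tail sequences prepended to the two
#' allele-specific forward primers.
#' @format Named character vector with elements `FAM` and `VIC`.
#' @export
kasp_tails <- c(FAM = "GAAGGTGACCAAGTTCATGCT",
                VIC = "GAAGGTCGGAGTCAACGGATT")

gc_percent <- function(seq) {
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  100 * sum(b %in% c("G", "C")) / length(b)
}

# basic GC-count melting temperature (Wallace/Marmur-Doty style long form)
tm_basic <- function(seq) {
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  64.9 + 41 * (sum(b %in% c("G", "C")) - 16.4) / length(b)
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# pick the primer length whose segment best satisfies GC/Tm; prefers a fully
# passing length, falls back to the one closest to the Tm window
pick_primer <- function(candidates, cfg) {
  gc <- vapply(candidates, gc_percent, numeric(1))
  tm <- vapply(candidates, tm_basic, numeric(1))
  ok <- gc >= cfg$gc_range[1] & gc <= cfg$gc_range[2] &
    tm >= cfg$tm_range[1] & tm <= cfg$tm_range[2]
  mid <- mean(cfg$tm_range)
  pick <- if (any(ok)) which(ok)[which.min(abs(tm[ok] - mid))]
          else which.min(abs(tm - mid))
  list(seq = candidates[pick], gc = gc[pick], tm = tm[pick], pass = ok[pick])
}

#' Assemble a KASP assay for one SNP
#'
#' The two allele-specific forward primers are genomic segments upstream of
#' (and including) the SNP, ending exactly on the SNP position carrying the
#' ref and the alt allele respectively, with the FAM tail prepended to the
#' ref primer and the VIC tail to the alt primer; the two genomic segments
#' are identical except for their 3' base. The common reverse primer is the
#' reverse complement of a downstream window, placed greedily at the
#' nearest downstream position (then shortest length) satisfying the GC/Tm
#' constraints with product length at most `cfg$max_product`. If no
#' placement satisfies the constraints a design-failure report is returned,
#' not an error.
#'
#' @param genome a `DNAStringSet`.
#' @param locus one-row data.frame (or list) with `id`, `chrom`, `pos`,
#'   `ref`, `alt`.
#' @param cfg a [kasp_config()].
#' @return List of class `kasp_assay`: `locus`, `designed` (logical),
#'   `forward_ref`, `forward_alt`, `reverse` (each a list with `seq`,
#'   `genomic`, `gc`, `tm`), `product_len`, `mix_ratio` (the conventional
#'   1:1:3 forward:forward:reverse annotation), `failure_reason`.
#' @export
assemble_kasp_assay <- function(genome, locus, cfg = kasp_config()) {
  w <- extract_flanks(genome, locus$chrom, locus$pos, cfg$flank)
  fail <- function(reason) {
    structure(list(locus = locus$id, designed = FALSE,
                   failure_reason = reason, mix_ratio = "1:1:3"),
              class = "kasp_assay")
  }
  if (w$truncated) return(fail("flanks truncated at contig end"))
  up <- substr(w$seq, 1, cfg$flank)          # 200 bp upstream of SNP
  down <- substr(w$seq, cfg$flank + 2, nchar(w$seq))
  # forward allele-specific segments end on the SNP base; the length is
  # chosen once (on the ref-allele candidate) so the two segments are
  # identical except for their 3' base
  cands <- vapply(cfg$primer_len_range, function(len) {
    paste0(substr(up, cfg$flank - len + 2, cfg$flank), locus$ref)
  }, character(1))
  f_ref <- pick_primer(cands, cfg)
  fwd_len <- nchar(f_ref$seq)
  alt_seg <- paste0(substr(f_ref$seq, 1, fwd_len - 1), locus$alt)
  f_alt <- list(seq = alt_seg, gc = gc_percent(alt_seg),
                tm = tm_basic(alt_seg))
  # greedy downstream search for the common reverse primer: nearest
  # placement first, shortest length first
  best <- NULL
  for (gap in seq_len(cfg$max_product)) {
    for (rlen in cfg$primer_len_range) {
      rev_end <- gap + rlen - 1L             # offset into `down`
      product <- fwd_len + rev_end
      if (product > cfg$max_product) next
      if (rev_end > nchar(down)) next
      genomic <- substr(down, gap, rev_end)
      gc <- gc_percent(genomic)
      tm <- tm_basic(genomic)
      if (gc < cfg$gc_range[1] || gc > cfg$gc_range[2]) next
      if (tm < cfg$tm_range[1] || tm > cfg$tm_range[2]) next
      best <- list(seq = revcomp(genomic), genomic = genomic,
                   gc = gc, tm = tm, pass = TRUE, product_len = product)
      break
    }
    if (!is.null(best)) break
  }
  if (is.null(best)) return(fail("no reverse-primer placement satisfies constraints"))
  structure(list(
    locus = locus$id, designed = TRUE,
    forward_ref = list(seq = paste0(kasp_tails[["FAM"]], f_ref$seq),
                       genomic = f_ref$seq, gc = f_ref$gc, tm = f_ref$tm),
    forward_alt = list(seq = paste0(kasp_tails[["VIC"]], f_alt$seq),
                       genomic = f_alt$seq, gc = f_alt$gc, tm = f_alt$tm),
    reverse = best[c("seq", "genomic", "gc", "tm")],
    product_len = best$product_len,
    mix_ratio = "1:1:3", failure_reason = NA_character_),
    class = "kasp_assay")
}

#' Validate a KASP assay against the design constraints
#'
#' Checks every primer's GC content and melting temperature (computed on
#' the genomic segment, excluding the fluorophore tail) against the
#' configured ranges, and the product length against the maximum.
#'
#' @param assay a `kasp_assay`.
#' @param cfg a [kasp_config()].
#' @return data.frame with one row per check: `check`, `value`, `pass`.
#' @export
validate_kasp_assay <- function(assay, cfg = kasp_config()) {
  if (!isTRUE(assay$designed)) {
    return(data.frame(check = "designed", value = NA_real_, pass = FALSE,
                      stringsAsFactors = FALSE))
  }
  rows <- list()
  for (p in c("forward_ref", "forward_alt", "reverse")) {
    seg <- assay[[p]]$genomic
    gc <- gc_percent(seg)
    tm <- tm_basic(seg)
    rows[[paste0(p, "_gc")]] <-
      c(gc, gc >= cfg$gc_range[1] && gc <= cfg$gc_range[2])
    rows[[paste0(p, "_tm")]] <-
      c(tm, tm >= cfg$tm_range[1] && tm <= cfg$tm_range[2])
  }
  rows[["product_len"]] <- c(assay$product_len,
                             assay$product_len <= cfg$max_product)
  data.frame(check = names(rows),
             value = vapply(rows, `[`, numeric(1), 1),
             pass = as.logical(vapply(rows, `[`, numeric(1), 2)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Design KASP assays for a whole panel
#'
#' @param genome a `DNAStringSet`.
#' @param loci data.frame of panel loci (`id`, `chrom`, `pos`, `ref`,
#'   `alt`).
#' @param cfg a [kasp_config()].
#' @return List with `assays` (list of `kasp_assay`) and `sheet`
#'   (tab-ready data.frame: locus, primer sequences, GC, Tm, product
#'   length, designed flag).
#' @export
design_kasp_panel <- function(genome, loci, cfg = kasp_config()) {
  assays <- lapply(seq_len(nrow(loci)), function(k) {
    assemble_kasp_assay(genome, loci[k, ], cfg)
  })
  sheet <- do.call(rbind, lapply(assays, function(a) {
    if (!a$designed) {
      return(data.frame(locus = a$locus, designed = FALSE,
                        forward_ref = NA, forward_alt = NA, reverse = NA,
                        gc_fwd = NA, tm_fwd = NA, gc_rev = NA, tm_rev = NA,
                        product_len = NA, stringsAsFactors = FALSE))
    }
    data.frame(locus = a$locus, designed = TRUE,
               forward_ref = a$forward_ref$seq,
               forward_alt = a$forward_alt$seq,
               reverse = a$reverse$seq,
               gc_fwd = a$forward_ref$gc, tm_fwd = a$forward_ref$tm,
               gc_rev = a$reverse$gc, tm_rev = a$reverse$tm,
               product_len = a$product_len, stringsAsFactors = FALSE)
  }))
  list(assays = assays, sheet = sheet)
}
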