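#' Read a multi-sample VCF into a genotype matrix
#'
#' Parses a VCF 4.x file (via \pkg{vcfR}) and returns the biallelic SNP
#' calls as a [geno_matrix()]. Only the GT field is used; phase separators
#' ("|") are treated like "/" so "0/1" and "1/0" become the same unordered
#' call.
#'
#' @param path path to an uncompressed or gzipped VCF file.
#' @param biallelic_only drop records that are not biallelic SNPs (default
#'   `TRUE`). The number of dropped records is attached as attribute
#'   `"dropped"` and reported with a message.
#' @return A `geno_matrix` with attribute `dropped` (count of excluded
#'   records).
#' @export
read_vcf <- function(path, biallelic_only = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("malformed VCF '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (ncol(vcf@gt) < 2L) stop("VCF has no sample columns: ", path)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  snp <- nchar(ref) == 1L & !is.na(alt) & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  keep <- if (biallelic_only) snp else rep(TRUE, length(ref))
  dropped <- sum(!keep)
  if (dropped > 0) message(dropped, " non-biallelic/non-SNP record(s) dropped")
  if (!any(keep)) stop("no biallelic SNP records in ", path)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <-
    paste0(fix[is.na(ids) | ids == ".", "CHROM"], "_",
           fix[is.na(ids) | ids == ".", "POS"])
  loci <- data.frame(id = ids, chrom = fix[, "CHROM"],
                     pos = as.integer(fix[, "POS"]),
                     ref = fix[, "REF"], alt = fix[, "ALT"],
                     stringsAsFactors = FALSE)
  samples <- colnames(gt)
  calls <- matrix(NA_character_, length(samples), nrow(loci))
  for (j in seq_len(nrow(loci))) {
    calls[, j] <- gt_to_call(gt[j, ], loci$ref[j], loci$alt[j])
  }
  g <- geno_matrix(samples, loci, calls)
  attr(g, "dropped") <- dropped
  g
}

# map VCF GT codes to sorted unordered calls; anything with "." is missing
gt_to_call <- function(codes, ref, alt) {
  codes <- gsub("|", "/", codes, fixed = TRUE)
  lv <- sort_call(ref, alt)
  out <- rep(NA_character_, length(codes))
  out[codes %in% "0/0"] <- lv[1]
  out[codes %in% c("0/1", "1/0")] <- lv[2]
  out[codes %in% "1/1"] <- lv[3]
  out
}

#' Write a genotype matrix as VCF
#'
#' Emits a minimal plain-text VCF 4.2 with GT-only FORMAT, preserving sample
#' and locus order, so that `read_vcf(write_vcf(g))` round-trips every call.
#'
#' @param g a `geno_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path) {
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##contig=<ID=", unique(g$loci$chrom), ">"),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", g$samples), collapse = "\t"))
  rows <- vapply(seq_len(n_loci(g)), function(j) {
    lv <- sort_call(g$loci$ref[j], g$loci$alt[j])
    code <- c("0/0", "0/1", "1/1")[match(g$calls[, j], lv)]
    code[is.na(code)] <- "./."
    paste(c(g$loci$chrom[j], g$loci$pos[j], g$loci$id[j], g$loci$ref[j],
            g$loci$alt[j], ".", "PASS", ".", "GT", code), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a reference genome from FASTA
#'
#' @param path FASTA file.
#' @return A [Biostrings::DNAStringSet] keyed by chromosome name (first
#'   whitespace-delimited token of each header).
#' @export
read_reference <- function(path) {
  genome <- Biostrings::readDNAStringSet(path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (anyDuplicated(names(genome))) {
    stop("duplicate chromosome names in ", path)
  }
  genome
}

#' Check genotype loci against the reference
#'
#' Verifies that the reference base at every locus position equals the
#' locus' declared ref allele.
#'
#' @param g a `geno_matrix`.
#' @param genome a `DNAStringSet` as from [read_reference()].
#' @return `TRUE` invisibly; errors on the first mismatch.
#' @export
validate_reference <- function(g, genome) {
  missing_chr <- setdiff(unique(g$loci$chrom), names(genome))
  if (length(missing_chr)) {
    stop("chromosome(s) absent from reference: ",
         paste(missing_chr, collapse = ", "))
  }
  for (j in seq_len(n_loci(g))) {
    base <- as.character(Biostrings::subseq(genome[[g$loci$chrom[j]]],
                                            g$loci$pos[j], g$loci$pos[j]))
    if (base != g$loci$ref[j]) {
      stop("reference mismatch at ", g$loci$id[j], ": genome has ", base,
           ", locus declares ref ", g$loci$ref[j])
    }
  }
  invisible(TRUE)
}

#' Extract the flanking window around a SNP
#'
#' Returns the `2 * flank + 1` bp sequence centered on the SNP (the SNP base
#' sits at the center). Windows that would run past a chromosome end are
#' truncated and flagged rather than silently shortened.
#'
#' @param genome a `DNAStringSet`.
#' @param chrom chromosome name.
#' @param pos 1-based SNP position.
#' @param flank flank length in bp on each side (>= 1); the default 200
#'   yields the 401 bp specificity window used for marker screening.
#' @return List with `seq` (character), `truncated` (logical), and the
#'   1-based closed interval `start`/`end` actually extracted.
#' @export
extract_flanks <- function(genome, chrom, pos, flank = 200L) {
  stopifnot(flank >= 1L)
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  len <- Biostrings::width(genome[names(genome) == chrom])
  if (pos < 1L || pos > len) stop("position ", pos, " outside ", chrom)
  start <- pos - flank
  end <- pos + flank
  truncated <- start < 1L || end > len
  start <- max(1L, start)
  end <- min(len, end)
  list(seq = as.character(Biostrings::subseq(genome[[chrom]], start, end)),
       truncated = truncated, start = start, end = end)
}

#' Read a sample-to-population metadata table
#'
#' @param path tab-separated file with columns `sample` and `population`
#'   (levels QTP, NW, NC, NE or UNKNOWN).
#' @return data.frame with columns `sample`, `population`.
#' @export
read_sample_meta <- function(path) {
  meta <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  if (!all(c("sample", "population") %in% names(meta))) {
    stop("metadata needs columns 'sample' and 'population'")
  }
  meta$sample <- as.character(meta$sample)
  meta$population <- as.character(meta$population)
  meta
}
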