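#' Simulation configuration for a structured germplasm collection
#'
#' Defaults emulate a wild collection of 90 accessions from four
#' geographic populations on 14 chromosomes: one strongly diverged
#' population (QTP, Balding-Nichols F = 0.3) and three weakly diverged,
#' mutually confusable northern populations (NW, NC, NE; F = 0.02 each)
#' that share a common intermediate ancestor (branch F = 0.05), so that
#' QTP separates cleanly while NW/NC/NE overlap.
#'
#' @param n_chrom number of chromosomes (default 14).
#' @param chrom_len chromosome length in bp (default 60000; recycled).
#' @param n_loci number of biallelic SNP loci (default 1000).
#' @param pop_sizes named sample counts per population (default
#'   `c(NW = 26, NC = 26, NE = 26, QTP = 12)`, 90 samples).
#' @param pop_f named Balding-Nichols divergence per population (default
#'   0.02 for NW/NC/NE, 0.3 for QTP).
#' @param shared_f divergence of the shared NW/NC/NE ancestral branch
#'   (default 0.05).
#' @param maf_range ancestral minor-allele-frequency range, sampled
#'   uniformly (default c(0.05, 0.5)).
#' @param missing_rate per-call missing probability (default 0.01).
#' @param n_duplicates number of samples duplicated verbatim and appended
#'   (default 0); duplicates emulate redundant accessions.
#' @param n_dup_segments number of 500 bp genome segments copied onto
#'   another chromosome to defeat the flank-specificity filter at planted
#'   loci (default 0).
#' @param min_gap minimum spacing between simulated loci in bp (default
#'   250, comfortably above the 100 bp isolation window).
#' @param edge_margin closest a locus may sit to a chromosome end (default
#'   250 bp, so 200 bp flanks are always extractable).
#' @param seed integer seed; a fixed seed reproduces the dataset exactly.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_chrom = 14L, chrom_len = 60000L, n_loci = 1000L,
                       pop_sizes = c(NW = 26L, NC = 26L, NE = 26L, QTP = 12L),
                       pop_f = c(NW = 0.02, NC = 0.02, NE = 0.02, QTP = 0.3),
                       shared_f = 0.05,
                       maf_range = c(0.05, 0.5), missing_rate = 0.01,
                       n_duplicates = 0L, n_dup_segments = 0L,
                       min_gap = 250L, edge_margin = 250L, seed = 42L) {
  stopifnot(n_chrom >= 1, all(chrom_len >= 1000), n_loci >= 1,
            all(pop_sizes >= 0), all(pop_f > 0), all(pop_f < 1),
            shared_f > 0, shared_f < 1,
            missing_rate >= 0, missing_rate < 1,
            maf_range[1] > 0, maf_range[2] <= 0.5)
  structure(list(n_chrom = as.integer(n_chrom),
                 chrom_len = rep_len(as.integer(chrom_len), n_chrom),
                 n_loci = as.integer(n_loci), pop_sizes = pop_sizes,
                 pop_f = pop_f, shared_f = shared_f, maf_range = maf_range,
                 missing_rate = missing_rate,
                 n_duplicates = as.integer(n_duplicates),
                 n_dup_segments = as.integer(n_dup_segments),
                 min_gap = as.integer(min_gap),
                 edge_margin = as.integer(edge_margin),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a reference genome
#'
#' Seeded random nucleotide sequences, one per chromosome, optionally with
#' planted duplicated segments (a 500 bp block copied onto the next
#' chromosome) to exercise the specificity filter.
#'
#' @param cfg a [sim_config()].
#' @return A `DNAStringSet` with chromosomes named `chr01`, `chr02`, ...;
#'   attribute `dup_segments` records planted duplications
#'   (chrom/start/end of the source block).
#' @export
simulate_reference <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  seqs <- vapply(seq_len(cfg$n_chrom), function(i) {
    paste(sample(c("A", "C", "G", "T"), cfg$chrom_len[i], replace = TRUE),
          collapse = "")
  }, character(1))
  names(seqs) <- sprintf("chr%02d", seq_len(cfg$n_chrom))
  dups <- NULL
  if (cfg$n_dup_segments > 0) {
    if (cfg$n_chrom < 2) stop("planting duplications needs >= 2 chromosomes")
    dups <- data.frame(chrom = character(0), start = integer(0),
                       end = integer(0))
    for (k in seq_len(cfg$n_dup_segments)) {
      src <- ((k - 1) %% cfg$n_chrom) + 1L
      dst <- (src %% cfg$n_chrom) + 1L
      start <- 1000L + (k - 1L) * 700L
      end <- start + 499L
      block <- substr(seqs[src], start, end)
      tgt <- cfg$chrom_len[dst] - 2000L - (k - 1L) * 700L
      substr(seqs[dst], tgt, tgt + 499L) <- block
      dups <- rbind(dups, data.frame(chrom = names(seqs)[src],
                                     start = start, end = end))
    }
  }
  genome <- Biostrings::DNAStringSet(seqs)
  attr(genome, "dup_segments") <- dups
  genome
}

#' Simulate structured genotypes on a reference
#'
#' Places `n_loci` SNPs on the genome (ref allele = genome base, alt drawn
#' from the other three bases), draws an ancestral alt-allele frequency per
#' locus from the configured range, diverges it per population under the
#' Balding-Nichols model
#' `p_k ~ Beta(p0 (1 - F)/F, (1 - p0)(1 - F)/F)` (the NW/NC/NE populations
#' diverge from a shared intermediate draw), samples genotypes as
#' Binomial(2, p_k) alt-allele dosages, masks calls missing at the
#' configured rate, and appends exact duplicates of the first
#' `n_duplicates` samples.
#'
#' @param cfg a [sim_config()].
#' @param genome a genome from [simulate_reference()] (regenerated from
#'   `cfg` when `NULL`).
#' @return List with `g` (a `geno_matrix`), `meta` (sample/population
#'   data.frame) and `truth` (list: per-locus ancestral and per-population
#'   allele frequencies, duplicate pairs).
#' @export
simulate_genotypes <- function(cfg = sim_config(), genome = NULL) {
  if (is.null(genome)) genome <- simulate_reference(cfg)
  set.seed(cfg$seed + 1L)
  # spread loci across chromosomes proportionally to length, spaced by
  # min_gap and clear of chromosome ends
  per_chrom <- table(factor(
    sample(seq_len(cfg$n_chrom), cfg$n_loci, replace = TRUE,
           prob = cfg$chrom_len),
    levels = seq_len(cfg$n_chrom)))
  loci <- NULL
  for (i in seq_len(cfg$n_chrom)) {
    k <- per_chrom[i]
    if (k == 0) next
    grid <- seq(cfg$edge_margin,
                cfg$chrom_len[i] - cfg$edge_margin, by = cfg$min_gap)
    if (length(grid) < k) stop("chromosome ", i, " too short for ", k, " loci")
    pos <- sort(sample(grid, k))
    loci <- rbind(loci, data.frame(chrom = names(genome)[i], pos = pos,
                                   stringsAsFactors = FALSE))
  }
  bases <- c("A", "C", "G", "T")
  ref <- vapply(seq_len(nrow(loci)), function(j) {
    as.character(Biostrings::subseq(genome[[loci$chrom[j]]],
                                    loci$pos[j], loci$pos[j]))
  }, character(1))
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  loci <- data.frame(id = sprintf("snp%05d", seq_len(nrow(loci))),
                     chrom = loci$chrom, pos = loci$pos, ref = ref,
                     alt = alt, stringsAsFactors = FALSE)
  L <- nrow(loci)
  pops <- names(cfg$pop_sizes)
  p0 <- stats::runif(L, cfg$maf_range[1], cfg$maf_range[2])
  bn_draw <- function(p, f) {
    a <- p * (1 - f) / f
    b <- (1 - p) * (1 - f) / f
    stats::rbeta(length(p), a, b)
  }
  northern <- intersect(c("NW", "NC", "NE"), pops)
  p_shared <- if (length(northern)) bn_draw(p0, cfg$shared_f) else NULL
  pop_freq <- vapply(pops, function(pp) {
    base <- if (pp %in% northern) p_shared else p0
    bn_draw(base, cfg$pop_f[[pp]])
  }, numeric(L))
  samples <- character(0)
  pop_lab <- character(0)
  dos <- NULL
  for (pp in pops) {
    npop <- cfg$pop_sizes[[pp]]
    if (npop == 0) next
    block <- matrix(stats::rbinom(npop * L, 2, rep(pop_freq[, pp],
                                                   each = npop)),
                    nrow = npop)
    dos <- rbind(dos, block)
    samples <- c(samples, sprintf("%s-%03d", pp, seq_len(npop)))
    pop_lab <- c(pop_lab, rep(pp, npop))
  }
  # missing mask
  if (cfg$missing_rate > 0) {
    mask <- matrix(stats::runif(length(dos)) < cfg$missing_rate,
                   nrow = nrow(dos))
    dos[mask] <- NA_integer_
  }
  dup_pairs <- NULL
  if (cfg$n_duplicates > 0) {
    idx <- seq_len(min(cfg$n_duplicates, nrow(dos)))
    dos <- rbind(dos, dos[idx, , drop = FALSE])
    dup_names <- paste0(samples[idx], "-dup")
    dup_pairs <- data.frame(original = samples[idx], duplicate = dup_names,
                            stringsAsFactors = FALSE)
    pop_lab <- c(pop_lab, pop_lab[idx])
    samples <- c(samples, dup_names)
  }
  calls <- matrix(NA_character_, nrow(dos), L)
  for (j in seq_len(L)) {
    lv <- sort_call(loci$ref[j], loci$alt[j])
    calls[, j] <- lv[dos[, j] + 1L]
  }
  g <- geno_matrix(samples, loci, calls)
  list(g = g,
       meta = data.frame(sample = samples, population = pop_lab,
                         stringsAsFactors = FALSE),
       truth = list(ancestral_freq = p0, pop_freq = pop_freq,
                    duplicate_pairs = dup_pairs))
}

#' Write a simulated dataset to disk
#'
#' Emits the full plain-text file set: VCF (genotypes), FASTA (reference),
#' TSV metadata, and a JSON truth report, such that
#' `read_vcf(<vcf>)` round-trips every call.
#'
#' @param sim result of [simulate_genotypes()].
#' @param genome the matching reference genome.
#' @param outdir output directory (created if needed).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_dataset <- function(sim, genome, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(outdir, "genotypes.vcf"),
             fasta = file.path(outdir, "reference.fa"),
             meta = file.path(outdir, "samples.tsv"),
             truth = file.path(outdir, "truth.json"))
  write_vcf(sim$g, paths[["vcf"]])
  Biostrings::writeXStringSet(genome, paths[["fasta"]])
  utils::write.table(sim$meta, paths[["meta"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth <- list(ancestral_freq = sim$truth$ancestral_freq,
                pop_freq = as.data.frame(sim$truth$pop_freq),
                duplicate_pairs = sim$truth$duplicate_pairs)
  jsonlite::write_json(truth, paths[["truth"]], digits = NA)
  invisible(paths)
}
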