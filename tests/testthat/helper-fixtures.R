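# shared fixtures and independent oracles

# tiny genotype matrix built directly from dosages (ref/alt fixed per locus)
make_matrix_from_dosage <- function(dos, ref = NULL, alt = NULL,
                                    chrom = "chr1", pos = NULL,
                                    samples = NULL) {
  L <- ncol(dos)
  if (is.null(ref)) ref <- rep("A", L)
  if (is.null(alt)) alt <- rep("G", L)
  if (is.null(pos)) pos <- seq(500, by = 400, length.out = L)
  if (is.null(samples)) {
    samples <- if (!is.null(rownames(dos))) rownames(dos)
               else sprintf("s%02d", seq_len(nrow(dos)))
  }
  loci <- data.frame(id = sprintf("L%02d", seq_len(L)), chrom = chrom,
                     pos = pos, ref = ref, alt = alt,
                     stringsAsFactors = FALSE)
  calls <- matrix(NA_character_, nrow(dos), L)
  for (j in seq_len(L)) {
    lv <- c(paste(ref[j], ref[j], sep = "/"),
            paste(sort(c(ref[j], alt[j])), collapse = "/"),
            paste(alt[j], alt[j], sep = "/"))
    calls[, j] <- lv[dos[, j] + 1L]
  }
  geno_matrix(samples, loci, calls)
}

# independent HWE oracle: dynamic program over individuals counting, for
# each (alleles-of-type-1 used, heterozygote count), the number of equally
# likely allele-to-slot arrangements; shares no code with the closed form.
dp_hwe_table <- function(n) {
  f <- matrix(0, nrow = 2 * n + 1, ncol = n + 1)  # [a1_used+1, h+1]
  f[1, 1] <- 1
  for (i in seq_len(n)) {
    g <- matrix(0, nrow = 2 * n + 1, ncol = n + 1)
    for (a in 0:(2 * (i - 1))) {
      for (h in 0:(i - 1)) {
        w <- f[a + 1, h + 1]
        if (w == 0) next
        g[a + 3, h + 1] <- g[a + 3, h + 1] + w       # hom for allele 1
        g[a + 2, h + 2] <- g[a + 2, h + 2] + 2 * w   # het (2 orderings)
        g[a + 1, h + 1] <- g[a + 1, h + 1] + w       # hom for allele 2
      }
    }
    f <- g
  }
  f
}

dp_hwe_oracle <- function(n_homref, n_het, n_homalt, table = NULL) {
  n <- n_homref + n_het + n_homalt
  n_a1 <- 2 * n_homref + n_het
  if (is.null(table)) table <- dp_hwe_table(n)
  weights <- table[n_a1 + 1, ]
  probs <- weights / sum(weights)
  p_obs <- probs[n_het + 1]
  sum(probs[probs <= p_obs * (1 + 1e-9)])
}

# brute-force core-selection oracle: enumerate every k-subset
brute_force_core <- function(g, k, weight_mr = 0.7, weight_sh = 0.3) {
  dmat <- mrd_matrix(g)
  combs <- utils::combn(n_samples(g), k)
  objs <- apply(combs, 2, function(s) {
    weighted_objective(g, s, weight_mr, weight_sh, dmat = dmat)$objective
  })
  best <- which.max(objs)
  list(objective = objs[best], subset = combs[, best])
}

# random unrooted binary tree with positive branch lengths + its additive
# distance matrix
random_additive_tree <- function(n) {
  tr <- ape::rtree(n, rooted = FALSE,
                   br = function(k) stats::runif(k, 0.05, 1))
  list(tree = tr, d = ape::cophenetic.phylo(tr))
}

# hand-designed screening fixture: 7 loci on a 2-chromosome genome, six of
# them violating exactly one criterion (specificity, missingness, PIC, HWE,
# two isolation partners) plus one clean survivor. 24 samples.
screen_fixture <- function() {
  set.seed(909)
  chr1 <- paste(sample(c("A", "C", "G", "T"), 3200, TRUE), collapse = "")
  chr2 <- paste(sample(c("A", "C", "G", "T"), 1200, TRUE), collapse = "")
  # plant the specificity-failing duplication: window around pos 300
  substr(chr2, 400, 800) <- substr(chr1, 100, 500)
  genome <- Biostrings::DNAStringSet(c(chr1 = chr1, chr2 = chr2))
  pos <- c(spec = 300L, miss = 800L, pic = 1300L, hwe = 1800L,
           iso_a = 2300L, iso_b = 2350L, clean = 2800L)
  ref <- vapply(pos, function(p) substr(chr1, p, p), character(1))
  alt <- vapply(ref, function(r) {
    setdiff(c("A", "C", "G", "T"), r)[1]
  }, character(1))
  n <- 24L
  dos_balanced <- c(rep(0L, 6), rep(1L, 12), rep(2L, 6))   # MAF .5, HWE-ok
  dos <- cbind(
    spec = dos_balanced,
    miss = dos_balanced,
    pic = c(rep(0L, 14), rep(1L, 8), rep(2L, 2)),          # MAF .25, PIC .30
    hwe = rep(1L, n),                                       # all het
    iso_a = dos_balanced,
    iso_b = dos_balanced,
    clean = dos_balanced
  )
  loci <- data.frame(id = names(pos), chrom = "chr1", pos = as.integer(pos),
                     ref = ref, alt = alt, stringsAsFactors = FALSE)
  calls <- matrix(NA_character_, n, length(pos))
  for (j in seq_along(pos)) {
    lv <- c(paste(ref[j], ref[j], sep = "/"),
            paste(sort(c(ref[j], alt[j])), collapse = "/"),
            paste(alt[j], alt[j], sep = "/"))
    calls[, j] <- lv[dos[, j] + 1L]
  }
  calls[1, 2] <- NA_character_                              # the missing call
  g <- geno_matrix(sprintf("s%02d", seq_len(n)), loci, calls)
  list(g = g, genome = genome)
}

# the default synthetic study fixture, built once per test run
default_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 42L)
      genome <- simulate_reference(cfg)
      sim <- simulate_genotypes(cfg, genome)
      cache <<- list(cfg = cfg, genome = genome, g = sim$g,
                     meta = sim$meta, truth = sim$truth)
    }
    cache
  }
})
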