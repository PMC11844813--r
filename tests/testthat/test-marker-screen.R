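test_that("flank uniqueness detects duplicates, reverse complements, edges", {
  set.seed(5)
  chr1 <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")
  win <- substr(chr1, 400, 410)   # 11-mer window around pos 405, flank 5
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(win)))

  genome1 <- Biostrings::DNAStringSet(c(chr1 = chr1))
  expect_true(flank_uniqueness(genome1, "chr1", 405, flank = 5))

  genome2 <- Biostrings::DNAStringSet(c(chr1 = chr1, chr2 = paste0("AAAA", win)))
  v <- flank_uniqueness(genome2, "chr1", 405, flank = 5)
  expect_false(as.logical(v))
  expect_identical(attr(v, "reason"), "multi_hit")

  genome3 <- Biostrings::DNAStringSet(c(chr1 = chr1, chr2 = paste0("AAAA", rc)))
  expect_false(as.logical(flank_uniqueness(genome3, "chr1", 405, flank = 5)))

  edge <- flank_uniqueness(genome1, "chr1", 3, flank = 5)
  expect_false(as.logical(edge))
  expect_identical(attr(edge, "reason"), "edge")
})

test_that("batch specificity agrees with the single-locus scan", {
  fx <- screen_fixture()
  single <- vapply(seq_len(n_loci(fx$g)), function(j) {
    as.logical(flank_uniqueness(fx$genome, fx$g$loci$chrom[j],
                                fx$g$loci$pos[j], 200))
  }, logical(1))
  batch <- fingercore:::flank_uniqueness_batch(fx$genome, fx$g$loci, 200)
  expect_identical(batch$verdict, single)
})

test_that("isolation window is closed at the threshold distance", {
  two_at_100 <- data.frame(chrom = "chr1", pos = c(500L, 600L))
  expect_identical(isolation_filter(two_at_100, 100), c(FALSE, FALSE))
  two_at_101 <- data.frame(chrom = "chr1", pos = c(500L, 601L))
  expect_identical(isolation_filter(two_at_101, 100), c(TRUE, TRUE))
  # chromosome boundaries do not leak proximity
  across <- data.frame(chrom = c("chr1", "chr2"), pos = c(500L, 550L))
  expect_identical(isolation_filter(across, 100), c(TRUE, TRUE))
  single <- data.frame(chrom = "chr1", pos = 500L)
  expect_identical(isolation_filter(single, 100), TRUE)
  expect_error(isolation_filter(data.frame(chrom = "chr1",
                                           pos = c(600L, 500L)), 100),
               "sorted")
})

test_that("cascade on the hand fixture isolates each criterion", {
  fx <- screen_fixture()
  rep <- screen_cascade(fx$g, fx$genome, screen_config())
  expect_identical(rep$survivors, "clean")
  v <- rep$verdicts
  crit <- c("specificity", "missing", "maf", "pic", "hwe", "isolation")
  fails <- lapply(seq_len(nrow(v)), function(i) crit[!unlist(v[i, crit])])
  names(fails) <- v$id
  expect_identical(fails$spec, "specificity")
  expect_identical(fails$miss, "missing")
  expect_identical(fails$pic, "pic")
  expect_identical(fails$hwe, "hwe")
  expect_identical(fails$iso_a, "isolation")
  expect_identical(fails$iso_b, "isolation")
  expect_identical(fails$clean, character(0))
  # overall is the conjunction of the individual criteria
  expect_identical(v$overall,
                   v$specificity & v$missing & v$maf & v$pic & v$hwe &
                     v$isolation)
})

test_that("fully relaxed thresholds let every locus survive", {
  fx <- screen_fixture()
  cfg <- screen_config(max_missing = 1, min_maf = 0, min_pic = 0,
                       hwe_alpha = 0, isolation = 0,
                       require_specificity = FALSE)
  rep <- screen_cascade(fx$g, NULL, cfg)
  expect_identical(rep$survivors, fx$g$loci$id)
})

test_that("survivor count is monotone in thresholds and specificity-off is a superset", {
  fx <- default_fixture()
  base <- screen_cascade(fx$g, fx$genome, screen_config())
  tighter_maf <- screen_cascade(fx$g, fx$genome, screen_config(min_maf = 0.3))
  tighter_pic <- screen_cascade(fx$g, fx$genome, screen_config(min_pic = 0.37))
  wider_iso <- screen_cascade(fx$g, fx$genome, screen_config(isolation = 200))
  expect_lte(length(tighter_maf$survivors), length(base$survivors))
  expect_lte(length(tighter_pic$survivors), length(base$survivors))
  expect_lte(length(wider_iso$survivors), length(base$survivors))
  no_spec <- screen_cascade(fx$g, NULL,
                            screen_config(require_specificity = FALSE))
  expect_true(all(base$survivors %in% no_spec$survivors))
})

test_that("chromosome-balanced selection honours quotas and tie-breaks", {
  # 14 chromosomes x 5 clean survivors each, descending PIC within chrom
  set.seed(99)
  n_chrom <- 14
  per <- 5
  chroms <- sprintf("c%02d", rep(seq_len(n_chrom), each = per))
  stats <- data.frame(
    id = sprintf("m%03d", seq_len(n_chrom * per)),
    chrom = chroms,
    pos = rep(seq(1000, by = 1000, length.out = per), n_chrom),
    pic = runif(n_chrom * per, 0.35, 0.375),
    maf = runif(n_chrom * per, 0.35, 0.5)
  )
  rep <- structure(list(stats = stats, survivors = stats$id),
                   class = "screen_report")
  core <- chromosome_balanced_select(rep, 52)
  expect_length(core, 52)
  counts <- table(stats$chrom[match(core, stats$id)])
  expect_setequal(as.integer(counts), c(3L, 4L))
  expect_identical(sum(counts == 4), 10L)   # 52 = 14*3 + 10
  expect_identical(sum(counts == 3), 4L)

  # target = survivor count returns everything
  expect_setequal(chromosome_balanced_select(rep, nrow(stats)), stats$id)

  # exact tie on pic and maf resolves to the lower locus id, stably
  stats2 <- stats
  stats2$pic <- 0.36
  stats2$maf <- 0.4
  rep2 <- structure(list(stats = stats2, survivors = stats2$id),
                    class = "screen_report")
  core2a <- chromosome_balanced_select(rep2, 14)
  core2b <- chromosome_balanced_select(rep2, 14)
  expect_identical(core2a, core2b)
  expect_identical(core2a, stats2$id[seq(1, by = per, length.out = n_chrom)])
})

test_that("quota shortfall on a thin chromosome is redistributed with warning", {
  stats <- data.frame(
    id = sprintf("m%02d", 1:11),
    chrom = c(rep("c1", 1), rep("c2", 5), rep("c3", 5)),
    pos = c(100, seq(100, 500, 100), seq(100, 500, 100)),
    pic = seq(0.375, 0.355, length.out = 11),
    maf = rep(0.4, 11)
  )
  rep <- structure(list(stats = stats, survivors = stats$id),
                   class = "screen_report")
  expect_warning(core <- chromosome_balanced_select(rep, 9), "redistributed")
  expect_length(core, 9)
  counts <- table(stats$chrom[match(core, stats$id)])
  expect_identical(as.integer(counts[["c1"]]), 1L)
})
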