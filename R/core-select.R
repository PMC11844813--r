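#' Modified Rogers distance between samples
#'
#' For each sample the per-locus allele "frequency" is its ref-allele dosage
#' divided by 2 (0, 0.5 or 1); the modified Rogers distance between two
#' samples is the Euclidean distance between their allele-frequency vectors
#' scaled so that opposite homozygotes at every locus give 1:
#' \deqn{MRD = \sqrt{\frac{1}{2L} \sum_l \sum_{a} (p_{il,a} - p_{jl,a})^2}}
#' Loci missing in either sample are excluded and `L` reduced accordingly
#' (pairwise deletion).
#'
#' @param g a `geno_matrix`.
#' @param i,j sample indices or labels.
#' @return Distance in `[0, 1]`.
#' @export
modified_rogers_distance <- function(g, i, j) {
  mrd_matrix(g)[i, j]
}

#' All-pairs modified Rogers distance matrix
#'
#' @param g a `geno_matrix`.
#' @return Symmetric samples x samples matrix; errors if some pair shares no
#'   called locus.
#' @export
mrd_matrix <- function(g) {
  p <- dosage_matrix(g) / 2             # alt-allele frequency per sample
  m <- !is.na(p)
  e <- p
  e[!m] <- 0
  mm <- m * 1
  # sum over shared loci of (p_i - p_j)^2, via masked expansion
  a <- (e^2) %*% t(mm)
  b <- e %*% t(e)
  ss <- a + t(a) - 2 * b
  shared <- mm %*% t(mm)
  if (any(shared[upper.tri(shared)] == 0)) {
    stop("some sample pair shares no called locus")
  }
  diag(shared) <- pmax(diag(shared), 1)
  # both alleles contribute equally: sum over alleles = 2 * ss
  d <- sqrt(pmax(2 * ss, 0) / (2 * shared))
  diag(d) <- 0
  d[d < 1e-12] <- 0
  dimnames(d) <- list(g$samples, g$samples)
  d
}

#' Core-collection optimizer configuration
#'
#' @param weight_mr weight of the mean modified Rogers distance component
#'   (default 0.7).
#' @param weight_sh weight of the Shannon diversity component (default 0.3);
#'   weights must sum to 1.
#' @param fractions sampling-fraction grid for [fraction_sweep()] (default
#'   0.1 to 0.9 in steps of 0.1).
#' @param restarts independent seeded random starts per optimization
#'   (default 10).
#' @param max_sweeps cap on steepest-ascent sweeps per start (default 200).
#' @param coverage_goal allele-coverage level defining the recommended
#'   fraction in a sweep (default 0.99).
#' @return List of class `core_config`.
#' @export
core_config <- function(weight_mr = 0.7, weight_sh = 0.3,
                        fractions = seq(0.1, 0.9, by = 0.1),
                        restarts = 10L, max_sweeps = 200L,
                        coverage_goal = 0.99) {
  stopifnot(weight_mr >= 0, weight_sh >= 0,
            abs(weight_mr + weight_sh - 1) < 1e-9,
            all(fractions > 0), all(fractions < 1), restarts >= 1)
  structure(list(weight_mr = weight_mr, weight_sh = weight_sh,
                 fractions = fractions, restarts = as.integer(restarts),
                 max_sweeps = as.integer(max_sweeps),
                 coverage_goal = coverage_goal),
            class = "core_config")
}

#' Weighted diversity objective of a sample subset
#'
#' The blended objective maximized by the core-collection search:
#' `weight_mr * MR + weight_sh * SH`, where MR is the mean pairwise modified
#' Rogers distance within the subset and SH is the per-locus-averaged
#' Shannon-Wiener index of the subset's pooled allele frequencies,
#' `-(1/L) * sum_l sum_a p ln p` (so SH sits on a scale commensurate with
#' MR in `[0, 1]`, its biallelic ceiling being `ln 2`).
#'
#' @param g a `geno_matrix`.
#' @param subset sample indices or labels, at least 2.
#' @param weight_mr,weight_sh component weights (default 0.7 / 0.3).
#' @param dmat optional precomputed [mrd_matrix()].
#' @return List with `objective`, `mr`, `sh`.
#' @export
weighted_objective <- function(g, subset, weight_mr = 0.7, weight_sh = 0.3,
                               dmat = NULL) {
  if (is.character(subset)) subset <- match(subset, g$samples)
  if (length(subset) < 2) stop("subset must contain at least 2 samples")
  if (is.null(dmat)) dmat <- mrd_matrix(g)
  sub_d <- dmat[subset, subset]
  mr <- mean(sub_d[upper.tri(sub_d)])
  d <- dosage_matrix(g)[subset, , drop = FALSE]
  sh <- pooled_shannon(colSums(d, na.rm = TRUE),
                       colSums(!is.na(d)))
  list(objective = weight_mr * mr + weight_sh * sh, mr = mr, sh = sh)
}

# mean per-locus Shannon index from pooled alt-dosage sums and called counts
pooled_shannon <- function(alt_sum, n_called) {
  use <- n_called > 0
  p <- alt_sum[use] / (2 * n_called[use])
  q <- 1 - p
  h <- numeric(length(p))
  pos <- p > 0 & p < 1
  h[pos] <- -(p[pos] * log(p[pos]) + q[pos] * log(q[pos]))
  sum(h) / length(alt_sum)
}

#' Allele coverage of a subset
#'
#' Fraction of the (locus, allele) pairs observed anywhere in the full
#' collection that are also observed within the subset.
#'
#' @param g a `geno_matrix`.
#' @param subset sample indices or labels (nonempty).
#' @return CV in `[0, 1]`.
#' @export
allele_coverage <- function(g, subset) {
  if (is.character(subset)) subset <- match(subset, g$samples)
  stopifnot(length(subset) >= 1)
  d <- dosage_matrix(g)
  full <- allele_presence(d)
  sub <- allele_presence(d[subset, , drop = FALSE])
  sum(sub) / sum(full)
}

# 2 x L logical: is (ref allele, alt allele) observed at each locus
allele_presence <- function(d) {
  alt <- colSums(d, na.rm = TRUE) > 0
  ref <- colSums(2 - d, na.rm = TRUE) > 0
  rbind(ref = ref, alt = alt)
}

#' Optimize a core collection at a fixed fraction
#'
#' Steepest-ascent local search over single-swap moves (replace one selected
#' sample by one unselected) on the weighted objective, from seeded random
#' starts with restarts; the best subset over all starts is returned.
#' Reproducible for a fixed seed.
#'
#' @param g a `geno_matrix`.
#' @param fraction fraction of samples to select; core size =
#'   `round(fraction * N)` (must be >= 2).
#' @param cfg a [core_config()].
#' @param seed integer seed for the random starts.
#' @param init optional sample labels used to seed the first start (e.g. a
#'   smaller core being grown); topped up / trimmed at random to size.
#' @param dmat optional precomputed [mrd_matrix()].
#' @return List of class `core_selection`: `selected` (labels), `objective`,
#'   `mr`, `sh`, `cv`, `fraction`, `size`.
#' @export
optimize_core <- function(g, fraction, cfg = core_config(), seed = 1L,
                          init = NULL, dmat = NULL) {
  n <- n_samples(g)
  k <- round(fraction * n)
  if (k < 2) stop("core size round(fraction * N) = ", k, " is below 2")
  if (k > n) stop("core size exceeds collection size")
  if (is.null(dmat)) dmat <- mrd_matrix(g)
  d <- dosage_matrix(g)
  alt <- d
  alt[is.na(alt)] <- 0L
  called <- !is.na(d)
  set.seed(seed)
  best <- NULL
  for (r in seq_len(cfg$restarts)) {
    if (r == 1 && !is.null(init)) {
      sel <- match(init, g$samples)
      if (anyNA(sel)) stop("init contains unknown sample labels")
      if (length(sel) > k) sel <- sample(sel, k)
      if (length(sel) < k) {
        sel <- c(sel, sample(setdiff(seq_len(n), sel), k - length(sel)))
      }
    } else {
      sel <- sample(n, k)
    }
    res <- ascend_swaps(sel, dmat, alt, called, cfg)
    if (is.null(best) || res$objective > best$objective + 1e-12) best <- res
  }
  sel <- sort(best$sel)
  structure(list(selected = g$samples[sel],
                 objective = best$objective, mr = best$mr, sh = best$sh,
                 cv = allele_coverage(g, sel),
                 fraction = fraction, size = k),
            class = "core_selection")
}

# steepest-ascent over single swaps; objective pieces kept incrementally
ascend_swaps <- function(sel, dmat, alt, called, cfg) {
  n <- nrow(dmat)
  L <- ncol(alt)
  k <- length(sel)
  w_mr <- cfg$weight_mr
  w_sh <- cfg$weight_sh
  npair <- k * (k - 1) / 2
  in_sel <- logical(n)
  in_sel[sel] <- TRUE
  rs <- rowSums(dmat[, sel, drop = FALSE])    # sum of d(x, s) over selected
  pair_sum <- sum(rs[sel]) / 2
  alt_sum <- colSums(alt[sel, , drop = FALSE])
  n_called <- colSums(called[sel, , drop = FALSE])
  obj_of <- function(psum, asum, ncal) {
    w_mr * (psum / npair) + w_sh * pooled_shannon(asum, ncal)
  }
  cur <- obj_of(pair_sum, alt_sum, n_called)
  for (sweep in seq_len(cfg$max_sweeps)) {
    best_gain <- 1e-10
    best_move <- NULL
    outs <- which(in_sel)
    ins <- which(!in_sel)
    for (o in outs) {
      psum_o <- pair_sum - rs[o]
      asum_o <- alt_sum - alt[o, ]
      ncal_o <- n_called - called[o, ]
      for (i in ins) {
        psum <- psum_o + rs[i] - dmat[i, o]
        val <- obj_of(psum, asum_o + alt[i, ], ncal_o + called[i, ])
        if (val - cur > best_gain) {
          best_gain <- val - cur
          best_move <- c(o, i)
        }
      }
    }
    if (is.null(best_move)) break
    o <- best_move[1]; i <- best_move[2]
    pair_sum <- pair_sum - rs[o] + rs[i] - dmat[i, o]
    alt_sum <- alt_sum - alt[o, ] + alt[i, ]
    n_called <- n_called - called[o, ] + called[i, ]
    rs <- rs - dmat[, o] + dmat[, i]
    in_sel[o] <- FALSE
    in_sel[i] <- TRUE
    cur <- obj_of(pair_sum, alt_sum, n_called)
  }
  list(sel = which(in_sel), objective = unname(cur),
       mr = unname(pair_sum) / npair,
       sh = pooled_shannon(alt_sum, n_called))
}

#' Sweep the sampling-fraction grid
#'
#' Optimizes one core per fraction on the grid, seeding each larger core
#' from the previous fraction's core (nesting keeps the coverage curve
#' monotone and the sweep cheap); restarts are only spent on the first
#' fraction. The recommended fraction is the smallest whose allele coverage
#' reaches `cfg$coverage_goal`.
#'
#' @param g a `geno_matrix`.
#' @param cfg a [core_config()].
#' @param seed integer seed.
#' @return List of class `fraction_sweep`: `selections` (list of
#'   `core_selection`), `table` (fraction, size, mr, sh, objective, cv),
#'   `recommended_fraction` (NA if the goal is never reached).
#' @export
fraction_sweep <- function(g, cfg = core_config(), seed = 1L) {
  dmat <- mrd_matrix(g)
  fr <- sort(cfg$fractions)
  sels <- vector("list", length(fr))
  prev <- NULL
  one_cfg <- cfg
  for (i in seq_along(fr)) {
    if (i > 1) one_cfg$restarts <- 1L
    sels[[i]] <- optimize_core(g, fr[i], one_cfg, seed = seed + i - 1L,
                               init = prev, dmat = dmat)
    prev <- sels[[i]]$selected
  }
  tab <- data.frame(
    fraction = fr,
    size = vapply(sels, `[[`, numeric(1), "size"),
    mr = vapply(sels, `[[`, numeric(1), "mr"),
    sh = vapply(sels, `[[`, numeric(1), "sh"),
    objective = vapply(sels, `[[`, numeric(1), "objective"),
    cv = vapply(sels, `[[`, numeric(1), "cv")
  )
  hit <- which(tab$cv >= cfg$coverage_goal)
  structure(list(selections = sels, table = tab,
                 recommended_fraction = if (length(hit)) fr[min(hit)] else NA),
            class = "fraction_sweep")
}

#' Compare diversity retention of a core against the full collection
#'
#' Mean per-locus He, Ho, Nei, Shannon, PIC and MAF for the subset and the
#' full collection, plus MAF spectra and the genotype-spectrum coefficient
#' of determination between the two.
#'
#' @param g a `geno_matrix`.
#' @param subset sample indices or labels.
#' @return List with `table` (statistic, core, full, ratio), `maf_spectrum`
#'   (core and full), `genotype_r2`.
#' @export
compare_diversity <- function(g, subset) {
  if (is.character(subset)) subset <- match(subset, g$samples)
  stopifnot(length(subset) >= 1)
  gc <- g[subset, ]
  sf <- locus_stats(g)
  sc <- locus_stats(gc)
  stat_names <- c("he", "ho", "nei", "shannon", "pic", "maf")
  core_m <- vapply(stat_names, function(s) mean(sc[[s]]), numeric(1))
  full_m <- vapply(stat_names, function(s) mean(sf[[s]]), numeric(1))
  tab <- data.frame(statistic = stat_names, core = core_m, full = full_m,
                    ratio = ifelse(full_m > 0, core_m / full_m, NA),
                    stringsAsFactors = FALSE, row.names = NULL)
  list(table = tab,
       maf_spectrum = list(core = maf_spectrum(sc$maf),
                           full = maf_spectrum(sf$maf)),
       genotype_r2 = spectrum_concordance(genotype_spectrum(g),
                                          genotype_spectrum(gc)))
}
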