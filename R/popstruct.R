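#' P-distance matrix between samples
#'
#' Genetic distance between two samples = proportion of panel loci at which
#' their unordered calls differ, among loci called in both (pairwise
#' deletion). A heterozygote vs a homozygote counts as a full mismatch
#' (call-level distance). Pairs that share no called locus are marked
#' uncomparable (`NA`) rather than identical.
#'
#' @param g a `geno_matrix`.
#' @param panel optional locus ids restricting the comparison (default: all
#'   loci).
#' @return List of class `dist_matrix`: `d` (symmetric matrix in `[0, 1]`,
#'   `NA` for uncomparable pairs), `shared` (compared-locus counts),
#'   `uncomparable` (data.frame of flagged pairs).
#' @export
p_distance_matrix <- function(g, panel = NULL) {
  if (!is.null(panel)) g <- g[, panel]
  calls <- g$calls
  n <- nrow(calls)
  d <- matrix(0, n, n, dimnames = list(g$samples, g$samples))
  sh <- matrix(0L, n, n, dimnames = list(g$samples, g$samples))
  for (i in seq_len(n)) {
    sh[i, i] <- sum(!is.na(calls[i, ]))
    if (i == n) break
    for (j in (i + 1):n) {
      both <- !is.na(calls[i, ]) & !is.na(calls[j, ])
      ns <- sum(both)
      sh[i, j] <- sh[j, i] <- ns
      d[i, j] <- d[j, i] <-
        if (ns > 0) sum(calls[i, both] != calls[j, both]) / ns else NA_real_
    }
  }
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  unc <- pairs[is.na(d[pairs]), , drop = FALSE]
  structure(list(d = d, shared = sh,
                 uncomparable = data.frame(
                   sample_a = g$samples[unc[, 1]],
                   sample_b = g$samples[unc[, 2]],
                   stringsAsFactors = FALSE)),
            class = "dist_matrix")
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via \pkg{ape}), exact on additive distance
#' matrices. Negative branch lengths, which NJ can produce on non-additive
#' input, are clamped to zero and flagged.
#'
#' @param d a `dist_matrix` from [p_distance_matrix()], or a plain symmetric
#'   matrix with sample dimnames.
#' @return An [ape::phylo] tree; attribute `clamped` gives the number of
#'   negative branch lengths set to zero.
#' @export
nj_tree <- function(d) {
  m <- if (inherits(d, "dist_matrix")) d$d else as.matrix(d)
  if (nrow(m) < 3) stop("neighbor joining needs at least 3 samples")
  if (anyNA(m)) stop("distance matrix contains uncomparable pairs")
  tree <- ape::nj(stats::as.dist(m))
  neg <- tree$edge.length < 0
  tree$edge.length[neg] <- 0
  attr(tree, "clamped") <- sum(neg)
  tree
}

#' Bootstrap supports for the NJ tree
#'
#' Resamples panel loci with replacement, rebuilds the p-distance NJ tree
#' per replicate, and scores each internal bipartition of the reference
#' tree by the percentage of replicates that contain it.
#'
#' @param g a `geno_matrix`.
#' @param panel optional locus ids (default all loci).
#' @param replicates number of bootstrap replicates (>= 1; 1000 is the
#'   conventional choice).
#' @param seed integer seed.
#' @return The reference [ape::phylo] tree with `node.label` set to the
#'   support percentages (`[0, 100]`) of its internal edges.
#' @export
bootstrap_support <- function(g, panel = NULL, replicates = 100L, seed = 1L) {
  stopifnot(replicates >= 1)
  if (!is.null(panel)) g <- g[, panel]
  ref <- nj_tree(p_distance_matrix(g))
  set.seed(seed)
  boot <- vector("list", replicates)
  for (b in seq_len(replicates)) {
    idx <- sample(n_loci(g), n_loci(g), replace = TRUE)
    # resampling with replacement repeats loci; relabel to keep ids unique
    loci_b <- g$loci[idx, , drop = FALSE]
    loci_b$id <- make.unique(loci_b$id)
    gb <- geno_matrix(g$samples, loci_b, g$calls[, idx, drop = FALSE])
    boot[[b]] <- nj_tree(p_distance_matrix(gb))
  }
  counts <- ape::prop.clades(ref, boot, rooted = FALSE)
  counts[is.na(counts)] <- 0
  ref$node.label <- round(100 * counts / replicates, 1)
  ref
}

#' PCA of the dosage matrix
#'
#' Principal components of the column-centered alt-allele dosage matrix;
#' missing dosages are imputed to the locus mean before centering. The sign
#' of each component is fixed so that its largest-magnitude locus loading is
#' positive, making coordinates reproducible under sample reordering.
#'
#' @param g a `geno_matrix`.
#' @param n_comp number of leading components to return (default 10, capped
#'   by the matrix rank).
#' @return List of class `pca_dosage`: `scores` (samples x components),
#'   `loadings`, `var_explained` (fractions, non-increasing).
#' @export
pca_dosage <- function(g, n_comp = 10L) {
  stopifnot(n_samples(g) >= 2, n_loci(g) >= 2)
  x <- dosage_matrix(g) * 1.0
  mu <- colMeans(x, na.rm = TRUE)
  for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- mu[j]
  keep <- apply(x, 2, stats::var) > 0
  if (!any(keep)) stop("all loci are constant: no variance to decompose")
  pc <- stats::prcomp(x[, keep, drop = FALSE], center = TRUE, scale. = FALSE)
  n_comp <- min(n_comp, ncol(pc$x))
  scores <- pc$x[, seq_len(n_comp), drop = FALSE]
  load <- pc$rotation[, seq_len(n_comp), drop = FALSE]
  for (k in seq_len(n_comp)) {
    top <- which.max(abs(load[, k]))
    if (load[top, k] < 0) {
      load[, k] <- -load[, k]
      scores[, k] <- -scores[, k]
    }
  }
  rownames(scores) <- g$samples
  structure(list(scores = scores, loadings = load,
                 var_explained = pc$sdev[seq_len(n_comp)]^2 / sum(pc$sdev^2)),
            class = "pca_dosage")
}

#' Assign queries to their nearest population
#'
#' For each query sample, computes its mean distance to the reference
#' samples of every population and calls the population with the smallest
#' mean; the margin is the gap to the second-best population. Exact ties
#' give the call "AMBIGUOUS".
#'
#' @param d a `dist_matrix` (or plain matrix) over references and queries.
#' @param meta data.frame with `sample`, `population` for the reference
#'   samples (UNKNOWN rows are ignored).
#' @param queries sample labels to classify; a query never serves as its own
#'   reference.
#' @return data.frame: `query`, `call`, `margin`, one mean-distance column
#'   per population.
#' @export
assign_population <- function(d, meta, queries) {
  m <- if (inherits(d, "dist_matrix")) d$d else as.matrix(d)
  meta <- meta[meta$population != "UNKNOWN", , drop = FALSE]
  pops <- sort(unique(meta$population))
  if (!length(pops)) stop("no reference populations in metadata")
  out <- lapply(queries, function(q) {
    if (!q %in% rownames(m)) stop("query not in distance matrix: ", q)
    means <- vapply(pops, function(p) {
      refs <- setdiff(intersect(meta$sample[meta$population == p],
                                rownames(m)), q)
      if (!length(refs)) return(NA_real_)
      v <- m[q, refs]
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }, numeric(1))
    if (all(is.na(means))) stop("query ", q, " has no comparable references")
    ord <- order(means)
    best <- means[ord[1]]
    second <- if (length(pops) > 1) means[ord[2]] else NA_real_
    tie <- !is.na(second) && second - best < 1e-12
    res <- data.frame(query = q,
                      call = if (tie) "AMBIGUOUS" else pops[ord[1]],
                      margin = if (is.na(second)) NA_real_ else second - best,
                      stringsAsFactors = FALSE)
    for (p in pops) res[[paste0("d_", p)]] <- means[[p]]
    res
  })
  do.call(rbind, out)
}
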