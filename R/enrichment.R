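# PreRanked GSEA (enrichment score, NES, permutation FDR), single-sample
# GSEA, rank-matrix assembly and PCA embedding for cross-dataset
# clustering.

# Core running-sum enrichment score from hit positions in a ranked list.
# pos: sorted 1-based positions of the set in the ranking; w: weights at
# those positions (|stat|^p in position order); N: ranking length.
# The running sum increases by w/sum(w) at each hit and decreases by
# 1/(N-k) at each miss; its maximum lies at a hit, its minimum just before
# a hit (or at the end, value 0). Returns the extremum of largest
# magnitude; an exact magnitude tie between the two extrema is reported
# as 0 (direction ambiguous), which keeps the statistic antisymmetric
# under ranking reversal.
es_from_positions <- function(pos, w, N) {
  k <- length(pos)
  if (k == 0L) stop("empty hit set")
  if (k >= N) stop("set covers the whole ranking")
  j <- seq_len(k)
  if (all(w == w[1L])) {
    # unweighted case: the running sum takes exact rational values with
    # denominator k(N-k); integer numerators make magnitude ties (which
    # occur routinely) exact rather than floating-point-dependent
    top <- max(j * (N - k) - (pos - j) * k)
    bot <- min((j - 1L) * (N - k) - (pos - j) * k)
    if (top == -bot) return(0)
    return(if (top > -bot) top / (k * (N - k)) else bot / (k * (N - k)))
  }
  sw <- sum(w)
  if (sw <= 0) stop("zero total hit weight")
  cw <- cumsum(w) / sw
  miss <- (pos - j) / (N - k)
  top <- max(cw - miss)
  bot <- min(c(0, cw[-k]) - miss)   # value just before each hit
  if (abs(top + bot) <= 1e-12 * max(top, -bot)) return(0)
  if (top > -bot) top else bot
}

#' PreRanked GSEA enrichment score
#'
#' Weighted Kolmogorov-Smirnov running-sum statistic of a gene set along a
#' ranked gene list. Hits increment the sum by `|stat|^p` (normalized over
#' set members), misses decrement it by `1/(N - k)`; the ES is the
#' running-sum extremum of largest magnitude (an exact magnitude tie
#' between the positive and negative extremum, possible for the discrete
#' unweighted statistic, is reported as 0: the direction is ambiguous and
#' this convention keeps the score antisymmetric under ranking reversal).
#' `p = 1` is the classical
#' weighted default; `p = 0` gives the unweighted KS statistic used for
#' connectivity scoring.
#'
#' @param ranking named numeric vector of per-gene statistics. It is
#'   sorted internally by decreasing statistic with lexicographic gene-id
#'   tie-break, so ties are pre-broken deterministically.
#' @param set character vector of gene ids; must intersect the ranking.
#' @param p weight exponent (default 1).
#' @return the enrichment score in `[-1, 1]`.
#' @export
#' @examples
#' r <- setNames(10:1, letters[1:10])
#' preranked_es(r, c("a", "b"), p = 0)
preranked_es <- function(ranking, set, p = 1) {
  stopifnot(is.numeric(ranking), !is.null(names(ranking)), p >= 0)
  ord <- order_desc_by_stat(ranking, names(ranking))
  stats_sorted <- ranking[ord]
  pos <- which(names(stats_sorted) %in% set)
  if (length(pos) == 0L)
    stop("gene set does not intersect the ranking")
  w <- if (p == 0) rep(1, length(pos)) else abs(stats_sorted[pos])^p
  if (all(w == 0)) w <- rep(1, length(pos))   # all-zero stats at hits
  es_from_positions(pos, w, length(ranking))
}

#' PreRanked GSEA over a collection with permutation NES and FDR
#'
#' Null enrichment scores are generated by permuting the gene labels of
#' the ranking (equivalently, drawing random set positions of the same
#' size). NES divides each ES by the mean magnitude of same-sign null
#' scores; the nominal p-value is two-sided with +1 smoothing, so its
#' minimum is `1/(n_perm + 1)` and it is never exactly zero. FDR q follows
#' the sign-stratified GSEA convention: for a set with NES*, q is the
#' smoothed fraction of pooled same-sign null NES at least as extreme,
#' divided by the fraction of observed same-sign NES at least as extreme,
#' clamped to (0, 1].
#'
#' @param ranking named numeric vector of per-gene statistics.
#' @param collection a `gene_set_collection`.
#' @param p weight exponent passed to [preranked_es()].
#' @param n_perm number of permutations (>= 100; default 1000).
#' @param seed integer seed for the permutation null.
#' @return data frame `set`, `size`, `ES`, `NES`, `p`, `q` sorted by NES
#'   decreasing.
#' @export
preranked_gsea <- function(ranking, collection, p = 1, n_perm = 1000,
                           seed = NULL) {
  stopifnot(inherits(collection, "gene_set_collection"), n_perm >= 100)
  if (length(collection) == 0L)
    return(data.frame(set = character(), size = integer(), ES = numeric(),
                      NES = numeric(), p = numeric(), q = numeric()))
  N <- length(ranking)
  ord <- order_desc_by_stat(ranking, names(ranking))
  stats_sorted <- ranking[ord]
  wall <- abs(stats_sorted)^p
  if (p == 0) wall <- rep(1, N)
  with_seed(seed, {
    res <- lapply(names(collection), function(nm) {
      set <- collection[[nm]]
      pos <- which(names(stats_sorted) %in% set)
      if (length(pos) == 0L)
        stop("set '", nm, "' does not intersect the ranking")
      if (length(pos) > N / 2)
        warning("set '", nm, "' covers more than half the universe; ",
                "permutation null poorly calibrated")
      k <- length(pos)
      es <- es_from_positions(pos, wall[pos], N)
      null <- vapply(seq_len(n_perm), function(i) {
        rp <- sort(sample.int(N, k))
        es_from_positions(rp, wall[rp], N)
      }, numeric(1))
      same <- null[sign(null) == sign(es)]
      denom <- if (length(same)) mean(abs(same)) else mean(abs(null))
      nes <- es / denom
      null_nes <- null / denom
      pval <- (1 + sum(abs(null) >= abs(es))) / (n_perm + 1)
      list(set = nm, size = k, ES = es, NES = nes, p = pval,
           null_nes = null_nes)
    })
    out <- data.frame(
      set = vapply(res, `[[`, "", "set"),
      size = vapply(res, function(x) x$size, integer(1)),
      ES = vapply(res, `[[`, numeric(1), "ES"),
      NES = vapply(res, `[[`, numeric(1), "NES"),
      p = vapply(res, `[[`, numeric(1), "p"))
    pooled <- unlist(lapply(res, `[[`, "null_nes"))
    out$q <- vapply(seq_len(nrow(out)), function(i) {
      nes <- out$NES[i]
      if (nes >= 0) {
        num <- (1 + sum(pooled >= nes)) / (1 + sum(pooled >= 0))
        den <- sum(out$NES >= nes) / max(1L, sum(out$NES >= 0))
      } else {
        num <- (1 + sum(pooled <= nes)) / (1 + sum(pooled < 0))
        den <- sum(out$NES <= nes) / max(1L, sum(out$NES < 0))
      }
      min(1, num / max(den, .Machine$double.eps))
    }, numeric(1))
    out[order(-out$NES, out$set, method = "radix"), , drop = FALSE]
  })
}

#' Single-sample GSEA enrichment score
#'
#' Barbie-style statistic: genes are ranked within the sample (largest
#' value gets rank N; ties in value are broken by gene id for
#' determinism); the score is the sum over the descending ranking of the
#' difference between the weighted in-set ECDF (weights `rank^alpha`) and
#' the unweighted out-of-set ECDF. Because only within-sample ranks enter,
#' the score is invariant under any strictly monotone transform of the
#' sample values.
#'
#' @param sample_values named numeric vector (one sample's expression).
#' @param set character vector of gene ids; must overlap the universe.
#' @param alpha rank weight exponent (default 0.25).
#' @return the (unnormalized) ssGSEA enrichment score.
#' @export
ssgsea_score <- function(sample_values, set, alpha = 0.25) {
  stopifnot(is.numeric(sample_values), !is.null(names(sample_values)),
            alpha >= 0)
  N <- length(sample_values)
  if (length(unique(sample_values)) == 1L)
    stop("constant sample: within-sample ranks are undefined")
  ord <- order_desc_by_stat(sample_values, names(sample_values))
  hit <- names(sample_values)[ord] %in% set
  k <- sum(hit)
  if (k == 0L) stop("gene set does not overlap the sample's universe")
  if (k >= N) stop("gene set covers the whole universe")
  r <- as.numeric(N:1)                 # rank by value, largest first
  w <- r^alpha * hit
  ecdf_in <- cumsum(w) / sum(w)
  ecdf_out <- cumsum(!hit) / (N - k)
  sum(ecdf_in - ecdf_out)
}

#' ssGSEA score matrix over a collection
#'
#' Applies [ssgsea_score()] to every set and sample. With
#' `normalize = TRUE` (default) the whole matrix is divided by its global
#' score range, the usual matrix-level normalization; downstream rank
#' assembly is invariant to this choice.
#'
#' @param expr gene x sample matrix.
#' @param collection a `gene_set_collection`.
#' @param alpha rank weight exponent.
#' @param normalize divide by the global range (on/off switch).
#' @return sets x samples numeric matrix of enrichment scores.
#' @export
ssgsea_matrix <- function(expr, collection, alpha = 0.25, normalize = TRUE) {
  check_expression(expr)
  stopifnot(inherits(collection, "gene_set_collection"),
            length(collection) > 0L)
  es <- vapply(colnames(expr), function(s) {
    v <- expr[, s]
    names(v) <- rownames(expr)
    vapply(collection, function(set) ssgsea_score(v, set, alpha), numeric(1))
  }, numeric(length(collection)))
  es <- matrix(es, nrow = length(collection),
               dimnames = list(names(collection), colnames(expr)))
  if (normalize) {
    rng <- diff(range(es))
    if (rng > 0) es <- es / rng
  }
  es
}

#' Rank samples within each gene set
#'
#' Converts a sets x samples score matrix into the ssGSEA rank matrix:
#' per set, samples are ranked by score with average ranks on ties. The
#' result is invariant to any strictly monotone per-set rescaling of the
#' scores.
#'
#' @param scores sets x samples numeric matrix (>= 2 samples).
#' @return sets x samples matrix of ranks in `[1, n_samples]`.
#' @export
build_rank_matrix <- function(scores) {
  stopifnot(is.matrix(scores))
  if (ncol(scores) < 2L) stop("rank matrix needs >= 2 samples")
  t(apply(scores, 1L, avg_rank))
}

#' PCA embedding of samples from a rank matrix
#'
#' Samples are the observations (the sets x samples matrix is transposed),
#' each set's ranks are centered (no scaling: ranks are already
#' commensurate), and the embedding is the projection onto the top-k right
#' singular directions of the centered matrix. Component signs are fixed
#' so that each loading vector's largest-magnitude entry is positive.
#'
#' @param rank_matrix sets x samples numeric matrix.
#' @param k number of components (default 3); must not exceed the matrix
#'   rank.
#' @return list with `coords` (samples x k), `explained` (variance
#'   fractions, non-increasing), `loadings` (sets x k); class
#'   `sigrev_embedding`.
#' @export
pca_embed <- function(rank_matrix, k = 3) {
  stopifnot(is.matrix(rank_matrix), k >= 1)
  x <- t(rank_matrix)                       # samples x sets
  xc <- scale(x, center = TRUE, scale = FALSE)
  sv <- svd(xc)
  tol <- max(dim(xc)) * max(sv$d) * .Machine$double.eps
  r <- sum(sv$d > tol)
  if (k > r)
    stop("k = ", k, " exceeds the rank of the centered matrix (", r, ")")
  flip <- vapply(seq_len(k), function(i) {
    j <- which.max(abs(sv$v[, i]))
    if (sv$v[j, i] < 0) -1 else 1
  }, numeric(1))
  coords <- sweep(sv$u[, seq_len(k), drop = FALSE] %*%
                    diag(sv$d[seq_len(k)], k), 2L, flip, "*")
  rownames(coords) <- colnames(rank_matrix)
  colnames(coords) <- paste0("PC", seq_len(k))
  loadings <- sweep(sv$v[, seq_len(k), drop = FALSE], 2L, flip, "*")
  rownames(loadings) <- rownames(rank_matrix)
  colnames(loadings) <- paste0("PC", seq_len(k))
  structure(list(coords = coords,
                 explained = (sv$d^2 / sum(sv$d^2))[seq_len(k)],
                 loadings = loadings),
            class = "sigrev_embedding")
}

#' Intersect two gene-set collections
#'
#' Keeps sets whose names occur in both collections and restricts their
#' membership to the shared gene universe (genes occurring in both
#' collections). Sets that become empty are dropped. Warns when the
#' intersection is empty.
#'
#' @param a,b `gene_set_collection` objects.
#' @return a `gene_set_collection`.
#' @export
intersect_collections <- function(a, b) {
  stopifnot(inherits(a, "gene_set_collection"),
            inherits(b, "gene_set_collection"))
  common <- intersect(names(a), names(b))
  universe <- intersect(unique(unlist(a, use.names = FALSE)),
                        unique(unlist(b, use.names = FALSE)))
  sets <- lapply(a[common], intersect, universe)
  sets <- sets[lengths(sets) > 0L]
  if (length(sets) == 0L) {
    warning("collection intersection is empty")
    return(gene_set_collection(list()))
  }
  gene_set_collection(sets)
}
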