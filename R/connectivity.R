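# Connectivity-map style drug screening: score each drug perturbation
# profile for reversal of a disease signature by the two-set KS
# connectivity statistic (Lamb convention) and by the genome-wide weighted
# Spearman (GWC) statistic, attach permutation p-values, rank drugs and
# flag hits. Negative scores mean the drug's transcriptional effect
# opposes the disease signature -- the repurposing signal.

#' Translate gene identifiers through an ortholog map
#'
#' Maps the gene ids of a differential result, named statistic vector or
#' perturbation library into a target namespace (e.g. mouse -> human).
#' Genes without a mapping are dropped with a message stating the count.
#' Many-to-many mappings are resolved deterministically: when several
#' source genes map to the same target, the pair whose source carries the
#' largest absolute statistic wins; when one source maps to several
#' targets, the lexicographically smallest target is kept.
#'
#' @param x a `sigrev_de` data frame, a named numeric vector, or a
#'   `perturbation_library`.
#' @param map data frame with columns `source`, `target`.
#' @return object of the same shape on the mapped universe.
#' @export
map_orthologs <- function(x, map) UseMethod("map_orthologs")

resolve_map <- function(genes, stat, map) {
  if (nrow(map) == 0L) stop("ortholog map is empty")
  m <- map[map$source %in% genes, c("source", "target"), drop = FALSE]
  m <- m[!duplicated(m), , drop = FALSE]
  # one source -> many targets: keep lexicographically smallest target
  m <- m[order(m$source, m$target, method = "radix"), , drop = FALSE]
  m <- m[!duplicated(m$source), , drop = FALSE]
  # many sources -> one target: keep the source with largest |statistic|
  s <- abs(stat[m$source])
  m <- m[order(m$target, -s, m$source, method = "radix"), , drop = FALSE]
  m <- m[!duplicated(m$target), , drop = FALSE]
  dropped <- length(genes) - nrow(m)
  if (dropped > 0L)
    message(dropped, " gene(s) without an ortholog mapping dropped")
  if (nrow(m) < 0.5 * length(genes))
    stop("fewer than 50% of genes mappable (", nrow(m), " of ",
         length(genes), ")")
  m
}

#' @export
map_orthologs.sigrev_de <- function(x, map) {
  m <- resolve_map(x$gene, stats::setNames(x$t, x$gene), map)
  out <- x[match(m$source, x$gene), , drop = FALSE]
  out$gene <- m$target
  out <- out[order(out$gene, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "d0") <- attr(x, "d0")
  attr(out, "s0_2") <- attr(x, "s0_2")
  class(out) <- class(x)
  out
}

#' @export
map_orthologs.numeric <- function(x, map) {
  m <- resolve_map(names(x), x, map)
  stats::setNames(unname(x[m$source]), m$target)
}

#' @export
map_orthologs.perturbation_library <- function(x, map) {
  # library statistics differ per drug; resolve collisions by the mean
  # absolute statistic across drugs
  m <- resolve_map(x$genes, stats::setNames(rowMeans(abs(x$stat)), x$genes),
                   map)
  stat <- x$stat[m$source, , drop = FALSE]
  p <- x$p[m$source, , drop = FALSE]
  rownames(stat) <- rownames(p) <- m$target
  ord <- order(m$target, method = "radix")
  perturbation_library(stat[ord, , drop = FALSE], p[ord, , drop = FALSE])
}

#' Two-set KS connectivity score of a drug against a disease signature
#'
#' The drug's genes are ranked by its statistic (descending); the
#' unweighted KS enrichment score is computed for the signature's up set
#' (`ES_up`) and down set (`ES_down`). Following the classical
#' connectivity-map convention the score is `(ES_up - ES_down) / 2` when
#' the two enrichment scores have opposite signs and 0 otherwise. A
#' perfect mimic scores +1; a perfect reverser scores -1.
#'
#' @param sig a `disease_signature`.
#' @param stat named numeric vector: the drug's per-gene statistic.
#' @param p weight exponent of the inner running statistic (default 0,
#'   the classical unweighted KS; weighting exposed as a switch).
#' @return score in `[-1, 1]`.
#' @export
ks_connectivity <- function(sig, stat, p = 0) {
  stopifnot(inherits(sig, "disease_signature"), is.numeric(stat),
            !is.null(names(stat)))
  up <- intersect(names(sig$up), names(stat))
  dn <- intersect(names(sig$down), names(stat))
  if (length(up) == 0L) stop("up set does not intersect the profile universe")
  if (length(dn) == 0L) stop("down set does not intersect the profile universe")
  es_up <- preranked_es(stat, up, p = p)
  es_dn <- preranked_es(stat, dn, p = p)
  if (sign(es_up) != sign(es_dn)) (es_up - es_dn) / 2 else 0
}

# Weighted Pearson correlation (weights w >= 0, not all zero).
weighted_pearson <- function(x, y, w) {
  sw <- sum(w)
  mx <- sum(w * x) / sw
  my <- sum(w * y) / sw
  cxy <- sum(w * (x - mx) * (y - my))
  cxx <- sum(w * (x - mx)^2)
  cyy <- sum(w * (y - my)^2)
  if (cxx <= 0 || cyy <= 0) stop("zero weighted variance")
  min(1, max(-1, cxy / sqrt(cxx * cyy)))
}

#' Genome-wide connectivity (GWC): weighted Spearman correlation
#'
#' Correlates the ranks of the disease and drug statistics over their
#' shared universe, weighting each gene by the arithmetic mean of the two
#' sides' `-log10` p-values (rescaled to mean 1). With all p-values equal
#' the score reduces exactly to classical Spearman rank correlation.
#'
#' @param disease_stat,disease_p named numeric vectors: per-gene disease
#'   statistic and p-value.
#' @param drug_stat,drug_p same for the drug profile.
#' @return weighted rank correlation in `[-1, 1]`.
#' @export
gwc_score <- function(disease_stat, disease_p, drug_stat, drug_p) {
  stopifnot(!is.null(names(disease_stat)), !is.null(names(drug_stat)))
  genes <- intersect(names(disease_stat), names(drug_stat))
  if (length(genes) < 10L)
    stop("shared universe has fewer than 10 genes")
  dp <- pmax(disease_p[genes], .Machine$double.xmin)
  gp <- pmax(drug_p[genes], .Machine$double.xmin)
  w <- (-log10(dp) - log10(gp)) / 2
  if (sum(w) <= 0) stop("zero total weight (all p-values are 1)")
  w <- w / mean(w)
  weighted_pearson(avg_rank(disease_stat[genes]),
                   avg_rank(drug_stat[genes]), w)
}

#' Permutation p-value of a connectivity score
#'
#' Permutes the gene labels of the drug profile (statistics and p-values
#' jointly), recomputes the score, and reports the two-sided smoothed
#' p-value `(1 + #\{|score_perm| >= |score_obs|\}) / (n_perm + 1)`, whose
#' minimum is `1/(n_perm + 1)`.
#'
#' @param score_fn function of `(stat, p)` returning a scalar score -- the
#'   observed score is `score_fn(stat, p)` and each permutation scrambles
#'   the gene labels of both vectors jointly.
#' @param stat named per-gene drug statistic.
#' @param p named per-gene drug p-values (same genes).
#' @param n_perm number of permutations (>= 100; default 1000).
#' @param seed integer seed.
#' @return list with `p` (the permutation p-value), `observed` and
#'   `null` (the permuted scores).
#' @export
permutation_p <- function(score_fn, stat, p, n_perm = 1000, seed = NULL) {
  stopifnot(is.function(score_fn), n_perm >= 100,
            !is.null(names(stat)))
  obs <- score_fn(stat, p)
  genes <- names(stat)
  with_seed(seed, {
    null <- vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(length(genes))
      ps <- stats::setNames(unname(stat)[idx], genes)
      pp <- stats::setNames(unname(p)[idx], genes)
      score_fn(ps, pp)
    }, numeric(1))
    list(p = (1 + sum(abs(null) >= abs(obs))) / (n_perm + 1),
         observed = obs, null = null)
  })
}

# Fast null for the unweighted two-set KS score: the null distribution
# depends only on (N, |up|, |down|), not on the profile, so one ensemble
# per signature size serves every drug in a screen.
ks_null_scores <- function(N, k_up, k_dn, n_perm) {
  vapply(seq_len(n_perm), function(i) {
    pos <- sample.int(N, k_up + k_dn)
    eu <- es_from_positions(sort(pos[seq_len(k_up)]), rep(1, k_up), N)
    ed <- es_from_positions(sort(pos[k_up + seq_len(k_dn)]), rep(1, k_dn), N)
    if (sign(eu) != sign(ed)) (eu - ed) / 2 else 0
  }, numeric(1))
}

# Vectorized GWC permutation p-value for one drug: permutes the drug's
# (rank, weight) jointly against the fixed disease side.
gwc_perm_p <- function(x_rank, w_dis, y_rank, w_drug, obs, n_perm) {
  n <- length(x_rank)
  null <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(n)
    w <- (w_dis + w_drug[idx]) / 2
    weighted_pearson(x_rank, y_rank[idx], w)
  }, numeric(1))
  (1 + sum(abs(null) >= abs(obs))) / (n_perm + 1)
}

#' Screen a perturbation library against a differential result
#'
#' For each signature size, builds the balanced disease signature from
#' `de`, scores every drug by the two-set KS statistic, ranks drugs
#' ascending (most negative, i.e. strongest reverser, first) and flags
#' hits where both the KS and the GWC score fall below `cutoff`. The GWC
#' score is genome-wide over the harmonized universe and therefore shared
#' across sizes. Permutation p-values (when `n_perm > 0`) use one shared
#' null ensemble per size for KS (the unweighted null is
#' profile-independent) and per-drug permutations for GWC.
#'
#' @param library a `perturbation_library`.
#' @param de a `sigrev_de` differential result (query side).
#' @param sizes signature sizes to screen (default `c(100, 200, 300,
#'   500)`).
#' @param cutoff hit threshold on both scores (default -0.5).
#' @param n_perm permutations for p-values; 0 skips p-values (ranking
#'   only).
#' @param fdr_threshold FDR cutoff for signature membership.
#' @param seed integer seed.
#' @return a `connectivity_screen` list: `records` (long data frame:
#'   `drug`, `size`, `ks_score`, `p_ks`, `gwc_score`, `p_gwc`, `rank_ks`,
#'   `rank_gwc`, `hit`), `ks_matrix` (drugs x sizes, the heatmap input),
#'   `gwc` (named per-drug vector), and `consensus` (per drug, number of
#'   sizes at which it is a hit and whether it is a hit at every scored
#'   size).
#' @export
connectivity_screen <- function(library, de, sizes = c(100, 200, 300, 500),
                                cutoff = -0.5, n_perm = 1000,
                                fdr_threshold = 0.01, seed = NULL) {
  stopifnot(inherits(library, "perturbation_library"),
            inherits(de, "sigrev_de"))
  genes <- intersect(de$gene, library$genes)
  if (length(genes) < 10L)
    stop("harmonized universe has fewer than 10 genes")
  de_u <- de[match(genes, de$gene), , drop = FALSE]
  stat <- library$stat[genes, , drop = FALSE]
  pmat <- library$p[genes, , drop = FALSE]
  drugs <- library$drugs
  nd <- length(drugs)
  with_seed(seed, {
    # genome-wide GWC once per drug
    x_rank <- avg_rank(de_u$t)
    w_dis <- -log10(pmax(de_u$p, .Machine$double.xmin))
    flat <- apply(stat, 2L, function(v) length(unique(v)) == 1L)
    if (any(flat))
      message(sum(flat), " drug profile(s) with zero spread score ",
              "GWC = 0 (no rank information)")
    gwc <- vapply(seq_len(nd), function(j) {
      if (flat[j]) return(0)
      w <- (w_dis - log10(pmax(pmat[, j], .Machine$double.xmin))) / 2
      weighted_pearson(x_rank, avg_rank(stat[, j]), w)
    }, numeric(1))
    names(gwc) <- drugs
    p_gwc <- rep(NA_real_, nd)
    if (n_perm > 0) {
      p_gwc <- vapply(seq_len(nd), function(j) {
        if (flat[j]) return(1)
        w_drug <- -log10(pmax(pmat[, j], .Machine$double.xmin))
        gwc_perm_p(x_rank, w_dis, avg_rank(stat[, j]), w_drug,
                   gwc[j], n_perm)
      }, numeric(1))
    }
    rank_gwc <- avg_rank(gwc)   # ascending: most negative first

    records <- list()
    ks_matrix <- matrix(NA_real_, nd, 0, dimnames = list(drugs, NULL))
    for (size in sizes) {
      sig <- tryCatch(build_signature(de_u, size, fdr_threshold),
                      error = function(e) {
                        warning("size ", size, " skipped: ",
                                conditionMessage(e))
                        NULL
                      })
      if (is.null(sig)) next
      ks <- vapply(seq_len(nd), function(j) {
        v <- stat[, j]
        names(v) <- genes
        ks_connectivity(sig, v)
      }, numeric(1))
      names(ks) <- drugs
      p_ks <- rep(NA_real_, nd)
      if (n_perm > 0) {
        null <- ks_null_scores(length(genes), length(sig$up),
                               length(sig$down), n_perm)
        p_ks <- vapply(ks, function(s)
          (1 + sum(abs(null) >= abs(s))) / (n_perm + 1), numeric(1))
      }
      ord_ks <- order(ks, drugs, method = "radix")
      rank_ks <- integer(nd)
      rank_ks[ord_ks] <- seq_len(nd)
      records[[as.character(size)]] <- data.frame(
        drug = drugs, size = size, ks_score = unname(ks), p_ks = p_ks,
        gwc_score = unname(gwc), p_gwc = p_gwc, rank_ks = rank_ks,
        rank_gwc = unname(rank_gwc),
        hit = unname(ks < cutoff & gwc < cutoff))
      ks_matrix <- cbind(ks_matrix, ks)
      colnames(ks_matrix)[ncol(ks_matrix)] <- paste0("size_", size)
    }
    if (length(records) == 0L) stop("no signature size could be built")
    rec <- do.call(rbind, records)
    rownames(rec) <- NULL
    n_hit <- tapply(rec$hit, rec$drug, sum)
    consensus <- data.frame(drug = names(n_hit),
                            n_sizes_hit = as.integer(n_hit),
                            consensus_hit = as.integer(n_hit) ==
                              length(unique(rec$size)),
                            row.names = NULL)
    structure(list(records = rec, ks_matrix = ks_matrix, gwc = gwc,
                   consensus = consensus, cutoff = cutoff,
                   sizes = unique(rec$size), seed = seed),
              class = "connectivity_screen")
  })
}

#' @export
print.connectivity_screen <- function(x, ...) {
  cat("connectivity_screen:", length(x$gwc), "drugs, sizes",
      paste(x$sizes, collapse = "/"), "; cutoff", x$cutoff, ";",
      sum(x$consensus$consensus_hit), "consensus hit(s)\n")
  invisible(x)
}

#' Write screen results
#'
#' `write_screen_results` emits the long records table as CSV;
#' `write_score_matrix` emits the drugs x sizes KS score matrix (heatmap
#' input) as CSV.
#'
#' @param screen a `connectivity_screen`.
#' @param path output path.
#' @export
write_screen_results <- function(screen, path) {
  stopifnot(inherits(screen, "connectivity_screen"))
  write_with_header(screen$records, path, "screen_results",
                    seed = screen$seed, sep = ",")
}

#' @rdname write_screen_results
#' @export
write_score_matrix <- function(screen, path) {
  stopifnot(inherits(screen, "connectivity_screen"))
  df <- data.frame(drug = rownames(screen$ks_matrix), screen$ks_matrix,
                   gwc = unname(screen$gwc[rownames(screen$ks_matrix)]),
                   check.names = FALSE)
  write_with_header(df, path, "score_matrix", seed = screen$seed, sep = ",")
}
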