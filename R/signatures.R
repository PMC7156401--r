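# Two-group differential expression with empirical-Bayes variance
# moderation, BH-FDR, balanced signature extraction and classifier gene
# lists. The moderation follows the classical hierarchical model for gene
# variances: s2_g | sigma2_g ~ sigma2_g * chisq(df)/df with a scaled
# inverse-chisquare prior sigma2_g ~ d0 * s0^2 / chisq(d0); the posterior
# variance shrinks each gene's s2 toward the ensemble prior s0^2.

#' Fit per-gene two-group linear models
#'
#' Ordinary least squares per gene for a two-group contrast: mean
#' difference A - B, pooled residual variance and residual degrees of
#' freedom `nA + nB - 2`.
#'
#' @param expr numeric gene x sample matrix of log2 values.
#' @param groups named vector mapping sample id -> group label.
#' @param contrast character pair `c(A, B)`: the reported log fold change
#'   is mean(A) - mean(B).
#' @return a `sigrev_de_fit` data frame: `gene`, `logFC`, `s2`, `df`, plus
#'   the unscaled standard error `sqrt(1/nA + 1/nB)` as an attribute.
#' @export
#' @examples
#' sim <- simulate_expression(100, 4, 10, 2, 0.5, seed = 1)
#' fit <- fit_linear_de(sim$expr, sim$groups, c("tumor", "normal"))
fit_linear_de <- function(expr, groups, contrast = c("tumor", "normal")) {
  check_expression(expr, groups)
  stopifnot(length(contrast) == 2L)
  groups <- groups[colnames(expr)]
  for (g in contrast)
    if (sum(groups == g) < 2L)
      stop("group '", g, "' needs at least 2 samples")
  a <- expr[, groups == contrast[1L], drop = FALSE]
  b <- expr[, groups == contrast[2L], drop = FALSE]
  nA <- ncol(a); nB <- ncol(b)
  df <- nA + nB - 2L
  s2 <- ((nA - 1L) * row_var(a) + (nB - 1L) * row_var(b)) / df
  out <- data.frame(gene = rownames(expr),
                    logFC = rowMeans(a) - rowMeans(b),
                    s2 = s2, df = df, row.names = NULL)
  attr(out, "stdev_unscaled") <- sqrt(1 / nA + 1 / nB)
  attr(out, "contrast") <- contrast
  class(out) <- c("sigrev_de_fit", "data.frame")
  out
}

#' Empirical-Bayes moderation of per-gene variances
#'
#' Estimates the prior degrees of freedom `d0` and prior variance `s0^2` by
#' closed-form moment matching on `log(s2)`: with constant residual df `d`,
#' `E[log s2] = log s0^2 + digamma(d/2) - log(d/2) - digamma(d0/2) +
#' log(d0/2)` and `Var[log s2] = trigamma(d/2) + trigamma(d0/2)`. The
#' trigamma equation is inverted by Newton iteration (tolerance 1e-8).
#' Posterior variances are `(d0 s0^2 + d s2) / (d0 + d)`; moderated t uses
#' them with `df + d0` total degrees of freedom, and q-values are BH.
#'
#' When the observed spread of `log(s2)` is no larger than the sampling
#' variance `trigamma(d/2)`, `d0` is infinite, `s0^2` is the arithmetic
#' mean of the sample variances, and every posterior variance equals
#' `s0^2` (so an equal-variance ensemble makes moderation an exact no-op
#' on t, with only the degrees of freedom changing). Zero sample
#' variances are offset to `1e-5` times the median variance for the
#' hyperparameter fit; when all variances are zero the fallback is
#' `d0 = Inf`, `s0^2 = 0`.
#'
#' @param fit a `sigrev_de_fit` from [fit_linear_de()] (>= 10 genes).
#' @param d0 optional override of the prior degrees of freedom (`Inf`
#'   allowed); `NULL` (default) estimates it from the ensemble.
#' @return a `sigrev_de` data frame: `gene`, `logFC`, `t`, `p`, `q`, `B`
#'   (log-odds, not computed: `NA`), `s2`, `s2_post`, `df_total`;
#'   attributes `d0`, `s0_2`.
#' @export
ebayes_moderate <- function(fit, d0 = NULL) {
  stopifnot(inherits(fit, "sigrev_de_fit"))
  if (nrow(fit) < 10L)
    stop("empirical-Bayes moderation needs >= 10 genes")
  d <- fit$df[1L]
  s2 <- fit$s2
  if (!is.null(d0) && d0 < 0) stop("d0 must be non-negative (Inf allowed)")
  if (all(s2 == 0)) {
    # degenerate ensemble: all residual variances zero
    if (is.null(d0)) d0 <- Inf
    s0_2 <- 0
  } else {
    med <- stats::median(s2)
    if (med == 0) {
      warning("more than half of the sample variances are zero; ",
              "moderation unreliable")
      med <- 1
    }
    x <- pmax(s2, 1e-5 * med)   # offset exact zeros for the log moments
    z <- log(x)
    if (is.null(d0)) {
      excess <- stats::var(z) - trigamma(d / 2)
      d0 <- if (is.na(excess) || excess <= 0) Inf
            else 2 * trigamma_inverse(excess)
    }
    s0_2 <- if (is.finite(d0) && d0 > 0)
      exp(mean(z) - digamma(d / 2) + log(d / 2) +
            digamma(d0 / 2) - log(d0 / 2))
    else if (is.finite(d0))   # d0 = 0: moderation off, prior unused
      NA_real_
    else
      mean(x)                 # d0 infinite: plain mean of the variances
  }
  s2_post <- if (!is.finite(d0)) rep(s0_2, length(s2))
             else if (d0 == 0) s2
             else (d0 * s0_2 + d * s2) / (d0 + d)
  se <- sqrt(s2_post) * attr(fit, "stdev_unscaled")
  t <- ifelse(se > 0, fit$logFC / se,
              sign(fit$logFC) * Inf)
  t[se == 0 & fit$logFC == 0] <- 0
  # total df capped at the pooled residual df of the whole ensemble
  df_total <- min(d + d0, d * nrow(fit))
  p <- 2 * stats::pt(-abs(t), df = df_total)
  out <- data.frame(gene = fit$gene, logFC = fit$logFC, t = t, p = p,
                    q = bh_adjust(p), B = NA_real_, s2 = s2,
                    s2_post = s2_post, df_total = df_total,
                    row.names = NULL)
  attr(out, "d0") <- d0
  attr(out, "s0_2") <- s0_2
  attr(out, "contrast") <- attr(fit, "contrast")
  class(out) <- c("sigrev_de", "data.frame")
  out
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Thin, validated wrapper over `stats::p.adjust(method = "BH")`.
#'
#' @param p numeric vector of p-values in `[0, 1]`; `NaN` rejected.
#' @return q-values, same order as input.
#' @export
bh_adjust <- function(p) {
  if (any(is.nan(p))) stop("NaN p-values are not allowed")
  if (any(is.na(p))) stop("missing p-values are not allowed")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Extract a balanced disease signature at a fixed size
#'
#' Takes the `size/2` most positive and `size/2` most negative genes by
#' moderated t among those with `q < fdr_threshold` (strict). Ties in t are
#' broken lexicographically by gene id for determinism. Errors (rather than
#' returning an undersized signature) when either direction lacks enough
#' significant genes, reporting the attainable maximum.
#'
#' @param de a `sigrev_de` from [ebayes_moderate()].
#' @param size total signature size (even; typically 100, 200, 300 or 500).
#' @param fdr_threshold strict BH-FDR cutoff for membership (default 0.01).
#' @return a `disease_signature`: ordered named weight vectors `up`
#'   (t descending) and `down` (t ascending).
#' @export
build_signature <- function(de, size, fdr_threshold = 0.01) {
  stopifnot(inherits(de, "sigrev_de"), size >= 2, size %% 2 == 0)
  half <- size / 2L
  sig_up <- de[de$q < fdr_threshold & de$t > 0, , drop = FALSE]
  sig_dn <- de[de$q < fdr_threshold & de$t < 0, , drop = FALSE]
  if (nrow(sig_up) < half || nrow(sig_dn) < half)
    stop("insufficient significant genes for size ", size, ": ",
         nrow(sig_up), " up and ", nrow(sig_dn), " down pass FDR < ",
         fdr_threshold, " (attainable balanced maximum ",
         2L * min(nrow(sig_up), nrow(sig_dn)), ")")
  up <- sig_up[order_desc_by_stat(sig_up$t, sig_up$gene), ][seq_len(half), ]
  dn <- sig_dn[order(sig_dn$t, sig_dn$gene, method = "radix"), ][seq_len(half), ]
  new_signature(stats::setNames(up$t, up$gene),
                stats::setNames(dn$t, dn$gene),
                fdr_threshold = fdr_threshold)
}

#' Build a discriminating classifier gene list between two groups
#'
#' Selects the top `n_genes` by absolute moderated t and records each
#' gene's direction (`up-in-A` / `up-in-B` for contrast `c(A, B)`).
#' Balanced selection is deliberately not enforced. A warning is emitted
#' when the weakest selected gene has `|t| < 2` (degenerate separation).
#'
#' @param expr gene x sample matrix.
#' @param groups named sample -> group vector (exactly two groups used).
#' @param n_genes classifier size (e.g. 75 or 95).
#' @param contrast the two group labels `c(A, B)`.
#' @return a `classifier_genes` data frame: `gene`, `t`, `direction`.
#' @export
build_classifier <- function(expr, groups, n_genes,
                             contrast = sort(unique(unname(groups)))) {
  stopifnot(length(contrast) == 2L)
  de <- ebayes_moderate(fit_linear_de(expr, groups, contrast))
  if (n_genes > nrow(de))
    stop("n_genes (", n_genes, ") exceeds available genes (", nrow(de), ")")
  ord <- order(-abs(de$t), de$gene, method = "radix")
  sel <- de[ord[seq_len(n_genes)], , drop = FALSE]
  if (min(abs(sel$t)) < 2)
    warning("weak separation: selected genes include |t| < 2")
  out <- data.frame(gene = sel$gene, t = sel$t,
                    direction = ifelse(sel$t > 0, "up-in-A", "up-in-B"),
                    row.names = NULL)
  attr(out, "contrast") <- contrast
  class(out) <- c("classifier_genes", "data.frame")
  out
}

#' Project a classifier gene list onto new samples
#'
#' Expression of each classifier gene is z-scored across samples; a
#' sample's score is the mean z of up-in-A genes minus the mean z of
#' up-in-B genes, and the nearest-centroid call follows the score sign
#' (positive -> A). Scores are invariant to per-gene affine rescaling of
#' the expression values. Genes with zero spread across samples are
#' dropped with a message.
#'
#' @param expr gene x sample matrix to classify.
#' @param classifier a `classifier_genes` list.
#' @return data frame `sample`, `score`, `call`.
#' @export
project_classifier <- function(expr, classifier) {
  stopifnot(inherits(classifier, "classifier_genes"))
  check_expression(expr)
  present <- classifier$gene %in% rownames(expr)
  if (mean(present) < 0.5)
    stop("only ", sum(present), " of ", length(present),
         " classifier genes present in expression matrix (< 50%)")
  cls <- classifier[present, , drop = FALSE]
  x <- expr[cls$gene, , drop = FALSE]
  sd <- apply(x, 1L, stats::sd)
  if (any(sd == 0)) {
    message("dropping ", sum(sd == 0), " zero-variance classifier gene(s)")
    x <- x[sd > 0, , drop = FALSE]
    cls <- cls[sd > 0, , drop = FALSE]
  }
  if (nrow(x) == 0L) stop("no classifier genes with variance remain")
  z <- (x - rowMeans(x)) / apply(x, 1L, stats::sd)
  up_a <- cls$direction == "up-in-A"
  score_a <- if (any(up_a)) colMeans(z[up_a, , drop = FALSE]) else 0
  score_b <- if (any(!up_a)) colMeans(z[!up_a, , drop = FALSE]) else 0
  score <- score_a - score_b
  contrast <- attr(classifier, "contrast")
  data.frame(sample = colnames(expr), score = unname(score),
             call = ifelse(score >= 0, contrast[1L], contrast[2L]),
             row.names = NULL)
}
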