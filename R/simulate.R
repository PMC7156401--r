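# Synthetic-data generators with planted ground truth. These emulate the
# statistical structure of the real inputs -- two-group microarray-like
# log2 intensity data with differential genes, a CMAP-style perturbation
# library containing planted signature reversers, coherent gene sets, and
# median-effect dose-response curves -- so every downstream stage can be
# validated against a known answer without external data.

#' Simulate two-group log2 expression data with planted differential genes
#'
#' Gene baselines are drawn from N(8, 1.5^2) log2 units (typical microarray
#' dynamic range); within-group noise is iid Gaussian with sd `sigma`.
#' `n_de` genes are shifted by +/- `effect` in the tumor group, half up and
#' half down; when `n_de` is odd the extra gene goes to the up set.
#'
#' @param n_genes number of genes.
#' @param n_per_group samples per group (>= 2); groups are labelled
#'   `"tumor"` and `"normal"`.
#' @param n_de number of planted differential genes (<= `n_genes`).
#' @param effect absolute log2 shift of planted genes in the tumor group.
#' @param sigma within-group noise sd, log2 units.
#' @param seed integer seed; identical seeds reproduce the matrix exactly.
#' @param baseline_mean,baseline_sd parameters of the baseline-mean
#'   distribution (defaults 8 and 1.5 log2 units).
#' @return list with `expr` (gene x sample matrix), `groups` (named
#'   vector), and `truth` (a `sigrev_truth` whose `de_genes` records gene,
#'   sign and effect size).
#' @export
#' @examples
#' sim <- simulate_expression(200, 4, 20, effect = 2, sigma = 0.5, seed = 1)
#' dim(sim$expr)
simulate_expression <- function(n_genes, n_per_group, n_de, effect, sigma,
                                seed = NULL, baseline_mean = 8,
                                baseline_sd = 1.5) {
  stopifnot(n_genes >= 1, n_per_group >= 2, n_de >= 0, n_de <= n_genes,
            effect >= 0, sigma > 0)
  with_seed(seed, {
    genes <- sprintf("gene_%05d", seq_len(n_genes))
    samples <- c(sprintf("tumor_%02d", seq_len(n_per_group)),
                 sprintf("normal_%02d", seq_len(n_per_group)))
    groups <- stats::setNames(rep(c("tumor", "normal"), each = n_per_group),
                              samples)
    base <- stats::rnorm(n_genes, baseline_mean, baseline_sd)
    expr <- matrix(stats::rnorm(n_genes * 2L * n_per_group, 0, sigma),
                   n_genes, 2L * n_per_group,
                   dimnames = list(genes, samples)) + base
    de_genes <- data.frame(gene = character(), sign = integer(),
                           effect = numeric())
    if (n_de > 0L) {
      idx <- sample.int(n_genes, n_de)
      n_up <- ceiling(n_de / 2)          # odd n_de: extra gene is up
      sgn <- rep(c(1L, -1L), c(n_up, n_de - n_up))
      expr[idx, groups == "tumor"] <-
        expr[idx, groups == "tumor"] + sgn * effect
      de_genes <- data.frame(gene = genes[idx], sign = sgn, effect = effect)
      de_genes <- de_genes[order(de_genes$gene), , drop = FALSE]
      rownames(de_genes) <- NULL
    }
    truth <- structure(list(de_genes = de_genes), class = "sigrev_truth")
    list(expr = expr, groups = groups, truth = truth)
  })
}

#' Simulate a drug perturbation library with planted reversers
#'
#' Reverser drugs have profiles `-rho * disease_t + noise`; null drugs are
#' pure noise with sd `noise_sd`. Per-gene p-values are derived from the
#' normal z-scores of each drug's own profile (the GWC statistic needs
#' drug-side significance weights). The gene universe equals the disease
#' universe.
#'
#' @param disease_t named numeric vector of per-gene signed disease
#'   statistics (e.g. moderated t).
#' @param n_drugs library size.
#' @param n_reversers number of planted reversers (<= `n_drugs`).
#' @param rho reversal strength in `[0, 1]`.
#' @param noise_sd noise sd in statistic units.
#' @param seed integer seed.
#' @return list with `library` (a `perturbation_library`) and `truth`
#'   (`reverser_drugs`: named vector drug -> rho).
#' @export
simulate_perturbation_library <- function(disease_t, n_drugs, n_reversers,
                                          rho, noise_sd, seed = NULL) {
  if (length(disease_t) == 0L) stop("disease statistic is empty")
  stopifnot(!is.null(names(disease_t)), n_drugs >= 1,
            n_reversers >= 0, n_reversers <= n_drugs,
            rho >= 0, rho <= 1, noise_sd >= 0)
  with_seed(seed, {
    genes <- names(disease_t)
    drugs <- sprintf("drug_%04d", seq_len(n_drugs))
    rev_idx <- if (n_reversers > 0L) sort(sample.int(n_drugs, n_reversers))
               else integer()
    stat <- matrix(stats::rnorm(length(genes) * n_drugs, 0, noise_sd),
                   length(genes), n_drugs, dimnames = list(genes, drugs))
    if (length(rev_idx))
      stat[, rev_idx] <- stat[, rev_idx] - rho * disease_t
    # p from z-scores of each profile; guard a degenerate zero-spread column
    mu <- colMeans(stat)
    sd <- apply(stat, 2L, stats::sd)
    sd[!is.finite(sd) | sd == 0] <- 1
    z <- sweep(sweep(stat, 2L, mu), 2L, sd, "/")
    p <- 2 * stats::pnorm(-abs(z))
    truth <- structure(
      list(reverser_drugs = stats::setNames(rep(rho, length(rev_idx)),
                                            drugs[rev_idx])),
      class = "sigrev_truth")
    list(library = perturbation_library(stat, p), truth = truth)
  })
}

#' Simulate gene-set collections with optional planted coherent sets
#'
#' Random sets are drawn uniformly from the universe. Coherent sets draw
#' most (80%) of their members from the supplied planted up- or
#' down-regulated genes, alternating direction, so they respond to the
#' disease contrast; their composition is recorded in the `coherent`
#' attribute.
#'
#' @param n_sets number of random (background) sets.
#' @param size_range integer vector `c(min, max)` of set sizes;
#'   `max <= length(universe)`.
#' @param universe character vector of gene ids.
#' @param n_coherent number of additional coherent sets.
#' @param up_genes,down_genes planted DE genes used to build coherent sets
#'   (required when `n_coherent > 0`).
#' @param seed integer seed.
#' @return a `gene_set_collection`; coherent sets are named
#'   `coherent_up_*` / `coherent_down_*` and described in
#'   `attr(, "coherent")`.
#' @export
simulate_gene_sets <- function(n_sets, size_range, universe, n_coherent = 0L,
                               up_genes = NULL, down_genes = NULL,
                               seed = NULL) {
  stopifnot(n_sets >= 0, length(size_range) == 2L, n_coherent >= 0)
  if (size_range[1L] > size_range[2L])
    stop("size_range is inverted: min > max")
  if (size_range[2L] > length(universe))
    stop("max set size exceeds universe size")
  if (n_coherent > 0L && is.null(up_genes) && is.null(down_genes))
    stop("coherent sets need up_genes and/or down_genes")
  with_seed(seed, {
    sets <- list()
    for (i in seq_len(n_sets)) {
      k <- sample(seq(size_range[1L], size_range[2L]), 1L)
      sets[[sprintf("random_set_%03d", i)]] <- sort(sample(universe, k))
    }
    coherent <- list()
    for (i in seq_len(n_coherent)) {
      dir_up <- if (is.null(down_genes)) TRUE
                else if (is.null(up_genes)) FALSE
                else i %% 2L == 1L
      pool <- if (dir_up) up_genes else down_genes
      k <- sample(seq(size_range[1L], size_range[2L]), 1L)
      n_sig <- min(length(pool), max(1L, round(0.8 * k)))
      members <- sample(pool, n_sig)
      rest <- setdiff(universe, members)
      if (k - n_sig > 0L) members <- c(members, sample(rest, k - n_sig))
      nm <- sprintf("coherent_%s_%03d", if (dir_up) "up" else "down", i)
      sets[[nm]] <- sort(members)
      coherent[[nm]] <- list(direction = if (dir_up) "up" else "down",
                             n_planted = n_sig, size = k)
    }
    out <- gene_set_collection(sets)
    attr(out, "coherent") <- coherent
    out
  })
}

# Median-effect fraction affected at dose D for parameters (Dm, m).
median_effect_fa <- function(D, Dm, m) {
  r <- (D / Dm)^m
  r / (1 + r)
}

#' Simulate a single-drug median-effect dose-response curve
#'
#' Fraction affected follows the median-effect equation
#' `fa = (D/Dm)^m / (1 + (D/Dm)^m)` plus Gaussian noise, then clipped into
#' (1e-4, 1 - 1e-4) so the logit stays finite.
#'
#' @param Dm median-effect dose (IC50), same concentration units as
#'   `doses`; must be > 0.
#' @param m unitless slope (> 0).
#' @param doses vector of positive doses.
#' @param noise_sd sd of additive noise on the fraction-affected scale.
#' @param seed integer seed.
#' @param drug drug id recorded in the table.
#' @return a dose-response data frame (`drug_a`, `dose_a`, `drug_b`,
#'   `dose_b`, `fa`) with the generating `(Dm, m)` in
#'   `attr(, "truth")$doseresp_params`.
#' @export
simulate_dose_response <- function(Dm, m, doses, noise_sd = 0, seed = NULL,
                                   drug = "drug_A") {
  stopifnot(Dm > 0, m > 0, noise_sd >= 0)
  if (any(doses <= 0)) stop("all doses must be positive")
  with_seed(seed, {
    fa <- median_effect_fa(doses, Dm, m) +
      stats::rnorm(length(doses), 0, noise_sd)
    tab <- data.frame(drug_a = drug, dose_a = doses, drug_b = "",
                      dose_b = 0, fa = clip_open(fa))
    attr(tab, "truth") <- structure(
      list(doseresp_params = stats::setNames(list(list(Dm = Dm, m = m)), drug)),
      class = "sigrev_truth")
    tab
  })
}

#' Simulate two-drug combination responses with a known combination index
#'
#' For each dose pair `(d1, d2)` the generated fraction affected `fa`
#' solves `d1 / DxA(fa) + d2 / DxB(fa) = kappa` by monotone root finding,
#' where `Dx(fa) = Dm (fa/(1-fa))^(1/m)`. Under `mode = "loewe_additive"`
#' `kappa = 1`, so recomputing the combination index at the generated
#' points returns exactly 1; under `mode = "ci_factor"` the generating CI
#' equals `kappa`.
#'
#' @param fitA,fitB `median_effect_fit` objects (or lists with `drug`,
#'   `Dm`, `m`).
#' @param dose_pairs data frame with columns `d1`, `d2` (>= 0, at least one
#'   positive per row).
#' @param mode `"loewe_additive"` or `"ci_factor"`.
#' @param kappa generating combination index (> 0) when
#'   `mode = "ci_factor"`.
#' @param noise_sd sd of additive noise on the fa scale.
#' @param seed integer seed.
#' @return a two-drug dose-response data frame; rows whose root falls
#'   outside (0, 1) are reported via the `unsolved` attribute (none can
#'   occur for positive doses and kappa).
#' @export
simulate_combination <- function(fitA, fitB, dose_pairs,
                                 mode = c("loewe_additive", "ci_factor"),
                                 kappa = 1, noise_sd = 0, seed = NULL) {
  mode <- match.arg(mode)
  if (mode == "loewe_additive") kappa <- 1
  stopifnot(kappa > 0, noise_sd >= 0,
            all(c("d1", "d2") %in% names(dose_pairs)))
  if (any(dose_pairs$d1 < 0 | dose_pairs$d2 < 0))
    stop("doses must be non-negative")
  if (any(dose_pairs$d1 + dose_pairs$d2 <= 0))
    stop("each dose pair needs at least one positive dose")
  with_seed(seed, {
    fa <- vapply(seq_len(nrow(dose_pairs)), function(i) {
      d1 <- dose_pairs$d1[i]; d2 <- dose_pairs$d2[i]
      g <- function(f)
        d1 / dose_for_effect(fitA, f) + d2 / dose_for_effect(fitB, f) - kappa
      lo <- 1e-9; hi <- 1 - 1e-9
      if (g(lo) < 0 || g(hi) > 0) return(NA_real_)   # unsolvable point
      stats::uniroot(g, c(lo, hi), tol = 1e-12)$root
    }, numeric(1))
    unsolved <- which(is.na(fa))
    if (length(unsolved))
      warning("no root in (0,1) for dose pair row(s) ",
              paste(unsolved, collapse = ", "))
    fa <- fa + stats::rnorm(length(fa), 0, noise_sd)
    tab <- data.frame(drug_a = fitA$drug, dose_a = dose_pairs$d1,
                      drug_b = fitB$drug, dose_b = dose_pairs$d2,
                      fa = clip_open(fa))
    attr(tab, "generating_ci") <- kappa
    attr(tab, "unsolved") <- unsolved
    tab
  })
}
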