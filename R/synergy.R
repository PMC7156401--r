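# Median-effect (Chou-Talalay) dose-response analysis and combination
# index. The median-effect equation fa/fu = (D/Dm)^m linearizes to
# log10(fa/(1-fa)) = m log10(D) - m log10(Dm), so (Dm, m) come from a
# least-squares line on the logit-log plot; Dm is the IC50. The
# combination index at an observed effect level compares the doses used
# to the single-agent doses that would achieve the same effect.

#' Convert viability readings to fraction affected
#'
#' `fa = 1 - treated / mean(control)`, clipped into (1e-4, 1 - 1e-4) so
#' the logit stays finite. When `doses` is supplied, replicate readings
#' at the same dose are averaged on the fa scale.
#'
#' @param treated numeric vector of treated-well OD readings (>= 0).
#' @param control numeric vector of control-well OD readings; mean must be
#'   positive.
#' @param doses optional vector parallel to `treated`; replicates per dose
#'   are averaged.
#' @return fa values (per reading, or per unique dose when `doses` given,
#'   named by dose).
#' @export
viability_to_fa <- function(treated, control, doses = NULL) {
  if (any(treated < 0) || any(control < 0)) stop("negative OD readings")
  mc <- mean(control)
  if (mc <= 0) stop("control mean must be positive")
  fa <- clip_open(1 - treated / mc)
  if (is.null(doses)) return(fa)
  stopifnot(length(doses) == length(treated))
  out <- tapply(fa, doses, mean)
  stats::setNames(as.numeric(out), names(out))
}

#' Fit the median-effect model to single-drug dose-response data
#'
#' Least-squares fit of `log10(fa/(1-fa)) = m log10(D) - m log10(Dm)` over
#' the single-drug rows of a dose-response table. Requires at least 3
#' distinct positive doses; zero-dose rows are excluded with a message.
#'
#' @param tab dose-response data frame (`drug_a`, `dose_a`, `drug_b`,
#'   `dose_b`, `fa`); only rows with `dose_b == 0` (or blank `drug_b`)
#'   are used.
#' @param drug optional drug id to select when the table mixes drugs.
#' @return a `median_effect_fit`: `drug`, `Dm` (median-effect dose =
#'   IC50), `m` (slope), `r` (correlation of the linearized regression),
#'   `n_points`.
#' @export
fit_median_effect <- function(tab, drug = NULL) {
  stopifnot(all(c("drug_a", "dose_a", "dose_b", "fa") %in% names(tab)))
  rows <- tab[tab$dose_b == 0, , drop = FALSE]
  if (!is.null(drug)) rows <- rows[rows$drug_a == drug, , drop = FALSE]
  if (is.null(drug)) {
    ids <- unique(rows$drug_a)
    if (length(ids) > 1L)
      stop("table mixes drugs (", paste(ids, collapse = ", "),
           "); pass `drug`")
    drug <- ids
  }
  zero <- rows$dose_a <= 0
  if (any(zero)) {
    message("excluding ", sum(zero), " zero-dose row(s)")
    rows <- rows[!zero, , drop = FALSE]
  }
  if (any(rows$fa <= 0 | rows$fa >= 1))
    stop("fa must lie strictly in (0, 1)")
  clipped <- rows$fa <= 1e-4 | rows$fa >= 1 - 1e-4
  if (any(clipped)) {
    # readouts at the clipping bounds carry no quantitative effect
    # information and distort the logit regression
    message("excluding ", sum(clipped), " clip-bound readout(s)")
    rows <- rows[!clipped, , drop = FALSE]
  }
  if (length(unique(rows$dose_a)) < 3L)
    stop("median-effect fit needs >= 3 distinct positive doses")
  x <- log10(rows$dose_a)
  y <- log10(rows$fa / (1 - rows$fa))
  fit <- stats::lm(y ~ x)
  m <- unname(stats::coef(fit)[2L])
  if (!is.finite(m) || m <= 0)
    warning("non-positive median-effect slope (m = ", signif(m, 3), ")")
  Dm <- 10^(-unname(stats::coef(fit)[1L]) / m)
  structure(list(drug = drug, Dm = Dm, m = m,
                 r = stats::cor(x, y), n_points = nrow(rows)),
            class = "median_effect_fit")
}

#' Dose required for a given effect level
#'
#' Median-effect algebra: `Dx = Dm * (fa / (1 - fa))^(1/m)`. Monotone
#' increasing in `fa`; `fa = 0.5` returns `Dm` for every slope.
#'
#' @param fit a `median_effect_fit` (or list with `Dm`, `m`).
#' @param fa effect level(s) strictly inside (0, 1).
#' @return dose(s), same concentration units as `Dm`.
#' @export
dose_for_effect <- function(fit, fa) {
  if (any(fa <= 0 | fa >= 1)) stop("fa must lie strictly in (0, 1)")
  fit$Dm * (fa / (1 - fa))^(1 / fit$m)
}

#' Combination index of an observed two-drug effect
#'
#' Mutually exclusive (classical two-term) form by default:
#' `CI = d1 / DxA(fa) + d2 / DxB(fa)`, where `Dx` is the single-agent
#' dose achieving the observed effect. The non-exclusive variant adds the
#' cross-term `d1 d2 / (DxA DxB)`. Points whose observed `fa` sits at the
#' clipping bounds are flagged unreliable.
#'
#' @param fitA,fitB `median_effect_fit` objects for the two agents.
#' @param d1,d2 administered doses (vectors of equal length).
#' @param fa_obs observed fraction affected at each dose pair.
#' @param form `"exclusive"` (default) or `"nonexclusive"`.
#' @return a data frame `d1`, `d2`, `fa`, `CI`, `label`, `reliable`;
#'   labels from [classify_ci()].
#' @export
combination_index <- function(fitA, fitB, d1, d2, fa_obs,
                              form = c("exclusive", "nonexclusive")) {
  form <- match.arg(form)
  stopifnot(length(d1) == length(d2), length(d1) == length(fa_obs))
  if (any(fa_obs <= 0 | fa_obs >= 1)) stop("fa_obs must lie in (0, 1)")
  dxa <- dose_for_effect(fitA, fa_obs)
  dxb <- dose_for_effect(fitB, fa_obs)
  ci <- d1 / dxa + d2 / dxb
  if (form == "nonexclusive") ci <- ci + (d1 * d2) / (dxa * dxb)
  reliable <- fa_obs > 1e-4 & fa_obs < 1 - 1e-4
  if (any(!reliable))
    warning(sum(!reliable), " point(s) at the fa clipping bounds ",
            "flagged unreliable")
  data.frame(d1 = d1, d2 = d2, fa = fa_obs, CI = ci,
             label = classify_ci(ci), reliable = reliable)
}

#' Classify a combination index into the synergy bands
#'
#' `CI < 0.85` synergistic; `0.9 <= CI <= 1.0` additive; `CI > 1.1`
#' antagonistic. The gaps `[0.85, 0.9)` and `(1.0, 1.1]` are labelled
#' `"borderline"` rather than forced into a class, making the
#' classification total and piecewise-constant on (0, Inf).
#'
#' @param ci numeric vector of combination indices (> 0).
#' @return character vector of labels.
#' @export
classify_ci <- function(ci) {
  if (any(ci <= 0)) stop("combination index must be positive")
  out <- rep("borderline", length(ci))
  out[ci < 0.85] <- "synergistic"
  out[ci >= 0.9 & ci <= 1.0] <- "additive"
  out[ci > 1.1] <- "antagonistic"
  out
}

#' Write a median-effect fit report as JSON
#'
#' @param fits a `median_effect_fit` or list of them.
#' @param path output path.
#' @export
write_fit_report <- function(fits, path) {
  if (inherits(fits, "median_effect_fit")) fits <- list(fits)
  jsonlite::write_json(lapply(fits, unclass), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a combination-index report as CSV
#'
#' @param ci_table data frame from [combination_index()].
#' @param path output path.
#' @param seed optional seed for the provenance header.
#' @export
write_ci_report <- function(ci_table, path, seed = NULL) {
  write_with_header(ci_table, path, "ci_report", seed, sep = ",")
}
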