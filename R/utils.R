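# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, evaluates `expr`, and restores the caller's RNG state so
#' that seeded generators do not perturb the global random stream.
#'
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param expr expression to evaluate.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a stage-specific seed from a master seed
#'
#' Deterministic derivation rule: a small polynomial hash of the stage name
#' combined with the master seed, reduced modulo 2^31 - 1 so the result is a
#' valid 32-bit integer seed. Every RNG consumer in [run_pipeline()] draws
#' its seed through this rule, giving reproducibility with stage
#' independence (changing one stage's draws never shifts another's).
#'
#' @param master integer master seed.
#' @param stage character stage name.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1L, "screen")
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master),
            is.character(stage), length(stage) == 1L, nzchar(stage))
  h <- 0
  for (cc in utf8ToInt(stage)) h <- (h * 31 + cc) %% 100003
  as.integer((abs(master) %% 2147483647 * 10007 + h * 97 + 1) %% 2147483647)
}

# Row variance of a numeric matrix (denominator n - 1).
row_var <- function(x) {
  n <- ncol(x)
  if (n < 2L) stop("row_var needs >= 2 columns")
  m <- rowMeans(x)
  rowSums((x - m)^2) / (n - 1)
}

# Invert the trigamma function by Newton iteration (tolerance 1e-8).
# Used for empirical-Bayes prior df estimation; follows the standard
# asymptotic start x ~ 0.5 + 1/y.
trigamma_inverse <- function(y) {
  stopifnot(is.numeric(y), length(y) == 1L, is.finite(y))
  if (y <= 0) stop("trigamma_inverse requires y > 0")
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in seq_len(60L)) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif) / x < 1e-8) break
  }
  x
}

# Average ranks with deterministic handling of ties (ties.method = "average").
avg_rank <- function(x) rank(x, ties.method = "average")

# Clip a numeric vector into the open interval (lo, hi).
clip_open <- function(x, lo = 1e-4, hi = 1 - 1e-4) pmin(pmax(x, lo), hi)

# Stable ordering by decreasing value with lexicographic gene-id tie-break.
order_desc_by_stat <- function(stat, ids) order(-stat, ids, method = "radix")

# Validate a gene-by-sample expression matrix + group assignment.
check_expression <- function(expr, groups = NULL) {
  if (!is.matrix(expr) || !is.numeric(expr))
    stop("expression must be a numeric matrix (genes x samples)")
  if (is.null(rownames(expr)) || anyDuplicated(rownames(expr)))
    stop("expression matrix needs unique gene ids as rownames")
  if (is.null(colnames(expr)) || anyDuplicated(colnames(expr)))
    stop("expression matrix needs unique sample ids as colnames")
  if (!all(is.finite(expr))) stop("expression values must all be finite")
  if (!is.null(groups)) {
    if (is.null(names(groups)) || !all(colnames(expr) %in% names(groups)))
      stop("groups must be a named vector covering every sample id")
  }
  invisible(TRUE)
}
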