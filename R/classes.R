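# Lightweight S3 containers. The pipeline works on plain base-R objects
# (numeric matrices with dimnames, data frames) wrapped in thin classes
# that carry invariants and print methods.

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors; names unique, sets
#'   non-empty.
#' @param description optional named character vector of set descriptions.
#' @return a `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, description = NULL) {
  stopifnot(is.list(sets))
  if (length(sets)) {
    if (is.null(names(sets)) || any(!nzchar(names(sets))))
      stop("every gene set needs a name")
    if (anyDuplicated(names(sets)))
      stop("duplicate set names: ",
           paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
    if (any(lengths(sets) == 0L)) stop("empty gene sets are not allowed")
    sets <- lapply(sets, as.character)
  }
  structure(sets, description = description, class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("gene_set_collection:", length(x), "sets; sizes",
      if (length(x)) paste0(min(lengths(x)), "-", max(lengths(x))) else "-", "\n")
  invisible(x)
}

#' Construct a drug perturbation library
#'
#' @param stat gene x drug matrix of signed differential statistics.
#' @param p gene x drug matrix of per-gene p-values, same dimnames.
#' @return a `perturbation_library` with fields `stat`, `p`, `genes`,
#'   `drugs`.
#' @export
perturbation_library <- function(stat, p) {
  stopifnot(is.matrix(stat), is.matrix(p), identical(dim(stat), dim(p)))
  if (is.null(rownames(stat)) || is.null(colnames(stat)))
    stop("library matrices need gene rownames and drug colnames")
  if (!identical(dimnames(stat), dimnames(p)))
    stop("stat and p dimnames disagree")
  if (!all(is.finite(stat))) stop("library statistics must be finite")
  if (any(p < 0 | p > 1)) stop("library p-values must lie in [0, 1]")
  structure(list(stat = stat, p = p,
                 genes = rownames(stat), drugs = colnames(stat)),
            class = "perturbation_library")
}

#' @export
print.perturbation_library <- function(x, ...) {
  cat("perturbation_library:", length(x$drugs), "drugs x",
      length(x$genes), "genes\n")
  invisible(x)
}

# Internal signature constructor enforcing the balance invariant.
new_signature <- function(up, down, fdr_threshold = NA_real_) {
  stopifnot(is.numeric(up), is.numeric(down),
            !is.null(names(up)), !is.null(names(down)))
  if (length(up) != length(down))
    stop("signature must be balanced: |up| = |down|")
  if (length(intersect(names(up), names(down))))
    stop("up and down lists overlap")
  structure(list(up = up[order(-up, names(up), method = "radix")],
                 down = down[order(down, names(down), method = "radix")],
                 size = length(up) + length(down),
                 fdr_threshold = fdr_threshold),
            class = "disease_signature")
}

#' @export
print.disease_signature <- function(x, ...) {
  cat("disease_signature:", x$size, "genes (", length(x$up), "up /",
      length(x$down), "down ), FDR threshold", x$fdr_threshold, "\n")
  invisible(x)
}

#' @export
print.median_effect_fit <- function(x, ...) {
  cat(sprintf("median_effect_fit [%s]: Dm = %.4g, m = %.4g, r = %.4f (n = %d)\n",
              x$drug, x$Dm, x$m, x$r, x$n_points))
  invisible(x)
}

#' @export
print.sigrev_truth <- function(x, ...) {
  cat("sigrev_truth:")
  if (!is.null(x$de_genes)) cat(" ", nrow(x$de_genes), "planted DE genes;")
  if (!is.null(x$reverser_drugs))
    cat(" ", length(x$reverser_drugs), "planted reversers;")
  if (!is.null(x$doseresp_params))
    cat(" ", length(x$doseresp_params), "dose-response curves;")
  cat("\n")
  invisible(x)
}
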