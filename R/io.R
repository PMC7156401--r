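# Readers and writers for the plain-text interchange formats used by the
# pipeline: expression TSV (+ two-column group TSV), GMT gene-set files,
# long-form perturbation-library TSV, dose-response CSV, differential
# result and signature TSV, truth/config JSON and .rnk rankings.
#
# Every writer stamps a "#"-prefixed provenance header (generator, seed if
# known); every reader skips "#" lines and reports malformed rows with
# their line numbers.

provenance_header <- function(what, seed = NULL) {
  paste0("# sigrev ", what,
         if (!is.null(seed)) paste0(" seed=", seed) else "",
         " written=", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
}

write_with_header <- function(df, path, what, seed = NULL, sep = "\t") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(what, seed), con)
  utils::write.table(df, con, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_table_checked <- function(path, sep, required, numeric_cols) {
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) < 1L) stop("no content in ", path)
  header <- strsplit(lines[[1L]], sep, fixed = TRUE)[[1L]]
  missing <- setdiff(required, header)
  if (length(missing))
    stop("missing column(s) ", paste(missing, collapse = ", "), " in ", path)
  body <- lines[-1L]
  body_lineno <- lineno[-1L]
  parts <- strsplit(body, sep, fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf != length(header))
  if (length(bad))
    stop("malformed row(s) in ", path, " at line(s) ",
         paste(utils::head(body_lineno[bad], 5L), collapse = ", "))
  df <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(df) <- header
  for (cl in intersect(numeric_cols, header)) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- which(is.na(v) & !(df[[cl]] %in% c("NA", "")))
    if (length(bad))
      stop("non-numeric value in column '", cl, "' of ", path,
           " at line(s) ", paste(utils::head(body_lineno[bad], 5L), collapse = ", "))
    df[[cl]] <- v
  }
  df
}

#' Write / read a gene-by-sample expression matrix as TSV
#'
#' The layout is one header row of sample ids, first column `gene`, values
#' in log2 units. Group labels travel in a separate two-column TSV
#' (`sample`, `group`), see [write_groups()].
#'
#' @param expr numeric matrix, genes x samples, dimnames required.
#' @param path output/input file path.
#' @param seed optional seed recorded in the provenance header.
#' @return `write_expression` returns the path invisibly;
#'   `read_expression` returns the numeric matrix.
#' @export
write_expression <- function(expr, path, seed = NULL) {
  check_expression(expr)
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE)
  write_with_header(df, path, "expression", seed)
}

#' @rdname write_expression
#' @export
read_expression <- function(path) {
  df <- read_table_checked(path, "\t", "gene", character())
  genes <- df$gene
  if (anyDuplicated(genes)) stop("duplicate gene ids in ", path)
  m <- as.matrix(df[, setdiff(names(df), "gene"), drop = FALSE])
  suppressWarnings(storage.mode(m) <- "double")
  if (anyNA(m)) stop("non-numeric expression values in ", path)
  rownames(m) <- genes
  m
}

#' Write / read sample-to-group assignments
#'
#' @param groups named character vector, sample id -> group label.
#' @inheritParams write_expression
#' @export
write_groups <- function(groups, path, seed = NULL) {
  df <- data.frame(sample = names(groups), group = unname(groups))
  write_with_header(df, path, "groups", seed)
}

#' @rdname write_groups
#' @export
read_groups <- function(path) {
  df <- read_table_checked(path, "\t", c("sample", "group"), character())
  stats::setNames(df$group, df$sample)
}

#' Write / read gene-set collections in GMT format
#'
#' GMT is tab-separated: set name, description, then one member per field.
#' Lines with fewer than three fields are rejected with their line number.
#'
#' @param sets a `gene_set_collection` (named list of character vectors).
#' @inheritParams write_expression
#' @export
write_gmt <- function(sets, path) {
  stopifnot(is.list(sets))
  con <- file(path, "w")
  on.exit(close(con))
  desc <- attr(sets, "description")
  for (nm in names(sets)) {
    d <- if (!is.null(desc) && nm %in% names(desc)) desc[[nm]] else "na"
    writeLines(paste(c(nm, d, sets[[nm]]), collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lineno <- which(keep)
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad))
    stop("malformed GMT line(s) (< 3 fields) in ", path, " at line(s) ",
         paste(utils::head(lineno[bad], 5L), collapse = ", "))
  sets <- lapply(parts, function(p) unique(p[-c(1L, 2L)]))
  names(sets) <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(names(sets))) stop("duplicate set names in ", path)
  gene_set_collection(sets,
    description = stats::setNames(vapply(parts, `[[`, "", 2L), names(sets)))
}

#' Write / read a drug perturbation library (long-form TSV)
#'
#' Columns: `drug`, `gene`, `statistic`, `pvalue`. In memory the library is
#' a `perturbation_library`: a list with `stat` and `p`, both gene x drug
#' matrices over a shared gene universe.
#'
#' @param lib a `perturbation_library`.
#' @inheritParams write_expression
#' @export
write_perturbation_library <- function(lib, path, seed = NULL) {
  stopifnot(inherits(lib, "perturbation_library"))
  df <- data.frame(
    drug = rep(colnames(lib$stat), each = nrow(lib$stat)),
    gene = rep(rownames(lib$stat), times = ncol(lib$stat)),
    statistic = as.vector(lib$stat),
    pvalue = as.vector(lib$p))
  write_with_header(df, path, "perturbation_library", seed)
}

#' @rdname write_perturbation_library
#' @export
read_perturbation_library <- function(path) {
  df <- read_table_checked(path, "\t", c("drug", "gene", "statistic", "pvalue"),
                           c("statistic", "pvalue"))
  genes <- unique(df$gene)
  drugs <- unique(df$drug)
  if (nrow(df) != length(genes) * length(drugs))
    stop("library in ", path, " is not complete over its gene universe ",
         "(every drug must cover every gene)")
  stat <- matrix(NA_real_, length(genes), length(drugs),
                 dimnames = list(genes, drugs))
  p <- stat
  stat[cbind(df$gene, df$drug)] <- df$statistic
  p[cbind(df$gene, df$drug)] <- df$pvalue
  perturbation_library(stat, p)
}

#' Write / read dose-response tables (CSV)
#'
#' Columns: `drug_a`, `dose_a`, `drug_b`, `dose_b`, `fa`. Single-drug rows
#' carry `drug_b = ""` and `dose_b = 0`.
#'
#' @param tab a dose-response data frame.
#' @inheritParams write_expression
#' @export
write_dose_response <- function(tab, path, seed = NULL) {
  stopifnot(all(c("drug_a", "dose_a", "drug_b", "dose_b", "fa") %in% names(tab)))
  write_with_header(tab, path, "dose_response", seed, sep = ",")
}

#' @rdname write_dose_response
#' @export
read_dose_response <- function(path) {
  df <- read_table_checked(path, ",", c("drug_a", "dose_a", "drug_b", "dose_b", "fa"),
                           c("dose_a", "dose_b", "fa"))
  if (any(df$dose_a < 0 | df$dose_b < 0)) stop("negative dose in ", path)
  if (any(df$dose_a + df$dose_b <= 0)) stop("row with no positive dose in ", path)
  df
}

#' Write / read a differential-expression result table (TSV)
#'
#' Mirrors the classical topTable layout: `gene`, `logFC`, `t`, `P.Value`,
#' `adj.P.Val`, `B`.
#'
#' @param de a `sigrev_de` data frame from [ebayes_moderate()].
#' @inheritParams write_expression
#' @export
write_de_table <- function(de, path, seed = NULL) {
  out <- data.frame(gene = de$gene, logFC = de$logFC, t = de$t,
                    P.Value = de$p, adj.P.Val = de$q, B = de$B)
  write_with_header(out, path, "differential_result", seed)
}

#' @rdname write_de_table
#' @export
read_de_table <- function(path) {
  df <- read_table_checked(path, "\t", c("gene", "logFC", "t", "P.Value", "adj.P.Val"),
                           c("logFC", "t", "P.Value", "adj.P.Val", "B"))
  out <- data.frame(gene = df$gene, logFC = df$logFC, t = df$t,
                    p = df$P.Value, q = df$adj.P.Val,
                    B = if ("B" %in% names(df)) df$B else NA_real_)
  class(out) <- c("sigrev_de", "data.frame")
  out
}

#' Write / read a disease signature (two-column TSV)
#'
#' Members of the up list carry their (positive) moderated t as weight,
#' members of the down list their negative t, so direction is encoded in
#' the weight sign.
#'
#' @param sig a `disease_signature`.
#' @inheritParams write_expression
#' @export
write_signature <- function(sig, path, seed = NULL) {
  stopifnot(inherits(sig, "disease_signature"))
  df <- data.frame(gene = c(names(sig$up), names(sig$down)),
                   weight = c(unname(sig$up), unname(sig$down)))
  write_with_header(df, path, "disease_signature", seed)
}

#' @rdname write_signature
#' @export
read_signature <- function(path, fdr_threshold = NA_real_) {
  df <- read_table_checked(path, "\t", c("gene", "weight"), "weight")
  up <- df$weight > 0
  new_signature(stats::setNames(df$weight[up], df$gene[up]),
                stats::setNames(df$weight[!up], df$gene[!up]),
                fdr_threshold = fdr_threshold)
}

#' Read a two-column .rnk ranking file
#'
#' @param path path to a tab-separated (gene, statistic) file.
#' @return named numeric vector sorted by decreasing statistic.
#' @export
read_rnk <- function(path) {
  df <- read_table_checked(path, "\t", character(), character())
  if (ncol(df) < 2L) stop("rnk file ", path, " needs two columns")
  v <- suppressWarnings(as.numeric(df[[2L]]))
  if (anyNA(v)) stop("non-numeric statistic in ", path)
  v <- stats::setNames(v, df[[1L]])
  v[order_desc_by_stat(v, names(v))]
}

#' Write / read planted ground truth as JSON
#'
#' @param truth a `sigrev_truth` object.
#' @inheritParams write_expression
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(x$de_genes) && length(x$de_genes))
    x$de_genes <- as.data.frame(x$de_genes)
  structure(x, class = "sigrev_truth")
}

#' Write an ortholog map / read one back
#'
#' Two-column TSV `source`, `target`.
#' @param map data frame with columns `source` and `target`.
#' @inheritParams write_expression
#' @export
write_ortholog_map <- function(map, path, seed = NULL) {
  stopifnot(all(c("source", "target") %in% names(map)))
  write_with_header(map[, c("source", "target")], path, "ortholog_map", seed)
}

#' @rdname write_ortholog_map
#' @export
read_ortholog_map <- function(path) {
  read_table_checked(path, "\t", c("source", "target"), character())
}
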