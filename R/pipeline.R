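# Unified configuration and end-to-end orchestration: signature building
# -> connectivity screen, with optional PreRanked GSEA, ssGSEA-PCA and
# synergy stages. Inputs are either loaded from the configured paths or,
# when paths are absent, generated by the synthetic-data module with
# planted ground truth. Every stage draws its seed deterministically from
# the master seed via derive_seed(), and every output file carries a
# "#"-prefixed provenance header.

#' Build a run configuration
#'
#' Returns the validated configuration list consumed by
#' [run_pipeline()]. All defaults mirror the pipeline's documented
#' settings (signature sizes 100/200/300/500, FDR < 0.01, hit cutoff
#' -0.5, 1000 permutations, ssGSEA alpha 0.25, 3 principal components,
#' mutually exclusive CI form).
#'
#' @param out_dir output directory.
#' @param seed master seed; per-stage seeds derive from it.
#' @param expression,groups,library,orthologs,gene_sets,dose_response
#'   optional input file paths; `NULL` inputs are simulated (expression,
#'   library, gene sets) or skipped (orthologs, dose-response).
#' @param sizes signature sizes.
#' @param fdr_threshold signature FDR cutoff.
#' @param cutoff connectivity hit cutoff.
#' @param n_perm permutations for p-values (0 disables).
#' @param ssgsea_alpha ssGSEA rank weight exponent.
#' @param pca_k embedding dimensions.
#' @param ci_form `"exclusive"` or `"nonexclusive"`.
#' @param contrast the two group labels compared, `c(A, B)`.
#' @param sim simulation settings (list: `n_genes`, `n_per_group`, `n_de`,
#'   `effect`, `sigma`, `n_drugs`, `n_reversers`, `rho`, `noise_sd`)
#'   used when inputs are not given.
#' @param run_gsea,run_ssgsea_pca,run_synergy stage switches.
#' @return a `run_config` list.
#' @export
run_config <- function(out_dir = "sigrev_run", seed = 1L,
                       expression = NULL, groups = NULL, library = NULL,
                       orthologs = NULL, gene_sets = NULL,
                       dose_response = NULL,
                       sizes = c(100, 200, 300, 500), fdr_threshold = 0.01,
                       cutoff = -0.5, n_perm = 1000, ssgsea_alpha = 0.25,
                       pca_k = 3, ci_form = "exclusive",
                       contrast = c("tumor", "normal"),
                       sim = list(), run_gsea = FALSE,
                       run_ssgsea_pca = FALSE, run_synergy = FALSE) {
  sim_defaults <- list(n_genes = 2000L, n_per_group = 5L, n_de = 200L,
                       effect = 2, sigma = 0.5, n_drugs = 200L,
                       n_reversers = 5L, rho = 0.8, noise_sd = 1,
                       n_sets = 50L, n_coherent = 10L,
                       set_size = c(15L, 60L))
  sim <- utils::modifyList(sim_defaults, sim)
  cfg <- list(out_dir = out_dir, seed = as.integer(seed),
              inputs = list(expression = expression, groups = groups,
                            library = library, orthologs = orthologs,
                            gene_sets = gene_sets,
                            dose_response = dose_response),
              sizes = sizes, fdr_threshold = fdr_threshold,
              cutoff = cutoff, n_perm = n_perm,
              ssgsea_alpha = ssgsea_alpha, pca_k = pca_k,
              ci_form = ci_form, contrast = contrast, sim = sim,
              run_gsea = run_gsea, run_ssgsea_pca = run_ssgsea_pca,
              run_synergy = run_synergy)
  validate_config(cfg)
  class(cfg) <- "run_config"
  cfg
}

validate_config <- function(cfg) {
  stopifnot(cfg$fdr_threshold > 0, cfg$fdr_threshold < 1,
            cfg$cutoff > -1, cfg$cutoff < 1,
            cfg$n_perm >= 0, cfg$ssgsea_alpha >= 0, cfg$pca_k >= 1,
            all(cfg$sizes >= 2), all(cfg$sizes %% 2 == 0),
            cfg$ci_form %in% c("exclusive", "nonexclusive"),
            length(cfg$contrast) == 2L)
  # inputs that are named must exist
  for (nm in names(cfg$inputs)) {
    pth <- cfg$inputs[[nm]]
    if (!is.null(pth) && !file.exists(pth))
      stop("configured input '", nm, "' not found: ", pth)
  }
  invisible(TRUE)
}

#' Read / write a run configuration as YAML
#'
#' The configuration serializes to a single human-readable YAML file with
#' sections (`inputs`, `sim`, scalar settings).
#'
#' @param cfg a `run_config`.
#' @param path file path.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$inputs <- raw$inputs[!vapply(raw$inputs, is.null, logical(1))]
  do.call(run_config, c(raw[setdiff(names(raw), "inputs")], raw$inputs))
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(cfg), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the signature-reversal pipeline end to end
#'
#' Stages: (1) acquire inputs (load configured files or simulate with
#' planted truth); (2) differential expression (linear fit +
#' empirical-Bayes moderation), written as a topTable-style TSV; (3)
#' connectivity screen over all signature sizes, written as results CSV
#' and score-matrix CSV; optionally (4) PreRanked GSEA of the moderated-t
#' ranking against the gene sets, (5) ssGSEA -> rank matrix -> PCA
#' embedding, (6) median-effect fits + combination indices of a
#' dose-response table. A JSON manifest records inputs, config hash, seed
#' and package version. Any stage error aborts with the stage name;
#' partial outputs are retained next to a `FAILED` marker file.
#'
#' @param cfg a `run_config`.
#' @return (invisibly) a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  validate_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "init"
  res <- list()
  tryCatch({
    # ---- stage: data ----
    stage <- "data"
    if (!is.null(cfg$inputs$expression)) {
      if (is.null(cfg$inputs$groups))
        stop("expression input given without a groups file")
      expr <- read_expression(cfg$inputs$expression)
      groups <- read_groups(cfg$inputs$groups)
      truth <- NULL
    } else {
      s <- cfg$sim
      sim <- simulate_expression(s$n_genes, s$n_per_group, s$n_de,
                                 s$effect, s$sigma,
                                 seed = derive_seed(cfg$seed, "expression"))
      expr <- sim$expr; groups <- sim$groups; truth <- sim$truth
    }

    # ---- stage: signatures ----
    stage <- "signatures"
    fit <- fit_linear_de(expr, groups, cfg$contrast)
    de <- ebayes_moderate(fit)
    write_de_table(de, file.path(cfg$out_dir, "differential_result.tsv"),
                   seed = cfg$seed)
    res$de <- de

    # ---- stage: library ----
    stage <- "library"
    if (!is.null(cfg$inputs$library)) {
      lib <- read_perturbation_library(cfg$inputs$library)
      if (!is.null(cfg$inputs$orthologs)) {
        map <- read_ortholog_map(cfg$inputs$orthologs)
        res$de_mapped <- map_orthologs(de, map)
      } else res$de_mapped <- de
    } else {
      disease_t <- stats::setNames(de$t, de$gene)
      s <- cfg$sim
      libsim <- simulate_perturbation_library(
        disease_t, s$n_drugs, s$n_reversers, s$rho, s$noise_sd,
        seed = derive_seed(cfg$seed, "library"))
      lib <- libsim$library
      if (!is.null(truth)) truth$reverser_drugs <- libsim$truth$reverser_drugs
      res$de_mapped <- de
    }

    # ---- stage: screen ----
    stage <- "screen"
    screen <- connectivity_screen(lib, res$de_mapped, sizes = cfg$sizes,
                                  cutoff = cfg$cutoff, n_perm = cfg$n_perm,
                                  fdr_threshold = cfg$fdr_threshold,
                                  seed = derive_seed(cfg$seed, "screen"))
    write_screen_results(screen, file.path(cfg$out_dir, "screen_results.csv"))
    write_score_matrix(screen, file.path(cfg$out_dir, "score_matrix.csv"))
    res$screen <- screen

    # ---- stage: gene sets / enrichment ----
    if (cfg$run_gsea || cfg$run_ssgsea_pca) {
      stage <- "gene_sets"
      if (!is.null(cfg$inputs$gene_sets)) {
        sets <- read_gmt(cfg$inputs$gene_sets)
      } else {
        s <- cfg$sim
        tr <- if (!is.null(truth)) truth$de_genes else NULL
        # without planted truth there is nothing to build coherent sets
        # from; fall back to purely random sets
        sets <- simulate_gene_sets(
          s$n_sets, s$set_size, rownames(expr),
          n_coherent = if (is.null(tr)) 0L else s$n_coherent,
          up_genes = if (!is.null(tr)) tr$gene[tr$sign > 0],
          down_genes = if (!is.null(tr)) tr$gene[tr$sign < 0],
          seed = derive_seed(cfg$seed, "gene_sets"))
      }
      if (cfg$run_gsea) {
        stage <- "gsea"
        ranking <- stats::setNames(de$t, de$gene)
        gsea <- preranked_gsea(ranking, sets,
                               n_perm = max(100, cfg$n_perm),
                               seed = derive_seed(cfg$seed, "gsea"))
        write_with_header(
          data.frame(NAME = gsea$set, ES = gsea$ES, NES = gsea$NES,
                     `NOM p-val` = gsea$p, `FDR q-val` = gsea$q,
                     check.names = FALSE),
          file.path(cfg$out_dir, "gsea_report.tsv"), "gsea_report",
          seed = cfg$seed)
        res$gsea <- gsea
      }
      if (cfg$run_ssgsea_pca) {
        stage <- "ssgsea_pca"
        ssg <- ssgsea_matrix(expr, sets, alpha = cfg$ssgsea_alpha)
        rk <- build_rank_matrix(ssg)
        emb <- pca_embed(rk, k = cfg$pca_k)
        out <- data.frame(sample = rownames(emb$coords), emb$coords,
                          group = unname(groups[rownames(emb$coords)]))
        write_with_header(out, file.path(cfg$out_dir, "embedding.csv"),
                          "embedding", seed = cfg$seed, sep = ",")
        res$ssgsea <- ssg; res$embedding <- emb
      }
    }

    # ---- stage: synergy ----
    if (cfg$run_synergy && !is.null(cfg$inputs$dose_response)) {
      stage <- "synergy"
      tab <- read_dose_response(cfg$inputs$dose_response)
      single <- tab[tab$dose_b == 0, , drop = FALSE]
      fits <- lapply(unique(single$drug_a), function(d)
        fit_median_effect(single, drug = d))
      names(fits) <- unique(single$drug_a)
      write_fit_report(fits, file.path(cfg$out_dir, "median_effect_fits.json"))
      res$fits <- fits
      combo <- tab[tab$dose_b > 0 & tab$dose_a > 0, , drop = FALSE]
      if (nrow(combo)) {
        pairs <- unique(combo[, c("drug_a", "drug_b")])
        ci_all <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
          rows <- combo[combo$drug_a == pairs$drug_a[i] &
                          combo$drug_b == pairs$drug_b[i], , drop = FALSE]
          ci <- combination_index(fits[[pairs$drug_a[i]]],
                                  fits[[pairs$drug_b[i]]],
                                  rows$dose_a, rows$dose_b, rows$fa,
                                  form = cfg$ci_form)
          cbind(drug_a = pairs$drug_a[i], drug_b = pairs$drug_b[i], ci)
        }))
        write_ci_report(ci_all, file.path(cfg$out_dir, "ci_report.csv"),
                        seed = cfg$seed)
        res$ci <- ci_all
      }
    }

    # ---- manifest ----
    stage <- "manifest"
    manifest <- list(
      package = "sigrev",
      version = as.character(utils::packageVersion("sigrev")),
      seed = cfg$seed, config_hash = config_hash(cfg),
      inputs = cfg$inputs[!vapply(cfg$inputs, is.null, logical(1))],
      stages = names(res))
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    res$manifest <- manifest
    if (!is.null(truth)) {
      write_truth(truth, file.path(cfg$out_dir, "truth.json"))
      res$truth <- truth
    }
    invisible(res)
  }, error = function(e) {
    writeLines(paste0("stage: ", stage, "\n", conditionMessage(e)),
               file.path(cfg$out_dir, "FAILED"))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
}
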