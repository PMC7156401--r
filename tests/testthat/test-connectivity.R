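# Connectivity scoring: KS two-set statistic, GWC weighted Spearman,
# permutation significance, ortholog mapping and the library screen.

make_sig <- function(up, dn) {
  sigrev:::new_signature(setNames(rep(1, length(up)), up),
                         setNames(rep(-1, length(dn)), dn))
}

test_that("KS connectivity is +1 on self, -1 on the exact negation", {
  sim <- default_sim(201, n_genes = 600, n_de = 100)
  de <- ebayes_moderate(fit_linear_de(sim$expr, sim$groups))
  sig <- build_signature(de, 100)
  dis <- setNames(de$t, de$gene)
  expect_equal(ks_connectivity(sig, dis), 1)
  expect_equal(ks_connectivity(sig, -dis), -1)
  expect_error(ks_connectivity(sig, setNames(1:5, paste0("x", 1:5))),
               "up set")
})

test_that("KS connectivity matches brute-force enumeration and antisymmetry on N <= 12", {
  genes <- sprintf("g%02d", 1:12)
  up_sets <- combn(12, 2)
  set.seed(55)
  for (trial in 1:60) {
    u <- up_sets[, sample(ncol(up_sets), 1)]
    rest <- setdiff(1:12, u)
    d <- sample(rest, 2)
    sig <- make_sig(genes[u], genes[d])
    prof <- setNames(sample(12), genes)   # a fixed random permutation
    srt <- names(prof)[order(-prof, names(prof), method = "radix")]
    expect_equal(ks_connectivity(sig, prof),
                 brute_ks_connectivity(srt, genes[u], genes[d]),
                 tolerance = 1e-12)
    # antisymmetry under profile negation (ranks reverse exactly because
    # the profile is a permutation with no ties)
    srt_neg <- names(prof)[order(prof, names(prof), method = "radix")]
    expect_equal(ks_connectivity(sig, -prof),
                 brute_ks_connectivity(srt_neg, genes[u], genes[d]),
                 tolerance = 1e-12)
    expect_equal(ks_connectivity(sig, -prof), -ks_connectivity(sig, prof),
                 tolerance = 1e-12)
  }
})

test_that("GWC reduces to Spearman under uniform weights and matches the hand oracle", {
  set.seed(14)
  x <- setNames(rnorm(12), sprintf("g%02d", 1:12))
  y <- setNames(rnorm(12), names(x))
  p_flat <- setNames(rep(0.05, 12), names(x))
  expect_equal(gwc_score(x, p_flat, y, p_flat),
               cor(x, y, method = "spearman"), tolerance = 1e-12)
  # drug identical to disease scores 1 regardless of weights
  p_var <- setNames(runif(12, 1e-6, 1), names(x))
  expect_equal(gwc_score(x, p_var, x, p_flat), 1, tolerance = 1e-12)
  # hand-computed weighted covariance oracle on stated stats/p-values
  ds <- setNames(c(2.1, -0.3, 1.4, -2.2, 0.7, 0.1, -1.1, 0.9, 1.8, -0.6,
                   0.2, -1.9), sprintf("g%02d", 1:12))
  dp <- setNames(c(0.01, 0.8, 0.05, 0.005, 0.3, 0.9, 0.1, 0.2, 0.02, 0.5,
                   0.85, 0.008), names(ds))
  gs <- setNames(c(-1.9, 0.2, -1.0, 2.0, -0.5, 0.3, 1.2, -0.8, -1.5, 0.4,
                   -0.1, 1.7), names(ds))
  gp <- setNames(c(0.02, 0.7, 0.08, 0.01, 0.4, 0.95, 0.15, 0.25, 0.03,
                   0.6, 0.9, 0.015), names(ds))
  w <- (-log10(dp) - log10(gp)) / 2
  expect_equal(gwc_score(ds, dp, gs, gp),
               oracle_weighted_rank_cor(ds, gs, w), tolerance = 1e-12)
  # symmetry in its two arguments
  expect_equal(gwc_score(ds, dp, gs, gp), gwc_score(gs, gp, ds, dp),
               tolerance = 1e-12)
  # invariance to strictly monotone transforms of either statistic vector
  expect_equal(gwc_score(ds, dp, gs, gp),
               gwc_score(exp(ds), dp, gs^3, gp), tolerance = 1e-12)
  expect_error(gwc_score(ds[1:5], dp[1:5], gs[1:5], gp[1:5]), "10 genes")
  p_one <- setNames(rep(1, 12), names(ds))
  expect_error(gwc_score(ds, p_one, gs, p_one), "zero total weight")
})

test_that("permutation p has the smoothing bound and matches exhaustive enumeration", {
  set.seed(3)
  dis <- setNames(c(1.2, -0.5, 2.0, -1.7, 0.3), paste0("g", 1:5))
  prof <- setNames(c(-1.1, 0.4, -1.9, 1.5, -0.2), names(dis))
  pv <- setNames(rep(0.1, 5), names(dis))
  score_fn <- function(stat, p) cor(dis[names(stat)], stat,
                                    method = "spearman")
  # exhaustive null over all 120 label permutations
  perms <- all_perms(5)
  obs <- score_fn(prof, pv)
  null_all <- apply(perms, 1, function(ix)
    score_fn(setNames(unname(prof)[ix], names(prof)), pv))
  p_exact <- mean(abs(null_all) >= abs(obs))
  res <- permutation_p(score_fn, prof, pv, n_perm = 1000, seed = 8)
  se <- sqrt(p_exact * (1 - p_exact) / 1000)
  expect_lt(abs(res$p - p_exact), 3 * se + 2 / 1001)
  # minimum attainable p is 1/(n_perm + 1)
  expect_gte(res$p, 1 / 1001)
  expect_error(permutation_p(score_fn, prof, pv, n_perm = 10), "n_perm")
})

test_that("ortholog mapping translates, drops and resolves deterministically", {
  de <- structure(
    data.frame(gene = paste0("m", 1:6), logFC = c(1, -2, 3, -4, 5, -6),
               t = c(1, -2, 3, -4, 5, -6), p = rep(0.01, 6),
               q = rep(0.02, 6), B = NA_real_),
    class = c("sigrev_de", "data.frame"))
  # identity map leaves the object unchanged (gene set and stats)
  ident <- data.frame(source = paste0("m", 1:6), target = paste0("m", 1:6))
  same <- map_orthologs(de, ident)
  expect_setequal(same$gene, de$gene)
  expect_equal(same$t[match(de$gene, same$gene)], de$t)
  # a missing gene is dropped with a message stating the count
  expect_message(out <- map_orthologs(de, ident[-2, ]), "1 gene")
  expect_false("m2" %in% out$gene)
  # many-to-one: the source with largest |statistic| wins
  mm <- data.frame(source = c("m1", "m6"), target = c("H1", "H1"))
  expect_error(map_orthologs(de, mm), "50%")   # only 2/6 mappable
  mm_full <- rbind(mm, data.frame(source = paste0("m", 2:5),
                                  target = paste0("H", 2:5)))
  res <- map_orthologs(de, mm_full)
  expect_equal(res$t[res$gene == "H1"], -6)    # m6 has |t| = 6 > 1
  # one-to-many: lexicographically smallest target kept
  otm <- data.frame(source = paste0("m", 1:6),
                    target = c("Hb", paste0("H", 2:6)))
  otm <- rbind(otm, data.frame(source = "m1", target = "Ha"))
  res2 <- map_orthologs(de, otm)
  expect_true("Ha" %in% res2$gene)
  expect_false("Hb" %in% res2$gene)

  # library mapping agrees with plain set-intersection on the universe
  set.seed(20)
  genes <- sprintf("m%04d", 1:500)
  stat <- matrix(rnorm(1000), 500, 2, dimnames = list(genes, c("d1", "d2")))
  lib <- perturbation_library(stat, matrix(0.5, 500, 2,
                                           dimnames = dimnames(stat)))
  map <- data.frame(source = sample(genes, 400),
                    target = sprintf("h%04d", 1:400))
  mapped <- suppressMessages(map_orthologs(lib, map))
  expect_setequal(mapped$genes, map$target)
  expect_equal(mapped$stat[map$target[5], "d1"],
               lib$stat[map$source[5], "d1"])
})

test_that("screen recovers a perfect planted reverser at every size", {
  # 600 planted DE genes so that even the 500-gene signature (250 per
  # direction) is buildable at FDR < 0.01
  sim <- default_sim(301, n_de = 600)
  de <- ebayes_moderate(fit_linear_de(sim$expr, sim$groups))
  lib <- simulate_perturbation_library(setNames(de$t, de$gene), 50, 1,
                                       rho = 1, noise_sd = 0, seed = 302)
  scr <- connectivity_screen(lib$library, de, n_perm = 0, seed = 303)
  rev <- names(lib$truth$reverser_drugs)
  rec <- scr$records[scr$records$drug == rev, ]
  expect_equal(nrow(rec), 4)                      # all four sizes scored
  expect_true(all(rec$rank_ks == 1))
  expect_true(all(rec$ks_score <= -0.9))
  expect_true(all(rec$gwc_score <= -0.9))
  expect_true(all(rec$hit))
  expect_true(scr$consensus$consensus_hit[scr$consensus$drug == rev])
  # ranks are a permutation of 1..n_drugs at each size
  for (s in unique(scr$records$size))
    expect_setequal(scr$records$rank_ks[scr$records$size == s], 1:50)
})

test_that("adding a drug never changes the relative order of existing drugs", {
  sim <- default_sim(310, n_genes = 800, n_de = 100)
  de <- ebayes_moderate(fit_linear_de(sim$expr, sim$groups))
  lib <- simulate_perturbation_library(setNames(de$t, de$gene), 30, 2,
                                       rho = 0.7, noise_sd = 1, seed = 311)
  scr1 <- connectivity_screen(lib$library, de, sizes = 100, n_perm = 0)
  # append one extra drug
  extra_stat <- cbind(lib$library$stat,
                      drug_extra = rnorm(nrow(lib$library$stat)))
  extra_p <- cbind(lib$library$p, drug_extra = 0.5)
  lib2 <- perturbation_library(extra_stat, extra_p)
  scr2 <- connectivity_screen(lib2, de, sizes = 100, n_perm = 0)
  old <- scr1$records[order(scr1$records$rank_ks), "drug"]
  new <- scr2$records[order(scr2$records$rank_ks), "drug"]
  expect_identical(old, setdiff(new, "drug_extra"))
})

test_that("screen skips unbuildable sizes with a warning", {
  sim <- default_sim(320, n_genes = 500, n_de = 60)
  de <- ebayes_moderate(fit_linear_de(sim$expr, sim$groups))
  lib <- simulate_perturbation_library(setNames(de$t, de$gene), 10, 1,
                                       rho = 1, noise_sd = 0.5, seed = 321)
  expect_warning(scr <- connectivity_screen(lib$library, de,
                                            sizes = c(40, 400), n_perm = 0),
                 "skipped")
  expect_equal(unique(scr$records$size), 40)
})
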