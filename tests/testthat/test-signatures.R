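# Differential expression, empirical-Bayes moderation, signatures and
# classifiers.

test_that("per-gene linear fit matches hand-computed pooled statistics", {
  expr <- rbind(g1 = c(1, 3, 5, 7), g2 = c(2, 2, 2, 2))
  colnames(expr) <- paste0("s", 1:4)
  groups <- setNames(c("A", "A", "B", "B"), colnames(expr))
  fit <- fit_linear_de(expr, groups, c("A", "B"))
  # {1,3} vs {5,7}: diff = 2 - 6 = -4; pooled s2 = (2 + 2)/2 = 2; df = 2
  expect_equal(fit$logFC[fit$gene == "g1"], -4)
  expect_equal(fit$s2[fit$gene == "g1"], 2)
  expect_equal(fit$df[fit$gene == "g1"], 2)
  # identical values in both groups: diff 0, s2 0
  expect_equal(fit$logFC[fit$gene == "g2"], 0)
  expect_equal(fit$s2[fit$gene == "g2"], 0)

  # permuting sample order leaves all statistics unchanged
  perm <- expr[, c(3, 1, 4, 2)]
  fit2 <- fit_linear_de(perm, groups, c("A", "B"))
  expect_equal(fit2$logFC, fit$logFC)
  expect_equal(fit2$s2, fit$s2)

  expect_error(fit_linear_de(expr, groups, c("A", "C")), "C")
})

test_that("moderated t agrees with the direct-formula oracle to 1e-10", {
  for (seed in c(1, 2, 3)) {
    sim <- default_sim(seed, n_genes = 50, n_per_group = 4, n_de = 10,
                       effect = 1.5, sigma = 0.6)
    fit <- fit_linear_de(sim$expr, sim$groups)
    de <- ebayes_moderate(fit)
    orc <- oracle_moderated_t(fit$logFC, fit$s2, fit$df[1],
                              attr(fit, "stdev_unscaled"))
    expect_equal(attr(de, "d0"), orc$d0, tolerance = 1e-8)
    expect_equal(de$t, orc$t, tolerance = 1e-10)
  }
})

test_that("moderated t matches limma's eBayes on the same data", {
  skip_if_not_installed("limma")
  sim <- default_sim(42, n_genes = 400, n_per_group = 4, n_de = 40)
  design <- cbind(Intercept = 1,
                  tumor = as.numeric(sim$groups == "tumor"))
  lfit <- limma::eBayes(limma::lmFit(sim$expr, design))
  de <- ebayes_moderate(fit_linear_de(sim$expr, sim$groups))
  expect_equal(attr(de, "d0"), lfit$df.prior, tolerance = 1e-6)
  expect_equal(attr(de, "s0_2"), lfit$s2.prior, tolerance = 1e-6)
  expect_equal(de$t, unname(lfit$t[, "tumor"]), tolerance = 1e-8)
  expect_equal(de$p, unname(lfit$p.value[, "tumor"]), tolerance = 1e-8)
})

test_that("d0 limits behave as documented", {
  sim <- default_sim(7, n_genes = 80, n_per_group = 4, n_de = 10)
  fit <- fit_linear_de(sim$expr, sim$groups)
  # d0 -> 0: moderation off, ordinary t with pooled variance
  de0 <- ebayes_moderate(fit, d0 = 0)
  ord_t <- fit$logFC / (sqrt(fit$s2) * attr(fit, "stdev_unscaled"))
  expect_equal(de0$t, ord_t, tolerance = 1e-12)
  # d0 -> Inf: every posterior variance equals s0^2
  deI <- ebayes_moderate(fit, d0 = Inf)
  expect_equal(unique(round(deI$s2_post, 12)),
               round(attr(deI, "s0_2"), 12))
})

test_that("equal-variance ensemble makes moderation a rescaling no-op", {
  # every gene has the same residual pattern, hence identical s2
  base <- c(-1, 1, -2, 2, 0, 0)
  expr <- t(sapply(1:30, function(i) base + i / 10))
  rownames(expr) <- sprintf("g%02d", 1:30)
  colnames(expr) <- paste0("s", 1:6)
  groups <- setNames(rep(c("A", "B"), each = 3), colnames(expr))
  fit <- fit_linear_de(expr, groups, c("A", "B"))
  expect_equal(length(unique(round(fit$s2, 12))), 1L)
  de <- ebayes_moderate(fit)
  expect_identical(attr(de, "d0"), Inf)
  # d0 infinite with zero spread: s0^2 = mean(s2) = s2, an exact no-op
  expect_equal(attr(de, "s0_2"), fit$s2[1], tolerance = 1e-12)
  expect_equal(de$s2_post, fit$s2, tolerance = 1e-12)
  ord_t <- fit$logFC / (sqrt(fit$s2) * attr(fit, "stdev_unscaled"))
  expect_equal(de$t, ord_t, tolerance = 1e-12)
})

test_that("BH adjustment is correct, order-invariant and validated", {
  # hand step-up: p = (.01,.02,.03), m = 3 -> q = (.03,.03,.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  p <- runif(50)
  idx <- sample(50)
  expect_equal(bh_adjust(p)[idx], bh_adjust(p[idx]))
  expect_error(bh_adjust(c(0.1, NaN)), "NaN")
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
})

test_that("signature extraction is balanced, pure and contrast-antisymmetric", {
  sim <- default_sim(3)
  de <- ebayes_moderate(fit_linear_de(sim$expr, sim$groups))
  sig <- build_signature(de, 100)
  expect_length(sig$up, 50)
  expect_length(sig$down, 50)
  expect_length(intersect(names(sig$up), names(sig$down)), 0)
  expect_true(all(de$q[match(c(names(sig$up), names(sig$down)),
                             de$gene)] < 0.01))
  # members are overwhelmingly planted genes (truth purity >= 95%)
  planted <- sim$truth$de_genes$gene
  expect_gte(mean(c(names(sig$up), names(sig$down)) %in% planted), 0.95)

  # flipping the contrast exactly swaps up and down lists
  de_rev <- ebayes_moderate(fit_linear_de(sim$expr, sim$groups,
                                          c("normal", "tumor")))
  sig_rev <- build_signature(de_rev, 100)
  expect_identical(names(sig_rev$up), names(sig$down))
  expect_identical(names(sig_rev$down), names(sig$up))
  expect_equal(unname(sig_rev$up), unname(-sig$down))

  # null data: error, never an undersized signature
  null <- simulate_expression(500, 4, 0, 1, 0.5, seed = 9)
  de_null <- ebayes_moderate(fit_linear_de(null$expr, null$groups))
  expect_error(build_signature(de_null, 100), "attainable")
})

test_that("classifier construction and projection recover planted groups", {
  sim <- default_sim(17, n_genes = 1000, n_per_group = 6, n_de = 100)
  cls <- build_classifier(sim$expr, sim$groups, 95,
                          contrast = c("tumor", "normal"))
  expect_equal(nrow(cls), 95)
  expect_setequal(unique(cls$direction), c("up-in-A", "up-in-B"))
  expect_false(anyDuplicated(cls$gene) > 0)
  # classifier genes are dominated by planted separators
  expect_gte(mean(cls$gene %in% sim$truth$de_genes$gene), 0.8)

  proj <- project_classifier(sim$expr, cls)
  expect_gte(mean(proj$call == sim$groups[proj$sample]), 0.95)

  # score is invariant to per-gene affine rescaling
  resc <- sim$expr * 3 + 5
  expect_equal(project_classifier(resc, cls)$score, proj$score,
               tolerance = 1e-12)

  expect_error(build_classifier(sim$expr, sim$groups, 5000), "exceeds")
  # near-identical groups warn about weak separation
  flat <- simulate_expression(200, 3, 0, 1, 0.5, seed = 2)
  expect_warning(build_classifier(flat$expr, flat$groups, 20,
                                  contrast = c("tumor", "normal")),
                 "weak separation")
  # <50% overlap is an error naming the count
  sub <- sim$expr[setdiff(rownames(sim$expr), cls$gene[1:60]), ]
  expect_error(project_classifier(sub, cls), "50%")
})

test_that("realized FDR stays controlled on planted data", {
  fdr <- vapply(1:20, function(s) {
    sim <- default_sim(400 + s)
    de <- ebayes_moderate(fit_linear_de(sim$expr, sim$groups))
    called <- de$gene[de$q < 0.01]
    if (length(called) == 0) return(0)
    mean(!called %in% sim$truth$de_genes$gene)
  }, numeric(1))
  expect_lte(mean(fdr), 0.05)
})
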