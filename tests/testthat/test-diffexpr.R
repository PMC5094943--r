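test_that("detection calls follow the one-sided signed-rank rule", {
  expect_false(detection_call(c(5, 5, 5, 5), c(5, 5, 5, 5))$detected)
  res <- detection_call(6:10, 5:9)  # five +1 differences: p = 1/32
  expect_equal(res$p_value, 1 / 32)
  expect_true(res$detected)
  expect_error(detection_call(1:4, 1:3), "equal length")
  expect_error(detection_call(1:3, 1:3), "at least 4")
  # a gene is detected when at least one probe set is detected
  expect_true(gene_detected(list(
    list(pm = c(5, 5, 5, 5), mm = c(5, 5, 5, 5)),
    list(pm = 6:10, mm = 5:9)
  )))
})

test_that("the detection filter applies the ceiling(n/3) inclusion rule", {
  det <- matrix(FALSE, 3, 10,
                dimnames = list(c("g_none", "g_three", "g_four"),
                                paste0("s", 1:10)))
  det["g_three", 1:3] <- TRUE
  det["g_four", 1:4] <- TRUE
  inc <- expression_filter(det, paste0("s", 1:10))
  # n = 10: need >= ceil(10/3) = 4 detected samples
  expect_identical(inc, "g_four")
  # n = 9: need exactly 3
  inc9 <- expression_filter(det[, 1:9], paste0("s", 1:9))
  expect_setequal(inc9, c("g_three", "g_four"))
  # all-detected gene always included; never-detected never included
  all_det <- matrix(TRUE, 1, 6, dimnames = list("g", paste0("s", 1:6)))
  expect_identical(expression_filter(all_det, paste0("s", 1:6)), "g")
  expect_error(expression_filter(det, character(0)), "no samples")
})

test_that("the variance-prior moments estimator recovers known hyperparameters", {
  set.seed(21)
  d0 <- 4; s0 <- 0.05; df <- 8
  s2 <- s0 * (rchisq(20000, df) / df) / (rchisq(20000, d0) / d0)
  # i.e. s2 ~ s0 * F(df, d0)
  est <- estimate_variance_prior(s2, df)
  expect_equal(est$d0, d0, tolerance = 0.15)
  expect_equal(est$s0_2, s0, tolerance = 0.05)
})

test_that("moderated fit reduces to the pooled t at prior df 0 and to the z-form at infinity", {
  tg <- make_two_group(n_genes = 300, n_per_group = 4, n_up = 20, n_down = 20,
                       effect = 1, seed = 31)
  m <- as.matrix(tg$expression[, -1])
  a <- m[, tg$samples$group == "A"]; b <- m[, tg$samples$group == "B"]

  de0 <- fit_moderated(tg$expression, tg$samples, contrast = c("A", "B"),
                       prior_df = 0)
  ord <- oracle_pooled_t(a, b)
  expect_equal(de0$t, unname(ord$t), tolerance = 1e-8)
  expect_equal(de0$p, unname(ord$p), tolerance = 1e-8)

  s0 <- 0.06
  deI <- fit_moderated(tg$expression, tg$samples, contrast = c("A", "B"),
                       prior_df = Inf, prior_var = s0)
  z <- (rowMeans(a) - rowMeans(b)) / sqrt(s0 * (1 / 4 + 1 / 4))
  expect_equal(deI$t, unname(z), tolerance = 1e-8)
  expect_equal(deI$p, unname(2 * pnorm(-abs(z))), tolerance = 1e-8)
})

test_that("moderated variance is a convex combination lying between s2 and the prior", {
  tg <- make_two_group(n_genes = 400, n_per_group = 5, n_up = 0, n_down = 0,
                       seed = 41)
  de <- fit_moderated(tg$expression, tg$samples, contrast = c("A", "B"))
  g <- glance(de)
  m <- as.matrix(tg$expression[, -1])
  a <- m[, 1:5]; b <- m[, 6:10]
  s2 <- (rowSums((a - rowMeans(a))^2) + rowSums((b - rowMeans(b))^2)) / 8
  s2_tilde <- (de$log2fc / de$t)^2 / (1 / 5 + 1 / 5)
  ok <- is.finite(s2_tilde)
  lo <- pmin(s2[ok], g$prior_var); hi <- pmax(s2[ok], g$prior_var)
  expect_true(all(s2_tilde[ok] >= lo - 1e-10 & s2_tilde[ok] <= hi + 1e-10))
})

test_that("moderated fit agrees with the established limma implementation", {
  skip_if_not_installed("limma")
  tg <- make_two_group(n_genes = 500, n_per_group = 5, n_up = 30, n_down = 30,
                       effect = 1, seed = 51)
  de <- fit_moderated(tg$expression, tg$samples, contrast = c("A", "B"))
  m <- as.matrix(tg$expression[, -1])
  rownames(m) <- tg$expression$gene
  design <- cbind(B = 1, AvsB = tg$samples$group == "A")
  fit <- limma::eBayes(limma::lmFit(m, design))
  expect_equal(glance(de)$prior_df, fit$df.prior, tolerance = 1e-6)
  expect_equal(glance(de)$prior_var, fit$s2.prior, tolerance = 1e-6)
  expect_equal(de$t, unname(fit$t[, "AvsB"]), tolerance = 1e-8)
  expect_equal(de$p, unname(fit$p.value[, "AvsB"]), tolerance = 1e-8)
})

test_that("null genes give t = 0 cases and uniform p-values", {
  # a gene with equal group means has log2fc 0, fc 1, t 0, p 1
  expr <- tibble::tibble(gene = "flat", s1 = 1, s2 = 2, s3 = 1, s4 = 2)
  samp <- tibble::tibble(sample_id = paste0("s", 1:4),
                         group = c("A", "A", "B", "B"))
  de <- fit_moderated(expr, samp, contrast = c("A", "B"), prior_df = 0)
  expect_equal(de$log2fc, 0)
  expect_equal(de$fc, 1)
  expect_equal(de$t, 0)
  expect_equal(de$p, 1)

  tg <- make_two_group(n_genes = 4000, n_per_group = 5, n_up = 0, n_down = 0,
                       seed = 61)
  den <- fit_moderated(tg$expression, tg$samples, contrast = c("A", "B"))
  ks <- suppressWarnings(ks.test(den$p, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
  rej <- mean(den$p < 0.05)
  expect_gt(rej, 0.035)
  expect_lt(rej, 0.065)
})

test_that("the interaction fit recovers planted interaction effects and balanced-design algebra", {
  st <- make_study(n_genes = 800, n_interaction = 40, interaction_effect = 1.5,
                   prior_var = 0.04, seed = 71)
  fit <- interaction_fit(st$expression, st$samples)
  truth <- st$truth$interaction_genes
  est <- fit$log2fc[match(truth$gene, fit$gene)]
  # planted +-1.5 log2 interaction coefficients are recovered
  expect_gt(cor(est, truth$effect), 0.95)
  expect_lt(max(abs(est - truth$effect)), 1)
  degs <- call_degs(fit, fdr = 0.10, fc_up = 1, fc_down = 1)
  found <- length(intersect(c(degs$up, degs$down), truth$gene))
  expect_gt(found / nrow(truth), 0.8)

  # no-interaction gene: identical aging effect in both genotypes
  expr <- tibble::tibble(gene = "gX",
                         a = 1, b = 1.2, c = 2, d = 2.2,   # WT young/old
                         e = 5, f = 5.2, g = 6, h = 6.2)   # KO young/old
  samp <- tibble::tibble(sample_id = letters[1:8],
                         genotype = rep(c("WT", "KO"), each = 4),
                         age = rep(rep(c("young", "old"), each = 2), 2))
  f0 <- interaction_fit(expr, samp, prior_df = 0)
  expect_equal(f0$log2fc, 0, tolerance = 1e-12)
  expect_equal(f0$p, 1, tolerance = 1e-10)

  # balanced 2x2: the interaction t equals a two-group fit on per-sample
  # aging deviations (old minus its genotype's young mean, gene-wise)
  stb <- make_study(n_genes = 200,
                    cells = c("young-WT" = 4, "young-KO" = 4,
                              "old-WT" = 4, "old-KO" = 4),
                    n_interaction = 10, seed = 72)
  fb <- interaction_fit(stb$expression, stb$samples, prior_df = 0)
  m <- as.matrix(stb$expression[, -1])
  grp <- paste(stb$samples$genotype, stb$samples$age, sep = ".")
  dev <- m[, grp == "KO.old"] - rowMeans(m[, grp == "KO.young"])
  dev2 <- m[, grp == "WT.old"] - rowMeans(m[, grp == "WT.young"])
  # coefficient identity in the balanced design
  expect_equal(fb$log2fc, unname(rowMeans(dev) - rowMeans(dev2)),
               tolerance = 1e-10)

  expect_error(interaction_fit(stb$expression, stb$samples[-(1:4), ]),
               "Empty design cell")
})

test_that("DEG calling uses strict thresholds", {
  de <- tibble::tibble(
    gene = paste0("g", 1:6),
    fc = c(2.0, 1.50, 0.5, 0.67, 3.0, 0.2),
    fdr = c(0.05, 0.05, 0.05, 0.05, 0.10, 0.2),
    included = TRUE
  )
  degs <- call_degs(de)
  expect_identical(degs$up, "g1")      # g2 sits exactly on fc_up; g5 on fdr
  expect_identical(degs$down, "g3")    # g4 sits exactly on fc_down
})

test_that("detection-filtered genes stay in the table flagged as excluded", {
  tg <- make_two_group(n_genes = 30, n_per_group = 3, n_up = 0, n_down = 0,
                       seed = 81)
  det <- matrix(TRUE, 30, 6,
                dimnames = list(tg$expression$gene, tg$samples$sample_id))
  det[1:5, ] <- FALSE
  de <- fit_moderated(tg$expression, tg$samples, contrast = c("A", "B"),
                      detection = det)
  expect_identical(nrow(de), 30L)
  expect_identical(sum(de$included), 25L)
  expect_true(all(is.na(de$p[!de$included])))
  expect_true(all(!is.na(de$p[de$included])))
  # BH was applied over included genes only
  expect_equal(de$fdr[de$included], bh_adjust(de$p[de$included]))
})

test_that("DE recovery and FDR hold at the reference effect size", {
  hits <- 0; calls <- 0; fps <- 0
  for (seed in 1:5) {
    tg <- make_two_group(n_genes = 1000, n_per_group = 5, n_up = 50, n_down = 50,
                         effect = 1, prior_df = 40, prior_var = 0.0625,
                         seed = 100 + seed)
    de <- fit_moderated(tg$expression, tg$samples, contrast = c("A", "B"))
    degs <- call_degs(de, fdr = 0.10, fc_up = 1, fc_down = 1)
    called <- c(degs$up, degs$down)
    true <- c(tg$truth$up_genes, tg$truth$down_genes)
    hits <- hits + length(intersect(called, true))
    calls <- calls + length(called)
    fps <- fps + length(setdiff(called, true))
  }
  expect_gt(hits / (5 * 100), 0.90)   # sensitivity
  expect_lt(fps / calls, 0.12)        # realized false-discovery proportion
})
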