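make_fc <- function(n = 500, seed = 1, mean = 0, sd = 1) {
  withr::with_seed(seed, tibble::tibble(
    gene = sprintf("g%04d", 1:n),
    log2fc = rnorm(n, mean, sd)
  ))
}

test_that("directional bias shares its p-value with the rank-sum kernel", {
  fc <- make_fc(400, seed = 2)
  sig <- fc$gene[1:50]
  bias <- directional_bias(fc, sig, name = "s")
  ref <- rank_sum_test(fc$log2fc[1:50], fc$log2fc[-(1:50)], "two.sided")
  expect_identical(bias$p_value, ref$p_value)
  expect_identical(bias$n_used, 50L)
  # quartiles describe the linear FC of each side
  expect_equal(bias$fc_q50, median(2^fc$log2fc[1:50]))
  expect_equal(bias$bg_q50, median(2^fc$log2fc[-(1:50)]))
})

test_that("strong planted shifts give extreme signed p-values with the right sign", {
  fc <- make_fc(2000, seed = 3, sd = 0.1)
  fc$log2fc[1:100] <- fc$log2fc[1:100] + 1
  up <- directional_bias(fc, fc$gene[1:100])
  expect_lt(up$p_value, 1e-10)
  expect_gt(up$signed_log10p, 10)
  fc$log2fc[201:300] <- fc$log2fc[201:300] - 1
  down <- directional_bias(fc, fc$gene[201:300])
  expect_lt(down$signed_log10p, -10)
})

test_that("degenerate and missing-gene signature inputs are handled", {
  fc <- make_fc(100, seed = 4)
  expect_error(directional_bias(fc, fc$gene), "no background")
  expect_error(directional_bias(fc, c("absent1", "absent2")), "No gene")
  # absent genes are dropped but counted
  bias <- directional_bias(fc, c(fc$gene[1:10], "absent"))
  expect_identical(bias$n_used, 10L)
  expect_identical(bias$n_dropped, 1L)
})

test_that("signed log10 p follows the stated transform and clamps p = 0", {
  expect_equal(signed_log10p(0.01, +1), 2)
  expect_equal(signed_log10p(0.01, -1), -2)
  expect_equal(signed_log10p(1, -1), 0)
  expect_equal(signed_log10p(3.5e-25, +1), 24.456, tolerance = 1e-3)
  expect_warning(v <- signed_log10p(0, +1), "clamped")
  expect_true(is.finite(v) && v > 300)
  expect_error(signed_log10p(1.5, 1))
})

test_that("direction counts, Fisher p and the hypergeometric null band are coherent", {
  # balanced null: half the background up, signature at the null center
  withr::with_seed(5, {
    fc <- tibble::tibble(gene = sprintf("g%05d", 1:10100),
                         log2fc = rep(c(-1, 1), length.out = 10100))
  })
  sig <- fc$gene[1:100]  # 50 up / 50 down by construction
  res <- direction_count_test(fc, sig)
  expect_identical(res$n_up + res$n_down, 100L)
  expect_gt(res$p_value, 0.8)
  # the null band at p = 0.5 spans roughly 40-60 of 100
  expect_equal(res$null_lo, qhyper(0.025, 5050, 5050, 100))
  expect_equal(res$null_hi, qhyper(0.975, 5050, 5050, 100))
  expect_lt(res$null_lo, 45); expect_gt(res$null_lo, 35)
  expect_gt(res$null_hi, 55); expect_lt(res$null_hi, 65)

  # all-up signature against a balanced background: overwhelming
  fc2 <- fc
  fc2$log2fc[1:100] <- abs(fc2$log2fc[1:100]) + 0.5
  res2 <- direction_count_test(fc2, sig)
  expect_identical(res2$n_up, 100L)
  expect_lt(res2$p_value, 1e-20)

  # ties at FC exactly 1 count as down by default, up on request
  fc3 <- tibble::tibble(gene = c("a", "b", "c", "d"), log2fc = c(0, 0, 1, -1))
  r3 <- direction_count_test(fc3, c("a", "c"))
  expect_identical(r3$n_up, 1L)
  r3u <- direction_count_test(fc3, c("a", "c"), tie_up = TRUE)
  expect_identical(r3u$n_up, 2L)
})

test_that("overlap AUC equals the rank-sum U statistic scaled by n1*n2", {
  for (i in 1:25) {
    fc <- make_fc(200, seed = 100 + i)
    sig <- withr::with_seed(200 + i, sample(fc$gene, 20))
    oc <- overlap_curve(fc, sig)
    u <- rank_sum_test(fc$log2fc[fc$gene %in% sig],
                       fc$log2fc[!fc$gene %in% sig])$statistic
    expect_equal(oc$auc, u / (20 * 180), tolerance = 1e-9,
                 label = paste("auc-u instance", i))
  }
})

test_that("overlap curve extremes and tie handling behave", {
  fc <- tibble::tibble(gene = sprintf("g%03d", 1:100),
                       log2fc = seq(2, -2, length.out = 100))
  # signature = the 10 most-increased genes: maximal AUC of 1
  oc_top <- overlap_curve(fc, fc$gene[1:10])
  expect_equal(oc_top$auc, 1)
  oc_bot <- overlap_curve(fc, fc$gene[91:100])
  expect_equal(oc_bot$auc, 0)
  # reversing the ranking swaps the extremes
  expect_equal(overlap_curve(fc, fc$gene[91:100], decreasing = FALSE)$auc, 1)
  # fully tied statistic: the curve is the diagonal, AUC = 1/2
  fc_tied <- tibble::tibble(gene = fc$gene, log2fc = 0)
  expect_equal(overlap_curve(fc_tied, fc$gene[1:10])$auc, 0.5)
  # curve is monotone within the unit square
  expect_true(all(diff(oc_top$points$x) >= 0))
  expect_true(all(diff(oc_top$points$y) >= 0))
  expect_true(all(oc_top$points$y >= 0 & oc_top$points$y <= 1))
})

test_that("random signatures give AUC centered at one half", {
  fc <- make_fc(500, seed = 6)
  aucs <- vapply(1:300, function(i) {
    sig <- withr::with_seed(1000 + i, sample(fc$gene, 25))
    overlap_curve(fc, sig)$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.012)
})

test_that("signature ranking orders by signed log10 p and supports paired comparison", {
  fc <- make_fc(1000, seed = 7, sd = 0.3)
  fc$log2fc[1:60] <- fc$log2fc[1:60] + 1.2    # strongly up
  fc$log2fc[61:120] <- fc$log2fc[61:120] - 0.6  # moderately down
  sigs <- list(up_set = fc$gene[1:60], down_set = fc$gene[61:120],
               null_set = fc$gene[301:360])
  rk <- rank_signatures(fc, sigs)
  expect_identical(rk$signature[1], "up_set")
  expect_identical(rk$signature[3], "down_set")
  expect_true(all(diff(rk$signed_log10p) <= 0))
  expect_true(all(c("n_up", "direction_p", "auc") %in% names(rk)))

  # identical vectors: delta signed log10 p is zero for every signature
  rk2 <- rank_signatures(fc, sigs, compare = fc)
  expect_equal(rk2$delta_signed_log10p, rep(0, 3))

  # monotonicity: shifting the signature genes up strictly increases
  # the signed log10 p
  fc_shift <- fc
  idx <- fc_shift$gene %in% sigs$null_set
  fc_shift$log2fc[idx] <- fc_shift$log2fc[idx] + 0.4
  b0 <- directional_bias(fc, sigs$null_set)$signed_log10p
  b1 <- directional_bias(fc_shift, sigs$null_set)$signed_log10p
  expect_gt(b1, b0)
})

test_that("a null-sampled signature collection rejects at the nominal rate", {
  fc <- make_fc(2000, seed = 8)
  ps <- vapply(1:400, function(i) {
    sig <- withr::with_seed(3000 + i, sample(fc$gene, 50))
    directional_bias(fc, sig)$p_value
  }, numeric(1))
  rej <- mean(ps < 0.05)
  expect_gt(rej, 0.025)
  expect_lt(rej, 0.075)
})
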