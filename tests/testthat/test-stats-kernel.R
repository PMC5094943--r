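test_that("rank-sum test matches its exact examples and handles degeneracy", {
  expect_equal(rank_sum_test(1, 2, "less")$p_value, 0.5)
  expect_equal(rank_sum_test(1:3, 4:6, "less")$p_value, 0.05)
  res <- rank_sum_test(c(3, 3, 3), c(3, 3, 3))
  expect_equal(res$p_value, 1)
  expect_error(rank_sum_test(numeric(0), 1))
})

test_that("exact rank-sum path agrees with brute-force enumeration", {
  set.seed(101)
  for (i in 1:40) {
    m <- sample(1:5, 1); n <- sample(1:5, 1)
    repeat {  # tie-free draws: the exact path requires no ties
      x <- round(rnorm(m), 3); y <- round(rnorm(n), 3)
      if (!anyDuplicated(c(x, y))) break
    }
    for (alt in c("two.sided", "greater", "less")) {
      expect_equal(rank_sum_test(x, y, alt)$p_value,
                   oracle_rank_sum(x, y, alt),
                   tolerance = 1e-12,
                   label = paste("rank-sum", alt, "m", m, "n", n))
    }
  }
})

test_that("signed-rank test matches exact examples, enumeration, and its approximation switch", {
  expect_equal(signed_rank_test(c(1, 2, 3), "greater")$p_value, 0.125)
  res0 <- signed_rank_test(c(0, 0))
  expect_equal(res0$p_value, 1)
  expect_match(res0$method, "degenerate")

  set.seed(202)
  for (i in 1:40) {
    n <- sample(1:10, 1)
    d <- round(rnorm(n), 2)
    d <- d[d != 0]
    if (length(d) == 0) next
    for (alt in c("two.sided", "greater", "less")) {
      expect_equal(signed_rank_test(d, alt)$p_value,
                   oracle_signed_rank(d, alt),
                   tolerance = 1e-12,
                   label = paste("signed-rank", alt, "n", n))
    }
  }

  # exact and normal approximation agree closely at the switch boundary
  set.seed(7)
  d <- rnorm(15, mean = 0.3)
  p_exact <- signed_rank_test(d, "greater", exact_max = 15)$p_value
  p_approx <- signed_rank_test(d, "greater", exact_max = 1)$p_value
  expect_lt(abs(p_exact - p_approx), 1e-2)
})

test_that("Fisher exact matches enumeration, including the probability-sum two-sided rule", {
  expect_equal(fisher_exact(matrix(c(2, 0, 0, 2), 2))$p_value, 1 / 3)
  expect_equal(fisher_exact(matrix(c(5, 5, 0, 0), 2))$p_value, 1)
  expect_equal(fisher_exact(matrix(c(8, 2, 2, 8), 2))$p_value,
               oracle_fisher(matrix(c(8, 2, 2, 8), 2)), tolerance = 1e-12)
  expect_error(fisher_exact(matrix(0, 2, 2)), "grand total")

  set.seed(303)
  for (i in 1:40) {
    tab <- matrix(rpois(4, 3), 2)
    if (sum(tab) == 0 || sum(tab) > 30) next
    for (alt in c("two.sided", "greater", "less")) {
      expect_equal(fisher_exact(tab, alt)$p_value, oracle_fisher(tab, alt),
                   tolerance = 1e-12,
                   label = paste("fisher", alt, paste(tab, collapse = ",")))
    }
  }
})

test_that("hypergeometric enrichment matches direct summation", {
  expect_equal(hypergeom_enrich(2, 2, 2, 10)$p_value, 1 / 45)
  expect_equal(hypergeom_enrich(3, 3, 3, 3)$p_value, 1)
  expect_equal(hypergeom_enrich(0, 5, 3, 20)$p_value, 1)
  expect_error(hypergeom_enrich(5, 3, 10, 20), "Inconsistent")
  set.seed(404)
  for (i in 1:30) {
    N <- sample(5:30, 1); K <- sample(0:N, 1); n <- sample(1:N, 1)
    k_range <- max(0, n + K - N):min(n, K)
    k <- k_range[sample.int(length(k_range), 1)]
    expect_equal(hypergeom_enrich(k, n, K, N)$p_value,
                 oracle_hypergeom(k, n, K, N), tolerance = 1e-12)
  }
})

test_that("conditional set enrichment subtracts significant-child hits from parents", {
  universe <- paste0("g", 1:40)
  hits <- paste0("g", 1:10)
  sets <- list(child = paste0("g", 1:10),
               parent = paste0("g", 1:20),
               unrelated = paste0("g", 30:39))
  plain <- hypergeom_enrich_sets(sets, hits, universe)
  cond <- hypergeom_enrich_sets(sets, hits, universe,
                                children = list(parent = "child"))
  p_parent <- function(tbl) tbl$p_value[tbl$set == "parent"]
  expect_lt(p_parent(plain), 0.05)
  # all parent hits belong to the significant child, so the conditional
  # parent test loses its signal entirely
  expect_gt(p_parent(cond), p_parent(plain))
  expect_true(cond$conditioned[cond$set == "parent"])
  expect_equal(cond$p_value[cond$set == "child"],
               plain$p_value[plain$set == "child"])
})

test_that("BH adjustment is correct, order-preserving, and dominates the input", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.5, 1.2)))

  set.seed(505)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15) && all(adj <= 1))
    # permutation equivariance
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm]), adj[perm], tolerance = 1e-15)
  }
})

test_that("rank correlation behaves as Spearman's r_s", {
  expect_equal(rank_correlation(1:5, (1:5)^3), 1)
  expect_equal(rank_correlation(1:5, -(1:5)), -1)
  expect_equal(rank_correlation(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_warning(r <- rank_correlation(c(1, 1, 1), 1:3), "constant")
  expect_true(is.na(r))
  # invariance under strictly monotone transforms
  set.seed(606)
  x <- rnorm(30); y <- rnorm(30)
  expect_equal(rank_correlation(x, y), rank_correlation(exp(x), y^3 + y))
})

test_that("protected LSD produces a valid letter partition", {
  # identical groups share one letter
  d0 <- data.frame(v = rep(c(1, 2, 1.5), 4), g = rep(c("a", "b", "c", "d"), each = 3))
  l0 <- protected_lsd(d0, v, g)
  expect_true(all(tidy(l0)$letter == tidy(l0)$letter[1]))

  # two clearly separated groups: letters differ and p equals pooled t
  set.seed(9)
  d2 <- data.frame(v = c(rnorm(5, 0), rnorm(5, 4)), g = rep(c("lo", "hi"), each = 5))
  l2 <- protected_lsd(d2, v, g)
  expect_identical(sort(tidy(l2)$letter), c("a", "b"))
  tt <- t.test(v ~ g, data = d2, var.equal = TRUE)
  expect_equal(l2$pairwise_p["lo", "hi"], tt$p.value, tolerance = 1e-10)

  # letter sharing mirrors the pairwise p matrix exactly
  set.seed(10)
  d3 <- data.frame(v = c(rnorm(4, 0), rnorm(4, 0.3), rnorm(4, 3)),
                   g = rep(c("g1", "g2", "g3"), each = 4))
  l3 <- protected_lsd(d3, v, g)
  letts <- setNames(tidy(l3)$letter, tidy(l3)$group)
  share <- function(a, b) {
    any(strsplit(letts[a], "")[[1]] %in% strsplit(letts[b], "")[[1]])
  }
  for (a in names(letts)) for (b in names(letts)) {
    if (a == b) next
    expect_identical(share(a, b), unname(l3$pairwise_p[a, b] >= l3$alpha),
                     label = paste("sharing", a, b))
  }
  expect_true(all(nchar(letts) >= 1))

  # partition invariant to input order
  perm <- sample(nrow(d3))
  l3p <- protected_lsd(d3[perm, ], v, g)
  expect_identical(tidy(l3p), tidy(l3))

  # protection: omnibus-null data collapse to a single letter
  set.seed(11)
  d4 <- data.frame(v = rnorm(12), g = rep(c("x", "y", "z"), each = 4))
  l4 <- protected_lsd(d4, v, g)
  if (l4$f_p_value >= 0.05) expect_true(all(tidy(l4)$letter == "a"))
  expect_error(protected_lsd(data.frame(v = rep(1, 6), g = rep(c("a", "b"), 3)), v, g),
               "variance")
})

test_that("comparative-Ct arithmetic follows 2^-ddCt", {
  expect_equal(delta_delta_ct(20, 20, 0), 1)
  expect_equal(delta_delta_ct(21, 20, 0), 0.5)
  expect_equal(delta_delta_ct(18, 20, 0), 4)
  # calibrator_delta shifts the reference
  expect_equal(delta_delta_ct(22, 20, 2), 1)
  expect_error(delta_delta_ct(c(1, 2), 1))
  expect_error(delta_delta_ct(NA, 1))
})
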