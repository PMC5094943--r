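norm_alternative <- function(alternative) {
  alternative <- match.arg(gsub("-", ".", alternative),
                           c("two.sided", "greater", "less"))
  alternative
}

test_result <- function(statistic, p_value, alternative, method) {
  out <- tibble::tibble(
    statistic = as.numeric(statistic),
    p_value = as.numeric(p_value),
    alternative = alternative,
    method = method
  )
  class(out) <- c("sig_test", class(out))
  out
}

#' Wilcoxon-Mann-Whitney rank-sum test
#'
#' Mid-rank handling of ties.  The null distribution is enumerated exactly
#' when the combined sample size is at most 12 and there are no ties;
#' otherwise a normal approximation with tie-corrected variance and
#' continuity correction is used.  The reported statistic is the
#' Mann-Whitney U for the first sample.
#'
#' @param x,y Numeric samples (each non-empty).
#' @param alternative `"two.sided"` (default), `"greater"` (x shifted up),
#'   or `"less"`.
#' @param exact_max Combined sample size at or below which the exact null
#'   is enumerated (ties permitting).
#' @return A one-row tibble: `statistic`, `p_value`, `alternative`,
#'   `method`.
#' @export
rank_sum_test <- function(x, y, alternative = "two.sided", exact_max = 12L) {
  alternative <- norm_alternative(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 1 || length(y) < 1) abort("Both samples must be non-empty.")
  if (anyNA(x) || anyNA(y)) abort("Missing values are not supported.")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y) <= exact_max) && !ties
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = alternative, exact = exact,
                correct = TRUE)
  )
  method <- if (exact) "rank-sum: exact enumeration" else
    "rank-sum: normal approximation (tie-corrected, continuity-corrected)"
  p <- wt$p.value
  if (!is.finite(p)) {  # every observation tied: no rank variation
    p <- 1
    method <- "rank-sum: degenerate (no rank variation)"
  }
  test_result(unname(wt$statistic), min(p, 1), alternative, method)
}

# exact null distribution of 2*W+ (doubled signed-rank sum, so mid-ranks
# become integers) by dynamic-programming convolution over sign patterns
signed_rank_exact_p <- function(w_plus, ranks, alternative) {
  ir <- as.integer(round(2 * ranks))
  total <- sum(ir)
  counts <- numeric(total + 1L)   # index k+1 holds #patterns with 2W+ = k
  counts[1] <- 1
  for (r in ir) {
    shifted <- c(numeric(r), counts[seq_len(total + 1L - r)])
    counts <- counts + shifted
  }
  npat <- 2^length(ir)
  w2 <- round(2 * w_plus)
  p_ge <- sum(counts[(w2 + 1L):(total + 1L)]) / npat
  p_le <- sum(counts[1:(w2 + 1L)]) / npat
  switch(alternative,
         greater = p_ge,
         less = p_le,
         two.sided = min(1, 2 * min(p_ge, p_le)))
}

#' Wilcoxon signed-rank test on paired differences
#'
#' Zero differences are dropped.  The null is enumerated exactly (all sign
#' patterns, with mid-ranks for tied magnitudes) when at most `exact_max`
#' non-zero differences remain; otherwise a normal approximation with
#' tie-corrected variance and continuity correction is used.  The statistic
#' is W+, the sum of ranks of positive differences.
#'
#' @param d Numeric vector of paired differences.
#' @param alternative `"two.sided"`, `"greater"` (positive shift), or
#'   `"less"`.
#' @param exact_max Largest n for which the exact null is enumerated.
#' @return A one-row tibble: `statistic`, `p_value`, `alternative`,
#'   `method`.  If every difference is zero the result is flagged
#'   degenerate with p = 1.
#' @export
signed_rank_test <- function(d, alternative = "two.sided", exact_max = 15L) {
  alternative <- norm_alternative(alternative)
  d <- as.numeric(d)
  if (length(d) < 1) abort("`d` must be non-empty.")
  if (anyNA(d)) abort("Missing values are not supported.")
  d <- d[d != 0]
  if (length(d) == 0) {
    return(test_result(0, 1, alternative,
                       "signed-rank: degenerate (all differences zero)"))
  }
  n <- length(d)
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  if (n <= exact_max) {
    p <- signed_rank_exact_p(w_plus, r, alternative)
    return(test_result(w_plus, p, alternative, "signed-rank: exact enumeration"))
  }
  mu <- n * (n + 1) / 4
  tie_tab <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
  z_num <- w_plus - mu
  cc <- 0.5
  p <- switch(alternative,
    greater = pnorm((z_num - cc) / sqrt(sigma2), lower.tail = FALSE),
    less = pnorm((z_num + cc) / sqrt(sigma2)),
    two.sided = min(1, 2 * min(
      pnorm((z_num - cc) / sqrt(sigma2), lower.tail = FALSE),
      pnorm((z_num + cc) / sqrt(sigma2))
    ))
  )
  test_result(w_plus, p, alternative,
              "signed-rank: normal approximation (tie-corrected, continuity-corrected)")
}

#' Fisher's exact test on a 2x2 table
#'
#' Hypergeometric enumeration over tables with the observed margins.  The
#' two-sided p-value sums the probabilities of all tables no more probable
#' than the observed one (the convention of mainstream implementations,
#' not the doubling convention).  The statistic is the conditional
#' maximum-likelihood odds ratio.
#'
#' @param table A 2x2 matrix of non-negative counts.
#' @param alternative `"two.sided"`, `"greater"`, or `"less"` (odds ratio
#'   above / below 1).
#' @return A one-row tibble: `statistic`, `p_value`, `alternative`,
#'   `method`.
#' @export
fisher_exact <- function(table, alternative = "two.sided") {
  alternative <- norm_alternative(alternative)
  table <- as.matrix(table)
  if (!identical(dim(table), c(2L, 2L))) abort("`table` must be 2x2.")
  if (any(table < 0) || any(table != round(table))) {
    abort("`table` must hold non-negative integers.")
  }
  if (sum(table) == 0) abort("The table's grand total is zero.")
  ft <- fisher.test(table, alternative = alternative)
  test_result(unname(ft$estimate), min(ft$p.value, 1), alternative,
              "Fisher exact: hypergeometric enumeration")
}

#' Hypergeometric over-representation test
#'
#' Upper-tail probability of observing `hits` or more members of a gene set
#' among the `universe_hits` interesting genes, drawing `set_size` genes
#' from a universe of `universe_size`.
#'
#' @param hits Observed overlap count.
#' @param set_size Size of the gene set drawn.
#' @param universe_hits Number of interesting genes in the universe.
#' @param universe_size Universe size.
#' @return A one-row tibble with the overlap as statistic.
#' @export
hypergeom_enrich <- function(hits, set_size, universe_hits, universe_size) {
  vals <- c(hits, set_size, universe_hits, universe_size)
  if (any(vals < 0) || any(vals != round(vals))) abort("Counts must be non-negative integers.")
  if (hits > set_size || set_size > universe_size || hits > universe_hits ||
      universe_hits > universe_size ||
      set_size - hits > universe_size - universe_hits) {
    abort("Inconsistent counts for a hypergeometric test.")
  }
  p <- phyper(hits - 1, universe_hits, universe_size - universe_hits,
              set_size, lower.tail = FALSE)
  test_result(hits, min(p, 1), "greater", "hypergeometric: upper tail")
}

#' Hypergeometric enrichment over a gene-set collection
#'
#' Tests each supplied set for over-representation of `hits` within
#' `universe`.  When a `children` map is supplied (named list:
#' parent set name -> character vector of child set names), hit genes
#' belonging to significant children (p < `alpha`) are removed from the
#' parent's set before the parent is tested, in one pass - an
#' ontology-free analogue of conditional enrichment testing.
#'
#' @param sets Gene sets (tibble from [read_gmt()] or a named list).
#' @param hits Character vector of interesting genes (e.g. DEGs).
#' @param universe Character vector of background genes.
#' @param children Optional named list mapping a parent set name to its
#'   child set names.
#' @param alpha Child-significance cutoff used by the conditional pass.
#' @return A tibble with one row per set: overlap counts, raw p, BH FDR,
#'   and whether the conditional adjustment changed the set.
#' @export
hypergeom_enrich_sets <- function(sets, hits, universe, children = NULL,
                                  alpha = 0.05) {
  sets_l <- gene_set_list(sets)
  universe <- unique(as.character(universe))
  hits <- intersect(unique(as.character(hits)), universe)
  sets_l <- lapply(sets_l, intersect, universe)
  one <- function(members) {
    k <- length(intersect(members, hits))
    hypergeom_enrich(k, length(members), length(hits), length(universe))$p_value
  }
  p0 <- vapply(sets_l, one, numeric(1))
  conditioned <- rep(FALSE, length(sets_l))
  if (!is.null(children)) {
    sig_children <- names(p0)[p0 < alpha]
    for (parent in names(children)) {
      if (!parent %in% names(sets_l)) next
      kids <- intersect(children[[parent]], sig_children)
      kids <- setdiff(kids, parent)
      if (length(kids) == 0) next
      remove <- intersect(unique(unlist(sets_l[kids])), hits)
      reduced <- setdiff(sets_l[[parent]], remove)
      sets_l[[parent]] <- reduced
      conditioned[names(sets_l) == parent] <- TRUE
    }
  }
  out <- tibble::tibble(
    set = names(sets_l),
    set_size = lengths(sets_l),
    hits = vapply(sets_l, function(m) length(intersect(m, hits)), integer(1)),
    universe_hits = length(hits),
    universe_size = length(universe),
    p_value = vapply(sets_l, function(m) {
      if (length(m) == 0) return(1)
      one(m)
    }, numeric(1)),
    conditioned = conditioned
  )
  out$fdr <- bh_adjust(out$p_value)
  dplyr::arrange(out, .data$p_value)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement; the input order is
#' preserved in the output.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  p <- as.numeric(p)
  if (anyNA(p) || any(p < 0 | p > 1)) abort("p-values must lie in [0, 1].")
  p.adjust(p, method = "BH")
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks.
#'
#' @param x,y Numeric vectors of equal length (at least 3).
#' @return The rank correlation, or `NA` (with a warning) when either
#'   vector is constant.
#' @export
rank_correlation <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 3) abort("Need at least 3 observations.")
  if (anyNA(x) || anyNA(y)) abort("Missing values are not supported.")
  if (sd(x) == 0 || sd(y) == 0) {
    warn("Rank correlation undefined for a constant vector; returning NA.")
    return(NA_real_)
  }
  cor(x, y, method = "spearman")
}

# Piepho-style insert-and-absorb compact letter display.
# `nonsig[i, j]` TRUE when groups i and j are NOT significantly different.
compact_letters <- function(group_names, nonsig, order_by) {
  cols <- list(group_names)
  pairs <- which(!nonsig & upper.tri(nonsig), arr.ind = TRUE)
  if (nrow(pairs) > 0) {
    for (k in seq_len(nrow(pairs))) {
      gi <- group_names[pairs[k, 1]]; gj <- group_names[pairs[k, 2]]
      new_cols <- list()
      for (col in cols) {
        if (gi %in% col && gj %in% col) {
          new_cols <- c(new_cols, list(setdiff(col, gi)), list(setdiff(col, gj)))
        } else {
          new_cols <- c(new_cols, list(col))
        }
      }
      # absorb: drop columns that are subsets of another column
      keep <- rep(TRUE, length(new_cols))
      for (a in seq_along(new_cols)) {
        for (b in seq_along(new_cols)) {
          if (a != b && keep[a] && keep[b] &&
              all(new_cols[[a]] %in% new_cols[[b]]) &&
              !(all(new_cols[[b]] %in% new_cols[[a]]) && a < b)) {
            keep[a] <- FALSE
          }
        }
      }
      cols <- new_cols[keep]
    }
  }
  # order letter columns by the best-ranked group they contain
  rank_of <- setNames(rank(-order_by, ties.method = "first"), group_names)
  first_rank <- vapply(cols, function(col) min(rank_of[col]), numeric(1))
  cols <- cols[order(first_rank)]
  letters_pool <- c(letters, paste0(rep(letters, each = 26), letters))
  out <- setNames(rep("", length(group_names)), group_names)
  for (i in seq_along(cols)) {
    for (g in cols[[i]]) out[g] <- paste0(out[g], letters_pool[i])
  }
  out
}

#' Protected Fisher's LSD with compact letter display
#'
#' One-way ANOVA followed by pairwise least-significant-difference t-tests
#' using the pooled mean-square error and its degrees of freedom.  In the
#' protected variant (default) pairwise comparisons are only declared
#' significant when the omnibus F-test rejects at `alpha`; otherwise all
#' groups share one letter.  Two groups share a letter iff their pairwise
#' LSD p-value is at or above `alpha`.
#'
#' @param data A data frame of observations.
#' @param value Column (tidy-select, unquoted) holding the response.
#' @param group Column (unquoted) holding the group labels.
#' @param alpha Significance level.
#' @param protect Gate pairwise tests on the omnibus F-test.
#' @return An object of class `sigshift_lsd`: letters per group (ordered
#'   by decreasing mean), the pairwise p matrix, pooled MSE and df, and
#'   the omnibus F statistic and p-value.  See [tidy.sigshift_lsd()].
#' @export
protected_lsd <- function(data, value, group, alpha = 0.05, protect = TRUE) {
  value <- dplyr::pull(data, {{ value }})
  group <- as.character(dplyr::pull(data, {{ group }}))
  ok <- !is.na(value) & !is.na(group)
  value <- value[ok]; group <- group[ok]
  counts <- table(group)
  if (length(counts) < 2) abort("Need at least 2 groups.")
  if (any(counts < 2)) abort("Every group needs at least 2 observations.")
  groups <- names(counts)
  means <- tapply(value, group, mean)[groups]
  ns <- as.numeric(counts[groups])
  ss_within <- sum(tapply(value, group, function(v) sum((v - mean(v))^2)))
  df_within <- sum(ns) - length(groups)
  mse <- ss_within / df_within
  if (mse == 0) abort("Zero within-group variance everywhere; LSD is undefined.")
  grand <- mean(value)
  ss_between <- sum(ns * (means - grand)^2)
  df_between <- length(groups) - 1
  f_stat <- (ss_between / df_between) / mse
  f_p <- pf(f_stat, df_between, df_within, lower.tail = FALSE)

  k <- length(groups)
  pmat <- matrix(1, k, k, dimnames = list(groups, groups))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      se <- sqrt(mse * (1 / ns[i] + 1 / ns[j]))
      tval <- (means[i] - means[j]) / se
      pij <- 2 * pt(-abs(tval), df_within)
      pmat[i, j] <- pmat[j, i] <- pij
    }
  }
  gated <- protect && f_p >= alpha
  nonsig <- if (gated) matrix(TRUE, k, k, dimnames = dimnames(pmat)) else pmat >= alpha
  letts <- compact_letters(groups, nonsig, order_by = means)
  ord <- order(-means)
  letters_tbl <- tibble::tibble(
    group = groups[ord], n = as.integer(ns[ord]),
    mean = as.numeric(means[ord]), letter = unname(letts[groups[ord]])
  )
  structure(
    list(letters = letters_tbl, pairwise_p = pmat, mse = mse,
         df = df_within, f_statistic = f_stat, f_p_value = f_p,
         alpha = alpha, protected = protect, gated = gated),
    class = "sigshift_lsd"
  )
}

#' @describeIn protected_lsd Letters table (group, n, mean, letter).
#' @param x A `sigshift_lsd` object.
#' @param ... Unused.
#' @export
tidy.sigshift_lsd <- function(x, ...) x$letters

#' @describeIn protected_lsd One-row summary with the omnibus F-test and
#'   pooled error variance.
#' @export
glance.sigshift_lsd <- function(x, ...) {
  tibble::tibble(f_statistic = x$f_statistic, f_p_value = x$f_p_value,
                 mse = x$mse, df = x$df, n_groups = nrow(x$letters),
                 alpha = x$alpha, gated = x$gated)
}

#' @export
print.sigshift_lsd <- function(x, ...) {
  cat("Protected Fisher's LSD (alpha =", x$alpha, ")\n")
  cat(sprintf("Omnibus F = %.3f, p = %.4g, pooled MSE = %.4g on %d df%s\n",
              x$f_statistic, x$f_p_value, x$mse, x$df,
              if (x$gated) " [omnibus not significant: one letter]" else ""))
  print(x$letters)
  invisible(x)
}

#' Relative expression by the comparative Ct method
#'
#' Computes `2^-ddCt` where `dCt = ct_target - ct_endogenous` and
#' `ddCt = dCt - calibrator_delta`.  With `calibrator_delta` equal to the
#' mean dCt of the calibrator group, the calibrator group's mean relative
#' expression on the dCt scale is 1.
#'
#' @param ct_target Ct values of the target gene.
#' @param ct_endogenous Ct values of the endogenous control, same samples.
#' @param calibrator_delta The calibrator group's mean dCt.
#' @return Relative expression values, vectorized.
#' @export
delta_delta_ct <- function(ct_target, ct_endogenous, calibrator_delta = 0) {
  if (length(ct_target) != length(ct_endogenous)) {
    abort("`ct_target` and `ct_endogenous` must have equal length.")
  }
  if (anyNA(ct_target) || anyNA(ct_endogenous) ||
      any(!is.finite(c(ct_target, ct_endogenous, calibrator_delta)))) {
    abort("Ct values must be finite.")
  }
  2^-((ct_target - ct_endogenous) - calibrator_delta)
}
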