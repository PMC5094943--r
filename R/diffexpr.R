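# expression tibble -> numeric matrix with gene rownames
expr_matrix <- function(expr) {
  expr <- validate_expression(expr)
  m <- as.matrix(expr[, -1, drop = FALSE])
  rownames(m) <- expr$gene
  m
}

detection_matrix <- function(detection) {
  detection <- tibble::as_tibble(detection)
  m <- as.matrix(detection[, -1, drop = FALSE])
  rownames(m) <- as.character(detection[[1]])
  storage.mode(m) <- "logical"
  m
}

#' Above-background detection call for one probe set
#'
#' One-sided Wilcoxon signed-rank test that perfect-match probe
#' intensities exceed their paired mismatch intensities; the probe set is
#' called detected when p < `alpha`.
#'
#' @param pm,mm Paired probe intensity vectors (equal length, at least 4).
#' @param alpha Significance level for the call.
#' @return A one-row tibble: `detected`, `p_value`, `n_probes`.
#' @export
detection_call <- function(pm, mm, alpha = 0.05) {
  if (length(pm) != length(mm)) abort("`pm` and `mm` must have equal length.")
  if (length(pm) < 4) abort("Need at least 4 probe pairs.")
  res <- signed_rank_test(pm - mm, alternative = "greater")
  tibble::tibble(detected = res$p_value < alpha, p_value = res$p_value,
                 n_probes = length(pm))
}

#' Gene-level detection from multiple probe sets
#'
#' A gene is detected in a sample when at least one of its probe sets is
#' detected.
#'
#' @param probe_sets A list of `list(pm =, mm =)` probe-pair vectors, one
#'   element per probe set.
#' @inheritParams detection_call
#' @return Logical scalar.
#' @export
gene_detected <- function(probe_sets, alpha = 0.05) {
  any(vapply(probe_sets,
             function(ps) detection_call(ps$pm, ps$mm, alpha)$detected,
             logical(1)))
}

#' Detection-based gene inclusion filter
#'
#' A gene enters a comparison when it is detected above background in at
#' least `min_fraction` of the comparison's samples.  The count threshold
#' is `ceiling(min_fraction * n)`: a gene must be detected in at least
#' n/3 samples exactly, rounded up when n/3 is not an integer.
#'
#' @param detection Logical detection table (gene column plus one logical
#'   column per sample) or logical matrix with gene rownames.
#' @param samples Character vector of sample ids in the comparison.
#' @param min_fraction Minimum detected fraction (default 1/3).
#' @return Character vector of included gene ids.
#' @export
expression_filter <- function(detection, samples, min_fraction = 1 / 3) {
  m <- if (is.matrix(detection)) detection else detection_matrix(detection)
  if (length(samples) == 0) abort("The comparison has no samples.")
  missing <- setdiff(samples, colnames(m))
  if (length(missing) > 0) {
    abort(paste0("Samples absent from the detection matrix: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  n <- length(samples)
  need <- ceiling(min_fraction * n - 1e-9)
  counts <- rowSums(m[, samples, drop = FALSE])
  included <- rownames(m)[counts >= need]
  sig_log("Detection filter: ", length(included), " of ", nrow(m),
          " genes detected in >= ", need, " of ", n, " samples.")
  included
}

# Newton inversion of the trigamma function (used by the moments
# estimator of the variance-prior degrees of freedom)
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (-dif / x < 1e-8) break
  }
  x
}

#' Estimate the empirical-Bayes variance prior
#'
#' Fits the scaled-F model `s^2 ~ s0^2 * F(df, d0)` to observed gene-wise
#' residual variances by the closed-form moments method on log variances
#' (digamma/trigamma matching), returning the prior degrees of freedom
#' `d0` and prior variance `s0^2` toward which gene variances are shrunk.
#'
#' @param s2 Gene-wise residual variances (positive; non-positive values
#'   are excluded from estimation).
#' @param df Residual degrees of freedom per gene (scalar or vector).
#' @return A list with elements `d0` (possibly `Inf`) and `s0_2`.
#' @export
estimate_variance_prior <- function(s2, df) {
  df <- rep_len(df, length(s2))
  ok <- is.finite(s2) & s2 > 0 & df > 0
  if (sum(ok) < 2) abort("Need at least 2 positive variances to estimate the prior.")
  s2 <- s2[ok]; df <- df[ok]
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- sum((e - emean)^2) / (length(e) - 1) - mean(trigamma(df / 2))
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_2 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_2 <- exp(emean)
  }
  list(d0 = d0, s0_2 = s0_2)
}

# shrink gene variances toward the prior; returns moderated variances and
# total df.  d0 = 0 leaves variances untouched; d0 = Inf replaces them.
squeeze_variance <- function(s2, df, d0, s0_2) {
  if (is.infinite(d0)) {
    list(s2_tilde = rep_len(s0_2, length(s2)), df_total = rep_len(Inf, length(s2)))
  } else {
    list(s2_tilde = (d0 * s0_2 + df * s2) / (d0 + df), df_total = d0 + df)
  }
}

de_result <- function(genes, included, mean_a, mean_b, log2fc, se_scale, s2,
                      df_resid, prior, contrast, n_a, n_b) {
  sq <- squeeze_variance(s2, df_resid, prior$d0, prior$s0_2)
  se <- sqrt(sq$s2_tilde * se_scale)
  t_mod <- ifelse(se == 0,
                  ifelse(log2fc == 0, 0, sign(log2fc) * Inf),
                  log2fc / se)
  p <- 2 * pt(-abs(t_mod), sq$df_total)
  out <- tibble::tibble(
    gene = genes,
    mean_a = unname(mean_a), mean_b = unname(mean_b),
    log2fc = unname(log2fc), fc = unname(2^log2fc),
    t = unname(t_mod), df_total = unname(rep_len(sq$df_total, length(genes))),
    p = unname(p),
    fdr = NA_real_, included = included
  )
  out$fdr[included] <- bh_adjust(p[included])
  out[!included, c("mean_a", "mean_b", "log2fc", "fc", "t", "df_total", "p")] <- NA
  structure(out,
            contrast = contrast, prior = prior,
            n_per_group = c(n_a, n_b),
            n_included = sum(included),
            class = c("sigshift_de", class(out)))
}

#' Moderated two-group differential expression
#'
#' Gene-wise least squares on log2 expression for one two-group contrast.
#' Residual variances are shrunk toward the empirical-Bayes prior
#' (see [estimate_variance_prior()]); the moderated t-statistic is the
#' log2 fold change over its shrunk standard error, with `d0 + df`
#' degrees of freedom.  P-values are two-sided; BH adjustment is applied
#' over included genes only.  Genes excluded by the detection filter stay
#' in the table with `included = FALSE` and missing statistics.
#'
#' @param expr Expression tibble (see [validate_expression()]).
#' @param samples Sample table with `sample_id` and the grouping column.
#' @param contrast Length-2 character: (numerator group, denominator
#'   group); the fold change is numerator over denominator.
#' @param group_col Name of the grouping column in `samples`.
#' @param detection Optional detection table passed to
#'   [expression_filter()].
#' @param min_detect_fraction Detection fraction threshold.
#' @param prior_df,prior_var Override the estimated prior (`prior_df = 0`
#'   recovers the ordinary pooled t; `prior_df = Inf` uses the common
#'   variance `prior_var` for every gene).  When `prior_df = Inf` and
#'   `prior_var` is missing, the prior variance is the mean gene variance.
#' @return A tibble of class `sigshift_de` with per-gene columns `gene`,
#'   `mean_a`, `mean_b`, `log2fc`, `fc`, `t`, `df_total`, `p`, `fdr`,
#'   `included`; the contrast label and fitted prior are attached as
#'   attributes (see [glance.sigshift_de()]).
#' @export
fit_moderated <- function(expr, samples, contrast, group_col = "group",
                          detection = NULL, min_detect_fraction = 1 / 3,
                          prior_df = NULL, prior_var = NULL) {
  m <- expr_matrix(expr)
  samples <- validate_samples(samples)
  if (!group_col %in% names(samples)) {
    abort(paste0("Sample table has no '", group_col, "' column."))
  }
  if (length(contrast) != 2) abort("`contrast` must name two groups.")
  grp <- setNames(as.character(samples[[group_col]]), samples$sample_id)
  ids_a <- names(grp)[grp == contrast[1]]
  ids_b <- names(grp)[grp == contrast[2]]
  for (k in 1:2) {
    if (length(list(ids_a, ids_b)[[k]]) == 0) {
      abort(paste0("Group '", contrast[k], "' has no samples."))
    }
  }
  missing <- setdiff(c(ids_a, ids_b), colnames(m))
  if (length(missing) > 0) {
    abort(paste0("Samples absent from the expression table: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  n_a <- length(ids_a); n_b <- length(ids_b)
  df_resid <- n_a + n_b - 2
  if (df_resid < 1) {
    abort(paste0("No residual degrees of freedom: groups '", contrast[1],
                 "' and '", contrast[2], "' have ", n_a, " + ", n_b,
                 " samples."))
  }
  included <- rep(TRUE, nrow(m))
  if (!is.null(detection)) {
    inc <- expression_filter(detection, c(ids_a, ids_b), min_detect_fraction)
    included <- rownames(m) %in% inc
  }
  ma <- m[, ids_a, drop = FALSE]
  mb <- m[, ids_b, drop = FALSE]
  mean_a <- rowMeans(ma)
  mean_b <- rowMeans(mb)
  ss <- rowSums((ma - mean_a)^2) + rowSums((mb - mean_b)^2)
  s2 <- ss / df_resid
  prior <- resolve_prior(s2[included], df_resid, prior_df, prior_var)
  de_result(rownames(m), included, mean_a, mean_b, mean_a - mean_b,
            se_scale = 1 / n_a + 1 / n_b, s2 = s2, df_resid = df_resid,
            prior = prior,
            contrast = paste0(contrast[1], "_vs_", contrast[2]),
            n_a = n_a, n_b = n_b)
}

resolve_prior <- function(s2_included, df_resid, prior_df, prior_var) {
  if (is.null(prior_df)) {
    estimate_variance_prior(s2_included, df_resid)
  } else if (prior_df == 0) {
    list(d0 = 0, s0_2 = prior_var %||% 0)
  } else if (is.infinite(prior_df)) {
    list(d0 = Inf, s0_2 = prior_var %||% mean(s2_included))
  } else {
    list(d0 = prior_df,
         s0_2 = prior_var %||% estimate_variance_prior(s2_included, df_resid)$s0_2)
  }
}

#' Moderated genotype-by-age interaction test
#'
#' Two-factor cell-means model per gene; the interaction coefficient is
#' the aging log2 fold change in KO minus the aging log2 fold change in
#' WT, i.e. (old-KO minus young-KO) minus (old-WT minus young-WT).  The
#' coefficient is tested by a moderated t with variance pooled across the
#' four cells and shrunk as in [fit_moderated()].
#'
#' @inheritParams fit_moderated
#' @param genotype_col,age_col Factor columns in `samples`; levels must be
#'   WT/KO and young/old, and all four cells must be non-empty.
#' @return A `sigshift_de` tibble; `log2fc` holds the interaction
#'   coefficient (log2 units) and `fc = 2^log2fc`.
#' @export
interaction_fit <- function(expr, samples, genotype_col = "genotype",
                            age_col = "age", detection = NULL,
                            min_detect_fraction = 1 / 3,
                            prior_df = NULL, prior_var = NULL) {
  m <- expr_matrix(expr)
  samples <- validate_samples(samples)
  gt <- as.character(samples[[genotype_col]])
  ag <- as.character(samples[[age_col]])
  cell <- paste(gt, ag, sep = ".")
  wanted <- c("KO.old", "KO.young", "WT.old", "WT.young")
  ids <- lapply(wanted, function(w) samples$sample_id[cell == w])
  names(ids) <- wanted
  empty <- wanted[lengths(ids) == 0]
  if (length(empty) > 0) {
    abort(paste0("Empty design cell(s): ", paste(empty, collapse = ", ")))
  }
  ns <- lengths(ids)
  n <- sum(ns)
  df_resid <- n - 4L
  if (df_resid < 1) abort("No residual degrees of freedom in the 2x2 design.")
  included <- rep(TRUE, nrow(m))
  if (!is.null(detection)) {
    inc <- expression_filter(detection, unlist(ids), min_detect_fraction)
    included <- rownames(m) %in% inc
  }
  cell_means <- vapply(ids, function(s) rowMeans(m[, s, drop = FALSE]),
                       numeric(nrow(m)))
  if (is.null(dim(cell_means))) {  # single-gene input
    cell_means <- matrix(cell_means, nrow = 1, dimnames = list(NULL, wanted))
  }
  ss <- Reduce(`+`, lapply(wanted, function(w) {
    rowSums((m[, ids[[w]], drop = FALSE] - cell_means[, w])^2)
  }))
  s2 <- ss / df_resid
  coef <- (cell_means[, "KO.old"] - cell_means[, "KO.young"]) -
          (cell_means[, "WT.old"] - cell_means[, "WT.young"])
  se_scale <- sum(1 / ns)
  prior <- resolve_prior(s2[included], df_resid, prior_df, prior_var)
  de_result(rownames(m), included,
            mean_a = cell_means[, "KO.old"] - cell_means[, "KO.young"],
            mean_b = cell_means[, "WT.old"] - cell_means[, "WT.young"],
            log2fc = coef, se_scale = se_scale, s2 = s2,
            df_resid = df_resid, prior = prior,
            contrast = "genotype_x_age",
            n_a = sum(ns[c("KO.old", "KO.young")]),
            n_b = sum(ns[c("WT.old", "WT.young")]))
}

#' Call differentially expressed genes
#'
#' Up: `fdr < fdr_threshold` and linear `fc > fc_up`; down: `fdr <
#' fdr_threshold` and `fc < fc_down`.  Inequalities are strict, so a gene
#' sitting exactly on a threshold is not called.
#'
#' @param de A `sigshift_de` result.
#' @param fdr FDR threshold.
#' @param fc_up,fc_down Linear fold-change thresholds.
#' @return A list with character vectors `up` and `down`.
#' @export
call_degs <- function(de, fdr = 0.10, fc_up = 1.50, fc_down = 0.67) {
  ok <- de$included & !is.na(de$fdr)
  list(
    up = de$gene[ok & de$fdr < fdr & de$fc > fc_up],
    down = de$gene[ok & de$fdr < fdr & de$fc < fc_down]
  )
}

#' @describeIn fit_moderated Per-gene result table (drops the class).
#' @param x A `sigshift_de` object.
#' @param ... Unused.
#' @export
tidy.sigshift_de <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "sigshift_de")
  out
}

#' @describeIn fit_moderated One-row fit summary: contrast, group sizes,
#'   genes included, and the fitted variance prior (`prior_df`,
#'   `prior_var`).
#' @export
glance.sigshift_de <- function(x, ...) {
  prior <- attr(x, "prior")
  npg <- attr(x, "n_per_group")
  tibble::tibble(
    contrast = attr(x, "contrast"),
    n_genes = nrow(x),
    n_included = attr(x, "n_included"),
    n_a = npg[1], n_b = npg[2],
    prior_df = prior$d0, prior_var = prior$s0_2
  )
}

#' @export
print.sigshift_de <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("Moderated DE: %s (%d + %d samples); %d/%d genes included; prior df = %.3g, prior var = %.3g\n",
              g$contrast, g$n_a, g$n_b, g$n_included, g$n_genes,
              g$prior_df, g$prior_var))
  NextMethod()
}
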