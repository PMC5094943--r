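#' Extract a fold-change vector from a differential-expression result
#'
#' @param x A `sigshift_de` result (included genes only) or any data frame
#'   with a `gene` column plus `log2fc` and/or `fc`.
#' @return A tibble with columns `gene`, `log2fc`, `fc`, one row per gene.
#' @export
as_fc_vector <- function(x) {
  tab <- tibble::as_tibble(x)
  if (!"gene" %in% names(tab)) abort("Need a `gene` column.")
  if ("included" %in% names(tab)) tab <- tab[tab$included %in% TRUE, , drop = FALSE]
  if (!"log2fc" %in% names(tab)) {
    if (!"fc" %in% names(tab)) abort("Need a `log2fc` or `fc` column.")
    tab$log2fc <- log2(tab$fc)
  }
  if (!"fc" %in% names(tab)) tab$fc <- 2^tab$log2fc
  tab <- tab[, c("gene", "log2fc", "fc")]
  tab <- tab[complete.cases(tab), , drop = FALSE]
  if (any(!is.finite(tab$log2fc)) || any(tab$fc <= 0)) {
    abort("Fold changes must be finite and positive.")
  }
  if (anyDuplicated(tab$gene)) abort("Duplicate gene in fold-change vector.")
  tab
}

# split a fold-change vector by signature membership; drops (and logs)
# signature genes absent from the vector
split_by_signature <- function(fc, signature, sig_name = NULL) {
  fc <- as_fc_vector(fc)
  genes <- if (is.data.frame(signature)) as.character(signature$gene)
           else as.character(signature)
  genes <- unique(genes)
  present <- intersect(genes, fc$gene)
  dropped <- length(genes) - length(present)
  if (dropped > 0) {
    sig_log("Signature '", sig_name %||% "?", "': ", dropped,
            " gene(s) absent from the fold-change vector were dropped.")
  }
  if (length(present) == 0) {
    abort(paste0("No gene of signature '", sig_name %||% "?",
                 "' is present in the fold-change vector."))
  }
  in_sig <- fc$gene %in% present
  if (all(in_sig)) {
    abort(paste0("Signature '", sig_name %||% "?",
                 "' covers the whole fold-change vector; no background remains."))
  }
  list(sig = fc[in_sig, ], bg = fc[!in_sig, ], n_dropped = dropped)
}

#' Directional fold-change bias of a signature
#'
#' Wilcoxon rank-sum comparison of log2 fold changes between signature
#' genes and all other (background) genes, summarized with linear-FC
#' quartiles and a signed log10 p-value whose sign follows the difference
#' in median log2 fold change (positive = signature biased toward
#' increased expression).
#'
#' @param fc A fold-change vector (see [as_fc_vector()]).
#' @param signature Character vector of signature genes, or a
#'   `sigshift_signature` tibble.
#' @param name Signature name for the output row.
#' @return A one-row tibble: `signature`, `n_used`, `n_dropped`,
#'   `mean_fc`, FC quartiles for signature (`fc_q25/q50/q75`) and
#'   background (`bg_q25/q50/q75`), `p_value`, `signed_log10p`.
#' @export
directional_bias <- function(fc, signature, name = NULL) {
  name <- name %||% attr(signature, "name") %||% "signature"
  parts <- split_by_signature(fc, signature, name)
  test <- rank_sum_test(parts$sig$log2fc, parts$bg$log2fc,
                        alternative = "two.sided")
  dir_sign <- sign(median(parts$sig$log2fc) - median(parts$bg$log2fc))
  qs <- quantile(parts$sig$fc, c(0.25, 0.5, 0.75), names = FALSE)
  qb <- quantile(parts$bg$fc, c(0.25, 0.5, 0.75), names = FALSE)
  tibble::tibble(
    signature = name,
    n_used = nrow(parts$sig),
    n_dropped = parts$n_dropped,
    mean_fc = mean(parts$sig$fc),
    fc_q25 = qs[1], fc_q50 = qs[2], fc_q75 = qs[3],
    bg_q25 = qb[1], bg_q50 = qb[2], bg_q75 = qb[3],
    p_value = test$p_value,
    signed_log10p = signed_log10p(test$p_value, dir_sign)
  )
}

#' Signed log10 p-value
#'
#' `-log10(p)` carrying the sign of the directional shift: positive when
#' signature genes are biased toward increased expression, negative
#' otherwise.  `p = 0` is clamped at the smallest positive double with a
#' warning.
#'
#' @param p P-value in (0, 1\].
#' @param direction_sign +1, -1, or 0.
#' @return Signed log10 p, vectorized.
#' @export
signed_log10p <- function(p, direction_sign) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p must lie in [0, 1].")
  if (any(p == 0, na.rm = TRUE)) {
    warn("p = 0 clamped to the machine floor.")
    p[p == 0] <- .Machine$double.xmin
  }
  -log10(p) * sign(direction_sign)
}

#' Direction-count exact test for a signature
#'
#' Dichotomizes every gene as up (FC > 1) or down (FC <= 1; ties at
#' exactly 1 count as down unless `tie_up = TRUE`) and tests the 2x2
#' signature/background x up/down table with Fisher's exact test
#' (two-sided).  Also returns the middle 95% of the hypergeometric null
#' for the signature's up-count, given the overall up-proportion.
#'
#' @inheritParams directional_bias
#' @param tie_up Count FC exactly 1 as up instead of down.
#' @return A one-row tibble: counts (`n_up`, `n_down`, `bg_up`,
#'   `bg_down`), `p_value`, and the null band (`null_lo`, `null_hi`).
#' @export
direction_count_test <- function(fc, signature, name = NULL, tie_up = FALSE) {
  name <- name %||% attr(signature, "name") %||% "signature"
  parts <- split_by_signature(fc, signature, name)
  is_up <- function(v) if (tie_up) v >= 1 else v > 1
  n_up <- sum(is_up(parts$sig$fc)); n_down <- nrow(parts$sig) - n_up
  bg_up <- sum(is_up(parts$bg$fc)); bg_down <- nrow(parts$bg) - bg_up
  tab <- matrix(c(n_up, n_down, bg_up, bg_down), nrow = 2)
  test <- fisher_exact(tab, alternative = "two.sided")
  n_sig <- nrow(parts$sig)
  total_up <- n_up + bg_up
  total <- n_sig + nrow(parts$bg)
  band <- qhyper(c(0.025, 0.975), total_up, total - total_up, n_sig)
  tibble::tibble(
    signature = name,
    n_up = n_up, n_down = n_down, bg_up = bg_up, bg_down = bg_down,
    p_value = test$p_value,
    null_lo = band[1], null_hi = band[2]
  )
}

#' Cumulative-overlap curve and AUC for a signature
#'
#' Genes are ranked by log2 fold change (descending by default; ties
#' broken by gene id for determinism) and the cumulative recovery of
#' signature genes is traced.  Two curves are returned: the raw
#' cumulative count against rank, and the unit-square curve (background
#' fraction passed on x, signature fraction recovered on y) whose
#' trapezoidal area equals the Wilcoxon-Mann-Whitney statistic
#' `U / (n1 * n2)`; tied fold-change blocks contribute diagonal segments.
#' `auc_minus_half` is the signed area between the curve and the
#' diagonal; the rank-sum p-value of the signature/background comparison
#' is attached as its significance.
#'
#' @inheritParams directional_bias
#' @param decreasing Rank by decreasing log2 fold change (default); set
#'   `FALSE` to measure enrichment among down-regulated genes.
#' @return An object of class `sigshift_overlap`: `curve` (per-rank
#'   tibble), `points` (unit-square vertices), `auc`, `auc_minus_half`,
#'   `p_value`, `n_signature`, `n_background`.
#' @export
overlap_curve <- function(fc, signature, name = NULL, decreasing = TRUE) {
  name <- name %||% attr(signature, "name") %||% "signature"
  parts <- split_by_signature(fc, signature, name)
  all_fc <- dplyr::bind_rows(
    dplyr::mutate(parts$sig, in_signature = TRUE),
    dplyr::mutate(parts$bg, in_signature = FALSE)
  )
  stat <- if (decreasing) -all_fc$log2fc else all_fc$log2fc
  ord <- order(stat, all_fc$gene)
  all_fc <- all_fc[ord, ]
  n1 <- nrow(parts$sig); n2 <- nrow(parts$bg)
  curve <- tibble::tibble(
    rank = seq_len(nrow(all_fc)),
    gene = all_fc$gene,
    log2fc = all_fc$log2fc,
    in_signature = all_fc$in_signature,
    cum_count = cumsum(all_fc$in_signature)
  )
  curve$cum_frac <- curve$cum_count / n1
  curve$bg_frac <- cumsum(!all_fc$in_signature) / n2
  # unit-square vertices at tie-block boundaries (diagonal across ties)
  block_end <- c(diff(stat[ord]) != 0, TRUE)
  points <- tibble::tibble(
    x = c(0, curve$bg_frac[block_end]),
    y = c(0, curve$cum_frac[block_end])
  )
  auc <- sum(diff(points$x) * (head(points$y, -1) + points$y[-1]) / 2)
  test <- rank_sum_test(parts$sig$log2fc, parts$bg$log2fc,
                        alternative = "two.sided")
  structure(
    list(signature = name, curve = curve, points = points,
         auc = auc, auc_minus_half = auc - 0.5,
         p_value = test$p_value,
         n_signature = n1, n_background = n2,
         decreasing = decreasing),
    class = "sigshift_overlap"
  )
}

#' @export
print.sigshift_overlap <- function(x, ...) {
  cat(sprintf("Cumulative overlap: '%s' (%d signature / %d background genes)\n",
              x$signature, x$n_signature, x$n_background))
  cat(sprintf("AUC = %.4f (AUC - 0.5 = %+.4f), rank-sum p = %.3g\n",
              x$auc, x$auc_minus_half, x$p_value))
  invisible(x)
}

#' @describeIn overlap_curve One-row summary (signature, auc,
#'   auc_minus_half, p_value, sizes).
#' @param x A `sigshift_overlap` object.
#' @param ... Unused.
#' @export
glance.sigshift_overlap <- function(x, ...) {
  tibble::tibble(signature = x$signature, auc = x$auc,
                 auc_minus_half = x$auc_minus_half, p_value = x$p_value,
                 n_signature = x$n_signature, n_background = x$n_background)
}

#' Rank a signature collection by directional enrichment
#'
#' Computes the full enrichment summary (directional bias, direction
#' counts, overlap AUC) for every signature against one fold-change
#' vector, sorted by signed log10 p descending.  With `compare`, the bias
#' statistics are also computed against a second fold-change vector and
#' the difference in signed log10 p is reported (sorted by that
#' difference).
#'
#' @param fc A fold-change vector (see [as_fc_vector()]).
#' @param signatures Gene sets: tibble from [read_gmt()], named list of
#'   character vectors, or list of `sigshift_signature` tibbles.
#' @param compare Optional second fold-change vector.
#' @return A tibble of class `sigshift_enrichment`, one row per
#'   signature.
#' @export
rank_signatures <- function(fc, signatures, compare = NULL) {
  sets <- gene_set_list(signatures)
  if (length(sets) < 1) abort("Need at least one signature.")
  fc <- as_fc_vector(fc)
  rows <- purrr::imap(sets, function(genes, nm) {
    bias <- directional_bias(fc, genes, name = nm)
    counts <- direction_count_test(fc, genes, name = nm)
    oc <- overlap_curve(fc, genes, name = nm)
    out <- dplyr::bind_cols(
      bias,
      counts[, c("n_up", "n_down", "bg_up", "bg_down", "null_lo", "null_hi")],
      direction_p = counts$p_value,
      auc = oc$auc
    )
    if (!is.null(compare)) {
      bias2 <- directional_bias(compare, genes, name = nm)
      out$signed_log10p_compare <- bias2$signed_log10p
      out$delta_signed_log10p <- out$signed_log10p - bias2$signed_log10p
    }
    out
  })
  out <- dplyr::bind_rows(rows)
  out <- if (is.null(compare)) {
    dplyr::arrange(out, dplyr::desc(.data$signed_log10p))
  } else {
    dplyr::arrange(out, dplyr::desc(.data$delta_signed_log10p))
  }
  class(out) <- c("sigshift_enrichment", class(out))
  out
}
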