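#' One-vs-rest differential expression for a compendium population
#'
#' Moderated-t contrast of one labeled cell population against all other
#' compendium samples pooled, with BH adjustment within the contrast.
#'
#' @param expr Compendium expression tibble.
#' @param samples Sample table with `sample_id` and a population column.
#' @param population Population to contrast against the rest.
#' @param population_col Name of the population column.
#' @inheritParams fit_moderated
#' @return A `sigshift_de` tibble (fold changes are population over rest).
#' @export
one_vs_rest <- function(expr, samples, population,
                        population_col = "population", ...) {
  samples <- validate_samples(samples)
  pops <- as.character(samples[[population_col]])
  if (!population %in% pops) {
    abort(paste0("Unknown population: '", population, "'."))
  }
  if (sum(pops == population) < 2) {
    abort(paste0("Population '", population, "' needs at least 2 replicates."))
  }
  if (all(pops == population)) abort("The rest group is empty.")
  tmp <- tibble::tibble(
    sample_id = samples$sample_id,
    group = ifelse(pops == population, population, ".rest")
  )
  fit_moderated(expr, tmp, contrast = c(population, ".rest"), ...)
}

#' Two-stage signature-gene selection
#'
#' From a differential-expression result, derive a fixed-size signature:
#' stage 1 keeps genes whose fold change is concordant with `direction`
#' (FC > 1 for `"up"`, FC < 1 for `"down"`); stage 2 keeps the `n_p` of
#' those with lowest p-value; stage 3 keeps the `n_sig` of those with the
#' most extreme fold change (highest for `"up"`, lowest for `"down"`).
#' Ties at the stage-2 cutoff are broken by larger `|log2fc|` then gene
#' id; ties at the stage-3 cutoff by smaller p then gene id.  If fewer
#' than `n_sig` genes survive stage 1, all survivors are returned and the
#' result is flagged short.
#'
#' @param de A `sigshift_de` result (or any tibble with `gene`, `fc`,
#'   `log2fc`, `p`).
#' @param n_p Stage-2 size.
#' @param n_sig Final signature size.
#' @param direction `"up"` or `"down"`.
#' @param candidates Optional character vector restricting the candidate
#'   genes before stage 2 (e.g. a pre-filtered DEG list).
#' @param name Signature name recorded on the result.
#' @return A tibble of class `sigshift_signature` with columns `gene`,
#'   `log2fc`, `fc`, `p`, ordered by derivation fold change; attributes
#'   `name`, `direction`, `stage_sizes`, `short`.
#' @export
select_signature <- function(de, n_p = 150L, n_sig = 100L,
                             direction = c("up", "down"),
                             candidates = NULL, name = NULL) {
  direction <- match.arg(direction)
  if (n_sig > n_p) abort("`n_sig` must not exceed `n_p`.")
  tab <- tibble::as_tibble(de)[, c("gene", "log2fc", "fc", "p")]
  if ("included" %in% names(de)) tab <- tab[de$included, , drop = FALSE]
  tab <- tab[complete.cases(tab), , drop = FALSE]
  stage1 <- if (direction == "up") tab[tab$fc > 1, ] else tab[tab$fc < 1, ]
  if (!is.null(candidates)) stage1 <- stage1[stage1$gene %in% candidates, ]
  if (nrow(stage1) == 0) {
    warn(paste0("No ", direction, "-concordant candidate genes; returning an empty signature."))
    out <- stage1
  } else {
    stage2 <- head(
      dplyr::arrange(stage1, .data$p, dplyr::desc(abs(.data$log2fc)), .data$gene),
      n_p
    )
    stage3 <- if (direction == "up") {
      dplyr::arrange(stage2, dplyr::desc(.data$fc), .data$p, .data$gene)
    } else {
      dplyr::arrange(stage2, .data$fc, .data$p, .data$gene)
    }
    out <- head(stage3, n_sig)
  }
  short <- nrow(out) < n_sig
  if (short && nrow(stage1) > 0) {
    sig_log("Signature '", name %||% "?", "': only ", nrow(out),
            " of the requested ", n_sig, " genes available.")
  }
  structure(out,
            name = name, direction = direction,
            n_p = as.integer(n_p), n_sig = as.integer(n_sig),
            stage_sizes = c(stage1 = nrow(stage1),
                            stage2 = as.integer(min(nrow(stage1), n_p)),
                            stage3 = nrow(out)),
            short = short,
            class = c("sigshift_signature", class(out)))
}

#' @export
print.sigshift_signature <- function(x, ...) {
  ss <- attr(x, "stage_sizes")
  cat(sprintf("Signature '%s' (%s): %d genes [stage sizes %d -> %d -> %d]\n",
              attr(x, "name") %||% "?", attr(x, "direction"),
              nrow(x), ss[1], ss[2], ss[3]))
  NextMethod()
}

#' Derive signatures for every compendium population
#'
#' Runs [one_vs_rest()] and [select_signature()] for each population and
#' reports per-population candidate-gene counts, including the number of
#' genes passing the conventional DEG criterion (FDR < `fdr` with FC >
#' `fc_up`).
#'
#' @inheritParams one_vs_rest
#' @inheritParams select_signature
#' @param fdr,fc_up DEG-count reporting thresholds.
#' @param ... Passed to [fit_moderated()] via [one_vs_rest()].
#' @return A list: `signatures` (named list of `sigshift_signature`
#'   tibbles), `collection` (tibble acceptable to [write_gmt()]), and
#'   `summary` (one row per population).
#' @export
derive_all <- function(expr, samples, population_col = "population",
                       n_p = 150L, n_sig = 100L, fdr = 0.10, fc_up = 1.50,
                       ...) {
  samples <- validate_samples(samples)
  pops <- sort(unique(as.character(samples[[population_col]])))
  sigs <- vector("list", length(pops))
  names(sigs) <- pops
  summary_rows <- vector("list", length(pops))
  for (i in seq_along(pops)) {
    de <- one_vs_rest(expr, samples, pops[i], population_col = population_col, ...)
    sigs[[i]] <- select_signature(de, n_p = n_p, n_sig = n_sig,
                                  direction = "up", name = pops[i])
    degs <- call_degs(de, fdr = fdr, fc_up = fc_up)
    ss <- attr(sigs[[i]], "stage_sizes")
    summary_rows[[i]] <- tibble::tibble(
      population = pops[i],
      n_deg_up = length(degs$up),
      n_fc_concordant = ss[["stage1"]],
      n_signature = ss[["stage3"]]
    )
  }
  collection <- tibble::tibble(
    set = pops,
    description = paste0("signature genes (", purrr::map_int(sigs, nrow), ")"),
    genes = purrr::map(sigs, function(s) as.character(s$gene))
  )
  list(signatures = sigs, collection = collection,
       summary = dplyr::bind_rows(summary_rows))
}
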