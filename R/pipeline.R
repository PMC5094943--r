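#' Run the full study analysis
#'
#' Orchestrates the complete workflow on a 2x2 genotype-by-age expression
#' study: moderated differential expression for the four group contrasts
#' (KO vs WT within each age; old vs young within each genotype) plus the
#' genotype-by-age interaction; DEG counts at the configured thresholds;
#' genome-wide rank correlations of fold changes across comparisons;
#' directional enrichment of a signature collection against each
#' fold-change vector; and the paired comparison of signed log10 p
#' between the two aging contrasts.  With `out_dir`, every table is
#' written as TSV together with a JSON run manifest recording the
#' configuration, seed, file digests and per-stage wall-clock time.
#'
#' @param expr,samples Study expression and sample tables (`samples`
#'   needs `sample_id`, `group`, `genotype`, `age`).  Ignored when
#'   `preset` is given.
#' @param signatures Optional signature collection (tibble from
#'   [read_gmt()] or named list).  With a preset, signatures are derived
#'   from the preset's compendium when this is `NULL`.
#' @param detection Optional detection table for the inclusion filter.
#' @param preset Optional [simulate_preset()] scenario name; generates
#'   the inputs instead of using `expr`/`samples`.
#' @param seed Seed for preset generation (recorded in the manifest).
#' @param config A [sigshift_config()].
#' @param out_dir Optional output directory for TSV tables + manifest.
#' @return A list of class `sigshift_run`: `de` (named list of
#'   `sigshift_de`), `deg_counts`, `correlations`, `enrichment` (named
#'   list of `sigshift_enrichment`), `delta_aging`, `truth` (for
#'   presets), and `manifest`.
#' @export
run_study <- function(expr = NULL, samples = NULL, signatures = NULL,
                      detection = NULL, preset = NULL, seed = 1L,
                      config = sigshift_config(), out_dir = NULL) {
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  truth <- NULL
  stage <- function(name, code) {
    s <- proc.time()[["elapsed"]]
    out <- tryCatch(force(code), error = function(e) {
      abort(paste0("Stage '", name, "' failed: ", conditionMessage(e)))
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - s, 3)
    out
  }

  if (!is.null(preset)) {
    sim <- stage("simulate", simulate_preset(preset, seed = seed))
    expr <- sim$study$expression
    samples <- sim$study$samples
    detection <- detection %||% sim$study$detection
    truth <- sim$study$truth
    if (is.null(signatures)) {
      derived <- stage("signatures",
                       derive_all(sim$compendium$expression,
                                  sim$compendium$samples,
                                  n_p = config$n_p, n_sig = config$n_sig))
      signatures <- derived$collection
    }
  }
  if (is.null(expr) || is.null(samples)) {
    abort("Provide `expr` and `samples`, or a `preset`.")
  }
  samples <- validate_samples(samples, expr = expr, design = "study")

  contrasts <- list(
    youngKO_vs_youngWT = c("young-KO", "young-WT"),
    oldKO_vs_oldWT = c("old-KO", "old-WT"),
    oldWT_vs_youngWT = c("old-WT", "young-WT"),
    oldKO_vs_youngKO = c("old-KO", "young-KO")
  )
  de <- stage("differential_expression", {
    fits <- purrr::map(contrasts, function(ct) {
      fit_moderated(expr, samples, contrast = ct, detection = detection,
                    min_detect_fraction = config$min_detect_fraction)
    })
    fits$interaction <- interaction_fit(expr, samples, detection = detection,
                                        min_detect_fraction = config$min_detect_fraction)
    fits
  })

  deg_counts <- stage("deg_counts", {
    purrr::imap(de, function(fit, nm) {
      degs <- call_degs(fit, fdr = config$fdr, fc_up = config$fc_up,
                        fc_down = config$fc_down)
      tibble::tibble(contrast = nm,
                     n_included = attr(fit, "n_included"),
                     n_up = length(degs$up), n_down = length(degs$down))
    }) |> dplyr::bind_rows()
  })

  correlations <- stage("rank_correlations", {
    pair_cor <- function(a, b) {
      fa <- as_fc_vector(de[[a]]); fb <- as_fc_vector(de[[b]])
      common <- intersect(fa$gene, fb$gene)
      rank_correlation(fa$log2fc[match(common, fa$gene)],
                       fb$log2fc[match(common, fb$gene)])
    }
    tibble::tibble(
      comparison = c("aging_WT_vs_aging_KO", "genotype_young_vs_genotype_old"),
      r_s = c(pair_cor("oldWT_vs_youngWT", "oldKO_vs_youngKO"),
              pair_cor("youngKO_vs_youngWT", "oldKO_vs_oldWT"))
    )
  })

  enrichment <- NULL
  delta_aging <- NULL
  if (!is.null(signatures)) {
    enrichment <- stage("enrichment", {
      purrr::map(de[names(contrasts)], function(fit) {
        rank_signatures(as_fc_vector(fit), signatures)
      })
    })
    delta_aging <- stage("delta_aging", {
      rank_signatures(as_fc_vector(de$oldKO_vs_youngKO), signatures,
                      compare = as_fc_vector(de$oldWT_vs_youngWT))
    })
  }

  manifest <- list(
    config = unclass(config), seed = seed, preset = preset,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    package_version = as.character(utils::packageVersion("sigshift")),
    stages = as.list(timings),
    elapsed = round(proc.time()[["elapsed"]] - t0, 3)
  )
  result <- structure(
    list(de = de, deg_counts = deg_counts, correlations = correlations,
         enrichment = enrichment, delta_aging = delta_aging,
         truth = truth, manifest = manifest),
    class = "sigshift_run"
  )
  if (!is.null(out_dir)) {
    result$manifest$files <- write_run(result, out_dir)
  }
  result
}

# write every run table as TSV and return name -> list(path, md5)
write_run <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  emit <- function(tbl, name) {
    path <- file.path(out_dir, paste0(name, ".tsv"))
    write_table(tibble::as_tibble(tbl), path)
    files[[name]] <<- list(path = path,
                           md5 = unname(tools::md5sum(path)))
  }
  for (nm in names(result$de)) emit(result$de[[nm]], paste0("de_", nm))
  emit(result$deg_counts, "deg_counts")
  emit(result$correlations, "correlations")
  if (!is.null(result$enrichment)) {
    for (nm in names(result$enrichment)) {
      emit(result$enrichment[[nm]], paste0("enrichment_", nm))
    }
    emit(result$delta_aging, "enrichment_delta_aging")
  }
  manifest_path <- file.path(out_dir, "manifest.json")
  manifest <- result$manifest
  manifest$files <- files
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  files$manifest <- list(path = manifest_path,
                         md5 = unname(tools::md5sum(manifest_path)))
  files
}

#' @export
print.sigshift_run <- function(x, ...) {
  cat("sigshift run (", x$manifest$elapsed, "s )\n", sep = "")
  print(x$deg_counts)
  print(x$correlations)
  invisible(x)
}

#' Relative-expression qPCR analysis with letter display
#'
#' Comparative-Ct analysis of a long Ct table: per target gene (and per
#' tissue when a tissue column is present), each sample's dCt is its
#' target Ct minus its endogenous-control Ct; ddCt subtracts the
#' calibrator group's mean dCt, and relative expression is `2^-ddCt`
#' rescaled so the calibrator group's mean relative expression is
#' exactly 1.
#' Group letters come from protected Fisher's LSD on the dCt values
#' (variance-stabilized scale; set `scale = "relative"` to test the
#' `2^-ddCt` values instead).
#'
#' @param ct Long tibble with columns `sample_id`, `group`, `gene`, `ct`
#'   (and optionally a tissue column).
#' @param endogenous Endogenous control gene name.
#' @param calibrator Calibrator group label.
#' @param tissue_col Optional name of a tissue column to stratify by.
#' @param alpha LSD significance level.
#' @param scale Scale for the ANOVA/LSD: `"dct"` or `"relative"`.
#' @return A list of class `sigshift_qpcr`: `samples` (per-sample
#'   relative expression), `summary` (group mean, standard error, n,
#'   letter per gene x tissue), `lsd` (named list of `sigshift_lsd`).
#' @export
run_qpcr <- function(ct, endogenous = "Rn18s", calibrator = "young-WT",
                     tissue_col = NULL, alpha = 0.05,
                     scale = c("dct", "relative")) {
  scale <- match.arg(scale)
  ct <- tibble::as_tibble(ct)
  needed <- c("sample_id", "group", "gene", "ct")
  missing <- setdiff(needed, names(ct))
  if (length(missing) > 0) {
    abort(paste0("Ct table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  strat <- if (!is.null(tissue_col)) ct[[tissue_col]] else ""
  ct$._stratum <- as.character(strat)
  endo <- ct[ct$gene == endogenous, ]
  if (nrow(endo) == 0) abort(paste0("No rows for endogenous control '", endogenous, "'."))
  targets <- ct[ct$gene != endogenous, ]
  key <- function(d) paste(d$sample_id, d$._stratum)
  endo_ct <- setNames(endo$ct, key(endo))
  missing_endo <- unique(targets$sample_id[!key(targets) %in% names(endo_ct)])
  if (length(missing_endo) > 0) {
    abort(paste0("Missing endogenous control for sample(s): ",
                 paste(head(missing_endo, 5), collapse = ", ")))
  }
  targets$dct <- targets$ct - endo_ct[key(targets)]
  if (!calibrator %in% targets$group) {
    abort(paste0("Calibrator group '", calibrator, "' absent from the Ct table."))
  }

  out_samples <- targets |>
    dplyr::group_by(.data$gene, .data$._stratum) |>
    dplyr::group_modify(function(d, k) {
      if (!any(d$group == calibrator)) {
        abort(paste0("Calibrator group '", calibrator, "' missing for a gene/tissue stratum."))
      }
      cal_delta <- mean(d$dct[d$group == calibrator])
      rel <- delta_delta_ct(d$ct, d$ct - d$dct, cal_delta)
      # rescale so the calibrator group's mean relative expression is
      # exactly 1 on the linear scale
      d$relative_expression <- rel / mean(rel[d$group == calibrator])
      d
    }) |>
    dplyr::ungroup()

  keys <- dplyr::distinct(out_samples, .data$gene, .data$._stratum)
  lsd_list <- purrr::pmap(keys, function(gene, ._stratum) {
    d <- out_samples[out_samples$gene == gene & out_samples$._stratum == ._stratum, ]
    vcol <- if (scale == "dct") "dct" else "relative_expression"
    protected_lsd(d, !!vcol, !!"group", alpha = alpha)
  })
  names(lsd_list) <- paste0(keys$gene,
                            ifelse(nzchar(keys$._stratum), paste0(".", keys$._stratum), ""))

  summary <- out_samples |>
    dplyr::group_by(.data$gene, .data$._stratum, .data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_relative = mean(.data$relative_expression),
      se = sd(.data$relative_expression) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  letter_tbl <- purrr::imap(lsd_list, function(l, nm) {
    i <- match(nm, names(lsd_list))
    dplyr::mutate(l$letters[, c("group", "letter")],
                  gene = keys$gene[i], ._stratum = keys$._stratum[i])
  }) |> dplyr::bind_rows()
  summary <- dplyr::left_join(summary, letter_tbl,
                              by = c("gene", "._stratum", "group"))
  rename_stratum <- function(d) {
    if (!is.null(tissue_col)) names(d)[names(d) == "._stratum"] <- tissue_col
    else d$._stratum <- NULL
    d
  }
  structure(
    list(samples = rename_stratum(out_samples),
         summary = rename_stratum(summary),
         lsd = lsd_list,
         endogenous = endogenous, calibrator = calibrator, scale = scale),
    class = "sigshift_qpcr"
  )
}

#' @export
print.sigshift_qpcr <- function(x, ...) {
  cat("qPCR relative expression (control: ", x$endogenous,
      "; calibrator: ", x$calibrator, "; LSD on ", x$scale, ")\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' @describeIn run_qpcr Group summary table.
#' @param x A `sigshift_qpcr` object.
#' @param ... Unused.
#' @export
tidy.sigshift_qpcr <- function(x, ...) x$summary
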