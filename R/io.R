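#' Validate an expression table
#'
#' An expression table is a tibble whose first column (`gene`) holds unique
#' gene identifiers and whose remaining columns hold finite numeric log2
#' expression values, one column per sample.  All pipeline functions accept
#' this layout.
#'
#' @param expr A data frame: first column gene identifiers, remaining
#'   columns numeric log2 expression values named by sample.
#' @param detection Optional logical data frame of identical layout
#'   (gene column plus one logical column per sample) holding
#'   above-background detection calls.
#'
#' @return `expr` as a validated tibble, invisibly gene-ordered as given.
#' @export
validate_expression <- function(expr, detection = NULL) {
  expr <- tibble::as_tibble(expr)
  if (ncol(expr) < 2L) {
    abort("An expression table needs a gene column plus at least one sample column.")
  }
  names(expr)[1] <- "gene"
  genes <- as.character(expr$gene)
  dup <- unique(genes[duplicated(genes)])
  if (length(dup) > 0) {
    abort(paste0("Duplicate gene identifier(s): ", paste(head(dup, 5), collapse = ", ")))
  }
  samples <- names(expr)[-1]
  dup_s <- unique(samples[duplicated(samples)])
  if (length(dup_s) > 0) {
    abort(paste0("Duplicate sample identifier(s): ", paste(head(dup_s, 5), collapse = ", ")))
  }
  for (s in samples) {
    col <- expr[[s]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(col)))))[1]
      abort(paste0("Non-numeric expression value at gene row ", bad %||% 1L,
                   ", sample column '", s, "'."))
    }
    if (anyNA(col) || any(!is.finite(col))) {
      bad <- which(!is.finite(col))[1]
      abort(paste0("Non-finite expression value at gene row ", bad,
                   ", sample column '", s, "'."))
    }
  }
  if (!is.null(detection)) {
    detection <- tibble::as_tibble(detection)
    if (!identical(dim(detection), dim(expr))) {
      abort("`detection` must have the same dimensions as `expr`.")
    }
    if (!all(vapply(detection[-1], is.logical, logical(1)))) {
      abort("`detection` sample columns must be logical.")
    }
  }
  expr$gene <- genes
  invisible(expr)
}

#' Validate a sample table against an expression table
#'
#' @param samples A data frame with a `sample_id` column and any of
#'   `group`, `genotype`, `age`, `population`.
#' @param expr Optional companion expression table; when given, every
#'   sample id must match an expression column exactly once.
#' @param design `"none"`, `"study"` (requires genotype in WT/KO and age
#'   in young/old with all four cells non-empty), or `"compendium"`
#'   (requires a non-empty `population` column).
#'
#' @return The sample table as a validated tibble, invisibly.
#' @export
validate_samples <- function(samples, expr = NULL,
                             design = c("none", "study", "compendium")) {
  design <- match.arg(design)
  samples <- tibble::as_tibble(samples)
  if (!"sample_id" %in% names(samples)) {
    abort("Sample table must have a `sample_id` column.")
  }
  ids <- as.character(samples$sample_id)
  if (anyDuplicated(ids)) {
    abort(paste0("Duplicate sample_id: ", ids[duplicated(ids)][1]))
  }
  if (!is.null(expr)) {
    cols <- names(expr)[-1]
    missing <- setdiff(ids, cols)
    if (length(missing) > 0) {
      abort(paste0("sample_id absent from expression table: ",
                   paste(head(missing, 5), collapse = ", ")))
    }
  }
  if (design == "study") {
    for (col in c("genotype", "age")) {
      if (!col %in% names(samples)) abort(paste0("Study design needs a `", col, "` column."))
    }
    if (!all(samples$genotype %in% c("WT", "KO"))) abort("`genotype` must be WT or KO.")
    if (!all(samples$age %in% c("young", "old"))) abort("`age` must be young or old.")
    cells <- table(samples$genotype, samples$age)
    if (any(cells == 0)) abort("All four genotype x age cells must be non-empty.")
  }
  if (design == "compendium") {
    if (!"population" %in% names(samples)) abort("Compendium design needs a `population` column.")
    if (any(!nzchar(samples$population) | is.na(samples$population))) {
      abort("Population labels must be non-empty.")
    }
  }
  invisible(samples)
}

#' Read a gene-by-sample expression matrix from TSV
#'
#' The file layout is genes in rows and samples in columns: the first
#' column holds gene identifiers, the header row holds sample identifiers.
#' Values are log2-scale expression intensities.
#'
#' @param path Path to a tab-delimited expression file.
#' @param meta_path Optional path to a sample-metadata sidecar TSV with a
#'   `sample_id` column.
#'
#' @return A validated expression tibble, or, when `meta_path` is given, a
#'   list with elements `expression` and `samples`.
#' @export
read_expression <- function(path, meta_path = NULL) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  expr <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                          progress = FALSE)
  for (j in seq_along(expr)[-1]) {
    num <- suppressWarnings(as.numeric(expr[[j]]))
    bad <- which(is.na(num) & !is.na(expr[[j]]))
    if (length(bad) > 0) {
      abort(paste0("Non-numeric cell at row ", bad[1], ", column '",
                   names(expr)[j], "': '", expr[[j]][bad[1]], "'"))
    }
    expr[[j]] <- num
  }
  expr <- validate_expression(expr)
  if (is.null(meta_path)) return(expr)
  samples <- read_sample_table(meta_path, expr = expr)
  list(expression = expr, samples = samples)
}

#' Read a sample metadata table from TSV
#'
#' @inheritParams validate_samples
#' @param path Path to a TSV with a `sample_id` column plus factor columns
#'   (`group`, `genotype`, `age`, `population`).
#' @return A validated sample tibble.
#' @export
read_sample_table <- function(path, expr = NULL, design = "none") {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  samples <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                             progress = FALSE)
  validate_samples(samples, expr = expr, design = design)
  samples
}

#' Write an expression table to TSV
#'
#' Values round-trip through [read_expression()] at full double precision.
#'
#' @param expr An expression tibble (see [validate_expression()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  expr <- validate_expression(expr)
  readr::write_tsv(expr, path)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT dialect: one set per line; tab-separated fields are the set
#' name, a description, then member genes.  Duplicate members within a line
#' are collapsed with a logged warning.
#'
#' @param path Path to a GMT file.
#' @return A tibble with columns `set`, `description` and the list-column
#'   `genes`; one row per set.  An empty file yields zero rows.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble::tibble(set = character(), description = character(),
                          genes = list()))
  }
  parsed <- purrr::imap(lines, function(line, i) {
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      abort(paste0("GMT line ", i, " has fewer than 3 tab-separated fields."))
    }
    members <- fields[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      sig_log("GMT set '", fields[1], "' (line ", i, "): collapsed ",
              sum(duplicated(members)), " duplicate member(s).")
      members <- unique(members)
    }
    if (length(members) == 0) {
      abort(paste0("GMT line ", i, " (set '", fields[1], "') has no members."))
    }
    list(set = fields[1], description = fields[2], genes = members)
  })
  out <- tibble::tibble(
    set = purrr::map_chr(parsed, "set"),
    description = purrr::map_chr(parsed, "description"),
    genes = purrr::map(parsed, "genes")
  )
  if (anyDuplicated(out$set)) {
    abort(paste0("Duplicate gene-set name: ", out$set[duplicated(out$set)][1]))
  }
  out
}

#' Write gene sets to a GMT file
#'
#' @param sets A gene-set tibble as returned by [read_gmt()], a named list
#'   of character vectors, or a list of signature tibbles from
#'   [select_signature()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  sets <- as_gene_set_collection(sets)
  lines <- purrr::pmap_chr(sets, function(set, description, genes) {
    paste(c(set, description, genes), collapse = "\t")
  })
  writeLines(lines, path)
  invisible(path)
}

# coerce the accepted gene-set inputs to the canonical collection tibble
as_gene_set_collection <- function(sets) {
  if (is.data.frame(sets)) {
    stopifnot(all(c("set", "genes") %in% names(sets)))
    if (!"description" %in% names(sets)) sets$description <- ""
    return(tibble::as_tibble(sets[, c("set", "description", "genes")]))
  }
  if (is.list(sets)) {
    nm <- names(sets)
    if (is.null(nm) || any(!nzchar(nm))) abort("Gene-set lists must be named.")
    genes <- purrr::map(sets, function(s) {
      if (is.data.frame(s)) as.character(s$gene) else as.character(s)
    })
    return(tibble::tibble(set = nm, description = "", genes = unname(genes)))
  }
  abort("Unsupported gene-set container.")
}

# named list of character vectors from any accepted gene-set input
gene_set_list <- function(sets) {
  coll <- as_gene_set_collection(sets)
  setNames(coll$genes, coll$set)
}

#' Write a result table to TSV
#'
#' Row order is deterministic: differential-expression tables keep their
#' gene order; enrichment tables are sorted by `signed_log10p` descending.
#' Numeric values round-trip at full double precision.
#'
#' @param result A tibble, e.g. from [fit_moderated()] or
#'   [rank_signatures()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(result, path) {
  if (!is.data.frame(result)) abort("`result` must be a data frame.")
  if ("signed_log10p" %in% names(result)) {
    result <- dplyr::arrange(result, dplyr::desc(.data$signed_log10p))
  }
  out <- tibble::as_tibble(result)
  out <- out[, !vapply(out, is.list, logical(1)), drop = FALSE]
  readr::write_tsv(out, path)
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles the thresholds and signature-derivation sizes used throughout
#' the pipeline, with validation.
#'
#' @param fdr FDR threshold for calling differentially expressed genes.
#' @param fc_up,fc_down Linear fold-change thresholds for up / down calls
#'   (strict inequalities).
#' @param detect_alpha Significance level for the above-background
#'   detection call.
#' @param min_detect_fraction Minimum fraction of comparison samples in
#'   which a gene must be detected to enter a comparison.
#' @param n_p Stage-two signature size (lowest p-values kept).
#' @param n_sig Final signature size (most extreme fold changes kept).
#' @param seed Optional integer seed recorded in run manifests.
#' @return A validated list of class `sigshift_config`.
#' @export
sigshift_config <- function(fdr = 0.10, fc_up = 1.50, fc_down = 0.67,
                            detect_alpha = 0.05, min_detect_fraction = 1 / 3,
                            n_p = 150L, n_sig = 100L, seed = NULL) {
  stopifnot(fdr > 0, fdr < 1, fc_up > 1, fc_down > 0, fc_down < 1,
            detect_alpha > 0, detect_alpha < 1,
            min_detect_fraction > 0, min_detect_fraction <= 1,
            n_p >= 1, n_sig >= 1, n_sig <= n_p)
  structure(
    list(fdr = fdr, fc_up = fc_up, fc_down = fc_down,
         detect_alpha = detect_alpha,
         min_detect_fraction = min_detect_fraction,
         n_p = as.integer(n_p), n_sig = as.integer(n_sig), seed = seed),
    class = "sigshift_config"
  )
}

#' Read a configuration from a YAML or flat key=value file
#'
#' Recognised keys are the arguments of [sigshift_config()]; unknown keys
#' are rejected.
#'
#' @param path Path to a YAML (or `key: value` / `key=value`) file.
#' @return A `sigshift_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- strsplit(lines, "[:=]", perl = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = ":"), ""))
  known <- names(formals(sigshift_config))
  bad <- setdiff(keys, known)
  if (length(bad) > 0) abort(paste0("Unknown config key(s): ", paste(bad, collapse = ", ")))
  args <- lapply(setNames(vals, keys), function(v) {
    # support simple fractions like 1/3
    if (grepl("^\\s*[0-9.eE+-]+\\s*/\\s*[0-9.eE+-]+\\s*$", v)) {
      parts <- as.numeric(strsplit(v, "/")[[1]])
      parts[1] / parts[2]
    } else {
      as.numeric(v)
    }
  })
  do.call(sigshift_config, args)
}
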