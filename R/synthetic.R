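# Gene-wise standard deviations from the scaled inverse-chi-square prior
# sigma_g^2 ~ prior_var * prior_df / chisq(prior_df): the model under
# which empirical-Bayes variance shrinkage is exactly specified.
draw_gene_sd <- function(n_genes, prior_df = 4, prior_var = 0.05) {
  sqrt(prior_var * prior_df / rchisq(n_genes, df = prior_df))
}

# Baselines from a two-component mixture: most genes well expressed, a
# fraction sitting near background so the detection filter has work to do.
draw_baselines <- function(n_genes, baseline_mean = 7, baseline_sd = 1.5,
                           frac_background = 0.15, background_mean = 3,
                           background_sd = 0.5) {
  near_bg <- runif(n_genes) < frac_background
  baseline <- ifelse(near_bg,
                     rnorm(n_genes, background_mean, background_sd),
                     rnorm(n_genes, baseline_mean, baseline_sd))
  list(baseline = baseline, near_background = near_bg)
}

expr_tibble <- function(mat, genes, sample_ids) {
  out <- tibble::as_tibble(as.data.frame(mat))
  names(out) <- sample_ids
  dplyr::bind_cols(tibble::tibble(gene = genes), out)
}

#' Simulate a labeled cell-population reference compendium
#'
#' Log2 expression is gene baseline plus a planted population-specific
#' marker effect plus Gaussian noise whose gene-wise variance is drawn
#' from the scaled inverse-chi-square prior matching the empirical-Bayes
#' model.  Marker blocks are disjoint across populations.
#'
#' @param n_genes Number of genes.
#' @param n_populations Number of cell populations.
#' @param n_replicates Replicate samples per population.
#' @param n_markers Planted marker genes per population.
#' @param marker_effect Marker elevation in log2 units.
#' @param baseline_mean,baseline_sd Expressed-gene baseline distribution
#'   (log2 units).
#' @param prior_df,prior_var Gene-variance prior (inverse-gamma shape via
#'   degrees of freedom, and scale).
#' @param seed Integer seed; identical seeds give identical output.
#' @return A list: `expression`, `samples` (with `population`), and
#'   `truth` (named list `markers`, plus effect and per-gene noise sd).
#' @export
make_compendium <- function(n_genes = 2000L, n_populations = 5L,
                            n_replicates = 3L, n_markers = 100L,
                            marker_effect = 2, baseline_mean = 7,
                            baseline_sd = 1.5, prior_df = 4,
                            prior_var = 0.05, seed = 1L) {
  if (n_markers * n_populations > n_genes) {
    abort("Marker blocks exceed the gene count; reduce `n_markers` or `n_populations`.")
  }
  with_seed(seed, {
    genes <- sprintf("g%04d", seq_len(n_genes))
    pops <- sprintf("pop%02d", seq_len(n_populations))
    baseline <- rnorm(n_genes, baseline_mean, baseline_sd)
    gene_sd <- draw_gene_sd(n_genes, prior_df, prior_var)
    markers <- lapply(seq_len(n_populations), function(k) {
      genes[((k - 1) * n_markers + 1):(k * n_markers)]
    })
    names(markers) <- pops
    sample_ids <- as.vector(vapply(pops, function(p) {
      paste0(p, "_r", seq_len(n_replicates))
    }, character(n_replicates)))
    pop_of <- rep(pops, each = n_replicates)
    mat <- matrix(baseline, n_genes, length(sample_ids)) +
      matrix(rnorm(n_genes * length(sample_ids), 0, gene_sd),
             n_genes, length(sample_ids))
    for (k in seq_along(pops)) {
      idx <- match(markers[[k]], genes)
      mat[idx, pop_of == pops[k]] <- mat[idx, pop_of == pops[k]] + marker_effect
    }
    list(
      expression = expr_tibble(mat, genes, sample_ids),
      samples = tibble::tibble(sample_id = sample_ids, population = pop_of),
      truth = list(markers = markers, marker_effect = marker_effect,
                   gene_sd = setNames(gene_sd, genes),
                   baseline = setNames(baseline, genes))
    )
  })
}

#' Simulate a 2x2 genotype-by-age expression study with infiltration
#'
#' Per sample, linear-scale expression is the host signal
#' `2^(baseline + planted effects + noise)` plus, for each infiltrating
#' population and each of its marker genes,
#' `weight * 2^(baseline + profile_effect)`; the sum is re-logged to
#' log2.  Infiltration is therefore additive on the linear scale, as a
#' cell mixture is, and marker fold changes respond sub-linearly to the
#' mixing weight.  Only the marker complement of a population
#' contributes: the uniform whole-transcriptome component of a real
#' mixture is removed by upstream normalization and is not simulated.
#' Planted host effects are a
#' genotype main effect (applied to KO samples), an age main effect
#' (applied to old samples), and an interaction effect (applied to old-KO
#' only, so it equals the interaction coefficient of the two-factor
#' model).  A configurable fraction of genes sits near background and is
#' flagged undetected in a random subset of samples.
#'
#' @param n_genes Number of genes.
#' @param cells Named integer vector of design cell sizes; names are
#'   `group` labels of the form `age-genotype` (young-WT, young-KO,
#'   old-WT, old-KO).
#' @param n_age,n_genotype,n_interaction Numbers of genes carrying each
#'   planted host effect (drawn from non-marker, well-expressed genes;
#'   the three sets are disjoint).
#' @param age_effect,genotype_effect,interaction_effect Effect magnitudes
#'   in log2 units; each affected gene gets a random sign.
#' @param populations Named list of marker gene-id vectors (e.g. from a
#'   compendium's `truth$markers`) defining infiltration profiles.
#'   Marker ids must be gene ids of this study (`g0001`-style).
#' @param infiltration Tibble with columns `population`, `group`,
#'   `weight` (non-negative linear mixing weight of that population's
#'   profile in every sample of that group).
#' @param profile_effect Marker elevation (log2) within an infiltrating
#'   population's pure profile.
#' @param baseline_mean,baseline_sd,frac_background,background_mean
#'   Baseline mixture parameters.
#' @param background_detect_rate Probability that a near-background gene
#'   is called detected in a given sample (well-expressed genes are
#'   always detected).
#' @param prior_df,prior_var Gene-variance prior.
#' @param seed Integer seed.
#' @return A list: `expression`, `samples` (columns `sample_id`, `group`,
#'   `genotype`, `age`), `detection`, and `truth` (planted effect sets
#'   with signed effects, infiltration weights, markers).
#' @export
make_study <- function(n_genes = 2000L,
                       cells = c("young-WT" = 5L, "young-KO" = 5L,
                                 "old-WT" = 6L, "old-KO" = 8L),
                       n_age = 0L, n_genotype = 0L, n_interaction = 0L,
                       age_effect = 1, genotype_effect = 1,
                       interaction_effect = 1,
                       populations = NULL, infiltration = NULL,
                       profile_effect = 4,
                       baseline_mean = 7, baseline_sd = 1.5,
                       frac_background = 0.15, background_mean = 3,
                       background_detect_rate = 0.3,
                       prior_df = 4, prior_var = 0.05, seed = 1L) {
  stopifnot(length(cells) == 4, all(cells >= 1))
  parts <- strsplit(names(cells), "-", fixed = TRUE)
  ages <- vapply(parts, `[`, "", 1)
  genos <- vapply(parts, `[`, "", 2)
  if (!setequal(paste(ages, genos), c("young WT", "young KO", "old WT", "old KO"))) {
    abort("`cells` must name the four young/old x WT/KO groups as 'age-genotype'.")
  }
  if (!is.null(infiltration)) {
    infiltration <- tibble::as_tibble(infiltration)
    stopifnot(all(c("population", "group", "weight") %in% names(infiltration)))
    if (any(infiltration$weight < 0)) abort("Infiltration weights must be non-negative.")
    if (is.null(populations)) abort("`infiltration` needs `populations` profiles.")
    unknown <- setdiff(infiltration$population, names(populations))
    if (length(unknown) > 0) {
      abort(paste0("Infiltration references undefined population(s): ",
                   paste(unknown, collapse = ", ")))
    }
  }
  with_seed(seed, {
    genes <- sprintf("g%04d", seq_len(n_genes))
    bl <- draw_baselines(n_genes, baseline_mean, baseline_sd,
                         frac_background, background_mean)
    gene_sd <- draw_gene_sd(n_genes, prior_df, prior_var)
    sample_ids <- unlist(lapply(seq_along(cells), function(i) {
      paste0(names(cells)[i], "_s", seq_len(cells[i]))
    }), use.names = FALSE)
    group <- rep(names(cells), times = cells)
    age <- rep(ages, times = cells)
    geno <- rep(genos, times = cells)
    n_samples <- length(sample_ids)

    marker_pool <- unique(unlist(populations, use.names = FALSE))
    free <- setdiff(genes[!bl$near_background], marker_pool)
    need <- n_age + n_genotype + n_interaction
    if (need > length(free)) abort("Not enough free genes for the requested effect sets.")
    chosen <- sample(free, need)
    effect_set <- function(ids, magnitude) {
      if (length(ids) == 0) return(tibble::tibble(gene = character(), effect = numeric()))
      tibble::tibble(gene = ids,
                     effect = magnitude * sample(c(-1, 1), length(ids), replace = TRUE))
    }
    age_set <- effect_set(chosen[seq_len(n_age)], age_effect)
    geno_set <- effect_set(chosen[n_age + seq_len(n_genotype)], genotype_effect)
    int_set <- effect_set(chosen[n_age + n_genotype + seq_len(n_interaction)],
                          interaction_effect)

    log2_host <- matrix(bl$baseline, n_genes, n_samples)
    add_effect <- function(mat, set, cols) {
      if (nrow(set) == 0 || !any(cols)) return(mat)
      idx <- match(set$gene, genes)
      mat[idx, cols] <- mat[idx, cols] + set$effect
      mat
    }
    log2_host <- add_effect(log2_host, age_set, age == "old")
    log2_host <- add_effect(log2_host, geno_set, geno == "KO")
    log2_host <- add_effect(log2_host, int_set, age == "old" & geno == "KO")
    log2_host <- log2_host +
      matrix(rnorm(n_genes * n_samples, 0, gene_sd), n_genes, n_samples)

    linear <- 2^log2_host
    weights_used <- NULL
    if (!is.null(infiltration) && nrow(infiltration) > 0) {
      # each population contributes through its marker complement only:
      # upstream normalization removes the uniform (whole-transcriptome)
      # component of a cell mixture, so only marker-specific excess
      # survives into a normalized matrix
      profiles <- lapply(populations, function(markers) {
        ifelse(genes %in% markers, 2^(bl$baseline + profile_effect), 0)
      })
      weights_used <- tidyr::expand_grid(
        sample_id = sample_ids,
        population = unique(infiltration$population)
      )
      weights_used$weight <- 0
      for (r in seq_len(nrow(infiltration))) {
        in_group <- group == infiltration$group[r]
        linear[, in_group] <- linear[, in_group] +
          infiltration$weight[r] * profiles[[infiltration$population[r]]]
        sel <- weights_used$population == infiltration$population[r] &
          weights_used$sample_id %in% sample_ids[in_group]
        weights_used$weight[sel] <- weights_used$weight[sel] + infiltration$weight[r]
      }
    }
    mat <- log2(linear)

    det <- matrix(TRUE, n_genes, n_samples)
    if (any(bl$near_background)) {
      nb <- which(bl$near_background)
      det[nb, ] <- matrix(runif(length(nb) * n_samples) < background_detect_rate,
                          length(nb), n_samples)
    }
    detection <- dplyr::bind_cols(
      tibble::tibble(gene = genes),
      tibble::as_tibble(as.data.frame(det)) |> setNames(sample_ids)
    )
    list(
      expression = expr_tibble(mat, genes, sample_ids),
      samples = tibble::tibble(sample_id = sample_ids, group = group,
                               genotype = geno, age = age),
      detection = detection,
      truth = list(
        age_genes = age_set, genotype_genes = geno_set,
        interaction_genes = int_set,
        infiltration = weights_used,
        markers = populations,
        near_background = genes[bl$near_background],
        gene_sd = setNames(gene_sd, genes)
      )
    )
  })
}

#' Simulate a two-group contrast dataset
#'
#' Two groups with planted up- and down-regulated genes, for exercising
#' signature selection in both directions (tissue-vs-tissue or
#' treatment-vs-control style comparisons).  `up`/`down` are relative to
#' the first label: an up gene is higher in group `labels[1]`.
#'
#' @param n_genes Number of genes.
#' @param n_per_group Samples per group.
#' @param labels Length-2 group labels.
#' @param n_up,n_down Numbers of planted up/down genes.
#' @param effect Planted effect magnitude in log2 units.
#' @param baseline_mean,baseline_sd,prior_df,prior_var As in
#'   [make_compendium()].
#' @param seed Integer seed.
#' @return A list: `expression`, `samples`, `truth` (`up_genes`,
#'   `down_genes`, `effect`).
#' @export
make_two_group <- function(n_genes = 2000L, n_per_group = 3L,
                           labels = c("A", "B"), n_up = 150L, n_down = 150L,
                           effect = 1.5, baseline_mean = 7, baseline_sd = 1.5,
                           prior_df = 4, prior_var = 0.05, seed = 1L) {
  if (n_up + n_down > n_genes) abort("Too many planted genes.")
  stopifnot(length(labels) == 2, n_per_group >= 2)
  with_seed(seed, {
    genes <- sprintf("g%04d", seq_len(n_genes))
    baseline <- rnorm(n_genes, baseline_mean, baseline_sd)
    gene_sd <- draw_gene_sd(n_genes, prior_df, prior_var)
    up_genes <- genes[seq_len(n_up)]
    down_genes <- genes[n_up + seq_len(n_down)]
    sample_ids <- c(paste0(labels[1], "_s", seq_len(n_per_group)),
                    paste0(labels[2], "_s", seq_len(n_per_group)))
    group <- rep(labels, each = n_per_group)
    mat <- matrix(baseline, n_genes, length(sample_ids)) +
      matrix(rnorm(n_genes * length(sample_ids), 0, gene_sd),
             n_genes, length(sample_ids))
    in_a <- group == labels[1]
    mat[match(up_genes, genes), in_a] <- mat[match(up_genes, genes), in_a] + effect
    mat[match(down_genes, genes), in_a] <- mat[match(down_genes, genes), in_a] - effect
    list(
      expression = expr_tibble(mat, genes, sample_ids),
      samples = tibble::tibble(sample_id = sample_ids, group = group),
      truth = list(up_genes = up_genes, down_genes = down_genes,
                   effect = effect, gene_sd = setNames(gene_sd, genes))
    )
  })
}

#' Preset end-to-end simulation scenarios
#'
#' Bundles a reference compendium and a 2x2 study emulating the
#' qualitative patterns an aging-infiltration experiment produces:
#'
#' * `"null"`: no planted structure anywhere.
#' * `"infiltration"`: monocyte-like infiltration in all old samples plus
#'   B-cell-like infiltration in old-KO only, so the B-like population
#'   dominates the old-KO vs old-WT enrichment ranking.
#' * `"steatosis"`: a WAT-like (adipose) profile whose weight rises with age
#'   much more in WT than in KO, so the WAT signature's overlap AUC for
#'   the aging contrast is larger in WT than in KO.
#'
#' @param preset `"null"`, `"infiltration"`, or `"steatosis"`.
#' @param seed Integer seed.
#' @param n_genes,n_populations Scenario size.
#' @return A list: `compendium` (from [make_compendium()]), `study` (from
#'   [make_study()]), and `scenario` (a list recording the preset, the
#'   infiltrating population of interest, and weights).
#' @export
simulate_preset <- function(preset = c("null", "infiltration", "steatosis"), seed = 1L,
                            n_genes = 2000L, n_populations = 5L) {
  preset <- match.arg(preset)
  comp <- make_compendium(n_genes = n_genes, n_populations = n_populations,
                          seed = seed)
  pops <- names(comp$truth$markers)
  scenario <- list(preset = preset, target_population = NA_character_)
  infiltration <- NULL
  if (preset == "infiltration") {
    # pop01 = monocyte-like (age-driven in both genotypes);
    # pop02 = B-cell-like (old-KO only)
    infiltration <- tibble::tibble(
      population = c("pop01", "pop01", "pop02"),
      group = c("old-WT", "old-KO", "old-KO"),
      weight = c(0.10, 0.10, 0.15)
    )
    scenario$target_population <- "pop02"
  } else if (preset == "steatosis") {
    # pop01 = WAT-like; aging raises its weight strongly in WT, weakly in KO
    infiltration <- tibble::tibble(
      population = c("pop01", "pop01", "pop01", "pop01"),
      group = c("young-WT", "young-KO", "old-WT", "old-KO"),
      weight = c(0.01, 0.01, 0.15, 0.04)
    )
    scenario$target_population <- "pop01"
  }
  study <- make_study(n_genes = n_genes, populations = comp$truth$markers,
                      infiltration = infiltration, seed = seed + 1L)
  scenario$infiltration <- infiltration
  list(compendium = comp, study = study, scenario = scenario)
}
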