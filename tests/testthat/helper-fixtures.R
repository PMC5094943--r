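options(sigshift.verbose = FALSE)

tiny_expr <- function() {
  tibble::tibble(
    gene = c("GeneA", "GeneB", "GeneC"),
    s1 = c(1.5, 2.25, -0.125),
    s2 = c(3.0, 0.5, 7.125)
  )
}

# balanced Ct table: one target shifted down by 2 cycles in old-KO
tiny_ct <- function(shift_group = "old-KO", shift = -2, noise = 0.05, seed = 42) {
  groups <- rep(c("young-WT", "young-KO", "old-WT", "old-KO"), each = 4)
  ids <- paste0("s", seq_along(groups))
  withr::with_seed(seed, dplyr::bind_rows(
    tibble::tibble(sample_id = ids, group = groups, gene = "Tgt",
                   ct = 25 + shift * (groups == shift_group) +
                     stats::rnorm(length(ids), 0, noise)),
    tibble::tibble(sample_id = ids, group = groups, gene = "Rn18s",
                   ct = 10 + stats::rnorm(length(ids), 0, noise))
  ))
}
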