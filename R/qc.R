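#' Merge barcode replicates into nucleotide-genotype estimates
#'
#' Each nucleotide genotype (primary barcode) is assigned the
#' cell-count-weighted mean fluorescence of its replicates, with the
#' replicate count, total cells and the index of dispersion (variance /
#' mean of replicate fluorescence on the linear scale, `10^mu`) recorded.
#' The dispersion cutoffs used downstream are only meaningful in linear
#' FACS units, hence the back-transform.
#'
#' @param estimates Calibrated estimates tibble (`primary`, `secondary`,
#'   `mu`, `n_cells`, `fit_ok`).
#' @return Tibble: `primary`, `fluorescence`, `n_replicates`,
#'   `total_cells`, `index_of_dispersion`.
#' @export
merge_replicates <- function(estimates) {
  estimates |>
    dplyr::filter(.data$fit_ok, .data$n_cells > 0) |>
    dplyr::group_by(.data$primary) |>
    dplyr::summarise(
      fluorescence = weighted.mean(.data$mu, .data$n_cells),
      n_replicates = dplyr::n(),
      total_cells = sum(.data$n_cells),
      index_of_dispersion = if (dplyr::n() > 1) {
        var(10^.data$mu) / mean(10^.data$mu)
      } else 0,
      .groups = "drop")
}

#' Quality-filter thresholds
#'
#' Presets reproduce the published per-landscape cutoffs: amacGFP,
#' cgreGFP and ppluGFP2 genotypes required, respectively, a minimum of 2,
#' 3 and 3 replicates; cell counts over 26, 14 and 23; and indices of
#' dispersion under 525, 575 and 1000.
#'
#' @param preset `"amacGFP"`, `"cgreGFP"`, `"ppluGFP2"` or `"custom"`.
#' @param min_replicates,min_cells,max_dispersion Custom thresholds
#'   (required when `preset = "custom"`).
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(preset = c("amacGFP", "cgreGFP", "ppluGFP2",
                                     "custom"),
                          min_replicates = NULL, min_cells = NULL,
                          max_dispersion = NULL) {
  preset <- match.arg(preset)
  vals <- switch(preset,
    amacGFP = list(min_replicates = 2, min_cells = 26,
                   max_dispersion = 525),
    cgreGFP = list(min_replicates = 3, min_cells = 14,
                   max_dispersion = 575),
    ppluGFP2 = list(min_replicates = 3, min_cells = 23,
                    max_dispersion = 1000),
    custom = list(min_replicates = min_replicates, min_cells = min_cells,
                  max_dispersion = max_dispersion))
  if (any(vapply(vals, is.null, logical(1)))) {
    stop("custom preset requires all three thresholds")
  }
  structure(c(vals, preset = preset), class = "qc_thresholds")
}

#' Apply quality filters to genotype records
#'
#' A record survives iff `n_replicates >= min_replicates`,
#' `total_cells > min_cells` and `index_of_dispersion < max_dispersion`.
#'
#' @param records Tibble from [merge_replicates()].
#' @param thresholds A [qc_thresholds()] object.
#' @return The surviving records.
#' @export
apply_qc <- function(records, thresholds = qc_thresholds("amacGFP")) {
  records |>
    dplyr::filter(.data$n_replicates >= thresholds$min_replicates,
                  .data$total_cells > thresholds$min_cells,
                  .data$index_of_dispersion < thresholds$max_dispersion)
}

#' Control-based false positive and false negative rates
#'
#' Chromophore-mutant genotypes are expected dark: the false positive
#' rate is the fraction of them classified bright. Genotypes encoding the
#' wildtype protein (synonymous-only) are expected bright: the false
#' negative rate is the fraction of them classified dim or dark. A single
#' threshold separates bright from dim/dark; by default it is midway
#' between the dark mode (median of chromophore mutants) and the mean of
#' the wildtype-coding genotypes.
#'
#' @param records Tibble with `aa_muts` and `fluorescence` (nucleotide- or
#'   protein-level).
#' @param chromophore_sites Integer positions of the chromophore.
#' @param dark_threshold Optional explicit bright/dark threshold (log10).
#' @return One-row tibble with `fp_rate`, `fp_n`, `fp_total`, `fn_rate`,
#'   `fn_n`, `fn_total`, `threshold`. Rates are `NA` when a control set
#'   is empty.
#' @export
control_error_rates <- function(records, chromophore_sites,
                                dark_threshold = NULL) {
  parsed <- parse_mutations(records$aa_muts)
  is_chromo <- vapply(parsed, function(p) {
    any(p$site %in% chromophore_sites)
  }, logical(1))
  is_wt <- records$aa_muts == ""
  wt_f <- records$fluorescence[is_wt]
  chromo_f <- records$fluorescence[is_chromo]
  thr <- dark_threshold %||%
    ((median(chromo_f) + mean(wt_f)) / 2)
  fp_total <- sum(is_chromo)
  fn_total <- sum(is_wt)
  tibble::tibble(
    fp_rate = if (fp_total > 0) mean(chromo_f >= thr) else NA_real_,
    fp_n = sum(chromo_f >= thr),
    fp_total = fp_total,
    fn_rate = if (fn_total > 0) mean(wt_f < thr) else NA_real_,
    fn_n = sum(wt_f < thr),
    fn_total = fn_total,
    threshold = thr)
}

#' Collapse synonymous nucleotide genotypes to protein genotypes
#'
#' Nucleotide genotypes coding for the same protein are merged with a
#' cell-count-weighted mean fluorescence. The synonymous-only wildtype
#' population additionally provides the wildtype reference mean and
#' standard deviation, stored as attributes `wt_mean`, `wt_sd`, `wt_n`.
#'
#' @param records Tibble with `aa_muts`, `fluorescence`, `total_cells`
#'   (and optionally `n_replicates`).
#' @return Protein-level tibble: `aa_muts`, `n_muts`, `fluorescence`,
#'   `total_cells`, `n_nt_genotypes`.
#' @export
collapse_synonymous <- function(records) {
  out <- records |>
    dplyr::group_by(.data$aa_muts) |>
    dplyr::summarise(
      fluorescence = weighted.mean(.data$fluorescence, .data$total_cells),
      total_cells = sum(.data$total_cells),
      n_nt_genotypes = dplyr::n(),
      .groups = "drop") |>
    dplyr::mutate(n_muts = vapply(parse_mutations(.data$aa_muts), nrow,
                                  integer(1))) |>
    dplyr::relocate("aa_muts", "n_muts")
  wt_f <- records$fluorescence[records$aa_muts == ""]
  attr(out, "wt_mean") <- if (length(wt_f) > 0) mean(wt_f) else NA_real_
  attr(out, "wt_sd") <- if (length(wt_f) > 1) sd(wt_f) else NA_real_
  attr(out, "wt_n") <- length(wt_f)
  out
}
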