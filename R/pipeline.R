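#' Configuration of an end-to-end synthetic sort-seq analysis
#'
#' @param preset Landscape preset (`"flat"` or `"sharp"`).
#' @param length Protein length (default 235 residues).
#' @param n_genotypes Library size (default 2000).
#' @param qc_preset QC threshold preset name.
#' @param reads_per_half,coding_error_rate Genotyping-read settings.
#' @param run_model Train fitness networks (default TRUE).
#' @param run_design Run the genetic-algorithm design stage (default
#'   FALSE; requires `run_model`).
#' @param model_candidates Architectures sampled in the grid search.
#' @param design_target,design_picks Design stage settings.
#' @param out_dir Optional directory for TSV/JSON outputs.
#' @param seed Global seed; stage seeds are derived from it.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(preset = "flat", length = 235,
                            n_genotypes = 2000, qc_preset = "amacGFP",
                            reads_per_half = 8,
                            coding_error_rate = 0.002,
                            run_model = TRUE, run_design = FALSE,
                            model_candidates = 4, design_target = 6,
                            design_picks = 8, out_dir = NULL, seed = 1) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full synthetic sort-seq pipeline
#'
#' Simulates a ground-truth landscape and library, sorts and sequences
#' it, calls genotypes, infers fluorescence, applies quality control,
#' computes landscape statistics, optionally trains fitness networks and
#' designs distant variants, and collates a summary.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_run` with each stage's output and a
#'   `summary` list of headline statistics.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  t0 <- Sys.time()
  landscape <- make_landscape(config$length,
                              landscape_preset(config$preset),
                              seed = config$seed)
  spec <- library_spec(n_genotypes = config$n_genotypes,
                       seed = config$seed + 1)
  gates <- gate_scheme()
  library <- generate_library(landscape, spec)
  sim <- simulate_sort(library, landscape, spec, gates)

  coding <- simulate_coding_reads(
    library, per_base_error_rate = config$coding_error_rate,
    reads_per_half = config$reads_per_half, seed = config$seed + 2)
  calls <- call_genotypes(coding, landscape$wildtype_cds)
  accepted <- calls[calls$status == "accepted",
                    c("primary", "aa_muts")]

  counts <- merge_secondary_barcodes(sim$counts)
  normalized <- normalize_by_count_controls(counts, sim$controls,
                                            spec$count_control_cells)
  estimates <- estimate_fluorescence(normalized, gates)
  wt_primaries <- library$primary[library$wt_control]
  calibration <- calibrate_machines(estimates, wt_primaries)
  estimates <- apply_calibration(estimates, calibration)

  genotypes <- merge_replicates(estimates) |>
    dplyr::filter(!.data$primary %in% wt_primaries) |>
    dplyr::inner_join(accepted, by = "primary")
  errors <- control_error_rates(genotypes, landscape$chromophore_sites)
  qc_pass <- apply_qc(genotypes, qc_thresholds(config$qc_preset))
  dataset <- collapse_synonymous(qc_pass)

  singles <- single_effects(dataset)
  epi <- epistasis(dataset, singles)
  curve <- additive_fraction_curve(epi,
                                   functional_threshold =
                                     gates$boundaries[1])
  ld50_lof <- try(fit_ld50(dataset, "loss_of_function",
                           functional_threshold = gates$boundaries[1]),
                  silent = TRUE)
  ld50_wt <- try(fit_ld50(dataset, "loss_of_wt_level"), silent = TRUE)
  profile <- try(peak_profile(dataset), silent = TRUE)

  model <- NULL; posterior <- NULL; encoded <- NULL
  r2_linear <- NA_real_; r2_best <- NA_real_; search <- NULL
  if (config$run_model) {
    encoded <- encode_genotypes(dataset, landscape$wildtype) |>
      split_dataset(seed = config$seed + 3) |>
      filter_for_training()
    linear <- train_fitnet(encoded, arch_linear(),
                           seed = config$seed + 4)
    r2_linear <- tryCatch(model_r2(linear, encoded),
                          error = function(e) NA_real_)
    gs <- grid_search(encoded, n_candidates = config$model_candidates,
                      seed = config$seed + 5)
    model <- gs$model
    search <- gs$search
    r2_best <- tryCatch(model_r2(model, encoded),
                        error = function(e) NA_real_)
  }

  designs <- NULL; picks <- NULL
  if (config$run_design && config$run_model) {
    posterior <- train_posterior(encoded, seed = config$seed + 6)
    panel <- synthetic_natural_panel(landscape, seed = config$seed + 7)
    train_genos <- encoded$genotypes[encoded$split == "train"]
    pool <- build_pool(dataset, train_genos, landscape$wildtype, panel)
    pops <- evolve_replicates(
      model, pool,
      ga_params(target_muts = config$design_target,
                seed = config$seed + 8),
      landscape$wildtype)
    designs <- filter_candidates(pops, model, posterior,
                                 config$design_target,
                                 seed = config$seed + 9)
    if (nrow(designs) > 0) {
      picks <- select_diverse(designs,
                              min(config$design_picks, nrow(designs)),
                              landscape$wildtype)
    }
  }

  summary <- list(
    preset = config$preset,
    n_library = nrow(library),
    mean_aa_substitutions = mean(library$n_aa_muts[!library$wt_control]),
    n_called = sum(calls$status == "accepted"),
    n_genotypes_qc = nrow(qc_pass),
    n_protein_genotypes = nrow(dataset),
    wt_mean = attr(dataset, "wt_mean"),
    wt_sd = attr(dataset, "wt_sd"),
    fp_rate = errors$fp_rate,
    fn_rate = errors$fn_rate,
    ld50_loss_of_function = if (inherits(ld50_lof, "logistic_fit"))
      ld50_lof$ld50 else NA_real_,
    ld50_loss_of_wt_level = if (inherits(ld50_wt, "logistic_fit"))
      ld50_wt$ld50 else NA_real_,
    frac_epistasis_gt_0.3 = mean(abs(epi$epistasis[epi$computable &
                                                     epi$n_muts >= 2])
                                 > 0.3),
    r2_linear = r2_linear,
    r2_two_layer = r2_best,
    n_designs = if (is.null(designs)) NA_integer_ else nrow(designs),
    calibration_slope = calibration$slope,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  run <- structure(list(
    config = config, landscape = landscape, library = library,
    sim = sim, calls = calls, estimates = estimates,
    calibration = calibration, genotypes = genotypes, errors = errors,
    dataset = dataset, singles = singles, epistasis = epi,
    additive_fraction = curve,
    ld50_loss_of_function = if (inherits(ld50_lof, "logistic_fit"))
      ld50_lof else NULL,
    ld50_loss_of_wt_level = if (inherits(ld50_wt, "logistic_fit"))
      ld50_wt else NULL,
    peak_profile = if (inherits(profile, "try-error")) NULL else profile,
    model = model, model_search = search, posterior = posterior,
    encoded = encoded, designs = designs, picks = picks,
    summary = summary), class = "pipeline_run")

  if (!is.null(config$out_dir)) write_pipeline(run, config$out_dir)
  run
}

#' @export
print.pipeline_run <- function(x, ...) {
  s <- x$summary
  cat("<pipeline_run '", s$preset, "'> ", s$n_library, " genotypes, ",
      s$n_protein_genotypes, " after QC+collapse\n",
      "  mean substitutions ", round(s$mean_aa_substitutions, 2),
      "; FP ", signif(100 * s$fp_rate, 2), "%, FN ",
      signif(100 * s$fn_rate, 2), "%\n",
      "  LD50 (loss of function) ", signif(s$ld50_loss_of_function, 3),
      "; LD50 (wt level) ", signif(s$ld50_loss_of_wt_level, 3), "\n",
      sep = "")
  if (!is.na(s$r2_linear)) {
    cat("  validation R2: linear ", signif(s$r2_linear, 3),
        ", two-layer ", signif(s$r2_two_layer, 3), "\n", sep = "")
  }
  invisible(x)
}

# Persist the main tables and summary of a run.
write_pipeline <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(run$dataset, file.path(out_dir, "dataset.tsv"))
  readr::write_tsv(run$singles, file.path(out_dir, "single_effects.tsv"))
  readr::write_tsv(run$epistasis, file.path(out_dir, "epistasis.tsv"))
  readr::write_tsv(run$calls, file.path(out_dir, "consensus_calls.tsv"))
  if (!is.null(run$designs)) {
    readr::write_tsv(run$designs, file.path(out_dir, "designs.tsv"))
  }
  jsonlite::write_json(run$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Write reads as FASTQ
#'
#' Constant quality strings; gate/sorter metadata goes in the read name.
#'
#' @param reads Tibble with a `seq` column; other columns are encoded in
#'   the read names.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_fastq <- function(reads, path) {
  meta <- reads[setdiff(names(reads), "seq")]
  names_part <- if (ncol(meta) > 0) {
    apply(meta, 1, function(r) paste(paste0(names(meta), "=", r),
                                     collapse = ";"))
  } else rep("", nrow(reads))
  lines <- as.vector(rbind(
    paste0("@read", seq_len(nrow(reads)),
           ifelse(names_part == "", "", paste0(" ", names_part))),
    reads$seq,
    "+",
    strrep("I", nchar(reads$seq))))
  writeLines(lines, path)
  invisible(path)
}
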