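# Small shared fixtures, built in code at test time.

tiny_landscape <- function(seed = 2, preset = "flat", length = 60) {
  make_landscape(length, landscape_preset(preset), seed = seed)
}

# additive-only landscape: no epistatic terms
additive_landscape <- function(seed = 11, length = 60) {
  make_landscape(length,
                 landscape_config(epistasis_density = 0),
                 seed = seed)
}

# protein-level dataset straight from landscape truth (noise-free)
truth_dataset <- function(landscape, n = 2000, seed = 5, ...) {
  g <- sample_genotypes(landscape, n, seed = seed, ...)
  g <- dplyr::distinct(g, aa_muts, .keep_all = TRUE)
  g$fluorescence <- g$true_f
  g$total_cells <- 100
  g$n_nt_genotypes <- 1L
  attr(g, "wt_mean") <- landscape$config$f_wt
  attr(g, "wt_sd") <- 0.03
  g
}

# dataset additive on the fluorescence scale itself (no threshold, no
# chromophore override): the exact no-epistasis null of the additive
# expectation
additive_truth_dataset <- function(landscape, n = 3000, seed = 5, ...) {
  g <- sample_genotypes(landscape, n, seed = seed, ...)
  g <- dplyr::distinct(g, aa_muts, .keep_all = TRUE)
  g$fluorescence <- landscape$config$f_wt +
    fitness_potential(landscape, g$aa_muts)
  g$total_cells <- 100
  g$n_nt_genotypes <- 1L
  attr(g, "wt_mean") <- landscape$config$f_wt
  attr(g, "wt_sd") <- 0.03
  g
}

# hand-built half-amplicon reads for one barcode
make_reads <- function(primary, cds, n_fwd = 5, n_rev = 5,
                       overlap = 30, mutate_read = NULL) {
  len <- nchar(cds)
  mid <- floor(len / 2)
  n_end <- min(mid + ceiling(overlap / 2), len)
  c_start <- max(n_end - overlap + 1, 1)
  halves <- c(N = substr(cds, 1, n_end), C = substr(cds, c_start, len))
  rows <- list()
  for (h in c("N", "C")) {
    fwd <- paste0(primary, sortscape:::MISEQ_CONSTANT, halves[[h]])
    rc <- sortscape:::reverse_complement(halves[[h]])
    rev <- paste0(primary, sortscape:::MISEQ_CONSTANT, rc)
    rows[[h]] <- tibble::tibble(
      primary = primary, half = h,
      dir = rep(c("fwd", "rev"), c(n_fwd, n_rev)),
      seq = c(rep(fwd, n_fwd), rep(rev, n_rev)))
  }
  out <- dplyr::bind_rows(rows)
  if (!is.null(mutate_read)) out <- mutate_read(out)
  out
}

# gate-count tibble from named vectors
gate_counts_tbl <- function(...) {
  rows <- list(...)
  dplyr::bind_rows(lapply(rows, function(r) {
    tibble::tibble(primary = r$primary,
                   secondary = r$secondary,
                   sorter = r$sorter %||% "A",
                   gate = r$gate, reads = r$reads)
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
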