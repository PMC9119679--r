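#' Specification of a simulated sort-seq library
#'
#' Defaults emulate the published experimental scale: error-prone PCR
#' libraries averaging ~4 amino-acid substitutions per clone, several
#' secondary-barcode replicates per genotype, ~35 sorted cells per
#' replicate, and 5000 count-control cells of each control barcode spiked
#' into every gate.
#'
#' @param n_genotypes Number of primary-barcoded genotypes.
#' @param per_nt_mutation_rate Per-base substitution probability; `NULL`
#'   calibrates the rate to `target_mean_aa` substitutions per genotype.
#' @param target_mean_aa Target mean amino-acid substitutions (used only
#'   when `per_nt_mutation_rate` is `NULL`).
#' @param mean_barcode_replicates Expected secondary barcodes per primary.
#' @param cells_per_replicate_mean Expected sorted cells per replicate.
#' @param reads_per_cell Expected sequencing reads per sorted cell.
#' @param missort_rate Probability a cell is recorded one gate away from
#'   its true gate.
#' @param count_control_cells Cells per count-control barcode per gate.
#' @param n_controls Number of count-control barcodes.
#' @param n_wildtype_controls Known-barcode spike-in standards used as
#'   positive controls and machine-calibration anchors; they emulate the
#'   wildtype GFPs of several orthologs added to each library, so their
#'   known brightness levels span the measurement range (`anchor_levels`
#'   below the landscape wildtype).
#' @param anchor_levels Log10 offsets below the wildtype fluorescence at
#'   which the spike-in standards sit (recycled over the standards).
#' @param seed RNG seed used by the simulators.
#' @return A list of class `library_spec`.
#' @export
library_spec <- function(n_genotypes = 2000,
                         per_nt_mutation_rate = NULL,
                         target_mean_aa = 4,
                         mean_barcode_replicates = 8,
                         cells_per_replicate_mean = 35,
                         reads_per_cell = 2,
                         missort_rate = 0.005,
                         count_control_cells = 5000,
                         n_controls = 4,
                         n_wildtype_controls = 20,
                         anchor_levels = c(0, 0.4, 0.8, 1.2),
                         seed = 1) {
  rates <- c(per_nt_mutation_rate %||% 0, missort_rate)
  stopifnot(all(rates >= 0), all(rates <= 1),
            n_genotypes > 0, mean_barcode_replicates > 0,
            cells_per_replicate_mean > 0, reads_per_cell > 0,
            count_control_cells > 0)
  structure(list(n_genotypes = n_genotypes,
                 per_nt_mutation_rate = per_nt_mutation_rate,
                 target_mean_aa = target_mean_aa,
                 mean_barcode_replicates = mean_barcode_replicates,
                 cells_per_replicate_mean = cells_per_replicate_mean,
                 reads_per_cell = reads_per_cell,
                 missort_rate = missort_rate,
                 count_control_cells = count_control_cells,
                 n_controls = n_controls,
                 n_wildtype_controls = n_wildtype_controls,
                 anchor_levels = anchor_levels,
                 seed = seed), class = "library_spec")
}

#' FACS gate scheme
#'
#' Seven increasing log10-fluorescence boundaries define eight gates;
#' gate 1 is open below the first boundary (the darkest gate) and gate 8
#' open above the last. A second sorter is simulated as an affine
#' distortion of the measurement scale: machine B records
#' `b_scale * F + b_offset` and applies the same nominal boundaries.
#'
#' @param boundaries Seven strictly increasing log10 thresholds.
#' @param b_scale,b_offset Affine distortion of sorter B's scale.
#' @return A list of class `gate_scheme`.
#' @export
gate_scheme <- function(boundaries = c(2.0, 2.4, 2.8, 3.2, 3.6, 4.0, 4.4),
                        b_scale = 1.05, b_offset = -0.15) {
  stopifnot(length(boundaries) == 7, all(diff(boundaries) > 0), b_scale > 0)
  structure(list(boundaries = boundaries, n_gates = 8L,
                 b_scale = b_scale, b_offset = b_offset),
            class = "gate_scheme")
}

# Expected amino-acid substitutions per genotype is ~ rate * sum over nt
# sites of the fraction of single-base changes that alter the protein;
# invert that relation for a target mean (single-hit approximation).
#' Calibrate the per-base mutation rate to a target substitution count
#'
#' @param cds Coding sequence (without the stop codon is fine).
#' @param target_mean_aa Desired mean amino-acid substitutions (including
#'   nonsense changes) per genotype.
#' @return Per-base substitution probability.
#' @export
calibrate_nt_rate <- function(cds, target_mean_aa = 4) {
  n <- nchar(cds) - nchar(cds) %% 3
  codons <- substring(cds, seq(1, n, 3), seq(3, n, 3))
  ns_frac <- 0
  for (cd in codons) {
    aa <- GENETIC_CODE_1[[cd]]
    for (pos in 1:3) {
      for (alt in setdiff(NT_ALPHABET, substr(cd, pos, pos))) {
        cd2 <- cd
        substr(cd2, pos, pos) <- alt
        if (GENETIC_CODE_1[[cd2]] != aa) ns_frac <- ns_frac + 1 / 3
      }
    }
  }
  target_mean_aa / ns_frac
}

#' Generate a barcoded mutant library
#'
#' Applies i.i.d. per-base substitutions to the wildtype CDS of each of
#' `n_genotypes` clones and assigns unique 20-nt primary barcodes
#' (collisions are regenerated). Synonymous-only genotypes and
#' chromophore/nonsense mutants arise by chance, exactly as in an
#' error-prone PCR library.
#'
#' @param landscape A [make_landscape()] landscape.
#' @param spec A [library_spec()].
#' @return Tibble with `primary`, `cds`, `aa_muts`, `n_aa_muts`,
#'   `premature_stop`, `true_f`.
#' @export
generate_library <- function(landscape, spec = library_spec()) {
  set.seed(spec$seed)
  rate <- spec$per_nt_mutation_rate %||%
    calibrate_nt_rate(substr(landscape$wildtype_cds, 1,
                             3 * landscape$length),
                      spec$target_mean_aa)
  cds_wt <- substr(landscape$wildtype_cds, 1, 3 * landscape$length)
  nt <- strsplit(cds_wt, "")[[1]]
  n_nt <- length(nt)
  n <- spec$n_genotypes

  mut_mask <- matrix(runif(n * n_nt) < rate, nrow = n)
  cds <- vapply(seq_len(n), function(i) {
    s <- nt
    idx <- which(mut_mask[i, ])
    if (length(idx) > 0) {
      s[idx] <- vapply(idx, function(j) {
        sample(setdiff(NT_ALPHABET, s[j]), 1)
      }, character(1))
    }
    paste(s, collapse = "")
  }, character(1))

  prot <- vapply(cds, translate_cds, character(1), USE.NAMES = FALSE)
  premature_stop <- grepl("*", prot, fixed = TRUE)
  aa_muts <- protein_mutations(landscape$wildtype, prot)
  # known-barcode spike-in standards (ortholog wildtypes of graded
  # brightness in the real experiment) used as calibration anchors
  n_wt <- spec$n_wildtype_controls
  anchor_f <- landscape$config$f_wt -
    rep(spec$anchor_levels, length.out = n_wt)
  lib <- tibble::tibble(
    primary = unique_barcodes(n + n_wt, 20),
    cds = c(cds, rep(cds_wt, n_wt)),
    aa_muts = c(aa_muts, rep("", n_wt)),
    premature_stop = c(premature_stop, rep(FALSE, n_wt)),
    wt_control = rep(c(FALSE, TRUE), c(n, n_wt)))
  lib$n_aa_muts <- vapply(parse_mutations(lib$aa_muts), nrow, integer(1))
  lib$true_f <- c(true_fluorescence(landscape, lib$aa_muts[seq_len(n)]),
                  anchor_f)
  lib <- dplyr::relocate(lib, "primary", "cds", "aa_muts", "n_aa_muts",
                         "premature_stop", "true_f", "wt_control")
  attr(lib, "per_nt_mutation_rate") <- rate
  lib
}

#' Simulate FACS sorting and gate-count sequencing of a library
#'
#' Each primary barcode receives a Poisson-distributed number of secondary
#' barcode replicates; each replicate is assigned to one of two sorters
#' and sorts a Poisson number of cells. Every cell draws a log10
#' fluorescence from Normal(true F, cell_noise_sd), is binned by the
#' sorter's gate boundaries (sorter B on its distorted scale), mis-sorted
#' into an adjacent gate with probability `missort_rate`, and emits a
#' Poisson number of reads. Count-control barcodes are spiked in with
#' exactly `count_control_cells` cells per gate and sorter.
#'
#' @param library A [generate_library()] tibble.
#' @param landscape The landscape that generated it.
#' @param spec The [library_spec()].
#' @param gates A [gate_scheme()].
#' @return A list of class `sort_sim` with elements `counts` (tibble:
#'   `primary`, `secondary`, `sorter`, `gate`, `reads`), `cells` (same
#'   keys with true sorted `cells`), `controls` (control barcodes),
#'   `truth` (the library with true fluorescence), `gates`, `spec`.
#' @export
simulate_sort <- function(library, landscape, spec = library_spec(),
                          gates = gate_scheme()) {
  set.seed(spec$seed + 1L)
  n <- nrow(library)
  n_rep <- 1L + rpois(n, max(spec$mean_barcode_replicates - 1, 0))
  rep_tbl <- tibble::tibble(
    primary = rep(library$primary, n_rep),
    true_f = rep(library$true_f, n_rep))
  n_reps_total <- nrow(rep_tbl)
  rep_tbl$secondary <- unique_barcodes(n_reps_total, 10)
  rep_tbl$sorter <- sample(c("A", "B"), n_reps_total, replace = TRUE)
  rep_tbl$n_cells <- rpois(n_reps_total, spec$cells_per_replicate_mean)

  cell <- tibble::tibble(
    rep_id = rep(seq_len(n_reps_total), rep_tbl$n_cells),
    f = rnorm(sum(rep_tbl$n_cells),
              rep(rep_tbl$true_f, rep_tbl$n_cells),
              landscape$config$cell_noise_sd),
    sorter = rep(rep_tbl$sorter, rep_tbl$n_cells))
  measured <- ifelse(cell$sorter == "B",
                     gates$b_scale * cell$f + gates$b_offset, cell$f)
  gate <- findInterval(measured, gates$boundaries) + 1L
  mis <- runif(nrow(cell)) < spec$missort_rate
  shift <- ifelse(runif(nrow(cell)) < 0.5, -1L, 1L)
  gate[mis] <- pmin(pmax(gate[mis] + shift[mis], 1L), gates$n_gates)
  cell$gate <- gate

  cells <- cell |>
    dplyr::count(.data$rep_id, .data$gate, name = "cells") |>
    dplyr::left_join(
      tibble::tibble(rep_id = seq_len(n_reps_total),
                     primary = rep_tbl$primary,
                     secondary = rep_tbl$secondary,
                     sorter = rep_tbl$sorter),
      by = "rep_id") |>
    dplyr::select("primary", "secondary", "sorter", "gate", "cells")

  counts <- cells |>
    dplyr::mutate(reads = rpois(dplyr::n(),
                                .data$cells * spec$reads_per_cell)) |>
    dplyr::filter(.data$reads > 0) |>
    dplyr::select("primary", "secondary", "sorter", "gate", "reads")

  controls <- unique_barcodes(spec$n_controls, 20)
  ctrl <- tidyr::expand_grid(
    primary = controls,
    sorter = c("A", "B"),
    gate = seq_len(gates$n_gates)) |>
    dplyr::mutate(
      secondary = strrep("A", 10),
      cells = spec$count_control_cells,
      reads = rpois(dplyr::n(),
                    spec$count_control_cells * spec$reads_per_cell)) |>
    dplyr::select("primary", "secondary", "sorter", "gate", "reads")

  structure(list(
    counts = dplyr::bind_rows(counts, ctrl),
    cells = cells,
    controls = controls,
    truth = library,
    gates = gates,
    spec = spec), class = "sort_sim")
}

#' Expand simulated gate counts into barcode-carrying read sequences
#'
#' Emits one row per read with the sequence layout used by the gate-count
#' caller: 20-nt primary barcode, 10-bp constant region, 10-nt secondary
#' barcode. Intended for small simulations that exercise the read-level
#' path; the compact count table carries the same information.
#'
#' @param sim A [simulate_sort()] result.
#' @return Tibble with `seq`, `sorter`, `gate`.
#' @export
sort_reads <- function(sim) {
  counts <- sim$counts
  tibble::tibble(
    seq = rep(paste0(counts$primary, HISEQ_CONSTANT, counts$secondary),
              counts$reads),
    sorter = rep(counts$sorter, counts$reads),
    gate = rep(counts$gate, counts$reads))
}

#' Simulate paired half-amplicon genotyping reads
#'
#' The coding sequence is amplified as two overlapping halves, each
#' sequenced as forward/reverse read pairs carrying the primary barcode
#' and a constant region. Substitution errors are i.i.d. per base over
#' the whole read (barcode and constant region included); quality values
#' are not modeled.
#'
#' @param library A [generate_library()] tibble.
#' @param per_base_error_rate Substitution error probability (<= 0.05).
#' @param reads_per_half Expected read pairs per half (Poisson).
#' @param overlap Overlap (nt) between the two halves.
#' @param seed RNG seed.
#' @return Tibble with `primary` (truth label), `half` ("N"/"C"), `dir`
#'   ("fwd"/"rev"), `seq` (barcode + constant + payload).
#' @export
simulate_coding_reads <- function(library, per_base_error_rate = 0.005,
                                  reads_per_half = 10, overlap = 30,
                                  seed = 1) {
  stopifnot(per_base_error_rate >= 0, per_base_error_rate <= 0.05)
  set.seed(seed)
  len <- nchar(library$cds[1])
  mid <- floor(len / 2)
  n_end <- min(mid + ceiling(overlap / 2), len)
  c_start <- max(n_end - overlap + 1, 1)

  one_bc <- function(primary, cds) {
    halves <- c(N = substr(cds, 1, n_end), C = substr(cds, c_start, len))
    out <- list()
    for (h in c("N", "C")) {
      n_pairs <- rpois(1, reads_per_half)
      if (n_pairs == 0) next
      fwd <- paste0(primary, MISEQ_CONSTANT, halves[[h]])
      rev <- paste0(primary, MISEQ_CONSTANT, reverse_complement(halves[[h]]))
      seqs <- c(rep(fwd, n_pairs), rep(rev, n_pairs))
      out[[h]] <- tibble::tibble(
        primary = primary, half = h,
        dir = rep(c("fwd", "rev"), each = n_pairs),
        seq = seqs)
    }
    dplyr::bind_rows(out)
  }
  reads <- dplyr::bind_rows(
    lapply(seq_len(nrow(library)), function(i) {
      one_bc(library$primary[i], library$cds[i])
    }))
  if (nrow(reads) > 0 && per_base_error_rate > 0) {
    reads$seq <- add_read_errors(reads$seq, per_base_error_rate)
  }
  attr(reads, "overlap") <- overlap
  reads
}

# i.i.d. substitution errors over full read sequences
add_read_errors <- function(seqs, rate) {
  chars <- strsplit(seqs, "")
  lens <- lengths(chars)
  flat <- unlist(chars)
  hit <- which(runif(length(flat)) < rate)
  if (length(hit) > 0) {
    flat[hit] <- vapply(flat[hit], function(b) {
      sample(setdiff(NT_ALPHABET, b), 1)
    }, character(1), USE.NAMES = FALSE)
  }
  vapply(split(flat, rep(seq_along(seqs), lens)), paste,
         character(1), collapse = "", USE.NAMES = FALSE)
}
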