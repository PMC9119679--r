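#' Call consensus genotypes from half-amplicon reads
#'
#' Implements the barcode consensus rules used for genotyping sort-seq
#' libraries: reads lacking the constant region next to the barcode are
#' dropped; per barcode, half and read direction a per-position consensus
#' is built; barcodes with fewer than `min_reads` reads in one or both
#' halves, or with less than `agreement` agreement at any position, are
#' discarded. Forward and reverse consensi must agree exactly, the two
#' halves must match 100% over their expected overlap, and the merged
#' sequence is compared to the wildtype CDS; calls containing indels are
#' rejected (the downstream genotype model is substitution-only).
#'
#' @param reads Tibble from [simulate_coding_reads()] (columns `half`,
#'   `dir`, `seq`; the `primary` column, if present, is ignored — barcodes
#'   are taken from the reads themselves).
#' @param wildtype_cds Wildtype coding sequence (no stop codon needed; any
#'   trailing stop is trimmed to a multiple of 3 at translation).
#' @param min_reads Minimum reads per half (default 5).
#' @param agreement Minimum per-position consensus agreement (default 0.8;
#'   exact ties fail this threshold).
#' @param constant Constant-region motif expected at positions 21-30.
#' @return Tibble of consensus calls: `primary`, `status`
#'   (`"accepted"`/`"rejected"`), `reason`, `cds`, `nt_muts`, `aa_muts`,
#'   `n_reads_N`, `n_reads_C`. The attribute `"dropped_reads"` counts
#'   reads discarded for a missing constant region.
#' @export
call_genotypes <- function(reads, wildtype_cds, min_reads = 5,
                           agreement = 0.8, constant = MISEQ_CONSTANT) {
  has_const <- substr(reads$seq, 21, 30) == constant
  dropped <- sum(!has_const)
  reads <- reads[has_const, , drop = FALSE]
  bc <- substr(reads$seq, 1, 20)
  payload <- substring(reads$seq, 31)

  wt_len <- nchar(wildtype_cds) - nchar(wildtype_cds) %% 3
  wildtype_cds <- substr(wildtype_cds, 1, wt_len)
  # the amplicons cover the coding region proper; drop a trailing stop
  last_codon <- substr(wildtype_cds, wt_len - 2, wt_len)
  if (!is.na(GENETIC_CODE_1[last_codon]) &&
      GENETIC_CODE_1[[last_codon]] == "*") {
    wt_len <- wt_len - 3
    wildtype_cds <- substr(wildtype_cds, 1, wt_len)
  }
  wt_prot <- translate_cds(wildtype_cds)

  groups <- split(seq_along(bc), bc)
  calls <- lapply(names(groups), function(b) {
    idx <- groups[[b]]
    h <- reads$half[idx]
    d <- reads$dir[idx]
    pay <- payload[idx]
    n_N <- sum(h == "N")
    n_C <- sum(h == "C")
    rejected <- function(reason) {
      tibble::tibble(primary = b, status = "rejected", reason = reason,
                     cds = NA_character_, nt_muts = NA_character_,
                     aa_muts = NA_character_, n_reads_N = n_N,
                     n_reads_C = n_C)
    }
    if (n_N < min_reads || n_C < min_reads) {
      return(rejected("insufficient_reads"))
    }
    half_cons <- list()
    for (hh in c("N", "C")) {
      cons_by_dir <- list()
      for (dd in c("fwd", "rev")) {
        stack <- pay[h == hh & d == dd]
        if (length(stack) == 0) next
        if (length(unique(nchar(stack))) != 1) {
          return(rejected("length_mismatch"))
        }
        cons <- position_consensus(stack, agreement)
        if (is.null(cons)) return(rejected("low_agreement"))
        if (dd == "rev") cons <- reverse_complement(cons)
        cons_by_dir[[dd]] <- cons
      }
      if (length(cons_by_dir) == 2 &&
          cons_by_dir$fwd != cons_by_dir$rev) {
        return(rejected("fwd_rev_mismatch"))
      }
      half_cons[[hh]] <- cons_by_dir[[1]]
    }
    n_len <- nchar(half_cons$N)
    c_len <- nchar(half_cons$C)
    ov <- n_len + c_len - wt_len
    if (ov < 1) return(rejected("no_overlap"))
    tail_n <- substring(half_cons$N, n_len - ov + 1)
    head_c <- substr(half_cons$C, 1, ov)
    if (tail_n != head_c) return(rejected("overlap_mismatch"))
    cds <- paste0(half_cons$N, substring(half_cons$C, ov + 1))
    if (nchar(cds) != wt_len) return(rejected("indel"))
    wt_chars <- strsplit(wildtype_cds, "")[[1]]
    cd_chars <- strsplit(cds, "")[[1]]
    diff_nt <- which(cd_chars != wt_chars)
    nt_muts <- format_mutations(diff_nt, wt_chars[diff_nt],
                                cd_chars[diff_nt])
    aa_muts <- protein_mutations(wt_prot, translate_cds(cds))
    tibble::tibble(primary = b, status = "accepted", reason = NA_character_,
                   cds = cds, nt_muts = nt_muts, aa_muts = aa_muts,
                   n_reads_N = n_N, n_reads_C = n_C)
  })
  out <- dplyr::bind_rows(calls)
  attr(out, "dropped_reads") <- dropped
  out
}

# Per-position majority consensus over equal-length reads; NULL when any
# position falls below the agreement threshold (ties fail: a 50/50 split
# is below 0.8).
position_consensus <- function(stack, agreement) {
  m <- matrix(unlist(strsplit(stack, "")), nrow = length(stack),
              byrow = TRUE)
  cnt <- matrix(vapply(NT_ALPHABET, function(b) colSums(m == b),
                       numeric(ncol(m))), ncol = length(NT_ALPHABET))
  best <- max.col(cnt, ties.method = "first")
  frac <- cnt[cbind(seq_len(nrow(cnt)), best)] / length(stack)
  if (any(frac < agreement)) return(NULL)
  paste(NT_ALPHABET[best], collapse = "")
}

#' Tally gate reads per barcode pair
#'
#' Groups barcode reads by (primary, secondary, sorter) and counts reads
#' per gate. Reads whose 10-bp constant region (between the 20-nt primary
#' and 10-nt secondary barcode) does not match are discarded and counted.
#'
#' @param reads Tibble with `seq`, `sorter`, `gate` (e.g. [sort_reads()]).
#' @param constant Constant-region motif.
#' @return Tibble `primary`, `secondary`, `sorter`, `gate`, `reads`,
#'   sorted canonically; attribute `"dropped_reads"` counts discards.
#' @export
count_gate_reads <- function(reads, constant = HISEQ_CONSTANT) {
  ok <- substr(reads$seq, 21, 30) == constant
  out <- reads[ok, , drop = FALSE] |>
    dplyr::mutate(primary = substr(.data$seq, 1, 20),
                  secondary = substr(.data$seq, 31, 40)) |>
    dplyr::count(.data$primary, .data$secondary, .data$sorter, .data$gate,
                 name = "reads") |>
    dplyr::arrange(.data$primary, .data$secondary, .data$sorter, .data$gate)
  attr(out, "dropped_reads") <- sum(!ok)
  out
}

#' Merge sequencing-error secondary barcodes
#'
#' A secondary barcode with fewer than `max_reads` total reads that
#' differs from another secondary of the same primary (and sorter) by at
#' most `max_dist` nucleotides is treated as a sequencing error of the
#' more abundant barcode and its reads are added to it. The rule is
#' applied iteratively until stable, processing candidates in ascending
#' read count (ties broken lexicographically), so total reads per primary
#' are conserved and no primary is ever lost.
#'
#' @param counts Gate-count tibble from [count_gate_reads()].
#' @param max_reads Merge candidates have strictly fewer reads than this
#'   (default 6: "fewer than six").
#' @param max_dist Maximum Hamming distance (default 2).
#' @return Gate-count tibble with error barcodes absorbed.
#' @export
merge_secondary_barcodes <- function(counts, max_reads = 6, max_dist = 2) {
  merged <- counts |>
    dplyr::group_by(.data$primary, .data$sorter) |>
    dplyr::group_modify(~ merge_group(.x, max_reads, max_dist)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$primary, .data$secondary, .data$sorter, .data$gate)
  merged
}

merge_group <- function(df, max_reads, max_dist) {
  repeat {
    totals <- df |>
      dplyr::group_by(.data$secondary) |>
      dplyr::summarise(total = sum(.data$reads), .groups = "drop") |>
      dplyr::arrange(.data$total, .data$secondary)
    if (nrow(totals) < 2) return(df)
    cand <- totals$secondary[totals$total < max_reads]
    changed <- FALSE
    for (cb in cand) {
      totals_now <- tapply(df$reads, df$secondary, sum)
      if (!cb %in% names(totals_now)) next
      others <- setdiff(names(totals_now), cb)
      if (length(others) == 0) next
      d <- vapply(others, function(o) hamming(cb, o), numeric(1))
      near <- others[d <= max_dist & totals_now[others] > totals_now[[cb]]]
      if (length(near) == 0) next
      target <- near[which.max(totals_now[near])]
      moved <- df[df$secondary == cb, ]
      moved$secondary <- target
      df <- dplyr::bind_rows(df[df$secondary != cb, ], moved) |>
        dplyr::group_by(.data$secondary, .data$gate) |>
        dplyr::summarise(reads = sum(.data$reads), .groups = "drop")
      changed <- TRUE
      break
    }
    if (!changed) return(df)
  }
}

#' Convert gate read counts to cell counts with count controls
#'
#' For each sorter and gate, the mean read count of the count-control
#' barcodes (each sorted at a known fixed number of cells) converts reads
#' to cells: `cells = reads * cells_per_control / mean(control reads)`.
#'
#' @param counts Gate-count tibble (controls included).
#' @param control_barcodes Character vector of control primary barcodes.
#' @param cells_per_control Cells sorted per control barcode per gate.
#' @return Gate-count tibble with a `cells` column; control rows removed.
#' @export
normalize_by_count_controls <- function(counts, control_barcodes,
                                        cells_per_control = 5000) {
  ctrl <- counts |>
    dplyr::filter(.data$primary %in% control_barcodes) |>
    dplyr::group_by(.data$sorter, .data$gate) |>
    dplyr::summarise(ctrl_mean = mean(.data$reads), .groups = "drop")
  data_gates <- counts |>
    dplyr::filter(!.data$primary %in% control_barcodes) |>
    dplyr::distinct(.data$sorter, .data$gate)
  missing <- dplyr::anti_join(data_gates, ctrl, by = c("sorter", "gate"))
  bad <- ctrl$ctrl_mean <= 0
  if (nrow(missing) > 0 || any(bad)) {
    stop("count-control normalization undefined: no control reads for ",
         "sorter/gate ",
         paste(c(paste(missing$sorter, missing$gate, sep = "/"),
                 paste(ctrl$sorter[bad], ctrl$gate[bad], sep = "/")),
               collapse = ", "))
  }
  counts |>
    dplyr::filter(!.data$primary %in% control_barcodes) |>
    dplyr::left_join(ctrl, by = c("sorter", "gate")) |>
    dplyr::mutate(cells = .data$reads * cells_per_control /
                    .data$ctrl_mean) |>
    dplyr::select(-"ctrl_mean")
}
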