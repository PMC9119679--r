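#' One-hot encode protein genotypes
#'
#' Builds the design matrix for fitness modeling: for each position, a
#' binary indicator per amino-acid state observed in the dataset at that
#' position (wildtype state included), so every genotype's row has
#' exactly one active state per position. The stop state `"*"` is a valid
#' state. Genotypes with negative fluorescence are excluded from the
#' response.
#'
#' @param dataset Protein-level tibble (`aa_muts`, `fluorescence`).
#' @param wildtype Wildtype protein sequence.
#' @param full_alphabet Encode all 20 amino acids (plus `"*"`) at every
#'   position instead of only observed states.
#' @return Object of class `onehot_dataset`: design matrix `X`, response
#'   `y`, `genotypes` (mutation-set strings), `col_info` (site, state,
#'   label, is_wt), `wildtype`, and a `split` slot (NULL until
#'   [split_dataset()]).
#' @export
encode_genotypes <- function(dataset, wildtype, full_alphabet = FALSE) {
  keep <- dataset$fluorescence >= 0
  dataset <- dataset[keep, , drop = FALSE]
  wt <- strsplit(wildtype, "")[[1]]
  L <- length(wt)
  parsed <- parse_mutations(dataset$aa_muts)
  bad <- unlist(lapply(parsed, function(p) p$alt[!p$alt %in% AA_ALPHABET]))
  if (length(bad) > 0) stop("unknown amino-acid symbol: ", bad[1])

  if (full_alphabet) {
    states_by_site <- lapply(seq_len(L), function(s) {
      unique(c(wt[s], AA_ALPHABET))
    })
  } else {
    obs <- dplyr::bind_rows(parsed)
    states_by_site <- lapply(seq_len(L), function(s) {
      c(wt[s], sort(unique(obs$alt[obs$site == s])))
    })
  }
  col_info <- tibble::tibble(
    site = rep(seq_len(L), lengths(states_by_site)),
    state = unlist(states_by_site))
  col_info$label <- paste0(col_info$site, ":", col_info$state)
  col_info$is_wt <- col_info$state == wt[col_info$site]

  col_index <- setNames(seq_len(nrow(col_info)), col_info$label)
  wt_cols <- col_index[paste0(seq_len(L), ":", wt)]
  n <- nrow(dataset)
  X <- matrix(0L, nrow = n, ncol = nrow(col_info),
              dimnames = list(NULL, col_info$label))
  base_row <- integer(L)
  base_row[] <- wt_cols
  for (i in seq_len(n)) {
    cols <- base_row
    p <- parsed[[i]]
    if (nrow(p) > 0) {
      cols[p$site] <- col_index[paste0(p$site, ":", p$alt)]
    }
    X[i, cols] <- 1L
  }
  structure(list(X = X, y = dataset$fluorescence,
                 genotypes = dataset$aa_muts,
                 col_info = col_info, wildtype = wildtype,
                 split = NULL),
            class = "onehot_dataset")
}

#' Decode one-hot rows back to mutation sets
#'
#' @param ds An `onehot_dataset`.
#' @param rows Row indices (default all).
#' @return Character vector of mutation-set strings.
#' @export
decode_genotypes <- function(ds, rows = seq_len(nrow(ds$X))) {
  wt <- strsplit(ds$wildtype, "")[[1]]
  non_wt <- which(!ds$col_info$is_wt)
  vapply(rows, function(i) {
    active <- non_wt[ds$X[i, non_wt] == 1]
    if (length(active) == 0) return("")
    s <- ds$col_info$site[active]
    format_mutations(s, wt[s], ds$col_info$state[active])
  }, character(1))
}

#' @export
print.onehot_dataset <- function(x, ...) {
  cat("<onehot_dataset> ", nrow(x$X), " genotypes x ", ncol(x$X),
      " indicators", sep = "")
  if (!is.null(x$split)) {
    cat(" (", paste(names(table(x$split)), table(x$split), sep = ":",
                    collapse = " "), ")", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Random train/validation/test split
#'
#' @param ds An `onehot_dataset`.
#' @param fractions Three fractions summing to 1 (default 0.6/0.2/0.2).
#' @param seed RNG seed.
#' @return The dataset with a `split` factor
#'   (`train`/`validation`/`test`); disjoint and exhaustive.
#' @export
split_dataset <- function(ds, fractions = c(0.6, 0.2, 0.2), seed = 1) {
  stopifnot(length(fractions) == 3,
            abs(sum(fractions) - 1) < 1e-8)
  set.seed(seed)
  n <- nrow(ds$X)
  n1 <- round(fractions[1] * n)
  n2 <- round(fractions[2] * n)
  labels <- rep(c("train", "validation", "test"),
                c(n1, n2, n - n1 - n2))
  ds$split <- factor(sample(labels),
                     levels = c("train", "validation", "test",
                                "excluded"))
  ds
}

#' Filter splits for fair training and scoring
#'
#' Iteratively removes training genotypes containing mutations present in
#' fewer than `min_genotypes` distinct training genotypes, repeating
#' until every training-set mutation reaches the threshold (removing a
#' genotype lowers other mutations' counts, so a fixed point is
#' required). The validation set is then pruned of genotypes containing
#' mutations absent from the final training set.
#'
#' @param ds A split `onehot_dataset`.
#' @param min_genotypes Occurrence threshold (default 10).
#' @return The dataset with pruned genotypes relabeled `"excluded"`.
#' @export
filter_for_training <- function(ds, min_genotypes = 10) {
  if (is.null(ds$split)) stop("dataset must be split first")
  non_wt <- which(!ds$col_info$is_wt)
  Xm <- ds$X[, non_wt, drop = FALSE]
  train <- ds$split == "train"
  repeat {
    counts <- colSums(Xm[train, , drop = FALSE])
    rare <- counts > 0 & counts < min_genotypes
    if (!any(rare)) break
    hit <- rowSums(Xm[, rare, drop = FALSE]) > 0
    drop <- train & hit
    if (!any(drop)) break
    train[drop] <- FALSE
  }
  if (!any(train)) stop("training set empty after filtering")
  train_muts <- colSums(Xm[train, , drop = FALSE]) > 0
  val <- ds$split == "validation"
  val_bad <- val & rowSums(Xm[, !train_muts, drop = FALSE]) > 0
  split <- as.character(ds$split)
  split[ds$split == "train" & !train] <- "excluded"
  split[val_bad] <- "excluded"
  ds$split <- factor(split, levels = levels(ds$split))
  ds
}
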