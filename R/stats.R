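#' Single-mutant effect table
#'
#' Effects are defined only for mutations observed in isolation:
#' `effect = F_single - F_wt`, with the wildtype mean taken from the
#' protein-level wildtype record and the wildtype spread from the
#' synonymous wildtype population (attributes set by
#' [collapse_synonymous()], or supplied explicitly).
#'
#' @param dataset Protein-level tibble (`aa_muts`, `n_muts`,
#'   `fluorescence`, optionally `n_nt_genotypes`).
#' @param wt_sd Wildtype standard deviation; defaults to the dataset's
#'   `wt_sd` attribute.
#' @return Tibble `mutation`, `site`, `state`, `f_single`, `effect`,
#'   `n_obs`, with attributes `f_wt` and `wt_sd`.
#' @export
single_effects <- function(dataset, wt_sd = NULL) {
  wt_rows <- dataset$aa_muts == ""
  if (!any(wt_rows)) stop("no wildtype genotypes in dataset")
  f_wt <- attr(dataset, "wt_mean") %||%
    mean(dataset$fluorescence[wt_rows])
  singles <- dataset[dataset$n_muts == 1, , drop = FALSE]
  parsed <- parse_mutations(singles$aa_muts)
  out <- tibble::tibble(
    mutation = singles$aa_muts,
    site = vapply(parsed, function(p) p$site[1], integer(1)),
    state = vapply(parsed, function(p) p$alt[1], character(1)),
    f_single = singles$fluorescence,
    effect = singles$fluorescence - f_wt,
    n_obs = if ("n_nt_genotypes" %in% names(singles)) {
      singles$n_nt_genotypes
    } else rep(1L, nrow(singles)))
  attr(out, "f_wt") <- f_wt
  attr(out, "wt_sd") <- wt_sd %||% attr(dataset, "wt_sd")
  out
}

#' Additive-expectation epistasis
#'
#' For each genotype `m`, the expected fluorescence under independent
#' mutation effects is `F_wt + sum_i (F_i - F_wt) x_i` over its
#' mutations, capped to the observed range of the dataset (expected
#' values cannot exceed the maximum observed measurement nor fall below
#' the minimum); epistasis is `F_m - expected`. Genotypes carrying a
#' mutation never observed in isolation are flagged non-computable.
#'
#' @param dataset Protein-level tibble.
#' @param singles A [single_effects()] table.
#' @return Tibble `aa_muts`, `n_muts`, `observed`, `expected` (capped),
#'   `expected_raw`, `epistasis`, `computable`.
#' @export
epistasis <- function(dataset, singles = single_effects(dataset)) {
  f_wt <- attr(singles, "f_wt")
  f_min <- min(dataset$fluorescence)
  f_max <- max(dataset$fluorescence)
  eff <- setNames(singles$effect, singles$mutation)
  recs <- dataset[dataset$n_muts >= 1, , drop = FALSE]
  parsed <- strsplit(recs$aa_muts, ":", fixed = TRUE)
  expected_raw <- vapply(parsed, function(m) {
    e <- eff[m]
    if (anyNA(e)) NA_real_ else f_wt + sum(e)
  }, numeric(1))
  computable <- !is.na(expected_raw)
  expected <- pmin(pmax(expected_raw, f_min), f_max)
  tibble::tibble(
    aa_muts = recs$aa_muts,
    n_muts = recs$n_muts,
    observed = recs$fluorescence,
    expected = expected,
    expected_raw = expected_raw,
    epistasis = recs$fluorescence - expected,
    computable = computable)
}

#' Fraction of genotypes behaving additively, by mutational distance
#'
#' At each mutation count, the number of computable genotypes observed
#' functional divided by the number expected to be functional under the
#' additive (no-epistasis) expectation. Without epistasis the curve is a
#' constant 100%.
#'
#' @param records An [epistasis()] tibble.
#' @param functional_threshold Log10 fluorescence above which a genotype
#'   counts as functional (default 2.0, the upper boundary of the darkest
#'   gate).
#' @return Tibble `n_muts`, `observed_functional`, `expected_functional`,
#'   `fraction`; distances with a zero denominator are omitted.
#' @export
additive_fraction_curve <- function(records, functional_threshold = 2.0) {
  records |>
    dplyr::filter(.data$computable) |>
    dplyr::group_by(.data$n_muts) |>
    dplyr::summarise(
      observed_functional = sum(.data$observed >= functional_threshold),
      expected_functional = sum(.data$expected >= functional_threshold),
      .groups = "drop") |>
    dplyr::filter(.data$expected_functional > 0) |>
    dplyr::mutate(fraction = .data$observed_functional /
                    .data$expected_functional)
}

#' Mutational LD50 from a logistic fit
#'
#' Fits `f(x) = L / (1 + exp(-k (x - x0)))` to the per-distance fraction
#' of genotypes that are non-functional (`mode = "loss_of_function"`:
#' below `functional_threshold`, i.e. in the darkest gate) or that have
#' left the wildtype band (`mode = "loss_of_wt_level"`: more than
#' `wt_sd_mult` wildtype standard deviations below the wildtype mean),
#' and solves `f(x) = 0.5`.
#'
#' @param dataset Protein-level tibble.
#' @param mode `"loss_of_function"` or `"loss_of_wt_level"`.
#' @param functional_threshold Darkest-gate boundary (default 2.0).
#' @param wt_mean,wt_sd Wildtype reference statistics; default to the
#'   dataset attributes.
#' @param wt_sd_mult Width of the wildtype band in SDs (default 2).
#' @param min_genotypes Minimum genotypes per distance bin (default 15).
#' @return Object of class `logistic_fit`: parameters `L`, `k`, `x0`,
#'   the solved `ld50` (`NA` when `f(x) = 0.5` has no solution), and the
#'   fitted per-distance fractions.
#' @export
fit_ld50 <- function(dataset,
                     mode = c("loss_of_function", "loss_of_wt_level"),
                     functional_threshold = 2.0,
                     wt_mean = NULL, wt_sd = NULL, wt_sd_mult = 2,
                     min_genotypes = 15) {
  mode <- match.arg(mode)
  if (mode == "loss_of_wt_level") {
    wt_mean <- wt_mean %||% attr(dataset, "wt_mean")
    wt_sd <- wt_sd %||% attr(dataset, "wt_sd")
    if (is.null(wt_mean) || is.null(wt_sd) || is.na(wt_sd)) {
      stop("loss_of_wt_level mode needs wildtype mean and sd")
    }
    cut <- wt_mean - wt_sd_mult * wt_sd
  } else {
    cut <- functional_threshold
  }
  fractions <- dataset |>
    dplyr::group_by(.data$n_muts) |>
    dplyr::summarise(n = dplyr::n(),
                     fraction = mean(.data$fluorescence < cut),
                     .groups = "drop") |>
    dplyr::filter(.data$n >= min_genotypes)
  if (nrow(fractions) < 4) {
    stop("need at least 4 distance bins with >= ", min_genotypes,
         " genotypes")
  }
  fit_logistic(fractions$n_muts, fractions$fraction, mode = mode,
               data = fractions)
}

#' Fit a logistic curve and solve for its half-point
#'
#' @param x,y Numeric vectors (e.g. mutational distance and fraction).
#' @param mode Optional label stored on the fit.
#' @param data Optional tibble stored on the fit.
#' @return A `logistic_fit` object.
#' @export
fit_logistic <- function(x, y, mode = NULL, data = NULL) {
  obj <- function(par) {
    sum((y - par[1] / (1 + exp(-par[2] * (x - par[3]))))^2)
  }
  x0_init <- if (any(y >= 0.5)) x[which(y >= 0.5)[1]] else max(x)
  fit <- optim(c(max(min(max(y), 1.05), 0.1), 1, x0_init), obj,
               method = "L-BFGS-B",
               lower = c(1e-3, 1e-3, 0),
               upper = c(1.05, 10, max(x) + 1))
  L <- fit$par[1]; k <- fit$par[2]; x0 <- fit$par[3]
  ld50 <- if (2 * L - 1 > 0) x0 - log(2 * L - 1) / k else NA_real_
  structure(list(L = L, k = k, x0 = x0, ld50 = ld50,
                 converged = fit$convergence == 0,
                 mode = mode, data = data),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("<logistic_fit", if (!is.null(x$mode)) paste0(" (", x$mode, ")"),
      "> L=", signif(x$L, 3), " k=", signif(x$k, 3),
      " x0=", signif(x$x0, 3), " ld50=", signif(x$ld50, 3), "\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.logistic_fit <- function(x, ...) {
  tibble::tibble(term = c("L", "k", "x0"),
                 estimate = c(x$L, x$k, x$x0))
}

#' @exportS3Method generics::glance
glance.logistic_fit <- function(x, ...) {
  tibble::tibble(ld50 = x$ld50, L = x$L, k = x$k, x0 = x$x0,
                 converged = x$converged,
                 mode = x$mode %||% NA_character_)
}

#' Median fluorescence profile away from an origin genotype
#'
#' Median fluorescence as a function of amino-acid Hamming distance from
#' the origin (the wildtype, or e.g. a single-mutant background),
#' reported only for distances with at least `min_genotypes` genotypes.
#'
#' @param dataset Protein-level tibble.
#' @param origin Mutation-set string of the origin genotype (default
#'   wildtype, `""`); must be present in the dataset.
#' @param min_genotypes Minimum genotypes per distance (default 15).
#' @return Tibble `distance`, `n`, `median_f`.
#' @export
peak_profile <- function(dataset, origin = "", min_genotypes = 15) {
  if (!origin %in% dataset$aa_muts) stop("origin genotype not in dataset")
  d <- mutation_set_distance(dataset$aa_muts, origin)
  tibble::tibble(distance = d, f = dataset$fluorescence) |>
    dplyr::group_by(.data$distance) |>
    dplyr::summarise(n = dplyr::n(), median_f = median(.data$f),
                     .groups = "drop") |>
    dplyr::filter(.data$n >= min_genotypes)
}

#' Cross-ortholog transfer of single-mutant effects
#'
#' Among mutations measured in isolation in two landscapes (positions
#' aligned by `site_map`, identical target states), the fraction that is
#' neutral in A (within `neutral_sd_mult` wildtype SDs) and deleterious
#' in B (reducing fluorescence by more than `deleterious_sd_mult`
#' wildtype SDs).
#'
#' @param singles_a,singles_b [single_effects()] tables.
#' @param site_map Optional two-column data frame `site_a`, `site_b`
#'   aligning positions; identity by default.
#' @param neutral_sd_mult,deleterious_sd_mult Thresholds in wildtype SDs
#'   (defaults 2 and 5).
#' @return One-row tibble `fraction`, `n_events`, `n_shared`.
#' @export
cross_ortholog_transfer <- function(singles_a, singles_b, site_map = NULL,
                                    neutral_sd_mult = 2,
                                    deleterious_sd_mult = 5) {
  sd_a <- attr(singles_a, "wt_sd")
  sd_b <- attr(singles_b, "wt_sd")
  if (is.null(sd_a) || is.null(sd_b) || is.na(sd_a) || is.na(sd_b)) {
    stop("both single-effect tables need a wildtype sd")
  }
  b <- singles_b
  if (!is.null(site_map)) {
    b <- b |>
      dplyr::inner_join(site_map, by = c(site = "site_b")) |>
      dplyr::mutate(site = .data$site_a) |>
      dplyr::select(-"site_a")
  }
  shared <- dplyr::inner_join(
    singles_a |> dplyr::select("site", "state", effect_a = "effect"),
    b |> dplyr::select("site", "state", effect_b = "effect"),
    by = c("site", "state"))
  if (nrow(shared) == 0) {
    return(tibble::tibble(fraction = NA_real_, n_events = 0L,
                          n_shared = 0L))
  }
  events <- abs(shared$effect_a) <= neutral_sd_mult * sd_a &
    shared$effect_b < -deleterious_sd_mult * sd_b
  tibble::tibble(fraction = mean(events), n_events = sum(events),
                 n_shared = nrow(shared))
}

#' Per-site-pair epistasis from double mutants
#'
#' For each pair of sites with at least one computable double mutant
#' (genotypes with exactly those two mutations), the pair's epistasis is
#' the value of largest magnitude among its double mutants.
#'
#' @param records An [epistasis()] tibble.
#' @return Tibble `site1`, `site2`, `epistasis`, `n_doubles`.
#' @export
pair_epistasis <- function(records) {
  doubles <- records |>
    dplyr::filter(.data$n_muts == 2, .data$computable)
  if (nrow(doubles) == 0) {
    return(tibble::tibble(site1 = integer(), site2 = integer(),
                          epistasis = numeric(), n_doubles = integer()))
  }
  parsed <- parse_mutations(doubles$aa_muts)
  doubles$site1 <- vapply(parsed, function(p) min(p$site), integer(1))
  doubles$site2 <- vapply(parsed, function(p) max(p$site), integer(1))
  doubles |>
    dplyr::group_by(.data$site1, .data$site2) |>
    dplyr::summarise(
      epistasis = .data$epistasis[which.max(abs(.data$epistasis))],
      n_doubles = dplyr::n(), .groups = "drop")
}

#' Sharing of epistatic site pairs between two landscapes
#'
#' Among site pairs with measurable double-mutant epistasis in both
#' landscapes, those with `|epistasis| > cutoff` in either are the
#' candidate epistatic pairs; the reported fraction is the share of them
#' epistatic in both.
#'
#' @param epi_a,epi_b [epistasis()] tibbles for the two landscapes.
#' @param site_map Optional `site_a`/`site_b` alignment (identity by
#'   default).
#' @param cutoff Epistasis magnitude cutoff (default 0.3, a two-fold
#'   fluorescence change; 1.0 would be ten-fold).
#' @return One-row tibble `fraction`, `n_either`, `n_both`,
#'   `n_measured_both`.
#' @export
shared_epistatic_pairs <- function(epi_a, epi_b, site_map = NULL,
                                   cutoff = 0.3) {
  pa <- pair_epistasis(epi_a)
  pb <- pair_epistasis(epi_b)
  if (!is.null(site_map)) {
    m <- setNames(site_map$site_a, site_map$site_b)
    pb <- pb |>
      dplyr::mutate(site1 = m[as.character(.data$site1)],
                    site2 = m[as.character(.data$site2)]) |>
      dplyr::filter(!is.na(.data$site1), !is.na(.data$site2)) |>
      dplyr::mutate(s1 = pmin(.data$site1, .data$site2),
                    s2 = pmax(.data$site1, .data$site2),
                    site1 = .data$s1, site2 = .data$s2) |>
      dplyr::select(-"s1", -"s2")
  }
  shared <- dplyr::inner_join(
    pa |> dplyr::select("site1", "site2", e_a = "epistasis"),
    pb |> dplyr::select("site1", "site2", e_b = "epistasis"),
    by = c("site1", "site2"))
  if (nrow(shared) == 0) {
    return(tibble::tibble(fraction = NA_real_, n_either = 0L, n_both = 0L,
                          n_measured_both = 0L))
  }
  either <- abs(shared$e_a) > cutoff | abs(shared$e_b) > cutoff
  both <- abs(shared$e_a) > cutoff & abs(shared$e_b) > cutoff
  tibble::tibble(
    fraction = if (sum(either) > 0) sum(both) / sum(either) else NA_real_,
    n_either = sum(either), n_both = sum(both),
    n_measured_both = nrow(shared))
}

#' Summarize single-mutant effects against residue annotations
#'
#' Categorical annotations (e.g. buried vs exposed residues) yield
#' per-category effect distributions compared with a rank-sum test;
#' numeric per-mutation annotations (e.g. externally computed stability
#' changes) yield a Spearman rank correlation.
#'
#' @param singles A [single_effects()] table.
#' @param annotations Tibble with `site` and either `category` or a
#'   numeric `score` column (or both).
#' @return List with `by_category` (tibble of medians and n), `rank_test`
#'   (htest or NULL), `rank_correlation` (tibble or NULL), `unmatched`
#'   (number of effect rows without annotation).
#' @export
annotate_effects <- function(singles, annotations) {
  joined <- dplyr::left_join(singles, annotations, by = "site")
  unmatched <- sum(!singles$site %in% annotations$site)
  by_category <- NULL; rank_test <- NULL; rank_cor <- NULL
  if ("category" %in% names(joined)) {
    with_cat <- joined[!is.na(joined$category), ]
    by_category <- with_cat |>
      dplyr::group_by(.data$category) |>
      dplyr::summarise(n = dplyr::n(),
                       median_effect = median(.data$effect),
                       .groups = "drop")
    cats <- unique(with_cat$category)
    if (length(cats) == 2) {
      rank_test <- stats::wilcox.test(
        effect ~ category, data = with_cat, exact = FALSE)
    }
  }
  if ("score" %in% names(joined)) {
    ok <- !is.na(joined$score)
    if (sum(ok) >= 3) {
      ct <- stats::cor.test(joined$score[ok], joined$effect[ok],
                            method = "spearman", exact = FALSE)
      rank_cor <- tibble::tibble(rho = unname(ct$estimate),
                                 p_value = ct$p.value, n = sum(ok))
    }
  }
  list(by_category = by_category, rank_test = rank_test,
       rank_correlation = rank_cor, unmatched = unmatched)
}

#' Spatial proximity of epistatically interacting residue pairs
#'
#' Compares the spatial distance distributions of epistatic versus
#' non-epistatic site pairs with a rank-sum test. Distances come from an
#' external table (e.g. residue-residue distances from a structure).
#'
#' @param pairs A [pair_epistasis()] tibble.
#' @param distance_table Tibble `site1`, `site2`, `distance` (unordered
#'   pairs; both orders are accepted).
#' @param cutoff Epistasis magnitude cutoff (default 0.3).
#' @return List with `summary` (medians and n per group), `rank_test`
#'   (htest or NULL), `n_missing` (pairs without a distance).
#' @export
epistatic_pair_proximity <- function(pairs, distance_table, cutoff = 0.3) {
  dt <- dplyr::bind_rows(
    distance_table,
    distance_table |> dplyr::rename(site1 = "site2", site2 = "site1")) |>
    dplyr::distinct(.data$site1, .data$site2, .keep_all = TRUE)
  joined <- dplyr::left_join(pairs, dt, by = c("site1", "site2"))
  n_missing <- sum(is.na(joined$distance))
  joined <- joined[!is.na(joined$distance), ]
  joined$epistatic <- abs(joined$epistasis) > cutoff
  summary <- joined |>
    dplyr::group_by(.data$epistatic) |>
    dplyr::summarise(n = dplyr::n(),
                     median_distance = median(.data$distance),
                     .groups = "drop")
  rank_test <- NULL
  if (length(unique(joined$epistatic)) == 2 &&
      length(unique(joined$distance)) > 1) {
    rank_test <- stats::wilcox.test(distance ~ epistatic, data = joined,
                                    exact = FALSE)
  }
  list(summary = summary, rank_test = rank_test, n_missing = n_missing)
}
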