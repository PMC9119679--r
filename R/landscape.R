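#' Configuration for a ground-truth fluorescence landscape
#'
#' The generator draws per-site additive mutation effects from a
#' neutral-or-deleterious mixture and site-pair epistatic terms, then maps
#' a genotype's summed "fitness potential" to log10 fluorescence through a
#' sigmoid threshold. This reproduces the empirical shape of GFP
#' deep-mutational-scan data: a bimodal fluorescence distribution (a dark
#' mode plus a near-wildtype mode) with an abrupt functional threshold.
#'
#' @param p_neutral Probability a mutant state is (near-)neutral; neutral
#'   effects are Normal(0, `neutral_sd`).
#' @param neutral_sd SD of neutral effects (log10 units).
#' @param deleterious_scale Mean of the exponential deleterious-effect
#'   magnitude (log10 units; effects are negative).
#' @param epistasis_density Fraction of residue pairs carrying an epistatic
#'   term.
#' @param epistasis_scale Mean magnitude of epistatic terms (log10 units).
#' @param epistasis_negative_bias Probability an epistatic term is negative.
#' @param f_dark Floor log10 fluorescence of non-functional genotypes.
#' @param f_wt Wildtype log10 fluorescence.
#' @param steepness,midpoint Sigmoid transform parameters: fluorescence is
#'   `f_dark + (f_wt - f_dark) * plogis(steepness * (potential - midpoint)) /
#'   plogis(-steepness * midpoint)`, normalized so the wildtype
#'   (potential 0) maps exactly to `f_wt`. Large steepness gives the
#'   abrupt threshold of fragile peaks; small steepness a near-linear
#'   decline typical of robust peaks whose fluorescence is additive.
#' @param cell_noise_sd SD of per-cell log10 fluorescence around the
#'   genotype's true value (default 0.2, spreading a genotype's cells
#'   over two to three 0.4-wide gates so the gate fit is identifiable).
#' @return A list of class `landscape_config`.
#' @export
landscape_config <- function(p_neutral = 0.40,
                             neutral_sd = 0.02,
                             deleterious_scale = 0.65,
                             epistasis_density = 0.01,
                             epistasis_scale = 0.35,
                             epistasis_negative_bias = 0.9,
                             f_dark = 1.8,
                             f_wt = 4.2,
                             steepness = 6,
                             midpoint = -2,
                             cell_noise_sd = 0.2) {
  cfg <- list(p_neutral = p_neutral, neutral_sd = neutral_sd,
              deleterious_scale = deleterious_scale,
              epistasis_density = epistasis_density,
              epistasis_scale = epistasis_scale,
              epistasis_negative_bias = epistasis_negative_bias,
              f_dark = f_dark, f_wt = f_wt,
              steepness = steepness, midpoint = midpoint,
              cell_noise_sd = cell_noise_sd)
  stopifnot(p_neutral >= 0, p_neutral <= 1,
            epistasis_density >= 0, epistasis_density <= 1,
            epistasis_negative_bias >= 0, epistasis_negative_bias <= 1)
  if (f_dark >= f_wt || steepness <= 0) {
    stop("transform must be monotone non-decreasing: require f_dark < f_wt ",
         "and steepness > 0")
  }
  structure(cfg, class = "landscape_config")
}

#' Landscape presets emulating flat and sharp fitness peaks
#'
#' `"flat"` draws mostly independent, moderately deleterious effects with
#' sparse epistasis (a mutationally robust peak); `"sharp"` draws stronger
#' effects with dense negative epistasis (a fragile peak that loses
#' function after few mutations).
#'
#' @param name `"flat"` or `"sharp"`.
#' @return A `landscape_config`.
#' @export
landscape_preset <- function(name = c("flat", "sharp")) {
  name <- match.arg(name)
  switch(name,
    # gentle, near-linear transform: mutation costs stay visible in
    # fluorescence, reproducing the additive behavior of robust peaks
    flat = landscape_config(steepness = 2, midpoint = -1.2),
    sharp = landscape_config(p_neutral = 0.35, deleterious_scale = 0.9,
                             epistasis_density = 0.25,
                             epistasis_scale = 0.5,
                             epistasis_negative_bias = 0.95))
}

#' Build a ground-truth genotype-to-fluorescence landscape
#'
#' Generates a random wildtype protein and coding sequence, designates
#' three consecutive chromophore residues (any substitution there
#' abolishes fluorescence), draws additive mutation effects and site-pair
#' epistatic terms, and fixes the sigmoid transform.
#'
#' @param length Number of residues (>= 30).
#' @param config A [landscape_config()].
#' @param seed Integer RNG seed; the landscape is a pure function of
#'   `(length, config, seed)`.
#' @return An object of class `landscape`: wildtype protein and CDS,
#'   chromophore sites, an additive-effect matrix (site x state), an
#'   epistatic term table (`site1 < site2`, `effect`), and the transform
#'   parameters.
#' @export
make_landscape <- function(length = 235, config = landscape_config(),
                           seed = 1) {
  stopifnot(length >= 30)
  if (!inherits(config, "landscape_config")) {
    config <- do.call(landscape_config, config)
  }
  set.seed(seed)

  sense_codons <- names(GENETIC_CODE_1)[GENETIC_CODE_1 != "*"]
  # avoid ATG-start constraints etc.; any sense codon works for simulation
  codons <- sample(sense_codons, length, replace = TRUE)
  wildtype_cds <- paste(c(codons, "TAA"), collapse = "")
  wildtype <- translate_cds(paste(codons, collapse = ""))

  chromophore_sites <- floor(length * 0.27) + 0:2

  aa_states <- AA_ALPHABET
  wt_chars <- strsplit(wildtype, "")[[1]]
  eff <- matrix(0, nrow = length, ncol = base::length(aa_states),
                dimnames = list(NULL, aa_states))
  for (s in seq_len(length)) {
    alt <- setdiff(aa_states, c(wt_chars[s], "*"))
    is_neutral <- runif(base::length(alt)) < config$p_neutral
    e <- ifelse(is_neutral,
                rnorm(base::length(alt), 0, config$neutral_sd),
                -rexp(base::length(alt), 1 / config$deleterious_scale))
    eff[s, alt] <- e
  }
  # wildtype states stay 0; "*" handled as premature stop (forced dark)

  n_pairs <- round(config$epistasis_density * choose(length, 2))
  if (n_pairs > 0) {
    pair_idx <- sample.int(choose(length, 2), n_pairs)
    all_pairs <- which(upper.tri(matrix(0, length, length)), arr.ind = TRUE)
    chosen <- all_pairs[pair_idx, , drop = FALSE]
    sign <- ifelse(runif(n_pairs) < config$epistasis_negative_bias, -1, 1)
    epi <- tibble::tibble(
      site1 = as.integer(chosen[, 1]),
      site2 = as.integer(chosen[, 2]),
      effect = sign * rexp(n_pairs, 1 / config$epistasis_scale))
  } else {
    epi <- tibble::tibble(site1 = integer(), site2 = integer(),
                          effect = numeric())
  }
  epi_mat <- matrix(0, length, length)
  if (nrow(epi) > 0) {
    epi_mat[cbind(epi$site1, epi$site2)] <- epi$effect
    epi_mat[cbind(epi$site2, epi$site1)] <- epi$effect
  }

  structure(list(
    wildtype = wildtype,
    wildtype_cds = wildtype_cds,
    length = length,
    chromophore_sites = chromophore_sites,
    additive_effects = eff,
    epistatic_terms = epi,
    epistasis_matrix = epi_mat,
    config = config,
    seed = seed), class = "landscape")
}

#' @export
print.landscape <- function(x, ...) {
  cat("<landscape> ", x$length, " aa, chromophore at ",
      paste(x$chromophore_sites, collapse = "/"),
      ", ", nrow(x$epistatic_terms), " epistatic site pairs\n",
      "transform: F_dark=", x$config$f_dark, " F_wt=", x$config$f_wt,
      " steepness=", x$config$steepness, " midpoint=", x$config$midpoint,
      "\n", sep = "")
  invisible(x)
}

#' Fitness potential of protein genotypes
#'
#' The summed additive effects of a genotype's mutations plus the
#' epistatic terms of its mutated site pairs; the wildtype has potential 0.
#'
#' @param landscape A [make_landscape()] object.
#' @param genotypes Character vector of mutation-set strings (or full
#'   protein sequences of the wildtype length).
#' @return Numeric vector of potentials (log10 fluorescence units).
#' @export
fitness_potential <- function(landscape, genotypes) {
  parsed <- .parse_genotypes(landscape, genotypes)
  vapply(parsed, function(p) {
    if (nrow(p) == 0) return(0)
    add <- sum(landscape$additive_effects[cbind(p$site,
                                                match(p$alt, AA_ALPHABET))])
    ep <- 0
    if (nrow(p) > 1) {
      cmb <- utils::combn(p$site, 2)
      ep <- sum(landscape$epistasis_matrix[cbind(cmb[1, ], cmb[2, ])])
    }
    add + ep
  }, numeric(1))
}

.parse_genotypes <- function(landscape, genotypes) {
  is_protein <- nchar(genotypes) == landscape$length &
    !grepl("[0-9]", genotypes)
  out <- vector("list", length(genotypes))
  if (any(is_protein)) {
    out[is_protein] <- parse_mutations(
      protein_mutations(landscape$wildtype, genotypes[is_protein]))
  }
  if (any(!is_protein)) {
    out[!is_protein] <- parse_mutations(genotypes[!is_protein])
  }
  wt <- strsplit(landscape$wildtype, "")[[1]]
  for (p in out) {
    if (nrow(p) > 0) {
      bad <- !(p$alt %in% AA_ALPHABET)
      if (any(bad)) {
        stop("unknown amino-acid symbol '", p$alt[bad][1],
             "' at position ", p$site[bad][1])
      }
      if (any(p$site < 1 | p$site > landscape$length)) {
        stop("mutation site out of range")
      }
    }
  }
  out
}

#' True log10 fluorescence of protein genotypes
#'
#' Maps genotypes through the landscape's normalized sigmoid (see
#' [landscape_config()]); the wildtype maps exactly to `f_wt`. Genotypes
#' mutating a chromophore site, or carrying a premature stop, are forced
#' to `f_dark` regardless of other mutations.
#'
#' @inheritParams fitness_potential
#' @return Numeric vector of log10 fluorescence values.
#' @export
true_fluorescence <- function(landscape, genotypes) {
  cfg <- landscape$config
  parsed <- .parse_genotypes(landscape, genotypes)
  pot <- fitness_potential(landscape, genotypes)
  dark <- vapply(parsed, function(p) {
    nrow(p) > 0 && (any(p$site %in% landscape$chromophore_sites) ||
                      any(p$alt == "*"))
  }, logical(1))
  f <- cfg$f_dark + (cfg$f_wt - cfg$f_dark) *
    plogis(cfg$steepness * (pot - cfg$midpoint)) /
    plogis(-cfg$steepness * cfg$midpoint)
  f[dark] <- cfg$f_dark
  f
}

#' Sample random protein genotypes from a landscape
#'
#' Draws genotypes with a Poisson-distributed number of amino-acid
#' substitutions at uniformly chosen sites and states, together with their
#' true fluorescence. This is the protein-level shortcut used to study the
#' landscape itself without simulating the sequencing experiment.
#'
#' @param landscape A landscape.
#' @param n Number of genotypes.
#' @param mean_muts Mean substitutions per genotype (Poisson; default 4,
#'   the scale observed in error-prone PCR mutant libraries).
#' @param include_stops Allow `"*"` as a target state (default FALSE).
#' @param states_per_site Restrict each site to this many reachable
#'   alternative states (drawn once per call), emulating the limited
#'   amino-acid accessibility of single-nucleotide mutagenesis; `NULL`
#'   allows all states.
#' @param seed RNG seed.
#' @return Tibble with `aa_muts`, `n_muts`, `true_f`.
#' @export
sample_genotypes <- function(landscape, n, mean_muts = 4,
                             include_stops = FALSE,
                             states_per_site = NULL, seed = 1) {
  set.seed(seed)
  wt <- strsplit(landscape$wildtype, "")[[1]]
  states <- if (include_stops) AA_ALPHABET else setdiff(AA_ALPHABET, "*")
  allowed <- lapply(seq_len(landscape$length), function(s) {
    alt <- setdiff(states, wt[s])
    if (!is.null(states_per_site) && states_per_site < length(alt)) {
      alt <- sample(alt, states_per_site)
    }
    alt
  })
  k <- rpois(n, mean_muts)
  muts <- vapply(k, function(ki) {
    if (ki == 0) return("")
    ki <- min(ki, landscape$length)
    sites <- sample.int(landscape$length, ki)
    alt <- vapply(sites, function(s) {
      a <- allowed[[s]]
      if (length(a) == 1) a else sample(a, 1)
    }, character(1))
    format_mutations(sites, wt[sites], alt)
  }, character(1))
  tibble::tibble(
    aa_muts = muts,
    n_muts = lengths(regmatches(muts, gregexpr(":", muts))) +
      as.integer(muts != ""),
    true_f = true_fluorescence(landscape, muts))
}
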