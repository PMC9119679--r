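#' Build the mutation pool for the genetic algorithm
#'
#' Candidate moves are mutations seen in at least `min_genotypes`
#' distinct training genotypes, whose impact — the median difference in
#' fluorescence over at least `min_pairs` background pairs (genotype
#' pairs identical except for the focal mutation) — is at least
#' `min_impact` log10 units. Wildtype states at every pooled site are
#' included as reversion moves so the algorithm can revert evolutionary
#' dead-ends. Sampling weights put `nonnatural_ratio` of the probability
#' mass on moves not observed in the natural-sequence panel, steering
#' designs away from known natural genotypes.
#'
#' @param dataset Protein-level tibble (`aa_muts`, `fluorescence`).
#' @param train_genotypes Mutation-set strings of the model's (filtered)
#'   training genotypes.
#' @param wildtype Wildtype protein sequence.
#' @param natural_panel Tibble `site`, `state` of amino-acid states found
#'   in natural sequences (e.g. from [panel_from_alignment()] or
#'   [synthetic_natural_panel()]); `NULL` marks every move non-natural.
#' @param min_genotypes,min_pairs,min_impact Pool thresholds (defaults
#'   10, 5, -0.1).
#' @param nonnatural_ratio Sampling mass on non-natural moves (default
#'   0.6).
#' @return Tibble of class `mutation_pool`: `site`, `state`, `type`
#'   (`mutant`/`reversion`), `n_genotypes`, `n_pairs`, `impact`,
#'   `natural`, `weight`.
#' @export
build_pool <- function(dataset, train_genotypes, wildtype,
                       natural_panel = NULL, min_genotypes = 10,
                       min_pairs = 5, min_impact = -0.1,
                       nonnatural_ratio = 0.6) {
  wt <- strsplit(wildtype, "")[[1]]
  train_parsed <- parse_mutations(train_genotypes)
  occ <- table(unlist(lapply(train_parsed, function(p) {
    if (nrow(p) == 0) character() else paste0(p$ref, p$site, p$alt)
  })))
  candidates <- names(occ)[occ >= min_genotypes]

  mut_sets <- strsplit(dataset$aa_muts, ":", fixed = TRUE)

  pool_rows <- lapply(candidates, function(m) {
    has <- which(vapply(mut_sets, function(s) m %in% s, logical(1)))
    partners <- vapply(mut_sets[has], function(s) {
      paste(setdiff(s, m), collapse = ":")
    }, character(1))
    idx <- match(partners, dataset$aa_muts)
    found <- !is.na(idx)
    n_pairs <- sum(found)
    if (n_pairs < min_pairs) return(NULL)
    impact <- median(dataset$fluorescence[has[found]] -
                       dataset$fluorescence[idx[found]])
    if (impact < min_impact) return(NULL)
    p <- parse_mutations(m)[[1]]
    tibble::tibble(site = p$site, state = p$alt, type = "mutant",
                   n_genotypes = as.integer(occ[[m]]),
                   n_pairs = n_pairs, impact = impact)
  })
  pool <- dplyr::bind_rows(pool_rows)
  if (nrow(pool) == 0) stop("empty mutation pool")

  reversions <- tibble::tibble(
    site = sort(unique(pool$site)),
    state = wt[sort(unique(pool$site))],
    type = "reversion",
    n_genotypes = NA_integer_, n_pairs = NA_integer_,
    impact = NA_real_)
  pool <- dplyr::bind_rows(pool, reversions)

  if (is.null(natural_panel)) {
    pool$natural <- pool$type == "reversion"
  } else {
    key <- paste(natural_panel$site, natural_panel$state)
    pool$natural <- pool$type == "reversion" |
      paste(pool$site, pool$state) %in% key
  }
  n_nat <- sum(pool$natural); n_non <- sum(!pool$natural)
  pool$weight <- ifelse(pool$natural,
                        if (n_nat > 0) (1 - nonnatural_ratio) / n_nat else 0,
                        if (n_non > 0) nonnatural_ratio / n_non else 0)
  pool$weight <- pool$weight / sum(pool$weight)
  class(pool) <- c("mutation_pool", class(pool))
  pool
}

#' Natural-state panel from an alignment
#'
#' @param sequences Character vector of aligned sequences (same length as
#'   the wildtype; `-` gaps ignored).
#' @return Tibble `site`, `state` of states observed in the panel.
#' @export
panel_from_alignment <- function(sequences) {
  chars <- strsplit(sequences, "")
  L <- length(chars[[1]])
  stopifnot(all(lengths(chars) == L))
  m <- do.call(rbind, chars)
  out <- lapply(seq_len(L), function(s) {
    st <- setdiff(unique(m[, s]), "-")
    tibble::tibble(site = s, state = st)
  })
  dplyr::bind_rows(out)
}

#' Synthetic natural-ortholog panel
#'
#' Emulates a panel of natural homologs by mutating the wildtype at
#' random sites, preferring near-neutral states of the landscape — a
#' stand-in for a real alignment of natural sequences when working fully
#' synthetically.
#'
#' @param landscape A landscape.
#' @param n_seqs Number of panel sequences (default 20).
#' @param divergence Substitutions per sequence (default 15).
#' @param seed RNG seed.
#' @return Tibble `site`, `state`.
#' @export
synthetic_natural_panel <- function(landscape, n_seqs = 20,
                                    divergence = 15, seed = 1) {
  set.seed(seed)
  wt <- strsplit(landscape$wildtype, "")[[1]]
  rows <- list()
  for (i in seq_len(n_seqs)) {
    sites <- sample(setdiff(seq_len(landscape$length),
                            landscape$chromophore_sites), divergence)
    states <- vapply(sites, function(s) {
      eff <- landscape$additive_effects[s, setdiff(AA_ALPHABET,
                                                   c(wt[s], "*"))]
      # prefer tolerated states, as natural divergence does
      names(eff)[which.max(eff + rnorm(length(eff), 0, 0.05))]
    }, character(1))
    rows[[i]] <- tibble::tibble(site = sites, state = states)
  }
  dplyr::bind_rows(rows) |> dplyr::distinct()
}

#' Genetic-algorithm parameters
#'
#' Defaults follow the published algorithm: a population of 50 wildtype
#' genotypes; each generation half the population is set aside
#' untouched; pairs of the other half cross over with probability 0.7 at
#' 0-5 uniformly placed breakpoints (strict reciprocal exchange); each
#' residue mutates with probability 0.012 using pool moves (reversions
#' included); genotypes exceeding the target mutation count lose one
#' previously added mutation; fluorescence is the median of 20 Monte
#' Carlo dropout passes; the run stops a few generations after the
#' population median plateaus.
#'
#' @param target_muts Target mutation count of designed genotypes.
#' @param pop_size Population size (even; default 50).
#' @param crossover_prob Per-pair crossover probability (default 0.7).
#' @param max_crossovers Maximum breakpoints per crossover event.
#' @param mutation_prob Per-residue mutation probability (default 0.012,
#'   the midpoint of the published 0.01-0.015 range).
#' @param untouched_frac Fraction left untouched each generation.
#' @param mc_samples MC dropout passes per evaluation (default 20).
#' @param plateau_eps,plateau_window Plateau detection: stop when the
#'   population median changes by less than `plateau_eps` over
#'   `plateau_window` generations.
#' @param plateau_extra Extra generations run after the plateau.
#' @param max_generations Hard cap (default 100).
#' @param seed RNG seed.
#' @return A list of class `ga_params`.
#' @export
ga_params <- function(target_muts = 6, pop_size = 50,
                      crossover_prob = 0.7, max_crossovers = 5,
                      mutation_prob = 0.012, untouched_frac = 0.5,
                      mc_samples = 20, plateau_eps = 0.005,
                      plateau_window = 5, plateau_extra = 3,
                      max_generations = 100, seed = 1) {
  stopifnot(pop_size %% 2 == 0, crossover_prob >= 0, crossover_prob <= 1,
            mutation_prob >= 0, mutation_prob <= 1, target_muts >= 1)
  structure(list(target_muts = target_muts, pop_size = pop_size,
                 crossover_prob = crossover_prob,
                 max_crossovers = max_crossovers,
                 mutation_prob = mutation_prob,
                 untouched_frac = untouched_frac,
                 mc_samples = mc_samples, plateau_eps = plateau_eps,
                 plateau_window = plateau_window,
                 plateau_extra = plateau_extra,
                 max_generations = max_generations, seed = seed),
            class = "ga_params")
}

#' Evolve a population of designed genotypes
#'
#' One replicate of the genetic algorithm, driven by a trained fitness
#' network as the evaluation function.
#'
#' @param model A `fitnet` (supporting Monte Carlo prediction).
#' @param pool A [build_pool()] mutation pool.
#' @param params A [ga_params()].
#' @param wildtype Wildtype protein sequence.
#' @return List of class `ga_run`: `population` (tibble `aa_muts`,
#'   `n_muts`, `pred_median`, `pred_sd`), `history` (tibble per
#'   generation), `moves_sampled` (indices of pool moves used),
#'   `at_target_seen` (every on-target genotype that survived selection
#'   in any generation), `converged`.
#' @export
evolve <- function(model, pool, params = ga_params(),
                   wildtype = model$wildtype) {
  set.seed(params$seed)
  wt <- strsplit(wildtype, "")[[1]]
  L <- length(wt)
  pop <- matrix(rep(wt, params$pop_size), nrow = params$pop_size,
                byrow = TRUE)
  moves_sampled <- integer(0)
  at_target_seen <- character(0)
  history <- list()
  plateau_at <- NA_integer_
  preds <- eval_population(model, pop, wt, params$mc_samples)

  for (gen in seq_len(params$max_generations)) {
    ord <- sample.int(nrow(pop))
    pop <- pop[ord, , drop = FALSE]
    preds <- preds[ord, , drop = FALSE]
    n_keep <- round(params$untouched_frac * nrow(pop))
    untouched <- pop[seq_len(n_keep), , drop = FALSE]
    working <- pop[-seq_len(n_keep), , drop = FALSE]

    # reciprocal crossover on pairs, 0-5 uniformly placed breakpoints
    n_pairs <- floor(nrow(working) / 2)
    for (p in seq_len(n_pairs)) {
      if (runif(1) > params$crossover_prob) next
      k <- sample(0:params$max_crossovers, 1)
      if (k == 0) next
      cuts <- sort(sample.int(L - 1, min(k, L - 1)))
      seg_id <- findInterval(seq_len(L), cuts + 0.5) %% 2 == 1
      i1 <- 2 * p - 1; i2 <- 2 * p
      tmp <- working[i1, seg_id]
      working[i1, seg_id] <- working[i2, seg_id]
      working[i2, seg_id] <- tmp
    }

    # mutation step: pool moves (including wildtype reversions)
    n_events <- rbinom(nrow(working), L, params$mutation_prob)
    for (i in which(n_events > 0)) {
      mv <- sample.int(nrow(pool), n_events[i], replace = TRUE,
                       prob = pool$weight)
      moves_sampled <- c(moves_sampled, mv)
      working[i, pool$site[mv]] <- pool$state[mv]
    }

    # bounce back toward the target: drop one added mutation if over
    over <- which(rowSums(t(t(working) != wt)) > params$target_muts)
    for (i in over) {
      mutated <- which(working[i, ] != wt)
      revert <- sample(mutated, 1)
      working[i, revert] <- wt[revert]
    }

    # offspring are added to the population; parents are retained and the
    # merged pool is truncated back to the population size by predicted
    # fluorescence. The whole pool is (re-)evaluated so every genotype
    # carries fresh Monte Carlo noise and no genotype keeps a lucky
    # frozen score.
    all_pop <- rbind(pop, working)
    all_preds <- eval_population(model, all_pop, wt, params$mc_samples)
    keep <- order(all_preds$median, decreasing = TRUE)[
      seq_len(params$pop_size)]
    pop <- all_pop[keep, , drop = FALSE]
    preds <- all_preds[keep, , drop = FALSE]

    n_muts_now <- rowSums(t(t(pop) != wt))
    if (any(n_muts_now == params$target_muts)) {
      hit <- pop[n_muts_now == params$target_muts, , drop = FALSE]
      at_target_seen <- union(
        at_target_seen,
        protein_mutations(wildtype, apply(hit, 1, paste, collapse = "")))
    }
    med <- median(preds$median)
    med_muts <- median(n_muts_now)
    history[[gen]] <- tibble::tibble(
      generation = gen, median_pred = med,
      best_pred = max(preds$median),
      median_muts = med_muts,
      mean_muts = mean(rowSums(t(t(pop) != wt))))
    # the plateau criterion only applies once the population sits at the
    # desired mutation count; stopping earlier would select near-wildtype
    # genotypes
    if (is.na(plateau_at) && gen > params$plateau_window &&
        med_muts >= params$target_muts) {
      past <- history[[gen - params$plateau_window]]
      if (past$median_muts >= params$target_muts &&
          abs(med - past$median_pred) < params$plateau_eps) {
        plateau_at <- gen
      }
    }
    if (!is.na(plateau_at) && gen >= plateau_at + params$plateau_extra) {
      break
    }
  }

  genotypes <- protein_mutations(wildtype, apply(pop, 1, paste,
                                                 collapse = ""))
  structure(list(
    population = tibble::tibble(
      aa_muts = genotypes,
      n_muts = vapply(parse_mutations(genotypes), nrow, integer(1)),
      pred_median = preds$median, pred_sd = preds$sd),
    history = dplyr::bind_rows(history),
    moves_sampled = unique(moves_sampled),
    at_target_seen = at_target_seen,
    converged = !is.na(plateau_at)), class = "ga_run")
}

eval_population <- function(model, pop, wt, mc_samples) {
  genos <- protein_mutations(paste(wt, collapse = ""),
                             apply(pop, 1, paste, collapse = ""))
  predict_mc(model, genos, n_samples = mc_samples)
}

#' Run replicated genetic-algorithm designs
#'
#' Repeats [evolve()] with distinct seeds until at least `n_replicates`
#' runs have completed and every pool move has been sampled at least
#' once (up to `max_replicates`).
#'
#' @param model,pool,params,wildtype As in [evolve()].
#' @param n_replicates Minimum replicates (default 10).
#' @param max_replicates Hard cap (default `3 * n_replicates`).
#' @return Tibble of final populations with a `replicate` column.
#' @export
evolve_replicates <- function(model, pool, params = ga_params(),
                              wildtype = model$wildtype,
                              n_replicates = 10,
                              max_replicates = 3 * n_replicates) {
  sampled <- integer(0)
  runs <- list()
  r <- 0
  while (r < max_replicates &&
         (r < n_replicates || length(sampled) < nrow(pool))) {
    r <- r + 1
    p <- params
    p$seed <- params$seed + r - 1
    run <- evolve(model, pool, p, wildtype)
    sampled <- union(sampled, run$moves_sampled)
    runs[[r]] <- dplyr::mutate(run$population, replicate = r)
  }
  dplyr::bind_rows(runs)
}

#' Filter designed candidates with two independent models
#'
#' Keeps unique genotypes at exactly the target mutation count whose
#' prediction minus its Monte Carlo SD exceeds the wildtype prediction
#' under both the optimized and the a-posteriori model.
#'
#' @param populations Tibble from [evolve_replicates()] (or an
#'   [evolve()] population).
#' @param opt_model,post_model Trained `fitnet`s.
#' @param target_muts Required mutation count.
#' @param mc_samples,seed MC evaluation settings.
#' @return Tibble of `design_candidate`s: `aa_muts`, `n_muts`,
#'   `opt_median`, `opt_sd`, `post_median`, `post_sd`.
#' @export
filter_candidates <- function(populations, opt_model, post_model,
                              target_muts, mc_samples = 20, seed = 1) {
  cands <- populations |>
    dplyr::distinct(.data$aa_muts, .keep_all = TRUE) |>
    dplyr::filter(.data$n_muts == target_muts)
  if (nrow(cands) == 0) {
    message("no candidates at the target mutation count")
    return(tibble::tibble(aa_muts = character(), n_muts = integer(),
                          opt_median = numeric(), opt_sd = numeric(),
                          post_median = numeric(), post_sd = numeric()))
  }
  opt <- predict_mc(opt_model, cands$aa_muts, n_samples = mc_samples,
                    seed = seed)
  post_has_dropout <- any(vapply(post_model$arch$hidden, `[[`,
                                 numeric(1), "dropout") > 0)
  post <- if (post_has_dropout) {
    predict_mc(post_model, cands$aa_muts, n_samples = mc_samples,
               seed = seed)
  } else {
    tibble::tibble(median = predict(post_model, cands$aa_muts), sd = 0)
  }
  wt_opt <- predict_mc(opt_model, "", n_samples = mc_samples,
                       seed = seed)$median
  wt_post <- if (post_has_dropout) {
    predict_mc(post_model, "", n_samples = mc_samples, seed = seed)$median
  } else predict(post_model, "")
  keep <- (opt$median - opt$sd) > wt_opt &
    (post$median - post$sd) > wt_post
  tibble::tibble(aa_muts = cands$aa_muts, n_muts = cands$n_muts,
                 opt_median = opt$median, opt_sd = opt$sd,
                 post_median = post$median, post_sd = post$sd)[keep, ]
}

#' Select diverse representative candidates
#'
#' Greedy identity clustering with a decreasing similarity threshold
#' (0.999 down to 0.80 in steps of 0.002): candidates are seeded in
#' order of predicted fluorescence, each sequence joins the first seed
#' with fractional identity at or above the threshold, and the schedule
#' stops at the first threshold yielding at most `n` clusters. The
#' highest-predicted member of each cluster is returned.
#'
#' @param candidates A [filter_candidates()] tibble (needs `aa_muts`,
#'   `opt_median`) with a `wildtype` attribute or explicit `wildtype`.
#' @param n Number of representatives.
#' @param wildtype Wildtype protein sequence.
#' @param thresholds Similarity schedule.
#' @return The selected rows with a `cluster` column.
#' @export
select_diverse <- function(candidates, n, wildtype,
                           thresholds = seq(0.999, 0.80, by = -0.002)) {
  stopifnot(nrow(candidates) >= 1, n >= 1)
  if (n >= nrow(candidates)) {
    candidates$cluster <- seq_len(nrow(candidates))
    return(candidates)
  }
  ord <- order(candidates$opt_median, decreasing = TRUE)
  cands <- candidates[ord, , drop = FALSE]
  seqs <- strsplit(mutate_protein(wildtype, cands$aa_muts), "")
  L <- length(seqs[[1]])
  sim <- function(a, b) sum(a == b) / L
  for (thr in thresholds) {
    cluster <- integer(nrow(cands))
    seeds <- integer(0)
    for (i in seq_len(nrow(cands))) {
      assigned <- FALSE
      for (s in seeds) {
        if (sim(seqs[[i]], seqs[[s]]) >= thr) {
          cluster[i] <- cluster[s]
          assigned <- TRUE
          break
        }
      }
      if (!assigned) {
        seeds <- c(seeds, i)
        cluster[i] <- length(seeds)
      }
    }
    if (max(cluster) <= n) {
      cands$cluster <- cluster
      reps <- cands[!duplicated(cands$cluster), , drop = FALSE]
      return(reps)
    }
  }
  # schedule exhausted: return the n best seeds at the final threshold
  cands$cluster <- cluster
  reps <- cands[!duplicated(cands$cluster), , drop = FALSE]
  head(reps, n)
}

#' Random combinations of individually neutral pool moves
#'
#' Baseline designs for benchmarking: `n` genotypes each carrying
#' `target_muts` distinct mutant moves drawn uniformly from the pool
#' (whose members are individually neutral-or-better by construction),
#' with no model guidance.
#'
#' @param pool A [build_pool()] pool.
#' @param wildtype Wildtype protein.
#' @param target_muts Substitutions per genotype.
#' @param n Number of genotypes.
#' @param seed RNG seed.
#' @return Tibble `aa_muts`, `n_muts`.
#' @export
random_neutral_designs <- function(pool, wildtype, target_muts, n,
                                   seed = 1) {
  set.seed(seed)
  wt <- strsplit(wildtype, "")[[1]]
  mutants <- pool[pool$type == "mutant", , drop = FALSE]
  sites <- unique(mutants$site)
  if (length(sites) < target_muts) {
    stop("pool spans fewer sites than the target mutation count")
  }
  genos <- vapply(seq_len(n), function(i) {
    pick_sites <- sample(sites, target_muts)
    states <- vapply(pick_sites, function(s) {
      opts <- mutants$state[mutants$site == s]
      if (length(opts) == 1) opts else sample(opts, 1)
    }, character(1))
    format_mutations(pick_sites, wt[pick_sites], states)
  }, character(1))
  tibble::tibble(aa_muts = genos,
                 n_muts = rep(target_muts, n))
}
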