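toy_dataset <- function() {
  d <- tibble::tibble(
    aa_muts = c("", "A5T", "K7R", "A5T:K7R", "A5T:K7R:G9S"),
    n_muts = c(0L, 1L, 1L, 2L, 3L),
    fluorescence = c(4.0, 3.8, 3.9, 2.0, 1.9),
    n_nt_genotypes = 1L, total_cells = 100)
  attr(d, "wt_mean") <- 4.0
  attr(d, "wt_sd") <- 0.03
  d
}

test_that("single-mutant effects are measured against the wildtype mean", {
  s <- single_effects(toy_dataset())
  expect_equal(s$effect[s$mutation == "A5T"], -0.2)
  expect_equal(s$effect[s$mutation == "K7R"], -0.1)
  # mutations never seen alone are absent
  expect_false("G9S" %in% s$mutation)
  expect_equal(attr(s, "f_wt"), 4.0)
})

test_that("epistasis is observed minus the capped additive expectation", {
  d <- toy_dataset()
  s <- single_effects(d)
  e <- epistasis(d, s)
  dbl <- e[e$aa_muts == "A5T:K7R", ]
  expect_equal(dbl$expected, 3.7)
  expect_equal(dbl$epistasis, -1.7)
  # a single-mutant genotype has epistasis exactly 0
  expect_equal(e$epistasis[e$aa_muts == "A5T"], 0)
  # a genotype with an unmeasured single is flagged non-computable
  expect_false(e$computable[e$aa_muts == "A5T:K7R:G9S"])
})

test_that("expectations are capped to the observed range", {
  d <- tibble::tibble(
    aa_muts = c("", "A5T", "K7R", "A5T:K7R"),
    n_muts = c(0L, 1L, 1L, 2L),
    fluorescence = c(4.0, 4.3, 4.4, 4.5),
    n_nt_genotypes = 1L)
  attr(d, "wt_mean") <- 4.0
  s <- single_effects(d, wt_sd = 0.03)
  e <- epistasis(d, s)
  dbl <- e[e$aa_muts == "A5T:K7R", ]
  # raw expectation 4.0 + 0.3 + 0.4 = 4.7, capped at the dataset max 4.5
  expect_equal(dbl$expected_raw, 4.7)
  expect_equal(dbl$expected, 4.5)
  expect_equal(dbl$epistasis, 0)
  # invariant on every record
  expect_true(all(e$expected <= max(d$fluorescence) &
                    e$expected >= min(d$fluorescence)))
})

test_that("a purely additive dataset yields zero epistasis", {
  ls0 <- additive_landscape()
  d <- additive_truth_dataset(ls0, n = 4000, states_per_site = 5,
                              seed = 21)
  s <- single_effects(d)
  e <- epistasis(d, s)
  comp <- e[e$computable & e$n_muts >= 2, ]
  expect_gt(nrow(comp), 200)
  # uncapped expectations reproduce the truth exactly; capping can only
  # bite at the observed extremes
  expect_gte(mean(abs(comp$epistasis) < 1e-8), 0.99)
  curve <- additive_fraction_curve(e, functional_threshold = 2.0)
  expect_true(all(curve$fraction >= 0.95 & curve$fraction <= 1.05))
})

test_that("the additive-fraction curve omits empty denominators", {
  e <- tibble::tibble(
    aa_muts = c("A1T", "A1T:K2R"),
    n_muts = c(1L, 2L),
    observed = c(4, 1.8),
    expected = c(4, 1.8),
    expected_raw = c(4, 1.8),
    epistasis = c(0, 0),
    computable = TRUE)
  curve <- additive_fraction_curve(e, functional_threshold = 2.0)
  expect_false(2 %in% curve$n_muts)  # expected_functional is 0 at d=2
  expect_equal(curve$fraction[curve$n_muts == 1], 1)
})

test_that("logistic fits invert exactly on noiseless logistic fractions", {
  x <- 0:9
  y <- 1 / (1 + exp(-2 * (x - 4.1)))
  fit <- fit_logistic(x, y)
  expect_equal(fit$ld50, 4.1, tolerance = 1e-3)
  expect_equal(fit$L, 1, tolerance = 1e-3)
  expect_equal(fit$k, 2, tolerance = 1e-2)
})

test_that("LD50s are recovered and ordered across modes", {
  ls1 <- tiny_landscape()
  d <- truth_dataset(ls1, n = 6000, seed = 22, mean_muts = 5)
  lof <- fit_ld50(d, "loss_of_function", functional_threshold = 2.0)
  wtl <- fit_ld50(d, "loss_of_wt_level")
  expect_true(is.finite(lof$ld50))
  expect_true(is.finite(wtl$ld50))
  # losing the wildtype band always precedes losing function
  expect_lt(wtl$ld50, lof$ld50)
  td <- generics::glance(lof)
  expect_equal(td$ld50, lof$ld50)
})

test_that("peak profiles report medians per distance with a floor on n", {
  ls1 <- tiny_landscape()
  d <- truth_dataset(ls1, n = 3000, seed = 23)
  prof <- peak_profile(d, origin = "", min_genotypes = 1)
  expect_equal(prof$median_f[prof$distance == 0],
               median(d$fluorescence[d$n_muts == 0]))
  prof15 <- peak_profile(d, origin = "", min_genotypes = 15)
  expect_true(all(prof15$n >= 15))
  # invariance to row order
  set.seed(1)
  prof2 <- peak_profile(d[sample.int(nrow(d)), ], origin = "",
                        min_genotypes = 1)
  expect_equal(prof, prof2)
  expect_error(peak_profile(d, origin = "Z9QQQ1Z"), "origin")
})

test_that("cross-ortholog transfer classifies with wildtype-sd thresholds", {
  mk_singles <- function(effects, sd) {
    s <- tibble::tibble(
      mutation = names(effects),
      site = as.integer(gsub("[^0-9]", "", names(effects))),
      state = substring(names(effects), nchar(names(effects))),
      f_single = 4 + unname(effects),
      effect = unname(effects),
      n_obs = 1L)
    attr(s, "wt_sd") <- sd
    attr(s, "f_wt") <- 4
    s
  }
  a <- mk_singles(c(A1T = -0.01, K2R = -0.5, G3S = 0.02), 0.03)
  b <- mk_singles(c(A1T = -0.2, K2R = -0.5, G3S = 0.01), 0.03)
  out <- cross_ortholog_transfer(a, b)
  # A1T: |−0.01| <= 2*0.03 in A and −0.2 < −5*0.03 in B -> counted
  expect_equal(out$n_shared, 3L)
  expect_equal(out$n_events, 1L)
  expect_equal(out$fraction, 1 / 3)
  # self-comparison has no neutral->deleterious events
  self <- cross_ortholog_transfer(a, a)
  expect_equal(self$fraction, 0)
})

test_that("shared epistatic pairs handle identical and disjoint sets", {
  e <- tibble::tibble(
    aa_muts = c("A1T:K2R", "A1T:K2R", "G3S:L4V"),
    n_muts = 2L,
    observed = c(2, 2.2, 4),
    expected = c(3.9, 3.9, 4),
    expected_raw = c(3.9, 3.9, 4),
    epistasis = c(-1.9, -1.7, 0),
    computable = TRUE)
  same <- shared_epistatic_pairs(e, e, cutoff = 0.3)
  expect_equal(same$fraction, 1)
  e2 <- e
  e2$epistasis <- c(0, 0, -1)   # disjoint epistatic pairs
  disjoint <- shared_epistatic_pairs(e, e2, cutoff = 0.3)
  expect_equal(disjoint$fraction, 0)
  pairs <- pair_epistasis(e)
  expect_equal(nrow(pairs), 2)
  expect_equal(pairs$epistasis[pairs$site1 == 1], -1.9)
})

test_that("pair sharing between landscapes tracks the generators' overlap", {
  # two landscapes engineered to share half of A's epistatic site pairs;
  # oracle: the exact overlap fraction computed from the term tables
  base <- make_landscape(40, landscape_config(
    p_neutral = 0.9, epistasis_density = 0.08,
    epistasis_scale = 1.2, epistasis_negative_bias = 1), seed = 31)
  other <- base
  keep <- seq_len(floor(nrow(base$epistatic_terms) / 2))
  moved <- base$epistatic_terms
  # reposition the second half of the terms to fresh site pairs
  set.seed(32)
  n_move <- nrow(moved) - length(keep)
  taken <- paste(moved$site1, moved$site2)
  for (i in seq_len(n_move)) {
    repeat {
      s <- sort(sample.int(40, 2))
      if (!paste(s[1], s[2]) %in% taken) break
    }
    moved$site1[length(keep) + i] <- s[1]
    moved$site2[length(keep) + i] <- s[2]
    taken <- c(taken, paste(s[1], s[2]))
  }
  other$epistatic_terms <- moved
  other$epistasis_matrix[] <- 0
  other$epistasis_matrix[cbind(moved$site1, moved$site2)] <- moved$effect
  other$epistasis_matrix[cbind(moved$site2, moved$site1)] <- moved$effect

  da <- truth_dataset(base, n = 20000, states_per_site = 3, seed = 33,
                      mean_muts = 2.2)
  db <- truth_dataset(other, n = 20000, states_per_site = 3, seed = 34,
                      mean_muts = 2.2)
  ea <- epistasis(da, single_effects(da))
  eb <- epistasis(db, single_effects(db))
  out <- shared_epistatic_pairs(ea, eb, cutoff = 0.3)
  pa <- pair_epistasis(ea); pa <- pa[abs(pa$epistasis) > 0.3, ]
  pb <- pair_epistasis(eb); pb <- pb[abs(pb$epistasis) > 0.3, ]
  key <- function(p) paste(p$site1, p$site2)
  oracle <- length(intersect(key(pa), key(pb))) /
    length(union(key(pa), key(pb)))
  expect_equal(out$fraction, oracle, tolerance = 0.35)
  expect_gt(out$n_either, 10)
})

test_that("annotation summaries behave at the null and at perfect signal", {
  d <- tibble::tibble(
    aa_muts = c("", "A5T", "K7R", "G9S", "L11V"),
    n_muts = c(0L, 1L, 1L, 1L, 1L),
    fluorescence = c(4.0, 3.8, 3.9, 3.2, 4.0),
    n_nt_genotypes = 1L)
  attr(d, "wt_mean") <- 4.0
  s <- single_effects(d, wt_sd = 0.03)
  ann_num <- tibble::tibble(site = s$site, score = -s$effect)
  out <- annotate_effects(s, ann_num)
  expect_equal(out$rank_correlation$rho, -1)
  ann_cat <- tibble::tibble(site = c(5, 7, 9, 11),
                            category = c("buried", "exposed", "buried",
                                         "exposed"))
  out2 <- annotate_effects(s, ann_cat)
  expect_equal(nrow(out2$by_category), 2)
})

test_that("epistatic pairs at fixed short distances are detected", {
  pairs <- tibble::tibble(site1 = c(1, 2, 3, 4), site2 = c(5, 6, 7, 8),
                          epistasis = c(-1, -0.8, 0.01, 0),
                          n_doubles = 3L)
  dist_tbl <- tibble::tibble(site1 = c(1, 2, 3, 4), site2 = c(5, 6, 7, 8),
                             distance = c(5, 5, 20, 20))
  out <- epistatic_pair_proximity(pairs, dist_tbl, cutoff = 0.3)
  med <- out$summary
  expect_equal(med$median_distance[med$epistatic], 5)
  expect_equal(med$median_distance[!med$epistatic], 20)
  # all pairs equidistant: no difference to detect
  dist_eq <- dist_tbl; dist_eq$distance <- 10
  out_eq <- epistatic_pair_proximity(pairs, dist_eq, cutoff = 0.3)
  expect_true(is.null(out_eq$rank_test))
})
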