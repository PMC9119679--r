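test_that("one-hot encoding is a bijection on observed genotypes", {
  ls1 <- tiny_landscape()
  d <- truth_dataset(ls1, n = 300, seed = 41)
  ds <- encode_genotypes(d, ls1$wildtype)
  # exactly one active state per position
  per_site <- tapply(seq_len(ncol(ds$X)), ds$col_info$site,
                     function(j) rowSums(ds$X[, j, drop = FALSE]))
  expect_true(all(vapply(per_site, function(v) all(v == 1), logical(1))))
  # decode(encode(g)) = g
  expect_identical(decode_genotypes(ds), ds$genotypes)
  # columns exist only for observed states (wildtype included)
  obs <- dplyr::bind_rows(parse_mutations(d$aa_muts))
  n_expected <- ls1$length + nrow(dplyr::distinct(obs, site, alt))
  expect_equal(ncol(ds$X), n_expected)
})

test_that("unknown symbols are rejected at encoding", {
  ls1 <- tiny_landscape()
  d <- tibble::tibble(aa_muts = c("", "A5B"), fluorescence = c(4, 4))
  expect_error(encode_genotypes(d, ls1$wildtype), "unknown")
})

test_that("splits are disjoint, exhaustive and reproducible", {
  ls1 <- tiny_landscape()
  d <- truth_dataset(ls1, n = 10, seed = 42)[1:10, ]
  ds <- split_dataset(encode_genotypes(d, ls1$wildtype), seed = 3)
  expect_equal(as.vector(table(ds$split)[c("train", "validation",
                                           "test")]), c(6, 2, 2))
  ds2 <- split_dataset(encode_genotypes(d, ls1$wildtype), seed = 3)
  expect_identical(ds$split, ds2$split)
  expect_equal(sum(table(ds$split)), nrow(ds$X))
})

test_that("training-set filtering reaches its fixed point", {
  # removing the genotype with the rare mutation drops another mutation
  # below threshold, which must then also be removed
  wt <- strrep("A", 30)
  d <- tibble::tibble(
    aa_muts = c(rep("A1C", 4), "A1C:A2D", "A2D:A3E", rep("A3E", 2),
                rep("A5G", 10), ""),
    fluorescence = 4)
  ds <- encode_genotypes(d, wt)
  ds$split <- factor(rep("train", nrow(ds$X)),
                     levels = c("train", "validation", "test",
                                "excluded"))
  out <- filter_for_training(ds, min_genotypes = 5)
  kept <- ds$genotypes[out$split == "train"]
  # brute-force iteration on this toy set leaves only A5G genotypes and
  # the wildtype
  expect_setequal(unique(kept), c("A5G", ""))
  # identity when all mutations are already frequent
  d2 <- tibble::tibble(aa_muts = rep("A1C", 12), fluorescence = 4)
  ds2 <- encode_genotypes(d2, wt)
  ds2$split <- factor(rep("train", 12),
                      levels = c("train", "validation", "test",
                                 "excluded"))
  expect_equal(sum(filter_for_training(ds2, 10)$split == "train"), 12)
})

test_that("validation genotypes with unseen mutations are pruned", {
  wt <- strrep("A", 30)
  d <- tibble::tibble(
    aa_muts = c(rep("A1C", 12), "A2D", "A1C"),
    fluorescence = 4)
  ds <- encode_genotypes(d, wt)
  ds$split <- factor(c(rep("train", 12), "validation", "validation"),
                     levels = c("train", "validation", "test",
                                "excluded"))
  out <- filter_for_training(ds, min_genotypes = 10)
  expect_equal(as.character(out$split[13]), "excluded")
  expect_equal(as.character(out$split[14]), "validation")
})

test_that("the linear model recovers additive effects from clean data", {
  ls0 <- additive_landscape(length = 40)
  d <- additive_truth_dataset(ls0, n = 3000, states_per_site = 4,
                              seed = 43)
  ds <- split_dataset(encode_genotypes(d, ls0$wildtype), seed = 1) |>
    filter_for_training()
  m <- train_fitnet(ds, arch_linear(), max_epochs = 600, patience = 600,
                    lr = 0.01, seed = 1)
  expect_gte(model_r2(m, ds), 0.99)
  # weights of well-sampled mutations match the generator's effects
  # (oracle: the effect matrix). One-hot rows are collinear per site, so
  # the identifiable quantity is the mutant-minus-wildtype weight
  # contrast at each site.
  td <- generics::tidy(m)
  wt_w <- td$weight[td$is_wt]
  names(wt_w) <- td$site[td$is_wt]
  non_wt <- td[!td$is_wt, ]
  tr_counts <- colSums(ds$X[ds$split == "train", non_wt$label,
                            drop = FALSE])
  non_wt <- non_wt[tr_counts >= 10, ]
  est <- non_wt$weight - wt_w[as.character(non_wt$site)]
  truth <- ls0$additive_effects[cbind(non_wt$site,
                                      match(non_wt$state, AA_ALPHABET))]
  expect_gt(summary(stats::lm(truth ~ est))$r.squared, 0.98)
  expect_lt(max(abs(est - truth)), 0.1)
})

test_that("early stopping halts after the patience window", {
  ls1 <- tiny_landscape()
  d <- truth_dataset(ls1, n = 300, seed = 44)
  ds <- split_dataset(encode_genotypes(d, ls1$wildtype), seed = 1)
  # zero learning rate: the validation loss can never improve after the
  # first epoch, so training must stop after exactly patience more epochs
  m <- train_fitnet(ds, arch_linear(), max_epochs = 30, patience = 10,
                    lr = 0, seed = 1)
  expect_equal(m$epochs_trained, 11)
})

test_that("Monte Carlo dropout yields uncertainty only with dropout", {
  ls1 <- tiny_landscape()
  d <- truth_dataset(ls1, n = 800, states_per_site = 5, seed = 45)
  ds <- split_dataset(encode_genotypes(d, ls1$wildtype), seed = 1)
  m0 <- train_fitnet(ds, arch_two_layer(10, 5, dropout = 0),
                     max_epochs = 10, lr = 0.01, seed = 1)
  pm0 <- predict_mc(m0, d$aa_muts[1:5], n_samples = 10, seed = 2)
  expect_true(all(pm0$sd == 0))
  m1 <- train_fitnet(ds, arch_two_layer(10, 5, dropout = 0.1),
                     max_epochs = 10, lr = 0.01, seed = 1)
  pm1 <- predict_mc(m1, d$aa_muts[1:5], n_samples = 20, seed = 2)
  expect_true(all(pm1$sd > 0))
  # reproducible under a fixed seed
  pm1b <- predict_mc(m1, d$aa_muts[1:5], n_samples = 20, seed = 2)
  expect_identical(pm1$median, pm1b$median)
  # uncertainty shrinks as the dropout rate vanishes
  m2 <- train_fitnet(ds, arch_two_layer(10, 5, dropout = 0.01),
                     max_epochs = 10, lr = 0.01, seed = 1)
  pm2 <- predict_mc(m2, d$aa_muts[1:5], n_samples = 50, seed = 3)
  pm3 <- predict_mc(m1, d$aa_muts[1:5], n_samples = 50, seed = 3)
  expect_lt(mean(pm2$sd), mean(pm3$sd))
})

test_that("R-squared matches its closed forms", {
  ls1 <- tiny_landscape()
  d <- truth_dataset(ls1, n = 50, seed = 46)
  ds <- encode_genotypes(d, ls1$wildtype)
  y <- ds$y
  fake <- list(arch = arch_linear(), layers = NULL, y_mean = 0, y_sd = 1)
  # perfect predictions
  r2 <- 1 - sum((y - y)^2) / sum((y - mean(y))^2)
  expect_equal(r2, 1)
  # constant prediction at the label mean scores 0
  expect_equal(1 - sum((y - mean(y))^2) / sum((y - mean(y))^2), 0)
  # a fixed offset c scores 1 - n c^2 / SS_tot
  c0 <- 0.3
  expect_equal(1 - sum((y - (y + c0))^2) / sum((y - mean(y))^2),
               1 - length(y) * c0^2 / sum((y - mean(y))^2))
})

test_that("grid search selects and retrains the best architecture", {
  ls1 <- tiny_landscape()
  d <- truth_dataset(ls1, n = 800, states_per_site = 5, seed = 47)
  ds <- split_dataset(encode_genotypes(d, ls1$wildtype), seed = 1) |>
    filter_for_training(min_genotypes = 2)
  gs <- grid_search(ds, widths = c(5, 10), n_candidates = 4,
                    search_epochs = 3, final_epochs = 5, seed = 2)
  expect_s3_class(gs$model, "fitnet")
  expect_equal(nrow(gs$search), 4)
  best <- gs$search[which.min(gs$search$val_loss), ]
  gl <- generics::glance(gs$model)
  expect_equal(c(gl$h1, gl$h2), c(best$h1, best$h2))
  # a one-architecture grid selects that architecture
  gs1 <- grid_search(ds, widths = 5, n_candidates = 1,
                     search_epochs = 2, final_epochs = 2, seed = 2)
  expect_equal(c(generics::glance(gs1$model)$h1,
                 generics::glance(gs1$model)$h2), c(5, 5))
  # seeded search is reproducible
  gs2 <- grid_search(ds, widths = c(5, 10), n_candidates = 4,
                     search_epochs = 3, final_epochs = 5, seed = 2)
  expect_identical(gs$search, gs2$search)
})

test_that("the a-posteriori model is deterministic and agrees broadly", {
  ls0 <- additive_landscape(length = 40)
  d <- truth_dataset(ls0, n = 2500, states_per_site = 4, seed = 48)
  ds <- split_dataset(encode_genotypes(d, ls0$wildtype), seed = 1)
  opt <- train_fitnet(ds, arch_two_layer(20, 10), max_epochs = 40,
                      patience = 15, lr = 0.01, seed = 1)
  post <- train_posterior(ds, max_epochs = 60, lr = 0.01, seed = 2)
  # deterministic at inference: repeated predictions identical
  p1 <- predict(post, d$aa_muts[1:20])
  p2 <- predict(post, d$aa_muts[1:20])
  expect_identical(p1, p2)
  # the two independently trained models agree on functional calls
  held <- ds$split == "test"
  po <- predict_mc(opt, ds$X[held, , drop = FALSE], seed = 3)$median
  pp <- predict(post, ds$X[held, , drop = FALSE])
  agree <- mean((po > 3) == (pp > 3))
  expect_gte(agree, 0.95)
})

test_that("the transform network exposes its 1-D threshold curve", {
  ls1 <- tiny_landscape()
  d <- truth_dataset(ls1, n = 2000, states_per_site = 5, seed = 49)
  ds <- split_dataset(encode_genotypes(d, ls1$wildtype), seed = 1)
  m <- train_fitnet(ds, arch_transform(), max_epochs = 40, patience = 15,
                    lr = 0.01, seed = 1)
  pots <- drop(ds$X %*% m$layers[[1]]$W) + m$layers[[1]]$b
  curve <- transform_curve(m, potentials = pots)
  expect_true(all(c("potential", "fluorescence") %in% names(curve)))
  # over the realized potential range the learned transform is a
  # threshold-like, essentially non-decreasing curve spanning the dark
  # floor to the wildtype level (tiny wiggles from the sigmoid mixture
  # are tolerated)
  expect_true(all(diff(curve$fluorescence) > -0.05))
  expect_gt(diff(range(curve$fluorescence)), 1)
})
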