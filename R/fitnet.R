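#' Network architectures for fitness modeling
#'
#' Presets mirror the modeling ladder used for GFP landscapes:
#' * `arch_linear()` — a single linear output node; its weighted sum of
#'   mutation indicators is the *fitness potential*.
#' * `arch_sigmoid()` — the linear node followed by one sigmoid node and
#'   a linear output, capturing the abrupt threshold between dark and
#'   near-wildtype genotypes.
#' * `arch_transform()` — one linear node (the potential) feeding 10
#'   sigmoid nodes and a linear output; the learned 1-D transform can be
#'   exported with [transform_curve()].
#' * `arch_two_layer(h1, h2)` — a linear hidden layer and a sigmoid
#'   hidden layer, each followed by Monte Carlo dropout (rate 0.1, active
#'   at inference; never after the output node).
#' * `arch_posterior()` — 10 and 100 leaky-ReLU hidden nodes with a
#'   leaky-ReLU output, used as an independent a-posteriori filter.
#'
#' @param h1,h2 Hidden-layer widths.
#' @param dropout Dropout rate after each hidden layer.
#' @return A list of class `fitnet_arch`.
#' @name fitnet_arch
NULL

new_arch <- function(name, hidden, out_act = "linear") {
  structure(list(name = name, hidden = hidden, out_act = out_act),
            class = "fitnet_arch")
}

#' @rdname fitnet_arch
#' @export
arch_linear <- function() new_arch("linear", list())

#' @rdname fitnet_arch
#' @export
arch_sigmoid <- function() {
  new_arch("sigmoid", list(
    list(width = 1, act = "linear", dropout = 0),
    list(width = 1, act = "sigmoid", dropout = 0)))
}

#' @rdname fitnet_arch
#' @export
arch_transform <- function() {
  new_arch("transform", list(
    list(width = 1, act = "linear", dropout = 0),
    list(width = 10, act = "sigmoid", dropout = 0)))
}

#' @rdname fitnet_arch
#' @export
arch_two_layer <- function(h1 = 50, h2 = 20, dropout = 0.1) {
  new_arch("two_layer", list(
    list(width = h1, act = "linear", dropout = dropout),
    list(width = h2, act = "sigmoid", dropout = dropout)))
}

#' @rdname fitnet_arch
#' @export
arch_posterior <- function() {
  new_arch("posterior", list(
    list(width = 10, act = "lrelu", dropout = 0),
    list(width = 100, act = "lrelu", dropout = 0)),
    out_act = "lrelu")
}

activate <- function(z, act) {
  switch(act,
         linear = z,
         sigmoid = 1 / (1 + exp(-z)),
         lrelu = ifelse(z > 0, z, 0.3 * z))
}

activate_grad <- function(a, z, act) {
  switch(act,
         linear = matrix(1, nrow(z), ncol(z)),
         sigmoid = a * (1 - a),
         lrelu = ifelse(z > 0, 1, 0.3))
}

init_layers <- function(arch, p_in) {
  widths <- c(p_in, vapply(arch$hidden, `[[`, numeric(1), "width"), 1)
  acts <- c(vapply(arch$hidden, `[[`, character(1), "act"), arch$out_act)
  drops <- c(vapply(arch$hidden, `[[`, numeric(1), "dropout"), 0)
  lapply(seq_along(acts), function(i) {
    limit <- sqrt(6 / (widths[i] + widths[i + 1]))
    list(W = matrix(runif(widths[i] * widths[i + 1], -limit, limit),
                    widths[i], widths[i + 1]),
         b = numeric(widths[i + 1]),
         act = acts[i], dropout = drops[i])
  })
}

forward_pass <- function(layers, X, dropout_active = FALSE) {
  caches <- vector("list", length(layers))
  A <- X
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    Z <- A %*% l$W + matrix(l$b, nrow(A), length(l$b), byrow = TRUE)
    A_out <- activate(Z, l$act)
    mask <- NULL
    if (dropout_active && l$dropout > 0) {
      keep <- 1 - l$dropout
      mask <- matrix(rbinom(length(A_out), 1, keep) / keep,
                     nrow(A_out), ncol(A_out))
      A_out <- A_out * mask
    }
    caches[[i]] <- list(A_in = A, Z = Z, A_out = A_out, mask = mask)
    A <- A_out
  }
  list(yhat = drop(A), caches = caches)
}

backward_pass <- function(layers, caches, y) {
  n <- length(y)
  grads <- vector("list", length(layers))
  delta <- matrix(2 * (drop(caches[[length(layers)]]$A_out) - y) / n,
                  ncol = 1)
  for (i in rev(seq_along(layers))) {
    l <- layers[[i]]
    cache <- caches[[i]]
    if (!is.null(cache$mask)) delta <- delta * cache$mask
    dZ <- delta * activate_grad(activate(cache$Z, l$act), cache$Z, l$act)
    grads[[i]] <- list(W = crossprod(cache$A_in, dZ), b = colSums(dZ))
    if (i > 1) delta <- dZ %*% t(l$W)
  }
  grads
}

#' Train a fitness neural network
#'
#' Minimizes mean squared error with Adam on minibatches, with early
#' stopping on the validation loss: training stops when the validation
#' loss has not improved for `patience` epochs, and the best-validation
#' weights are restored. Dropout is applied during training (and kept
#' available for Monte Carlo prediction); validation loss is computed
#' deterministically. The response is standardized internally; losses
#' are reported on the original log10-fluorescence scale.
#'
#' @param ds A split (optionally filtered) `onehot_dataset`.
#' @param arch A [fitnet_arch] preset.
#' @param max_epochs Maximum training epochs (default 30).
#' @param patience Early-stopping patience in epochs (default 10).
#' @param lr Adam learning rate (default 1e-3).
#' @param batch_size Minibatch size (default 64).
#' @param seed RNG seed (initialization, shuffling, dropout).
#' @return Object of class `fitnet`: trained `layers`, `arch`,
#'   `col_info`, `wildtype`, scaling, and a per-epoch `history` tibble.
#' @export
train_fitnet <- function(ds, arch = arch_linear(), max_epochs = 30,
                         patience = 10, lr = 1e-3, batch_size = 64,
                         seed = 1) {
  set.seed(seed)
  split <- ds$split %||% factor(rep("train", nrow(ds$X)))
  tr <- split == "train"
  va <- split == "validation"
  if (!any(tr)) stop("no training genotypes")
  X_tr <- ds$X[tr, , drop = FALSE]
  y_mean <- mean(ds$y[tr])
  y_sd <- sd(ds$y[tr])
  if (!is.finite(y_sd) || y_sd < 1e-8) y_sd <- 1
  y_tr <- (ds$y[tr] - y_mean) / y_sd
  X_va <- ds$X[va, , drop = FALSE]
  y_va <- (ds$y[va] - y_mean) / y_sd
  monitor_val <- nrow(X_va) > 0

  layers <- init_layers(arch, ncol(X_tr))
  adam <- lapply(layers, function(l) {
    list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0)
  })
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t <- 0
  n <- nrow(X_tr)
  history <- list()
  best_loss <- Inf; best_layers <- layers; since_best <- 0
  epochs_run <- 0

  for (epoch in seq_len(max_epochs)) {
    idx <- sample.int(n)
    starts <- seq(1, n, by = batch_size)
    for (s in starts) {
      rows <- idx[s:min(s + batch_size - 1, n)]
      fw <- forward_pass(layers, X_tr[rows, , drop = FALSE],
                         dropout_active = TRUE)
      grads <- backward_pass(layers, fw$caches, y_tr[rows])
      t <- t + 1
      for (i in seq_along(layers)) {
        g <- grads[[i]]
        a <- adam[[i]]
        a$mW <- b1 * a$mW + (1 - b1) * g$W
        a$vW <- b2 * a$vW + (1 - b2) * g$W^2
        a$mb <- b1 * a$mb + (1 - b1) * g$b
        a$vb <- b2 * a$vb + (1 - b2) * g$b^2
        adam[[i]] <- a
        mW_hat <- a$mW / (1 - b1^t); vW_hat <- a$vW / (1 - b2^t)
        mb_hat <- a$mb / (1 - b1^t); vb_hat <- a$vb / (1 - b2^t)
        layers[[i]]$W <- layers[[i]]$W - lr * mW_hat / (sqrt(vW_hat) + eps)
        layers[[i]]$b <- layers[[i]]$b - lr * mb_hat / (sqrt(vb_hat) + eps)
      }
    }
    train_loss <- mean((forward_pass(layers, X_tr)$yhat - y_tr)^2)
    val_loss <- if (monitor_val) {
      mean((forward_pass(layers, X_va)$yhat - y_va)^2)
    } else train_loss
    if (!is.finite(train_loss) || !is.finite(val_loss)) {
      stop("training diverged (non-finite loss) at epoch ", epoch)
    }
    history[[epoch]] <- tibble::tibble(
      epoch = epoch,
      train_loss = train_loss * y_sd^2,
      val_loss = val_loss * y_sd^2)
    epochs_run <- epoch
    if (val_loss < best_loss - 1e-12) {
      best_loss <- val_loss
      best_layers <- layers
      since_best <- 0
    } else {
      since_best <- since_best + 1
      if (since_best >= patience) break
    }
  }

  structure(list(arch = arch, layers = best_layers,
                 col_info = ds$col_info, wildtype = ds$wildtype,
                 y_mean = y_mean, y_sd = y_sd,
                 history = dplyr::bind_rows(history),
                 epochs_trained = epochs_run,
                 best_val_loss = best_loss * y_sd^2,
                 seed = seed), class = "fitnet")
}

#' @export
print.fitnet <- function(x, ...) {
  widths <- vapply(x$arch$hidden, `[[`, numeric(1), "width")
  cat("<fitnet ", x$arch$name, "> hidden [",
      paste(widths, collapse = ", "), "], ",
      x$epochs_trained, " epochs, best val MSE ",
      signif(x$best_val_loss, 4), "\n", sep = "")
  invisible(x)
}

# Build a design matrix for arbitrary genotypes using the model's columns.
encode_for_model <- function(model, genotypes) {
  ci <- model$col_info
  wt <- strsplit(model$wildtype, "")[[1]]
  col_index <- setNames(seq_len(nrow(ci)), ci$label)
  wt_cols <- col_index[paste0(seq_along(wt), ":", wt)]
  parsed <- parse_mutations(genotypes)
  X <- matrix(0L, length(genotypes), nrow(ci),
              dimnames = list(NULL, ci$label))
  for (i in seq_along(genotypes)) {
    cols <- wt_cols
    p <- parsed[[i]]
    if (nrow(p) > 0) {
      j <- col_index[paste0(p$site, ":", p$alt)]
      if (anyNA(j)) {
        stop("genotype contains a state unseen by the model: ",
             paste0(p$ref, p$site, p$alt)[is.na(j)][1])
      }
      cols[p$site] <- j
    }
    X[i, cols] <- 1L
  }
  X
}

model_matrix <- function(model, newdata) {
  if (is.matrix(newdata)) return(newdata)
  if (inherits(newdata, "onehot_dataset")) return(newdata$X)
  if (is.character(newdata)) return(encode_for_model(model, newdata))
  stop("newdata must be a matrix, onehot_dataset or genotype strings")
}

#' Deterministic predictions from a fitness network
#'
#' @param object A `fitnet`.
#' @param newdata Design matrix, `onehot_dataset`, or character vector of
#'   mutation-set genotypes.
#' @param ... Unused.
#' @return Numeric vector of predicted log10 fluorescence.
#' @export
predict.fitnet <- function(object, newdata, ...) {
  X <- model_matrix(object, newdata)
  object$y_mean + object$y_sd * forward_pass(object$layers, X)$yhat
}

#' Monte Carlo dropout predictions
#'
#' Runs `n_samples` stochastic forward passes with the dropout masks
#' active and summarizes each genotype by the median and standard
#' deviation of its predictions. For an architecture without dropout all
#' passes are identical and the SD is zero.
#'
#' @param model A `fitnet`.
#' @param newdata As in [predict.fitnet()].
#' @param n_samples Number of passes (default 20).
#' @param seed Optional RNG seed for reproducible masks.
#' @return Tibble `median`, `sd` (one row per genotype).
#' @export
predict_mc <- function(model, newdata, n_samples = 20, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- model_matrix(model, newdata)
  draws <- vapply(seq_len(n_samples), function(i) {
    model$y_mean + model$y_sd *
      forward_pass(model$layers, X, dropout_active = TRUE)$yhat
  }, numeric(nrow(X)))
  if (nrow(X) == 1) draws <- matrix(draws, nrow = 1)
  tibble::tibble(
    median = apply(draws, 1, median),
    sd = apply(draws, 1, sd))
}

#' Coefficient of determination on a labeled split
#'
#' `1 - SS_res / SS_tot` between known and predicted fluorescence.
#' Models with dropout layers are scored on the median of `n_samples`
#' Monte Carlo passes; deterministic models on a single pass.
#'
#' @param model A `fitnet`.
#' @param ds An `onehot_dataset`.
#' @param split Which split to score (default `"validation"`).
#' @param n_samples MC passes for dropout models (default 20).
#' @param seed RNG seed for the MC passes.
#' @return R-squared (NA with a warning if the labels have no variance).
#' @export
model_r2 <- function(model, ds, split = "validation", n_samples = 20,
                     seed = 1) {
  rows <- if (is.null(ds$split)) rep(TRUE, nrow(ds$X)) else
    ds$split == split
  if (!any(rows)) stop("no genotypes in split '", split, "'")
  X <- ds$X[rows, , drop = FALSE]
  y <- ds$y[rows]
  if (var(y) == 0) {
    warning("labels have zero variance; R^2 undefined")
    return(NA_real_)
  }
  has_dropout <- any(vapply(model$arch$hidden, `[[`, numeric(1),
                            "dropout") > 0)
  pred <- if (has_dropout) {
    predict_mc(model, X, n_samples = n_samples, seed = seed)$median
  } else {
    predict(model, X)
  }
  1 - sum((y - pred)^2) / sum((y - mean(y))^2)
}

#' Random grid search over hidden-layer widths
#'
#' Samples `n_candidates` (h1, h2) width pairs from the grid
#' {1..10, 20, 50, 100, 200}, trains each for `search_epochs` epochs,
#' selects the architecture with the smallest validation MSE, and
#' retrains it for up to `final_epochs` epochs.
#'
#' @param ds A split, filtered `onehot_dataset`.
#' @param widths Width grid.
#' @param n_candidates Architectures sampled (default 8).
#' @param search_epochs Epochs per searched architecture (default 10).
#' @param final_epochs Maximum epochs for the selected model (default 30).
#' @param dropout Dropout rate (default 0.1).
#' @param lr,batch_size,patience Passed to [train_fitnet()].
#' @param seed RNG seed.
#' @return List with `model` (the retrained best `fitnet`) and `search`
#'   (tibble of candidate widths and validation losses).
#' @export
grid_search <- function(ds, widths = c(1:10, 20, 50, 100, 200),
                        n_candidates = 8, search_epochs = 10,
                        final_epochs = 30, dropout = 0.1, lr = 1e-3,
                        batch_size = 64, patience = 10, seed = 1) {
  set.seed(seed)
  grid <- expand.grid(h1 = widths, h2 = widths)
  pick <- grid[sample.int(nrow(grid), min(n_candidates, nrow(grid))), ]
  results <- purrr::map2_dfr(pick$h1, pick$h2, function(h1, h2) {
    m <- train_fitnet(ds, arch_two_layer(h1, h2, dropout),
                      max_epochs = search_epochs,
                      patience = search_epochs, lr = lr,
                      batch_size = batch_size, seed = seed)
    tibble::tibble(h1 = h1, h2 = h2, val_loss = m$best_val_loss)
  })
  best <- results[which.min(results$val_loss), ]
  model <- train_fitnet(ds, arch_two_layer(best$h1, best$h2, dropout),
                        max_epochs = final_epochs, patience = patience,
                        lr = lr, batch_size = batch_size, seed = seed)
  list(model = model, search = results)
}

#' Train the independent a-posteriori model
#'
#' A leaky-ReLU network (widths 10, 100, 1) trained and validated on its
#' own 90/10 split of the full dataset for up to 500 epochs, used only as
#' an independent filter for designed candidates. It has no dropout and
#' is deterministic at inference.
#'
#' @param ds An `onehot_dataset` (any existing split is ignored).
#' @param split_frac Train/validation fractions (default 0.9/0.1).
#' @param max_epochs Default 500.
#' @param patience Default 10.
#' @param lr,batch_size Passed to [train_fitnet()].
#' @param seed RNG seed.
#' @return A `fitnet`.
#' @export
train_posterior <- function(ds, split_frac = c(0.9, 0.1),
                            max_epochs = 500, patience = 10, lr = 1e-3,
                            batch_size = 64, seed = 1) {
  set.seed(seed)
  n <- nrow(ds$X)
  n_tr <- round(split_frac[1] * n)
  lab <- sample(rep(c("train", "validation"), c(n_tr, n - n_tr)))
  ds$split <- factor(lab, levels = c("train", "validation", "test",
                                     "excluded"))
  train_fitnet(ds, arch_posterior(), max_epochs = max_epochs,
               patience = patience, lr = lr, batch_size = batch_size,
               seed = seed)
}

#' Extract the learned potential-to-fluorescence transform
#'
#' For architectures whose first hidden layer is a single linear node
#' (the fitness potential), evaluates the rest of the network over a
#' grid of potential values, exporting the learned 1-D transform.
#'
#' @param model A `fitnet` with a width-1 first hidden layer.
#' @param n Number of grid points.
#' @param potentials Optional numeric vector whose range sets the grid
#'   (e.g. the fitness potentials of the training genotypes); by default
#'   a span around the wildtype potential sized from the weight scale.
#' @return Tibble `potential`, `fluorescence`.
#' @export
transform_curve <- function(model, n = 200, potentials = NULL) {
  if (length(model$arch$hidden) == 0 ||
      model$arch$hidden[[1]]$width != 1) {
    stop("transform_curve needs a single-linear-node first hidden layer")
  }
  wt_X <- encode_for_model(model, "")
  pots <- forward_pass(model$layers[1], wt_X)$yhat
  if (is.null(potentials)) {
    span <- 8 * median(abs(model$layers[[1]]$W)) *
      sqrt(ncol(wt_X)) + 1
    grid <- seq(pots - span, pots + span, length.out = n)
  } else {
    grid <- seq(min(potentials), max(potentials), length.out = n)
  }
  A <- matrix(grid, ncol = 1)
  for (i in seq_along(model$layers)[-1]) {
    l <- model$layers[[i]]
    A <- activate(A %*% l$W + matrix(l$b, nrow(A), length(l$b),
                                     byrow = TRUE), l$act)
  }
  tibble::tibble(potential = grid,
                 fluorescence = model$y_mean + model$y_sd * drop(A))
}

#' @exportS3Method generics::tidy
tidy.fitnet <- function(x, ...) {
  first <- x$layers[[1]]
  w <- if (ncol(first$W) == 1) drop(first$W) else NULL
  if (is.null(w)) {
    stop("tidy() reports per-mutation weights; the first layer of this ",
         "architecture is not a single node")
  }
  out <- x$col_info
  out$weight <- w * x$y_sd
  out
}

#' @exportS3Method generics::glance
glance.fitnet <- function(x, ...) {
  widths <- vapply(x$arch$hidden, `[[`, numeric(1), "width")
  tibble::tibble(architecture = x$arch$name,
                 h1 = if (length(widths) > 0) widths[1] else 0,
                 h2 = if (length(widths) > 1) widths[2] else 0,
                 epochs_trained = x$epochs_trained,
                 best_val_loss = x$best_val_loss)
}
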