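#' Rectified linear unit
#'
#' `relu(x) = x` for `x >= 0`, else 0; the activation used in all five
#' hidden layers of the classifier.
#'
#' @param x Numeric vector or matrix.
#' @return Same shape as `x`.
#' @export
#' @examples
#' relu(c(-3, 0, 2))
relu <- function(x) {
  pmax(x, 0)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Configuration of the seven-layer classifier
#'
#' The network has one input layer (width 231 for pair-similarity vectors),
#' exactly five fully connected hidden layers with ReLU activations, and an
#' output layer of two independently sigmoid-activated units trained
#' against one-hot targets with binary cross-entropy; the reported score is
#' the positive-class unit. Training is plain stochastic gradient descent
#' with momentum, inverted dropout on the hidden activations, and L2
#' parameter regularization. When `validation_fraction > 0` a stratified
#' slice is held out and training stops early once validation AUC has not
#' improved for `patience` epochs (best weights restored).
#'
#' @param hidden Integer vector of exactly 5 hidden-layer widths.
#' @param dropout Dropout ratio in \[0, 1) applied to hidden activations
#'   during training only.
#' @param learning_rate Positive SGD step size.
#' @param momentum Momentum coefficient in \[0, 1).
#' @param batch_size Mini-batch size.
#' @param l2 L2 regularization strength (>= 0).
#' @param epochs Maximum training epochs.
#' @param seed Integer seed; initialization, shuffling and dropout are all
#'   reproducible from it.
#' @param validation_fraction Fraction held out for early stopping; 0
#'   disables early stopping.
#' @param patience Early-stopping patience in epochs.
#' @param output_units 2 (one-hot two-sigmoid head, default) or 1 (single
#'   sigmoid unit).
#' @param class_weight Reweight the loss inversely to class frequency
#'   (default off).
#' @return A list of class `dnn_config`.
#' @export
dnn_config <- function(hidden = c(128, 64, 32, 16, 8), dropout = 0.2,
                       learning_rate = 0.01, momentum = 0.9,
                       batch_size = 64, l2 = 1e-4, epochs = 100,
                       seed = 1L, validation_fraction = 0.1, patience = 20,
                       output_units = 2L, class_weight = FALSE) {
  if (length(hidden) != 5L || any(hidden < 1)) {
    abort("`hidden` must give exactly 5 positive hidden-layer widths.")
  }
  stopifnot(dropout >= 0, dropout < 1, learning_rate >= 0,
            momentum >= 0, momentum < 1, batch_size >= 1, l2 >= 0,
            epochs >= 0, validation_fraction >= 0, validation_fraction < 1,
            patience >= 1, output_units %in% c(1L, 2L))
  structure(list(hidden = as.integer(hidden), dropout = dropout,
                 learning_rate = learning_rate, momentum = momentum,
                 batch_size = as.integer(batch_size), l2 = l2,
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 validation_fraction = validation_fraction,
                 patience = as.integer(patience),
                 output_units = as.integer(output_units),
                 class_weight = class_weight),
            class = "dnn_config")
}

dnn_param_count <- function(config, input_width = 231L) {
  dims <- c(input_width, config$hidden, config$output_units)
  sum(dims[-length(dims)] * dims[-1]) + sum(dims[-1])
}

init_params <- function(dims) {
  n_layer <- length(dims) - 1L
  w <- vector("list", n_layer)
  b <- vector("list", n_layer)
  for (l in seq_len(n_layer)) {
    sdev <- sqrt(2 / dims[l])               # He initialization for ReLU
    w[[l]] <- matrix(rnorm(dims[l] * dims[l + 1L], sd = sdev),
                     dims[l], dims[l + 1L])
    b[[l]] <- rep(0, dims[l + 1L])
  }
  list(w = w, b = b)
}

# Forward pass; when training, applies inverted dropout with fresh masks
# drawn from the current RNG stream and returns the intermediates needed
# for backprop.
dnn_forward <- function(params, x, dropout = 0, training = FALSE) {
  n_layer <- length(params$w)
  a <- x
  zs <- vector("list", n_layer)
  as <- vector("list", n_layer + 1L)
  masks <- vector("list", n_layer - 1L)
  as[[1L]] <- a
  for (l in seq_len(n_layer - 1L)) {
    z <- sweep(a %*% params$w[[l]], 2L, params$b[[l]], "+")
    h <- relu(z)
    if (training && dropout > 0) {
      m <- matrix(rbinom(length(h), 1L, 1 - dropout), nrow(h)) /
        (1 - dropout)
      h <- h * m
      masks[[l]] <- m
    }
    zs[[l]] <- z
    a <- h
    as[[l + 1L]] <- a
  }
  zout <- sweep(a %*% params$w[[n_layer]], 2L, params$b[[n_layer]], "+")
  p <- sigmoid(zout)
  list(p = p, zs = zs, as = as, masks = masks)
}

dnn_backward <- function(params, fw, targets, l2, sample_w = NULL) {
  n_layer <- length(params$w)
  b <- nrow(targets)
  dz <- (fw$p - targets) / b
  if (!is.null(sample_w)) dz <- dz * sample_w
  gw <- vector("list", n_layer)
  gb <- vector("list", n_layer)
  for (l in rev(seq_len(n_layer))) {
    gw[[l]] <- crossprod(fw$as[[l]], dz) + l2 * params$w[[l]]
    gb[[l]] <- colSums(dz)
    if (l > 1L) {
      da <- dz %*% t(params$w[[l]])
      if (!is.null(fw$masks[[l - 1L]])) da <- da * fw$masks[[l - 1L]]
      dz <- da * (fw$zs[[l - 1L]] > 0)
    }
  }
  list(w = gw, b = gb)
}

bce_loss <- function(p, targets, params, l2) {
  eps <- 1e-12
  ll <- -mean(rowSums(targets * log(p + eps) +
                      (1 - targets) * log(1 - p + eps)))
  ll + l2 / 2 * sum(vapply(params$w, function(w) sum(w^2), numeric(1)))
}

dnn_targets <- function(y, output_units) {
  if (output_units == 2L) cbind(positive = y, negative = 1 - y)
  else cbind(positive = y)
}

#' Train the seven-layer classifier on encoded peptides
#'
#' @param x Numeric matrix of encoded peptides (rows = items; 231 columns
#'   for pair-similarity vectors).
#' @param y Binary labels (1 = binding site), one per row; at least two
#'   items per class.
#' @param config A [dnn_config()].
#' @return An object of class `pbs_dnn`: the layer parameters plus the
#'   config and a per-epoch history tibble. Dropout is active only during
#'   training; inference through [predict_proba()] is deterministic.
#' @export
train_dnn <- function(x, y, config = dnn_config()) {
  x <- as.matrix(x)
  y <- as.integer(y)
  stopifnot(nrow(x) == length(y))
  if (any(!y %in% c(0L, 1L))) abort("`y` must be binary 0/1.")
  if (min(table(factor(y, levels = 0:1))) < 2L) {
    abort("at least two items per class are required to train.")
  }
  dims <- c(ncol(x), config$hidden, config$output_units)

  withr::with_seed(config$seed, {
    n <- nrow(x)
    val_idx <- integer(0)
    if (config$validation_fraction > 0) {
      k <- max(1L, round(config$validation_fraction * n))
      cand <- c(sample(which(y == 1L)), sample(which(y == 0L)))
      take <- unlist(lapply(split(cand, y[cand]), function(ix) {
        head(ix, max(1L, round(config$validation_fraction * length(ix))))
      }), use.names = FALSE)
      if (length(take) >= 4L && length(unique(y[take])) == 2L &&
          length(unique(y[-take])) == 2L) {
        val_idx <- take
      }
    }
    tr_idx <- setdiff(seq_len(n), val_idx)
    xt <- x[tr_idx, , drop = FALSE]
    yt <- y[tr_idx]

    params <- init_params(dims)
    vel <- lapply(params$w, function(w) w * 0)
    velb <- lapply(params$b, function(b) b * 0)
    targets <- dnn_targets(yt, config$output_units)
    sw <- NULL
    if (isTRUE(config$class_weight)) {
      tab <- table(factor(yt, levels = 0:1))
      sw <- (length(yt) / (2 * as.numeric(tab)))[yt + 1L]
    }

    history <- vector("list", config$epochs)
    best_auc <- -Inf
    best_params <- params
    best_epoch <- 0L
    stall <- 0L
    epochs_run <- 0L
    loss <- NA_real_

    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(nrow(xt))
      starts <- seq(1L, length(ord), by = config$batch_size)
      for (s in starts) {
        ix <- ord[s:min(s + config$batch_size - 1L, length(ord))]
        fw <- dnn_forward(params, xt[ix, , drop = FALSE],
                          dropout = config$dropout, training = TRUE)
        gr <- dnn_backward(params, fw, targets[ix, , drop = FALSE],
                           config$l2,
                           if (is.null(sw)) NULL else sw[ix])
        for (l in seq_along(params$w)) {
          vel[[l]] <- config$momentum * vel[[l]] -
            config$learning_rate * gr$w[[l]]
          velb[[l]] <- config$momentum * velb[[l]] -
            config$learning_rate * gr$b[[l]]
          params$w[[l]] <- params$w[[l]] + vel[[l]]
          params$b[[l]] <- params$b[[l]] + velb[[l]]
        }
      }
      epochs_run <- ep
      fw_all <- dnn_forward(params, xt)
      loss <- bce_loss(fw_all$p, targets, params, config$l2)
      val_auc <- NA_real_
      if (length(val_idx)) {
        pv <- dnn_forward(params, x[val_idx, , drop = FALSE])$p[, 1L]
        val_auc <- auc_mw(pv, y[val_idx])
        if (val_auc > best_auc + 1e-9) {
          best_auc <- val_auc
          best_params <- params
          best_epoch <- ep
          stall <- 0L
        } else {
          stall <- stall + 1L
        }
      }
      history[[ep]] <- tibble(epoch = ep, loss = loss, val_auc = val_auc)
      if (length(val_idx) && stall >= config$patience) break
    }
    if (length(val_idx) && best_epoch > 0L) params <- best_params
  })

  structure(
    list(params = params, config = config, dims = dims,
         n_train = length(tr_idx), n_validation = length(val_idx),
         epochs_run = epochs_run, final_loss = loss,
         best_val_auc = if (length(val_idx)) best_auc else NA_real_,
         history = bind_rows(history), parent = NULL),
    class = "pbs_dnn")
}

#' Predict binding probabilities
#'
#' Deterministic forward pass (dropout disabled); the score is the sigmoid
#' output of the positive-class unit, a probability in (0, 1).
#'
#' @param model A `pbs_dnn` from [train_dnn()] or [fine_tune()].
#' @param x Encoded peptide matrix (or a single vector) whose width matches
#'   the model input.
#' @return Numeric vector of probabilities, one per row of `x`.
#' @export
predict_proba <- function(model, x) {
  stopifnot(inherits(model, "pbs_dnn"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  if (ncol(x) != model$dims[1L]) {
    abort(sprintf("input width %d does not match model input width %d.",
                  ncol(x), model$dims[1L]))
  }
  dnn_forward(model$params, x)$p[, 1L]
}

#' Fine-tune a trained classifier on a child benchmark
#'
#' Transfer learning across the domain hierarchy: the child model starts
#' from the parent's parameters and continues SGD on the child data at a
#' reduced learning rate. With `epochs = 0` no update is made and the
#' returned model predicts identically to the parent.
#'
#' @param parent A trained `pbs_dnn`.
#' @param x,y Child training data (same input width as the parent).
#' @param epochs Fine-tuning epochs (default 50).
#' @param learning_rate Defaults to a tenth of the parent's rate.
#' @param ... Further [dnn_config()] fields to override (e.g. `seed`,
#'   `dropout`).
#' @return A `pbs_dnn` whose `parent` field references the parent model,
#'   so a cluster model fine-tuned from a family model fine-tuned from a
#'   group model carries its full ancestor chain.
#' @export
fine_tune <- function(parent, x, y, epochs = 50, learning_rate = NULL,
                      ...) {
  stopifnot(inherits(parent, "pbs_dnn"))
  x <- as.matrix(x)
  if (ncol(x) != parent$dims[1L]) {
    abort("child input width does not match the parent model.")
  }
  overrides <- list(...)
  cfg <- parent$config
  cfg$epochs <- as.integer(epochs)
  cfg$learning_rate <- learning_rate %||% (cfg$learning_rate / 10)
  for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
  cfg <- do.call(dnn_config, unclass(cfg))

  if (cfg$epochs == 0L) {
    child <- parent
    child$config <- cfg
    child$parent <- parent
    child$epochs_run <- 0L
    child$history <- tibble(epoch = integer(), loss = double(),
                            val_auc = double())
    return(child)
  }

  y <- as.integer(y)
  child <- withr::with_seed(cfg$seed + 1000L, {
    warm <- train_dnn_from(parent$params, x, y, cfg)
    warm
  })
  child$parent <- parent
  child
}

# Continue SGD from given parameters (no re-initialization); shares the
# training loop with train_dnn via a temporary seed-stable path.
train_dnn_from <- function(start_params, x, y, config) {
  if (min(table(factor(y, levels = 0:1))) < 2L) {
    abort("at least two items per class are required to train.")
  }
  dims <- c(ncol(x), config$hidden, config$output_units)
  params <- start_params
  vel <- lapply(params$w, function(w) w * 0)
  velb <- lapply(params$b, function(b) b * 0)
  targets <- dnn_targets(y, config$output_units)
  history <- vector("list", config$epochs)
  loss <- NA_real_
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(nrow(x))
    starts <- seq(1L, length(ord), by = config$batch_size)
    for (s in starts) {
      ix <- ord[s:min(s + config$batch_size - 1L, length(ord))]
      fw <- dnn_forward(params, x[ix, , drop = FALSE],
                        dropout = config$dropout, training = TRUE)
      gr <- dnn_backward(params, fw, targets[ix, , drop = FALSE],
                         config$l2)
      for (l in seq_along(params$w)) {
        vel[[l]] <- config$momentum * vel[[l]] -
          config$learning_rate * gr$w[[l]]
        velb[[l]] <- config$momentum * velb[[l]] -
          config$learning_rate * gr$b[[l]]
        params$w[[l]] <- params$w[[l]] + vel[[l]]
        params$b[[l]] <- params$b[[l]] + velb[[l]]
      }
    }
    fw_all <- dnn_forward(params, x)
    loss <- bce_loss(fw_all$p, targets, params, config$l2)
    history[[ep]] <- tibble(epoch = ep, loss = loss, val_auc = NA_real_)
  }
  structure(
    list(params = params, config = config, dims = dims, n_train = nrow(x),
         n_validation = 0L, epochs_run = config$epochs, final_loss = loss,
         best_val_auc = NA_real_, history = bind_rows(history),
         parent = NULL),
    class = "pbs_dnn")
}

#' Select a configuration by 10-fold cross-validated AUC
#'
#' Each candidate configuration is trained on every training fold and
#' scored on its held-out fold; the configuration with the highest mean
#' fold AUC wins. Ties break toward fewer parameters, then grid order.
#'
#' @param x,y Encoded training data.
#' @param grid A list of [dnn_config()] candidates.
#' @param k Folds (default 10).
#' @param seed Fold-assignment seed.
#' @return The winning `dnn_config`, with a `results` attribute holding
#'   the per-candidate mean AUCs.
#' @export
hyperparameter_search <- function(x, y, grid, k = 10, seed = 1L) {
  if (!length(grid)) abort("`grid` must contain at least one configuration.")
  x <- as.matrix(x)
  y <- as.integer(y)
  folds <- stratified_folds(y, k, seed)
  res <- purrr::imap_dfr(grid, function(cfg, i) {
    aucs <- vapply(seq_len(k), function(f) {
      tr <- folds != f
      m <- train_dnn(x[tr, , drop = FALSE], y[tr], cfg)
      auc_mw(predict_proba(m, x[!tr, , drop = FALSE]), y[!tr])
    }, numeric(1))
    tibble(config_id = i, mean_auc = mean(aucs),
           params = dnn_param_count(cfg, ncol(x)))
  })
  best <- res[order(-res$mean_auc, res$params, res$config_id), ][1L, ]
  out <- grid[[best$config_id]]
  attr(out, "results") <- res
  out
}

#' @export
print.pbs_dnn <- function(x, ...) {
  cat(sprintf(
    "<pbs_dnn> layers %s; %d parameters; %d epochs; final loss %.4f%s\n",
    paste(x$dims, collapse = "-"),
    sum(vapply(x$params$w, length, integer(1))) +
      sum(vapply(x$params$b, length, integer(1))),
    x$epochs_run, x$final_loss,
    if (!is.null(x$parent)) " (fine-tuned)" else ""))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.pbs_dnn <- function(x, ...) {
  tibble(
    input_width = x$dims[1L],
    n_parameters = sum(vapply(x$params$w, length, integer(1))) +
      sum(vapply(x$params$b, length, integer(1))),
    epochs_run = x$epochs_run,
    final_loss = x$final_loss,
    best_val_auc = x$best_val_auc,
    fine_tuned = !is.null(x$parent))
}
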