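#' Neural-network model configuration
#'
#' Training hyperparameters for the backpropagation multilayer perceptron.
#' Defaults follow the protocol used throughout the package: learning rate
#' 0.1 (0.2 is the common alternative), momentum 0.02, at most 700 training
#' epochs, tanh activation in hidden and output layers, and initial weights
#' drawn uniformly from (-1, 1) with the candidate set (out of
#' `init_trials` draws) whose overall mean is closest to zero.
#'
#' @param h1 neurons in the first hidden layer (>= 1).
#' @param h2 neurons in the optional second hidden layer (0 = absent).
#' @param eta learning rate.
#' @param momentum momentum coefficient of the generalized delta rule.
#' @param max_epochs hard epoch cap.
#' @param init_trials candidate random weight sets drawn at initialization.
#' @param patience epochs the validation RMS may exceed its running best
#'   (by more than `tol`) before training stops; best-epoch weights are
#'   restored.
#' @param tol tolerance on the validation-RMS increase.
#' @param margin interior margin of the (-1, 1) normalization; 1.0 maps the
#'   training extremes exactly to -1/+1 (tanh saturation risk at the
#'   extremes; use e.g. 0.9 to keep targets strictly interior).
#' @param seed RNG seed governing initialization and pattern order.
#' @return a `qf_ann_config`.
#' @export
ann_config <- function(h1 = 4L, h2 = 0L, eta = 0.1, momentum = 0.02,
                       max_epochs = 700L, init_trials = 20L,
                       patience = 20L, tol = 0, margin = 1.0, seed = 1L) {
  stopifnot(h1 >= 1L, h2 >= 0L, eta > 0, momentum >= 0, max_epochs >= 1L,
            init_trials >= 1L, patience >= 1L, margin > 0, margin <= 1)
  structure(list(h1 = as.integer(h1), h2 = as.integer(h2), eta = eta,
                 momentum = momentum, max_epochs = as.integer(max_epochs),
                 init_trials = as.integer(init_trials),
                 patience = as.integer(patience), tol = tol,
                 margin = margin, seed = as.integer(seed)),
            class = "qf_ann_config")
}

#' Split a dataset into training and validation sets
#'
#' The data are ordered ascending by y and every 5th point (1-based sorted
#' positions 5, 10, 15, ...) forms the validation set; the rest train the
#' weights. The validation size is floor(N/5).
#'
#' @param dataset a [qsar_dataset()] with N >= 5.
#' @return list of integer index vectors `train` and `validation` (indices
#'   into the original order).
#' @export
split_validation <- function(dataset) {
  stopifnot(inherits(dataset, "qf_dataset"))
  n <- length(dataset$y)
  if (n < 5L) stop("need N >= 5 for a non-empty validation set",
                   call. = FALSE)
  ord <- order(dataset$y)
  val_pos <- seq_len(n) %% 5L == 0L
  list(train = ord[!val_pos], validation = ord[val_pos])
}

#' Affine (-1, 1) normalization
#'
#' Maps the training minimum to `-margin` and maximum to `+margin`;
#' `denormalize()` is the exact inverse.
#'
#' @param values numeric vector.
#' @param bounds list with `min` and `max` (from training data only).
#' @param margin interior margin (see [ann_config()]).
#' @return normalized (resp. denormalized) numeric vector.
#' @export
normalize <- function(values, bounds, margin = 1.0) {
  if (bounds$max <= bounds$min) {
    stop("constant feature cannot be normalized", call. = FALSE)
  }
  margin * (2 * (values - bounds$min) / (bounds$max - bounds$min) - 1)
}

#' @rdname normalize
#' @export
denormalize <- function(values, bounds, margin = 1.0) {
  (values / margin + 1) / 2 * (bounds$max - bounds$min) + bounds$min
}

.layer_sizes <- function(n_inputs, config) {
  c(n_inputs, config$h1, if (config$h2 > 0L) config$h2, 1L)
}

#' Initialize network weights
#'
#' Draws `init_trials` candidate weight sets uniformly from (-1, 1) and
#' returns the one whose overall mean is closest to zero. Deterministic for
#' a fixed seed.
#'
#' @param topology integer vector of layer sizes, input first, e.g.
#'   `c(4, 4, 1)`.
#' @param seed RNG seed.
#' @param init_trials number of candidate draws.
#' @return list of weight matrices, each `(n_in + 1) x n_out` with the bias
#'   in the last row.
#' @export
init_weights <- function(topology, seed = 1L, init_trials = 20L) {
  stopifnot(length(topology) >= 2L, all(topology >= 1L))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  draw <- function() {
    lapply(seq_len(length(topology) - 1L), function(l) {
      matrix(stats::runif((topology[l] + 1L) * topology[l + 1L], -1, 1),
             topology[l] + 1L, topology[l + 1L])
    })
  }
  cands <- replicate(init_trials, draw(), simplify = FALSE)
  means <- vapply(cands, function(w) abs(mean(unlist(w))), 0)
  cands[[which.min(means)]]
}

#' Forward pass of an ANN model
#'
#' @param object a `qf_ann_model`.
#' @param newdata data frame or named vector supplying every input
#'   descriptor (raw, unnormalized scale).
#' @param normalized return the network output in normalized (-1, 1) space
#'   instead of log10(IC50).
#' @param ... unused.
#' @return numeric predictions.
#' @export
predict.qf_ann_model <- function(object, newdata, normalized = FALSE, ...) {
  nms <- object$inputs
  if (is.null(dim(newdata))) newdata <- as.data.frame(as.list(newdata))
  newdata <- as.data.frame(newdata)
  missing <- setdiff(nms, names(newdata))
  if (length(missing)) stop("missing input descriptor(s): ",
                            paste(missing, collapse = ", "), call. = FALSE)
  xn <- vapply(seq_along(nms), function(j) {
    normalize(newdata[[nms[j]]], object$bounds$x[[j]], object$margin)
  }, numeric(nrow(newdata)))
  xn <- matrix(xn, nrow = nrow(newdata))
  out <- cpp_ann_forward(object$weights, xn)
  if (normalized) out else denormalize(out, object$bounds$y, object$margin)
}

.ann_stats <- function(model, dataset, split) {
  pr <- function(idx) {
    pred <- predict(model, dataset$X[idx, model$inputs, drop = FALSE])
    obs <- dataset$y[idx]
    predn <- predict(model, dataset$X[idx, model$inputs, drop = FALSE],
                     normalized = TRUE)
    obsn <- normalize(obs, model$bounds$y, model$margin)
    list(r2 = stats::cor(obs, pred)^2,
         rms = sqrt(mean((predn - obsn)^2)))
  }
  tr <- pr(split$train)
  va <- pr(split$validation)
  list(R2_tr = tr$r2, RMS_tr = tr$rms, R2_val = va$r2, RMS_val = va$rms,
       R2_sum = tr$r2 + va$r2)
}

#' Train a backpropagation network on a train/validation split
#'
#' Features and target are normalized into (-1, 1) using bounds taken from
#' the training subset only. Weights are updated pattern-by-pattern with
#' the generalized delta rule (learning rate `eta`, momentum); the pattern
#' order is a seeded shuffle per epoch. Training stops at `max_epochs` or
#' when the validation RMS has exceeded its running best for `patience`
#' consecutive epochs; the weights of the best-validation epoch are
#' returned. Validation data never contribute gradient updates.
#'
#' @param dataset a [qsar_dataset()].
#' @param split a [split_validation()] result.
#' @param inputs character vector of input descriptor names.
#' @param config an [ann_config()].
#' @return list with `model` (a `qf_ann_model`) and `stats` (R2_tr, RMS_tr,
#'   R2_val, RMS_val, R2_sum; RMS in normalized units).
#' @export
ann_train <- function(dataset, split, inputs, config = ann_config()) {
  stopifnot(inherits(dataset, "qf_dataset"),
            inherits(config, "qf_ann_config"))
  missing <- setdiff(inputs, names(dataset$X))
  if (length(missing)) stop("unknown descriptor(s): ",
                            paste(missing, collapse = ", "), call. = FALSE)
  tr_idx <- split$train; va_idx <- split$validation
  xb <- lapply(inputs, function(nm) {
    v <- dataset$X[[nm]][tr_idx]
    list(min = min(v), max = max(v))
  })
  yb <- list(min = min(dataset$y[tr_idx]), max = max(dataset$y[tr_idx]))
  norm_block <- function(idx) {
    m <- vapply(seq_along(inputs), function(j) {
      normalize(dataset$X[[inputs[j]]][idx], xb[[j]], config$margin)
    }, numeric(length(idx)))
    matrix(m, nrow = length(idx))
  }
  xtr <- norm_block(tr_idx)
  ytr <- normalize(dataset$y[tr_idx], yb, config$margin)
  xva <- norm_block(va_idx)
  yva <- normalize(dataset$y[va_idx], yb, config$margin)

  topo <- .layer_sizes(length(inputs), config)
  w0 <- init_weights(topo, seed = config$seed,
                     init_trials = config$init_trials)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed + 1L)
  orders <- t(vapply(seq_len(config$max_epochs),
                     function(e) sample.int(length(tr_idx)),
                     integer(length(tr_idx))))
  fit <- cpp_ann_train(w0, xtr, ytr, xva, yva, config$eta, config$momentum,
                       config$max_epochs, config$patience, config$tol,
                       orders)
  model <- structure(list(weights = fit$weights, inputs = inputs,
                          bounds = list(x = xb, y = yb),
                          margin = config$margin, topology = topo,
                          config = config,
                          epochs_run = fit$epochs_run,
                          best_epoch = fit$best_epoch,
                          rms_val_trace = fit$rms_val,
                          rms_tr_trace = fit$rms_tr),
                     class = "qf_ann_model")
  stats <- .ann_stats(model, dataset, split)
  model$stats <- stats
  list(model = model, stats = stats)
}

#' @export
print.qf_ann_model <- function(x, ...) {
  cat(sprintf("<qf_ann_model %s: inputs %s; epochs %d (best %d)>\n",
              paste(x$topology, collapse = "-"),
              paste(x$inputs, collapse = ", "),
              x$epochs_run, x$best_epoch))
  if (!is.null(x$stats)) {
    cat(sprintf("R2_tr = %.3f (RMS_tr = %.3f), R2_val = %.3f (RMS_val = %.3f)\n",
                x$stats$R2_tr, x$stats$RMS_tr, x$stats$R2_val,
                x$stats$RMS_val))
  }
  invisible(x)
}

#' Stepwise input selection for the neural network (BeANN)
#'
#' Greedy growth of the input set: the best 1-input network by
#' R2_sum = R2_tr + R2_val is found over the pool; holding the chosen
#' inputs fixed, every remaining descriptor is tried as the (k+1)-th input
#' and the network with the highest R2_sum is kept. Every candidate is
#' trained on the same split with the same seed policy, so the selection
#' is deterministic for a fixed master seed. Candidates whose training
#' fails are skipped and logged.
#'
#' @param dataset a [qsar_dataset()].
#' @param pool character vector of candidate input descriptors (see
#'   [candidate_pool()]).
#' @param config an [ann_config()].
#' @param n_max largest input count grown to (capped at the pool size).
#' @param split optional precomputed [split_validation()] result.
#' @return list indexed by input count; each element has `model`, `stats`
#'   and `inputs`. Attribute `skipped` records failed candidates.
#' @export
beann_select <- function(dataset, pool, config = ann_config(),
                         n_max = 4L, split = split_validation(dataset)) {
  stopifnot(length(pool) >= 1L)
  n_max <- min(n_max, length(pool))
  chosen <- character()
  results <- list()
  skipped <- character()
  for (size in seq_len(n_max)) {
    best <- NULL
    for (cand in setdiff(pool, chosen)) {
      fit <- tryCatch(ann_train(dataset, split, c(chosen, cand), config),
                      error = function(e) {
                        skipped <<- c(skipped,
                                      sprintf("%s: %s", cand,
                                              conditionMessage(e)))
                        NULL
                      })
      if (is.null(fit)) next
      if (is.null(best) || fit$stats$R2_sum > best$stats$R2_sum) {
        best <- fit
        best$new_input <- cand
      }
    }
    if (is.null(best)) break
    chosen <- c(chosen, best$new_input)
    results[[size]] <- list(inputs = chosen, model = best$model,
                            stats = best$stats)
  }
  attr(results, "skipped") <- skipped
  results
}

#' Candidate descriptor pool for the network
#'
#' Union of the top-m descriptors by absolute Pearson correlation with the
#' activity and the descriptors of the linear (BMLR) models, duplicates
#' removed with stable order (correlation ranking first).
#'
#' @param dataset a [qsar_dataset()].
#' @param bmlr_descriptors character vector of descriptors from the linear
#'   models.
#' @param m number of top-correlated descriptors (default 15).
#' @return character vector of descriptor names.
#' @export
candidate_pool <- function(dataset, bmlr_descriptors = character(),
                           m = 15L) {
  stopifnot(inherits(dataset, "qf_dataset"))
  ok <- vapply(dataset$X, function(v) stats::var(v) > 0, TRUE)
  cors <- vapply(dataset$X[ok], function(v) abs(stats::cor(v, dataset$y)),
                 0)
  top <- names(sort(cors, decreasing = TRUE))[seq_len(min(m, length(cors)))]
  unique(c(top, bmlr_descriptors))
}
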