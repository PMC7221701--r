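#' QSAR datasets
#'
#' Couples compound ids, a complete descriptor block and the modeled
#' activity y = log10(IC50) with IC50 in nM.
#'
#' @param compound_ids character vector.
#' @param X data frame (or matrix) of numeric descriptor columns, no
#'   missing values.
#' @param y numeric response, finite.
#' @return a `qf_dataset`.
#' @export
qsar_dataset <- function(compound_ids, X, y) {
  X <- as.data.frame(X)
  stopifnot(length(compound_ids) == nrow(X), length(y) == nrow(X))
  if (nrow(X) < 2L) stop("need at least 2 observations", call. = FALSE)
  if (anyNA(X)) stop("descriptor block contains missing values",
                     call. = FALSE)
  if (any(!is.finite(y))) stop("y must be finite", call. = FALSE)
  structure(list(compound_ids = as.character(compound_ids), X = X,
                 y = as.numeric(y)),
            class = "qf_dataset")
}

#' @export
print.qf_dataset <- function(x, ...) {
  cat(sprintf("<qf_dataset: N = %d, %d descriptors>\n",
              length(x$y), ncol(x$X)))
  invisible(x)
}

.design <- function(dataset, descriptors) {
  missing <- setdiff(descriptors, names(dataset$X))
  if (length(missing)) {
    stop("unknown descriptor(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  as.matrix(cbind(`(Intercept)` = 1, dataset$X[descriptors]))
}

#' Ordinary least squares with the full QSAR statistics block
#'
#' Fits log10(IC50) = D0 + sum B_i D_i and reports coefficients with their
#' standard errors and t-statistics, plus R2, s2 (squared standard
#' deviation of residuals, SSres/(N-k-1)) and the Fisher criterion
#' F = (R2/k) / ((1-R2)/(N-k-1)).
#'
#' @param dataset a [qsar_dataset()].
#' @param descriptors character vector of descriptor names to include.
#' @return a `qf_linear_model`: intercept, `terms` data frame
#'   (name, coef, se, t) and `stats` list (R2, s2, F, N, k).
#' @export
fit_ols <- function(dataset, descriptors) {
  stopifnot(inherits(dataset, "qf_dataset"))
  x <- .design(dataset, descriptors)
  y <- dataset$y
  n <- nrow(x); k <- length(descriptors)
  if (n <= k + 1L) stop("need N > k + 1 observations", call. = FALSE)
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    dropped <- colnames(x)[qx$pivot[seq(qx$rank + 1L, ncol(x))]]
    stop("singular design; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  coefs <- qr.coef(qx, y)
  fitted <- drop(x %*% coefs)
  res <- y - fitted
  ssres <- sum(res^2)
  sstot <- sum((y - mean(y))^2)
  r2 <- 1 - ssres / sstot
  s2 <- ssres / (n - k - 1)
  xtx_inv <- matrix(NA_real_, ncol(x), ncol(x))
  xtx_inv[qx$pivot, qx$pivot] <- chol2inv(qr.R(qx))
  se <- sqrt(pmax(s2 * diag(xtx_inv), 0))
  tval <- ifelse(se > 0, coefs / se, Inf * sign(coefs))
  f <- if (k > 0) (r2 / k) / ((1 - r2) / (n - k - 1)) else NA_real_
  structure(list(
    intercept = unname(coefs[1]),
    terms = data.frame(name = descriptors,
                       coef = unname(coefs[-1]),
                       se = unname(se[-1]),
                       t = unname(tval[-1]),
                       stringsAsFactors = FALSE),
    intercept_se = unname(se[1]),
    intercept_t = unname(tval[1]),
    stats = list(R2 = r2, s2 = s2, F = f, N = n, k = k),
    qr = qx, fitted = fitted, residuals = res
  ), class = "qf_linear_model")
}

#' Construct a linear QSAR model from known coefficients
#'
#' Builds a `qf_linear_model` directly from an intercept and named
#' coefficients (with optional standard errors), e.g. to evaluate a
#' published regression equation without refitting it.
#'
#' @param intercept model intercept D0.
#' @param coefs named numeric vector of descriptor coefficients B_i.
#' @param se optional numeric vector of standard errors of `coefs`.
#' @param stats optional list of model statistics.
#' @return a `qf_linear_model` usable with [predict()].
#' @export
linear_model <- function(intercept, coefs = numeric(), se = NULL,
                         stats = list()) {
  if (length(coefs) && is.null(names(coefs))) {
    stop("coefs must be named by descriptor", call. = FALSE)
  }
  if (anyDuplicated(names(coefs))) stop("duplicate term names",
                                        call. = FALSE)
  if (is.null(se)) se <- rep(NA_real_, length(coefs))
  structure(list(
    intercept = intercept,
    terms = data.frame(name = names(coefs), coef = unname(coefs),
                       se = unname(se), t = unname(coefs / se),
                       stringsAsFactors = FALSE),
    stats = stats
  ), class = "qf_linear_model")
}

#' @export
print.qf_linear_model <- function(x, ...) {
  s <- x$stats
  cat(sprintf("Log(IC50) = %.3f%s\n", x$intercept,
              if (nrow(x$terms)) paste0(" + ", paste(
                sprintf("(%.3f +/- %.3f)*%s", x$terms$coef, x$terms$se,
                        x$terms$name), collapse = " + ")) else ""))
  cat(sprintf("N = %d, R2 = %.4f, s2 = %.4f, F = %.1f\n",
              s$N, s$R2, s$s2, s$F))
  invisible(x)
}

#' Predict log10(IC50) from a linear QSAR model
#'
#' @param object a `qf_linear_model`.
#' @param newdata named numeric vector, data frame or descriptor matrix
#'   supplying every model descriptor.
#' @param ... unused.
#' @return numeric predictions.
#' @export
predict.qf_linear_model <- function(object, newdata, ...) {
  nms <- object$terms$name
  if (is.null(dim(newdata))) {
    missing <- setdiff(nms, names(newdata))
    if (length(missing)) stop("missing descriptor(s): ",
                              paste(missing, collapse = ", "),
                              call. = FALSE)
    if (!length(nms)) return(object$intercept)
    return(object$intercept +
             sum(object$terms$coef * as.numeric(newdata[nms])))
  }
  newdata <- as.data.frame(newdata)
  missing <- setdiff(nms, names(newdata))
  if (length(missing)) stop("missing descriptor(s): ",
                            paste(missing, collapse = ", "), call. = FALSE)
  if (!length(nms)) return(rep(object$intercept, nrow(newdata)))
  object$intercept +
    as.vector(as.matrix(newdata[nms]) %*% object$terms$coef)
}

#' Leave-one-out cross-validated R2
#'
#' Squared Pearson correlation between observed y and leave-one-out
#' predictions, computed with the hat-matrix identity
#' e_(i) = e_i / (1 - h_ii) (algebraically identical to N explicit refits).
#'
#' @inheritParams fit_ols
#' @return R2_cv.
#' @export
loo_r2cv <- function(dataset, descriptors) {
  stopifnot(inherits(dataset, "qf_dataset"))
  n <- length(dataset$y)
  if (n <= length(descriptors) + 2L) {
    stop("need N > k + 2 observations for LOO", call. = FALSE)
  }
  fit <- fit_ols(dataset, descriptors)
  q <- qr.Q(fit$qr)
  h <- rowSums(q^2)
  loo_pred <- dataset$y - fit$residuals / (1 - h)
  stats::cor(dataset$y, loo_pred)^2
}

#' Search configuration for best multilinear regression
#'
#' @param max_terms largest model size searched.
#' @param breadth number of models carried per size in the forward search.
#' @param collinearity_cap maximum absolute pairwise Pearson correlation
#'   allowed among selected descriptors.
#' @param min_f minimum Fisher F for a model to be retained.
#' @return a `qf_selection_config` list.
#' @export
selection_config <- function(max_terms = 4L, breadth = 50L,
                             collinearity_cap = 0.8, min_f = 0) {
  stopifnot(max_terms >= 1L, breadth >= 1L,
            collinearity_cap > 0, collinearity_cap <= 1)
  structure(list(max_terms = as.integer(max_terms),
                 breadth = as.integer(breadth),
                 collinearity_cap = collinearity_cap, min_f = min_f),
            class = "qf_selection_config")
}

#' Best multilinear regression (BMLR) forward descriptor search
#'
#' Breadth-limited forward selection: all admissible descriptor pairs (pairs
#' whose absolute mutual correlation does not exceed the collinearity cap)
#' are fitted and the best `breadth` kept; each retained subset is then
#' extended one descriptor at a time, re-ranked, and pruned again, up to
#' `max_terms`. One-descriptor models are ranked directly. Models are ranked
#' by R2 with F as tie-breaker, then by descriptor-name order, which makes
#' the search deterministic for a fixed pool ordering.
#'
#' @param dataset a [qsar_dataset()]; the descriptor pool is every column
#'   of `dataset$X` unless `pool` restricts it.
#' @param config a [selection_config()].
#' @param pool optional character vector restricting the descriptor pool.
#' @return list indexed by model size; each element is a list of
#'   `qf_linear_model`s, best first, each with `stats$R2_cv` attached.
#' @export
bmlr_search <- function(dataset, config = selection_config(), pool = NULL) {
  stopifnot(inherits(dataset, "qf_dataset"))
  if (is.null(pool)) pool <- names(dataset$X)
  if (anyNA(dataset$X[pool])) {
    stop("descriptor pool contains missing values", call. = FALSE)
  }
  # drop constant descriptors up front
  keep <- vapply(dataset$X[pool], function(v) stats::var(v) > 0, TRUE)
  pool <- pool[keep]
  max_terms <- config$max_terms
  if (max_terms > length(pool)) {
    warning(sprintf("pool smaller than max_terms; searching up to %d",
                    length(pool)))
    max_terms <- length(pool)
  }
  cm <- abs(stats::cor(dataset$X[pool]))
  rank_key <- function(fit) {
    c(-fit$stats$R2, -fit$stats$F)
  }
  order_fits <- function(fits) {
    if (!length(fits)) return(fits)
    r2 <- vapply(fits, function(f) f$stats$R2, 0)
    fv <- vapply(fits, function(f) f$stats$F, 0)
    nm <- vapply(fits, function(f) paste(sort(f$terms$name),
                                         collapse = "|"), "")
    fits[order(-r2, -fv, nm)]
  }
  try_fit <- function(desc) {
    tryCatch(fit_ols(dataset, desc), error = function(e) NULL)
  }
  results <- list()

  singles <- order_fits(Filter(Negate(is.null), lapply(pool, try_fit)))
  singles <- Filter(function(f) f$stats$F >= config$min_f, singles)
  results[[1]] <- utils::head(singles, config$breadth)

  frontier <- NULL
  if (max_terms >= 2L) {
    pairs <- utils::combn(pool, 2, simplify = FALSE)
    pairs <- Filter(function(p) cm[p[1], p[2]] <= config$collinearity_cap,
                    pairs)
    fits <- order_fits(Filter(Negate(is.null), lapply(pairs, try_fit)))
    fits <- Filter(function(f) f$stats$F >= config$min_f, fits)
    frontier <- utils::head(fits, config$breadth)
    results[[2]] <- frontier
  }
  k <- 3L
  while (k <= max_terms && length(frontier)) {
    cand <- list()
    seen <- character()
    for (f in frontier) {
      chosen <- f$terms$name
      for (d in setdiff(pool, chosen)) {
        if (max(cm[d, chosen]) > config$collinearity_cap) next
        key <- paste(sort(c(chosen, d)), collapse = "|")
        if (key %in% seen) next
        seen <- c(seen, key)
        ft <- try_fit(c(chosen, d))
        if (!is.null(ft) && ft$stats$F >= config$min_f) {
          cand[[length(cand) + 1L]] <- ft
        }
      }
    }
    frontier <- utils::head(order_fits(cand), config$breadth)
    results[[k]] <- frontier
    k <- k + 1L
  }
  # attach leave-one-out R2 to the models actually reported
  lapply(results, function(fits) {
    lapply(fits, function(f) {
      f$stats$R2_cv <- tryCatch(loo_r2cv(dataset, f$terms$name),
                                error = function(e) NA_real_)
      f
    })
  })
}

#' Interleaved ABC split
#'
#' Sorts the data ascending by y and deals the sorted positions into three
#' subsets: positions 1, 4, 7, ... form A, positions 2, 5, 8, ... form B
#' and positions 3, 6, 9, ... form C (1-based).
#'
#' @param dataset a [qsar_dataset()] with N >= 3.
#' @return list of integer index vectors `A`, `B`, `C` (indices into the
#'   original data order).
#' @export
abc_split <- function(dataset) {
  stopifnot(inherits(dataset, "qf_dataset"))
  n <- length(dataset$y)
  if (n < 3L) stop("ABC split needs N >= 3", call. = FALSE)
  ord <- order(dataset$y)
  pos <- seq_len(n)
  list(A = ord[pos %% 3L == 1L],
       B = ord[pos %% 3L == 2L],
       C = ord[pos %% 3L == 0L])
}

.subset_dataset <- function(dataset, idx) {
  qsar_dataset(dataset$compound_ids[idx],
               dataset$X[idx, , drop = FALSE], dataset$y[idx])
}

#' ABC leave-many-out cross-validation
#'
#' The model with the given descriptors is refitted on each pairwise union
#' of the ABC subsets (AB, BC, CA) and used to predict the held-out third
#' (C, A, B respectively). Fold statistics are the training R2, the
#' training leave-one-out R2 and the external prediction R2 (squared
#' Pearson correlation between predicted and observed); R2_abc is the mean
#' of the three external values.
#'
#' @inheritParams fit_ols
#' @return a `qf_abc_report`: data frame `folds` with columns `train`,
#'   `held_out`, `r2_fit`, `r2_fit_cv`, `r2_pred`, plus `r2_abc`.
#' @export
abc_validate <- function(dataset, descriptors) {
  split <- abc_split(dataset)
  combos <- list(c("A", "B"), c("B", "C"), c("C", "A"))
  held <- c("C", "A", "B")
  folds <- lapply(seq_along(combos), function(i) {
    tr_idx <- c(split[[combos[[i]][1]]], split[[combos[[i]][2]]])
    te_idx <- split[[held[i]]]
    tr <- .subset_dataset(dataset, tr_idx)
    fit <- tryCatch(fit_ols(tr, descriptors), error = function(e) {
      stop(sprintf("fold (%s,%s): %s",
                   paste(combos[[i]], collapse = ""), held[i],
                   conditionMessage(e)), call. = FALSE)
    })
    pred <- predict(fit, dataset$X[te_idx, , drop = FALSE])
    data.frame(
      train = paste(combos[[i]], collapse = ""),
      held_out = held[i],
      r2_fit = fit$stats$R2,
      r2_fit_cv = tryCatch(loo_r2cv(tr, descriptors),
                           error = function(e) NA_real_),
      r2_pred = stats::cor(dataset$y[te_idx], pred)^2,
      stringsAsFactors = FALSE)
  })
  folds <- do.call(rbind, folds)
  structure(list(folds = folds, r2_abc = mean(folds$r2_pred)),
            class = "qf_abc_report")
}

#' @export
print.qf_abc_report <- function(x, ...) {
  for (i in seq_len(nrow(x$folds))) {
    cat(sprintf("(%s,%s): R2 = %.3f, R2cv = %.3f, R2pred = %.3f\n",
                x$folds$train[i], x$folds$held_out[i], x$folds$r2_fit[i],
                x$folds$r2_fit_cv[i], x$folds$r2_pred[i]))
  }
  cat(sprintf("R2_abc = %.3f\n", x$r2_abc))
  invisible(x)
}

#' X/Y/XY-scrambling randomization test
#'
#' Detects chance correlation: per trial the response (`mode = "y"`), the
#' descriptor columns (`mode = "x"`, each column permuted independently) or
#' both (`mode = "xy"`) are permuted, the model with the given descriptors
#' is refitted, and its R2 recorded. A sound model shows scrambled R2 far
#' below the unscrambled value.
#'
#' @inheritParams fit_ols
#' @param mode `"x"`, `"y"` or `"xy"`.
#' @param trials number of scrambling trials (the full protocol uses
#'   10,000).
#' @param seed RNG seed for reproducibility.
#' @return a `qf_scrambling_report`: mode, trials, seed, vector `r2`, and
#'   summaries `r2_mean` and `r2_max`.
#' @export
scramble_validate <- function(dataset, descriptors, mode = c("y", "x", "xy"),
                              trials = 10000L, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(trials >= 1L)
  n <- length(dataset$y)
  x0 <- dataset$X[descriptors]
  r2 <- numeric(trials)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  for (t in seq_len(trials)) {
    xs <- x0
    ys <- dataset$y
    if (mode %in% c("x", "xy")) {
      for (j in seq_along(xs)) xs[[j]] <- xs[[j]][sample.int(n)]
    }
    if (mode %in% c("y", "xy")) ys <- ys[sample.int(n)]
    ds <- qsar_dataset(dataset$compound_ids, xs, ys)
    r2[t] <- tryCatch(fit_ols(ds, descriptors)$stats$R2,
                      error = function(e) NA_real_)
  }
  structure(list(mode = mode, trials = as.integer(trials),
                 seed = as.integer(seed), r2 = r2,
                 r2_mean = mean(r2, na.rm = TRUE),
                 r2_max = max(r2, na.rm = TRUE)),
            class = "qf_scrambling_report")
}

#' @export
print.qf_scrambling_report <- function(x, ...) {
  cat(sprintf("%s-scrambling: %d trials, mean R2 = %.4f, max R2 = %.4f\n",
              x$mode, x$trials, x$r2_mean, x$r2_max))
  invisible(x)
}

#' Curate a raw activity table into a modeling dataset
#'
#' Applies the activity-data curation rules: IC50 must be positive (rows
#' rejected with a reason), the response is y = log10(IC50 nM), compounds
#' with MW >= 600 Da are excluded when MW is available, gross activity
#' outliers (|z| > `z_cut` on y) are excluded, and a warning is emitted
#' when the curated activity range spans fewer than 3 log units.
#'
#' @param raw data frame with columns `compound_id` and `IC50_nM`, and
#'   optionally `MW`.
#' @param z_cut z-score threshold for the outlier rule (default 3).
#' @param mw_cut molecular-weight exclusion threshold in Da (default 600).
#' @return list with `data` (data frame `compound_id`, `y`), `excluded`
#'   (data frame `compound_id`, `reason`) and `y_range`.
#' @export
curate_dataset <- function(raw, z_cut = 3, mw_cut = 600) {
  stopifnot(all(c("compound_id", "IC50_nM") %in% names(raw)))
  excluded <- data.frame(compound_id = character(), reason = character(),
                         stringsAsFactors = FALSE)
  drop <- function(ids, reason) {
    excluded <<- rbind(excluded,
                       data.frame(compound_id = as.character(ids),
                                  reason = reason,
                                  stringsAsFactors = FALSE))
  }
  bad <- is.na(raw$IC50_nM) | raw$IC50_nM <= 0
  if (any(bad)) drop(raw$compound_id[bad], "non-positive IC50")
  raw <- raw[!bad, , drop = FALSE]
  if ("MW" %in% names(raw)) {
    heavy <- !is.na(raw$MW) & raw$MW >= mw_cut
    if (any(heavy)) drop(raw$compound_id[heavy],
                         sprintf("MW >= %g Da", mw_cut))
    raw <- raw[!heavy, , drop = FALSE]
  }
  y <- log10(raw$IC50_nM)
  if (length(y) > 2L && stats::sd(y) > 0) {
    z <- (y - mean(y)) / stats::sd(y)
    out <- abs(z) > z_cut
    if (any(out)) drop(raw$compound_id[out],
                       sprintf("|z| > %g activity outlier", z_cut))
    raw <- raw[!out, , drop = FALSE]
    y <- y[!out]
  }
  rng <- if (length(y)) diff(range(y)) else NA_real_
  if (!is.na(rng) && rng < 3) {
    warning(sprintf(
      "activity range spans %.2f log units (< 3); model may be unstable",
      rng))
  }
  list(data = data.frame(compound_id = raw$compound_id, y = y,
                         stringsAsFactors = FALSE),
       excluded = excluded, y_range = rng)
}
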