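test_that("OLS recovers exact linear data and rejects singular designs", {
  X <- data.frame(x = 1:5)
  ds <- make_dataset(X, 1 + 2 * X$x)
  fit <- fit_ols(ds, "x")
  expect_equal(fit$intercept, 1.0, tolerance = 1e-10)
  expect_equal(fit$terms$coef, 2.0, tolerance = 1e-10)
  expect_equal(fit$stats$R2, 1.0, tolerance = 1e-12)
  expect_equal(fit$stats$s2, 0.0, tolerance = 1e-18)

  Xc <- data.frame(a = rnorm(10), const = rep(1, 10))
  expect_error(fit_ols(make_dataset(Xc, rnorm(10)), c("a", "const")),
               "singular|collinear")
})

test_that("OLS statistics match the reference implementation to 1e-8", {
  set.seed(101)
  for (i in 1:100) {
    n <- sample(15:40, 1); k <- sample(1:4, 1)
    X <- as.data.frame(matrix(rnorm(n * k), n, k))
    names(X) <- paste0("d", seq_len(k))
    y <- rnorm(n, sd = 2) + as.matrix(X) %*% rnorm(k)
    ds <- make_dataset(X, drop(y))
    fit <- fit_ols(ds, names(X))
    ref <- summary(stats::lm(y ~ ., data = cbind(X, y = drop(y))))
    expect_equal(c(fit$intercept, fit$terms$coef),
                 unname(ref$coefficients[, 1]), tolerance = 1e-8)
    expect_equal(c(fit$intercept_se, fit$terms$se),
                 unname(ref$coefficients[, 2]), tolerance = 1e-8)
    expect_equal(c(fit$intercept_t, fit$terms$t),
                 unname(ref$coefficients[, 3]), tolerance = 1e-8)
    expect_equal(fit$stats$R2, ref$r.squared, tolerance = 1e-10)
    expect_equal(fit$stats$F, unname(ref$fstatistic[1]), tolerance = 1e-6)
    expect_equal(fit$stats$s2, ref$sigma^2, tolerance = 1e-8)
    # internal consistency: t = B / ErrB
    expect_equal(fit$terms$t, fit$terms$coef / fit$terms$se,
                 tolerance = 1e-6)
  }
})

test_that("prediction is the linear form in the descriptors", {
  m <- linear_model(2.5, c(a = 1.5, b = -0.5))
  expect_equal(predict(m, c(a = 0, b = 0)), 2.5)
  expect_equal(predict(m, c(a = 2, b = 2)), 2.5 + 3 - 1)
  expect_error(predict(m, c(a = 1)), "missing descriptor")
  expect_equal(predict(linear_model(3.1), numeric()), 3.1)
  # linearity identity: f(a) + f(b) - D0 = f(a + b)
  set.seed(5)
  for (i in 1:20) {
    a <- c(a = rnorm(1), b = rnorm(1))
    b <- c(a = rnorm(1), b = rnorm(1))
    expect_equal(predict(m, a) + predict(m, b) - m$intercept,
                 predict(m, a + b), tolerance = 1e-12)
  }
})

test_that("hat-matrix LOO equals explicit refitting", {
  X <- data.frame(x = 1:6)
  expect_equal(loo_r2cv(make_dataset(X, 1 + 2 * X$x), "x"), 1.0,
               tolerance = 1e-9)

  set.seed(55)
  X <- as.data.frame(matrix(rnorm(30), 15, 2)); names(X) <- c("a", "b")
  y <- 0.5 + X$a - 0.7 * X$b + rnorm(15, sd = 0.4)
  ds <- make_dataset(X, y)
  loo <- loo_r2cv(ds, c("a", "b"))
  preds <- vapply(1:15, function(i) {
    f <- stats::lm(y[-i] ~ a + b, data = X[-i, ])
    unname(stats::predict(f, X[i, ]))
  }, 0)
  expect_equal(loo, stats::cor(y, preds)^2, tolerance = 1e-10)

  # pure noise: LOO R2 stays near zero
  set.seed(77)
  Xn <- data.frame(d = rnorm(50))
  expect_lt(loo_r2cv(make_dataset(Xn, rnorm(50)), "d"), 0.15)
})

test_that("forward search matches exhaustive best-subset on small pools", {
  set.seed(202)
  n <- 60; p <- 10
  X <- as.data.frame(matrix(rnorm(n * p), n, p))
  names(X) <- sprintf("d%02d", 1:p)
  y <- 3 * X$d01 - 2 * X$d07 + rnorm(n, sd = 0.1)
  ds <- make_dataset(X, y)

  res <- bmlr_search(ds, selection_config(max_terms = 2))
  expect_setequal(res[[2]][[1]]$terms$name, c("d01", "d07"))

  # unbounded breadth reproduces exhaustive enumeration for k <= 3
  set.seed(203)
  y2 <- X$d02 - X$d05 + 0.5 * X$d08 + rnorm(n, sd = 0.3)
  ds2 <- make_dataset(X, y2)
  res2 <- bmlr_search(ds2, selection_config(max_terms = 3,
                                            breadth = choose(p, 2),
                                            collinearity_cap = 1))
  for (k in 1:3) {
    subsets <- utils::combn(names(X), k, simplify = FALSE)
    r2s <- vapply(subsets, function(s) fit_ols(ds2, s)$stats$R2, 0)
    best <- subsets[[which.max(r2s)]]
    expect_setequal(res2[[k]][[1]]$terms$name, best)
    expect_equal(res2[[k]][[1]]$stats$R2, max(r2s), tolerance = 1e-12)
  }
  # in-sample R2 of the best model never decreases with size
  best_r2 <- vapply(res2, function(lv) lv[[1]]$stats$R2, 0)
  expect_true(all(diff(best_r2) >= -1e-12))
})

test_that("a single perfect predictor yields R2 = 1 at size one", {
  X <- data.frame(good = rnorm(30), junk = rnorm(30))
  ds <- make_dataset(X, 2 + 4 * X$good)
  res <- bmlr_search(ds, selection_config(max_terms = 1))
  expect_equal(res[[1]][[1]]$terms$name, "good")
  expect_equal(res[[1]][[1]]$stats$R2, 1, tolerance = 1e-12)
})

test_that("search warns when the pool is smaller than max_terms", {
  X <- data.frame(a = rnorm(20), b = rnorm(20))
  ds <- make_dataset(X, rnorm(20))
  expect_warning(bmlr_search(ds, selection_config(max_terms = 4)),
                 "pool smaller")
})

test_that("ABC split deals sorted positions into interleaved thirds", {
  ds <- make_dataset(data.frame(d = rnorm(9)), sort(rnorm(9)))
  sp <- abc_split(ds)
  expect_equal(sp$A, c(1, 4, 7))
  expect_equal(sp$B, c(2, 5, 8))
  expect_equal(sp$C, c(3, 6, 9))

  for (n in c(3, 10, 17, 100)) {
    d <- make_dataset(data.frame(d = rnorm(n)), rnorm(n))
    sp <- abc_split(d)
    all_idx <- sort(c(sp$A, sp$B, sp$C))
    expect_equal(all_idx, seq_len(n))            # partition
    sizes <- lengths(sp)
    expect_lte(diff(range(sizes)), 1L)           # balanced
  }
  expect_equal(lengths(abc_split(make_dataset(data.frame(d = rnorm(10)),
                                              rnorm(10)))),
               c(A = 4L, B = 3L, C = 3L))
  expect_error(abc_split(make_dataset(data.frame(d = rnorm(2)),
                                      rnorm(2))), "N >= 3")
})

test_that("ABC validation refits each pairwise union and averages", {
  X <- data.frame(x = seq(0, 5, length.out = 12))
  exact <- make_dataset(X, 1 + 2 * X$x)
  rep <- abc_validate(exact, "x")
  expect_equal(rep$folds$r2_pred, rep(1, 3), tolerance = 1e-9)
  expect_equal(rep$r2_abc, 1, tolerance = 1e-9)
  expect_equal(rep$folds$train, c("AB", "BC", "CA"))
  expect_equal(rep$folds$held_out, c("C", "A", "B"))

  set.seed(9)
  Xr <- as.data.frame(matrix(rnorm(60), 30, 2)); names(Xr) <- c("a", "b")
  yr <- Xr$a - Xr$b + rnorm(30, sd = 0.5)
  ds <- make_dataset(Xr, yr)
  rep2 <- abc_validate(ds, c("a", "b"))
  sp <- abc_split(ds)
  manual <- function(tr, te) {
    f <- stats::lm(y ~ a + b, data = cbind(Xr[tr, ], y = yr[tr]))
    stats::cor(yr[te], stats::predict(f, Xr[te, ]))^2
  }
  expect_equal(rep2$folds$r2_pred[1], manual(c(sp$A, sp$B), sp$C),
               tolerance = 1e-10)
  expect_equal(rep2$folds$r2_pred[2], manual(c(sp$B, sp$C), sp$A),
               tolerance = 1e-10)
  expect_equal(rep2$folds$r2_pred[3], manual(c(sp$C, sp$A), sp$B),
               tolerance = 1e-10)
  expect_equal(rep2$r2_abc, mean(rep2$folds$r2_pred))
})

test_that("scrambling is reproducible and matches the null expectation", {
  gen <- gen_linear_dataset(synthetic_spec(n = 200, seed = 8))
  ds <- gen$dataset
  r1 <- scramble_validate(ds, gen$truth$support, "y", trials = 50,
                          seed = 42)
  r2 <- scramble_validate(ds, gen$truth$support, "y", trials = 50,
                          seed = 42)
  expect_identical(r1$r2, r2$r2)
  expect_lte(r1$r2_mean, r1$r2_max)

  # E[R2] = k / (n - 1) for independent y; 500 trials, k = 4, n = 200
  null4 <- gen_null_dataset(n = 200, k = 4, seed = 12)
  sc <- scramble_validate(null4, names(null4$X), "y", trials = 500,
                          seed = 7)
  se <- stats::sd(sc$r2) / sqrt(sc$trials)
  expect_lt(abs(sc$r2_mean - 4 / 199), 3 * se)

  # xy mode also permutes descriptors but has the same null level
  sxy <- scramble_validate(null4, names(null4$X), "xy", trials = 100,
                           seed = 7)
  expect_lt(abs(sxy$r2_mean - 4 / 199),
            4 * stats::sd(sxy$r2) / sqrt(sxy$trials))
})

test_that("activity curation applies the log, range, outlier and MW rules", {
  raw <- data.frame(compound_id = paste0("c", 1:4),
                    IC50_nM = c(1, 10, 100, 1000))
  cur <- curate_dataset(raw)
  expect_equal(cur$data$y, c(0, 1, 2, 3))
  expect_equal(cur$y_range, 3)
  expect_equal(nrow(cur$excluded), 0)

  narrow <- data.frame(compound_id = paste0("c", 1:5),
                       IC50_nM = 10^seq(1, 2.5, length.out = 5))
  expect_warning(curate_dataset(narrow), "log units")

  # single extreme point among 50 is excluded by the z-rule
  set.seed(3)
  y <- stats::rnorm(49, 2, 0.5)
  wide <- data.frame(compound_id = paste0("c", 1:50),
                     IC50_nM = 10^c(y, 2 + 5 * 0.5))
  cur2 <- suppressWarnings(curate_dataset(wide))
  expect_true("c50" %in% cur2$excluded$compound_id)
  expect_match(cur2$excluded$reason[cur2$excluded$compound_id == "c50"],
               "outlier")

  bad <- data.frame(compound_id = c("a", "b", "c", "d"),
                    IC50_nM = c(-1, 0, 10, 1000),
                    MW = c(300, 300, 650, 300))
  cur3 <- suppressWarnings(curate_dataset(bad))
  expect_setequal(cur3$excluded$compound_id, c("a", "b", "c"))
  expect_equal(cur3$data$compound_id, "d")
})
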