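#' Synthetic dataset specification
#'
#' Seeded generators stand in for curated activity sets: descriptor
#' matrices with planted linear or nonlinear structure-activity signal and
#' known ground truth. Defaults mirror realistic training-set scale
#' (a few hundred compounds, activity noise 0.3 log units, a small
#' informative support inside a larger descriptor pool) so that fitted
#' models land in the statistical range typical of good QSAR equations.
#'
#' @param n number of compounds.
#' @param k_informative number of descriptors carrying signal.
#' @param k_noise number of pure-noise descriptors.
#' @param beta true coefficients (length `k_informative`).
#' @param intercept true intercept, log10 IC50 (nM).
#' @param sigma additive Gaussian noise, log units.
#' @param rho optional equicorrelation among descriptor columns.
#' @param nonlinear flag marking a nonlinear (tanh-composed) response.
#' @param seed RNG seed.
#' @return a `qf_synthetic_spec`.
#' @export
synthetic_spec <- function(n = 239L, k_informative = 3L, k_noise = 17L,
                           beta = c(0.6, -0.5, 0.45), intercept = 2.9,
                           sigma = 0.3, rho = 0, nonlinear = FALSE,
                           seed = 1L) {
  stopifnot(n > k_informative + 1L, sigma >= 0, rho >= 0, rho < 1,
            length(beta) == k_informative)
  structure(list(n = as.integer(n), k_informative = as.integer(k_informative),
                 k_noise = as.integer(k_noise), beta = beta,
                 intercept = intercept, sigma = sigma, rho = rho,
                 nonlinear = nonlinear, seed = as.integer(seed)),
            class = "qf_synthetic_spec")
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

.gen_X <- function(n, k, rho) {
  X <- matrix(stats::rnorm(n * k), n, k)
  if (rho > 0) {
    common <- stats::rnorm(n)
    X <- sqrt(1 - rho) * X + sqrt(rho) * common
  }
  colnames(X) <- sprintf("d%02d", seq_len(k))
  as.data.frame(X)
}

#' Generate a dataset with a planted linear structure-activity model
#'
#' Descriptors are standard normal (optionally equicorrelated); the
#' response is `intercept + X beta + N(0, sigma^2)` over the informative
#' columns (always the first `k_informative`). If the realized activity
#' span is below 3 log units, y (and with it the effective coefficients
#' and noise) is scaled up so the span criterion of curated activity sets
#' holds; the returned ground truth reflects the scaling.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `dataset` (a [qsar_dataset()]) and `truth`
#'   (`support`, `beta`, `intercept`, `sigma`).
#' @export
gen_linear_dataset <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "qf_synthetic_spec"))
  .with_seed(spec$seed, {
    k <- spec$k_informative + spec$k_noise
    X <- .gen_X(spec$n, k, spec$rho)
    support <- colnames(X)[seq_len(spec$k_informative)]
    signal <- spec$intercept +
      as.matrix(X[support]) %*% spec$beta
    y <- drop(signal) + stats::rnorm(spec$n, 0, spec$sigma)
    beta <- spec$beta; sigma <- spec$sigma
    span <- diff(range(y))
    if (span < 3 && span > 0) {
      s <- 3 / span
      y <- spec$intercept + (y - spec$intercept) * s
      beta <- beta * s
      sigma <- sigma * s
    }
    list(dataset = qsar_dataset(sprintf("cmp%04d", seq_len(spec$n)), X, y),
         truth = list(support = support, beta = beta,
                      intercept = spec$intercept, sigma = sigma))
  })
}

#' Generate a dataset with a planted nonlinear (tanh-composed) response
#'
#' The response is a sum of saturating tanh transforms of the informative
#' descriptors plus Gaussian noise, a surface a single-descriptor linear
#' probe cannot explain well but a small tanh network can.
#'
#' @param spec a [synthetic_spec()] with `nonlinear = TRUE`; the first two
#'   informative descriptors are used.
#' @return list with `dataset` and `truth` (`support`, `form`, `sigma`).
#' @export
gen_nonlinear_dataset <- function(spec = synthetic_spec(
                                    n = 250L, k_informative = 2L,
                                    k_noise = 4L, beta = c(1.2, 0.9),
                                    sigma = 0.2, nonlinear = TRUE)) {
  stopifnot(inherits(spec, "qf_synthetic_spec"), isTRUE(spec$nonlinear),
            spec$k_informative >= 2L)
  .with_seed(spec$seed, {
    k <- spec$k_informative + spec$k_noise
    X <- .gen_X(spec$n, k, spec$rho)
    support <- colnames(X)[1:2]
    b <- spec$beta
    f <- function(d1, d2) {
      spec$intercept + b[1] * tanh(1.4 * d1 - 0.4) +
        b[2] * tanh(1.6 * d2 + 0.3)
    }
    y <- f(X[[support[1]]], X[[support[2]]]) +
      stats::rnorm(spec$n, 0, spec$sigma)
    list(dataset = qsar_dataset(sprintf("cmp%04d", seq_len(spec$n)), X, y),
         truth = list(support = support, form = f, sigma = spec$sigma))
  })
}

#' Generate a null dataset (response independent of all descriptors)
#'
#' @param n compounds; `k` descriptors; `seed` RNG seed.
#' @param k number of descriptor columns.
#' @param seed RNG seed.
#' @return a [qsar_dataset()].
#' @export
gen_null_dataset <- function(n = 100L, k = 4L, seed = 1L) {
  stopifnot(n > k + 2L)
  .with_seed(seed, {
    X <- .gen_X(n, k, 0)
    y <- stats::rnorm(n, 3, 0.8)
    qsar_dataset(sprintf("cmp%04d", seq_len(n)), X, y)
  })
}

#' Generate a docking table with constructive funnel ground truth
#'
#' Builds per-compound, per-target binding energies, heavy-atom counts and
#' physicochemical properties so that the number of compounds surviving
#' each screening stage (energy/LE exclusion, Lipinski >= 3/4, solubility,
#' multitarget LE >= 0.4) matches `survivors` exactly. The returned ledger
#' records the intended pass/fail per rule, so downstream stages can be
#' verified against construction rather than re-derived.
#'
#' @param n number of compounds.
#' @param targets character vector of target names.
#' @param survivors stage survivor counts `c(energy, lipinski, solubility,
#'   multitarget)`, non-increasing and at most `n`; fractions of `n` are
#'   also accepted (all values <= 1).
#' @param seed RNG seed.
#' @return list with `docking` (compound_id, target, dG_kcal_mol, n_heavy,
#'   LE), `properties` (MW, logP, HBD, HBA, solubility_mg_ml) and `ledger`
#'   (intended pass flags and `selected`).
#' @export
gen_docking_table <- function(n = 100L,
                              targets = c("AChE", "BACE1", "GSK3b", "SERT"),
                              survivors = c(0.4, 0.25, 0.15, 0.10),
                              seed = 1L) {
  if (all(survivors <= 1)) survivors <- round(survivors * n)
  survivors <- as.integer(survivors)
  if (length(survivors) != 4L || any(diff(survivors) > 0L) ||
      survivors[1] > n || any(survivors < 0L)) {
    stop("survivors must be 4 non-increasing counts within n",
         call. = FALSE)
  }
  s <- survivors
  .with_seed(seed, {
    ids <- sprintf("Z%06d", seq_len(n))
    # group per compound: 4 = passes everything ... 0 = fails energy stage
    group <- c(rep(4L, s[4]), rep(3L, s[3] - s[4]), rep(2L, s[2] - s[3]),
               rep(1L, s[1] - s[2]), rep(0L, n - s[1]))
    dock <- do.call(rbind, lapply(seq_len(n), function(i) {
      nh <- sample(23:32, length(targets), replace = TRUE)
      le <- stats::runif(length(targets), 0.42, 0.55)
      if (group[i] == 3L) {
        # fail only the multitarget LE >= 0.4 rule on one target,
        # staying above the 0.35 stage-1 floor
        j <- sample(length(targets), 1)
        le[j] <- stats::runif(1, 0.36, 0.395)
      }
      dg <- -le * nh
      if (group[i] == 0L) {
        j <- sample(length(targets), 1)
        dg[j] <- stats::runif(1, -7.9, -6.0)
        le[j] <- -dg[j] / nh[j]
      }
      data.frame(compound_id = ids[i], target = targets,
                 dG_kcal_mol = dg, n_heavy = nh, LE = le,
                 stringsAsFactors = FALSE)
    }))
    props <- data.frame(
      compound_id = ids,
      MW = ifelse(group >= 2L | group == 0L, stats::runif(n, 300, 480),
                  stats::runif(n, 620, 700)),
      logP = ifelse(group == 1L, stats::runif(n, 5.5, 7), stats::runif(n, 1, 4.5)),
      HBD = sample(0:3, n, replace = TRUE),
      HBA = sample(3:8, n, replace = TRUE),
      solubility_mg_ml = ifelse(group == 2L, stats::runif(n, 0.001, 0.008),
                                stats::runif(n, 0.02, 0.5)),
      stringsAsFactors = FALSE)
    # multitarget (LE >= 0.4 everywhere) holds by construction for groups
    # 1, 2 and 4; group 3 has an engineered sub-0.4 target and group 0 an
    # engineered weak binder
    ledger <- data.frame(
      compound_id = ids,
      pass_energy_le = group >= 1L,
      pass_lipinski = group != 1L,
      pass_solubility = group != 2L,
      pass_multitarget_le = !group %in% c(0L, 3L),
      selected = group == 4L,
      stringsAsFactors = FALSE)
    list(docking = dock, properties = props, ledger = ledger)
  })
}

#' Generate a library of random, valence-respecting molecules
#'
#' Random acyclic molecules over C/N/O/S/halogens rendered as SMILES, plus
#' a fixed list of canonical fixtures (methane, ethanol, propane,
#' n-pentane, n-hexane, cyclopropane) present regardless of seed. Every
#' generated SMILES re-parses to an identical graph.
#'
#' @param n number of random molecules (in addition to the fixtures).
#' @param max_atoms maximum heavy atoms per random molecule (>= 2).
#' @param seed RNG seed.
#' @return a [compound_library()]; each record stores its SMILES in
#'   `properties$smiles`.
#' @export
gen_molecule_set <- function(n = 20L, max_atoms = 12L, seed = 1L) {
  stopifnot(max_atoms >= 2L)
  fixtures <- c(methane = "C", ethanol = "CCO", propane = "CCC",
                n_pentane = "CCCCC", n_hexane = "CCCCCC",
                cyclopropane = "C1CC1")
  recs <- lapply(names(fixtures), function(nm) {
    mol <- parse_smiles(fixtures[[nm]], id = nm)
    compound_record(nm, mol, list(smiles = fixtures[[nm]]))
  })
  .with_seed(seed, {
    for (i in seq_len(n)) {
      id <- sprintf("rnd%03d", i)
      mol <- .random_tree_molecule(id, max_atoms)
      smi <- write_smiles(mol)
      recs[[length(recs) + 1L]] <- compound_record(id, mol,
                                                   list(smiles = smi))
    }
    compound_library(recs)
  })
}

# random tree with element-valence bookkeeping; single bonds only
.random_tree_molecule <- function(id, max_atoms) {
  elems_pool <- c("C", "C", "C", "C", "N", "O", "S", "F", "Cl", "Br")
  val <- c(C = 4L, N = 3L, O = 2L, S = 2L, F = 1L, Cl = 1L, Br = 1L)
  n <- sample(2:max_atoms, 1)
  elements <- character(n)
  free <- integer(n)
  elements[1] <- "C"
  free[1] <- val[["C"]]
  bonds <- data.frame(a1 = integer(), a2 = integer(), order = numeric())
  for (i in 2:n) {
    open <- which(free[seq_len(i - 1L)] > 0L)
    if (!length(open)) { n <- i - 1L; break }
    parent <- if (length(open) == 1L) open else sample(open, 1)
    el <- sample(elems_pool, 1)
    elements[i] <- el
    free[i] <- val[[el]] - 1L
    free[parent] <- free[parent] - 1L
    bonds <- rbind(bonds, data.frame(a1 = parent, a2 = i, order = 1))
  }
  new_molecule(id, elements[seq_len(n)], bonds)
}
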