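test_that("ligand efficiency is |dG| per heavy atom", {
  expect_equal(ligand_efficiency(0, 20), 0)
  expect_equal(ligand_efficiency(-10.2, 28), 10.2 / 28)
  expect_error(ligand_efficiency(-9, 0), "n_heavy")
  expect_equal(round_half_up(ligand_efficiency(-9.1, 20)), 0.46)
  expect_equal(round_half_up(0.455), 0.46)
  expect_equal(round_half_up(0.4549), 0.45)
  expect_equal(round_half_up(-0.455), -0.46)
})

test_that("Lipinski check counts violations over the four conditions", {
  r <- lipinski_pass(450, 3, 2, 5)
  expect_true(r$pass); expect_equal(r$violations, 0L)
  # one violation still passes the >= 3-of-4 rule
  r2 <- lipinski_pass(650, 3, 2, 5)
  expect_true(r2$pass); expect_equal(r2$violated, "MW")
  r3 <- lipinski_pass(650, 6, 2, 5)
  expect_false(r3$pass); expect_equal(r3$violations, 2L)
  # strict variant
  expect_false(lipinski_pass(650, 3, 2, 5, min_satisfied = 4)$pass)
  expect_error(lipinski_pass(NA, 3, 2, 5), "missing")
})

test_that("energy/LE exclusions use strict inequalities", {
  expect_false(energy_le_filter(-7.9, 0.50)$keep)
  expect_match(energy_le_filter(-7.9, 0.50)$reason, "dG")
  expect_false(energy_le_filter(-9.0, 0.34)$keep)
  expect_match(energy_le_filter(-9.0, 0.34)$reason, "LE")
  # boundary values are kept
  expect_true(energy_le_filter(-8.0, 0.35)$keep)
  expect_true(energy_le_filter(-8.5, 0.40)$keep)
})

test_that("solubility categories follow the mg/mL cutpoints", {
  expect_equal(solubility_category(c(0.005, 0.01, 0.03, 0.06, 0.10)),
               c("low", "moderate", "moderate", "moderate", "high"))
  expect_false(solubility_filter(mg_per_ml = 0.005))
  expect_true(solubility_filter(mg_per_ml = 0.03))
  expect_true(solubility_filter(mg_per_ml = 0.10))
  expect_false(solubility_filter(category = "low"))
  expect_error(solubility_filter(), "category or")
})

test_that("applicability domain widens the training box by the expansion", {
  X <- data.frame(d1 = c(0, 10), d2 = c(-5, 5))
  ad <- build_ad(X, expansion = 0.2)
  expect_equal(in_domain(c(d1 = 11.9, d2 = 0), ad)$flag, 1L)
  expect_equal(in_domain(c(d1 = 12.1, d2 = 0), ad)$flag, 0L)
  expect_equal(in_domain(c(d1 = 12.1, d2 = 0), ad)$outside, "d1")
  expect_equal(in_domain(c(d1 = 5, d2 = 0), ad)$flag, 1L)
  # one descriptor outside is enough to discard the prediction
  expect_equal(in_domain(c(d1 = 5, d2 = 8), ad)$flag, 0L)

  # expansion 0 accepts exactly the training hull
  ad0 <- build_ad(X, expansion = 0)
  expect_equal(in_domain(c(d1 = 0, d2 = -5), ad0)$flag, 1L)
  expect_equal(in_domain(c(d1 = -1e-9, d2 = 0), ad0)$flag, 0L)

  # monotone in the expansion: accepted(e1) subset of accepted(e2)
  set.seed(8)
  ad1 <- build_ad(X, 0.1); ad2 <- build_ad(X, 0.3)
  for (i in 1:200) {
    x <- c(d1 = stats::runif(1, -10, 20), d2 = stats::runif(1, -15, 15))
    if (in_domain(x, ad1)$flag == 1L) {
      expect_equal(in_domain(x, ad2)$flag, 1L)
    }
  }
  expect_error(build_ad(data.frame(a = c(1, 1))), "constant")
  expect_error(in_domain(c(other = 1), build_ad(X)), "unknown")
})

test_that("consensus prediction is the arithmetic mean", {
  expect_equal(consensus_prediction(3, 4), 3.5)
  expect_equal(consensus_prediction(2.2, 2.2), 2.2)
  set.seed(10)
  for (i in 1:100) {
    a <- stats::rnorm(1); b <- stats::rnorm(1)
    expect_equal(consensus_prediction(a, b), consensus_prediction(b, a))
  }
  expect_error(consensus_prediction(3, NA), "present")
})

test_that("multitarget selection requires LE >= 0.4 on every target", {
  mk <- function(id, le) data.frame(compound_id = id,
                                    target = c("A", "B", "C", "D"),
                                    LE = le)
  dock <- rbind(mk("ok", c(0.41, 0.40, 0.45, 0.50)),
                mk("low", c(0.41, 0.39, 0.45, 0.50)),
                mk("part", c(0.5, 0.5, 0.5, 0.5))[1:3, ])
  res <- multitarget_select(dock, targets = c("A", "B", "C", "D"))
  expect_equal(res$selected, "ok")
  expect_equal(res$skipped, "part")

  # brute-force agreement on a random table
  set.seed(12)
  ids <- sprintf("m%03d", 1:100)
  tab <- do.call(rbind, lapply(ids, function(id) {
    data.frame(compound_id = id, target = c("A", "B"),
               LE = stats::runif(2, 0.3, 0.5))
  }))
  res2 <- multitarget_select(tab, targets = c("A", "B"))
  brute <- ids[vapply(ids, function(id) {
    all(tab$LE[tab$compound_id == id] >= 0.4)
  }, TRUE)]
  expect_setequal(res2$selected, brute)

  # Lipinski gate and the all-four subset
  lip <- data.frame(compound_id = "ok", MW = 650, logP = 2, HBD = 1,
                    HBA = 4)
  res3 <- multitarget_select(mk("ok", rep(0.5, 4)), lipinski = lip)
  expect_equal(res3$selected, "ok")
  expect_length(res3$strict, 0L)  # one violation: not in the strict set
})

test_that("the screening funnel reproduces constructive ground truth", {
  gd <- gen_docking_table(n = 200, survivors = c(80, 50, 30, 15),
                          seed = 6)
  rep <- run_screen(gd$docking, gd$properties)
  led <- rep$ledger[match(gd$ledger$compound_id, rep$ledger$compound_id), ]
  expect_equal(led$pass_energy_le, gd$ledger$pass_energy_le)
  expect_equal(led$pass_lipinski, gd$ledger$pass_lipinski)
  expect_equal(led$pass_solubility, gd$ledger$pass_solubility)
  expect_equal(led$pass_multitarget_le, gd$ledger$pass_multitarget_le)
  expect_equal(led$selected, gd$ledger$selected)
  expect_equal(sum(led$pass_energy_le), 80)
  expect_equal(sum(led$pass_energy_le & led$pass_lipinski), 50)
  expect_equal(sum(led$pass_energy_le & led$pass_lipinski &
                     led$pass_solubility), 30)
  expect_length(rep$selected, 15)
})

test_that("filters are conjunctive: selection is order-invariant", {
  gd <- gen_docking_table(n = 120, survivors = c(60, 40, 25, 12),
                          seed = 16)
  rep <- run_screen(gd$docking, gd$properties)
  led <- rep$ledger
  # recompute the selection as an unordered conjunction of the rules
  conj <- led$pass_energy_le & led$pass_lipinski & led$pass_solubility &
    led$pass_multitarget_le
  expect_equal(led$selected, unname(conj))
  # every selected compound shows all mandatory rules passed
  sel <- led[led$selected, ]
  expect_true(all(sel$pass_energy_le & sel$pass_lipinski &
                    sel$pass_solubility & sel$pass_multitarget_le))
})

test_that("degenerate screening inputs are handled gracefully", {
  empty <- run_screen(data.frame(compound_id = character(),
                                 target = character(),
                                 dG_kcal_mol = numeric()))
  expect_length(empty$selected, 0L)
  expect_equal(nrow(empty$ledger), 0L)

  # a single compound failing only solubility
  dock <- data.frame(compound_id = "c1", target = c("A", "B"),
                     dG_kcal_mol = c(-10, -11), n_heavy = 24)
  props <- data.frame(compound_id = "c1", MW = 400, logP = 2, HBD = 1,
                      HBA = 4, solubility_mg_ml = 0.002)
  rep <- run_screen(dock, props)
  led <- rep$ledger
  expect_true(led$pass_energy_le)
  expect_true(led$pass_lipinski)
  expect_false(led$pass_solubility)
  expect_false(led$selected)
})

test_that("screening consumes models for AD flags and consensus", {
  set.seed(44)
  # small planted linear problem doubles as the per-target model
  X <- data.frame(d1 = stats::rnorm(40), d2 = stats::rnorm(40))
  y <- 2 + X$d1 - 0.5 * X$d2 + stats::rnorm(40, sd = 0.1)
  ds <- make_dataset(X, y)
  bm <- fit_ols(ds, c("d1", "d2"))
  sp <- split_validation(ds)
  an <- ann_train(ds, sp, c("d1", "d2"), ann_config(h1 = 2, seed = 3))
  ad <- build_ad(X)
  models <- list(T1 = list(bmlr = bm, ann = an$model, ad = ad))

  dock <- data.frame(compound_id = c("in", "out"), target = "T1",
                     dG_kcal_mol = -10, n_heavy = 22)
  props <- data.frame(compound_id = c("in", "out"), MW = 350, logP = 2,
                      HBD = 1, HBA = 3, solubility_mg_ml = 0.1)
  desc <- descriptor_matrix(data.frame(compound_id = c("in", "out"),
                                       d1 = c(0, 99), d2 = c(0, 0)))
  rep <- run_screen(dock, props, models = models, descriptors = desc)
  expect_equal(nrow(rep$predictions), 1L)
  expect_equal(rep$predictions$compound_id, "in")
  expect_equal(rep$predictions$consensus,
               (rep$predictions$bmlr_pred + rep$predictions$ann_pred) / 2)
  expect_match(rep$ledger$ad_flags[rep$ledger$compound_id == "out"],
               "T1=0")
})
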