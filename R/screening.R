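#' Ligand efficiency
#'
#' LE = |dG| / n_heavy, in kcal/mol per heavy atom. Values are reported
#' rounded half-up to 2 decimals by convention; this function returns full
#' precision (see [round_half_up()]).
#'
#' @param dG docking binding free energy in kcal/mol (negative = binding).
#' @param n_heavy heavy (non-hydrogen) atom count, >= 1.
#' @return ligand efficiency, kcal/mol per heavy atom.
#' @export
ligand_efficiency <- function(dG, n_heavy) {
  if (any(n_heavy < 1L)) stop("n_heavy must be >= 1", call. = FALSE)
  abs(dG) / n_heavy
}

#' Round half away from zero
#'
#' Display rounding used for ligand efficiencies and report tables
#' (`round()` in R rounds half to even). Rounding follows decimal
#' semantics: a tiny guard absorbs binary floating-point representation
#' error, so e.g. 9.1/20 rounds to 0.46 as its decimal value 0.455
#' demands.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Lipinski rule-of-five profile and pass check
#'
#' Violations are counted over the four conditions MW > 500 Da, logP > 5,
#' H-bond donors > 5, H-bond acceptors > 10 (acceptors = N + O count). A
#' compound passes when it satisfies at least `min_satisfied` of the four
#' conditions.
#'
#' @param MW molecular weight, Da.
#' @param logP octanol/water partition coefficient.
#' @param HBD hydrogen-bond donor count.
#' @param HBA hydrogen-bond acceptor count.
#' @param min_satisfied minimum number of satisfied conditions (default 3,
#'   the relaxed rule used for screening).
#' @return list with `pass`, `violations` (count) and `violated` (names).
#' @export
lipinski_pass <- function(MW, logP, HBD, HBA, min_satisfied = 3L) {
  vals <- c(MW = MW, logP = logP, HBD = HBD, HBA = HBA)
  if (anyNA(vals)) {
    stop("missing Lipinski propert(ies): ",
         paste(names(vals)[is.na(vals)], collapse = ", "), call. = FALSE)
  }
  violated <- c(MW = MW > 500, logP = logP > 5, HBD = HBD > 5, HBA = HBA > 10)
  nv <- sum(violated)
  list(pass = (4L - nv) >= min_satisfied, violations = nv,
       violated = names(violated)[violated])
}

#' Binding-energy / ligand-efficiency exclusion filter
#'
#' Excludes a docking record when its binding energy is greater than
#' `dG_cut` or its ligand efficiency is less than `LE_cut` (strict
#' inequalities: boundary values are kept).
#'
#' @param dG binding free energy, kcal/mol.
#' @param LE ligand efficiency, kcal/mol per heavy atom.
#' @param dG_cut energy threshold (default -8.0).
#' @param LE_cut efficiency threshold (default 0.35).
#' @return list with `keep` and `reason` (`NA` when kept).
#' @export
energy_le_filter <- function(dG, LE, dG_cut = -8.0, LE_cut = 0.35) {
  if (dG > dG_cut) {
    list(keep = FALSE, reason = sprintf("dG %.2f > %.1f kcal/mol", dG,
                                        dG_cut))
  } else if (LE < LE_cut) {
    list(keep = FALSE, reason = sprintf("LE %.3f < %.2f", LE, LE_cut))
  } else {
    list(keep = TRUE, reason = NA_character_)
  }
}

#' Solubility category
#'
#' Categorical aqueous solubility: low < 0.01 mg/mL, moderate in
#' \[0.01, 0.06\] mg/mL, high > 0.06 mg/mL. Compounds in the low category
#' are excluded from screening.
#'
#' @param mg_per_ml numeric solubility in mg/mL.
#' @return character category.
#' @export
solubility_category <- function(mg_per_ml) {
  ifelse(mg_per_ml < 0.01, "low",
         ifelse(mg_per_ml <= 0.06, "moderate", "high"))
}

#' @rdname solubility_category
#' @param category solubility category (`"low"`, `"moderate"`, `"high"`);
#'   derived from `mg_per_ml` when absent.
#' @return `solubility_filter()` returns `TRUE` (keep) or `FALSE`.
#' @export
solubility_filter <- function(category = NULL, mg_per_ml = NULL) {
  if (is.null(category)) {
    if (is.null(mg_per_ml)) {
      stop("need a solubility category or a mg/mL value", call. = FALSE)
    }
    category <- solubility_category(mg_per_ml)
  }
  stopifnot(category %in% c("low", "moderate", "high"))
  category != "low"
}

#' Applicability domain of a QSAR model
#'
#' The domain is the per-descriptor min-max box of the training data,
#' widened on each side by `expansion` times the training range. A
#' prediction is trusted (flag 1) only when every model descriptor of the
#' query lies inside its widened interval.
#'
#' @param X training descriptor block (data frame) restricted to the model
#'   descriptors; columns must be non-constant.
#' @param expansion widening fraction per side (default 0.20).
#' @return a `qf_ad`: data frame of `train_min`, `train_max`, `lo`, `hi`
#'   per descriptor, with attribute `expansion`.
#' @export
build_ad <- function(X, expansion = 0.20) {
  stopifnot(expansion >= 0)
  X <- as.data.frame(X)
  rng <- vapply(X, range, numeric(2))
  span <- rng[2, ] - rng[1, ]
  if (any(span <= 0)) {
    stop("constant training column(s): ",
         paste(colnames(rng)[span <= 0], collapse = ", "), call. = FALSE)
  }
  structure(
    data.frame(descriptor = colnames(rng),
               train_min = rng[1, ], train_max = rng[2, ],
               lo = rng[1, ] - expansion * span,
               hi = rng[2, ] + expansion * span,
               row.names = NULL, stringsAsFactors = FALSE),
    expansion = expansion, class = c("qf_ad", "data.frame"))
}

#' @rdname build_ad
#' @param x named numeric vector or one-row data frame of descriptor
#'   values.
#' @param ad a `qf_ad`.
#' @return `in_domain()` returns list with `flag` (1 inside / 0 outside)
#'   and `outside` (offending descriptor names).
#' @export
in_domain <- function(x, ad) {
  stopifnot(inherits(ad, "qf_ad"))
  if (is.data.frame(x)) x <- unlist(x[1, , drop = TRUE])
  missing <- setdiff(ad$descriptor, names(x))
  if (length(missing)) stop("unknown descriptor(s) for AD check: ",
                            paste(missing, collapse = ", "), call. = FALSE)
  v <- as.numeric(x[ad$descriptor])
  out <- is.na(v) | v < ad$lo | v > ad$hi
  list(flag = as.integer(!any(out)), outside = ad$descriptor[out])
}

#' Consensus activity prediction
#'
#' Arithmetic mean of the linear (BMLR) and neural (ANN) predictions of
#' log10(IC50), used for in-domain compounds only.
#'
#' @param bmlr_pred linear-model prediction, log10 IC50 (nM).
#' @param ann_pred network prediction, log10 IC50 (nM).
#' @return consensus log10 IC50.
#' @export
consensus_prediction <- function(bmlr_pred, ann_pred) {
  if (length(bmlr_pred) == 0L || length(ann_pred) == 0L ||
      anyNA(bmlr_pred) || anyNA(ann_pred)) {
    stop("both predictions must be present for a consensus", call. = FALSE)
  }
  (bmlr_pred + ann_pred) / 2
}

#' Multitarget candidate selection
#'
#' Selects compounds whose ligand efficiency is at least `LE_min` for
#' every requested target and whose Lipinski profile satisfies at least
#' `min_lipinski` of the four conditions. The subset additionally
#' satisfying all four conditions is reported separately. Compounds
#' missing a record for any requested target are skipped and logged.
#'
#' @param docking data frame with columns `compound_id`, `target`, `LE`.
#' @param lipinski data frame with columns `compound_id`, `MW`, `logP`,
#'   `HBD`, `HBA`, or `NULL` to skip the Lipinski condition.
#' @param targets targets every compound must cover; default all targets
#'   present in `docking`.
#' @param LE_min minimum per-target ligand efficiency (default 0.4,
#'   boundary inclusive).
#' @param min_lipinski minimum satisfied Lipinski conditions (default 3).
#' @return list with `selected` (ids), `strict` (ids also satisfying all
#'   four Lipinski conditions) and `skipped` (ids lacking a target
#'   record).
#' @export
multitarget_select <- function(docking, lipinski = NULL,
                               targets = unique(docking$target),
                               LE_min = 0.4, min_lipinski = 3L) {
  stopifnot(all(c("compound_id", "target", "LE") %in% names(docking)))
  ids <- unique(docking$compound_id)
  skipped <- character(); selected <- character(); strict <- character()
  for (id in ids) {
    rec <- docking[docking$compound_id == id & docking$target %in% targets, ]
    if (!all(targets %in% rec$target)) {
      skipped <- c(skipped, id)
      next
    }
    if (!all(rec$LE[match(targets, rec$target)] >= LE_min)) next
    nv <- 0L
    if (!is.null(lipinski)) {
      lp <- lipinski[lipinski$compound_id == id, ]
      if (!nrow(lp)) { skipped <- c(skipped, id); next }
      lr <- lipinski_pass(lp$MW[1], lp$logP[1], lp$HBD[1], lp$HBA[1],
                          min_satisfied = min_lipinski)
      if (!lr$pass) next
      nv <- lr$violations
    }
    selected <- c(selected, id)
    if (nv == 0L) strict <- c(strict, id)
  }
  list(selected = selected, strict = strict, skipped = skipped)
}

#' Run the full virtual-screening funnel
#'
#' Applies, per compound: (1) the binding-energy / ligand-efficiency
#' exclusion per target, (2) the Lipinski >= 3/4 rule, (3) the solubility
#' category exclusion, (4) the multitarget LE >= `LE_min` condition over
#' all requested targets, (5) the applicability-domain check per model and
#' (6) BMLR+ANN consensus predictions for in-domain compounds. The filters
#' are conjunctive, so the surviving set does not depend on their order;
#' the ledger retains every compound including excluded ones.
#'
#' @param docking data frame with columns `compound_id`, `target`,
#'   `dG_kcal_mol` and optionally `n_heavy` (taken from `library` when
#'   absent) and `LE` (recomputed when absent).
#' @param properties data frame keyed by `compound_id` with columns `MW`,
#'   `logP`, `HBD`, `HBA` and `solubility` (category) or
#'   `solubility_mg_ml`.
#' @param library optional [compound_library()] supplying heavy-atom
#'   counts and, when `properties` lacks them, MW/HBD/HBA.
#' @param models optional named list (by target) of lists with elements
#'   `bmlr` (`qf_linear_model`), `ann` (`qf_ann_model`) and `ad`
#'   (`qf_ad`); used for AD flags and consensus predictions.
#' @param descriptors optional `qf_descmat` with the query descriptor
#'   values used by `models` and the AD check.
#' @param config list of thresholds: `dG_cut`, `LE_cut`, `LE_min`,
#'   `min_lipinski`.
#' @return a `qf_screening_report`: `ledger` data frame (one row per
#'   compound with per-rule outcomes), `predictions` (per compound-target
#'   consensus for in-domain survivors), `selected` ids, `strict` ids and
#'   `skipped` ids.
#' @export
run_screen <- function(docking, properties = NULL, library = NULL,
                       models = NULL, descriptors = NULL,
                       config = list()) {
  cfg <- utils::modifyList(list(dG_cut = -8.0, LE_cut = 0.35, LE_min = 0.4,
                                min_lipinski = 3L), config)
  stopifnot(all(c("compound_id", "target", "dG_kcal_mol") %in%
                  names(docking)))
  if (nrow(docking) == 0L) {
    return(structure(list(ledger = data.frame(), predictions = data.frame(),
                          selected = character(), strict = character(),
                          skipped = character()),
                     class = "qf_screening_report"))
  }
  targets <- unique(docking$target)
  # heavy atom counts: explicit column, else from the library
  if (is.null(docking$n_heavy)) docking$n_heavy <- NA_integer_
  need <- is.na(docking$n_heavy)
  if (any(need)) {
    if (is.null(library)) {
      stop("docking table lacks n_heavy and no library was given",
           call. = FALSE)
    }
    docking$n_heavy[need] <- vapply(docking$compound_id[need], function(id) {
      rec <- library$records[[id]]
      if (is.null(rec)) NA_integer_ else heavy_atom_count(rec$molecule)
    }, integer(1))
  }
  unmatched <- unique(docking$compound_id[is.na(docking$n_heavy)])
  docking <- docking[!is.na(docking$n_heavy), , drop = FALSE]
  if (is.null(docking$LE)) {
    docking$LE <- ligand_efficiency(docking$dG_kcal_mol, docking$n_heavy)
  }
  ids <- unique(docking$compound_id)
  prop_row <- function(id) {
    if (!is.null(properties)) {
      r <- properties[properties$compound_id == id, , drop = FALSE]
      if (nrow(r)) return(r[1, ])
    }
    NULL
  }
  rows <- lapply(ids, function(id) {
    rec <- docking[docking$compound_id == id, , drop = FALSE]
    covered <- all(targets %in% rec$target)
    e_ok <- covered && all(vapply(seq_len(nrow(rec)), function(i) {
      energy_le_filter(rec$dG_kcal_mol[i], rec$LE[i], cfg$dG_cut,
                       cfg$LE_cut)$keep
    }, TRUE))
    pr <- prop_row(id)
    lip_ok <- NA; lip_viol <- NA_integer_
    if (!is.null(pr) && all(c("MW", "logP", "HBD", "HBA") %in% names(pr))) {
      lr <- lipinski_pass(pr$MW, pr$logP, pr$HBD, pr$HBA,
                          min_satisfied = cfg$min_lipinski)
      lip_ok <- lr$pass; lip_viol <- lr$violations
    }
    sol_ok <- NA
    if (!is.null(pr)) {
      if (!is.null(pr[["solubility"]]) && !is.na(pr[["solubility"]])) {
        sol_ok <- solubility_filter(category = pr[["solubility"]])
      } else if (!is.null(pr[["solubility_mg_ml"]]) &&
                 !is.na(pr[["solubility_mg_ml"]])) {
        sol_ok <- solubility_filter(mg_per_ml = pr[["solubility_mg_ml"]])
      }
    }
    mt_ok <- covered && all(rec$LE[match(targets, rec$target)] >= cfg$LE_min)
    data.frame(compound_id = id, covered = covered,
               pass_energy_le = e_ok,
               pass_lipinski = lip_ok, lipinski_violations = lip_viol,
               pass_solubility = sol_ok,
               pass_multitarget_le = mt_ok,
               stringsAsFactors = FALSE)
  })
  ledger <- do.call(rbind, rows)
  mandatory <- c("pass_energy_le", "pass_lipinski", "pass_solubility",
                 "pass_multitarget_le")
  pass_all <- apply(ledger[mandatory], 1, function(v) {
    all(v[!is.na(v)]) && !all(is.na(v))
  })
  ledger$selected <- pass_all & ledger$covered
  preds <- data.frame()
  ledger$ad_flags <- NA_character_
  if (!is.null(models) && !is.null(descriptors)) {
    for (i in which(ledger$selected)) {
      id <- ledger$compound_id[i]
      drow <- descriptors[descriptors$compound_id == id, , drop = FALSE]
      if (!nrow(drow)) next
      flags <- character()
      for (tg in names(models)) {
        m <- models[[tg]]
        adres <- in_domain(drow[setdiff(names(drow), "compound_id")],
                           m$ad)
        flags <- c(flags, sprintf("%s=%d", tg, adres$flag))
        if (adres$flag == 1L) {
          bp <- predict(m$bmlr, drow)
          ap <- predict(m$ann, drow)
          preds <- rbind(preds, data.frame(
            compound_id = id, target = tg, bmlr_pred = bp, ann_pred = ap,
            consensus = consensus_prediction(bp, ap),
            stringsAsFactors = FALSE))
        }
      }
      ledger$ad_flags[i] <- paste(flags, collapse = ";")
    }
  }
  strict <- ledger$compound_id[ledger$selected &
                                 !is.na(ledger$lipinski_violations) &
                                 ledger$lipinski_violations == 0L]
  structure(list(ledger = ledger, predictions = preds,
                 selected = ledger$compound_id[ledger$selected],
                 strict = strict,
                 skipped = unmatched),
            class = "qf_screening_report")
}

#' @export
print.qf_screening_report <- function(x, ...) {
  cat(sprintf("<qf_screening_report: %d compounds, %d selected>\n",
              nrow(x$ledger), length(x$selected)))
  invisible(x)
}
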