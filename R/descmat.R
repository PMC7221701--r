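#' Descriptor matrices
#'
#' A descriptor matrix is a data frame with one row per compound, a
#' `compound_id` column, and named numeric descriptor columns. Each column
#' carries a provenance tag (`"computed"` or `"external"`) in the
#' `provenance` attribute. Descriptors that are undefined for a structure
#' (e.g. kappa3 of propane) are stored as `NA`; model building requires
#' complete columns, so undefined values are never silently imputed.
#'
#' @param library a [compound_library()].
#' @param cpsa compute CPSA descriptors where 3D coordinates are present
#'   (`TRUE`), never (`FALSE`), or require them for all compounds
#'   (`"require"`).
#' @param sasa_points lattice points per atom for the SASA sampling.
#' @return a `qf_descmat` data frame.
#' @export
compute_descriptors <- function(library, cpsa = FALSE, sasa_points = 960L) {
  stopifnot(inherits(library, "qf_library"))
  rows <- lapply(library$records, function(rec) {
    .descriptor_row(rec$molecule, cpsa = cpsa, sasa_points = sasa_points)
  })
  all_names <- unique(unlist(lapply(rows, names)))
  mat <- do.call(rbind, lapply(rows, function(r) {
    out <- stats::setNames(rep(NA_real_, length(all_names)), all_names)
    out[names(r)] <- r
    out
  }))
  df <- data.frame(compound_id = library_ids(library), mat,
                   row.names = NULL, check.names = FALSE,
                   stringsAsFactors = FALSE)
  descriptor_matrix(df)
}

.descriptor_row <- function(mol, cpsa = FALSE, sasa_points = 960L) {
  safe <- function(expr) {
    tryCatch(expr, qf_descriptor_undefined = function(e) NA_real_)
  }
  out <- constitutional_descriptors(mol)
  out["balaban_J"] <- safe(balaban_index(mol))
  for (m in 1:3) {
    out[paste0("kappa", m)] <- safe(kier_shape_index(mol, m))
  }
  for (ord in 0:2) {
    for (v in c("IC", "SIC", "CIC", "BIC")) {
      out[paste0(v, ord)] <- information_content(mol, v, ord)
    }
  }
  zq <- zefirov_charges(mol)
  out["q_min_zefirov"] <- charge_extrema(zq, NULL, "min")
  out["q_max_zefirov"] <- charge_extrema(zq, NULL, "max")
  out["q_max_O_zefirov"] <- safe(charge_extrema(zq, "O", "max"))
  out["q_min_N_zefirov"] <- safe(charge_extrema(zq, "N", "min"))
  hb <- hbond_counts(mol)
  out["n_hbd"] <- hb[["donors"]]
  out["n_hba"] <- hb[["acceptors"]]
  do_cpsa <- isTRUE(cpsa) || identical(cpsa, "require")
  if (do_cpsa) {
    if (is.null(mol$coords)) {
      if (identical(cpsa, "require")) {
        stop(sprintf("compound %s has no 3D coordinates for CPSA", mol$id),
             call. = FALSE)
      }
    } else {
      s <- shrake_rupley_sasa(mol, n_points = sasa_points)
      out <- c(out, cpsa_descriptors(mol, zq, s))
    }
  }
  out
}

#' Construct / validate a descriptor matrix
#'
#' @param df data frame with a `compound_id` column and numeric descriptor
#'   columns.
#' @param provenance named character vector tagging columns as `"computed"`
#'   or `"external"`; defaults to `"computed"` for untagged columns.
#' @return a `qf_descmat`.
#' @export
descriptor_matrix <- function(df, provenance = NULL) {
  stopifnot(is.data.frame(df), "compound_id" %in% names(df))
  if (anyDuplicated(names(df))) stop("duplicate column names",
                                     call. = FALSE)
  if (anyDuplicated(df$compound_id)) stop("duplicate compound ids",
                                          call. = FALSE)
  desc_cols <- setdiff(names(df), "compound_id")
  prov <- stats::setNames(rep("computed", length(desc_cols)), desc_cols)
  if (!is.null(provenance)) {
    known <- intersect(names(provenance), desc_cols)
    prov[known] <- provenance[known]
  }
  structure(df, provenance = prov,
            class = c("qf_descmat", "data.frame"))
}

#' Names of the descriptor columns of a matrix
#' @param dm a `qf_descmat`.
#' @param complete_only keep only columns without missing values.
#' @return character vector of descriptor names.
#' @export
descriptor_names <- function(dm, complete_only = FALSE) {
  nm <- setdiff(names(dm), "compound_id")
  if (complete_only) nm <- nm[!vapply(dm[nm], anyNA, TRUE)]
  nm
}

#' Append externally computed descriptor columns
#'
#' Quantum-chemical (AM1-type) descriptors are not computed internally;
#' they are joined onto a descriptor matrix from a table keyed by compound
#' id and tagged with provenance `"external"`. Compounds missing from the
#' table receive `NA` and are reported in the `incomplete` attribute.
#'
#' @param dm a `qf_descmat`.
#' @param table data frame with a `compound_id` column and external
#'   descriptor columns, or a path to such a CSV file.
#' @return the extended `qf_descmat`; attribute `incomplete` lists
#'   compounds without external values, attribute `unmatched` lists table
#'   ids absent from the matrix.
#' @export
attach_external_descriptors <- function(dm, table) {
  stopifnot(inherits(dm, "qf_descmat"))
  if (is.character(table)) {
    table <- utils::read.csv(table, check.names = FALSE,
                             stringsAsFactors = FALSE)
  }
  stopifnot("compound_id" %in% names(table))
  new_cols <- setdiff(names(table), "compound_id")
  clash <- intersect(new_cols, names(dm))
  if (length(clash)) {
    stop("duplicate column name(s): ", paste(clash, collapse = ", "),
         call. = FALSE)
  }
  idx <- match(dm$compound_id, table$compound_id)
  unmatched <- setdiff(table$compound_id, dm$compound_id)
  prov <- attr(dm, "provenance")
  out <- as.data.frame(dm)
  for (cl in new_cols) out[[cl]] <- as.numeric(table[[cl]])[idx]
  incomplete <- dm$compound_id[is.na(idx)]
  res <- descriptor_matrix(
    out, provenance = c(prov, stats::setNames(rep("external",
                                                  length(new_cols)),
                                              new_cols)))
  attr(res, "incomplete") <- incomplete
  attr(res, "unmatched") <- unmatched
  res
}

#' Write / read a descriptor matrix as CSV with a provenance sidecar
#'
#' @param dm a `qf_descmat`.
#' @param path CSV path; the provenance tags go to `<path>.provenance.json`.
#' @return `path`, invisibly.
#' @export
write_descriptors <- function(dm, path) {
  stopifnot(inherits(dm, "qf_descmat"))
  utils::write.csv(as.data.frame(dm), path, row.names = FALSE)
  jsonlite::write_json(as.list(attr(dm, "provenance")),
                       paste0(path, ".provenance.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_descriptors
#' @export
read_descriptors <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  side <- paste0(path, ".provenance.json")
  prov <- if (file.exists(side)) {
    unlist(jsonlite::read_json(side))
  } else NULL
  descriptor_matrix(df, provenance = prov)
}
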