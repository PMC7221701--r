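#' Read an SDF (V2000) file into a compound library
#'
#' Parsing is delegated to ChemmineR; atom coordinates are attached to the
#' molecules and SDF data fields are mapped into record properties (numeric
#' where possible). Implicit hydrogens of heavy atoms are assigned by
#' standard valence rules unless hydrogens are explicit in the record.
#'
#' @param path path to an SDF file.
#' @return a [compound_library()].
#' @export
read_sdf <- function(path) {
  sset <- ChemmineR::read.SDFset(path)
  valid <- ChemmineR::validSDF(sset)
  if (!all(valid)) {
    stop("malformed SDF record(s) at index: ",
         paste(which(!valid), collapse = ", "), call. = FALSE)
  }
  records <- lapply(seq_along(sset), function(i) {
    sdf <- sset[[i]]
    hdr <- ChemmineR::header(sdf)
    id <- trimws(hdr[["Molecule_Name"]])
    if (!nzchar(id)) id <- sprintf("mol%04d", i)
    mol <- .sdf_to_molecule(sdf, id, i)
    props <- as.list(ChemmineR::datablock(sdf))
    props <- lapply(props, function(v) {
      num <- suppressWarnings(as.numeric(v))
      if (!is.na(num)) num else v
    })
    compound_record(id, mol, props)
  })
  # de-duplicate ids from sloppy files by suffixing
  ids <- vapply(records, `[[`, "", "id")
  if (anyDuplicated(ids)) {
    ids <- make.unique(ids, sep = "_")
    records <- Map(function(r, id) { r$id <- id; r$molecule$id <- id; r },
                   records, ids)
  }
  compound_library(records)
}

.sdf_to_molecule <- function(sdf, id, record_index) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_[0-9]+$", "", rownames(ab))
  coords <- unname(ab[, 1:3, drop = FALSE])
  if (is.null(dim(bb))) bb <- matrix(bb, nrow = 1)
  bonds <- if (nrow(bb)) {
    ord <- as.numeric(bb[, 3])
    aromatic <- ord == 4
    ord[aromatic] <- 1.5
    data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
               order = ord, aromatic = aromatic)
  } else {
    data.frame(a1 = integer(), a2 = integer(), order = numeric(),
               aromatic = logical())
  }
  if (nrow(bonds) &&
      (max(bonds$a1, bonds$a2) > length(elements) ||
       min(bonds$a1, bonds$a2) < 1L)) {
    stop(sprintf("SDF record %d (%s): bond table references missing atoms",
                 record_index, id), call. = FALSE)
  }
  # explicit hydrogens present => no implicit assignment on their neighbors
  has_explicit_h <- any(elements == "H")
  mol <- tryCatch(
    new_molecule(id, elements, bonds,
                 explicit_h = if (has_explicit_h) 0L else NA_integer_,
                 coords = coords),
    error = function(e) {
      stop(sprintf("SDF record %d (%s): %s", record_index, id,
                   conditionMessage(e)), call. = FALSE)
    })
  mol
}

#' Write molecules to an SDF (V2000) file
#'
#' @param x a `qf_library`, `qf_record`, `qf_molecule` or list of molecules.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(x, path) {
  mols <- if (inherits(x, "qf_library")) {
    lapply(x$records, function(r) list(mol = r$molecule, props = r$properties))
  } else if (inherits(x, "qf_record")) {
    list(list(mol = x$molecule, props = x$properties))
  } else if (inherits(x, "qf_molecule")) {
    list(list(mol = x, props = list()))
  } else {
    lapply(x, function(m) list(mol = m, props = list()))
  }
  sdfs <- lapply(mols, function(entry) {
    mol <- entry$mol
    n <- nrow(mol$atoms)
    coords <- if (!is.null(mol$coords)) mol$coords else matrix(0, n, 3)
    ab <- cbind(coords, matrix(0, n, 13))
    colnames(ab) <- paste0("C", 1:16)
    rownames(ab) <- paste(mol$atoms$element, seq_len(n), sep = "_")
    b <- mol$bonds
    nb <- nrow(b)
    bb <- if (nb) {
      ord <- ifelse(b$aromatic, 4, b$order)
      cbind(b$a1, b$a2, ord, matrix(0, nb, 4))
    } else matrix(numeric(0), 0, 7)
    colnames(bb) <- paste0("C", 1:7)
    hdr <- c(Molecule_Name = mol$id, Source = "qsarfunnel", Comment = "",
             Counts_Line = sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                                   n, nb))
    datab <- vapply(entry$props, function(v) as.character(v)[1], "")
    methods::new(methods::getClass("SDF", where = asNamespace("ChemmineR")),
                 header = hdr, atomblock = ab, bondblock = bb,
                 datablock = datab)
  })
  sset <- methods::new(methods::getClass("SDFset",
                                         where = asNamespace("ChemmineR")),
                       SDF = unname(sdfs),
                       ID = vapply(mols, function(e) e$mol$id, ""))
  ChemmineR::write.SDF(sset, path)
  invisible(path)
}
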