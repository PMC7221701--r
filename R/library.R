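#' Compound records and libraries
#'
#' A `qf_record` couples a compound id with its molecule and a named list of
#' properties (MW, logP, solubility category, external descriptor values...).
#' A `qf_library` is an ordered collection of records with unique ids.
#'
#' @param id compound identifier, unique within a library.
#' @param molecule a `qf_molecule`.
#' @param properties named list of numbers or categories.
#' @return `compound_record()` returns a `qf_record`;
#'   `compound_library()` a `qf_library`.
#' @export
compound_record <- function(id, molecule, properties = list()) {
  stopifnot(inherits(molecule, "qf_molecule"))
  if (length(properties) && anyDuplicated(names(properties))) {
    stop("duplicate property names", call. = FALSE)
  }
  structure(list(id = as.character(id), molecule = molecule,
                 properties = properties),
            class = "qf_record")
}

#' @param records list of `qf_record` objects (or `qf_molecule`s, which are
#'   wrapped with their own id).
#' @rdname compound_record
#' @export
compound_library <- function(records = list()) {
  records <- lapply(records, function(r) {
    if (inherits(r, "qf_molecule")) compound_record(r$id, r) else r
  })
  ok <- vapply(records, inherits, TRUE, "qf_record")
  if (!all(ok)) stop("all elements must be qf_record objects", call. = FALSE)
  ids <- vapply(records, `[[`, "", "id")
  if (anyDuplicated(ids)) {
    stop("duplicate compound ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  names(records) <- ids
  structure(list(records = records), class = "qf_library")
}

#' @export
length.qf_library <- function(x) length(x$records)

#' @export
`[[.qf_library` <- function(x, i) x$records[[i]]

#' @export
print.qf_library <- function(x, ...) {
  cat(sprintf("<qf_library: %d compounds>\n", length(x)))
  invisible(x)
}

#' Compound ids of a library
#' @param library a `qf_library`.
#' @return character vector of ids in iteration order.
#' @export
library_ids <- function(library) {
  stopifnot(inherits(library, "qf_library"))
  names(library$records)
}
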