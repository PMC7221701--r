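#' Parse a SMILES string into a molecular graph
#'
#' Supports the organic subset and bracket atoms, branches, ring closures
#' (including `%nn`), bond symbols `- = # :`, formal charges and bracket
#' hydrogen counts. Stereo tokens (`/ \ @`) are accepted and ignored: all
#' descriptors in this package are stereo-insensitive. Aromatic (lowercase)
#' atoms are connected by aromatic bonds, which contribute order 1.5 where a
#' numeric bond order is needed. Implicit hydrogens are assigned by standard
#' valence rules; atom order follows SMILES token order.
#'
#' @param text a single non-empty SMILES string.
#' @param id compound identifier attached to the molecule.
#' @return a [new_molecule()] object.
#' @examples
#' parse_smiles("CCO")           # ethanol: 3 heavy atoms, C2H6O
#' heavy_atom_count(parse_smiles("c1ccccc1"))  # benzene: 6
#' @export
parse_smiles <- function(text, id = text) {
  if (!is.character(text) || length(text) != 1L || !nzchar(text)) {
    stop("SMILES must be a single non-empty string", call. = FALSE)
  }
  chars <- strsplit(text, "")[[1]]
  np <- length(chars)
  perr <- function(pos, msg) {
    stop(sprintf("SMILES parse error at position %d ('%s'): %s",
                 pos, substr(text, pos, pos), msg), call. = FALSE)
  }

  atoms <- list()     # element, aromatic, charge, hcount (NA = by valence)
  bonds <- list()     # a1, a2, order (numeric; 1.5 = aromatic)
  prev <- NA_integer_ # current attachment atom
  stack <- integer()  # branch stack
  pending <- NA      # bond symbol awaiting next atom ("-","=","#",":")
  rings <- list()     # closure label -> list(atom, bond)

  add_atom <- function(element, aromatic, charge = 0L, hcount = NA_integer_,
                       pos = 0L) {
    atoms[[length(atoms) + 1L]] <<- list(element = element,
                                         aromatic = aromatic,
                                         charge = charge, hcount = hcount)
    idx <- length(atoms)
    if (!is.na(prev)) add_bond(prev, idx, pos)
    prev <<- idx
    idx
  }
  bond_order <- function(sym, i, j) {
    if (!is.na(sym)) {
      switch(sym, "-" = 1, "=" = 2, "#" = 3, ":" = 1.5)
    } else if (atoms[[i]]$aromatic && atoms[[j]]$aromatic) 1.5 else 1
  }
  add_bond <- function(i, j, pos) {
    if (i == j) perr(pos, "ring bond to self")
    bonds[[length(bonds) + 1L]] <<- list(a1 = i, a2 = j,
                                         order = bond_order(pending, i, j))
    pending <<- NA
  }

  i <- 1L
  while (i <= np) {
    ch <- chars[i]
    nxt <- if (i < np) chars[i + 1L] else ""
    if (ch %in% c("/", "\\")) { # stereo bond: treat as single
      i <- i + 1L
    } else if (ch %in% c("-", "=", "#", ":")) {
      if (!is.na(pending)) perr(i, "two consecutive bond symbols")
      pending <- ch
      i <- i + 1L
    } else if (ch == "(") {
      if (is.na(prev)) perr(i, "branch before any atom")
      stack <- c(stack, prev)
      i <- i + 1L
    } else if (ch == ")") {
      if (!length(stack)) perr(i, "unmatched ')'")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch == "[") {
      close <- NA_integer_
      for (j in seq(i + 1L, np)) if (chars[j] == "]") { close <- j; break }
      if (is.na(close)) perr(i, "unclosed bracket atom")
      spec <- substr(text, i + 1L, close - 1L)
      m <- regmatches(spec, regexec(
        "^([0-9]*)([A-Za-z][a-z]?)(@{0,2}H?[0-9]*)((?:\\+{1,}|-{1,}|[+-][0-9]+)?)$",
        spec))[[1]]
      if (length(m) == 0L || !nzchar(m[3])) perr(i, "bad bracket atom")
      sym <- m[3]
      aromatic <- sym == tolower(sym) && sym %in% c("b", "c", "n", "o", "p",
                                                    "s", "se", "as")
      element <- paste0(toupper(substr(sym, 1, 1)), substring(sym, 2))
      hpart <- sub("^@{0,2}", "", m[4])
      hcount <- if (!nzchar(hpart)) 0L
        else if (hpart == "H") 1L
        else as.integer(sub("H", "", hpart))
      cpart <- m[5]
      charge <- if (!nzchar(cpart)) 0L
        else if (grepl("^[+-][0-9]+$", cpart)) as.integer(cpart)
        else (nchar(cpart)) * (if (substr(cpart, 1, 1) == "+") 1L else -1L)
      add_atom(element, aromatic, charge, hcount, pos = i)
      i <- close + 1L
    } else if (grepl("[0-9%]", ch)) {
      if (is.na(prev)) perr(i, "ring closure before any atom")
      if (ch == "%") {
        if (i + 2L > np || !grepl("^[0-9]{2}$", substr(text, i + 1L, i + 2L)))
          perr(i, "'%' needs two digits")
        label <- substr(text, i + 1L, i + 2L)
        i <- i + 3L
      } else {
        label <- ch
        i <- i + 1L
      }
      if (!is.null(rings[[label]])) {
        open <- rings[[label]]
        sym <- if (!is.na(pending)) pending else open$bond
        hold <- pending; pending <- sym
        add_bond(open$atom, prev, i - 1L)
        rings[[label]] <- NULL
      } else {
        rings[[label]] <- list(atom = prev, bond = pending)
        pending <- NA
      }
    } else if (grepl("[A-Za-z*]", ch)) {
      two <- paste0(ch, nxt)
      if (two %in% c("Cl", "Br")) {
        add_atom(two, FALSE, pos = i); i <- i + 2L
      } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
        add_atom(ch, FALSE, pos = i); i <- i + 1L
      } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
        add_atom(toupper(ch), TRUE, pos = i); i <- i + 1L
      } else {
        perr(i, "unparsable atom token")
      }
    } else {
      perr(i, "unexpected character")
    }
  }
  if (length(stack)) {
    stop(sprintf("SMILES parse error: %d unclosed branch(es) in '%s'",
                 length(stack), text), call. = FALSE)
  }
  if (length(rings)) {
    stop(sprintf("SMILES parse error: unclosed ring closure(s) %s in '%s'",
                 paste(names(rings), collapse = ", "), text), call. = FALSE)
  }
  if (!length(atoms)) stop("SMILES contains no atoms", call. = FALSE)

  elements <- vapply(atoms, `[[`, "", "element")
  aromatic_atom <- vapply(atoms, `[[`, FALSE, "aromatic")
  charges <- vapply(atoms, `[[`, 0L, "charge")
  hcount <- vapply(atoms, `[[`, NA_integer_, "hcount")
  bdf <- if (length(bonds)) {
    data.frame(a1 = vapply(bonds, `[[`, 0L, "a1"),
               a2 = vapply(bonds, `[[`, 0L, "a2"),
               order = vapply(bonds, `[[`, 0, "order"))
  } else data.frame(a1 = integer(), a2 = integer(), order = numeric())
  bdf$aromatic <- bdf$order == 1.5
  bdf$order[bdf$aromatic] <- 1.5

  # implicit H on aromatic non-bracket atoms by the aromatic convention:
  # trivalent sigma frame for carbon, none for heteroatoms
  for (k in which(aromatic_atom & is.na(hcount))) {
    if (elements[k] == "C") {
      conn <- sum(bdf$a1 == k | bdf$a2 == k)
      hcount[k] <- max(0L, 3L - as.integer(conn))
    } else {
      hcount[k] <- 0L
    }
  }
  new_molecule(id, elements, bdf, formal_charge = charges,
               explicit_h = hcount)
}

#' Render a molecule as a (non-canonical) SMILES string
#'
#' Depth-first traversal emitting ring-closure digits; used for round-trip
#' checks and for serializing generated molecules. Aromatic bonds are written
#' with lowercase atoms where both endpoints are aromatic carbons in a cycle;
#' otherwise Kekule-style explicit orders are used.
#'
#' @param mol a `qf_molecule`.
#' @return SMILES string preserving heavy-atom count and bond multiset.
#' @export
write_smiles <- function(mol) {
  stopifnot(inherits(mol, "qf_molecule"))
  b <- mol$bonds
  n <- nrow(mol$atoms)
  adj <- lapply(seq_len(n), function(i) integer())
  if (nrow(b)) for (k in seq_len(nrow(b))) {
    adj[[b$a1[k]]] <- c(adj[[b$a1[k]]], k)
    adj[[b$a2[k]]] <- c(adj[[b$a2[k]]], k)
  }
  other <- function(k, i) if (b$a1[k] == i) b$a2[k] else b$a1[k]
  bsym <- function(k) switch(as.character(b$order[k]),
                             "1" = "", "1.5" = ":", "2" = "=", "3" = "#")
  atom_tok <- function(i) {
    el <- mol$atoms$element[i]; q <- mol$atoms$formal_charge[i]
    if (q == 0L) el
    else sprintf("[%s%s%s%s]", el,
                 if (mol$atoms$implicit_h[i] > 0) "H" else "",
                 if (mol$atoms$implicit_h[i] > 1)
                   mol$atoms$implicit_h[i] else "",
                 if (q > 0) paste(rep("+", q), collapse = "")
                 else paste(rep("-", -q), collapse = ""))
  }
  # two-pass scheme: a DFS spanning tree marks the non-tree (ring-closure)
  # bonds, whose digits are then emitted at both endpoints
  closure <- logical(nrow(b))
  seen <- rep(FALSE, n)
  parent_bond <- rep(NA_integer_, n)
  st <- list(1L)
  seen[1L] <- TRUE
  while (length(st)) {
    i <- st[[length(st)]]; st[[length(st)]] <- NULL
    for (k in adj[[i]]) {
      j <- other(k, i)
      if (!seen[j]) {
        seen[j] <- TRUE
        parent_bond[j] <- k
        st[[length(st) + 1L]] <- j
      } else if (is.na(parent_bond[i]) || parent_bond[i] != k) {
        closure[k] <- TRUE
      }
    }
  }
  closure[stats::na.omit(parent_bond)] <- FALSE
  digit_of <- integer(nrow(b))
  nd <- 0L
  for (k in which(closure)) { nd <- nd + 1L; digit_of[k] <- nd }
  dig <- function(d) if (d < 10) as.character(d) else sprintf("%%%02d", d)
  visited <- rep(FALSE, n)
  emit2 <- function(i) {
    visited[i] <<- TRUE
    out <- atom_tok(i)
    for (k in adj[[i]]) {
      if (closure[k]) out <- paste0(out, bsym(k), dig(digit_of[k]))
    }
    kids <- character()
    for (k in adj[[i]]) {
      if (closure[k]) next
      j <- other(k, i)
      if (visited[j]) next
      kids <- c(kids, paste0(bsym(k), emit2(j)))
    }
    if (length(kids) > 1L) {
      out <- paste0(out, paste0("(", kids[-length(kids)], ")",
                                collapse = ""), kids[length(kids)])
    } else if (length(kids) == 1L) out <- paste0(out, kids)
    out
  }
  if (any(!seen)) stop("cannot write SMILES of a disconnected molecule",
                       call. = FALSE)
  emit2(1L)
}

#' Read a .smi file (one SMILES plus optional id per line)
#'
#' @param path file path; lines are `SMILES [id]`, whitespace-separated.
#' @return a [compound_library()] of parsed molecules.
#' @export
read_smi <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  records <- lapply(seq_along(lines), function(i) {
    parts <- strsplit(lines[i], "[[:space:]]+")[[1]]
    id <- if (length(parts) > 1L) parts[2] else sprintf("mol%04d", i)
    compound_record(id, parse_smiles(parts[1], id = id))
  })
  compound_library(records)
}
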