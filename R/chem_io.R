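# Tripos mol2 reading/writing and the element-composition filter.
#
# The mol2 dialect in the wild (especially PDB-derived files) is messy:
# element identity is keyed off the SYBYL atom-type prefix, with a fallback
# to the atom name.  Charges are read when a column is present but are never
# required downstream (electrostatics is excluded everywhere).

.ELEMENTS <- c("H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na",
               "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Fe", "Co",
               "Ni", "Cu", "Zn", "As", "Se", "Br", "Ru", "I", "Pt", "Hg", "Du",
               "LP")

#' Allowed organic elements for dataset filtering
#'
#' The element whitelist applied to validation molecules: C, O, N, S, F, Cl,
#' Br, P and H.
#' @export
ALLOWED_ELEMENTS <- c("C", "O", "N", "S", "F", "Cl", "Br", "P", "H")

.normalize_element <- function(tok) {
  tok <- sub("\\..*$", "", tok)           # strip SYBYL subtype (e.g. C.3)
  tok <- gsub("[^A-Za-z]", "", tok)
  if (nchar(tok) == 0) return(NA_character_)
  cand2 <- if (nchar(tok) >= 2)
    paste0(toupper(substr(tok, 1, 1)), tolower(substr(tok, 2, 2))) else ""
  if (cand2 %in% .ELEMENTS) return(cand2)
  cand1 <- toupper(substr(tok, 1, 1))
  if (cand1 %in% .ELEMENTS) return(cand1)
  NA_character_
}

.element_from_fields <- function(type, name) {
  e <- .normalize_element(type)
  if (is.na(e)) e <- .normalize_element(name)
  e
}

#' Construct a molecule record
#'
#' A molecule record holds the molecular graph (elements and bonds) together
#' with one reference 3D geometry whose bond lengths and angles are treated as
#' fixed by the torsion sampler.
#'
#' @param name molecule identifier.
#' @param elements character vector of element symbols, one per atom.
#' @param coords numeric matrix (n x 3) of Cartesian coordinates in Angstrom.
#' @param bonds data.frame with integer columns \code{i}, \code{j} (1-based
#'   atom indices) and character column \code{order} (\code{"1"}, \code{"2"},
#'   \code{"3"}, \code{"am"}, \code{"ar"}, ...).
#' @param charges optional numeric vector of per-atom partial charges.
#' @return an object of class \code{mol_record} with derived
#'   \code{heavy_idx} (indices of all non-hydrogen atoms).
#' @export
mol_record <- function(name, elements, coords, bonds, charges = NULL) {
  coords <- as.matrix(coords)
  n <- length(elements)
  .assert(n >= 1, "molecule '%s': needs at least one atom", name)
  .assert(nrow(coords) == n && ncol(coords) == 3,
          "molecule '%s': coords must be %d x 3", name, n)
  .assert(all(is.finite(coords)), "molecule '%s': non-finite coordinates", name)
  if (nrow(bonds) > 0) {
    .assert(all(c(bonds$i, bonds$j) >= 1) && all(c(bonds$i, bonds$j) <= n),
            "molecule '%s': bond atom index out of range", name)
    .assert(all(bonds$i != bonds$j), "molecule '%s': self-bond", name)
  }
  structure(list(name = name,
                 elements = elements,
                 coords = unname(coords),
                 bonds = data.frame(i = as.integer(bonds$i),
                                    j = as.integer(bonds$j),
                                    order = as.character(bonds$order),
                                    stringsAsFactors = FALSE),
                 charges = charges,
                 heavy_idx = which(elements != "H")),
            class = "mol_record")
}

#' @export
print.mol_record <- function(x, ...) {
  cat(sprintf("<mol_record> %s: %d atoms (%d heavy), %d bonds\n",
              x$name, length(x$elements), length(x$heavy_idx), nrow(x$bonds)))
  invisible(x)
}

#' Read a (multi-)molecule Tripos mol2 file
#'
#' Parses every \code{@<TRIPOS>MOLECULE} block in file order.  Element
#' identity is taken from the SYBYL atom-type prefix with a fallback to the
#' atom name; a ninth ATOM column, when present, is read as the partial
#' charge.
#'
#' @param path path to a mol2 file.
#' @return a list of \code{\link{mol_record}} objects, one per MOLECULE block.
#' @export
read_mol2 <- function(path) {
  .assert(file.exists(path), "file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^\\s*@<TRIPOS>MOLECULE", lines)
  .assert(length(starts) >= 1, "no @<TRIPOS>MOLECULE block in %s", path)
  ends <- c(starts[-1] - 1, length(lines))
  records <- vector("list", length(starts))
  for (b in seq_along(starts)) {
    block <- lines[starts[b]:ends[b]]
    rec <- tryCatch(.parse_mol2_block(block),
                    error = function(e)
                      stop(sprintf("mol2 molecule block %d: %s",
                                   b, conditionMessage(e)), call. = FALSE))
    records[[b]] <- rec
  }
  records
}

.parse_mol2_block <- function(block) {
  .assert(length(block) >= 3, "truncated MOLECULE block")
  name <- trimws(block[2])
  counts <- suppressWarnings(as.integer(strsplit(trimws(block[3]), "\\s+")[[1]]))
  .assert(length(counts) >= 1 && !is.na(counts[1]), "bad counts line")
  natoms <- counts[1]
  nbonds <- if (length(counts) >= 2 && !is.na(counts[2])) counts[2] else 0L
  atom_at <- grep("^\\s*@<TRIPOS>ATOM", block)
  .assert(length(atom_at) == 1, "missing @<TRIPOS>ATOM section")
  atom_lines <- block[(atom_at + 1):(atom_at + natoms)]
  .assert(!anyNA(atom_lines), "ATOM section shorter than atom count")
  elements <- character(natoms)
  coords <- matrix(NA_real_, natoms, 3)
  charges <- rep(NA_real_, natoms)
  for (a in seq_len(natoms)) {
    f <- strsplit(trimws(atom_lines[a]), "\\s+")[[1]]
    .assert(length(f) >= 6, "ATOM line %d has fewer than 6 fields", a)
    xyz <- suppressWarnings(as.numeric(f[3:5]))
    .assert(all(is.finite(xyz)), "ATOM line %d: bad coordinates", a)
    coords[a, ] <- xyz
    e <- .element_from_fields(f[6], f[2])
    .assert(!is.na(e), "ATOM line %d: cannot determine element from '%s'/'%s'",
            a, f[6], f[2])
    elements[a] <- e
    if (length(f) >= 9) charges[a] <- suppressWarnings(as.numeric(f[9]))
  }
  if (all(is.na(charges))) charges <- NULL
  bonds <- data.frame(i = integer(0), j = integer(0), order = character(0),
                      stringsAsFactors = FALSE)
  if (nbonds > 0) {
    bond_at <- grep("^\\s*@<TRIPOS>BOND", block)
    .assert(length(bond_at) == 1, "missing @<TRIPOS>BOND section")
    bond_lines <- block[(bond_at + 1):(bond_at + nbonds)]
    .assert(!anyNA(bond_lines), "BOND section shorter than bond count")
    bi <- bj <- integer(nbonds); bo <- character(nbonds)
    for (k in seq_len(nbonds)) {
      f <- strsplit(trimws(bond_lines[k]), "\\s+")[[1]]
      .assert(length(f) >= 4, "BOND line %d has fewer than 4 fields", k)
      bi[k] <- as.integer(f[2]); bj[k] <- as.integer(f[3]); bo[k] <- f[4]
    }
    bonds <- data.frame(i = bi, j = bj, order = bo, stringsAsFactors = FALSE)
  }
  mol_record(name, elements, coords, bonds, charges)
}

#' Write molecules or a conformer ensemble to a mol2 file
#'
#' A single record, a list of records, or a \code{conf_ensemble} (all
#' conformers share one topology and are written as consecutive MOLECULE
#' blocks) can be serialized.  \code{read_mol2(write_mol2(x))} reproduces atom
#' count, element sequence, bond list and coordinates to 1e-3 Angstrom.
#'
#' @param x a \code{mol_record}, list of them, or a \code{conf_ensemble}.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_mol2 <- function(x, path) {
  if (inherits(x, "mol_record")) x <- list(x)
  if (inherits(x, "conf_ensemble")) {
    mol <- x$molecule
    x <- lapply(seq_along(x$conformers), function(i) {
      m <- mol
      m$coords <- x$conformers[[i]]$coords
      m$name <- sprintf("%s_conf%d", mol$name, i)
      m
    })
  }
  .assert(is.list(x) && length(x) >= 1, "no molecules to write")
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop(sprintf("cannot write %s", path),
                                           call. = FALSE))
  on.exit(close(con))
  for (mol in x) {
    n <- length(mol$elements)
    nb <- nrow(mol$bonds)
    has_q <- !is.null(mol$charges)
    writeLines(c("@<TRIPOS>MOLECULE", mol$name,
                 sprintf(" %d %d 0 0 0", n, nb), "SMALL",
                 if (has_q) "USER_CHARGES" else "NO_CHARGES",
                 "@<TRIPOS>ATOM"), con)
    for (a in seq_len(n)) {
      q <- if (has_q) mol$charges[a] else 0
      writeLines(sprintf("%7d %-6s %10.4f %10.4f %10.4f %-6s %3d %-6s %9.4f",
                         a, paste0(mol$elements[a], a),
                         mol$coords[a, 1], mol$coords[a, 2], mol$coords[a, 3],
                         mol$elements[a], 1L, "MOL", q), con)
    }
    if (nb > 0) {
      writeLines("@<TRIPOS>BOND", con)
      for (k in seq_len(nb))
        writeLines(sprintf("%6d %5d %5d %s", k, mol$bonds$i[k], mol$bonds$j[k],
                           mol$bonds$order[k]), con)
    }
  }
  invisible(path)
}

#' Partition molecules by allowed element composition
#'
#' Keeps exactly the molecules all of whose atoms belong to the allowed
#' element set; the rest go into \code{removed}.  The partition is complete
#' and disjoint.
#'
#' @param records list of \code{mol_record}.
#' @param allowed character vector of allowed element symbols; defaults to the
#'   organic set C, O, N, S, F, Cl, Br, P, H.
#' @return list with components \code{kept} and \code{removed}.
#' @export
filter_allowed_elements <- function(records, allowed = ALLOWED_ELEMENTS) {
  ok <- vapply(records, function(r) all(r$elements %in% allowed), logical(1))
  list(kept = records[ok], removed = records[!ok])
}
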