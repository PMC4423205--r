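#' Hierarchical coordinate model
#'
#' A `structure_model` holds one atom table plus assembly operators and free
#' metadata. The atom table uses author numbering (as deposited) and PDB v3
#' primed atom names (`C1'`, `O2'`, ...). One row per atom with columns:
#' `eleno` (serial), `elety` (atom name), `resid` (residue name), `chain`,
#' `resno` (author residue number), `insert` (insertion code, `""` if none),
#' `x`, `y`, `z` (Angstrom), `o` (occupancy), `b` (isotropic B, Angstrom^2),
#' `elesy` (element symbol), `polymer_class` (one of `protein`, `nucleotide`,
#' `ion`, `water`, `other`).
#'
#' @name structure_model
NULL

# --- chemistry dictionaries -------------------------------------------------

.AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL", "MSE", "SEC", "PYL")

# standard + frequent modified ribo/deoxyribonucleotides, mapped to a parent
# base for pairing chemistry (res_name itself is always retained).
.NT_PARENT <- c(
  A = "A", C = "C", G = "G", U = "U", I = "G",
  DA = "A", DC = "C", DG = "G", DT = "U", DU = "U", DI = "G",
  PSU = "U", "5MU" = "U", "4SU" = "U", UMS = "U", US1 = "U", "2MU" = "U",
  OMU = "U", H2U = "U",
  "5MC" = "C", OMC = "C", CBV = "C", CSL = "C",
  OMG = "G", "2MG" = "G", "7MG" = "G", M2G = "G", YG = "G", GTP = "G",
  "1MA" = "A", MA6 = "A", RIA = "A", AMP = "A", ATP = "A"
)

.ION_NAMES <- c("NA", "K", "MG", "CA", "SR", "RB", "CS", "LI", "ZN", "MN",
                "FE", "FE2", "CO", "NI", "CU", "CD", "BA", "TL", "CL", "BR",
                "IOD", "F")

.WATER_NAMES <- c("HOH", "WAT", "DOD", "H2O")

.AA1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
          GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
          MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
          TYR = "Y", VAL = "V", MSE = "M", SEC = "U", PYL = "O")

#' Classify a residue name into a polymer class
#'
#' Classification is total: names absent from the amino-acid, nucleotide, ion
#' and water dictionaries fall through to `"other"`.
#'
#' @param resname character vector of residue names.
#' @return character vector over `protein`, `nucleotide`, `ion`, `water`,
#'   `other`.
#' @export
classify_residue <- function(resname) {
  rn <- toupper(trimws(resname))
  out <- rep("other", length(rn))
  out[rn %in% .AA3] <- "protein"
  out[rn %in% names(.NT_PARENT)] <- "nucleotide"
  out[rn %in% .ION_NAMES] <- "ion"
  out[rn %in% .WATER_NAMES] <- "water"
  out
}

#' Parent base of a (possibly modified) nucleotide residue name
#'
#' Modified nucleotides (e.g. the 2'-methylseleno-uridine used for anomalous
#' phasing) are mapped to their parent base so that base-pair chemistry applies;
#' unknown names return `NA`.
#'
#' @param resname character vector.
#' @return character vector over A, C, G, U or `NA`.
#' @export
parent_base <- function(resname) {
  unname(.NT_PARENT[toupper(trimws(resname))])
}

# PDB v2 dialect -> v3 primed names; '*' was used for primes historically;
# mmCIF values carrying primes arrive quoted.
normalize_atom_names <- function(elety) {
  e <- gsub("\"", "", trimws(elety), fixed = TRUE)
  e <- gsub("*", "'", e, fixed = TRUE)
  swap <- c("O1P" = "OP1", "O2P" = "OP2", "O3P" = "OP3", "C5M" = "C7")
  hit <- e %in% names(swap)
  e[hit] <- swap[e[hit]]
  e
}

#' Construct a structure model from an atom table
#'
#' @param atoms data.frame with at least `elety`, `resid`, `chain`, `resno`,
#'   `x`, `y`, `z`; missing bookkeeping columns are filled with defaults.
#' @param assembly_ops list of `list(R = 3x3, t = 3-vector)` rigid operators
#'   used to build the biological assembly.
#' @param metadata named list (space group, cell, ...).
#' @return object of class `structure_model`.
#' @export
new_structure_model <- function(atoms, assembly_ops = list(), metadata = list()) {
  stopifnot(is.data.frame(atoms))
  need <- c("elety", "resid", "chain", "resno", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop("atom table lacks columns: ", paste(miss, collapse = ", "))
  if (!all(is.finite(atoms$x)) || !all(is.finite(atoms$y)) || !all(is.finite(atoms$z)))
    stop("non-finite atom coordinates")
  n <- nrow(atoms)
  if (is.null(atoms$eleno)) atoms$eleno <- seq_len(n)
  if (is.null(atoms$insert)) atoms$insert <- rep("", n)
  atoms$insert[is.na(atoms$insert)] <- ""
  if (is.null(atoms$o)) atoms$o <- rep(1, n)
  if (is.null(atoms$b)) atoms$b <- rep(0, n)
  if (is.null(atoms$elesy)) atoms$elesy <- guess_element(atoms$elety)
  if (any(atoms$o < 0 | atoms$o > 1, na.rm = TRUE))
    stop("occupancy outside [0, 1]")
  atoms$elety <- normalize_atom_names(atoms$elety)
  if (is.null(atoms$polymer_class))
    atoms$polymer_class <- classify_residue(atoms$resid)
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, assembly_ops = assembly_ops,
                 metadata = metadata),
            class = "structure_model")
}

guess_element <- function(elety) {
  e <- trimws(elety)
  two <- toupper(substr(e, 1L, 2L))
  known2 <- c("SE", "FE", "MG", "MN", "ZN", "NA", "CL", "BR", "SR", "RB",
              "CS", "CA", "NI", "CU", "CO", "CD", "LI", "TL", "BA")
  out <- toupper(substr(gsub("[^A-Za-z].*", "", e), 1L, 1L))
  hit <- two %in% known2 & nchar(e) >= 2 & !grepl("'", e, fixed = TRUE)
  # ambiguous cases like "CA" (calcium vs C-alpha) are resolved by the caller
  # through the residue context; default to the single-letter reading here.
  out[hit & !(two %in% c("CA", "CO", "CD"))] <- two[hit & !(two %in% c("CA", "CO", "CD"))]
  out
}

#' @export
print.structure_model <- function(x, ...) {
  a <- x$atoms
  key <- paste(a$chain, a$resno, a$insert)
  cls <- tapply(a$polymer_class, key, function(z) z[1L])
  cat("structure_model:", nrow(a), "atoms,", length(unique(key)), "residues,",
      length(unique(a$chain)), "chain(s)\n")
  print(table(factor(cls, levels = c("protein", "nucleotide", "ion", "water",
                                     "other"))))
  if (length(x$assembly_ops))
    cat(length(x$assembly_ops), "assembly operator(s)\n")
  invisible(x)
}

#' Residue-level summary table of a model
#'
#' One row per residue in file order with the residue's polymer class.
#'
#' @param model structure_model.
#' @return data.frame with `chain`, `resno`, `insert`, `resid`,
#'   `polymer_class`, `natoms`.
#' @export
residue_table <- function(model) {
  a <- model$atoms
  key <- paste(a$chain, a$resno, a$insert, sep = "\r")
  first <- !duplicated(key)
  data.frame(chain = a$chain[first], resno = a$resno[first],
             insert = a$insert[first], resid = a$resid[first],
             polymer_class = a$polymer_class[first],
             natoms = as.vector(table(factor(key, levels = key[first]))),
             stringsAsFactors = FALSE)
}

#' Extract one residue's atoms
#'
#' @param model structure_model.
#' @param chain chain identifier.
#' @param resno author residue number.
#' @param insert insertion code, default `""`.
#' @return data.frame of atoms (possibly 0 rows).
#' @export
get_residue <- function(model, chain, resno, insert = "") {
  a <- model$atoms
  a[a$chain == chain & a$resno == resno & a$insert == insert, , drop = FALSE]
}

#' Named coordinate lookup within a residue atom table
#' @keywords internal
atom_xyz <- function(res_atoms, name) {
  i <- match(name, res_atoms$elety)
  if (is.na(i)) return(NULL)
  as.numeric(res_atoms[i, c("x", "y", "z")])
}

#' Subset a model by chain identifiers
#'
#' @param model structure_model.
#' @param chains character vector of chain ids to keep.
#' @param keep_solvent keep waters and ions belonging to no chain filter?
#' @return structure_model.
#' @export
select_chains <- function(model, chains, keep_solvent = FALSE) {
  a <- model$atoms
  keep <- a$chain %in% chains
  if (keep_solvent) keep <- keep | a$polymer_class %in% c("water", "ion")
  new_structure_model(a[keep, , drop = FALSE],
                      assembly_ops = model$assembly_ops,
                      metadata = model$metadata)
}

#' Coordinate matrix of a model
#' @param model structure_model.
#' @return n x 3 numeric matrix.
#' @export
coords <- function(model) {
  as.matrix(model$atoms[, c("x", "y", "z")])
}

set_coords <- function(model, xyz) {
  model$atoms$x <- xyz[, 1L]
  model$atoms$y <- xyz[, 2L]
  model$atoms$z <- xyz[, 3L]
  model
}

#' Combine two models into one
#'
#' Atom serials are renumbered; chains keep their identifiers (rename first if
#' they collide).
#' @param a,b structure_model objects.
#' @return structure_model.
#' @export
combine_models <- function(a, b) {
  at <- rbind(a$atoms, b$atoms)
  at$eleno <- seq_len(nrow(at))
  new_structure_model(at, assembly_ops = a$assembly_ops,
                      metadata = a$metadata)
}
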