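#' Read a macromolecular coordinate file
#'
#' Parses PDB or mmCIF through bio3d, collapses alternate locations to the
#' highest-occupancy conformer (ties broken by altloc letter order), normalizes
#' atom names to PDB v3 primed convention and assigns every residue exactly one
#' polymer class. Unknown residue names are classified `"other"` with a warning,
#' never an error.
#'
#' @param path file path.
#' @param format `"pdb"`, `"mmcif"` or `"auto"` (by extension).
#' @return a [structure_model].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.cif$|\\.mmcif$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  parsed <- tryCatch(
    suppressWarnings(
      if (format == "pdb") bio3d::read.pdb(path, verbose = FALSE,
                                           rm.alt = FALSE)
      else bio3d::read.cif(path, verbose = FALSE, rm.alt = FALSE)),
    error = function(e) stop("parse error reading ", basename(path), " as ",
                             format, ": ", conditionMessage(e), call. = FALSE)
  )
  at <- parsed$atom
  if (is.null(at) || nrow(at) == 0)
    stop("parse error reading ", basename(path), ": no atom records")
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  at$b[is.na(at$b)] <- 0
  at$chain[is.na(at$chain)] <- " "
  at$elety <- normalize_atom_names(at$elety)
  # altloc collapse: highest occupancy wins, then altloc letter order
  ord <- order(at$chain, at$resno, at$insert, at$elety, -at$o, at$alt)
  at <- at[ord, , drop = FALSE]
  dupl <- duplicated(paste(at$chain, at$resno, at$insert, at$elety, sep = "\r"))
  at <- at[!dupl, , drop = FALSE]
  at <- at[order(match(at$eleno, sort(at$eleno))), , drop = FALSE]
  at <- at[order(at$eleno), , drop = FALSE]

  elesy <- at$elesy
  if (is.null(elesy)) elesy <- rep(NA_character_, nrow(at))
  fix <- is.na(elesy) | elesy == ""
  elesy[fix] <- guess_element(at$elety[fix])
  # residue context resolves CA ambiguity (calcium ion vs protein C-alpha)
  elesy[toupper(at$resid) == "CA"] <- "CA"
  elesy[toupper(at$resid) == "SR"] <- "SR"

  cls <- classify_residue(at$resid)
  unk <- unique(at$resid[cls == "other"])
  if (length(unk))
    warning("unknown residue name(s) classified 'other': ",
            paste(unk, collapse = ", "))
  atoms <- data.frame(eleno = at$eleno, elety = at$elety, resid = at$resid,
                      chain = at$chain, resno = at$resno, insert = at$insert,
                      x = at$x, y = at$y, z = at$z, o = at$o, b = at$b,
                      elesy = toupper(elesy), polymer_class = cls,
                      stringsAsFactors = FALSE)
  meta <- list(source = path, format = format)
  ops <- list()
  if (format == "pdb") {
    head1 <- readLines(path, n = 2000L, warn = FALSE)
    cry <- grep("^CRYST1", head1, value = TRUE)
    if (length(cry)) {
      meta$cell <- suppressWarnings(as.numeric(c(
        substr(cry[1], 7, 15), substr(cry[1], 16, 24), substr(cry[1], 25, 33),
        substr(cry[1], 34, 40), substr(cry[1], 41, 47), substr(cry[1], 48, 54))))
      meta$space_group <- trimws(substr(cry[1], 56, 66))
    }
    ops <- parse_smtry(head1)
  }
  new_structure_model(atoms, assembly_ops = ops, metadata = meta)
}

# crystallographic symmetry operators from PDB REMARK 290 SMTRY records
parse_smtry <- function(lines) {
  sm <- grep("^REMARK 290   SMTRY", lines, value = TRUE)
  if (!length(sm)) return(list())
  row <- as.integer(substr(sm, 19, 19))
  opno <- as.integer(substr(sm, 20, 23))
  vals <- t(vapply(sm, function(l) {
    as.numeric(strsplit(trimws(substr(l, 24, 80)), "\\s+")[[1L]])[1:4]
  }, numeric(4)))
  ops <- list()
  for (k in sort(unique(opno))) {
    sel <- opno == k
    if (sum(sel) != 3L) next
    m <- vals[sel, , drop = FALSE][order(row[sel]), , drop = FALSE]
    ops[[length(ops) + 1L]] <- list(R = m[, 1:3], t = m[, 4L])
  }
  ops
}

#' Crystallographic symmetry mates in contact with a model
#'
#' Applies every crystal symmetry operator combined with unit-cell
#' translations (-1..1 along each axis; cell angles must be 90 degrees) and
#' returns the transformed copies that approach the original model within
#' `contact_dist`. Used to reconstruct crystal-contact assemblies such as
#' symmetry dimers.
#'
#' @param model structure_model carrying `assembly_ops` and a `cell` in its
#'   metadata (populated by [read_structure()] from CRYST1/REMARK 290).
#' @param contact_dist Angstrom (default 5).
#' @param mate_chain_suffix appended to chain ids of each returned mate.
#' @return list of `list(op, shift, n_contacts, model)` sorted by decreasing
#'   `n_contacts` (atom pairs within `contact_dist`).
#' @export
symmetry_mates <- function(model, contact_dist = 5, mate_chain_suffix = "s") {
  ops <- model$assembly_ops
  cell <- model$metadata$cell
  if (!length(ops)) stop("model carries no symmetry operators")
  if (is.null(cell) || any(abs(cell[4:6] - 90) > 1e-3))
    stop("symmetry expansion requires an orthogonal unit cell")
  xyz <- coords(model)
  lo <- apply(xyz, 2L, min); hi <- apply(xyz, 2L, max)
  out <- list()
  for (k in seq_along(ops)) for (n1 in -1:1) for (n2 in -1:1) for (n3 in -1:1) {
    R <- ops[[k]]$R
    tv <- ops[[k]]$t + c(n1 * cell[1L], n2 * cell[2L], n3 * cell[3L])
    if (max(abs(R - diag(3))) < 1e-9 && max(abs(tv)) < 1e-9) next
    m2xyz <- sweep(xyz %*% t(R), 2L, tv, "+")
    lo2 <- apply(m2xyz, 2L, min); hi2 <- apply(m2xyz, 2L, max)
    if (any(lo2 > hi + contact_dist) || any(hi2 < lo - contact_dist)) next
    keep1 <- which(xyz[, 1L] > lo2[1L] - contact_dist &
                     xyz[, 1L] < hi2[1L] + contact_dist)
    if (!length(keep1)) next
    dd <- fields_dist(xyz[keep1, , drop = FALSE], m2xyz)
    ncont <- sum(dd <= contact_dist)
    if (ncont == 0L) next
    mate <- set_coords(model, m2xyz)
    mate$atoms$chain <- paste0(mate$atoms$chain, mate_chain_suffix)
    out[[length(out) + 1L]] <- list(op = k, shift = c(n1, n2, n3),
                                    n_contacts = ncont, model = mate)
  }
  out[order(-vapply(out, `[[`, 0L, "n_contacts"))]
}

fields_dist <- function(a, b) {
  sqrt(pmax(outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b), 0))
}

#' Write a structure model to PDB or mmCIF
#'
#' Round-tripping through [read_structure()] preserves names, numbering and
#' coordinates to format precision (1e-3 Angstrom).
#'
#' @param model structure_model (non-empty).
#' @param path output file path.
#' @param format `"pdb"` or `"mmcif"`.
#' @return invisibly, `path`.
#' @export
write_structure <- function(model, path, format = c("pdb", "mmcif")) {
  format <- match.arg(format)
  a <- model$atoms
  if (nrow(a) == 0) stop("refusing to write an empty model")
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("unwritable path (no such directory): ", dir)
  if (format == "pdb") {
    type <- ifelse(a$polymer_class %in% c("protein", "nucleotide"),
                   "ATOM", "HETATM")
    ch <- a$chain
    ch[ch == "" | is.na(ch)] <- " "
    bio3d::write.pdb(file = path,
                     xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                     type = type, resno = a$resno, resid = a$resid,
                     eleno = a$eleno, elety = a$elety, chain = ch,
                     insert = ifelse(a$insert == "", NA, a$insert),
                     o = a$o, b = a$b, elesy = a$elesy)
  } else {
    write_mmcif_atoms(a, path)
  }
  invisible(path)
}

# minimal atom_site loop_ emitter (bio3d reads mmCIF but does not write it)
write_mmcif_atoms <- function(a, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("data_model", "#", "loop_",
               "_atom_site.group_PDB", "_atom_site.id",
               "_atom_site.type_symbol", "_atom_site.label_atom_id",
               "_atom_site.label_alt_id", "_atom_site.label_comp_id",
               "_atom_site.label_asym_id", "_atom_site.label_entity_id",
               "_atom_site.label_seq_id", "_atom_site.pdbx_PDB_ins_code",
               "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
               "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
               "_atom_site.auth_seq_id", "_atom_site.auth_comp_id",
               "_atom_site.auth_asym_id", "_atom_site.auth_atom_id",
               "_atom_site.pdbx_PDB_model_num"), con)
  grp <- ifelse(a$polymer_class %in% c("protein", "nucleotide"),
                "ATOM", "HETATM")
  q <- function(x) {
    x <- as.character(x)
    x[x == "" | is.na(x)] <- "?"
    ifelse(grepl("'", x, fixed = TRUE), paste0('"', x, '"'), x)
  }
  lines <- paste(grp, a$eleno, q(a$elesy), q(a$elety), ".", q(a$resid),
                 q(a$chain), "1", a$resno, q(a$insert),
                 sprintf("%.3f", a$x), sprintf("%.3f", a$y),
                 sprintf("%.3f", a$z), sprintf("%.2f", a$o),
                 sprintf("%.2f", a$b), a$resno, q(a$resid), q(a$chain),
                 q(a$elety), "1")
  writeLines(lines, con)
  writeLines("#", con)
}

#' Apply a rigid (or mirror) transform to all atoms
#'
#' Positions are mapped `x -> R x + t`. `R` must be orthonormal; a determinant
#' of -1 (improper operation) is permitted so that the explicit mirror operator
#' of the synthetic-data module can pass through the same machinery.
#'
#' @param model structure_model.
#' @param rotation 3 x 3 orthonormal matrix.
#' @param translation numeric 3-vector, Angstrom.
#' @return transformed structure_model (metadata preserved).
#' @export
apply_transform <- function(model, rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3L, 3L)))
    stop("rotation must be 3 x 3")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6)
    stop("rotation matrix is not orthonormal")
  xyz <- coords(model) %*% t(rotation)
  xyz <- sweep(xyz, 2L, as.numeric(translation), "+")
  set_coords(model, xyz)
}
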