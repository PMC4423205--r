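#' Rigid-body superposition and epitope mapping
#'
#' Kabsch least-squares superposition (SVD with reflection-branch correction,
#' so the rotation is always proper: mirror images of chiral sets can never be
#' superposed to zero), atom pairing by author numbering or by global sequence
#' alignment, and substitution mapping of a binding epitope across homologous
#' sequences.
#'
#' @name superposition
NULL

# core Kabsch fit: proper rotation R and translation t minimizing |R a + t - b|
kabsch_fit <- function(a, b) {
  ca <- colMeans(a); cb <- colMeans(b)
  H <- crossprod(sweep(a, 2L, ca), sweep(b, 2L, cb))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  t <- cb - as.numeric(R %*% ca)
  list(R = R, t = t)
}

#' Kabsch superposition of two matched coordinate sets
#'
#' @param coords_a,coords_b n x 3 matrices of matched positions (n >= 3, not
#'   collinear). `coords_a` is moved onto `coords_b`.
#' @return list of class `superposition_result`: `rotation` (proper, det +1),
#'   `translation`, `rmsd` (Angstrom, after the transform), `n_atoms`.
#' @export
kabsch_superpose <- function(coords_a, coords_b) {
  coords_a <- as.matrix(coords_a); coords_b <- as.matrix(coords_b)
  if (!all(dim(coords_a) == dim(coords_b)))
    stop("coordinate sets must have matching dimensions")
  n <- nrow(coords_a)
  if (n < 3L) stop("need at least 3 matched atoms")
  spread <- svd(sweep(coords_a, 2L, colMeans(coords_a)))$d
  if (spread[2L] < 1e-6)
    stop("degenerate geometry: matched set is collinear")
  fit <- kabsch_fit(coords_a, coords_b)
  moved <- sweep(coords_a %*% t(fit$R), 2L, fit$t, "+")
  rmsd <- sqrt(mean(rowSums((moved - coords_b)^2)))
  structure(list(rotation = fit$R, translation = fit$t, rmsd = rmsd,
                 n_atoms = n),
            class = "superposition_result")
}

#' @export
print.superposition_result <- function(x, ...) {
  cat(sprintf("superposition: rmsd %.3f A over %d atoms\n", x$rmsd, x$n_atoms))
  invisible(x)
}

model_chain_sequence <- function(model, chain) {
  rt <- residue_table(model)
  rt <- rt[rt$chain == chain & rt$polymer_class == "protein", , drop = FALSE]
  list(seq = paste(ifelse(is.na(.AA1[toupper(rt$resid)]), "X",
                          .AA1[toupper(rt$resid)]), collapse = ""),
       table = rt)
}

#' Pair atoms between two models for superposition
#'
#' Residues are matched either by author numbering (`pairing = "seq_num"`) or
#' by a Needleman-Wunsch global protein sequence alignment
#' (`pairing = "alignment"`, BLOSUM62, gap open/extend 10/0.5); atoms are then
#' matched by name within matched residues. Unpaired residues and atoms are
#' dropped and counted.
#'
#' @param model_a,model_b structure_model objects.
#' @param chain_a,chain_b one chain of each to pair.
#' @param selection `"calpha"` (protein C-alpha only), `"all_atom"` (all heavy
#'   atoms of matched residues) or `"custom"` with `atom_names`.
#' @param pairing `"seq_num"` or `"alignment"`.
#' @param atom_names for `selection = "custom"`.
#' @return list: `a`, `b` (matched n x 3 matrices), `n_atoms`,
#'   `n_residues`, `dropped_a`, `dropped_b` (residue counts).
#' @export
pair_atoms <- function(model_a, model_b, chain_a, chain_b,
                       selection = c("calpha", "all_atom", "custom"),
                       pairing = c("seq_num", "alignment"),
                       atom_names = NULL) {
  selection <- match.arg(selection)
  pairing <- match.arg(pairing)
  rta <- residue_table(model_a)
  rta <- rta[rta$chain == chain_a & rta$polymer_class == "protein", ,
             drop = FALSE]
  rtb <- residue_table(model_b)
  rtb <- rtb[rtb$chain == chain_b & rtb$polymer_class == "protein", ,
             drop = FALSE]
  if (!nrow(rta) || !nrow(rtb))
    stop("no protein residues found on the requested chains")
  if (pairing == "seq_num") {
    common <- intersect(rta$resno, rtb$resno)
    ia <- match(common, rta$resno); ib <- match(common, rtb$resno)
  } else {
    sa <- model_chain_sequence(model_a, chain_a)
    sb <- model_chain_sequence(model_b, chain_b)
    data("BLOSUM62", package = "Biostrings", envir = environment())
    al <- Biostrings::pairwiseAlignment(sa$seq, sb$seq, type = "global",
                                        substitutionMatrix = BLOSUM62,
                                        gapOpening = 10, gapExtension = 0.5)
    pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1L]]
    pb <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1L]]
    ia <- integer(0); ib <- integer(0); ka <- 0L; kb <- 0L
    for (i in seq_along(pa)) {
      if (pa[i] != "-") ka <- ka + 1L
      if (pb[i] != "-") kb <- kb + 1L
      if (pa[i] != "-" && pb[i] != "-") {
        ia <- c(ia, ka); ib <- c(ib, kb)
      }
    }
  }
  xa <- list(); xb <- list(); nres <- 0L
  for (k in seq_along(ia)) {
    res_a <- get_residue(model_a, chain_a, rta$resno[ia[k]], rta$insert[ia[k]])
    res_b <- get_residue(model_b, chain_b, rtb$resno[ib[k]], rtb$insert[ib[k]])
    nm <- switch(selection,
                 calpha = "CA",
                 all_atom = intersect(res_a$elety, res_b$elety),
                 custom = atom_names)
    nm <- intersect(intersect(nm, res_a$elety), res_b$elety)
    nm <- nm[!grepl("^H", nm)]
    if (!length(nm)) next
    nres <- nres + 1L
    xa[[length(xa) + 1L]] <- do.call(rbind, lapply(nm, atom_xyz,
                                                   res_atoms = res_a))
    xb[[length(xb) + 1L]] <- do.call(rbind, lapply(nm, atom_xyz,
                                                   res_atoms = res_b))
  }
  if (!length(xa)) stop("empty pairing: no atoms matched")
  a <- do.call(rbind, xa); b <- do.call(rbind, xb)
  list(a = a, b = b, n_atoms = nrow(a), n_residues = nres,
       dropped_a = nrow(rta) - nres, dropped_b = nrow(rtb) - nres)
}

#' Superpose one chain onto another and report the r.m.s.d.
#'
#' Convenience wrapper around [pair_atoms()] + [kabsch_superpose()].
#'
#' @inheritParams pair_atoms
#' @return `superposition_result` with pairing bookkeeping attached.
#' @export
superpose_chains <- function(model_a, model_b, chain_a, chain_b,
                             selection = "calpha", pairing = "seq_num") {
  pr <- pair_atoms(model_a, model_b, chain_a, chain_b, selection, pairing)
  out <- kabsch_superpose(pr$a, pr$b)
  out$n_residues <- pr$n_residues
  out$dropped_a <- pr$dropped_a
  out$dropped_b <- pr$dropped_b
  out$selection <- selection
  out
}

#' Default effect annotations for epitope substitutions
#'
#' Seeded with mutational binding results for the CCL2 epitope of the
#' NOX-E36 L-aptamer: R18K, V22K and H66Y are neutral; S21P, S63F and S63Y
#' are detrimental. The table is configuration, not code: pass your own to
#' [epitope_map()].
#'
#' @return data.frame with `position`, `ref`, `sub`, `effect`.
#' @export
epitope_effect_table <- function() {
  data.frame(
    position = c(18L, 21L, 22L, 63L, 63L, 66L),
    ref = c("R", "S", "V", "S", "S", "H"),
    sub = c("K", "P", "K", "F", "Y", "Y"),
    effect = c("neutral", "detrimental", "neutral", "detrimental",
               "detrimental", "neutral"),
    stringsAsFactors = FALSE)
}

#' Map epitope substitutions across homologous sequences
#'
#' Restricted to the reference's interface (contact) positions, reports the
#' residue each homolog presents at every contact position and flags
#' substitutions with an effect annotation looked up from a user-editable
#' table; substitutions absent from the table are `"unknown"`.
#'
#' @param reference_seq reference protein sequence (1-letter string); position
#'   i of the string is author position i unless `offset` shifts it.
#' @param contact_positions integer vector of author positions in contact.
#' @param homolog_seqs named character vector of homolog sequences, each
#'   already aligned to the reference (same length, `-` for gaps).
#' @param effect_table as [epitope_effect_table()].
#' @param offset author number of the first reference character minus 1.
#' @return data.frame: `position`, `ref`, one column per homolog, and
#'   `<name>_effect` columns.
#' @export
epitope_map <- function(reference_seq, contact_positions, homolog_seqs,
                        effect_table = epitope_effect_table(), offset = 0L) {
  ref <- strsplit(reference_seq, "")[[1L]]
  for (h in homolog_seqs)
    if (nchar(h) != length(ref))
      stop("homolog sequences must be aligned to the reference (equal length)")
  out <- data.frame(position = sort(unique(contact_positions)))
  idx <- out$position - offset
  if (any(idx < 1L | idx > length(ref)))
    stop("contact position outside the reference sequence")
  out$ref <- ref[idx]
  for (nm in names(homolog_seqs)) {
    hs <- strsplit(homolog_seqs[[nm]], "")[[1L]]
    out[[nm]] <- hs[idx]
    eff <- character(nrow(out))
    for (r in seq_len(nrow(out))) {
      if (out[[nm]][r] == out$ref[r]) { eff[r] <- "identical"; next }
      hit <- effect_table$position == out$position[r] &
        effect_table$ref == out$ref[r] & effect_table$sub == out[[nm]][r]
      eff[r] <- if (any(hit)) effect_table$effect[which(hit)[1L]] else "unknown"
    }
    out[[paste0(nm, "_effect")]] <- eff
  }
  out
}
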