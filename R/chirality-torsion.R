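#' Sugar chirality, glycosidic torsions and pseudorotation
#'
#' Chirality-aware nucleotide geometry. D/L sugar handedness is read from the
#' signed volume of the substituent triad at C4'; the glycosidic torsion chi
#' and the pseudorotation pucker are reported both raw (as computed on the
#' deposited coordinates) and chirality-corrected. For L-nucleotides the
#' correction negates torsions, which shifts the pseudorotation phase by 180
#' degrees and thereby swaps every endo label with its exo partner - the
#' inversion required to name L-sugar puckers consistently with the D
#' convention.
#'
#' @name chirality_torsion
NULL

# sign convention calibrated so ideal D-ribose gives positive volumes
.CHIRALITY_MIN_VOL <- 0.1 # Angstrom^3

#' Detect D/L chirality of a nucleotide sugar
#'
#' Sign of the triple product `(C3'-C4') x (O4'-C4') . (C5'-C4')`; positive is
#' D, negative is L. When the glycosidic nitrogen is present the equivalent
#' triad at C1' (`(O4'-C1') x (C2'-C1') . (N-C1')`) is cross-checked and any
#' disagreement yields `"undetermined"`.
#'
#' @param res_atoms residue atom table (one nucleotide), as returned by
#'   [get_residue()].
#' @return list with `label` (`"D"`, `"L"` or `"undetermined"`) and
#'   `signed_volume` (Angstrom^3, at C4').
#' @export
detect_chirality <- function(res_atoms) {
  need <- c("C3'", "C4'", "C5'", "O4'")
  pos <- lapply(need, atom_xyz, res_atoms = res_atoms)
  if (any(vapply(pos, is.null, TRUE))) {
    warning("missing sugar atoms; chirality undetermined for residue ",
            res_atoms$resno[1L])
    return(list(label = "undetermined", signed_volume = NA_real_))
  }
  names(pos) <- need
  sv <- sum(vcross(pos[["C3'"]] - pos[["C4'"]], pos[["O4'"]] - pos[["C4'"]]) *
              (pos[["C5'"]] - pos[["C4'"]]))
  lab <- if (sv > .CHIRALITY_MIN_VOL) "D"
  else if (sv < -.CHIRALITY_MIN_VOL) "L"
  else "undetermined"
  # cross-check at C1' when the glycosidic nitrogen is available
  c1 <- atom_xyz(res_atoms, "C1'")
  c2 <- atom_xyz(res_atoms, "C2'")
  nglyc <- atom_xyz(res_atoms, "N9") %||% atom_xyz(res_atoms, "N1")
  if (!is.null(c1) && !is.null(c2) && !is.null(nglyc) && lab != "undetermined") {
    sv1 <- sum(vcross(pos[["O4'"]] - c1, c2 - c1) * (nglyc - c1))
    lab1 <- if (sv1 > .CHIRALITY_MIN_VOL) "D"
    else if (sv1 < -.CHIRALITY_MIN_VOL) "L" else "undetermined"
    if (lab1 != lab) lab <- "undetermined"
  }
  list(label = lab, signed_volume = sv)
}

#' Glycosidic torsion chi with syn/anti classification
#'
#' chi is O4'-C1'-N9-C4 for purines and O4'-C1'-N1-C2 for pyrimidines,
#' computed on the coordinates as deposited. For L-nucleotides the
#' chirality-corrected value is `-chi`; the syn/anti call is made on the
#' corrected value (syn iff chi_corrected in (-90, 90]), so it is invariant
#' under mirroring.
#'
#' @param res_atoms residue atom table (one nucleotide).
#' @param chirality `"D"`, `"L"`, or `NULL` to detect it from the sugar.
#' @return list with `chi`, `chi_corrected` (degrees), `glycosidic_class`
#'   (`"syn"` or `"anti"`) and `chirality`.
#' @export
chi_torsion <- function(res_atoms, chirality = NULL) {
  base <- parent_base(res_atoms$resid[1L])
  pur <- !is.na(base) && base %in% c("A", "G")
  nm <- if (pur) c("O4'", "C1'", "N9", "C4") else c("O4'", "C1'", "N1", "C2")
  pos <- lapply(nm, atom_xyz, res_atoms = res_atoms)
  if (any(vapply(pos, is.null, TRUE)))
    stop("no glycosidic torsion: residue ", res_atoms$resid[1L], " ",
         res_atoms$resno[1L], " lacks atoms ",
         paste(nm[vapply(pos, is.null, TRUE)], collapse = ", "))
  chi <- dihedral(pos[[1L]], pos[[2L]], pos[[3L]], pos[[4L]])
  if (is.null(chirality)) chirality <- detect_chirality(res_atoms)$label
  chi_c <- if (identical(chirality, "L")) -chi else chi
  cls <- if (chi_c > -90 && chi_c <= 90) "syn" else "anti"
  list(chi = chi, chi_corrected = chi_c, glycosidic_class = cls,
       chirality = chirality)
}

.PUCKER_LABELS <- c("C3'-endo", "C4'-exo", "O4'-endo", "C1'-exo", "C2'-endo",
                    "C3'-exo", "C4'-endo", "O4'-exo", "C1'-endo", "C2'-exo")

pucker_label <- function(P) {
  .PUCKER_LABELS[(floor((P %% 360) / 36) %% 10) + 1L]
}

#' Pseudorotation analysis of a sugar ring
#'
#' Computes the five endocyclic torsions, the pseudorotation phase
#' `tan P = ((nu4 + nu1) - (nu3 + nu0)) / (2 nu2 (sin 36 + sin 72))` (resolved
#' by the two-argument arctangent) and the amplitude `tau_m = nu2 / cos P`,
#' then assigns the envelope-state label from 36-degree-wide bins starting at
#' C3'-endo for P in [0, 36). The chirality-corrected label is obtained by
#' negating the torsions (equivalently, P + 180 degrees) for L-sugars - the
#' endo/exo inversion - and equals the raw label for D-sugars.
#'
#' @param res_atoms residue atom table (one nucleotide).
#' @param chirality `"D"`, `"L"`, or `NULL` to detect it.
#' @return list with `nu` (5 torsions, degrees), `P` (degrees in [0, 360)),
#'   `tau_m` (degrees), `raw_label`, `corrected_label`, `chirality`.
#' @export
pseudorotation <- function(res_atoms, chirality = NULL) {
  nm <- c("C1'", "C2'", "C3'", "C4'", "O4'")
  pos <- lapply(nm, atom_xyz, res_atoms = res_atoms)
  if (any(vapply(pos, is.null, TRUE)))
    stop("pseudorotation needs all five ring atoms; residue ",
         res_atoms$resno[1L], " lacks ",
         paste(nm[vapply(pos, is.null, TRUE)], collapse = ", "))
  p <- do.call(rbind, pos)
  rownames(p) <- nm
  nu <- ring_torsions(p)
  den <- 2 * nu[3L] * (sin(36 / DEG) + sin(72 / DEG))
  num <- (nu[5L] + nu[2L]) - (nu[4L] + nu[1L])
  P <- (atan2(num, den) * DEG) %% 360
  tau_m <- nu[3L] / cos(P / DEG)
  if (!is.finite(tau_m) || abs(tau_m) < 5) {
    return(list(nu = nu, P = P, tau_m = tau_m, raw_label = "undetermined",
                corrected_label = "undetermined",
                chirality = chirality %||% "undetermined"))
  }
  raw <- pucker_label(P)
  if (is.null(chirality)) chirality <- detect_chirality(res_atoms)$label
  corr <- if (identical(chirality, "L")) pucker_label(P + 180) else raw
  list(nu = nu, P = P, tau_m = tau_m, raw_label = raw,
       corrected_label = corr, chirality = chirality)
}

#' Per-nucleotide geometry report
#'
#' Runs chirality detection, glycosidic torsion analysis and pseudorotation on
#' every nucleotide of a model. Residues with missing atoms are retained with
#' `NA` entries (and excluded from any summary counts downstream), never
#' silently dropped.
#'
#' @param model structure_model.
#' @return data.frame with one row per nucleotide: `chain`, `resno`, `resid`,
#'   `chirality`, `chi`, `chi_corrected`, `glycosidic_class`, `P`, `tau_m`,
#'   `raw_pucker`, `pucker` (chirality-corrected).
#' @export
nucleotide_geometry <- function(model) {
  rt <- residue_table(model)
  rt <- rt[rt$polymer_class == "nucleotide", , drop = FALSE]
  out <- lapply(seq_len(nrow(rt)), function(i) {
    res <- get_residue(model, rt$chain[i], rt$resno[i], rt$insert[i])
    ch <- detect_chirality(res)
    chi <- tryCatch(chi_torsion(res, chirality = ch$label),
                    error = function(e) NULL)
    pk <- tryCatch(pseudorotation(res, chirality = ch$label),
                   error = function(e) NULL)
    data.frame(chain = rt$chain[i], resno = rt$resno[i], resid = rt$resid[i],
               chirality = ch$label,
               chi = chi$chi %||% NA_real_,
               chi_corrected = chi$chi_corrected %||% NA_real_,
               glycosidic_class = chi$glycosidic_class %||% NA_character_,
               P = pk$P %||% NA_real_, tau_m = pk$tau_m %||% NA_real_,
               raw_pucker = pk$raw_label %||% NA_character_,
               pucker = pk$corrected_label %||% NA_character_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
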