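#' Protein-nucleic acid interface characterization
#'
#' Buried-area interface metrics from Shrake-Rupley SASA, inter-chain hydrogen
#' bonds, salt bridges (electrostatic contacts) and cation-pi interactions.
#' The interface area follows the buried-area convention
#' `interface = (dA_side_a + dA_side_b) / 2`, i.e. the mean of the two sides'
#' buried areas; both per-side areas are always reported as well.
#'
#' @name interface_analysis
NULL

# donor / acceptor chemistry (heavy atoms) per residue type
.PROT_DONORS <- list(
  backbone = "N",
  ARG = c("NE", "NH1", "NH2"), LYS = "NZ", HIS = c("ND1", "NE2"),
  ASN = "ND2", GLN = "NE2", SER = "OG", THR = "OG1", TYR = "OH",
  TRP = "NE1", CYS = "SG")
.PROT_ACCEPTORS <- list(
  backbone = "O",
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  SER = "OG", THR = "OG1", TYR = "OH", HIS = c("ND1", "NE2"), MET = "SD")
.RNA_EXTRA_DONORS <- "O2'"
.RNA_EXTRA_ACCEPTORS <- c("O2'", "O3'", "O4'", "O5'", "OP1", "OP2")

polar_atoms <- function(res_atoms, role = c("donor", "acceptor")) {
  role <- match.arg(role)
  cls <- res_atoms$polymer_class[1L]
  rn <- toupper(res_atoms$resid[1L])
  nm <- character(0)
  if (cls == "protein") {
    tab <- if (role == "donor") .PROT_DONORS else .PROT_ACCEPTORS
    nm <- c(tab$backbone, tab[[rn]])
  } else if (cls == "nucleotide") {
    nm <- c(base_edge_atoms(res_atoms, role),
            if (role == "donor") .RNA_EXTRA_DONORS else .RNA_EXTRA_ACCEPTORS)
  }
  intersect(nm, res_atoms$elety)
}

residue_polar_table <- function(model, chains, role) {
  rt <- residue_table(model)
  rt <- rt[rt$chain %in% chains &
             rt$polymer_class %in% c("protein", "nucleotide"), , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(rt))) {
    res <- get_residue(model, rt$chain[i], rt$resno[i], rt$insert[i])
    for (a in polar_atoms(res, role))
      out[[length(out) + 1L]] <- data.frame(
        chain = rt$chain[i], resno = rt$resno[i], resid = rt$resid[i],
        atom = a, x = atom_xyz(res, a)[1L], y = atom_xyz(res, a)[2L],
        z = atom_xyz(res, a)[3L], stringsAsFactors = FALSE)
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

cross_contacts <- function(tab_a, tab_b, lo, hi) {
  if (is.null(tab_a) || is.null(tab_b)) return(NULL)
  xa <- as.matrix(tab_a[, c("x", "y", "z")])
  xb <- as.matrix(tab_b[, c("x", "y", "z")])
  dd <- sqrt(pmax(outer(rowSums(xa^2), rowSums(xb^2), "+") -
                    2 * xa %*% t(xb), 0))
  hit <- which(dd >= lo & dd <= hi, arr.ind = TRUE)
  if (!nrow(hit)) return(NULL)
  data.frame(chain_a = tab_a$chain[hit[, 1L]], resno_a = tab_a$resno[hit[, 1L]],
             resid_a = tab_a$resid[hit[, 1L]], atom_a = tab_a$atom[hit[, 1L]],
             chain_b = tab_b$chain[hit[, 2L]], resno_b = tab_b$resno[hit[, 2L]],
             resid_b = tab_b$resid[hit[, 2L]], atom_b = tab_b$atom[hit[, 2L]],
             distance = dd[hit], stringsAsFactors = FALSE)
}

#' Inter-chain hydrogen bonds
#'
#' Donor-acceptor N/O (and S) pairs across the two sides with heavy-atom
#' distance in `[2.4, cutoff]` Angstrom, using per-residue chemistry tables
#' (backbone and side chains; ribose 2'-OH as donor and acceptor; phosphate
#' oxygens as acceptors). Hydrogens are never required.
#'
#' @param model structure_model.
#' @param side_a,side_b character vectors of chain ids (disjoint).
#' @param cutoff distance cutoff, Angstrom (default 3.5).
#' @return data.frame of contacts with `type = "hbond"`; the `a` side columns
#'   are the `side_a` residue regardless of donor/acceptor direction.
#' @export
interchain_hbonds <- function(model, side_a, side_b, cutoff = 3.5) {
  if (length(intersect(side_a, side_b)))
    stop("side_a and side_b must be disjoint chain sets")
  da <- residue_polar_table(model, side_a, "donor")
  ab <- residue_polar_table(model, side_b, "acceptor")
  db <- residue_polar_table(model, side_b, "donor")
  aa <- residue_polar_table(model, side_a, "acceptor")
  h1 <- cross_contacts(da, ab, 2.4, cutoff)
  if (!is.null(h1)) h1$donor_side <- "a"
  h2 <- cross_contacts(aa, db, 2.4, cutoff)
  if (!is.null(h2)) h2$donor_side <- "b"
  out <- rbind(h1, h2)
  if (is.null(out)) return(NULL)
  # one bond per unordered atom pair (O2'<->O2' style duplicates collapse)
  key <- paste(out$chain_a, out$resno_a, out$atom_a,
               out$chain_b, out$resno_b, out$atom_b)
  out <- out[!duplicated(key), , drop = FALSE]
  out$type <- "hbond"
  rownames(out) <- NULL
  out
}

#' Salt bridges (electrostatic contacts)
#'
#' Charged-group nitrogens (Arg NE/NH1/NH2, Lys NZ, His ND1/NE2) to
#' phosphate/carboxylate oxygens within `cutoff` (default 4.0 Angstrom).
#' Pairs already counted as hydrogen bonds can be excluded so that the direct
#' hydrogen-bond tally and the electrostatic tally stay disjoint.
#'
#' @param model structure_model.
#' @param side_a,side_b chain sets.
#' @param cutoff Angstrom (default 4.0).
#' @param exclude data.frame of hydrogen bonds to exclude (atom-pair keyed).
#' @return data.frame of contacts with `type = "salt_bridge"`, or `NULL`.
#' @export
salt_bridges <- function(model, side_a, side_b, cutoff = 4.0, exclude = NULL) {
  charged <- function(chains) {
    rt <- residue_table(model)
    rt <- rt[rt$chain %in% chains, , drop = FALSE]
    out <- list()
    for (i in seq_len(nrow(rt))) {
      res <- get_residue(model, rt$chain[i], rt$resno[i], rt$insert[i])
      rn <- toupper(res$resid[1L])
      nm <- switch(rn, ARG = c("NE", "NH1", "NH2"), LYS = "NZ",
                   HIS = c("ND1", "NE2"), character(0))
      for (a in intersect(nm, res$elety))
        out[[length(out) + 1L]] <- data.frame(
          chain = rt$chain[i], resno = rt$resno[i], resid = rt$resid[i],
          atom = a, x = atom_xyz(res, a)[1L], y = atom_xyz(res, a)[2L],
          z = atom_xyz(res, a)[3L], stringsAsFactors = FALSE)
    }
    if (!length(out)) return(NULL)
    do.call(rbind, out)
  }
  anionic <- function(chains) {
    rt <- residue_table(model)
    rt <- rt[rt$chain %in% chains, , drop = FALSE]
    out <- list()
    for (i in seq_len(nrow(rt))) {
      res <- get_residue(model, rt$chain[i], rt$resno[i], rt$insert[i])
      rn <- toupper(res$resid[1L])
      nm <- if (res$polymer_class[1L] == "nucleotide") c("OP1", "OP2")
      else switch(rn, ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
                  character(0))
      for (a in intersect(nm, res$elety))
        out[[length(out) + 1L]] <- data.frame(
          chain = rt$chain[i], resno = rt$resno[i], resid = rt$resid[i],
          atom = a, x = atom_xyz(res, a)[1L], y = atom_xyz(res, a)[2L],
          z = atom_xyz(res, a)[3L], stringsAsFactors = FALSE)
    }
    if (!length(out)) return(NULL)
    do.call(rbind, out)
  }
  s1 <- cross_contacts(charged(side_a), anionic(side_b), 0, cutoff)
  s2 <- cross_contacts(anionic(side_a), charged(side_b), 0, cutoff)
  out <- rbind(s1, s2)
  if (is.null(out)) return(NULL)
  if (!is.null(exclude) && nrow(exclude)) {
    keyx <- paste(exclude$chain_a, exclude$resno_a, exclude$atom_a,
                  exclude$chain_b, exclude$resno_b, exclude$atom_b)
    key <- paste(out$chain_a, out$resno_a, out$atom_a,
                 out$chain_b, out$resno_b, out$atom_b)
    out <- out[!(key %in% keyx), , drop = FALSE]
  }
  if (!nrow(out)) return(NULL)
  out$type <- "salt_bridge"
  rownames(out) <- NULL
  out
}

.AROMATIC_RINGS <- list(
  PHE = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TRP = list(c("CG", "CD1", "CD2", "NE1", "CE2"),
             c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2")),
  HIS = list(c("CG", "ND1", "CD2", "CE1", "NE2"))
)

residue_rings <- function(res_atoms) {
  cls <- res_atoms$polymer_class[1L]
  rn <- toupper(res_atoms$resid[1L])
  defs <- if (cls == "protein") .AROMATIC_RINGS[[rn]]
  else if (cls == "nucleotide") {
    pb <- parent_base(rn)
    if (is.na(pb)) NULL
    else if (pb %in% c("A", "G")) list(.BASE_RING6, .BASE_RING5)
    else list(.BASE_RING6)
  }
  if (is.null(defs)) return(list())
  out <- list()
  for (d in defs) {
    if (!all(d %in% res_atoms$elety)) next
    xyz <- do.call(rbind, lapply(d, atom_xyz, res_atoms = res_atoms))
    out[[length(out) + 1L]] <- list(centroid = colMeans(xyz),
                                    normal = plane_normal(xyz))
  }
  out
}

#' Cation-pi contacts across an interface
#'
#' A contact is reported when a cationic group center (Arg guanidinium CZ or
#' Lys NZ) lies within `max_dist` of an aromatic ring centroid (Phe, Tyr, Trp,
#' His rings or nucleobase rings) and the centroid->cation vector is within
#' `max_angle` of the ring normal (face-on approach).
#'
#' @param model structure_model.
#' @param side_a,side_b chain sets.
#' @param max_dist Angstrom (default 6.0).
#' @param max_angle degrees from the ring normal (default 45).
#' @return data.frame (cation residue, ring residue, distance, angle), or
#'   `NULL` when there is none.
#' @export
cation_pi <- function(model, side_a, side_b, max_dist = 6.0, max_angle = 45) {
  cations <- function(chains) {
    rt <- residue_table(model)
    rt <- rt[rt$chain %in% chains, , drop = FALSE]
    out <- list()
    for (i in seq_len(nrow(rt))) {
      res <- get_residue(model, rt$chain[i], rt$resno[i], rt$insert[i])
      rn <- toupper(res$resid[1L])
      nm <- switch(rn, ARG = "CZ", LYS = "NZ", NULL)
      if (is.null(nm) || !(nm %in% res$elety)) next
      out[[length(out) + 1L]] <- list(chain = rt$chain[i], resno = rt$resno[i],
                                      resid = rt$resid[i], atom = nm,
                                      xyz = atom_xyz(res, nm))
    }
    out
  }
  rings <- function(chains) {
    rt <- residue_table(model)
    rt <- rt[rt$chain %in% chains, , drop = FALSE]
    out <- list()
    for (i in seq_len(nrow(rt))) {
      res <- get_residue(model, rt$chain[i], rt$resno[i], rt$insert[i])
      for (rg in residue_rings(res))
        out[[length(out) + 1L]] <- c(list(chain = rt$chain[i],
                                          resno = rt$resno[i],
                                          resid = rt$resid[i]), rg)
    }
    out
  }
  hits <- list()
  scan <- function(cats, rgs) {
    for (ct in cats) for (rg in rgs) {
      v <- ct$xyz - rg$centroid
      d <- vnorm(v)
      if (d > max_dist || d < 1e-6) next
      ang <- axis_angle(v, rg$normal)
      if (ang <= max_angle)
        hits[[length(hits) + 1L]] <<- data.frame(
          cation_chain = ct$chain, cation_resno = ct$resno,
          cation_resid = ct$resid, cation_atom = ct$atom,
          ring_chain = rg$chain, ring_resno = rg$resno,
          ring_resid = rg$resid, distance = d, angle = ang,
          stringsAsFactors = FALSE)
    }
  }
  scan(cations(side_a), rings(side_b))
  scan(cations(side_b), rings(side_a))
  if (!length(hits)) return(NULL)
  out <- do.call(rbind, hits)
  # one contact per cation/ring-residue pair (keep the closest ring)
  key <- paste(out$cation_chain, out$cation_resno, out$ring_chain,
               out$ring_resno)
  out <- out[order(out$distance), , drop = FALSE]
  out <- out[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Interface report between two chain sets
#'
#' Buried areas are `dA_X = sasa(X alone) - sasa(X in complex)` per side;
#' `interface_area = (dA_a + dA_b) / 2`. Interface residues are those burying
#' more than 0.1 Angstrom^2. Contacts (hydrogen bonds, salt bridges excluding
#' atoms pairs already counted as hydrogen bonds, cation-pi) are computed
#' across the two sides. Waters and ions are excluded from areas by default.
#'
#' @param model structure_model containing both sides.
#' @param side_a,side_b disjoint chain sets.
#' @param probe,n_points SASA parameters.
#' @param hbond_cutoff,salt_cutoff contact cutoffs, Angstrom.
#' @param include_solvent include waters/ions in the area calculation?
#' @return list of class `interface_report`: `buried_a`, `buried_b`,
#'   `interface_area`, `interface_residues` (per side), `hbonds`,
#'   `salt_bridges`, `cation_pi`, plus the per-side SASA objects.
#' @export
interface_report <- function(model, side_a, side_b, probe = 1.4,
                             n_points = 960, hbond_cutoff = 3.5,
                             salt_cutoff = 4.0, include_solvent = FALSE) {
  if (!length(side_a) || !length(side_b))
    stop("both sides must name at least one chain")
  if (length(intersect(side_a, side_b)))
    stop("side_a and side_b must be disjoint chain sets")
  ma <- select_chains(model, side_a)
  mb <- select_chains(model, side_b)
  mab <- select_chains(model, c(side_a, side_b))
  sa <- sasa(ma, probe, n_points, include_solvent)
  sb <- sasa(mb, probe, n_points, include_solvent)
  sab <- sasa(mab, probe, n_points, include_solvent)
  in_a <- mab$atoms$chain %in% side_a
  buried_a <- sa$total - sum(sab$atom_area[in_a])
  buried_b <- sb$total - sum(sab$atom_area[!in_a])

  iface_res <- function(s_alone, s_cplx, chains) {
    ra <- s_alone$residue_area
    rc <- s_cplx$residue_area
    rc <- rc[rc$chain %in% chains, , drop = FALSE]
    m <- merge(ra, rc, by = c("chain", "resno", "insert", "resid"),
               suffixes = c("_alone", "_complex"))
    m$buried <- m$area_alone - m$area_complex
    m <- m[m$buried > 0.1, , drop = FALSE]
    m[order(m$chain, m$resno), c("chain", "resno", "resid", "buried")]
  }
  hb <- interchain_hbonds(mab, side_a, side_b, hbond_cutoff)
  sbg <- salt_bridges(mab, side_a, side_b, salt_cutoff, exclude = hb)
  cp <- cation_pi(mab, side_a, side_b)
  structure(list(
    side_a = side_a, side_b = side_b,
    buried_a = buried_a, buried_b = buried_b,
    interface_area = (buried_a + buried_b) / 2,
    interface_residues = list(a = iface_res(sa, sab, side_a),
                              b = iface_res(sb, sab, side_b)),
    hbonds = hb, salt_bridges = sbg, cation_pi = cp,
    sasa = list(a = sa, b = sb, complex = sab)),
    class = "interface_report")
}

#' @export
print.interface_report <- function(x, ...) {
  cat(sprintf("interface: %.1f A^2 (side a buried %.1f, side b buried %.1f)\n",
              x$interface_area, x$buried_a, x$buried_b))
  cat(sprintf("interface residues: %d (a) / %d (b); H-bonds: %d; salt bridges: %d; cation-pi: %d\n",
              nrow(x$interface_residues$a), nrow(x$interface_residues$b),
              if (is.null(x$hbonds)) 0L else nrow(x$hbonds),
              if (is.null(x$salt_bridges)) 0L else nrow(x$salt_bridges),
              if (is.null(x$cation_pi)) 0L else nrow(x$cation_pi)))
  invisible(x)
}
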