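#' Base pairing, pseudoknots and helix handedness
#'
#' Hydrogen-bond detection between nucleobases (heavy atoms only; crystal
#' models carry no hydrogens), dictionary-based pair classification
#' (Watson-Crick, Hoogsteen, named noncanonical types such as the GG N7-N1
#' carbonyl-amino and GA N3-amino amino-N1 pairs), strand orientation from
#' backbone direction vectors, pseudoknot detection by crossing enumeration
#' and helix handedness from virtual C1' dihedrals.
#'
#' @name base_pairing
NULL

base_edge_atoms <- function(res_atoms, role = c("donor", "acceptor")) {
  role <- match.arg(role)
  pb <- parent_base(res_atoms$resid[1L])
  if (is.na(pb)) return(character(0))
  tab <- if (role == "donor") .BASE_DONORS else .BASE_ACCEPTORS
  intersect(tab[[pb]], res_atoms$elety)
}

nucleotide_residues <- function(model) {
  rt <- residue_table(model)
  rt <- rt[rt$polymer_class == "nucleotide", , drop = FALSE]
  rt$pos <- seq_len(nrow(rt))
  rt
}

#' Hydrogen bonds between nucleobases
#'
#' All donor-acceptor N/O pairs between distinct bases with heavy-atom
#' distance in `[2.4, cutoff]` Angstrom. Donor/acceptor roles come from
#' per-base chemistry tables on the parent base, so modified nucleotides pair
#' through their parent chemistry.
#'
#' @param model structure_model.
#' @param cutoff heavy-atom distance cutoff, Angstrom (default 3.5).
#' @return data.frame with donor/acceptor residue references, atom names and
#'   `distance`.
#' @export
find_base_hbonds <- function(model, cutoff = 3.5) {
  rt <- nucleotide_residues(model)
  empty <- data.frame(donor_chain = character(0), donor_resno = integer(0),
                      donor_atom = character(0), acceptor_chain = character(0),
                      acceptor_resno = integer(0), acceptor_atom = character(0),
                      donor_pos = integer(0), acceptor_pos = integer(0),
                      distance = numeric(0), stringsAsFactors = FALSE)
  if (nrow(rt) < 2L) return(empty)
  don <- list(); acc <- list()
  for (i in seq_len(nrow(rt))) {
    res <- get_residue(model, rt$chain[i], rt$resno[i], rt$insert[i])
    for (a in base_edge_atoms(res, "donor"))
      don[[length(don) + 1L]] <- list(pos = i, atom = a,
                                      xyz = atom_xyz(res, a))
    for (a in base_edge_atoms(res, "acceptor"))
      acc[[length(acc) + 1L]] <- list(pos = i, atom = a,
                                      xyz = atom_xyz(res, a))
  }
  if (!length(don) || !length(acc)) return(empty)
  dxyz <- do.call(rbind, lapply(don, `[[`, "xyz"))
  axyz <- do.call(rbind, lapply(acc, `[[`, "xyz"))
  dpos <- vapply(don, `[[`, 0L, "pos"); apos <- vapply(acc, `[[`, 0L, "pos")
  dd <- sqrt(pmax(outer(rowSums(dxyz^2), rowSums(axyz^2), "+") -
                    2 * dxyz %*% t(axyz), 0))
  hit <- which(dd >= 2.4 & dd <= cutoff & outer(dpos, apos, "!="),
               arr.ind = TRUE)
  if (!nrow(hit)) return(empty)
  di <- hit[, 1L]; ai <- hit[, 2L]
  data.frame(donor_chain = rt$chain[dpos[di]], donor_resno = rt$resno[dpos[di]],
             donor_atom = vapply(don[di], `[[`, "", "atom"),
             acceptor_chain = rt$chain[apos[ai]],
             acceptor_resno = rt$resno[apos[ai]],
             acceptor_atom = vapply(acc[ai], `[[`, "", "atom"),
             donor_pos = dpos[di], acceptor_pos = apos[ai],
             distance = dd[hit], stringsAsFactors = FALSE)
}

base_ring_xyz <- function(res_atoms) {
  pb <- parent_base(res_atoms$resid[1L])
  nm <- if (!is.na(pb) && pb %in% c("A", "G"))
    union(.BASE_RING6, .BASE_RING5) else .BASE_RING6
  keep <- res_atoms$elety %in% nm
  as.matrix(res_atoms[keep, c("x", "y", "z")])
}

backbone_direction <- function(res_atoms) {
  c5 <- atom_xyz(res_atoms, "C5'")
  c3 <- atom_xyz(res_atoms, "C3'")
  if (is.null(c5) || is.null(c3)) return(NULL)
  c3 - c5
}

# local 5'->3' strand direction at residue `pos` of the nucleotide table:
# C1'-to-C1' propagation when a chain neighbour exists (robust to unusual
# sugar orientations), else the intra-residue C5'->C3' vector
strand_direction <- function(model, rt, pos) {
  c1_of <- function(p) {
    if (p < 1L || p > nrow(rt)) return(NULL)
    if (rt$chain[p] != rt$chain[pos]) return(NULL)
    atom_xyz(get_residue(model, rt$chain[p], rt$resno[p], rt$insert[p]), "C1'")
  }
  two_sided <- function(p) {
    a <- c1_of(p - 1L); b <- c1_of(p + 1L)
    if (is.null(a) || is.null(b)) NULL else b - a
  }
  # prefer the centred difference here or at the nearest chain neighbour
  # (terminal one-sided chords are dominated by the helical tangent)
  for (p in c(pos, pos - 1L, pos + 1L)) {
    d <- two_sided(p)
    if (!is.null(d)) return(d)
  }
  here <- c1_of(pos)
  nxt <- c1_of(pos + 1L)
  prv <- c1_of(pos - 1L)
  if (!is.null(here) && !is.null(nxt)) return(nxt - here)
  if (!is.null(here) && !is.null(prv)) return(here - prv)
  backbone_direction(get_residue(model, rt$chain[pos], rt$resno[pos],
                                 rt$insert[pos]))
}

#' Classify one candidate base pair
#'
#' Requires at least two base-base hydrogen bonds, near-coplanar bases
#' (inter-plane angle <= `max_plane_angle`) and an edge-on approach (the
#' inter-centroid vector must lie within `max_plane_angle` of both base
#' planes, which rejects stacked neighbours). The hydrogen-bond pattern is
#' matched against dictionaries of canonical Watson-Crick, Hoogsteen-edge and
#' named noncanonical pairs; valid but unmatched pairs are reported as
#' noncanonical, subtype `"unclassified"`. Orientation is parallel iff the
#' local 5'->3' backbone directions (C5'->C3') of the two residues have a
#' positive dot product.
#'
#' @param res_i,res_j residue atom tables (chain order i before j).
#' @param hbonds data.frame of hydrogen bonds between exactly these two
#'   residues (as from [find_base_hbonds()]).
#' @param max_plane_angle coplanarity threshold, degrees (default 35).
#' @param dir_i,dir_j optional local 5'->3' backbone direction vectors; when
#'   omitted, the intra-residue C5'->C3' vectors are used.
#' @return a list describing the pair, or `NULL` when the geometry does not
#'   qualify.
#' @export
classify_pair <- function(res_i, res_j, hbonds, max_plane_angle = 35,
                          dir_i = NULL, dir_j = NULL) {
  if (is.null(hbonds) || nrow(hbonds) < 2L) return(NULL)
  ri <- base_ring_xyz(res_i); rj <- base_ring_xyz(res_j)
  if (nrow(ri) < 6L || nrow(rj) < 6L) return(NULL)
  ni <- plane_normal(ri); nj <- plane_normal(rj)
  if (axis_angle(ni, nj) > max_plane_angle) return(NULL)
  cc <- colMeans(rj) - colMeans(ri)
  # edge-on gates: centroid separation must be in-plane, not along the
  # normals, and the vertical (normal-direction) offset small - together
  # these reject stacked and diagonal neighbours
  if (90 - axis_angle(cc, ni) > max_plane_angle ||
      90 - axis_angle(cc, nj) > max_plane_angle) return(NULL)
  if (abs(sum(cc * vunit(ni))) > 2.5 || abs(sum(cc * vunit(nj))) > 2.5)
    return(NULL)

  bi <- parent_base(res_i$resid[1L]); bj <- parent_base(res_j$resid[1L])
  # observed bonds as (atom on i, atom on j)
  on_i <- hbonds$donor_chain == res_i$chain[1L] &
    hbonds$donor_resno == res_i$resno[1L]
  obs <- unique(cbind(ifelse(on_i, hbonds$donor_atom, hbonds$acceptor_atom),
                      ifelse(on_i, hbonds$acceptor_atom, hbonds$donor_atom)))
  match_dict <- function(entry) {
    combos <- list()
    if (identical(c(bi, bj), entry$bases))
      combos <- c(combos, list(entry$bonds))
    if (identical(c(bj, bi), entry$bases))
      combos <- c(combos, list(lapply(entry$bonds, rev)))
    for (bonds in combos) {
      nhit <- sum(vapply(bonds, function(bp)
        any(obs[, 1L] == bp[1L] & obs[, 2L] == bp[2L]), TRUE))
      if (nhit >= 2L) return(TRUE)
    }
    FALSE
  }
  hitidx <- which(vapply(.PAIR_DICT, match_dict, TRUE))
  if (length(hitidx)) {
    entry <- .PAIR_DICT[[hitidx[1L]]]
    type <- entry$type; subtype <- entry$subtype
  } else {
    type <- "noncanonical"; subtype <- "unclassified"
  }
  d1 <- dir_i %||% backbone_direction(res_i)
  d2 <- dir_j %||% backbone_direction(res_j)
  orientation <- if (is.null(d1) || is.null(d2)) NA_character_
  else if (sum(d1 * d2) > 0) "parallel" else "antiparallel"
  list(chain_i = res_i$chain[1L], resno_i = res_i$resno[1L],
       resid_i = res_i$resid[1L], chain_j = res_j$chain[1L],
       resno_j = res_j$resno[1L], resid_j = res_j$resid[1L],
       pair_type = type, subtype = subtype, orientation = orientation,
       n_hbonds = nrow(obs), plane_angle = axis_angle(ni, nj))
}

#' Find and classify all base pairs of a model
#'
#' @param model structure_model.
#' @param cutoff hydrogen-bond distance cutoff, Angstrom.
#' @param max_plane_angle coplanarity threshold, degrees.
#' @return data.frame of classified pairs (`pos_i < pos_j` in chain order)
#'   with the columns of [classify_pair()] plus `pos_i`, `pos_j`.
#' @export
find_base_pairs <- function(model, cutoff = 3.5, max_plane_angle = 35) {
  rt <- nucleotide_residues(model)
  hb <- find_base_hbonds(model, cutoff)
  empty <- data.frame(pos_i = integer(0), pos_j = integer(0),
                      chain_i = character(0), resno_i = integer(0),
                      resid_i = character(0), chain_j = character(0),
                      resno_j = integer(0), resid_j = character(0),
                      pair_type = character(0), subtype = character(0),
                      orientation = character(0), n_hbonds = integer(0),
                      plane_angle = numeric(0), stringsAsFactors = FALSE)
  if (!nrow(hb)) return(empty)
  lo <- pmin(hb$donor_pos, hb$acceptor_pos)
  hi <- pmax(hb$donor_pos, hb$acceptor_pos)
  keys <- unique(paste(lo, hi))
  out <- list()
  for (k in keys) {
    ij <- as.integer(strsplit(k, " ")[[1L]])
    sub <- hb[lo == ij[1L] & hi == ij[2L], , drop = FALSE]
    res_i <- get_residue(model, rt$chain[ij[1L]], rt$resno[ij[1L]],
                         rt$insert[ij[1L]])
    res_j <- get_residue(model, rt$chain[ij[2L]], rt$resno[ij[2L]],
                         rt$insert[ij[2L]])
    cp <- classify_pair(res_i, res_j, sub, max_plane_angle,
                        dir_i = strand_direction(model, rt, ij[1L]),
                        dir_j = strand_direction(model, rt, ij[2L]))
    if (!is.null(cp))
      out[[length(out) + 1L]] <- c(list(pos_i = ij[1L], pos_j = ij[2L]), cp)
  }
  if (!length(out)) return(empty)
  do.call(rbind, lapply(out, function(x)
    as.data.frame(x, stringsAsFactors = FALSE)))
}

#' Flag pseudoknot (crossing) base pairs
#'
#' Two pairs (i, k) and (j, l), indexed by chain position, cross iff
#' i < j < k < l. All crossing pairs are flagged and grouped into minimal
#' mutually-crossing components.
#'
#' @param pairs data.frame with columns `pos_i`, `pos_j` (as from
#'   [find_base_pairs()]).
#' @return input with logical column `pseudoknot` and integer `knot_group`
#'   (`NA` for non-crossing pairs).
#' @export
detect_pseudoknots <- function(pairs) {
  n <- nrow(pairs)
  flag <- logical(n)
  parent <- seq_len(n)
  findp <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1L) for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
    i <- pairs$pos_i[a]; k <- pairs$pos_j[a]
    j <- pairs$pos_i[b]; l <- pairs$pos_j[b]
    if ((i < j && j < k && k < l) || (j < i && i < l && l < k)) {
      flag[a] <- flag[b] <- TRUE
      ra <- findp(a); rb <- findp(b)
      if (ra != rb) parent[rb] <- ra
    }
  }
  grp <- rep(NA_integer_, n)
  if (any(flag)) {
    roots <- vapply(which(flag), findp, 0L)
    grp[flag] <- as.integer(factor(roots))
  }
  pairs$pseudoknot <- flag
  pairs$knot_group <- grp
  pairs
}

#' Helix handedness from consecutive C1' atoms
#'
#' The screw sense of the C1' trace: with the helix axis (principal component
#' of the trace) oriented 5' to 3', a positive mean azimuthal progression
#' about the axis means right-handed (clockwise 5'->3', as in natural D-RNA),
#' negative left-handed (the mirror situation of L-RNA).
#' The mean virtual dihedral over C1'(n)..C1'(n+3) windows is reported as a
#' descriptive statistic (negative for right-handed nucleic-acid twists under
#' the IUPAC sign convention); mirroring flips both.
#'
#' @param c1_xyz n x 3 matrix of consecutive C1' positions in 5'->3' order
#'   (n >= 4), or a [structure_model] together with `chain`.
#' @param chain,resnos when `c1_xyz` is a model: chain id and optional residue
#'   numbers (defaults to all nucleotides of the chain, in numbering order).
#' @return list with `handedness` (`"right"`, `"left"` or `"undetermined"`)
#'   and `mean_virtual_dihedral` (degrees).
#' @export
helix_handedness <- function(c1_xyz, chain = NULL, resnos = NULL) {
  if (inherits(c1_xyz, "structure_model")) {
    model <- c1_xyz
    a <- model$atoms
    sel <- a$elety == "C1'" & a$polymer_class == "nucleotide"
    if (!is.null(chain)) sel <- sel & a$chain == chain
    if (!is.null(resnos)) sel <- sel & a$resno %in% resnos
    a <- a[sel, , drop = FALSE]
    a <- a[order(a$resno), , drop = FALSE]
    c1_xyz <- as.matrix(a[, c("x", "y", "z")])
  }
  if (nrow(c1_xyz) < 4L)
    return(list(handedness = "undetermined",
                mean_virtual_dihedral = NA_real_))
  tor <- vapply(seq_len(nrow(c1_xyz) - 3L), function(i)
    dihedral(c1_xyz[i, ], c1_xyz[i + 1L, ], c1_xyz[i + 2L, ],
             c1_xyz[i + 3L, ]), 0)
  # global helix axis from the principal component of the trace, oriented
  # 5'->3'; the sign of the mean azimuthal progression about that axis is the
  # screw sense (robust to per-residue phase wobble, and invariant under
  # reversal of traversal)
  n <- nrow(c1_xyz)
  X <- sweep(c1_xyz, 2L, colMeans(c1_xyz))
  ax <- svd(X)$v[, 1L]
  if (sum(ax * (c1_xyz[n, ] - c1_xyz[1L, ])) < 0) ax <- -ax
  e1 <- vunit(vcross(ax, if (abs(ax[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)))
  e2 <- vcross(ax, e1)
  ang <- atan2(X %*% e2, X %*% e1)
  dang <- diff(ang)
  dang <- ((dang + pi) %% (2 * pi)) - pi
  screw <- mean(dang)
  list(handedness = if (screw > 0) "right" else "left",
       mean_virtual_dihedral = mean(tor))
}

# handedness of a short stacked-pair run from base-pair step twists: for
# consecutive pairs the C1'-C1' vectors rotate about the local rise vector;
# a right-handed step rotates them by the right-hand rule
pair_step_handedness <- function(model, rt, pair_run) {
  c1 <- function(pos) atom_xyz(get_residue(model, rt$chain[pos],
                                           rt$resno[pos], rt$insert[pos]),
                               "C1'")
  twists <- c()
  for (r in seq_len(nrow(pair_run) - 1L)) {
    a1 <- c1(pair_run$pos_i[r]); b1 <- c1(pair_run$pos_j[r])
    a2 <- c1(pair_run$pos_i[r + 1L]); b2 <- c1(pair_run$pos_j[r + 1L])
    if (is.null(a1) || is.null(b1) || is.null(a2) || is.null(b2)) next
    rise <- (a2 + b2) / 2 - (a1 + b1) / 2
    v1 <- b1 - a1; v2 <- b2 - a2
    if (vnorm(rise) < 1e-6) next
    ax <- vunit(rise)
    # signed in-plane rotation of the pair vector about the rise
    p1 <- vunit(v1 - sum(v1 * ax) * ax)
    p2 <- vunit(v2 - sum(v2 * ax) * ax)
    twists <- c(twists, atan2(sum(vcross(p1, p2) * ax), sum(p1 * p2)) * DEG)
  }
  if (!length(twists))
    return(list(handedness = "undetermined", mean_step_twist = NA_real_))
  m <- mean(twists)
  list(handedness = if (m > 0) "right" else "left", mean_step_twist = m)
}

#' Secondary structure: pairs, helices, pseudoknots, dot-bracket
#'
#' @param model structure_model.
#' @param cutoff hydrogen-bond cutoff, Angstrom.
#' @return list with `pairs` (pseudoknot-flagged pair table), `helices`
#'   (stacked runs of >= 2 consecutive pairs, with handedness) and
#'   `dot_bracket` (one character per nucleotide; `()` nested, `[]` crossing).
#' @export
secondary_structure <- function(model, cutoff = 3.5) {
  rt <- nucleotide_residues(model)
  pairs <- detect_pseudoknots(find_base_pairs(model, cutoff))
  helices <- list()
  if (nrow(pairs) >= 2L) {
    ord <- order(pairs$pos_i)
    ps <- pairs[ord, , drop = FALSE]
    run <- 1L
    for (r in 2:nrow(ps)) {
      if (ps$pos_i[r] == ps$pos_i[r - 1L] + 1L &&
          ps$pos_j[r] == ps$pos_j[r - 1L] - 1L) {
        run <- run + 1L
      } else {
        if (run >= 2L) helices[[length(helices) + 1L]] <- ps[(r - run):(r - 1L), ]
        run <- 1L
      }
    }
    if (run >= 2L)
      helices[[length(helices) + 1L]] <- ps[(nrow(ps) - run + 1L):nrow(ps), ]
    helices <- lapply(helices, function(h) {
      hd <- pair_step_handedness(model, rt, h)
      list(pairs = h, handedness = hd$handedness,
           mean_step_twist = hd$mean_step_twist)
    })
  }
  db <- rep(".", nrow(rt))
  if (nrow(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      br <- if (isTRUE(pairs$pseudoknot[r])) c("[", "]") else c("(", ")")
      db[pairs$pos_i[r]] <- br[1L]
      db[pairs$pos_j[r]] <- br[2L]
    }
  }
  list(pairs = pairs, helices = helices,
       dot_bracket = paste(db, collapse = ""))
}
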