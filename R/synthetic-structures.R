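#' Synthetic structural fixtures
#'
#' Desk-scale generators for every geometric object the pipeline analyses:
#' sugar rings at prescribed pseudorotation states, idealized planar bases,
#' complete ribonucleotides, single-stranded and duplex A-form helices and
#' their exact mirror images, and ion coordination shells. These are
#' statistical/geometric stand-ins, not reconstructions of any particular
#' deposited fold.
#'
#' @name synthetic_data
NULL

# Internal-coordinate constants calibrated once against ideal D-ribonucleotide
# geometry. Signs encode D-chirality: mirroring the finished model yields L.
.RIB <- list(
  ring_names = c("C1'", "C2'", "C3'", "C4'", "O4'"),
  ring_bonds = c(1.526, 1.525, 1.523, 1.452, 1.414), # C1'C2',C2'C3',C3'C4',C4'O4',O4'C1'
  ring_angle0 = 104.5,                               # reference endocyclic angle
  c5_bond = 1.529, c5_angle = 110.5, c5_offset = 119, # C5' off nu3, D sign +
  o2_bond = 1.429, o2_angle = 112.0, o2_offset = 119, # O2' off C4'-C3'-C2'-C1'
  o3_bond = 1.428, o3_angle = 110.5, o3_offset = -119, # O3' off nu2
  glyc_bond = 1.465, glyc_angle = 110.4               # C1'-N, O4'/C2'-C1'-N
)

#' Build a ribose ring at a prescribed pseudorotation state
#'
#' Constructs a five-membered sugar ring whose endocyclic torsions follow
#' `nu_j = tau_m * cos(P + j * 144)`, j = 0..4, by least-squares ring closure:
#' bond lengths are held fixed, bond angles are restrained near their reference
#' value and the five torsions are driven to the targets. The residual torsion
#' error must not exceed 0.5 degrees or an error is raised. Exocyclic C5', O2'
#' and O3' are attached with D-ribose stereochemistry, so
#' [detect_chirality()] reports D by construction; mirror the model for L.
#'
#' @param P pseudorotation phase, degrees.
#' @param tau_m puckering amplitude, degrees, in (0, 60].
#' @param resid residue name for the emitted nucleotide (default `"U"`).
#' @return a [structure_model] holding one nucleotide (sugar only, no base).
#' @export
build_sugar_ring <- function(P, tau_m, resid = "U") {
  xyz <- solve_sugar_ring(P, tau_m)
  sug <- attach_exocyclic(xyz)
  atoms <- data.frame(elety = rownames(sug), resid = resid, chain = "A",
                      resno = 1L, x = sug[, 1L], y = sug[, 2L], z = sug[, 3L],
                      elesy = ifelse(substr(rownames(sug), 1L, 1L) == "O",
                                     "O", "C"),
                      stringsAsFactors = FALSE)
  new_structure_model(atoms, metadata = list(P = P, tau_m = tau_m))
}

# Ring-closure least squares over the 5 ring atom coordinates.
solve_sugar_ring <- function(P, tau_m) {
  if (!is.finite(tau_m) || tau_m <= 0 || tau_m > 60)
    stop("tau_m must lie in (0, 60] degrees")
  # Altona-Sundaralingam convention: nu2 = tau_m cos P
  nu_t <- tau_m * cos((P + 144 * ((0:4) - 2)) / DEG)
  b0 <- .RIB$ring_bonds
  a0 <- .RIB$ring_angle0

  # init: flat regular pentagon + out-of-plane displacement in pucker phase
  r0 <- mean(b0) / (2 * sin(pi / 5))
  ang <- (90 + 72 * (0:4)) / DEG
  init <- cbind(r0 * cos(ang), r0 * sin(ang),
                0.35 * (tau_m / 40) * cos((P + 90 + 144 * (0:4)) / DEG))

  # atoms in ring order C1' C2' C3' C4' O4'; torsion nu_j is about bond
  # (j+1, j+2) using atoms (j, j+1, j+2, j+3) with the wrap C4'-O4'-C1'-C2'
  resfun <- function(par) {
    p <- matrix(par, ncol = 3L)
    idx <- function(i) ((i - 1L) %% 5L) + 1L
    bonds <- vapply(1:5, function(i) vnorm(p[idx(i + 1), ] - p[i, ]), 0)
    angs <- vapply(1:5, function(i)
      vec_angle(p[idx(i - 1 + 5), ], p[i, ], p[idx(i + 1), ]), 0)
    nus <- vapply(0:4, function(j)
      dihedral(p[idx(j + 5), ], p[idx(j + 1 + 5), ],
               p[idx(j + 2 + 5), ], p[idx(j + 3 + 5), ]), 0)
    # the j-loop above yields torsions in order (nu1, nu2, nu3, nu4, nu0)
    c(100 * (bonds - b0), 0.02 * (angs - a0),
      10 * (nus - nu_t[c(2, 3, 4, 5, 1)]))
  }
  fit <- minpack.lm::nls.lm(par = as.numeric(init), fn = resfun,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-14, ptol = 1e-14))
  p <- matrix(fit$par, ncol = 3L)
  rownames(p) <- .RIB$ring_names
  nus <- ring_torsions(p)
  err <- max(abs(((nus - nu_t + 180) %% 360) - 180))
  if (err > 0.5)
    stop(sprintf("ring closure did not converge: torsion residual %.2f deg", err))
  p
}

# endocyclic torsions nu0..nu4 from a named ring coordinate matrix
ring_torsions <- function(p) {
  g <- function(n) p[n, ]
  c(dihedral(g("C4'"), g("O4'"), g("C1'"), g("C2'")),
    dihedral(g("O4'"), g("C1'"), g("C2'"), g("C3'")),
    dihedral(g("C1'"), g("C2'"), g("C3'"), g("C4'")),
    dihedral(g("C2'"), g("C3'"), g("C4'"), g("O4'")),
    dihedral(g("C3'"), g("C4'"), g("O4'"), g("C1'")))
}

attach_exocyclic <- function(ring) {
  g <- function(n) ring[n, ]
  nu2 <- dihedral(g("C1'"), g("C2'"), g("C3'"), g("C4'"))
  nu3 <- dihedral(g("C2'"), g("C3'"), g("C4'"), g("O4'"))
  rev2 <- dihedral(g("C4'"), g("C3'"), g("C2'"), g("C1'"))
  C5 <- place_atom(g("C2'"), g("C3'"), g("C4'"), .RIB$c5_bond, .RIB$c5_angle,
                   nu3 + .RIB$c5_offset)
  O2 <- place_atom(g("C4'"), g("C3'"), g("C2'"), .RIB$o2_bond, .RIB$o2_angle,
                   rev2 + .RIB$o2_offset)
  O3 <- place_atom(g("C1'"), g("C2'"), g("C3'"), .RIB$o3_bond, .RIB$o3_angle,
                   nu2 + .RIB$o3_offset)
  out <- rbind(ring, "C5'" = C5, "O2'" = O2, "O3'" = O3)
  out
}

# --- planar base templates --------------------------------------------------

# Idealized planar bases built from fused regular polygons (bond ~1.38 A).
# Frame convention: base in the z = 0 plane, glycosidic nitrogen at the
# origin, the ring system on the +y side (so the C1' direction is -y).
base_template <- function(base) {
  base <- toupper(base)
  hex_names <- c("N1", "C2", "N3", "C4", "C5", "C6")
  s <- 1.38
  ctr <- c(0, s, 0)
  hex <- t(vapply(0:5, function(k) {
    a <- (-90 + 60 * k) / DEG
    ctr + s * c(cos(a), sin(a), 0)
  }, numeric(3)))
  rownames(hex) <- hex_names
  exo <- function(v, bond) {
    d <- vunit(v - ctr)
    v + bond * d
  }
  if (base %in% c("C", "U")) {
    m <- hex
    m <- rbind(m, O2 = exo(hex["C2", ], 1.23))
    if (base == "C") m <- rbind(m, N4 = exo(hex["C4", ], 1.34))
    if (base == "U") m <- rbind(m, O4 = exo(hex["C4", ], 1.23))
    # ring sense matched to the purine template so that the flipped
    # (antiparallel) partner presents a compatible Watson-Crick edge
    m[, 1L] <- -m[, 1L]
    glyc <- "N1"
  } else if (base %in% c("A", "G")) {
    # pentagon fused on the C4-C5 edge, on the side away from the hexagon
    e1 <- hex["C4", ]; e2 <- hex["C5", ]
    mid <- (e1 + e2) / 2
    outdir <- vunit(mid - ctr)
    apo <- s / (2 * tan(pi / 5))
    r5 <- s / (2 * sin(pi / 5))
    c5 <- mid + apo * outdir
    # pentagon vertices at angles measured from c5; two are C4/C5
    a0 <- atan2(e1[2] - c5[2], e1[1] - c5[1])
    a1 <- atan2(e2[2] - c5[2], e2[1] - c5[1])
    # walk from C4 away from C5 around the pentagon: N9, C8, N7
    step <- 2 * pi / 5
    dir5 <- if (((a0 - a1) %% (2 * pi)) < pi) 1 else -1
    penta <- t(vapply(1:3, function(k) {
      a <- a0 + dir5 * step * k
      c5 + r5 * c(cos(a), sin(a), 0)
    }, numeric(3)))
    rownames(penta) <- c("N9", "C8", "N7")
    m <- rbind(hex, penta)
    exo5 <- function(v, bond) v + bond * vunit(v - c5)
    if (base == "A") m <- rbind(m, N6 = exo(hex["C6", ], 1.34))
    if (base == "G") m <- rbind(m, O6 = exo(hex["C6", ], 1.23),
                                N2 = exo(hex["C2", ], 1.34))
    glyc <- "N9"
    # re-seat frame on N9
    m <- sweep(m, 2L, m["N9", ])
    ctr2 <- colMeans(m[c(hex_names, "N9", "C8", "N7"), ])
    ang <- atan2(ctr2[1], ctr2[2]) # rotate so centroid sits on +y
    R <- rotation_about(c(0, 0, 1), ang * DEG)
    m <- m %*% t(R)
    return(structure(m, glyc = glyc))
  } else stop("invalid base: ", base)
  structure(m, glyc = glyc)
}

# donor/acceptor chemistry of base edges (heavy atoms only)
.BASE_DONORS <- list(A = "N6", C = "N4", G = c("N1", "N2"), U = "N3")
.BASE_ACCEPTORS <- list(A = c("N1", "N3", "N7"), C = c("O2", "N3"),
                        G = c("O6", "N3", "N7"), U = c("O2", "O4"))
.BASE_RING6 <- c("N1", "C2", "N3", "C4", "C5", "C6")
.BASE_RING5 <- c("C4", "C5", "N7", "C8", "N9")

# canonical hydrogen-bond dictionaries (first name on base i, second on j)
.PAIR_DICT <- list(
  list(bases = c("G", "C"), type = "watson_crick", subtype = "GC Watson-Crick",
       bonds = list(c("O6", "N4"), c("N1", "N3"), c("N2", "O2"))),
  list(bases = c("A", "U"), type = "watson_crick", subtype = "AU Watson-Crick",
       bonds = list(c("N6", "O4"), c("N1", "N3"))),
  list(bases = c("A", "U"), type = "hoogsteen", subtype = "AU Hoogsteen",
       bonds = list(c("N7", "N3"), c("N6", "O4"))),
  list(bases = c("G", "C"), type = "hoogsteen", subtype = "GC+ Hoogsteen",
       bonds = list(c("N7", "N3"), c("O6", "N4"))),
  list(bases = c("G", "G"), type = "noncanonical",
       subtype = "GG N7-N1 carbonyl-amino",
       bonds = list(c("N7", "N1"), c("O6", "N2"))),
  list(bases = c("G", "A"), type = "noncanonical",
       subtype = "GA N3-amino amino-N1",
       bonds = list(c("N3", "N6"), c("N2", "N1"))),
  list(bases = c("G", "U"), type = "noncanonical", subtype = "GU wobble",
       bonds = list(c("O6", "N3"), c("N1", "O2")))
)

#' Build a complete ribonucleotide in the base frame
#'
#' Planar idealized base plus a sugar at the requested pucker, attached at the
#' requested glycosidic torsion with D stereochemistry, plus an approximate
#' 5' backbone (O5', P, OP1, OP2).
#'
#' @param base one of `"A"`, `"C"`, `"G"`, `"U"`.
#' @param chi glycosidic torsion, degrees (default -160, anti).
#' @param P,tau_m sugar pucker (defaults: C3'-endo, 38 deg).
#' @return named coordinate matrix (rows are atom names).
#' @keywords internal
build_nucleotide_frame <- function(base, chi = -160, P = 18, tau_m = 38) {
  bt <- base_template(base)
  glyc <- attr(bt, "glyc")
  N <- bt[glyc, ]
  if (glyc == "N9") {
    ringA <- bt["C4", ]; ringB <- bt["C8", ]; cref <- bt["C4", ]
  } else {
    ringA <- bt["C2", ]; ringB <- bt["C6", ]; cref <- bt["C2", ]
  }
  dirc <- -vunit(vunit(ringA - N) + vunit(ringB - N))
  C1 <- N + .RIB$glyc_bond * dirc

  ring <- solve_sugar_ring(P, tau_m)
  sug <- attach_exocyclic(ring)
  th1 <- vec_angle(sug["O4'", ], sug["C1'", ], sug["C2'", ])

  O4t <- place_atom(cref, N, C1, vnorm(sug["O4'", ] - sug["C1'", ]),
                    .RIB$glyc_angle, chi)
  c2_at <- function(delta) place_atom(cref, N, C1,
                                      vnorm(sug["C2'", ] - sug["C1'", ]),
                                      .RIB$glyc_angle, chi + delta)
  f <- function(delta) vec_angle(O4t, C1, c2_at(delta)) - th1
  # two mirror solutions +/- delta; pick the D branch (positive triple product)
  delta <- tryCatch(stats::uniroot(f, c(5, 175))$root, error = function(e) NA)
  if (is.na(delta)) stop("glycosidic attachment failed")
  pick <- function(d) {
    C2 <- c2_at(d)
    sv <- sum(vcross(O4t - C1, C2 - C1) * (N - C1))
    list(C2 = C2, sv = sv)
  }
  s1 <- pick(delta); s2 <- pick(-delta)
  C2t <- if (s1$sv > 0) s1$C2 else s2$C2

  # rigid-place the sugar by its (C1', O4', C2') triad
  src <- rbind(sug["C1'", ], sug["O4'", ], sug["C2'", ])
  dst <- rbind(C1, O4t, C2t)
  tr <- kabsch_fit(src, dst)
  sug2 <- sweep(sug %*% t(tr$R), 2L, tr$t, "+")

  g <- function(n) sug2[n, ]
  O5 <- place_atom(g("C3'"), g("C4'"), g("C5'"), 1.423, 111.0, 54)
  Pp <- place_atom(g("C4'"), g("C5'"), O5, 1.600, 120.0, 180)
  OP1 <- place_atom(g("C5'"), O5, Pp, 1.485, 108.0, 60)
  OP2 <- place_atom(g("C5'"), O5, Pp, 1.485, 108.0, -60)
  rbind(P = Pp, OP1 = OP1, OP2 = OP2, "O5'" = O5, sug2, bt)
}

nucleotide_to_atoms <- function(m, base, chain, resno) {
  nm <- rownames(m)
  data.frame(elety = nm, resid = base, chain = chain, resno = resno,
             x = m[, 1L], y = m[, 2L], z = m[, 3L],
             elesy = substr(nm, 1L, 1L), stringsAsFactors = FALSE)
}

# standard in-helix placement of the base frame (axis = z through origin);
# the base extends outward from the axis so that successive stacked residues
# keep realistic (non-hydrogen-bonding) separations
helix_seat <- function(m, radius = 6) {
  R <- rotation_about(c(0, 0, 1), -90)
  m2 <- m %*% t(R)
  m2[, 1L] <- m2[, 1L] + radius
  m2
}

#' Rigid placement of a paired partner base
#'
#' Finds the rigid in-plane transform (after the 180-degree flip about x that
#' turns the partner over) placing `frame2` against the seated `frame1` so the
#' listed donor-acceptor pairs sit at the target distance. Deterministic
#' coarse-grid search followed by a quasi-Newton polish.
#' @keywords internal
pair_partner_transform <- function(seated1, frame2, bonds, target = 2.90) {
  flip <- diag(c(1, -1, -1))
  f2 <- frame2 %*% t(flip)
  nm1 <- rownames(seated1); nm2 <- rownames(f2)
  i1 <- match(vapply(bonds, `[`, "", 1L), nm1)
  i2 <- match(vapply(bonds, `[`, "", 2L), nm2)
  if (anyNA(i1) || anyNA(i2)) stop("bond atoms absent from base templates")
  obj <- function(par) {
    R <- rotation_about(c(0, 0, 1), par[1L])
    p2 <- sweep(f2 %*% t(R), 2L, c(par[2L], par[3L], 0), "+")
    d <- sqrt(rowSums((seated1[i1, , drop = FALSE] -
                         p2[i2, , drop = FALSE])^2))
    dd <- sqrt(pmax(outer(rowSums(seated1^2), rowSums(p2^2), "+") -
                      2 * seated1 %*% t(p2), 0))
    dd[cbind(i1, i2)] <- Inf
    pen <- 0.25 * sum(pmax(0, 2.8 - dd)^2)
    4 * sum((d - target)^2) + pen
  }
  # analytic initialization: anti-align the two edges, then separate the edge
  # centroids by the bond target along the outward edge normal
  edge1 <- seated1[i1, , drop = FALSE]
  edge2 <- f2[i2, , drop = FALSE]
  e1 <- colMeans(edge1); e2 <- colMeans(edge2)
  d1 <- vunit((e1 - colMeans(seated1)) * c(1, 1, 0))
  tan1 <- if (nrow(edge1) > 1L)
    vunit((edge1[nrow(edge1), ] - edge1[1L, ]) * c(1, 1, 0))
  else vcross(c(0, 0, 1), d1)
  tan2 <- if (nrow(edge2) > 1L)
    vunit((edge2[nrow(edge2), ] - edge2[1L, ]) * c(1, 1, 0))
  else vcross(c(0, 0, 1), vunit((e2 - colMeans(f2)) * c(1, 1, 0)))
  th0 <- (atan2(tan1[2L], tan1[1L]) - atan2(tan2[2L], tan2[1L])) * DEG
  best <- NULL
  for (dth in c(0, -15, 15)) for (gap in c(target, target + 0.5)) {
    R0 <- rotation_about(c(0, 0, 1), th0 + dth)
    t0 <- e1 + gap * d1 - as.numeric(R0 %*% e2)
    v <- c(th0 + dth, t0[1L], t0[2L])
    val <- obj(v)
    if (is.null(best) || val < best$val) best <- list(par = v, val = val)
  }
  opt <- stats::optim(best$par, obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  R <- rotation_about(c(0, 0, 1), opt$par[1L])
  list(R = R %*% flip, t = c(opt$par[2L], opt$par[3L], 0),
       value = opt$value)
}

.RNA_COMPLEMENT <- c(A = "U", U = "A", G = "C", C = "G")

#' Build an ideal A-form helix fixture (D or exact mirror-image L)
#'
#' Places fixed internal template nucleotides by helical twist and rise about
#' the z axis; all sugars are C3'-endo by construction and the D form is a
#' right-handed (5'->3' clockwise) helix. `chirality = "L"` applies
#' [mirror_structure()] to the finished D model, so all interatomic distances
#' are identical between the two forms. With `duplex = TRUE` a Watson-Crick
#' complementary strand (chain B, antiparallel) is added.
#'
#' @param sequence string over A, C, G, U (length >= 2), 5' to 3'.
#' @param twist helical twist, degrees per step, in (0, 60].
#' @param rise helical rise, Angstrom per step.
#' @param chirality `"D"` or `"L"`.
#' @param duplex also build the complementary strand?
#' @param chi glycosidic torsion of every residue, degrees.
#' @return a [structure_model]; strand A is chain `"A"`, the complement `"B"`.
#' @export
build_aform_helix <- function(sequence, twist = 32.7, rise = 2.81,
                              chirality = c("D", "L"), duplex = FALSE,
                              chi = -160) {
  chirality <- match.arg(chirality)
  seqv <- strsplit(toupper(sequence), "")[[1L]]
  if (length(seqv) < 2L) stop("sequence must have length >= 2")
  if (!all(seqv %in% c("A", "C", "G", "U")))
    stop("invalid sequence character: ",
         paste(setdiff(seqv, c("A", "C", "G", "U")), collapse = ""))
  if (!is.finite(twist) || twist <= 0 || twist > 60)
    stop("twist must lie in (0, 60] degrees per step")
  n <- length(seqv)

  frames <- list()
  for (b in unique(c(seqv, if (duplex) unname(.RNA_COMPLEMENT[seqv]))))
    frames[[b]] <- build_nucleotide_frame(b, chi = chi)
  glyc_of <- function(m) if ("N9" %in% rownames(m)) "N9" else "N1"

  # per pair type: solve the partner placement against the bare base, then
  # normalize into a standard pair frame (glycosidic-N line along x, pair
  # midpoint displaced off the helix axis) so both strands trace one helix
  y_disp <- 4.0
  placed <- list()
  if (duplex) {
    base_sub <- function(m) m[rownames(m) %in%
                                c(.BASE_RING6, .BASE_RING5, "O6", "N6",
                                  "N2", "O2", "O4", "N4"), , drop = FALSE]
    for (b in unique(seqv)) {
      comp <- .RNA_COMPLEMENT[[b]]
      dict <- Filter(function(d) d$type == "watson_crick" &&
                       setequal(d$bases, c(b, comp)), .PAIR_DICT)[[1L]]
      bonds <- dict$bonds
      if (dict$bases[1L] != b) bonds <- lapply(bonds, rev)
      tr <- pair_partner_transform(base_sub(frames[[b]]), frames[[comp]],
                                   bonds)
      m1 <- frames[[b]]
      m2 <- sweep(frames[[comp]] %*% t(tr$R), 2L, tr$t, "+")
      n1 <- m1[glyc_of(m1), ]; n2 <- m2[glyc_of(m2), ]
      mid <- (n1 + n2) / 2
      u <- vunit((n1 - mid) * c(1, 1, 0))
      Rf <- rotation_about(c(0, 0, 1), -atan2(u[2L], u[1L]) * DEG)
      tf <- c(0, y_disp, 0)
      seat <- function(m) sweep(sweep(m, 2L, mid) %*% t(Rf), 2L, tf, "+")
      placed[[b]] <- list(a = seat(m1), b = seat(m2))
    }
  } else {
    for (b in unique(seqv))
      placed[[b]] <- list(a = helix_seat(frames[[b]]))
  }

  rows <- list()
  for (k in seq_len(n)) {
    b <- seqv[k]
    Rk <- rotation_about(c(0, 0, 1), (k - 1L) * twist)
    tk <- c(0, 0, (k - 1L) * rise)
    mA <- sweep(placed[[b]]$a %*% t(Rk), 2L, tk, "+")
    rows[[length(rows) + 1L]] <- nucleotide_to_atoms(mA, b, "A", k)
    if (duplex) {
      comp <- .RNA_COMPLEMENT[[b]]
      mB <- sweep(placed[[b]]$b %*% t(Rk), 2L, tk, "+")
      rows[[length(rows) + 1L]] <- nucleotide_to_atoms(mB, comp, "B", n - k + 1L)
    }
  }
  atoms <- do.call(rbind, rows)
  atoms <- atoms[order(atoms$chain, atoms$resno), , drop = FALSE]
  atoms$eleno <- seq_len(nrow(atoms))
  model <- new_structure_model(atoms,
                               metadata = list(twist = twist, rise = rise,
                                               chirality = chirality,
                                               sequence = sequence))
  if (chirality == "L") model <- mirror_structure(model)
  model
}

#' Mirror a structure (x -> -x)
#'
#' A single reflection through the yz plane: an exact involution that preserves
#' every interatomic distance and negates every proper dihedral, converting
#' D-nucleotides to L and flipping helix handedness.
#'
#' @param model structure_model.
#' @return mirrored structure_model.
#' @export
mirror_structure <- function(model) {
  xyz <- coords(model)
  xyz[, 1L] <- -xyz[, 1L]
  model <- set_coords(model, xyz)
  model$metadata$chirality <- switch(model$metadata$chirality %||% "",
                                     D = "L", L = "D",
                                     model$metadata$chirality)
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build an ion coordination-shell fixture
#'
#' One ion at the origin surrounded by water oxygens at the given distances,
#' either on the six octahedral axes (recycled over the distance list) or on
#' deterministic irregular directions (golden-angle spiral).
#'
#' @param ion_element element symbol (e.g. `"SR"`, `"MG"`).
#' @param distances ligand distances, Angstrom (> 0).
#' @param geometry `"octahedral"` or `"irregular"` (alias `"random"`).
#' @return a [structure_model] with the ion plus `length(distances)` waters.
#' @export
build_ion_shell <- function(ion_element, distances,
                            geometry = c("octahedral", "irregular", "random")) {
  geometry <- match.arg(geometry)
  if (any(!is.finite(distances) | distances <= 0))
    stop("all ligand distances must be positive")
  n <- length(distances)
  dirs <- if (geometry == "octahedral") {
    ax <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
    ax[((seq_len(n) - 1L) %% 6L) + 1L, , drop = FALSE]
  } else {
    sphere_points(max(n, 3L))[seq_len(n), , drop = FALSE]
  }
  lig <- dirs * distances
  el <- toupper(ion_element)
  atoms <- data.frame(
    elety = c(el, rep("O", n)),
    resid = c(el, rep("HOH", n)),
    chain = c("I", rep("W", n)),
    resno = c(1L, seq_len(n) + 1L),
    x = c(0, lig[, 1L]), y = c(0, lig[, 2L]), z = c(0, lig[, 3L]),
    elesy = c(el, rep("O", n)), stringsAsFactors = FALSE)
  new_structure_model(atoms, metadata = list(geometry = geometry))
}
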