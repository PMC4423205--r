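# shared fixture builders: all test structures are generated in code

# one residue's atoms as a data.frame; `atoms` is a named list of 3-vectors
mk_res <- function(chain, resno, resid, atoms) {
  do.call(rbind, lapply(seq_along(atoms), function(i)
    data.frame(elety = names(atoms)[i], resid = resid, chain = chain,
               resno = resno, x = atoms[[i]][1], y = atoms[[i]][2],
               z = atoms[[i]][3], elesy = substr(names(atoms)[i], 1, 1),
               stringsAsFactors = FALSE)))
}

# small non-collinear polypeptide trace
mk_toy_protein <- function(chain = "A", n = 12, offset = c(0, 0, 0)) {
  do.call(rbind, lapply(seq_len(n), function(i) {
    base <- c(3 * i, 2 * sin(i), cos(2 * i)) + offset
    mk_res(chain, i, c("ALA", "ARG", "SER", "GLY")[(i %% 4) + 1],
           list(N = base, CA = base + c(1, 0.5, 0.3), C = base + c(2, 0, 0),
                O = base + c(2, 1.2, 0.4)))
  }))
}

# parametric helix point trace
helix_points <- function(r, twist_deg, rise, n = 8) {
  t(sapply(0:(n - 1), function(k)
    c(r * cos(k * twist_deg / 180 * pi), r * sin(k * twist_deg / 180 * pi),
      k * rise)))
}

# independent dihedral oracle: signed angle between plane normals
dihedral_oracle <- function(p1, p2, p3, p4) {
  n1 <- pracma_cross(p2 - p1, p3 - p2)
  n2 <- pracma_cross(p3 - p2, p4 - p3)
  cosang <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  ang <- acos(max(-1, min(1, cosang))) * 180 / pi
  # IUPAC sign: clockwise viewed along the central bond is positive, which
  # is a NEGATIVE right-handed rotation of n1 into n2 about p3 - p2
  s <- -sign(sum(pracma_cross(n1, n2) * (p3 - p2)))
  if (s < 0) -ang else ang
}
pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# independent quaternion-method superposition oracle (Horn): the optimal
# rmsd from the largest eigenvalue of the 4x4 key matrix, no rotation built
quaternion_rmsd <- function(a, b) {
  A <- sweep(a, 2, colMeans(a)); B <- sweep(b, 2, colMeans(b))
  S <- t(A) %*% B
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[1, 3] + S[3, 1]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  lmax <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  sqrt(max((sum(A^2) + sum(B^2) - 2 * lmax) / nrow(a), 0))
}

# brute-force crossing enumeration oracle for pseudoknot detection
crossings_oracle <- function(pos_i, pos_j) {
  n <- length(pos_i)
  flag <- logical(n)
  if (n > 1) for (a in 1:(n - 1)) for (b in (a + 1):n) {
    i <- pos_i[a]; k <- pos_j[a]; j <- pos_i[b]; l <- pos_j[b]
    if ((i < j && j < k && k < l) || (j < i && i < l && l < k))
      flag[a] <- flag[b] <- TRUE
  }
  flag
}

# engineered base pair: two full nucleotides placed so the named donor ->
# acceptor atom pairs (on base i -> base j) sit near 2.9 A
mk_engineered_pair <- function(base_i, base_j, bonds, chain = "A",
                               resno_i = 1, resno_j = 10) {
  fr1 <- spiegelmer:::build_nucleotide_frame(base_i)
  fr2 <- spiegelmer:::build_nucleotide_frame(base_j)
  sub <- function(m) m[rownames(m) %in%
                         c(spiegelmer:::.BASE_RING6, spiegelmer:::.BASE_RING5,
                           "O6", "N6", "N2", "O2", "O4", "N4"), , drop = FALSE]
  tr <- spiegelmer:::pair_partner_transform(sub(fr1), fr2, bonds)
  m2 <- sweep(fr2 %*% t(tr$R), 2, tr$t, "+")
  at <- rbind(
    spiegelmer:::nucleotide_to_atoms(fr1, base_i, chain, resno_i),
    spiegelmer:::nucleotide_to_atoms(m2, base_j, chain, resno_j))
  new_structure_model(at)
}

# ATOM record writer for hand-crafted PDB text fixtures (altloc tests)
pdb_atom_line <- function(serial, name, alt, resn, chain, resno, x, y, z,
                          o = 1, b = 0, elem = substr(name, 1, 1)) {
  paste0("ATOM  ", sprintf("%5d", serial), " ", sprintf(" %-3s", name), alt,
         sprintf("%3s", resn), " ", chain, sprintf("%4d", resno), "    ",
         sprintf("%8.3f%8.3f%8.3f%6.2f%6.2f", x, y, z, o, b),
         "          ", sprintf("%2s", elem))
}
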