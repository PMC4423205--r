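test_that("dihedral follows the IUPAC convention and matches an independent formula", {
  expect_equal(dihedral(c(1, 1, 0), c(0, 1, 0), c(0, 0, 0), c(1, 0, 0)), 0)
  expect_equal(abs(dihedral(c(-1, 1, 0), c(0, 1, 0), c(0, 0, 0), c(1, 0, 0))),
               180)
  set.seed(11)
  for (k in 1:25) {
    p <- lapply(1:4, function(i) rnorm(3) * 3)
    d1 <- dihedral(p[[1]], p[[2]], p[[3]], p[[4]])
    d2 <- dihedral_oracle(p[[1]], p[[2]], p[[3]], p[[4]])
    expect_lt(abs(d1 - d2), 1e-9)
    # mirroring negates
    pm <- lapply(p, function(v) v * c(-1, 1, 1))
    expect_lt(abs(dihedral(pm[[1]], pm[[2]], pm[[3]], pm[[4]]) + d1), 1e-9)
  }
  expect_error(dihedral(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)),
               "torsion")
  expect_error(dihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "torsion")
})

test_that("sugar chirality is detected as D for built rings, L for mirrors", {
  m <- build_aform_helix("GCGC")
  for (i in 1:4) {
    expect_equal(detect_chirality(get_residue(m, "A", i))$label, "D")
  }
  mm <- mirror_structure(m)
  for (i in 1:4) {
    ch <- detect_chirality(get_residue(mm, "A", i))
    expect_equal(ch$label, "L")
    expect_lt(ch$signed_volume, -0.1)
  }
  # missing sugar atoms -> undetermined with a warning
  res <- get_residue(m, "A", 1)
  expect_warning(out <- detect_chirality(res[res$elety != "C5'", ]),
                 "missing")
  expect_equal(out$label, "undetermined")
})

test_that("chi classification uses the corrected torsion and is mirror-invariant", {
  syn <- new_structure_model(spiegelmer:::nucleotide_to_atoms(
    spiegelmer:::build_nucleotide_frame("A", chi = 30), "A", "A", 1))
  anti <- new_structure_model(spiegelmer:::nucleotide_to_atoms(
    spiegelmer:::build_nucleotide_frame("A", chi = 180), "A", "A", 1))
  expect_equal(chi_torsion(get_residue(syn, "A", 1))$glycosidic_class, "syn")
  ct <- chi_torsion(get_residue(anti, "A", 1))
  expect_equal(ct$glycosidic_class, "anti")
  expect_lt(abs(abs(ct$chi) - 180), 1e-6)
  # mirrored residue: chi negates, class unchanged
  for (chi0 in c(-160, -100, 30, 85)) {
    m <- new_structure_model(spiegelmer:::nucleotide_to_atoms(
      spiegelmer:::build_nucleotide_frame("G", chi = chi0), "G", "A", 1))
    mm <- mirror_structure(m)
    a <- chi_torsion(get_residue(m, "A", 1))
    b <- chi_torsion(get_residue(mm, "A", 1))
    expect_lt(abs(a$chi + b$chi), 1e-6)
    expect_equal(a$glycosidic_class, b$glycosidic_class)
    expect_equal(b$chirality, "L")
  }
})

test_that("pseudorotation recovers built pucker states and bin labels", {
  # identity round trip across the full phase wheel
  for (P in seq(0, 342, by = 18)) {
    m <- build_sugar_ring(P, 38)
    pk <- pseudorotation(get_residue(m, "A", 1), chirality = "D")
    expect_lt(abs(((pk$P - P + 180) %% 360) - 180), 1)
    expect_lt(abs(pk$tau_m - 38), 1)
  }
  # named bin examples
  lab <- function(P) pseudorotation(get_residue(build_sugar_ring(P, 40),
                                                "A", 1),
                                    chirality = "D")$raw_label
  expect_equal(lab(18), "C3'-endo")
  expect_equal(lab(162), "C2'-endo")
  expect_equal(lab(198), "C3'-exo")
  expect_equal(lab(126), "C1'-exo")
  expect_equal(lab(54), "C4'-exo")
})

test_that("negating ring torsions shifts the phase by exactly 180 degrees", {
  m <- build_sugar_ring(18, 40)
  res <- get_residue(m, "A", 1)
  pk <- pseudorotation(res, chirality = "D")
  mm <- mirror_structure(m)
  pkm <- pseudorotation(get_residue(mm, "A", 1), chirality = "L")
  expect_lt(abs(pkm$nu + pk$nu)[which.max(abs(pkm$nu + pk$nu))], 1e-9)
  expect_lt(abs(((pkm$P - pk$P - 180) %% 360 + 180) %% 360 - 180), 1e-6)
  # endo/exo inversion: raw flips, corrected label equals the D label
  expect_equal(pk$raw_label, "C3'-endo")
  expect_equal(pkm$raw_label, "C3'-exo")
  expect_equal(pkm$corrected_label, "C3'-endo")
})

test_that("near-planar rings are reported undetermined, not mislabelled", {
  m <- build_sugar_ring(18, 3 + 1e-9)
  pk <- pseudorotation(get_residue(m, "A", 1), chirality = "D")
  expect_equal(pk$raw_label, "undetermined")
})

test_that("nucleotide_geometry reports every nucleotide with consistent fields", {
  m <- build_aform_helix("GAUC", duplex = TRUE)
  geo <- nucleotide_geometry(m)
  expect_equal(nrow(geo), 8L)
  expect_true(all(geo$chirality == "D"))
  expect_true(all(geo$pucker == "C3'-endo"))
  expect_true(all(geo$glycosidic_class == "anti"))
  geoL <- nucleotide_geometry(mirror_structure(m))
  expect_true(all(geoL$chirality == "L"))
  expect_true(all(geoL$raw_pucker == "C3'-exo"))
  expect_true(all(geoL$pucker == "C3'-endo"))
})
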