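test_that("PDB and mmCIF round trips preserve names, numbering, coordinates", {
  m <- build_aform_helix("GCAUGCAU")
  for (fmt in c("pdb", "mmcif")) {
    f <- tempfile(fileext = if (fmt == "pdb") ".pdb" else ".cif")
    write_structure(m, f, format = fmt)
    m2 <- read_structure(f)
    expect_equal(nrow(m2$atoms), nrow(m$atoms))
    expect_equal(m2$atoms$elety, m$atoms$elety)
    expect_equal(m2$atoms$resno, m$atoms$resno)
    expect_equal(m2$atoms$resid, m$atoms$resid)
    expect_lt(max(abs(coords(m2) - coords(m))), 1e-3)
    rt <- residue_table(m2)
    expect_true(all(rt$polymer_class == "nucleotide"))
    expect_equal(nrow(rt), 8L)
  }
})

test_that("parse errors are raised for missing, empty and malformed files", {
  expect_error(read_structure(tempfile()), "not found")
  ef <- tempfile(fileext = ".pdb")
  writeLines(character(0), ef)
  expect_error(read_structure(ef), "parse error")
  expect_error(write_structure(new_structure_model(
    data.frame(elety = "C", resid = "ALA", chain = "A", resno = 1,
               x = 0, y = 0, z = 0)[0, ]), tempfile(fileext = ".pdb")),
    "empty")
})

test_that("altlocs collapse to highest occupancy, ties by letter order", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_atom_line(1, "N",  " ", "ALA", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", "A", "ALA", "A", 1, 1, 0, 0, o = 0.4),
    pdb_atom_line(3, "CA", "B", "ALA", "A", 1, 2, 0, 0, o = 0.6),
    pdb_atom_line(4, "CB", "A", "ALA", "A", 1, 3, 0, 0, o = 0.5),
    pdb_atom_line(5, "CB", "B", "ALA", "A", 1, 4, 0, 0, o = 0.5),
    "END"), f)
  m <- read_structure(f)
  expect_equal(nrow(m$atoms), 3L)
  expect_equal(m$atoms$x[m$atoms$elety == "CA"], 2)  # occupancy 0.6 wins
  expect_equal(m$atoms$x[m$atoms$elety == "CB"], 3)  # tie -> altloc A
  # no altloc characters on re-write
  f2 <- tempfile(fileext = ".pdb")
  write_structure(m, f2)
  expect_equal(nrow(read_structure(f2)$atoms), 3L)
})

test_that("residue classification is total and warns on unknown names", {
  expect_equal(classify_residue(c("ALA", "G", "HOH", "SR", "XYZ")),
               c("protein", "nucleotide", "water", "ion", "other"))
  f <- tempfile(fileext = ".pdb")
  writeLines(c(pdb_atom_line(1, "C1", " ", "LIG", "A", 1, 0, 0, 0), "END"), f)
  expect_warning(m <- read_structure(f), "LIG")
  expect_equal(m$atoms$polymer_class, "other")
  # modified nucleotide maps to its parent base
  expect_equal(parent_base(c("UMS", "PSU", "A")), c("U", "U", "A"))
  expect_equal(classify_residue("UMS"), "nucleotide")
})

test_that("apply_transform is rigid: identity, composition, closure, distances", {
  m <- build_aform_helix("GCGA")
  expect_equal(coords(apply_transform(m)), coords(m))
  t1 <- c(1, -2, 3); t2 <- c(-4, 0.5, 2)
  m12 <- apply_transform(apply_transform(m, translation = t1), translation = t2)
  expect_equal(coords(m12), coords(apply_transform(m, translation = t1 + t2)))
  Rz <- spiegelmer:::rotation_about(c(0, 0, 1), 180)
  back <- apply_transform(apply_transform(m, Rz), Rz)
  expect_lt(max(abs(coords(back) - coords(m))), 1e-9)
  # pairwise distances preserved under an arbitrary rotation
  R <- spiegelmer:::rotation_about(c(1, 2, -1), 63.7)
  d0 <- dist(coords(m)[1:40, ])
  d1 <- dist(coords(apply_transform(m, R, c(5, 5, 5)))[1:40, ])
  expect_lt(max(abs(d0 - d1)), 1e-9)
  expect_error(apply_transform(m, matrix(1:9 / 10, 3)), "orthonormal")
})

test_that("symmetry operators are parsed and mates found in contact", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "CRYST1   20.000   20.000   20.000  90.00  90.00  90.00 P 1",
    "REMARK 290   SMTRY1   1  1.000000  0.000000  0.000000        0.00000",
    "REMARK 290   SMTRY2   1  0.000000  1.000000  0.000000        0.00000",
    "REMARK 290   SMTRY3   1  0.000000  0.000000  1.000000        0.00000",
    pdb_atom_line(1, "CA", " ", "GLY", "A", 1, 0.5, 1.0, 1.0),
    pdb_atom_line(2, "CA", " ", "GLY", "A", 2, 18.5, 1.0, 1.0),
    "END"), f)
  m <- read_structure(f)
  expect_length(m$assembly_ops, 1L)
  mates <- symmetry_mates(m, contact_dist = 4)
  expect_gt(length(mates), 0L)
  # the +x cell translation brings atom 2 (x=18.5) next to atom 1 (x=20.5)
  shifts <- vapply(mates, function(z) paste(z$shift, collapse = ","), "")
  expect_true("1,0,0" %in% shifts)
})
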