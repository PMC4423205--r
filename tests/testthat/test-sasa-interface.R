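test_that("SASA matches closed forms for isolated and overlapping spheres", {
  one <- new_structure_model(mk_res("W", 1, "UNX", list(O = c(0, 0, 0))))
  s1 <- sasa(one, include_solvent = TRUE)
  expect_lt(abs(s1$total - 4 * pi * (1.52 + 1.4)^2) /
              (4 * pi * (1.52 + 1.4)^2), 0.005)

  # two atoms beyond r1 + r2 + 2 probe: sum of isolated spheres
  sep <- new_structure_model(rbind(
    mk_res("W", 1, "UNX", list(O = c(0, 0, 0))),
    mk_res("W", 2, "UNX", list(N = c(10, 0, 0)))))
  s2 <- sasa(sep, include_solvent = TRUE)
  exact2 <- 4 * pi * ((1.52 + 1.4)^2 + (1.55 + 1.4)^2)
  expect_lt(abs(s2$total - exact2) / exact2, 0.005)

  # two overlapping equal spheres: analytic spherical-cap formula
  d <- 2
  two <- new_structure_model(rbind(
    mk_res("W", 1, "UNX", list(O = c(0, 0, 0))),
    mk_res("W", 2, "UNX", list(O = c(d, 0, 0)))))
  s3 <- sasa(two, n_points = 2000, include_solvent = TRUE)
  R <- 1.52 + 1.4
  h <- R - d / 2
  exact3 <- 2 * (4 * pi * R^2 - 2 * pi * R * h)
  expect_lt(abs(s3$total - exact3) / exact3, 0.01)

  expect_error(sasa(new_structure_model(
    mk_res("W", 1, "UNX", list(Q9 = c(0, 0, 0))))), "radius")
})

test_that("SASA is invariant under rigid transforms and mirroring", {
  m <- build_aform_helix("GCAUG")
  s0 <- sasa(m, n_points = 5000)
  R <- spiegelmer:::rotation_about(c(2, -1, 0.5), 41)
  s1 <- sasa(apply_transform(m, R, c(7, -3, 11)), n_points = 5000)
  expect_lt(abs(s1$total - s0$total) / s0$total, 0.001)
  s2 <- sasa(mirror_structure(m), n_points = 5000)
  expect_lt(abs(s2$total - s0$total) / s0$total, 0.001)
  # per-chain sums equal member atom sums
  expect_equal(sum(s0$atom_area), s0$total)
})

test_that("interface area is the mean of the two buried areas, zero when apart", {
  arg <- mk_res("P", 18, "ARG", list(N = c(0, 0, 5), CA = c(1, 0, 5),
                                     C = c(2, 0, 5), O = c(3, 0, 5),
                                     NE = c(0, 1, 5), NH1 = c(0, 0, 2.9),
                                     NH2 = c(1, 1, 5)))
  rna <- mk_res("R", 10, "U", list(P = c(0, 0, -1.5), OP1 = c(0, 0, 0),
                                   OP2 = c(1, 0, -2), `C1'` = c(4, 4, 0)))
  names(rna$elety) <- NULL
  far <- new_structure_model(rbind(arg, within(rna, x <- x + 100)))
  ir0 <- interface_report(far, "P", "R")
  expect_equal(ir0$interface_area, 0)
  expect_equal(nrow(ir0$interface_residues$a), 0L)
  expect_null(ir0$hbonds)

  m <- new_structure_model(rbind(arg, rna))
  ir <- interface_report(m, "P", "R")
  expect_gt(ir$interface_area, 0)
  expect_equal(ir$interface_area, (ir$buried_a + ir$buried_b) / 2)
  expect_error(interface_report(m, "P", "P"), "disjoint")
  expect_error(interface_report(m, character(0), "R"), "chain")
})

test_that("inter-chain hydrogen bonds honour chemistry tables and the window", {
  arg <- mk_res("P", 18, "ARG", list(N = c(0, 0, 5), CA = c(1, 0, 5),
                                     C = c(2, 0, 5), O = c(3, 0, 5),
                                     NE = c(0, 1, 5), NH1 = c(0, 0, 2.9),
                                     NH2 = c(1, 1, 5)))
  rna <- mk_res("R", 10, "U", list(P = c(0, 0, -1.5), OP1 = c(0, 0, 0),
                                   OP2 = c(1, 0, -2), `C1'` = c(4, 4, 0)))
  m <- new_structure_model(rbind(arg, rna))
  hb <- interchain_hbonds(m, "P", "R")
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$atom_a, "NH1")
  expect_equal(hb$atom_b, "OP1")
  expect_equal(hb$distance, 2.9, tolerance = 1e-9)
  expect_null(interchain_hbonds(m, "P", "R", cutoff = 2.3))

  # a CA-CA contact is never a hydrogen bond
  ca <- new_structure_model(rbind(
    mk_res("P", 1, "GLY", list(N = c(9, 9, 9), CA = c(0, 0, 0))),
    mk_res("R", 2, "GLY", list(N = c(9, 9, 6), CA = c(2.9, 0, 0)))))
  hb2 <- interchain_hbonds(ca, "P", "R")
  expect_true(is.null(hb2) || !any(hb2$atom_a == "CA"))
})

test_that("salt bridges pair charged nitrogens with anionic oxygens, H-bonds excluded", {
  lys <- mk_res("P", 19, "LYS", list(N = c(9, 9, 0), CA = c(10, 9, 0),
                                     NZ = c(0, 0, 3.6)))
  rna <- mk_res("R", 9, "C", list(P = c(0, 0, -1.5), OP1 = c(0, 0, 0),
                                  OP2 = c(1.5, 0, 0.5)))
  m <- new_structure_model(rbind(lys, rna))
  sb <- salt_bridges(m, "P", "R")
  expect_equal(nrow(sb), 2L)  # NZ to both phosphate oxygens within 4.0
  # atoms already counted as H-bonds drop out of the electrostatic tally
  hb <- data.frame(chain_a = "P", resno_a = 19, atom_a = "NZ",
                   chain_b = "R", resno_b = 9, atom_b = "OP1")
  sb2 <- salt_bridges(m, "P", "R", exclude = hb)
  expect_equal(nrow(sb2), 1L)
  expect_equal(sb2$atom_b, "OP2")
})

test_that("cation-pi requires a face-on approach within distance and angle gates", {
  g <- spiegelmer:::base_template("G")
  gat <- mk_res("R", 5, "G",
                setNames(lapply(seq_len(nrow(g)), function(i) g[i, ]),
                         rownames(g)))
  ctr <- colMeans(g[spiegelmer:::.BASE_RING6, ])
  stacked <- new_structure_model(rbind(
    mk_res("P", 24, "ARG", list(N = c(9, 9, 9), CA = c(10, 9, 9),
                                CZ = ctr + c(0, 0, 4))), gat))
  cp <- cation_pi(stacked, "P", "R")
  expect_equal(nrow(cp), 1L)
  expect_equal(cp$cation_resid, "ARG")
  expect_lt(cp$angle, 45)

  inplane <- new_structure_model(rbind(
    mk_res("P", 24, "ARG", list(N = c(9, 9, 9), CA = c(10, 9, 9),
                                CZ = ctr + c(5, 0, 0))), gat))
  expect_null(cation_pi(inplane, "P", "R"))
  faraway <- new_structure_model(rbind(
    mk_res("P", 24, "ARG", list(N = c(9, 9, 9), CA = c(10, 9, 9),
                                CZ = ctr + c(0, 0, 8))), gat))
  expect_null(cation_pi(faraway, "P", "R"))
})

test_that("interface contacts and H-bond sets are mirror-invariant", {
  arg <- mk_res("P", 18, "ARG", list(N = c(0, 0, 5), CA = c(1, 0, 5),
                                     C = c(2, 0, 5), O = c(3, 0, 5),
                                     NE = c(0, 1, 5), NH1 = c(0, 0, 2.9),
                                     NH2 = c(1, 1, 5)))
  rna <- mk_res("R", 10, "U", list(P = c(0, 0, -1.5), OP1 = c(0, 0, 0),
                                   OP2 = c(1, 0, -2), `C1'` = c(4, 4, 0)))
  m <- new_structure_model(rbind(arg, rna))
  mm <- mirror_structure(m)
  h1 <- interchain_hbonds(m, "P", "R")
  h2 <- interchain_hbonds(mm, "P", "R")
  expect_equal(h1$atom_a, h2$atom_a)
  expect_equal(h1$distance, h2$distance, tolerance = 1e-9)
})
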