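test_that("helix builder validates its specification", {
  expect_error(build_aform_helix("G"), "length")
  expect_error(build_aform_helix("GCXG"), "invalid sequence")
  expect_error(build_aform_helix("GCGC", twist = 75), "twist")
  expect_error(build_sugar_ring(18, 0), "tau_m")
  expect_error(build_ion_shell("MG", c(2.0, -1)), "positive")
})

test_that("D and L helices are exact mirror twins with identical distances", {
  hD <- build_aform_helix("GCAUGC", chirality = "D")
  hL <- build_aform_helix("GCAUGC", chirality = "L")
  expect_equal(hD$atoms$elety, hL$atoms$elety)
  dD <- dist(coords(hD)); dL <- dist(coords(hL))
  expect_lt(max(abs(dD - dL)), 1e-9)
  geo <- nucleotide_geometry(hL)
  expect_true(all(geo$chirality == "L"))
})

test_that("mirror_structure is an involution that negates dihedrals", {
  m <- build_aform_helix("GCGA")
  mm <- mirror_structure(mirror_structure(m))
  expect_identical(coords(mm), coords(m))
  # arbitrary atom quadruples: dihedral negates under one mirror
  xyz <- coords(m)
  m1 <- coords(mirror_structure(m))
  set.seed(5)
  for (k in 1:10) {
    i <- sample(nrow(xyz), 4)
    d0 <- tryCatch(dihedral(xyz[i[1], ], xyz[i[2], ], xyz[i[3], ],
                            xyz[i[4], ]), error = function(e) NULL)
    if (is.null(d0)) next
    expect_lt(abs(dihedral(m1[i[1], ], m1[i[2], ], m1[i[3], ], m1[i[4], ]) +
                    d0), 1e-9)
  }
})

test_that("duplex fixtures pair every position Watson-Crick and antiparallel", {
  for (s in c("GCGCGC", "GAUCGU")) {
    d <- build_aform_helix(s, duplex = TRUE)
    bp <- find_base_pairs(d)
    expect_equal(sum(bp$pair_type == "watson_crick"), nchar(s))
    expect_true(all(bp$orientation == "antiparallel"))
    # every strand-A position is paired with its complement
    expect_setequal(bp$resno_i[bp$chain_i == "A"], seq_len(nchar(s)))
  }
})

test_that("ion shells are built at the prescribed distances and geometries", {
  sh <- build_ion_shell("SR", rep(2.62, 6), geometry = "octahedral")
  site <- coordination_shell(sh, ion_index = 1)
  expect_equal(site$n, 6L)
  expect_equal(site$d_mean, 2.62, tolerance = 1e-12)
  expect_equal(site$d_sd, 0)
  sh3 <- build_ion_shell("K", c(2.8, 2.9, 3.0), geometry = "irregular")
  site3 <- coordination_shell(sh3, ion_index = 1)
  expect_equal(site3$n, 3L)
  expect_false(site3$empty)
  sc <- score_ion_identity(site3)
  expect_true(attr(sc, "low_confidence") == FALSE || site3$n >= 3)
})

test_that("sensorgram generator is deterministic and obeys closed-form limits", {
  s1 <- generate_sensorgrams(noise_sd = 0.5, seed = 42)
  s2 <- generate_sensorgrams(noise_sd = 0.5, seed = 42)
  expect_identical(s1, s2)
  s3 <- generate_sensorgrams(noise_sd = 0.5, seed = 43)
  expect_false(identical(s1$response_RU, s3$response_RU))

  # zero concentration -> identically zero response
  z <- generate_sensorgrams(concentrations = c(0, 0), noise_sd = 0)
  expect_true(all(z$response_RU == 0))

  # C = Kd at equilibrium, no transport limit -> plateau at Rmax/2
  ka <- 1e6; kd <- 1.32e-3; Kd <- kd / ka
  eq <- generate_sensorgrams(ka = ka, kd = kd, Rmax = 50, kt = 1e12,
                             concentrations = Kd, t_assoc = 6000,
                             t_dissoc = 10, dt = 10, noise_sd = 0)
  plateau <- max(eq$response_RU)
  expect_lt(abs(plateau - 25) / 25, 1e-3)

  # large kt reduces to the closed-form 1:1 association curve
  tt <- seq(0, 240, by = 1)
  C <- 5e-9
  r <- model_response(ka, kd, 50, C, tt, 240, kt = 1e11)
  req <- 50 * C / (C + Kd)
  cf <- req * (1 - exp(-(ka * C + kd) * tt))
  expect_lt(max(abs(r - cf)) / max(cf), 1e-3)
})
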