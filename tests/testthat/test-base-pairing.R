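test_that("base hydrogen bonds: construction, window and brute-force parity", {
  # far-separated strands -> none
  a <- build_aform_helix("GCG")
  b <- apply_transform(build_aform_helix("CGC"), translation = c(50, 0, 0))
  b$atoms$chain <- "B"
  far <- combine_models(a, b)
  expect_equal(nrow(find_base_hbonds(far)), 0L)

  # ideal G-C pair fixture carries the three canonical bonds
  gc <- mk_engineered_pair("G", "C", list(c("O6", "N4"), c("N1", "N3"),
                                          c("N2", "O2")))
  hb <- find_base_hbonds(gc)
  key <- paste(pmin(hb$donor_atom, hb$acceptor_atom),
               pmax(hb$donor_atom, hb$acceptor_atom))
  expect_true(all(c("N4 O6", "N1 N3", "N2 O2") %in% key))

  # parity with an independent all-pairs scan on a 10-nt fixture
  m <- build_aform_helix("GCAUGCGCAU", duplex = FALSE)
  hb2 <- find_base_hbonds(m, cutoff = 3.5)
  donors <- list(A = "N6", C = "N4", G = c("N1", "N2"), U = "N3")
  acceptors <- list(A = c("N1", "N3", "N7"), C = c("O2", "N3"),
                    G = c("O6", "N3", "N7"), U = c("O2", "O4"))
  found <- list()
  rt <- residue_table(m)
  for (i in seq_len(nrow(rt))) for (j in seq_len(nrow(rt))) {
    if (i == j) next
    ri <- get_residue(m, rt$chain[i], rt$resno[i])
    rj <- get_residue(m, rt$chain[j], rt$resno[j])
    for (da in intersect(donors[[rt$resid[i]]], ri$elety))
      for (aa in intersect(acceptors[[rt$resid[j]]], rj$elety)) {
        d <- sqrt(sum((spiegelmer:::atom_xyz(ri, da) -
                         spiegelmer:::atom_xyz(rj, aa))^2))
        if (d >= 2.4 && d <= 3.5)
          found[[length(found) + 1]] <- paste(i, da, j, aa)
      }
  }
  got <- paste(hb2$donor_pos, hb2$donor_atom, hb2$acceptor_pos,
               hb2$acceptor_atom)
  expect_setequal(got, unlist(found))
})

test_that("pair dictionaries classify canonical, Hoogsteen and named pairs", {
  gc <- mk_engineered_pair("G", "C", list(c("O6", "N4"), c("N1", "N3"),
                                          c("N2", "O2")))
  bp <- find_base_pairs(gc)
  expect_equal(bp$pair_type, "watson_crick")

  au_h <- mk_engineered_pair("A", "U", list(c("N7", "N3"), c("N6", "O4")))
  bp2 <- find_base_pairs(au_h)
  expect_equal(bp2$pair_type, "hoogsteen")

  gg <- mk_engineered_pair("G", "G", list(c("N7", "N1"), c("O6", "N2")))
  bp3 <- find_base_pairs(gg)
  expect_equal(bp3$pair_type, "noncanonical")
  expect_equal(bp3$subtype, "GG N7-N1 carbonyl-amino")

  ga <- mk_engineered_pair("G", "A", list(c("N3", "N6"), c("N2", "N1")))
  bp4 <- find_base_pairs(ga)
  expect_equal(bp4$subtype, "GA N3-amino amino-N1")

  gu <- mk_engineered_pair("G", "U", list(c("O6", "N3"), c("N1", "O2")))
  bp5 <- find_base_pairs(gu)
  expect_equal(bp5$pair_type, "noncanonical")
  expect_equal(bp5$subtype, "GU wobble")

  # every reported pair satisfies the geometric gates
  for (bp_i in list(bp, bp2, bp3, bp4, bp5)) {
    expect_true(all(bp_i$n_hbonds >= 2))
    expect_true(all(bp_i$plane_angle <= 35))
  }
})

test_that("pair classification needs two bonds and near-coplanar bases", {
  gc <- mk_engineered_pair("G", "C", list(c("O6", "N4"), c("N1", "N3"),
                                          c("N2", "O2")))
  rt <- residue_table(gc)
  ri <- get_residue(gc, "A", 1); rj <- get_residue(gc, "A", 10)
  hb <- find_base_hbonds(gc)
  expect_null(classify_pair(ri, rj, hb[1, , drop = FALSE]))
  # tilt one base far out of plane: rejected
  tilt <- gc
  sel <- tilt$atoms$resno == 10
  xyz <- coords(tilt)
  ctr <- colMeans(xyz[sel, ])
  R <- spiegelmer:::rotation_about(c(1, 0, 0), 60)
  xyz[sel, ] <- sweep(sweep(xyz[sel, ], 2, ctr) %*% t(R), 2, ctr, "+")
  tilt <- spiegelmer:::set_coords(tilt, xyz)
  expect_null(classify_pair(get_residue(tilt, "A", 1),
                            get_residue(tilt, "A", 10),
                            find_base_hbonds(gc)))
})

test_that("pseudoknot detection equals brute-force crossing enumeration", {
  # definition cases
  nested <- data.frame(pos_i = c(1, 2, 3), pos_j = c(20, 19, 18))
  expect_false(any(detect_pseudoknots(nested)$pseudoknot))
  cross <- data.frame(pos_i = c(1, 5), pos_j = c(10, 15))
  expect_true(all(detect_pseudoknots(cross)$pseudoknot))

  set.seed(7)
  for (rep in 1:100) {
    n <- sample(5:30, 1)
    i <- sample(1:40, n, replace = TRUE)
    j <- sample(1:40, n, replace = TRUE)
    keep <- i != j
    pi0 <- pmin(i, j)[keep]; pj0 <- pmax(i, j)[keep]
    dup <- duplicated(paste(pi0, pj0))
    pairs <- data.frame(pos_i = pi0[!dup], pos_j = pj0[!dup])
    got <- detect_pseudoknots(pairs)$pseudoknot
    expect_identical(got, crossings_oracle(pairs$pos_i, pairs$pos_j))
  }
})

test_that("helix handedness reads the screw sense and flips under mirroring", {
  expect_equal(helix_handedness(helix_points(6, 32.7, 2.81))$handedness,
               "right")
  expect_equal(helix_handedness(helix_points(6, -32.7, 2.81))$handedness,
               "left")
  expect_equal(helix_handedness(helix_points(9.4, 36, 3.4))$handedness,
               "right")
  h <- build_aform_helix("GCAUGCAU")
  expect_equal(helix_handedness(h, chain = "A")$handedness, "right")
  expect_equal(helix_handedness(mirror_structure(h), chain = "A")$handedness,
               "left")
  expect_equal(helix_handedness(helix_points(6, 32.7, 2.81)[1:3, ])$handedness,
               "undetermined")
})

test_that("secondary structure assembles helices and a dot-bracket string", {
  d <- build_aform_helix("GCGCGC", duplex = TRUE)
  ss <- secondary_structure(d)
  expect_equal(nrow(ss$pairs), 6L)
  expect_equal(sum(ss$pairs$pseudoknot), 0L)
  expect_equal(length(ss$helices), 1L)
  expect_equal(ss$helices[[1]]$handedness, "right")
  expect_equal(ss$dot_bracket, paste0(strrep("(", 6), strrep(")", 6)))
  ssL <- secondary_structure(mirror_structure(d))
  expect_equal(nrow(ssL$pairs), 6L)
  expect_equal(ssL$helices[[1]]$handedness, "left")
})
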