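test_that("Kabsch superposition: identity, rigid closure, proper rotation", {
  set.seed(21)
  a <- matrix(rnorm(36), ncol = 3)
  r0 <- kabsch_superpose(a, a)
  expect_lt(r0$rmsd, 1e-12)
  expect_lt(max(abs(r0$rotation - diag(3))), 1e-9)

  for (k in 1:10) {
    R <- spiegelmer:::rotation_about(rnorm(3), runif(1, 1, 179))
    tr <- rnorm(3) * 10
    b <- sweep(a %*% t(R), 2, tr, "+")
    res <- kabsch_superpose(a, b)
    expect_lt(res$rmsd, 1e-9)
    expect_lt(max(abs(res$rotation - R)), 1e-9)
    expect_equal(det(res$rotation), 1, tolerance = 1e-9)
  }
  expect_error(kabsch_superpose(a[1:2, ], a[1:2, ]), "at least 3")
  expect_error(kabsch_superpose(a, a[1:5, ]), "matching dimensions")
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("Kabsch agrees with the quaternion-method oracle on random sets", {
  set.seed(33)
  for (k in 1:15) {
    n <- sample(4:40, 1)
    a <- matrix(rnorm(3 * n), ncol = 3)
    b <- matrix(rnorm(3 * n), ncol = 3) * 0.3 +
      sweep(a %*% t(spiegelmer:::rotation_about(rnorm(3), runif(1, 0, 180))),
            2, rnorm(3), "+")
    expect_lt(abs(kabsch_superpose(a, b)$rmsd - quaternion_rmsd(a, b)), 1e-9)
  }
})

test_that("mirror images of chiral sets never superpose to zero", {
  h <- build_aform_helix("GCGCAU")
  xyz <- coords(h)
  xm <- xyz
  xm[, 1] <- -xm[, 1]
  expect_gt(kabsch_superpose(xyz, xm)$rmsd, 0.5)
})

test_that("atom pairing by numbering and by alignment drops what cannot match", {
  pm <- new_structure_model(mk_toy_protein())
  pm2 <- apply_transform(pm, spiegelmer:::rotation_about(c(1, 1, 0), 30),
                         c(3, -2, 1))
  pr <- pair_atoms(pm, pm2, "A", "A", selection = "calpha")
  expect_equal(pr$n_atoms, 12L)
  sp <- superpose_chains(pm, pm2, "A", "A")
  expect_lt(sp$rmsd, 1e-9)

  pm3 <- new_structure_model(mk_toy_protein()[
    mk_toy_protein()$resno <= 9, ])
  pr3 <- pair_atoms(pm, pm3, "A", "A")
  expect_equal(pr3$dropped_a, 3L)
  expect_equal(pr3$n_residues, 9L)

  pr4 <- pair_atoms(pm, pm2, "A", "A", selection = "all_atom",
                    pairing = "alignment")
  expect_equal(pr4$n_atoms, 48L)
  expect_lt(kabsch_superpose(pr4$a, pr4$b)$rmsd, 1e-9)
  expect_error(pair_atoms(pm, pm2, "A", "Z"), "chains")
})

test_that("superposition rmsd is invariant under pre-applied rigid moves", {
  pm <- new_structure_model(mk_toy_protein())
  noisy <- pm
  set.seed(4)
  noisy <- spiegelmer:::set_coords(noisy, coords(pm) + rnorm(length(coords(pm))) * 0.3)
  base <- superpose_chains(pm, noisy, "A", "A")$rmsd
  moved <- apply_transform(pm, spiegelmer:::rotation_about(c(0, 1, 2), 77),
                           c(-5, 5, 0))
  expect_equal(superpose_chains(moved, noisy, "A", "A")$rmsd, base,
               tolerance = 1e-9)
})

test_that("epitope substitution flags follow the annotation table, not code", {
  ref <- paste(rep("A", 70), collapse = "")
  hom <- paste(c(rep("A", 20), "P", rep("A", 49)), collapse = "")
  tab <- data.frame(position = 21, ref = "A", sub = "P",
                    effect = "detrimental")
  em <- epitope_map(ref, c(18, 21), c(h = hom), effect_table = tab)
  expect_equal(em$h_effect, c("identical", "detrimental"))
  # scrambled table: same substitution now annotated neutral
  tab2 <- transform(tab, effect = "neutral")
  em2 <- epitope_map(ref, c(18, 21), c(h = hom), effect_table = tab2)
  expect_equal(em2$h_effect[2], "neutral")
  # unknown substitutions are flagged unknown; self-comparison is identical
  em3 <- epitope_map(ref, c(18, 21), c(h = ref))
  expect_true(all(em3$h_effect == "identical"))
  expect_error(epitope_map(ref, 21, c(h = "SHORT")), "aligned")
  # the shipped default table carries the published mutational outcomes
  def <- epitope_effect_table()
  expect_equal(def$effect[def$position == 21 & def$sub == "P"], "detrimental")
  expect_equal(def$effect[def$position == 66 & def$sub == "Y"], "neutral")
})
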