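test_that("hand-checked rotation: 90 degrees about a z-axis bond", {
  rows <- rbind(
    atom_row(1, "N", "ALA", 1, c(0, 0, 0)),
    atom_row(2, "CA", "ALA", 1, c(0, 0, 1)),
    atom_row(3, "CB", "ALA", 1, c(1, 0, 1)))
  s <- new_structure(rows, id = "z_toy")
  conf <- rotate_about_bond(s, hinge_spec(1, "N-CA"), 90)
  cb <- conf$structure$atoms[3, c("x", "y", "z")]
  expect_equal(as.numeric(cb), c(0, 1, 1), tolerance = 1e-9)
  # atoms on the axis do not move
  expect_equal(as.numeric(conf$structure$atoms[2, c("x", "y", "z")]),
               c(0, 0, 1), tolerance = 1e-12)
})

test_that("zero and full-turn rotations are exact identities", {
  toy <- make_two_domain_toy(seed = 1)
  same <- rotate_about_bond(toy$structure, toy$hinge, 0)
  expect_identical(same$structure$atoms, toy$structure$atoms)
  full <- rotate_about_bond(toy$structure, toy$hinge, 360)
  expect_identical(full$structure$atoms, toy$structure$atoms)
})

test_that("rotations invert and compose additively", {
  toy <- make_two_domain_toy(seed = 1)
  xyz0 <- as.matrix(toy$structure$atoms[, c("x", "y", "z")])
  there <- rotate_about_bond(toy$structure, toy$hinge, 37)
  back <- rotate_about_bond(there$structure, toy$hinge, -37)
  expect_lt(max(abs(as.matrix(back$structure$atoms[, c("x", "y", "z")]) -
                      xyz0)), 1e-6)
  two_step <- rotate_about_bond(there$structure, toy$hinge, 23)
  one_step <- rotate_about_bond(toy$structure, toy$hinge, 60)
  expect_lt(max(abs(
    as.matrix(two_step$structure$atoms[, c("x", "y", "z")]) -
      as.matrix(one_step$structure$atoms[, c("x", "y", "z")]))), 1e-6)
})

test_that("rotation is a rigid motion of each segment", {
  toy <- make_two_domain_toy(seed = 1)
  conf <- rotate_about_bond(toy$structure, toy$hinge, 55)
  a0 <- toy$structure$atoms
  a1 <- conf$structure$atoms
  for (mask in list(conf$moving, !conf$moving)) {
    idx <- which(mask)
    if (length(idx) > 40) idx <- idx[seq(1, length(idx), length.out = 40)]
    d0 <- dist(as.matrix(a0[idx, c("x", "y", "z")]))
    d1 <- dist(as.matrix(a1[idx, c("x", "y", "z")]))
    expect_lt(max(abs(d1 - d0)), 1e-6)
  }
  # the hinge bond length is invariant
  bond_len <- function(a) {
    n <- a[a$resno == toy$hinge$residue & a$name == "N", c("x", "y", "z")]
    ca <- a[a$resno == toy$hinge$residue & a$name == "CA", c("x", "y", "z")]
    sqrt(sum((as.numeric(n) - as.numeric(ca))^2))
  }
  expect_equal(bond_len(a1), bond_len(a0), tolerance = 1e-9)
})

test_that("missing bond atoms are a configuration error", {
  helix <- make_peptide(strrep("A", 10))
  expect_error(rotate_about_bond(helix, hinge_spec(77), 20),
               "configuration error")
})

test_that("the CA-C bond moves only the carbonyl within the hinge residue", {
  toy <- make_two_domain_toy(seed = 1)
  conf <- rotate_about_bond(toy$structure, hinge_spec(toy$hinge$residue,
                                                      "CA-C"), 40)
  a0 <- toy$structure$atoms
  a1 <- conf$structure$atoms
  hres <- toy$hinge$residue
  unmoved <- a0$resno < hres |
    (a0$resno == hres & a0$name %in% c("N", "CA", "CB"))
  expect_identical(a1[unmoved, c("x", "y", "z")],
                   a0[unmoved, c("x", "y", "z")])
  moved_o <- a0$resno == hres & a0$name == "O"
  expect_false(isTRUE(all.equal(a1[moved_o, c("x", "y", "z")],
                                a0[moved_o, c("x", "y", "z")])))
})

test_that("opening the toy increases centroid distance monotonically", {
  toy <- make_two_domain_toy(seed = 1)
  ser <- opening_series(toy$structure, toy$hinge, c(20, 40, 60, 80),
                        toy$partition, toy$triad)
  m0 <- opening_metrics(toy$structure, toy$partition, toy$triad)
  cent <- c(m0$centroid_distance, ser$metrics$centroid_distance)
  expect_true(all(diff(cent) > 0))
  # the catalytic site sheds crowding atoms as the structure opens
  expect_lt(ser$metrics$exposure_count[4], m0$exposure_count)
  # determinism: identical conformers give identical metrics
  again <- opening_series(toy$structure, toy$hinge, c(20, 40, 60, 80),
                          toy$partition, toy$triad)
  expect_identical(ser$metrics, again$metrics)
  # empty angle list gives an empty series
  none <- opening_series(toy$structure, toy$hinge, numeric(0),
                         toy$partition, toy$triad)
  expect_equal(length(none$conformers), 0L)
  expect_equal(nrow(none$metrics), 0L)
})

test_that("closing the toy further creates steric clashes", {
  toy <- make_two_domain_toy(seed = 1)
  opened <- rotate_about_bond(toy$structure, toy$hinge, 40)
  expect_equal(clash_count(opened), 0L)
  expect_equal(clash_count(opened, threshold = 0), 0L)
  # rotating backwards drives the domains into each other
  crashed <- rotate_about_bond(toy$structure, toy$hinge, -25)
  expect_gt(clash_count(crashed, threshold = 2.5), 0L)
})

test_that("single-domain partitions are rejected by opening metrics", {
  toy <- make_two_domain_toy(seed = 1)
  lone <- domain_partition(c(1, 20), c(200, 220), protein_id = "half")
  expect_error(opening_metrics(toy$structure, lone, toy$triad),
               "both N-ter and C-ter")
})

test_that("propensity scores rank domain charge products", {
  ref <- apeh_domain_charges()
  wide <- data.frame(
    protein = unique(ref$protein),
    nter_net = ref$net[ref$region == "N-ter"],
    cter_net = ref$net[ref$region == "C-ter"])
  ranked <- opening_propensity_score(wide)
  expect_equal(ranked$score[ranked$protein == "APEH-1_Ch"], -2)
  expect_equal(ranked$score[ranked$protein == "APEH-1_Tb"], 18)
  # opposite-charge domains (attraction) rank strictly below all
  # like-charge pairs (repulsion)
  expect_equal(ranked$protein[1], "APEH-1_Ch")
  expect_true(all(ranked$score[-1] > ranked$score[1]))
  # zero net charge on one domain gives score zero
  z <- opening_propensity_score(data.frame(protein = "z", nter_net = 0,
                                           cter_net = -5))
  expect_equal(z$score, 0)
  # also accepts charge-profile objects
  profs <- list(
    x = region_charge_profile("DDAAAAKKAA",
                              domain_partition(c(1, 4), c(7, 10))),
    y = region_charge_profile("KKAAAAKRRA",
                              domain_partition(c(1, 4), c(7, 10))))
  pr <- opening_propensity_score(profs)
  expect_equal(pr$score[pr$protein == "x"], -2 * 2)
  expect_equal(pr$score[pr$protein == "y"], 2 * 3)
})
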