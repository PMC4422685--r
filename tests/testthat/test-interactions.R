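test_that("a designed Glu-Lys pair is found at its exact distance", {
  s <- make_charged_pair(3.5)
  sb <- find_salt_bridges(s)
  expect_equal(nrow(sb), 1L)
  expect_equal(sb$resname_a, "GLU")
  expect_equal(sb$resname_b, "LYS")
  expect_equal(sb$atom_a, "OE1")
  expect_equal(sb$atom_b, "NZ")
  expect_equal(sb$distance, 3.5, tolerance = 1e-9)
  # outside the cutoff: nothing
  expect_equal(nrow(find_salt_bridges(make_charged_pair(4.2))), 0L)
  # boundary is inclusive
  expect_equal(nrow(find_salt_bridges(make_charged_pair(4.0))), 1L)
})

test_that("polyalanine has no salt bridges and distant atoms no H-bonds", {
  poly <- make_peptide(strrep("A", 12))
  expect_equal(nrow(find_salt_bridges(poly)), 0L)
  far <- make_charged_pair(5.0)
  expect_equal(nrow(find_salt_bridges(far)), 0L)
  hb <- find_hbonds(far)
  expect_false(any(hb$distance > 3.5))
})

test_that("an ideal helix shows the canonical O(i)..N(i+4) backbone bonds", {
  helix <- make_peptide(strrep("A", 10))
  hb <- find_hbonds(helix)
  canonical <- hb[hb$atom_a == "N" & hb$atom_b == "O" &
                    hb$resno_a - hb$resno_b == 4, , drop = FALSE]
  expect_equal(sort(canonical$resno_b), 1:6)
  expect_true(all(canonical$distance > 2.7 & canonical$distance < 3.2))
  expect_true(all(canonical$angle_dha >= 90))
})

test_that("detector counts are monotone in the distance cutoff", {
  s <- random_test_structure(3)
  ns <- vapply(c(3.0, 3.5, 4.0, 4.5),
               function(co) nrow(find_salt_bridges(s, cutoff = co)),
               integer(1))
  expect_true(all(diff(ns) >= 0))
  nh <- vapply(c(2.8, 3.2, 3.5, 3.8), function(co)
    nrow(find_hbonds(s, hbond_criteria(max_da = co))), integer(1))
  expect_true(all(diff(nh) >= 0))
})

test_that("detection equals the brute-force oracle on random structures", {
  for (seed in 1:12) {
    s <- random_test_structure(seed)
    sb <- find_salt_bridges(s)
    oracle <- bf_salt_bridges(s)
    expect_equal(nrow(sb), nrow(oracle), info = paste("seed", seed))
    if (nrow(sb)) {
      expect_equal(sb$resno_a, oracle$resno_a)
      expect_equal(sb$resno_b, oracle$resno_b)
      expect_equal(sb$distance, oracle$distance, tolerance = 1e-9)
    }
    hb <- find_hbonds(s)
    ohb <- bf_hbonds(s)
    expect_equal(nrow(hb), nrow(ohb), info = paste("seed", seed))
    if (nrow(hb)) {
      expect_equal(paste(hb$resno_a, hb$atom_a, hb$resno_b, hb$atom_b),
                   paste(ohb$resno_a, ohb$atom_a, ohb$resno_b, ohb$atom_b))
    }
  }
})

test_that("results are invariant to rigid motion and atom order", {
  s <- random_test_structure(11)
  sb0 <- find_salt_bridges(s)
  hb0 <- find_hbonds(s)
  # arbitrary rotation + translation
  ax <- c(1, 2, 3)
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")])
  th <- 73 * pi / 180
  u <- ax / sqrt(sum(ax^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  R <- diag(3) * cos(th) + sin(th) * K + (1 - cos(th)) * (u %o% u)
  moved <- s
  moved$atoms[, c("x", "y", "z")] <- xyz %*% t(R) +
    matrix(c(5, -3, 11), nrow(xyz), 3, byrow = TRUE)
  sb1 <- find_salt_bridges(moved)
  expect_equal(sb1$resno_a, sb0$resno_a)
  expect_equal(sb1$distance, sb0$distance, tolerance = 1e-6)
  hb1 <- find_hbonds(moved)
  expect_equal(nrow(hb1), nrow(hb0))
  # shuffled atom rows give the same residue-pair set
  set.seed(1)
  shuf <- s
  shuf$atoms <- shuf$atoms[sample(nrow(shuf$atoms)), ]
  sb2 <- find_salt_bridges(shuf)
  expect_equal(paste(sb2$resno_a, sb2$resno_b),
               paste(sb0$resno_a, sb0$resno_b))
})

test_that("the hbplus-style preset is stricter than the heavy default", {
  s <- random_test_structure(5)
  heavy <- find_hbonds(s, hbond_criteria("heavy"))
  strict <- find_hbonds(s, hbond_criteria("hbplus"))
  # hbplus allows longer D-A but imposes the short H..A bound on backbone
  # donors; every strict backbone bond within 3.5 A must also be in heavy
  key <- function(d) paste(d$resno_a, d$atom_a, d$resno_b, d$atom_b)
  strict_short <- strict[strict$distance <= 3.5, , drop = FALSE]
  expect_true(all(key(strict_short) %in% key(heavy)))
})

test_that("interactions classify by domain with the linker excluded", {
  toy <- make_two_domain_toy(seed = 1)
  sb <- classify_interdomain(find_salt_bridges(toy$structure),
                             toy$partition)
  counts <- interaction_counts(sb)
  expect_equal(unname(counts["inter"]), toy$truth$n_inter_salt_bridges)
  hb <- classify_interdomain(find_hbonds(toy$structure), toy$partition)
  hcounts <- interaction_counts(hb)
  expect_equal(unname(hcounts["inter"]), toy$truth$n_inter_hbond_records)
  # all-intra table has zero inter
  helix <- make_peptide(strrep("A", 10))
  part1 <- domain_partition(c(1, 10), c(12, 12), protein_id = "h")
  hhb <- classify_interdomain(find_hbonds(helix), part1)
  expect_equal(unname(interaction_counts(hhb)["inter"]), 0L)
  # a contact touching the linker is classed linker, not inter
  fake <- find_salt_bridges(make_charged_pair(3.0))
  fake$resno_a <- 5; fake$resno_b <- 12
  part <- domain_partition(c(1, 4), c(9, 15), protein_id = "t")
  lab <- classify_interdomain(fake, part)
  expect_equal(lab$domain_class, "linker")
  expect_equal(unname(interaction_counts(lab)["inter"]), 0L)
  # residues outside every region are a classification error
  fake$resno_b <- 99
  expect_error(classify_interdomain(fake, part), "99")
})
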