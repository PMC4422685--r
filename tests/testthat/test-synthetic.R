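test_that("peptides rebuild their input dihedrals to high precision", {
  set.seed(9)
  phi <- runif(12, -150, -50)
  psi <- runif(12, -60, 150)
  pep <- make_peptide(strrep("A", 12), phi = phi, psi = psi)
  r <- ramachandran_summary(pep)
  interior <- 2:11
  expect_lt(max(abs(r$phi[interior] - phi[interior])), 1e-3)
  expect_lt(max(abs(r$psi[interior] - psi[interior])), 1e-3)
})

test_that("helical and extended geometries have the expected contacts", {
  helix <- make_peptide(strrep("A", 10), phi = -57, psi = -47)
  a <- helix$atoms
  for (i in 1:6) {
    O <- as.numeric(a[a$resno == i & a$name == "O", c("x", "y", "z")])
    N4 <- as.numeric(a[a$resno == i + 4 & a$name == "N", c("x", "y", "z")])
    d <- sqrt(sum((O - N4)^2))
    expect_gt(d, 2.7)
    expect_lt(d, 3.2)
  }
  ext <- make_peptide(strrep("A", 5), phi = -139, psi = 135)
  ae <- ext$atoms
  for (i in 1:3) {
    A <- as.matrix(ae[ae$resno == i, c("x", "y", "z")])
    B <- as.matrix(ae[ae$resno == i + 2, c("x", "y", "z")])
    D <- sqrt(outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B))
    expect_gt(min(D), 4)
  }
})

test_that("single residues and bad codes are handled", {
  one <- make_peptide("K")
  expect_equal(length(unique(one$atoms$resno)), 1L)
  expect_true("NZ" %in% one$atoms$name)
  expect_error(make_peptide("AZ"), "invalid residue")
  expect_error(make_peptide(""), "empty")
})

test_that("the two-domain toy realises its designed ground truth", {
  toy <- make_two_domain_toy(n_salt_bridges = 2, n_hbonds = 1, seed = 1)
  sb <- classify_interdomain(find_salt_bridges(toy$structure),
                             toy$partition)
  inter <- sb[sb$domain_class == "inter", ]
  expect_equal(nrow(inter), 2L)
  expect_equal(sort(inter$distance),
               sort(toy$truth$salt_bridges$distance), tolerance = 1e-6)
  expect_setequal(paste(inter$resno_a, inter$resno_b),
                  paste(toy$truth$salt_bridges$res_a,
                        toy$truth$salt_bridges$res_b))
  hb <- classify_interdomain(find_hbonds(toy$structure), toy$partition)
  expect_equal(sum(hb$domain_class == "inter"),
               toy$truth$n_inter_hbond_records)
  # a contact-free design yields no inter-domain interactions
  bare <- make_two_domain_toy(n_salt_bridges = 0, n_hbonds = 0, seed = 1)
  sb0 <- classify_interdomain(find_salt_bridges(bare$structure),
                              bare$partition)
  expect_equal(sum(sb0$domain_class == "inter"), 0L)
})

test_that("toy generation is deterministic and validates its inputs", {
  t1 <- make_two_domain_toy(seed = 4)
  t2 <- make_two_domain_toy(seed = 4)
  expect_identical(t1$structure$atoms, t2$structure$atoms)
  expect_identical(t1$truth, t2$truth)
  expect_error(make_two_domain_toy(bridge_distance = 4.5),
               "detection cutoffs")
  expect_error(make_two_domain_toy(n_per_domain = 5), "at least")
  expect_error(make_two_domain_toy(n_salt_bridges = 40),
               "construction error")
})

test_that("simulated Ct tables invert the expression relation", {
  eff <- data.frame(gene = c("tg", "ref"), efficiency = c(1, 1))
  sim <- make_ct_table(data.frame(gene = "tg", tissue = "t1", fold = 8),
                       eff, reference_gene = "ref", control_tissue = "c0",
                       noise_sd = 0)
  ct <- sim$ct
  expect_equal(ct$ct[ct$gene == "tg" & ct$tissue == "c0"][1] -
                 ct$ct[ct$gene == "tg" & ct$tissue == "t1"][1], 3)
  expect_true(all(ct$ct[ct$gene == "ref"] ==
                    ct$ct[ct$gene == "ref"][1]))
  expect_error(make_ct_table(data.frame(gene = "g", tissue = "t",
                                        fold = -1), eff,
                             reference_gene = "ref", control_tissue = "c"),
               "positive")
  expect_error(make_ct_table(data.frame(gene = "g", tissue = "t", fold = 2),
                             eff, reference_gene = "ref",
                             control_tissue = "c", noise_sd = -1), ">= 0")
})

test_that("Ct simulation is reproducible byte for byte", {
  eff <- data.frame(gene = c("tg", "ref"), efficiency = c(0.95, 1.05))
  truth <- data.frame(gene = "tg", tissue = c("a", "b"), fold = c(2, 5))
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(make_ct_table(truth, eff, "ref", "c0", noise_sd = 0.3,
                          seed = 11)$ct, f1, row.names = FALSE)
  write.csv(make_ct_table(truth, eff, "ref", "c0", noise_sd = 0.3,
                          seed = 11)$ct, f2, row.names = FALSE)
  expect_identical(readLines(f1), readLines(f2))
  # and the global RNG stream is left untouched
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(make_ct_table(truth, eff, "ref", "c0",
                                         noise_sd = 1, seed = 3))
  expect_identical(rnorm(1), before)
})

test_that("the fold-8 delta-Ct example holds for any efficiency", {
  # ct difference = log(fold) / log(1 + e)
  for (e in c(0.9, 1.0, 1.1)) {
    eff <- data.frame(gene = c("tg", "ref"), efficiency = c(e, 1))
    sim <- make_ct_table(data.frame(gene = "tg", tissue = "t", fold = 8),
                         eff, reference_gene = "ref",
                         control_tissue = "c", noise_sd = 0)
    ct <- sim$ct
    dct <- ct$ct[ct$gene == "tg" & ct$tissue == "c"][1] -
      ct$ct[ct$gene == "tg" & ct$tissue == "t"][1]
    expect_equal(dct, log(8) / log(1 + e), tolerance = 1e-12)
  }
})
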