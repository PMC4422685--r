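test_that("a minimal single-atom PDB parses to one residue with one atom", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(paste0("ATOM      1  CA  ALA A   1       1.000   2.000",
                    "   3.000  1.00  0.00           C"), f)
  s <- read_structure(f)
  expect_equal(nrow(s$atoms), 1L)
  expect_equal(s$atoms$name, "CA")
  expect_equal(as.numeric(s$atoms[1, c("x", "y", "z")]), c(1, 2, 3))
})

test_that("write-then-read round trip preserves coordinates and identity", {
  pep <- make_peptide("GADKE", phi = -70, psi = 140)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(pep, f)
  back <- read_structure(f)
  expect_equal(nrow(back$atoms), nrow(pep$atoms))
  expect_equal(back$atoms$name, pep$atoms$name)
  expect_equal(back$atoms$resname, pep$atoms$resname)
  expect_equal(back$atoms$resno, pep$atoms$resno)
  expect_lt(max(abs(as.matrix(back$atoms[, c("x", "y", "z")]) -
                      as.matrix(pep$atoms[, c("x", "y", "z")]))), 1e-3)
})

test_that("degenerate PDB inputs raise format errors, duplicates warn", {
  f <- withr::local_tempfile(fileext = ".pdb")
  file.create(f)
  expect_error(read_structure(f), "format error")
  expect_error(read_structure(file.path(tempdir(), "absent.pdb")),
               "not found")
  dup <- paste0("ATOM  %5d  CA  ALA A   1      %6.3f   0.000   0.000",
                "  1.00  0.00           C")
  writeLines(c(sprintf(dup, 1, 1.0), sprintf(dup, 2, 2.0), "END"), f)
  expect_warning(s <- read_structure(f), "duplicate")
  expect_equal(nrow(s$atoms), 1L)
  expect_equal(s$atoms$x, 1.0)
})

test_that("extract_sequence handles structures, strings, files and regions", {
  tri <- make_peptide("GAD")
  expect_equal(extract_sequence(tri), "GAD")
  expect_equal(extract_sequence("QWERTYKLMN", region = c(2, 4)), "WER")
  expect_error(extract_sequence("QWER", region = c(2, 9)), "range error")
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">seq1", "MKTAYIAKQR"), fa)
  expect_equal(extract_sequence(fa), "MKTAYIAKQR")
  expect_equal(extract_sequence(fa, region = c(1, 3)), "MKT")
  # unknown residue names map to X
  odd <- make_peptide("GA")
  odd$atoms$resname[odd$atoms$resno == 2] <- "MSE"
  expect_equal(extract_sequence(odd), "GX")
})

test_that("compute_dihedral follows the IUPAC sign convention", {
  expect_equal(compute_dihedral(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0),
                                c(0, 1, 1)), -90)
  # trans and cis planar arrangements
  expect_equal(compute_dihedral(c(1, 1, 0), c(1, 0, 0), c(0, 0, 0),
                                c(-1, -1, 0)), 180)
  expect_equal(compute_dihedral(c(1, 1, 0), c(1, 0, 0), c(0, 0, 0),
                                c(-1, 1, 0)), 0)
  expect_error(compute_dihedral(c(0, 0, 0), c(0, 0, 0), c(0, 1, 0),
                                c(1, 1, 1)), "undefined dihedral")
  expect_error(compute_dihedral(c(2, 0, 0), c(1, 0, 0), c(0, 0, 0),
                                c(-1, 0, 0)), "undefined dihedral")
})

test_that("dihedral symmetries hold on random quadruples", {
  # the torsion angle is invariant under reversing the atom order
  # (IUPAC definition) and negates under mirror reflection
  set.seed(42)
  for (k in 1:25) {
    pts <- matrix(stats::rnorm(12), 4, 3)
    d <- tryCatch(compute_dihedral(pts[1, ], pts[2, ], pts[3, ], pts[4, ]),
                  error = function(e) NULL)
    if (is.null(d)) next
    rev <- compute_dihedral(pts[4, ], pts[3, ], pts[2, ], pts[1, ])
    expect_equal(rev, d, tolerance = 1e-9)
    mir <- pts
    mir[, 3] <- -mir[, 3]
    ref <- compute_dihedral(mir[1, ], mir[2, ], mir[3, ], mir[4, ])
    if (abs(abs(d) - 180) < 1e-9) {
      expect_equal(abs(ref), 180, tolerance = 1e-9)
    } else {
      expect_equal(ref, -d, tolerance = 1e-9)
    }
  }
})

test_that("measured backbone dihedrals agree with bio3d torsions", {
  pep <- make_peptide(strrep("A", 8), phi = -65, psi = 120)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(pep, f)
  tor <- bio3d::torsion.pdb(bio3d::read.pdb(f))
  rama <- ramachandran_summary(pep)
  # both read back from PDB-precision coordinates
  expect_equal(rama$phi[2:7], tor$phi[2:7], tolerance = 0.1)
  expect_equal(rama$psi[2:7], tor$psi[2:7], tolerance = 0.1)
})

test_that("an ideal alpha-helix is fully core in the Ramachandran summary", {
  helix <- make_peptide(strrep("A", 10))
  r <- ramachandran_summary(helix)
  interior <- !is.na(r$phi) & !is.na(r$psi)
  expect_equal(sum(interior), 8L)
  expect_equal(max(abs(r$phi[interior] - (-57))), 0, tolerance = 1e-3)
  expect_equal(max(abs(r$psi[interior] - (-47))), 0, tolerance = 1e-3)
  expect_true(all(r$region[interior] == "core"))
  expect_equal(attr(r, "fraction_core_allowed"), 1.0)
})

test_that("structures too short for dihedrals warn and give NA fraction", {
  two <- make_peptide("AA")
  expect_warning(r <- ramachandran_summary(two), "fraction undefined")
  expect_true(all(is.na(r$phi) | is.na(r$psi)))
  expect_true(is.na(attr(r, "fraction_core_allowed")))
})
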