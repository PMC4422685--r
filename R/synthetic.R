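## Synthetic-data generators with known ground truth.
##
## Peptides are built from ideal internal coordinates (N-CA 1.458 A,
## CA-C 1.525 A, C-N 1.329 A, standard backbone angles) with user-supplied
## backbone dihedrals; side chains get a single idealised rotamer carrying
## the charged/polar group atoms (aromatic rings and branched apolar side
## chains are truncated at CB - enough for every geometric detector in the
## package, not a physical decoy). Every generator returns its ground truth
## and is deterministic under a fixed seed.

AA_123 <- stats::setNames(names(AA_321), AA_321)

## Evaluate `code` under a fixed RNG seed without disturbing the caller's
## RNG state.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

## Side-chain internal-coordinate templates. Each row: atom, three
## previously placed reference atoms, bond length, bond angle, dihedral.
## CB itself is placed from (C, N, CA) for every non-Gly residue.
SIDECHAIN_TEMPLATES <- list(
  ASP = list(c("CG", "N", "CA", "CB", 1.52, 113.0, 180),
             c("OD1", "CA", "CB", "CG", 1.25, 118.5, 0),
             c("OD2", "CA", "CB", "CG", 1.25, 118.5, 180)),
  GLU = list(c("CG", "N", "CA", "CB", 1.52, 113.0, 180),
             c("CD", "CA", "CB", "CG", 1.52, 113.0, 180),
             c("OE1", "CB", "CG", "CD", 1.25, 118.5, 0),
             c("OE2", "CB", "CG", "CD", 1.25, 118.5, 180)),
  LYS = list(c("CG", "N", "CA", "CB", 1.52, 111.0, 180),
             c("CD", "CA", "CB", "CG", 1.52, 111.0, 180),
             c("CE", "CB", "CG", "CD", 1.52, 111.0, 180),
             c("NZ", "CG", "CD", "CE", 1.49, 111.0, 180)),
  ARG = list(c("CG", "N", "CA", "CB", 1.52, 111.0, 180),
             c("CD", "CA", "CB", "CG", 1.52, 111.0, 180),
             c("NE", "CB", "CG", "CD", 1.46, 112.0, 180),
             c("CZ", "CG", "CD", "NE", 1.33, 124.0, 180),
             c("NH1", "CD", "NE", "CZ", 1.33, 120.0, 0),
             c("NH2", "CD", "NE", "CZ", 1.33, 120.0, 180)),
  HIS = list(c("CG", "N", "CA", "CB", 1.50, 113.8, 180),
             c("ND1", "CA", "CB", "CG", 1.38, 122.0, 90),
             c("CD2", "CA", "CB", "CG", 1.36, 129.0, -90),
             c("CE1", "CB", "CG", "ND1", 1.32, 109.0, 180),
             c("NE2", "CB", "CG", "CD2", 1.37, 107.0, 180)),
  SER = list(c("OG", "N", "CA", "CB", 1.42, 110.8, 180)),
  THR = list(c("OG1", "N", "CA", "CB", 1.43, 109.5, 180)),
  CYS = list(c("SG", "N", "CA", "CB", 1.81, 114.0, 180)),
  ASN = list(c("CG", "N", "CA", "CB", 1.52, 113.0, 180),
             c("OD1", "CA", "CB", "CG", 1.23, 121.0, 0),
             c("ND2", "CA", "CB", "CG", 1.33, 117.0, 180)),
  GLN = list(c("CG", "N", "CA", "CB", 1.52, 113.0, 180),
             c("CD", "CA", "CB", "CG", 1.52, 113.0, 180),
             c("OE1", "CB", "CG", "CD", 1.23, 121.0, 0),
             c("NE2", "CB", "CG", "CD", 1.33, 117.0, 180)))

element_of <- function(name) substr(gsub("^[0-9]+", "", name), 1L, 1L)

#' Build a peptide from ideal internal coordinates
#'
#' Backbone geometry uses ideal bond lengths and angles; phi/psi/omega are
#' taken from the arguments (recycled along the sequence; phi of the first
#' residue is undefined by construction and ignored). Re-measuring the
#' backbone dihedrals of the product returns the inputs to well below
#' 1e-3 degrees.
#'
#' @param sequence One-letter amino-acid string.
#' @param phi,psi Backbone dihedrals in degrees (vectors recycled to the
#'   sequence length). Defaults build an alpha-helix (-57, -47).
#' @param omega Peptide-bond dihedral, default 180 (trans).
#' @param id Structure label.
#' @param chain Chain identifier.
#' @return An `apeh_structure` with source `"synthetic"`.
#' @examples
#' helix <- make_peptide(strrep("A", 10)) # ideal alpha-helix decamer
#' @export
make_peptide <- function(sequence, phi = -57, psi = -47, omega = 180,
                         id = "peptide", chain = "A") {
  aa1 <- strsplit(toupper(sequence), "")[[1L]]
  n <- length(aa1)
  if (!n) stop("empty sequence", call. = FALSE)
  bad <- !(aa1 %in% names(AA_123))
  if (any(bad))
    stop("invalid residue code(s): ", paste(unique(aa1[bad]), collapse = ", "),
         call. = FALSE)
  phi <- rep_len(phi, n)
  psi <- rep_len(psi, n)
  omega <- rep_len(omega, n)
  if (!all(is.finite(c(phi, psi, omega))))
    stop("dihedrals must be finite", call. = FALSE)

  N <- CA <- C <- O <- matrix(NA_real_, n, 3L)
  N[1L, ] <- c(0, 0, 0)
  CA[1L, ] <- c(1.458, 0, 0)
  ang <- 111.2 * pi / 180
  C[1L, ] <- CA[1L, ] + 1.525 * c(-cos(ang), sin(ang), 0)
  if (n > 1L) {
    for (i in 2:n) {
      N[i, ] <- place_atom(N[i - 1L, ], CA[i - 1L, ], C[i - 1L, ],
                           1.329, 116.2, psi[i - 1L])
      CA[i, ] <- place_atom(CA[i - 1L, ], C[i - 1L, ], N[i, ],
                            1.458, 121.7, omega[i - 1L])
      C[i, ] <- place_atom(C[i - 1L, ], N[i, ], CA[i, ],
                           1.525, 111.2, phi[i])
    }
  }
  for (i in seq_len(n))
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ], 1.231, 120.5, psi[i] + 180)

  rows <- list()
  serial <- 0L
  add <- function(resno, resname, name, xyz) {
    serial <<- serial + 1L
    rows[[length(rows) + 1L]] <<- data.frame(
      type = "ATOM", serial = serial, name = name, altloc = "",
      resname = resname, chain = chain, resno = resno, icode = "",
      x = xyz[1L], y = xyz[2L], z = xyz[3L], occupancy = 1, bfactor = 0,
      element = element_of(name), stringsAsFactors = FALSE)
  }
  for (i in seq_len(n)) {
    res3 <- AA_123[[aa1[i]]]
    add(i, res3, "N", N[i, ])
    add(i, res3, "CA", CA[i, ])
    add(i, res3, "C", C[i, ])
    add(i, res3, "O", O[i, ])
    placed <- list(N = N[i, ], CA = CA[i, ], C = C[i, ])
    if (res3 != "GLY") {
      placed$CB <- place_atom(placed$C, placed$N, placed$CA,
                              1.53, 110.5, 122.6)
      add(i, res3, "CB", placed$CB)
      for (row in SIDECHAIN_TEMPLATES[[res3]]) {
        xyz <- place_atom(placed[[row[2L]]], placed[[row[3L]]],
                          placed[[row[4L]]], as.numeric(row[5L]),
                          as.numeric(row[6L]), as.numeric(row[7L]))
        placed[[row[1L]]] <- xyz
        add(i, res3, row[1L], xyz)
      }
    }
  }
  new_structure(do.call(rbind, rows), id = id, source = "synthetic")
}

#' Random sequence with a specified charge composition
#'
#' @param length Sequence length.
#' @param n_neg,n_pos Exact number of acidic (D/E) and basic (H/K/R)
#'   residues; the remainder is drawn from the neutral alphabet.
#' @param seed RNG seed.
#' @return One-letter string; profiling it returns exactly (n_neg, n_pos).
#' @export
random_charged_sequence <- function(length, n_neg, n_pos, seed = 1) {
  if (n_neg + n_pos > length)
    stop("n_neg + n_pos exceeds sequence length", call. = FALSE)
  neutral <- setdiff(names(AA_RESIDUE_MASS), c("D", "E", "H", "K", "R"))
  with_seed(seed, {
    aa <- c(sample(c("D", "E"), n_neg, replace = TRUE),
            sample(c("H", "K", "R"), n_pos, replace = TRUE),
            sample(neutral, length - n_neg - n_pos, replace = TRUE))
    paste(sample(aa), collapse = "")
  })
}

## Positions of the directly placed contact-group atoms for a designed
## contact between residues with CB positions cba/cbb at target distance t.
## The functional-group atoms are laid along the CB-CB axis so the contact
## distance is exact; `polar` collects the donor/acceptor/charged atoms
## used for clearance checks.
contact_atom_positions <- function(kind, cba, cbb, t) {
  u <- unitv(cbb - cba)
  d <- vnorm(cbb - cba)
  s <- (d - t) / 2
  ref <- if (abs(u[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  pv <- unitv(cross3(u, ref))
  if (kind == "salt_bridge") {
    a_side <- list(CG = cba + u * (s / 3), CD = cba + u * (2 * s / 3),
                   OE1 = cba + u * s, OE2 = cba + u * (s - 0.6) + pv * 2.2)
    b_side <- list(CG = cbb - u * (s / 4), CD = cbb - u * (s / 2),
                   CE = cbb - u * (3 * s / 4), NZ = cbb - u * s)
    polar <- rbind(a_side$OE1, a_side$OE2, b_side$NZ)
  } else {
    a_side <- list(OG = cba + u * s)
    b_side <- list(CG = cbb - u * (2 * s / 3), OD1 = cbb - u * s,
                   ND2 = cbb - u * (2 * s / 3) + pv * 2.0)
    polar <- rbind(a_side$OG, b_side$OD1, b_side$ND2)
  }
  list(a = a_side, b = b_side, polar = polar)
}

## Minimum cross distance between two atom subsets of a structure.
min_cross_dist <- function(a, sel1, sel2) {
  min(cross_dist(as.matrix(a[sel1, c("x", "y", "z")]),
                 as.matrix(a[sel2, c("x", "y", "z")])))
}

#' Designed two-domain toy structure
#'
#' Builds two helical "domains" joined by an extended linker, closes them
#' against each other by a rigid rotation about the central linker N-CA
#' bond (stopping at a minimum inter-domain backbone separation), and then
#' realises a designed set of inter-domain salt bridges and hydrogen bonds
#' by placing the relevant side-chain group atoms directly at their target
#' distances (within 1e-6 A). Only designed residues are charged, so the
#' designed contacts are provably the only inter-domain interactions - the
#' generator verifies this and fails otherwise. A Ser/Asp/His pseudo-triad
#' sits mid C-terminal domain for site-environment and exposure metrics.
#'
#' The closing rotation is chosen on the far side of the steric minimum, so
#' that further positive rotation about the returned hinge monotonically
#' increases the inter-domain centroid distance (a pure opening motion).
#'
#' @param n_per_domain Residues per domain (default 20).
#' @param linker_length Linker residues (default 10, the canonical
#'   two-domain APEH connector length).
#' @param n_salt_bridges,n_hbonds Number of designed inter-domain contacts.
#' @param bridge_distance,hbond_distance Target contact distances in
#'   angstroms (must lie within the respective detection cutoffs).
#' @param min_backbone_gap Smallest allowed inter-domain atom distance when
#'   closing (default 4.6 A, keeping non-designed atoms outside both
#'   detector cutoffs).
#' @param seed RNG seed (contact-site selection order).
#' @return List: `structure`, `partition`, `triad`, `hinge`
#'   (an [hinge_spec()]), and `truth` with the designed contacts and their
#'   counts.
#' @export
make_two_domain_toy <- function(n_per_domain = 20, linker_length = 10,
                                n_salt_bridges = 2, n_hbonds = 1,
                                bridge_distance = 3.2, hbond_distance = 2.9,
                                min_backbone_gap = 4.6, seed = 1) {
  if (bridge_distance > 4.0 || hbond_distance > 3.5)
    stop("target contact distances must lie within the detection cutoffs",
         call. = FALSE)
  nA <- n_per_domain
  nL <- linker_length
  nB <- n_per_domain
  n <- nA + nL + nB
  if (nA < 8L || nL < 3L)
    stop("toy needs at least 8 residues per domain and a 3+ residue linker",
         call. = FALSE)

  ## triad positions mid domain B
  t0 <- nA + nL + max(3L, floor(nB / 2L) - 1L)
  triad_pos <- c(ser = t0, asp = t0 + 1L, his = t0 + 2L)

  seq1 <- rep("A", n)
  seq1[triad_pos] <- c("S", "D", "H")

  ## helical domains; extended linker carrying a double reverse turn at its
  ## middle so the chain folds back and the domains can pack face to face
  phi <- c(rep(-57, nA), rep(-139, nL), rep(-57, nB))
  psi <- c(rep(-47, nA), rep(135, nL), rep(-47, nB))
  if (nL >= 6L) {
    turn <- nA + floor(nL / 2) + c(-1L, 0L, 1L, 2L)
    phi[turn] <- c(-60, -90, -60, -90)
    psi[turn] <- c(-30, 0, -30, 0)
  }

  hinge <- hinge_spec(nA + ceiling(nL / 2), "N-CA")
  build <- function(s1) {
    pep <- make_peptide(paste(s1, collapse = ""), phi = phi, psi = psi,
                        id = "two_domain_toy")
    pep
  }
  pep0 <- build(seq1)

  ## closing rotation: scan the full turn, find the steric-collision window
  ## around the centroid-distance minimum, and close at its upper edge.
  a0 <- pep0$atoms
  selA <- a0$resno <= nA
  selB <- a0$resno > nA + nL
  centroid_d <- function(conf) {
    a <- conf$structure$atoms
    vnorm(colMeans(as.matrix(a[selA, c("x", "y", "z")])) -
            colMeans(as.matrix(a[selB, c("x", "y", "z")])))
  }
  grid <- seq(0, 359.5, by = 0.5)
  dcent <- gap <- numeric(length(grid))
  for (k in seq_along(grid)) {
    conf <- rotate_about_bond(pep0, hinge, grid[k])
    dcent[k] <- centroid_d(conf)
    gap[k] <- min_cross_dist(conf$structure$atoms, selA, selB)
  }
  k_min <- which.min(dcent)
  feasible <- gap >= min_backbone_gap
  if (!any(feasible))
    stop("construction error: no sterically feasible closed state",
         call. = FALSE)
  k <- k_min
  steps <- 0L
  while (!feasible[(k - 1L) %% length(grid) + 1L] && steps <= length(grid)) {
    k <- k + 1L
    steps <- steps + 1L
  }
  close_angle <- grid[(k - 1L) %% length(grid) + 1L]

  ## pick designed contact sites on the closed poly-Ala backbone
  closed0 <- rotate_about_bond(pep0, hinge, close_angle)$structure
  cb <- closed0$atoms[closed0$atoms$name == "CB", , drop = FALSE]
  cand_A <- setdiff(which(cb$resno >= 3L & cb$resno <= nA - 2L), integer(0))
  cand_B <- which(cb$resno >= nA + nL + 3L & cb$resno <= n - 2L &
                    !(cb$resno %in% triad_pos))
  targets <- c(rep(bridge_distance, n_salt_bridges),
               rep(hbond_distance, n_hbonds))
  kinds <- c(rep("salt_bridge", n_salt_bridges), rep("hbond", n_hbonds))

  ## clearance reference sets: polar (N/O/S) atoms trip the H-bond audit,
  ## charged atoms trip the salt-bridge audit
  at0 <- closed0$atoms
  polar_sel <- at0$element %in% c("N", "O", "S")
  polar_xyz <- as.matrix(at0[polar_sel, c("x", "y", "z")])
  polar_res <- at0$resno[polar_sel]
  charged_sel <- (at0$resname == "ASP" & at0$name %in% c("OD1", "OD2")) |
    (at0$resname == "HIS" & at0$name %in% c("ND1", "NE2"))
  charged_xyz <- as.matrix(at0[charged_sel, c("x", "y", "z")])
  charged_res <- at0$resno[charged_sel]

  pairs <- list()
  used <- integer(0)
  placed_pts <- NULL
  order_A <- with_seed(seed, sample(cand_A))
  for (ci in seq_along(targets)) {
    t <- targets[ci]
    best <- NULL
    for (ia in order_A) {
      if (cb$resno[ia] %in% used) next
      for (ib in cand_B) {
        if (cb$resno[ib] %in% used) next
        cba <- as.numeric(cb[ia, c("x", "y", "z")])
        cbb <- as.numeric(cb[ib, c("x", "y", "z")])
        d <- vnorm(cbb - cba)
        ## the placed contact atoms sit (d - t)/2 from each CB; keeping
        ## that arm >= 4.25 A leaves them clear of the partner backbone
        if (d < t + 8.5 || d > t + 12) next
        pts <- contact_atom_positions(kinds[ci], cba, cbb, t)
        excl <- c(cb$resno[ia], cb$resno[ib])
        other_polar <- polar_xyz[!(polar_res %in% excl), , drop = FALSE]
        other_charged <- charged_xyz[!(charged_res %in% excl), , drop = FALSE]
        polar_clear <- min(cross_dist(pts$polar, other_polar))
        charged_clear <- if (nrow(other_charged))
          min(cross_dist(pts$polar, other_charged)) else Inf
        pair_clear <- if (is.null(placed_pts)) Inf
          else min(cross_dist(pts$polar, placed_pts))
        if (polar_clear < 3.9 || charged_clear < 4.3 || pair_clear < 4.3)
          next
        score <- min(polar_clear, charged_clear, pair_clear)
        if (is.null(best) || score > best$score)
          best <- list(res_a = cb$resno[ia], res_b = cb$resno[ib],
                       kind = kinds[ci], target = t, score = score,
                       polar = pts$polar)
      }
    }
    if (is.null(best))
      stop("construction error: no feasible site for designed contact ", ci,
           call. = FALSE)
    pairs[[length(pairs) + 1L]] <- best[c("res_a", "res_b", "kind", "target")]
    used <- c(used, best$res_a, best$res_b)
    placed_pts <- rbind(placed_pts, best$polar)
  }

  ## rebuild with the designed residue types and re-close
  for (p in pairs) {
    if (p$kind == "salt_bridge") {
      seq1[p$res_a] <- "E"; seq1[p$res_b] <- "K"
    } else {
      seq1[p$res_a] <- "S"; seq1[p$res_b] <- "N"
    }
  }
  closed <- rotate_about_bond(build(seq1), hinge, close_angle)$structure
  a <- closed$atoms

  set_xyz <- function(resno, name, xyz) {
    i <- which(a$resno == resno & a$name == name)
    a[i, c("x", "y", "z")] <<- as.list(xyz)
  }
  get_xyz <- function(resno, name) atom_xyz(a, resno, name)

  for (p in pairs) {
    pts <- contact_atom_positions(p$kind, get_xyz(p$res_a, "CB"),
                                  get_xyz(p$res_b, "CB"), p$target)
    for (nm in names(pts$a)) set_xyz(p$res_a, nm, pts$a[[nm]])
    for (nm in names(pts$b)) set_xyz(p$res_b, nm, pts$b[[nm]])
  }
  closed$atoms <- a

  partition <- domain_partition(c(1L, nA), c(nA + nL + 1L, n),
                                linker = c(nA + 1L, nA + nL),
                                protein_id = "two_domain_toy")
  triad <- triad_spec(triad_pos["ser"], triad_pos["asp"], triad_pos["his"])

  ## verify ground truth with a direct distance audit (generator-side check,
  ## independent of the detector module's selection logic): the only
  ## inter-domain charged contacts are the designed bridges, and the only
  ## inter-domain donor/acceptor contacts are the designed H-bonds plus the
  ## NZ->OE1 contact each designed bridge necessarily carries (a charged
  ## pair at 3.2 A also satisfies the H-bond distance criterion).
  in_A <- function(r) r <= nA
  in_B <- function(r) r > nA + nL
  designed_pairset <- vapply(pairs, function(p)
    paste(sort(c(p$res_a, p$res_b)), collapse = "-"), character(1L))
  audit_cross <- function(set1, set2, lim) {
    if (!nrow(set1) || !nrow(set2)) return(character(0))
    D <- cross_dist(as.matrix(set1[, c("x", "y", "z")]),
                    as.matrix(set2[, c("x", "y", "z")]))
    hit <- which(D <= lim, arr.ind = TRUE)
    r1 <- set1$resno[hit[, 1L]]
    r2 <- set2$resno[hit[, 2L]]
    inter <- (in_A(r1) & in_B(r2)) | (in_B(r1) & in_A(r2))
    unique(vapply(which(inter), function(i)
      paste(sort(c(r1[i], r2[i])), collapse = "-"), character(1L)))
  }
  acid <- a[(a$resname == "GLU" & a$name %in% c("OE1", "OE2")) |
              (a$resname == "ASP" & a$name %in% c("OD1", "OD2")), ,
            drop = FALSE]
  base <- a[(a$resname == "LYS" & a$name == "NZ") |
              (a$resname == "HIS" & a$name %in% c("ND1", "NE2")), ,
            drop = FALSE]
  sb_pairs <- designed_pairset[kinds == "salt_bridge"]
  if (!setequal(audit_cross(acid, base, 4.1), sb_pairs))
    stop("construction error: accidental inter-domain salt bridge(s)",
         call. = FALSE)
  donors <- rbind(a[a$name == "N" & a$resname != "PRO", , drop = FALSE],
                  a[(a$resname == "SER" & a$name == "OG") |
                      (a$resname == "THR" & a$name == "OG1") |
                      (a$resname == "ASN" & a$name == "ND2") |
                      (a$resname == "LYS" & a$name == "NZ") |
                      (a$resname == "HIS" & a$name %in% c("ND1", "NE2")), ,
                    drop = FALSE])
  acceptors <- rbind(a[a$name %in% c("O", "OXT"), , drop = FALSE],
                     a[(a$resname == "ASP" & a$name %in% c("OD1", "OD2")) |
                         (a$resname == "GLU" & a$name %in% c("OE1", "OE2")) |
                         (a$resname == "ASN" & a$name == "OD1") |
                         (a$resname == "SER" & a$name == "OG") |
                         (a$resname == "THR" & a$name == "OG1") |
                         (a$resname == "HIS" & a$name %in% c("ND1", "NE2")), ,
                       drop = FALSE])
  hb_hits <- audit_cross(donors, acceptors, 3.6)
  if (!setequal(hb_hits, designed_pairset))
    stop("construction error: accidental inter-domain hydrogen bond(s): ",
         paste(setdiff(hb_hits, designed_pairset), collapse = ", "),
         call. = FALSE)

  truth <- list(
    n_inter_salt_bridges = n_salt_bridges,
    n_inter_hbonds = n_hbonds,
    n_inter_hbond_records = n_hbonds + n_salt_bridges,
    salt_bridges = do.call(rbind, lapply(pairs[kinds == "salt_bridge"],
      function(p) data.frame(res_a = p$res_a, res_b = p$res_b,
                             distance = p$target))),
    hbonds = do.call(rbind, lapply(pairs[kinds == "hbond"],
      function(p) data.frame(res_a = p$res_a, res_b = p$res_b,
                             distance = p$target))),
    close_angle = close_angle)

  list(structure = closed, partition = partition, triad = triad,
       hinge = hinge, truth = truth)
}

#' Simulated qPCR Ct table from known fold changes
#'
#' Inverts the efficiency-corrected expression relation: the reference gene
#' gets a constant baseline Ct in every tissue and each target gene's Ct in
#' a tissue is set so that its true fold versus the control tissue equals
#' the requested value, then Gaussian cycle noise is added per replicate.
#'
#' @param true_folds data.frame with columns `gene`, `tissue`, `fold`
#'   (fold of 1 is implied for the control tissue).
#' @param eff data.frame with `gene`, `efficiency` covering all genes
#'   including the reference.
#' @param reference_gene,control_tissue Labels; the reference gene must be
#'   in `eff`.
#' @param noise_sd Gaussian noise on each Ct, in cycles (>= 0).
#' @param n_replicates Technical replicates per (tissue, gene).
#' @param seed RNG seed.
#' @param base_ct_reference,base_ct_target Baseline Ct values (cycles).
#' @return List: `ct` (data.frame sample, tissue, gene, ct, replicate) and
#'   `truth` (the requested folds, control rows included).
#' @export
make_ct_table <- function(true_folds, eff, reference_gene = "actb",
                          control_tissue = "liver", noise_sd = 0,
                          n_replicates = 3, seed = 1,
                          base_ct_reference = 18, base_ct_target = 25) {
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (any(true_folds$fold <= 0) || !all(is.finite(true_folds$fold)))
    stop("true folds must be positive and finite", call. = FALSE)
  e_of <- function(g) {
    e <- eff$efficiency[match(g, eff$gene)]
    if (any(is.na(e))) stop("no efficiency for gene ", g, call. = FALSE)
    e
  }
  genes <- unique(true_folds$gene)
  tissues <- unique(c(control_tissue, true_folds$tissue))
  rows <- list()
  truth <- list()
  for (g in genes) {
    b <- 1 + e_of(g)
    for (t in tissues) {
      fold <- if (t == control_tissue) 1 else {
        v <- true_folds$fold[true_folds$gene == g & true_folds$tissue == t]
        if (!length(v)) next
        v[1L]
      }
      ## fold = b^(ct_control - ct_sample) with a flat reference gene
      ct_mean <- base_ct_target - log(fold) / log(b)
      rows[[length(rows) + 1L]] <- data.frame(tissue = t, gene = g,
                                              ct_mean = ct_mean)
      truth[[length(truth) + 1L]] <- data.frame(gene = g, tissue = t,
                                                fold = fold)
    }
  }
  for (t in tissues)
    rows[[length(rows) + 1L]] <- data.frame(tissue = t, gene = reference_gene,
                                            ct_mean = base_ct_reference)
  means <- do.call(rbind, rows)
  out <- with_seed(seed, {
    reps <- means[rep(seq_len(nrow(means)), each = n_replicates), ,
                  drop = FALSE]
    reps$replicate <- rep(seq_len(n_replicates), times = nrow(means))
    reps$ct <- reps$ct_mean + stats::rnorm(nrow(reps), 0, noise_sd)
    reps
  })
  out$sample <- paste0(out$tissue, "_", out$gene, "_r", out$replicate)
  ct <- out[, c("sample", "tissue", "gene", "ct", "replicate")]
  rownames(ct) <- NULL
  list(ct = ct, truth = do.call(rbind, truth))
}
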