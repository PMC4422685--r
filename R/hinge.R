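## Rigid hinge-rotation simulation of domain opening.
##
## The two domains of an APEH-like protein are connected by a short linker;
## rotating everything C-terminal to one backbone bond of a linker residue
## models the closed-to-open transition as a purely geometric motion (no
## energetics, no clash resolution - clashes are counted and reported).

#' Hinge specification
#'
#' @param residue Author residue number of the hinge (should lie in the
#'   linker region of the partition in use).
#' @param bond `"N-CA"` or `"CA-C"`.
#' @return Object of class `apeh_hinge`.
#' @export
hinge_spec <- function(residue, bond = c("N-CA", "CA-C")) {
  bond <- match.arg(bond)
  structure(list(residue = as.integer(residue), bond = bond),
            class = "apeh_hinge")
}

## Index of atoms that move: everything strictly C-terminal to the bond in
## sequence order. For N-CA the hinge residue moves except its N; for CA-C
## only its C/O(/OXT) move.
moving_atom_mask <- function(atoms, hinge) {
  later <- atoms$resno > hinge$residue
  inres <- atoms$resno == hinge$residue
  if (hinge$bond == "N-CA") {
    later | (inres & atoms$name != "N")
  } else {
    later | (inres & atoms$name %in% c("C", "O", "OXT"))
  }
}

#' Rotate a structure about a backbone bond
#'
#' All atoms C-terminal to the chosen bond are rotated as a rigid body about
#' the bond axis; everything upstream is untouched. Bond lengths and all
#' intra-segment distances are preserved exactly (rigid motion).
#'
#' @param x An `apeh_structure` (single chain assumed).
#' @param hinge An [hinge_spec()] (or residue number, with `bond`).
#' @param angle Rotation in degrees.
#' @param bond Bond name when `hinge` is given as a number.
#' @return Object of class `apeh_conformer`: list with `structure`, `hinge`,
#'   `angle` and the logical `moving` mask.
#' @export
rotate_about_bond <- function(x, hinge, angle, bond = "N-CA") {
  stopifnot(is_structure(x))
  if (!inherits(hinge, "apeh_hinge")) hinge <- hinge_spec(hinge, bond)
  a <- x$atoms
  nm <- strsplit(hinge$bond, "-", fixed = TRUE)[[1L]]
  p1 <- atom_xyz(a, hinge$residue, nm[1L])
  p2 <- atom_xyz(a, hinge$residue, nm[2L])
  if (is.null(p1) || is.null(p2))
    stop("configuration error: hinge residue ", hinge$residue,
         " lacks ", hinge$bond, " bond atoms", call. = FALSE)
  moving <- moving_atom_mask(a, hinge)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  if (any(moving) && angle %% 360 != 0) {
    xyz[moving, ] <- rotate_points(xyz[moving, , drop = FALSE], p1, p2 - p1,
                                   angle)
  }
  a$x <- xyz[, 1L]; a$y <- xyz[, 2L]; a$z <- xyz[, 3L]
  out <- x
  out$atoms <- a
  structure(list(structure = out, hinge = hinge, angle = angle,
                 moving = moving), class = "apeh_conformer")
}

as_structure <- function(x) {
  if (is_structure(x)) x
  else if (inherits(x, "apeh_conformer")) x$structure
  else stop("expected an apeh_structure or apeh_conformer", call. = FALSE)
}

#' Count steric clashes introduced by a hinge rotation
#'
#' Number of atom pairs with one atom in the fixed segment and one in the
#' moved segment closer than `threshold`, excluding pairs within the hinge
#' residue itself (which remain covalently bonded through the rotated bond).
#'
#' @param conformer An `apeh_conformer`.
#' @param threshold Distance in angstroms (default 2.0).
#' @return Integer clash count.
#' @export
clash_count <- function(conformer, threshold = 2.0) {
  stopifnot(inherits(conformer, "apeh_conformer"))
  if (threshold <= 0) return(0L)
  a <- conformer$structure$atoms
  fixed <- a[!conformer$moving, , drop = FALSE]
  moved <- a[conformer$moving, , drop = FALSE]
  if (!nrow(fixed) || !nrow(moved)) return(0L)
  D <- cross_dist(as.matrix(fixed[, c("x", "y", "z")]),
                  as.matrix(moved[, c("x", "y", "z")]))
  hres <- conformer$hinge$residue
  excl <- outer(fixed$resno == hres, moved$resno == hres, `&`)
  sum(D < threshold & !excl)
}

#' Opening metrics of a conformer
#'
#' Quantifies how open a two-domain conformer is: (a) distance between the
#' centroids of the N-ter and C-ter region atoms; (b) minimum inter-domain
#' atom distance; (c) site-exposure proxy, the count of N-ter-domain atoms
#' within `shell_radius` of any triad side-chain atom (fewer atoms crowding
#' the catalytic site = more exposed); (d) clash count (conformers only).
#'
#' @param x An `apeh_conformer` or `apeh_structure`.
#' @param partition An `apeh_partition` with both N-ter and C-ter regions.
#' @param triad An [triad_spec()].
#' @param shell_radius Exposure shell in angstroms (default 8).
#' @param clash_threshold Passed to [clash_count()] for conformers.
#' @return One-row data.frame: angle, centroid_distance,
#'   min_interdomain_distance, exposure_count, clash_count.
#' @export
opening_metrics <- function(x, partition, triad, shell_radius = 8,
                            clash_threshold = 2.0) {
  s <- as_structure(x)
  a <- polymer_atoms(s)
  lab <- region_label_for(partition, a$resno)
  nter <- a[!is.na(lab) & lab == "N-ter", , drop = FALSE]
  cter <- a[!is.na(lab) & lab == "C-ter", , drop = FALSE]
  if (!nrow(nter) || !nrow(cter))
    stop("partition must place atoms in both N-ter and C-ter regions",
         call. = FALSE)
  ncent <- colMeans(as.matrix(nter[, c("x", "y", "z")]))
  ccent <- colMeans(as.matrix(cter[, c("x", "y", "z")]))
  D <- cross_dist(as.matrix(nter[, c("x", "y", "z")]),
                  as.matrix(cter[, c("x", "y", "z")]))
  tres <- c(triad$ser, triad$asp, triad$his)
  tsc <- sidechain_atoms(a[a$resno %in% tres, , drop = FALSE])
  if (!nrow(tsc))
    stop("configuration error: triad residues have no side-chain atoms",
         call. = FALSE)
  E <- cross_dist(as.matrix(nter[, c("x", "y", "z")]),
                  as.matrix(tsc[, c("x", "y", "z")]))
  data.frame(
    angle = if (inherits(x, "apeh_conformer")) x$angle else 0,
    centroid_distance = vnorm(ncent - ccent),
    min_interdomain_distance = min(D),
    exposure_count = sum(apply(E, 1L, min) <= shell_radius),
    clash_count = if (inherits(x, "apeh_conformer"))
      clash_count(x, clash_threshold) else NA_integer_)
}

#' Hinge-rotation opening series
#'
#' Generates one conformer per rotation angle about the hinge bond and
#' attaches opening metrics; optionally writes each conformer as a PDB file.
#'
#' @param x An `apeh_structure`.
#' @param hinge An [hinge_spec()].
#' @param angles Rotation angles in degrees (default 20, 40, 60, 80).
#' @param partition,triad Passed to [opening_metrics()].
#' @param shell_radius,clash_threshold Passed to [opening_metrics()].
#' @param out_prefix Optional path prefix: conformers are written to
#'   `<prefix><angle>.pdb`.
#' @return List of class `apeh_opening_series`: `conformers` (list) and
#'   `metrics` (data.frame, one row per angle).
#' @export
opening_series <- function(x, hinge, angles = c(20, 40, 60, 80),
                           partition = NULL, triad = NULL,
                           shell_radius = 8, clash_threshold = 2.0,
                           out_prefix = NULL) {
  stopifnot(is_structure(x), inherits(hinge, "apeh_hinge"))
  conformers <- lapply(angles, function(th) rotate_about_bond(x, hinge, th))
  metrics <- NULL
  if (!is.null(partition) && !is.null(triad) && length(angles)) {
    metrics <- do.call(rbind, lapply(conformers, opening_metrics,
                                     partition = partition, triad = triad,
                                     shell_radius = shell_radius,
                                     clash_threshold = clash_threshold))
  } else if (length(angles)) {
    metrics <- data.frame(angle = angles)
  } else {
    metrics <- data.frame(angle = numeric(0))
  }
  if (!is.null(out_prefix)) {
    for (i in seq_along(conformers))
      write_structure(conformers[[i]]$structure,
                      paste0(out_prefix, angles[i], ".pdb"))
  }
  structure(list(conformers = conformers, metrics = metrics),
            class = "apeh_opening_series")
}

#' @export
print.apeh_opening_series <- function(x, ...) {
  cat("Hinge opening series (", length(x$conformers), " conformer(s))\n",
      sep = "")
  print.data.frame(x$metrics)
  invisible(x)
}

#' Charge-based domain opening propensity (heuristic)
#'
#' Scores each protein by the product of its N-ter and C-ter domain net
#' charges: a positive product means like-charged domains (electrostatic
#' repulsion, open-prone), a negative product means attraction
#' (closed-prone). Proteins are ranked by ascending score (least to most
#' open-prone), ties broken by total net charge. This is a deliberately
#' simple electrostatic heuristic, not an energy model.
#'
#' @param profiles Either a named list of `apeh_charge_profile` objects or a
#'   data.frame with columns `protein`, `nter_net`, `cter_net`.
#' @return data.frame: protein, nter_net, cter_net, score, total_net, rank
#'   (1 = least open-prone), sorted by rank.
#' @export
opening_propensity_score <- function(profiles) {
  if (is.data.frame(profiles)) {
    df <- profiles
    if (!all(c("protein", "nter_net", "cter_net") %in% names(df)))
      stop("need columns protein, nter_net, cter_net", call. = FALSE)
  } else {
    rows <- lapply(seq_along(profiles), function(i) {
      p <- profiles[[i]]
      nter <- p$net[p$region == "N-ter"]
      cter <- p$net[p$region == "C-ter"]
      if (!length(nter) || !length(cter))
        stop("profile ", i, " lacks an N-ter or C-ter region", call. = FALSE)
      data.frame(protein = if (!is.null(names(profiles)))
                   names(profiles)[i] else attr(p, "protein_id"),
                 nter_net = nter, cter_net = cter,
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
  }
  df$score <- df$nter_net * df$cter_net
  df$total_net <- df$nter_net + df$cter_net
  df <- df[order(df$score, df$total_net), , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}
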