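## Geometric detection of salt bridges and hydrogen bonds, plus
## intra-/inter-domain classification against a partition.
##
## Salt bridges follow the classical side-chain charged-group criterion
## (any Asp/Glu carboxylate oxygen within a distance cutoff, 4.0 A by
## default, of any Lys/Arg/His side-chain nitrogen), reported at
## residue-pair granularity with the closest qualifying atom pair.
## Hydrogen bonds use heavy-atom donor/acceptor tables with a
## donor-acceptor distance cutoff and, where an amide hydrogen can be
## placed at its ideal position, a D-H...A angle test; a stricter preset
## reproduces the common hydrogen-resolved criteria (H...A <= 2.5 A,
## D...A <= 3.9 A, angle >= 90 deg).

ACIDIC_ATOMS <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
BASIC_ATOMS <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
                    HIS = c("ND1", "NE2"))

SC_DONORS <- list(SER = "OG", THR = "OG1", TYR = "OH", ASN = "ND2",
                  GLN = "NE2", LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
                  HIS = c("ND1", "NE2"), TRP = "NE1", CYS = "SG")
SC_ACCEPTORS <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
                     ASN = "OD1", GLN = "OE1", SER = "OG", THR = "OG1",
                     TYR = "OH", HIS = c("ND1", "NE2"), MET = "SD")

select_named_atoms <- function(atoms, table) {
  keep <- rep(FALSE, nrow(atoms))
  for (res in names(table))
    keep <- keep | (atoms$resname == res & atoms$name %in% table[[res]])
  atoms[keep, , drop = FALSE]
}

res_key <- function(atoms) paste0(atoms$chain, ":", atoms$resno, atoms$icode)

warn_missing_sidechains <- function(atoms, table, what) {
  for (res in names(table)) {
    have <- atoms[atoms$resname == res, , drop = FALSE]
    if (!nrow(have)) next
    per <- split(have$name, res_key(have))
    bad <- names(per)[!vapply(per, function(n) any(table[[res]] %in% n),
                              logical(1L))]
    if (length(bad))
      warning("skipping ", res, " residue(s) lacking ", what, " atoms: ",
              paste(bad, collapse = ", "), call. = FALSE)
  }
}

empty_interactions <- function(kind) {
  out <- data.frame(chain_a = character(), resno_a = integer(),
                    resname_a = character(), atom_a = character(),
                    chain_b = character(), resno_b = integer(),
                    resname_b = character(), atom_b = character(),
                    distance = numeric(), angle_dha = numeric(),
                    stringsAsFactors = FALSE)
  attr(out, "kind") <- kind
  class(out) <- c("apeh_interactions", "data.frame")
  out
}

#' Detect salt bridges
#'
#' A residue pair forms a salt bridge when the minimum distance between any
#' acidic side-chain oxygen (Asp OD1/OD2, Glu OE1/OE2) and any basic
#' side-chain nitrogen (Lys NZ; Arg NE/NH1/NH2; His ND1/NE2) is within the
#' cutoff. One record per residue pair, reporting the closest atom pair;
#' side `a` is the acidic residue. Sorted by residue numbers.
#'
#' @param x An `apeh_structure`.
#' @param cutoff Distance cutoff in angstroms (default 4.0).
#' @param include_his Count histidine as a basic partner (default TRUE, in
#'   line with counting His among the positive residues)?
#' @return data.frame of class `apeh_interactions` with columns chain/resno/
#'   resname/atom for both partners, `distance` (A) and `angle_dha` (NA for
#'   salt bridges).
#' @export
find_salt_bridges <- function(x, cutoff = 4.0, include_his = TRUE) {
  stopifnot(is_structure(x), cutoff > 0)
  a <- polymer_atoms(x)
  basic_table <- if (include_his) BASIC_ATOMS else BASIC_ATOMS[c("LYS", "ARG")]
  warn_missing_sidechains(a, ACIDIC_ATOMS, "carboxylate")
  warn_missing_sidechains(a, basic_table, "basic nitrogen")
  acid <- select_named_atoms(a, ACIDIC_ATOMS)
  base <- select_named_atoms(a, basic_table)
  if (!nrow(acid) || !nrow(base)) return(empty_interactions("salt_bridge"))
  D <- cross_dist(as.matrix(acid[, c("x", "y", "z")]),
                  as.matrix(base[, c("x", "y", "z")]))
  hits <- which(D <= cutoff, arr.ind = TRUE)
  if (!nrow(hits)) return(empty_interactions("salt_bridge"))
  rec <- data.frame(
    chain_a = acid$chain[hits[, 1L]], resno_a = acid$resno[hits[, 1L]],
    resname_a = acid$resname[hits[, 1L]], atom_a = acid$name[hits[, 1L]],
    chain_b = base$chain[hits[, 2L]], resno_b = base$resno[hits[, 2L]],
    resname_b = base$resname[hits[, 2L]], atom_b = base$name[hits[, 2L]],
    distance = D[hits], angle_dha = NA_real_, stringsAsFactors = FALSE)
  pair <- paste(rec$chain_a, rec$resno_a, rec$chain_b, rec$resno_b)
  rec <- rec[order(pair, rec$distance, rec$atom_a, rec$atom_b), , drop = FALSE]
  rec <- rec[!duplicated(paste(rec$chain_a, rec$resno_a, rec$chain_b,
                               rec$resno_b)), , drop = FALSE]
  rec <- rec[order(rec$resno_a, rec$resno_b), , drop = FALSE]
  rownames(rec) <- NULL
  attr(rec, "kind") <- "salt_bridge"
  class(rec) <- c("apeh_interactions", "data.frame")
  rec
}

#' Hydrogen-bond criteria
#'
#' @param preset `"heavy"` (default): donor-acceptor distance <= `max_da`
#'   (3.5 A) and, when an ideal amide H can be placed, D-H...A angle >=
#'   `min_dha` (90 deg). `"hbplus"`: H...A <= 2.5 A, D...A <= 3.9 A,
#'   D-H...A >= 90 deg, applied where the H is placeable.
#' @param max_da,max_ha,min_dha Override individual thresholds.
#' @return List of class `apeh_hbond_criteria`.
#' @export
hbond_criteria <- function(preset = c("heavy", "hbplus"), max_da = NULL,
                           max_ha = NULL, min_dha = NULL) {
  preset <- match.arg(preset)
  crit <- switch(preset,
    heavy = list(name = "heavy", max_da = 3.5, max_ha = Inf, min_dha = 90),
    hbplus = list(name = "hbplus", max_da = 3.9, max_ha = 2.5, min_dha = 90))
  if (!is.null(max_da)) crit$max_da <- max_da
  if (!is.null(max_ha)) crit$max_ha <- max_ha
  if (!is.null(min_dha)) crit$min_dha <- min_dha
  structure(crit, class = "apeh_hbond_criteria")
}

## Ideal amide H on backbone N of residue i: along the external bisector of
## N->CA and N->C(i-1), 1.0 A from N. Returns NULL for the first residue of
## a chain (or missing neighbours).
place_amide_h <- function(atoms, rt, i) {
  if (i < 2L || rt$chain[i] != rt$chain[i - 1L]) return(NULL)
  sub <- function(j, nm) atom_xyz(atoms[atoms$chain == rt$chain[j] &
                                          atoms$resno == rt$resno[j] &
                                          atoms$icode == rt$icode[j], ,
                                        drop = FALSE], rt$resno[j], nm)
  N <- sub(i, "N"); CA <- sub(i, "CA"); Cprev <- sub(i - 1L, "C")
  if (is.null(N) || is.null(CA) || is.null(Cprev)) return(NULL)
  d <- unitv(N - CA) + unitv(N - Cprev)
  if (vnorm(d) < 1e-6) return(NULL)
  N + unitv(d) * 1.0
}

#' Detect hydrogen bonds
#'
#' Heavy-atom donor/acceptor detection: donors are backbone amide N (except
#' proline) plus standard side-chain donors; acceptors are backbone carbonyl
#' O (and OXT) plus standard side-chain acceptors. A donor-acceptor pair is
#' reported once. Pairs within one residue, and the directly bonded
#' N(i)-O(i-1) backbone pair, are excluded. For backbone donors the amide H
#' is placed at its ideal position and the D-H...A angle test applied; for
#' donors without a placeable H only the distance criteria apply.
#'
#' @param x An `apeh_structure`.
#' @param criteria An [hbond_criteria()] object.
#' @return data.frame of class `apeh_interactions`; side `a` is the donor.
#' @export
find_hbonds <- function(x, criteria = hbond_criteria()) {
  stopifnot(is_structure(x), inherits(criteria, "apeh_hbond_criteria"))
  a <- polymer_atoms(x)
  rt <- residue_table(x)

  don_bb <- a[a$name == "N" & a$resname != "PRO", , drop = FALSE]
  don_sc <- select_named_atoms(a, SC_DONORS)
  don <- rbind(don_bb, don_sc)
  acc_bb <- a[a$name %in% c("O", "OXT"), , drop = FALSE]
  acc_sc <- select_named_atoms(a, SC_ACCEPTORS)
  acc <- rbind(acc_bb, acc_sc)
  if (!nrow(don) || !nrow(acc)) return(empty_interactions("hbond"))

  D <- cross_dist(as.matrix(don[, c("x", "y", "z")]),
                  as.matrix(acc[, c("x", "y", "z")]))
  hits <- which(D <= criteria$max_da, arr.ind = TRUE)
  if (!nrow(hits)) return(empty_interactions("hbond"))

  keep <- logical(nrow(hits))
  angle <- rep(NA_real_, nrow(hits))
  hcache <- new.env(parent = emptyenv())
  rt_index <- stats::setNames(seq_len(nrow(rt)), rt$key)
  for (k in seq_len(nrow(hits))) {
    di <- hits[k, 1L]; ai <- hits[k, 2L]
    same_res <- don$chain[di] == acc$chain[ai] &&
      don$resno[di] == acc$resno[ai] && don$icode[di] == acc$icode[ai]
    if (same_res) next
    ## covalently linked through the peptide bond: amide N(i) vs O(i-1)
    if (don$name[di] == "N" && acc$name[ai] == "O" &&
        don$chain[di] == acc$chain[ai] &&
        don$resno[di] - acc$resno[ai] == 1L) next
    ok <- TRUE
    if (don$name[di] == "N") {
      key <- paste(don$chain[di], don$resno[di], don$icode[di], sep = "|")
      if (!exists(key, envir = hcache)) {
        i <- rt_index[[key]]
        assign(key, if (is.null(i)) NULL else place_amide_h(a, rt, i),
               envir = hcache)
      }
      H <- get(key, envir = hcache)
      if (!is.null(H)) {
        Dxyz <- as.numeric(don[di, c("x", "y", "z")])
        Axyz <- as.numeric(acc[ai, c("x", "y", "z")])
        ha <- vnorm(Axyz - H)
        ang <- acos(pmin(1, pmax(-1, sum(unitv(Dxyz - H) * unitv(Axyz - H))))) *
          180 / pi
        angle[k] <- ang
        if (ha > criteria$max_ha || ang < criteria$min_dha) ok <- FALSE
      }
    }
    keep[k] <- ok
  }
  hits <- hits[keep, , drop = FALSE]
  angle <- angle[keep]
  if (!nrow(hits)) return(empty_interactions("hbond"))
  rec <- data.frame(
    chain_a = don$chain[hits[, 1L]], resno_a = don$resno[hits[, 1L]],
    resname_a = don$resname[hits[, 1L]], atom_a = don$name[hits[, 1L]],
    chain_b = acc$chain[hits[, 2L]], resno_b = acc$resno[hits[, 2L]],
    resname_b = acc$resname[hits[, 2L]], atom_b = acc$name[hits[, 2L]],
    distance = D[hits], angle_dha = angle, stringsAsFactors = FALSE)
  rec <- rec[!duplicated(paste(rec$chain_a, rec$resno_a, rec$atom_a,
                               rec$chain_b, rec$resno_b, rec$atom_b)), ,
             drop = FALSE]
  rec <- rec[order(rec$resno_a, rec$resno_b, rec$atom_a, rec$atom_b), ,
             drop = FALSE]
  rownames(rec) <- NULL
  attr(rec, "kind") <- "hbond"
  class(rec) <- c("apeh_interactions", "data.frame")
  rec
}

#' Classify interactions as intra- or inter-domain
#'
#' Annotates each interaction with a `domain_class`: `intra-N` (both
#' residues in the N-ter region), `intra-C`, `inter` (one residue in each
#' domain), or `linker` (either residue in the linker; excluded from both
#' intra and inter tallies).
#'
#' @param interactions An `apeh_interactions` table.
#' @param partition An `apeh_partition` covering every residue involved.
#' @return The annotated table; [interaction_counts()] summarises it.
#' @export
classify_interdomain <- function(interactions, partition) {
  out <- interactions
  if (!nrow(out)) {
    out$domain_class <- character(0)
    return(out)
  }
  lab_a <- region_label_for(partition, out$resno_a)
  lab_b <- region_label_for(partition, out$resno_b)
  bad <- unique(c(out$resno_a[is.na(lab_a)], out$resno_b[is.na(lab_b)]))
  if (length(bad))
    stop("classification error: residue(s) outside all partition regions: ",
         paste(sort(bad), collapse = ", "), call. = FALSE)
  out$domain_class <- ifelse(
    lab_a == "linker" | lab_b == "linker", "linker",
    ifelse(lab_a == "N-ter" & lab_b == "N-ter", "intra-N",
           ifelse(lab_a == "C-ter" & lab_b == "C-ter", "intra-C", "inter")))
  out
}

#' Summary counts for a classified interaction table
#'
#' @param interactions Output of [classify_interdomain()] (or an
#'   unclassified table, in which case only `total` is reported).
#' @return Named integer vector: total, intra-N, intra-C, inter, linker.
#' @export
interaction_counts <- function(interactions) {
  out <- c(total = nrow(interactions), `intra-N` = 0L, `intra-C` = 0L,
           inter = 0L, linker = 0L)
  if (!is.null(interactions$domain_class)) {
    tab <- table(interactions$domain_class)
    for (k in intersect(names(tab), names(out))) out[k] <- as.integer(tab[k])
  }
  out
}

#' @export
print.apeh_interactions <- function(x, ...) {
  cat(attr(x, "kind"), "interactions:", nrow(x), "record(s)\n")
  print.data.frame(utils::head(as.data.frame(x), 15L))
  if (nrow(x) > 15L) cat("... (", nrow(x) - 15L, " more rows)\n", sep = "")
  invisible(x)
}
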