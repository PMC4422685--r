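# Brute-force oracles and hand-built fixtures, kept deliberately naive
# (nested loops over explicit atom lists) so they are independent of the
# package's vectorised detection paths.

euclid <- function(p, q) sqrt(sum((p - q)^2))

atom_coords <- function(atoms, i) as.numeric(atoms[i, c("x", "y", "z")])

# residue-pair salt bridges by exhaustive enumeration
bf_salt_bridges <- function(x, cutoff = 4.0, include_his = TRUE) {
  a <- x$atoms[x$atoms$type == "ATOM", , drop = FALSE]
  acid_tab <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
  base_tab <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"))
  if (include_his) base_tab$HIS <- c("ND1", "NE2")
  found <- list()
  for (i in seq_len(nrow(a))) {
    if (!(a$resname[i] %in% names(acid_tab))) next
    if (!(a$name[i] %in% acid_tab[[a$resname[i]]])) next
    for (j in seq_len(nrow(a))) {
      if (!(a$resname[j] %in% names(base_tab))) next
      if (!(a$name[j] %in% base_tab[[a$resname[j]]])) next
      d <- euclid(atom_coords(a, i), atom_coords(a, j))
      if (d <= cutoff) {
        key <- paste(a$resno[i], a$resno[j])
        if (is.null(found[[key]]) || d < found[[key]])
          found[[key]] <- d
      }
    }
  }
  if (!length(found)) {
    return(data.frame(resno_a = integer(), resno_b = integer(),
                      distance = numeric()))
  }
  parts <- do.call(rbind, lapply(names(found), function(k)
    as.integer(strsplit(k, " ")[[1]])))
  out <- data.frame(resno_a = parts[, 1], resno_b = parts[, 2],
                    distance = unname(unlist(found)))
  out[order(out$resno_a, out$resno_b), , drop = FALSE]
}

# donor/acceptor hydrogen bonds by exhaustive enumeration (heavy criteria:
# D-A distance, plus the amide-H angle test when residue i-1 provides a C)
bf_hbonds <- function(x, max_da = 3.5, min_dha = 90) {
  a <- x$atoms[x$atoms$type == "ATOM", , drop = FALSE]
  don_tab <- list(SER = "OG", THR = "OG1", TYR = "OH", ASN = "ND2",
                  GLN = "NE2", LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
                  HIS = c("ND1", "NE2"), TRP = "NE1", CYS = "SG")
  acc_tab <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
                  ASN = "OD1", GLN = "OE1", SER = "OG", THR = "OG1",
                  TYR = "OH", HIS = c("ND1", "NE2"), MET = "SD")
  is_donor <- function(i) {
    (a$name[i] == "N" && a$resname[i] != "PRO") ||
      (a$resname[i] %in% names(don_tab) &&
         a$name[i] %in% don_tab[[a$resname[i]]])
  }
  is_acceptor <- function(j) {
    a$name[j] %in% c("O", "OXT") ||
      (a$resname[j] %in% names(acc_tab) &&
         a$name[j] %in% acc_tab[[a$resname[j]]])
  }
  amide_h <- function(i) {
    resno <- a$resno[i]
    prevC <- which(a$resno == resno - 1 & a$name == "C")
    myCA <- which(a$resno == resno & a$name == "CA")
    if (!length(prevC) || !length(myCA)) return(NULL)
    N <- atom_coords(a, i)
    v1 <- N - atom_coords(a, myCA[1])
    v2 <- N - atom_coords(a, prevC[1])
    v <- v1 / sqrt(sum(v1^2)) + v2 / sqrt(sum(v2^2))
    N + v / sqrt(sum(v^2))
  }
  rows <- list()
  for (i in seq_len(nrow(a))) {
    if (!is_donor(i)) next
    for (j in seq_len(nrow(a))) {
      if (!is_acceptor(j)) next
      if (a$resno[i] == a$resno[j]) next
      if (a$name[i] == "N" && a$name[j] == "O" &&
          a$resno[i] - a$resno[j] == 1) next
      d <- euclid(atom_coords(a, i), atom_coords(a, j))
      if (d > max_da) next
      if (a$name[i] == "N") {
        H <- amide_h(i)
        if (!is.null(H)) {
          dh <- atom_coords(a, i) - H
          ah <- atom_coords(a, j) - H
          cosang <- sum(dh * ah) / sqrt(sum(dh^2) * sum(ah^2))
          if (acos(max(-1, min(1, cosang))) * 180 / pi < min_dha) next
        }
      }
      rows[[length(rows) + 1]] <- data.frame(
        resno_a = a$resno[i], atom_a = a$name[i],
        resno_b = a$resno[j], atom_b = a$name[j], distance = d)
    }
  }
  if (!length(rows)) {
    return(data.frame(resno_a = integer(), atom_a = character(),
                      resno_b = integer(), atom_b = character(),
                      distance = numeric()))
  }
  out <- do.call(rbind, rows)
  out[order(out$resno_a, out$resno_b, out$atom_a, out$atom_b), ,
      drop = FALSE]
}

# all side-chain atoms of non-triad residues within cutoff of a triad
# side-chain atom, by exhaustive scan
bf_triad_neighbours <- function(x, triad, cutoff = 3.0) {
  a <- x$atoms[x$atoms$type == "ATOM", , drop = FALSE]
  bb <- c("N", "CA", "C", "O", "OXT")
  tres <- c(triad$ser, triad$asp, triad$his)
  hits <- list()
  for (i in seq_len(nrow(a))) {
    if (a$name[i] %in% bb || a$resno[i] %in% tres) next
    best <- Inf
    for (j in seq_len(nrow(a))) {
      if (a$name[j] %in% bb || !(a$resno[j] %in% tres)) next
      best <- min(best, euclid(atom_coords(a, i), atom_coords(a, j)))
    }
    if (best <= cutoff)
      hits[[length(hits) + 1]] <- data.frame(resno = a$resno[i],
                                             atom = a$name[i],
                                             distance = best)
  }
  if (!length(hits)) {
    return(data.frame(resno = integer(), atom = character(),
                      distance = numeric()))
  }
  out <- do.call(rbind, hits)
  out[order(out$resno, out$atom), , drop = FALSE]
}

# random peptide with charged residues and mixed secondary structure,
# for detector-vs-oracle equivalence sweeps
random_test_structure <- function(seed, n_min = 20, n_max = 60) {
  set.seed(seed)
  n <- sample(n_min:n_max, 1)
  seqn <- random_charged_sequence(n, n_neg = max(1, n %/% 8),
                                  n_pos = max(1, n %/% 8), seed = seed)
  basin <- sample(c("helix", "ext"), n, replace = TRUE)
  phi <- ifelse(basin == "helix", -57, -139) + stats::runif(n, -10, 10)
  psi <- ifelse(basin == "helix", -47, 135) + stats::runif(n, -10, 10)
  make_peptide(seqn, phi = phi, psi = psi, id = paste0("random", seed))
}

# hand-built micro-structure: one atom table row
atom_row <- function(serial, name, resname, resno, xyz, chain = "A") {
  data.frame(type = "ATOM", serial = serial, name = name, altloc = "",
             resname = resname, chain = chain, resno = resno, icode = "",
             x = xyz[1], y = xyz[2], z = xyz[3], occupancy = 1, bfactor = 0,
             element = substr(name, 1, 1), stringsAsFactors = FALSE)
}

# Glu/Lys pair whose closest charged atoms sit at exactly `d` angstroms
make_charged_pair <- function(d) {
  rows <- rbind(
    atom_row(1, "N", "GLU", 1, c(0, 0, 0)),
    atom_row(2, "CA", "GLU", 1, c(1.5, 0, 0)),
    atom_row(3, "C", "GLU", 1, c(2.2, 1.2, 0)),
    atom_row(4, "O", "GLU", 1, c(2.0, 2.3, 0)),
    atom_row(5, "CB", "GLU", 1, c(2.2, -1.2, 0)),
    atom_row(6, "CG", "GLU", 1, c(3.6, -1.2, 0)),
    atom_row(7, "CD", "GLU", 1, c(4.3, -2.4, 0)),
    atom_row(8, "OE1", "GLU", 1, c(5.6, -2.4, 0)),
    atom_row(9, "OE2", "GLU", 1, c(3.7, -3.5, 0)),
    atom_row(10, "N", "LYS", 2, c(5.6 + d, 3.0, 0)),
    atom_row(11, "CA", "LYS", 2, c(5.6 + d, 1.5, 0)),
    atom_row(12, "C", "LYS", 2, c(6.8 + d, 0.8, 0)),
    atom_row(13, "O", "LYS", 2, c(7.9 + d, 1.4, 0)),
    atom_row(14, "CB", "LYS", 2, c(5.6 + d, 0.2, 0)),
    atom_row(15, "CG", "LYS", 2, c(5.6 + d, -1.0, 0)),
    atom_row(16, "CD", "LYS", 2, c(5.6 + d, -2.2, 0)),
    atom_row(17, "CE", "LYS", 2, c(5.6 + d, -2.4, 1.2)),
    atom_row(18, "NZ", "LYS", 2, c(5.6 + d, -2.4, 0)))
  new_structure(rows, id = sprintf("pair_%.1f", d))
}
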