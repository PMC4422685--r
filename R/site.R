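## Catalytic-triad environment: side-chain atoms of non-triad residues
## within a cutoff of any triad side-chain atom, with a charge-character
## summary. "Side chain" means atoms beyond the backbone, CB inclusive;
## glycine contributes nothing.

BACKBONE_NAMES <- c("N", "CA", "C", "O", "OXT")

sidechain_atoms <- function(atoms) {
  atoms[!(atoms$name %in% BACKBONE_NAMES) &
          !grepl("^H", atoms$element) & !grepl("^[0-9]*H", atoms$name), ,
        drop = FALSE]
}

atom_charge_class <- function(resname, name) {
  neg <- (resname == "ASP" & name %in% c("OD1", "OD2")) |
    (resname == "GLU" & name %in% c("OE1", "OE2"))
  pos <- (resname == "LYS" & name == "NZ") |
    (resname == "ARG" & name %in% c("NE", "NH1", "NH2")) |
    (resname == "HIS" & name %in% c("ND1", "NE2"))
  ifelse(neg, "negative", ifelse(pos, "positive", "neutral"))
}

#' Catalytic triad specification
#'
#' @param ser,asp,his Author residue numbers of the Ser/Asp/His triad.
#' @return Object of class `apeh_triad`.
#' @examples
#' triad_spec(585, 673, 705) # APEH-1_Ch numbering
#' @export
triad_spec <- function(ser, asp, his) {
  structure(list(ser = as.integer(ser), asp = as.integer(asp),
                 his = as.integer(his)), class = "apeh_triad")
}

#' Side-chain environment of the catalytic triad
#'
#' Lists every side-chain atom of non-triad residues within `cutoff` of any
#' triad side-chain atom, with its minimum distance, the closest triad atom
#' (ties broken by atom-name order) and a per-atom charge class
#' (carboxylate O negative; Lys/Arg/His side-chain N positive).
#'
#' @param x An `apeh_structure`.
#' @param triad An [triad_spec()].
#' @param cutoff Shell radius in angstroms (default 3.0).
#' @return Object of class `apeh_site_env`: list with `neighbours`
#'   (data.frame chain, resno, resname, atom, closest_triad_resno,
#'   closest_triad_atom, distance, charge_class), `n_negative_atoms`,
#'   `n_positive_atoms`, `triad`, `cutoff`.
#' @export
triad_environment <- function(x, triad, cutoff = 3.0) {
  stopifnot(is_structure(x), inherits(triad, "apeh_triad"), cutoff > 0)
  a <- polymer_atoms(x)
  tres <- c(triad$ser, triad$asp, triad$his)
  missing <- tres[!(tres %in% a$resno)]
  if (length(missing))
    stop("configuration error: triad residue(s) absent from structure: ",
         paste(missing, collapse = ", "), call. = FALSE)
  sc <- sidechain_atoms(a)
  tsc <- sc[sc$resno %in% tres, , drop = FALSE]
  if (!nrow(tsc))
    stop("configuration error: triad residues have no side-chain atoms",
         call. = FALSE)
  other <- sc[!(sc$resno %in% tres), , drop = FALSE]
  neigh <- data.frame(chain = character(), resno = integer(),
                      resname = character(), atom = character(),
                      closest_triad_resno = integer(),
                      closest_triad_atom = character(),
                      distance = numeric(), charge_class = character(),
                      stringsAsFactors = FALSE)
  if (nrow(other)) {
    D <- cross_dist(as.matrix(other[, c("x", "y", "z")]),
                    as.matrix(tsc[, c("x", "y", "z")]))
    dmin <- apply(D, 1L, min)
    within <- which(dmin <= cutoff)
    if (length(within)) {
      closest <- vapply(within, function(i) {
        ord <- order(D[i, ], tsc$name)
        ord[1L]
      }, integer(1L))
      neigh <- data.frame(
        chain = other$chain[within], resno = other$resno[within],
        resname = other$resname[within], atom = other$name[within],
        closest_triad_resno = tsc$resno[closest],
        closest_triad_atom = tsc$name[closest],
        distance = dmin[within],
        charge_class = atom_charge_class(other$resname[within],
                                         other$name[within]),
        stringsAsFactors = FALSE)
      neigh <- neigh[order(neigh$resno, neigh$atom), , drop = FALSE]
      rownames(neigh) <- NULL
    }
  }
  structure(list(neighbours = neigh,
                 n_negative_atoms = sum(neigh$charge_class == "negative"),
                 n_positive_atoms = sum(neigh$charge_class == "positive"),
                 triad = triad, cutoff = cutoff),
            class = "apeh_site_env")
}

#' Charge character of a triad environment
#'
#' @param env An `apeh_site_env`.
#' @return `"negative-dominated"`, `"positive-dominated"`, or `"balanced"`.
#' @export
environment_charge_summary <- function(env) {
  stopifnot(inherits(env, "apeh_site_env"))
  if (env$n_negative_atoms > env$n_positive_atoms) "negative-dominated"
  else if (env$n_positive_atoms > env$n_negative_atoms) "positive-dominated"
  else "balanced"
}

#' @export
print.apeh_site_env <- function(x, ...) {
  cat("Triad environment (Ser", x$triad$ser, "/Asp", x$triad$asp, "/His",
      x$triad$his, ", cutoff ", x$cutoff, " A): ", nrow(x$neighbours),
      " neighbour atom(s), ", x$n_negative_atoms, " negative, ",
      x$n_positive_atoms, " positive -> ", environment_charge_summary(x),
      "\n", sep = "")
  if (nrow(x$neighbours)) print.data.frame(x$neighbours)
  invisible(x)
}
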