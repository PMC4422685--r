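## Backbone dihedral summaries and a simple rectangle-union Ramachandran
## region map. Published Ramachandran references (PROCHECK and successors)
## define regions empirically from high-resolution structures; for model QC
## at the "fraction in core+allowed" level a documented rectangle union is
## sufficient and keeps the classification fully transparent and
## user-overridable.

#' Default Ramachandran region map
#'
#' A data.frame of phi/psi rectangles (degrees, inclusive bounds) labelled
#' `core` or `allowed`. Core covers the right-handed helical basin and the
#' extended/sheet basin; allowed adds the bridge between them and the
#' left-handed helical basin. Pass a modified copy to
#' [ramachandran_summary()] to change the classification.
#'
#' @return data.frame with columns region, phi_min, phi_max, psi_min, psi_max.
#' @export
rama_region_map <- function() {
  data.frame(
    region = c("core", "core", "core", "allowed", "allowed", "allowed"),
    phi_min = c(-180, -180, -180, -180, -180, 20),
    phi_max = c(-20, -20, -20, -20, -20, 100),
    psi_min = c(-120, 90, -180, 50, -150, -20),
    psi_max = c(50, 180, -150, 90, -120, 100),
    stringsAsFactors = FALSE)
}

classify_rama <- function(phi, psi, map) {
  hit <- function(row) phi >= map$phi_min[row] & phi <= map$phi_max[row] &
    psi >= map$psi_min[row] & psi <= map$psi_max[row]
  out <- rep("outlier", length(phi))
  for (r in which(map$region == "allowed")) out[hit(r)] <- "allowed"
  for (r in which(map$region == "core")) out[hit(r)] <- "core"
  out[is.na(phi) | is.na(psi)] <- NA_character_
  out
}

#' Backbone dihedrals and Ramachandran summary
#'
#' Computes per-residue (phi, psi) from backbone N/CA/C atoms and classifies
#' each residue against a rectangle-union region map. Terminal residues
#' (no preceding C or following N) get NA dihedrals and are excluded from
#' the fraction.
#'
#' @param x An `apeh_structure` with at least 3 consecutive residues
#'   carrying complete backbone N, CA, C atoms.
#' @param map Region map, see [rama_region_map()].
#' @return data.frame (class `apeh_rama`) with chain, resno, resname, phi,
#'   psi, region; attribute `fraction_core_allowed` holds the fraction of
#'   assessed residues in core or allowed regions (NA when nothing is
#'   assessable, with a warning).
#' @export
ramachandran_summary <- function(x, map = rama_region_map()) {
  stopifnot(is_structure(x))
  a <- polymer_atoms(x)
  rt <- residue_table(x)
  n <- nrow(rt)
  phi <- psi <- rep(NA_real_, n)
  get <- function(i, name) atom_xyz(a[a$chain == rt$chain[i] &
                                        a$resno == rt$resno[i] &
                                        a$icode == rt$icode[i], , drop = FALSE],
                                    rt$resno[i], name)
  bb <- lapply(seq_len(n), function(i)
    list(N = get(i, "N"), CA = get(i, "CA"), C = get(i, "C")))
  for (i in seq_len(n)) {
    this <- bb[[i]]
    if (is.null(this$N) || is.null(this$CA) || is.null(this$C)) next
    if (i > 1L && rt$chain[i] == rt$chain[i - 1L] && !is.null(bb[[i - 1L]]$C)) {
      phi[i] <- tryCatch(
        compute_dihedral(bb[[i - 1L]]$C, this$N, this$CA, this$C),
        error = function(e) NA_real_)
    }
    if (i < n && rt$chain[i] == rt$chain[i + 1L] && !is.null(bb[[i + 1L]]$N)) {
      psi[i] <- tryCatch(
        compute_dihedral(this$N, this$CA, this$C, bb[[i + 1L]]$N),
        error = function(e) NA_real_)
    }
  }
  region <- classify_rama(phi, psi, map)
  assessed <- !is.na(phi) & !is.na(psi)
  if (!any(assessed)) {
    warning("no residue with complete (phi, psi); fraction undefined",
            call. = FALSE)
    frac <- NA_real_
  } else {
    frac <- mean(region[assessed] %in% c("core", "allowed"))
  }
  out <- data.frame(chain = rt$chain, resno = rt$resno, resname = rt$resname,
                    phi = phi, psi = psi, region = region,
                    stringsAsFactors = FALSE)
  attr(out, "fraction_core_allowed") <- frac
  class(out) <- c("apeh_rama", "data.frame")
  out
}

#' @export
print.apeh_rama <- function(x, ...) {
  frac <- attr(x, "fraction_core_allowed")
  cat("Ramachandran summary: ", sum(!is.na(x$phi) & !is.na(x$psi)),
      " assessed residues, fraction core+allowed = ",
      if (is.na(frac)) "NA" else sprintf("%.3f", frac), "\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("... (", nrow(x) - 10L, " more rows)\n", sep = "")
  invisible(x)
}
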