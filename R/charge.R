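## Sequence-level charge bookkeeping per domain region.
##
## Convention used throughout: negative = Asp + Glu side chains, positive =
## His + Lys + Arg side chains (histidine counted as positive, no pKa
## modelling), net = positives - negatives in elementary charge units.
## Terminal amine/carboxylate charges are not counted.

#' Average residue masses (Da)
#'
#' Standard average masses of amino-acid residues (monomer minus one water).
#' @keywords internal
AA_RESIDUE_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)

WATER_MASS <- 18.0153

#' Domain partition of a two-domain protein
#'
#' Inclusive residue-number regions labelled `N-ter`, `linker`, `C-ter`.
#' When `linker` is omitted it is taken as the gap between the N-ter end and
#' the C-ter start (the canonical two-domain APEH architecture has a
#' ten-residue connector).
#'
#' @param nter,cter Numeric `c(start, end)`, inclusive.
#' @param linker Optional `c(start, end)`; defaults to the gap between the
#'   domains, or no linker region when the domains are adjacent.
#' @param protein_id Label.
#' @return Object of class `apeh_partition`: data.frame(label, start, end).
#' @examples
#' domain_partition(c(1, 450), c(461, 729), protein_id = "APEH-1_Ch")
#' @export
domain_partition <- function(nter, cter, linker = NULL, protein_id = "protein") {
  if (is.null(linker) && cter[1L] - nter[2L] > 1L)
    linker <- c(nter[2L] + 1L, cter[1L] - 1L)
  regions <- rbind(
    data.frame(label = "N-ter", start = nter[1L], end = nter[2L]),
    if (!is.null(linker))
      data.frame(label = "linker", start = linker[1L], end = linker[2L]),
    data.frame(label = "C-ter", start = cter[1L], end = cter[2L]))
  if (any(regions$start > regions$end))
    stop("region start must not exceed end", call. = FALSE)
  for (i in seq_len(nrow(regions) - 1L))
    if (regions$end[i] >= regions$start[i + 1L])
      stop("partition regions overlap or are out of order", call. = FALSE)
  structure(regions, protein_id = protein_id,
            class = c("apeh_partition", "data.frame"))
}

#' Parse a partition from a compact region string
#'
#' @param spec String like `"Nter:1-450,linker:451-460,Cter:461-729"`.
#' @param protein_id Label.
#' @return An `apeh_partition`.
#' @export
parse_partition <- function(spec, protein_id = "protein") {
  parts <- strsplit(spec, ",", fixed = TRUE)[[1L]]
  got <- list()
  for (p in parts) {
    kv <- strsplit(trimws(p), ":", fixed = TRUE)[[1L]]
    if (length(kv) != 2L) stop("bad region spec: ", p, call. = FALSE)
    rng <- as.integer(strsplit(kv[2L], "-", fixed = TRUE)[[1L]])
    lab <- tolower(gsub("[^a-z]", "", tolower(kv[1L])))
    got[[lab]] <- rng
  }
  if (is.null(got$nter) || is.null(got$cter))
    stop("region spec must define Nter and Cter", call. = FALSE)
  domain_partition(got$nter, got$cter, linker = got$linker,
                   protein_id = protein_id)
}

region_label_for <- function(partition, resno) {
  out <- rep(NA_character_, length(resno))
  for (i in seq_len(nrow(partition)))
    out[resno >= partition$start[i] & resno <= partition$end[i]] <-
      partition$label[i]
  out
}

#' Charge class of a residue
#'
#' @param aa One-letter code(s); D/E are negative, H/K/R positive, all other
#'   standard residues (and 'X') neutral.
#' @return Character vector in {"negative", "positive", "neutral"}.
#' @export
residue_charge_class <- function(aa) {
  aa <- toupper(aa)
  ok <- aa %in% c(names(AA_RESIDUE_MASS), "X")
  if (!all(ok))
    stop("invalid one-letter code(s): ", paste(unique(aa[!ok]), collapse = ", "),
         call. = FALSE)
  ifelse(aa %in% c("D", "E"), "negative",
         ifelse(aa %in% c("H", "K", "R"), "positive", "neutral"))
}

#' Per-region charge profile of a sequence
#'
#' Counts acidic (D+E) and basic (H+K+R) residues and the net charge in
#' each region of a partition. The protein total is taken over the N-ter
#' and C-ter regions only (the linker is excluded from domain totals, as in
#' published domain tallies); set `include_linker_in_total = TRUE` for a
#' full-partition total.
#'
#' @param sequence One-letter string; positions are residue numbers 1..n.
#' @param partition An `apeh_partition` (or `c(start, end)` treated as one
#'   full region).
#' @param include_linker_in_total Count linker residues in `total_net`?
#' @return Object of class `apeh_charge_profile`: data.frame(region, start,
#'   end, n_negative, n_positive, net) with attributes `protein_id` and
#'   `total_net`.
#' @export
region_charge_profile <- function(sequence, partition,
                                  include_linker_in_total = FALSE) {
  aa <- strsplit(toupper(sequence), "")[[1L]]
  if (is.numeric(partition) && length(partition) == 2L) {
    partition <- structure(
      data.frame(label = "full", start = partition[1L], end = partition[2L]),
      protein_id = "protein", class = c("apeh_partition", "data.frame"))
  }
  if (max(partition$end) > length(aa) || min(partition$start) < 1L)
    stop("range error: partition exceeds sequence length ", length(aa),
         call. = FALSE)
  cls <- residue_charge_class(aa)
  rows <- lapply(seq_len(nrow(partition)), function(i) {
    idx <- partition$start[i]:partition$end[i]
    nneg <- sum(cls[idx] == "negative")
    npos <- sum(cls[idx] == "positive")
    data.frame(region = partition$label[i], start = partition$start[i],
               end = partition$end[i], n_negative = nneg, n_positive = npos,
               net = npos - nneg, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  in_total <- if (include_linker_in_total) rep(TRUE, nrow(out))
              else out$region != "linker"
  attr(out, "total_net") <- sum(out$net[in_total])
  attr(out, "protein_id") <- attr(partition, "protein_id")
  class(out) <- c("apeh_charge_profile", "data.frame")
  out
}

#' @export
print.apeh_charge_profile <- function(x, ...) {
  cat("Charge profile for '", attr(x, "protein_id"), "' (net = HKR - DE)\n",
      sep = "")
  print.data.frame(as.data.frame(x))
  cat("Total protein net charge (domains): ", attr(x, "total_net"), "\n",
      sep = "")
  invisible(x)
}

#' Average molecular mass of a protein sequence
#'
#' Sum of standard average residue masses plus one water (18.02 Da).
#'
#' @param sequence Non-empty one-letter string of standard residues.
#' @param kda Report in kDa rounded to one decimal instead of Da?
#' @return Mass in Da (or kDa when `kda = TRUE`).
#' @examples
#' molecular_mass("GG") # 132.12 Da
#' @export
molecular_mass <- function(sequence, kda = FALSE) {
  aa <- strsplit(toupper(sequence), "")[[1L]]
  if (!length(aa)) stop("empty sequence", call. = FALSE)
  bad <- !(aa %in% names(AA_RESIDUE_MASS))
  if (any(bad))
    stop("cannot compute mass: non-standard residue(s) ",
         paste(unique(aa[bad]), collapse = ", "), call. = FALSE)
  m <- sum(AA_RESIDUE_MASS[aa]) + WATER_MASS
  if (kda) round(m / 1000, 1) else m
}

#' Combined charge table for several proteins
#'
#' One block of rows per protein: per-region acidic/basic counts, net
#' charges and the protein total, mirroring the layout of published
#' domain-charge comparisons.
#'
#' @param proteins Named list; each element a list with `sequence` and
#'   `partition`.
#' @return data.frame with columns protein, region, start, end, n_negative,
#'   n_positive, net, total_net. Zero proteins give a zero-row table.
#' @export
charge_table <- function(proteins) {
  if (!length(proteins))
    return(data.frame(protein = character(), region = character(),
                      start = integer(), end = integer(),
                      n_negative = integer(), n_positive = integer(),
                      net = integer(), total_net = integer()))
  ids <- names(proteins)
  if (is.null(ids)) ids <- paste0("protein", seq_along(proteins))
  blocks <- lapply(seq_along(proteins), function(i) {
    prof <- region_charge_profile(proteins[[i]]$sequence,
                                  proteins[[i]]$partition)
    cbind(protein = ids[i], as.data.frame(prof),
          total_net = attr(prof, "total_net"))
  })
  do.call(rbind, blocks)
}
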