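## Published reference values for the Antarctic/temperate fish APEH
## isoforms, shipped as plain data so the worked examples and the
## propensity ranking can run without any external download. Domain
## boundaries and per-domain charge tallies come from the published
## comparison of the four Antarctic isoform models; primer efficiencies
## from the published qRT-PCR assay design.

#' Published domain partitions of the four Antarctic APEH isoforms
#'
#' Inclusive residue ranges of the beta-propeller (N-ter) and catalytic
#' alpha/beta (C-ter) domains; the ten-residue connector between them is the
#' linker/hinge segment.
#'
#' @return Named list of [domain_partition()] objects for APEH-1_Tb,
#'   APEH-2_Tb, APEH-1_Ch, APEH-2_Ch.
#' @export
apeh_domain_partitions <- function() {
  list(
    `APEH-1_Tb` = domain_partition(c(1, 450), c(461, 728),
                                   protein_id = "APEH-1_Tb"),
    `APEH-2_Tb` = domain_partition(c(1, 420), c(431, 690),
                                   protein_id = "APEH-2_Tb"),
    `APEH-1_Ch` = domain_partition(c(1, 450), c(461, 729),
                                   protein_id = "APEH-1_Ch"),
    `APEH-2_Ch` = domain_partition(c(1, 420), c(431, 690),
                                   protein_id = "APEH-2_Ch"))
}

#' Published per-domain charge tallies of the four Antarctic APEH isoforms
#'
#' Acidic (D+E) and basic (H+K+R) residue counts and net charges per domain,
#' as reported for the homology models of the two isoform pairs. These are
#' reference inputs (e.g. for [opening_propensity_score()]), not values the
#' package recomputes - recomputation needs the deposited sequences.
#'
#' @return data.frame: protein, region, n_negative, n_positive, net.
#' @export
apeh_domain_charges <- function() {
  data.frame(
    protein = rep(c("APEH-1_Tb", "APEH-2_Tb", "APEH-1_Ch", "APEH-2_Ch"),
                  each = 2L),
    region = rep(c("N-ter", "C-ter"), 4L),
    n_negative = c(64, 29, 42, 24, 56, 29, 46, 24),
    n_positive = c(58, 26, 51, 31, 57, 27, 53, 31),
    net = c(-6, -3, 9, 7, 1, -2, 7, 7),
    stringsAsFactors = FALSE)
}

#' Published catalytic-triad numbering of the C. hamatus isoforms
#'
#' @return Named list of [triad_spec()]: Ser585/Asp673/His705 (APEH-1_Ch)
#'   and Ser555/Asp643/His675 (APEH-2_Ch).
#' @export
apeh_triads <- function() {
  list(`APEH-1_Ch` = triad_spec(585, 673, 705),
       `APEH-2_Ch` = triad_spec(555, 643, 675))
}

#' Published qRT-PCR primer efficiencies
#'
#' Fractional amplification efficiencies of the assay primer pairs for the
#' apeh-1/apeh-2 target genes and the beta-actin reference in C. hamatus
#' (Ch) and D. labrax (Dl). Also available as
#' `system.file("extdata", "primer_efficiencies.csv", package = "apehkit")`.
#'
#' @return data.frame: gene, species, efficiency.
#' @export
apeh_primer_efficiencies <- function() {
  utils::read.csv(system.file("extdata", "primer_efficiencies.csv",
                              package = "apehkit"),
                  stringsAsFactors = FALSE)
}
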