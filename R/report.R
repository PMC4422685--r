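## Pipeline orchestration: run every applicable analysis stage from one
## configuration and emit machine-readable TSV + JSON reports. Stages whose
## inputs are absent are skipped with a notice, so a FASTA-only
## configuration still yields the charge table.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the full analysis report
#'
#' Orchestrates the pipeline over one configuration: sequence charge
#' profiling, salt-bridge/H-bond detection with inter-domain
#' classification, catalytic-site environment, hinge-opening series, and
#' expression folds. Each produced section is written as both TSV and JSON
#' under `out_dir`; sections whose inputs are not configured are skipped
#' with a message. Outputs are deterministic given identical inputs.
#'
#' @param config A named list (or path to a YAML file with the same keys):
#'   \describe{
#'     \item{fasta}{named character vector/list of FASTA paths or raw
#'       sequences for charge profiling}
#'     \item{partitions}{named list of partition strings
#'       (`"Nter:1-450,linker:451-460,Cter:461-729"`) or
#'       `apeh_partition` objects, by protein id}
#'     \item{pdb}{path to the structure to analyse}
#'     \item{triad}{`c(ser, asp, his)` residue numbers}
#'     \item{hinge}{list(residue=, bond=, angles=)}
#'     \item{salt_bridge_cutoff, hbond_preset, site_cutoff, shell_radius,
#'       clash_threshold}{cutoffs; defaults 4.0, "heavy", 3.0, 8, 2.0}
#'     \item{ct, efficiencies}{CSV paths (or data.frames) for the qPCR
#'       stage, with `reference_gene` and `control_tissue`}
#'   }
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with every computed section.
#' @export
run_report <- function(config, out_dir = ".") {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config))
      stop("validation error: config file not found: ", config, call. = FALSE)
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading a config file requires the 'yaml' package", call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config))
    stop("validation error: config must be a list or a YAML path",
         call. = FALSE)
  for (f in c("pdb", "ct")) {
    if (!is.null(config[[f]]) && is.character(config[[f]]) &&
        !file.exists(config[[f]]))
      stop("validation error: ", f, " file not found: ", config[[f]],
           call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()

  get_partition <- function(id) {
    p <- config$partitions[[id]]
    if (is.null(p) && length(config$partitions) == 1L)
      p <- config$partitions[[1L]]
    if (is.character(p)) p <- parse_partition(p, protein_id = id)
    p
  }

  ## charge profiles from sequences
  if (!is.null(config$fasta)) {
    ids <- names(config$fasta)
    if (is.null(ids)) ids <- paste0("protein", seq_along(config$fasta))
    proteins <- lapply(seq_along(config$fasta), function(i) {
      list(sequence = extract_sequence(config$fasta[[i]]),
           partition = get_partition(ids[i]))
    })
    names(proteins) <- ids
    out$charges <- charge_table(proteins)
    write_tsv(out$charges, file.path(out_dir, "charge_table.tsv"))
    write_json(out$charges, file.path(out_dir, "charge_table.json"))
  } else message("no sequences configured; charge table skipped")

  ## structural analyses
  if (!is.null(config$pdb)) {
    s <- read_structure(config$pdb)
    part <- get_partition(s$id)
    bridges <- find_salt_bridges(
      s, cutoff = if (is.null(config$salt_bridge_cutoff)) 4.0
                  else config$salt_bridge_cutoff)
    hb <- find_hbonds(s, hbond_criteria(
      if (is.null(config$hbond_preset)) "heavy" else config$hbond_preset))
    if (!is.null(part)) {
      bridges <- classify_interdomain(bridges, part)
      hb <- classify_interdomain(hb, part)
    }
    out$salt_bridges <- as.data.frame(bridges)
    out$hbonds <- as.data.frame(hb)
    out$interaction_summary <- list(
      salt_bridges = as.list(interaction_counts(bridges)),
      hbonds = as.list(interaction_counts(hb)))
    write_tsv(out$salt_bridges, file.path(out_dir, "salt_bridges.tsv"))
    write_tsv(out$hbonds, file.path(out_dir, "hbonds.tsv"))
    write_json(out$interaction_summary,
               file.path(out_dir, "interaction_summary.json"))

    if (!is.null(config$triad)) {
      triad <- triad_spec(config$triad[[1L]], config$triad[[2L]],
                          config$triad[[3L]])
      env <- triad_environment(s, triad,
        cutoff = if (is.null(config$site_cutoff)) 3.0 else config$site_cutoff)
      out$site_environment <- env$neighbours
      out$site_summary <- list(
        n_negative_atoms = env$n_negative_atoms,
        n_positive_atoms = env$n_positive_atoms,
        character = environment_charge_summary(env))
      write_tsv(env$neighbours, file.path(out_dir, "site_environment.tsv"))
      write_json(out$site_summary, file.path(out_dir, "site_summary.json"))

      if (!is.null(config$hinge) && !is.null(part)) {
        hs <- hinge_spec(config$hinge$residue,
                         if (is.null(config$hinge$bond)) "N-CA"
                         else config$hinge$bond)
        angles <- if (is.null(config$hinge$angles)) c(20, 40, 60, 80)
                  else unlist(config$hinge$angles)
        series <- opening_series(
          s, hs, angles = angles, partition = part, triad = triad,
          shell_radius = if (is.null(config$shell_radius)) 8
                         else config$shell_radius,
          clash_threshold = if (is.null(config$clash_threshold)) 2.0
                            else config$clash_threshold,
          out_prefix = file.path(out_dir, "conformer_"))
        out$hinge_metrics <- series$metrics
        write_tsv(series$metrics, file.path(out_dir, "hinge_metrics.tsv"))
        write_json(series$metrics, file.path(out_dir, "hinge_metrics.json"))
      } else message("no hinge configured; opening series skipped")
    } else message("no triad configured; site environment skipped")
  } else message("no structure configured; structural sections skipped")

  ## expression
  if (!is.null(config$ct)) {
    ct <- if (is.character(config$ct))
      utils::read.csv(config$ct, stringsAsFactors = FALSE) else config$ct
    eff <- if (is.character(config$efficiencies))
      utils::read.csv(config$efficiencies, stringsAsFactors = FALSE)
    else config$efficiencies
    expr <- fold_table(ct, eff, reference_gene = config$reference_gene,
                       control_tissue = config$control_tissue)
    out$expression <- expr$folds
    write_tsv(expr$folds, file.path(out_dir, "expression_folds.tsv"))
    write_json(expr$folds, file.path(out_dir, "expression_folds.json"))
    if (!is.null(expr$ratios)) {
      out$expression_ratios <- expr$ratios
      write_tsv(expr$ratios, file.path(out_dir, "expression_ratios.tsv"))
      write_json(expr$ratios, file.path(out_dir, "expression_ratios.json"))
    }
  } else message("no Ct table configured; expression section skipped")

  invisible(out)
}
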