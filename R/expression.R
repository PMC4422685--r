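## Efficiency-corrected relative expression from qPCR cycle thresholds.
##
## Efficiencies are fractional (e = 1 means perfect doubling), so the
## amplification base is b = 1 + e; published per-primer efficiencies in
## the 0.92-1.11 range correspond to bases of 1.92-2.11. The relative
## expression of a target gene versus a reference gene is
##   R = (1 + e_target)^dCt_target / (1 + e_ref)^dCt_ref
## with dCt oriented as control minus sample.

check_efficiency <- function(e, what = "efficiency") {
  if (!all(is.finite(e)) || any(e <= 0) || any(e > 1.2))
    stop(what, " out of sanity bounds (0, 1.2]: ", paste(e, collapse = ", "),
         call. = FALSE)
  invisible(e)
}

#' Pfaffl efficiency-corrected expression ratio
#'
#' @param e_target,e_ref Fractional amplification efficiencies in (0, 1.2].
#' @param dct_target,dct_ref Delta-Ct in cycles, control minus sample.
#' @return R = (1 + e_target)^dct_target / (1 + e_ref)^dct_ref.
#' @examples
#' pfaffl_ratio(1, 1, 3, 1) # 2^3 / 2^1 = 4
#' @export
pfaffl_ratio <- function(e_target, e_ref, dct_target, dct_ref) {
  check_efficiency(e_target, "target efficiency")
  check_efficiency(e_ref, "reference efficiency")
  if (!all(is.finite(dct_target)) || !all(is.finite(dct_ref)))
    stop("delta-Ct values must be finite", call. = FALSE)
  (1 + e_target)^dct_target / (1 + e_ref)^dct_ref
}

#' Per-tissue expression folds and gene ratios
#'
#' Replicate Ct values are averaged per (tissue, gene) before delta-Ct
#' computation; folds are relative to `control_tissue`, normalised by
#' `reference_gene`. With exactly two target genes a per-tissue ratio
#' column (later gene / earlier gene, lexicographically) is also returned;
#' override the orientation with `ratio_genes = c(numerator, denominator)`.
#'
#' @param ct data.frame with columns `tissue`, `gene`, `ct` (and optionally
#'   `replicate`, `sample`).
#' @param eff data.frame with columns `gene`, `efficiency` (fractional).
#' @param reference_gene Internal control gene present in every tissue.
#' @param control_tissue Tissue all folds are expressed against.
#' @param ratio_genes Optional `c(numerator_gene, denominator_gene)`.
#' @return Object of class `apeh_expression`: list with `folds` (gene,
#'   tissue, dct_target, dct_ref, fold) and `ratios` (tissue, ratio; NULL
#'   when not applicable).
#' @export
fold_table <- function(ct, eff, reference_gene, control_tissue,
                       ratio_genes = NULL) {
  need <- c("tissue", "gene", "ct")
  if (!all(need %in% names(ct)))
    stop("ct table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!all(c("gene", "efficiency") %in% names(eff)))
    stop("efficiency table needs columns gene, efficiency", call. = FALSE)
  if (any(ct$ct <= 0) || !all(is.finite(ct$ct)))
    stop("Ct values must be positive and finite", call. = FALSE)
  eff_of <- function(g) {
    e <- eff$efficiency[match(g, eff$gene)]
    if (any(is.na(e)))
      stop("no efficiency for gene(s): ",
           paste(unique(g[is.na(e)]), collapse = ", "), call. = FALSE)
    check_efficiency(e)
  }
  mean_ct <- stats::aggregate(ct ~ tissue + gene, data = ct, FUN = mean)
  tissues <- unique(ct$tissue)
  if (!(control_tissue %in% tissues))
    stop("data error: control tissue '", control_tissue, "' absent",
         call. = FALSE)
  lookup <- function(tissue, gene) {
    v <- mean_ct$ct[mean_ct$tissue == tissue & mean_ct$gene == gene]
    if (!length(v)) NA_real_ else v
  }
  no_ref <- tissues[vapply(tissues, function(t)
    is.na(lookup(t, reference_gene)), logical(1L))]
  if (length(no_ref))
    stop("data error: reference gene '", reference_gene,
         "' missing in tissue(s): ", paste(no_ref, collapse = ", "),
         call. = FALSE)
  targets <- setdiff(unique(ct$gene), reference_gene)
  rows <- list()
  for (g in targets) {
    ctrl_t <- lookup(control_tissue, g)
    ctrl_r <- lookup(control_tissue, reference_gene)
    if (is.na(ctrl_t))
      stop("data error: gene '", g, "' missing in control tissue",
           call. = FALSE)
    for (t in tissues) {
      smp_t <- lookup(t, g)
      if (is.na(smp_t)) next
      dct_t <- ctrl_t - smp_t
      dct_r <- ctrl_r - lookup(t, reference_gene)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, tissue = t, dct_target = dct_t, dct_ref = dct_r,
        fold = pfaffl_ratio(eff_of(g), eff_of(reference_gene), dct_t, dct_r),
        stringsAsFactors = FALSE)
    }
  }
  folds <- do.call(rbind, rows)
  ratios <- NULL
  if (is.null(ratio_genes) && length(targets) == 2L)
    ratio_genes <- sort(targets, decreasing = TRUE)
  if (!is.null(ratio_genes)) {
    if (!all(ratio_genes %in% targets))
      stop("ratio_genes must name two target genes", call. = FALSE)
    num <- folds[folds$gene == ratio_genes[1L], c("tissue", "fold")]
    den <- folds[folds$gene == ratio_genes[2L], c("tissue", "fold")]
    m <- merge(num, den, by = "tissue", suffixes = c("_num", "_den"))
    ratios <- data.frame(tissue = m$tissue, ratio = m$fold_num / m$fold_den,
                         stringsAsFactors = FALSE)
    attr(ratios, "ratio") <- paste(ratio_genes, collapse = " / ")
  }
  structure(list(folds = folds, ratios = ratios,
                 reference_gene = reference_gene,
                 control_tissue = control_tissue),
            class = "apeh_expression")
}

#' @export
print.apeh_expression <- function(x, ...) {
  cat("Expression folds vs '", x$control_tissue, "' (reference gene '",
      x$reference_gene, "')\n", sep = "")
  print.data.frame(x$folds)
  if (!is.null(x$ratios)) {
    cat("Per-tissue fold ratio (", attr(x$ratios, "ratio"), "):\n", sep = "")
    print.data.frame(x$ratios)
  }
  invisible(x)
}
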