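# RT-qPCR relative quantification by the 2^deltaCt method. Expression is
# measured relative to the TATA-box binding protein (TBP) reference
# transcript, assayed in both its human (tumor) and murine (stroma) forms;
# N_target = 2^(Ct_reference - Ct_target). Values are then rescaled so that
# a target amplifying at the basal quantification limit Ct = 35 scores 1.

#' Delta-Ct between a target gene and the reference
#'
#' `deltaCt = Ct_reference - Ct_target`, so a target with more template
#' (lower Ct) than the reference has a positive deltaCt.
#'
#' @param ct_target,ct_reference cycle-threshold values.
#' @return deltaCt in cycles (vectorized).
#' @export
delta_ct <- function(ct_target, ct_reference) {
  ct_reference - ct_target
}

#' Combine the human and murine TBP reference Ct values
#'
#' The two reference transcripts are combined by the arithmetic mean of
#' their Ct values (the geometric mean of the linear quantities); if only
#' one is detected it passes through unchanged.
#'
#' @param ct_tbp_human,ct_tbp_murine reference Ct values; `NA` = absent.
#' @return combined reference Ct (vectorized); `NA` when both are absent.
#' @export
combine_references <- function(ct_tbp_human, ct_tbp_murine) {
  rowMeans(cbind(ct_tbp_human, ct_tbp_murine), na.rm = TRUE)
}

#' Relative expression from deltaCt
#'
#' `N_target = 2^deltaCt`: one PCR cycle corresponds to a doubling of
#' template.
#'
#' @param dct deltaCt in cycles.
#' @return unitless relative expression.
#' @export
n_target <- function(dct) 2^dct

#' Quantify a Ct table into relative expression records
#'
#' Attaches each sample's combined TBP reference Ct, computes the raw
#' relative expression `N_target = 2^(Ct_ref - Ct_target)`, and normalizes
#' it so that a target at the basal quantification limit (`Ct = 35`) maps
#' to 1 and each cycle below 35 doubles the value:
#' `expression = N_target / 2^(Ct_ref - 35)`. Undetected targets
#' (`Ct >= undetected_ct` or missing) are floored at the basal level 1 and
#' flagged `below_basal`, preserving sample counts for the rank tests.
#' Samples lacking both TBP references are dropped with a warning.
#'
#' @param ct data.frame with columns `sample_id`, `group`, `gene`,
#'   `species_tag` (`"human"`/`"murine"`), `ct`; reference rows have
#'   `gene == "TBP"`.
#' @param basal_ct basal quantification limit, cycles (default 35).
#' @param undetected_ct Ct at or above which a target counts as undetected
#'   (default 40).
#' @param reference `"per-sample"` (each sample's own combined reference,
#'   the default) or `"cohort-median"` (the cohort median reference Ct,
#'   for cross-sample comparability when reference levels drift).
#' @return data.frame: `sample_id`, `group`, `gene`, `ct`, `reference_ct`,
#'   `n_target`, `expression`, `below_basal`.
#' @export
quantify_expression <- function(ct, basal_ct = 35, undetected_ct = 40,
                                reference = c("per-sample", "cohort-median")) {
  reference <- match.arg(reference)
  ct <- validate_ct_table(ct)
  refs <- ct[ct$gene == "TBP", , drop = FALSE]
  targets <- ct[ct$gene != "TBP", , drop = FALSE]
  if (nrow(refs) == 0L)
    pdx_validation_error("no TBP reference rows in Ct table")
  if (nrow(targets) == 0L)
    pdx_validation_error("no target-gene rows in Ct table")
  ref_by_sample <- vapply(split(refs$ct, refs$sample_id), function(v) {
    v <- v[!is.na(v) & v < undetected_ct]
    if (length(v) == 0L) NA_real_ else mean(v)
  }, 0)
  missing_ref <- names(ref_by_sample)[is.na(ref_by_sample)]
  if (length(missing_ref) > 0L) {
    warning(sprintf("sample(s) without any detected TBP reference dropped: %s",
                    paste(missing_ref, collapse = ", ")))
    ref_by_sample <- ref_by_sample[!is.na(ref_by_sample)]
  }
  targets <- targets[targets$sample_id %in% names(ref_by_sample), , drop = FALSE]
  if (nrow(targets) == 0L)
    pdx_validation_error("no target rows left after dropping reference-less samples")
  own_ref <- unname(ref_by_sample[targets$sample_id])
  ref_used <- if (reference == "cohort-median")
    rep(median(ref_by_sample), nrow(targets)) else own_ref
  undet <- is.na(targets$ct) | targets$ct >= undetected_ct
  dct <- delta_ct(targets$ct, ref_used)
  raw <- n_target(dct)
  expr <- raw / 2^(ref_used - basal_ct)   # = 2^(basal_ct - ct) per-sample
  raw[undet] <- 2^(ref_used[undet] - basal_ct) * 1  # basal-level floor
  expr[undet] <- 1
  out <- data.frame(sample_id = targets$sample_id,
                    group = targets$group,
                    gene = targets$gene,
                    ct = targets$ct,
                    reference_ct = ref_used,
                    n_target = raw,
                    expression = expr,
                    below_basal = undet)
  rownames(out) <- NULL
  out
}

#' Compare one gene's expression between treated and control groups
#'
#' Two-tailed Mann-Whitney U test on the basal-normalized expressions, with
#' the fold change of group medians of the raw relative expression
#' (`N_target`) reported alongside.
#'
#' @param expr expression records from [quantify_expression()].
#' @param gene gene symbol.
#' @param treated,control group labels.
#' @return list: `gene`, `fold_change` (treated median / control median of
#'   `N_target`), `n_treated`, `n_control`, and `test` (a `pdx_test`).
#' @export
compare_expression <- function(expr, gene, treated, control = "control") {
  g <- expr[expr$gene == gene, , drop = FALSE]
  xt <- g[g$group == treated, , drop = FALSE]
  xc <- g[g$group == control, , drop = FALSE]
  if (nrow(xt) < 2L || nrow(xc) < 2L)
    pdx_not_evaluable(sprintf(
      "gene '%s': need >= 2 samples per group (%d treated, %d control)",
      gene, nrow(xt), nrow(xc)))
  res <- mann_whitney(xt$expression, xc$expression)
  list(gene = gene,
       fold_change = median(xt$n_target) / median(xc$n_target),
       n_treated = nrow(xt), n_control = nrow(xc),
       test = res)
}

#' Treated-versus-control comparison for every gene in a Ct table
#'
#' @param expr expression records from [quantify_expression()].
#' @param treated,control group labels.
#' @return data.frame: `gene`, `group`, `fold_change`, `n_treated`,
#'   `n_control`, `p_two_sided`, `method`.
#' @export
compare_all_genes <- function(expr, treated, control = "control") {
  genes <- sort(unique(expr$gene))
  do.call(rbind, lapply(genes, function(g) {
    r <- compare_expression(expr, g, treated, control)
    data.frame(gene = g, group = treated, fold_change = r$fold_change,
               n_treated = r$n_treated, n_control = r$n_control,
               p_two_sided = r$test$p_two_sided, method = r$test$method)
  }))
}
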