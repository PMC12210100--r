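# Relative expression by the 2^-ddCt method, with one or several reference
# genes (technical replicates averaged first).

#' Relative expression (2^-ddCt) with one reference gene
#'
#' Technical replicates are averaged within each group and gene, then
#' `dCt = mean Ct(target) - mean Ct(reference)` per group,
#' `ddCt = dCt(treated) - dCt(control)`, and the fold change is
#' `efficiency^-ddCt` (efficiency 2 is the textbook 2^-ddCt; pass the
#' estimated amplification efficiency for an efficiency-corrected variant).
#'
#' When the target and reference carry the same number of replicates, a
#' per-replicate ddCt is formed by replicate index and its standard
#' deviation reported as a dispersion summary (`sd_ddct`).
#'
#' @param target,reference lists with numeric Ct vectors `$control` and
#'   `$treated` (at least one replicate each).
#' @param efficiency amplification efficiency (default 2).
#' @return list with `fold_change`, `ddct`, `dct_control`, `dct_treated`,
#'   `sd_ddct` (NA when replicate counts differ).
#' @export
#' @examples
#' relative_expression(
#'   target = list(control = c(24, 24.2), treated = c(25, 25.1)),
#'   reference = list(control = c(20, 20.1), treated = c(20, 20.2))
#' )
relative_expression <- function(target, reference, efficiency = 2) {
  .check_ct_group(target, "target")
  .check_ct_group(reference, "reference")
  dct_c <- mean(target$control) - mean(reference$control)
  dct_t <- mean(target$treated) - mean(reference$treated)
  ddct <- dct_t - dct_c
  sd_ddct <- NA_real_
  if (length(target$control) == length(reference$control) &&
      length(target$treated) == length(reference$treated) &&
      length(target$treated) == length(target$control)) {
    rep_ddct <- (target$treated - reference$treated) -
      (target$control - reference$control)
    if (length(rep_ddct) > 1L) sd_ddct <- stats::sd(rep_ddct)
  }
  list(
    fold_change = efficiency^(-ddct),
    ddct = ddct, dct_control = dct_c, dct_treated = dct_t,
    sd_ddct = sd_ddct
  )
}

.check_ct_group <- function(x, what) {
  if (!is.list(x) || is.null(x$control) || is.null(x$treated) ||
      !length(x$control) || !length(x$treated)) {
    stop(what, " must provide Ct values for both 'control' and 'treated'")
  }
  invisible(TRUE)
}

#' Relative expression against several reference genes
#'
#' Computes the per-reference 2^-ddCt fold change and combines them as the
#' geometric mean (equivalently, normalisation against the geometric mean of
#' the reference genes).
#'
#' @param target Ct list as in [relative_expression()].
#' @param references list of reference Ct lists (at least one).
#' @param efficiency amplification efficiency.
#' @return list with `per_reference` (named numeric fold changes) and
#'   `combined` (geometric mean).
#' @export
multi_reference_expression <- function(target, references, efficiency = 2) {
  if (!length(references)) stop("at least one reference gene is required")
  folds <- vapply(references, function(ref) {
    relative_expression(target, ref, efficiency)$fold_change
  }, numeric(1L))
  if (is.null(names(folds)) || any(!nzchar(names(folds)))) {
    names(folds) <- paste0("ref", seq_along(folds))
  }
  list(per_reference = folds, combined = exp(mean(log(folds))))
}

#' 2^-ddCt analysis of a long-format Ct table
#'
#' Works on the Ct CSV schema `sample_id, group, gene, ct` with groups
#' `control`/`treated`, computing the fold change of the target gene against
#' each reference gene and their geometric-mean combination.
#'
#' @param ct data.frame (or CSV path) with columns `sample_id`, `group`,
#'   `gene`, `ct`.
#' @param target target gene name.
#' @param references character vector of reference gene names.
#' @param control_group,treated_group group labels.
#' @param efficiency amplification efficiency.
#' @return data.frame with one row per reference plus a `combined` row:
#'   `reference`, `ddct`, `fold_change`.
#' @export
ddct_table <- function(ct, target, references,
                       control_group = "control", treated_group = "treated",
                       efficiency = 2) {
  if (is.character(ct) && length(ct) == 1L) {
    ct <- utils::read.csv(ct, check.names = FALSE,
                          fileEncoding = "UTF-8-BOM")
  }
  need <- c("sample_id", "group", "gene", "ct")
  absent <- setdiff(need, names(ct))
  if (length(absent)) stop("missing Ct column(s): ",
                           paste(absent, collapse = ", "))
  if (any(!is.finite(ct$ct)) || any(ct$ct <= 0 | ct$ct >= 45)) {
    stop("Ct values must lie in (0, 45)")
  }
  pick <- function(gene, group) ct$ct[ct$gene == gene & ct$group == group]
  grab <- function(gene) {
    g <- list(control = pick(gene, control_group),
              treated = pick(gene, treated_group))
    .check_ct_group(g, gene)
    g
  }
  tgt <- grab(target)
  refs <- lapply(references, grab)
  names(refs) <- references
  res <- lapply(refs, function(ref) {
    relative_expression(tgt, ref, efficiency)
  })
  folds <- vapply(res, `[[`, numeric(1L), "fold_change")
  ddcts <- vapply(res, `[[`, numeric(1L), "ddct")
  rbind(
    data.frame(reference = references, ddct = ddcts, fold_change = folds,
               row.names = NULL),
    data.frame(reference = "combined",
               ddct = mean(ddcts),
               fold_change = exp(mean(log(folds))))
  )
}
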