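# Derivation of aggregate and desaturation-index traits from measured milk
# fatty-acid percentages (gas-chromatography output, % of total FA).

.FA_MEASURED <- c(
  "C6:0", "C8:0", "C10:0", "C11:0", "C12:0", "C13:0", "C14:0", "C14:1",
  "C15:0", "C16:0", "C16:1", "C17:0", "C17:1", "C18:0", "C18:1cis-9", "C20:0"
)
.FA_SATURATED <- grep(":0$", .FA_MEASURED, value = TRUE)
.FA_UNSATURATED <- setdiff(.FA_MEASURED, .FA_SATURATED)

.FA_DERIVED <- c(
  "sfa", "ufa", "sfa_ufa", "c14_index", "c16_index", "c17_index",
  "c18_index", "total_index"
)

# product (cis-9 unsaturated) / substrate (saturated) pairs of the
# delta-9 desaturase indices
.FA_INDEX_PAIRS <- list(
  c14_index = c(unsat = "C14:1", sat = "C14:0"),
  c16_index = c(unsat = "C16:1", sat = "C16:0"),
  c17_index = c(unsat = "C17:1", sat = "C17:0"),
  c18_index = c(unsat = "C18:1cis-9", sat = "C18:0")
)

#' Fatty-acid name sets
#'
#' The 16 measured milk fatty acids and their partition into saturated
#' (carbon chain with `:0`) and cis-9 unsaturated members. These sets define
#' the SFA/UFA aggregates and the desaturation indices; pass modified sets to
#' [aggregate_saturation()] to change membership.
#'
#' @return named list with elements `measured`, `saturated`, `unsaturated`,
#'   and `derived` (names of the derived trait columns appended by
#'   [derive_fa_traits()]).
#' @export
fatty_acid_sets <- function() {
  list(
    measured = .FA_MEASURED,
    saturated = .FA_SATURATED,
    unsaturated = .FA_UNSATURATED,
    derived = .FA_DERIVED
  )
}

#' Desaturation index
#'
#' `100 * unsat / (unsat + sat)`: the percentage of a delta-9 desaturase
#' product relative to product plus substrate, e.g. the C14 index is
#' `C14:1 / (C14:1 + C14:0) * 100`.
#'
#' @param unsat concentration of the cis-9 unsaturated product (% of total FA).
#' @param sat concentration of the saturated substrate (% of total FA).
#' @return index in `[0, 100]`; `NA` where either input is missing or the
#'   denominator is zero (the latter with a warning, not an error).
#' @export
#' @examples
#' compute_index(1, 3) # 25
compute_index <- function(unsat, sat) {
  stopifnot(is.numeric(unsat), is.numeric(sat))
  if (any(unsat < 0, na.rm = TRUE) || any(sat < 0, na.rm = TRUE)) {
    stop("fatty-acid concentrations must be non-negative")
  }
  denom <- unsat + sat
  zero <- !is.na(denom) & denom == 0
  if (any(zero)) {
    warning(sum(zero), " zero denominator(s) in desaturation index; returning NA")
    denom[zero] <- NA_real_
  }
  100 * unsat / denom
}

#' Total desaturation index
#'
#' Pooled index over the four desaturase product/substrate pairs:
#' `100 * (C14:1 + C16:1 + C17:1 + C18:1cis-9) / (sum of the four products and
#' their four saturated substrates)`. All eight fatty acids must be present;
#' a missing value propagates to a missing index.
#'
#' @param profile named numeric vector or data.frame with fatty-acid columns
#'   named as in `fatty_acid_sets()$measured`.
#' @return total index (%), vectorised over data.frame rows.
#' @export
compute_total_index <- function(profile) {
  df <- .as_fa_frame(profile)
  un <- .FA_UNSATURATED
  sa <- c("C14:0", "C16:0", "C17:0", "C18:0")
  num <- .row_sum(df, un, all_required = TRUE)
  den <- num + .row_sum(df, sa, all_required = TRUE)
  compute_index(num, den - num)
}

#' Saturated/unsaturated aggregates
#'
#' Sums the saturated and unsaturated members that are present (non-missing)
#' in each profile and their ratio. The ratio is `NA` (with a warning) where
#' the unsaturated sum is zero.
#'
#' @param profile named numeric vector or data.frame of fatty-acid columns.
#' @param saturated,unsaturated membership sets; default the measured-set
#'   partition of [fatty_acid_sets()].
#' @return data.frame with columns `sfa`, `ufa`, `sfa_ufa` (one row per
#'   profile).
#' @export
#' @examples
#' aggregate_saturation(c("C14:0" = 10, "C14:1" = 5)) # sfa 10, ufa 5, ratio 2
aggregate_saturation <- function(profile,
                                 saturated = .FA_SATURATED,
                                 unsaturated = .FA_UNSATURATED) {
  df <- .as_fa_frame(profile)
  if (nrow(df) == 0L || ncol(df) == 0L) stop("empty fatty-acid profile")
  sfa <- .row_sum(df, saturated, all_required = FALSE)
  ufa <- .row_sum(df, unsaturated, all_required = FALSE)
  zero <- !is.na(ufa) & ufa == 0
  ratio <- sfa / ufa
  if (any(zero)) {
    warning(sum(zero), " profile(s) with zero UFA; SFA/UFA set to NA")
    ratio[zero] <- NA_real_
  }
  data.frame(sfa = sfa, ufa = ufa, sfa_ufa = ratio)
}

#' Append derived fatty-acid traits
#'
#' Adds the eight derived trait columns (`sfa`, `ufa`, `sfa_ufa`, the four
#' single-pair desaturation indices and `total_index`) to a phenotype table
#' holding measured fatty-acid columns, giving the full analysed trait set
#' (16 measured + 8 derived). Missing measured values propagate to missing
#' derived traits for that row.
#'
#' @param pheno data.frame with fatty-acid columns named as in
#'   `fatty_acid_sets()$measured` (extra columns are kept untouched).
#' @return `pheno` with the derived columns appended.
#' @export
derive_fa_traits <- function(pheno) {
  stopifnot(is.data.frame(pheno))
  agg <- aggregate_saturation(pheno)
  pheno$sfa <- agg$sfa
  pheno$ufa <- agg$ufa
  pheno$sfa_ufa <- agg$sfa_ufa
  for (ix in names(.FA_INDEX_PAIRS)) {
    pair <- .FA_INDEX_PAIRS[[ix]]
    pheno[[ix]] <- compute_index(.col_or_na(pheno, pair[["unsat"]]),
                                 .col_or_na(pheno, pair[["sat"]]))
  }
  pheno$total_index <- compute_total_index(pheno)
  pheno
}

.as_fa_frame <- function(profile) {
  if (is.data.frame(profile)) return(profile)
  if (is.numeric(profile) && !is.null(names(profile))) {
    return(as.data.frame(as.list(profile), check.names = FALSE))
  }
  stop("profile must be a data.frame or a named numeric vector")
}

.col_or_na <- function(df, nm) {
  if (nm %in% names(df)) df[[nm]] else rep(NA_real_, nrow(df))
}

# row sums over the named subset; all_required: NA unless every member present,
# otherwise sum over the non-missing members (0 if none).
.row_sum <- function(df, members, all_required) {
  cols <- vapply(members, function(nm) .col_or_na(df, nm), numeric(nrow(df)))
  cols <- matrix(cols, nrow = nrow(df))
  if (all_required) {
    rowSums(cols)
  } else {
    rowSums(cols, na.rm = TRUE)
  }
}
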