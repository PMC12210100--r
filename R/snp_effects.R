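# Genotype/allele frequencies and Falconer gene effects (additive a,
# dominance d, allele substitution alpha) computed from genotype
# least-squares means.

#' Genotype and allele frequencies
#'
#' From genotype counts for a biallelic SNP, with allele A the first-listed
#' allele of the SNP name (C for a C/T variant): `p = (2 n_AA + n_AB) / (2 N)`
#' and `q = 1 - p`. Values are returned at full precision; round with
#' [round_half_away()] at the reporting layer.
#'
#' @param n_AA,n_AB,n_BB genotype counts (non-negative, total > 0).
#' @param alleles the two allele symbols, A first.
#' @return list with `counts`, genotype frequencies `f_AA`, `f_AB`, `f_BB`,
#'   allele frequencies `p` (A) and `q` (B), `n` (total animals) and a
#'   summary `table` data.frame.
#' @export
#' @examples
#' genotype_allele_frequencies(460, 471, 109)
genotype_allele_frequencies <- function(n_AA, n_AB, n_BB,
                                        alleles = c("C", "T")) {
  counts <- c(n_AA, n_AB, n_BB)
  stopifnot(length(counts) == 3L, all(counts >= 0))
  n <- sum(counts)
  if (n == 0) stop("total genotype count is zero")
  f <- counts / n
  p <- (2 * n_AA + n_AB) / (2 * n)
  genos <- c(paste0(alleles[1L], alleles[1L]),
             paste0(alleles[1L], alleles[2L]),
             paste0(alleles[2L], alleles[2L]))
  list(
    counts = stats::setNames(counts, genos),
    f_AA = f[1L], f_AB = f[2L], f_BB = f[3L],
    p = p, q = 1 - p, n = n, alleles = alleles,
    table = data.frame(genotype = genos, n = counts, frequency = f)
  )
}

#' Additive and dominance effects from genotype means
#'
#' Falconer parameterisation on the genotype least-squares means:
#' `a = (AA - BB) / 2` (half the homozygote difference) and
#' `d = AB - (AA + BB) / 2` (heterozygote deviation from the homozygote
#' midpoint).
#'
#' @param lsm_AA,lsm_AB,lsm_BB genotype least-squares means (trait units).
#' @return list with `a` and `d`.
#' @export
#' @examples
#' add_dom_effects(0.4866, 0.4272, 0.5463)
add_dom_effects <- function(lsm_AA, lsm_AB, lsm_BB) {
  list(
    a = (lsm_AA - lsm_BB) / 2,
    d = lsm_AB - (lsm_AA + lsm_BB) / 2
  )
}

#' Allele-substitution effect
#'
#' `alpha = a + d * (q - p)` with `p = freq(A)` and `q = freq(B)`: the
#' average change in genotypic value per substitution of allele B for A at
#' the population's allele frequencies.
#'
#' @param a additive effect.
#' @param d dominance effect.
#' @param p,q allele frequencies (must sum to 1).
#' @return alpha, trait units.
#' @export
allele_substitution <- function(a, d, p, q) {
  if (abs(p + q - 1) > 1e-8) stop("allele frequencies must sum to 1")
  a + d * (q - p)
}

#' SNP effects with significance from a model fit
#'
#' Computes a, d and alpha as estimable contrasts over the genotype
#' least-squares means of a fitted animal model (`k_a = (1/2, 0, -1/2)`,
#' `k_d = (-1/2, 1, -1/2)`, `k_alpha = k_a + (q - p) k_d` in AA/AB/BB order),
#' with standard errors from `k' vcov(LSM) k`, t-tests on the model's
#' residual degrees of freedom, and significance stars (`*` p < 0.05,
#' `**` p < 0.01).
#'
#' @param fit an [fit_animal_model()] object (genotype classes named
#'   AA/AB/BB as `paste0` of the alleles, e.g. CC/CT/TT).
#' @param counts either a [genotype_allele_frequencies()] result or a
#'   3-vector of genotype counts in AA/AB/BB order.
#' @param alleles allele symbols, A first (used when `counts` is a vector).
#' @return data.frame (class `snp_effects`) with one row per effect:
#'   `effect`, `estimate`, `se`, `t`, `p_value`, `stars`; allele frequencies
#'   kept as attributes `p` and `q`.
#' @export
effect_significance <- function(fit, counts, alleles = c("C", "T")) {
  stopifnot(inherits(fit, "animal_model_fit"))
  if (is.numeric(counts) && length(counts) == 3L) {
    counts <- genotype_allele_frequencies(counts[1L], counts[2L], counts[3L],
                                          alleles = alleles)
  }
  lsm <- genotype_lsm(fit)
  genos <- paste0(
    c(counts$alleles[1L], counts$alleles[1L], counts$alleles[2L]),
    c(counts$alleles[1L], counts$alleles[2L], counts$alleles[2L])
  )
  idx <- match(genos, lsm$genotype)
  if (anyNA(idx)) {
    stop("fit genotype classes (", paste(lsm$genotype, collapse = ", "),
         ") do not match the expected ", paste(genos, collapse = "/"))
  }
  mu <- lsm$lsm[idx]
  V <- attr(lsm, "vcov_lsm")[idx, idx]
  k_a <- c(0.5, 0, -0.5)
  k_d <- c(-0.5, 1, -0.5)
  k_alpha <- k_a + (counts$q - counts$p) * k_d
  K <- rbind(a = k_a, d = k_d, alpha = k_alpha)
  est <- drop(K %*% mu)
  se <- sqrt(diag(K %*% V %*% t(K)))
  tv <- est / se
  pv <- 2 * stats::pt(-abs(tv), df = fit$df_residual)
  out <- data.frame(
    effect = rownames(K),
    estimate = est,
    se = se,
    t = tv,
    p_value = pv,
    stars = significance_stars(pv),
    row.names = NULL
  )
  attr(out, "p") <- counts$p
  attr(out, "q") <- counts$q
  class(out) <- c("snp_effects", "data.frame")
  out
}
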