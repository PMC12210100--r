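# Seed-deterministic simulator of half-sib sire-family dairy populations:
# three-generation pedigree, gene-dropped SNP genotypes, and fatty-acid
# phenotypes generated under the same mixed animal model the estimation
# machinery assumes, with the generating truth recorded.

#' Default per-trait generating parameters
#'
#' One row per measured fatty acid: the population mean `mu` (% of total FA),
#' phenotypic variance `sigma2_p`, and the true additive (`a`) and dominance
#' (`d`) genotype effects in trait units. Effects default to the reported
#' association scale for the short/medium-chain fatty acids and zero for the
#' remainder; means and variances are field-typical milk fatty-acid values.
#'
#' @return data.frame with columns `trait`, `mu`, `sigma2_p`, `a`, `d`.
#' @export
default_trait_params <- function() {
  df <- data.frame(
    trait = c("C6:0", "C8:0", "C10:0", "C11:0", "C12:0", "C13:0", "C14:0",
              "C14:1", "C15:0", "C16:0", "C16:1", "C17:0", "C17:1", "C18:0",
              "C18:1cis-9", "C20:0"),
    mu = c(0.49, 0.95, 2.80, 0.055, 3.00, 0.10, 11.5,
           0.90, 0.90, 32.0, 1.50, 0.60, 0.25, 10.5,
           20.0, 0.15),
    stringsAsFactors = FALSE
  )
  df$sigma2_p <- (0.22 * df$mu)^2
  df$a <- 0
  df$d <- 0
  eff <- list(
    "C6:0" = c(-0.0299, -0.0893), "C8:0" = c(-0.0279, -0.0483),
    "C10:0" = c(-0.0688, -0.0616), "C11:0" = c(-0.0038, -0.0021),
    "C12:0" = c(-0.0517, -0.0349), "C13:0" = c(-0.0026, -0.0013),
    "C14:0" = c(-0.1758, -0.0351), "C14:1" = c(0.0529, 0.0102)
  )
  for (tr in names(eff)) {
    i <- match(tr, df$trait)
    df$a[i] <- eff[[tr]][1L]
    df$d[i] <- eff[[tr]][2L]
  }
  df
}

#' Simulation configuration
#'
#' Defaults emulate the validation population the pipeline is designed for:
#' 44 paternal half-sib families of about 24 daughters (~1056 cows) across
#' 23 farms and 4 lactation stages, SNP allele frequency 0.6688 for the
#' first allele, heritability 0.30 (inside the 0.07-0.42 range reported for
#' milk fatty acids), an age-at-calving covariate in months with a small
#' positive regression, and 8% missing phenotypes per trait.
#'
#' @param n_sires number of paternal half-sib families.
#' @param daughters_per_sire daughters (phenotyped cows) per sire.
#' @param n_farms,n_stages numbers of farms and lactation stages.
#' @param allele_freq_p founder frequency of the first allele.
#' @param alleles the two allele symbols.
#' @param h2 narrow-sense heritability of every simulated trait.
#' @param traits traits to simulate; default all 16 measured fatty acids.
#' @param trait_params data.frame as [default_trait_params()].
#' @param farm_sd,stage_sd standard deviations of the fixed farm and stage
#'   effects (trait-relative: multiplied by `sqrt(sigma2_p)` per trait).
#' @param age_range age-at-calving range (months).
#' @param b_age regression on age, per month, trait-relative (multiplied by
#'   `sqrt(sigma2_p)`).
#' @param missing_rate per-trait probability a phenotype is missing.
#' @param n_maternal_grandsires founder bulls siring the dams.
#' @param dam_reuse_rate fraction of cows sharing an already-used dam.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_sires = 44L,
                       daughters_per_sire = 24L,
                       n_farms = 23L,
                       n_stages = 4L,
                       allele_freq_p = 0.6688,
                       alleles = c("C", "T"),
                       h2 = 0.30,
                       traits = NULL,
                       trait_params = default_trait_params(),
                       farm_sd = 0.25,
                       stage_sd = 0.15,
                       age_range = c(22, 40),
                       b_age = 0.01,
                       missing_rate = 0.08,
                       n_maternal_grandsires = 44L,
                       dam_reuse_rate = 0) {
  stopifnot(n_sires >= 1L, daughters_per_sire >= 1L, n_farms >= 1L,
            n_stages >= 1L, allele_freq_p > 0, allele_freq_p < 1,
            h2 >= 0, h2 < 1, missing_rate >= 0, missing_rate < 1)
  if (!is.null(traits)) {
    unknown <- setdiff(traits, trait_params$trait)
    if (length(unknown)) stop("unknown trait(s): ",
                              paste(unknown, collapse = ", "))
    trait_params <- trait_params[trait_params$trait %in% traits, ,
                                 drop = FALSE]
  }
  structure(
    list(n_sires = as.integer(n_sires),
         daughters_per_sire = as.integer(daughters_per_sire),
         n_farms = as.integer(n_farms), n_stages = as.integer(n_stages),
         allele_freq_p = allele_freq_p, alleles = alleles, h2 = h2,
         trait_params = trait_params, farm_sd = farm_sd, stage_sd = stage_sd,
         age_range = age_range, b_age = b_age, missing_rate = missing_rate,
         n_maternal_grandsires = as.integer(n_maternal_grandsires),
         dam_reuse_rate = dam_reuse_rate),
    class = "sim_config"
  )
}

#' Simulate a three-generation half-sib pedigree
#'
#' Structure: founder grandsires/granddams produce the sires; a pool of
#' founder maternal grandsires produces the dams (one per cow unless
#' `dam_reuse_rate > 0`); each cow has a recorded sire and dam. The returned
#' pedigree carries the phenotyped cow ids in `attr(ped, "cows")`.
#'
#' @param cfg a [sim_config()].
#' @param seed RNG seed (identical seed and config give a byte-identical
#'   pedigree).
#' @return a `pedigree` object.
#' @export
simulate_pedigree <- function(cfg, seed) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(seed)
  n_cows <- cfg$n_sires * cfg$daughters_per_sire
  sires <- sprintf("S%03d", seq_len(cfg$n_sires))
  gsire <- sprintf("GS%03d", seq_len(cfg$n_sires))
  gdam <- sprintf("GD%03d", seq_len(cfg$n_sires))
  mgs <- sprintf("MGS%03d", seq_len(cfg$n_maternal_grandsires))
  cows <- sprintf("C%05d", seq_len(n_cows))
  cow_sire <- rep(sires, each = cfg$daughters_per_sire)

  n_dams <- n_cows
  if (cfg$dam_reuse_rate > 0) {
    n_dams <- max(1L, round(n_cows * (1 - cfg$dam_reuse_rate)))
  }
  dams <- sprintf("D%05d", seq_len(n_dams))
  cow_dam <- if (n_dams == n_cows) dams else sample(dams, n_cows, replace = TRUE)
  dam_sire <- sample(mgs, n_dams, replace = TRUE)

  rec <- rbind(
    data.frame(animal = c(gsire, gdam, mgs), sire = NA_character_,
               dam = NA_character_, stringsAsFactors = FALSE),
    data.frame(animal = sires, sire = gsire, dam = gdam,
               stringsAsFactors = FALSE),
    data.frame(animal = dams, sire = dam_sire, dam = NA_character_,
               stringsAsFactors = FALSE),
    data.frame(animal = cows, sire = cow_sire, dam = cow_dam,
               stringsAsFactors = FALSE)
  )
  ped <- load_pedigree(rec)
  attr(ped, "cows") <- cows
  ped
}

#' Gene-drop genotypes through a pedigree
#'
#' Founders draw two alleles independently at frequency `p` for the first
#' allele; each offspring inherits one uniformly chosen allele from each
#' parent's pair (an unknown parent contributes a founder-frequency draw).
#' No selection, so allele frequency is preserved in expectation across
#' generations.
#'
#' @param ped a `pedigree`.
#' @param p frequency of the first allele in founders.
#' @param seed RNG seed.
#' @param alleles the two allele symbols (first = the `p` allele).
#' @return data.frame `animal_id`, `allele1`, `allele2`, `genotype`
#'   (alphabetically ordered two-letter string, e.g. CC/CT/TT).
#' @export
simulate_genotypes <- function(ped, p, seed, alleles = c("C", "T")) {
  stopifnot(inherits(ped, "pedigree"), p > 0, p <= 1)
  set.seed(seed)
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$animal
  si <- idx[ped$sire]
  di <- idx[ped$dam]
  a1 <- integer(n)  # 1 = first allele, 0 = second
  a2 <- integer(n)
  founder <- is.na(si) & is.na(di)
  a1[founder] <- stats::rbinom(sum(founder), 1L, p)
  a2[founder] <- stats::rbinom(sum(founder), 1L, p)
  for (i in which(!founder)) {
    s <- si[i]
    a1[i] <- if (is.na(s)) {
      stats::rbinom(1L, 1L, p)
    } else if (stats::runif(1L) < 0.5) a1[s] else a2[s]
    dd <- di[i]
    a2[i] <- if (is.na(dd)) {
      stats::rbinom(1L, 1L, p)
    } else if (stats::runif(1L) < 0.5) a1[dd] else a2[dd]
  }
  al1 <- ifelse(a1 == 1L, alleles[1L], alleles[2L])
  al2 <- ifelse(a2 == 1L, alleles[1L], alleles[2L])
  geno <- ifelse(al1 <= al2, paste0(al1, al2), paste0(al2, al1))
  data.frame(animal_id = ped$animal, allele1 = al1, allele2 = al2,
             genotype = geno, stringsAsFactors = FALSE)
}

# Polygenic values for every pedigree animal by the Mendelian-sampling
# recursion: u_i = (u_s + u_d)/2 + m_i, with Var(m_i) depending on how many
# parents are known and on parental inbreeding, which reproduces
# Var(u) = A * sigma2_a exactly. One column per trait.
.simulate_breeding_values <- function(ped, sigma2_a, inbreeding) {
  n <- nrow(ped)
  tnames <- names(sigma2_a)
  Tn <- length(sigma2_a)
  idx <- seq_len(n)
  names(idx) <- ped$animal
  si <- idx[ped$sire]
  di <- idx[ped$dam]
  Fv <- inbreeding
  u <- matrix(0, n, Tn, dimnames = list(ped$animal, tnames))
  sa <- as.numeric(sigma2_a)
  for (i in seq_len(n)) {
    s <- si[i]
    dd <- di[i]
    if (is.na(s) && is.na(dd)) {
      u[i, ] <- stats::rnorm(Tn, 0, sqrt(sa))
    } else if (!is.na(s) && !is.na(dd)) {
      msv <- sa * (0.5 - 0.25 * (Fv[s] + Fv[dd]))
      u[i, ] <- 0.5 * (u[s, ] + u[dd, ]) + stats::rnorm(Tn, 0, sqrt(msv))
    } else {
      known <- if (is.na(s)) dd else s
      msv <- sa * (0.75 - 0.25 * Fv[known])
      u[i, ] <- 0.5 * u[known, ] + stats::rnorm(Tn, 0, sqrt(msv))
    }
  }
  u
}

#' Simulate fatty-acid phenotypes under the animal model
#'
#' For each configured trait, cow phenotypes are generated as
#' `y = mu + g(genotype) + farm + stage + b * (age - mean age) + u + e`
#' with `g(AA) = +a`, `g(AB) = d`, `g(BB) = -a`, polygenic values `u` with
#' covariance `A * sigma2_a` (`sigma2_a = h2 * sigma2_p`, drawn by the exact
#' Mendelian-sampling recursion), and residuals with variance
#' `(1 - h2) * sigma2_p`. Farm and stage effects are drawn once per call and
#' recorded in the truth object. Per-trait missingness is applied at
#' `cfg$missing_rate`.
#'
#' @param ped pedigree from [simulate_pedigree()] (needs `attr(ped, "cows")`).
#' @param genotypes table from [simulate_genotypes()].
#' @param cfg a [sim_config()].
#' @param seed RNG seed.
#' @param inbreeding optional named inbreeding coefficients for the pedigree
#'   (computed from the relationship matrix when `NULL`).
#' @return list with `phenotypes` (data.frame `cow_id`, `farm`,
#'   `lactation_stage`, `calving_age`, one column per trait) and `truth`
#'   (all generating parameters and per-animal breeding values).
#' @export
simulate_phenotypes <- function(ped, genotypes, cfg, seed,
                                inbreeding = NULL) {
  stopifnot(inherits(ped, "pedigree"), inherits(cfg, "sim_config"))
  cows <- attr(ped, "cows")
  if (is.null(cows)) stop("pedigree lacks a 'cows' attribute; ",
                          "use simulate_pedigree() or set it manually")
  if (is.null(inbreeding)) {
    inbreeding <- inbreeding_coefficients(ped)
  }
  set.seed(seed)
  tp <- cfg$trait_params
  n <- length(cows)
  sigma2_a <- stats::setNames(cfg$h2 * tp$sigma2_p, tp$trait)
  sigma2_e <- stats::setNames((1 - cfg$h2) * tp$sigma2_p, tp$trait)

  farm <- sprintf("farm%02d", sample.int(cfg$n_farms, n, replace = TRUE))
  stage <- sprintf("stage%d", sample.int(cfg$n_stages, n, replace = TRUE))
  age <- round(stats::runif(n, cfg$age_range[1L], cfg$age_range[2L]), 1L)
  farm_eff <- stats::setNames(stats::rnorm(cfg$n_farms, 0, cfg$farm_sd),
                              sprintf("farm%02d", seq_len(cfg$n_farms)))
  stage_eff <- stats::setNames(stats::rnorm(cfg$n_stages, 0, cfg$stage_sd),
                               sprintf("stage%d", seq_len(cfg$n_stages)))

  u <- .simulate_breeding_values(ped, sigma2_a, inbreeding)

  geno <- genotypes$genotype[match(cows, genotypes$animal_id)]
  AA <- paste0(cfg$alleles[1L], cfg$alleles[1L])
  het <- paste0(sort(cfg$alleles)[1L], sort(cfg$alleles)[2L])
  out <- data.frame(cow_id = cows, farm = farm, lactation_stage = stage,
                    calving_age = age, stringsAsFactors = FALSE)
  mid_age <- mean(cfg$age_range)
  for (k in seq_len(nrow(tp))) {
    tr <- tp$trait[k]
    sdp <- sqrt(tp$sigma2_p[k])
    g <- ifelse(geno == AA, tp$a[k],
                ifelse(geno == het, tp$d[k], -tp$a[k]))
    e <- stats::rnorm(n, 0, sqrt(sigma2_e[tr]))
    y <- tp$mu[k] + g + sdp * farm_eff[farm] + sdp * stage_eff[stage] +
      cfg$b_age * sdp * (age - mid_age) + u[cows, tr] + e
    if (cfg$missing_rate > 0) {
      y[stats::runif(n) < cfg$missing_rate] <- NA_real_
    }
    out[[tr]] <- y
  }
  truth <- list(
    h2 = cfg$h2, trait_params = tp, sigma2_a = sigma2_a,
    sigma2_e = sigma2_e, b_age = cfg$b_age * sqrt(tp$sigma2_p),
    farm_effects = farm_eff, stage_effects = stage_eff,
    breeding_values = u, allele_freq_p = cfg$allele_freq_p,
    missing_rate = cfg$missing_rate, seed = seed
  )
  list(phenotypes = out, truth = truth)
}

#' Simulate a complete study population
#'
#' Pedigree, gene-dropped genotypes and phenotypes in one call (sub-seeds
#' `seed`, `seed + 1`, `seed + 2` respectively, so the whole bundle is
#' reproducible from one integer).
#'
#' @param cfg a [sim_config()].
#' @param seed RNG seed.
#' @return list with `pedigree`, `genotypes` (cow rows only in
#'   `$genotypes_cows`), `phenotypes`, `truth`.
#' @export
simulate_population <- function(cfg = sim_config(), seed = 1L) {
  ped <- simulate_pedigree(cfg, seed)
  geno <- simulate_genotypes(ped, cfg$allele_freq_p, seed + 1L,
                             alleles = cfg$alleles)
  phe <- simulate_phenotypes(ped, geno, cfg, seed + 2L)
  cows <- attr(ped, "cows")
  list(
    pedigree = ped,
    genotypes = geno,
    genotypes_cows = data.frame(
      cow_id = cows,
      genotype = geno$genotype[match(cows, geno$animal_id)],
      stringsAsFactors = FALSE
    ),
    phenotypes = phe$phenotypes,
    truth = phe$truth
  )
}

#' Simulate a qPCR Ct table with known fold change
#'
#' Generates control/treated triplicate Ct values for one target and the
#' given reference genes such that the true relative expression of the
#' target equals `fold_change_true`; Gaussian noise with standard deviation
#' `noise_sd` (cycles) is added per replicate. With `noise_sd = 0` the
#' estimated fold change equals the truth exactly.
#'
#' @param fold_change_true true fold change (> 0).
#' @param noise_sd per-replicate Ct noise (cycles).
#' @param seed RNG seed.
#' @param n_replicates technical replicates per group and gene.
#' @param target,references gene names.
#' @return data.frame `sample_id`, `group`, `gene`, `ct`.
#' @export
simulate_ct_table <- function(fold_change_true, noise_sd = 0.2, seed = 1L,
                              n_replicates = 3L, target = "NFKB2",
                              references = c("GAPDH", "MARVELD1")) {
  stopifnot(fold_change_true > 0, noise_sd >= 0, n_replicates >= 1L)
  set.seed(seed)
  ddct <- -log2(fold_change_true)
  base <- stats::setNames(c(24, seq(20, by = 1,
                                    length.out = length(references))),
                          c(target, references))
  rows <- list()
  for (gene in c(target, references)) {
    for (grp in c("control", "treated")) {
      mu <- base[[gene]] + if (gene == target && grp == "treated") ddct else 0
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = paste0(substr(grp, 1L, 4L), "_", seq_len(n_replicates)),
        group = grp,
        gene = gene,
        ct = mu + stats::rnorm(n_replicates, 0, noise_sd),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
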