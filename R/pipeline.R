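# Readers/writers and the end-to-end association pipeline:
# phenotypes -> derived traits -> kinship -> per-trait animal model ->
# genotype LSMs -> a/d/alpha effects -> TSV report bundle.

#' Read and validate a phenotype table
#'
#' Schema: `cow_id, farm, lactation_stage, calving_age`, then one numeric
#' column per measured fatty acid (named as in
#' `fatty_acid_sets()$measured`); empty cells are missing values. Schema
#' violations are reported with the offending data line numbers (header =
#' line 1). Files with a UTF-8 BOM or CRLF line endings parse identically to
#' plain LF files.
#'
#' @param path CSV file path (or a data.frame, validated in place).
#' @return validated data.frame.
#' @export
read_phenotypes <- function(path) {
  df <- if (is.data.frame(path)) path else {
    utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8-BOM",
                    colClasses = "character")
  }
  if (nrow(df) == 0L) stop("phenotype table is empty")
  need <- c("cow_id", "farm", "lactation_stage", "calving_age")
  absent <- setdiff(need, names(df))
  if (length(absent)) {
    stop("phenotype table missing column(s): ",
         paste(absent, collapse = ", "))
  }
  num_cols <- c("calving_age",
                intersect(c(.FA_MEASURED, .FA_DERIVED), names(df)))
  for (col in num_cols) {
    raw <- trimws(as.character(df[[col]]))
    raw[raw == ""] <- NA_character_
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(val))
    if (length(bad)) {
      stop("non-numeric value(s) in column '", col, "' at line(s) ",
           paste(bad + 1L, collapse = ", "))
    }
    df[[col]] <- val
  }
  df$cow_id <- as.character(df$cow_id)
  df
}

#' Read and validate a genotype table
#'
#' Schema: `cow_id, genotype` with genotype codes drawn from `allowed`
#' (default CC/CT/TT). Unknown codes are reported with line numbers.
#'
#' @param path CSV path or data.frame.
#' @param allowed permitted genotype strings.
#' @return validated data.frame.
#' @export
read_genotypes <- function(path, allowed = c("CC", "CT", "TT")) {
  df <- if (is.data.frame(path)) path else {
    utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8-BOM",
                    colClasses = "character")
  }
  if (nrow(df) == 0L) stop("genotype table is empty")
  absent <- setdiff(c("cow_id", "genotype"), names(df))
  if (length(absent)) {
    stop("genotype table missing column(s): ",
         paste(absent, collapse = ", "))
  }
  bad <- which(!(df$genotype %in% allowed))
  if (length(bad)) {
    stop("unknown genotype code(s) ",
         paste(unique(df$genotype[bad]), collapse = ", "),
         " at line(s) ", paste(bad + 1L, collapse = ", "))
  }
  dup <- df$cow_id[duplicated(df$cow_id)]
  if (length(dup)) {
    stop("duplicated cow id(s) in genotype table: ",
         paste(unique(dup), collapse = ", "))
  }
  df$cow_id <- as.character(df$cow_id)
  df
}

#' Write a phenotype table (with derived traits) to CSV
#'
#' @param pheno data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.csv(pheno, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Run the full candidate-gene association pipeline
#'
#' Derives the aggregate/index traits, builds the pedigree relationship
#' matrix once, fits the animal model per trait, and writes a deterministic
#' report bundle to `out_dir`:
#' \describe{
#'   \item{frequencies.tsv}{genotype and allele frequencies (4 dp).}
#'   \item{associations.tsv}{per trait and genotype: n, LSM, SE, letter
#'     groups at 0.05/0.01, overall genotype p-value.}
#'   \item{effects.tsv}{per trait: a, d, alpha with SEs and stars, plus the
#'     allele frequencies used.}
#'   \item{manifest.json}{trait list, model options, record accounting
#'     (input = used + dropped per trait) and MD5s of the written tables.}
#' }
#' Values are carried at full precision internally and rounded
#' half-away-from-zero to 4 decimals only in the written reports. Rerunning
#' with identical inputs produces byte-identical files.
#'
#' @param pheno phenotype table or CSV path ([read_phenotypes()] schema).
#' @param geno genotype table or CSV path ([read_genotypes()] schema).
#' @param ped pedigree or CSV path ([load_pedigree()]).
#' @param out_dir output directory (created if needed).
#' @param traits traits to analyse; default all 24 (16 measured + 8 derived)
#'   present in the table.
#' @param method `"reml"` or `"fixed_h2"`.
#' @param h2 heritability for `method = "fixed_h2"`.
#' @param alleles allele symbols, first allele = reference for p.
#' @param verbose print per-trait progress.
#' @return invisible list with `frequencies`, `associations`, `effects`,
#'   `manifest`.
#' @export
run_pipeline <- function(pheno, geno, ped, out_dir,
                         traits = NULL, method = "reml", h2 = NULL,
                         alleles = c("C", "T"), verbose = FALSE) {
  pheno <- read_phenotypes(pheno)
  geno <- read_genotypes(geno, allowed = c(
    paste0(alleles[1L], alleles[1L]),
    paste0(sort(alleles)[1L], sort(alleles)[2L]),
    paste0(alleles[2L], alleles[2L])
  ))
  if (!inherits(ped, "pedigree")) ped <- load_pedigree(ped)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  pheno <- derive_fa_traits(pheno)
  all_traits <- intersect(c(.FA_MEASURED, .FA_DERIVED), names(pheno))
  traits <- traits %||% all_traits
  unknown <- setdiff(traits, names(pheno))
  if (length(unknown)) {
    stop("trait column(s) not in the phenotype table: ",
         paste(unknown, collapse = ", "))
  }

  # frequency table over all genotyped cows
  AA <- paste0(alleles[1L], alleles[1L])
  AB <- paste0(sort(alleles)[1L], sort(alleles)[2L])
  BB <- paste0(alleles[2L], alleles[2L])
  cnt <- c(sum(geno$genotype == AA), sum(geno$genotype == AB),
           sum(geno$genotype == BB))
  freq <- genotype_allele_frequencies(cnt[1L], cnt[2L], cnt[3L],
                                      alleles = alleles)

  A <- additive_relationship_matrix(ped)
  assoc_rows <- list()
  eff_rows <- list()
  accounting <- list()
  for (tr in traits) {
    if (verbose) message("fitting trait ", tr)
    fit <- fit_animal_model(pheno, geno, trait = tr, A = A,
                            method = method, h2 = h2)
    lsm <- genotype_lsm(fit)
    eff <- effect_significance(fit, freq)
    assoc_rows[[tr]] <- data.frame(
      trait = tr, genotype = lsm$genotype, n = lsm$n,
      lsm = lsm$lsm, se = lsm$se,
      letters05 = lsm$letters05, letters01 = lsm$letters01,
      p_overall = attr(lsm, "p_overall"),
      stringsAsFactors = FALSE
    )
    eff_rows[[tr]] <- data.frame(
      trait = tr,
      a = eff$estimate[1L], se_a = eff$se[1L], stars_a = eff$stars[1L],
      d = eff$estimate[2L], se_d = eff$se[2L], stars_d = eff$stars[2L],
      alpha = eff$estimate[3L], se_alpha = eff$se[3L],
      stars_alpha = eff$stars[3L],
      p = freq$p, q = freq$q, stringsAsFactors = FALSE
    )
    accounting[[tr]] <- list(n_used = fit$n_used, n_dropped = fit$n_dropped,
                             h2 = fit$h2, converged = fit$converged)
  }
  associations <- do.call(rbind, c(assoc_rows, make.row.names = FALSE))
  effects <- do.call(rbind, c(eff_rows, make.row.names = FALSE))

  freq_out <- freq$table
  freq_out$frequency <- .fmt4(freq_out$frequency)
  freq_out$allele <- c(alleles[1L], "", alleles[2L])
  freq_out$allele_frequency <- c(.fmt4(freq$p), "", .fmt4(freq$q))
  .write_tsv(freq_out, file.path(out_dir, "frequencies.tsv"))

  assoc_out <- associations
  for (col in c("lsm", "se", "p_overall")) assoc_out[[col]] <- .fmt4(assoc_out[[col]])
  .write_tsv(assoc_out, file.path(out_dir, "associations.tsv"))

  eff_out <- effects
  for (col in c("a", "se_a", "d", "se_d", "alpha", "se_alpha", "p", "q")) {
    eff_out[[col]] <- .fmt4(eff_out[[col]])
  }
  .write_tsv(eff_out, file.path(out_dir, "effects.tsv"))

  manifest <- list(
    package = "milkqtl",
    version = as.character(utils::packageVersion("milkqtl")),
    traits = traits,
    model = list(method = method, h2 = h2),
    n_animals_pedigree = nrow(ped),
    n_genotyped = nrow(geno),
    record_accounting = accounting,
    table_md5 = as.list(tools::md5sum(file.path(
      out_dir, c("frequencies.tsv", "associations.tsv", "effects.tsv")
    )))
  )
  names(manifest$table_md5) <- basename(names(manifest$table_md5))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(frequencies = freq, associations = associations,
                 effects = effects, manifest = manifest))
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
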