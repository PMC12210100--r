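# Small simulated populations shared by the model-level tests.

small_sim_config <- function(...) {
  sim_config(n_sires = 8L, daughters_per_sire = 25L, n_farms = 4L,
              n_stages = 3L, traits = "C10:0", missing_rate = 0, ...)
}

# population bundle plus merged records and design pieces for one trait
make_test_population <- function(cfg = small_sim_config(), seed = 101L,
                                 trait = "C10:0") {
  pop <- simulate_population(cfg, seed)
  A <- additive_relationship_matrix(pop$pedigree)
  records <- merge(pop$phenotypes, pop$genotypes_cows, by = "cow_id",
                   sort = FALSE)
  spec <- model_spec(trait)
  des <- build_design(records, spec, rownames(A))
  list(pop = pop, A = A, records = records, spec = spec, des = des)
}

# tiny hand-rolled record set over a named pedigree (no simulator), for
# design-matrix and MME unit tests
toy_records <- function(n = 8L, seed = 5L, n_farms = 2L, n_stages = 1L) {
  set.seed(seed)
  ped <- load_pedigree(data.frame(
    animal = c("S1", "S2", sprintf("c%d", seq_len(n))),
    sire = c(NA, NA, rep(c("S1", "S2"), length.out = n)),
    dam = rep(NA_character_, n + 2L)
  ))
  geno <- sample(c("CC", "CT", "TT"), n, replace = TRUE,
                 prob = c(0.45, 0.45, 0.10))
  while (length(unique(geno)) < 3L) {
    geno <- sample(c("CC", "CT", "TT"), n, replace = TRUE)
  }
  records <- data.frame(
    cow_id = sprintf("c%d", seq_len(n)),
    farm = sprintf("farm%d", sample(rep_len(seq_len(n_farms), n))),
    lactation_stage = sprintf("stage%d",
                              sample(rep_len(seq_len(n_stages), n))),
    calving_age = round(runif(n, 24, 36), 1),
    genotype = geno,
    y = rnorm(n, 3, 0.5),
    stringsAsFactors = FALSE
  )
  list(ped = ped, records = records,
       spec = model_spec("y"))
}
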