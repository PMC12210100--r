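test_that("design matrix uses reference coding and drops incomplete rows", {
  toy <- toy_records(n = 9, n_farms = 1, n_stages = 1)
  ids <- toy$ped$animal
  des <- build_design(toy$records, toy$spec, ids)
  # intercept + 2 genotype dummies + 0 farm + 0 stage + centred covariate
  expect_equal(ncol(des$X), 4L)
  expect_equal(des$n_used, 9L)
  expect_equal(sum(des$Z), 9)

  rec_na <- toy$records
  rec_na$y[3] <- NA
  des_na <- build_design(rec_na, toy$spec, ids)
  expect_equal(des_na$n_used, 8L)
  expect_equal(des_na$n_dropped, 1L)

  # farm perfectly confounded with genotype -> aliasing error naming columns
  rec_alias <- toy$records
  rec_alias$farm <- rec_alias$genotype
  expect_error(build_design(rec_alias, toy$spec, ids), "aliased")

  rec_lost <- toy$records[toy$records$genotype != "TT", ]
  expect_error(build_design(rec_lost, toy$spec, ids), "genotype class")

  rec_stranger <- toy$records
  rec_stranger$cow_id[1] <- "ghost"
  expect_error(build_design(rec_stranger, toy$spec, ids), "not in the pedigree")
  des_drop <- build_design(rec_stranger, toy$spec, ids,
                           missing_animal = "drop")
  expect_equal(des_drop$n_used, 8L)
})

test_that("MME solutions equal dense GLS and collapse to OLS without polygenic variance", {
  toy <- toy_records(n = 8, n_farms = 2)
  A <- additive_relationship_matrix(toy$ped)
  des <- build_design(toy$records, toy$spec, rownames(A))
  s2a <- 0.3
  s2e <- 0.7
  mme <- solve_mme(des$y, des$X, des$Z, inverse_relationship_matrix(A),
                   s2a, s2e)
  V <- s2a * des$Z %*% A %*% t(des$Z) + s2e * diag(length(des$y))
  expect_equal(unname(mme$beta), gls_oracle(des$y, des$X, V)$beta,
               tolerance = 1e-10)

  # sigma2_a = 0: exact OLS fallback, u = 0
  ols <- solve_mme(des$y, des$X, des$Z, inverse_relationship_matrix(A), 0, s2e)
  expect_equal(unname(ols$beta), unname(qr.coef(qr(des$X), des$y)))
  expect_equal(unname(ols$u), rep(0, ncol(des$Z)))
  # and a huge lambda drives u towards 0
  shr <- solve_mme(des$y, des$X, des$Z, inverse_relationship_matrix(A),
                   1e-9, s2e)
  expect_lt(max(abs(shr$u)), 1e-6)
})

test_that("record order does not change solutions or LSMs", {
  tp <- make_test_population(seed = 61)
  fit1 <- fit_animal_model(tp$pop$phenotypes, tp$pop$genotypes_cows,
                           trait = "C10:0", A = tp$A,
                           method = "fixed_h2", h2 = 0.3)
  perm <- sample(nrow(tp$pop$phenotypes))
  fit2 <- fit_animal_model(tp$pop$phenotypes[perm, ], tp$pop$genotypes_cows,
                           trait = "C10:0", A = tp$A,
                           method = "fixed_h2", h2 = 0.3)
  expect_equal(fit1$beta, fit2$beta, tolerance = 1e-10)
  expect_equal(genotype_lsm(fit1)$lsm, genotype_lsm(fit2)$lsm,
               tolerance = 1e-10)
})

test_that("EM-REML matches a dense likelihood grid and keeps the objective monotone", {
  set.seed(71)
  cfg <- sim_config(n_sires = 4, daughters_per_sire = 15, n_farms = 2,
                    n_stages = 2, traits = "C10:0", missing_rate = 0)
  pop <- simulate_population(cfg, seed = 15)
  A <- additive_relationship_matrix(pop$pedigree)
  rec <- merge(pop$phenotypes, pop$genotypes_cows, by = "cow_id", sort = FALSE)
  des <- build_design(rec, model_spec("C10:0"), rownames(A))
  vc <- reml_variance_components(des$y, des$X, A = A, z_index = des$z_index)
  expect_true(vc$converged)
  expect_true(all(diff(vc$loglik_trace) > -1e-7))
  h2_grid <- reml_grid_oracle(des$y, des$X, A[des$z_index, des$z_index])
  expect_lt(abs(vc$h2 - h2_grid), 0.01)
})

test_that("pure-noise data drives the polygenic variance to the boundary", {
  cfg <- sim_config(n_sires = 25, daughters_per_sire = 30, n_farms = 2,
                    n_stages = 2, traits = "C10:0", missing_rate = 0, h2 = 0)
  cfg$trait_params$a <- 0
  cfg$trait_params$d <- 0
  h2_hat <- vapply(1:2, function(r) {
    pop <- simulate_population(cfg, seed = 25 + 10 * r)
    A <- additive_relationship_matrix(pop$pedigree)
    rec <- merge(pop$phenotypes, pop$genotypes_cows, by = "cow_id",
                 sort = FALSE)
    des <- build_design(rec, model_spec("C10:0"), rownames(A))
    suppressWarnings(
      reml_variance_components(des$y, des$X, A = A, z_index = des$z_index)
    )$h2
  }, numeric(1))
  expect_lt(mean(h2_hat), 0.06)
})

test_that("heritability is recovered from simulated populations", {
  h2_hat <- numeric(4)
  for (r in seq_along(h2_hat)) {
    cfg <- sim_config(n_sires = 12, daughters_per_sire = 50, n_farms = 5,
                      n_stages = 3, traits = "C10:0", missing_rate = 0)
    pop <- simulate_population(cfg, seed = 300 + r)
    A <- additive_relationship_matrix(pop$pedigree)
    fit <- fit_animal_model(pop$phenotypes, pop$genotypes_cows,
                            trait = "C10:0", A = A)
    h2_hat[r] <- fit$h2
  }
  expect_lt(abs(mean(h2_hat) - 0.30), 0.10)
})

test_that("balanced single-farm data gives LSMs equal to raw genotype means", {
  set.seed(99)
  n <- 30
  geno <- rep(c("CC", "CT", "TT"), each = n / 3)
  ped <- load_pedigree(data.frame(animal = sprintf("c%02d", 1:n),
                                  sire = 0, dam = 0))
  recs <- data.frame(
    cow_id = sprintf("c%02d", 1:n), farm = "f1", lactation_stage = "s1",
    calving_age = rep(24:33, 3), genotype = geno,  # same ages in every class
    y = rnorm(n, mean = c(CC = 2, CT = 2.4, TT = 3)[geno], sd = 0.1)
  )
  A <- additive_relationship_matrix(ped)
  fit <- fit_animal_model(recs, NULL, trait = "y", spec = model_spec("y"),
                          A = A, method = "fixed_h2", h2 = 0)
  lsm <- genotype_lsm(fit)
  expect_equal(lsm$lsm, as.numeric(tapply(recs$y, geno, mean)),
               tolerance = 1e-10)
  expect_equal(lsm$n, rep(10L, 3))
})

test_that("well-separated genotype classes get distinct letters, invariant to labels", {
  set.seed(100)
  n <- 90
  geno <- rep(c("CC", "CT", "TT"), each = n / 3)
  ped <- load_pedigree(data.frame(animal = sprintf("c%02d", 1:n),
                                  sire = 0, dam = 0))
  recs <- data.frame(
    cow_id = sprintf("c%02d", 1:n), farm = rep(c("f1", "f2"), n / 2),
    lactation_stage = "s1", calving_age = round(runif(n, 24, 36), 1),
    genotype = geno,
    y = rnorm(n, mean = c(CC = 0.49, CT = 0.43, TT = 0.55)[geno], sd = 0.02)
  )
  A <- additive_relationship_matrix(ped)
  fit <- fit_animal_model(recs, NULL, trait = "y", spec = model_spec("y"),
                          A = A, method = "fixed_h2", h2 = 0.2)
  lsm <- genotype_lsm(fit)
  # all three classes separated at both levels -> three distinct letters
  expect_equal(nchar(lsm$letters05), rep(1L, 3))
  expect_equal(nchar(lsm$letters01), rep(1L, 3))
  expect_equal(length(unique(lsm$letters01)), 3L)
  expect_lt(attr(lsm, "p_overall"), 1e-6)

  # relabelling genotypes (changing the reference class) moves no LSM
  recs2 <- recs
  recs2$genotype <- c(CC = "ZZ", CT = "CT", TT = "TT")[recs$genotype]
  fit2 <- fit_animal_model(recs2, NULL, trait = "y", spec = model_spec("y"),
                           A = A, method = "fixed_h2", h2 = 0.2,
                           expected_genotypes = c("ZZ", "CT", "TT"))
  lsm2 <- genotype_lsm(fit2)
  expect_equal(sort(lsm2$lsm), sort(lsm$lsm), tolerance = 1e-10)
})

test_that("the overall genotype F-test matches the GLS full-vs-reduced oracle", {
  toy <- toy_records(n = 20, seed = 13, n_farms = 2)
  A <- additive_relationship_matrix(toy$ped)
  fit <- fit_animal_model(toy$records, NULL, spec = toy$spec, A = A,
                          method = "fixed_h2", h2 = 0.25)
  test <- test_genotype_effect(fit)
  expect_equal(test$df1, 2L)

  # oracle: weighted RSS difference between the model with and without
  # genotype, in the metric of the fitted V
  des <- fit$design
  V <- fit$sigma2_a * des$Z %*% A %*% t(des$Z) +
    fit$sigma2_e * diag(length(des$y))
  Vi <- solve(V)
  wrss <- function(X) {
    b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% des$y)
    r <- des$y - X %*% b
    drop(t(r) %*% Vi %*% r)
  }
  labels <- c("(Intercept)", des$terms)[des$assign + 1L]
  X_red <- des$X[, labels != "genotype", drop = FALSE]
  F_oracle <- (wrss(X_red) - wrss(des$X)) / 2
  expect_equal(test$F, F_oracle, tolerance = 1e-8)

  # huge effect -> overwhelming evidence
  recs_big <- toy$records
  recs_big$y <- recs_big$y +
    c(CC = 0, CT = 25, TT = 50)[recs_big$genotype]
  fit_big <- fit_animal_model(recs_big, NULL, spec = toy$spec, A = A,
                              method = "fixed_h2", h2 = 0.25)
  expect_lt(test_genotype_effect(fit_big)$p_value, 1e-10)
})

test_that("MME, GLS and the eigen-space fit agree on random small instances", {
  set.seed(123)
  for (rep in 1:10) {
    n <- sample(10:30, 1)
    toy <- toy_records(n = n, seed = 1000 + rep, n_farms = 2)
    A <- additive_relationship_matrix(toy$ped)
    des <- build_design(toy$records, toy$spec, rownames(A))
    s2a <- runif(1, 0.05, 1)
    s2e <- runif(1, 0.2, 1)
    mme <- solve_mme(des$y, des$X, des$Z, inverse_relationship_matrix(A),
                     s2a, s2e)
    V <- s2a * des$Z %*% A %*% t(des$Z) + s2e * diag(n)
    expect_equal(unname(mme$beta), gls_oracle(des$y, des$X, V)$beta,
                 tolerance = 1e-8)
  }
})
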