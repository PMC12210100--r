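test_that("pedigree loading validates, sorts, and synthesizes phantom parents", {
  p1 <- load_pedigree(data.frame(animal = "X", sire = 0, dam = 0))
  expect_s3_class(p1, "pedigree")
  expect_equal(inbreeding_coefficients(p1), c(X = 0))

  # input order irrelevant: parents end up before offspring
  p2 <- load_pedigree(data.frame(animal = c("C", "A", "B"),
                                 sire = c("A", 0, 0), dam = c("B", 0, 0)))
  expect_equal(p2$animal[3], "C")
  expect_true(all(match(c("A", "B"), p2$animal) < match("C", p2$animal)))

  # phantom parent gets a founder record
  p3 <- load_pedigree(data.frame(animal = "K", sire = "S9", dam = 0))
  expect_setequal(p3$animal, c("K", "S9"))
  expect_equal(attr(p3, "phantom"), "S9")

  expect_error(
    load_pedigree(data.frame(animal = "A", sire = "A", dam = 0)),
    "cycle"
  )
  expect_error(
    load_pedigree(data.frame(animal = c("A", "B"), sire = c("B", "A"),
                             dam = c(0, 0))),
    "cycle"
  )
  expect_error(
    load_pedigree(data.frame(animal = c("A", "A"), sire = c(0, 0),
                             dam = c(0, 0))),
    "duplicated"
  )
})

test_that("generation truncation keeps ancestors within g parent steps", {
  chain <- load_pedigree(data.frame(
    animal = c("g5", "g4", "g3", "g2", "g1"),
    sire = c(NA, "g5", "g4", "g3", "g2"),
    dam = NA
  ))
  t0 <- truncate_to_generations(chain, "g1", 0)
  expect_equal(t0$animal, "g1")
  expect_true(is.na(t0$sire))

  t3 <- truncate_to_generations(chain, "g1", 3)
  expect_setequal(t3$animal, c("g1", "g2", "g3", "g4"))
  expect_true(is.na(t3$sire[t3$animal == "g4"]))

  tall <- truncate_to_generations(chain, "g1", 10)
  expect_equal(as.data.frame(tall), as.data.frame(chain))

  expect_error(truncate_to_generations(chain, "nope", 2), "not in pedigree")
})

test_that("truncation never increases relationship coefficients", {
  set.seed(33)
  for (rep in 1:5) {
    ped <- random_toy_pedigree(10)
    A_full <- additive_relationship_matrix(ped)
    tr <- truncate_to_generations(ped, ped$animal[nrow(ped)], 1)
    A_tr <- additive_relationship_matrix(tr)
    common <- tr$animal
    expect_true(all(A_tr[common, common] <= A_full[common, common] + 1e-12))
  }
})

test_that("tabular A matches known coefficients and the enumeration oracle", {
  # unrelated founders -> identity
  founders <- load_pedigree(data.frame(animal = letters[1:4], sire = 0, dam = 0))
  expect_equal(additive_relationship_matrix(founders),
               diag(4), ignore_attr = TRUE)

  ped <- load_pedigree(data.frame(
    animal = c("S", "D", "D2", "PO", "FS", "HS"),
    sire   = c(NA, NA, NA, "S", "S", "S"),
    dam    = c(NA, NA, NA, "D", "D", "D2")
  ))
  A <- additive_relationship_matrix(ped)
  expect_equal(A["S", "PO"], 0.5)    # parent-offspring
  expect_equal(A["PO", "FS"], 0.5)   # full sibs
  expect_equal(A["PO", "HS"], 0.25)  # half sibs
  expect_equal(A, enum_kinship_oracle(ped))

  # offspring of a half-sib mating: F = 0.125
  hsm <- load_pedigree(data.frame(
    animal = c("S", "D1", "D2", "X", "Y", "O"),
    sire = c(NA, NA, NA, "S", "S", "X"),
    dam = c(NA, NA, NA, "D1", "D2", "Y")
  ))
  Ah <- additive_relationship_matrix(hsm)
  expect_equal(Ah["O", "O"], 1.125)
  expect_equal(inbreeding_coefficients(hsm)[["O"]], 0.125)
  expect_equal(Ah, enum_kinship_oracle(hsm))

  # random toy pedigrees against the exhaustive gene-drop oracle
  set.seed(91)
  for (rep in 1:5) {
    ped_r <- random_toy_pedigree(9)
    expect_equal(additive_relationship_matrix(ped_r),
                 enum_kinship_oracle(ped_r), tolerance = 1e-12)
  }

  # inbreeding switch zeroes the diagonal excess
  expect_equal(diag(additive_relationship_matrix(hsm, inbreeding = FALSE)),
               rep(1, 6), ignore_attr = TRUE)
})

test_that("A is positive semi-definite on simulated pedigrees", {
  cfg <- sim_config(n_sires = 5, daughters_per_sire = 12, n_farms = 3,
                    n_stages = 2, traits = "C10:0")
  ped <- simulate_pedigree(cfg, seed = 7)
  A <- additive_relationship_matrix(ped)
  expect_true(isSymmetric(A))
  expect_gte(min(eigen(A, symmetric = TRUE, only.values = TRUE)$values),
             -1e-10)
  expect_true(all(diag(A) >= 1))
})

test_that("relationship-matrix inversion is accurate and validated", {
  ident <- diag(3)
  dimnames(ident) <- list(letters[1:3], letters[1:3])
  expect_equal(inverse_relationship_matrix(ident), ident)

  trio <- load_pedigree(data.frame(animal = c("C", "A", "B"),
                                   sire = c("A", 0, 0), dam = c("B", 0, 0)))
  A <- additive_relationship_matrix(trio)
  expect_equal(inverse_relationship_matrix(A), solve(A), tolerance = 1e-10)

  # 500-animal simulated pedigree: A %*% Ainv recovers the identity
  cfg <- sim_config(n_sires = 10, daughters_per_sire = 20, n_farms = 3,
                    n_stages = 2, traits = "C10:0")
  big <- simulate_pedigree(cfg, seed = 19)
  Ab <- additive_relationship_matrix(big)
  Abi <- inverse_relationship_matrix(Ab, tol = 1e-8)
  expect_lt(max(abs(Ab %*% Abi - diag(nrow(Ab)))), 1e-8)

  sing <- matrix(1, 2, 2, dimnames = list(c("i", "j"), c("i", "j")))
  expect_error(inverse_relationship_matrix(sing), "singular")
})

test_that("kinship writers round-trip", {
  trio <- load_pedigree(data.frame(animal = c("C", "A", "B"),
                                   sire = c("A", 0, 0), dam = c("B", 0, 0)))
  A <- additive_relationship_matrix(trio)
  f1 <- tempfile(fileext = ".tsv")
  write_kinship(A, f1, format = "matrix")
  back <- utils::read.delim(f1, check.names = FALSE)
  expect_equal(as.matrix(back[, -1]), A, ignore_attr = TRUE)

  f2 <- tempfile(fileext = ".tsv")
  write_kinship(A, f2, format = "triplet")
  trip <- utils::read.delim(f2)
  rebuilt <- matrix(0, 3, 3, dimnames = dimnames(A))
  for (r in seq_len(nrow(trip))) {
    rebuilt[trip$id_i[r], trip$id_j[r]] <- trip$value[r]
    rebuilt[trip$id_j[r], trip$id_i[r]] <- trip$value[r]
  }
  expect_equal(rebuilt, A)
})
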