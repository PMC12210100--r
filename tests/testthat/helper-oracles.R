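# Independent oracles used across the suite. None of these share code with
# the package's own implementations.

# Exact additive relationship by exhaustive gene-drop enumeration: every
# founder (or unknown-parent slot) gets a unique allele label, every possible
# combination of meiosis outcomes is enumerated, and A_ij is the expected
# number of IBD allele matches between i and j divided by 2. Exact (not Monte
# Carlo); only feasible for toy pedigrees.
enum_kinship_oracle <- function(ped) {
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$animal
  si <- unname(idx[ped$sire])
  di <- unname(idx[ped$dam])
  # fixed labels for founder / unknown-parent slots
  lab0 <- matrix(NA_integer_, n, 2L)
  counter <- 0L
  choices <- list() # each: c(animal, slot, parent)
  for (i in seq_len(n)) {
    for (slot in 1:2) {
      par <- if (slot == 1L) si[i] else di[i]
      if (is.na(par)) {
        counter <- counter + 1L
        lab0[i, slot] <- counter
      } else {
        choices[[length(choices) + 1L]] <- c(i, slot, par)
      }
    }
  }
  nc <- length(choices)
  stopifnot(nc <= 16L) # 2^16 patterns max
  npat <- 2L^nc
  Aacc <- matrix(0, n, n)
  for (pat in 0:(npat - 1L)) {
    lab <- lab0
    bits <- as.integer(intToBits(pat))[seq_len(max(nc, 1L))]
    for (k in seq_len(nc)) {
      ch <- choices[[k]]
      lab[ch[1L], ch[2L]] <- lab[ch[3L], 1L + bits[k]]
    }
    eq <- outer(lab[, 1L], lab[, 1L], "==") +
      outer(lab[, 1L], lab[, 2L], "==") +
      outer(lab[, 2L], lab[, 1L], "==") +
      outer(lab[, 2L], lab[, 2L], "==")
    Aacc <- Aacc + eq
  }
  A <- Aacc / (2 * npat)
  dimnames(A) <- list(ped$animal, ped$animal)
  A
}

# dense-V generalized least squares
gls_oracle <- function(y, X, V) {
  Vi <- solve(V)
  XtVX <- t(X) %*% Vi %*% X
  beta <- solve(XtVX, t(X) %*% Vi %*% y)
  list(beta = as.numeric(beta), vcov = solve(XtVX), Vi = Vi)
}

# profiled REML log-likelihood on a dense heritability grid
reml_grid_oracle <- function(y, X, H, h2_grid = seq(0.005, 0.95, by = 0.005)) {
  n <- length(y)
  p <- ncol(X)
  ll <- vapply(h2_grid, function(h2) {
    V0 <- h2 * H + (1 - h2) * diag(n)
    ch <- chol(V0)
    Vi <- chol2inv(ch)
    XtVX <- t(X) %*% Vi %*% X
    b <- solve(XtVX, t(X) %*% Vi %*% y)
    r <- y - X %*% b
    s2p <- drop(t(r) %*% Vi %*% r) / (n - p)
    -0.5 * (2 * sum(log(diag(ch))) + n * log(s2p) +
              determinant(XtVX / s2p)$modulus[1] +
              drop(t(r) %*% Vi %*% r) / s2p)
  }, numeric(1L))
  h2_grid[which.max(ll)]
}

# random toy pedigree of n animals: each non-founder picks parents among
# earlier animals (or unknown)
random_toy_pedigree <- function(n, p_founder = 0.4) {
  animal <- sprintf("a%02d", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (i >= 3 && stats::runif(1) > p_founder) {
      pick <- sample(i - 1L, min(2L, i - 1L))
      sire[i] <- animal[pick[1L]]
      if (length(pick) > 1L && stats::runif(1) > 0.3) dam[i] <- animal[pick[2L]]
    }
  }
  load_pedigree(data.frame(animal = animal, sire = sire, dam = dam))
}
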