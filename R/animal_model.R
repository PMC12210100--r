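# Mixed animal model for one trait:
#   y = mu + genotype + farm + lactation stage + b * age-at-calving
#       + polygenic animal effect (Var = A * sigma2_a) + residual
# Variance components by EM-REML; solutions by GLS/BLUP, with Henderson's
# mixed-model equations available as a stand-alone solver.

#' Model specification for the single-trait animal model
#'
#' Names the phenotype-table columns holding the trait, the fixed factors and
#' the covariate. The age-at-calving covariate is treated as a continuous
#' regression by default; set `covariate_as_factor = TRUE` to fit age classes
#' instead.
#'
#' @param trait name of the trait column (one of the 24 analysed traits).
#' @param id,genotype,farm,stage,covariate column names in the merged
#'   phenotype/genotype table.
#' @param covariate_as_factor fit the covariate as a class factor.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(trait,
                       id = "cow_id",
                       genotype = "genotype",
                       farm = "farm",
                       stage = "lactation_stage",
                       covariate = "calving_age",
                       covariate_as_factor = FALSE) {
  structure(
    list(trait = trait, id = id, genotype = genotype, farm = farm,
         stage = stage, covariate = covariate,
         covariate_as_factor = covariate_as_factor),
    class = "model_spec"
  )
}

#' Build the design matrices for the animal model
#'
#' Drops records with any missing field (counted in `n_dropped`), builds the
#' fixed-effects matrix X (intercept, treatment-coded genotype, farm and
#' stage where they have more than one observed level, centred covariate)
#' and the record-to-animal incidence matrix Z over the supplied pedigree
#' order. Rank deficiency is a hard error naming the aliased columns.
#'
#' @param records merged phenotype/genotype data.frame.
#' @param spec a [model_spec()].
#' @param animal_ids pedigree animal ids, in the order of the A matrix.
#' @param missing_animal what to do with records whose animal is not in
#'   `animal_ids`: `"error"` (default) or `"drop"`.
#' @param expected_genotypes genotype classes that must each be non-empty
#'   (`NULL` to skip the check).
#' @return list with `y`, `X`, `Z` (dense incidence), `z_index`, the used
#'   records, level maps, `n_used`, `n_dropped` and the covariate centre.
#' @export
build_design <- function(records, spec, animal_ids,
                         missing_animal = c("error", "drop"),
                         expected_genotypes = c("CC", "CT", "TT")) {
  stopifnot(inherits(spec, "model_spec"))
  missing_animal <- match.arg(missing_animal)
  need <- c(spec$id, spec$trait, spec$genotype, spec$farm, spec$stage,
            spec$covariate)
  absent <- setdiff(need, names(records))
  if (length(absent)) {
    stop("missing column(s) in records: ", paste(absent, collapse = ", "))
  }
  df <- records[, need]
  names(df) <- c("id", "y", "genotype", "farm", "stage", "cov")
  df$id <- as.character(df$id)
  n_total <- nrow(df)
  df <- df[stats::complete.cases(df), , drop = FALSE]
  in_ped <- df$id %in% animal_ids
  if (!all(in_ped)) {
    if (missing_animal == "error") {
      stop(sum(!in_ped), " record(s) with animal not in the pedigree, e.g. '",
           df$id[!in_ped][1L], "'")
    }
    df <- df[in_ped, , drop = FALSE]
  }
  n_used <- nrow(df)
  if (n_used == 0L) stop("no usable records after dropping incomplete rows")
  if (!is.null(expected_genotypes)) {
    empty <- setdiff(expected_genotypes, unique(df$genotype))
    if (length(empty)) {
      stop("genotype class(es) with zero records: ",
           paste(empty, collapse = ", "))
    }
  }
  df$genotype <- factor(df$genotype, levels = sort(unique(df$genotype)))
  df$farm <- factor(df$farm)
  df$stage <- factor(df$stage)
  terms <- "genotype"
  if (nlevels(df$farm) > 1L) terms <- c(terms, "farm")
  if (nlevels(df$stage) > 1L) terms <- c(terms, "stage")
  cov_center <- NA_real_
  if (spec$covariate_as_factor) {
    df$cov <- factor(df$cov)
    if (nlevels(df$cov) > 1L) terms <- c(terms, "cov")
  } else {
    cov_center <- mean(df$cov)
    df$cov_c <- df$cov - cov_center
    terms <- c(terms, "cov_c")
  }
  X <- stats::model.matrix(stats::reformulate(terms), df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }
  z_index <- match(df$id, animal_ids)
  Z <- matrix(0, n_used, length(animal_ids),
              dimnames = list(NULL, animal_ids))
  Z[cbind(seq_len(n_used), z_index)] <- 1
  list(
    y = df$y, X = X, Z = Z, z_index = z_index, data = df,
    n_used = n_used, n_dropped = n_total - n_used,
    assign = attr(X, "assign"), terms = terms,
    genotype_levels = levels(df$genotype),
    farm_levels = levels(df$farm), stage_levels = levels(df$stage),
    cov_center = cov_center, rank = qrX$rank
  )
}

# Eigen-reduction of the phenotyped-animal relationship submatrix
# H = Z A Z'. Precompute once and reuse across replicate fits on the same
# record set.
#' @rdname reml_variance_components
#' @param z_index record-to-animal index (alternative to a dense `Z`).
#' @export
kinship_eigen <- function(A, Z = NULL, z_index = NULL) {
  H <- if (!is.null(z_index)) {
    A[z_index, z_index, drop = FALSE]
  } else if (is.matrix(Z)) {
    Z %*% A %*% t(Z)
  } else {
    A
  }
  eigen(H, symmetric = TRUE)
}

#' EM-REML variance components for the animal model
#'
#' Estimates the polygenic and residual variances of the single-trait animal
#' model by restricted maximum likelihood. The model is first reduced to the
#' phenotyped animals (`H = Z A Z'`), `H` is eigen-decomposed once, and the
#' EM-REML recurrences for the mixed-model equations are run in the rotated
#' basis where the covariance is diagonal, so every iteration is cheap while
#' remaining the exact EM map for the REML objective (the REML log-likelihood
#' is non-decreasing across iterations and is returned as a trace).
#'
#' Convergence: relative change of both components below `tol`. Because the
#' EM fixed-point residual can undersell the remaining distance to the
#' maximiser, interior solutions are polished by a 1-D profiled-likelihood
#' optimisation of the same REML objective (accepted only when it does not
#' decrease the log-likelihood). A polygenic variance collapsing below
#' `1e-8` of the total is declared a boundary (zero-heritability) solution.
#' Hitting `max_iter` flags the fit non-converged with a warning.
#'
#' @param y phenotype vector.
#' @param X fixed-effects design (full column rank).
#' @param Z record-to-animal incidence matrix (or `NULL` with `z_index`).
#' @param A additive relationship matrix over the pedigree.
#' @param tol relative convergence tolerance (default 1e-6).
#' @param max_iter maximum EM iterations (default 500).
#' @param init optional `c(sigma2_a, sigma2_e)` starting values.
#' @param eigen_H optional precomputed [kinship_eigen()] decomposition.
#' @return list with `sigma2_a`, `sigma2_e`, `h2`, `loglik`, `loglik_trace`,
#'   `iterations`, `converged`, `boundary`.
#' @export
reml_variance_components <- function(y, X, Z = NULL, A = NULL,
                                     tol = 1e-6, max_iter = 500L,
                                     init = NULL, z_index = NULL,
                                     eigen_H = NULL) {
  eH <- eigen_H %||% kinship_eigen(A, Z = Z, z_index = z_index)
  d <- pmax(eH$values, 1e-12)
  U <- eH$vectors
  yt <- drop(crossprod(U, y))
  Xt <- crossprod(U, X)
  n <- length(yt)
  p <- ncol(Xt)
  XtXf <- crossprod(Xt)
  Xtyf <- drop(crossprod(Xt, yt))
  yy <- sum(yt^2)

  if (is.null(init)) {
    r0 <- qr.resid(qr(Xt), yt)
    s2p <- sum(r0^2) / (n - p)
    init <- c(0.5 * s2p, 0.5 * s2p)
  }
  # one EM-REML update of (sigma2_a, sigma2_e)
  em_step <- function(sa, se) {
    lambda <- se / sa
    w <- 1 + lambda / d
    Xw <- Xt / w
    S <- XtXf - crossprod(Xt, Xw)
    rhs <- Xtyf - drop(crossprod(Xw, yt))
    Sch <- chol(S)
    b <- backsolve(Sch, forwardsolve(t(Sch), rhs))
    u <- (yt - drop(Xt %*% b)) / w
    Sinv <- chol2inv(Sch)
    quad <- rowSums((Xt %*% Sinv) * Xt)
    trDC <- sum(1 / (d * w)) + sum(quad / (d * w^2))
    c((sum(u^2 / d) + se * trDC) / n,
      (yy - sum(b * Xtyf) - sum(u * yt)) / (n - p))
  }
  ll <- function(th) .reml_loglik(yt, Xt, d, th[1L], th[2L])

  # EM with monotone step-lengthening: extrapolate the EM step on the log
  # scale and accept only if the REML log-likelihood does not decrease, so
  # the EM ascent guarantee is preserved while convergence is much faster
  # than plain EM. Convergence is declared on the EM fixed-point residual.
  th <- c(init[1L], init[2L])
  ll_trace <- numeric(0)
  converged <- FALSE
  boundary <- FALSE
  iter <- 0L
  step <- 1
  while (iter < max_iter) {
    iter <- iter + 1L
    th_em <- em_step(th[1L], th[2L])
    if (th_em[1L] < 1e-8 * sum(th_em)) {
      th <- c(0, th_em[2L])
      ll_trace <- c(ll_trace, ll(c(1e-300, th_em[2L])))
      converged <- TRUE
      boundary <- TRUE
      break
    }
    rel <- max(abs(th_em - th) / (th + 1e-12))
    accepted <- th_em
    ll_acc <- ll(th_em)
    if (step > 1) {
      th_ext <- exp(log(th) + step * (log(th_em) - log(th)))
      ll_ext <- ll(th_ext)
      if (is.finite(ll_ext) && ll_ext >= ll_acc) {
        accepted <- th_ext
        ll_acc <- ll_ext
        step <- min(step * 2, 64)
      } else {
        step <- 2
      }
    } else {
      step <- 2
    }
    th <- accepted
    ll_trace <- c(ll_trace, ll_acc)
    if (rel < tol) {
      converged <- TRUE
      break
    }
  }
  sa <- th[1L]
  se <- th[2L]
  # EM's fixed-point stopping rule can halt while the slow EM trajectory is
  # still short of the maximiser; polish the interior solution by a 1-D
  # profiled-REML optimisation of the same objective around the EM estimate
  # (accepted only if it does not decrease the log-likelihood).
  if (!boundary && sa > 0) {
    prof <- function(h2) {
      v0 <- h2 * d + (1 - h2)
      XtVX <- crossprod(Xt, Xt / v0)
      b <- solve(XtVX, crossprod(Xt, yt / v0))
      r <- yt - drop(Xt %*% b)
      s2p <- sum(r^2 / v0) / (n - p)
      list(ll = .reml_loglik(yt, Xt, d, h2 * s2p, (1 - h2) * s2p),
           s2p = s2p)
    }
    h2_em <- sa / (sa + se)
    lo <- max(1e-6, h2_em - 0.15)
    hi <- min(1 - 1e-6, h2_em + 0.15)
    opt <- stats::optimize(function(h2) prof(h2)$ll, lower = lo, upper = hi,
                           maximum = TRUE, tol = 1e-9)
    cur_ll <- if (length(ll_trace)) ll_trace[length(ll_trace)] else -Inf
    if (opt$objective >= cur_ll) {
      if (opt$maximum - lo <= 1e-5 && lo <= 2e-6) {
        # profile maximum pinned at the zero-heritability edge: the REML
        # optimum is on the boundary, which slow EM drift never reaches
        at0 <- prof(0)
        sa <- 0
        se <- at0$s2p
        ll_trace <- c(ll_trace, at0$ll)
        converged <- TRUE
        boundary <- TRUE
      } else {
        at <- prof(opt$maximum)
        sa <- opt$maximum * at$s2p
        se <- (1 - opt$maximum) * at$s2p
        ll_trace <- c(ll_trace, opt$objective)
        # an interior profile maximum is the (scale-profiled) REML optimum,
        # even if the EM fixed-point loop itself ran out of iterations
        if (opt$maximum - lo > 1e-5 && hi - opt$maximum > 1e-5) {
          converged <- TRUE
        }
      }
    }
  }
  if (!converged) {
    warning("EM-REML did not converge in ", max_iter,
            " iterations; returning the last estimates")
  }
  list(
    sigma2_a = sa, sigma2_e = se, h2 = sa / (sa + se),
    loglik = if (length(ll_trace)) ll_trace[length(ll_trace)] else NA_real_,
    loglik_trace = ll_trace, iterations = iter,
    converged = converged, boundary = boundary
  )
}

# REML log-likelihood (up to an additive constant) in the rotated basis
.reml_loglik <- function(yt, Xt, d, sa, se) {
  v <- sa * d + se
  XtVX <- crossprod(Xt, Xt / v)
  b <- solve(XtVX, crossprod(Xt, yt / v))
  r <- yt - drop(Xt %*% b)
  -0.5 * (sum(log(v)) +
            as.numeric(determinant(XtVX, logarithm = TRUE)$modulus) +
            sum(r^2 / v))
}

#' Solve Henderson's mixed-model equations
#'
#' The animal-model equations
#' `[X'X, X'Z; Z'X, Z'Z + lambda * Ainv] [beta; u] = [X'y; Z'y]` with
#' `lambda = sigma2_e / sigma2_a`, solved densely. `sigma2_a = 0` falls back
#' to ordinary least squares with `u = 0`. The solution is verified against
#' the system residual (`< 1e-8 * ||RHS||`).
#'
#' @param y,X,Z model arrays as from [build_design()].
#' @param A_inv inverse relationship matrix over the pedigree.
#' @param sigma2_a,sigma2_e variance components.
#' @return list with `beta`, `u` (named by animal), `c_inv` (inverse
#'   coefficient matrix; `vcov(beta, u) = c_inv * sigma2_e`), `lambda`.
#' @export
solve_mme <- function(y, X, Z, A_inv, sigma2_a, sigma2_e) {
  p <- ncol(X)
  q <- ncol(Z)
  if (sigma2_a <= 0) {
    qrX <- qr(X)
    beta <- qr.coef(qrX, y)
    XtXi <- chol2inv(qr.R(qrX))
    c_inv <- matrix(0, p + q, p + q)
    c_inv[seq_len(p), seq_len(p)] <- XtXi
    return(list(beta = beta, u = stats::setNames(numeric(q), colnames(Z)),
                c_inv = c_inv, lambda = Inf))
  }
  lambda <- sigma2_e / sigma2_a
  C <- rbind(
    cbind(crossprod(X), crossprod(X, Z)),
    cbind(crossprod(Z, X), crossprod(Z) + lambda * A_inv)
  )
  rhs <- c(crossprod(X, y), crossprod(Z, y))
  ch <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(ch)) {
    stop("singular mixed-model coefficient matrix; check for aliased fixed ",
         "effects or a singular relationship matrix")
  }
  sol <- backsolve(ch, forwardsolve(t(ch), rhs))
  resid_norm <- sqrt(sum((C %*% sol - rhs)^2))
  if (resid_norm > 1e-8 * sqrt(sum(rhs^2))) {
    stop("mixed-model equations solved inaccurately (residual norm ",
         format(resid_norm), ")")
  }
  c_inv <- chol2inv(ch)
  beta <- stats::setNames(sol[seq_len(p)], colnames(X))
  u <- stats::setNames(sol[p + seq_len(q)], colnames(Z))
  list(beta = beta, u = u, c_inv = c_inv, lambda = lambda)
}

#' Fit the single-trait mixed animal model
#'
#' End-to-end fit: merges genotypes into the phenotype table, builds the
#' design, estimates variance components by [reml_variance_components()] (or
#' profiles the residual variance at a fixed heritability), and computes
#' fixed-effect solutions with their covariance by GLS together with BLUP
#' polygenic predictions for every pedigree animal. The GLS solutions are
#' identical to Henderson's mixed-model equations (see [solve_mme()]); the
#' equivalence is part of the package's test suite.
#'
#' @param pheno phenotype data.frame (see [read_phenotypes()] for the schema).
#' @param geno genotype data.frame with columns `cow_id`, `genotype`.
#' @param ped a [load_pedigree()] pedigree (or `NULL` when `A` is given).
#' @param trait trait column to analyse, or a full [model_spec()] via `spec`.
#' @param spec optional [model_spec()]; overrides `trait`.
#' @param A optional precomputed relationship matrix (dimnames = animal ids).
#' @param method `"reml"` (default) or `"fixed_h2"` with `h2` supplied.
#' @param h2 heritability used when `method = "fixed_h2"`.
#' @param eigen_H optional precomputed [kinship_eigen()] for the record set.
#' @param tol,max_iter REML controls.
#' @param ... passed to [build_design()].
#' @return object of class `animal_model_fit` with elements `beta`,
#'   `vcov_beta`, `u`, `sigma2_a`, `sigma2_e`, `h2`, `loglik`, `n_used`,
#'   `n_dropped`, `df_residual`, `design`, `converged`.
#' @export
fit_animal_model <- function(pheno, geno = NULL, ped = NULL, trait = NULL,
                             spec = NULL, A = NULL,
                             method = c("reml", "fixed_h2"), h2 = NULL,
                             eigen_H = NULL, tol = 1e-6, max_iter = 500L,
                             ...) {
  method <- match.arg(method)
  spec <- spec %||% model_spec(trait)
  records <- pheno
  if (!is.null(geno)) {
    records <- merge(pheno, geno, by = spec$id, sort = FALSE)
  }
  if (is.null(A)) {
    if (is.null(ped)) stop("supply a pedigree or a relationship matrix A")
    A <- additive_relationship_matrix(ped)
  }
  ids <- rownames(A)
  des <- build_design(records, spec, ids, ...)
  eH <- eigen_H %||% kinship_eigen(A, z_index = des$z_index)

  if (method == "reml") {
    vc <- reml_variance_components(des$y, des$X, A = A, tol = tol,
                                   max_iter = max_iter, eigen_H = eH)
  } else {
    stopifnot(!is.null(h2), h2 >= 0, h2 < 1)
    vc <- .profile_fixed_h2(des$y, des$X, eH, h2)
  }

  gls <- .gls_eigen(des$y, des$X, eH, vc$sigma2_a, vc$sigma2_e)
  # BLUP for every pedigree animal: u = sigma2_a * A[, obs] Z' V^-1 r
  u <- if (vc$sigma2_a > 0) {
    drop(vc$sigma2_a * (A[, des$z_index, drop = FALSE] %*% gls$vinv_r))
  } else {
    numeric(nrow(A))
  }
  names(u) <- ids

  structure(
    list(
      beta = gls$beta, vcov_beta = gls$vcov_beta, u = u,
      sigma2_a = vc$sigma2_a, sigma2_e = vc$sigma2_e,
      h2 = vc$sigma2_a / (vc$sigma2_a + vc$sigma2_e),
      loglik = vc$loglik, loglik_trace = vc$loglik_trace %||% numeric(0),
      n_used = des$n_used, n_dropped = des$n_dropped,
      df_residual = des$n_used - des$rank,
      design = des, spec = spec,
      converged = vc$converged %||% TRUE,
      boundary = vc$boundary %||% (vc$sigma2_a == 0)
    ),
    class = "animal_model_fit"
  )
}

# GLS in the rotated basis; also returns V^-1 (y - X beta) in the original
# basis for downstream BLUP.
.gls_eigen <- function(y, X, eH, sa, se) {
  d <- pmax(eH$values, 1e-12)
  U <- eH$vectors
  yt <- drop(crossprod(U, y))
  Xt <- crossprod(U, X)
  v <- sa * d + se
  XtVX <- crossprod(Xt, Xt / v)
  vcov_beta <- chol2inv(chol(XtVX))
  beta <- drop(vcov_beta %*% crossprod(Xt, yt / v))
  names(beta) <- colnames(X)
  dimnames(vcov_beta) <- list(colnames(X), colnames(X))
  r <- yt - drop(Xt %*% beta)
  list(beta = beta, vcov_beta = vcov_beta,
       vinv_r = drop(U %*% (r / v)))
}

# residual variance profiled at a fixed heritability (lambda known)
.profile_fixed_h2 <- function(y, X, eH, h2) {
  d <- pmax(eH$values, 1e-12)
  U <- eH$vectors
  yt <- drop(crossprod(U, y))
  Xt <- crossprod(U, X)
  n <- length(yt)
  p <- ncol(Xt)
  v0 <- h2 * d + (1 - h2)          # V / sigma2_p
  XtVX <- crossprod(Xt, Xt / v0)
  beta <- solve(XtVX, crossprod(Xt, yt / v0))
  r <- yt - drop(Xt %*% beta)
  s2p <- sum(r^2 / v0) / (n - p)
  list(sigma2_a = h2 * s2p, sigma2_e = (1 - h2) * s2p,
       loglik = .reml_loglik(yt, Xt, d, h2 * s2p, (1 - h2) * s2p),
       loglik_trace = numeric(0), converged = TRUE, boundary = (h2 == 0))
}

#' @export
print.animal_model_fit <- function(x, ...) {
  cat("Animal-model fit:", x$spec$trait, "\n")
  cat(sprintf("  n used %d (dropped %d); sigma2_a %.5g, sigma2_e %.5g, h2 %.3f%s\n",
              x$n_used, x$n_dropped, x$sigma2_a, x$sigma2_e, x$h2,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

# rows of the estimable-function matrix K producing the genotype LSMs:
# intercept + own genotype effect + unweighted mean over farm and stage
# levels + covariate at its centre (0 after centring).
.lsm_K <- function(fit) {
  des <- fit$design
  X <- des$X
  K <- matrix(0, length(des$genotype_levels), ncol(X),
              dimnames = list(des$genotype_levels, colnames(X)))
  K[, 1L] <- 1  # intercept
  # per-column term label; assign = 0 marks the intercept column
  labels <- c("(Intercept)", des$terms)[des$assign + 1L]
  for (g in seq_along(des$genotype_levels)) {
    lev <- des$genotype_levels[g]
    if (g > 1L) {
      K[g, colnames(X) == paste0("genotype", lev)] <- 1
    }
    for (term in c("farm", "stage", "cov")) {
      cols <- which(!is.na(labels) & labels == term)
      if (length(cols)) {
        nlev <- length(cols) + 1L  # treatment coding: reference level absorbed
        K[g, cols] <- 1 / nlev
      }
    }
    # centred continuous covariate evaluated at its mean contributes 0
  }
  K
}

#' Genotype least-squares means
#'
#' Model-based marginal means per genotype: intercept plus genotype effect,
#' averaged (unweighted) over the observed farm and lactation-stage levels,
#' with the covariate at its mean. Standard errors come from the quadratic
#' form `k' vcov(beta) k`; pairwise genotype differences are tested with
#' t-tests on `n_used - rank(X)` degrees of freedom and summarised as letter
#' groups (lowercase at 0.05, uppercase at 0.01; genotypes sharing no letter
#' differ at that level).
#'
#' @param fit an [fit_animal_model()] object.
#' @return data.frame (class `lsm_table`) with columns `genotype`, `n`,
#'   `lsm`, `se`, `letters05`, `letters01`, and attributes `pairwise`
#'   (p-value matrix), `vcov_lsm`, `p_overall`.
#' @export
genotype_lsm <- function(fit) {
  stopifnot(inherits(fit, "animal_model_fit"))
  K <- .lsm_K(fit)
  lsm <- drop(K %*% fit$beta)
  V <- K %*% fit$vcov_beta %*% t(K)
  se <- sqrt(diag(V))
  k <- length(lsm)
  pmat <- matrix(NA_real_, k, k, dimnames = list(rownames(K), rownames(K)))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) next
      sed <- sqrt(V[i, i] + V[j, j] - 2 * V[i, j])
      tv <- (lsm[i] - lsm[j]) / sed
      pmat[i, j] <- 2 * stats::pt(-abs(tv), df = fit$df_residual)
    }
  }
  n_per <- table(fit$design$data$genotype)[rownames(K)]
  out <- data.frame(
    genotype = rownames(K),
    n = as.integer(n_per),
    lsm = lsm,
    se = se,
    letters05 = .letter_groups(pmat, lsm, 0.05, letters),
    letters01 = .letter_groups(pmat, lsm, 0.01, LETTERS),
    row.names = NULL
  )
  test <- test_genotype_effect(fit)
  attr(out, "pairwise") <- pmat
  attr(out, "vcov_lsm") <- V
  attr(out, "p_overall") <- test$p_value
  class(out) <- c("lsm_table", "data.frame")
  out
}

# compact letter display: sweep over means sorted ascending, collect maximal
# runs whose pairwise tests are all non-significant, drop contained runs,
# letter them in order (ties in the sweep broken by ascending mean).
.letter_groups <- function(pmat, means, alpha, pool) {
  k <- length(means)
  ord <- order(means)
  ns <- function(i, j) pmat[ord[i], ord[j]] > alpha
  runs <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && all(vapply(i:j, function(m) ns(m, j + 1L), logical(1L)))) {
      j <- j + 1L
    }
    runs[[length(runs) + 1L]] <- i:j
  }
  keep <- !vapply(seq_along(runs), function(r) {
    any(vapply(seq_along(runs), function(s) {
      s != r && all(runs[[r]] %in% runs[[s]])
    }, logical(1L)))
  }, logical(1L))
  runs <- unique(runs[keep])
  lab <- character(k)
  for (r in seq_along(runs)) {
    for (m in runs[[r]]) lab[m] <- paste0(lab[m], pool[r])
  }
  out <- character(k)
  out[ord] <- lab
  out
}

#' Overall genotype test
#'
#' Wald F-test of the joint null that all genotype effects are equal
#' (2 numerator degrees of freedom for three genotype classes), with
#' denominator degrees of freedom `n_used - rank(X)`.
#'
#' @param fit an [fit_animal_model()] object.
#' @return list with `F`, `df1`, `df2`, `p_value`.
#' @export
test_genotype_effect <- function(fit) {
  stopifnot(inherits(fit, "animal_model_fit"))
  des <- fit$design
  labels <- c("(Intercept)", des$terms)[des$assign + 1L]
  cols <- which(labels == "genotype")
  bg <- fit$beta[cols]
  Vg <- fit$vcov_beta[cols, cols, drop = FALSE]
  df1 <- length(cols)
  Fstat <- drop(t(bg) %*% solve(Vg, bg)) / df1
  df2 <- fit$df_residual
  list(F = Fstat, df1 = df1, df2 = df2,
       p_value = stats::pf(Fstat, df1, df2, lower.tail = FALSE))
}
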