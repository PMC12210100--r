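# Pedigree parsing/validation and the numerator (additive) relationship
# matrix built by the tabular method.

.PED_UNKNOWN <- c("0", "", ".", "NA")

#' Load and validate a pedigree
#'
#' Accepts a CSV path (header required; first three columns animal, sire, dam)
#' or a data.frame. Unknown parents may be coded `0`, an empty field, `.` or
#' `NA`. Parents that appear only as sire/dam get a synthesized founder record
#' (a "phantom parent"). Records are topologically sorted so that parents
#' precede offspring; a cycle (an animal its own ancestor, including
#' self-parenting) or a duplicated animal id is a hard error.
#'
#' @param x file path or data.frame with columns animal, sire, dam.
#' @param unknown character codes treated as "parent unknown".
#' @return an object of class `pedigree`: a data.frame with character columns
#'   `animal`, `sire`, `dam` (NA for unknown) in topological order, with
#'   attribute `phantom` listing synthesized founder ids.
#' @export
load_pedigree <- function(x, unknown = .PED_UNKNOWN) {
  if (is.character(x) && length(x) == 1L) {
    x <- utils::read.csv(x, header = TRUE, colClasses = "character",
                         check.names = FALSE, fileEncoding = "UTF-8-BOM")
  }
  stopifnot(is.data.frame(x))
  if (ncol(x) < 3L) stop("pedigree table needs 3 columns: animal, sire, dam")
  ped <- data.frame(
    animal = trimws(as.character(x[[1L]])),
    sire = trimws(as.character(x[[2L]])),
    dam = trimws(as.character(x[[3L]])),
    stringsAsFactors = FALSE
  )
  for (col in c("sire", "dam")) {
    ped[[col]][ped[[col]] %in% unknown | is.na(ped[[col]])] <- NA_character_
  }
  if (any(ped$animal %in% unknown | is.na(ped$animal))) {
    stop("animal id missing or equal to the unknown-parent sentinel")
  }
  dup <- ped$animal[duplicated(ped$animal)]
  if (length(dup)) {
    stop("duplicated animal id(s): ", paste(unique(dup), collapse = ", "))
  }
  parents <- setdiff(stats::na.omit(c(ped$sire, ped$dam)), ped$animal)
  if (length(parents)) {
    ped <- rbind(
      data.frame(animal = parents, sire = NA_character_, dam = NA_character_,
                 stringsAsFactors = FALSE),
      ped
    )
  }
  ped <- .topological_sort(ped)
  attr(ped, "phantom") <- parents
  class(ped) <- c("pedigree", "data.frame")
  ped
}

# Kahn-style layered sort; errors naming a cycle member if no progress is made
.topological_sort <- function(ped) {
  n <- nrow(ped)
  placed <- logical(n)
  known <- ped$animal
  order_idx <- integer(0)
  placed_ids <- character(0)
  remaining <- seq_len(n)
  while (length(remaining)) {
    ready <- remaining[
      (is.na(ped$sire[remaining]) | ped$sire[remaining] %in% placed_ids) &
      (is.na(ped$dam[remaining]) | ped$dam[remaining] %in% placed_ids)
    ]
    if (!length(ready)) {
      stop("pedigree cycle detected involving animal '",
           ped$animal[remaining[1L]], "'")
    }
    order_idx <- c(order_idx, ready)
    placed_ids <- c(placed_ids, ped$animal[ready])
    remaining <- setdiff(remaining, ready)
  }
  out <- ped[order_idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.pedigree <- function(x, ...) {
  cat("Pedigree with", nrow(x), "animals (",
      sum(is.na(x$sire) & is.na(x$dam)), "founders,",
      length(attr(x, "phantom") %||% character(0)), "phantom parents )\n")
  print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' Truncate a pedigree to a fixed number of ancestral generations
#'
#' Keeps the focal animals and every ancestor reachable in at most `g` parent
#' steps; parents beyond the horizon are recoded unknown. With `g = 0` only
#' the focal animals remain, all founders. Truncation with `g` at least the
#' pedigree depth is the identity.
#'
#' @param ped a [load_pedigree()] object.
#' @param focal_ids animals of interest (must all be in the pedigree).
#' @param g number of ancestor generations to retain (one step = one parent
#'   link).
#' @return truncated `pedigree`.
#' @export
truncate_to_generations <- function(ped, focal_ids, g) {
  stopifnot(inherits(ped, "pedigree"), g >= 0)
  focal_ids <- as.character(focal_ids)
  missing <- setdiff(focal_ids, ped$animal)
  if (length(missing)) {
    stop("focal id(s) not in pedigree: ", paste(missing, collapse = ", "))
  }
  keep <- frontier <- unique(focal_ids)
  step <- 0L
  while (step < g && length(frontier)) {
    rows <- ped[ped$animal %in% frontier, , drop = FALSE]
    frontier <- setdiff(stats::na.omit(c(rows$sire, rows$dam)), keep)
    keep <- c(keep, frontier)
    step <- step + 1L
  }
  out <- ped[ped$animal %in% keep, , drop = FALSE]
  out$sire[!(out$sire %in% keep)] <- NA_character_
  out$dam[!(out$dam %in% keep)] <- NA_character_
  rownames(out) <- NULL
  attr(out, "phantom") <- intersect(attr(ped, "phantom"), keep)
  class(out) <- c("pedigree", "data.frame")
  out
}

#' Additive (numerator) relationship matrix
#'
#' Builds A by the tabular method over the topologically sorted pedigree:
#' `A[i,i] = 1 + 0.5 * A[s,d]` (diagonal carries inbreeding) and
#' `A[i,j] = 0.5 * (A[j,s] + A[j,d])` for older animals `j`, with unknown
#' parents contributing zero. Set `inbreeding = FALSE` to force a unit
#' diagonal (classical sire-model approximation, kept for comparison).
#'
#' @param ped a [load_pedigree()] object.
#' @param inbreeding accumulate inbreeding on the diagonal (default TRUE).
#' @return symmetric matrix with the pedigree's animal ids as dimnames.
#' @export
additive_relationship_matrix <- function(ped, inbreeding = TRUE) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$animal
  si <- idx[ped$sire]
  di <- idx[ped$dam]
  A <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  for (i in seq_len(n)) {
    s <- si[i]
    d <- di[i]
    if (inbreeding && !is.na(s) && !is.na(d)) {
      A[i, i] <- 1 + 0.5 * A[s, d]
    } else {
      A[i, i] <- 1
    }
    if (i > 1L) {
      j <- seq_len(i - 1L)
      val <- numeric(i - 1L)
      if (!is.na(s)) val <- val + 0.5 * A[j, s]
      if (!is.na(d)) val <- val + 0.5 * A[j, d]
      A[j, i] <- val
      A[i, j] <- val
    }
  }
  A
}

#' Inbreeding coefficients
#'
#' `F = diag(A) - 1` from the tabular-method relationship matrix.
#'
#' @param ped a `pedigree`, or a precomputed A matrix.
#' @return named numeric vector of inbreeding coefficients.
#' @export
inbreeding_coefficients <- function(ped) {
  A <- if (inherits(ped, "pedigree")) additive_relationship_matrix(ped) else ped
  diag(A) - 1
}

#' Inverse of the relationship matrix
#'
#' Dense Cholesky inversion of A (the study-scale pedigrees, a few thousand
#' animals, do not need sparse inverse rules). A non-positive-definite A is an
#' error unless `jitter > 0`, in which case `jitter` is added to the diagonal
#' and the inversion retried. The inverse is verified against
#' `max |A %*% Ainv - I| < tol`.
#'
#' @param A relationship matrix from [additive_relationship_matrix()].
#' @param tol verification tolerance on the max elementwise residual.
#' @param jitter diagonal regularization used only if plain Cholesky fails.
#' @return the inverse matrix, same dimnames as `A`.
#' @export
inverse_relationship_matrix <- function(A, tol = 1e-8, jitter = 0) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch) && jitter > 0) {
    ch <- tryCatch(chol(A + diag(jitter, nrow(A))), error = function(e) NULL)
  }
  if (is.null(ch)) {
    stop("relationship matrix is numerically singular; ",
         "prune the pedigree (e.g. drop duplicate identical-twin records) ",
         "or set jitter > 0")
  }
  Ainv <- chol2inv(ch)
  dimnames(Ainv) <- dimnames(A)
  resid <- max(abs(A %*% Ainv - diag(nrow(A))))
  if (resid > tol) {
    stop(sprintf("inverse verification failed: max |A Ainv - I| = %.3g > %g",
                 resid, tol))
  }
  Ainv
}

#' Write a kinship matrix to disk
#'
#' @param A relationship matrix with id dimnames.
#' @param path output file.
#' @param format `"matrix"`: TSV with an id header row and id first column;
#'   `"triplet"`: sparse upper-triangle triplets `id_i, id_j, value` (non-zero
#'   entries only).
#' @return `path`, invisibly.
#' @export
write_kinship <- function(A, path, format = c("matrix", "triplet")) {
  format <- match.arg(format)
  if (format == "matrix") {
    df <- data.frame(id = rownames(A), A, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    ut <- which(upper.tri(A, diag = TRUE) & A != 0, arr.ind = TRUE)
    df <- data.frame(
      id_i = rownames(A)[ut[, 1L]],
      id_j = colnames(A)[ut[, 2L]],
      value = A[ut]
    )
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
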