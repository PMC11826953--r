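# Aitchison-geometry primitives for 5-part macronutrient energy compositions.

#' Macronutrient part names
#'
#' Canonical ordering of the five macronutrient energy-composition parts used
#' throughout the package: protein, carbohydrate, saturated fat,
#' monounsaturated fat, polyunsaturated fat.
#'
#' @return Character vector of length 5.
#' @export
macro_parts <- function() {
  c("protein", "carbohydrate", "saturated", "monounsaturated", "polyunsaturated")
}

#' Energy conversion factors (kcal per gram)
#'
#' Atwater-style factors: 4 kcal/g for protein and carbohydrate, 9 kcal/g for
#' each fat class.
#'
#' @return Named numeric vector of length 5.
#' @export
kcal_factors <- function() {
  c(protein = 4, carbohydrate = 4, saturated = 9,
    monounsaturated = 9, polyunsaturated = 9)
}

#' Close a positive vector onto the unit simplex
#'
#' Rescales a strictly positive vector so that its parts sum to 1. Closure is
#' scale invariant: `closure(c * v)` equals `closure(v)` for any `c > 0`.
#'
#' @param v Numeric vector with all entries strictly positive.
#' @return Numeric vector of the same length summing to 1.
#' @export
closure <- function(v) {
  nm <- names(v)
  v <- as.numeric(v)
  if (length(v) < 1 || anyNA(v) || any(v <= 0)) {
    stop("closure() requires a non-empty vector of strictly positive entries")
  }
  stats::setNames(v / sum(v), nm)
}

#' Energy-weighted macronutrient composition from gram intakes
#'
#' Converts daily gram intakes of the five macronutrients into energy shares:
#' each intake is multiplied by its calorie contribution (4 kcal/g for protein
#' and carbohydrate, 9 kcal/g for each fat) and the resulting energy vector is
#' closed so the shares sum to 1.
#'
#' @param grams Numeric vector of length 5 in the [macro_parts()] order
#'   (protein, carbohydrate, saturated, monounsaturated, polyunsaturated),
#'   g/day, all strictly positive.
#' @return Named composition (length-5 numeric, positive, summing to 1).
#' @export
energy_shares <- function(grams) {
  grams <- as.numeric(grams)
  if (length(grams) != 5) stop("energy_shares() expects a 5-part gram vector")
  if (anyNA(grams) || any(grams <= 0)) {
    stop("energy_shares() requires strictly positive gram intakes")
  }
  x <- closure(grams * kcal_factors())
  names(x) <- macro_parts()
  x
}

check_composition <- function(x, tol = 1e-9) {
  nm <- names(x)
  x <- as.numeric(x)
  if (anyNA(x) || any(x <= 0)) stop("composition parts must be strictly positive")
  if (abs(sum(x) - 1) > tol) stop("composition parts must sum to 1")
  stats::setNames(x, nm)
}

#' Additive log-ratio transform and its inverse
#'
#' `alr()` maps a D-part composition to D-1 log-ratios against the last part:
#' `alr_i = log(x_i / x_D)`. `alr_inv()` is the exact inverse (close the
#' exponentiated coordinates with an appended reference 1).
#'
#' @param x Composition (positive, sums to 1).
#' @param z Numeric vector of D-1 alr coordinates.
#' @return `alr()`: numeric vector of length D-1; `alr_inv()`: composition of
#'   length D.
#' @export
alr <- function(x) {
  x <- check_composition(x)
  D <- length(x)
  log(x[-D] / x[D])
}

#' @rdname alr
#' @export
alr_inv <- function(z) {
  z <- as.numeric(z)
  if (anyNA(z) || any(!is.finite(z))) stop("alr coordinates must be finite")
  closure(exp(c(z, 0)))
}

#' Orthonormal balance (sequential binary partition) basis
#'
#' Builds a (D-1) x D contrast matrix of pivot balance coordinates. With
#' `focal = "default"` the parts are taken in their natural order; with a
#' focal part index (or name, for D = 5 compositions) the parts are reordered
#' so the focal part is isolated in the first balance:
#' `z1 = sqrt((D-1)/D) * log(x_focal / gmean(rest))`, with positive z1 meaning
#' the focal part sits above the geometric mean of the rest. Rows are
#' orthonormal and each row's coefficients sum to zero.
#'
#' @param D Number of parts (>= 2).
#' @param focal `"default"`, a part index in 1..D, or (when D = 5) one of
#'   [macro_parts()].
#' @return Matrix with D-1 rows and D columns; attribute `"focal"` records the
#'   focal part index.
#' @export
make_basis <- function(D = 5, focal = "default") {
  if (!is.numeric(D) || length(D) != 1 || D < 2 || D != round(D)) {
    stop("D must be an integer >= 2")
  }
  if (identical(focal, "default")) {
    ord <- seq_len(D)
  } else {
    if (is.character(focal)) {
      if (D != 5) stop("named focal parts are only defined for D = 5")
      focal <- match(focal, macro_parts())
    }
    focal <- as.numeric(focal)
    if (is.na(focal) || focal < 1 || focal > D || focal != round(focal)) {
      stop("invalid focal part")
    }
    ord <- c(focal, setdiff(seq_len(D), focal))
  }
  B <- matrix(0, nrow = D - 1, ncol = D)
  for (i in seq_len(D - 1)) {
    r <- D - i                      # number of parts after the pivot
    a <- sqrt(r / (r + 1))
    B[i, ord[i]] <- a
    B[i, ord[(i + 1):D]] <- -a / r
  }
  attr(B, "focal") <- ord[1]
  B
}

#' Isometric log-ratio transform and its inverse
#'
#' `ilr()` computes balance coordinates `z = B %*% log(x)` for an orthonormal
#' basis `B` (rows sum to zero, so the closure constant cancels). `ilr_inv()`
#' maps coordinates back onto the simplex via `closure(exp(t(B) %*% z))`.
#' Euclidean distances between ilr vectors do not depend on the basis choice.
#'
#' @param x Composition, or a matrix/data.frame of compositions (rows).
#' @param z Numeric vector of D-1 balance coordinates.
#' @param basis Basis matrix from [make_basis()].
#' @return `ilr()`: numeric vector (or matrix, one row per input row) of
#'   balance coordinates; `ilr_inv()`: a composition.
#' @export
ilr <- function(x, basis = make_basis(if (is.matrix(x) || is.data.frame(x)) ncol(x) else length(x))) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.matrix(x)) {
    if (ncol(x) != ncol(basis)) stop("composition/basis dimension mismatch")
    apply(x, 1, check_composition)
    return(log(x) %*% t(basis))
  }
  x <- check_composition(x)
  if (length(x) != ncol(basis)) stop("composition/basis dimension mismatch")
  as.numeric(basis %*% log(x))
}

#' @rdname ilr
#' @export
ilr_inv <- function(z, basis = make_basis(length(z) + 1)) {
  z <- as.numeric(z)
  if (length(z) != nrow(basis)) stop("coordinate/basis dimension mismatch")
  closure(exp(as.numeric(t(basis) %*% z)))
}

#' Variation matrix of a compositional data set
#'
#' Entry (i, j) is the sample variance (n-1 denominator) of `log(x_i / x_j)`
#' across rows. Values near zero indicate two parts that are nearly
#' proportional across the sample; the matrix is symmetric with zero diagonal.
#'
#' @param data Matrix or data.frame of compositions, one row per sample,
#'   at least 2 rows.
#' @return D x D numeric matrix.
#' @export
variation_matrix <- function(data) {
  if (is.data.frame(data)) data <- as.matrix(data)
  if (!is.matrix(data) || nrow(data) < 2) {
    stop("variation_matrix() needs at least 2 samples")
  }
  L <- log(data)
  D <- ncol(L)
  T <- matrix(0, D, D, dimnames = list(colnames(data), colnames(data)))
  for (i in seq_len(D - 1)) {
    for (j in (i + 1):D) {
      T[i, j] <- T[j, i] <- stats::var(L[, i] - L[, j])
    }
  }
  T
}

#' Compositional (geometric) mean
#'
#' The closed vector of componentwise geometric means -- the simplex analogue
#' of the arithmetic mean. It equals `ilr_inv` of the arithmetic mean of the
#' ilr coordinates under any orthonormal basis.
#'
#' @param data Matrix or data.frame of compositions, one row per sample.
#' @return Composition of length D.
#' @export
compositional_mean <- function(data) {
  if (is.data.frame(data)) data <- as.matrix(data)
  if (is.vector(data)) data <- matrix(data, nrow = 1)
  if (nrow(data) < 1) stop("compositional_mean() needs at least 1 sample")
  out <- closure(exp(colMeans(log(data))))
  names(out) <- colnames(data)
  out
}

#' Reallocation specification
#'
#' Describes a displacement of a fixed fraction of total energy in the
#' composition: proportional reallocation (`"take"` removes `delta` from the
#' focal part and distributes it over the others in proportion to their
#' current shares; `"add"` does the reverse) or a one-to-one `"pairwise"`
#' substitution from a donor part to a recipient part.
#'
#' @param focal Focal part (name or index) for add/take modes, or the donor
#'   for pairwise mode.
#' @param delta Magnitude of the displaced energy fraction (default 0.06,
#'   i.e. 6% of total energy).
#' @param mode One of `"add"`, `"take"`, `"pairwise"`.
#' @param to Recipient part, pairwise mode only.
#' @return An object of class `realloc_spec`.
#' @export
realloc_spec <- function(focal, delta = 0.06, mode = c("add", "take", "pairwise"),
                         to = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(delta) || length(delta) != 1 || delta < 0 || delta >= 1) {
    stop("delta must be a fraction in [0, 1)")
  }
  if (mode == "pairwise" && is.null(to)) stop("pairwise mode needs a 'to' part")
  structure(list(focal = focal, delta = delta, mode = mode, to = to),
            class = "realloc_spec")
}

part_index <- function(part, x) {
  if (is.character(part)) {
    i <- match(part, names(x) %||% macro_parts())
  } else {
    i <- as.integer(part)
  }
  if (is.na(i) || i < 1 || i > length(x)) stop("unknown composition part: ", part)
  i
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Proportionally reallocate a fraction of energy to or from one part
#'
#' Add mode moves `delta` of total energy into the focal part, removing it
#' from every other part in proportion to their current shares (each other
#' part is scaled by `(1 - x_f - delta) / (1 - x_f)`); take mode is the same
#' displacement with opposite sign. The result is a valid composition.
#'
#' @param x Composition.
#' @param spec A [realloc_spec()] with mode `"add"` or `"take"` (pairwise
#'   specs are dispatched to [substitute_pairwise()]).
#' @return Reallocated composition.
#' @export
reallocate <- function(x, spec) {
  x <- check_composition(x)
  stopifnot(inherits(spec, "realloc_spec"))
  if (spec$mode == "pairwise") {
    return(substitute_pairwise(x, spec$focal, spec$to, spec$delta))
  }
  f <- part_index(spec$focal, x)
  d <- if (spec$mode == "add") spec$delta else -spec$delta
  xf_new <- x[f] + d
  if (xf_new <= 0 || xf_new >= 1) {
    stop(sprintf(
      "infeasible reallocation: displacing %.3f of energy %s part %d drives a share out of (0, 1); the displacement cap is the smallest feasible share (default cap 6%%)",
      spec$delta, if (d > 0) "into" else "out of", f))
  }
  scale <- (1 - xf_new) / (1 - x[f])
  out <- x * scale
  out[f] <- xf_new
  if (any(out <= 0)) {
    stop("infeasible reallocation: a non-focal share is driven to zero (6% cap rule)")
  }
  out / sum(out)
}

#' One-to-one isotemporal substitution between two parts
#'
#' Moves `delta` of total energy from the donor part to the recipient part;
#' every other part is left byte-identical and the total is preserved exactly.
#' With `from == to` (or `delta = 0`) the composition is returned unchanged.
#'
#' @param x Composition.
#' @param from Donor part (name or index).
#' @param to Recipient part.
#' @param delta Displaced energy fraction (default 0.06).
#' @return Substituted composition.
#' @export
substitute_pairwise <- function(x, from, to, delta = 0.06) {
  x <- check_composition(x)
  i <- part_index(from, x)
  j <- part_index(to, x)
  if (i == j || delta == 0) return(x)
  if (x[i] - delta <= 0) {
    stop(sprintf(
      "infeasible substitution: donor share %.4f cannot give up %.3f (6%% cap rule)",
      x[i], delta))
  }
  x[i] <- x[i] - delta
  x[j] <- x[j] + delta
  x
}
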