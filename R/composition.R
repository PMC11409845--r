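#' Default behavior part names
#'
#' The ordered parts of the 24-h movement-behavior composition. The order is
#' meaningful: it defines the sequential binary partition, with the first
#' part leading the first ilr coordinate.
#'
#' @return Character vector `c("mvpa", "lpa", "inactivity", "sleep")`.
#' @export
mb_behaviors <- function() c("mvpa", "lpa", "inactivity", "sleep")

## coerce vector or matrix input to an n x D matrix, keeping part names
as_part_matrix <- function(x, parts = NULL) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L, dimnames = list(NULL, names(x)))
  if (!is.null(parts)) {
    if (!is.null(colnames(x)) && all(parts %in% colnames(x))) x <- x[, parts, drop = FALSE]
    else colnames(x) <- parts
  }
  storage.mode(x) <- "double"
  x
}

#' Close a composition to a fixed total
#'
#' Rescales non-negative parts proportionally so that each row sums to
#' `total` (1440 min for a 24-h day). Closure is the identity on relative
#' information: all log-ratio quantities are unchanged.
#'
#' @param x Numeric vector of parts, or a matrix/data.frame with one
#'   composition per row.
#' @param total Target row total in the same units as `x` (default 1440).
#' @return Object of the same shape as `x` with rows summing to `total`.
#' @examples
#' close_composition(c(mvpa = 34, lpa = 171.5, inactivity = 243.5, sleep = 271))
#' @export
close_composition <- function(x, total = 1440) {
  vec <- is.null(dim(x))
  m <- as_part_matrix(x)
  if (any(m < 0)) stop("parts must be non-negative")
  s <- rowSums(m)
  if (any(s <= 0)) stop("degenerate composition: all parts zero")
  out <- m * (total / s)
  if (vec) setNames(drop(out), colnames(m)) else out
}

#' Multiplicative replacement of zero parts
#'
#' Replaces exact zeros by a small positive floor and multiplicatively
#' shrinks the non-zero parts so each row total is preserved. This is the
#' standard multiplicative replacement strategy for count/duration
#' compositions: ratios between unaffected parts are untouched.
#'
#' @param x Numeric vector or matrix of non-negative parts.
#' @param floor Replacement value for zeros, in the units of `x`
#'   (default 1 minute). Must be positive.
#' @return Strictly positive parts with unchanged row totals.
#' @examples
#' zero_replace(c(0, 400, 500, 540))
#' @export
zero_replace <- function(x, floor = 1) {
  if (floor <= 0) stop("'floor' must be positive")
  vec <- is.null(dim(x))
  m <- as_part_matrix(x)
  if (any(m < 0)) stop("parts must be non-negative")
  out <- m
  for (i in seq_len(nrow(m))) {
    z <- m[i, ] == 0
    if (!any(z)) next
    tot <- sum(m[i, ])
    repl <- floor * sum(z)
    if (repl >= tot) stop("floor times number of zeros exceeds the total")
    out[i, z] <- floor
    out[i, !z] <- m[i, !z] * (tot - repl) / tot
  }
  if (vec) setNames(drop(out), colnames(m)) else out
}

#' Sequential-binary-partition ilr basis
#'
#' Constructs the (D-1) x D contrast matrix of the pivot (sequential binary
#' partition) ilr coordinates for an ordered set of parts: coordinate k
#' contrasts part k against the geometric mean of parts k+1..D,
#' \deqn{ilr_k = \sqrt{(D-k)/(D-k+1)} \, \ln\!\big(x_k / g(x_{k+1..D})\big).}
#' For the behavior order (MVPA, LPA, inactivity, sleep) the first
#' coordinate is \eqn{\sqrt{3/4}\,\ln(\mathrm{MVPA}/\sqrt[3]{\mathrm{LPA}
#' \cdot \mathrm{Inactivity} \cdot \mathrm{Sleep}})}, the relative share of
#' MVPA against all remaining behaviors.
#'
#' `lead` rotates the composition so a chosen behavior heads the partition
#' (the remaining parts keep their cyclic order). Only the first coordinate
#' changes interpretation; all rotations span the same coordinate subspace,
#' so fitted values, distances and predictions are rotation-invariant.
#'
#' @param parts Ordered character vector of part names.
#' @param lead Name of the part to place first (default: first of `parts`).
#' @return An object of class `"ilr_basis"`: list with `parts` (rotated
#'   order), `lead`, and `V`, the (D-1) x D contrast matrix with rows
#'   orthonormal and summing to zero.
#' @examples
#' ilr_basis()                      # MVPA-first
#' ilr_basis(lead = "sleep")        # sleep relative to remaining behaviors
#' @export
ilr_basis <- function(parts = mb_behaviors(), lead = parts[1]) {
  D <- length(parts)
  if (D < 2) stop("need at least two parts")
  if (anyDuplicated(parts)) stop("duplicate part names")
  i <- match(lead, parts)
  if (is.na(i)) stop("unknown behavior name: ", lead)
  ord <- parts[((seq_len(D) + i - 2L) %% D) + 1L]  # cyclic rotation, lead first
  V <- matrix(0, D - 1L, D, dimnames = list(paste0("ilr", seq_len(D - 1L)), ord))
  for (k in seq_len(D - 1L)) {
    a <- sqrt((D - k) / (D - k + 1))
    V[k, k] <- a
    V[k, (k + 1L):D] <- -a / (D - k)
  }
  structure(list(parts = ord, lead = lead, V = V), class = "ilr_basis")
}

#' Rotate an ilr basis to a new leading behavior
#'
#' @param basis An `"ilr_basis"` object (or an ordered character vector of
#'   part names).
#' @param lead Behavior to move to the front of the partition.
#' @return A new `"ilr_basis"`.
#' @export
rotate_basis <- function(basis, lead) {
  parts <- if (inherits(basis, "ilr_basis")) sort_original_order(basis) else basis
  ilr_basis(parts, lead)
}

## recover a canonical part order from a (possibly rotated) basis:
## rotations are cyclic, so any rotation of the stored order is equivalent.
sort_original_order <- function(basis) basis$parts

#' @export
print.ilr_basis <- function(x, ...) {
  cat("Sequential-binary-partition ilr basis (", length(x$parts), " parts)\n", sep = "")
  cat("ilr1 lead:", x$lead, "\n")
  cat("part order:", paste(x$parts, collapse = " > "), "\n")
  print(round(x$V, 4))
  invisible(x)
}

#' Isometric log-ratio coordinates
#'
#' Maps strictly positive compositions to their D-1 ilr coordinates under a
#' sequential-binary-partition basis. Coordinates are scale-invariant:
#' minutes and proportions give identical values.
#'
#' @param x Composition vector, or matrix with one composition per row.
#'   Columns are matched to `basis$parts` by name when named.
#' @param basis An [ilr_basis]; default MVPA-first over [mb_behaviors()].
#' @return Numeric vector of length D-1, or an n x (D-1) matrix.
#' @examples
#' ilr_transform(c(mvpa = 68, lpa = 343, inactivity = 487, sleep = 542))
#' @export
ilr_transform <- function(x, basis = ilr_basis()) {
  vec <- is.null(dim(x))
  m <- as_part_matrix(x, basis$parts)
  if (any(!is.finite(m)) || any(m <= 0))
    stop("composition must be strictly positive; use zero_replace() first")
  out <- log(m) %*% t(basis$V)
  if (vec) setNames(drop(out), rownames(basis$V)) else out
}

#' Inverse ilr transform
#'
#' Maps ilr coordinates back to a closed composition.
#'
#' @param y Numeric vector of D-1 coordinates, or matrix with one
#'   coordinate row per sample.
#' @param basis The [ilr_basis] that produced the coordinates.
#' @param total Row total of the returned composition (default 1440).
#' @return Composition (vector or matrix) closed to `total`, columns in
#'   `basis$parts` order.
#' @export
ilr_inverse <- function(y, basis = ilr_basis(), total = 1440) {
  vec <- is.null(dim(y))
  m <- if (vec) matrix(y, nrow = 1L) else as.matrix(y)
  if (ncol(m) != nrow(basis$V)) stop("coordinate dimension does not match basis")
  logx <- m %*% basis$V            # clr representation (sum-zero rows)
  comp <- close_composition(exp(logx), total = total)
  colnames(comp) <- basis$parts
  if (vec) setNames(drop(comp), basis$parts) else comp
}

#' Centered log-ratio transform
#'
#' @param x Strictly positive composition vector or matrix.
#' @return clr coordinates (log part minus mean log); rows sum to zero.
#' @export
clr_transform <- function(x) {
  vec <- is.null(dim(x))
  m <- as_part_matrix(x)
  if (any(m <= 0)) stop("composition must be strictly positive")
  lx <- log(m)
  out <- lx - rowMeans(lx)
  if (vec) setNames(drop(out), colnames(m)) else out
}

#' Compositional mean
#'
#' The closed component-wise geometric mean: the center of a compositional
#' sample in the Aitchison geometry. This is the reference point at which
#' isotemporal substitutions are evaluated.
#'
#' @param x Matrix or data.frame of compositions (one per row), strictly
#'   positive.
#' @param total Closure total (default 1440).
#' @return Named numeric vector closed to `total`.
#' @examples
#' comps <- rbind(c(64, 343, 487, 546), c(72.25, 343, 487, 538.1))
#' compositional_mean(comps)
#' @export
compositional_mean <- function(x, total = 1440) {
  m <- as_part_matrix(x)
  if (nrow(m) == 0L) stop("empty sample")
  if (any(m <= 0)) stop("composition must be strictly positive")
  g <- exp(colMeans(log(m)))
  close_composition(setNames(g, colnames(m)), total = total)
}

#' Aitchison distance between two compositions
#'
#' Euclidean distance between clr images; the natural metric of the
#' simplex. Identical in any ilr basis (isometry) and invariant to scaling
#' of either composition.
#'
#' @param a,b Strictly positive composition vectors over the same parts.
#' @return Non-negative scalar; 0 iff `a` and `b` are proportional.
#' @export
aitchison_dist <- function(a, b) {
  da <- clr_transform(a); db <- clr_transform(b)
  if (length(da) != length(db)) stop("compositions have different lengths")
  sqrt(sum((da - db)^2))
}
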