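#' Standard generator bases for supported matrix Lie groups
#'
#' Builds the fixed generator basis of one of the supported matrix groups:
#' `so2` (planar rotations, 2x2), `se2` (planar rigid motions, 3x3
#' homogeneous), `sim2` (planar similarities: rigid motions plus dilation,
#' 3x3 homogeneous) and `se3` (spatial rigid motions, 4x4 homogeneous).
#' The basis is ordered rotations first, then translations, then (for
#' `sim2`) the dilation.  Generator entries are exact integers so that
#' closed-form checks are unambiguous.
#'
#' Translations and dilations become linear maps in homogeneous
#' coordinates: points are columns `(x, y, 1)` (or `(x, y, z, 1)` for
#' `se3`).  The `sim2` dilation generator is the identity on the spatial
#' block and zero on the homogeneous row, the standard similarity-group
#' convention.
#'
#' @param name Group name, one of `"so2"`, `"se2"`, `"sim2"`, `"se3"`.
#' @return An object of class `"lie_group"`: a list with elements `name`,
#'   `generators` (named list of square matrices), `rep_dim` (matrix size)
#'   and `dim` (number of generators).
#' @examples
#' g <- lie_group("se2")
#' g$dim          # 3: one rotation, two translations
#' lie_exp(g, c(0, 1, 2))   # pure translation by (1, 2)
#' @export
lie_group <- function(name = c("so2", "se2", "sim2", "se3")) {
  if (length(name) != 1L || !name %in% c("so2", "se2", "sim2", "se3"))
    stop("unsupported group name: ", paste(name, collapse = ", "),
         " (supported: so2, se2, sim2, se3)")
  E <- function(d, i, j) { m <- matrix(0, d, d); m[i, j] <- 1; m }
  gens <- switch(name,
    so2 = list(so2_rot = matrix(c(0, 1, -1, 0), 2, 2)),
    se2 = list(
      se2_rot = E(3, 2, 1) - E(3, 1, 2),
      se2_tx  = E(3, 1, 3),
      se2_ty  = E(3, 2, 3)),
    sim2 = list(
      sim2_rot = E(3, 2, 1) - E(3, 1, 2),
      sim2_tx  = E(3, 1, 3),
      sim2_ty  = E(3, 2, 3),
      sim2_dil = E(3, 1, 1) + E(3, 2, 2)),
    se3 = list(
      se3_rx = E(4, 3, 2) - E(4, 2, 3),
      se3_ry = E(4, 1, 3) - E(4, 3, 1),
      se3_rz = E(4, 2, 1) - E(4, 1, 2),
      se3_tx = E(4, 1, 4),
      se3_ty = E(4, 2, 4),
      se3_tz = E(4, 3, 4)))
  structure(
    list(name = name, generators = gens,
         rep_dim = nrow(gens[[1L]]), dim = length(gens)),
    class = "lie_group")
}

#' @export
print.lie_group <- function(x, ...) {
  cat(sprintf("<lie_group> %s: %d generator%s, %dx%d representation\n",
              x$name, x$dim, if (x$dim > 1) "s" else "",
              x$rep_dim, x$rep_dim))
  cat("  basis:", paste(names(x$generators), collapse = ", "), "\n")
  invisible(x)
}

#' Group element wrapper
#'
#' A group element is an invertible square matrix tagged with the name of
#' the group it belongs to; composition and action check the tag.
#'
#' @param matrix Square numeric matrix.
#' @param group Group label (a string, e.g. `"se2"`).
#' @return An object of class `"lie_element"`.
#' @export
lie_element <- function(matrix, group) {
  if (!is.matrix(matrix) || nrow(matrix) != ncol(matrix))
    stop("group element must be a square matrix")
  if (!all(is.finite(matrix))) stop("group element has non-finite entries")
  structure(list(matrix = matrix, group = group), class = "lie_element")
}

#' @export
print.lie_element <- function(x, ...) {
  cat(sprintf("<lie_element> %s (%dx%d)\n", x$group,
              nrow(x$matrix), ncol(x$matrix)))
  print(x$matrix)
  invisible(x)
}

# Sum of coefficient-weighted generators; validates the coefficient vector.
algebra_element <- function(spec, coeffs) {
  stopifnot(inherits(spec, "lie_group"))
  if (length(coeffs) != spec$dim)
    stop(sprintf("expected %d coefficients for %s, got %d",
                 spec$dim, spec$name, length(coeffs)))
  if (!all(is.finite(coeffs))) stop("non-finite generator coefficients")
  A <- matrix(0, spec$rep_dim, spec$rep_dim)
  for (k in seq_len(spec$dim)) A <- A + coeffs[k] * spec$generators[[k]]
  A
}

#' Exponential map from algebra coefficients to a group element
#'
#' Computes `exp(sum_k theta_k T_k)` for the generator basis of `spec`.
#' The zero vector maps to the exact identity; otherwise the matrix
#' exponential is evaluated by scaling-and-squaring with Pade
#' approximation ([Matrix::expm()]), accurate to better than 1e-10 in max
#' norm on the supported bases.
#'
#' @param spec A [lie_group()].
#' @param coeffs Numeric vector of algebra coefficients, one per generator.
#' @return A [lie_element()].
#' @export
lie_exp <- function(spec, coeffs) {
  A <- algebra_element(spec, coeffs)
  m <- if (all(A == 0)) diag(spec$rep_dim)
       else as.matrix(Matrix::expm(A))
  lie_element(m, spec$name)
}

# x^n for square matrices by binary exponentiation (n >= 0 integer).
mat_pow <- function(x, n) {
  out <- diag(nrow(x))
  base <- x
  while (n > 0) {
    if (n %% 2 == 1) out <- out %*% base
    base <- base %*% base
    n <- n %/% 2
  }
  out
}

#' Recursive limit-product approximation of the exponential map
#'
#' Evaluates the n-fold product `(I + (1/n) sum_k theta_k T_k)^n`, the
#' finite-n truncation of the limit that defines the exponential map as a
#' recursion of infinitesimal transformations.  Its max-norm error against
#' [lie_exp()] decreases as O(1/n).
#'
#' @inheritParams lie_exp
#' @param n Number of factors (positive integer).
#' @return A [lie_element()].
#' @examples
#' g <- lie_group("so2")
#' e1 <- lie_limit_product(g, pi / 2, 100)$matrix
#' e2 <- lie_exp(g, pi / 2)$matrix
#' max(abs(e1 - e2))   # ~ first-order in 1/n
#' @export
lie_limit_product <- function(spec, coeffs, n) {
  if (length(n) != 1L || !is.finite(n) || n < 1)
    stop("n must be a positive integer")
  n <- as.integer(n)
  A <- algebra_element(spec, coeffs)
  lie_element(mat_pow(diag(spec$rep_dim) + A / n, n), spec$name)
}

#' Compose and invert group elements
#'
#' `lie_compose(a, b)` applies `b` first, then `a` (matrix product
#' `a$matrix %*% b$matrix` acting on column vectors), the convention of a
#' product of exponentials read right to left.  `lie_inverse(a)` returns
#' the inverse element.
#'
#' @param a,b Objects of class `"lie_element"` from the same group.
#' @return A [lie_element()].
#' @export
lie_compose <- function(a, b) {
  stopifnot(inherits(a, "lie_element"), inherits(b, "lie_element"))
  if (!identical(a$group, b$group))
    stop(sprintf("cannot compose elements of different groups (%s vs %s)",
                 a$group, b$group))
  if (nrow(a$matrix) != nrow(b$matrix))
    stop("cannot compose elements of different matrix size")
  lie_element(a$matrix %*% b$matrix, a$group)
}

#' @rdname lie_compose
#' @export
lie_inverse <- function(a) {
  stopifnot(inherits(a, "lie_element"))
  rc <- rcond(a$matrix)
  if (!is.finite(rc) || rc < .Machine$double.eps)
    stop("group element matrix is numerically singular")
  lie_element(solve(a$matrix), a$group)
}

#' Infinitesimal action of a generator on a point
#'
#' First-order action `x + eps * T x` of a perturbation `1 + eps T` around
#' the identity.  Points of dimension `nrow(T) - 1` are lifted to
#' homogeneous coordinates (trailing 1) and projected back.  The
#' difference from the exact action `exp(eps T) x` is O(eps^2).
#'
#' @param eps Small real parameter.
#' @param T Generator matrix (square).
#' @param x Numeric point/state vector.
#' @return Numeric vector, same length as `x`.
#' @export
infinitesimal_action <- function(eps, T, x) {
  d <- nrow(T)
  if (length(x) == d) {
    as.numeric(x + eps * (T %*% x))
  } else if (length(x) == d - 1L) {
    xh <- c(x, 1)
    as.numeric((xh + eps * (T %*% xh))[seq_len(d - 1L)])
  } else {
    stop(sprintf("point of length %d incompatible with %dx%d generator",
                 length(x), d, d))
  }
}

#' Apply a group element to a cloud of points
#'
#' Points are stored as columns of `points`.  Under the `"vector"`
#' representation the point dimension must equal the matrix size; under
#' `"homogeneous"` the points have one dimension less, are lifted with a
#' trailing 1, transformed, and projected back.  The action is a left
#' action: `lie_act(lie_compose(a, b), P)` equals
#' `lie_act(a, lie_act(b, P))`.
#'
#' @param g A [lie_element()].
#' @param points Numeric matrix, one point per column (a vector is taken
#'   as a single point).
#' @param representation `"vector"` or `"homogeneous"`.
#' @return Matrix of transformed points, same shape as `points`.
#' @export
lie_act <- function(g, points, representation = c("vector", "homogeneous")) {
  stopifnot(inherits(g, "lie_element"))
  representation <- match.arg(representation)
  if (!is.matrix(points)) points <- matrix(points, ncol = 1L)
  d <- nrow(g$matrix)
  if (representation == "vector") {
    if (nrow(points) != d)
      stop(sprintf("vector representation needs %d-dimensional points", d))
    g$matrix %*% points
  } else {
    if (nrow(points) != d - 1L)
      stop(sprintf("homogeneous representation needs %d-dimensional points",
                   d - 1L))
    ph <- rbind(points, 1)
    out <- g$matrix %*% ph
    out[seq_len(d - 1L), , drop = FALSE]
  }
}

#' Plain-text serialization of generators and group elements
#'
#' Matrices are written whitespace-delimited, row-major, preceded by a
#' one-line header `# lie <group> <nrow> <ncol>`.  Used by the CLI audit
#' commands.
#'
#' @param x A [lie_element()] or a plain matrix.
#' @param path Output file path.
#' @param group Group label when `x` is a plain matrix.
#' @return `write_lie_matrix` returns `path` invisibly; `read_lie_matrix`
#'   returns a [lie_element()].
#' @export
write_lie_matrix <- function(x, path, group = NULL) {
  if (inherits(x, "lie_element")) {
    m <- x$matrix; group <- x$group
  } else {
    m <- x
    if (is.null(group)) stop("group label required for a plain matrix")
  }
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# lie %s %d %d", group, nrow(m), ncol(m)), con)
  writeLines(apply(m, 1L, function(r) paste(sprintf("%.17g", r),
                                            collapse = " ")), con)
  invisible(path)
}

#' @rdname write_lie_matrix
#' @export
read_lie_matrix <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  if (length(hdr) != 5L || hdr[1L] != "#" || hdr[2L] != "lie")
    stop("not a lie matrix file (bad header): ", path)
  nr <- as.integer(hdr[4L]); nc <- as.integer(hdr[5L])
  vals <- scan(text = paste(lines[-1L], collapse = "\n"), quiet = TRUE)
  if (length(vals) != nr * nc) stop("matrix body size mismatch in ", path)
  lie_element(matrix(vals, nr, nc, byrow = TRUE), hdr[3L])
}
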