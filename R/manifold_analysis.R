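#' Conserved-quantity check along a trajectory
#'
#' Differentiates a scalar function of state along a trajectory by
#' central finite differences and reports the maximum absolute derivative
#' per unit time.  A satisfied static tracking constraint turns each
#' readout coordinate into such a conserved quantity.
#'
#' @param traj A `"trajectory"` (or `"wtne_run"`).
#' @param func Scalar function of the state vector (or an integer state
#'   index, meaning that coordinate).
#' @param tol Conservation tolerance (per unit time).
#' @param label Name for the report.
#' @return Object of class `"conserved_check"`: list with `label`,
#'   `max_abs_derivative`, `verdict`.
#' @export
conserved_residual <- function(traj, func, tol = 1e-4,
                               label = deparse(substitute(func))) {
  if (inherits(traj, "wtne_run")) traj <- traj$trajectory
  if (length(traj$times) < 3L)
    stop("need at least 3 time points for a central difference")
  if (is.numeric(func) && length(func) == 1L) {
    idx <- as.integer(func)
    label <- sprintf("state[%d]", idx)
    vals <- traj$states[, idx]
  } else {
    vals <- apply(traj$states, 1L, func)
  }
  dt <- traj$times[2L] - traj$times[1L]
  n <- length(vals)
  deriv <- (vals[3:n] - vals[1:(n - 2L)]) / (2 * dt)
  m <- max(abs(deriv))
  structure(list(label = label, max_abs_derivative = m,
                 verdict = if (m < tol) "conserved" else "not_conserved",
                 tol = tol),
            class = "conserved_check")
}

#' @export
print.conserved_check <- function(x, ...) {
  cat(sprintf("<conserved_check> %s: max |d/dt| = %.3g -> %s (tol %.3g)\n",
              x$label, x$max_abs_derivative, x$verdict, x$tol))
  invisible(x)
}

#' Static tracking verdict: conserved readout and small terminal error
#'
#' For a static-input run, checks that every post-transient readout
#' coordinate is conserved (central-difference derivative below `tol`)
#' and that the terminal error norm is below `tol_rel` times the input
#' norm.
#'
#' @param run A `"wtne_run"` from a static-input integration.
#' @param agent The [agent_system()] that produced it.
#' @param input_frame The static input frame.
#' @param tol Conservation tolerance per coordinate (per unit time).
#' @param tol_rel Relative terminal error tolerance.
#' @return List with `verdict`, `max_derivative` (worst coordinate),
#'   `terminal_error_rel`, `per_coordinate` derivatives.
#' @export
static_tracking_check <- function(run, agent, input_frame, tol = 1e-4,
                                  tol_rel = 1e-3) {
  u <- readout_block(run, agent)
  j0 <- transient_index(run$trace)
  nt <- nrow(u)
  if (nt - j0 < 3L) stop("too few post-transient samples")
  dt <- run$trajectory$times[2L] - run$trajectory$times[1L]
  uu <- u[j0:nt, , drop = FALSE]
  m <- nrow(uu)
  dudt <- (uu[3:m, , drop = FALSE] - uu[1:(m - 2L), , drop = FALSE]) /
    (2 * dt)
  per_coord <- apply(abs(dudt), 2L, max)
  term_rel <- sqrt(sum(run$trace$errors[nt, ]^2)) /
    sqrt(sum(as.numeric(input_frame)^2))
  list(verdict = all(per_coord < tol) && term_rel < tol_rel,
       max_derivative = max(per_coord),
       terminal_error_rel = term_rel,
       per_coordinate = per_coord)
}

#' Effective dimensionality of a point set
#'
#' Mean-centers the rows, takes the principal-component variance
#' spectrum, and reports the smallest number of components whose variance
#' fractions sum to at least `variance_threshold`, together with the
#' participation ratio `(sum lambda)^2 / sum lambda^2`.  Data whose total
#' variance is negligible relative to their magnitude (ratio below
#' `var_floor`, i.e. RMS excursion under ~0.003% of the signal) are
#' reported as dimension 0 with an empty spectrum — the
#' constant-trajectory case, robust to the residual drift of an
#' exponentially converged simulation.
#'
#' @param points Time x d matrix (rows are observations).
#' @param variance_threshold Fraction of variance to capture, in (0, 1].
#' @param var_floor Relative total-variance floor below which the data
#'   count as constant.
#' @return Object of class `"manifold_report"`: list with
#'   `dim_estimate`, `variance_spectrum` (sorted fractions),
#'   `participation_ratio`, `total_variance`, `threshold`.
#' @export
effective_dimension <- function(points, variance_threshold = 0.99,
                                var_floor = 1e-9) {
  if (!is.matrix(points)) points <- as.matrix(points)
  if (nrow(points) < 2L) stop("need at least 2 rows")
  if (variance_threshold <= 0 || variance_threshold > 1)
    stop("variance_threshold must lie in (0, 1]")
  ctr <- scale(points, center = TRUE, scale = FALSE)
  total_var <- sum(ctr^2) / (nrow(points) - 1L)
  msq <- mean(rowSums(points^2))
  if (total_var <= var_floor * max(msq, .Machine$double.xmin)) {
    return(structure(list(dim_estimate = 0L,
                          variance_spectrum = numeric(0),
                          participation_ratio = 0,
                          total_variance = total_var,
                          threshold = variance_threshold),
                     class = "manifold_report"))
  }
  ev <- svd(ctr, nu = 0, nv = 0)$d^2
  ev <- ev[ev > 0]
  frac <- ev / sum(ev)
  structure(list(
    dim_estimate = as.integer(which(cumsum(frac) >=
                                      variance_threshold - 1e-12)[1L]),
    variance_spectrum = frac,
    participation_ratio = sum(ev)^2 / sum(ev^2),
    total_variance = total_var,
    threshold = variance_threshold),
    class = "manifold_report")
}

#' @export
print.manifold_report <- function(x, ...) {
  cat(sprintf(
    "<manifold_report> dim %d at %.2f variance; participation ratio %.2f\n",
    x$dim_estimate, x$threshold, x$participation_ratio))
  invisible(x)
}

#' Bound on dimension gained from a moving latent
#'
#' A trajectory tracking a world with an M-dimensional latent can gain
#' at most M extra manifold dimensions over its static-input dimension.
#' The verdict allows an integer `slack` (default 1) for threshold
#' effects at the variance cut.
#'
#' @param static_report,dynamic_report `"manifold_report"`s from the
#'   same agent/readout subspace under static and moving inputs.
#' @param latent_dim Latent dimension M of the world model.
#' @param slack Integer slack.
#' @return List with `verdict`, `bound`, `dynamic_dim`.
#' @export
dimension_gain_check <- function(static_report, dynamic_report,
                                 latent_dim, slack = 1) {
  bound <- static_report$dim_estimate + latent_dim + slack
  list(verdict = dynamic_report$dim_estimate <= bound,
       bound = bound, dynamic_dim = dynamic_report$dim_estimate)
}

#' Coarse-graining levels and constraint hierarchies
#'
#' A coarse-graining level maps the fine state to a lower-dimensional
#' summary `y = G(x)` and imposes a constraint `C(y) = 0` on it; a
#' hierarchy is an ordered list of levels (coarsest first) defining
#' nested manifolds `M_i = { x in M_{i-1} : C_i(G_i(x)) = 0 }`.
#' `G` and `C` may be functions or matrices (a matrix `C` means the
#' linear residual `C y`).
#'
#' @param G Coarse-graining map: function of the state, or a matrix.
#' @param C Constraint map: function of the coarse vector (returning a
#'   residual vector), or a matrix.
#' @param label Level name.
#' @return `coarse_grain_level()` returns a `"coarse_grain_level"`;
#'   `constraint_hierarchy()` a `"constraint_hierarchy"`.
#' @export
coarse_grain_level <- function(G, C, label = "level") {
  Gf <- if (is.matrix(G)) { Gm <- G; function(x) as.numeric(Gm %*% x) }
        else G
  Cf <- if (is.matrix(C)) { Cm <- C; function(y) as.numeric(Cm %*% y) }
        else C
  structure(list(G = Gf, C = Cf, label = label),
            class = "coarse_grain_level")
}

#' @rdname coarse_grain_level
#' @param ... Levels, coarsest first (or a single list of levels).
#' @export
constraint_hierarchy <- function(...) {
  levels <- list(...)
  if (length(levels) == 1L && !inherits(levels[[1L]], "coarse_grain_level"))
    levels <- levels[[1L]]
  if (!all(vapply(levels, inherits, TRUE, "coarse_grain_level")))
    stop("all levels must be coarse_grain_level objects")
  structure(list(levels = levels), class = "constraint_hierarchy")
}

#' @rdname coarse_grain_level
#' @param level A `"coarse_grain_level"`.
#' @param x Fine-grained state vector.
#' @export
coarse_grain <- function(level, x) level$G(as.numeric(x))

#' @rdname coarse_grain_level
#' @param y Coarse vector.
#' @return `constraint_residual()` returns the Euclidean norm of the
#'   constraint residual (zero iff satisfied).
#' @export
constraint_residual <- function(level, y) sqrt(sum(level$C(y)^2))

#' Recursive membership in the nested manifolds
#'
#' Level i is satisfied only if all levels up to i have constraint
#' residual below `tol` — the recursive definition of the nested
#' manifolds, which forces failure to propagate downward.
#'
#' @param hierarchy A [constraint_hierarchy()].
#' @param x State vector.
#' @param tol Residual tolerance.
#' @return Logical vector, one verdict per level (coarsest first).
#' @export
membership <- function(hierarchy, x, tol = 1e-8) {
  ok <- vapply(hierarchy$levels, function(lv)
    constraint_residual(lv, coarse_grain(lv, x)) < tol, TRUE)
  cumall <- cumprod(ok) > 0
  as.logical(cumall)
}

#' Sample-based compatibility (nesting) check
#'
#' Draws points from `sampler` and flags any point that satisfies a
#' deeper level while violating a coarser one — the signature of an
#' incompatible hierarchy.  The check is probabilistic, not a proof.
#'
#' @param hierarchy A [constraint_hierarchy()].
#' @param sampler Function `n -> matrix` (one point per row); ideally
#'   biased toward points satisfying the constraints.
#' @param n_samples Number of sampled points.
#' @param tol Residual tolerance shared with [membership()].
#' @return List with `verdict` and `counterexamples` (matrix of
#'   offending points, 0 rows when compatible).
#' @export
check_nesting <- function(hierarchy, sampler, n_samples = 1000,
                          tol = 1e-8) {
  pts <- sampler(n_samples)
  if (!is.matrix(pts)) pts <- matrix(pts, ncol = 1L)
  if (nrow(pts) == 0L) stop("sampler produced no points")
  nlev <- length(hierarchy$levels)
  bad <- logical(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    ok <- vapply(hierarchy$levels, function(lv)
      constraint_residual(lv, coarse_grain(lv, pts[i, ])) < tol, TRUE)
    # a deeper level satisfied while some coarser one is violated
    if (nlev >= 2L)
      for (l in 2:nlev)
        if (ok[l] && !all(ok[seq_len(l - 1L)])) { bad[i] <- TRUE; break }
  }
  list(verdict = !any(bad),
       counterexamples = pts[bad, , drop = FALSE])
}
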