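#' Layer and network constructors for the symmetry audit
#'
#' A layer is a weight matrix, a bias vector and an element-wise
#' activation; a network is an ordered list of layers whose dimensions
#' chain.  These are audit subjects, not trainable models: the package
#' checks whether infinitesimal group actions on the input are
#' annihilated (invariance) or reproduced at the output (equivariance)
#' by the layered map.
#'
#' @param W Weight matrix (outputs x inputs).
#' @param b Bias vector (length `nrow(W)`; a scalar is recycled).
#' @param activation One of `"identity"`, `"tanh"`, `"relu"`,
#'   `"logistic"`.  The relu derivative at exactly 0 is taken as 0.
#' @return `layer_spec()` returns a `"layer_spec"`; `feedforward_net()`
#'   a `"feedforward_net"` (list of layers).
#' @export
layer_spec <- function(W, b = 0,
                       activation = c("identity", "tanh", "relu",
                                      "logistic")) {
  activation <- match.arg(activation)
  if (!is.matrix(W)) W <- matrix(W, nrow = 1L)
  b <- rep_len(b, nrow(W))
  structure(list(W = W, b = b, activation = activation),
            class = "layer_spec")
}

#' @rdname layer_spec
#' @param ... Layers (or a single list of layers).
#' @export
feedforward_net <- function(...) {
  layers <- list(...)
  if (length(layers) == 1L && !inherits(layers[[1L]], "layer_spec"))
    layers <- layers[[1L]]
  if (!all(vapply(layers, inherits, TRUE, "layer_spec")))
    stop("all arguments must be layer_spec objects")
  for (l in seq_along(layers)[-1L])
    if (ncol(layers[[l]]$W) != nrow(layers[[l - 1L]]$W))
      stop(sprintf("layer %d input dim %d != layer %d output dim %d",
                   l, ncol(layers[[l]]$W), l - 1L,
                   nrow(layers[[l - 1L]]$W)))
  structure(list(layers = layers), class = "feedforward_net")
}

#' @export
print.feedforward_net <- function(x, ...) {
  dims <- c(ncol(x$layers[[1L]]$W),
            vapply(x$layers, function(l) nrow(l$W), 1L))
  acts <- vapply(x$layers, function(l) l$activation, "")
  cat(sprintf("<feedforward_net> %s (%s)\n",
              paste(dims, collapse = " -> "),
              paste(acts, collapse = ", ")))
  invisible(x)
}

act_fun <- function(name) {
  switch(name,
         identity = function(v) v,
         tanh     = tanh,
         relu     = function(v) pmax(v, 0),
         logistic = function(v) 1 / (1 + exp(-v)))
}

# Derivative of the activation as a function of the pre-activation.
act_deriv <- function(name) {
  switch(name,
         identity = function(v) rep(1, length(v)),
         tanh     = function(v) 1 - tanh(v)^2,
         relu     = function(v) as.numeric(v > 0),   # subgradient 0 at 0
         logistic = function(v) { s <- 1 / (1 + exp(-v)); s * (1 - s) })
}

#' Forward pass returning all intermediate activations
#'
#' @param net A [feedforward_net()].
#' @param x0 Input vector.
#' @return List of activation vectors `x0, x1, ..., xL` (length L + 1).
#' @export
ffn_forward <- function(net, x0) {
  stopifnot(inherits(net, "feedforward_net"))
  if (length(x0) != ncol(net$layers[[1L]]$W))
    stop(sprintf("input of length %d expected, got %d",
                 ncol(net$layers[[1L]]$W), length(x0)))
  xs <- vector("list", length(net$layers) + 1L)
  xs[[1L]] <- as.numeric(x0)
  for (l in seq_along(net$layers)) {
    ly <- net$layers[[l]]
    xs[[l + 1L]] <- act_fun(ly$activation)(
      as.numeric(ly$W %*% xs[[l]] + ly$b))
  }
  xs
}

#' Transport an input generator through the layers
#'
#' An infinitesimal input change `eps * T0 x0` propagates through layer l
#' with the chain-rule factor `J_l W_l`, where `J_l` is the diagonal
#' Jacobian of the element-wise activation at the layer's pre-activation
#' on the forward pass of `x0`.  The transported generator after l layers
#' is `T_l = J_l W_l ... J_1 W_1 T0` (an `n_l x n_0` matrix acting on the
#' input), and the transported tangent is `T_l x0`.
#'
#' @param net A [feedforward_net()].
#' @param T0 Input generator: a square matrix of size `length(x0)`.
#' @param x0 Base input vector.
#' @return Object of class `"generator_propagation"`: list with
#'   `transported` (list `T_0 ... T_L`), `jacobians` (diagonal entries per
#'   layer), `tangents` (list of `T_l x0`), `activations`, and
#'   `input_generator`.
#' @export
propagate_generator <- function(net, T0, x0) {
  stopifnot(inherits(net, "feedforward_net"))
  if (!is.matrix(T0) || nrow(T0) != ncol(T0) || nrow(T0) != length(x0))
    stop("T0 must be square with the input dimension")
  xs <- ffn_forward(net, x0)
  L <- length(net$layers)
  transported <- vector("list", L + 1L)
  jac <- vector("list", L)
  transported[[1L]] <- T0
  for (l in seq_len(L)) {
    ly <- net$layers[[l]]
    pre <- as.numeric(ly$W %*% xs[[l]] + ly$b)
    jl <- act_deriv(ly$activation)(pre)
    jac[[l]] <- jl
    transported[[l + 1L]] <- (ly$W %*% transported[[l]]) * jl
  }
  structure(
    list(transported = transported, jacobians = jac,
         tangents = lapply(transported, function(Tl)
           as.numeric(Tl %*% x0)),
         activations = xs, input_generator = T0),
    class = "generator_propagation")
}

# Resolve per-input tangent columns: either from a generator matrix T0 or
# from an explicit tangent matrix (one column per input).
input_tangents <- function(inputs, T0 = NULL, tangents = NULL) {
  if (!is.matrix(inputs)) inputs <- matrix(inputs, ncol = 1L)
  if (is.null(tangents)) {
    if (is.null(T0)) stop("supply either T0 or explicit tangents")
    tangents <- T0 %*% inputs
  } else {
    if (!is.matrix(tangents)) tangents <- matrix(tangents, ncol = 1L)
    if (!all(dim(tangents) == dim(inputs)))
      stop("tangents must match inputs in shape")
  }
  list(inputs = inputs, tangents = tangents)
}

# Transport a single tangent vector through the net; returns the list of
# per-layer transported tangents t_0 ... t_L.
transport_tangent <- function(net, x0, t0) {
  xs <- ffn_forward(net, x0)
  L <- length(net$layers)
  ts <- vector("list", L + 1L)
  ts[[1L]] <- as.numeric(t0)
  for (l in seq_len(L)) {
    ly <- net$layers[[l]]
    pre <- as.numeric(ly$W %*% xs[[l]] + ly$b)
    ts[[l + 1L]] <- as.numeric(ly$W %*% ts[[l]]) *
      act_deriv(ly$activation)(pre)
  }
  ts
}

#' Layer-wise invariance (null-space) residuals
#'
#' For each layer l the residual is the norm of the transported tangent
#' *after* that layer, `||J_l W_l t_{l-1}||`: it vanishes exactly when
#' the orbit tangent lies in the null space of the layer map at the
#' forward-pass linearization, the necessary condition for first-order
#' invariance of the network output.  Residuals are reported per layer as
#' the maximum over the supplied inputs, with a tri-state verdict:
#' `"satisfied"` below `tol_strict`, `"approximate"` below `tol_loose`.
#'
#' @param net A [feedforward_net()].
#' @param inputs Input sample, one column per input (drawn from the orbit
#'   of interest).
#' @param T0 Input generator matrix, or `NULL` if `tangents` given.
#' @param tangents Optional explicit orbit tangents (same shape as
#'   `inputs`), e.g. finite-difference tangents of a rendered orbit.
#' @param tol_strict,tol_loose Verdict thresholds.
#' @return Object of class `"invariance_report"`: data frame with
#'   columns `layer`, `residual`, `verdict`, plus attribute
#'   `first_satisfied` (first layer below `tol_strict`, or `NA`).
#' @export
invariance_residual <- function(net, inputs, T0 = NULL, tangents = NULL,
                                tol_strict = 1e-8, tol_loose = 1e-4) {
  it <- input_tangents(inputs, T0, tangents)
  L <- length(net$layers)
  res <- numeric(L)
  for (i in seq_len(ncol(it$inputs))) {
    ts <- transport_tangent(net, it$inputs[, i], it$tangents[, i])
    for (l in seq_len(L))
      res[l] <- max(res[l], sqrt(sum(ts[[l + 1L]]^2)))
  }
  verdict <- ifelse(res < tol_strict, "satisfied",
                    ifelse(res < tol_loose, "approximate", "violated"))
  out <- data.frame(layer = seq_len(L), residual = res, verdict = verdict)
  fs <- which(res < tol_strict)
  attr(out, "first_satisfied") <- if (length(fs)) fs[1L] else NA_integer_
  class(out) <- c("invariance_report", "data.frame")
  out
}

#' Output equivariance residual for autoencoder-shaped networks
#'
#' Measures `max_x || t_N(x) - t_0(x) ||`, the difference between the
#' tangent transported to the output and the input tangent: zero means
#' the output transforms exactly as the input under the infinitesimal
#' group action (the transported generator at the output acts as the
#' input generator on the orbit).
#'
#' @inheritParams invariance_residual
#' @return Scalar residual (max over inputs).
#' @export
equivariance_residual <- function(net, inputs, T0 = NULL,
                                  tangents = NULL) {
  n_in <- ncol(net$layers[[1L]]$W)
  n_out <- nrow(net$layers[[length(net$layers)]]$W)
  if (n_in != n_out)
    stop(sprintf(
      "equivariance needs autoencoder shape (input %d != output %d)",
      n_in, n_out))
  it <- input_tangents(inputs, T0, tangents)
  worst <- 0
  for (i in seq_len(ncol(it$inputs))) {
    ts <- transport_tangent(net, it$inputs[, i], it$tangents[, i])
    worst <- max(worst,
                 sqrt(sum((ts[[length(ts)]] - ts[[1L]])^2)))
  }
  worst
}

#' Empirical order of output sensitivity to an orbit perturbation
#'
#' Fits the slope of `log ||net(x(eps)) - net(x0)||` against `log eps`,
#' where `x(eps)` walks along the group orbit through `x0`: the exact
#' path `expm(eps T0) x0` when a generator matrix is given, a
#' user-supplied `perturb(eps)` path (e.g. re-rendering a world model at
#' a shifted latent), or the straight tangent step when only a tangent
#' vector is available.  Slope ~2 certifies first-order invariance along
#' the orbit (the linear response is annihilated and only the orbit's
#' Taylor remainder survives); slope ~1 is the generic response.
#' Differences at machine precision are trimmed from the fit with a
#' warning.  Note that a layer annihilating the tangent *exactly* gives
#' an identically zero response to the straight tangent step, so the
#' curved orbit path is what makes the second-order remainder visible.
#'
#' @param net A [feedforward_net()].
#' @param x0 Base input.
#' @param T0 Input generator matrix, or `NULL`.
#' @param tangent Explicit tangent vector (straight-line fallback).
#' @param perturb Optional path function `eps -> input`, with
#'   `perturb(0) == x0`.
#' @param eps_grid Decreasing positive perturbation sizes spanning at
#'   least two decades.
#' @return List with `slope`, `eps`, `delta` (response norms).
#' @export
first_order_check <- function(net, x0, T0 = NULL, tangent = NULL,
                              perturb = NULL,
                              eps_grid = 10^seq(-2, -4, length.out = 9)) {
  path <- if (!is.null(perturb)) perturb
  else if (!is.null(T0))
    function(e) as.numeric(as.matrix(Matrix::expm(e * T0)) %*% x0)
  else if (!is.null(tangent)) function(e) x0 + e * tangent
  else stop("supply T0, a tangent, or a perturb function")
  if (max(eps_grid) / min(eps_grid) < 99)
    stop("eps_grid must span at least two decades")
  base <- ffn_forward(net, x0)
  y0 <- base[[length(base)]]
  delta <- vapply(eps_grid, function(e) {
    y <- ffn_forward(net, path(e))
    sqrt(sum((y[[length(y)]] - y0)^2))
  }, 1.0)
  keep <- delta > 1e-13 * max(1, sqrt(sum(y0^2)))
  if (!all(keep)) {
    warning("trimming eps values with responses at machine precision")
    if (sum(keep) < 3L) stop("too few usable eps values after trimming")
  }
  fit <- stats::lm(log(delta[keep]) ~ log(eps_grid[keep]))
  list(slope = unname(stats::coef(fit)[2L]), eps = eps_grid[keep],
       delta = delta[keep])
}

#' Build a layer annihilating a set of orbit tangents
#'
#' Returns a linear layer whose weight rows span (part of) the orthogonal
#' complement of the supplied tangent vectors, so `W t = 0` for every
#' tangent `t`.  Inserting such a layer into a network forces the
#' invariance residual at that layer to zero on the orbit.
#'
#' @param orbit_tangents Matrix of tangent vectors, one per column (an
#'   empty matrix constrains nothing).
#' @param width Number of output units; at most
#'   `n - rank(orbit_tangents)`.
#' @return A [layer_spec()] with identity activation and zero bias.
#' @export
construct_invariant_layer <- function(orbit_tangents, width) {
  if (is.null(orbit_tangents) || length(orbit_tangents) == 0L)
    stop("supply a matrix of tangent vectors (possibly 0 columns)")
  n <- nrow(orbit_tangents)
  if (ncol(orbit_tangents) == 0L) {
    if (width > n) stop("width exceeds the input dimension")
    return(layer_spec(diag(n)[seq_len(width), , drop = FALSE]))
  }
  sv <- svd(orbit_tangents, nu = n)
  rank <- sum(sv$d > max(sv$d) * max(dim(orbit_tangents)) *
                .Machine$double.eps)
  if (width > n - rank)
    stop(sprintf(
      "width %d exceeds the %d-dimensional orthogonal complement",
      width, n - rank))
  W <- t(sv$u[, rank + seq_len(width), drop = FALSE])
  layer_spec(W)
}

#' Plain-text serialization of layered networks
#'
#' One block per layer: a header `layer <out> <in> <activation>`, the
#' weight rows, then a `bias` line.
#'
#' @param net A [feedforward_net()].
#' @param path File path.
#' @return `read_ffn` returns a [feedforward_net()].
#' @export
write_ffn <- function(net, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (ly in net$layers) {
    writeLines(sprintf("layer %d %d %s", nrow(ly$W), ncol(ly$W),
                       ly$activation), con)
    writeLines(apply(ly$W, 1L, function(r)
      paste(sprintf("%.17g", r), collapse = " ")), con)
    writeLines(paste("bias", paste(sprintf("%.17g", ly$b),
                                   collapse = " ")), con)
  }
  invisible(path)
}

#' @rdname write_ffn
#' @export
read_ffn <- function(path) {
  lines <- readLines(path)
  layers <- list()
  i <- 1L
  while (i <= length(lines)) {
    hdr <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    if (hdr[1L] != "layer")
      stop(sprintf("expected 'layer' header at line %d of %s", i, path))
    nr <- as.integer(hdr[2L]); nc <- as.integer(hdr[3L])
    W <- matrix(scan(text = paste(lines[i + seq_len(nr)], collapse = "\n"),
                     quiet = TRUE), nr, nc, byrow = TRUE)
    bl <- strsplit(trimws(lines[i + nr + 1L]), "\\s+")[[1L]]
    if (bl[1L] != "bias")
      stop(sprintf("expected 'bias' line at line %d of %s",
                   i + nr + 1L, path))
    layers[[length(layers) + 1L]] <-
      layer_spec(W, as.numeric(bl[-1L]), hdr[4L])
    i <- i + nr + 2L
  }
  feedforward_net(layers)
}
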