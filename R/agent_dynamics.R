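#' Reservoir agent with a world-tracking readout block
#'
#' The agent state `x = (z, u)` stacks `n_hidden` recurrent (reservoir)
#' units `z` and `n_input` readout units `u`, one per input pixel.  The
#' continuous-time dynamics are a leaky rate model,
#' \preformatted{
#'   tau z' = -z + W_zz r(z) + W_in I
#'   tau u' = -u + W_u  r(z)          - tau k (u - I)
#' }
#' where `r` is the unit nonlinearity (`tanh` or identity), `I(t)` is the
#' input frame, `W_u` is the (ridge-fitted) readout matrix and the last
#' term is proportional error feedback `K E` with Comparator error
#' `E = p(x) - I` and gain `K = -k (dp/dx)^T` acting on the readout
#' coordinates only (`p` is the coordinate selector of `u`).
#'
#' The reservoir follows the echo-state recipe: dense Gaussian `W_zz`
#' rescaled to a fixed spectral radius, Gaussian `W_in` scaled by
#' `1/sqrt(n_input)`, both pure functions of `seed`.
#'
#' @param n_hidden Number of reservoir units.
#' @param n_input Input dimension Y (pixels).
#' @param tau Leak time constant in seconds.
#' @param spectral_radius Target spectral radius of `W_zz`.
#' @param input_scale Scale of `W_in` entries (default `1/sqrt(n_input)`).
#' @param activation Unit nonlinearity, `"tanh"` or `"identity"`.
#' @param seed Seed for the reservoir draw.
#' @return An object of class `"agent_system"`.
#' @export
agent_system <- function(n_hidden = 200, n_input, tau = 0.1,
                         spectral_radius = 0.9, input_scale = NULL,
                         activation = c("tanh", "identity"), seed = 1) {
  activation <- match.arg(activation)
  stopifnot(tau > 0, n_hidden >= 1, n_input >= 1)
  if (is.null(input_scale)) input_scale <- 1 / sqrt(n_input)
  mats <- with_seed(seed, {
    Wzz <- matrix(stats::rnorm(n_hidden^2), n_hidden)
    Win <- matrix(stats::rnorm(n_hidden * n_input), n_hidden) * input_scale
    list(Wzz = Wzz, Win = Win)
  })
  rad <- max(Mod(eigen(mats$Wzz, only.values = TRUE)$values))
  if (rad > 0) mats$Wzz <- mats$Wzz * (spectral_radius / rad)
  structure(
    list(n_hidden = as.integer(n_hidden), n_input = as.integer(n_input),
         n_units = as.integer(n_hidden + n_input),
         W_zz = mats$Wzz, W_in = mats$Win, tau = tau,
         spectral_radius = spectral_radius, activation = activation,
         readout = NULL, feedback = feedback_spec(0), seed = seed),
    class = "agent_system")
}

#' @export
print.agent_system <- function(x, ...) {
  cat(sprintf(
    "<agent_system> %d reservoir + %d readout units (tau %.3g s, rho %.2g, %s)\n",
    x$n_hidden, x$n_input, x$tau, x$spectral_radius, x$activation))
  cat(sprintf("  readout: %s; feedback gain k = %.4g\n",
              if (is.null(x$readout)) "not fitted" else "fitted",
              x$feedback$gain_scale))
  invisible(x)
}

#' Readout specification
#'
#' The readout is the coordinate-selector projection `p(x) = u` composed
#' with the linear map `u ~ W_u r(z)` that the fit installs in the `u`
#' dynamics.  `readout_units` and `hidden_units` partition the state
#' indices.
#'
#' @param w_u Readout matrix (`n_input` x `n_hidden`).
#' @param n_hidden,n_input State block sizes.
#' @param sigma Output nonlinearity (`"identity"` or `"tanh"`).
#' @return An object of class `"readout_spec"`.
#' @export
readout_spec <- function(w_u, n_hidden, n_input,
                         sigma = c("identity", "tanh")) {
  sigma <- match.arg(sigma)
  if (!is.matrix(w_u) || nrow(w_u) != n_input || ncol(w_u) != n_hidden)
    stop(sprintf("w_u must be %d x %d", n_input, n_hidden))
  structure(list(w_u = w_u, sigma = sigma,
                 hidden_units = seq_len(n_hidden),
                 readout_units = n_hidden + seq_len(n_input)),
            class = "readout_spec")
}

#' Proportional feedback gain
#'
#' `design_gain()` realizes the negative readout-transpose gain
#' `K = -k (dp/dx)^T`: the Comparator error is injected (scaled by `-k`)
#' into the readout coordinates only, which suffices to make the
#' Lyapunov function of the error non-increasing once the readout
#' reproduces the input manifold.  `k = 0` disables feedback.
#'
#' @param gain_scale Non-negative scalar gain k.
#' @return An object of class `"feedback_spec"`.
#' @export
feedback_spec <- function(gain_scale = 0) {
  stopifnot(is.finite(gain_scale), gain_scale >= 0)
  structure(list(gain_scale = gain_scale), class = "feedback_spec")
}

#' @rdname feedback_spec
#' @param agent An [agent_system()] (used for the gain matrix shape).
#' @return `design_gain` returns a `"feedback_spec"`; its dense
#'   `gain_matrix()` is `-k t(P)` with `P` the readout selector.
#' @export
design_gain <- function(agent, gain_scale) {
  fb <- feedback_spec(gain_scale)
  fb$agent_dims <- c(agent$n_units, agent$n_input)
  fb
}

#' @rdname feedback_spec
#' @param fb A `"feedback_spec"` from [design_gain()].
#' @export
gain_matrix <- function(fb) {
  if (is.null(fb$agent_dims)) stop("gain built without agent dimensions")
  K <- matrix(0, fb$agent_dims[1L], fb$agent_dims[2L])
  nz <- fb$agent_dims[1L] - fb$agent_dims[2L]
  for (j in seq_len(fb$agent_dims[2L])) K[nz + j, j] <- -fb$gain_scale
  K
}

#' Comparator error and Lyapunov function
#'
#' `comparator_error()` computes `E = p(x) - I`, the signed mismatch
#' between the readout coordinates of the state and the current input
#' frame.  `lyapunov()` is the Comparator energy `V = 0.5 * sum(E^2)`,
#' non-negative and zero exactly at perfect tracking.
#'
#' @param x Full state vector, or directly the readout block if
#'   `readout` is `NULL` and `length(x) == length(I)`.
#' @param I Input frame (length Y).
#' @param readout A [readout_spec()] supplying the selector (optional
#'   when `x` is already the readout block).
#' @return `comparator_error`: numeric error vector; `lyapunov`: scalar.
#' @export
comparator_error <- function(x, I, readout = NULL) {
  u <- if (!is.null(readout)) x[readout$readout_units]
       else if (length(x) == length(I)) x
       else stop("supply a readout_spec to select the readout block")
  if (length(u) != length(I))
    stop(sprintf("input frame of length %d does not match readout %d",
                 length(I), length(u)))
  as.numeric(u - I)
}

#' @rdname comparator_error
#' @param E Error vector.
#' @export
lyapunov <- function(E) {
  if (!all(is.finite(E))) stop("non-finite Comparator error")
  0.5 * sum(E^2)
}

# Right-hand side of the agent ODE.  I is the current input frame, k the
# feedback gain.  Returns the full state derivative.
agent_rhs <- function(agent, x, I, w_u, k) {
  nz <- agent$n_hidden
  z <- x[seq_len(nz)]
  u <- x[nz + seq_len(agent$n_input)]
  r <- if (agent$activation == "tanh") tanh(z) else z
  dz <- (-z + agent$W_zz %*% r + agent$W_in %*% I) / agent$tau
  du <- (-u + w_u %*% r) / agent$tau - k * (u - I)
  c(dz, du)
}

#' Fixed-step RK4 integration of the agent driven by an input stream
#'
#' Integrates the leaky-rate dynamics with classical Runge-Kutta at the
#' stream's sampling step, holding each input frame constant over its
#' step (zero-order hold).  The Comparator error and Lyapunov value are
#' recorded at every sample.  The run is a pure function of the agent,
#' the stream and the initial state.
#'
#' @param agent An [agent_system()] (its `readout`/`feedback` fields are
#'   used unless overridden).
#' @param input Input stream, time x Y matrix with attribute `times` (or
#'   a `dt` argument).
#' @param x0 Initial state (default zeros).
#' @param dt Step in seconds; defaults to the stream step.  Must satisfy
#'   `dt <= tau / 10`.
#' @param readout Optional [readout_spec()] override.
#' @param feedback Optional [feedback_spec()] override.
#' @return List of class `"wtne_run"` with `trajectory` (class
#'   `"trajectory"`: `times`, `states`) and `trace` (class
#'   `"comparator_trace"`: `times`, `errors`, `lyapunov`).
#' @export
integrate_agent <- function(agent, input, x0 = NULL, dt = NULL,
                            readout = NULL, feedback = NULL) {
  stopifnot(inherits(agent, "agent_system"))
  if (!is.matrix(input)) input <- matrix(input, ncol = agent$n_input)
  if (ncol(input) != agent$n_input)
    stop(sprintf("input stream has %d columns, agent expects %d",
                 ncol(input), agent$n_input))
  times <- attr(input, "times")
  if (is.null(dt)) {
    if (is.null(times)) stop("supply dt or a stream with a times attribute")
    dt <- times[2L] - times[1L]
  }
  if (!is.null(times) && max(abs(diff(times) - dt)) > 1e-9 * dt)
    stop("input stream time base does not match dt")
  if (is.null(times)) times <- (seq_len(nrow(input)) - 1) * dt
  if (dt > agent$tau / 10 + 1e-12)
    stop(sprintf("dt = %g too coarse for tau = %g (need dt <= tau/10)",
                 dt, agent$tau))
  if (is.null(readout)) readout <- agent$readout
  w_u <- if (is.null(readout)) matrix(0, agent$n_input, agent$n_hidden)
         else readout$w_u
  if (is.null(feedback)) feedback <- agent$feedback
  k <- if (is.null(feedback)) 0 else feedback$gain_scale
  if (is.null(x0)) x0 <- numeric(agent$n_units)
  if (length(x0) != agent$n_units)
    stop(sprintf("x0 of length %d expected", agent$n_units))

  nt <- nrow(input)
  states <- matrix(0, nt, agent$n_units)
  errors <- matrix(0, nt, agent$n_input)
  V <- numeric(nt)
  x <- as.numeric(x0)
  uix <- agent$n_hidden + seq_len(agent$n_input)
  for (i in seq_len(nt)) {
    I <- input[i, ]
    states[i, ] <- x
    errors[i, ] <- x[uix] - I
    V[i] <- 0.5 * sum(errors[i, ]^2)
    if (i < nt) {
      k1 <- agent_rhs(agent, x, I, w_u, k)
      k2 <- agent_rhs(agent, x + dt / 2 * k1, I, w_u, k)
      k3 <- agent_rhs(agent, x + dt / 2 * k2, I, w_u, k)
      k4 <- agent_rhs(agent, x + dt * k3, I, w_u, k)
      x <- x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      if (!all(is.finite(x)) || max(abs(x)) > 1e6)
        stop(sprintf("state divergence at step %d (t = %.4g s)",
                     i + 1L, times[i + 1L]))
    }
  }
  traj <- structure(list(times = times, states = states,
                         input_ref = attr(input, "input_ref")),
                    class = "trajectory")
  trace <- structure(list(times = times, errors = errors, lyapunov = V),
                     class = "comparator_trace")
  structure(list(trajectory = traj, trace = trace, dt = dt,
                 gain_scale = k),
            class = "wtne_run")
}

#' @export
print.wtne_run <- function(x, ...) {
  nt <- length(x$trajectory$times)
  cat(sprintf(
    "<wtne_run> %d steps, dt %.4g s, gain k = %.4g\n", nt, x$dt,
    x$gain_scale))
  cat(sprintf("  terminal ||E|| = %.4g, V = %.4g\n",
              sqrt(sum(x$trace$errors[nt, ]^2)), x$trace$lyapunov[nt]))
  invisible(x)
}

#' Readout block of a trajectory
#'
#' @param traj A `"trajectory"` (or a `"wtne_run"`).
#' @param agent The [agent_system()] that produced it.
#' @return Time x Y matrix of readout-unit values.
#' @export
readout_block <- function(traj, agent) {
  if (inherits(traj, "wtne_run")) traj <- traj$trajectory
  traj$states[, agent$n_hidden + seq_len(agent$n_input), drop = FALSE]
}

#' Analytic time derivative of the Lyapunov function
#'
#' Evaluates `V' = E^T (dp/dx [f(x) + K E] - dI/dt)` at a single state:
#' the readout rows of the closed-loop vector field, dotted with the
#' error.  Along an integrated trajectory the finite-difference slope of
#' `V(t)` converges to this value as the step shrinks.
#'
#' @param agent An [agent_system()] with a fitted readout.
#' @param x Full state vector.
#' @param I Input frame.
#' @param dI_dt Input frame time derivative (0 for static input).
#' @param feedback Optional [feedback_spec()] override.
#' @return Scalar `V'`.
#' @export
vdot <- function(agent, x, I, dI_dt = 0, feedback = NULL) {
  if (is.null(feedback)) feedback <- agent$feedback
  k <- if (is.null(feedback)) 0 else feedback$gain_scale
  w_u <- if (is.null(agent$readout))
    matrix(0, agent$n_input, agent$n_hidden) else agent$readout$w_u
  f <- agent_rhs(agent, x, I, w_u, k)
  uix <- agent$n_hidden + seq_len(agent$n_input)
  E <- x[uix] - I
  sum(E * (f[uix] - rep_len(dI_dt, agent$n_input)))
}

#' Ridge fit of the linear readout on teacher-forced open-loop runs
#'
#' Integrates the agent open loop (no feedback, readout inert) on each
#' training stream, collects the post-transient reservoir features
#' `r(z(t))` and solves the multi-response ridge normal equations for the
#' map from features to input frames.  Training on *constant* streams
#' (the default built by [wtne()]) samples reservoir fixed points, the
#' static regime in which the tracking constraint turns every readout
#' coordinate into a conserved quantity.
#'
#' @param agent An [agent_system()].
#' @param streams List of input streams (time x Y matrices with `times`
#'   attributes), or a single stream.
#' @param ridge Ridge penalty lambda (> 0 advised; exactly 0 fails on
#'   singular designs with a hint).
#' @param burn Seconds discarded from the start of each stream.
#' @param dt Integration step (defaults per stream).
#' @param x0 Initial state for the training integrations.
#' @return A [readout_spec()] with attributes `residual_rms` (root mean
#'   squared training residual) and `n_samples`.
#' @export
fit_readout <- function(agent, streams, ridge = 1e-6, burn = 1,
                        dt = NULL, x0 = NULL) {
  if (!is.list(streams)) streams <- list(streams)
  feats <- list(); targs <- list()
  for (s in streams) {
    run <- integrate_agent(agent, s, x0 = x0, dt = dt,
                           readout = NULL, feedback = feedback_spec(0))
    keep <- run$trajectory$times >= burn
    if (!any(keep))
      stop("burn-in leaves no training samples; shorten burn")
    z <- run$trajectory$states[keep, seq_len(agent$n_hidden),
                               drop = FALSE]
    feats[[length(feats) + 1L]] <-
      if (agent$activation == "tanh") tanh(z) else z
    targs[[length(targs) + 1L]] <-
      (if (is.matrix(s)) s else matrix(s, ncol = agent$n_input))[keep, ,
                                                         drop = FALSE]
  }
  Phi <- do.call(rbind, feats)
  Yt <- do.call(rbind, targs)
  G <- crossprod(Phi) + diag(ridge, agent$n_hidden)
  sol <- tryCatch(solve(G, crossprod(Phi, Yt)),
                  error = function(e)
                    stop("singular ridge system; use ridge > 0 (",
                         conditionMessage(e), ")"))
  w_u <- t(sol)
  res <- Phi %*% sol - Yt
  out <- readout_spec(w_u, agent$n_hidden, agent$n_input)
  attr(out, "residual_rms") <- sqrt(mean(res^2))
  attr(out, "n_samples") <- nrow(Phi)
  out
}

#' Transient cutoff of a Comparator trace
#'
#' The transient is over at the first time the Lyapunov value falls below
#' twice the median of its final quartile; all post-transient statistics
#' use this index.
#'
#' @param trace A `"comparator_trace"`.
#' @return Integer index of the first post-transient sample.
#' @export
transient_index <- function(trace) {
  V <- trace$lyapunov
  nt <- length(V)
  tail_med <- stats::median(V[seq.int(max(1L, floor(3 * nt / 4)), nt)])
  idx <- which(V <= 2 * tail_med)
  if (length(idx)) idx[1L] else nt
}

#' Logarithmic line search for the feedback gain
#'
#' Runs short closed-loop simulations over a log-spaced gain grid and
#' scores each gain by the fraction of post-transient steps on which the
#' Lyapunov value does not increase (slack 1e-9); ties are broken toward
#' the smaller terminal Lyapunov value.  Gains that diverge score 0.
#'
#' @param agent An [agent_system()] with a fitted readout.
#' @param input Input stream for the search (typically a static frame).
#' @param grid Candidate gains.
#' @param slack Non-increase slack on V differences.
#' @return List with `k_star`, `fraction` (of non-increasing steps at
#'   `k_star`) and the full `table`.
#' @export
search_gain <- function(agent, input,
                        grid = 10^seq(-1, 2, length.out = 7),
                        slack = 1e-9) {
  score <- data.frame(k = grid, fraction = 0, terminal_V = Inf)
  for (i in seq_along(grid)) {
    run <- tryCatch(
      integrate_agent(agent, input, feedback = feedback_spec(grid[i])),
      error = function(e) NULL)
    if (is.null(run)) next
    V <- run$trace$lyapunov
    j0 <- transient_index(run$trace)
    dV <- diff(V[j0:length(V)])
    score$fraction[i] <- if (length(dV)) mean(dV <= slack) else 1
    score$terminal_V[i] <- V[length(V)]
  }
  best <- order(-score$fraction, score$terminal_V)[1L]
  list(k_star = grid[best], fraction = score$fraction[best],
       table = score)
}

#' First-order covariance residual of the agent dynamics
#'
#' Checks whether the closed-form vector field commutes with an
#' infinitesimal group action: given a state action `T_x` (by default
#' acting on the readout block only, zero on the hidden block) and the
#' pixel-space action `T_I`, the residual is
#' `max_s || (d/d eps) f(x + eps T_x x; I + eps T_I I) - T_x f(x; I) ||`
#' over the supplied sample, evaluated by central differences.  Zero
#' certifies covariance of the dynamics under the supplied action.
#'
#' @param agent An [agent_system()] (readout and feedback as stored).
#' @param T_input Pixel-space generator (Y x Y).
#' @param states Sample of full states, one per row.
#' @param inputs Sample of input frames, one per row (matched to states).
#' @param T_hidden Optional hidden-block generator (`NULL` = zero: the
#'   group is taken to act on the readout block only).
#' @param eps Central-difference step.
#' @return Scalar residual (max over the sample).
#' @export
dynamics_equivariance_residual <- function(agent, T_input, states, inputs,
                                           T_hidden = NULL, eps = 1e-5) {
  if (!is.matrix(states)) states <- matrix(states, nrow = 1L)
  if (!is.matrix(inputs)) inputs <- matrix(inputs, nrow = 1L)
  stopifnot(nrow(states) == nrow(inputs))
  nz <- agent$n_hidden
  w_u <- if (is.null(agent$readout))
    matrix(0, agent$n_input, agent$n_hidden) else agent$readout$w_u
  k <- agent$feedback$gain_scale
  act_state <- function(x) {
    z <- x[seq_len(nz)]; u <- x[nz + seq_len(agent$n_input)]
    c(if (is.null(T_hidden)) numeric(nz) else as.numeric(T_hidden %*% z),
      as.numeric(T_input %*% u))
  }
  worst <- 0
  for (s in seq_len(nrow(states))) {
    x <- states[s, ]; I <- inputs[s, ]
    Tx <- act_state(x)
    TI <- as.numeric(T_input %*% I)
    fp <- agent_rhs(agent, x + eps * Tx, I + eps * TI, w_u, k)
    fm <- agent_rhs(agent, x - eps * Tx, I - eps * TI, w_u, k)
    lhs <- (fp - fm) / (2 * eps)
    f0 <- agent_rhs(agent, x, I, w_u, k)
    z <- f0[seq_len(nz)]; uu <- f0[nz + seq_len(agent$n_input)]
    rhs <- c(if (is.null(T_hidden)) numeric(nz)
             else as.numeric(T_hidden %*% z),
             as.numeric(T_input %*% uu))
    worst <- max(worst, max(abs(lhs - rhs)))
  }
  worst
}

#' Exactly solvable constrained toy system
#'
#' The differential-algebraic toy problem `x' = 0, y' = 1` with the
#' algebraic tracking constraint `x = C`.  The ODE subsystem has general
#' solution `x = A, y = t + B`, so the constraint is satisfiable exactly
#' when the integration constant `A = x0` can be chosen equal to `C`:
#' the constraint is a conserved quantity in disguise, selected by the
#' initial condition.
#'
#' @param C Constraint constant.
#' @param x0,y0 Initial values.
#' @return An object of class `"toy_constrained_system"`.
#' @export
toy_constrained_system <- function(C, x0, y0 = 0) {
  stopifnot(is.finite(C), is.finite(x0), is.finite(y0))
  structure(list(C = C, x0 = x0, y0 = y0),
            class = "toy_constrained_system")
}

#' @rdname toy_constrained_system
#' @param toy A `toy_constrained_system`.
#' @param duration,dt Integration horizon and step (seconds).
#' @param tol Constraint satisfaction tolerance.
#' @return `solve_toy` returns a list with `times`, `analytic` (exact
#'   `x`, `y` columns), `numeric` (RK4 trajectory), `max_error`
#'   (numeric vs analytic), and a `constraint` report (`compatible`,
#'   `max_violation`).  An incompatible `x0 != C` is reported, not an
#'   error: `x` is conserved, so the violation persists for all time.
#' @export
solve_toy <- function(toy, duration = 1, dt = 1e-3, tol = 1e-9) {
  stopifnot(inherits(toy, "toy_constrained_system"), dt > 0)
  times <- seq(0, duration, by = dt)
  analytic <- cbind(x = rep(toy$x0, length(times)), y = times + toy$y0)
  rhs <- function(s) c(0, 1)
  num <- matrix(0, length(times), 2L,
                dimnames = list(NULL, c("x", "y")))
  s <- c(toy$x0, toy$y0)
  for (i in seq_along(times)) {
    num[i, ] <- s
    if (i < length(times)) {
      k1 <- rhs(s); k2 <- rhs(s + dt / 2 * k1)
      k3 <- rhs(s + dt / 2 * k2); k4 <- rhs(s + dt * k3)
      s <- s + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
  }
  viol <- max(abs(num[, "x"] - toy$C))
  list(times = times, analytic = analytic, numeric = num,
       max_error = max(abs(num - analytic)),
       constraint = list(compatible = abs(toy$x0 - toy$C) <= tol,
                         max_violation = viol))
}
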