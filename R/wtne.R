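#' Fit a world-tracking agent to a Lie generative world
#'
#' `wtne()` is the package's central estimator.  Given a generative world
#' model it (i) builds (or accepts) a reservoir agent sized to the
#' world's pixel count, (ii) ridge-fits the linear readout on
#' teacher-forced open-loop runs at a grid of constant latent
#' configurations — the static regime in which the tracking constraint
#' `p(x) = I` holds at reservoir fixed points, (iii) line-searches the
#' proportional feedback gain for Lyapunov descent on a static input,
#' and (iv) stores a closed-loop validation run at the world's reference
#' image, from which the residual/fitted/plot methods read.
#'
#' The training grid spans `train_range` (a latent interval per
#' coordinate); with the default world this covers the slow-path chart
#' `[-0.5, 0.5]` rad.  Fitting on constant streams rather than a moving
#' path keeps the quasi-static lag of the reservoir out of the readout
#' map.
#'
#' @param world A [world_model()].
#' @param agent An [agent_system()], or `NULL` to build the default
#'   (200 reservoir units, tau 0.1 s, spectral radius 0.9).
#' @param n_hidden Reservoir size when `agent` is `NULL`.
#' @param train_range Latent interval(s) for the training grid: a
#'   2-vector, or a 2-column matrix with one row per latent coordinate.
#' @param n_train Number of constant-latent training segments.
#' @param segment Training segment duration in seconds.
#' @param burn Seconds discarded from each segment before the ridge fit.
#' @param ridge Ridge penalty.
#' @param dt Integration step in seconds.
#' @param gain_grid Candidate feedback gains for the line search.
#' @param gain_duration Duration of each gain-search run (seconds).
#' @param validate_duration Duration of the stored validation run.
#' @param seed Seed for the reservoir draw.
#' @return An object of class `"wtne"`.
#' @examples
#' \donttest{
#' w <- world_model(cam = camera(8, 8))
#' fit <- wtne(w, n_hidden = 40, n_train = 9, seed = 2)
#' print(fit)
#' coef(fit)[1:3, 1:3]
#' }
#' @export
wtne <- function(world, agent = NULL, n_hidden = 200,
                 train_range = c(-0.5, 0.5), n_train = 25,
                 segment = 1.5, burn = 1, ridge = 1e-6, dt = 0.01,
                 gain_grid = 10^seq(-1, 2, length.out = 7),
                 gain_duration = 5, validate_duration = 8, seed = 1) {
  stopifnot(inherits(world, "world_model"))
  if (is.null(agent))
    agent <- agent_system(n_hidden = n_hidden, n_input = world$n_pixels,
                          seed = seed)
  if (agent$n_input != world$n_pixels)
    stop("agent input dimension does not match the world's pixel count")
  if (!is.matrix(train_range))
    train_range <- matrix(rep(train_range, each = world$latent_dim),
                          world$latent_dim)
  if (ncol(train_range) != 2L || nrow(train_range) != world$latent_dim)
    stop("train_range must give a (min, max) per latent coordinate")

  # Teacher-forced constant-latent training streams.
  grid <- sapply(seq_len(world$latent_dim), function(k)
    seq(train_range[k, 1L], train_range[k, 2L], length.out = n_train))
  grid <- matrix(grid, n_train)
  streams <- lapply(seq_len(n_train), function(i) {
    frame <- generate_frame(world, grid[i, ])
    nt <- length(seq(0, segment, by = dt))
    structure(matrix(rep(frame, each = nt), nt),
              times = seq(0, segment, by = dt))
  })
  readout <- fit_readout(agent, streams, ridge = ridge, burn = burn,
                         dt = dt)
  agent$readout <- readout

  # Gain line search on the static reference frame.
  ref <- world$reference_image
  nt <- length(seq(0, gain_duration, by = dt))
  static_stream <- structure(matrix(rep(as.numeric(ref), each = nt), nt),
                             times = seq(0, gain_duration, by = dt))
  gs <- search_gain(agent, static_stream, grid = gain_grid)
  agent$feedback <- design_gain(agent, gs$k_star)

  # Stored closed-loop validation run at the reference image.
  nt <- length(seq(0, validate_duration, by = dt))
  val_stream <- structure(matrix(rep(as.numeric(ref), each = nt), nt),
                          times = seq(0, validate_duration, by = dt))
  val <- integrate_agent(agent, val_stream)
  nt <- length(val$trace$lyapunov)
  terminal_err <- sqrt(sum(val$trace$errors[nt, ]^2))
  structure(
    list(world = world, agent = agent, k_star = gs$k_star,
         gain_fraction = gs$fraction, gain_table = gs$table,
         train_grid = grid, ridge = ridge, dt = dt, burn = burn,
         train_residual_rms = attr(readout, "residual_rms"),
         n_train_samples = attr(readout, "n_samples"),
         validation = val,
         terminal_error = terminal_err,
         terminal_error_rel = terminal_err /
           sqrt(sum(as.numeric(ref)^2)),
         transient_index = transient_index(val$trace),
         seed = seed, call = match.call()),
    class = "wtne")
}

#' @export
print.wtne <- function(x, ...) {
  cat("World-tracking agent fit\n")
  cat(sprintf("  world: latent dim %d -> %d pixels; agent: %d + %d units\n",
              x$world$latent_dim, x$world$n_pixels,
              x$agent$n_hidden, x$agent$n_input))
  cat(sprintf("  readout ridge fit: RMS residual %.3g on %d samples\n",
              x$train_residual_rms, x$n_train_samples))
  cat(sprintf("  feedback gain k* = %.4g (V non-increasing on %.1f%% of steps)\n",
              x$k_star, 100 * x$gain_fraction))
  cat(sprintf("  static validation: terminal ||E||/||I|| = %.3g\n",
              x$terminal_error_rel))
  invisible(x)
}

#' @export
summary.wtne <- function(object, ...) {
  V <- object$validation$trace$lyapunov
  j0 <- object$transient_index
  dV <- diff(V[j0:length(V)])
  structure(
    list(fit = object,
         lyapunov_descent = if (length(dV)) mean(dV <= 1e-9) else 1,
         transient_time = object$validation$trajectory$times[j0],
         terminal_V = V[length(V)]),
    class = "summary.wtne")
}

#' @export
print.summary.wtne <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  transient over at t = %.3g s; terminal V = %.3g\n",
              x$transient_time, x$terminal_V))
  cat(sprintf("  post-transient Lyapunov descent: %.1f%% of steps\n",
              100 * x$lyapunov_descent))
  invisible(x)
}

#' @export
coef.wtne <- function(object, ...) object$agent$readout$w_u

#' Closed-loop prediction (tracking) on new inputs
#'
#' Runs the fitted agent closed loop on either a latent path (rendered
#' through the fitted world) or a raw input stream, and returns the run;
#' the tracked readout is `readout_block(run, fit$agent)`.
#'
#' @param object A fitted [wtne()] object.
#' @param path Latent path matrix (from [latent_path()]).
#' @param input Raw input stream (overrides `path`).
#' @param x0 Initial state (default: the validation run's terminal
#'   state, i.e. the agent already tracking the reference frame).
#' @param ... Unused.
#' @return A `"wtne_run"`.
#' @export
predict.wtne <- function(object, path = NULL, input = NULL, x0 = NULL,
                         ...) {
  if (is.null(input)) {
    if (is.null(path)) stop("supply a latent path or an input stream")
    input <- render_path(object$world, path)
  }
  if (is.null(x0)) {
    st <- object$validation$trajectory$states
    x0 <- st[nrow(st), ]
  }
  integrate_agent(object$agent, input, x0 = x0)
}

#' Simulate closed-loop runs from a fitted tracking agent
#'
#' Each simulation draws a seeded slow sinusoid latent path (random
#' phase), renders it through the fitted world and integrates the agent
#' closed loop.
#'
#' @param object A fitted [wtne()] object.
#' @param nsim Number of runs.
#' @param seed RNG seed for the path draws.
#' @param duration Run duration in seconds.
#' @param ... Unused.
#' @return List of `"wtne_run"` objects (length `nsim`).
#' @export
simulate.wtne <- function(object, nsim = 1, seed = 1, duration = 10,
                          ...) {
  phases <- with_seed(seed, stats::runif(nsim, 0, 2 * pi))
  lapply(seq_len(nsim), function(i) {
    p <- latent_path("sinusoid", latent_dim = object$world$latent_dim,
                     duration = duration, dt = object$dt,
                     phase = phases[i])
    predict(object, path = p)
  })
}

#' @export
residuals.wtne <- function(object, ...) object$validation$trace$errors

#' @export
fitted.wtne <- function(object, ...)
  readout_block(object$validation, object$agent)

#' Plot the Lyapunov descent of the validation run
#'
#' @param x A fitted [wtne()] object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.wtne <- function(x, ...) {
  tr <- x$validation$trace
  graphics::plot(tr$times, pmax(tr$lyapunov, 1e-300), type = "l",
                 log = "y", xlab = "time (s)",
                 ylab = "Lyapunov V(t)", ...)
  graphics::abline(v = tr$times[x$transient_index], lty = 2)
  invisible(x)
}
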