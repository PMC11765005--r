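#' Screw joint for a kinematic chain
#'
#' A joint is described by its screw axis in se(3): a 4x4 matrix with a
#' 3x3 skew-symmetric rotation block, a translation column and a zero
#' bottom row.  For a revolute joint the axis is the unit rotation axis
#' `omega` through `point`, optionally with pitch `h` (translation per
#' radian along the axis); the screw matrix is
#' `[[omega]_x, -omega x q + h omega; 0, 0]`.
#'
#' @param axis Unit 3-vector, joint rotation axis.
#' @param point 3-vector, a point the axis passes through.
#' @param pitch Translation per radian along the axis (0 = pure revolute).
#' @param label Joint name.
#' @param angle_range Admissible angle interval in radians.
#' @return An object of class `"screw_joint"`.
#' @export
screw_joint <- function(axis = c(0, 0, 1), point = c(0, 0, 0), pitch = 0,
                        label = "joint", angle_range = c(-pi, pi)) {
  axis <- axis / sqrt(sum(axis^2))
  S <- matrix(0, 4, 4)
  S[1:3, 1:3] <- skew3(axis)
  S[1:3, 4] <- -crossprod3(axis, point) + pitch * axis
  structure(list(screw = S, label = label, angle_range = angle_range),
            class = "screw_joint")
}

skew3 <- function(w) {
  matrix(c(0, w[3], -w[2],
           -w[3], 0, w[1],
           w[2], -w[1], 0), 3, 3)
}

crossprod3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Kinematic chain with body markers
#'
#' An ordered list of screw joints, a home configuration `M` (the rigid
#' transform of the end link at zero joint angles) and a set of 3-D
#' markers attached to the end link.  The end-link pose at joint vector
#' theta is the product of exponentials
#' `exp(S_1 theta_1) ... exp(S_n theta_n) M`.
#'
#' @param joints List of [screw_joint()]s (applied in list order).
#' @param home 4x4 rigid home transform.
#' @param markers 3 x k matrix of marker positions in the home frame
#'   (one column per marker).
#' @return An object of class `"kinematic_chain"`.
#' @export
kinematic_chain <- function(joints, home = diag(4), markers) {
  if (length(joints) == 0L) stop("chain needs at least one joint")
  R <- home[1:3, 1:3]
  if (max(abs(crossprod(R) - diag(3))) > 1e-9 || abs(det(R) - 1) > 1e-9)
    stop("home transform rotation block is not a proper rotation")
  if (!is.matrix(markers) || nrow(markers) != 3L)
    stop("markers must be a 3 x k matrix")
  structure(list(joints = joints, home = home, markers = markers),
            class = "kinematic_chain")
}

#' Forward kinematics by the product of exponentials
#'
#' @param chain A [kinematic_chain()].
#' @param theta Joint angle vector (radians), one per joint, within each
#'   joint's `angle_range`.
#' @return List with `end_transform` (4x4) and `markers` (3 x k cloud of
#'   the chain markers under the end transform).
#' @export
pose_chain <- function(chain, theta) {
  stopifnot(inherits(chain, "kinematic_chain"))
  nj <- length(chain$joints)
  if (length(theta) != nj)
    stop(sprintf("chain has %d joints, got %d angles", nj, length(theta)))
  for (i in seq_len(nj)) {
    rng <- chain$joints[[i]]$angle_range
    if (theta[i] < rng[1] || theta[i] > rng[2])
      stop(sprintf("angle %d = %.4g outside range [%.4g, %.4g]",
                   i, theta[i], rng[1], rng[2]))
  }
  Tm <- diag(4)
  for (i in seq_len(nj)) {
    Si <- chain$joints[[i]]$screw * theta[i]
    Ei <- if (theta[i] == 0) diag(4) else as.matrix(Matrix::expm(Si))
    Tm <- Tm %*% Ei
  }
  Tm <- Tm %*% chain$home
  mk <- Tm %*% rbind(chain$markers, 1)
  list(end_transform = Tm, markers = mk[1:3, , drop = FALSE])
}

#' Orthographic Gaussian-splat camera
#'
#' Renders 3-D marker clouds by dropping z and depositing one unit-mass
#' Gaussian splat per marker on the raster.  The raster is row-major with
#' origin at the top-left; world x maps to columns, world y to rows
#' (y up), with the world origin at the raster center.  Unit splat mass
#' and a smooth kernel make the pixel map differentiable in the latent
#' parameters, which is what lets a low-dimensional model generate a
#' smooth image manifold.
#'
#' @param rows,cols Raster size in pixels.
#' @param scale World units per pixel.
#' @param splat_sigma Gaussian splat width in pixels.
#' @return An object of class `"camera"`.
#' @export
camera <- function(rows = 16, cols = 16, scale = 1, splat_sigma = 1.5) {
  stopifnot(rows >= 1, cols >= 1, splat_sigma > 0, scale > 0)
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 scale = scale, splat_sigma = splat_sigma,
                 n_pixels = as.integer(rows) * as.integer(cols)),
            class = "camera")
}

#' Render a marker cloud to an image frame
#'
#' @param markers 3 x k (or 2 x k, z assumed 0) matrix of world points.
#' @param cam A [camera()].
#' @return Numeric vector of length `rows * cols` (row-major raster),
#'   values clipped to `[0, 1]`, with attribute `raster = c(rows, cols)`.
#' @export
render_cloud <- function(markers, cam) {
  stopifnot(inherits(cam, "camera"))
  px <- numeric(cam$n_pixels)
  if (length(markers) > 0L && ncol(markers) > 0L) {
    cx <- (cam$cols + 1) / 2
    cy <- (cam$rows + 1) / 2
    colc <- rep(seq_len(cam$cols), times = cam$rows)  # row-major order
    rowc <- rep(seq_len(cam$rows), each = cam$cols)
    s2 <- 2 * cam$splat_sigma^2
    norm <- 2 * pi * cam$splat_sigma^2
    for (j in seq_len(ncol(markers))) {
      pc <- cx + markers[1, j] / cam$scale
      pr <- cy - markers[2, j] / cam$scale
      px <- px + exp(-((colc - pc)^2 + (rowc - pr)^2) / s2) / norm
    }
  }
  structure(pmin(px, 1), raster = c(cam$rows, cam$cols))
}

#' Image frame as a matrix
#'
#' @param frame Frame vector from [render_cloud()] or [generate_frame()].
#' @return `rows x cols` matrix.
#' @export
frame_matrix <- function(frame) {
  r <- attr(frame, "raster")
  if (is.null(r)) stop("frame carries no raster attribute")
  matrix(frame, nrow = r[1], ncol = r[2], byrow = TRUE)
}

#' Lie generative world model
#'
#' A world model is a smooth map from a low-dimensional latent
#' configuration (dimension M) to image space (dimension X = pixels),
#' realized as a group orbit of a reference marker cloud: the latent
#' vector is exponentiated to a group element which acts on the reference
#' cloud, and the transformed cloud is rendered.  By construction the
#' generated images form the orbit of the reference image, so M << X and
#' the image stream is highly compressible.
#'
#' `world_model()` builds a pure-group world (latent dim = group dim);
#' `kinematic_world()` builds a jointed-chain world (latent dim = number
#' of joints) whose images are product-of-exponentials poses.
#'
#' @param group A [lie_group()] (`so2`, `se2` or `sim2` for planar
#'   worlds; markers are 2-D columns).
#' @param markers 2 x k reference marker cloud (planar groups); defaults
#'   to three markers within 2 px of the origin, matched to the default
#'   camera so a full rotation orbit stays low-dimensional.
#' @param cam A [camera()].
#' @param reference_latent Latent coordinates of the reference frame.
#' @return An object of class `"world_model"` with fields `latent_dim`,
#'   `n_pixels`, `reference_latent` and `reference_image`.
#' @export
world_model <- function(group = lie_group("so2"),
                        markers = default_markers(),
                        cam = camera(),
                        reference_latent = rep(0, group$dim)) {
  stopifnot(inherits(group, "lie_group"), inherits(cam, "camera"))
  if (!is.matrix(markers) || nrow(markers) != 2L)
    stop("planar world markers must be a 2 x k matrix")
  if (length(reference_latent) != group$dim)
    stop("reference_latent length must equal the group dimension")
  if (group$dim > cam$n_pixels / 10)
    stop("latent dimension must be well below the pixel count (M <= X/10)")
  w <- structure(
    list(kind = "group", group = group, markers = markers, cam = cam,
         latent_dim = group$dim, n_pixels = cam$n_pixels,
         reference_latent = reference_latent, reference_image = NULL),
    class = "world_model")
  w$reference_image <- generate_frame(w, reference_latent)
  w
}

#' @rdname world_model
#' @param chain A [kinematic_chain()] (for `kinematic_world`).
#' @export
kinematic_world <- function(chain, cam = camera(),
                            reference_latent = rep(0, length(chain$joints))) {
  stopifnot(inherits(chain, "kinematic_chain"), inherits(cam, "camera"))
  M <- length(chain$joints)
  if (length(reference_latent) != M)
    stop("reference_latent length must equal the joint count")
  if (M > cam$n_pixels / 10)
    stop("latent dimension must be well below the pixel count (M <= X/10)")
  w <- structure(
    list(kind = "chain", chain = chain, cam = cam,
         latent_dim = M, n_pixels = cam$n_pixels,
         reference_latent = reference_latent, reference_image = NULL),
    class = "world_model")
  w$reference_image <- generate_frame(w, reference_latent)
  w
}

# Default reference cloud: three markers within 2 px of the origin.  At
# splat sigma 1.5 px this keeps the full rotation orbit of the rendered
# images within ~6 principal dimensions (smooth, heavily overlapping
# splats), the compressible regime the generative model is meant to
# produce.
default_markers <- function() {
  cbind(c(2, 0), c(0, 1.4), c(-1.2, -1))
}

#' @export
print.world_model <- function(x, ...) {
  cat(sprintf("<world_model> %s: latent dim %d -> %d pixels (%dx%d)\n",
              if (x$kind == "group") x$group$name else
                sprintf("chain[%d joints]", length(x$chain$joints)),
              x$latent_dim, x$n_pixels, x$cam$rows, x$cam$cols))
  invisible(x)
}

#' Generate the image frame at a latent configuration
#'
#' For a group world, exponentiates the latent coefficients and acts on
#' the reference cloud; for a chain world, poses the chain.  The frame at
#' the reference latent equals the stored `reference_image` bit for bit.
#'
#' @param model A [world_model()].
#' @param theta Latent vector of length `model$latent_dim`.
#' @return Image frame vector (see [render_cloud()]).
#' @export
generate_frame <- function(model, theta) {
  stopifnot(inherits(model, "world_model"))
  if (length(theta) != model$latent_dim)
    stop(sprintf("latent vector of length %d expected, got %d",
                 model$latent_dim, length(theta)))
  if (model$kind == "group") {
    g <- lie_exp(model$group, theta)
    rep <- if (model$group$rep_dim == 2L) "vector" else "homogeneous"
    pts <- lie_act(g, model$markers, rep)
    render_cloud(pts, model$cam)
  } else {
    render_cloud(pose_chain(model$chain, theta)$markers, model$cam)
  }
}

#' Sample a stack of frames along a latent grid
#'
#' @param model A [world_model()].
#' @param coeff_grid Matrix of latent vectors (one per row) or a list of
#'   latent vectors.
#' @return Matrix, one frame per row (grid order preserved), with
#'   attribute `raster`.
#' @export
orbit_sample <- function(model, coeff_grid) {
  if (is.list(coeff_grid)) coeff_grid <- do.call(rbind, coeff_grid)
  if (!is.matrix(coeff_grid)) coeff_grid <- matrix(coeff_grid, ncol = 1L)
  if (nrow(coeff_grid) == 0L) stop("coefficient grid is empty")
  out <- matrix(0, nrow(coeff_grid), model$n_pixels)
  for (i in seq_len(nrow(coeff_grid)))
    out[i, ] <- generate_frame(model, coeff_grid[i, ])
  structure(out, raster = c(model$cam$rows, model$cam$cols))
}

# Evaluate an expression under a fixed RNG seed, restoring RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Sampled latent trajectories
#'
#' Produces a deterministic time-sampled latent path theta(t) of one of
#' three kinds: `"constant"` (theta0 forever), `"sinusoid"`
#' (`theta0 + amplitude * sin(2 pi frequency t)` per coordinate) and
#' `"filtered_walk"` (seeded Gaussian walk hard-low-passed in the Fourier
#' domain so that all power lies at or below `cutoff`, then scaled so its
#' root-mean-square deviation from theta0 equals `amplitude`).
#'
#' The defaults encode a *slow* path: amplitude 0.5 rad keeps a rotation
#' world inside a single chart, and frequency 0.05 Hz is well below the
#' default agent bandwidth (leak time constant 0.1 s) so transients
#' complete between appreciable input changes.
#'
#' @param kind Path kind.
#' @param latent_dim Number of latent coordinates.
#' @param duration Path duration in seconds.
#' @param dt Sampling step in seconds.
#' @param theta0 Baseline latent vector (recycled to `latent_dim`).
#' @param amplitude Per-coordinate amplitude (recycled).
#' @param frequency Sinusoid frequency in Hz (recycled).
#' @param phase Sinusoid phase offset in radians (recycled).
#' @param cutoff Filtered-walk low-pass cutoff in Hz.
#' @param seed RNG seed for `"filtered_walk"`.
#' @return Matrix (time x latent_dim) with attribute `times`.
#' @export
latent_path <- function(kind = c("constant", "sinusoid", "filtered_walk"),
                        latent_dim = 1, duration = 20, dt = 0.01,
                        theta0 = 0, amplitude = 0.5, frequency = 0.05,
                        phase = 0, cutoff = 0.5, seed = 1) {
  kind <- match.arg(kind)
  if (dt <= 0 || duration < dt) stop("need dt > 0 and duration >= dt")
  times <- seq(0, duration, by = dt)
  nt <- length(times)
  theta0 <- rep_len(theta0, latent_dim)
  amplitude <- rep_len(amplitude, latent_dim)
  frequency <- rep_len(frequency, latent_dim)
  phase <- rep_len(phase, latent_dim)
  th <- matrix(rep(theta0, each = nt), nt, latent_dim)
  if (kind == "sinusoid") {
    for (k in seq_len(latent_dim))
      th[, k] <- th[, k] +
        amplitude[k] * sin(2 * pi * frequency[k] * times + phase[k])
  } else if (kind == "filtered_walk") {
    noise <- with_seed(seed, matrix(stats::rnorm(nt * latent_dim), nt))
    freqs <- (seq_len(nt) - 1) / (nt * dt)
    freqs <- pmin(freqs, 1 / dt - freqs)      # two-sided frequency axis
    keep <- freqs <= cutoff
    for (k in seq_len(latent_dim)) {
      w <- cumsum(noise[, k])
      sp <- stats::fft(w)
      sp[!keep] <- 0
      f <- Re(stats::fft(sp, inverse = TRUE)) / nt
      f <- f - mean(f)
      rms <- sqrt(mean(f^2))
      if (rms > 0) f <- f * amplitude[k] / rms
      th[, k] <- th[, k] + f
    }
  }
  structure(th, times = times, kind = kind, dt = dt)
}

#' Incompressible reference input stream
#'
#' The structureless counterpart of a world-model stream: every pixel
#' varies in time independently, i.i.d. uniform on `[0, 1]`.  Used as the
#' control condition under which tracking is predicted to fail and the
#' trajectory manifold is not dimensionally reduced.
#'
#' @param n_pixels Pixel count X.
#' @param duration,dt Stream length and step (seconds).
#' @param seed RNG seed (stream is a pure function of it).
#' @param power Optional target mean-square value; the stream is scaled
#'   so `mean(stream^2)` equals it (scaling preserves incompressibility).
#' @return Matrix (time x X) with attribute `times`.
#' @export
incompressible_input <- function(n_pixels, duration, dt, seed = 1,
                                 power = NULL) {
  stopifnot(n_pixels >= 1, dt > 0, duration >= dt)
  nt <- length(seq(0, duration, by = dt))
  s <- with_seed(seed, matrix(stats::runif(nt * n_pixels), nt))
  if (!is.null(power)) s <- s * sqrt(power / mean(s^2))
  structure(s, times = seq(0, duration, by = dt), dt = dt)
}

#' Render a latent path to an input stream
#'
#' @param model A [world_model()].
#' @param path Latent path matrix from [latent_path()].
#' @return Matrix (time x X) of frames with attributes `times`, `raster`.
#' @export
render_path <- function(model, path) {
  st <- orbit_sample(model, unclass(path))
  attr(st, "times") <- attr(path, "times")
  attr(st, "dt") <- attr(path, "dt")
  st
}

#' Write and read P2 portable graymap frames
#'
#' Frames are quantized to `maxval` gray levels.  `write_frame_stack()`
#' writes one PGM per frame plus a tab-separated manifest (frame index,
#' file, latent values).
#'
#' @param frame Frame vector with `raster` attribute.
#' @param path Output file.
#' @param maxval Gray levels (default 255).
#' @return `read_pgm` returns a frame vector with `raster` attribute.
#' @export
write_pgm <- function(frame, path, maxval = 255L) {
  r <- attr(frame, "raster")
  if (is.null(r)) stop("frame carries no raster attribute")
  v <- as.integer(round(pmin(pmax(frame, 0), 1) * maxval))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("P2", sprintf("%d %d", r[2], r[1]), sprintf("%d", maxval)),
             con)
  m <- matrix(v, nrow = r[1], ncol = r[2], byrow = TRUE)
  writeLines(apply(m, 1L, paste, collapse = " "), con)
  invisible(path)
}

#' @rdname write_pgm
#' @export
read_pgm <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  if (trimws(lines[1L]) != "P2") stop("not a P2 graymap: ", path)
  vals <- scan(text = paste(lines[-1L], collapse = " "), quiet = TRUE)
  nc <- vals[1L]; nr <- vals[2L]; maxval <- vals[3L]
  px <- vals[-(1:3)]
  if (length(px) != nr * nc) stop("pixel count mismatch in ", path)
  structure(px / maxval, raster = c(nr, nc))
}

#' @rdname write_pgm
#' @param stack Frame stack (one frame per row) with `raster` attribute.
#' @param dir Output directory (created if missing).
#' @param latents Optional matrix of latent values, one row per frame.
#' @param prefix File name prefix.
#' @export
write_frame_stack <- function(stack, dir, latents = NULL,
                              prefix = "frame") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  r <- attr(stack, "raster")
  files <- character(nrow(stack))
  for (i in seq_len(nrow(stack))) {
    files[i] <- sprintf("%s_%04d.pgm", prefix, i)
    write_pgm(structure(stack[i, ], raster = r),
              file.path(dir, files[i]))
  }
  man <- data.frame(index = seq_len(nrow(stack)), file = files)
  if (!is.null(latents)) {
    latents <- as.matrix(latents)
    colnames(latents) <- sprintf("theta%d", seq_len(ncol(latents)))
    man <- cbind(man, latents)
  }
  utils::write.table(man, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file.path(dir, "manifest.tsv"))
}
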