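# Shared fixtures, built in code.  Expensive fits are memoized per test
# session so unit tests and acceptance tests can share one fit.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Small world/agent for fast unit tests: 8x8 raster, 40-unit reservoir.
small_world <- function() memo("small_world", function()
  world_model(cam = camera(8, 8)))

small_fit <- function() memo("small_fit", function()
  wtne(small_world(), n_hidden = 40, n_train = 9, seed = 3,
       gain_duration = 3, validate_duration = 5))

# Reference study conditions: 16x16 so2 world, 200-unit reservoir.
full_fit <- function() memo("full_fit", function()
  wtne(world_model(), n_hidden = 200, seed = 1))

# Closed-form SE(2) exponential for coefficients (w, a, b) in the
# (rotation, tx, ty) generator order: independent oracle for lie_exp.
se2_exp_closed <- function(w, a, b) {
  if (abs(w) < 1e-300) {
    V <- diag(2)
  } else {
    V <- matrix(c(sin(w), 1 - cos(w), -(1 - cos(w)), sin(w)), 2, 2) / w
  }
  R <- matrix(c(cos(w), sin(w), -sin(w), cos(w)), 2, 2)
  rbind(cbind(R, V %*% c(a, b)), c(0, 0, 1))
}

rot2 <- function(a) matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)

# Random small feedforward net (tanh/logistic mix) for oracle checks.
random_net <- function(dims, seed, acts = NULL) {
  set.seed(seed)
  if (is.null(acts))
    acts <- rep_len(c("tanh", "logistic"), length(dims) - 1L)
  layers <- lapply(seq_len(length(dims) - 1L), function(l)
    layer_spec(matrix(rnorm(dims[l + 1L] * dims[l], sd = 0.6),
                      dims[l + 1L]),
               rnorm(dims[l + 1L], sd = 0.2), acts[l]))
  feedforward_net(layers)
}

# Three-level planar arm with z-axis revolute screws at distinct points:
# the default non-commuting kinematic fixture.
toy_chain <- function() {
  kinematic_chain(
    joints = list(
      screw_joint(c(0, 0, 1), c(0, 0, 0), label = "shoulder"),
      screw_joint(c(0, 0, 1), c(1, 0, 0), label = "elbow"),
      screw_joint(c(1, 0, 0), c(2, 0, 0), label = "wrist_roll")),
    home = rbind(cbind(diag(3), c(2, 0, 0)), c(0, 0, 0, 1)),
    markers = cbind(c(0.5, 0, 0), c(0, 0.3, 0), c(-0.3, -0.2, 0.1),
                    c(0, 0, 0.4), c(0.2, 0.2, -0.2)))
}

# R^3 two-level nested hierarchy fixture: x1 = 0, then x1 = x2 = 0.
nested_hierarchy <- function() {
  constraint_hierarchy(
    coarse_grain_level(matrix(c(1, 0, 0), 1), diag(1), "plane"),
    coarse_grain_level(matrix(c(1, 0, 0, 0, 1, 0), 2, byrow = TRUE),
                       diag(2), "line"))
}

incompatible_hierarchy <- function() {
  constraint_hierarchy(
    coarse_grain_level(matrix(c(1, 0, 0), 1),
                       function(y) y - 1, "x1_is_1"),
    coarse_grain_level(matrix(c(1, 0, 0), 1), diag(1), "x1_is_0"))
}
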