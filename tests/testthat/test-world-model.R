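test_that("product of exponentials reproduces closed-form poses", {
  ch <- toy_chain()
  # zero angles: exactly the home configuration
  p0 <- pose_chain(ch, c(0, 0, 0))
  expect_identical(p0$end_transform, ch$home)
  # single revolute joint about z, identity home: marker flips sign
  ch1 <- kinematic_chain(list(screw_joint(c(0, 0, 1))),
                         markers = cbind(c(1, 0, 0)))
  p <- pose_chain(ch1, pi)
  expect_lt(max(abs(p$markers - c(-1, 0, 0))), 1e-10)
  expect_error(pose_chain(ch, c(0, 0)), "3 joints")
  expect_error(pose_chain(ch1, 4), "outside range")
})

test_that("joint order matters for non-commuting screws", {
  ch <- toy_chain()
  swapped <- kinematic_chain(ch$joints[c(2, 1, 3)], ch$home, ch$markers)
  th <- c(0.6, -0.4, 0.8)
  d <- max(abs(pose_chain(ch, th)$end_transform -
                 pose_chain(swapped, th)$end_transform))
  expect_gt(d, 1e-3)
})

test_that("the splat renderer deposits unit-mass Gaussians", {
  cam <- camera(16, 16, splat_sigma = 1.5)
  expect_equal(as.numeric(render_cloud(matrix(0, 2, 0), cam)),
               numeric(256))
  # single marker at the optical center: arg-max at the raster center
  f <- render_cloud(cbind(c(0, 0, 0)), cam)
  m <- frame_matrix(f)
  ctr <- which(m == max(m), arr.ind = TRUE)
  expect_true(all(ctr[1, ] %in% 8:9))
  # total intensity ~ number of in-frame markers (all >= 3 sigma inside)
  mk <- cbind(c(1, 2, 0), c(-2, 0, 0), c(0, -1, 0))
  expect_equal(sum(render_cloud(mk, cam)), 3, tolerance = 0.01)
})

test_that("generation is the group orbit of the reference image", {
  w <- small_world()
  expect_identical(generate_frame(w, w$reference_latent),
                   w$reference_image)
  # rotation periodicity
  expect_lt(max(abs(generate_frame(w, 1.2) -
                      generate_frame(w, 1.2 + 2 * pi))), 1e-12)
  # group path on latents vs group action on the cloud (property test)
  set.seed(31)
  for (i in 1:20) {
    th <- runif(1, -pi, pi); dl <- runif(1, -1, 1)
    gamma <- lie_exp(w$group, dl)
    lhs <- generate_frame(w, th + dl)
    rhs <- render_cloud(
      lie_act(gamma, lie_act(lie_exp(w$group, th), w$markers)), w$cam)
    expect_lt(max(abs(lhs - rhs)), 1e-12)
  }
  expect_error(generate_frame(w, c(1, 2)), "length 1")
})

test_that("orbit sampling preserves order and inverts cleanly", {
  w <- small_world()
  grid <- matrix(seq(-1, 1, length.out = 7), ncol = 1)
  stack <- orbit_sample(w, grid)
  expect_equal(nrow(stack), 7)
  expect_equal(orbit_sample(w, matrix(0))[1, ],
               as.numeric(w$reference_image))
  # theta and inverse-then-forward give the same frame
  g <- lie_exp(w$group, 0.4)
  th2 <- 0.7
  back <- lie_act(lie_inverse(g), lie_act(g, rot2(th2) %*% w$markers))
  expect_lt(max(abs(render_cloud(back, w$cam) -
                      generate_frame(w, th2))), 1e-12)
})

test_that("latent paths have the declared spectral content", {
  cst <- latent_path("constant", duration = 2, dt = 0.01, theta0 = 0.3)
  expect_equal(as.numeric(cst), rep(0.3, nrow(cst)))
  expect_equal(stats::var(as.numeric(cst)), 0)
  # sinusoid: discrete Fourier peak at the requested frequency
  sp <- latent_path("sinusoid", duration = 40, dt = 0.01,
                    amplitude = 1, frequency = 0.2)
  v <- as.numeric(sp) - mean(sp)
  P <- Mod(stats::fft(v))^2
  nt <- length(v)
  fgrid <- (seq_len(nt) - 1) / (nt * 0.01)
  expect_equal(fgrid[which.max(P[seq_len(nt %/% 2)])], 0.2,
               tolerance = 0.02)
  # filtered walk: <1% of power above the cutoff
  fw <- latent_path("filtered_walk", duration = 40, dt = 0.01,
                    cutoff = 0.5, seed = 4)
  v <- as.numeric(fw) - mean(fw)
  P <- Mod(stats::fft(v))^2
  f2 <- pmin(fgrid, 1 / 0.01 - fgrid)
  expect_lt(sum(P[f2 > 0.5 + 1e-9]) / sum(P), 0.01)
  # determinism
  expect_identical(
    latent_path("filtered_walk", duration = 5, dt = 0.01, seed = 9),
    latent_path("filtered_walk", duration = 5, dt = 0.01, seed = 9))
  expect_error(latent_path("sinusoid", duration = 0.001, dt = 0.01),
               "duration")
})

test_that("incompressible streams are seeded i.i.d. uniforms", {
  s1 <- incompressible_input(25, 4, 0.01, seed = 2)
  expect_identical(s1, incompressible_input(25, 4, 0.01, seed = 2))
  expect_equal(mean(s1[seq_len(400), seq_len(25)]), 0.5,
               tolerance = 0.02)
  # near full rank at the 99% variance cut
  s <- incompressible_input(40, 0.99, 0.01, seed = 3)   # 100 x 40
  d <- effective_dimension(s)$dim_estimate
  expect_gte(d, 0.9 * min(nrow(s) - 1, 40))
  # power matching preserves shape
  sp <- incompressible_input(25, 1, 0.01, seed = 2, power = 0.004)
  expect_equal(mean(sp^2), 0.004, tolerance = 1e-12)
})

test_that("group streams are compressible, noise streams are not", {
  w <- small_world()
  full <- orbit_sample(w, matrix(seq(-pi, pi, length.out = 120), ncol = 1))
  expect_lte(effective_dimension(full)$dim_estimate, 6)
  expect_lte(w$latent_dim, w$n_pixels / 10)
  noise <- incompressible_input(w$n_pixels, 1.19, 0.01, seed = 8)
  expect_gte(effective_dimension(noise)$dim_estimate,
             5 * effective_dimension(full)$dim_estimate)
})

test_that("frames round-trip through P2 graymaps with a manifest", {
  w <- small_world()
  f <- generate_frame(w, 0.5)
  tmp <- withr::local_tempfile(fileext = ".pgm")
  write_pgm(f, tmp)
  expect_identical(readLines(tmp)[1], "P2")
  back <- read_pgm(tmp)
  expect_equal(attr(back, "raster"), attr(f, "raster"))
  expect_lt(max(abs(back - f)), 1 / 255)   # quantization only
  dir <- withr::local_tempdir()
  stack <- orbit_sample(w, matrix(c(-0.2, 0, 0.2), ncol = 1))
  man <- write_frame_stack(stack, dir, latents = c(-0.2, 0, 0.2))
  tab <- utils::read.table(man, header = TRUE, sep = "\t")
  expect_equal(nrow(tab), 3)
  expect_true(all(file.exists(file.path(dir, tab$file))))
})
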