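test_that("a sourceless layout yields the identically zero field", {
  g <- grid_spec(16)
  u <- solve_field(matrix(0, 16, 16), g)
  expect_identical(u, matrix(0, 16, 16))
})

test_that("sparse stationary solve matches Jacobi relaxation and Euler stepping", {
  g <- grid_spec(20, D = 1, gamma = 1 / 25)
  cfg <- source_configuration(list(source_disk(8, 11, 3, 1)), g)
  x <- rasterize(cfg)
  u <- solve_steady_state(cfg, input = x)
  expect_lt(max(abs(u - jacobi_solve(x, g))), 1e-7)
  expect_lt(max(abs(u - euler_solve(x, g))), 1e-6)
})

test_that("solutions obey mirror symmetry and the discrete maximum principle", {
  g <- grid_spec(32)
  for (s in 1:20) {
    cfg <- sample_configuration(g, radius = 5, seed = s)
    u <- solve_steady_state(cfg)
    um <- solve_steady_state(mirror_config(cfg))
    expect_lt(max(abs(um - u[, g$L:1])), 1e-9)
    expect_true(all(u >= -1e-12))
    expect_true(all(u <= max(vapply(cfg$disks, `[[`, 0, "value")) + 1e-12))
  }
})

test_that("strip-source profile matches the 1-d recurrence closed form", {
  # gamma chosen so the diffusion length is 1 pixel: lateral absorbing-edge
  # effects at the center column are ~exp(-L/2), far below tolerance
  L <- 48L
  g <- grid_spec(L, D = 1, gamma = 1)
  r0 <- 19L
  v <- 0.8
  input <- matrix(0, L, L)
  input[r0 + 1L, ] <- v
  u <- solve_field(input, g)
  expect_lt(max(abs(u[, L %/% 2] - strip_1d_closed_form(L, 1, 1, r0, v))), 1e-8)
})

test_that("field decays monotonically away from a single centered disk", {
  g <- grid_spec(41)
  cfg <- source_configuration(list(source_disk(20, 20, 5, 1)), g)
  u <- solve_steady_state(cfg)
  ray <- u[21, 21:41]  # rightward axis ray from the center
  expect_true(all(diff(ray) <= 1e-12))
  ray2 <- u[21:41, 21]
  expect_true(all(diff(ray2) <= 1e-12))
})

test_that("far-apart disks superpose and scaling the free value scales its contribution", {
  # small diffusion length so the disks do not interact above tolerance
  g <- grid_spec(48, D = 1, gamma = 1)
  d1 <- source_disk(23, 12, 4, 1)
  d2 <- source_disk(23, 36, 4, 0.6)
  u_both <- solve_steady_state(source_configuration(list(d1, d2), g))
  u1 <- solve_steady_state(source_configuration(list(d1), g))
  u2 <- solve_steady_state(source_configuration(list(d2), g))
  mask <- rasterize(source_configuration(list(d1, d2), g)) == 0
  expect_lt(max(abs(u_both - (u1 + u2))[mask]), 1e-6)

  # Dirichlet linearity: halving the disk value halves its field
  d2h <- source_disk(23, 36, 4, 0.3)
  u2h <- solve_steady_state(source_configuration(list(d2h), g))
  expect_lt(max(abs(u2h - 0.5 * u2)), 1e-9)
})

test_that("larger decay rates produce pointwise smaller fields outside sources", {
  L <- 32L
  cfg1 <- sample_configuration(grid_spec(L, D = 1, gamma = 1 / 400),
                               radius = 5, seed = 3)
  x <- rasterize(cfg1)
  u_slow <- solve_field(x, grid_spec(L, D = 1, gamma = 1 / 400))
  u_fast <- solve_field(x, grid_spec(L, D = 1, gamma = 1 / 100))
  out <- x == 0
  expect_true(all(u_fast[out] <= u_slow[out] + 1e-12))
  expect_true(any(u_fast[out] < u_slow[out]))
})

test_that("dataset generation is deterministic, split correctly, and invariant-clean", {
  g <- grid_spec(24)
  ds1 <- generate_dataset(10, seed = 5, grid = g, radius = 3)
  ds2 <- generate_dataset(10, seed = 5, grid = g, radius = 3)
  expect_identical(ds1, ds2)
  expect_identical(ds1$train_idx, 1:8)
  expect_identical(ds1$test_idx, 9:10)
  expect_length(intersect(ds1$train_idx, ds1$test_idx), 0)
  expect_true(all(ds1$targets >= 0 & ds1$targets <= 1))
  # boundary pixels stay below interior levels under the zero ghost boundary
  expect_true(all(ds1$targets[1, , ] < 1 - 1e-9))

  ds3 <- generate_dataset(10, seed = 6, grid = g, radius = 3)
  expect_false(identical(ds1$inputs, ds3$inputs))
})

test_that("dataset containers round-trip through disk", {
  g <- grid_spec(16)
  ds <- generate_dataset(4, seed = 9, grid = g, radius = 2)
  f <- tempfile(fileext = ".rds")
  dataset_save(ds, f)
  expect_identical(dataset_load(f), ds)
  unlink(f)
})
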