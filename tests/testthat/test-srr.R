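delta_model <- function(spacing = 1, thickness = 1, sigma = 0) {
  acquisition_model(spacing, thickness, blur_fwhm = 1e-6,
                    noise_sigma = sigma)
}

test_that("initialization from a single identity stack is that stack", {
  v <- gaussian_blob(12)
  st <- suppressWarnings(
    simulate_lr_stack(v, list(kind = "shifted", shift_mm = 0),
                      delta_model())
  )
  init <- ibp_initialize(list(st))
  expect_equal(init$data, v$data, tolerance = 1e-12)
})

test_that("initialization averages stacks voxelwise", {
  mk <- function(value) {
    v <- srr_volume(array(value, c(6, 6, 6)), 1,
                    meta = list(background = value))
    suppressWarnings(
      simulate_lr_stack(v, list(kind = "shifted", shift_mm = 0),
                        delta_model())
    )
  }
  init <- ibp_initialize(list(mk(4), mk(6)))
  expect_equal(unique(as.numeric(init$data)), 5)
  expect_error(ibp_initialize(list()), "at least one")
})

test_that("averaging three orthogonal stacks beats any single stack", {
  v <- gaussian_blob(32, width = 50)
  plan <- plan_orthogonal(4, 1)
  model <- acquisition_model(1, 4)
  stacks <- simulate_plan(v, plan, model)
  init <- ibp_initialize(stacks)
  err_init <- rms_diff(init, v)
  for (k in 1:3) {
    single <- transform_volume(upsample_stack(stacks[[k]]), plan[k, ],
                               "inverse")
    expect_lt(err_init, rms_diff(single, v))
  }
})

test_that("simulating from the generating volume reproduces the stacks", {
  v <- gaussian_blob(24, width = 30)
  plan <- plan_orthogonal(4, 1)
  stacks <- simulate_plan(v, plan, acquisition_model(1, 4))
  sim <- ibp_simulate(v, stacks)
  for (k in 1:3)
    expect_equal(sim[[k]]$data, stacks[[k]]$data, tolerance = 1e-9)
  # linearity of the forward model
  v2 <- v; v2$data <- 2 * v$data
  sim2 <- ibp_simulate(v2, stacks)
  for (k in 1:3)
    expect_equal(sim2[[k]]$data, 2 * sim[[k]]$data, tolerance = 1e-9)
})

test_that("residual norms match an independent computation", {
  v <- gaussian_blob(16)
  st <- simulate_lr_stack(v, list(kind = "shifted", shift_mm = 0),
                          acquisition_model(1, 2))
  expect_equal(ibp_residual(list(st), list(st)), 0)
  st2 <- st
  st2$data <- st$data + 3.5
  expect_equal(ibp_residual(list(st), list(st2), "max_abs"), 3.5)
  set.seed(99)
  st3 <- st
  st3$data <- st$data + array(rnorm(length(st$data)), dim(st$data))
  d <- st$data - st3$data
  expect_equal(ibp_residual(list(st), list(st3), "rms"),
               sqrt(mean(d^2)), tolerance = 1e-12)
  expect_error(ibp_residual(list(st), list(st, st2)), "length")
})

test_that("the update is a fixed point at zero difference and adds DC", {
  v <- gaussian_blob(12)
  st <- suppressWarnings(
    simulate_lr_stack(v, list(kind = "shifted", shift_mm = 0),
                      delta_model())
  )
  est <- ibp_initialize(list(st))
  upd <- ibp_update(est, list(st), list(st))
  expect_equal(upd$data, est$data, tolerance = 1e-14)
  st_lo <- st
  st_lo$data <- st$data - 2.5
  upd2 <- ibp_update(est, list(st), list(st_lo))
  expect_equal(upd2$data, est$data + 2.5, tolerance = 1e-12)
})

test_that("a two-stack update equals the hand-computed mean difference", {
  v <- gaussian_blob(12)
  g <- list(kind = "shifted", shift_mm = 0)
  obs <- lapply(c(31, 32), function(s)
    suppressWarnings(simulate_lr_stack(v, g, delta_model(sigma = 2), seed = s)))
  est <- ibp_initialize(obs)
  sim <- suppressWarnings(ibp_simulate(est, obs))
  upd <- ibp_update(est, obs, sim)
  # identity geometry at AR 1: upsampling and inverse transform are the
  # identity, so the update is the plain mean of the two difference stacks
  manual <- est$data +
    ((obs[[1]]$data - sim[[1]]$data) + (obs[[2]]$data - sim[[2]]$data)) / 2
  expect_equal(upd$data, manual, tolerance = 1e-12)
})

test_that("degenerate single-stack reconstruction converges immediately", {
  v <- gaussian_blob(12)
  st <- suppressWarnings(
    simulate_lr_stack(v, list(kind = "shifted", shift_mm = 0),
                      delta_model())
  )
  fit <- suppressWarnings(ibp_reconstruct(list(st)))
  expect_true(fit$converged)
  expect_equal(fit$iterations_run, 1L)
  expect_equal(fit$trace$residual, 0)
  expect_equal(fit$volume$data, v$data, tolerance = 1e-12)
})

test_that("reconstruction improves on initialization and residuals decay", {
  ph <- make_resolution_phantom(grid_shape = 64, spacing = 26 / 64)
  plan <- plan_orthogonal(4 * 26 / 64, 26 / 64)
  model <- acquisition_model(26 / 64, 4 * 26 / 64)
  stacks <- simulate_plan(ph, plan, model)
  cfg <- ibp_config(max_iterations = 5, residual_threshold = 0,
                    fill_value = 100)
  fit <- ibp_reconstruct(stacks, cfg)
  init <- ibp_initialize(stacks, cfg)
  expect_lt(rms_diff(fit$volume, ph), rms_diff(init, ph))
  expect_lte(fit$trace$residual[5], fit$trace$residual[1])
})

test_that("forward-model consistency drives the AR 1 residual to the floor", {
  v <- gaussian_blob(24, width = 60)
  st <- simulate_lr_stack(v, list(kind = "shifted", shift_mm = 0),
                          acquisition_model(1, 1))  # blur FWHM = spacing
  dr <- diff(range(st$data))
  fit <- ibp_reconstruct(list(st),
                         ibp_config(max_iterations = 60,
                                    residual_threshold = 1e-6 * dr))
  expect_true(fit$converged)
  expect_lt(tail(fit$trace$residual, 1), 1e-6 * dr)
})

test_that("non-finite stack data cannot reach the estimate silently", {
  v <- gaussian_blob(8)
  st <- simulate_lr_stack(v, list(kind = "shifted", shift_mm = 0),
                          acquisition_model(1, 2))
  st$data[1] <- NaN
  expect_error(ibp_reconstruct(list(st), ibp_config(residual_threshold = 0)),
               "finite")
})
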