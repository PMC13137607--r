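# Guidance correction, flow-matching and diffusion samplers, posterior
# sampling, and the minimizer.

test_that("guidance step has the closed-form behaviour on a quadratic", {
  # E = ||x||^2 has gradient 2x and Lipschitz constant L = 2
  x <- withr::with_seed(1, matrix(rnorm(30), 10, 3))
  cfg <- guidance_config(lam = 0.25, normalize_gradient = "off")
  x_new <- guidance_step(x, params = NULL, cfg = cfg,
                         grad_fn = function(z) 2 * z)
  expect_equal(sum(x_new^2), (1 - 2 * 0.25)^2 * sum(x^2), tolerance = 1e-12)
  # lambda -> 0 limit: output -> input
  cfg0 <- guidance_config(lam = 1e-12, normalize_gradient = "off")
  x_eps <- guidance_step(x, params = NULL, cfg = cfg0,
                         grad_fn = function(z) 2 * z)
  expect_lt(max(abs(x_eps - x)), 1e-10)
  # lambda = 0 is the exact identity
  expect_identical(
    guidance_step(x, params = NULL, cfg = guidance_config(lam = 0)), x)
})

test_that("a small normalized guidance step lowers molecular energy", {
  lig <- fx_set(10, seed = 1)[[4]]
  p <- fx_params(10, seed = 1)[[4]]
  x <- lig$coords + withr::with_seed(3, matrix(rnorm(3 * p$natoms,
                                                     sd = 0.15), ncol = 3))
  before <- total_energy(x, p)$total
  cfg <- guidance_config(lam = 0.01, normalize_gradient = "rms_per_atom")
  after <- total_energy(guidance_step(x, p, cfg = cfg), p)$total
  expect_lt(after, before)
})

test_that("unnormalized steps below 2/L descend; far above may not", {
  params <- fx_params(10, seed = 1)
  descended <- increased <- 0L
  for (b in seq_along(params)) {
    p <- params[[b]]
    x <- p$coords + withr::with_seed(b, matrix(rnorm(3 * p$natoms,
                                                     sd = 0.08), ncol = 3))
    g <- gradient_total(x, p)
    # local Lipschitz estimate: power iteration on the Hessian via
    # finite-difference Hessian-vector products
    v <- withr::with_seed(b + 50, matrix(rnorm(3 * p$natoms), ncol = 3))
    v <- v / sqrt(sum(v^2))
    L <- NA
    for (it in 1:15) {
      hv <- (gradient_total(x + 1e-4 * v, p) -
               gradient_total(x - 1e-4 * v, p)) / 2e-4
      L <- sqrt(sum(hv^2))
      v <- hv / max(L, 1e-12)
    }
    e0 <- total_energy(x, p)$total
    cfg <- guidance_config(lam = 1 / L, normalize_gradient = "off")
    e1 <- total_energy(guidance_step(x, p, cfg = cfg), p)$total
    if (e1 < e0) descended <- descended + 1L
    cfg4 <- guidance_config(lam = 4 / L, normalize_gradient = "off")
    e4 <- total_energy(guidance_step(x, p, cfg = cfg4), p)$total
    if (e4 > e0) increased <- increased + 1L
  }
  expect_identical(descended, length(params))  # lambda = 1/L always descends
  expect_gt(increased, 0L)                     # 4/L overshoots somewhere
})

test_that("parameterization failure is skipped or raised per config", {
  x <- matrix(0, 2, 3)
  cfg_skip <- guidance_config(lam = 0.1, skip_on_param_failure = TRUE)
  expect_warning(out <- guidance_step(x, params = NULL, cfg = cfg_skip),
                 "skipped")
  expect_identical(out, x)
  cfg_hard <- guidance_config(lam = 0.1, skip_on_param_failure = FALSE)
  expect_error(guidance_step(x, params = NULL, cfg = cfg_hard),
               class = "ffguide_parameterization_error")
})

test_that("the flow sampler is exact for a constant clean-sample field", {
  lig <- fx_set(10, seed = 1)[[1]]
  den <- make_toy_denoiser("perfect", lig)
  x0 <- withr::with_seed(5, matrix(rnorm(length(lig$coords)), ncol = 3))
  for (steps in c(1, 3, 7, 50)) {
    xf <- flow_sample(x0, den, steps = steps)
    expect_lt(max(abs(xf - lig$coords)), 1e-10)
  }
  # one step returns the t = 0 prediction itself
  den2 <- function(x, t, pocket = NULL) x * 0.5
  expect_equal(flow_sample(x0, den2, steps = 1), x0 * 0.5,
               tolerance = 1e-12)
  # atom-count violations are caught
  bad <- function(x, t, pocket = NULL) x[-1, , drop = FALSE]
  expect_error(flow_sample(x0, bad, steps = 2), "dimensions")
})

test_that("posterior sampling follows the scalar coefficient oracle", {
  sch <- diffusion_schedule(30)
  n <- 4
  xhat <- withr::with_seed(8, matrix(rnorm(3 * n), n, 3))
  xt <- withr::with_seed(9, matrix(rnorm(3 * n), n, 3))
  for (s in c(1, 2, 7, 15, 30)) {
    ab_s <- sch$alpha_bar[s + 1]; ab_p <- sch$alpha_bar[s]
    a_s <- ab_s / ab_p; b_s <- 1 - a_s
    c1 <- sqrt(ab_p) * b_s / (1 - ab_s)
    c2 <- sqrt(a_s) * (1 - ab_p) / (1 - ab_s)
    vv <- b_s * (1 - ab_p) / (1 - ab_s)
    got <- withr::with_seed(77, compute_posterior(xhat, xt, s, sch))
    want <- c1 * xhat + c2 * xt
    if (s > 1) {
      want <- want + sqrt(vv) * withr::with_seed(77, matrix(rnorm(3 * n),
                                                            n, 3))
    }
    expect_equal(got, want, tolerance = 1e-12)
  }
  # the final step is deterministic and returns xhat exactly
  expect_identical(withr::with_seed(1, compute_posterior(xhat, xt, 1, sch)),
                   withr::with_seed(2, compute_posterior(xhat, xt, 1, sch)))
  expect_equal(compute_posterior(xhat, xt, 1, sch), xhat, tolerance = 1e-12)
  # near the clean end of a fine schedule the posterior mean is
  # (approximately) a convex combination: for xhat = xt the mean
  # coefficients sum to ~1 (the identity is exact only at the terminal
  # step and degrades toward the noisy end)
  sch100 <- diffusion_schedule(100)
  coef_sum <- function(s, sch) {
    ab_s <- sch$alpha_bar[s + 1]; ab_p <- sch$alpha_bar[s]
    a_s <- ab_s / ab_p
    (sqrt(ab_p) * (1 - a_s) + sqrt(a_s) * (1 - ab_p)) / (1 - ab_s)
  }
  expect_identical(coef_sum(1, sch100), 1)
  for (s in 2:5) expect_lt(abs(coef_sum(s, sch100) - 1), 0.01)
  expect_error(compute_posterior(xhat, xt, 0, sch), "range")
  expect_error(compute_posterior(xhat, xt, 31, sch), "range")
})

test_that("the diffusion sampler contracts to the prediction and is seeded", {
  lig <- fx_set(10, seed = 1)[[2]]
  den <- make_toy_denoiser("perfect", lig)
  sch <- diffusion_schedule(10)
  xT <- withr::with_seed(6, matrix(rnorm(length(lig$coords)), ncol = 3))
  xf <- diffusion_sample(xT, den, schedule = sch, seed = 123)
  expect_lt(max(abs(xf - lig$coords)), 1e-6)
  # bit-identical trajectories for a fixed seed
  den2 <- make_toy_denoiser("noisy_target", lig, seed = 2)
  r1 <- diffusion_sample(xT, den2, schedule = sch, seed = 99)
  r2 <- diffusion_sample(xT, den2, schedule = sch, seed = 99)
  expect_identical(r1, r2)
  r3 <- diffusion_sample(xT, den2, schedule = sch, seed = 100)
  expect_false(identical(r1, r3))
})

test_that("zero-lambda guided samplers are bit-identical to the base ones", {
  lig <- fx_set(10, seed = 1)[[3]]
  p <- fx_params(10, seed = 1)[[3]]
  den <- make_toy_denoiser("noisy_target", lig, seed = 4)
  sch <- diffusion_schedule(12)
  cfg0 <- guidance_config(lam = 0)
  for (seed in 1:5) {
    x0 <- withr::with_seed(seed, matrix(rnorm(length(lig$coords)),
                                        ncol = 3))
    expect_identical(flow_sample(x0, den, steps = 9, cfg = cfg0,
                                 params = p),
                     flow_sample(x0, den, steps = 9))
    expect_identical(diffusion_sample(x0, den, schedule = sch, cfg = cfg0,
                                      params = p, seed = seed),
                     diffusion_sample(x0, den, schedule = sch, seed = seed))
  }
})

test_that("guided sampling lowers the mean final energy (paired)", {
  lig <- fx_set(10, seed = 1)[[1]]   # ethanol: small and quick
  p <- fx_params(10, seed = 1)[[1]]
  cfg <- guidance_config(lam = 0.05)
  n_pairs <- 40
  d_flow <- d_diff <- numeric(n_pairs)
  sch <- diffusion_schedule(15)
  for (k in seq_len(n_pairs)) {
    den <- make_toy_denoiser("strained_target", lig, seed = 1000 + k)
    x0 <- withr::with_seed(2000 + k, matrix(rnorm(length(lig$coords)),
                                            ncol = 3))
    e_u <- total_energy(flow_sample(x0, den, steps = 12), p)$total
    e_g <- total_energy(flow_sample(x0, den, steps = 12, cfg = cfg,
                                    params = p), p)$total
    d_flow[k] <- e_g - e_u
    e_u2 <- total_energy(diffusion_sample(x0, den, schedule = sch,
                                          seed = k), p)$total
    e_g2 <- total_energy(diffusion_sample(x0, den, schedule = sch,
                                          cfg = cfg, params = p,
                                          seed = k), p)$total
    d_diff[k] <- e_g2 - e_u2
  }
  expect_lt(mean(d_flow), 0)
  expect_lt(mean(d_diff), 0)
  expect_lt(t.test(d_flow, alternative = "less")$p.value, 0.01)
  expect_lt(t.test(d_diff, alternative = "less")$p.value, 0.01)
})

test_that("guidance can be restricted to a time window", {
  lig <- fx_set(10, seed = 1)[[1]]
  p <- fx_params(10, seed = 1)[[1]]
  den <- make_toy_denoiser("noisy_target", lig, seed = 1)
  x0 <- withr::with_seed(1, matrix(rnorm(length(lig$coords)), ncol = 3))
  cfg_none <- guidance_config(lam = 0.05, guidance_start_t = 2,
                              guidance_end_t = 3)
  expect_error(guidance_config(lam = 0.05, guidance_start_t = 0.9,
                               guidance_end_t = 0.1), "start")
  # a window past t = 1 never triggers: identical to unguided
  expect_identical(flow_sample(x0, den, steps = 8, cfg = cfg_none,
                               params = p),
                   flow_sample(x0, den, steps = 8))
})

test_that("the minimizer is monotone and finds the reference minimum", {
  ligs <- fx_set(10, seed = 1)[c(1, 4, 9)]
  params <- fx_params(10, seed = 1)[c(1, 4, 9)]
  for (k in seq_along(ligs)) {
    p <- params[[k]]
    p$coords <- p$coords + withr::with_seed(k, matrix(
      rnorm(3 * p$natoms, sd = 0.1), ncol = 3))
    res <- minimize(p, max_iters = 2000, tol_grad = 1e-3)
    expect_true(all(diff(res$energy_trace) <= 1e-12))
    expect_lte(res$energy$total, res$energy_trace[1])
    lig_start <- ligs[[k]]; lig_start$coords <- p$coords
    ref <- mmff_reference_minimize(lig_start)
    expect_lt(abs(res$energy$total - ref$energies[1]), 0.5)
  }
})

test_that("an already-converged geometry is a minimizer fixed point", {
  p <- fx_params(10, seed = 1)[[5]]
  first <- minimize(p, max_iters = 3000, tol_grad = 1e-3)
  p$coords <- first$coords
  again <- minimize(p, tol_grad = 1e-3)
  expect_identical(again$iterations, 0L)
  expect_identical(again$coords, first$coords)
})

test_that("conditional minimization honours the rigid pocket", {
  p <- fx_params(10, seed = 1)[[2]]
  pk <- make_toy_pocket("point_charges", seed = 6)
  res <- minimize(p, pocket = pk, max_iters = 400, tol_grad = 0.05)
  expect_true(all(diff(res$energy_trace) <= 1e-12))
  expect_true(res$energy$cross_vdw != 0 || res$energy$cross_electrostatic != 0)
})
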