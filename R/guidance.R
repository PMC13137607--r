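# Energy-guided sampling: the gradient correction step, the Euler
# flow-matching sampler, the DDPM-style diffusion sampler with posterior
# sampling, and their guided variants. The guidance is applied to the
# predicted clean structure (X-hat) before each integration/posterior
# update, because the clean-sample parameterization is what makes the
# molecular energy computable mid-trajectory. Guidance touches coordinates
# only; categorical atom/bond state rides along unchanged.

#' Guidance configuration
#'
#' @param lam Step scale lambda > 0 (with `rms_per_atom` normalization,
#'   lambda is the RMS per-atom displacement in Angstrom). A zero value
#'   disables the correction, reducing guided samplers bit-for-bit to
#'   their unguided counterparts.
#' @param normalize_gradient One of `"rms_per_atom"` (default: divide the
#'   gradient by its root-mean-square per-atom norm), `"global_norm"`
#'   (divide by the Frobenius norm), or `"off"` (raw gradient; lambda then
#'   has units A^2 mol/kcal and the descent guarantee lambda < 2/L
#'   applies).
#' @param guidance_start_t,guidance_end_t Apply the correction only for
#'   sampler times t in this window (defaults: the whole trajectory).
#' @param skip_on_param_failure If `TRUE` (default), a failed or missing
#'   parameterization makes the step a no-op (with a warning) instead of
#'   an error, so guided sampling degrades gracefully to the base
#'   algorithm on bad intermediate structures.
#' @return An object of class `guidance_config`.
#' @export
guidance_config <- function(lam = 0.1,
                            normalize_gradient = c("rms_per_atom",
                                                   "global_norm", "off"),
                            guidance_start_t = 0, guidance_end_t = 1,
                            skip_on_param_failure = TRUE) {
  if (!is.numeric(lam) || lam < 0) stop("lam must be >= 0")
  if (guidance_start_t > guidance_end_t) stop("guidance_start_t > guidance_end_t")
  structure(list(lam = lam,
                 normalize_gradient = match.arg(normalize_gradient),
                 guidance_start_t = guidance_start_t,
                 guidance_end_t = guidance_end_t,
                 skip_on_param_failure = skip_on_param_failure),
            class = "guidance_config")
}

normalize_grad <- function(g, mode) {
  switch(mode,
         off = g,
         rms_per_atom = {
           rms <- sqrt(mean(rowSums(g^2)))
           if (rms > 0) g / rms else g
         },
         global_norm = {
           nrm <- sqrt(sum(g^2))
           if (nrm > 0) g / nrm else g
         })
}

#' Energy-guidance correction step
#'
#' Returns `xhat1 - lambda * g`, where `g` is the (optionally normalized)
#' gradient of the total energy at `xhat1`. With `normalize_gradient =
#' "off"` and `lambda < 2/L` (L the local Lipschitz constant of the
#' gradient) this is a descent step: the total energy does not increase.
#'
#' @param xhat1 N x 3 predicted clean coordinates.
#' @param params `mmff_params` for the structure, or `NULL` if
#'   parameterization failed upstream (behaviour then controlled by
#'   `cfg$skip_on_param_failure`).
#' @param pocket Optional [pocket_structure()] for the cross-terms.
#' @param cfg A [guidance_config()].
#' @param spec A [cross_term_spec()].
#' @param grad_fn Optional override: a function `x -> N x 3 gradient`,
#'   replacing the force-field gradient (used for surrogate potentials).
#' @return Corrected N x 3 coordinates.
#' @export
guidance_step <- function(xhat1, params, pocket = NULL,
                          cfg = guidance_config(),
                          spec = cross_term_spec(), grad_fn = NULL) {
  xhat1 <- as.matrix(xhat1)
  if (cfg$lam == 0) return(xhat1)
  if (is.null(grad_fn) && is.null(params)) {
    if (cfg$skip_on_param_failure) {
      warning("no parameterization available; guidance step skipped",
              call. = FALSE)
      return(xhat1)
    }
    stop(parameterization_error("guidance step requires a parameter set"))
  }
  g <- tryCatch(
    if (is.null(grad_fn)) gradient_total(xhat1, params, pocket, spec)
    else grad_fn(xhat1),
    error = function(e) {
      if (cfg$skip_on_param_failure) NULL else stop(e)
    })
  if (is.null(g) || !all(is.finite(g))) {
    if (!is.null(g)) warning("non-finite guidance gradient; step skipped",
                             call. = FALSE)
    return(xhat1)
  }
  xhat1 - cfg$lam * normalize_grad(g, cfg$normalize_gradient)
}

check_denoised <- function(xhat, x) {
  xhat <- as.matrix(xhat)
  if (!identical(dim(xhat), dim(x))) {
    stop("denoiser changed the coordinate dimensions (",
         paste(dim(xhat), collapse = "x"), " vs ",
         paste(dim(x), collapse = "x"), ")")
  }
  xhat
}

in_guidance_window <- function(t, cfg) {
  !is.null(cfg) && t >= cfg$guidance_start_t && t <= cfg$guidance_end_t
}

#' Euler flow-matching sampler
#'
#' Integrates the recovered vector field `u = (xhat1 - x_t) / (1 - t)` from
#' t = 0 to t = 1 with uniform steps, where `xhat1` is the denoiser's
#' clean-sample prediction. When a [guidance_config()] is supplied, `xhat1`
#' is corrected by [guidance_step()] before each update (within the
#' configured time window).
#'
#' @param x0 N x 3 prior draw (t = 0 state).
#' @param denoiser A function `(x_t, t, pocket) -> xhat1` (see
#'   [make_toy_denoiser()] for test denoisers).
#' @param pocket Optional [pocket_structure()], passed to the denoiser and
#'   to the guidance cross-terms.
#' @param steps Number of Euler steps (>= 1).
#' @param cfg Optional [guidance_config()]; `NULL` means unguided.
#' @param params Optional `mmff_params` of the molecule being generated
#'   (needed for force-field guidance; the atom graph is fixed during
#'   sampling, so one parameterization serves the whole trajectory).
#' @param spec A [cross_term_spec()].
#' @param trace If `TRUE`, attach per-step times and (when `params` is
#'   given) total energies of the running prediction as an attribute.
#' @return Final N x 3 coordinates.
#' @export
flow_sample <- function(x0, denoiser, pocket = NULL, steps,
                        cfg = NULL, params = NULL,
                        spec = cross_term_spec(), trace = FALSE) {
  stopifnot(steps >= 1)
  x <- as.matrix(x0)
  dt <- 1 / steps
  log_t <- log_e <- numeric(0)
  for (s in seq_len(steps) - 1L) {
    t <- s * dt
    xhat <- check_denoised(denoiser(x, t, pocket), x)
    if (in_guidance_window(t, cfg)) {
      xhat <- guidance_step(xhat, params, pocket, cfg, spec)
    }
    u <- (xhat - x) / max(1 - t, 1e-6)
    x <- x + dt * u
    if (trace && !is.null(params)) {
      log_t <- c(log_t, t)
      log_e <- c(log_e, total_energy(xhat, params, pocket, spec)$total)
    }
  }
  if (trace) attr(x, "trace") <- data.frame(t = log_t, energy = log_e)
  x
}

#' Diffusion noise schedule
#'
#' Discrete forward-process schedule for the diffusion sampler, stored as
#' the cumulative signal fraction (alpha-bar) sequence over `n_steps`
#' steps, with the time relabeling tau(t) = round(T (1 - t)) so that
#' tau(1) is the clean end and tau(0) the fully noised end.
#'
#' @param n_steps Total step count T.
#' @param kind `"cosine"` (default) or `"linear"` beta schedule.
#' @return An object of class `diffusion_schedule` with fields `n_steps`
#'   and `alpha_bar` (length T + 1, `alpha_bar[1] = 1` is the clean end,
#'   strictly decreasing).
#' @export
diffusion_schedule <- function(n_steps = 100, kind = c("cosine", "linear")) {
  kind <- match.arg(kind)
  stopifnot(n_steps >= 1)
  s_idx <- 0:n_steps
  if (kind == "cosine") {
    f <- cos(((s_idx / n_steps + 0.008) / 1.008) * pi / 2)^2
    ab <- f / f[1]
    ab <- pmin(pmax(ab, 1e-6), 1)
  } else {
    beta <- seq(1e-4, 0.2, length.out = n_steps)
    ab <- c(1, cumprod(1 - beta))
  }
  ab[1] <- 1
  structure(list(n_steps = as.integer(n_steps), alpha_bar = ab,
                 kind = kind),
            class = "diffusion_schedule")
}

#' Relabel continuous time to a diffusion step index
#' @param t Time in `[0, 1]` (1 = clean).
#' @param schedule A [diffusion_schedule()].
#' @return Integer step index tau(t) = round(T (1 - t)).
#' @export
tau_index <- function(t, schedule) {
  as.integer(round(schedule$n_steps * (1 - t)))
}

#' Sample from the forward-process posterior
#'
#' Draws `x_{s-1}` from the Gaussian posterior `q(x_{s-1} | x_s, xhat1)` of
#' the forward noising process, given the current noisy sample `xt` at step
#' `s = step_index` and the clean-sample estimate `xhat1`. The mean is the
#' schedule-weighted combination of `xhat1` and `xt`; the variance is the
#' standard posterior variance. The final step (`step_index = 1`) is
#' deterministic: it returns the posterior mean, which there equals
#' `xhat1`.
#'
#' @param xhat1 Clean-sample estimate, N x 3.
#' @param xt Current noisy sample, N x 3.
#' @param step_index Step `s` in `1..T` (1 is the last, least-noisy step).
#' @param schedule A [diffusion_schedule()].
#' @return N x 3 sample (uses the current RNG stream).
#' @export
compute_posterior <- function(xhat1, xt, step_index, schedule) {
  s <- as.integer(step_index)
  if (s < 1 || s > schedule$n_steps) {
    stop("step_index out of range 1..", schedule$n_steps)
  }
  ab_s <- schedule$alpha_bar[s + 1]
  ab_prev <- schedule$alpha_bar[s]
  alpha_s <- ab_s / ab_prev
  beta_s <- 1 - alpha_s
  c1 <- sqrt(ab_prev) * beta_s / (1 - ab_s)
  c2 <- sqrt(alpha_s) * (1 - ab_prev) / (1 - ab_s)
  var_s <- beta_s * (1 - ab_prev) / (1 - ab_s)
  mean_s <- c1 * as.matrix(xhat1) + c2 * as.matrix(xt)
  if (s == 1 || var_s <= 0) return(mean_s)
  mean_s + sqrt(var_s) * matrix(stats::rnorm(length(mean_s)),
                                nrow(mean_s), ncol(mean_s))
}

#' Diffusion sampler with clean-sample prediction
#'
#' Iterates denoise -> (optional guidance correction of the clean-sample
#' estimate) -> posterior sampling from step T down to 1. Reproducible
#' given `seed`.
#'
#' @inheritParams flow_sample
#' @param xT N x 3 prior draw (fully noised state).
#' @param schedule A [diffusion_schedule()].
#' @param seed Optional integer seed for the posterior noise; the global
#'   RNG state is preserved.
#' @return Final N x 3 coordinates.
#' @export
diffusion_sample <- function(xT, denoiser, pocket = NULL,
                             schedule = diffusion_schedule(),
                             cfg = NULL, params = NULL,
                             spec = cross_term_spec(), seed = NULL,
                             trace = FALSE) {
  run <- function() {
    x <- as.matrix(xT)
    log_t <- log_e <- numeric(0)
    for (s in schedule$n_steps:1) {
      t <- 1 - s / schedule$n_steps
      xhat <- check_denoised(denoiser(x, t, pocket), x)
      if (in_guidance_window(t, cfg)) {
        xhat <- guidance_step(xhat, params, pocket, cfg, spec)
      }
      x <- compute_posterior(xhat, x, s, schedule)
      if (trace && !is.null(params)) {
        log_t <- c(log_t, t)
        log_e <- c(log_e, total_energy(xhat, params, pocket, spec)$total)
      }
    }
    if (trace) attr(x, "trace") <- data.frame(t = log_t, energy = log_e)
    x
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
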