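# Protein-conditioned post-optimization: monotone descent on the total
# energy over ligand coordinates with a rigid pocket. L-BFGS directions
# with Armijo backtracking, falling back to steepest descent when the
# quasi-Newton direction is not a descent direction.

#' Minimize a ligand's total energy
#'
#' Gradient-based descent on [total_energy()] with respect to ligand
#' coordinates, the pocket (if any) held rigid. Line-search (Armijo
#' backtracking on L-BFGS directions) guarantees the accepted energy
#' sequence is non-increasing; the final energy is never above the
#' initial one.
#'
#' @param ligand A [ligand_graph()] (parameterizable), or an `mmff_params`
#'   object (its stored coordinates are then the start).
#' @param pocket Optional [pocket_structure()] for conditional
#'   minimization; `NULL` minimizes the intramolecular energy only.
#' @param max_iters Iteration cap.
#' @param tol_grad Convergence threshold on the gradient max-norm,
#'   kcal/mol/Angstrom.
#' @param spec A [cross_term_spec()].
#' @return A list with `ligand` (coordinates updated; pass-through when the
#'   input was a parameter set), `energy` (final `energy_breakdown`),
#'   `coords`, `iterations`, `converged`, and `energy_trace`.
#' @export
minimize <- function(ligand, pocket = NULL, max_iters = 1000,
                     tol_grad = 0.01, spec = cross_term_spec()) {
  if (inherits(ligand, "mmff_params")) {
    params <- ligand
    lig_out <- NULL
    x <- params$coords
  } else {
    stopifnot(inherits(ligand, "ligand_graph"))
    params <- parameterize(ligand)
    lig_out <- ligand
    x <- ligand$coords
  }
  fn <- function(x) total_energy(x, params, pocket, spec)$total
  gr <- function(x) gradient_total(x, params, pocket, spec)

  n <- length(x)
  mem_s <- list(); mem_y <- list(); mem_rho <- numeric(0)
  m_max <- 8
  f <- fn(x)
  g <- gr(x)
  trace <- f
  iters <- 0L
  converged <- max(abs(g)) < tol_grad
  while (!converged && iters < max_iters) {
    iters <- iters + 1L
    # two-loop recursion
    q <- as.vector(g)
    k <- length(mem_s)
    alpha <- numeric(k)
    if (k > 0) {
      for (i in k:1) {
        alpha[i] <- mem_rho[i] * sum(mem_s[[i]] * q)
        q <- q - alpha[i] * mem_y[[i]]
      }
      gamma <- sum(mem_s[[k]] * mem_y[[k]]) / sum(mem_y[[k]]^2)
      q <- q * gamma
      for (i in 1:k) {
        beta <- mem_rho[i] * sum(mem_y[[i]] * q)
        q <- q + mem_s[[i]] * (alpha[i] - beta)
      }
    } else {
      q <- q / max(sqrt(sum(q^2)), 1)   # bounded first step
    }
    d <- -matrix(q, nrow(x), 3)
    gd <- sum(g * d)
    if (!is.finite(gd) || gd >= 0) {   # not a descent direction: reset
      mem_s <- list(); mem_y <- list(); mem_rho <- numeric(0)
      d <- -g / max(sqrt(sum(g^2)), 1)
      gd <- sum(g * d)
    }
    # Armijo backtracking
    step <- 1
    accepted <- FALSE
    for (ls in 1:30) {
      x_new <- x + step * d
      f_new <- fn(x_new)
      if (is.finite(f_new) && f_new <= f + 1e-4 * step * gd) {
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) break               # cannot decrease further
    g_new <- gr(x_new)
    s_vec <- as.vector(x_new - x)
    y_vec <- as.vector(g_new - g)
    sy <- sum(s_vec * y_vec)
    if (is.finite(sy) && sy > 1e-10) {
      mem_s <- c(mem_s, list(s_vec))
      mem_y <- c(mem_y, list(y_vec))
      mem_rho <- c(mem_rho, 1 / sy)
      if (length(mem_s) > m_max) {
        mem_s <- mem_s[-1]; mem_y <- mem_y[-1]; mem_rho <- mem_rho[-1]
      }
    }
    x <- x_new; f <- f_new; g <- g_new
    trace <- c(trace, f)
    converged <- max(abs(g)) < tol_grad
  }
  if (!is.null(lig_out)) lig_out$coords <- x
  list(ligand = lig_out, coords = x,
       energy = total_energy(x, params, pocket, spec),
       iterations = iters, converged = converged, energy_trace = trace)
}
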