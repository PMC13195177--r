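# Inner fluence optimization: projected gradient descent with
# Barzilai-Borwein step initialization and backtracking line search over
# nonnegative fluence, for a fixed iteration budget per outer loop.
# Backtracking certifies monotone descent of the total objective;
# nonnegativity is maintained by projection at every iterate.  The BB
# (spectral) trial step is essential here: the objective mixes weight-3000
# target terms with MaxEUD terms whose curvature scales like 1/E0^2, so
# plain fixed-step gradient descent stalls long before the per-loop budget
# can equilibrate the trade-off.

#' Inner-optimizer settings
#'
#' @param inner_iterations descent iterations per run (>= 0; the per-loop
#'   budget of the outer feedback controller).
#' @param tolerance relative objective-change floor; the run stops early once
#'   an accepted step improves the total objective by less than this
#'   fraction.
#' @param max_backtracks line-search halvings before the run is declared
#'   converged at the current iterate.
#' @param armijo sufficient-decrease constant of the line search.
#' @return an `ofv_optimizer_config`.
#' @export
optimizer_config <- function(inner_iterations = 40L, tolerance = 1e-7,
                             max_backtracks = 30L, armijo = 1e-4) {
  stopifnot(inner_iterations >= 0, tolerance >= 0, max_backtracks >= 1,
            armijo > 0, armijo < 0.5)
  structure(list(inner_iterations = as.integer(inner_iterations),
                 tolerance = tolerance,
                 max_backtracks = as.integer(max_backtracks),
                 armijo = armijo),
            class = "ofv_optimizer_config")
}

#' Optimize fluence for a fixed objective set
#'
#' Runs `config$inner_iterations` projected-gradient steps from `start`
#' (the outer loop warm-starts each call from the previous solution).  Each
#' step backtracks until the Armijo sufficient-decrease condition holds, so
#' the per-iteration total objective sequence is nonincreasing; iterates are
#' projected onto the nonnegative orthant.
#'
#' @param influence an `ofv_influence`.
#' @param objectives list of `ofv_objective` terms.
#' @param start nonnegative starting fluence (length = beamlet count).
#' @param config an `ofv_optimizer_config`.
#' @param phantom the `ofv_phantom` supplying structure masks.
#' @return list with `fluence`, `dose` (matrix, Gy), `report`
#'   (an `ofv_report` at the final iterate), `objective_trace` (total
#'   objective per accepted iterate, starting value first), `iterations`
#'   (accepted steps), `converged` (logical).
#' @export
optimize_fluence <- function(influence, objectives, start,
                             config = optimizer_config(), phantom) {
  stopifnot(inherits(influence, "ofv_influence"),
            inherits(config, "ofv_optimizer_config"))
  x <- as.numeric(start)
  if (length(x) != influence$n_beamlets)
    stop("start fluence length does not match beamlet count")
  if (any(x < 0)) stop("start fluence must be nonnegative")

  f <- total_objective(objectives, influence, x, phantom)
  if (!is.finite(f)) stop("non-finite objective at start")
  trace <- f
  converged <- FALSE
  it <- 0L
  x_prev <- NULL
  g_prev <- NULL

  while (it < config$inner_iterations) {
    g <- total_gradient_fluence(objectives, influence, x, phantom)
    if (!all(is.finite(g))) stop("non-finite gradient at iteration ", it + 1L)
    # effective gradient: at the boundary x = 0, ignore components pushing
    # further negative (they are annihilated by the projection)
    ge <- g; ge[x <= 0 & g > 0] <- 0
    gn2 <- sum(ge^2)
    if (gn2 == 0) { converged <- TRUE; break }
    # Barzilai-Borwein (BB1) spectral trial step; fall back to a scale
    # heuristic on the first iteration or when curvature is not positive
    t <- NA_real_
    if (!is.null(x_prev)) {
      dx <- x - x_prev; dg <- g - g_prev
      curv <- sum(dx * dg)
      if (curv > 0) t <- sum(dx * dx) / curv
    }
    if (!is.finite(t) || t <= 0)
      t <- max(as.numeric(x %*% g) / gn2, 1 / sqrt(gn2))
    accepted <- FALSE
    for (bt in seq_len(config$max_backtracks)) {
      xn <- pmax(x - t * g, 0)
      fn <- total_objective(objectives, influence, xn, phantom)
      # Armijo condition on the projected step
      if (is.finite(fn) && fn <= f - config$armijo * sum(g * (x - xn))) {
        accepted <- TRUE; break
      }
      t <- t / 2
    }
    if (!accepted || !any(xn != x)) { converged <- TRUE; break }
    rel <- (f - fn) / max(abs(f), .Machine$double.eps)
    x_prev <- x; g_prev <- g
    x <- xn; f <- fn
    it <- it + 1L
    trace <- c(trace, f)
    if (rel < config$tolerance) { converged <- TRUE; break }
  }

  dose <- compute_dose(influence, x)
  list(fluence = x, dose = dose,
       report = objective_report(objectives, dose, phantom),
       objective_trace = trace, iterations = it, converged = converged)
}

# Uniform starting fluence scaled so that the mean PTV dose equals the
# prescription; removes dependence on arbitrary starts (Phase 1 entry point).
initial_fluence <- function(influence, phantom, prescription) {
  per_unit <- as.numeric(influence$A %*% rep(1, influence$n_beamlets))
  m <- mean(per_unit[phantom$masks$PTV])
  if (m <= 0) stop("no beamlet reaches the PTV; check the beam set")
  rep(prescription / m, influence$n_beamlets)
}
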