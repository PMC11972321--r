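#' PCSO configuration
#'
#' Constants of the Predator Crow Search Optimization run. The algorithm
#' maintains a population of `pop_size` prey positions (candidate solutions)
#' driven toward the best-so-far elite by phase-dependent Brownian/Levy
#' steps, plus a crow flock whose agents follow each other's memorized best
#' positions; predator and crow proposals are blended 50:50 each iteration.
#'
#' @param dim Problem dimension (>= 1).
#' @param lower,upper Bound vectors of length `dim` (scalars are recycled);
#'   `lower <= upper` elementwise.
#' @param pop_size Population size tau (>= 4).
#' @param max_iters Iteration budget Qmax (>= 3).
#' @param step_constant Step-size constant C (default 0.5).
#' @param flight_length Crow flight length FL (default 2.0).
#' @param mask_prob Per-dimension Bernoulli probability of the binary jump
#'   mask H (default 0.2).
#' @param levy_exponent Tail exponent of the Levy steps (default 1.5).
#' @param seed Integer seed; a run is bitwise reproducible given the config.
#' @param stagnation_window Optional early stop: halt when the best fitness
#'   has not improved for this many iterations (default `NULL`, off; the
#'   standard termination is the fixed `max_iters` budget).
#' @return A `pcso_config` list.
#' @export
pcso_config <- function(dim, lower = -5, upper = 5, pop_size = 30L,
                        max_iters = 100L, step_constant = 0.5,
                        flight_length = 2.0, mask_prob = 0.2,
                        levy_exponent = 1.5, seed = 1L,
                        stagnation_window = NULL) {
  stopifnot(dim >= 1L, pop_size >= 4L, max_iters >= 3L,
            mask_prob >= 0, mask_prob <= 1, levy_exponent > 0,
            levy_exponent < 2)
  lower <- rep_len(as.numeric(lower), dim)
  upper <- rep_len(as.numeric(upper), dim)
  if (any(!is.finite(lower)) || any(!is.finite(upper)))
    stop("bounds must be finite")
  if (any(lower > upper)) stop("lower must be <= upper elementwise")
  structure(list(dim = as.integer(dim), lower = lower, upper = upper,
                 pop_size = as.integer(pop_size),
                 max_iters = as.integer(max_iters),
                 step_constant = step_constant,
                 flight_length = flight_length, mask_prob = mask_prob,
                 levy_exponent = levy_exponent, seed = as.integer(seed),
                 stagnation_window = stagnation_window),
            class = "pcso_config")
}

clip_positions <- function(P, lower, upper) {
  # scalar fast path when the box is uniform across dimensions
  if (lower[1] == lower[length(lower)] && all(lower == lower[1]) &&
      all(upper == upper[1]))
    return(pmin(pmax(P, lower[1]), upper[1]))
  t(pmin(pmax(t(P), lower), upper))
}

#' Adaptive step-size multiplier M
#'
#' The iteration-dependent multiplier `(1 - Q/Qmax)^(2*Q/Qmax)`, equal to 1
#' at the start, 0.5 halfway and 0 at the last iteration; it damps the
#' exploitation-phase and jump steps as the search matures.
#'
#' @param Q Current iteration, `0 <= Q <= Qmax`.
#' @param Qmax Iteration budget (> 0).
#' @return Scalar multiplier in `[0, 1]`.
#' @export
adaptive_M <- function(Q, Qmax) {
  stopifnot(Qmax > 0)
  if (Q < 0 || Q > Qmax) stop("Q out of range [0, Qmax]")
  (1 - Q / Qmax)^(2 * Q / Qmax)
}

#' Brownian step vector
#'
#' Independent standard normal draws, the step distribution of the
#' exploration-oriented moves.
#'
#' @param dim Length of the vector.
#' @return Numeric vector.
#' @export
brownian_vector <- function(dim) stats::rnorm(dim)

#' Levy step vector (Mantegna's algorithm)
#'
#' Heavy-tailed symmetric steps `u / |v|^(1/beta)` with
#' `u ~ N(0, sigma_u^2)`, `v ~ N(0, 1)` and the Mantegna scale
#' `sigma_u = [Gamma(1+b) sin(pi b/2) / (Gamma((1+b)/2) b 2^((b-1)/2))]^(1/b)`,
#' giving tail decay `P(|step| > t) ~ t^(-beta)`.
#'
#' @param dim Length of the vector.
#' @param exponent Tail exponent beta in (0, 2) (default 1.5).
#' @return Numeric vector.
#' @export
levy_vector <- function(dim, exponent = 1.5) {
  b <- exponent
  sigma_u <- (gamma(1 + b) * sin(pi * b / 2) /
                (gamma((1 + b) / 2) * b * 2^((b - 1) / 2)))^(1 / b)
  u <- stats::rnorm(dim, 0, sigma_u)
  v <- stats::rnorm(dim)
  u / abs(v)^(1 / b)
}

#' Which phase does iteration Q belong to?
#'
#' Phase 1 (Brownian exploration) while `Q < Qmax/3`, phase 2 (half Levy,
#' half damped Brownian) while `Qmax/3 <= Q < 2*Qmax/3`, phase 3 (Levy
#' exploitation) for `Q >= 2*Qmax/3`.
#'
#' @param Q Current iteration (1-based).
#' @param Qmax Iteration budget.
#' @return Integer 1, 2 or 3.
#' @export
pcso_phase <- function(Q, Qmax) {
  if (Q < Qmax / 3) 1L else if (Q < 2 * Qmax / 3) 2L else 3L
}

#' Initialize a PCSO swarm
#'
#' Prey positions are drawn i.i.d. uniformly inside the box; crow positions
#' and memories start at the same points; every position is evaluated and the
#' elite (best-so-far) recorded.
#'
#' @param config A [pcso_config()].
#' @param objective Function mapping a `dim`-vector to a finite scalar
#'   (minimized).
#' @return A `pcso_swarm` list with prey/crow/memory matrices, fitness
#'   vectors, the elite, and the evaluation counter.
#' @export
init_population <- function(config, objective) {
  tau <- config$pop_size; d <- config$dim
  U <- matrix(stats::runif(tau * d), tau, d)
  prey <- sweep(sweep(U, 2, config$upper - config$lower, "*"),
                2, config$lower, "+")
  fitness <- eval_positions(objective, prey)
  best <- which.min(fitness)
  structure(list(prey = prey, fitness = fitness,
                 crow = prey, mem = prey, mem_fitness = fitness,
                 best_position = prey[best, ], best_fitness = fitness[best],
                 evaluations = tau),
            class = "pcso_swarm")
}

eval_positions <- function(objective, P) {
  f <- vapply(seq_len(nrow(P)), function(i) objective(P[i, ]), numeric(1))
  bad <- which(!is.finite(f))
  if (length(bad))
    stop("objective returned a non-finite value at position [",
         paste(signif(P[bad[1], ], 6), collapse = ", "), "]")
  f
}

elite_matrix <- function(swarm, tau) {
  matrix(swarm$best_position, tau, length(swarm$best_position), byrow = TRUE)
}

#' Phase-1 proposal step (Brownian exploration)
#'
#' For every agent, `step = YA * (elite - YA * prey)` with Brownian `YA`,
#' and `prey <- prey + C * Y * step` with `Y ~ Uniform(0,1)` per dimension,
#' clipped to the bounds. The proposal is returned in the swarm's prey slots;
#' acceptance is the optimizer's job.
#'
#' @param swarm A `pcso_swarm`.
#' @param Q Current iteration.
#' @param config A [pcso_config()].
#' @return The swarm with proposed prey positions.
#' @export
phase1_step <- function(swarm, Q, config) {
  tau <- config$pop_size; d <- config$dim
  E <- elite_matrix(swarm, tau)
  YA <- matrix(stats::rnorm(tau * d), tau, d)
  Y <- matrix(stats::runif(tau * d), tau, d)
  step <- YA * (E - YA * swarm$prey)
  swarm$prey <- clip_positions(swarm$prey + config$step_constant * Y * step,
                               config$lower, config$upper)
  swarm
}

#' Phase-2 proposal step (half Levy, half damped Brownian)
#'
#' The first `ceiling(tau/2)` agents take Levy steps against the elite
#' (`step = YR * (elite - YR * prey)`, `prey <- prey + C * Y * step`); the
#' rest take Brownian steps damped by [adaptive_M()]
#' (`step = YA * (YA * elite - prey)`, `prey <- prey + C * M * step`).
#'
#' @inheritParams phase1_step
#' @return The swarm with proposed prey positions.
#' @export
phase2_step <- function(swarm, Q, config) {
  tau <- config$pop_size; d <- config$dim
  E <- elite_matrix(swarm, tau)
  half <- ceiling(tau / 2)
  i1 <- seq_len(half); i2 <- setdiff(seq_len(tau), i1)
  prey <- swarm$prey

  YR <- matrix(levy_vector(half * d, config$levy_exponent), half, d)
  Y <- matrix(stats::runif(half * d), half, d)
  step1 <- YR * (E[i1, , drop = FALSE] - YR * prey[i1, , drop = FALSE])
  prey[i1, ] <- prey[i1, , drop = FALSE] + config$step_constant * Y * step1

  if (length(i2)) {
    M <- adaptive_M(Q, config$max_iters)
    YA <- matrix(stats::rnorm(length(i2) * d), length(i2), d)
    step2 <- YA * (YA * E[i2, , drop = FALSE] - prey[i2, , drop = FALSE])
    prey[i2, ] <- prey[i2, , drop = FALSE] + config$step_constant * M * step2
  }
  swarm$prey <- clip_positions(prey, config$lower, config$upper)
  swarm
}

#' Phase-3 proposal step (Levy exploitation)
#'
#' All agents take damped Levy steps around the elite:
#' `step = YR * (YR * elite - prey)`, `prey <- prey + C * M * step`.
#'
#' @inheritParams phase1_step
#' @return The swarm with proposed prey positions.
#' @export
phase3_step <- function(swarm, Q, config) {
  tau <- config$pop_size; d <- config$dim
  E <- elite_matrix(swarm, tau)
  M <- adaptive_M(Q, config$max_iters)
  YR <- matrix(levy_vector(tau * d, config$levy_exponent), tau, d)
  step <- YR * (YR * E - swarm$prey)
  swarm$prey <- clip_positions(swarm$prey + config$step_constant * M * step,
                               config$lower, config$upper)
  swarm
}

#' Raid jump proposal
#'
#' Long masked leap: `position + M * (Smin + Y * (Smax - Smin)) * H` with
#' `Y ~ Uniform(0,1)` per dimension and `H` elementwise
#' Bernoulli(`mask_prob`); damped by [adaptive_M()] and clipped. Accepts a
#' single position vector or a matrix of row positions.
#'
#' @param position Position vector or matrix (rows = agents).
#' @param config A [pcso_config()].
#' @param Q Current iteration.
#' @return Jumped position(s), clipped to bounds.
#' @export
raid_jump <- function(position, config, Q) {
  P <- if (is.matrix(position)) position else matrix(position, 1)
  n <- nrow(P); d <- ncol(P)
  M <- adaptive_M(Q, config$max_iters)
  Y <- matrix(stats::runif(n * d), n, d)
  H <- matrix(stats::runif(n * d) < config$mask_prob, n, d)
  span <- matrix(config$upper - config$lower, n, d, byrow = TRUE)
  lo <- matrix(config$lower, n, d, byrow = TRUE)
  out <- clip_positions(P + M * (lo + Y * span) * H, config$lower,
                        config$upper)
  if (is.matrix(position)) out else out[1, ]
}

#' Crow step
#'
#' The crow moves toward the memorized best position of a followed flock
#' mate: `crow + rand * FL * (mem_j - crow)` with a scalar
#' `rand ~ Uniform(0, 1)`.
#'
#' @param crow_position Current crow position vector.
#' @param memory_j Memory (personal best) of the followed crow.
#' @param flight_length Flight length FL.
#' @param lower,upper Optional bounds for clipping.
#' @return Updated position.
#' @export
crow_step <- function(crow_position, memory_j, flight_length = 2.0,
                      lower = NULL, upper = NULL) {
  out <- crow_position + stats::runif(1) * flight_length *
    (memory_j - crow_position)
  if (!is.null(lower)) out <- pmin(pmax(out, lower), upper)
  out
}

#' Blend predator and crow proposals
#'
#' Elementwise midpoint `0.5 * raid + 0.5 * crow`, optionally clipped.
#'
#' @param raid_candidate,crow_candidate Equal-length position vectors (or
#'   equal-shape matrices).
#' @param lower,upper Optional bounds for clipping.
#' @return Blended position(s).
#' @export
hybrid_update <- function(raid_candidate, crow_candidate,
                          lower = NULL, upper = NULL) {
  if (length(raid_candidate) != length(crow_candidate))
    stop("dimension mismatch between raid and crow candidates")
  out <- 0.5 * raid_candidate + 0.5 * crow_candidate
  if (!is.null(lower)) {
    out <- if (is.matrix(out)) clip_positions(out, lower, upper)
           else pmin(pmax(out, lower), upper)
  }
  out
}

#' Run Predator Crow Search Optimization
#'
#' Minimizes `objective` over the box in `config`. Each iteration runs the
#' phase step prescribed by the iteration thirds, then forms, for every
#' agent, the 50:50 blend of a raid jump from its prey position and a crow
#' step toward a random flock mate's memory; every proposal is evaluated and
#' accepted per agent only when it improves that agent's fitness (greedy
#' elitism), so the best-fitness history never increases. The run costs
#' `pop_size * (2 * max_iters + 1)` objective evaluations (initial
#' population, then phase proposal + hybrid proposal per agent per
#' iteration).
#'
#' @param objective Function mapping a `dim`-vector to a finite scalar.
#' @param config A [pcso_config()].
#' @param callback Optional `function(Q, swarm)` invoked after each
#'   iteration.
#' @return A `pcso_result`: `best_position`, `best_fitness`, `history`
#'   (best fitness after each iteration, non-increasing), `evaluations`,
#'   `config`, `seed`.
#' @export
pcso_optimize <- function(objective, config, callback = NULL) {
  set.seed(config$seed)
  swarm <- init_population(config, objective)
  Qmax <- config$max_iters
  tau <- config$pop_size
  history <- numeric(Qmax)
  since_improve <- 0L
  iters_run <- 0L

  for (Q in seq_len(Qmax)) {
    prev_best <- swarm$best_fitness
    phase <- pcso_phase(Q, Qmax)
    proposal <- switch(phase, phase1_step(swarm, Q, config),
                       phase2_step(swarm, Q, config),
                       phase3_step(swarm, Q, config))
    swarm <- accept_proposals(swarm, proposal$prey, objective)

    # hybrid predator-crow proposals
    raid <- raid_jump(swarm$prey, config, Q)
    follow <- vapply(seq_len(tau), function(e)
      sample(seq_len(tau)[-e], 1L), integer(1))
    rnd <- stats::runif(tau)
    crow_new <- swarm$crow + rnd * config$flight_length *
      (swarm$mem[follow, , drop = FALSE] - swarm$crow)
    crow_new <- clip_positions(crow_new, config$lower, config$upper)
    swarm$crow <- crow_new
    hybrid <- hybrid_update(raid, crow_new, config$lower, config$upper)
    swarm <- accept_proposals(swarm, hybrid, objective)

    history[Q] <- swarm$best_fitness
    iters_run <- Q
    if (!is.null(callback)) callback(Q, swarm)
    since_improve <- if (swarm$best_fitness < prev_best) 0L
                     else since_improve + 1L
    if (!is.null(config$stagnation_window) &&
        since_improve >= config$stagnation_window) break
  }

  structure(list(best_position = swarm$best_position,
                 best_fitness = swarm$best_fitness,
                 history = history[seq_len(iters_run)],
                 evaluations = swarm$evaluations,
                 config = config, seed = config$seed),
            class = "pcso_result")
}

accept_proposals <- function(swarm, proposals, objective) {
  f <- eval_positions(objective, proposals)
  swarm$evaluations <- swarm$evaluations + length(f)
  improve <- f < swarm$fitness
  if (any(improve)) {
    swarm$prey[improve, ] <- proposals[improve, , drop = FALSE]
    swarm$fitness[improve] <- f[improve]
  }
  mem_improve <- f < swarm$mem_fitness
  if (any(mem_improve)) {
    swarm$mem[mem_improve, ] <- proposals[mem_improve, , drop = FALSE]
    swarm$mem_fitness[mem_improve] <- f[mem_improve]
  }
  b <- which.min(f)
  if (f[b] < swarm$best_fitness) {
    swarm$best_fitness <- f[b]
    swarm$best_position <- proposals[b, ]
  }
  swarm
}

#' @export
print.pcso_result <- function(x, ...) {
  cat(sprintf("pcso_result: best fitness %.6g after %d evaluations (%d iterations)\n",
              x$best_fitness, x$evaluations, length(x$history)))
  invisible(x)
}

#' Standard benchmark objectives
#'
#' @param name `"sphere"`, `"rosenbrock"` or `"rastrigin"`.
#' @return The objective function (vector -> scalar, minimum 0 for sphere
#'   and rosenbrock at 0/1..1, rastrigin at 0).
#' @export
benchmark_function <- function(name = c("sphere", "rosenbrock", "rastrigin")) {
  switch(match.arg(name),
    sphere = function(x) sum(x^2),
    rosenbrock = function(x) {
      n <- length(x)
      sum(100 * (x[-1] - x[-n]^2)^2 + (1 - x[-n])^2)
    },
    rastrigin = function(x) 10 * length(x) + sum(x^2 - 10 * cos(2 * pi * x)))
}

#' Equal-budget uniform random search baseline
#'
#' Draws the same number of uniform points in the box as a PCSO run with the
#' given config would evaluate, and returns the best; used as the paired
#' baseline in the efficacy checks.
#'
#' @param objective Objective function.
#' @param config A [pcso_config()] (its budget and bounds are used).
#' @return List with `best_fitness`, `best_position`, `evaluations`.
#' @export
random_search <- function(objective, config) {
  set.seed(config$seed)
  n_eval <- config$pop_size * (2L * config$max_iters + 1L)
  d <- config$dim
  best_f <- Inf; best_x <- NULL
  block <- 1000L
  done <- 0L
  while (done < n_eval) {
    m <- min(block, n_eval - done)
    U <- matrix(stats::runif(m * d), m, d)
    P <- sweep(sweep(U, 2, config$upper - config$lower, "*"),
               2, config$lower, "+")
    f <- eval_positions(objective, P)
    i <- which.min(f)
    if (f[i] < best_f) { best_f <- f[i]; best_x <- P[i, ] }
    done <- done + m
  }
  list(best_fitness = best_f, best_position = best_x, evaluations = n_eval)
}
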