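# Logarithmic simulated annealing driven by the CSP neighbourhood, plus the
# deterministic compact initial conformation.

#' Annealing configuration
#'
#' @param iterations number of annealing iterations; one iteration is one
#'   subchain perturbation plus one acceptance decision (default 2000).
#' @param gamma constant of the logarithmic cooling schedule
#'   T(k) = gamma / log(k + 2). The default 1.0 makes the initial
#'   temperature 1/log(2), which accepts a unit uphill move (one lost
#'   contact under a unit-attraction table, the median uphill step on the
#'   fixture suite) with probability 0.5.
#' @param seed integer seed; the run is fully reproducible given the seed.
#' @param policy a \code{\link{perturbation_policy}}.
#' @param strict_greedy take the literal minimum-energy neighbour every
#'   iteration (monotone descent, no Metropolis test).
#' @param strict_contacts restrict contacts to lattice-adjacent pairs.
#' @return A list of class \code{"anneal_config"}.
#' @export
anneal_config <- function(iterations = 2000L, gamma = 1.0, seed = 1L,
                          policy = default_policy(), strict_greedy = FALSE,
                          strict_contacts = FALSE) {
  if (iterations < 1L) stop("'iterations' must be >= 1", call. = FALSE)
  if (gamma <= 0) stop("'gamma' must be positive", call. = FALSE)
  structure(list(iterations = as.integer(iterations), gamma = gamma,
                 seed = as.integer(seed), policy = policy,
                 strict_greedy = isTRUE(strict_greedy),
                 strict_contacts = isTRUE(strict_contacts)),
            class = "anneal_config")
}

#' Deterministic compact initial conformation
#'
#' Builds the layered zigzag the annealer starts from: rows of ten steps
#' alternating forward-left (1,1,0) and forward-right (1,-1,0), a two-step
#' row transition of left-up (0,1,1) then right-up (0,-1,1), a reversed row
#' alternating backward-right (-1,-1,0) and backward-left (-1,1,0), another
#' two-step transition, repeated while residues remain. The result is a
#' valid self-avoiding chain for every n, far more compact than a straight
#' chain; starting compact is what lets the subchain CSP find many feasible
#' re-placements early on.
#'
#' @param n chain length (>= 1).
#' @param seq optional \code{\link{aa_sequence}} of length n to attach;
#'   defaults to poly-alanine (positions do not depend on the sequence).
#' @return An \code{"fcc_conformation"} starting at the origin.
#' @export
initial_conformation <- function(n, seq = NULL) {
  if (n < 1L || n != round(n)) stop("'n' must be a positive integer",
                                    call. = FALSE)
  fl <- c(1L, 1L, 0L); fr <- c(1L, -1L, 0L)
  br <- c(-1L, -1L, 0L); bl <- c(-1L, 1L, 0L)
  lu <- c(0L, 1L, 1L); ru <- c(0L, -1L, 1L)
  row_fwd <- rep(list(fl, fr), 5L)
  row_bwd <- rep(list(br, bl), 5L)
  cycle <- c(row_fwd, list(lu, ru), row_bwd, list(lu, ru))
  moves <- rep(cycle, length.out = n - 1L)
  pos <- matrix(0L, n, 3L)
  if (n > 1L)
    for (i in 2:n) pos[i, ] <- pos[i - 1L, ] + moves[[i - 1L]]
  if (is.null(seq)) seq <- aa_sequence(rep("A", n))
  conformation(seq, pos)
}

#' Logarithmic cooling schedule
#'
#' T(k) = gamma / log(k + 2): positive and strictly decreasing in the
#' iteration index k >= 0.
#'
#' @param k iteration number (>= 0, vectorized).
#' @param gamma positive schedule constant.
#' @return Temperature(s).
#' @export
log_temperature <- function(k, gamma) {
  if (!is.numeric(gamma) || gamma <= 0)
    stop("'gamma' must be positive", call. = FALSE)
  if (any(k < 0)) stop("'k' must be >= 0", call. = FALSE)
  gamma / log(k + 2)
}

#' Metropolis acceptance rule
#'
#' Downhill or neutral moves (delta_e <= 0) are always accepted; an uphill
#' move is accepted with probability exp(-delta_e / temperature). Vectorized
#' over \code{delta_e}; uses R's global RNG.
#'
#' @param delta_e energy change(s) of the proposed move.
#' @param temperature positive temperature.
#' @return logical vector of acceptance decisions.
#' @export
metropolis_accept <- function(delta_e, temperature) {
  if (!is.numeric(temperature) || temperature <= 0)
    stop("'temperature' must be positive", call. = FALSE)
  delta_e <= 0 | runif(length(delta_e)) < exp(-delta_e / temperature)
}

#' Run the hybrid CP + simulated-annealing search
#'
#' Starts from \code{\link{initial_conformation}}. At iteration k a subchain
#' perturbation is drawn from the policy, \code{\link{best_neighbour}}
#' enumerates all re-placements of that subchain and proposes the best
#' distinct one, and the proposal is accepted by the Metropolis rule at
#' temperature T(k) of the logarithmic schedule (with
#' \code{strict_greedy = TRUE} the minimum-energy solution is always taken,
#' giving monotone descent). The incumbent best conformation is tracked
#' throughout. Two runs with the same seed and config are identical.
#'
#' @param seq an \code{\link{aa_sequence}} (or string).
#' @param table a \code{"contact_potential"}.
#' @param config an \code{\link{anneal_config}}.
#' @param validate re-validate the conformation invariants every iteration
#'   (slower; meant for tests).
#' @param verbose print a progress line every 100 iterations.
#' @return An object of class \code{"fcc_fold"}: list with
#'   \code{best_conformation}, \code{best_energy}, \code{trajectory} (data
#'   frame with one row per iteration: iteration, l, b, anchor, count,
#'   proposed_energy, accepted, current_energy, best_energy),
#'   \code{initial_energy}, \code{wall_time}, \code{seed}, \code{config}.
#' @export
run_hybrid <- function(seq, table, config = anneal_config(),
                       validate = FALSE, verbose = FALSE) {
  seq <- as_aa_seq(seq)
  stopifnot(inherits(table, "contact_potential"),
            inherits(config, "anneal_config"))
  t0 <- proc.time()[["elapsed"]]
  set.seed(config$seed)
  n <- length(seq)
  cur <- initial_conformation(n, seq = seq)
  cur_e <- conformation_energy(cur, table, strict = config$strict_contacts)
  init_e <- cur_e
  best <- cur; best_e <- cur_e
  iters <- config$iterations
  traj <- data.frame(iteration = seq_len(iters) - 1L, l = NA_integer_,
                     b = NA_integer_, anchor = NA_integer_,
                     count = NA_real_, proposed_energy = NA_real_,
                     accepted = NA, current_energy = NA_real_,
                     best_energy = NA_real_)
  for (k in seq_len(iters) - 1L) {
    pert <- sample_perturbation(config$policy, n)
    prop <- best_neighbour(cur, pert, table,
                           strict_greedy = config$strict_greedy,
                           strict_contacts = config$strict_contacts)
    delta <- prop$energy - cur_e
    if (config$strict_greedy) {
      accepted <- TRUE
    } else if (prop$unchanged) {
      accepted <- FALSE
    } else {
      accepted <- metropolis_accept(delta, log_temperature(k, config$gamma))
    }
    if (accepted) {
      cur <- prop$conformation
      cur_e <- prop$energy
      if (validate) validate_conformation(cur)
      if (cur_e < best_e) { best <- cur; best_e <- cur_e }
    }
    traj[k + 1L, c("l", "b", "anchor")] <-
      c(pert$length, pert$dilation, pert$anchor)
    traj$count[k + 1L] <- prop$count
    traj$proposed_energy[k + 1L] <- prop$energy
    traj$accepted[k + 1L] <- accepted
    traj$current_energy[k + 1L] <- cur_e
    traj$best_energy[k + 1L] <- best_e
    if (verbose && (k + 1L) %% 100L == 0L)
      message(sprintf("iter %5d  current %.3f  best %.3f", k + 1L, cur_e,
                      best_e))
  }
  structure(list(best_conformation = best, best_energy = best_e,
                 trajectory = traj, initial_energy = init_e,
                 wall_time = proc.time()[["elapsed"]] - t0,
                 seed = config$seed, config = config),
            class = "fcc_fold")
}

#' @export
print.fcc_fold <- function(x, ...) {
  cat(sprintf(paste0("Hybrid fold result: n = %d, %d iterations, seed %d\n",
                     "  initial energy %.3f -> best energy %.3f ",
                     "(%.1f s)\n"),
              nrow(x$best_conformation$positions),
              nrow(x$trajectory), x$seed, x$initial_energy, x$best_energy,
              x$wall_time))
  invisible(x)
}
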