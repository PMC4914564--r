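# Precompute the pieces of the evaluation function the simulator needs:
# one summed dyadic weight matrix for density/simx/ego_alter plus the
# transitive-triplet and degree-popularity coefficients.
model_sim_pieces <- function(model, adj, present, v) {
  beta_tt <- 0; beta_ip <- 0
  wsum <- matrix(0, nrow(adj), ncol(adj), dimnames = dimnames(adj))
  for (e in eval_effects(model)) {
    if (e$name == "transtrip") beta_tt <- beta_tt + e$parameter
    else if (e$name == "inpop") beta_ip <- beta_ip + e$parameter
    else wsum <- wsum + e$parameter * dyadic_weight_matrix(e, adj, present, v)
  }
  list(wsum = wsum, beta_tt = beta_tt, beta_ip = beta_ip)
}

#' Simulate one SAOM microstep
#'
#' One actor, chosen with probability proportional to its rate, receives a
#' change opportunity after an exponential waiting time and either keeps the
#' network or toggles one symmetric tie, with multinomial-logit choice
#' probabilities proportional to `exp(f_i)` of the resulting network.
#'
#' @param x a [wave_network()].
#' @param model a [saom_model()].
#' @param v a [covariate_table()].
#' @param period period index selecting the basic rate.
#' @return list with the new `wave_network` (`network`), the waiting time
#'   `dt` and whether a tie changed (`changed`).
#' @export
microstep <- function(x, model, v = NULL, period = 1L) {
  res <- simulate_steps(x, model, v, period, n_steps = 1L)
  res
}

#' Run a fixed number of SAOM microsteps
#'
#' Step-count-controlled simulation (no clock), used for studying the
#' model's stationary behavior.
#'
#' @inheritParams microstep
#' @param n_steps number of microsteps to run.
#' @return list with `network`, `dt` (total exponential waiting time of the
#'   steps taken) and `changed`.
#' @export
simulate_steps <- function(x, model, v = NULL, period = 1L, n_steps = 1L) {
  adj <- as_adjacency(x)
  present <- presence_of(x)
  if (sum(present) < 2) stop("need at least two present actors")
  ids <- rownames(adj)
  lam <- rate_vector(model, v, period, ids, present)
  pieces <- model_sim_pieces(model, adj, present, v)
  out <- simulate_microsteps_cpp(adj, lam, pieces$wsum, pieces$beta_tt,
                                 pieces$beta_ip, Inf, as.integer(n_steps),
                                 1L)
  dt <- sum(rexp(n_steps, rate = sum(lam)))
  new_adj <- out$adjacency
  dimnames(new_adj) <- dimnames(adj)
  list(network = wave_network(new_adj,
                              period = if (inherits(x, "wave_network"))
                                x$period else period,
                              present = present),
       dt = dt, changed = any(new_adj != adj))
}

#' Simulate one observation period of network evolution
#'
#' Iterates microsteps over one unit-duration period: exponential waiting
#' times accumulate until the period boundary, at which point the current
#' network state is returned as the next wave.
#'
#' @inheritParams microstep
#' @param x_start `wave_network` at the start of the period.
#' @param max_steps abort threshold against runaway chains; defaults to
#'   `5000 + 100 * n * rho`.
#' @return the end-of-period `wave_network` with attribute `steps`.
#' @export
simulate_period <- function(x_start, model, v = NULL, period = 1L,
                            max_steps = NULL) {
  adj <- as_adjacency(x_start)
  present <- presence_of(x_start)
  if (sum(present) < 2) stop("need at least two present actors")
  ids <- rownames(adj)
  lam <- rate_vector(model, v, period, ids, present)
  if (is.null(max_steps))
    max_steps <- ceiling(5000 + 100 * sum(lam))
  pieces <- model_sim_pieces(model, adj, present, v)
  out <- simulate_microsteps_cpp(adj, lam, pieces$wsum, pieces$beta_tt,
                                 pieces$beta_ip, 1.0,
                                 as.integer(max_steps), 0L)
  if (isTRUE(out$hit_cap))
    stop("simulation exceeded ", max_steps, " microsteps in one period; ",
         "the chain may be degenerate (check rate and density parameters)")
  new_adj <- out$adjacency
  dimnames(new_adj) <- dimnames(adj)
  res <- wave_network(new_adj, period = period, present = present)
  attr(res, "steps") <- out$steps
  res
}

#' Tie-choice probabilities of a mover
#'
#' The multinomial-logit probabilities over a mover's choice set (keep the
#' network, or toggle the tie to each present partner), computed by full
#' re-evaluation of `f_i` on every candidate network. Serves as a readable
#' reference for the simulator's incremental computation.
#'
#' @inheritParams microstep
#' @param i the mover's actor id.
#' @return named numeric vector of probabilities; `"keep"` plus one entry
#'   per present partner.
#' @export
choice_probabilities <- function(x, i, model, v = NULL) {
  adj <- as_adjacency(x)
  present <- presence_of(x)
  ids <- rownames(adj)
  k <- actor_index(x, i)
  partners <- setdiff(which(present), k)
  f <- numeric(length(partners) + 1)
  f[1] <- evaluate(x, k, model, v)
  for (p in seq_along(partners)) {
    j <- partners[p]
    adj2 <- adj
    adj2[k, j] <- adj2[j, k] <- 1L - adj2[k, j]
    x2 <- wave_network(adj2, present = present)
    f[p + 1] <- evaluate(x2, k, model, v)
  }
  w <- exp(f - max(f))
  pr <- w / sum(w)
  names(pr) <- c("keep", ids[partners])
  pr
}
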