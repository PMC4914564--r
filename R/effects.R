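#' Effect statistics of the evaluation function
#'
#' Each statistic `s_ik(x)` measures one structural or covariate-related
#' feature of actor `i`'s personal network in the symmetric binary network
#' `x`. The evaluation function is their linear combination
#' `f_i(x) = sum_k beta_k s_ik(x)`; an actor choosing among tie changes
#' prefers networks with higher `f_i`.
#'
#' * `stat_density`: the actor's degree `sum_j x_ij` (baseline cost/benefit
#'   of having ties).
#' * `stat_transtrip`: transitive triplets `sum_{j,h} x_ij x_ih x_jh` over
#'   ordered pairs `j != h` - twice the number of triangles through `i`
#'   (triadic closure).
#' * `stat_inpop`: degree popularity `sum_j x_ij deg(j)` - the summed
#'   degrees of the actor's partners.
#' * `stat_simx`: covariate homophily `sum_j x_ij (sim_ij - mean(sim))`,
#'   centered similarity summed over partners.
#' * `stat_ego_alter`: `v_i * sum_j x_ij v_j`, the product of ego's
#'   covariate and its partners' covariate total (values mean-centered by
#'   default).
#'
#' @param x a [wave_network()] or a symmetric 0/1 matrix.
#' @param i actor id (name) or index.
#' @param v a [covariate_table()].
#' @param name covariate name.
#' @param center for `stat_ego_alter`: center covariate values at the
#'   present-roster mean before multiplying (the model's convention)?
#' @return numeric scalar.
#' @name effect_statistics
NULL

actor_index <- function(x, i) {
  adj <- as_adjacency(x)
  if (is.character(i)) {
    k <- match(i, rownames(adj))
    if (is.na(k)) stop("actor '", i, "' not in roster")
    k
  } else as.integer(i)
}

#' @rdname effect_statistics
#' @export
stat_density <- function(x, i) {
  adj <- as_adjacency(x)
  sum(adj[actor_index(x, i), ])
}

#' @rdname effect_statistics
#' @export
stat_transtrip <- function(x, i) {
  adj <- as_adjacency(x)
  k <- actor_index(x, i)
  as.numeric(adj[k, ] %*% adj %*% adj[, k])
}

#' @rdname effect_statistics
#' @export
stat_inpop <- function(x, i) {
  adj <- as_adjacency(x)
  k <- actor_index(x, i)
  sum(adj[k, ] * colSums(adj))
}

#' Dyadic covariate similarity
#'
#' Categorical covariates: 1 when equal, 0 otherwise. Ordinal covariates:
#' `1 - |v_i - v_j| / range(v)` with the range taken over the supplied
#' roster (present actors).
#'
#' @param v a [covariate_table()].
#' @param name covariate name.
#' @param i,j actor ids.
#' @param actors roster over which an ordinal covariate's range is taken;
#'   defaults to all actors in `v`.
#' @return similarity in `[0, 1]`.
#' @export
similarity <- function(v, name, i, j, actors = NULL) {
  if (is.null(actors)) actors <- v$actor
  S <- similarity_matrix(v, name, actors = actors)
  S[as.character(i), as.character(j)]
}

similarity_matrix <- function(v, name, actors = NULL) {
  if (is.null(actors)) actors <- v$actor
  vals <- covariate_values(v, name, actors)
  ty <- covariate_type(v, name)
  n <- length(actors)
  if (ty == "categorical") {
    S <- outer(vals, vals, `==`) * 1
  } else {
    rng <- diff(range(as.numeric(vals)))
    if (rng == 0)
      stop("ordinal covariate '", name, "' has zero range on this roster; ",
           "declare it categorical")
    S <- 1 - abs(outer(as.numeric(vals), as.numeric(vals), `-`)) / rng
  }
  dimnames(S) <- list(actors, actors)
  S
}

#' @rdname effect_statistics
#' @export
stat_simx <- function(x, i, v, name) {
  adj <- as_adjacency(x)
  pres <- presence_of(x)
  k <- actor_index(x, i)
  ids <- rownames(adj)[pres]
  S <- similarity_matrix(v, name, ids)
  simbar <- mean(S[upper.tri(S)])
  Sc <- matrix(0, nrow(adj), ncol(adj), dimnames = dimnames(adj))
  Sc[ids, ids] <- S - simbar
  sum(adj[k, ] * Sc[k, ])
}

#' @rdname effect_statistics
#' @export
stat_ego_alter <- function(x, i, v, name, center = TRUE) {
  adj <- as_adjacency(x)
  pres <- presence_of(x)
  k <- actor_index(x, i)
  vals <- rep(0, nrow(adj))
  ids <- rownames(adj)[pres]
  vv <- as.numeric(covariate_values(v, name, ids))
  if (center) vv <- vv - mean(vv)
  vals[pres] <- vv
  vals[k] * sum(adj[k, ] * vals)
}

# n x n dyadic weight matrix W such that s_ik = sum_j x_ij W[i, j],
# for density/simx/ego_alter; used by evaluate() and the simulator.
dyadic_weight_matrix <- function(effect, adj, present, v) {
  n <- nrow(adj)
  ids <- rownames(adj)
  W <- matrix(0, n, n, dimnames = dimnames(adj))
  pres_ids <- ids[present]
  switch(effect$name,
    density = { W[present, present] <- 1 },
    simx = {
      S <- similarity_matrix(v, effect$covariate, pres_ids)
      W[pres_ids, pres_ids] <- S - mean(S[upper.tri(S)])
    },
    ego_alter = {
      vv <- as.numeric(covariate_values(v, effect$covariate, pres_ids))
      vv <- vv - mean(vv)
      W[pres_ids, pres_ids] <- outer(vv, vv)
    },
    stop("not a dyadic-weight effect: ", effect$name)
  )
  diag(W) <- 0
  W
}

effect_statistic <- function(effect, x, i, v) {
  switch(effect$name,
    density = stat_density(x, i),
    transtrip = stat_transtrip(x, i),
    inpop = stat_inpop(x, i),
    simx = stat_simx(x, i, v, effect$covariate),
    ego_alter = stat_ego_alter(x, i, v, effect$covariate),
    stop("not an evaluation effect: ", effect$name)
  )
}

#' Evaluation function for one actor
#'
#' `f_i(x) = sum_k beta_k s_ik(x)` over the model's evaluation effects.
#'
#' @param x a `wave_network` or symmetric 0/1 matrix.
#' @param i actor id or index.
#' @param model a [saom_model()].
#' @param v a [covariate_table()] (needed for covariate effects).
#' @return numeric scalar.
#' @export
evaluate <- function(x, i, model, v = NULL) {
  sum(vapply(eval_effects(model), function(e)
    e$parameter * effect_statistic(e, x, i, v), numeric(1)))
}

#' Rate function for one actor
#'
#' `lambda_i = rho_m * exp(sum_h alpha_h v_hi)`: the period's basic rate
#' scaled by exponential covariate terms. Rate covariates use their raw
#' numeric codes, so for a 0/1 covariate `exp(alpha)` is the rate ratio
#' between the two classes. The degree-dependent rate factor is disabled
#' (identically 1).
#'
#' @param i actor id.
#' @param model a [saom_model()].
#' @param v a [covariate_table()].
#' @param period period index (1-based into `model$rate_basic`).
#' @return positive rate.
#' @export
rate <- function(i, model, v = NULL, period = 1L) {
  rho <- model$rate_basic[period]
  if (is.na(rho) || rho <= 0) stop("no positive basic rate for period ",
                                   period)
  lp <- 0
  for (e in rate_effects(model)) {
    vi <- as.numeric(covariate_values(v, e$covariate, as.character(i)))
    lp <- lp + e$parameter * vi
  }
  out <- rho * exp(lp)
  if (!is.finite(out))
    stop("non-finite rate for actor ", i, " (check alpha and covariate ",
         "scaling)")
  out
}

rate_vector <- function(model, v, period, ids, present) {
  rho <- model$rate_basic[period]
  lp <- rep(0, length(ids))
  for (e in rate_effects(model)) {
    vv <- as.numeric(covariate_values(v, e$covariate, ids))
    lp <- lp + e$parameter * vv
  }
  lam <- rho * exp(lp)
  if (any(!is.finite(lam))) stop("non-finite rates; check rate parameters")
  lam[!present] <- 0
  lam
}
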