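# BFS geodesic distances on a symmetric 0/1 matrix (Inf = unreachable)
geodesic_distances <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  reach <- diag(1L, n)
  frontier <- diag(1L, n)
  d <- 0L
  while (any(frontier > 0) && d < n) {
    d <- d + 1L
    nxt <- (frontier %*% adj > 0) & (reach == 0)
    if (!any(nxt)) break
    D[nxt] <- d
    reach[nxt] <- 1L
    frontier <- nxt * 1L
  }
  D
}

# undirected triad census via closed-form counts: classes with 0, 1, 2, 3
# edges among the C(n,3) actor triples
triad_census_undirected <- function(adj) {
  n <- nrow(adj)
  if (n < 3) return(c(empty = 0, one_edge = 0, two_path = 0, triangle = 0))
  deg <- rowSums(adj)
  m <- sum(adj) / 2
  tri <- sum(diag(adj %*% adj %*% adj)) / 6
  p2 <- sum(choose(deg, 2))           # 2-stars, closed or open
  two_path <- p2 - 3 * tri
  one_edge <- m * (n - 2) - 2 * two_path - 3 * tri
  empty <- choose(n, 3) - one_edge - two_path - tri
  c(empty = empty, one_edge = one_edge, two_path = two_path,
    triangle = tri)
}

#' Auxiliary network statistics for goodness of fit
#'
#' The concatenated vector of (i) the degree distribution - counts of
#' actors with degree 0..K, (ii) the geodesic distribution - counts of
#' dyads at shortest-path distance 1..L plus an "unreachable" bin, and
#' (iii) the undirected triad census (empty, one-edge, two-path, triangle).
#' Only present actors enter.
#'
#' @param x a [wave_network()] or symmetric 0/1 matrix.
#' @param K degree truncation; degrees above K fall in the last bin.
#'   Default: max observed degree + 2.
#' @param L geodesic truncation; finite distances above L fall in the L
#'   bin.
#' @return named numeric vector with attribute `groups` mapping entries to
#'   the three statistic families.
#' @export
aux_stats <- function(x, K = NULL, L = 5) {
  adj <- as_adjacency(x)
  pres <- presence_of(x)
  adj <- adj[pres, pres, drop = FALSE]
  n <- nrow(adj)
  deg <- rowSums(adj)
  if (is.null(K)) K <- max(deg) + 2
  degc <- pmin(deg, K)
  deg_counts <- vapply(0:K, function(d) sum(degc == d), numeric(1))
  names(deg_counts) <- paste0("deg", 0:K)
  D <- geodesic_distances(adj)
  dv <- D[upper.tri(D)]
  dvc <- pmin(dv, L)  # finite distances beyond L fall into the L bin
  geo_counts <- vapply(1:L, function(d)
    sum(is.finite(dv) & dvc == d), numeric(1))
  geo_counts <- c(geo_counts, sum(is.infinite(dv)))
  names(geo_counts) <- c(paste0("geo", 1:L), "geo_unreachable")
  tc <- triad_census_undirected(adj)
  names(tc) <- paste0("triad_", names(tc))
  out <- c(deg_counts, geo_counts, tc)
  attr(out, "groups") <- c(rep("degree", K + 1), rep("geodesic", L + 1),
                           rep("triad", 4))
  out
}

#' Mahalanobis distance of an observation from a simulated sample
#'
#' `MHD(v) = (v - vbar)' Sigma^-1 (v - vbar)` with mean and covariance
#' taken from the simulated sample. Coordinates with zero variance across
#' simulations are dropped before inversion; a Moore-Penrose pseudo-inverse
#' is the fallback for a still-singular covariance.
#'
#' @param obs numeric observed vector.
#' @param sims matrix of simulated vectors (rows = simulations).
#' @return nonnegative distance; attribute `dropped` gives the number of
#'   zero-variance coordinates removed.
#' @export
mahalanobis_distance <- function(obs, sims) {
  keep <- apply(sims, 2, function(col) var(col) > 0)
  dropped <- sum(!keep)
  if (!any(keep)) {
    out <- 0
    attr(out, "dropped") <- dropped
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  S <- sims[, keep, drop = FALSE]
  o <- obs[keep]
  mu <- colMeans(S)
  Sig <- cov(S)
  Siginv <- tryCatch(solve(Sig), error = function(e) MASS::ginv(Sig))
  d <- as.numeric(t(o - mu) %*% Siginv %*% (o - mu))
  d <- max(d, 0)
  attr(d, "dropped") <- dropped
  attr(d, "degenerate") <- FALSE
  d
}

#' Monte Carlo Mahalanobis distance goodness-of-fit test
#'
#' Simulates every period from the fitted model `n_sims` times, pools each
#' replicate's auxiliary statistics (degree distribution, geodesic
#' distribution, triad census summed over end waves), and compares the
#' observed pooled vector to the simulated cloud by Mahalanobis distance.
#' The one-tailed Monte Carlo p-value uses the add-one estimator
#' `p = (1 + #\{sim MHD >= obs MHD\}) / (1 + n_sims)`.
#'
#' @param model fitted [saom_model()] (or a `saom_fit`, whose model is
#'   used).
#' @param waves observed [wave_network()] list.
#' @param v a [covariate_table()].
#' @param n_sims number of Monte Carlo replicates (>= 20).
#' @param K,L truncation settings passed to [aux_stats()] (K defaults to
#'   the maximum over observed end waves plus 2, shared by all replicates).
#' @param per_wave if `TRUE`, return one test per period instead of the
#'   pooled test.
#' @return An object of class `saom_gof`: list with `mhd`, `p`,
#'   `sim_mhd`, `n_sims`, `observed`, `sim_stats` and settings.
#' @export
mhd_test <- function(model, waves, v = NULL, n_sims = 100, K = NULL,
                     L = 5, per_wave = FALSE) {
  if (inherits(model, "saom_fit")) model <- model$model
  if (n_sims < 20) stop("n_sims must be at least 20")
  M <- length(waves) - 1L
  if (length(model$rate_basic) == 1 && M > 1)
    model$rate_basic <- rep(model$rate_basic, M)
  if (is.null(K)) {
    K <- max(vapply(waves[-1], function(w)
      max(rowSums(w$adjacency[w$present, w$present, drop = FALSE])),
      numeric(1))) + 2
  }
  wave_aux <- function(w) aux_stats(w, K = K, L = L)
  obs_per_wave <- lapply(waves[-1], wave_aux)
  obs <- Reduce(`+`, obs_per_wave)
  sim_per_wave <- vector("list", M)
  sim_pooled <- matrix(NA_real_, n_sims, length(obs))
  for (m in seq_len(M)) sim_per_wave[[m]] <- matrix(NA_real_, n_sims,
                                                    length(obs))
  for (r in seq_len(n_sims)) {
    acc <- 0
    for (m in seq_len(M)) {
      xe <- simulate_period(waves[[m]], model, v, period = m)
      a <- wave_aux(xe)
      sim_per_wave[[m]][r, ] <- a
      acc <- acc + a
    }
    sim_pooled[r, ] <- acc
  }
  colnames(sim_pooled) <- names(obs)
  one_test <- function(o, S) {
    d_obs <- mahalanobis_distance(o, S)
    if (isTRUE(attr(d_obs, "degenerate"))) {
      warning("all simulated statistics constant; GOF test degenerate")
      return(list(mhd = as.numeric(d_obs), p = 1,
                  sim_mhd = rep(0, nrow(S))))
    }
    # leave-one-out distances keep simulated replicates exchangeable with
    # the observation (which is not part of its own reference cloud)
    sim_d <- vapply(seq_len(nrow(S)), function(r)
      as.numeric(mahalanobis_distance(S[r, ], S[-r, , drop = FALSE])),
      numeric(1))
    p <- (1 + sum(sim_d >= as.numeric(d_obs))) / (1 + nrow(S))
    list(mhd = as.numeric(d_obs), p = p, sim_mhd = sim_d)
  }
  if (per_wave) {
    tests <- lapply(seq_len(M), function(m)
      one_test(obs_per_wave[[m]], sim_per_wave[[m]]))
    return(structure(list(per_wave = tests, n_sims = n_sims, K = K, L = L),
                     class = "saom_gof"))
  }
  tst <- one_test(obs, sim_pooled)
  structure(list(mhd = tst$mhd, p = tst$p, sim_mhd = tst$sim_mhd,
                 n_sims = n_sims, observed = obs, sim_stats = sim_pooled,
                 K = K, L = L),
            class = "saom_gof")
}

#' @export
print.saom_gof <- function(x, ...) {
  if (!is.null(x$per_wave)) {
    cat("<saom_gof> per-wave tests:\n")
    for (m in seq_along(x$per_wave))
      cat(sprintf("  period %d: MHD = %.2f, p = %.3f\n", m,
                  x$per_wave[[m]]$mhd, x$per_wave[[m]]$p))
  } else {
    cat(sprintf("<saom_gof> MHD = %.2f, p = %.3f (%d simulations)\n",
                x$mhd, x$p, x$n_sims))
  }
  invisible(x)
}

#' Long-format table of simulated vs observed auxiliary statistics
#'
#' One row per (replicate, statistic) pair plus the observed values, ready
#' for violin plots of the three statistic families.
#'
#' @param gof a pooled `saom_gof`.
#' @return data frame with columns `statistic`, `group`, `source`,
#'   `replicate`, `value`.
#' @export
gof_long_table <- function(gof) {
  if (is.null(gof$sim_stats)) stop("per-wave gof has no pooled table")
  stats <- colnames(gof$sim_stats)
  groups <- attr(gof$observed, "groups")
  sim <- data.frame(
    statistic = rep(stats, each = nrow(gof$sim_stats)),
    group = rep(groups, each = nrow(gof$sim_stats)),
    source = "simulated",
    replicate = rep(seq_len(nrow(gof$sim_stats)), times = length(stats)),
    value = as.vector(gof$sim_stats))
  obs <- data.frame(statistic = stats, group = groups, source = "observed",
                    replicate = NA_integer_,
                    value = as.numeric(gof$observed))
  rbind(sim, obs)
}
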