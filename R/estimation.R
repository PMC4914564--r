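#' Estimation options
#'
#' Budgets and numerical settings for the three-phase method-of-moments
#' stochastic approximation.
#'
#' @param n1 simulations per point for the Phase-1 finite-difference
#'   derivative (common random numbers across points).
#' @param n2_subphases number of Phase-2 sub-phases; the gain is halved and
#'   the iteration count doubled at each.
#' @param n2_base iterations in the first sub-phase.
#' @param n3 Phase-3 simulations for convergence t-ratios and standard
#'   errors.
#' @param n3_deriv simulations per point for the Phase-3 derivative
#'   re-estimate.
#' @param gain initial Robbins-Monro gain.
#' @param fd_step finite-difference step for evaluation/rate-covariate
#'   parameters (basic rates use a proportional step of the same size).
#' @param conv_threshold convergence requires every |t-ratio| below this.
#' @param ridge ridge added to a near-singular derivative matrix.
#' @param max_steps per-period microstep cap guarding against degenerate
#'   chains (`NULL` = automatic).
#' @param theta_max hard clamp on |evaluation parameters| during updates.
#' @param refresh_deriv re-estimate the derivative after the first
#'   sub-phase (the Phase-1 estimate is taken at the start value)?
#' @param auto_init_rates initialize basic rates from the observed
#'   per-period Hamming distances?
#' @param max_retries extra small-gain Phase-2 blocks run when the
#'   convergence check fails after Phase 3.
#' @param step_max largest per-parameter movement allowed in one Phase-2
#'   update (trust-region style truncation).
#' @return list of options.
#' @export
estimation_options <- function(n1 = 50, n2_subphases = 4, n2_base = 50,
                               n3 = 500, n3_deriv = 25, gain = 0.2,
                               fd_step = 0.2, conv_threshold = 0.15,
                               ridge = 1e-6, max_steps = NULL,
                               theta_max = 8, refresh_deriv = TRUE,
                               auto_init_rates = TRUE, max_retries = 1,
                               step_max = 0.5) {
  as.list(environment())
}

# ---- fit context: everything about the data that does not depend on theta

fit_context <- function(waves, model, v) {
  if (length(waves) < 2) stop("need at least 2 waves")
  M <- length(waves) - 1L
  if (length(model$rate_basic) != M)
    stop("model has ", length(model$rate_basic), " rate parameters for ",
         M, " periods")
  ids <- rownames(waves[[1]]$adjacency)
  for (w in waves) {
    if (!identical(rownames(w$adjacency), ids))
      stop("all waves must share the same full roster")
  }
  evals <- eval_effects(model)
  rates <- rate_effects(model)
  dyadic <- vapply(evals, function(e)
    e$name %in% c("density", "simx", "ego_alter"), logical(1))
  periods <- vector("list", M)
  for (m in seq_len(M)) {
    ws <- waves[[m]]; we <- waves[[m + 1L]]
    pres_start <- ws$present
    joint <- ws$present & we$present
    if (sum(pres_start) < 2) stop("fewer than 2 actors present in wave ", m)
    Wsim <- lapply(evals[dyadic], dyadic_weight_matrix,
                   adj = ws$adjacency, present = pres_start, v = v)
    Wstat <- lapply(evals[dyadic], dyadic_weight_matrix,
                    adj = ws$adjacency, present = joint, v = v)
    rc <- if (length(rates))
      vapply(rates, function(e)
        as.numeric(covariate_values(v, e$covariate, ids)), numeric(length(ids)))
    else matrix(0, length(ids), 0)
    periods[[m]] <- list(
      adj_start = ws$adjacency, adj_end = we$adjacency,
      pres_start = pres_start, joint = joint, Wsim = Wsim, Wstat = Wstat,
      rate_cov = rc)
  }
  theta_labels <- c(paste0("rate.period", seq_len(M)),
                    vapply(rates, effect_label, character(1)),
                    vapply(evals, effect_label, character(1)))
  list(M = M, ids = ids, evals = evals, rates = rates, dyadic = dyadic,
       periods = periods, n_rate = M, n_alpha = length(rates),
       n_beta = length(evals), theta_labels = theta_labels,
       fixed = c(rep(FALSE, M), vapply(rates, `[[`, logical(1), "fixed"),
                 vapply(evals, `[[`, logical(1), "fixed")))
}

theta_from_model <- function(model, ctx) {
  c(model$rate_basic,
    vapply(ctx$rates, `[[`, numeric(1), "parameter"),
    vapply(ctx$evals, `[[`, numeric(1), "parameter"))
}

model_from_theta <- function(theta, model, ctx) {
  model$rate_basic <- theta[seq_len(ctx$n_rate)]
  k <- ctx$n_rate
  eff <- model$effects
  for (idx in seq_along(eff)) {
    if (eff[[idx]]$name == "rate_covariate") next
  }
  # rebuild effect parameters in the ctx ordering
  ri <- 0L; ei <- 0L
  for (idx in seq_along(eff)) {
    if (eff[[idx]]$name == "rate_covariate") {
      ri <- ri + 1L
      eff[[idx]]$parameter <- theta[k + ri]
    } else {
      ei <- ei + 1L
      eff[[idx]]$parameter <- theta[k + ctx$n_alpha + ei]
    }
  }
  model$effects <- eff
  model
}

# statistics of one period given its end-wave adjacency (observed or
# simulated), restricted to jointly present actors
period_stats <- function(adj_end, ctx, m) {
  pd <- ctx$periods[[m]]
  joint <- pd$joint
  a0 <- pd$adj_start; a1 <- adj_end
  a0[!joint, ] <- 0L; a0[, !joint] <- 0L
  a1[!joint, ] <- 0L; a1[, !joint] <- 0L
  dif <- abs(a1 - a0)
  hamming <- sum(dif) / 2
  d_i <- rowSums(dif)
  alpha_stats <- if (ctx$n_alpha)
    as.numeric(crossprod(pd$rate_cov * joint, d_i)) else numeric(0)
  deg <- rowSums(a1)
  beta_stats <- numeric(ctx$n_beta)
  di <- 0L
  A2 <- NULL
  for (k in seq_len(ctx$n_beta)) {
    e <- ctx$evals[[k]]
    if (e$name == "transtrip") {
      if (is.null(A2)) A2 <- a1 %*% a1
      beta_stats[k] <- sum(A2 * a1)
    } else if (e$name == "inpop") {
      beta_stats[k] <- sum(deg^2)
    } else {
      di <- di + 1L
      beta_stats[k] <- sum(pd$Wstat[[di]] * a1)
    }
  }
  list(hamming = hamming, alpha = alpha_stats, beta = beta_stats)
}

assemble_stats <- function(per_period, ctx) {
  rates <- vapply(per_period, `[[`, numeric(1), "hamming")
  alphas <- if (ctx$n_alpha)
    Reduce(`+`, lapply(per_period, `[[`, "alpha")) else numeric(0)
  betas <- Reduce(`+`, lapply(per_period, `[[`, "beta"))
  out <- c(rates, alphas, betas)
  names(out) <- ctx$theta_labels
  out
}

#' Observed target statistics
#'
#' The method-of-moments targets: for each evaluation effect, the end-wave
#' statistic summed over jointly present actors and over periods; for each
#' period, the Hamming distance (number of differing dyads) between
#' consecutive waves; for each rate covariate, the covariate-weighted count
#' of per-actor tie changes.
#'
#' @param waves list of [wave_network()] (at least 2) on a shared roster.
#' @param model a [saom_model()].
#' @param v a [covariate_table()].
#' @return named numeric vector in parameter order.
#' @export
observed_targets <- function(waves, model, v = NULL) {
  ctx <- fit_context(waves, model, v)
  per <- lapply(seq_len(ctx$M), function(m)
    period_stats(ctx$periods[[m]]$adj_end, ctx, m))
  assemble_stats(per, ctx)
}

sim_stats_once <- function(theta, ctx, opts) {
  M <- ctx$M
  rho <- theta[seq_len(M)]
  alpha <- theta[M + seq_len(ctx$n_alpha)]
  beta <- theta[M + ctx$n_alpha + seq_len(ctx$n_beta)]
  beta_tt <- 0; beta_ip <- 0
  per <- vector("list", M)
  for (m in seq_len(M)) {
    pd <- ctx$periods[[m]]
    n <- length(ctx$ids)
    wsum <- matrix(0, n, n)
    beta_tt <- 0; beta_ip <- 0; di <- 0L
    for (k in seq_len(ctx$n_beta)) {
      e <- ctx$evals[[k]]
      if (e$name == "transtrip") beta_tt <- beta[k]
      else if (e$name == "inpop") beta_ip <- beta[k]
      else { di <- di + 1L; wsum <- wsum + beta[k] * pd$Wsim[[di]] }
    }
    lp <- if (ctx$n_alpha) as.numeric(pd$rate_cov %*% alpha)
          else numeric(n)
    lam <- rho[m] * exp(lp)
    lam[!pd$pres_start] <- 0
    if (any(!is.finite(lam))) stop("non-finite rates during simulation")
    max_steps <- if (is.null(opts$max_steps))
      ceiling(5000 + 100 * sum(lam)) else opts$max_steps
    out <- simulate_microsteps_cpp(pd$adj_start, lam, wsum, beta_tt,
                                   beta_ip, 1.0, as.integer(max_steps), 0L)
    if (isTRUE(out$hit_cap)) stop("microstep cap exceeded (degenerate chain)")
    per[[m]] <- period_stats(out$adjacency, ctx, m)
  }
  assemble_stats(per, ctx)
}

# central finite-difference derivative of E[S] w.r.t. theta, with common
# random numbers across the two points of each difference; only free
# parameters are perturbed
fd_derivative <- function(theta, ctx, opts, n_reps) {
  p <- length(theta)
  free <- which(!ctx$fixed)
  eps <- ifelse(seq_len(p) <= ctx$n_rate,
                pmax(opts$fd_step, opts$fd_step * abs(theta)), opts$fd_step)
  # keep the lower rate point positive
  eps[seq_len(ctx$n_rate)] <- pmin(eps[seq_len(ctx$n_rate)],
                                   1.8 * theta[seq_len(ctx$n_rate)])
  seeds <- sample.int(2^31 - 2, n_reps)
  D <- matrix(0, p, p, dimnames = list(ctx$theta_labels, ctx$theta_labels))
  for (k in free) {
    hi <- theta; hi[k] <- hi[k] + eps[k] / 2
    lo <- theta; lo[k] <- lo[k] - eps[k] / 2
    acc <- numeric(p)
    for (r in seq_len(n_reps)) {
      set.seed(seeds[r])
      s_hi <- sim_stats_once(hi, ctx, opts)
      set.seed(seeds[r])
      s_lo <- sim_stats_once(lo, ctx, opts)
      acc <- acc + (s_hi - s_lo)
    }
    D[, k] <- acc / (n_reps * eps[k])
  }
  diag(D)[ctx$fixed] <- 1  # keep invertible; fixed rows/cols are inert
  D
}

solve_ridge <- function(D, b, ridge) {
  out <- tryCatch(solve(D, b), error = function(e) NULL)
  if (is.null(out) || any(!is.finite(out))) {
    warning("near-singular derivative matrix; applying ridge")
    out <- solve(D + diag(ridge, nrow(D)), b)
  }
  out
}

# protect the Newton direction on badly conditioned derivative estimates:
# scale a ridge to the diagonal until the condition number is tolerable
condition_derivative <- function(D, max_kappa = 1e6) {
  sv <- svd(D)$d
  if (min(sv) <= 0 || max(sv) / min(sv) > max_kappa) {
    lam <- max(sv) / max_kappa
    D <- D + diag(pmax(lam, 1e-8), nrow(D))
  }
  D
}

cap_step <- function(step, step_max) {
  biggest <- max(abs(step))
  if (is.finite(biggest) && biggest > step_max)
    step <- step * (step_max / biggest)
  step
}

clamp_theta <- function(theta, ctx, opts) {
  r <- seq_len(ctx$n_rate)
  theta[r] <- pmin(pmax(theta[r], 0.05), 50)
  rest <- setdiff(seq_along(theta), r)
  theta[rest] <- pmin(pmax(theta[rest], -opts$theta_max), opts$theta_max)
  theta
}

#' Fit a SAOM by method of moments
#'
#' Three-phase Robbins-Monro stochastic approximation. Phase 1 estimates
#' the derivative of the expected statistics with respect to the parameters
#' by finite differences over simulated periods; Phase 2 runs sub-phases of
#' Newton-like updates `theta <- theta - a D^-1 (S_sim - S_obs)` with the
#' gain halved per sub-phase, each sub-phase ending with trajectory
#' averaging; Phase 3 simulates at the final estimate to obtain convergence
#' t-ratios (mean deviation / sd of deviations per statistic) and
#' delta-method standard errors, with a re-estimated derivative. Basic rate
#' parameters are fitted by matching the expected to the observed Hamming
#' distance per period (unconditional moment estimation).
#'
#' @param waves list of [wave_network()] on a shared roster.
#' @param model starting [saom_model()]; its parameters seed Phase 2.
#' @param v a [covariate_table()].
#' @param opts an [estimation_options()] list.
#' @return An object of class `saom_fit`: the fitted model, an `estimates`
#'   data frame (estimate, standard error, convergence t-ratio, Wald chi2,
#'   DF, p-value per free parameter), `converged`, `tstats`, phase-2
#'   iteration count and the statistic covariance.
#' @export
robbins_monro_fit <- function(waves, model, v = NULL,
                              opts = estimation_options()) {
  ctx <- fit_context(waves, model, v)
  s_obs <- observed_targets(waves, model, v)
  theta <- clamp_theta(theta_from_model(model, ctx), ctx, opts)
  free <- !ctx$fixed
  if (isTRUE(opts$auto_init_rates)) {
    # a period's Hamming distance understates the number of microstep
    # changes (back-and-forth toggles cancel); 3H/n is a serviceable start
    n_pres <- vapply(ctx$periods, function(pd) sum(pd$pres_start),
                     numeric(1))
    h <- s_obs[seq_len(ctx$n_rate)]
    theta[seq_len(ctx$n_rate)] <- pmax(0.5, 3 * h / n_pres)
  }

  # Phase 1: derivative at the start value
  D <- condition_derivative(fd_derivative(theta, ctx, opts,
                                          ctx_reps(opts$n1)))

  # Phase 2: stochastic approximation with sub-phase averaging
  n_iter_total <- 0L
  fails <- 0L
  for (sub in seq_len(opts$n2_subphases)) {
    a <- opts$gain / 2^(sub - 1)
    n_iter <- opts$n2_base * 2^(sub - 1)
    hist <- matrix(NA_real_, n_iter, length(theta))
    for (it in seq_len(n_iter)) {
      s_sim <- tryCatch(sim_stats_once(theta, ctx, opts),
                        error = function(e) NULL)
      if (is.null(s_sim)) {
        fails <- fails + 1L
        theta[free] <- theta[free] * 0.8  # pull back toward zero
        hist[it, ] <- theta
        next
      }
      step <- cap_step(solve_ridge(D, s_sim - s_obs, opts$ridge),
                       opts$step_max / a)
      step[!free] <- 0
      theta <- clamp_theta(theta - a * step, ctx, opts)
      hist[it, ] <- theta
    }
    theta <- clamp_theta(colMeans(hist), ctx, opts)
    n_iter_total <- n_iter_total + n_iter
    if (isTRUE(opts$refresh_deriv) && sub == 1) {
      # the Phase-1 derivative was taken at the start value; re-estimate
      # near the solution before the small-gain sub-phases
      D <- condition_derivative(fd_derivative(theta, ctx, opts,
                                              ctx_reps(opts$n1)))
    }
  }

  # Phase 3: t-ratios, covariance, standard errors; when the convergence
  # check fails, one further small-gain Phase-2 block is run from the
  # current answer and Phase 3 repeated
  phase3 <- function(theta) {
    S3 <- matrix(NA_real_, opts$n3, length(theta))
    ok <- logical(opts$n3)
    for (r in seq_len(opts$n3)) {
      s <- tryCatch(sim_stats_once(theta, ctx, opts),
                    error = function(e) NULL)
      if (!is.null(s)) { S3[r, ] <- s; ok[r] <- TRUE }
    }
    S3 <- S3[ok, , drop = FALSE]
    if (nrow(S3) < 10) stop("Phase 3 failed: too few successful simulations")
    S3
  }
  tstats_of <- function(S3) {
    dev <- sweep(S3, 2, s_obs)
    sds <- apply(dev, 2, sd)
    colMeans(dev) / ifelse(sds > 0, sds, Inf)
  }
  S3 <- phase3(theta)
  tstats <- tstats_of(S3)
  retries <- 0L
  while (any(abs(tstats[free]) >= opts$conv_threshold) &&
         retries < opts$max_retries) {
    retries <- retries + 1L
    a <- opts$gain / 2^(opts$n2_subphases - 1)
    n_iter <- opts$n2_base * 2^(opts$n2_subphases - 1)
    hist <- matrix(NA_real_, n_iter, length(theta))
    for (it in seq_len(n_iter)) {
      s_sim <- tryCatch(sim_stats_once(theta, ctx, opts),
                        error = function(e) NULL)
      if (is.null(s_sim)) { hist[it, ] <- theta; next }
      step <- cap_step(solve_ridge(D, s_sim - s_obs, opts$ridge),
                       opts$step_max / a)
      step[!free] <- 0
      theta <- clamp_theta(theta - a * step, ctx, opts)
      hist[it, ] <- theta
    }
    theta <- clamp_theta(colMeans(hist), ctx, opts)
    n_iter_total <- n_iter_total + n_iter
    S3 <- phase3(theta)
    tstats <- tstats_of(S3)
  }
  Sigma <- cov(S3)
  D3 <- fd_derivative(theta, ctx, opts, ctx_reps(opts$n3_deriv))
  Dinv <- tryCatch(solve(D3), error = function(e) {
    warning("near-singular Phase-3 derivative; applying ridge")
    solve(D3 + diag(opts$ridge, nrow(D3)))
  })
  cov_theta <- Dinv %*% Sigma %*% t(Dinv)
  se <- sqrt(pmax(diag(cov_theta), 0))
  converged <- all(abs(tstats[free]) < opts$conv_threshold)

  est <- data.frame(parameter = ctx$theta_labels, estimate = theta,
                    se = se, t_ratio = tstats, row.names = NULL,
                    stringsAsFactors = FALSE)
  # Wald tests for effect parameters (not period rates)
  est$X2 <- NA_real_
  est$DF <- NA_real_
  est$p_value <- NA_real_
  eff_rows <- which(seq_along(theta) > ctx$n_rate)
  for (r in eff_rows) {
    if (se[r] > 0) {
      wt <- wald_test(theta[r], se[r])
      est$X2[r] <- wt$X2; est$DF[r] <- wt$DF; est$p_value[r] <- wt$p
    }
  }
  structure(list(model = model_from_theta(theta, model, ctx),
                 estimates = est, tstats = tstats, converged = converged,
                 n_iterations = n_iter_total, n_failures = fails,
                 cov_theta = cov_theta, sigma = Sigma,
                 s_obs = s_obs, ctx_labels = ctx$theta_labels),
            class = "saom_fit")
}

ctx_reps <- function(n) max(3L, as.integer(n))

#' @export
print.saom_fit <- function(x, ...) {
  cat("<saom_fit>", if (x$converged) "converged" else "NOT converged",
      sprintf("(max |t| = %.3f, %d phase-2 iterations)\n",
              max(abs(x$tstats)), x$n_iterations))
  df <- x$estimates
  df$estimate <- round(df$estimate, 3)
  df$se <- round(df$se, 3)
  df$t_ratio <- round(df$t_ratio, 3)
  df$X2 <- round(df$X2, 3)
  df$p_value <- signif(df$p_value, 3)
  print(df)
  invisible(x)
}

#' Wald-type test of a single parameter
#'
#' Under the null hypothesis that the parameter is zero, the squared ratio
#' of estimate to standard error is chi-squared with one degree of freedom.
#'
#' @param estimate parameter estimate.
#' @param se its standard error (must be positive).
#' @return list with `X2`, `DF` (= 1) and the upper-tail `p`.
#' @export
wald_test <- function(estimate, se) {
  if (!is.numeric(se) || se <= 0) stop("se must be positive")
  X2 <- (estimate / se)^2
  list(X2 = X2, DF = 1L, p = pchisq(X2, df = 1, lower.tail = FALSE))
}

#' Stepwise forward selection of effects
#'
#' Mirrors the analytical protocol of adding candidate effects one by one
#' to a baseline model (density plus per-period rates), refitting, and
#' retaining an addition only when significant at `alpha`. Covariate
#' homophily candidates are added as a similarity + ego x alter pair and
#' retained only when both members are significant. A candidate whose refit
#' does not converge is dropped with a trace annotation.
#'
#' @param waves list of [wave_network()].
#' @param candidates list of candidates; each candidate is a single
#'   [saom_effect()] or a list of effects added together (e.g. the
#'   simx/ego_alter pair).
#' @param v a [covariate_table()].
#' @param opts an [estimation_options()] list.
#' @param alpha significance threshold for retention.
#' @param density_init,rate_init starting values for the baseline model.
#' @param fitter fitting function with the signature of
#'   [robbins_monro_fit()]; injectable for testing the selection logic.
#' @return list with the final fitted model (`fit`), the final `model`, and
#'   a `trace` data frame (candidate, estimate, p-value, kept, reason).
#' @export
forward_select <- function(waves, candidates, v = NULL,
                           opts = estimation_options(), alpha = 0.05,
                           density_init = -1, rate_init = 3,
                           fitter = robbins_monro_fit) {
  M <- length(waves) - 1L
  base_effects <- list(saom_effect("density", parameter = density_init))
  current <- saom_model(base_effects, rep(rate_init, M))
  current_fit <- fitter(waves, current, v, opts)
  current <- current_fit$model
  trace <- list()
  for (cand in candidates) {
    if (inherits(cand, "saom_effect")) cand <- list(cand)
    labels <- vapply(cand, effect_label, character(1))
    trial <- saom_model(c(current$effects, cand), current$rate_basic)
    fit <- tryCatch(fitter(waves, trial, v, opts), error = function(e) NULL)
    if (is.null(fit) || !isTRUE(fit$converged)) {
      for (lb in labels)
        trace[[length(trace) + 1L]] <- data.frame(
          candidate = lb, estimate = NA_real_, p_value = NA_real_,
          kept = FALSE, reason = "not converged")
      next
    }
    rows <- match(labels, fit$estimates$parameter)
    pv <- fit$estimates$p_value[rows]
    estv <- fit$estimates$estimate[rows]
    keep <- all(!is.na(pv)) && all(pv < alpha)
    for (k in seq_along(labels))
      trace[[length(trace) + 1L]] <- data.frame(
        candidate = labels[k], estimate = estv[k], p_value = pv[k],
        kept = keep,
        reason = if (keep) "significant" else if (length(labels) > 1)
          "pair not jointly significant" else "not significant")
    if (keep) {
      current <- fit$model
      current_fit <- fit
    }
  }
  trace_df <- if (length(trace))
    do.call(rbind, c(trace, list(make.row.names = FALSE))) else NULL
  list(fit = current_fit, model = current, trace = trace_df)
}

#' Default candidate order for forward selection
#'
#' Structural effects first (transitive triplets, degree popularity), then
#' per covariate the paired similarity + ego x alter homophily candidates,
#' then covariate rate effects.
#'
#' @param simx_covariates covariates to test for homophily.
#' @param rate_covariates covariates to test on the rate function.
#' @return list of candidates for [forward_select()].
#' @export
default_candidates <- function(simx_covariates = character(),
                               rate_covariates = character()) {
  cands <- list(saom_effect("transtrip"), saom_effect("inpop"))
  for (cv in simx_covariates)
    cands <- c(cands, list(list(saom_effect("simx", cv),
                                saom_effect("ego_alter", cv))))
  for (cv in rate_covariates)
    cands <- c(cands, list(saom_effect("rate_covariate", cv)))
  cands
}

#' Write fit results as a results table CSV
#'
#' Columns mirror the conventional SAOM summary: Estimate, Std error,
#' t ratio, X2, DF, P-value.
#'
#' @param fit a `saom_fit`.
#' @param path output CSV path.
#' @param seed seed to record alongside the results.
#' @return the data frame written, invisibly.
#' @export
write_fit_csv <- function(fit, path, seed = NA) {
  df <- fit$estimates
  names(df) <- c("Effect", "Estimate", "Std.error", "t.ratio", "X2", "DF",
                 "P.value")
  df$converged <- fit$converged
  df$seed <- seed
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}
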