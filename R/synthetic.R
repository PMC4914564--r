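#' Generate a synthetic group roster with covariates
#'
#' Emulates the composition of a wild vervet monkey group: actors carry a
#' sex (0 = male, 1 = female), a matriline, an age class (0 = juvenile,
#' 1 = adult) and a dominance rank from a latent linear hierarchy ordered
#' by matriline blocks (matrilines hold contiguous rank ranges, as is
#' typical of female-philopatric cercopithecines).
#'
#' @param n group size (>= 2). Field groups ranged from 25 to 48 actors.
#' @param female_fraction expected fraction of females (default 0.5, the
#'   middle of the observed 44-56% range).
#' @param n_matrilines number of matrilines (multinomial assignment).
#' @param adult_fraction expected fraction of adults (default 0.4,
#'   matching the observed 31-43% adult ratios).
#' @return list with `roster` (actor ids), `covariates` (a
#'   [covariate_table()]; `rank` ordinal, `matriline` categorical) and
#'   `latent_order` (actor ids most dominant first).
#' @export
gen_roster <- function(n, female_fraction = 0.5, n_matrilines = 4,
                       adult_fraction = 0.4) {
  if (n < 2) stop("need at least 2 actors")
  if (female_fraction < 0 || female_fraction > 1 ||
      adult_fraction < 0 || adult_fraction > 1)
    stop("fractions must lie in [0, 1]")
  if (n_matrilines < 1) stop("need at least one matriline")
  ids <- sprintf("id%02d", seq_len(n))
  sex <- rbinom(n, 1, female_fraction)
  matriline <- sample.int(n_matrilines, n, replace = TRUE)
  age <- rbinom(n, 1, adult_fraction)
  # latent hierarchy: matrilines ordered, actors contiguous within blocks
  latent <- order(matriline, sample.int(n))
  rank <- integer(n)
  rank[latent] <- seq_len(n)
  cv <- covariate_table(
    data.frame(actor = ids, sex = sex, matriline = matriline, rank = rank,
               age_class = age),
    types = c(sex = "categorical", matriline = "categorical",
              rank = "ordinal", age_class = "categorical"))
  list(roster = ids, covariates = cv, latent_order = ids[latent])
}

#' Random starting network
#'
#' Erdos-Renyi graph over the roster at the given density.
#'
#' @param roster actor ids.
#' @param density expected edge density.
#' @return a [wave_network()].
#' @export
gen_initial_network <- function(roster, density = 0.1) {
  n <- length(roster)
  adj <- matrix(0L, n, n, dimnames = list(roster, roster))
  ut <- which(upper.tri(adj))
  adj[ut] <- rbinom(length(ut), 1, density)
  adj[lower.tri(adj)] <- t(adj)[lower.tri(adj)]
  wave_network(adj)
}

#' Forward-simulate a wave sequence from a known model
#'
#' Simulates each observation period with [simulate_period()], applying
#' composition change at the period boundaries: joiners start with no ties,
#' leavers drop out with all their ties (an emulation of infant
#' integration and male migration between quarters).
#'
#' @param model the true [saom_model()] (its `rate_basic` length fixes the
#'   number of periods: `n_waves - 1`).
#' @param x0 starting [wave_network()].
#' @param v a [covariate_table()] covering every actor in `x0`.
#' @param n_waves number of waves (>= 2).
#' @param turnover optional list with integer vectors `join` and `leave`
#'   (per boundary counts); actors to leave are drawn from those present,
#'   joiners from those currently absent. Default: no turnover.
#' @return list with `waves` (list of `wave_network`) and `truth` (model,
#'   settings, per-wave presence).
#' @export
gen_waves <- function(model, x0, v = NULL, n_waves = 8, turnover = NULL) {
  if (n_waves < 2) stop("need at least 2 waves")
  if (length(model$rate_basic) == 1 && n_waves > 2)
    model$rate_basic <- rep(model$rate_basic, n_waves - 1)
  if (length(model$rate_basic) != n_waves - 1)
    stop("model must carry one rate per period")
  waves <- vector("list", n_waves)
  waves[[1]] <- x0
  for (m in seq_len(n_waves - 1)) {
    nxt <- simulate_period(waves[[m]], model, v, period = m)
    if (!is.null(turnover)) {
      adj <- nxt$adjacency
      pres <- nxt$present
      nl <- if (length(turnover$leave) >= m) turnover$leave[m] else 0L
      nj <- if (length(turnover$join) >= m) turnover$join[m] else 0L
      if (nl > 0) {
        out <- sample(which(pres), min(nl, sum(pres) - 2))
        pres[out] <- FALSE
        adj[out, ] <- 0L
        adj[, out] <- 0L
      }
      if (nj > 0 && any(!pres)) {
        joiners <- sample(which(!pres), min(nj, sum(!pres)))
        pres[joiners] <- TRUE
      }
      nxt <- wave_network(adj, period = m + 1L, present = pres)
    } else {
      nxt$period <- m + 1L
    }
    waves[[m + 1]] <- nxt
  }
  list(waves = waves,
       truth = list(model = model, n_waves = n_waves, turnover = turnover))
}

#' Generate scan-like behavior count matrices from a true network
#'
#' For each of the three behaviors, dyad counts are Binomial(n_scans,
#' p_link) on true ties and Binomial(n_scans, p_background) elsewhere: the
#' three behaviors share the true network but carry independent sampling
#' noise, so the two-of-three binarization rule is meaningfully exercised.
#' Grooming counts are split at random between the two directions;
#' proximity matrices are symmetric.
#'
#' @param true_network a [wave_network()].
#' @param n_scans scans per dyad and period.
#' @param p_link per-scan association probability on true ties.
#' @param p_background per-scan association probability elsewhere (must be
#'   smaller than `p_link`).
#' @return named list of three count matrices as from
#'   [build_behavior_matrices()].
#' @export
gen_scan_counts <- function(true_network, n_scans = 200, p_link = 0.3,
                            p_background = 0.02) {
  if (p_background < 0 || p_link > 1 || p_background >= p_link)
    stop("need 0 <= p_background < p_link <= 1")
  adj <- as_adjacency(true_network)
  n <- nrow(adj)
  ids <- rownames(adj)
  out <- lapply(BEHAVIORS, function(bh) {
    m <- matrix(0L, n, n, dimnames = list(ids, ids))
    ut <- which(upper.tri(m), arr.ind = TRUE)
    p <- ifelse(adj[upper.tri(adj)] == 1, p_link, p_background)
    counts <- rbinom(nrow(ut), n_scans, p)
    if (bh == "groom") {
      given <- rbinom(nrow(ut), counts, 0.5)
      m[ut] <- given
      m[ut[, c(2, 1), drop = FALSE]] <- counts - given
    } else {
      m[upper.tri(m)] <- counts
      m[lower.tri(m)] <- t(m)[lower.tri(m)]
    }
    storage.mode(m) <- "integer"
    attr(m, "behavior") <- bh
    attr(m, "period") <- if (inherits(true_network, "wave_network"))
      true_network$period else 1L
    m
  })
  names(out) <- BEHAVIORS
  out
}

#' Expand behavior count matrices into scan-record rows
#'
#' Inverse of [build_behavior_matrices()]: emits one record per grooming
#' count (directed) and one per proximity dyad count, in the CSV dialect
#' the ingestion step consumes.
#'
#' @param counts named list of three count matrices.
#' @param period period identifier for the records.
#' @return data frame with columns period, focal, partner, behavior.
#' @export
scan_records_from_counts <- function(counts,
                                     period = attr(counts[[1]], "period")) {
  rows <- list()
  for (bh in BEHAVIORS) {
    m <- counts[[bh]]
    ids <- rownames(m)
    idx <- if (bh == "groom") which(m > 0, arr.ind = TRUE)
           else which(upper.tri(m) & m > 0, arr.ind = TRUE)
    if (nrow(idx) == 0) next
    reps <- m[idx]
    rows[[bh]] <- data.frame(
      period = period,
      focal = rep(ids[idx[, 1]], reps),
      partner = rep(ids[idx[, 2]], reps),
      behavior = bh)
  }
  if (!length(rows))
    return(data.frame(period = integer(), focal = character(),
                      partner = character(), behavior = character()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a winner-loser matrix from a latent hierarchy
#'
#' Agonistic bouts fall on uniformly random dyads; the higher-ranked actor
#' wins each bout with probability `1 - upset_prob`.
#'
#' @param rank_order actor ids, most dominant first.
#' @param n_bouts total number of bouts.
#' @param upset_prob probability the lower-ranked actor wins (in
#'   `[0, 0.5)`).
#' @return square integer wins matrix with actor-id dimnames.
#' @export
gen_agonistic <- function(rank_order, n_bouts = 500, upset_prob = 0.1) {
  if (upset_prob < 0 || upset_prob >= 0.5)
    stop("upset_prob must lie in [0, 0.5)")
  ids <- as.character(rank_order)
  n <- length(ids)
  wins <- matrix(0L, n, n, dimnames = list(ids, ids))
  if (n_bouts > 0 && n >= 2) {
    a <- sample.int(n, n_bouts, replace = TRUE)
    b <- sapply(a, function(x) sample(setdiff(seq_len(n), x), 1))
    hi <- pmin(a, b)   # ids are in rank order: smaller index = higher rank
    lo <- pmax(a, b)
    upset <- runif(n_bouts) < upset_prob
    for (k in seq_len(n_bouts)) {
      if (upset[k]) wins[lo[k], hi[k]] <- wins[lo[k], hi[k]] + 1L
      else wins[hi[k], lo[k]] <- wins[hi[k], lo[k]] + 1L
    }
  }
  wins
}

#' Generate a complete synthetic study with known ground truth
#'
#' Bundles the generators into one call emulating a field study: a roster
#' with covariates, a true model with structural and homophily dynamics,
#' SAOM-simulated waves, scan-like count matrices per wave, and an
#' agonistic matrix consistent with the latent hierarchy.
#'
#' @param n group size.
#' @param n_waves number of quarterly waves (default 8, two years of
#'   3-month periods).
#' @param model true [saom_model()]; default: density -1.8, transitive
#'   triplets 0.4, degree popularity 0.1, same-sex homophily 0.5, basic
#'   rate 1.5 per period (a quarter replaces a moderate minority of ties,
#'   keeping the simulated panels away from the dense degenerate regime).
#' @param x0_density starting network density.
#' @param turnover passed to [gen_waves()].
#' @param scans,p_link,p_background passed to [gen_scan_counts()].
#' @param n_bouts,upset_prob passed to [gen_agonistic()].
#' @param ... passed to [gen_roster()].
#' @return list with `roster`, `covariates`, `latent_order`, `waves`,
#'   `scan_counts` (per wave), `agonistic`, and `truth`.
#' @export
gen_study <- function(n = 30, n_waves = 8, model = NULL, x0_density = 0.05,
                      turnover = NULL, scans = 200, p_link = 0.3,
                      p_background = 0.02, n_bouts = 500, upset_prob = 0.1,
                      ...) {
  ros <- gen_roster(n, ...)
  if (is.null(model)) {
    model <- saom_model(list(
      saom_effect("density", parameter = -1.8),
      saom_effect("transtrip", parameter = 0.4),
      saom_effect("inpop", parameter = 0.1),
      saom_effect("simx", "sex", parameter = 0.5)),
      rate_basic = rep(1.5, n_waves - 1))
  }
  x0 <- gen_initial_network(ros$roster, x0_density)
  gw <- gen_waves(model, x0, ros$covariates, n_waves, turnover)
  scan_counts <- lapply(gw$waves, gen_scan_counts, n_scans = scans,
                        p_link = p_link, p_background = p_background)
  ago <- gen_agonistic(ros$latent_order, n_bouts, upset_prob)
  list(roster = ros$roster, covariates = ros$covariates,
       latent_order = ros$latent_order, waves = gw$waves,
       scan_counts = scan_counts, agonistic = ago,
       truth = c(gw$truth, list(latent_order = ros$latent_order)))
}
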