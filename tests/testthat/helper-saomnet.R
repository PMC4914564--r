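# shared fixtures and independent brute-force oracles

rand_sym_graph <- function(n, p = 0.4) {
  adj <- matrix(0L, n, n, dimnames = list(paste0("a", seq_len(n)),
                                          paste0("a", seq_len(n))))
  ut <- which(upper.tri(adj))
  adj[ut] <- rbinom(length(ut), 1, p)
  adj[lower.tri(adj)] <- t(adj)[lower.tri(adj)]
  adj
}

rand_covariates <- function(n) {
  covariate_table(
    data.frame(actor = paste0("a", seq_len(n)),
               sex = rbinom(n, 1, 0.5),
               matriline = sample.int(3, n, replace = TRUE),
               rank = sample.int(n),
               age_class = rbinom(n, 1, 0.4)),
    types = c(sex = "categorical", matriline = "categorical",
              rank = "ordinal", age_class = "categorical"))
}

# brute-force effect statistics: plain loops, no matrix algebra
bf_density <- function(adj, i) sum(adj[i, ])

bf_transtrip <- function(adj, i) {
  n <- nrow(adj)
  tot <- 0
  for (j in seq_len(n)) for (h in seq_len(n)) {
    if (j == h || j == i || h == i) next
    tot <- tot + adj[i, j] * adj[i, h] * adj[j, h]
  }
  tot
}

bf_inpop <- function(adj, i) {
  n <- nrow(adj)
  tot <- 0
  for (j in seq_len(n)) {
    if (adj[i, j] == 1) tot <- tot + sum(adj[, j])
  }
  tot
}

bf_sim <- function(v, name, i, j, ids) {
  vals <- v[[name]][match(ids, v$actor)]
  ty <- attr(v, "types")[[name]]
  if (ty == "categorical") as.numeric(vals[i] == vals[j])
  else 1 - abs(vals[i] - vals[j]) / diff(range(vals))
}

bf_simx <- function(adj, i, v, name) {
  ids <- rownames(adj)
  n <- nrow(adj)
  sims <- c()
  for (a in seq_len(n - 1)) for (b in (a + 1):n)
    sims <- c(sims, bf_sim(v, name, a, b, ids))
  simbar <- mean(sims)
  tot <- 0
  for (j in seq_len(n)) if (j != i)
    tot <- tot + adj[i, j] * (bf_sim(v, name, i, j, ids) - simbar)
  tot
}

bf_ego_alter <- function(adj, i, v, name) {
  ids <- rownames(adj)
  vals <- v[[name]][match(ids, v$actor)]
  vals <- vals - mean(vals)
  tot <- 0
  for (j in seq_len(nrow(adj))) if (j != i)
    tot <- tot + adj[i, j] * vals[j]
  vals[i] * tot
}

# brute-force I&SI over every permutation
bf_isi_best <- function(wins) {
  n <- nrow(wins)
  perms <- saomnet:::permutations_of(n)
  best <- c(Inf, Inf)
  for (k in seq_len(ncol(perms))) {
    cc <- count_inconsistencies(perms[, k], wins)
    sc <- c(cc$I, cc$SI)
    if (sc[1] < best[1] || (sc[1] == best[1] && sc[2] < best[2]))
      best <- sc
  }
  best
}

triangle_net <- function() {
  adj <- matrix(0L, 3, 3, dimnames = list(c("a1", "a2", "a3"),
                                          c("a1", "a2", "a3")))
  adj[upper.tri(adj)] <- 1L
  adj[lower.tri(adj)] <- 1L
  wave_network(adj)
}

star_net <- function(leaves = 4) {
  n <- leaves + 1
  ids <- c("c", paste0("l", seq_len(leaves)))
  adj <- matrix(0L, n, n, dimnames = list(ids, ids))
  adj[1, -1] <- 1L
  adj[-1, 1] <- 1L
  wave_network(adj)
}
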