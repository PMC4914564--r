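#' Count rank inconsistencies of a dominance order
#'
#' Given a candidate order (most dominant first) and a winner-loser count
#' matrix, a dyad is inconsistent when the lower-ranked actor won strictly
#' more conflicts against the higher-ranked one than vice versa. Tied dyads
#' (equal wins both ways, including 0-0) impose no constraint.
#'
#' @param order character or integer vector: permutation of the matrix's
#'   actors, most dominant first.
#' @param wins square nonnegative integer matrix; `wins[i, j]` = conflicts i
#'   won against j. Needs dimnames matching the order's ids (or the order
#'   may be given as row indices).
#' @return list with `I` (number of inconsistent dyads) and `SI` (summed
#'   rank distances of the inconsistent dyads).
#' @export
count_inconsistencies <- function(order, wins) {
  wins <- as.matrix(wins)
  n <- nrow(wins)
  idx <- if (is.numeric(order)) as.integer(order)
         else match(as.character(order), rownames(wins))
  if (length(idx) != n || anyNA(idx) || anyDuplicated(idx))
    stop("order must be a permutation of the matrix's actors")
  w <- wins[idx, idx, drop = FALSE]
  ut <- upper.tri(w)
  incons <- ut & (t(w) > w)   # lower-ranked beat higher-ranked more often
  I <- sum(incons)
  SI <- if (I == 0) 0L else {
    pos <- which(incons, arr.ind = TRUE)
    sum(pos[, 2] - pos[, 1])
  }
  list(I = as.integer(I), SI = as.integer(SI))
}

# all permutations of 1..n (columns), n small
permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  do.call(cbind, lapply(seq_len(n), function(k) {
    rbind(rep(k, ncol(sub)), ifelse(sub >= k, sub + 1L, sub))
  }))
}

isi_score <- function(perm, wins) {
  cc <- count_inconsistencies(perm, wins)
  c(cc$I, cc$SI)
}

lex_better <- function(a, b) a[1] < b[1] || (a[1] == b[1] && a[2] < b[2])

#' I&SI dominance ranking
#'
#' Orders actors from most to least dominant by the I&SI criterion: first
#' minimize the number of inconsistencies I (dyads where the lower-ranked
#' actor dominates the higher-ranked one), then minimize SI, the summed rank
#' distances of the remaining inconsistencies. For rosters of up to
#' `exhaustive_max` actors the optimum is found by exhaustive search over
#' all permutations; larger matrices use a heuristic that starts from the
#' win-proportion order and sweeps pairwise swaps, accepting
#' (I, SI)-lexicographic improvements until a full sweep makes none.
#'
#' @param wins square winner-loser count matrix with actor-id dimnames.
#' @param max_sweeps iteration budget for the swap heuristic.
#' @param exhaustive_max largest n solved exhaustively (default 8).
#' @param n_restarts randomized restarts of the swap descent (heuristic
#'   mode); restarts draw start orders from the current RNG stream.
#' @return An object of class `isi_ranking`: list with `order` (actor ids,
#'   most dominant first), `I`, `SI`, `tied` (TRUE when several optimal
#'   orders exist, exhaustive mode only) and `method`.
#' @export
isi_rank <- function(wins, max_sweeps = 100, exhaustive_max = 8,
                     n_restarts = 20) {
  wins <- as.matrix(wins)
  n <- nrow(wins)
  if (n < 1) stop("need at least one actor")
  if (is.null(rownames(wins)))
    rownames(wins) <- colnames(wins) <- paste0("a", seq_len(n))
  if (any(wins < 0) || any(diag(wins) != 0))
    stop("wins must be nonnegative with zero diagonal")
  ids <- rownames(wins)
  if (n == 1) {
    return(structure(list(order = ids, I = 0L, SI = 0L, tied = FALSE,
                          method = "trivial"), class = "isi_ranking"))
  }

  if (n <= exhaustive_max) {
    perms <- permutations_of(n)
    best <- NULL; best_score <- c(Inf, Inf); n_opt <- 0L
    # id-sorted candidate orders ensure the lexicographically smallest
    # optimal order (by actor id) is found first among ties
    ord_ids <- order(ids)
    for (k in seq_len(ncol(perms))) {
      perm <- ord_ids[perms[, k]]
      sc <- isi_score(perm, wins)
      if (lex_better(sc, best_score)) {
        best_score <- sc; best <- perm; n_opt <- 1L
      } else if (sc[1] == best_score[1] && sc[2] == best_score[2]) {
        n_opt <- n_opt + 1L
        if (is_lex_smaller_ids(ids[perm], ids[best])) best <- perm
      }
    }
    return(structure(list(order = ids[best], I = as.integer(best_score[1]),
                          SI = as.integer(best_score[2]), tied = n_opt > 1L,
                          method = "exhaustive"), class = "isi_ranking"))
  }

  # heuristic: pairwise-swap descent from the win-proportion order, with
  # randomized restarts to escape local optima of the (I, SI) landscape
  tot_w <- rowSums(wins)
  tot_l <- colSums(wins)
  prop <- ifelse(tot_w + tot_l > 0, tot_w / (tot_w + tot_l), 0.5)
  descend <- function(cur) {
    cur_score <- isi_score(cur, wins)
    for (sweep in seq_len(max_sweeps)) {
      improved <- FALSE
      for (a in seq_len(n)) {
        for (b in seq_len(n)) {
          if (a == b) next
          # swap the actors at positions a and b
          cand <- cur
          cand[c(a, b)] <- cand[c(b, a)]
          sc <- isi_score(cand, wins)
          if (lex_better(sc, cur_score)) {
            cur <- cand; cur_score <- sc; improved <- TRUE
          }
          # move the actor at position a to position b (shift the rest)
          cand2 <- append(cur[-a], cur[a], after = b - (a < b))
          sc2 <- isi_score(cand2, wins)
          if (lex_better(sc2, cur_score)) {
            cur <- cand2; cur_score <- sc2; improved <- TRUE
          }
        }
      }
      if (!improved) break
    }
    list(order = cur, score = cur_score)
  }
  best <- descend(order(-prop, ids))
  for (restart in seq_len(n_restarts)) {
    res <- descend(sample.int(n))
    if (lex_better(res$score, best$score)) best <- res
    if (best$score[1] == 0) break   # a perfectly linear order is optimal
  }
  structure(list(order = ids[best$order], I = as.integer(best$score[1]),
                 SI = as.integer(best$score[2]), tied = NA,
                 method = "heuristic"), class = "isi_ranking")
}

is_lex_smaller_ids <- function(a, b) {
  for (k in seq_along(a)) {
    if (a[k] < b[k]) return(TRUE)
    if (a[k] > b[k]) return(FALSE)
  }
  FALSE
}

#' @export
print.isi_ranking <- function(x, ...) {
  cat("<isi_ranking> I =", x$I, "SI =", x$SI,
      if (isTRUE(x$tied)) "(tied optimum)" else "", "\n")
  cat("  ", paste(x$order, collapse = " > "), "\n")
  invisible(x)
}

#' Read a winner-loser matrix from CSV
#' @param path CSV with actor-id header row and first column.
#' @return integer matrix.
#' @export
read_agonistic_matrix <- function(path) {
  m <- as.matrix(read.csv(path, row.names = 1, check.names = FALSE))
  storage.mode(m) <- "integer"
  m
}

#' Write an I&SI ranking to CSV
#' @param x an `isi_ranking`.
#' @param path output CSV path (columns rank, actor; I/SI in a comment
#'   footer).
#' @return `x`, invisibly.
#' @export
write_ranking <- function(x, path) {
  df <- data.frame(rank = seq_along(x$order), actor = x$order)
  write.csv(df, path, row.names = FALSE)
  cat(sprintf("# I=%d SI=%d method=%s\n", x$I, x$SI, x$method),
      file = path, append = TRUE)
  invisible(x)
}
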