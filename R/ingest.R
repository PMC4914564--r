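#' Behaviors recognised in scan records
#' @export
BEHAVIORS <- c("groom", "prox1m", "prox5m")

#' Read scan-sampling records from CSV
#'
#' Expects the columns `period,focal,partner,behavior`. Behavior must be one
#' of `groom`, `prox1m`, `prox5m`.
#'
#' @param path CSV file path.
#' @return data frame of scan records.
#' @export
read_scan_records <- function(path) {
  rec <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("period", "focal", "partner", "behavior")
  miss <- setdiff(need, names(rec))
  if (length(miss)) stop("scan record file lacks columns: ",
                         paste(miss, collapse = ", "))
  validate_scan_records(rec)
  rec
}

validate_scan_records <- function(rec) {
  if (any(rec$focal == rec$partner))
    stop("scan records with focal == partner are invalid")
  bad <- setdiff(unique(rec$behavior), BEHAVIORS)
  if (length(bad)) stop("unknown behavior(s): ", paste(bad, collapse = ", "))
  invisible(rec)
}

#' Build per-behavior dyadic count matrices for one period
#'
#' Tallies scan records into one square count matrix per behavior over the
#' given roster. Grooming is directed at this stage (`counts[i, j]` = records
#' of i grooming j); proximity records are inherently symmetric, so a single
#' proximity record increments both orientations once, producing a symmetric
#' matrix whose dyad value equals the number of records.
#'
#' @param records scan-record data frame (see [read_scan_records()]).
#' @param roster character vector of actor ids for this wave.
#' @param period period identifier; only matching records are used.
#' @return named list of three count matrices (`groom`, `prox1m`, `prox5m`)
#'   with attributes `behavior` and `period`.
#' @export
build_behavior_matrices <- function(records, roster, period) {
  roster <- as.character(roster)
  validate_scan_records(records)
  rec <- records[records$period == period, , drop = FALSE]
  ids <- unique(c(rec$focal, rec$partner))
  unknown <- setdiff(ids, roster)
  if (length(unknown))
    stop("actor id(s) not in roster: ", paste(unknown, collapse = ", "))
  if (nrow(rec) == 0)
    warning("no scan records for period ", period,
            "; returning zero matrices")
  n <- length(roster)
  out <- lapply(BEHAVIORS, function(bh) {
    m <- matrix(0L, n, n, dimnames = list(roster, roster))
    sub <- rec[rec$behavior == bh, , drop = FALSE]
    if (nrow(sub)) {
      i <- match(sub$focal, roster)
      j <- match(sub$partner, roster)
      for (k in seq_along(i)) {
        m[i[k], j[k]] <- m[i[k], j[k]] + 1L
        if (bh != "groom") m[j[k], i[k]] <- m[j[k], i[k]] + 1L
      }
    }
    attr(m, "behavior") <- bh
    attr(m, "period") <- period
    m
  })
  names(out) <- BEHAVIORS
  out
}

#' Symmetric dyadic values of a behavior count matrix
#'
#' Grooming matrices are symmetrized by the dyadic sum (grooming given plus
#' received); proximity matrices are already symmetric and are returned
#' unchanged. The result is the valued matrix to which the partner threshold
#' is applied.
#'
#' @param m count matrix from [build_behavior_matrices()].
#' @param behavior behavior label; defaults to the matrix's `behavior`
#'   attribute.
#' @return symmetric numeric matrix of dyadic values.
#' @export
dyadic_values <- function(m, behavior = attr(m, "behavior")) {
  m <- as.matrix(m)
  if (is.null(behavior)) stop("behavior label required")
  if (behavior == "groom") m + t(m) else {
    if (!isTRUE(all.equal(m, t(m))))
      stop("proximity count matrix must be symmetric")
    m
  }
}

#' Mutual-partner threshold for one behavior matrix
#'
#' The threshold is one-third of a standard deviation above the mean of the
#' dyadic values: `mean + sd/3`, computed over all unordered off-diagonal
#' dyads, zeros included, with the sample (n-1) standard deviation. Dyads
#' whose value strictly exceeds the threshold count as associates for that
#' behavior.
#'
#' @param m count matrix (or symmetric valued matrix), or a plain numeric
#'   vector of unordered dyadic values.
#' @param behavior behavior label used for symmetrization (ignored for
#'   vector input).
#' @return numeric threshold.
#' @export
compute_threshold <- function(m, behavior = attr(m, "behavior")) {
  vals <- if (is.matrix(m)) {
    d <- dyadic_values(m, behavior)
    d[upper.tri(d)]
  } else as.numeric(m)
  if (length(vals) < 2) stop("need at least 2 off-diagonal dyads")
  s <- sd(vals)
  if (s == 0)
    warning("all dyadic values identical; threshold equals the mean and no ",
            "dyad can exceed it")
  mean(vals) + s / 3
}

#' Binarize one wave into a mutual preferred partner network
#'
#' A dyad is a mutual preferred social partner pair - a network tie - when
#' its symmetrized value strictly exceeds the behavior-specific threshold in
#' at least two of the three behavior matrices (grooming, 1 m and 5 m
#' proximity).
#'
#' @param groom,prox1,prox5 count matrices for one period sharing a roster.
#' @param period period identifier stored on the result; defaults to the
#'   `period` attribute of `groom`.
#' @param min_behaviors how many behaviors must exceed threshold (default 2).
#' @return A [wave_network()] with attribute `thresholds` (named numeric).
#' @export
binarize_wave <- function(groom, prox1, prox5,
                          period = attr(groom, "period"),
                          min_behaviors = 2) {
  mats <- list(groom = groom, prox1m = prox1, prox5m = prox5)
  rosters <- lapply(mats, rownames)
  for (k in 2:3) {
    if (!identical(rosters[[1]], rosters[[k]])) {
      diff <- union(setdiff(rosters[[1]], rosters[[k]]),
                    setdiff(rosters[[k]], rosters[[1]]))
      stop("roster mismatch between behavior matrices: ",
           paste(diff, collapse = ", "))
    }
  }
  if (is.null(period)) period <- 1L
  thr <- vapply(BEHAVIORS, function(bh) compute_threshold(mats[[bh]], bh),
                numeric(1))
  above <- lapply(BEHAVIORS, function(bh)
    dyadic_values(mats[[bh]], bh) > thr[[bh]])
  n_above <- Reduce(`+`, above)
  adj <- (n_above >= min_behaviors) * 1L
  diag(adj) <- 0L
  wn <- wave_network(adj, period = period)
  attr(wn, "thresholds") <- thr
  wn
}

#' Write a wave network to CSV
#'
#' Writes the labeled adjacency matrix and, optionally, an edge list with
#' `i < j` by roster order.
#'
#' @param x a `wave_network`.
#' @param matrix_path path for the adjacency CSV (row names = actor ids).
#' @param edges_path optional path for an `i,j` edge-list CSV.
#' @return `x`, invisibly.
#' @export
write_wave_network <- function(x, matrix_path, edges_path = NULL) {
  write.csv(as.data.frame(x$adjacency), matrix_path)
  if (!is.null(edges_path)) {
    idx <- which(upper.tri(x$adjacency) & x$adjacency == 1L, arr.ind = TRUE)
    el <- data.frame(i = rownames(x$adjacency)[idx[, 1]],
                     j = colnames(x$adjacency)[idx[, 2]])
    write.csv(el, edges_path, row.names = FALSE)
  }
  invisible(x)
}

#' Read a wave network back from a labeled adjacency CSV
#' @param path CSV written by [write_wave_network()].
#' @param period period identifier to attach.
#' @return A `wave_network`.
#' @export
read_wave_network <- function(path, period = 1L) {
  m <- as.matrix(read.csv(path, row.names = 1, check.names = FALSE))
  wave_network(m, period = period)
}
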