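#' saomnet: dynamic social network analysis with stochastic actor-oriented
#' models
#'
#' Converts scan-sampling association data into binary partner networks,
#' ranks individuals by the I&SI dominance criterion, and models network
#' change over observation waves with a continuous-time stochastic
#' actor-oriented model (SAOM) estimated by method of moments.
#'
#' @importFrom Rcpp sourceCpp
#' @importFrom stats pchisq rbinom rnorm runif sd var cov rexp
#' @importFrom utils read.csv write.csv head
#' @useDynLib saomnet, .registration = TRUE
#' @keywords internal
"_PACKAGE"

#' Construct a single-wave binary network
#'
#' A wave network holds the symmetric binary adjacency matrix of "mutual
#' preferred social partner" ties for one observation period, over a fixed
#' full roster, together with a per-actor presence flag. Actors absent in a
#' wave are structural zeros: they hold no ties and take no part in
#' simulation for that wave.
#'
#' @param adjacency square 0/1 matrix with identical row and column names
#'   (the roster). Must be symmetric with a zero diagonal.
#' @param period integer period identifier.
#' @param present logical vector, one entry per roster actor (named or in
#'   roster order). Defaults to all present.
#' @return An object of class `wave_network`.
#' @export
wave_network <- function(adjacency, period = 1L, present = NULL) {
  adjacency <- as.matrix(adjacency)
  n <- nrow(adjacency)
  if (ncol(adjacency) != n) stop("adjacency must be square")
  if (is.null(rownames(adjacency))) {
    rownames(adjacency) <- colnames(adjacency) <- paste0("a", seq_len(n))
  }
  if (is.null(colnames(adjacency))) colnames(adjacency) <- rownames(adjacency)
  if (!identical(rownames(adjacency), colnames(adjacency)))
    stop("row and column names must agree")
  if (!all(adjacency %in% c(0, 1)))
    stop("adjacency entries must be 0 or 1")
  if (!isTRUE(all.equal(adjacency, t(adjacency))))
    stop("adjacency must be symmetric")
  if (any(diag(adjacency) != 0)) stop("adjacency diagonal must be zero")
  if (is.null(present)) present <- rep(TRUE, n)
  if (!is.null(names(present))) present <- present[rownames(adjacency)]
  if (length(present) != n) stop("present must have one entry per actor")
  names(present) <- rownames(adjacency)
  if (any(adjacency[!present, ] != 0) || any(adjacency[, !present] != 0))
    stop("absent actors cannot hold ties")
  storage.mode(adjacency) <- "integer"
  structure(list(adjacency = adjacency, period = as.integer(period),
                 present = present),
            class = "wave_network")
}

#' @export
print.wave_network <- function(x, ...) {
  cat("<wave_network> period", x$period, "-", sum(x$present), "of",
      length(x$present), "actors present,",
      sum(x$adjacency) / 2, "ties\n")
  invisible(x)
}

#' Roster of a wave network
#' @param x a `wave_network`.
#' @param present_only return only actors present in the wave?
#' @return character vector of actor ids.
#' @export
roster <- function(x, present_only = FALSE) {
  ids <- rownames(x$adjacency)
  if (present_only) ids[x$present] else ids
}

as_adjacency <- function(x) {
  if (inherits(x, "wave_network")) x$adjacency else as.matrix(x)
}

presence_of <- function(x) {
  if (inherits(x, "wave_network")) x$present
  else rep(TRUE, nrow(as.matrix(x)))
}

#' Construct an actor covariate table
#'
#' Stores per-actor attributes (typically sex, matriline, dominance rank and
#' age class) together with each covariate's declared measurement type.
#' Categorical covariates enter similarity as equality indicators; ordinal
#' covariates as `1 - |v_i - v_j| / range(v)`.
#'
#' @param df data frame with an `actor` column plus one column per covariate.
#' @param types named character vector mapping covariate names to
#'   `"categorical"` or `"ordinal"`. Covariates not named default to
#'   `"categorical"` when non-numeric and `"ordinal"` when numeric.
#' @return An object of class `covariate_table` (a data frame).
#' @export
covariate_table <- function(df, types = NULL) {
  df <- as.data.frame(df)
  if (!"actor" %in% names(df)) stop("df must have an 'actor' column")
  if (anyDuplicated(df$actor)) stop("duplicate actor ids")
  covs <- setdiff(names(df), "actor")
  full <- vapply(covs, function(cv) {
    if (!is.null(types) && cv %in% names(types)) types[[cv]]
    else if (is.numeric(df[[cv]])) "ordinal" else "categorical"
  }, character(1))
  bad <- setdiff(full, c("categorical", "ordinal"))
  if (length(bad)) stop("unknown covariate type: ", paste(bad, collapse = ", "))
  for (cv in covs) {
    if (any(is.na(df[[cv]])))
      stop("covariate '", cv, "' is missing for some actors")
  }
  df$actor <- as.character(df$actor)
  structure(df, types = full, class = c("covariate_table", "data.frame"))
}

covariate_type <- function(v, name) {
  ty <- attr(v, "types")
  if (!name %in% names(ty)) stop("unknown covariate: ", name)
  ty[[name]]
}

covariate_values <- function(v, name, actors = NULL) {
  if (!name %in% names(v)) stop("unknown covariate: ", name)
  vals <- v[[name]]
  names(vals) <- v$actor
  if (!is.null(actors)) {
    missing <- setdiff(actors, v$actor)
    if (length(missing))
      stop("covariates missing for actors: ", paste(missing, collapse = ", "))
    vals <- vals[actors]
  }
  vals
}

#' Define one model effect
#'
#' Effects are the terms of the evaluation function (density, transitive
#' triplets, degree popularity, covariate similarity, covariate ego x alter)
#' or of the rate function (covariate rate effects). Structural effects take
#' no covariate; covariate effects require one.
#'
#' @param name one of `"density"`, `"transtrip"`, `"inpop"`, `"simx"`,
#'   `"ego_alter"`, `"rate_covariate"`.
#' @param covariate covariate name, required for covariate effects.
#' @param parameter numeric parameter value (beta for evaluation effects,
#'   alpha for rate effects).
#' @param fixed logical; fixed parameters are not updated during estimation.
#' @return An object of class `saom_effect`.
#' @export
saom_effect <- function(name, covariate = NULL, parameter = 0,
                        fixed = FALSE) {
  name <- match.arg(name, c("density", "transtrip", "inpop", "simx",
                            "ego_alter", "rate_covariate"))
  needs_cov <- name %in% c("simx", "ego_alter", "rate_covariate")
  if (needs_cov && is.null(covariate))
    stop("effect '", name, "' requires a covariate")
  if (!needs_cov && !is.null(covariate))
    stop("structural effect '", name, "' takes no covariate")
  structure(list(name = name, covariate = covariate,
                 parameter = as.numeric(parameter), fixed = isTRUE(fixed)),
            class = "saom_effect")
}

effect_label <- function(e) {
  if (is.null(e$covariate)) e$name else paste0(e$name, ".", e$covariate)
}

#' Specify a stochastic actor-oriented model
#'
#' Bundles the evaluation and rate effects with the per-period basic rate
#' parameters. The density (out-degree) effect is always required: without a
#' baseline cost for tie creation the tie-choice model is degenerate, so a
#' model lacking it is rejected.
#'
#' @param effects list of [saom_effect()] objects.
#' @param rate_basic numeric vector of per-period basic rate parameters
#'   `rho_m > 0`, one per transition between consecutive waves.
#' @return An object of class `saom_model`.
#' @export
saom_model <- function(effects, rate_basic) {
  if (inherits(effects, "saom_effect")) effects <- list(effects)
  stopifnot(all(vapply(effects, inherits, logical(1), "saom_effect")))
  if (!any(vapply(effects, function(e) e$name == "density", logical(1))))
    stop("model must include the density effect")
  rate_basic <- as.numeric(rate_basic)
  if (any(rate_basic <= 0)) stop("rate parameters must be positive")
  labels <- vapply(effects, effect_label, character(1))
  if (anyDuplicated(labels)) stop("duplicate effects: ",
                                  paste(labels[duplicated(labels)],
                                        collapse = ", "))
  structure(list(effects = effects, rate_basic = rate_basic),
            class = "saom_model")
}

#' @export
print.saom_model <- function(x, ...) {
  cat("<saom_model>\n  rate rho:",
      paste(format(x$rate_basic, digits = 3), collapse = ", "), "\n")
  for (e in x$effects)
    cat(sprintf("  %-22s %8.4f%s\n", effect_label(e), e$parameter,
                if (e$fixed) " (fixed)" else ""))
  invisible(x)
}

eval_effects <- function(model) {
  Filter(function(e) e$name != "rate_covariate", model$effects)
}

rate_effects <- function(model) {
  Filter(function(e) e$name == "rate_covariate", model$effects)
}

#' Convenience constructor for a standard model
#'
#' Builds a [saom_model()] with density plus optional structural and
#' covariate effects, all with zero starting parameters.
#'
#' @param n_periods number of transitions (waves minus one).
#' @param transtrip,inpop include the structural effect?
#' @param simx,ego_alter,rate_covariates character vectors of covariate
#'   names for the corresponding effects.
#' @param rate_init initial value for every basic rate parameter.
#' @param density_init initial density parameter.
#' @return A `saom_model`.
#' @export
saom_model_basic <- function(n_periods, transtrip = FALSE, inpop = FALSE,
                             simx = character(), ego_alter = character(),
                             rate_covariates = character(),
                             rate_init = 3, density_init = -1) {
  eff <- list(saom_effect("density", parameter = density_init))
  if (transtrip) eff <- c(eff, list(saom_effect("transtrip")))
  if (inpop) eff <- c(eff, list(saom_effect("inpop")))
  for (cv in simx) eff <- c(eff, list(saom_effect("simx", cv)))
  for (cv in ego_alter) eff <- c(eff, list(saom_effect("ego_alter", cv)))
  for (cv in rate_covariates)
    eff <- c(eff, list(saom_effect("rate_covariate", cv)))
  saom_model(eff, rep(rate_init, n_periods))
}
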