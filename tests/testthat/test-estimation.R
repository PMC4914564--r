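ids3 <- paste0("a", 1:3)
empty3 <- function(p) wave_network(matrix(0L, 3, 3,
                                          dimnames = list(ids3, ids3)),
                                   period = p)
tri3 <- function(p) {
  adj <- matrix(1L, 3, 3, dimnames = list(ids3, ids3))
  diag(adj) <- 0L
  wave_network(adj, period = p)
}

test_that("observed targets sum end-wave statistics and Hamming distances", {
  m <- saom_model(list(saom_effect("density"), saom_effect("transtrip")),
                  rate_basic = 1)
  # identical consecutive waves: zero rate target
  tt <- observed_targets(list(tri3(1), tri3(2)), m)
  expect_equal(unname(tt["rate.period1"]), 0)
  # second wave a triangle: transtrip target 2 per actor
  tt2 <- observed_targets(list(empty3(1), tri3(2)), m)
  expect_equal(unname(tt2["transtrip"]), 6)
  expect_equal(unname(tt2["density"]), 6)
  expect_equal(unname(tt2["rate.period1"]), 3)
  # empty second wave: structural targets 0
  tt3 <- observed_targets(list(tri3(1), empty3(2)), m)
  expect_equal(unname(tt3["density"]), 0)
  expect_equal(unname(tt3["transtrip"]), 0)
  expect_error(observed_targets(list(tri3(1)), m), "2 waves")
})

test_that("rate-covariate targets weight per-actor change counts", {
  v <- covariate_table(data.frame(actor = ids3, sex = c(1, 1, 0)),
                       types = c(sex = "categorical"))
  m <- saom_model(list(saom_effect("density"),
                       saom_effect("rate_covariate", "sex")), 1)
  tt <- observed_targets(list(empty3(1), tri3(2)), m, v)
  # each actor gains 2 ties; actors 1 and 2 carry code 1
  expect_equal(unname(tt["rate_covariate.sex"]), 4)
})

test_that("Wald test follows the chi-squared(1) tail", {
  w0 <- wald_test(0, 1)
  expect_equal(w0$X2, 0)
  expect_equal(w0$p, 1)
  w1 <- wald_test(2, 1)
  expect_equal(w1$X2, 4)
  expect_equal(round(w1$p, 4), 0.0455)
  w2 <- wald_test(1.96, 1)
  expect_equal(round(w2$p, 2), 0.05)
  expect_equal(w2$DF, 1L)
  expect_error(wald_test(1, 0), "positive")
  # symmetric in the sign of the estimate
  expect_equal(wald_test(-2, 1)$p, w1$p)
})

test_that("phase-3 t-ratios at the generating parameters stay on the
           standard-normal scale", {
  set.seed(51)
  ros <- gen_roster(15)
  x0 <- gen_initial_network(ros$roster, 0.1)
  m <- saom_model(list(saom_effect("density", parameter = -1.3),
                       saom_effect("transtrip", parameter = 0.3)),
                  rate_basic = rep(2, 3))
  gw <- gen_waves(m, x0, ros$covariates, 4)
  # no phase-2 updates: phase 3 simulates at the generating parameters
  f <- robbins_monro_fit(gw$waves, m, ros$covariates,
                         estimation_options(n1 = 5, n2_subphases = 0,
                                            n3 = 200, n3_deriv = 5,
                                            auto_init_rates = FALSE,
                                            max_retries = 0))
  # the observed statistics are one draw from the model, so each t-ratio
  # (mean simulated deviation / sd) is approximately standard normal -
  # small only after fitting, which matches the data draw itself
  expect_lt(max(abs(f$tstats)), 4)
  expect_equal(f$n_iterations, 0L)
})

test_that("fit results carry coherent inference columns", {
  set.seed(52)
  ros <- gen_roster(14)
  x0 <- gen_initial_network(ros$roster, 0.12)
  m <- saom_model(saom_effect("density", parameter = -1.2),
                  rate_basic = rep(2, 2))
  gw <- gen_waves(m, x0, ros$covariates, 3)
  fitm <- saom_model_basic(2, density_init = -1, rate_init = 2)
  f <- robbins_monro_fit(gw$waves, fitm, ros$covariates,
                         estimation_options(n1 = 8, n2_subphases = 2,
                                            n2_base = 25, n3 = 120,
                                            n3_deriv = 8))
  est <- f$estimates
  expect_true(all(est$se > 0))
  drow <- est[est$parameter == "density", ]
  expect_equal(drow$X2, (drow$estimate / drow$se)^2)
  expect_equal(drow$p_value,
               pchisq(drow$X2, 1, lower.tail = FALSE))
  expect_true(all(f$model$rate_basic > 0))
})

test_that("forward selection applies the pairing rule to homophily", {
  # constructed fitter: simx significant, ego_alter not -> pair dropped
  mock_fitter <- function(waves, model, v, opts) {
    labels <- vapply(model$effects, saomnet:::effect_label, character(1))
    p <- ifelse(labels == "simx.sex", 0.001,
                ifelse(labels == "ego_alter.sex", 0.50, 0.01))
    est <- data.frame(
      parameter = c(paste0("rate.period", seq_along(model$rate_basic)),
                    labels),
      estimate = 0.5, se = 0.1, t_ratio = 0.01)
    est$X2 <- 25; est$DF <- 1L
    est$p_value <- c(rep(NA_real_, length(model$rate_basic)), p)
    structure(list(model = model, estimates = est, tstats = 0.01,
                   converged = TRUE), class = "saom_fit")
  }
  waves <- list(empty3(1), tri3(2))
  sel <- forward_select(waves, list(list(saom_effect("simx", "sex"),
                                         saom_effect("ego_alter", "sex"))),
                        fitter = mock_fitter)
  expect_false(any(sel$trace$kept))
  expect_match(sel$trace$reason[1], "pair")
  # both significant -> kept
  mock_fitter2 <- function(waves, model, v, opts) {
    f <- mock_fitter(waves, model, v, opts)
    f$estimates$p_value[!is.na(f$estimates$p_value)] <- 0.001
    f
  }
  sel2 <- forward_select(waves, list(list(saom_effect("simx", "sex"),
                                          saom_effect("ego_alter", "sex"))),
                         fitter = mock_fitter2)
  expect_true(all(sel2$trace$kept))
  expect_true(any(vapply(sel2$model$effects, function(e)
    e$name == "simx", logical(1))))
  # non-converged candidate is dropped with an annotation
  mock_fitter3 <- function(waves, model, v, opts) {
    f <- mock_fitter(waves, model, v, opts)
    if (length(model$effects) > 1) f$converged <- FALSE
    f
  }
  sel3 <- forward_select(waves, list(saom_effect("transtrip")),
                         fitter = mock_fitter3)
  expect_false(sel3$trace$kept[1])
  expect_match(sel3$trace$reason[1], "converged")
})

test_that("fit tables serialize with the conventional columns", {
  mock_fit <- structure(list(
    estimates = data.frame(parameter = c("rate.period1", "density"),
                           estimate = c(2, -1.5), se = c(0.3, 0.2),
                           t_ratio = c(0.05, -0.02), X2 = c(NA, 56.25),
                           DF = c(NA, 1), p_value = c(NA, 1e-13)),
    converged = TRUE), class = "saom_fit")
  tmp <- tempfile(fileext = ".csv")
  write_fit_csv(mock_fit, tmp, seed = 7)
  df <- read.csv(tmp)
  expect_named(df, c("Effect", "Estimate", "Std.error", "t.ratio", "X2",
                     "DF", "P.value", "converged", "seed"))
  expect_equal(df$seed, c(7, 7))
})
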