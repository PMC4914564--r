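test_that("roster generation respects its contracts", {
  set.seed(71)
  ros <- gen_roster(30, female_fraction = 0.5)
  expect_length(ros$roster, 30)
  expect_setequal(names(ros$covariates),
                  c("actor", "sex", "matriline", "rank", "age_class"))
  expect_setequal(ros$covariates$rank, 1:30)
  # latent order is consistent with the rank covariate
  expect_equal(ros$covariates$actor[order(ros$covariates$rank)],
               ros$latent_order)
  # matriline blocks hold contiguous ranks
  rk <- ros$covariates$rank
  ml <- ros$covariates$matriline
  for (g in unique(ml)) {
    r <- sort(rk[ml == g])
    expect_equal(r, seq(min(r), max(r)))
  }
  expect_error(gen_roster(1), "2 actors")
  expect_error(gen_roster(10, female_fraction = 1.5), "0, 1")
})

test_that("a single matriline makes matriline similarity identically 1", {
  set.seed(72)
  ros <- gen_roster(8, n_matrilines = 1)
  v <- ros$covariates
  for (i in 1:7)
    expect_equal(similarity(v, "matriline", paste0("id0", i), "id08"), 1)
})

test_that("generation is byte-identical under a repeated seed", {
  set.seed(73)
  s1 <- gen_study(n = 12, n_waves = 3, scans = 50)
  set.seed(73)
  s2 <- gen_study(n = 12, n_waves = 3, scans = 50)
  expect_identical(s1$covariates, s2$covariates)
  expect_identical(lapply(s1$waves, `[[`, "adjacency"),
                   lapply(s2$waves, `[[`, "adjacency"))
  expect_identical(s1$scan_counts, s2$scan_counts)
  expect_identical(s1$agonistic, s2$agonistic)
})

test_that("all-or-nothing scan counts recover the true network exactly", {
  set.seed(74)
  truth <- wave_network(rand_sym_graph(12, 0.25))
  counts <- gen_scan_counts(truth, n_scans = 20, p_link = 1,
                            p_background = 0)
  wn <- binarize_wave(counts$groom, counts$prox1m, counts$prox5m)
  expect_identical(wn$adjacency, truth$adjacency)
  # no scans -> all-zero matrices
  z <- gen_scan_counts(truth, n_scans = 0, p_link = 1, p_background = 0)
  expect_true(all(vapply(z, function(m) all(m == 0), logical(1))))
  expect_error(gen_scan_counts(truth, p_link = 0.1, p_background = 0.2),
               "p_background")
})

test_that("scan records round-trip through the ingestion tally", {
  set.seed(75)
  truth <- wave_network(rand_sym_graph(8, 0.3), period = 2L)
  counts <- gen_scan_counts(truth, n_scans = 10, p_link = 0.6,
                            p_background = 0.05)
  rec <- scan_records_from_counts(counts, period = 2L)
  back <- build_behavior_matrices(rec, roster(truth), 2L)
  for (bh in BEHAVIORS)
    expect_equal(unname(dyadic_values(back[[bh]], bh)),
                 unname(dyadic_values(counts[[bh]], bh)))
})

test_that("agonistic bouts without upsets reproduce the latent order", {
  set.seed(76)
  ros <- gen_roster(7)
  wins <- gen_agonistic(ros$latent_order, n_bouts = 800, upset_prob = 0)
  rk <- isi_rank(wins)
  expect_equal(rk$order, ros$latent_order)
  expect_equal(rk$I, 0L)
  # no bouts -> zero matrix
  expect_true(all(gen_agonistic(ros$latent_order, 0, 0) == 0))
  expect_error(gen_agonistic(ros$latent_order, 10, 0.6), "upset_prob")
})

test_that("noisy dominance sampling still correlates with the hierarchy", {
  set.seed(77)
  rho <- replicate(15, {
    ros <- gen_roster(10)
    wins <- gen_agonistic(ros$latent_order, n_bouts = 1500,
                          upset_prob = 0.1)
    rk <- isi_rank(wins)
    cor(match(ros$latent_order, ros$latent_order),
        match(rk$order, ros$latent_order), method = "spearman")
  })
  expect_gte(mean(rho), 0.9)
})

test_that("turnover changes wave rosters as configured", {
  set.seed(78)
  ros <- gen_roster(12)
  x0 <- gen_initial_network(ros$roster, 0.15)
  m <- saom_model(saom_effect("density", parameter = -1), rate_basic = 2)
  gw0 <- gen_waves(m, x0, ros$covariates, 4)
  expect_true(all(vapply(gw0$waves, function(w) all(w$present),
                         logical(1))))
  gw1 <- gen_waves(m, x0, ros$covariates, 4,
                   turnover = list(leave = c(2, 0, 0), join = c(0, 1, 0)))
  expect_equal(sum(gw1$waves[[2]]$present), 10)
  expect_equal(sum(gw1$waves[[3]]$present), 11)
  # leavers hold no ties
  gone <- !gw1$waves[[2]]$present
  expect_true(all(gw1$waves[[2]]$adjacency[gone, ] == 0))
})

test_that("stronger triadic closure in the truth yields more triangles", {
  set.seed(79)
  tri_count <- function(beta_tt) {
    ros <- gen_roster(15)
    x0 <- gen_initial_network(ros$roster, 0.1)
    m <- saom_model(list(saom_effect("density", parameter = -1.5),
                         saom_effect("transtrip", parameter = beta_tt)),
                    rate_basic = rep(2, 3))
    gw <- gen_waves(m, x0, ros$covariates, 4)
    adj <- gw$waves[[4]]$adjacency
    sum(diag(adj %*% adj %*% adj)) / 6
  }
  t_hi <- mean(replicate(25, tri_count(0.5)))
  t_lo <- mean(replicate(25, tri_count(0)))
  expect_gt(t_hi, t_lo)
})
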