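test_that("structural statistics match hand-worked configurations", {
  tri <- triangle_net()
  st <- star_net(4)
  empty <- wave_network(matrix(0L, 3, 3,
                               dimnames = list(paste0("a", 1:3),
                                               paste0("a", 1:3))))
  # degree
  expect_equal(stat_density(empty, "a1"), 0)
  expect_equal(stat_density(tri, "a2"), 2)
  expect_equal(stat_density(st, "c"), 4)
  # transitive triplets: ordered pairs (j, h) and (h, j) in a triangle
  expect_equal(stat_transtrip(empty, "a1"), 0)
  expect_equal(stat_transtrip(tri, "a1"), 2)
  path <- wave_network(matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3, 3,
                              dimnames = list(paste0("a", 1:3),
                                              paste0("a", 1:3))))
  expect_equal(stat_transtrip(path, "a2"), 0)  # no j-h tie
  # degree popularity
  expect_equal(stat_inpop(empty, "a1"), 0)
  expect_equal(stat_inpop(st, "l1"), 4)   # the center's degree
  expect_equal(stat_inpop(st, "c"), 4)    # four leaves of degree 1
  expect_equal(stat_inpop(tri, "a1"), 4)  # two partners of degree 2
})

test_that("similarity honours covariate type declarations", {
  v <- covariate_table(
    data.frame(actor = paste0("a", 1:4), matriline = c(1, 1, 2, 3),
               rank = c(1, 5, 2, 3)),
    types = c(matriline = "categorical", rank = "ordinal"))
  expect_equal(similarity(v, "matriline", "a1", "a2"), 1)
  expect_equal(similarity(v, "matriline", "a1", "a3"), 0)
  # ordinal ranks 1 and 5 with range 4 -> 0; ranks 2 and 3 -> 0.75
  expect_equal(similarity(v, "rank", "a1", "a2"), 0)
  expect_equal(similarity(v, "rank", "a3", "a4"), 0.75)
  # zero-range ordinal covariate is rejected with advice
  vz <- covariate_table(data.frame(actor = c("a1", "a2"), tenure = c(2, 2)),
                        types = c(tenure = "ordinal"))
  expect_error(similarity(vz, "tenure", "a1", "a2"), "categorical")
})

test_that("homophily statistic centers similarity over all dyads", {
  ids <- paste0("a", 1:3)
  v <- covariate_table(data.frame(actor = ids, grp = c(0, 0, 1)),
                       types = c(grp = "categorical"))
  # all actors alike -> centered similarity vanishes
  vsame <- covariate_table(data.frame(actor = ids, grp = c(1, 1, 1)),
                           types = c(grp = "categorical"))
  adj <- matrix(0L, 3, 3, dimnames = list(ids, ids))
  adj["a1", "a2"] <- adj["a2", "a1"] <- 1L
  x <- wave_network(adj)
  expect_equal(stat_simx(x, "a1", vsame, "grp"), 0)
  # similarities (1, 0, 0): mean 1/3; single tie a1-a2 -> 1 - 1/3
  expect_equal(stat_simx(x, "a1", v, "grp"), 2 / 3)
  expect_equal(stat_simx(x, "a3", v, "grp"), 0)  # isolate
})

test_that("ego x alter multiplies ego by the partner total", {
  ids <- paste0("a", 1:3)
  v <- covariate_table(data.frame(actor = ids, z = c(1, 1, 0)),
                       types = c(z = "ordinal"))
  adj <- matrix(0L, 3, 3, dimnames = list(ids, ids))
  adj["a1", "a2"] <- adj["a2", "a1"] <- 1L
  adj["a1", "a3"] <- adj["a3", "a1"] <- 1L
  x <- wave_network(adj)
  # raw codes: ego 1 with partners 1 and 0
  expect_equal(stat_ego_alter(x, "a1", v, "z", center = FALSE), 1)
  # ego code 0 kills the product regardless of ties
  expect_equal(stat_ego_alter(x, "a3", v, "z", center = FALSE), 0)
  empty <- wave_network(matrix(0L, 3, 3, dimnames = list(ids, ids)))
  expect_equal(stat_ego_alter(empty, "a1", v, "z"), 0)
})

test_that("evaluation function is the beta-weighted sum of statistics", {
  tri <- triangle_net()
  m0 <- saom_model(list(saom_effect("density", parameter = 0),
                        saom_effect("transtrip", parameter = 0)), 1)
  expect_equal(evaluate(tri, "a1", m0), 0)
  m1 <- saom_model(saom_effect("density", parameter = -1), 1)
  expect_equal(evaluate(tri, "a1", m1), -2)
  m2 <- saom_model(list(saom_effect("density", parameter = -1),
                        saom_effect("transtrip", parameter = 0.5)), 1)
  expect_equal(evaluate(tri, "a1", m2), -2 + 0.5 * 2)
})

test_that("rate function multiplies the basic rate by covariate terms", {
  ids <- paste0("a", 1:2)
  v <- covariate_table(data.frame(actor = ids, sex = c(1, 0)),
                       types = c(sex = "categorical"))
  m <- saom_model(saom_effect("density"), rate_basic = 2)
  expect_equal(rate("a1", m, v, 1), 2)
  # a sex rate effect of 0.66 gives a female/male rate ratio exp(0.66)
  m2 <- saom_model(list(saom_effect("density"),
                        saom_effect("rate_covariate", "sex",
                                    parameter = 0.66)), 2)
  expect_equal(rate("a1", m2, v, 1) / rate("a2", m2, v, 1), exp(0.66))
  m3 <- saom_model(list(saom_effect("density"),
                        saom_effect("rate_covariate", "sex",
                                    parameter = 0)), 2)
  expect_equal(rate("a1", m3, v, 1), 2)
  expect_error(rate("a1", m, v, 5), "period")
})

test_that("statistics agree with brute-force loops on random graphs", {
  set.seed(31)
  for (r in 1:50) {
    n <- sample(4:8, 1)
    adj <- rand_sym_graph(n)
    v <- rand_covariates(n)
    x <- wave_network(adj)
    i <- sample(n, 1)
    id <- paste0("a", i)
    expect_equal(stat_density(x, id), bf_density(adj, i))
    expect_equal(stat_transtrip(x, id), bf_transtrip(adj, i))
    expect_equal(stat_inpop(x, id), bf_inpop(adj, i))
    expect_equal(stat_simx(x, id, v, "rank"), bf_simx(adj, i, v, "rank"))
    expect_equal(stat_ego_alter(x, id, v, "sex"),
                 bf_ego_alter(adj, i, v, "sex"))
  }
})

test_that("statistics are invariant under consistent relabeling", {
  set.seed(32)
  n <- 7
  adj <- rand_sym_graph(n)
  v <- rand_covariates(n)
  perm <- sample.int(n)
  adj2 <- adj[perm, perm]
  x <- wave_network(adj)
  x2 <- wave_network(adj2)
  for (i in seq_len(n)) {
    id <- paste0("a", i)
    expect_equal(stat_transtrip(x2, id), stat_transtrip(x, id))
    expect_equal(stat_inpop(x2, id), stat_inpop(x, id))
    expect_equal(stat_simx(x2, id, v, "rank"), stat_simx(x, id, v, "rank"))
  }
})

test_that("the simulator's incremental evaluation matches full re-evaluation", {
  set.seed(33)
  for (r in 1:30) {
    n <- sample(4:8, 1)
    adj <- rand_sym_graph(n)
    v <- rand_covariates(n)
    m <- saom_model(list(
      saom_effect("density", parameter = rnorm(1)),
      saom_effect("transtrip", parameter = rnorm(1, 0, 0.5)),
      saom_effect("inpop", parameter = rnorm(1, 0, 0.3)),
      saom_effect("simx", "sex", parameter = rnorm(1)),
      saom_effect("ego_alter", "rank", parameter = rnorm(1, 0, 0.2))), 1)
    pieces <- saomnet:::model_sim_pieces(m, adj, rep(TRUE, n), v)
    i <- sample(n, 1)
    j <- sample(setdiff(seq_len(n), i), 1)
    d_cpp <- saomnet:::delta_eval_cpp(adj, i, j, pieces$wsum,
                                      pieces$beta_tt, pieces$beta_ip)
    adj2 <- adj
    adj2[i, j] <- adj2[j, i] <- 1L - adj2[i, j]
    d_ref <- evaluate(wave_network(adj2), i, m, v) -
      evaluate(wave_network(adj), i, m, v)
    expect_equal(d_cpp, d_ref, tolerance = 1e-10)
  }
})
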