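# Core state machine: hand-traced micro-oracles and structural properties.

test_that("sim_params validates its invariants", {
  p <- sim_params(N = 10, generations = 5)
  expect_s3_class(p, "sim_params")
  expect_error(sim_params(N = 1))
  expect_error(sim_params(Pm = 1.5))
  expect_error(sim_params(Tf = 0))
  expect_error(sim_params(init_num_languages = 0))
  expect_error(sim_params(fitness_floor = 0))
})

test_that("shared_languages matches direct interval arithmetic", {
  langs <- new_languages(0.65)
  got <- shared_languages(list(a = 0.5, p = 0.2), list(a = 0.8, p = 0.2), langs)
  expect_equal(got$pos, 0.65)  # 0.65 in [0.6, 0.7]

  # zero-width identity case
  got <- shared_languages(list(a = 0.4, p = 0), list(a = 0.4, p = 0),
                          new_languages(0.4))
  expect_equal(got$pos, 0.4)

  # disjoint intervals
  got <- shared_languages(list(a = 0.1, p = 0.05), list(a = 0.9, p = 0.05),
                          new_languages(0.5))
  expect_equal(nrow(got), 0)

  # empty language population
  got <- shared_languages(list(a = 0.5, p = 1), list(a = 0.5, p = 1),
                          new_languages(numeric(0), integer(0)))
  expect_equal(nrow(got), 0)
})

test_that("fast all-pairs interval search equals the brute-force oracle", {
  set.seed(7)
  for (rep in 1:200) {
    n <- sample(2:30, 1)
    nl <- sample(0:20, 1)
    agents <- new_agents(runif(n), runif(n, 0, 0.5))
    langs <- new_languages(runif(nl), seq_len(nl))
    log <- run_communication_round(agents, langs)
    oracle <- brute_shared(agents, langs)
    ok <- oracle[oracle$n_shared > 0, ]
    # same successful pairs
    expect_equal(data.frame(i = log$pair_i, j = log$pair_j),
                 ok[, c("i", "j")], ignore_attr = TRUE)
    # chosen language is genuinely shared by each pair
    if (length(log$pair_i)) {
      for (k in seq_along(log$pair_i)) {
        sh <- shared_languages(agents[log$pair_i[k], ],
                               agents[log$pair_j[k], ], langs)
        expect_true(log$pair_lang_pos[k] %in% sh$pos)
      }
    }
    # repertoire sizes against per-agent brute force
    n_i <- vapply(seq_len(n), function(i) {
      sum(langs$pos >= agents$a[i] - agents$p[i] &
            langs$pos <= agents$a[i] + agents$p[i])
    }, 0L)
    expect_identical(log$usable_counts, n_i)
  }
})

test_that("communication round: enumerated 3-agent case and empty cases", {
  # three agents with identical intervals containing one language
  agents <- new_agents(c(0.5, 0.5, 0.5), 0.1)
  langs <- new_languages(0.55)
  log <- run_communication_round(agents, langs)
  expect_equal(length(log$pair_i), 3)  # all 3 pairs succeed
  expect_setequal(log$users$agent, 1:3)
  expect_identical(log$usable_counts, rep(1L, 3))

  # no languages -> empty log
  log <- run_communication_round(agents, new_languages(numeric(0), integer(0)))
  expect_equal(length(log$pair_i), 0)
  expect_equal(nrow(log$users), 0)

  # 2 agents sharing 2 languages: exactly one language chosen, symmetric
  set.seed(5)
  agents <- new_agents(c(0.5, 0.5), 0.2)
  langs <- new_languages(c(0.45, 0.6))
  log <- run_communication_round(agents, langs)
  expect_equal(length(log$pair_i), 1)
  expect_true(log$pair_lang_pos %in% langs$pos)
  expect_equal(nrow(log$users), 2)           # both agents, same language
  expect_equal(unique(log$users$lang), log$pair_lang)
})

test_that("fitness matches hand evaluation", {
  params <- sim_params(N = 10, W1 = 3, W2 = 10)
  # two successes both via a language at 0.8, a = 1, p = 0.5
  agents <- new_agents(c(1, 0.9, 0.9), 0.5)
  langs <- new_languages(0.8)
  log <- manual_log(data.frame(i = c(1, 1), j = c(2, 3), lang = c(1, 1)),
                    langs, 3, rep(1L, 3))
  f <- compute_fitness(agents, log, params)
  expect_equal(f[1], 3 * 1.6 - 10 * 1.5^1)  # -10.2

  # no successes, a = 0, p = 0 -> -W2 * 1^0
  agents0 <- new_agents(c(0, 0), 0)
  log0 <- manual_log(data.frame(i = integer(0), j = integer(0),
                                lang = integer(0)),
                     langs, 2, rep(0L, 2))
  expect_equal(compute_fitness(agents0, log0, params), c(-10, -10))

  # one success via a language at 0.5, a = 0.5, p = 0
  agents1 <- new_agents(c(0.5, 0.5), 0)
  langs1 <- new_languages(0.5)
  log1 <- manual_log(data.frame(i = 1, j = 2, lang = 1), langs1, 2, c(1L, 1L))
  expect_equal(compute_fitness(agents1, log1, params)[1], 1.5 - 10)  # -8.5
})

test_that("fitness agrees with naive per-term re-evaluation on a seeded log", {
  set.seed(11)
  agents <- new_agents(runif(15), runif(15, 0, 0.4))
  langs <- new_languages(runif(8), 1:8)
  log <- run_communication_round(agents, langs)
  params <- sim_params(N = 15, W1 = 3, W2 = 10)
  f <- compute_fitness(agents, log, params)
  naive <- vapply(seq_len(15), function(i) {
    mine <- log$pair_i == i | log$pair_j == i
    params$W1 * sum(log$pair_lang_pos[mine]) -
      params$W2 * (agents$p[i] + 1)^agents$a[i]
  }, numeric(1))
  expect_identical(f, naive)
})

test_that("roulette selection follows floored weights (binomial oracle)", {
  # floored weights 1 and 3 -> parent-class shares 25% / 75%; one big
  # population of two genotype classes gives 1e5 independent draws
  draws <- 1e5
  params <- sim_params(N = draws, Pm = 0, fitness_floor = 1)
  agents <- new_agents(rep(c(0.2, 0.7), draws / 2), 0)
  fit <- rep(c(0, 2), draws / 2)  # floored weights 1 and 3
  set.seed(123)
  off <- reproduce_agents(agents, fit, params)
  # per-class totals: class 2 weight share = (draws/2 * 3) / (draws/2 * 4)
  p_expected <- 0.75
  sigma <- sqrt(draws * p_expected * (1 - p_expected))
  expect_lt(abs(sum(off$a == 0.7) - draws * p_expected), 3 * sigma)
})

test_that("mutation edge cases: Pm = 0 and zero variance copy parents", {
  agents <- new_agents(runif(20), runif(20))
  set.seed(1)
  off <- reproduce_agents(agents, rep(1, 20), sim_params(N = 20, Pm = 0))
  expect_true(all(off$a %in% agents$a) && all(off$p %in% agents$p))
  off2 <- reproduce_agents(agents, rep(1, 20),
                           sim_params(N = 20, Pm = 1, mut_var = 0))
  expect_true(all(off2$a %in% agents$a) && all(off2$p %in% agents$p))
  # genotypes never negative after mutation
  set.seed(2)
  off3 <- reproduce_agents(new_agents(rep(0.01, 50), rep(0.01, 50)),
                           rep(1, 50),
                           sim_params(N = 50, Pm = 1, mut_var = 2))
  expect_true(all(off3$a >= 0) && all(off3$p >= 0))
})

test_that("displacement matches hand evaluation of the pull sums", {
  params <- sim_params(N = 10, F = 0.001)
  # two users above with n_i = 1 -> (0.002, 0)
  langs <- new_languages(0.5)
  agents <- new_agents(c(0.6, 0.6), 0.2)
  log <- manual_log(data.frame(i = 1, j = 2, lang = 1), langs, 2, c(1L, 1L))
  d <- language_displacement(langs, log, agents, params)
  expect_equal(d$d_plus, 0.002)
  expect_equal(d$d_minus, 0)

  # a user exactly at l_x contributes to neither side
  agents_eq <- new_agents(c(0.5, 0.5), 0.2)
  log_eq <- manual_log(data.frame(i = 1, j = 2, lang = 1), langs, 2, c(1L, 1L))
  d <- language_displacement(langs, log_eq, agents_eq, params)
  expect_equal(unlist(d), c(d_plus = 0, d_minus = 0))

  # 3 users above with n_i = 2, 1 below with n_i = 1 -> (0.0015, -0.001)
  agents4 <- new_agents(c(0.6, 0.6, 0.6, 0.4), 0.3)
  log4 <- manual_log(data.frame(i = c(1, 2, 3), j = c(4, 4, 4), lang = 1),
                     langs, 4, c(2L, 2L, 2L, 1L))
  d <- language_displacement(langs, log4, agents4, params)
  expect_equal(unlist(d), c(d_plus = 0.0015, d_minus = -0.001))
})

test_that("cultural change and division follow the displacement rule", {
  params <- sim_params(N = 20, F = 0.001, Fd = 0.008)
  langs <- new_languages(0.5)
  # division: pulled 0.009 both ways -> children at 0.509 and 0.491
  agents <- new_agents(c(rep(0.6, 9), rep(0.4, 9)), 0.2)
  succ <- data.frame(i = 1:9, j = 10:18, lang = 1)
  log <- manual_log(succ, langs, 18, rep(1L, 18))
  out <- apply_cultural_change(langs, log, agents, params, 1)
  expect_equal(out$events$kind, "division")
  expect_equal(sort(out$langs$pos), c(0.491, 0.509))
  expect_true(all(attr(out$langs, "division_child")))
  expect_false(any(out$langs$lineage_id == 1))  # parent re-keyed

  # change: pulled 0.002 upward only -> moves to 0.502
  agents2 <- new_agents(c(0.6, 0.6), 0.2)
  log2 <- manual_log(data.frame(i = 1, j = 2, lang = 1), langs, 2, c(1L, 1L))
  out2 <- apply_cultural_change(langs, log2, agents2, params, 1)
  expect_equal(out2$events$kind, "change")
  expect_equal(out2$langs$pos, 0.502)
  expect_equal(out2$langs$lineage_id, 1L)  # lineage survives change

  # unused language: no displacement, no event
  log3 <- manual_log(data.frame(i = integer(0), j = integer(0),
                                lang = integer(0)), langs, 2, c(0L, 0L))
  out3 <- apply_cultural_change(langs, log3, new_agents(c(1, 1), 0), params, 1)
  expect_equal(nrow(out3$events), 0)
  expect_equal(out3$langs$pos, 0.5)
})

test_that("extinction removes exactly the unused languages", {
  langs <- new_languages(c(0.2, 0.5, 0.8), 1:3)
  agents <- new_agents(c(0.2, 0.5), 0.4)
  # users recorded for languages 1 and 2 only
  log <- manual_log(data.frame(i = c(1, 1), j = c(2, 2), lang = c(1, 2)),
                    langs, 2, c(2L, 2L))
  out <- apply_extinction(langs, log, 1)
  expect_equal(out$langs$lineage_id, 1:2)
  expect_equal(out$events$kind, "extinction")
  expect_equal(out$events$parent1, 0.8)

  # all used -> no extinctions
  log_all <- manual_log(data.frame(i = c(1, 1, 1), j = c(2, 2, 2), lang = 1:3),
                        langs, 2, c(3L, 3L))
  expect_equal(nrow(apply_extinction(langs, log_all, 1)$events), 0)

  # nobody communicated -> everything goes extinct
  log_none <- manual_log(data.frame(i = integer(0), j = integer(0),
                                    lang = integer(0)), langs, 2, c(0L, 0L))
  out3 <- apply_extinction(langs, log_none, 1)
  expect_equal(nrow(out3$langs), 0)
  expect_equal(nrow(out3$events), 3)

  # division children of this generation are exempt
  kids <- new_languages(c(0.4, 0.6), 4:5)
  attr(kids, "division_child") <- c(TRUE, TRUE)
  out4 <- apply_extinction(kids, log_none, 1)
  expect_equal(nrow(out4$langs), 2)
})

test_that("fusion merges greedily at midpoints until all gaps >= Tf", {
  params <- sim_params(N = 10, Tf = 0.02)
  out <- apply_fusion(new_languages(c(0.50, 0.51), 1:2), params, 1)
  expect_equal(out$langs$pos, 0.505)
  expect_equal(out$events$kind, "fusion")

  out2 <- apply_fusion(new_languages(c(0.50, 0.53), 1:2), params, 1)
  expect_equal(sort(out2$langs$pos), c(0.50, 0.53))
  expect_equal(nrow(out2$events), 0)

  # cascade: 0.50/0.51 -> 0.505, then 0.505/0.52 -> 0.5125
  out3 <- apply_fusion(new_languages(c(0.52, 0.50, 0.51), 1:3), params, 1)
  expect_equal(out3$langs$pos, 0.5125)
  expect_equal(nrow(out3$events), 2)
  expect_equal(out3$events$child1, c(0.505, 0.5125))

  # property: after fusion all pairwise gaps >= Tf
  set.seed(9)
  for (r in 1:50) {
    pos <- runif(sample(2:15, 1))
    res <- apply_fusion(new_languages(pos, seq_along(pos)), params, 1)
    if (nrow(res$langs) > 1) {
      expect_true(min(diff(sort(res$langs$pos))) >= params$Tf)
    }
    # each fusion event reduces the count by one
    expect_equal(nrow(res$langs), length(pos) - nrow(res$events))
  }
})
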