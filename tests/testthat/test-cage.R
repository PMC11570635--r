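# Cage dynamics: seeding designs, deterministic recursion, stochastic
# sampling distribution, and the observation model.

test_that("presets reproduce the experimental seeding tables", {
  s <- seed_population(cage_preset("self_elim_1to3")$config)
  expect_equal(sum(s$count), 120)
  expect_equal(s$count[s$genotype == "E;L"], 15)
  expect_equal(s$count[s$genotype == "E/E;L/L"], 15)
  expect_equal(s$count[s$genotype == "Y+;F"], 45)
  expect_equal(s$count[s$genotype == "Y+/Y+;F/F"], 45)

  s <- seed_population(cage_preset("hover_1to1")$config)
  expect_equal(s$count, c(30, 30, 30, 30))
  expect_true(all(grepl("Y-", s$genotype[3:4])))

  s <- seed_population(cage_preset("control_noCas9_1to1")$config)
  expect_true(all(grepl("E0", s$genotype[1:2])))
  expect_false(cage_preset("control_noCas9_1to1")$params$cas9_active)

  # generation-0 carrier fraction of the 1:3 design is the seeding ratio
  pre <- cage_preset("self_elim_1to3")
  tr <- run_deterministic(pre$config, pre$params)
  expect_equal(tr$dsred[tr$generation == 0], 0.25)
  expect_equal(tr$freq_L[tr$generation == 0], 0.25)
})

test_that("neutral parameters conserve allele frequencies to machine precision", {
  pre <- cage_preset("hover_1to3", generations = 12)
  tr <- run_deterministic(pre$config, neutral_params("hover"))
  # allele frequencies never move; the carrier fraction equilibrates to
  # Hardy-Weinberg in one generation of random mating and then never moves
  expect_equal(tr$dsred[2:13], rep(tr$dsred[2], 12), tolerance = 1e-14)
  expect_equal(tr$freq_L, rep(0.25, 13), tolerance = 1e-14)
  expect_equal(tr$freq_F, rep(0.75, 13), tolerance = 1e-14)
  expect_equal(tr$freq_R, rep(0, 13))
  # allele frequencies sum to 1 every generation
  expect_equal(tr$freq_L + tr$freq_F + tr$freq_R, rep(1, 13),
               tolerance = 1e-12)
})

test_that("the generation-1 carrier surge exceeds the seeded fraction", {
  # dominant-marker segregation from homo-/hemizygous founders
  for (preset in c("self_elim_1to3", "hover_1to3", "self_elim_1to1")) {
    pre <- cage_preset(preset)
    tr <- run_deterministic(pre$config, pre$params)
    expect_gt(tr$dsred[2], tr$dsred[1])
  }
})

test_that("stepwise and full deterministic runs agree", {
  pre <- cage_preset("self_elim_1to3")
  tr <- run_deterministic(pre$config, pre$params)
  states <- attr(tr, "states")
  s0 <- states[states$generation == 0, c("sex", "genotype", "freq")]
  s1 <- step_deterministic(s0, pre$params)
  s1_full <- states[states$generation == 1, c("sex", "genotype", "freq")]
  expect_equal(
    dplyr::arrange(s1, sex, genotype),
    dplyr::arrange(tibble::as_tibble(s1_full), sex, genotype),
    tolerance = 1e-12, ignore_attr = TRUE
  )
})

test_that("every stochastic trajectory state is frequency-normalized and viable", {
  pre <- cage_preset("self_elim_1to3")
  set.seed(99)
  tr <- edriver:::.run_stoch_counts(pre$config, pre$params)
  eng <- edriver:::.build_engine(pre$params)
  for (g in seq_len(ncol(tr$fc))) {
    expect_true(all(tr$fc[eng$fviab == 0, g] == 0))
    expect_true(all(tr$mc[eng$mviab == 0, g] == 0))
  }
})

test_that("identical seeds give identical stochastic trajectories", {
  pre <- cage_preset("hover_1to3")
  a <- run_stochastic(pre$config, pre$params, reps = 3, seed = 7)
  b <- run_stochastic(pre$config, pre$params, reps = 3, seed = 7)
  expect_identical(a, b)
  c <- run_stochastic(pre$config, pre$params, reps = 3, seed = 8)
  expect_false(identical(a, c))
})

test_that("large-census stochastic runs converge to the deterministic path", {
  pre <- cage_preset("self_elim_1to3")
  big <- pre$config
  big$census_adults <- 100000L
  det <- run_deterministic(pre$config, pre$params)
  st <- run_stochastic(big, pre$params, reps = 1, seed = 5)
  # per-generation multinomial noise on an allele frequency is at most
  # sqrt(0.25 / (1.5 N)); treat accumulation as a random walk and allow 3 sigma
  for (g in 1:9) {
    tol <- 3 * sqrt(g * 0.25 / (1.5 * 100000))
    expect_lt(abs(st$freq_L[g + 1] - det$freq_L[g + 1]), tol)
    expect_lt(abs(st$dsred[g + 1] - det$dsred[g + 1]),
              3 * sqrt(g * 0.25 / 100000))
  }
})

test_that("one neutral stochastic step is the exact Mendelian multinomial", {
  state <- tibble::tibble(
    sex = c("female", "male"),
    genotype = c("Y+/Y-;L/F", "Y+;L"),
    count = c(60, 60)
  )
  pre <- cage_preset("hover_1to3")
  params <- neutral_params()
  v <- edriver:::.vectors_from_tbl(state, "count")
  eng <- edriver:::.build_engine(params)
  expected <- edriver:::.next_gen_dist(v$f, v$m, eng)

  set.seed(123)
  pooled_f <- rep(0, length(expected$f))
  for (r in 1:200) {
    nxt <- edriver:::.step_stoch_vec(v$f, v$m, eng, 120L)
    pooled_f <- pooled_f + nxt$f
  }
  keep <- expected$f > 0
  # chi-square goodness of fit of pooled female genotype counts
  gof <- suppressWarnings(
    stats::chisq.test(pooled_f[keep], p = expected$f[keep])
  )
  expect_gt(gof$p.value, 0.01)
  expect_true(all(pooled_f[!keep] == 0))
})

test_that("observation of a monomorphic population is deterministic in reads", {
  state <- tibble::tibble(
    sex = c("female", "male"), genotype = c("E/E;L/L", "E;L"),
    count = c(60, 60)
  )
  config <- cage_preset("hover_1to3")$config
  obs <- observe(state, config, seed = 1)
  expect_equal(obs$reads_L, config$read_depth)
  expect_equal(obs$reads_F + obs$reads_R, 0L)
  expect_equal(obs$dsred_positive, obs$dsred_scored) # everyone carries DsRed
})

test_that("read fractions converge to population allele fractions at depth", {
  state <- tibble::tibble(
    sex = c("female", "male"),
    genotype = c("Y+/Y-;L/F", "Y+;F"),
    count = c(60, 60)
  )
  # population X pool: 60 L + 60 F (females) + 60 F (males) -> L share 1/3
  config <- cage_config(state, mode = "hover", ngs_flies = 120L,
                        read_depth = 200000L)
  obs <- observe(state, config, seed = 2)
  expect_equal(obs$reads_L / config$read_depth, 1 / 3, tolerance = 0.01)
  expect_equal(obs$reads_L + obs$reads_F + obs$reads_R, 200000L)
})

test_that("repeated 25-fly observations are unbiased", {
  state <- tibble::tibble(
    sex = c("female", "male"),
    genotype = c("Y+/Y+;L/L", "Y+;F"),
    count = c(40, 80) # X pool: 80 L, 80 F
  )
  config <- cage_preset("hover_1to3")$config
  set.seed(31)
  fr <- replicate(200, {
    v <- edriver:::.vectors_from_tbl(state, "count")
    o <- edriver:::.observe_counts(v$f, v$m, config)
    o$reads_L / config$read_depth
  })
  expect_equal(mean(fr), 0.5, tolerance = 0.02)
  # two-stage sampling inflates the variance well beyond read-multinomial
  expect_gt(stats::sd(fr), sqrt(0.25 / config$read_depth) * 3)
})

test_that("sampling more flies than exist takes the whole population", {
  state <- tibble::tibble(
    sex = c("female", "male"), genotype = c("Y+/Y+;L/L", "Y+;F"),
    count = c(3, 3)
  )
  config <- cage_preset("hover_1to3")$config # asks for 25 of 6 flies
  obs <- observe(state, config, seed = 4)
  # pooled alleles are then exactly 6 L + 3 F
  expect_equal(obs$reads_L / config$read_depth, 2 / 3, tolerance = 0.03)
})

test_that("hover deployment with no costs keeps the cassette frequency flat", {
  pre <- cage_preset("hover_1to1", generations = 15)
  params <- drive_params(mode = "hover", s_drive_hover = 0, s_Fhom = 0,
                         cas9_active = FALSE, c = 0, l = 0, m = 0)
  tr <- run_deterministic(pre$config, params)
  # flat after the one-generation Hardy-Weinberg segregation surge
  expect_equal(tr$dsred[2:16], rep(tr$dsred[2], 15), tolerance = 1e-13)
  expect_gt(tr$dsred[2], 0.5)
})

test_that("extinction is reported as a flagged state, not an error", {
  # a cage seeded only with drive males and F/F drive females collapses
  seeding <- tibble::tibble(
    sex = c("female", "male"),
    genotype = c("E/E;F/F", "E;L"),
    count = c(10, 10)
  )
  expect_error(
    cfg <- cage_config(seeding, census_adults = 20, generations = 3),
    NA
  )
  tr <- run_deterministic(cfg, drive_params())
  expect_true(attr(tr, "extinct"))
  expect_true(all(is.na(tr$dsred[-1])))
})
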