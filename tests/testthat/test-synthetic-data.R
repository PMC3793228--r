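test_that("the Yule simulator honours its stopping rules exactly", {
  tr <- simulate_yule(0.5, stop_time = 5, seed = 1)
  expect_equal(crown_age(tr, tol = 1e-9), 5, tolerance = 1e-9)
  expect_true(check_ultrametric(tr, tol = 1e-9)$ok)

  tr64 <- simulate_yule(1.0, stop_tips = 64, seed = 2)
  expect_equal(ape::Ntip(tr64), 64L)
  expect_true(check_ultrametric(tr64, tol = 1e-9)$ok)
  expect_true(all(tr64$edge.length > 0))

  expect_error(simulate_yule(0), "> 0")
  expect_error(simulate_yule(1), "exactly one")
  expect_error(simulate_yule(1, stop_time = 2, stop_tips = 5), "exactly one")
})

test_that("same seed gives byte-identical serialized trees", {
  a <- ape::write.tree(simulate_yule(0.7, stop_time = 4, seed = 77))
  b <- ape::write.tree(simulate_yule(0.7, stop_time = 4, seed = 77))
  d <- ape::write.tree(simulate_yule(0.7, stop_time = 4, seed = 78))
  expect_identical(a, b)
  expect_false(identical(a, d))
})

test_that("Yule tip counts match the closed-form expectation", {
  lambda <- 0.5; t <- 3; reps <- 2000
  m <- exp(lambda * t)                       # per-lineage geometric mean
  tips <- vapply(seq_len(reps), function(i)
    ape::Ntip(simulate_yule(lambda, stop_time = t, seed = 10000 + i)),
    integer(1))
  exp_mean <- 2 * m                          # two independent crown lineages
  exp_var <- 2 * m * (m - 1)                 # sum of two geometric variances
  se <- sqrt(exp_var / reps)
  expect_lt(abs(mean(tips) - exp_mean), 3 * se)
  expect_gte(min(tips), 2)
})

test_that("the crown estimator recovers the Yule rate from simulated trees", {
  lambda <- 0.5; t <- 8
  tips <- vapply(1:500, function(i)
    ape::Ntip(simulate_yule(lambda, stop_time = t, seed = 20000 + i)),
    integer(1))
  r_hat <- pure_birth_rate(tips, t, n0 = 2)
  # median-consistency: the median estimate sits within 10% of the truth
  expect_lt(abs(median(r_hat) - lambda) / lambda, 0.10)
  # method of moments proper: invert the expectation at the mean tip count
  expect_lt(abs(pure_birth_rate(mean(tips), t, n0 = 2) - lambda) / lambda, 0.05)
  # the per-tree error distribution matches the exact two-geometric law
  set.seed(321)
  n_exact <- (rgeom(2e4, exp(-lambda * t)) + 1) +
             (rgeom(2e4, exp(-lambda * t)) + 1)
  med_exact <- median(abs(log(n_exact / 2) / t - lambda)) / lambda
  med_sim <- median(abs(r_hat - lambda)) / lambda
  expect_lt(abs(med_sim - med_exact), 0.03)
})

test_that("the birth-death simulator prunes extinct lineages and conditions on survival", {
  for (i in 1:30) {
    tr <- simulate_birth_death(1, 0.5, stop_time = 3, seed = 3000 + i)
    expect_gte(ape::Ntip(tr), 2L)
    expect_true(check_ultrametric(tr, tol = 1e-9)$ok)
    expect_lte(crown_age(tr, tol = 1e-9), 3 + 1e-9)
  }
  expect_error(simulate_birth_death(1, 1.5, stop_time = 1), "mu")
})

test_that("at zero extinction the birth-death sampler matches the Yule tip-count law", {
  reps <- 600
  bd <- vapply(seq_len(reps), function(i)
    ape::Ntip(simulate_birth_death(0.6, 0, stop_time = 3,
                                   condition_on_survival = FALSE,
                                   seed = 40000 + i)), integer(1))
  yu <- vapply(seq_len(reps), function(i)
    ape::Ntip(simulate_yule(0.6, stop_time = 3, seed = 50000 + i)),
    integer(1))
  expect_gt(suppressWarnings(ks.test(bd, yu))$p.value, 0.01)
})

test_that("the extinction-matched crown estimator recovers the net rate", {
  lambda <- 1; mu <- 0.5; t <- 3; eps <- mu / lambda
  tips <- vapply(1:2000, function(i)
    ape::Ntip(simulate_birth_death(lambda, mu, stop_time = t,
                                   seed = 60000 + i)), integer(1))
  r_hat <- ms_rate(mean(tips), t, epsilon = eps, mode = "crown")
  expect_lt(abs(r_hat - (lambda - mu)) / (lambda - mu), 0.15)
})

test_that("synthetic rate tables follow the requested log-normal structure", {
  specs <- data.frame(hotspot = c("A", "B"), n_lineages = c(4, 3),
                      meanlog = log(c(2, 0.5)), sdlog = c(0, 0))
  tbl <- generate_lineage_table(specs, seed = 1)
  expect_equal(nrow(tbl), 7L)
  expect_equal(tbl$rate[tbl$hotspot == "A"], rep(2, 4))
  expect_equal(tbl$rate[tbl$hotspot == "B"], rep(0.5, 3))
  expect_false(anyDuplicated(tbl$lineage_id) > 0)

  big <- generate_lineage_table(
    data.frame(hotspot = "H", n_lineages = 1e4, meanlog = 0.2, sdlog = 0.4),
    seed = 2)
  mu_ln <- exp(0.2 + 0.4^2 / 2)
  sd_ln <- sqrt((exp(0.4^2) - 1) * exp(2 * 0.2 + 0.4^2))
  expect_lt(abs(mean(big$rate) - mu_ln), 3 * sd_ln / sqrt(1e4))
  expect_identical(generate_lineage_table(specs, seed = 1), tbl)
  expect_error(generate_lineage_table(transform(specs, sdlog = -1)), "sdlog")
})

test_that("hotspot means shaped like the published ones rank the fastest hotspot first", {
  means <- c(Paramos = 1.36, Mediterranean = 1.07, SucculentKaroo = 0.76,
             Hawaii = 0.73, Cerrado = 0.58, Cape = 0.40, California = 0.39,
             SWAustralia = 0.14)
  specs <- data.frame(hotspot = names(means), n_lineages = 6,
                      meanlog = log(means), sdlog = 0.4)
  tbl <- generate_lineage_table(specs, seed = 99)
  p <- exact_fastest_probability(tbl, k = 5)
  expect_equal(names(which.max(p)), "Paramos")
  smry <- summarize_resampling(tbl, k = 5, n_samples = 200, n_iterations = 30,
                               seed = 4)
  expect_equal(smry$hotspot[which.max(smry$prob_fastest_mean)], "Paramos")
})

test_that("packaged tables carry the transcribed records", {
  lin <- paramo_lineages()
  expect_equal(nrow(lin), 13L)
  expect_equal(lin$n_species[lin$lineage_id == "Lupinus"], 66L)
  expect_true(is.na(lin$crown_age_min[lin$lineage_id == "Jamesonia+Eriosorus"]))
  meta <- hotspot_metadata()
  expect_equal(nrow(meta), 8L)
  expect_equal(meta$area_km2[meta$hotspot == "Paramos"], 35000)
  # round-trip through the CSV writer/reader is identity
  tf <- withr::local_tempfile(fileext = ".csv")
  write.csv(lin, tf, row.names = FALSE, na = "")
  expect_equal(suppressWarnings(read_lineage_csv(tf)), lin,
               ignore_attr = TRUE)
})
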