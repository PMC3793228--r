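test_that("the hotspot mean of the packaged lineage rates matches the published value", {
  rt <- rate_table(paramo_lineages())
  expect_equal(hotspot_mean_rate(rt$rate_mean_age), 1.36,
               tolerance = 0.005 / 1.36)
  expect_equal(hotspot_mean_rate(rep(2.5, 3)), 2.5)
  expect_error(hotspot_mean_rate(numeric(0)), "at least one")
})

test_that("percentile bootstrap is deterministic per seed and degenerate on constants", {
  expect_equal(bootstrap_mean_ci(c(5, 5, 5, 5), seed = 1),
               list(mean = 5, ci_low = 5, ci_high = 5))
  vals <- rate_table(paramo_lineages())$rate_mean_age
  a <- bootstrap_mean_ci(vals, seed = 42)
  b <- bootstrap_mean_ci(vals, seed = 42)
  c <- bootstrap_mean_ci(vals, seed = 43)
  expect_identical(a, b)
  expect_false(identical(a, c))
  expect_lte(a$ci_low, a$mean)
  expect_gte(a$ci_high, a$mean)
  expect_warning(out <- bootstrap_mean_ci(1.5), "degenerate")
  expect_equal(out, list(mean = 1.5, ci_low = 1.5, ci_high = 1.5))
})

test_that("two-point bootstrap frequencies match exact enumeration", {
  # resampling {0, 10} twice gives means 0/5/10 with probabilities 1/4, 1/2, 1/4
  n_boot <- 1e5
  boots <- with(list(v = c(0, 10)), {
    set.seed(99)
    vapply(seq_len(n_boot), function(i) mean(sample(c(0, 10), 2, TRUE)),
           numeric(1))
  })
  freq <- table(factor(boots, levels = c(0, 5, 10))) / n_boot
  p <- c(0.25, 0.5, 0.25)
  sigma <- sqrt(p * (1 - p) / n_boot)
  expect_true(all(abs(as.vector(freq) - p) < 3 * sigma))
  # the package's percentile interval on the same two points spans the support
  ci <- bootstrap_mean_ci(c(0, 10), n_boot = 1e4, seed = 3)
  expect_equal(ci$mean, 5)
  expect_lte(ci$ci_low, 5)
  expect_gte(ci$ci_high, 5)
})

test_that("bootstrap interval width shrinks with sample size at fixed spread", {
  widths <- function(n) {
    vapply(1:100, function(s) {
      vals <- with_fixed_values(n, s)
      ci <- bootstrap_mean_ci(vals, n_boot = 300, seed = s)
      ci$ci_high - ci$ci_low
    }, numeric(1))
  }
  with_fixed_values <- function(n, s) {
    set.seed(1000 + s)
    rnorm(n, mean = 1, sd = 0.5)
  }
  expect_lt(median(widths(50)), median(widths(5)))
})

test_that("density metrics reproduce the internally consistent published cells", {
  expect_equal(species_density(3431, 35000), 0.098, tolerance = 0.0005 / 0.098)
  expect_equal(species_density(1004, 28311), 0.035, tolerance = 0.0005 / 0.035)
  expect_equal(species_density(0, 100), 0)
  expect_error(species_density(10, 0), "> 0")
  rt <- rate_table(paramo_lineages())
  expect_equal(speciation_density(mean(rt$rate_mean_age), 35000) * 1e6,
               38.80, tolerance = 0.05 / 38.80)
  expect_equal(speciation_density(0, 100), 0)
})

test_that("published cell validation flags exactly the impossible density cells", {
  v <- validate_hotspot_cells(hotspot_metadata())
  bad <- v[!v$consistent, ]
  expect_setequal(bad$hotspot, c("Cerrado", "Cape Floristic Region"))
  expect_true(all(bad$cell == "species_density"))
  ok <- v[v$cell == "species_density" & v$consistent, "hotspot"]
  expect_setequal(ok, c("Paramos", "Hawaiian Archipelago",
                        "California Floristic Province",
                        "Mediterranean Floristic Province",
                        "Southwest Australia", "Succulent Karoo"))
  expect_true(all(v$consistent[v$cell == "speciation_density"]))
})

test_that("the assembled summary joins rates, intervals and densities per hotspot", {
  smry <- assemble_summary(rate_table(paramo_lineages()), hotspot_metadata(),
                           seed = 42)
  expect_equal(nrow(smry), 1L)
  expect_equal(smry$hotspot, "Paramos")
  expect_equal(smry$n_lineages, 13L)
  expect_equal(smry$mean_rate, 1.36, tolerance = 0.005 / 1.36)
  expect_equal(smry$species_density, 0.098, tolerance = 0.0005 / 0.098)
  expect_equal(smry$speciation_density * 1e6, 38.80, tolerance = 0.05 / 38.80)
  expect_lte(smry$ci_low, smry$mean_rate)
  expect_gte(smry$ci_high, smry$mean_rate)
  # upper summary comes from minimum ages, hence exceeds the mean summary
  expect_gt(smry$mean_rate_upper, smry$mean_rate)
  expect_lt(smry$mean_rate_lower, smry$mean_rate)
})

test_that("the summary is invariant to input row order and errors on missing metadata", {
  rt <- rate_table(paramo_lineages())
  rt$hotspot[1:6] <- "Elsewhere"
  meta <- hotspot_metadata()
  expect_error(assemble_summary(rt, meta, seed = 1), "Elsewhere")
  meta2 <- rbind(meta[, c("hotspot", "area_km2", "species_total")],
                 data.frame(hotspot = "Elsewhere", area_km2 = 1000,
                            species_total = 10))
  a <- assemble_summary(rt, meta2, seed = 9)
  b <- assemble_summary(rt[sample(nrow(rt)), ], meta2[sample(nrow(meta2)), ],
                        seed = 9)
  expect_equal(a, b)
  expect_equal(a$hotspot, sort(a$hotspot))
})

test_that("a single-lineage hotspot summarizes to that lineage's rate", {
  rt <- data.frame(lineage_id = "only", hotspot = "H", rate_mean_age = 0.7)
  meta <- data.frame(hotspot = "H", area_km2 = 100, species_total = 5)
  smry <- suppressWarnings(assemble_summary(rt, meta, seed = 1))
  expect_equal(smry$mean_rate, 0.7)
  expect_equal(smry$ci_low, 0.7)
  expect_equal(smry$ci_high, 0.7)
})
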