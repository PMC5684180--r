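test_that("pie-chart construction validates its probabilities", {
  d <- fas_distribution(filtering = 0.6, blockage = 0.4)
  expect_equal(unname(d$probs), c(0, 0.6, 0, 0.4))
  expect_error(fas_distribution(filtering = 0.5, blockage = 0.4), "sum to 1")
  expect_error(fas_distribution(filtering = -0.2, blockage = 1.2), "non-negative")
  presets <- fas_presets()
  expect_named(presets, c("f60b40", "f40b60", "f20b80", "blockage_only"))
  for (p in presets) expect_equal(sum(p$probs), 1)
})

test_that("transfer function reproduces the regime maps", {
  # reflection halves the rate; blockage zeroes it; transmission is identity
  expect_equal(fas_transfer(0.8, 3), 0.4)
  expect_equal(fas_transfer(0.8, 4), 0)
  expect_equal(fas_transfer(0.8, 0), 0.8)
  expect_equal(fas_transfer(0.8, 1), 0.8)
  # filtering soft cap with defaults theta = 0.5, kappa = 0.25
  expect_equal(fas_transfer(0.8, 2), 0.575)
  expect_equal(fas_transfer(0.3, 2), 0.3)  # below the knee: unchanged
  expect_error(fas_transfer(0.5, 7), "regime")
  expect_error(fas_transfer(1.3, 0), "rates")
})

test_that("transfer is monotone, never rate-increasing, and zero at zero", {
  r <- seq(0, 1, by = 0.01)
  for (reg in 0:4) {
    out <- fas_transfer(r, reg)
    expect_true(all(diff(out) >= -1e-12))        # monotone non-decreasing
    expect_true(all(out <= r + 1e-12))           # never increases a rate
  }
  for (reg in 2:4) expect_equal(fas_transfer(0, reg), 0)
})

test_that("assignments injure an exact neuron count with pie-chart regimes", {
  d <- fas_distribution(filtering = 0.2, blockage = 0.8)
  a0 <- sample_assignment(500, 0, d, seed = 1)
  expect_true(all(a0$regime == 0L))
  a1 <- sample_assignment(500, 1, fas_distribution(blockage = 1), seed = 2)
  expect_true(all(a1$regime == 4L))
  a <- sample_assignment(10000, 0.3, d, seed = 3)
  counts <- tabulate(a$regime + 1L, nbins = 5)
  expect_identical(counts[1], 7000L)             # exact-count injury
  # multinomial 99% bands around (600, 2400) for the injured regimes
  expect_true(abs(counts[3] - 600) < 2.58 * sqrt(3000 * 0.2 * 0.8) + 1)
  expect_true(abs(counts[5] - 2400) < 2.58 * sqrt(3000 * 0.8 * 0.2) + 1)
  expect_error(sample_assignment(100, 1.5, d, seed = 1), "injury_level")
  expect_error(sample_assignment(100, 0.5, d), "seed")
})

test_that("sampled regime proportions match the pie-chart (chi-square)", {
  d <- fas_distribution(0.1, 0.3, 0.2, 0.4)
  pass <- vapply(1:20, function(s) {
    a <- sample_assignment(10000, 0.5, d, seed = s)
    inj <- a$regime[a$regime > 0L]
    chisq.test(tabulate(inj, nbins = 4), p = d$probs)$p.value > 0.01
  }, logical(1))
  expect_gte(sum(pass), 19L)
})

test_that("effective outputs equal the elementwise transfer of rates", {
  set.seed(4)
  q <- 8
  lv <- sample.int(q, 200, replace = TRUE) - 1L
  v <- level_values(q)[lv + 1L]
  a <- sample_assignment(200, 0.6, fas_distribution(0.25, 0.25, 0.25, 0.25), seed = 5)
  out <- effective_output(v, a)
  # independent elementwise oracle: transfer acts on the signal magnitude,
  # preserving sign; blockage transmits nothing
  for (i in seq_along(v)) {
    expected <- if (a$regime[i] == 4L) 0 else sign(v[i]) * fas_transfer(abs(v[i]), a$regime[i])
    expect_equal(out[i], expected)
  }
  # identity for an uninjured assignment
  a0 <- sample_assignment(200, 0, fas_distribution(blockage = 1), seed = 6)
  expect_identical(effective_output(v, a0), v)
  expect_error(effective_output(v[-1], a), "equal length")
})

test_that("blocked neurons are silenced, frozen, and emit nothing", {
  fx <- tiny_random_net(80, 4, seed = 7)
  p <- get_pattern(fx$memories, 1)
  blocked <- sample_assignment(80, 1, fas_distribution(blockage = 1), seed = 8)
  set.seed(1)
  res <- run_to_convergence(fx$net, p, noise_sigma = 0.2, assignment = blocked)
  expect_identical(res$levels, rep(0L, 80))      # all silenced, none updates
  expect_equal(effective_output(level_values(2)[unclass(p) + 1L], blocked),
               rep(0, 80))
  # partial blockage: blocked neurons silent, healthy ones untouched at a
  # stored fixed point
  part <- sample_assignment(80, 0.3, fas_distribution(blockage = 1), seed = 9)
  res2 <- run_to_convergence(fx$net, p, noise_sigma = 0, assignment = part)
  idx <- which(part$regime == 4L)
  expect_true(all(res2$levels[idx] == 0L))
})

test_that("pie-charts load from YAML and JSON with normalization", {
  y <- file.path(tempdir(), "pc.yaml")
  writeLines(c("label: demo", "filtering: 0.3", "blockage: 0.7"), y)
  expect_warning(read_fas_distribution(y), "blockage")
  d <- suppressWarnings(read_fas_distribution(y))
  expect_equal(unname(d$probs), c(0, 0.3, 0, 0.7))
  expect_equal(d$label, "demo")
  # un-normalized fractions are rescaled to sum to 1
  y2 <- file.path(tempdir(), "pc2.yaml")
  writeLines(c("filtering: 1.2", "blockage: 0.8"), y2)
  expect_equal(unname(read_fas_distribution(y2)$probs), c(0, 0.6, 0, 0.4))
  shipped <- system.file("extdata", "piechart_f60b40.yaml", package = "fasnet")
  d2 <- read_fas_distribution(shipped)
  expect_equal(unname(d2$probs), c(0, 0.6, 0, 0.4))
  j <- file.path(tempdir(), "pc.json")
  writeLines('{"filtering": 0.7, "blockage": 0.3}', j)
  expect_equal(unname(read_fas_distribution(j)$probs), c(0, 0.7, 0, 0.3))
  bad <- file.path(tempdir(), "pc_bad.yaml")
  writeLines(c("filtering: 0.5", "spikes: 0.5"), bad)
  expect_error(read_fas_distribution(bad), "unknown pie-chart keys")
})
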