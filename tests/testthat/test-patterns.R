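test_that("random generator obeys its contract and is reproducible", {
  ms <- generate_random_memories(900, 126, 2, 0.5, seed = 1)
  expect_s3_class(ms, "memory_set")
  expect_equal(dim(ms$levels), c(126, 900))
  expect_true(all(ms$levels %in% 0:1))
  # exact active count per pattern
  expect_true(all(rowSums(ms$levels != 0L) == 450))
  ms2 <- generate_random_memories(900, 126, 2, 0.5, seed = 1)
  expect_identical(ms$levels, ms2$levels)
  expect_error(generate_random_memories(900, 126, 2, 0.5), "seed")
  expect_error(generate_random_memories(-1, 5, 2, 0.5, seed = 1), "positive")
  expect_warning(generate_random_memories(100, 20, 2, 0.5, seed = 1), "capacity")
  expect_error(suppressWarnings(generate_random_memories(100, 40, 2, 0.5, seed = 1)))
})

test_that("degenerate full-activity pattern has all neurons active", {
  ms <- generate_random_memories(10, 1, 2, 1.0, seed = 0)
  expect_equal(unname(ms$levels[1, ]), rep(1L, 10))
})

test_that("empirical mean pairwise overlap matches the closed-form expectation", {
  cases <- list(c(a = 0.5, q = 2), c(a = 0.3, q = 2), c(a = 0.6, q = 8))
  for (cs in cases) {
    ms <- generate_random_memories(900, 40, cs[["q"]], cs[["a"]], seed = 5)
    expect_equal(mean_pairwise_overlap(ms),
                 expected_overlap_random(cs[["a"]], cs[["q"]]),
                 tolerance = 0.02)
  }
  # multi-level sparse-ish patterns reach the 20-25% overlap band
  expect_true(expected_overlap_random(0.6, 8) > 0.20 &&
              expected_overlap_random(0.6, 8) < 0.25)
})

test_that("correlated family hits its target overlap", {
  cf <- generate_correlated_family(1080, 3, 8, 0.65, seed = 2)
  expect_equal(n_memories(cf), 3L)
  expect_lt(abs(mean_pairwise_overlap(cf) - 0.65), 0.05)
  # near-identical limit
  cf2 <- generate_correlated_family(100, 2, 2, 0.99, seed = 3)
  expect_gt(mean_pairwise_overlap(cf2), 0.95)
  # Monte-Carlo check of the copy-fraction construction over seeds
  ovs <- vapply(1:20, function(s)
    mean_pairwise_overlap(generate_correlated_family(1080, 5, 8, 0.65, seed = s)),
    numeric(1))
  expect_lt(abs(mean(ovs) - 0.65), 0.02)
  # convergence at large N
  big <- generate_correlated_family(10000, 3, 8, 0.65, seed = 4)
  expect_lt(abs(mean_pairwise_overlap(big) - 0.65), 0.02)
  expect_error(generate_correlated_family(100, 3, 8, 0.05, seed = 1), "target_overlap")
  expect_error(generate_correlated_family(100, 3, 8, 0.65), "seed")
})

test_that("overlap equals 1 - normalized Hamming distance", {
  set.seed(9)
  for (q in c(2, 5, 8)) {
    x <- sample.int(q, 500, replace = TRUE) - 1L
    y <- sample.int(q, 500, replace = TRUE) - 1L
    expect_identical(overlap(x, y), overlap_oracle(x, y))
    expect_equal(overlap(x, y), 1 - mean(x != y))
  }
  expect_error(overlap(1:3, 1:4), "equal length")
})

test_that("pairwise overlap matrix is symmetric with unit diagonal", {
  ms <- generate_random_memories(400, 12, 4, 0.5, seed = 6)
  ov <- pairwise_overlap(ms)
  expect_equal(diag(ov), rep(1, 12), ignore_attr = TRUE)
  expect_identical(ov, t(ov))
  expect_identical(ov[2, 5], overlap_oracle(ms$levels[2, ], ms$levels[5, ]))
  # complementary binary pair -> 0; identical pair -> 1
  comp <- memory_set(rbind(c(0L, 1L, 0L), c(1L, 0L, 1L), c(0L, 1L, 0L)), 2)
  ovc <- pairwise_overlap(comp)
  expect_equal(ovc[1, 2], 0)
  expect_equal(ovc[1, 3], 1)
})

test_that("cue noise corrupts an exact count of positions", {
  ms <- generate_random_memories(1000, 1, 2, 0.5, seed = 8)
  p <- get_pattern(ms, 1)
  expect_identical(add_cue_noise(p, 0, seed = 1), p)
  noisy <- add_cue_noise(p, 0.2, seed = 1)
  expect_identical(overlap(noisy, p), 0.8)
  # q = 2, full noise: the only different level is the complement
  flipped <- add_cue_noise(p, 1, seed = 2)
  expect_equal(unclass(flipped), 1L - unclass(p), ignore_attr = TRUE)
  expect_error(add_cue_noise(p, 1.2), "noise_level")
  expect_error(add_cue_noise(p, -0.1), "noise_level")
  # multi-level: corrupted positions never keep their old level
  ms8 <- generate_random_memories(1000, 1, 8, 0.6, seed = 9)
  p8 <- get_pattern(ms8, 1)
  n8 <- add_cue_noise(p8, 0.3, seed = 3)
  expect_identical(overlap(n8, p8), 0.7)
})

test_that("cue noise preserves level frequencies in expectation for balanced binary patterns", {
  ms <- generate_random_memories(2000, 1, 2, 0.5, seed = 10)
  p <- get_pattern(ms, 1)
  set.seed(123)  # one continuous stream across replicates
  fracs <- vapply(1:100, function(s) mean(add_cue_noise(p, 0.3) == 1L),
                  numeric(1))
  expect_lt(abs(mean(fracs) - 0.5), 0.01)
})

test_that("image encoding quantizes and flattens row-major", {
  img <- matrix(c(0, 255, 128, 64), 2, 2, byrow = TRUE)
  expect_equal(unclass(encode_image(img, 2)), c(0L, 1L, 1L, 0L), ignore_attr = TRUE)
  # q = 256 is the identity on integer intensities
  img2 <- matrix(0:249, 25, 10, byrow = TRUE)
  expect_equal(unclass(encode_image(img2, 256)), 0:249, ignore_attr = TRUE)
  # uniform-noise image -> approximately uniform level histogram
  img3 <- noise_image(30, 36, seed = 4)
  lv <- encode_image(img3, 8)
  chi <- chisq.test(tabulate(lv + 1L, nbins = 8))
  expect_gt(chi$p.value, 0.01)
  expect_error(encode_image(matrix(numeric(0), 0, 0), 8), "non-empty")
})

test_that("PGM images are read in both ASCII and binary form", {
  px <- matrix(c(0, 64, 128, 255, 10, 200), nrow = 2, byrow = TRUE)
  p2 <- file.path(tempdir(), "img.pgm")
  writeLines(c("P2", "# a comment", "3 2", "255",
               paste(t(px)[, 1], collapse = " "), paste(t(px)[, 2], collapse = " ")), p2)
  expect_equal(read_pgm(p2), px)
  p5 <- file.path(tempdir(), "img5.pgm")
  con <- file(p5, "wb")
  writeChar("P5\n3 2\n255\n", con, eos = NULL)
  writeBin(as.raw(as.integer(t(px))), con)
  close(con)
  expect_equal(read_pgm(p5), px)
  expect_equal(read_image_gray(p5), px)
  # intensities are rescaled when maxval is not 255
  p2b <- file.path(tempdir(), "img_max100.pgm")
  writeLines(c("P2", "1 1", "100", "50"), p2b)
  expect_equal(read_pgm(p2b), matrix(127.5, 1, 1))
  # a PGM flows into encode_image
  lv <- encode_image(read_pgm(p2), 4)
  expect_equal(unclass(lv), c(0L, 1L, 2L, 3L, 0L, 3L), ignore_attr = TRUE)
})

test_that("memory sets round-trip through CSV + JSON sidecar", {
  ms <- generate_random_memories(50, 4, 8, 0.6, seed = 12)
  f <- file.path(tempdir(), "ms.csv")
  write_memory_set(ms, f)
  back <- read_memory_set(f)
  expect_identical(back$levels, ms$levels)
  expect_identical(back$n_levels, ms$n_levels)
  expect_equal(attr(back, "generator")$seed, 12)
})
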