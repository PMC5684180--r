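# Small fixtures shared across test files; everything is generated in code.

tiny_random_net <- function(n = 100, m = 5, seed = 1) {
  ms <- generate_random_memories(n, m, 2, 0.5, seed = seed)
  list(memories = ms, net = hebbian_train(ms))
}

# independent brute-force overlap: loop, no vectorized trickery
overlap_oracle <- function(x, y) {
  x <- as.integer(x); y <- as.integer(y)
  hits <- 0L
  for (i in seq_along(x)) if (x[i] == y[i]) hits <- hits + 1L
  hits / length(x)
}

# deterministic uniform-noise "image" built from a seeded RNG
noise_image <- function(rows, cols, seed) {
  set.seed(seed)
  matrix(sample(0:255, rows * cols, replace = TRUE), rows, cols)
}
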