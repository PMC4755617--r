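# Small in-code fixtures shared across test files.

# a tiny deterministic cell map: 3 cells, one per class
tiny_map <- function() {
  cell_map(x = c(10, 50, 150), y = c(10, 60, 20),
           cell_type = c("cancer", "lymphocyte", "stromal"),
           tumor_id = "tiny")
}

# random cell map with all three classes present
random_map <- function(n = 200, width = 1000, height = 800, seed = 1) {
  withr::with_seed(seed, {
    cell_map(runif(n, 0, width), runif(n, 0, height),
             sample(cell_classes(), n, replace = TRUE),
             tumor_id = "random")
  })
}

# independent brute-force oracle: two-sided Fisher p by hypergeometric
# enumeration over all tables with the observed margins
fisher_enum_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  xs <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(xs, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# independent entropy oracle: accumulate cells one at a time and compute
# the index from the final tallies term by term
shannon_by_enumeration <- function(types) {
  tally <- setNames(numeric(3), cell_classes())
  for (t in types) tally[t] <- tally[t] + 1
  p <- tally / sum(tally)
  s <- 0
  for (pi in p) if (pi > 0) s <- s - pi * log(pi)
  s
}
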