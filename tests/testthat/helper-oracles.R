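# Independent oracles, deliberately naive: direct choose() arithmetic in
# linear space, per-table summation, no windowing, no log-space, no
# sorting shortcuts. They share nothing with the package's computational
# path beyond base pmf primitives.

oracle_fisher_p <- function(a, b, c, d, alternative = "two.sided") {
  n1 <- a + b; n2 <- c + d; s <- a + c
  if (n1 == 0 || n2 == 0 || s == 0 || b + d == 0) return(1)
  supp <- max(0, s - n2):min(s, n1)
  prob <- choose(n1, supp) * choose(n2, s - supp) / choose(n1 + n2, s)
  obs <- prob[supp == a]
  switch(alternative,
         less = sum(prob[supp <= a]),
         greater = sum(prob[supp >= a]),
         two.sided = sum(prob[prob <= obs * (1 + 1e-7)]))
}

# Full double-binomial enumeration of power: every (a, c) outcome pair,
# rejection decided per table by oracle_fisher_p (cached per margin).
oracle_power <- function(n1, n2, alpha, p0, p1, alternative = "two.sided") {
  pa <- dbinom(0:n1, n1, p1)
  pc <- dbinom(0:n2, n2, p0)
  pow <- 0
  for (s in 0:(n1 + n2)) {
    supp <- max(0, s - n2):min(s, n1)
    prob <- choose(n1, supp) * choose(n2, s - supp) / choose(n1 + n2, s)
    for (i in seq_along(supp)) {
      a <- supp[i]
      pval <- switch(alternative,
                     less = sum(prob[supp <= a]),
                     greater = sum(prob[supp >= a]),
                     two.sided = sum(prob[prob <= prob[i] * (1 + 1e-7)]))
      # same boundary convention as the engine: a table whose p-value
      # equals alpha (a rational, attainable at small n) rejects
      if (pval <= alpha * (1 + 1e-9)) pow <- pow + pa[a + 1] * pc[s - a + 1]
    }
  }
  pow
}

# Random non-degenerate tables with total at most n_max, fixed RNG state.
random_tables <- function(n, n_max = 40, seed = 421) {
  set.seed(seed)
  out <- vector("list", n)
  i <- 1L
  while (i <= n) {
    cells <- as.integer(rmultinom(1, sample(4:n_max, 1), runif(4, 0.05, 1)))
    t <- contingency_table(cells[1], cells[2], cells[3], cells[4])
    if ((t$a + t$b) > 0 && (t$c + t$d) > 0 &&
        (t$a + t$c) > 0 && (t$b + t$d) > 0) {
      out[[i]] <- t
      i <- i + 1L
    }
  }
  out
}

paper_design <- function() power_spec(2000, 2000, alpha = 0.05)
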