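# Shared fixtures: tiny in-code data builders used across test files.

# A small labelled genotype table with optional missing calls.
tiny_baseline <- function(seed = 1, n_per_pop = 10, n_loci = 6, fct = 0.2) {
  gen_baselines(n_pops = 2, n_loci = n_loci, fct = fct,
                n_per_pop = n_per_pop, seed = seed)
}

# Write a genepop file from raw text lines, return the path.
genepop_file <- function(lines) {
  path <- tempfile(fileext = ".gen")
  writeLines(lines, path)
  path
}

# A deterministic cod-like life table for per-recruit tests.
toy_life_table <- function() {
  life_table(ages = 3:7,
             M = rep(0.2, 5),
             selectivity = c(0.2, 0.6, 1, 1, 1),
             weight = c(1, 2, 3.5, 5, 7),
             maturity = c(0, 0.2, 0.6, 0.9, 1))
}

# Random valid life table for property tests.
random_life_table <- function(seed) {
  set.seed(seed)
  n <- sample(4:10, 1)
  ages <- 3:(2 + n)
  life_table(ages,
             M = runif(n, 0.05, 0.4),
             selectivity = runif(n, 0.1, 1.5),
             weight = sort(runif(n, 0.5, 10)),
             maturity = sort(runif(n, 0, 1)))
}

# Exhaustive least-cost oracle: branch-and-bound over all simple paths on a
# small grid (8-neighbour moves, edge weight = mean endpoint cost x step
# length x cell size). Independent of the igraph-based implementation.
brute_force_lcp <- function(cost, cell_km, source, target) {
  nr <- nrow(cost); nc <- ncol(cost)
  best <- Inf
  visited <- matrix(FALSE, nr, nc)
  moves <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
                 dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  recurse <- function(r, c, acc) {
    if (acc >= best) return()
    if (r == target[1] && c == target[2]) { best <<- acc; return() }
    visited[r, c] <<- TRUE
    for (k in 1:8) {
      r2 <- r + moves[k, 1]; c2 <- c + moves[k, 2]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (visited[r2, c2] || is.na(cost[r2, c2])) next
      step <- if (moves[k, 1] != 0 && moves[k, 2] != 0) sqrt(2) else 1
      recurse(r2, c2, acc + (cost[r, c] + cost[r2, c2]) / 2 * step * cell_km)
    }
    visited[r, c] <<- FALSE
  }
  recurse(source[1], source[2], 0)
  best
}
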