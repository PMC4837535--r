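# Brute-force mean log deviation: explicit scalar loop, kept independent
# of the package's vectorized implementation so it can serve as an oracle.
oracle_theil <- function(p, y) {
  s <- 0
  for (i in seq_along(p)) {
    if (p[i] > 0) s <- s + p[i] * log(p[i] / y[i])
  }
  s
}

# Random strictly positive share table summing to one on both sides.
random_shares <- function(n) {
  p <- stats::rgamma(n, shape = 2) + 1e-6
  y <- stats::rgamma(n, shape = 2) + 1e-6
  tibble::tibble(unit = sprintf("u%02d", seq_len(n)),
                 p = p / sum(p), y = y / sum(y))
}

# Random single-year panel with positive populations/areas/amounts.
random_panel <- function(n, year = 2013) {
  tibble::tibble(
    unit = sprintf("u%02d", seq_len(n)),
    year = as.integer(year),
    population_10k = stats::rlnorm(n, log(3000), 0.8),
    area_10k_km2 = stats::rlnorm(n, log(15), 1),
    institutions = stats::rgamma(n, 2) * 1e4,
    personnel = stats::rgamma(n, 2) * 1e5,
    beds = stats::rgamma(n, 2) * 1e5,
    investment_100m_yuan = stats::rgamma(n, 2) * 100)
}

# Random partition of the given units into k non-empty named regions.
random_partition <- function(units, k) {
  n <- length(units)
  g <- c(seq_len(k), sample.int(k, n - k, replace = TRUE))[sample.int(n)]
  tibble::tibble(unit = units, region = sprintf("g%d", g))
}
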