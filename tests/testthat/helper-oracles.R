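# Independent oracles, coded directly from textbook formulas and kept free of
# the package's estimation internals.

# One-way ANOVA intraclass estimator with ML (n) divisors: between- and
# within-pair mean squares from sums of squares over pairs of two.
icc_anova_oracle <- function(y1, y2) {
  n <- length(y1)
  grand <- mean(c(y1, y2))
  m_between <- sum(2 * ((y1 + y2) / 2 - grand)^2) / n
  m_within <- sum((y1 - y2)^2 / 2) / n
  (m_between - m_within) / (m_between + m_within)
}

# Direct bivariate normal log-density (no package code).
dbvn_log <- function(y1, y2, mu1, mu2, v, r) {
  det <- v^2 * (1 - r^2)
  q <- ((y1 - mu1)^2 + (y2 - mu2)^2 - 2 * r * (y1 - mu1) * (y2 - mu2)) /
    (v * (1 - r^2))
  -log(2 * pi) - 0.5 * log(det) - 0.5 * q
}

# Moment estimates of (a2, c2) from sample twin correlations.
moments_oracle <- function(y) {
  rmz <- cor(y$MZ$y1, y$MZ$y2)
  rdz <- cor(y$DZ$y1, y$DZ$y2)
  c(a2 = 2 * (rmz - rdz), c2 = 2 * rdz - rmz)
}

# Exhaustive grid search of the AE likelihood: for each a2 on a 0.005 grid,
# minimize the directly-coded negative log-likelihood over mean and total
# variance with a generic optimizer.
grid_oracle_ae <- function(data, resolution = 0.005) {
  nll_at <- function(a2) {
    f <- function(par) {
      mu <- par[1]; v <- exp(par[2])
      -(sum(dbvn_log(data$MZ$y1, data$MZ$y2, mu, mu, v, a2)) +
          sum(dbvn_log(data$DZ$y1, data$DZ$y2, mu, mu, v, a2 / 2)))
    }
    optim(c(mean(c(data$MZ$y1, data$MZ$y2, data$DZ$y1, data$DZ$y2)),
            log(var(c(data$MZ$y1, data$MZ$y2, data$DZ$y1, data$DZ$y2)))),
          f, method = "Nelder-Mead", control = list(reltol = 1e-14, maxit = 2000))$value
  }
  grid <- seq(0, 0.995, by = resolution)
  min(vapply(grid, nll_at, 0))
}
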