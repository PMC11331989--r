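# Independent brute-force oracles shared across test files.

# JZS two-sample Bayes factor by dense trapezoidal quadrature on a log grid,
# written independently of the package's adaptive quadrature path.
bf_oracle_two_sample <- function(t, n1, n2, scale) {
  nu <- n1 + n2 - 2; neff <- n1 * n2 / (n1 + n2); rate <- scale^2 / 2
  g <- exp(seq(log(1e-8), log(1e6), length.out = 200000))
  dens <- sqrt(rate) / gamma(0.5) * g^(-1.5) * exp(-rate / g)
  f <- (1 + neff * g)^(-0.5) *
    (1 + t^2 / (nu * (1 + neff * g)))^(-(nu + 1) / 2) * dens
  w <- diff(g)
  num <- sum((f[-1] + f[-length(f)]) / 2 * w)
  num / (1 + t^2 / nu)^(-(nu + 1) / 2)
}
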