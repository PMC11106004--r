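# Dirichlet draw via normalized gammas; alpha entries of 0 give exact zeros
rdirichlet1 <- function(alpha) {
  g <- rep(0, length(alpha))
  pos <- alpha > 0
  g[pos] <- rgamma(sum(pos), shape = alpha[pos], rate = 1)
  if (sum(g) == 0) {
    g[pos] <- 1 / sum(pos)
  }
  g / sum(g)
}

# lognormal parameterized by arithmetic mean and sd
rlnorm_mean_sd <- function(n, mean, sd) {
  sdlog <- sqrt(log(1 + (sd / mean)^2))
  meanlog <- log(mean) - sdlog^2 / 2
  rlnorm(n, meanlog, sdlog)
}
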