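# exhaustive two-sided Mann-Whitney p-value: enumerate every assignment
# of the pooled values to the two groups (independent of wilcox.test)
mw_exact_oracle <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(length(pooled), n1)
  u_all <- apply(combs, 2, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
  mu <- n1 * length(y) / 2
  p <- if (u_obs > mu) {
    2 * mean(u_all >= u_obs)
  } else if (u_obs < mu) {
    2 * mean(u_all <= u_obs)
  } else {
    1
  }
  min(p, 1)
}
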