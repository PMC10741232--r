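# brute-force ML oracle for 2-SNP haplotype frequencies: grid over the
# 3-simplex, multinomial likelihood of the 9 two-locus genotype classes
grid_ml_oracle <- function(g, step = 0.01) {
  counts <- as.vector(table(factor(g[, 1], 0:2), factor(g[, 2], 0:2)))
  s <- seq(0, 1, step)
  grid <- expand.grid(f1 = s, f2 = s, f3 = s)
  grid <- grid[grid$f1 + grid$f2 + grid$f3 <= 1 + 1e-12, ]
  F <- cbind(grid$f1, grid$f2, grid$f3,
             pmax(0, 1 - grid$f1 - grid$f2 - grid$f3))
  # haplotypes in order (0,0), (0,1), (1,0), (1,1) of minor dosage
  hap_d <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  P <- matrix(0, nrow(F), 9)
  for (i in 1:4) for (j in 1:4) {
    d <- hap_d[i, ] + hap_d[j, ]
    col <- d[1] + 1 + 3 * d[2]         # column-major 3x3 class index
    P[, col] <- P[, col] + F[, i] * F[, j]
  }
  ll <- log(pmax(P, 1e-300)) %*% counts
  best <- which.max(ll)
  list(freqs = F[best, ], loglik = ll[best])
}
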