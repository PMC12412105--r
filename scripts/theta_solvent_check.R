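#!/usr/bin/env Rscript

# Verifies the near-theta solvent parameterization used for the tethered
# phase-separation stage: with polymer-water repulsion a_pw = 27 (against
# a_ii = 25), a free test chain should show near-ideal size scaling,
# R_g ~ N^0.5 within ~10%. Run from the repository root:
#
#   Rscript scripts/theta_solvent_check.R [a_pw]

suppressPackageStartupMessages(library(capsort))

args <- commandArgs(trailingOnly = TRUE)
a_pw <- if (length(args) >= 1) as.numeric(args[1]) else 27

rg2_chain <- function(N, a_pw, seed) {
  set.seed(seed)
  L <- c(10, 10, 10)
  n_solv <- round(3 * prod(L)) - N
  # a single free chain (compact random-walk start) in solvent, periodic box
  cx <- cumsum(c(5, rnorm(N - 1, sd = 0.4))) %% L[1]
  cy <- cumsum(c(5, rnorm(N - 1, sd = 0.4))) %% L[2]
  cz <- cumsum(c(5, rnorm(N - 1, sd = 0.4))) %% L[3]
  pos <- rbind(cbind(cx, cy, cz),
               cbind(runif(n_solv, 0, L[1]), runif(n_solv, 0, L[2]),
                     runif(n_solv, 0, L[3])))
  aij <- matrix(25, 5, 5)
  aij[2, 4] <- aij[4, 2] <- a_pw   # PNIPAM-water (1-based: type 1 x type 3)
  vel <- matrix(rnorm(3 * nrow(pos)), nrow(pos), 3)
  vel <- sweep(vel, 2, colMeans(vel))
  sys <- dpd_system(pos, vel, c(rep(1L, N), rep(3L, n_solv)),
                    rep(TRUE, nrow(pos)), L, periodic_z = TRUE, aij = aij,
                    bonds = cbind(seq_len(N - 1), 2:N))
  r <- dpd_integrate(sys, 3000, seed = seed + 1)
  sys <- r$system
  acc <- 0
  for (k in 1:6) {
    r <- dpd_integrate(sys, 400, seed = seed + 1 + k)
    sys <- r$system
    # unwrap the chain through periodic boundaries before measuring
    p <- sys$pos[1:N, ]
    for (d in 1:3) {
      steps <- diff(p[, d])
      steps <- steps - L[d] * round(steps / L[d])
      p[, d] <- cumsum(c(p[1, d], steps))
    }
    acc <- acc + mean(scale(p, scale = FALSE)^2) * 3
  }
  acc / 6
}

Ns <- c(10, 20, 40)
cat(sprintf("a_polymer-water = %g\n", a_pw))
rg <- sapply(Ns, function(N) {
  m <- mean(sapply(1:3, function(s) rg2_chain(N, a_pw, 1000 * s + N)))
  cat(sprintf("  N = %3d: <R_g^2> = %.3f\n", N, m))
  m
})
fit <- stats::lm(log(rg) ~ log(Ns))
nu <- unname(coef(fit)[2] / 2)
cat(sprintf("scaling exponent nu = %.3f (ideal 0.5; within 10%%: %s)\n",
            nu, abs(nu - 0.5) / 0.5 <= 0.1))
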