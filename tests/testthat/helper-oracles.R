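# Independent oracles used across the suite. These deliberately avoid the
# package's own computation paths: quadrature instead of the closed-form
# integral, triple-loop superposition instead of shift-accumulate
# convolution, pairwise-comparison enumeration instead of the rank-based
# Mann-Whitney statistic.

# TIA by adaptive quadrature of the fitted model over 0-2000 h plus the
# analytic tail of the remaining exponentials.
tia_by_quadrature <- function(fit, upper = 2000) {
  f <- function(t) vapply(t, function(tt)
    sum(fit$amplitudes * exp(-fit$lambdas * tt)), numeric(1))
  q <- stats::integrate(f, 0, upper, rel.tol = 1e-10, abs.tol = 0,
                        subdivisions = 500L)$value
  q + sum(fit$amplitudes * exp(-fit$lambdas * upper) / fit$lambdas)
}

# Brute-force voxel dose-rate superposition: loop over every source voxel
# and every kernel element, accumulate at the target, then apply the
# density scaling.
brute_force_dose_rate <- function(activity, density, kernel) {
  a <- activity$data
  s <- kernel$s_values
  d <- dim(a); ds <- dim(s); ctr <- (ds + 1L) %/% 2L
  out <- array(0, d)
  src <- which(a != 0, arr.ind = TRUE)
  for (r in seq_len(nrow(src))) {
    for (ii in seq_len(ds[1])) for (jj in seq_len(ds[2]))
      for (kk in seq_len(ds[3])) {
        if (s[ii, jj, kk] == 0) next
        tgt <- src[r, ] + c(ii, jj, kk) - ctr
        if (all(tgt >= 1L) && all(tgt <= d))
          out[tgt[1], tgt[2], tgt[3]] <-
            out[tgt[1], tgt[2], tgt[3]] +
            a[src[r, 1], src[r, 2], src[r, 3]] * s[ii, jj, kk]
      }
  }
  ifelse(density$data > 0, out / density$data, 0)
}

# Exact two-sided Mann-Whitney p by full enumeration, with U computed from
# pairwise comparisons (greater = 1, tie = 1/2) rather than midranks.
mw_enumeration_oracle <- function(x, y) {
  U_of <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  pooled <- c(x, y)
  n <- length(pooled); nx <- length(x)
  cmb <- utils::combn(n, nx)
  Us <- apply(cmb, 2, function(ix) U_of(pooled[ix], pooled[-ix]))
  U <- U_of(x, y)
  eps <- 1e-9
  list(U = U,
       p = min(1, 2 * min(mean(Us <= U + eps), mean(Us >= U - eps))))
}

# A normalised 3x3x3 "spread" kernel satisfying energy closure, for tests
# that need a non-trivial kernel support.
spread_kernel <- function(spacing_mm, delta = energy_delta()) {
  w <- array(0, c(3, 3, 3))
  w[2, 2, 2] <- 6
  w[c(1, 3), 2, 2] <- 1; w[2, c(1, 3), 2] <- 1; w[2, 2, c(1, 3)] <- 1
  w <- w / sum(w)
  ref_mass <- prod(rep(spacing_mm, length.out = 3)) / 1000
  voxel_kernel(w * delta / ref_mass, spacing_mm, delta)
}

# A tiny two-organ phantom used by several quantification tests.
small_phantom <- function(conc = c(0.2, 0.05), t_eff = c(24, 10)) {
  make_phantom(phantom_spec(
    shape = c(20, 20, 20), spacing_mm = 4,
    organs = list(
      phantom_organ("neck uptake", "sphere", c(28, 28, 28), 10,
                    conc[1], t_eff[1]),
      phantom_organ("liver", "sphere", c(56, 56, 56), 14,
                    conc[2], t_eff[2], density_g_per_ml = 1.05))))
}
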