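# Independent oracles used across the test files, plus a cache for the
# expensive traveling-wave solutions shared by several tests.

# Closed-form annular Poiseuille profile under axial pressure gradient g:
# w(r) = g r^2 / (4 mu) + C1 log r + C2 with no-slip at r1, r2.
annulus_profile_exact <- function(r1, r2, mu, g) {
  a <- g / (4 * mu)
  C <- solve(rbind(c(log(r1), 1), c(log(r2), 1)),
             c(-a * r1^2, -a * r2^2))
  function(r) a * r^2 + C[1] * log(r) + C[2]
}

# Long-wavelength (lubrication) oracle for peristaltic pumping in a
# periodic annulus: wave-frame flux from the periodic-pressure constraint,
# then the lab centerline velocity over one wavelength.  Independent of the
# finite-element path: uses only the closed-form annular resistance and
# profile plus quadrature.
lub_peristalsis_oracle <- function(phi0, R1 = 30e-6, R2 = 70e-6, mu = 1e-3,
                                   cw = 1, f = 8.67, n = 4096L) {
  lam <- cw / f
  xi <- (seq_len(n) - 1) / n * lam
  r1 <- R1 * (1 + phi0 * sin(2 * pi * xi / lam))
  A <- pi * (R2^2 - r1^2)
  Rf <- annular_resistance(r1, R2, mu)
  Fw <- -cw * sum(Rf * A) / sum(Rf)
  Qlab <- Fw + cw * A
  r0 <- (R1 + R2) / 2
  kf <- vapply(r1, function(ri) {
    w <- annulus_profile_exact(ri, R2, mu, -1)
    w(r0) * annular_resistance(ri, R2, mu)
  }, 0)
  ucl <- Qlab * kf
  list(xi = xi, ucl = ucl,
       mean_eulerian = mean(ucl),
       oscillatory = diff(range(ucl)),
       Q_mean = mean(Qlab))
}

# Shared cache of traveling-wave solutions (several tests reuse the same
# configurations; solving once keeps the suite fast).
.tw_cache <- new.env(parent = emptyenv())
cached_wave_solution <- function(phi0, m, reverse = FALSE) {
  key <- sprintf("phi%g_m%d_%d", phi0, m, as.integer(reverse))
  if (is.null(.tw_cache[[key]]))
    .tw_cache[[key]] <- solve_traveling_wave(wave_spec(phi0), m = m,
                                             reverse = reverse)
  .tw_cache[[key]]
}

cached_wave_metrics <- function(phi0, m, reverse = FALSE) {
  key <- sprintf("met_phi%g_m%d_%d", phi0, m, as.integer(reverse))
  if (is.null(.tw_cache[[key]]))
    .tw_cache[[key]] <- wave_frame_metrics(cached_wave_solution(phi0, m, reverse))
  .tw_cache[[key]]
}
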