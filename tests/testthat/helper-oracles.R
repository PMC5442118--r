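# Independent dense grid-search least-squares oracles for the relaxometry
# fits. These enumerate the parameter space (with successive zoom stages of
# the same enumeration) and never reuse the package's profiled solvers.

t2_grid_oracle <- function(signal, te, t2_range = c(1, 300), stages = 3L) {
  s0_range <- c(1e-6, 2 * max(signal))
  best <- c(NA, NA)
  for (st in seq_len(stages)) {
    t2g <- seq(t2_range[1], t2_range[2], length.out = 401)
    s0g <- seq(s0_range[1], s0_range[2], length.out = 301)
    rss_best <- Inf
    for (t2 in t2g) {
      e <- exp(-te / t2)
      # RSS(S0) = sum(s^2) - 2 S0 sum(s e) + S0^2 sum(e^2), enumerated over S0
      rss <- sum(signal^2) - 2 * s0g * sum(signal * e) + s0g^2 * sum(e * e)
      i <- which.min(rss)
      if (rss[i] < rss_best) {
        rss_best <- rss[i]
        best <- c(s0g[i], t2)
      }
    }
    dt <- diff(t2_range) / 400; ds <- diff(s0_range) / 300
    t2_range <- c(max(t2_range[1], best[2] - 3 * dt), best[2] + 3 * dt)
    s0_range <- c(max(1e-6, best[1] - 3 * ds), best[1] + 3 * ds)
  }
  list(S0 = best[1], T2_ms = best[2])
}

ll_grid_oracle <- function(signal, ti, tau_range = c(0.05, 5), stages = 3L) {
  smax <- max(abs(signal))
  a_range <- c(1e-6, 2 * smax)
  b_range <- c(1e-6, 4 * smax)
  n <- length(signal)
  sy <- sum(signal); syy <- sum(signal^2)
  best <- c(NA, NA, NA)
  for (st in seq_len(stages)) {
    taug <- seq(tau_range[1], tau_range[2], length.out = 81)
    ag <- seq(a_range[1], a_range[2], length.out = 81)
    bg <- seq(b_range[1], b_range[2], length.out = 81)
    rss_best <- Inf
    for (tau in taug) {
      e <- exp(-ti / tau)
      se <- sum(e); see <- sum(e * e); sye <- sum(signal * e)
      # RSS(A,B) from sufficient statistics, enumerated on the A x B grid
      rss <- syy + outer(n * ag^2 - 2 * ag * sy, bg^2 * see + 2 * bg * sye, `+`) -
        2 * outer(ag, bg) * se
      i <- arrayInd(which.min(rss), dim(rss))
      if (rss[i] < rss_best) {
        rss_best <- rss[i[1], i[2]]
        best <- c(ag[i[1]], bg[i[2]], tau)
      }
    }
    da <- diff(a_range) / 80; db <- diff(b_range) / 80; dt <- diff(tau_range) / 80
    a_range <- c(max(1e-6, best[1] - 3 * da), best[1] + 3 * da)
    b_range <- c(max(1e-6, best[2] - 3 * db), best[2] + 3 * db)
    tau_range <- c(max(0.05, best[3] - 3 * dt), best[3] + 3 * dt)
  }
  list(A = best[1], B = best[2], T1star_s = best[3])
}

# exhaustive lattice scan of the annulus, independent of make_geometry
annulus_count_oracle <- function(m, cx, cy, r_inner, r_outer) {
  n <- 0L
  for (x in seq_len(m)) {
    for (y in seq_len(m)) {
      r <- sqrt((x - cx)^2 + (y - cy)^2)
      if (r >= r_inner && r < r_outer) n <- n + 1L
    }
  }
  n
}
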