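# shared fixture builders (all data is generated in code)

paper_grid <- c(0.03, 0.1, 0.3, 1, 3, 10, 30, 100)

noiseless_screen <- function(top, bottom, hill, ic50, ...) {
  screen_scenario(data.frame(top = top, bottom = bottom, hill = hill,
                             ic50 = ic50),
                  noise_sd = 0, ...)
}

# a small two-arm course from explicit day-0 / day-t medians (1 mouse/arm)
two_point_course <- function(C0, Ct, T0, Tt, day = 21) {
  tumor_course(data.frame(
    mouse_id = rep(c("C1", "T1"), each = 2),
    arm = rep(c("control", "treated"), each = 2),
    day = c(0, day, 0, day),
    volume_mm3 = c(C0, Ct, T0, Tt)))
}

# counts with planted two-group effects on the first `n_planted` features
planted_counts <- function(n_planted = 20, n_features = 2000, log2fc = 3,
                           seed = 1, ...) {
  gen_counts(count_scenario(
    n_features = n_features,
    planted_idx = seq_len(n_planted),
    planted_log2fc = rep(c(1, -1), length.out = n_planted) * log2fc,
    seed = seed, ...))
}

# --- independent oracles -------------------------------------------------

# two-sided Fisher p by full hypergeometric enumeration over the margins
fisher_enum_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  k <- max(0, c1 - r2):min(r1, c1)
  pk <- dhyper(k, r1, r2, c1)
  p_obs <- dhyper(a, r1, r2, c1)
  sum(pk[pk <= p_obs * (1 + 1e-7)])
}

# BH step-up adjustment by direct enumeration of the definition
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- rev(cummin(rev(p[o] * m / seq_len(m))))
  pmin(1, adj)[order(o)]
}

# signed KS statistic by scanning every position of the profile; deviations
# are compared as integer numerators over the common denominator t*n so
# exact ties resolve the same way regardless of evaluation order
ks_scan_oracle <- function(tags, profile) {
  n <- length(profile)
  t <- length(tags)
  r <- match(tags, profile)
  nums <- vapply(0:n, function(i) sum(r <= i) * n - i * t, numeric(1))
  dp <- max(0, nums); dm <- max(0, -nums)
  if (dp > dm) dp / (t * n) else if (dm > dp) -dm / (t * n) else 0
}

# full connectivity recomputation (single-instance profiles)
connectivity_oracle <- function(query, profiles) {
  raw <- vapply(profiles, function(prof) {
    a <- ks_scan_oracle(query$up, prof)
    b <- ks_scan_oracle(query$down, prof)
    if (sign(a) == sign(b)) 0 else (a - b) / 2
  }, numeric(1))
  100 * raw / max(abs(raw))
}
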