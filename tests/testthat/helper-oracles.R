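# Independent oracles, deliberately written as naive loops so they share no
# code path with the package implementations.

# Straight-summation VMR oracle: trapezoid by explicit loop, per-event
# pre-window mean background, session-minimum normalization, per-pressure
# means.
oracle_score_set <- function(samples, fs, events) {
  trap <- function(v, t) {
    s <- 0
    for (k in 2:length(v)) s <- s + (t[k] - t[k - 1]) * (v[k] + v[k - 1]) / 2
    s
  }
  win <- function(t0, t1) {
    i0 <- round(t0 * fs) + 1
    i1 <- round(t1 * fs) + 1
    list(v = samples[i0:i1], t = (seq(i0, i1) - 1) / fs)
  }
  n <- nrow(events)
  stim <- pre <- numeric(n)
  for (i in seq_len(n)) {
    pw <- win(events$onset_s[i] - events$pre_interval_s[i], events$onset_s[i])
    sw <- win(events$onset_s[i], events$onset_s[i] + events$duration_s[i])
    bg <- mean(pw$v)
    stim[i] <- trap(abs(sw$v - bg), sw$t)
    pre[i] <- trap(abs(pw$v - bg), pw$t)
  }
  keep <- !events$is_sensitization
  nrm <- min(pre[keep])
  vmr <- stim / nrm
  pressures <- sort(unique(events$pressure_mmHg[keep]))
  means <- numeric(0)
  for (p in pressures) {
    sel <- keep & events$pressure_mmHg == p
    means <- c(means, mean(vmr[sel]))
  }
  list(vmr = vmr[keep], per_pressure = setNames(means, pressures), nrm = nrm)
}

# Brute-force balanced two-way decomposition via explicit level loops.
oracle_two_way <- function(y, a, b) {
  a <- as.character(a); b <- as.character(b)
  la <- unique(a); lb <- unique(b)
  grand <- mean(y)
  ss_a <- 0
  for (i in la) ss_a <- ss_a + sum(a == i) * (mean(y[a == i]) - grand)^2
  ss_b <- 0
  for (j in lb) ss_b <- ss_b + sum(b == j) * (mean(y[b == j]) - grand)^2
  ss_ab <- 0
  ss_e <- 0
  for (i in la) for (j in lb) {
    sel <- a == i & b == j
    cm <- mean(y[sel])
    ss_ab <- ss_ab + sum(sel) *
      (cm - mean(y[a == i]) - mean(y[b == j]) + grand)^2
    ss_e <- ss_e + sum((y[sel] - cm)^2)
  }
  ni <- length(la); nj <- length(lb); n <- length(y) / (ni * nj)
  df <- c(ni - 1, nj - 1, (ni - 1) * (nj - 1), ni * nj * (n - 1))
  ss <- c(ss_a, ss_b, ss_ab, ss_e)
  list(ss = ss, df = df, f = (ss[1:3] / df[1:3]) / (ss[4] / df[4]))
}

# Study parameter sets used across tests: the package defaults at the 25 Hz
# study rate, and the effects-off null.
study_params <- function(seed = 1, sampling_rate = 25, ...) {
  sim_params(seed = seed, sampling_rate = sampling_rate, ...)
}
null_study_params <- function(seed = 1, sampling_rate = 25, ...) {
  sim_params_null(seed = seed, sampling_rate = sampling_rate, ...)
}
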