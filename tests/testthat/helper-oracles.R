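# Independent oracles and fixture builders used across the suite.

# circular mean in degrees, independent implementation
circ_mean_deg <- function(phases_rad) {
  (atan2(mean(sin(phases_rad)), mean(cos(phases_rad))) * 180 / pi) %% 360
}

# von Mises sampler (Best & Fisher 1979 rejection scheme)
rvonmises <- function(n, mu, kappa) {
  if (kappa == 0) return(runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 0L
  while (i < n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
      i <- i + 1L
      out[i] <- (mu + sign(u[3] - 0.5) * acos(f)) %% (2 * pi)
    }
  }
  out
}

# pulse train of n 1-s stimulation trains at f Hz, 50% duty, trains
# separated by `gap` s of darkness (the pairing structure modulation
# statistics assume)
build_train_stim <- function(n_trains, f = 40, train_len = 1, gap = 1,
                             duty = 0.5, t_start = 2) {
  onsets <- unlist(lapply(seq_len(n_trains), function(k) {
    start <- t_start + (k - 1) * (train_len + gap)
    start + (seq_len(round(f * train_len)) - 1L) / f
  }))
  pulse_train(onsets, onsets + duty / f, freq = f, duty = duty)
}

# brute-force sums-of-squares two-way ANOVA without replication
# (condition x day table), from the definitional formulas
ss_anova_norep <- function(y) {   # y: matrix cond x day
  g <- mean(y)
  ssc <- ncol(y) * sum((rowMeans(y) - g)^2)
  ssd <- nrow(y) * sum((colMeans(y) - g)^2)
  sst <- sum((y - g)^2)
  sse <- sst - ssc - ssd
  dfc <- nrow(y) - 1; dfd <- ncol(y) - 1; dfe <- dfc * dfd
  list(F_cond = (ssc / dfc) / (sse / dfe),
       F_day = (ssd / dfd) / (sse / dfe),
       df = c(dfc, dfd, dfe))
}

# brute-force within-subject two-way repeated-measures ANOVA
# y[c, d, s]: each effect tested against its interaction with subject
ss_anova_rm <- function(y) {
  C <- dim(y)[1]; D <- dim(y)[2]; S <- dim(y)[3]
  g <- mean(y)
  m_c <- apply(y, 1, mean); m_d <- apply(y, 2, mean); m_s <- apply(y, 3, mean)
  m_cd <- apply(y, c(1, 2), mean)
  m_cs <- apply(y, c(1, 3), mean)
  m_ds <- apply(y, c(2, 3), mean)
  ss_c <- D * S * sum((m_c - g)^2)
  ss_d <- C * S * sum((m_d - g)^2)
  ss_cd <- S * sum((m_cd - outer(m_c, rep(1, D)) - outer(rep(1, C), m_d) + g)^2)
  ss_cs <- D * sum((m_cs - outer(m_c, rep(1, S)) - outer(rep(1, C), m_s) + g)^2)
  ss_ds <- C * sum((m_ds - outer(m_d, rep(1, S)) - outer(rep(1, D), m_s) + g)^2)
  resid <- y
  for (ci in 1:C) for (di in 1:D) for (si in 1:S)
    resid[ci, di, si] <- y[ci, di, si] - m_cd[ci, di] - m_cs[ci, si] -
      m_ds[di, si] + m_c[ci] + m_d[di] + m_s[si] - g
  ss_cds <- sum(resid^2)
  list(F_cond = (ss_c / (C - 1)) / (ss_cs / ((C - 1) * (S - 1))),
       F_day = (ss_d / (D - 1)) / (ss_ds / ((D - 1) * (S - 1))),
       F_int = (ss_cd / ((C - 1) * (D - 1))) /
         (ss_cds / ((C - 1) * (D - 1) * (S - 1))))
}

# a small randomized-but-valid session for round-trip property tests
random_session <- function(seed) {
  withr::with_seed(seed, {
    stim <- make_pulse_train(sample(c(5, 10, 20, 30, 40), 1), 0.5, 4)
    sig <- continuous_signal(rnorm(400), rate = 100, region = "LHb")
    spk <- lapply(seq_len(sample(1:3, 1)), function(i)
      spike_train(sort(runif(sample(5:40, 1), 0, 4)),
                  unit_id = paste0("u", i), region = "VP"))
    blocks <- trial_blocks(c("S+A", "S-A"), c(0, 2), c(1.5, 3.5),
                           opto = c(TRUE, FALSE))
    ev <- event_series(presses = sort(runif(10, 0, 4)),
                       rewards = sort(runif(3, 0, 4)))
    session(signals = list(sig), spikes = spk, stim = list(stim),
            blocks = blocks, events = ev,
            metadata = list(subject = "r1", day = 1, schedule = "VI30"))
  })
}
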