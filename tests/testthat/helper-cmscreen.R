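# Build a recording from a pressure vector on a uniform grid.
uniform_rec <- function(pressure, rate = 120, shape = "spiral",
                        id = "T1", group = NULL) {
  n <- length(pressure)
  pen_recording(t = (seq_len(n) - 1) / rate, x = seq_len(n),
                y = rep(0, n), pressure = pressure,
                participant_id = id, shape = shape, group = group)
}

# Independent brute-force SPARC oracle: direct DFT by explicit summation,
# explicit threshold scan for the cutoff, explicit polyline segment sum.
# Shares no code with cmscreen::sparc().
sparc_oracle <- function(signal, rate, pad_level = 4, fc_max = 10,
                         amp_threshold = 0.05, freq_normalized = FALSE,
                         mode = "pressure_derivative") {
  if (mode == "pressure_derivative") {
    signal <- (signal[-1] - signal[-length(signal)]) * rate
    if (all(signal == 0)) return(0)
  }
  N <- length(signal)
  nfft <- 2^(ceiling(log2(N)) + pad_level)
  ks <- 0:(nfft / 2)
  mag <- vapply(ks, function(k) {
    Mod(sum(signal * exp(-2i * pi * k * (0:(N - 1)) / nfft)))
  }, numeric(1))
  freq <- ks * rate / nfft
  vhat <- mag / mag[1]
  keep <- which(freq <= fc_max)
  vhat <- vhat[keep]; freq <- freq[keep]
  kcut <- 1
  for (j in seq_along(vhat)) if (vhat[j] >= amp_threshold) kcut <- j
  if (kcut < 2) return(0)
  vhat <- vhat[1:kcut]; freq <- freq[1:kcut]
  if (freq_normalized) freq <- freq / freq[kcut]
  total <- 0
  for (j in 2:kcut) {
    total <- total + sqrt((freq[j] - freq[j - 1])^2 +
                            (vhat[j] - vhat[j - 1])^2)
  }
  -total
}

# A small labeled feature table for screen-module unit tests.
toy_features <- function(n0 = 6, n1 = 5, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (g in c("nonCM", "CM")) {
    n <- if (g == "nonCM") n0 else n1
    shift <- if (g == "nonCM") 0 else -0.5
    for (i in seq_len(n)) {
      pid <- sprintf("%s%02d", if (g == "nonCM") "N" else "C", i)
      for (s in c("spiral", "square", "triangular")) {
        rows[[length(rows) + 1]] <- data.frame(
          participant_id = pid, group = g, shape = s,
          DT = exp(rnorm(1, log(6), 0.2)),
          AP = exp(rnorm(1, log(1.5) + shift, 0.2)),
          SP = -60 + rnorm(1, 10 * shift, 8))
      }
    }
  }
  do.call(rbind, rows)
}
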