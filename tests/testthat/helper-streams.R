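# Shared fixtures: hand-constructed photon streams and independent
# brute-force oracles used across the suite.

# Wrap raw photon vectors into the photon_stream container used by the
# burst-processing functions. Times in seconds.
make_stream <- function(t_s, channel, period, nanotime = NULL,
                        clock_rate = 1e8, duration = max(t_s) + 0.01,
                        background_rate = c(DD = 0, DA = 0, AA = 0)) {
  o <- order(t_s)
  if (is.null(nanotime)) nanotime <- rep(0, length(t_s))
  acq <- acquisition_settings(duration = duration,
                              background_rate = background_rate,
                              clock_rate = clock_rate)
  structure(list(
    photons = data.frame(timestamp = round(t_s[o] * clock_rate),
                         channel = channel[o], period = period[o],
                         nanotime = nanotime[o],
                         truth_burst = rep(NA_integer_, length(t_s)),
                         stringsAsFactors = FALSE),
    clock_rate = clock_rate, settings = acq, truth = NULL),
    class = "photon_stream")
}

# A single-row burst table covering photons i1..i2 of a stream.
burst_row <- function(stream, i1, i2) {
  t <- stream$photons$timestamp
  data.frame(i_start = i1, i_stop = i2, start_tick = t[i1],
             stop_tick = t[i2], n_photons = i2 - i1 + 1L,
             duration_ms = (t[i2] - t[i1]) / stream$clock_rate * 1000)
}

# Brute-force burst oracle: tests every m-photon window directly, marks
# covered photons, and splits maximal runs. Independent of find_bursts.
brute_force_bursts <- function(t, m, T_ticks, min_photons) {
  n <- length(t)
  cover <- logical(n)
  for (i in seq_len(max(n - m + 1L, 0L))) {
    if (t[i + m - 1L] - t[i] <= T_ticks) cover[i:(i + m - 1L)] <- TRUE
  }
  r <- rle(cover)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_photons
  data.frame(i_start = starts[keep], i_stop = ends[keep])
}

# Monte-Carlo PDA oracle: sample bursts directly from the state model and
# histogram the apparent efficiencies. Independent of the quadrature path.
mc_pda_histogram <- function(n_mc, burst_sizes, fractions, centers, widths,
                             R0, breaks, max_size = 250) {
  sizes <- pmin(burst_sizes, max_size)
  N <- sample(sizes, n_mc, replace = TRUE)
  s <- sample(seq_along(fractions), n_mc, replace = TRUE, prob = fractions)
  R <- pmax(stats::rnorm(n_mc, centers[s], widths[s]), 1e-2)
  E <- 1 / (1 + (R / R0)^6)
  a <- stats::rbinom(n_mc, N, E)
  tabulate(findInterval(a / N, breaks, rightmost.closed = TRUE),
           length(breaks) - 1L)
}

# Naive O(n^2) kernel-sum oracle for the 2CDE scores.
naive_kde <- function(t_eval, t_src, tau) {
  vapply(t_eval, function(ti) sum(exp(-abs(ti - t_src) / tau)), 0)
}

naive_alex_2cde <- function(t_dex, t_aex, tau) {
  nb_aex <- (1 + 2 / length(t_aex)) * (naive_kde(t_aex, t_aex, tau) - 1)
  nb_dex <- (1 + 2 / length(t_dex)) * (naive_kde(t_dex, t_dex, tau) - 1)
  br_da <- sum((naive_kde(t_aex, t_dex, tau) / nb_aex)[nb_aex > 0]) /
    length(t_dex)
  br_ad <- sum((naive_kde(t_dex, t_aex, tau) / nb_dex)[nb_dex > 0]) /
    length(t_aex)
  max(100 - 50 * (br_da + br_ad), 0)
}
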