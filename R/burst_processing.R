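# Reduction of a photon stream to a filtered table of per-burst FRET
# efficiencies and stoichiometries: all-photon sliding-window burst search,
# ALEX correction algebra, kernel-density (2CDE) and burst-asymmetry
# filtering, species sorting, and FRET histogram construction.

#' Burst-search parameters (all-photon sliding window)
#'
#' A photon belongs to a burst when it sits inside a window of `m`
#' consecutive photons spanning at most `T_us` microseconds; maximal runs of
#' such photons form candidate bursts, kept when they contain at least
#' `min_photons` photons.
#'
#' @param m Window size in photons (>= 2).
#' @param T_us Window duration in microseconds (> 0).
#' @param min_photons Minimum total photons per burst (>= m).
#' @return Object of class `burst_search_params`.
#' @export
burst_search_params <- function(m = 10, T_us = 500, min_photons = 50) {
  if (m < 2) stop("m must be >= 2")
  if (T_us <= 0) stop("T_us must be > 0")
  if (min_photons < m) stop("min_photons must be >= m")
  structure(list(m = m, T_us = T_us, min_photons = min_photons),
            class = "burst_search_params")
}

#' Correction constants for FRET efficiency calculation
#'
#' @param gamma Detection-efficiency ratio (> 0).
#' @param alpha Donor leakage into the acceptor channel.
#' @param delta Direct acceptor excitation under donor excitation.
#' @param background_rate Named per-class background rates in Hz
#'   (`DD`, `DA`, `AA`); `NULL` to estimate from inter-burst photons.
#' @param R0 Foerster radius (nm).
#' @param tau_D0 Unquenched donor lifetime (ns).
#' @return Object of class `correction_set`.
#' @export
correction_set <- function(gamma = 1, alpha = 0, delta = 0,
                           background_rate = NULL, R0 = 5.5, tau_D0 = 4) {
  if (gamma <= 0) stop("gamma must be > 0")
  if (alpha < 0 || delta < 0) stop("alpha/delta must be >= 0")
  if (!is.null(background_rate)) {
    if (any(background_rate < 0)) stop("background rates must be >= 0")
    stopifnot(all(c("DD", "DA", "AA") %in% names(background_rate)))
  }
  structure(list(gamma = gamma, alpha = alpha, delta = delta,
                 background_rate = background_rate, R0 = R0,
                 tau_D0 = tau_D0),
            class = "correction_set")
}

#' All-photon sliding-window burst search
#'
#' @param stream A `photon_stream`.
#' @param params [burst_search_params()].
#' @return data.frame of non-overlapping, time-ordered bursts with columns
#'   `i_start`, `i_stop` (photon indices, inclusive), `start_tick`,
#'   `stop_tick`, `n_photons`, `duration_ms`. Empty stream gives zero rows.
#' @export
find_bursts <- function(stream, params = burst_search_params()) {
  stopifnot(inherits(stream, "photon_stream"))
  t <- stream$photons$timestamp
  n <- length(t)
  empty <- data.frame(i_start = integer(0), i_stop = integer(0),
                      start_tick = numeric(0), stop_tick = numeric(0),
                      n_photons = integer(0), duration_ms = numeric(0))
  if (n < params$m) return(empty)
  if (is.unsorted(t)) stop("photon stream must be time-ordered")
  T_ticks <- params$T_us * 1e-6 * stream$clock_rate
  m <- params$m
  ok <- which(t[m:n] - t[1:(n - m + 1)] <= T_ticks)
  if (length(ok) == 0L) return(empty)
  # coverage: photon i is in a burst if any qualifying window contains it
  inc <- integer(n + 1L)
  inc[ok] <- inc[ok] + 1L
  inc[ok + m] <- inc[ok + m] - 1L
  cover <- cumsum(inc)[seq_len(n)] > 0L
  r <- rle(cover)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= params$min_photons
  i1 <- starts[keep]; i2 <- ends[keep]
  data.frame(i_start = i1, i_stop = i2,
             start_tick = t[i1], stop_tick = t[i2],
             n_photons = i2 - i1 + 1L,
             duration_ms = (t[i2] - t[i1]) / stream$clock_rate * 1000)
}

#' Estimate per-class background rates from inter-burst photons
#'
#' Counts photons outside all bursts in each ALEX class and divides by the
#' inter-burst observation time; background is treated as stationary.
#'
#' @param stream A `photon_stream`.
#' @param bursts Burst table from [find_bursts()].
#' @return Named numeric vector of rates (Hz) for classes `DD`, `DA`, `AA`.
#' @export
estimate_background <- function(stream, bursts) {
  ph <- stream$photons
  in_burst <- rep(FALSE, nrow(ph))
  for (b in seq_len(nrow(bursts))) {
    in_burst[bursts$i_start[b]:bursts$i_stop[b]] <- TRUE
  }
  free <- ph[!in_burst, ]
  t_total <- stream$settings$duration
  t_burst <- sum(bursts$duration_ms) / 1000
  t_free <- max(t_total - t_burst, 1e-9)
  c(DD = sum(free$period == "Dex" & free$channel == "D") / t_free,
    DA = sum(free$period == "Dex" & free$channel == "A") / t_free,
    AA = sum(free$period == "Aex" & free$channel == "A") / t_free)
}

# kernel density of photons at `times_y` evaluated at `times_x`; exponential
# kernel with decay tau (same units as the timestamps)
.kde_at <- function(times_x, times_y, tau) {
  if (length(times_y) == 0L) return(numeric(length(times_x)))
  colSums(exp(-abs(outer(times_y, times_x, "-")) / tau))
}

# no-burden KDE: excludes the photon itself, with the (1 + 2/N) small-N
# correction of the 2CDE method
.nbkde_self <- function(times, tau) {
  n <- length(times)
  (1 + 2 / n) * (.kde_at(times, times, tau) - 1)
}

#' ALEX-2CDE burst score
#'
#' Kernel-density brightness-ratio score detecting bursts whose donor- and
#' acceptor-excitation photons are not homogeneously interleaved (coincident
#' molecules, mid-burst bleaching). A homogeneous burst scores near 0;
#' heterogeneous bursts score high (up to ~100).
#'
#' @param t_dex,t_aex Timestamps of the burst's donor-excitation and
#'   acceptor-excitation photons (clock ticks).
#' @param tau_ticks Kernel decay time in clock ticks.
#' @return Finite non-negative score; 0 by convention when either
#'   excitation class has fewer than 2 photons.
#' @export
alex_2cde <- function(t_dex, t_aex, tau_ticks) {
  stopifnot(tau_ticks > 0)
  if (length(t_dex) < 2L || length(t_aex) < 2L) return(0)
  nb_aex <- .nbkde_self(t_aex, tau_ticks)
  nb_dex <- .nbkde_self(t_dex, tau_ticks)
  ok_a <- nb_aex > 0
  ok_d <- nb_dex > 0
  if (!any(ok_a) || !any(ok_d)) return(0)
  br_da <- sum(.kde_at(t_aex, t_dex, tau_ticks)[ok_a] / nb_aex[ok_a]) /
    length(t_dex)
  br_ad <- sum(.kde_at(t_dex, t_aex, tau_ticks)[ok_d] / nb_dex[ok_d]) /
    length(t_aex)
  max(100 - 50 * (br_da + br_ad), 0)
}

#' FRET-2CDE burst score
#'
#' Kernel-density score over the donor-excitation photons only, sensitive to
#' FRET dynamics or acceptor loss within a burst. Static homogeneous bursts
#' score near the ideal value of 10.
#'
#' @param t_dd,t_da Timestamps of donor-excitation photons in the donor and
#'   acceptor channels.
#' @param tau_ticks Kernel decay time in clock ticks.
#' @return Finite score; 10 by convention when either channel has fewer
#'   than 2 photons.
#' @export
fret_2cde <- function(t_dd, t_da, tau_ticks) {
  stopifnot(tau_ticks > 0)
  if (length(t_dd) < 2L || length(t_da) < 2L) return(10)
  kde_a_at_d <- .kde_at(t_dd, t_da, tau_ticks)
  kde_d_at_a <- .kde_at(t_da, t_dd, tau_ticks)
  nb_d <- .nbkde_self(t_dd, tau_ticks)
  nb_a <- .nbkde_self(t_da, tau_ticks)
  e_d <- mean(kde_a_at_d / pmax(kde_a_at_d + nb_d, .Machine$double.eps))
  oe_a <- mean(kde_d_at_a / pmax(kde_d_at_a + nb_a, .Machine$double.eps))
  110 - 100 * (e_d + oe_a)
}

#' Burst asymmetry statistic
#'
#' Signed difference between the mean timestamps of the acceptor- and
#' donor-channel donor-excitation photons, normalized by the burst duration.
#' Mid-burst acceptor photobleaching shifts acceptor photons early, giving a
#' negative value; reversing time flips the sign.
#'
#' @param t_dd,t_da Timestamps of the two donor-excitation photon classes.
#' @param t_start,t_stop Burst limits (ticks).
#' @return Statistic in [-1, 1], or `NA` when either class is empty.
#' @export
asymmetry_statistic <- function(t_dd, t_da, t_start, t_stop) {
  if (length(t_dd) == 0L || length(t_da) == 0L) return(NA_real_)
  dur <- t_stop - t_start
  if (dur <= 0) return(0)
  (mean(t_da) - mean(t_dd)) / dur
}

#' Compute per-burst ALEX metrics for all bursts of a stream
#'
#' For every burst: raw and background-corrected photon counts in the three
#' ALEX classes, proximity ratio, corrected FRET efficiency
#' `E = (F_DA - a F_DD - d F_AA) / (g F_DD + F_DA - a F_DD - d F_AA)`,
#' stoichiometry `S = (F_DD + F_DA) / (F_DD + F_DA + F_AA)`, ALEX-2CDE and
#' FRET-2CDE scores, the asymmetry statistic, and (when nanotimes are
#' present) the relative donor lifetime.
#'
#' @param stream A `photon_stream`.
#' @param bursts Burst table from [find_bursts()].
#' @param corr [correction_set()]; a `NULL` `background_rate` is estimated
#'   with [estimate_background()].
#' @param kde_tau_us Kernel decay time for the 2CDE scores (microseconds).
#' @param lifetime_min_photons Minimum donor-channel photons for a per-burst
#'   lifetime estimate.
#' @return data.frame (class `burst_metrics`), one row per burst, with the
#'   columns documented above plus `undefined` flagging bursts whose
#'   denominators vanished; background rates and settings are attached as
#'   attributes.
#' @export
burst_metrics <- function(stream, bursts, corr = correction_set(),
                          kde_tau_us = 100, lifetime_min_photons = 20) {
  stopifnot(inherits(stream, "photon_stream"))
  nb <- nrow(bursts)
  bg <- corr$background_rate
  if (is.null(bg)) bg <- estimate_background(stream, bursts)
  t <- stream$photons$timestamp
  ch <- stream$photons$channel
  pe <- stream$photons$period
  nt <- stream$photons$nanotime
  tb <- stream$photons$truth_burst
  tau_ticks <- kde_tau_us * 1e-6 * stream$clock_rate
  clock <- stream$clock_rate

  out <- vector("list", nb)
  for (b in seq_len(nb)) {
    idx <- bursts$i_start[b]:bursts$i_stop[b]
    is_dd <- pe[idx] == "Dex" & ch[idx] == "D"
    is_da <- pe[idx] == "Dex" & ch[idx] == "A"
    is_aa <- pe[idx] == "Aex" & ch[idx] == "A"
    n_dd <- sum(is_dd); n_da <- sum(is_da); n_aa <- sum(is_aa)
    dur_s <- bursts$duration_ms[b] / 1000
    f_dd <- max(n_dd - bg[["DD"]] * dur_s, 0)
    f_da <- max(n_da - bg[["DA"]] * dur_s, 0)
    f_aa <- max(n_aa - bg[["AA"]] * dur_s, 0)

    e_pr <- if (n_dd + n_da > 0) n_da / (n_da + n_dd) else NA_real_
    da_corr <- f_da - corr$alpha * f_dd - corr$delta * f_aa
    den <- corr$gamma * f_dd + da_corr
    e_corr <- if (is.finite(den) && den > 0) da_corr / den else NA_real_
    s_den <- f_dd + f_da + f_aa
    s <- if (s_den > 0) (f_dd + f_da) / s_den else NA_real_

    t_b <- t[idx]
    alex <- alex_2cde(t_b[pe[idx] == "Dex"], t_b[pe[idx] == "Aex"], tau_ticks)
    fret <- fret_2cde(t_b[is_dd], t_b[is_da], tau_ticks)
    asym <- asymmetry_statistic(t_b[is_dd], t_b[is_da],
                                bursts$start_tick[b], bursts$stop_tick[b])
    tau_rel <- if (sum(is_dd) >= lifetime_min_photons) {
      donor_lifetime(nt[idx][is_dd], corr$tau_D0)
    } else NA_real_
    truth <- if (!is.null(tb)) {
      tv <- tb[idx]
      if (all(is.na(tv))) NA_integer_ else {
        as.integer(names(sort(table(tv), decreasing = TRUE))[1])
      }
    } else NA_integer_

    out[[b]] <- data.frame(
      burst = b, start_tick = bursts$start_tick[b],
      stop_tick = bursts$stop_tick[b], duration_ms = bursts$duration_ms[b],
      N_DD = n_dd, N_DA = n_da, N_AA = n_aa,
      F_DD = f_dd, F_DA = f_da, F_AA = f_aa,
      E_PR = e_pr, E = e_corr, S = s,
      alex_2cde = alex, fret_2cde = fret, asymmetry = asym,
      tau_rel = tau_rel,
      undefined = is.na(e_corr) || is.na(s),
      truth_burst = truth
    )
  }
  res <- if (nb > 0) do.call(rbind, out) else
    data.frame(burst = integer(0))
  attr(res, "background_rate") <- bg
  attr(res, "corrections") <- corr
  attr(res, "kde_tau_us") <- kde_tau_us
  class(res) <- c("burst_metrics", "data.frame")
  res
}

#' Relative donor lifetime of a burst
#'
#' Mean-nanotime estimator of the donor lifetime in presence of the acceptor
#' relative to the unquenched lifetime; under static FRET
#' `tau_D(A)/tau_D(0) = 1 - E`.
#'
#' @param nanotimes Donor-channel donor-excitation nanotimes (ns).
#' @param tau_D0 Unquenched donor lifetime (ns).
#' @param irf_offset Instrument-response offset subtracted from every
#'   nanotime (ns).
#' @return `tau_D(A)/tau_D(0)`.
#' @export
donor_lifetime <- function(nanotimes, tau_D0, irf_offset = 0) {
  stopifnot(tau_D0 > 0)
  mean(nanotimes - irf_offset) / tau_D0
}

#' Select the FRET-active burst population
#'
#' Retains bursts whose stoichiometry falls inside `S_window` (excluding
#' donor-only molecules at S ~ 1 and acceptor-only at S ~ 0) and which pass
#' the ALEX-2CDE, asymmetry and definedness filters. Idempotent.
#'
#' @param metrics A `burst_metrics` table.
#' @param S_window Stoichiometry window (default 0.3-0.7).
#' @param E_window Optional efficiency window.
#' @param alex_2cde_max ALEX-2CDE retention threshold (default 10).
#' @param asymmetry_max Absolute asymmetry threshold (default 0.25); bursts
#'   with an undefined asymmetry are rejected.
#' @return The retained subset, with the applied thresholds attached as the
#'   `filters` attribute. A warning is issued when nothing survives.
#' @export
sort_species <- function(metrics, S_window = c(0.3, 0.7), E_window = NULL,
                         alex_2cde_max = 10, asymmetry_max = 0.25) {
  keep <- !metrics$undefined &
    !is.na(metrics$S) & metrics$S >= S_window[1] & metrics$S <= S_window[2] &
    metrics$alex_2cde <= alex_2cde_max &
    !is.na(metrics$asymmetry) & abs(metrics$asymmetry) <= asymmetry_max
  if (!is.null(E_window)) {
    keep <- keep & !is.na(metrics$E) &
      metrics$E >= E_window[1] & metrics$E <= E_window[2]
  }
  res <- metrics[keep & !is.na(keep), , drop = FALSE]
  if (nrow(res) == 0L) warning("no bursts retained by sort_species")
  attr(res, "filters") <- list(S_window = S_window, E_window = E_window,
                               alex_2cde_max = alex_2cde_max,
                               asymmetry_max = asymmetry_max)
  attr(res, "background_rate") <- attr(metrics, "background_rate")
  attr(res, "corrections") <- attr(metrics, "corrections")
  class(res) <- c("burst_metrics", "data.frame")
  res
}

#' Build a FRET efficiency histogram from filtered burst metrics
#'
#' @param metrics Filtered `burst_metrics` (at least one row).
#' @param n_bins Number of equal-width bins (default 40).
#' @param range Efficiency range (default [0, 1]); efficiencies outside are
#'   clamped into the edge bins so counts always sum to the burst count.
#' @param use Efficiency column to bin: `"E"` (corrected) or `"E_PR"`.
#' @return Object of class `fret_histogram`: list with `breaks`, `mids`,
#'   `counts`, `burst_sizes` (per retained burst, total donor-excitation
#'   photons, preserved for PDA), and `n_bursts`.
#' @export
build_fret_histogram <- function(metrics, n_bins = 40, range = c(0, 1),
                                 use = c("E", "E_PR")) {
  use <- match.arg(use)
  e <- metrics[[use]]
  e <- e[!is.na(e)]
  if (length(e) == 0L) stop("no bursts with defined efficiency")
  breaks <- seq(range[1], range[2], length.out = n_bins + 1L)
  e <- pmin(pmax(e, range[1]), range[2])
  bin <- findInterval(e, breaks, rightmost.closed = TRUE)
  counts <- tabulate(bin, nbins = n_bins)
  sizes <- (metrics$N_DD + metrics$N_DA)[!is.na(metrics[[use]])]
  structure(list(breaks = breaks, mids = (breaks[-1] + breaks[-length(breaks)]) / 2,
                 counts = counts, burst_sizes = sizes,
                 n_bursts = length(e)),
            class = "fret_histogram")
}

#' @export
print.fret_histogram <- function(x, ...) {
  cat(sprintf("FRET histogram: %d bursts in %d bins on [%g, %g]\n",
              x$n_bursts, length(x$counts), min(x$breaks), max(x$breaks)))
  invisible(x)
}
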