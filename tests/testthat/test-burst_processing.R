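# Burst search, ALEX correction algebra, kernel-density and asymmetry
# filters, species sorting, lifetimes and histogram construction.

test_that("quiet background yields no bursts; a dense cluster yields one", {
  set.seed(1)
  # 200 Hz homogeneous background for 10 s: far below 10-in-500us
  t_bg <- sort(runif(2000, 0, 10))
  st <- make_stream(t_bg, rep("D", 2000), rep("Dex", 2000), duration = 10)
  expect_equal(nrow(find_bursts(st)), 0)

  # 100 photons in 1 ms injected into silence
  t_cl <- sort(runif(100, 5, 5.001))
  st2 <- make_stream(c(t_bg, t_cl), rep("D", 2100), rep("Dex", 2100),
                     duration = 10)
  b <- find_bursts(st2, burst_search_params(m = 10, T_us = 500,
                                            min_photons = 50))
  expect_equal(nrow(b), 1)
  # burst spans exactly the 100 injected photons
  expect_equal(b$n_photons, 100)
  tick <- st2$photons$timestamp
  expect_true(all(tick[b$i_start:b$i_stop] >= 5 * 1e8 - 1))
})

test_that("sliding-window search agrees with a brute-force window scan", {
  set.seed(2)
  t_bg <- sort(runif(10000, 0, 10))            # 1 kHz background
  inj_start <- seq(0.25, 9.75, length.out = 20)
  t_inj <- unlist(lapply(inj_start, function(s) sort(runif(100, s, s + 0.001))))
  t_all <- sort(c(t_bg, t_inj))
  n <- length(t_all)
  st <- make_stream(t_all, rep("D", n), rep("Dex", n), duration = 10)
  p <- burst_search_params(m = 10, T_us = 500, min_photons = 50)
  got <- find_bursts(st, p)
  oracle <- brute_force_bursts(st$photons$timestamp, p$m,
                               p$T_us * 1e-6 * st$clock_rate, p$min_photons)
  expect_equal(got$i_start, oracle$i_start)
  expect_equal(got$i_stop, oracle$i_stop)
  # at least 19 of the 20 injected clusters recovered, each span within
  # +/- 2 photons of the injected 100
  expect_gte(nrow(got), 19)
  hits <- vapply(inj_start, function(s) {
    any(abs(got$start_tick / 1e8 - s) < 0.002)
  }, TRUE)
  expect_gte(sum(hits), 19)
  matched <- got[vapply(seq_len(nrow(got)), function(i) {
    any(abs(got$start_tick[i] / 1e8 - inj_start) < 0.002)
  }, TRUE), ]
  # spans match the injected 100 photons, allowing for the ~1 background
  # photon expected inside each 1 ms cluster and window-edge pickup
  expect_true(all(abs(matched$n_photons - 100) <= 5))
})

test_that("empty and tiny streams return an empty burst table", {
  st <- make_stream(numeric(0), character(0), character(0), duration = 1)
  expect_equal(nrow(find_bursts(st)), 0)
})

test_that("ALEX algebra: proximity ratio, stoichiometry and gamma correction", {
  mk <- function(n_dd, n_da, n_aa) {
    n <- n_dd + n_da + n_aa
    t_s <- seq(0, 0.001, length.out = n)
    make_stream(t_s,
                c(rep("D", n_dd), rep("A", n_da), rep("A", n_aa)),
                c(rep("Dex", n_dd + n_da), rep("Aex", n_aa)),
                duration = 0.01)
  }
  st <- mk(20, 80, 50)
  m <- burst_metrics(st, burst_row(st, 1, 150),
                     correction_set(background_rate = c(DD = 0, DA = 0,
                                                        AA = 0)))
  expect_equal(m$E_PR, 0.8)
  expect_equal(m$E, 0.8)
  expect_equal(m$S, 100 / 150)

  # no acceptor-excitation photons: acceptor-dark molecule, S = 1
  st2 <- mk(50, 50, 0)
  m2 <- burst_metrics(st2, burst_row(st2, 1, 100),
                      correction_set(background_rate = c(DD = 0, DA = 0,
                                                         AA = 0)))
  expect_equal(m2$S, 1)

  # gamma = 2 halves the weight of acceptor counts in the efficiency
  m3 <- burst_metrics(st2, burst_row(st2, 1, 100),
                      correction_set(gamma = 2,
                                     background_rate = c(DD = 0, DA = 0,
                                                         AA = 0)))
  expect_equal(m3$E, 50 / (2 * 50 + 50))
})

test_that("background correction subtracts rate x duration per class", {
  n <- 200
  t_s <- seq(0, 0.01, length.out = n)  # 10 ms burst
  st <- make_stream(t_s, c(rep("D", 100), rep("A", 100)),
                    rep("Dex", n), duration = 0.02)
  corr <- correction_set(background_rate = c(DD = 1000, DA = 3000, AA = 0))
  m <- burst_metrics(st, burst_row(st, 1, n), corr)
  # 10 ms x 1 kHz = 10 and x 3 kHz = 30 photons removed
  expect_equal(m$F_DD, 100 - 10, tolerance = 0.01)
  expect_equal(m$F_DA, 100 - 30, tolerance = 0.01)
  expect_equal(m$E, m$F_DA / (m$F_DA + m$F_DD))
})

test_that("degenerate bursts are flagged undefined, not errors", {
  n <- 30
  t_s <- seq(0, 0.001, length.out = n)
  st <- make_stream(t_s, rep("A", n), rep("Aex", n), duration = 0.01)
  m <- burst_metrics(st, burst_row(st, 1, n),
                     correction_set(background_rate = c(DD = 0, DA = 0,
                                                        AA = 0)))
  expect_true(m$undefined)
  expect_true(is.na(m$E))
})

test_that("ALEX-2CDE separates interleaved from segregated bursts and matches a direct kernel sum", {
  # 200 photons, perfectly alternating Dex/Aex at uniform spacing
  n <- 200
  t_s <- seq(0, 0.002, length.out = n)
  tick <- t_s * 1e8
  alt <- rep(c("Dex", "Aex"), n / 2)
  tau <- 100e-6 * 1e8
  sc_alt <- alex_2cde(tick[alt == "Dex"], tick[alt == "Aex"], tau)
  expect_lte(sc_alt, 10)
  expect_equal(sc_alt, naive_alex_2cde(tick[alt == "Dex"],
                                       tick[alt == "Aex"], tau))
  # artifact burst: all Dex in the first half, all Aex in the second
  seg <- c(rep("Dex", n / 2), rep("Aex", n / 2))
  sc_seg <- alex_2cde(tick[seg == "Dex"], tick[seg == "Aex"], tau)
  expect_gt(sc_seg, 10)
  expect_equal(sc_seg, naive_alex_2cde(tick[seg == "Dex"],
                                       tick[seg == "Aex"], tau))
  # degenerate input: one photon per class, finite score by convention
  expect_identical(alex_2cde(tick[1], tick[2], tau), 0)
  expect_true(is.finite(fret_2cde(tick[1], tick[2], tau)))
})

test_that("thresholding ALEX-2CDE separates labeled burst classes at >= 95% balanced accuracy", {
  set.seed(9)
  tau <- 100e-6 * 1e8
  n_per <- 80
  score_homog <- replicate(n_per, {
    n <- rpois(1, 80) + 20
    tick <- sort(runif(n, 0, 1e-3)) * 1e8
    lab <- sample(c("Dex", "Aex"), n, replace = TRUE)
    alex_2cde(tick[lab == "Dex"], tick[lab == "Aex"], tau)
  })
  score_coinc <- replicate(n_per, {
    n <- rpois(1, 80) + 20
    half <- n %/% 2
    t_dex <- sort(runif(half, 0, 5e-4)) * 1e8
    t_aex <- sort(runif(n - half, 5e-4, 1e-3)) * 1e8
    alex_2cde(t_dex, t_aex, tau)
  })
  sens <- mean(score_homog <= 10)
  spec <- mean(score_coinc > 10)
  expect_gte((sens + spec) / 2, 0.95)
})

test_that("asymmetry statistic is antisymmetric and flags acceptor bleaching", {
  n <- 100
  tick <- seq(0, 1e5, length.out = n)
  inter <- rep(c("D", "A"), n / 2)
  a_sym <- asymmetry_statistic(tick[inter == "D"], tick[inter == "A"],
                               0, 1e5)
  expect_lt(abs(a_sym), 0.05)
  # acceptor photons only in the first half (mid-burst acceptor bleach)
  ch <- c(rep("A", n / 2), rep("D", n / 2))
  a_bl <- asymmetry_statistic(tick[ch == "D"], tick[ch == "A"], 0, 1e5)
  expect_lt(a_bl, -0.25)
  # reversing time flips the sign
  rev_tick <- 1e5 - tick
  a_rev <- asymmetry_statistic(rev_tick[ch == "D"], rev_tick[ch == "A"],
                               0, 1e5)
  expect_equal(a_rev, -a_bl)
  expect_true(is.na(asymmetry_statistic(tick, numeric(0), 0, 1e5)))
})

test_that("simulated acceptor bleaching is rejected by the asymmetry filter", {
  sp <- species_spec("wt", "dual", 1, 4.4, 0.2)
  acq <- acquisition_settings(duration = 20, bleach_fraction = 1, seed = 21)
  st <- simulate_photon_stream(sp, acq)
  b <- find_bursts(st)
  m <- burst_metrics(st, b)
  sel <- suppressWarnings(sort_species(m))
  # nearly all bursts carry a mid-burst bleach and must be filtered out
  expect_lt(nrow(sel) / max(nrow(m), 1), 0.25)
})

test_that("species sorting retains the dual-label population and is idempotent", {
  dual <- species_spec("dual", "dual", 1, 4.4, 0.2)
  donly <- species_spec("donly", "donor_only")
  aonly <- species_spec("aonly", "acceptor_only")
  acq <- acquisition_settings(duration = 30, seed = 77)

  st_d <- simulate_photon_stream(donly, acq)
  m_d <- burst_metrics(st_d, find_bursts(st_d))
  expect_equal(nrow(suppressWarnings(sort_species(m_d))), 0)

  st_a <- simulate_photon_stream(aonly, acq)
  m_a <- burst_metrics(st_a, find_bursts(st_a))
  expect_equal(nrow(suppressWarnings(sort_species(m_a))), 0)

  st_mix <- simulate_photon_stream(list(dual, donly),
                                   acquisition_settings(duration = 60,
                                                        seed = 78),
                                   weights = c(0.5, 0.5))
  b <- find_bursts(st_mix)
  m <- burst_metrics(st_mix, b)
  sel <- sort_species(m)
  # ground-truth species labels carried by the simulator
  truth_kind <- st_mix$truth$kind[sel$truth_burst]
  expect_true(all(truth_kind == "dual"))
  frac_retained <- nrow(sel) / nrow(m)
  truth_dual_frac <- mean(st_mix$truth$kind[m$truth_burst] == "dual")
  se <- sqrt(truth_dual_frac * (1 - truth_dual_frac) / nrow(m))
  expect_lt(abs(frac_retained - truth_dual_frac), 4 * se + 0.03)
  # idempotence
  sel2 <- sort_species(sel)
  expect_equal(as.data.frame(sel2), as.data.frame(sel))
})

test_that("corrected efficiency equals the proximity ratio when corrections are trivial", {
  sp <- species_spec("wt", "dual", c(0.6, 0.4), c(4.4, 6.3), c(0.3, 0.3))
  acq <- acquisition_settings(duration = 10,
                              background_rate = c(DD = 0, DA = 0, AA = 0),
                              gamma = 1, alpha = 0, delta = 0, seed = 14)
  st <- simulate_photon_stream(sp, acq)
  b <- find_bursts(st)
  m <- burst_metrics(st, b, correction_set(background_rate = c(DD = 0,
                                                               DA = 0,
                                                               AA = 0)))
  ok <- !m$undefined
  expect_true(all(abs(m$E[ok] - m$E_PR[ok]) < 1e-12))
})

test_that("median burst efficiency decreases strictly with programmed distance", {
  med <- vapply(3:8, function(R) {
    sp <- species_spec("x", "dual", 1, R, 0.1)
    acq <- acquisition_settings(duration = 10, seed = 400 + R)
    st <- simulate_photon_stream(sp, acq)
    m <- burst_metrics(st, find_bursts(st))
    sel <- suppressWarnings(sort_species(m, S_window = c(0.2, 0.8)))
    stats::median(sel$E, na.rm = TRUE)
  }, 0)
  expect_true(all(diff(med) < 0))
})

test_that("relative donor lifetime reflects the static FRET line", {
  # direct estimator check against the sample mean
  set.seed(6)
  nts <- rexp(1000, 1 / 2)
  ratio <- donor_lifetime(nts, tau_D0 = 4)
  expect_equal(ratio, mean(nts) / 4)
  expect_lt(abs(ratio - 0.5), 2 * sd(nts) / sqrt(1000) / 4)

  # high-FRET bursts: tau_DA/tau_D0 ~ 1 - E
  sp <- species_spec("hi", "dual", 1, 4.4, 0)
  acq <- acquisition_settings(duration = 15,
                              background_rate = c(DD = 0, DA = 0, AA = 0),
                              seed = 44)
  st <- simulate_photon_stream(sp, acq)
  m <- burst_metrics(st, find_bursts(st))
  e_true <- fret_efficiency(4.4, 5.5)
  expect_equal(mean(m$tau_rel, na.rm = TRUE), 1 - e_true, tolerance = 0.05)

  # donor-only bursts: unquenched, ratio ~ 1
  sp0 <- species_spec("d0", "donor_only")
  st0 <- simulate_photon_stream(sp0, acq)
  m0 <- burst_metrics(st0, find_bursts(st0))
  expect_equal(mean(m0$tau_rel, na.rm = TRUE), 1, tolerance = 0.05)
})

test_that("FRET histograms conserve counts and resolve a two-state mixture", {
  n <- 100
  t_s <- sort(runif(n * 10, 0, 1))
  # constructed metrics: 100 bursts all at E = 0.8
  metrics <- data.frame(E = rep(0.8, 100), E_PR = rep(0.8, 100),
                        N_DD = rep(20, 100), N_DA = rep(80, 100))
  h <- build_fret_histogram(metrics, n_bins = 40, range = c(0, 1))
  expect_equal(sum(h$counts), 100)
  expect_equal(sum(h$counts > 0), 1)
  expect_equal(h$counts[findInterval(0.8, h$breaks)], 100)

  sp <- species_spec("two", "dual", c(0.5, 0.5), c(4.4, 6.3), c(0.25, 0.25))
  st <- simulate_photon_stream(sp, acquisition_settings(duration = 40,
                                                        seed = 91))
  m <- burst_metrics(st, find_bursts(st))
  sel <- sort_species(m)
  h2 <- build_fret_histogram(sel)
  expect_equal(sum(h2$counts), h2$n_bursts)
  expect_equal(length(h2$burst_sizes), h2$n_bursts)
  # bimodal with modes near the programmed efficiencies 0.79 and 0.31
  hi_bin <- which.max(h2$counts * (h2$mids > 0.55))
  lo_bin <- which.max(h2$counts * (h2$mids < 0.55))
  expect_lt(abs(h2$mids[hi_bin] - fret_efficiency(4.4, 5.5)), 0.08)
  expect_lt(abs(h2$mids[lo_bin] - fret_efficiency(6.3, 5.5)), 0.08)
})
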