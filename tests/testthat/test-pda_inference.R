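# PDA: exact degenerate cases, equivalence with a Monte-Carlo oracle,
# chi-square calibration, and parameter recovery from synthetic bursts.

breaks40 <- seq(0, 1, length.out = 41)

test_that("two-photon bursts at eps one-half give the exact binomial masses", {
  model <- pda_state_model(1, 5.5, 0, R0 = 5.5)  # eps = 1/2 exactly
  expd <- pda_expected_histogram(model, rep(2L, 400), breaks40)
  expect_equal(sum(expd), 400)
  nz <- which(expd > 1e-9)
  # apparent E in {0, 1/2, 1}: first bin, the bin left-closed at 0.5, last
  expect_equal(nz, c(1L, findInterval(0.5, breaks40), 40L))
  expect_equal(unname(expd[nz]), c(100, 200, 100))
})

test_that("a zero-efficiency state places all mass in the first bin", {
  model <- pda_state_model(1, 1000, 0, R0 = 5.5)
  expd <- pda_expected_histogram(model, rpois(200, 40) + 1L, breaks40)
  expect_equal(expd[1], sum(expd))
})

test_that("expected histogram mass equals the burst count for any model", {
  set.seed(10)
  for (i in 1:5) {
    k <- sample(1:3, 1)
    fr <- rexp(k); fr <- fr / sum(fr)
    model <- pda_state_model(fr, runif(k, 3, 8), runif(1, 0.05, 0.6))
    sizes <- rpois(500, runif(1, 20, 120)) + 1L
    expd <- pda_expected_histogram(model, sizes, breaks40)
    expect_equal(sum(expd), length(sizes), tolerance = 1e-6)
  }
})

test_that("semi-analytic histogram matches a brute-force Monte-Carlo oracle", {
  set.seed(11)
  n_mc <- 1e6
  grid <- expand.grid(R = c(4.4, 5.5, 6.3), sigma = c(0.1, 0.3))
  sizes <- rpois(2000, 60) + 1L
  for (g in seq_len(nrow(grid))) {
    model <- pda_state_model(1, grid$R[g], grid$sigma[g], R0 = 5.5)
    semi <- pda_expected_histogram(model, sizes, breaks40)
    p_semi <- semi / sum(semi)
    mc <- mc_pda_histogram(n_mc, sizes, 1, grid$R[g], grid$sigma[g],
                           5.5, breaks40)
    p_mc <- mc / n_mc
    tol <- 5 * sqrt(pmax(p_semi, 1e-6) * (1 - p_semi) / n_mc) + 2e-4
    expect_true(all(abs(p_mc - p_semi) < tol),
                info = sprintf("R=%.1f sigma=%.1f", grid$R[g],
                               grid$sigma[g]))
  }
})

test_that("shot-noise width shrinks as burst sizes grow", {
  sds <- vapply(c(15, 40, 100, 200), function(nbar) {
    model <- pda_state_model(1, 5.5, 0, R0 = 5.5)
    expd <- pda_expected_histogram(model, rep(nbar, 100), breaks40)
    p <- expd / sum(expd)
    mids <- (breaks40[-1] + breaks40[-41]) / 2
    sqrt(sum(p * (mids - sum(p * mids))^2))
  }, 0)
  expect_true(all(diff(sds) < 0))
})

test_that("background counts broaden the apparent-efficiency distribution", {
  clean <- pda_state_model(1, 4.4, 0, R0 = 5.5)
  noisy <- pda_state_model(1, 4.4, 0, R0 = 5.5,
                           background_mean = c(D = 3, A = 3))
  sizes <- rep(50L, 200)
  e_clean <- pda_expected_histogram(clean, sizes, breaks40)
  e_noisy <- pda_expected_histogram(noisy, sizes, breaks40)
  expect_equal(sum(e_noisy), 200, tolerance = 1e-6)
  mids <- (breaks40[-1] + breaks40[-41]) / 2
  mu <- function(e) sum(e / sum(e) * mids)
  # background on both channels pulls the mean toward one half
  expect_lt(mu(e_noisy), mu(e_clean))
})

test_that("fitting a model to data generated from itself calibrates chi-square", {
  set.seed(12)
  sizes <- rpois(4000, 60) + 1L
  truth <- pda_state_model(c(0.7, 0.3), c(4.4, 6.3), 0.3)
  counts <- mc_pda_histogram(length(sizes), sizes, truth$fractions,
                             truth$distance_center, truth$distance_width,
                             5.5, breaks40)
  h <- list(breaks = breaks40, counts = counts, burst_sizes = sizes)
  fit <- pda_fit(h, truth, seed = 2)
  expect_gte(fit$reduced_chi2, 0.5)
  expect_lte(fit$reduced_chi2, 1.5)
  expect_equal(sum(fit$model_counts), sum(counts), tolerance = 1e-6)
})

test_that("two-state fractions and distances are recovered from 3000+ bursts", {
  set.seed(13)
  sizes <- rpois(3500, 60) + 1L
  counts <- mc_pda_histogram(length(sizes), sizes, c(0.7, 0.3),
                             c(4.4, 6.3), c(0.3, 0.3), 5.5, breaks40)
  h <- list(breaks = breaks40, counts = counts, burst_sizes = sizes)
  fit <- pda_fit(h, pda_state_model(c(0.5, 0.5), c(4.0, 6.8), 0.4), seed = 3)
  expect_equal(unname(fraction_folded(fit)["f_F"]), 0.7, tolerance = 0.05)
  expect_lt(abs(fit$distance_center[1] - 4.4), 0.2)
  expect_lt(abs(fit$distance_center[2] - 6.3), 0.2)
  expect_equal(sum(fit$fractions), 1, tolerance = 1e-9)
})

test_that("single-state data fitted with two states yields a dominant fraction", {
  set.seed(14)
  sizes <- rpois(3000, 60) + 1L
  counts <- mc_pda_histogram(length(sizes), sizes, 1, 4.4, 0.3, 5.5,
                             breaks40)
  h <- list(breaks = breaks40, counts = counts, burst_sizes = sizes)
  fit <- pda_fit(h, pda_state_model(c(0.6, 0.4), c(4.4, 6.3), 0.3),
                 seed = 4)
  expect_gte(max(fit$fractions), 0.95)
})

test_that("recovery error stays small across occupancies (seeded replicates)", {
  set.seed(15)
  cases <- expand.grid(f = c(0.2, 0.5, 0.8), rep = 1:3)
  err_f <- err_r <- numeric(nrow(cases))
  for (i in seq_len(nrow(cases))) {
    f <- cases$f[i]
    sizes <- rpois(3000, 60) + 1L
    counts <- mc_pda_histogram(length(sizes), sizes, c(f, 1 - f),
                               c(4.4, 6.3), c(0.3, 0.3), 5.5, breaks40)
    h <- list(breaks = breaks40, counts = counts, burst_sizes = sizes)
    fit <- pda_fit(h, pda_state_model(c(0.5, 0.5), c(4.2, 6.5), 0.35),
                   n_restarts = 3, seed = 100 + i)
    err_f[i] <- abs(fraction_folded(fit)["f_F"] - f)
    err_r[i] <- max(abs(fit$distance_center - c(4.4, 6.3)))
  }
  expect_lte(mean(err_f), 0.05)
  expect_lte(mean(err_r), 0.2)
})

test_that("fraction_folded returns the requested state and errors are restart sds", {
  set.seed(16)
  sizes <- rpois(2000, 50) + 1L
  counts <- mc_pda_histogram(length(sizes), sizes, c(0.6, 0.4),
                             c(4.4, 6.3), c(0.3, 0.3), 5.5, breaks40)
  h <- list(breaks = breaks40, counts = counts, burst_sizes = sizes)
  fit <- pda_fit(h, pda_state_model(c(0.5, 0.5), c(4.4, 6.3), 0.3),
                 seed = 5)
  ff <- fraction_folded(fit)
  expect_equal(unname(ff["f_F"]), fit$fractions[which.min(fit$distance_center)])
  expect_equal(unname(ff["f_F"]) + fit$fractions[which.max(fit$distance_center)],
               1, tolerance = 1e-9)
  expect_gte(ff["se"], 0)
  expect_error(fraction_folded(fit, 5), "invalid")
  expect_identical(fit$meta$error_definition,
                   "sd of estimates over converged restarts in the best chi-square basin")
})

test_that("invalid state models are rejected", {
  expect_error(pda_state_model(c(0.5, 0.6), c(4, 6)), "sum to 1")
  expect_error(pda_state_model(1, -4), "positive")
  expect_error(pda_expected_histogram(pda_state_model(1, 5), rep(10, 5),
                                      seq(0.2, 1, length.out = 5)),
               "partition")
})
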