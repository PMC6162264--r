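# Shot-noise-limited probability distribution analysis (PDA) of FRET
# efficiency histograms. The expected histogram marginalizes, per
# conformational state, over a Gaussian inter-dye distance distribution
# (Gauss-Hermite quadrature) and over binomial photon partitioning at each
# observed burst size, with optional Poisson background counts; chi-square
# minimization over state fractions and distances recovers the
# conformational equilibrium beyond the shot-noise limit.

#' Define a PDA state model
#'
#' A mixture of static conformational states, each a Gaussian distribution
#' of inter-dye distances, sharing one Foerster radius and one set of
#' detection corrections.
#'
#' @param fractions State occupancies (sum to 1).
#' @param distance_center Per-state mean inter-dye distance (nm).
#' @param distance_width Per-state Gaussian width (nm); may be length 1 to
#'   share one width across states.
#' @param R0 Foerster radius (nm).
#' @param gamma,alpha Detection corrections entering the apparent acceptor
#'   probability exactly as in burst processing.
#' @param background_mean Mean background photons per burst in the donor and
#'   acceptor channel, named `D` and `A`.
#' @return Object of class `pda_state_model`.
#' @export
pda_state_model <- function(fractions, distance_center,
                            distance_width = 0.3, R0 = 5.5,
                            gamma = 1, alpha = 0,
                            background_mean = c(D = 0, A = 0)) {
  k <- length(fractions)
  if (length(distance_width) == 1L) distance_width <- rep(distance_width, k)
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must be >= 0 and sum to 1")
  if (length(distance_center) != k || length(distance_width) != k)
    stop("distance_center/distance_width must match fractions")
  if (any(distance_center <= 0) || any(distance_width < 0) || R0 <= 0)
    stop("distances and R0 must be positive, widths non-negative")
  stopifnot(all(c("D", "A") %in% names(background_mean)),
            all(background_mean >= 0))
  structure(list(fractions = fractions, distance_center = distance_center,
                 distance_width = distance_width, R0 = R0, gamma = gamma,
                 alpha = alpha, background_mean = background_mean),
            class = "pda_state_model")
}

# Gauss-Hermite nodes mapped to a Gaussian N(mu, sigma); weights normalized
# to sum to one. sigma = 0 collapses to a point mass.
.gh_nodes <- function(mu, sigma, n_nodes) {
  if (sigma <= 0) return(list(x = mu, w = 1))
  gh <- pracma::gaussHermite(n_nodes)
  list(x = mu + sqrt(2) * sigma * gh$x, w = gh$w / sum(gh$w))
}

# apparent-E bin index for values e in [0,1] given histogram breaks
.e_bin <- function(e, breaks) {
  findInterval(e, breaks, rightmost.closed = TRUE)
}

# Per-size apparent-E mass for one acceptor probability eps: returns vector
# of bin masses for a burst of N photons (a ~ Binom(N, eps)), convolved with
# truncated Poisson background counts in each channel when present.
.size_mass <- function(N, eps, breaks, bgD, bgA) {
  n_bins <- length(breaks) - 1L
  a <- 0:N
  pa_max <- if (bgA > 0) stats::qpois(0.9999, bgA) else 0L
  pd_max <- if (bgD > 0) stats::qpois(0.9999, bgD) else 0L
  out <- numeric(n_bins)
  wpa <- stats::dpois(0:pa_max, bgA); wpa <- wpa / sum(wpa)
  wpd <- stats::dpois(0:pd_max, bgD); wpd <- wpd / sum(wpd)
  pmf <- stats::dbinom(a, N, eps)
  for (ia in 0:pa_max) {
    for (id in 0:pd_max) {
      e_app <- (a + ia) / (N + ia + id)
      bin <- .e_bin(e_app, breaks)
      w <- wpa[ia + 1L] * wpd[id + 1L]
      m <- rowsum(pmf * w, bin)
      out[as.integer(rownames(m))] <- out[as.integer(rownames(m))] + m[, 1]
    }
  }
  out
}

#' Semi-analytic PDA expected histogram
#'
#' Computes the expected FRET efficiency histogram of a state model for a
#' given empirical burst-size list: for each state the Gaussian distance
#' distribution is marginalized by Gauss-Hermite quadrature into apparent
#' acceptor probabilities, photon shot noise enters as an exact binomial at
#' every observed burst size (with optional Poisson background counts per
#' channel), and the resulting apparent-E mass is binned and mixed by the
#' state fractions. Total mass equals the number of bursts.
#'
#' @param model A `pda_state_model`.
#' @param burst_sizes Observed donor-excitation photon counts, one per
#'   burst; sizes above `max_size` are capped (equivalent to random photon
#'   subsampling of very large bursts).
#' @param breaks Histogram bin edges partitioning [0, 1].
#' @param gh_nodes Number of Gauss-Hermite nodes (default 32).
#' @param max_size Burst-size cap (default 250).
#' @return Numeric vector of expected counts per bin.
#' @export
pda_expected_histogram <- function(model, burst_sizes, breaks,
                                   gh_nodes = 32, max_size = 250) {
  stopifnot(inherits(model, "pda_state_model"), length(burst_sizes) > 0)
  if (abs(breaks[1]) > 1e-9 || abs(breaks[length(breaks)] - 1) > 1e-9)
    stop("breaks must partition [0, 1]")
  sizes <- pmin(burst_sizes, max_size)
  sizes <- sizes[sizes > 0]
  size_tab <- table(sizes)
  uniq_n <- as.integer(names(size_tab))
  size_w <- as.numeric(size_tab)
  n_bins <- length(breaks) - 1L
  bgD <- model$background_mean[["D"]]
  bgA <- model$background_mean[["A"]]

  expected <- numeric(n_bins)
  for (s in seq_along(model$fractions)) {
    nodes <- .gh_nodes(model$distance_center[s], model$distance_width[s],
                       gh_nodes)
    R <- pmax(nodes$x, 1e-2)
    eps <- apparent_acceptor_prob(fret_efficiency(R, model$R0),
                                  model$gamma, model$alpha)
    state_mass <- numeric(n_bins)
    for (k in seq_along(eps)) {
      node_mass <- numeric(n_bins)
      for (j in seq_along(uniq_n)) {
        node_mass <- node_mass +
          size_w[j] * .size_mass(uniq_n[j], eps[k], breaks, bgD, bgA)
      }
      state_mass <- state_mass + nodes$w[k] * node_mass
    }
    expected <- expected + model$fractions[s] * state_mass
  }
  expected
}

# Precomputed kernel for fast fitting: bin-mass of a/N for every eps on a
# fixed grid, already weighted over the empirical burst-size distribution.
# Rows: eps grid; columns: histogram bins.
.pda_kernel <- function(burst_sizes, breaks, eps_grid, bgD, bgA,
                        max_size = 250) {
  sizes <- pmin(burst_sizes, max_size)
  sizes <- sizes[sizes > 0]
  size_tab <- table(sizes)
  uniq_n <- as.integer(names(size_tab))
  size_w <- as.numeric(size_tab)
  n_bins <- length(breaks) - 1L
  K <- matrix(0, nrow = length(eps_grid), ncol = n_bins)
  simple <- bgD <= 0 && bgA <= 0
  for (j in seq_along(uniq_n)) {
    N <- uniq_n[j]
    if (simple) {
      bin <- .e_bin((0:N) / N, breaks)
      # pmf matrix (a x eps), rows grouped into bins
      pmf <- outer(0:N, eps_grid, function(a, e) stats::dbinom(a, N, e))
      m <- rowsum(pmf, bin)
      K[, as.integer(rownames(m))] <- K[, as.integer(rownames(m))] +
        size_w[j] * t(m)
    } else {
      for (k in seq_along(eps_grid)) {
        K[k, ] <- K[k, ] +
          size_w[j] * .size_mass(N, eps_grid[k], breaks, bgD, bgA)
      }
    }
  }
  list(K = K, eps_grid = eps_grid, n_bursts = length(sizes))
}

# expected histogram from the kernel by linear interpolation in eps
.expected_from_kernel <- function(model, kernel, gh_nodes = 32) {
  eg <- kernel$eps_grid
  n_bins <- ncol(kernel$K)
  expected <- numeric(n_bins)
  for (s in seq_along(model$fractions)) {
    nodes <- .gh_nodes(model$distance_center[s], model$distance_width[s],
                       gh_nodes)
    R <- pmax(nodes$x, 1e-2)
    eps <- apparent_acceptor_prob(fret_efficiency(R, model$R0),
                                  model$gamma, model$alpha)
    eps <- pmin(pmax(eps, eg[1]), eg[length(eg)])
    i <- pmin(findInterval(eps, eg), length(eg) - 1L)
    frac <- (eps - eg[i]) / (eg[i + 1L] - eg[i])
    rows <- kernel$K[i, , drop = FALSE] * (1 - frac) +
      kernel$K[i + 1L, , drop = FALSE] * frac
    expected <- expected + model$fractions[s] * colSums(rows * nodes$w)
  }
  expected
}

# softmax over K-1 free logits (last state is the reference)
.softmax_fractions <- function(logits) {
  z <- exp(c(logits, 0) - max(c(logits, 0)))
  z / sum(z)
}

#' Fit a PDA state model to a FRET histogram by chi-square minimization
#'
#' Minimizes the Pearson chi-square between the observed histogram and the
#' semi-analytic expected histogram over the free parameters: state
#' fractions (on the simplex via a softmax parameterization), distance
#' centers, and (optionally) a shared distance width. Parameter errors are
#' the standard deviations of the estimates over `n_restarts` independent
#' restarts from randomized initial values.
#'
#' @param histogram A `fret_histogram` (from [build_fret_histogram()]) or a
#'   list with `breaks`, `counts` and `burst_sizes`.
#' @param model0 Initial `pda_state_model`; its distances/width seed the
#'   restarts and its R0/corrections/background are held fixed.
#' @param fit_width Fit one shared distance width (default `TRUE`); when
#'   `FALSE` the widths of `model0` are held fixed.
#' @param fit_fractions,fit_centers Fit the state fractions / the distance
#'   centers (default `TRUE`).
#' @param n_restarts Number of randomized restarts (default 10); the
#'   reported errors are the standard deviation over converged restarts.
#' @param seed Master seed from which per-restart seeds are derived.
#' @param gh_nodes Gauss-Hermite nodes for the distance marginalization.
#' @param eps_grid_step Grid step of the precomputed binomial kernel in
#'   apparent acceptor probability (default 0.0025).
#' @param min_expected Bins with expected counts below this enter the
#'   chi-square merged away (excluded); default 3.
#' @param max_size Burst-size cap (default 250).
#' @return Object of class `pda_fit`: `model` (best-fit `pda_state_model`),
#'   `fractions`, `fractions_se`, `distance_center`, `distance_center_se`,
#'   `distance_width`, `distance_width_se`, `chi2`, `reduced_chi2`,
#'   `model_counts` (the fitted "cityscape", summing to the burst count),
#'   `restarts` (per-restart estimates), `n_converged`, `unreliable`
#'   (TRUE when more than half the restarts failed), and `meta`.
#' @export
pda_fit <- function(histogram, model0, fit_width = TRUE,
                    fit_fractions = TRUE, fit_centers = TRUE,
                    n_restarts = 10, seed = 1, gh_nodes = 32,
                    eps_grid_step = 0.0025, min_expected = 3,
                    max_size = 250) {
  stopifnot(inherits(model0, "pda_state_model"))
  counts <- histogram$counts
  breaks <- histogram$breaks
  sizes <- histogram$burst_sizes
  if (sum(counts) < 1) stop("histogram must contain at least one count")
  k <- length(model0$fractions)
  n_bursts <- sum(counts)

  eps_grid <- seq(0, 1, by = eps_grid_step)
  kernel <- .pda_kernel(sizes, breaks, eps_grid,
                        model0$background_mean[["D"]],
                        model0$background_mean[["A"]], max_size)

  # parameter packing: [logits (k-1) | log centers (k) | log width (1)]
  pack <- function(fr, ce, wi) {
    th <- c()
    if (fit_fractions) th <- c(th, log(fr[-k] / fr[k]))
    if (fit_centers) th <- c(th, log(ce))
    if (fit_width) th <- c(th, log(wi))
    th
  }
  unpack <- function(th) {
    i <- 0L
    fr <- model0$fractions
    if (fit_fractions) {
      fr <- .softmax_fractions(th[seq_len(k - 1L)]); i <- k - 1L
    }
    ce <- model0$distance_center
    if (fit_centers) { ce <- exp(th[i + seq_len(k)]); i <- i + k }
    wi <- model0$distance_width
    if (fit_width) wi <- rep(exp(th[i + 1L]), k)
    list(fr = fr, ce = ce, wi = wi)
  }
  mk_model <- function(p) {
    pda_state_model(p$fr, p$ce, p$wi, R0 = model0$R0, gamma = model0$gamma,
                    alpha = model0$alpha,
                    background_mean = model0$background_mean)
  }
  objective <- function(th) {
    p <- unpack(th)
    if (any(p$ce < 0.5) || any(p$ce > 20) || any(p$wi > 5)) return(1e10)
    expd <- .expected_from_kernel(mk_model(p), kernel, gh_nodes)
    use <- expd >= min_expected
    if (sum(use) < 2L) return(1e10)
    sum((counts[use] - expd[use])^2 / expd[use])
  }

  n_free <- (k - 1L) * fit_fractions + k * fit_centers + 1L * fit_width
  restarts <- vector("list", n_restarts)
  for (r in seq_len(n_restarts)) {
    est <- with_seed(seed + r, {
      fr0 <- model0$fractions
      ce0 <- model0$distance_center
      wi0 <- max(model0$distance_width[1], 0.05)
      if (r > 1L) { # restart 1 starts exactly at model0
        fr0 <- fr0 * stats::runif(k, 0.5, 1.5); fr0 <- fr0 / sum(fr0)
        ce0 <- ce0 * exp(stats::rnorm(k, 0, 0.08))
        wi0 <- wi0 * exp(stats::rnorm(1, 0, 0.3))
      }
      th0 <- pack(fr0, ce0, wi0)
      opt <- tryCatch({
        o1 <- stats::optim(th0, objective, method = "Nelder-Mead",
                           control = list(maxit = 2000, reltol = 1e-10))
        # restart the simplex once from the optimum: Nelder-Mead can stall
        # on a collapsed simplex before reaching the basin floor
        stats::optim(o1$par, objective, method = "Nelder-Mead",
                     control = list(maxit = 2000, reltol = 1e-10))
      }, error = function(e) NULL)
      if (is.null(opt)) NULL else {
        p <- unpack(opt$par)
        list(chi2 = opt$value, fr = p$fr, ce = p$ce, wi = p$wi[1],
             converged = opt$convergence == 0)
      }
    })
    restarts[[r]] <- est
  }
  ok <- !vapply(restarts, is.null, TRUE)
  conv <- ok & vapply(restarts, function(x) isTRUE(x$converged), TRUE)
  if (!any(ok)) stop("all PDA restarts failed")
  used <- if (any(conv)) conv else ok
  chis <- vapply(restarts[used], `[[`, 0, "chi2")
  best <- restarts[used][[which.min(chis)]]
  # restarts trapped in a different local minimum do not measure the
  # uncertainty of the reported optimum; keep only those in the best basin
  basin <- chis <= min(chis) + max(0.05 * min(chis), 2)
  used[used] <- basin
  chis <- chis[basin]

  fr_mat <- do.call(rbind, lapply(restarts[used], `[[`, "fr"))
  ce_mat <- do.call(rbind, lapply(restarts[used], `[[`, "ce"))
  wi_vec <- vapply(restarts[used], `[[`, 0, "wi")
  sd0 <- function(x) if (length(x) > 1L) stats::sd(x) else 0

  model_best <- mk_model(list(fr = best$fr, ce = best$ce,
                              wi = rep(best$wi, k)))
  model_counts <- pda_expected_histogram(model_best, sizes, breaks,
                                         gh_nodes, max_size)
  use <- model_counts >= min_expected
  dof <- max(sum(use) - 1L - n_free, 1L)
  chi2 <- sum((counts[use] - model_counts[use])^2 / model_counts[use])

  structure(list(
    model = model_best,
    fractions = best$fr, fractions_se = apply(fr_mat, 2, sd0),
    distance_center = best$ce, distance_center_se = apply(ce_mat, 2, sd0),
    distance_width = best$wi, distance_width_se = sd0(wi_vec),
    chi2 = chi2, reduced_chi2 = chi2 / dof, dof = dof,
    model_counts = model_counts, observed_counts = counts, breaks = breaks,
    restarts = data.frame(
      restart = which(used), chi2 = chis,
      converged = vapply(restarts[used], `[[`, TRUE, "converged")),
    n_converged = sum(conv), unreliable = sum(conv) < n_restarts / 2,
    meta = list(seed = seed, n_restarts = n_restarts,
                error_definition =
                  "sd of estimates over converged restarts in the best chi-square basin",
                fit_width = fit_width, fit_fractions = fit_fractions,
                fit_centers = fit_centers, gh_nodes = gh_nodes,
                eps_grid_step = eps_grid_step, min_expected = min_expected,
                max_size = max_size)
  ), class = "pda_fit")
}

#' @export
print.pda_fit <- function(x, ...) {
  cat("PDA chi-square fit\n")
  st <- data.frame(fraction = round(x$fractions, 3),
                   se = round(x$fractions_se, 3),
                   R_nm = round(x$distance_center, 2),
                   R_se = round(x$distance_center_se, 2))
  print(st)
  cat(sprintf("shared width: %.2f nm (se %.2f)\n",
              x$distance_width, x$distance_width_se))
  cat(sprintf("reduced chi-square: %.2f (%d dof, %d/%d restarts converged)\n",
              x$reduced_chi2, x$dof, x$n_converged,
              x$meta$n_restarts))
  if (x$unreliable) cat("WARNING: fit marked unreliable\n")
  invisible(x)
}

#' Folded (closed-state) fraction from a PDA fit
#'
#' @param fit A `pda_fit`.
#' @param closed_state_index Index of the closed (folded, high-FRET) state;
#'   defaults to the state with the smallest distance center.
#' @return Named numeric vector with `f_F` and its restart error `se`.
#' @export
fraction_folded <- function(fit, closed_state_index = NULL) {
  stopifnot(inherits(fit, "pda_fit"))
  k <- length(fit$fractions)
  if (is.null(closed_state_index))
    closed_state_index <- which.min(fit$distance_center)
  if (closed_state_index < 1 || closed_state_index > k)
    stop("invalid closed_state_index")
  c(f_F = unname(fit$fractions[closed_state_index]),
    se = unname(fit$fractions_se[closed_state_index]))
}
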