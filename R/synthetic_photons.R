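# Seeded generator of PIE/ALEX photon streams emulating freely diffusing,
# dual-labeled two-state molecules in vesicles, plus a dose-response table
# simulator. Stands in for the confocal instrument so that burst search,
# filtering and PDA can be tested against ground truth.

#' Evaluate expr with a temporary RNG seed, restoring the previous state
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' FRET efficiency from the Foerster equation
#'
#' @param R Inter-dye distance (nm).
#' @param R0 Foerster radius (nm), the distance of half-maximal transfer.
#' @return `1 / (1 + (R / R0)^6)`.
#' @export
fret_efficiency <- function(R, R0) {
  stopifnot(all(R > 0), R0 > 0)
  1 / (1 + (R / R0)^6)
}

# Probability that a donor-excitation photon is detected in the acceptor
# channel, given transfer efficiency E, detection-efficiency ratio gamma and
# donor leakage alpha. Inverts exactly under the standard ALEX correction
# E = (N_DA - a N_DD) / (g N_DD + N_DA - a N_DD). Direct acceptor excitation
# is handled additively (proportional to N_AA), not here.
apparent_acceptor_prob <- function(E, gamma = 1, alpha = 0) {
  (gamma * E + alpha * (1 - E)) / (gamma * E + (1 + alpha) * (1 - E))
}

#' Specify a fluorescent species for the photon-stream simulator
#'
#' A species is a dual-labeled molecule with one or more static
#' conformational states (each a Gaussian inter-dye distance distribution),
#' or a donor-only / acceptor-only contaminant.
#'
#' @param label Species name.
#' @param kind `"dual"`, `"donor_only"` or `"acceptor_only"`.
#' @param state_fractions Occupancies of the conformational states
#'   (non-negative, sum to 1). Ignored for single-dye species.
#' @param distance_center,distance_width Per-state mean and Gaussian
#'   standard deviation of the inter-dye distance (nm).
#' @param brightness Detected photons per ms while the molecule transits the
#'   observation volume.
#' @param donor_lifetime_unquenched Unquenched donor lifetime tau_D(0), ns.
#' @return Object of class `species_spec`.
#' @export
species_spec <- function(label, kind = c("dual", "donor_only", "acceptor_only"),
                         state_fractions = 1,
                         distance_center = 5, distance_width = 0,
                         brightness = 100,
                         donor_lifetime_unquenched = 4) {
  kind <- match.arg(kind)
  if (kind == "dual") {
    if (any(state_fractions < 0)) stop("state_fractions must be >= 0")
    if (abs(sum(state_fractions) - 1) > 1e-8)
      stop("state_fractions must sum to 1")
    if (length(distance_center) != length(state_fractions) ||
        length(distance_width) != length(state_fractions))
      stop("distance_center/distance_width must match state_fractions length")
    if (any(distance_center <= 0)) stop("distance_center must be > 0")
    if (any(distance_width < 0)) stop("distance_width must be >= 0")
  }
  if (brightness <= 0) stop("brightness must be > 0")
  structure(list(label = label, kind = kind,
                 state_fractions = state_fractions,
                 distance_center = distance_center,
                 distance_width = distance_width,
                 brightness = brightness,
                 donor_lifetime_unquenched = donor_lifetime_unquenched),
            class = "species_spec")
}

#' Acquisition settings for the photon-stream simulator
#'
#' @param duration Measurement length (s).
#' @param background_rate Named vector of stationary background rates (Hz)
#'   for the three ALEX photon classes `DD` (donor excitation, donor
#'   channel), `DA` (donor excitation, acceptor channel) and `AA`
#'   (acceptor excitation, acceptor channel).
#' @param burst_rate Molecule transits per second.
#' @param transit_time_mean Mean transit duration (ms); transits are
#'   exponential.
#' @param dex_fraction Fraction of a dual-label molecule's photons emitted
#'   under donor excitation (PIE duty handling; default 0.5).
#' @param excitation_period Laser alternation period (ns), used as the
#'   nanotime range of background photons.
#' @param clock_rate Macrotime clock (ticks per second).
#' @param R0 Foerster radius (nm).
#' @param gamma Detection-efficiency ratio.
#' @param alpha Donor leakage into the acceptor channel.
#' @param delta Direct acceptor excitation under donor excitation.
#' @param bleach_fraction Fraction of dual-label bursts given a mid-burst
#'   acceptor bleach (acceptor photons cease partway through the transit);
#'   exists to exercise the asymmetry filter. Default 0.
#' @param seed Integer seed; identical seed and settings give an identical
#'   stream.
#' @return Object of class `acquisition_settings`.
#' @export
acquisition_settings <- function(duration = 30,
                                 background_rate = c(DD = 1000, DA = 600,
                                                     AA = 600),
                                 burst_rate = 20,
                                 transit_time_mean = 1,
                                 dex_fraction = 0.5,
                                 excitation_period = 50,
                                 clock_rate = 1e8,
                                 R0 = 5.5, gamma = 1, alpha = 0, delta = 0,
                                 bleach_fraction = 0,
                                 seed = NULL) {
  if (duration <= 0) stop("invalid 'duration': must be > 0")
  if (any(background_rate < 0)) stop("invalid 'background_rate': must be >= 0")
  if (!all(c("DD", "DA", "AA") %in% names(background_rate)))
    stop("invalid 'background_rate': needs names DD, DA, AA")
  if (burst_rate < 0) stop("invalid 'burst_rate': must be >= 0")
  if (transit_time_mean <= 0) stop("invalid 'transit_time_mean': must be > 0")
  if (R0 <= 0) stop("invalid 'R0': must be > 0")
  if (gamma <= 0) stop("invalid 'gamma': must be > 0")
  if (alpha < 0 || alpha >= 1) stop("invalid 'alpha': must be in [0, 1)")
  if (delta < 0 || delta >= 1) stop("invalid 'delta': must be in [0, 1)")
  if (dex_fraction <= 0 || dex_fraction >= 1)
    stop("invalid 'dex_fraction': must be in (0, 1)")
  if (bleach_fraction < 0 || bleach_fraction > 1)
    stop("invalid 'bleach_fraction': must be in [0, 1]")
  structure(list(duration = duration, background_rate = background_rate,
                 burst_rate = burst_rate,
                 transit_time_mean = transit_time_mean,
                 dex_fraction = dex_fraction,
                 excitation_period = excitation_period,
                 clock_rate = clock_rate, R0 = R0, gamma = gamma,
                 alpha = alpha, delta = delta,
                 bleach_fraction = bleach_fraction, seed = seed),
            class = "acquisition_settings")
}

#' Simulate a PIE photon stream
#'
#' Generates a time-tagged photon stream: Poisson background in all three
#' ALEX classes plus molecule transits ("bursts"). Bursts arrive as a
#' Poisson process; transit durations are exponential; the photon count of a
#' burst is Poisson(brightness x duration). For each dual-label burst a
#' conformational state and an inter-dye distance `R ~ N(center, width)` are
#' drawn, the transfer efficiency follows the Foerster equation, and
#' donor-excitation photons are partitioned binomially between acceptor and
#' donor channels with the apparent probability implied by E, gamma and
#' alpha; acceptor-excitation photons report direct acceptor excitation.
#' Donor-channel nanotimes are exponential with mean `tau_D(0) (1 - E)`.
#'
#' @param species A `species_spec` or list of them.
#' @param acq [acquisition_settings()].
#' @param weights Mixture weights over species (sum to 1).
#' @return Object of class `photon_stream`: list with `photons` (data.frame
#'   `timestamp` in clock ticks, `channel` "D"/"A", `period` "Dex"/"Aex",
#'   `nanotime` ns), `clock_rate`, `settings`, and `truth`, a per-burst
#'   ground-truth data.frame (species, state, distance, efficiency, span).
#' @export
simulate_photon_stream <- function(species, acq = acquisition_settings(),
                                   weights = NULL) {
  if (inherits(species, "species_spec")) species <- list(species)
  if (length(species) == 0L) stop("need at least one species")
  stopifnot(all(vapply(species, inherits, TRUE, "species_spec")))
  if (is.null(weights)) weights <- rep(1 / length(species), length(species))
  if (length(weights) != length(species) || abs(sum(weights) - 1) > 1e-8)
    stop("weights must match species and sum to 1")

  with_seed(acq$seed, {
    dur <- acq$duration
    # stationary background, one Poisson process per photon class
    bg <- lapply(c(DD = "DD", DA = "DA", AA = "AA"), function(cl) {
      n <- stats::rpois(1, acq$background_rate[[cl]] * dur)
      sort(stats::runif(n, 0, dur))
    })
    ph_t <- c(bg$DD, bg$DA, bg$AA)
    ph_ch <- c(rep("D", length(bg$DD)), rep("A", length(bg$DA)),
               rep("A", length(bg$AA)))
    ph_pe <- c(rep("Dex", length(bg$DD)), rep("Dex", length(bg$DA)),
               rep("Aex", length(bg$AA)))
    ph_nt <- stats::runif(length(ph_t), 0, acq$excitation_period)
    ph_burst <- rep(NA_integer_, length(ph_t))

    n_bursts <- stats::rpois(1, acq$burst_rate * dur)
    truth <- NULL
    bl_t <- bl_ch <- bl_pe <- bl_nt <- bl_id <- vector("list", n_bursts)
    tr_state <- rep(NA_integer_, n_bursts)
    tr_R <- tr_E <- tr_start <- tr_dur <- rep(NA_real_, n_bursts)
    tr_N <- integer(n_bursts)
    tr_bleach <- logical(n_bursts)
    if (n_bursts > 0) {
      starts <- sort(stats::runif(n_bursts, 0, dur))
      sp_idx <- sample.int(length(species), n_bursts, replace = TRUE,
                           prob = weights)
      for (b in seq_len(n_bursts)) {
        sp <- species[[sp_idx[b]]]
        tdur <- stats::rexp(1, 1 / acq$transit_time_mean) / 1000  # s
        N <- stats::rpois(1, sp$brightness * tdur * 1000)
        state <- NA_integer_; Rda <- NA_real_; E <- NA_real_
        bleached <- FALSE
        if (N > 0) {
          t_ph <- sort(stats::runif(N, starts[b], starts[b] + tdur))
          if (sp$kind == "dual") {
            state <- sample.int(length(sp$state_fractions), 1,
                                prob = sp$state_fractions)
            Rda <- max(stats::rnorm(1, sp$distance_center[state],
                                    sp$distance_width[state]), 1e-3)
            E <- fret_efficiency(Rda, acq$R0)
            eps <- apparent_acceptor_prob(E, acq$gamma, acq$alpha)
            is_dex <- stats::runif(N) < acq$dex_fraction
            ch <- ifelse(is_dex,
                         ifelse(stats::runif(N) < eps, "A", "D"),
                         "A")
            pe <- ifelse(is_dex, "Dex", "Aex")
            # direct acceptor excitation adds photons on top, prop. to AA
            n_aa <- sum(!is_dex)
            if (acq$delta > 0 && n_aa > 0) {
              nd <- stats::rpois(1, acq$delta * n_aa)
              if (nd > 0) {
                t_ph <- c(t_ph, stats::runif(nd, starts[b], starts[b] + tdur))
                ch <- c(ch, rep("A", nd)); pe <- c(pe, rep("Dex", nd))
              }
            }
            if (acq$bleach_fraction > 0 &&
                stats::runif(1) < acq$bleach_fraction) {
              bleached <- TRUE
              t_b <- starts[b] + stats::runif(1, 0.3, 0.7) * tdur
              late_acc <- ch == "A" & t_ph > t_b
              # after the acceptor dies, FRET is lost: Dex photons revert to
              # the donor channel, Aex photons vanish
              ch[late_acc & pe == "Dex"] <- "D"
              keep <- !(late_acc & pe == "Aex")
              t_ph <- t_ph[keep]; ch <- ch[keep]; pe <- pe[keep]
            }
            nt <- numeric(length(t_ph))
            don <- ch == "D"
            nt[don] <- stats::rexp(sum(don),
                                   1 / (sp$donor_lifetime_unquenched *
                                          max(1 - E, 1e-3)))
            nt[!don] <- stats::rexp(sum(!don), 1 / 1.5)
          } else if (sp$kind == "donor_only") {
            # no acceptor: every photon comes from donor excitation; leakage
            # alone can put some in the acceptor channel
            ch <- ifelse(stats::runif(N) < acq$alpha / (1 + acq$alpha),
                         "A", "D")
            pe <- rep("Dex", N)
            E <- 0
            nt <- stats::rexp(N, 1 / sp$donor_lifetime_unquenched)
          } else { # acceptor_only
            ch <- rep("A", N)
            pe <- rep("Aex", N)
            if (acq$delta > 0) {
              # direct excitation during the donor period
              pe[stats::runif(N) < acq$delta / (1 + acq$delta)] <- "Dex"
            }
            nt <- stats::rexp(N, 1 / 1.5)
          }
          bl_t[[b]] <- t_ph; bl_ch[[b]] <- ch; bl_pe[[b]] <- pe
          bl_nt[[b]] <- nt; bl_id[[b]] <- rep(b, length(t_ph))
        }
        tr_state[b] <- state; tr_R[b] <- Rda; tr_E[b] <- E
        tr_start[b] <- starts[b]; tr_dur[b] <- tdur * 1000
        tr_N[b] <- N; tr_bleach[b] <- bleached
      }
      ph_t <- c(ph_t, unlist(bl_t, use.names = FALSE))
      ph_ch <- c(ph_ch, unlist(bl_ch, use.names = FALSE))
      ph_pe <- c(ph_pe, unlist(bl_pe, use.names = FALSE))
      ph_nt <- c(ph_nt, unlist(bl_nt, use.names = FALSE))
      ph_burst <- c(ph_burst, unlist(bl_id, use.names = FALSE))
      truth <- data.frame(
        burst = seq_len(n_bursts),
        species = vapply(species[sp_idx], `[[`, "", "label"),
        kind = vapply(species[sp_idx], `[[`, "", "kind"),
        state = tr_state, distance_nm = tr_R, efficiency = tr_E,
        start_s = tr_start, duration_ms = tr_dur, n_photons = tr_N,
        bleached = tr_bleach, stringsAsFactors = FALSE)
    }

    o <- order(ph_t)
    photons <- data.frame(
      timestamp = round(ph_t[o] * acq$clock_rate),
      channel = ph_ch[o], period = ph_pe[o], nanotime = ph_nt[o],
      truth_burst = ph_burst[o],
      stringsAsFactors = FALSE
    )
    structure(list(photons = photons, clock_rate = acq$clock_rate,
                   settings = acq, truth = truth),
              class = "photon_stream")
  })
}

#' @export
print.photon_stream <- function(x, ...) {
  cat(sprintf("PIE photon stream: %d photons over %.1f s (clock %g Hz)\n",
              nrow(x$photons), x$settings$duration, x$clock_rate))
  tab <- table(x$photons$period, x$photons$channel)
  print(tab)
  if (!is.null(x$truth))
    cat(sprintf("%d simulated molecule transits\n", nrow(x$truth)))
  invisible(x)
}

#' Simulate a corrector dose-response table
#'
#' Draws folded fractions around the four-parameter logistic curve
#' ([logistic4()]) with Gaussian noise, clamped to [0, 1].
#'
#' @param params Named list/vector with `f_min`, `f_max`, `EC50`, `n`.
#' @param concentrations Corrector concentrations (uM, >= 0).
#' @param noise_sd Gaussian noise on the folded fraction (fraction units).
#' @param replicates Replicates per concentration.
#' @param seed Optional integer seed.
#' @return data.frame with columns `concentration_uM`, `replicate`, `f_F`.
#' @export
simulate_dose_response <- function(params, concentrations, noise_sd = 0.03,
                                   replicates = 3, seed = NULL) {
  params <- as.list(params)
  stopifnot(all(c("f_min", "f_max", "EC50", "n") %in% names(params)))
  if (params$EC50 <= 0) stop("EC50 must be > 0")
  if (params$n <= 0) stop("n must be > 0")
  if (any(concentrations < 0)) stop("concentrations must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  with_seed(seed, {
    conc <- rep(concentrations, each = replicates)
    mu <- logistic4(conc, params$f_min, params$f_max, params$EC50, params$n)
    f <- pmin(pmax(mu + stats::rnorm(length(conc), 0, noise_sd), 0), 1)
    data.frame(concentration_uM = conc,
               replicate = rep(seq_len(replicates), length(concentrations)),
               f_F = f)
  })
}
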