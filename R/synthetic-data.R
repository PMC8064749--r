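.defaults_env <- new.env(parent = emptyenv())

#' Default synthetic-cohort parameters
#'
#' Reads (and caches) the generator defaults shipped with the package:
#' heat-response rate models for QC and SC fibers, per-compound pruritogen
#' response targets, rating-curve shapes per stimulus and sensory quality,
#' dysesthesia/wheal/flare area models, and marker joint-expression
#' distributions for the ISH panels.
#'
#' @return Nested list mirroring `inst/extdata/fiber_defaults.yaml`.
#' @export
fiber_defaults <- function() {
  if (is.null(.defaults_env$cfg)) {
    path <- system.file("extdata", "fiber_defaults.yaml", package = "pruriphys")
    .defaults_env$cfg <- yaml::read_yaml(path)
  }
  .defaults_env$cfg
}

#' Fiber model for the synthetic generators
#'
#' Bundles the heat-response and pruritogen-response parameters of one
#' fiber type. Individual parameters can be overridden.
#'
#' @param type Fiber type: `"QC"`, `"SC"`, `"C_MIA"`, `"A_MSA"`, `"A_MIA"`.
#' @param heat Named list overriding heat-rate parameters (QC/SC only).
#' @param pruritogens Named list overriding per-compound parameters, e.g.
#'   `list(ALA = list(target_net_aps = 50))`.
#' @return A list of class `fiber_model`.
#' @export
fiber_model <- function(type = c("QC", "SC", "C_MIA", "A_MSA", "A_MIA"),
                        heat = list(), pruritogens = list()) {
  type <- match.arg(type)
  cfg <- fiber_defaults()
  h <- cfg$heat[[type]]
  if (!is.null(h)) h[names(heat)] <- heat
  p <- cfg$pruritogens[[type]]
  for (cp in names(pruritogens)) {
    if (is.null(p[[cp]])) p[[cp]] <- list()
    p[[cp]][names(pruritogens[[cp]])] <- pruritogens[[cp]]
  }
  for (cp in names(p)) {
    pp <- p[[cp]]
    if (pp$response_prob < 0 || pp$response_prob > 1) {
      stop("response probability must be in [0, 1]")
    }
    if (pp$target_net_aps < 0 || pp$decay_tau_s <= 0) {
      stop("rates and targets must be non-negative")
    }
  }
  structure(list(type = type, heat = h, pruritogens = p),
            class = "fiber_model")
}

# Heat-response rate function (spikes/s at the receptive field) for one
# fiber type, as a function of time since stimulus onset.
heat_rate_fn <- function(model, stimulus) {
  rise <- stimulus$rise_time
  plat <- stimulus$plateau_duration
  h <- model$heat
  if (model$type == "QC") {
    function(t) {
      ifelse(t >= 0 & t < rise, h$burst_rate_hz,
        ifelse(t >= rise & t <= rise + plat,
               h$plateau_init_hz * exp(-(t - rise) / h$adapt_tau_s), 0))
    }
  } else if (model$type == "SC") {
    tp <- rise + h$peak_time_in_plateau_s
    function(t) {
      ifelse(t >= 0 & t <= rise + plat,
             h$peak_rate_hz * exp(-0.5 * ((t - tp) / h$peak_sd_s)^2), 0)
    }
  } else {
    function(t) rep(0, length(t))   # heat-insensitive archetype
  }
}

# Inhomogeneous Poisson process on [0, t_max] by thinning.
sim_inhomogeneous_poisson <- function(rate_fn, t_max, rate_max) {
  if (rate_max <= 0) return(numeric(0))
  out <- numeric(0)
  t <- 0
  repeat {
    t <- t + stats::rexp(1, rate_max)
    if (t > t_max) break
    if (stats::runif(1) <= rate_fn(t) / rate_max) out <- c(out, t)
  }
  out
}

# Noise-free archetype: spike times where the integrated rate crosses
# 0.5, 1.5, 2.5, ... (the expected spike positions of the rate profile).
deterministic_spike_times <- function(rate_fn, t_max, dt = 5e-4) {
  grid <- seq(0, t_max, by = dt)
  lam <- cumsum(rate_fn(grid)) * dt
  total <- lam[length(lam)]
  if (total < 0.5) return(numeric(0))
  targets <- seq(0.5, total, by = 1)
  lam <- lam + seq_along(lam) * 1e-12   # enforce strict monotonicity
  stats::approx(lam, grid, xout = targets, ties = "ordered")$y
}

#' Generate a heat-evoked spike train with known ground truth
#'
#' Simulates the response of a QC or SC fiber to the stepped heat stimulus
#' as an inhomogeneous Poisson process: QC fibers fire at a high constant
#' rate during the temperature rise and then adapt exponentially during
#' the plateau; SC fibers follow a Gaussian rate bump peaking during the
#' plateau with no onset burst. Recorded spike times lag emission by the
#' fiber's conduction latency from skin. With `noise = FALSE` a
#' deterministic archetype is produced (spikes at the expected positions
#' of the rate profile).
#'
#' @param type `"QC"` or `"SC"` (the emitted ground-truth label).
#' @param stimulus A [heat_stimulus()].
#' @param latency Conduction latency from skin in seconds; drawn uniformly
#'   from the configured C-fiber range (0.1-0.5 s) when `NULL`.
#' @param noise Poisson spiking (`TRUE`, default) or the deterministic
#'   archetype (`FALSE`).
#' @param rate_scale Multiplier on the rate profile (0 gives an empty train).
#' @param seed Optional RNG seed for reproducibility.
#' @param model Optional [fiber_model()] override.
#' @return List with `train` (a [spike_train()] whose metadata carries the
#'   latency), `true_type`, and `latency`.
#' @export
generate_heat_train <- function(type = c("QC", "SC"),
                                stimulus = heat_stimulus(),
                                latency = NULL, noise = TRUE,
                                rate_scale = 1, seed = NULL, model = NULL) {
  type <- match.arg(type)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(model)) model <- fiber_model(type)
  cfg <- fiber_defaults()
  if (is.null(latency)) {
    latency <- stats::runif(1, cfg$latency_range_s[1], cfg$latency_range_s[2])
  }
  base_fn <- heat_rate_fn(model, stimulus)
  rate_fn <- function(t) rate_scale * base_fn(t)
  t_max <- stimulus$rise_time + stimulus$plateau_duration
  rate_max <- max(rate_fn(seq(0, t_max, by = 1e-3)), 1e-9)
  emission <- if (noise) {
    sim_inhomogeneous_poisson(rate_fn, t_max, rate_max)
  } else {
    deterministic_spike_times(rate_fn, t_max)
  }
  ts <- sort(unique(emission + latency))
  cv <- stats::runif(1, 0.5, 1.5)   # C-fiber conduction velocity, m/s
  meta <- fiber_metadata(conduction_latency_skin = latency,
                         conduction_velocity = cv,
                         conduction_distance = cv * latency * 100)
  list(train = spike_train(ts, fiber_id = paste0(type, "_sim"), metadata = meta),
       true_type = type, latency = latency)
}

#' Generate a cohort of heat-evoked trains
#'
#' @param n_qc,n_sc Number of QC and SC fibers.
#' @param stimulus A [heat_stimulus()].
#' @param noise Passed to [generate_heat_train()].
#' @param seed Optional RNG seed.
#' @return List of entries as returned by [generate_heat_train()].
#' @export
generate_heat_cohort <- function(n_qc = 100, n_sc = 100,
                                 stimulus = heat_stimulus(), noise = TRUE,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  types <- c(rep("QC", n_qc), rep("SC", n_sc))
  lapply(seq_along(types), function(i) {
    e <- generate_heat_train(types[i], stimulus, noise = noise)
    e$train$fiber_id <- sprintf("%s_%03d", types[i], i)
    e
  })
}

#' Classify a generated heat cohort
#'
#' Runs [classify_heat_response()] on every fiber of a generated cohort
#' and tabulates predicted against true labels.
#'
#' @param cohort As returned by [generate_heat_cohort()].
#' @param stimulus The [heat_stimulus()] used to generate the cohort.
#' @param ... Passed to [classify_heat_response()] (tolerance, burst rule).
#' @return Data frame with `fiber_id`, `true_type`, `label`, `peak_time`,
#'   `equality_line_value`, `burst_at_onset`.
#' @export
classify_heat_cohort <- function(cohort, stimulus = heat_stimulus(), ...) {
  rows <- lapply(cohort, function(e) {
    cl <- classify_heat_response(e$train, stimulus, e$train$metadata, ...)
    data.frame(fiber_id = e$train$fiber_id, true_type = e$true_type,
               label = cl$label, peak_time = cl$peak_time,
               equality_line_value = cl$equality_line_value,
               burst_at_onset = cl$burst_at_onset, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate one intradermal injection recording
#'
#' Poisson model of a pruritogen (or vehicle) injection: spontaneous
#' baseline activity at `baseline_rate_hz` for 60 s before injection, a
#' low-rate artifact during the injection interval, and - in responsive
#' fibers - a post-injection discharge with exponentially decaying rate
#' whose integral over the observation window is set so that the expected
#' net response across fibers equals the configured target mean for that
#' fiber type and compound (non-responders contribute zero, so responders
#' receive `target/response_prob`). Vehicle recordings have no
#' post-injection discharge beyond the injection artifact.
#'
#' @param fiber_type `"QC"`, `"SC"`, `"C_MIA"`, `"A_MSA"`, or `"A_MIA"`.
#' @param compound `"ALA"` or `"BAM8_22"` (vehicle names are taken from
#'   the configured mapping when `vehicle = TRUE`).
#' @param vehicle Generate the paired vehicle recording instead.
#' @param responds Force the responder state (logical), or `NULL` to draw
#'   it from the configured response probability.
#' @param fiber_id Fiber identifier.
#' @param baseline_rate_hz Spontaneous rate; 0 by default (CMHs are
#'   essentially silent at rest, which also makes the configured target
#'   the exact expected net response).
#' @param observation_s Post-injection observation, s (default 300).
#' @param injection_s Injection-interval duration, s.
#' @param seed Optional RNG seed.
#' @param model Optional [fiber_model()] override.
#' @return An [injection_recording()].
#' @export
generate_injection <- function(fiber_type, compound, vehicle = FALSE,
                               responds = NULL, fiber_id = "sim",
                               baseline_rate_hz = 0, observation_s = 300,
                               injection_s = 10, seed = NULL, model = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(model)) model <- fiber_model(fiber_type)
  cfg <- fiber_defaults()
  pp <- model$pruritogens[[compound]]
  if (is.null(pp)) stop("no pruritogen parameters for compound ", compound)

  baseline_count <- stats::rpois(1, 60 * baseline_rate_hz)
  artifact <- sort(stats::runif(stats::rpois(1, 1.5), 0, injection_s))

  post <- numeric(0)
  label <- compound
  if (vehicle) {
    label <- cfg$vehicles[[compound]]
    if (is.null(label)) label <- paste0("VEH_", compound)
  } else {
    if (is.null(responds)) responds <- stats::runif(1) < pp$response_prob
    if (responds && pp$target_net_aps > 0) {
      tau <- pp$decay_tau_s
      frac <- 1 - exp(-observation_s / tau)
      expected <- pp$target_net_aps / max(pp$response_prob, 1e-12)
      n <- stats::rpois(1, expected)
      if (n > 0) {
        u <- stats::runif(n)
        post <- injection_s + sort(-tau * log(1 - u * frac))
      }
    }
  }
  if (baseline_rate_hz > 0) {
    n_bg <- stats::rpois(1, baseline_rate_hz * observation_s)
    post <- sort(c(post, injection_s + stats::runif(n_bg, 0, observation_s)))
  }
  spikes <- sort(unique(c(artifact, post)))
  injection_recording(fiber_id = fiber_id, compound = label,
                      baseline_count = baseline_count,
                      injection_interval = c(0, injection_s),
                      post_spikes = spikes,
                      observation_duration = observation_s)
}

#' Generate a vehicle/pruritogen recording pair for one fiber
#'
#' @inheritParams generate_injection
#' @return List with `vehicle` and `pruritogen` recordings sharing
#'   `fiber_id`, plus `responds` (the drawn ground truth).
#' @export
generate_injection_pair <- function(fiber_type, compound, fiber_id = "sim",
                                    responds = NULL, baseline_rate_hz = 0,
                                    seed = NULL, model = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(model)) model <- fiber_model(fiber_type)
  if (is.null(responds)) {
    responds <- stats::runif(1) <
      model$pruritogens[[compound]]$response_prob
  }
  veh <- generate_injection(fiber_type, compound, vehicle = TRUE,
                            fiber_id = fiber_id,
                            baseline_rate_hz = baseline_rate_hz, model = model)
  pru <- generate_injection(fiber_type, compound, responds = responds,
                            fiber_id = fiber_id,
                            baseline_rate_hz = baseline_rate_hz, model = model)
  list(vehicle = veh, pruritogen = pru, responds = responds)
}

#' Generate and score an injection cohort
#'
#' Simulates a cohort of fibers, each receiving a vehicle/pruritogen block
#' per compound (the paired design), and scores every block with
#' [net_response()].
#'
#' @param n_qc,n_sc Number of QC and SC fibers.
#' @param compounds Compounds injected into every fiber.
#' @param baseline_rate_hz Spontaneous rate passed to the generator.
#' @param seed Optional RNG seed.
#' @param window,threshold Scoring parameters (see [net_response()]).
#' @return Tidy data frame: `fiber_id`, `fiber_type`, `compound`,
#'   `net_aps`, `responsive`, `true_responder`.
#' @export
generate_injection_cohort <- function(n_qc = 29, n_sc = 31,
                                      compounds = c("ALA", "BAM8_22"),
                                      baseline_rate_hz = 0, seed = NULL,
                                      window = 300, threshold = 10) {
  if (!is.null(seed)) set.seed(seed)
  types <- c(rep("QC", n_qc), rep("SC", n_sc))
  rows <- list()
  for (i in seq_along(types)) {
    fid <- sprintf("%s_%03d", types[i], i)
    model <- fiber_model(types[i])
    for (cp in compounds) {
      pair <- generate_injection_pair(types[i], cp, fiber_id = fid,
                                      baseline_rate_hz = baseline_rate_hz,
                                      model = model)
      nr <- net_response(pair$pruritogen, pair$vehicle, window = window,
                         threshold = threshold)
      rows[[length(rows) + 1]] <- data.frame(
        fiber_id = fid, fiber_type = types[i], compound = cp,
        net_aps = nr$net_aps, responsive = nr$responsive,
        true_responder = pair$responds, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Smooth AR(1) rater noise: ratings drift rather than jump between
# successive 30-s reports.
ar1_noise <- function(n, sd, rho) {
  z <- stats::rnorm(n)
  e <- numeric(n)
  e[1] <- z[1]
  for (i in seq_len(n)[-1]) e[i] <- rho * e[i - 1] + sqrt(1 - rho^2) * z[i]
  sd * e
}

#' Generate gLMS rating sessions for a cohort of subjects
#'
#' Each subject rates itch, pricking/stinging and burning every 30 s after
#' each of the five stimuli (three single pruritogens and two
#' combinations). The mean percept follows a saturating-rise times
#' exponential-decay curve peaking 1-2 min after injection, with
#' histamine-containing stimuli decaying more slowly; subjects carry
#' multiplicative lognormal gains (overall and per quality), a per-cell
#' chance of not perceiving a quality at all, and smooth AR(1) rater
#' noise. Ratings below the "barely detectable" floor report as zero, and
#' each session applies the protocol stopping rule (minimum 5 min, maximum
#' 20 min, stop once every quality has three successive zeros).
#'
#' @param n_subjects Number of subjects.
#' @param stimuli Stimulus labels (defaults to the configured five).
#' @param seed Optional RNG seed.
#' @return Tidy ratings data frame: `subject_id`, `stimulus`, `quality`,
#'   `time_min`, `rating`.
#' @export
generate_rating_cohort <- function(n_subjects = 29, stimuli = NULL,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- fiber_defaults()$ratings
  if (is.null(stimuli)) stimuli <- names(cfg$stimuli)
  qualities <- cfg$qualities
  grid <- seq(0.5, 20, by = 0.5)
  rows <- list()
  for (s in seq_len(n_subjects)) {
    sid <- sprintf("S%02d", s)
    s_gain <- stats::rlnorm(1, 0, cfg$subject_gain_sdlog)
    q_gain <- stats::rlnorm(length(qualities), 0, cfg$quality_gain_sdlog)
    names(q_gain) <- qualities
    for (st in stimuli) {
      stim <- cfg$stimuli[[st]]
      mat <- sapply(qualities, function(q) {
        if (stats::runif(1) >= cfg$perceive_prob[[q]]) return(rep(0, length(grid)))
        mean_curve <- stim$peak[[q]] * s_gain * q_gain[[q]] *
          (1 - exp(-grid / cfg$rise_min)) * exp(-grid / stim$decay_min)
        r <- mean_curve *
          exp(ar1_noise(length(grid), cfg$noise_sdlog, cfg$noise_ar1))
        r[r < cfg$zero_floor] <- 0
        pmin(r, 100)
      })
      # protocol stop: first sample at/after 5 min where every quality has
      # three successive zeros
      stop_idx <- length(grid)
      for (i in which(grid >= 5)) {
        if (i >= 3 && all(mat[(i - 2):i, ] == 0)) { stop_idx <- i; break }
      }
      for (q in qualities) {
        rows[[length(rows) + 1]] <- data.frame(
          subject_id = sid, stimulus = st, quality = q,
          time_min = grid[seq_len(stop_idx)],
          rating = mat[seq_len(stop_idx), q], stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate dysesthesia, wheal and flare areas for a cohort
#'
#' Lognormal area model per measure with a multiplicative enlargement for
#' histamine-containing stimuli (histamine drives much larger wheal,
#' flare and dysesthesia areas than the MRGPR agonists).
#'
#' @param n_subjects Number of subjects.
#' @param seed Optional RNG seed.
#' @return Tidy data frame: `subject_id`, `stimulus`, `measure`, `area_cm2`.
#' @export
generate_area_cohort <- function(n_subjects = 29, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- fiber_defaults()
  stimuli <- names(cfg$ratings$stimuli)
  acfg <- cfg$areas
  rows <- list()
  for (s in seq_len(n_subjects)) {
    sid <- sprintf("S%02d", s)
    s_gain <- stats::rlnorm(1, 0, acfg$subject_sdlog)
    for (m in names(acfg$measures)) {
      mm <- acfg$measures[[m]]
      for (st in stimuli) {
        mult <- if (st %in% acfg$his_stimuli) mm$his_mult else 1
        area <- mm$base_cm2 * mult * s_gain *
          stats::rlnorm(1, 0, acfg$noise_sdlog)
        rows[[length(rows) + 1]] <- data.frame(
          subject_id = sid, stimulus = st, measure = m, area_cm2 = area,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a synthetic puncta cohort
#'
#' Draws a marker state per neuron from a configured joint distribution
#' over the panel's co-expression regions, then draws puncta counts from
#' well-separated negative-binomial distributions for positive and
#' negative states, so that thresholding recovers the states with a small
#' known error rate.
#'
#' @param n_donors Number of donors (or DRGs for macaque).
#' @param neurons_per_donor Neurons counted per donor.
#' @param species `"human"` (3-marker panel, threshold > 5) or `"macaque"`
#'   (2-marker panel, threshold > 3).
#' @param joint Optional named probability vector over co-expression
#'   regions (names like `"MRGPRD+MRGPRX1+TRPV1"`, single markers, and
#'   `"none"`); must be non-negative and sum to 1. Defaults to the
#'   configured joint for the species.
#' @param seed Optional RNG seed.
#' @return Tidy data frame: `species`, `donor_id`, `section_id`,
#'   `neuron_id`, `marker`, `puncta`.
#' @export
generate_puncta_cohort <- function(n_donors = 4, neurons_per_donor = 150,
                                   species = c("human", "macaque"),
                                   joint = NULL, seed = NULL) {
  species <- match.arg(species)
  if (!is.null(seed)) set.seed(seed)
  cfg <- fiber_defaults()$ish[[species]]
  panel <- cfg$panel
  if (is.null(joint)) joint <- unlist(cfg$joint)
  if (any(joint < 0) || abs(sum(joint) - 1) > 1e-6) {
    stop("inconsistent joint probabilities: must be non-negative and sum to 1")
  }
  region_markers <- lapply(names(joint), function(r) {
    if (r == "none") character(0) else strsplit(r, "+", fixed = TRUE)[[1]]
  })
  bad <- !vapply(region_markers, function(m) all(m %in% panel), logical(1))
  if (any(bad)) stop("joint regions name markers outside the panel")
  pos <- cfg$puncta$positive
  neg <- cfg$puncta$negative
  rows <- list()
  for (d in seq_len(n_donors)) {
    did <- sprintf("D%02d", d)
    states <- sample(seq_along(joint), neurons_per_donor, replace = TRUE,
                     prob = joint)
    for (i in seq_len(neurons_per_donor)) {
      on <- panel %in% region_markers[[states[i]]]
      puncta <- ifelse(on,
                       stats::rnbinom(length(panel), mu = pos$mu, size = pos$size),
                       stats::rnbinom(length(panel), mu = neg$mu, size = neg$size))
      rows[[length(rows) + 1]] <- data.frame(
        species = species, donor_id = did,
        section_id = sprintf("%s_sec%d", did, (i %% 3) + 1),
        neuron_id = sprintf("%s_n%03d", did, i),
        marker = panel, puncta = puncta, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
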