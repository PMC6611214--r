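#' Ground-truth parameters for a simulated single-item ERP experiment
#'
#' Bundles every parameter of the synthetic generator: the latent per-item
#' preference utilities, the ERP component templates (shape, latency,
#' topography, base amplitude), the microvolt-per-utility slopes linking
#' preference to component amplitude, trial noise, and the behavioural
#' choice/willingness-to-pay model. Downstream recovery tests read the truth
#' back from this object.
#'
#' The default design mirrors a 12-product shopping study: 36 participants,
#' 30 viewing trials per product (360 epochs per participant), epochs from
#' -200 to 3000 ms sampled at 512 Hz, and a pairwise-choice task of 66 pairs
#' per block repeated over 7 blocks (462 choice trials).
#'
#' @param n_participants number of simulated participants.
#' @param n_items number of products; utilities must have one entry each.
#' @param utilities latent preference per item, arbitrary units. The default
#'   `seq(n_items, 1)` makes item 1 the most preferred.
#' @param component_slopes named numeric, microvolts of component amplitude
#'   per unit utility for `p200`, `n200`, `lpp`, `psw`. A positive `n200`
#'   slope makes the (negative) N200 less deep for preferred items.
#' @param component_templates list of component descriptions as produced by
#'   [default_component_templates()]; each has a unit-peak time course, a
#'   base amplitude in microvolts and a channel topography with weights in
#'   \[0, 1\].
#' @param noise_sd total trial noise standard deviation, microvolts.
#' @param pink_noise_fraction fraction of noise variance carried by 1/f
#'   (pink) noise rather than white noise.
#' @param amp_jitter_sigma sigma of the multiplicative lognormal amplitude
#'   jitter applied per component per trial (mean 1).
#' @param subject_amp_sd SD of per-participant additive amplitude offsets
#'   per component, microvolts.
#' @param artifact_fraction fraction of trials receiving an injected spike
#'   artifact large enough to trip the rejection thresholds.
#' @param artifact_amplitude spike amplitude in microvolts.
#' @param choice_temperature softmax temperature of the pairwise choice
#'   model, in utility units; smaller is more deterministic.
#' @param utility_subject_sd SD of per-participant perturbations of the
#'   utilities used in the behavioural tasks (drives inter-subject
#'   disagreement).
#' @param trials_per_item viewing trials per product.
#' @param sampling_rate Hz.
#' @param epoch_window c(start, end) in ms around stimulus onset.
#' @param channels ordered 10-20 electrode labels.
#' @param wtp_slope currency units of bid per utility unit.
#' @param wtp_noise_sd SD of bid noise, currency units.
#' @param seed master seed; per-participant substreams are derived from it
#'   by fixed offsets (1009 for epochs, 2003 for choices, 3001 for bids).
#' @return an object of class `simulation_truth`.
#' @export
simulation_truth <- function(n_participants = 36,
                             n_items = 12,
                             utilities = seq(n_items, 1),
                             component_slopes = c(p200 = 0, n200 = 0.2,
                                                  lpp = 0.35, psw = 0.3),
                             component_templates = default_component_templates(),
                             noise_sd = 12,
                             pink_noise_fraction = 0.5,
                             amp_jitter_sigma = 0.3,
                             subject_amp_sd = 1.5,
                             artifact_fraction = 0.05,
                             artifact_amplitude = 200,
                             choice_temperature = 1,
                             utility_subject_sd = 3.75,
                             trials_per_item = 30,
                             sampling_rate = 512,
                             epoch_window = c(-200, 3000),
                             channels = c("F3", "Fz", "F4",
                                          "C3", "Cz", "C4",
                                          "P3", "Pz", "P4"),
                             wtp_slope = 3.5,
                             wtp_noise_sd = 5,
                             seed = 1L) {
  truth <- structure(list(
    n_participants = as.integer(n_participants),
    n_items = as.integer(n_items),
    utilities = as.numeric(utilities),
    component_slopes = component_slopes,
    component_templates = component_templates,
    noise_sd = noise_sd,
    pink_noise_fraction = pink_noise_fraction,
    amp_jitter_sigma = amp_jitter_sigma,
    subject_amp_sd = subject_amp_sd,
    artifact_fraction = artifact_fraction,
    artifact_amplitude = artifact_amplitude,
    choice_temperature = choice_temperature,
    utility_subject_sd = utility_subject_sd,
    trials_per_item = as.integer(trials_per_item),
    sampling_rate = sampling_rate,
    epoch_window = epoch_window,
    channels = channels,
    wtp_slope = wtp_slope,
    wtp_noise_sd = wtp_noise_sd,
    seed = as.integer(seed)
  ), class = "simulation_truth")
  validate_truth(truth)
  truth
}

#' Default ERP component templates
#'
#' Four canonical components: a P200 and N200 as Gaussian bumps with
#' fronto-central topography (the N200 negative-going), an LPP Gaussian with
#' centro-parietal topography, and a positive slow wave as a smoothed boxcar
#' spanning 800-3000 ms, also posterior-weighted.
#'
#' @return named list of template descriptions.
#' @export
default_component_templates <- function() {
  anterior <- c(F3 = 1, Fz = 1, F4 = 1, C3 = 0.5, Cz = 0.5, C4 = 0.5,
                P3 = 0.2, Pz = 0.2, P4 = 0.2)
  posterior <- c(F3 = 0.2, Fz = 0.2, F4 = 0.2, C3 = 0.6, Cz = 0.6, C4 = 0.6,
                 P3 = 1, Pz = 1, P4 = 1)
  list(
    p200 = list(shape = "gaussian", center = 180, width = 30,
                base = 6, topography = anterior),
    n200 = list(shape = "gaussian", center = 300, width = 50,
                base = -8, topography = anterior),
    lpp = list(shape = "gaussian", center = 600, width = 120,
               base = 3, topography = posterior),
    psw = list(shape = "boxcar", start = 800, end = 3000, edge = 50,
               base = 1.5, topography = posterior)
  )
}

validate_truth <- function(truth) {
  stopifnot(inherits(truth, "simulation_truth"))
  if (length(truth$utilities) != truth$n_items)
    stop("utilities must have exactly n_items (", truth$n_items, ") entries")
  if (truth$sampling_rate <= 0) stop("sampling_rate must be > 0")
  if (!(truth$epoch_window[1] < 0 && truth$epoch_window[2] > 0))
    stop("epoch_window must straddle stimulus onset (start < 0 < end)")
  if (truth$pink_noise_fraction < 0 || truth$pink_noise_fraction > 1)
    stop("pink_noise_fraction must lie in [0, 1]")
  for (nm in names(truth$component_templates)) {
    tm <- truth$component_templates[[nm]]
    topo <- tm$topography
    bad <- setdiff(names(topo), truth$channels)
    if (length(bad))
      stop("unknown channel in '", nm, "' topography: ",
           paste(bad, collapse = ", "))
    if (any(topo < 0 | topo > 1))
      stop("topography weights for '", nm, "' must lie in [0, 1]")
    if (tm$shape == "gaussian" && tm$width <= 0)
      stop("template '", nm, "' must have width > 0")
  }
  invisible(truth)
}

#' Time grid of an epoch
#' @param truth a `simulation_truth`.
#' @return numeric vector of sample times in ms, strictly increasing and
#'   containing stimulus onset (t = 0) within one sample step.
#' @export
epoch_times <- function(truth) {
  step <- 1000 / truth$sampling_rate
  seq(truth$epoch_window[1], truth$epoch_window[2], by = step)
}

## unit-peak time course of one component
template_curve <- function(tmpl, times) {
  if (tmpl$shape == "gaussian") {
    exp(-((times - tmpl$center)^2) / (2 * tmpl$width^2))
  } else if (tmpl$shape == "boxcar") {
    stats::plogis((times - tmpl$start) / tmpl$edge) *
      stats::plogis((tmpl$end - times) / tmpl$edge)
  } else {
    stop("unknown template shape: ", tmpl$shape)
  }
}

## matrix (nt x nseries) of unit-variance 1/f noise, via spectral shaping
pink_noise_matrix <- function(nt, nseries) {
  w <- matrix(stats::rnorm(nt * nseries), nt, nseries)
  if (nt < 4) return(w)
  f <- c(0, pmin(seq_len(nt - 1), rev(seq_len(nt - 1))))
  scale <- c(0, 1 / sqrt(f[-1]))
  x <- Re(stats::mvfft(stats::mvfft(w) * scale, inverse = TRUE)) / nt
  x / stats::sd(x)
}

#' Simulate single-trial EEG epochs
#'
#' Every epoch is the sum over components of
#' `template(t) * topography(channel) * amplitude`, where the amplitude is
#' `base + slope * utility_item + participant offset`, scaled by a
#' multiplicative lognormal trial jitter, plus a white/pink noise mixture.
#' A configurable fraction of trials receives a single-sample voltage spike
#' exceeding the artifact-rejection thresholds; those trials are flagged in
#' `artifact_flags` (generator ground truth — the rejection stage detects
#' them independently).
#'
#' Deterministic for a fixed `truth$seed`: participant `p` uses the
#' substream seeded with `seed + 1009 * p`.
#'
#' @param truth a `simulation_truth`.
#' @return an `epoch_set`: list with `data` (participant x item x trial x
#'   channel x time array, microvolts), `channels`, `times` (ms), and
#'   `artifact_flags` (participant x item x trial x channel).
#' @export
simulate_epochs <- function(truth) {
  validate_truth(truth)
  times <- epoch_times(truth)
  nt <- length(times)
  P <- truth$n_participants; I <- truth$n_items
  R <- truth$trials_per_item; C <- length(truth$channels)

  curves <- lapply(truth$component_templates, template_curve, times = times)
  topos <- lapply(truth$component_templates, function(tm) {
    w <- numeric(C); names(w) <- truth$channels
    w[names(tm$topography)] <- tm$topography
    w
  })
  comp_names <- names(truth$component_templates)

  data <- array(0, dim = c(P, I, R, C, nt),
                dimnames = list(NULL, NULL, NULL, truth$channels, NULL))
  flags <- array(FALSE, dim = c(P, I, R, C),
                 dimnames = list(NULL, NULL, NULL, truth$channels))
  sig <- truth$amp_jitter_sigma

  for (p in seq_len(P)) {
    set.seed(truth$seed + 1009L * p)
    subj_off <- stats::rnorm(length(comp_names), 0, truth$subject_amp_sd)
    names(subj_off) <- comp_names
    ep <- array(0, dim = c(I, R, C, nt))
    for (k in comp_names) {
      slope <- if (k %in% names(truth$component_slopes))
        truth$component_slopes[[k]] else 0
      amp_item <- truth$component_templates[[k]]$base +
        slope * truth$utilities + subj_off[[k]]
      jitter <- if (sig > 0)
        matrix(stats::rlnorm(I * R, -sig^2 / 2, sig), I, R)
      else matrix(1, I, R)
      amp <- amp_item * jitter              # I x R, recycles by row
      spat <- outer(topos[[k]], curves[[k]])  # C x nt
      ep <- ep + array(outer(as.vector(amp), as.vector(spat)),
                       dim = c(I, R, C, nt))
    }
    if (truth$noise_sd > 0) {
      f <- truth$pink_noise_fraction
      noise <- array(0, dim = c(nt, I * R * C))
      if (f < 1)
        noise <- noise + sqrt(1 - f) * truth$noise_sd *
          matrix(stats::rnorm(nt * I * R * C), nt)
      if (f > 0)
        noise <- noise + sqrt(f) * truth$noise_sd *
          pink_noise_matrix(nt, I * R * C)
      ## noise columns are (item, trial, channel) in array order
      ep <- ep + aperm(array(noise, dim = c(nt, I, R, C)), c(2, 3, 4, 1))
    }
    if (truth$artifact_fraction > 0) {
      hit <- matrix(stats::runif(I * R) < truth$artifact_fraction, I, R)
      for (idx in which(hit)) {
        i <- (idx - 1) %% I + 1
        r <- (idx - 1) %/% I + 1
        ch <- sample.int(C, 1)
        t0 <- sample(which(times > 0), 1)
        ep[i, r, ch, t0] <- ep[i, r, ch, t0] +
          sample(c(-1, 1), 1) * truth$artifact_amplitude
        flags[p, i, r, ch] <- TRUE
      }
    }
    data[p, , , , ] <- ep
  }
  structure(list(data = data, channels = truth$channels, times = times,
                 artifact_flags = flags, truth = truth),
            class = "epoch_set")
}

#' Simulate the pairwise-choice task
#'
#' Bradley-Terry style choices: each participant carries perturbed utilities
#' `u_p = utilities + N(0, utility_subject_sd)` and chooses item a over b
#' with probability `plogis((u_a - u_b) / choice_temperature)`. All
#' `choose(n_items, 2)` pairs appear once per block, with the block design
#' repeated `n_blocks` times and left/right position randomised.
#'
#' @param truth a `simulation_truth`.
#' @param n_blocks number of block repetitions (7 in the emulated design).
#' @return data.frame with columns `participant`, `block`, `item_a`,
#'   `item_b`, `chosen`, `side` (screen side of the chosen item).
#' @export
simulate_choices <- function(truth, n_blocks = 7L) {
  validate_truth(truth)
  if (truth$choice_temperature <= 0)
    stop("choice_temperature must be > 0")
  pairs <- utils::combn(truth$n_items, 2)
  npair <- ncol(pairs)
  out <- vector("list", truth$n_participants)
  for (p in seq_len(truth$n_participants)) {
    set.seed(truth$seed + 2003L * p)
    u <- truth$utilities + stats::rnorm(truth$n_items, 0, truth$utility_subject_sd)
    blocks <- lapply(seq_len(n_blocks), function(b) {
      ord <- sample.int(npair)
      a <- pairs[1, ord]; bb <- pairs[2, ord]
      p_a <- stats::plogis((u[a] - u[bb]) / truth$choice_temperature)
      pick_a <- stats::runif(npair) < p_a
      chosen <- ifelse(pick_a, a, bb)
      a_left <- stats::runif(npair) < 0.5
      side <- ifelse(pick_a == a_left, "left", "right")
      data.frame(participant = p, block = b, item_a = a, item_b = bb,
                 chosen = chosen, side = side)
    })
    out[[p]] <- do.call(rbind, blocks)
  }
  do.call(rbind, out)
}

#' Simulate the willingness-to-pay (BDM auction) task
#'
#' Each participant bids `clip(wtp_slope * u_p + noise, 0, allocation)` for
#' every item from a fixed virtual allocation; a hidden price is drawn
#' uniformly on \[0, allocation\] and the item counts as purchased when the
#' bid exceeds it (Becker-DeGroot-Marschak rule).
#'
#' @param truth a `simulation_truth`.
#' @param allocation budget per item in currency units (default 50).
#' @return data.frame with columns `participant`, `item`, `bid`,
#'   `hidden_price`, `purchased`.
#' @export
simulate_wtp <- function(truth, allocation = 50) {
  validate_truth(truth)
  out <- vector("list", truth$n_participants)
  for (p in seq_len(truth$n_participants)) {
    set.seed(truth$seed + 3001L * p)
    u <- truth$utilities + stats::rnorm(truth$n_items, 0, truth$utility_subject_sd)
    bid <- pmin(pmax(truth$wtp_slope * u +
                       stats::rnorm(truth$n_items, 0, truth$wtp_noise_sd),
                     0), allocation)
    hidden <- stats::runif(truth$n_items, 0, allocation)
    out[[p]] <- data.frame(participant = p, item = seq_len(truth$n_items),
                           bid = bid, hidden_price = hidden,
                           purchased = bid > hidden)
  }
  do.call(rbind, out)
}
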