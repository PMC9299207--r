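#' Parametric beat morphology
#'
#' One cardiac cycle is modeled as the sum of a systolic and a diastolic
#' (dicrotic) Gaussian lobe. Centers are fractions of the instantaneous beat
#' period; widths are in seconds. This minimal two-lobe model reproduces the
#' qualitative PPG morphology variants seen across subjects -- steep or broad
#' systolic upstrokes, a pronounced dicrotic notch, or a diastolic wave fused
#' into the systolic decay.
#'
#' @param sys_amp,sys_width_s,sys_center_frac Systolic lobe amplitude, width
#'   (s) and center (fraction of the period).
#' @param dia_amp,dia_width_s,dia_center_frac Diastolic lobe parameters.
#' @param preset_name Optional name.
#' @return A list of class `beat_model`.
#' @export
beat_model <- function(sys_amp = 1, sys_width_s = 0.10, sys_center_frac = 0.30,
                       dia_amp = 0.35, dia_width_s = 0.12,
                       dia_center_frac = 0.65, preset_name = "custom") {
  stopifnot(sys_amp > 0, dia_amp > 0, sys_width_s > 0, dia_width_s > 0,
            sys_center_frac > 0, sys_center_frac < dia_center_frac,
            dia_center_frac < 1)
  structure(list(sys_amp = sys_amp, sys_width_s = sys_width_s,
                 sys_center_frac = sys_center_frac, dia_amp = dia_amp,
                 dia_width_s = dia_width_s, dia_center_frac = dia_center_frac,
                 preset_name = preset_name),
            class = "beat_model")
}

#' Beat morphology presets
#'
#' Named [beat_model()]s spanning the common PPG variants: `classic`
#' (moderate notch), `steep_upstroke` (fast, narrow systole), `prominent_notch`
#' (deep dicrotic notch with a strong reflected wave), `fused_diastolic`
#' (diastolic wave merged into the systolic decay, no secondary minimum) and
#' `broad_systole` (slow, wide systolic lobe).
#'
#' @return Named list of `beat_model`s.
#' @export
ppg_presets <- function() {
  # diastolic widths are generous so the runoff fills the cycle, as in real
  # PPG: inter-beat valleys stay V-shaped instead of flattening out
  list(
    classic = beat_model(1.00, 0.100, 0.30, 0.40, 0.180, 0.60,
                         preset_name = "classic"),
    steep_upstroke = beat_model(1.00, 0.060, 0.22, 0.30, 0.160, 0.55,
                                preset_name = "steep_upstroke"),
    prominent_notch = beat_model(1.00, 0.075, 0.28, 0.45, 0.110, 0.60,
                                 preset_name = "prominent_notch"),
    fused_diastolic = beat_model(1.00, 0.090, 0.30, 0.50, 0.240, 0.45,
                                 preset_name = "fused_diastolic"),
    broad_systole = beat_model(1.00, 0.130, 0.35, 0.25, 0.150, 0.70,
                               preset_name = "broad_systole"))
}

#' Evaluate one beat of a morphology on a sample grid
#'
#' @param model A [beat_model()].
#' @param period_s Beat period in seconds.
#' @param fs Sampling rate in Hz.
#' @return Numeric amplitude series of one beat (onset to next onset).
#' @export
beat_waveform <- function(model, period_s = 1, fs = 300) {
  tt <- seq(0, period_s, by = 1 / fs)
  model$sys_amp * exp(-(tt - model$sys_center_frac * period_s)^2 /
                        (2 * model$sys_width_s^2)) +
    model$dia_amp * exp(-(tt - model$dia_center_frac * period_s)^2 /
                          (2 * model$dia_width_s^2))
}

#' Simulation specification
#'
#' Describes a synthetic PPG recording: duration, sampling rate, mean heart
#' rate, a respiratory oscillator that modulates beat amplitude (`am_depth`),
#' baseline (`bw_depth`) and instantaneous period (`fm_depth`), additive
#' white noise, and a morphology schedule (which [beat_model()] is active
#' from which time onward). All randomness flows from `seed`.
#'
#' @param duration_s Recording length in seconds.
#' @param fs Sampling rate in Hz (>= 20 so the 0.5--5 Hz band is resolvable).
#' @param hr_bpm Mean heart rate in beats per minute (30--180).
#' @param resp_rate_hz Respiratory rate in Hz.
#' @param am_depth,bw_depth,fm_depth Modulation depths in `[0, 1)`.
#' @param noise_sd Additive white-noise standard deviation (amplitude units).
#' @param seed Integer RNG seed.
#' @param morphology_schedule List of `list(time_s=, model=)` entries,
#'   sorted by time, first at 0.
#' @return A list of class `simulation_spec`.
#' @export
simulation_spec <- function(duration_s = 60, fs = 300, hr_bpm = 60,
                            resp_rate_hz = 0.25, am_depth = 0.15,
                            bw_depth = 0.15, fm_depth = 0.15,
                            noise_sd = 0.02, seed = 1,
                            morphology_schedule = NULL) {
  if (is.null(morphology_schedule)) {
    morphology_schedule <- list(list(time_s = 0, model = ppg_presets()$classic))
  }
  stopifnot(duration_s > 0, fs >= 20, hr_bpm >= 30, hr_bpm <= 180,
            resp_rate_hz > 0, am_depth >= 0, am_depth < 1,
            bw_depth >= 0, bw_depth < 1, fm_depth >= 0, fm_depth < 1,
            noise_sd >= 0)
  times <- vapply(morphology_schedule, `[[`, numeric(1), "time_s")
  if (any(times < 0) || any(times >= duration_s)) {
    stop("morphology_schedule times must lie in [0, duration_s)")
  }
  if (is.unsorted(times)) stop("morphology_schedule must be sorted by time")
  if (times[1] != 0) stop("morphology_schedule must start at time 0")
  structure(list(duration_s = duration_s, fs = fs, hr_bpm = hr_bpm,
                 resp_rate_hz = resp_rate_hz, am_depth = am_depth,
                 bw_depth = bw_depth, fm_depth = fm_depth,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 morphology_schedule = morphology_schedule),
            class = "simulation_spec")
}

#' Simulate a PPG stream with exact ground-truth fiducials
#'
#' Beat onsets are placed iteratively with instantaneous period
#' `60/hr * (1 + fm_depth * sin(2*pi*resp_rate*t))`; each beat is the active
#' morphology's two-Gaussian waveform, amplitude-scaled by
#' `1 + am_depth * sin(.)` at its onset; the baseline is shifted by
#' `bw_depth * sin(.)`; white noise of sd `noise_sd` is added last. A
#' lead-in beat before time zero is rendered (but not annotated) so that the
#' first annotated onset sits in a genuine inter-beat valley.
#'
#' Ground truth is computed on the noiseless signal and carried to the noisy
#' one: `EP` is the local minimum nearest each nominal onset (within a
#' quarter period), `SYS` the maximum of the beat, and `MS` the maximum of
#' the first derivative between them. `SYS`/`MS` are only annotated for
#' beats that fit entirely inside the recording.
#'
#' @param spec A [simulation_spec()].
#' @return A list: `stream` (noisy [signal_stream()]), `clean` (noiseless
#'   samples), `truth` (fiducial-point `data.frame`), `beat_times` (nominal
#'   onset seconds of annotated beats), `beat_periods`, and `spec`.
#' @export
simulate_ppg <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  fs <- spec$fs
  n <- as.integer(round(spec$duration_s * fs))
  t <- (seq_len(n) - 1) / fs
  T_bar <- 60 / spec$hr_bpm
  omega <- 2 * pi * spec$resp_rate_hz

  # onset placement; the lead-in beat starts one period before the first
  # annotated onset, which is offset from t = 0 so that the valley preceding
  # it lies strictly inside the record
  onsets <- numeric(0)
  periods <- numeric(0)
  o <- (0.15 - 1) * T_bar
  while (o < spec$duration_s) {
    Ti <- T_bar * (1 + spec$fm_depth * sin(omega * o))
    onsets <- c(onsets, o)
    periods <- c(periods, Ti)
    o <- o + Ti
  }

  sched_t <- vapply(spec$morphology_schedule, `[[`, numeric(1), "time_s")
  active_model <- function(time) {
    k <- findInterval(max(time, 0), sched_t)
    spec$morphology_schedule[[max(k, 1L)]]$model
  }

  clean <- numeric(n)
  for (b in seq_along(onsets)) {
    ob <- onsets[b]; Tb <- periods[b]
    mdl <- active_model(ob)
    amp <- 1 + spec$am_depth * sin(omega * ob)
    from <- max(1L, as.integer(floor((ob - 0.5 * Tb) * fs)) + 1L)
    to <- min(n, as.integer(ceiling((ob + 1.5 * Tb) * fs)) + 1L)
    if (from > to) next
    tt <- t[from:to]
    # lobe centers anchor to the nominal period: systolic and reflected-wave
    # timing are nearly fixed in real PPG, and period modulation is absorbed
    # by diastole
    sys_c <- ob + mdl$sys_center_frac * T_bar
    dia_c <- ob + mdl$dia_center_frac * T_bar
    # gated linear diastolic runoff: real PPG decays monotonically from
    # systole into the next onset, so inter-beat valleys are V-shaped; a
    # pure lobe sum would leave unphysiological flat segments instead
    tau <- tt - ob
    runoff <- 0.5 * mdl$sys_amp * stats::pnorm((tau - (sys_c - ob)) /
                                                 mdl$sys_width_s) *
      pmax(0, 1 - tau / Tb)
    clean[from:to] <- clean[from:to] +
      amp * (mdl$sys_amp * exp(-(tt - sys_c)^2 / (2 * mdl$sys_width_s^2)) +
             mdl$dia_amp * exp(-(tt - dia_c)^2 / (2 * mdl$dia_width_s^2)) +
             runoff)
  }
  clean <- clean + spec$bw_depth * sin(omega * t)
  noisy <- clean + stats::rnorm(n, 0, spec$noise_sd)

  # ground truth on the noiseless signal, annotated beats only (onset >= 0)
  ann <- which(onsets >= -1e-9)
  dclean <- diff(clean)
  ep_idx <- integer(0); ms_idx <- integer(0); sys_idx <- integer(0)
  beat_times <- numeric(0); beat_periods <- numeric(0)
  for (b in ann) {
    ob <- onsets[b]; Tb <- periods[b]
    Tprev <- if (b > 1) periods[b - 1] else Tb
    nom <- as.integer(round(ob * fs)) + 1L
    w0 <- max(1L, nom - as.integer(round(0.25 * Tprev * fs)))
    w1 <- min(n, nom + as.integer(round(0.25 * Tb * fs)))
    if (w0 >= w1) next
    ep <- w0 - 1L + which.min(clean[w0:w1])
    ep_idx <- c(ep_idx, ep)
    beat_times <- c(beat_times, ob)
    beat_periods <- c(beat_periods, Tb)
    if (ob + Tb < spec$duration_s) {  # full beats get SYS and MS
      bend <- min(n, as.integer(round((ob + Tb) * fs)) + 1L)
      sys <- ep - 1L + which.max(clean[ep:bend])
      if (sys > ep + 1L) {
        ms <- ep - 1L + which.max(dclean[ep:(sys - 1L)])
        sys_idx <- c(sys_idx, sys)
        ms_idx <- c(ms_idx, ms)
      }
    }
  }
  truth <- rbind(
    fiducial_points(ep_idx, (ep_idx - 1) / fs, rep("EP", length(ep_idx))),
    fiducial_points(ms_idx, (ms_idx - 1) / fs, rep("MS", length(ms_idx))),
    fiducial_points(sys_idx, (sys_idx - 1) / fs, rep("SYS", length(sys_idx))))
  truth <- truth[order(truth$timestamp, truth$label), , drop = FALSE]

  list(stream = signal_stream(noisy, fs = fs, t0 = 0), clean = clean,
       truth = truth, beat_times = beat_times, beat_periods = beat_periods,
       spec = spec)
}

#' Standard synthetic evaluation suite
#'
#' Builds the specifications of the seeded multi-subject stress suite used
#' to benchmark the segmenters: `n_subjects` recordings of `duration_s`
#' seconds, morphology presets and mean heart rates cycling across subjects,
#' respiratory modulation depths (amplitude, baseline, frequency) drawn
#' uniformly from `depth_range` per subject, and white noise calibrated to
#' `snr_db` against each subject's noiseless waveform.
#'
#' @param n_subjects Number of recordings.
#' @param duration_s Length of each recording in seconds.
#' @param seed Master seed; every subject's spec derives from it.
#' @param depth_range Range the three modulation depths are drawn from.
#' @param snr_db Signal-to-noise ratio of the additive noise, in dB.
#' @return A list of [simulation_spec()]s.
#' @export
standard_suite_specs <- function(n_subjects = 10, duration_s = 120, seed = 1,
                                 depth_range = c(0.1, 0.3), snr_db = 20) {
  presets <- ppg_presets()
  hrs <- c(60, 72, 84, 66, 78)
  lapply(seq_len(n_subjects), function(i) {
    set.seed(seed * 1000L + i)
    depths <- stats::runif(3, depth_range[1], depth_range[2])
    base <- simulation_spec(
      duration_s = duration_s, fs = 300,
      hr_bpm = hrs[(i - 1) %% length(hrs) + 1],
      resp_rate_hz = 0.25,
      am_depth = depths[1], bw_depth = depths[2], fm_depth = depths[3],
      noise_sd = 0, seed = seed * 1000L + i,
      morphology_schedule = list(list(
        time_s = 0,
        model = presets[[(i - 1) %% length(presets) + 1]])))
    clean <- simulate_ppg(base)$clean
    base$noise_sd <- stats::sd(clean - mean(clean)) / 10^(snr_db / 20)
    base
  })
}

#' Prime template from a simulation specification
#'
#' Re-simulates the specification noiselessly and extracts a typical full
#' cycle (onset to next onset) with exact fiducial indices -- the cycle
#' whose length is closest to the median cycle length, which is what an
#' expert asked for "a typical cardiac cycle" would annotate. When the
#' specification has no frequency modulation all cycles are identical, so
#' this is also the first cycle.
#'
#' @param spec A [simulation_spec()].
#' @param id Template identifier.
#' @return An [annotated_template()].
#' @export
make_prime_template <- function(spec, id = "prime") {
  stopifnot(inherits(spec, "simulation_spec"))
  nspec <- spec
  nspec$noise_sd <- 0
  sim <- simulate_ppg(nspec)
  ep <- sim$truth$index[sim$truth$label == "EP"]
  ms <- sim$truth$index[sim$truth$label == "MS"]
  sys <- sim$truth$index[sim$truth$label == "SYS"]
  if (length(ep) < 2 || length(ms) < 1 || length(sys) < 1) {
    stop("simulation too short to extract a template cycle")
  }
  lens <- diff(ep)
  k <- which.min(abs(lens - stats::median(lens)))
  s <- ep[k]; e <- ep[k + 1]
  ms1 <- ms[ms > s & ms < e][1]
  sys1 <- sys[sys > s & sys < e][1]
  if (is.na(ms1) || is.na(sys1)) stop("no full cycle for template extraction")
  annotated_template(sim$clean[s:e], fs = spec$fs, onset_idx = 1L,
                     ms_idx = ms1 - s + 1L, sys_idx = sys1 - s + 1L, id = id)
}
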