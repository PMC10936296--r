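# Synthetic lifting/lowering study generator.
#
# Emulates the structure of the emulator experiment: 10 participants x
# 7 conditions (C1-C6, NoExo) x 2 repetitions of a 5 s lift / 10 s hold /
# 5 s lower cycle; 8 surface-EMG channels at 1000 Hz; two load-cell
# channels (F_S, F_W) at 90 Hz; MVIC and rest recordings; per-condition
# body-map discomfort reports.  Force/EMG coupling is generative
# (model-driven), not fitted to any measured means.

#' EMG channel names used throughout the package
#'
#' Right/left multifidus (MF), erector spinae longissimus (ES), latissimus
#' dorsi (LD) and rectus abdominis (RA).
#' @return Character vector of 8 channel names.
#' @export
emg_channel_names <- function() {
  c("Rt_MF", "Lt_MF", "Rt_ES", "Lt_ES", "Rt_LD", "Lt_LD", "Rt_RA", "Lt_RA")
}

#' The 27 body segments of the localized discomfort map
#'
#' Labels for the Corlett-Bishop style body diagram used for VAS discomfort
#' localization.  `LB` (lower back), `LS`/`RS` (left/right shoulder) are the
#' segments the generator couples to device-to-body forces.
#' @return Character vector of 27 segment labels.
#' @export
body_segments <- function() {
  c("Neck", "LS", "RS", "UB", "MB", "LB",
    "L_UpperArm", "R_UpperArm", "L_Elbow", "R_Elbow",
    "L_Forearm", "R_Forearm", "L_Wrist", "R_Wrist",
    "L_Hand", "R_Hand", "L_Buttock", "R_Buttock",
    "L_Thigh", "R_Thigh", "L_Knee", "R_Knee",
    "L_Calf", "R_Calf", "L_Ankle", "R_Ankle", "Chest")
}

# run code with a private, restorable RNG stream
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Study configuration
#'
#' Defaults encode the experiment's structure: 10 participants, conditions
#' C1-C6 plus NoExo, two repetitions, 5/10/5 s lift/hold/lower cadence,
#' EMG at 1000 Hz, load cells at 90 Hz, lifted load 20% of body weight,
#' strap stiffness 700 N/m, and 3 of 10 participants carrying the
#' co-contractor EMG phenotype.
#'
#' @param n_participants number of participants.
#' @param conditions condition labels; `"NoExo"` is the no-device control.
#' @param repetitions repetitions per condition.
#' @param lift_s,hold_s,lower_s phase durations in seconds.
#' @param emg_rate,force_rate sampling rates in Hz.
#' @param strap_stiffness elastic strap stiffness in N/m.
#' @param load_fraction lifted load as a fraction of body weight.
#' @param n_cocontractors participants whose EMG rises with the exosuit.
#' @param torque_lever lever (m) converting load force to the peak assistive
#'   torque demanded of the device: `tau_peak = load_fraction * m * g *
#'   torque_lever`, scaled by a per-participant random effect.  The default
#'   0.06 m places peak device forces in the tens-of-newtons range typical
#'   of passive back-assist emulators.
#' @param hold_fraction static hold torque as a fraction of `tau_peak`.
#' @param task_intensity peak task EMG as a fraction of the MVIC range.
#' @param reducer_factor,cocontractor_factor multiplicative exo-condition
#'   EMG factors for the two phenotypes (back muscles).
#' @param ra_factor_weight how strongly rectus abdominis follows the
#'   phenotype factor (0 = identical activity with/without exosuit).
#' @param force_noise_sd load-cell noise SD in newtons.
#' @param vas_noise_sd discomfort report noise SD (VAS points).
#' @param report_threshold VAS above which a segment counts as reported.
#' @param f50_waist,f50_shoulder half-saturation forces (N) of the monotone
#'   force-to-VAS maps for the lower back and shoulder segments.
#' @param mvic_s,rest_s durations of the MVIC and rest recordings (s).
#' @param candidates a `config_candidates` table giving the per-condition
#'   pulley geometry; defaults to [study_candidates()].
#' @param geom_base base [exo_geometry()] for the anchors.
#' @param seed integer seed making the dataset fully reproducible.
#' @return Object of class `study_config`.
#' @export
study_config <- function(n_participants = 10,
                         conditions = c("C1", "C2", "C3", "C4", "C5", "C6", "NoExo"),
                         repetitions = 2,
                         lift_s = 5, hold_s = 10, lower_s = 5,
                         emg_rate = 1000, force_rate = 90,
                         strap_stiffness = 700,
                         load_fraction = 0.20,
                         n_cocontractors = 3,
                         torque_lever = 0.06,
                         hold_fraction = 0.2,
                         task_intensity = 0.5,
                         reducer_factor = 0.8,
                         cocontractor_factor = 1.25,
                         ra_factor_weight = 0.1,
                         force_noise_sd = 2,
                         vas_noise_sd = 0.3,
                         report_threshold = 0.5,
                         f50_waist = 150, f50_shoulder = 150,
                         mvic_s = 5, rest_s = 5,
                         candidates = study_candidates(),
                         geom_base = exo_geometry(p2 = c(0, 0.2)),
                         seed = 1L) {
  if (any(c(lift_s, hold_s, lower_s, mvic_s, rest_s) <= 0)) stop("durations must be positive")
  if (any(c(emg_rate, force_rate) <= 0)) stop("sampling rates must be positive")
  if (n_participants < 1 || repetitions < 1) stop("need >= 1 participant and repetition")
  if (n_cocontractors < 0 || n_cocontractors > n_participants) {
    stop("'n_cocontractors' must be between 0 and n_participants")
  }
  if (load_fraction <= 0 || strap_stiffness <= 0) stop("load and stiffness must be positive")
  if (anyDuplicated(conditions)) stop("duplicate condition labels")
  exo <- setdiff(conditions, "NoExo")
  miss <- setdiff(exo, candidates$name)
  if (length(miss)) stop("no candidate geometry for condition(s): ", paste(miss, collapse = ", "))
  structure(list(
    n_participants = as.integer(n_participants), conditions = conditions,
    repetitions = as.integer(repetitions),
    lift_s = lift_s, hold_s = hold_s, lower_s = lower_s,
    emg_rate = emg_rate, force_rate = force_rate,
    strap_stiffness = strap_stiffness, load_fraction = load_fraction,
    n_cocontractors = as.integer(n_cocontractors),
    torque_lever = torque_lever, hold_fraction = hold_fraction,
    task_intensity = task_intensity, reducer_factor = reducer_factor,
    cocontractor_factor = cocontractor_factor, ra_factor_weight = ra_factor_weight,
    force_noise_sd = force_noise_sd, vas_noise_sd = vas_noise_sd,
    report_threshold = report_threshold,
    f50_waist = f50_waist, f50_shoulder = f50_shoulder,
    mvic_s = mvic_s, rest_s = rest_s,
    candidates = candidates, geom_base = geom_base,
    seed = as.integer(seed)
  ), class = "study_config")
}

# normalized effort envelope on [0, 1]: raised-cosine pulses peaking at
# mid-lift and mid-lower, a static plateau during the hold
effort_envelope <- function(lift_s, hold_s, lower_s, rate, hold_fraction) {
  n_lift <- round(lift_s * rate); n_hold <- round(hold_s * rate)
  n_lower <- round(lower_s * rate)
  t_lift <- (seq_len(n_lift) - 1) / rate
  t_lower <- (seq_len(n_lower) - 1) / rate
  c(sin(pi * t_lift / lift_s)^2,
    rep(hold_fraction, n_hold),
    sin(pi * t_lower / lower_s)^2)
}

#' Strap tension time profile for one trial
#'
#' The trunk-supporting torque demand is a raised-cosine pulse during the
#' lift and during the lower (peak `tau_peak` at mid-phase) with a small
#' static plateau during the hold; the tension follows as
#' `T(t) = tau(t) / r_eff`.  `NoExo` trials carry zero tension.
#'
#' @param tau_peak peak assistive torque demand in newton-metres.
#' @param r_eff effective moment arm of the condition geometry (m, > 0).
#' @param lift_s,hold_s,lower_s phase durations (s).
#' @param rate sampling rate (Hz).
#' @param hold_fraction hold-phase torque as a fraction of `tau_peak`.
#' @return Numeric tension series in newtons.
#' @export
tension_profile <- function(tau_peak, r_eff, lift_s = 5, hold_s = 10,
                            lower_s = 5, rate = 90, hold_fraction = 0.2) {
  if (r_eff <= 0) stop_degenerate("tension_profile: r_eff must be positive")
  if (tau_peak < 0) stop("'tau_peak' must be non-negative")
  tau_peak * effort_envelope(lift_s, hold_s, lower_s, rate, hold_fraction) / r_eff
}

#' Load-cell force channels from a tension series
#'
#' `F_S(t) = T(t) + e`, `F_W(t) = K T(t) + e` with i.i.d. Gaussian noise.
#' Negative samples are clipped at zero when `clip = TRUE` (tensile and
#' compressive load cells cannot read below zero).
#'
#' @param tension tension series in newtons.
#' @param k_ratio waist/shoulder force ratio K of the condition geometry.
#' @param noise_sd load-cell noise SD (N).
#' @param clip clip negative samples at zero.
#' @return List with numeric series `F_S` and `F_W`.
#' @export
force_channels <- function(tension, k_ratio, noise_sd = 0, clip = TRUE) {
  n <- length(tension)
  f_s <- tension + stats::rnorm(n, 0, noise_sd)
  f_w <- k_ratio * tension + stats::rnorm(n, 0, noise_sd)
  if (clip) {
    f_s <- pmax(f_s, 0)
    f_w <- pmax(f_w, 0)
  }
  list(F_S = f_s, F_W = f_w)
}

# band-limited (20-400 Hz) zero-mean unit-RMS carrier noise
emg_carrier <- function(n, rate, filt) {
  x <- signal::filtfilt(filt, stats::rnorm(n))
  x / sqrt(mean(x^2))
}

#' Synthesize an 8-channel EMG recording for one trial
#'
#' Each channel is amplitude-modulated band-limited noise:
#' `x(t) = (rest + task_intensity * (mvic - rest) * envelope(t) * factor) *
#' carrier(t)` where the carrier is zero-mean, unit-RMS and band-limited to
#' 20-400 Hz so the analysis band-pass is approximately transparent to it.
#' In exo conditions the phenotype factor is < 1 for reducers and > 1 for
#' co-contractors on the back muscles; rectus abdominis channels get a
#' near-1 factor (abdominal activity barely changes with the exosuit).
#'
#' @param envelope normalized effort envelope at the EMG rate.
#' @param mvic_amp,rest_amp per-channel MVIC and rest RMS amplitudes (mV),
#'   named as [emg_channel_names()].
#' @param factor phenotype factor applied to back-muscle channels.
#' @param ra_factor factor applied to the RA channels.
#' @param task_intensity peak task amplitude as a fraction of the MVIC range.
#' @param rate EMG sampling rate (Hz).
#' @param filt band-pass filter object for the carrier (internal reuse).
#' @return Numeric matrix `length(envelope) x 8` in millivolts.
#' @export
emg_channels <- function(envelope, mvic_amp, rest_amp, factor = 1,
                         ra_factor = 1, task_intensity = 0.5, rate = 1000,
                         filt = NULL) {
  ch <- emg_channel_names()
  if (is.null(filt)) filt <- signal::butter(4, c(20, 400) / (rate / 2), type = "pass")
  n <- length(envelope)
  out <- matrix(0, n, length(ch), dimnames = list(NULL, ch))
  for (j in seq_along(ch)) {
    f <- if (grepl("_RA$", ch[j])) ra_factor else factor
    amp <- rest_amp[[ch[j]]] +
      task_intensity * (mvic_amp[[ch[j]]] - rest_amp[[ch[j]]]) * envelope * f
    out[, j] <- amp * emg_carrier(n, rate, filt)
  }
  out
}

# monotone saturating force -> VAS map
vas_map <- function(force, f50) 10 * force / (force + f50)

#' Discomfort report for one participant-condition
#'
#' VAS for the lower-back segment is a monotone saturating map of the peak
#' waist force; the two shoulder segments follow the peak shoulder force.
#' Scores are noise-perturbed and clipped to `[0, 10]`; a segment is
#' reported when its VAS exceeds `report_threshold`.  The remaining 24
#' segments are never reported by the generator.
#'
#' @param peak_fs,peak_fw peak shoulder and waist forces (N).
#' @param config a [study_config()] (noise and saturation parameters).
#' @return Data frame with columns `segment`, `vas`, `reported`.
#' @export
discomfort_reports <- function(peak_fs, peak_fw, config) {
  seg <- c("LB", "LS", "RS")
  base <- c(vas_map(peak_fw, config$f50_waist),
            vas_map(peak_fs, config$f50_shoulder),
            vas_map(peak_fs, config$f50_shoulder))
  vas <- pmin(10, pmax(0, base + stats::rnorm(3, 0, config$vas_noise_sd)))
  data.frame(segment = seg, vas = vas,
             reported = vas > config$report_threshold,
             stringsAsFactors = FALSE)
}

#' Generate a complete synthetic study
#'
#' Produces `n_participants x length(conditions) x repetitions` trials plus
#' per-participant MVIC and rest recordings and per participant-condition
#' discomfort reports.  Per-participant condition order is a seeded
#' permutation (emulating a Latin-square randomization).  Exactly
#' `n_cocontractors` participants carry the co-contractor phenotype.  The
#' result is bit-identical for identical seeds.
#'
#' @param config a [study_config()].
#' @return Object of class `study_dataset`: list with `config`,
#'   `participants`, `emg_params`, `trials`, `mvic`, `rest`, `discomfort`
#'   and a `truth` table of generator ground truth per trial.
#' @export
generate_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  with_seed(config$seed, generate_study_impl(config))
}

generate_study_impl <- function(config) {
  ch <- emg_channel_names()
  npart <- config$n_participants
  pids <- sprintf("P%02d", seq_len(npart))
  rtrunc <- function(n, mean, sd) {
    x <- stats::rnorm(n, mean, sd)
    pmin(pmax(x, mean - 3 * sd), mean + 3 * sd)
  }

  # --- participants: anthropometrics (cohort 171.14 +/- 9.37 cm,
  # 71.24 +/- 5.16 kg), phenotype split, random-effect scalars
  phenotype <- rep("reducer", npart)
  phenotype[sample.int(npart, config$n_cocontractors)] <- "cocontractor"
  participants <- data.frame(
    pid = pids,
    body_mass_kg = rtrunc(npart, 71.24, 5.16),
    stature_m = rtrunc(npart, 1.7114, 0.0937),
    phenotype = phenotype,
    force_scale = exp(stats::rnorm(npart, 0, 0.08)),
    stringsAsFactors = FALSE
  )

  base_mvic <- c(MF = 0.45, ES = 0.50, LD = 0.35, RA = 0.30)  # mV RMS
  emg_params <- stats::setNames(vector("list", npart), pids)
  for (i in seq_len(npart)) {
    muscle <- sub("^(Rt|Lt)_", "", ch)
    mvic_amp <- stats::setNames(base_mvic[muscle] * exp(stats::rnorm(8, 0, 0.15)), ch)
    rest_amp <- stats::setNames(stats::runif(8, 0.010, 0.020), ch)
    emg_params[[pids[i]]] <- list(mvic_amp = mvic_amp, rest_amp = rest_amp)
  }

  # --- condition geometry summaries
  exo_conditions <- setdiff(config$conditions, "NoExo")
  cand <- config$candidates
  geom_tab <- cand[match(exo_conditions, cand$name), , drop = FALSE]
  rownames(geom_tab) <- geom_tab$name

  filt <- signal::butter(4, c(20, 400) / (config$emg_rate / 2), type = "pass")
  env_emg <- effort_envelope(config$lift_s, config$hold_s, config$lower_s,
                             config$emg_rate, config$hold_fraction)
  n_force <- round((config$lift_s + config$hold_s + config$lower_s) * config$force_rate)

  # --- MVIC and rest recordings (per participant)
  mvic <- rest <- stats::setNames(vector("list", npart), pids)
  n_mvic <- round(config$mvic_s * config$emg_rate)
  t_mvic <- (seq_len(n_mvic) - 1) / config$emg_rate
  ramp <- pmin(1, pmin(t_mvic, config$mvic_s - 1 / config$emg_rate - t_mvic))  # 1 s ramps
  mvic_env <- pmin(1, pmax(0, ramp))
  n_rest <- round(config$rest_s * config$emg_rate)
  for (pid in pids) {
    pars <- emg_params[[pid]]
    m <- matrix(0, n_mvic, 8, dimnames = list(NULL, ch))
    r <- matrix(0, n_rest, 8, dimnames = list(NULL, ch))
    for (j in seq_along(ch)) {
      amp <- pars$rest_amp[j] + (pars$mvic_amp[j] - pars$rest_amp[j]) * mvic_env
      m[, j] <- amp * emg_carrier(n_mvic, config$emg_rate, filt)
      r[, j] <- pars$rest_amp[j] * emg_carrier(n_rest, config$emg_rate, filt)
    }
    mvic[[pid]] <- m
    rest[[pid]] <- r
  }

  # --- trials
  trials <- list()
  truth <- list()
  g <- 9.81
  for (i in seq_len(npart)) {
    pid <- pids[i]
    pars <- emg_params[[pid]]
    tau_peak <- config$load_fraction * participants$body_mass_kg[i] * g *
      config$torque_lever * participants$force_scale[i]
    order_i <- sample(config$conditions)  # seeded permutation per participant
    for (cond in order_i) {
      exo <- cond != "NoExo"
      if (exo) {
        r_eff <- geom_tab[cond, "r_eff"]
        k_ratio <- geom_tab[cond, "k_ratio"]
        tension <- tension_profile(tau_peak, r_eff, config$lift_s, config$hold_s,
                                   config$lower_s, config$force_rate,
                                   config$hold_fraction)
      } else {
        r_eff <- NA_real_; k_ratio <- NA_real_
        tension <- numeric(n_force)
      }
      base_factor <- if (!exo) 1
        else if (participants$phenotype[i] == "cocontractor") config$cocontractor_factor
        else config$reducer_factor
      ra_factor <- 1 + config$ra_factor_weight * (base_factor - 1)
      for (rep_i in seq_len(config$repetitions)) {
        if (exo) {
          fc <- force_channels(tension, k_ratio, config$force_noise_sd, clip = TRUE)
        } else {
          fc <- list(F_S = stats::rnorm(n_force, 0, config$force_noise_sd),
                     F_W = stats::rnorm(n_force, 0, config$force_noise_sd))
        }
        emg <- emg_channels(env_emg, pars$mvic_amp, pars$rest_amp,
                            factor = base_factor, ra_factor = ra_factor,
                            task_intensity = config$task_intensity,
                            rate = config$emg_rate, filt = filt)
        trials[[length(trials) + 1L]] <- list(
          pid = pid, condition = cond, repetition = rep_i,
          emg = emg, emg_rate = config$emg_rate,
          forces = cbind(F_S = fc$F_S, F_W = fc$F_W),
          force_rate = config$force_rate
        )
        truth[[length(truth) + 1L]] <- data.frame(
          pid = pid, condition = cond, repetition = rep_i,
          tau_peak = if (exo) tau_peak else 0,
          r_eff = r_eff, k_ratio = k_ratio,
          peak_tension = if (exo) tau_peak / r_eff else 0,
          peak_fw_true = if (exo) k_ratio * tau_peak / r_eff else 0,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  truth <- do.call(rbind, truth)

  # --- discomfort: one report per participant-condition (repetitions share
  # the same analytic peak forces; VAS noise drawn once per condition)
  disc <- list()
  for (i in seq_len(npart)) {
    pid <- pids[i]
    for (cond in config$conditions) {
      tt <- truth[truth$pid == pid & truth$condition == cond, ]
      rep_row <- discomfort_reports(mean(tt$peak_tension), mean(tt$peak_fw_true), config)
      rep_row <- rep_row[rep_row$reported, , drop = FALSE]
      if (nrow(rep_row)) {
        disc[[length(disc) + 1L]] <- cbind(pid = pid, condition = cond, rep_row)
      }
    }
  }
  disc <- if (length(disc)) do.call(rbind, disc) else
    data.frame(pid = character(), condition = character(), segment = character(),
               vas = numeric(), reported = logical(), stringsAsFactors = FALSE)
  rownames(disc) <- NULL

  structure(list(config = config, participants = participants,
                 emg_params = emg_params, trials = trials,
                 mvic = mvic, rest = rest, discomfort = disc, truth = truth),
            class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  cat("<study_dataset>\n")
  cat(sprintf("  %d participants x %d conditions x %d repetitions = %d trials\n",
              x$config$n_participants, length(x$config$conditions),
              x$config$repetitions, length(x$trials)))
  cat(sprintf("  EMG %g Hz (8 ch), forces %g Hz; seed %d\n",
              x$config$emg_rate, x$config$force_rate, x$config$seed))
  cat(sprintf("  co-contractors: %d; discomfort rows: %d\n",
              sum(x$participants$phenotype == "cocontractor"), nrow(x$discomfort)))
  invisible(x)
}
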