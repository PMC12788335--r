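#' Configuration for the synthetic sprint-signal generator
#'
#' The generator emulates the structure of shank-IMU recordings of the first
#' ~15 m of a sprint: about ten ground contacts whose durations shrink from
#' ~184 ms (step 1) to ~104 ms (steps 9-10), with the contact fraction of the
#' step cycle falling linearly from 77.4% at step 1 to 50% at step 8 and
#' constant after. Per-step contact durations are drawn from step-specific
#' Gaussians, rounded to frames and floored at 13 frames so that the
#' postprocessing filter (contacts < 12 frames removed) can never delete a
#' true contact.
#'
#' Signal morphology is an invention (the real waveforms are not public): a
#' damped-oscillation impact transient in `a_res` starting at each initial
#' contact plus a low stance bump, and a smooth Gaussian swing peak in
#' `w_res` centred mid-flight. What matters for the detector is that the two
#' channels carry class-discriminative temporal patterns at both short and
#' long receptive fields, with large amplitude heterogeneity across athletes
#' and steps (making per-run min-max scaling consequential).
#'
#' @param fs Sampling rate in Hz.
#' @param n_steps Number of ground contacts per run.
#' @param gc_means_ms,gc_sd_ms Per-step mean/SD contact times in ms. When
#'   `n_steps` exceeds the schedule length the last value is reused.
#' @param contact_fraction_step1,contact_fraction_step8 Fraction of the step
#'   cycle spent in contact at steps 1 and 8 (linear in between, constant
#'   after step 8).
#' @param impact_amp_range Range of the multiplicative per-athlete amplitude
#'   factor.
#' @param noise_sd Additive noise SD relative to the athlete's impact
#'   amplitude.
#' @param label_lag_frames Integer frame offset injected between the label
#'   and signal streams (positive = labels lead the signal); exercises the
#'   cross-correlation synchronization.
#' @param lead_flight_ms,tail_flight_ms Flight padding before the first and
#'   after the last contact.
#' @param seed Master RNG seed; athlete-level draws are keyed by athlete id
#'   so regenerating any subset of a study is split-stable.
#' @return A `gait_sim_config` list.
#' @export
gait_sim_config <- function(fs = 250,
                            n_steps = 10,
                            gc_means_ms = c(184, 175, 134, 132, 124, 122, 115, 114, 104, 104),
                            gc_sd_ms = c(30, 24, 16, 13, 13, 11, 12, 10, 12, 5),
                            contact_fraction_step1 = 0.774,
                            contact_fraction_step8 = 0.5,
                            impact_amp_range = c(0.6, 1.6),
                            noise_sd = 0.05,
                            label_lag_frames = 0L,
                            lead_flight_ms = 200,
                            tail_flight_ms = 200,
                            seed = NULL) {
  if (fs <= 0) abort("fs must be positive")
  if (n_steps < 1) abort("n_steps must be at least 1")
  if (any(gc_means_ms <= 0) || any(gc_sd_ms < 0)) {
    abort("contact-time means must be positive and SDs nonnegative")
  }
  fr <- c(contact_fraction_step1, contact_fraction_step8)
  if (any(fr <= 0) || any(fr >= 1)) {
    abort("contact fractions must lie strictly between 0 and 1 (otherwise flight time is nonpositive)")
  }
  pad <- function(x) c(x, rep(x[length(x)], max(0, n_steps - length(x))))[seq_len(n_steps)]
  structure(list(
    fs = fs, n_steps = n_steps,
    gc_means_ms = pad(gc_means_ms), gc_sd_ms = pad(gc_sd_ms),
    contact_fraction_step1 = contact_fraction_step1,
    contact_fraction_step8 = contact_fraction_step8,
    impact_amp_range = impact_amp_range, noise_sd = noise_sd,
    label_lag_frames = as.integer(label_lag_frames),
    lead_flight_ms = lead_flight_ms, tail_flight_ms = tail_flight_ms,
    seed = seed
  ), class = "gait_sim_config")
}

contact_fractions <- function(cfg) {
  steps <- seq_len(cfg$n_steps)
  f <- cfg$contact_fraction_step1 +
    (cfg$contact_fraction_step8 - cfg$contact_fraction_step1) *
      pmin(steps - 1, 7) / 7
  f
}

athlete_amp_factor <- function(cfg, athlete_id) {
  draw <- function() runif(1, cfg$impact_amp_range[1], cfg$impact_amp_range[2])
  if (is.null(cfg$seed)) draw() else {
    local_seed(hash_id("athlete", athlete_id, seed = cfg$seed), draw())
  }
}

#' Generate one synthetic sprint run
#'
#' Draws per-step contact durations from the configured Gaussians, derives
#' flight durations from the contact-fraction schedule, then synthesizes the
#' two resultant channels and the aligned binary label stream. Identical
#' seeds give bit-identical output; each (athlete, run, leg) gets its own
#' deterministic substream of the master seed.
#'
#' @param cfg A [gait_sim_config()].
#' @param athlete_id,run_id,leg Stream identity.
#' @return A [gc_run()] with a `label` column and a `true_segments`
#'   attribute (tibble `step`, `ic`, `tc`, `duration_frames`, `duration_ms`)
#'   describing the constructed ground truth relative to the signal stream.
#' @export
generate_run <- function(cfg, athlete_id = "A01", run_id = "R1", leg = "left") {
  stopifnot(inherits(cfg, "gait_sim_config"))
  amp <- athlete_amp_factor(cfg, athlete_id)
  body <- function() generate_run_impl(cfg, amp, athlete_id, run_id, leg)
  if (is.null(cfg$seed)) body() else {
    local_seed(hash_id("run", athlete_id, run_id, leg, seed = cfg$seed), body())
  }
}

generate_run_impl <- function(cfg, amp, athlete_id, run_id, leg) {
  fs <- cfg$fs
  dt <- 1000 / fs
  n <- cfg$n_steps

  contact_ms <- rnorm(n, cfg$gc_means_ms, cfg$gc_sd_ms)
  contact_fr <- pmax(13L, as.integer(round(contact_ms / dt)))
  frac <- contact_fractions(cfg)
  flight_ms <- contact_fr * dt * (1 / frac - 1)
  if (any(flight_ms <= 0)) abort("contact-fraction schedule produced nonpositive flight time")
  flight_fr <- pmax(1L, as.integer(round(flight_ms / dt)))

  lead <- as.integer(round(cfg$lead_flight_ms / dt))
  tail_ <- as.integer(round(cfg$tail_flight_ms / dt))
  n_frames <- lead + sum(contact_fr) + sum(flight_fr[-n]) + tail_

  ic <- integer(n)
  tc <- integer(n)
  pos <- lead
  for (i in seq_len(n)) {
    ic[i] <- pos + 1L
    tc[i] <- ic[i] + contact_fr[i]
    pos <- tc[i] - 1L + if (i < n) flight_fr[i] else 0L
  }

  a <- rep(1.0, n_frames)
  w <- rep(0.5, n_frames)
  lab <- integer(n_frames)

  imp_len <- as.integer(round(60 / dt))
  tau_ms <- 12
  f_osc <- 55
  for (i in seq_len(n)) {
    span <- ic[i]:(tc[i] - 1L)
    lab[span] <- 1L
    step_amp <- amp * exp(rnorm(1, 0, 0.15))
    # stance bump
    cf <- contact_fr[i]
    a[span] <- a[span] + 1.5 * step_amp * sin(pi * (seq_len(cf) - 0.5) / cf)
    w[span] <- w[span] + 1.0 * step_amp * sin(pi * (seq_len(cf) - 0.5) / cf)
    # impact transient at initial contact
    m <- min(imp_len, cf)
    tj <- (seq_len(m) - 1) * dt
    a[ic[i]:(ic[i] + m - 1L)] <- a[ic[i]:(ic[i] + m - 1L)] +
      8 * step_amp * exp(-tj / tau_ms) * abs(sin(2 * pi * f_osc * tj / 1000 + 0.3))
    # swing peak mid-flight
    if (i < n) {
      fl <- flight_fr[i]
      mid <- tc[i] + fl / 2
      span_f <- tc[i]:(tc[i] + fl - 1L)
      w[span_f] <- w[span_f] +
        6 * amp * exp(rnorm(1, 0, 0.15)) * exp(-((span_f - mid)^2) / (2 * (fl / 5)^2))
    }
  }

  a <- pmax(0, a + rnorm(n_frames, 0, cfg$noise_sd * 8 * amp))
  w <- pmax(0, w + rnorm(n_frames, 0, cfg$noise_sd * 6 * amp))

  lag <- cfg$label_lag_frames
  lab_out <- lab
  if (lag != 0) {
    lab_out <- integer(n_frames)
    src <- seq_len(n_frames) + lag # positive lag: labels lead the signal
    ok <- src >= 1 & src <= n_frames
    lab_out[ok] <- lab[src[ok]]
  }

  segs <- tibble(
    step = seq_len(n), ic = ic, tc = tc,
    duration_frames = contact_fr,
    duration_ms = contact_fr * dt
  )
  gc_run(a, w, lab_out, fs = fs, athlete_id = athlete_id, run_id = run_id,
    leg = leg, true_segments = segs
  )
}

#' Study design: athletes, runs, legs, exclusions and split assignment
#'
#' The default mirrors the study that motivated the package: 12 athletes
#' (6 female, 6 male) x 3 runs x 2 legs; run 3 of athlete 1 excluded
#' (sensor download failure), athletes 1 and 12 held out as the TEST group,
#' and within the remaining athletes runs 1-2 assigned to TRAIN and run 3 to
#' VAL. That yields 70 athlete-run-leg streams: 40 TRAIN, 20 VAL, 10 TEST.
#'
#' @param n_athletes,runs_per_athlete,legs Design dimensions.
#' @param exclusions Tibble with columns `athlete_id`, `run_id` of excluded
#'   runs.
#' @param test_athletes Athlete ids reserved exclusively for TEST.
#' @param val_run Run id assigned to VAL for non-test athletes.
#' @return A `gc_design` list with tibbles `athletes` and `streams` (the
#'   latter has one row per (athlete, run, leg) with `split` among
#'   TRAIN/VAL/TEST, `NA` for excluded rows).
#' @export
sprint_study_design <- function(n_athletes = 12, runs_per_athlete = 3,
                                legs = c("left", "right"),
                                exclusions = tibble(athlete_id = "A01", run_id = "R3"),
                                test_athletes = c("A01", "A12"),
                                val_run = "R3") {
  ids <- sprintf("A%02d", seq_len(n_athletes))
  athletes <- tibble(
    athlete_id = ids,
    sex = rep(c("m", "f"), length.out = n_athletes)
  )
  streams <- tidyr::expand_grid(
    athlete_id = ids,
    run_id = sprintf("R%d", seq_len(runs_per_athlete)),
    leg = legs
  )
  if (anyDuplicated(streams)) abort("duplicate (athlete, run, leg) in design")
  streams$excluded <- paste(streams$athlete_id, streams$run_id) %in%
    paste(exclusions$athlete_id, exclusions$run_id)
  streams$split <- dplyr::case_when(
    streams$excluded ~ NA_character_,
    streams$athlete_id %in% test_athletes ~ "TEST",
    streams$run_id == val_run ~ "VAL",
    TRUE ~ "TRAIN"
  )
  structure(list(athletes = athletes, streams = streams), class = "gc_design")
}

#' @export
print.gc_design <- function(x, ...) {
  tab <- table(x$streams$split[!x$streams$excluded])
  cat(sprintf(
    "<gc_design> %d athletes, %d streams (%d excluded): %s\n",
    nrow(x$athletes), nrow(x$streams), sum(x$streams$excluded),
    paste(names(tab), tab, sep = "=", collapse = ", ")
  ))
  invisible(x)
}

#' Generate a full synthetic study
#'
#' One synthetic run per non-excluded (athlete, run, leg) of the design, with
#' per-athlete amplitude factors drawn once per athlete (keyed by athlete id,
#' so any subset regenerates identically under the same master seed).
#'
#' @param cfg A [gait_sim_config()].
#' @param design A [sprint_study_design()].
#' @return A `gc_study` list: `runs` (named list of [gc_run()]s), `streams`
#'   (the design tibble restricted to generated rows, with a `stream_id`
#'   column), and `design`.
#' @export
generate_study <- function(cfg, design = sprint_study_design()) {
  stopifnot(inherits(design, "gc_design"))
  rows <- dplyr::filter(design$streams, !.data$excluded)
  rows$stream_id <- paste(rows$athlete_id, rows$run_id, rows$leg, sep = "/")
  if (anyDuplicated(rows$stream_id)) abort("duplicate (athlete, run, leg) in design")
  runs <- purrr::pmap(
    list(rows$athlete_id, rows$run_id, rows$leg),
    function(a, r, l) generate_run(cfg, a, r, l)
  )
  names(runs) <- rows$stream_id
  structure(list(runs = runs, streams = rows, design = design, config = cfg),
    class = "gc_study"
  )
}

#' Split a generated study into run lists by TRAIN/VAL/TEST
#'
#' @param study A `gc_study` from [generate_study()].
#' @return Named list of run lists, one per split.
#' @export
study_splits <- function(study) {
  stopifnot(inherits(study, "gc_study"))
  sp <- split(study$streams$stream_id, study$streams$split)
  lapply(sp, function(ids) study$runs[ids])
}

#' Write / read a study manifest
#'
#' The manifest is a YAML file listing athletes, stream rows (athlete, run,
#' leg, split, excluded) and the file each stream was written to.
#'
#' @param design A `gc_design`.
#' @param path Manifest file path.
#' @param files Optional character vector of per-stream file names.
#' @return `write_manifest()` returns `path` invisibly; `read_manifest()`
#'   the reconstructed `gc_design` (with a `file` column when present).
#' @export
write_manifest <- function(design, path, files = NULL) {
  streams <- design$streams
  if (!is.null(files)) streams$file <- files
  yaml::write_yaml(list(
    athletes = lapply(seq_len(nrow(design$athletes)), function(i) as.list(design$athletes[i, ])),
    streams = lapply(seq_len(nrow(streams)), function(i) as.list(streams[i, ]))
  ), path)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  raw <- yaml::read_yaml(path)
  design <- structure(list(
    athletes = dplyr::bind_rows(lapply(raw$athletes, as_tibble)),
    streams = dplyr::bind_rows(lapply(raw$streams, function(s) {
      s$split <- s$split %||% NA_character_
      as_tibble(s)
    }))
  ), class = "gc_design")
  design
}
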