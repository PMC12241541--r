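# Synthetic study generator: trial schedules, behavior, and parcellated BOLD
# with the statistical structure the downstream pipeline assumes.

#' Default region roles for the synthetic parcellation
#'
#' Assigns each region of the synthetic parcellation a role in the generative
#' model: responsive regions receive a trial-locked hemodynamic response whose
#' amplitude is `sign * (1 + gain * difficulty)`; a designated subset of the
#' positively responsive regions additionally responds `incorrect_delay`
#' seconds late on incorrect trials (a minimal mechanism for a temporally
#' imprecise response). Non-responsive regions are baseline noise only.
#'
#' Heterogeneity matters: were every responsive region scaled by the same
#' difficulty gain, the z-scored spatial pattern would be invariant to
#' difficulty (a common scale factor cancels under per-timepoint
#' normalization) and the difficulty axis would carry no regional signal.
#' The default therefore mixes difficulty-scaled positive regions (gain > 0;
#' the ground-truth "hard" set, whose first `n_delayed` members are also
#' delayed on errors and hence the ground-truth "hard and correct" set),
#' task-responsive but difficulty-flat positive regions (gain = 0), and
#' difficulty-scaled negative regions. Effect geography (which indices get
#' which role) is arbitrary by exchangeability of region labels.
#'
#' @param n_regions Total number of regions in the parcellation.
#' @param n_gain Positively responsive regions with difficulty gain.
#' @param n_flat Positively responsive regions with zero gain.
#' @param n_negative Negatively responsive regions (difficulty-scaled).
#' @param n_delayed Number of gain regions (first indices) whose response is
#'   delayed on incorrect trials (must be `<= n_gain`).
#' @param gain Per-difficulty-level multiplicative amplitude gain.
#' @return A data.frame with one row per region and columns `region`, `sign`
#'   (-1, 0, +1), `gain`, and `delayed` (logical).
#' @export
region_roles <- function(n_regions = 482L, n_gain = 60L, n_flat = 40L,
                         n_negative = 20L, n_delayed = 30L, gain = 0.5) {
  stopifnot(n_gain + n_flat + n_negative <= n_regions, n_delayed <= n_gain)
  sign <- integer(n_regions)
  g <- numeric(n_regions)
  sign[seq_len(n_gain + n_flat)] <- 1L
  g[seq_len(n_gain)] <- gain
  if (n_negative > 0L) {
    neg <- n_gain + n_flat + seq_len(n_negative)
    sign[neg] <- -1L
    g[neg] <- gain
  }
  data.frame(
    region = seq_len(n_regions),
    sign = sign,
    gain = g,
    delayed = seq_len(n_regions) <= n_delayed
  )
}

#' Parameters of the synthetic study generator
#'
#' Bundles the generative parameters for the simulated mental-rotation study:
#' 24 participants scanned on 2 days with 8 scans per day, each scan holding a
#' 35 s task block (5 s instruction, then 9 trials of 3 s with a 0.33 s
#' inter-trial interval; 3 trials per difficulty level). Defaults are
#' calibrated to the study design the package emulates: accuracy drops 9
#' percentage points and response time grows by 0.26 s per difficulty level,
#' and on incorrect trials the delayed region subset responds 3 s late.
#'
#' @param n_participants Number of participants.
#' @param n_regions Number of parcellated regions (400 cortical +
#'   28 cerebellar + 54 subcortical in the emulated atlas).
#' @param tr Repetition time in seconds.
#' @param n_days,scans_per_day Session structure.
#' @param instruction_dur Instruction period at block start, seconds.
#' @param trial_dur Trial duration, seconds.
#' @param iti Inter-trial interval, seconds.
#' @param trials_per_level Trials per difficulty level per block.
#' @param accuracy_base P(correct) at difficulty 0 (Easy).
#' @param accuracy_decrement Drop in P(correct) per difficulty level.
#' @param rt_base Mean response time at difficulty 0, seconds.
#' @param rt_slope Response-time increase per difficulty level, seconds.
#' @param rt_sd Trial-level Gaussian RT noise, seconds.
#' @param roles Region-role table from [region_roles()].
#' @param incorrect_delay Response-onset delay on incorrect trials for the
#'   delayed region subset, seconds; must be a non-negative multiple of `tr`.
#' @param noise_sd SD of additive i.i.d. Gaussian noise on the BOLD signal,
#'   in units of the peak-normalized hemodynamic response.
#' @param frames_per_run Frames recorded per scan; must cover the block plus
#'   the response window tail.
#' @param seed Integer seed driving all randomness of the generator.
#' @return An object of class `generator_params` (a named list).
#' @export
generator_params <- function(n_participants = 24L, n_regions = 482L, tr = 1,
                             n_days = 2L, scans_per_day = 8L,
                             instruction_dur = 5, trial_dur = 3, iti = 0.33,
                             trials_per_level = 3L,
                             accuracy_base = 0.95, accuracy_decrement = 0.09,
                             rt_base = 1.0, rt_slope = 0.26, rt_sd = 0.3,
                             roles = region_roles(n_regions),
                             incorrect_delay = 3, noise_sd = 0.5,
                             frames_per_run = 50L, seed = 1L) {
  if (accuracy_base - 2 * accuracy_decrement <= 0 ||
      accuracy_base - 2 * accuracy_decrement >= 1)
    stop("accuracy_base - 2*accuracy_decrement must lie in (0, 1)")
  if (incorrect_delay < 0 || abs(incorrect_delay / tr -
                                 round(incorrect_delay / tr)) > 1e-8)
    stop("incorrect_delay must be a non-negative integer multiple of tr")
  if (max(roles$region) > n_regions)
    stop("region roles reference indices beyond n_regions")
  block_dur <- instruction_dur +
    3 * trials_per_level * (trial_dur + iti) - iti
  if (frames_per_run * tr < block_dur)
    stop("frames_per_run too short to cover the task block")
  structure(list(
    n_participants = as.integer(n_participants),
    n_regions = as.integer(n_regions), tr = tr,
    n_days = as.integer(n_days), scans_per_day = as.integer(scans_per_day),
    instruction_dur = instruction_dur, trial_dur = trial_dur, iti = iti,
    trials_per_level = as.integer(trials_per_level),
    accuracy_base = accuracy_base, accuracy_decrement = accuracy_decrement,
    rt_base = rt_base, rt_slope = rt_slope, rt_sd = rt_sd,
    roles = roles, incorrect_delay = incorrect_delay, noise_sd = noise_sd,
    frames_per_run = as.integer(frames_per_run), seed = as.integer(seed)
  ), class = "generator_params")
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate the trial schedule for a simulated study
#'
#' Builds the per-trial schedule for every participant and run. Each run holds
#' one task block: `instruction_dur` seconds of instruction followed by nine
#' trials (3 per difficulty level) of `trial_dur` seconds separated by `iti`.
#' The difficulty order of each run is a seeded random permutation of
#' \{0,0,0,1,1,1,2,2,2\} that is identical across participants (as in the
#' emulated design, where trial order was held consistent across
#' participants).
#'
#' @param params A [generator_params()] object.
#' @param n_runs Runs per participant (default: all
#'   `n_days * scans_per_day`).
#' @return A `trial_table` data.frame with columns `participant`, `day`,
#'   `scan`, `trial_index`, `onset` (s from block start), `duration`,
#'   `difficulty` (0 = Easy, 1 = Medium, 2 = Hard), `correct`, `rt` (both NA
#'   until [generate_behavior()] fills them).
#' @export
generate_trial_schedule <- function(params, n_runs = params$n_days * params$scans_per_day) {
  stopifnot(inherits(params, "generator_params"))
  if (n_runs < 0) stop("n_runs must be non-negative")
  n_trials <- 3L * params$trials_per_level
  base_levels <- rep(0:2, each = params$trials_per_level)
  orders <- with_seed(params$seed, lapply(seq_len(max(n_runs, 0L)), function(r)
    sample(base_levels)))
  onsets <- params$instruction_dur +
    (seq_len(n_trials) - 1L) * (params$trial_dur + params$iti)
  rows <- vector("list", n_runs * params$n_participants)
  k <- 0L
  for (p in seq_len(params$n_participants)) {
    for (r in seq_len(n_runs)) {
      k <- k + 1L
      rows[[k]] <- data.frame(
        participant = p,
        day = ((r - 1L) %/% params$scans_per_day) + 1L,
        scan = ((r - 1L) %% params$scans_per_day) + 1L,
        trial_index = seq_len(n_trials),
        onset = onsets,
        duration = params$trial_dur,
        difficulty = orders[[r]],
        correct = NA,
        rt = NA_real_
      )
    }
  }
  out <- if (k > 0L) do.call(rbind, rows[seq_len(k)]) else data.frame(
    participant = integer(), day = integer(), scan = integer(),
    trial_index = integer(), onset = numeric(), duration = numeric(),
    difficulty = integer(), correct = logical(), rt = numeric())
  class(out) <- c("trial_table", "data.frame")
  out
}

#' Simulate trial-level behavior
#'
#' Fills the `correct` and `rt` columns of a schedule under a
#' linear-probability accuracy model and a linear RT model:
#' `P(correct) = accuracy_base - accuracy_decrement * difficulty` (clipped to
#' \[0, 1\]) and `rt = rt_base + rt_slope * difficulty + N(0, rt_sd^2)`,
#' truncated to `(0, duration]`. Incorrect trials keep their (slower,
#' noisier) RT; downstream RT models exclude them by contract.
#'
#' @param schedule A `trial_table` from [generate_trial_schedule()].
#' @param params A [generator_params()] object.
#' @return The schedule with `correct` (logical) and `rt` (seconds) filled.
#' @export
generate_behavior <- function(schedule, params) {
  stopifnot(inherits(params, "generator_params"))
  if (nrow(schedule) == 0L) stop("schedule is empty")
  n <- nrow(schedule)
  p_correct <- pmin(1, pmax(0, params$accuracy_base -
                              params$accuracy_decrement * schedule$difficulty))
  with_seed(params$seed + 1L, {
    schedule$correct <- stats::runif(n) < p_correct
    rt <- params$rt_base + params$rt_slope * schedule$difficulty +
      stats::rnorm(n, 0, params$rt_sd)
    # truncate into (0, duration]: resample offenders from the body
    bad <- which(rt <= 0 | rt > schedule$duration)
    while (length(bad) > 0L) {
      rt[bad] <- params$rt_base + params$rt_slope * schedule$difficulty[bad] +
        stats::rnorm(length(bad), 0, params$rt_sd)
      bad <- bad[rt[bad] <= 0 | rt[bad] > schedule$duration[bad]]
    }
    schedule$rt <- rt
  })
  schedule
}

#' Generate parcellated BOLD time series
#'
#' Produces one regions x frames matrix per participant and run. Responsive
#' regions receive, for each trial, an impulse at the trial-onset frame
#' convolved with the canonical hemodynamic response, scaled by
#' `sign * (1 + gain * difficulty)`. On incorrect trials the delayed region
#' subset has its impulse shifted `incorrect_delay` seconds later. All
#' regions receive additive i.i.d. Gaussian noise with SD `noise_sd`;
#' baseline is zero (downstream stages z-score or regress, so scale and
#' offset are arbitrary). Trial onsets are placed on the frame grid by
#' rounding to the nearest frame, matching the FIR design convention.
#'
#' @param schedule A behavior-filled `trial_table` (incorrect-trial delays
#'   require `correct`; if `correct` is all NA, trials are treated as
#'   correct).
#' @param params A [generator_params()] object.
#' @param hrf Optional response kernel sampled at `tr` (defaults to the
#'   peak-normalized canonical HRF).
#' @return A list of `parcellated_bold` objects, each a list with
#'   `participant`, `day`, `scan`, `data` (regions x frames), `tr`,
#'   `region_labels`, `region_groups`.
#' @export
generate_bold <- function(schedule, params,
                          hrf = canonical_hrf(hrf_spec(tr = params$tr))) {
  stopifnot(inherits(params, "generator_params"))
  if (nrow(schedule) == 0L) stop("schedule is empty")
  delay_fr <- params$incorrect_delay / params$tr
  if (abs(delay_fr - round(delay_fr)) > 1e-8)
    stop("incorrect_delay must be an integer multiple of tr")
  delay_fr <- round(delay_fr)
  n_fr <- params$frames_per_run
  # lower-triangular convolution operator: K[k, t] = hrf[t - k + 1]
  K <- matrix(0, n_fr, n_fr)
  for (k in seq_len(n_fr)) {
    len <- min(length(hrf), n_fr - k + 1L)
    K[k, k:(k + len - 1L)] <- hrf[seq_len(len)]
  }
  roles <- params$roles
  labels <- sprintf("region_%03d", seq_len(params$n_regions))
  groups <- ifelse(roles$sign > 0, ifelse(roles$delayed, "positive_delayed",
                                          "positive"),
                   ifelse(roles$sign < 0, "negative", "unresponsive"))
  runs <- unique(schedule[c("participant", "day", "scan")])
  runs <- runs[order(runs$participant, runs$day, runs$scan), , drop = FALSE]
  out <- with_seed(params$seed + 2L, lapply(seq_len(nrow(runs)), function(i) {
    sel <- schedule$participant == runs$participant[i] &
      schedule$day == runs$day[i] & schedule$scan == runs$scan[i]
    trials <- schedule[sel, , drop = FALSE]
    sticks <- matrix(0, params$n_regions, n_fr)
    for (j in seq_len(nrow(trials))) {
      fr <- round(trials$onset[j] / params$tr) + 1L
      incorrect <- isTRUE(!trials$correct[j])
      amp <- roles$sign * (1 + roles$gain * trials$difficulty[j])
      resp <- which(roles$sign != 0L)
      for (r in resp) {
        f <- fr + if (incorrect && roles$delayed[r]) delay_fr else 0L
        if (f <= n_fr) sticks[r, f] <- sticks[r, f] + amp[r]
      }
    }
    signal <- sticks %*% K
    if (params$noise_sd > 0)
      signal <- signal + matrix(stats::rnorm(length(signal), 0, params$noise_sd),
                                nrow(signal))
    structure(list(participant = runs$participant[i], day = runs$day[i],
                   scan = runs$scan[i], data = signal, tr = params$tr,
                   region_labels = labels, region_groups = groups),
              class = "parcellated_bold")
  }))
  out
}

#' Simulate a complete study
#'
#' Convenience wrapper chaining [generate_trial_schedule()],
#' [generate_behavior()] and [generate_bold()].
#'
#' @param params A [generator_params()] object.
#' @param n_runs Runs per participant.
#' @return A list with elements `schedule` (behavior-filled `trial_table`),
#'   `bold` (list of `parcellated_bold`), and `params`.
#' @export
simulate_study <- function(params = generator_params(),
                           n_runs = params$n_days * params$scans_per_day) {
  schedule <- generate_behavior(generate_trial_schedule(params, n_runs), params)
  list(schedule = schedule, bold = generate_bold(schedule, params),
       params = params)
}

#' Write / read a trial table as BIDS-style events.tsv
#'
#' Columns follow the BIDS events convention: `onset`, `duration`,
#' `trial_type` (Easy/Medium/Hard), `difficulty`, `response_time`, `correct`,
#' plus `participant`, `day`, `scan` to keep the study in one file.
#'
#' @param schedule A `trial_table`.
#' @param path Output / input TSV path.
#' @return `write_events_tsv` returns `path` invisibly; `read_events_tsv`
#'   returns a `trial_table`.
#' @export
write_events_tsv <- function(schedule, path) {
  out <- data.frame(
    participant = schedule$participant, day = schedule$day,
    scan = schedule$scan, onset = schedule$onset,
    duration = schedule$duration,
    trial_type = c("Easy", "Medium", "Hard")[schedule$difficulty + 1L],
    difficulty = schedule$difficulty,
    response_time = ifelse(is.na(schedule$rt), "n/a",
                           format(schedule$rt, digits = 10)),
    correct = ifelse(is.na(schedule$correct), "n/a",
                     as.integer(schedule$correct))
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  x <- utils::read.delim(path, na.strings = "n/a")
  out <- data.frame(
    participant = x$participant, day = x$day, scan = x$scan,
    trial_index = stats::ave(x$onset, x$participant, x$day, x$scan,
                             FUN = seq_along),
    onset = x$onset, duration = x$duration, difficulty = x$difficulty,
    correct = as.logical(x$correct), rt = as.numeric(x$response_time)
  )
  class(out) <- c("trial_table", "data.frame")
  out
}
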