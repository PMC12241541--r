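# FIR deconvolution: canonical HRF, response-window estimation, design
# construction with day/scan nuisance, and per-participant GLM fitting.

#' Canonical hemodynamic response specification
#'
#' Double-gamma parameterization in the SPM convention: the response is the
#' difference of two gamma densities, `dgamma(t, peak_delay/peak_dispersion,
#' scale = peak_dispersion) - dgamma(t, undershoot_delay/undershoot_dispersion,
#' scale = undershoot_dispersion) / peak_undershoot_ratio`. Defaults are the
#' SPM canonical values (peak 6 s, undershoot 16 s, dispersions 1, ratio 6).
#'
#' @param peak_delay,undershoot_delay Gamma delays in seconds.
#' @param peak_dispersion,undershoot_dispersion Gamma dispersions.
#' @param peak_undershoot_ratio Peak-to-undershoot amplitude ratio.
#' @param tr Sampling interval in seconds.
#' @return An object of class `hrf_spec`.
#' @export
hrf_spec <- function(peak_delay = 6, undershoot_delay = 16,
                     peak_dispersion = 1, undershoot_dispersion = 1,
                     peak_undershoot_ratio = 6, tr = 1) {
  vals <- c(peak_delay, undershoot_delay, peak_dispersion,
            undershoot_dispersion, peak_undershoot_ratio, tr)
  if (any(vals <= 0)) stop("all hrf_spec parameters must be positive")
  structure(list(peak_delay = peak_delay, undershoot_delay = undershoot_delay,
                 peak_dispersion = peak_dispersion,
                 undershoot_dispersion = undershoot_dispersion,
                 peak_undershoot_ratio = peak_undershoot_ratio, tr = tr),
            class = "hrf_spec")
}

#' Sample the canonical double-gamma HRF
#'
#' Evaluates the double-gamma response on the grid `0, tr, 2*tr, ...` up to
#' `length` seconds, peak-normalized so the maximum equals 1. The value at
#' t = 0 is exactly 0.
#'
#' @param spec An [hrf_spec()].
#' @param length Kernel support in seconds (default 32).
#' @return Numeric vector of kernel samples.
#' @export
canonical_hrf <- function(spec = hrf_spec(), length = 32) {
  if (length < spec$tr) stop("length must be at least one TR")
  t <- seq(0, length, by = spec$tr)
  h <- hrf_value(t, spec)
  h / max(h)
}

# unnormalized double-gamma evaluated at arbitrary times
hrf_value <- function(t, spec) {
  stats::dgamma(t, shape = spec$peak_delay / spec$peak_dispersion,
                scale = spec$peak_dispersion) -
    stats::dgamma(t, shape = spec$undershoot_delay / spec$undershoot_dispersion,
                  scale = spec$undershoot_dispersion) /
    spec$peak_undershoot_ratio
}

#' Estimate the FIR response window from trial duration
#'
#' Convolves a boxcar of `trial_duration` with the canonical HRF sampled at
#' the spec's TR and returns the number of frames up to (and including) the
#' first strictly negative sample of the convolution: the window within which
#' the trial-evoked response is non-negative. With a 3 s trial and TR = 1 s
#' under SPM defaults the convolution first dips below zero 14 s after trial
#' onset, giving a 15-frame window.
#'
#' @param trial_duration Trial duration in seconds.
#' @param spec An [hrf_spec()].
#' @param horizon Maximum horizon searched, seconds.
#' @return Integer window length in frames, with attribute
#'   `first_negative_s`, the time (seconds after onset) of the first
#'   negative sample.
#' @export
response_window <- function(trial_duration, spec = hrf_spec(), horizon = 64) {
  if (trial_duration <= 0) stop("trial_duration must be positive")
  h <- canonical_hrf(spec, length = horizon)
  n_box <- max(1L, round(trial_duration / spec$tr))
  # exact boxcar convolution via cumulative sums (FFT round-off would turn
  # the exact zero at t = 0 into a spuriously negative sample)
  cs <- cumsum(h)
  conv <- cs - c(rep(0, n_box), cs[seq_len(length(h) - n_box)])
  neg <- which(conv < 0)
  if (length(neg) == 0L)
    stop("convolution never negative within horizon; degenerate HRF spec")
  first_neg <- neg[1L] - 1L          # 0-based frame == seconds / tr
  structure(as.integer(first_neg + 1L),
            first_negative_s = first_neg * spec$tr)
}

#' Build an FIR design matrix with day and scan nuisance regressors
#'
#' One indicator column per (condition, timepoint offset 0..window-1): column
#' `cond_t03` carries a 1 at frame `onset_frame + 3` of every trial assigned
#' to `cond`. Trials of a condition share columns, so the per-timepoint betas
#' are the condition's mean trial-locked response. Nuisance structure follows
#' the blocked two-day design: one day regressor (0 = day 1, 1 = day 2) and
#' one indicator column per scan, giving e.g. 15 + 1 + 16 = 32 columns for a
#' single-condition model over 2 days x 8 scans. Runs are concatenated along
#' the time axis in (day, scan) order.
#'
#' Trial onsets are aligned to the frame grid by rounding to the nearest
#' frame (`onset_rounding = "nearest"`, the default, appropriate for designs
#' whose inter-trial interval is not a multiple of TR); with `"strict"`,
#' onsets further than `tol` seconds from a frame raise an error.
#'
#' @param schedule A `trial_table` for one participant.
#' @param conditions Named list mapping condition label to a logical
#'   predicate over schedule rows, e.g.
#'   `list(hard_incorrect = function(tr) tr$difficulty == 2 & !tr$correct)`.
#' @param window Window length in frames (see [response_window()]).
#' @param frames_per_run Frames per run in the BOLD data.
#' @param tr Repetition time, seconds.
#' @param onset_rounding `"nearest"` or `"strict"`.
#' @param tol Grid tolerance in seconds for `"strict"` rounding.
#' @return An object of class `fir_design`: list with `matrix` (frames x
#'   regressors), `labels`, `fir_columns` (index of FIR columns),
#'   `condition` per FIR column, `window`, `runs` (data.frame of day/scan
#'   per run), `tr`.
#' @export
build_fir_design <- function(schedule, conditions, window,
                             frames_per_run, tr = 1,
                             onset_rounding = c("nearest", "strict"),
                             tol = 1e-6) {
  onset_rounding <- match.arg(onset_rounding)
  if (nrow(schedule) == 0L) stop("schedule is empty")
  if (window < 1) stop("window must be >= 1 frame")
  if (length(unique(schedule$participant)) != 1L)
    stop("build_fir_design expects a single participant's schedule")
  fr <- schedule$onset / tr
  if (onset_rounding == "strict" && any(abs(fr - round(fr)) > tol / tr))
    stop("trial onsets do not align to the frame grid")
  schedule$onset_frame <- round(fr)
  runs <- unique(schedule[c("day", "scan")])
  runs <- runs[order(runs$day, runs$scan), , drop = FALSE]
  n_runs <- nrow(runs)
  total_frames <- n_runs * frames_per_run
  labels <- character(0)
  cols <- list()
  cond_of <- character(0)
  for (cname in names(conditions)) {
    pred <- conditions[[cname]](schedule)
    pred[is.na(pred)] <- FALSE
    if (!any(pred))
      warning(sprintf("condition '%s' has zero trials; columns are all-zero",
                      cname))
    block <- matrix(0, total_frames, window)
    trials <- schedule[pred, , drop = FALSE]
    for (j in seq_len(nrow(trials))) {
      run_idx <- which(runs$day == trials$day[j] & runs$scan == trials$scan[j])
      base <- (run_idx - 1L) * frames_per_run + trials$onset_frame[j] + 1L
      for (k in seq_len(window)) {
        f <- base + k - 1L
        if (f <= run_idx * frames_per_run) block[f, k] <- 1
      }
    }
    colnames(block) <- sprintf("%s_t%02d", cname, seq_len(window) - 1L)
    cols[[cname]] <- block
    labels <- c(labels, colnames(block))
    cond_of <- c(cond_of, rep(cname, window))
  }
  fir_mat <- do.call(cbind, cols)
  day_col <- matrix(rep(as.numeric(runs$day > 1), each = frames_per_run),
                    ncol = 1, dimnames = list(NULL, "day"))
  scan_cols <- matrix(0, total_frames, n_runs)
  for (i in seq_len(n_runs))
    scan_cols[(i - 1L) * frames_per_run + seq_len(frames_per_run), i] <- 1
  colnames(scan_cols) <- sprintf("scan_%02d", seq_len(n_runs))
  mat <- cbind(fir_mat, day_col, scan_cols)
  structure(list(matrix = mat, labels = colnames(mat),
                 fir_columns = seq_len(ncol(fir_mat)),
                 condition = cond_of, window = as.integer(window),
                 runs = runs, tr = tr,
                 frames_per_run = as.integer(frames_per_run)),
            class = "fir_design")
}

# standard condition predicates for the two FIR models
#' Condition predicates for the difficulty and error FIR models
#'
#' `difficulty_conditions()` returns the three correct-trial difficulty
#' conditions (easy/medium/hard, correct responses only);
#' `hard_incorrect_condition()` the single hard-incorrect condition.
#'
#' @return Named list of predicate functions over a `trial_table`.
#' @export
difficulty_conditions <- function() {
  list(
    easy_correct   = function(s) s$difficulty == 0 & s$correct,
    medium_correct = function(s) s$difficulty == 1 & s$correct,
    hard_correct   = function(s) s$difficulty == 2 & s$correct
  )
}

#' @rdname difficulty_conditions
#' @export
hard_incorrect_condition <- function() {
  list(hard_incorrect = function(s) s$difficulty == 2 & !s$correct)
}

#' Fit an FIR GLM for one participant
#'
#' Regresses every region's concatenated BOLD time series on the FIR design.
#' `method = "fixed"` (default) treats scan intercepts as fixed effects and
#' solves ordinary least squares for all regions at once via a pivoted QR;
#' `method = "mixed"` fits, per region, a linear mixed model with the FIR and
#' day regressors fixed and a random intercept per scan (lme4), falling back
#' to the fixed fit for regions whose mixed fit fails to converge (with a
#' warning). On balanced noiseless data the two routes agree.
#'
#' The day and scan indicator columns are mutually collinear by construction
#' (day is the sum of its scans' indicators); the pivoted QR drops a
#' redundant nuisance column, which leaves the FIR betas untouched. An
#' aliased FIR column, in contrast, is a genuine identifiability failure and
#' raises an error naming the columns.
#'
#' @param bold List of `parcellated_bold` runs for one participant, or a
#'   single regions x frames matrix spanning the concatenated design.
#' @param design An `fir_design` for the same runs.
#' @param method `"fixed"` or `"mixed"`.
#' @return An object of class `fir_betas`: list with `betas` (named list per
#'   condition of regions x window matrices), `participant`, `window`,
#'   `conditions`, `method`, `dropped` (nuisance columns dropped), `notes`.
#' @export
fit_fir <- function(bold, design, method = c("fixed", "mixed")) {
  method <- match.arg(method)
  stopifnot(inherits(design, "fir_design"))
  if (is.list(bold) && !is.matrix(bold)) {
    ord <- order(vapply(bold, function(b) b$day, numeric(1)),
                 vapply(bold, function(b) b$scan, numeric(1)))
    bold <- bold[ord]
    participant <- bold[[1L]]$participant
    Y <- do.call(cbind, lapply(bold, function(b) b$data))
  } else {
    participant <- NA
    Y <- bold
  }
  X <- design$matrix
  if (ncol(Y) != nrow(X))
    stop(sprintf("BOLD frames (%d) do not match design rows (%d)",
                 ncol(Y), nrow(X)))
  if (anyNA(Y)) stop("BOLD data contain NA values")
  Yt <- t(Y)                                   # frames x regions
  qrX <- qr(X)
  aliased <- setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])
  zero_cols <- which(colSums(abs(X)) == 0)     # conditions with zero trials
  bad_fir <- setdiff(intersect(aliased, design$fir_columns), zero_cols)
  if (length(bad_fir) > 0L)
    stop("rank-deficient design: collinear FIR columns: ",
         paste(design$labels[bad_fir], collapse = ", "))
  coef <- qr.coef(qrX, Yt)                     # regressors x regions
  coef[is.na(coef)] <- 0
  if (length(zero_cols) > 0L)
    coef[intersect(zero_cols, design$fir_columns), ] <- NA_real_
  notes <- character(0)
  if (method == "mixed") {
    fir_X <- X[, design$fir_columns, drop = FALSE]
    fnames <- sprintf("f%03d", seq_len(ncol(fir_X)))
    df <- as.data.frame(fir_X)
    names(df) <- fnames
    df$day <- X[, "day"]
    df$scan <- factor(max.col(X[, grep("^scan_", colnames(X)),
                                drop = FALSE]))
    fml <- stats::as.formula(paste(
      "y ~ 0 +", paste(fnames, collapse = " + "), "+ day + (1 | scan)"))
    for (r in seq_len(ncol(Yt))) {
      df$y <- Yt[, r]
      fit <- tryCatch({
        m <- suppressMessages(lme4::lmer(fml, data = df, REML = FALSE))
        lme4::fixef(m)[fnames]
      }, error = function(e) NULL)
      if (is.null(fit)) {
        notes <- c(notes, sprintf("region %d: mixed fit failed, fixed fallback", r))
      } else {
        fit[is.na(fit)] <- 0
        coef[design$fir_columns, r] <- fit
      }
    }
    if (length(notes) > 0L)
      warning(sprintf("%d region(s) fell back to the fixed-effect fit",
                      length(notes)))
  }
  conds <- unique(design$condition)
  betas <- lapply(conds, function(cn) {
    idx <- design$fir_columns[design$condition == cn]
    b <- t(coef[idx, , drop = FALSE])          # regions x window
    colnames(b) <- sprintf("t%02d", seq_len(design$window) - 1L)
    b
  })
  names(betas) <- conds
  structure(list(betas = betas, participant = participant,
                 window = design$window, conditions = conds,
                 method = method,
                 dropped = design$labels[setdiff(aliased, design$fir_columns)],
                 notes = notes),
            class = "fir_betas")
}

#' Fit FIR models for every participant of a study
#'
#' Runs [build_fir_design()] + [fit_fir()] per participant and stacks the
#' betas into one array. With `model = "joint"` (default) all four
#' conditions (easy/medium/hard-correct and hard-incorrect) share one
#' design, so overlapping responses of temporally adjacent trials are
#' unmixed by the least-squares fit; `model = "separate"` reproduces the
#' two-model scheme in which the correct-trial difficulty model and the
#' 32-regressor hard-incorrect model are fit independently, leaving the
#' respective other trials unmodeled (their overlap then biases the betas
#' in rapid designs — see the methods vignette).
#'
#' @param bold List of `parcellated_bold` runs (all participants).
#' @param schedule The behavior-filled `trial_table`.
#' @param window FIR window in frames.
#' @param tr Repetition time, seconds.
#' @param method Passed to [fit_fir()].
#' @param model `"joint"` or `"separate"` condition designs.
#' @return A 4-d array `[participant, condition, region, timepoint]` with
#'   conditions `easy_correct`, `medium_correct`, `hard_correct`,
#'   `hard_incorrect`; class `fir_study`. Conditions a participant never
#'   produced are NA.
#' @export
fit_study_fir <- function(bold, schedule, window, tr = 1,
                          method = "fixed",
                          model = c("joint", "separate")) {
  model <- match.arg(model)
  participants <- sort(unique(schedule$participant))
  frames_per_run <- ncol(bold[[1L]]$data)
  n_regions <- nrow(bold[[1L]]$data)
  conds <- c("easy_correct", "medium_correct", "hard_correct",
             "hard_incorrect")
  out <- array(NA_real_,
               dim = c(length(participants), length(conds), n_regions, window),
               dimnames = list(participant = participants, condition = conds,
                               region = bold[[1L]]$region_labels,
                               timepoint = sprintf("t%02d", seq_len(window) - 1L)))
  for (pi in seq_along(participants)) {
    p <- participants[pi]
    sched_p <- schedule[schedule$participant == p, , drop = FALSE]
    bold_p <- Filter(function(b) b$participant == p, bold)
    if (model == "joint") {
      dj <- build_fir_design(sched_p,
                             c(difficulty_conditions(),
                               hard_incorrect_condition()),
                             window, frames_per_run, tr)
      fj <- fit_fir(bold_p, dj, method = method)
      for (cn in names(fj$betas)) out[pi, cn, , ] <- fj$betas[[cn]]
    } else {
      d1 <- build_fir_design(sched_p, difficulty_conditions(), window,
                             frames_per_run, tr)
      f1 <- fit_fir(bold_p, d1, method = method)
      d2 <- build_fir_design(sched_p, hard_incorrect_condition(), window,
                             frames_per_run, tr)
      f2 <- fit_fir(bold_p, d2, method = method)
      for (cn in names(f1$betas)) out[pi, cn, , ] <- f1$betas[[cn]]
      out[pi, "hard_incorrect", , ] <- f2$betas[["hard_incorrect"]]
    }
  }
  class(out) <- c("fir_study", class(out))
  out
}
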