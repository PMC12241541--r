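# Shared fixture worlds, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, .fixtures)) assign(name, force(expr), .fixtures)
  get(name, .fixtures)
}

# Small heterogeneous world: 40 regions (8 difficulty-gain regions of which
# all 8 delayed on errors, 6 flat, 4 negative), 6 participants.
tiny_params <- function(seed = 11L, noise_sd = 0.4) {
  generator_params(
    n_participants = 6L, n_regions = 40L,
    roles = region_roles(40L, n_gain = 8L, n_flat = 6L, n_negative = 4L,
                         n_delayed = 8L),
    noise_sd = noise_sd, seed = seed)
}

tiny_study <- function() fixture("tiny_study", simulate_study(tiny_params()))

tiny_betas <- function() fixture("tiny_betas", {
  st <- tiny_study()
  fit_study_fir(st$bold, st$schedule, window = 15L)
})

# Study-scale latent-axis world: 24 participants, 80 regions whose
# difficulty-gain set coincides with the delayed (correct-timing) set.
axis_params <- function(seed = 21L) {
  generator_params(
    n_participants = 24L, n_regions = 80L,
    roles = region_roles(80L, n_gain = 16L, n_flat = 12L, n_negative = 8L,
                         n_delayed = 16L),
    noise_sd = 0.5, seed = seed)
}

axis_pipeline <- function() fixture("axis_pipeline", {
  st <- simulate_study(axis_params())
  fb <- fit_study_fir(st$bold, st$schedule, window = 15L)
  lat <- suppressWarnings(fit_pca(zscore_timepoints(fb), n_max = 40L))
  lab1 <- contrast_labels(lat, "easy_correct", "hard_correct")
  lab2 <- contrast_labels(lat, "hard_incorrect", "hard_correct")
  g1 <- lda_sweep(lat, lab1, pc_range = 1:20, folds = 5L, seed = 3L)
  g2 <- lda_sweep(lat, lab2, pc_range = 1:20, folds = 5L, seed = 3L)
  op1 <- select_operating_point(g1)
  op2 <- select_operating_point(g2)
  a1 <- train_final_lda(lat, lab1, op1$timepoint, 13L)
  a2 <- train_final_lda(lat, lab2, op2$timepoint, 13L)
  axes <- orthogonalize_axes(a1, a2)
  pr <- project_axes(lat, axes)
  list(study = st, betas = fb, latent = lat, grids = list(g1, g2),
       ops = list(op1, op2), axes = axes, projection = pr,
       roles = axis_params()$roles)
})

# A bare latent_space wrapper for unit tests that construct scores directly.
make_latent <- function(scores, obs, components = NULL) {
  structure(list(
    components = if (is.null(components))
      diag(ncol(scores))[seq_len(ncol(scores)), , drop = FALSE]
    else components,
    explained_variance_ratio = rep(1 / ncol(scores), ncol(scores)),
    scores = scores, obs = obs, center = rep(0, ncol(scores))),
    class = "latent_space")
}
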