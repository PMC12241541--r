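# Z-scoring, PCA, balanced accuracy, grouped LDA sweeps, Gram-Schmidt,
# projection.

test_that("z-scoring standardizes every (subject, condition, timepoint) slice", {
  fb <- tiny_betas()
  z <- zscore_timepoints(fb)
  d <- dim(z)
  for (p in c(1L, d[1L])) for (cn in c(1L, 4L)) for (tp in c(1L, 8L, 15L)) {
    v <- z[p, cn, , tp]
    expect_lt(abs(mean(v)), 1e-10)
    expect_equal(stats::sd(v), 1, tolerance = 1e-10)
  }
  expect_equal(zscore_timepoints(z), z, tolerance = 1e-10)   # idempotent
  # affine invariance: a * X + b per slice gives the same z-scores
  fb2 <- fb
  for (p in seq_len(d[1L])) for (cn in seq_len(d[2L])) for (tp in seq_len(d[4L]))
    fb2[p, cn, , tp] <- 3.7 * fb[p, cn, , tp] + 2.2
  expect_equal(zscore_timepoints(fb2), z, tolerance = 1e-10)
  # degenerate slice errors
  fb3 <- fb; fb3[1L, 1L, , 1L] <- 5
  expect_error(zscore_timepoints(fb3), "zero spread")
})

test_that("PCA matches an eigen-decomposition oracle", {
  set.seed(31)
  x <- matrix(rnorm(60 * 12), 60) %*% diag(c(6, 4, 3, rep(1, 9)))
  lat <- fit_pca(list(x = x, obs = data.frame(participant = 1,
                                              condition = "a",
                                              timepoint = seq_len(60))),
                 n_max = 12L)
  ev <- eigen(stats::cov(x), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(lat$explained_variance_ratio, ev / sum(ev), tolerance = 1e-8)
  expect_true(all(diff(lat$explained_variance_ratio) <= 1e-12))
  # components orthonormal; reconstruction with all PCs is complete
  cc <- lat$components %*% t(lat$components)
  expect_equal(cc, diag(12L), tolerance = 1e-8, ignore_attr = TRUE)
  recon <- lat$scores %*% lat$components
  expect_equal(recon, sweep(x, 2L, lat$center), tolerance = 1e-8,
               ignore_attr = TRUE)
  # rank-1 data put all variance on PC1
  r1 <- outer(rnorm(30), rnorm(5))
  lat1 <- suppressWarnings(fit_pca(list(x = r1,
      obs = data.frame(participant = 1, condition = "a",
                       timepoint = seq_len(30))), n_max = 4L))
  expect_equal(lat1$explained_variance_ratio[1L], 1, tolerance = 1e-10)
})

test_that("balanced accuracy is the mean of sensitivity and specificity", {
  expect_equal(balanced_accuracy(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  expect_equal(balanced_accuracy(c(0, 0, 1, 1), c(1, 1, 1, 1)), 0.5)
  # TP = 3, FN = 1, TN = 2, FP = 2 -> (0.75 + 0.5) / 2
  truth <- c(rep("pos", 4), rep("neg", 4))
  pred <- c("pos", "pos", "pos", "neg", "neg", "neg", "pos", "pos")
  expect_equal(balanced_accuracy(truth, pred), 0.625)
  expect_error(balanced_accuracy(rep("a", 4), rep("a", 4)), "two classes")
})

test_that("subject-grouped CV never splits a participant", {
  for (seed in 1:5) {
    subjects <- rep(1:9, times = sample(2:5, 9, replace = TRUE))
    f <- wmdynamics:::subject_folds(subjects, 4L, seed)
    expect_true(all(tapply(f, subjects, function(x) length(unique(x))) == 1L))
    expect_equal(sort(unique(f)), 1:4)
  }
  expect_error(wmdynamics:::subject_folds(1:3, 5L, 1L), "fewer")
})

test_that("LDA sweep scores the full grid and finds separable structure", {
  set.seed(51)
  n_sub <- 10L
  obs <- expand.grid(timepoint = 1:3, condition = c("a", "b"),
                     participant = seq_len(n_sub),
                     stringsAsFactors = FALSE)[, 3:1]
  # class-separated clusters at every timepoint, 6 PCs
  x <- matrix(rnorm(nrow(obs) * 6, sd = 0.3), ncol = 6)
  x[obs$condition == "b", 1L] <- x[obs$condition == "b", 1L] + 4
  lat <- make_latent(x, obs)
  g <- lda_sweep(lat, factor(obs$condition), t_range = 1:3, pc_range = 1:6,
                 folds = 5L, seed = 2L)
  expect_equal(dim(g$balanced_accuracy), c(3L, 6L))
  expect_true(all(g$balanced_accuracy >= 0 & g$balanced_accuracy <= 1,
                  na.rm = TRUE))
  expect_equal(max(g$balanced_accuracy, na.rm = TRUE), 1)
  op <- select_operating_point(g)
  expect_equal(op$balanced_accuracy, 1)
})

test_that("label-permuted data scores at chance", {
  set.seed(61)
  n_sub <- 12L
  obs <- expand.grid(timepoint = 1:2, condition = c("a", "b"),
                     participant = seq_len(n_sub),
                     stringsAsFactors = FALSE)[, 3:1]
  x <- matrix(rnorm(nrow(obs) * 5, sd = 0.3), ncol = 5)
  x[obs$condition == "b", 1L] <- x[obs$condition == "b", 1L] + 3
  lat <- make_latent(x, obs)
  means <- vapply(1:10, function(perm) {
    flip <- sample(c(TRUE, FALSE), n_sub, replace = TRUE)
    lab <- obs$condition
    fl <- flip[obs$participant]
    lab[fl] <- c(a = "b", b = "a")[lab[fl]]
    g <- lda_sweep(lat, factor(lab), t_range = 1:2, pc_range = c(2L, 5L),
                   folds = 4L, seed = perm)
    mean(g$balanced_accuracy, na.rm = TRUE)
  }, numeric(1))
  expect_lt(abs(mean(means) - 0.5), 0.06)
})

test_that("operating-point selection follows the tie rules", {
  g <- structure(list(balanced_accuracy = matrix(0.9, 1, 1,
         dimnames = list(timepoint = 5, n_pcs = 7)),
         t_range = 5L, pc_range = 7L, folds = 5L, seed = 1L),
         class = "sweep_grid")
  expect_equal(select_operating_point(g)[c("timepoint", "n_pcs")],
               list(timepoint = 5L, n_pcs = 7L))
  # two equal maxima at one timepoint -> smaller PC count; across
  # timepoints -> earliest
  m <- matrix(c(0.7, 0.9, 0.9,
                0.9, 0.8, 0.9), nrow = 2, byrow = TRUE,
              dimnames = list(timepoint = 1:2, n_pcs = 1:3))
  g2 <- structure(list(balanced_accuracy = m, t_range = 1:2, pc_range = 1:3,
                       folds = 5L, seed = 1L), class = "sweep_grid")
  op <- select_operating_point(g2)
  expect_equal(op$timepoint, 1L)
  expect_equal(op$n_pcs, 2L)
  g3 <- g2; g3$balanced_accuracy[] <- NA
  expect_error(select_operating_point(g3), "invalid")
})

test_that("final LDA direction matches the Fisher closed form", {
  set.seed(71)
  n <- 500L
  mu2 <- c(6, -3.2, 2.4, 0, 1.2)   # well-separated spherical classes
  x <- rbind(matrix(rnorm(n * 5), n),
             sweep(matrix(rnorm(n * 5), n), 2L, -mu2))
  obs <- data.frame(participant = rep(1:10, length.out = 2L * n),
                    condition = rep(c("a", "b"), each = n), timepoint = 1L)
  lat <- make_latent(x, obs)
  ax <- train_final_lda(lat, factor(obs$condition), timepoint = 1L,
                        n_pcs = 5L, shrinkage = 0)
  # spherical classes: direction parallel to Sigma^-1 (mu2 - mu1) = mu2
  cosine <- sum(ax$direction * mu2) /
    sqrt(sum(ax$direction^2) * sum(mu2^2))
  expect_gt(cosine, 0.97)
  expect_equal(ax$train_balanced_accuracy, 1, tolerance = 0.02)
  # positive class (second level) projects positively
  proj <- x %*% ax$direction
  expect_gt(mean(proj[obs$condition == "b"]), mean(proj[obs$condition == "a"]))
  # equal means: projections overlap heavily
  lab0 <- factor(rep(c("a", "b"), length.out = 2L * n))
  ax0 <- train_final_lda(lat, lab0, 1L, 5L)
  p0 <- x %*% ax0$direction
  expect_lt(abs(mean(p0[lab0 == "b"]) - mean(p0[lab0 == "a"])),
            stats::sd(p0))
  expect_error(train_final_lda(lat, factor(obs$condition), 1L, n_pcs = 9L),
               "exceeds")
})

test_that("Gram-Schmidt orthogonalization", {
  # hand-worked 2-D case (|r| of a constant 2-vector is undefined -> NA)
  ax <- orthogonalize_axes(c(1, 0), c(1, 1))
  expect_equal(ax$axis2_orth, c(0, 1))
  expect_true(is.na(ax$corr_with_raw["axis2"]))
  # |r| fidelity against the plain correlation oracle in higher dimension
  a <- c(2, -1, 0.5, 3); b <- c(1, 1, -2, 0.5)
  ax3 <- orthogonalize_axes(a, b)
  expect_equal(unname(ax3$corr_with_raw["axis1"]), abs(stats::cor(a / sqrt(sum(a^2)), a)))
  expect_equal(unname(ax3$corr_with_raw["axis2"]),
               abs(stats::cor(ax3$axis2_orth, b)))
  # fixed point for already-orthonormal inputs
  ax2 <- orthogonalize_axes(c(0, 1, 0), c(0, 0, 1))
  expect_equal(ax2$axis1_orth, c(0, 1, 0))
  expect_equal(ax2$axis2_orth, c(0, 0, 1))
  # random inputs: unit norms, zero dot product
  set.seed(81)
  for (i in 1:20) {
    a <- rnorm(8); b <- rnorm(8)
    o <- orthogonalize_axes(a, b)
    expect_lt(abs(sum(o$axis1_orth * o$axis2_orth)), 1e-10)
    expect_equal(sum(o$axis1_orth^2), 1, tolerance = 1e-10)
    expect_equal(sum(o$axis2_orth^2), 1, tolerance = 1e-10)
  }
  expect_error(orthogonalize_axes(c(1, 2), c(2, 4)), "collinear")
  expect_error(orthogonalize_axes(c(0, 0), c(1, 1)), "non-zero")
})

test_that("projection identities and linearity", {
  pipe <- axis_pipeline()
  lat <- pipe$latent; axes <- pipe$axes
  k <- length(axes$axis1_orth)
  # self-projection of an axis is 1; cross-projection is 0
  expect_equal(sum(axes$axis1_orth * axes$axis1_orth), 1, tolerance = 1e-10)
  expect_equal(sum(axes$axis2_orth * axes$axis1_orth), 0, tolerance = 1e-10)
  pr <- project_axes(lat, axes)
  expect_equal(nrow(pr$regions), dim(pipe$betas)[3L])
  # linearity: scaling the scores scales the trajectories
  lat2 <- lat; lat2$scores <- 2 * lat$scores
  pr2 <- project_axes(lat2, axes)
  expect_equal(pr2$trajectories$axis1, 2 * pr$trajectories$axis1,
               tolerance = 1e-10)
})

test_that("Medium trajectory lies between Easy and Hard at the peak", {
  pipe <- axis_pipeline()
  tj <- pipe$projection$trajectories
  hard <- tj[tj$condition == "hard_correct", ]
  easy <- tj[tj$condition == "easy_correct", ]
  med <- tj[tj$condition == "medium_correct", ]
  # peak timepoint: largest Easy-Hard separation on the difficulty axis
  pk <- which.max(hard$axis1 - easy$axis1)
  expect_gt(med$axis1[pk], easy$axis1[pk])
  expect_lt(med$axis1[pk], hard$axis1[pk])
})
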