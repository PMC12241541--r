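# Latent-axis analysis: z-scoring, PCA over stacked FIR betas,
# subject-grouped LDA sweeps, Gram-Schmidt orthogonalization, projection.

#' Z-score FIR betas across regions at each timepoint
#'
#' For every (participant, condition, timepoint) slice of an `fir_study`
#' array, centers and scales the region vector to mean 0 and (sample) SD 1.
#' Slices that are entirely NA (e.g. a condition a participant never
#' produced) are passed through as NA.
#'
#' @param betas A `[participant, condition, region, timepoint]` array from
#'   [fit_study_fir()].
#' @return Array of the same shape and dimnames.
#' @export
zscore_timepoints <- function(betas) {
  d <- dim(betas)
  if (d[3L] < 2L) stop("need at least 2 regions to z-score")
  out <- betas
  for (p in seq_len(d[1L])) for (cn in seq_len(d[2L])) for (tp in seq_len(d[4L])) {
    v <- betas[p, cn, , tp]
    if (all(is.na(v))) next
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0)
      stop(sprintf("zero spread in slice (participant %d, condition %d, timepoint %d)",
                   p, cn, tp))
    out[p, cn, , tp] <- (v - mean(v)) / s
  }
  out
}

#' Stack an fir_study array into an observation matrix
#'
#' Rows are (participant, condition, timepoint) triples; columns are
#' regions. All-NA rows (unavailable conditions) are dropped.
#'
#' @param betas An `fir_study`-shaped array.
#' @return List with `x` (matrix) and `obs` (data.frame `participant`,
#'   `condition`, `timepoint` aligned with rows of `x`).
#' @export
stack_observations <- function(betas) {
  d <- dim(betas)
  dn <- dimnames(betas)
  obs <- expand.grid(timepoint = seq_len(d[4L]), condition = dn$condition,
                     participant = dn$participant, stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)[, 3:1]
  x <- matrix(NA_real_, nrow(obs), d[3L], dimnames = list(NULL, dn$region))
  i <- 0L
  for (p in seq_len(d[1L])) for (cn in seq_len(d[2L])) for (tp in seq_len(d[4L])) {
    i <- i + 1L
    x[i, ] <- betas[p, cn, , tp]
  }
  keep <- !apply(is.na(x), 1L, all)
  if (anyNA(x[keep, ])) stop("partially missing observation rows")
  list(x = x[keep, , drop = FALSE], obs = obs[keep, , drop = FALSE])
}

#' Principal component analysis of stacked FIR observations
#'
#' Centers the observation matrix by column (region) means and extracts up
#' to `n_max` principal components. Components are orthonormal directions in
#' region space; scores are the centered data projected onto them.
#'
#' @param betas An `fir_study` array (z-scored; see [zscore_timepoints()]),
#'   or a list from [stack_observations()].
#' @param n_max Maximum number of components to retain; truncated (with a
#'   warning) to the matrix rank.
#' @return An object of class `latent_space`: `components` (n_pcs x
#'   regions), `explained_variance_ratio`, `scores` (obs x n_pcs), `obs`
#'   (row metadata), `center`.
#' @export
fit_pca <- function(betas, n_max = 40L) {
  stacked <- if (is.array(betas) && length(dim(betas)) == 4L)
    stack_observations(betas) else betas
  x <- stacked$x
  if (nrow(x) < 2L) stop("need at least 2 observations for PCA")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  pos <- pc$sdev > max(pc$sdev) * 1e-12
  rank <- sum(pos)
  if (n_max > rank) {
    warning(sprintf("n_max = %d exceeds rank %d; truncating", n_max, rank))
    n_max <- rank
  }
  evr_all <- pc$sdev^2 / sum(pc$sdev^2)
  k <- seq_len(n_max)
  structure(list(
    components = t(pc$rotation[, k, drop = FALSE]),   # n_pcs x regions
    explained_variance_ratio = evr_all[k],
    scores = pc$x[, k, drop = FALSE],
    obs = stacked$obs,
    center = pc$center
  ), class = "latent_space")
}

#' Balanced accuracy of a binary prediction
#'
#' The mean of sensitivity and specificity; chance level is 0.5 for any
#' class balance.
#'
#' @param truth,predicted Vectors of class labels (any type); `truth` must
#'   contain both classes.
#' @return Scalar in \[0, 1\].
#' @export
balanced_accuracy <- function(truth, predicted) {
  classes <- sort(unique(as.character(truth)))
  if (length(classes) != 2L)
    stop("truth must contain exactly two classes")
  truth <- as.character(truth); predicted <- as.character(predicted)
  sens <- mean(predicted[truth == classes[2L]] == classes[2L])
  spec <- mean(predicted[truth == classes[1L]] == classes[1L])
  (sens + spec) / 2
}

# Ledoit-Wolf shrinkage intensity toward the scaled-identity target,
# computed from (within-class) centered rows.
ledoit_wolf_lambda <- function(xc) {
  n <- nrow(xc); p <- ncol(xc)
  S <- crossprod(xc) / n
  mu <- mean(diag(S))
  d2 <- sum((S - diag(mu, p))^2) / p
  if (d2 <= .Machine$double.eps) return(0)
  b2 <- sum(vapply(seq_len(n), function(i)
    sum((tcrossprod(xc[i, ]) - S)^2), numeric(1))) / (n^2 * p)
  min(1, min(b2, d2) / d2)
}

# Fisher discriminant with shrinkage of the pooled within-class covariance
# toward a scaled identity; shrinkage = "auto" uses the Ledoit-Wolf
# intensity (essential when observations-per-class is small relative to the
# number of PCs). Returns the direction, projected class means, midpoint
# threshold, and the shrinkage used.
fisher_lda <- function(x, y, shrinkage = "auto") {
  # second class (second factor level, or later in sort order) is positive
  classes <- if (is.factor(y)) levels(droplevels(y))
             else sort(unique(as.character(y)))
  stopifnot(length(classes) == 2L)
  y <- as.character(y)
  x <- as.matrix(x)
  x1 <- x[y == classes[1L], , drop = FALSE]
  x2 <- x[y == classes[2L], , drop = FALSE]
  mu1 <- colMeans(x1); mu2 <- colMeans(x2)
  xc <- rbind(sweep(x1, 2L, mu1), sweep(x2, 2L, mu2))
  sw <- crossprod(xc) / nrow(x)
  lam <- if (identical(shrinkage, "auto")) ledoit_wolf_lambda(xc)
         else as.numeric(shrinkage)
  target <- mean(diag(sw)) * diag(ncol(x))
  repeat {
    sw_s <- (1 - lam) * sw + lam * target
    w <- tryCatch(solve(sw_s, mu2 - mu1), error = function(e) NULL)
    if (!is.null(w) && all(is.finite(w))) break
    lam <- if (lam == 0) 1e-4 else min(1, lam * 10)
    if (lam >= 1 && !is.null(w)) break
  }
  list(w = w, mu1 = mu1, mu2 = mu2, classes = classes,
       threshold = sum(w * (mu1 + mu2)) / 2, shrinkage = lam)
}

predict_lda <- function(fit, x) {
  proj <- as.matrix(x) %*% fit$w
  ifelse(proj > fit$threshold, fit$classes[2L], fit$classes[1L])
}

# Seeded assignment of subjects to k folds, balanced in size.
subject_folds <- function(subjects, k, seed) {
  subs <- sort(unique(subjects))
  if (length(subs) < k) stop("fewer distinct subjects than folds")
  shuffled <- with_seed(seed, sample(subs))
  fold_of <- rep(seq_len(k), length.out = length(subs))
  names(fold_of) <- shuffled
  unname(fold_of[match(as.character(subjects), names(fold_of))])
}

#' Build contrast labels for a condition pair
#'
#' Returns a per-observation factor whose first level is the negative class
#' and second level the positive class (the class that projects positively
#' on the trained axis); observations of other conditions are NA.
#'
#' @param latent A `latent_space`.
#' @param negative,positive Condition names of the contrast.
#' @return Factor of length `nrow(latent$scores)`.
#' @export
contrast_labels <- function(latent, negative, positive) {
  factor(ifelse(latent$obs$condition %in% c(negative, positive),
                latent$obs$condition, NA),
         levels = c(negative, positive))
}

#' Sweep LDA classification over timepoints and PC counts
#'
#' For every cell (timepoint t, PC count k), trains a Fisher LDA on the
#' first k PC scores of the observations at timepoint t and evaluates
#' out-of-fold balanced accuracy under subject-grouped cross-validation: a
#' participant's observations are never split between training and test.
#' Cells where a training fold lacks a class are flagged invalid (NA), not
#' scored 0.
#'
#' @param latent A `latent_space`.
#' @param labels Per-observation class label (length `nrow(latent$scores)`);
#'   `NA` rows are excluded from the sweep.
#' @param subjects Per-observation subject identifier (defaults to
#'   `latent$obs$participant`).
#' @param t_range,pc_range Timepoints and PC counts swept.
#' @param folds Number of cross-validation folds.
#' @param seed Seed for the fold assignment.
#' @param shrinkage Within-class covariance shrinkage intensity in \[0, 1\],
#'   or `"auto"` for the Ledoit-Wolf estimate.
#' @return Object of class `sweep_grid`: `balanced_accuracy` (timepoint x
#'   n_pcs matrix), `t_range`, `pc_range`, `folds`, `seed`.
#' @export
lda_sweep <- function(latent, labels, subjects = latent$obs$participant,
                      t_range = 1:15, pc_range = 1:40, folds = 5L,
                      seed = 1L, shrinkage = "auto") {
  keep <- !is.na(labels)
  pc_range <- pc_range[pc_range <= ncol(latent$scores)]
  fold_of <- subject_folds(subjects[keep], folds, seed)
  grid <- matrix(NA_real_, length(t_range), length(pc_range),
                 dimnames = list(timepoint = t_range, n_pcs = pc_range))
  tp_all <- latent$obs$timepoint[keep]
  y_all <- as.character(labels[keep])
  sc_all <- latent$scores[keep, , drop = FALSE]
  for (ti in seq_along(t_range)) {
    sel <- tp_all == t_range[ti]
    if (!any(sel)) next
    y <- y_all[sel]; f <- fold_of[sel]
    sc <- sc_all[sel, , drop = FALSE]
    for (ki in seq_along(pc_range)) {
      x <- sc[, seq_len(pc_range[ki]), drop = FALSE]
      accs <- rep(NA_real_, folds)
      ok <- TRUE
      for (fd in seq_len(folds)) {
        tr <- f != fd; te <- f == fd
        if (length(unique(y[tr])) < 2L || length(unique(y[te])) < 2L) {
          ok <- FALSE; break
        }
        fit <- fisher_lda(x[tr, , drop = FALSE], y[tr], shrinkage)
        accs[fd] <- balanced_accuracy(y[te], predict_lda(fit, x[te, , drop = FALSE]))
      }
      if (ok) grid[ti, ki] <- mean(accs)
    }
  }
  structure(list(balanced_accuracy = grid, t_range = t_range,
                 pc_range = pc_range, folds = folds, seed = seed),
            class = "sweep_grid")
}

#' Select the operating point of a sweep grid
#'
#' Picks the timepoint whose best cell attains the grid maximum (ties
#' resolved to the earliest timepoint) and, at that timepoint, the minimum
#' PC count achieving the maximum.
#'
#' @param grid A `sweep_grid`.
#' @return List with `timepoint`, `n_pcs`, `balanced_accuracy`.
#' @export
select_operating_point <- function(grid) {
  g <- grid$balanced_accuracy
  if (all(is.na(g))) stop("all sweep cells are invalid")
  best <- max(g, na.rm = TRUE)
  hit <- which(g == best, arr.ind = TRUE)
  ti <- min(hit[, 1L])
  ki <- min(hit[hit[, 1L] == ti, 2L])
  list(timepoint = grid$t_range[ti], n_pcs = grid$pc_range[ki],
       balanced_accuracy = best)
}

#' Train the final LDA axis at a chosen timepoint
#'
#' Fits a Fisher discriminant on the first `n_pcs` PC scores of the
#' observations at `timepoint`, using all subjects. The sign is fixed so
#' the second-named class projects positively.
#'
#' @param latent A `latent_space`.
#' @param labels Per-observation labels; NA rows excluded. The positive
#'   class is the later one in sort order (e.g. `hard_correct` beats
#'   `easy_correct`); pass a factor to control ordering explicitly.
#' @param timepoint Timepoint whose observations are used.
#' @param n_pcs Number of leading PCs.
#' @param shrinkage Within-class covariance shrinkage (logged in the
#'   result).
#' @return Object of class `lda_axis`: `direction` (length `n_pcs`),
#'   `timepoint`, `n_pcs`, `classes`, `shrinkage`, `train_balanced_accuracy`.
#' @export
train_final_lda <- function(latent, labels, timepoint, n_pcs = 13L,
                            shrinkage = "auto") {
  if (n_pcs > ncol(latent$scores))
    stop("n_pcs exceeds the number of available PCs")
  keep <- !is.na(labels) & latent$obs$timepoint == timepoint
  x <- latent$scores[keep, seq_len(n_pcs), drop = FALSE]
  y <- labels[keep]
  if (is.factor(y)) y <- droplevels(y)
  fit <- fisher_lda(x, y, shrinkage)
  # sign convention: positive projection for the second-named class
  if (mean(x[as.character(y) == fit$classes[2L], , drop = FALSE] %*% fit$w) <
      mean(x[as.character(y) == fit$classes[1L], , drop = FALSE] %*% fit$w))
    fit$w <- -fit$w
  structure(list(direction = as.numeric(fit$w), timepoint = timepoint,
                 n_pcs = n_pcs, classes = fit$classes,
                 shrinkage = fit$shrinkage,
                 train_balanced_accuracy =
                   balanced_accuracy(y, predict_lda(fit, x))),
            class = "lda_axis")
}

#' Select a PC count by the added-explained-variance rule
#'
#' Returns the largest leading-PC count such that every retained PC adds at
#' least `min_added` explained variance ratio (default 1%).
#'
#' @param latent A `latent_space`.
#' @param min_added Minimum added explained variance ratio per PC.
#' @return Integer PC count.
#' @export
select_n_pcs_variance <- function(latent, min_added = 0.01) {
  below <- which(latent$explained_variance_ratio < min_added)
  if (length(below) == 0L) length(latent$explained_variance_ratio)
  else below[1L] - 1L
}

#' Normalize and orthogonalize two discriminant axes (Gram-Schmidt)
#'
#' The first axis is normalized; the second is replaced by its residual
#' after removing the component along the first, then normalized. The
#' absolute Pearson correlation between each orthogonalized axis and its raw
#' axis is reported as a fidelity check.
#'
#' @param axis1,axis2 `lda_axis` objects or plain numeric vectors in the
#'   same PC basis.
#' @return Object of class `lda_axes`: `axis1_raw`, `axis2_raw`,
#'   `axis1_orth`, `axis2_orth`, `corr_with_raw` (named length-2).
#' @export
orthogonalize_axes <- function(axis1, axis2) {
  v1 <- if (inherits(axis1, "lda_axis")) axis1$direction else as.numeric(axis1)
  v2 <- if (inherits(axis2, "lda_axis")) axis2$direction else as.numeric(axis2)
  if (length(v1) != length(v2))
    stop("axes must live in the same PC basis (equal length)")
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) stop("axes must be non-zero")
  u1 <- v1 / n1
  resid <- v2 - sum(u1 * v2) * u1
  if (sqrt(sum(resid^2)) < 1e-10 * n2)
    stop("axes are collinear; orthogonalized second axis undefined")
  u2 <- resid / sqrt(sum(resid^2))
  # |r| is undefined (NA) when either vector has zero spread
  safe_cor <- function(a, b)
    if (stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_
    else abs(stats::cor(a, b))
  structure(list(axis1_raw = v1, axis2_raw = v2,
                 axis1_orth = u1, axis2_orth = u2,
                 corr_with_raw = c(axis1 = safe_cor(u1, v1),
                                   axis2 = safe_cor(u2, v2))),
            class = "lda_axes")
}

#' Project regions and condition trajectories into the discriminant plane
#'
#' Maps each region through the PCA components onto the two orthogonalized
#' axes (one scalar loading per region per axis), and projects the mean
#' per-condition, per-timepoint PC scores onto the axes, including
#' conditions never used to train either axis.
#'
#' @param latent A `latent_space`.
#' @param axes An `lda_axes` object (axes in the leading-PC basis of
#'   `latent`).
#' @return List with `regions` (data.frame `region`, `axis1`, `axis2`) and
#'   `trajectories` (data.frame `condition`, `timepoint`, `axis1`, `axis2`,
#'   averaged over participants).
#' @export
project_axes <- function(latent, axes) {
  k <- length(axes$axis1_orth)
  if (k > nrow(latent$components))
    stop("axes dimensionality exceeds the latent space")
  comp <- latent$components[seq_len(k), , drop = FALSE]  # k x regions
  reg <- data.frame(
    region = colnames(comp),
    axis1 = as.numeric(crossprod(comp, axes$axis1_orth)),
    axis2 = as.numeric(crossprod(comp, axes$axis2_orth))
  )
  sc <- latent$scores[, seq_len(k), drop = FALSE]
  agg <- stats::aggregate(
    data.frame(axis1 = as.numeric(sc %*% axes$axis1_orth),
               axis2 = as.numeric(sc %*% axes$axis2_orth)),
    by = list(condition = latent$obs$condition,
              timepoint = latent$obs$timepoint),
    FUN = mean)
  list(regions = reg, trajectories = agg[order(agg$condition, agg$timepoint), ])
}
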