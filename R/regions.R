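# Quadrant-based region selection and the net-BOLD difficulty statistic.

#' Assign regions to quadrants of the discriminant plane
#'
#' Quadrants follow the task-semantics convention: the difficulty loading is
#' positive for regions biased to Hard trials and the performance loading is
#' positive for regions biased to Correct responses. Q1 = hard & correct,
#' Q2 = easy & correct, Q3 = easy & incorrect, Q4 = hard & incorrect. Zero
#' loadings (measure-zero in practice) resolve deterministically to the
#' positive side.
#'
#' @param loadings A data.frame with columns `region`, `difficulty`,
#'   `performance` (or the `regions` element of [project_axes()], whose
#'   `axis1`/`axis2` are taken as difficulty/performance).
#' @return A `region_quadrant_map` data.frame: `region`,
#'   `loading_difficulty`, `loading_performance`, `quadrant` (factor
#'   Q1..Q4).
#' @export
assign_quadrants <- function(loadings) {
  if (all(c("axis1", "axis2") %in% names(loadings)) &&
      !("difficulty" %in% names(loadings))) {
    loadings$difficulty <- loadings$axis1
    loadings$performance <- loadings$axis2
  }
  d <- loadings$difficulty; p <- loadings$performance
  if (any(!is.finite(d)) || any(!is.finite(p)))
    stop("non-finite loadings")
  hard <- d >= 0; correct <- p >= 0
  quadrant <- ifelse(hard & correct, "Q1",
                     ifelse(!hard & correct, "Q2",
                            ifelse(!hard & !correct, "Q3", "Q4")))
  out <- data.frame(region = loadings$region,
                    loading_difficulty = d, loading_performance = p,
                    quadrant = factor(quadrant, levels = paste0("Q", 1:4)))
  class(out) <- c("region_quadrant_map", "data.frame")
  out
}

#' Net BOLD response of an FIR time course
#'
#' Signed area between the beta time course and y = 0, accumulated
#' pointwise over the window (rectangle rule, width = TR): positive and
#' negative excursions cancel.
#'
#' @param beta_series Numeric vector over the FIR window.
#' @param tr Repetition time, seconds.
#' @return Scalar signed area (signal units x seconds).
#' @export
net_bold <- function(beta_series, tr = 1) {
  if (anyNA(beta_series)) stop("NA in beta series")
  sum(beta_series) * tr
}

#' Net-BOLD table for a region set across difficulty conditions
#'
#' Computes [net_bold()] for every (participant, difficulty, region) cell of
#' the correct-trial difficulty conditions of an `fir_study` array.
#'
#' @param betas An `fir_study` array.
#' @param regions Region labels (or indices) to include.
#' @param tr Repetition time, seconds.
#' @return A data.frame `participant`, `difficulty` (0/1/2), `region`,
#'   `net_bold`.
#' @export
net_bold_table <- function(betas, regions, tr = 1) {
  conds <- c(easy_correct = 0L, medium_correct = 1L, hard_correct = 2L)
  dn <- dimnames(betas)
  if (is.numeric(regions)) regions <- dn$region[regions]
  rows <- list(); k <- 0L
  for (p in dn$participant) for (cn in names(conds)) {
    sl <- betas[p, cn, regions, , drop = FALSE]
    nb <- rowSums(matrix(sl, nrow = length(regions))) * tr
    k <- k + 1L
    rows[[k]] <- data.frame(participant = p, difficulty = conds[[cn]],
                            region = regions, net_bold = nb)
  }
  do.call(rbind, rows)
}

#' Per-region effect of difficulty on net BOLD
#'
#' For each region, models net BOLD on ordinal difficulty (0/1/2) with
#' participant as a repeated-measure grouping: a random participant
#' intercept (`method = "mixed"`, lme4) or fixed participant intercepts
#' (`method = "fixed"`). Two-sided p-values use the t distribution with
#' residual degrees of freedom; q-values are Benjamini-Hochberg adjusted
#' across regions. Regions whose fit fails are flagged and excluded from
#' the FDR step with a warning.
#'
#' @param net_table Output of [net_bold_table()].
#' @param alpha FDR level defining the significant set.
#' @param method `"mixed"` or `"fixed"`.
#' @return A `net_bold_result` data.frame: `region`, `slope`, `t_stat`,
#'   `p_value`, `q_value`, `significant`, `failed`.
#' @export
difficulty_effect <- function(net_table, alpha = 0.05,
                              method = c("mixed", "fixed")) {
  method <- match.arg(method)
  if (length(unique(net_table$difficulty)) < 2L)
    stop("need at least 2 difficulty levels")
  if (length(unique(net_table$participant)) < 2L)
    stop("need at least 2 participants")
  regions <- unique(net_table$region)
  res <- lapply(regions, function(rg) {
    d <- net_table[net_table$region == rg, , drop = FALSE]
    est <- tryCatch({
      if (method == "mixed") {
        m <- suppressMessages(lme4::lmer(
          net_bold ~ difficulty + (1 | participant), data = d, REML = TRUE))
        cf <- summary(m)$coefficients
        df <- stats::nobs(m) - nrow(cf)
        c(cf["difficulty", "Estimate"], cf["difficulty", "t value"], df)
      } else {
        m <- stats::lm(net_bold ~ difficulty + factor(participant), data = d)
        cf <- summary(m)$coefficients
        c(cf["difficulty", "Estimate"], cf["difficulty", "t value"],
          m$df.residual)
      }
    }, error = function(e) NULL)
    if (is.null(est) || !all(is.finite(est)))
      return(data.frame(region = rg, slope = NA_real_, t_stat = NA_real_,
                        p_value = NA_real_, failed = TRUE))
    data.frame(region = rg, slope = est[1L], t_stat = est[2L],
               p_value = 2 * stats::pt(-abs(est[2L]), est[3L]),
               failed = FALSE)
  })
  out <- do.call(rbind, res)
  if (any(out$failed))
    warning(sprintf("%d region(s) had singular fits; excluded from FDR",
                    sum(out$failed)))
  out$q_value <- NA_real_
  ok <- !out$failed
  out$q_value[ok] <- stats::p.adjust(out$p_value[ok], method = "BH")
  out$significant <- !is.na(out$q_value) & out$q_value < alpha
  class(out) <- c("net_bold_result", "data.frame")
  out
}
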