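# Diagnostic statistics: empirical ROC/AUC, operating points, binormal
# closed forms, and a cohort simulator parameterized by published group
# summaries (mean +/- SE, n per group).

#' Cohort summary statistics
#'
#' A group summary `mean +/- se` over `n` eyes for one choroidal metric.
#' The implied group SD is `se * sqrt(n)`.
#'
#' @param label Group label (e.g. `"healthy"`, `"CSC"`, `"VKH"`).
#' @param metric Metric name (e.g. `"vessel_volume"`).
#' @param mean Group mean.
#' @param se Standard error of the mean (> 0).
#' @param n Number of eyes (>= 2).
#' @return A one-row tibble of class `cohort_summary`.
#' @export
cohort_summary <- function(label, metric, mean, se, n) {
  if (!(se > 0)) stop("se must be > 0", call. = FALSE)
  if (!(n >= 2)) stop("n must be >= 2", call. = FALSE)
  out <- tibble::tibble(label = label, metric = metric, mean = mean,
                        se = se, n = as.integer(n), sd = se * sqrt(n))
  class(out) <- c("cohort_summary", class(out))
  out
}

#' Bundled cohort summary statistics for the three study groups
#'
#' Published group means, standard errors and eye counts of the three
#' choroidal metrics measured in the central 6-mm ETDRS circle: healthy
#' eyes, central serous chorioretinopathy (CSC), and Vogt-Koyanagi-Harada
#' disease / sympathetic ophthalmia (VKH/SO). These summaries parameterize
#' the binormal ROC model and the cohort simulator.
#'
#' @return A tibble with columns `label`, `metric`, `mean`, `se`, `n`,
#'   `sd`.
#' @export
reference_cohorts <- function() {
  rows <- list(
    cohort_summary("healthy", "vessel_volume",   3.17, 0.11, 77),
    cohort_summary("healthy", "choroidal_volume", 6.47, 0.21, 77),
    cohort_summary("healthy", "vessel_index",    49.09, 0.32, 77),
    cohort_summary("CSC",     "vessel_volume",   4.68, 0.23, 34),
    cohort_summary("CSC",     "choroidal_volume", 9.23, 0.40, 34),
    cohort_summary("CSC",     "vessel_index",    50.41, 0.59, 34),
    cohort_summary("VKH",     "vessel_volume",   3.83, 0.17, 33),
    cohort_summary("VKH",     "choroidal_volume", 8.04, 0.34, 33),
    cohort_summary("VKH",     "vessel_index",    47.52, 0.59, 33)
  )
  do.call(rbind, rows)
}

flip_if_low <- function(x, direction) if (direction == "low") -x else x

#' Mann-Whitney (pair-counting) AUC
#'
#' The fraction of (diseased, healthy) score pairs ordered correctly, with
#' ties counted 0.5 — the probability interpretation of the area under the
#' empirical ROC curve, which it equals exactly.
#'
#' @param disease,healthy Numeric score vectors (non-empty).
#' @param direction `"high"` if disease scores run higher, `"low"`
#'   otherwise.
#' @return AUC in `[0, 1]`.
#' @examples
#' mann_whitney_auc(c(2, 3), c(1, 2))  # 0.875
#' @export
mann_whitney_auc <- function(disease, healthy, direction = c("high", "low")) {
  direction <- match.arg(direction)
  if (!length(disease) || !length(healthy))
    stop("both score lists must be non-empty", call. = FALSE)
  d <- flip_if_low(disease, direction)
  h <- flip_if_low(healthy, direction)
  r <- rank(c(d, h))
  n1 <- length(d); n0 <- length(h)
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Empirical ROC curve
#'
#' Operating points at every distinct score (rule: positive iff
#' score > threshold, after orienting by `direction`), with the trapezoidal
#' AUC — equal to [mann_whitney_auc()] exactly — and the Youden-optimal
#' cutoff.
#'
#' @inheritParams mann_whitney_auc
#' @return An object of class `choro_roc`: list with `points` (tibble of
#'   `threshold`, `sensitivity`, `specificity`), `auc`, `direction`,
#'   `cutoff` and the operating characteristics at the cutoff.
#' @export
roc_curve <- function(disease, healthy, direction = c("high", "low")) {
  direction <- match.arg(direction)
  if (!length(disease) || !length(healthy))
    stop("both score lists must be non-empty", call. = FALSE)
  d <- flip_if_low(disease, direction)
  h <- flip_if_low(healthy, direction)
  thr <- c(-Inf, sort(unique(c(d, h))))
  sens <- vapply(thr, function(t) mean(d > t), numeric(1))
  spec <- vapply(thr, function(t) mean(h <= t), numeric(1))
  # trapezoid over the specificity-ordered traversal
  fpr <- 1 - spec
  o <- order(fpr, sens)
  auc <- sum(diff(fpr[o]) * (head(sens[o], -1) + tail(sens[o], -1)) / 2)
  cut <- youden_from_scores(d, h)
  out <- structure(list(
    points = tibble::tibble(
      threshold = flip_if_low(thr, direction),
      sensitivity = sens, specificity = spec),
    auc = auc, direction = direction,
    cutoff = flip_if_low(cut$threshold, direction),
    sensitivity = cut$sensitivity, specificity = cut$specificity
  ), class = "choro_roc")
  out
}

# Youden-optimal cutoff on oriented scores. Candidates are the midpoints of
# gaps between distinct pooled values plus one point beyond each end, so a
# separating gap yields its midpoint. Ties in J prefer the more specific
# operating point, then the lower threshold; if no candidate beats J = 0
# (indistinguishable groups) the lowest candidate is returned.
youden_from_scores <- function(d, h) {
  v <- sort(unique(c(d, h)))
  cand <- if (length(v) == 1L) c(v - 1, v + 1)
          else c(v[1] - 1, (head(v, -1) + tail(v, -1)) / 2, v[length(v)] + 1)
  sens <- vapply(cand, function(t) mean(d > t), numeric(1))
  spec <- vapply(cand, function(t) mean(h <= t), numeric(1))
  J <- sens + spec - 1
  if (max(J) <= 1e-12) {
    i <- 1L
  } else {
    best <- which(J >= max(J) - 1e-12)
    i <- best[order(-spec[best], cand[best])][1]
  }
  list(threshold = cand[i], sensitivity = sens[i], specificity = spec[i])
}

#' Youden-optimal cutoff of a ROC curve
#'
#' The threshold maximizing `sensitivity + specificity - 1`. For perfectly
#' separated groups this is the midpoint of the separating gap; ties prefer
#' the more specific operating point; indistinguishable groups return the
#' lowest candidate.
#'
#' @param roc A `choro_roc` from [roc_curve()].
#' @return Scalar threshold.
#' @export
youden_cutoff <- function(roc) {
  stopifnot(inherits(roc, "choro_roc"))
  roc$cutoff
}

#' @export
print.choro_roc <- function(x, ...) {
  cat(sprintf("<choro_roc> AUC = %.4f (disease = %s); Youden cutoff %.4g (sens %.3f, spec %.3f)\n",
              x$auc, x$direction, x$cutoff, x$sensitivity, x$specificity))
  invisible(x)
}

#' @export
tidy.choro_roc <- function(x, ...) x$points

#' @export
glance.choro_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, cutoff = x$cutoff,
                 sensitivity = x$sensitivity, specificity = x$specificity,
                 direction = x$direction)
}

#' Plot a ROC curve
#'
#' @param object A `choro_roc`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.choro_roc <- function(object, ...) {
  df <- object$points[order(1 - object$points$specificity,
                            object$points$sensitivity), ]
  ggplot2::ggplot(df, ggplot2::aes(x = 1 - .data$specificity,
                                   y = .data$sensitivity)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  subtitle = sprintf("AUC = %.3f", object$auc)) +
    ggplot2::theme_minimal()
}

#' Binormal closed-form AUC
#'
#' For Gaussian score distributions `N(mu1, sd1^2)` (diseased) and
#' `N(mu0, sd0^2)` (healthy), the probability a diseased score exceeds a
#' healthy one: `pnorm((mu1 - mu0) / sqrt(sd0^2 + sd1^2))`.
#'
#' @param mu1,sd1 Diseased-group mean and SD.
#' @param mu0,sd0 Healthy-group mean and SD.
#' @return AUC in `[0, 1]`.
#' @export
binormal_auc <- function(mu1, sd1, mu0, sd0) {
  if (sd1 <= 0 || sd0 <= 0) stop("standard deviations must be > 0", call. = FALSE)
  pnorm((mu1 - mu0) / sqrt(sd0^2 + sd1^2))
}

#' Binormal operating characteristics at a fixed cutoff
#'
#' With the disease-high rule (positive iff score > cutoff):
#' `sensitivity = 1 - pnorm((c - mu1)/sd1)`,
#' `specificity = pnorm((c - mu0)/sd0)`.
#'
#' @param cutoff Decision threshold.
#' @inheritParams binormal_auc
#' @param direction `"high"` or `"low"`.
#' @return A tibble with `sensitivity` and `specificity`.
#' @export
binormal_operating_point <- function(cutoff, mu1, sd1, mu0, sd0,
                                     direction = c("high", "low")) {
  direction <- match.arg(direction)
  if (direction == "low") {
    cutoff <- -cutoff; mu1 <- -mu1; mu0 <- -mu0
  }
  tibble::tibble(
    sensitivity = 1 - pnorm((cutoff - mu1) / sd1),
    specificity = pnorm((cutoff - mu0) / sd0)
  )
}

#' Simulate cohort replicates from group summaries
#'
#' Per replicate, draws `n` scores per group from
#' `Normal(mean, (se * sqrt(n))^2)` and computes the empirical
#' Mann-Whitney AUC plus, optionally, sensitivity and specificity at a
#' fixed cutoff. The mean replicate AUC converges to [binormal_auc()].
#' Deterministic given `seed`.
#'
#' @param diseased,healthy [cohort_summary()] rows (or lists with `mean`,
#'   `se`, `n`).
#' @param n_reps Number of replicates.
#' @param seed Integer seed.
#' @param cutoff Optional fixed decision threshold.
#' @param direction `"high"` or `"low"`.
#' @return An object of class `cohort_sim`: list with `reps` (tibble of
#'   per-replicate `auc`, `sensitivity`, `specificity`), `auc_closed_form`,
#'   `cutoff`, `direction`, and the two summaries.
#' @export
simulate_cohorts <- function(diseased, healthy, n_reps = 10000, seed = 1L,
                             cutoff = NULL, direction = c("high", "low")) {
  direction <- match.arg(direction)
  g <- function(s) list(mean = s$mean[1], sd = s$se[1] * sqrt(s$n[1]),
                        n = as.integer(s$n[1]))
  ds <- g(diseased); hs <- g(healthy)
  if (ds$sd <= 0 || hs$sd <= 0 || ds$n < 2 || hs$n < 2)
    stop("invalid cohort summaries", call. = FALSE)
  sgn <- if (direction == "low") -1 else 1
  res <- withr::with_seed(as.integer(seed), {
    D <- matrix(rnorm(n_reps * ds$n, ds$mean, ds$sd), n_reps)
    H <- matrix(rnorm(n_reps * hs$n, hs$mean, hs$sd), n_reps)
    auc <- vapply(seq_len(n_reps), function(i) {
      r <- rank(c(sgn * D[i, ], sgn * H[i, ]))
      (sum(r[seq_len(ds$n)]) - ds$n * (ds$n + 1) / 2) / (ds$n * hs$n)
    }, numeric(1))
    if (!is.null(cutoff)) {
      sens <- rowMeans(sgn * D > sgn * cutoff)
      spec <- rowMeans(sgn * H <= sgn * cutoff)
    } else {
      sens <- spec <- rep(NA_real_, n_reps)
    }
    tibble::tibble(rep = seq_len(n_reps), auc = auc,
                   sensitivity = sens, specificity = spec)
  })
  structure(list(
    reps = res,
    auc_closed_form = sgn_auc(ds, hs, sgn),
    cutoff = cutoff, direction = direction,
    diseased = ds, healthy = hs, seed = as.integer(seed)
  ), class = "cohort_sim")
}

sgn_auc <- function(ds, hs, sgn) {
  binormal_auc(sgn * ds$mean, ds$sd, sgn * hs$mean, hs$sd)
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat(sprintf("<cohort_sim> %d replicates; mean AUC = %.4f (closed form %.4f)\n",
              nrow(x$reps), mean(x$reps$auc), x$auc_closed_form))
  if (!is.null(x$cutoff))
    cat(sprintf("  at cutoff %.4g: sens %.2f%%, spec %.2f%%\n", x$cutoff,
                100 * mean(x$reps$sensitivity), 100 * mean(x$reps$specificity)))
  invisible(x)
}

#' @export
tidy.cohort_sim <- function(x, ...) x$reps

#' @export
glance.cohort_sim <- function(x, ...) {
  tibble::tibble(
    auc_mc_mean = mean(x$reps$auc),
    auc_mc_se = stats::sd(x$reps$auc) / sqrt(nrow(x$reps)),
    auc_closed_form = x$auc_closed_form,
    cutoff = if (is.null(x$cutoff)) NA_real_ else x$cutoff,
    sensitivity = mean(x$reps$sensitivity),
    specificity = mean(x$reps$specificity),
    n_reps = nrow(x$reps)
  )
}

#' Nonparametric group comparison of a metric across cohorts
#'
#' Thin wrapper over `stats::kruskal.test` plus pairwise Wilcoxon tests
#' with Holm correction, for reporting alongside the ROC analyses.
#'
#' @param scores Named list of numeric vectors, one per group.
#' @return A list with `kruskal` (htest) and `pairwise` (tibble of
#'   group pairs and adjusted p-values).
#' @export
compare_groups <- function(scores) {
  stopifnot(is.list(scores), length(scores) >= 2)
  x <- unlist(scores, use.names = FALSE)
  gl <- factor(rep(names(scores), lengths(scores)))
  kw <- stats::kruskal.test(x, gl)
  pw <- stats::pairwise.wilcox.test(x, gl, p.adjust.method = "holm")
  m <- pw$p.value
  idx <- which(!is.na(m), arr.ind = TRUE)
  pairwise <- tibble::tibble(
    group1 = rownames(m)[idx[, 1]],
    group2 = colnames(m)[idx[, 2]],
    p_adj = m[idx]
  )
  list(kruskal = kw, pairwise = pairwise)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
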