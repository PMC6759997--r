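#' Construct a single-ROI paired intensity measurement
#'
#' One region of interest (ROI, one cell) from a two-channel fluorescence
#' image: paired per-pixel intensities of the two channels plus the
#' condition label of the image it came from.
#'
#' @param roi_id character identifier.
#' @param condition condition label (e.g. `"untransfected"`, `"24h"`).
#' @param ch1,ch2 non-negative numeric intensity vectors of equal length
#'   (>= 3 pixels).
#' @return An object of class `roi_measurement`.
#' @export
roi_measurement <- function(roi_id, condition, ch1, ch2) {
  if (length(ch1) != length(ch2)) stop("channel vectors differ in length")
  if (length(ch1) < 3) stop("an ROI needs at least 3 pixels")
  if (any(ch1 < 0) || any(ch2 < 0)) stop("intensities must be non-negative")
  structure(list(roi_id = as.character(roi_id),
                 condition = as.character(condition),
                 ch1 = as.numeric(ch1), ch2 = as.numeric(ch2)),
            class = "roi_measurement")
}

#' Subtract a scalar background from an intensity vector
#'
#' Element-wise `max(intensity - background, 0)`.
#'
#' @param channel numeric intensity vector.
#' @param background single non-negative value.
#' @return Corrected vector.
#' @export
subtract_background <- function(channel, background) {
  if (length(background) != 1 || is.na(background) || background < 0) {
    stop("background must be a single non-negative value")
  }
  pmax(channel - background, 0)
}

#' Estimate a scalar background as a low percentile of the image
#'
#' @param channel numeric intensity vector (whole image or ROI).
#' @param prob percentile used as the background level, default 0.05.
#' @return Single background value.
#' @export
estimate_background <- function(channel, prob = 0.05) {
  if (prob < 0 || prob > 1) stop("prob must be in [0, 1]")
  unname(stats::quantile(channel, probs = prob, type = 7))
}

#' Pearson colocalization coefficient of one ROI
#'
#' Product-moment correlation of the two channels over the paired pixels of
#' the ROI, after optional scalar background subtraction per channel.
#'
#' @param m an [roi_measurement()].
#' @param background length-2 numeric of per-channel backgrounds (or a
#'   single value applied to both), default `c(0, 0)`.
#' @return Pearson r in `[-1, 1]`.
#' @export
pearson_roi <- function(m, background = c(0, 0)) {
  if (length(background) == 1) background <- rep(background, 2)
  x <- subtract_background(m$ch1, background[1])
  y <- subtract_background(m$ch2, background[2])
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant channel after background subtraction: r undefined")
  }
  stats::cor(x, y)
}

#' Compare per-ROI correlation values between two conditions
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test. For small groups (both
#' sizes <= `exact_max_n`) the exact null distribution is used: via the
#' exact rank-sum distribution when there are no ties, and by complete
#' enumeration of group assignments when there are. Larger groups use the
#' normal approximation with continuity and tie correction. Significance
#' stars follow the convention p <= 1e-4 `"****"`, <= 1e-3 `"***"`,
#' <= 0.01 `"**"`, <= 0.05 `"*"`, else `"ns"`.
#'
#' @param a,b numeric vectors of per-ROI Pearson r values (each >= 2).
#' @param exact_max_n largest per-group size for the exact test, default 12.
#' @return A list of class `group_comparison`: `group_a`, `group_b`,
#'   `u_statistic` (Mann-Whitney U of group `a`), `p_value`, `stars`,
#'   `method`.
#' @export
compare_conditions <- function(a, b, exact_max_n = 12) {
  if (length(a) < 2 || length(b) < 2) {
    stop("each group needs at least 2 values")
  }
  na <- length(a)
  nb <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- anyDuplicated(pooled) > 0

  if (max(na, nb) <= exact_max_n && !ties) {
    p <- stats::wilcox.test(a, b, exact = TRUE)$p.value
    method <- "exact"
  } else if (max(na, nb) <= exact_max_n &&
             choose(na + nb, na) <= 5e5) {
    p <- mw_enumerate_p(r, na)
    method <- "exact (enumeration, ties)"
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value)
    method <- "normal approximation"
  }
  stars <- stars_for_p(p)
  structure(list(group_a = a, group_b = b, u_statistic = u,
                 p_value = p, stars = stars, method = method),
            class = "group_comparison")
}

# Two-sided permutation p from complete enumeration of which pooled ranks
# belong to group a; handles ties through midranks.
mw_enumerate_p <- function(pooled_ranks, na) {
  n <- length(pooled_ranks)
  mid <- na * (n - na) / 2
  u_obs <- sum(pooled_ranks[seq_len(na)]) - na * (na + 1) / 2
  combos <- utils::combn(n, na)
  u_perm <- colSums(matrix(pooled_ranks[combos], nrow = na)) -
    na * (na + 1) / 2
  mean(abs(u_perm - mid) >= abs(u_obs - mid) - 1e-9)
}

#' Significance stars for a p value
#'
#' @param p p value in `[0, 1]`.
#' @return `"****"`, `"***"`, `"**"`, `"*"` or `"ns"`.
#' @export
stars_for_p <- function(p) {
  vapply(p, function(pp) {
    if (is.na(pp)) return(NA_character_)
    if (pp <= 1e-4) "****"
    else if (pp <= 1e-3) "***"
    else if (pp <= 0.01) "**"
    else if (pp <= 0.05) "*"
    else "ns"
  }, character(1))
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "Mann-Whitney (%s): n = %d vs %d, U = %g, p = %.4g %s\n",
    x$method, length(x$group_a), length(x$group_b),
    x$u_statistic, x$p_value, x$stars))
  invisible(x)
}
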