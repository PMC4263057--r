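#' Mann-Whitney U test for two small groups
#'
#' Rank-sum comparison of two independent samples, reporting the U statistic
#' of the first group, the normal-approximation z without continuity
#' correction (tie-corrected variance) and its two-sided p, and — whenever
#' the pooled size is at most 12 — an exact two-sided p obtained by complete
#' enumeration of the permutation distribution of U (valid under ties, where
#' the classical exact tables are not). Both p-values are always reported
#' together for small cohorts because they can differ materially (e.g. fully
#' separated 2-vs-4 groups: asymptotic 0.064, exact 2/15).
#'
#' @param x,y numeric samples for the two groups (both non-empty).
#' @return List with \code{u} (U of \code{x}), \code{z},
#'   \code{p_asymptotic}, \code{p_exact} (NA when pooled n > 12) and
#'   \code{degenerate} (TRUE when all pooled values are identical, in which
#'   case both p-values are 1).
#' @export
mann_whitney <- function(x, y) {
  if (!length(x) || !length(y))
    stop_invalid_spec("both groups must be non-empty")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  pooled <- c(x, y)
  r <- rank(pooled)
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2

  if (diff(range(pooled)) == 0) {
    return(list(u = u1, z = 0, p_asymptotic = 1,
                p_exact = if (n <= 12L) 1 else NA_real_, degenerate = TRUE))
  }

  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  z <- (u1 - n1 * n2 / 2) / sqrt(sigma2)
  p_asym <- min(1, 2 * stats::pnorm(-abs(z)))

  p_exact <- NA_real_
  if (n <= 12L) {
    subsets <- utils::combn(n, n1)
    offset <- n1 * (n1 + 1) / 2
    u_all <- colSums(matrix(r[subsets], nrow = n1)) - offset
    eps <- 1e-9
    lo <- mean(u_all <= u1 + eps)
    hi <- mean(u_all >= u1 - eps)
    p_exact <- min(1, 2 * min(lo, hi))
  }
  list(u = u1, z = z, p_asymptotic = p_asym, p_exact = p_exact,
       degenerate = FALSE)
}

#' Fisher's exact test for a 2 x 2 table
#'
#' Two-sided p-value: the sum of hypergeometric probabilities, at the
#' observed margins, of all tables at most as probable as the observed one.
#' A table with an empty margin carries no information and returns p = 1
#' with a degenerate flag.
#'
#' @param tab 2 x 2 matrix of non-negative integer counts.
#' @return List with \code{p} and \code{degenerate}.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (any(dim(tab) != 2L) || any(tab < 0) || any(tab != round(tab)))
    stop_invalid_spec("tab must be a 2 x 2 matrix of non-negative integers")
  m <- sum(tab[, 1]); nn <- sum(tab[, 2]); k <- sum(tab[1, ])
  if (m == 0 || nn == 0 || k == 0 || sum(tab[2, ]) == 0)
    return(list(p = 1, degenerate = TRUE))
  xs <- max(0, k - nn):min(k, m)
  probs <- stats::dhyper(xs, m, nn, k)
  p_obs <- stats::dhyper(tab[1, 1], m, nn, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  list(p = min(1, p), degenerate = FALSE)
}

#' Group summary of per-subject metrics
#'
#' Builds the familiar two-group clinical summary: per metric and group, the
#' mean and n-1 sample SD (SD reported as NA with a flag when a group has a
#' single value), plus the Mann-Whitney comparison between groups
#' ([mann_whitney()], both asymptotic and exact p reported).
#'
#' @param records data.frame with columns \code{subject_id}, \code{group}
#'   and one numeric column per metric.
#' @param metrics metric column names to summarize; default all numeric
#'   columns except \code{subject_id}.
#' @param group_levels the two group labels, in display order; default the
#'   sorted unique values of \code{group}.
#' @return data.frame of class \code{group_summary}: one row per metric with
#'   \code{mean_<g>}, \code{sd_<g>}, \code{n_<g>} for each group and
#'   \code{u}, \code{z}, \code{p_asymptotic}, \code{p_exact}.
#' @examples
#' rec <- cohort_cases()
#' summarize_cohort(rec, metrics = c("q_max", "v_max"))
#' @export
summarize_cohort <- function(records, metrics = NULL, group_levels = NULL) {
  stopifnot(is.data.frame(records))
  if (!all(c("subject_id", "group") %in% names(records)))
    stop_invalid_spec("records need 'subject_id' and 'group' columns")
  if (is.null(group_levels)) group_levels <- sort(unique(records$group))
  if (length(group_levels) != 2L ||
      !all(group_levels %in% records$group))
    stop_invalid_spec("exactly two non-empty groups are required")
  if (is.null(metrics))
    metrics <- setdiff(names(records)[vapply(records, is.numeric, logical(1))],
                       c("subject_id"))
  for (m in metrics) {
    if (!m %in% names(records))
      stop_invalid_spec(sprintf("metric '%s' not present in records", m))
    bad <- which(!is.finite(records[[m]]))
    if (length(bad))
      stop_pcmri(sprintf("subject '%s' is missing metric '%s'",
                         records$subject_id[bad[1]], m),
                 "pcmri_missing_metric")
  }
  rows <- lapply(metrics, function(m) {
    a <- records[[m]][records$group == group_levels[1]]
    b <- records[[m]][records$group == group_levels[2]]
    mw <- mann_whitney(a, b)
    out <- data.frame(metric = m,
                      mean_a = mean(a),
                      sd_a = if (length(a) > 1) stats::sd(a) else NA_real_,
                      n_a = length(a),
                      mean_b = mean(b),
                      sd_b = if (length(b) > 1) stats::sd(b) else NA_real_,
                      n_b = length(b),
                      u = mw$u, z = mw$z,
                      p_asymptotic = mw$p_asymptotic, p_exact = mw$p_exact,
                      stringsAsFactors = FALSE)
    names(out) <- sub("_a$", paste0("_", group_levels[1]), names(out))
    names(out) <- sub("_b$", paste0("_", group_levels[2]), names(out))
    out
  })
  out <- do.call(rbind, rows)
  attr(out, "group_levels") <- group_levels
  class(out) <- c("group_summary", class(out))
  out
}

#' Format a group summary at a chosen display precision
#'
#' Rounds means and SDs half-away-from-zero to a per-metric number of
#' decimals (the convention used in printed clinical tables); the raw
#' doubles in the summary itself are untouched.
#'
#' @param summary a [summarize_cohort()] result.
#' @param digits single integer or named vector (by metric) of decimals.
#' @return data.frame of character columns \code{"mean +/- sd"} per group.
#' @export
format_group_summary <- function(summary, digits = 2) {
  stopifnot(inherits(summary, "group_summary"))
  gl <- attr(summary, "group_levels")
  dg <- if (length(digits) == 1L)
    stats::setNames(rep(digits, nrow(summary)), summary$metric)
  else digits
  fmt <- function(mu, sd, d) {
    if (is.na(sd)) sprintf("%s (n=1)", format(round_half_away(mu, d)))
    else sprintf("%s ± %s", format(round_half_away(mu, d)),
                 format(round_half_away(sd, d)))
  }
  data.frame(
    metric = summary$metric,
    stats::setNames(data.frame(
      vapply(seq_len(nrow(summary)), function(i)
        fmt(summary[[paste0("mean_", gl[1])]][i],
            summary[[paste0("sd_", gl[1])]][i], dg[summary$metric[i]]),
        character(1)),
      vapply(seq_len(nrow(summary)), function(i)
        fmt(summary[[paste0("mean_", gl[2])]][i],
            summary[[paste0("sd_", gl[2])]][i], dg[summary$metric[i]]),
        character(1)),
      stringsAsFactors = FALSE), gl),
    p_asymptotic = signif(summary$p_asymptotic, 2),
    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Published per-case aortic-root hemodynamics cohort
#'
#' Per-case hemodynamic and wall-elasticity metrics for a published
#' proof-of-concept cohort of two healthy controls and four recipients of a
#' composite valve-conduit aortic-root prosthesis: sinus area (cm^2) and
#' diameter (cm), peak and mean volumetric flow (ml/s), peak velocity
#' (cm/s), effective orifice area (cm^2) and its ratio to the sinus area,
#' compliance (mm^2 mmHg^-1 10^-3), distensibility (mmHg^-1 10^-3) and
#' stiffness index beta. Useful as a worked example for
#' [summarize_cohort()].
#'
#' @return data.frame with one row per subject.
#' @export
cohort_cases <- function() {
  f <- system.file("extdata", "aortic_root_cases.csv", package = "pcmriflow",
                   mustWork = TRUE)
  utils::read.csv(f, stringsAsFactors = FALSE)
}
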