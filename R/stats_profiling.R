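#' Pooled-variance two-sample t-test
#'
#' Student's t with pooled variance and `n_a + n_b - 2` degrees of freedom
#' (Welch available behind `var_equal = FALSE`). The statistic is computed
#' for `mean(a) - mean(b)`. Two degenerate cases are handled explicitly:
#' both groups constant and equal gives `t = 0, p = 1`; both constant but
#' unequal is flagged degenerate (no finite statistic) rather than
#' returning infinities.
#'
#' @param a,b numeric vectors with at least 2 values each.
#' @param var_equal pooled variance (classic Student) when TRUE.
#' @return list with `t`, `p`, `df`, `degenerate`.
#' @examples
#' two_sample_t(c(1, 2, 3), c(4, 5, 6))  # t = -3.674, p = 0.0214
#' @export
two_sample_t <- function(a, b, var_equal = TRUE) {
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 values")
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, p = 1, df = length(a) + length(b) - 2,
                  degenerate = FALSE))
    return(list(t = NA_real_, p = NA_real_,
                df = length(a) + length(b) - 2, degenerate = TRUE))
  }
  tt <- stats::t.test(a, b, var.equal = var_equal)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), degenerate = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR procedure: on sorted p-values,
#' `q_(i) = min_{j >= i} p_(j) * m / j`, mapped back to input order and
#' capped at 1.
#'
#' @param p_values numeric vector in `[0, 1]` (NAs propagate).
#' @return q-values in input order.
#' @export
bh_fdr <- function(p_values) {
  stopifnot(all(is.na(p_values) | (p_values >= 0 & p_values <= 1)))
  stats::p.adjust(p_values, method = "BH")
}

#' Log response ratio with delta-method confidence interval
#'
#' `RR = ln(mean(treatment) / mean(control))`, with
#' `Var(RR) = s_t^2 / (n_t * m_t^2) + s_c^2 / (n_c * m_c^2)` and an
#' equal-tailed normal interval -- the standard form in the ecology
#' meta-analysis literature. Positive RR means treatment-enriched;
#' significance is the interval excluding 0.
#'
#' @param control,treatment numeric vectors; both means must be positive
#'   for the ratio to exist (otherwise the result is flagged
#'   incomputable).
#' @param confidence interval level, default 0.95.
#' @return list with `rr`, `low`, `high`, `significant`, `computable`.
#' @export
response_ratio <- function(control, treatment, confidence = 0.95) {
  mc <- mean(control); mt <- mean(treatment)
  if (!(mc > 0 && mt > 0))
    return(list(rr = NA_real_, low = NA_real_, high = NA_real_,
                significant = NA, computable = FALSE))
  rr <- log(mt / mc)
  v <- sd(treatment)^2 / (length(treatment) * mt^2) +
       sd(control)^2 / (length(control) * mc^2)
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  half <- z * sqrt(v)
  list(rr = rr, low = rr - half, high = rr + half,
       significant = (rr - half) > 0 || (rr + half) < 0,
       computable = TRUE)
}

#' Group comparison of an abundance matrix
#'
#' Per-target two-group statistics in the layout of a strain-association
#' table: group means with SD and SEM, pooled t and p, BH q-values
#' computed over the targets whose mean normalised hits reach
#' `min_mean_hits` in at least one group (low-abundance targets keep their
#' raw p but are not part of the FDR set), and the log response ratio of
#' group B over group A with its confidence interval.
#'
#' @param mat targets-by-samples matrix, e.g. from [abundance_matrix()].
#' @param groups named character vector mapping sample name to group, or a
#'   data frame with columns `sample` and `group`; exactly two groups,
#'   each with at least 2 samples. The first group (in factor order) is
#'   treated as A (control/reference), the second as B (treatment).
#' @param method `"ttest"`, `"response_ratio"` or both.
#' @param min_mean_hits abundance gate for the FDR set, default 5.
#' @param confidence response-ratio interval level.
#' @return data frame sorted by p with one row per target.
#' @export
compare_groups <- function(mat, groups,
                           method = c("ttest", "response_ratio"),
                           min_mean_hits = 5, confidence = 0.95) {
  method <- match.arg(method, several.ok = TRUE)
  if (is.data.frame(groups)) {
    stopifnot(all(c("sample", "group") %in% names(groups)))
    groups <- stats::setNames(as.character(groups$group), groups$sample)
  }
  if (!all(colnames(mat) %in% names(groups)))
    stop("samples missing from group table: ",
         paste(setdiff(colnames(mat), names(groups)), collapse = ", "))
  groups <- groups[colnames(mat)]
  lev <- sort(unique(groups))
  if (length(lev) != 2) stop("exactly two groups required")
  a_cols <- names(groups)[groups == lev[1]]
  b_cols <- names(groups)[groups == lev[2]]
  if (length(a_cols) < 2 || length(b_cols) < 2)
    stop("each group needs at least 2 samples")

  rows <- lapply(rownames(mat), function(tg) {
    a <- mat[tg, a_cols]; b <- mat[tg, b_cols]
    out <- data.frame(target = tg,
                      n_A = length(a), mean_A = mean(a), sd_A = sd(a),
                      sem_A = sd(a) / sqrt(length(a)),
                      n_B = length(b), mean_B = mean(b), sd_B = sd(b),
                      sem_B = sd(b) / sqrt(length(b)),
                      stringsAsFactors = FALSE)
    if ("ttest" %in% method) {
      tt <- two_sample_t(a, b)
      out$t <- tt$t; out$p <- tt$p; out$degenerate <- tt$degenerate
    }
    if ("response_ratio" %in% method) {
      r <- response_ratio(a, b, confidence)
      out$rr <- r$rr; out$rr_low <- r$low; out$rr_high <- r$high
    }
    out$enriched_in <- if (mean(b) > mean(a)) lev[2] else
      if (mean(b) < mean(a)) lev[1] else NA_character_
    out
  })
  res <- do.call(rbind, rows)
  if ("ttest" %in% method) {
    gate <- res$mean_A >= min_mean_hits | res$mean_B >= min_mean_hits
    res$q <- NA_real_
    res$q[gate] <- bh_fdr(res$p[gate])
    res <- res[order(res$p), , drop = FALSE]
  }
  rownames(res) <- NULL
  res
}
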