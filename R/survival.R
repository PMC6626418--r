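# Kaplan-Meier product-limit estimation and the Mantel-Haenszel (log-rank)
# test, implemented from first principles (the survival package is used only
# as an independent oracle in the test suite). Convention: event = 1 means
# death observed at `time`; event = 0 means right-censored at `time`; at tied
# times, events precede censorings.

#' Kaplan-Meier product-limit estimate
#'
#' @param time Non-negative times (days).
#' @param event 0/1 event indicators (1 = death observed).
#' @return Object of class `km_curve`: `event_times` (distinct times with at
#'   least one event, ascending), `survival` (step values), `at_risk`,
#'   `n_events`, `median` (days) and `median_censored` (`TRUE` when the curve
#'   never reaches 0.5, in which case `median` is the maximum observed time
#'   and should be read as "> median" days).
#' @export
km_estimate <- function(time, event) {
  stopifnot(length(time) == length(event), length(time) >= 1L)
  if (any(time < 0)) stop("negative survival time")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  ord <- order(time, -event) # events first within ties
  time <- time[ord]
  event <- event[ord]
  n <- length(time)

  ev_times <- sort(unique(time[event == 1]))
  at_risk <- integer(length(ev_times))
  n_events <- integer(length(ev_times))
  surv <- numeric(length(ev_times))
  s <- 1
  for (i in seq_along(ev_times)) {
    t_i <- ev_times[i]
    at_risk[i] <- sum(time >= t_i)
    n_events[i] <- sum(time == t_i & event == 1)
    s <- s * (1 - n_events[i] / at_risk[i])
    surv[i] <- s
  }
  below <- which(surv <= 0.5 + 1e-15)
  if (length(below)) {
    median <- ev_times[below[1]]
    median_censored <- FALSE
  } else {
    median <- max(time)
    median_censored <- TRUE
  }
  structure(list(event_times = ev_times, survival = surv, at_risk = at_risk,
                 n_events = n_events, n = n, median = median,
                 median_censored = median_censored),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  med <- if (x$median_censored) paste0("> ", x$median) else x$median
  cat("<km_curve> n = ", x$n, ", ", sum(x$n_events), " events, median ",
      med, " days\n", sep = "")
  invisible(x)
}

#' Mantel-Haenszel (log-rank) test for two or more groups
#'
#' At each distinct event time a (groups x 2) hypergeometric table of
#' deaths/survivors among those at risk contributes observed-minus-expected
#' deaths and their (co)variance; the statistic is the quadratic form, chi
#' squared with (groups - 1) degrees of freedom.
#'
#' @param time,event As in [km_estimate()].
#' @param group Group labels (>= 2 non-empty groups).
#' @return Object of class `logrank_result`: `chi_square`, `df`, `p_value`,
#'   `n` (per-group sizes), `observed`, `expected`.
#' @export
logrank <- function(time, event, group) {
  stopifnot(length(time) == length(event), length(time) == length(group))
  if (any(time < 0)) stop("negative survival time")
  group <- factor(group)
  g <- nlevels(group)
  if (g < 2L) stop("log-rank test needs at least two groups")
  if (sum(event) == 0) stop("log-rank test undefined with zero events")

  ev_times <- sort(unique(time[event == 1]))
  obs <- numeric(g)
  exp_d <- numeric(g)
  V <- matrix(0, g, g)
  for (t_i in ev_times) {
    at_risk <- time >= t_i
    n_i <- sum(at_risk)
    n_ig <- tabulate(group[at_risk], g)
    d_i <- sum(time == t_i & event == 1)
    d_ig <- tabulate(group[time == t_i & event == 1], g)
    obs <- obs + d_ig
    exp_d <- exp_d + d_i * n_ig / n_i
    if (n_i > 1) {
      c_i <- d_i * (n_i - d_i) / (n_i - 1) / n_i^2
      V <- V + c_i * (diag(n_ig * n_i, g) - outer(n_ig, n_ig))
    }
  }
  u <- (obs - exp_d)[-g]
  Vr <- V[-g, -g, drop = FALSE]
  chi <- tryCatch(drop(t(u) %*% solve(Vr, u)), error = function(e) {
    drop(t(u) %*% MASS_ginv(Vr) %*% u)
  })
  df <- g - 1L
  structure(list(chi_square = chi, df = df,
                 p_value = stats::pchisq(chi, df, lower.tail = FALSE),
                 n = tabulate(group, g), observed = obs, expected = exp_d,
                 groups = levels(group)),
            class = "logrank_result")
}

# Moore-Penrose pseudoinverse (tiny local fallback for a singular log-rank
# covariance, e.g. a group with no one at risk at any event time).
MASS_ginv <- function(m, tol = 1e-10) {
  s <- svd(m)
  keep <- s$d > tol * max(s$d)
  if (!any(keep)) return(matrix(0, ncol(m), nrow(m)))
  s$v[, keep, drop = FALSE] %*% (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' @export
print.logrank_result <- function(x, ...) {
  cat("<logrank> chi2 = ", signif(x$chi_square, 4), ", df = ", x$df,
      ", p = ", signif(x$p_value, 3), "\n", sep = "")
  invisible(x)
}

#' Compare survival across cluster cohorts
#'
#' Kaplan-Meier curve and median per cluster, every pairwise log-rank test,
#' an overall k-group log-rank, and the headline p value: the minimum
#' unadjusted pairwise p ("the two most disparate survival curves"). Because
#' the minimum of pairwise p values is anti-conservative, a
#' Bonferroni-adjusted column is reported alongside; neither replaces the
#' other.
#'
#' @param solution A `cluster_solution` (or a named integer vector of labels
#'   with sample IDs as names).
#' @param pheno A [phenotype_table()].
#' @param min_group_size Clusters smaller than this are excluded with a
#'   warning (default 5).
#' @return Object of class `survival_report`: `curves` (per-cluster
#'   [km_estimate()]), `pairwise` (data frame), `overall`
#'   (a `logrank_result` or `NULL`), `headline_p`, `most_disparate_pair`,
#'   `n_dropped` (labelled samples without survival data).
#' @export
compare_clusters <- function(solution, pheno, min_group_size = 5L) {
  stopifnot(inherits(pheno, "phenotype_table"))
  if (inherits(solution, "cluster_solution")) {
    labels <- solution$labels
    ids <- solution$sample_ids
  } else {
    labels <- as.integer(solution)
    ids <- names(solution)
  }
  if (is.null(ids)) stop("cluster labels must carry sample IDs")

  m <- match(ids, pheno$sample_id)
  dropped <- sum(is.na(m))
  if (dropped > 0) {
    message(dropped, " labelled sample(s) lack survival data; dropped")
  }
  keep <- !is.na(m)
  labels <- labels[keep]
  time <- pheno$os_time[m[keep]]
  event <- pheno$os_event[m[keep]]

  sizes <- table(labels)
  small <- as.integer(names(sizes)[sizes < min_group_size])
  if (length(small)) {
    warning("excluding cluster(s) below min_group_size: ",
            paste(small, collapse = ", "))
    keep2 <- !(labels %in% small)
    labels <- labels[keep2]
    time <- time[keep2]
    event <- event[keep2]
  }
  clusters <- sort(unique(labels))
  curves <- lapply(clusters, function(k) {
    km_estimate(time[labels == k], event[labels == k])
  })
  names(curves) <- as.character(clusters)

  pairwise <- NULL
  overall <- NULL
  headline_p <- NA_real_
  pair <- c(NA_integer_, NA_integer_)
  if (length(clusters) >= 2L && sum(event) > 0) {
    combos <- utils::combn(clusters, 2L)
    pw <- data.frame(cluster_a = combos[1, ], cluster_b = combos[2, ],
                     chi_square = NA_real_, p_value = NA_real_)
    for (j in seq_len(ncol(combos))) {
      sel <- labels %in% combos[, j]
      if (sum(event[sel]) == 0) next
      lr <- logrank(time[sel], event[sel], labels[sel])
      pw$chi_square[j] <- lr$chi_square
      pw$p_value[j] <- lr$p_value
    }
    pw$p_bonferroni <- pmin(1, pw$p_value * nrow(pw))
    pairwise <- pw
    overall <- logrank(time, event, labels)
    if (any(!is.na(pw$p_value))) {
      best <- which.min(pw$p_value)
      headline_p <- pw$p_value[best]
      pair <- c(pw$cluster_a[best], pw$cluster_b[best])
    }
  }
  structure(list(curves = curves, pairwise = pairwise, overall = overall,
                 headline_p = headline_p, most_disparate_pair = pair,
                 clusters = clusters, n_dropped = dropped),
            class = "survival_report")
}

#' @export
print.survival_report <- function(x, ...) {
  cat("<survival_report> ", length(x$clusters), " cluster(s)\n", sep = "")
  for (k in names(x$curves)) {
    cv <- x$curves[[k]]
    med <- if (cv$median_censored) paste0("> ", round(cv$median)) else round(cv$median)
    cat("  cluster ", k, ": n = ", cv$n, ", median ", med, " days\n", sep = "")
  }
  if (!is.na(x$headline_p)) {
    cat("  most disparate pair ", x$most_disparate_pair[1], " vs ",
        x$most_disparate_pair[2], ": p = ", signif(x$headline_p, 3), "\n",
        sep = "")
  }
  invisible(x)
}
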