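# per-field score matrix for fast resampling: rows = distinct fields,
# cols = species, entries = class rank (0 = absent); plus region per field
.field_matrix <- function(survey) {
  fl <- .field_level(survey)
  fields <- unique(survey[, c("field_id", "region")])
  sp <- sort(unique(fl$species))
  M <- matrix(0L, nrow(fields), length(sp),
              dimnames = list(fields$field_id, sp))
  M[cbind(match(fl$field_id, fields$field_id),
          match(fl$species, sp))] <- .class_rank(fl$score)
  list(M = M, region = fields$region, species = sp)
}

#' Stratified resample of a survey
#'
#' Draws fields with replacement within each regional stratum so that the
#' resampled survey has exactly \code{strata_sizes[r]} fields in region
#' \code{r}, equalizing sampling effort with a reference design.
#' Resampled duplicate fields receive fresh field identifiers. Uses the
#' current RNG state; call \code{set.seed()} for reproducibility.
#'
#' @param survey A validated survey table (typically one period).
#' @param strata_sizes Named integer vector, region -> number of fields.
#' @return A survey table with renumbered fields.
#' @export
stratified_resample <- function(survey, strata_sizes) {
  if (is.null(names(strata_sizes)) || any(names(strata_sizes) == ""))
    stop("strata_sizes must be named by region")
  miss <- setdiff(names(strata_sizes), unique(survey$region))
  if (length(miss))
    stop("region(s) absent from the survey: ", paste(miss, collapse = ", "))
  fields <- unique(survey[, c("field_id", "region")])
  picked <- unlist(lapply(names(strata_sizes), function(r) {
    pool <- fields$field_id[fields$region == r]
    pool[sample.int(length(pool), strata_sizes[[r]], replace = TRUE)]
  }), use.names = FALSE)
  idx <- split(seq_len(nrow(survey)), survey$field_id)
  out <- do.call(rbind, lapply(seq_along(picked), function(i) {
    block <- survey[idx[[picked[i]]], , drop = FALSE]
    block$field_id <- sprintf("r%05d", i)
    block
  }))
  rownames(out) <- NULL
  stopifnot(identical(
    as.integer(table(unique(out[, c("field_id", "region")])$region)[
      names(strata_sizes)]),
    as.integer(strata_sizes)))
  out
}

#' Stratified-bootstrap confidence intervals for commonness metrics
#'
#' For each species, the mean and percentile confidence interval of the
#' regional frequency and the midpoint mean local abundance over \code{B}
#' stratified resamples of the survey (fields drawn with replacement
#' within regions, [stratified_resample()]'s scheme). A species absent
#' from a replicate contributes frequency 0 to that replicate and is
#' excluded from the replicate's abundance mean (abundance is defined
#' over fields of presence only).
#'
#' @param survey A validated survey table, usually restricted to one
#'   period/crop; only control plots enter by default.
#' @param strata_sizes Named integer vector, region -> fields per
#'   replicate.
#' @param B Number of bootstrap replicates (>= 2; default 1000).
#' @param level Confidence level in (0, 1); default 0.95 gives the 2.5th
#'   and 97.5th percentiles.
#' @param plot Plot filter passed to the selection (default "control").
#' @param keep_replicates Return the replicate matrices as attributes
#'   \code{"freq_replicates"} / \code{"abund_replicates"}.
#' @return Data frame with one row per species and metric
#'   (\code{"frequency"} in percent, \code{"abundance"} in
#'   individuals/m2): \code{mean}, \code{ci_low}, \code{ci_high}.
#' @export
bootstrap_commonness <- function(survey, strata_sizes, B = 1000,
                                 level = 0.95, plot = "control",
                                 keep_replicates = FALSE) {
  if (B < 2) stop("B must be at least 2")
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  sel <- .select_survey(survey, plot = plot)
  miss <- setdiff(names(strata_sizes), unique(sel$region))
  if (length(miss))
    stop("region(s) absent from the survey: ", paste(miss, collapse = ", "))
  fm <- .field_matrix(sel)
  mids <- c(0, unname(class_midpoints()))  # rank 0 = absent
  A <- matrix(mids[fm$M + 1L], nrow(fm$M), ncol(fm$M))
  P <- fm$M > 0L
  n_total <- sum(strata_sizes)
  pools <- lapply(names(strata_sizes), function(r) which(fm$region == r))
  sizes <- as.integer(strata_sizes)
  freq_rep <- matrix(NA_real_, B, length(fm$species))
  ab_rep <- matrix(NA_real_, B, length(fm$species))
  for (b in seq_len(B)) {
    rows <- unlist(lapply(seq_along(pools), function(j)
      pools[[j]][sample.int(length(pools[[j]]), sizes[j], replace = TRUE)]),
      use.names = FALSE)
    stopifnot(length(rows) == n_total)  # stratum-size conservation
    npres <- colSums(P[rows, , drop = FALSE])
    freq_rep[b, ] <- npres / n_total
    ab <- colSums(A[rows, , drop = FALSE]) / npres
    ab[npres == 0L] <- NA_real_
    ab_rep[b, ] <- ab
  }
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  mk <- function(rep_mat, metric, scale) {
    data.frame(species = fm$species, metric = metric,
               mean = scale * colMeans(rep_mat, na.rm = TRUE),
               ci_low = scale * apply(rep_mat, 2, stats::quantile,
                                      probs[1], na.rm = TRUE),
               ci_high = scale * apply(rep_mat, 2, stats::quantile,
                                       probs[2], na.rm = TRUE),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  out <- rbind(mk(freq_rep, "frequency", 100), mk(ab_rep, "abundance", 1))
  if (keep_replicates) {
    colnames(freq_rep) <- colnames(ab_rep) <- fm$species
    attr(out, "freq_replicates") <- 100 * freq_rep
    attr(out, "abund_replicates") <- ab_rep
  }
  out
}

#' Categorical status call from a bootstrap interval
#'
#' Compares the first-period point value of a species to the second
#' period's bootstrap confidence interval: \code{"+"} (significant
#' increase) when the old value lies below the interval, \code{"-"}
#' (decrease) when above, \code{"="} when inside. Species without a
#' first-period value (\code{NA}: below the survey's recording floor)
#' are \code{"N"} (new) when the interval lower bound reaches the
#' detection threshold, i.e. the species is now established clearly
#' above the old recording floor, and \code{"?"} (undeterminable)
#' otherwise.
#'
#' @param point_p1 First-period point value(s); \code{NA} when the
#'   species was below the recording floor.
#' @param ci_low,ci_high Bootstrap interval of the second-period mean.
#' @param detection_threshold Recording floor of the first survey, on
#'   the metric's scale (default 2.3, the percent-frequency floor of a
#'   survey retaining only its 29 most frequent species).
#' @return Character vector of status codes
#'   \code{"+", "-", "=", "N", "?"}.
#' @export
#' @examples
#' classify_status(26.5, 33.1, 45.1)  # "+"
#' classify_status(38.0, 29.7, 41.1)  # "="
#' classify_status(NA, 8.0, 16.6)     # "N"
classify_status <- function(point_p1, ci_low, ci_high,
                            detection_threshold = 2.3) {
  n <- max(length(point_p1), length(ci_low), length(ci_high))
  point_p1 <- rep_len(point_p1, n)
  ci_low <- rep_len(ci_low, n)
  ci_high <- rep_len(ci_high, n)
  if (any(ci_low > ci_high, na.rm = TRUE))
    stop("invalid interval: ci_low > ci_high")
  out <- character(n)
  known <- !is.na(point_p1)
  out[known & point_p1 < ci_low] <- "+"
  out[known & point_p1 > ci_high] <- "-"
  out[known & point_p1 >= ci_low & point_p1 <= ci_high] <- "="
  out[!known] <- ifelse(ci_low[!known] >= detection_threshold, "N", "?")
  out
}

# exact permutation p-value for Spearman's rho (two-sided), midrank ties
.spearman_exact_p <- function(x, y) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  obs <- stats::cor(rx, ry)
  perms <- matrix(1L, 1, 1)
  for (k in 2:n) {
    m <- nrow(perms)
    perms <- do.call(rbind, lapply(seq_len(k), function(pos) {
      cbind(perms[, seq_len(pos - 1), drop = FALSE], k,
            perms[, seq(pos, k - 1)[seq_len(k - pos)], drop = FALSE])
    }))
  }
  rxc <- rx - mean(rx); ryc <- ry - mean(ry)
  M <- matrix(ryc[perms], nrow(perms), n)
  rho_perm <- drop(M %*% rxc) /
    sqrt(sum(rxc^2) * sum(ryc^2))
  mean(abs(rho_perm) >= abs(obs) - 1e-12)
}

#' Within-period trend test
#'
#' Spearman rank correlation between a yearly commonness metric and the
#' year, with a categorical trend call: \code{"+"}/\code{"-"} when
#' p < \code{alpha} (sign of rho), \code{"(+)"}/\code{"(-)"} for a
#' marginal trend (\code{alpha} <= p < \code{alpha_marginal}), else
#' \code{"="}. P-values use the exact permutation distribution for
#' n <= 9 years (midrank ties) and the t approximation otherwise.
#'
#' @param years Integer vector of years (>= 4 distinct values).
#' @param values Metric value per year (same length).
#' @param alpha Significance level (default 0.05).
#' @param alpha_marginal Marginal-trend level (default 0.10).
#' @return List with \code{rho}, \code{p} and \code{trend}.
#' @export
#' @examples
#' yearly_trend(2002:2008, c(2, 1, 4, 3, 6, 5, 7))
yearly_trend <- function(years, values, alpha = 0.05,
                         alpha_marginal = 0.10) {
  if (length(years) != length(values))
    stop("years and values must have the same length")
  if (length(unique(years)) < 4)
    stop("insufficient data: at least 4 years are required")
  rho <- stats::cor(rank(years), rank(values))
  n <- length(years)
  if (n <= 9) {
    p <- .spearman_exact_p(years, values)
  } else if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  }
  trend <- if (p < alpha) {
    if (rho > 0) "+" else "-"
  } else if (p < alpha_marginal) {
    if (rho > 0) "(+)" else "(-)"
  } else "="
  list(rho = rho, p = p, trend = trend)
}

#' Per-year commonness metrics
#'
#' Regional frequency (percent) and mean local abundance per survey
#' year, either raw or effort-equalized by a per-year stratified
#' bootstrap mean.
#'
#' @param survey A validated survey table (one period).
#' @param strata_sizes Optional named vector of per-region field counts;
#'   when supplied, each year's metrics are the mean over \code{B}
#'   stratified resamples of that year's fields.
#' @param B Bootstrap replicates per year (default 200).
#' @param plot Plot filter (default "control").
#' @return Data frame with columns \code{year}, \code{species},
#'   \code{frequency}, \code{abundance}.
#' @export
yearly_metrics <- function(survey, strata_sizes = NULL, B = 200,
                           plot = "control") {
  sel <- .select_survey(survey, plot = plot)
  out <- lapply(sort(unique(sel$year)), function(yr) {
    s <- sel[sel$year == yr, , drop = FALSE]
    if (is.null(strata_sizes)) {
      ss <- species_summary(s, plot = plot)
      data.frame(year = yr, species = ss$species,
                 frequency = 100 * ss$F, abundance = ss$A,
                 stringsAsFactors = FALSE)
    } else {
      bc <- bootstrap_commonness(s, strata_sizes, B = B, plot = plot)
      fr <- bc[bc$metric == "frequency", ]
      ab <- bc[bc$metric == "abundance", ]
      data.frame(year = yr, species = fr$species, frequency = fr$mean,
                 abundance = ab$mean[match(fr$species, ab$species)],
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Between-period status table
#'
#' Assembles the per-species status report: second-period bootstrap mean
#' and confidence interval for frequency and abundance, first-period
#' point values, categorical status calls, and the within-period
#' Spearman trend.
#'
#' @param survey_p2 Second-period survey table.
#' @param reference Data frame with columns \code{species},
#'   \code{freq_p1} (percent) and \code{abund_p1} (individuals/m2);
#'   \code{NA} for species below the first survey's recording floor.
#'   Species absent from \code{reference} are treated as \code{NA}.
#' @param strata_sizes Named region -> field-count vector matching the
#'   first-period design.
#' @param B,level Bootstrap replicates and confidence level.
#' @param detection_threshold_freq,detection_threshold_abund Recording
#'   floors used by [classify_status()] for the two metrics (defaults
#'   2.3 percent and 0.5 individuals/m2).
#' @param trend Logical: add the per-year Spearman trend columns
#'   (default TRUE when the survey spans >= 4 years).
#' @param seed Optional integer seed.
#' @return Data frame, one row per species, ordered by decreasing
#'   second-period frequency.
#' @export
status_table <- function(survey_p2, reference = NULL, strata_sizes,
                         B = 1000, level = 0.95,
                         detection_threshold_freq = 2.3,
                         detection_threshold_abund = 0.5,
                         trend = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  bc <- bootstrap_commonness(survey_p2, strata_sizes, B = B, level = level)
  fr <- bc[bc$metric == "frequency", ]
  ab <- bc[bc$metric == "abundance", ]
  ab <- ab[match(fr$species, ab$species), ]
  out <- data.frame(species = fr$species,
                    freq_p2 = fr$mean, freq_lo = fr$ci_low,
                    freq_hi = fr$ci_high,
                    abund_p2 = ab$mean, abund_lo = ab$ci_low,
                    abund_hi = ab$ci_high, stringsAsFactors = FALSE)
  if (is.null(reference))
    reference <- data.frame(species = character(0), freq_p1 = numeric(0),
                            abund_p1 = numeric(0))
  m <- match(out$species, reference$species)
  out$freq_p1 <- reference$freq_p1[m]
  out$abund_p1 <- reference$abund_p1[m]
  out$freq_status <- classify_status(out$freq_p1, out$freq_lo, out$freq_hi,
                                     detection_threshold_freq)
  out$abund_status <- classify_status(out$abund_p1, out$abund_lo,
                                      out$abund_hi,
                                      detection_threshold_abund)
  if (is.null(trend))
    trend <- length(unique(survey_p2$year)) >= 4
  if (trend) {
    ym <- yearly_metrics(survey_p2)
    tr <- lapply(out$species, function(s) {
      d <- ym[ym$species == s, , drop = FALSE]
      yrs <- sort(unique(ym$year))
      v <- d$frequency[match(yrs, d$year)]
      v[is.na(v)] <- 0
      yearly_trend(yrs, v)
    })
    out$trend_rho <- vapply(tr, `[[`, numeric(1), "rho")
    out$trend_p <- vapply(tr, `[[`, numeric(1), "p")
    out$trend <- vapply(tr, `[[`, character(1), "trend")
  }
  out <- out[order(-out$freq_p2), ]
  rownames(out) <- NULL
  out
}
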