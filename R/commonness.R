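#' Mean local abundance from cover-class counts
#'
#' Converts per-species cover-class counts to a mean density over the
#' fields of presence, weighting each occurrence by its class midpoint:
#' \deqn{A = [11.5 n_3 + 35.5 n_4 + 75.5 n_5 + 1.5 (N - n_3 - n_4 - n_5)] / N}
#' where \eqn{n_3}, \eqn{n_4}, \eqn{n_5} count fields scored 3, 4, 5 and
#' \eqn{N} is the total number of occurrences. All lower classes
#' (\code{"+"}, 1, 2) carry the midpoint 1.5, so \eqn{A} is always in
#' [1.5, 75.5].
#'
#' @param n3,n4,n5 Nonnegative integer counts of fields scored 3, 4, 5.
#' @param N Positive integer, total number of occurrences (fields of
#'   presence). Must satisfy \code{n3 + n4 + n5 <= N}.
#' @return Numeric vector of mean densities (individuals/m2).
#' @export
#' @examples
#' mean_local_abundance(0, 0, 0, 4)   # 1.5
#' mean_local_abundance(2, 1, 1, 10)  # 14.3
mean_local_abundance <- function(n3, n4, n5, N) {
  counts <- cbind(n3 = n3, n4 = n4, n5 = n5, N = N)
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("class counts must be finite and nonnegative")
  if (any(counts != round(counts)))
    stop("class counts must be integers")
  if (any(counts[, "N"] < 1))
    stop("mean local abundance is undefined when N = 0 (no occurrence)")
  n345 <- counts[, "n3"] + counts[, "n4"] + counts[, "n5"]
  if (any(n345 > counts[, "N"]))
    stop("n3 + n4 + n5 must not exceed N")
  unname((11.5 * counts[, "n3"] + 35.5 * counts[, "n4"] +
            75.5 * counts[, "n5"] + 1.5 * (counts[, "N"] - n345)) /
           counts[, "N"])
}

#' Count cover-class scores
#'
#' Tallies a vector of class symbols into the counts consumed by
#' [mean_local_abundance()].
#'
#' @param scores Character vector of class symbols (see
#'   [abundance_classes()]).
#' @return Named list with elements \code{n3}, \code{n4}, \code{n5} and
#'   \code{N}.
#' @export
class_counts <- function(scores) {
  scores <- .normalize_score(scores)
  bad <- setdiff(unique(scores), abundance_classes())
  if (length(bad))
    stop("unknown score symbol(s): ", paste(bad, collapse = ", "))
  list(n3 = sum(scores == "3"), n4 = sum(scores == "4"),
       n5 = sum(scores == "5"), N = length(scores))
}

#' Normalized between-period change index
#'
#' The change in a commonness statistic (regional frequency or local
#' abundance) between two survey periods, normalized to [-1, 1]:
#' \deqn{Ch = (S_{new} - S_{old}) / (S_{new} + S_{old})}
#' The index is antisymmetric under period swap, equals 1 for a new
#' colonizer (\code{s_old = 0}) and -1 for a local extinction.
#'
#' @param s_old,s_new Nonnegative statistic values in the earlier and
#'   later period. At least one of each pair must be positive.
#' @return Numeric vector of change indices in [-1, 1].
#' @export
#' @examples
#' change_index(26.5, 39.1)  # 0.192
change_index <- function(s_old, s_new) {
  if (any(!is.finite(s_old)) || any(!is.finite(s_new)) ||
      any(s_old < 0) || any(s_new < 0))
    stop("change_index requires finite nonnegative inputs")
  tot <- s_old + s_new
  if (any(tot == 0))
    stop("change index undefined when both period values are zero")
  (s_new - s_old) / tot
}

# aggregate a survey to field level: one row per (field, species) keeping
# the maximum class over repeated visits (years) of the same field
.field_level <- function(survey) {
  key <- paste(survey$field_id, survey$species, sep = "\r")
  rk <- .class_rank(survey$score)
  best <- tapply(rk, key, max)
  keep <- match(paste(names(best),
                      unname(best), sep = "\r"),
                paste(key, rk, sep = "\r"))
  survey[keep, , drop = FALSE]
}

# filter a survey table by period / crop / plot; NULL keeps everything
.select_survey <- function(survey, period = NULL, crop = NULL, plot = "control") {
  keep <- rep(TRUE, nrow(survey))
  if (!is.null(period)) keep <- keep & survey$period %in% period
  if (!is.null(crop)) keep <- keep & survey$crop %in% crop
  if (!is.null(plot)) keep <- keep & survey$plot %in% plot
  survey[keep, , drop = FALSE]
}

#' Regional frequency of occurrence
#'
#' The fraction of distinct surveyed fields in which each species occurs,
#' within a period/crop/plot selection. Fields surveyed in several years
#' count once; the denominator is the number of distinct fields in the
#' selection.
#'
#' @param survey A validated survey table (see [read_survey()]).
#' @param period,crop Optional filters; \code{NULL} keeps all.
#' @param plot Plot type(s) to keep; defaults to \code{"control"}, the
#'   unweeded plots expressing the field's potential flora.
#' @return Named numeric vector mapping species to frequency in [0, 1].
#' @export
regional_frequency <- function(survey, period = NULL, crop = NULL,
                               plot = "control") {
  sel <- .select_survey(survey, period, crop, plot)
  if (nrow(sel) == 0L)
    stop("empty selection: no survey records match the requested ",
         "period/crop/plot")
  n_fields <- length(unique(sel$field_id))
  fl <- .field_level(sel)
  tab <- table(fl$species)
  structure(as.numeric(tab) / n_fields, names = names(tab))
}

#' Per-species commonness summary
#'
#' Computes, for every species in a period/crop/plot selection, the
#' regional frequency \code{F}, the midpoint mean local abundance
#' \code{A} and the underlying cover-class counts. Aggregation is at
#' field level by default (the maximum class over repeated visits of a
#' field); \code{aggregate = "sample"} treats every visit as a sample.
#'
#' @inheritParams regional_frequency
#' @param aggregate \code{"field"} (default) or \code{"sample"}.
#' @return Data frame with columns \code{species}, \code{F}, \code{A},
#'   \code{n3}, \code{n4}, \code{n5}, \code{N}.
#' @export
species_summary <- function(survey, period = NULL, crop = NULL,
                            plot = "control",
                            aggregate = c("field", "sample")) {
  aggregate <- match.arg(aggregate)
  sel <- .select_survey(survey, period, crop, plot)
  if (nrow(sel) == 0L)
    stop("empty selection: no survey records match the requested ",
         "period/crop/plot")
  if (aggregate == "field") {
    n_units <- length(unique(sel$field_id))
    sel <- .field_level(sel)
  } else {
    n_units <- nrow(unique(sel[, c("field_id", "year")]))
  }
  sp <- sort(unique(sel$species))
  out <- do.call(rbind, lapply(sp, function(s) {
    cc <- class_counts(sel$score[sel$species == s])
    data.frame(species = s, F = cc$N / n_units,
               A = mean_local_abundance(cc$n3, cc$n4, cc$n5, cc$N),
               n3 = cc$n3, n4 = cc$n4, n5 = cc$n5, N = cc$N,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Fidelity of species to a focal crop
#'
#' The percentage of a species' estimated individuals found in the focal
#' crop relative to all individuals across all crops in the survey.
#' Individuals are estimated from cover-class midpoints (the same
#' midpoints as [mean_local_abundance()]), summed over field-level
#' occurrences. Fidelity measures specialization: 100 means the species
#' was only ever recorded in the focal crop.
#'
#' @param survey A survey table spanning several crops.
#' @param focal_crop Crop token, e.g. \code{"maize"}.
#' @param period,plot Optional filters as in [regional_frequency()].
#' @param species Optional species subset; species absent from the whole
#'   selection raise an error.
#' @return Named numeric vector of fidelity percentages in [0, 100].
#' @export
crop_fidelity <- function(survey, focal_crop, period = NULL,
                          plot = "control", species = NULL) {
  sel <- .select_survey(survey, period, NULL, plot)
  if (nrow(sel) == 0L) stop("empty selection")
  fl <- .field_level(sel)
  fl$mid <- class_midpoints()[.normalize_score(fl$score)]
  total <- tapply(fl$mid, fl$species, sum)
  infoc <- fl[fl$crop %in% focal_crop, , drop = FALSE]
  focal <- tapply(infoc$mid, infoc$species, sum)
  if (is.null(species)) species <- names(total)
  miss <- setdiff(species, names(total))
  if (length(miss))
    stop("fidelity undefined for species absent from the survey: ",
         paste(miss, collapse = ", "))
  f <- focal[species]
  f[is.na(f)] <- 0
  out <- 100 * as.numeric(f) / as.numeric(total[species])
  names(out) <- species
  out
}
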