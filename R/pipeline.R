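#' Analysis run configuration
#'
#' Bundles the tunable parameters of the end-to-end analysis.
#'
#' @param focal_crop Crop whose weed flora is analysed (default
#'   \code{"maize"}).
#' @param strata_sizes Named region -> field-count vector used by the
#'   effort-equalizing bootstrap (defaults to the historical design:
#'   East 26, South-West 64, North-Parisian basin 41, West 26,
#'   South-East 17).
#' @param B Bootstrap replicates (default 1000; runs with \code{B < 100}
#'   are flagged "low-replicate" in the manifest).
#' @param level Confidence level (default 0.95).
#' @param min_occurrences Species-inclusion rule for the trait models:
#'   minimum number of second-period control-plot occurrences
#'   (default 5).
#' @param detection_threshold_freq,detection_threshold_abund Recording
#'   floors for [classify_status()].
#' @param lambda Pagel's lambda for the PGLS fits: numeric or
#'   \code{"ML"} (default).
#' @param n_axes Ordination axes used as predictors (default 6).
#' @param log_traits Quantitative traits log-transformed before the
#'   per-trait models (skewed size/output traits by default).
#' @param seed Mandatory integer seed.
#' @return List of class \code{"weed_config"}.
#' @export
weed_config <- function(focal_crop = "maize",
                        strata_sizes = c("East" = 26, "South-West" = 64,
                                         "North-Parisian-basin" = 41,
                                         "West" = 26, "South-East" = 17),
                        B = 1000, level = 0.95, min_occurrences = 5,
                        detection_threshold_freq = 2.3,
                        detection_threshold_abund = 0.5,
                        lambda = "ML", n_axes = 6,
                        log_traits = c("height", "seed_weight",
                                       "fecundity", "seed_longevity"),
                        seed) {
  if (missing(seed)) stop("a seed is mandatory for a reproducible run")
  structure(list(focal_crop = focal_crop, strata_sizes = strata_sizes,
                 B = B, level = level, min_occurrences = min_occurrences,
                 detection_threshold_freq = detection_threshold_freq,
                 detection_threshold_abund = detection_threshold_abund,
                 lambda = lambda, n_axes = n_axes, log_traits = log_traits,
                 seed = as.integer(seed)),
            class = "weed_config")
}

#' Interspecific frequency-abundance regression
#'
#' PGLS of log regional frequency on log mean local abundance across
#' species, the macroecological abundance-occupancy relationship. Its
#' residuals measure whether a species is more (positive) or less
#' (negative) frequent than its local abundance predicts, and feed
#' [residual_group_tests()].
#'
#' @param summary A [species_summary()] data frame (columns
#'   \code{species}, \code{F}, \code{A}).
#' @param tree Phylogeny covering the species.
#' @param lambda Pagel's lambda (default \code{"ML"}).
#' @return A \code{"pgls"} fit of \code{log(F) ~ log(A)}.
#' @export
frequency_abundance_regression <- function(summary, tree, lambda = "ML") {
  stopifnot(all(c("species", "F", "A") %in% names(summary)))
  d <- data.frame(species = summary$species,
                  log_frequency = log(summary$F),
                  log_abundance = log(summary$A),
                  stringsAsFactors = FALSE)
  pgls(log_frequency ~ log_abundance, d, tree, lambda = lambda)
}

#' Between-period change regression
#'
#' PGLS of the normalized frequency change on the normalized abundance
#' change over the species with both periods observed (status calls
#' other than \code{"N"} and \code{"?"}).
#'
#' @param changes Data frame with columns \code{species},
#'   \code{ch_freq}, \code{ch_abund} (from [change_index()]).
#' @param tree Phylogeny covering the species.
#' @param lambda Pagel's lambda (default \code{"ML"}).
#' @return A \code{"pgls"} fit of \code{ch_freq ~ ch_abund}.
#' @export
change_regression <- function(changes, tree, lambda = "ML") {
  stopifnot(all(c("species", "ch_freq", "ch_abund") %in% names(changes)))
  ok <- stats::complete.cases(changes[, c("ch_freq", "ch_abund")])
  changes <- changes[ok, , drop = FALSE]
  if (nrow(changes) < 3)
    stop("insufficient data: fewer than 3 species with defined change ",
         "on both metrics")
  pgls(ch_freq ~ ch_abund, changes, tree, lambda = lambda)
}

#' Per-trait PGLS coefficient table
#'
#' Fits one PGLS per trait (\code{response ~ trait}) and stacks the
#' non-intercept coefficient rows, mirroring the usual per-trait
#' performance table. Qualitative traits expand to level contrasts
#' against their alphabetically-first (baseline) level.
#'
#' @param response Named numeric vector of the response (names are
#'   species).
#' @param traits Validated trait table.
#' @param tree Phylogeny.
#' @param lambda Pagel's lambda (default \code{"ML"}).
#' @param log_traits Quantitative traits to log before fitting.
#' @return Data frame with columns \code{trait}, \code{term},
#'   \code{estimate}, \code{se}, \code{t}, \code{p}, \code{lambda}.
#' @export
trait_pgls_table <- function(response, traits, tree, lambda = "ML",
                             log_traits = character(0)) {
  if (is.null(names(response))) stop("response must be named by species")
  sch <- trait_schema()
  m <- match(names(response), traits$species)
  if (anyNA(m))
    stop("species missing from the trait table: ",
         paste(names(response)[is.na(m)], collapse = ", "))
  tt <- traits[m, , drop = FALSE]
  vars <- c(sch$quantitative, names(sch$qualitative))
  vars <- vars[vars %in% names(tt)]
  rows <- lapply(vars, function(v) {
    x <- tt[[v]]
    if (is.numeric(x) && v %in% log_traits) x <- log(x)
    d <- data.frame(species = tt$species, y = unname(response), x = x,
                    stringsAsFactors = FALSE)
    fit <- pgls(y ~ x, d, tree, lambda = lambda)
    keep <- setdiff(names(coef(fit)), "(Intercept)")
    data.frame(trait = v, term = sub("^x", "", keep),
               estimate = unname(coef(fit)[keep]),
               se = unname(fit$se[keep]), t = unname(fit$tval[keep]),
               p = unname(fit$pval[keep]), lambda = fit$lambda,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full diachronic weed-survey analysis
#'
#' Orchestrates the pipeline: pre-flight species consistency check,
#' second-period commonness summary, stratified-bootstrap status calls
#' against the first period, normalized change indices, the
#' frequency-abundance PGLS with residual group contrasts, per-trait
#' PGLS models, the Hill-Smith ordination and the joint axis-PGLS
#' models, and (when a first period is available) the change
#' regression. Stages run in that order; any failure aborts with the
#' stage name; identical inputs + config give identical reports.
#'
#' @param survey Validated survey table (may contain both periods).
#' @param traits Validated trait table.
#' @param tree Validated phylogeny.
#' @param annotations Optional validated annotation table.
#' @param reference Optional first-period reference values (see
#'   [status_table()]); defaults to computing them from the survey's
#'   \code{"P1970s"} rows when present.
#' @param config A [weed_config()].
#' @return Object of class \code{"weed_report"}: a list of result tables
#'   (\code{summary}, \code{status}, \code{changes}, per-trait and
#'   per-axis coefficient tables, ordination contributions, group-test
#'   summaries), the fitted model objects, and a run \code{manifest}.
#' @export
run_weed_analysis <- function(survey, traits, tree, annotations = NULL,
                              reference = NULL, config) {
  stopifnot(inherits(config, "weed_config"))
  stage <- "pre-flight"
  report <- list()
  tryCatch({
    survey <- validate_survey(survey)
    p2 <- survey[survey$period == "P2000s", , drop = FALSE]
    if (!nrow(p2)) stop("no second-period (P2000s) records")
    set.seed(config$seed)

    stage <- "summarize"
    ss <- species_summary(p2, crop = config$focal_crop, plot = "control")
    keep <- ss$N >= config$min_occurrences
    ss_model <- ss[keep, , drop = FALSE]
    check_species_consistency(traits = traits, tree = tree,
                              annotations = annotations,
                              species = ss_model$species)
    report$summary <- ss

    stage <- "status"
    if (is.null(reference) && any(survey$period == "P1970s")) {
      p1 <- survey[survey$period == "P1970s", , drop = FALSE]
      s1 <- species_summary(p1, crop = config$focal_crop, plot = "control")
      reference <- data.frame(species = s1$species,
                              freq_p1 = 100 * s1$F, abund_p1 = s1$A,
                              stringsAsFactors = FALSE)
      # emulate the first survey's recording floor
      low <- reference$freq_p1 < config$detection_threshold_freq
      reference$freq_p1[low] <- NA
      reference$abund_p1[low] <- NA
    }
    st <- status_table(p2, reference, config$strata_sizes,
                       B = config$B, level = config$level,
                       detection_threshold_freq =
                         config$detection_threshold_freq,
                       detection_threshold_abund =
                         config$detection_threshold_abund)
    report$status <- st

    stage <- "change indices"
    defined <- !is.na(st$freq_p1) & !is.na(st$abund_p1) &
      !st$freq_status %in% c("N", "?") & !st$abund_status %in% c("N", "?")
    changes <- data.frame(
      species = st$species[defined],
      ch_freq = change_index(st$freq_p1[defined], st$freq_p2[defined]),
      ch_abund = change_index(st$abund_p1[defined], st$abund_p2[defined]),
      stringsAsFactors = FALSE)
    report$changes <- changes

    stage <- "frequency-abundance PGLS"
    fa <- frequency_abundance_regression(ss_model, tree,
                                         lambda = config$lambda)
    report$freq_abund_fit <- fa

    stage <- "residual group tests"
    if (!is.null(annotations))
      report$group_tests <- residual_group_tests(residuals(fa),
                                                 annotations)

    stage <- "per-trait PGLS"
    resp <- list(
      log_frequency = stats::setNames(log(ss_model$F), ss_model$species),
      log_abundance = stats::setNames(log(ss_model$A), ss_model$species))
    fid <- tryCatch(
      crop_fidelity(survey, config$focal_crop, period = "P2000s",
                    species = ss_model$species),
      error = function(e) NULL)
    if (!is.null(fid) && length(unique(survey$crop)) > 1)
      resp$fidelity <- fid
    report$trait_models <- lapply(resp, function(y)
      trait_pgls_table(y, traits, tree, lambda = config$lambda,
                       log_traits = config$log_traits))

    stage <- "ordination"
    mtr <- traits[match(ss_model$species, traits$species), , drop = FALSE]
    ord <- hill_smith(mtr, n_axes = config$n_axes)
    report$ordination <- ord
    report$contributions <- data.frame(
      column = rownames(ord$contributions), trait = ord$col_trait,
      ord$contributions, stringsAsFactors = FALSE, row.names = NULL)

    stage <- "axis PGLS"
    ax <- axis_scores(ord)
    report$axis_models <- lapply(resp, function(y) {
      d <- cbind(data.frame(y = unname(y)),
                 ax[match(names(y), ax$species), , drop = FALSE])
      f <- stats::as.formula(paste("y ~",
                                   paste(names(ax)[-1], collapse = " + ")))
      fit <- pgls(f, d, tree, lambda = config$lambda)
      keep <- setdiff(names(coef(fit)), "(Intercept)")
      data.frame(axis = keep, estimate = unname(coef(fit)[keep]),
                 se = unname(fit$se[keep]), t = unname(fit$tval[keep]),
                 p = unname(fit$pval[keep]), lambda = fit$lambda,
                 stringsAsFactors = FALSE)
    })

    stage <- "change regression"
    if (nrow(changes) >= 3)
      report$change_fit <- change_regression(changes, tree,
                                             lambda = config$lambda)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  report$manifest <- list(
    seed = config$seed,
    config = unclass(config),
    config_hash = .config_hash(config),
    low_replicate = config$B < 100,
    n_species_model = nrow(report$summary[report$summary$N >=
                                            config$min_occurrences, ]),
    package_version = as.character(utils::packageVersion("weedshift")),
    r_version = paste(R.version$major, R.version$minor, sep = "."))
  structure(report, class = "weed_report")
}

# stable hash of the configuration (md5 of its deparsed form)
.config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(unclass(config)), f)
  unname(tools::md5sum(f))
}

#' @export
print.weed_report <- function(x, ...) {
  cat("Diachronic weed-survey analysis report\n")
  cat(sprintf("  species summarized: %d (modelled: %d)\n",
              nrow(x$summary), x$manifest$n_species_model))
  if (!is.null(x$status))
    cat("  status calls (frequency): ",
        paste(sprintf("%s:%d", names(table(x$status$freq_status)),
                      table(x$status$freq_status)), collapse = " "), "\n")
  if (!is.null(x$freq_abund_fit)) {
    s <- x$freq_abund_fit
    cat(sprintf(paste0("  frequency~abundance PGLS: slope = %.3f, ",
                       "lambda = %.3f, Adj-R2 = %.3f\n"),
                coef(s)[2], s$lambda, s$adj_r2))
  }
  invisible(x)
}

#' Write a report to CSV files with a run manifest
#'
#' One CSV per result table plus \code{manifest.json} recording the
#' seed, configuration, configuration hash and versions. Re-running the
#' pipeline with an identical seed and configuration reproduces the CSVs
#' byte for byte.
#'
#' @param report A \code{"weed_report"} (or any named list of data
#'   frames).
#' @param out_dir Output directory (created if needed).
#' @return Character vector of written file paths (the manifest last),
#'   invisibly.
#' @export
write_report <- function(report, out_dir) {
  if (!dir.exists(out_dir))
    if (!dir.create(out_dir, recursive = TRUE))
      stop("cannot create output directory: ", out_dir)
  if (file.access(out_dir, mode = 2) != 0)
    stop("output directory is not writable: ", out_dir)
  paths <- character(0)
  flatten <- function(x, prefix = "") {
    for (nm in names(x)) {
      obj <- x[[nm]]
      fname <- if (nzchar(prefix)) paste(prefix, nm, sep = "_") else nm
      if (is.data.frame(obj)) {
        p <- file.path(out_dir, paste0(fname, ".csv"))
        utils::write.csv(obj, p, row.names = FALSE, fileEncoding = "UTF-8")
        paths <<- c(paths, p)
      } else if (is.list(obj) && !inherits(obj, c("pgls", "hill_smith",
                                                  "group_tests")) &&
                 nm != "manifest") {
        flatten(obj, fname)
      }
    }
  }
  flatten(report)
  manifest <- if (!is.null(report$manifest)) report$manifest else list()
  manifest$files <- basename(paths)
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(c(paths, mp))
}
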