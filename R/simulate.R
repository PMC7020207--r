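#' Configuration for the synthetic survey generator
#'
#' Defines the study design the generator emulates: two survey periods
#' over five regional strata, with the historical-period stratum sizes of
#' the French maize monitoring design (East 26, South-West 64,
#' North-Parisian basin 41, West 26, South-East 17; 175 fields in all)
#' and a later period of 484 fields allocated proportionally. Species
#' occupancies are drawn from a lognormal distribution truncated to
#' (0, 1), producing the few-common/many-rare shape typical of weed
#' surveys, and each species' mean local density follows the
#' abundance-occupancy coupling
#' \code{log(mu) = coupling_intercept + coupling_slope * log(p)} plus
#' lognormal noise.
#'
#' @param regions Character vector of region names.
#' @param n_fields_p1,n_fields_p2 Integer stratum sizes per region for
#'   the two periods (same order as \code{regions}).
#' @param n_species Number of species in the pool.
#' @param occupancy Optional explicit vector of occupancy probabilities
#'   (length \code{n_species}); when \code{NULL} they are drawn from the
#'   truncated lognormal below.
#' @param occupancy_meanlog,occupancy_sdlog Parameters of the lognormal
#'   occupancy distribution (defaults \code{log(0.08)} and 1.1).
#' @param coupling_slope Slope \code{b} linking log-occupancy to log mean
#'   density; \code{b > 0} yields the positive interspecific
#'   frequency-abundance relationship observed in real surveys. Default
#'   1.1.
#' @param coupling_intercept Intercept \code{a} on the log-density scale;
#'   default 3.2 (so a species present in ~60\% of fields averages
#'   ~14 plants/m2).
#' @param coupling_sdlog Lognormal noise around the coupling line
#'   (default 0.5).
#' @param density_sdlog Within-species lognormal spread of field
#'   densities around the species mean (default 1).
#' @param period_effect Multiplicative shift of each species' occupancy in
#'   the second period (scalar or per-species vector; default 1, no
#'   temporal change).
#' @param crop Crop token written into the table (default "maize").
#' @param years_p1,years_p2 Candidate survey years for each period.
#' @param seed Integer seed driving all draws.
#' @return A list of class \code{"survey_sim_config"}.
#' @export
survey_sim_config <- function(regions = c("East", "South-West",
                                          "North-Parisian-basin", "West",
                                          "South-East"),
                              n_fields_p1 = c(26, 64, 41, 26, 17),
                              n_fields_p2 = c(72, 178, 114, 72, 48),
                              n_species = 95,
                              occupancy = NULL,
                              occupancy_meanlog = log(0.08),
                              occupancy_sdlog = 1.1,
                              coupling_slope = 1.1,
                              coupling_intercept = 3.2,
                              coupling_sdlog = 0.5,
                              density_sdlog = 1,
                              period_effect = 1,
                              crop = "maize",
                              years_p1 = 1973:1976,
                              years_p2 = 2002:2008,
                              seed = 1L) {
  stopifnot(length(n_fields_p1) == length(regions),
            length(n_fields_p2) == length(regions),
            all(n_fields_p1 >= 1), all(n_fields_p2 >= 1),
            n_species >= 1, is.finite(coupling_slope))
  if (!is.null(occupancy))
    stopifnot(length(occupancy) == n_species,
              all(occupancy > 0), all(occupancy < 1))
  structure(list(regions = regions,
                 n_fields_p1 = as.integer(n_fields_p1),
                 n_fields_p2 = as.integer(n_fields_p2),
                 n_species = as.integer(n_species), occupancy = occupancy,
                 occupancy_meanlog = occupancy_meanlog,
                 occupancy_sdlog = occupancy_sdlog,
                 coupling_slope = coupling_slope,
                 coupling_intercept = coupling_intercept,
                 coupling_sdlog = coupling_sdlog,
                 density_sdlog = density_sdlog,
                 period_effect = period_effect, crop = crop,
                 years_p1 = years_p1, years_p2 = years_p2,
                 seed = as.integer(seed)),
            class = "survey_sim_config")
}

# truncated lognormal on (0, 1): redraw values >= 1
.r_occupancy <- function(n, meanlog, sdlog) {
  p <- stats::rlnorm(n, meanlog, sdlog)
  while (any(p >= 1))
    p[p >= 1] <- stats::rlnorm(sum(p >= 1), meanlog, sdlog)
  pmax(p, 1e-6)
}

#' Generate a synthetic two-period survey
#'
#' Draws a long-format survey table under \code{config}: per-region field
#' counts match the configuration exactly; each species is present in a
#' field with its occupancy probability (times the period effect in the
#' second period); present species receive a density drawn from a
#' lognormal whose mean follows the abundance-occupancy coupling, then
#' discretized to the six-class scale by [density_to_class()].
#'
#' Each plot is conditioned on expressing at least one species, so the
#' per-region field counts of the long table match the design exactly.
#'
#' @param config A [survey_sim_config()].
#' @return A validated survey data frame (control plots only). The true
#'   occupancy probabilities and species mean densities are attached as
#'   attributes \code{"occupancy"} and \code{"mean_density"}.
#' @export
sim_survey <- function(config = survey_sim_config()) {
  stopifnot(inherits(config, "survey_sim_config"))
  set.seed(config$seed)
  n_sp <- config$n_species
  species <- sprintf("sp%03d", seq_len(n_sp))
  p <- config$occupancy
  if (is.null(p))
    p <- .r_occupancy(n_sp, config$occupancy_meanlog, config$occupancy_sdlog)
  mu <- exp(config$coupling_intercept +
              config$coupling_slope * log(p) +
              stats::rnorm(n_sp, 0, config$coupling_sdlog))
  shift <- rep_len(config$period_effect, n_sp)
  rows <- list()
  fid <- 0L
  for (per in c("P1970s", "P2000s")) {
    sizes <- if (per == "P1970s") config$n_fields_p1 else config$n_fields_p2
    years <- if (per == "P1970s") config$years_p1 else config$years_p2
    occ <- if (per == "P1970s") p else pmin(p * shift, 0.99)
    for (r in seq_along(config$regions)) {
      n_f <- sizes[r]
      P <- matrix(stats::runif(n_f * n_sp), n_f, n_sp) <
        matrix(occ, n_f, n_sp, byrow = TRUE)
      # an unweeded control plot always expresses at least one weed;
      # conditioning keeps the per-region field counts exact
      empty <- which(rowSums(P) == 0L)
      while (length(empty)) {
        P[empty, ] <- matrix(stats::runif(length(empty) * n_sp),
                             length(empty), n_sp) <
          matrix(occ, length(empty), n_sp, byrow = TRUE)
        empty <- empty[rowSums(P[empty, , drop = FALSE]) == 0L]
      }
      idx <- which(P, arr.ind = TRUE)
      idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
      dens <- stats::rlnorm(nrow(idx),
                            log(mu[idx[, 2]]) - config$density_sdlog^2 / 2,
                            config$density_sdlog)
      yr <- sample(years, n_f, replace = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        field_id = sprintf("f%04d", fid + idx[, 1]),
        year = yr[idx[, 1]],
        period = per, region = config$regions[r], crop = config$crop,
        plot = "control", species = species[idx[, 2]],
        score = density_to_class(dens), stringsAsFactors = FALSE)
      fid <- fid + n_f
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "occupancy") <- stats::setNames(p, species)
  attr(out, "mean_density") <- stats::setNames(mu, species)
  validate_survey(out)
}

#' Generate a random ultrametric phylogeny
#'
#' Pure-birth (Yule) tree with depth normalized to 1 and tips labelled
#' \code{sp001, sp002, ...} to match [sim_survey()] and
#' [sim_trait_table()].
#'
#' @param n_tips Number of tips (>= 2).
#' @param seed Integer seed.
#' @return An ultrametric [ape::phylo] of depth 1.
#' @export
sim_tree <- function(n_tips, seed = 1L) {
  if (!is.numeric(n_tips) || n_tips < 2)
    stop("n_tips must be at least 2")
  set.seed(as.integer(seed))
  tree <- ape::rphylo(as.integer(n_tips), birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  tree$tip.label <- sprintf("sp%03d", seq_len(as.integer(n_tips)))
  tree
}

#' Simulate a response with phylogenetic signal
#'
#' Draws i.i.d. standard-normal predictors and a response
#' \code{y = X beta + eps} whose errors follow a multivariate normal with
#' covariance \code{sigma2 * V(lambda)}, where \code{V(lambda)} is the
#' tree's shared branch-length covariance with off-diagonals scaled by
#' Pagel's lambda. \code{lambda = 1} is Brownian evolution on the tree;
#' \code{lambda = 0} removes all cross-species covariance.
#'
#' @param tree Ultrametric [ape::phylo] (>= 3 tips).
#' @param lambda True phylogenetic signal in [0, 1]; default 0.7, a
#'   moderate signal typical of ecological performance measures.
#' @param sigma2 Residual variance scale (> 0).
#' @param beta Coefficient vector (intercept first); its length minus one
#'   sets the number of predictors.
#' @param seed Integer seed.
#' @return Data frame with columns \code{species}, \code{y} and
#'   predictors \code{x1 ...}; the error covariance used is attached as
#'   attribute \code{"V"}.
#' @export
sim_brownian_traits <- function(tree, lambda = 0.7, sigma2 = 1,
                                beta = c(0, 1), seed = 1L) {
  validate_tree(tree)
  n <- length(tree$tip.label)
  if (n < 3) stop("at least 3 tips are required")
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]")
  if (sigma2 <= 0) stop("sigma2 must be positive")
  set.seed(as.integer(seed))
  V <- pagel_transform(phylo_vcv(tree), lambda = lambda)
  U <- tryCatch(chol(sigma2 * V), error = function(e)
    stop("singular phylogenetic covariance (lambda = ", lambda,
         "): ", conditionMessage(e)))
  k <- length(beta) - 1L
  X <- if (k > 0) matrix(stats::rnorm(n * k), n, k) else
    matrix(0, n, 0)
  eps <- drop(crossprod(U, stats::rnorm(n)))
  y <- drop(cbind(1, X) %*% beta) + eps
  out <- data.frame(species = tree$tip.label, y = y)
  if (k > 0) {
    Xd <- as.data.frame(X)
    names(Xd) <- paste0("x", seq_len(k))
    out <- cbind(out, Xd)
  }
  attr(out, "V") <- sigma2 * V
  out
}

#' Generate a plausible species-trait table
#'
#' Fills the full trait schema (see [trait_schema()]) with values drawn
#' uniformly inside the published min-max ranges for each quantitative
#' trait (e.g. SLA in [10.9, 53.7] cm2/g) and qualitative levels sampled
#' with realistic modality frequencies. Purely a stand-in for real trait
#' measurements: values are mutually independent, which real trait
#' tables are not.
#'
#' @param n_species Number of species (>= 2).
#' @param seed Integer seed.
#' @return A validated trait data frame with species \code{sp001, ...}.
#' @export
sim_trait_table <- function(n_species, seed = 1L) {
  if (n_species < 2) stop("n_species must be at least 2")
  set.seed(as.integer(seed))
  n <- as.integer(n_species)
  ranges <- list(sla = c(10.9, 53.7), height = c(20, 500),
                 seed_weight = c(0.05, 39.9), flowering_onset = c(1, 8),
                 flowering_duration = c(1, 12), fecundity = c(30, 40000),
                 seed_longevity = c(3, 100), ellenberg_l = c(5, 9),
                 ellenberg_n = c(1, 9), ellenberg_t = c(5, 9),
                 herbicide_sensitivity = c(1.5, 6))
  out <- data.frame(species = sprintf("sp%03d", seq_len(n)),
                    stringsAsFactors = FALSE)
  for (tr in names(ranges)) {
    lo <- ranges[[tr]][1]; hi <- ranges[[tr]][2]
    # skewed traits on a log scale, indicator-style traits uniform
    if (tr %in% c("height", "seed_weight", "fecundity", "seed_longevity"))
      out[[tr]] <- round(exp(stats::runif(n, log(lo), log(hi))), 3)
    else out[[tr]] <- round(stats::runif(n, lo, hi), 2)
  }
  out$life_form <- sample(c("geophyte", "hemicryptophyte", "therophyte"), n,
                          replace = TRUE, prob = c(10, 12, 73))
  out$emergence <- sample(c("all_year", "autumn_winter_spring", "spring",
                            "spring_summer", "summer"), n,
                          replace = TRUE, prob = c(29, 15, 9, 24, 18))
  out$dispersal <- sample(c("animal", "gravity", "wind"), n,
                          replace = TRUE, prob = c(25, 33, 37))
  out$photosynthesis <- sample(c("C3", "C4"), n, replace = TRUE,
                               prob = c(0.75, 0.25))
  # guarantee every modality is observed at least once on decent-size pools
  if (n >= 15) {
    sch <- trait_schema()$qualitative
    i <- 0L
    for (tr in names(sch)) for (lev in sch[[tr]]) {
      i <- i + 1L
      if (!lev %in% out[[tr]]) out[[tr]][i] <- lev
    }
  }
  validate_traits(out)
}

#' Generate a synthetic annotation table
#'
#' Random taxonomic group, origin class and resistance flags for a
#' species pool, for exercising the residual group tests.
#'
#' @inheritParams sim_trait_table
#' @return A validated annotation data frame.
#' @export
sim_annotation_table <- function(n_species, seed = 1L) {
  if (n_species < 2) stop("n_species must be at least 2")
  set.seed(as.integer(seed))
  n <- as.integer(n_species)
  out <- data.frame(
    species = sprintf("sp%03d", seq_len(n)),
    group_taxo = sample(c("Dicot", "Pooideae", "Panicoideae"), n,
                        replace = TRUE, prob = c(0.7, 0.15, 0.15)),
    origin = sample(c("native", "archaeophyte", "neophyte"), n,
                    replace = TRUE, prob = c(0.4, 0.4, 0.2)),
    resistant_pops = sample(c(TRUE, FALSE), n, replace = TRUE,
                            prob = c(0.15, 0.85)),
    stringsAsFactors = FALSE)
  validate_annotations(out)
}
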