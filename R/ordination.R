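#' Build the mixed quantitative/qualitative design matrix
#'
#' Prepares a species-by-trait table for the Hill-Smith ordination.
#' Quantitative columns are centred and scaled to unit variance under the
#' row weights (population convention, divisor n for uniform weights).
#' Each qualitative trait expands to one column per observed level: the
#' 0/1 indicator is centred by the level frequency and divided by its
#' square root, \eqn{z_k = (x_k - p_k) / \sqrt{p_k}}, the classic
#' Hill-Smith weighting under which a qualitative trait with m observed
#' levels carries total inertia m - 1 and an all-quantitative table
#' reduces exactly to correlation-matrix PCA.
#'
#' @param traits Data frame with a species identifier column plus numeric
#'   and character/factor trait columns.
#' @param row_weights Optional nonnegative weights (one per species,
#'   normalized to sum to 1); default uniform.
#' @param species Name of the species identifier column (default
#'   \code{"species"}; row names are used if absent).
#' @return List of class \code{"mixed_design"}: \code{Z} (the weighted
#'   design), \code{weights}, \code{col_trait} (column-to-trait map),
#'   \code{col_type}, \code{species}.
#' @export
build_mixed_design <- function(traits, row_weights = NULL,
                               species = "species") {
  stopifnot(is.data.frame(traits), nrow(traits) >= 2)
  sp <- if (species %in% names(traits)) as.character(traits[[species]])
  else rownames(traits)
  if (anyDuplicated(sp)) stop("duplicated species in trait table")
  vars <- setdiff(names(traits), species)
  n <- nrow(traits)
  w <- if (is.null(row_weights)) rep(1 / n, n) else {
    stopifnot(length(row_weights) == n, all(row_weights >= 0),
              sum(row_weights) > 0)
    row_weights / sum(row_weights)
  }
  cols <- list(); col_trait <- character(0); col_type <- character(0)
  for (v in vars) {
    x <- traits[[v]]
    if (is.numeric(x)) {
      m <- sum(w * x)
      s <- sqrt(sum(w * (x - m)^2))
      if (s < 1e-12)
        stop("quantitative trait '", v, "' is constant (degenerate column)")
      cols[[v]] <- (x - m) / s
      col_trait <- c(col_trait, v); col_type <- c(col_type, "quant")
    } else {
      x <- as.character(x)
      levs <- sort(unique(x))
      if (is.factor(traits[[v]])) {
        dropped <- setdiff(levels(traits[[v]]), levs)
        if (length(dropped))
          warning("trait '", v, "': unobserved level(s) dropped: ",
                  paste(dropped, collapse = ", "))
      }
      if (length(levs) < 2)
        stop("qualitative trait '", v, "' has a single observed level")
      for (lev in levs) {
        ind <- as.numeric(x == lev)
        p <- sum(w * ind)
        cols[[paste(v, lev, sep = ".")]] <- (ind - p) / sqrt(p)
        col_trait <- c(col_trait, v); col_type <- c(col_type, "qual")
      }
    }
  }
  Z <- do.call(cbind, cols)
  rownames(Z) <- sp
  structure(list(Z = Z, weights = w, col_trait = col_trait,
                 col_type = col_type, species = sp),
            class = "mixed_design")
}

#' Hill-Smith ordination of a mixed trait table
#'
#' A PCA-like weighted eigendecomposition that accommodates quantitative
#' and qualitative variables simultaneously, via the design of
#' [build_mixed_design()]. Eigenvalues decompose the total inertia
#' (number of quantitative traits + sum over qualitative traits of
#' observed levels minus one); row (species) scores on distinct axes are
#' orthogonal under the row weights, and column loadings are on the
#' correlation scale. Axis signs are arbitrary in any ordination; here
#' each axis is oriented so that its largest-magnitude loading is
#' positive.
#'
#' @param traits A trait data frame, or a prebuilt \code{"mixed_design"}.
#' @param n_axes Number of axes to retain (default 6; truncated to the
#'   design's rank with a warning if larger).
#' @param ... Passed on to [build_mixed_design()].
#' @return Object of class \code{"hill_smith"}: \code{eig} (all positive
#'   eigenvalues), \code{pct_inertia}, \code{total_inertia},
#'   \code{row_scores} (species x axes), \code{col_scores} (column
#'   loadings x axes), \code{contributions} (signed per-column
#'   percentages whose absolute values sum to 100 per axis),
#'   \code{trait_contributions} (absolute percentages aggregated per
#'   source trait), \code{col_trait}, \code{weights}.
#' @export
#' @examples
#' tr <- sim_trait_table(40, seed = 1)
#' ord <- hill_smith(tr, n_axes = 4)
#' ord$pct_inertia[1:4]
hill_smith <- function(traits, n_axes = 6, ...) {
  design <- if (inherits(traits, "mixed_design")) traits
  else build_mixed_design(traits, ...)
  Z <- design$Z
  w <- design$weights
  C <- crossprod(Z, Z * w)
  ev <- eigen(C, symmetric = TRUE)
  pos <- ev$values > max(ev$values) * 1e-10
  eig <- ev$values[pos]
  U <- ev$vectors[, pos, drop = FALSE]
  rank <- length(eig)
  if (n_axes > rank) {
    warning("n_axes = ", n_axes, " exceeds the design rank ", rank,
            "; truncated")
    n_axes <- rank
  }
  U <- U[, seq_len(n_axes), drop = FALSE]
  # orient: largest-|loading| column positive on each axis
  for (k in seq_len(n_axes)) {
    j <- which.max(abs(U[, k]))
    if (U[j, k] < 0) U[, k] <- -U[, k]
  }
  axes <- paste0("Axis", seq_len(n_axes))
  col_scores <- sweep(U, 2, sqrt(eig[seq_len(n_axes)]), `*`)
  dimnames(col_scores) <- list(colnames(Z), axes)
  row_scores <- Z %*% U
  dimnames(row_scores) <- list(design$species, axes)
  contrib <- 100 * sign(U) * U^2
  dimnames(contrib) <- list(colnames(Z), axes)
  tc <- rowsum(abs(contrib), group = design$col_trait)
  structure(list(eig = eig, pct_inertia = 100 * eig / sum(eig),
                 total_inertia = sum(eig),
                 row_scores = row_scores, col_scores = col_scores,
                 contributions = contrib, trait_contributions = tc,
                 col_trait = design$col_trait, weights = w,
                 n_axes = n_axes),
            class = "hill_smith")
}

#' @export
print.hill_smith <- function(x, ...) {
  cat("Hill-Smith ordination\n")
  cat(sprintf("Total inertia: %.4g over %d positive eigenvalues\n",
              x$total_inertia, length(x$eig)))
  k <- x$n_axes
  cat(sprintf("First %d axes explain %.1f%% of the inertia\n", k,
              sum(x$pct_inertia[seq_len(k)])))
  print(round(rbind(eigenvalue = x$eig[seq_len(k)],
                    `pct inertia` = x$pct_inertia[seq_len(k)]), 3))
  invisible(x)
}

#' @export
summary.hill_smith <- function(object, ...) {
  print(object)
  cat("\nSigned column contributions (%):\n")
  print(round(object$contributions, 2))
  invisible(object)
}

#' @export
plot.hill_smith <- function(x, axes = c(1, 2), ...) {
  stopifnot(length(axes) == 2, all(axes <= x$n_axes))
  rs <- x$row_scores[, axes]
  cs <- x$col_scores[, axes]
  graphics::plot(rs, pch = 16, cex = 0.6,
                 xlab = colnames(rs)[1], ylab = colnames(rs)[2],
                 main = "Hill-Smith ordination", ...)
  graphics::abline(h = 0, v = 0, lty = 3)
  sc <- max(abs(rs)) / max(abs(cs))
  graphics::arrows(0, 0, cs[, 1] * sc * 0.8, cs[, 2] * sc * 0.8,
                   length = 0.05, col = "grey40")
  graphics::text(cs * sc * 0.85, labels = rownames(cs), cex = 0.6,
                 col = "grey20")
  invisible(x)
}

#' Ordination axes as species-level predictors
#'
#' Extracts species scores on selected axes as a data frame keyed by
#' species, ready to join with commonness metrics and feed to [pgls()].
#'
#' @param object A \code{"hill_smith"} result.
#' @param axes Integer vector of axis numbers (default all retained).
#' @return Data frame with a \code{species} column and one column per
#'   requested axis.
#' @export
axis_scores <- function(object, axes = seq_len(object$n_axes)) {
  stopifnot(inherits(object, "hill_smith"))
  if (any(axes < 1) || any(axes > object$n_axes))
    stop("unknown axis requested; available: 1..", object$n_axes)
  out <- data.frame(species = rownames(object$row_scores),
                    object$row_scores[, axes, drop = FALSE],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
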