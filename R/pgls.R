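#' Phylogenetic covariance matrix from a tree
#'
#' The matrix of shared root-to-tip path lengths: entry (i, j) is the
#' depth of the most recent common ancestor of tips i and j, and the
#' diagonal holds the tip depths. Under Brownian trait evolution this is
#' the expected trait covariance up to a rate constant.
#'
#' @param tree A validated [ape::phylo] with branch lengths.
#' @param species Optional species vector; the matrix is pruned and
#'   ordered to it. Missing tips are an error listing the absences.
#' @return Symmetric numeric matrix with tip labels as dimnames.
#' @export
phylo_vcv <- function(tree, species = NULL) {
  validate_tree(tree)
  if (!is.null(species)) {
    miss <- setdiff(species, tree$tip.label)
    if (length(miss))
      stop("species missing from the tree: ", paste(miss, collapse = ", "))
    if (length(species) < length(tree$tip.label))
      tree <- ape::keep.tip(tree, species)
  }
  V <- ape::vcv.phylo(tree)
  if (!is.null(species)) V <- V[species, species, drop = FALSE]
  V
}

#' Pagel branch-length transformations of a phylogenetic covariance
#'
#' \code{lambda} multiplies all off-diagonal entries of \code{V} (tip
#' variances unchanged): 0 gives a star phylogeny, 1 leaves the tree
#' untouched. \code{delta} raises node depths to a power, modelling
#' late (\code{delta > 1}) or early (\code{delta < 1}) trait change; it
#' is applied elementwise to \code{V} after normalizing the tree depth to
#' 1, so it is dimensionless. On non-ultrametric trees the elementwise
#' delta transform is only an approximation and a warning is issued.
#'
#' @param V Phylogenetic covariance matrix from [phylo_vcv()].
#' @param lambda Off-diagonal multiplier in [0, 1].
#' @param delta Positive depth power (default 1, no transform).
#' @return The transformed covariance matrix.
#' @export
pagel_transform <- function(V, lambda = 1, delta = 1) {
  if (!is.matrix(V) || nrow(V) != ncol(V))
    stop("V must be a square matrix")
  if (!is.finite(lambda) || lambda < 0 || lambda > 1)
    stop("lambda must be in [0, 1]")
  if (!is.finite(delta) || delta <= 0)
    stop("delta must be positive")
  if (delta != 1) {
    d <- diag(V)
    if (max(d) <= 0) stop("V has no positive tip depth")
    if (diff(range(d)) > 1e-8 * max(d))
      warning("tree is not ultrametric; elementwise delta transform is ",
              "approximate")
    V <- (V / max(d))^delta
  }
  if (lambda != 1) {
    d <- diag(V)
    V <- lambda * V
    diag(V) <- d
  }
  V
}

# GLS core on a fixed covariance: whiten by the Cholesky factor and run
# ordinary least squares on the transformed problem. sigma2 is the ML
# estimate (divisor n); standard errors use the n/(n-p) correction so
# t-tests follow the usual GLS convention.
.gls_core <- function(y, X, V) {
  n <- length(y)
  p <- ncol(X)
  if (n <= p) stop("more coefficients than observations (n <= p)")
  U <- tryCatch(chol(V), error = function(e) {
    stop("phylogenetic covariance is not positive definite ",
         "(reciprocal condition estimate ",
         format(Matrix_rcond <- tryCatch(rcond(V), error = function(e2) NA),
                digits = 3), "): ", conditionMessage(e))
  })
  yw <- backsolve(U, y, transpose = TRUE)
  Xw <- backsolve(U, X, transpose = TRUE)
  qrX <- qr(Xw)
  if (qrX$rank < p)
    stop("design matrix is rank deficient (rank ", qrX$rank, " < ", p, ")")
  beta <- qr.coef(qrX, yw)
  res_w <- yw - Xw %*% beta
  rss <- sum(res_w^2)
  sigma2 <- rss / n
  logdetV <- 2 * sum(log(diag(U)))
  loglik <- -0.5 * (n * log(2 * pi) + n * log(sigma2) + logdetV + n)
  XtX_inv <- chol2inv(qr.R(qrX))
  se <- sqrt(diag(XtX_inv) * sigma2 * n / (n - p))
  tval <- beta / se
  pval <- 2 * stats::pt(abs(tval), df = n - p, lower.tail = FALSE)
  # null (intercept-only) GLS under the same V for the R2 baseline
  ones <- matrix(1, n, 1)
  ow <- backsolve(U, ones, transpose = TRUE)
  mu0 <- sum(ow * yw) / sum(ow^2)
  rss0 <- sum((yw - ow * mu0)^2)
  r2 <- 1 - rss / rss0
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - p)
  Fstat <- if (p > 1) ((rss0 - rss) / (p - 1)) / (rss / (n - p)) else NA_real_
  fitted <- drop(X %*% beta)
  list(beta = drop(beta), se = se, tval = drop(tval), pval = drop(pval),
       sigma2 = sigma2, loglik = loglik, r2 = r2, adj_r2 = adj_r2,
       F = Fstat, df = c(p - 1, n - p), fitted = fitted,
       residuals = y - fitted, U = U, rss_w = rss)
}

# profile log-likelihood at given (lambda, delta)
.profile_ll <- function(lambda, delta, y, X, V) {
  ll <- tryCatch(.gls_core(y, X, pagel_transform(V, lambda, delta))$loglik,
                 error = function(e) NA_real_)
  if (!is.finite(ll))
    stop("non-finite profile likelihood at lambda = ",
         format(lambda, digits = 4), ", delta = ",
         format(delta, digits = 4))
  ll
}

# golden-section maximization of f on [lo, hi]
.golden_max <- function(f, lo, hi, tol = 1e-4) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  while (b - a > tol) {
    if (f1 < f2) {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- f(x2)
    } else {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- f(x1)
    }
  }
  x <- (a + b) / 2
  list(par = x, value = f(x))
}

# grid-then-refine maximization of the profile likelihood over one
# parameter; grid is fixed (21 points) for reproducibility
.profile_max <- function(f, lo, hi, n_grid = 21L) {
  grid <- seq(lo, hi, length.out = n_grid)
  vals <- vapply(grid, f, numeric(1))
  i <- which.max(vals)
  a <- grid[max(1L, i - 1L)]
  b <- grid[min(n_grid, i + 1L)]
  ref <- .golden_max(f, a, b)
  if (ref$value >= vals[i]) ref else list(par = grid[i], value = vals[i])
}

#' Phylogenetic generalized least squares
#'
#' Fits a linear model whose error covariance follows the phylogeny,
#' optionally transformed by Pagel's lambda (strength of phylogenetic
#' signal) and delta (depth acceleration). Coefficients are the GLS
#' solution \eqn{\hat\beta = (X'V^{-1}X)^{-1} X'V^{-1} y}; the residual
#' variance is estimated by maximum likelihood and lambda/delta can be
#' profiled over bounded grids refined by golden-section search
#' (\code{lambda} in [0, 1], \code{delta} in (0.1, 3]).
#'
#' @param formula Model formula; variables are taken from \code{data}.
#' @param data Data frame with one row per species and a species
#'   identifier column (or row names) matching the tree's tip labels.
#' @param tree A validated [ape::phylo]; pruned to the modelled species.
#' @param lambda Numeric in [0, 1], or \code{"ML"} to estimate.
#' @param delta Positive numeric, or \code{"ML"} to estimate.
#' @param species Name of the species identifier column (default
#'   \code{"species"}; row names are used if absent).
#' @return An object of class \code{"pgls"} with methods for
#'   \code{print}, \code{summary}, \code{coef}, \code{residuals},
#'   \code{fitted}, \code{predict}, \code{logLik}, \code{simulate},
#'   \code{plot} and \code{nobs}, plus [lambda_lrt()] for the likelihood
#'   ratio test of phylogenetic signal.
#' @export
#' @examples
#' tr <- sim_tree(40, seed = 2)
#' d <- sim_brownian_traits(tr, lambda = 0.7, beta = c(0, 0.5), seed = 3)
#' fit <- pgls(y ~ x1, d, tr, lambda = "ML")
#' summary(fit)
pgls <- function(formula, data, tree, lambda = 1, delta = 1,
                 species = "species") {
  stopifnot(is.data.frame(data))
  sp <- if (species %in% names(data)) as.character(data[[species]])
  else rownames(data)
  if (anyDuplicated(sp)) stop("duplicated species in data")
  V <- phylo_vcv(tree, species = sp)
  mf <- stats::model.frame(formula, data)
  if (nrow(mf) != nrow(data))
    stop("missing values in model variables; PGLS requires complete data")
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  ml_lambda <- identical(lambda, "ML")
  ml_delta <- identical(delta, "ML")
  lam <- if (ml_lambda) 1 else lambda
  del <- if (ml_delta) 1 else delta
  if (!ml_lambda && (!is.numeric(lam) || lam < 0 || lam > 1))
    stop("lambda must be in [0, 1] or \"ML\"")
  if (!ml_delta && (!is.numeric(del) || del <= 0))
    stop("delta must be positive or \"ML\"")
  if (ml_lambda && ml_delta) {
    # coarse joint grid, then coordinate-wise refinement
    lg <- seq(0, 1, length.out = 21L)
    dg <- seq(0.1, 3, length.out = 21L)
    val <- outer(lg, dg, Vectorize(function(l, d)
      .profile_ll(l, d, y, X, V)))
    i <- arrayInd(which.max(val), dim(val))
    lam <- lg[i[1]]; del <- dg[i[2]]
    for (it in 1:2) {
      lam <- .profile_max(function(l) .profile_ll(l, del, y, X, V), 0, 1)$par
      del <- .profile_max(function(d) .profile_ll(lam, d, y, X, V),
                          0.1, 3)$par
    }
  } else if (ml_lambda) {
    lam <- .profile_max(function(l) .profile_ll(l, del, y, X, V), 0, 1)$par
  } else if (ml_delta) {
    del <- .profile_max(function(d) .profile_ll(lam, d, y, X, V), 0.1, 3)$par
  }
  core <- .gls_core(y, X, pagel_transform(V, lam, del))
  names(core$beta) <- names(core$se) <- names(core$tval) <-
    names(core$pval) <- colnames(X)
  res <- structure(core$residuals, names = sp)
  fitted <- structure(core$fitted, names = sp)
  out <- structure(list(
    call = match.call(), formula = formula, species = sp,
    coefficients = core$beta, se = core$se, tval = core$tval,
    pval = core$pval, lambda = lam, delta = del,
    ml = c(lambda = ml_lambda, delta = ml_delta),
    sigma2 = core$sigma2, loglik = core$loglik, r2 = core$r2,
    adj_r2 = core$adj_r2, fstatistic = core$F, df = core$df,
    residuals = res, fitted = fitted, y = structure(y, names = sp),
    X = X, V_raw = V, terms = attr(mf, "terms"),
    model = mf), class = "pgls")
  out
}

#' @export
print.pgls <- function(x, ...) {
  cat("Phylogenetic GLS\n")
  cat("Call: ", deparse(x$call), "\n", sep = "")
  cat(sprintf("lambda = %.4g%s, delta = %.4g%s, logLik = %.4f\n",
              x$lambda, if (x$ml["lambda"]) " (ML)" else "",
              x$delta, if (x$ml["delta"]) " (ML)" else "", x$loglik))
  cat("Coefficients:\n")
  print(round(x$coefficients, 5))
  invisible(x)
}

#' @export
summary.pgls <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
               `t value` = object$tval, `Pr(>|t|)` = object$pval)
  structure(list(call = object$call, coefficients = tab,
                 lambda = object$lambda, delta = object$delta,
                 ml = object$ml, loglik = object$loglik,
                 r2 = object$r2, adj_r2 = object$adj_r2,
                 fstatistic = object$fstatistic, df = object$df,
                 sigma2 = object$sigma2,
                 n = length(object$residuals)),
            class = "summary.pgls")
}

#' @export
print.summary.pgls <- function(x, ...) {
  cat("Phylogenetic GLS\n")
  cat("Call: ", deparse(x$call), "\n\n", sep = "")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat(sprintf("\nlambda = %.4g%s, delta = %.4g%s\n",
              x$lambda, if (x$ml["lambda"]) " (ML)" else " (fixed)",
              x$delta, if (x$ml["delta"]) " (ML)" else " (fixed)"))
  cat(sprintf("n = %d, logLik = %.4f, sigma2(ML) = %.4g\n",
              x$n, x$loglik, x$sigma2))
  if (is.finite(x$fstatistic))
    cat(sprintf("F = %.4g on %d and %d df, R2 = %.4g, Adj-R2 = %.4g\n",
                x$fstatistic, x$df[1], x$df[2], x$r2, x$adj_r2))
  invisible(x)
}

#' @export
coef.pgls <- function(object, ...) object$coefficients

#' @export
#' @rdname pgls
#' @param object,x A fitted \code{"pgls"} object.
#' @param type Residual type: \code{"response"} (y - X beta) or
#'   \code{"normalized"} (whitened by the fitted covariance and scaled to
#'   unit variance).
#' @param ... Unused.
residuals.pgls <- function(object, type = c("response", "normalized"),
                           ...) {
  type <- match.arg(type)
  if (type == "response") return(object$residuals)
  V <- pagel_transform(object$V_raw, object$lambda, object$delta)
  U <- chol(V)
  r <- backsolve(U, unclass(object$residuals), transpose = TRUE)
  structure(r / sqrt(object$sigma2), names = names(object$residuals))
}

#' @export
fitted.pgls <- function(object, ...) object$fitted

#' @export
nobs.pgls <- function(object, ...) length(object$residuals)

#' @export
logLik.pgls <- function(object, ...) {
  structure(object$loglik,
            df = length(object$coefficients) + 1L + sum(object$ml),
            nobs = length(object$residuals), class = "logLik")
}

#' @export
predict.pgls <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  tt <- stats::delete.response(object$terms)
  mf <- stats::model.frame(tt, newdata)
  X <- stats::model.matrix(tt, mf)
  drop(X %*% object$coefficients)
}

#' @export
simulate.pgls <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  V <- pagel_transform(object$V_raw, object$lambda, object$delta)
  U <- chol(object$sigma2 * V)
  n <- length(object$fitted)
  out <- as.data.frame(vapply(seq_len(nsim), function(i)
    unclass(object$fitted) + drop(crossprod(U, stats::rnorm(n))),
    numeric(n)))
  names(out) <- paste0("sim_", seq_len(nsim))
  rownames(out) <- names(object$fitted)
  out
}

#' @export
plot.pgls <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  r <- residuals(x, type = "normalized")
  graphics::plot(unclass(x$fitted), unclass(x$residuals),
                 xlab = "Fitted", ylab = "Residuals (response)",
                 main = "Residuals vs fitted", ...)
  graphics::abline(h = 0, lty = 3)
  stats::qqnorm(r, main = "Normalized residuals")
  stats::qqline(r)
  invisible(x)
}

#' Likelihood-ratio test of phylogenetic signal
#'
#' Compares the fitted model to the same model refitted at
#' \code{lambda = 0} (a star phylogeny, i.e. no phylogenetic covariance)
#' keeping delta at its fitted value. The statistic 2 (logLik_ML -
#' logLik_0) is referred to a chi-square with 1 df; because lambda = 0
#' sits on the boundary of its [0, 1] range this reference is
#' conservative, so reported p-values are upper bounds on the true ones.
#'
#' @param object A \code{"pgls"} fit (usually with \code{lambda = "ML"}).
#' @param tol Tolerance for detecting optimizer failure (fitted
#'   likelihood below the null beyond \code{tol} is an error).
#' @return An object of class \code{"htest"} with the statistic, df and
#'   p-value; the null fit is attached as attribute \code{"null_fit"}.
#' @export
lambda_lrt <- function(object, tol = 1e-6) {
  stopifnot(inherits(object, "pgls"))
  V0 <- pagel_transform(object$V_raw, 0, object$delta)
  core0 <- .gls_core(unclass(object$y), object$X, V0)
  stat <- 2 * (object$loglik - core0$loglik)
  if (stat < -tol)
    stop("optimizer failure: ML log-likelihood (", format(object$loglik),
         ") is below the lambda = 0 log-likelihood (",
         format(core0$loglik), ")")
  stat <- max(stat, 0)
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  structure(list(statistic = c("LR chi-square" = stat),
                 parameter = c(df = 1), p.value = p,
                 method = paste("Likelihood ratio test of Pagel's lambda",
                                "(H0: lambda = 0)"),
                 estimate = c(lambda = object$lambda),
                 data.name = deparse(object$call$formula)),
            class = "htest", null_loglik = core0$loglik)
}
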