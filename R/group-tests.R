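#' Kruskal-Wallis contrast of values across groups
#'
#' Rank-based test (midrank tie correction) of whether several groups
#' share a location, via [stats::kruskal.test()]. Used on the residuals
#' of the frequency-abundance PGLS to ask whether particular lineages or
#' origin classes are more abundant than their regional frequency
#' predicts.
#'
#' @param values Numeric vector.
#' @param groups Group labels, same length.
#' @return List with \code{statistic} (H, chi-square scale), \code{df}
#'   (groups - 1) and \code{p}.
#' @export
kw_test <- function(values, groups) {
  groups <- as.character(groups)
  if (length(values) != length(groups))
    stop("values and groups must have the same length")
  tab <- table(groups)
  if (length(tab) < 2) stop("at least 2 groups are required")
  if (any(tab == 0)) stop("empty group(s)")
  if (length(unique(values)) == 1L)  # no variation: no group difference
    return(list(statistic = 0, df = length(tab) - 1L, p = 1))
  ht <- stats::kruskal.test(values, factor(groups))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Dunn post-hoc pairwise comparisons
#'
#' Pairwise z statistics on the pooled midranks with tie correction,
#' \deqn{z_{ij} = (\bar R_i - \bar R_j) /
#'   \sqrt{\left(\frac{N(N+1)}{12} - \frac{\sum (t^3 - t)}{12(N-1)}\right)
#'   (1/n_i + 1/n_j)}}
#' with two-sided normal p-values, optionally adjusted for the number of
#' pairs.
#'
#' @inheritParams kw_test
#' @param adjust Multiplicity adjustment: \code{"none"} (default),
#'   \code{"bonferroni"} or \code{"holm"}.
#' @return Data frame with columns \code{group1}, \code{group2},
#'   \code{z}, \code{p}, \code{p_adj}.
#' @export
dunn_test <- function(values, groups, adjust = c("none", "bonferroni",
                                                 "holm")) {
  adjust <- match.arg(adjust)
  groups <- as.character(groups)
  if (length(values) != length(groups))
    stop("values and groups must have the same length")
  tab <- table(groups)
  if (length(tab) < 2) stop("at least 2 groups are required")
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  ties <- table(values)
  tiecor <- sum(ties^3 - ties) / (12 * (N - 1))
  v0 <- N * (N + 1) / 12 - tiecor
  gn <- sort(names(tab))
  pairs <- utils::combn(gn, 2)
  z <- apply(pairs, 2, function(gp) {
    if (v0 <= 0) return(0)  # all values tied: no contrast
    (rbar[[gp[1]]] - rbar[[gp[2]]]) /
      sqrt(v0 * (1 / tab[[gp[1]]] + 1 / tab[[gp[2]]]))
  })
  p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z,
                    p = p, p_adj = stats::p.adjust(p, method = adjust),
                    stringsAsFactors = FALSE, row.names = NULL)
  out
}

# maximal cliques of a small undirected graph by subset enumeration
.max_cliques <- function(adj) {
  g <- rownames(adj)
  k <- length(g)
  if (k > 16) stop("too many groups for subset enumeration")
  subsets <- lapply(seq_len(2^k - 1), function(m)
    which(bitwAnd(m, 2^(seq_len(k) - 1)) > 0))
  is_clique <- vapply(subsets, function(s)
    all(adj[s, s] | diag(TRUE, length(s))), logical(1))
  cl <- subsets[is_clique]
  maximal <- vapply(seq_along(cl), function(i)
    !any(vapply(cl, function(other)
      length(other) > length(cl[[i]]) && all(cl[[i]] %in% other),
      logical(1))), logical(1))
  cl[maximal]
}

#' Compact letter display from pairwise comparisons
#'
#' Assigns letters to groups such that two groups share a letter if and
#' only if they belong to a common maximal clique of the
#' non-significance graph (pairwise p >= alpha). Cliques are ordered
#' deterministically by their alphabetically-first member, so the output
#' is reproducible.
#'
#' @param pairwise Data frame from [dunn_test()] (columns \code{group1},
#'   \code{group2} and a p-value column).
#' @param alpha Significance level (default 0.05).
#' @param p_col P-value column to use (default \code{"p_adj"}, falling
#'   back to \code{"p"}).
#' @return Named character vector, group -> letter string.
#' @export
#' @examples
#' pw <- data.frame(group1 = c("A", "A", "B"), group2 = c("B", "C", "C"),
#'                  p = c(0.60, 0.01, 0.30))
#' letter_display(pw)  # A "a", B "ab", C "b"
letter_display <- function(pairwise, alpha = 0.05, p_col = NULL) {
  if (is.null(p_col))
    p_col <- if ("p_adj" %in% names(pairwise)) "p_adj" else "p"
  need <- c("group1", "group2", p_col)
  if (!all(need %in% names(pairwise)))
    stop("pairwise table must have columns ", paste(need, collapse = ", "))
  g <- sort(unique(c(pairwise$group1, pairwise$group2)))
  adj <- matrix(TRUE, length(g), length(g), dimnames = list(g, g))
  sig <- pairwise[[p_col]] < alpha
  for (i in seq_len(nrow(pairwise))) {
    a <- pairwise$group1[i]; b <- pairwise$group2[i]
    adj[a, b] <- adj[b, a] <- !sig[i]
  }
  cliques <- .max_cliques(adj)
  cliques <- cliques[order(vapply(cliques, min, numeric(1)),
                           -vapply(cliques, length, numeric(1)))]
  letters_out <- stats::setNames(rep("", length(g)), g)
  for (i in seq_along(cliques)) {
    lab <- letters[i]
    letters_out[cliques[[i]]] <- paste0(letters_out[cliques[[i]]], lab)
  }
  letters_out
}

#' Residual contrasts across species groupings
#'
#' Runs, for each requested grouping of a species annotation table, the
#' Kruskal-Wallis test, Dunn pairwise comparisons and the compact letter
#' display on per-species values (typically response-scale residuals of
#' the frequency-abundance PGLS).
#'
#' @param values Named numeric vector (names are species).
#' @param annotations Validated annotation table (see
#'   [read_annotation_table()]).
#' @param groupings Annotation columns to contrast (default all three).
#' @param adjust Dunn adjustment (default \code{"none"}, matching the
#'   common reporting convention; see [dunn_test()]).
#' @param alpha Significance level for the letter display.
#' @return Named list (one element per grouping) of lists with
#'   \code{kw}, \code{pairwise}, \code{letters}; class
#'   \code{"group_tests"}.
#' @export
residual_group_tests <- function(values, annotations,
                                 groupings = c("group_taxo", "origin",
                                               "resistant_pops"),
                                 adjust = "none", alpha = 0.05) {
  if (is.null(names(values)))
    stop("values must be named by species")
  m <- match(names(values), annotations$species)
  if (anyNA(m))
    stop("species missing from the annotation table: ",
         paste(names(values)[is.na(m)], collapse = ", "))
  ann <- annotations[m, , drop = FALSE]
  out <- lapply(groupings, function(gr) {
    if (!gr %in% names(ann)) stop("unknown grouping: ", gr)
    labels <- as.character(ann[[gr]])
    kw <- kw_test(values, labels)
    pw <- dunn_test(values, labels, adjust = adjust)
    list(kw = kw, pairwise = pw,
         letters = letter_display(pw, alpha = alpha))
  })
  names(out) <- groupings
  structure(out, class = "group_tests")
}

#' @export
print.group_tests <- function(x, ...) {
  for (gr in names(x)) {
    cat(sprintf("%s: Kruskal-Wallis chi-square = %.3f, df = %d, p = %.4g\n",
                gr, x[[gr]]$kw$statistic, x[[gr]]$kw$df, x[[gr]]$kw$p))
    lt <- x[[gr]]$letters
    cat("  letters: ",
        paste(sprintf("%s=%s", names(lt), lt), collapse = ", "), "\n")
  }
  invisible(x)
}
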