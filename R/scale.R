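#' The six-class cover-abundance scale
#'
#' Weed surveys analysed by this package score species on a six-class
#' cover-abundance scale: \code{"+"} (a single individual in the whole
#' plot), \code{"1"} (< 1 individual/m2), \code{"2"} (1--2), \code{"3"}
#' (3--20), \code{"4"} (21--50) and \code{"5"} (> 50 individuals/m2).
#'
#' @return Character vector of the six class symbols, in increasing order
#'   of abundance.
#' @seealso [class_midpoints()], [density_to_class()]
#' @export
#' @examples
#' abundance_classes()
abundance_classes <- function() {
  c("+", "1", "2", "3", "4", "5")
}

#' Density midpoints of the cover-abundance classes
#'
#' Classes \code{"+"}, \code{"1"} and \code{"2"} all carry the midpoint
#' 1.5 individuals/m2; classes \code{"3"}, \code{"4"} and \code{"5"} carry
#' 11.5, 35.5 and 75.5 respectively. These are the weights used by
#' [mean_local_abundance()] and [crop_fidelity()].
#'
#' @return Named numeric vector mapping class symbol to midpoint density
#'   (individuals/m2).
#' @export
#' @examples
#' class_midpoints()[["4"]]  # 35.5
class_midpoints <- function() {
  c("+" = 1.5, "1" = 1.5, "2" = 1.5, "3" = 11.5, "4" = 35.5, "5" = 75.5)
}

#' Discretize a plant density to the six-class scale
#'
#' Converts densities (individuals/m2) to abundance classes using
#' exhaustive interval boundaries: a literal singleton in the plot
#' (density * plot_area <= 1) maps to \code{"+"}; densities below 1 map to
#' class \code{"1"}; [1, 3) to \code{"2"}; [3, 20] to \code{"3"};
#' (20, 50] to \code{"4"}; above 50 to \code{"5"}.
#'
#' @param density Numeric vector of positive densities (individuals/m2).
#' @param plot_area Plot area in m2 used to detect the singleton class
#'   \code{"+"}; default 2000.
#' @return Character vector of class symbols.
#' @export
#' @examples
#' density_to_class(c(0.0004, 0.5, 1.9, 12, 35, 80))
density_to_class <- function(density, plot_area = 2000) {
  stopifnot(is.numeric(density), all(is.finite(density)), all(density > 0))
  cls <- character(length(density))
  cls[density > 50] <- "5"
  cls[density > 20 & density <= 50] <- "4"
  cls[density >= 3 & density <= 20] <- "3"
  cls[density >= 1 & density < 3] <- "2"
  cls[density < 1] <- "1"
  cls[density * plot_area <= 1] <- "+"
  cls
}

# score ordering helper: rank of a class symbol on the scale (1..6)
.class_rank <- function(score) {
  match(score, abundance_classes())
}

# normalize score spellings: "0.5" is accepted for the presence class "+",
# numeric classes may arrive as numbers
.normalize_score <- function(score) {
  s <- trimws(as.character(score))
  s[s == "0.5"] <- "+"
  s
}
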