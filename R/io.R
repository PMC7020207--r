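#' Default survey column schema
#'
#' Maps the survey table's logical fields to CSV column names. Override
#' entries to read files with different headers.
#'
#' @param ... Named overrides, e.g. \code{species = "taxon"}.
#' @return Named character vector of column names.
#' @export
survey_schema <- function(...) {
  schema <- c(field_id = "field_id", year = "year", period = "period",
              region = "region", crop = "crop", plot = "plot",
              species = "species", score = "score")
  over <- c(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(schema))
    if (length(bad)) stop("unknown schema field(s): ",
                          paste(bad, collapse = ", "))
    schema[names(over)] <- over
  }
  schema
}

#' Validate a survey table
#'
#' Checks the invariants of the long-format survey table: known score
#' symbols, no duplicated (field, year, plot, species) rows, and a unique
#' region and period per field. Offending rows are reported by row
#' number; nothing is silently dropped.
#'
#' @param survey Data frame with the standard survey columns.
#' @return The validated table (scores normalized, e.g. \code{"0.5"} to
#'   \code{"+"}), invisibly classed as before.
#' @export
validate_survey <- function(survey) {
  need <- names(survey_schema())
  miss <- setdiff(need, names(survey))
  if (length(miss))
    stop("survey table is missing column(s): ", paste(miss, collapse = ", "))
  survey$score <- .normalize_score(survey$score)
  bad <- which(!survey$score %in% abundance_classes())
  if (length(bad))
    stop("unknown score symbol(s) ",
         paste(unique(survey$score[bad]), collapse = ", "),
         " in row(s): ", paste(utils::head(bad, 20), collapse = ", "))
  key <- paste(survey$field_id, survey$year, survey$plot, survey$species,
               sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup))
    stop("duplicated (field, year, plot, species) record(s) in row(s): ",
         paste(utils::head(dup, 20), collapse = ", "))
  per_field <- unique(survey[, c("field_id", "region", "period")])
  multi <- per_field$field_id[duplicated(per_field$field_id)]
  if (length(multi))
    stop("field(s) mapped to more than one region or period: ",
         paste(unique(multi), collapse = ", "))
  survey
}

#' Read a long-format survey table
#'
#' Reads a UTF-8 comma-separated survey file (header row mandatory, "."
#' decimal mark), renames columns according to \code{schema} and
#' validates it with [validate_survey()].
#'
#' @param path Path to a CSV file.
#' @param schema Column-name map from [survey_schema()].
#' @return A validated survey data frame with the standard columns.
#' @export
read_survey <- function(path, schema = survey_schema()) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", fileEncoding = "UTF-8")
  miss <- setdiff(unname(schema), names(raw))
  if (length(miss))
    stop("survey file ", path, " lacks declared column(s): ",
         paste(miss, collapse = ", "))
  out <- raw[, unname(schema)]
  names(out) <- names(schema)
  out$year <- as.integer(out$year)
  if (anyNA(out$year)) stop("non-integer year value(s) in ", path)
  validate_survey(out)
}

#' Write a survey table
#'
#' @param survey A validated survey table.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_survey <- function(survey, path) {
  utils::write.csv(validate_survey(survey)[, names(survey_schema())],
                   path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' The species-trait schema
#'
#' The trait table mixes eleven quantitative traits (specific leaf area,
#' maximum plant height, seed weight, flowering onset and duration,
#' fecundity, seed longevity, Ellenberg L/N/T indicator values, and a
#' herbicide-sensitivity score) with four qualitative traits (Raunkiaer
#' life form, emergence period, dispersal mode, photosynthetic pathway).
#'
#' @return List with elements \code{quantitative} (character vector of
#'   column names) and \code{qualitative} (named list of allowed levels).
#' @export
trait_schema <- function() {
  list(
    quantitative = c("sla", "height", "seed_weight", "flowering_onset",
                     "flowering_duration", "fecundity", "seed_longevity",
                     "ellenberg_l", "ellenberg_n", "ellenberg_t",
                     "herbicide_sensitivity"),
    qualitative = list(
      life_form = c("geophyte", "hemicryptophyte", "therophyte"),
      emergence = c("all_year", "autumn_winter_spring", "spring",
                    "spring_summer", "summer"),
      dispersal = c("animal", "gravity", "wind"),
      photosynthesis = c("C3", "C4")
    )
  )
}

#' Validate a species-trait table
#'
#' Enforces a total trait schema: every declared trait present, no
#' missing values after validation, qualitative levels drawn from the
#' declared modalities. As a flagged convenience, \code{fill_missing =
#' TRUE} imputes missing quantitative values by the trait mean and
#' missing qualitative values by the modal level, with a warning; proper
#' imputation is out of this package's scope.
#'
#' @param traits Data frame with a \code{species} column and the trait
#'   columns of \code{schema}.
#' @param schema Trait schema, see [trait_schema()].
#' @param fill_missing Logical; fill missing values by mean/mode
#'   (default \code{FALSE}: missing values are an error).
#' @return The validated (possibly filled) trait table.
#' @export
validate_traits <- function(traits, schema = trait_schema(),
                            fill_missing = FALSE) {
  need <- c("species", schema$quantitative, names(schema$qualitative))
  miss <- setdiff(need, names(traits))
  if (length(miss))
    stop("trait table is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(traits$species))
    stop("duplicated species in trait table")
  for (tr in schema$quantitative) {
    traits[[tr]] <- as.numeric(traits[[tr]])
    if (anyNA(traits[[tr]])) {
      if (!fill_missing)
        stop("missing/non-numeric values in quantitative trait '", tr,
             "' (species: ",
             paste(traits$species[is.na(traits[[tr]])], collapse = ", "),
             ")")
      warning("filling missing '", tr, "' with the trait mean (flagged ",
              "convenience, not an imputation method)")
      traits[[tr]][is.na(traits[[tr]])] <- mean(traits[[tr]], na.rm = TRUE)
    }
  }
  for (tr in names(schema$qualitative)) {
    v <- as.character(traits[[tr]])
    v[v == ""] <- NA
    bad <- !is.na(v) & !v %in% schema$qualitative[[tr]]
    if (any(bad))
      stop("qualitative trait '", tr, "' has level(s) outside the schema: ",
           paste(unique(v[bad]), collapse = ", "))
    if (anyNA(v)) {
      if (!fill_missing)
        stop("missing values in qualitative trait '", tr, "' (species: ",
             paste(traits$species[is.na(v)], collapse = ", "), ")")
      warning("filling missing '", tr, "' with the modal level (flagged ",
              "convenience)")
      tab <- table(v)
      v[is.na(v)] <- names(tab)[which.max(tab)]
    }
    traits[[tr]] <- v
  }
  traits
}

#' Read a species-trait table
#'
#' @inheritParams validate_traits
#' @param path CSV path.
#' @return Validated trait data frame.
#' @export
read_trait_table <- function(path, schema = trait_schema(),
                             fill_missing = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  validate_traits(raw, schema, fill_missing)
}

#' Read a species annotation table
#'
#' Annotations carry the groupings used for residual contrasts: broad
#' taxonomy (\code{Dicot}, \code{Pooideae}, \code{Panicoideae}), origin
#' class (\code{native}, \code{archaeophyte}, \code{neophyte}) and a
#' logical flag for species with known herbicide-resistant populations.
#'
#' @param path CSV path with columns \code{species}, \code{group_taxo},
#'   \code{origin}, \code{resistant_pops}.
#' @return Validated annotation data frame.
#' @export
read_annotation_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ann <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  validate_annotations(ann)
}

#' @rdname read_annotation_table
#' @param annotations Data frame to validate in place of a file.
#' @export
validate_annotations <- function(annotations) {
  need <- c("species", "group_taxo", "origin", "resistant_pops")
  miss <- setdiff(need, names(annotations))
  if (length(miss))
    stop("annotation table is missing column(s): ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(annotations$species))
    stop("duplicated species in annotation table")
  bad <- setdiff(unique(annotations$group_taxo),
                 c("Dicot", "Pooideae", "Panicoideae"))
  if (length(bad)) stop("unknown group_taxo level(s): ",
                        paste(bad, collapse = ", "))
  bad <- setdiff(unique(annotations$origin),
                 c("native", "archaeophyte", "neophyte"))
  if (length(bad)) stop("unknown origin level(s): ",
                        paste(bad, collapse = ", "))
  annotations$resistant_pops <- as.logical(annotations$resistant_pops)
  if (anyNA(annotations$resistant_pops))
    stop("resistant_pops must be logical (TRUE/FALSE)")
  annotations
}

#' Read a phylogeny in Newick format
#'
#' Wraps [ape::read.tree()] with the validation this package's analyses
#' require: branch lengths present, finite and nonnegative, unique tip
#' labels. Zero-length terminal branches are permitted but warned about.
#'
#' @param path Path to a Newick file.
#' @return An [ape::phylo] object.
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("unparseable Newick in ", path,
                                            ": ", conditionMessage(e)))
  if (is.null(tree)) stop("unparseable Newick in ", path)
  validate_tree(tree)
}

#' @rdname read_tree
#' @param tree An [ape::phylo] object to validate.
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths; an ultrametric tree with branch ",
         "lengths is required")
  if (any(!is.finite(tree$edge.length)))
    stop("non-finite branch length(s)")
  if (any(tree$edge.length < 0))
    stop("negative branch length(s)")
  if (anyDuplicated(tree$tip.label))
    stop("duplicated tip label(s): ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  term <- tree$edge[, 2] <= length(tree$tip.label)
  if (any(tree$edge.length[term] == 0))
    warning("zero-length terminal branch(es) present")
  tree
}

#' Write a phylogeny in Newick format
#'
#' @param tree An [ape::phylo] object.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(validate_tree(tree), file = path)
  invisible(path)
}

#' Cross-file species consistency check
#'
#' Species tokens are case-sensitive exact keys across the survey, trait,
#' annotation and tree inputs. This pre-flight check reports, for each
#' pair of supplied inputs, the species present in one but not the other,
#' and fails if any analysis species lacks a trait row or a tip.
#'
#' @param survey,traits,tree,annotations Any subset of the four inputs
#'   (\code{NULL} to skip).
#' @param species Optional explicit species set to check; defaults to the
#'   survey's species (or the union of what is supplied).
#' @return Invisibly, the checked species vector.
#' @export
check_species_consistency <- function(survey = NULL, traits = NULL,
                                      tree = NULL, annotations = NULL,
                                      species = NULL) {
  if (is.null(species)) {
    species <- if (!is.null(survey)) unique(survey$species)
    else unique(c(if (!is.null(traits)) traits$species,
                  if (!is.null(tree)) tree$tip.label,
                  if (!is.null(annotations)) annotations$species))
  }
  fail <- character(0)
  report <- function(what, have) {
    miss <- setdiff(species, have)
    if (length(miss))
      fail <<- c(fail, paste0(what, " lacks ", length(miss),
                              " species: ",
                              paste(utils::head(miss, 10), collapse = ", ")))
  }
  if (!is.null(traits)) report("trait table", traits$species)
  if (!is.null(tree)) report("tree", tree$tip.label)
  if (!is.null(annotations)) report("annotation table", annotations$species)
  if (length(fail))
    stop("species mismatch across inputs:\n  ",
         paste(fail, collapse = "\n  "))
  invisible(species)
}
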