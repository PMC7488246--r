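#' Class scales for the ordinal pigmentation grades
#'
#' Field phenotyping uses 5-grade darkness scales (eye: 0 = lightest to 4 =
#' darkest; hair: 0 = red, 1 = blond, ..., 4 = dark). Classification uses the
#' coarser forensic scales: eye 3-class (blue / intermediate / brown), hair
#' 4-class (red / blond / brown / dark) and hair 3-class with blond and brown
#' merged. `class_scale()` returns a scale definition: the ordered class
#' labels, the grade-to-class mapping and a representative grade value per
#' class (used to orient one-vs-rest ROC scores and to convert continuous
#' predictions into classes).
#'
#' The default eye mapping \{0,1\} -> blue, \{2\} -> intermediate, \{3,4\} ->
#' brown is the symmetric split of the 5-grade scale; hair pins grades 0, 1
#' and 4 to red, blond and dark and assigns \{2,3\} to brown. Both are
#' configurable through the `mapping` argument.
#'
#' @param name one of `"eye3"`, `"hair4"`, `"hair3"`.
#' @param mapping optional length-5 character vector giving the class of each
#'   grade 0-4 (must use only that scale's labels).
#' @return An object of class `class_scale`: list with `name`, `levels`,
#'   `mapping` (grade -> label) and `centers` (label -> representative grade).
#' @export
class_scale <- function(name = c("eye3", "hair4", "hair3"), mapping = NULL) {
  name <- match.arg(name)
  defaults <- list(
    eye3 = list(levels = c("blue", "intermediate", "brown"),
                mapping = c("blue", "blue", "intermediate", "brown", "brown")),
    hair4 = list(levels = c("red", "blond", "brown", "dark"),
                 mapping = c("red", "blond", "brown", "brown", "dark")),
    hair3 = list(levels = c("red", "blond+brown", "dark"),
                 mapping = c("red", "blond+brown", "blond+brown",
                             "blond+brown", "dark")))
  def <- defaults[[name]]
  if (is.null(mapping)) mapping <- def$mapping
  if (length(mapping) != 5 || !all(mapping %in% def$levels))
    stop("mapping must assign each grade 0-4 one of: ",
         paste(def$levels, collapse = ", "))
  grades <- 0:4
  centers <- vapply(def$levels,
                    function(lv) mean(grades[mapping == lv]), numeric(1))
  out <- list(name = name, levels = def$levels,
              mapping = stats::setNames(mapping, grades), centers = centers)
  class(out) <- "class_scale"
  out
}

apply_scale <- function(grade, scale) {
  if (any(is.na(grade) | grade < 0 | grade > 4 | grade != as.integer(grade)))
    stop("grades must be integers in 0-4")
  factor(unname(scale$mapping[as.character(grade)]), levels = scale$levels)
}

#' Convert 5-grade eye darkness to the 3-class scale
#'
#' @param grade integer eye grades 0-4.
#' @param scale an eye `class_scale` (default mapping \{0,1\} blue, \{2\}
#'   intermediate, \{3,4\} brown).
#' @return Factor with levels blue < intermediate < brown.
#' @export
eye_grade_to_class <- function(grade, scale = class_scale("eye3")) {
  stopifnot(identical(scale$name, "eye3"))
  apply_scale(grade, scale)
}

#' Convert 5-grade hair scale to the 4-class scale
#'
#' @param grade integer hair grades 0-4 (0 red, 1 blond, 4 dark).
#' @param scale a hair-4 `class_scale`.
#' @return Factor with levels red, blond, brown, dark.
#' @export
hair_grade_to_class4 <- function(grade, scale = class_scale("hair4")) {
  stopifnot(identical(scale$name, "hair4"))
  apply_scale(grade, scale)
}

#' Merge the blond and brown hair classes
#'
#' The 4-class hair problem is hard to separate between blond and brown;
#' merging them into a single class gives the 3-class hair scale (red,
#' blond+brown, dark) on which classifier performance improves.
#'
#' @param class4 factor or character of 4-class hair labels.
#' @return Factor with levels red, blond+brown, dark.
#' @export
merge_blond_brown <- function(class4) {
  lab <- as.character(class4)
  known <- c(red = "red", blond = "blond+brown", brown = "blond+brown",
             dark = "dark")
  bad <- setdiff(unique(lab[!is.na(lab)]), names(known))
  if (length(bad)) stop("unknown hair class label(s): ",
                        paste(bad, collapse = ", "))
  factor(unname(known[lab]), levels = c("red", "blond+brown", "dark"))
}

#' Drop populations without enough phenotypic diversity
#'
#' Populations exhibiting fewer than `min_distinct_grades` distinct grades of
#' the trait's 5-grade scale are removed (all their samples), balancing the
#' phenotypic classes before association analysis. Applied per trait.
#'
#' @param phenotypes phenotype data frame with `population` and the grade
#'   columns.
#' @param trait `"eye"` or `"hair"`.
#' @param min_distinct_grades minimum number of distinct grades a population
#'   must show to be retained (default 4).
#' @return The filtered phenotype table with attribute
#'   `"removed_populations"`; error if nothing survives.
#' @export
filter_populations_by_grade_diversity <- function(phenotypes,
                                                  trait = c("eye", "hair"),
                                                  min_distinct_grades = 4) {
  trait <- match.arg(trait)
  col <- paste0(trait, "_grade")
  stopifnot(col %in% names(phenotypes), "population" %in% names(phenotypes))
  n_distinct <- tapply(phenotypes[[col]], phenotypes$population,
                       function(g) length(unique(g)))
  keep_pops <- names(n_distinct)[n_distinct >= min_distinct_grades]
  out <- phenotypes[phenotypes$population %in% keep_pops, , drop = FALSE]
  if (nrow(out) == 0)
    stop("grade-diversity filter removed every population")
  attr(out, "removed_populations") <- setdiff(names(n_distinct), keep_pops)
  out
}
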