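# Body-surface-area Km factors used by the FDA human-equivalent-dose
# formula (dose_animal = dose_human * Km_human / Km_animal).
KM_FACTORS <- c(human = 37, mouse = 3, rat = 6, rabbit = 12, dog = 20)

#' Human-equivalent dose translation by body-surface area
#'
#' Converts a human mg/kg dose to an animal dose with the standard
#' body-surface-area scaling `dose_animal = dose_human * Km_human /
#' Km_animal` (Km 37 for human, 3 for mouse), optionally rounded to a
#' working granularity, e.g. 10.5 mg/kg/day in humans becomes 129.5, then
#' 130 mg/kg/day in mice when rounded to the nearest 10.
#'
#' @param human_dose Human dose, mg/kg/day.
#' @param km_human,km_animal Body-surface-area Km factors (defaults 37 and
#'   3, human to mouse).
#' @param granularity Round the animal dose to this step in mg/kg (half
#'   up); `NULL` keeps full precision.
#' @return Animal dose in mg/kg/day.
#' @examples
#' hed_animal_dose(10.5, granularity = 10)  # 130
#' @export
hed_animal_dose <- function(human_dose, km_human = 37, km_animal = 3,
                            granularity = NULL) {
  stopifnot(human_dose >= 0, km_human > 0, km_animal > 0)
  dose <- human_dose * km_human / km_animal
  if (!is.null(granularity)) {
    stopifnot(granularity > 0)
    dose <- floor(dose / granularity + 0.5) * granularity
  }
  dose
}

#' Invert the human-equivalent-dose scaling
#'
#' @param animal_dose Animal dose, mg/kg/day.
#' @inheritParams hed_animal_dose
#' @return The unrounded human dose in mg/kg/day.
#' @export
hed_human_dose <- function(animal_dose, km_human = 37, km_animal = 3) {
  stopifnot(animal_dose >= 0, km_human > 0, km_animal > 0)
  animal_dose * km_animal / km_human
}

#' Diet admixture concentration for a target daily dose
#'
#' How much compound to mix per gram of diet so that an animal of the given
#' body weight eating `daily_intake` grams per day receives `dose` mg/kg/day.
#'
#' @param dose Target dose, mg/kg body weight per day.
#' @param body_weight Body weight in kg (a 30 g mouse is 0.030).
#' @param daily_intake Daily food intake in g (3 g for a mouse on high-fat
#'   diet).
#' @return Concentration in mg compound per g diet.
#' @examples
#' diet_admixture(130, 0.030, 3)  # 1.3 mg/day over 3 g -> 0.433 mg/g
#' @export
diet_admixture <- function(dose, body_weight, daily_intake) {
  stopifnot(dose >= 0, body_weight > 0, daily_intake > 0)
  dose * body_weight / daily_intake
}

#' Apportion an extract dose over fractions and fraction constituents
#'
#' Fraction doses are stated percentages of the whole-extract dose;
#' compound doses are stated percentages of one parent fraction's dose
#' (chained proportions). Mirrors dose adjustment in bioactivity-guided
#' fractionation, where fraction and compound feeding doses are matched to
#' their abundance in the parent extract.
#'
#' @param extract_dose Whole-extract dose, mg/kg/day.
#' @param fractions Data frame with columns `fraction` and `pct_extract`
#'   (percent of the extract each fraction represents).
#' @param compounds Optional data frame with columns `compound`, `parent`
#'   (a fraction name) and `pct_fraction` (percent of that fraction).
#' @return A tibble with columns `item`, `level` (`"fraction"` or
#'   `"compound"`), `parent`, `pct` and `dose` (mg/kg/day). Warns if the
#'   percentages at any one level sum above 100.
#' @examples
#' apportion_doses(
#'   130,
#'   tibble::tibble(fraction = c("F2", "F3", "F4"),
#'                  pct_extract = c(13.7, 9.8, 10.3)),
#'   tibble::tibble(compound = c("IX", "AP", "GP", "GG", "GE"),
#'                  parent = "F4", pct_fraction = c(4, 4, 20, 4, 4))
#' )
#' @export
apportion_doses <- function(extract_dose, fractions, compounds = NULL) {
  stopifnot(extract_dose >= 0,
            all(c("fraction", "pct_extract") %in% names(fractions)))
  fractions <- tibble::as_tibble(fractions)
  if (any(fractions$pct_extract <= 0 | fractions$pct_extract > 100)) {
    stop("fraction percentages must lie in (0, 100]")
  }
  if (sum(fractions$pct_extract) > 100) {
    warning("fraction percentages sum above 100% of the extract")
  }
  frac_tbl <- tibble::tibble(
    item = fractions$fraction,
    level = "fraction",
    parent = "extract",
    pct = fractions$pct_extract,
    dose = extract_dose * fractions$pct_extract / 100
  )
  out <- frac_tbl
  if (!is.null(compounds)) {
    stopifnot(all(c("compound", "parent", "pct_fraction") %in% names(compounds)))
    compounds <- tibble::as_tibble(compounds)
    if (any(compounds$pct_fraction <= 0 | compounds$pct_fraction > 100)) {
      stop("compound percentages must lie in (0, 100]")
    }
    missing_parent <- setdiff(compounds$parent, frac_tbl$item)
    if (length(missing_parent) > 0) {
      stop("unknown parent fraction(s): ", paste(missing_parent, collapse = ", "))
    }
    over <- tapply(compounds$pct_fraction, compounds$parent, sum)
    if (any(over > 100)) {
      warning("compound percentages sum above 100% within a fraction")
    }
    parent_dose <- frac_tbl$dose[match(compounds$parent, frac_tbl$item)]
    comp_tbl <- tibble::tibble(
      item = compounds$compound,
      level = "compound",
      parent = compounds$parent,
      pct = compounds$pct_fraction,
      dose = parent_dose * compounds$pct_fraction / 100
    )
    out <- dplyr::bind_rows(frac_tbl, comp_tbl)
  }
  out
}
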