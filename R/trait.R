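#' Survival-trait configuration
#'
#' The dichotomous survival trait: cases survived to at least
#' `case_min_age` (85 by default), controls died or were last followed up
#' at an age in \[`control_min_age`, `control_max_age_exclusive`), i.e.
#' \[75, 85) by default. Ages below the control window are excluded.
#'
#' @param case_min_age minimum age (years) for case status.
#' @param control_min_age lower bound (inclusive) of the control window.
#' @param control_max_age_exclusive upper bound (exclusive) of the control
#'   window.
#' @param alive_controls if `FALSE`, individuals alive at last follow-up in
#'   the control window are excluded instead of used as controls
#'   (sensitivity switch; the default reproduces the standard definition in
#'   which the control window applies to death age or age at last
#'   follow-up alike).
#' @return a `trait_config` list.
#' @export
trait_config <- function(case_min_age = 85, control_min_age = 75,
                         control_max_age_exclusive = 85,
                         alive_controls = TRUE) {
  if (!(control_min_age < control_max_age_exclusive &&
        control_max_age_exclusive <= case_min_age)) {
    stop("need control_min_age < control_max_age_exclusive <= case_min_age")
  }
  structure(list(case_min_age = case_min_age,
                 control_min_age = control_min_age,
                 control_max_age_exclusive = control_max_age_exclusive,
                 alive_controls = alive_controls),
            class = "trait_config")
}

#' Assign case/control/excluded status
#'
#' Case if age >= `case_min_age` regardless of vital status (survival to
#' the case age is demonstrated whether the age is a death age or a
#' follow-up age); control if the age (death or last follow-up) falls in
#' the control window; excluded otherwise.
#'
#' @param age age in years (lifespan if died, else age at last follow-up).
#' @param died logical; TRUE if the age is an observed lifespan.
#' @param cfg a [trait_config()].
#' @return factor with levels case, control, excluded.
#' @export
assign_class <- function(age, died, cfg = trait_config()) {
  if (any(age <= 0)) stop("ages must be positive")
  cls <- ifelse(age >= cfg$case_min_age, "case",
                ifelse(age >= cfg$control_min_age &
                         age < cfg$control_max_age_exclusive,
                       "control", "excluded"))
  if (!cfg$alive_controls) {
    cls[cls == "control" & !died] <- "excluded"
  }
  factor(cls, levels = c("case", "control", "excluded"))
}

#' Build the labelled analysis cohort
#'
#' Joins phenotype records to the genotyped individuals, assigns
#' case/control/excluded status, and emits a summary table (counts and
#' covariate percentages by class and sex when covariates are supplied).
#'
#' @param phenotypes data frame with `individual_id`, `age`, `died`.
#' @param cfg a [trait_config()].
#' @param covariates optional covariate data frame (with `individual_id`,
#'   `education`, `smoking`, `sex`) used for the summary table.
#' @param individual_ids optional character vector (e.g. the genotyped
#'   individuals); every id must have a phenotype record or an error lists
#'   the missing ones. Defaults to the phenotype ids.
#' @return object of class `survival_cohort`: list with `labels` (named
#'   0/1 vector over case+control individuals, 1 = case), `class` (factor
#'   over all ids), `excluded` (ids), `summary` (data frame).
#' @export
build_cohort <- function(phenotypes, cfg = trait_config(),
                         covariates = NULL, individual_ids = NULL) {
  if (is.null(individual_ids)) individual_ids <- phenotypes$individual_id
  missing_ids <- setdiff(individual_ids, phenotypes$individual_id)
  if (length(missing_ids)) {
    stop("no phenotype record for individual(s): ",
         paste(utils::head(missing_ids, 10), collapse = ", "),
         if (length(missing_ids) > 10) " ...")
  }
  ph <- phenotypes[match(individual_ids, phenotypes$individual_id), ]
  cls <- assign_class(ph$age, ph$died, cfg)
  names(cls) <- individual_ids
  keep <- cls != "excluded"
  labels <- as.integer(cls[keep] == "case")
  names(labels) <- individual_ids[keep]
  summ <- data.frame(class = c("case", "control"),
                     N = c(sum(labels == 1), sum(labels == 0)))
  if (!is.null(covariates)) {
    cv <- covariates[match(names(labels), covariates$individual_id), ]
    by_sex <- function(lab, sex) {
      sel <- labels == lab & cv$sex == sex
      c(N = sum(sel),
        pct_education = 100 * mean(cv$education[sel]),
        pct_smoking = 100 * mean(cv$smoking[sel]))
    }
    summ <- rbind(
      data.frame(sex = "male", class = c("case", "control"),
                 t(sapply(1:0, function(l) by_sex(l, 0)))),
      data.frame(sex = "female", class = c("case", "control"),
                 t(sapply(1:0, function(l) by_sex(l, 1)))),
      data.frame(sex = "total", class = c("case", "control"),
                 t(sapply(1:0, function(l) {
                   sel <- labels == l
                   c(N = sum(sel),
                     pct_education = 100 * mean(cv$education[sel]),
                     pct_smoking = 100 * mean(cv$smoking[sel]))
                 }))))
  }
  structure(list(labels = labels, class = cls,
                 excluded = individual_ids[!keep], summary = summ),
            class = "survival_cohort")
}

#' @export
print.survival_cohort <- function(x, ...) {
  cat("Survival-trait cohort:", sum(x$labels == 1), "cases,",
      sum(x$labels == 0), "controls,", length(x$excluded), "excluded\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
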