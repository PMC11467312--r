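#' Cohort tables
#'
#' A cohort table describes the subjects of a two-group stroke study: one row
#' per subject with age (years), sex, lesion age (weeks since stroke onset),
#' lesion volume (mm^3, possibly missing), stroke type (I = ischemic,
#' H = hemorrhagic) and group (subacute vs chronic). Subjects are conventionally
#' classed as subacute when the lesion is younger than 26 weeks (6 months).
#'
#' @name cohort
NULL

# lesion-age threshold (weeks) separating subacute from chronic
SUBACUTE_THRESHOLD_WEEKS <- 26

#' Load the bundled reference cohort
#'
#' Returns the 27-subject post-stroke aphasia cohort shipped with the package
#' (13 subacute, 14 chronic; lesion volume missing for 5 subjects). Group
#' labels are preserved exactly as published, including subject 25 whose
#' 25-week lesion age carries a chronic label.
#'
#' @return A `cohort_table` data frame with columns `id`, `age`, `sex`,
#'   `lesion_age_weeks`, `lesion_volume_mm3`, `stroke_type`, `group`.
#' @examples
#' coh <- load_reference_cohort()
#' table(coh$group)
#' @export
load_reference_cohort <- function() {
  path <- system.file("extdata", "reference_cohort.csv", package = "ciplvnet",
                      mustWork = TRUE)
  read_cohort_csv(path)
}

#' Read / write cohort CSV
#'
#' The cohort CSV has a fixed header: id, age, sex, lesion_age_weeks,
#' lesion_volume_mm3, stroke_type, group. Missing lesion volumes are `NA`.
#'
#' @param path file path
#' @return `read_cohort_csv`: a `cohort_table` data frame.
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_cohort(df)
}

#' @rdname read_cohort_csv
#' @param cohort a cohort table
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_cohort <- function(df) {
  need <- c("id", "age", "sex", "lesion_age_weeks", "lesion_volume_mm3",
            "stroke_type", "group")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("cohort table missing columns: ",
                         paste(miss, collapse = ", "))
  stopifnot(all(df$sex %in% c("M", "F")),
            all(df$stroke_type %in% c("I", "H")),
            all(df$group %in% c("subacute", "chronic")),
            all(df$lesion_age_weeks > 0))
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Specification for a synthetic cohort
#'
#' @param n_subacute,n_chronic group sizes (>= 1)
#' @param age_range min/max age in years, sampled uniformly (integer years)
#' @param lesion_age_subacute,lesion_age_chronic min/max lesion age in weeks for
#'   each group, sampled uniformly; subacute values must stay below 26 weeks and
#'   chronic values at or above it, since generated group labels are derived
#'   from the lesion age
#' @param volume_meanlog,volume_sdlog log-normal parameters for lesion volume
#'   (mm^3)
#' @param p_female probability of female sex
#' @param p_missing_volume probability that a subject's volume is missing
#' @return a `cohort_spec` list
#' @export
cohort_spec <- function(n_subacute = 13, n_chronic = 14,
                        age_range = c(40, 78),
                        lesion_age_subacute = c(2, 24),
                        lesion_age_chronic = c(26, 200),
                        volume_meanlog = 11, volume_sdlog = 0.8,
                        p_female = 0.33, p_missing_volume = 0.2) {
  if (n_subacute < 1 || n_chronic < 1) stop("group sizes must be >= 1")
  if (diff(age_range) < 0 || diff(lesion_age_subacute) < 0 ||
      diff(lesion_age_chronic) < 0) stop("ranges must be increasing")
  if (lesion_age_subacute[2] >= SUBACUTE_THRESHOLD_WEEKS)
    stop("subacute lesion ages must be < ", SUBACUTE_THRESHOLD_WEEKS, " weeks")
  if (lesion_age_chronic[1] < SUBACUTE_THRESHOLD_WEEKS)
    stop("chronic lesion ages must be >= ", SUBACUTE_THRESHOLD_WEEKS, " weeks")
  if (p_female < 0 || p_female > 1 || p_missing_volume < 0 ||
      p_missing_volume > 1) stop("probabilities must be in [0, 1]")
  structure(as.list(environment()), class = "cohort_spec")
}

#' Generate a synthetic cohort table
#'
#' Lesion ages are drawn from the per-group uniform distributions of the spec;
#' the group label is then derived from the 26-week threshold (so generated
#' tables always satisfy the subacute-iff-under-26-weeks invariant).
#'
#' @param spec a [cohort_spec()]
#' @param seed integer seed; the same spec and seed give an identical table
#' @return a `cohort_table` data frame
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = 1) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_subacute + spec$n_chronic
  rng <- local_rng(seed)
  la <- c(stats::runif(spec$n_subacute, spec$lesion_age_subacute[1],
                       spec$lesion_age_subacute[2]),
          stats::runif(spec$n_chronic, spec$lesion_age_chronic[1],
                       spec$lesion_age_chronic[2]))
  vol <- round(stats::rlnorm(n, spec$volume_meanlog, spec$volume_sdlog))
  vol[stats::runif(n) < spec$p_missing_volume] <- NA
  df <- data.frame(
    id = seq_len(n),
    age = round(stats::runif(n, spec$age_range[1], spec$age_range[2])),
    sex = ifelse(stats::runif(n) < spec$p_female, "F", "M"),
    lesion_age_weeks = round(la, 1),
    lesion_volume_mm3 = vol,
    stroke_type = ifelse(stats::runif(n) < 0.12, "H", "I"),
    group = ifelse(la < SUBACUTE_THRESHOLD_WEEKS, "subacute", "chronic"),
    stringsAsFactors = FALSE
  )
  validate_cohort(df)
}

# Seed the RNG for a generator call. Seeds must be kept below 2^31 - 1;
# derived sub-seeds are folded back into range.
local_rng <- function(seed) {
  seed <- as.numeric(seed) %% 2147483647
  set.seed(as.integer(seed))
  invisible(seed)
}
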