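#' Anthropometric reference used by the cohort generator
#'
#' Age- and sex-conditional normal distributions for height (m) and body mass
#' (kg) of 3- to 5-year-old children, with means/SDs rounded from growth
#' reference charts for this age band. The study population reports only the
#' age and sex distribution, so these defaults exist to give the generator
#' plausible covariates for the Schofield resting-EE prediction; they are not
#' fitted to any particular sample.
#'
#' @return a data.frame with columns `age`, `sex`, `height_mean`, `height_sd`,
#'   `mass_mean`, `mass_sd`.
#' @export
anthropometry_defaults <- function() {
  ref <- expand.grid(age = 3:5, sex = c("male", "female"),
                     stringsAsFactors = FALSE)
  hm <- c("3.male" = 0.96, "4.male" = 1.03, "5.male" = 1.10,
          "3.female" = 0.95, "4.female" = 1.02, "5.female" = 1.09)
  mm <- c("3.male" = 14.3, "4.male" = 16.3, "5.male" = 18.3,
          "3.female" = 13.9, "4.female" = 15.9, "5.female" = 17.9)
  key <- paste(ref$age, ref$sex, sep = ".")
  ref$height_mean <- unname(hm[key])
  ref$height_sd <- 0.04
  ref$mass_mean <- unname(mm[key])
  ref$mass_sd <- 1.8
  ref
}

#' Generate a synthetic cohort of preschool-aged participants
#'
#' Ages are drawn from `age_mix` over {3, 4, 5} years (default mirrors the
#' study sample: 36% / 28% / 36%), sex from `p_male`, and height/mass from the
#' age- and sex-conditional normals in [anthropometry_defaults()]. Output is a
#' pure function of `seed`.
#'
#' @param n number of participants (>= 1).
#' @param seed integer seed.
#' @param age_mix length-3 proportions for ages 3, 4, 5; must sum to 1.
#' @param p_male probability of male sex (study sample: 20 of 25).
#' @return a data.frame with columns `id`, `age`, `sex`, `height_m`, `mass_kg`.
#' @export
make_cohort <- function(n, seed = 1L, age_mix = c(0.36, 0.28, 0.36),
                        p_male = 0.8) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("`n` must be a positive count")
  n <- as.integer(n)
  if (length(age_mix) != 3L || abs(sum(age_mix) - 1) > 1e-6)
    stop("`age_mix` must be 3 proportions summing to 1")
  ref <- anthropometry_defaults()
  with_seed(seed, {
    age <- sample(3:5, n, replace = TRUE, prob = age_mix)
    sex <- ifelse(stats::runif(n) < p_male, "male", "female")
    idx <- match(paste(age, sex, sep = "."), paste(ref$age, ref$sex, sep = "."))
    height <- stats::rnorm(n, ref$height_mean[idx], ref$height_sd[idx])
    mass <- stats::rnorm(n, ref$mass_mean[idx], ref$mass_sd[idx])
    # truncate to physically sensible support
    height <- pmax(height, 0.80)
    mass <- pmax(mass, 10)
    data.frame(id = sprintf("P%03d", seq_len(n)), age = age, sex = sex,
               height_m = height, mass_kg = mass, stringsAsFactors = FALSE)
  })
}

#' Validate a participant record
#' @param p one-row data.frame or list with `age`, `sex`, `height_m`, `mass_kg`.
#' @return invisibly TRUE; errors on invariant violation.
#' @keywords internal
check_participant <- function(p) {
  stopifnot(p$age >= 3, p$age <= 5, p$height_m > 0, p$mass_kg > 0,
            p$sex %in% c("male", "female"))
  invisible(TRUE)
}
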