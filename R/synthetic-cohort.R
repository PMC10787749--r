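#' Settings for the synthetic cohort generator
#'
#' The cohort emulates an early-adult population study: a continuous SES
#' composite (a sum of standardized education / income / occupation /
#' subjective-status indicators, simulated directly as a standardized score),
#' demographic and technical covariates, and the behavioral / physiological
#' mediator columns. Mediators are tied to SES through a Gaussian copula: each
#' mediator's latent score is `rho * ses + sqrt(1 - rho^2) * noise`, so the
#' configured `ses_*_corr` values are the latent correlations (attained
#' exactly for the Gaussian marginals, attenuated for thresholded binary or
#' ordinal mediators).
#'
#' `ses_bmi_corr` doubles as the structural path coefficient SES -> BMI used
#' when counts route part of a gene's SES effect through BMI
#' (see [generate_counts()]), which gives mediation a closed-form truth.
#'
#' @param ses_bmi_corr Latent SES-BMI correlation (structural a-path).
#' @param ses_stress_corr,ses_smoking_corr,ses_alcohol_corr Latent
#'   correlations for perceived stress, smoking, alcohol category.
#' @param ses_finstress_corr,ses_insurance_corr Latent correlations for
#'   financial stress and insurance access.
#' @param bmi_mean,bmi_sd BMI marginal (kg/m^2).
#' @param waist_bmi_corr Latent correlation between waist circumference and
#'   BMI (waist tracks BMI, not SES directly).
#' @param waist_mean,waist_sd Waist circumference marginal (cm).
#' @param age_range Uniform age range in years.
#' @param n_plates,n_batches Number of assay plates / sequencing batches.
#' @param smoking_rate,finstress_rate,insurance_rate Marginal rates of the
#'   binary mediators.
#' @param alcohol_probs Marginal probabilities of the four alcohol categories
#'   ("0", "1-2", "3-5", ">5" drinks per occasion).
#' @return A named list of class `cohort_config`.
#' @export
cohort_config <- function(ses_bmi_corr = -0.3,
                          ses_stress_corr = -0.25,
                          ses_smoking_corr = -0.2,
                          ses_alcohol_corr = 0.1,
                          ses_finstress_corr = -0.35,
                          ses_insurance_corr = 0.3,
                          bmi_mean = 27, bmi_sd = 5,
                          waist_bmi_corr = 0.9,
                          waist_mean = 92, waist_sd = 13,
                          age_range = c(33, 43),
                          n_plates = 8, n_batches = 4,
                          smoking_rate = 0.25,
                          finstress_rate = 0.2,
                          insurance_rate = 0.85,
                          alcohol_probs = c(0.35, 0.3, 0.25, 0.1)) {
  cfg <- as.list(environment())
  for (nm in grep("_corr$", names(cfg), value = TRUE))
    if (abs(cfg[[nm]]) > 1) stop("correlations must lie in [-1, 1]")
  if (abs(sum(alcohol_probs) - 1) > 1e-8 || length(alcohol_probs) != 4L)
    stop("`alcohol_probs` must be 4 probabilities summing to 1")
  structure(cfg, class = "cohort_config")
}

#' Generate a synthetic study cohort
#'
#' Produces a per-sample metadata table with the SES composite exposure,
#' the model covariates (sex, race, age, pregnancy, plate, fasting hours,
#' anti-inflammatory use, recent symptoms and illness), a batch label, and the
#' mediator columns (BMI, waist circumference, perceived stress, smoking,
#' alcohol category, financial stress, insurance). Deterministic given
#' `seed`; `n_samples = 0` yields an empty table with the full schema.
#'
#' @param n_samples Number of samples (>= 0).
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @return A `data.frame` with one row per sample. The structural SES->BMI
#'   coefficient is attached as attribute `ses_bmi_corr`.
#' @export
generate_cohort <- function(n_samples, config = cohort_config(), seed = 1L) {
  if (!is.numeric(n_samples) || length(n_samples) != 1L || n_samples < 0)
    stop("`n_samples` must be a nonnegative integer")
  n <- as.integer(n_samples)
  cfg <- config

  latent <- function(rho, z, n) rho * z + sqrt(1 - rho^2) * rnorm(n)

  tab <- withr::with_seed(as.integer(seed), {
    ses <- rnorm(n)
    z_bmi <- latent(cfg$ses_bmi_corr, ses, n)
    z_waist <- latent(cfg$waist_bmi_corr, z_bmi, n)
    z_stress <- latent(cfg$ses_stress_corr, ses, n)
    z_smoke <- latent(cfg$ses_smoking_corr, ses, n)
    z_alc <- latent(cfg$ses_alcohol_corr, ses, n)
    z_fin <- latent(cfg$ses_finstress_corr, ses, n)
    z_ins <- latent(cfg$ses_insurance_corr, ses, n)

    sex <- sample(c("female", "male"), n, replace = TRUE)
    alc_cuts <- qnorm(cumsum(cfg$alcohol_probs))[1:3]
    alcohol <- cut(z_alc, breaks = c(-Inf, alc_cuts, Inf),
                   labels = c("0", "1-2", "3-5", ">5"), ordered_result = TRUE)
    data.frame(
      sample_id = sprintf("s%04d", seq_len(n)),
      ses = ses,
      sex = sex,
      race = sample(c("white", "black", "hispanic", "other"), n,
                    replace = TRUE, prob = c(0.55, 0.2, 0.17, 0.08)),
      age = round(runif(n, cfg$age_range[1], cfg$age_range[2]), 1),
      pregnancy = ifelse(sex == "female" & runif(n) < 0.04, "yes", "no"),
      anti_inflammatory_use = ifelse(runif(n) < 0.15, "yes", "no"),
      recent_symptoms = ifelse(runif(n) < 0.3, "yes", "no"),
      recent_illness = ifelse(runif(n) < 0.2, "yes", "no"),
      fasting_hours = round(pmin(rgamma(n, shape = 2, scale = 3), 24), 1),
      plate = sprintf("plate%02d", sample.int(cfg$n_plates, n, replace = TRUE)),
      batch = sprintf("batch%d", sample.int(cfg$n_batches, n, replace = TRUE)),
      bmi = cfg$bmi_mean + cfg$bmi_sd * z_bmi,
      waist = cfg$waist_mean + cfg$waist_sd * z_waist,
      perceived_stress = pmin(pmax(round(16 + 6 * z_stress), 0), 40),
      smoking = as.integer(z_smoke > qnorm(1 - cfg$smoking_rate)),
      alcohol = alcohol,
      financial_stress = as.integer(z_fin > qnorm(1 - cfg$finstress_rate)),
      insurance = as.integer(z_ins > qnorm(1 - cfg$insurance_rate)),
      stringsAsFactors = FALSE
    )
  })
  if (n == 0L) tab <- tab[integer(0), , drop = FALSE]
  stopifnot(!anyNA(tab))
  attr(tab, "ses_bmi_corr") <- cfg$ses_bmi_corr
  tab
}
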