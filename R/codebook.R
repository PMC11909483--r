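#' Baseline covariate codebook
#'
#' Fixed schema for the baseline covariates produced by the synthetic trial
#' generator and consumed by the compliance prediction model. Covariates span
#' the 11 baseline domains assessed in web-CBT trials of this design
#' (sociodemographics, university factors, stressors, anxiety/depression
#' characteristics, comorbid disorders, treatment, physical health, social
#' networks, personality/resilience, internet preferences). A versioned,
#' stable codebook keeps attribution output (feature names, domain tags)
#' reproducible across runs.
#'
#' @return A data.frame with columns \code{name}, \code{type}
#'   (\code{"binary"}, \code{"ordinal"}, \code{"continuous"},
#'   \code{"categorical"}), \code{min}, \code{max}, \code{domain}, and
#'   \code{compliance_weight} (the generator's loading of the covariate on
#'   the latent compliance propensity; 0 for covariates that carry no
#'   signal).
#' @export
covariate_codebook <- function() {
  cb <- rbind(
    data.frame(name = "employed",            type = "binary",  min = 0, max = 1,  domain = "sociodemographics",  compliance_weight = -1.0),
    data.frame(name = "first_generation",    type = "binary",  min = 0, max = 1,  domain = "sociodemographics",  compliance_weight = 0),
    data.frame(name = "female",              type = "binary",  min = 0, max = 1,  domain = "sociodemographics",  compliance_weight = 0),
    data.frame(name = "age_20",              type = "binary",  min = 0, max = 1,  domain = "sociodemographics",  compliance_weight = 0),
    data.frame(name = "age_21_22",           type = "binary",  min = 0, max = 1,  domain = "sociodemographics",  compliance_weight = 0),
    data.frame(name = "age_23_plus",         type = "binary",  min = 0, max = 1,  domain = "sociodemographics",  compliance_weight = 0),
    data.frame(name = "country_mexico",      type = "binary",  min = 0, max = 1,  domain = "university",         compliance_weight = 0),
    data.frame(name = "univ_unam",           type = "binary",  min = 0, max = 1,  domain = "university",         compliance_weight = 0.8),
    data.frame(name = "clinic_waitlist",     type = "binary",  min = 0, max = 1,  domain = "university",         compliance_weight = 0),
    data.frame(name = "clinic_campus",       type = "binary",  min = 0, max = 1,  domain = "university",         compliance_weight = 0),
    data.frame(name = "covid_stress",        type = "ordinal", min = 0, max = 10, domain = "covid_stressors",    compliance_weight = 0),
    data.frame(name = "chronic_stress",      type = "ordinal", min = 0, max = 10, domain = "other_stressors",    compliance_weight = -0.4),
    data.frame(name = "sexual_assault",      type = "binary",  min = 0, max = 1,  domain = "other_stressors",    compliance_weight = 0.7),
    data.frame(name = "mde_months",          type = "ordinal", min = 0, max = 12, domain = "anxiety_depression", compliance_weight = 0.6),
    data.frame(name = "high_baseline",       type = "binary",  min = 0, max = 1,  domain = "anxiety_depression", compliance_weight = -0.7),
    data.frame(name = "work_impairment",     type = "ordinal", min = 0, max = 10, domain = "comorbidity",        compliance_weight = 1.0),
    data.frame(name = "sad_situational",     type = "ordinal", min = 0, max = 16, domain = "comorbidity",        compliance_weight = 0.9),
    data.frame(name = "phobia_history",      type = "binary",  min = 0, max = 1,  domain = "comorbidity",        compliance_weight = -0.6),
    data.frame(name = "prior_treatment",     type = "binary",  min = 0, max = 1,  domain = "treatment",          compliance_weight = 0),
    data.frame(name = "role_home",           type = "ordinal", min = 0, max = 10, domain = "physical_health",    compliance_weight = 0.8),
    data.frame(name = "role_relationships",  type = "ordinal", min = 0, max = 10, domain = "physical_health",    compliance_weight = 0.7),
    data.frame(name = "underweight",         type = "binary",  min = 0, max = 1,  domain = "physical_health",    compliance_weight = 0.4),
    data.frame(name = "loneliness",          type = "ordinal", min = 0, max = 16, domain = "social_networks",    compliance_weight = 0.6),
    data.frame(name = "confidants",          type = "ordinal", min = 0, max = 10, domain = "social_networks",    compliance_weight = 0.5),
    data.frame(name = "irritability",        type = "ordinal", min = 0, max = 10, domain = "personality",        compliance_weight = -0.5),
    data.frame(name = "resilience",          type = "ordinal", min = 0, max = 10, domain = "personality",        compliance_weight = 0),
    data.frame(name = "helpful_reminders",   type = "ordinal", min = 0, max = 3,  domain = "internet_preferences", compliance_weight = 0.8),
    data.frame(name = "helpful_texting",     type = "ordinal", min = 0, max = 3,  domain = "internet_preferences", compliance_weight = 0.7),
    data.frame(name = "desire_stress",       type = "ordinal", min = 0, max = 3,  domain = "internet_preferences", compliance_weight = -0.5),
    data.frame(name = "desire_sleep",        type = "ordinal", min = 0, max = 3,  domain = "internet_preferences", compliance_weight = -0.4)
  )
  attr(cb, "codebook_version") <- "1.0"
  cb
}

#' Names of the numeric covariate columns the codebook declares
#'
#' @return Character vector of covariate names, in codebook order.
#' @export
codebook_names <- function() covariate_codebook()$name
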