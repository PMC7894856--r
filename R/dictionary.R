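#' Build a mixed-type clinical feature dictionary
#'
#' Defines the variable catalogue a synthetic high-risk cohort is generated
#' from: ~119 features spanning seven domains (sociodemographic, comorbidity,
#' psychobehavioral, pharmacy, vitals, labs, utilization) with per-feature
#' marginal parameters. Named clinical features carry typical prevalences and
#' measurement scales for a high-risk primary-care population; generic filler
#' features draw Bernoulli prevalences uniformly from [0.05, 0.5], Poisson
#' rates from [0.5, 5], and standard-normal continuous marginals. The
#' catalogue deliberately plants two near-duplicate measurement pairs
#' (weight/BMI, eGFR/creatinine) and two near-constant flags so that
#' correlation and low-variance pruning have realistic work to do.
#'
#' @param n_features total number of features (at least the named set;
#'   \code{NULL} emits the named set only).
#' @param seed integer seed controlling the generic-feature marginals.
#' @return a data.frame with one row per feature: \code{name}, \code{domain},
#'   \code{type} (binary/count/continuous), marginal parameters (\code{p},
#'   \code{lambda}, \code{mu}, \code{sigma}) and a \code{special} column
#'   marking derived features (\code{dup}, \code{derived_sum},
#'   \code{adherence}) with \code{parent}/\code{parent_r} where relevant.
#' @export
feature_dictionary <- function(n_features = 119L, seed = 20140101L) {
  f <- function(name, domain, type, p = NA, lambda = NA, mu = NA, sigma = NA,
                special = "", parent = NA, parent_r = NA) {
    data.frame(name = name, domain = domain, type = type, p = p,
               lambda = lambda, mu = mu, sigma = sigma, special = special,
               parent = parent, parent_r = parent_r,
               stringsAsFactors = FALSE)
  }
  rows <- list(
    # sociodemographic / insurance
    f("age", "sociodemographic", "continuous", mu = 64.7, sigma = 14.1),
    f("female", "sociodemographic", "binary", p = 0.071),
    f("race_black", "sociodemographic", "binary", p = 0.205),
    f("race_hispanic", "sociodemographic", "binary", p = 0.02),
    f("race_other", "sociodemographic", "binary", p = 0.077),
    f("medicaid", "sociodemographic", "binary", p = 0.014),
    f("married", "sociodemographic", "binary", p = 0.35),
    f("rural", "sociodemographic", "binary", p = 0.30),
    f("homeless", "sociodemographic", "binary", p = 0.03),
    f("priority_group", "sociodemographic", "count", lambda = 3),
    f("service_connected", "sociodemographic", "binary", p = 0.35),
    f("copay_exempt", "sociodemographic", "binary", p = 0.25),
    f("va_pension", "sociodemographic", "binary", p = 0.08),
    f("english_primary", "sociodemographic", "binary", p = 0.93),
    f("employed", "sociodemographic", "binary", p = 0.25),
    f("distance_to_facility", "sociodemographic", "continuous",
      mu = 15, sigma = 12),
    # comorbidity flags (Elixhauser-style) + burden count
    f("chf", "comorbidity", "binary", p = 0.103),
    f("arrhythmia", "comorbidity", "binary", p = 0.12),
    f("valvular", "comorbidity", "binary", p = 0.04),
    f("pulm_circ", "comorbidity", "binary", p = 0.02),
    f("pvd", "comorbidity", "binary", p = 0.09),
    f("htn_uncomp", "comorbidity", "binary", p = 0.45),
    f("paralysis", "comorbidity", "binary", p = 0.02),
    f("neuro_other", "comorbidity", "binary", p = 0.07),
    f("copd", "comorbidity", "binary", p = 0.267),
    f("dm_uncomp", "comorbidity", "binary", p = 0.369),
    f("dm_comp", "comorbidity", "binary", p = 0.134),
    f("hypothyroid", "comorbidity", "binary", p = 0.11),
    f("renal_failure", "comorbidity", "binary", p = 0.08),
    f("liver_disease", "comorbidity", "binary", p = 0.06),
    f("pud", "comorbidity", "binary", p = 0.025),
    f("hiv_aids", "comorbidity", "binary", p = 0.012),
    f("lymphoma", "comorbidity", "binary", p = 0.012),
    f("metastatic_cancer", "comorbidity", "binary", p = 0.015),
    f("solid_tumor", "comorbidity", "binary", p = 0.05),
    f("rheumatoid", "comorbidity", "binary", p = 0.025),
    f("coagulopathy", "comorbidity", "binary", p = 0.04),
    f("obesity", "comorbidity", "binary", p = 0.17),
    f("weight_loss", "comorbidity", "binary", p = 0.05),
    f("blood_loss_anemia", "comorbidity", "binary", p = 0.012),
    f("elix_count", "comorbidity", "count", special = "derived_sum"),
    # psychobehavioral
    f("depression", "psychobehavioral", "binary", p = 0.408),
    f("psychoses", "psychobehavioral", "binary", p = 0.04),
    f("drug_abuse", "psychobehavioral", "binary", p = 0.105),
    f("alcohol_abuse", "psychobehavioral", "binary", p = 0.12),
    f("ptsd", "psychobehavioral", "binary", p = 0.20),
    f("anxiety", "psychobehavioral", "binary", p = 0.15),
    f("smoking", "psychobehavioral", "binary", p = 0.35),
    f("suicide_risk", "psychobehavioral", "binary", p = 0.03),
    f("psych_visits", "psychobehavioral", "count", lambda = 1.2),
    f("mh_inpatient", "psychobehavioral", "binary", p = 0.05),
    # pharmacy
    f("any_med", "pharmacy", "binary", p = 0.927),
    f("antihypertensive", "pharmacy", "binary", p = 0.62),
    f("antidepressant", "pharmacy", "binary", p = 0.407),
    f("glucose_lowering", "pharmacy", "binary", p = 0.284),
    f("opioid_rx", "pharmacy", "binary", p = 0.25),
    f("sedative_rx", "pharmacy", "binary", p = 0.12),
    f("statin", "pharmacy", "binary", p = 0.48),
    f("anticoagulant", "pharmacy", "binary", p = 0.12),
    f("antipsychotic_rx", "pharmacy", "binary", p = 0.07),
    f("inhaler_rx", "pharmacy", "binary", p = 0.15),
    f("n_active_meds", "pharmacy", "count", lambda = 5),
    f("pdc_weighted", "pharmacy", "continuous", special = "adherence"),
    f("pdc_antihypertensive", "pharmacy", "continuous", special = "adherence"),
    f("pdc_statin", "pharmacy", "continuous", special = "adherence"),
    # vitals
    f("sbp", "vitals", "continuous", mu = 132.8, sigma = 15.1),
    f("dbp", "vitals", "continuous", mu = 76.4, sigma = 9.5),
    f("bmi", "vitals", "continuous", mu = 29.9, sigma = 6.4),
    f("weight_kg", "vitals", "continuous", mu = 92, sigma = 19,
      special = "dup", parent = "bmi", parent_r = 0.92),
    f("pulse", "vitals", "continuous", mu = 78, sigma = 11),
    f("resp_rate", "vitals", "continuous", mu = 17, sigma = 2.5),
    f("temp_c", "vitals", "continuous", mu = 36.8, sigma = 0.4),
    f("pain_score", "vitals", "continuous", mu = 2.5, sigma = 2.2),
    # labs
    f("albumin", "labs", "continuous", mu = 3.93, sigma = 0.41),
    f("creatinine", "labs", "continuous", mu = 1.11, sigma = 0.42),
    f("egfr", "labs", "continuous", mu = 72, sigma = 21,
      special = "dup", parent = "creatinine", parent_r = -0.90),
    f("a1c", "labs", "continuous", mu = 6.62, sigma = 1.41),
    f("glucose", "labs", "continuous", mu = 118, sigma = 38),
    f("hemoglobin", "labs", "continuous", mu = 13.8, sigma = 1.8),
    f("wbc", "labs", "continuous", mu = 7.6, sigma = 2.3),
    f("platelets", "labs", "continuous", mu = 235, sigma = 68),
    f("sodium", "labs", "continuous", mu = 139, sigma = 3),
    f("potassium", "labs", "continuous", mu = 4.2, sigma = 0.45),
    f("bilirubin", "labs", "continuous", mu = 0.7, sigma = 0.5),
    f("ast", "labs", "continuous", mu = 28, sigma = 16),
    f("alt", "labs", "continuous", mu = 26, sigma = 17),
    f("inr", "labs", "continuous", mu = 1.1, sigma = 0.4),
    f("ldl", "labs", "continuous", mu = 102, sigma = 33),
    f("tsh", "labs", "continuous", mu = 2.3, sigma = 1.6),
    # prior utilization
    f("outpatient_visits", "utilization", "count", lambda = 12),
    f("primary_care_visits", "utilization", "count", lambda = 4),
    f("specialty_visits", "utilization", "count", lambda = 5),
    f("ed_visits_prior", "utilization", "count", lambda = 0.8),
    f("inpatient_admits", "utilization", "count", lambda = 0.3),
    f("inpatient_days_prior", "utilization", "count", lambda = 1.0),
    f("surgery_admits", "utilization", "count", lambda = 0.08),
    f("homebased_visits", "utilization", "count", lambda = 0.15),
    f("phone_visits", "utilization", "count", lambda = 2.5),
    f("no_shows", "utilization", "count", lambda = 1.5),
    f("nursing_home", "utilization", "binary", p = 0.02),
    f("rare_flag_1", "utilization", "binary", p = 0.003)
  )
  dict <- do.call(rbind, rows)
  n_named <- nrow(dict)
  if (is.null(n_features)) n_features <- n_named
  if (n_features < n_named)
    stop_config("n_features must be >= %d (the named clinical set)", n_named)
  n_extra <- n_features - n_named
  if (n_extra > 0L) {
    extra_domains <- rep(c("labs", "vitals", "utilization"),
                         length.out = n_extra)
    extra_types <- rep(c("continuous", "binary", "count"),
                       length.out = n_extra)
    pars <- with_seed(seed, list(p = runif(n_extra, 0.05, 0.5),
                                 lambda = runif(n_extra, 0.5, 5)))
    extra <- do.call(rbind, lapply(seq_len(n_extra), function(i) {
      nm <- sprintf("nuisance_%02d", i)
      switch(extra_types[i],
        continuous = f(nm, extra_domains[i], "continuous", mu = 0, sigma = 1),
        binary = f(nm, extra_domains[i], "binary", p = pars$p[i]),
        count = f(nm, extra_domains[i], "count", lambda = pars$lambda[i]))
    }))
    # one more near-constant flag so low-variance pruning sees >1 victim
    extra$p[extra$type == "binary"][1] <- 0.004
    dict <- rbind(dict, extra)
  }
  rownames(dict) <- NULL
  dict
}
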