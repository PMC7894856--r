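#' Specify planted subgroup structure for a synthetic cohort
#'
#' A planted structure declares, for each synthetic subgroup, a signature —
#' the set of features whose distribution is shifted for its members — plus
#' subgroup sizes, a background fraction of patients who belong to no
#' subgroup, per-subgroup two-year outcome models, and per-subgroup
#' medication-adherence targets. Continuous and count signature effects are
#' in standardized units (mean shift in baseline SDs); binary effects are
#' additive prevalence shifts.
#'
#' @param subgroup_sizes named integer vector of subgroup sizes.
#' @param signatures data.frame with columns \code{subgroup}, \code{feature},
#'   \code{effect}; feature names must exist in \code{dictionary}.
#' @param background_fraction proportion of the cohort in no subgroup,
#'   in [0, 1).
#' @param outcome_model data.frame with columns \code{subgroup} (including a
#'   \code{"background"} row), \code{p_mortality}, \code{mean_ip_days},
#'   \code{mean_ed_visits}.
#' @param dictionary feature dictionary from [feature_dictionary()].
#' @param adherence named numeric vector of PDC targets in [0, 1] per
#'   subgroup (plus \code{"background"}).
#' @param categories named character vector: the true domain category of each
#'   subgroup (comorbidity / sociodemographic / psychobehavioral).
#' @param seed integer seed used by [generate_cohort()] unless overridden.
#' @param high_risk_threshold minimum risk percentile of emitted patients.
#' @return an object of class \code{planted_structure}.
#' @export
planted_structure <- function(subgroup_sizes, signatures, background_fraction,
                              outcome_model, dictionary,
                              adherence = NULL, categories = NULL,
                              seed = 1L, high_risk_threshold = 75L) {
  if (is.null(names(subgroup_sizes)))
    names(subgroup_sizes) <- paste0("subgroup_", seq_along(subgroup_sizes))
  if (any(subgroup_sizes <= 0)) stop_config("subgroup sizes must be positive")
  if (background_fraction < 0 || background_fraction >= 1)
    stop_config("background_fraction must be in [0, 1)")
  missing_feat <- setdiff(signatures$feature, dictionary$name)
  if (length(missing_feat))
    stop_config("signature features absent from dictionary: %s",
                paste(missing_feat, collapse = ", "))
  missing_grp <- setdiff(signatures$subgroup, names(subgroup_sizes))
  if (length(missing_grp))
    stop_config("signatures reference unknown subgroups: %s",
                paste(missing_grp, collapse = ", "))
  need <- c(names(subgroup_sizes), "background")
  if (!all(need %in% outcome_model$subgroup))
    stop_config("outcome_model must cover every subgroup and 'background'")
  signatures$domain <- dictionary$domain[match(signatures$feature,
                                               dictionary$name)]
  if (is.null(adherence))
    adherence <- stats::setNames(rep(0.77, length(need)), need)
  structure(
    list(n_subgroups = length(subgroup_sizes),
         subgroup_sizes = subgroup_sizes,
         signatures = signatures,
         background_fraction = background_fraction,
         outcome_model = outcome_model,
         adherence = adherence,
         categories = categories,
         dictionary = dictionary,
         seed = as.integer(seed),
         high_risk_threshold = as.integer(high_risk_threshold)),
    class = "planted_structure")
}

#' @export
print.planted_structure <- function(x, ...) {
  cat(sprintf("planted_structure: %d subgroups (n = %d) + %.0f%% background\n",
              x$n_subgroups, sum(x$subgroup_sizes),
              100 * x$background_fraction))
  cat(sprintf("  signature features: %d across %d domains\n",
              length(unique(x$signatures$feature)),
              length(unique(x$signatures$domain))))
  invisible(x)
}

#' Reference planted structure: twelve subgroups of high-risk patients
#'
#' The package's canonical validation scenario: a cohort of high-risk
#' patients containing twelve planted subgroups (sizes 30 to 600, summing to
#' 75\% of the cohort) plus 25\% background patients. Subgroups mirror the
#' kinds of clusters seen in high-risk EHR populations: nine driven by
#' clinical signatures (defining diagnoses with their associated labs,
#' vitals, pharmacy and utilization shifts), two driven purely by
#' psychobehavioral features, and three purely by sociodemographic features.
#' Defining diagnosis flags reach ~95\% in-group prevalence, associated
#' continuous measures shift by 1.5-3 baseline SDs, and each subgroup has a
#' distinct two-year outcome model (mortality 1\%-45\%).
#'
#' @param seed integer seed stored in the structure.
#' @param n_features number of dictionary features (default 119).
#' @param n_total intended cohort size; subgroup sizes are apportioned
#'   proportionally (largest-remainder) so that subgroup members total
#'   75\% of the cohort.
#' @return a \code{planted_structure}; generate with
#'   \code{generate_cohort(st, n_total)} for the intended 25\%
#'   background fraction.
#' @export
study_structure <- function(seed = 20140101L, n_features = 119L,
                            n_total = 3000L) {
  dict <- feature_dictionary(n_features = n_features,
                             seed = derive_seeds(seed, 1L))
  p_of <- function(f) dict$p[dict$name == f]
  sig <- function(subgroup, feature, target = NULL, d = NULL) {
    effect <- if (!is.null(target)) target - p_of(feature) else d
    data.frame(subgroup = subgroup, feature = feature, effect = effect,
               stringsAsFactors = FALSE)
  }
  sizes_ref <- c(insulin_dependent_diabetes = 600L, metastatic_cancer = 240L,
                 chronic_renal_disease = 230L, chronic_liver_disease = 200L,
                 heart_failure = 170L, chronic_pulmonary_disease = 160L,
                 psychoses = 120L, polysubstance_use = 160L,
                 medicaid_predominant = 90L, female_predominant = 150L,
                 hispanic_predominant = 100L, post_surgical = 30L)
  sizes <- stats::setNames(largest_remainder(sizes_ref,
                                             round(0.75 * n_total)),
                           names(sizes_ref))
  signatures <- rbind(
    # uncontrolled, insulin-managed diabetes: both diabetes flags, poor
    # glycemic labs, a heavy medication burden
    sig("insulin_dependent_diabetes", "dm_comp", target = 0.95),
    sig("insulin_dependent_diabetes", "dm_uncomp", target = 0.95),
    sig("insulin_dependent_diabetes", "glucose_lowering", target = 0.97),
    sig("insulin_dependent_diabetes", "a1c", d = 3.5),
    sig("insulin_dependent_diabetes", "glucose", d = 3.0),
    sig("insulin_dependent_diabetes", "n_active_meds", d = 1.5),
    sig("insulin_dependent_diabetes", "obesity", target = 0.60),
    sig("insulin_dependent_diabetes", "bmi", d = 1.5),
    sig("insulin_dependent_diabetes", "statin", target = 0.90),
    sig("insulin_dependent_diabetes", "pvd", target = 0.45),
    sig("insulin_dependent_diabetes", "neuro_other", target = 0.40),
    sig("insulin_dependent_diabetes", "ldl", d = 1.0),
    sig("insulin_dependent_diabetes", "primary_care_visits", d = 1.5),

    # advanced cancer: defining flags, cachexia labs, heavy utilization
    sig("metastatic_cancer", "metastatic_cancer", target = 0.95),
    sig("metastatic_cancer", "solid_tumor", target = 0.90),
    sig("metastatic_cancer", "weight_loss", target = 0.90),
    sig("metastatic_cancer", "albumin", d = -3.0),
    sig("metastatic_cancer", "hemoglobin", d = -2.0),
    sig("metastatic_cancer", "inpatient_admits", d = 2.5),
    sig("metastatic_cancer", "inpatient_days_prior", d = 2.5),
    sig("metastatic_cancer", "specialty_visits", d = 2.5),
    sig("metastatic_cancer", "ed_visits_prior", d = 1.5),
    sig("metastatic_cancer", "age", d = 0.8),

    sig("chronic_renal_disease", "renal_failure", target = 0.95),
    sig("chronic_renal_disease", "creatinine", d = 4.0),
    sig("chronic_renal_disease", "potassium", d = 2.0),
    sig("chronic_renal_disease", "sodium", d = -1.2),
    sig("chronic_renal_disease", "hemoglobin", d = -1.5),
    sig("chronic_renal_disease", "albumin", d = -1.0),
    sig("chronic_renal_disease", "htn_uncomp", target = 0.90),
    sig("chronic_renal_disease", "dm_comp", target = 0.50),
    sig("chronic_renal_disease", "n_active_meds", d = 1.5),
    sig("chronic_renal_disease", "specialty_visits", d = 2.0),
    sig("chronic_renal_disease", "ed_visits_prior", d = 1.0),
    sig("chronic_renal_disease", "inpatient_admits", d = 1.0),

    sig("chronic_liver_disease", "liver_disease", target = 0.95),
    sig("chronic_liver_disease", "bilirubin", d = 3.0),
    sig("chronic_liver_disease", "ast", d = 2.5),
    sig("chronic_liver_disease", "alt", d = 2.0),
    sig("chronic_liver_disease", "inr", d = 2.0),
    sig("chronic_liver_disease", "platelets", d = -2.0),
    sig("chronic_liver_disease", "albumin", d = -1.5),
    sig("chronic_liver_disease", "alcohol_abuse", target = 0.60),
    sig("chronic_liver_disease", "coagulopathy", target = 0.50),
    sig("chronic_liver_disease", "ed_visits_prior", d = 1.0),

    sig("heart_failure", "chf", target = 0.97),
    sig("heart_failure", "arrhythmia", target = 0.90),
    sig("heart_failure", "valvular", target = 0.50),
    sig("heart_failure", "pulm_circ", target = 0.40),
    sig("heart_failure", "anticoagulant", target = 0.90),
    sig("heart_failure", "sbp", d = -2.0),
    sig("heart_failure", "pulse", d = 1.5),
    sig("heart_failure", "age", d = 1.0),
    sig("heart_failure", "hemoglobin", d = -1.0),
    sig("heart_failure", "inpatient_days_prior", d = 2.5),
    sig("heart_failure", "inpatient_admits", d = 2.0),
    sig("heart_failure", "ed_visits_prior", d = 1.5),
    sig("heart_failure", "n_active_meds", d = 2.0),

    sig("chronic_pulmonary_disease", "copd", target = 0.97),
    sig("chronic_pulmonary_disease", "inhaler_rx", target = 0.97),
    sig("chronic_pulmonary_disease", "smoking", target = 0.90),
    sig("chronic_pulmonary_disease", "resp_rate", d = 3.0),
    sig("chronic_pulmonary_disease", "pulse", d = 1.5),
    sig("chronic_pulmonary_disease", "ed_visits_prior", d = 2.0),
    sig("chronic_pulmonary_disease", "weight_loss", target = 0.40),
    sig("chronic_pulmonary_disease", "wbc", d = 1.0),
    sig("chronic_pulmonary_disease", "albumin", d = -1.0),
    sig("chronic_pulmonary_disease", "inpatient_admits", d = 1.5),
    sig("chronic_pulmonary_disease", "n_active_meds", d = 1.5),
    sig("chronic_pulmonary_disease", "outpatient_visits", d = 2.0),

    # defined purely by psychobehavioral features
    sig("psychoses", "psychoses", target = 0.97),
    sig("psychoses", "psych_visits", d = 3.5),
    sig("psychoses", "mh_inpatient", target = 0.90),
    sig("psychoses", "depression", target = 0.97),
    sig("psychoses", "anxiety", target = 0.90),
    sig("psychoses", "suicide_risk", target = 0.25),
    sig("psychoses", "smoking", target = 0.50),

    # defined purely by psychobehavioral features
    sig("polysubstance_use", "drug_abuse", target = 0.97),
    sig("polysubstance_use", "alcohol_abuse", target = 0.95),
    sig("polysubstance_use", "suicide_risk", target = 0.70),
    sig("polysubstance_use", "smoking", target = 0.97),
    sig("polysubstance_use", "ptsd", target = 0.90),
    sig("polysubstance_use", "anxiety", target = 0.80),
    sig("polysubstance_use", "psych_visits", d = 1.0),
    sig("polysubstance_use", "mh_inpatient", target = 0.80),
    sig("polysubstance_use", "depression", target = 0.60),

    # defined purely by sociodemographic features
    sig("medicaid_predominant", "medicaid", target = 0.95),
    sig("medicaid_predominant", "homeless", target = 0.70),
    sig("medicaid_predominant", "priority_group", d = 2.5),
    sig("medicaid_predominant", "age", d = -2.5),
    sig("medicaid_predominant", "female", target = 0.20),
    sig("medicaid_predominant", "married", target = 0.05),
    sig("medicaid_predominant", "copay_exempt", target = 0.97),
    sig("medicaid_predominant", "va_pension", target = 0.35),
    sig("medicaid_predominant", "employed", target = 0.03),
    sig("medicaid_predominant", "rural", target = 0.05),
    sig("medicaid_predominant", "service_connected", target = 0.05),

    sig("female_predominant", "female", target = 0.97),
    sig("female_predominant", "age", d = -3.0),
    sig("female_predominant", "married", target = 0.70),
    sig("female_predominant", "employed", target = 0.55),
    sig("female_predominant", "service_connected", target = 0.90),
    sig("female_predominant", "hemoglobin", d = -2.5),
    sig("female_predominant", "creatinine", d = -1.5),
    sig("female_predominant", "bmi", d = -1.0),
    sig("female_predominant", "ptsd", target = 0.55),
    sig("female_predominant", "anxiety", target = 0.60),
    sig("female_predominant", "depression", target = 0.70),
    sig("female_predominant", "antidepressant", target = 0.75),
    sig("female_predominant", "smoking", target = 0.08),
    sig("female_predominant", "psych_visits", d = 1.2),

    # defined purely by sociodemographic features
    sig("hispanic_predominant", "race_hispanic", target = 0.97),
    sig("hispanic_predominant", "english_primary", target = 0.15),
    sig("hispanic_predominant", "distance_to_facility", d = -0.8),
    sig("hispanic_predominant", "race_black", target = 0.02),
    sig("hispanic_predominant", "race_other", target = 0.60),
    sig("hispanic_predominant", "age", d = -1.5),
    sig("hispanic_predominant", "medicaid", target = 0.15),
    sig("hispanic_predominant", "married", target = 0.60),
    sig("hispanic_predominant", "priority_group", d = 1.5),
    sig("hispanic_predominant", "homeless", target = 0.10),
    sig("hispanic_predominant", "rural", target = 0.08),
    sig("hispanic_predominant", "service_connected", target = 0.15),

    sig("post_surgical", "surgery_admits", d = 4.0),
    sig("post_surgical", "inpatient_days_prior", d = 3.0),
    sig("post_surgical", "inpatient_admits", d = 2.5),
    sig("post_surgical", "wbc", d = 2.0),
    sig("post_surgical", "pain_score", d = 2.5),
    sig("post_surgical", "hemoglobin", d = -1.5),
    sig("post_surgical", "coagulopathy", target = 0.60),
    sig("post_surgical", "blood_loss_anemia", target = 0.50),
    sig("post_surgical", "opioid_rx", target = 0.90),
    sig("post_surgical", "temp_c", d = 1.0)
  )
  outcome_model <- data.frame(
    subgroup = c(names(sizes), "background"),
    p_mortality = c(0.08, 0.45, 0.25, 0.22, 0.28, 0.15, 0.04, 0.06,
                    0.05, 0.01, 0.03, 0.12, 0.10),
    mean_ip_days = c(3, 12, 8, 9, 10, 6, 5, 7, 3, 1.5, 2, 20, 2.5),
    mean_ed_visits = c(1.5, 2.0, 2.5, 2.8, 2.5, 2.2, 2.5, 4.0,
                       2.0, 1.2, 1.5, 3.0, 1.3),
    stringsAsFactors = FALSE)
  adherence <- stats::setNames(
    c(0.80, 0.77, 0.82, 0.70, 0.82, 0.75, 0.55, 0.45,
      0.60, 0.80, 0.75, 0.77, 0.77),
    c(names(sizes), "background"))
  categories <- stats::setNames(
    c(rep("comorbidity", 6), "psychobehavioral", "psychobehavioral",
      "sociodemographic", "sociodemographic", "sociodemographic",
      "comorbidity"),
    names(sizes))
  planted_structure(sizes, signatures, background_fraction = 0.25,
                    outcome_model = outcome_model, dictionary = dict,
                    adherence = adherence, categories = categories,
                    seed = seed)
}

#' Generate a synthetic high-risk cohort with planted subgroups
#'
#' Draws a patient-level feature table from the structure's dictionary:
#' subgroup members have their signature features shifted by the stated
#' effects relative to the common baseline marginals, background patients
#' receive small random perturbations (standardized effect at most 0.5 on a
#' few randomly chosen signature features) so that some genuinely resist
#' clustering, and two-year outcomes are drawn from each subgroup's outcome
#' model. A risk percentile is assigned as a noisy monotone function of a
#' latent severity score, rank-mapped onto the high-risk range.
#'
#' @param structure a [planted_structure()].
#' @param n_total cohort size; must be at least the sum of subgroup sizes.
#'   The remainder becomes background.
#' @param seed integer; defaults to the structure's seed.
#' @return a \code{cohort_table}: a data.frame with \code{patient_id},
#'   \code{true_label}, \code{risk_percentile}, outcome columns
#'   (\code{died_2y}, \code{any_hosp_2y}, \code{inpatient_days_2y},
#'   \code{any_ed_2y}, \code{ed_visits_2y}) and one column per dictionary
#'   feature; the dictionary and structure ride along as attributes.
#' @export
generate_cohort <- function(structure, n_total, seed = structure$seed) {
  stopifnot(inherits(structure, "planted_structure"))
  dict <- structure$dictionary
  sizes <- structure$subgroup_sizes
  if (n_total < sum(sizes))
    stop_config("n_total (%d) smaller than sum of subgroup sizes (%d)",
                n_total, sum(sizes))
  n_signature <- length(unique(structure$signatures$feature))
  if (nrow(dict) < n_signature + 10L)
    stop_config("dictionary must contain at least %d features",
                n_signature + 10L)
  n_bg <- n_total - sum(sizes)
  with_seed(seed, {
    labels <- sample(rep(c(names(sizes), "background"), c(sizes, n_bg)))
    n <- n_total
    # per-row effect matrix, one column per feature
    E <- matrix(0, n, nrow(dict), dimnames = list(NULL, dict$name))
    for (g in names(sizes)) {
      rows <- which(labels == g)
      s <- structure$signatures[structure$signatures$subgroup == g, ]
      for (k in seq_len(nrow(s))) E[rows, s$feature[k]] <- s$effect[k]
    }
    # background patients are atypical in idiosyncratic ways: each gets
    # moderate shifts on its own random set of features (unique combinations
    # of conditions and utilization), so they scatter in feature space and
    # genuinely resist density-based clustering instead of pooling into a
    # "baseline" cluster of their own
    perturbable <- dict$name[dict$special == ""]
    bg_rows <- which(labels == "background")
    for (i in bg_rows) {
      k <- min(5L + stats::rpois(1L, 5), length(perturbable))
      feats <- sample(perturbable, k)
      for (fname in feats) {
        type <- dict$type[dict$name == fname]
        E[i, fname] <- if (type == "binary") stats::runif(1, -0.6, 0.6)
                       else stats::runif(1, -2.5, 2.5)
      }
    }
    Z <- matrix(NA_real_, n, nrow(dict), dimnames = list(NULL, dict$name))
    X <- matrix(NA_real_, n, nrow(dict), dimnames = list(NULL, dict$name))
    adher_t <- structure$adherence[labels]
    for (j in seq_len(nrow(dict))) {
      fname <- dict$name[j]
      type <- dict$type[j]
      special <- dict$special[j]
      if (special == "derived_sum" || special == "adherence" ||
          special == "dup") next
      if (type == "binary") {
        p <- pmin(0.995, pmax(0.005, dict$p[j] + E[, j]))
        X[, j] <- stats::rbinom(n, 1L, p)
      } else if (type == "count") {
        lam <- pmax(0.01, dict$lambda[j] + E[, j] * sqrt(dict$lambda[j]))
        X[, j] <- stats::rpois(n, lam)
      } else {
        Z[, j] <- stats::rnorm(n) + E[, j]
        X[, j] <- dict$mu[j] + dict$sigma[j] * Z[, j]
      }
    }
    # derived features: comorbidity burden, correlated duplicates, adherence
    for (j in which(dict$special == "derived_sum")) {
      com <- dict$name[dict$domain == "comorbidity" & dict$type == "binary"]
      X[, j] <- rowSums(X[, com, drop = FALSE])
    }
    for (j in which(dict$special == "dup")) {
      r <- dict$parent_r[j]
      zp <- Z[, dict$parent[j]]
      z <- r * zp + sqrt(1 - r^2) * stats::rnorm(n)
      X[, j] <- dict$mu[j] + dict$sigma[j] * z
    }
    for (j in which(dict$special == "adherence")) {
      t_j <- pmin(0.98, pmax(0.02, adher_t))
      X[, j] <- stats::rbeta(n, t_j * 3, (1 - t_j) * 3)
    }
    # risk percentile: noisy monotone transform of latent severity
    zs <- function(nm) {
      if (!nm %in% colnames(X)) return(rep(0, n))
      v <- X[, nm]
      if (stats::sd(v) == 0) rep(0, n) else as.numeric(scale(v))
    }
    severity <- 0.8 * zs("elix_count") + 0.4 * zs("age") +
      0.5 * zs("inpatient_admits") + 0.3 * zs("ed_visits_prior") +
      stats::rnorm(n, sd = 0.8)
    thr <- structure$high_risk_threshold
    risk <- thr + floor((100 - thr) * (rank(severity, ties.method = "first") -
                                         0.5) / n)
    om <- structure$outcome_model
    om_idx <- match(labels, om$subgroup)
    died <- stats::rbinom(n, 1L, om$p_mortality[om_idx])
    ip_days <- stats::rpois(n, om$mean_ip_days[om_idx])
    ed_visits <- stats::rpois(n, om$mean_ed_visits[om_idx])
    cohort <- data.frame(
      patient_id = sprintf("P%05d", seq_len(n)),
      true_label = labels,
      risk_percentile = as.integer(risk),
      died_2y = died,
      any_hosp_2y = as.integer(ip_days > 0),
      inpatient_days_2y = ip_days,
      any_ed_2y = as.integer(ed_visits > 0),
      ed_visits_2y = ed_visits,
      stringsAsFactors = FALSE)
    cohort <- cbind(cohort, as.data.frame(X))
    # patients with no documented medication use have no adherence data
    no_med <- cohort$any_med == 0
    cohort[no_med, dict$name[dict$special == "adherence"]] <- NA_real_
    attr(cohort, "dictionary") <- dict
    attr(cohort, "structure") <- structure
    class(cohort) <- c("cohort_table", "data.frame")
    cohort
  })
}

#' @export
print.cohort_table <- function(x, ...) {
  dict <- attr(x, "dictionary")
  cat(sprintf("cohort_table: %d patients, %d features, %d planted subgroups\n",
              nrow(x), nrow(dict),
              length(setdiff(unique(x$true_label), "background"))))
  cat(sprintf("  background: %d patients; risk percentile %d-%d\n",
              sum(x$true_label == "background"),
              min(x$risk_percentile), max(x$risk_percentile)))
  invisible(x)
}

# feature columns of a cohort table (everything except bookkeeping/outcomes)
cohort_feature_names <- function(cohort) {
  dict <- attr(cohort, "dictionary")
  intersect(dict$name, names(cohort))
}

#' Mask cohort feature cells to emulate missing data
#'
#' Under MCAR, each targeted cell is masked independently at its domain's
#' rate. Under \code{MAR_on_utilization}, the masking probability is a
#' monotone (logistic) function of a fully observed conditioning variable,
#' so patients with fewer visits have more gaps. Pre-mask values are kept in
#' the \code{"truth"} attribute for downstream oracles.
#'
#' @param cohort a \code{cohort_table}.
#' @param per_domain_rates named numeric vector of masking rates in [0, 1]
#'   by domain; unnamed domains default to 0.
#' @param mechanism \code{"MCAR"} or \code{"MAR_on_utilization"}.
#' @param seed integer seed.
#' @param mar_var conditioning variable for the MAR mechanism (never masked).
#' @param mar_strength logistic slope on the standardized conditioning
#'   variable (negative: more utilization, fewer gaps).
#' @return the cohort with masked cells set to \code{NA}; attributes
#'   \code{"truth"} (pre-mask feature columns) and \code{"mask"} record the
#'   ground truth.
#' @export
inject_missingness <- function(cohort, per_domain_rates,
                               mechanism = c("MCAR", "MAR_on_utilization"),
                               seed = 1L, mar_var = "outpatient_visits",
                               mar_strength = -1.0) {
  mechanism <- match.arg(mechanism)
  if (any(per_domain_rates < 0 | per_domain_rates > 1))
    stop_config("missingness rates must be in [0, 1]")
  dict <- attr(cohort, "dictionary")
  feats <- cohort_feature_names(cohort)
  truth <- as.data.frame(cohort)[, feats]
  if (mechanism == "MAR_on_utilization") {
    if (!mar_var %in% names(cohort) || anyNA(cohort[[mar_var]]))
      stop_config("MAR mechanism needs a fully observed conditioning variable")
    z_cond <- as.numeric(scale(cohort[[mar_var]]))
  }
  mask <- matrix(FALSE, nrow(cohort), length(feats),
                 dimnames = list(NULL, feats))
  with_seed(seed, {
    for (fname in feats) {
      domain <- dict$domain[dict$name == fname]
      rate <- if (domain %in% names(per_domain_rates))
        per_domain_rates[[domain]] else 0
      if (rate <= 0) next
      if (mechanism == "MAR_on_utilization" && fname == mar_var) next
      pr <- if (mechanism == "MCAR") rep(rate, nrow(cohort))
            else stats::plogis(stats::qlogis(pmin(pmax(rate, 1e-6),
                                                  1 - 1e-6)) +
                               mar_strength * z_cond)
      hit <- stats::runif(nrow(cohort)) < pr
      mask[hit, fname] <- TRUE
      cohort[[fname]][hit] <- NA
    }
  })
  attr(cohort, "truth") <- truth
  attr(cohort, "mask") <- mask
  cohort
}

#' Generate pharmacy fill histories matching patient adherence targets
#'
#' Emits a refill sequence per patient and medication class whose long-run
#' day-level coverage approximates the patient's target proportion of days
#' covered (PDC). Refill gaps are drawn so that, by renewal arithmetic,
#' expected coverage equals the target; at moderate targets a fraction of
#' refills arrive early, producing overlapping fills that exercise the
#' union logic of PDC computation. Patients whose target comes from a
#' masked/absent adherence value receive no fills.
#'
#' @param cohort a \code{cohort_table} (targets read from its
#'   \code{pdc_<class>} columns unless \code{adherence_targets} is given).
#' @param classes medication class names; each must map to a
#'   \code{pdc_<class>} column when targets are taken from the cohort.
#' @param adherence_targets optional named vector of per-subgroup targets in
#'   [0, 1] overriding the per-patient columns.
#' @param window integer vector \code{c(first_day, last_day)}, inclusive.
#' @param seed integer seed.
#' @return data.frame with columns \code{patient_id},
#'   \code{medication_class}, \code{start_day}, \code{days_supplied};
#'   the observation window is attached as attribute \code{"window"}.
#' @export
generate_fill_histories <- function(cohort, classes = c("antihypertensive",
                                                        "statin"),
                                    adherence_targets = NULL,
                                    window = c(0L, 364L), seed = 1L) {
  if (length(classes) == 0L) stop_config("empty medication class list")
  if (!is.null(adherence_targets) &&
      any(adherence_targets < 0 | adherence_targets > 1))
    stop_config("adherence targets must be in [0, 1]")
  w_len <- window[2] - window[1] + 1L
  if (w_len <= 0L) stop_config("observation window is empty")
  supply <- 30L
  with_seed(seed, {
    out <- vector("list", length(classes) * nrow(cohort))
    k <- 0L
    for (cls in classes) {
      targets <- if (!is.null(adherence_targets)) {
        unname(adherence_targets[cohort$true_label])
      } else {
        col <- paste0("pdc_", cls)
        if (!col %in% names(cohort))
          stop_config("no pdc_%s column and no adherence_targets given", cls)
        cohort[[col]]
      }
      for (i in seq_len(nrow(cohort))) {
        t_i <- targets[i]
        if (is.na(t_i) || t_i <= 0) next
        if (t_i >= 1) {
          starts <- seq(window[1], window[2], by = supply)
          k <- k + 1L
          out[[k]] <- data.frame(patient_id = cohort$patient_id[i],
                                 medication_class = cls,
                                 start_day = as.integer(starts),
                                 days_supplied = supply,
                                 stringsAsFactors = FALSE)
          next
        }
        # renewal calibration: coverage = E[covered]/E[cycle length] = target
        q <- if (t_i < 0.85) 0.15 else 0
        mean_overlap <- 8
        num <- q * (supply - mean_overlap) + (1 - q) * supply
        mean_gap <- max((num / t_i - q * (supply - mean_overlap)) /
                          max(1 - q, 1e-9) - supply, 0.5)
        day <- window[1] + sample.int(10L, 1L) - 1L
        starts <- integer(0); supplies <- integer(0)
        while (day <= window[2]) {
          starts <- c(starts, day); supplies <- c(supplies, supply)
          if (q > 0 && stats::runif(1) < q) {
            gap <- -sample.int(15L, 1L)  # early refill: overlap
          } else {
            gap <- round(stats::rexp(1, rate = 1 / mean_gap))
          }
          day <- day + supply + gap
        }
        if (length(starts)) {
          k <- k + 1L
          out[[k]] <- data.frame(patient_id = cohort$patient_id[i],
                                 medication_class = cls,
                                 start_day = starts,
                                 days_supplied = supplies,
                                 stringsAsFactors = FALSE)
        }
      }
    }
    fills <- if (k) do.call(rbind, out[seq_len(k)]) else
      data.frame(patient_id = character(0), medication_class = character(0),
                 start_day = integer(0), days_supplied = integer(0))
    attr(fills, "window") <- as.integer(window)
    fills
  })
}

#' Generate repeated laboratory and vital-sign measurements
#'
#' For every non-missing lab/vital cell, emits a short series of noisy
#' observations at random days within the window; the per-patient median of
#' each series recovers the underlying value up to measurement noise, which
#' is what median aggregation is for.
#'
#' @param cohort a \code{cohort_table} (possibly after
#'   [inject_missingness()]).
#' @param variables which features to emit series for; defaults to all
#'   lab/vital features.
#' @param noise_frac measurement noise SD as a fraction of the feature's
#'   marginal SD.
#' @param window integer \code{c(first_day, last_day)}.
#' @param seed integer seed.
#' @return data.frame with columns \code{patient_id}, \code{variable},
#'   \code{day}, \code{value}.
#' @export
generate_repeated_measures <- function(cohort, variables = NULL,
                                       noise_frac = 0.25,
                                       window = c(0L, 364L), seed = 1L) {
  dict <- attr(cohort, "dictionary")
  if (is.null(variables))
    variables <- dict$name[dict$domain %in% c("labs", "vitals") &
                           dict$type == "continuous" &
                           dict$name %in% names(cohort)]
  with_seed(seed, {
    pieces <- lapply(variables, function(v) {
      sd_v <- dict$sigma[dict$name == v]
      if (is.na(sd_v)) sd_v <- stats::sd(cohort[[v]], na.rm = TRUE)
      ok <- which(!is.na(cohort[[v]]))
      if (!length(ok)) return(NULL)
      n_obs <- 1L + stats::rpois(length(ok), 2)
      idx <- rep(ok, n_obs)
      data.frame(patient_id = cohort$patient_id[idx],
                 variable = v,
                 day = sample(seq(window[1], window[2]), length(idx),
                              replace = TRUE),
                 value = cohort[[v]][idx] +
                   stats::rnorm(length(idx), sd = noise_frac * sd_v),
                 stringsAsFactors = FALSE)
    })
    series <- do.call(rbind, pieces)
    rownames(series) <- NULL
    attr(series, "window") <- as.integer(window)
    series
  })
}

#' Write a synthetic cohort and its companions to disk
#'
#' Emits the cohort CSV, a JSON data dictionary, a JSON ground-truth file
#' (labels, generative parameters, seed), and TSVs for fill histories and
#' repeated measures when supplied.
#'
#' @param cohort a \code{cohort_table}.
#' @param dir output directory (created if needed).
#' @param fills,series optional outputs of [generate_fill_histories()] /
#'   [generate_repeated_measures()].
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir, fills = NULL, series = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(cohort = file.path(dir, "cohort.csv"),
             dictionary = file.path(dir, "dictionary.json"),
             truth = file.path(dir, "ground_truth.json"))
  utils::write.csv(as.data.frame(cohort), paths["cohort"], row.names = FALSE)
  dict <- attr(cohort, "dictionary")
  jsonlite::write_json(dict[, c("name", "domain", "type")],
                       paths["dictionary"], auto_unbox = TRUE, digits = NA)
  st <- attr(cohort, "structure")
  jsonlite::write_json(
    list(true_label = cohort$true_label,
         patient_id = cohort$patient_id,
         subgroup_sizes = as.list(st$subgroup_sizes),
         background_fraction = st$background_fraction,
         signatures = st$signatures,
         seed = st$seed),
    paths["truth"], auto_unbox = TRUE, digits = NA)
  if (!is.null(fills)) {
    paths <- c(paths, fills = file.path(dir, "fills.tsv"))
    utils::write.table(fills, paths["fills"], sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  if (!is.null(series)) {
    paths <- c(paths, series = file.path(dir, "repeated_measures.tsv"))
    utils::write.table(series, paths["series"], sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(paths)
}
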