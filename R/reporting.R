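#' Per-cluster two-year outcome summaries
#'
#' Exact group-by aggregation of the descriptive outcomes: cluster size,
#' two-year mortality, any-hospitalization rate and mean inpatient days,
#' any-ED rate and mean ED visits, and mean risk percentile. Outlier
#' (noise) patients are a first-class row, never silently dropped, and an
#' overall row closes the table.
#'
#' @param labels cluster labels (integer, 0 = noise) in patient order.
#' @param outcomes data.frame with columns \code{died_2y},
#'   \code{any_hosp_2y}, \code{inpatient_days_2y}, \code{any_ed_2y},
#'   \code{ed_visits_2y} and optionally \code{risk_percentile} and
#'   \code{patient_id}, aligned with \code{labels}.
#' @return data.frame of class \code{outcome_summary}: one row per cluster,
#'   one for noise, one overall; percentages in [0, 100], full precision.
#' @export
summarize_outcomes <- function(labels, outcomes) {
  stopifnot(length(labels) == nrow(outcomes))
  need <- c("died_2y", "any_hosp_2y", "inpatient_days_2y", "any_ed_2y",
            "ed_visits_2y")
  miss_col <- setdiff(need, names(outcomes))
  if (length(miss_col))
    stop_config("outcomes missing columns: %s",
                paste(miss_col, collapse = ", "))
  bad <- which(rowSums(is.na(outcomes[, need])) > 0L)
  if (length(bad)) {
    ids <- if ("patient_id" %in% names(outcomes))
      outcomes$patient_id[bad] else as.character(bad)
    stop_config("labeled patient(s) without outcomes: %s",
                paste(utils::head(ids, 5), collapse = ", "))
  }
  risk <- outcomes$risk_percentile %||% rep(NA_real_, nrow(outcomes))
  one_row <- function(group, idx) {
    n <- length(idx)
    if (n == 0L)
      return(data.frame(group = group, n = 0L, mortality_pct = NA_real_,
                        hosp_pct = NA_real_, mean_ip_days = NA_real_,
                        ed_pct = NA_real_, mean_ed_visits = NA_real_,
                        mean_risk = NA_real_, stringsAsFactors = FALSE))
    data.frame(group = group, n = n,
               mortality_pct = 100 * mean(outcomes$died_2y[idx]),
               hosp_pct = 100 * mean(outcomes$any_hosp_2y[idx]),
               mean_ip_days = mean(outcomes$inpatient_days_2y[idx]),
               ed_pct = 100 * mean(outcomes$any_ed_2y[idx]),
               mean_ed_visits = mean(outcomes$ed_visits_2y[idx]),
               mean_risk = mean(risk[idx]),
               stringsAsFactors = FALSE)
  }
  ids <- sort(setdiff(unique(labels), 0L))
  rows <- lapply(ids, function(k)
    one_row(as.character(k), which(labels == k)))
  rows <- c(rows, list(one_row("noise", which(labels == 0L)),
                       one_row("overall", seq_along(labels))))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("outcome_summary", "data.frame")
  out
}

#' Baseline descriptive table for a cohort
#'
#' Mean (SD) for continuous and count variables, n (\%) for binary flags,
#' over whatever feature columns the input carries.
#'
#' @param cohort a \code{cohort_table} or plain data.frame of features.
#' @param dictionary optional feature dictionary (taken from the cohort's
#'   attribute when absent).
#' @return data.frame: variable, type, n (non-missing), numeric mean/sd or
#'   count/percent, and a formatted \code{summary} string.
#' @export
baseline_table <- function(cohort, dictionary = attr(cohort, "dictionary")) {
  if (nrow(cohort) == 0L) stop_config("empty cohort")
  feats <- if (!is.null(dictionary))
    intersect(dictionary$name, names(cohort)) else names(cohort)
  rows <- lapply(feats, function(v) {
    x <- cohort[[v]]
    obs <- x[!is.na(x)]
    u <- unique(obs)
    binary <- length(u) <= 2L && all(u %in% c(0, 1))
    if (binary) {
      data.frame(variable = v, type = "binary", n_obs = length(obs),
                 value = sum(obs), spread = 100 * mean(obs),
                 summary = sprintf("%d (%.1f)", sum(obs), 100 * mean(obs)),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(variable = v, type = "continuous", n_obs = length(obs),
                 value = mean(obs), spread = stats::sd(obs),
                 summary = sprintf("%.2f (%.2f)", mean(obs),
                                   stats::sd(obs)),
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare recovered clusters against planted ground truth
#'
#' Matches each planted subgroup to the largest recovered cluster whose
#' majority true label is that subgroup, then measures partition agreement
#' (ARI over clustered points, with background as its own true class),
#' noise fraction, signature recovery (a true signature feature among the
#' cluster's top-5 evidence variables), and category-suggestion accuracy.
#'
#' @param labels recovered cluster labels (0 = noise).
#' @param true_labels planted subgroup names (\code{"background"} for none).
#' @param evidence output of [suggest_labels()] for the recovered clusters.
#' @param structure the [planted_structure()] that generated the cohort.
#' @return list: \code{ari}, \code{noise_fraction}, \code{n_clusters},
#'   \code{signature_hit_rate}, \code{category_accuracy}, and the per
#'   subgroup \code{matches} table.
#' @export
evaluate_recovery <- function(labels, true_labels, evidence = NULL,
                              structure = NULL) {
  stopifnot(length(labels) == length(true_labels))
  clustered <- labels > 0L
  ari <- if (any(clustered))
    adjusted_rand_index(labels[clustered], true_labels[clustered])
  else NA_real_
  out <- list(ari = ari, noise_fraction = mean(!clustered),
              n_clusters = length(setdiff(unique(labels), 0L)))
  if (!is.null(structure)) {
    groups <- names(structure$subgroup_sizes)
    matches <- data.frame(subgroup = groups, cluster = NA_integer_,
                          signature_hit = FALSE, category_ok = FALSE,
                          stringsAsFactors = FALSE)
    for (gi in seq_along(groups)) {
      g <- groups[gi]
      # the subgroup's cluster is the modal destination of its clustered
      # members; a subgroup whose members all land in noise is unrecovered
      dest <- labels[clustered & true_labels == g]
      if (!length(dest)) next
      best <- names(sort(table(dest), decreasing = TRUE))[1]
      matches$cluster[gi] <- as.integer(best)
      if (!is.null(evidence) && best %in% names(evidence)) {
        ev <- evidence[[best]]
        sig_feats <- structure$signatures$feature[
          structure$signatures$subgroup == g]
        matches$signature_hit[gi] <- any(ev$evidence$variable %in% sig_feats)
        if (!is.null(structure$categories))
          matches$category_ok[gi] <-
            structure$categories[[g]] %in% ev$suggested_category
      }
    }
    out$matches <- matches
    out$signature_hit_rate <- mean(matches$signature_hit)
    out$category_accuracy <- mean(matches$category_ok)
  }
  out
}

pipeline_defaults <- function() {
  list(n_total = 3000L, n_features = 119L, n_sets = 5L, set_size = NULL,
       stratum_width = 5L, high_risk_threshold = 75L,
       missing_labs = 0.15, missing_vitals = 0.08, missing_socio = 0.02,
       min_variance = 0.0099, r_max = 0.80, fcs_cycles = 10L,
       perplexity = 30, tsne_iterations = 1000L, learning_rate = 200,
       exaggeration = 12, noise_target = 0.25, lambda_noise = 0.5,
       penalty_grid_n = 100L, outdir = NULL)
}

#' Validate a pipeline configuration
#'
#' The configuration is a flat key-value document (YAML file or list);
#' unknown keys are rejected and a seed is mandatory. Missing keys fall
#' back to the documented defaults.
#'
#' @param config list or path to a YAML file.
#' @return the completed configuration list.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) stop_config("config must provide a seed")
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), c(names(defaults), "seed"))
  if (length(unknown))
    stop_config("unknown config key(s): %s", paste(unknown, collapse = ", "))
  out <- utils::modifyList(defaults, config)
  if (is.null(out$set_size)) out$set_size <- out$n_total %/% out$n_sets
  out
}

#' Run the full subgrouping pipeline on a synthetic cohort
#'
#' Executes every stage end to end: synthetic cohort generation (planted
#' subgroups, fill histories, repeated measures, missingness), feature
#' preparation, risk-stratified disjoint sampling, per-training-set t-SNE
#' embedding, OPTICS hyperparameter tuning across the training sets, final
#' embedding and clustering of the validation set, ridge-based cluster
#' profiling with label evidence, and per-cluster outcome summaries. All
#' randomness derives from the single config seed, so a rerun reproduces
#' every artifact; when \code{outdir} is set each stage writes its outputs
#' plus a JSON manifest of every tunable parameter.
#'
#' @param config list or YAML path accepted by [validate_config()].
#' @return list of class \code{pipeline_result} with the per-stage objects
#'   (\code{cohort}, \code{features}, \code{samples}, \code{tuning},
#'   \code{validation}, \code{profiles}, \code{evidence},
#'   \code{importance}, \code{outcomes}, \code{recovery},
#'   \code{manifest}).
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  seeds <- derive_seeds(cfg$seed, 20L)
  st <- study_structure(seed = seeds[1], n_features = cfg$n_features,
                        n_total = cfg$n_total)
  cohort <- generate_cohort(st, n_total = cfg$n_total)
  fills <- generate_fill_histories(cohort, seed = seeds[2])
  cohort <- inject_missingness(
    cohort,
    per_domain_rates = c(labs = cfg$missing_labs,
                         vitals = cfg$missing_vitals,
                         sociodemographic = cfg$missing_socio),
    mechanism = "MCAR", seed = seeds[3])
  series <- generate_repeated_measures(cohort, seed = seeds[4])
  fm <- build_feature_matrix(cohort, series = series, fills = fills,
                             min_variance = cfg$min_variance,
                             r_max = cfg$r_max, n_cycles = cfg$fcs_cycles,
                             seed = seeds[5])
  plan <- sample_plan(n_sets = cfg$n_sets, set_size = cfg$set_size,
                      stratum_width = cfg$stratum_width,
                      high_risk_threshold = cfg$high_risk_threshold,
                      seed = seeds[6])
  samples <- stratified_sample(
    data.frame(patient_id = cohort$patient_id,
               risk_percentile = cohort$risk_percentile,
               stringsAsFactors = FALSE), plan)
  tcfg <- function(seed) tsne_config(
    perplexity = cfg$perplexity, n_iterations = cfg$tsne_iterations,
    exaggeration = cfg$exaggeration,
    exaggeration_iter = min(250L, cfg$tsne_iterations %/% 4L),
    learning_rate = cfg$learning_rate,
    momentum_switch = min(250L, cfg$tsne_iterations %/% 4L), seed = seed)
  train_idx <- which(samples$roles == "train")
  train_emb <- lapply(seq_along(train_idx), function(i) {
    ids <- samples$sets[[train_idx[i]]]$patient_id
    embed_tsne(fm$matrix[ids, , drop = FALSE], tcfg(seeds[10L + i]))
  })
  tuning <- tune_hyperparameters(train_emb,
                                 noise_target = cfg$noise_target,
                                 lambda_noise = cfg$lambda_noise)
  val_ids <- samples$sets[[which(samples$roles == "validation")]]$patient_id
  val_emb <- embed_tsne(fm$matrix[val_ids, , drop = FALSE], tcfg(seeds[8]))
  val_res <- extract_clusters(optics_order(val_emb$coordinates,
                                           tuning$config))
  labels <- val_res$labels
  grid <- penalty_grid(cfg$penalty_grid_n)
  profiles <- profile_clusters(fm$matrix[val_ids, , drop = FALSE], labels,
                               grid)
  importance <- if (length(profiles) >= 2L) importance_ranges(profiles)
                else NULL
  evidence <- suggest_labels(profiles, fm$domains)
  val_rows <- match(val_ids, cohort$patient_id)
  outcomes <- summarize_outcomes(
    labels, as.data.frame(cohort)[val_rows,
                                  c("patient_id", "risk_percentile",
                                    "died_2y", "any_hosp_2y",
                                    "inpatient_days_2y", "any_ed_2y",
                                    "ed_visits_2y")])
  recovery <- evaluate_recovery(labels, cohort$true_label[val_rows],
                                evidence, st)
  manifest <- list(
    seed = cfg$seed, stage_seeds = seeds, n_total = cfg$n_total,
    n_features = cfg$n_features,
    subgroup_sizes = as.list(st$subgroup_sizes),
    background_fraction = st$background_fraction,
    missingness = c(labs = cfg$missing_labs, vitals = cfg$missing_vitals,
                    sociodemographic = cfg$missing_socio),
    min_variance = cfg$min_variance, r_max = cfg$r_max,
    fcs_cycles = cfg$fcs_cycles, adherence_weighting = "days_of_therapy",
    sampling = list(n_sets = cfg$n_sets, set_size = cfg$set_size,
                    stratum_width = cfg$stratum_width,
                    high_risk_threshold = cfg$high_risk_threshold),
    tsne = list(perplexity = cfg$perplexity,
                n_iterations = cfg$tsne_iterations,
                exaggeration = cfg$exaggeration,
                exaggeration_iter = min(250L, cfg$tsne_iterations %/% 4L),
                learning_rate = cfg$learning_rate,
                momentum = c(0.5, 0.8)),
    optics = list(tuned = unclass(tuning$config)[c("min_pts", "eps",
                                                   "extraction")],
                  grid = tuning$scores,
                  noise_target = cfg$noise_target,
                  lambda_noise = cfg$lambda_noise),
    ridge = list(grid_n = cfg$penalty_grid_n, grid_range = c(1e-4, 1e4),
                 normalization = "unit_max_abs", intercept = "unpenalized"))
  result <- structure(
    list(cohort = cohort, features = fm, samples = samples,
         train_embeddings = train_emb, tuning = tuning,
         validation = list(embedding = val_emb, clustering = val_res,
                           ids = val_ids),
         profiles = profiles, importance = importance, evidence = evidence,
         outcomes = outcomes, recovery = recovery, manifest = manifest),
    class = "pipeline_result")
  if (!is.null(cfg$outdir)) write_pipeline(result, cfg$outdir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  rec <- x$recovery
  cat(sprintf(paste0("pipeline_result: %d clusters on the validation set ",
                     "(%.1f%% noise)\n"),
              rec$n_clusters, 100 * rec$noise_fraction))
  if (!is.null(rec$ari))
    cat(sprintf("  planted-label ARI (clustered points): %.3f\n", rec$ari))
  invisible(x)
}

#' Write every pipeline artifact to a directory
#' @param result a \code{pipeline_result}.
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
write_pipeline <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_cohort(result$cohort, file.path(dir, "cohort"))
  utils::write.csv(
    data.frame(patient_id = rownames(result$features$matrix),
               result$features$matrix, check.names = FALSE),
    file.path(dir, "feature_matrix.csv"), row.names = FALSE)
  jsonlite::write_json(result$features$provenance,
                       file.path(dir, "feature_provenance.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  write_sample_sets(result$samples, file.path(dir, "samples"))
  write_embedding(result$validation$embedding, dir, "validation_embedding")
  write_clustering(result$validation$clustering, dir,
                   ids = result$validation$ids)
  if (!is.null(result$importance))
    write_profiles(result$profiles, result$importance, result$evidence, dir)
  utils::write.table(result$outcomes, file.path(dir, "outcomes.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
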