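#' Median-aggregate repeated measurements into per-patient features
#'
#' Patients with several observations of a lab or vital sign contribute the
#' median of their series (the even-length median is the midpoint of the two
#' central values); patients with no series for a variable get \code{NA}.
#'
#' @param series long data.frame with columns \code{patient_id},
#'   \code{variable}, \code{value} (a \code{day} column is allowed and
#'   ignored).
#' @return wide data.frame: one row per patient, one column per variable.
#' @export
aggregate_medians <- function(series) {
  stopifnot(all(c("patient_id", "variable", "value") %in% names(series)))
  meds <- stats::aggregate(value ~ patient_id + variable, data = series,
                           FUN = stats::median)
  wide <- stats::reshape(meds, idvar = "patient_id", timevar = "variable",
                         direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  rownames(wide) <- NULL
  wide
}

#' Proportion of days covered for one fill history
#'
#' PDC is the fraction of days in the observation window on which the
#' patient had medication on hand: the size of the union of covered day
#' sets intersected with the window, divided by the window length.
#' Overlapping fills never double-count.
#'
#' @param start_day integer vector of fill start days.
#' @param days_supplied positive integer vector, same length.
#' @param window integer \code{c(first_day, last_day)}, inclusive.
#' @return a single value in [0, 1]; zero fills give 0.
#' @export
compute_pdc <- function(start_day, days_supplied, window) {
  w_len <- window[2] - window[1] + 1L
  if (w_len <= 0L) stop_config("observation window is empty")
  if (length(start_day) == 0L) return(0)
  stopifnot(length(start_day) == length(days_supplied),
            all(days_supplied >= 1))
  covered <- logical(w_len)
  for (k in seq_along(start_day)) {
    a <- max(start_day[k], window[1])
    b <- min(start_day[k] + days_supplied[k] - 1L, window[2])
    if (a <= b) covered[(a - window[1] + 1L):(b - window[1] + 1L)] <- TRUE
  }
  sum(covered) / w_len
}

#' Weighted medication adherence across classes
#'
#' Combines per-class PDC values into a single adherence summary, weighting
#' each class by its days of therapy so that a medication prescribed for
#' more of the year contributes more. Set all weights equal for an
#' unweighted mean.
#'
#' @param pdc numeric vector of per-class PDC values (may contain \code{NA}
#'   for classes never prescribed).
#' @param weights nonnegative weights (days of therapy per class).
#' @return weighted mean over classes with positive weight; \code{NA} if no
#'   class has any therapy.
#' @export
weighted_adherence <- function(pdc, weights = rep(1, length(pdc))) {
  keep <- !is.na(pdc) & weights > 0
  if (!any(keep)) return(NA_real_)
  sum(pdc[keep] * weights[keep]) / sum(weights[keep])
}

# Per-patient, per-class PDC table from a fill-history data.frame.
# Patients with no fills in any class get NA (unknown adherence); patients
# with fills in some class get 0 for classes with none (prescribed elsewhere,
# uncovered here). Weighted adherence uses days-of-therapy weights.
pdc_table <- function(fills, classes, patient_ids,
                      window = attr(fills, "window")) {
  if (is.null(window)) stop_config("fill history carries no window")
  out <- matrix(NA_real_, length(patient_ids), length(classes),
                dimnames = list(patient_ids, classes))
  dot <- matrix(0, length(patient_ids), length(classes),
                dimnames = list(patient_ids, classes))
  has_any <- patient_ids %in% fills$patient_id
  by_pc <- split(fills, list(fills$patient_id, fills$medication_class),
                 drop = TRUE)
  for (chunk in by_pc) {
    pid <- chunk$patient_id[1]; cls <- chunk$medication_class[1]
    if (!pid %in% patient_ids || !cls %in% classes) next
    out[pid, cls] <- compute_pdc(chunk$start_day, chunk$days_supplied, window)
    dot[pid, cls] <- sum(pmax(0L, pmin(chunk$start_day + chunk$days_supplied
                                       - 1L, window[2]) -
                                  pmax(chunk$start_day, window[1]) + 1L))
  }
  out[has_any, ][is.na(out[has_any, ])] <- 0
  weighted <- vapply(seq_along(patient_ids), function(i)
    weighted_adherence(out[i, ], dot[i, ]), numeric(1))
  weighted[has_any & is.na(weighted)] <- 0
  data.frame(patient_id = patient_ids, out, pdc_weighted = weighted,
             row.names = NULL, check.names = FALSE,
             stringsAsFactors = FALSE)
}

col_variance <- function(x) {
  obs <- x[!is.na(x)]
  u <- unique(obs)
  if (length(u) <= 2L && all(u %in% c(0, 1))) {
    p <- mean(obs)
    p * (1 - p)
  } else {
    stats::var(obs)
  }
}

#' Drop features with extremely low variance
#'
#' A column is removed when its observed-value variance falls below the
#' threshold; binary columns use the population variance p(1-p), so the
#' default threshold 0.0099 drops flags with prevalence below 1\% or above
#' 99\%.
#'
#' @param X numeric matrix (may contain \code{NA}).
#' @param min_variance variance threshold.
#' @return list with \code{matrix} (retained columns) and \code{removed}
#'   (character vector of dropped names).
#' @export
low_variance_filter <- function(X, min_variance = 0.0099) {
  stopifnot(ncol(X) >= 1L)
  v <- apply(X, 2, col_variance)
  drop <- which(is.na(v) | v < min_variance)
  if (length(drop) == ncol(X))
    stop_config("low-variance filter removed every column (threshold %g)",
                min_variance)
  list(matrix = X[, setdiff(seq_len(ncol(X)), drop), drop = FALSE],
       removed = colnames(X)[drop])
}

#' Greedily prune highly correlated features
#'
#' While any retained pair has pairwise-complete Pearson |r| above
#' \code{r_max}, the member of the worst offending pair with the larger mean
#' absolute correlation to all other retained columns is dropped (ties: the
#' later column in the fixed input order). The result contains no pair with
#' |r| above the threshold, and re-running it removes nothing.
#'
#' @param X numeric matrix.
#' @param r_max correlation threshold (default 0.80).
#' @return list with \code{matrix} and \code{removed}, a data.frame of
#'   (dropped, kept, r) records.
#' @export
correlation_prune <- function(X, r_max = 0.80) {
  removed <- data.frame(dropped = character(0), kept = character(0),
                        r = numeric(0), stringsAsFactors = FALSE)
  if (ncol(X) < 2L) return(list(matrix = X, removed = removed))
  R <- abs(suppressWarnings(stats::cor(X, use = "pairwise.complete.obs")))
  diag(R) <- 0
  R[is.na(R)] <- 0
  keep <- seq_len(ncol(X))
  while (TRUE) {
    sub <- R[keep, keep, drop = FALSE]
    m <- max(sub)
    if (m <= r_max) break
    idx <- which(sub == m, arr.ind = TRUE)[1, ]
    i <- keep[idx[1]]; j <- keep[idx[2]]
    mean_i <- mean(R[i, setdiff(keep, i)])
    mean_j <- mean(R[j, setdiff(keep, j)])
    drop <- if (mean_i > mean_j) i
            else if (mean_j > mean_i) j
            else max(i, j)
    other <- if (drop == i) j else i
    removed <- rbind(removed,
                     data.frame(dropped = colnames(X)[drop],
                                kept = colnames(X)[other], r = m,
                                stringsAsFactors = FALSE))
    keep <- setdiff(keep, drop)
    if (length(keep) < 2L) break
  }
  list(matrix = X[, keep, drop = FALSE], removed = removed)
}

#' Count missing analysis variables per patient
#'
#' Computed after pruning and before imputation, mirroring the use of a
#' missingness-index variable as a feature in its own right.
#'
#' @param X numeric matrix with \code{NA} for missing cells.
#' @return integer vector, one count per row.
#' @export
missingness_count <- function(X) {
  as.integer(rowSums(is.na(X)))
}

ridge_lm <- function(Xp, y, lambda = NULL) {
  # least squares with a small ridge for numerical stability under
  # collinearity; intercept unpenalized via centering
  n <- nrow(Xp)
  if (is.null(lambda)) lambda <- 1e-6 * n
  cx <- colMeans(Xp)
  cy <- mean(y)
  Xc <- sweep(Xp, 2, cx)
  A <- crossprod(Xc) + diag(lambda, ncol(Xp))
  beta <- solve(A, crossprod(Xc, y - cy))
  list(beta = drop(beta), intercept = cy - sum(cx * beta),
       predict = function(Xnew) drop(Xnew %*% beta) + cy - sum(cx * beta))
}

#' Single chained-equations (FCS) imputation
#'
#' Fills missing cells once: after initializing from observed-value draws,
#' each incomplete variable is regressed on all others over \code{n_cycles}
#' sweeps — a linear model with residual-noise draws for continuous/count
#' variables, a logistic model with Bernoulli draws for binary ones — using
#' the currently completed data. Observed cells are never altered and the
#' result is deterministic given the seed.
#'
#' @param X numeric matrix with \code{NA} for missing cells; every column
#'   must have at least one observed value.
#' @param n_cycles number of sweeps (default 10).
#' @param seed integer seed (mandatory).
#' @return completed matrix of the same shape.
#' @export
impute_fcs <- function(X, n_cycles = 10L, seed) {
  if (missing(seed)) stop_config("impute_fcs requires an explicit seed")
  stopifnot(n_cycles >= 1L)
  miss <- is.na(X)
  fully <- colnames(X)[colSums(!miss) == 0L]
  if (length(fully))
    stop_config("column(s) fully missing: %s", paste(fully, collapse = ", "))
  if (!any(miss)) return(X)
  is_binary <- apply(X, 2, function(x) {
    u <- unique(x[!is.na(x)]); length(u) <= 2L && all(u %in% c(0, 1))
  })
  incomplete <- which(colSums(miss) > 0L)
  with_seed(seed, {
    for (j in incomplete) {
      obs <- X[!miss[, j], j]
      X[miss[, j], j] <- sample(obs, sum(miss[, j]), replace = TRUE)
    }
    for (cycle in seq_len(n_cycles)) {
      for (j in incomplete) {
        mis_j <- miss[, j]
        Xp <- X[, -j, drop = FALSE]
        y_obs <- X[!mis_j, j]
        if (is_binary[j]) {
          p_hat <- tryCatch({
            fit <- suppressWarnings(stats::glm.fit(
              cbind(1, Xp[!mis_j, , drop = FALSE]), y_obs,
              family = stats::binomial(),
              control = stats::glm.control(maxit = 15)))
            cf <- fit$coefficients
            cf[is.na(cf)] <- 0
            stats::plogis(drop(cbind(1, Xp[mis_j, , drop = FALSE]) %*% cf))
          }, error = function(e) rep(mean(y_obs), sum(mis_j)))
          p_hat <- pmin(pmax(p_hat, 1e-6), 1 - 1e-6)
          X[mis_j, j] <- stats::rbinom(sum(mis_j), 1L, p_hat)
        } else {
          fit <- ridge_lm(Xp[!mis_j, , drop = FALSE], y_obs)
          res <- y_obs - fit$predict(Xp[!mis_j, , drop = FALSE])
          sigma <- sqrt(sum(res^2) /
                          max(length(res) - ncol(Xp) - 1L, 1L))
          if (!is.finite(sigma)) sigma <- stats::sd(y_obs)
          X[mis_j, j] <- fit$predict(Xp[mis_j, , drop = FALSE]) +
            stats::rnorm(sum(mis_j), sd = sigma)
        }
      }
    }
    X
  })
}

#' Standardize a complete feature matrix
#'
#' Centers and scales every column by its fitting-set mean and sample SD;
#' binary columns are standardized by the same rule so that downstream ridge
#' coefficients are comparable across feature types. The transform is
#' fit once and can be re-applied to new data.
#'
#' @param X complete numeric matrix.
#' @return object of class \code{feature_transform} with elements
#'   \code{matrix} (the z-scored data), \code{center}, \code{scale}.
#' @export
standardize_features <- function(X) {
  if (anyNA(X)) stop_config("standardize requires a complete matrix")
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  zero <- which(scl == 0)
  if (length(zero))
    stop_config("zero-variance column(s) reached standardization: %s",
                paste(colnames(X)[zero], collapse = ", "))
  structure(list(matrix = scale(X, center = ctr, scale = scl)[, ,
                                                              drop = FALSE],
                 center = ctr, scale = scl),
            class = "feature_transform")
}

#' Apply a stored standardization to new data
#' @param transform a \code{feature_transform}.
#' @param X matrix with the same columns as the fitting set.
#' @return z-scored matrix using the stored (mean, sd).
#' @export
apply_standardization <- function(transform, X) {
  stopifnot(inherits(transform, "feature_transform"))
  scale(X[, names(transform$center), drop = FALSE],
        center = transform$center, scale = transform$scale)[, , drop = FALSE]
}

#' Build the analysis-ready standardized feature matrix
#'
#' Runs the fixed preparation order on a cohort: median aggregation of
#' repeated measures, per-class PDC and weighted adherence from fill
#' histories, low-variance filtering, greedy correlation pruning, the
#' missingness-count feature, single FCS imputation, and standardization.
#' Every applied step and its parameters are recorded in the provenance.
#'
#' @param cohort a \code{cohort_table}.
#' @param series optional repeated-measures data.frame; when given, its
#'   medians replace the corresponding cohort columns.
#' @param fills optional fill-history data.frame; when given, per-class PDC
#'   and the weighted adherence replace the cohort's adherence columns.
#' @param min_variance,r_max pruning thresholds.
#' @param n_cycles FCS sweeps.
#' @param seed integer seed for imputation.
#' @return object of class \code{feature_matrix}: standardized matrix
#'   (\code{$matrix}, rownames = patient ids), per-column \code{$domains},
#'   the \code{$report} pruning report, the fitted \code{$transform}, and
#'   \code{$provenance}.
#' @export
build_feature_matrix <- function(cohort, series = NULL, fills = NULL,
                                 min_variance = 0.0099, r_max = 0.80,
                                 n_cycles = 10L, seed = 1L) {
  dict <- attr(cohort, "dictionary")
  feats <- cohort_feature_names(cohort)
  X <- as.matrix(as.data.frame(cohort)[, feats])
  rownames(X) <- cohort$patient_id
  provenance <- list()
  if (!is.null(series)) {
    med <- aggregate_medians(series)
    vars <- setdiff(names(med), "patient_id")
    for (v in intersect(vars, colnames(X))) {
      X[, v] <- NA_real_
      X[med$patient_id, v] <- med[[v]]
    }
    provenance <- c(provenance, list(list(step = "aggregate_medians",
                                          variables = vars)))
  }
  if (!is.null(fills)) {
    classes <- sort(unique(fills$medication_class))
    pt <- pdc_table(fills, classes, cohort$patient_id)
    for (cls in classes) {
      col <- paste0("pdc_", cls)
      if (col %in% colnames(X)) X[, col] <- pt[[cls]]
    }
    if ("pdc_weighted" %in% colnames(X))
      X[, "pdc_weighted"] <- pt$pdc_weighted
    provenance <- c(provenance, list(list(step = "compute_pdc",
                                          classes = classes,
                                          weighting = "days_of_therapy")))
  }
  lv <- low_variance_filter(X, min_variance)
  provenance <- c(provenance, list(list(step = "low_variance_filter",
                                        min_variance = min_variance,
                                        removed = lv$removed)))
  cp <- correlation_prune(lv$matrix, r_max)
  provenance <- c(provenance, list(list(step = "correlation_prune",
                                        r_max = r_max,
                                        removed = cp$removed)))
  X <- cp$matrix
  n_miss <- missingness_count(X)
  if (stats::var(n_miss) > 0) {
    X <- cbind(X, n_missing = n_miss)
    dict <- rbind(dict, data.frame(name = "n_missing", domain = "missingness",
                                   type = "count", p = NA, lambda = NA,
                                   mu = NA, sigma = NA, special = "",
                                   parent = NA, parent_r = NA))
  }
  provenance <- c(provenance, list(list(step = "missingness_count",
                                        added = stats::var(n_miss) > 0)))
  X <- impute_fcs(X, n_cycles = n_cycles, seed = seed)
  provenance <- c(provenance, list(list(step = "impute_fcs",
                                        n_cycles = n_cycles, seed = seed)))
  tr <- standardize_features(X)
  provenance <- c(provenance, list(list(step = "standardize")))
  report <- list(n_original = length(feats),
                 removed_low_variance = lv$removed,
                 removed_correlated = cp$removed,
                 n_retained = ncol(tr$matrix))
  structure(list(matrix = tr$matrix,
                 domains = stats::setNames(
                   dict$domain[match(colnames(tr$matrix), dict$name)],
                   colnames(tr$matrix)),
                 report = report,
                 transform = tr[c("center", "scale")],
                 provenance = provenance),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d patients x %d standardized variables\n",
              nrow(x$matrix), ncol(x$matrix)))
  cat(sprintf("  pruned: %d low-variance, %d correlated (of %d original)\n",
              length(x$report$removed_low_variance),
              nrow(x$report$removed_correlated), x$report$n_original))
  invisible(x)
}
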