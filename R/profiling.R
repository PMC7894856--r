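#' Ridge regression with an unpenalized intercept
#'
#' Linear-probability ridge fit for one-versus-rest cluster membership:
#' minimizes ||y - b0 - X b||^2 + lambda ||b||^2 with the intercept left
#' unpenalized, solved in closed form via the normal equations on centered
#' data.
#'
#' @param X complete numeric matrix (standardized features).
#' @param y binary 0/1 membership indicator containing both classes.
#' @param lambda positive penalty.
#' @return list with \code{coefficients} (named) and \code{intercept}.
#' @export
fit_ridge <- function(X, y, lambda) {
  if (lambda <= 0) stop_config("lambda must be positive")
  if (length(unique(y)) < 2L)
    stop_config("one-vs-rest outcome must contain both classes")
  cx <- colMeans(X)
  cy <- mean(y)
  Xc <- sweep(X, 2, cx)
  A <- crossprod(Xc)
  diag(A) <- diag(A) + lambda
  beta <- drop(solve(A, crossprod(Xc, y - cy)))
  names(beta) <- colnames(X)
  list(coefficients = beta, intercept = cy - sum(cx * beta))
}

#' Log-spaced ridge penalty grid
#' @param n number of penalties (default 100).
#' @param range lower and upper penalty bounds.
#' @return numeric vector of length \code{n}.
#' @export
penalty_grid <- function(n = 100L, range = c(1e-4, 1e4)) {
  exp(seq(log(range[1]), log(range[2]), length.out = n))
}

#' Characterize one cluster with a grid of one-versus-rest ridge models
#'
#' Fits one ridge model per penalty value with the outcome indicating
#' membership in the given cluster versus membership in any other cluster
#' (noise points are excluded from both classes), averages the coefficient
#' vectors element-wise across the grid, and normalizes the average to unit
#' maximum absolute value so that profiles are comparable across clusters.
#'
#' @param X standardized feature matrix (all patients).
#' @param labels integer cluster labels (0 = noise).
#' @param cluster_id the cluster to profile.
#' @param grid penalty grid; a length other than 100 triggers a warning but
#'   proceeds.
#' @return object of class \code{cluster_profile}: normalized
#'   \code{coefficients}, the grid, and \code{n_members}.
#' @export
profile_cluster <- function(X, labels, cluster_id, grid = penalty_grid()) {
  if (length(grid) != 100L)
    warning(sprintf("penalty grid has %d values (reference design uses 100)",
                    length(grid)), call. = FALSE)
  keep <- labels > 0L
  Xk <- X[keep, , drop = FALSE]
  y <- as.integer(labels[keep] == cluster_id)
  if (!any(y == 1L)) stop_config("cluster %s is empty", cluster_id)
  if (!any(y == 0L)) stop_config("no rest class to contrast against")
  cx <- colMeans(Xk)
  Xc <- sweep(Xk, 2, cx)
  XtX <- crossprod(Xc)
  Xty <- crossprod(Xc, y - mean(y))
  acc <- numeric(ncol(Xk))
  for (lam in grid) {
    A <- XtX
    diag(A) <- diag(A) + lam
    acc <- acc + drop(solve(A, Xty))
  }
  avg <- acc / length(grid)
  m <- max(abs(avg))
  coefs <- if (m > 0) avg / m else avg
  names(coefs) <- colnames(X)
  structure(list(cluster_id = cluster_id, coefficients = coefs,
                 penalty_grid = grid, n_members = sum(y)),
            class = "cluster_profile")
}

#' Profile every cluster
#' @param X standardized feature matrix.
#' @param labels integer cluster labels (0 = noise).
#' @param grid penalty grid.
#' @return named list of \code{cluster_profile} objects.
#' @export
profile_clusters <- function(X, labels, grid = penalty_grid()) {
  ids <- sort(setdiff(unique(labels), 0L))
  profiles <- lapply(ids, function(k) profile_cluster(X, labels, k, grid))
  names(profiles) <- as.character(ids)
  profiles
}

#' Cross-cluster coefficient-range variable importance
#'
#' For each variable, the range (maximum minus minimum) of its normalized
#' coefficient across cluster profiles; variables with the 20 largest
#' ranges are flagged. A large range marks a variable that separates at
#' least one cluster from the rest.
#'
#' @param profiles list of \code{cluster_profile} objects (at least 2).
#' @param n_top number of variables to flag (default 20).
#' @return data.frame of class \code{importance_table}: \code{variable},
#'   \code{range}, \code{rank}, \code{top20}, sorted by descending range
#'   with ties broken by the fixed variable order.
#' @export
importance_ranges <- function(profiles, n_top = 20L) {
  if (length(profiles) < 2L) stop_config("need at least 2 profiles")
  M <- vapply(profiles, function(p) p$coefficients,
              numeric(length(profiles[[1]]$coefficients)))
  rng <- apply(M, 1, max) - apply(M, 1, min)
  ord <- order(-rng, seq_along(rng))
  out <- data.frame(variable = rownames(M)[ord], range = rng[ord],
                    rank = seq_along(rng),
                    top20 = seq_along(rng) <= min(n_top, length(rng)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("importance_table", "data.frame")
  out
}

# map a feature domain to a cluster category; clinical domains collapse to
# "comorbidity", matching how mixed lab/utilization-driven clusters are
# conventionally categorized
domain_category <- function(domain) {
  ifelse(domain %in% c("sociodemographic", "psychobehavioral"),
         domain, "comorbidity")
}

#' Automated cluster label evidence
#'
#' For each cluster, reports the five variables with the largest absolute
#' normalized coefficients (with sign and domain tag) and suggests a
#' category — comorbidity, sociodemographic, or psychobehavioral — as the
#' majority category among them. A tie between categories reports all tied
#' categories rather than silently choosing one; final human-readable
#' labels remain a manual act on this evidence.
#'
#' @param profiles list of \code{cluster_profile} objects.
#' @param domains named character vector mapping variables to domain tags.
#' @param n_evidence evidence list length (default 5).
#' @return named list per cluster with \code{evidence} (data.frame of
#'   variable, coefficient, domain) and \code{suggested_category}
#'   (character vector; length > 1 on ties).
#' @export
suggest_labels <- function(profiles, domains, n_evidence = 5L) {
  lapply(profiles, function(p) {
    ord <- order(-abs(p$coefficients), seq_along(p$coefficients))
    top <- ord[seq_len(min(n_evidence, length(ord)))]
    ev <- data.frame(variable = names(p$coefficients)[top],
                     coefficient = unname(p$coefficients[top]),
                     domain = unname(domains[names(p$coefficients)[top]]),
                     stringsAsFactors = FALSE)
    ev$category <- domain_category(ev$domain)
    tab <- table(ev$category)
    best <- names(tab)[tab == max(tab)]
    list(cluster_id = p$cluster_id, evidence = ev,
         suggested_category = best)
  })
}

#' Write cluster profiles, importance table and label evidence
#' @param profiles list of \code{cluster_profile}s.
#' @param importance an \code{importance_table}.
#' @param evidence output of [suggest_labels()].
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_profiles <- function(profiles, importance, evidence, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  prof_path <- file.path(dir, "cluster_profiles.tsv")
  long <- do.call(rbind, lapply(profiles, function(p)
    data.frame(cluster = p$cluster_id, variable = names(p$coefficients),
               coefficient = unname(p$coefficients),
               stringsAsFactors = FALSE)))
  utils::write.table(long, prof_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  imp_path <- file.path(dir, "importance.tsv")
  utils::write.table(importance, imp_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  ev_path <- file.path(dir, "label_evidence.json")
  jsonlite::write_json(evidence, ev_path, auto_unbox = TRUE, digits = NA)
  invisible(c(prof_path, imp_path, ev_path))
}
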