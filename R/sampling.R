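#' Define a risk-stratified subsampling plan
#'
#' Describes how to draw several disjoint analysis sets from a high-risk
#' population while preserving its risk-percentile distribution: strata are
#' half-open percentile intervals of fixed width starting at the high-risk
#' threshold (the top stratum absorbs percentile 99), per-stratum
#' allocations use largest-remainder rounding so each set has exactly
#' \code{set_size} patients, and exactly one set is reserved for validation.
#'
#' @param n_sets number of disjoint sets (10 training + 1 validation in the
#'   reference design).
#' @param set_size patients per set.
#' @param stratum_width width of each risk-percentile stratum (default 5).
#' @param high_risk_threshold lower percentile bound of the population.
#' @param n_validation number of validation sets (must be 1).
#' @param seed integer seed.
#' @return object of class \code{sample_plan}.
#' @export
sample_plan <- function(n_sets = 11L, set_size = 10000L, stratum_width = 5L,
                        high_risk_threshold = 75L, n_validation = 1L,
                        seed = 1L) {
  if (n_validation != 1L) stop_config("exactly one validation set is required")
  if (n_sets < 1L || set_size < 1L || stratum_width < 1L)
    stop_config("n_sets, set_size and stratum_width must be positive")
  roles <- c(rep("train", n_sets - 1L), "validation")
  structure(list(n_sets = as.integer(n_sets), set_size = as.integer(set_size),
                 stratum_width = as.integer(stratum_width),
                 high_risk_threshold = as.integer(high_risk_threshold),
                 roles = roles, seed = as.integer(seed)),
            class = "sample_plan")
}

# Largest-remainder apportionment of `total` across proportions `p`.
largest_remainder <- function(p, total) {
  quota <- p / sum(p) * total
  alloc <- floor(quota)
  short <- total - sum(alloc)
  if (short > 0L) {
    rem <- quota - alloc
    top <- order(rem, seq_along(rem), decreasing = c(TRUE, FALSE),
                 method = "radix")[seq_len(short)]
    alloc[top] <- alloc[top] + 1L
  }
  as.integer(alloc)
}

#' Draw disjoint risk-stratified subsamples
#'
#' Samples \code{n_sets} pairwise-disjoint sets without replacement across
#' all sets, allocating patients to each set per stratum via
#' largest-remainder rounding of the population stratum proportions.
#'
#' @param population data.frame with columns \code{patient_id} and
#'   \code{risk_percentile}.
#' @param plan a [sample_plan()].
#' @return list of class \code{sample_sets}: \code{sets} (list of
#'   data.frames with \code{patient_id}, \code{risk_percentile}),
#'   \code{roles}, \code{strata} breaks, and per-set stratum counts.
#' @export
stratified_sample <- function(population, plan) {
  stopifnot(inherits(plan, "sample_plan"),
            all(c("patient_id", "risk_percentile") %in% names(population)))
  thr <- plan$high_risk_threshold
  if (any(population$risk_percentile < thr))
    stop_config("population contains percentiles below the high-risk threshold")
  need <- plan$n_sets * plan$set_size
  if (nrow(population) < need)
    stop_config("population (%d) smaller than n_sets x set_size (%d)",
                nrow(population), need)
  breaks <- seq(thr, 100L, by = plan$stratum_width)
  if (breaks[length(breaks)] < 100L) breaks <- c(breaks, 100L)
  stratum <- cut(population$risk_percentile, breaks = breaks, right = FALSE,
                 include.lowest = FALSE)
  # percentile 99 belongs in the top stratum; cut() above already includes
  # it because the final break is 100 and intervals are [a, b)
  counts <- table(stratum)
  props <- as.numeric(counts) / nrow(population)
  alloc <- largest_remainder(props, plan$set_size)
  names(alloc) <- names(counts)
  if (any(alloc * plan$n_sets > as.numeric(counts))) {
    bad <- names(counts)[alloc * plan$n_sets > as.numeric(counts)]
    stop_config("stratum exhausted: %s", paste(bad, collapse = ", "))
  }
  sets <- replicate(plan$n_sets,
                    vector("character", 0), simplify = FALSE)
  with_seed(plan$seed, {
    for (s in names(counts)) {
      ids <- population$patient_id[!is.na(stratum) & stratum == s]
      ids <- sample(ids)  # one shuffle, then deal consecutive blocks
      k <- alloc[[s]]
      if (k == 0L) next
      for (m in seq_len(plan$n_sets)) {
        take <- ids[((m - 1L) * k + 1L):(m * k)]
        sets[[m]] <- c(sets[[m]], take)
      }
    }
  })
  sets <- lapply(sets, function(ids) {
    population[match(ids, population$patient_id),
               c("patient_id", "risk_percentile")]
  })
  stratum_counts <- t(vapply(sets, function(df)
    as.integer(table(cut(df$risk_percentile, breaks = breaks,
                         right = FALSE))), integer(length(counts))))
  colnames(stratum_counts) <- names(counts)
  structure(list(sets = sets, roles = plan$roles, strata = breaks,
                 stratum_counts = stratum_counts, plan = plan),
            class = "sample_sets")
}

#' @export
print.sample_sets <- function(x, ...) {
  cat(sprintf("sample_sets: %d disjoint sets of %d (%d train, %d validation)\n",
              length(x$sets), nrow(x$sets[[1]]),
              sum(x$roles == "train"), sum(x$roles == "validation")))
  invisible(x)
}

#' Write sample sets as per-set id lists plus a JSON manifest
#' @param samples a \code{sample_sets} object.
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_sample_sets <- function(samples, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (m in seq_along(samples$sets)) {
    p <- file.path(dir, sprintf("set_%02d_%s.tsv", m, samples$roles[m]))
    utils::write.table(samples$sets[[m]], p, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    paths <- c(paths, p)
  }
  manifest <- file.path(dir, "sampling_manifest.json")
  jsonlite::write_json(list(roles = samples$roles,
                            strata = samples$strata,
                            stratum_counts = samples$stratum_counts,
                            seed = samples$plan$seed),
                       manifest, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, manifest))
}
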