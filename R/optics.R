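#' OPTICS configuration
#'
#' @param min_pts minimum neighborhood size defining a core point (the core
#'   distance is the distance to the min_pts-th nearest neighbor, counting
#'   the point itself).
#' @param eps generating distance bound; \code{Inf} considers all neighbors.
#' @param extraction list describing cluster extraction: either
#'   \code{list(mode = "xi", xi = 0.05)} for steep-area extraction,
#'   \code{list(mode = "cut", eps_prime = <value>)} for a flat reachability
#'   cut, or \code{list(mode = "cut", quantile = <q>)} to place the cut at a
#'   quantile of the finite reachability values.
#' @param seed optional integer (reserved for tie shuffling; ties are broken
#'   by point index by default, which is deterministic).
#' @return object of class \code{optics_config}.
#' @export
optics_config <- function(min_pts = 25L, eps = Inf,
                          extraction = list(mode = "xi", xi = 0.05),
                          seed = NULL) {
  if (min_pts < 2L) stop_config("min_pts must be >= 2")
  if (!is.null(extraction)) {
    if (is.null(extraction$mode) || !extraction$mode %in% c("xi", "cut"))
      stop_config("extraction mode must be 'xi' or 'cut'")
    if (extraction$mode == "xi" &&
        (is.null(extraction$xi) || extraction$xi <= 0 || extraction$xi >= 1))
      stop_config("xi must be in (0, 1)")
    if (extraction$mode == "cut" && is.null(extraction$eps_prime) &&
        is.null(extraction$quantile))
      stop_config("cut extraction needs eps_prime or quantile")
    if (!is.null(extraction$eps_prime) && extraction$eps_prime > eps)
      stop_config("cut threshold must not exceed eps")
  }
  structure(list(min_pts = as.integer(min_pts), eps = eps,
                 extraction = extraction, seed = seed),
            class = "optics_config")
}

#' Compute the OPTICS ordering and reachability profile
#'
#' Standard OPTICS: each point's core distance is the distance to its
#' min_pts-th nearest neighbor (undefined when fewer than min_pts neighbors
#' lie within \code{eps}); points are processed through a priority queue
#' keyed by smallest reachability, with ties broken by point index, so the
#' ordering is deterministic for a fixed input order.
#'
#' @param points n x d coordinate matrix (finite values).
#' @param config an [optics_config()].
#' @return object of class \code{optics_result}: \code{order} (a
#'   permutation), \code{reachability} and \code{core_distance} (per point,
#'   \code{NA} = undefined), \code{labels} (empty until
#'   [extract_clusters()]), and the config.
#' @export
optics_order <- function(points, config = optics_config()) {
  points <- as.matrix(points)
  if (!all(is.finite(points))) stop_config("coordinates must be finite")
  n <- nrow(points)
  if (n < config$min_pts)
    stop_config("need at least min_pts = %d points", config$min_pts)
  D <- as.matrix(stats::dist(points))
  eps <- config$eps
  k <- config$min_pts
  core <- unname(apply(D, 1, function(d) sort(d, partial = k)[k]))
  if (is.finite(eps)) core[core > eps] <- NA_real_
  reach <- rep(NA_real_, n)
  processed <- logical(n)
  in_seeds <- logical(n)
  ord <- integer(n)
  pos <- 0L
  update_seeds <- function(p) {
    if (is.na(core[p])) return(invisible())
    nb <- which(!processed & D[p, ] <= eps)
    if (!length(nb)) return(invisible())
    newreach <- pmax(core[p], D[p, nb])
    better <- is.na(reach[nb]) | newreach < reach[nb]
    reach[nb[better]] <<- newreach[better]
    in_seeds[nb[better]] <<- TRUE
  }
  for (start in seq_len(n)) {
    if (processed[start]) next
    p <- start
    repeat {
      processed[p] <- TRUE
      in_seeds[p] <- FALSE
      pos <- pos + 1L
      ord[pos] <- p
      update_seeds(p)
      cand <- which(in_seeds)
      if (!length(cand)) break
      p <- cand[which.min(reach[cand])]  # which.min: lowest index on ties
    }
  }
  structure(list(order = ord, reachability = reach, core_distance = core,
                 labels = NULL, config = config, points = points),
            class = "optics_result")
}

# maximal steep region starting at `i` going in direction dir (-1 = down,
# +1 = up): monotone in dir with at most min_pts - 1 consecutive non-steep
# points, ending at the last steep point.
steep_region <- function(r, i, dir, xi, min_pts) {
  n <- length(r)
  steep <- function(j) {
    if (j >= n) return(FALSE)
    if (dir < 0) r[j] * (1 - xi) >= r[j + 1] else r[j] <= r[j + 1] * (1 - xi)
  }
  mono <- function(j) if (dir < 0) r[j + 1] <= r[j] else r[j + 1] >= r[j]
  end <- i
  j <- i
  flat <- 0L
  while (j < n) {
    if (!mono(j)) break
    if (steep(j)) { flat <- 0L; end <- j + 1L } else {
      flat <- flat + 1L
      if (flat >= min_pts) break
    }
    j <- j + 1L
  }
  c(start = i, end = end)
}

#' Extract flat cluster labels from an OPTICS ordering
#'
#' Cut mode walks the ordering with a reachability threshold: a point with
#' reachability within the threshold joins the current cluster; a point
#' beyond it starts a new cluster if its own core distance is within the
#' threshold and is otherwise noise. Xi mode extracts clusters between
#' xi-steep down and up areas of the reachability profile; the hierarchy is
#' flattened by letting the outermost non-trivial interval win. In both
#' modes clusters smaller than min_pts are dissolved to noise, which
#' carries the reserved label 0.
#'
#' @param result an \code{optics_result}.
#' @param extraction extraction config (defaults to the one in the result's
#'   config).
#' @return the result with \code{labels} filled: integer per point, 0 =
#'   noise.
#' @export
extract_clusters <- function(result, extraction = NULL) {
  stopifnot(inherits(result, "optics_result"))
  extraction <- extraction %||% result$config$extraction
  if (is.null(extraction)) stop_config("no extraction configuration")
  n <- length(result$order)
  min_pts <- result$config$min_pts
  ord <- result$order
  r_ord <- result$reachability[ord]
  labels <- integer(n)
  if (extraction$mode == "cut") {
    eps_prime <- extraction$eps_prime
    if (is.null(eps_prime)) {
      fin <- r_ord[is.finite(r_ord)]
      if (!length(fin)) fin <- 0
      eps_prime <- stats::quantile(fin, extraction$quantile, names = FALSE)
    }
    cur <- 0L; next_id <- 0L
    for (i in seq_len(n)) {
      p <- ord[i]
      r <- r_ord[i]
      if (is.na(r) || r > eps_prime) {
        cd <- result$core_distance[p]
        if (!is.na(cd) && cd <= eps_prime) {
          next_id <- next_id + 1L
          cur <- next_id
          labels[p] <- cur
        } else {
          cur <- 0L
          labels[p] <- 0L
        }
      } else {
        if (cur == 0L) { next_id <- next_id + 1L; cur <- next_id }
        labels[p] <- cur
      }
    }
    attr(labels, "eps_prime") <- eps_prime
  } else {
    xi <- extraction$xi
    r <- ifelse(is.na(r_ord), Inf, r_ord)
    rr <- c(r, Inf)  # sentinel for boundary conditions
    sdas <- list()
    clusters <- list()
    mib <- 0
    i <- 1L
    is_sd <- function(j) rr[j] * (1 - xi) >= rr[j + 1]
    is_su <- function(j) rr[j] <= rr[j + 1] * (1 - xi)
    filter_sdas <- function(sdas, mib) {
      Filter(function(D) rr[D["start"]] * (1 - xi) >= D["mib"],
             lapply(sdas, function(D) { D["mib"] <- max(D["mib"], mib); D }))
    }
    while (i < n) {
      mib <- max(mib, rr[i])
      if (is_sd(i)) {
        sdas <- filter_sdas(sdas, mib)
        Dn <- steep_region(rr[seq_len(n)], i, -1L, xi, min_pts)
        Dn["mib"] <- 0
        sdas <- c(sdas, list(Dn))
        i <- unname(Dn["end"]) + 1L
        mib <- rr[min(i, n)]
      } else if (is_su(i)) {
        sdas <- filter_sdas(sdas, mib)
        U <- steep_region(rr[seq_len(n)], i, 1L, xi, min_pts)
        i <- unname(U["end"]) + 1L
        mib <- rr[min(i, n)]
        r_end <- rr[unname(U["end"]) + 1L]
        for (Dn in sdas) {
          if (Dn["mib"] > min(rr[Dn["start"]], r_end) * (1 - xi)) next
          s <- unname(Dn["start"]); e <- unname(U["end"])
          if (rr[s] * (1 - xi) >= r_end) {
            cand <- which(rr[s:unname(Dn["end"])] > r_end)
            if (length(cand)) s <- s + max(cand) - 1L
          } else if (r_end * (1 - xi) >= rr[s]) {
            cand <- which(rr[unname(U["start"]):e] < rr[s])
            if (length(cand)) e <- unname(U["start"]) + max(cand) - 1L
              else next
          }
          if (e - s + 1L >= min_pts)
            clusters <- c(clusters, list(c(s, e)))
        }
      } else i <- i + 1L
    }
    # flatten the hierarchy: drop the trivial full-span interval, then let
    # the outermost containing interval win so uniform-density regions are
    # not carved up by incidental nested wiggles
    clusters <- Filter(function(cl) !(cl[1] == 1L && cl[2] == n), clusters)
    if (length(clusters)) {
      sizes <- vapply(clusters, function(cl) cl[2] - cl[1] + 1L, numeric(1))
      for (ci in order(sizes, decreasing = FALSE)) {
        cl <- clusters[[ci]]
        labels[ord[cl[1]:cl[2]]] <- ci
      }
      labels <- match(labels, sort(unique(labels[labels > 0L])))
      labels[is.na(labels)] <- 0L
    }
  }
  # dissolve undersized clusters
  tab <- table(labels[labels > 0L])
  small <- as.integer(names(tab)[tab < min_pts])
  labels[labels %in% small] <- 0L
  keep <- sort(unique(labels[labels > 0L]))
  labels[labels > 0L] <- match(labels[labels > 0L], keep)
  ep <- attr(labels, "eps_prime")
  labels <- as.integer(labels)
  result$labels <- labels
  result$eps_prime <- ep
  result
}

#' @export
print.optics_result <- function(x, ...) {
  cat(sprintf("optics_result: %d points ordered (min_pts = %d)\n",
              length(x$order), x$config$min_pts))
  if (!is.null(x$labels)) {
    k <- length(setdiff(unique(x$labels), 0L))
    cat(sprintf("  %d clusters, %.1f%% noise\n", k,
                100 * mean(x$labels == 0L)))
  }
  invisible(x)
}

#' Default hyperparameter grid for OPTICS tuning
#'
#' Candidates over the neighborhood size and the reachability-cut quantile.
#' Because the cut quantile directly bounds the clustered fraction from
#' above, the candidate quantiles bracket one minus the tuner's noise
#' target (0.75 by default) rather than spanning the whole unit interval.
#'
#' @param min_pts candidate neighborhood sizes.
#' @param quantile candidate reachability-cut quantiles.
#' @return data.frame grid in a fixed order.
#' @export
default_tuning_grid <- function(min_pts = c(5L, 10L, 15L, 20L),
                                quantile = c(0.60, 0.65, 0.70,
                                             0.75, 0.80)) {
  expand.grid(min_pts = min_pts, quantile = quantile,
              KEEP.OUT.ATTRS = FALSE)
}

#' Tune OPTICS hyperparameters across training embeddings
#'
#' Clusters every training embedding under each candidate and scores the
#' candidate by the median, across sets, of the mean silhouette of
#' clustered points minus a penalty for deviating from the target noise
#' fraction. A candidate that clusters nothing anywhere scores -Inf and is
#' never selected unless every candidate fails, which is an error. Ties are
#' broken by grid order, so the choice is deterministic.
#'
#' @param embeddings list of n x 2 coordinate matrices (or
#'   \code{tsne_embedding} objects).
#' @param grid data.frame of candidates from [default_tuning_grid()].
#' @param noise_target desired noise fraction (default 0.25).
#' @param lambda_noise penalty weight on |noise fraction - target|.
#' @return list with \code{config} (the chosen [optics_config()]),
#'   \code{scores} (the full score table) and \code{best} (row index).
#' @export
tune_hyperparameters <- function(embeddings, grid = default_tuning_grid(),
                                 noise_target = 0.25, lambda_noise = 0.5) {
  if (nrow(grid) < 1L) stop_config("empty candidate grid")
  if (length(embeddings) < 2L) stop_config("need at least 2 training sets")
  coords <- lapply(embeddings, function(e)
    if (inherits(e, "tsne_embedding")) e$coordinates else as.matrix(e))
  scores <- numeric(nrow(grid))
  details <- vector("list", nrow(grid))
  for (gi in seq_len(nrow(grid))) {
    cfg <- optics_config(min_pts = grid$min_pts[gi],
                         extraction = list(mode = "cut",
                                           quantile = grid$quantile[gi]))
    per_set <- vapply(coords, function(pts) {
      res <- extract_clusters(optics_order(pts, cfg))
      labs <- res$labels
      clustered <- labs > 0L
      if (!any(clustered)) return(-Inf)
      noise_frac <- mean(!clustered)
      k <- length(unique(labs[clustered]))
      sil <- if (k >= 2L) {
        mean(cluster::silhouette(labs[clustered],
                                 stats::dist(pts[clustered, ,
                                                 drop = FALSE]))[, 3])
      } else 0
      sil - lambda_noise * abs(noise_frac - noise_target)
    }, numeric(1))
    scores[gi] <- stats::median(per_set)
    details[[gi]] <- per_set
  }
  if (all(!is.finite(scores)))
    stop_config("every candidate clustered nothing on every training set")
  best <- which.max(scores)  # first max in grid order
  list(config = optics_config(min_pts = grid$min_pts[best],
                              extraction = list(mode = "cut",
                                                quantile =
                                                  grid$quantile[best])),
       scores = cbind(grid, score = scores),
       per_set = details, best = best)
}

#' Write reachability profile and labels
#' @param result a labeled \code{optics_result}.
#' @param dir output directory.
#' @param ids optional patient ids (defaults to row numbers).
#' @return invisibly, the paths written.
#' @export
write_clustering <- function(result, dir, ids = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(result$order)
  ids <- ids %||% as.character(seq_len(n))
  reach_path <- file.path(dir, "reachability.tsv")
  utils::write.table(
    data.frame(position = seq_len(n), patient_id = ids[result$order],
               reachability = result$reachability[result$order],
               core_distance = result$core_distance[result$order]),
    reach_path, sep = "\t", row.names = FALSE, quote = FALSE)
  labels_path <- file.path(dir, "labels.tsv")
  lab <- result$labels
  utils::write.table(
    data.frame(patient_id = ids,
               cluster = ifelse(lab == 0L, "noise", as.character(lab))),
    labels_path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(reach_path, labels_path))
}
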