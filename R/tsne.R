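#' t-SNE configuration
#'
#' Hyperparameters for the exact (quadratic-cost) t-SNE implementation used
#' to map the standardized feature matrix to two dimensions. Defaults are
#' the widely used published settings: perplexity 30, 1,000 iterations,
#' early exaggeration factor 12 for 250 iterations, learning rate 200, and
#' a momentum switch from 0.5 to 0.8 at iteration 250.
#'
#' @param perplexity effective neighborhood size; must be < n - 1.
#' @param n_iterations total gradient-descent iterations.
#' @param exaggeration early-exaggeration multiplier on the input
#'   similarities.
#' @param exaggeration_iter duration (iterations) of the exaggeration phase;
#'   must be < \code{n_iterations}.
#' @param learning_rate gradient step size.
#' @param momentum length-2 vector: initial and final momentum.
#' @param momentum_switch iteration at which momentum switches.
#' @param seed integer seed for the random initialization.
#' @return object of class \code{tsne_config}.
#' @export
tsne_config <- function(perplexity = 30, n_iterations = 1000L,
                        exaggeration = 12, exaggeration_iter = 250L,
                        learning_rate = 200, momentum = c(0.5, 0.8),
                        momentum_switch = 250L, seed = 1L) {
  if (exaggeration_iter >= n_iterations)
    stop_config("exaggeration phase must be shorter than the full run")
  if (perplexity < 1) stop_config("perplexity must be >= 1")
  structure(list(perplexity = perplexity,
                 n_iterations = as.integer(n_iterations),
                 exaggeration = exaggeration,
                 exaggeration_iter = as.integer(exaggeration_iter),
                 learning_rate = learning_rate, momentum = momentum,
                 momentum_switch = as.integer(momentum_switch),
                 seed = as.integer(seed), output_dim = 2L),
            class = "tsne_config")
}

#' Calibrate per-point Gaussian bandwidths to a target perplexity
#'
#' For each point, binary-searches the Gaussian bandwidth until the Shannon
#' entropy H of the conditional neighbor distribution p(.|i) satisfies
#' 2^H = perplexity within tolerance (at most 50 bisection steps after
#' bracketing). Self-probabilities are zero and each row sums to one.
#'
#' @param D2 symmetric matrix of squared distances with zero diagonal.
#' @param perplexity target perplexity, in [1, n - 1].
#' @param tol absolute tolerance on the achieved perplexity.
#' @return list with \code{P} (row-stochastic conditional matrix),
#'   \code{sigma} (per-point bandwidths) and \code{residual}
#'   (|achieved - target| perplexity per point).
#' @export
calibrate_bandwidths <- function(D2, perplexity, tol = 1e-5) {
  n <- nrow(D2)
  if (!all(is.finite(D2))) stop_config("non-finite distances")
  if (perplexity > n - 1) stop_config("perplexity must be <= n - 1")
  P <- matrix(0, n, n)
  sigma <- numeric(n)
  residual <- numeric(n)
  log_target <- log(perplexity)
  for (i in seq_len(n)) {
    d <- D2[i, -i]
    d <- d - min(d)  # entropy is shift-invariant; avoids underflow
    beta <- 1; beta_min <- -Inf; beta_max <- Inf
    for (step in seq_len(50L)) {
      w <- exp(-d * beta)
      sw <- sum(w)
      H <- log(sw) + beta * sum(d * w) / sw
      if (abs(exp(H) - perplexity) < tol) break
      if (H > log_target) {  # too entropic: narrow the kernel
        beta_min <- beta
        beta <- if (is.finite(beta_max)) (beta + beta_max) / 2 else beta * 2
      } else {
        beta_max <- beta
        beta <- if (is.finite(beta_min)) (beta + beta_min) / 2 else beta / 2
      }
    }
    p <- w / sw
    P[i, -i] <- p
    sigma[i] <- sqrt(1 / (2 * beta))
    residual[i] <- abs(exp(H) - perplexity)
  }
  list(P = P, sigma = sigma, residual = residual)
}

#' Symmetrized joint probabilities from conditionals
#'
#' P = (p(j|i) + p(i|j)) / (2n): symmetric, nonnegative, total mass one.
#'
#' @param conditionals row-stochastic matrix of conditional probabilities.
#' @return symmetric joint probability matrix.
#' @export
joint_probabilities <- function(conditionals) {
  n <- nrow(conditionals)
  (conditionals + t(conditionals)) / (2 * n)
}

#' KL divergence and its exact gradient for a t-SNE layout
#'
#' Computes KL(P || Q) under the Student-t (one degree of freedom)
#' low-dimensional kernel together with the exact analytic gradient with
#' respect to the embedding coordinates.
#'
#' @param P joint probability matrix.
#' @param Y n x 2 coordinate matrix.
#' @return list with \code{kl} and \code{grad} (n x 2).
#' @export
tsne_gradient <- function(P, Y) {
  n <- nrow(Y)
  sq <- rowSums(Y^2)
  D2 <- outer(sq, sq, "+") - 2 * tcrossprod(Y)
  Qnum <- 1 / (1 + D2)
  diag(Qnum) <- 0
  Z <- sum(Qnum)
  Q <- Qnum / Z
  W <- (P - Q) * Qnum
  grad <- 4 * (rowSums(W) * Y - W %*% Y)
  Pc <- pmax(P, 1e-12)
  Qc <- pmax(Q, 1e-12)
  kl <- sum(P * (log(Pc) - log(Qc)))
  list(kl = kl, grad = grad)
}

#' Gradient-descent optimization of a t-SNE embedding
#'
#' Minimizes KL(P || Q) with momentum, per-coordinate adaptive gains, and
#' early exaggeration. After the exaggeration phase the step is guarded:
#' an update that would increase the (unexaggerated) KL resets the momentum
#' and backtracks the step size, so the recorded trace is non-increasing
#' from that point on. Exact quadratic-cost gradients throughout.
#'
#' @param P joint probability matrix from [joint_probabilities()].
#' @param config a [tsne_config()].
#' @return object of class \code{tsne_embedding}: \code{coordinates}
#'   (n x 2), \code{kl_trace} (KL against the unexaggerated P at every
#'   iteration), and the config snapshot.
#' @export
tsne_embed <- function(P, config = tsne_config()) {
  n <- nrow(P)
  with_seed(config$seed, {
    Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
    V <- matrix(0, n, 2)
    gains <- matrix(1, n, 2)
    kl_trace <- numeric(config$n_iterations)
    step_scale <- 1
    g <- tsne_gradient(P, Y)
    kl_prev <- g$kl
    for (iter in seq_len(config$n_iterations)) {
      exag <- iter <= config$exaggeration_iter
      P_use <- if (exag) P * config$exaggeration else P
      mom <- if (iter < config$momentum_switch) config$momentum[1]
             else config$momentum[2]
      g_opt <- if (exag) tsne_gradient(P_use, Y) else g
      repeat {
        flip <- sign(g_opt$grad) != sign(V)
        gains_new <- ifelse(flip, gains + 0.2, gains * 0.8)
        gains_new[gains_new < 0.01] <- 0.01
        V_new <- mom * V -
          config$learning_rate * step_scale * gains_new * g_opt$grad
        Y_new <- Y + V_new
        Y_new <- sweep(Y_new, 2, colMeans(Y_new))
        if (!all(is.finite(Y_new)))
          stop_config("t-SNE diverged at iteration %d", iter)
        g_new <- tsne_gradient(P, Y_new)
        if (exag || g_new$kl <= kl_prev + 1e-9) {
          Y <- Y_new; V <- V_new; gains <- gains_new
          g <- g_new
          step_scale <- min(1, step_scale * 1.2)
          break
        }
        # backtrack: kill momentum, shrink the step
        V <- matrix(0, n, 2)
        step_scale <- step_scale / 2
        if (step_scale < 1e-8) { g <- tsne_gradient(P, Y); break }
      }
      kl_prev <- g$kl
      kl_trace[iter] <- g$kl
    }
    structure(list(coordinates = Y, kl_trace = kl_trace, config = config),
              class = "tsne_embedding")
  })
}

#' Embed a standardized feature matrix in two dimensions
#'
#' Full t-SNE front-to-back: Euclidean squared distances on the
#' standardized matrix, per-point bandwidth calibration to the target
#' perplexity, symmetrization, and gradient-descent optimization.
#'
#' @param X standardized numeric matrix (rows = patients).
#' @param config a [tsne_config()].
#' @return a \code{tsne_embedding} whose coordinates carry the input
#'   rownames, with per-point calibration residuals attached.
#' @export
embed_tsne <- function(X, config = tsne_config()) {
  D2 <- as.matrix(stats::dist(X))^2
  cal <- calibrate_bandwidths(D2, config$perplexity)
  P <- joint_probabilities(cal$P)
  emb <- tsne_embed(P, config)
  rownames(emb$coordinates) <- rownames(X)
  emb$calibration_residual <- cal$residual
  emb$sigma <- cal$sigma
  emb
}

#' @export
print.tsne_embedding <- function(x, ...) {
  cat(sprintf("tsne_embedding: %d points, final KL = %.4f\n",
              nrow(x$coordinates), x$kl_trace[length(x$kl_trace)]))
  invisible(x)
}

#' Write embedding coordinates and run metadata
#' @param embedding a \code{tsne_embedding}.
#' @param dir output directory.
#' @param name file stem.
#' @return invisibly, the paths written.
#' @export
write_embedding <- function(embedding, dir, name = "embedding") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  co <- file.path(dir, paste0(name, ".tsv"))
  ids <- rownames(embedding$coordinates) %||%
    as.character(seq_len(nrow(embedding$coordinates)))
  utils::write.table(
    data.frame(patient_id = ids, x = embedding$coordinates[, 1],
               y = embedding$coordinates[, 2]),
    co, sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- file.path(dir, paste0(name, "_meta.json"))
  jsonlite::write_json(list(config = unclass(embedding$config),
                            kl_trace = embedding$kl_trace),
                       meta, auto_unbox = TRUE, digits = NA)
  invisible(c(co, meta))
}
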