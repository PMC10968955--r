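#' Define a known pairwise mixed graphical model
#'
#' Ground-truth generating model for recovery experiments: a pairwise
#' Markov random field whose continuous nodes have linear-Gaussian full
#' conditionals (conditional variance `variances`, conditional mean
#' `thresholds + variances * (W x)`) and whose binary nodes have logistic
#' full conditionals (logit `thresholds + W x`).
#'
#' @param nodes Character vector of node names.
#' @param types `"continuous"`/`"binary"` per node.
#' @param interactions Symmetric numeric matrix with zero diagonal (pairwise
#'   coupling parameters).
#' @param thresholds Per-node intercept (continuous: conditional-mean
#'   offset; binary: logit intercept). Recycled if scalar.
#' @param variances Conditional variance per continuous node (recycled if
#'   scalar); must be positive.
#' @return A `true_graph` object.
#' @export
true_graph <- function(nodes, types, interactions, thresholds = 0,
                       variances = 1) {
  p <- length(nodes)
  types <- as.character(types)
  if (length(types) != p || !all(types %in% c("continuous", "binary"))) {
    stop("types must be one of continuous/binary per node", call. = FALSE)
  }
  if (!is.matrix(interactions) || nrow(interactions) != p ||
      ncol(interactions) != p) {
    stop("interaction matrix dimension must equal the node count",
         call. = FALSE)
  }
  if (max(abs(interactions - t(interactions))) > 1e-10) {
    stop("interaction matrix must be symmetric", call. = FALSE)
  }
  if (any(diag(interactions) != 0)) {
    stop("interaction matrix must have zero diagonal", call. = FALSE)
  }
  thresholds <- rep_len(thresholds, p)
  variances <- rep_len(variances, p)
  if (any(variances[types == "continuous"] <= 0)) {
    stop("continuous variances must be > 0", call. = FALSE)
  }
  dimnames(interactions) <- list(nodes, nodes)
  g <- structure(list(nodes = nodes, types = types,
                      interactions = interactions,
                      thresholds = setNames(thresholds, nodes),
                      variances = setNames(variances, nodes)),
                 class = "true_graph")
  check_continuous_block(g)
  g
}

# the joint over the continuous block (at any fixed binary configuration)
# has precision diag(1/sigma^2) - W_cc; it must be positive definite or the
# Gibbs chain diverges
check_continuous_block <- function(graph) {
  cont <- graph$types == "continuous"
  if (!any(cont)) return(invisible(TRUE))
  K <- diag(1 / graph$variances[cont], sum(cont)) -
    graph$interactions[cont, cont, drop = FALSE]
  ev <- eigen(K, symmetric = TRUE)
  if (min(ev$values) <= 1e-10) {
    worst <- graph$nodes[cont][which.max(abs(ev$vectors[, which.min(ev$values)]))]
    stop("divergent continuous conditional: joint precision of the ",
         "continuous block is not positive definite (node ", worst, ")",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.true_graph <- function(x, ...) {
  cat("true_graph:", length(x$nodes), "nodes,",
      sum(x$interactions[upper.tri(x$interactions)] != 0), "edges\n")
  invisible(x)
}

#' Write a true graph as JSON
#'
#' @param graph A [true_graph()].
#' @param path Output path.
#' @export
write_true_graph <- function(graph, path) {
  jsonlite::write_json(
    list(nodes = graph$nodes, types = graph$types,
         interactions = graph$interactions,
         thresholds = unname(graph$thresholds),
         variances = unname(graph$variances)),
    path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' Sample from a known mixed graphical model
#'
#' Single-chain Gibbs sampler: each sweep updates every node from its full
#' conditional (linear-Gaussian for continuous nodes, logistic for binary
#' nodes given the current neighbors). After `burn_in` sweeps, one row is
#' retained every `thin` sweeps.
#'
#' @param graph A [true_graph()].
#' @param n Number of samples (rows) to return.
#' @param burn_in Burn-in sweeps (default 1000, conservative for graphs of
#'   up to ~20 nodes).
#' @param thin Keep one sample every `thin` sweeps (default 10).
#' @param seed Integer seed (draws are reproducible given the seed).
#' @return A [mixed_data()] with `n` rows.
#' @export
sample_mgm <- function(graph, n, burn_in = 1000, thin = 10, seed = 1L) {
  if (!inherits(graph, "true_graph")) stop("graph must be a true_graph",
                                           call. = FALSE)
  if (n < 1 || burn_in < 1 || thin < 1) {
    stop("n, burn_in and thin must be positive", call. = FALSE)
  }
  check_continuous_block(graph)
  set.seed(seed)
  is_bin <- as.integer(graph$types == "binary")
  init <- ifelse(is_bin == 1L, rbinom(length(graph$nodes), 1, 0.5),
                 graph$thresholds)
  x <- gibbs_mgm_cpp(is_bin, graph$interactions,
                     unname(graph$thresholds), unname(graph$variances),
                     as.integer(n), as.integer(burn_in), as.integer(thin),
                     as.numeric(init))
  colnames(x) <- graph$nodes
  mixed_data(x, graph$types)
}

#' Re-sample a cohort from a known dependence structure
#'
#' Replaces the graph-node columns of a cohort with draws from the mixed
#' graphical model `graph`, with thresholds and conditional variances
#' calibrated (by damped stochastic approximation on short Gibbs runs) so
#' the marginal means, SDs and prevalences of the original columns are
#' preserved while the requested pairwise dependence is imposed. Integer
#' columns are rounded back to integers and clipped to their original
#' observed range; columns not named in the graph pass through unchanged
#' (raw answer items are then no longer coherent with re-sampled scores).
#'
#' @param cohort Data frame whose graph-node columns are numeric (binary
#'   nodes coded 0/1).
#' @param graph A [true_graph()] whose nodes are a subset of the cohort
#'   columns.
#' @param seed Integer seed.
#' @param calibration_iter,calibration_n Iterations and sample size of the
#'   moment-matching loop.
#' @return The cohort with node columns replaced; attribute
#'   `"marginal_drift"` records the achieved absolute drift per node.
#' @export
inject_dependence <- function(cohort, graph, seed = 1L,
                              calibration_iter = 15, calibration_n = 4000) {
  stopifnot(is.data.frame(cohort), inherits(graph, "true_graph"))
  missing_nodes <- setdiff(graph$nodes, names(cohort))
  if (length(missing_nodes)) {
    stop("graph node(s) not found in cohort: ",
         paste(missing_nodes, collapse = ", "), call. = FALSE)
  }
  n <- nrow(cohort)
  p <- length(graph$nodes)
  cols <- lapply(graph$nodes, function(nd) as.numeric(cohort[[nd]]))
  names(cols) <- graph$nodes
  if (any(vapply(cols, anyNA, logical(1)))) {
    stop("node columns must be complete", call. = FALSE)
  }
  is_bin <- graph$types == "binary"
  for (j in which(is_bin)) {
    if (!all(cols[[j]] %in% c(0, 1))) {
      stop("binary node column ", graph$nodes[j], " must be coded 0/1",
           call. = FALSE)
    }
  }

  target_mean <- vapply(cols, mean, numeric(1))
  target_sd <- vapply(cols, sd, numeric(1))
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

  # the interaction matrix is read on the standardized scale: the model is
  # calibrated with continuous nodes at mean 0 / sd 1 (binary prevalences
  # as observed), then mapped back to the original units
  theta <- ifelse(is_bin, qlogis(clamp(target_mean, 0.02, 0.98)), 0)
  sig2 <- rep(1, p)

  for (it in seq_len(calibration_iter)) {
    g <- true_graph(graph$nodes, graph$types, graph$interactions,
                    thresholds = theta, variances = sig2)
    s <- sample_mgm(g, calibration_n, burn_in = 300, thin = 2,
                    seed = iteration_seed(seed, it, 7L))
    m_hat <- colMeans(s$values)
    sd_hat <- apply(s$values, 2, sd)
    damp <- 0.8
    theta[is_bin] <- theta[is_bin] + damp *
      (qlogis(clamp(target_mean[is_bin], 0.02, 0.98)) -
         qlogis(clamp(m_hat[is_bin], 0.02, 0.98)))
    theta[!is_bin] <- theta[!is_bin] - damp * m_hat[!is_bin]
    ratio <- (1 / pmax(sd_hat[!is_bin], 1e-8))^(2 * damp)
    sig2_new <- sig2
    sig2_new[!is_bin] <- sig2[!is_bin] * clamp(ratio, 0.5, 2)
    # keep the continuous block proper
    gtry <- try(true_graph(graph$nodes, graph$types, graph$interactions,
                           thresholds = theta, variances = sig2_new),
                silent = TRUE)
    if (!inherits(gtry, "try-error")) sig2 <- sig2_new
  }

  g <- true_graph(graph$nodes, graph$types, graph$interactions,
                  thresholds = theta, variances = sig2)
  s <- sample_mgm(g, n, burn_in = 1000, thin = 10, seed = seed)

  out <- cohort
  drift <- numeric(p)
  for (j in seq_len(p)) {
    v <- s$values[, j]
    orig <- cols[[j]]
    if (!is_bin[j]) {
      v <- v * target_sd[j] + target_mean[j]
      if (all(orig == round(orig))) {
        v <- clamp(round(v), min(orig), max(orig))
      }
    }
    out[[graph$nodes[j]]] <- v
    drift[j] <- abs(mean(v) - target_mean[j])
  }
  attr(out, "marginal_drift") <- setNames(drift, graph$nodes)
  attr(out, "generating_graph") <- g
  out
}
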