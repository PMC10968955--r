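# Internal: standardize continuous columns (mean 0, unit variance, using
# the 1/n variance convention of the coordinate-descent objective); binary
# columns stay 0/1.
prep_design <- function(data) {
  stopifnot(inherits(data, "mixed_data"))
  X <- data$values
  for (j in which(data$types == "continuous")) {
    s <- sd(X[, j])
    if (!is.finite(s) || s == 0) {
      stop("degenerate (zero-variance) continuous node: ", data$nodes[j],
           call. = FALSE)
    }
    X[, j] <- (X[, j] - mean(X[, j])) / s
  }
  X
}

node_response <- function(X, data, node) {
  i <- match(node, data$nodes)
  if (is.na(i)) stop("unknown node: ", node, call. = FALSE)
  list(i = i, y = X[, i], x = X[, -i, drop = FALSE],
       type = data$types[i], predictors = data$nodes[-i])
}

lambda_max_value <- function(x, y) {
  max(abs(crossprod(x, y - mean(y)))) / length(y)
}

#' Regularization grid for one node
#'
#' Log-spaced descending grid from the smallest lambda that zeroes every
#' coefficient down to `lambda_min_ratio` times it.
#'
#' @param data A [mixed_data()].
#' @param node Node name.
#' @param nlambda Grid size (default 50).
#' @param lambda_min_ratio Ratio of smallest to largest lambda (default 0.01).
#' @return Decreasing numeric vector.
#' @export
lambda_grid <- function(data, node, nlambda = 50, lambda_min_ratio = 0.01) {
  X <- prep_design(data)
  nr <- node_response(X, data, node)
  lmax <- lambda_max_value(nr$x, nr$y)
  if (lmax <= 0) lmax <- 1e-4
  exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = nlambda))
}

fit_path <- function(y, x, type, lambdas, tol = 1e-7, max_iter = 10000) {
  if (type == "continuous") {
    cd_gaussian_path(x, y, lambdas, tol, max_iter)
  } else {
    cd_logistic_path(x, y, lambdas, tol, max_iter)
  }
}

#' Nodewise L1-penalized regression
#'
#' Regresses one node on all others: a lasso linear regression for a
#' continuous node (on the standardized scale) or an L1-penalized logistic
#' regression for a binary node, solved by cyclic coordinate descent to
#' tolerance 1e-7. The intercept is unpenalized.
#'
#' @param data A [mixed_data()].
#' @param node Node name.
#' @param lambda Non-negative regularization strength.
#' @return Named coefficient vector over the remaining nodes, with
#'   attributes `intercept` and `lambda`.
#' @export
nodewise_fit <- function(data, node, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda < 0) {
    stop("lambda must be a single non-negative number", call. = FALSE)
  }
  X <- prep_design(data)
  nr <- node_response(X, data, node)
  fit <- fit_path(nr$y, nr$x, nr$type, lambda)
  if (!fit$converged[1]) {
    stop("coordinate descent did not converge for node ", node,
         " at lambda ", signif(lambda, 4), " after ", fit$iterations[1],
         " iterations", call. = FALSE)
  }
  structure(setNames(fit$beta[, 1], nr$predictors),
            intercept = fit$b0[1], lambda = lambda, type = nr$type)
}

ebic_path <- function(y, x, type, fit, gamma) {
  n <- length(y)
  p_cand <- ncol(x)
  nlam <- ncol(fit$beta)
  vapply(seq_len(nlam), function(l) {
    beta <- fit$beta[, l]
    eta <- fit$b0[l] + as.numeric(x %*% beta)
    df <- sum(beta != 0)
    if (type == "continuous") {
      rss <- sum((y - eta)^2)
      m2ll <- n * log(2 * pi * rss / n) + n
    } else {
      mu <- plogis(eta)
      mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
      m2ll <- -2 * sum(y * log(mu) + (1 - y) * log(1 - mu))
    }
    m2ll + df * log(n) + 2 * gamma * df * log(p_cand)
  }, numeric(1))
}

#' EBIC selection of the regularization strength
#'
#' Fits the full lasso path with warm starts and returns the grid value
#' minimizing the extended BIC,
#' `-2 loglik + df log(n) + 2 gamma df log(p - 1)`, with `df` the count of
#' non-zero coefficients. At `gamma = 0` this is the ordinary BIC. Ties are
#' broken toward the smallest lambda among the minimizers.
#'
#' @inheritParams nodewise_fit
#' @param gamma EBIC sparsity weight (default 0.25).
#' @param lambda_grid Decreasing positive grid (default [lambda_grid()]).
#' @return The selected lambda, with attribute `ebic` (the criterion along
#'   the grid).
#' @export
select_lambda <- function(data, node, gamma = 0.25,
                          lambda_grid = exponet::lambda_grid(data, node)) {
  if (length(lambda_grid) == 0) stop("empty lambda grid", call. = FALSE)
  if (any(lambda_grid <= 0)) stop("lambda grid must be positive", call. = FALSE)
  X <- prep_design(data)
  nr <- node_response(X, data, node)
  grid <- sort(lambda_grid, decreasing = TRUE)
  fit <- fit_path(nr$y, nr$x, nr$type, grid)
  ebic <- ebic_path(nr$y, nr$x, nr$type, fit, gamma)
  minimizers <- which(ebic <= min(ebic) + 1e-9)
  sel <- max(minimizers)  # grid is decreasing: last index = smallest lambda
  structure(grid[sel], ebic = setNames(ebic, signif(grid, 6)))
}

#' Aggregate nodewise coefficients into an undirected network
#'
#' Combines the two directed coefficients of each node pair into one edge:
#' magnitude `mean(|b_jk|, |b_kj|)` on the standardized scale; under the
#' `"AND"` rule the edge is zero unless both coefficients are non-zero
#' (under `"OR"`, either suffices). The edge sign is the common coefficient
#' sign, or undefined (`NA`) when the two disagree.
#'
#' @param fits Named list (one entry per node) of named coefficient vectors
#'   over the remaining nodes, e.g. from [nodewise_fit()].
#' @param rule `"AND"` (default) or `"OR"`.
#' @param types Optional node types carried into the result.
#' @return A `pairwise_network`: weights (symmetric non-negative magnitude
#'   matrix, zero diagonal), signs, nodes, types.
#' @export
aggregate_edges <- function(fits, rule = c("AND", "OR"), types = NULL) {
  rule <- match.arg(rule)
  nodes <- names(fits)
  p <- length(nodes)
  if (p < 2) stop("need fits for at least two nodes", call. = FALSE)
  B <- matrix(0, p, p, dimnames = list(nodes, nodes))
  for (nd in nodes) {
    v <- fits[[nd]]
    missing_pred <- setdiff(setdiff(nodes, nd), names(v))
    if (length(missing_pred)) {
      stop("nodewise fit for ", nd, " lacks coefficient(s) for: ",
           paste(missing_pred, collapse = ", "), call. = FALSE)
    }
    B[nd, setdiff(nodes, nd)] <- v[setdiff(nodes, nd)]
  }
  W <- matrix(0, p, p, dimnames = list(nodes, nodes))
  S <- matrix(0, p, p, dimnames = list(nodes, nodes))
  for (j in seq_len(p - 1)) {
    for (k in (j + 1):p) {
      bjk <- B[j, k]; bkj <- B[k, j]
      keep <- if (rule == "AND") bjk != 0 && bkj != 0 else bjk != 0 || bkj != 0
      if (!keep) next
      W[j, k] <- W[k, j] <- mean(c(abs(bjk), abs(bkj)))
      sj <- sign(bjk); sk <- sign(bkj)
      s <- if (sj == 0) sk else if (sk == 0) sj
      else if (sj == sk) sj else NA_real_
      S[j, k] <- S[k, j] <- s
    }
  }
  structure(list(nodes = nodes, types = types, weights = W, signs = S,
                 predictability = setNames(rep(NA_real_, p), nodes),
                 lambda = NULL, gamma = NULL, rule = rule, betas = B),
            class = "pairwise_network")
}

#' Node predictability
#'
#' How well each node is explained by its selected neighbors, via an
#' unpenalized refit on the selected predictors: R-squared for a continuous
#' node; for a binary node the normalized accuracy
#' `(accuracy - majority rate) / (1 - majority rate)`, floored at 0. A node
#' with no selected neighbors scores 0; a degenerate (constant) node is
#' flagged `NA` with a warning.
#'
#' @param data A [mixed_data()].
#' @param selected Named list: per node, character vector of selected
#'   neighbor names.
#' @return Named numeric vector in `[0, 1]` (or `NA` where undefined).
#' @export
predictability <- function(data, selected) {
  X <- prep_design(data)
  out <- setNames(rep(NA_real_, length(data$nodes)), data$nodes)
  for (nd in data$nodes) {
    i <- match(nd, data$nodes)
    y <- data$values[, i]
    if (sd(y) == 0) {
      warning("degenerate node ", nd, ": predictability undefined")
      next
    }
    nb <- selected[[nd]]
    if (is.null(nb) || length(nb) == 0) { out[nd] <- 0; next }
    Z <- X[, nb, drop = FALSE]
    if (data$types[i] == "continuous") {
      f <- lm.fit(cbind(1, Z), X[, i])
      rss <- sum(f$residuals^2)
      tss <- sum((X[, i] - mean(X[, i]))^2)
      out[nd] <- max(0, min(1, 1 - rss / tss))
    } else {
      f <- suppressWarnings(glm.fit(cbind(1, Z), y, family = binomial()))
      acc <- mean((f$fitted.values >= 0.5) == (y == 1))
      maj <- max(mean(y), 1 - mean(y))
      if (maj >= 1) {
        warning("degenerate node ", nd, ": predictability undefined")
        next
      }
      out[nd] <- max(0, (acc - maj) / (1 - maj))
    }
  }
  out
}

#' Estimate a pairwise mixed graphical model
#'
#' The full nodewise workhorse: for every node, fits the L1 path of that
#' node on all others by cyclic coordinate descent with warm starts along a
#' log-spaced grid, selects the regularization by EBIC, then aggregates the
#' directed coefficients into an undirected weighted network and computes
#' node predictability from unpenalized refits.
#'
#' @param data A [mixed_data()].
#' @param gamma EBIC sparsity weight (default 0.25).
#' @param rule Edge aggregation rule, `"AND"` (default) or `"OR"`.
#' @param nlambda,lambda_min_ratio Grid parameters (defaults 50, 0.01).
#' @return A `pairwise_network` with weights, signs, per-node selected
#'   lambda and predictability.
#' @export
estimate_network <- function(data, gamma = 0.25, rule = c("AND", "OR"),
                             nlambda = 50, lambda_min_ratio = 0.01) {
  rule <- match.arg(rule)
  stopifnot(inherits(data, "mixed_data"))
  X <- prep_design(data)
  fits <- list()
  lambdas <- setNames(numeric(length(data$nodes)), data$nodes)
  for (nd in data$nodes) {
    nr <- node_response(X, data, nd)
    lmax <- lambda_max_value(nr$x, nr$y)
    if (lmax <= 0) lmax <- 1e-4
    grid <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                    length.out = nlambda))
    fit <- fit_path(nr$y, nr$x, nr$type, grid)
    ebic <- ebic_path(nr$y, nr$x, nr$type, fit, gamma)
    sel <- max(which(ebic <= min(ebic) + 1e-9))
    fits[[nd]] <- setNames(fit$beta[, sel], nr$predictors)
    lambdas[nd] <- grid[sel]
  }
  net <- aggregate_edges(fits, rule = rule, types = data$types)
  selected <- lapply(net$nodes, function(nd) {
    net$nodes[net$weights[nd, ] != 0]
  })
  names(selected) <- net$nodes
  net$predictability <- predictability(data, selected)
  net$lambda <- lambdas
  net$gamma <- gamma
  net$n <- nrow(data$values)
  net
}

#' @export
print.pairwise_network <- function(x, ...) {
  p <- length(x$nodes)
  ec <- sum(x$weights[upper.tri(x$weights)] != 0)
  cat("pairwise_network:", p, "nodes,", ec, "of", p * (p - 1) / 2,
      "edges non-zero (", x$rule, "rule )\n")
  if (!all(is.na(x$predictability))) {
    cat("  mean predictability:",
        round(mean(x$predictability, na.rm = TRUE), 3), "\n")
  }
  invisible(x)
}

# signed weights: magnitude with the edge sign applied where defined
signed_weights <- function(network) {
  sw <- network$weights
  neg <- !is.na(network$signs) & network$signs == -1
  sw[neg] <- -sw[neg]
  sw
}
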