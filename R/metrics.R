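#' Strength centrality
#'
#' Sum of absolute edge weights incident to a node (or all nodes).
#'
#' @param network A `pairwise_network`.
#' @param node Optional node name; default computes all nodes.
#' @return Named non-negative numeric vector (or scalar for one node).
#' @export
node_strength <- function(network, node = NULL) {
  stopifnot(inherits(network, "pairwise_network"))
  s <- rowSums(abs(network$weights))
  if (is.null(node)) return(s)
  if (!node %in% network$nodes) stop("unknown node: ", node, call. = FALSE)
  s[[node]]
}

# half-up rounding (so 40.05 -> 40.1), matching conventional report format
round_half_up <- function(x, digits = 1) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Network summary report
#'
#' Strength centralities, edge counts and mean predictability of an
#' estimated network: the count of non-zero edges out of `p(p-1)/2`
#' possible, the non-zero fraction (also as a percentage rounded half-up to
#' one decimal), and the mean predictability over all nodes.
#'
#' @param network A `pairwise_network`.
#' @return A `centrality_report` list.
#' @export
network_summary <- function(network) {
  stopifnot(inherits(network, "pairwise_network"))
  p <- length(network$nodes)
  possible <- p * (p - 1) / 2
  edges <- sum(network$weights[upper.tri(network$weights)] != 0)
  frac <- if (possible > 0) edges / possible else 0
  structure(list(
    strength = node_strength(network),
    edge_count = edges,
    possible_edges = possible,
    nonzero_fraction = frac,
    nonzero_percent = round_half_up(100 * frac, 1),
    mean_predictability = mean(network$predictability, na.rm = TRUE)
  ), class = "centrality_report")
}

#' @export
print.centrality_report <- function(x, ...) {
  cat("Network summary:", x$edge_count, "of", x$possible_edges,
      "possible edges non-zero (", sprintf("%.1f%%", x$nonzero_percent), ")\n")
  if (is.finite(x$mean_predictability)) {
    cat("  mean predictability:", round(x$mean_predictability, 3), "\n")
  }
  cat("  strength:\n")
  s <- sort(x$strength, decreasing = TRUE)
  for (nd in names(s)) cat(sprintf("    %-10s %.3f\n", nd, s[nd]))
  invisible(x)
}

#' Read a dense edge-weight matrix CSV
#'
#' Reads a square, symmetric edge-weight matrix (first column node names,
#' header row matching) into a `pairwise_network` with unknown
#' predictability.
#'
#' @param path CSV path.
#' @param types Optional named node types.
#' @return A `pairwise_network`.
#' @export
read_edge_matrix <- function(path, types = NULL) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  nodes <- as.character(df[[1]])
  W <- as.matrix(df[, -1, drop = FALSE])
  mode(W) <- "numeric"
  if (nrow(W) != ncol(W) || !identical(nodes, colnames(W))) {
    stop("edge matrix must be square with matching row/column names",
         call. = FALSE)
  }
  dimnames(W) <- list(nodes, nodes)
  if (max(abs(W - t(W))) > 1e-10) stop("edge matrix must be symmetric",
                                       call. = FALSE)
  diag(W) <- 0
  S <- matrix(0, nrow(W), ncol(W), dimnames = dimnames(W))
  S[W != 0] <- 1  # stored magnitudes; positive by convention
  structure(list(nodes = nodes, types = types, weights = abs(W), signs = S,
                 predictability = setNames(rep(NA_real_, length(nodes)), nodes),
                 lambda = NULL, gamma = NULL, rule = "AND", betas = NULL),
            class = "pairwise_network")
}

#' Packaged example network
#'
#' The edge-weight matrix of a previously reported 11-node
#' exposome-psychopathology network estimated on a non-clinical sample of
#' 1100 adults: the exposome score (ES), six symptom domains (depressive D,
#' anxiety ANX, manic M, ADHD, psychotic-like experiences PLEs, OCD), age,
#' and binary education, gender and employment covariates. All reported
#' edges are positive.
#'
#' @return A `pairwise_network`.
#' @export
example_network <- function() {
  path <- system.file("extdata", "example_network_edges.csv",
                      package = "exponet")
  types <- c(ES = "continuous", D = "continuous", ANX = "continuous",
             M = "continuous", ADHD = "continuous", PLEs = "continuous",
             OCD = "continuous", Age = "continuous", Ed = "binary",
             G = "binary", Emp = "binary")
  read_edge_matrix(path, types = types)
}

#' Write a centrality report as JSON
#'
#' @param report A `centrality_report`.
#' @param path Output path.
#' @export
write_centrality_report <- function(report, path) {
  jsonlite::write_json(
    list(strength = as.list(report$strength),
         edge_count = report$edge_count,
         possible_edges = report$possible_edges,
         nonzero_fraction = report$nonzero_fraction,
         nonzero_percent = report$nonzero_percent,
         mean_predictability = report$mean_predictability),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
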