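# counter-based per-iteration seed: order-independent across iterations,
# kept inside the 32-bit signed range
iteration_seed <- function(seed, i, stream = 0L) {
  as.integer((as.double(seed) * 100003 + as.double(i) * 7919 +
                as.double(stream) * 52361) %% 2147483629)
}

edge_labels <- function(nodes) {
  p <- length(nodes)
  out <- character(0)
  for (j in seq_len(p - 1)) {
    for (k in (j + 1):p) out <- c(out, paste0(nodes[j], "--", nodes[k]))
  }
  out
}

upper_tri_vec <- function(M) {
  p <- nrow(M)
  v <- numeric(0)
  for (j in seq_len(p - 1)) v <- c(v, M[j, (j + 1):p])
  v
}

zero_variance_cols <- function(values) {
  which(apply(values, 2, function(col) length(unique(col)) < 2))
}

#' Non-parametric bootstrap of an estimated network
#'
#' Resamples respondents with replacement `B` times, re-estimates the full
#' network per resample, and retains the per-iteration edge weights (signed
#' where the sign is defined) and node strengths. Resamples in which any
#' column becomes constant are skipped and logged, never imputed.
#' Per-iteration seeds are derived from `seed` by a counter scheme, so
#' iteration `i` draws the same resample regardless of execution order.
#'
#' @param data A [mixed_data()].
#' @param B Number of bootstrap iterations (default 1000).
#' @param seed Integer seed.
#' @param indices Optional list of row-index vectors overriding the random
#'   resampling (diagnostic use, e.g. the identity resample).
#' @param ... Estimation settings passed to [estimate_network()].
#' @return A `bootstrap_run` (mode `"nonparametric"`).
#' @export
nonparametric_boot <- function(data, B = 1000, seed = 1L, indices = NULL,
                               ...) {
  stopifnot(inherits(data, "mixed_data"))
  if (B < 1) stop("B must be >= 1", call. = FALSE)
  n <- nrow(data$values)
  point <- estimate_network(data, ...)
  labels <- edge_labels(point$nodes)
  edges <- matrix(NA_real_, B, length(labels),
                  dimnames = list(NULL, labels))
  strengths <- matrix(NA_real_, B, length(point$nodes),
                      dimnames = list(NULL, point$nodes))
  skipped <- integer(0)
  for (b in seq_len(B)) {
    if (is.null(indices)) {
      set.seed(iteration_seed(seed, b, 1L))
      idx <- sample.int(n, n, replace = TRUE)
    } else {
      idx <- indices[[b]]
    }
    vals <- data$values[idx, , drop = FALSE]
    if (length(zero_variance_cols(vals))) {
      skipped <- c(skipped, b)
      next
    }
    net <- estimate_network(mixed_data(vals, data$types), ...)
    edges[b, ] <- upper_tri_vec(signed_weights(net))
    strengths[b, ] <- node_strength(net)
  }
  if (length(skipped)) {
    message(length(skipped), " bootstrap iteration(s) skipped: ",
            "zero-variance column in resample")
  }
  structure(list(mode = "nonparametric", B = B, seed = seed,
                 point = point, edges = edges, strengths = strengths,
                 skipped = skipped),
            class = "bootstrap_run")
}

#' Case-drop bootstrap of node strength
#'
#' For each drop proportion, draws `B` subsamples without replacement
#' retaining `round((1 - proportion) * n)` rows, re-estimates the network,
#' and correlates (Pearson) the subsample strength vector with the
#' full-sample strengths. Iterations with a constant strength vector (or a
#' zero-variance column) are flagged and excluded from quantiles; drop
#' proportions whose subsample would hold fewer than `p + 1` rows are
#' skipped with a warning.
#'
#' @param data A [mixed_data()].
#' @param proportions Strictly increasing drop proportions in (0, 1);
#'   default the 0.05..0.75 grid conventional in bootstrap network
#'   stability analysis.
#' @param B Iterations per proportion (default 1000).
#' @param seed Integer seed.
#' @param ... Estimation settings passed to [estimate_network()].
#' @return A `bootstrap_run` (mode `"casedrop"`) holding the correlation
#'   matrix (proportions x iterations).
#' @export
casedrop_boot <- function(data, proportions = seq(0.05, 0.75, by = 0.05),
                          B = 1000, seed = 1L, ...) {
  stopifnot(inherits(data, "mixed_data"))
  if (B < 1) stop("B must be >= 1", call. = FALSE)
  if (any(proportions <= 0 | proportions >= 1) ||
      any(diff(proportions) <= 0)) {
    stop("drop proportions must be strictly increasing within (0, 1)",
         call. = FALSE)
  }
  n <- nrow(data$values)
  p <- length(data$nodes)
  point <- estimate_network(data, ...)
  s0 <- node_strength(point)
  cors <- matrix(NA_real_, length(proportions), B,
                 dimnames = list(paste0("drop_", proportions), NULL))
  flagged <- matrix(FALSE, length(proportions), B)
  kept_props <- logical(length(proportions))
  for (ip in seq_along(proportions)) {
    keep_n <- round((1 - proportions[ip]) * n)
    if (keep_n < p + 1) {
      warning("drop proportion ", proportions[ip],
              " skipped: subsample smaller than p + 1 rows")
      next
    }
    kept_props[ip] <- TRUE
    for (b in seq_len(B)) {
      set.seed(iteration_seed(seed, b, 100L + ip))
      idx <- sample.int(n, keep_n, replace = FALSE)
      vals <- data$values[idx, , drop = FALSE]
      if (length(zero_variance_cols(vals))) {
        flagged[ip, b] <- TRUE
        next
      }
      s <- node_strength(estimate_network(mixed_data(vals, data$types), ...))
      if (sd(s) == 0 || sd(s0) == 0) {
        flagged[ip, b] <- TRUE  # correlation undefined
        next
      }
      cors[ip, b] <- cor(s, s0)
    }
  }
  structure(list(mode = "casedrop", B = B, seed = seed, point = point,
                 proportions = proportions, kept = kept_props,
                 correlations = cors, flagged = flagged,
                 full_strength = s0),
            class = "bootstrap_run")
}

#' @export
print.bootstrap_run <- function(x, ...) {
  cat("bootstrap_run:", x$mode, ", B =", x$B, "\n")
  if (x$mode == "casedrop") {
    cat("  proportions:", paste(x$proportions, collapse = " "), "\n")
  }
  invisible(x)
}

#' Correlation stability coefficient
#'
#' The largest drop proportion in the case-drop grid at which at least
#' `probability_level` of the bootstrap iterations correlate at least
#' `correlation_threshold` with the full-sample statistic; 0 if no
#' proportion qualifies. Values above 0.25 are conventionally deemed
#' acceptable; the returned object carries that flag.
#'
#' @param run A case-drop [`bootstrap_run`][casedrop_boot].
#' @param correlation_threshold Default 0.7.
#' @param probability_level Default 0.95.
#' @return A `stability_result` with the coefficient, the per-proportion
#'   qualifying fractions and correlation quantiles.
#' @export
cs_coefficient <- function(run, correlation_threshold = 0.7,
                           probability_level = 0.95) {
  if (!inherits(run, "bootstrap_run") || run$mode != "casedrop") {
    stop("run must be a case-drop bootstrap_run", call. = FALSE)
  }
  if (!any(run$kept) || all(is.na(run$correlations))) {
    stop("empty case-drop run", call. = FALSE)
  }
  props <- run$proportions
  frac <- rep(NA_real_, length(props))
  qs <- matrix(NA_real_, length(props), 3,
               dimnames = list(NULL, c("q025", "q500", "q975")))
  for (ip in seq_along(props)) {
    if (!run$kept[ip]) next
    cc <- run$correlations[ip, ]
    cc <- cc[!is.na(cc)]
    if (length(cc) == 0) { frac[ip] <- 0; next }
    frac[ip] <- mean(cc >= correlation_threshold)
    qs[ip, ] <- quantile(cc, c(0.025, 0.5, 0.975), names = FALSE)
  }
  ok <- which(!is.na(frac) & frac >= probability_level)
  cs <- if (length(ok)) max(props[ok]) else 0
  structure(list(cs_coefficient = cs,
                 correlation_threshold = correlation_threshold,
                 probability_level = probability_level,
                 per_proportion = data.frame(proportion = props,
                                             fraction_above = frac,
                                             qs),
                 exceeds_0.25 = cs > 0.25),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("CS-coefficient: %.3f (threshold %.2f, level %.2f) - %s\n",
              x$cs_coefficient, x$correlation_threshold,
              x$probability_level,
              if (x$exceeds_0.25) "exceeds the 0.25 acceptability rule"
              else "does NOT exceed the 0.25 acceptability rule"))
  invisible(x)
}

#' Bootstrapped difference test
#'
#' Tests whether two bootstrapped statistics (two edges, or two node
#' strengths, from a non-parametric run) differ: significant iff the
#' two-sided `(1 - alpha)` percentile interval of the per-iteration
#' difference excludes zero.
#'
#' @param run A non-parametric [`bootstrap_run`][nonparametric_boot].
#' @param statistic_a,statistic_b Edge labels (`"a--b"`) or node names.
#' @param alpha Significance level (default 0.05).
#' @return List with `result` (`"significant"`/`"not_significant"`), the
#'   percentile `interval`, the retained iteration count and the point
#'   difference; carries a precision warning when fewer than 100 iterations
#'   are retained.
#' @export
difference_test <- function(run, statistic_a, statistic_b, alpha = 0.05) {
  if (!inherits(run, "bootstrap_run") || run$mode != "nonparametric") {
    stop("run must be a non-parametric bootstrap_run", call. = FALSE)
  }
  get_stat <- function(name) {
    if (name %in% colnames(run$edges)) return(run$edges[, name])
    rev_name <- paste(rev(strsplit(name, "--", fixed = TRUE)[[1]]),
                      collapse = "--")
    if (rev_name %in% colnames(run$edges)) return(run$edges[, rev_name])
    if (name %in% colnames(run$strengths)) return(run$strengths[, name])
    stop("statistic not present in run: ", name, call. = FALSE)
  }
  a <- get_stat(statistic_a)
  b <- get_stat(statistic_b)
  d <- a - b
  d <- d[!is.na(d)]
  precision_warning <- length(d) < 100
  if (precision_warning) {
    warning("fewer than 100 retained iterations; interval is imprecise")
  }
  ci <- quantile(d, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  significant <- ci[1] > 0 || ci[2] < 0
  point_a <- get_point(run, statistic_a)
  point_b <- get_point(run, statistic_b)
  list(result = if (significant) "significant" else "not_significant",
       interval = ci, n_retained = length(d),
       difference = point_a - point_b,
       precision_warning = precision_warning)
}

get_point <- function(run, name) {
  net <- run$point
  if (name %in% net$nodes) return(node_strength(net, name))
  parts <- strsplit(name, "--", fixed = TRUE)[[1]]
  if (length(parts) == 2 && all(parts %in% net$nodes)) {
    return(signed_weights(net)[parts[1], parts[2]])
  }
  stop("statistic not present in run: ", name, call. = FALSE)
}
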