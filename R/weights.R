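#' Natural-log odds weight
#'
#' Converts a meta-analytic odds ratio into the log-odds weight used by the
#' exposome score.
#'
#' @param odds_ratio Positive odds ratio.
#' @return The natural logarithm of `odds_ratio`.
#' @examples
#' log_odds_weight(3.40) # ~1.22, the emotional-abuse weight
#' @export
log_odds_weight <- function(odds_ratio) {
  if (!is.numeric(odds_ratio) || any(!is.finite(odds_ratio)) ||
      any(odds_ratio <= 0)) {
    stop("`odds_ratio` must be a positive finite number", call. = FALSE)
  }
  log(odds_ratio)
}

#' The ten scoreable exposome components
#'
#' Component identifiers, in canonical order. Advanced paternal age carries
#' two weight tiers (35-54 years and >=55 years at the respondent's birth);
#' all other components have a single weight.
#'
#' @return Character vector of component ids.
#' @export
es_components <- function() {
  c("winter_birth", "obstetric_complications", "advanced_paternal_age",
    "non_right_handedness", "emotional_neglect", "emotional_abuse",
    "bullying", "sexual_abuse", "cannabis_use", "urban_upbringing")
}

new_weight_table <- function(components, paternal_tiers) {
  stopifnot(is.data.frame(components), is.data.frame(paternal_tiers))
  req <- c("component", "odds_ratio", "log_odds")
  if (!all(req %in% names(components))) {
    stop("weight table needs columns component, odds_ratio, log_odds",
         call. = FALSE)
  }
  if (!setequal(components$component, es_components())) {
    stop("weight table must contain exactly the 10 exposome components",
         call. = FALSE)
  }
  if (any(components$odds_ratio <= 0) || any(paternal_tiers$odds_ratio <= 0)) {
    stop("odds ratios must be positive", call. = FALSE)
  }
  dev <- abs(components$log_odds - log(components$odds_ratio))
  dev_t <- abs(paternal_tiers$log_odds - log(paternal_tiers$odds_ratio))
  if (any(c(dev, dev_t) > 0.005)) {
    stop("log_odds inconsistent with ln(odds_ratio) beyond 0.005", call. = FALSE)
  }
  components <- components[match(es_components(), components$component), ]
  rownames(components) <- NULL
  structure(list(components = components, paternal_tiers = paternal_tiers),
            class = "weight_table")
}

#' Default exposure weight table
#'
#' The meta-analytic odds ratios and log-odds weights for the ten exposome
#' components, as shipped in `inst/extdata/exposure_weights.json`. Log-odds
#' are recomputed as `log(odds_ratio)` at full precision; the JSON resource
#' also records the conventional 2-decimal printed values, which the
#' constructor checks for consistency.
#'
#' @param path Optional path to an alternative JSON weight resource.
#' @return A `weight_table` object.
#' @export
default_weight_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "exposure_weights.json", package = "exponet")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("weight resource not found: ", path, call. = FALSE)
  }
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  comp <- raw$components
  comp$log_odds <- log(comp$odds_ratio)
  printed_dev <- abs(round(comp$log_odds, 2) - comp$printed_log_odds)
  if (any(printed_dev > 0.005)) {
    stop("recomputed log-odds disagree with the recorded printed values",
         call. = FALSE)
  }
  tiers <- raw$paternal_age_tiers
  tiers$log_odds <- log(tiers$odds_ratio)
  new_weight_table(
    components = comp[, c("component", "odds_ratio", "log_odds")],
    paternal_tiers = tiers[, c("tier", "odds_ratio", "log_odds")]
  )
}

#' @export
print.weight_table <- function(x, ...) {
  cat("Exposome weight table (10 components)\n")
  df <- x$components
  df$log_odds <- round(df$log_odds, 4)
  print(df, row.names = FALSE)
  cat("Advanced paternal age tiers:\n")
  tf <- x$paternal_tiers
  tf$log_odds <- round(tf$log_odds, 4)
  print(tf, row.names = FALSE)
  invisible(x)
}

# weight lookup used by the scorer; tier is "35-54" or ">=55" and only
# consulted for the paternal-age component
component_weight <- function(weights, component, tier = NULL) {
  if (component == "advanced_paternal_age" && !is.null(tier)) {
    i <- match(tier, weights$paternal_tiers$tier)
    if (is.na(i)) stop("unknown paternal tier: ", tier, call. = FALSE)
    return(weights$paternal_tiers$log_odds[i])
  }
  i <- match(component, weights$components$component)
  if (is.na(i)) stop("unknown component: ", component, call. = FALSE)
  weights$components$log_odds[i]
}
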