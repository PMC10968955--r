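#' Binarize raw exposure answers
#'
#' Turns raw survey answers into the ten present/absent/missing exposome
#' components:
#' * winter birth: month of birth in December-February;
#' * obstetric complications: any "yes" among caesarean-for-complications,
#'   low birth weight (<2500 g) and preterm (<37 weeks); with no "yes", any
#'   "I don't know" renders the component missing;
#' * advanced paternal age: father aged >=35 years at the respondent's
#'   birth, with tiers 35-54 and >=55;
#' * non-right-handedness: left- or mixed-handed;
#' * four childhood-trauma screens (emotional neglect, emotional abuse,
#'   bullying, sexual abuse), each its own component;
#' * problematic cannabis use: at least one of the eleven problem items
#'   affirmed;
#' * urban upbringing: any non-rural residence category.
#'
#' @param cohort Data frame in the raw-cohort schema produced by
#'   [generate_cohort()] (one row per respondent). Missing answers are `NA`;
#'   the obstetric items may also be `"I don't know"`.
#' @return Data frame with `respondent_id`, one column per component holding
#'   1 (present), 0 (absent) or `NA` (missing), and `paternal_tier`
#'   (`"none"`, `"35-54"`, `">=55"` or `NA`).
#' @export
binarize_exposures <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  n <- nrow(cohort)
  id <- if ("respondent_id" %in% names(cohort)) cohort$respondent_id else seq_len(n)

  month <- parse_month(cohort$birth_month)
  winter <- ifelse(is.na(month), NA_integer_, as.integer(month %in% c(12L, 1L, 2L)))

  oc_items <- c("oc_csection", "oc_low_birth_weight", "oc_preterm")
  missing_oc <- setdiff(oc_items, names(cohort))
  if (length(missing_oc)) {
    stop("cohort lacks obstetric item(s): ", paste(missing_oc, collapse = ", "),
         call. = FALSE)
  }
  oc <- binarize_any_yes_matrix(cohort, oc_items)

  pat_age <- as.numeric(cohort$paternal_age)
  pat <- ifelse(is.na(pat_age), NA_integer_, as.integer(pat_age >= 35))
  tier <- rep(NA_character_, n)
  tier[!is.na(pat) & pat == 0L] <- "none"
  tier[!is.na(pat_age) & pat_age >= 35 & pat_age < 55] <- "35-54"
  tier[!is.na(pat_age) & pat_age >= 55] <- ">=55"

  hand <- parse_level(cohort$handedness, c("right", "left", "mixed"), "handedness")
  non_right <- ifelse(is.na(hand), NA_integer_, as.integer(hand != "right"))

  trauma <- lapply(c("emotional_neglect", "emotional_abuse", "bullying",
                     "sexual_abuse"), function(col) {
    yes_no_to_int(cohort[[col]], col)
  })

  cpq_cols <- grep("^cpq_", names(cohort), value = TRUE)
  if (length(cpq_cols) == 0) stop("cohort lacks cpq_* items", call. = FALSE)
  cannabis <- binarize_any_yes_matrix(cohort, cpq_cols)

  res <- parse_level(cohort$residence,
                     c("rural", "city_le_100k", "city_100k_500k", "city_gt_500k"),
                     "residence")
  urban <- ifelse(is.na(res), NA_integer_, as.integer(res != "rural"))

  out <- data.frame(
    respondent_id = id,
    winter_birth = winter,
    obstetric_complications = oc,
    advanced_paternal_age = pat,
    non_right_handedness = non_right,
    emotional_neglect = trauma[[1]],
    emotional_abuse = trauma[[2]],
    bullying = trauma[[3]],
    sexual_abuse = trauma[[4]],
    cannabis_use = cannabis,
    urban_upbringing = urban,
    paternal_tier = tier,
    stringsAsFactors = FALSE
  )
  class(out) <- c("exposure_profile", "data.frame")
  out
}

# rowwise over the given columns: any "yes" -> 1 (an affirmative dominates);
# otherwise any "I don't know"/NA -> NA (missing); else 0
binarize_any_yes_matrix <- function(df, cols) {
  n <- nrow(df)
  m <- matrix(NA_character_, nrow = n, ncol = length(cols))
  for (k in seq_along(cols)) {
    a <- tolower(trimws(as.character(df[[cols[k]]])))
    a[!nzchar(a) | is.na(df[[cols[k]]])] <- NA_character_
    bad <- !is.na(a) & !(a %in% c("yes", "no", "i don't know", "i dont know"))
    if (any(bad)) {
      stop("unparseable answer in ", cols[k], ": ",
           paste(unique(a[bad]), collapse = ", "), call. = FALSE)
    }
    m[, k] <- a
  }
  yes <- rowSums(m == "yes", na.rm = TRUE) > 0
  unknown <- rowSums(is.na(m) | m %in% c("i don't know", "i dont know")) > 0
  ifelse(yes, 1L, ifelse(unknown, NA_integer_, 0L))
}

yes_no_to_int <- function(x, field) {
  if (is.null(x)) stop("cohort lacks column ", field, call. = FALSE)
  a <- tolower(trimws(as.character(x)))
  out <- ifelse(is.na(x), NA_integer_,
                ifelse(a == "yes", 1L, ifelse(a == "no", 0L, -9L)))
  if (any(out == -9L, na.rm = TRUE)) {
    stop("unparseable yes/no answer in field ", field, call. = FALSE)
  }
  out
}

parse_month <- function(x) {
  if (is.null(x)) stop("cohort lacks column birth_month", call. = FALSE)
  if (is.numeric(x)) {
    m <- as.integer(x)
    bad <- !is.na(m) & (m < 1L | m > 12L)
    if (any(bad)) stop("birth_month outside 1..12", call. = FALSE)
    return(m)
  }
  nm <- tolower(trimws(as.character(x)))
  idx <- match(nm, tolower(month.name))
  idx2 <- match(nm, tolower(month.abb))
  m <- ifelse(is.na(idx), idx2, idx)
  num <- suppressWarnings(as.integer(nm))
  m <- ifelse(is.na(m), num, m)
  bad <- is.na(m) & !is.na(x) & nzchar(nm)
  if (any(bad)) {
    stop("unparseable birth_month value(s): ",
         paste(unique(nm[bad]), collapse = ", "), call. = FALSE)
  }
  as.integer(m)
}

parse_level <- function(x, levels, field) {
  if (is.null(x)) stop("cohort lacks column ", field, call. = FALSE)
  a <- tolower(trimws(as.character(x)))
  bad <- !is.na(x) & nzchar(a) & !(a %in% levels)
  if (any(bad)) {
    stop("unparseable level in field ", field, ": ",
         paste(unique(a[bad]), collapse = ", "), call. = FALSE)
  }
  ifelse(is.na(x) | !nzchar(a), NA_character_, a)
}

#' Compute the exposome score
#'
#' Each present component contributes its log-odds weight (advanced paternal
#' age contributes the weight of its tier); absent and missing components
#' contribute zero. The contribution sum is divided by the number of
#' exposure components: the fixed total of 10 under `"fixed_total"` (the
#' default, under which the analytic mean for published sample prevalences
#' reproduces the published mean score), or the respondent's count of
#' non-missing components under `"per_respondent_recorded"`.
#'
#' @param profile An `exposure_profile` from [binarize_exposures()] (any
#'   number of rows).
#' @param weights A [`weight_table`][default_weight_table].
#' @param denominator_policy `"fixed_total"` or `"per_respondent_recorded"`.
#' @return Data frame with `respondent_id`, `score`, `n_recorded` and one
#'   contribution column per component (prefix `contrib_`).
#' @export
compute_es <- function(profile, weights = default_weight_table(),
                       denominator_policy = c("fixed_total",
                                              "per_respondent_recorded")) {
  denominator_policy <- match.arg(denominator_policy)
  if (!inherits(weights, "weight_table")) {
    stop("`weights` must be a weight_table", call. = FALSE)
  }
  comps <- es_components()
  if (!all(comps %in% names(profile))) {
    stop("profile lacks component column(s): ",
         paste(setdiff(comps, names(profile)), collapse = ", "), call. = FALSE)
  }
  states <- as.matrix(profile[, comps])
  n_recorded <- rowSums(!is.na(states))
  if (denominator_policy == "per_respondent_recorded" && any(n_recorded == 0)) {
    stop("score undefined: all components missing for respondent(s) ",
         paste(head(which(n_recorded == 0)), collapse = ", "),
         " under per_respondent_recorded", call. = FALSE)
  }

  w <- setNames(weights$components$log_odds, weights$components$component)
  contrib <- sweep(ifelse(is.na(states), 0, states), 2, w[comps], `*`)

  # paternal tier overrides the component-level weight
  pat_present <- !is.na(states[, "advanced_paternal_age"]) &
    states[, "advanced_paternal_age"] == 1
  if (any(pat_present)) {
    tiers <- profile$paternal_tier[pat_present]
    tiers[is.na(tiers) | tiers == "none"] <- "35-54"
    tw <- setNames(weights$paternal_tiers$log_odds, weights$paternal_tiers$tier)
    unknown <- !(tiers %in% names(tw))
    if (any(unknown)) stop("unknown paternal tier: ",
                           paste(unique(tiers[unknown]), collapse = ", "),
                           call. = FALSE)
    contrib[pat_present, "advanced_paternal_age"] <- tw[tiers]
  }

  denom <- if (denominator_policy == "fixed_total") length(comps) else n_recorded
  score <- rowSums(contrib) / denom

  out <- data.frame(respondent_id = profile$respondent_id,
                    score = score, n_recorded = n_recorded)
  contrib_df <- as.data.frame(contrib)
  names(contrib_df) <- paste0("contrib_", comps)
  out <- cbind(out, contrib_df)
  attr(out, "denominator_policy") <- denominator_policy
  rownames(out) <- NULL
  out
}

#' Score a raw cohort
#'
#' Convenience wrapper: binarizes exposures and computes the exposome score
#' in one step.
#'
#' @inheritParams compute_es
#' @param cohort Raw cohort data frame (see [generate_cohort()]).
#' @return See [compute_es()].
#' @export
score_cohort <- function(cohort, weights = default_weight_table(),
                         denominator_policy = "fixed_total") {
  compute_es(binarize_exposures(cohort), weights, denominator_policy)
}
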