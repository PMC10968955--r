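# Instrument ranges for the six symptom sum-scores
symptom_ranges <- function() {
  data.frame(
    scale = c("pq16", "gad7", "phq9", "mdq", "ocir", "asrs5"),
    min = c(0, 0, 0, 0, 0, 0),
    max = c(16, 21, 27, 13, 72, 24),
    stringsAsFactors = FALSE
  )
}

default_symptom_marginals <- function() {
  r <- symptom_ranges()
  r$mean <- c(5.3, 7.6, 9.4, 5.5, 22.3, 10.1)
  r$sd <- c(4.0, 5.5, 6.2, 3.7, 14.7, 4.3)
  r[, c("scale", "mean", "sd", "min", "max")]
}

default_exposure_prevalences <- function() {
  c(winter_birth = 0.245, obstetric_complications = 0.319,
    advanced_paternal_age = 0.248, non_right_handedness = 0.097,
    emotional_neglect = 0.524, emotional_abuse = 0.434,
    bullying = 0.539, sexual_abuse = 0.212,
    cannabis_use = 0.065, urban_upbringing = 0.611)
}

default_covariate_marginals <- function() {
  list(
    age = list(mean = 27.1, sd = 5.1, min = 18, max = 35),
    gender_male = 0.486,
    education = c(primary = 0.055, vocational = 0.081,
                  secondary = 0.503, higher = 0.361),
    employment = c(unemployed = 0.149, part_time = 0.155,
                   student = 0.184, full_time = 0.513)
  )
}

#' Specify a synthetic cohort
#'
#' Collects the marginal targets the generator calibrates to. Defaults are
#' the published sample characteristics of a non-clinical web-survey cohort
#' of 1100 Polish adults aged 18-35: exposure prevalences (e.g. emotional
#' neglect 52.4%, urban upbringing 61.1%), symptom-scale means and SDs
#' (e.g. PHQ-9 9.4 +/- 6.2), covariate marginals, and missingness rates for
#' obstetric complications (21.5%) and paternal age (18.2%).
#'
#' @param n_respondents Number of respondents to generate.
#' @param exposure_prevalences Named probabilities for the ten components.
#' @param symptom_marginals Data frame with columns `scale`, `mean`, `sd`,
#'   `min`, `max`; ranges must match the instruments (PQ-16 0-16, GAD-7
#'   0-21, PHQ-9 0-27, MDQ 0-13, OCI-R 0-72, ASRS-5 0-24).
#' @param covariate_marginals List with `age` (mean/sd/min/max),
#'   `gender_male`, `education`, `employment`.
#' @param missingness Named per-field missingness probabilities; recognised
#'   fields are `obstetric_complications` (all three items become
#'   "I don't know") and `paternal_age`, plus any raw column name (set to
#'   `NA`).
#' @param seed Integer seed; the cohort is a deterministic function of the
#'   spec including the seed.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_respondents = 1100,
                        exposure_prevalences = default_exposure_prevalences(),
                        symptom_marginals = default_symptom_marginals(),
                        covariate_marginals = default_covariate_marginals(),
                        missingness = c(obstetric_complications = 0.215,
                                        paternal_age = 0.182),
                        seed = 1L) {
  if (!is.numeric(n_respondents) || n_respondents < 1) {
    stop("n_respondents must be a positive count", call. = FALSE)
  }
  prev <- default_exposure_prevalences()
  prev[names(exposure_prevalences)] <- exposure_prevalences
  if (any(prev < 0 | prev > 1)) {
    stop("exposure prevalences must lie in [0, 1]", call. = FALSE)
  }
  sm <- symptom_marginals
  req <- c("scale", "mean", "sd", "min", "max")
  if (!is.data.frame(sm) || !all(req %in% names(sm))) {
    stop("symptom_marginals needs columns scale, mean, sd, min, max",
         call. = FALSE)
  }
  ranges <- symptom_ranges()
  for (i in seq_len(nrow(sm))) {
    r <- ranges[ranges$scale == sm$scale[i], ]
    if (nrow(r) == 1 && (sm$min[i] != r$min || sm$max[i] != r$max)) {
      stop("range for ", sm$scale[i], " must be [", r$min, ", ", r$max, "]",
           call. = FALSE)
    }
    if (sm$min[i] >= sm$max[i]) stop("min must be < max", call. = FALSE)
    if (sm$sd[i] <= 0) stop("sd must be > 0", call. = FALSE)
    if (sm$mean[i] < sm$min[i] || sm$mean[i] > sm$max[i]) {
      stop("requested mean for ", sm$scale[i], " outside instrument range",
           call. = FALSE)
    }
  }
  if (any(missingness < 0 | missingness > 1)) {
    stop("missingness probabilities must lie in [0, 1]", call. = FALSE)
  }
  structure(list(n_respondents = as.integer(n_respondents),
                 exposure_prevalences = prev,
                 symptom_marginals = sm,
                 covariate_marginals = covariate_marginals,
                 missingness = missingness,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic cohort spec: n =", x$n_respondents, ", seed =", x$seed, "\n")
  cat("  prevalences:",
      paste(names(x$exposure_prevalences),
            sprintf("%.3f", x$exposure_prevalences), collapse = ", "), "\n")
  invisible(x)
}

# mean of a normal censored (clipped) to [lo, hi]
censored_normal_mean <- function(mu, sigma, lo, hi) {
  a <- (lo - mu) / sigma
  b <- (hi - mu) / sigma
  lo * pnorm(a) + hi * (1 - pnorm(b)) +
    mu * (pnorm(b) - pnorm(a)) + sigma * (dnorm(a) - dnorm(b))
}

# latent mean such that clipping to [lo, hi] yields the target mean
solve_latent_mean <- function(target, sigma, lo, hi) {
  uniroot(function(m) censored_normal_mean(m, sigma, lo, hi) - target,
          lower = lo - 6 * sigma, upper = hi + 6 * sigma, tol = 1e-9)$root
}

# latent mean of a [lo, hi]-truncated normal with fixed sd such that
# P(X >= cut) equals the target probability
solve_truncnorm_mean <- function(p_above, sigma, lo, hi, cut) {
  f <- function(m) {
    zl <- pnorm((lo - m) / sigma)
    zh <- pnorm((hi - m) / sigma)
    zc <- pnorm((cut - m) / sigma)
    (zh - zc) / (zh - zl) - p_above
  }
  uniroot(f, lower = lo - 2 * sigma, upper = hi, tol = 1e-9)$root
}

rtruncnorm1 <- function(n, mu, sigma, lo, hi) {
  u <- runif(n, pnorm((lo - mu) / sigma), pnorm((hi - mu) / sigma))
  mu + sigma * qnorm(u)
}

yes_no <- function(x) ifelse(x == 1L, "yes", "no")

#' Generate a synthetic cohort of raw survey answers
#'
#' Draws respondent-level raw answers (month of birth, obstetric items with
#' "I don't know" support, paternal age in years, handedness, trauma
#' screens, eleven cannabis-problem items, residence category), integer
#' symptom sum-scores, and covariates, calibrated so that downstream
#' binarization reproduces the requested prevalences in expectation and symptom
#' means land on target despite rounding and range-clipping. Missingness is
#' injected completely at random per field.
#'
#' @param spec A [cohort_spec()].
#' @return Data frame, one row per respondent, with attribute
#'   `"cohort_spec"`.
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) stop("spec must be a cohort_spec",
                                           call. = FALSE)
  set.seed(spec$seed)
  n <- spec$n_respondents
  prev <- spec$exposure_prevalences
  miss <- spec$missingness

  # month of birth: uniform within winter {Dec, Jan, Feb} and within the
  # other nine months, re-weighted so winter prevalence hits target
  p_w <- prev[["winter_birth"]]
  month_probs <- rep((1 - p_w) / 9, 12)
  month_probs[c(12, 1, 2)] <- p_w / 3
  birth_month <- sample.int(12, n, replace = TRUE, prob = month_probs)

  # obstetric items: per-item yes-probability solved so any-yes hits target
  q_oc <- 1 - (1 - prev[["obstetric_complications"]])^(1 / 3)
  oc <- matrix(yes_no(rbinom(3 * n, 1, q_oc)), ncol = 3)
  m_oc <- if ("obstetric_complications" %in% names(miss))
    miss[["obstetric_complications"]] else 0
  oc_missing <- runif(n) < m_oc
  oc[oc_missing, ] <- "I don't know"

  # paternal age: truncated normal, sd 6 on 16-70 years, latent mean solved
  # so that P(reported age >= 35) equals the target prevalence (reported
  # ages are integers, so the latent cut sits at 34.5)
  mu_pat <- solve_truncnorm_mean(prev[["advanced_paternal_age"]], 6, 16, 70, 34.5)
  paternal_age <- round(rtruncnorm1(n, mu_pat, 6, 16, 70))
  m_pat <- if ("paternal_age" %in% names(miss)) miss[["paternal_age"]] else 0
  paternal_age[runif(n) < m_pat] <- NA

  p_nrh <- prev[["non_right_handedness"]]
  handedness <- sample(c("right", "left", "mixed"), n, replace = TRUE,
                       prob = c(1 - p_nrh, 0.72 * p_nrh, 0.28 * p_nrh))

  trauma <- lapply(c("emotional_neglect", "emotional_abuse", "bullying",
                     "sexual_abuse"),
                   function(cmp) yes_no(rbinom(n, 1, prev[[cmp]])))

  q_cpq <- 1 - (1 - prev[["cannabis_use"]])^(1 / 11)
  cpq <- matrix(yes_no(rbinom(11 * n, 1, q_cpq)), ncol = 11)

  p_urb <- prev[["urban_upbringing"]]
  residence <- sample(c("rural", "city_le_100k", "city_100k_500k",
                        "city_gt_500k"), n, replace = TRUE,
                      prob = c(1 - p_urb, 0.5 * p_urb, 0.25 * p_urb,
                               0.25 * p_urb))

  # symptom scores: latent Gaussian, mean solved for the censoring bias,
  # rounded to integers and clipped to the instrument range
  sm <- spec$symptom_marginals
  symptoms <- lapply(seq_len(nrow(sm)), function(i) {
    mu <- solve_latent_mean(sm$mean[i], sm$sd[i], sm$min[i], sm$max[i])
    x <- rnorm(n, mu, sm$sd[i])
    pmin(pmax(round(x), sm$min[i]), sm$max[i])
  })
  names(symptoms) <- sm$scale

  cv <- spec$covariate_marginals
  mu_age <- solve_latent_mean(cv$age$mean, cv$age$sd, cv$age$min, cv$age$max)
  age <- round(pmin(pmax(rnorm(n, mu_age, cv$age$sd), cv$age$min),
                    cv$age$max))
  gender <- sample(c("male", "female"), n, replace = TRUE,
                   prob = c(cv$gender_male, 1 - cv$gender_male))
  education <- sample(names(cv$education), n, replace = TRUE,
                      prob = cv$education)
  employment <- sample(names(cv$employment), n, replace = TRUE,
                       prob = cv$employment)

  out <- data.frame(
    respondent_id = seq_len(n),
    birth_month = birth_month,
    oc_csection = oc[, 1], oc_low_birth_weight = oc[, 2], oc_preterm = oc[, 3],
    paternal_age = paternal_age,
    handedness = handedness,
    emotional_neglect = trauma[[1]], emotional_abuse = trauma[[2]],
    bullying = trauma[[3]], sexual_abuse = trauma[[4]],
    stringsAsFactors = FALSE
  )
  cpq_df <- as.data.frame(cpq, stringsAsFactors = FALSE)
  names(cpq_df) <- sprintf("cpq_%02d", 1:11)
  out <- cbind(out, cpq_df)
  out$residence <- residence
  out <- cbind(out, as.data.frame(symptoms))
  out$age <- age
  out$gender <- gender
  out$education <- education
  out$employment <- employment

  # generic MCAR injection for any other named raw column
  extra <- setdiff(names(miss), c("obstetric_complications", "paternal_age"))
  for (field in extra) {
    if (!field %in% names(out)) next
    out[[field]][runif(n) < miss[[field]]] <- NA
  }

  attr(out, "cohort_spec") <- spec
  out
}
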