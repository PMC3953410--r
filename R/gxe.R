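#' Score-by-physical-activity interaction model
#'
#' One joint OLS fit of trait ~ score + PA + score:PA + covariates, with PA
#' entered as an ordinal 0/1/2 code (low/moderate/high), so the interaction
#' coefficient is the change in the per-allele score effect per one-step
#' increase in PA category. Stratum-specific score effects come from
#' separate per-stratum fits with the same covariates (PA categorical for
#' stratification, ordinal in the joint model). The attenuation percentage
#' is computed from the low- and high-stratum betas.
#'
#' @param trait Numeric outcome vector.
#' @param score Risk-score (or single-SNP dosage) vector.
#' @param pa Ordinal PA code 0/1/2 (or a factor low/moderate/high, coerced).
#' @param covariates Optional covariate data.frame.
#' @param stratified Also fit the three per-stratum models? A PA level
#'   absent (or with too few individuals) is marked absent rather than
#'   aborting the joint fit.
#' @param predictor_name,trait_name Labels carried into the result.
#' @return A list (class `interaction_result`): `beta_interaction`, `se`,
#'   `p` (the score-by-PA coefficient), `beta_main`, joint `n`, and when
#'   stratified a data.frame `strata` with per-level beta, se, p, n and an
#'   `attenuation_pct` (low to high).
#' @export
fit_interaction <- function(trait, score, pa, covariates = NULL,
                            stratified = TRUE,
                            predictor_name = "GRS", trait_name = "trait") {
  if (is.factor(pa)) pa <- as.integer(pa) - 1L
  if (!all(stats::na.omit(pa) %in% 0:2)) {
    stop("pa must be coded 0/1/2 (low/moderate/high)", call. = FALSE)
  }
  df <- data.frame(.y = trait, .s = score, .pa = pa)
  if (!is.null(covariates)) df <- cbind(df, as.data.frame(covariates))
  cc <- stats::complete.cases(df)
  dat <- df[cc, , drop = FALSE]
  fit <- stats::lm(.y ~ .s * .pa + ., data = dat)
  check_full_rank(fit)
  sm <- summary(fit)$coefficients
  out <- list(predictor = predictor_name, trait = trait_name,
              beta_interaction = unname(sm[".s:.pa", "Estimate"]),
              se = unname(sm[".s:.pa", "Std. Error"]),
              p = unname(sm[".s:.pa", "Pr(>|t|)"]),
              beta_main = unname(sm[".s", "Estimate"]),
              se_main = unname(sm[".s", "Std. Error"]),
              n = nrow(dat))
  if (stratified) {
    covs <- setdiff(names(dat), c(".y", ".s", ".pa"))
    strata <- lapply(0:2, function(level) {
      sub <- dat[dat$.pa == level, c(".y", ".s", covs), drop = FALSE]
      if (nrow(sub) < length(covs) + 4L) {
        return(data.frame(pa = level, beta = NA_real_, se = NA_real_,
                          p = NA_real_, n = nrow(sub), absent = TRUE))
      }
      sfit <- stats::lm(.y ~ ., data = sub)
      ssm <- summary(sfit)$coefficients
      data.frame(pa = level, beta = unname(ssm[".s", "Estimate"]),
                 se = unname(ssm[".s", "Std. Error"]),
                 p = unname(ssm[".s", "Pr(>|t|)"]),
                 n = nrow(sub), absent = FALSE)
    })
    strata <- do.call(rbind, strata)
    strata$pa_label <- c("low", "moderate", "high")[strata$pa + 1L]
    out$strata <- strata
    out$attenuation_pct <- if (!any(strata$absent) &&
                               !is.na(strata$beta[1]) && strata$beta[1] != 0) {
      attenuation_pct(strata$beta[1], strata$beta[3])
    } else {
      NA_real_
    }
  }
  class(out) <- "interaction_result"
  out
}

#' Percent attenuation of a stratum effect
#'
#' 100 * (beta_low - beta_high) / beta_low: the percentage by which the
#' per-allele effect in the high-exposure stratum is smaller than in the
#' low-exposure stratum. An effect larger in the high stratum yields a
#' negative attenuation (aggravation).
#'
#' @param beta_low Effect in the low-exposure stratum (non-zero).
#' @param beta_high Effect in the high-exposure stratum.
#' @return Percent attenuation.
#' @export
attenuation_pct <- function(beta_low, beta_high) {
  if (any(beta_low == 0)) {
    stop("attenuation undefined when the low-stratum beta is 0", call. = FALSE)
  }
  100 * (beta_low - beta_high) / beta_low
}

#' Exact one-sided binomial sign test for directional consistency
#'
#' Upper-tail probability of observing at least `n_consistent` of `n_total`
#' effect estimates agreeing in sign with their reference directions under
#' the null of coin-flip signs:
#' \deqn{p = \sum_{k=n_c}^{n} \binom{n}{k} 2^{-n},}
#' evaluated as an explicit log-binomial sum. One-sided by convention for
#' replication-consistency testing.
#'
#' @param n_consistent Count of directionally consistent estimates.
#' @param n_total Total estimates examined (>= 1).
#' @return A list (class `sign_test_result`): `n_total`, `n_consistent`,
#'   `p_one_sided`.
#' @export
sign_binomial_test <- function(n_consistent, n_total) {
  if (n_total < 1 || n_consistent < 0 || n_consistent > n_total) {
    stop("need 0 <= n_consistent <= n_total, n_total >= 1", call. = FALSE)
  }
  k <- seq.int(n_consistent, n_total)
  p <- if (n_total <= 50) {
    # exact: binomial coefficients and their sum stay below 2^53
    sum(choose(n_total, k)) / 2^n_total
  } else {
    sum(exp(lchoose(n_total, k) - n_total * log(2)))
  }
  out <- list(n_total = as.integer(n_total),
              n_consistent = as.integer(n_consistent),
              p_one_sided = min(p, 1))
  class(out) <- "sign_test_result"
  out
}

#' Count directionally consistent effect estimates
#'
#' Compares the sign of each estimated beta with its expected reference
#' direction (+1 for a BMI-increasing allele, -1 otherwise). A beta of
#' exactly zero counts as inconsistent and is reported separately.
#'
#' @param betas Named numeric vector of estimates (names are rsIDs), or a
#'   list of `assoc_result` objects.
#' @param reference_directions Named vector of +1/-1 expected signs, one
#'   per estimate.
#' @return A list: `n_consistent`, `n_total`, `n_zero`, and the logical
#'   vector `consistent` (named by rsID).
#' @export
count_consistent <- function(betas, reference_directions) {
  if (is.list(betas) && !is.numeric(betas)) {
    betas <- stats::setNames(
      vapply(betas, function(r) r$beta, numeric(1)),
      vapply(betas, function(r) r$predictor, character(1)))
  }
  missing_ref <- setdiff(names(betas), names(reference_directions))
  if (length(missing_ref) > 0L) {
    stop("no reference direction for: ",
         paste(missing_ref, collapse = ", "), call. = FALSE)
  }
  ref <- reference_directions[names(betas)]
  if (!all(ref %in% c(-1, 1))) {
    stop("reference directions must be +1 or -1", call. = FALSE)
  }
  consistent <- sign(betas) == ref  # beta == 0 -> sign 0 -> inconsistent
  list(n_consistent = sum(consistent), n_total = length(betas),
       n_zero = sum(betas == 0), consistent = consistent)
}

#' Cochran's Q heterogeneity test for two effect estimates
#'
#' Fixed-effect test of whether two estimates (e.g. this cohort vs an
#' external European-ancestry reference) share a common underlying value:
#' inverse-variance weights w = 1/se^2, pooled beta = sum(w b)/sum(w),
#' Q = sum w (b - pooled)^2, df = 1, p from the chi-squared upper tail.
#' I^2 = max(0, (Q - df)/Q) is reported as a supplementary descriptive.
#'
#' @param beta_a,se_a Estimate and SE in study A (se > 0).
#' @param beta_b,se_b Estimate and SE in study B (se > 0).
#' @param rsid Optional locus label.
#' @return A list (class `heterogeneity_result`): `rsid`, the inputs,
#'   `pooled_beta`, `q_statistic`, `df`, `p`, `i_squared`.
#' @export
cochran_q <- function(beta_a, se_a, beta_b, se_b, rsid = NA_character_) {
  if (se_a <= 0 || se_b <= 0) stop("SEs must be > 0", call. = FALSE)
  w <- c(1 / se_a^2, 1 / se_b^2)
  b <- c(beta_a, beta_b)
  pooled <- sum(w * b) / sum(w)
  q <- sum(w * (b - pooled)^2)
  out <- list(rsid = rsid, beta_a = beta_a, se_a = se_a,
              beta_b = beta_b, se_b = se_b,
              pooled_beta = pooled, q_statistic = q, df = 1L,
              p = stats::pchisq(q, 1, lower.tail = FALSE),
              i_squared = max(0, (q - 1) / q))
  class(out) <- "heterogeneity_result"
  out
}
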