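#' Rank-based inverse-normal transformation
#'
#' Maps a trait to standard-normal quantiles via the Blom offset:
#' \eqn{\Phi^{-1}((r - 3/8)/(n + 1/4))} with average ranks for ties, where n
#' counts non-missing values. Missing values stay missing. The result has
#' sample mean ~0 and SD ~1 and is invariant to any monotone transform of
#' the input.
#'
#' @param values Numeric vector, possibly with NAs; needs >= 2 non-missing
#'   values with non-zero variance.
#' @param offset Rank offset; default 3/8 (Blom).
#' @return Transformed vector, same length and NA pattern as the input.
#' @export
inverse_normal_transform <- function(values, offset = 3/8) {
  ok <- !is.na(values)
  x <- values[ok]
  if (length(x) < 2L) stop("need >= 2 non-missing values", call. = FALSE)
  if (stats::sd(x) == 0) stop("constant vector cannot be transformed", call. = FALSE)
  r <- rank(x, ties.method = "average")
  out <- values
  out[ok] <- stats::qnorm((r - offset) / (length(x) + 1 - 2 * offset))
  out
}

#' Build a covariate design for the standard adjustment sets
#'
#' `"bmi-set"`: age, age^2, sex, region and the first two principal
#' components (the adjustment used for BMI, weight-class and interaction
#' models). `"dxa-set"`: age, age^2 and sex (the adjustment used for the
#' DXA fat-percentage traits). Age^2 is always constructed internally from
#' the age column; sex and region become 0/1 indicators (reference levels
#' male and Beijing, recorded in the `reference_levels` attribute).
#'
#' @param data A phenotype data.frame with `age`, `sex` and (for
#'   `"bmi-set"`) `region`, `pc1`, `pc2`.
#' @param preset `"bmi-set"` or `"dxa-set"`.
#' @return A numeric data.frame of covariate columns.
#' @export
covariate_set <- function(data, preset = c("bmi-set", "dxa-set")) {
  preset <- match.arg(preset)
  out <- data.frame(age = data$age, age2 = data$age^2,
                    sex = as.integer(data$sex == "female"))
  if (preset == "bmi-set") {
    out$region <- as.integer(data$region == "Shanghai")
    out$pc1 <- data$pc1
    out$pc2 <- data$pc2
  }
  attr(out, "reference_levels") <- c(sex = "male", region = "Beijing")
  out
}

# Shared complete-case assembly for the regression helpers.
assemble_design <- function(trait, predictor, covariates) {
  df <- data.frame(.y = trait, .x = predictor)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == length(trait))
    df <- cbind(df, covariates)
  }
  cc <- stats::complete.cases(df)
  list(data = df[cc, , drop = FALSE], n_dropped = sum(!cc))
}

check_full_rank <- function(fit) {
  alias <- is.na(stats::coef(fit))
  if (any(alias)) {
    stop("rank-deficient design; collinear column(s): ",
         paste(names(stats::coef(fit))[alias], collapse = ", "),
         call. = FALSE)
  }
}

#' Linear association of a trait with a SNP dosage or risk score
#'
#' Ordinary least squares with intercept: trait ~ predictor + covariates,
#' the additive per-allele model. Rows with any missing value in trait,
#' predictor or covariates are dropped per model (so the analysis n floats
#' with trait availability) and counted. With `transform = TRUE` the trait
#' is inverse-normal transformed (on the complete-case sample) before
#' fitting, giving effects per SD.
#'
#' @param trait Numeric outcome vector.
#' @param predictor Numeric dosage or score vector, same length.
#' @param covariates Optional data.frame/matrix of covariate columns (see
#'   [covariate_set()]).
#' @param transform Apply [inverse_normal_transform()] to the trait first?
#' @param predictor_name,trait_name Labels carried into the result.
#' @return A list (class `assoc_result`): `predictor`, `trait`, `beta`,
#'   `se`, `p`, `n`, `n_dropped`, `covariates`, `transformed`.
#' @export
linear_assoc <- function(trait, predictor, covariates = NULL,
                         transform = FALSE,
                         predictor_name = "predictor", trait_name = "trait") {
  asm <- assemble_design(trait, predictor, covariates)
  dat <- asm$data
  n_par <- ncol(dat) + 1L
  if (nrow(dat) < n_par + 2L) {
    stop("too few complete cases for the model", call. = FALSE)
  }
  if (transform) dat$.y <- inverse_normal_transform(dat$.y)
  fit <- stats::lm(.y ~ ., data = dat)
  check_full_rank(fit)
  sm <- summary(fit)$coefficients
  out <- list(predictor = predictor_name, trait = trait_name,
              beta = unname(sm[".x", "Estimate"]),
              se = unname(sm[".x", "Std. Error"]),
              p = unname(sm[".x", "Pr(>|t|)"]),
              n = nrow(dat), n_dropped = asm$n_dropped,
              covariates = setdiff(names(dat), c(".y", ".x")),
              transformed = transform)
  class(out) <- "assoc_result"
  out
}

#' Logistic association with a weight-class contrast
#'
#' Maximum-likelihood logistic regression of case vs control weight class
#' on a dosage or score plus covariates (other classes are excluded from
#' the model). Reports the per-allele odds ratio with Wald 95\% CI and
#' p-value. Non-convergence or separation (diverging coefficients) is an
#' error with a diagnostic, never a silent result.
#'
#' @param weight_class Factor from [classify_weight()].
#' @param case_class,control_class Class labels forming the contrast, e.g.
#'   `"obese"` vs `"normal"`.
#' @param predictor Numeric dosage or score vector.
#' @param covariates Optional covariate data.frame.
#' @param predictor_name Label carried into the result.
#' @return A list (class `or_result`): `predictor`, `contrast`,
#'   `odds_ratio`, `ci_low`, `ci_high`, `p`, `beta`, `se`, `n_cases`,
#'   `n_controls`, `covariates`.
#' @export
logistic_assoc <- function(weight_class, case_class, control_class,
                           predictor, covariates = NULL,
                           predictor_name = "predictor") {
  in_contrast <- weight_class %in% c(case_class, control_class)
  y <- ifelse(weight_class == case_class, 1L, 0L)
  y[!in_contrast] <- NA_integer_
  asm <- assemble_design(y, predictor, covariates)
  dat <- asm$data
  if (sum(dat$.y == 1L) == 0L || sum(dat$.y == 0L) == 0L) {
    stop("empty case or control class after complete-case filtering",
         call. = FALSE)
  }
  fit <- stats::glm(.y ~ ., data = dat, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-10,
                                                 maxit = 50))
  if (!fit$converged) {
    stop("logistic fit did not converge (possible separation)", call. = FALSE)
  }
  check_full_rank(fit)
  sm <- summary(fit)$coefficients
  beta <- unname(sm[".x", "Estimate"])
  se <- unname(sm[".x", "Std. Error"])
  if (abs(beta) > 15 || se > 100) {
    stop(sprintf("degenerate logistic estimate (beta=%.2f, se=%.2f); likely separation",
                 beta, se), call. = FALSE)
  }
  out <- list(predictor = predictor_name,
              contrast = paste(case_class, "vs", control_class),
              odds_ratio = exp(beta),
              ci_low = exp(beta - stats::qnorm(0.975) * se),
              ci_high = exp(beta + stats::qnorm(0.975) * se),
              p = unname(sm[".x", "Pr(>|z|)"]),
              beta = beta, se = se,
              n_cases = sum(dat$.y == 1L), n_controls = sum(dat$.y == 0L),
              covariates = setdiff(names(dat), c(".y", ".x")))
  class(out) <- "or_result"
  out
}

#' Variance explained by a biallelic locus
#'
#' Fraction of trait variance attributable to a locus under the additive
#' model: 2 f (1 - f) beta^2, with beta the per-allele effect on the
#' standardized (unit-variance) trait. Symmetric in f and 1 - f, so the
#' effect-allele frequency may be supplied directly even when it exceeds
#' 0.5 (min(f, 1 - f) is used internally, which is equivalent).
#'
#' @param f Allele frequency in [0, 1].
#' @param beta_std Per-allele effect on the standardized trait.
#' @return Fraction of variance explained (multiply by 100 for percent).
#' @export
explained_variance <- function(f, beta_std) {
  if (any(f < 0 | f > 1)) stop("f must be in [0,1]", call. = FALSE)
  fm <- pmin(f, 1 - f)
  2 * fm * (1 - fm) * beta_std^2
}

#' Convert a per-allele BMI effect to grams of body weight
#'
#' BMI = weight / height^2, so a per-allele effect of beta kg/m^2
#' corresponds to beta * height^2 kg, i.e. beta * height^2 * 1000 grams,
#' for a person of the given height.
#'
#' @param beta_bmi Per-allele BMI effect, kg/m^2.
#' @param height Height in meters (> 0).
#' @param round_grams Round to the nearest gram (display convention)?
#' @return Grams per allele.
#' @export
bmi_effect_to_weight <- function(beta_bmi, height, round_grams = TRUE) {
  if (any(height <= 0)) stop("height must be positive", call. = FALSE)
  g <- beta_bmi * height^2 * 1000
  if (round_grams) round(g) else g
}

#' Bonferroni-adjusted significance threshold
#'
#' @param alpha Family-wise level.
#' @param m Number of tests (>= 1).
#' @return alpha / m.
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  alpha / m
}
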