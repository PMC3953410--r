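#' Format a beta (SE) cell
#'
#' @param beta,se Numeric estimate and standard error.
#' @param digits Decimal places (default 2).
#' @return Character, e.g. `"0.11 (0.02)"`.
#' @export
format_beta_se <- function(beta, se, digits = 2) {
  sprintf("%.*f (%.*f)", digits, beta, digits, se)
}

#' Format an OR (95% CI) cell
#'
#' @param or,lo,hi Odds ratio and CI bounds.
#' @return Character, e.g. `"1.06 (1.03-1.10)"`.
#' @export
format_or_ci <- function(or, lo, hi) {
  sprintf("%.2f (%.2f-%.2f)", or, lo, hi)
}

#' Format a p-value for report tables
#'
#' Two significant figures; scientific notation (upper-case E) below 0.001,
#' e.g. `"1.54E-07"`.
#'
#' @param p P-value(s).
#' @return Character vector.
#' @export
format_p <- function(p) {
  vapply(p, function(x) {
    if (is.na(x)) return("NA")
    if (x < 0.001) sprintf("%.2E", x)
    else format(signif(x, 2), scientific = FALSE)
  }, character(1))
}

#' Render an analysis result table in a report layout
#'
#' Formats a results data.frame into tab-delimited text shaped like the
#' standard report tables: `table1` (per-SNP and per-score BMI
#' associations: beta (SE), p, explained variance), `table2`
#' (fat-percentage traits side by side), `table3` (obesity and overweight
#' odds-ratio contrasts side by side), `table4` (PA-stratified score
#' effects plus the interaction term). Betas/SEs and ORs/CIs print with 2
#' decimals; p-values per [format_p()].
#'
#' @param results A data.frame; required columns depend on the layout
#'   (`table1`: label, beta, se, p, and optionally eaf, explained_var_pct;
#'   `table2`: label and beta/se/p triples suffixed _body, _trunk, _leg;
#'   `table3`: label and or/ci_low/ci_high/p suffixed _ob, _ow; `table4`:
#'   label, beta/se/p for low/moderate/high strata plus beta_int, se_int,
#'   p_int).
#' @param layout One of `"table1"`, `"table2"`, `"table3"`, `"table4"`.
#' @return Character scalar of tab-delimited text (header + rows).
#' @export
render_table <- function(results, layout = c("table1", "table2", "table3",
                                             "table4")) {
  layout <- match.arg(layout)
  if (is.null(results) || nrow(as.data.frame(results)) == 0L) {
    stop("empty results cannot be rendered", call. = FALSE)
  }
  results <- as.data.frame(results)
  need <- function(cols) {
    miss <- setdiff(cols, names(results))
    if (length(miss) > 0L) {
      stop(sprintf("layout %s needs column(s): %s", layout,
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
  }
  rows <- switch(layout,
    table1 = {
      need(c("label", "beta", "se", "p"))
      header <- "Predictor\tEAF\tBeta (SE)\tP\tExplained variance (%)"
      body <- sprintf("%s\t%s\t%s\t%s\t%s",
        results$label,
        if ("eaf" %in% names(results)) ifelse(is.na(results$eaf), "",
                                              sprintf("%.2f", results$eaf)) else "",
        format_beta_se(results$beta, results$se),
        format_p(results$p),
        if ("explained_var_pct" %in% names(results))
          ifelse(is.na(results$explained_var_pct), "",
                 sprintf("%.2f", results$explained_var_pct)) else "")
      c(header, body)
    },
    table2 = {
      need(c("label", "beta_body", "se_body", "p_body", "beta_trunk",
             "se_trunk", "p_trunk", "beta_leg", "se_leg", "p_leg"))
      header <- paste("Predictor", "Body fat % Beta (SE)", "P",
                      "Trunk fat % Beta (SE)", "P",
                      "Leg fat % Beta (SE)", "P", sep = "\t")
      body <- sprintf("%s\t%s\t%s\t%s\t%s\t%s\t%s",
        results$label,
        format_beta_se(results$beta_body, results$se_body),
        format_p(results$p_body),
        format_beta_se(results$beta_trunk, results$se_trunk),
        format_p(results$p_trunk),
        format_beta_se(results$beta_leg, results$se_leg),
        format_p(results$p_leg))
      c(header, body)
    },
    table3 = {
      need(c("label", "or_ob", "ci_low_ob", "ci_high_ob", "p_ob",
             "or_ow", "ci_low_ow", "ci_high_ow", "p_ow"))
      header <- paste("Predictor", "Obesity vs. Normal OR (95% CI)", "P",
                      "Overweight vs. Normal OR (95% CI)", "P", sep = "\t")
      body <- sprintf("%s\t%s\t%s\t%s\t%s",
        results$label,
        format_or_ci(results$or_ob, results$ci_low_ob, results$ci_high_ob),
        format_p(results$p_ob),
        format_or_ci(results$or_ow, results$ci_low_ow, results$ci_high_ow),
        format_p(results$p_ow))
      c(header, body)
    },
    table4 = {
      need(c("label", "beta_low", "se_low", "p_low", "beta_mod", "se_mod",
             "p_mod", "beta_high", "se_high", "p_high", "beta_int",
             "se_int", "p_int"))
      header <- paste("Score", "Low PA Beta (SE)", "P",
                      "Moderate PA Beta (SE)", "P", "High PA Beta (SE)",
                      "P", "Interaction Beta (SE)", "P", sep = "\t")
      body <- sprintf("%s\t%s\t%s\t%s\t%s\t%s\t%s\t%s\t%s",
        results$label,
        format_beta_se(results$beta_low, results$se_low),
        format_p(results$p_low),
        format_beta_se(results$beta_mod, results$se_mod),
        format_p(results$p_mod),
        format_beta_se(results$beta_high, results$se_high),
        format_p(results$p_high),
        format_beta_se(results$beta_int, results$se_int),
        format_p(results$p_int))
      c(header, body)
    })
  paste(rows, collapse = "\n")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; keys mirror the arguments of [run_pipeline()]
#'   (`input` with panel/genotypes/phenotypes paths, or `simulation` with
#'   [sim_config()] fields; `qc`, `grs`, `seed`, `out_dir`).
#' @return A named list.
#' @export
read_pipeline_config <- function(path) {
  yaml::read_yaml(path)
}

#' Run the full risk-score analysis pipeline
#'
#' Orchestrates the stages end-to-end: load (or simulate) panel, genotypes
#' and phenotypes; per-SNP QC (call rate + exact HWE); overall/EA/EAA risk
#' scores with the mean-imputation rule; per-SNP and per-score linear
#' associations with BMI (raw and inverse-normal transformed, with
#' explained variance from the standardized-trait fit) and with the DXA
#' fat-percentage traits; logistic obesity/overweight contrasts;
#' directional-consistency sign tests; and the score-by-PA interaction
#' models with stratified effects. Every exclusion is accounted for in the
#' run manifest; a fixed seed makes the simulated run fully reproducible.
#'
#' @param config A named list (see [read_pipeline_config()]): either
#'   `config$input = list(panel=, genotypes=, phenotypes=)` or
#'   `config$simulation` (a list of [sim_config()] overrides); optional
#'   `qc = list(call_rate_min=, hwe_p_min=)`, `grs = list(max_missing=)`,
#'   `seed`, `out_dir`.
#' @return A list (class `pipeline_result`) with `qc_report`,
#'   `kept_snps`, `grs_summaries`, `table1`, `table2`, `table3`, `table4`
#'   (data.frames), `sign_tests`, `rendered` (formatted text per table),
#'   and `manifest`. When `config$out_dir` is set the rendered tables, the
#'   QC report and the manifest are also written there.
#' @export
run_pipeline <- function(config) {
  has_input <- !is.null(config$input)
  has_sim <- !is.null(config$simulation)
  if (has_input == has_sim) {
    stop("config must set exactly one of 'input' and 'simulation'",
         call. = FALSE)
  }
  seed <- if (!is.null(config$seed)) as.integer(config$seed) else 1L
  stage <- "load"
  manifest <- list(seed = seed, r_version = R.version.string,
                   package_version = as.character(
                     utils::packageVersion("grsobesity")),
                   stages = list())
  result <- try({
    if (has_input) {
      panel <- read_panel(config$input$panel)
      geno <- read_genotypes(config$input$genotypes, panel)
      phen <- read_phenotypes(config$input$phenotypes)
    } else {
      sim_args <- config$simulation
      sim_args$seed <- seed
      cfg <- do.call(sim_config, sim_args)
      coh <- simulate_cohort(cfg)
      panel <- cfg$panel
      geno <- coh$genotypes
      phen <- coh$phenotypes
    }
    manifest$config_hash <- hash_config(config)
    manifest$stages$load <- list(n_individuals = nrow(geno),
                                 n_snps = ncol(geno))

    stage <- "qc"
    qc_cfg <- config$qc
    qc_report <- snp_qc(geno,
      call_rate_min = if (!is.null(qc_cfg$call_rate_min)) qc_cfg$call_rate_min else 0.95,
      hwe_p_min = if (!is.null(qc_cfg$hwe_p_min)) qc_cfg$hwe_p_min else 0.01)
    kept <- qc_report$rsid[qc_report$pass]
    manifest$stages$qc <- list(n_pass = length(kept),
                               n_fail = sum(!qc_report$pass))

    stage <- "grs"
    max_missing <- if (!is.null(config$grs$max_missing)) config$grs$max_missing else 3L
    kp <- panel[panel$rsid %in% kept, , drop = FALSE]
    subsets <- list(GRS = kp$rsid,
                    `EA GRS` = kp$rsid[kp$in_ea_set],
                    `EAA GRS` = kp$rsid[kp$in_eaa_set])
    grs_list <- lapply(subsets, function(snps) {
      compute_grs(geno, panel, subset = snps, max_missing = max_missing)
    })
    grs_summaries <- lapply(grs_list, grs_summary)
    manifest$stages$grs <- list(
      n_scored = vapply(grs_list, nrow, integer(1)),
      n_excluded = vapply(grs_list,
                          function(g) nrow(attr(g, "exclusions")), integer(1)))

    stage <- "association"
    dat <- merge_scores(phen, grs_list)
    covs_bmi <- covariate_set(dat, "bmi-set")
    covs_dxa <- covariate_set(dat, "dxa-set")
    geno_o <- geno[match(dat$individual_id, rownames(geno)), , drop = FALSE]

    one_linear <- function(predictor, label, trait, covs, transform = FALSE) {
      linear_assoc(dat[[trait]], predictor, covs, transform = transform,
                   predictor_name = label, trait_name = trait)
    }
    predictors <- c(
      stats::setNames(lapply(kept, function(rs) as.numeric(geno_o[, rs])), kept),
      lapply(grs_list, function(g) {
        g$score[match(dat$individual_id, g$individual_id)]
      }))
    labels <- names(predictors)

    t1_rows <- lapply(labels, function(lb) {
      raw <- one_linear(predictors[[lb]], lb, "bmi", covs_bmi)
      std <- one_linear(predictors[[lb]], lb, "bmi", covs_bmi, transform = TRUE)
      eaf <- panel$eaf[match(lb, panel$rsid)]
      ev <- if (!is.na(eaf)) 100 * explained_variance(eaf, std$beta) else NA_real_
      data.frame(label = lb, eaf = eaf, beta = raw$beta, se = raw$se,
                 p = raw$p, beta_std = std$beta,
                 explained_var_pct = ev, n = raw$n)
    })
    table1 <- do.call(rbind, t1_rows)

    has_dxa <- all(c("body_fat_pct", "trunk_fat_pct", "leg_fat_pct")
                   %in% names(dat)) &&
      sum(stats::complete.cases(dat$body_fat_pct)) > ncol(covs_dxa) + 4L
    table2 <- if (has_dxa) {
      t2_rows <- lapply(labels, function(lb) {
        fat <- lapply(c(body = "body_fat_pct", trunk = "trunk_fat_pct",
                        leg = "leg_fat_pct"),
                      function(tr) one_linear(predictors[[lb]], lb, tr, covs_dxa))
        data.frame(label = lb,
                   beta_body = fat$body$beta, se_body = fat$body$se,
                   p_body = fat$body$p,
                   beta_trunk = fat$trunk$beta, se_trunk = fat$trunk$se,
                   p_trunk = fat$trunk$p,
                   beta_leg = fat$leg$beta, se_leg = fat$leg$se,
                   p_leg = fat$leg$p)
      })
      do.call(rbind, t2_rows)
    } else NULL

    # a single degenerate per-SNP fit (e.g. separation at a rare allele)
    # yields an NA row and a manifest note rather than aborting the run
    fit_failures <- character(0)
    safe_logistic <- function(lb, case) {
      tryCatch(
        suppressWarnings(logistic_assoc(dat$weight_class, case, "normal",
                                        predictors[[lb]], covs_bmi,
                                        predictor_name = lb)),
        error = function(e) {
          fit_failures <<- c(fit_failures,
                             sprintf("%s [%s]: %s", lb, case, e$message))
          list(odds_ratio = NA_real_, ci_low = NA_real_,
               ci_high = NA_real_, p = NA_real_)
        })
    }
    t3_rows <- lapply(labels, function(lb) {
      ob <- safe_logistic(lb, "obese")
      ow <- safe_logistic(lb, "overweight")
      data.frame(label = lb,
                 or_ob = ob$odds_ratio, ci_low_ob = ob$ci_low,
                 ci_high_ob = ob$ci_high, p_ob = ob$p,
                 or_ow = ow$odds_ratio, ci_low_ow = ow$ci_low,
                 ci_high_ow = ow$ci_high, p_ow = ow$p)
    })
    table3 <- do.call(rbind, t3_rows)
    manifest$stages$association <- list(n_predictors = length(labels),
                                        logistic_fit_failures = fit_failures)

    stage <- "sign_tests"
    snp_rows <- table1[table1$label %in% kept, ]
    ref <- stats::setNames(rep(1, nrow(snp_rows)), snp_rows$label)
    cc <- count_consistent(stats::setNames(snp_rows$beta, snp_rows$label), ref)
    sign_tests <- list(bmi = c(
      list(trait = "bmi"),
      sign_binomial_test(cc$n_consistent, cc$n_total)[c("n_total",
                                                        "n_consistent",
                                                        "p_one_sided")]))

    stage <- "interaction"
    pa_code <- as.integer(dat$pa_level) - 1L
    t4_rows <- lapply(names(grs_list), function(lb) {
      ir <- fit_interaction(dat$bmi, predictors[[lb]], pa_code, covs_bmi,
                            predictor_name = lb, trait_name = "bmi")
      st <- ir$strata
      data.frame(label = lb,
                 beta_low = st$beta[1], se_low = st$se[1], p_low = st$p[1],
                 beta_mod = st$beta[2], se_mod = st$se[2], p_mod = st$p[2],
                 beta_high = st$beta[3], se_high = st$se[3],
                 p_high = st$p[3],
                 beta_int = ir$beta_interaction, se_int = ir$se,
                 p_int = ir$p,
                 attenuation_pct = ir$attenuation_pct, n = ir$n)
    })
    table4 <- do.call(rbind, t4_rows)
    manifest$stages$interaction <- list(
      n = table4$n[1],
      pa_counts = as.list(table(dat$pa_level)))

    rendered <- list(table1 = render_table(table1, "table1"),
                     table3 = render_table(table3, "table3"),
                     table4 = render_table(table4, "table4"))
    if (!is.null(table2)) rendered$table2 <- render_table(table2, "table2")

    list(qc_report = qc_report, kept_snps = kept,
         grs_summaries = grs_summaries,
         table1 = table1, table2 = table2, table3 = table3,
         table4 = table4, sign_tests = sign_tests,
         rendered = rendered, manifest = manifest)
  }, silent = TRUE)
  if (inherits(result, "try-error")) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 attr(result, "condition")$message), call. = FALSE)
  }
  if (!is.null(config$out_dir)) {
    write_pipeline_outputs(result, config$out_dir)
  }
  class(result) <- "pipeline_result"
  result
}

merge_scores <- function(phen, grs_list) {
  dat <- phen
  # restrict to individuals scored in all subsets (missingness cap)
  common <- Reduce(intersect, lapply(grs_list, function(g) g$individual_id))
  dat <- dat[dat$individual_id %in% common, , drop = FALSE]
  dat
}

hash_config <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(config), tmp)
  unname(tools::md5sum(tmp))
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(result$rendered)) {
    writeLines(result$rendered[[nm]], file.path(out_dir, paste0(nm, ".tsv")))
  }
  utils::write.table(result$qc_report, file.path(out_dir, "qc_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(yaml::as.yaml(result$manifest),
             file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}
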