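#' Per-rat mean viscoelasticity estimates
#'
#' Reduces a cohort to one row per rat: the mean elasticity and viscosity
#' per method. In `fast` mode the measurement-level parameters are averaged
#' directly; in `full_physics` mode each rat's replicate curves are measured
#' through the physical simulators and pipelines ([cohort_to_curves]) and a
#' Voigt fit per method provides the estimates.
#'
#' @param rats List of `rat_record`s.
#' @param mode `"fast"` or `"full_physics"`.
#' @param rho Mass density, kg/m^3.
#' @param seed Base seed (full_physics measurement noise).
#' @param noise Relative measurement noise for full_physics mode.
#' @return A data.frame: `rat_id, stage, mu_swe, eta_swe, mu_dma, eta_dma`
#'   (kPa / Pa s).
#' @export
rat_estimates <- function(rats, mode = c("fast", "full_physics"), rho = 1000,
                          seed = 1L, noise = 0) {
  mode <- match.arg(mode)
  rows <- lapply(rats, function(r) {
    if (mode == "fast") {
      sm <- colMeans(r$swe_measurements)
      dm <- colMeans(r$dma_measurements)
      data.frame(rat_id = r$rat_id, stage = r$stage,
                 mu_swe = sm[["mu_kpa"]], eta_swe = sm[["eta_pas"]],
                 mu_dma = dm[["mu_kpa"]], eta_dma = dm[["eta_pas"]])
    } else {
      cv <- cohort_to_curves(r, "full_physics", rho = rho,
                             seed = seed + 1000L * r$rat_id, noise = noise)
      fs <- fit_dispersion(cv$swe, "voigt", rho)
      fd <- fit_dispersion(cv$dma, "voigt", rho)
      data.frame(rat_id = r$rat_id, stage = r$stage,
                 mu_swe = fs$params$mu / 1000, eta_swe = fs$params$eta,
                 mu_dma = fd$params$mu / 1000, eta_dma = fd$params$eta)
    }
  })
  do.call(rbind, rows)
}

#' Per-rat combined-band Voigt estimates
#'
#' Builds each rat's DMA-band and SWE-band dispersion curves (from the
#' per-rat mean parameters in fast mode) and fits the single wide-band
#' Voigt model, yielding the combined elasticity and viscosity used for
#' staging.
#'
#' @param est Data.frame from [rat_estimates].
#' @param rho Mass density, kg/m^3.
#' @return `est` with columns `mu_comb` (kPa) and `eta_comb` (Pa s) added.
#' @export
combined_rat_estimates <- function(est, rho = 1000) {
  mu_c <- eta_c <- numeric(nrow(est))
  for (i in seq_len(nrow(est))) {
    pswe <- rheo_params("voigt", 1000 * est$mu_swe[i], est$eta_swe[i])
    pdma <- rheo_params("voigt", 1000 * est$mu_dma[i], est$eta_dma[i])
    fit <- combined_estimate(
      model_dispersion(pdma, dma_default_freqs(), rho, band = "dma"),
      model_dispersion(pswe, seq(160, 380, 20), rho, band = "swe"), rho)
    mu_c[i] <- fit$params$mu / 1000
    eta_c[i] <- fit$params$eta
  }
  est$mu_comb <- mu_c
  est$eta_comb <- eta_c
  est
}

#' Full study report for a cohort
#'
#' Assembles the study's statistical analysis from per-rat estimates:
#' \itemize{
#'   \item stage-wise mean and SD per method and parameter, after the
#'     1.5 IQR outlier exclusion within each stage group;
#'   \item Welch t tests between methods within each stage;
#'   \item one-way ANOVA with Tukey--Kramer pairwise comparisons across
#'     stages, per method and parameter;
#'   \item Pearson correlation between SWE and DMA per-rat means (elasticity
#'     and viscosity);
#'   \item combined-band Voigt estimates per rat and ROC staging analyses
#'     (S0 vs S1--S4 and S0--S1 vs S2--S4) on the combined elasticity.
#' }
#'
#' @param rats List of `rat_record`s from [generate_cohort].
#' @param mode Estimation mode, see [rat_estimates].
#' @param rho Mass density, kg/m^3.
#' @param seed Base seed for full_physics noise.
#' @param noise Relative noise for full_physics measurements.
#' @return A `study_report` list: `estimates`, `stage_summary`,
#'   `method_tests`, `anova`, `tukey`, `correlation`, `roc`.
#' @export
study_report <- function(rats, mode = "fast", rho = 1000, seed = 1L,
                         noise = 0) {
  est <- rat_estimates(rats, mode, rho, seed, noise)
  est <- combined_rat_estimates(est, rho)
  stages <- c("S0", "S1", "S2", "S3", "S4")
  stages <- stages[stages %in% est$stage]
  params <- c("mu_swe", "eta_swe", "mu_dma", "eta_dma", "mu_comb", "eta_comb")

  # stage summaries with IQR exclusion
  summ <- list(); filtered <- list()
  for (pp in params) {
    for (ss in stages) {
      v <- est[[pp]][est$stage == ss]
      fl <- suppressWarnings(iqr_filter(v))
      filtered[[paste(pp, ss)]] <- fl$kept
      summ[[length(summ) + 1L]] <- data.frame(
        parameter = pp, stage = ss, n = length(fl$kept),
        n_excluded = length(fl$excluded),
        mean = mean(fl$kept), sd = stats::sd(fl$kept))
    }
  }
  stage_summary <- do.call(rbind, summ)

  # Welch t between methods per stage
  mt <- list()
  for (ss in stages) {
    for (quant in c("mu", "eta")) {
      x <- filtered[[paste(paste0(quant, "_swe"), ss)]]
      y <- filtered[[paste(paste0(quant, "_dma"), ss)]]
      tt <- method_t_test(x, y)
      mt[[length(mt) + 1L]] <- data.frame(stage = ss, parameter = quant,
                                          t = tt$t, p = tt$p)
    }
  }
  method_tests <- do.call(rbind, mt)

  # ANOVA + Tukey across stages
  anova_res <- list(); tukey_res <- list()
  for (pp in params) {
    gr <- lapply(stages, function(ss) filtered[[paste(pp, ss)]])
    av <- one_way_anova(gr)
    anova_res[[pp]] <- av
    tk <- tukey_kramer(gr)
    tk$stage_i <- stages[tk$i]
    tk$stage_j <- stages[tk$j]
    tukey_res[[pp]] <- tk
  }

  correlation <- list(
    elasticity = pearson_test(est$mu_swe, est$mu_dma),
    viscosity = pearson_test(est$eta_swe, est$eta_dma))

  roc <- list(
    s0_vs_rest = roc_analysis(est$mu_comb, est$stage != "S0"),
    s01_vs_s234 = roc_analysis(est$mu_comb, !(est$stage %in% c("S0", "S1"))))

  structure(list(estimates = est, stage_summary = stage_summary,
                 method_tests = method_tests, anova = anova_res,
                 tukey = tukey_res, correlation = correlation, roc = roc),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  cat(sprintf("  %d rats, stages: %s\n", nrow(x$estimates),
              paste(table(x$estimates$stage), collapse = "/")))
  cat(sprintf("  elasticity SWE~DMA: r = %.3f (p = %.3g)\n",
              x$correlation$elasticity$r, x$correlation$elasticity$p))
  cat(sprintf("  viscosity  SWE~DMA: r = %.3f (p = %.3g)\n",
              x$correlation$viscosity$r, x$correlation$viscosity$p))
  cat(sprintf("  ROC S0 vs S1-S4: AUROC %.3f, cutoff %.2f kPa\n",
              x$roc$s0_vs_rest$auroc, x$roc$s0_vs_rest$cutoff))
  cat(sprintf("  ROC S0-S1 vs S2-S4: AUROC %.3f, cutoff %.2f kPa\n",
              x$roc$s01_vs_s234$auroc, x$roc$s01_vs_s234$cutoff))
  invisible(x)
}

#' Run the full synthetic study and write its artifacts
#'
#' Generates a cohort, computes the [study_report], and writes the cohort
#' measurement table (CSV), the stage summaries (CSV) and the test results
#' (JSON) under `out_dir`. Fully reproducible from `(config, seed)`.
#'
#' @param config A [cohort_config]; its seed is overridden by `seed`.
#' @param seed Integer seed.
#' @param mode `"fast"` or `"full_physics"`.
#' @param out_dir Output directory (created if missing); `NULL` skips
#'   writing.
#' @return The `study_report`, invisibly with `$cohort` attached.
#' @export
run_study <- function(config = cohort_config(), seed = 1L, mode = "fast",
                      out_dir = NULL) {
  config$seed <- as.integer(seed)
  rats <- generate_cohort(config)
  rep <- study_report(rats, mode = mode, seed = seed)
  rep$cohort <- rats
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(cohort_table(rats),
                     file.path(out_dir, "cohort.csv"), row.names = FALSE)
    utils::write.csv(rep$stage_summary,
                     file.path(out_dir, "stage_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(rep$estimates, file.path(out_dir, "rat_estimates.csv"),
                     row.names = FALSE)
    tests <- list(
      correlation = rep$correlation,
      anova = rep$anova,
      roc = lapply(rep$roc, unclass),
      method_tests = rep$method_tests)
    jsonlite::write_json(tests, file.path(out_dir, "tests.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  invisible(rep)
}
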