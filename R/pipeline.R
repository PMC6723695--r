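#' End-to-end uric-acid Mendelian-randomization analysis on one cohort
#'
#' Chains the full instrument-construction and causal-analysis pipeline on
#' a (by default simulated) biobank-style cohort: quality-control filter,
#' stage-1 association scan with FDR control, stage-2 confirmation with
#' sign concordance, pooled re-estimation, representative tag-SNP selection
#' per gene region, weighted-score construction and grouping,
#' instrument-strength diagnostics, mixture cure regression of lifetime
#' disease risk under the three score codings, and MR-Egger / IVW
#' sensitivity analyses.
#'
#' @param cohort list with elements \code{genotypes} and \code{data} as
#'   produced by \code{\link{simulate_uamr_cohort}}; simulated when
#'   \code{NULL}.
#' @param n,seed,... forwarded to \code{\link{simulate_uamr_cohort}} when
#'   \code{cohort} is \code{NULL}.
#' @param n_stage1 size of the discovery stage; the remaining subjects form
#'   the confirmation stage.
#' @param q_alpha,confirm_alpha thresholds of
#'   \code{\link{two_stage_confirm}}.
#' @param covariate_cols columns of \code{cohort$data} adjusted for in the
#'   association scans.
#' @param out_dir optional directory: stage artifacts are written there as
#'   TSV/JSON with the seed recorded.
#' @return object of class \code{"uamr_report"}: a list with the QC log,
#'   both association tables, the confirmation table, tag weights, scores
#'   and groups, instrument diagnostics, the three mixture fits (as in
#'   \code{\link{compare_codings}}) and the MR sensitivity results.
#' @export
run_uamr <- function(cohort = NULL, n = 10000, seed = NULL,
                     n_stage1 = round(0.7 * n), q_alpha = 0.05,
                     confirm_alpha = 0.05,
                     covariate_cols = c("recruit_age", "male", "bmi",
                                        paste0("pc", 1:5)),
                     out_dir = NULL, ...) {
  if (is.null(cohort))
    cohort <- simulate_uamr_cohort(n = n, seed = seed, ...)
  geno <- cohort$genotypes
  dat <- cohort$data
  n <- nrow(dat)
  stage1_idx <- seq_len(min(n_stage1, n - 1))
  stage2_idx <- setdiff(seq_len(n), stage1_idx)

  qc <- qc_filter(geno)
  covars <- dat[covariate_cols]
  sub_geno <- function(idx) {
    structure(list(dosage = geno$dosage[idx, qc$kept, drop = FALSE],
                   map = geno$map[match(qc$kept, geno$map$snp_id), ]),
              class = "genotypes")
  }
  scan1 <- assoc_scan(sub_geno(stage1_idx), dat$sua[stage1_idx],
                      covars[stage1_idx, ])
  scan1$q_value <- fdr_adjust(scan1$p_value)
  scan2 <- assoc_scan(sub_geno(stage2_idx), dat$sua[stage2_idx],
                      covars[stage2_idx, ])
  conf <- two_stage_confirm(scan1, scan2, q_alpha, confirm_alpha)
  if (length(conf$confirmed) == 0) {
    message("no SNPs confirmed; stopping before tag selection")
    return(structure(list(qc = qc, stage1 = scan1, stage2 = scan2,
                          confirmation = conf, seed = seed),
                     class = "uamr_report"))
  }
  pooled <- assoc_scan(sub_geno(seq_len(n)), dat$sua, covars,
                       snp_ids = conf$confirmed)
  region_of <- stats::setNames(geno$map$region_id, geno$map$snp_id)
  pooled$bp <- geno$map$bp[match(pooled$snp_id, geno$map$snp_id)]
  weights <- select_tag_snps(pooled, region_of)

  score <- compute_wgrs(geno, weights)
  strength <- instrument_strength(score, dat$sua, covars)
  dat$wgrs <- score
  fits <- compare_codings(dat)

  status <- as.integer(dat$kind != "right_censored")
  out_assoc <- snp_outcome_assoc(geno, status,
                                 covariates = dat[, "male", drop = FALSE],
                                 snp_ids = conf$confirmed)
  pairs_all <- snp_assoc_pairs(pooled, out_assoc)
  pairs_tags <- pairs_all[pairs_all$snp_id %in% weights$snp_id, ]
  egger_all <- if (nrow(pairs_all) >= 3) mr_egger(pairs_all) else NULL
  egger_tags <- if (nrow(pairs_tags) >= 3) mr_egger(pairs_tags) else NULL
  ivw_tags <- if (nrow(pairs_tags) >= 2) mr_ivw(pairs_tags) else NULL

  report <- structure(list(
    qc = qc, stage1 = scan1, stage2 = scan2, confirmation = conf,
    pooled = pooled, weights = weights, scores = score,
    groups = list(quartile = group_scores(score, "quartile"),
                  median = group_scores(score, "median")),
    instrument = strength, fits = fits,
    mr = list(pairs_confirmed = pairs_all, pairs_tags = pairs_tags,
              egger_confirmed = egger_all, egger_tags = egger_tags,
              ivw_tags = ivw_tags),
    n = n, seed = seed), class = "uamr_report")
  if (!is.null(out_dir)) .write_uamr_artifacts(report, out_dir)
  report
}

.write_uamr_artifacts <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) utils::write.table(
    x, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(report$qc$log, "qc_exclusions.tsv")
  wt(report$stage1, "assoc_stage1.tsv")
  wt(report$stage2, "assoc_stage2.tsv")
  wt(report$confirmation$table, "two_stage_confirmation.tsv")
  wt(report$weights, "wgrs_weights.tsv")
  fit2 <- report$fits$two_group
  sm <- summary(fit2)
  jsonlite::write_json(list(
    seed = report$seed, n = report$n,
    instrument = report$instrument,
    two_group = list(coefficients = as.list(fit2$coefficients),
                     loglik = fit2$loglik, aic = fit2$aic,
                     or_high = sm$logistic["wgrs_high", ]),
    aic = report$fits$aic,
    mr_egger_tags = report$mr$egger_tags),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.uamr_report <- function(x, ...) {
  cat("Uric-acid MR pipeline report\n")
  cat(sprintf("  n = %d; QC kept %d/%d SNPs\n", x$n,
              length(x$qc$kept), nrow(x$qc$log)))
  cat(sprintf("  stage 1 discoveries: %d; confirmed: %d; tag SNPs: %d\n",
              length(x$confirmation$discovered),
              length(x$confirmation$confirmed),
              if (is.null(x$weights)) 0L else nrow(x$weights)))
  if (!is.null(x$instrument))
    cat(sprintf("  instrument: F = %.2f, incremental R^2 = %.4f\n",
                x$instrument$f_stat, x$instrument$r_squared))
  if (!is.null(x$fits)) {
    cat("  mixture-fit AICs by score coding:\n")
    print(x$fits$aic)
    sm <- summary(x$fits$two_group)
    cat("  two-group model, logistic part (OR scale):\n")
    print(round(sm$logistic, 3))
  }
  if (!is.null(x$mr$egger_tags))
    cat(sprintf("  MR-Egger (tag SNPs): intercept %.4f (p = %.2f), slope %.3f\n",
                x$mr$egger_tags$intercept, x$mr$egger_tags$intercept_p,
                x$mr$egger_tags$slope))
  invisible(x)
}

#' Onset-sequence analysis across diseases
#'
#' For each disease's event table, fits the Turnbull-Frydman step curve and
#' the sex-adjusted logistic-GGD mixture, and reports the estimated
#' susceptible fractions and the peak (modal) onset age - the quantities
#' that order diseases along the life course. Per-disease failures are
#' isolated and reported, not propagated.
#'
#' @param events named list of data frames, each holding event columns
#'   (\code{entry_age}, \code{kind}, \code{left}, \code{right}) and a
#'   \code{male} indicator.
#' @param age_grid grid for locating the density peak.
#' @return object of class \code{"onset_report"}: per disease the
#'   \code{turnbull} fit, the \code{cure_ggd} fit, susceptible fractions by
#'   sex and peak onset ages, or the error message when a stage failed.
#' @export
run_onset_sequence <- function(events, age_grid = seq(1, 100, by = 0.25)) {
  out <- lapply(names(events), function(ds) {
    d <- events[[ds]]
    tryCatch({
      tb <- turnbull(event_observations(d$entry_age, d$kind, d$left, d$right))
      fit <- cure_ggd(
        survival::Surv(left, ifelse(is.finite(right), right, NA_real_),
                       type = "interval2") ~ male,
        data = d, entry = ~entry_age)
      prof <- data.frame(male = c(0, 1),
                         row.names = c("female", "male"))
      pis <- predict(fit, prof, type = "susceptibility")
      dens <- predict(fit, prof, type = "density", times = age_grid)
      list(disease = ds, turnbull = tb, fit = fit,
           susceptible = stats::setNames(pis, rownames(prof)),
           peak_age = stats::setNames(age_grid[apply(dens, 2, which.max)],
                                      rownames(prof)))
    }, error = function(e) list(disease = ds, error = conditionMessage(e)))
  })
  names(out) <- names(events)
  structure(out, class = "onset_report")
}

#' @export
print.onset_report <- function(x, ...) {
  cat("Onset-sequence analysis\n")
  for (ds in names(x)) {
    r <- x[[ds]]
    if (!is.null(r$error)) {
      cat(sprintf("  %-22s FAILED: %s\n", ds, r$error))
    } else {
      cat(sprintf(
        "  %-22s susceptible F/M: %.2f/%.2f; peak onset F/M: %.0f/%.0f\n",
        ds, r$susceptible["female"], r$susceptible["male"],
        r$peak_age["female"], r$peak_age["male"]))
    }
  }
  invisible(x)
}
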