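#' Reference panel of serum-urate-associated SNPs
#'
#' The eight representative tag SNPs used for the weighted genetic risk
#' score, one per urate-associated gene region (MUC1, GCKR, SLC2A9, PKD2,
#' ABCG2, WDR1, IBSP, MEPE), with their published per-minor-allele effects
#' on serum uric acid (mg/dL). Minor-allele frequencies are synthetic:
#' chosen so each SNP's share of trait variance roughly matches its
#' published per-SNP R-squared at a trait SD of 1.5 mg/dL, capped near 0.5
#' where the implied frequency is unattainable.
#'
#' @return data frame with columns \code{snp_id}, \code{chrom}, \code{bp},
#'   \code{maf}, \code{beta_sua}, \code{region_id}.
#' @export
sua_snp_panel <- function() {
  data.frame(
    snp_id = c("rs4148155", "rs3733588", "rs2725211", "rs17013282",
               "rs17013187", "rs3756224", "rs1260326", "rs4072037"),
    chrom = c("4", "4", "4", "4", "4", "4", "2", "1"),
    bp = c(89054667L, 9997303L, 88970375L, 88765873L,
           88733531L, 10105739L, 27730940L, 155162067L),
    maf = c(0.31, 0.45, 0.32, 0.27, 0.50, 0.45, 0.45, 0.45),
    beta_sua = c(0.31, -0.24, 0.27, 0.20, 0.15, 0.11, 0.10, 0.11),
    region_id = c("ABCG2", "SLC2A9", "PKD2", "MEPE", "IBSP", "WDR1",
                  "GCKR", "MUC1"),
    stringsAsFactors = FALSE)
}

#' Simulate Hardy-Weinberg genotypes with optional within-region LD
#'
#' Minor-allele dosages (0/1/2) drawn by thresholding a latent Gaussian at
#' the Hardy-Weinberg genotype quantiles of each SNP's minor-allele
#' frequency. SNPs sharing a \code{region_id} share a latent factor with
#' loading \code{sqrt(ld_rho)}, inducing positive pairwise linkage
#' disequilibrium that grows monotonically with \code{ld_rho};
#' \code{ld_rho = 0} gives independent SNPs.
#'
#' @param snp_specs data frame like \code{\link{sua_snp_panel}} (columns
#'   \code{snp_id}, \code{maf}, \code{region_id}; \code{chrom}/\code{bp}
#'   optional).
#' @param n number of subjects.
#' @param ld_rho latent-factor correlation in \eqn{[0, 1)}.
#' @param miss_rate per-entry missingness probability (missing calls are
#'   \code{NA}).
#' @param seed optional integer seed set locally.
#' @return object of class \code{"genotypes"}: list with \code{dosage}
#'   (n x m integer matrix, columns named by SNP) and \code{map} (the spec
#'   table).
#' @export
simulate_genotypes <- function(snp_specs, n, ld_rho = 0, miss_rate = 0,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (NROW(snp_specs) == 0L) stop("empty snp_specs")
  stopifnot(n > 0, ld_rho >= 0, ld_rho < 1)
  if (is.null(snp_specs$region_id)) snp_specs$region_id <- snp_specs$snp_id
  if (any(snp_specs$maf <= 0 | snp_specs$maf > 0.5))
    stop("maf must be in (0, 0.5]")
  m <- nrow(snp_specs)
  z <- matrix(stats::rnorm(n * m), n, m)
  if (ld_rho > 0) {
    for (rg in unique(snp_specs$region_id)) {
      j <- which(snp_specs$region_id == rg)
      if (length(j) > 1) {
        u <- stats::rnorm(n)
        z[, j] <- sqrt(ld_rho) * u + sqrt(1 - ld_rho) * z[, j]
      }
    }
  }
  dos <- matrix(0L, n, m, dimnames = list(NULL, snp_specs$snp_id))
  for (j in seq_len(m)) {
    p <- snp_specs$maf[j]
    t0 <- stats::qnorm((1 - p)^2)
    t1 <- stats::qnorm((1 - p)^2 + 2 * p * (1 - p))
    dos[, j] <- (z[, j] > t0) + (z[, j] > t1)
  }
  if (miss_rate > 0)
    dos[matrix(stats::runif(n * m) < miss_rate, n, m)] <- NA_integer_
  structure(list(dosage = dos, map = as.data.frame(snp_specs)),
            class = "genotypes")
}

#' @export
print.genotypes <- function(x, ...) {
  cat(sprintf("genotypes: %d subjects x %d SNPs (%d regions)\n",
              nrow(x$dosage), ncol(x$dosage),
              length(unique(x$map$region_id))))
  invisible(x)
}

#' Simulate serum uric acid from an additive genetic model
#'
#' \eqn{SUA_i = \beta_0 + \sum_j \beta_j g_{ij} + \sum_k \gamma_k c_{ik}
#' + N(0, \sigma^2)}; missing dosages contribute their SNP's mean dosage so
#' every subject gets a value.
#'
#' @param genotypes a \code{"genotypes"} object.
#' @param covariates optional data frame of covariates.
#' @param covariate_effects named vector of effects (names must be columns
#'   of \code{covariates}).
#' @param intercept baseline mg/dL.
#' @param noise_sd residual SD, mg/dL.
#' @param seed optional seed.
#' @return numeric vector of SUA values (mg/dL).
#' @export
simulate_sua <- function(genotypes, covariates = NULL,
                         covariate_effects = NULL, intercept = 5.0,
                         noise_sd = 1.45, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(noise_sd >= 0)
  G <- genotypes$dosage
  if (anyNA(G)) {
    md <- colMeans(G, na.rm = TRUE)
    for (j in which(colSums(is.na(G)) > 0)) G[is.na(G[, j]), j] <- md[j]
  }
  sua <- intercept + as.vector(G %*% genotypes$map$beta_sua)
  if (!is.null(covariate_effects)) {
    if (!all(names(covariate_effects) %in% names(covariates)))
      stop("covariate_effects names missing from covariates")
    Cm <- as.matrix(covariates[names(covariate_effects)])
    sua <- sua + as.vector(Cm %*% covariate_effects)
  }
  sua + stats::rnorm(nrow(G), 0, noise_sd)
}

#' Sex-specific hyperuricemia classification
#'
#' Hyperuricemia is SUA at or above 7.7 mg/dL in men and 6.6 mg/dL in
#' women (boundary values are hyperuricemic).
#'
#' @param sua serum uric acid, mg/dL.
#' @param sex vector coded \code{"male"}/\code{"female"} (or \code{"M"}/
#'   \code{"F"}); any other code is an error.
#' @return logical vector.
#' @export
classify_hyperuricemia <- function(sua, sex) {
  sex <- tolower(as.character(sex))
  sex[sex == "m"] <- "male"; sex[sex == "f"] <- "female"
  bad <- !sex %in% c("male", "female")
  if (any(bad)) stop("unknown sex code: ", paste(unique(sex[bad]), collapse = ", "))
  cut <- ifelse(sex == "male", 7.7, 6.6)
  sua >= cut
}

#' Estimated glomerular filtration rate (MDRD study equation)
#'
#' \eqn{eGFR = 175 \times Scr^{-1.154} \times Age^{-0.203} \times
#' (0.742 \text{ if female}) \times (1.212 \text{ if African-American})},
#' in mL/min/1.73 m^2.
#'
#' @param scr serum creatinine, mg/dL (> 0).
#' @param age years (> 0).
#' @param female,african_american logical flags.
#' @return eGFR in mL/min/1.73 m^2.
#' @examples
#' compute_egfr(1.0, 50)  # 79.095
#' @export
compute_egfr <- function(scr, age, female = FALSE, african_american = FALSE) {
  if (any(scr <= 0) || any(age <= 0)) stop("scr and age must be positive")
  175 * scr^-1.154 * age^-0.203 *
    ifelse(female, 0.742, 1) * ifelse(african_american, 1.212, 1)
}

#' Generating values for the mixture cure model
#'
#' Container for the coefficients that generate (or describe) a
#' logistic-GGD mixture: log-odds of susceptibility, effects on mean log
#' onset age, effects on log sigma, and the shape. The default is the
#' two-group lifetime-CVD-risk model: baseline susceptibility 3.03\%
#' (women, low score), odds ratios 2.85 for men and 1.62 for the high-score
#' group, location 4.16, log-scale -2.37, shape 1.42.
#'
#' @param logistic named log-odds vector; first element is the intercept,
#'   remaining names must match covariate columns at simulation time.
#' @param location,scale named vectors likewise (intercept-only by
#'   default).
#' @param shape the GGD shape q.
#' @return object of class \code{"mixture_truth"}.
#' @export
mixture_truth <- function(logistic = c("(Intercept)" = stats::qlogis(0.0303),
                                       male = log(2.85), high = log(1.62)),
                          location = c("(Intercept)" = 4.16),
                          scale = c("(Intercept)" = -2.37),
                          shape = 1.42) {
  if (is.null(names(logistic)) || names(logistic)[1] == "")
    names(logistic)[1] <- "(Intercept)"
  if (is.null(names(location))) names(location)[1] <- "(Intercept)"
  if (is.null(names(scale))) names(scale)[1] <- "(Intercept)"
  stopifnot(is.finite(exp(scale[["(Intercept)"]])))
  structure(list(logistic = logistic, location = location, scale = scale,
                 shape = shape), class = "mixture_truth")
}

.truth_lp <- function(coefs, covariates, n) {
  lp <- rep(coefs[[1]], n)
  extra <- names(coefs)[-1]
  if (length(extra)) {
    if (!all(extra %in% names(covariates)))
      stop("covariates named in truth not present: ",
           paste(setdiff(extra, names(covariates)), collapse = ", "))
    lp <- lp + as.vector(as.matrix(covariates[extra]) %*% coefs[-1])
  }
  lp
}

#' Simulate onset-age observations from the mixture cure model
#'
#' Each subject is susceptible with probability
#' \eqn{\pi_i = \mathrm{logit}^{-1}(z_i'\beta)}; susceptible subjects get a
#' GGD onset age \eqn{\log T = \mu_i + \sigma_i W}. Two observation
#' schemes are emulated. Biobank-style (\code{mode = "twb"}): onset at or
#' before the recruitment age is recorded as an exact (self-reported) age,
#' otherwise the subject is right-censored at recruitment; no truncation.
#' Longitudinal-exam style (\code{mode = "cvdfacts"}): onset between two
#' consecutive examination ages yields an interval-censored record, onset
#' after the last exam (or non-susceptibility) a right-censored one; entry
#' age is the first exam, and subjects whose onset falls at or before entry
#' are excluded, which is exactly how left truncation arises in such
#' cohorts.
#'
#' @param covariates data frame with the columns named in \code{truth}.
#' @param truth a \code{\link{mixture_truth}}.
#' @param mode observation scheme.
#' @param recruit_age recruitment ages (TWB mode); a vector, or the name of
#'   a column of \code{covariates}; default column \code{"recruit_age"}.
#' @param exam_ages strictly increasing examination ages (CVDFACTS mode).
#' @param onset_resolution \code{"years"} records exact onsets to whole
#'   years (self-report realism; the likelihood still treats them as
#'   exact), \code{"exact"} keeps full resolution.
#' @param seed optional seed.
#' @return data frame: the event-observation columns
#'   (\code{subject_id, entry_age, kind, left, right}) followed by the
#'   covariate columns of the retained subjects (all subjects in TWB mode).
#' @export
simulate_event_times <- function(covariates, truth,
                                 mode = c("twb", "cvdfacts"),
                                 recruit_age = NULL, exam_ages = NULL,
                                 onset_resolution = c("years", "exact"),
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mode <- match.arg(mode)
  onset_resolution <- match.arg(onset_resolution)
  n <- nrow(covariates)
  pi_ <- stats::plogis(.truth_lp(truth$logistic, covariates, n))
  mu <- .truth_lp(truth$location, covariates, n)
  sig <- exp(.truth_lp(truth$scale, covariates, n))
  if (any(!is.finite(pi_)) || any(!is.finite(mu)) || any(!is.finite(sig)))
    stop("non-finite linear predictor in generating model")
  susceptible <- stats::rbinom(n, 1, pi_) == 1
  onset <- rep(Inf, n)
  onset[susceptible] <- rggd(sum(susceptible), mu[susceptible],
                             sig[susceptible], truth$shape)
  if (onset_resolution == "years")
    onset[susceptible] <- pmax(1, round(onset[susceptible]))
  if (mode == "twb") {
    if (is.null(recruit_age)) recruit_age <- "recruit_age"
    if (is.character(recruit_age)) recruit_age <- covariates[[recruit_age]]
    if (is.null(recruit_age)) stop("recruit_age required in TWB mode")
    recruit_age <- rep_len(recruit_age, n)
    ev <- onset <= recruit_age
    obs <- event_observations(
      entry_age = 0,
      kind = ifelse(ev, "exact", "right_censored"),
      left = ifelse(ev, onset, recruit_age),
      right = ifelse(ev, onset, Inf))
    return(cbind(obs, covariates))
  }
  if (is.null(exam_ages) || length(exam_ages) < 2 ||
      any(diff(exam_ages) <= 0))
    stop("cvdfacts mode needs strictly increasing exam_ages (>= 2)")
  entry <- exam_ages[1]
  keep <- !(susceptible & onset <= entry)  # left truncation by construction
  onset <- onset[keep]
  nk <- sum(keep)
  last <- exam_ages[length(exam_ages)]
  j <- findInterval(onset, exam_ages, left.open = TRUE)
  inband <- is.finite(onset) & onset <= last
  obs <- event_observations(
    entry_age = entry,
    kind = ifelse(inband, "interval", "right_censored"),
    left = ifelse(inband, exam_ages[pmax(j, 1)], last),
    right = ifelse(inband, exam_ages[pmin(j + 1, length(exam_ages))], Inf))
  cbind(obs, covariates[keep, , drop = FALSE])
}

#' Simulate a full biobank-style cohort for the uric-acid MR pipeline
#'
#' Generates genotypes at the tag-SNP panel (plus optional null SNPs),
#' covariates (sex, recruitment age, BMI, five standard-normal principal
#' components), serum uric acid from the additive model, the true weighted
#' score and its median split, and lifetime-CVD event observations from the
#' mixture cure model. This is the study design the analysis pipeline
#' assumes, so every downstream stage can be exercised without any data
#' download.
#'
#' @param n subjects.
#' @param panel SNP specification (default \code{\link{sua_snp_panel}}).
#' @param n_null_snps extra unassociated SNPs (MAF drawn uniform 0.05-0.5)
#'   appended to the panel for the association scan.
#' @param truth generating \code{\link{mixture_truth}}; its \code{male} and
#'   \code{high} terms are wired to the simulated sex and median-split true
#'   score.
#' @param ld_rho within-region LD of the causal panel.
#' @param frac_male fraction of men.
#' @param age_mean,age_sd,age_range recruitment-age distribution (normal,
#'   truncated to the range).
#' @param seed optional seed.
#' @return list with \code{genotypes} and \code{data} (covariates, SUA,
#'   true score/group and event columns), and the \code{truth} used.
#' @export
simulate_uamr_cohort <- function(n = 10000, panel = sua_snp_panel(),
                                 n_null_snps = 0, truth = mixture_truth(),
                                 ld_rho = 0, frac_male = 0.5,
                                 age_mean = 48.9, age_sd = 11.1,
                                 age_range = c(30, 70), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  specs <- panel
  if (n_null_snps > 0) {
    null_specs <- data.frame(
      snp_id = sprintf("null%04d", seq_len(n_null_snps)),
      chrom = sample(as.character(c(1:3, 5:12)), n_null_snps, TRUE),
      bp = sample.int(2e8, n_null_snps),
      maf = stats::runif(n_null_snps, 0.05, 0.5),
      beta_sua = 0,
      region_id = sprintf("null_region%04d", seq_len(n_null_snps)),
      stringsAsFactors = FALSE)
    specs <- rbind(panel, null_specs)
  }
  geno <- simulate_genotypes(specs, n, ld_rho = ld_rho)
  male <- stats::rbinom(n, 1, frac_male)
  age <- stats::rnorm(n, age_mean, age_sd)
  while (any(out <- age < age_range[1] | age > age_range[2]))
    age[out] <- stats::rnorm(sum(out), age_mean, age_sd)
  covars <- data.frame(male = male, recruit_age = age,
                       bmi = stats::rnorm(n, 24.3, 3.6))
  for (k in 1:5) covars[[paste0("pc", k)]] <- stats::rnorm(n)
  covars$sua <- simulate_sua(geno, covars,
                             covariate_effects = c(male = 1.3, bmi = 0.05))
  true_score <- as.vector(geno$dosage[, panel$snp_id, drop = FALSE] %*%
                            panel$beta_sua)
  covars$true_wgrs <- true_score
  covars$high <- as.integer(true_score > stats::median(true_score))
  data <- simulate_event_times(covars, truth, mode = "twb",
                               recruit_age = "recruit_age")
  list(genotypes = geno, data = data, truth = truth)
}
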