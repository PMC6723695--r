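#' Hardy-Weinberg equilibrium test from genotype counts
#'
#' Default is the 1-df chi-square goodness-of-fit test of the observed
#' genotype counts against the Hardy-Weinberg expectation; an exact test
#' (Wigginton-style enumeration of heterozygote counts conditional on the
#' allele counts) is available for small samples or rare alleles.
#'
#' @param n0,n1,n2 counts of major-homozygote, heterozygote and
#'   minor-homozygote genotypes.
#' @param method \code{"chisq"} (default) or \code{"exact"}.
#' @return two-sided p-value.
#' @examples
#' hwe_test(25, 50, 25)   # perfect HWE: p = 1
#' hwe_test(50, 0, 50)    # chi-square 100
#' @export
hwe_test <- function(n0, n1, n2, method = c("chisq", "exact")) {
  method <- match.arg(method)
  n <- n0 + n1 + n2
  if (n == 0) stop("all genotype counts are zero")
  if (method == "chisq") {
    p <- (n1 + 2 * n2) / (2 * n)
    e <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
    if (any(e == 0)) return(1)  # monomorphic: nothing to test
    x2 <- sum((c(n0, n1, n2) - e)^2 / e)
    return(stats::pchisq(x2, df = 1, lower.tail = FALSE))
  }
  # exact: enumerate heterozygote counts with fixed minor-allele count
  nA <- n1 + 2 * n2          # minor allele count (orientation-free)
  if (nA > n) nA <- 2 * n - nA
  if (nA == 0) return(1)
  het <- seq(nA %% 2, nA, by = 2)
  hom_min <- (nA - het) / 2
  hom_maj <- n - het - hom_min
  lp <- lfactorial(n) - lfactorial(het) - lfactorial(hom_min) -
    lfactorial(hom_maj) + het * log(2) +
    lfactorial(nA) + lfactorial(2 * n - nA) - lfactorial(2 * n)
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- which(het == n1)
  min(1, sum(pr[pr <= pr[obs] * (1 + 1e-12)]))
}

#' Quality-control filter for a genotype matrix
#'
#' A SNP is excluded if it is monomorphic among called genotypes, its
#' genotyping call rate is below \code{min_gcr}, its minor-allele frequency
#' is below \code{min_maf}, it deviates from Hardy-Weinberg equilibrium at
#' \code{hwe_alpha}, or it lies on a sex chromosome. The exclusion log
#' records the first triggered reason per SNP, in that order.
#'
#' @param genotypes a \code{"genotypes"} object (see
#'   \code{\link{simulate_genotypes}}; \code{NA} encodes a missing call).
#' @param min_gcr minimum genotyping call rate.
#' @param min_maf minimum minor-allele frequency (strict: MAF exactly at
#'   the threshold is kept).
#' @param hwe_alpha HWE p-value threshold (strict).
#' @param exclude_sex_chroms drop SNPs on X/Y (tokens X, Y, XY, 23, 24,
#'   25).
#' @param hwe_method passed to \code{\link{hwe_test}}.
#' @return list with \code{kept} (SNP ids) and \code{log} (data frame
#'   \code{snp_id}, \code{excluded}, \code{reason}).
#' @export
qc_filter <- function(genotypes, min_gcr = 0.95, min_maf = 0.01,
                      hwe_alpha = 0.001, exclude_sex_chroms = TRUE,
                      hwe_method = "chisq") {
  G <- genotypes$dosage
  map <- genotypes$map
  m <- ncol(G)
  reason <- rep(NA_character_, m)
  sex_tokens <- c("X", "Y", "XY", "23", "24", "25")
  for (j in seq_len(m)) {
    g <- G[, j]
    called <- !is.na(g)
    tab <- c(sum(g[called] == 0), sum(g[called] == 1), sum(g[called] == 2))
    maf <- (tab[2] + 2 * tab[3]) / (2 * sum(called))
    maf <- min(maf, 1 - maf)
    if (sum(tab > 0) <= 1) {
      reason[j] <- "nonpolymorphic"
    } else if (mean(called) < min_gcr) {
      reason[j] <- "low_call_rate"
    } else if (maf < min_maf) {
      reason[j] <- "low_maf"
    } else if (hwe_test(tab[1], tab[2], tab[3], hwe_method) < hwe_alpha) {
      reason[j] <- "hwe_deviation"
    } else if (exclude_sex_chroms &&
               toupper(as.character(map$chrom[j])) %in% sex_tokens) {
      reason[j] <- "sex_chromosome"
    }
  }
  excluded <- !is.na(reason)
  list(kept = map$snp_id[!excluded],
       log = data.frame(snp_id = map$snp_id, excluded = excluded,
                        reason = reason, stringsAsFactors = FALSE))
}

#' Per-SNP linear association scan of a quantitative trait
#'
#' For each SNP, ordinary least squares of the trait on the minor-allele
#' dosage (treated as 0/1/2 ordinal) plus covariates; two-sided p-values
#' from the t distribution. Subjects missing a SNP's genotype are dropped
#' for that SNP only (no imputation). A rank-deficient per-SNP design is
#' flagged (\code{NA} estimates), never an error.
#'
#' @param genotypes a \code{"genotypes"} object.
#' @param trait numeric trait vector (e.g. serum uric acid, mg/dL).
#' @param covariates optional data frame of adjustment covariates (age,
#'   sex, BMI, principal components, ...).
#' @param snp_ids subset of SNPs to scan (default all).
#' @return data frame with one row per SNP: \code{snp_id}, \code{beta}
#'   (trait units per minor allele), \code{se}, \code{t_stat},
#'   \code{p_value}, \code{n_used}.
#' @export
assoc_scan <- function(genotypes, trait, covariates = NULL, snp_ids = NULL) {
  G <- genotypes$dosage
  if (is.null(snp_ids)) snp_ids <- colnames(G)
  n <- length(trait)
  stopifnot(nrow(G) == n)
  C <- if (is.null(covariates)) matrix(1, n, 1) else
    cbind(1, as.matrix(covariates))
  res <- lapply(snp_ids, function(id) {
    g <- G[, id]
    use <- !is.na(g) & !is.na(trait) & stats::complete.cases(C)
    X <- cbind(g[use], C[use, , drop = FALSE])
    y <- trait[use]
    qr_ <- qr(X)
    if (qr_$rank < ncol(X))
      return(data.frame(snp_id = id, beta = NA_real_, se = NA_real_,
                        t_stat = NA_real_, p_value = NA_real_,
                        n_used = sum(use)))
    fit <- stats::lm.fit(X, y)
    df <- sum(use) - ncol(X)
    rss <- sum(fit$residuals^2)
    XtXinv11 <- chol2inv(qr.R(qr_))[1, 1]
    se <- sqrt(rss / df * XtXinv11)
    tval <- fit$coefficients[1] / se
    data.frame(snp_id = id, beta = fit$coefficients[1], se = se,
               t_stat = tval,
               p_value = 2 * stats::pt(-abs(tval), df),
               n_used = sum(use))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' False-discovery-rate adjustment
#'
#' \code{"bh"} gives Benjamini-Hochberg step-up adjusted p-values;
#' \code{"storey"} (the default, matching the positive-FDR convention)
#' gives q-values with the null proportion \eqn{\pi_0} estimated at a fixed
#' \eqn{\lambda = 0.5} (\code{pi0 = \#\{p > \lambda\} / (m(1-\lambda))},
#' capped at 1), or by the smoother extrapolation of \eqn{\pi_0(\lambda)}
#' to \eqn{\lambda \to 1} with \code{pi0_method = "smoother"}. Storey
#' q-values are the BH values scaled by \eqn{\pi_0}, hence never larger.
#'
#' @param p p-values in \eqn{[0, 1]} (NaN is an error).
#' @param method \code{"storey"} or \code{"bh"}.
#' @param lambda tuning constant for the fixed-lambda \eqn{\pi_0} estimate.
#' @param pi0_method \code{"fixed"} or \code{"smoother"}.
#' @return vector of q-values, same order as \code{p}.
#' @export
fdr_adjust <- function(p, method = c("storey", "bh"), lambda = 0.5,
                       pi0_method = c("fixed", "smoother")) {
  method <- match.arg(method)
  pi0_method <- match.arg(pi0_method)
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must be in [0, 1]")
  bh <- stats::p.adjust(p, method = "BH")
  if (method == "bh") return(bh)
  m <- length(p)
  if (pi0_method == "fixed") {
    pi0 <- min(1, sum(p > lambda) / (m * (1 - lambda)))
  } else {
    lam <- seq(0.05, 0.9, by = 0.05)
    pi0l <- vapply(lam, function(l) sum(p > l) / (m * (1 - l)), numeric(1))
    sp <- stats::smooth.spline(lam, pi0l, df = 3)
    pi0 <- min(1, max(stats::predict(sp, x = 0.9)$y, 0))
  }
  if (pi0 <= 0) pi0 <- 1 / m
  pmin(1, pi0 * bh)
}

#' Two-stage discovery and confirmation of associated SNPs
#'
#' Discovery: stage-1 q-value below \code{q_alpha}. Confirmation: stage-2
#' nominal p-value below \code{confirm_alpha} with an effect of the same
#' sign. SNPs discovered in stage 1 but absent from stage 2 are recorded as
#' unconfirmable.
#'
#' @param stage1,stage2 association tables from \code{\link{assoc_scan}};
#'   \code{stage1} must carry a \code{q_value} column (add one with
#'   \code{\link{fdr_adjust}}).
#' @param q_alpha stage-1 FDR threshold.
#' @param confirm_alpha stage-2 nominal threshold.
#' @return list with \code{confirmed} (SNP ids), \code{discovered},
#'   \code{unconfirmable}, and \code{table} (per discovered SNP: both
#'   stages' estimates and the decision).
#' @export
two_stage_confirm <- function(stage1, stage2, q_alpha = 0.05,
                              confirm_alpha = 0.05) {
  if (is.null(stage1$q_value)) stop("stage1 needs a q_value column")
  disc <- stage1[!is.na(stage1$q_value) & stage1$q_value < q_alpha, ]
  idx <- match(disc$snp_id, stage2$snp_id)
  unconf <- disc$snp_id[is.na(idx)]
  tab <- data.frame(
    snp_id = disc$snp_id,
    beta1 = disc$beta, q_value1 = disc$q_value,
    beta2 = stage2$beta[idx], p_value2 = stage2$p_value[idx])
  tab$confirmed <- !is.na(tab$beta2) & tab$p_value2 < confirm_alpha &
    sign(tab$beta1) == sign(tab$beta2)
  list(confirmed = tab$snp_id[tab$confirmed],
       discovered = disc$snp_id,
       unconfirmable = unconf,
       table = tab)
}

#' Composite linkage disequilibrium r-squared
#'
#' Squared Pearson correlation of minor-allele dosage vectors (composite
#' LD; no phasing).
#'
#' @param dosage_a,dosage_b dosage vectors on the same subjects.
#' @return r-squared in \eqn{[0, 1]}.
#' @export
ld_r2 <- function(dosage_a, dosage_b) {
  use <- !is.na(dosage_a) & !is.na(dosage_b)
  a <- dosage_a[use]; b <- dosage_b[use]
  if (stats::var(a) == 0 || stats::var(b) == 0)
    stop("zero-variance dosage vector")
  stats::cor(a, b)^2
}

#' Representative tag-SNP selection per gene region
#'
#' Within each region, keeps the single SNP with the largest absolute
#' trait effect (ties broken by smaller p-value, then smaller base-pair
#' position) - one representative per correlated region, so a score built
#' from the result is not dominated by large LD blocks.
#'
#' @param assoc association table (typically combined-sample estimates)
#'   with columns \code{snp_id}, \code{beta}, \code{p_value}.
#' @param region_of named character vector mapping snp_id to region, or a
#'   data frame with columns \code{snp_id}, \code{region_id}.
#' @return data frame of score weights: \code{snp_id}, \code{region_id},
#'   \code{beta} - the \code{weights} input of \code{\link{compute_wgrs}}.
#' @export
select_tag_snps <- function(assoc, region_of) {
  if (is.data.frame(region_of))
    region_of <- stats::setNames(region_of$region_id, region_of$snp_id)
  if (!all(assoc$snp_id %in% names(region_of)))
    stop("every SNP needs a region")
  assoc$region_id <- unname(region_of[assoc$snp_id])
  assoc$bp <- if (is.null(assoc$bp)) seq_len(nrow(assoc)) else assoc$bp
  picked <- lapply(split(assoc, assoc$region_id), function(d) {
    if (nrow(d) == 0L) return(NULL)
    o <- order(-abs(d$beta), d$p_value, d$bp)
    d[o[1], c("snp_id", "region_id", "beta")]
  })
  out <- do.call(rbind, picked)
  rownames(out) <- NULL
  out[order(-abs(out$beta)), ]
}
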