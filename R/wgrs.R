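#' Weighted genetic risk score
#'
#' \eqn{WGRS_i = \sum_j \beta_j g_{ij}}: minor-allele dosages weighted by
#' their per-allele trait effects (sign-aware; negative effects subtract).
#' Missing dosages are replaced by that SNP's mean dosage so every subject
#' is scorable (mean imputation is used for scoring only; the association
#' scan drops missing calls instead).
#'
#' @param genotypes a \code{"genotypes"} object.
#' @param weights data frame with columns \code{snp_id}, \code{beta}
#'   (e.g. from \code{\link{select_tag_snps}}).
#' @return numeric score vector; the subjects whose score used imputed
#'   dosages are listed in attribute \code{"imputed"}.
#' @export
compute_wgrs <- function(genotypes, weights) {
  G <- genotypes$dosage
  missing_snp <- setdiff(weights$snp_id, colnames(G))
  if (length(missing_snp))
    stop("weight SNP absent from genotypes: ",
         paste(missing_snp, collapse = ", "))
  Gm <- G[, weights$snp_id, drop = FALSE]
  imputed <- which(rowSums(is.na(Gm)) > 0)
  if (length(imputed)) {
    md <- colMeans(Gm, na.rm = TRUE)
    for (j in seq_len(ncol(Gm))) Gm[is.na(Gm[, j]), j] <- md[j]
  }
  score <- as.vector(Gm %*% weights$beta)
  attr(score, "imputed") <- imputed
  score
}

#' Group a risk score into quartiles or a median split
#'
#' Quartile mode cuts at the 25/50/75 sample percentiles with left-closed
#' bins (labels \code{Q1}-\code{Q4}); median mode labels scores at or below
#' the median \code{"low"} and above it \code{"high"} (ties at the median
#' go to \code{"low"}).
#'
#' @param scores numeric scores.
#' @param mode \code{"quartile"} or \code{"median"}.
#' @return a factor of group labels.
#' @export
group_scores <- function(scores, mode = c("quartile", "median")) {
  mode <- match.arg(mode)
  if (stats::var(scores, na.rm = TRUE) == 0) stop("constant scores")
  if (mode == "median") {
    md <- stats::median(scores)
    return(factor(ifelse(scores <= md, "low", "high"),
                  levels = c("low", "high")))
  }
  if (length(scores) < 4) stop("quartile mode needs n >= 4")
  qs <- stats::quantile(scores, c(0.25, 0.5, 0.75), names = FALSE)
  cut(scores, breaks = c(-Inf, qs, Inf), labels = paste0("Q", 1:4),
      right = FALSE)
}

#' Instrument-strength diagnostics for a genetic score
#'
#' Regresses the exposure on the score (plus optional covariates) and
#' reports the score's partial F statistic and its incremental R-squared
#' over the covariates - the standard check that a Mendelian-randomization
#' instrument is strong (F well above 10).
#'
#' @param scores instrument values.
#' @param exposure exposure trait (e.g. serum uric acid, mg/dL).
#' @param covariates optional data frame.
#' @return list with \code{f_stat}, \code{r_squared} (incremental), and
#'   \code{n}.
#' @export
instrument_strength <- function(scores, exposure, covariates = NULL) {
  use <- !is.na(scores) & !is.na(exposure)
  if (!is.null(covariates)) use <- use & stats::complete.cases(covariates)
  n <- sum(use)
  if (n <= 2) stop("need more than 2 complete observations")
  y <- exposure[use]
  if (is.null(covariates)) {
    f0 <- stats::lm(y ~ 1)
    f1 <- stats::lm(y ~ scores[use])
  } else {
    C <- as.matrix(covariates)[use, , drop = FALSE]
    f0 <- stats::lm(y ~ C)
    f1 <- stats::lm(y ~ scores[use] + C)
  }
  rss0 <- sum(stats::residuals(f0)^2)
  rss1 <- sum(stats::residuals(f1)^2)
  df1 <- f1$df.residual
  f_stat <- (rss0 - rss1) / (rss1 / df1)
  tss <- sum((y - mean(y))^2)
  list(f_stat = f_stat, r_squared = (rss0 - rss1) / tss, n = n)
}
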