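test_that("HWE chi-square matches hand computation; exact test agrees when balanced", {
  expect_equal(hwe_test(25, 50, 25), 1)
  # (50, 0, 50): expected (25, 50, 25), chi-square 100
  expect_lt(hwe_test(50, 0, 50), 1e-20)
  expect_equal(pchisq(100, 1, lower.tail = FALSE), hwe_test(50, 0, 50),
               tolerance = 1e-10)
  expect_error(hwe_test(0, 0, 0), "zero")
  set.seed(201)
  for (p in c(0.2, 0.35, 0.5)) {
    g <- rbinom(1000, 1, p) + rbinom(1000, 1, p)
    tab <- tabulate(g + 1L, 3L)
    pc <- hwe_test(tab[1], tab[2], tab[3], "chisq")
    pe <- hwe_test(tab[1], tab[2], tab[3], "exact")
    expect_lt(abs(pc - pe) / pe, 0.35)
  }
})

test_that("QC filter applies the five exclusion rules with strict thresholds", {
  n <- 2000
  set.seed(202)
  mono <- rep(0L, n)
  low_maf <- c(rep(1L, 36), rep(0L, n - 36))        # maf 0.009
  at_maf <- c(rep(1L, 40), rep(0L, n - 40))         # maf 0.010
  hwe_bad <- c(rep(0L, 1000), rep(2L, 1000))        # extreme HWE failure
  miss <- c(rep(NA_integer_, 150), rbinom(n - 150, 2, 0.3))  # GCR 0.925
  good <- rbinom(n, 2, 0.3)
  sexy <- rbinom(n, 2, 0.3)
  g <- structure(list(
    dosage = cbind(mono = mono, low_maf = low_maf, at_maf = at_maf,
                   hwe_bad = hwe_bad, miss = miss, good = good, sexy = sexy),
    map = data.frame(
      snp_id = c("mono", "low_maf", "at_maf", "hwe_bad", "miss", "good",
                 "sexy"),
      chrom = c("1", "2", "3", "4", "5", "6", "X"))), class = "genotypes")
  qc <- qc_filter(g)
  expect_setequal(qc$kept, c("at_maf", "good"))
  rl <- setNames(qc$log$reason, qc$log$snp_id)
  expect_equal(unname(rl[c("mono", "low_maf", "hwe_bad", "miss", "sexy")]),
               c("nonpolymorphic", "low_maf", "hwe_deviation",
                 "low_call_rate", "sex_chromosome"))
  # HWE threshold is strict at p < 0.001
  expect_true(hwe_test(1000, 0, 1000) < 0.001)
})

test_that("association scan equals the general-purpose regression oracle", {
  set.seed(203)
  n <- 500
  cohort <- simulate_uamr_cohort(n = n, n_null_snps = 12, seed = 203)
  g <- cohort$genotypes
  # inject some missingness to exercise per-SNP dropping
  g$dosage[sample(length(g$dosage), 200)] <- NA_integer_
  covars <- cohort$data[c("recruit_age", "male", "bmi", "pc1", "pc2")]
  scan <- assoc_scan(g, cohort$data$sua, covars)
  for (id in sample(scan$snp_id, 10)) {
    d <- cbind(sua = cohort$data$sua, dose = g$dosage[, id], covars)
    ref <- summary(lm(sua ~ ., data = d))$coefficients["dose", ]
    row <- scan[scan$snp_id == id, ]
    expect_equal(row$beta, unname(ref[1]), tolerance = 1e-10)
    expect_equal(row$se, unname(ref[2]), tolerance = 1e-10)
    expect_equal(row$p_value, unname(ref[4]), tolerance = 1e-10)
    expect_equal(row$n_used, sum(!is.na(g$dosage[, id])))
  }
  # exact linear trait with no covariates: slope recovered exactly
  gg <- simulate_genotypes(data.frame(snp_id = "s", maf = 0.3,
                                      region_id = "r"), 200, seed = 1)
  sc <- assoc_scan(gg, 0.31 * gg$dosage[, 1])
  expect_equal(sc$beta, 0.31, tolerance = 1e-12)
  expect_lt(sc$p_value, 1e-100)
})

test_that("null p-values are uniform and scan flags degenerate designs", {
  set.seed(204)
  specs <- data.frame(snp_id = sprintf("s%04d", 1:2000),
                      maf = runif(2000, 0.05, 0.5),
                      region_id = sprintf("s%04d", 1:2000))
  g <- simulate_genotypes(specs, n = 300)
  scan <- assoc_scan(g, rnorm(300))
  expect_gt(ks.test(scan$p_value, "punif")$p.value, 0.01)
  # collinear covariate: flagged, not a crash
  g1 <- simulate_genotypes(specs[1, ], n = 50, seed = 1)
  out <- assoc_scan(g1, rnorm(50),
                    covariates = data.frame(c1 = g1$dosage[, 1]))
  expect_true(is.na(out$beta))
})

test_that("BH agrees with brute-force step-up for small m; Storey never exceeds BH", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04), method = "bh"),
               rep(0.04, 4))
  expect_equal(fdr_adjust(rep(0.2, 5), method = "bh"), rep(0.2, 5))
  brute_bh <- function(p) {
    m <- length(p); o <- order(p); q <- numeric(m)
    for (i in seq_len(m)) {
      cand <- vapply(i:m, function(j) m * p[o[j]] / j, numeric(1))
      q[o[i]] <- min(1, min(cand))
    }
    q
  }
  set.seed(205)
  for (m in c(1, 2, 5, 10)) {
    p <- round(runif(m), 3)
    expect_equal(fdr_adjust(p, method = "bh"), brute_bh(p), tolerance = 1e-12)
  }
  p <- c(runif(80), runif(20, 0, 1e-4))
  expect_true(all(fdr_adjust(p, "storey") <= fdr_adjust(p, "bh") + 1e-12))
  expect_error(fdr_adjust(c(0.1, NA)), "0, 1")
  q <- fdr_adjust(runif(50), "storey", pi0_method = "smoother")
  expect_true(all(q >= 0 & q <= 1))
})

test_that("false-discovery proportion is controlled at the nominal level", {
  set.seed(206)
  m <- 200; n <- 300; n_true <- 10
  fdp <- replicate(200, {
    beta <- c(rep(0.6, n_true), rep(0, m - n_true))
    g <- matrix(rbinom(n * m, 2, 0.3), n, m)
    y <- g %*% beta + rnorm(n)
    # per-SNP simple OLS p-values, vectorized for speed
    gc <- scale(g, scale = FALSE); yc <- y - mean(y)
    bhat <- as.vector(crossprod(gc, yc)) / colSums(gc^2)
    rss <- sum(yc^2) - bhat^2 * colSums(gc^2)
    se <- sqrt(rss / (n - 2) / colSums(gc^2))
    p <- 2 * pt(-abs(bhat / se), n - 2)
    qv <- fdr_adjust(p, "storey")
    sel <- which(qv < 0.05)
    if (!length(sel)) NA_real_ else mean(sel > n_true)
  })
  expect_lt(mean(fdp, na.rm = TRUE), 0.07)
})

test_that("two-stage confirmation enforces significance and sign concordance", {
  s1 <- data.frame(snp_id = c("a", "b", "c", "d"),
                   beta = c(0.3, -0.2, 0.25, 0.1),
                   q_value = c(0.01, 0.02, 0.03, 0.4))
  s2 <- data.frame(snp_id = c("a", "b", "c"),
                   beta = c(0.28, 0.3, -0.2),
                   p_value = c(0.001, 0.001, 0.001))
  out <- two_stage_confirm(s1, s2)
  expect_equal(out$confirmed, "a")        # b flips sign, c flips sign
  expect_equal(out$discovered, c("a", "b", "c"))
  expect_equal(out$unconfirmable, character(0))
  s1b <- s1[1:3, ]; s2b <- s2[1:2, ]
  expect_equal(two_stage_confirm(s1b, s2b)$unconfirmable, "c")
  expect_error(two_stage_confirm(s1[, -3], s2), "q_value")
})

test_that("two-stage pipeline confirms the causal panel with expected power", {
  set.seed(207)
  n1 <- 7000; n2 <- 3000
  panel <- sua_snp_panel()
  strong <- panel$snp_id[abs(panel$beta_sua) >= 0.15]
  hits <- replicate(10, {
    cohort <- simulate_uamr_cohort(n = n1 + n2, n_null_snps = 40)
    g <- cohort$genotypes
    covars <- cohort$data[c("recruit_age", "male", "bmi",
                            paste0("pc", 1:5))]
    i1 <- seq_len(n1); i2 <- n1 + seq_len(n2)
    sub <- function(i) structure(list(dosage = g$dosage[i, ], map = g$map),
                                 class = "genotypes")
    s1 <- assoc_scan(sub(i1), cohort$data$sua[i1], covars[i1, ])
    s1$q_value <- fdr_adjust(s1$p_value)
    s2 <- assoc_scan(sub(i2), cohort$data$sua[i2], covars[i2, ])
    conf <- two_stage_confirm(s1, s2)
    c(strong = all(strong %in% conf$confirmed),
      frac = mean(panel$snp_id %in% conf$confirmed),
      null_conf = mean(setdiff(conf$discovered, panel$snp_id) %in%
                         conf$confirmed))
  })
  # effects of 0.15 mg/dL and larger are reliably discovered and confirmed;
  # 0.10-0.11 effects have partial stage-2 power at n = 3000 and trait SD 1.5
  expect_gte(mean(hits["strong", ]), 0.9)
  expect_gte(mean(hits["frac", ]), 0.75)
  # null SNPs essentially never confirmed
  expect_lte(mean(hits["null_conf", ], na.rm = TRUE), 0.05)
})

test_that("tag selection keeps the largest absolute effect per region", {
  assoc <- data.frame(snp_id = c("a", "b", "c", "d", "e"),
                      beta = c(0.25, 0.27, -0.30, 0.1, 0.1),
                      p_value = c(0.01, 0.01, 0.01, 0.04, 0.02),
                      bp = c(1, 2, 3, 10, 11))
  region <- c(a = "R1", b = "R1", c = "R1", d = "R2", e = "R2")
  w <- select_tag_snps(assoc, region)
  expect_equal(nrow(w), 2L)
  expect_equal(w$snp_id[w$region_id == "R1"], "c")   # |−0.30| wins
  expect_equal(w$snp_id[w$region_id == "R2"], "e")   # tie on |beta|: smaller p
  # single-SNP region passes through
  w2 <- select_tag_snps(assoc[4, ], region)
  expect_equal(w2$snp_id, "d")
  expect_error(select_tag_snps(assoc, region[-1]), "region")
})

test_that("LD r-squared is the squared dosage correlation", {
  g <- c(0, 1, 2, 1, 0, 2)
  expect_equal(ld_r2(g, g), 1)
  expect_equal(ld_r2(g, 2 - g), 1)
  expect_error(ld_r2(g, rep(1, 6)), "variance")
  set.seed(208)
  a <- rbinom(1e5, 2, 0.3); b <- rbinom(1e5, 2, 0.3)
  expect_lt(ld_r2(a, b), 0.001)
})

test_that("scan dosage betas are invariant to affine covariate rescaling", {
  set.seed(209)
  cohort <- simulate_uamr_cohort(n = 800, n_null_snps = 3, seed = 209)
  covars <- cohort$data[c("recruit_age", "bmi")]
  s1 <- assoc_scan(cohort$genotypes, cohort$data$sua, covars)
  covars2 <- data.frame(recruit_age = 100 * covars$recruit_age - 3,
                        bmi = covars$bmi / 7 + 2)
  s2 <- assoc_scan(cohort$genotypes, cohort$data$sua, covars2)
  expect_equal(s1$beta, s2$beta, tolerance = 1e-8)
  expect_equal(s1$p_value, s2$p_value, tolerance = 1e-8)
})
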