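# Shared fixtures, built in code at test time.

# Biobank-style cohort: sex and a median-split-style binary score assigned
# at random, recruitment ages truncated-normal as in the study population.
make_twb_cohort <- function(n, truth = mixture_truth(), seed = NULL,
                            recruit = NULL, resolution = "years") {
  if (!is.null(seed)) set.seed(seed)
  d <- data.frame(male = stats::rbinom(n, 1, 0.5),
                  high = stats::rbinom(n, 1, 0.5))
  if (is.null(recruit)) {
    a <- stats::rnorm(n, 48.9, 11.1)
    while (any(out <- a < 30 | a > 70)) a[out] <- stats::rnorm(sum(out), 48.9, 11.1)
    recruit <- a
  }
  d$recruit_age <- rep_len(recruit, n)
  simulate_event_times(d, truth, mode = "twb", recruit_age = "recruit_age",
                       onset_resolution = resolution)
}

surv_events <- function(d) {
  survival::Surv(d$left, ifelse(is.finite(d$right), d$right, NA_real_),
                 type = "interval2")
}

cure_formula <- survival::Surv(
  left, ifelse(is.finite(right), right, NA_real_), type = "interval2") ~ male + high

table4c_truth <- c(qlogis(0.0303), log(2.85), log(1.62), 4.16, -2.37, 1.42)

# Independent brute-force innermost-interval oracle on raw values, exact
# observations widened by a tiny epsilon (the implementation is symbolic).
brute_innermost <- function(obs, eps = 1e-9) {
  l <- ifelse(obs$kind == "exact", obs$left - eps, obs$left)
  r <- obs$right
  lefts <- sort(unique(c(l, obs$entry_age)))
  rights <- sort(unique(r))
  out <- NULL
  for (a in lefts) for (b in rights) {
    if (b <= a) next
    inside <- c(lefts, rights)
    if (any(inside > a + eps / 2 & inside < b - eps / 2)) next
    out <- rbind(out, data.frame(left = a, right = b))
  }
  out
}
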