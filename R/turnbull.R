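#' Turnbull-Frydman nonparametric estimator of the onset-age distribution
#'
#' Nonparametric maximum-likelihood estimation of an event-time distribution
#' from left-truncated, interval- and right-censored ages of onset, by the
#' self-consistency (EM) iteration of Turnbull extended to left truncation
#' (Frydman). The NPMLE places mass only on the "innermost" intervals: the
#' maximal intersections \eqn{(p, q]} of the observation intervals whose
#' interior contains no other interval endpoint. Exact onset ages are treated
#' as degenerate intervals, handled symbolically (no numerical epsilon).
#'
#' With right-censoring-heavy data the estimated cumulative curve can
#' plateau below 1 before the terminal interval; that tail defect is the
#' empirical signature of a non-susceptible ("cured") fraction and is what
#' motivates the parametric mixture model in \code{\link{cure_ggd}}.
#'
#' @param obs an \code{\link{event_observations}} data frame, or a
#'   \code{survival::Surv} object (types \code{"right"}, \code{"interval"},
#'   \code{"interval2"}).
#' @param entry optional entry (left-truncation) ages when \code{obs} is a
#'   \code{Surv} object; ignored otherwise.
#' @param tol EM stopping rule: maximum absolute change of any interval mass.
#' @param max_iter iteration cap; non-convergence is reported, never silent.
#' @return an object of class \code{"turnbull"}: a list with \code{support}
#'   (data frame of innermost intervals \code{left}, \code{right} and their
#'   \code{mass} and cumulative mass), \code{loglik}, \code{n},
#'   \code{n_iter}, \code{converged}.
#' @examples
#' obs <- event_observations(entry_age = 0,
#'                           kind = c("interval", "interval", "exact"),
#'                           left = c(1, 2, 2.5), right = c(3, 4, 2.5))
#' fit <- turnbull(obs)
#' fit$support
#' @seealso \code{\link{innermost_intervals}}, \code{\link{predict.turnbull}}
#' @export
turnbull <- function(obs, entry = NULL, tol = 1e-8, max_iter = 10000L) {
  if (survival::is.Surv(obs)) obs <- .surv_to_events(obs, entry)
  if (!inherits(obs, "event_obs")) {
    obs <- event_observations(entry_age = obs$entry_age, kind = obs$kind,
                              left = obs$left, right = obs$right,
                              subject_id = obs$subject_id)
  }
  n <- nrow(obs)
  if (n == 0L) stop("no observations")
  enc <- .tb_encode(obs)
  iv <- .tb_innermost(enc)
  K <- nrow(iv)
  # inclusion matrices on the symbolic codes: A[i,k] = innermost k inside
  # subject i's interval; H[i,k] = innermost k after subject i's entry age
  A <- outer(enc$lcode, iv$lcode, `<=`) & outer(enc$rcode, iv$rcode, `>=`)
  storage.mode(A) <- "double"
  H <- outer(enc$ecode, iv$lcode, `<=`)
  storage.mode(H) <- "double"
  if (any(rowSums(A) == 0))
    stop("internal error: observation not covered by any innermost interval")
  s <- rep(1 / K, K)
  converged <- FALSE
  warned <- FALSE
  it <- 0L
  ll_trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    dA <- as.vector(A %*% s)
    dH <- as.vector(H %*% s)
    if (!warned && any(dH < 1e-12)) {
      warning("truncation set with mass < 1e-12: unstable EM weights")
      warned <- TRUE
    }
    ll_trace[it] <- sum(log(dA)) - sum(log(dH))
    m <- s * (colSums(A / dA) + colSums((1 - H) / dH))
    s_new <- m / sum(m)
    delta <- max(abs(s_new - s))
    s <- s_new
    if (delta < tol) { converged <- TRUE; break }
  }
  dA <- as.vector(A %*% s)
  dH <- as.vector(H %*% s)
  ll <- sum(log(dA)) - sum(log(dH))
  support <- data.frame(left = iv$lval, right = iv$rval, mass = s,
                        cum_mass = cumsum(s))
  structure(list(support = support, loglik = ll, loglik_trace = ll_trace,
                 n = n, n_iter = it, converged = converged,
                 call = match.call()),
            class = "turnbull")
}

# Symbolic endpoint encoding: every distinct finite age value v gets an even
# integer code 2*rank(v); the left endpoint of an exact observation at v gets
# 2*rank(v) - 1, i.e. "v minus epsilon", so degenerate intervals order
# correctly without a numerical epsilon. Inf gets the largest code.
.tb_encode <- function(obs) {
  vals <- sort(unique(c(obs$left, obs$right[is.finite(obs$right)],
                        obs$entry_age)))
  code <- function(v) 2L * match(v, vals)
  lcode <- code(obs$left)
  ex <- obs$kind == "exact"
  lcode[ex] <- lcode[ex] - 1L
  rcode <- ifelse(is.finite(obs$right), code(obs$right),
                  2L * length(vals) + 2L)
  ecode <- code(obs$entry_age)
  list(lcode = lcode, rcode = rcode, ecode = ecode, vals = vals,
       inf_code = 2L * length(vals) + 2L)
}

.tb_innermost <- function(enc) {
  lefts <- sort(unique(c(enc$lcode, enc$ecode)))
  rights <- sort(unique(enc$rcode))
  lv <- integer(0); rv <- integer(0)
  for (l in lefts) {
    r <- rights[rights > l]
    if (!length(r)) next
    r <- r[1]
    # innermost: no left endpoint strictly inside (l, r)
    if (any(lefts > l & lefts < r)) next
    lv <- c(lv, l); rv <- c(rv, r)
  }
  keep <- !duplicated(paste(lv, rv))
  lv <- lv[keep]; rv <- rv[keep]
  decode <- function(code) {
    v <- rep(Inf, length(code))
    fin <- code < enc$inf_code
    v[fin] <- enc$vals[ceiling(code[fin] / 2)]
    v
  }
  data.frame(lcode = lv, rcode = rv, lval = decode(lv), rval = decode(rv))
}

#' Innermost (Turnbull) intervals of a censored sample
#'
#' The maximal intersections on which the NPMLE can place mass: intervals
#' \eqn{(p, q]} with \eqn{p} a left endpoint (including entry ages) and
#' \eqn{q} a right endpoint, containing no other endpoint strictly inside.
#' Exact observations contribute degenerate intervals (\code{left == right}).
#'
#' @inheritParams turnbull
#' @return data frame with columns \code{left}, \code{right}; right-censored
#'   tails appear as \code{right == Inf}.
#' @export
innermost_intervals <- function(obs, entry = NULL) {
  if (survival::is.Surv(obs)) obs <- .surv_to_events(obs, entry)
  if (nrow(obs) == 0L) stop("no observations")
  enc <- .tb_encode(obs)
  iv <- .tb_innermost(enc)
  data.frame(left = iv$lval, right = iv$rval)
}

#' Survival probability from a fitted Turnbull curve
#'
#' \eqn{S(t) = 1 - \sum_{r_k \le t} m_k}: the step function drops at the
#' right endpoint of each innermost interval (the conventional
#' representation; the NPMLE is undefined inside an innermost interval, and
#' the value returned there is the left-endpoint value).
#'
#' @param object a \code{"turnbull"} fit.
#' @param times ages at which to evaluate.
#' @param ... unused.
#' @return data frame with columns \code{time}, \code{surv}, \code{cum_inc}.
#' @export
predict.turnbull <- function(object, times, ...) {
  sup <- object$support
  fin <- is.finite(sup$right)
  surv <- vapply(times, function(t) 1 - sum(sup$mass[fin & sup$right <= t]),
                 numeric(1))
  data.frame(time = times, surv = surv, cum_inc = 1 - surv)
}

#' @export
print.turnbull <- function(x, ...) {
  cat("Turnbull-Frydman NPMLE\n")
  cat(sprintf("  n = %d subjects, %d innermost intervals\n",
              x$n, nrow(x$support)))
  cat(sprintf("  log-likelihood %.4f after %d EM iterations (%s)\n",
              x$loglik, x$n_iter,
              if (x$converged) "converged" else "NOT converged"))
  tail_mass <- sum(x$support$mass[!is.finite(x$support$right)])
  cat(sprintf("  mass beyond last finite endpoint: %.4f\n", tail_mass))
  invisible(x)
}

#' Step event-time curve
#'
#' Plots the cumulative incidence (1 - survival) step function of a fitted
#' Turnbull curve; additional fitted curves can be overlaid with
#' \code{add = TRUE} to compare strata (e.g. sex by risk-score group).
#'
#' @param x a \code{"turnbull"} fit.
#' @param add overlay on an existing plot.
#' @param col,lty passed to \code{lines}.
#' @param xlab,ylab,main,ylim usual graphics parameters.
#' @param ... further arguments to \code{lines}.
#' @export
plot.turnbull <- function(x, add = FALSE, col = 1, lty = 1,
                          xlab = "Age (years)",
                          ylab = "Cumulative incidence",
                          main = "Event time curve", ylim = c(0, 1), ...) {
  sup <- x$support[is.finite(x$support$right), ]
  tt <- c(0, rep(sup$right, each = 2), max(sup$right) * 1.05)
  cc <- cumsum(sup$mass)
  yy <- c(0, 0, rep(cc, each = 2))
  if (!add) {
    graphics::plot(tt, yy, type = "n", xlab = xlab, ylab = ylab,
                   main = main, ylim = ylim)
  }
  graphics::lines(tt, yy, col = col, lty = lty, ...)
  invisible(x)
}
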