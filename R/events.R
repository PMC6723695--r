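#' Event-time observations with truncation and mixed censoring
#'
#' The canonical per-subject record for onset-age analyses: an entry age
#' (left-truncation age, 0 meaning none), an observation kind, and the
#' censoring interval \code{(left, right]}. Exact self-reported onsets have
#' \code{left == right}; interval-censored onsets (bracketed by two
#' examination ages) have \code{left < right < Inf}; right-censored subjects
#' have \code{right == Inf} with \code{left} the last event-free age.
#'
#' @param subject_id character ids (generated when omitted).
#' @param entry_age non-negative entry (truncation) ages; subjects are known
#'   event-free at entry, and the likelihood conditions on that.
#' @param kind one of \code{"exact"}, \code{"interval"},
#'   \code{"right_censored"}.
#' @param left,right interval endpoints in years.
#' @return a \code{data.frame} of validated observations with class
#'   \code{"event_obs"} prepended.
#' @examples
#' event_observations(entry_age = c(0, 30), kind = c("exact", "interval"),
#'                    left = c(55, 40), right = c(55, 43))
#' @export
event_observations <- function(entry_age, kind, left, right,
                               subject_id = NULL) {
  n <- max(length(kind), length(left), length(right), length(entry_age))
  if (is.null(subject_id)) subject_id <- sprintf("S%05d", seq_len(n))
  left <- rep_len(left, n); right <- rep_len(right, n)
  kind <- rep_len(as.character(kind), n)
  bad <- !kind %in% c("exact", "interval", "right_censored")
  if (any(bad)) stop("unknown observation kind: ", paste(unique(kind[bad]), collapse = ", "))
  entry_age <- rep_len(as.numeric(entry_age), n)
  left <- as.numeric(left); right <- as.numeric(right)
  stopifnot(length(left) == n, length(right) == n)
  if (any(entry_age < 0)) stop("entry_age must be >= 0")
  if (any(entry_age > left + 1e-12))
    stop("entry_age must not exceed the interval left endpoint")
  ex <- kind == "exact"; iv <- kind == "interval"; rc <- kind == "right_censored"
  if (any(ex & (left != right | !is.finite(right))))
    stop("exact observations need finite left == right")
  if (any(iv & !(left < right & is.finite(right))))
    stop("interval observations need left < right < Inf")
  if (any(rc & is.finite(right)))
    stop("right-censored observations need right == Inf")
  out <- data.frame(subject_id = as.character(subject_id),
                    entry_age = entry_age, kind = kind,
                    left = left, right = right,
                    stringsAsFactors = FALSE)
  class(out) <- c("event_obs", "data.frame")
  out
}

# Convert a survival::Surv response (+ optional entry ages) to event_obs
# columns. Supported Surv types: "right" and "interval" / "interval2".
.surv_to_events <- function(y, entry = NULL) {
  if (!survival::is.Surv(y)) stop("response must be a survival::Surv object")
  type <- attr(y, "type")
  n <- nrow(y)
  if (is.null(entry)) entry <- numeric(n)
  if (type == "right") {
    tm <- y[, "time"]; st <- y[, "status"]
    kind <- ifelse(st == 1, "exact", "right_censored")
    left <- tm
    right <- ifelse(st == 1, tm, Inf)
  } else if (type %in% c("interval", "interval2")) {
    st <- y[, "status"]
    t1 <- y[, 1]; t2 <- y[, 2]
    kind <- character(n); left <- numeric(n); right <- numeric(n)
    kind[st == 1] <- "exact"; left[st == 1] <- t1[st == 1]; right[st == 1] <- t1[st == 1]
    kind[st == 0] <- "right_censored"; left[st == 0] <- t1[st == 0]; right[st == 0] <- Inf
    kind[st == 2] <- "interval"; left[st == 2] <- 0; right[st == 2] <- t1[st == 2]
    kind[st == 3] <- "interval"; left[st == 3] <- t1[st == 3]; right[st == 3] <- t2[st == 3]
  } else {
    stop("unsupported Surv type: ", type)
  }
  event_observations(entry_age = entry, kind = kind, left = left, right = right)
}

#' Read / write event-observation tables
#'
#' Plain CSV with columns \code{subject_id, entry_age, kind, left, right};
#' \code{right} may be the string \code{"Inf"} for right-censored rows.
#'
#' @param path file path.
#' @param obs an \code{event_obs} data frame.
#' @return \code{read_events} the validated \code{event_obs} data frame;
#'   \code{write_events} the path, invisibly.
#' @export
read_events <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  event_observations(entry_age = d$entry_age, kind = d$kind,
                     left = d$left, right = as.numeric(d$right),
                     subject_id = d$subject_id)
}

#' @rdname read_events
#' @export
write_events <- function(obs, path) {
  utils::write.csv(as.data.frame(obs), path, row.names = FALSE)
  invisible(path)
}
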