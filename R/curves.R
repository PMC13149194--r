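# Digitized survival-curve and number-at-risk containers with their CSV
# dialects (`time_months,survival` / `time_months,n_risk` / IPD
# `time_months,event,arm`).

#' Digitized Kaplan-Meier curve
#'
#' Ordered (time, survival) coordinates for one endpoint and arm, as produced
#' by plot digitization. Times must be non-negative and strictly increasing,
#' survival within \[0, 1\] and non-increasing (violations up to 1e-6 are
#' flattened; larger ones are rejected with the offending row). A (0, 1)
#' anchor is prepended when absent, matching the product-limit convention.
#'
#' @param time months.
#' @param survival survival probabilities.
#' @return data.frame with columns `time`, `survival`, class `cua_curve`.
#' @export
digitized_curve <- function(time, survival) {
  if (length(time) != length(survival) || length(time) == 0)
    stop_input("time and survival must be non-empty and of equal length")
  if (any(!is.finite(time)) || any(time < 0))
    stop_input("curve times must be finite and non-negative")
  if (any(diff(time) <= 0))
    stop_input("curve times must be strictly increasing (row ",
               which(diff(time) <= 0)[1] + 1, ")")
  bad <- which(survival < 0 | survival > 1)
  if (length(bad))
    stop_input("survival out of [0, 1] at row ", bad[1])
  rise <- diff(survival)
  if (any(rise > 1e-6))
    stop_input("survival must be non-increasing (row ",
               which(rise > 1e-6)[1] + 1, ")")
  survival <- cummin(survival)  # flatten sub-tolerance digitization jitter
  if (time[1] > 0) {
    time <- c(0, time)
    survival <- c(1, survival)
  } else if (abs(survival[1] - 1) > 1e-6) {
    stop_input("survival at time 0 must be 1")
  } else {
    survival[1] <- 1
  }
  structure(data.frame(time = time, survival = survival),
            class = c("cua_curve", "data.frame"))
}

#' Number-at-risk table
#'
#' @param time months; first entry must be 0 (enrolled N).
#' @param n_risk subjects still at risk; non-negative and non-increasing.
#' @return data.frame with columns `time`, `n_risk`, class `cua_risktable`.
#' @export
risk_table <- function(time, n_risk) {
  if (length(time) != length(n_risk) || length(time) < 2)
    stop_input("risk table needs at least two (time, n_risk) entries")
  if (time[1] != 0) stop_input("risk table must start at time 0")
  if (any(diff(time) <= 0)) stop_input("risk-table times must be increasing")
  if (any(n_risk < 0) || any(diff(n_risk) > 0))
    stop_input("n_risk must be non-negative and non-increasing")
  structure(data.frame(time = time, n_risk = as.integer(n_risk)),
            class = c("cua_risktable", "data.frame"))
}

read_csv_checked <- function(path, header_cols) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  x <- utils::read.csv(path, check.names = FALSE)
  if (!identical(names(x)[seq_along(header_cols)], header_cols))
    stop_input(path, ": expected header ", paste(header_cols, collapse = ","))
  x
}

#' Read / write a digitized curve CSV (`time_months,survival`)
#' @param path CSV file path.
#' @return [digitized_curve()] for the reader; invisibly `path` for writers.
#' @export
read_digitized_curve <- function(path) {
  x <- read_csv_checked(path, c("time_months", "survival"))
  digitized_curve(x$time_months, x$survival)
}

#' @rdname read_digitized_curve
#' @param curve a `cua_curve`.
#' @export
write_digitized_curve <- function(curve, path) {
  utils::write.csv(data.frame(time_months = curve$time, survival = curve$survival),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a number-at-risk CSV (`time_months,n_risk`)
#' @param path CSV file path.
#' @return [risk_table()] for the reader; invisibly `path` for writers.
#' @export
read_risk_table <- function(path) {
  x <- read_csv_checked(path, c("time_months", "n_risk"))
  risk_table(x$time_months, x$n_risk)
}

#' @rdname read_risk_table
#' @param risk a `cua_risktable`.
#' @export
write_risk_table <- function(risk, path) {
  utils::write.csv(data.frame(time_months = risk$time, n_risk = risk$n_risk),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write individual patient data CSV (`time_months,event,arm`)
#' @param path CSV file path.
#' @return `cua_ipd` for the reader; invisibly `path` for writers.
#' @export
read_ipd <- function(path) {
  x <- read_csv_checked(path, c("time_months", "event", "arm"))
  as_cua_ipd(data.frame(time = x$time_months, event = x$event, arm = x$arm,
                        stringsAsFactors = FALSE))
}

#' @rdname read_ipd
#' @param ipd a `cua_ipd`.
#' @export
write_ipd <- function(ipd, path) {
  utils::write.csv(data.frame(time_months = ipd$time, event = ipd$event,
                              arm = ipd$arm),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
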