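#' Fit winsorization bounds from observed response times
#'
#' The lower and upper bounds are the empirical `lower_q` and `upper_q`
#' quantiles of the observed response times, using the linear-interpolation
#' quantile definition (`stats::quantile` type 7). Times outside the bounds
#' are clamped by [winsorize()] to limit the influence of extreme waits on
#' per-physician means.
#'
#' @param times Numeric vector of response times in minutes (NAs dropped).
#' @param lower_q,upper_q Quantile fractions, default 0.05 and 0.95.
#' @return A `winsor_bounds` object: list with `lower_min`, `upper_min`.
#' @export
#' @examples
#' fit_winsor_bounds(1:100) # approx (5.95, 95.05)
fit_winsor_bounds <- function(times, lower_q = 0.05, upper_q = 0.95) {
  times <- times[!is.na(times)]
  if (!length(times)) {
    stop("cannot fit winsor bounds on empty times", call. = FALSE)
  }
  if (!(lower_q >= 0 && lower_q < upper_q && upper_q <= 1)) {
    stop("need 0 <= lower_q < upper_q <= 1", call. = FALSE)
  }
  qs <- stats::quantile(times, c(lower_q, upper_q), names = FALSE, type = 7)
  structure(
    list(lower_min = qs[1], upper_min = qs[2]),
    class = "winsor_bounds"
  )
}

#' @export
print.winsor_bounds <- function(x, ...) {
  cat(sprintf(
    "<winsor_bounds> [%.2f, %.2f] min\n", x$lower_min, x$upper_min
  ))
  invisible(x)
}

#' Clamp response times to winsor bounds
#'
#' @param t Numeric vector of minutes (`NA` passes through).
#' @param bounds A `winsor_bounds` object from [fit_winsor_bounds()].
#' @return `pmin(pmax(t, lower), upper)`; idempotent.
#' @export
winsorize <- function(t, bounds) {
  pmin(pmax(t, bounds$lower_min), bounds$upper_min)
}

#' Per-physician response rate and mean response time
#'
#' For each physician `P_i` with `N` received requests of which `N_R` were
#' answered: the response rate is `R = N_R / N`, and the mean response time
#' is `S_T / N_R` where `S_T` is the total (optionally winsorized) response
#' time over answered requests. Physicians with no answered requests have
#' rate 0 and an absent (`NA`) mean.
#'
#' @param records Record tibble.
#' @param bounds Optional `winsor_bounds`; when supplied, each response time
#'   is clamped before summation.
#' @return Tibble with one row per physician: `physician_code`, `n_total`,
#'   `n_responded`, `response_rate`, `total_response_time_min`,
#'   `mean_response_time_min`.
#' @export
compute_physician_stats <- function(records, bounds = NULL) {
  t <- records$response_time_min
  if (!is.null(bounds)) {
    t <- winsorize(t, bounds)
  }
  df <- tibble::tibble(
    physician_code = records$physician_code,
    responded = records$response_status,
    t = ifelse(records$response_status & !is.na(t), t, NA_real_)
  )
  out <- dplyr::summarise(
    dplyr::group_by(df, .data$physician_code),
    n_total = dplyr::n(),
    n_responded = sum(.data$responded),
    total_response_time_min = sum(.data$t, na.rm = TRUE),
    .groups = "drop"
  )
  out$response_rate <- out$n_responded / out$n_total
  out$mean_response_time_min <- ifelse(
    out$n_responded > 0,
    out$total_response_time_min / out$n_responded,
    NA_real_
  )
  out[c(
    "physician_code", "n_total", "n_responded", "response_rate",
    "total_response_time_min", "mean_response_time_min"
  )]
}

#' Corpus-level mean response time
#'
#' The mean of (optionally winsorized) per-request response times over all
#' answered requests — a corpus-level figure, not a mean of per-physician
#' means. This is the reference against which the high-quality-service
#' proportion ([hqos_prop()]) judges a physician as "fast".
#'
#' @param records Record tibble.
#' @param bounds Optional `winsor_bounds` applied before averaging.
#' @return Mean response time in minutes (`NA` if no answered request).
#' @export
global_mean_response_time <- function(records, bounds = NULL) {
  t <- records$response_time_min[records$response_status]
  t <- t[!is.na(t)]
  if (!length(t)) {
    return(NA_real_)
  }
  if (!is.null(bounds)) {
    t <- winsorize(t, bounds)
  }
  mean(t)
}

#' Write per-physician stats as CSV
#'
#' @param stats Tibble from [compute_physician_stats()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_physician_stats <- function(stats, path) {
  utils::write.csv(stats, path, row.names = FALSE, na = "")
  invisible(path)
}
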