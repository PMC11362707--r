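#' Parse response-time durations into minutes
#'
#' Consultation exports mix bare numeric minutes with human-readable
#' durations such as `"8 h 12 min"`, `"2h20min"` or `"20 min"`. This parser
#' accepts both, plus the null markers used by common exports (`""`,
#' `"null"`, `"NA"`), which map to `NA`.
#'
#' @param x Character vector of duration strings (or numerics).
#' @return Numeric vector of minutes; `NA` where the input is a null marker.
#'   Strings that are neither a numeric, a recognised duration, nor a null
#'   marker yield `NaN` so callers can distinguish "absent" from
#'   "unparsable".
#' @export
#' @examples
#' parse_duration_min(c("8 h 12 min", "20 min", "9", "null"))
parse_duration_min <- function(x) {
  if (is.numeric(x)) {
    return(as.numeric(x))
  }
  x <- stringi::stri_trim_both(as.character(x))
  out <- rep(NaN, length(x))
  null_like <- is.na(x) | x %in% c("", "null", "NULL", "NA", "None")
  out[null_like] <- NA_real_
  num <- suppressWarnings(as.numeric(x))
  plain <- !null_like & !is.na(num)
  out[plain] <- num[plain]
  rest <- which(!null_like & !plain)
  if (length(rest)) {
    pat <- "^(?:(\\d+)\\s*h(?:ours?)?)?\\s*(?:(\\d+)\\s*min(?:utes?)?)?$"
    m <- stringi::stri_match_first_regex(x[rest], pat, case_insensitive = TRUE)
    h <- suppressWarnings(as.numeric(m[, 2]))
    mi <- suppressWarnings(as.numeric(m[, 3]))
    ok <- !is.na(m[, 1]) & (!is.na(h) | !is.na(mi))
    h[is.na(h)] <- 0
    mi[is.na(mi)] <- 0
    out[rest[ok]] <- (h * 60 + mi)[ok]
  }
  out
}

#' Format minutes as an "H h M min" string
#'
#' Inverse of [parse_duration_min()] for presentation; whole hours print as
#' `"3 h"`, sub-hour durations as `"40 min"`.
#'
#' @param minutes Numeric vector of minutes.
#' @return Character vector.
#' @export
format_duration_min <- function(minutes) {
  vapply(minutes, function(m) {
    if (is.na(m)) {
      return(NA_character_)
    }
    h <- floor(m / 60)
    r <- round(m - h * 60)
    if (h > 0 && r > 0) {
      sprintf("%d h %d min", h, r)
    } else if (h > 0) {
      sprintf("%d h", h)
    } else {
      sprintf("%d min", r)
    }
  }, character(1))
}

# Coerce truthy/falsy text to logical; returns NA where unrecognised.
parse_logical <- function(x) {
  if (is.logical(x)) {
    return(x)
  }
  x <- tolower(stringi::stri_trim_both(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "1", "yes")] <- TRUE
  out[x %in% c("false", "f", "0", "no")] <- FALSE
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
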