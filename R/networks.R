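#' Yeo-7 network codes
#'
#' Integer codes for the seven canonical resting-state networks used
#' throughout the package. Code 0 denotes unassigned vertices (e.g. the
#' medial wall); codes 1..7 follow the standard Yeo ordering.
#'
#' @format Named integer vector of length 7.
#' @export
yeo7_networks <- c(
  Visual           = 1L,
  Somatomotor      = 2L,
  DorsalAttention  = 3L,
  VentralAttention = 4L,
  Limbic           = 5L,
  Frontoparietal   = 6L,
  Default          = 7L
)

#' Short network labels (VIS, SN, DAN, VAN, LIM, FPN, DN) indexed by code 1..7.
#' @rdname yeo7_networks
#' @export
yeo7_abbrev <- c("VIS", "SN", "DAN", "VAN", "LIM", "FPN", "DN")

network_name <- function(code) {
  out <- rep(NA_character_, length(code))
  ok <- !is.na(code) & code >= 1 & code <= 7
  out[ok] <- yeo7_abbrev[code[ok]]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(..., call. = FALSE)
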