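#' Typed error conditions
#'
#' All fatal errors raised by the package carry a condition class of the form
#' `wgr_<type>_error` in addition to `wgr_error`, so callers (and tests) can
#' branch on the failure mode rather than on message text.
#'
#' @param message error message
#' @param class short type tag, e.g. "unidentifiable"
#' @param ... additional condition fields
#' @keywords internal
#' @noRd
wgr_stop <- function(message, class, ...) {
  stop(errorCondition(
    message,
    class = c(paste0("wgr_", class, "_error"), "wgr_error"),
    ...
  ))
}

wgr_warn <- function(message, class, ...) {
  warning(warningCondition(
    message,
    class = c(paste0("wgr_", class, "_warning"), "wgr_warning"),
    ...
  ))
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
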