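#' Re-exported generics
#'
#' Generics re-exported so that `tidy()`, `glance()` and `autoplot()`
#' work on posturekit objects without attaching their home packages.
#'
#' @name reexports
#' @importFrom generics tidy
#' @export
generics::tidy

#' @rdname reexports
#' @importFrom generics glance
#' @export
generics::glance

#' @rdname reexports
#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
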