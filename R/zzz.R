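#' @keywords internal
#' @useDynLib adcr, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom rlang .data
#' @importFrom tibble as_tibble
"_PACKAGE"

#' @export
tibble::as_tibble
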