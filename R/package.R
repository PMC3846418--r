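#' @keywords internal
#' @importFrom rlang .data abort
#' @importFrom stats predict
"_PACKAGE"
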