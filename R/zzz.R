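#' @importFrom data.table data.table setorderv := .N
NULL

.datatable.aware <- TRUE

#' chromoscan: structural discovery of chromoviral LTR retrotransposons
#'
#' See the package vignette for the underlying model and design choices.
#' @keywords internal
"_PACKAGE"
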