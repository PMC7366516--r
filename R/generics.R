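# broom-style verbs, re-exported from generics so karyotree methods
# cooperate with broom and the rest of the tidymodels ecosystem.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
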