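#' @import stats
#' @importFrom graphics par points segments
#' @importFrom utils modifyList
NULL

.onLoad <- function(libname, pkgname) {
  register_model("reversible_toy", make_toy_model())
}
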