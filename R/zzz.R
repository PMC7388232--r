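#' @useDynLib elastroot, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd median prcomp binom.test
#' @importFrom utils modifyList tail
NULL
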