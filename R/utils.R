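#' @importFrom methods is
#' @importFrom stats pbinom pnorm pt rnorm runif setNames p.adjust dhyper
#'   cor hclust cutree as.dist
#' @importFrom utils read.delim write.table packageVersion head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# argument errors are user-facing: no call in the condition
stop_arg <- function(...) stop(..., call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
}
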