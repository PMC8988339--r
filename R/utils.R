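#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor pnorm pt qnorm rank p.adjust phyper wilcox.test
#'   rnbinom rnorm runif sd setNames rbinom quantile
#' @importFrom utils read.delim write.table head packageVersion
NULL

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
.msgf  <- function(fmt, ...) message(sprintf(fmt, ...))

.assert_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    .stopf("%s is missing required column(s): %s", what,
           paste(miss, collapse = ", "))
}
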