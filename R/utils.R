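# Classed conditions: "conpatch_input_error" for bad user input / files,
# "conpatch_compute_error" for numerical or algorithmic failures. The CLI
# maps these onto exit codes 2 and 3.

stop_input <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("conpatch_input_error", "conpatch_error")))
}

stop_compute <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("conpatch_compute_error", "conpatch_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
assert_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    stop_input("'%s' must be a single finite number in [%s, %s]", name, lower, upper)
  x
}

# log(sum(exp(x))) along rows of a matrix, stable
row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  ok <- is.finite(mx)
  out <- rep(-Inf, nrow(m))
  out[ok] <- mx[ok] + log(rowSums(exp(m[ok, , drop = FALSE] - mx[ok])))
  out
}
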