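#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_validation <- function(...) {
  stop(structure(class = c("fruitrack_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_config <- function(...) {
  stop(structure(class = c("fruitrack_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

assert_finite <- function(x, what) {
  if (!all(is.finite(x))) stop_validation(what, " must be finite")
  invisible(x)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) pmax(x, 0)

# Convert an RGB array (h x w x 3, values in [0,1]) or matrix to grayscale.
as_gray <- function(img) {
  if (is.matrix(img)) return(img)
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] == 1L) return(img[, , 1L])
    return(0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L])
  }
  stop_validation("expected a matrix or h x w x c array")
}
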