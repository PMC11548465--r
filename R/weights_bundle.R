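#' Write a bundle of named numeric arrays as plain text
#'
#' Simple serialization for operator weights and codebooks: each entry is
#' stored with its name, its dimensions, and its values in column-major
#' order, one entry per block. Round-trips exactly at full double precision.
#'
#' @param bundle named list of numeric vectors, matrices or arrays
#' @param path output file path
#' @return `path`, invisibly.
#' @seealso [read_weights_bundle()]
#' @export
write_weights_bundle <- function(bundle, path) {
  if (is.null(names(bundle)) || any(!nzchar(names(bundle))))
    stop_validation("every bundle entry must be named")
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(bundle)) {
    x <- bundle[[nm]]
    d <- if (is.null(dim(x))) length(x) else dim(x)
    writeLines(c(paste0("@", nm),
                 paste(d, collapse = " "),
                 paste(format(as.numeric(x), digits = 17, trim = TRUE,
                              scientific = TRUE),
                       collapse = " ")), con)
  }
  invisible(path)
}

#' Read a weights bundle written by [write_weights_bundle()]
#'
#' @param path input file path
#' @return Named list of arrays (vectors stay vectors, higher-dimensional
#'   entries get their `dim` restored).
#' @export
read_weights_bundle <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!startsWith(lines[i], "@"))
      stop("malformed bundle at line ", i, ": expected '@name'")
    nm <- substring(lines[i], 2L)
    d <- as.integer(strsplit(lines[i + 1L], " ", fixed = TRUE)[[1]])
    v <- as.numeric(strsplit(lines[i + 2L], " ", fixed = TRUE)[[1]])
    if (length(v) != prod(d)) stop("bundle entry '", nm, "' has wrong length")
    out[[nm]] <- if (length(d) > 1L) array(v, d) else v
    i <- i + 3L
  }
  out
}

#' Serialize a VLAD codebook to the weights-bundle format
#'
#' @param cb a `vlad_codebook` from [fit_codebook()]
#' @param path output file path
#' @return `path`, invisibly.
#' @export
write_codebook <- function(cb, path) {
  write_weights_bundle(list(centroids = cb$centroids, k = as.numeric(cb$k)),
                       path)
}

#' Read a VLAD codebook from a weights-bundle file
#'
#' @param path input file path
#' @return A `vlad_codebook`.
#' @export
read_codebook <- function(path) {
  b <- read_weights_bundle(path)
  structure(list(centroids = b$centroids, k = as.integer(b$k)),
            class = "vlad_codebook")
}
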