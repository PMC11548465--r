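#' Fit a VLAD codebook by k-means clustering
#'
#' Clusters pooled local descriptors into `k` centroids; VLAD signatures are
#' later computed as residuals against these centroids. The clustering is
#' seeded and therefore reproducible.
#'
#' @param descriptors an n x d matrix of pooled descriptors (or a
#'   `descriptor_set`), n >= k
#' @param k number of clusters (codebook size, default 8)
#' @param seed RNG seed for the k-means initialization
#' @return A list of class `vlad_codebook` with `centroids` (k x d) and `k`.
#' @export
fit_codebook <- function(descriptors, k = 8L, seed = 1L) {
  if (inherits(descriptors, "descriptor_set")) descriptors <- descriptors$descriptors
  descriptors <- as.matrix(descriptors)
  if (nrow(descriptors) < k)
    stop_validation("need at least k = ", k, " descriptors, got ", nrow(descriptors))
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(seed)
  uniq <- unique(descriptors)
  if (nrow(uniq) < k)
    stop_validation("fewer than k distinct descriptors")
  km <- stats::kmeans(descriptors, centers = uniq[sample(nrow(uniq), k), , drop = FALSE],
                      iter.max = 50L)
  structure(list(centroids = unname(km$centers), k = k), class = "vlad_codebook")
}

#' VLAD encoding of a descriptor set
#'
#' Vector of Locally Aggregated Descriptors: each descriptor's residual to its
#' nearest codebook centroid is accumulated into that centroid's slot; the
#' concatenated `k * d` vector is power-normalized (signed square root) and
#' then L2-normalized. An empty descriptor set, or one whose residuals are all
#' zero, yields the all-zero degenerate vector (flagged via the `degenerate`
#' attribute); degenerate signatures carry no appearance evidence.
#'
#' @param ds a `descriptor_set` (or plain n x d matrix)
#' @param cb a `vlad_codebook` from [fit_codebook()]
#' @return A numeric vector of length `k * d` of class `vlad`, with attribute
#'   `degenerate` (logical).
#' @export
vlad_encode <- function(ds, cb) {
  X <- if (inherits(ds, "descriptor_set")) ds$descriptors else as.matrix(ds)
  C <- cb$centroids
  d <- ncol(C); k <- nrow(C)
  if (nrow(X) == 0L) return(vlad_degenerate(k * d))
  if (ncol(X) != d)
    stop_validation("descriptor dimension (", ncol(X),
                    ") does not match codebook (", d, ")")
  d2 <- outer(rowSums(X^2), rowSums(C^2), "+") - 2 * X %*% t(C)
  nearest <- max.col(-d2, ties.method = "first")
  v <- matrix(0, k, d)
  for (i in seq_len(nrow(X)))
    v[nearest[i], ] <- v[nearest[i], ] + (X[i, ] - C[nearest[i], ])
  v <- as.numeric(t(v))          # centroid-major k*d layout
  v <- sign(v) * sqrt(abs(v))    # power normalization
  nrm <- sqrt(sum(v^2))
  if (nrm < 1e-12) return(vlad_degenerate(k * d))
  structure(v / nrm, class = "vlad", degenerate = FALSE)
}

vlad_degenerate <- function(len) {
  structure(numeric(len), class = "vlad", degenerate = TRUE)
}

is_degenerate <- function(v) isTRUE(attr(v, "degenerate"))

#' Cosine similarity between two VLAD signatures
#'
#' Returns the cosine of the angle between the two signatures, in `[-1, 1]`
#' (1 = identical appearance direction). If either vector is degenerate
#' (all-zero: no appearance evidence), the sentinel `NA` is returned rather
#' than any numeric similarity; callers must treat `NA` as "no evidence",
#' never as dissimilarity.
#'
#' @param a,b vectors of equal length (typically class `vlad`)
#' @return Cosine similarity, or `NA` for degenerate input.
#' @export
appearance_similarity <- function(a, b) {
  if (length(a) != length(b))
    stop_validation("signature dimensions differ (", length(a), " vs ", length(b), ")")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (is_degenerate(a) || is_degenerate(b) || na < 1e-12 || nb < 1e-12)
    return(NA_real_)
  sum(a * b) / (na * nb)
}

#' Displacement-consistency validation of an appearance match
#'
#' Different regions of the same scene move with (nearly) the same
#' displacement between neighbouring frames. A candidate appearance match is
#' therefore only accepted if its track-to-detection displacement agrees with
#' the displacement of an independently matched anchor region in the same
#' frame, to within a pixel tolerance. With no anchor available the check is
#' vacuously passed.
#'
#' @param candidate list with elements `track` and `detection`, each a length-2
#'   `(x, y)` region center in pixel coordinates
#' @param anchor same structure as `candidate`, from an already-matched pair,
#'   or `NULL` when no anchor exists
#' @param tolerance pixel tolerance (closed boundary: a difference exactly
#'   equal to `tolerance` is accepted)
#' @return `TRUE` or `FALSE`.
#' @export
validate_match <- function(candidate, anchor = NULL, tolerance = 10) {
  if (is.null(anchor)) return(TRUE)
  dc <- candidate$detection - candidate$track
  da <- anchor$detection - anchor$track
  sqrt(sum((dc - da)^2)) <= tolerance
}
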