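#' Ordered-quantile (rank inverse-normal) normalizing transform
#'
#' Fits the rank-based normal-scores transform: observation with rank r
#' (ties receive their average rank) maps to
#' qnorm((r - offset) / (n - 2*offset + 1)). With the default offset 0.5
#' this is qnorm((r - 0.5)/n), which sends the median of an odd-length
#' tie-free vector exactly to 0 and makes the transformed sample as close
#' to Gaussian as a rank transform can. New values are mapped by monotone
#' piecewise-linear interpolation between the stored (value, score) pairs,
#' with linear extrapolation beyond the observed range, so the transform
#' is invertible everywhere.
#'
#' @param y numeric vector, length >= 3, not constant.
#' @param offset plotting-position offset in (0, 1); 0.5 by default,
#'   0.375 gives the Blom variant.
#' @return object of class `rank_normal`: list with `sorted_originals`,
#'   `normal_scores` (deduplicated ascending pairs), `offset`, `n`.
#' @examples
#' m <- fit_rank_normal(c(3, 1, 4, 1, 5, 9, 2, 6))
#' z <- rank_normal_transform(m, c(3, 1, 4))
#' rank_normal_inverse(m, z)
#' @export
fit_rank_normal <- function(y, offset = 0.5) {
  if (length(y) < 3L) stop("need at least 3 observations")
  if (any(is.na(y))) stop("y must be complete")
  if (offset <= 0 || offset >= 1) stop("offset must lie in (0, 1)")
  if (length(unique(y)) < 2L) stop("y is constant; no transform exists")
  n <- length(y)
  r <- rank(y, ties.method = "average")
  z <- stats::qnorm((r - offset) / (n - 2 * offset + 1))
  ord <- order(y)
  ys <- y[ord]; zs <- z[ord]
  keep <- !duplicated(ys)
  structure(list(sorted_originals = ys[keep], normal_scores = zs[keep],
                 offset = offset, n = n),
            class = "rank_normal")
}

#' @export
print.rank_normal <- function(x, ...) {
  cat("rank_normal transform: n =", x$n, ", offset =", x$offset,
      ",", length(x$sorted_originals), "support points\n")
  invisible(x)
}

## piecewise-linear map through (xs, zs) with linear tail extrapolation
.pwl <- function(x, xs, zs) {
  out <- stats::approx(xs, zs, xout = x, ties = "ordered")$y
  k <- length(xs)
  lo <- !is.na(x) & x < xs[1L]
  hi <- !is.na(x) & x > xs[k]
  if (any(lo)) {
    sl <- (zs[2L] - zs[1L]) / (xs[2L] - xs[1L])
    out[lo] <- zs[1L] + sl * (x[lo] - xs[1L])
  }
  if (any(hi)) {
    sl <- (zs[k] - zs[k - 1L]) / (xs[k] - xs[k - 1L])
    out[hi] <- zs[k] + sl * (x[hi] - xs[k])
  }
  out
}

#' Apply a fitted rank-normal transform
#' @param model a [fit_rank_normal] fit.
#' @param y_new numeric vector.
#' @return transformed values (normal scale).
#' @export
rank_normal_transform <- function(model, y_new) {
  stopifnot(inherits(model, "rank_normal"))
  .pwl(y_new, model$sorted_originals, model$normal_scores)
}

#' Invert a fitted rank-normal transform
#' @param model a [fit_rank_normal] fit.
#' @param z numeric vector on the normal scale.
#' @return values on the original scale.
#' @export
rank_normal_inverse <- function(model, z) {
  stopifnot(inherits(model, "rank_normal"))
  .pwl(z, model$normal_scores, model$sorted_originals)
}

#' Serialize a rank-normal transform to JSON
#' @param model a [fit_rank_normal] fit.
#' @param path optional file path; if omitted the JSON string is returned.
#' @return JSON string (invisibly, if written to `path`).
#' @export
rank_normal_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "rank_normal"))
  js <- jsonlite::toJSON(unclass(model), digits = NA, auto_unbox = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Restore a rank-normal transform from JSON
#' @param json JSON string or path to a JSON file.
#' @return a `rank_normal` object.
#' @export
rank_normal_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  structure(list(sorted_originals = as.numeric(x$sorted_originals),
                 normal_scores = as.numeric(x$normal_scores),
                 offset = x$offset, n = x$n),
            class = "rank_normal")
}
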