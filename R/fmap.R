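#' @useDynLib mssfnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Validate a feature map
#'
#' A feature map is a 4-axis numeric array in (batch, channels, height, width)
#' order holding unitless activations. All extents must be at least 1 and all
#' values finite.
#'
#' @param x candidate array.
#' @return `x`, invisibly, after validation.
#' @export
check_fmap <- function(x) {
  if (!is.array(x) || length(dim(x)) != 4L)
    stop("feature map must be a 4-axis (batch, channels, height, width) array")
  if (any(dim(x) < 1L)) stop("feature map extents must all be >= 1")
  if (!all(is.finite(x))) stop("feature map contains non-finite values")
  invisible(x)
}

# Concatenate 4-axis arrays along the channel axis (axis 2).
cat_channels <- function(xs) {
  d <- dim(xs[[1L]])
  cs <- vapply(xs, function(x) dim(x)[2L], integer(1))
  out <- array(0, dim = c(d[1L], sum(cs), d[3L], d[4L]))
  at <- 0L
  for (x in xs) {
    out[, at + seq_len(dim(x)[2L]), , ] <- x
    at <- at + dim(x)[2L]
  }
  out
}

# Split a 4-axis array along the channel axis into pieces of the given sizes.
split_channels <- function(x, sizes) {
  at <- 0L
  out <- vector("list", length(sizes))
  for (i in seq_along(sizes)) {
    out[[i]] <- x[, at + seq_len(sizes[i]), , , drop = FALSE]
    at <- at + sizes[i]
  }
  out
}

# Zero-pad / crop the channel axis to n channels (pad at the end).
pad_channels <- function(x, n) {
  d <- dim(x)
  if (d[2L] == n) return(x)
  out <- array(0, dim = c(d[1L], n, d[3L], d[4L]))
  out[, seq_len(min(d[2L], n)), , ] <- x[, seq_len(min(d[2L], n)), , ]
  out
}
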