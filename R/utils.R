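#' Wrap angles into [-180, 180)
#'
#' @param x numeric vector of angles in degrees.
#' @return angles wrapped to the half-open interval \code{[-180, 180)}.
#' @export
wrap_angle <- function(x) {
  y <- (x + 180) %% 360
  y - 180
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.norm3 <- function(a) sqrt(sum(a * a))

.unit3 <- function(a) {
  n <- .norm3(a)
  if (n < 1e-12) stop("zero-length vector")
  a / n
}

.assert <- function(ok, msg, ...) if (!ok) stop(sprintf(msg, ...), call. = FALSE)
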