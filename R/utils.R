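#' Convert pressure from mmHg to Pa
#'
#' @param p Pressure in mmHg.
#' @return Pressure in Pa (1 mmHg = 133.322 Pa).
#' @export
mmHg_to_Pa <- function(p) p * 133.322

#' Convert pressure from Pa to mmHg
#'
#' @param p Pressure in Pa.
#' @return Pressure in mmHg.
#' @export
Pa_to_mmHg <- function(p) p / 133.322

vec_norm <- function(v) sqrt(sum(v * v))

row_norms <- function(m) sqrt(rowSums(m * m))

normalize_rows <- function(m) {
  n <- row_norms(m)
  n[n == 0] <- 1
  m / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

stopifnot_scalar <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be positive", name), call. = FALSE)
  invisible(x)
}
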