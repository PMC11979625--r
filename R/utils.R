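#' Convert a z-score to a two-sided normal p-value
#'
#' The two-sided tail probability of the standard normal at `|z|`, floored at
#' 1e-300 so that extreme scores never underflow to an exact zero (which would
#' break log-scale binning downstream).
#'
#' @param z Numeric vector of finite z-scores.
#' @return Numeric vector of p-values in (0, 1].
#' @examples
#' z_to_p(0)      # 1
#' z_to_p(-6.02)  # ~1.75e-09
#' @export
z_to_p <- function(z) {
  if (!is.numeric(z) || any(!is.finite(z))) {
    stop("z must be finite numeric", call. = FALSE)
  }
  pmax(2 * stats::pnorm(-abs(z)), 1e-300)
}

# Smallest representable p-value across the package (see z_to_p).
P_FLOOR <- 1e-300

#' @noRd
check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min || x != floor(x)) {
    stop(sprintf("'%s' must be a single integer >= %d", name, min), call. = FALSE)
  }
  as.integer(x)
}

#' @noRd
check_prob <- function(x, name, lo = 0, hi = 1, lo_open = FALSE, hi_open = FALSE) {
  ok <- length(x) == 1L && is.numeric(x) && !is.na(x) &&
    (if (lo_open) x > lo else x >= lo) &&
    (if (hi_open) x < hi else x <= hi)
  if (!ok) {
    stop(sprintf(
      "'%s' must be in %s%g, %g%s", name,
      if (lo_open) "(" else "[", lo, hi, if (hi_open) ")" else "]"
    ), call. = FALSE)
  }
  as.numeric(x)
}

#' @noRd
check_pvalues <- function(p, name = "p") {
  if (length(p) == 0L) stop(sprintf("'%s' is empty", name), call. = FALSE)
  if (!is.numeric(p) || any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop(sprintf("'%s' must be numeric in (0, 1]", name), call. = FALSE)
  }
  as.numeric(p)
}
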