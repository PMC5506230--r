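#' The eight-band EEG frequency scheme of Kubicki et al.
#'
#' Returns the fixed partition of the 1.5--44 Hz range used throughout the
#' pipeline: delta 1.5--6, theta 6.5--8, alpha1 8.5--10, alpha2 10.5--12,
#' beta1 12.5--18, beta2 18.5--21, beta3 21.5--30 and gamma 35--44 Hz.
#' Half-hertz band edges make bin assignment unambiguous at the 1 Hz spectral
#' resolution of 1-s epochs: a bin belongs to the band whose interval contains
#' its center frequency, and gap bins (e.g. 30--35 Hz) belong to no band.
#'
#' @return A data frame with columns `band`, `low` and `high` (Hz),
#'   one row per band, in fixed order.
#' @examples
#' kubicki_bands()
#' @export
kubicki_bands <- function() {
  data.frame(
    band = c("delta", "theta", "alpha1", "alpha2",
             "beta1", "beta2", "beta3", "gamma"),
    low  = c(1.5, 6.5, 8.5, 10.5, 12.5, 18.5, 21.5, 35),
    high = c(6.0, 8.0, 10.0, 12.0, 18.0, 21.0, 30.0, 44),
    stringsAsFactors = FALSE
  )
}

validate_bands <- function(bands) {
  stopifnot(is.data.frame(bands), all(c("band", "low", "high") %in% names(bands)))
  if (anyDuplicated(bands$band)) stop("band names must be unique", call. = FALSE)
  if (any(bands$low >= bands$high)) stop("band low edge must be below high edge", call. = FALSE)
  o <- order(bands$low)
  if (any(bands$high[o][-nrow(bands)] > bands$low[o][-1]))
    stop("bands must not overlap", call. = FALSE)
  bands
}

## Map each band to the 1 Hz-resolution DFT bins (integer center frequencies)
## whose centers fall inside [low, high]. Returns a named list of bin
## frequencies in Hz; with a 1-s epoch, bin k (0-based) sits at k Hz.
band_bins <- function(bands = kubicki_bands(), resolution = 1) {
  validate_bands(bands)
  out <- lapply(seq_len(nrow(bands)), function(i) {
    f <- seq(ceiling(bands$low[i] / resolution) * resolution,
             floor(bands$high[i] / resolution) * resolution, by = resolution)
    f[f >= bands$low[i] & f <= bands$high[i]]
  })
  names(out) <- bands$band
  out
}
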