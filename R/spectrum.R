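#' Construct an integer-binned EI mass spectrum
#'
#' A mass spectrum is stored as one intensity per integer m/z bin over a
#' closed range, by default m/z 85 to 500 (416 bins), the acquisition range
#' of a typical GC-TOF/MS metabolomics run. The spectrum is the universal
#' feature vector for both library matching and SIMCA class modeling.
#'
#' @param intensities Numeric vector of non-negative intensities, one per
#'   integer m/z in `[mz_min, mz_max]`.
#' @param mz_min,mz_max Integer m/z bounds of the binning grid (closed range).
#' @return An object of class `mass_spectrum`.
#' @examples
#' s <- mass_spectrum(c(50, 0, 25), mz_min = 100, mz_max = 102)
#' normalize_spectrum(s)
#' @export
mass_spectrum <- function(intensities, mz_min = 85L, mz_max = 500L) {
  mz_min <- as.integer(mz_min)
  mz_max <- as.integer(mz_max)
  if (mz_max < mz_min) stop("mz_max must be >= mz_min", call. = FALSE)
  intensities <- as.numeric(intensities)
  n_bins <- mz_max - mz_min + 1L
  if (length(intensities) != n_bins) {
    stop(sprintf("intensities must have %d values for m/z %d-%d, got %d",
                 n_bins, mz_min, mz_max, length(intensities)), call. = FALSE)
  }
  if (anyNA(intensities) || any(!is.finite(intensities))) {
    stop("intensities must be finite and non-missing", call. = FALSE)
  }
  if (any(intensities < 0)) {
    stop("intensities must be non-negative", call. = FALSE)
  }
  structure(list(mz_min = mz_min, mz_max = mz_max, intensities = intensities),
            class = "mass_spectrum")
}

#' @export
print.mass_spectrum <- function(x, ...) {
  n_pos <- sum(x$intensities > 0)
  base <- if (n_pos > 0) x$mz_min + which.max(x$intensities) - 1L else NA
  cat(sprintf("<mass_spectrum> m/z %d-%d, %d non-zero bins, base peak m/z %s\n",
              x$mz_min, x$mz_max, n_pos, base))
  invisible(x)
}

#' m/z axis of a spectrum
#'
#' @param spec A `mass_spectrum`.
#' @return Integer vector of the m/z value of each bin.
#' @export
mz_axis <- function(spec) {
  stopifnot(inherits(spec, "mass_spectrum"))
  seq.int(spec$mz_min, spec$mz_max)
}

#' Normalize a spectrum to relative intensities (base peak = 100)
#'
#' Rescales all intensities by a common factor so the most intense fragment
#' (the base peak) equals exactly 100, the convention for relative EI
#' intensities used throughout library matching and class modeling.
#'
#' @param spec A `mass_spectrum` with at least one positive intensity.
#' @return A `mass_spectrum` on the same bin grid with base peak 100.
#' @export
normalize_spectrum <- function(spec) {
  stopifnot(inherits(spec, "mass_spectrum"))
  top <- max(spec$intensities)
  if (top <= 0) {
    stop("cannot normalize an empty (all-zero) spectrum", call. = FALSE)
  }
  mass_spectrum(spec$intensities * (100 / top), spec$mz_min, spec$mz_max)
}

#' Spectrum weighting scheme
#'
#' In EI spectra the low masses dominate in raw intensity but the high masses
#' carry the structural information, so similarity scoring transforms each
#' bin to `intensity^intensity_exponent * mz^mass_exponent` before
#' correlating. The defaults (0.5, 2) follow the convention of EI library
#' search of damping intensity and strongly up-weighting high m/z;
#' `spectrum_weighting(1, 0)` is the identity transform.
#'
#' @param intensity_exponent Non-negative exponent applied to intensities.
#' @param mass_exponent Non-negative exponent applied to the m/z value.
#' @return An object of class `spectrum_weighting`.
#' @export
spectrum_weighting <- function(intensity_exponent = 0.5, mass_exponent = 2) {
  if (!is.finite(intensity_exponent) || intensity_exponent < 0) {
    stop("intensity_exponent must be finite and >= 0", call. = FALSE)
  }
  if (!is.finite(mass_exponent) || mass_exponent < 0) {
    stop("mass_exponent must be finite and >= 0", call. = FALSE)
  }
  structure(list(intensity_exponent = intensity_exponent,
                 mass_exponent = mass_exponent),
            class = "spectrum_weighting")
}

#' Apply mass weighting to a spectrum
#'
#' @param spec A `mass_spectrum`.
#' @param w A `spectrum_weighting`.
#' @return Numeric vector, one weighted value per bin:
#'   `intensity^a * mz^b`.
#' @export
weight_spectrum <- function(spec, w = spectrum_weighting()) {
  stopifnot(inherits(spec, "mass_spectrum"), inherits(w, "spectrum_weighting"))
  if (any(spec$intensities < 0)) {
    stop("spectrum has negative intensities", call. = FALSE)
  }
  spec$intensities^w$intensity_exponent * mz_axis(spec)^w$mass_exponent
}

#' Degree of coincidence between two weighted spectra
#'
#' The degree of coincidence (DOC) is the Pearson product-moment correlation
#' between two weighted spectral vectors; it is the match score used for
#' library identification. It is symmetric and invariant to positive affine
#' rescaling of either argument.
#'
#' @param u,v Numeric vectors of equal length (typically the output of
#'   [weight_spectrum()]).
#' @return The correlation, in `[-1, 1]`.
#' @export
pearson_doc <- function(u, v) {
  u <- as.numeric(u)
  v <- as.numeric(v)
  if (length(u) != length(v)) {
    stop("weighted vectors must have equal length", call. = FALSE)
  }
  if (length(u) < 2L) stop("need at least two bins", call. = FALSE)
  if (stats::var(u) == 0 || stats::var(v) == 0) {
    stop("undefined correlation: zero-variance spectrum vector",
         call. = FALSE)
  }
  stats::cor(u, v)
}

# DOC between two spectra under a weighting; NA (not an error) when one side
# has zero variance, so callers can treat degenerate candidates as non-matches.
doc_between <- function(spec_a, spec_b, w = spectrum_weighting()) {
  u <- weight_spectrum(spec_a, w)
  v <- weight_spectrum(spec_b, w)
  if (stats::var(u) == 0 || stats::var(v) == 0) return(NA_real_)
  stats::cor(u, v)
}
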