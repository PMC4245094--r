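#' Multipeak fat spectrum
#'
#' A fat spectrum is the set of triglyceride proton resonances used by both
#' the imaging and the spectroscopy branch: chemical shifts in ppm and
#' relative amplitudes that sum to one. Peaks in the 0.5--3.0 ppm range are
#' *measurable* in a non-water-suppressed liver spectrum; peaks within
#' 0.8 ppm of the water resonance (4.7 ppm) are *hidden* underneath water and
#' can only be restored from their published relative amplitudes.
#'
#' @param chemical_shift_ppm Numeric vector of peak positions in ppm.
#' @param relative_amplitude Positive amplitudes; normalised to sum to 1.
#' @param water_shift_ppm Water resonance position, ppm (default 4.7).
#'
#' @return A tibble of class `fat_spectrum` with columns
#'   `chemical_shift_ppm`, `relative_amplitude` and `role`
#'   (`"measurable"` or `"hidden"`), and attribute `water_shift_ppm`.
#' @export
#' @examples
#' fat_spectrum(c(1.3, 5.3), c(0.9, 0.1))
fat_spectrum <- function(chemical_shift_ppm, relative_amplitude,
                         water_shift_ppm = 4.7) {
  if (length(chemical_shift_ppm) != length(relative_amplitude) ||
      length(chemical_shift_ppm) == 0L) {
    abort("`chemical_shift_ppm` and `relative_amplitude` must be non-empty vectors of equal length.")
  }
  if (any(relative_amplitude <= 0)) {
    abort("All relative amplitudes must be positive.")
  }
  if (any(chemical_shift_ppm < 0 | chemical_shift_ppm > 6)) {
    abort("Chemical shifts must lie in [0, 6] ppm.")
  }
  amp <- relative_amplitude / sum(relative_amplitude)
  measurable <- chemical_shift_ppm >= 0.5 & chemical_shift_ppm <= 3.0
  hidden <- abs(chemical_shift_ppm - water_shift_ppm) <= 0.8
  if (any(measurable & hidden) || any(!measurable & !hidden)) {
    abort(paste0("Each peak must be either measurable (0.5-3.0 ppm) or hidden ",
                 "(within 0.8 ppm of water); offending shifts: ",
                 paste(chemical_shift_ppm[(measurable & hidden) |
                                          (!measurable & !hidden)], collapse = ", ")))
  }
  out <- tibble::tibble(
    chemical_shift_ppm = as.numeric(chemical_shift_ppm),
    relative_amplitude = amp,
    role = ifelse(measurable, "measurable", "hidden")
  )
  attr(out, "water_shift_ppm") <- water_shift_ppm
  class(out) <- c("fat_spectrum", class(out))
  out
}

#' Six-peak liver fat spectrum
#'
#' The published six-resonance liver triglyceride model (olefinic 5.3,
#' glycerol 4.2, diacyl 2.75, alpha-carboxyl 2.1, methylene 1.3 and methyl
#' 0.9 ppm) with relative amplitudes 0.047 / 0.039 / 0.006 / 0.120 / 0.700 /
#' 0.088. The 5.3 and 4.2 ppm peaks sit under the water resonance and form
#' the hidden subset (8.6% of total fat signal).
#'
#' @return A [fat_spectrum()].
#' @export
#' @examples
#' sp <- default_fat_spectrum()
#' sum(sp$relative_amplitude)
#' measurable_fraction(sp)
default_fat_spectrum <- function() {
  fat_spectrum(
    chemical_shift_ppm = c(5.3, 4.2, 2.75, 2.1, 1.3, 0.9),
    relative_amplitude = c(0.047, 0.039, 0.006, 0.120, 0.700, 0.088)
  )
}

#' @rdname default_fat_spectrum
#' @param spectrum A [fat_spectrum()].
#' @export
measurable_fraction <- function(spectrum) {
  sum(spectrum$relative_amplitude[spectrum$role == "measurable"])
}

#' @rdname default_fat_spectrum
#' @export
hidden_fraction <- function(spectrum) {
  sum(spectrum$relative_amplitude[spectrum$role == "hidden"])
}

#' Read or write a fat spectrum as JSON
#'
#' Alternate spectral models can be supplied by configuration as a small JSON
#' document of `(chemical_shift_ppm, relative_amplitude)` pairs plus
#' `water_shift_ppm`.
#'
#' @param spectrum A [fat_spectrum()].
#' @param path File path.
#' @return `read_fat_spectrum()` returns a [fat_spectrum()];
#'   `write_fat_spectrum()` returns `path` invisibly.
#' @export
write_fat_spectrum <- function(spectrum, path) {
  jsonlite::write_json(
    list(
      water_shift_ppm = attr(spectrum, "water_shift_ppm"),
      peaks = data.frame(
        chemical_shift_ppm = spectrum$chemical_shift_ppm,
        relative_amplitude = spectrum$relative_amplitude
      )
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_fat_spectrum
#' @export
read_fat_spectrum <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  fat_spectrum(doc$peaks$chemical_shift_ppm, doc$peaks$relative_amplitude,
               water_shift_ppm = doc$water_shift_ppm)
}

#' Gradient-echo acquisition protocols
#'
#' Spoiled gradient-echo protocols at 3 T as used for liver fat
#' quantification: a triple-echo protocol (TE 2.3/3.45/4.6 ms, flip 30 deg)
#' and a multi-echo protocol (TE 1.15--8.05 ms in 1.15 ms steps, flip
#' 15 deg), both at TR 180 ms. Low flip angles keep T1 weighting negligible.
#'
#' @param echo_times_ms Strictly increasing echo times, ms.
#' @param repetition_time_ms TR, ms.
#' @param flip_angle_deg Flip angle, degrees.
#' @param field_strength_T Static field, tesla.
#' @param label `"triple"` or `"multi"`.
#' @return A list of class `gre_protocol`.
#' @export
#' @examples
#' triple_echo_protocol()
#' multi_echo_protocol()$echo_times_ms
gre_protocol <- function(echo_times_ms, repetition_time_ms = 180,
                         flip_angle_deg = 30, field_strength_T = 3,
                         label = c("triple", "multi")) {
  label <- match.arg(label)
  if (any(echo_times_ms <= 0) || is.unsorted(echo_times_ms, strictly = TRUE)) {
    abort("`echo_times_ms` must be strictly increasing and positive.")
  }
  n_expected <- if (label == "triple") 3L else 7L
  if (length(echo_times_ms) != n_expected) {
    abort(sprintf("A '%s' protocol must have exactly %d echoes, got %d.",
                  label, n_expected, length(echo_times_ms)))
  }
  structure(
    list(echo_times_ms = as.numeric(echo_times_ms),
         repetition_time_ms = repetition_time_ms,
         flip_angle_deg = flip_angle_deg,
         field_strength_T = field_strength_T,
         label = label),
    class = "gre_protocol"
  )
}

#' @rdname gre_protocol
#' @export
triple_echo_protocol <- function(field_strength_T = 3) {
  gre_protocol(c(2.3, 3.45, 4.6), 180, 30, field_strength_T, "triple")
}

#' @rdname gre_protocol
#' @export
multi_echo_protocol <- function(field_strength_T = 3) {
  gre_protocol(seq(1.15, 8.05, by = 1.15), 180, 15, field_strength_T, "multi")
}

#' @export
print.gre_protocol <- function(x, ...) {
  cat(sprintf("<gre_protocol '%s'> TR %g ms, flip %g deg, %g T\n  TE (ms): %s\n",
              x$label, x$repetition_time_ms, x$flip_angle_deg,
              x$field_strength_T, paste(x$echo_times_ms, collapse = ", ")))
  invisible(x)
}

#' Tissue state for the forward models
#'
#' Proton densities and relaxation times of one liver voxel/ROI, in arbitrary
#' proton-density units. `fat_t2_ms` may be a single value shared by all fat
#' peaks or one value per peak of the spectrum used downstream.
#'
#' @param water_density,fat_density Non-negative proton densities.
#' @param t2star_ms Effective transverse relaxation for gradient-echo decay.
#' @param water_t2_ms,fat_t2_ms Spin-echo T2 values for the MRS branch, ms.
#' @return A list of class `tissue_state`.
#' @export
tissue_state <- function(water_density, fat_density, t2star_ms = 20,
                         water_t2_ms = 25, fat_t2_ms = 60) {
  stopifnot_scalar_number(water_density, "water_density", min = 0)
  stopifnot_scalar_number(fat_density, "fat_density", min = 0)
  if (t2star_ms <= 0 || water_t2_ms <= 0 || any(fat_t2_ms <= 0)) {
    abort("Relaxation times must be positive.")
  }
  structure(
    list(water_density = water_density, fat_density = fat_density,
         t2star_ms = t2star_ms, water_t2_ms = water_t2_ms,
         fat_t2_ms = fat_t2_ms),
    class = "tissue_state"
  )
}

# ppm offsets from water -> Hz at the given field
ppm_to_hz <- function(shift_ppm, field_T, water_shift_ppm = 4.7) {
  (shift_ppm - water_shift_ppm) * .gamma_mhz_t * field_T
}

#' Complex fat modulation factor
#'
#' The dephasing factor of the composite fat signal relative to water at echo
#' time `te_ms`: `c(TE) = sum_p a_p exp(i 2 pi df_p TE)`, with `df_p` the
#' frequency offset (Hz) of peak `p` from water at the given field strength.
#' Its modulus never exceeds 1; at TE = 0 it is exactly 1.
#'
#' @param te_ms Echo time(s), ms, non-negative.
#' @param spectrum A [fat_spectrum()].
#' @param field_T Field strength in tesla.
#' @return Complex vector, one value per echo time.
#' @export
#' @examples
#' fat_modulation(c(0, 2.3), default_fat_spectrum())
fat_modulation <- function(te_ms, spectrum = default_fat_spectrum(),
                           field_T = 3) {
  if (any(te_ms < 0)) abort("`te_ms` must be non-negative.")
  df_hz <- ppm_to_hz(spectrum$chemical_shift_ppm, field_T,
                     attr(spectrum, "water_shift_ppm"))
  vapply(te_ms, function(te) {
    sum(spectrum$relative_amplitude * exp(1i * 2 * pi * df_hz * te / 1000))
  }, complex(1))
}

#' Noise-free gradient-echo magnitude signal
#'
#' The magnitude forward model shared by the phantom and the estimator:
#' `S(TE) = |W + F c(TE)| exp(-TE / T2*)`. T1 weighting is omitted (low flip
#' angle acquisition).
#'
#' @param tissue A [tissue_state()].
#' @param protocol A [gre_protocol()].
#' @param spectrum A [fat_spectrum()].
#' @return Numeric vector of non-negative magnitudes, one per echo.
#' @export
#' @examples
#' gre_signal(tissue_state(0.9, 0.1), triple_echo_protocol())
gre_signal <- function(tissue, protocol, spectrum = default_fat_spectrum()) {
  if (tissue$water_density + tissue$fat_density <= 0) {
    abort("Tissue densities must not both be zero.")
  }
  if (tissue$t2star_ms <= 0) abort("`t2star_ms` must be positive.")
  te <- protocol$echo_times_ms
  cmod <- fat_modulation(te, spectrum, protocol$field_strength_T)
  Mod(tissue$water_density + tissue$fat_density * cmod) *
    exp(-te / tissue$t2star_ms)
}

#' Proton-density fat fraction from densities
#'
#' PDFF is the fat proton density divided by the sum of the fat and water
#' proton densities.
#'
#' @param fat_density,water_density Non-negative densities, not both zero.
#' @return A value in `[0, 1]`.
#' @export
#' @examples
#' pdff_from_densities(3, 7)
pdff_from_densities <- function(fat_density, water_density) {
  if (any(fat_density < 0) || any(water_density < 0)) {
    abort("Densities must be non-negative.")
  }
  if (any(fat_density + water_density <= 0)) {
    abort("`fat_density` + `water_density` must be positive.")
  }
  fat_density / (fat_density + water_density)
}
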