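# One-row feature extraction for a trimmed, energy-normalized segment:
# the full temporal + spectral feature set used in group comparisons.

feature_schema <- c("length_s",
                    "amp_slope", "amp_curv",
                    "se_avg", "se_slope", "se_curv",
                    "kurt_avg", "kurt_slope", "kurt_curv",
                    "e_0_400", "e_400_800", "e_800_1600", "e_1600_3200",
                    "e_gt_3200", "weighted_freq_hz")

#' Extract the full feature row of a segment
#'
#' Temporal features are the DCT shape descriptors of the amplitude, sample
#' entropy, and kurtosis contours (the amplitude average is one by
#' construction and therefore not reported); spectral features are the five
#' relative band energies and the weighted (centroid-approximating)
#' frequency.
#'
#' @param seg a `cough_segment` from [trim_segment()] / [normalize_energy()].
#' @param frame_s,hop_s contour frame parameters (s).
#' @param m,r_factor,decimate_to_hz sample-entropy parameters (see
#'   [sample_entropy_contour()]).
#' @param edges interior band edges in Hz.
#' @return One-row data.frame with columns `length_s`, `amp_slope`,
#'   `amp_curv`, `se_avg`, `se_slope`, `se_curv`, `kurt_avg`, `kurt_slope`,
#'   `kurt_curv`, `e_0_400` ... `e_gt_3200`, `weighted_freq_hz`, and an
#'   attribute `undefined_frames` (count of contour frames dropped as
#'   undefined).
#' @export
extract_features <- function(seg, frame_s = 0.02, hop_s = 0.01,
                             m = 2L, r_factor = 0.2, decimate_to_hz = 4410,
                             edges = band_edge_defaults) {
  stopifnot(is_segment(seg))
  amp <- amplitude_contour(seg, frame_s, hop_s)
  se <- sample_entropy_contour(seg, frame_s, hop_s, m, r_factor,
                               decimate_to_hz)
  ku <- kurtosis_contour(seg, frame_s, hop_s)
  amp_sh <- contour_shape(amp)
  se_sh <- contour_shape(se)
  ku_sh <- contour_shape(ku)
  dec <- dct_band_decompose(seg, edges)
  out <- data.frame(
    length_s = seg$duration,
    amp_slope = amp_sh[["slope"]], amp_curv = amp_sh[["curvature"]],
    se_avg = se_sh[["average"]], se_slope = se_sh[["slope"]],
    se_curv = se_sh[["curvature"]],
    kurt_avg = ku_sh[["average"]], kurt_slope = ku_sh[["slope"]],
    kurt_curv = ku_sh[["curvature"]],
    e_0_400 = dec$rel_energy[1], e_400_800 = dec$rel_energy[2],
    e_800_1600 = dec$rel_energy[3], e_1600_3200 = dec$rel_energy[4],
    e_gt_3200 = dec$rel_energy[5],
    weighted_freq_hz = weighted_frequency(dec)
  )
  attr(out, "undefined_frames") <- sum(is.na(se$values)) + sum(is.na(ku$values))
  out
}
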