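#' Standard 32-channel 10-20 montage
#'
#' Unit-sphere electrode positions for the 32 channels of the extended 10-20
#' montage used throughout the package. Positions are derived from the
#' standard spherical layout: each electrode is parameterised by an
#' inclination from the vertex (Cz) and an azimuth measured from the nasion
#' direction (positive to the right), and mapped onto the unit sphere with
#' +x right, +y anterior, +z superior. These idealised positions are what the
#' surface-Laplacian transform and the blink spatial profile use; no
#' subject-specific digitisation is modelled.
#'
#' @return A numeric matrix with one row per channel (rownames are channel
#'   labels, in the canonical recording order) and columns `x`, `y`, `z`.
#' @export
#' @examples
#' m <- eeg_montage()
#' stopifnot(all(abs(rowSums(m^2) - 1) < 1e-12))
eeg_montage <- function() {
  # inclination (deg from vertex), azimuth (deg from nasion, + = right)
  tab <- matrix(c(
    92,  -18,   # Fp1
    92,   18,   # Fp2
    92,   54,   # F8
    60,   39,   # F4
    46,    0,   # Fz
    60,  -39,   # F3
    92,  -54,   # F7
    113, -72,   # FT9
    113,  72,   # FT10
    72,  -69,   # FC5
    32,  -45,   # FC1
    32,   45,   # FC2
    72,   69,   # FC6
    92,  -90,   # T7
    92,   90,   # T8
    46,  -90,   # C3
    0,     0,   # Cz
    46,   90,   # C4
    72, -111,   # CP5
    32, -135,   # CP1
    32,  135,   # CP2
    72,  111,   # CP6
    113, -108,  # TP9
    113,  108,  # TP10
    92,  -126,  # P7
    60,  -141,  # P3
    46,  180,   # Pz
    60,  141,   # P4
    92,  126,   # P8
    92,  -162,  # O1
    92,  180,   # Oz
    92,  162    # O2
  ), ncol = 2, byrow = TRUE)
  inc <- tab[, 1] * pi / 180
  az  <- tab[, 2] * pi / 180
  pos <- cbind(x = sin(inc) * sin(az),
               y = sin(inc) * cos(az),
               z = cos(inc))
  rownames(pos) <- eeg_channels()
  pos
}

#' Canonical channel order of the 32-channel montage
#' @return Character vector of the 32 channel labels in recording order.
#' @keywords internal
eeg_channels <- function() {
  c("Fp1", "Fp2", "F8", "F4", "Fz", "F3", "F7", "FT9", "FT10",
    "FC5", "FC1", "FC2", "FC6", "T7", "T8", "C3", "Cz", "C4",
    "CP5", "CP1", "CP2", "CP6", "TP9", "TP10", "P7", "P3", "Pz",
    "P4", "P8", "O1", "Oz", "O2")
}

#' Scalp region map
#'
#' Assignment of the 32 channels to five non-overlapping scalp regions
#' (frontal, parietal, temporal, occipital, central) used for regional band
#' power and region-pair connectivity summaries.
#'
#' @return Named list of character vectors of channel labels.
#' @export
eeg_regions <- function() {
  list(
    Frontal   = c("Fp1", "Fp2", "F8", "F4", "Fz", "F3", "F7"),
    Parietal  = c("P7", "P3", "Pz", "P4", "P8"),
    Temporal  = c("T7", "T8", "TP9", "TP10", "FT9", "FT10"),
    Occipital = c("O1", "O2", "Oz"),
    Central   = c("FC5", "FC1", "FC2", "FC6", "C3", "Cz", "C4",
                  "CP5", "CP1", "CP2", "CP6")
  )
}
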