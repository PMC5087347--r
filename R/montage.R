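#' Standard 32-channel montage (10-20 system)
#'
#' Electrode labels for the 32-channel layout used by preprocessed
#' affective-EEG recordings (Geneva order), with a coarse brain-lobe
#' annotation for reporting channel rankings.
#'
#' @param n_channels Number of channels. For 32 the standard 10-20 labels
#'   are returned; otherwise generic labels `Ch01`, `Ch02`, ... are used.
#' @return Character vector of channel labels of length `n_channels`.
#' @examples
#' montage_labels(32)[1:5]
#' montage_labels(4)
#' @export
montage_labels <- function(n_channels = 32L) {
  std <- c("Fp1", "AF3", "F3", "F7", "FC5", "FC1", "C3", "T7",
           "CP5", "CP1", "P3", "P7", "PO3", "O1", "Oz", "Pz",
           "Fp2", "AF4", "F4", "F8", "FC6", "FC2", "C4", "T8",
           "CP6", "CP2", "P4", "P8", "PO4", "O2", "Fz", "Cz")
  if (n_channels == 32L) std else sprintf("Ch%02d", seq_len(n_channels))
}

#' Brain lobe of an electrode label
#'
#' Maps 10-20 electrode labels to a coarse lobe annotation
#' (Frontal, Central, Parietal, Temporal, Occipital) for ranked-channel
#' reports; unrecognised labels map to `NA`.
#'
#' @param labels Character vector of electrode labels.
#' @return Character vector of lobe names.
#' @examples
#' electrode_lobe(c("Fp1", "Pz", "T7", "Oz"))
#' @export
electrode_lobe <- function(labels) {
  prefix <- sub("[0-9z]+$", "", labels)
  lobe <- c(Fp = "Frontal", AF = "Frontal", F = "Frontal", FC = "Frontal",
            C = "Central", CP = "Parietal", P = "Parietal", PO = "Parietal",
            T = "Temporal", O = "Occipital")
  unname(lobe[prefix])
}
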