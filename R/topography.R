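#' The 21-electrode analysis subset
#'
#' Channels over which P1/N1 amplitude and latency analyses are run;
#' probe-evoked activity is concentrated fronto-centrally, so far
#' temporal/occipital sites and the mastoid reference channels are
#' excluded.
#'
#' @return character vector of 21 channel labels.
#' @export
analysisChannels <- function() {
  c("Fp1", "Fz", "F3", "F7", "FC5", "FC1", "C3", "CP5", "CP1", "Pz",
    "P3", "P4", "CP6", "CP2", "Cz", "C4", "FC6", "FC2", "F4", "F8", "Fp2")
}

#' Topographic factor map
#'
#' Maps each analysis channel to an Anteriority level (Front, Center,
#' Back) and a Laterality level (Left, Middle, Right) for the topographic
#' factors of the repeated-measures ANOVA.  The shipped default is a 3 x 3
#' partition of the 21-channel subset; a user TSV (columns `channel`,
#' `anteriority`, `laterality`) can replace it.
#'
#' @param path optional path to an override TSV.
#' @return data.frame with columns `channel`, `anteriority`, `laterality`.
#' @export
topoMap <- function(path = NULL) {
  if (!is.null(path)) {
    d <- utils::read.delim(path, sep = "\t", header = TRUE,
                           fileEncoding = "UTF-8")
    stopifnot(all(c("channel", "anteriority", "laterality") %in% names(d)))
    return(d)
  }
  front  <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8")
  center <- c("FC5", "FC1", "FC2", "FC6", "C3", "Cz", "C4")
  back   <- c("CP5", "CP1", "CP2", "CP6", "P3", "Pz", "P4")
  left   <- c("Fp1", "F7", "F3", "FC5", "FC1", "C3", "CP5", "CP1", "P3")
  middle <- c("Fz", "Cz", "Pz")
  right  <- c("Fp2", "F8", "F4", "FC6", "FC2", "C4", "CP6", "CP2", "P4")
  ch <- analysisChannels()
  data.frame(
    channel = ch,
    anteriority = ifelse(ch %in% front, "Front",
                         ifelse(ch %in% center, "Center", "Back")),
    laterality = ifelse(ch %in% left, "Left",
                        ifelse(ch %in% middle, "Middle", "Right")))
}
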