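#' Construct a channel layout
#'
#' @param channels data.frame with columns \code{channel_id},
#'   \code{region}, \code{label}.
#' @param separationCm emitter-detector distance in cm.
#' @return a [ChannelLayout-class].
#' @export
#' @examples
#' layout <- defaultChannelLayout()
#' nChannels(layout)
channelLayout <- function(channels, separationCm = 3.5) {
  channels$channel_id <- as.character(channels$channel_id)
  channels$region <- as.character(channels$region)
  channels$label <- as.character(channels$label)
  new("ChannelLayout", channels = channels, separationCm = separationCm)
}

#' The default seven-channel montage
#'
#' Three channels over the frontopolar prefrontal cortex (10-10
#' positions Fp1, Fpz, Fp2 for the left, medial and right PFC) and four
#' in a square template over the right parietal area centred on P6,
#' with a 3.5 cm emitter-detector separation.
#'
#' @param separationCm emitter-detector distance in cm.
#' @return a [ChannelLayout-class] with 7 channels.
#' @export
defaultChannelLayout <- function(separationCm = 3.5) {
  channelLayout(data.frame(
    channel_id = c("CH1", "CH2", "CH3", "CH4", "CH5", "CH6", "CH7"),
    region = c("lPFC", "mPFC", "rPFC", rep("rParietal", 4L)),
    label = c("Fp1", "Fpz", "Fp2", "P6-q1", "P6-q2", "P6-q3", "P6-q4"),
    stringsAsFactors = FALSE), separationCm = separationCm)
}

#' @describeIn channelLayout number of channels in a layout.
#' @param object a \code{ChannelLayout}.
#' @export
nChannels <- function(object) nrow(object@channels)

#' Channel ids belonging to a region set
#'
#' @param layout a [ChannelLayout-class].
#' @param regionSet \code{"PFC"} (the three frontopolar channels),
#'   \code{"parietal"} (the four right-parietal channels) or
#'   \code{"both"}.
#' @return character vector of channel ids.
#' @export
regionChannels <- function(layout, regionSet = c("PFC", "parietal", "both")) {
  regionSet <- match.arg(regionSet)
  ch <- layout@channels
  keep <- switch(regionSet,
    PFC = ch$region %in% PFC_REGIONS,
    parietal = ch$region == "rParietal",
    both = rep(TRUE, nrow(ch)))
  ch$channel_id[keep]
}

setMethod("show", "ChannelLayout", function(object) {
  ch <- object@channels
  cat("ChannelLayout with", nrow(ch), "channels,",
      object@separationCm, "cm separation\n")
  cat("  PFC:", paste(ch$label[ch$region %in% PFC_REGIONS], collapse = ", "),
      "| parietal:", paste(ch$label[ch$region == "rParietal"], collapse = ", "),
      "\n")
})
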