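## Accessor generics. Slot access from user code should go through these.

#' Trial table of a session
#' @param x a SessionRecord
#' @return data.frame of trial records
#' @export
setGeneric("trials", function(x) standardGeneric("trials"))

#' @rdname trials
#' @export
setMethod("trials", "SessionRecord", function(x) x@trials)

#' Continuous streams of a session
#' @param x a SessionRecord
#' @return a ContinuousStreams object
#' @export
setGeneric("streams", function(x) standardGeneric("streams"))

#' @rdname streams
#' @export
setMethod("streams", "SessionRecord", function(x) x@streams)

#' Number of neural channels
#' @param x a SessionRecord or BinnedFeatures
#' @return integer
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @rdname nChannels
#' @export
setMethod("nChannels", "SessionRecord", function(x) x@nChannels)

#' @rdname nChannels
#' @export
setMethod("nChannels", "BinnedFeatures", function(x) ncol(x@values))

#' Feature value matrix (bins x channels)
#' @param x a BinnedFeatures
#' @return numeric matrix
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @rdname featureValues
#' @export
setMethod("featureValues", "BinnedFeatures", function(x) x@values)

#' Bin width in milliseconds
#' @param x a BinnedFeatures
#' @return integer
#' @export
setGeneric("binWidthMs", function(x) standardGeneric("binWidthMs"))

#' @rdname binWidthMs
#' @export
setMethod("binWidthMs", "BinnedFeatures", function(x) x@binWidthMs)

#' Bin start times (ms, session clock)
#' @param x a BinnedFeatures
#' @return numeric vector
#' @export
setGeneric("binStartTimes", function(x) standardGeneric("binStartTimes"))

#' @rdname binStartTimes
#' @export
setMethod("binStartTimes", "BinnedFeatures", function(x) x@binStartTimesMs)

#' Channel mask
#' @param x a BinnedFeatures or RidgeDecoder
#' @return logical vector
#' @export
setGeneric("channelMask", function(x) standardGeneric("channelMask"))

#' @rdname channelMask
#' @export
setMethod("channelMask", "BinnedFeatures", function(x) x@channelMask)

#' @rdname channelMask
#' @export
setMethod("channelMask", "RidgeDecoder", function(x) x@channelMask)

#' Orthonormal basis of a manifold
#' @param x a ContextManifold
#' @return channels x K matrix
#' @export
setGeneric("manifoldBasis", function(x) standardGeneric("manifoldBasis"))

#' @rdname manifoldBasis
#' @export
setMethod("manifoldBasis", "ContextManifold", function(x) x@basis)
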