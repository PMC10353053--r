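#' @rdname VelocityField-class
#' @export
setGeneric("velocityValues", function(object) standardGeneric("velocityValues"))

#' @rdname VelocityField-class
#' @export
setGeneric("spatialStep", function(object) standardGeneric("spatialStep"))

#' @rdname VelocityField-class
#' @export
setGeneric("timeStep", function(object) standardGeneric("timeStep"))

#' @rdname VelocityField-class
#' @export
setGeneric("lvLength", function(object) standardGeneric("lvLength"))

#' @rdname VelocityField-class
#' @export
setGeneric("nyquistVelocity", function(object) standardGeneric("nyquistVelocity"))

#' @rdname VelocityField-class
#' @export
setGeneric("spaceAxis", function(object) standardGeneric("spaceAxis"))

#' @rdname VelocityField-class
#' @export
setGeneric("timeAxis", function(object) standardGeneric("timeAxis"))

#' @rdname PressureField-class
#' @export
setGeneric("pressureTotal", function(object) standardGeneric("pressureTotal"))

#' @rdname PressureField-class
#' @export
setGeneric("pressureInertial", function(object) standardGeneric("pressureInertial"))

#' @rdname PressureField-class
#' @export
setGeneric("pressureConvective", function(object) standardGeneric("pressureConvective"))

#' @rdname RRSeries-class
#' @export
setGeneric("rrIntervals", function(object) standardGeneric("rrIntervals"))

#' @rdname RRSeries-class
#' @export
setGeneric("beatTimes", function(object) standardGeneric("beatTimes"))

#' @rdname RRSeries-class
#' @export
setGeneric("ectopicFlags", function(object) standardGeneric("ectopicFlags"))

#' @rdname ECGRecord-class
#' @export
setGeneric("ecgSamples", function(object) standardGeneric("ecgSamples"))

#' @rdname ECGRecord-class
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))

#' @rdname ECGRecord-class
#' @export
setGeneric("recordDuration", function(object) standardGeneric("recordDuration"))

#' @rdname IVPGResult-class
#' @export
setGeneric("ivpdProfile", function(object, segment = "total") standardGeneric("ivpdProfile"))

#' @rdname IVPGResult-class
#' @export
setGeneric("ivpgPeaks", function(object) standardGeneric("ivpgPeaks"))
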