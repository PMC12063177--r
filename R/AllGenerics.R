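#' @import methods
NULL

#' Accessors for trace and event objects
#'
#' Small generic accessor family used across the package instead of direct
#' slot access: `samples()` returns the raw current vector of a [Trace-class]
#' in pA, `samplingRate()` its sampling frequency in Hz, `protocol()` the
#' attached [VoltageProtocol-class] (or `NULL`), `traceMetadata()` the
#' free-form metadata list, `eventData()` the per-event `data.frame` of an
#' [EventTable-class] and `nEvents()` its row count.
#'
#' @param object A [Trace-class] or [EventTable-class] object.
#' @return `samples()` a numeric vector; `samplingRate()` a single number in
#'   Hz; `protocol()` a [VoltageProtocol-class] or `NULL`; `traceMetadata()`
#'   a named list; `eventData()` a `data.frame`; `nEvents()` an integer.
#' @name accessors
#' @aliases samples samplingRate protocol traceMetadata eventData nEvents
#' @examples
#' tr <- Trace(rnorm(100, 80, 2), samplingRate = 5e4)
#' samplingRate(tr)
#' length(samples(tr))
NULL

#' @rdname accessors
#' @export
setGeneric("samples", function(object) standardGeneric("samples"))

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))

#' @rdname accessors
#' @export
setGeneric("protocol", function(object) standardGeneric("protocol"))

#' @rdname accessors
#' @export
setGeneric("traceMetadata", function(object) standardGeneric("traceMetadata"))

#' @rdname accessors
#' @export
setGeneric("eventData", function(object) standardGeneric("eventData"))

#' @rdname accessors
#' @export
setGeneric("nEvents", function(object) standardGeneric("nEvents"))

#' Level-profile accessors
#'
#' Accessors for fitted [LevelProfile-class] summaries: the shallowest and
#' deepest fitted blockade levels (`iexMin()`, `iexMax()`, in excluded-current
#' percent), their difference `deltaIEX()` (the blockade "bandwidth", in
#' Delta-percent), and the discrete level census `levelCount()`.
#'
#' @param object A [LevelProfile-class].
#' @return A single numeric (or integer for `levelCount()`); `NA` until the
#'   corresponding fit/count has been run.
#' @name level-accessors
#' @aliases iexMin iexMax deltaIEX levelCount
NULL

#' @rdname level-accessors
#' @export
setGeneric("iexMin", function(object) standardGeneric("iexMin"))

#' @rdname level-accessors
#' @export
setGeneric("iexMax", function(object) standardGeneric("iexMax"))

#' @rdname level-accessors
#' @export
setGeneric("deltaIEX", function(object) standardGeneric("deltaIEX"))

#' @rdname level-accessors
#' @export
setGeneric("levelCount", function(object) standardGeneric("levelCount"))
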