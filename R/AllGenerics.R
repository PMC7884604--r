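# Accessor generics. Slot access from user code should go through these.

#' @rdname accessors
#' @param object an object from this package.
#' @export
setGeneric("zGrid", function(object) standardGeneric("zGrid"))

#' @rdname accessors
#' @export
setGeneric("statGrid", function(object) standardGeneric("statGrid"))

#' @rdname accessors
#' @export
setGeneric("clusters", function(object) standardGeneric("clusters"))

#' @rdname accessors
#' @export
setGeneric("observed", function(object) standardGeneric("observed"))

#' @rdname accessors
#' @export
setGeneric("predicted", function(object) standardGeneric("predicted"))

#' @rdname accessors
#' @export
setGeneric("folds", function(object) standardGeneric("folds"))

#' @rdname accessors
#' @export
setGeneric("chanceInterval", function(object) standardGeneric("chanceInterval"))

#' @rdname accessors
#' @export
setGeneric("designMatrix", function(object) standardGeneric("designMatrix"))

#' @rdname accessors
#' @export
setGeneric("censored", function(object) standardGeneric("censored"))

#' @rdname accessors
#' @export
setGeneric("retained", function(object) standardGeneric("retained"))

#' @rdname accessors
#' @export
setGeneric("masks", function(object) standardGeneric("masks"))

#' @rdname accessors
#' @export
setGeneric("motionTrace", function(object) standardGeneric("motionTrace"))

#' @rdname accessors
#' @export
setGeneric("runData", function(object) standardGeneric("runData"))

#' @rdname accessors
#' @export
setGeneric("affineMatrix", function(object) standardGeneric("affineMatrix"))

#' Accessors for bariconn objects
#'
#' Small read-only accessors: `zGrid` (Fisher-z array of a
#' [ConnectivityMap-class]), `statGrid`/`clusters` (a
#' [ContrastResult-class]), `observed`/`predicted`/`folds`/`chanceInterval`
#' (a [PredictionResult-class] or [HormoneStats-class]),
#' `designMatrix`/`censored` (a [NuisanceDesign-class]), `retained`
#' (a [CleanRun-class]), and `runData`/`motionTrace`/`masks`/`affineMatrix`
#' (a [BoldRun-class] or [CleanRun-class]).
#'
#' @param object an object from this package.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
setMethod("zGrid", "ConnectivityMap", function(object) object@zgrid)
#' @rdname accessors
setMethod("statGrid", "ContrastResult", function(object) object@stat)
#' @rdname accessors
setMethod("clusters", "ContrastResult", function(object) object@clusters)
#' @rdname accessors
setMethod("observed", "PredictionResult", function(object) object@observed)
#' @rdname accessors
setMethod("predicted", "PredictionResult", function(object) object@predicted)
#' @rdname accessors
setMethod("folds", "PredictionResult", function(object) object@folds)
#' @rdname accessors
setMethod("chanceInterval", "PredictionResult",
          function(object) c(low = object@permLow, high = object@permHigh))
#' @rdname accessors
setMethod("chanceInterval", "HormoneStats",
          function(object) c(low = object@permLow, high = object@permHigh))
#' @rdname accessors
setMethod("designMatrix", "NuisanceDesign", function(object) object@matrix)
#' @rdname accessors
setMethod("censored", "NuisanceDesign", function(object) object@censored)
#' @rdname accessors
setMethod("retained", "CleanRun", function(object) object@retained)
#' @rdname accessors
setMethod("masks", "BoldRun", function(object) object@masks)
#' @rdname accessors
setMethod("masks", "CleanRun", function(object) object@masks)
#' @rdname accessors
setMethod("motionTrace", "BoldRun", function(object) object@motion)
#' @rdname accessors
setMethod("runData", "BoldRun", function(object) object@data)
#' @rdname accessors
setMethod("runData", "CleanRun", function(object) object@residuals)
#' @rdname accessors
setMethod("affineMatrix", "BoldRun", function(object) object@affine)
#' @rdname accessors
setMethod("affineMatrix", "CleanRun", function(object) object@affine)
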