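#' Accessors for flycourt classes
#'
#' Small accessor generics so downstream code never touches slots.
#'
#' @param object a flycourt object.
#' @return The extracted component (see the class documentation).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("poses", function(object) standardGeneric("poses"))
#' @rdname accessors
#' @export
setGeneric("frameRate", function(object) standardGeneric("frameRate"))
#' @rdname accessors
#' @export
setGeneric("frameLabels", function(object) standardGeneric("frameLabels"))
#' @rdname accessors
#' @export
setGeneric("boutTable", function(object) standardGeneric("boutTable"))
#' @rdname accessors
#' @export
setGeneric("polarData", function(object) standardGeneric("polarData"))
#' @rdname accessors
#' @export
setGeneric("binTable", function(object) standardGeneric("binTable"))
#' @rdname accessors
#' @export
setGeneric("trackedTrial", function(object) standardGeneric("trackedTrial"))
#' @rdname accessors
#' @export
setGeneric("trueLabels", function(object) standardGeneric("trueLabels"))
#' @rdname accessors
#' @export
setGeneric("scenario", function(object) standardGeneric("scenario"))

#' @rdname accessors
#' @export
setMethod("poses", "TrackedTrial", function(object) object@poses)
#' @rdname accessors
#' @export
setMethod("poses", "SyntheticTrial", function(object) object@trial@poses)
#' @rdname accessors
#' @export
setMethod("frameRate", "TrackedTrial", function(object) object@frameRate)
#' @rdname accessors
#' @export
setMethod("frameRate", "SyntheticTrial", function(object) object@trial@frameRate)
#' @rdname accessors
#' @export
setMethod("frameRate", "PolarTrack", function(object) object@frameRate)
#' @rdname accessors
#' @export
setMethod("frameLabels", "BehaviorLabels", function(object) object@label)
#' @rdname accessors
#' @export
setMethod("frameLabels", "SyntheticTrial", function(object) object@labels@label)
#' @rdname accessors
#' @export
setMethod("boutTable", "BehaviorLabels", function(object) object@bouts)
#' @rdname accessors
#' @export
setMethod("boutTable", "SyntheticTrial", function(object) object@labels@bouts)
#' @rdname accessors
#' @export
setMethod("polarData", "PolarTrack", function(object) object@data)
#' @rdname accessors
#' @export
setMethod("binTable", "PathProfile", function(object)
  data.frame(bin_center_rad = object@binCenter, mean_mm = object@meanR,
             n = object@counts))
#' @rdname accessors
#' @export
setMethod("trackedTrial", "SyntheticTrial", function(object) object@trial)
#' @rdname accessors
#' @export
setMethod("trueLabels", "SyntheticTrial", function(object) object@labels)
#' @rdname accessors
#' @export
setMethod("scenario", "SyntheticTrial", function(object) object@scenario)
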