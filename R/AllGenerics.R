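#' @import methods
NULL

#' @rdname descriptorMatrix
#' @export
setGeneric("descriptorMatrix", function(x, ...) standardGeneric("descriptorMatrix"))

#' @rdname descriptorMatrix
#' @export
setGeneric("descriptorNames", function(x) standardGeneric("descriptorNames"))

#' @rdname descriptorMatrix
#' @export
setGeneric("compoundIds", function(x) standardGeneric("compoundIds"))

#' @rdname activityValues
#' @export
setGeneric("activityValues", function(x, ...) standardGeneric("activityValues"))

#' @rdname splitLabels
#' @export
setGeneric("splitLabels", function(x) standardGeneric("splitLabels"))

#' @rdname splitLabels
#' @export
setGeneric("splitLabels<-", function(x, value) standardGeneric("splitLabels<-"))

#' @rdname trainSet
#' @export
setGeneric("trainSet", function(x) standardGeneric("trainSet"))

#' @rdname trainSet
#' @export
setGeneric("testSet", function(x) standardGeneric("testSet"))

#' @rdname compoundProperties
#' @export
setGeneric("compoundProperties", function(x) standardGeneric("compoundProperties"))

#' @rdname bindingAffinity
#' @export
setGeneric("bindingAffinity", function(x) standardGeneric("bindingAffinity"))
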