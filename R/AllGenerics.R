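#' @rdname FrameStack-class
#' @param object,x a frameTriage object.
#' @export
setGeneric("nEvents", function(x) standardGeneric("nEvents"))

#' @rdname FrameStack-class
#' @export
setGeneric("frameShape", function(x) standardGeneric("frameShape"))

#' @rdname DetectorGeometry-class
#' @export
setGeneric("panelNames", function(x) standardGeneric("panelNames"))

#' @rdname DetectorGeometry-class
#' @export
setGeneric("dataShape", function(x) standardGeneric("dataShape"))

#' @rdname PolyFit-class
#' @export
setGeneric("inflections", function(x) standardGeneric("inflections"))

#' @rdname LabelSet-class
#' @export
setGeneric("labelCounts", function(x) standardGeneric("labelCounts"))

#' @rdname LabelSet-class
#' @export
setGeneric("labelRefs", function(x) standardGeneric("labelRefs"))

#' @export
#' @rdname FrameStack-class
setMethod("nEvents", "FrameStack", function(x) x@nEvents)

#' @export
#' @rdname FrameStack-class
setMethod("frameShape", "FrameStack", function(x) x@frameShape)

#' @export
#' @rdname DetectorGeometry-class
setMethod("panelNames", "DetectorGeometry", function(x) x@panels$name)

#' @export
#' @rdname DetectorGeometry-class
setMethod("dataShape", "DetectorGeometry", function(x) x@dataShape)

#' @export
#' @rdname PolyFit-class
setMethod("inflections", "PolyFit", function(x) x@inflections)

#' @export
#' @rdname PolyFit-class
setMethod("coef", "PolyFit", function(object, ...) object@coefficients)

#' @export
#' @rdname LabelSet-class
setMethod("labelCounts", "LabelSet", function(x) {
  tab <- table(factor(x@refs$label, levels = c("good", "bad", "skip")))
  stats::setNames(as.integer(tab), names(tab))
})

#' @export
#' @rdname LabelSet-class
setMethod("labelRefs", "LabelSet", function(x) x@refs)
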