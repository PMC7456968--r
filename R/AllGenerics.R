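#' @rdname betaValues
#' @export
setGeneric("betaValues", function(x) standardGeneric("betaValues"))

#' @rdname probeManifest
#' @export
setGeneric("probeManifest", function(x) standardGeneric("probeManifest"))

#' @rdname sampleGroups
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' @rdname survivalOutcome
#' @export
setGeneric("survivalOutcome", function(x) standardGeneric("survivalOutcome"))

#' @rdname filterProbes
#' @export
setGeneric("filterProbes",
    function(x, ..., availabilityMin = 0.9) standardGeneric("filterProbes"))

#' @rdname imputeMissing
#' @export
setGeneric("imputeMissing", function(x) standardGeneric("imputeMissing"))

#' @rdname normalizeBetweenSamples
#' @export
setGeneric("normalizeBetweenSamples",
    function(x) standardGeneric("normalizeBetweenSamples"))

#' @rdname signatureMarkers
#' @export
setGeneric("signatureMarkers", function(x) standardGeneric("signatureMarkers"))

#' @rdname signatureCutoff
#' @export
setGeneric("signatureCutoff", function(x) standardGeneric("signatureCutoff"))

#' @rdname riskScores
#' @export
setGeneric("riskScores", function(model, x) standardGeneric("riskScores"))
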