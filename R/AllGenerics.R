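#' @rdname GwasCohort-accessors
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @rdname GwasCohort-accessors
#' @export
setGeneric("snpInfo", function(x) standardGeneric("snpInfo"))

#' @rdname GwasCohort-accessors
#' @export
setGeneric("outcome", function(x) standardGeneric("outcome"))

#' @rdname GwasCohort-accessors
#' @export
setGeneric("outcome<-", function(x, value) standardGeneric("outcome<-"))

#' @rdname GwasCohort-accessors
#' @export
setGeneric("covariates", function(x) standardGeneric("covariates"))

#' @rdname GwasCohort-accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname GwasCohort-accessors
#' @export
setGeneric("nSnps", function(x) standardGeneric("nSnps"))

#' @rdname GwasCohort-accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname encodeAdditive
#' @export
setGeneric("encodeAdditive", function(x) standardGeneric("encodeAdditive"))

#' @rdname CohortSplit-accessors
#' @export
setGeneric("stage1", function(x) standardGeneric("stage1"))

#' @rdname CohortSplit-accessors
#' @export
setGeneric("stage2", function(x) standardGeneric("stage2"))

#' @rdname CohortSplit-accessors
#' @export
setGeneric("manifest", function(x) standardGeneric("manifest"))
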