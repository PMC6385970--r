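#' @include AllClasses.R
NULL

#' Accessors for GenomeSeq and RepeatFamily objects
#'
#' `genomeId()` and `genomeLength()` return the identifier and length of
#' a [GenomeSeq-class]; `genomeString()` the plain character sequence;
#' `isCircularGenome()` the topology flag.  `familyId()`,
#' `familyLength()`, `representative()`, `repeatCopies()`, `copyCount()`
#' and `isTandem()` access the slots of a [RepeatFamily-class].
#'
#' @param x a `GenomeSeq` or `RepeatFamily` object.
#' @return the corresponding slot value (see Details).
#' @name accessors
#' @examples
#' g <- GenomeSeq("toy", "ACGTACGT")
#' genomeId(g); genomeLength(g)
NULL

#' @rdname accessors
#' @export
setGeneric("genomeId", function(x) standardGeneric("genomeId"))
#' @rdname accessors
#' @export
setGeneric("genomeLength", function(x) standardGeneric("genomeLength"))
#' @rdname accessors
#' @export
setGeneric("genomeString", function(x) standardGeneric("genomeString"))
#' @rdname accessors
#' @export
setGeneric("isCircularGenome", function(x) standardGeneric("isCircularGenome"))
#' @rdname accessors
#' @export
setGeneric("familyId", function(x) standardGeneric("familyId"))
#' @rdname accessors
#' @export
setGeneric("familyLength", function(x) standardGeneric("familyLength"))
#' @rdname accessors
#' @export
setGeneric("representative", function(x) standardGeneric("representative"))
#' @rdname accessors
#' @export
setGeneric("repeatCopies", function(x) standardGeneric("repeatCopies"))
#' @rdname accessors
#' @export
setGeneric("copyCount", function(x) standardGeneric("copyCount"))
#' @rdname accessors
#' @export
setGeneric("isTandem", function(x) standardGeneric("isTandem"))

#' @rdname accessors
#' @export
setMethod("genomeId", "GenomeSeq", function(x) x@id)
#' @rdname accessors
#' @export
setMethod("genomeLength", "GenomeSeq", function(x) length(x@seq))
#' @rdname accessors
#' @export
setMethod("genomeString", "GenomeSeq", function(x) as.character(x@seq))
#' @rdname accessors
#' @export
setMethod("isCircularGenome", "GenomeSeq", function(x) x@circular)

#' @rdname accessors
#' @export
setMethod("familyId", "RepeatFamily", function(x) x@familyId)
#' @rdname accessors
#' @export
setMethod("familyLength", "RepeatFamily", function(x) length(x@representative))
#' @rdname accessors
#' @export
setMethod("representative", "RepeatFamily", function(x) x@representative)
#' @rdname accessors
#' @export
setMethod("repeatCopies", "RepeatFamily", function(x) x@copies)
#' @rdname accessors
#' @export
setMethod("copyCount", "RepeatFamily", function(x) length(x@copies))
#' @rdname accessors
#' @export
setMethod("isTandem", "RepeatFamily", function(x) x@tandem)
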