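#' Accessors for simulation and k-mer containers
#'
#' @param x a [PipSimulation-class] or [KmerProfile-class] object.
#' @return `genomeSeq` returns the simulated genome as a `DNAStringSet`;
#'   `trueSites` and `decoySites` return `GRanges`; `simParams` the
#'   generator parameter list; `kmerSize`, `kmerCounts` and `kmerTotal`
#'   the k, the named count vector and the total window count of a
#'   profile.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("genomeSeq", function(x) standardGeneric("genomeSeq"))

#' @rdname accessors
#' @export
setGeneric("trueSites", function(x) standardGeneric("trueSites"))

#' @rdname accessors
#' @export
setGeneric("decoySites", function(x) standardGeneric("decoySites"))

#' @rdname accessors
#' @export
setGeneric("simParams", function(x) standardGeneric("simParams"))

#' @rdname accessors
#' @export
setGeneric("kmerSize", function(x) standardGeneric("kmerSize"))

#' @rdname accessors
#' @export
setGeneric("kmerCounts", function(x) standardGeneric("kmerCounts"))

#' @rdname accessors
#' @export
setGeneric("kmerTotal", function(x) standardGeneric("kmerTotal"))

#' @rdname accessors
setMethod("genomeSeq", "PipSimulation", function(x) x@genome)

#' @rdname accessors
setMethod("trueSites", "PipSimulation", function(x) x@trueSites)

#' @rdname accessors
setMethod("decoySites", "PipSimulation", function(x) x@decoySites)

#' @rdname accessors
setMethod("simParams", "PipSimulation", function(x) x@params)

#' @rdname accessors
setMethod("kmerSize", "KmerProfile", function(x) x@k)

#' @rdname accessors
setMethod("kmerCounts", "KmerProfile", function(x) x@counts)

#' @rdname accessors
setMethod("kmerTotal", "KmerProfile", function(x) x@total)
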