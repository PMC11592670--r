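#' @title Accessor generics
#' @description Accessor generics for the S4 containers in this package.
#'   Each has methods documented with the corresponding class.
#' @param x an object
#' @param ... additional arguments for methods
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("clusters", function(x, ...) standardGeneric("clusters"))

#' @rdname accessors
#' @export
setGeneric("nClusters", function(x) standardGeneric("nClusters"))

#' @rdname accessors
#' @export
setGeneric("centroids", function(x, ...) standardGeneric("centroids"))

#' @rdname accessors
#' @export
setGeneric("clusterVolumes", function(x, ...)
    standardGeneric("clusterVolumes"))

#' @rdname accessors
#' @export
setGeneric("voxelDims", function(x) standardGeneric("voxelDims"))

#' @rdname accessors
#' @export
setGeneric("surfaceArea", function(x) standardGeneric("surfaceArea"))

#' @rdname accessors
#' @export
setGeneric("enclosedVolume", function(x) standardGeneric("enclosedVolume"))

#' @rdname accessors
#' @export
setGeneric("meshFaces", function(x) standardGeneric("meshFaces"))

#' @rdname accessors
#' @export
setGeneric("meshVertices", function(x) standardGeneric("meshVertices"))

#' @rdname accessors
#' @export
setGeneric("boundaryVertices", function(x) standardGeneric("boundaryVertices"))

#' @rdname accessors
#' @export
setGeneric("shapeAlpha", function(x) standardGeneric("shapeAlpha"))

#' @rdname accessors
#' @export
setGeneric("components", function(x, ...) standardGeneric("components"))

#' @rdname accessors
#' @export
setGeneric("nComponents", function(x) standardGeneric("nComponents"))

#' @rdname accessors
#' @export
setGeneric("mixtureWeights", function(x) standardGeneric("mixtureWeights"))

#' @rdname accessors
#' @export
setGeneric("exponent", function(x) standardGeneric("exponent"))

#' @rdname accessors
#' @export
setGeneric("classification", function(x) standardGeneric("classification"))

#' @rdname accessors
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))

#' @rdname accessors
#' @export
setGeneric("ryrCounts", function(x) standardGeneric("ryrCounts"))

#' @rdname accessors
#' @export
setGeneric("totalRyr", function(x) standardGeneric("totalRyr"))

#' @rdname accessors
#' @export
setGeneric("repulsionStep", function(x) standardGeneric("repulsionStep"))

#' @rdname accessors
#' @export
setGeneric("meanNnd", function(x) standardGeneric("meanNnd"))

#' @rdname accessors
#' @export
setGeneric("networkDomain", function(x) standardGeneric("networkDomain"))
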