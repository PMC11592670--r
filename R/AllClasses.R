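#' ClusterSet: a table of segmented RyR clusters
#'
#' Container for the per-cluster measurements extracted from a labeled
#' segmentation volume (or loaded from a CSV table): centroid coordinates in
#' physical nanometres, cluster volume in cubic micrometres, voxel count, and
#' the membership flags produced by the refinement pipeline
#' (\code{in_cell}, \code{peripheral}, \code{size_outlier},
#' \code{nnd_outlier}).
#'
#' Coordinates are voxel-centre positions on a 0-based grid scaled by the
#' voxel dimensions, so all downstream distances are Euclidean distances in
#' nanometres regardless of voxel anisotropy.
#'
#' @slot clusters data.frame with columns \code{id}, \code{x}, \code{y},
#'   \code{z} (nm), \code{volume} (um^3), \code{voxel_count}, and logical
#'   flag columns.
#' @slot voxelDims numeric(3), voxel edge lengths (dx, dy, dz) in nm, or NA
#'   when the table was not derived from a voxel grid.
#' @slot metadata list of provenance information (source file, generator
#'   spec, seed, ...).
#'
#' @examples
#' df <- data.frame(id = 1:3, x = c(0, 100, 500), y = 0, z = 0,
#'                  volume = c(0.1, 0.2, 0.15))
#' cs <- ClusterSet(df)
#' nClusters(cs)
#'
#' @aliases ClusterSet
#' @export ClusterSet
#' @exportClass ClusterSet
ClusterSet <- setClass("ClusterSet",
    slots = c(clusters = "data.frame",
              voxelDims = "numeric",
              metadata = "list"))

.FLAG_COLUMNS <- c("in_cell", "peripheral", "size_outlier", "nnd_outlier")

setValidity("ClusterSet", function(object) {
    df <- object@clusters
    need <- c("id", "x", "y", "z", "volume")
    miss <- setdiff(need, names(df))
    if (length(miss))
        return(paste("missing cluster columns:", paste(miss, collapse = ", ")))
    if (anyDuplicated(df$id)) return("cluster ids must be unique")
    if (nrow(df) > 0) {
        if (!all(is.finite(df$x) & is.finite(df$y) & is.finite(df$z)))
            return("centroids must be finite")
        if (!all(is.finite(df$volume) & df$volume > 0))
            return("volumes must be positive and finite")
    }
    if (!(length(object@voxelDims) == 3L))
        return("voxelDims must have length 3")
    TRUE
})

#' @rdname ClusterSet-class
#' @param data data.frame of per-cluster rows (columns id, x, y, z, volume;
#'   optionally voxel_count and flag columns).
#' @param voxelDims numeric(3) voxel dimensions in nm, or NA.
#' @param metadata list of provenance information.
#' @export
ClusterSet <- function(data, voxelDims = rep(NA_real_, 3), metadata = list()) {
    data <- as.data.frame(data)
    if (is.null(data$voxel_count)) data$voxel_count <- NA_integer_
    for (fl in .FLAG_COLUMNS) if (is.null(data[[fl]])) data[[fl]] <- FALSE
    new("ClusterSet", clusters = data, voxelDims = as.numeric(voxelDims),
        metadata = metadata)
}

#' @rdname accessors
#' @export
setMethod("clusters", "ClusterSet", function(x, ...) x@clusters)

#' @rdname accessors
#' @export
setMethod("nClusters", "ClusterSet", function(x) nrow(x@clusters))

#' @rdname accessors
#' @export
setMethod("centroids", "ClusterSet", function(x, ...) {
    m <- as.matrix(x@clusters[, c("x", "y", "z")])
    rownames(m) <- x@clusters$id
    m
})

#' @rdname accessors
#' @export
setMethod("clusterVolumes", "ClusterSet", function(x, ...) x@clusters$volume)

#' @rdname accessors
#' @export
setMethod("voxelDims", "ClusterSet", function(x) x@voxelDims)

setMethod("show", "ClusterSet", function(object) {
    df <- object@clusters
    cat("ClusterSet with", nrow(df), "clusters\n")
    if (!all(is.na(object@voxelDims)))
        cat("  voxel dims (nm):", paste(object@voxelDims, collapse = " x "),
            "\n")
    if (nrow(df)) {
        cat("  in_cell:", sum(df$in_cell), " peripheral:",
            sum(df$peripheral), " size_outlier:", sum(df$size_outlier),
            " nnd_outlier:", sum(df$nnd_outlier), "\n")
        cat("  volume (um^3): mean", signif(mean(df$volume), 4), "sd",
            signif(stats::sd(df$volume), 4), "\n")
    }
})

#' CellGeometry: an alpha-shape surface of the peripheral cluster network
#'
#' Triangulated boundary surface of a cell's cluster point cloud, produced by
#' [alphaShape()] or [optimizeAlpha()]. Vertices are in nanometres; the
#' surface area is reported in square micrometres and the enclosed volume in
#' cubic micrometres.
#'
#' @slot vertices numeric matrix (n x 3), all input points in nm.
#' @slot faces integer matrix (m x 3) of vertex indices forming boundary
#'   triangles.
#' @slot alpha the alpha parameter (nm) of the selected shape.
#' @slot surfaceArea surface area in um^2.
#' @slot volume enclosed volume in um^3.
#' @slot boundaryVertices integer indices of vertices lying on the boundary
#'   surface.
#' @slot metadata list (e.g. the alpha sweep table).
#'
#' @aliases CellGeometry
#' @export CellGeometry
#' @exportClass CellGeometry
CellGeometry <- setClass("CellGeometry",
    slots = c(vertices = "matrix", faces = "matrix", alpha = "numeric",
              surfaceArea = "numeric", volume = "numeric",
              boundaryVertices = "integer", metadata = "list"))

setValidity("CellGeometry", function(object) {
    if (ncol(object@vertices) != 3) return("vertices must be n x 3")
    if (nrow(object@faces) > 0) {
        if (ncol(object@faces) != 3) return("faces must be m x 3")
        if (max(object@faces) > nrow(object@vertices) || min(object@faces) < 1)
            return("faces reference invalid vertices")
    }
    if (!is.finite(object@surfaceArea) || object@surfaceArea <= 0)
        return("surfaceArea must be positive and finite")
    if (!is.finite(object@volume) || object@volume <= 0)
        return("volume must be positive and finite")
    TRUE
})

#' @rdname accessors
#' @export
setMethod("surfaceArea", "CellGeometry", function(x) x@surfaceArea)

#' @rdname accessors
#' @export
setMethod("enclosedVolume", "CellGeometry", function(x) x@volume)

#' @rdname accessors
#' @export
setMethod("meshFaces", "CellGeometry", function(x) x@faces)

#' @rdname accessors
#' @export
setMethod("meshVertices", "CellGeometry", function(x) x@vertices)

#' @rdname accessors
#' @export
setMethod("boundaryVertices", "CellGeometry", function(x) x@boundaryVertices)

#' @rdname accessors
#' @export
setMethod("shapeAlpha", "CellGeometry", function(x) x@alpha)

setMethod("show", "CellGeometry", function(object) {
    cat("CellGeometry (alpha shape)\n")
    cat("  alpha:", signif(object@alpha, 5), "nm\n")
    cat("  ", nrow(object@vertices), "vertices,", nrow(object@faces),
        "boundary faces,", length(object@boundaryVertices),
        "boundary vertices\n")
    cat("  surface area:", signif(object@surfaceArea, 5), "um^2",
        " enclosed volume:", signif(object@volume, 5), "um^3\n")
})

#' GammaMixtureFit: a fitted Gamma mixture model of cluster sizes
#'
#' Result of [fitGammaMixture()] / [selectComponents()]. Components are
#' stored in increasing order of their means; each has a shape
#' \eqn{\alpha > 0}, a rate \eqn{\beta > 0} (so the component mean is
#' \eqn{\alpha/\beta}) and a mixing weight. Weights sum to one.
#'
#' @slot components data.frame with columns \code{shape}, \code{rate},
#'   \code{weight}, one row per component, ordered by increasing mean.
#' @slot logLik maximized log-likelihood.
#' @slot bic Bayesian Information Criterion, \eqn{k \ln n - 2 \log L} with
#'   \eqn{k = 3m - 1} free parameters for \eqn{m} components.
#' @slot nObs number of observations used in the fit.
#' @slot converged logical, optimizer convergence status.
#' @slot metadata list (initial values, optimizer diagnostics).
#'
#' @aliases GammaMixtureFit
#' @export GammaMixtureFit
#' @exportClass GammaMixtureFit
GammaMixtureFit <- setClass("GammaMixtureFit",
    slots = c(components = "data.frame", logLik = "numeric", bic = "numeric",
              nObs = "integer", converged = "logical", metadata = "list"))

setValidity("GammaMixtureFit", function(object) {
    cmp <- object@components
    if (!all(c("shape", "rate", "weight") %in% names(cmp)))
        return("components needs shape, rate, weight columns")
    if (any(cmp$shape <= 0) || any(cmp$rate <= 0))
        return("shapes and rates must be positive")
    if (abs(sum(cmp$weight) - 1) > 1e-8)
        return("mixture weights must sum to 1")
    if (any(cmp$weight < -1e-12 | cmp$weight > 1 + 1e-12))
        return("weights must lie in [0, 1]")
    if (!is.finite(object@bic)) return("BIC must be finite")
    TRUE
})

#' @rdname accessors
#' @export
setMethod("components", "GammaMixtureFit", function(x, ...) x@components)

#' @rdname accessors
#' @export
setMethod("nComponents", "GammaMixtureFit", function(x) nrow(x@components))

#' @rdname accessors
#' @export
setMethod("mixtureWeights", "GammaMixtureFit",
          function(x) x@components$weight)

#' @importFrom stats logLik
#' @export
setMethod("logLik", "GammaMixtureFit", function(object, ...) object@logLik)

#' @rdname accessors
#' @param object a GammaMixtureFit
#' @export
setGeneric("mixtureBIC", function(object) standardGeneric("mixtureBIC"))

#' @rdname accessors
#' @export
setMethod("mixtureBIC", "GammaMixtureFit", function(object) object@bic)

setMethod("show", "GammaMixtureFit", function(object) {
    cmp <- object@components
    cat("GammaMixtureFit with", nrow(cmp), "component(s), n =",
        object@nObs, "\n")
    for (i in seq_len(nrow(cmp))) {
        cat(sprintf(
            "  [%d] shape %.4g  rate %.4g  weight %.3f  (mean %.4g um^3)\n",
            i, cmp$shape[i], cmp$rate[i], cmp$weight[i],
            cmp$shape[i] / cmp$rate[i]))
    }
    cat("  logLik:", signif(object@logLik, 8), "  BIC:",
        signif(object@bic, 8), "  converged:", object@converged, "\n")
})

#' PowerLawFit: power-law fit to the ascending NND histogram
#'
#' Result of [fitPowerLaw()]: the exponent \eqn{b} of \eqn{p(x) = A x^b}
#' fitted by ordinary least squares on the log-log histogram of
#' nearest-neighbor distances, restricted to the ascending left tail below
#' half of the peak bin. \eqn{b \approx 1} is the signature of a random
#' (Poisson) point pattern on a surface, \eqn{b > 1} of repulsion between
#' clusters, and \eqn{b < 1} of clustering.
#'
#' @slot exponent fitted exponent b.
#' @slot logIntercept fitted log(A) (on the density scale).
#' @slot rSquared coefficient of determination of the log-log fit.
#' @slot fitBins integer indices of the histogram bins used.
#' @slot classification one of "clustering", "poisson", "repulsion".
#' @slot histogram list describing the histogram (edges, counts, centers,
#'   peak index, n).
#'
#' @aliases PowerLawFit
#' @export PowerLawFit
#' @exportClass PowerLawFit
PowerLawFit <- setClass("PowerLawFit",
    slots = c(exponent = "numeric", logIntercept = "numeric",
              rSquared = "numeric", fitBins = "integer",
              classification = "character", histogram = "list"))

setValidity("PowerLawFit", function(object) {
    if (!length(object@fitBins)) return("fitBins must be non-empty")
    if (!is.finite(object@exponent)) return("exponent must be finite")
    if (!object@classification %in% c("clustering", "poisson", "repulsion"))
        return("unknown classification")
    TRUE
})

#' @rdname accessors
#' @export
setMethod("exponent", "PowerLawFit", function(x) x@exponent)

#' @rdname accessors
#' @export
setMethod("classification", "PowerLawFit", function(x) x@classification)

setMethod("show", "PowerLawFit", function(object) {
    cat("PowerLawFit: b =", signif(object@exponent, 4),
        " (", object@classification, ")\n", sep = "")
    cat("  log(A):", signif(object@logIntercept, 4), "  R^2:",
        signif(object@rSquared, 4), "  bins used:",
        paste(range(object@fitBins), collapse = "-"), "\n")
})

#' CRUNetwork: a generated calcium-release-unit network
#'
#' A CRU network produced by [generateNetwork()]: positions on a (periodic)
#' rectangular domain, per-CRU RyR counts summing exactly to the total RyR
#' budget, and the repulsion step (0 = uniform random, 100 = crystal-like)
#' at which the positions were taken.
#'
#' @slot positions numeric matrix (n x 2) of CRU positions in nm.
#' @slot ryrCounts integer vector, RyRs per CRU (>= 1).
#' @slot step repulsion step in 0..100.
#' @slot domain list(width, height, periodic) in nm.
#' @slot totalRyr total number of RyRs (exact sum of ryrCounts).
#' @slot meanNnd mean nearest-neighbor distance (nm) of the positions.
#' @slot seed integer seed used for generation.
#' @slot metadata list of generation parameters.
#'
#' @aliases CRUNetwork
#' @export CRUNetwork
#' @exportClass CRUNetwork
CRUNetwork <- setClass("CRUNetwork",
    slots = c(positions = "matrix", ryrCounts = "integer", step = "integer",
              domain = "list", totalRyr = "integer", meanNnd = "numeric",
              seed = "integer", metadata = "list"))

setValidity("CRUNetwork", function(object) {
    n <- nrow(object@positions)
    if (length(object@ryrCounts) != n)
        return("one RyR count per CRU required")
    if (any(object@ryrCounts < 1L)) return("RyR counts must be >= 1")
    if (sum(object@ryrCounts) != object@totalRyr)
        return("ryrCounts must sum exactly to totalRyr")
    if (object@step < 0L || object@step > 100L)
        return("step must lie in [0, 100]")
    d <- object@domain
    if (!all(c("width", "height") %in% names(d)))
        return("domain needs width and height")
    p <- object@positions
    if (n && (any(p[, 1] < 0 | p[, 1] > d$width) ||
              any(p[, 2] < 0 | p[, 2] > d$height)))
        return("positions must lie within the domain")
    TRUE
})

#' @rdname accessors
#' @export
setMethod("positions", "CRUNetwork", function(x) x@positions)

#' @rdname accessors
#' @export
setMethod("ryrCounts", "CRUNetwork", function(x) x@ryrCounts)

#' @rdname accessors
#' @export
setMethod("totalRyr", "CRUNetwork", function(x) x@totalRyr)

#' @rdname accessors
#' @export
setMethod("repulsionStep", "CRUNetwork", function(x) x@step)

#' @rdname accessors
#' @export
setMethod("meanNnd", "CRUNetwork", function(x) x@meanNnd)

#' @rdname accessors
#' @export
setMethod("networkDomain", "CRUNetwork", function(x) x@domain)

setMethod("show", "CRUNetwork", function(object) {
    cat("CRUNetwork:", nrow(object@positions), "CRUs, step",
        object@step, "/100\n")
    cat("  domain:", signif(object@domain$width / 1000, 4), "x",
        signif(object@domain$height / 1000, 4), "um",
        if (isTRUE(object@domain$periodic)) "(periodic)" else "", "\n")
    cat("  total RyR:", object@totalRyr, "  mean RyR/CRU:",
        signif(mean(object@ryrCounts), 4), "\n")
    cat("  mean NND:", signif(object@meanNnd, 5), "nm\n")
})

#' CellAnalysis: full refinement and statistics for one cell
#'
#' Bundle returned by [analyzeCell()]: the refined [ClusterSet-class] (with
#' membership flags filled in), the optimized alpha-shape
#' [CellGeometry-class], the nearest-neighbor distances of the retained
#' clusters, the Gamma mixture fit of cluster sizes, the power-law fit of
#' the NND histogram, and a one-row summary table.
#'
#' @slot clusterSet refined ClusterSet.
#' @slot geometry CellGeometry (or NULL when the cell was degenerate).
#' @slot nnd numeric, nearest-neighbor distances (nm) of retained clusters,
#'   before Tukey filtering.
#' @slot sizeFit GammaMixtureFit (or NULL).
#' @slot nndFit PowerLawFit (or NULL).
#' @slot summary one-row data.frame of per-cell statistics.
#' @slot params list of pipeline parameters (epsilon, minPts, ...).
#'
#' @aliases CellAnalysis
#' @export CellAnalysis
#' @exportClass CellAnalysis
CellAnalysis <- setClass("CellAnalysis",
    slots = c(clusterSet = "ClusterSet", geometry = "ANY", nnd = "numeric",
              sizeFit = "ANY", nndFit = "ANY", summary = "data.frame",
              params = "list"))

setMethod("show", "CellAnalysis", function(object) {
    cat("CellAnalysis\n")
    s <- object@summary
    cat("  clusters retained:", s$n_clusters, "\n")
    cat("  surface area:", signif(s$surface_area, 5), "um^2",
        " volume:", signif(s$volume, 5), "um^3\n")
    cat("  NND (nm): mean", signif(s$nnd_mean, 5), "sd",
        signif(s$nnd_sd, 5), "\n")
    cat("  size (um^3): mean", signif(s$size_mean, 4), "sd",
        signif(s$size_sd, 4), "\n")
    cat("  repulsion exponent b:", signif(s$b, 4), "\n")
    if (!is.na(s$alpha1))
        cat(sprintf(
            "  mixture: a1 %.3g b1 %.3g a2 %.3g b2 %.3g pi %.3g\n",
            s$alpha1, s$beta1, s$alpha2, s$beta2, s$pi))
})
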