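#' Full peripheral-network refinement and statistics for one cell
#'
#' Runs the complete refinement pipeline on a cluster table, in order:
#' \enumerate{
#'   \item nearest-neighbor distances of all centroids;
#'   \item DBSCAN radius \eqn{\epsilon = \mathrm{median} + 3 c\,\mathrm{MAD}}
#'     of those distances, min_samples = 3;
#'   \item DBSCAN; the largest density cluster is the cell, the rest is
#'     segmentation noise;
#'   \item optimized alpha shape of the cell's centroids; its boundary
#'     vertices are the peripheral clusters;
#'   \item nearest-neighbor distances recomputed on the retained clusters;
#'   \item Tukey's fences (k = 3) applied separately to the size list and
#'     the NND list;
#'   \item Gamma mixture fit of the filtered sizes and power-law fit of the
#'     filtered NND histogram.
#' }
#'
#' @param cs a [ClusterSet-class].
#' @param peripheralOnly logical; when TRUE the NND statistics are computed
#'   on the peripheral (alpha-shape boundary) clusters only, instead of all
#'   in-cell clusters (the default).
#' @param nBins bins for the NND histogram (default 50).
#' @param mixtureComponents candidate component counts for the size
#'   mixture, selected by BIC (default 1:2); a single value skips the BIC
#'   comparison.
#' @param fenceK Tukey fence multiplier (default 3).
#' @param seed passed to the mixture fit restarts.
#' @return a [CellAnalysis-class].
#' @export
analyzeCell <- function(cs, peripheralOnly = FALSE, nBins = 50L,
                        mixtureComponents = 1:2, fenceK = 3.0, seed = 1L) {
    stopifnot(is(cs, "ClusterSet"))
    pts <- centroids(cs)
    nndAll <- nearestNeighborDistances(pts)
    params <- dbscanEpsilon(nndAll)
    cs <- extractCell(cs, params)
    df <- clusters(cs)
    inCell <- which(df$in_cell)
    if (length(inCell) < 4)
        stop("analyzeCell: fewer than 4 in-cell clusters")

    geom <- optimizeAlpha(pts[inCell, , drop = FALSE])
    df$peripheral <- FALSE
    df$peripheral[inCell[boundaryVertices(geom)]] <- TRUE

    retained <- if (peripheralOnly) which(df$peripheral) else inCell
    if (length(retained) < 4) {
        warning("analyzeCell: empty or tiny retained set; ",
                "statistics are NaN")
        summary <- .cellSummaryRow(geom, integer(0), numeric(0),
                                   numeric(0), NULL, NULL)
        return(new("CellAnalysis", clusterSet = initialize(cs,
                       clusters = df),
                   geometry = geom, nnd = numeric(0), sizeFit = NULL,
                   nndFit = NULL, summary = summary,
                   params = c(params, list(peripheralOnly = peripheralOnly))))
    }
    nnd <- nearestNeighborDistances(pts[retained, , drop = FALSE])
    sizes <- df$volume[retained]

    tkSize <- tukeyFilter(sizes, k = fenceK)
    tkNnd <- tukeyFilter(nnd, k = fenceK)
    df$size_outlier[retained] <- !tkSize$mask
    df$nnd_outlier[retained] <- !tkNnd$mask

    sizeFit <- tryCatch({
        if (length(mixtureComponents) > 1L)
            selectComponents(tkSize$values,
                             candidates = mixtureComponents, seed = seed)
        else fitGammaMixture(tkSize$values,
                             nComponents = mixtureComponents, seed = seed)
    }, error = function(e) {
        warning("size mixture fit failed: ", conditionMessage(e))
        NULL
    })
    nndFit <- tryCatch({
        d <- tkNnd$values
        d <- d[d > 0]  # zero distances have no log
        fitPowerLaw(nndHistogram(d, nBins = nBins))
    }, error = function(e) {
        warning("power-law fit failed: ", conditionMessage(e))
        NULL
    })

    summary <- .cellSummaryRow(geom, retained, tkNnd$values,
                               tkSize$values, sizeFit, nndFit)
    new("CellAnalysis", clusterSet = initialize(cs, clusters = df),
        geometry = geom, nnd = nnd, sizeFit = sizeFit, nndFit = nndFit,
        summary = summary,
        params = c(params, list(peripheralOnly = peripheralOnly,
                                nBins = nBins, fenceK = fenceK)))
}

# 13-field per-cell summary mirroring the per-cell result tables:
# geometry, counts, NND and size statistics, repulsion exponent, and the
# two-component mixture parameters.
.cellSummaryRow <- function(geom, retained, nndKept, sizeKept, sizeFit,
                            nndFit) {
    mix <- rep(NA_real_, 5)
    if (!is.null(sizeFit) && nComponents(sizeFit) == 2L) {
        cmp <- components(sizeFit)
        mix <- c(cmp$shape[1], cmp$rate[1], cmp$shape[2], cmp$rate[2],
                 cmp$weight[1])
    }
    data.frame(
        surface_area = if (is.null(geom)) NaN else surfaceArea(geom),
        volume = if (is.null(geom)) NaN else enclosedVolume(geom),
        n_clusters = length(retained),
        nnd_mean = if (length(nndKept)) mean(nndKept) else NaN,
        nnd_sd = if (length(nndKept) > 1) stats::sd(nndKept) else NaN,
        size_mean = if (length(sizeKept)) mean(sizeKept) else NaN,
        size_sd = if (length(sizeKept) > 1) stats::sd(sizeKept) else NaN,
        b = if (is.null(nndFit)) NaN else exponent(nndFit),
        alpha1 = mix[1], beta1 = mix[2], alpha2 = mix[3], beta2 = mix[4],
        pi = mix[5])
}
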