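# Reading labeled segmentation volumes and cluster tables; writing the
# result artifacts (tables, meshes, network descriptors).

#' Read a labeled segmentation volume into a cluster table
#'
#' Reads a multi-page TIFF stack of integer labels (0 = background, k > 0 =
#' cluster id) and summarizes each label into one cluster row: centroid as
#' the unweighted mean of its voxel centers in physical nanometres, and
#' volume as voxel count x voxel volume in cubic micrometres.
#'
#' Coordinates are voxel-center positions on a 0-based grid: x runs along
#' image columns, y along rows, z along pages, each scaled by the
#' corresponding voxel dimension. The default voxel geometry is the SIM
#' acquisition grid (55.5 x 55.5 nm laterally, 150 nm axially).
#'
#' @param path TIFF file path.
#' @param voxelDims numeric(3), voxel edge lengths (dx, dy, dz) in nm.
#' @return a [ClusterSet-class].
#' @export
readLabelVolume <- function(path, voxelDims = c(55.5, 55.5, 150)) {
    stopifnot(length(voxelDims) == 3, all(voxelDims > 0))
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    arr <- simplify2array(pages)            # row (y), col (x), page (z)
    if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
    if (length(dim(arr)) != 3L)
        stop("expected a single-channel labeled stack")
    if (!all(.isWholeNumber(arr)))
        stop("label image must have integer pixel values")
    idx <- which(arr != 0, arr.ind = TRUE)
    if (nrow(idx) == 0)
        stop("no nonzero labels in ", path)
    lab <- as.integer(round(arr[idx]))
    f <- factor(lab)
    cnt <- as.integer(table(f))
    cx <- as.numeric(tapply((idx[, 2] - 1) * voxelDims[1], f, mean))
    cy <- as.numeric(tapply((idx[, 1] - 1) * voxelDims[2], f, mean))
    cz <- as.numeric(tapply((idx[, 3] - 1) * voxelDims[3], f, mean))
    voxVol <- prod(voxelDims) * 1e-9        # nm^3 -> um^3
    df <- data.frame(id = as.integer(levels(f)), x = cx, y = cy, z = cz,
                     volume = cnt * voxVol, voxel_count = cnt)
    ClusterSet(df[order(df$id), ], voxelDims = voxelDims,
               metadata = list(source = path))
}

#' Read / write a cluster table CSV
#'
#' The CSV interchange format: comma-separated, header row, "." decimal;
#' columns \code{id}, \code{x}, \code{y}, \code{z} (nm), \code{volume}
#' (um^3), optionally \code{voxel_count} and the flag columns. Reading
#' initializes absent flags to FALSE.
#'
#' @param path CSV file path.
#' @return \code{readClusterTable}: a [ClusterSet-class].
#' @export
readClusterTable <- function(path) {
    df <- utils::read.csv(path)
    need <- c("id", "x", "y", "z", "volume")
    miss <- setdiff(need, names(df))
    if (length(miss))
        stop("cluster table is missing column(s): ",
             paste(miss, collapse = ", "))
    num <- df[, c("x", "y", "z", "volume")]
    if (anyNA(num) || !all(vapply(num, function(v)
        all(is.finite(v)), logical(1))))
        stop("cluster table contains non-finite values")
    ClusterSet(df, metadata = list(source = path))
}

#' @rdname readClusterTable
#' @param cs a [ClusterSet-class].
#' @return \code{writeClusterTable}: the path, invisibly.
#' @export
writeClusterTable <- function(cs, path) {
    stopifnot(is(cs, "ClusterSet"))
    utils::write.csv(clusters(cs), path, row.names = FALSE)
    invisible(path)
}

#' Read / write a triangle mesh as Wavefront OBJ
#'
#' Minimal OBJ support for the alpha-shape surface: \code{v} lines for
#' vertices (nm) and \code{f} lines for triangular faces.
#'
#' @param geom a [CellGeometry-class].
#' @param path OBJ file path.
#' @return \code{writeMeshOBJ}: the path, invisibly;
#'   \code{readMeshOBJ}: list with \code{vertices} and \code{faces}.
#' @export
writeMeshOBJ <- function(geom, path) {
    stopifnot(is(geom, "CellGeometry"))
    v <- meshVertices(geom)
    f <- meshFaces(geom)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
        sprintf("v %.6f %.6f %.6f", v[, 1], v[, 2], v[, 3]),
        sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3])), con)
    invisible(path)
}

#' @rdname writeMeshOBJ
#' @export
readMeshOBJ <- function(path) {
    ln <- readLines(path)
    vl <- ln[startsWith(ln, "v ")]
    fl <- ln[startsWith(ln, "f ")]
    parse3 <- function(lines, what) {
        m <- do.call(rbind, lapply(strsplit(lines, "\\s+"), function(p)
            as.numeric(p[2:4])))
        if (what == "f") storage.mode(m) <- "integer"
        m
    }
    list(vertices = parse3(vl, "v"), faces = parse3(fl, "f"))
}

#' Read / write a CRU network as JSON
#'
#' JSON descriptor consumed by downstream pacemaker-cell simulators:
#' positions (nm), per-CRU RyR counts, repulsion step, domain, total RyR
#' count, mean NND and seed.
#'
#' @param net a [CRUNetwork-class].
#' @param path JSON file path.
#' @return \code{writeNetworkJSON}: the path, invisibly;
#'   \code{readNetworkJSON}: a [CRUNetwork-class].
#' @export
writeNetworkJSON <- function(net, path) {
    stopifnot(is(net, "CRUNetwork"))
    p <- positions(net)
    jsonlite::write_json(list(
        positions = data.frame(x = p[, 1], y = p[, 2]),
        ryr_counts = ryrCounts(net),
        step = repulsionStep(net),
        domain = networkDomain(net),
        total_ryr = totalRyr(net),
        mean_nnd = meanNnd(net),
        seed = net@seed), path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writeNetworkJSON
#' @export
readNetworkJSON <- function(path) {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    new("CRUNetwork",
        positions = cbind(j$positions$x, j$positions$y),
        ryrCounts = as.integer(j$ryr_counts),
        step = as.integer(j$step),
        domain = list(width = j$domain$width, height = j$domain$height,
                      periodic = isTRUE(j$domain$periodic)),
        totalRyr = as.integer(j$total_ryr),
        meanNnd = as.numeric(j$mean_nnd),
        seed = as.integer(j$seed),
        metadata = list(source = path))
}

#' Write all result artifacts of a cell analysis
#'
#' Writes, into \code{outDir}: the refined cluster table
#' (\code{<prefix>_clusters.csv}, with membership flags), the one-row
#' per-cell summary (\code{<prefix>_summary.csv}: surface area, volume,
#' cluster count, NND mean/SD, size mean/SD, repulsion exponent b and the
#' mixture parameters), the NND list (\code{<prefix>_nnd.csv}), and the
#' alpha-shape mesh (\code{<prefix>_mesh.obj}).
#'
#' @param analysis a [CellAnalysis-class].
#' @param outDir output directory (created if needed).
#' @param prefix file-name prefix (default "cell").
#' @return named character vector of the written paths, invisibly.
#' @export
writeResults <- function(analysis, outDir, prefix = "cell") {
    stopifnot(is(analysis, "CellAnalysis"))
    if (!dir.exists(outDir) &&
        !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
        stop("cannot create output directory ", outDir)
    paths <- c(
        clusters = file.path(outDir, paste0(prefix, "_clusters.csv")),
        summary = file.path(outDir, paste0(prefix, "_summary.csv")),
        nnd = file.path(outDir, paste0(prefix, "_nnd.csv")),
        mesh = file.path(outDir, paste0(prefix, "_mesh.obj")))
    writeClusterTable(analysis@clusterSet, paths[["clusters"]])
    utils::write.csv(analysis@summary, paths[["summary"]],
                     row.names = FALSE)
    utils::write.csv(data.frame(nnd = analysis@nnd), paths[["nnd"]],
                     row.names = FALSE)
    if (!is.null(analysis@geometry)) {
        writeMeshOBJ(analysis@geometry, paths[["mesh"]])
    } else {
        paths <- paths[names(paths) != "mesh"]
    }
    invisible(paths)
}
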