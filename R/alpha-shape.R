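#' Delaunay tetrahedralization of a 3D point set
#'
#' Incremental (Bowyer-Watson) Delaunay tetrahedralization. Ties between
#' cospherical points are broken by a deterministic, vanishingly small
#' symbolic jitter (1e-7 of the point-cloud extent), so the result is
#' reproducible and exact for all practical purposes at nanometre scale.
#'
#' @param points numeric matrix (n x 3), n >= 4, distinct rows, not all
#'   coplanar.
#' @return integer matrix (m x 4) of point indices, one tetrahedron per row.
#' @export
delaunay3d <- function(points) {
    points <- .asPointMatrix(points)
    n <- nrow(points)
    if (n < 4) stop("need at least 4 points")
    if (anyDuplicated(points))
        stop("duplicate points are not allowed in the triangulation")
    ctr <- colMeans(points)
    x <- sweep(points, 2, ctr)
    sv <- svd(x, nu = 0, nv = 0)$d
    if (sv[3] < 1e-9 * sv[1])
        stop("degenerate input: points are (nearly) coplanar or collinear")
    sc <- max(apply(points, 2, function(v) diff(range(v))))
    x <- x / sc
    .withSeed(20260921L, {
        x <- x + matrix(stats::runif(3 * n, -5e-8, 5e-8), n, 3)
        ord <- sample.int(n)
        .delaunay3d_cpp(x, ord)
    })
}

# Circumradius of each tetrahedron, vectorized (Cramer's rule on
# u.y = |u|^2/2 etc. with u, v, w the edge vectors from the first vertex).
.tetCircumradii <- function(points, tets) {
    a <- points[tets[, 1], , drop = FALSE]
    u <- points[tets[, 2], , drop = FALSE] - a
    v <- points[tets[, 3], , drop = FALSE] - a
    w <- points[tets[, 4], , drop = FALSE] - a
    ru <- rowSums(u^2) / 2
    rv <- rowSums(v^2) / 2
    rw <- rowSums(w^2) / 2
    cx <- v[, 2] * w[, 3] - v[, 3] * w[, 2]
    cy <- v[, 3] * w[, 1] - v[, 1] * w[, 3]
    cz <- v[, 1] * w[, 2] - v[, 2] * w[, 1]
    det <- u[, 1] * cx + u[, 2] * cy + u[, 3] * cz
    # columns of the adjugate, built from cross products
    c2x <- w[, 2] * u[, 3] - w[, 3] * u[, 2]
    c2y <- w[, 3] * u[, 1] - w[, 1] * u[, 3]
    c2z <- w[, 1] * u[, 2] - w[, 2] * u[, 1]
    c3x <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
    c3y <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
    c3z <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
    y1 <- (ru * cx + rv * c2x + rw * c3x) / det
    y2 <- (ru * cy + rv * c2y + rw * c3y) / det
    y3 <- (ru * cz + rv * c2z + rw * c3z) / det
    r <- sqrt(y1^2 + y2^2 + y3^2)
    r[!is.finite(r)] <- Inf  # degenerate slivers: never kept at finite alpha
    r
}

.tetVolumes <- function(points, tets) {
    a <- points[tets[, 1], , drop = FALSE]
    u <- points[tets[, 2], , drop = FALSE] - a
    v <- points[tets[, 3], , drop = FALSE] - a
    w <- points[tets[, 4], , drop = FALSE] - a
    abs(u[, 1] * (v[, 2] * w[, 3] - v[, 3] * w[, 2]) -
        u[, 2] * (v[, 1] * w[, 3] - v[, 3] * w[, 1]) +
        u[, 3] * (v[, 1] * w[, 2] - v[, 2] * w[, 1])) / 6
}

# Circumradii with degenerate (flat, formally infinite-radius) tetrahedra
# mapped to the largest finite radius: such tets carry no volume but are
# needed for connectivity of exactly-degenerate (e.g. lattice) inputs, and
# enter the complex at the convex-hull limit.
.boundedRadii <- function(points, tets) {
    r <- .tetCircumradii(points, tets)
    fin <- is.finite(r)
    if (!all(fin)) r[!fin] <- max(r[fin])
    r
}

.triangleAreas <- function(points, faces) {
    a <- points[faces[, 1], , drop = FALSE]
    u <- points[faces[, 2], , drop = FALSE] - a
    v <- points[faces[, 3], , drop = FALSE] - a
    cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
    cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
    cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
    sqrt(cx^2 + cy^2 + cz^2) / 2
}

# Properties of the alpha complex at a given alpha: boundary faces, surface
# area (nm^2), enclosed volume (nm^3), face-connected component count of the
# kept tetrahedra, and whether every input point is covered by a kept tet.
# what = "full" computes everything; "surface" skips the connectivity pass
# (used by the density sweep); "connectivity" skips the surface measures
# (used by the alpha lower-bound search).
.alphaComplex <- function(points, tets, radii, alpha, what = "full") {
    keep <- which(radii <= alpha)
    if (!length(keep))
        return(list(empty = TRUE))
    kt <- tets[keep, , drop = FALSE]
    f <- rbind(kt[, c(2, 3, 4)], kt[, c(1, 3, 4)],
               kt[, c(1, 2, 4)], kt[, c(1, 2, 3)])
    lo <- pmin(f[, 1], f[, 2], f[, 3])
    hi <- pmax(f[, 1], f[, 2], f[, 3])
    mid <- f[, 1] + f[, 2] + f[, 3] - lo - hi
    K <- nrow(points) + 1
    key <- (lo * K + mid) * K + hi
    grp <- match(key, key)           # first occurrence index per face
    cnt <- tabulate(grp, nbins = length(key))
    mult <- cnt[grp]
    out <- list(empty = FALSE)
    if (what != "connectivity") {
        boundary <- f[mult == 1L, , drop = FALSE]
        out$boundaryFaces <- boundary
        out$boundaryVertices <- sort(unique(as.vector(boundary)))
        out$area <- sum(.triangleAreas(points, boundary))
        out$volume <- sum(.tetVolumes(points, kt))
    }
    if (what != "surface") {
        # connectivity of kept tets through shared (multiplicity 2) faces:
        # union-find over the tet pairs adjacent at each interior face
        m <- length(keep)
        tetOf <- rep.int(seq_len(m), 4)  # face row -> kept-tet index
        rows2 <- which(mult == 2L)
        rows2 <- rows2[order(grp[rows2])]  # the two rows of a face adjoin
        a <- tetOf[rows2[c(TRUE, FALSE)]]
        b <- tetOf[rows2[c(FALSE, TRUE)]]
        parent <- seq_len(m)
        findRoot <- function(i) {
            while (parent[i] != i) {
                parent[i] <<- parent[parent[i]]
                i <- parent[i]
            }
            i
        }
        for (e in seq_along(a)) {
            r1 <- findRoot(a[e])
            r2 <- findRoot(b[e])
            if (r1 != r2) parent[r1] <- r2
        }
        out$nComponents <- length(unique(vapply(seq_len(m), findRoot,
                                                integer(1))))
        out$covered <- length(unique(as.vector(kt))) == nrow(points)
    }
    out
}

#' Alpha shape of a 3D point cloud
#'
#' The alpha complex of the Delaunay tetrahedralization: tetrahedra with
#' circumradius at most \code{alpha} are kept; the boundary surface is the
#' set of triangles belonging to exactly one kept tetrahedron. For
#' \code{alpha = Inf} the shape is the convex hull.
#'
#' @param points numeric matrix (n x 3) in nm.
#' @param alpha alpha radius in nm (Inf for the convex hull).
#' @param tets optional precomputed tetrahedralization from [delaunay3d()].
#' @return a [CellGeometry-class].
#' @export
alphaShape <- function(points, alpha, tets = NULL) {
    points <- .asPointMatrix(points)
    if (is.null(tets)) tets <- delaunay3d(points)
    radii <- .boundedRadii(points, tets)
    st <- .alphaComplex(points, tets, radii, alpha)
    if (st$empty) stop("alpha too small: empty alpha complex")
    new("CellGeometry", vertices = points,
        faces = st$boundaryFaces, alpha = alpha,
        surfaceArea = st$area * 1e-6, volume = st$volume * 1e-9,
        boundaryVertices = as.integer(st$boundaryVertices),
        metadata = list(nComponents = st$nComponents, covered = st$covered))
}

#' Optimized alpha shape of the cell's cluster network
#'
#' Sweeps a geometric grid of alpha values between the smallest alpha
#' producing a single connected shape that covers every point and the
#' convex-hull limit, and selects the alpha maximizing the density of
#' points on the shape's surface (boundary vertices per unit surface area).
#' This tight bounding surface captures the peripheral clusters of the
#' cell; its vertices define the \code{peripheral} flag downstream.
#'
#' @param points numeric matrix (n x 3) of cluster centroids in nm
#'   (n >= 4, not all coplanar).
#' @param nAlpha number of alpha values in the sweep (default 32).
#' @return a [CellGeometry-class]; \code{metadata(x)$sweep} records the
#'   alpha grid with surface densities. Ties are broken toward the larger
#'   (smoother) alpha.
#' @export
optimizeAlpha <- function(points, nAlpha = 32L) {
    points <- .asPointMatrix(points)
    tets <- delaunay3d(points)
    radii <- .boundedRadii(points, tets)
    alphaMax <- max(radii)
    # smallest alpha (among circumradius values) with a connected, covering
    # complex; connectivity and coverage are monotone in alpha
    cand <- sort(unique(radii))
    lo <- 1L
    hi <- length(cand)
    ok <- function(i) {
        st <- .alphaComplex(points, tets, radii, cand[i],
                            what = "connectivity")
        !st$empty && st$nComponents == 1L && st$covered
    }
    if (!ok(hi)) stop("full Delaunay complex is not connected; degenerate input")
    while (lo < hi) {
        mid <- (lo + hi) %/% 2L
        if (ok(mid)) hi <- mid else lo <- mid + 1L
    }
    alphaMin <- cand[lo]
    grid <- exp(seq(log(alphaMin), log(alphaMax), length.out = nAlpha))
    dens <- numeric(nAlpha)
    stats_ <- vector("list", nAlpha)
    for (i in seq_len(nAlpha)) {
        st <- .alphaComplex(points, tets, radii, grid[i], what = "surface")
        stats_[[i]] <- st
        dens[i] <- if (st$empty || st$area <= 0) -Inf
                   else length(st$boundaryVertices) / (st$area * 1e-6)
    }
    best <- max(dens)
    pick <- max(which(dens >= best * (1 - 1e-12)))  # ties -> larger alpha
    st <- .alphaComplex(points, tets, radii, grid[pick])
    new("CellGeometry", vertices = points,
        faces = st$boundaryFaces, alpha = grid[pick],
        surfaceArea = st$area * 1e-6, volume = st$volume * 1e-9,
        boundaryVertices = as.integer(st$boundaryVertices),
        metadata = list(
            sweep = data.frame(alpha = grid, surfaceDensity = dens),
            alphaMin = alphaMin, alphaMax = alphaMax,
            nComponents = st$nComponents, covered = st$covered))
}
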