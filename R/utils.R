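# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. A NULL seed uses (and advances) the global stream.
.withSeed <- function(seed, code) {
    if (is.null(seed)) return(force(code))
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (had) {
            assign(".Random.seed", old, envir = globalenv())
        } else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE)) {
            rm(".Random.seed", envir = globalenv())
        }
    })
    set.seed(as.integer(seed))
    force(code)
}

.asPointMatrix <- function(points, ncol = 3L) {
    points <- as.matrix(points)
    storage.mode(points) <- "double"
    if (ncol(points) != ncol)
        stop("expected a matrix with ", ncol, " coordinate columns")
    if (anyNA(points) || any(!is.finite(points)))
        stop("coordinates must be finite")
    points
}

# Squared Euclidean distances between the rows of `a` (m x d) and `b` (n x d).
.crossDist2 <- function(a, b) {
    d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
    d2[d2 < 0] <- 0
    d2
}

.isWholeNumber <- function(x, tol = 1e-8) {
    is.finite(x) & abs(x - round(x)) < tol
}
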