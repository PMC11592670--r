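#' Gamma mixture density
#'
#' Density of a weighted mixture of Gamma distributions with shape/rate
#' parameterization,
#' \deqn{p(x) = \sum_j w_j \frac{\beta_j^{\alpha_j}}{\Gamma(\alpha_j)}
#'   x^{\alpha_j - 1} e^{-\beta_j x},}
#' the model used for RyR cluster volumes (two right-skewed subpopulations
#' of smaller and larger clusters).
#'
#' @param x positive numeric vector of volumes (um^3).
#' @param fit a [GammaMixtureFit-class], or a list with elements
#'   \code{shape}, \code{rate}, \code{weight} (vectors of equal length;
#'   weights summing to 1).
#' @return density values at \code{x}.
#' @examples
#' agg <- list(shape = c(4.35, 2.22), rate = c(125, 10.64),
#'             weight = c(0.16, 0.84))
#' integrate(dGammaMixture, 0, Inf, fit = agg)
#' @export
dGammaMixture <- function(x, fit) {
    p <- .mixParams(fit)
    if (any(x <= 0)) stop("dGammaMixture: x must be positive")
    dens <- 0
    for (j in seq_along(p$shape))
        dens <- dens + p$weight[j] *
            stats::dgamma(x, shape = p$shape[j], rate = p$rate[j])
    dens
}

#' @rdname dGammaMixture
#' @param n number of draws.
#' @param seed optional integer seed (the caller's RNG stream is preserved).
#' @return for \code{rGammaMixture}, a numeric vector of draws with an
#'   integer attribute \code{component} giving the generating component of
#'   each draw.
#' @export
rGammaMixture <- function(n, fit, seed = NULL) {
    p <- .mixParams(fit)
    .withSeed(seed, {
        comp <- sample.int(length(p$shape), n, replace = TRUE,
                           prob = p$weight)
        x <- stats::rgamma(n, shape = p$shape[comp], rate = p$rate[comp])
        attr(x, "component") <- comp
        x
    })
}

.mixParams <- function(fit) {
    if (is(fit, "GammaMixtureFit")) {
        cmp <- components(fit)
        p <- list(shape = cmp$shape, rate = cmp$rate, weight = cmp$weight)
    } else {
        p <- fit
        if (length(p$weight) == length(p$shape) - 1L)
            p$weight <- c(p$weight, 1 - sum(p$weight))
    }
    stopifnot(length(p$shape) == length(p$rate),
              length(p$shape) == length(p$weight),
              all(p$shape > 0), all(p$rate > 0),
              abs(sum(p$weight) - 1) < 1e-8)
    p
}

#' Method-of-moments initialization for a two-component Gamma mixture
#'
#' Splits the sorted data at the median and matches Gamma moments on each
#' half: \eqn{\alpha = \bar{x}^2 / s^2}, \eqn{\beta = \bar{x} / s^2}. The
#' mixing weight starts at 0.5. This places one component on the smaller
#' and one on the larger sizes, which is enough for the bounded likelihood
#' maximization to take over.
#'
#' @param data positive numeric vector (n >= 4).
#' @return list with \code{shape}, \code{rate} (each length 2, lower half
#'   first) and \code{weight} (scalar, weight of the first component).
#' @export
momentsInit <- function(data) {
    n <- length(data)
    if (n < 4) stop("momentsInit: need at least 4 observations")
    if (any(data <= 0)) stop("momentsInit: data must be positive")
    s <- sort(data)
    halves <- list(s[seq_len(n %/% 2)], s[(n %/% 2 + 1):n])
    est <- vapply(halves, function(h) {
        m <- mean(h)
        v <- stats::var(h)
        vmin <- (m * 1e-6)^2 + .Machine$double.xmin
        if (!is.finite(v) || v < vmin) {
            warning("momentsInit: (near-)zero variance half; flooring")
            v <- vmin
        }
        c(shape = m^2 / v, rate = m / v)
    }, numeric(2))
    list(shape = est["shape", ], rate = est["rate", ], weight = 0.5)
}

# Negative log-likelihood of an m-component Gamma mixture.
# Parameter vector: (shape_1, rate_1, ..., shape_m, rate_m, stick_1..m-1)
# where weights come from stick-breaking lengths in [0,1] (for m = 2 the
# single stick length is the first component's weight itself).
.mixUnpack <- function(par, m) {
    shape <- par[seq(1, 2 * m, by = 2)]
    rate <- par[seq(2, 2 * m, by = 2)]
    if (m == 1L) {
        weight <- 1
    } else {
        stick <- par[(2 * m + 1):(3 * m - 1)]
        weight <- numeric(m)
        rem <- 1
        for (j in seq_len(m - 1L)) {
            weight[j] <- stick[j] * rem
            rem <- rem - weight[j]
        }
        weight[m] <- rem
    }
    list(shape = shape, rate = rate, weight = weight)
}

.mixNegLogLik <- function(par, x, m) {
    p <- .mixUnpack(par, m)
    dens <- 0
    for (j in seq_len(m))
        dens <- dens + p$weight[j] *
            stats::dgamma(x, shape = p$shape[j], rate = p$rate[j])
    -sum(log(pmax(dens, .Machine$double.xmin)))
}

#' Fit a Gamma mixture by bounded maximum likelihood
#'
#' Maximizes the exact mixture log-likelihood with box constraints
#' (shapes and rates positive, mixing weight in \[0, 1\]) using L-BFGS-B,
#' starting from the method-of-moments initialization. If the primary start
#' does not converge, a small number of multiplicatively perturbed restarts
#' is tried and the best solution kept. Components are reported in
#' increasing order of their means.
#'
#' @param data positive numeric vector of cluster volumes (um^3).
#' @param nComponents number of Gamma components (1 or 2 typical).
#' @param init optional initialization list (\code{shape}, \code{rate},
#'   \code{weight}); defaults to [momentsInit()] for two components and
#'   whole-sample moments for one.
#' @param nStarts number of perturbed restarts tried when the first
#'   optimization fails to converge.
#' @param seed seed for the restart perturbations.
#' @return a [GammaMixtureFit-class]. BIC is \eqn{k \ln n - 2 \log L} with
#'   \eqn{k = 3m - 1}.
#' @examples
#' x <- rGammaMixture(2000, list(shape = c(4.35, 2.22),
#'                    rate = c(125, 10.64), weight = 0.16), seed = 1)
#' fitGammaMixture(x, 2)
#' @export
fitGammaMixture <- function(data, nComponents = 2L, init = NULL,
                            nStarts = 5L, seed = 1L) {
    x <- as.numeric(data)
    if (any(x <= 0)) stop("fitGammaMixture: data must be positive")
    n <- length(x)
    m <- as.integer(nComponents)
    if (n < 3 * m) stop("fitGammaMixture: too few observations")
    if (is.null(init)) {
        if (m == 2L) {
            init <- momentsInit(x)
        } else {
            mu <- mean(x)
            v <- stats::var(x)
            init <- list(shape = rep(mu^2 / v, m), rate = rep(mu / v, m),
                         weight = rep(1 / m, max(m - 1L, 1L)))
            if (m > 1L)  # spread the starts so components can separate
                init$shape <- init$shape * exp(seq(-0.5, 0.5, length.out = m))
        }
    }
    stickInit <- if (m == 1L) numeric(0) else {
        w <- init$weight
        if (length(w) == 1L && m == 2L) w else rep(1 / m, m - 1L)
    }
    par0 <- c(rbind(init$shape, init$rate), stickInit)
    lower <- c(rep(1e-6, 2 * m), rep(1e-6, m - 1L))
    upper <- c(rep(Inf, 2 * m), rep(1 - 1e-6, m - 1L))

    runOpt <- function(par) {
        tryCatch(
            stats::optim(par, .mixNegLogLik, x = x, m = m,
                         method = "L-BFGS-B", lower = lower, upper = upper,
                         control = list(maxit = 1000L)),
            error = function(e) NULL)
    }
    best <- runOpt(par0)
    if (is.null(best) || best$convergence != 0L) {
        .withSeed(seed, {
            for (s in seq_len(nStarts)) {
                par <- par0 * exp(stats::runif(length(par0), -0.4, 0.4))
                par <- pmin(pmax(par, lower + 1e-9),
                            ifelse(is.finite(upper), upper - 1e-9, par))
                cand <- runOpt(par)
                if (!is.null(cand) &&
                    (is.null(best) || cand$value < best$value))
                    best <- cand
            }
        })
    }
    if (is.null(best)) stop("fitGammaMixture: optimization failed")
    p <- .mixUnpack(best$par, m)
    ord <- order(p$shape / p$rate)
    cmp <- data.frame(shape = p$shape[ord], rate = p$rate[ord],
                      weight = p$weight[ord])
    ll <- -best$value
    k <- 3L * m - 1L
    new("GammaMixtureFit", components = cmp, logLik = ll,
        bic = k * log(n) - 2 * ll, nObs = as.integer(n),
        converged = best$convergence == 0L,
        metadata = list(init = init, optim = best[c("convergence",
                                                    "message", "counts")]))
}

#' Select the number of mixture components by BIC
#'
#' Fits a Gamma mixture for each candidate component count and returns the
#' fit with the lowest Bayesian Information Criterion, balancing goodness
#' of fit against model complexity.
#'
#' @param data positive numeric vector.
#' @param candidates integer vector of component counts (default 1:2).
#' @param ... passed to [fitGammaMixture()].
#' @return the best [GammaMixtureFit-class]; attribute \code{"bicTable"}
#'   records the BIC of every candidate.
#' @export
selectComponents <- function(data, candidates = 1:2, ...) {
    stopifnot(length(candidates) > 0)
    fits <- lapply(candidates, function(m) {
        tryCatch(fitGammaMixture(data, nComponents = m, ...),
                 error = function(e) NULL)
    })
    ok <- !vapply(fits, is.null, logical(1))
    if (!any(ok)) stop("selectComponents: all candidate fits failed")
    bics <- vapply(fits[ok], mixtureBIC, numeric(1))
    best <- fits[ok][[which.min(bics)]]
    attr(best, "bicTable") <- data.frame(m = candidates[ok], bic = bics)
    best
}

#' Summary statistics of one mixture component
#'
#' For a Gamma(shape \eqn{\alpha}, rate \eqn{\beta}) component: mean
#' \eqn{\alpha/\beta}, standard deviation \eqn{\sqrt{\alpha}/\beta}, excess
#' kurtosis \eqn{6/\alpha}, and the 95th percentile of the component
#' distribution (the threshold used to define the largest clusters).
#'
#' @param fit a [GammaMixtureFit-class].
#' @param component component index (in increasing order of means).
#' @return list with \code{mean}, \code{sd}, \code{excessKurtosis},
#'   \code{percentile95} (all in um^3 except the kurtosis) and the
#'   component parameters.
#' @examples
#' # printed aggregated parameters: shape 2.22, rate 10.64
#' f <- list(shape = c(4.35, 2.22), rate = c(125, 10.64), weight = 0.16)
#' fit <- fitGammaMixture(rGammaMixture(5000, f, seed = 1), 2)
#' componentStats(fit, 2)
#' @export
componentStats <- function(fit, component) {
    cmp <- components(fit)
    if (component < 1 || component > nrow(cmp))
        stop("component index out of bounds")
    a <- cmp$shape[component]
    b <- cmp$rate[component]
    list(shape = a, rate = b, weight = cmp$weight[component],
         mean = a / b, sd = sqrt(a) / b,
         excessKurtosis = 6 / a,
         percentile95 = stats::qgamma(0.95, shape = a, rate = b))
}

#' Threshold volume defining the largest clusters
#'
#' The 95th percentile of the larger-mean component of a two-component
#' Gamma mixture fit, used as the volume threshold marking the tail of the
#' distribution that represents the largest RyR clusters.
#'
#' @param fit a two-component [GammaMixtureFit-class].
#' @return threshold volume in um^3.
#' @export
largeCruThreshold <- function(fit) {
    if (nComponents(fit) < 2L)
        stop("largeCruThreshold: requires a two-component fit")
    componentStats(fit, nComponents(fit))$percentile95
}

#' Flag clusters above the large-cluster threshold
#'
#' Adds a logical \code{large_cru} column to a [ClusterSet-class], TRUE for
#' clusters whose volume is at least [largeCruThreshold()] of the fit.
#'
#' @param cs a [ClusterSet-class].
#' @param fit a two-component [GammaMixtureFit-class].
#' @return the ClusterSet with the \code{large_cru} column set.
#' @export
flagLargeCRUs <- function(cs, fit) {
    stopifnot(is(cs, "ClusterSet"))
    thr <- largeCruThreshold(fit)
    df <- cs@clusters
    df$large_cru <- df$volume >= thr
    initialize(cs, clusters = df,
               metadata = c(cs@metadata, list(largeCruThreshold = thr)))
}
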