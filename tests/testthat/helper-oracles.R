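# Independent oracles and small fixtures shared across the test files.

# Numerically stable log(cosh(u)).
logCosh <- function(u) abs(u) + log1p(exp(-2 * abs(u))) - log(2)

# E{G(nu)} for nu ~ N(0,1), G = log cosh; deterministic quadrature.
gaussLogCosh <- function() {
    stats::integrate(function(u) stats::dnorm(u) * logCosh(u),
        -Inf, Inf)$value
}

# Exhaustive negentropy oracle: the unmixing angle in [0, pi/2) maximizing
# the summed squared negentropy approximation of the two orthogonal
# projections.  Independent of the fixed-point iteration path.
negentropyGridAngle <- function(Z, stepDeg = 0.05) {
    eg <- gaussLogCosh()
    thetas <- seq(0, pi / 2, by = stepDeg * pi / 180)
    J <- vapply(thetas, function(th) {
        w1 <- c(cos(th), sin(th))
        w2 <- c(-sin(th), cos(th))
        (mean(logCosh(Z %*% w1)) - eg)^2 +
            (mean(logCosh(Z %*% w2)) - eg)^2
    }, numeric(1L))
    thetas[which.max(J)]
}

# Angle (degrees) between two directions modulo the 90-degree ambiguity of
# a 2-D orthonormal unmixing (component permutation and sign).
angleGapDeg <- function(a, b) {
    d <- (a - b) * 180 / pi
    d <- d %% 90
    min(d, 90 - d)
}

# Whitened mixture of two independent uniform sources at a known rotation.
uniformRotationMixture <- function(n, thetaDeg, seed) {
    set.seed(seed)
    S <- cbind(runif(n, -sqrt(3), sqrt(3)), runif(n, -sqrt(3), sqrt(3)))
    th <- thetaDeg * pi / 180
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
    S %*% t(R)
}

# A small scene rendered once for tests that only need a valid image.
testScene <- function(h = 60, w = 80, seed = 1, nSpots = 20, spotScale = 3,
                      shadingAmplitude = 0.3) {
    simulateScene(h, w, nSpots = nSpots, spotScale = spotScale,
        shadingAmplitude = shadingAmplitude, seed = seed)
}
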