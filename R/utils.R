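# Internal numeric helpers shared across modules.

.cross <- function(a, b) {
    c(a[2L] * b[3L] - a[3L] * b[2L],
      a[3L] * b[1L] - a[1L] * b[3L],
      a[1L] * b[2L] - a[2L] * b[1L])
}

.norm3 <- function(v) sqrt(sum(v * v))

.unit <- function(v) {
    n <- .norm3(v)
    if (n < 1e-12)
        stop("degenerate geometry: zero-length vector", call. = FALSE)
    v / n
}

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

# Internal-coordinate (NeRF) placement: position atom D bonded to C with
# bond length r, angle B-C-D = theta (deg) and torsion A-B-C-D = phi (deg).
.placeAtom <- function(a, b, c, r, theta, phi) {
    theta <- .deg2rad(theta)
    phi <- .deg2rad(phi)
    bcHat <- .unit(c - b)
    nHat <- .unit(.cross(b - a, bcHat))
    mHat <- .cross(nHat, bcHat)
    c + r * (-cos(theta) * bcHat +
             sin(theta) * (cos(phi) * mHat + sin(phi) * nHat))
}

# Rodrigues rotation of points (rows of xyz) about the axis through
# `origin` with direction `axis`, by `angleDeg` degrees.
.rotateAbout <- function(xyz, origin, axis, angleDeg) {
    k <- .unit(axis)
    ang <- .deg2rad(angleDeg)
    K <- matrix(c(0, k[3L], -k[2L],
                  -k[3L], 0, k[1L],
                  k[2L], -k[1L], 0), nrow = 3L)
    R <- diag(3L) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
    shifted <- sweep(xyz, 2L, origin)
    sweep(shifted %*% t(R), 2L, origin, FUN = "+")
}

# Evaluate expr with a temporary RNG state seeded by `seed`; the caller's
# RNG stream is restored afterwards. NULL seed leaves the stream alone.
.withSeed <- function(seed, expr) {
    if (is.null(seed))
        return(force(expr))
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(suppressWarnings(
            rm(".Random.seed", envir = globalenv())), add = TRUE)
    }
    set.seed(seed)
    expr
}
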