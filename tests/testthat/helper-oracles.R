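# Independent oracle implementations and fixture helpers. Each oracle is
# coded from a different derivation than the implementation it checks.

crossOracle <- function(a, b) {
    c(a[2] * b[3] - a[3] * b[2],
      a[3] * b[1] - a[1] * b[3],
      a[1] * b[2] - a[2] * b[1])
}

# distance: componentwise norm
distOracle <- function(a, b) sqrt((a[1] - b[1])^2 + (a[2] - b[2])^2 +
                                  (a[3] - b[3])^2)

# angle: arccos of normalized dot product
angleOracle <- function(a, b, c) {
    u <- a - b
    v <- c - b
    acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
}

# torsion by projection onto the plane perpendicular to the b->c axis,
# signed by the triple product with the axis (not the bonded-normals
# formula used by the implementation)
dihedralOracle <- function(a, b, c, d) {
    axis <- (c - b) / sqrt(sum((c - b)^2))
    u <- (a - b) - sum((a - b) * axis) * axis
    w <- (d - c) - sum((d - c) * axis) * axis
    atan2(sum(crossOracle(u, w) * axis), sum(u * w)) * 180 / pi
}

randomRotation <- function() {
    qr.Q(qr(matrix(stats::rnorm(9), 3))) -> Q
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    Q
}

applyRigid <- function(frame, R, shift) {
    atomFrame(atoms(frame), sweep(coords(frame) %*% t(R), 2, shift, "+"))
}

rigidTrajectory <- function(traj, R, shift) {
    arr <- coords(traj)
    for (i in seq_len(nFrames(traj)))
        arr[, , i] <- sweep(arr[, , i] %*% t(R), 2, shift, "+")
    trajectoryFromFrames(
        lapply(seq_len(dim(arr)[3]),
               function(i) atomFrame(atoms(traj), arr[, , i])),
        "rigid copy")
}

randomFragmentParams <- function() {
    list(d1 = stats::runif(1, 0.5, 8), theta1 = stats::runif(1, 5, 175),
         chi1 = stats::runif(1, -179.9, 180), d2 = stats::runif(1, 0.5, 5))
}

selALD <- function(nm) atomSelector("A", 500L, nm)

chi1Quad <- function() list(selALD("C50"), selALD("N99"), selALD("CA"),
                            selALD("C80"))

chi1Moving <- function() lapply(c("C80", "H99", "CB", "CG", "CD", "CAD"),
                                selALD)

# tiny two-atom frame for clash-energy cases
twoAtomFrame <- function(d) {
    atomFrame(data.frame(name = c("X1", "X2"), element = "C",
                         resname = "TST", resno = 1L, chain = "A"),
              rbind(c(0, 0, 0), c(d, 0, 0)))
}
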