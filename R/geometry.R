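#' Euclidean distance between two points
#'
#' @param a,b numeric length-3 coordinates, Angstrom.
#' @return distance in Angstrom.
#' @examples
#' measureDistance(c(0, 0, 0), c(3, 4, 0))  # 5
#' @export
measureDistance <- function(a, b) {
    stopifnot(length(a) == 3L, length(b) == 3L,
              all(is.finite(a)), all(is.finite(b)))
    .norm3(a - b)
}

#' Angle at a vertex
#'
#' Angle in degrees at vertex `b` between the rays b->a and b->c.
#'
#' @param a,b,c numeric length-3 coordinates, Angstrom.
#' @return angle in degrees, in \[0, 180\].
#' @examples
#' measureAngle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0))  # 90
#' @export
measureAngle <- function(a, b, c) {
    u <- .unit(a - b)
    v <- .unit(c - b)
    .rad2deg(acos(max(-1, min(1, sum(u * v)))))
}

#' Signed torsion angle
#'
#' Signed dihedral a-b-c-d in degrees, IUPAC convention: cis = 0, trans =
#' 180, positive for a clockwise rotation of the far bond viewed along
#' b->c (right-hand rule). Range (-180, 180]. The convention matters
#' because the chi1 reactive windows are sign-sensitive.
#'
#' @param a,b,c,d numeric length-3 coordinates, Angstrom.
#' @return signed dihedral in degrees.
#' @examples
#' measureDihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))  # 0 (cis)
#' @export
measureDihedral <- function(a, b, c, d) {
    b1 <- b - a
    b2 <- c - b
    b3 <- d - c
    n1 <- .cross(b1, b2)
    n2 <- .cross(b2, b3)
    if (.norm3(n1) < 1e-12 || .norm3(n2) < 1e-12)
        stop("degenerate geometry: collinear bonded triple", call. = FALSE)
    deg <- .rad2deg(atan2(sum(.cross(n1, n2) * (b2 / .norm3(b2))),
                          sum(n1 * n2)))
    if (deg <= -180 + 1e-9) deg <- deg + 360
    deg
}

#' Reactive-pose threshold presets and constructor
#'
#' Builds the four-criteria definition of a reactive binding pose. Two
#' named presets are packaged: `"DAP"` (d1 < 4.0 A, theta1 < 80 deg,
#' -120 < chi1 < -90 deg, d2 < 2.0 A) and `"2-APA"` (same except
#' -125 < chi1 < -75 deg). The chi1 window is centred near -90 deg, the
#' alignment at which the scissile C-alpha--COO- bond is perpendicular to
#' the conjugated Schiff-base/pyridine plane.
#'
#' @param preset `"DAP"` or `"2-APA"`, or NULL when giving explicit
#'   thresholds.
#' @param d1Max,theta1Max,d2Max upper bounds (Angstrom, degrees,
#'   Angstrom).
#' @param chi1Window numeric(2) signed-degree window, lo < hi.
#' @param label criteria label; defaults to the preset name.
#' @return a [ReactiveCriteria-class].
#' @export
reactiveCriteria <- function(preset = NULL, d1Max = 4.0, theta1Max = 80,
                             chi1Window = c(-120, -90), d2Max = 2.0,
                             label = NULL) {
    if (!is.null(preset)) {
        preset <- match.arg(preset, c("DAP", "2-APA"))
        chi1Window <- switch(preset, "DAP" = c(-120, -90),
                             "2-APA" = c(-125, -75))
        d1Max <- 4.0; theta1Max <- 80; d2Max <- 2.0
        if (is.null(label)) label <- preset
    }
    if (is.null(label)) label <- "custom"
    new("ReactiveCriteria", d1Max = d1Max, theta1Max = theta1Max,
        chi1Window = as.numeric(chi1Window), d2Max = d2Max, label = label)
}

#' Read reactive criteria from YAML
#'
#' Expects fields `d1_max`, `theta1_max`, `chi1_window` (two numbers),
#' `d2_max` and optional `label`.
#'
#' @param path path to a YAML file.
#' @return a [ReactiveCriteria-class].
#' @export
readCriteria <- function(path) {
    y <- yaml::read_yaml(path)
    reactiveCriteria(d1Max = y$d1_max, theta1Max = y$theta1_max,
                     chi1Window = as.numeric(unlist(y$chi1_window)),
                     d2Max = y$d2_max,
                     label = if (is.null(y$label)) "custom" else y$label)
}

setMethod("show", "ReactiveCriteria", function(object) {
    cat(sprintf(
        "ReactiveCriteria '%s': d1 < %.1f A, theta1 < %.0f deg, %s < chi1 < %s deg, d2 < %.1f A\n",
        object@label, object@d1Max, object@theta1Max,
        format(object@chi1Window[1L]), format(object@chi1Window[2L]),
        object@d2Max))
})

#' Measure the four pose descriptors of one frame
#'
#' Computes, from the role-mapped atoms: d1 = |HZ - CA| (ammonium proton
#' to alpha-carbon), d2 = |OE1 - H1| (glutamate carboxylate to pyridinium
#' proton), theta1 = angle HZ-CA-H99, and chi1 = dihedral
#' C50-N99-CA-C80 (alignment of the scissile bond with the Schiff-base
#' pi system).
#'
#' @param frame an [AtomFrame-class].
#' @param rolemap a [RoleMap-class] binding the mechanistic roles.
#' @return named list with numeric fields `d1`, `theta1`, `chi1`, `d2`.
#' @seealso [classifyPose()], [summarizeTrajectory()]
#' @export
poseDescriptors <- function(frame, rolemap) {
    r <- resolveRoles(frame, rolemap)
    list(d1 = measureDistance(r$HZ$xyz, r$CA$xyz),
         theta1 = measureAngle(r$HZ$xyz, r$CA$xyz, r$H99$xyz),
         chi1 = measureDihedral(r$C50$xyz, r$N99$xyz, r$CA$xyz, r$C80$xyz),
         d2 = measureDistance(r$OE1$xyz, r$H1$xyz))
}

#' Classify one pose against the reactive criteria
#'
#' A pose is reactive iff all four strict inequalities hold:
#' d1 < d1Max, theta1 < theta1Max, lo < chi1 < hi, and d2 < d2Max.
#' Boundary values are non-reactive.
#'
#' @param desc descriptor list from [poseDescriptors()].
#' @param crit a [ReactiveCriteria-class].
#' @return list with logical `reactive` and named logical(4) `pass`
#'   (d1, theta1, chi1, d2).
#' @export
classifyPose <- function(desc, crit) {
    stopifnot(is(crit, "ReactiveCriteria"))
    pass <- c(d1 = desc$d1 < crit@d1Max,
              theta1 = desc$theta1 < crit@theta1Max,
              chi1 = desc$chi1 > crit@chi1Window[1L] &&
                     desc$chi1 < crit@chi1Window[2L],
              d2 = desc$d2 < crit@d2Max)
    list(reactive = all(pass), pass = pass)
}

.crossCols <- function(a, b) {
    rbind(a[2L, ] * b[3L, ] - a[3L, ] * b[2L, ],
          a[3L, ] * b[1L, ] - a[1L, ] * b[3L, ],
          a[1L, ] * b[2L, ] - a[2L, ] * b[1L, ])
}

#' Pose descriptors for every frame of an ensemble
#'
#' Vectorized across frames: roles are resolved once against the shared
#' atom table, then the four descriptors are computed for all frames at
#' once. Equivalent to calling [poseDescriptors()] frame by frame.
#'
#' @param traj a [Trajectory-class].
#' @param rolemap a [RoleMap-class].
#' @return data.frame with columns `frame`, `d1`, `theta1`, `chi1`, `d2`.
#' @export
trajectoryDescriptors <- function(traj, rolemap) {
    stopifnot(is(traj, "Trajectory"))
    r <- resolveRoles(getFrame(traj, 1L), rolemap)
    m <- nFrames(traj)
    # 3 x m matrix of one atom's coordinates across frames
    at <- function(role) matrix(traj@coords[r[[role]]$index, , ], nrow = 3L)
    hz <- at("HZ"); ca <- at("CA"); h99 <- at("H99")
    c50 <- at("C50"); n99 <- at("N99"); c80 <- at("C80")
    oe1 <- at("OE1"); h1 <- at("H1")
    d1 <- sqrt(colSums((hz - ca)^2))
    d2 <- sqrt(colSums((oe1 - h1)^2))
    u <- hz - ca
    v <- h99 - ca
    cosang <- colSums(u * v) / (sqrt(colSums(u^2)) * sqrt(colSums(v^2)))
    theta1 <- .rad2deg(acos(pmax(-1, pmin(1, cosang))))
    b1 <- n99 - c50; b2 <- ca - n99; b3 <- c80 - ca
    n1 <- .crossCols(b1, b2)
    n2 <- .crossCols(b2, b3)
    b2u <- sweep(b2, 2L, sqrt(colSums(b2^2)), "/")
    chi1 <- .rad2deg(atan2(colSums(.crossCols(n1, n2) * b2u),
                           colSums(n1 * n2)))
    chi1[chi1 <= -180 + 1e-9] <- chi1[chi1 <= -180 + 1e-9] + 360
    data.frame(frame = seq_len(m), d1 = d1, theta1 = theta1,
               chi1 = chi1, d2 = d2)
}

#' Count reactive binding poses over an ensemble
#'
#' Computes descriptors per frame, classifies each frame independently,
#' and aggregates: trajectories are ranked by the number of frames with
#' reactive binding poses.
#'
#' @param traj a [Trajectory-class].
#' @param rolemap a [RoleMap-class].
#' @param crit a [ReactiveCriteria-class].
#' @param label variant label stored on the summary (defaults to the
#'   trajectory's source label).
#' @return a [PoseSummary-class].
#' @export
summarizeTrajectory <- function(traj, rolemap, crit,
                                label = traj@sourceLabel) {
    stopifnot(is(traj, "Trajectory"), is(crit, "ReactiveCriteria"))
    m <- nFrames(traj)
    d <- trajectoryDescriptors(traj, rolemap)
    passMat <- cbind(d1 = d$d1 < crit@d1Max,
                     theta1 = d$theta1 < crit@theta1Max,
                     chi1 = d$chi1 > crit@chi1Window[1L] &
                            d$chi1 < crit@chi1Window[2L],
                     d2 = d$d2 < crit@d2Max)
    reactive <- rowSums(passMat) == 4L
    new("PoseSummary", variantLabel = label, nFrames = m,
        nReactive = as.integer(sum(reactive)),
        fraction = sum(reactive) / m,
        perCriterionPass = as.integer(colSums(passMat)) |>
            stats::setNames(colnames(passMat)))
}

setMethod("show", "PoseSummary", function(object) {
    cat(sprintf("PoseSummary '%s': %d / %d frames reactive (%.3f)\n",
                object@variantLabel, object@nReactive, object@nFrames,
                object@fraction))
    cat("  per-criterion pass counts:",
        paste(names(object@perCriterionPass), object@perCriterionPass,
              sep = "=", collapse = " "), "\n")
})

#' Tabulate pose summaries
#'
#' @param summaries list of [PoseSummary-class] objects.
#' @return data.frame with columns variant_label, n_frames, n_reactive,
#'   fraction, pass_d1, pass_theta1, pass_chi1, pass_d2.
#' @export
summaryTable <- function(summaries) {
    if (is(summaries, "PoseSummary")) summaries <- list(summaries)
    do.call(rbind, lapply(summaries, function(s)
        data.frame(variant_label = s@variantLabel, n_frames = s@nFrames,
                   n_reactive = s@nReactive, fraction = s@fraction,
                   pass_d1 = s@perCriterionPass[["d1"]],
                   pass_theta1 = s@perCriterionPass[["theta1"]],
                   pass_chi1 = s@perCriterionPass[["chi1"]],
                   pass_d2 = s@perCriterionPass[["d2"]],
                   stringsAsFactors = FALSE)))
}
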