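# Catalytic-lysine ammonium conformation analysis. The three
# conformations (MC1-MC3) are assigned by nearest anchor: MC1 near the
# cofactor's phenolic oxygen (short d1, most reaction-competent), MC2
# near the Asp65 side chain, MC3 displaced further away (long d1, rarely
# meets the d1 criterion). Each frame is classified independently; the
# conformations rarely interchange on short trajectories, so no dwell
# smoothing is applied.

.MC_STATES <- c("MC1", "MC2", "MC3")

#' Classify the catalytic lysine conformation of one frame
#'
#' Assigns the state whose anchor atom lies closest to the lysine NZ;
#' exact ties are broken in the order MC1 > MC2 > MC3. The pose distance
#' d1 (HZ--CA) is reported alongside.
#'
#' @param frame an [AtomFrame-class].
#' @param rolemap a [RoleMap-class] mapping `LYS_NZ`, the three
#'   `MC*_ANCHOR` roles, `HZ` and `CA`.
#' @return list with `state` (character), `anchorDistances` (named
#'   numeric(3), Angstrom) and `d1` (Angstrom).
#' @export
classifyLys <- function(frame, rolemap) {
    r <- resolveRoles(frame, rolemap)
    for (role in c("LYS_NZ", "MC1_ANCHOR", "MC2_ANCHOR", "MC3_ANCHOR"))
        if (is.null(r[[role]]))
            stop("missing atom for role ", role,
                 ": rolemap does not map it", call. = FALSE)
    nz <- r$LYS_NZ$xyz
    dists <- c(MC1 = measureDistance(nz, r$MC1_ANCHOR$xyz),
               MC2 = measureDistance(nz, r$MC2_ANCHOR$xyz),
               MC3 = measureDistance(nz, r$MC3_ANCHOR$xyz))
    list(state = .MC_STATES[which.min(dists)],  # which.min: first = MC1 wins ties
         anchorDistances = dists,
         d1 = measureDistance(r$HZ$xyz, r$CA$xyz))
}

#' Lysine conformation profile of an ensemble
#'
#' Classifies every frame with [classifyLys()] and tabulates per-state
#' frame counts and mean d1. States with no member frames report a count
#' of 0 and an `NA` mean.
#'
#' @param traj a [Trajectory-class].
#' @param rolemap a [RoleMap-class].
#' @return list with `profile` (data.frame: state, n, mean_d1) and
#'   `frames` (data.frame: frame, state, d1, dist_MC1..dist_MC3).
#' @export
conformationProfile <- function(traj, rolemap) {
    stopifnot(is(traj, "Trajectory"))
    m <- nFrames(traj)
    states <- character(m)
    d1 <- numeric(m)
    dmat <- matrix(0, nrow = m, ncol = 3L,
                   dimnames = list(NULL, .MC_STATES))
    for (i in seq_len(m)) {
        cl <- classifyLys(getFrame(traj, i), rolemap)
        states[i] <- cl$state
        d1[i] <- cl$d1
        dmat[i, ] <- cl$anchorDistances
    }
    profile <- data.frame(
        state = .MC_STATES,
        n = vapply(.MC_STATES, function(s) sum(states == s), integer(1L)),
        mean_d1 = vapply(.MC_STATES, function(s)
            if (any(states == s)) mean(d1[states == s]) else NA_real_,
            numeric(1L)),
        stringsAsFactors = FALSE)
    frames <- data.frame(frame = seq_len(m), state = states, d1 = d1,
                         dist_MC1 = dmat[, 1L], dist_MC2 = dmat[, 2L],
                         dist_MC3 = dmat[, 3L], stringsAsFactors = FALSE)
    list(profile = profile, frames = frames)
}
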