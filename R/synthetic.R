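# Synthetic aldimine fixtures: minimal geometric fragments realizing
# prescribed descriptor values, ensembles with known reactive fractions,
# and variant panels with a stated linear activity model. Fragments are
# geometric, not chemically complete aldimines: the pipeline consumes
# geometry, not chemistry.

.FRAG_MC2_ANCHOR <- c(2.5, 3.5, 2.5)    # Asp65 side-chain O stand-in
.FRAG_MC3_ANCHOR <- c(2.5, 3.5, -3.0)   # Glu71 side-chain O stand-in

#' Build a minimal aldimine fragment with prescribed descriptors
#'
#' Constructs an ~18-atom active-site fragment (Schiff-base core, a
#' 4-carbon substrate side chain ending in the distal alpha-carbon, a
#' pyridine-ring stand-in with phenolic oxygen and pyridinium proton, the
#' catalytic lysine NZ/HZ, and the three MC anchor oxygens) whose measured
#' pose descriptors are exactly the requested values:
#' `poseDescriptors(buildFragment(...), syntheticRoleMap())` recovers
#' (d1, theta1, chi1, d2) to machine precision.
#'
#' @param d1 HZ--CA distance, Angstrom (> 0).
#' @param theta1 HZ-CA-H99 angle, degrees, strictly inside (0, 180).
#' @param chi1 C50-N99-CA-C80 dihedral, signed degrees in (-180, 180].
#' @param d2 OE1--H1 distance, Angstrom (> 0).
#' @param mcState optional `"MC1"`, `"MC2"` or `"MC3"`; when given, the
#'   lysine NZ is placed 2.8 Angstrom from that anchor and well away from
#'   the other two.
#' @return an [AtomFrame-class].
#' @seealso [syntheticRoleMap()], [fragmentBonds()], [simulateTrajectory()]
#' @examples
#' fr <- buildFragment(3.0, 60, -100, 1.8)
#' poseDescriptors(fr, syntheticRoleMap())
#' @export
buildFragment <- function(d1, theta1, chi1, d2, mcState = NULL) {
    if (!is.finite(d1) || d1 <= 0 || !is.finite(d2) || d2 <= 0)
        stop("d1 and d2 must be positive and finite", call. = FALSE)
    if (!is.finite(theta1) || theta1 <= 0 || theta1 >= 180)
        stop("theta1 must lie strictly inside (0, 180) degrees",
             call. = FALSE)
    if (!is.finite(chi1) || chi1 <= -180 || chi1 > 180)
        stop("chi1 must lie in (-180, 180] degrees", call. = FALSE)
    if (!is.null(mcState))
        mcState <- match.arg(mcState, c("MC1", "MC2", "MC3"))

    wrap <- function(x) ((x + 180) %% 360) - 180
    n99 <- c(0, 0, 0)
    ca <- c(1.47, 0, 0)
    c50 <- 1.40 * c(cos(.deg2rad(120)), sin(.deg2rad(120)), 0)
    c80 <- .placeAtom(c50, n99, ca, 1.53, 111, chi1)
    h99 <- .placeAtom(c50, n99, ca, 1.09, 109, wrap(chi1 + 120))
    cb <- .placeAtom(c50, n99, ca, 1.53, 109, wrap(chi1 - 120))
    cg <- .placeAtom(n99, ca, cb, 1.53, 112, 180)
    cd <- .placeAtom(ca, cb, cg, 1.53, 112, 180)
    cad <- .placeAtom(cb, cg, cd, 1.53, 112, 180)
    hz <- .placeAtom(n99, h99, ca, d1, theta1, 90)
    c3 <- .placeAtom(ca, n99, c50, 1.40, 120, 180)
    o3 <- .placeAtom(n99, c50, c3, 1.36, 120, 0)
    n1 <- .placeAtom(n99, c50, c3, 1.35, 120, 180)
    h1 <- .placeAtom(c50, c3, n1, 1.01, 120, 180)
    oe1 <- h1 + d2 * .unit(h1 - n1)
    od65 <- .FRAG_MC2_ANCHOR
    oe71 <- .FRAG_MC3_ANCHOR
    anchors <- list(MC1 = o3, MC2 = od65, MC3 = oe71)
    nz <- if (is.null(mcState)) {
        .placeAtom(h99, ca, hz, 1.05, 115, 60)
    } else {
        others <- Reduce(`+`, anchors[setdiff(names(anchors), mcState)]) / 2
        anchors[[mcState]] + 2.8 * .unit(anchors[[mcState]] - others)
    }

    atab <- data.frame(
        name = c("C50", "N99", "CA", "C80", "H99", "CB", "CG", "CD",
                 "CAD", "C3", "O3", "N1", "H1", "NZ", "HZ", "OE1",
                 "OD1", "OE1"),
        element = c("C", "N", "C", "C", "H", "C", "C", "C", "C", "C",
                    "O", "N", "H", "N", "H", "O", "O", "O"),
        resname = c(rep("ALD", 13L), "LYS", "LYS", "GLU", "ASP", "GLU"),
        resno = c(rep(500L, 13L), 46L, 46L, 246L, 65L, 71L),
        chain = "A",
        stringsAsFactors = FALSE)
    xyz <- rbind(c50, n99, ca, c80, h99, cb, cg, cd, cad, c3, o3, n1,
                 h1, nz, hz, oe1, od65, oe71)
    atomFrame(atab, xyz)
}

#' RoleMap matching the synthetic fragment atom names
#'
#' @return a [RoleMap-class] binding every required and optional role to
#'   the atoms emitted by [buildFragment()].
#' @export
syntheticRoleMap <- function() {
    s <- atomSelector
    roleMap(HZ = s("A", 46L, "HZ"), CA = s("A", 500L, "CA"),
            H99 = s("A", 500L, "H99"), C50 = s("A", 500L, "C50"),
            N99 = s("A", 500L, "N99"), C80 = s("A", 500L, "C80"),
            OE1 = s("A", 246L, "OE1"), H1 = s("A", 500L, "H1"),
            DISTAL_CA = s("A", 500L, "CAD"), LYS_NZ = s("A", 46L, "NZ"),
            MC1_ANCHOR = s("A", 500L, "O3"),
            MC2_ANCHOR = s("A", 65L, "OD1"),
            MC3_ANCHOR = s("A", 71L, "OE1"),
            PLP_ANCHOR_SET = list(s("A", 500L, "C50"), s("A", 500L, "C3"),
                                  s("A", 500L, "O3"), s("A", 500L, "N1"),
                                  s("A", 500L, "H1")))
}

#' Bond list of the synthetic fragment
#'
#' Explicit covalent topology of the [buildFragment()] fragment (bond
#' perception is deliberately never performed). Used to derive the
#' non-bonded exclusions for [clashEnergy()].
#'
#' @return two-column character matrix of bonded atom-name pairs.
#' @export
fragmentBonds <- function() {
    rbind(c("C50", "N99"), c("N99", "CA"), c("CA", "C80"),
          c("CA", "H99"), c("CA", "CB"), c("CB", "CG"), c("CG", "CD"),
          c("CD", "CAD"), c("C50", "C3"), c("C3", "O3"), c("C3", "N1"),
          c("N1", "H1"), c("NZ", "HZ"))
}

#' Default perturbable dihedrals of the synthetic aldimine side chain
#'
#' The three rotatable heavy-atom dihedrals of the substrate side chain
#' (about CA-CB, CB-CG and CG-CD), each with its downstream moving set.
#' The alignment dihedral chi1 is deliberately not in this set: it is
#' held at its initial value during library construction.
#'
#' @param maxPerturb per-dihedral maximum perturbation, degrees
#'   (default 30).
#' @return list of dihedral descriptors suitable for [rotamerSpec()].
#' @export
aldimineDihedrals <- function(maxPerturb = 30) {
    s <- function(nm) atomSelector("A", 500L, nm)
    list(list(quad = list(s("N99"), s("CA"), s("CB"), s("CG")),
              moving = list(s("CG"), s("CD"), s("CAD")),
              maxPerturb = maxPerturb),
         list(quad = list(s("CA"), s("CB"), s("CG"), s("CD")),
              moving = list(s("CD"), s("CAD")),
              maxPerturb = maxPerturb),
         list(quad = list(s("CB"), s("CG"), s("CD"), s("CAD")),
              moving = list(s("CAD")),
              maxPerturb = maxPerturb))
}

.sampleInside <- function(lo, hi, sd) {
    v <- stats::runif(1L, lo, hi) + stats::rnorm(1L, 0, sd)
    min(hi, max(lo, v))
}

.sampleChiOutside <- function(window, margin) {
    loSide <- c(-178, window[1L] - margin)
    hiSide <- c(window[2L] + margin, 178)
    w <- c(max(0, diff(loSide)), max(0, diff(hiSide)))
    if (all(w <= 0))
        stop("chi1 window leaves no room to violate it", call. = FALSE)
    side <- sample.int(2L, 1L, prob = w)
    rng <- if (side == 1L) loSide else hiSide
    stats::runif(1L, rng[1L], rng[2L])
}

#' Simulate an ensemble with a known reactive fraction
#'
#' Generates `round(nFrames * reactiveFraction)` frames strictly inside
#' every criteria window and the rest strictly outside at least one, at
#' randomized frame positions. Sampling is margin-respecting (reactive
#' values at least `marginDist` / `marginAng` inside the windows,
#' violations at least that far outside), so descriptor jitter can never
#' flip a truth label.
#'
#' @param nFrames number of frames (>= 1).
#' @param reactiveFraction target fraction in \[0, 1\].
#' @param criteria a [ReactiveCriteria-class].
#' @param jitterSd descriptor jitter scale: applied as `jitterSd`
#'   Angstrom to distances and `10 * jitterSd` degrees to angles, then
#'   clamped to the margin-respecting range.
#' @param seed optional RNG seed; the caller's RNG state is preserved.
#' @param marginDist,marginAng safety margins (Angstrom, degrees).
#' @return list with elements `trajectory` ([Trajectory-class]),
#'   `labels` (logical truth per frame) and `descriptors` (data.frame of
#'   the generated d1/theta1/chi1/d2 per frame).
#' @export
simulateTrajectory <- function(nFrames, reactiveFraction, criteria,
                               jitterSd = 0.3, seed = NULL,
                               marginDist = 0.1, marginAng = 2) {
    stopifnot(nFrames >= 1L)
    if (!is.finite(reactiveFraction) || reactiveFraction < 0 ||
        reactiveFraction > 1)
        stop("reactiveFraction must lie in [0, 1]", call. = FALSE)
    stopifnot(is(criteria, "ReactiveCriteria"))
    .withSeed(seed, {
        nReactive <- round(nFrames * reactiveFraction)
        labels <- rep(FALSE, nFrames)
        labels[sample.int(nFrames, nReactive)] <- TRUE
        sdD <- jitterSd
        sdA <- 10 * jitterSd
        w <- criteria@chi1Window
        desc <- data.frame(d1 = numeric(nFrames), theta1 = numeric(nFrames),
                           chi1 = numeric(nFrames), d2 = numeric(nFrames))
        frames <- vector("list", nFrames)
        for (i in seq_len(nFrames)) {
            if (labels[i]) {
                v <- c(d1 = .sampleInside(1.5, criteria@d1Max - marginDist, sdD),
                       theta1 = .sampleInside(15, criteria@theta1Max - marginAng, sdA),
                       chi1 = .sampleInside(w[1L] + marginAng,
                                            w[2L] - marginAng, sdA),
                       d2 = .sampleInside(0.9, criteria@d2Max - marginDist, sdD))
            } else {
                canViolate <- c(d1 = TRUE,
                                theta1 = criteria@theta1Max + marginAng < 176,
                                chi1 = TRUE, d2 = TRUE)
                viol <- stats::runif(4L) < 0.5 & canViolate
                if (!any(viol))
                    viol[sample(which(canViolate), 1L)] <- TRUE
                v <- c(
                    d1 = if (viol[["d1"]])
                        stats::runif(1L, criteria@d1Max + marginDist,
                                     criteria@d1Max + 2.5)
                    else .sampleInside(1.5, criteria@d1Max - marginDist, sdD),
                    theta1 = if (viol[["theta1"]])
                        stats::runif(1L, criteria@theta1Max + marginAng, 176)
                    else .sampleInside(15, criteria@theta1Max - marginAng, sdA),
                    chi1 = if (viol[["chi1"]])
                        .sampleChiOutside(w, marginAng)
                    else .sampleInside(w[1L] + marginAng,
                                       w[2L] - marginAng, sdA),
                    d2 = if (viol[["d2"]])
                        stats::runif(1L, criteria@d2Max + marginDist,
                                     criteria@d2Max + 2)
                    else .sampleInside(0.9, criteria@d2Max - marginDist, sdD))
            }
            desc[i, ] <- v
            frames[[i]] <- buildFragment(v[["d1"]], v[["theta1"]],
                                         v[["chi1"]], v[["d2"]])
        }
        list(trajectory = trajectoryFromFrames(frames, "synthetic ensemble"),
             labels = labels, descriptors = desc)
    })
}

#' Simulate an ensemble with co-generated lysine conformations
#'
#' Frames are assigned MC states; d1 is drawn per state from the regimes
#' seen in the active site (MC1 short, mean ~2.9 Angstrom; MC2
#' intermediate; MC3 long, > 4.8 Angstrom), while theta1, chi1 and d2 are
#' sampled inside their reactive windows so that d1 is the discriminating
#' criterion.
#'
#' @param nFrames number of frames.
#' @param stateProbs named numeric(3), sampling probabilities for MC1,
#'   MC2, MC3 (default uniform).
#' @param criteria a [ReactiveCriteria-class] (chi1/theta1/d2 windows).
#' @param seed optional RNG seed.
#' @return list with `trajectory`, `states` (character truth per frame)
#'   and `d1` (numeric truth per frame).
#' @seealso [classifyLys()], [conformationProfile()]
#' @export
simulateLysEnsemble <- function(nFrames,
                                stateProbs = c(MC1 = 1, MC2 = 1, MC3 = 1) / 3,
                                criteria = reactiveCriteria("DAP"),
                                seed = NULL) {
    stopifnot(nFrames >= 1L)
    .withSeed(seed, {
        states <- sample(c("MC1", "MC2", "MC3"), nFrames, replace = TRUE,
                         prob = stateProbs)
        d1 <- vapply(states, function(s) switch(s,
            MC1 = min(3.3, max(2.5, stats::rnorm(1L, 2.9, 0.15))),
            MC2 = stats::runif(1L, 3.5, 4.5),
            MC3 = stats::runif(1L, 4.9, 6.0)), numeric(1L))
        w <- criteria@chi1Window
        frames <- vector("list", nFrames)
        for (i in seq_len(nFrames)) {
            frames[[i]] <- buildFragment(
                d1 = d1[i],
                theta1 = stats::runif(1L, 30, criteria@theta1Max - 5),
                chi1 = stats::runif(1L, w[1L] + 3, w[2L] - 3),
                d2 = stats::runif(1L, 1.1, criteria@d2Max - 0.1),
                mcState = states[i])
        }
        list(trajectory = trajectoryFromFrames(frames, "lysine ensemble"),
             states = unname(states), d1 = unname(d1))
    })
}

#' Construct a PanelSpec
#'
#' Defaults emulate the study conditions of an engineered-variant panel:
#' 20 variants whose true reactive fractions spread over (0, 1), 200
#' frames per trajectory, and specific activities on the mU/mg scale of a
#' thermophilic decarboxylase panel (slope 700 mU/mg per unit fraction,
#' additive Gaussian noise of 200 mU/mg, which places the realized
#' Pearson r in the 0.6-0.8 regime).
#'
#' @param nVariants number of variants.
#' @param nFrames frames per trajectory.
#' @param trueFractions per-variant true reactive fractions (default an
#'   even spread over \[0.05, 0.95\]).
#' @param intercept,slope activity model `a + b * fraction`, mU/mg.
#' @param noiseSd additive activity noise SD, mU/mg.
#' @param seed RNG seed.
#' @return a [PanelSpec-class].
#' @export
panelSpec <- function(nVariants = 20L, nFrames = 200L,
                      trueFractions = seq(0.05, 0.95,
                                          length.out = nVariants),
                      intercept = 0, slope = 700, noiseSd = 200,
                      seed = 1L) {
    new("PanelSpec", nVariants = as.integer(nVariants),
        nFrames = as.integer(nFrames),
        trueFractions = as.numeric(trueFractions),
        intercept = intercept, slope = slope, noiseSd = noiseSd,
        seed = as.integer(seed))
}

#' Simulate a variant panel with a stated activity model
#'
#' Per variant i, generates a trajectory with true reactive fraction f_i
#' (via [simulateTrajectory()]) and a specific activity
#' `a_i = intercept + slope * f_i + eps_i`, `eps_i ~ N(0, noiseSd^2)`.
#' Negative generated activities are clamped at 0 and flagged.
#'
#' @param spec a [PanelSpec-class].
#' @param criteria a [ReactiveCriteria-class].
#' @return list with `trajectories` (named list of [Trajectory-class]),
#'   `activity` (data.frame in the [loadActivityTable()] layout: variant,
#'   substrate, activity, stderr, detectable, plus `clamped`), and
#'   `truth` (data.frame: variant, true_fraction, n_reactive_truth,
#'   noise, activity).
#' @export
simulatePanel <- function(spec, criteria = reactiveCriteria("DAP")) {
    stopifnot(is(spec, "PanelSpec"))
    validObject(spec)
    .withSeed(spec@seed, {
        labels <- sprintf("V%02d", seq_len(spec@nVariants))
        trajs <- vector("list", spec@nVariants)
        nTruth <- integer(spec@nVariants)
        for (i in seq_len(spec@nVariants)) {
            sim <- simulateTrajectory(spec@nFrames, spec@trueFractions[i],
                                      criteria)
            trajs[[i]] <- sim$trajectory
            trajs[[i]]@sourceLabel <- labels[i]
            nTruth[i] <- sum(sim$labels)
        }
        names(trajs) <- labels
        noise <- stats::rnorm(spec@nVariants, 0, spec@noiseSd)
        raw <- spec@intercept + spec@slope * spec@trueFractions + noise
        clamped <- raw < 0
        act <- pmax(raw, 0)
        list(trajectories = trajs,
             activity = data.frame(variant = labels,
                                   substrate = "synthetic",
                                   activity = act, stderr = NA_real_,
                                   detectable = TRUE, clamped = clamped,
                                   stringsAsFactors = FALSE),
             truth = data.frame(variant = labels,
                                true_fraction = spec@trueFractions,
                                n_reactive_truth = nTruth, noise = noise,
                                activity = act, stringsAsFactors = FALSE))
    })
}
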