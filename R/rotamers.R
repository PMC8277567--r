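# Covalent-ligand rotamer library construction: random dihedral
# perturbation about a fixed cofactor anchor, then greedy pruning by
# ordering score, distal-CA deviation and pairwise-RMSD uniqueness.

#' Construct a RotamerSpec
#'
#' Defaults follow the library-construction protocol: 10 000 candidates
#' drawn by uniform +/-30 degree perturbation of the rotatable side-chain
#' heavy-atom dihedrals with the alignment dihedral chi1 held at -90
#' degrees, pruned to at most 400 rotamers that are mutually distinct by
#' more than 0.0050 Angstrom heavy-atom RMSD and whose distal
#' alpha-carbon stays within 2.5 Angstrom of the reference.
#'
#' @param nCandidates candidates to generate.
#' @param dihedrals perturbable dihedral list (see [aldimineDihedrals()]).
#' @param uniquenessRmsdMin pairwise heavy-atom RMSD floor, Angstrom.
#' @param distalCaMaxDev distal alpha-carbon deviation cutoff, Angstrom.
#' @param libraryCap maximum retained rotamers (may be `Inf`).
#' @param chi1Init held chi1 value, degrees.
#' @param seed RNG seed for candidate generation.
#' @return a [RotamerSpec-class].
#' @export
rotamerSpec <- function(nCandidates = 10000L,
                        dihedrals = aldimineDihedrals(),
                        uniquenessRmsdMin = 0.0050, distalCaMaxDev = 2.5,
                        libraryCap = 400L, chi1Init = -90, seed = 1L) {
    new("RotamerSpec", nCandidates = as.integer(nCandidates),
        dihedrals = dihedrals, uniquenessRmsdMin = uniquenessRmsdMin,
        distalCaMaxDev = distalCaMaxDev, libraryCap = as.numeric(libraryCap),
        chi1Init = chi1Init, seed = as.integer(seed))
}

setMethod("show", "RotamerSpec", function(object) {
    cat(sprintf(paste0(
        "RotamerSpec: %d candidates, %d dihedral(s), RMSD floor %.4f A,\n",
        "  distal-CA cutoff %.1f A, cap %s, chi1 held at %.0f deg, seed %d\n"),
        object@nCandidates, length(object@dihedrals),
        object@uniquenessRmsdMin, object@distalCaMaxDev,
        format(object@libraryCap), object@chi1Init, object@seed))
})

.resolveIndices <- function(frame, selectors) {
    vapply(selectors, function(sel) {
        idx <- .matchSelector(frame@atoms, sel)
        if (length(idx) == 0L)
            stop("missing atom for selector ", sel$chain, "/", sel$resno,
                 "/", sel$name, call. = FALSE)
        if (length(idx) > 1L)
            stop("ambiguous selector ", sel$chain, "/", sel$resno, "/",
                 sel$name, call. = FALSE)
        idx
    }, integer(1L))
}

#' Set a torsion angle by rotating a moving set
#'
#' Rotates the atoms of `movingSet` about the axis through the second and
#' third atoms of `quad` so that the measured torsion equals `target`.
#' Atoms outside the moving set are untouched bitwise. If `anchorSet` is
#' given, a moving set intersecting it raises an anchor-violation error.
#'
#' @param frame an [AtomFrame-class].
#' @param quad list of 4 [atomSelector()]s defining the torsion.
#' @param target target torsion, signed degrees.
#' @param movingSet list of selectors for the atoms to rotate (must
#'   include the 4th quad atom for the torsion to change).
#' @param anchorSet optional list of selectors that must never move.
#' @return a new [AtomFrame-class].
#' @export
setDihedral <- function(frame, quad, target, movingSet, anchorSet = NULL) {
    stopifnot(is(frame, "AtomFrame"), length(quad) == 4L)
    qi <- .resolveIndices(frame, quad)
    mi <- .resolveIndices(frame, movingSet)
    if (!is.null(anchorSet)) {
        ai <- .resolveIndices(frame, anchorSet)
        if (length(intersect(mi, ai)))
            stop("anchor violation: moving set contains anchor atom(s) ",
                 paste(frame@atoms$name[intersect(mi, ai)], collapse = ", "),
                 call. = FALSE)
    }
    p <- lapply(qi, function(i) frame@coords[i, ])
    current <- measureDihedral(p[[1L]], p[[2L]], p[[3L]], p[[4L]])
    delta <- target - current
    if (abs(delta) < 1e-12)
        return(frame)
    xyz <- frame@coords
    # rotating by +delta about b->c adds delta to the measured torsion
    xyz[mi, ] <- .rotateAbout(xyz[mi, , drop = FALSE], p[[2L]],
                              p[[3L]] - p[[2L]], delta)
    new("AtomFrame", atoms = frame@atoms, coords = xyz)
}

#' Generate perturbed rotamer candidates
#'
#' Draws `spec@nCandidates` conformers from the template by perturbing
#' each listed dihedral with an independent uniform deviate in
#' `[-maxPerturb, +maxPerturb]` degrees. Cofactor-anchor atoms (the
#' rolemap's `PLP_ANCHOR_SET`, if mapped) must not appear in any moving
#' set and keep bit-identical coordinates; chi1 is untouched and must
#' already equal `spec@chi1Init`.
#'
#' @param template an [AtomFrame-class] with chi1 pre-set to
#'   `spec@chi1Init`.
#' @param spec a [RotamerSpec-class].
#' @param rolemap a [RoleMap-class] (used for the chi1 check and anchor
#'   set); defaults to the synthetic fragment mapping.
#' @return list of [AtomFrame-class] candidates.
#' @export
generateCandidates <- function(template, spec,
                               rolemap = syntheticRoleMap()) {
    stopifnot(is(template, "AtomFrame"), is(spec, "RotamerSpec"))
    validObject(spec)
    r <- resolveRoles(template, rolemap)
    chi1 <- measureDihedral(r$C50$xyz, r$N99$xyz, r$CA$xyz, r$C80$xyz)
    if (abs(chi1 - spec@chi1Init) > 1e-6)
        stop("template chi1 (", format(chi1), " deg) is not pre-set to ",
             spec@chi1Init, " deg", call. = FALSE)
    anchorIdx <- if (!is.null(r$PLP_ANCHOR_SET))
        vapply(r$PLP_ANCHOR_SET, `[[`, integer(1L), "index") else integer()
    dihedrals <- lapply(spec@dihedrals, function(d) {
        mi <- .resolveIndices(template, d$moving)
        if (length(intersect(mi, anchorIdx)))
            stop("anchor violation: a moving set contains cofactor-anchor ",
                 "atom(s)", call. = FALSE)
        list(qi = .resolveIndices(template, d$quad), mi = mi,
             bound = d$maxPerturb)
    })
    .withSeed(spec@seed, {
        lapply(seq_len(spec@nCandidates), function(k) {
            xyz <- template@coords
            for (d in dihedrals) {
                delta <- stats::runif(1L, -d$bound, d$bound)
                if (delta == 0) next
                b <- xyz[d$qi[2L], ]
                cc <- xyz[d$qi[3L], ]
                xyz[d$mi, ] <- .rotateAbout(xyz[d$mi, , drop = FALSE],
                                            b, cc - b, delta)
            }
            new("AtomFrame", atoms = template@atoms, coords = xyz)
        })
    })
}

.heavySelection <- function(frame, selection = NULL) {
    if (is.null(selection))
        which(toupper(frame@atoms$element) != "H")
    else .resolveIndices(frame, selection)
}

#' Heavy-atom RMSD without superposition
#'
#' Root-mean-square deviation over the selected atoms, computed in the
#' shared laboratory frame (no fitting: all rotamers share the fixed
#' cofactor anchor, so superposition would mask real differences).
#'
#' @param a,b [AtomFrame-class] objects with identical atom tables.
#' @param selection optional list of selectors; default all non-hydrogen
#'   atoms.
#' @return RMSD in Angstrom.
#' @export
heavyAtomRmsd <- function(a, b, selection = NULL) {
    stopifnot(is(a, "AtomFrame"), is(b, "AtomFrame"))
    if (!identical(a@atoms$name, b@atoms$name) ||
        !identical(a@atoms$resno, b@atoms$resno) ||
        !identical(a@atoms$chain, b@atoms$chain))
        stop("selection mismatch: frames differ in atom identity/order",
             call. = FALSE)
    idx <- .heavySelection(a, selection)
    d <- a@coords[idx, , drop = FALSE] - b@coords[idx, , drop = FALSE]
    sqrt(sum(d * d) / length(idx))
}

#' Non-bonded exclusions from an explicit bond list
#'
#' Expands a covalent bond list to all atom-name pairs within
#' `separation` bonds of each other (default 2, i.e. 1-2 and 1-3 pairs),
#' for use as [clashEnergy()] exclusions. Bond topology is always
#' supplied explicitly; it is never perceived from distances.
#'
#' @param bonds two-column character matrix of bonded atom-name pairs.
#' @param separation maximum graph distance to exclude.
#' @return two-column character matrix of excluded pairs.
#' @export
bondedExclusions <- function(bonds, separation = 2L) {
    adj <- split(c(bonds[, 2L], bonds[, 1L]), c(bonds[, 1L], bonds[, 2L]))
    nodes <- names(adj)
    out <- list()
    for (start in nodes) {
        dist <- stats::setNames(rep(Inf, length(nodes)), nodes)
        dist[start] <- 0
        queue <- start
        while (length(queue)) {
            v <- queue[1L]; queue <- queue[-1L]
            for (w in adj[[v]]) {
                if (dist[w] > dist[v] + 1L && dist[v] + 1L <= separation) {
                    dist[w] <- dist[v] + 1L
                    queue <- c(queue, w)
                }
            }
        }
        near <- names(dist)[is.finite(dist) & dist > 0]
        out[[start]] <- cbind(start, near)
    }
    ex <- do.call(rbind, out)
    ex[ex[, 1L] < ex[, 2L], , drop = FALSE]
}

#' Soft steric-clash score
#'
#' Sum over non-excluded atom pairs of a soft repulsive term: zero beyond
#' the contact distance and increasing monotonically as the pair distance
#' shrinks, `((contact - d) / contact)^2` for d < contact. Arbitrary
#' units, lower is better; deterministic. Used only to order candidates
#' for greedy retention during pruning.
#'
#' @param frame an [AtomFrame-class].
#' @param excludedPairs two-column character matrix of atom-name pairs to
#'   skip (typically [bondedExclusions()] of the covalent topology).
#' @param contactDist contact distance, Angstrom.
#' @return non-negative score.
#' @export
clashEnergy <- function(frame, excludedPairs = NULL, contactDist = 3.0) {
    stopifnot(is(frame, "AtomFrame"))
    n <- nrow(frame@coords)
    if (n < 2L) return(0)
    D <- as.matrix(stats::dist(frame@coords))
    skip <- matrix(FALSE, n, n)
    if (!is.null(excludedPairs) && nrow(excludedPairs)) {
        nm <- frame@atoms$name
        for (k in seq_len(nrow(excludedPairs))) {
            i <- which(nm == excludedPairs[k, 1L])
            j <- which(nm == excludedPairs[k, 2L])
            skip[i, j] <- TRUE
            skip[j, i] <- TRUE
        }
    }
    upper <- upper.tri(D) & !skip & D < contactDist
    sum(((contactDist - D[upper]) / contactDist)^2)
}

#' Prune a candidate set into a rotamer library
#'
#' Candidates are visited in ascending ordering-score (clash energy by
#' default); one is retained iff its distal alpha-carbon deviates by less
#' than `spec@distalCaMaxDev` from the reference's and its heavy-atom
#' RMSD to every already-retained rotamer exceeds
#' `spec@uniquenessRmsdMin`, stopping once `spec@libraryCap` rotamers are
#' retained. With an infinite cap and a zero RMSD floor this reduces to
#' the distal-CA filter alone.
#'
#' @param candidates list of [AtomFrame-class] objects sharing one atom
#'   table.
#' @param spec a [RotamerSpec-class].
#' @param reference [AtomFrame-class] supplying the reference distal
#'   alpha-carbon position (by default the construction template stands
#'   in for a docked reference).
#' @param rolemap a [RoleMap-class] mapping `DISTAL_CA`.
#' @param energies optional numeric ordering scores (lower first); when
#'   NULL, [clashEnergy()] is computed per candidate.
#' @param excludedPairs clash-energy exclusions; defaults to the 1-2/1-3
#'   pairs of the synthetic fragment topology.
#' @return a [RotamerLibrary-class].
#' @export
pruneLibrary <- function(candidates, spec, reference,
                         rolemap = syntheticRoleMap(), energies = NULL,
                         excludedPairs = bondedExclusions(fragmentBonds())) {
    if (!length(candidates))
        stop("empty candidate list", call. = FALSE)
    stopifnot(is(spec, "RotamerSpec"), is(reference, "AtomFrame"))
    if (is.null(rolemap@roles$DISTAL_CA))
        stop("missing atom for role DISTAL_CA: rolemap does not map it",
             call. = FALSE)
    refR <- resolveRoles(reference, rolemap)
    if (is.null(refR$DISTAL_CA))
        stop("missing atom for role DISTAL_CA in reference", call. = FALSE)
    refCad <- refR$DISTAL_CA$xyz
    cadIdx <- refR$DISTAL_CA$index
    if (is.null(energies))
        energies <- vapply(candidates, clashEnergy, numeric(1L),
                           excludedPairs = excludedPairs)
    stopifnot(length(energies) == length(candidates))

    heavy <- .heavySelection(candidates[[1L]])
    nh <- length(heavy)
    X <- t(vapply(candidates,
                  function(fr) as.vector(fr@coords[heavy, , drop = FALSE]),
                  numeric(3L * nh)))
    dev <- vapply(candidates,
                  function(fr) .norm3(fr@coords[cadIdx, ] - refCad),
                  numeric(1L))

    ord <- order(energies)
    retained <- integer()
    R <- matrix(numeric(), nrow = 0L, ncol = 3L * nh)
    for (k in ord) {
        if (length(retained) >= spec@libraryCap) break
        if (!(dev[k] < spec@distalCaMaxDev)) next
        if (nrow(R)) {
            rmsd <- sqrt(rowSums(sweep(R, 2L, X[k, ])^2) / nh)
            if (any(rmsd <= spec@uniquenessRmsdMin)) next
        }
        retained <- c(retained, k)
        R <- rbind(R, X[k, ])
    }
    new("RotamerLibrary", rotamers = candidates[retained],
        energies = energies[retained],
        referenceLabel = "construction template", spec = spec)
}

#' Number of rotamers in a library
#'
#' @param lib a [RotamerLibrary-class].
#' @return integer count.
#' @export
librarySize <- function(lib) {
    stopifnot(is(lib, "RotamerLibrary"))
    length(lib@rotamers)
}

#' Rotamers and ordering scores of a library
#'
#' @param lib a [RotamerLibrary-class].
#' @return `libraryRotamers`: list of [AtomFrame-class];
#'   `libraryEnergies`: numeric scores (lower = better).
#' @export
libraryRotamers <- function(lib) {
    stopifnot(is(lib, "RotamerLibrary"))
    lib@rotamers
}

#' @rdname libraryRotamers
#' @export
libraryEnergies <- function(lib) {
    stopifnot(is(lib, "RotamerLibrary"))
    lib@energies
}

setMethod("show", "RotamerLibrary", function(object) {
    cat("RotamerLibrary:", length(object@rotamers), "rotamer(s)")
    if (length(object@energies))
        cat(sprintf(", score range [%.3g, %.3g]",
                    min(object@energies), max(object@energies)))
    cat("\n  reference:", object@referenceLabel, "\n")
})

#' @describeIn writeModels write a rotamer library as multi-model PDB
#' @export
setMethod("writeModels", "RotamerLibrary", function(x, path, ...) {
    traj <- trajectoryFromFrames(x@rotamers, "rotamer library")
    writeModels(traj, path)
})
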