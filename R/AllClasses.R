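#' @import methods
NULL

.ATOM_COLS <- c("name", "element", "resname", "resno", "chain")

.validateAtomTable <- function(atoms) {
    if (!is.data.frame(atoms))
        return("'atoms' must be a data.frame")
    missing <- setdiff(.ATOM_COLS, names(atoms))
    if (length(missing))
        return(paste0("atom table lacks column(s): ",
                      paste(missing, collapse = ", ")))
    if (any(!nzchar(atoms$name)))
        return("atom names must be non-empty")
    if (any(nchar(atoms$chain) != 1L))
        return("chain identifiers must be single characters")
    key <- paste(atoms$chain, atoms$resno, atoms$name, sep = "|")
    if (anyDuplicated(key))
        return(paste0("duplicated (chain, resno, name) triple: ",
                      key[duplicated(key)][1L]))
    NULL
}

#' Single conformational snapshot of an atom set
#'
#' An `AtomFrame` holds one model's coordinates: an atom table (name,
#' element, residue name, residue number, chain) plus an n x 3 matrix of
#' Cartesian coordinates in Angstrom. Atom order is significant and the
#' (chain, resno, name) triple is unique within a frame.
#'
#' @slot atoms data.frame with columns `name`, `element`, `resname`,
#'   `resno`, `chain`, one row per atom.
#' @slot coords numeric matrix, one row per atom, columns x/y/z in Angstrom.
#'
#' @seealso [atomFrame()], [Trajectory-class], [getFrame()]
#' @exportClass AtomFrame
setClass("AtomFrame",
    representation(atoms = "data.frame", coords = "matrix"))

setValidity("AtomFrame", function(object) {
    msg <- .validateAtomTable(object@atoms)
    if (!is.null(msg)) return(msg)
    if (!is.numeric(object@coords) || ncol(object@coords) != 3L)
        return("'coords' must be a numeric matrix with 3 columns")
    if (nrow(object@coords) != nrow(object@atoms))
        return("'coords' and 'atoms' disagree on atom count")
    if (!all(is.finite(object@coords)))
        return("coordinates must be finite")
    TRUE
})

#' Ordered ensemble of conformational snapshots
#'
#' A `Trajectory` stores an ordered sequence of models sharing one atom
#' table: coordinates live in an n_atoms x 3 x n_frames array. All frames
#' therefore have identical atom count and identical (chain, resno, name)
#' ordering by construction; files violating this are rejected at read
#' time.
#'
#' @slot atoms shared atom table (see [AtomFrame-class]).
#' @slot coords numeric array `c(n_atoms, 3, n_frames)`, Angstrom.
#' @slot sourceLabel free-text provenance label.
#'
#' @seealso [readModels()], [writeModels()], [getFrame()], [nFrames()]
#' @exportClass Trajectory
setClass("Trajectory",
    representation(atoms = "data.frame", coords = "array",
                   sourceLabel = "character"))

setValidity("Trajectory", function(object) {
    msg <- .validateAtomTable(object@atoms)
    if (!is.null(msg)) return(msg)
    d <- dim(object@coords)
    if (length(d) != 3L || d[2L] != 3L)
        return("'coords' must be an n_atoms x 3 x n_frames array")
    if (d[1L] != nrow(object@atoms))
        return("'coords' and 'atoms' disagree on atom count")
    if (d[3L] < 1L)
        return("a Trajectory needs at least one frame")
    if (!all(is.finite(object@coords)))
        return("coordinates must be finite")
    if (length(object@sourceLabel) != 1L)
        return("'sourceLabel' must be a single string")
    TRUE
})

#' Mapping from mechanistic roles to atom selectors
#'
#' A `RoleMap` binds the mechanistic roles of the aldimine active site
#' (HZ, CA, H99, C50, N99, C80, OE1, H1, and optional DISTAL_CA, LYS_NZ,
#' MC1/MC2/MC3 anchors, PLP anchor set) to concrete atom selectors of the
#' form (chain, resno, atom name). Geometry code never hardcodes residue
#' numbers; all numbering differences are absorbed here.
#'
#' @slot roles named list; each element is a selector
#'   `list(chain=, resno=, name=)`, except `PLP_ANCHOR_SET` which is a
#'   list of such selectors.
#'
#' @seealso [roleMap()], [readRoleMap()], [resolveRoles()]
#' @exportClass RoleMap
setClass("RoleMap", representation(roles = "list"))

.REQUIRED_ROLES <- c("HZ", "CA", "H99", "C50", "N99", "C80", "OE1", "H1")
.OPTIONAL_ROLES <- c("DISTAL_CA", "LYS_NZ", "MC1_ANCHOR", "MC2_ANCHOR",
                     "MC3_ANCHOR", "PLP_ANCHOR_SET")

.validateSelector <- function(sel, role) {
    if (!is.list(sel) || !all(c("chain", "resno", "name") %in% names(sel)))
        return(paste0("selector for role ", role,
                      " must have fields chain, resno, name"))
    if (nchar(sel$chain) != 1L)
        return(paste0("selector for role ", role,
                      " must carry a single-character chain"))
    NULL
}

setValidity("RoleMap", function(object) {
    roles <- object@roles
    if (is.null(names(roles)) || any(!nzchar(names(roles))))
        return("all roles must be named")
    missing <- setdiff(.REQUIRED_ROLES, names(roles))
    if (length(missing))
        return(paste0("required role(s) missing: ",
                      paste(missing, collapse = ", ")))
    for (role in setdiff(names(roles), "PLP_ANCHOR_SET")) {
        msg <- .validateSelector(roles[[role]], role)
        if (!is.null(msg)) return(msg)
    }
    if ("PLP_ANCHOR_SET" %in% names(roles)) {
        for (sel in roles$PLP_ANCHOR_SET) {
            msg <- .validateSelector(sel, "PLP_ANCHOR_SET")
            if (!is.null(msg)) return(msg)
        }
    }
    TRUE
})

#' Threshold windows defining a reactive binding pose
#'
#' The four geometric criteria believed necessary for the C-alpha--COO-
#' cleavage step: upper bounds on d1 (proton donor to alpha-carbon) and d2
#' (cofactor protonation contact), an upper bound on theta1, and a signed
#' window on the alignment dihedral chi1. All comparisons are strict;
#' boundary values are non-reactive.
#'
#' @slot d1Max upper bound on d1, Angstrom.
#' @slot theta1Max upper bound on theta1, degrees.
#' @slot chi1Window numeric(2), lo < hi, signed degrees.
#' @slot d2Max upper bound on d2, Angstrom.
#' @slot label criteria-set name (e.g. substrate).
#'
#' @seealso [reactiveCriteria()], [classifyPose()]
#' @exportClass ReactiveCriteria
setClass("ReactiveCriteria",
    representation(d1Max = "numeric", theta1Max = "numeric",
                   chi1Window = "numeric", d2Max = "numeric",
                   label = "character"))

setValidity("ReactiveCriteria", function(object) {
    if (object@d1Max <= 0 || object@d2Max <= 0)
        return("distance bounds must be positive")
    if (object@theta1Max <= 0 || object@theta1Max > 180)
        return("theta1Max must lie in (0, 180]")
    w <- object@chi1Window
    if (length(w) != 2L || w[1L] >= w[2L] || w[1L] < -180 || w[2L] > 180)
        return("chi1Window must be (lo, hi) with -180 <= lo < hi <= 180")
    TRUE
})

#' Per-trajectory reactive-pose statistics
#'
#' @slot variantLabel variant/trajectory label.
#' @slot nFrames number of frames examined.
#' @slot nReactive frames passing all four criteria.
#' @slot fraction nReactive / nFrames.
#' @slot perCriterionPass named integer(4): frames passing each single
#'   criterion (d1, theta1, chi1, d2); each is >= nReactive.
#'
#' @seealso [summarizeTrajectory()]
#' @exportClass PoseSummary
setClass("PoseSummary",
    representation(variantLabel = "character", nFrames = "integer",
                   nReactive = "integer", fraction = "numeric",
                   perCriterionPass = "integer"))

setValidity("PoseSummary", function(object) {
    if (object@nReactive > object@nFrames)
        return("nReactive cannot exceed nFrames")
    if (abs(object@fraction - object@nReactive / object@nFrames) > 1e-12)
        return("fraction must equal nReactive / nFrames")
    if (!identical(sort(names(object@perCriterionPass)),
                   sort(c("d1", "theta1", "chi1", "d2"))))
        return("perCriterionPass must be named d1, theta1, chi1, d2")
    if (any(object@perCriterionPass < object@nReactive))
        return("each per-criterion count must be >= nReactive")
    TRUE
})

#' Generation and pruning parameters for a rotamer library
#'
#' @slot nCandidates number of perturbed candidates to draw (default 10000).
#' @slot dihedrals list of perturbable dihedrals; each element is
#'   `list(quad = <4 selectors>, moving = <selectors>, maxPerturb = deg)`.
#' @slot uniquenessRmsdMin minimum pairwise heavy-atom RMSD between
#'   retained rotamers, Angstrom (default 0.0050).
#' @slot distalCaMaxDev maximum distance the distal alpha-carbon may
#'   deviate from the reference rotamer, Angstrom (default 2.5).
#' @slot libraryCap maximum library size (default 400).
#' @slot chi1Init value the alignment dihedral chi1 is held at, degrees
#'   (default -90, the catalytically ideal value).
#' @slot seed RNG seed for candidate generation.
#'
#' @seealso [rotamerSpec()], [generateCandidates()], [pruneLibrary()]
#' @exportClass RotamerSpec
setClass("RotamerSpec",
    representation(nCandidates = "integer", dihedrals = "list",
                   uniquenessRmsdMin = "numeric", distalCaMaxDev = "numeric",
                   libraryCap = "numeric", chi1Init = "numeric",
                   seed = "integer"))

setValidity("RotamerSpec", function(object) {
    if (object@libraryCap < 1)
        return("libraryCap must be >= 1")
    if (is.finite(object@libraryCap) &&
        object@nCandidates < object@libraryCap)
        return("nCandidates must be >= libraryCap")
    if (object@uniquenessRmsdMin <= 0)
        return("uniquenessRmsdMin must be positive")
    if (object@distalCaMaxDev <= 0)
        return("distalCaMaxDev must be positive")
    for (d in object@dihedrals) {
        if (!all(c("quad", "moving", "maxPerturb") %in% names(d)))
            return("each dihedral needs fields quad, moving, maxPerturb")
        if (length(d$quad) != 4L)
            return("each dihedral quad needs exactly 4 selectors")
        if (d$maxPerturb < 0)
            return("maxPerturb must be >= 0")
    }
    TRUE
})

#' Pruned ensemble of aldimine conformers
#'
#' Retained rotamers share the fixed cofactor-anchor coordinates; all
#' pairwise heavy-atom RMSDs exceed the uniqueness threshold and every
#' rotamer's distal alpha-carbon lies within the stated deviation of the
#' reference. Energies are the (arbitrary-unit, lower-is-better) ordering
#' scores used during greedy retention.
#'
#' @slot rotamers list of [AtomFrame-class] objects.
#' @slot energies numeric, one score per retained rotamer.
#' @slot referenceLabel label of the reference rotamer used for the
#'   distal-CA cutoff.
#' @slot spec the [RotamerSpec-class] that produced the library.
#'
#' @seealso [pruneLibrary()], [writeModels()]
#' @exportClass RotamerLibrary
setClass("RotamerLibrary",
    representation(rotamers = "list", energies = "numeric",
                   referenceLabel = "character", spec = "RotamerSpec"))

setValidity("RotamerLibrary", function(object) {
    if (length(object@rotamers) != length(object@energies))
        return("one energy per rotamer required")
    if (length(object@rotamers) > object@spec@libraryCap)
        return("library exceeds its cap")
    TRUE
})

#' Pearson correlation between predictions and activities
#'
#' @slot r sample Pearson product-moment correlation, in [-1, 1].
#' @slot n number of paired observations (>= 3).
#' @slot pairs data.frame with columns `label`, `x`, `y`.
#'
#' @seealso [pearsonR()], [correlateWithActivity()]
#' @exportClass CorrelationResult
setClass("CorrelationResult",
    representation(r = "numeric", n = "integer", pairs = "data.frame"))

setValidity("CorrelationResult", function(object) {
    if (abs(object@r) > 1 + 1e-12)
        return("|r| must be <= 1")
    if (object@n < 3L)
        return("at least 3 paired observations required")
    TRUE
})

#' Parameters of a synthetic variant panel
#'
#' Describes a panel of enzyme variants for the generator: per-variant
#' true reactive fractions and a linear activity model
#' `activity = intercept + slope * fraction + Normal(0, noiseSd^2)`.
#'
#' @slot nVariants number of variants.
#' @slot nFrames frames per trajectory.
#' @slot trueFractions numeric in [0, 1], one per variant.
#' @slot intercept,slope activity model coefficients (mU/mg; slope per
#'   unit fraction).
#' @slot noiseSd standard deviation of the additive activity noise, mU/mg.
#' @slot seed RNG seed.
#'
#' @seealso [panelSpec()], [simulatePanel()]
#' @exportClass PanelSpec
setClass("PanelSpec",
    representation(nVariants = "integer", nFrames = "integer",
                   trueFractions = "numeric", intercept = "numeric",
                   slope = "numeric", noiseSd = "numeric", seed = "integer"))

setValidity("PanelSpec", function(object) {
    if (length(object@trueFractions) != object@nVariants)
        return("need one true fraction per variant")
    if (any(object@trueFractions < 0 | object@trueFractions > 1))
        return("true fractions must lie in [0, 1]")
    if (object@noiseSd < 0)
        return("noiseSd must be >= 0")
    if (object@nFrames < 1L)
        return("nFrames must be >= 1")
    TRUE
})
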