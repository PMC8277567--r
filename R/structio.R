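#' Construct an AtomFrame
#'
#' @param atoms data.frame with columns `name`, `element`, `resname`,
#'   `resno`, `chain`.
#' @param coords numeric n x 3 matrix of coordinates, Angstrom.
#' @return an [AtomFrame-class].
#' @examples
#' af <- atomFrame(
#'   data.frame(name = c("N", "CA"), element = c("N", "C"),
#'              resname = "GLY", resno = 1L, chain = "A"),
#'   rbind(c(0, 0, 0), c(1.47, 0, 0)))
#' @export
atomFrame <- function(atoms, coords) {
    coords <- as.matrix(coords)
    dimnames(coords) <- NULL
    storage.mode(coords) <- "double"
    atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
    rownames(atoms) <- NULL
    new("AtomFrame", atoms = atoms, coords = coords)
}

#' Assemble a Trajectory from frames
#'
#' All frames must share the same atom table (count, order and identity);
#' a mismatch raises a consistency error.
#'
#' @param frames list of [AtomFrame-class] objects.
#' @param sourceLabel free-text provenance label.
#' @return a [Trajectory-class].
#' @export
trajectoryFromFrames <- function(frames, sourceLabel = "") {
    if (!length(frames))
        stop("a Trajectory needs at least one frame", call. = FALSE)
    ref <- frames[[1L]]@atoms
    for (i in seq_along(frames)) {
        a <- frames[[i]]@atoms
        if (!identical(dim(a), dim(ref)) ||
            !all(a$name == ref$name & a$chain == ref$chain &
                 a$resno == ref$resno))
            stop("inconsistent atom composition at frame ", i, call. = FALSE)
    }
    arr <- array(0, dim = c(nrow(ref), 3L, length(frames)))
    for (i in seq_along(frames))
        arr[, , i] <- frames[[i]]@coords
    new("Trajectory", atoms = ref, coords = arr, sourceLabel = sourceLabel)
}

#' @describeIn nFrames frame count of a trajectory
#' @export
setMethod("nFrames", "Trajectory", function(x) dim(x@coords)[3L])

#' @describeIn getFrame extract the i-th model as an AtomFrame
#' @export
setMethod("getFrame", "Trajectory", function(x, i) {
    i <- as.integer(i)
    if (i < 1L || i > nFrames(x))
        stop("frame index ", i, " out of range", call. = FALSE)
    new("AtomFrame", atoms = x@atoms,
        coords = x@coords[, , i, drop = TRUE])
})

#' @describeIn atoms atom table of a frame
#' @export
setMethod("atoms", "AtomFrame", function(x) x@atoms)

#' @describeIn atoms shared atom table of a trajectory
#' @export
setMethod("atoms", "Trajectory", function(x) x@atoms)

#' @describeIn coords coordinates of a frame (n x 3)
#' @export
setMethod("coords", "AtomFrame", function(x) x@coords)

#' @describeIn coords coordinate array of a trajectory (n x 3 x m)
#' @export
setMethod("coords", "Trajectory", function(x) x@coords)

setMethod("show", "AtomFrame", function(object) {
    cat("AtomFrame with", nrow(object@atoms), "atoms\n")
    cat("  residues:",
        paste(unique(paste0(object@atoms$resname, object@atoms$resno)),
              collapse = " "), "\n")
})

setMethod("show", "Trajectory", function(object) {
    cat("Trajectory:", nFrames(object), "frame(s),",
        nrow(object@atoms), "atoms per frame\n")
    if (nzchar(object@sourceLabel))
        cat("  source:", object@sourceLabel, "\n")
})

.modelBlocks <- function(lines) {
    isAtom <- grepl("^(ATOM  |HETATM)", lines)
    modelStarts <- grep("^MODEL", lines)
    if (!length(modelStarts)) {
        if (!any(isAtom))
            stop("no ATOM/HETATM records found", call. = FALSE)
        return(list(which(isAtom)))
    }
    ends <- grep("^ENDMDL", lines)
    if (length(ends) != length(modelStarts))
        stop("unbalanced MODEL/ENDMDL records", call. = FALSE)
    lapply(seq_along(modelStarts), function(i) {
        idx <- seq(modelStarts[i] + 1L, ends[i] - 1L)
        idx[isAtom[idx]]
    })
}

.checkAtomLines <- function(lines, idx) {
    for (i in idx) {
        ln <- lines[i]
        for (fld in list(c(31L, 38L), c(39L, 46L), c(47L, 54L))) {
            val <- suppressWarnings(as.numeric(substr(ln, fld[1L], fld[2L])))
            if (is.na(val))
                stop("malformed coordinate field at line ", i, call. = FALSE)
        }
        if (!nzchar(trimws(substr(ln, 13L, 16L))))
            stop("empty atom name at line ", i, call. = FALSE)
    }
}

#' Read a multi-model PDB file as a Trajectory
#'
#' Reads a fixed-column PDB file (MODEL/ENDMDL dialect, or a single-model
#' file treated as a one-frame trajectory). Atom identity and ordering
#' must be identical across models; ragged files are rejected with a
#' consistency error and malformed coordinate fields with a line-numbered
#' parse error. Coordinate parsing is delegated to [bio3d::read.pdb()].
#'
#' Hydrogens are first-class atoms here: the pose descriptors involve
#' them, so files lacking the mapped hydrogens fail later at
#' [resolveRoles()], never silently.
#'
#' @param path path to a PDB file.
#' @param sourceLabel provenance label stored on the result (defaults to
#'   the file name).
#' @return a [Trajectory-class].
#' @seealso [writeModels()], [resolveRoles()]
#' @export
readModels <- function(path, sourceLabel = basename(path)) {
    if (!file.exists(path))
        stop("file not found: ", path, call. = FALSE)
    lines <- readLines(path, warn = FALSE)
    blocks <- .modelBlocks(lines)
    .checkAtomLines(lines, unlist(blocks))
    identity <- lapply(blocks, function(idx)
        paste(substr(lines[idx], 13L, 27L)))
    for (i in seq_along(identity)) {
        if (!identical(identity[[i]], identity[[1L]]))
            stop("inconsistent atom composition: model ", i,
                 " differs from model 1", call. = FALSE)
    }
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    atab <- data.frame(name = pdb$atom$elety,
                       element = pdb$atom$elesy,
                       resname = pdb$atom$resid,
                       resno = as.integer(pdb$atom$resno),
                       chain = pdb$atom$chain,
                       stringsAsFactors = FALSE)
    xyz <- pdb$xyz
    if (is.null(dim(xyz)))
        xyz <- matrix(xyz, nrow = 1L)
    nAtoms <- nrow(atab)
    nMod <- nrow(xyz)
    arr <- array(0, dim = c(nAtoms, 3L, nMod))
    for (j in seq_len(nMod))
        arr[, , j] <- matrix(xyz[j, ], ncol = 3L, byrow = TRUE)
    new("Trajectory", atoms = atab, coords = arr, sourceLabel = sourceLabel)
}

.writePdb <- function(atab, xyzMat, path) {
    bio3d::write.pdb(pdb = NULL, file = path, xyz = xyzMat,
                     type = rep("ATOM", nrow(atab)),
                     resno = atab$resno, resid = atab$resname,
                     eleno = seq_len(nrow(atab)), elety = atab$name,
                     chain = atab$chain, elesy = atab$element)
}

#' @describeIn writeModels write a Trajectory as MODEL/ENDMDL-delimited PDB
#' @export
setMethod("writeModels", "Trajectory", function(x, path, ...) {
    validObject(x)
    m <- nFrames(x)
    xyzMat <- t(apply(x@coords, 3L, function(fr) as.vector(t(fr))))
    if (m == 1L)
        xyzMat <- matrix(xyzMat, nrow = 1L)
    .writePdb(x@atoms, xyzMat, path)
    if (m == 1L) {
        # a one-frame trajectory is still a model-delimited ensemble
        lines <- readLines(path, warn = FALSE)
        atomIdx <- grep("^(ATOM|HETATM)", lines)
        lines <- append(lines, "ENDMDL", after = max(atomIdx))
        lines <- append(lines, "MODEL        1", after = min(atomIdx) - 1L)
        writeLines(lines, path)
    }
    invisible(path)
})

#' @describeIn writeModels write an AtomFrame as a single-model PDB
#' @export
setMethod("writeModels", "AtomFrame", function(x, path, ...) {
    validObject(x)
    .writePdb(x@atoms, matrix(as.vector(t(x@coords)), nrow = 1L), path)
    invisible(path)
})

#' Atom selector
#'
#' A selector names exactly one atom by (chain, residue number, atom
#' name). `NA` in a field acts as a wildcard; a selector must still
#' resolve to exactly one atom or [resolveRoles()] raises an ambiguity
#' error.
#'
#' @param chain single-character chain identifier (or NA).
#' @param resno residue number (or NA).
#' @param name atom name.
#' @return a selector list with fields `chain`, `resno`, `name`.
#' @export
atomSelector <- function(chain, resno, name) {
    list(chain = as.character(chain), resno = resno, name = name)
}

#' Construct a RoleMap
#'
#' @param ... named selectors (see [atomSelector()]), one per role.
#'   Required roles: HZ, CA, H99, C50, N99, C80, OE1, H1. Optional:
#'   DISTAL_CA, LYS_NZ, MC1_ANCHOR, MC2_ANCHOR, MC3_ANCHOR, and
#'   PLP_ANCHOR_SET (a list of selectors).
#' @return a [RoleMap-class].
#' @seealso [readRoleMap()], [syntheticRoleMap()]
#' @export
roleMap <- function(...) {
    new("RoleMap", roles = list(...))
}

#' Read a RoleMap from YAML
#'
#' Expected layout: a top-level `roles:` mapping each role to
#' `{chain: A, resno: 46, name: HZ}`; `PLP_ANCHOR_SET` maps to a list of
#' such entries.
#'
#' @param path path to a YAML file.
#' @return a [RoleMap-class].
#' @export
readRoleMap <- function(path) {
    y <- yaml::read_yaml(path)
    roles <- if (!is.null(y$roles)) y$roles else y
    roles <- lapply(stats::setNames(names(roles), names(roles)), function(nm) {
        v <- roles[[nm]]
        if (nm == "PLP_ANCHOR_SET")
            lapply(v, function(s) atomSelector(s$chain, s$resno, s$name))
        else atomSelector(v$chain, v$resno, v$name)
    })
    new("RoleMap", roles = roles)
}

#' Write a RoleMap to YAML
#'
#' @param x a [RoleMap-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeRoleMap <- function(x, path) {
    stopifnot(is(x, "RoleMap"))
    yaml::write_yaml(list(roles = x@roles), path)
    invisible(path)
}

setMethod("show", "RoleMap", function(object) {
    cat("RoleMap with roles:",
        paste(names(object@roles), collapse = ", "), "\n")
})

.matchSelector <- function(atab, sel) {
    hit <- rep(TRUE, nrow(atab))
    if (!is.na(sel$chain)) hit <- hit & atab$chain == sel$chain
    if (!is.na(sel$resno)) hit <- hit & atab$resno == sel$resno
    if (!is.na(sel$name)) hit <- hit & atab$name == sel$name
    which(hit)
}

#' Resolve a RoleMap against one frame
#'
#' Binds every mapped role to exactly one atom of the frame. A selector
#' matching no atom raises a missing-atom error naming the role; one
#' matching several atoms raises an ambiguity error.
#'
#' @param frame an [AtomFrame-class].
#' @param rolemap a [RoleMap-class].
#' @return named list; each element holds `index`, the atom's identity
#'   fields, and `xyz` (length-3 numeric). `PLP_ANCHOR_SET`, when mapped,
#'   resolves to a list of such bindings.
#' @export
resolveRoles <- function(frame, rolemap) {
    stopifnot(is(frame, "AtomFrame"), is(rolemap, "RoleMap"))
    atab <- frame@atoms
    bindOne <- function(sel, role) {
        idx <- .matchSelector(atab, sel)
        if (length(idx) == 0L)
            stop("missing atom for role ", role, " (selector ",
                 sel$chain, "/", sel$resno, "/", sel$name, ")",
                 call. = FALSE)
        if (length(idx) > 1L)
            stop("ambiguous selector for role ", role, ": matches ",
                 length(idx), " atoms", call. = FALSE)
        list(index = idx, name = atab$name[idx], chain = atab$chain[idx],
             resno = atab$resno[idx], xyz = as.numeric(frame@coords[idx, ]))
    }
    out <- list()
    for (role in names(rolemap@roles)) {
        if (role == "PLP_ANCHOR_SET") {
            out[[role]] <- lapply(rolemap@roles[[role]], bindOne,
                                  role = "PLP_ANCHOR_SET")
        } else {
            out[[role]] <- bindOne(rolemap@roles[[role]], role)
        }
    }
    out
}
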