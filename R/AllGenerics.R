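#' Number of frames in an ensemble
#'
#' @param x a [Trajectory-class].
#' @return integer frame count.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Extract one frame from an ensemble
#'
#' @param x a [Trajectory-class].
#' @param i frame index (1-based).
#' @return an [AtomFrame-class].
#' @export
setGeneric("getFrame", function(x, i) standardGeneric("getFrame"))

#' Atom table of a coordinate container
#'
#' @param x an [AtomFrame-class] or [Trajectory-class].
#' @return data.frame with columns name, element, resname, resno, chain.
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' Cartesian coordinates of a coordinate container
#'
#' @param x an [AtomFrame-class] or [Trajectory-class].
#' @return n x 3 matrix (frame) or n x 3 x m array (trajectory), Angstrom.
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' Write an ensemble to a multi-model PDB file
#'
#' @param x object to write ([Trajectory-class] or [RotamerLibrary-class]).
#' @param path output file path.
#' @param ... further arguments passed to methods.
#' @return `path`, invisibly.
#' @export
setGeneric("writeModels", function(x, path, ...) standardGeneric("writeModels"))
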