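#' Atomic model container
#'
#' A light-weight table of atoms aligned to the reference volume frame:
#' element, chain, residue id and Cartesian position in Angstrom (centred
#' coordinates, box centre at the origin).
#'
#' @param atoms data.frame with columns `element`, `chain`, `resid`, `x`,
#'   `y`, `z`.
#' @return an object of class `atomic_model`.
#' @export
atomic_model <- function(atoms) {
  need <- c("element", "chain", "resid", "x", "y", "z")
  if (!all(need %in% names(atoms)))
    stop("atoms must have columns element, chain, resid, x, y, z")
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("atom positions must be finite")
  structure(list(atoms = as.data.frame(atoms)), class = "atomic_model")
}

#' @export
print.atomic_model <- function(x, ...) {
  cat(sprintf("atomic_model: %d atoms, %d chain(s)\n", nrow(x$atoms),
              length(unique(x$atoms$chain))))
  invisible(x)
}

#' Read an atomic model from a PDB file
#'
#' Thin wrapper over `bio3d::read.pdb`; coordinates are used as stored
#' (assumed aligned to the reference map's centred frame).
#'
#' @param path PDB file path.
#' @return an [atomic_model()].
#' @export
read_pdb_model <- function(path) {
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom
  atomic_model(data.frame(element = a$elesy, chain = a$chain, resid = a$resno,
                          x = a$x, y = a$y, z = a$z,
                          stringsAsFactors = FALSE))
}

#' Write an atomic model to a PDB file
#'
#' @param mdl an [atomic_model()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb_model <- function(mdl, path) {
  a <- mdl$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resid, chain = as.character(a$chain),
                   resid = rep("GLY", nrow(a)),
                   elety = substr(paste0(a$element), 1, 2),
                   elesy = as.character(a$element))
  invisible(path)
}

#' Render an atomic model as a Gaussian density
#'
#' Places one isotropic Gaussian per atom — enough to test map/model
#' co-deformation exactly against pseudo-atomic phantoms.
#'
#' @param mdl an [atomic_model()].
#' @param box box size in voxels.
#' @param voxel_size Angstrom per voxel.
#' @param sigma Gaussian width in Angstrom (default 2 voxels).
#' @return a [volume_grid()].
#' @export
render_model <- function(mdl, box, voxel_size, sigma = 2 * voxel_size) {
  c0 <- floor(box / 2)
  ax <- ((0:(box - 1)) - c0) * voxel_size
  vals <- array(0, dim = c(box, box, box))
  gx <- array(rep(ax, times = box * box), dim = c(box, box, box))
  gy <- aperm(gx, c(2, 1, 3))
  gz <- aperm(gx, c(3, 2, 1))
  for (i in seq_len(nrow(mdl$atoms))) {
    d2 <- (gx - mdl$atoms$x[i])^2 + (gy - mdl$atoms$y[i])^2 +
      (gz - mdl$atoms$z[i])^2
    vals <- vals + exp(-d2 / (2 * sigma^2))
  }
  volume_grid(vals, voxel_size)
}
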