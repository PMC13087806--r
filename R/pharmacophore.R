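# Pharmacophore constraint points and pose checking.
#
# A pose satisfies a constraint point when at least one atom of the matching
# feature class lies within (inclusive) the point's radius of its center.
# Feature typing is deliberately simple and documented here: hydrogen-bond
# acceptors are oxygens of any kind plus nitrogens carrying no hydrogen
# (pyridine-type, with an available lone pair); donors are nitrogens or
# oxygens bearing at least one hydrogen. Constraint weights parameterize the
# docking score of the downstream docking engine and are carried as metadata
# only.

#' A pharmacophore constraint point
#'
#' @param feature `"HBA"` (acceptor) or `"HBD"` (donor).
#' @param center Numeric xyz, Angstrom, receptor frame.
#' @param radius Sphere radius, Angstrom (> 0).
#' @param weight Constraint weight (metadata; > 0).
#' @return `nah_pharmacophore_point` object.
#' @export
pharmacophore_point <- function(feature = c("HBA", "HBD"), center, radius,
                                weight = 10) {
  feature <- match.arg(feature)
  stopifnot(length(center) == 3, is.numeric(center), radius > 0, weight > 0)
  structure(list(feature = feature, center = as.numeric(center),
                 radius = radius, weight = weight),
            class = "nah_pharmacophore_point")
}

#' The default ATP-site pharmacophore constraint
#'
#' Two constraint points in the kinase ATP site used for docking-based
#' prioritization: a hydrogen-bond acceptor sphere (radius 0.7 A, weight 10,
#' centered at x = 34.7400, y = 4.8230, z = -70.2390) and a hydrogen-bond
#' donor sphere (radius 1.0 A, weight 10, centered at x = 32.8370,
#' y = 5.3580, z = -71.2780), both in the receptor coordinate frame.
#'
#' @return List of two `nah_pharmacophore_point` objects.
#' @export
default_pharmacophore <- function() {
  list(
    HBA = pharmacophore_point("HBA", c(34.7400, 4.8230, -70.2390),
                              radius = 0.7, weight = 10),
    HBD = pharmacophore_point("HBD", c(32.8370, 5.3580, -71.2780),
                              radius = 1.0, weight = 10)
  )
}

# Feature atom classes of a molecule (see header for the typing rules).
.feature_atoms <- function(mol) {
  elem <- mol$atoms$elem
  nh <- mol$atoms$nH
  list(
    HBA = which(elem == "O" | (elem == "N" & nh == 0L)),
    HBD = which((elem == "N" | elem == "O") & nh >= 1L)
  )
}

#' Construct a 3D pose
#'
#' @param mol An `nah_mol`.
#' @param coordinates Numeric matrix (n_atoms x 3), Angstrom, receptor frame.
#' @param feature_atoms Optional list with integer vectors `HBA` and `HBD`;
#'   by default perceived from the molecule.
#' @return `nah_pose` object.
#' @export
pose <- function(mol, coordinates, feature_atoms = NULL) {
  coordinates <- as.matrix(coordinates)
  stopifnot(nrow(coordinates) == nrow(mol$atoms), ncol(coordinates) == 3)
  if (is.null(feature_atoms)) feature_atoms <- .feature_atoms(mol)
  stopifnot(all(unlist(feature_atoms) %in% seq_len(nrow(mol$atoms))))
  structure(list(mol = mol, coordinates = coordinates,
                 feature_atoms = feature_atoms),
            class = "nah_pose")
}

#' Read poses from an SDF file with 3D coordinates
#'
#' Feature atoms are perceived with the simplified donor/acceptor typing
#' described in [check_pharmacophore()].
#'
#' @param path SDF file (V2000, 3D coordinates in the receptor frame).
#' @return List of `nah_pose` objects.
#' @export
read_poses <- function(path) {
  sdfs <- ChemmineR::read.SDFset(path)
  lapply(ChemmineR::cid(sdfs), function(id) {
    sdf <- sdfs[[id]]
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    elem <- sub("_.*$", "", rownames(ab))
    chg_code <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
                  `5` = -1L, `6` = -2L, `7` = -3L)
    charge <- if ("C6" %in% colnames(ab)) {
      chg_code[as.character(ab[, "C6"])]
    } else rep(0L, nrow(ab))
    atoms <- data.frame(elem = elem, charge = as.integer(charge))
    bonds <- data.frame(from = as.integer(bb[, 1]), to = as.integer(bb[, 2]),
                        order = pmin(as.integer(bb[, 3]), 3L))
    mol <- .mol_finalize(atoms, bonds)
    pose(mol, ab[, 1:3, drop = FALSE])
  })
}

#' Check a pose against pharmacophore constraint points
#'
#' A point is satisfied iff at least one atom of the matching feature class
#' lies within Euclidean distance <= radius of the point center (inclusive
#' boundary). A pose without feature atoms of a required class simply fails
#' that point. The check is invariant under any rigid-body transform applied
#' simultaneously to the pose and the points.
#'
#' @param pose An `nah_pose`.
#' @param points List of `nah_pharmacophore_point` (default:
#'   [default_pharmacophore()]).
#' @return List with `points` (data.frame feature, satisfied, min_distance)
#'   and `overall` (logical: all points satisfied).
#' @export
check_pharmacophore <- function(pose, points = default_pharmacophore()) {
  stopifnot(inherits(pose, "nah_pose"))
  rows <- lapply(points, function(p) {
    idx <- pose$feature_atoms[[p$feature]]
    if (length(idx) == 0) {
      return(data.frame(feature = p$feature, satisfied = FALSE,
                        min_distance = NA_real_))
    }
    d <- sqrt(colSums((t(pose$coordinates[idx, , drop = FALSE]) - p$center)^2))
    data.frame(feature = p$feature, satisfied = min(d) <= p$radius,
               min_distance = min(d))
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(points = tab, overall = all(tab$satisfied))
}

#' Apply a rigid-body transform to poses and points
#'
#' Utility for invariance checks: rotates then translates a pose's
#' coordinates, or a pharmacophore point's center.
#'
#' @param x An `nah_pose` or `nah_pharmacophore_point`.
#' @param rotation 3x3 rotation matrix.
#' @param translation Length-3 numeric.
#' @return Object of the same class, transformed.
#' @export
rigid_transform <- function(x, rotation = diag(3), translation = c(0, 0, 0)) {
  if (inherits(x, "nah_pose")) {
    x$coordinates <- sweep(x$coordinates %*% t(rotation), 2, -translation)
    x
  } else if (inherits(x, "nah_pharmacophore_point")) {
    x$center <- as.numeric(rotation %*% x$center + translation)
    x
  } else {
    stop("rigid_transform expects a pose or a pharmacophore point")
  }
}
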