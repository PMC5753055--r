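#' Idealized backbone geometry
#'
#' Bond lengths (Angstrom) and bond angles (degrees) used to build Cartesian
#' backbone coordinates from dihedrals. Defaults are standard idealized
#' peptide values; the ester-specific entries place the C-terminal methyl
#' ester oxygen. All values can be overridden, and the full table is carried
#' in the returned object so a build is reproducible from its inputs alone.
#'
#' @param ... Named overrides of the default entries (see
#'   `backbone_geometry()` output for names).
#' @return Object of class `"backbone_geometry"` (named list).
#' @export
backbone_geometry <- function(...) {
  g <- list(
    # bond lengths, Angstrom
    b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
    b_c_os = 1.337, b_n_h = 1.010, b_ca_ha = 1.090,
    # bond angles, degrees
    a_c_n_ca = 121.7, a_n_ca_c = 111.2, a_ca_c_n = 116.2,
    a_ca_c_o = 120.5, a_ca_c_os = 114.0)
  over <- list(...)
  bad <- setdiff(names(over), names(g))
  if (length(bad)) stop("unknown geometry entries: ", paste(bad, collapse = ", "))
  g[names(over)] <- over
  if (any(unlist(g[startsWith(names(g), "b_")]) <= 0))
    stop("bond lengths must be > 0")
  ang <- unlist(g[startsWith(names(g), "a_")])
  if (any(ang <= 0 | ang >= 180)) stop("bond angles must lie in (0, 180)")
  structure(g, class = "backbone_geometry")
}

# Place, for every frame at once, atom D given atoms A-B-C, bond length
# |C-D|, bond angle B-C-D and dihedral A-B-C-D (NeRF chain extension).
# a, b, c: n x 3 matrices; theta, chi in degrees (scalars or length-n).
place_atom <- function(a, b, c, bond, theta, chi) {
  th <- (180 - theta) * pi / 180   # supplement: angle from the BC direction
  ch <- chi * pi / 180
  bc <- c - b
  bc <- bc / sqrt(rowSums(bc^2))
  ab <- b - a
  n <- cbind(ab[, 2] * bc[, 3] - ab[, 3] * bc[, 2],
             ab[, 3] * bc[, 1] - ab[, 1] * bc[, 3],
             ab[, 1] * bc[, 2] - ab[, 2] * bc[, 1])
  n <- n / sqrt(rowSums(n^2))
  m <- cbind(n[, 2] * bc[, 3] - n[, 3] * bc[, 2],
             n[, 3] * bc[, 1] - n[, 1] * bc[, 3],
             n[, 1] * bc[, 2] - n[, 2] * bc[, 1])
  d_local_x <- bond * cos(th)
  d_local_y <- bond * sin(th) * cos(ch)
  d_local_z <- bond * sin(th) * sin(ch)
  c + bc * d_local_x + m * d_local_y + n * d_local_z
}

#' Build Cartesian coordinates from a dihedral ensemble
#'
#' Converts every frame's (phi, psi, omega) to backbone heavy-atom
#' coordinates (N, CA, C, O per residue) by sequential chain extension with
#' the idealized `geometry`. A Boc N-terminus contributes the cap carbonyl
#' carbon (residue 0), which realizes phi of residue 1; the methyl-ester
#' C-terminus contributes the ester oxygen OS, which realizes psi of the
#' last residue. Re-measuring dihedrals from the built coordinates with
#' [measure_dihedrals()] recovers the inputs (phi of residue 1 only when the
#' cap is present; omega of residue 1 is a fixed-trans convention and is not
#' rebuilt). Side chains are not built.
#'
#' @param dihedrals A `dihedral_ensemble`.
#' @param geometry A [backbone_geometry()].
#' @return Object of class `"ensemble_3d"`: list with `xyz` (an
#'   `n_frames x (3 * n_atoms)` matrix, Angstrom, bio3d-style layout
#'   x1,y1,z1,x2,...), `atoms` (data frame: `name`, `resno`, `resid`) and
#'   `spec`.
#' @export
build_coordinates <- function(dihedrals, geometry = backbone_geometry()) {
  stopifnot(inherits(dihedrals, "dihedral_ensemble"),
            inherits(geometry, "backbone_geometry"))
  spec <- dihedrals$spec
  n_res <- length(spec$sequence)
  nf <- dihedrals$n_frames
  has_cap <- spec$n_terminus == "boc"
  g <- geometry

  atoms <- list()
  coords <- list()   # each entry an nf x 3 matrix
  add <- function(xyz, name, resno, resid) {
    coords[[length(coords) + 1L]] <<- xyz
    atoms[[length(atoms) + 1L]] <<- data.frame(name = name, resno = resno,
                                               resid = resid)
  }
  rep3 <- function(x, y, z) cbind(rep(x, nf), rep(y, nf), rep(z, nf))

  deg <- pi / 180
  if (has_cap) {
    # seed triad: cap C, N1, CA1 in the z = 0 plane
    add(rep3(0, 0, 0), "C", 0L, "BOC")
    add(rep3(g$b_c_n, 0, 0), "N", 1L, spec$sequence[1])
    add(rep3(g$b_c_n - g$b_n_ca * cos(g$a_c_n_ca * deg),
             g$b_n_ca * sin(g$a_c_n_ca * deg), 0),
        "CA", 1L, spec$sequence[1])
    i_c_prev <- 1L; i_n <- 2L; i_ca <- 3L
    # C1 from cap-C, N1, CA1 with dihedral phi(1)
    add(place_atom(coords[[i_c_prev]], coords[[i_n]], coords[[i_ca]],
                   g$b_ca_c, g$a_n_ca_c, dihedrals$phi[, 1]),
        "C", 1L, spec$sequence[1])
  } else {
    # no cap: seed triad is N1, CA1, C1; phi(1) is not realizable
    add(rep3(0, 0, 0), "N", 1L, spec$sequence[1])
    add(rep3(g$b_n_ca, 0, 0), "CA", 1L, spec$sequence[1])
    add(rep3(g$b_n_ca - g$b_ca_c * cos(g$a_n_ca_c * deg),
             g$b_ca_c * sin(g$a_n_ca_c * deg), 0),
        "C", 1L, spec$sequence[1])
  }

  idx <- function(name, resno) {
    at <- do.call(rbind, atoms)
    which(at$name == name & at$resno == resno)
  }

  for (i in seq_len(n_res)) {
    i_n  <- idx("N", i); i_ca <- idx("CA", i); i_c <- idx("C", i)
    last <- i == n_res
    # next amide nitrogen (or ester oxygen) from psi(i)
    nxt <- place_atom(coords[[i_n]], coords[[i_ca]], coords[[i_c]],
                      if (last) g$b_c_os else g$b_c_n,
                      if (last) g$a_ca_c_os else g$a_ca_c_n,
                      dihedrals$psi[, i])
    # carbonyl O opposite the next in-chain atom
    add(place_atom(coords[[i_n]], coords[[i_ca]], coords[[i_c]],
                   g$b_c_o, g$a_ca_c_o, wrap_angle(dihedrals$psi[, i] + 180)),
        "O", i, spec$sequence[i])
    if (last) {
      add(nxt, "OS", n_res + 1L, "OME")
    } else {
      add(nxt, "N", i + 1L, spec$sequence[i + 1])
      i_n2 <- length(coords)
      add(place_atom(coords[[i_ca]], coords[[i_c]], coords[[i_n2]],
                     g$b_n_ca, g$a_c_n_ca, dihedrals$omega[, i + 1]),
          "CA", i + 1L, spec$sequence[i + 1])
      i_ca2 <- length(coords)
      add(place_atom(coords[[i_c]], coords[[i_n2]], coords[[i_ca2]],
                     g$b_ca_c, g$a_n_ca_c, dihedrals$phi[, i + 1]),
          "C", i + 1L, spec$sequence[i + 1])
    }
  }

  at <- do.call(rbind, atoms)
  n_atoms <- nrow(at)
  xyz <- matrix(NA_real_, nf, 3L * n_atoms)
  for (k in seq_len(n_atoms))
    xyz[, (3 * k - 2):(3 * k)] <- coords[[k]]
  if (any(!is.finite(xyz))) stop("non-finite coordinates produced")
  structure(list(xyz = xyz, atoms = at, spec = spec, geometry = g),
            class = "ensemble_3d")
}

#' @export
print.ensemble_3d <- function(x, ...) {
  cat("3D ensemble: ", nrow(x$xyz), " models x ", nrow(x$atoms),
      " atoms (", x$spec$label, ")\n", sep = "")
  invisible(x)
}

#' Coordinates of one atom across all models
#'
#' @param ensemble An `ensemble_3d`.
#' @param name Atom name (e.g. `"CA"`).
#' @param resno Residue number.
#' @return `n_models x 3` matrix of coordinates (Angstrom).
#' @export
atom_xyz <- function(ensemble, name, resno) {
  k <- which(ensemble$atoms$name == name & ensemble$atoms$resno == resno)
  if (length(k) != 1L)
    stop("atom ", name, " of residue ", resno, " not found in ensemble")
  ensemble$xyz[, (3 * k - 2):(3 * k), drop = FALSE]
}

# dihedral angle (degrees) for four n x 3 coordinate matrices
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cross <- function(u, v) cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                                u[, 3] * v[, 1] - u[, 1] * v[, 3],
                                u[, 1] * v[, 2] - u[, 2] * v[, 1])
  n1 <- cross(b1, b2); n2 <- cross(b2, b3)
  m1 <- cross(n1, b2 / sqrt(rowSums(b2^2)))
  x <- rowSums(n1 * n2); y <- rowSums(m1 * n2)
  # IUPAC sign convention (positive clockwise viewed from atom 2 to 3)
  wrap_angle(-atan2(y, x) * 180 / pi)
}

#' Re-measure backbone dihedrals from coordinates
#'
#' Computes phi, psi and omega for every residue of a built (or read)
#' `ensemble_3d` directly from the Cartesian coordinates. Angles whose
#' defining atoms are absent (phi of residue 1 without an N-terminal cap;
#' omega of residue 1) are `NA`. psi of the last residue is measured against
#' the ester oxygen OS when present.
#'
#' @param ensemble An `ensemble_3d`.
#' @return List of `n_frames x n_residues` matrices `phi`, `psi`, `omega`
#'   (degrees in (-180, 180]).
#' @export
measure_dihedrals <- function(ensemble) {
  stopifnot(inherits(ensemble, "ensemble_3d"))
  at <- ensemble$atoms
  n_res <- max(at$resno[at$name %in% c("N", "CA", "C")])
  nf <- nrow(ensemble$xyz)
  phi <- psi <- omega <- matrix(NA_real_, nf, n_res)
  has <- function(name, resno)
    any(at$name == name & at$resno == resno)
  for (i in seq_len(n_res)) {
    n_i  <- atom_xyz(ensemble, "N", i)
    ca_i <- atom_xyz(ensemble, "CA", i)
    c_i  <- atom_xyz(ensemble, "C", i)
    if (has("C", i - 1L))
      phi[, i] <- dihedral_angle(atom_xyz(ensemble, "C", i - 1L), n_i, ca_i, c_i)
    nxt <- if (i < n_res) {
      if (has("N", i + 1L)) atom_xyz(ensemble, "N", i + 1L) else NULL
    } else if (has("OS", n_res + 1L)) atom_xyz(ensemble, "OS", n_res + 1L) else NULL
    if (!is.null(nxt)) psi[, i] <- dihedral_angle(n_i, ca_i, c_i, nxt)
    if (i > 1L && has("CA", i - 1L))
      omega[, i] <- dihedral_angle(atom_xyz(ensemble, "CA", i - 1L),
                                   atom_xyz(ensemble, "C", i - 1L), n_i, ca_i)
  }
  list(phi = phi, psi = psi, omega = omega)
}
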