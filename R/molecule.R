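#' @useDynLib lmf12, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Bohr per Angstrom; the single place where the unit conversion lives.
.BOHR_PER_ANGSTROM <- 1.8897259886

.ELEMENTS <- c(H = 1, He = 2, C = 6, N = 7, O = 8)

#' Molecular geometry container
#'
#' Builds a molecule from element symbols and Cartesian coordinates.
#' Coordinates are stored internally in bohr; XYZ files are in Angstrom.
#'
#' @param symbols character vector of element symbols (H, He, C, N, O).
#' @param coords numeric n x 3 matrix of coordinates.
#' @param unit "angstrom" or "bohr".
#' @return An object of class `lmf12_molecule` with fields `symbols`,
#'   `coords` (bohr), `charges`, `n_electrons` and `nuclear_repulsion`
#'   (hartree).
#' @export
molecule <- function(symbols, coords, unit = c("angstrom", "bohr")) {
  unit <- match.arg(unit)
  coords <- matrix(as.numeric(coords), ncol = 3)
  if (length(symbols) != nrow(coords))
    stop("symbols and coords disagree in length")
  unknown <- setdiff(symbols, names(.ELEMENTS))
  if (length(unknown))
    stop("unsupported elements: ", paste(unknown, collapse = ", "))
  if (unit == "angstrom") coords <- coords * .BOHR_PER_ANGSTROM
  z <- unname(.ELEMENTS[symbols])
  enuc <- 0
  n <- length(z)
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      r <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      enuc <- enuc + z[i] * z[j] / r
    }
  }
  structure(list(symbols = symbols, coords = coords, charges = z,
                 n_electrons = sum(z), nuclear_repulsion = enuc),
            class = "lmf12_molecule")
}

#' @export
print.lmf12_molecule <- function(x, ...) {
  cat(sprintf("<lmf12_molecule> %d atoms (%s), %d electrons, Enuc = %.8f Eh\n",
              length(x$symbols), paste(x$symbols, collapse = ""),
              x$n_electrons, x$nuclear_repulsion))
  invisible(x)
}

#' Read an XYZ geometry file
#'
#' Standard XYZ: atom count, comment line, then `symbol x y z` in Angstrom.
#'
#' @param path file path.
#' @return an [molecule()] object.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  rows <- lines[seq(3, 2 + n)]
  parts <- strsplit(trimws(rows), "\\s+")
  sym <- vapply(parts, `[[`, "", 1)
  xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
  molecule(sym, xyz, unit = "angstrom")
}

#' Write an XYZ geometry file
#' @param mol a molecule.
#' @param path output path.
#' @param comment comment line.
#' @export
write_xyz <- function(mol, path, comment = "generated by lmf12") {
  ang <- mol$coords / .BOHR_PER_ANGSTROM
  lines <- c(sprintf("%d", length(mol$symbols)), comment,
             sprintf("%-2s %18.10f %18.10f %18.10f",
                     mol$symbols, ang[, 1], ang[, 2], ang[, 3]))
  writeLines(lines, path)
  invisible(path)
}

#' Rigidly transform a molecule
#' @param mol molecule.
#' @param shift length-3 translation in bohr.
#' @param axis,angle optional rotation axis (length 3) and angle (radians)
#'   applied before the translation.
#' @export
transform_molecule <- function(mol, shift = c(0, 0, 0), axis = NULL, angle = 0) {
  xyz <- mol$coords
  if (!is.null(axis) && angle != 0) {
    a <- axis / sqrt(sum(axis^2))
    K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
    R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
    xyz <- xyz %*% t(R)
  }
  xyz <- sweep(xyz, 2, -as.numeric(shift))
  molecule(mol$symbols, xyz, unit = "bohr")
}

#' Merge two molecules into one (no bonding implied)
#' @param a,b molecules.
#' @export
combine_molecules <- function(a, b) {
  molecule(c(a$symbols, b$symbols), rbind(a$coords, b$coords), unit = "bohr")
}

# ------------------------------------------------------------- fixtures

#' Generate deterministic test geometries
#'
#' Synthetic desk-scale stand-ins for large benchmark systems: hydrogen
#' bonded water chains, all-trans alkanes, and noble-gas pairs.  The seed
#' only controls an optional tiny symmetric-breaking jitter (off by
#' default), so identical calls give byte-identical geometries.
#'
#' @param kind one of "water_chain", "alkane", "noble_pair".
#' @param n number of repeat units (waters, carbons) or ignored for
#'   noble_pair.
#' @param separation for noble_pair: the interatomic distance in bohr.
#' @param seed integer seed for the jitter stream.
#' @param jitter amplitude (bohr) of random displacement, default 0.
#' @return an [molecule()] object.
#' @export
generate_fixture <- function(kind = c("water_chain", "alkane", "noble_pair"),
                             n = 1, separation = 5.6, seed = 1, jitter = 0) {
  kind <- match.arg(kind)
  if (n < 1) stop("n must be >= 1")
  if (kind == "noble_pair") {
    if (separation <= 0) stop("separation must be positive (bohr)")
    mol <- molecule(c("He", "He"),
                    rbind(c(0, 0, 0), c(0, 0, separation)), unit = "bohr")
  } else if (kind == "water_chain") {
    # O-H bond 0.9572 A, HOH angle 104.5 deg; chain of waters spaced along x
    # at a hydrogen-bonding O..O distance of 2.8 A, alternating orientation.
    roh <- 0.9572; ang <- 104.5 * pi / 180
    sym <- character(0); xyz <- NULL
    for (k in seq_len(n)) {
      ox <- (k - 1) * 2.8
      flip <- if (k %% 2 == 0) -1 else 1
      o <- c(ox, 0, 0)
      h1 <- o + c(roh * cos(ang / 2), flip * roh * sin(ang / 2), 0)
      h2 <- o + c(roh * cos(ang / 2), -flip * roh * sin(ang / 2) * 0.25,
                  flip * roh * sin(ang / 2) * 0.97)
      sym <- c(sym, "O", "H", "H")
      xyz <- rbind(xyz, o, h1, h2)
    }
    mol <- molecule(sym, xyz, unit = "angstrom")
  } else {
    # all-trans alkane C_n H_{2n+2}: zig-zag carbon backbone in the xz
    # plane, hydrogens placed in exact local tetrahedral frames
    rcc <- 1.526; rch <- 1.091; tet <- acos(-1 / 3)
    ch <- cos(tet / 2); sh <- sin(tet / 2)
    cs <- t(vapply(seq_len(n), function(k)
      c(ch * rcc * ((k - 1) %% 2), 0, sh * rcc * (k - 1)), numeric(3)))
    if (n == 1) {
      d <- rch / sqrt(3)
      xyz <- rbind(c(0, 0, 0), c(d, d, d), c(d, -d, -d), c(-d, d, -d),
                   c(-d, -d, d))
      sym <- c("C", "H", "H", "H", "H")
    } else {
      sym <- rep("C", n); xyz <- cs
      unit <- function(v) v / sqrt(sum(v^2))
      # three H on a chain-end carbon, tetrahedral about the C-C bond
      cap3 <- function(cc, u) {
        e1 <- unit(c(u[3], 0, -u[1]))        # perpendicular in the xz plane
        e2 <- c(0, 1, 0)
        t(vapply(0:2, function(m)
          cc + rch * (-u / 3 + sqrt(8) / 3 * (cos(2 * pi * m / 3) * e1 +
                                                sin(2 * pi * m / 3) * e2)),
          numeric(3)))
      }
      for (k in seq_len(n)) {
        if (k == 1) {
          hs <- cap3(cs[1, ], unit(cs[2, ] - cs[1, ]))
        } else if (k == n) {
          hs <- cap3(cs[n, ], unit(cs[n - 1, ] - cs[n, ]))
        } else {
          u1 <- unit(cs[k - 1, ] - cs[k, ]); u2 <- unit(cs[k + 1, ] - cs[k, ])
          b <- unit(-(u1 + u2))
          hs <- rbind(cs[k, ] + rch * (b * ch + c(0, 1, 0) * sh),
                      cs[k, ] + rch * (b * ch - c(0, 1, 0) * sh))
        }
        sym <- c(sym, rep("H", nrow(hs))); xyz <- rbind(xyz, hs)
      }
    }
    mol <- molecule(sym, xyz, unit = "angstrom")
  }
  if (jitter > 0) {
    set.seed(as.integer(seed))
    mol$coords <- mol$coords + matrix(stats::rnorm(length(mol$coords), 0, jitter),
                                      ncol = 3)
    mol <- molecule(mol$symbols, mol$coords, unit = "bohr")
  }
  mol
}
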