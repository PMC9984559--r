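## Torsion-angle containers and I/O.
##
## The torsion table (one row per frame x residue, phi/psi in degrees) is the
## canonical interchange format of the pipeline: everything downstream runs
## from it, so the whole system is testable without MD trajectory files.

#' Construct a torsion trajectory
#'
#' The universal currency of the pipeline: a frames x residues x 2 array of
#' backbone dihedral angles (phi, psi) in degrees, with per-frame timestamps
#' in picoseconds.
#'
#' @param angles Numeric array `c(n_frames, n_residues, 2)`; `[,,1]` is phi,
#'   `[,,2]` is psi, degrees. Values are wrapped into `[-180, 180)`.
#' @param times Numeric vector of frame timestamps (ps), strictly increasing.
#' @param residue_ids Integer vector of residue indices (default `1:n_residues`).
#' @param variant_id,gene Identifying labels.
#' @return An object of class `torsion_trajectory`.
#' @export
torsion_trajectory <- function(angles, times, residue_ids = NULL,
                               variant_id = "variant", gene = "gene") {
  if (length(dim(angles)) != 3 || dim(angles)[3] != 2)
    stop_dlrpmds("angles must be a frames x residues x 2 array")
  if (length(times) != dim(angles)[1])
    stop_dlrpmds("length(times) (%d) != number of frames (%d)",
                 length(times), dim(angles)[1])
  if (any(!is.finite(angles)))
    stop_dlrpmds("angles contain missing or non-finite values")
  if (length(times) > 1 && any(diff(times) <= 0))
    stop_dlrpmds("timestamps must be strictly increasing")
  if (is.null(residue_ids)) residue_ids <- seq_len(dim(angles)[2])
  if (length(residue_ids) != dim(angles)[2])
    stop_dlrpmds("residue_ids length mismatch")
  structure(
    list(variant_id = variant_id, gene = gene,
         times = as.numeric(times),
         angles = wrap_angle(angles),
         residue_ids = as.integer(residue_ids)),
    class = "torsion_trajectory")
}

#' @export
print.torsion_trajectory <- function(x, ...) {
  cat(sprintf("torsion_trajectory '%s' (%s): %d frames x %d residues, t = %g..%g ps\n",
              x$variant_id, x$gene, n_frames(x), n_residues(x),
              min(x$times), max(x$times)))
  invisible(x)
}

#' @rdname torsion_trajectory
#' @param traj A `torsion_trajectory`.
#' @export
n_frames <- function(traj) length(traj$times)

#' @rdname torsion_trajectory
#' @export
n_residues <- function(traj) dim(traj$angles)[2]

#' Signed dihedral angle of four points
#'
#' IUPAC convention: cis = 0 deg, trans reported as -180 (the half-open
#' `[-180, 180)` wrap). Looking along the p2->p3 bond, a clockwise rotation of
#' the far bond relative to the near bond is positive.
#'
#' @param p1,p2,p3,p4 Numeric length-3 coordinate vectors (Angstrom).
#' @return Dihedral angle in degrees in `[-180, 180)`.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b0 <- p1 - p2
  b1 <- p3 - p2
  b2 <- p4 - p3
  nb1 <- sqrt(sum(b1^2))
  if (nb1 < 1e-12) stop_dlrpmds("degenerate geometry: zero-length central bond")
  b1 <- b1 / nb1
  # components of the outer bonds orthogonal to the central bond
  v <- b0 - sum(b0 * b1) * b1
  w <- b2 - sum(b2 * b1) * b1
  if (sqrt(sum(v^2)) < 1e-9 || sqrt(sum(w^2)) < 1e-9)
    stop_dlrpmds("degenerate geometry: collinear points")
  x <- sum(v * w)
  y <- sum(c(b1[2] * v[3] - b1[3] * v[2],
             b1[3] * v[1] - b1[1] * v[3],
             b1[1] * v[2] - b1[2] * v[1]) * w)
  wrap_angle(atan2(y, x) * 180 / pi)
}

#' Read a torsion table
#'
#' Tab-separated text with header `frame time_ps residue phi psi`, one row per
#' (frame, residue); comment lines start with `#`. Angles are wrapped into
#' `[-180, 180)`. Every frame must contain the same residue set and a single
#' timestamp; timestamps must be strictly increasing in frame order.
#'
#' @param path File path.
#' @param variant_id,gene Labels attached to the trajectory (default: file name).
#' @return A [torsion_trajectory()].
#' @export
read_torsion_table <- function(path, variant_id = NULL, gene = "gene") {
  if (is.null(variant_id))
    variant_id <- sub("\\.[^.]*$", "", basename(path))
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  need <- c("frame", "time_ps", "residue", "phi", "psi")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_dlrpmds("torsion table '%s' is missing column(s): %s",
                 path, paste(miss, collapse = ", "))
  if (any(duplicated(df[c("frame", "residue")]))) {
    d <- which(duplicated(df[c("frame", "residue")]))[1]
    stop_dlrpmds("duplicated (frame, residue) pair at data row %d of '%s'", d, path)
  }
  frames <- sort(unique(df$frame))
  residues <- sort(unique(df$residue))
  # every frame must carry the full residue set
  tab <- table(df$frame)
  if (any(tab != length(residues))) {
    bad <- names(tab)[tab != length(residues)][1]
    stop_dlrpmds("frame %s of '%s' does not cover all %d residues",
                 bad, path, length(residues))
  }
  df <- df[order(df$frame, df$residue), ]
  times <- df$time_ps[!duplicated(df$frame)]
  if (any(tapply(df$time_ps, df$frame, function(t) length(unique(t))) != 1))
    stop_dlrpmds("inconsistent time_ps within a frame of '%s'", path)
  if (length(times) > 1 && any(diff(times) <= 0))
    stop_dlrpmds("timestamps not strictly increasing in '%s'", path)
  ang <- array(NA_real_, c(length(frames), length(residues), 2))
  ang[, , 1] <- matrix(df$phi, nrow = length(frames), byrow = TRUE)
  ang[, , 2] <- matrix(df$psi, nrow = length(frames), byrow = TRUE)
  torsion_trajectory(ang, times, residues, variant_id = variant_id, gene = gene)
}

#' Write a torsion table
#'
#' Inverse of [read_torsion_table()]; values round-trip to the printed
#' precision (6 decimals).
#'
#' @param traj A `torsion_trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_torsion_table <- function(traj, path) {
  nf <- n_frames(traj); nr <- n_residues(traj)
  phi <- matrix(traj$angles[, , 1], nrow = nf)
  psi <- matrix(traj$angles[, , 2], nrow = nf)
  df <- data.frame(
    frame = rep(seq_len(nf) - 1L, each = nr),
    time_ps = rep(traj$times, each = nr),
    residue = rep(traj$residue_ids, nf),
    phi = sprintf("%.6f", as.vector(t(phi))),
    psi = sprintf("%.6f", as.vector(t(psi))))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# torsion table: variant=%s gene=%s", traj$variant_id, traj$gene), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Select a time window of a trajectory
#'
#' Keeps frames with `start_ps <= t < end_ps` (half-open). With a 40 ns run
#' saved every 30 ps from t = 0, the last-10-ns window `[30000, 40000)`
#' contains exactly 334 frames.
#'
#' @param traj A `torsion_trajectory`.
#' @param start_ps,end_ps Window bounds in ps, `start_ps < end_ps`.
#' @return The windowed `torsion_trajectory`.
#' @export
select_window <- function(traj, start_ps, end_ps) {
  if (start_ps >= end_ps) stop_dlrpmds("start_ps must be < end_ps")
  keep <- traj$times >= start_ps & traj$times < end_ps
  if (!any(keep)) stop_dlrpmds("window [%g, %g) selects no frames", start_ps, end_ps)
  torsion_trajectory(traj$angles[keep, , , drop = FALSE], traj$times[keep],
                     traj$residue_ids, traj$variant_id, traj$gene)
}

#' Backbone phi/psi from atomic coordinates
#'
#' Thin adapter from raw coordinates to the canonical torsion table. Each
#' frame supplies N, CA, C coordinates per residue; phi(i) uses
#' C(i-1)-N(i)-CA(i)-C(i) and psi(i) uses N(i)-CA(i)-C(i)-N(i+1), so the two
#' terminal residues lack one angle each and are dropped (reported via the
#' `dropped_residues` attribute).
#'
#' @param coords Numeric array `c(n_frames, n_residues, 3 backbone atoms, 3)`;
#'   third dimension ordered N, CA, C.
#' @param times Frame timestamps (ps).
#' @param residue_ids Residue indices (default `1:n_residues`).
#' @param variant_id,gene Labels.
#' @return A [torsion_trajectory()] over residues `2..(n_residues-1)`.
#' @export
torsion_from_coords <- function(coords, times, residue_ids = NULL,
                                variant_id = "variant", gene = "gene") {
  d <- dim(coords)
  if (length(d) != 4 || d[3] != 3 || d[4] != 3)
    stop_dlrpmds("coords must be frames x residues x 3 atoms (N,CA,C) x 3 (xyz)")
  nf <- d[1]; nr <- d[2]
  if (nr < 3) stop_dlrpmds("need at least 3 residues to form phi/psi")
  if (is.null(residue_ids)) residue_ids <- seq_len(nr)
  keep <- 2:(nr - 1)
  ang <- array(NA_real_, c(nf, length(keep), 2))
  for (f in seq_len(nf)) {
    for (k in seq_along(keep)) {
      i <- keep[k]
      ang[f, k, 1] <- dihedral_angle(coords[f, i - 1, 3, ], coords[f, i, 1, ],
                                     coords[f, i, 2, ], coords[f, i, 3, ])
      ang[f, k, 2] <- dihedral_angle(coords[f, i, 1, ], coords[f, i, 2, ],
                                     coords[f, i, 3, ], coords[f, i + 1, 1, ])
    }
  }
  out <- torsion_trajectory(ang, times, residue_ids[keep], variant_id, gene)
  attr(out, "dropped_residues") <- residue_ids[-keep]
  out
}

#' Backbone torsions from a multi-model PDB file
#'
#' Optional adapter: reads a multi-model PDB (e.g. a trajectory exported as
#' models) with bio3d and emits the canonical trajectory via
#' [torsion_from_coords()]. Frame times are `(0:(n-1)) * dt_ps`.
#'
#' @param path PDB file with one MODEL per frame.
#' @param dt_ps Time between models (ps), default 30.
#' @param variant_id,gene Labels.
#' @return A [torsion_trajectory()].
#' @export
torsion_from_pdb <- function(path, dt_ps = 30, variant_id = NULL, gene = "gene") {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop_dlrpmds("torsion_from_pdb requires the 'bio3d' package")
  if (is.null(variant_id)) variant_id <- sub("\\.[^.]*$", "", basename(path))
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  sel <- bio3d::atom.select(pdb, elety = c("N", "CA", "C"))
  at <- pdb$atom[sel$atom, ]
  resnos <- unique(at$resno)
  xyz <- pdb$xyz[, sel$xyz, drop = FALSE]
  nf <- nrow(xyz); nr <- length(resnos)
  coords <- array(NA_real_, c(nf, nr, 3, 3))
  atom_order <- c(N = 1L, CA = 2L, C = 3L)
  for (a in seq_len(nrow(at))) {
    r <- match(at$resno[a], resnos)
    slot <- atom_order[[at$elety[a]]]
    coords[, r, slot, ] <- xyz[, (3 * a - 2):(3 * a)]
  }
  if (any(!is.finite(coords)))
    stop_dlrpmds("PDB '%s' is missing backbone atoms for some residues", path)
  torsion_from_coords(coords, times = (seq_len(nf) - 1) * dt_ps,
                      residue_ids = resnos, variant_id = variant_id, gene = gene)
}
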