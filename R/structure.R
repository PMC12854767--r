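#' Multi-frame XYZ trajectories and conjugation topologies
#'
#' `read_xyz_trajectory()` reads a concatenated multi-frame XYZ file
#' (repeated blocks of atom count, comment line, element x y z rows, all in
#' Angstrom). A comment line of the form `t = <fs>` (or containing
#' `time_fs=<fs>`) sets the frame time; otherwise frames are numbered with
#' unit spacing. `read_topology()` reads the conjugation-topology JSON with
#' keys `sigma_bonds` (5 pairs), `pi_bonds` (5 pairs) and `dihedrals`
#' (10 quadruples), all 0-based atom indices; indices are converted to
#' 1-based internally.
#'
#' @param path File path.
#' @return `read_xyz_trajectory()`: an `mpa_trajectory` list with `elements`
#'   (character), `coords` (n_atoms x 3 x n_frames array, Angstrom),
#'   `times_fs`. `read_topology()`: an `mpa_topology` list with
#'   `sigma_bonds`, `pi_bonds` (5 x 2 integer matrices) and `dihedrals`
#'   (10 x 4), 1-based.
#' @name trajectory_io
NULL

new_trajectory <- function(elements, coords, times_fs) {
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  if (any(!is.finite(coords))) {
    abort("non-finite coordinates", class = "mpaspec_validation_error")
  }
  structure(list(elements = elements, coords = coords, times_fs = times_fs),
            class = "mpa_trajectory")
}

#' @export
print.mpa_trajectory <- function(x, ...) {
  cat(sprintf("mpa_trajectory: %d atoms x %d frames (Angstrom)\n",
              dim(x$coords)[1], dim(x$coords)[3]))
  invisible(x)
}

#' @rdname trajectory_io
#' @export
read_xyz_trajectory <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("trajectory file not found: ", path),
          class = "mpaspec_io_error")
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) | seq_along(lines) %% 1 == 0]
  i <- 1L
  frames <- list(); comments <- character()
  while (i <= length(lines) && nzchar(trimws(lines[i]))) {
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat < 1L) {
      abort(sprintf("malformed XYZ: expected atom count at line %d", i),
            class = "mpaspec_io_error")
    }
    if (i + 1L + nat > length(lines)) {
      abort("malformed XYZ: truncated frame", class = "mpaspec_io_error")
    }
    comments <- c(comments, lines[i + 1L])
    block <- lines[(i + 2L):(i + 1L + nat)]
    parts <- strsplit(trimws(block), "\\s+")
    el <- vapply(parts, `[`, character(1), 1)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    frames[[length(frames) + 1L]] <- list(el = el, xyz = xyz)
    i <- i + 2L + nat
    while (i <= length(lines) && !nzchar(trimws(lines[i]))) i <- i + 1L
  }
  if (!length(frames)) {
    abort("no frames in XYZ file", class = "mpaspec_io_error")
  }
  nat <- vapply(frames, function(f) length(f$el), integer(1))
  if (length(unique(nat)) != 1L) {
    abort("atom count varies across frames", class = "mpaspec_io_error")
  }
  coords <- array(NA_real_, c(nat[1], 3, length(frames)))
  for (k in seq_along(frames)) coords[, , k] <- frames[[k]]$xyz
  tm <- regmatches(comments,
                   regexpr("(?:t *= *|time_fs *= *)([-0-9.eE+]+)", comments))
  times <- suppressWarnings(as.numeric(sub("^[^0-9.+-]*", "", tm)))
  if (length(times) != length(frames) || any(is.na(times))) {
    times <- as.numeric(seq_along(frames) - 1L)
  }
  new_trajectory(frames[[1]]$el, coords, times)
}

#' Write a multi-frame XYZ trajectory
#' @param traj An `mpa_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_xyz_trajectory <- function(traj, path) {
  con <- file(path, "w"); on.exit(close(con))
  nat <- dim(traj$coords)[1]
  for (k in seq_len(dim(traj$coords)[3])) {
    writeLines(as.character(nat), con)
    writeLines(sprintf("t = %.6f fs", traj$times_fs[k]), con)
    writeLines(sprintf("%-2s %18.10f %18.10f %18.10f", traj$elements,
                       traj$coords[, 1, k], traj$coords[, 2, k],
                       traj$coords[, 3, k]), con)
  }
  invisible(path)
}

new_topology <- function(sigma_bonds, pi_bonds, dihedrals, n_atoms = NULL) {
  sigma_bonds <- matrix(as.integer(sigma_bonds), ncol = 2)
  pi_bonds <- matrix(as.integer(pi_bonds), ncol = 2)
  dihedrals <- matrix(as.integer(dihedrals), ncol = 4)
  if (nrow(sigma_bonds) != 5L || nrow(pi_bonds) != 5L ||
      nrow(dihedrals) != 10L) {
    abort("topology must have 5 sigma bonds, 5 pi bonds, 10 dihedrals",
          class = "mpaspec_validation_error")
  }
  bonds <- rbind(sigma_bonds, pi_bonds)
  central <- dihedrals[, 2:3, drop = FALSE]
  match_bond <- function(pair) {
    any(apply(bonds, 1, function(b) all(b == pair) || all(rev(b) == pair)))
  }
  if (!all(apply(central, 1, match_bond))) {
    abort("each dihedral's central pair must be one of the sigma/pi bonds",
          class = "mpaspec_validation_error")
  }
  if (!is.null(n_atoms)) {
    idx <- c(bonds, dihedrals)
    if (any(idx < 1L) || any(idx > n_atoms)) {
      abort("topology indices outside atom range",
            class = "mpaspec_validation_error")
    }
  }
  structure(list(sigma_bonds = sigma_bonds, pi_bonds = pi_bonds,
                 dihedrals = dihedrals),
            class = "mpa_topology")
}

#' @rdname trajectory_io
#' @export
read_topology <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("topology file not found: ", path),
          class = "mpaspec_io_error")
  }
  j <- jsonlite::fromJSON(path)
  new_topology(as.matrix(j$sigma_bonds) + 1L, as.matrix(j$pi_bonds) + 1L,
               as.matrix(j$dihedrals) + 1L)
}

#' Write a conjugation topology as 0-based JSON
#' @param topo An `mpa_topology`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_topology <- function(topo, path) {
  jsonlite::write_json(
    list(indexing = "0-based",
         sigma_bonds = topo$sigma_bonds - 1L,
         pi_bonds = topo$pi_bonds - 1L,
         dihedrals = topo$dihedrals - 1L),
    path, auto_unbox = TRUE)
  invisible(path)
}

#' Bond length in a single frame
#'
#' Euclidean distance between two atoms, in Angstrom.
#'
#' @param frame n_atoms x 3 coordinate matrix (Angstrom).
#' @param pair Two 1-based atom indices.
#' @return Length in Angstrom.
#' @export
bond_length <- function(frame, pair) {
  d <- frame[pair[1], ] - frame[pair[2], ]
  len <- sqrt(sum(d^2))
  if (len == 0) {
    abort("identical atom positions: zero bond length",
          class = "mpaspec_validation_error")
  }
  len
}

#' Bond-length alternation
#'
#' \eqn{BLA = \frac{1}{5}\left[\sum_{i=1}^5 \sigma_i - \sum_{i=1}^5
#' \pi_i\right]}: the mean single-bond length minus the mean double-bond
#' length over the conjugated backbone.
#'
#' @param frame n_atoms x 3 coordinate matrix (Angstrom).
#' @param topo An `mpa_topology`.
#' @return BLA in Angstrom.
#' @export
bla <- function(frame, topo) {
  s <- apply(topo$sigma_bonds, 1, function(p) bond_length(frame, p))
  p <- apply(topo$pi_bonds, 1, function(p) bond_length(frame, p))
  (sum(s) - sum(p)) / 5
}

#' Dihedral angle of an atom quadruple
#'
#' IUPAC sign convention: looking down the b-c axis of quadruple (a, b, c,
#' d), the angle from the a-b-c half-plane to the b-c-d half-plane, positive
#' clockwise; range (-180, 180] degrees. Computed with the atan2 form, which
#' is stable near 0 and 180 degrees.
#'
#' @param frame n_atoms x 3 coordinate matrix.
#' @param quad Four 1-based atom indices.
#' @return Angle in degrees, in (-180, 180].
#' @export
dihedral_angle <- function(frame, quad) {
  p <- frame[quad, , drop = FALSE]
  b1 <- p[2, ] - p[1, ]
  b2 <- p[3, ] - p[2, ]
  b3 <- p[4, ] - p[3, ]
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  if (sum(n1^2) < 1e-20 || sum(n2^2) < 1e-20) {
    abort("collinear atoms: dihedral undefined",
          class = "mpaspec_validation_error")
  }
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  ang <- -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Dihedral planarity statistic
#'
#' \eqn{P = \sum_{i=1}^{10} p_i = \sum_{i=1}^{10} \frac{||\theta_i| -
#' 90|}{90}} over the ten backbone dihedrals: each dihedral contributes 1
#' when planar (0 or 180 degrees) and 0 when fully twisted (+-90 degrees),
#' so P ranges from 0 (all perpendicular) to 10 (fully planar). Because the
#' absolute angle is taken first, the statistic is continuous across the
#' +-180 degree wrap.
#'
#' @inheritParams bla
#' @return P, dimensionless in \[0, 10\].
#' @export
planarity <- function(frame, topo) {
  th <- apply(topo$dihedrals, 1, function(q) dihedral_angle(frame, q))
  sum(planarity_component(th))
}

planarity_component <- function(theta_deg) {
  abs(abs(wrap_angle(theta_deg)) - 90) / 90
}

#' Per-frame structural descriptor timeline
#'
#' Evaluates every descriptor (sigma and pi bond lengths, BLA, the ten
#' dihedrals, planarity) on each trajectory frame.
#'
#' @param traj An `mpa_trajectory`.
#' @param topo An `mpa_topology` consistent with the trajectory's atoms.
#' @return An `mpa_timeline` tibble: `frame`, `time_fs`, `bla`, `planarity`,
#'   `sigma_1..5`, `pi_1..5`, `theta_1..10` (degrees in (-180, 180]).
#' @export
structure_timeline <- function(traj, topo) {
  n_at <- dim(traj$coords)[1]
  idx <- c(topo$sigma_bonds, topo$pi_bonds, topo$dihedrals)
  if (any(idx > n_at)) {
    abort("topology indices exceed trajectory atom count",
          class = "mpaspec_validation_error")
  }
  rows <- purrr::map_dfr(seq_len(dim(traj$coords)[3]), function(k) {
    fr <- traj$coords[, , k]
    s <- apply(topo$sigma_bonds, 1, function(p) bond_length(fr, p))
    p <- apply(topo$pi_bonds, 1, function(p) bond_length(fr, p))
    th <- apply(topo$dihedrals, 1, function(q) dihedral_angle(fr, q))
    out <- tibble(frame = k, time_fs = traj$times_fs[k],
                  bla = (sum(s) - sum(p)) / 5,
                  planarity = sum(planarity_component(th)))
    out[paste0("sigma_", 1:5)] <- as.list(s)
    out[paste0("pi_", 1:5)] <- as.list(p)
    out[paste0("theta_", 1:10)] <- as.list(th)
    out
  })
  structure(rows, class = c("mpa_timeline", class(rows)))
}

#' Descriptive summary of a structural timeline
#'
#' Mean, standard deviation and a Freedman-Diaconis histogram per
#' descriptor column; purely descriptive.
#'
#' @param timeline An `mpa_timeline`.
#' @param columns Descriptor columns to summarise (default `bla`,
#'   `planarity`).
#' @return List with `moments` (tibble) and `histograms` (named list of
#'   tibbles `mid`, `count`).
#' @export
timeline_summary <- function(timeline,
                             columns = c("bla", "planarity")) {
  moments <- purrr::map_dfr(columns, function(cl) {
    dplyr::mutate(moment_summary(timeline[[cl]]), descriptor = cl,
                  .before = 1)
  })
  histograms <- purrr::map(setNames(columns, columns), function(cl) {
    x <- timeline[[cl]]
    h <- graphics::hist(x, breaks = "FD", plot = FALSE)
    tibble(mid = h$mids, count = h$counts)
  })
  list(moments = moments, histograms = histograms)
}

#' Write a structural timeline as TSV
#' @param timeline An `mpa_timeline`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timeline <- function(timeline, path) {
  writeLines(paste0("# mpaspec structural timeline; units: Angstrom, ",
                    "degrees in (-180, 180]; indices 0-based in topology"),
             path)
  readr::write_tsv(as_tibble(timeline), path, append = TRUE,
                   col_names = TRUE, progress = FALSE)
  invisible(path)
}
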