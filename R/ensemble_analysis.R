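.spect_labels <- c("S0-closed-shell", "bright-pipi", "dark-npi", "triplet")

#' MCH assignment of a diagonal state
#'
#' Given the unitary relating the spin-free (MCH) basis to the diagonal
#' spin-mixed basis, returns the MCH spin component with maximal squared
#' overlap with the active diagonal state.
#'
#' @param U unitary matrix with MCH components as rows and diagonal states as
#'   columns.
#' @param active_diagonal active diagonal state index.
#' @return MCH spin-component index.
#' @export
mch_assignment <- function(U, active_diagonal) {
  which.max(Mod(U[, active_diagonal])^2)
}

#' Spectroscopic character classification
#'
#' Classifies a state by the magnitude of its transition dipole moment from
#' the ground state: above 0.05 a.u. it is a bright ppi* state, between
#' 1e-6 and 0.05 a.u. (both inclusive) a dark npi* state, and below 1e-6 a.u.
#' a triplet. The closed-shell ground state is always labelled `S0`.
#'
#' @param transition_dipole_magnitude dipole magnitude(s), a.u.; must be
#'   non-negative.
#' @param multiplicity spin multiplicity; 3 forces the triplet class.
#' @param is_ground logical; TRUE yields the ground-state class.
#' @param as_code return the integer class code instead of the label.
#' @return character label(s) from `S0-closed-shell`, `bright-pipi`,
#'   `dark-npi`, `triplet` (or codes 1-4).
#' @export
#' @examples
#' classify_spectroscopic(0.2)    # bright
#' classify_spectroscopic(0.01)   # dark
#' classify_spectroscopic(1e-7)   # triplet
classify_spectroscopic <- function(transition_dipole_magnitude,
                                   multiplicity = 1L, is_ground = FALSE,
                                   as_code = FALSE) {
  m <- transition_dipole_magnitude
  if (any(m < 0)) stop("transition dipole magnitude must be non-negative")
  ig <- rep_len(is_ground, length(m))
  mult <- rep_len(multiplicity, length(m))
  code <- ifelse(ig, 1L,
          ifelse(mult == 3L, 4L,
          ifelse(m > 0.05, 2L,
          ifelse(m >= 1e-6, 3L, 4L))))
  if (as_code) code else .spect_labels[code]
}

# class label of one trajectory snapshot under a representation
.traj_classes <- function(traj, representation, space) {
  switch(representation,
    diagonal = paste0("diag", traj$active),
    MCH = space$sf_labels[
      space$components$sf_index[traj$mch_comp]],
    spectroscopic = .spect_labels[traj$spect]
  )
}

#' Ensemble population traces
#'
#' Fraction of trajectories occupying each class at every grid time, counting
#' each trajectory by its active state mapped to the chosen representation
#' (classical occupations). Trajectories that terminated early in valid
#' terminal states are held in their terminal class for the remaining grid.
#'
#' @param trajectories list of `trajectory` objects (sharing one state space).
#' @param representation one of `"diagonal"`, `"MCH"`, `"spectroscopic"`.
#' @param grid time grid in fs; default the snapshot grid of the longest
#'   trajectory.
#' @return A `population_trace`: data frame with `time_fs` and one fraction
#'   column per class; attributes `representation`, `n_trajectories`,
#'   `classes`.
#' @export
ensemble_populations <- function(trajectories,
                                 representation = c("MCH", "diagonal",
                                                    "spectroscopic"),
                                 grid = NULL) {
  representation <- match.arg(representation)
  if (length(trajectories) == 0) stop("empty trajectory set")
  space <- trajectories[[1]]$space
  if (is.null(grid)) {
    grid <- trajectories[[which.max(vapply(trajectories, function(t)
      max(t$time_fs), numeric(1)))]]$time_fs
  }
  classes <- switch(representation,
    diagonal = paste0("diag", seq_len(space$n_components)),
    MCH = space$sf_labels,
    spectroscopic = .spect_labels
  )
  counts <- matrix(0L, length(grid), length(classes),
                   dimnames = list(NULL, classes))
  for (traj in trajectories) {
    cls <- .traj_classes(traj, representation, space)
    # held in the terminal class beyond the trajectory's own end
    idx <- findInterval(grid, traj$time_fs, rightmost.closed = FALSE)
    idx[idx < 1L] <- 1L
    idx[idx > length(cls)] <- length(cls)
    ci <- match(cls[idx], classes)
    counts[cbind(seq_along(grid), ci)] <- counts[cbind(seq_along(grid), ci)] + 1L
  }
  frac <- counts / length(trajectories)
  out <- data.frame(time_fs = grid, frac, check.names = FALSE)
  structure(out, representation = representation,
            n_trajectories = length(trajectories), classes = classes,
            class = c("population_trace", "data.frame"))
}

#' Filter trajectories by the validity rule
#'
#' Keeps trajectories that completed the full simulation time, plus early
#' terminated ones whose final contiguous residence (by MCH assignment) in
#' the closed-shell ground state or the lowest triplet lasted at least the
#' residence threshold.
#'
#' @param trajectories list of `trajectory` objects.
#' @param t_max_fs full simulation time (fs).
#' @param residence_threshold_fs minimum final residence in S0 or T1 (fs),
#'   default 15 fs.
#' @return list with elements `kept` and `discarded`.
#' @export
filter_trajectories <- function(trajectories, t_max_fs,
                                residence_threshold_fs = 15) {
  if (residence_threshold_fs < 0) stop("residence threshold must be >= 0")
  keep <- vapply(trajectories, function(traj) {
    if (traj$status == "completed" &&
        max(traj$time_fs) >= t_max_fs - 1e-9) return(TRUE)
    space <- traj$space
    sf <- space$components$sf_index[traj$mch_comp]
    valid_sf <- c(1L, if (space$n_triplets > 0) space$n_singlets + 1L)
    in_valid <- sf %in% valid_sf
    n <- length(in_valid)
    if (!in_valid[n]) return(FALSE)
    first <- n
    while (first > 1 && in_valid[first - 1]) first <- first - 1
    (traj$time_fs[n] - traj$time_fs[first]) >= residence_threshold_fs
  }, logical(1))
  list(kept = trajectories[keep], discarded = trajectories[!keep])
}

#' Hop statistics of an ensemble
#'
#' Tallies accepted hop events by transition class (internal conversion among
#' singlets or among triplets, intersystem crossing in either direction) and
#' frustrated attempts, and summarizes the SOC magnitudes and energy gaps at
#' accepted ISC hops.
#'
#' @param trajectories list of `trajectory` objects.
#' @return Object of class `hop_summary`: list with `counts` (named integer
#'   vector), `mean_soc_cm1`, `max_soc_cm1`, `mean_abs_de_ev` (NA when no ISC
#'   hop occurred), and the pooled hop event table `events`.
#' @export
hop_statistics <- function(trajectories) {
  ev <- do.call(rbind, lapply(seq_along(trajectories), function(i) {
    h <- trajectories[[i]]$hops
    if (nrow(h) == 0) return(NULL)
    h$traj <- i
    h
  }))
  counts <- c(`singlet IC` = 0L, `triplet IC` = 0L, `S->T ISC` = 0L,
              `T->S ISC` = 0L, frustrated = 0L)
  if (is.null(ev)) {
    return(structure(list(counts = counts, mean_soc_cm1 = NA_real_,
                          max_soc_cm1 = NA_real_, mean_abs_de_ev = NA_real_,
                          events = NULL), class = "hop_summary"))
  }
  acc <- ev[!ev$frustrated, , drop = FALSE]
  counts["frustrated"] <- sum(ev$frustrated)
  counts["singlet IC"] <- sum(acc$from_mult == 1 & acc$to_mult == 1)
  counts["triplet IC"] <- sum(acc$from_mult == 3 & acc$to_mult == 3)
  counts["S->T ISC"] <- sum(acc$from_mult == 1 & acc$to_mult == 3)
  counts["T->S ISC"] <- sum(acc$from_mult == 3 & acc$to_mult == 1)
  isc <- acc[acc$from_mult != acc$to_mult, , drop = FALSE]
  structure(list(
    counts = counts,
    mean_soc_cm1 = if (nrow(isc) > 0) mean(isc$soc_cm1) else NA_real_,
    max_soc_cm1 = if (nrow(isc) > 0) max(isc$soc_cm1) else NA_real_,
    mean_abs_de_ev = if (nrow(isc) > 0) mean(abs(isc$delta_e_ev)) else NA_real_,
    events = ev
  ), class = "hop_summary")
}

#' @export
print.hop_summary <- function(x, ...) {
  cat("hop statistics\n")
  for (nm in names(x$counts)) cat(sprintf("  %-11s %d\n", nm, x$counts[[nm]]))
  if (!is.na(x$mean_soc_cm1)) {
    cat(sprintf("  ISC hops: mean |SOC| %.1f cm^-1 (max %.1f), mean |dE| %.4f eV\n",
                x$mean_soc_cm1, x$max_soc_cm1, x$mean_abs_de_ev))
  }
  invisible(x)
}

#' Geometry descriptors
#'
#' `bond_length` returns the Euclidean distance between two atoms;
#' `out_of_plane_angle` returns the angle (degrees) between the bond vector
#' `anchor -> atom` and the least-squares plane of the given plane atoms.
#'
#' @param geometry numeric matrix (n_atoms x 3), Angstrom.
#' @param i,j atom indices.
#' @return bond length in the input length unit.
#' @export
#' @rdname descriptors
bond_length <- function(geometry, i, j) {
  geometry <- as.matrix(geometry)
  if (max(i, j) > nrow(geometry) || min(i, j) < 1) stop("invalid atom index")
  sqrt(sum((geometry[i, ] - geometry[j, ])^2))
}

#' @param atom index of the displaced (out-of-plane) atom.
#' @param anchor index of the atom the bond vector starts from; default the
#'   plane atom closest to `atom`.
#' @param plane_atoms indices (>= 3) of the atoms defining the reference
#'   plane; must not be collinear.
#' @return angle in degrees in [0, 90].
#' @export
#' @rdname descriptors
out_of_plane_angle <- function(geometry, atom, plane_atoms, anchor = NULL) {
  geometry <- as.matrix(geometry)
  if (length(plane_atoms) < 3) stop("need at least three plane atoms")
  P <- geometry[plane_atoms, , drop = FALSE]
  ctr <- colMeans(P)
  sv <- svd(sweep(P, 2, ctr))
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1e-300)) {
    stop("plane atoms are collinear; plane is undefined")
  }
  normal <- sv$v[, 3]
  if (is.null(anchor)) {
    d <- rowSums(sweep(P, 2, geometry[atom, ])^2)
    anchor <- plane_atoms[which.min(d)]
  }
  bond <- geometry[atom, ] - geometry[anchor, ]
  nb <- sqrt(sum(bond^2))
  if (nb == 0) stop("atom and anchor coincide")
  s <- abs(sum(bond * normal)) / nb
  asin(min(1, s)) * 180 / pi
}

#' Write a population trace as a delimited table
#'
#' Tab-separated export with a commented header carrying units and metadata.
#'
#' @param trace a `population_trace`.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_population_trace <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# population trace, representation: %s", attr(trace, "representation")),
    sprintf("# n_trajectories: %d", attr(trace, "n_trajectories")),
    "# time in fs, populations are dimensionless fractions"
  ), con)
  utils::write.table(as.data.frame(trace), con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
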