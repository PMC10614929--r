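# Trajectory analytics: per-residue lipid-contact frequencies, residues-
# in-contact time series with replicate aggregation, and Ca2+-lipid
# coordination events. All distances use the minimum-image convention in
# an orthorhombic box; hydrogens are excluded from contact determination
# by default (heavy-atom convention).

#' Parameters for contact and coordination analysis
#'
#' @param contact_cutoff protein-lipid contact cutoff in nm (default
#'   0.40, heavy-atom minimum distance).
#' @param coordination_cutoff ion-lipid coordination cutoff in nm (0.35).
#' @param sample_interval_ns frame sampling interval in ns (default 2).
#' @param analysis_window_ns length of the trailing analysis window in ns
#'   (default 1000, i.e. the final 1 microsecond).
#' @param lipid_oxygen_atoms atom names of the lipid phosphate oxygens
#'   considered as coordination partners.
#' @param exclude_hydrogens drop atoms whose name starts with H from
#'   contact determination (default `TRUE`).
#' @return object of class `contact_params`.
#' @export
contact_params <- function(contact_cutoff = 0.40,
                           coordination_cutoff = 0.35,
                           sample_interval_ns = 2,
                           analysis_window_ns = 1000,
                           lipid_oxygen_atoms = c("O13", "O14", "O11", "O12"),
                           exclude_hydrogens = TRUE) {
  stopifnot(contact_cutoff > 0, coordination_cutoff > 0,
            sample_interval_ns > 0, analysis_window_ns > 0)
  structure(list(contact_cutoff = contact_cutoff,
                 coordination_cutoff = coordination_cutoff,
                 sample_interval_ns = sample_interval_ns,
                 analysis_window_ns = analysis_window_ns,
                 lipid_oxygen_atoms = lipid_oxygen_atoms,
                 exclude_hydrogens = exclude_hydrogens),
            class = "contact_params")
}

#' Minimum-image distance in an orthorhombic box
#'
#' @param a,b numeric length-3 coordinates (nm) or n x 3 matrices.
#' @param box length-3 box edge lengths in nm.
#' @return Euclidean distance(s) to the nearest periodic image.
#' @export
min_image_distance <- function(a, b, box) {
  stopifnot(all(box > 0))
  if (is.null(dim(a))) a <- matrix(a, ncol = 3L)
  if (is.null(dim(b))) b <- matrix(b, ncol = 3L)
  d <- a - b
  d <- d - sweep(round(sweep(d, 2L, box, "/")), 2L, box, "*")
  sqrt(rowSums(d^2))
}

# Coordinates of selected atoms in one frame as an n x 3 matrix.
frame_coords <- function(traj, rows, f) {
  m <- traj$coords[rows, , f, drop = FALSE]
  dim(m) <- dim(m)[1:2]
  m
}

# Squared min-image distance matrix between two coordinate sets (one frame).
dist2_matrix <- function(xa, xb, box) {
  d2 <- matrix(0, nrow(xa), nrow(xb))
  for (k in 1:3) {
    dk <- outer(xa[, k], xb[, k], "-")
    dk <- dk - box[k] * round(dk / box[k])
    d2 <- d2 + dk * dk
  }
  d2
}

# Nearest-time subsampling of frames onto a regular interval grid.
sampled_frame_indices <- function(times_ps, interval_ns) {
  interval_ps <- interval_ns * 1000
  if (length(times_ps) == 1L) return(1L)
  grid <- seq(times_ps[1L], times_ps[length(times_ps)], by = interval_ps)
  unique(vapply(grid, function(t) which.min(abs(times_ps - t)), integer(1L)))
}

contact_atom_rows <- function(traj, params) {
  at <- traj$atoms
  heavy <- if (params$exclude_hydrogens) !grepl("^H", at$atom_name)
           else rep(TRUE, nrow(at))
  lipid <- at$category %in% c("lipid_PS", "lipid_PC") & heavy
  list(protein = which(at$category == "protein" & heavy),
       lipid_any = which(lipid),
       lipid_PS = which(lipid & at$category == "lipid_PS"),
       lipid_PC = which(lipid & at$category == "lipid_PC"),
       lipid_acyl = which(lipid & at$lipid_region == "acyl"))
}

# Per-frame logical matrix (frames x residues): residue has any atom
# within cutoff of any atom in lipid_rows.
residue_contact_matrix <- function(traj, frames, lipid_rows, cutoff,
                                   protein_rows) {
  resno <- traj$atoms$resno[protein_rows]
  resids <- sort(unique(resno))
  grp <- match(resno, resids)
  out <- matrix(FALSE, length(frames), length(resids),
                dimnames = list(NULL, resids))
  if (length(lipid_rows) == 0L || length(protein_rows) == 0L) return(out)
  cut2 <- cutoff^2
  for (i in seq_along(frames)) {
    f <- frames[i]
    d2 <- dist2_matrix(frame_coords(traj, protein_rows, f),
                       frame_coords(traj, lipid_rows, f),
                       traj$box[f, ])
    amin <- apply(d2, 1L, min)
    out[i, ] <- vapply(seq_along(resids),
                       function(g) any(amin[grp == g] < cut2), logical(1L))
  }
  out
}

#' Per-residue lipid contact frequencies over the analysis window
#'
#' Restricts the trajectory to the trailing analysis window, subsamples
#' frames at the sampling interval, and reports for each protein residue
#' the percentage of analyzed frames in which any of its atoms lies within
#' the contact cutoff of any lipid atom, with splits for PS lipids, PC
#' lipids and lipid acyl-region atoms.
#'
#' @param traj an [md_trajectory()].
#' @param params a [contact_params()].
#' @return data.frame of class `contact_profile` with columns `residue`,
#'   `frequency_any`, `frequency_PS`, `frequency_PC`, `frequency_acyl`
#'   (percent); attribute `n_frames` gives the number of analyzed frames.
#' @export
residue_lipid_contact_frequency <- function(traj,
                                            params = contact_params()) {
  stopifnot(inherits(traj, "md_traj"), inherits(params, "contact_params"))
  span_ns <- (traj$times_ps[n_frames(traj)] - traj$times_ps[1L]) / 1000
  if (params$analysis_window_ns > span_ns + 1e-9)
    stopf("analysis window (%g ns) longer than trajectory span (%g ns)",
          params$analysis_window_ns, span_ns)
  t_start <- traj$times_ps[n_frames(traj)] - params$analysis_window_ns * 1000
  in_win <- which(traj$times_ps >= t_start - 1e-9)
  frames <- in_win[sampled_frame_indices(traj$times_ps[in_win],
                                         params$sample_interval_ns)]
  rows <- contact_atom_rows(traj, params)
  freq <- function(lipid_rows) {
    m <- residue_contact_matrix(traj, frames, lipid_rows,
                                params$contact_cutoff, rows$protein)
    100 * colMeans(m)
  }
  any_ <- freq(rows$lipid_any)
  out <- data.frame(residue = as.integer(names(any_)),
                    frequency_any = unname(any_),
                    frequency_PS = unname(freq(rows$lipid_PS)),
                    frequency_PC = unname(freq(rows$lipid_PC)),
                    frequency_acyl = unname(freq(rows$lipid_acyl)))
  attr(out, "n_frames") <- length(frames)
  class(out) <- c("contact_profile", "data.frame")
  out
}

#' Number of residues in membrane contact over time
#'
#' Counts, for every sampled frame of the whole trajectory, the number of
#' protein residues with at least one atom within the contact cutoff of
#' any lipid atom.
#'
#' @param traj an [md_trajectory()].
#' @param params a [contact_params()].
#' @param replicate replicate identifier recorded in the output.
#' @return data.frame with columns `time_ns`, `n_contacts`, `replicate`.
#' @export
residues_in_contact_timeseries <- function(traj,
                                           params = contact_params(),
                                           replicate = 1L) {
  stopifnot(inherits(traj, "md_traj"))
  frames <- sampled_frame_indices(traj$times_ps, params$sample_interval_ns)
  rows <- contact_atom_rows(traj, params)
  m <- residue_contact_matrix(traj, frames, rows$lipid_any,
                              params$contact_cutoff, rows$protein)
  data.frame(time_ns = traj$times_ps[frames] / 1000,
             n_contacts = as.integer(rowSums(m)),
             replicate = replicate)
}

#' Aggregate residues-in-contact series across replicates
#'
#' Replicate series must share an identical time grid (no interpolation).
#' Returns the pointwise mean and standard error (SD/sqrt(n)) across
#' replicates, plus each replicate's time-averaged contact count over the
#' trailing window with the mean and SD of those scalars.
#'
#' @param series_list list of >= 2 data.frames from
#'   [residues_in_contact_timeseries()].
#' @param window_ns trailing window for the time-averaged summary in ns
#'   (default 1000).
#' @return list with `curve` (data.frame: `time_ns`, `mean`, `se`),
#'   `replicate_means`, `mean`, `sd`, `n_replicates`.
#' @export
aggregate_replicates <- function(series_list, window_ns = 1000) {
  if (length(series_list) < 2L)
    stopf("at least two replicates are required")
  grids <- lapply(series_list, `[[`, "time_ns")
  if (!all(vapply(grids[-1L], identical, logical(1L), grids[[1L]])))
    stopf("replicate time grids do not match (interpolation not supported)")
  t <- grids[[1L]]
  counts <- vapply(series_list, `[[`, numeric(length(t)), "n_contacts")
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1L)
  n <- ncol(counts)
  mu <- rowMeans(counts)
  se <- apply(counts, 1L, sd) / sqrt(n)
  in_win <- t >= max(t) - window_ns + 1e-9
  rep_means <- colMeans(counts[in_win, , drop = FALSE])
  list(curve = data.frame(time_ns = t, mean = mu, se = se),
       replicate_means = rep_means, mean = mean(rep_means),
       sd = sd(rep_means), n_replicates = n)
}

#' Compare time-averaged membrane contacts between two conditions
#'
#' One-tailed two-sample Student t-test of the per-replicate scalar means,
#' testing for reduced binding in condition b (H1: mean(b) < mean(a));
#' `tails = 2` gives the two-tailed test. When both groups have zero
#' variance and equal means the one-tailed p-value is 0.5 by convention
#' (1 for two-tailed).
#'
#' @param cond_a,cond_b numeric vectors of per-replicate means (n >= 2).
#' @param tails 1 (default) or 2.
#' @return a `stat_result` (see [unpaired_t_test()]).
#' @export
compare_conditions <- function(cond_a, cond_b, tails = 1L) {
  res <- unpaired_t_test(cond_a, cond_b, tails = 2L)
  if (tails == 2L) return(res)
  t <- res$statistic
  p <- if (is.na(t)) NA_real_ else pt(t, res$df, lower.tail = FALSE)
  structure(list(test = "one-tailed two-sample Student t (H1: b < a)",
                 statistic = t, df = res$df, p_value = p, tails = 1L),
            class = "stat_result")
}

#' Maximal sub-cutoff runs in a distance series
#'
#' Core event scanner: given a per-frame distance series on a regular
#' grid, returns the maximal runs of consecutive frames with distance
#' strictly below the cutoff. Event duration is the run length times the
#' frame spacing (equivalently `t_end - t_start + dt`).
#'
#' @param distances numeric per-frame distances (nm).
#' @param times_ns frame times in ns (regular spacing).
#' @param cutoff distance cutoff in nm.
#' @return data.frame with `start`, `end` (frame indices), `t_start_ns`,
#'   `t_end_ns`, `duration_ns`.
#' @export
coordination_events_from_series <- function(distances, times_ns, cutoff) {
  stopifnot(length(distances) == length(times_ns))
  below <- distances < cutoff
  if (!any(below))
    return(data.frame(start = integer(), end = integer(),
                      t_start_ns = numeric(), t_end_ns = numeric(),
                      duration_ns = numeric()))
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  dt <- if (length(times_ns) > 1L) times_ns[2L] - times_ns[1L] else 1
  data.frame(start = starts[keep], end = ends[keep],
             t_start_ns = times_ns[starts[keep]],
             t_end_ns = times_ns[ends[keep]],
             duration_ns = (ends[keep] - starts[keep] + 1L) * dt)
}

#' Detect Ca2+-lipid coordination events
#'
#' For every (ion, lipid molecule) pair, an event is a maximal run of
#' consecutive sampled frames in which the minimum distance from the ion
#' to that lipid's phosphate oxygen atoms (named in
#' `params$lipid_oxygen_atoms`) is below the coordination cutoff
#' (0.35 nm). The same ion bridging two lipids simultaneously yields two
#' events. Also returns, per ion, the per-frame distance to the nearest
#' lipid atom of any type.
#'
#' @param traj an [md_trajectory()].
#' @param params a [contact_params()].
#' @return list with `events` (data.frame: `ion`, `lipid_resno`, `start`,
#'   `end`, `t_start_ns`, `t_end_ns`, `duration_ns`) and
#'   `nearest_lipid` (data.frame: `ion`, `time_ns`, `distance_nm`).
#' @export
detect_coordination_events <- function(traj, params = contact_params()) {
  stopifnot(inherits(traj, "md_traj"))
  at <- traj$atoms
  ions <- which(at$category == "ion_Ca")
  empty <- list(events = data.frame(ion = integer(), lipid_resno = integer(),
                                    start = integer(), end = integer(),
                                    t_start_ns = numeric(),
                                    t_end_ns = numeric(),
                                    duration_ns = numeric()),
                nearest_lipid = data.frame(ion = integer(),
                                           time_ns = numeric(),
                                           distance_nm = numeric()))
  if (length(ions) == 0L) return(empty)
  frames <- sampled_frame_indices(traj$times_ps, params$sample_interval_ns)
  times_ns <- traj$times_ps[frames] / 1000
  lipid_all <- which(at$category %in% c("lipid_PS", "lipid_PC"))
  oxy <- lipid_all[at$atom_name[lipid_all] %in% params$lipid_oxygen_atoms]
  oxy_mol <- at$resno[oxy]
  mols <- sort(unique(oxy_mol))
  # distances: frames x ions x oxygen atoms
  d_oxy <- array(NA_real_, dim = c(length(frames), length(ions), length(oxy)))
  nearest <- matrix(NA_real_, length(frames), length(ions))
  for (i in seq_along(frames)) {
    f <- frames[i]
    xi <- frame_coords(traj, ions, f)
    if (length(oxy) > 0L)
      d_oxy[i, , ] <- sqrt(dist2_matrix(xi, frame_coords(traj, oxy, f),
                                        traj$box[f, ]))
    nearest[i, ] <- sqrt(apply(dist2_matrix(
      xi, frame_coords(traj, lipid_all, f), traj$box[f, ]), 1L, min))
  }
  events <- list()
  for (k in seq_along(ions)) {
    for (m in mols) {
      cols <- which(oxy_mol == m)
      dmin <- apply(d_oxy[, k, cols, drop = FALSE], 1L, min)
      ev <- coordination_events_from_series(dmin, times_ns,
                                            params$coordination_cutoff)
      if (nrow(ev) > 0L) {
        ev$ion <- k
        ev$lipid_resno <- m
        events[[length(events) + 1L]] <- ev
      }
    }
  }
  events <- if (length(events) > 0L) {
    ev <- do.call(rbind, events)
    ev[order(ev$ion, ev$lipid_resno, ev$start),
       c("ion", "lipid_resno", "start", "end", "t_start_ns", "t_end_ns",
         "duration_ns")]
  } else empty$events
  rownames(events) <- NULL
  list(events = events,
       nearest_lipid = data.frame(
         ion = rep(seq_along(ions), each = length(frames)),
         time_ns = rep(times_ns, length(ions)),
         distance_nm = as.vector(nearest)))
}
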