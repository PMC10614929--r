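# Synthetic membrane-binding trajectories with exact planted truth.
#
# The membrane is a static schematic slab: one-atom lipid "molecules" on a
# square lateral grid at a fixed z, each tagged PS or PC and headgroup or
# acyl. A protein pseudo-residue contacts the membrane in a frame by being
# placed directly above a grid site of the scheduled lipid class/region at
# a distance drawn inside the contact cutoff; in unscheduled frames it sits
# at 1.5-3x the cutoff. Because the grid spacing (1 nm) exceeds every
# cutoff, the nearest lipid atom is always the designated site, so the
# schedule IS the truth, with guaranteed margins on both sides of the
# cutoff. Ion-lipid coordination episodes are planted the same way around
# the 0.35 nm coordination cutoff above a PS phosphate oxygen (O13).

#' Specification of a synthetic membrane-binding trajectory
#'
#' @param n_frames number of frames.
#' @param dt_ps frame spacing in ps (default 2000, i.e. 2 ns sampling).
#' @param box box edge lengths in nm (orthorhombic; default 14 x 14 x 14,
#'   the lateral size of the membrane patches being emulated).
#' @param residues integer ids of protein pseudo-residues.
#' @param contact_schedule data.frame with columns `residue`, `frame`
#'   (1-based), `class` (`"PS"` or `"PC"`), `region` (`"headgroup"` or
#'   `"acyl"`): the frames in which each residue is planted in contact.
#' @param n_ions number of Ca2+ ions.
#' @param ion_schedule data.frame with columns `ion`, `start`, `end`
#'   (1-based frame intervals during which the ion coordinates its partner
#'   PS phosphate oxygen below the coordination cutoff). Intervals of one
#'   ion must be disjoint and separated by at least one frame.
#' @param ps_fraction fraction of lipid sites tagged PS (default 0.3,
#'   matching a 30:70 PS:PC membrane).
#' @param lipid_spacing lateral grid spacing in nm (must exceed all
#'   cutoffs).
#' @param slab_z z position of the slab in nm.
#' @param contact_cutoff,coordination_cutoff cutoffs in nm that the planted
#'   distances straddle (defaults 0.40 and 0.35).
#' @param seed RNG seed for the planted distance draws.
#' @return object of class `traj_spec`.
#' @export
traj_spec <- function(n_frames, dt_ps = 2000, box = c(14, 14, 14),
                      residues = 1:10,
                      contact_schedule = NULL,
                      n_ions = 0L, ion_schedule = NULL,
                      ps_fraction = 0.3, lipid_spacing = 1.0,
                      slab_z = 2.0, contact_cutoff = 0.40,
                      coordination_cutoff = 0.35, seed = 1L) {
  stopifnot(n_frames >= 1L, dt_ps > 0, all(box > 0),
            lipid_spacing > max(contact_cutoff, coordination_cutoff))
  if (slab_z + 3 * contact_cutoff >= box[3L])
    stopf("scheduled distances not achievable inside the box",
          class = "guvmem_parameter_error")
  cs <- if (is.null(contact_schedule))
    data.frame(residue = integer(), frame = integer(),
               class = character(), region = character())
  else as.data.frame(contact_schedule)
  stopifnot(all(c("residue", "frame", "class", "region") %in% names(cs)))
  if (nrow(cs) > 0L) {
    if (any(cs$frame < 1L | cs$frame > n_frames))
      stopf("contact_schedule frame out of range [1, %d]", n_frames,
            class = "guvmem_parameter_error")
    if (!all(cs$class %in% c("PS", "PC")) ||
        !all(cs$region %in% c("headgroup", "acyl")))
      stopf("contact_schedule class/region labels invalid",
            class = "guvmem_parameter_error")
    if (anyDuplicated(cs[c("residue", "frame")]))
      stopf("contact_schedule has duplicate (residue, frame) entries",
            class = "guvmem_parameter_error")
    if (!all(cs$residue %in% residues))
      stopf("contact_schedule references unknown residues",
            class = "guvmem_parameter_error")
  }
  is_ <- if (is.null(ion_schedule))
    data.frame(ion = integer(), start = integer(), end = integer())
  else as.data.frame(ion_schedule)
  stopifnot(all(c("ion", "start", "end") %in% names(is_)))
  if (nrow(is_) > 0L) {
    if (any(is_$start < 1L | is_$end > n_frames | is_$start > is_$end))
      stopf("ion_schedule interval out of range [1, %d]", n_frames,
            class = "guvmem_parameter_error")
    if (any(is_$ion < 1L | is_$ion > n_ions))
      stopf("ion_schedule references unknown ions",
            class = "guvmem_parameter_error")
    for (i in unique(is_$ion)) {
      iv <- is_[is_$ion == i, , drop = FALSE]
      iv <- iv[order(iv$start), , drop = FALSE]
      if (nrow(iv) > 1L && any(iv$start[-1L] <= iv$end[-nrow(iv)] + 1L))
        stopf("ion %d has overlapping or adjacent intervals", i,
              class = "guvmem_parameter_error")
    }
  }
  structure(list(n_frames = as.integer(n_frames), dt_ps = dt_ps, box = box,
                 residues = as.integer(residues), contact_schedule = cs,
                 n_ions = as.integer(n_ions), ion_schedule = is_,
                 ps_fraction = ps_fraction, lipid_spacing = lipid_spacing,
                 slab_z = slab_z, contact_cutoff = contact_cutoff,
                 coordination_cutoff = coordination_cutoff, seed = seed),
            class = "traj_spec")
}

# Lipid site table for a spec: lateral grid, 30/70 PS/PC in a period-10
# pattern, regions alternating headgroup/acyl within the pattern.
lipid_sites <- function(spec) {
  nx <- floor(spec$box[1L] / spec$lipid_spacing)
  ny <- floor(spec$box[2L] / spec$lipid_spacing)
  i <- seq_len(nx * ny) - 1L
  n_ps <- max(1L, round(10 * spec$ps_fraction))
  class <- ifelse(i %% 10L < n_ps, "PS", "PC")
  region <- ifelse((i %/% 10L + i) %% 2L == 0L, "headgroup", "acyl")
  data.frame(
    site = i + 1L,
    x = (i %% nx + 0.5) * spec$lipid_spacing,
    y = (i %/% nx + 0.5) * spec$lipid_spacing,
    z = spec$slab_z,
    class = class, region = region,
    atom_name = ifelse(class == "PS" & region == "headgroup", "O13",
                ifelse(class == "PC" & region == "headgroup", "P", "C2A")),
    resname = ifelse(class == "PS", "DOPS", "DOPC"))
}

# Deterministic allocator of distinct sites of a given (class, region).
site_allocator <- function(sites) {
  used <- integer()
  function(class, region) {
    pool <- sites$site[sites$class == class & sites$region == region]
    free <- setdiff(pool, used)
    s <- if (length(free) > 0L) free[1L] else pool[1L]
    used <<- c(used, s)
    s
  }
}

#' Generate a synthetic trajectory with exact contact truth
#'
#' Deterministic under the spec's seed. Planted in-contact distances are
#' drawn uniformly in `[0.7, 0.95] * cutoff` and out-of-contact distances
#' in `[1.5, 3] * cutoff`, so downstream contact analysis at the same
#' cutoff recovers the schedule exactly. The returned `contact_truth`
#' holds per-residue contact-frame fractions (overall and split by PS, PC
#' and acyl) and the exact list of ion coordination events.
#'
#' @param spec a [traj_spec()].
#' @return list with elements `traj` ([md_trajectory()]) and `truth`
#'   (class `contact_truth`: `residues` data.frame, `events` data.frame
#'   with `ion`, `lipid_resno`, `start`, `end`, `t_start_ns`, `t_end_ns`,
#'   `duration_ns`).
#' @export
generate_trajectory <- function(spec) {
  stopifnot(inherits(spec, "traj_spec"))
  sites <- lipid_sites(spec)
  nf <- spec$n_frames
  n_res <- length(spec$residues)
  alloc <- site_allocator(sites)

  # site assignment: one per (residue, class, region) combination on demand
  key <- function(r, cl, rg) paste(r, cl, rg, sep = "|")
  site_of <- new.env(parent = emptyenv())
  cs <- spec$contact_schedule
  for (i in seq_len(nrow(cs))) {
    k <- key(cs$residue[i], cs$class[i], cs$region[i])
    if (!exists(k, envir = site_of, inherits = FALSE))
      site_of[[k]] <- alloc(cs$class[i], cs$region[i])
  }
  home <- vapply(spec$residues, function(r) {
    own <- cs[cs$residue == r, , drop = FALSE]
    if (nrow(own) > 0L) site_of[[key(r, own$class[1L], own$region[1L])]]
    else alloc("PC", "headgroup")
  }, integer(1L))
  ion_partner <- vapply(seq_len(spec$n_ions), function(i)
    alloc("PS", "headgroup"), integer(1L))

  # per-frame target site and distance for every residue and ion
  tgt <- matrix(rep(home, each = nf), nrow = nf)          # frames x residues
  in_contact <- matrix(FALSE, nf, n_res)
  res_idx <- match(cs$residue, spec$residues)
  for (i in seq_len(nrow(cs))) {
    tgt[cs$frame[i], res_idx[i]] <-
      site_of[[key(cs$residue[i], cs$class[i], cs$region[i])]]
    in_contact[cs$frame[i], res_idx[i]] <- TRUE
  }
  ion_on <- matrix(FALSE, nf, max(spec$n_ions, 1L))
  for (i in seq_len(nrow(spec$ion_schedule))) {
    iv <- spec$ion_schedule[i, ]
    ion_on[iv$start:iv$end, iv$ion] <- TRUE
  }

  cc <- spec$contact_cutoff
  kc <- spec$coordination_cutoff
  dists <- with_seed(spec$seed, {
    rd <- matrix(runif(nf * n_res), nf, n_res)
    rd <- ifelse(in_contact, (0.7 + 0.25 * rd) * cc, (1.5 + 1.5 * rd) * cc)
    id <- if (spec$n_ions > 0L) {
      m <- matrix(runif(nf * spec$n_ions), nf, spec$n_ions)
      ifelse(ion_on[, seq_len(spec$n_ions), drop = FALSE],
             (0.7 + 0.25 * m) * kc, (1.5 + 1.5 * m) * kc)
    } else matrix(0, nf, 0L)
    list(res = rd, ion = id)
  })

  # atom table: protein residues, then lipid sites, then ions
  n_lip <- nrow(sites)
  lip_resno_base <- max(spec$residues) + 100L
  atoms <- data.frame(
    index = seq_len(n_res + n_lip + spec$n_ions),
    atom_name = c(rep("CA", n_res), sites$atom_name,
                  rep("CA", spec$n_ions)),
    resno = c(spec$residues, lip_resno_base + sites$site,
              lip_resno_base + n_lip + seq_len(spec$n_ions)),
    resname = c(rep("GLY", n_res), sites$resname,
                rep("CA", spec$n_ions)),
    category = c(rep("protein", n_res),
                 ifelse(sites$class == "PS", "lipid_PS", "lipid_PC"),
                 rep("ion_Ca", spec$n_ions)),
    lipid_region = c(rep("n/a", n_res), sites$region,
                     rep("n/a", spec$n_ions)),
    stringsAsFactors = FALSE)

  coords <- array(0, dim = c(nrow(atoms), 3L, nf))
  lip_rows <- n_res + seq_len(n_lip)
  for (f in seq_len(nf)) {
    coords[lip_rows, , f] <- as.matrix(sites[c("x", "y", "z")])
    s <- tgt[f, ]
    coords[seq_len(n_res), , f] <-
      cbind(sites$x[s], sites$y[s], sites$z[s] + dists$res[f, ])
    if (spec$n_ions > 0L) {
      p <- ion_partner
      coords[n_res + n_lip + seq_len(spec$n_ions), , f] <-
        cbind(sites$x[p], sites$y[p], sites$z[p] + dists$ion[f, ])
    }
  }
  times_ps <- spec$dt_ps * (seq_len(nf) - 1L)
  traj <- md_trajectory(atoms, coords, times_ps, spec$box)

  # exact truth from the schedule
  frac <- function(sel) colSums(sel) / nf
  by_class <- function(cl) {
    m <- matrix(FALSE, nf, n_res)
    sub <- cs[cs$class == cl, , drop = FALSE]
    m[cbind(sub$frame, match(sub$residue, spec$residues))] <- TRUE
    m
  }
  by_region <- function(rg) {
    m <- matrix(FALSE, nf, n_res)
    sub <- cs[cs$region == rg, , drop = FALSE]
    m[cbind(sub$frame, match(sub$residue, spec$residues))] <- TRUE
    m
  }
  residues_truth <- data.frame(
    residue = spec$residues,
    frac_any = frac(in_contact),
    frac_PS = frac(by_class("PS")),
    frac_PC = frac(by_class("PC")),
    frac_acyl = frac(by_region("acyl")))

  dt_ns <- spec$dt_ps / 1000
  ev <- spec$ion_schedule
  events <- if (nrow(ev) > 0L) {
    ev <- ev[order(ev$ion, ev$start), , drop = FALSE]
    data.frame(ion = ev$ion,
               lipid_resno = lip_resno_base + ion_partner[ev$ion],
               start = ev$start, end = ev$end,
               t_start_ns = times_ps[ev$start] / 1000,
               t_end_ns = times_ps[ev$end] / 1000,
               duration_ns = (ev$end - ev$start + 1L) * dt_ns)
  } else data.frame(ion = integer(), lipid_resno = integer(),
                    start = integer(), end = integer(),
                    t_start_ns = numeric(), t_end_ns = numeric(),
                    duration_ns = numeric())
  truth <- structure(list(residues = residues_truth, events = events,
                          in_contact = in_contact),
                     class = "contact_truth")
  list(traj = traj, truth = truth)
}

#' Randomized trajectory specification emulating a binding simulation
#'
#' Convenience wrapper that drafts a contact schedule stochastically: each
#' listed interface residue is in contact in a given frame with probability
#' `contact_prob` (classes split `ps_bias` PS : rest PC, regions mostly
#' headgroup with `acyl_prob` acyl), emulating a protein settled on the
#' membrane through a basic-residue patch. Ions receive a few short
#' coordination episodes (1-3 frames, i.e. 2-6 ns at the default spacing).
#'
#' @param seed RNG seed.
#' @param n_frames,dt_ps trajectory length and spacing (defaults: 501
#'   frames at 2 ns, i.e. a 1 microsecond analysis window).
#' @param residues protein residue ids.
#' @param contact_residues subset of `residues` forming the interface.
#' @param contact_prob per-frame contact probability of interface residues.
#' @param ps_bias fraction of contacts through PS lipids.
#' @param acyl_prob fraction of contacts reaching the acyl region.
#' @param n_ions,n_ion_events ions and planted coordination episodes.
#' @return a [traj_spec()].
#' @export
sample_traj_spec <- function(seed, n_frames = 501L, dt_ps = 2000,
                             residues = 21:60,
                             contact_residues = c(30, 34, 37, 39, 54, 57),
                             contact_prob = 0.8, ps_bias = 0.8,
                             acyl_prob = 0.1, n_ions = 2L,
                             n_ion_events = 3L) {
  with_seed(seed + 1L, {
    cs <- do.call(rbind, lapply(contact_residues, function(r) {
      fr <- which(runif(n_frames) < contact_prob)
      if (length(fr) == 0L) return(NULL)
      data.frame(residue = r, frame = fr,
                 class = ifelse(runif(length(fr)) < ps_bias, "PS", "PC"),
                 region = ifelse(runif(length(fr)) < acyl_prob,
                                 "acyl", "headgroup"))
    }))
    is_ <- NULL
    if (n_ions > 0L && n_ion_events > 0L) {
      starts <- sort(sample.int(n_frames - 4L, n_ion_events)) + 1L
      keep <- c(TRUE, diff(starts) > 4L)
      starts <- starts[keep]
      is_ <- data.frame(ion = rep_len(seq_len(n_ions), length(starts)),
                        start = starts,
                        end = starts + sample(0:2, length(starts),
                                              replace = TRUE))
    }
    traj_spec(n_frames = n_frames, dt_ps = dt_ps, residues = residues,
              contact_schedule = cs, n_ions = n_ions, ion_schedule = is_,
              seed = seed)
  })
}
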