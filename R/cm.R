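# Conformational Memories: two-phase Monte-Carlo/simulated-annealing sampling
# of hinge-region backbone conformations.

KB_KCAL <- 0.0019872  # Boltzmann constant, kcal/(mol K)

#' Geometric simulated-annealing temperature ladder
#'
#' `T_i = t_start * (t_end / t_start)^(i / (n_steps - 1))`, i = 0..n_steps-1:
#' the first emitted temperature is exactly `t_start`, the last exactly
#' `t_end`.
#'
#' @param t_start,t_end start and end temperatures (Kelvin),
#'   `t_start >= t_end > 0`.
#' @param n_steps number of temperatures in the ladder.
#' @param mc_steps Monte-Carlo steps applied at each temperature
#'   (default 50000).
#' @return an `annealing_schedule` tibble with columns `step`, `temperature`.
#' @export
make_schedule <- function(t_start, t_end, n_steps, mc_steps = 50000) {
  if (t_end <= 0 || t_start < t_end) abort("need t_start >= t_end > 0")
  if (n_steps < 1) abort("n_steps must be >= 1")
  if (n_steps == 1 && t_start != t_end) {
    abort("a single-step schedule needs t_start == t_end")
  }
  temps <- if (n_steps == 1) t_start else {
    t_start * (t_end / t_start)^((seq_len(n_steps) - 1) / (n_steps - 1))
  }
  out <- tibble::tibble(step = seq_len(n_steps), temperature = temps)
  attr(out, "mc_steps") <- as.integer(mc_steps)
  class(out) <- c("annealing_schedule", class(out))
  out
}

#' Metropolis acceptance test
#'
#' Accepts with probability `min(1, exp(-delta_e / (kB T)))`; downhill moves
#' (`delta_e <= 0`) are always accepted.  Uses R's RNG, so results are
#' reproducible under `set.seed()`.
#'
#' @param delta_e energy change of the proposed move, kcal/mol.
#' @param temperature temperature in Kelvin (> 0).
#' @return logical: accept the move?
#' @export
metropolis_accept <- function(delta_e, temperature) {
  if (!is.finite(delta_e)) abort("delta_e must be finite")
  if (temperature <= 0) abort("temperature must be positive")
  delta_e <= 0 || runif(1) < exp(-delta_e / (KB_KCAL * temperature))
}

PROLINE_RANGES <- list(phi = c(-120, 40), psi = c(-70, 0), omega = c(-160, 160))

#' Define the sampled hinge region of a helix
#'
#' The hinge region is the hinge residue plus the four residues preceding it
#' (five residues).  By default phi and psi of every region residue are freed
#' over the full circle and omega is held at its current value; proline
#' residues instead get the proline dihedral windows
#' (-120 < phi < 40, -70 < psi < 0) with omega freed over (-160, 160).  The
#' N-CA-C bond angle of each region residue is free within
#' `+/- bond_angle_range` of its current value.
#'
#' @param h a `helix`.
#' @param hinge absolute residue index of the hinge residue.
#' @param n_before number of residues preceding the hinge to include
#'   (default 4).
#' @param dihedral_ranges optional tibble with columns `residue_index`,
#'   `name` (`"phi"`, `"psi"` or `"omega"`), `lo`, `hi` overriding the
#'   defaults (supplying a range for omega frees it).
#' @param bond_angle_range half-width, degrees, of the bond-angle window
#'   (default 8).
#' @return a `hinge_spec`: list with `hinge`, `region`, `dihedrals` and
#'   `bond_angles` tibbles.
#' @export
hinge_spec <- function(h, hinge, n_before = 4, dihedral_ranges = NULL,
                       bond_angle_range = 8) {
  h <- as_helix(h)
  res <- sort(unique(h$residue_index))
  region <- (hinge - n_before):hinge
  if (!all(region %in% res)) abort("hinge region extends outside the helix")
  if (!(hinge - n_before - 1) %in% res || !(hinge + 1) %in% res) {
    abort("hinge region needs a flanking residue on each side")
  }
  seq3 <- helix_sequence(h)
  ic <- internal_coords(h)
  dih <- purrr::map_dfr(region, function(i) {
    rn <- seq3[[as.character(i)]]
    if (rn == "PRO") {
      tibble::tibble(residue_index = i,
                     name = c("phi", "psi", "omega"),
                     lo = c(PROLINE_RANGES$phi[1], PROLINE_RANGES$psi[1],
                            PROLINE_RANGES$omega[1]),
                     hi = c(PROLINE_RANGES$phi[2], PROLINE_RANGES$psi[2],
                            PROLINE_RANGES$omega[2]))
    } else {
      tibble::tibble(residue_index = i, name = c("phi", "psi"),
                     lo = -180, hi = 180)
    }
  })
  if (!is.null(dihedral_ranges)) {
    dihedral_ranges <- tibble::as_tibble(dihedral_ranges)
    key <- paste(dih$residue_index, dih$name)
    okey <- paste(dihedral_ranges$residue_index, dihedral_ranges$name)
    dih <- dih[!key %in% okey, ]
    dih <- dplyr::bind_rows(dih, dihedral_ranges)
    dih <- dih[order(dih$residue_index, dih$name), ]
  }
  if (any(dih$lo < -180 | dih$hi > 180 | dih$lo >= dih$hi)) {
    abort("dihedral ranges must be proper subranges of (-180, 180]")
  }
  angles <- tibble::tibble(
    residue_index = region,
    center = ic$tau[match(region, ic$residue_index)],
    range = bond_angle_range)
  structure(list(hinge = hinge, region = region, dihedrals = dih,
                 bond_angles = angles), class = "hinge_spec")
}

# ---- degree-of-freedom topology -------------------------------------------

# Measurement atoms, rotation axis and rigidly moved atom block for one
# backbone degree of freedom.  Row indices refer to the helix atom table,
# which must be in residue order.
dof_topology <- function(h, residue, name) {
  res <- sort(unique(h$residue_index))
  k <- match(residue, res)
  idx <- function(ri, an) which(h$residue_index == ri & h$atom == an)[1]
  after <- which(h$residue_index > residue)
  this <- which(h$residue_index == residue)
  atom_of <- function(rows) h$atom[rows]
  if (name == "phi") {
    meas <- c(idx(res[k - 1], "C"), idx(residue, "N"), idx(residue, "CA"),
              idx(residue, "C"))
    moved <- c(this[!atom_of(this) %in% c("N", "CA")], after)
  } else if (name == "psi") {
    meas <- c(idx(residue, "N"), idx(residue, "CA"), idx(residue, "C"),
              idx(res[k + 1], "N"))
    moved <- c(this[atom_of(this) == "O"], after)
  } else if (name == "omega") {
    meas <- c(idx(res[k - 1], "CA"), idx(res[k - 1], "C"), idx(residue, "N"),
              idx(residue, "CA"))
    moved <- c(this[atom_of(this) != "N"], after)
  } else if (name == "tau") {
    meas <- c(idx(residue, "N"), idx(residue, "CA"), idx(residue, "C"))
    moved <- c(this[atom_of(this) %in% c("C", "O")], after)
  } else {
    abort(sprintf("unknown degree of freedom '%s'", name))
  }
  if (anyNA(meas)) {
    abort(sprintf("residue %d lacks the backbone atoms to define %s",
                  residue, name))
  }
  list(meas = meas, moved = moved)
}

dof_value <- function(h, residue, name) {
  top <- dof_topology(h, residue, name)
  p <- lapply(top$meas, function(i) as.numeric(h[i, c("x", "y", "z")]))
  if (name == "tau") bond_angle(p[[1]], p[[2]], p[[3]])
  else dihedral_angle(p[[1]], p[[2]], p[[3]], p[[4]])
}

# Set one degree of freedom to `target` by rigid rotation of its distal
# block.  Dihedral rotations are exact (both axis atoms lie on the rotation
# line, so every other internal coordinate is preserved); a bond-angle
# rotation additionally disturbs the adjacent psi and omega readings, which
# are restored afterwards so the move matches internal-coordinate semantics.
set_dof <- function(h, residue, name, target) {
  top <- dof_topology(h, residue, name)
  cur <- dof_value(h, residue, name)
  if (name == "tau") {
    res <- sort(unique(h$residue_index))
    k <- match(residue, res)
    has_next <- k < length(res)
    psi_old <- if (has_next) dof_value(h, residue, "psi") else NULL
    om_old <- if (has_next) dof_value(h, res[k + 1], "omega") else NULL
    xyz <- as.matrix(h[, c("x", "y", "z")])
    n <- xyz[top$meas[1], ]; ca <- xyz[top$meas[2], ]; c <- xyz[top$meas[3], ]
    axis <- cross3(n - ca, c - ca)
    xyz[top$moved, ] <- rotate_about_axis(xyz[top$moved, , drop = FALSE],
                                          ca, axis, target - cur)
    h$x <- xyz[, 1]; h$y <- xyz[, 2]; h$z <- xyz[, 3]
    if (has_next) {
      h <- set_dof(h, residue, "psi", psi_old)
      h <- set_dof(h, res[k + 1], "omega", om_old)
    }
  } else {
    xyz <- as.matrix(h[, c("x", "y", "z")])
    b <- xyz[top$meas[2], ]; c <- xyz[top$meas[3], ]
    xyz[top$moved, ] <- rotate_about_axis(xyz[top$moved, , drop = FALSE],
                                          c, c - b, -(wrap_angle(target - cur)))
    h$x <- xyz[, 1]; h$y <- xyz[, 2]; h$z <- xyz[, 3]
  }
  h
}

#' Propose one Monte-Carlo move
#'
#' Draws new values for two distinct free dihedrals (uniformly within their
#' allowed ranges, or within the retained memory bins in biased mode) and
#' perturbs one free bond angle uniformly within its window, leaving every
#' other coordinate unchanged.  Uses R's RNG.
#'
#' @param h a `helix`.
#' @param spec a [hinge_spec()].
#' @param memory optional memory map tibble (from a [run_cm()] exploratory
#'   phase) switching the proposal to biased mode.
#' @return the candidate `helix` with rebuilt Cartesian coordinates.
#' @export
propose_move <- function(h, spec, memory = NULL) {
  h <- as_helix(h)
  dih <- spec$dihedrals
  nvary <- min(2, nrow(dih))
  pick <- sample.int(nrow(dih), nvary)
  for (p in pick) {
    lo <- dih$lo[p]; hi <- dih$hi[p]
    if (!is.null(memory)) {
      bins <- memory[memory$residue_index == dih$residue_index[p] &
                       memory$name == dih$name[p] & memory$retained, ]
      if (nrow(bins) == 0) {
        abort("empty retained memory for a free dihedral: lower the retention threshold")
      }
      b <- bins[sample.int(nrow(bins), 1), ]
      lo <- b$bin_start; hi <- b$bin_end
    }
    h <- set_dof(h, dih$residue_index[p], dih$name[p], runif(1, lo, hi))
  }
  ang <- spec$bond_angles
  a <- sample.int(nrow(ang), 1)
  h <- set_dof(h, ang$residue_index[a], "tau",
               runif(1, ang$center[a] - ang$range[a],
                     ang$center[a] + ang$range[a]))
  h
}

# ---- kernel preparation ---------------------------------------------------

# Assemble kernel inputs: DOF descriptors, dynamic pair list and the static
# energy constant.
cm_prepare <- function(h, spec, params, cutoff_nb, cutoff_elec, dielectric) {
  h <- as_helix(h)
  n <- nrow(h)
  dof_specs <- function(rows, type) {
    purrr::map(seq_len(nrow(rows)), function(r) {
      if (type == "dihedral") {
        top <- dof_topology(h, rows$residue_index[r], rows$name[r])
        terms <- params$torsions[[rows$name[r]]]
        out <- list(meas = top$meas, moved = top$moved,
                    lo = rows$lo[r], hi = rows$hi[r],
                    init = dof_value(h, rows$residue_index[r], rows$name[r]))
        if (!is.null(terms) && nrow(terms)) {
          out$tor_A <- terms$amplitude; out$tor_n <- terms$periodicity
          out$tor_d <- terms$phase
        }
        out
      } else {
        ri <- rows$residue_index[r]
        top <- dof_topology(h, ri, "tau")
        out <- list(meas = top$meas, moved = top$moved,
                    lo = rows$center[r] - rows$range[r],
                    hi = rows$center[r] + rows$range[r],
                    init = dof_value(h, ri, "tau"))
        res <- sort(unique(h$residue_index))
        k <- match(ri, res)
        if (k < length(res)) {
          psi <- dof_topology(h, ri, "psi")
          omg <- dof_topology(h, res[k + 1], "omega")
          out$psi_meas <- psi$meas; out$psi_moved <- psi$moved
          out$om_meas <- omg$meas; out$om_moved <- omg$moved
        }
        out
      }
    })
  }
  dih <- dof_specs(spec$dihedrals, "dihedral")
  ang <- dof_specs(spec$bond_angles, "angle")
  # per-atom signature over all DOFs; pairs with equal signatures are rigid
  sig <- rep("", n)
  alldof <- c(dih, ang)
  for (k in seq_along(alldof)) {
    sig[alldof[[k]]$moved] <- paste0(sig[alldof[[k]]$moved], k, ",")
  }
  pairs <- t(utils::combn(n, 2))
  excl <- bonded_exclusions(helix_bonds(h), n)
  keep <- !(paste(pairs[, 1], pairs[, 2]) %in% paste(excl[, 1], excl[, 2]))
  pairs <- pairs[keep, , drop = FALSE]
  dynamic <- sig[pairs[, 1]] != sig[pairs[, 2]]
  q <- ff_charges(params, h$residue_name, h$atom)
  lj <- ff_lj(params, h$element, h$residue_name, h$atom)
  coeff <- dielectric$coefficient
  mkpair <- function(p) {
    list(i = p[, 1], j = p[, 2],
         qq = COULOMB_CONST * q[p[, 1]] * q[p[, 2]] / coeff,
         eij = sqrt(lj$eps[p[, 1]] * lj$eps[p[, 2]]),
         rmij = (lj$rmin[p[, 1]] + lj$rmin[p[, 2]]) / 2)
  }
  dyn <- mkpair(pairs[dynamic, , drop = FALSE])
  # static contribution, computed once
  stat <- pair_energies(as.matrix(h[, c("x", "y", "z")]), q, lj$eps, lj$rmin,
                        pairs[!dynamic, , drop = FALSE], dielectric,
                        cutoff_nb, cutoff_elec)
  list(dih = dih, ang = ang, pairs = dyn,
       static_energy = sum(stat$coulomb) + sum(stat$lj))
}

run_kernel <- function(h, prep, temps, mc_steps, biased_bins, mem_edges,
                       dielectric, cutoff_nb, cutoff_elec, seed,
                       record_stride = 0) {
  dih <- prep$dih
  if (!is.null(biased_bins)) {
    for (k in seq_along(dih)) {
      dih[[k]]$bin_lo <- biased_bins[[k]]$lo
      dih[[k]]$bin_hi <- biased_bins[[k]]$hi
    }
  }
  .cm_kernel(as.matrix(as_helix(h)[, c("x", "y", "z")]), dih, prep$ang,
             as.integer(prep$pairs$i), as.integer(prep$pairs$j),
             prep$pairs$qq, prep$pairs$eij, prep$pairs$rmij,
             dielectric$model == "distance", cutoff_nb, cutoff_elec,
             temps, as.integer(mc_steps), !is.null(biased_bins),
             mem_edges %||% list(), KB_KCAL, as.double(seed),
             as.integer(record_stride))
}

# Rebuild a helix frame from a snapshot of DOF values (dihedrals then bond
# angles, in spec order).
rebuild_frame <- function(h, spec, values) {
  dih <- spec$dihedrals
  nd <- nrow(dih)
  for (k in seq_len(nd)) {
    h <- set_dof(h, dih$residue_index[k], dih$name[k], values[k])
  }
  ang <- spec$bond_angles
  for (k in seq_len(nrow(ang))) {
    h <- set_dof(h, ang$residue_index[k], "tau", values[nd + k])
  }
  h
}

#' Run a two-phase Conformational Memories search
#'
#' Phase 1 (exploratory) anneals from high temperature while accumulating,
#' for every free dihedral, a histogram of its values over all accepted
#' states (the "memories").  Phase 2 (biased) re-anneals from a lower start
#' temperature proposing only within the retained (highly populated) bins.
#' The output ensemble is drawn at evenly spaced accepted states of the final
#' temperature of the biased phase.
#'
#' @param h a `helix`, parameterised by `params`.
#' @param spec a [hinge_spec()].
#' @param params a `forcefield` (default [default_forcefield()]).
#' @param exploratory,biased annealing schedules; defaults are a
#'   3000 K -> 310 K ladder of 18 temperatures and a 749.4 K -> 310 K ladder
#'   of nine temperatures, 50,000 Monte-Carlo steps at each temperature.
#' @param n_output ensemble size to emit (default 112).
#' @param bin_width memory histogram bin width, degrees (default 10).
#' @param retain_frac a bin is retained when it holds at least this fraction
#'   of a dihedral's accepted samples (default 0.01).
#' @param cutoff_nb,cutoff_elec nonbonded and electrostatic cutoffs, Angstrom.
#' @param dielectric dielectric model (default the force field's; the
#'   sampling default is distance-dependent `eps(r) = r`).
#' @param seed integer seed; identical seeds give bit-identical runs.
#' @return a `cm_run`: list with `ensemble` (list of `helix` frames),
#'   `energies` (tibble `frame`, `energy`), `memory` (tibble with per-bin
#'   counts and retention flags), `acceptance` (per-phase, per-temperature
#'   acceptance counts) and `provenance`.
#' @export
run_cm <- function(h, spec, params = default_forcefield(),
                   exploratory = make_schedule(3000, 310, 18),
                   biased = make_schedule(749.4, 310, 9),
                   n_output = 112, bin_width = 10, retain_frac = 0.01,
                   cutoff_nb = 8, cutoff_elec = 20, dielectric = NULL,
                   seed = 1) {
  h <- as_helix(h)
  dielectric <- dielectric %||% params$dielectric
  prep <- cm_prepare(h, spec, params, cutoff_nb, cutoff_elec, dielectric)
  dihrows <- spec$dihedrals
  mem_edges <- purrr::map(seq_len(nrow(dihrows)), function(k) {
    e <- seq(dihrows$lo[k], dihrows$hi[k], by = bin_width)
    if (tail(e, 1) < dihrows$hi[k]) e <- c(e, dihrows$hi[k])
    e
  })
  r1 <- run_kernel(h, prep, exploratory$temperature,
                   attr(exploratory, "mc_steps"), NULL, mem_edges,
                   dielectric, cutoff_nb, cutoff_elec, seed)
  memory <- purrr::map_dfr(seq_len(nrow(dihrows)), function(k) {
    e <- mem_edges[[k]]
    counts <- r1$memory_counts[[k]]
    tibble::tibble(residue_index = dihrows$residue_index[k],
                   name = dihrows$name[k],
                   bin_start = e[-length(e)], bin_end = e[-1],
                   count = counts,
                   retained = counts >= retain_frac * sum(counts) & counts > 0)
  })
  bins <- purrr::map(seq_len(nrow(dihrows)), function(k) {
    m <- memory[memory$residue_index == dihrows$residue_index[k] &
                  memory$name == dihrows$name[k] & memory$retained, ]
    if (nrow(m) == 0) {
      abort("empty retained memory for a free dihedral: lower the retention threshold")
    }
    list(lo = m$bin_start, hi = m$bin_end)
  })
  r2 <- run_kernel(h, prep, biased$temperature, attr(biased, "mc_steps"),
                   bins, NULL, dielectric, cutoff_nb, cutoff_elec, seed + 1)
  acceptance <- dplyr::bind_rows(
    tibble::tibble(phase = "exploratory", step = exploratory$step,
                   temperature = exploratory$temperature,
                   accepted = as.integer(r1$accepted_per_temperature),
                   steps = attr(exploratory, "mc_steps")),
    tibble::tibble(phase = "biased", step = biased$step,
                   temperature = biased$temperature,
                   accepted = as.integer(r2$accepted_per_temperature),
                   steps = attr(biased, "mc_steps")))
  nsnap <- nrow(r2$snapshots)
  if (nsnap == 0) {
    abort(paste0(
      "no accepted states at the final temperature; acceptance per ",
      "temperature was: ",
      paste(sprintf("%.0fK:%d", acceptance$temperature, acceptance$accepted),
            collapse = ", ")))
  }
  sel <- unique(round(seq(1, nsnap, length.out = min(n_output, nsnap))))
  if (length(sel) < n_output) {
    sel <- round(seq(1, nsnap, length.out = n_output))
  }
  frames <- purrr::map(sel, function(s) rebuild_frame(h, spec, r2$snapshots[s, ]))
  energies <- tibble::tibble(
    frame = seq_along(sel),
    energy = r2$snapshot_energies[sel] + prep$static_energy)
  structure(list(
    ensemble = frames, energies = energies, memory = memory,
    acceptance = acceptance,
    provenance = list(seed = seed, n_output = n_output,
                      bin_width = bin_width, retain_frac = retain_frac,
                      exploratory = list(
                        temperatures = exploratory$temperature,
                        mc_steps = attr(exploratory, "mc_steps")),
                      biased = list(temperatures = biased$temperature,
                                    mc_steps = attr(biased, "mc_steps")),
                      static_energy = prep$static_energy),
    spec = spec), class = "cm_run")
}

#' @export
print.cm_run <- function(x, ...) {
  cat(sprintf(
    "Conformational Memories run: %d conformers, %d free dihedrals, seed %s\n",
    length(x$ensemble), nrow(x$spec$dihedrals),
    format(x$provenance$seed)))
  cat(sprintf("energy range: %.2f .. %.2f kcal/mol\n",
              min(x$energies$energy), max(x$energies$energy)))
  invisible(x)
}

#' Fixed-temperature Monte-Carlo sampling
#'
#' Runs the sampler at a single temperature and records the chain state of
#' every free dihedral at each recorded step (the chain marginal converges to
#' the Boltzmann distribution of the energy model).
#'
#' @inheritParams run_cm
#' @param temperature temperature in Kelvin.
#' @param n_steps number of Monte-Carlo steps.
#' @param record_stride record the chain every this many steps (default 1).
#' @return a tibble with one row per recorded step and one column per free
#'   dihedral (named `residue.name`), plus attribute `acceptance_rate`.
#' @export
sample_fixed_temperature <- function(h, spec, params = default_forcefield(),
                                     temperature = 310, n_steps = 50000,
                                     cutoff_nb = 8, cutoff_elec = 20,
                                     dielectric = NULL, seed = 1,
                                     record_stride = 1) {
  h <- as_helix(h)
  dielectric <- dielectric %||% params$dielectric
  prep <- cm_prepare(h, spec, params, cutoff_nb, cutoff_elec, dielectric)
  r <- run_kernel(h, prep, temperature, n_steps, NULL, NULL, dielectric,
                  cutoff_nb, cutoff_elec, seed, record_stride = record_stride)
  chain <- tibble::as_tibble(as.data.frame(r$chain))
  names(chain) <- paste(spec$dihedrals$residue_index, spec$dihedrals$name,
                        sep = ".")
  attr(chain, "acceptance_rate") <-
    as.integer(r$accepted_per_temperature)[1] / n_steps
  chain
}

#' Superpose an ensemble on an anchor segment
#'
#' Rigid-body transforms every frame to minimise the backbone (N, CA, C)
#' RMSD of the anchor residues against the first frame.
#'
#' @param ensemble a `cm_run` or list of `helix` frames.
#' @param anchor integer vector of anchor residue indices (>= 3 residues).
#' @return the input with transformed frames (same type).
#' @export
superpose_ensemble <- function(ensemble, anchor) {
  frames <- if (inherits(ensemble, "cm_run")) ensemble$ensemble else ensemble
  if (length(anchor) < 3) {
    abort("anchor must contain at least 3 residues (superposition is under-determined)")
  }
  sel <- function(f) helix_coords(f, atoms = c("N", "CA", "C"),
                                  residues = anchor)
  ref <- sel(frames[[1]])
  if (nrow(ref) < 3) abort("anchor residues missing from the frames")
  out <- purrr::map(frames, function(f) {
    fit <- kabsch_fit(ref, sel(f))
    xyz <- as.matrix(f[, c("x", "y", "z")])
    xyz <- sweep(sweep(xyz, 2, fit$center_b) %*% t(fit$rotation), 2,
                 fit$center_a, `+`)
    f$x <- xyz[, 1]; f$y <- xyz[, 2]; f$z <- xyz[, 3]
    f
  })
  if (inherits(ensemble, "cm_run")) {
    ensemble$ensemble <- out
    ensemble
  } else {
    out
  }
}

#' Write a memory map as TSV
#'
#' Columns: `dihedral` (`residue.name`), `bin_start`, `bin_end`, `count`,
#' `retained`.
#' @param memory the `memory` tibble of a `cm_run`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_memory_map <- function(memory, path) {
  d <- data.frame(dihedral = paste(memory$residue_index, memory$name, sep = "."),
                  bin_start = memory$bin_start, bin_end = memory$bin_end,
                  count = memory$count, retained = memory$retained)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
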