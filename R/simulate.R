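#' Synthetic protein-ligand complex and trajectory generator
#'
#' Builds a deliberately minimal "aromatic cage" complex and trajectories
#' over it in which each interaction channel is satisfied in a
#' controlled fraction of frames. The template is a stand-in for a
#' Tudor-domain methyl-reader pocket binding an amidine/pyrrolidinium
#' ligand: an aromatic ring for cation-pi (a Phe-like residue), a second
#' aromatic ring for pi-pi stacking (a Trp-like residue), a carboxylate
#' pair for the amidine salt bridge (an Asp-like residue), a tyrosine
#' hydroxyl accepting a ligand hydrogen bond, and a ligand donor/
#' hydrogen/acceptor triad for the intramolecular hydrogen bond.
#' Channel clusters are spatially decoupled (each channel moves only its
#' own dedicated ligand atoms) so planted probabilities are independent.
#'
#' @name synthetic-data
NULL

hexagon <- function(center, radius = 1.39, z = 0) {
  t(vapply(0:5, function(k)
    c(center[1] + radius * cos(k * pi / 3),
      center[2] + radius * sin(k * pi / 3),
      center[3] + z), numeric(3)))
}

backbone_quad <- function(x0) {
  rbind(c(x0 - 5, -6.0, 0.0),    # N
        c(x0 - 4, -5.2, 0.3),    # CA
        c(x0 - 3, -6.0, 0.1),    # C
        c(x0 - 3, -7.2, 0.2))    # O
}

#' Build the toy aromatic-cage complex template
#'
#' Deterministic; the reference geometry satisfies every declared
#' channel with a margin of at least 0.3 A / 5 degrees from the
#' cutoffs, which a self-check verifies at construction time.
#'
#' @return object of class `complex_template`: `atoms`, `ref_coords`
#'   (n x 3), `channels` (list of [channel()]), `movers` (per-channel
#'   placement rules) and `spec` (the default [interaction_spec()]).
#' @export
make_toy_complex <- function() {
  rows <- list(); coords <- list()
  add <- function(name, element, resname, resno, xyz) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, element = element, resname = resname, resno = resno,
      stringsAsFactors = FALSE)
    coords[[length(coords) + 1L]] <<- xyz
  }
  add_quad <- function(resname, resno, x0) {
    bb <- backbone_quad(x0)
    for (i in 1:4) add(c("N", "CA", "C", "O")[i], c("N", "C", "C", "O")[i],
                       resname, resno, bb[i, ])
  }

  # PHE 141: cation-pi ring at the origin cluster
  add_quad("PHE", 141L, 0)
  phe_ring <- hexagon(c(0, 0, 0))
  phe_names <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
  for (i in 1:6) add(phe_names[i], "C", "PHE", 141L, phe_ring[i, ])

  # TRP 151 (six-membered ring only): pi-pi partner at x = 20
  add_quad("TRP", 151L, 20)
  trp_ring <- hexagon(c(20, 0, 0))
  trp_names <- c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3")
  for (i in 1:6) add(trp_names[i], "C", "TRP", 151L, trp_ring[i, ])

  # TYR 170: hydroxyl H-bond acceptor at x = 60
  add_quad("TYR", 170L, 60)
  add("OH", "O", "TYR", 170L, c(60, 0, 0))

  # ASP 184: carboxylate pair at x = 40
  add_quad("ASP", 184L, 40)
  add("OD1", "O", "ASP", 184L, c(40, 0, 0))
  add("OD2", "O", "ASP", 184L, c(42.2, 0, 0))

  # Ligand (one residue, dedicated atoms per channel)
  add("NP", "N", "LIG", 1L, c(0, 0, 3.2))           # pyrrolidinium-like cation
  lig_ring <- hexagon(c(20, 0, 3.6))
  for (i in 1:6) add(paste0("C", i), "C", "LIG", 1L, lig_ring[i, ])
  add("NH1", "N", "LIG", 1L, c(40, 0, 3.3))         # amidine nitrogens
  add("NH2", "N", "LIG", 1L, c(42.2, 0, 3.3))
  add("ND1", "N", "LIG", 1L, c(60, 0, 2.6))         # donor to Tyr170 OH
  add("HD1", "H", "LIG", 1L, c(60, 0, 1.6))
  add("ND2", "N", "LIG", 1L, c(80, 0, 3.0))         # intramolecular donor
  add("HD2", "H", "LIG", 1L, c(80, 0, 2.0))
  add("OA", "O", "LIG", 1L, c(80, 0, 0))            # intramolecular acceptor

  atoms <- do.call(rbind, rows)
  atoms$serial <- seq_len(nrow(atoms))
  atoms$chain <- "A"
  ref <- do.call(rbind, coords)

  channels <- list(
    channel("hbond", "ligand-Tyr170 H-bond",
            donor = "LIG 1 ND1", hydrogen = "LIG 1 HD1",
            acceptor = "TYR 170 OH"),
    channel("intramol_hbond", "intramolecular H-bond",
            donor = "LIG 1 ND2", hydrogen = "LIG 1 HD2",
            acceptor = "LIG 1 OA"),
    channel("salt_bridge", "amidine-Asp184 salt bridge",
            anion_oxygens = "ASP 184 OD1,OD2",
            cation_nitrogens = "LIG 1 NH1,NH2"),
    channel("cation_pi", "pyrrolidinium-Phe141 cation-pi",
            cation = "LIG 1 NP",
            rings = "PHE 141 CG,CD1,CE1,CZ,CE2,CD2"),
    channel("pi_pi", "isoindoline-Trp151 pi-pi",
            rings_a = "LIG 1 C1,C2,C3,C4,C5,C6",
            rings_b = "TRP 151 CD2,CE2,CZ2,CH2,CZ3,CE3"))

  # Placement rules: each channel rigidly moves its own ligand atoms
  # along (or about) a fixed axis from an anchor; ON/OFF draw ranges
  # stay >= 0.3 A / 5 deg away from the cutoffs on either side.
  movers <- list(
    "ligand-Tyr170 H-bond" = list(
      type = "axial", atoms = "LIG 1 ND1,HD1", probe = "LIG 1 ND1",
      anchor = c(60, 0, 0), axis = c(0, 0, 1),
      on = c(2.5, 2.7), off = c(3.4, 4.5)),
    "intramolecular H-bond" = list(
      type = "axial", atoms = "LIG 1 ND2,HD2", probe = "LIG 1 ND2",
      anchor = c(80, 0, 0), axis = c(0, 0, 1),
      on = c(2.7, 3.2), off = c(3.9, 5.0)),
    "amidine-Asp184 salt bridge" = list(
      type = "axial", atoms = "LIG 1 NH1,NH2", probe = "LIG 1 NH1",
      anchor = c(40, 0, 0), axis = c(0, 0, 1),
      on = c(2.9, 3.7), off = c(4.4, 6.0)),
    "pyrrolidinium-Phe141 cation-pi" = list(
      type = "spherical", atoms = "LIG 1 NP", probe = "LIG 1 NP",
      anchor = c(0, 0, 0), axis = c(0, 0, 1),
      on = c(3.0, 5.5), off = c(6.4, 8.0), theta = c(0, 40)),
    "isoindoline-Trp151 pi-pi" = list(
      type = "axial", atoms = "LIG 1 C1,C2,C3,C4,C5,C6", probe = NULL,
      anchor = c(20, 0, 0), axis = c(0, 0, 1),
      on = c(3.3, 5.1), off = c(5.9, 7.5)))

  tpl <- structure(list(atoms = atoms, ref_coords = ref,
                        channels = channels, movers = movers,
                        spec = interaction_spec()),
                   class = "complex_template")
  margins <- template_margins(tpl)
  if (any(margins$distance_margin < 0.3) ||
      any(margins$angle_margin < 5, na.rm = TRUE))
    stop("make_toy_complex: reference geometry violates the required margins")  # nocov
  tpl
}

#' @export
print.complex_template <- function(x, ...) {
  cat(sprintf("Toy complex template: %d atoms, %d channels\n",
              nrow(x$atoms), length(x$channels)))
  for (ch in x$channels) cat(sprintf("  - %s [%s]\n", ch$label, ch$kind))
  invisible(x)
}

template_trajectory <- function(tpl, xyz = NULL) {
  trajectory(tpl$atoms, if (is.null(xyz)) tpl$ref_coords else xyz)
}

#' Margins of the template reference geometry
#'
#' Measures, for every channel on the reference geometry, how far each
#' governing quantity sits from its cutoff (distance margin in A, angle
#' margin in degrees; `NA` where the kind has no angle criterion).
#'
#' @param tpl a [make_toy_complex()] template.
#' @return data.frame with columns `channel`, `kind`, `distance`,
#'   `distance_margin`, `angle`, `angle_margin`.
#' @export
template_margins <- function(tpl) {
  traj <- template_trajectory(tpl)
  co <- tpl$ref_coords
  spec <- tpl$spec
  rows <- lapply(tpl$channels, function(ch) {
    ri <- resolve_channel(traj, ch)
    if (ch$kind %in% c("hbond", "intramol_hbond")) {
      cutoff <- if (ch$kind == "hbond") spec$hbond_distance_cutoff
                else spec$intramol_hbond_distance_cutoff
      d <- vnorm(co[ri$donor, ] - co[ri$acceptor, ])
      a <- vertex_angle(co[ri$donor, ], co[ri$hydrogen, ], co[ri$acceptor, ])
      data.frame(channel = ch$label, kind = ch$kind, distance = d,
                 distance_margin = cutoff - d, angle = a,
                 angle_margin = a - spec$hbond_angle_cutoff)
    } else if (ch$kind == "salt_bridge") {
      ao <- co[ri$anion_oxygens, , drop = FALSE]
      cn <- co[ri$cation_nitrogens, , drop = FALSE]
      d <- min(sqrt(outer(rowSums(ao^2), rowSums(cn^2), "+") -
                      2 * tcrossprod(ao, cn)))
      data.frame(channel = ch$label, kind = ch$kind, distance = d,
                 distance_margin = spec$salt_bridge_cutoff - d,
                 angle = NA_real_, angle_margin = NA_real_)
    } else if (ch$kind == "cation_pi") {
      g <- ring_geometry(co[ri$rings[[1L]], , drop = FALSE])
      v <- co[ri$cation, ] - g$centroid
      a <- angle_vector_to_normal(g$normal, v)
      data.frame(channel = ch$label, kind = ch$kind, distance = vnorm(v),
                 distance_margin = spec$cation_pi_distance_cutoff - vnorm(v),
                 angle = a, angle_margin = spec$cation_pi_angle_cutoff - a)
    } else {
      ga <- ring_geometry(co[ri$rings_a[[1L]], , drop = FALSE])
      gb <- ring_geometry(co[ri$rings_b[[1L]], , drop = FALSE])
      d <- vnorm(ga$centroid - gb$centroid)
      a <- angle_vector_to_normal(ga$normal, gb$normal)
      data.frame(channel = ch$label, kind = ch$kind, distance = d,
                 distance_margin = spec$pipi_distance_cutoff - d,
                 angle = a, angle_margin = spec$pipi_angle_cutoff - a)
    }
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Per-channel occupancy plan for trajectory simulation
#'
#' Target Bernoulli probabilities per channel plus the global rigid
#' jitter amplitude. The default probabilities are the occupancy levels
#' reported for Spindlin1 inhibitor MD runs of this interaction set:
#' a highly maintained salt bridge (94 %), partially maintained
#' cation-pi contacts (54.1 %), an occasionally formed intramolecular
#' hydrogen bond (31 %), a moderately held protein-ligand hydrogen bond
#' (55.5 %) and a rarely held pi-pi stack (2 %).
#'
#' @param probs named numeric vector of probabilities in \[0, 1\],
#'   names = channel labels.
#' @param jitter_sd translation SD of the global rigid jitter, A.
#' @param jitter_rot_deg rotation amplitude of the global rigid jitter,
#'   degrees.
#' @return object of class `channel_plan`.
#' @export
channel_plan <- function(probs = c("ligand-Tyr170 H-bond" = 0.555,
                                   "intramolecular H-bond" = 0.31,
                                   "amidine-Asp184 salt bridge" = 0.94,
                                   "pyrrolidinium-Phe141 cation-pi" = 0.541,
                                   "isoindoline-Trp151 pi-pi" = 0.02),
                         jitter_sd = 0.3, jitter_rot_deg = 2) {
  if (is.null(names(probs)) || any(!nzchar(names(probs))))
    stop_config("channel_plan: probabilities must be named by channel label")
  if (any(probs < 0 | probs > 1))
    stop_config("channel_plan: probabilities must lie in [0, 1]")
  if (jitter_sd < 0 || jitter_rot_deg < 0)
    stop_config("channel_plan: jitter amplitudes must be non-negative")
  structure(list(probs = probs, jitter_sd = jitter_sd,
                 jitter_rot_deg = jitter_rot_deg),
            class = "channel_plan")
}

# Stable 31-bit hash of a label combined with the master seed, so each
# channel owns a pseudo-random stream that does not depend on channel
# order.
stream_seed <- function(label, master_seed) {
  h <- 0
  for (c in utf8ToInt(label)) h <- (h * 31 + c) %% 2147483647
  as.integer((h + (master_seed %% 2147483647) * 7919) %% 2147483647)
}

rotation_about <- function(axis, angle_deg) {
  u <- axis / vnorm(axis)
  th <- angle_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
               nrow = 3L, byrow = TRUE)
  ct * diag(3) + st * ux + (1 - ct) * tcrossprod(u)
}

#' Simulate a trajectory with planted channel occupancies
#'
#' For every frame and channel an independent Bernoulli(p) draw decides
#' whether the channel is ON; ON frames place the channel's dedicated
#' mobile atoms uniformly inside the criterion-satisfying region (minus
#' a 0.3 A / 5 degree safety margin), OFF frames push them beyond the
#' cutoff plus the same margin, so OFF frames can never satisfy the
#' criterion. A global rigid jitter (small random rotation +
#' translation of the whole frame) is applied last; rigid motion leaves
#' every detector unchanged, so the planted probabilities are exact.
#' Each channel draws from its own pseudo-random stream derived from
#' the master seed and the channel label, making output independent of
#' channel ordering and bitwise reproducible for a given seed.
#'
#' @param tpl a [make_toy_complex()] template.
#' @param plan a [channel_plan()]; every plan label must name a template
#'   channel.
#' @param n_frames number of frames (>= 1).
#' @param seed master integer seed.
#' @return a [trajectory()] carrying the realized ON/OFF states as
#'   attribute `states` (frames x channels logical matrix).
#' @export
simulate_trajectory <- function(tpl, plan = channel_plan(), n_frames = 100L,
                                seed = 1L) {
  if (n_frames < 1L) stop_config("simulate_trajectory: n_frames must be >= 1")
  unknown <- setdiff(names(plan$probs), names(tpl$movers))
  if (length(unknown))
    stop_config("simulate_trajectory: plan names unknown channel(s): %s",
                paste(unknown, collapse = ", "))
  traj0 <- template_trajectory(tpl)
  labels <- names(plan$probs)

  mover_idx <- lapply(tpl$movers[labels], function(mv)
    resolve_selection(traj0, mv$atoms))
  all_idx <- unlist(mover_idx)
  if (anyDuplicated(all_idx))
    stop_config("simulate_trajectory: channels share mobile atoms; plan is unsatisfiable")

  n_at <- nrow(tpl$atoms)
  xyz <- array(rep(tpl$ref_coords, times = n_frames),
               dim = c(n_at, 3L, n_frames))
  states <- matrix(NA, nrow = n_frames, ncol = length(labels),
                   dimnames = list(NULL, labels))

  for (j in seq_along(labels)) {
    lab <- labels[j]
    mv <- tpl$movers[[lab]]
    idx <- mover_idx[[j]]
    set.seed(stream_seed(lab, seed))
    u <- matrix(stats::runif(4L * n_frames), ncol = 4L)
    on <- u[, 1L] <= plan$probs[[lab]]
    states[, j] <- on
    ref_block <- tpl$ref_coords[idx, , drop = FALSE]
    probe_ref <- if (is.null(mv$probe)) colMeans(ref_block)
                 else tpl$ref_coords[resolve_selection(traj0, mv$probe), ]
    for (f in seq_len(n_frames)) {
      rng <- if (on[f]) mv$on else mv$off
      d <- rng[1L] + u[f, 2L] * (rng[2L] - rng[1L])
      target <- if (mv$type == "spherical") {
        th <- (mv$theta[1L] + u[f, 3L] * (mv$theta[2L] - mv$theta[1L])) * pi / 180
        ph <- u[f, 4L] * 2 * pi
        mv$anchor + d * c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
      } else {
        mv$anchor + d * mv$axis
      }
      delta <- target - probe_ref
      xyz[idx, , f] <- sweep(ref_block, 2L, delta, FUN = "+")
    }
  }

  if (plan$jitter_sd > 0 || plan$jitter_rot_deg > 0) {
    set.seed(stream_seed("__global_rigid_jitter__", seed))
    center <- colMeans(tpl$ref_coords)
    for (f in seq_len(n_frames)) {
      ax <- stats::rnorm(3L)
      ang <- stats::runif(1L, -plan$jitter_rot_deg, plan$jitter_rot_deg)
      tr <- stats::rnorm(3L, sd = plan$jitter_sd)
      rot <- rotation_about(ax, ang)
      fr <- sweep(xyz[, , f], 2L, center)
      fr <- fr %*% t(rot)
      xyz[, , f] <- sweep(fr, 2L, center + tr, FUN = "+")
    }
  }

  out <- trajectory(tpl$atoms, xyz)
  attr(out, "states") <- states
  out
}

#' Simulate a two-group score table
#'
#' Gaussian active/inactive score draws emulating binding-free-energy
#' rescoring output. Defaults reproduce the study conditions of the
#' discrimination analysis: 17 actives (mean -76.3 kcal/mol) against 3
#' inactives (mean -60.35 kcal/mol), SD 4 kcal/mol.
#'
#' @param mean_active,mean_inactive group means, kcal/mol.
#' @param sd_active,sd_inactive group SDs (> 0), kcal/mol.
#' @param n_active,n_inactive group sizes (0 allowed; downstream
#'   summaries will refuse an empty group).
#' @param seed integer seed.
#' @param kind score-kind tag.
#' @return a [score_table()] (possibly with an empty group).
#' @export
simulate_scores <- function(mean_active = -76.3, sd_active = 4,
                            n_active = 17L,
                            mean_inactive = -60.35, sd_inactive = 4,
                            n_inactive = 3L, seed = 1L, kind = "MMGBSA") {
  if (sd_active <= 0 || sd_inactive <= 0)
    stop_config("simulate_scores: SDs must be positive")
  set.seed(stream_seed(paste0("scores:", kind), seed))
  sa <- mean_active + sd_active * stats::rnorm(n_active)
  si <- mean_inactive + sd_inactive * stats::rnorm(n_inactive)
  score_table(compound = c(sprintf("act%02d", seq_len(n_active)),
                           sprintf("ina%02d", seq_len(n_inactive))),
              score = c(sa, si),
              activity = rep(c("active", "inactive"),
                             c(n_active, n_inactive)),
              kind = kind)
}

#' Simulate a noisy dose-response plate
#'
#' Responses on a four-parameter logistic curve plus Gaussian noise,
#' per replicate. Defaults emulate the fluorescence-polarization assay
#' layout: a 12-point 1:3 serial dilution from 100 uM measured in
#' triplicate, around a planted IC50 of 182.6 nM with Hill slope 1 and
#' 0/100 % plateaus.
#'
#' @param ic50 planted IC50 (molar).
#' @param hill Hill slope.
#' @param top,bottom plateau percentages.
#' @param concentrations dilution series, molar.
#' @param noise_sd response noise SD, percentage points.
#' @param replicates replicates per concentration.
#' @param seed integer seed.
#' @param compound compound label.
#' @return data.frame with columns `compound`, `concentration`,
#'   `replicate`, `inhibition`.
#' @export
simulate_dose_response <- function(ic50 = 182.6e-9, hill = 1, top = 100,
                                   bottom = 0,
                                   concentrations = 1e-4 * (1 / 3)^(0:11),
                                   noise_sd = 2, replicates = 3L, seed = 1L,
                                   compound = "cmpd") {
  if (any(concentrations <= 0))
    stop_config("simulate_dose_response: concentrations must be positive")
  set.seed(stream_seed(paste0("assay:", compound), seed))
  mu <- fourpl(concentrations, ic50, hill, top, bottom)
  out <- expand.grid(replicate = seq_len(replicates),
                     concentration = concentrations)
  out$inhibition <- rep(mu, each = replicates) +
    if (noise_sd > 0) stats::rnorm(nrow(out), sd = noise_sd) else 0
  data.frame(compound = compound,
             concentration = out$concentration,
             replicate = out$replicate,
             inhibition = out$inhibition,
             stringsAsFactors = FALSE)
}
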