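#' Geometric cutoffs for interaction detection
#'
#' Bundles the distance and angle cutoffs used by the per-frame
#' detectors. Defaults follow the CPPTRAJ-style trajectory-analysis
#' conventions used for Spindlin1 inhibitor complexes: hydrogen bonds at
#' a donor-acceptor distance of 3.0 A with a donor-H-acceptor angle of
#' at least 135 degrees (extended to 3.5 A for ligand intramolecular
#' hydrogen bonds); salt bridges at 4.0 A between charged-atom sets;
#' cation-pi at 6.0 A cation-to-ring-centroid with the cation within
#' 45 degrees of the ring axis. No such published criterion exists for
#' pi-pi stacking, so a conventional face-to-face rule is supplied
#' (centroid distance 5.5 A, interplanar angle 30 degrees); both are
#' configurable and recorded in every report.
#'
#' All cutoff comparisons are inclusive.
#'
#' @param hbond_distance_cutoff donor-acceptor distance, A.
#' @param hbond_angle_cutoff minimum donor-H-acceptor angle, degrees.
#' @param intramol_hbond_distance_cutoff donor-acceptor distance for
#'   intramolecular hydrogen bonds, A.
#' @param salt_bridge_cutoff minimum anion-O / cation-N distance, A.
#' @param cation_pi_distance_cutoff cation to ring-centroid distance, A.
#' @param cation_pi_angle_cutoff maximum angle between the ring normal
#'   and the centroid-to-cation vector, degrees.
#' @param pipi_distance_cutoff ring-centroid distance, A.
#' @param pipi_angle_cutoff maximum interplanar angle, degrees.
#' @return object of class `interaction_spec`.
#' @export
interaction_spec <- function(hbond_distance_cutoff = 3.0,
                             hbond_angle_cutoff = 135,
                             intramol_hbond_distance_cutoff = 3.5,
                             salt_bridge_cutoff = 4.0,
                             cation_pi_distance_cutoff = 6.0,
                             cation_pi_angle_cutoff = 45,
                             pipi_distance_cutoff = 5.5,
                             pipi_angle_cutoff = 30) {
  spec <- list(hbond_distance_cutoff = hbond_distance_cutoff,
               hbond_angle_cutoff = hbond_angle_cutoff,
               intramol_hbond_distance_cutoff = intramol_hbond_distance_cutoff,
               salt_bridge_cutoff = salt_bridge_cutoff,
               cation_pi_distance_cutoff = cation_pi_distance_cutoff,
               cation_pi_angle_cutoff = cation_pi_angle_cutoff,
               pipi_distance_cutoff = pipi_distance_cutoff,
               pipi_angle_cutoff = pipi_angle_cutoff)
  dists <- spec[grep("distance|bridge", names(spec))]
  if (any(unlist(dists) <= 0))
    stop_config("interaction_spec: distance cutoffs must be positive")
  angs <- spec[c("hbond_angle_cutoff", "cation_pi_angle_cutoff", "pipi_angle_cutoff")]
  if (any(unlist(angs) <= 0) ||
      spec$cation_pi_angle_cutoff > 90 || spec$pipi_angle_cutoff > 90)
    stop_config("interaction_spec: angle cutoffs must be in (0, 90] (hbond angle in (0, 180])")
  if (spec$hbond_angle_cutoff > 180)
    stop_config("interaction_spec: hbond angle cutoff must be <= 180 degrees")
  structure(spec, class = "interaction_spec")
}

#' @export
print.interaction_spec <- function(x, ...) {
  cat("Interaction detection cutoffs (inclusive):\n")
  cat(sprintf("  H-bond:          D-A <= %.2f A, D-H-A >= %.0f deg\n",
              x$hbond_distance_cutoff, x$hbond_angle_cutoff))
  cat(sprintf("  intramol H-bond: D-A <= %.2f A (same angle rule)\n",
              x$intramol_hbond_distance_cutoff))
  cat(sprintf("  salt bridge:     min O-N <= %.2f A\n", x$salt_bridge_cutoff))
  cat(sprintf("  cation-pi:       d <= %.2f A, axis angle <= %.0f deg\n",
              x$cation_pi_distance_cutoff, x$cation_pi_angle_cutoff))
  cat(sprintf("  pi-pi:           d <= %.2f A, plane angle <= %.0f deg\n",
              x$pipi_distance_cutoff, x$pipi_angle_cutoff))
  invisible(x)
}

# Cutoff comparisons are inclusive. The 1e-9 guard absorbs the last-ulp
# error of distances/angles reconstructed from decimal coordinates, so a
# geometry built exactly at the cutoff tests true while anything 1e-6
# beyond tests false.
.cut_eps <- 1e-9
le_cut <- function(x, cutoff) x <= cutoff + .cut_eps
ge_cut <- function(x, cutoff) x >= cutoff - .cut_eps

#' Hydrogen-bond detector
#'
#' True iff the donor-acceptor distance is within the cutoff (3.0 A by
#' default; the extended intramolecular cutoff of 3.5 A when
#' `intramolecular = TRUE`) and the donor-hydrogen-acceptor angle is at
#' least the angle cutoff (135 degrees by default; 180 is linear/ideal).
#' The hydrogen must be explicit; a donor-hydrogen distance above 1.5 A
#' draws a covalency warning.
#'
#' @param donor,hydrogen,acceptor 3-vectors, Angstrom.
#' @param spec an [interaction_spec()].
#' @param intramolecular use the extended intramolecular distance cutoff?
#' @return logical scalar.
#' @export
detect_hbond <- function(donor, hydrogen, acceptor,
                         spec = interaction_spec(), intramolecular = FALSE) {
  if (vnorm(donor - hydrogen) > 1.5)
    warning(sprintf("detect_hbond: donor-hydrogen distance %.2f A is not covalently plausible",
                    vnorm(donor - hydrogen)))
  cutoff <- if (intramolecular) spec$intramol_hbond_distance_cutoff
            else spec$hbond_distance_cutoff
  d_da <- vnorm(donor - acceptor)
  if (!le_cut(d_da, cutoff)) return(FALSE)
  ang <- vertex_angle(donor, hydrogen, acceptor)
  ge_cut(ang, spec$hbond_angle_cutoff)
}

#' Salt-bridge detector
#'
#' True iff the minimum distance over all pairs of declared anionic
#' oxygens (e.g. both carboxylate oxygens of an aspartate) and cationic
#' nitrogens (e.g. both amidine nitrogens) is within the cutoff. The
#' minimum rule reflects that charged groups, not specific atoms, form
#' the contact.
#'
#' @param anion_oxygens,cation_nitrogens coordinate matrices (k x 3),
#'   k >= 1.
#' @param spec an [interaction_spec()].
#' @return logical scalar.
#' @export
detect_salt_bridge <- function(anion_oxygens, cation_nitrogens,
                               spec = interaction_spec()) {
  ao <- matrix(as.numeric(anion_oxygens), ncol = 3L)
  cn <- matrix(as.numeric(cation_nitrogens), ncol = 3L)
  if (nrow(ao) == 0L || nrow(cn) == 0L)
    stop_config("detect_salt_bridge: empty charged-atom set")
  d2 <- outer(rowSums(ao^2), rowSums(cn^2), "+") - 2 * tcrossprod(ao, cn)
  le_cut(sqrt(max(0, min(d2))), spec$salt_bridge_cutoff)
}

#' Cation-pi detector
#'
#' Two criteria, both inclusive: (i) the distance between the cation and
#' the aromatic-ring centroid is within the distance cutoff, and (ii)
#' the angle between the ring-plane normal and the centroid-to-cation
#' vector is within the angle cutoff (0 = cation on the ring axis).
#'
#' @param cation 3-vector (position of the charged nitrogen).
#' @param ring coordinate matrix (>= 5 x 3) of ring atoms, or a list of
#'   such matrices for fused ring systems (OR rule: any ring satisfying
#'   both criteria counts).
#' @param spec an [interaction_spec()].
#' @return logical scalar.
#' @export
detect_cation_pi <- function(cation, ring, spec = interaction_spec()) {
  rings <- if (is.list(ring) && !is.data.frame(ring)) ring else list(ring)
  for (r in rings) {
    r <- as.matrix(r)
    if (nrow(r) < 5L)
      stop_geometry("detect_cation_pi: a ring needs >= 5 atoms, got %d", nrow(r))
    g <- ring_geometry(r)
    v <- cation - g$centroid
    if (le_cut(vnorm(v), spec$cation_pi_distance_cutoff) &&
        le_cut(angle_vector_to_normal(g$normal, v), spec$cation_pi_angle_cutoff))
      return(TRUE)
  }
  FALSE
}

#' Pi-pi stacking detector (face-to-face)
#'
#' True iff the ring-centroid distance is within the distance cutoff and
#' the folded angle between the two ring-plane normals is within the
#' angle cutoff. This is the conventional face-to-face criterion;
#' T-shaped stacking is deliberately not matched.
#'
#' @param ring_a,ring_b coordinate matrices (>= 5 x 3), or lists of such
#'   matrices for fused systems (OR rule over ring pairs).
#' @param spec an [interaction_spec()].
#' @return logical scalar.
#' @export
detect_pi_pi <- function(ring_a, ring_b, spec = interaction_spec()) {
  as <- if (is.list(ring_a) && !is.data.frame(ring_a)) ring_a else list(ring_a)
  bs <- if (is.list(ring_b) && !is.data.frame(ring_b)) ring_b else list(ring_b)
  for (ra in as) for (rb in bs) {
    ra <- as.matrix(ra); rb <- as.matrix(rb)
    if (nrow(ra) < 5L || nrow(rb) < 5L)
      stop_geometry("detect_pi_pi: rings need >= 5 atoms")
    ga <- ring_geometry(ra); gb <- ring_geometry(rb)
    d <- vnorm(ga$centroid - gb$centroid)
    ang <- angle_vector_to_normal(ga$normal, gb$normal)
    if (le_cut(d, spec$pipi_distance_cutoff) && le_cut(ang, spec$pipi_angle_cutoff))
      return(TRUE)
  }
  FALSE
}

# ---- channels --------------------------------------------------------------

.channel_roles <- list(
  hbond          = c("donor", "hydrogen", "acceptor"),
  intramol_hbond = c("donor", "hydrogen", "acceptor"),
  salt_bridge    = c("anion_oxygens", "cation_nitrogens"),
  cation_pi      = c("cation", "rings"),
  pi_pi          = c("rings_a", "rings_b"))

#' Declare an interaction channel
#'
#' A channel names one interaction to follow across trajectory frames: a
#' kind, a human-readable label (e.g. `"amidine-Asp184"`) and the
#' participating atoms per role, given as selector strings (see
#' [resolve_selection()]). Ring roles (`rings`, `rings_a`, `rings_b`)
#' take a list of selectors, one per ring, each resolving to >= 5 atoms;
#' a fused bicyclic aromatic (tryptophan) is declared as two rings and
#' OR-reduced by the detectors.
#'
#' @param kind one of `"hbond"`, `"intramol_hbond"`, `"salt_bridge"`,
#'   `"cation_pi"`, `"pi_pi"`.
#' @param label channel label, unique within an analysis.
#' @param ... role = selector entries as required by the kind: `donor`,
#'   `hydrogen`, `acceptor` (single-atom selectors); `anion_oxygens`,
#'   `cation_nitrogens` (multi-atom selectors); `cation` (single-atom);
#'   `rings` / `rings_a` / `rings_b` (list or character vector of ring
#'   selectors).
#' @return object of class `channel`.
#' @export
channel <- function(kind, label, ...) {
  kind <- match.arg(kind, names(.channel_roles))
  roles <- list(...)
  need <- .channel_roles[[kind]]
  miss <- setdiff(need, names(roles))
  if (length(miss))
    stop_config("channel '%s' (%s): missing role(s) %s",
                label, kind, paste(miss, collapse = ", "))
  extra <- setdiff(names(roles), need)
  if (length(extra))
    stop_config("channel '%s' (%s): unknown role(s) %s",
                label, kind, paste(extra, collapse = ", "))
  structure(list(kind = kind, label = label, roles = roles[need]),
            class = "channel")
}

#' @export
print.channel <- function(x, ...) {
  cat(sprintf("Channel '%s' [%s]\n", x$label, x$kind))
  for (r in names(x$roles))
    cat(sprintf("  %-17s %s\n", paste0(r, ":"),
                paste(unlist(x$roles[[r]]), collapse = " | ")))
  invisible(x)
}

resolve_one <- function(traj, sel, role, label) {
  idx <- tryCatch(resolve_selection(traj, sel), error = function(e)
    stop_config("channel '%s', role %s: %s", label, role, conditionMessage(e)))
  idx
}

# Resolve a channel's selector strings against a trajectory once;
# returns index sets keyed by role.
resolve_channel <- function(traj, ch) {
  out <- list()
  for (role in names(ch$roles)) {
    sel <- ch$roles[[role]]
    if (role %in% c("rings", "rings_a", "rings_b")) {
      sels <- unlist(sel, use.names = FALSE)
      out[[role]] <- lapply(sels, function(s) {
        idx <- resolve_one(traj, s, role, ch$label)
        if (length(idx) < 5L)
          stop_config("channel '%s': ring selector '%s' resolves to %d atoms (need >= 5)",
                      ch$label, s, length(idx))
        g <- ring_geometry(frame_coords(traj, 1L)[idx, , drop = FALSE])
        if (g$planarity_rms > 0.3)
          warning(sprintf("channel '%s': ring '%s' has planarity RMS %.2f A (> 0.3 A)",
                          ch$label, s, g$planarity_rms))
        idx
      })
    } else {
      idx <- resolve_one(traj, sel, role, ch$label)
      if (role %in% c("donor", "hydrogen", "acceptor", "cation") && length(idx) != 1L)
        stop_config("channel '%s': role %s must resolve to exactly one atom (got %d)",
                    ch$label, role, length(idx))
      out[[role]] <- idx
    }
  }
  out
}

detect_frame <- function(coords, kind, ri, spec) {
  switch(kind,
    hbond = detect_hbond(coords[ri$donor, ], coords[ri$hydrogen, ],
                         coords[ri$acceptor, ], spec, intramolecular = FALSE),
    intramol_hbond = detect_hbond(coords[ri$donor, ], coords[ri$hydrogen, ],
                                  coords[ri$acceptor, ], spec,
                                  intramolecular = TRUE),
    salt_bridge = detect_salt_bridge(coords[ri$anion_oxygens, , drop = FALSE],
                                     coords[ri$cation_nitrogens, , drop = FALSE],
                                     spec),
    cation_pi = detect_cation_pi(coords[ri$cation, ],
                                 lapply(ri$rings, function(ix)
                                   coords[ix, , drop = FALSE]),
                                 spec),
    pi_pi = detect_pi_pi(lapply(ri$rings_a, function(ix) coords[ix, , drop = FALSE]),
                         lapply(ri$rings_b, function(ix) coords[ix, , drop = FALSE]),
                         spec))
}

#' Evaluate one channel over all trajectory frames
#'
#' Runs the channel's detector on every frame and returns the boolean
#' event series. Multi-ring roles OR-reduce (any declared ring of a
#' fused system satisfying the criteria counts).
#'
#' @param traj a [trajectory()].
#' @param ch a [channel()].
#' @param spec an [interaction_spec()].
#' @return logical vector of length `n_frames(traj)`.
#' @export
evaluate_channel <- function(traj, ch, spec = interaction_spec()) {
  ri <- resolve_channel(traj, ch)
  nf <- n_frames(traj)
  out <- logical(nf)
  for (f in seq_len(nf)) {
    out[f] <- tryCatch(
      detect_frame(traj$xyz[, , f], ch$kind, ri, spec),
      error = function(e)
        stop_geometry("channel '%s', frame %d: %s", ch$label, f,
                      conditionMessage(e)))
  }
  out
}
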