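#' Specification of a synthetic patient/control cohort
#'
#' Describes the statistical world the generator samples from: a
#' distance-dependent random connectome with structural hubs, log-normal
#' streamline counts and surface areas, and a patient group whose surface
#' areas are reduced in a set of left temporal/subcortical regions.
#'
#' Defaults encode the modelled condition -- left mesial temporal lobe
#' epilepsy with unilateral (left) atrophy of two control standard
#' deviations in the temporal pole, amygdala, hippocampus, parahippocampal
#' gyrus, putamen and thalamus -- and anatomically motivated geometry
#' (exponential distance decay of connection probability and streamline
#' counts, bilateral thalamus/insula as structural hubs, fibre lengths equal
#' to tortuosity-scaled Euclidean distance).
#'
#' @param n_patients,n_controls cohort sizes; at least 3 controls are
#'   required so that leave-one-out scoring keeps >= 2 references.
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @param edge_density_scale distance-decay constant (mm) of connection
#'   probability.
#' @param edge_base_prob connection probability within the contact radius.
#' @param edge_contact_radius distance (mm) below which regions count as
#'   abutting: connection probability stays at `edge_base_prob` and
#'   streamline counts at their maximum; decay applies beyond it.
#' @param region_size_exponent beyond the contact radius, edge probability
#'   and streamline counts additionally scale with
#'   `(A_i * A_j / median^2)^exponent` where `A` are canonical region
#'   areas: larger regions host more streamline endpoints, so small (e.g.
#'   subcortical) structures keep their strong local bundles but sparse
#'   long-range connectivity.
#' @param hub_regions base names of regions whose connection probabilities
#'   are boosted bilaterally.
#' @param hub_boost multiplicative probability boost for hub regions.
#' @param count_lognormal_mu,count_lognormal_sigma parameters of log
#'   streamline counts at zero distance; the mean decays linearly in
#'   distance with scale `count_distance_scale` (mm).
#' @param count_distance_scale see above.
#' @param area_lognormal_sigma total multiplicative spread (sd of log
#'   areas) around the canonical per-region surface areas.
#' @param area_global_fraction fraction of the log-area variance carried
#'   by a shared per-subject brain-size factor (the rest is independent
#'   regional variation). Brain size varies globally between people while
#'   regional proportions are comparatively tight; allometric scoring
#'   (see [surface_area_deviation()]) removes the shared part.
#' @param atrophy_regions base names of left-hemisphere regions atrophied
#'   in patients.
#' @param atrophy_effect_sd surface-area reduction in units of the control
#'   standard deviation (>= 0; applied to patients only).
#' @param tortuosity factor >= 1 mapping Euclidean distance to fibre length.
#' @param fibre_length_cv coefficient of variation of fibre-length noise.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 10L, n_controls = 10L, seed = 1L,
                        edge_density_scale = 50, edge_base_prob = 0.95,
                        edge_contact_radius = 30, region_size_exponent = 0.5,
                        hub_regions = hub_region_names(), hub_boost = 1.5,
                        count_lognormal_mu = 5.5, count_lognormal_sigma = 0.7,
                        count_distance_scale = 25,
                        area_lognormal_sigma = 0.10,
                        area_global_fraction = 0.75,
                        atrophy_regions = atrophy_region_names(),
                        atrophy_effect_sd = 2.0,
                        tortuosity = 1.3, fibre_length_cv = 0.05) {
  stopifnot(n_patients >= 0, edge_density_scale > 0, edge_base_prob > 0,
            count_lognormal_sigma > 0, area_lognormal_sigma > 0,
            area_global_fraction >= 0, area_global_fraction < 1,
            tortuosity >= 1, fibre_length_cv >= 0)
  if (n_controls < 3L) {
    stop("n_controls must be >= 3: leave-one-out deviation scoring needs ",
         "at least 2 remaining controls")
  }
  if (atrophy_effect_sd < 0) stop("atrophy_effect_sd must be >= 0")
  structure(
    list(n_patients = as.integer(n_patients),
         n_controls = as.integer(n_controls), seed = as.integer(seed),
         edge_density_scale = edge_density_scale,
         edge_base_prob = edge_base_prob,
         edge_contact_radius = edge_contact_radius,
         region_size_exponent = region_size_exponent,
         hub_regions = hub_regions, hub_boost = hub_boost,
         count_lognormal_mu = count_lognormal_mu,
         count_lognormal_sigma = count_lognormal_sigma,
         count_distance_scale = count_distance_scale,
         area_lognormal_sigma = area_lognormal_sigma,
         area_global_fraction = area_global_fraction,
         atrophy_regions = atrophy_regions,
         atrophy_effect_sd = atrophy_effect_sd,
         tortuosity = tortuosity, fibre_length_cv = fibre_length_cv),
    class = "cohort_spec"
  )
}

#' Deterministic canonical region coordinates
#'
#' Places the 82 regions in a hemisphere-mirrored 3-D layout (mm): cortical
#' regions on a half-ellipsoidal shell via a golden-spiral lattice, with
#' hand-placed positions for regions whose anatomical adjacency matters to
#' the modelled disease (mesial temporal structures, insula), and the seven
#' subcortical structures in an inner shell. Right-hemisphere regions are
#' exact x-negated mirrors of their left counterparts.
#'
#' The layout is synthetic: it reproduces the coarse geometry of a brain
#' (inter-region distances of roughly 10--160 mm, deep central subcortex,
#' adjacent mesial temporal cluster), not any individual's anatomy.
#'
#' @param atlas atlas table from [load_atlas()].
#' @return An 82x3 matrix of coordinates (mm), rownames = atlas labels.
#' @export
canonical_coordinates <- function(atlas = load_atlas()) {
  n_cort <- 34L
  golden <- pi * (3 - sqrt(5))
  k <- seq_len(n_cort) - 1L
  zf <- 1 - 2 * (k + 0.5) / n_cort
  r <- sqrt(pmax(0, 1 - zf^2))
  theta <- golden * k
  x <- -abs(r * cos(theta)) - 0.15   # keep strictly inside the left half
  y <- r * sin(theta)
  cort <- cbind(x * 60, y * 80, zf * 55)

  base <- atlas$base[seq_len(n_cort)]
  overrides <- rbind(
    temporalpole    = c(-45, -10, -30),
    parahippocampal = c(-30, -24, -18),
    entorhinal      = c(-32, -14, -24),
    insula          = c(-35,   5,   5)
  )
  for (nm in rownames(overrides)) {
    cort[match(nm, base), ] <- overrides[nm, ]
  }
  sub <- rbind(
    accumbens   = c(-10,   8,  -8),
    amygdala    = c(-22,  -2, -14),
    caudate     = c(-14,  10,   8),
    hippocampus = c(-26, -18, -10),
    pallidum    = c(-18,   0,   0),
    putamen     = c(-24,   4,  -2),
    thalamus    = c(-12, -18,   6)
  )
  left <- rbind(cort, sub)
  right <- left
  right[, 1] <- -right[, 1]
  out <- rbind(left, right)
  rownames(out) <- atlas$label
  colnames(out) <- c("x", "y", "z")
  out
}

# Canonical (noise-free) per-region surface areas in mm^2, one hemisphere:
# typical Desikan-Killiany white-surface areas for cortex, grey/white
# interface areas for subcortex. The mesial temporal structures are small,
# which matters downstream (size-scaled connectivity).
canonical_areas <- function(atlas = load_atlas()) {
  cort <- c(
    bankssts = 1000, caudalanteriorcingulate = 700,
    caudalmiddlefrontal = 2300, cuneus = 1500, entorhinal = 450,
    frontalpole = 250, fusiform = 3400, inferiorparietal = 5000,
    inferiortemporal = 3600, insula = 2300, isthmuscingulate = 1000,
    lateraloccipital = 5000, lateralorbitofrontal = 2700, lingual = 3200,
    medialorbitofrontal = 1900, middletemporal = 3500, paracentral = 1400,
    parahippocampal = 700, parsopercularis = 1700, parsorbitalis = 700,
    parstriangularis = 1500, pericalcarine = 1400, postcentral = 4200,
    posteriorcingulate = 1300, precentral = 5200, precuneus = 3900,
    rostralanteriorcingulate = 800, rostralmiddlefrontal = 5500,
    superiorfrontal = 7300, superiorparietal = 5300,
    superiortemporal = 3800, supramarginal = 4000, temporalpole = 500,
    transversetemporal = 400
  )
  sub <- c(accumbens = 150, amygdala = 350, caudate = 600, hippocampus = 700,
           pallidum = 300, putamen = 800, thalamus = 1200)
  stopifnot(identical(names(cort), atlas$base[1:34]))
  out <- c(cort, sub, cort, sub)
  names(out) <- atlas$label
  out
}

# Linear-scale standard deviation of a log-normal with median m and sdlog s.
lognormal_sd <- function(m, s) {
  m * exp(s^2 / 2) * sqrt(exp(s^2) - 1)
}

#' Sample one control connectome
#'
#' Draws a symmetric random connectome: edges appear with probability
#' decaying exponentially in inter-region distance (boosted for hub
#' regions), streamline counts are log-normal with a distance-decaying
#' mean, fibre lengths are tortuosity-scaled Euclidean distances with small
#' multiplicative noise, and surface areas are log-normal around the
#' canonical per-region values.
#'
#' Randomness is taken from the current R RNG stream; seed the stream (or
#' use [generate_cohort()]) for reproducibility.
#'
#' @param spec a [cohort_spec()].
#' @param subject_id character scalar.
#' @param atlas atlas table.
#' @return A validated `connectome` with `group = "control"`.
#' @export
sample_control_connectome <- function(spec, subject_id,
                                      atlas = load_atlas()) {
  xyz <- canonical_coordinates(atlas)
  d <- as.matrix(stats::dist(xyz))
  n <- nrow(atlas)

  dd <- pmax(d - spec$edge_contact_radius, 0)  # pmax(matrix, .) keeps dims
  canon <- canonical_areas(atlas)
  szf <- (canon / stats::median(canon))^spec$region_size_exponent
  size_fac <- outer(szf, szf)
  size_fac[dd == 0] <- 1                 # abutting regions connect regardless
  p <- spec$edge_base_prob * exp(-dd / spec$edge_density_scale) *
    pmin(size_fac, 1)
  hubs <- region_indices(atlas, spec$hub_regions, "both")
  p[hubs, ] <- p[hubs, ] * spec$hub_boost
  p[, hubs] <- p[, hubs] * spec$hub_boost
  p <- pmin(p, 0.95)
  diag(p) <- 0

  up <- upper.tri(d)
  edge <- matrix(FALSE, n, n)
  edge[up] <- runif(sum(up)) < p[up]

  meanlog <- spec$count_lognormal_mu - dd / spec$count_distance_scale +
    log(pmin(size_fac, 1))
  S <- matrix(0, n, n)
  S[up][edge[up]] <- pmax(2, round(rlnorm(sum(edge[up]),
                                          meanlog = meanlog[up][edge[up]],
                                          sdlog = spec$count_lognormal_sigma)))
  S <- S + t(S)

  L <- matrix(0, n, n)
  len <- d[up][edge[up]] * spec$tortuosity *
    pmax(0.5, 1 + rnorm(sum(edge[up]), 0, spec$fibre_length_cv))
  L[up][edge[up]] <- len
  L <- L + t(L)

  canon <- canonical_areas(atlas)
  sg <- spec$area_lognormal_sigma * sqrt(spec$area_global_fraction)
  sr <- spec$area_lognormal_sigma * sqrt(1 - spec$area_global_fraction)
  global <- rnorm(1, 0, sg)
  areas <- rlnorm(n, meanlog = log(canon) + global, sdlog = sr)

  connectome(subject_id, "control", S, L, areas, atlas)
}

#' Sample one patient connectome
#'
#' A control draw whose surface areas in the atrophy regions (left
#' hemisphere) are reduced by `atrophy_effect_sd` times that region's
#' control-population standard deviation, floored at 5% of the canonical
#' area so areas stay strictly positive. With `atrophy_effect_sd = 0` the
#' patient distribution is identical to the control distribution.
#'
#' @inheritParams sample_control_connectome
#' @return A validated `connectome` with `group = "patient"`.
#' @export
sample_patient_connectome <- function(spec, subject_id,
                                      atlas = load_atlas()) {
  x <- sample_control_connectome(spec, subject_id, atlas)
  x$group <- "patient"
  idx <- region_indices(atlas, spec$atrophy_regions, "left")
  canon <- canonical_areas(atlas)
  pop_sd <- lognormal_sd(canon[idx], spec$area_lognormal_sigma)
  x$areas[idx] <- pmax(x$areas[idx] - spec$atrophy_effect_sd * pop_sd,
                       0.05 * canon[idx])
  validate_connectome(x)
}

#' Generate a full synthetic cohort
#'
#' Draws `n_controls` control and `n_patients` patient connectomes,
#' reproducibly from `spec$seed`. If `dir` is given, each subject is written
#' via [write_connectome()] under `dir/<subject_id>/` together with a
#' `manifest.tsv` and an echo of the generating spec.
#'
#' @param spec a [cohort_spec()].
#' @param dir optional output directory.
#' @param atlas atlas table.
#' @return A list with elements `connectomes` (named list) and `manifest`
#'   (data.frame with `subject_id`, `group`).
#' @export
generate_cohort <- function(spec, dir = NULL, atlas = load_atlas()) {
  stopifnot(inherits(spec, "cohort_spec"))
  ids_c <- sprintf("control%02d", seq_len(spec$n_controls))
  ids_p <- sprintf("patient%02d", seq_len(spec$n_patients))
  cons <- with_seed(spec$seed, {
    c(lapply(ids_c, function(id) sample_control_connectome(spec, id, atlas)),
      lapply(ids_p, function(id) sample_patient_connectome(spec, id, atlas)))
  })
  names(cons) <- c(ids_c, ids_p)
  manifest <- data.frame(
    subject_id = names(cons),
    group = vapply(cons, `[[`, "", "group"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (x in cons) write_connectome(x, file.path(dir, x$subject_id))
    write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    cfg <- data.frame(
      key = names(spec),
      value = vapply(spec, function(v) paste(format(v), collapse = ","), ""),
      row.names = NULL
    )
    write.table(cfg, file.path(dir, "cohort_spec.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  list(connectomes = cons, manifest = manifest)
}

#' Read a cohort written by [generate_cohort()]
#'
#' @param dir cohort directory containing `manifest.tsv`.
#' @param atlas atlas table.
#' @return As [generate_cohort()].
#' @export
read_cohort <- function(dir, atlas = load_atlas()) {
  mf <- file.path(dir, "manifest.tsv")
  if (!file.exists(mf)) stop("no manifest.tsv under ", dir)
  manifest <- read.delim(mf, stringsAsFactors = FALSE)
  cons <- lapply(manifest$subject_id, function(id) {
    read_connectome(file.path(dir, id), atlas)
  })
  names(cons) <- manifest$subject_id
  list(connectomes = cons, manifest = manifest)
}
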