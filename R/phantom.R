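# Synthetic two-channel z-stack phantoms: membrane-delimited, optionally
# branched rod-shaped cells (hemispherically capped capsules) containing 1-2
# ellipsoidal nuclei whose integrated nuclear-channel intensity is
# proportional to ploidy, plus nuclei-only control fields emulating the
# haploid "semen spot" ploidy control. Full ground truth is returned so
# every downstream stage can be validated without tissue data.

#' Phantom specification
#'
#' Study conditions for the synthetic generator. Geometry is in micrometres,
#' intensities in detector counts. The nuclear channel is `"DAPI"`, the
#' membrane channel `"WGA"`. The membrane shell of each cell is drawn just
#' outside the true cell region, so the ground-truth cell label is the volume
#' enclosed by the membrane staining -- the quantity the seeded growth
#' "to the limits of the membrane staining" measures.
#'
#' @param shape voxel counts (z, y, x)
#' @param voxel_size voxel extents (z, y, x) in um
#' @param n_cells number of cells (or nuclei, for control fields)
#' @param cell_length_range,cell_diameter_range cell geometry ranges in um;
#'   length is tip-to-tip, so an unbranched cell of length L and radius
#'   r = diameter/2 has the capsule volume pi r^2 (L - 2r) + 4/3 pi r^3
#' @param branch_probability probability that a cell carries one branch
#' @param nuclearity_probs named probabilities over nuclearity `"1"`, `"2"`
#' @param ploidy_probs named probabilities over classes `"2n"`, `"4n"`
#'   (applied per cell: all nuclei of one cell share a class, as observed for
#'   binucleated tetraploid cardiomyocytes)
#' @param reference_2n_intensity integrated nuclear-channel counts of a
#'   diploid nucleus before scatter
#' @param intensity_cv coefficient of variation of integrated nuclear
#'   intensity within a ploidy class (lognormal scatter)
#' @param membrane_thickness membrane shell thickness, um
#' @param membrane_intensity,cytoplasm_intensity,background_intensity channel
#'   levels in counts
#' @param noise_sd additive Gaussian noise SD, counts
#' @param z_attenuation per-um exponential decay coefficient (0 = none)
#' @param saturation_limit maximum representable intensity
#' @param nucleus_axes ellipsoid semi-axes in um: along the cell axis, then
#'   the two transverse semi-axes
#' @param max_place_attempts rejection-sampling retry budget per cell
#' @param seed RNG seed; identical spec + seed gives bit-identical output
#' @return a validated `PhantomSpec`
#' @export
phantom_spec <- function(shape = c(64L, 256L, 256L),
                         voxel_size = c(0.5, 0.5, 0.5),
                         n_cells = 16L,
                         cell_length_range = c(30, 42),
                         cell_diameter_range = c(8, 11),
                         branch_probability = 0.15,
                         nuclearity_probs = c("1" = 0.25, "2" = 0.75),
                         ploidy_probs = c("2n" = 0.9, "4n" = 0.1),
                         reference_2n_intensity = 8e6,
                         intensity_cv = 0.05,
                         membrane_thickness = 1.0,
                         membrane_intensity = 1400,
                         cytoplasm_intensity = 200,
                         background_intensity = 100,
                         noise_sd = 50,
                         z_attenuation = 0,
                         saturation_limit = 65535,
                         nucleus_axes = c(5, 2.2, 2.2),
                         max_place_attempts = 100L,
                         seed = 1L) {
  spec <- list(shape = as.integer(shape), voxel_size = as.numeric(voxel_size),
               n_cells = as.integer(n_cells),
               cell_length_range = cell_length_range,
               cell_diameter_range = cell_diameter_range,
               branch_probability = branch_probability,
               nuclearity_probs = nuclearity_probs,
               ploidy_probs = ploidy_probs,
               reference_2n_intensity = reference_2n_intensity,
               intensity_cv = intensity_cv,
               membrane_thickness = membrane_thickness,
               membrane_intensity = membrane_intensity,
               cytoplasm_intensity = cytoplasm_intensity,
               background_intensity = background_intensity,
               noise_sd = noise_sd, z_attenuation = z_attenuation,
               saturation_limit = saturation_limit,
               nucleus_axes = as.numeric(nucleus_axes),
               max_place_attempts = as.integer(max_place_attempts),
               seed = as.integer(seed))
  validate_phantom_spec(spec)
  structure(spec, class = "PhantomSpec")
}

validate_phantom_spec <- function(s) {
  chk_pos <- function(name) {
    v <- s[[name]]
    if (any(!is.finite(v)) || any(v <= 0))
      stop_named("invalid_spec", "phantom spec field '%s' must be positive", name)
  }
  for (f in c("shape", "voxel_size", "cell_length_range", "cell_diameter_range",
              "reference_2n_intensity", "membrane_thickness",
              "membrane_intensity", "saturation_limit", "nucleus_axes",
              "max_place_attempts"))
    chk_pos(f)
  for (f in c("branch_probability", "intensity_cv", "noise_sd",
              "z_attenuation", "background_intensity", "cytoplasm_intensity"))
    if (any(s[[f]] < 0))
      stop_named("invalid_spec", "phantom spec field '%s' must be non-negative", f)
  if (s$n_cells < 0)
    stop_named("invalid_spec", "phantom spec field 'n_cells' must be >= 0")
  for (f in c("nuclearity_probs", "ploidy_probs")) {
    p <- s[[f]]
    if (is.null(names(p)) || any(p < 0) || abs(sum(p) - 1) > 1e-8)
      stop_named("invalid_spec",
                 "phantom spec field '%s' must be named probabilities summing to 1", f)
  }
  if (min(s$cell_length_range) <= max(s$cell_diameter_range))
    stop_named("invalid_spec",
               "cell_length_range must exceed cell_diameter_range (tip-to-tip length)")
  ext <- s$shape * s$voxel_size
  need <- min(s$cell_length_range) + 2 * (1.5 * s$membrane_thickness + 0.5)
  if (s$n_cells > 0 && max(ext[2:3]) < need)
    stop_named("invalid_spec",
               "stack extent too small to hold a cell of minimum length")
  invisible(s)
}

# voxel indices (linear, 1-based) and distances for all voxels of the full
# array whose centres lie within `radius` of any of the given segments.
# segs: list of list(A=, B=) physical um coordinates (z,y,x).
raster_segments <- function(dm, vox, segs, radius) {
  pts <- do.call(rbind, lapply(segs, function(s) rbind(s$A, s$B)))
  lo <- pmax(floor((apply(pts, 2, min) - radius) / vox), 0)
  hi <- pmin(ceiling((apply(pts, 2, max) + radius) / vox), dm)
  if (any(hi <= lo)) return(list(idx = integer(0), d = numeric(0)))
  zi <- (lo[1] + 1):hi[1]; yi <- (lo[2] + 1):hi[2]; xi <- (lo[3] + 1):hi[3]
  nzb <- length(zi); nyb <- length(yi); nxb <- length(xi)
  zc <- (zi - 0.5) * vox[1]; yc <- (yi - 0.5) * vox[2]; xc <- (xi - 0.5) * vox[3]
  Z <- rep(zc, times = nyb * nxb)
  Y <- rep(rep(yc, each = nzb), times = nxb)
  X <- rep(xc, each = nzb * nyb)
  d2 <- rep(Inf, nzb * nyb * nxb)
  for (s in segs) {
    ab <- s$B - s$A
    L2 <- sum(ab^2)
    pz <- Z - s$A[1]; py <- Y - s$A[2]; px <- X - s$A[3]
    tt <- if (L2 > 0) pmin(pmax((pz * ab[1] + py * ab[2] + px * ab[3]) / L2, 0), 1) else 0
    dz <- pz - tt * ab[1]; dy <- py - tt * ab[2]; dx <- px - tt * ab[3]
    d2 <- pmin(d2, dz * dz + dy * dy + dx * dx)
  }
  keep <- d2 <= radius^2
  # linear index into the full (z,y,x) array
  iz <- rep(zi, times = nyb * nxb)
  iy <- rep(rep(yi, each = nzb), times = nxb)
  ix <- rep(xi, each = nzb * nyb)
  lin <- iz + dm[1] * (iy - 1) + dm[1] * dm[2] * (ix - 1)
  list(idx = lin[keep], d = sqrt(d2[keep]))
}

# voxel indices within an ellipsoid of revolution: semi-axis a1 along unit
# vector u, semi-axis a2 transverse; centre C (um).
raster_spheroid <- function(dm, vox, C, u, a1, a2) {
  r <- max(a1, a2)
  lo <- pmax(floor((C - r) / vox), 0)
  hi <- pmin(ceiling((C + r) / vox), dm)
  if (any(hi <= lo)) return(integer(0))
  zi <- (lo[1] + 1):hi[1]; yi <- (lo[2] + 1):hi[2]; xi <- (lo[3] + 1):hi[3]
  nzb <- length(zi); nyb <- length(yi); nxb <- length(xi)
  Z <- rep((zi - 0.5) * vox[1], times = nyb * nxb) - C[1]
  Y <- rep(rep((yi - 0.5) * vox[2], each = nzb), times = nxb) - C[2]
  X <- rep((xi - 0.5) * vox[3], each = nzb * nyb) - C[3]
  ax <- Z * u[1] + Y * u[2] + X * u[3]
  perp2 <- pmax(Z * Z + Y * Y + X * X - ax * ax, 0)
  keep <- (ax / a1)^2 + perp2 / a2^2 <= 1
  iz <- rep(zi, times = nyb * nxb)
  iy <- rep(rep(yi, each = nzb), times = nxb)
  ix <- rep(xi, each = nzb * nyb)
  lin <- iz + dm[1] * (iy - 1) + dm[1] * dm[2] * (ix - 1)
  lin[keep]
}

ploidy_factor <- function(class) as.numeric(sub("n$", "", class)) / 2

#' Generate a synthetic two-channel cardiomyocyte phantom
#'
#' Places non-overlapping capsule-shaped cells (optionally with one branch)
#' with at least one membrane-thickness gap between membrane shells, draws
#' cytoplasm and membrane on the membrane channel and ellipsoidal nuclei on
#' the nuclear channel, applies optional depth attenuation, additive Gaussian
#' noise, and clipping at the saturation limit.
#'
#' @param spec a [phantom_spec()]
#' @return list with `stack` (a `ZStack`) and `truth` (a `GroundTruth`: cell
#'   and nucleus `LabelVolume`s plus per-cell and per-nucleus tables; nucleus
#'   `true_intensity` is the summed nuclear-channel signal over the nucleus
#'   mask before background, noise, attenuation and clipping)
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  with_seed(spec$seed, {
    dm <- spec$shape
    vox <- spec$voxel_size
    ext <- dm * vox
    n <- prod(dm)
    t <- spec$membrane_thickness
    pad <- 0.5
    nc <- spec$n_cells

    dapi <- array(spec$background_intensity, dm)
    wga <- array(spec$background_intensity, dm)
    cell_lab <- array(0L, dm)
    nuc_lab <- array(0L, dm)
    forbidden <- logical(n)

    # --- geometry sampling -------------------------------------------------
    # orientation near the x axis (myofibre-like alignment; small tilt out of
    # plane) so the structured row layout below can guarantee placement
    geoms <- vector("list", nc)
    for (i in seq_len(nc)) {
      L <- runif(1, spec$cell_length_range[1], spec$cell_length_range[2])
      r <- runif(1, spec$cell_diameter_range[1],
                 spec$cell_diameter_range[2]) / 2
      Ls <- L - 2 * r    # axis-segment length: hemispherical caps add 2r
      tilt <- runif(1, -5, 5) * pi / 180
      az <- runif(1, -4, 4) * pi / 180
      u <- c(sin(tilt), cos(tilt) * sin(az), cos(tilt) * cos(az))
      m <- r + 1.5 * t   # forbidden radius: shell (t) + half-gap (t/2)
      # branch decided now so the layout reserves room for it
      branch <- NULL
      if (runif(1) < spec$branch_probability) {
        fu <- runif(1, 0.35, 0.65)
        th <- sample(c(-1, 1), 1) * runif(1, 35, 60) * pi / 180
        u2 <- c(runif(1, -0.1, 0.1),
                u[2] * cos(th) + u[3] * sin(th),
                -u[2] * sin(th) + u[3] * cos(th))
        u2 <- u2 / sqrt(sum(u2^2))
        L2 <- min(runif(1, 0.3, 0.45) * Ls, 12)
        branch <- list(fu = fu, u2 = u2, L2 = L2)
      }
      # half-extent of the axis skeleton (main axis + branch tip) per axis,
      # measured from the cell centre
      half <- abs(Ls / 2 * u)
      if (!is.null(branch)) {
        v <- (branch$fu - 0.5) * Ls * u + branch$L2 * branch$u2
        half <- pmax(half, abs(v))
      }
      geoms[[i]] <- list(L = L, Ls = Ls, r = r, u = u, m = m, branch = branch,
                         ex = 2 * (half[3] + m + pad),
                         sy = half[2],
                         az_half = half[1])
    }

    # --- structured layout -------------------------------------------------
    # rows along y, cells side by side along x; rows alternate between a low
    # and a high z band, so adjacent rows only need the in-plane distance
    # sqrt(M^2 - dz^2) between axes (M = sum of forbidden radii). Same-band
    # rows (two apart) are kept a full M apart in y. Non-overlap holds by
    # construction; the forbidden mask below re-verifies it voxelwise.
    rows <- list()
    cur <- integer(0)
    x_used <- 0
    for (i in seq_len(nc)) {
      g <- geoms[[i]]
      if (g$ex > ext[3])
        stop_named("placement_failure",
                   "could only place %d of %d cells without overlap", 0L, nc)
      if (length(cur) && x_used + g$ex > ext[3]) {
        rows <- c(rows, list(cur))
        cur <- integer(0)
        x_used <- 0
      }
      cur <- c(cur, i)
      x_used <- x_used + g$ex
    }
    if (length(cur)) rows <- c(rows, list(cur))

    centers <- matrix(NA_real_, nc, 3)
    prev <- NULL
    prev2 <- NULL
    placed <- 0L
    for (k in seq_along(rows)) {
      idx <- rows[[k]]
      low_band <- k %% 2 == 1
      zs <- numeric(length(idx))
      for (j in seq_along(idx)) {
        g <- geoms[[idx[j]]]
        hz <- g$az_half + g$m + pad
        if (2 * hz > ext[1])
          stop_named("placement_failure",
                     "could only place %d of %d cells without overlap",
                     placed, nc)
        zj <- runif(1, 0, 0.5)
        zs[j] <- if (low_band) hz + zj else ext[1] - hz - zj
      }
      m_max <- max(vapply(geoms[idx], `[[`, 0, "m"))
      sy_max <- max(vapply(geoms[idx], `[[`, 0, "sy"))
      az_halfs <- vapply(geoms[idx], `[[`, 0, "az_half")
      z_ax_lo <- min(zs - az_halfs)
      z_ax_hi <- max(zs + az_halfs)
      y_half <- m_max + sy_max + pad
      if (k == 1) {
        y_c <- y_half
      } else {
        M <- prev$m_max + m_max + pad
        dz_min <- if (z_ax_lo > prev$z_ax_hi) z_ax_lo - prev$z_ax_hi
                  else if (prev$z_ax_lo > z_ax_hi) prev$z_ax_lo - z_ax_hi
                  else 0
        dy_req <- sqrt(max(0, M^2 - dz_min^2))
        y_c <- prev$y_c + dy_req + prev$sy_max + sy_max
        if (!is.null(prev2))
          y_c <- max(y_c, prev2$y_c + prev2$m_max + m_max + pad +
                       prev2$sy_max + sy_max)
      }
      if (y_c + y_half > ext[2])
        stop_named("placement_failure",
                   "could only place %d of %d cells without overlap",
                   placed, nc)
      x_total <- sum(vapply(geoms[idx], `[[`, 0, "ex"))
      cursor <- runif(1, 0, ext[3] - x_total)
      for (j in seq_along(idx)) {
        g <- geoms[[idx[j]]]
        centers[idx[j], ] <- c(zs[j], y_c, cursor + g$ex / 2)
        cursor <- cursor + g$ex
        placed <- placed + 1L
      }
      prev2 <- prev
      prev <- list(y_c = y_c, m_max = m_max, sy_max = sy_max,
                   z_ax_lo = z_ax_lo, z_ax_hi = z_ax_hi)
    }

    # --- painting and ground truth -----------------------------------------
    cells <- list()
    nuclei <- list()
    nuc_id <- 0L
    for (i in seq_len(nc)) {
      g <- geoms[[i]]
      Ls <- g$Ls; r <- g$r; u <- g$u
      C <- centers[i, ]
      A <- C - Ls / 2 * u
      B <- C + Ls / 2 * u
      segs <- list(list(A = A, B = B))
      if (!is.null(g$branch)) {
        P <- A + g$branch$fu * (B - A)
        segs <- c(segs, list(list(A = P, B = P + g$branch$L2 * g$branch$u2)))
      }
      ras <- raster_segments(dm, vox, segs, r + 1.5 * t)
      if (any(forbidden[ras$idx]))
        stop_named("placement_failure",
                   "could only place %d of %d cells without overlap", i - 1L,
                   nc)

      interior <- ras$idx[ras$d <= r]
      shell <- ras$idx[ras$d > r & ras$d <= r + t]
      cell_lab[interior] <- i
      wga[interior] <- spec$cytoplasm_intensity
      wga[shell] <- spec$membrane_intensity
      forbidden[ras$idx] <- TRUE

      # nuclei along the main axis
      m_nuc <- as.integer(sample(names(spec$nuclearity_probs), 1,
                                 prob = spec$nuclearity_probs))
      pclass <- sample(names(spec$ploidy_probs), 1, prob = spec$ploidy_probs)
      na <- spec$nucleus_axes
      fr <- if (m_nuc == 1) 0.5 + runif(1, -0.05, 0.05) else {
        # sibling nuclei must stay resolvable: centre separation at least
        # 2 * major semi-axis + 2 um, whatever the axis-segment length
        u0_lo <- max(0.22, (na[1] + 1) / Ls)
        u0 <- runif(1, u0_lo, max(u0_lo + 0.02, 0.30))
        c(0.5 - u0, 0.5 + u0)
      }
      fr <- pmin(pmax(fr, (na[1] + 0.5 - r) / Ls), 1 - (na[1] + 0.5 - r) / Ls)
      for (f in fr) {
        nuc_id <- nuc_id + 1L
        Cn <- A + f * (B - A)
        idxn <- raster_spheroid(dm, vox, Cn, u, na[1], na[2])
        idxn <- idxn[cell_lab[idxn] == i]  # guarantee containment
        Td <- spec$reference_2n_intensity * ploidy_factor(pclass) *
          rlnorm_cv(1, spec$intensity_cv)
        per_vox <- round(Td / length(idxn))
        dapi[idxn] <- dapi[idxn] + per_vox
        nuc_lab[idxn] <- nuc_id
        nuclei[[nuc_id]] <- data.frame(
          nucleus_id = nuc_id, cell_id = i,
          true_intensity = per_vox * length(idxn),
          ploidy_class = pclass, voxel_count = length(idxn))
      }
      cells[[i]] <- data.frame(
        cell_id = i, voxel_count = length(interior),
        volume_um3 = length(interior) * prod(vox),
        nuclearity = m_nuc,
        ploidy_label = if (m_nuc == 1) pclass else paste0(m_nuc, "*", pclass),
        branched = length(segs) > 1)
    }

    finalize_phantom(spec, dapi, wga, cell_lab, nuc_lab, cells, nuclei,
                     provenance = sprintf("phantom(seed=%d)", spec$seed))
  })
}

#' Generate a control field of nuclei with known genome copy number
#'
#' Emulates the ploidy control: a field of well-separated ellipsoidal nuclei
#' (no membrane signal) whose integrated intensities are
#' `reference_2n_intensity * control_genome_copies / 2` times a lognormal
#' scatter. `spec$n_cells` gives the number of nuclei.
#'
#' @param spec a [phantom_spec()]
#' @param control_genome_copies genome copies per control nucleus (1 for a
#'   haploid sperm-like control)
#' @return as [generate_phantom()]; the ground-truth cell table is empty
#' @export
generate_control_field <- function(spec, control_genome_copies = 1) {
  validate_phantom_spec(spec)
  if (!is.finite(control_genome_copies) || control_genome_copies <= 0)
    stop_named("invalid_control", "control_genome_copies must be positive")
  lattice_nuclei_field(
    spec,
    draw = function() list(pclass = NA_character_,
                           factor = control_genome_copies / 2),
    provenance = sprintf("control_field(seed=%d, copies=%g)", spec$seed,
                         control_genome_copies))
}

# shared placement for nuclei-only fields: a deterministic lattice with
# random orientation and intensity per nucleus. The minimum centre spacing
# so two major-axis tips can never touch is 2 * major semi-axis; 0.5 um
# clearance is added. High counts would jam a rejection sampler; a lattice
# cannot.
lattice_nuclei_field <- function(spec, draw, provenance) {
  with_seed(spec$seed, {
    dm <- spec$shape
    vox <- spec$voxel_size
    ext <- dm * vox
    na <- spec$nucleus_axes

    dapi <- array(spec$background_intensity, dm)
    wga <- array(spec$background_intensity, dm)
    nuc_lab <- array(0L, dm)
    nuclei <- list()

    min_pitch <- 2 * na[1] + 0.5
    margin <- na[1] + 0.5
    nreq <- spec$n_cells
    if (nreq > 0) {
      span <- ext - 2 * margin
      if (any(span < 0))
        stop_named("placement_failure", "could only place %d of %d nuclei",
                   0L, nreq)
      n_layers <- max(1L, floor(span[1] / min_pitch) + 1L)
      per_layer <- ceiling(nreq / n_layers)
      k <- ceiling(sqrt(per_layer))
      pitch_xy <- span[2:3] / max(k - 1, 1)
      if (k > 1 && any(pitch_xy < min_pitch))
        stop_named("placement_failure", "could only place %d of %d nuclei",
                   0L, nreq)
      zl <- if (n_layers == 1) margin + span[1] / 2
            else margin + (seq_len(n_layers) - 1) * span[1] / (n_layers - 1)
      grid <- expand.grid(z = zl,
                          y = margin + (seq_len(k) - 1) * pitch_xy[1],
                          x = margin + (seq_len(k) - 1) * pitch_xy[2])
      if (nrow(grid) < nreq)
        stop_named("placement_failure", "could only place %d of %d nuclei",
                   nrow(grid), nreq)
      for (i in seq_len(nreq)) {
        C <- as.numeric(grid[i, ])
        az <- runif(1, 0, 2 * pi)
        tilt <- runif(1, -10, 10) * pi / 180
        u <- c(sin(tilt), cos(tilt) * sin(az), cos(tilt) * cos(az))
        idxn <- raster_spheroid(dm, vox, C, u, na[1], na[2])
        d <- draw()
        Td <- spec$reference_2n_intensity * d$factor *
          rlnorm_cv(1, spec$intensity_cv)
        per_vox <- round(Td / length(idxn))
        dapi[idxn] <- dapi[idxn] + per_vox
        nuc_lab[idxn] <- i
        nuclei[[i]] <- data.frame(
          nucleus_id = i, cell_id = NA_integer_,
          true_intensity = per_vox * length(idxn),
          ploidy_class = d$pclass, voxel_count = length(idxn))
      }
    }
    finalize_phantom(spec, dapi, wga, array(0L, dm), nuc_lab, list(), nuclei,
                     provenance = provenance)
  })
}

#' Generate a field of nuclei with mixed ploidy
#'
#' Like [generate_control_field()], but each nucleus draws its ploidy class
#' from `spec$ploidy_probs` and its integrated intensity from
#' `reference_2n_intensity * (ploidy / 2n) * lognormal(1, intensity_cv)` --
#' a pure densitometry target without cell segmentation in the way.
#' `spec$n_cells` gives the number of nuclei.
#'
#' @param spec a [phantom_spec()]
#' @return as [generate_phantom()]; the ground-truth cell table is empty
#' @export
generate_nuclei_field <- function(spec) {
  validate_phantom_spec(spec)
  lattice_nuclei_field(
    spec,
    draw = function() {
      pclass <- sample(names(spec$ploidy_probs), 1, prob = spec$ploidy_probs)
      list(pclass = pclass, factor = ploidy_factor(pclass))
    },
    provenance = sprintf("nuclei_field(seed=%d)", spec$seed))
}

#' Generate a dense tissue-like nuclei slab
#'
#' Nucleus centres are uniform over the whole volume (clipping at every
#' border is allowed, as when tissue continues beyond the imaged stack) and
#' nuclei may overlap -- later nuclei overwrite earlier labels where they do.
#' The result is a nuclear channel that is statistically uniform with depth,
#' the regime the acquisition QC criteria assume; use it for QC and
#' attenuation fixtures, not for densitometry or morphometry (ground-truth
#' intensities are only exact for non-overlapping nuclei).
#'
#' @param spec a [phantom_spec()]; `n_cells` gives the number of nuclei
#' @return as [generate_phantom()]; the ground-truth cell table is empty
#' @export
generate_tissue_field <- function(spec) {
  validate_phantom_spec(spec)
  with_seed(spec$seed, {
    dm <- spec$shape
    vox <- spec$voxel_size
    ext <- dm * vox
    na <- spec$nucleus_axes

    dapi <- array(spec$background_intensity, dm)
    wga <- array(spec$background_intensity, dm)
    nuc_lab <- array(0L, dm)
    nuclei <- list()

    for (i in seq_len(spec$n_cells)) {
      C <- runif(3, 0, ext)
      az <- runif(1, 0, 2 * pi)
      tilt <- runif(1, -10, 10) * pi / 180
      u <- c(sin(tilt), cos(tilt) * sin(az), cos(tilt) * cos(az))
      idxn <- raster_spheroid(dm, vox, C, u, na[1], na[2])
      pclass <- sample(names(spec$ploidy_probs), 1, prob = spec$ploidy_probs)
      Td <- spec$reference_2n_intensity * ploidy_factor(pclass) *
        rlnorm_cv(1, spec$intensity_cv)
      nvox <- max(length(idxn), 1L)
      per_vox <- round(Td / nvox)
      dapi[idxn] <- dapi[idxn] + per_vox
      nuc_lab[idxn] <- i
      nuclei[[i]] <- data.frame(
        nucleus_id = i, cell_id = NA_integer_,
        true_intensity = per_vox * length(idxn),
        ploidy_class = pclass, voxel_count = length(idxn))
    }
    finalize_phantom(spec, dapi, wga, array(0L, dm), nuc_lab, list(), nuclei,
                     provenance = sprintf("tissue_field(seed=%d)", spec$seed))
  })
}

# shared tail of both generators: attenuation, noise, clipping, ground truth
finalize_phantom <- function(spec, dapi, wga, cell_lab, nuc_lab, cells, nuclei,
                             provenance) {
  dm <- spec$shape
  vox <- spec$voxel_size

  if (spec$z_attenuation > 0) {
    fac <- exp(-spec$z_attenuation * (seq_len(dm[1]) - 1) * vox[1])
    dapi <- dapi * fac  # recycles along z (first dimension)
    wga <- wga * fac
  }
  if (spec$noise_sd > 0) {
    dapi <- dapi + rnorm(length(dapi), 0, spec$noise_sd)
    wga <- wga + rnorm(length(wga), 0, spec$noise_sd)
  }
  dapi <- array(pmin(pmax(round(dapi), 0), spec$saturation_limit), dm)
  wga <- array(pmin(pmax(round(wga), 0), spec$saturation_limit), dm)

  cells_df <- if (length(cells)) do.call(rbind, cells) else
    data.frame(cell_id = integer(0), voxel_count = integer(0),
               volume_um3 = numeric(0), nuclearity = integer(0),
               ploidy_label = character(0), branched = logical(0))
  nuclei_df <- if (length(nuclei)) do.call(rbind, nuclei) else
    data.frame(nucleus_id = integer(0), cell_id = integer(0),
               true_intensity = numeric(0), ploidy_class = character(0),
               voxel_count = integer(0))

  if (nrow(cells_df)) {
    cen <- label_centroids_um(cell_lab, vox)
    at <- match(cells_df$cell_id, as.integer(rownames(cen)))
    cells_df$centroid_z <- cen[at, "z"]
    cells_df$centroid_y <- cen[at, "y"]
    cells_df$centroid_x <- cen[at, "x"]
    cells_df$touches_border <- cells_df$cell_id %in% labels_touching_border(cell_lab)
  }
  if (nrow(nuclei_df)) {
    cen <- label_centroids_um(nuc_lab, vox)
    at <- match(nuclei_df$nucleus_id, as.integer(rownames(cen)))
    nuclei_df$centroid_z <- cen[at, "z"]
    nuclei_df$centroid_y <- cen[at, "y"]
    nuclei_df$centroid_x <- cen[at, "x"]
  }

  stack <- zstack(list(DAPI = dapi, WGA = wga), vox, bit_depth = 16L,
                  provenance = provenance)
  truth <- structure(list(
    cell_labels = label_volume(cell_lab, vox, "cells"),
    nucleus_labels = label_volume(nuc_lab, vox, "nuclei"),
    cells = cells_df, nuclei = nuclei_df), class = "GroundTruth")
  list(stack = stack, truth = truth)
}

#' Apply exponential depth attenuation to a stack
#'
#' Multiplies every channel's plane at depth `d` um (measured from the first
#' plane) by `exp(-coefficient * d)`, emulating signal loss deeper in tissue.
#'
#' @param stack a `ZStack`
#' @param coefficient per-um decay coefficient; 0 returns the stack unchanged
#' @return an attenuated `ZStack`
#' @export
apply_z_attenuation <- function(stack, coefficient) {
  if (!is.finite(coefficient) || coefficient < 0)
    stop_named("invalid_coefficient", "attenuation coefficient must be >= 0")
  if (coefficient == 0) return(stack)
  nzp <- dim(stack$channels[[1]])[1]
  fac <- exp(-coefficient * (seq_len(nzp) - 1) * stack$voxel_size[1])
  stack$channels <- lapply(stack$channels, function(ch) {
    d <- dim(ch)
    array(ch * fac, d)  # fac recycles along z, the fastest-varying index
  })
  stack
}
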