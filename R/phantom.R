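# Synthetic multi-centre phantom generator.
#
# The phantom world: a two-channel 3D volume (a bright-tumour DWI-like
# channel and an inverted-contrast T2W-like channel) containing one tumour
# modelled as a randomly oriented ellipsoid with a smooth boundary
# perturbation. The EMVI-like label adds thin tubular protrusions beyond the
# tumour body (a fine boundary feature); the CR-like label controls coarse
# attributes (overall size and internal texture heterogeneity). Per-centre
# acquisition variability is a multiplicative gain, a smooth bias field and
# additive Gaussian noise.

#' Multi-channel 3D volume with voxel spacing
#'
#' @param data 4D numeric array `(nx, ny, nz, n_channels)`, or a 3D array for
#'   a single channel.
#' @param spacing voxel size in mm per axis (3 positive reals).
#' @param channel_names ordered channel names (default `c("DWI", "T2W")`
#'   truncated to the number of channels).
#' @param origin world coordinates of voxel (0, 0, 0).
#' @return a `volume_image` object.
#' @export
volume_image <- function(data, spacing, channel_names = NULL, origin = c(0, 0, 0)) {
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
  stopifnot(length(dim(data)) == 4L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive reals")
  if (any(!is.finite(data))) stop("volume values must be finite")
  nc <- dim(data)[4]
  if (is.null(channel_names)) channel_names <- c("DWI", "T2W", paste0("C", seq_len(nc)))[seq_len(nc)]
  stopifnot(length(channel_names) == nc)
  structure(list(data = data, spacing = as.numeric(spacing),
                 channel_names = channel_names, origin = as.numeric(origin)),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("volume_image %dx%dx%d, channels [%s], spacing %s mm\n",
              d[1], d[2], d[3], paste(x$channel_names, collapse = ", "),
              paste(format(x$spacing), collapse = "x")))
  invisible(x)
}

#' Binary tumour mask on an image grid
#'
#' @param data 3D array with values in \{0, 1\}.
#' @param spacing voxel size in mm per axis.
#' @return a `binary_mask` object.
#' @export
binary_mask <- function(data, spacing) {
  stopifnot(length(dim(data)) == 3L)
  if (!all(data %in% c(0, 1))) stop("mask values must be in {0, 1}")
  structure(list(data = array(as.numeric(data), dim(data)),
                 spacing = as.numeric(spacing)),
            class = "binary_mask")
}

#' Acquisition profile of one imaging centre
#'
#' Emulates scanner/protocol heterogeneity: a multiplicative intensity gain,
#' a smooth low-frequency bias field amplitude, additive Gaussian noise, and
#' the centre's acquisition voxel spacing.
#'
#' @param centre_id centre identifier string.
#' @param gain multiplicative intensity factor (> 0).
#' @param bias_amplitude amplitude of the smooth bias field (>= 0).
#' @param noise_sigma additive Gaussian noise standard deviation (>= 0).
#' @param spacing acquisition spacing in mm per axis.
#' @return a `centre_profile` object.
#' @export
centre_profile <- function(centre_id, gain = 1, bias_amplitude = 0,
                           noise_sigma = 0, spacing = c(2, 2, 2)) {
  stopifnot(gain > 0, bias_amplitude >= 0, noise_sigma >= 0,
            length(spacing) == 3L, all(spacing > 0))
  structure(list(centre_id = as.character(centre_id), gain = gain,
                 bias_amplitude = bias_amplitude, noise_sigma = noise_sigma,
                 spacing = as.numeric(spacing)),
            class = "centre_profile")
}

#' Default nine-centre panel
#'
#' Nine centre profiles with mild gain, bias and noise spread, emulating a
#' multi-centre cohort acquired on many scanners and protocols.
#'
#' @param n_centres number of centres (default 9).
#' @param seed integer seed for the profile draw.
#' @return list of [centre_profile] objects, ids `"C1"..."Cn"`.
#' @export
default_centre_profiles <- function(n_centres = 9L, seed = 202L) {
  with_seed(seed, {
    lapply(seq_len(n_centres), function(i)
      centre_profile(paste0("C", i),
                     gain = runif(1, 0.85, 1.15),
                     bias_amplitude = runif(1, 0, 0.08),
                     noise_sigma = runif(1, 0.18, 0.30),
                     spacing = c(2, 2, 2)))
  })
}

#' Geometric recipe for one phantom tumour
#'
#' @param grid_shape 3 positive integers (each >= 8), voxels per axis.
#' @param tumour_radius_range ellipsoid semi-axis range in mm.
#' @param emvi_protrusions list with `count`, `length` (mm) and `radius` (mm)
#'   of the tubular extensions added for EMVI-positive cases.
#' @param distractor_vessels list with `count`, `length` and `radius` (mm) of
#'   vessel-like tubes rendered at tumour intensity in EVERY case, detached
#'   from the tumour and excluded from the mask. They remove the "a bright
#'   tube exists" shortcut: the EMVI-like label is carried by tumour-attached
#'   tubes only, i.e. by fine boundary structure.
#' @param cr_texture heterogeneity amplitude in \[0, 1\] applied to
#'   non-responder (CR = 0) tumours; responders are more homogeneous and
#'   smaller (`cr_size_factor`).
#' @param cr_size_factor semi-axis shrink factor for CR = 1 tumours.
#' @param contrasts per-channel intensity levels (background/tumour, plus the
#'   protrusion level shared by invaded and distractor vessels).
#' @return a `phantom_spec` object.
#' @export
phantom_spec <- function(grid_shape = c(32, 32, 32),
                         tumour_radius_range = c(8, 14),
                         emvi_protrusions = list(count = 3, length = 11, radius = 3.2),
                         distractor_vessels = list(count = 0, length = 11, radius = 3.2),
                         cr_texture = 0.6,
                         cr_size_factor = 0.78,
                         contrasts = list(
                           dwi = c(background = 0.15, tumour = 1.0, protrusion = 1.0),
                           t2w = c(background = 0.80, tumour = 0.35, protrusion = 0.35))) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 8),
            length(tumour_radius_range) == 2L, all(tumour_radius_range > 0),
            diff(tumour_radius_range) >= 0,
            emvi_protrusions$count >= 0, emvi_protrusions$radius > 0,
            distractor_vessels$count >= 0, distractor_vessels$radius > 0,
            cr_texture >= 0, cr_texture <= 1)
  structure(list(grid_shape = as.integer(grid_shape),
                 tumour_radius_range = tumour_radius_range,
                 emvi_protrusions = emvi_protrusions,
                 distractor_vessels = distractor_vessels,
                 cr_texture = cr_texture, cr_size_factor = cr_size_factor,
                 contrasts = contrasts),
            class = "phantom_spec")
}

# Smooth low-frequency random field on a grid, scaled to max |f| = 1.
# Consumes the ambient RNG stream.
rand_smooth_field <- function(dims, n_modes = 3L) {
  ax <- lapply(dims, function(n) seq_len(n) / n)
  f <- array(0, dims)
  X <- array(rep(ax[[1]], times = dims[2] * dims[3]), dims)
  Y <- array(rep(rep(ax[[2]], each = dims[1]), times = dims[3]), dims)
  Z <- array(rep(ax[[3]], each = dims[1] * dims[2]), dims)
  for (k in seq_len(n_modes)) {
    fr <- runif(3, 0.5, 1.8)
    ph <- runif(3, 0, 2 * pi)
    a <- runif(1, 0.5, 1)
    f <- f + a * cos(2 * pi * (fr[1] * X + ph[1])) *
      cos(2 * pi * (fr[2] * Y + ph[2])) * cos(2 * pi * (fr[3] * Z + ph[3]))
  }
  f / max(abs(f))
}

# World coordinate arrays (mm) for a grid. 0-based indices: world = origin + index * spacing.
world_coords <- function(dims, spacing, origin = c(0, 0, 0)) {
  list(X = array(rep(origin[1] + (seq_len(dims[1]) - 1) * spacing[1],
                     times = dims[2] * dims[3]), dims),
       Y = array(rep(rep(origin[2] + (seq_len(dims[2]) - 1) * spacing[2],
                         each = dims[1]), times = dims[3]), dims),
       Z = array(rep(origin[3] + (seq_len(dims[3]) - 1) * spacing[3],
                     each = dims[1] * dims[2]), dims))
}

#' Generate one synthetic case
#'
#' Draws a tumour ellipsoid with smooth boundary perturbation, adds tubular
#' protrusions when `emvi = 1`, encodes `cr` in overall size and internal
#' texture, renders the DWI-like and T2W-like channels (the T2W-like channel
#' is synthesised at half the in-plane spacing and resampled onto the DWI
#' grid), applies the centre's acquisition shift, and samples clinical
#' covariates matched to a locally advanced rectal cancer cohort.
#'
#' @param spec a [phantom_spec].
#' @param profile a [centre_profile].
#' @param emvi,cr binary labels controlling the planted signals.
#' @param seed integer seed; identical arguments reproduce the case exactly.
#' @param patient_id optional id string.
#' @return a `case_record` list with fields `patient_id`, `centre_id`,
#'   `image`, `mask`, `emvi_label`, `cr_label`, `age`, `sex`, `cT`, `cN` and
#'   generator metadata in `geometry`.
#' @export
generate_case <- function(spec, profile, emvi, cr, seed,
                          patient_id = sprintf("P%09d", seed %% 1000000000L)) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(profile, "centre_profile"),
            emvi %in% c(0, 1), cr %in% c(0, 1))
  dims <- spec$grid_shape
  sp <- profile$spacing
  extent <- dims * sp
  rmax <- spec$tumour_radius_range[2] + (if (emvi == 1) spec$emvi_protrusions$length else 0)
  if (2 * rmax >= min(extent) * 0.9)
    stop(sprintf("grid too small: tumour (up to %.1f mm across) does not fit the %.0f mm extent",
                 2 * rmax, min(extent)))
  with_seed(seed, {
    eps <- 0.08  # relative amplitude of the smooth boundary perturbation
    centre <- extent / 2 + runif(3, -1, 1) * sp
    radii <- runif(3, spec$tumour_radius_range[1], spec$tumour_radius_range[2])
    if (cr == 1) radii <- radii * spec$cr_size_factor
    wc <- world_coords(dims, sp)
    perturb <- rand_smooth_field(dims)
    edist <- sqrt(((wc$X - centre[1]) / radii[1])^2 +
                  ((wc$Y - centre[2]) / radii[2])^2 +
                  ((wc$Z - centre[3]) / radii[3])^2)
    body <- edist <= 1 + eps * perturb
    # voxels within `radius` of the segment p0..p1
    cylinder <- function(p0, p1, radius) {
      seg <- p1 - p0
      L2 <- sum(seg^2)
      tproj <- ((wc$X - p0[1]) * seg[1] + (wc$Y - p0[2]) * seg[2] +
                (wc$Z - p0[3]) * seg[3]) / L2
      tclamp <- pmin(pmax(tproj, 0), 1)
      dist2 <- (wc$X - (p0[1] + tclamp * seg[1]))^2 +
               (wc$Y - (p0[2] + tclamp * seg[2]))^2 +
               (wc$Z - (p0[3] + tclamp * seg[3]))^2
      dist2 <= radius^2
    }
    prot <- array(FALSE, dims)
    if (emvi == 1 && spec$emvi_protrusions$count > 0) {
      for (i in seq_len(spec$emvi_protrusions$count)) {
        d <- rnorm(3); d <- d / sqrt(sum(d^2))
        # surface point of the unperturbed ellipsoid along direction d
        t_surf <- 1 / sqrt(sum((d / radii)^2))
        p0 <- centre + d * t_surf * 0.85   # start slightly inside the body
        p1 <- centre + d * (t_surf + spec$emvi_protrusions$length)
        prot <- prot | cylinder(p0, p1, spec$emvi_protrusions$radius)
      }
    }
    # normal mesorectal vessels: tumour-bright tubes in every case, detached
    # from the tumour and excluded from the mask
    vess <- array(FALSE, dims)
    dv <- spec$distractor_vessels
    if (dv$count > 0) {
      clearance <- max(radii) + dv$radius + 3
      for (i in seq_len(dv$count)) {
        for (try in 1:50) {
          p0 <- runif(3, 3, extent - 3)
          d <- rnorm(3); d <- d / sqrt(sum(d^2))
          p1 <- p0 + d * dv$length
          pts <- rbind(p0, (p0 + p1) / 2, p1)
          dmin <- min(sqrt(rowSums(sweep(pts, 2, centre)^2)))
          if (dmin > clearance && all(p1 > 1) && all(p1 < extent - 1)) break
        }
        if (dmin > clearance) vess <- vess | cylinder(p0, p1, dv$radius)
      }
    }
    mask_arr <- array(as.numeric(body | prot), dims)
    if (sum(mask_arr) == 0) stop("degenerate phantom: empty mask")

    # internal texture: heterogeneous for non-responders, homogeneous for CR
    tex_amp <- if (cr == 1) 0.1 * spec$cr_texture else spec$cr_texture
    texture <- 1 + tex_amp * rand_smooth_field(dims, n_modes = 4L)
    anatomy <- 0.05 * rand_smooth_field(dims)

    cd <- spec$contrasts$dwi
    dwi <- cd["background"] + anatomy
    dwi[vess] <- cd["protrusion"]        # vessels share the invaded-tube level
    dwi[body] <- (cd["tumour"] * texture)[body]
    dwi[prot & !body] <- cd["protrusion"]

    # T2W-like channel: synthesised at half in-plane spacing, then resampled
    # onto the DWI grid (mirrors T2W-to-DWI domain matching)
    sp_t2 <- c(sp[1] / 2, sp[2] / 2, sp[3])
    dims_t2 <- c(dims[1] * 2L - 1L, dims[2] * 2L - 1L, dims[3])
    wc2 <- world_coords(dims_t2, sp_t2)
    perturb2 <- resize_field(perturb, dims, dims_t2)
    edist2 <- sqrt(((wc2$X - centre[1]) / radii[1])^2 +
                   ((wc2$Y - centre[2]) / radii[2])^2 +
                   ((wc2$Z - centre[3]) / radii[3])^2)
    body2 <- edist2 <= 1 + eps * perturb2
    ct <- spec$contrasts$t2w
    t2 <- array(ct["background"], dims_t2) + 0.05 * resize_field(anatomy / 0.05, dims, dims_t2)
    t2[body2] <- ct["tumour"]
    t2_img <- volume_image(t2, sp_t2, channel_names = "T2W")
    t2_on_dwi <- resample_to_grid(t2_img, sp)
    stopifnot(identical(dim(t2_on_dwi$data)[1:3], as.integer(dims)))

    img <- volume_image(array(c(dwi, t2_on_dwi$data), c(dims, 2L)), sp,
                        channel_names = c("DWI", "T2W"))
    img <- apply_centre_shift(img, profile, seed = sample.int(.Machine$integer.max, 1))

    age <- round(min(max(rnorm(1, 65, 11), 25), 87))
    sex <- if (runif(1) < 0.35) "F" else "M"
    cT <- sample(c("1-2", "3", "4"), 1, prob = c(0.07, 0.81, 0.12))
    cN <- sample(c("0", "1", "2"), 1, prob = c(0.13, 0.24, 0.63))

    structure(list(patient_id = patient_id, centre_id = profile$centre_id,
                   image = img, mask = binary_mask(mask_arr, sp),
                   emvi_label = as.integer(emvi), cr_label = as.integer(cr),
                   age = age, sex = sex, cT = cT, cN = cN,
                   geometry = list(centre = centre, radii = radii, eps = eps)),
              class = "case_record")
  })
}

# trilinear resize of a plain 3D field to new dims (endpoint-aligned)
resize_field <- function(f, dims_in, dims_out) {
  co <- lapply(1:3, function(a) {
    if (dims_out[a] == 1L) 0
    else (seq_len(dims_out[a]) - 1) * (dims_in[a] - 1) / (dims_out[a] - 1)
  })
  out <- resize3d_fw_cpp(as.numeric(f), as.integer(dims_in), 1L,
                         co[[1]], co[[2]], co[[3]])
  array(out, dims_out)
}

#' Generate a multi-centre cohort
#'
#' Cases are spread over the centres (every centre is used when `n` allows),
#' labels are Bernoulli draws at the requested prevalences, and each case is
#' generated from its own sub-seed so the cohort is reproducible as a whole.
#'
#' @param n number of cases.
#' @param centres list of [centre_profile] objects.
#' @param p_emvi,p_cr prevalence of the EMVI-like and CR-like labels.
#' @param seed integer seed.
#' @param spec a [phantom_spec] shared by all cases.
#' @return list of `case_record` objects.
#' @export
generate_cohort <- function(n, centres, p_emvi = 0.60, p_cr = 0.28, seed = 1L,
                            spec = phantom_spec()) {
  stopifnot(n >= 1, length(centres) >= 1)
  with_seed(seed, {
    centre_idx <- sample(rep_len(seq_along(centres), n))
    emvi <- rbinom(n, 1, p_emvi)
    cr <- rbinom(n, 1, p_cr)
    case_seeds <- sample.int(.Machine$integer.max - 1L, n)
    lapply(seq_len(n), function(i)
      generate_case(spec, centres[[centre_idx[i]]], emvi[i], cr[i],
                    seed = case_seeds[i], patient_id = sprintf("P%04d", i)))
  })
}

#' Apply a centre's acquisition shift to a volume
#'
#' `output = gain * (volume + bias field) + Gaussian noise`, with a smooth
#' low-frequency bias field scaled by the profile's amplitude. The grid is
#' unchanged; an identity profile (gain 1, amplitude 0, sigma 0) returns the
#' volume unchanged.
#'
#' @param volume a [volume_image].
#' @param profile a [centre_profile].
#' @param seed integer seed for the bias field and noise.
#' @return a [volume_image] on the same grid.
#' @export
apply_centre_shift <- function(volume, profile, seed = 1L) {
  stopifnot(inherits(volume, "volume_image"), inherits(profile, "centre_profile"))
  dims <- dim(volume$data)[1:3]
  nc <- dim(volume$data)[4]
  with_seed(seed, {
    out <- volume$data
    for (c in seq_len(nc)) {
      v <- out[, , , c]
      if (profile$bias_amplitude > 0)
        v <- v + profile$bias_amplitude * rand_smooth_field(dims)
      v <- profile$gain * v
      if (profile$noise_sigma > 0)
        v <- v + array(rnorm(prod(dims), 0, profile$noise_sigma), dims)
      out[, , , c] <- v
    }
    volume_image(out, volume$spacing, volume$channel_names, volume$origin)
  })
}

#' Resample a volume onto a target spacing by trilinear interpolation
#'
#' The output grid starts at the same origin and covers the input extent
#' without extrapolation: `n_out = floor((n_in - 1) * s_in / s_out) + 1`.
#' Constant fields are preserved exactly; with the source spacing as target
#' the volume is returned voxel-identical.
#'
#' @param volume a [volume_image].
#' @param target_spacing mm per axis (3 positive reals).
#' @return a [volume_image] at the target spacing.
#' @export
resample_to_grid <- function(volume, target_spacing) {
  stopifnot(inherits(volume, "volume_image"))
  if (length(target_spacing) != 3L || any(target_spacing <= 0))
    stop("target spacing must be 3 positive reals")
  dims <- dim(volume$data)[1:3]
  nc <- dim(volume$data)[4]
  n_out <- pmax(1L, as.integer(floor((dims - 1) * volume$spacing / target_spacing + 1e-9)) + 1L)
  co <- lapply(1:3, function(a) (seq_len(n_out[a]) - 1) * target_spacing[a] / volume$spacing[a])
  out <- resize3d_fw_cpp(as.numeric(volume$data), as.integer(dims), nc,
                         co[[1]], co[[2]], co[[3]])
  volume_image(array(out, c(n_out, nc)), target_spacing,
               volume$channel_names, volume$origin)
}

#' Resample a binary mask by nearest neighbour
#' @param mask a [binary_mask].
#' @param target_spacing mm per axis.
#' @return a [binary_mask] at the target spacing.
#' @export
resample_mask <- function(mask, target_spacing) {
  stopifnot(inherits(mask, "binary_mask"))
  dims <- dim(mask$data)
  n_out <- pmax(1L, as.integer(floor((dims - 1) * mask$spacing / target_spacing + 1e-9)) + 1L)
  co <- lapply(1:3, function(a)
    round((seq_len(n_out[a]) - 1) * target_spacing[a] / mask$spacing[a]))
  out <- resize3d_fw_cpp(as.numeric(mask$data), as.integer(dims), 1L,
                         co[[1]], co[[2]], co[[3]])
  binary_mask(array(round(out), n_out), target_spacing)
}

#' Count mask voxels outside the tumour body envelope
#'
#' The trivial geometric oracle for the EMVI-like signal: voxels of the mask
#' whose ellipsoid distance exceeds the maximum perturbed body radius can
#' only belong to protrusions. EMVI-negative cases always score 0.
#'
#' @param case a `case_record` from [generate_case].
#' @return integer voxel count.
#' @export
protrusion_voxels <- function(case) {
  g <- case$geometry
  dims <- dim(case$mask$data)
  wc <- world_coords(dims, case$mask$spacing)
  edist <- sqrt(((wc$X - g$centre[1]) / g$radii[1])^2 +
                ((wc$Y - g$centre[2]) / g$radii[2])^2 +
                ((wc$Z - g$centre[3]) / g$radii[3])^2)
  sum(case$mask$data == 1 & edist > 1 + g$eps)
}

case_field <- function(cases, field) vapply(cases, function(x) x[[field]], vector(mode = "numeric", 1L))

cohort_df <- function(cases) {
  data.frame(patient_id = vapply(cases, function(x) x$patient_id, ""),
             centre_id = vapply(cases, function(x) x$centre_id, ""),
             emvi = vapply(cases, function(x) x$emvi_label, 1L),
             cr = vapply(cases, function(x) x$cr_label, 1L),
             age = vapply(cases, function(x) x$age, 1),
             sex = vapply(cases, function(x) x$sex, ""),
             cT = vapply(cases, function(x) x$cT, ""),
             cN = vapply(cases, function(x) x$cN, ""),
             stringsAsFactors = FALSE)
}

#' Cohort characteristics summary table
#'
#' Per-group counts with integer percentages for sex, cT, cN, response and
#' EMVI status, the age median and range, and group totals — the standard
#' demographics table of a multi-centre study. When `compare` names two of
#' the cohorts, a Kruskal-Wallis p-value between them is appended per
#' characteristic.
#'
#' @param cohorts named list of case lists (e.g. `list(All = ..., Development
#'   = ..., External = ...)`).
#' @param compare length-2 character vector naming the cohorts to compare, or
#'   `NULL` to skip the tests.
#' @return data frame with one row per characteristic level and one column
#'   per cohort (`"count (pct%)"` strings), plus `p_value` per characteristic.
#' @export
summarize_cohort <- function(cohorts, compare = NULL) {
  if (!is.list(cohorts) || is.null(names(cohorts))) cohorts <- list(All = cohorts)
  if (any(vapply(cohorts, length, 1L) == 0L)) stop("empty cohort")
  dfs <- lapply(cohorts, cohort_df)
  levels_of <- list(
    sex = c(Female = "F", Male = "M"),
    cT = c(`cT1-2` = "1-2", cT3 = "3", cT4 = "4"),
    cN = c(cN0 = "0", cN1 = "1", cN2 = "2"),
    response = c(`non-CR` = "0", CR = "1"),
    emvi = c(`EMVI+` = "1", `EMVI-` = "0"))
  col_for <- list(sex = "sex", cT = "cT", cN = "cN", response = "cr", emvi = "emvi")
  rows <- list()
  add_row <- function(characteristic, level, vals, p = NA_real_)
    rows[[length(rows) + 1L]] <<- c(list(characteristic = characteristic, level = level),
                                    vals, list(p_value = p))
  num_code <- function(df, col) {
    v <- df[[col]]
    if (col == "age") return(as.numeric(v))
    if (col == "sex") return(as.numeric(v == "M"))
    if (col == "cT") return(match(v, c("1-2", "3", "4")))
    if (col == "cN") return(match(v, c("0", "1", "2")))
    as.numeric(v)
  }
  pval <- function(col) {
    if (is.null(compare)) return(NA_real_)
    stopifnot(all(compare %in% names(dfs)))
    kruskal_wallis(list(num_code(dfs[[compare[1]]], col),
                        num_code(dfs[[compare[2]]], col)))$p_value
  }
  age_vals <- lapply(dfs, function(d)
    sprintf("%d (%d-%d)", round(median(d$age)), min(d$age), max(d$age)))
  add_row("age", "median (range)", age_vals, pval("age"))
  for (ch in names(levels_of)) {
    col <- col_for[[ch]]
    lv <- levels_of[[ch]]
    p <- pval(col)
    for (i in seq_along(lv)) {
      vals <- lapply(dfs, function(d) {
        v <- as.character(d[[col]])
        k <- sum(v == lv[i])
        sprintf("%d (%d%%)", k, round(100 * k / nrow(d)))
      })
      add_row(ch, names(lv)[i], vals, if (i == 1) p else NA_real_)
    }
  }
  add_row("total", "n", lapply(dfs, function(d) as.character(nrow(d))))
  out <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  names(out) <- c("characteristic", "level", names(dfs), "p_value")
  rownames(out) <- NULL
  out
}
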