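#' Synthetic lower-leg cast mesh
#'
#' Watertight, outward-oriented stand-in for a scanned plaster cast: a
#' capsule swept along a planar bent centreline (vertical shank, smooth
#' ankle bend, horizontal foot), built by smoothly deforming a subdivided
#' icosphere so the sphere's closed topology — and therefore watertightness —
#' is preserved by construction. The shape is deliberately schematic: the
#' pipeline only assumes cast-like topology and scale, not anatomy.
#'
#' Frame conventions (used by [cast_anchor()] and the plantar flattening):
#' the shank axis is +z, the foot extends towards +x, the sole rests near
#' z = 0, and y is the medial-lateral axis.
#'
#' @param leg_length shank length, mm.
#' @param calf_radii radius profile down the shank (proximal to distal), mm;
#'   length >= 1.
#' @param foot_length foot length beyond the ankle bend, mm.
#' @param foot_radius foot tube radius, mm.
#' @param ankle_angle angle between shank and foot axes, degrees
#'   (90 = plantigrade).
#' @param resolution target edge length, mm; must be below a quarter of the
#'   smallest radius so tube cross-sections stay well resolved.
#' @param seed recorded with the mesh (construction itself is deterministic).
#' @param name mesh identifier.
#' @return a watertight `cast_mesh` with attribute `"cast_params"`.
#' @export
make_cast <- function(leg_length = 250, calf_radii = c(42, 30),
                      foot_length = 170, foot_radius = 26,
                      ankle_angle = 90, resolution = 6, seed = 1L,
                      name = "synthetic_cast") {
  if (any(c(leg_length, calf_radii, foot_length, foot_radius) <= 0)) {
    abort("all cast dimensions must be positive")
  }
  min_r <- min(c(calf_radii, foot_radius))
  if (resolution >= min_r / 4) {
    abort(sprintf("resolution %.2f mm too coarse: must be < smallest radius / 4 = %.2f mm",
                  resolution, min_r / 4))
  }
  a <- ankle_angle * pi / 180
  r_bend <- 2 * foot_radius
  bend_len <- r_bend * a
  L <- leg_length + bend_len + foot_length

  # centreline heading, smoothstepped through the ankle bend, integrated on a
  # fine grid; the curve lives in the xz-plane so the frame is closed form
  ns <- 2000L
  s_grid <- seq(0, L, length.out = ns + 1L)
  u <- pmin(pmax((s_grid - leg_length) / bend_len, 0), 1)
  phi <- a * (3 * u^2 - 2 * u^3)
  dirs <- cbind(sin(phi), 0, -cos(phi))
  ds <- L / ns
  cx <- c(0, cumsum(dirs[-1, 1] * ds))
  cz <- c(0, cumsum(dirs[-1, 3] * ds))

  # radius profile: calf_radii spread along the upper shank, narrowing to the
  # foot radius at the ankle so the heel does not bulge below the sole plane
  rk_s <- c(seq(0, 0.85 * leg_length, length.out = max(length(calf_radii), 2L)),
            leg_length, L)
  rk_r <- c(if (length(calf_radii) == 1L) rep(calf_radii, 2) else calf_radii,
            foot_radius, foot_radius)

  # pick the subdivision level from the coarser of the longitudinal and
  # circumferential length scales
  char <- max(L / pi, max(rk_r))
  subdiv <- max(2L, ceiling(log2(char * 1.107 / resolution)))
  sph <- icosphere(subdiv)
  v <- sph$vertices

  t <- acos(pmin(pmax(v[, 3], -1), 1)) / pi  # 0 at shank top, 1 at toes
  s <- t * L
  rho <- sqrt(v[, 1]^2 + v[, 2]^2)
  ux <- ifelse(rho > 0, v[, 1] / rho, 0)
  uy <- ifelse(rho > 0, v[, 2] / rho, 0)

  # rounded end caps: quarter-circle taper over one end-radius of arclength
  r_of_s <- stats::approx(rk_s, rk_r, xout = s, rule = 2)$y
  cap0 <- rk_r[1] / L
  cap1 <- foot_radius / L
  g <- rep(1, length(t))
  i0 <- t < cap0
  g[i0] <- sqrt(pmax(1 - ((cap0 - t[i0]) / cap0)^2, 0))
  i1 <- t > 1 - cap1
  g[i1] <- sqrt(pmax(1 - ((t[i1] - (1 - cap1)) / cap1)^2, 0))

  phi_v <- stats::approx(s_grid, phi, xout = s, rule = 2)$y
  cx_v <- stats::approx(s_grid, cx, xout = s, rule = 2)$y
  cz_v <- stats::approx(s_grid, cz, xout = s, rule = 2)$y
  nx <- cos(phi_v)
  nz <- sin(phi_v)
  off <- r_of_s * g
  verts <- cbind(cx_v + off * ux * nx,
                 off * uy,
                 cz_v + off * ux * nz)
  # stand the cast on the ground plane: the centreline runs downward from the
  # shank top, so lifting by the overall minimum puts the sole near z = 0
  verts[, 3] <- verts[, 3] - min(verts[, 3])

  mesh <- triangle_mesh(verts, sph$faces, name = name)
  if (!is_watertight(mesh)) {
    abort("resolution too coarse: generated cast is not watertight")
  }
  attr(mesh, "cast_params") <- list(leg_length = leg_length,
                                    calf_radii = calf_radii,
                                    foot_length = foot_length,
                                    foot_radius = foot_radius,
                                    ankle_angle = ankle_angle,
                                    resolution = resolution, seed = seed)
  mesh
}

#' Named anchor points on a synthetic cast
#'
#' Resolves the cast regions the orthotist typically modifies to concrete
#' surface points, using the [make_cast()] frame conventions (foot towards
#' +x, shank up +z, sole at z = 0).
#'
#' @param mesh a cast from [make_cast()].
#' @param which one of `"toes"`, `"heel"`, `"ankle_medial"`,
#'   `"ankle_lateral"`, `"dorsal"`, `"calf"`, `"anterior_border"`.
#' @return a length-3 point on the surface.
#' @export
cast_anchor <- function(mesh, which = c("toes", "heel", "ankle_medial",
                                        "ankle_lateral", "dorsal", "calf",
                                        "anterior_border")) {
  which <- match.arg(which)
  v <- mesh$vertices
  zmax <- max(v[, 3])
  low <- v[, 3] < 0.35 * zmax
  idx <- switch(which,
    toes = which.max(v[, 1]),
    heel = {
      cand <- which(low)
      cand[which.min(v[cand, 1])]
    },
    ankle_medial = {
      cand <- which(v[, 3] > 0.15 * zmax & v[, 3] < 0.4 * zmax & v[, 1] < 0.3 * max(v[, 1]))
      cand[which.max(v[cand, 2])]
    },
    ankle_lateral = {
      cand <- which(v[, 3] > 0.15 * zmax & v[, 3] < 0.4 * zmax & v[, 1] < 0.3 * max(v[, 1]))
      cand[which.min(v[cand, 2])]
    },
    dorsal = {
      cand <- which(v[, 1] > 0.45 * max(v[, 1]))
      cand[which.max(v[cand, 3])]
    },
    calf = {
      cand <- which(v[, 3] > 0.6 * zmax & v[, 3] < 0.85 * zmax)
      cand[which.min(v[cand, 1])]
    },
    anterior_border = {
      cand <- which(v[, 1] > 0.55 * max(v[, 1]))
      cand[which.max(v[cand, 2] + 0.5 * v[cand, 3])]
    }
  )
  v[idx, ]
}

#' Plant modifications with exact ground truth
#'
#' Emulates the orthotist's rectification on a synthetic cast: localized
#' additions/subtractions as cosine-falloff patches displacing vertices
#' along their angle-weighted pseudonormals, plus an optional plantar
#' flattening that projects sole vertices onto a horizontal plane (recorded
#' as a negative displacement). The exact per-vertex displacement is
#' returned, making signed-distance recovery testable against ground truth.
#'
#' @param mesh a watertight `cast_mesh`.
#' @param patches list of patches, each a list with `center` (length-3 point
#'   or an anchor name for [cast_anchor()]), `radius` (mm) and `amplitude`
#'   (mm, positive = outward addition); displacement is
#'   `amplitude * 0.5 * (1 + cos(pi * d / radius))` inside the patch.
#' @param plantar_depth optional flattening depth, mm: downward-facing
#'   vertices below `min(z) + plantar_depth` are projected up onto that
#'   plane.
#' @param global_addition optional uniform outward displacement, mm, applied
#'   to every vertex before the plantar flattening — the thin universal
#'   smoothing layer an orthotist spreads over the whole cast.
#' @return list with `mesh` (modified), `ground_truth` (signed mm per
#'   vertex, positive = outward) and `patches` (resolved patch table).
#' @export
plant_modifications <- function(mesh, patches = list(), plantar_depth = NULL,
                                global_addition = 0) {
  stopifnot(inherits(mesh, "cast_mesh"))
  v <- mesh$vertices
  vn <- vertex_pseudonormals(mesh)
  truth <- numeric(nrow(v))
  resolved <- list()

  if (abs(global_addition) > 10) {
    abort("`global_addition` outside the +/-10 mm envelope")
  }
  disp <- rep(global_addition, nrow(v))
  for (i in seq_along(patches)) {
    p <- patches[[i]]
    if (is.character(p$center)) p$center <- cast_anchor(mesh, p$center)
    if (is.null(p$radius) || p$radius <= 0) {
      abort(sprintf("patch %d: radius must be positive", i))
    }
    if (abs(p$amplitude) > 10) {
      abort(sprintf("patch %d: amplitude %.1f mm outside the +/-10 mm envelope",
                    i, p$amplitude))
    }
    if (abs(p$amplitude) >= p$radius) {
      abort(sprintf(
        "patch %d would self-intersect: |amplitude| %.1f mm must stay below radius %.1f mm",
        i, abs(p$amplitude), p$radius))
    }
    d <- sqrt(colSums((t(v) - p$center)^2))
    w <- ifelse(d < p$radius, p$amplitude * 0.5 * (1 + cos(pi * d / p$radius)), 0)
    disp <- disp + w
    resolved[[i]] <- tibble::tibble(patch = i, cx = p$center[1], cy = p$center[2],
                                    cz = p$center[3], radius = p$radius,
                                    amplitude = p$amplitude)
  }
  v2 <- v + disp * vn
  truth <- truth + disp

  if (!is.null(plantar_depth)) {
    if (plantar_depth <= 0) abort("`plantar_depth` must be positive")
    plane_z <- min(v2[, 3]) + plantar_depth
    sole <- v2[, 3] < plane_z & vn[, 3] < -0.3
    dz <- plane_z - v2[sole, 3]
    v2[sole, 3] <- plane_z
    truth[sole] <- truth[sole] - dz
  }

  out <- mesh
  out$vertices <- v2
  out$name <- paste0(mesh$name, "_modified")
  areas <- face_areas(out$vertices, out$faces)
  if (any(areas <= 1e-9)) {
    abort("planted modifications collapsed faces; reduce amplitudes or flattening depth")
  }
  list(mesh = out, ground_truth = truth,
       patches = if (length(resolved)) dplyr::bind_rows(resolved) else NULL)
}

#' Perturb a mesh pose and add scan noise
#'
#' Applies a rigid displacement followed by isotropic Gaussian vertex jitter,
#' emulating a re-scan in a different pose. The true transform is returned
#' so registration can be scored against it.
#'
#' @param mesh a `cast_mesh`.
#' @param rotation_deg rotation magnitude, degrees.
#' @param axis rotation axis (default z).
#' @param translation length-3 translation, mm.
#' @param noise_sigma isotropic per-vertex jitter SD, mm.
#' @param seed RNG seed.
#' @return list with `mesh`, `transform` (the applied `rigid_transform`) and
#'   `noise_sigma`.
#' @export
perturb_mesh <- function(mesh, rotation_deg = 0, axis = c(0, 0, 1),
                         translation = c(0, 0, 0), noise_sigma = 0,
                         seed = 1L) {
  t <- rigid_transform(rotation_about(axis, rotation_deg), translation)
  out <- apply_transform(mesh, t)
  if (noise_sigma > 0) {
    out$vertices <- out$vertices + withr::with_seed(seed,
      matrix(rnorm(length(out$vertices), sd = noise_sigma),
             ncol = 3))
  }
  list(mesh = out, transform = t, noise_sigma = noise_sigma)
}

# the standard rectification layout used by the cohort simulator: a thin
# universal smoothing layer plus localized additions around the toes,
# anterior borders, ankle and heel (scaled by one amplitude); the plantar
# flattening depth is drawn separately
standard_patches <- function(amplitude) {
  list(
    list(center = "toes", radius = 45, amplitude = amplitude),
    list(center = "anterior_border", radius = 35, amplitude = 0.8 * amplitude),
    list(center = "heel", radius = 40, amplitude = 0.7 * amplitude),
    list(center = "ankle_medial", radius = 30, amplitude = 0.6 * amplitude),
    list(center = "calf", radius = 35, amplitude = 0.4 * amplitude)
  )
}

# paediatric stature model: quadratic growth curve in cm with Gaussian
# residual, ages in years
height_from_age <- function(age, sd_resid = 6, seed = NULL) {
  mu <- 68 + 8.4 * age - 0.15 * age^2
  noise <- if (is.null(seed)) rnorm(length(age), sd = sd_resid) else
    withr::with_seed(seed, rnorm(length(age), sd = sd_resid))
  pmin(pmax(mu + noise, 45), 210)
}

#' Calibrate the height effect on planted additions
#'
#' Finds the slope `b` (mm of addition amplitude per cm of stature) for
#' which the population Spearman correlation between height and the planted
#' addition amplitude `a + b * height + eps` reaches a target value, by
#' root-finding on a large simulated population (deterministic for a seed).
#'
#' @param target_rs target Spearman correlation.
#' @param sigma residual SD of the amplitude, mm.
#' @param n_pop population size used to evaluate the correlation.
#' @param seed RNG seed.
#' @return slope `b`, mm per cm.
#' @export
calibrate_height_slope <- function(target_rs = 0.35, sigma = 0.5,
                                   n_pop = 20000L, seed = 20L) {
  sim <- withr::with_seed(seed, {
    age <- runif(n_pop, 1, 18)
    h <- height_from_age(age)
    eps <- rnorm(n_pop, sd = sigma)
    list(h = h, eps = eps)
  })
  f <- function(b) {
    cor(rank(sim$h), rank(b * sim$h + sim$eps)) - target_rs
  }
  stats::uniroot(f, c(1e-5, 1), tol = 1e-6)$root
}

#' Simulate a study cohort with a planted height effect
#'
#' Generates `n` participants: ages uniform on 1-18 years, heights from a
#' paediatric growth curve (masked at `missing_height_fraction`, as happens
#' with incomplete clinical records), AFO type and pathology drawn from
#' realistic clinic proportions (fixed 30 : hinged 16 : PLS 2 : SMO 1 :
#' unknown 1; CP 25 : CTEV 6 : SB 5 : NF1 2 : Other 12 per 50), an addition
#' amplitude `a + b * height + eps` truncated below at 0.3 mm, and a plantar
#' flattening depth uniform on 0.8-3.5 mm.
#'
#' With `mesh_detail = "summary"` each participant's MMD summary is computed
#' directly from the planted ground-truth displacement field on a shared
#' template cast (fast; exact up to the planted field). With
#' `mesh_detail = "full"` a pre/post mesh pair is generated per participant
#' (cast scaled with stature, modifications planted, post cast rigidly
#' displaced), for end-to-end runs through registration and mapping; pairs
#' are written under `outdir` when given.
#'
#' @param n cohort size (>= 5).
#' @param seed RNG seed; every random draw derives from it.
#' @param effect list `a` (intercept, mm), `b` (slope, mm/cm), `sigma`
#'   (residual SD, mm). The default slope is calibrated so the population
#'   height-addition Spearman correlation is 0.35.
#' @param missing_height_fraction fraction of heights masked to `NA`.
#' @param mesh_detail `"summary"` or `"full"`.
#' @param resolution template-cast resolution, mm.
#' @param outdir optional directory for mesh pairs, landmarks, cohort CSV
#'   and ground-truth JSON (`mesh_detail = "full"`).
#' @param pose_sigma full mode: SD of the random pose displacement
#'   (degrees and mm).
#' @return list with `cohort` (tibble: participant covariates, planted truth
#'   and the per-participant `pmmd`/`nmmd`/`mmmd` summaries in summary mode),
#'   `truth` (effect parameters and per-participant amplitudes), and in full
#'   mode `pairs` (list of pre/post meshes with true transforms) plus
#'   `manifest` when files were written.
#' @export
simulate_cohort <- function(n = 50L, seed = 1L,
                            effect = list(a = 2.4, b = 0.0068, sigma = 0.5),
                            missing_height_fraction = 0.16,
                            mesh_detail = c("summary", "full"),
                            resolution = 6, outdir = NULL,
                            pose_sigma = 3) {
  mesh_detail <- match.arg(mesh_detail)
  if (n < 5) abort("need n >= 5")
  if (missing_height_fraction < 0 || missing_height_fraction >= 1) {
    abort("`missing_height_fraction` must be in [0, 1)")
  }
  draws <- withr::with_seed(seed, {
    age <- runif(n, 1, 18)
    height <- height_from_age(age)
    amp <- pmax(effect$a + effect$b * height + rnorm(n, sd = effect$sigma), 0.3)
    depth <- runif(n, 0.8, 3.5)
    afo <- sample(c("fixed", "hinged", "PLS", "SMO", "unknown"), n,
                  replace = TRUE, prob = c(30, 16, 2, 1, 1) / 50)
    pathology <- sample(c("CP", "CTEV", "SB", "NF1", "Other"), n,
                        replace = TRUE, prob = c(25, 6, 5, 2, 12) / 50)
    miss <- sample.int(n, floor(missing_height_fraction * n))
    pose <- matrix(rnorm(4 * n, sd = pose_sigma), ncol = 4)
    list(age = age, height = height, amp = amp, depth = depth, afo = afo,
         pathology = pathology, miss = miss, pose = pose)
  })

  cohort <- tibble::tibble(
    participant_id = sprintf("P%03d", seq_len(n)),
    age = draws$age,
    height = replace(draws$height, draws$miss, NA_real_),
    afo_type = draws$afo,
    pathology = draws$pathology,
    true_amplitude = draws$amp,
    true_plantar_depth = draws$depth
  )
  truth <- list(effect = effect, seed = seed,
                height_unmasked = draws$height,
                amplitude = draws$amp, plantar_depth = draws$depth)

  if (mesh_detail == "summary") {
    tpl <- template_fields(resolution)
    summ <- purrr::map2(draws$amp, draws$depth, function(A, D) {
      vals <- A * tpl$unit
      sole <- tpl$z < (tpl$z0 + D) & tpl$sole_normals
      vals[sole] <- -(tpl$z0 + D - tpl$z[sole])
      summarize_values(vals)
    })
    cohort <- dplyr::bind_cols(cohort, dplyr::bind_rows(summ))
    return(list(cohort = cohort, truth = truth))
  }

  # full mode: per-participant mesh pairs
  pairs <- vector("list", n)
  manifest <- NULL
  if (!is.null(outdir)) dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(n)) {
    # template is roughly a 124 cm child; floor keeps tube radii resolvable
    scale <- max(draws$height[i] / 124, 0.55)
    pre <- make_cast(leg_length = 250 * scale,
                     calf_radii = c(42, 30) * scale,
                     foot_length = 170 * scale, foot_radius = 26 * scale,
                     resolution = resolution * scale,
                     name = sprintf("P%03d_pre", i))
    planted <- plant_modifications(pre, standard_patches(draws$amp[i]),
                                   plantar_depth = draws$depth[i],
                                   global_addition = 0.55 * draws$amp[i])
    moved <- perturb_mesh(planted$mesh,
                          rotation_deg = draws$pose[i, 1],
                          axis = c(0.3, 0.5, 1),
                          translation = draws$pose[i, 2:4],
                          seed = seed + i)
    # landmarks: well-separated shank points; the orthotist's pen marks are
    # taken as unaffected by the rectification, so the pair is exact up to
    # the rigid pose
    zr <- range(pre$vertices[, 3])
    cand <- which(pre$vertices[, 3] > zr[1] + 0.7 * diff(zr))
    lm_idx <- cand[round(seq(1, length(cand), length.out = 6))]
    lm_pre <- landmark_set(pre$vertices[lm_idx, ], sprintf("L%d", 1:6))
    lm_post <- landmark_set(
      transform_points(pre$vertices[lm_idx, ], moved$transform),
      sprintf("L%d", 1:6))
    pairs[[i]] <- list(id = cohort$participant_id[i], pre = pre,
                       post = moved$mesh, true_transform = moved$transform,
                       ground_truth = planted$ground_truth,
                       landmarks_pre = lm_pre, landmarks_post = lm_post)
  }
  if (!is.null(outdir)) {
    rows <- purrr::map(pairs, function(p) {
      pre_path <- file.path(outdir, paste0(p$id, "_pre.ply"))
      post_path <- file.path(outdir, paste0(p$id, "_post.ply"))
      lm_pre_path <- file.path(outdir, paste0(p$id, "_landmarks_pre.csv"))
      lm_post_path <- file.path(outdir, paste0(p$id, "_landmarks_post.csv"))
      write_mesh(p$pre, pre_path)
      write_mesh(p$post, post_path)
      write.csv(as.data.frame(p$landmarks_pre), lm_pre_path, row.names = FALSE)
      write.csv(as.data.frame(p$landmarks_post), lm_post_path, row.names = FALSE)
      tibble::tibble(participant_id = p$id, pre = pre_path, post = post_path,
                     landmarks_pre = lm_pre_path, landmarks_post = lm_post_path)
    })
    manifest <- dplyr::bind_rows(rows)
    write.csv(cohort, file.path(outdir, "cohort.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(seed = seed, effect = effect, amplitude = draws$amp,
           plantar_depth = draws$depth,
           pose = as.data.frame(draws$pose)),
      file.path(outdir, "ground_truth.json"), digits = NA, auto_unbox = TRUE)
    write.csv(manifest, file.path(outdir, "manifest.csv"), row.names = FALSE)
  }
  list(cohort = cohort, truth = truth, pairs = pairs, manifest = manifest)
}

# deterministic per-resolution cache of the template cast and its unit
# modification field; rebuilding these dominates summary-mode cohort cost
.template_cache <- new.env(parent = emptyenv())

template_fields <- function(resolution) {
  key <- format(resolution, digits = 12)
  if (is.null(.template_cache[[key]])) {
    template <- make_cast(resolution = resolution, name = "template")
    unit <- plant_modifications(template, standard_patches(1),
                                global_addition = 0.55)$ground_truth
    z <- template$vertices[, 3]
    vn <- vertex_pseudonormals(template)
    .template_cache[[key]] <- list(template = template, unit = unit, z = z,
                                   z0 = min(z), sole_normals = vn[, 3] < -0.3)
  }
  .template_cache[[key]]
}

# shared summary kernel: pMMD/nMMD/mMMD etc. over a signed value vector
summarize_values <- function(values) {
  v <- values[!is.na(values)]
  pos <- v[v > 0]
  neg <- v[v < 0]
  tibble::tibble(
    pmmd = if (length(pos)) mean(pos) else NA_real_,
    nmmd = if (length(neg)) mean(-neg) else NA_real_,
    mmmd = mean(abs(v)),
    max_pmmd = if (length(pos)) max(pos) else NA_real_,
    max_nmmd = if (length(neg)) max(-neg) else NA_real_
  )
}
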