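#' Build a toy annotation volume and matching ontology
#'
#' Constructs a small brain-like label volume for testing and simulation:
#' a one-voxel outside-brain shell (label 0) surrounds an interior that is
#' partitioned into `n_leaf_regions` contiguous slabs along the third axis.
#' Every region crosses the declared midline plane on the first axis, so
#' each has left and right parts mirrored about the midline. The companion
#' ontology has root -> summary -> leaf levels with consecutive leaves
#' paired under one summary category.
#'
#' @param n_leaf_regions number of leaf regions (>= 2).
#' @param shape integer length-3 voxel extents.
#' @param voxel_size_um voxel edge length(s) in micrometres.
#' @param acronyms optional character vector of leaf acronyms (default
#'   `R1..Rn`).
#' @param summary_groups optional integer vector mapping each leaf to a
#'   summary-category index (default: consecutive leaves paired).
#' @return list with elements `volume` (an [annotation_volume()]) and
#'   `ontology` (a [region_ontology()]).
#' @export
build_toy_atlas <- function(n_leaf_regions, shape = c(20, 20, 20),
                            voxel_size_um = 25, acronyms = NULL,
                            summary_groups = NULL) {
  n <- as.integer(n_leaf_regions)
  shape <- as.integer(shape)
  if (n < 2L) stop("need at least 2 leaf regions")
  if (length(shape) != 3L || any(shape < 3L))
    stop("shape too small: need at least 3 voxels per axis")
  interior <- shape - 2L
  if (interior[3] < n)
    stop("shape too small: third axis cannot hold ", n, " regions")
  # contiguous slab bounds along axis 3 (1-based interior indices)
  breaks <- floor(seq(0, interior[3], length.out = n + 1L))
  thick <- diff(breaks)
  vox_per_region <- interior[1] * interior[2] * thick
  if (any(vox_per_region < 8L))
    stop("shape too small: a region would get fewer than 8 voxels")
  labels <- array(0L, dim = shape)
  for (i in seq_len(n)) {
    z0 <- 1L + breaks[i] + 1L
    z1 <- 1L + breaks[i + 1L]
    labels[2:(shape[1] - 1L), 2:(shape[2] - 1L), z0:z1] <- i
  }
  vol <- annotation_volume(labels, voxel_size_um, midline = shape[1] / 2)

  leaf_sum <- if (is.null(summary_groups)) ceiling(seq_len(n) / 2) else
    as.integer(summary_groups)
  if (length(leaf_sum) != n)
    stop("summary_groups must have one entry per leaf region")
  leaf_acr <- if (is.null(acronyms)) paste0("R", seq_len(n)) else
    as.character(acronyms)
  if (length(leaf_acr) != n || anyDuplicated(leaf_acr))
    stop("acronyms must be ", n, " unique names")
  n_sum <- max(leaf_sum)
  root_id <- 999L
  sum_ids <- 100L + seq_len(n_sum)
  regions <- rbind(
    data.frame(id = root_id, acronym = "root", name = "toy brain",
               parent_id = NA_integer_, stringsAsFactors = FALSE),
    data.frame(id = sum_ids, acronym = paste0("S", seq_len(n_sum)),
               name = paste("toy summary", seq_len(n_sum)),
               parent_id = root_id, stringsAsFactors = FALSE),
    data.frame(id = seq_len(n), acronym = leaf_acr,
               name = paste("toy region", seq_len(n)),
               parent_id = sum_ids[leaf_sum], stringsAsFactors = FALSE))
  c69 <- stats::setNames(leaf_acr, as.character(seq_len(n)))
  c25 <- stats::setNames(paste0("S", leaf_sum), leaf_acr)
  list(volume = vol, ontology = region_ontology(regions, c69, c25))
}

#' Specify a synthetic retrograde-labeling cohort
#'
#' Collects the generative parameters for [simulate_cohort()]: per-region
#' mean nucleus counts with negative-binomial inter-animal dispersion,
#' region-specific dual-projection probabilities, a correlated lognormal
#' two-channel intensity model with multiplicative dimming of the cervical
#' channel in dual cells, severity-dependent per-region sparing fractions,
#' and a behavior score coupled to the realized sparing of designated
#' regions.
#'
#' @param regions data.frame with columns `id` (leaf region label),
#'   `mean_count` (mean lumbar-labeled nuclei, >= 0), `dual_probability`
#'   (in \[0,1\]) and optionally `cervical_mean_count` (mean cervical-only
#'   nuclei; defaults to `mean_count`).
#' @param dispersion negative-binomial size parameter (> 0; `Inf` gives
#'   Poisson counts).
#' @param intensity_model list with `meanlog` and `sdlog` (named numerics
#'   for channels `lumbar` and `cervical`), `correlation` (cross-channel
#'   log-intensity correlation in dual cells, in \[-1,1\]),
#'   `dual_cervical_dimming` (multiplicative factor in (0,1\] applied to
#'   the cervical intensity of dual cells) and `jitter_sd_um` (isotropic
#'   Gaussian positional jitter between the two channel copies of a dual
#'   nucleus).
#' @param severity_sparing named list mapping severity label to a sparing
#'   fraction in \[0,1\]: either a scalar or a numeric named by region id.
#'   Severity `"none"` means no thinning.
#' @param behavior_link list with `region_ids`, `weights` and `noise_sd`:
#'   the behavior score is `9 *` the weighted mean realized sparing of
#'   these regions plus Gaussian noise, clipped to \[0, 9\].
#' @param arms data.frame with columns `condition`, `severity`,
#'   `n_animals`. Condition `"coinjected"` emulates a dual lumbar
#'   co-injection control: dual probability
#'   `coinjected_dual_probability` in every region, no dimming, no
#'   cervical-only nuclei.
#' @param coinjected_dual_probability co-detection probability in the
#'   co-injection control arm.
#' @param quantize_bms if `TRUE`, behavior scores are rounded to the 0.5
#'   steps of the real locomotor scale.
#' @param seed integer seed; a fixed seed makes [simulate_cohort()]
#'   byte-reproducible.
#' @return list of class `cohort_design`.
#' @export
cohort_design <- function(regions, dispersion = 40,
                          intensity_model = list(),
                          severity_sparing = list(),
                          behavior_link = NULL,
                          arms = data.frame(condition = "uninjured",
                                            severity = "none", n_animals = 4),
                          coinjected_dual_probability = 0.658,
                          quantize_bms = FALSE,
                          seed = 1L) {
  stopifnot(is.data.frame(regions),
            all(c("id", "mean_count", "dual_probability") %in% names(regions)))
  if (!("cervical_mean_count" %in% names(regions)))
    regions$cervical_mean_count <- regions$mean_count
  if (any(regions$mean_count < 0) || any(regions$cervical_mean_count < 0))
    stop("mean counts must be >= 0")
  if (any(regions$dual_probability < 0 | regions$dual_probability > 1))
    stop("dual_probability must lie in [0, 1]")
  if (!is.numeric(dispersion) || dispersion <= 0)
    stop("dispersion (negative-binomial size) must be > 0")
  im <- utils::modifyList(list(
    meanlog = c(lumbar = log(500), cervical = log(400)),
    sdlog = c(lumbar = 0.5, cervical = 0.5),
    correlation = 0.6, dual_cervical_dimming = 0.5,
    jitter_sd_um = 0.5), intensity_model)
  if (abs(im$correlation) > 1)
    stop("intensity correlation must lie in [-1, 1]")
  if (im$dual_cervical_dimming <= 0 || im$dual_cervical_dimming > 1)
    stop("dual_cervical_dimming must lie in (0, 1]")
  for (s in names(severity_sparing)) {
    v <- severity_sparing[[s]]
    if (any(v < 0 | v > 1))
      stop("sparing fractions for severity '", s, "' must lie in [0, 1]")
  }
  if (!is.null(behavior_link)) {
    stopifnot(all(c("region_ids", "weights") %in% names(behavior_link)))
    if (!all(behavior_link$region_ids %in% regions$id))
      stop("behavior_link region id not present in regions: ",
           paste(setdiff(behavior_link$region_ids, regions$id), collapse = ", "))
    behavior_link$noise_sd <- behavior_link$noise_sd %||% 0.5
  }
  stopifnot(all(c("condition", "severity", "n_animals") %in% names(arms)))
  unknown <- setdiff(setdiff(arms$severity, "none"), names(severity_sparing))
  if (length(unknown))
    stop("arm severity without sparing map: ", paste(unknown, collapse = ", "))
  if (coinjected_dual_probability < 0 || coinjected_dual_probability > 1)
    stop("coinjected_dual_probability must lie in [0, 1]")
  structure(list(regions = regions, dispersion = dispersion,
                 intensity_model = im, severity_sparing = severity_sparing,
                 behavior_link = behavior_link, arms = arms,
                 coinjected_dual_probability = coinjected_dual_probability,
                 quantize_bms = quantize_bms, seed = as.integer(seed)),
            class = "cohort_design")
}

#' Default study-sized cohort design
#'
#' Parameters emulating a dual cervical/lumbar retrograde-labeling study
#' across eleven supraspinal populations, with injury arms of graded
#' severity. Mean counts, dual-projection probabilities and sparing
#' fractions are set to the magnitudes reported for such studies (tens of
#' thousands of lumbar-projecting nuclei brain-wide, ~27% brain-wide
#' lumbar-projection index, ~42% overall co-label, mild injuries sparing
#' roughly half of the label and severe injuries nearly none).
#'
#' @param seed integer seed stored in the design.
#' @param scale multiplier on all mean counts (use < 1 for fast tests).
#' @return a [cohort_design()] whose region ids 1..11 match the leaves of
#'   `build_toy_atlas(11)`.
#' @export
default_cohort_design <- function(seed = 1L, scale = 1) {
  acr <- c("CST", "RN", "GRN", "LHA", "PVH", "PPN",
           "MDRN", "PRN", "VEST", "SOL", "DCN")
  lum <- c(8000, 1500, 5000, 1200, 1500, 800, 300, 3000, 1500, 800, 300)
  dual <- c(0.53, 0.144, 0.485, 0.548, 0.42, 0.42,
            0.30, 0.45, 0.40, 0.35, 0.085)
  # per-region lumbar-projection index targets used to size the cervical
  # channel: cervical total = lumbar * (1 - idx) / idx, of which the dual
  # cells contribute lumbar * dual, remainder is cervical-only
  idx <- c(0.28, 0.45, 0.35, 0.40, 0.55, 0.30, 0.05, 0.40, 0.15, 0.25, 0.45)
  cerv_total <- lum * (1 - idx) / idx
  cerv_only <- pmax(0, cerv_total - lum * dual)
  regions <- data.frame(id = seq_along(acr), acronym = acr,
                        mean_count = lum * scale,
                        dual_probability = dual,
                        cervical_mean_count = cerv_only * scale,
                        stringsAsFactors = FALSE)
  base_mild <- rep(0.66, 11); base_mild[1] <- 0.20
  base_mild[2] <- 0.751; base_mild[8] <- 0.833
  base_mod <- rep(0.27, 11); base_mod[1] <- 0.08
  base_mod[2] <- 0.32; base_mod[8] <- 0.35
  sev <- list(
    mild = stats::setNames(base_mild, regions$id),
    moderate = stats::setNames(base_mod, regions$id),
    severe = stats::setNames(rep(0.001, 11), regions$id))
  arms <- data.frame(
    condition = c("uninjured", "coinjected", "mild", "moderate", "severe"),
    severity = c("none", "none", "mild", "moderate", "severe"),
    n_animals = c(4, 3, 3, 6, 3), stringsAsFactors = FALSE)
  cohort_design(regions, dispersion = 40,
                severity_sparing = sev,
                behavior_link = list(region_ids = 6L, weights = 1,
                                     noise_sd = 0.75),
                arms = arms, seed = seed)
}

.rcounts <- function(n, mu, size) {
  if (mu <= 0) return(integer(n))
  if (is.infinite(size)) stats::rpois(n, mu) else
    stats::rnbinom(n, mu = mu, size = size)
}

#' Simulate a multi-animal labeled-nuclei cohort
#'
#' For each animal and region, a true lumbar-labeled count is drawn from a
#' negative binomial with the design mean and dispersion; each nucleus is
#' placed uniformly within its region's voxels and flagged dual with the
#' region's dual probability. Dual nuclei appear in both channels at
#' identical coordinates (the cervical copy then receives sub-resolution
#' Gaussian jitter) with intensities from the correlated lognormal model,
#' the cervical intensity multiplied by the dimming factor. Cervical-only
#' nuclei are drawn analogously. Injured animals' cells are thinned
#' binomially by the severity's per-region sparing fraction, and the
#' behavior score is a monotone map of the weighted realized sparing of the
#' linked regions plus Gaussian noise, clipped to \[0, 9\].
#'
#' @param design a [cohort_design()].
#' @param atlas list with `volume` and `ontology` (see [build_toy_atlas()]).
#' @return list of class `cohort` with elements `design`, `metadata`
#'   (animal_id, condition, severity, bms), `animals` (per animal: list of
#'   per-channel point data.frames with columns `x_um`,`y_um`,`z_um`,
#'   `intensity`,`region`,`dual`,`cell_id`) and `truth` (realized per
#'   animal x region counts before/after thinning and realized sparing).
#' @export
simulate_cohort <- function(design, atlas) {
  stopifnot(inherits(design, "cohort_design"))
  vol <- atlas$volume
  bad <- setdiff(design$regions$id,
                 setdiff(unique(as.vector(vol$labels)), 0L))
  if (length(bad))
    stop("design region id not present in annotation volume: ",
         paste(bad, collapse = ", "))
  set.seed(design$seed)
  vox <- lapply(design$regions$id, function(id)
    which(vol$labels == id, arr.ind = TRUE))
  names(vox) <- as.character(design$regions$id)
  vs <- vol$voxel_size_um
  im <- design$intensity_model

  animals <- list(); meta <- list(); truth <- list()
  a_num <- 0L
  for (k in seq_len(nrow(design$arms))) {
    arm <- design$arms[k, ]
    coin <- identical(arm$condition, "coinjected")
    for (j in seq_len(arm$n_animals)) {
      a_num <- a_num + 1L
      aid <- sprintf("%s_%02d", arm$condition, j)
      sp_map <- .sparing_for(design, arm$severity)
      lum_list <- list(); cer_list <- list(); tr <- list()
      cell0 <- 0L
      for (r in seq_len(nrow(design$regions))) {
        reg <- design$regions[r, ]
        spare <- sp_map[[as.character(reg$id)]]
        n_lum <- .rcounts(1L, reg$mean_count, design$dispersion)
        p_dual <- if (coin) design$coinjected_dual_probability else
          reg$dual_probability
        dual <- stats::rbinom(n_lum, 1L, p_dual) == 1L
        n_cer <- if (coin) 0L else
          .rcounts(1L, reg$cervical_mean_count, design$dispersion)
        # injury thins whole cells (both channels of a dual cell together)
        keep_lum <- stats::rbinom(n_lum, 1L, spare) == 1L
        keep_cer <- stats::rbinom(n_cer, 1L, spare) == 1L
        xyz_lum <- .place_uniform(vox[[as.character(reg$id)]], n_lum, vs)
        xyz_cer <- .place_uniform(vox[[as.character(reg$id)]], n_cer, vs)
        # intensities: dual cells from the correlated bivariate log model
        z1 <- stats::rnorm(n_lum); z2 <- stats::rnorm(n_lum)
        rho <- im$correlation
        log_l <- im$meanlog[["lumbar"]] + im$sdlog[["lumbar"]] * z1
        log_c_dual <- im$meanlog[["cervical"]] +
          im$sdlog[["cervical"]] * (rho * z1 + sqrt(1 - rho^2) * z2) +
          if (coin) 0 else log(im$dual_cervical_dimming)
        int_lum <- exp(log_l)
        int_cer_dual <- exp(log_c_dual)
        int_cer_only <- stats::rlnorm(n_cer, im$meanlog[["cervical"]],
                                      im$sdlog[["cervical"]])
        jit <- function(m) m + matrix(stats::rnorm(length(m), 0,
                                                   im$jitter_sd_um),
                                      nrow = nrow(m))
        ids <- cell0 + seq_len(n_lum); cell0 <- cell0 + n_lum + n_cer
        kl <- which(keep_lum)
        if (length(kl)) {
          lum_list[[r]] <- data.frame(
            x_um = xyz_lum[kl, 1], y_um = xyz_lum[kl, 2],
            z_um = xyz_lum[kl, 3], intensity = int_lum[kl],
            region = reg$id, dual = dual[kl], cell_id = ids[kl])
          kd <- which(keep_lum & dual)
          if (length(kd)) {
            cxyz <- jit(xyz_lum[kd, , drop = FALSE])
            cer_list[[length(cer_list) + 1L]] <- data.frame(
              x_um = cxyz[, 1], y_um = cxyz[, 2], z_um = cxyz[, 3],
              intensity = int_cer_dual[kd], region = reg$id,
              dual = TRUE, cell_id = ids[kd])
          }
        }
        if (n_cer > 0) {
          kc <- which(keep_cer)
          if (length(kc))
            cer_list[[length(cer_list) + 1L]] <- data.frame(
              x_um = xyz_cer[kc, 1], y_um = xyz_cer[kc, 2],
              z_um = xyz_cer[kc, 3], intensity = int_cer_only[kc],
              region = reg$id, dual = FALSE,
              cell_id = cell0 - n_cer + kc)
        }
        n_cells <- n_lum + n_cer
        n_kept <- sum(keep_lum) + sum(keep_cer)
        tr[[r]] <- data.frame(
          animal_id = aid, region = reg$id,
          n_lumbar_true = n_lum, n_cervical_only_true = n_cer,
          n_dual_true = sum(dual),
          n_lumbar_kept = sum(keep_lum), n_cervical_only_kept = sum(keep_cer),
          n_dual_kept = sum(keep_lum & dual),
          sparing_fraction = spare,
          realized_sparing = if (n_cells > 0) n_kept / n_cells else NA_real_,
          stringsAsFactors = FALSE)
      }
      tr <- do.call(rbind, tr)
      bms <- .behavior_score(design, tr)
      lum <- .bind_points(lum_list, aid, "lumbar")
      cer <- .bind_points(cer_list, aid, "cervical")
      animals[[aid]] <- list(lumbar = lum, cervical = cer)
      meta[[a_num]] <- data.frame(animal_id = aid, condition = arm$condition,
                                  severity = arm$severity, bms = bms,
                                  stringsAsFactors = FALSE)
      truth[[a_num]] <- tr
    }
  }
  structure(list(design = design, metadata = do.call(rbind, meta),
                 animals = animals, truth = do.call(rbind, truth)),
            class = "cohort")
}

.sparing_for <- function(design, severity) {
  ids <- as.character(design$regions$id)
  if (identical(severity, "none"))
    return(stats::setNames(as.list(rep(1, length(ids))), ids))
  v <- design$severity_sparing[[severity]]
  if (length(v) == 1L && is.null(names(v)))
    return(stats::setNames(as.list(rep(v, length(ids))), ids))
  if (!all(ids %in% names(v)))
    stop("severity '", severity, "' lacks sparing for region(s): ",
         paste(setdiff(ids, names(v)), collapse = ", "))
  as.list(v[ids])
}

.place_uniform <- function(vox_idx, n, vs) {
  if (n == 0L) return(matrix(numeric(0), ncol = 3))
  pick <- vox_idx[sample.int(nrow(vox_idx), n, replace = TRUE), , drop = FALSE]
  # voxel (i,j,k) 1-based owns [ (i-1)*vs, i*vs )
  offs <- matrix(stats::runif(3L * n), ncol = 3)
  sweep((pick - 1 + offs), 2, vs, `*`)
}

.behavior_score <- function(design, tr) {
  bl <- design$behavior_link
  if (is.null(bl)) return(NA_real_)
  s <- tr$realized_sparing[match(bl$region_ids, tr$region)]
  s[is.na(s)] <- 0
  w <- bl$weights / sum(bl$weights)
  score <- 9 * sum(w * s) + stats::rnorm(1, 0, bl$noise_sd)
  score <- min(9, max(0, score))
  if (isTRUE(design$quantize_bms)) score <- round(score * 2) / 2
  score
}

.bind_points <- function(lst, animal_id, channel) {
  lst <- Filter(function(d) !is.null(d) && nrow(d) > 0, lst)
  if (!length(lst)) {
    out <- data.frame(x_um = numeric(0), y_um = numeric(0), z_um = numeric(0),
                      intensity = numeric(0), region = integer(0),
                      dual = logical(0), cell_id = integer(0))
  } else out <- do.call(rbind, lst)
  rownames(out) <- NULL
  attr(out, "animal_id") <- animal_id
  attr(out, "channel") <- channel
  out
}

#' @export
print.cohort <- function(x, ...) {
  cat("cohort:", nrow(x$metadata), "animals,",
      nrow(x$design$regions), "regions; conditions:",
      paste(unique(x$metadata$condition), collapse = ", "), "\n")
  invisible(x)
}

#' Render a point set as a synthetic image stack
#'
#' Each nucleus becomes an anisotropic 3D Gaussian blob of its intensity on
#' a constant background, with optional additive Gaussian read noise. The
#' stack emulates light-sheet acquisition geometry, where the axial (z)
#' spread exceeds the lateral one.
#'
#' @param points data.frame with `x_um`, `y_um`, `z_um` and `intensity`.
#' @param shape integer length-3 voxel extents of the stack.
#' @param voxel_size_um voxel size(s) in micrometres.
#' @param blob_sigma_um length-2 numeric: Gaussian sigma in XY and Z (um).
#' @param background constant background intensity.
#' @param noise_sd standard deviation of additive Gaussian noise (0 for a
#'   deterministic stack).
#' @return list of class `image_stack` with `data` (3D array) and
#'   `voxel_size_um`.
#' @export
simulate_nuclei_stack <- function(points, shape, voxel_size_um,
                                  blob_sigma_um = c(1.7, 3.4),
                                  background = 100, noise_sd = 0) {
  shape <- as.integer(shape)
  vs <- as.numeric(voxel_size_um)
  if (length(vs) == 1L) vs <- rep(vs, 3L)
  ext <- shape * vs
  if (nrow(points) > 0) {
    inside <- points$x_um >= 0 & points$x_um < ext[1] &
      points$y_um >= 0 & points$y_um < ext[2] &
      points$z_um >= 0 & points$z_um < ext[3]
    if (!all(inside))
      stop(sum(!inside), " point(s) outside the stack bounds")
  }
  img <- array(background, dim = shape)
  sig_vox <- c(blob_sigma_um[1] / vs[1], blob_sigma_um[1] / vs[2],
               blob_sigma_um[2] / vs[3])
  half <- pmax(1L, ceiling(4 * sig_vox))
  for (i in seq_len(nrow(points))) {
    # voxel-center continuous coordinates of the point
    c_vox <- c(points$x_um[i] / vs[1], points$y_um[i] / vs[2],
               points$z_um[i] / vs[3]) + 0.5
    lo <- pmax(1L, floor(c_vox - half)); hi <- pmin(shape, ceiling(c_vox + half))
    gx <- exp(-((lo[1]:hi[1]) - c_vox[1])^2 / (2 * sig_vox[1]^2))
    gy <- exp(-((lo[2]:hi[2]) - c_vox[2])^2 / (2 * sig_vox[2]^2))
    gz <- exp(-((lo[3]:hi[3]) - c_vox[3])^2 / (2 * sig_vox[3]^2))
    blob <- points$intensity[i] * (gx %o% gy %o% gz)
    img[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <-
      img[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] + blob
  }
  if (noise_sd > 0)
    img <- img + array(stats::rnorm(length(img), 0, noise_sd), dim = shape)
  structure(list(data = img, voxel_size_um = vs), class = "image_stack")
}

#' Simulate a GFAP-stained lesion section
#'
#' Builds a 2D image of a spinal cord section in which astrocytic (GFAP+)
#' tissue is continuous everywhere except within a lesion band, where
#' GFAP-positive continuity exists only in the listed column spans
#' (bridges). The ground-truth bridge fraction, total span width divided by
#' cord width, is recorded for recovery tests.
#'
#' @param width_px,height_px image extents (columns x rows).
#' @param bridge_spans list of inclusive column intervals `c(start, end)`;
#'   must lie within the image and not overlap.
#' @param lesion_band inclusive row interval of the lesion; defaults to the
#'   middle third of the image.
#' @param gfap_high,gfap_low intensities of GFAP-positive and -negative
#'   pixels.
#' @return list of class `gfap_section` with `image` (rows x columns
#'   matrix), `lesion_band`, `bridge_spans` and `truth_fraction`.
#' @export
simulate_gfap_section <- function(width_px, height_px, bridge_spans = list(),
                                  lesion_band = NULL,
                                  gfap_high = 1, gfap_low = 0) {
  if (is.null(lesion_band))
    lesion_band <- c(floor(height_px / 3) + 1L, floor(2 * height_px / 3))
  spans <- lapply(bridge_spans, function(s) as.integer(round(s)))
  for (s in spans)
    if (length(s) != 2L || s[1] > s[2] || s[1] < 1L || s[2] > width_px)
      stop("bridge span outside image width: ", paste(s, collapse = "-"))
  if (length(spans) > 1) {
    o <- order(vapply(spans, `[`, integer(1), 1L))
    spans <- spans[o]
    for (i in seq_len(length(spans) - 1L))
      if (spans[[i + 1L]][1] <= spans[[i]][2])
        stop("bridge spans overlap")
  }
  img <- matrix(gfap_high, nrow = height_px, ncol = width_px)
  img[lesion_band[1]:lesion_band[2], ] <- gfap_low
  for (s in spans)
    img[lesion_band[1]:lesion_band[2], s[1]:s[2]] <- gfap_high
  truth <- sum(vapply(spans, function(s) s[2] - s[1] + 1L, integer(1))) /
    width_px
  structure(list(image = img, lesion_band = lesion_band,
                 bridge_spans = spans, truth_fraction = truth),
            class = "gfap_section")
}
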