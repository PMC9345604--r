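#' Spot-detection parameters
#'
#' Defaults follow the common practice for nuclear labels imaged by
#' light-sheet/confocal microscopy: a 4 um spot diameter in XY and 8 um in
#' Z, reflecting the poorer axial resolution.
#'
#' @param diameter_xy_um,diameter_z_um expected spot diameters (um, > 0).
#' @param intensity_threshold minimum raw image intensity at the detected
#'   peak for a spot to be kept (>= 0).
#' @return list of class `spot_params`.
#' @export
spot_params <- function(diameter_xy_um = 4, diameter_z_um = 8,
                        intensity_threshold = 0) {
  if (diameter_xy_um <= 0 || diameter_z_um <= 0)
    stop("spot diameters must be positive")
  if (intensity_threshold < 0)
    stop("intensity_threshold must be >= 0")
  structure(list(diameter_xy_um = diameter_xy_um,
                 diameter_z_um = diameter_z_um,
                 intensity_threshold = intensity_threshold),
            class = "spot_params")
}

#' Dual-label matching parameters
#'
#' @param max_distance_um maximum center-to-center distance for two nuclei
#'   to be considered the same cell (> 0).
#' @param metric `"euclidean"` (default: plain 3D distance) or
#'   `"anisotropic"`, in which z offsets are first converted into
#'   XY-equivalent units by dividing by `diameter_z_um / diameter_xy_um`,
#'   so the poorer axial resolution tolerates proportionally larger z
#'   offsets.
#' @param diameter_xy_um,diameter_z_um diameters defining the anisotropic
#'   scaling.
#' @return list of class `match_params`.
#' @export
match_params <- function(max_distance_um = 4,
                         metric = c("euclidean", "anisotropic"),
                         diameter_xy_um = 4, diameter_z_um = 8) {
  metric <- match.arg(metric)
  if (max_distance_um <= 0) stop("max_distance_um must be > 0")
  structure(list(max_distance_um = max_distance_um, metric = metric,
                 z_scale = if (metric == "anisotropic")
                   diameter_xy_um / diameter_z_um else 1),
            class = "match_params")
}

.gauss_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-half):half)^2 / (2 * sigma^2))
  k / sum(k)
}

# separable Gaussian blur of a 3D array with per-axis sigmas (voxels);
# edges are handled by replicate padding
.gauss_blur3 <- function(a, sigmas) {
  d <- dim(a)
  for (ax in 1:3) {
    k <- .gauss_kernel(sigmas[ax])
    if (length(k) == 1L) next
    half <- (length(k) - 1L) %/% 2L
    perm <- switch(ax, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
    b <- aperm(a, perm)
    db <- dim(b)
    m <- matrix(b, nrow = db[1])
    m <- rbind(m[rep(1L, half), , drop = FALSE], m,
               m[rep(nrow(m), half), , drop = FALSE])
    f <- stats::filter(m, k, sides = 2)
    f <- f[(half + 1L):(half + db[1]), , drop = FALSE]
    a <- aperm(array(f, dim = db), order(perm))
  }
  a
}

#' Detect spots in an image stack
#'
#' A classical difference-of-Gaussian detector standing in for the
#' proprietary spot functions of commercial rendering software: the stack
#' is band-pass filtered at scales set from the anisotropic spot diameters,
#' local maxima of the response are extracted with a minimum separation of
#' one spot diameter, and candidates whose raw image intensity at the peak
#' falls below `intensity_threshold` are discarded.
#'
#' @param stack an `image_stack` (see [simulate_nuclei_stack()]) or a list
#'   with `data` (3D array) and `voxel_size_um`.
#' @param params a [spot_params()].
#' @return data.frame with columns `x_um`, `y_um`, `z_um` (voxel-center
#'   coordinates of the peak) and `intensity` (raw image value at the
#'   peak), ordered by decreasing filter response.
#' @export
detect_spots <- function(stack, params = spot_params()) {
  if (is.null(stack$voxel_size_um))
    stop("stack carries no voxel-size metadata")
  a <- stack$data
  vs <- stack$voxel_size_um
  d <- dim(a)
  # sigma ~ radius / sqrt(2), per axis in voxel units
  sig_um <- c(params$diameter_xy_um, params$diameter_xy_um,
              params$diameter_z_um) / (2 * sqrt(2))
  s1 <- sig_um / vs
  g1 <- .gauss_blur3(a, s1)
  g2 <- .gauss_blur3(a, 1.6 * s1)
  dog <- g1 - g2
  # local maxima: strictly greater than the 26-neighbourhood
  nb_max <- array(-Inf, dim = d)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    xs <- pmin(pmax(seq_len(d[1]) + dx, 1L), d[1])
    ys <- pmin(pmax(seq_len(d[2]) + dy, 1L), d[2])
    zs <- pmin(pmax(seq_len(d[3]) + dz, 1L), d[3])
    nb_max <- pmax(nb_max, dog[xs, ys, zs])
  }
  # >= tolerates plateau ties (a blob centred on a voxel boundary peaks in
  # two voxels); the minimum-separation pass below keeps one of the twins
  tol <- max(1e-8 * max(abs(a)), .Machine$double.eps)
  cand <- which(dog >= nb_max & dog > tol)
  if (!length(cand))
    return(data.frame(x_um = numeric(0), y_um = numeric(0),
                      z_um = numeric(0), intensity = numeric(0)))
  idx <- arrayInd(cand, d)
  resp <- dog[cand]
  o <- order(-resp)
  idx <- idx[o, , drop = FALSE]; resp <- resp[o]; cand <- cand[o]
  # enforce minimum separation of one diameter (anisotropic ellipsoid)
  um <- sweep(idx - 0.5, 2, vs, `*`)
  keep <- logical(nrow(idx))
  min_d <- c(params$diameter_xy_um, params$diameter_xy_um,
             params$diameter_z_um)
  for (i in seq_len(nrow(idx))) {
    if (i == 1L) { keep[1L] <- TRUE; next }
    kept <- which(keep)
    dd <- sweep(um[kept, , drop = FALSE], 2, um[i, ], `-`)
    dd <- sweep(dd, 2, min_d, `/`)
    keep[i] <- all(rowSums(dd^2) >= 1)
  }
  idx <- idx[keep, , drop = FALSE]
  um <- um[keep, , drop = FALSE]
  raw <- a[idx]
  ok <- raw >= params$intensity_threshold
  data.frame(x_um = um[ok, 1], y_um = um[ok, 2], z_um = um[ok, 3],
             intensity = raw[ok])
}

# fixed-radius candidate pairs between two coordinate matrices via grid
# hashing; returns data.frame(i, j, dist) with dist <= r. One vectorized
# pass per neighbour-cell offset keeps this fast for 1e4-1e5 points.
.radius_pairs <- function(a, b, r, z_scale = 1) {
  if (nrow(a) == 0L || nrow(b) == 0L)
    return(data.frame(i = integer(0), j = integer(0), dist = numeric(0)))
  sa <- a; sb <- b
  sa[, 3] <- sa[, 3] * z_scale; sb[, 3] <- sb[, 3] * z_scale
  ca <- floor(sa / r); cb <- floor(sb / r)
  buckets <- split(seq_len(nrow(sb)), paste(cb[, 1], cb[, 2], cb[, 3]))
  bnames <- names(buckets)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  res_i <- list(); res_j <- list(); res_d <- list()
  for (k in seq_len(nrow(offs))) {
    keys <- paste(ca[, 1] + offs[k, 1], ca[, 2] + offs[k, 2],
                  ca[, 3] + offs[k, 3])
    bi <- match(keys, bnames)
    hit_a <- which(!is.na(bi))
    if (!length(hit_a)) next
    lst <- buckets[bi[hit_a]]
    lens <- lengths(lst)
    is <- rep.int(hit_a, lens)
    js <- unlist(lst, use.names = FALSE)
    dd <- sqrt((sb[js, 1] - sa[is, 1])^2 + (sb[js, 2] - sa[is, 2])^2 +
                 (sb[js, 3] - sa[is, 3])^2)
    keep <- dd <= r
    if (any(keep)) {
      res_i[[k]] <- is[keep]; res_j[[k]] <- js[keep]; res_d[[k]] <- dd[keep]
    }
  }
  data.frame(i = unlist(res_i, use.names = FALSE) %||% integer(0),
             j = unlist(res_j, use.names = FALSE) %||% integer(0),
             dist = unlist(res_d, use.names = FALSE) %||% numeric(0))
}

#' Match dual-labeled nuclei between two channels
#'
#' One-to-one matching of nuclei detected in the lumbar and cervical
#' channels: all candidate pairs closer than the distance threshold are
#' accepted greedily in ascending distance order (ties broken by the lowest
#' index pair), so each nucleus participates in at most one pair and the
#' result is deterministic for a fixed input.
#'
#' @param set_lumbar,set_cervical data.frames with `x_um`, `y_um`, `z_um`
#'   (intensities and other columns are preserved by index).
#' @param params a [match_params()].
#' @return list of class `match_result` with `pairs` (data.frame `i`
#'   lumbar index, `j` cervical index, `dist`), `unmatched_lumbar`,
#'   `unmatched_cervical`.
#' @export
match_dual <- function(set_lumbar, set_cervical, params = match_params()) {
  a <- as.matrix(set_lumbar[, c("x_um", "y_um", "z_um")])
  b <- as.matrix(set_cervical[, c("x_um", "y_um", "z_um")])
  if (nrow(a) && nrow(b)) {
    ra <- range(a); rb <- range(b)
    if (max(rb[2], ra[2]) > 100 * params$max_distance_um &&
        (ra[2] < rb[1] || rb[2] < ra[1]))
      warning("coordinate ranges of the two sets do not overlap; ",
              "are both in the same frame and unit?")
  }
  cand <- .radius_pairs(a, b, params$max_distance_um, params$z_scale)
  ord <- order(cand$dist, cand$i, cand$j)
  cand <- cand[ord, , drop = FALSE]
  used_a <- logical(nrow(a)); used_b <- logical(nrow(b))
  sel <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    i <- cand$i[k]; j <- cand$j[k]
    if (!used_a[i] && !used_b[j]) {
      used_a[i] <- TRUE; used_b[j] <- TRUE; sel[k] <- TRUE
    }
  }
  pairs <- cand[sel, , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs,
                 unmatched_lumbar = which(!used_a),
                 unmatched_cervical = which(!used_b),
                 n_lumbar = nrow(a), n_cervical = nrow(b),
                 params = params),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat("match_result:", nrow(x$pairs), "pairs of", x$n_lumbar, "lumbar /",
      x$n_cervical, "cervical nuclei\n")
  invisible(x)
}

#' Co-label rate of lumbar-projecting nuclei
#'
#' The fraction of lumbar-channel nuclei that were matched to a cervical
#' nucleus, overall and (when the lumbar set carries a `region` column)
#' per region. Regions with no lumbar nuclei are undefined and omitted.
#'
#' @param match a [match_dual()] result.
#' @param set_lumbar the lumbar point set the match was computed on.
#' @return data.frame with columns `region` (including an `"overall"`
#'   row), `n_lumbar`, `n_dual`, `rate`.
#' @export
colabel_rate <- function(match, set_lumbar) {
  stopifnot(inherits(match, "match_result"))
  n <- match$n_lumbar
  matched <- logical(n)
  matched[match$pairs$i] <- TRUE
  out <- data.frame(region = "overall", n_lumbar = n,
                    n_dual = sum(matched),
                    rate = if (n > 0) mean(matched) else NA_real_,
                    stringsAsFactors = FALSE)
  if (!is.null(set_lumbar$region) && n > 0) {
    reg <- as.character(set_lumbar$region)
    per <- do.call(rbind, lapply(split(seq_len(n), reg), function(ix)
      data.frame(n_lumbar = length(ix), n_dual = sum(matched[ix]),
                 rate = mean(matched[ix]))))
    per <- data.frame(region = rownames(per), per, stringsAsFactors = FALSE)
    rownames(per) <- NULL
    out <- rbind(per, out)
  }
  rownames(out) <- NULL
  out
}

#' Intensity contrast between dual and single-labeled nuclei
#'
#' Compares, per channel, the label intensity of nuclei detected as
#' dual-projecting against nuclei carrying that channel only, using a
#' Welch t test on log intensities (label intensities are approximately
#' lognormal). In co-injected control mode the cross-channel log-intensity
#' correlation among dual cells is also reported.
#'
#' @param match a [match_dual()] result.
#' @param set_lumbar,set_cervical the point sets the match was computed on;
#'   both need an `intensity` column.
#' @param coinjected if `TRUE`, also report the dual-cell cross-channel
#'   correlation.
#' @return list with `contrast` (per-channel data.frame: group geometric
#'   means, log-mean difference, ratio, t, df, p, `undefined` flag when a
#'   group has < 2 cells) and, if requested, `dual_correlation`
#'   (estimate, CI, p).
#' @export
intensity_contrast <- function(match, set_lumbar, set_cervical,
                               coinjected = FALSE) {
  stopifnot(inherits(match, "match_result"))
  one <- function(int, dual_idx, channel) {
    dual <- log(int[dual_idx])
    single <- log(int[setdiff(seq_along(int), dual_idx)])
    und <- length(dual) < 2 || length(single) < 2
    if (!und) tt <- stats::t.test(dual, single)
    data.frame(channel = channel,
               n_dual = length(dual), n_single = length(single),
               gm_dual = exp(mean(dual)), gm_single = exp(mean(single)),
               log_diff = if (und) NA_real_ else mean(dual) - mean(single),
               ratio = if (und) NA_real_ else
                 exp(mean(dual) - mean(single)),
               t = if (und) NA_real_ else unname(tt$statistic),
               df = if (und) NA_real_ else unname(tt$parameter),
               p = if (und) NA_real_ else tt$p.value,
               undefined = und, stringsAsFactors = FALSE)
  }
  contrast <- rbind(
    one(set_lumbar$intensity, match$pairs$i, "lumbar"),
    one(set_cervical$intensity, match$pairs$j, "cervical"))
  out <- list(contrast = contrast)
  if (coinjected) {
    if (nrow(match$pairs) >= 3) {
      ct <- stats::cor.test(log(set_lumbar$intensity[match$pairs$i]),
                            log(set_cervical$intensity[match$pairs$j]))
      out$dual_correlation <- data.frame(
        estimate = unname(ct$estimate), ci_lo = ct$conf.int[1],
        ci_hi = ct$conf.int[2], p = ct$p.value, n = nrow(match$pairs))
    } else {
      out$dual_correlation <- data.frame(estimate = NA_real_,
                                         ci_lo = NA_real_, ci_hi = NA_real_,
                                         p = NA_real_, n = nrow(match$pairs))
    }
  }
  out
}

#' Detection-threshold dropout curve
#'
#' Emulates the consequence of a less sensitive acquisition: for each
#' retained fraction `q`, only the brightest `q` fraction of cervical
#' nuclei are kept (ranked by intensity, ties broken by index), the dual
#' matching is recomputed, and the overall dual rate is re-estimated. When
#' dual cells carry systematically dimmer cervical label they drop out
#' disproportionately, so the apparent dual-innervation rate falls.
#'
#' @param set_lumbar,set_cervical point sets with intensities.
#' @param params a [match_params()].
#' @param retain_fractions fractions in (0, 1\] to evaluate (1 is always
#'   included as the reference).
#' @return data.frame with columns `fraction`, `n_retained`, `dual_rate`,
#'   `relative_change_pct` (vs the full set) and `empty` flag.
#' @export
dropout_curve <- function(set_lumbar, set_cervical, params = match_params(),
                          retain_fractions = c(1, 0.8, 0.6, 0.4, 0.2)) {
  if (is.null(set_cervical$intensity))
    stop("cervical intensities are required for the dropout analysis")
  fr <- sort(unique(c(1, retain_fractions)), decreasing = TRUE)
  n_c <- nrow(set_cervical)
  ord <- order(-set_cervical$intensity, seq_len(n_c))
  rate_at <- function(keep_idx) {
    m <- match_dual(set_lumbar, set_cervical[keep_idx, , drop = FALSE],
                    params)
    if (m$n_lumbar == 0) NA_real_ else nrow(m$pairs) / m$n_lumbar
  }
  rows <- lapply(fr, function(q) {
    n_keep <- as.integer(floor(q * n_c + 1e-9))
    keep <- if (n_keep > 0) ord[seq_len(n_keep)] else integer(0)
    r <- if (n_keep == 0) 0 else rate_at(keep)
    data.frame(fraction = q, n_retained = n_keep, dual_rate = r,
               empty = n_keep == 0)
  })
  out <- do.call(rbind, rows)
  ref <- out$dual_rate[out$fraction == 1][1]
  out$relative_change_pct <- if (is.na(ref) || ref == 0)
    ifelse(out$fraction == 1, 0, NA_real_) else
      100 * (out$dual_rate - ref) / ref
  out[, c("fraction", "n_retained", "dual_rate", "relative_change_pct",
          "empty")]
}
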