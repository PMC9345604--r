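#' Annotation volume
#'
#' A 3D integer label array in which voxel value 0 marks outside-brain and
#' positive values are leaf-region labels of the companion ontology. The
#' first array axis carries the left/right split; `midline` is the plane
#' coordinate (in voxel units, zero-based) separating the hemispheres.
#'
#' @param labels 3D integer array.
#' @param voxel_size_um positive numeric length 3, micrometres per voxel
#'   along each array axis.
#' @param midline midline plane coordinate along axis 1, in voxel units
#'   (may be fractional for odd extents). Defaults to half the extent.
#' @param orientation free-text axis convention tag recorded as metadata
#'   (registration upstream of this package is expected to have produced
#'   the standard orientation).
#' @return An object of class `annotation_volume`.
#' @export
annotation_volume <- function(labels, voxel_size_um,
                              midline = dim(labels)[1] / 2,
                              orientation = "asr") {
  if (length(dim(labels)) != 3L)
    stop("labels must be a 3D array")
  voxel_size_um <- as.numeric(voxel_size_um)
  if (length(voxel_size_um) == 1L) voxel_size_um <- rep(voxel_size_um, 3L)
  if (length(voxel_size_um) != 3L || any(!is.finite(voxel_size_um)) ||
      any(voxel_size_um <= 0))
    stop("voxel_size_um must be three positive numbers")
  if (midline < 0 || midline > dim(labels)[1])
    stop("midline outside array bounds")
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, voxel_size_um = voxel_size_um,
                 midline = midline, orientation = orientation),
            class = "annotation_volume")
}

#' @export
print.annotation_volume <- function(x, ...) {
  cat("annotation_volume:", paste(dim(x$labels), collapse = " x "),
      "voxels at", paste(x$voxel_size_um, collapse = "/"), "um;",
      length(setdiff(unique(as.vector(x$labels)), 0L)), "labels\n")
  invisible(x)
}

#' Assign detected nuclei to atlas regions and hemispheres
#'
#' Each point is mapped to the label of its containing voxel using
#' zero-based half-open voxel ownership: a coordinate `c` um along an axis
#' with voxel size `v` belongs to voxel `floor(c / v)`, which owns
#' `[v*i, v*(i+1))`. Points in label-0 voxels are flagged unassigned (region
#' 0), not dropped; points outside the array get region `NA` and
#' `out_of_bounds = TRUE`. The hemisphere is the side of the midline plane
#' along the first axis; points exactly on the midline are assigned to the
#' left hemisphere (documented tie-break).
#'
#' @param points data.frame with columns `x_um`, `y_um`, `z_um` (and any
#'   others, which are preserved).
#' @param volume an [annotation_volume()].
#' @return `points` with added columns `region` (integer label; 0 =
#'   unassigned, `NA` = out of bounds) and `hemisphere` (`"left"`/`"right"`,
#'   `NA` when out of bounds), plus attribute `n_out_of_bounds`.
#' @export
assign_points <- function(points, volume) {
  stopifnot(inherits(volume, "annotation_volume"))
  need <- c("x_um", "y_um", "z_um")
  if (!all(need %in% names(points)))
    stop("points need columns x_um, y_um, z_um")
  vs <- volume$voxel_size_um
  dims <- dim(volume$labels)
  n <- nrow(points)
  ix <- floor(points$x_um / vs[1])
  iy <- floor(points$y_um / vs[2])
  iz <- floor(points$z_um / vs[3])
  inb <- ix >= 0 & ix < dims[1] & iy >= 0 & iy < dims[2] &
    iz >= 0 & iz < dims[3] &
    is.finite(ix) & is.finite(iy) & is.finite(iz)
  region <- rep(NA_integer_, n)
  if (any(inb))
    region[inb] <- volume$labels[cbind(ix[inb] + 1L, iy[inb] + 1L,
                                       iz[inb] + 1L)]
  hemi <- rep(NA_character_, n)
  mid_um <- volume$midline * vs[1]
  hemi[inb] <- ifelse(points$x_um[inb] <= mid_um, "left", "right")
  points$region <- region
  points$hemisphere <- hemi
  attr(points, "n_out_of_bounds") <- sum(!inb)
  points
}

.meta_of <- function(ps, what) {
  v <- ps[[what]]
  if (!is.null(v) && length(v) >= 1L && !is.na(v[1])) return(v[1])
  attr(ps, what) %||% what
}

#' Count nuclei per region, channel and hemisphere
#'
#' Aggregates one or more assigned point sets into a long count table at
#' the requested ontology level. Every region of the ontology at that level
#' appears for every animal/channel present (zero counts included), so that
#' downstream sparing and screening see regions with no surviving label.
#' Unassigned (label 0) and out-of-bounds points are tallied separately in
#' the `flagged` attribute; region counts plus flagged counts always equal
#' the number of input points.
#'
#' @param points an assigned point set (see [assign_points()]) or a list of
#'   them. Each must carry `animal_id` and `channel` either as columns or
#'   as attributes.
#' @param ontology a [region_ontology()].
#' @param level `"leaf"`, `"region69"` or `"summary25"`.
#' @return data.frame of class `region_counts` with columns `animal_id`,
#'   `channel`, `region`, `hemisphere`, `count`; attributes `level` and
#'   `flagged` (per animal/channel unassigned and out-of-bounds tallies).
#' @export
count_by_region <- function(points, ontology,
                            level = c("leaf", "region69", "summary25")) {
  level <- match.arg(level)
  stopifnot(inherits(ontology, "region_ontology"))
  if (is.data.frame(points)) points <- list(points)
  region_names <- switch(level,
    leaf = collapse_regions(ontology, ontology$leaves, "leaf"),
    region69 = unique(unname(ontology$collapse_69)),
    summary25 = unique(unname(ontology$collapse_25)))
  region_names <- unique(region_names)
  hemis <- c("left", "right")
  out <- list(); flags <- list()
  for (ps in points) {
    aid <- .meta_of(ps, "animal_id")
    ch <- .meta_of(ps, "channel")
    if (!("region" %in% names(ps)))
      stop("points not assigned; run assign_points() first")
    oob <- is.na(ps$region)
    unas <- !oob & ps$region == 0L
    ok <- !oob & !unas
    rn <- collapse_regions(ontology, ps$region[ok], level)
    if (anyNA(rn))
      stop("point region id not covered by ontology collapse at level ", level)
    tab <- table(factor(rn, levels = region_names),
                 factor(ps$hemisphere[ok], levels = hemis))
    df <- as.data.frame(tab, stringsAsFactors = FALSE)
    names(df) <- c("region", "hemisphere", "count")
    df <- data.frame(animal_id = aid, channel = ch, df,
                     stringsAsFactors = FALSE)
    out[[length(out) + 1L]] <- df
    flags[[length(flags) + 1L]] <- data.frame(
      animal_id = aid, channel = ch, n_points = nrow(ps),
      unassigned = sum(unas), out_of_bounds = sum(oob),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res$count <- as.integer(res$count)
  rownames(res) <- NULL
  structure(res, level = level, flagged = do.call(rbind, flags),
            class = c("region_counts", "data.frame"))
}

#' Collapse an existing count table to a coarser level
#'
#' Summing counts then collapsing equals collapsing then summing; this
#' helper re-keys a leaf- or reporting-level table through the ontology's
#' collapse maps.
#'
#' @param counts a `region_counts` table at leaf or region69 level.
#' @param ontology a [region_ontology()].
#' @param level target level (coarser than the current one).
#' @return a `region_counts` table at the requested level.
#' @export
collapse_counts <- function(counts, ontology,
                            level = c("region69", "summary25")) {
  level <- match.arg(level)
  from <- attr(counts, "level")
  key <- switch(paste(from, level, sep = "->"),
    "leaf->region69" = {
      acr2id <- stats::setNames(as.character(ontology$leaves),
                                collapse_regions(ontology, ontology$leaves, "leaf"))
      ontology$collapse_69[acr2id[counts$region]]
    },
    "leaf->summary25" = {
      acr2id <- stats::setNames(as.character(ontology$leaves),
                                collapse_regions(ontology, ontology$leaves, "leaf"))
      ontology$collapse_25[ontology$collapse_69[acr2id[counts$region]]]
    },
    "region69->summary25" = ontology$collapse_25[counts$region],
    stop("cannot collapse from level '", from, "' to '", level, "'"))
  agg <- stats::aggregate(
    count ~ animal_id + channel + region + hemisphere,
    data = transform(counts, region = unname(key)), FUN = sum)
  agg$count <- as.integer(agg$count)
  structure(agg[order(agg$animal_id, agg$channel, agg$region, agg$hemisphere), ],
            level = level, flagged = attr(counts, "flagged"),
            class = c("region_counts", "data.frame"))
}

#' Left/right symmetry of regional counts
#'
#' Pools counts over animals and channels and reports, per region, the
#' left-hemisphere fraction L/(L+R) with an exact binomial confidence
#' interval. Regions with no nuclei on either side are returned flagged
#' undefined and should be excluded from summaries.
#'
#' @param counts a `region_counts` table carrying hemisphere keys.
#' @param conf_level confidence level for the binomial interval.
#' @return data.frame with columns `region`, `left`, `right`,
#'   `fraction_left`, `ci_lo`, `ci_hi`, `undefined`.
#' @export
hemisphere_symmetry <- function(counts, conf_level = 0.95) {
  l <- stats::aggregate(count ~ region,
                        data = counts[counts$hemisphere == "left", ], FUN = sum)
  r <- stats::aggregate(count ~ region,
                        data = counts[counts$hemisphere == "right", ], FUN = sum)
  m <- merge(l, r, by = "region", all = TRUE, suffixes = c("_l", "_r"))
  m$count_l[is.na(m$count_l)] <- 0L
  m$count_r[is.na(m$count_r)] <- 0L
  n <- m$count_l + m$count_r
  frac <- ifelse(n > 0, m$count_l / n, NA_real_)
  ci <- t(vapply(seq_len(nrow(m)), function(i) {
    if (n[i] == 0) return(c(NA_real_, NA_real_))
    bt <- stats::binom.test(m$count_l[i], n[i], conf.level = conf_level)
    as.numeric(bt$conf.int)
  }, numeric(2)))
  data.frame(region = m$region, left = m$count_l, right = m$count_r,
             fraction_left = frac, ci_lo = ci[, 1], ci_hi = ci[, 2],
             undefined = n == 0, stringsAsFactors = FALSE)
}
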