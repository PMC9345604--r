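.sum_counts <- function(counts, by = c("animal_id", "region")) {
  agg <- stats::aggregate(counts$count,
                          by = counts[, by, drop = FALSE], FUN = sum)
  names(agg)[ncol(agg)] <- "count"
  agg
}

#' Lumbar-projection index
#'
#' For each region the index is the number of lumbar-labeled nuclei
#' divided by the total number of supraspinal nuclei detected there
#' (lumbar + cervical). It is computed per animal and then averaged across
#' animals with its SEM; regions whose total is zero in an animal are
#' undefined for that animal and excluded from the average. The brain-wide
#' index is computed from each animal's brain-wide channel totals and then
#' averaged (per-region averaging of indices is available via
#' `brainwide = "regions"`).
#'
#' @param counts a `region_counts` table containing channels `"lumbar"`
#'   and `"cervical"` for each animal.
#' @param brainwide `"totals"` (default) or `"regions"`: whether the
#'   brain-wide value averages each animal's total-count index or the
#'   per-region indices.
#' @return list with `per_animal` (animal x region index with numerator
#'   and denominator), `per_region` (mean, SEM, n across animals) and
#'   `brainwide` (mean, SEM across animals).
#' @export
lumbar_projection_index <- function(counts,
                                    brainwide = c("totals", "regions")) {
  brainwide <- match.arg(brainwide)
  chs <- unique(counts$channel)
  if (!all(c("lumbar", "cervical") %in% chs))
    stop("counts must contain both 'lumbar' and 'cervical' channels")
  lum <- .sum_counts(counts[counts$channel == "lumbar", ])
  cer <- .sum_counts(counts[counts$channel == "cervical", ])
  m <- merge(lum, cer, by = c("animal_id", "region"), all = TRUE,
             suffixes = c("_lumbar", "_cervical"))
  m$count_lumbar[is.na(m$count_lumbar)] <- 0L
  m$count_cervical[is.na(m$count_cervical)] <- 0L
  m$denominator <- m$count_lumbar + m$count_cervical
  m$value <- ifelse(m$denominator > 0, m$count_lumbar / m$denominator,
                    NA_real_)
  m$undefined <- m$denominator == 0
  names(m)[names(m) == "count_lumbar"] <- "numerator"
  per_animal <- m[, c("animal_id", "region", "numerator", "count_cervical",
                      "denominator", "value", "undefined")]
  names(per_animal)[4] <- "cervical"
  per_region <- do.call(rbind, lapply(split(per_animal, per_animal$region),
    function(d) {
      v <- d$value[!d$undefined]
      data.frame(region = d$region[1], n_animals = length(v),
                 mean = if (length(v)) mean(v) else NA_real_,
                 sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v))
                       else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  rownames(per_region) <- NULL
  bw_vals <- if (brainwide == "totals") {
    tot <- do.call(rbind, lapply(split(per_animal, per_animal$animal_id),
      function(d) data.frame(
        value = sum(d$numerator) / max(1, sum(d$denominator)))))
    tot$value
  } else {
    sapply(split(per_animal, per_animal$animal_id),
           function(d) mean(d$value[!d$undefined]))
  }
  bw <- data.frame(mode = brainwide, n_animals = length(bw_vals),
                   mean = mean(bw_vals),
                   sem = stats::sd(bw_vals) / sqrt(length(bw_vals)))
  list(per_animal = per_animal, per_region = per_region, brainwide = bw)
}

#' Sparing index after spinal injury
#'
#' Expresses each injured animal's per-region count as a percentage of the
#' mean count in an uninjured reference cohort (reference mean set to
#' 100%). The brain-wide sparing of an animal is its total count as a
#' percentage of the mean reference total. Regions with a zero reference
#' mean, and regions on the exclusion list (by default the deep cerebellar
#' nuclei, whose detection is unreliable in ventrally imaged light-sheet
#' data), are flagged and omitted from brain-wide values.
#'
#' @param injured a `region_counts` table for the injured animals (single
#'   channel).
#' @param reference a `region_counts` table for >= 2 uninjured animals at
#'   the same injection level.
#' @param exclude character vector of region names to exclude
#'   (default `"DCN"`).
#' @return list of class `sparing_table` with `per_animal` (animal x
#'   region sparing %, count, reference mean, `excluded` flag),
#'   `reference_means`, `brainwide` (per-animal brain-wide sparing %) and
#'   `per_region` (group mean/SEM of sparing %).
#' @export
sparing_index <- function(injured, reference, exclude = "DCN") {
  ref_an <- unique(reference$animal_id)
  if (length(ref_an) < 2)
    stop("reference cohort must contain at least 2 animals")
  ref <- .sum_counts(reference)
  ref_mean <- stats::aggregate(count ~ region, data = ref, FUN = mean)
  names(ref_mean)[2] <- "reference_mean"
  inj <- .sum_counts(injured)
  m <- merge(inj, ref_mean, by = "region", all.x = TRUE)
  m$reference_mean[is.na(m$reference_mean)] <- 0
  m$excluded <- m$region %in% exclude | m$reference_mean == 0
  m$sparing_pct <- ifelse(m$excluded, NA_real_,
                          100 * m$count / m$reference_mean)
  per_animal <- m[order(m$animal_id, m$region),
                  c("animal_id", "region", "count", "reference_mean",
                    "sparing_pct", "excluded")]
  rownames(per_animal) <- NULL
  keep <- !per_animal$excluded
  ref_tot <- mean(tapply(ref$count[!(ref$region %in% exclude)],
                         ref$animal_id[!(ref$region %in% exclude)], sum))
  bw <- do.call(rbind, lapply(split(per_animal[keep, ],
                                    per_animal$animal_id[keep]),
    function(d) data.frame(animal_id = d$animal_id[1],
                           total = sum(d$count),
                           sparing_pct = 100 * sum(d$count) / ref_tot,
                           stringsAsFactors = FALSE)))
  rownames(bw) <- NULL
  pr <- do.call(rbind, lapply(split(per_animal[keep, ],
                                    per_animal$region[keep]),
    function(d) data.frame(region = d$region[1], n_animals = nrow(d),
                           mean_sparing_pct = mean(d$sparing_pct),
                           sem = stats::sd(d$sparing_pct) / sqrt(nrow(d)),
                           stringsAsFactors = FALSE)))
  rownames(pr) <- NULL
  structure(list(per_animal = per_animal, reference_means = ref_mean,
                 brainwide = bw, per_region = pr, exclude = exclude),
            class = "sparing_table")
}

#' Brain-wide count summary
#'
#' Per-animal totals, per-region means with SEM and range across animals,
#' and the number of detected regions (regions with at least `min_count`
#' nuclei in at least one animal).
#'
#' @param counts a `region_counts` table (leaf or reporting level).
#' @param min_count detection threshold per region (default 1).
#' @return list with `per_animal` (totals), `per_region` (mean, SEM, min,
#'   max), `total` (mean, SEM, range of totals) and `n_detected_regions`.
#' @export
brainwide_summary <- function(counts, min_count = 1) {
  per_an <- .sum_counts(counts, by = "animal_id")
  names(per_an)[2] <- "total"
  ar <- .sum_counts(counts, by = c("animal_id", "region"))
  pr <- do.call(rbind, lapply(split(ar, ar$region), function(d)
    data.frame(region = d$region[1], mean = mean(d$count),
               sem = if (nrow(d) > 1) stats::sd(d$count) / sqrt(nrow(d))
                     else NA_real_,
               min = min(d$count), max = max(d$count),
               stringsAsFactors = FALSE)))
  rownames(pr) <- NULL
  n_det <- sum(pr$max >= min_count)
  list(per_animal = per_an,
       per_region = pr,
       total = data.frame(mean = mean(per_an$total),
                          sem = if (nrow(per_an) > 1)
                            stats::sd(per_an$total) / sqrt(nrow(per_an))
                          else NA_real_,
                          min = min(per_an$total), max = max(per_an$total)),
       n_detected_regions = n_det)
}

# 8-connected component labels of a logical matrix (small images; BFS)
.label8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  offs <- cbind(rep(-1:1, times = 3), rep(-1:1, each = 3))
  offs <- offs[!(offs[, 1] == 0 & offs[, 2] == 0), ]
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[length(queue)]
      queue <- queue[-length(queue)]
      pr <- ((p - 1L) %% nr) + 1L
      pc <- ((p - 1L) %/% nr) + 1L
      rr <- pr + offs[, 1]; cc <- pc + offs[, 2]
      ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
      q <- (cc[ok] - 1L) * nr + rr[ok]
      q <- q[mask[q] & lab[q] == 0L]
      if (length(q)) {
        lab[q] <- cur
        queue <- c(queue, q)
      }
    }
  }
  lab
}

#' GFAP bridge fraction across a lesion
#'
#' Quantifies the width of astrocytic (GFAP-positive) tissue bridges that
#' span a lesion band, normalized to the width of the spinal cord. The
#' image is binarized at `gfap_threshold`; within the lesion band,
#' 8-connected components of GFAP-positive pixels are labeled, and a
#' column counts as bridged when a component touching both edges of the
#' band passes through it. Invariant to intensity rescaling on either side
#' of the threshold.
#'
#' @param section a `gfap_section` (see [simulate_gfap_section()]) or a
#'   numeric matrix (rows x columns).
#' @param lesion_band inclusive row interval of the lesion (taken from the
#'   section object when omitted).
#' @param gfap_threshold binarization threshold.
#' @param cord_columns columns spanned by the cord (default: all columns).
#' @return list with `fraction_pct`, `n_bridge_columns`, `cord_width` and
#'   `bridge_columns`.
#' @export
bridge_fraction <- function(section, lesion_band = NULL,
                            gfap_threshold = 0.5, cord_columns = NULL) {
  img <- if (inherits(section, "gfap_section")) section$image else section
  if (is.null(lesion_band) && inherits(section, "gfap_section"))
    lesion_band <- section$lesion_band
  if (is.null(lesion_band)) stop("lesion_band is required")
  if (lesion_band[1] < 1 || lesion_band[2] > nrow(img) ||
      lesion_band[1] > lesion_band[2])
    stop("lesion band outside the image")
  if (is.null(cord_columns)) cord_columns <- seq_len(ncol(img))
  if (!length(cord_columns)) stop("empty cord mask")
  band <- img[lesion_band[1]:lesion_band[2], cord_columns, drop = FALSE] >=
    gfap_threshold
  lab <- .label8(band)
  spanning <- intersect(lab[1, ], lab[nrow(lab), ])
  spanning <- spanning[spanning > 0]
  bridge_cols <- if (length(spanning))
    which(apply(lab, 2, function(col) any(col %in% spanning))) else integer(0)
  list(fraction_pct = 100 * length(bridge_cols) / length(cord_columns),
       n_bridge_columns = length(bridge_cols),
       cord_width = length(cord_columns),
       bridge_columns = cord_columns[bridge_cols])
}
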