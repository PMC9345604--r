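#' Split animals into high-performing and impaired groups by locomotor score
#'
#' Three-way partition of a cohort on the 0-9 open-field locomotor scale:
#' animals at or above `high_threshold` regained consistent plantar
#' stepping, animals at or below `impaired_threshold` show no or
#' infrequent stepping, and animals in between are excluded from the
#' two-group comparison.
#'
#' @param metadata data.frame with columns `animal_id` and `bms`.
#' @param high_threshold,impaired_threshold score cutoffs (defaults 5 and
#'   3.5).
#' @return data.frame with columns `animal_id`, `bms`, `group` (factor
#'   `"high"`, `"impaired"`, `"intermediate"`).
#' @export
split_by_bms <- function(metadata, high_threshold = 5,
                         impaired_threshold = 3.5) {
  stopifnot(all(c("animal_id", "bms") %in% names(metadata)))
  b <- metadata$bms
  if (any(!is.na(b) & (b < 0 | b > 9)))
    stop("BMS scores must lie in [0, 9]")
  grp <- ifelse(b >= high_threshold, "high",
                ifelse(b <= impaired_threshold, "impaired", "intermediate"))
  data.frame(animal_id = metadata$animal_id, bms = b,
             group = factor(grp, levels = c("high", "impaired",
                                            "intermediate")),
             stringsAsFactors = FALSE)
}

#' Screen regions for sparing differences between outcome groups
#'
#' Per-region two-sample comparison (Welch t test) of spared counts
#' between impaired and high-performing animals, with the significance
#' threshold adjusted for multiple comparisons by Bonferroni's rule
#' (alpha / m, where m counts only the regions actually tested). Also
#' reports the group-separation gap, the minimum high-performing value
#' minus the maximum impaired value, which is positive exactly when the
#' two groups' values do not overlap.
#'
#' @param sparing data.frame with columns `animal_id`, `region` and a
#'   value column (`sparing_pct` or `count`), e.g. the `per_animal`
#'   element of [sparing_index()].
#' @param groups data.frame from [split_by_bms()] (or any table with
#'   `animal_id` and `group` in `"high"`/`"impaired"`).
#' @param alpha family-wise significance level.
#' @param value name of the value column (default: `sparing_pct` if
#'   present, else `count`).
#' @return data.frame of class `group_comparison` with per-region group
#'   means, difference, gap, t, df, p and `significant` flag; attributes
#'   `m`, `alpha`, `threshold` and `skipped` (regions with < 2 animals in
#'   a group).
#' @export
screen_regions <- function(sparing, groups, alpha = 0.05, value = NULL) {
  if (is.null(value))
    value <- if ("sparing_pct" %in% names(sparing)) "sparing_pct" else "count"
  g <- groups[groups$group %in% c("high", "impaired"), ]
  d <- merge(sparing, g[, c("animal_id", "group")], by = "animal_id")
  if ("excluded" %in% names(d)) d <- d[!d$excluded, ]
  d <- d[order(d$region, d$animal_id), ]
  rows <- list(); skipped <- character(0)
  for (reg in sort(unique(d$region))) {
    di <- d[d$region == reg, ]
    hi <- di[[value]][di$group == "high"]
    im <- di[[value]][di$group == "impaired"]
    if (length(hi) < 2 || length(im) < 2) {
      skipped <- c(skipped, reg)
      next
    }
    degenerate <- stats::var(hi) == 0 && stats::var(im) == 0
    if (degenerate && mean(hi) == mean(im)) {
      tt <- list(statistic = NA_real_, parameter = NA_real_, p.value = 1)
    } else if (degenerate) {
      tt <- list(statistic = Inf, parameter = NA_real_, p.value = 0)
    } else {
      tt <- stats::t.test(hi, im)
    }
    rows[[as.character(reg)]] <- data.frame(
      region = reg, n_high = length(hi), n_impaired = length(im),
      mean_high = mean(hi), mean_impaired = mean(im),
      difference = mean(hi) - mean(im),
      gap = min(hi) - max(im),
      t = unname(tt$statistic), df = unname(tt$parameter),
      p = tt$p.value, stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no region had >= 2 animals in both groups")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  m <- nrow(out)
  thr <- alpha / m
  out$significant <- out$p < thr
  structure(out, m = m, alpha = alpha, threshold = thr, skipped = skipped,
            class = c("group_comparison", "data.frame"))
}

.sidak <- function(p, k) pmin(1, 1 - (1 - p)^k)

#' ANOVA with Sidak-adjusted post-hoc pairwise comparisons
#'
#' One-way (`value ~ condition`) or two-way (`value ~ region * condition`)
#' analysis of variance, followed by pairwise condition comparisons using
#' the pooled residual variance; pairwise p values are Sidak-adjusted,
#' `p_adj = 1 - (1 - p)^k` with `k` the number of comparisons. In the
#' two-way design the conditions are compared within each region and `k`
#' counts all region-wise pairs.
#'
#' @param data data.frame with a numeric `value` column, a `condition`
#'   column and (for the two-way design) a `region` column.
#' @param design `"one-way"` or `"two-way"`.
#' @return list with `anova` (the F table as a data.frame, with a
#'   `degenerate` flag when the residual variance is zero) and `posthoc`
#'   (pairwise comparisons with raw and Sidak-adjusted p values).
#' @export
anova_posthoc <- function(data, design = c("one-way", "two-way")) {
  design <- match.arg(design)
  stopifnot(all(c("value", "condition") %in% names(data)))
  data$condition <- factor(data$condition)
  if (design == "two-way") {
    stopifnot("region" %in% names(data))
    data$region <- factor(data$region)
    cells <- table(data$region, data$condition)
    bad <- which(cells < 2, arr.ind = TRUE)
    if (nrow(bad))
      stop("cell with fewer than 2 observations: region '",
           rownames(cells)[bad[1, 1]], "' x condition '",
           colnames(cells)[bad[1, 2]], "'")
    fit <- stats::aov(value ~ region * condition, data = data)
  } else {
    if (any(table(data$condition) < 2))
      stop("each condition needs >= 2 observations")
    fit <- stats::aov(value ~ condition, data = data)
  }
  atab <- as.data.frame(summary(fit)[[1]])
  atab$term <- trimws(rownames(atab))
  rownames(atab) <- NULL
  names(atab) <- c("df", "sum_sq", "mean_sq", "F", "p", "term")
  atab <- atab[, c("term", "df", "sum_sq", "mean_sq", "F", "p")]
  mse <- atab$mean_sq[atab$term == "Residuals"]
  df_res <- atab$df[atab$term == "Residuals"]
  # zero residual variance up to floating-point noise
  degenerate <- !is.finite(mse) ||
    mse <= 1e-12 * max(mean(data$value^2), .Machine$double.eps)
  atab$degenerate <- degenerate

  pair_t <- function(d1, d2, label, within = NA_character_) {
    n1 <- length(d1); n2 <- length(d2)
    diff <- mean(d1) - mean(d2)
    if (degenerate) {
      t <- if (diff == 0) NA_real_ else Inf
      p <- if (diff == 0) 1 else 0
    } else {
      se <- sqrt(mse * (1 / n1 + 1 / n2))
      t <- diff / se
      p <- 2 * stats::pt(-abs(t), df_res)
    }
    data.frame(region = within, comparison = label, difference = diff,
               t = t, df = df_res, p = p, stringsAsFactors = FALSE)
  }
  lv <- levels(data$condition)
  combs <- utils::combn(lv, 2, simplify = FALSE)
  rows <- list()
  if (design == "one-way") {
    for (cb in combs)
      rows[[length(rows) + 1L]] <- pair_t(
        data$value[data$condition == cb[1]],
        data$value[data$condition == cb[2]],
        paste(cb[1], "vs", cb[2]))
  } else {
    for (reg in levels(data$region)) for (cb in combs) {
      dr <- data[data$region == reg, ]
      rows[[length(rows) + 1L]] <- pair_t(
        dr$value[dr$condition == cb[1]],
        dr$value[dr$condition == cb[2]],
        paste(cb[1], "vs", cb[2]), within = reg)
    }
  }
  ph <- do.call(rbind, rows)
  ph$p_sidak <- .sidak(ph$p, nrow(ph))
  list(anova = atab, posthoc = ph)
}

#' Association between regional sparing and locomotor score
#'
#' Per-region Spearman rank correlation between sparing and the final
#' behavior score, with the per-animal scatter data returned for export.
#'
#' @param sparing data.frame with `animal_id`, `region` and a value column
#'   (`sparing_pct` or `count`).
#' @param metadata data.frame with `animal_id` and `bms`.
#' @param value value column name (default as in [screen_regions()]).
#' @return list with `correlations` (region, n, rho, p, `undefined` flag
#'   for constant vectors) and `scatter` (animal, region, value, bms).
#' @export
sparing_bms_association <- function(sparing, metadata, value = NULL) {
  if (is.null(value))
    value <- if ("sparing_pct" %in% names(sparing)) "sparing_pct" else "count"
  d <- merge(sparing, metadata[, c("animal_id", "bms")], by = "animal_id")
  if ("excluded" %in% names(d)) d <- d[!d$excluded, ]
  if (length(unique(d$animal_id)) < 3)
    stop("need at least 3 animals")
  cors <- do.call(rbind, lapply(split(d, d$region), function(di) {
    v <- di[[value]]
    und <- stats::sd(v) == 0 || stats::sd(di$bms) == 0 || nrow(di) < 3
    if (!und) {
      ct <- suppressWarnings(
        stats::cor.test(v, di$bms, method = "spearman", exact = FALSE))
      data.frame(region = di$region[1], n = nrow(di),
                 rho = unname(ct$estimate), p = ct$p.value,
                 undefined = FALSE, stringsAsFactors = FALSE)
    } else {
      data.frame(region = di$region[1], n = nrow(di), rho = NA_real_,
                 p = NA_real_, undefined = TRUE, stringsAsFactors = FALSE)
    }
  }))
  rownames(cors) <- NULL
  scatter <- d[, c("animal_id", "region", value, "bms")]
  list(correlations = cors, scatter = scatter)
}
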