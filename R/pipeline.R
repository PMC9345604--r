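#' Pipeline configuration
#'
#' Bundles everything an end-to-end run needs. In synthetic mode a toy
#' atlas and cohort are generated from `design`; in files mode the
#' ontology, annotation volume, point files and metadata are read from
#' `paths`.
#'
#' @param mode `"synthetic"` or `"files"`.
#' @param design a [cohort_design()] (synthetic mode; defaults to
#'   [default_cohort_design()] seeded with `seed`).
#' @param paths named list for files mode: `ontology` (JSON), `volume`
#'   (TIFF + sidecar), `points` (data.frame with columns `path`,
#'   `animal_id`, `channel`, optional `format`), `metadata` (CSV with
#'   `animal_id`, `condition`, `severity`, `bms`).
#' @param analyses character subset of `c("index", "coloc", "sparing",
#'   "screen")`.
#' @param level ontology level for count tables.
#' @param match a [match_params()].
#' @param alpha screening significance level.
#' @param exclude regions excluded from sparing summaries.
#' @param bms_high,bms_impaired thresholds for [split_by_bms()].
#' @param retain_fractions dropout-curve retention grid.
#' @param seed integer seed (required in synthetic mode).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("synthetic", "files"),
                            design = NULL, paths = list(),
                            analyses = c("index", "coloc", "sparing",
                                         "screen"),
                            level = "region69",
                            match = match_params(),
                            alpha = 0.05, exclude = "DCN",
                            bms_high = 5, bms_impaired = 3.5,
                            retain_fractions = c(1, 0.8, 0.6, 0.4, 0.2),
                            seed = 1L) {
  mode <- match.arg(mode)
  analyses <- match.arg(analyses, several.ok = TRUE)
  if (mode == "synthetic") {
    if (is.null(seed)) stop("synthetic mode requires a seed")
    if (is.null(design)) design <- default_cohort_design(seed = seed)
  } else {
    need <- c("ontology", "volume", "points", "metadata")
    miss <- setdiff(need, names(paths))
    if (length(miss))
      stop("files mode lacks path(s): ", paste(miss, collapse = ", "))
    for (p in c(paths$ontology, paths$volume, paths$metadata,
                paths$points$path))
      if (!file.exists(p)) stop("configured path does not exist: ", p)
  }
  structure(list(mode = mode, design = design, paths = paths,
                 analyses = analyses, level = level, match = match,
                 alpha = alpha, exclude = exclude, bms_high = bms_high,
                 bms_impaired = bms_impaired,
                 retain_fractions = retain_fractions,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

.log_stage <- function(verbose, ...) if (verbose) message("[supracount] ", ...)

#' Run the end-to-end quantification pipeline
#'
#' Executes load/generate, region assignment, counting and the requested
#' analyses in order, logging per-stage point tallies. With a fixed
#' configuration and seed the report is identical between runs. When
#' `out_dir` is given the tables are written as CSV and the summary as
#' JSON, with the configuration echoed into the report.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @param verbose log stage progress via `message()`.
#' @return list of class `run_report` with elements `config_echo`,
#'   `counts` (region counts at the configured level), `summary`
#'   (brain-wide summary of the uninjured lumbar channel) and, per
#'   requested analysis, `index`, `coloc` (colabel + contrast + dropout),
#'   `sparing`, `screening`.
#' @export
run_pipeline <- function(config, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (config$mode == "synthetic") {
    .log_stage(verbose, "generating synthetic cohort (seed ",
               config$design$seed, ")")
    n_reg <- nrow(config$design$regions)
    # volume sized so that nucleus densities stay realistically sparse
    # (well below one neighbour per 4 um matching radius)
    atlas <- build_toy_atlas(n_reg,
                             shape = c(80, 80, max(80, 8L * n_reg + 2L)),
                             voxel_size_um = 25,
                             acronyms = config$design$regions$acronym)
    cohort <- simulate_cohort(config$design, atlas)
    ontology <- atlas$ontology
    volume <- atlas$volume
    metadata <- cohort$metadata
    pointsets <- list()
    for (aid in names(cohort$animals))
      for (ch in names(cohort$animals[[aid]])) {
        ps <- cohort$animals[[aid]][[ch]]
        ps$animal_id <- rep(aid, nrow(ps))
        ps$channel <- rep(ch, nrow(ps))
        attr(ps, "animal_id") <- aid; attr(ps, "channel") <- ch
        pointsets[[paste(aid, ch, sep = "/")]] <- ps
      }
  } else {
    .log_stage(verbose, "loading inputs")
    ontology <- load_ontology(config$paths$ontology)
    volume <- read_volume(config$paths$volume)
    metadata <- utils::read.csv(config$paths$metadata,
                                stringsAsFactors = FALSE)
    pt <- config$paths$points
    pointsets <- list()
    for (i in seq_len(nrow(pt))) {
      ps <- read_points(pt$path[i],
                        format = if (!is.null(pt$format))
                          pt$format[i] else "auto",
                        animal_id = pt$animal_id[i], channel = pt$channel[i])
      ps$animal_id <- rep(pt$animal_id[i], nrow(ps))
      ps$channel <- rep(pt$channel[i], nrow(ps))
      attr(ps, "animal_id") <- pt$animal_id[i]
      attr(ps, "channel") <- pt$channel[i]
      pointsets[[paste(pt$animal_id[i], pt$channel[i], sep = "/")]] <- ps
    }
  }

  .log_stage(verbose, "assigning ", sum(vapply(pointsets, nrow, 1L)),
             " points to regions")
  assigned <- lapply(pointsets, function(ps) {
    # region column from a generator is ground truth; assignment is always
    # recomputed from the annotation volume
    ps$region <- NULL
    assign_points(ps, volume)
  })
  counts <- count_by_region(assigned, ontology, level = config$level)
  fl <- attr(counts, "flagged")
  .log_stage(verbose, "counted: ", sum(counts$count), " assigned, ",
             sum(fl$unassigned), " unassigned, ", sum(fl$out_of_bounds),
             " out of bounds")

  uninj <- metadata$animal_id[metadata$condition == "uninjured"]
  report <- list(config_echo = config, metadata = metadata, counts = counts)
  lum_uninj <- counts[counts$channel == "lumbar" &
                        counts$animal_id %in% uninj, ]
  if (nrow(lum_uninj))
    report$summary <- brainwide_summary(lum_uninj)

  if ("index" %in% config$analyses) {
    idx_an <- metadata$animal_id[metadata$condition %in% "uninjured"]
    sub <- counts[counts$animal_id %in% idx_an, ]
    if (all(c("lumbar", "cervical") %in% unique(sub$channel))) {
      .log_stage(verbose, "lumbar-projection index")
      report$index <- lumbar_projection_index(sub)
    }
  }
  if ("coloc" %in% config$analyses) {
    .log_stage(verbose, "dual-label colocalization")
    coloc <- list()
    for (aid in intersect(names_by_condition(metadata,
                                             c("uninjured", "coinjected")),
                          sub_names(assigned))) {
      lum <- assigned[[paste(aid, "lumbar", sep = "/")]]
      cer <- assigned[[paste(aid, "cervical", sep = "/")]]
      if (is.null(lum) || is.null(cer)) next
      lum$region_name <- collapse_regions(ontology,
                                          ifelse(lum$region > 0,
                                                 lum$region, NA),
                                          config$level)
      lum2 <- lum; lum2$region <- lum2$region_name
      m <- match_dual(lum, cer, config$match)
      coin <- metadata$condition[metadata$animal_id == aid] == "coinjected"
      coloc[[aid]] <- list(
        match_n_pairs = nrow(m$pairs),
        colabel = colabel_rate(m, lum2),
        contrast = intensity_contrast(m, lum, cer, coinjected = coin),
        dropout = if (!coin)
          dropout_curve(lum, cer, config$match,
                        config$retain_fractions))
    }
    report$coloc <- coloc
  }
  if ("sparing" %in% config$analyses && length(uninj) >= 2) {
    inj <- metadata$animal_id[!(metadata$condition %in%
                                  c("uninjured", "coinjected"))]
    if (length(inj)) {
      .log_stage(verbose, "sparing index for ", length(inj),
                 " injured animals")
      report$sparing <- sparing_index(
        counts[counts$channel == "lumbar" & counts$animal_id %in% inj, ],
        counts[counts$channel == "lumbar" & counts$animal_id %in% uninj, ],
        exclude = config$exclude)
    }
  }
  if ("screen" %in% config$analyses && !is.null(report$sparing) &&
      !all(is.na(metadata$bms))) {
    inj_meta <- metadata[!(metadata$condition %in%
                             c("uninjured", "coinjected")), ]
    groups <- split_by_bms(inj_meta, config$bms_high, config$bms_impaired)
    if (sum(groups$group == "high") >= 2 &&
        sum(groups$group == "impaired") >= 2) {
      .log_stage(verbose, "screening regions (",
                 sum(groups$group == "high"), " high vs ",
                 sum(groups$group == "impaired"), " impaired)")
      report$screening <- screen_regions(report$sparing$per_animal, groups,
                                         alpha = config$alpha)
      report$association <- sparing_bms_association(
        report$sparing$per_animal, inj_meta)
    }
  }

  if (!is.null(out_dir)) .write_report(report, out_dir)
  structure(report, class = "run_report")
}

names_by_condition <- function(metadata, conditions)
  metadata$animal_id[metadata$condition %in% conditions]

sub_names <- function(assigned)
  unique(sub("/.*$", "", names(assigned)))

.write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_counts(report$counts, file.path(out_dir, "counts.csv"))
  if (!is.null(report$index)) {
    utils::write.csv(report$index$per_region,
                     file.path(out_dir, "index_per_region.csv"),
                     row.names = FALSE)
    utils::write.csv(report$index$per_animal,
                     file.path(out_dir, "index_per_animal.csv"),
                     row.names = FALSE)
  }
  if (!is.null(report$sparing)) {
    utils::write.csv(report$sparing$per_animal,
                     file.path(out_dir, "sparing_per_animal.csv"),
                     row.names = FALSE)
    utils::write.csv(report$sparing$per_region,
                     file.path(out_dir, "sparing_per_region.csv"),
                     row.names = FALSE)
  }
  if (!is.null(report$screening))
    utils::write.csv(as.data.frame(report$screening),
                     file.path(out_dir, "screening.csv"), row.names = FALSE)
  summ <- list(
    n_animals = nrow(report$metadata),
    total_counts = sum(report$counts$count),
    brainwide_index_pct = if (!is.null(report$index))
      100 * report$index$brainwide$mean else NULL,
    brainwide_sparing = if (!is.null(report$sparing))
      stats::aggregate(sparing_pct ~ animal_id, report$sparing$brainwide,
                       mean) else NULL,
    screening_threshold = if (!is.null(report$screening))
      attr(report$screening, "threshold") else NULL,
    config = .config_as_list(report$config_echo))
  jsonlite::write_json(summ, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(out_dir)
}

.config_as_list <- function(config) {
  cfg <- unclass(config)
  cfg$design <- if (!is.null(cfg$design)) {
    d <- unclass(cfg$design)
    d$arms <- d$arms; d
  } else NULL
  cfg$match <- unclass(cfg$match)
  cfg
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report:", nrow(x$metadata), "animals;",
      "analyses:", paste(intersect(c("index", "coloc", "sparing",
                                     "screening", "association"),
                                   names(x)), collapse = ", "), "\n")
  invisible(x)
}
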