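# Shared fixture builders. All synthetic inputs are generated in code at
# test time; sizes are kept small enough for the whole suite to run in a
# few minutes on one core.

small_atlas <- function(n = 4, shape = c(40, 40, 40), voxel = 25, ...) {
  build_toy_atlas(n, shape = shape, voxel_size_um = voxel, ...)
}

small_design <- function(n = 4, mean_count = c(200, 100, 150, 50),
                         dual = c(0.5, 0.2, 0.4, 0.1),
                         cervical = c(300, 200, 100, 80),
                         sparing = 0.4, n_uninjured = 3, n_injured = 3,
                         seed = 7, ...) {
  cohort_design(
    regions = data.frame(id = seq_len(n), mean_count = mean_count[seq_len(n)],
                         dual_probability = dual[seq_len(n)],
                         cervical_mean_count = cervical[seq_len(n)]),
    severity_sparing = list(
      moderate = stats::setNames(rep(sparing, n), seq_len(n))),
    behavior_link = list(region_ids = 1L, weights = 1, noise_sd = 0.5),
    arms = data.frame(condition = c("uninjured", "moderate"),
                      severity = c("none", "moderate"),
                      n_animals = c(n_uninjured, n_injured)),
    seed = seed, ...)
}

# assigned pointsets for every animal/channel of a cohort
assign_cohort <- function(cohort, atlas) {
  out <- list()
  for (aid in names(cohort$animals))
    for (ch in names(cohort$animals[[aid]])) {
      ps <- cohort$animals[[aid]][[ch]]
      ps$region <- NULL
      ps <- assign_points(ps, atlas$volume)
      attr(ps, "animal_id") <- aid
      attr(ps, "channel") <- ch
      out[[paste(aid, ch, sep = "/")]] <- ps
    }
  out
}

# long count data.frame built by hand (for metric unit tests)
counts_df <- function(...) {
  d <- data.frame(..., stringsAsFactors = FALSE)
  if (is.null(d$hemisphere)) d$hemisphere <- "left"
  structure(d, level = "region69",
            class = c("region_counts", "data.frame"))
}

toy_ontology_json <- function(path) {
  doc <- list(
    list(id = 999, acronym = "root", name = "toy brain",
         parent_structure_id = NULL),
    list(id = 101, acronym = "S1", name = "summary 1",
         parent_structure_id = 999),
    list(id = 102, acronym = "S2", name = "summary 2",
         parent_structure_id = 999),
    list(id = 1, acronym = "R1", name = "leaf 1", parent_structure_id = 101),
    list(id = 2, acronym = "R2", name = "leaf 2", parent_structure_id = 101),
    list(id = 3, acronym = "R3", name = "leaf 3", parent_structure_id = 102),
    list(id = 4, acronym = "R4", name = "leaf 4", parent_structure_id = 102))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, null = "null")
  path
}
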