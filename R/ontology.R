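#' Region ontology
#'
#' A validated hierarchical brain-region graph together with the two collapse
#' maps used for reporting: leaf regions are first rolled up into reporting
#' regions (the "69-region" level of an Allen-style analysis) and reporting
#' regions are then grouped into a small set of summary categories (the
#' "25-category" level, e.g. the spinal, medial and lateral vestibular nuclei
#' collapsed into a single vestibular category).
#'
#' @param regions data.frame with columns `id` (integer annotation label),
#'   `acronym`, `name`, `parent_id` (integer or `NA` for the root) and,
#'   optionally, `level` (computed from parent depth when absent).
#' @param collapse_69 named character vector: leaf region id (as character)
#'   -> reporting-region name.
#' @param collapse_25 named character vector: reporting-region name ->
#'   summary-category name. Must cover every value of `collapse_69`.
#' @return An object of class `region_ontology`: a list with elements
#'   `regions`, `collapse_69`, `collapse_25` and `leaves` (integer ids of
#'   leaf regions).
#' @export
region_ontology <- function(regions, collapse_69, collapse_25) {
  stopifnot(is.data.frame(regions))
  need <- c("id", "acronym", "name", "parent_id")
  miss <- setdiff(need, names(regions))
  if (length(miss))
    stop("ontology regions table lacks column(s): ", paste(miss, collapse = ", "))
  regions$id <- as.integer(regions$id)
  regions$parent_id <- as.integer(regions$parent_id)
  dup <- regions$id[duplicated(regions$id)]
  if (length(dup))
    stop("duplicate region id: ", paste(unique(dup), collapse = ", "))
  if (any(regions$id == 0L))
    stop("region id 0 is reserved for outside-brain voxels")
  known <- regions$id
  dangling <- setdiff(stats::na.omit(regions$parent_id), known)
  if (length(dangling))
    stop("dangling parent id: ", paste(dangling, collapse = ", "))
  .check_acyclic(regions)
  if (!("level" %in% names(regions)))
    regions$level <- .region_depth(regions)
  leaves <- setdiff(regions$id, regions$parent_id)

  collapse_69 <- .as_named_chr(collapse_69, "collapse_69")
  collapse_25 <- .as_named_chr(collapse_25, "collapse_25")
  bad <- setdiff(as.integer(names(collapse_69)), known)
  if (length(bad))
    stop("collapse_69 refers to unknown region id: ", paste(bad, collapse = ", "))
  not_total <- setdiff(leaves, as.integer(names(collapse_69)))
  if (length(not_total))
    stop("collapse_69 is not total: leaf id ", paste(not_total, collapse = ", "),
         " unassigned")
  orphan <- setdiff(unname(collapse_69), names(collapse_25))
  if (length(orphan))
    stop("collapse_25 is not total: reporting region ",
         paste(unique(orphan), collapse = ", "), " unassigned")

  structure(
    list(regions = regions, collapse_69 = collapse_69,
         collapse_25 = collapse_25, leaves = sort(leaves)),
    class = "region_ontology")
}

.as_named_chr <- function(x, what) {
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop(what, " must be a fully named character vector")
  stats::setNames(as.character(x), names(x))
}

.check_acyclic <- function(regions) {
  parent <- stats::setNames(regions$parent_id, as.character(regions$id))
  for (id in regions$id) {
    seen <- character(0)
    cur <- id
    while (!is.na(cur)) {
      key <- as.character(cur)
      if (key %in% seen)
        stop("parent links form a cycle at region id ", cur)
      seen <- c(seen, key)
      cur <- parent[[key]]
      if (is.null(cur)) cur <- NA_integer_
    }
  }
  invisible(TRUE)
}

.region_depth <- function(regions) {
  parent <- stats::setNames(regions$parent_id, as.character(regions$id))
  vapply(regions$id, function(id) {
    d <- 0L
    cur <- parent[[as.character(id)]]
    while (!is.null(cur) && !is.na(cur)) {
      d <- d + 1L
      cur <- parent[[as.character(cur)]]
    }
    d
  }, integer(1))
}

#' Load a region ontology from an Allen-style structure-graph JSON document
#'
#' Accepts either a flat array of records (fields `id`, `acronym`, `name`,
#' `parent_structure_id`) or the nested `msg` tree dialect in which each
#' record carries a `children` array. Collapse maps are built from an
#' explicit grouping table when given; otherwise a default is derived from
#' the hierarchy itself (each leaf is its own reporting region, grouped
#' under its parent's acronym as summary category).
#'
#' @param path path to a JSON document (or an already-parsed list).
#' @param grouping optional data.frame with columns `leaf_id`, `region69`,
#'   `summary25` overriding the derived collapse maps. A template for the
#'   Allen atlas case ships in `inst/extdata/allen_summary_template.csv`.
#' @return A [region_ontology()].
#' @export
load_ontology <- function(path, grouping = NULL) {
  doc <- if (is.character(path)) jsonlite::read_json(path) else path
  if (!is.null(doc$msg)) doc <- doc$msg
  recs <- .flatten_structures(doc)
  regions <- do.call(rbind, lapply(recs, function(r) {
    data.frame(id = as.integer(r$id),
               acronym = as.character(r$acronym %||% paste0("id", r$id)),
               name = as.character(r$name %||% r$acronym %||% ""),
               parent_id = as.integer(r$parent_structure_id %||%
                                        r$parent_id %||% NA),
               stringsAsFactors = FALSE)
  }))
  # leaves: ids that are never a parent
  leaves <- setdiff(regions$id, regions$parent_id)
  if (is.null(grouping)) {
    acr <- stats::setNames(regions$acronym, as.character(regions$id))
    c69 <- stats::setNames(acr[as.character(leaves)], as.character(leaves))
    parent <- stats::setNames(regions$parent_id, as.character(regions$id))
    summ <- vapply(leaves, function(id) {
      p <- parent[[as.character(id)]]
      if (is.na(p)) acr[[as.character(id)]] else acr[[as.character(p)]]
    }, character(1))
    c25 <- stats::setNames(summ, unname(c69))
  } else {
    need <- c("leaf_id", "region69", "summary25")
    if (!all(need %in% names(grouping)))
      stop("grouping table needs columns: ", paste(need, collapse = ", "))
    c69 <- stats::setNames(as.character(grouping$region69),
                           as.character(grouping$leaf_id))
    u <- !duplicated(grouping$region69)
    c25 <- stats::setNames(as.character(grouping$summary25[u]),
                           as.character(grouping$region69[u]))
    conf <- tapply(grouping$summary25, grouping$region69,
                   function(x) length(unique(x)))
    if (any(conf > 1))
      stop("reporting region mapped to more than one summary category: ",
           paste(names(conf)[conf > 1], collapse = ", "))
  }
  region_ontology(regions, c69, c25)
}

.flatten_structures <- function(doc) {
  out <- list()
  walk <- function(node, parent = NULL) {
    rec <- node
    kids <- rec$children
    rec$children <- NULL
    if (is.null(rec$parent_structure_id) && is.null(rec$parent_id))
      rec$parent_structure_id <- parent
    out[[length(out) + 1L]] <<- rec
    for (k in kids) walk(k, rec$id)
  }
  for (node in doc) walk(node)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.region_ontology <- function(x, ...) {
  cat("region_ontology:", nrow(x$regions), "regions,",
      length(x$leaves), "leaves,",
      length(unique(x$collapse_69)), "reporting regions,",
      length(unique(x$collapse_25)), "summary categories\n")
  invisible(x)
}

#' Map leaf region ids to names at a collapse level
#'
#' @param ontology a [region_ontology()].
#' @param leaf_ids integer vector of leaf region ids.
#' @param level one of `"leaf"`, `"region69"`, `"summary25"`.
#' @return character vector of region names at the requested level.
#' @export
collapse_regions <- function(ontology, leaf_ids,
                             level = c("leaf", "region69", "summary25")) {
  level <- match.arg(level)
  key <- as.character(leaf_ids)
  if (level == "leaf") {
    acr <- stats::setNames(ontology$regions$acronym,
                           as.character(ontology$regions$id))
    out <- acr[key]
  } else {
    r69 <- ontology$collapse_69[key]
    out <- if (level == "region69") r69 else ontology$collapse_25[r69]
  }
  unname(out)
}
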