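#' Region policy for expected / non-expected labeling
#'
#' The policy names the anatomical regions whose activation counts as
#' expected (language-eloquent cortex) or non-expected (non-task-related
#' areas), plus the minimum cluster size in voxels. Region matching is
#' case-insensitive exact match after normalizing hyphens and whitespace,
#' so "Post-Central Gyrus" and "postcentral gyrus" are the same entry.
#'
#' @param expected,non_expected character vectors of region names; must
#'   be disjoint.
#' @param min_cluster_voxels minimum total voxel count; smaller clusters
#'   are filtered out. Default 5.
#' @return An object of class `region_policy`.
#' @export
region_policy <- function(expected, non_expected, min_cluster_voxels = 5L) {
  e <- normalize_region(expected)
  ne <- normalize_region(non_expected)
  if (length(intersect(e, ne)))
    stop("expected and non-expected region sets overlap: ",
         paste(intersect(e, ne), collapse = ", "), call. = FALSE)
  structure(list(expected = e, non_expected = ne,
                 min_cluster_voxels = as.integer(min_cluster_voxels)),
            class = "region_policy")
}

normalize_region <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("-", "", x, fixed = TRUE)
  gsub("[[:space:]]+", " ", x)
}

#' Default region policy for the sentence-completion language task
#'
#' Expected regions are the classical language areas (Broca: Brodmann 44
#' and 45; Wernicke: Brodmann 22; inferior and middle frontal gyri;
#' superior temporal gyrus). Non-expected regions are common
#' non-task-related sites (cerebellum, sub-gyral white matter, insula,
#' postcentral, supramarginal and superior frontal gyri). The vocabulary
#' is configurable via [region_policy()]; these defaults are a seed, not
#' an exhaustive atlas.
#'
#' @param min_cluster_voxels minimum cluster size; default 5.
#' @return A `region_policy`.
#' @export
default_region_policy <- function(min_cluster_voxels = 5L) {
  region_policy(
    expected = c("brodmann area 44", "brodmann area 45", "brodmann area 22",
                 "inferior frontal gyrus", "middle frontal gyrus",
                 "superior temporal gyrus"),
    non_expected = c("cerebellum", "sub-gyral", "insula",
                     "postcentral gyrus", "supramarginal gyrus",
                     "superior frontal gyrus"),
    min_cluster_voxels = min_cluster_voxels)
}

#' Label one activation cluster from its anatomical report
#'
#' The report lists, per anatomical region the cluster touches, the
#' number of voxels and the maximum Z-score (an xjView-style cluster
#' summary). Rules: clusters below the minimum size are filtered out;
#' if all recognized regions fall in one class, that class wins; if the
#' cluster spans both classes, the class of the entry with the highest
#' max Z wins; an exact Z tie across classes is not adjudicated and the
#' cluster is flagged for manual review. Regions in neither set are
#' ignored for the decision but reported.
#'
#' @param report data.frame with columns `region`, `voxels`, `max_z`
#'   (one row per anatomical region of the cluster).
#' @param policy a [region_policy()].
#' @return A list with `label` ("E", "NE" or NA), `status` ("ok",
#'   "filtered", "unlabelable"), `reason` and `ignored_regions`.
#' @export
label_cluster <- function(report, policy = default_region_policy()) {
  stopifnot(inherits(policy, "region_policy"))
  need <- c("region", "voxels", "max_z")
  miss <- setdiff(need, names(report))
  if (length(miss))
    stop("cluster report is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!nrow(report)) stop("cluster report has no entries", call. = FALSE)
  if (any(report$voxels <= 0)) stop("voxel counts must be positive", call. = FALSE)

  if (sum(report$voxels) < policy$min_cluster_voxels)
    return(list(label = NA_character_, status = "filtered",
                reason = sprintf("cluster size %d < minimum %d",
                                 sum(report$voxels), policy$min_cluster_voxels),
                ignored_regions = character(0)))

  reg <- normalize_region(report$region)
  cls <- ifelse(reg %in% policy$expected, "E",
                ifelse(reg %in% policy$non_expected, "NE", NA))
  ignored <- unique(report$region[is.na(cls)])
  known <- !is.na(cls)
  if (!any(known))
    return(list(label = NA_character_, status = "unlabelable",
                reason = "no region in the policy vocabulary; flag for manual review",
                ignored_regions = ignored))

  classes <- unique(cls[known])
  if (length(classes) == 1L)
    return(list(label = classes, status = "ok", reason = "single-class regions",
                ignored_regions = ignored))

  z <- report$max_z[known]
  top <- which(z == max(z))
  top_classes <- unique(cls[known][top])
  if (length(top_classes) > 1L)
    return(list(label = NA_character_, status = "unlabelable",
                reason = "Z-score tie across classes; flag for manual review",
                ignored_regions = ignored))
  list(label = top_classes, status = "ok",
       reason = "mixed-class cluster resolved by higher Z-score",
       ignored_regions = ignored)
}

#' Label many clusters from a long-format report table
#'
#' @param reports data.frame with columns `roi_id`, `region`, `voxels`,
#'   `max_z` (several rows per ROI).
#' @param policy a [region_policy()].
#' @return data.frame with one row per ROI: `roi_id`, `label`, `status`.
#' @export
label_clusters <- function(reports, policy = default_region_policy()) {
  ids <- unique(reports$roi_id)
  rows <- lapply(ids, function(id) {
    r <- label_cluster(reports[reports$roi_id == id, , drop = FALSE], policy)
    data.frame(roi_id = id, label = r$label, status = r$status,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Class counts and prevalence
#'
#' @param labels character vector of "E"/"NE" labels.
#' @return A list with `n_e`, `n_ne`, `prevalence_e_pct`,
#'   `prevalence_ne_pct`.
#' @export
summarize_labels <- function(labels) {
  labels <- labels[!is.na(labels)]
  if (!length(labels)) stop("no labels to summarize", call. = FALSE)
  n_e <- sum(labels == "E")
  n_ne <- sum(labels == "NE")
  n <- n_e + n_ne
  list(n_e = n_e, n_ne = n_ne,
       prevalence_e_pct = 100 * n_e / n,
       prevalence_ne_pct = 100 * n_ne / n)
}
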