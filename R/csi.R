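#' Compute connection strength indices (CSI)
#'
#' The CSI of a region, for one tracing case, is the number of rabies-labeled
#' presynaptic neurons assigned to that region divided by the number of
#' starter neurons at the injection site. Normalizing by starter count makes
#' cases with different injection sizes (pressure vs iontophoretic delivery)
#' directly comparable, so they can be pooled.
#'
#' Counts are summed over layers within a (case, region, hemisphere) cell
#' before normalization; laminar resolution is handled separately by
#' [laminar_distribution()]. Cases flagged `excluded` in the starter table
#' are dropped (with a message); ontology-excluded regions never enter.
#'
#' @param counts A validated count table ([read_count_table()]).
#' @param starters A validated starter table ([read_starter_table()]).
#' @param ontology Optional `region_ontology` used to check labels and drop
#'   excluded regions.
#' @return A `csi_table` tibble with columns `case_id`, `region`,
#'   `hemisphere`, `csi`, `count`, `n_starters`. `csi * n_starters == count`
#'   exactly.
#' @export
#' @examples
#' starters <- tibble::tibble(case_id = "c1", target_segment = "proximal",
#'                            method = "pressure", n_starters = 126L)
#' counts <- tibble::tibble(case_id = "c1", region = "CA3a",
#'                          hemisphere = "ipsilateral", layer = NA, count = 504L)
#' compute_csi(counts, starters)  # CSI = 4
compute_csi <- function(counts, starters, ontology = NULL) {
  starters <- validate_starter_table(starters)
  counts <- validate_count_table(counts, ontology)
  if (!is.null(ontology)) {
    included <- ontology$region[ontology$include]
    counts <- counts[counts$region %in% included, , drop = FALSE]
  }
  excl <- starters$case_id[starters$excluded]
  if (length(excl)) {
    message("dropping ", length(excl), " excluded case(s): ",
            paste(excl, collapse = ", "))
    counts <- counts[!(counts$case_id %in% excl), , drop = FALSE]
    starters <- starters[!starters$excluded, , drop = FALSE]
  }
  orphan <- setdiff(unique(counts$case_id), starters$case_id)
  if (length(orphan))
    stop("count rows reference case(s) with no starter row: ",
         paste(orphan, collapse = ", "))
  agg <- counts |>
    dplyr::group_by(.data$case_id, .data$region, .data$hemisphere) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop")
  out <- agg |>
    dplyr::left_join(starters[, c("case_id", "n_starters")], by = "case_id") |>
    dplyr::mutate(csi = .data$count / .data$n_starters) |>
    dplyr::select("case_id", "region", "hemisphere", "csi", "count",
                  "n_starters")
  class(out) <- c("csi_table", class(out))
  out
}

#' Summarize CSI gradients across target segments
#'
#' Aggregates per-case CSI values into cross-case mean, standard error and
#' case count for every (region, hemisphere, target segment) cell, the
#' layout used to compare input strength along the proximal-distal axis.
#' Pressure and iontophoretic cases are pooled by default (all values are
#' starter-normalized); set `by_method = TRUE` for stratified output.
#'
#' @param csi A `csi_table` from [compute_csi()].
#' @param starters The starter table (source of each case's target segment
#'   and method).
#' @param by_method If `TRUE`, summaries are additionally stratified by
#'   delivery method.
#' @return A `gradient_summary` tibble with columns `segment`, `region`,
#'   `hemisphere`, `mean_csi`, `se`, `n` (SE = sample SD / sqrt(n), n-1
#'   denominator; SE = 0 for n = 1).
#' @export
summarize_gradient <- function(csi, starters, by_method = FALSE) {
  starters <- validate_starter_table(starters)
  joined <- dplyr::left_join(
    csi, starters[, c("case_id", "target_segment", "method")], by = "case_id")
  if (anyNA(joined$target_segment))
    stop("CSI rows with no matching starter case: ",
         paste(unique(joined$case_id[is.na(joined$target_segment)]),
               collapse = ", "))
  keys <- c("target_segment", "region", "hemisphere",
            if (by_method) "method")
  out <- joined |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      mean_csi = mean(.data$csi),
      se = if (dplyr::n() > 1) sd(.data$csi) / sqrt(dplyr::n()) else 0,
      n = dplyr::n(),
      .groups = "drop") |>
    dplyr::rename(segment = "target_segment") |>
    dplyr::mutate(segment = factor(.data$segment, levels = SEGMENT_LEVELS)) |>
    dplyr::arrange(.data$segment, .data$hemisphere, .data$region)
  class(out) <- c("gradient_summary", class(out))
  out
}

#' Per-case summed CSI over a region group
#'
#' Grouped quantities such as "all ipsilateral CA3 input" are computed by
#' summing a case's CSIs over the member regions first, then averaging
#' across cases — the natural behaviour for a per-case normalized ratio.
#'
#' @param csi A `csi_table`.
#' @param starters Starter table.
#' @param regions Character vector of member region labels.
#' @param hemisphere Optional hemisphere filter
#'   (`"ipsilateral"`/`"contralateral"`; `NULL` = both).
#' @return A `gradient_summary` with one row per segment: mean, SE and n of
#'   the per-case summed CSI. The region column is a `+`-joined label.
#' @export
summarize_region_group <- function(csi, starters, regions, hemisphere = NULL) {
  sel <- csi$region %in% regions
  if (!is.null(hemisphere)) sel <- sel & csi$hemisphere %in% hemisphere
  if (!any(sel)) stop("no CSI rows match the requested region group")
  starters <- validate_starter_table(starters)
  per_case <- csi[sel, ] |>
    dplyr::group_by(.data$case_id) |>
    dplyr::summarise(csi = sum(.data$csi), .groups = "drop") |>
    dplyr::left_join(starters[, c("case_id", "target_segment")], by = "case_id")
  out <- per_case |>
    dplyr::group_by(.data$target_segment) |>
    dplyr::summarise(
      mean_csi = mean(.data$csi),
      se = if (dplyr::n() > 1) sd(.data$csi) / sqrt(dplyr::n()) else 0,
      n = dplyr::n(),
      .groups = "drop") |>
    dplyr::rename(segment = "target_segment") |>
    dplyr::mutate(region = paste(regions, collapse = "+"),
                  hemisphere = if (is.null(hemisphere)) "both"
                               else paste(hemisphere, collapse = "+"),
                  segment = factor(.data$segment, levels = SEGMENT_LEVELS)) |>
    dplyr::select("segment", "region", "hemisphere", "mean_csi", "se", "n")
  class(out) <- c("gradient_summary", class(out))
  out
}

resolve_cell_sum <- function(summary, spec) {
  stopifnot(is.list(spec), !is.null(spec$regions))
  sel <- summary$region %in% spec$regions
  if (!is.null(spec$hemisphere)) sel <- sel & summary$hemisphere %in% spec$hemisphere
  if (!is.null(spec$segment)) sel <- sel & summary$segment %in% spec$segment
  if (!any(sel)) stop("fold_ratio spec matches no summary rows")
  sum(summary$mean_csi[sel])
}

#' Fold ratio between two sets of summary cells
#'
#' Compares summed mean CSIs between two selections of the gradient summary
#' (e.g. all CA3 input to proximal CA1 vs the same to distal CA1). Each spec
#' is a list with `regions` (required), and optional `hemisphere` and
#' `segment` filters; the selected cells' mean CSIs are summed.
#'
#' @param summary A `gradient_summary` (computed, or the reference means).
#' @param numerator,denominator Cell-selection specs (see above).
#' @return A list with `ratio`, `percent_difference`
#'   (`100 * (num - den) / den`), and the two sums.
#' @export
#' @examples
#' m <- ca1_reference_means()
#' ca3 <- c("CA3a", "CA3b", "CA3c")
#' fold_ratio(m, list(regions = ca3, segment = "proximal"),
#'               list(regions = ca3, segment = "distal"))$ratio  # ~3.2
fold_ratio <- function(summary, numerator, denominator) {
  num <- resolve_cell_sum(summary, numerator)
  den <- resolve_cell_sum(summary, denominator)
  if (den <= 0)
    stop("denominator cells sum to ", den,
         "; a fold ratio needs a strictly positive denominator")
  if (num <= 0)
    stop("numerator cells sum to ", num, "; must be strictly positive")
  list(ratio = num / den,
       percent_difference = 100 * (num - den) / den,
       numerator_sum = num,
       denominator_sum = den)
}

#' Classify a region's gradient along the proximal-distal axis
#'
#' @param summary A `gradient_summary`.
#' @param region Region label.
#' @param hemisphere Hemisphere of the profile (default ipsilateral).
#' @return `"increasing"`, `"decreasing"` or `"non-monotonic"` by strict
#'   comparison of the proximal, intermediate and distal means; ties are
#'   non-monotonic (with a message).
#' @export
gradient_direction <- function(summary, region, hemisphere = "ipsilateral") {
  sel <- summary$region == region & summary$hemisphere == hemisphere
  prof <- summary[sel, ]
  m <- setNames(rep(NA_real_, 3L), SEGMENT_LEVELS)
  m[as.character(prof$segment)] <- prof$mean_csi
  if (anyNA(m))
    stop("region ", region, " (", hemisphere, "): missing segment mean(s): ",
         paste(names(m)[is.na(m)], collapse = ", "))
  if (m[1] < m[2] && m[2] < m[3]) return("increasing")
  if (m[1] > m[2] && m[2] > m[3]) return("decreasing")
  if (m[1] == m[2] || m[2] == m[3])
    message("region ", region, ": tied segment means; classified non-monotonic")
  "non-monotonic"
}

#' Laminar distribution of labeled cells within a region
#'
#' For a laminar-resolved region (e.g. the subiculum, where back-projecting
#' cells concentrate in the pyramidal cell layer), computes the percentage
#' of each case's labeled cells per layer, and the cross-case mean and SE.
#'
#' @param counts A validated count table with layer annotations for `region`.
#' @param region Region label.
#' @param hemisphere Hemisphere filter (default ipsilateral).
#' @return A list with `per_case` (tibble case_id x layer x percent) and
#'   `summary` (layer, mean_percent, se, n). Per-case percentages sum to 100;
#'   cases with zero total count are excluded from averaging.
#' @export
laminar_distribution <- function(counts, region, hemisphere = "ipsilateral") {
  counts <- validate_count_table(counts)
  rows <- counts[counts$region == region & counts$hemisphere == hemisphere, ]
  if (nrow(rows) == 0) stop("no count rows for region ", region)
  if (anyNA(rows$layer))
    stop("region ", region, " has rows without layer annotation; ",
         "a laminar query needs layer-resolved counts")
  per_case <- rows |>
    dplyr::group_by(.data$case_id) |>
    dplyr::mutate(total = sum(.data$count)) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$total > 0) |>
    dplyr::mutate(percent = 100 * .data$count / .data$total) |>
    dplyr::select("case_id", "layer", "percent")
  if (nrow(per_case) == 0) stop("all cases have zero total count in ", region)
  summary <- per_case |>
    dplyr::group_by(.data$layer) |>
    dplyr::summarise(
      mean_percent = mean(.data$percent),
      se = if (dplyr::n() > 1) sd(.data$percent) / sqrt(dplyr::n()) else 0,
      n = dplyr::n(),
      .groups = "drop")
  list(per_case = per_case, summary = summary)
}
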