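#' Read a brain-region ontology
#'
#' The ontology maps region labels to anatomical groups and controls which
#' regions may enter summaries. It is data, not code: new parcellations need
#' only a new JSON file. Each entry of the JSON `regions` array has fields
#' `label`, `group`, `hemispheres` (subset of ipsilateral/contralateral),
#' `layers` (possibly empty) and `include` (regions with `include = false`,
#' e.g. local ipsilateral CA1 where primary and trans-synaptic rabies
#' infection cannot be told apart, are dropped from all quantification).
#'
#' @param path Path to a JSON ontology file. Defaults to the parcellation
#'   shipped with the package, which covers the canonical (CA3a-c ipsi- and
#'   contralateral, MEC, LEC) and noncanonical (subiculum, pre/parasubiculum,
#'   contralateral CA1, median raphe, MS-DB) input sources to CA1.
#' @return A tibble of class `region_ontology` with columns `region`,
#'   `group`, `hemispheres` (list), `layers` (list), `include`.
#' @export
#' @examples
#' onto <- read_region_ontology()
#' onto$region
read_region_ontology <- function(path = ca1_ontology_path()) {
  raw <- jsonlite::read_json(path)
  if (is.null(raw$regions)) stop("ontology file has no 'regions' array: ", path)
  rows <- lapply(raw$regions, function(r) {
    if (is.null(r$label) || is.null(r$group))
      stop("ontology region entry missing 'label' or 'group'")
    tibble::tibble(
      region = r$label,
      group = r$group,
      hemispheres = list(unlist(r$hemispheres) %na% "ipsilateral"),
      layers = list(unlist(r$layers) %na% character(0)),
      include = isTRUE(r$include %||% TRUE)
    )
  })
  onto <- dplyr::bind_rows(rows)
  if (anyDuplicated(onto$region))
    stop("duplicate region labels in ontology: ",
         paste(unique(onto$region[duplicated(onto$region)]), collapse = ", "))
  bad_hemi <- setdiff(unlist(onto$hemispheres), HEMISPHERE_LEVELS)
  if (length(bad_hemi))
    stop("unknown hemisphere in ontology: ", paste(bad_hemi, collapse = ", "))
  class(onto) <- c("region_ontology", class(onto))
  onto
}

#' Path to the default CA1-input region ontology
#' @return File path of the JSON ontology installed with the package.
#' @export
ca1_ontology_path <- function() {
  system.file("extdata", "region_ontology.json", package = "ca1circuit",
              mustWork = TRUE)
}

#' Check count-table region labels against an ontology
#'
#' @param counts A labeled-cell count table (see [read_count_table()]).
#' @param ontology A `region_ontology`.
#' @return Invisibly, `counts` restricted to included regions. Unknown
#'   region labels are an error listing the offending rows.
#' @export
validate_regions <- function(counts, ontology) {
  unknown <- !(counts$region %in% ontology$region)
  if (any(unknown)) {
    rows <- head(which(unknown), 10L)
    stop("unknown region label(s) not in ontology: ",
         paste(unique(counts$region[unknown]), collapse = ", "),
         " (rows ", paste(rows, collapse = ", "), ")")
  }
  included <- ontology$region[ontology$include]
  invisible(counts[counts$region %in% included, , drop = FALSE])
}
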