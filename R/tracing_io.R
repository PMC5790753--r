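# Tabular IO for tracing data. CSV (comma, UTF-8, "." decimal) is the native
# dialect; TSV is accepted by sniffing the header line.

STARTER_COLS <- c("case_id", "target_segment", "method", "n_starters")
COUNT_COLS <- c("case_id", "region", "hemisphere", "layer", "count")

sniff_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

read_delim_quiet <- function(path) {
  readr::read_delim(path, delim = sniff_delim(path), col_types = readr::cols(),
                    show_col_types = FALSE, progress = FALSE)
}

#' Read a starter-injection table
#'
#' One row per tracing case: the targeted CA1 segment, the viral delivery
#' method and the number of starter neurons (GFP+/mCherry+ double-labeled
#' cells) at the injection site. Optional columns `excluded` (logical) and
#' `exclusion_reason` mark cases dropped from quantification (e.g. leak into
#' CA2); an excluded case must carry a nonempty reason.
#'
#' @param path CSV/TSV file with columns `case_id`, `target_segment`
#'   (proximal/intermediate/distal), `method` (pressure/iontophoretic),
#'   `n_starters` (integer >= 1).
#' @return A validated tibble.
#' @export
read_starter_table <- function(path) {
  tab <- read_delim_quiet(path)
  validate_starter_table(tab)
}

#' @rdname read_starter_table
#' @param starters A data frame to validate in place of a file.
#' @export
validate_starter_table <- function(starters) {
  missing_cols <- setdiff(STARTER_COLS, names(starters))
  if (length(missing_cols))
    stop("starter table missing column(s): ", paste(missing_cols, collapse = ", "))
  starters <- tibble::as_tibble(starters)
  if (!"excluded" %in% names(starters)) starters$excluded <- FALSE
  starters$excluded <- as.logical(starters$excluded)
  starters$excluded[is.na(starters$excluded)] <- FALSE
  if (!"exclusion_reason" %in% names(starters))
    starters$exclusion_reason <- NA_character_
  starters$exclusion_reason <- as.character(starters$exclusion_reason)
  if (!is.numeric(starters$n_starters))
    starters$n_starters <- suppressWarnings(as.numeric(starters$n_starters))
  if (anyDuplicated(starters$case_id)) {
    dup <- unique(starters$case_id[duplicated(starters$case_id)])
    stop("duplicate case_id in starter table: ", paste(dup, collapse = ", "))
  }
  bad_seg <- !(starters$target_segment %in% SEGMENT_LEVELS)
  if (any(bad_seg))
    stop("unknown target_segment (rows ",
         paste(head(which(bad_seg), 5L), collapse = ", "), "): ",
         paste(unique(starters$target_segment[bad_seg]), collapse = ", "))
  bad_method <- !(starters$method %in% METHOD_LEVELS)
  if (any(bad_method))
    stop("unknown method (rows ",
         paste(head(which(bad_method), 5L), collapse = ", "), ")")
  n <- starters$n_starters
  if (any(!is.finite(n) | n < 1 | n != round(n)))
    stop("n_starters must be integers >= 1 (rows ",
         paste(head(which(!is.finite(n) | n < 1 | n != round(n)), 5L),
               collapse = ", "), "); a case with zero starter neurons cannot ",
         "be normalized and is rejected at parse time")
  starters$n_starters <- as.integer(n)
  no_reason <- starters$excluded &
    (is.na(starters$exclusion_reason) | !nzchar(starters$exclusion_reason))
  if (any(no_reason))
    stop("excluded case(s) without exclusion_reason: ",
         paste(starters$case_id[no_reason], collapse = ", "))
  starters
}

#' Read a labeled-cell count table
#'
#' One row per case x region x hemisphere (x layer, for laminar-resolved
#' regions): the number of rabies-labeled presynaptic neurons assigned to
#' that anatomical structure.
#'
#' @param path CSV/TSV file with columns `case_id`, `region`, `hemisphere`
#'   (ipsilateral/contralateral), `layer` (may be empty), `count`
#'   (integer >= 0).
#' @param ontology Optional `region_ontology`; if supplied, region labels
#'   are checked against it (unknown labels are an error).
#' @return A validated tibble.
#' @export
read_count_table <- function(path, ontology = NULL) {
  tab <- read_delim_quiet(path)
  validate_count_table(tab, ontology)
}

#' @rdname read_count_table
#' @param counts A data frame to validate in place of a file.
#' @export
validate_count_table <- function(counts, ontology = NULL) {
  missing_cols <- setdiff(setdiff(COUNT_COLS, "layer"), names(counts))
  if (length(missing_cols))
    stop("count table missing column(s): ", paste(missing_cols, collapse = ", "))
  counts <- tibble::as_tibble(counts)
  if (!"layer" %in% names(counts)) counts$layer <- NA_character_
  counts$layer <- as.character(counts$layer)
  counts$layer[!is.na(counts$layer) & !nzchar(counts$layer)] <- NA_character_
  bad_hemi <- !(counts$hemisphere %in% HEMISPHERE_LEVELS)
  if (any(bad_hemi))
    stop("unknown hemisphere (rows ",
         paste(head(which(bad_hemi), 5L), collapse = ", "), ")")
  if (!is.numeric(counts$count))
    counts$count <- suppressWarnings(as.numeric(counts$count))
  bad_layer <- !is.na(counts$layer) & !(counts$layer %in% LAYER_LEVELS)
  if (any(bad_layer))
    stop("unknown layer (rows ",
         paste(head(which(bad_layer), 5L), collapse = ", "), "): ",
         paste(unique(counts$layer[bad_layer]), collapse = ", "))
  if (any(!is.finite(counts$count) | counts$count < 0 |
            counts$count != round(counts$count)))
    stop("count must be nonnegative integers")
  counts$count <- as.integer(counts$count)
  key <- paste(counts$case_id, counts$region, counts$hemisphere, counts$layer,
               sep = "\r")
  if (anyDuplicated(key)) {
    d <- counts[duplicated(key), c("case_id", "region", "hemisphere", "layer")]
    stop("duplicate (case, region, hemisphere, layer) row(s): ",
         paste(apply(head(d, 5L), 1L, paste, collapse = "/"), collapse = "; "))
  }
  if (!is.null(ontology)) validate_regions(counts, ontology)
  counts
}

#' Write tracing tables
#'
#' @param tab A starter or count table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracing_table <- function(tab, path) {
  readr::write_csv(tab, path, progress = FALSE)
  invisible(path)
}

#' Reference mean CSI table for CA1 inputs
#'
#' Cross-case mean connection-strength indices (and their standard errors)
#' for each input source region and each targeted CA1 segment, as measured
#' by monosynaptic rabies tracing. Shipped with the package as the default
#' ground truth for the synthetic tracing generator and as a fixture for
#' gradient arithmetic.
#'
#' @param path CSV with columns `segment`, `region`, `hemisphere`,
#'   `mean_csi`, `se`. Defaults to the installed reference table.
#' @return A tibble usable directly as a `gradient_summary` (with `n = NA`).
#' @export
#' @examples
#' means <- ca1_reference_means()
#' subset(means, region == "SUB")
ca1_reference_means <- function(path = system.file("extdata",
                                                   "ca1_input_means.csv",
                                                   package = "ca1circuit",
                                                   mustWork = TRUE)) {
  tab <- read_delim_quiet(path)
  stopifnot(all(c("segment", "region", "hemisphere", "mean_csi") %in% names(tab)))
  tab$segment <- factor(tab$segment, levels = SEGMENT_LEVELS)
  tab$n <- NA_integer_
  class(tab) <- c("gradient_summary", class(tab))
  tab
}
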