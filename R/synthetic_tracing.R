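#' Configuration for the synthetic rabies-tracing generator
#'
#' Defaults reproduce the study conditions of the quantified dataset:
#' per-segment starter-count means of 126/136/80 (pressure delivery) and
#' 21/27/26 (iontophoretic delivery), 6 pressure plus 4 iontophoretic cases
#' per targeted segment (30 cases total), and true per-region mean CSIs
#' taken from the reference means table ([ca1_reference_means()]). Starter
#' spreads are the published SEs scaled to SDs at the published case counts.
#'
#' @param starter_means Named list `pressure`/`iontophoretic`, each a
#'   length-3 numeric (proximal, intermediate, distal) of mean starter
#'   counts. Must be > 0.
#' @param starter_sds Same shape; SD of the (truncated-at-1, rounded)
#'   normal starter-count draw.
#' @param cases Named list `pressure`/`iontophoretic` of cases per segment.
#'   Must be >= 0 with >= 1 case overall per segment.
#' @param truth Data frame with columns `segment`, `region`, `hemisphere`,
#'   `mean_csi` giving the true CSI per region x segment (>= 0). Defaults
#'   to the reference means.
#' @param laminar_props Named list region -> named numeric of layer
#'   proportions (summing to 1); regions listed here get layer-resolved
#'   counts, split multinomially. Default: subiculum 92/4/4% across
#'   pyramidal cell, polymorphic and molecular layers.
#' @return A `tracing_config` list.
#' @export
tracing_config <- function(
    starter_means = list(pressure = c(126, 136, 80),
                         iontophoretic = c(21, 27, 26)),
    starter_sds = list(pressure = c(42, 78, 34),
                       iontophoretic = c(8, 10, 8)),
    cases = list(pressure = c(6, 6, 6), iontophoretic = c(4, 4, 4)),
    truth = ca1_reference_means(),
    laminar_props = list(
      SUB = c("pyramidal cell layer" = 0.92,
              "polymorphic layer" = 0.04,
              "molecular layer" = 0.04))) {
  for (m in METHOD_LEVELS) {
    mu <- starter_means[[m]]; sdv <- starter_sds[[m]]; nc <- cases[[m]]
    if (length(mu) != 3 || any(!is.finite(mu)) || any(mu <= 0))
      stop("starter_means$", m, " must be 3 finite positive values")
    if (length(sdv) != 3 || any(!is.finite(sdv)) || any(sdv < 0))
      stop("starter_sds$", m, " must be 3 finite nonnegative values")
    if (length(nc) != 3 || any(!is.finite(nc)) || any(nc < 0) ||
        any(nc != round(nc)))
      stop("cases$", m, " must be 3 nonnegative integers")
  }
  total <- cases$pressure + cases$iontophoretic
  if (any(total < 1)) stop("every segment needs at least one case")
  stopifnot(all(c("segment", "region", "hemisphere", "mean_csi") %in%
                  names(truth)))
  if (any(!is.finite(truth$mean_csi)) || any(truth$mean_csi < 0))
    stop("true CSIs must be finite and >= 0")
  for (r in names(laminar_props)) {
    p <- laminar_props[[r]]
    if (abs(sum(p) - 1) > 1e-8 || any(p < 0))
      stop("laminar_props$", r, " must be nonnegative and sum to 1")
  }
  structure(list(starter_means = starter_means, starter_sds = starter_sds,
                 cases = cases, truth = truth,
                 laminar_props = laminar_props),
            class = "tracing_config")
}

#' Generate a synthetic rabies-tracing dataset
#'
#' Draws, for each case, a starter-neuron count (normal around the
#' configured mean, rounded, truncated at 1), then for each region a
#' labeled-cell count as a Poisson variate with mean
#' `trueCSI * starterCount`. Counts are nonnegative integers and the
#' per-case ratio count/starters is an unbiased estimate of the true CSI.
#' Laminar-resolved regions are split multinomially across layers.
#' The output is a pure function of `(config, seed)`.
#'
#' @param config A [tracing_config()].
#' @param seed Integer seed governing all draws.
#' @return A list with validated `starters` and `counts` tables conforming
#'   to the IO schemas.
#' @export
#' @examples
#' d <- generate_tracing_dataset(tracing_config(), seed = 1)
#' head(d$counts)
generate_tracing_dataset <- function(config = tracing_config(), seed = 1L) {
  stopifnot(inherits(config, "tracing_config"))
  set.seed(as.integer(seed))
  starters_rows <- list()
  counts_rows <- list()
  for (si in seq_along(SEGMENT_LEVELS)) {
    seg <- SEGMENT_LEVELS[si]
    truth_seg <- config$truth[config$truth$segment == seg, , drop = FALSE]
    for (m in METHOD_LEVELS) {
      n_cases <- config$cases[[m]][si]
      if (n_cases == 0) next
      for (ci in seq_len(n_cases)) {
        case_id <- sprintf("%s-%s-%02d", substr(seg, 1, 4), substr(m, 1, 4), ci)
        n_start <- max(1L, as.integer(round(
          rnorm(1, config$starter_means[[m]][si], config$starter_sds[[m]][si]))))
        starters_rows[[length(starters_rows) + 1L]] <- tibble::tibble(
          case_id = case_id, target_segment = seg, method = m,
          n_starters = n_start)
        cnt <- rpois(nrow(truth_seg), truth_seg$mean_csi * n_start)
        for (ri in seq_len(nrow(truth_seg))) {
          region <- truth_seg$region[ri]
          hemi <- truth_seg$hemisphere[ri]
          props <- config$laminar_props[[region]]
          if (!is.null(props) && hemi == "ipsilateral") {
            split <- drop(rmultinom(1, cnt[ri], props))
            counts_rows[[length(counts_rows) + 1L]] <- tibble::tibble(
              case_id = case_id, region = region, hemisphere = hemi,
              layer = names(props), count = as.integer(split))
          } else {
            counts_rows[[length(counts_rows) + 1L]] <- tibble::tibble(
              case_id = case_id, region = region, hemisphere = hemi,
              layer = NA_character_, count = as.integer(cnt[ri]))
          }
        }
      }
    }
  }
  starters <- validate_starter_table(dplyr::bind_rows(starters_rows))
  counts <- validate_count_table(dplyr::bind_rows(counts_rows))
  list(starters = starters, counts = counts)
}
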