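# Control-region motif frequency surveys (the substrate of spatial
# frequency maps).

#' Define a haplogroup-diagnostic control-region motif
#'
#' @param label Haplogroup label the motif diagnoses.
#' @param defining Character vector of defining variant tokens.
#' @param parent Label of the parent motif, or `NA`.
#' @return A one-row tibble; rows can be stacked into a motif hierarchy.
#' @export
haplogroup_motif <- function(label, defining, parent = NA_character_) {
  if (length(defining) == 0) stop("motif must have at least one defining variant")
  tibble(label = label,
         defining = list(normalize_variant(defining)),
         parent = parent)
}

#' Survey population profiles for a diagnostic motif
#'
#' Counts, per population, the profiles carrying every defining variant
#' of the motif, and reports the percentage frequency. Motifs whose
#' defining variants include a reversion (e.g. a back-mutation of a
#' common transition) are matchable but flagged low-confidence, since
#' such motifs are unreliable in control-region surveys.
#'
#' @param profiles A [haplotype_table()] of control-region profiles.
#' @param motif A one-row motif tibble ([haplogroup_motif()]).
#' @param populations Optional metadata tibble with columns
#'   `population` and any of `region`, `lat`, `lon`; joined onto the
#'   result.
#' @param exclude_populations Populations flagged for exclusion from
#'   spatial interpolation (outlier handling, e.g. an island isolate
#'   whose extreme frequency would distort the surrounding surface).
#' @return A tibble: `population`, (`region`, `lat`, `lon`,) `n`,
#'   `carriers`, `freq_pct`, `excluded_from_interpolation`,
#'   `low_confidence_motif`.
#' @export
motif_frequency <- function(profiles, motif, populations = NULL,
                            exclude_populations = character(0)) {
  def <- motif$defining[[1]]
  def_pos <- variant_position(def)
  low_conf <- any(grepl("^@", def))

  # every profile must have been sequenced over the motif's positions
  for (rng in unique(profiles$range)) {
    if (!all(position_in_range(def_pos, rng))) {
      stop("motif ", motif$label, " touches positions outside the surveyed range ",
           rng)
    }
  }

  carries <- vapply(profiles$variants, function(v) all(def %in% v), logical(1))
  pops <- sort(unique(profiles$population))
  n <- vapply(pops, function(p) sum(profiles$population == p), integer(1))
  if (any(n == 0)) stop("population with zero profiles")
  k <- vapply(pops, function(p) sum(carries[profiles$population == p]), integer(1))
  out <- tibble(
    population = pops,
    n = unname(n),
    carriers = unname(k),
    freq_pct = unname(100 * k / n),
    excluded_from_interpolation = pops %in% exclude_populations,
    low_confidence_motif = low_conf
  )
  out$region <- vapply(pops, function(p) {
    profiles$region[profiles$population == p][1]
  }, character(1), USE.NAMES = FALSE)
  if (!is.null(populations)) {
    j <- match(out$population, populations$population)
    for (col in intersect(c("region", "lat", "lon"), names(populations))) {
      out[[col]] <- populations[[col]][j]
    }
  }
  out[, c("population", "region",
          intersect(c("lat", "lon"), names(out)),
          "n", "carriers", "freq_pct",
          "excluded_from_interpolation", "low_confidence_motif")]
}

#' Pool motif frequencies by region
#'
#' The regional frequency is the pooled ratio `sum(carriers)/sum(n)`,
#' which always lies between the smallest and largest population
#' frequency of the region.
#'
#' @param freq_table Output of [motif_frequency()].
#' @return A tibble: `region`, `n`, `carriers`, `freq_pct`.
#' @export
regional_rollup <- function(freq_table) {
  if (any(is.na(freq_table$region))) {
    stop("unmapped population(s): ",
         paste(freq_table$population[is.na(freq_table$region)], collapse = ", "))
  }
  regions <- sort(unique(freq_table$region))
  rows <- lapply(regions, function(r) {
    sub <- freq_table[freq_table$region == r, ]
    tibble(region = r, n = sum(sub$n), carriers = sum(sub$carriers),
           freq_pct = 100 * sum(sub$carriers) / sum(sub$n))
  })
  do.call(rbind, rows)
}
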