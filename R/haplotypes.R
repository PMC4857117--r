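#' Default region labels used in phylogeographic partitions
#'
#' The configurable label set for sample regions. Scenario partitions and
#' leaf classifications validate against this set (plus `"unassigned"`).
#'
#' @return Character vector of region labels.
#' @export
mito_regions <- function() {
  c("Arabian Peninsula", "Fertile Crescent", "Iran", "Eastern Africa",
    "Europe", "South Asia", "North Africa", "Caucasus", "unassigned")
}

parse_range <- function(range) {
  parts <- strsplit(range, ";", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^([0-9]+)-([0-9]+)$", trimws(parts)))
  if (any(vapply(m, length, integer(1)) != 3)) {
    stop("malformed range specification: ", range)
  }
  lo <- vapply(m, function(x) as.integer(x[2]), integer(1))
  hi <- vapply(m, function(x) as.integer(x[3]), integer(1))
  if (any(lo < 1L) || any(hi > MT_LENGTH) || any(lo > hi)) {
    stop("range outside 1..", MT_LENGTH, ": ", range)
  }
  cbind(lo = lo, hi = hi)
}

position_in_range <- function(pos, range) {
  iv <- parse_range(range)
  out <- rep(FALSE, length(pos))
  for (k in seq_len(nrow(iv))) out <- out | (pos >= iv[k, 1] & pos <= iv[k, 2])
  out
}

#' Assemble a haplotype table
#'
#' A haplotype table is a tibble with one row per sample: `sample_id`,
#' `population`, `region`, `range` (sequenced interval(s) in np
#' coordinates, e.g. `"1-16569"` for whole molecules or
#' `"16024-16365"` for HVS-I), and `variants`, a list-column of
#' canonical mutation tokens relative to the declared reference.
#'
#' @param sample_id Character vector of unique sample identifiers.
#' @param variants List of character vectors of variant tokens.
#' @param population Character vector of population names.
#' @param region Character vector of region labels (validated against
#'   `regions`).
#' @param range Sequenced range string(s), recycled.
#' @param reference `"rCRS"` or `"RSRS"`; stored as an attribute.
#' @param regions Permitted region label set.
#' @return A tibble of class `haplotype_table` with attribute
#'   `reference`.
#' @export
haplotype_table <- function(sample_id, variants,
                            population = "unknown",
                            region = "unassigned",
                            range = "1-16569",
                            reference = c("rCRS", "RSRS"),
                            regions = mito_regions()) {
  reference <- match.arg(reference)
  n <- length(sample_id)
  if (anyDuplicated(sample_id)) {
    stop("duplicate sample_id(s): ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  }
  stopifnot(length(variants) == n)
  population <- rep_len(as.character(population), n)
  region <- rep_len(as.character(region), n)
  range <- rep_len(as.character(range), n)
  bad_region <- !region %in% regions
  if (any(bad_region)) {
    stop("region label(s) not in the configured set: ",
         paste(unique(region[bad_region]), collapse = ", "))
  }
  # validate and normalize each distinct token once, then map
  all_tok <- unique(unlist(variants, use.names = FALSE))
  if (length(all_tok) > 0) {
    norm <- normalize_variant(all_tok)
    names(norm) <- all_tok
    variants <- lapply(variants, function(v) {
      sort_variants(unname(norm[as.character(v)]))
    })
  } else {
    variants <- lapply(variants, function(v) character(0))
  }
  range_cache <- lapply(unique(range), parse_range)
  names(range_cache) <- unique(range)
  for (i in seq_len(n)) {
    v <- variants[[i]]
    if (length(v) == 0) next
    pos <- variant_position(v)
    key <- paste(pos, sub("^@?[0-9]+\\.([0-9]+).*$", "\\1",
                          ifelse(grepl("\\.", v), v, "0")))
    if (anyDuplicated(key)) {
      stop("sample ", sample_id[i], " carries two variants at the same site")
    }
    iv <- range_cache[[range[i]]]
    inside <- rep(FALSE, length(pos))
    for (k in seq_len(nrow(iv))) inside <- inside | (pos >= iv[k, 1] & pos <= iv[k, 2])
    if (!all(inside)) {
      stop("sample ", sample_id[i], " has variants outside its declared range")
    }
  }
  out <- tibble(
    sample_id = as.character(sample_id),
    population = population,
    region = region,
    range = range,
    variants = variants
  )
  attr(out, "reference") <- reference
  class(out) <- c("haplotype_table", class(out))
  out
}

#' Read and write EMPOP-style variant profile tables
#'
#' The on-disk dialect is a tab-separated table with columns
#' `sample_id`, `population`, `region`, `range` and `variants`
#' (space-separated mutation tokens). Lines starting with `#` are
#' comments; a `# reference=` header records the reference.
#'
#' @param file Path to the TSV file.
#' @param reference Reference assumed when the file has no header.
#' @param regions Permitted region label set.
#' @return For `read_profiles()`, a [haplotype_table()].
#' @export
read_profiles <- function(file, reference = c("rCRS", "RSRS"),
                          regions = mito_regions()) {
  reference <- match.arg(reference)
  header <- readLines(file, n = 5L)
  ref_line <- grep("^#\\s*reference=", header, value = TRUE)
  if (length(ref_line) > 0) {
    reference <- match.arg(trimws(sub("^#\\s*reference=", "", ref_line[1])),
                           c("rCRS", "RSRS"))
  }
  d <- utils::read.delim(file, comment.char = "#", stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("sample_id", "population", "region", "range", "variants")
  if (!all(need %in% names(d))) {
    stop("profile table must have columns: ", paste(need, collapse = ", "))
  }
  vars <- lapply(strsplit(d$variants, "[[:space:]]+"), function(v) v[v != ""])
  haplotype_table(d$sample_id, vars, d$population, d$region, d$range,
                  reference = reference, regions = regions)
}

#' @rdname read_profiles
#' @param haplotypes A [haplotype_table()].
#' @export
write_profiles <- function(haplotypes, file) {
  d <- data.frame(
    sample_id = haplotypes$sample_id,
    population = haplotypes$population,
    region = haplotypes$region,
    range = haplotypes$range,
    variants = vapply(haplotypes$variants, paste, character(1), collapse = " "),
    stringsAsFactors = FALSE
  )
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste0("# reference=", attr(haplotypes, "reference") %||% "rCRS"), con)
  utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rebase haplotype profiles between the rCRS and RSRS references
#'
#' Profiles relative to one reference are converted to the other by
#' symmetric difference with the table of variants separating the two
#' references, restricted to each haplotype's sequenced range.
#' Converting twice returns the original profile. The rCRS/RSRS
#' difference list is configuration, supplied by the caller.
#'
#' @param haplotypes A [haplotype_table()].
#' @param target `"rCRS"` or `"RSRS"`.
#' @param diff_table Character vector of tokens separating the two
#'   references.
#' @return The rebased [haplotype_table()].
#' @export
convert_reference <- function(haplotypes, target = c("rCRS", "RSRS"),
                              diff_table) {
  target <- match.arg(target)
  current <- attr(haplotypes, "reference") %||% "rCRS"
  if (identical(current, target)) return(haplotypes)
  diff_table <- normalize_variant(diff_table)
  diff_pos <- variant_position(diff_table)
  out <- haplotypes
  out$variants <- lapply(seq_len(nrow(haplotypes)), function(i) {
    rng <- haplotypes$range[i]
    d <- diff_table[position_in_range(diff_pos, rng)]
    v <- haplotypes$variants[[i]]
    sort_variants(union(setdiff(v, d), setdiff(d, v)))
  })
  attr(out, "reference") <- target
  out
}
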