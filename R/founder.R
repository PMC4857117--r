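# Founder analysis: identify founder clusters of sink-population
# lineages under the f1/f2 criteria, date them with the linear founder
# clock, and scan migration times on a 200-year grid.

#' Define a source/sink scenario partition
#'
#' A scenario assigns every region label to the source, the sink, or
#' neither (excluded). Palestinian samples are a configurable special
#' case, analysed either with the Arabian populations, with the Fertile
#' Crescent populations, or left unassigned; Iranian lineages can be
#' included in or excluded from the source.
#'
#' @param name Scenario name.
#' @param source,sink Disjoint sets of region labels.
#' @param palestinian_mode `"with_arabia"`, `"with_fertile_crescent"`
#'   or `"unassigned"`.
#' @param include_iran_in_source If `FALSE`, `"Iran"` is removed from
#'   the source set.
#' @param palestinian_populations Population names treated as
#'   Palestinian.
#' @param regions Permitted region label set.
#' @return An object of class `founder_scenario`.
#' @export
founder_scenario <- function(name, source, sink,
                             palestinian_mode = c("unassigned", "with_arabia",
                                                  "with_fertile_crescent"),
                             include_iran_in_source = TRUE,
                             palestinian_populations = "Palestinian",
                             regions = union(mito_regions(), c(source, sink))) {
  palestinian_mode <- match.arg(palestinian_mode)
  source <- as.character(source); sink <- as.character(sink)
  if (length(intersect(source, sink)) > 0) {
    stop("source and sink region sets overlap: ",
         paste(intersect(source, sink), collapse = ", "))
  }
  if (!include_iran_in_source) source <- setdiff(source, "Iran")
  structure(
    list(name = name, source = source, sink = sink,
         palestinian_mode = palestinian_mode,
         include_iran_in_source = include_iran_in_source,
         palestinian_populations = palestinian_populations,
         regions = regions),
    class = "founder_scenario"
  )
}

#' The standard scenario presets
#'
#' The seven configurations of the published migration-time scans:
#' (A) Fertile Crescent + Caucasus + Iran + Arabian Peninsula into
#' Eastern Africa; (B) Fertile Crescent + Caucasus into Arabian
#' Peninsula + Eastern Africa; (C) Fertile Crescent + Caucasus into the
#' Arabian Peninsula; (D) Arabian Peninsula into Fertile Crescent +
#' Iran + Caucasus (reciprocal); (E) Arabian Peninsula into Fertile
#' Crescent + Caucasus (reciprocal, Iran excluded); (F) Fertile
#' Crescent + Iran + North Africa + Arabian Peninsula + Caucasus into
#' South Asia; (G) the same source into Europe.
#'
#' @param palestinian_mode Passed to every preset.
#' @return Named list of [founder_scenario()] objects (`A`..`G`).
#' @export
scenario_presets <- function(palestinian_mode = "unassigned") {
  fc <- "Fertile Crescent"; cau <- "Caucasus"; ir <- "Iran"
  ap <- "Arabian Peninsula"; ea <- "Eastern Africa"; na_ <- "North Africa"
  list(
    A = founder_scenario("A_into_eastern_africa",
                         source = c(fc, cau, ir, ap), sink = ea,
                         palestinian_mode = palestinian_mode),
    B = founder_scenario("B_into_arabia_and_eastern_africa",
                         source = c(fc, cau), sink = c(ap, ea),
                         palestinian_mode = palestinian_mode),
    C = founder_scenario("C_into_arabia",
                         source = c(fc, cau), sink = ap,
                         palestinian_mode = palestinian_mode),
    D = founder_scenario("D_reciprocal_into_fertile_crescent_with_iran",
                         source = ap, sink = c(fc, ir, cau),
                         palestinian_mode = palestinian_mode),
    E = founder_scenario("E_reciprocal_into_fertile_crescent",
                         source = ap, sink = c(fc, cau),
                         palestinian_mode = palestinian_mode),
    F = founder_scenario("F_into_south_asia",
                         source = c(fc, ir, na_, ap, cau), sink = "South Asia",
                         palestinian_mode = palestinian_mode),
    G = founder_scenario("G_into_europe",
                         source = c(fc, cau, ir, na_, ap), sink = "Europe",
                         palestinian_mode = palestinian_mode)
  )
}

#' Classify tree leaves as source, sink or excluded under a scenario
#'
#' @param tree A `mito_tree`.
#' @param haplotypes The [haplotype_table()] mapping leaves to
#'   populations and regions.
#' @param scenario A [founder_scenario()].
#' @return Character vector over nodes: `"source"`, `"sink"`,
#'   `"excluded"` for leaves, `NA` for internal nodes; attribute
#'   `counts` tabulates the classes.
#' @export
partition_leaves <- function(tree, haplotypes, scenario) {
  cls <- rep(NA_character_, n_nodes(tree))
  lv <- tree_leaves(tree)
  idx <- match(tree$sample_id[lv], haplotypes$sample_id)
  if (anyNA(idx)) {
    stop("leaves missing from the haplotype table: ",
         paste(tree$sample_id[lv][is.na(idx)], collapse = ", "))
  }
  region <- haplotypes$region[idx]
  population <- haplotypes$population[idx]
  unknown <- !region %in% scenario$regions
  if (any(unknown)) {
    stop("leaf region(s) not in the configured label set: ",
         paste(unique(region[unknown]), collapse = ", "))
  }
  pal <- population %in% scenario$palestinian_populations
  region[pal] <- switch(scenario$palestinian_mode,
                        with_arabia = "Arabian Peninsula",
                        with_fertile_crescent = "Fertile Crescent",
                        unassigned = "unassigned")
  iran_excluded <- !scenario$include_iran_in_source & region == "Iran" &
    !"Iran" %in% scenario$sink
  cls[lv] <- ifelse(iran_excluded, "excluded",
             ifelse(region %in% scenario$source, "source",
             ifelse(region %in% scenario$sink, "sink", "excluded")))
  attr(cls, "counts") <- table(factor(cls[lv], c("source", "sink", "excluded")))
  cls
}

#' Identify founder clusters under the f1/f2 criteria
#'
#' Every sink leaf walks rootward from its attachment node; the first
#' ancestor possessing at least one (f1) or two (f2) derived branches
#' leading exclusively into source-classed lineages is its founder
#' node. A derived source branch is a child branch carrying at least
#' one mutation whose (non-excluded) descendant leaves are all source —
#' a zero-mutation source tip sitting at the node does not count, which
#' keeps founder matches off the tips of the source phylogeny and
#' guards against homoplasy and back-migration. Sink leaves sharing a
#' founder node form one cluster; leaves with no qualifying ancestor
#' are clustered at the root and flagged.
#'
#' Each cluster is dated with the linear founder clock:
#' `age = rho_f * founder_rate`, where `rho_f` and its Saillard-type
#' error `sigma_f` are computed over the cluster's sink leaves only.
#'
#' @param tree A `mito_tree`.
#' @param partition Leaf classification from [partition_leaves()].
#' @param criterion `"f1"` or `"f2"`.
#' @param clock A [mito_clock()] supplying `founder_rate`.
#' @param count_fn Branch mutation counter.
#' @return A tibble of founder clusters: `founder` (node), `criterion`,
#'   `n_sink`, `n_derived_source_branches`, `rho_f`, `sigma_f`,
#'   `age_years`, `sigma_years`, `at_root`.
#' @export
identify_founders <- function(tree, partition, criterion = c("f1", "f2"),
                              clock = mito_clock(), count_fn = length) {
  criterion <- match.arg(criterion)
  k_needed <- if (criterion == "f1") 1L else 2L
  kids <- tree_children(tree)

  # per node: numbers of source / sink leaves below
  nsrc <- ifelse(!is.na(partition) & partition == "source", 1L, 0L)
  nsnk <- ifelse(!is.na(partition) & partition == "sink", 1L, 0L)
  for (v in rev(preorder(tree))) {
    p <- tree$parent[v]
    if (!is.na(p)) {
      nsrc[p] <- nsrc[p] + nsrc[v]
      nsnk[p] <- nsnk[p] + nsnk[v]
    }
  }

  derived_source_branches <- vapply(seq_len(n_nodes(tree)), function(v) {
    sum(vapply(kids[[v]], function(cc) {
      count_fn(tree$mutations[[cc]]) >= 1L && nsrc[cc] > 0L && nsnk[cc] == 0L
    }, logical(1)))
  }, integer(1))

  sink_leaves <- which(!is.na(partition) & partition == "sink" &
                         !is.na(tree$sample_id))
  if (length(sink_leaves) == 0) {
    return(tibble(founder = integer(0), criterion = character(0),
                  n_sink = integer(0), n_derived_source_branches = integer(0),
                  rho_f = numeric(0), sigma_f = numeric(0),
                  age_years = numeric(0), sigma_years = numeric(0),
                  at_root = logical(0)))
  }

  founder_of <- vapply(sink_leaves, function(lf) {
    v <- tree$parent[lf]
    while (!is.na(v)) {
      if (derived_source_branches[v] >= k_needed) return(v)
      v <- tree$parent[v]
    }
    1L # no qualifying ancestor: the root is the founder (flagged)
  }, integer(1))

  clusters <- split(sink_leaves, founder_of)
  rows <- lapply(names(clusters), function(fk) {
    f <- as.integer(fk)
    members <- clusters[[fk]]
    stats_f <- cluster_rho(tree, f, members, count_fn)
    tibble(
      founder = f, criterion = criterion, n_sink = length(members),
      n_derived_source_branches = derived_source_branches[f],
      rho_f = stats_f$rho, sigma_f = stats_f$sigma,
      age_years = stats_f$rho * clock$founder_rate,
      sigma_years = stats_f$sigma * clock$founder_rate,
      at_root = f == 1L && derived_source_branches[1L] < k_needed
    )
  })
  out <- do.call(rbind, rows)
  out[order(out$founder), , drop = FALSE]
}

# rho and Saillard sigma over a designated leaf set, from node f:
# branches on the paths f -> members; n_b counts member leaves only
cluster_rho <- function(tree, f, members, count_fn = length) {
  n_b <- integer(n_nodes(tree))
  m_cache <- integer(0)
  edges <- integer(0)
  for (lf in members) {
    v <- lf
    while (!is.na(v) && v != f) {
      n_b[v] <- n_b[v] + 1L
      edges <- c(edges, v)
      v <- tree$parent[v]
    }
    if (is.na(v)) stop("leaf ", lf, " is not a descendant of node ", f)
  }
  edges <- unique(edges)
  m_b <- vapply(edges, function(v) as.integer(count_fn(tree$mutations[[v]])),
                integer(1))
  n <- length(members)
  list(rho = sum(m_b * n_b[edges]) / n,
       sigma = sqrt(sum(n_b[edges]^2 * m_b)) / n)
}

#' Scan founder ages over a migration-time grid
#'
#' Distributes each founder cluster's age over equally spaced 200-year
#' intervals from 0 to 50 ka as a normal density truncated at zero
#' (mean `age_years`, sd `sigma_years`; a degenerate sd of zero puts
#' all mass in the bin containing the mean). Clusters are weighted by
#' their number of sink sequences (or equally, if requested) and the
#' total vector is normalized to sum to one.
#'
#' @param clusters Tibble from [identify_founders()].
#' @param grid_max,bin_width Grid extent and spacing in years.
#' @param weighting `"sink_size"` or `"equal"`.
#' @return An object of class `migration_scan`: a tibble with
#'   `bin_start`, `bin_mid`, `mass`, plus attributes `per_cluster`
#'   (matrix) and `criterion`.
#' @export
scan_migrations <- function(clusters, grid_max = 50000, bin_width = 200,
                            weighting = c("sink_size", "equal")) {
  weighting <- match.arg(weighting)
  if (nrow(clusters) == 0) stop("no founder clusters to scan")
  edges <- seq(0, grid_max, by = bin_width)
  nb <- length(edges) - 1L
  w <- if (weighting == "sink_size") clusters$n_sink / sum(clusters$n_sink)
       else rep(1 / nrow(clusters), nrow(clusters))
  per <- matrix(0, nrow = nrow(clusters), ncol = nb)
  for (i in seq_len(nrow(clusters))) {
    mu <- clusters$age_years[i]
    sd <- clusters$sigma_years[i]
    if (sd <= 0) {
      j <- min(nb, max(1L, findInterval(mu, edges, rightmost.closed = FALSE)))
      per[i, j] <- 1
    } else {
      p <- stats::pnorm(edges[-1L], mu, sd) - stats::pnorm(edges[-length(edges)], mu, sd)
      tot <- sum(p)
      if (tot <= 0) { # degenerate: far outside grid; clamp to nearest end
        j <- if (mu <= 0) 1L else nb
        per[i, j] <- 1
      } else {
        per[i, ] <- p / tot
      }
    }
    per[i, ] <- per[i, ] * w[i]
  }
  mass <- colSums(per)
  mass <- mass / sum(mass)
  out <- tibble(bin_start = edges[-length(edges)],
                bin_mid = edges[-length(edges)] + bin_width / 2,
                mass = mass)
  attr(out, "per_cluster") <- per
  attr(out, "criterion") <- unique(clusters$criterion)
  class(out) <- c("migration_scan", class(out))
  out
}

#' @rdname scan_migrations
#' @param scan A `migration_scan`.
#' @return `scan_mode()`: the midpoint (years) of the highest-mass bin.
#' @export
scan_mode <- function(scan) {
  scan$bin_mid[which.max(scan$mass)]
}

#' Run a complete founder analysis scenario
#'
#' Partitions the leaves, identifies and dates founder clusters under
#' both criteria, and produces the migration-time scans.
#'
#' @param tree A `mito_tree`.
#' @param haplotypes The [haplotype_table()].
#' @param scenario A [founder_scenario()].
#' @param clock A [mito_clock()].
#' @param criteria Criteria to run (default both `"f1"` and `"f2"`).
#' @param count_fn Branch mutation counter.
#' @param weighting Passed to [scan_migrations()].
#' @return A list of class `founder_report`: `scenario`, `counts`,
#'   `clusters` (named by criterion), `scans` (named by criterion).
#' @export
run_scenario <- function(tree, haplotypes, scenario, clock = mito_clock(),
                         criteria = c("f1", "f2"), count_fn = length,
                         weighting = "sink_size") {
  partition <- partition_leaves(tree, haplotypes, scenario)
  clusters <- lapply(criteria, function(cr) {
    identify_founders(tree, partition, cr, clock, count_fn)
  })
  names(clusters) <- criteria
  scans <- lapply(clusters, function(cl) {
    if (nrow(cl) == 0) NULL else scan_migrations(cl, weighting = weighting)
  })
  structure(
    list(scenario = scenario, partition = partition,
         counts = attr(partition, "counts"),
         clusters = clusters, scans = scans),
    class = "founder_report"
  )
}

#' @export
print.founder_report <- function(x, ...) {
  cat("founder analysis:", x$scenario$name, "\n")
  cat("  source:", paste(x$scenario$source, collapse = ", "), "\n")
  cat("  sink  :", paste(x$scenario$sink, collapse = ", "), "\n")
  print(x$counts)
  for (cr in names(x$clusters)) {
    cl <- x$clusters[[cr]]
    cat(sprintf("  %s: %d cluster(s)", cr, nrow(cl)))
    if (nrow(cl) > 0 && !is.null(x$scans[[cr]])) {
      cat(sprintf(", scan mode %.1f ka", scan_mode(x$scans[[cr]]) / 1000))
    }
    cat("\n")
  }
  invisible(x)
}
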