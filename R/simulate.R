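# Coalescent simulation of mitogenome haplotypes with known demographic
# truth: a source deme and a sink deme founded from it by a migration
# pulse at a known time, both descending from a small common ancestral
# (refugium) pool. Poisson mutations are dropped on branches under a
# linear or purifying-selection-corrected clock, at positions drawn
# from the molecule outside the conventionally excluded zones, with
# optional recurrent-site hotspots.

#' Simulation configuration
#'
#' Defaults emulate a Late Glacial founder event under the sudden
#' expansion model that star-like mtDNA clades reflect: a sink
#' population founded from the source at `pulse_time` (15 ka) and
#' immediately expanding to a large size, a large source population,
#' and a small shared ancestral (refugium) pool before the pulse, so
#' that in the collapsed haplotype tree the founding haplotype node
#' sits at the pulse and carries many mutationally derived source
#' branches. Effective sizes are coalescent intensity parameters
#' expressed in years (2 N_f times the generation time).
#'
#' @param seed Integer; fully determines the output.
#' @param n_source,n_sink Sample sizes (>= 1).
#' @param pulse_time Migration/founding time in years (>= 0).
#' @param ne_source Source coalescent intensity (years).
#' @param ne_sink Sink intensity between the present and the pulse
#'   (post-expansion size; the founding bottleneck is the ancestral
#'   pool).
#' @param ne_ancestral Intensity of the small shared ancestral
#'   (refugium) pool before the pulse.
#' @param years_per_mutation Linear whole-molecule mutation rate.
#' @param clock_mode `"linear"` (Poisson mean = branch_years /
#'   `years_per_mutation`) or `"corrected"` (mean = difference of the
#'   corrected clock's cumulative divergence at the branch endpoints).
#' @param clock A [mito_clock()] used when `clock_mode = "corrected"`.
#' @param hotspots Optional positions with elevated recurrence.
#' @param hotspot_weight Relative oversampling of hotspot positions.
#' @param source_region,sink_region Region labels given to the samples.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_source = 100L, n_sink = 50L,
                       pulse_time = 15000,
                       ne_source = 5e6, ne_sink = 5e6, ne_ancestral = 2000,
                       years_per_mutation = 3624,
                       clock_mode = c("linear", "corrected"),
                       clock = NULL,
                       hotspots = integer(0), hotspot_weight = 20,
                       source_region = "Fertile Crescent",
                       sink_region = "Arabian Peninsula") {
  clock_mode <- match.arg(clock_mode)
  if (n_source < 1L || n_sink < 1L) stop("sample sizes must be >= 1")
  if (pulse_time < 0) stop("pulse_time must be >= 0")
  stopifnot(ne_source > 0, ne_sink > 0, ne_ancestral > 0,
            years_per_mutation > 0)
  structure(as.list(environment()), class = "sim_config")
}

# excluded zones never receive simulated mutations (they are the sites
# a practitioner would filter anyway)
sim_position_pool <- function(policy = exclusion_policy()) {
  setdiff(seq_len(MT_LENGTH),
          c(policy$excluded_positions, policy$cstretch_zone,
            policy$ac_indel_zone, policy$clade_id_positions,
            16182L, 16183L))
}

# Kingman coalescent within one deme of constant intensity from `t0`
# until `t_end` (Inf for none); returns surviving lineage ids and the
# merge records.
coalesce_deme <- function(lineages, t0, t_end, intensity, next_id) {
  merges <- list()
  t <- t0
  while (length(lineages) > 1L) {
    k <- length(lineages)
    pair_rate <- k * (k - 1) / 2
    t_next <- t + stats::rexp(1) * intensity / pair_rate
    if (t_next > t_end) break
    t <- t_next
    pick <- sample.int(k, 2L)
    merges[[length(merges) + 1L]] <- list(
      id = next_id, time = t, children = lineages[pick]
    )
    lineages <- c(lineages[-pick], next_id)
    next_id <- next_id + 1L
  }
  list(lineages = lineages, merges = merges, next_id = next_id)
}

#' Simulate a mutation-annotated genealogy with a founder pulse
#'
#' Generates the coalescent genealogy of `n_source` source and `n_sink`
#' sink samples under the demographic model of [sim_config()], drops
#' Poisson mutations on its branches, and returns both the collapsed
#' mutation-annotated haplotype tree (zero-mutation coalescent nodes
#' merged into multifurcations) and the full genealogy with node ages,
#' together with the leaf haplotype table and the demographic truth.
#'
#' @param config A [sim_config()].
#' @param collapse Collapse zero-mutation internal branches in the
#'   returned `tree` (the haplotype-tree view used by the analysis
#'   stages).
#' @return A list: `tree` (`mito_tree`), `genealogy` (uncollapsed
#'   `mito_tree` with `ages` attribute), `haplotypes`
#'   ([haplotype_table()]), `truth` (list: `pulse_time`, `tmrca`,
#'   `node_ages`, `config`).
#' @export
simulate_genealogy <- function(config, collapse = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_src <- config$n_source
  n_snk <- config$n_sink
  n_tips <- n_src + n_snk
  Tp <- config$pulse_time

  ids_src <- seq_len(n_src)
  ids_snk <- n_src + seq_len(n_snk)
  ages <- rep(0, n_tips)
  next_id <- n_tips + 1L
  merges <- list()

  # sink deme: constant post-expansion size back to the pulse (sudden
  # expansion at founding; most sink lineages reach the pulse distinct)
  snk <- coalesce_deme(ids_snk, 0, Tp, config$ne_sink, next_id)
  merges <- c(merges, snk$merges)
  next_id <- snk$next_id

  # source deme: constant size until the pulse
  src <- coalesce_deme(ids_src, 0, Tp, config$ne_source, next_id)
  merges <- c(merges, src$merges)
  next_id <- src$next_id

  # shared ancestral pool from the pulse backwards
  pool <- coalesce_deme(c(src$lineages, snk$lineages), Tp, Inf,
                        config$ne_ancestral, next_id)
  merges <- c(merges, pool$merges)

  n_all <- n_tips + length(merges)
  parent <- rep(NA_integer_, n_all)
  ages <- c(ages, rep(NA_real_, n_all - n_tips))
  for (m in merges) {
    ages[m$id] <- m$time
    parent[m$children] <- m$id
  }
  root_old <- which(is.na(parent))
  stopifnot(length(root_old) == 1L)

  # reindex root-first, by decreasing age (parents before children)
  ord <- order(-ages, seq_len(n_all))
  ord <- c(root_old, setdiff(ord, root_old))
  remap <- integer(n_all)
  remap[ord] <- seq_len(n_all)
  new_parent <- rep(NA_integer_, n_all)
  new_parent[remap] <- ifelse(is.na(parent), NA_integer_, remap[parent])
  new_ages <- numeric(n_all)
  new_ages[remap] <- ages
  leaf_id <- rep(NA_character_, n_all)
  leaf_id[remap[ids_src]] <- sprintf("SRC_%03d", seq_len(n_src))
  leaf_id[remap[ids_snk]] <- sprintf("SNK_%03d", seq_len(n_snk))

  # Poisson mutations per branch
  pool_pos <- sim_position_pool()
  used <- logical(MT_LENGTH)
  hot <- as.integer(config$hotspots)
  mutations <- vector("list", n_all)
  mutations[[1L]] <- character(0)
  expected_branch <- function(t_child, t_parent) {
    if (config$clock_mode == "linear") {
      (t_parent - t_child) / config$years_per_mutation
    } else {
      ck <- config$clock %||% mito_clock()
      clock_divergence(ck, t_parent) - clock_divergence(ck, t_child)
    }
  }
  draw_positions <- function(k) {
    avail <- pool_pos[!used[pool_pos]]
    if (length(hot) == 0) {
      pos <- avail[sample.int(length(avail), min(k, length(avail)))]
      used[pos] <<- TRUE
      return(pos)
    }
    w_hot <- config$hotspot_weight * length(hot)
    n_hot <- stats::rbinom(1L, k, w_hot / (w_hot + length(avail)))
    pos <- avail[sample.int(length(avail), min(k - n_hot, length(avail)))]
    used[pos] <<- TRUE
    c(pos, if (n_hot > 0) sample(hot, n_hot, replace = TRUE))
  }
  for (v in seq_len(n_all)[-1L]) {
    lam <- expected_branch(new_ages[v], new_ages[new_parent[v]])
    k <- stats::rpois(1L, lam)
    if (k > 0) {
      pos <- unique(draw_positions(k))
      mutations[[v]] <- as.character(sort(pos))
    } else {
      mutations[[v]] <- character(0)
    }
  }

  genealogy <- structure(
    list(parent = new_parent, mutations = mutations, sample_id = leaf_id,
         label = rep(NA_character_, n_all), root_state = character(0)),
    class = "mito_tree"
  )
  attr(genealogy, "ages") <- new_ages

  states <- node_states(genealogy)
  lv <- tree_leaves(genealogy)
  haps <- haplotype_table(
    sample_id = genealogy$sample_id[lv],
    variants = states[lv],
    population = ifelse(startsWith(genealogy$sample_id[lv], "SRC"),
                        "SourcePop", "SinkPop"),
    region = ifelse(startsWith(genealogy$sample_id[lv], "SRC"),
                    config$source_region, config$sink_region),
    regions = union(mito_regions(), c(config$source_region, config$sink_region))
  )

  tree <- if (collapse) collapse_zero_branches(genealogy) else genealogy
  list(
    tree = tree,
    genealogy = genealogy,
    haplotypes = haps,
    truth = list(pulse_time = Tp, tmrca = max(new_ages),
                 node_ages = new_ages, config = config)
  )
}

#' Simulate a single clade of known age
#'
#' A clade whose most recent common ancestor sits at exactly
#' `age_years`: either a star genealogy or a Kingman coalescent
#' rescaled so the root age equals `age_years`. Used for rho-recovery
#' experiments.
#'
#' @param n Number of leaves.
#' @param age_years True clade age.
#' @param years_per_mutation Linear mutation rate.
#' @param model `"coalescent"` (rescaled) or `"star"`.
#' @param seed Optional seed.
#' @param clock,clock_mode As in [sim_config()].
#' @return A `mito_tree` with `ages` attribute.
#' @export
simulate_clade <- function(n, age_years, years_per_mutation = 3624,
                           model = c("coalescent", "star"), seed = NULL,
                           clock = NULL,
                           clock_mode = c("linear", "corrected")) {
  model <- match.arg(model)
  clock_mode <- match.arg(clock_mode)
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n >= 1, age_years >= 0)
  if (model == "star" || n == 1L) {
    parent <- c(NA_integer_, rep(1L, n))
    ages <- c(age_years, rep(0, n))
  } else {
    res <- coalesce_deme(seq_len(n), 0, Inf, 1, n + 1L)
    n_all <- n + length(res$merges)
    parent <- rep(NA_integer_, n_all)
    ages <- c(rep(0, n), rep(NA_real_, n_all - n))
    for (m in res$merges) {
      ages[m$id] <- m$time
      parent[m$children] <- m$id
    }
    ages <- ages / max(ages) * age_years
    root_old <- which(is.na(parent))
    ord <- c(root_old, setdiff(order(-ages, seq_len(n_all)), root_old))
    remap <- integer(n_all)
    remap[ord] <- seq_len(n_all)
    p2 <- rep(NA_integer_, n_all)
    p2[remap] <- ifelse(is.na(parent), NA_integer_, remap[parent])
    a2 <- numeric(n_all)
    a2[remap] <- ages
    parent <- p2
    ages <- a2
  }
  n_all <- length(parent)
  leaf_id <- rep(NA_character_, n_all)
  is_leaf <- !(seq_len(n_all) %in% parent[!is.na(parent)])
  leaf_id[is_leaf] <- sprintf("L%03d", seq_len(sum(is_leaf)))
  pool_pos <- sim_position_pool()
  used <- logical(MT_LENGTH)
  mutations <- vector("list", n_all)
  mutations[[1L]] <- character(0)
  for (v in seq_len(n_all)[-1L]) {
    dt <- ages[parent[v]] - ages[v]
    lam <- if (clock_mode == "linear") dt / years_per_mutation else {
      ck <- clock %||% mito_clock()
      clock_divergence(ck, ages[parent[v]]) - clock_divergence(ck, ages[v])
    }
    k <- stats::rpois(1L, lam)
    pos <- integer(0)
    if (k > 0) {
      avail <- pool_pos[!used[pool_pos]]
      pos <- avail[sample.int(length(avail), min(k, length(avail)))]
      used[pos] <- TRUE
    }
    mutations[[v]] <- as.character(sort(pos))
  }
  out <- structure(
    list(parent = parent, mutations = mutations, sample_id = leaf_id,
         label = rep(NA_character_, n_all), root_state = character(0)),
    class = "mito_tree"
  )
  attr(out, "ages") <- ages
  out
}

#' Write a named test fixture to disk
#'
#' Presets: `"toy_3leaf"` (three profiles whose greedy parsimony tree
#' has score 3), `"f1f2_demo"` (a six-leaf tree whose f1 founder is an
#' internal node and whose f2 founder falls back to the root),
#' `"pulse_15ka"` (100 source + 100 sink mitogenomes from a seeded
#' 15-ka founder pulse) and `"reference_ages"` (the packaged
#' divergence/age calibration table).
#'
#' @param name Preset name.
#' @param dir Output directory (created if needed).
#' @param seed Seed for the simulated preset.
#' @return Invisibly, the paths written.
#' @export
make_fixture <- function(name = c("toy_3leaf", "f1f2_demo", "pulse_15ka",
                                  "reference_ages"),
                         dir = ".", seed = 42L) {
  name <- match.arg(name)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  if (name == "toy_3leaf") {
    haps <- haplotype_table(c("A", "B", "C"),
                            list(c("73", "146"), c("73", "263"), "73"))
    p <- file.path(dir, "toy_3leaf_profiles.tsv")
    write_profiles(haps, p)
    paths <- p
  } else if (name == "f1f2_demo") {
    demo <- f1f2_demo_dataset()
    p1 <- file.path(dir, "f1f2_demo_tree.nwk")
    p2 <- file.path(dir, "f1f2_demo_profiles.tsv")
    write_tree(demo$tree, p1)
    write_profiles(demo$haplotypes, p2)
    paths <- c(p1, p2)
  } else if (name == "pulse_15ka") {
    sim <- simulate_genealogy(sim_config(seed = seed, n_source = 100L,
                                         n_sink = 100L, pulse_time = 15000))
    p1 <- file.path(dir, "pulse_15ka_tree.nwk")
    p2 <- file.path(dir, "pulse_15ka_profiles.tsv")
    write_tree(sim$tree, p1)
    write_profiles(sim$haplotypes, p2)
    paths <- c(p1, p2)
  } else if (name == "reference_ages") {
    src <- system.file("extdata", "r0ab_divergence_ages.tsv",
                       package = "mitofounder", mustWork = TRUE)
    p <- file.path(dir, "r0ab_divergence_ages.tsv")
    file.copy(src, p, overwrite = TRUE)
    paths <- p
  }
  invisible(paths)
}

#' The six-leaf f1/f2 demonstration dataset
#'
#' Root with a source leaf S2 (one private mutation) and an internal
#' node F one mutation below the root; F carries a source leaf S1 (one
#' private mutation), a zero-mutation source tip S3, and three sink
#' leaves K1--K3 (one private mutation each). Under f1 the founder of
#' the sink cluster is F (S1 is its single derived source branch; the
#' zero-mutation tip S3 does not count); under f2 no ancestor
#' qualifies, so the cluster is flagged at the root.
#'
#' @return A list with `tree` (`mito_tree`) and `haplotypes`.
#' @export
f1f2_demo_dataset <- function() {
  tr <- new_mito_tree()
  tr <- tree_add_node(tr, 1L, "200", sample_id = "S2")   # node 2
  tr <- tree_add_node(tr, 1L, "100")                     # node 3 = F
  tr <- tree_add_node(tr, 3L, "150", sample_id = "S1")   # node 4
  tr <- tree_add_node(tr, 3L, character(0), sample_id = "S3") # node 5
  tr <- tree_add_node(tr, 3L, "300", sample_id = "K1")   # node 6
  tr <- tree_add_node(tr, 3L, "310", sample_id = "K2")   # node 7
  tr <- tree_add_node(tr, 3L, "320", sample_id = "K3")   # node 8
  haps <- haplotype_table(
    sample_id = c("S1", "S2", "S3", "K1", "K2", "K3"),
    variants = list(c("100", "150"), "200", "100",
                    c("100", "300"), c("100", "310"), c("100", "320")),
    population = c(rep("SourcePop", 3), rep("SinkPop", 3)),
    region = c(rep("Fertile Crescent", 3), rep("Arabian Peninsula", 3))
  )
  list(tree = tr, haplotypes = haps)
}
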