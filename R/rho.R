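# rho-statistic coalescence dating on mutation-annotated trees.

#' Build a branch-mutation counter for dating
#'
#' Returns a function counting the mutations of a branch under a given
#' exclusion context and counting policy. By default all substitutions
#' and indels count, heteroplasmies (R/Y) count as mutations, and no
#' exclusion context is applied (trees are normally already filtered at
#' build time).
#'
#' @param context `NULL` or an [apply_exclusions()] context
#'   (`"dating"` drops np 16519 and the 16182C/16183C transversions).
#' @param count_indels Count insertion/deletion tokens.
#' @param count_heteroplasmies Count R/Y heteroplasmic tokens.
#' @param policy An [exclusion_policy()].
#' @return A function mapping a token vector to an integer count.
#' @export
mutation_counter <- function(context = NULL, count_indels = TRUE,
                             count_heteroplasmies = TRUE,
                             policy = exclusion_policy()) {
  function(tokens) {
    if (length(tokens) == 0) return(0L)
    if (!is.null(context)) tokens <- apply_exclusions(tokens, policy, context)
    if (!count_indels) tokens <- tokens[!variant_is_indel(tokens)]
    if (!count_heteroplasmies) tokens <- tokens[!grepl("[RY]$", tokens)]
    length(tokens)
  }
}

# branches below `node`: per-branch mutation count m_b and subtended
# leaf count n_b
branch_table <- function(tree, node = 1L, count_fn = length) {
  if (node < 1L || node > n_nodes(tree)) stop("node not in tree: ", node)
  counts <- leaf_counts(tree)
  below <- setdiff(descendants(tree, node), node)
  tibble(
    node = below,
    m_b = vapply(below, function(v) as.integer(count_fn(tree$mutations[[v]])),
                 integer(1)),
    n_b = counts[below]
  )
}

#' The rho statistic: mean mutational distance of leaves from a node
#'
#' `rho()` is the average number of mutations separating the haplotypes
#' of a clade from the clade's root haplotype, computed as
#' `sum(m_b * n_b) / n` over the branches below the node.
#' `sigma_rho()` is the heuristic standard error estimated from the
#' genealogy (Saillard estimator), `sqrt(sum(n_b^2 * m_b)) / n`.
#'
#' @param tree A `mito_tree`.
#' @param node Node index (default the root).
#' @param count_fn Branch mutation counter, see [mutation_counter()].
#' @return A number (mutations).
#' @examples
#' # star tree with leaf distances 1, 2, 3 -> rho = 2
#' @export
rho <- function(tree, node = 1L, count_fn = length) {
  if (node < 1L || node > n_nodes(tree)) stop("node not in tree: ", node)
  counts <- leaf_counts(tree)
  if (counts[node] < 1L) stop("node has no descendant leaves: ", node)
  b <- branch_table(tree, node, count_fn)
  sum(b$m_b * b$n_b) / counts[node]
}

#' @rdname rho
#' @export
sigma_rho <- function(tree, node = 1L, count_fn = length) {
  if (node < 1L || node > n_nodes(tree)) stop("node not in tree: ", node)
  counts <- leaf_counts(tree)
  if (counts[node] < 1L) stop("node has no descendant leaves: ", node)
  b <- branch_table(tree, node, count_fn)
  sqrt(sum(b$n_b^2 * b$m_b)) / counts[node]
}

#' Date all labelled clades of a tree
#'
#' One row per labelled internal node encompassing at least `min_n`
#' haplotypes (three by default, the conventional minimum for reporting
#' an age), plus any explicitly whitelisted labels; rows are ordered by
#' tree pre-order. Ages use the purifying-selection-corrected clock.
#'
#' @param tree A labelled `mito_tree` (see [label_haplogroups()]).
#' @param clock A [mito_clock()].
#' @param min_n Minimum clade size for inclusion.
#' @param include Labels reported even below the size minimum.
#' @param count_fn Branch mutation counter.
#' @return A tibble: `label`, `node`, `n`, `rho`, `sigma`, `age_ka`,
#'   `ci_low_ka`, `ci_high_ka`.
#' @export
date_clades <- function(tree, clock = mito_clock(), min_n = 3L,
                        include = character(0), count_fn = length) {
  counts <- leaf_counts(tree)
  ord <- preorder(tree)
  nodes <- ord[!is.na(tree$label[ord])]
  nodes <- nodes[counts[nodes] >= min_n | tree$label[nodes] %in% include]
  empty <- tibble(label = character(0), node = integer(0), n = integer(0),
                  rho = numeric(0), sigma = numeric(0), age_ka = numeric(0),
                  ci_low_ka = numeric(0), ci_high_ka = numeric(0))
  if (length(nodes) == 0) return(empty)
  rows <- lapply(nodes, function(v) {
    r <- rho(tree, v, count_fn)
    s <- sigma_rho(tree, v, count_fn)
    a <- convert_age(r, s, clock)
    tibble(label = tree$label[v], node = v, n = counts[v],
           rho = r, sigma = s,
           age_ka = a$age_years / 1000,
           ci_low_ka = a$ci_low_years / 1000,
           ci_high_ka = a$ci_high_years / 1000)
  })
  do.call(rbind, rows)
}

#' Ratio of regional rho diversities below a node
#'
#' Computes rho separately over the leaves of two regions (mean
#' mutational distance of each region's leaves from the node) and
#' returns their ratio, a simple unbiased diversity contrast between
#' e.g. Fertile Crescent and Arabian lineages of the same clade.
#'
#' @param tree A `mito_tree`.
#' @param haplotypes The [haplotype_table()] mapping leaves to regions.
#' @param region_a,region_b Region labels to contrast.
#' @param node Node index (default root).
#' @param count_fn Branch mutation counter.
#' @return `rho_A / rho_B`.
#' @export
regional_rho_ratio <- function(tree, haplotypes, region_a, region_b,
                               node = 1L, count_fn = length) {
  dists <- leaf_path_lengths(tree, node, count_fn)
  region <- haplotypes$region[match(names(dists), haplotypes$sample_id)]
  da <- dists[region %in% region_a]
  db <- dists[region %in% region_b]
  if (length(da) == 0) stop("no leaves from region ", paste(region_a, collapse = "/"),
                            " below node ", node)
  if (length(db) == 0) stop("no leaves from region ", paste(region_b, collapse = "/"),
                            " below node ", node)
  mean(da) / mean(db)
}
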