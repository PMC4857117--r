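#' Build a mutation-annotated haplotype tree by greedy maximum parsimony
#'
#' Haplotypes are attached one at a time, in order of decreasing profile
#' size (ties broken by sample id, or shuffled under `seed` when
#' `shuffle = TRUE`). Each haplotype is placed where it shares the most
#' derived variants with the existing tree: either directly at a node
#' whose state is a subset of its profile, or by splitting a branch when
#' part of that branch's mutations are shared — which is how private
#' variants shared by two or more haplotypes come to found new internal
#' nodes. Recurrent placements of the same variant on different branches
#' are permitted (see [recurrent_variants()]).
#'
#' An optional backbone tree plays the role of a curated reference
#' phylogeny: construction starts from it instead of from a bare root.
#' A haplotype that conflicts with a non-empty root state is attached at
#' the root with explicit reversion tokens, with a warning.
#'
#' For small datasets (`method = "auto"`, up to `exact_max_leaves`
#' haplotypes and no backbone) the builder switches to an exhaustive
#' search — every rooted topology is scored by Fitch parsimony with the
#' root state fixed, guaranteeing the minimum parsimony score — and the
#' optimal mutation-annotated tree is reconstructed with zero-mutation
#' internal branches collapsed. Larger datasets use the greedy
#' stepwise-addition heuristic.
#'
#' @param haplotypes A [haplotype_table()] whose profiles have already
#'   been filtered with the `"phylogeny"` exclusion context.
#' @param backbone Optional `mito_tree` to extend, or `NULL`.
#' @param root_state Variant profile of the root haplotype (ignored when
#'   a backbone is given).
#' @param seed Integer seed used when `shuffle = TRUE`.
#' @param shuffle Randomize attachment order (seeded) instead of the
#'   deterministic size/id order.
#' @param method `"auto"`, `"greedy"` or `"exact"`.
#' @param exact_max_leaves Largest dataset the `"auto"` method hands to
#'   the exhaustive search.
#' @return A `mito_tree` whose leaves map to `haplotypes$sample_id`.
#' @export
build_parsimony_tree <- function(haplotypes, backbone = NULL,
                                 root_state = character(0),
                                 seed = NULL, shuffle = FALSE,
                                 method = c("auto", "greedy", "exact"),
                                 exact_max_leaves = 6L) {
  method <- match.arg(method)
  ids <- haplotypes$sample_id
  if (anyDuplicated(ids)) {
    stop("duplicate sample_id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (method == "exact" ||
      (method == "auto" && is.null(backbone) && !shuffle &&
       nrow(haplotypes) <= exact_max_leaves)) {
    return(exact_parsimony_tree(haplotypes, root_state))
  }
  profiles <- haplotypes$variants
  ord <- order(-lengths(profiles), ids)
  if (isTRUE(shuffle)) {
    if (!is.null(seed)) set.seed(seed)
    ord <- sample(ord)
  }

  tree <- if (is.null(backbone)) new_mito_tree(root_state) else backbone
  states <- node_states(tree)

  for (k in ord) {
    p <- profiles[[k]]
    id <- ids[k]

    if (length(tree$root_state) > 0 && !all(tree$root_state %in% p)) {
      warning("haplotype ", id,
              " conflicts with the root state; attached at the root with reversions")
      missing <- setdiff(tree$root_state, p)
      muts <- sort_variants(c(paste0("@", missing), setdiff(p, tree$root_state)))
      tree <- tree_add_node(tree, 1L, muts, sample_id = id)
      states[[n_nodes(tree)]] <- p
      next
    }

    kids <- tree_children(tree)
    best <- list(score = -1L, node = NA_integer_, child = NA_integer_,
                 share = character(0))
    for (u in seq_len(n_nodes(tree))) {
      su <- states[[u]]
      if (!all(su %in% p)) next
      # plain attachment at u
      if (length(su) > best$score) {
        best <- list(score = length(su), node = u, child = NA_integer_,
                     share = character(0))
      }
      # split a child branch of u on the shared part of its mutations
      for (cc in kids[[u]]) {
        m <- tree$mutations[[cc]]
        s <- intersect(m, setdiff(p, su))
        if (length(s) > 0 && length(s) < length(m) &&
            (length(su) + length(s)) > best$score) {
          best <- list(score = length(su) + length(s), node = u, child = cc,
                       share = s)
        }
      }
    }

    if (is.na(best$child)) {
      u <- best$node
      tree <- tree_add_node(tree, u, setdiff(p, states[[u]]), sample_id = id)
      states[[n_nodes(tree)]] <- p
    } else {
      u <- best$node; cc <- best$child
      new_state <- sort_variants(c(states[[u]], best$share))
      # new internal node on the split branch
      tree <- tree_add_node(tree, u, best$share)
      w <- n_nodes(tree)
      states[[w]] <- new_state
      tree$parent[cc] <- w
      tree$mutations[[cc]] <- sort_variants(setdiff(tree$mutations[[cc]], best$share))
      tree <- tree_add_node(tree, w, setdiff(p, new_state), sample_id = id)
      states[[n_nodes(tree)]] <- p
    }
  }
  tree
}

#' Label eligible internal nodes with nested haplogroup names
#'
#' A node is eligible for a haplogroup label when it encompasses at
#' least `min_leaves` haplotypes (two, following standard nomenclature
#' practice) and its branch carries at least one mutation that is not at
#' the unreliable np 60, which is disregarded when identifying clades.
#' Labels nest: eligible nodes under a labelled ancestor extend that
#' ancestor's name, alternating numeric and alphabetic suffixes in the
#' style of mtDNA nomenclature.
#'
#' @param tree A `mito_tree`.
#' @param prefix Label given to the root (nomenclature anchor, e.g.
#'   `"R0a"`).
#' @param min_leaves Minimum number of descendant haplotypes.
#' @param policy An [exclusion_policy()] supplying the positions ignored
#'   for labelling.
#' @return The tree with `label` filled in on eligible nodes.
#' @export
label_haplogroups <- function(tree, prefix = "HG", min_leaves = 2L,
                              policy = exclusion_policy()) {
  counts <- leaf_counts(tree)
  kids <- tree_children(tree)
  tree$label <- rep(NA_character_, n_nodes(tree))
  tree$label[1L] <- prefix

  eligible <- function(v) {
    if (!is.na(tree$sample_id[v])) return(FALSE)
    if (counts[v] < min_leaves) return(FALSE)
    muts <- tree$mutations[[v]]
    informative <- muts[!variant_position(muts) %in% policy$clade_id_positions]
    length(informative) >= 1L
  }

  assign_below <- function(v, parent_label, depth) {
    idx <- 0L
    for (cc in kids[[v]]) {
      if (eligible(cc)) {
        idx <- idx + 1L
        suffix <- if (depth %% 2L == 0L) as.character(idx) else letters[idx]
        tree$label[cc] <<- paste0(parent_label, suffix)
        assign_below(cc, tree$label[cc], depth + 1L)
      } else {
        assign_below(cc, parent_label, depth)
      }
    }
  }
  assign_below(1L, prefix, 0L)
  tree
}

#' Classify a haplotype against a hierarchy of haplogroup motifs
#'
#' Returns the deepest motif whose defining variants are all present in
#' the profile; ties are broken by the larger number of defining
#' variants, then lexicographically by label.
#'
#' @param haplotype Character vector of variant tokens (a profile), or a
#'   single row of a [haplotype_table()].
#' @param motifs A tibble with columns `label`, `defining` (list-column
#'   of token vectors) and `parent` (label of the parent motif or NA).
#' @return A list with `label` (NA if nothing matches) and `score` (the
#'   number of matched defining variants, 0 for no match).
#' @export
assign_haplogroup <- function(haplotype, motifs) {
  if (is.data.frame(haplotype)) haplotype <- haplotype$variants[[1]]
  if (!is.data.frame(motifs) || nrow(motifs) == 0) {
    stop("empty motif list")
  }
  depth_of <- function(lab) {
    d <- 0L
    while (!is.na(lab)) {
      p <- motifs$parent[match(lab, motifs$label)]
      if (length(p) == 0 || is.na(p)) break
      d <- d + 1L
      lab <- p
    }
    d
  }
  prof <- normalize_variant(haplotype)
  hit <- vapply(motifs$defining,
                function(def) all(normalize_variant(def) %in% prof),
                logical(1))
  if (!any(hit)) return(list(label = NA_character_, score = 0L))
  cand <- motifs[hit, , drop = FALSE]
  depth <- vapply(cand$label, depth_of, integer(1))
  sizes <- lengths(cand$defining)
  ord <- order(-depth, -sizes, cand$label)
  list(label = cand$label[ord[1]], score = as.integer(sizes[ord[1]]))
}

# ---- exhaustive maximum parsimony for small datasets ----------------------

# all rooted binary topologies on the given tip indices, as nested
# pair-lists; deterministic enumeration order
all_rooted_topologies <- function(tips) {
  if (length(tips) == 1) return(list(tips[[1]]))
  out <- list()
  first <- tips[[1]]
  rest <- tips[-1]
  subsets <- function(m) {
    if (m == 0) return(list(integer(0)))
    sub <- subsets(m - 1L)
    c(sub, lapply(sub, function(s) c(s, m)))
  }
  for (s in subsets(length(rest))) {
    right <- setdiff(seq_along(rest), s)
    if (length(right) == 0) next
    for (L in all_rooted_topologies(c(list(first), rest[s]))) {
      for (R in all_rooted_topologies(rest[right])) {
        out[[length(out) + 1L]] <- list(L, R)
      }
    }
  }
  out
}

# Fitch cost of one binary character on a topology, with the state at
# the stem (root haplotype) fixed
fitch_cost <- function(topo, leaf_state, root_fixed) {
  cost <- 0L
  down <- function(node) {
    if (!is.list(node)) return(leaf_state[node])
    sets <- lapply(node, down)
    i <- intersect(sets[[1]], sets[[2]])
    if (length(i) > 0) return(i)
    cost <<- cost + 1L
    union(sets[[1]], sets[[2]])
  }
  top <- down(topo)
  if (!root_fixed %in% top) cost <- cost + 1L
  cost
}

exact_parsimony_tree <- function(haplotypes, root_state = character(0)) {
  ids <- haplotypes$sample_id
  profiles <- haplotypes$variants
  n <- length(ids)
  root_state <- sort_variants(normalize_variant(root_state))
  if (n == 0) return(new_mito_tree(root_state))
  ord <- order(-lengths(profiles), ids) # same canonical order as greedy
  ids <- ids[ord]; profiles <- profiles[ord]

  tokens <- sort_variants(unique(c(unlist(profiles), root_state)))
  leaf_mat <- vapply(profiles, function(p) as.integer(tokens %in% p),
                     integer(length(tokens)))
  dim(leaf_mat) <- c(length(tokens), n)
  root_vec <- as.integer(tokens %in% root_state)

  if (n == 1) {
    tr <- new_mito_tree(root_state)
    muts <- c(setdiff(profiles[[1]], root_state),
              paste0("@", setdiff(root_state, profiles[[1]])))
    muts <- muts[muts != "@"]
    return(tree_add_node(tr, 1L, muts, sample_id = ids[1]))
  }

  topos <- all_rooted_topologies(as.list(seq_len(n)))
  best_topo <- NULL
  best_score <- Inf
  for (tp in topos) {
    sc <- 0L
    for (k in seq_along(tokens)) {
      sc <- sc + fitch_cost(tp, leaf_mat[k, ], root_vec[k])
      if (sc >= best_score) break
    }
    if (sc < best_score) {
      best_score <- sc
      best_topo <- tp
    }
  }

  # reconstruct one minimal labelling: bottom-up Fitch sets, then
  # top-down assignment preferring the parent's state
  tr <- new_mito_tree(root_state)
  build <- function(node, parent_idx, parent_states) {
    if (!is.list(node)) {
      state <- leaf_mat[, node]
    } else {
      sets <- fitch_sets(node)
      state <- ifelse(vapply(seq_along(tokens), function(k) {
        parent_states[k] %in% sets[[k]]
      }, logical(1)), parent_states,
      vapply(sets, `[`, integer(1), 1))
    }
    gained <- tokens[state == 1L & parent_states == 0L]
    lost <- tokens[state == 0L & parent_states == 1L]
    muts <- c(gained, if (length(lost) > 0) paste0("@", lost))
    tr <<- tree_add_node(tr, parent_idx, muts,
                         sample_id = if (!is.list(node)) ids[node] else NA_character_)
    idx <- n_nodes(tr)
    if (is.list(node)) {
      build(node[[1]], idx, state)
      build(node[[2]], idx, state)
    }
  }
  fitch_sets <- function(node) {
    if (!is.list(node)) {
      return(lapply(seq_along(tokens), function(k) leaf_mat[k, node]))
    }
    a <- fitch_sets(node[[1]]); b <- fitch_sets(node[[2]])
    lapply(seq_along(tokens), function(k) {
      i <- intersect(a[[k]], b[[k]])
      if (length(i) > 0) i else union(a[[k]], b[[k]])
    })
  }
  if (length(tokens) == 0) {
    for (i in seq_len(n)) tr <- tree_add_node(tr, 1L, character(0), sample_id = ids[i])
    return(tr)
  }
  build(best_topo, 1L, root_vec)
  collapse_zero_branches(tr)
}
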