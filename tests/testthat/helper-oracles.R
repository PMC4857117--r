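# Independent oracles and generators used across the suite. These
# deliberately re-derive quantities by the most direct route available
# (explicit path walks, exhaustive enumeration, closed forms) rather
# than calling the implementation under test.

# rho by explicitly walking every leaf up to the node
rho_pathsum <- function(tree, node = 1L) {
  lv <- tree_leaves(tree)
  dists <- c()
  for (leaf in lv) {
    v <- leaf
    d <- 0L
    ok <- FALSE
    while (!is.na(v)) {
      if (v == node) { ok <- TRUE; break }
      d <- d + length(tree$mutations[[v]])
      v <- tree$parent[v]
    }
    if (ok) dists <- c(dists, d)
  }
  mean(dists)
}

# Saillard variance by direct per-branch accumulation over leaf paths
sigma_pathsum <- function(tree, node = 1L) {
  lv <- tree_leaves(tree)
  usage <- integer(length(tree$parent))
  n <- 0L
  for (leaf in lv) {
    v <- leaf
    path <- integer(0)
    while (!is.na(v) && v != node) { path <- c(path, v); v <- tree$parent[v] }
    if (!is.na(v)) { usage[path] <- usage[path] + 1L; n <- n + 1L }
  }
  idx <- which(usage > 0)
  sqrt(sum(usage[idx]^2 * lengths(tree$mutations[idx]))) / n
}

# random mutation-annotated tree: random topology by sequential random
# attachment, Poisson branch mutation counts at unique dummy positions
random_tree <- function(n_leaves, mean_muts = 1.5, max_extra_internal = 3) {
  tr <- new_mito_tree()
  next_pos <- 1000L
  take_muts <- function(k) {
    if (k == 0) return(character(0))
    out <- as.character(next_pos + seq_len(k))
    next_pos <<- next_pos + k
    out
  }
  for (i in seq_len(max_extra_internal)) {
    anchor <- sample.int(n_nodes(tr), 1)
    tr <- tree_add_node(tr, anchor, take_muts(rpois(1, mean_muts)))
  }
  for (i in seq_len(n_leaves)) {
    anchor <- sample.int(n_nodes(tr), 1)
    tr <- tree_add_node(tr, anchor, take_muts(rpois(1, mean_muts)),
                        sample_id = sprintf("L%02d", i))
  }
  tr
}

# ---- exhaustive parsimony oracle ------------------------------------------

oracle_topologies <- function(tips) {
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
    for (L in oracle_topologies(c(list(first), rest[s]))) {
      for (R in oracle_topologies(rest[right])) {
        out[[length(out) + 1L]] <- list(L, R)
      }
    }
  }
  out
}

oracle_fitch <- function(topo, states) {
  cost <- 0L
  down <- function(node) {
    if (!is.list(node)) return(states[[node]])
    a <- down(node[[1]]); b <- down(node[[2]])
    i <- intersect(a, b)
    if (length(i) > 0) return(i)
    cost <<- cost + 1L
    union(a, b)
  }
  top <- down(topo)
  if (!0 %in% top) cost <- cost + 1L
  cost
}

# minimum parsimony score over all rooted topologies, root state empty
oracle_min_parsimony <- function(profiles) {
  sites <- sort(unique(unlist(profiles)))
  topos <- oracle_topologies(as.list(seq_along(profiles)))
  best <- Inf
  for (tp in topos) {
    sc <- 0L
    for (s in sites) {
      st <- lapply(profiles, function(p) if (s %in% p) 1L else 0L)
      sc <- sc + oracle_fitch(tp, st)
    }
    best <- min(best, sc)
  }
  best
}

# ---- sequence mutator oracle for call_variants ----------------------------

TRANSITION_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")

random_reference <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# apply a set of variant tokens to a reference string, returning the
# aligned (sample, reference) pair that call_variants() expects
mutate_sequence <- function(reference, tokens) {
  ref <- strsplit(reference, "")[[1]]
  smp <- ref
  ins <- list() # position -> inserted string
  if (length(tokens) > 0) {
    v <- parse_variant(tokens)
    for (i in seq_len(nrow(v))) {
      p <- v$position[i]
      if (v$kind[i] == "transition") {
        smp[p] <- TRANSITION_PARTNER[[ref[p]]]
      } else if (v$kind[i] == "transversion") {
        smp[p] <- v$derived_base[i]
      } else if (v$kind[i] == "deletion") {
        smp[p] <- "-"
      } else if (v$kind[i] == "insertion") {
        ins[[as.character(p)]] <- v$insert_seq[i]
      }
    }
  }
  out_s <- character(0)
  out_r <- character(0)
  for (p in seq_along(ref)) {
    out_s <- c(out_s, smp[p])
    out_r <- c(out_r, ref[p])
    key <- as.character(p)
    if (!is.null(ins[[key]])) {
      seqc <- strsplit(ins[[key]], "")[[1]]
      out_s <- c(out_s, seqc)
      out_r <- c(out_r, rep("-", length(seqc)))
    }
  }
  list(sequence = paste(out_s, collapse = ""),
       reference = paste(out_r, collapse = ""))
}

# random conflict-free variant set consistent with the reference (a
# transversion token names a base one purine<->pyrimidine step from the
# reference base); avoids position 1
random_variant_set <- function(reference, n) {
  ref <- strsplit(reference, "")[[1]]
  pos <- sample(2:length(ref), n)
  tokens <- character(0)
  for (p in pos) {
    kind <- sample(c("transition", "transversion", "deletion", "insertion"), 1,
                   prob = c(0.6, 0.2, 0.1, 0.1))
    tv_base <- if (ref[p] %in% c("A", "G")) sample(c("C", "T"), 1)
               else sample(c("A", "G"), 1)
    tokens <- c(tokens, switch(kind,
      transition = as.character(p),
      transversion = paste0(p, tv_base),
      deletion = paste0(p, "d"),
      insertion = paste0(p, ".", 1, sample(c("A", "C", "G", "T"), 1))
    ))
  }
  tokens
}
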