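# Mutation-annotated rooted trees of mtDNA haplotypes.
#
# A `mito_tree` stores nodes in a flat indexed form: node 1 is the root;
# `parent[i]` is the parent index (NA for the root); `mutations[[i]]`
# holds the variant tokens on the branch *above* node i (empty for the
# root); `sample_id[i]` names the haplotype at leaf i (NA for internal
# nodes); `label[i]` carries an optional haplogroup label. `root_state`
# is the variant profile of the root haplotype relative to the
# reference, so replaying branch mutations root-to-leaf reproduces each
# leaf's profile.

#' Create a tree consisting of a bare root, and grow it node by node
#'
#' Low-level constructors used to assemble trees by hand (worked
#' examples, imported topologies). `tree_add_node()` appends a node
#' under `parent` with the given branch mutations and returns the
#' enlarged tree.
#'
#' @param root_state Variant profile of the root haplotype relative to
#'   the reference.
#' @return A `mito_tree`.
#' @export
new_mito_tree <- function(root_state = character(0)) {
  structure(
    list(
      parent = NA_integer_,
      mutations = list(character(0)),
      sample_id = NA_character_,
      label = NA_character_,
      root_state = sort_variants(root_state)
    ),
    class = "mito_tree"
  )
}

#' @rdname new_mito_tree
#' @param tree A `mito_tree`.
#' @param parent Index of the parent node.
#' @param mutations Variant tokens on the new branch.
#' @param sample_id Sample identifier for a leaf, or `NA` for an
#'   internal node.
#' @param label Optional haplogroup label.
#' @export
tree_add_node <- function(tree, parent, mutations = character(0),
                          sample_id = NA_character_, label = NA_character_) {
  stopifnot(parent >= 1L, parent <= length(tree$parent))
  tree$parent <- c(tree$parent, as.integer(parent))
  tree$mutations <- c(tree$mutations, list(sort_variants(mutations)))
  tree$sample_id <- c(tree$sample_id, sample_id)
  tree$label <- c(tree$label, label)
  tree
}

#' Number of nodes, leaves and the parsimony score of a tree
#'
#' `parsimony_score()` is the total number of mutations over all
#' branches (reversions count as events).
#'
#' @param tree A `mito_tree`.
#' @return Integer.
#' @export
parsimony_score <- function(tree) {
  sum(lengths(tree$mutations))
}

#' @rdname parsimony_score
#' @export
tree_leaves <- function(tree) which(!is.na(tree$sample_id))

n_nodes <- function(tree) length(tree$parent)

tree_children <- function(tree) {
  kids <- vector("list", n_nodes(tree))
  for (i in seq_along(tree$parent)) {
    p <- tree$parent[i]
    if (!is.na(p)) kids[[p]] <- c(kids[[p]], i)
  }
  kids
}

# nodes in root-first (pre-)order; children visited in index order
preorder <- function(tree) {
  kids <- tree_children(tree)
  out <- integer(0)
  stack <- 1L
  while (length(stack) > 0) {
    v <- stack[1L]
    stack <- stack[-1L]
    out <- c(out, v)
    stack <- c(kids[[v]], stack)
  }
  out
}

# number of descendant leaves below each node (a leaf counts itself)
leaf_counts <- function(tree) {
  counts <- ifelse(is.na(tree$sample_id), 0L, 1L)
  for (v in rev(preorder(tree))) {
    p <- tree$parent[v]
    if (!is.na(p)) counts[p] <- counts[p] + counts[v]
  }
  counts
}

descendants <- function(tree, node) {
  kids <- tree_children(tree)
  out <- integer(0)
  stack <- node
  while (length(stack) > 0) {
    v <- stack[1L]
    stack <- c(kids[[v]], stack[-1L])
    out <- c(out, v)
  }
  out
}

# apply branch tokens to a profile state; "@x" removes x when present,
# and a recurrent hit at an already-derived site reverts it (the second
# transition at a position restores the reference base)
apply_branch <- function(state, tokens) {
  for (tok in tokens) {
    if (startsWith(tok, "@")) {
      base <- substring(tok, 2L)
      if (base %in% state) {
        state <- setdiff(state, base)
      } else {
        state <- c(state, tok)
      }
    } else if (tok %in% state) {
      state <- setdiff(state, tok)
    } else {
      state <- c(state, tok)
    }
  }
  state
}

#' Replay branch mutations to obtain per-node haplotype states
#'
#' Walks the tree from the root, applying each branch's mutations
#' (respecting reversion flags) to the running profile.
#'
#' @param tree A `mito_tree`.
#' @return A list of character vectors, one profile per node.
#' @export
node_states <- function(tree) {
  states <- vector("list", n_nodes(tree))
  states[[1L]] <- tree$root_state
  for (v in preorder(tree)) {
    if (v == 1L) next
    states[[v]] <- sort_variants(
      apply_branch(states[[tree$parent[v]]], tree$mutations[[v]])
    )
  }
  states
}

#' Mutation-count distance from a node to each of its descendant leaves
#'
#' @param tree A `mito_tree`.
#' @param node Node index (default root).
#' @param count_fn Optional function filtering/counting the tokens of a
#'   branch (defaults to counting all tokens).
#' @return Named integer vector over descendant leaves (names are
#'   sample ids).
#' @export
leaf_path_lengths <- function(tree, node = 1L, count_fn = length) {
  kids <- tree_children(tree)
  out <- integer(0)
  ids <- character(0)
  walk <- function(v, acc) {
    acc <- acc + count_fn(tree$mutations[[v]])
    if (!is.na(tree$sample_id[v])) {
      out <<- c(out, acc)
      ids <<- c(ids, tree$sample_id[v])
    }
    for (c in kids[[v]]) walk(c, acc)
  }
  if (node < 1L || node > n_nodes(tree)) stop("node not in tree: ", node)
  for (c in kids[[node]]) walk(c, 0L)
  if (!is.na(tree$sample_id[node])) {
    out <- c(out, 0L)
    ids <- c(ids, tree$sample_id[node])
  }
  names(out) <- ids
  out
}

#' Report variants recurring on more than one branch
#'
#' Mirrors the underlining of recurrent mutations on published
#' mutation-annotated trees.
#'
#' @param tree A `mito_tree`.
#' @return Character vector of tokens appearing on two or more branches.
#' @export
recurrent_variants <- function(tree) {
  all_tok <- sub("^@", "", unlist(tree$mutations))
  sort_variants(unique(all_tok[duplicated(all_tok)]))
}

#' Collapse zero-mutation internal branches into multifurcations
#'
#' Internal nodes whose branch carries no mutation are merged into
#' their parent, the standard haplotype-tree view in which nodes are
#' sequence states rather than coalescent events. Leaves are never
#' removed (a zero-branch leaf is a sampled haplotype identical to its
#' ancestral node).
#'
#' @param tree A `mito_tree`.
#' @return A `mito_tree`.
#' @export
collapse_zero_branches <- function(tree) {
  repeat {
    victim <- which(
      lengths(tree$mutations) == 0L &
        is.na(tree$sample_id) &
        !is.na(tree$parent)
    )
    # keep internal nodes that still have children pointing at them
    if (length(victim) == 0) break
    v <- victim[1L]
    p <- tree$parent[v]
    tree$parent[tree$parent == v & !is.na(tree$parent)] <- p
    if (!is.na(tree$label[v]) && is.na(tree$label[p])) tree$label[p] <- tree$label[v]
    tree <- drop_node(tree, v)
  }
  tree
}

# remove node v (assumed childless or already re-parented), reindexing
drop_node <- function(tree, v) {
  keep <- setdiff(seq_len(n_nodes(tree)), v)
  remap <- rep(NA_integer_, n_nodes(tree))
  remap[keep] <- seq_along(keep)
  old_parent <- tree$parent[keep]
  new_parent <- ifelse(is.na(old_parent), NA_integer_, remap[old_parent])
  tree$parent <- as.integer(new_parent)
  tree$mutations <- tree$mutations[keep]
  tree$sample_id <- tree$sample_id[keep]
  tree$label <- tree$label[keep]
  tree
}

#' @export
print.mito_tree <- function(x, ...) {
  cat("mito_tree:", length(tree_leaves(x)), "leaves,", n_nodes(x), "nodes,",
      "parsimony score", parsimony_score(x), "\n")
  lab <- x$label[!is.na(x$label)]
  if (length(lab) > 0) cat("labelled haplogroups:", paste(lab, collapse = " "), "\n")
  invisible(x)
}

# ---- newick serialization -------------------------------------------------

quote_name <- function(x) {
  ifelse(grepl("^[A-Za-z0-9_.#|-]*$", x), x, paste0("'", gsub("'", "''", x), "'"))
}

#' Write a mutation-annotated tree as newick with comment blocks
#'
#' Branch mutation lists travel in `[&m=...]` comment blocks and branch
#' lengths equal mutation counts; the root's profile is recorded in a
#' `[&root=...]` block, so `read_tree(write_tree(t))` reproduces the
#' topology, mutations, labels and leaf map.
#'
#' @param tree A `mito_tree`.
#' @param file Path to write to.
#' @return `file`, invisibly.
#' @export
write_tree <- function(tree, file) {
  kids <- tree_children(tree)
  fmt <- function(v) {
    name <- if (!is.na(tree$sample_id[v])) tree$sample_id[v]
            else if (!is.na(tree$label[v])) tree$label[v] else ""
    muts <- tree$mutations[[v]]
    com <- paste0("[&m=", paste(muts, collapse = " "), "]")
    if (v == 1L && length(tree$root_state) > 0) {
      com <- paste0(com, "[&root=", paste(tree$root_state, collapse = " "), "]")
    }
    core <- if (length(kids[[v]]) > 0) {
      paste0("(", paste(vapply(kids[[v]], fmt, character(1)), collapse = ","),
             ")", quote_name(name))
    } else {
      quote_name(name)
    }
    if (v == 1L) paste0(core, com) else paste0(core, com, ":", length(muts))
  }
  writeLines(paste0(fmt(1L), ";"), file)
  invisible(file)
}

#' Read a mutation-annotated newick tree
#'
#' Accepts the dialect written by [write_tree()]; plain newick without
#' comment blocks yields zero-mutation branches.
#'
#' @param file Path to a newick file (or a literal newick string).
#' @return A `mito_tree`.
#' @export
read_tree <- function(file) {
  txt <- if (file.exists(file)) paste(readLines(file), collapse = "") else file
  txt <- gsub("[[:space:]]+", " ", trimws(txt))
  if (!endsWith(txt, ";")) stop("malformed newick: missing terminal ';'")
  chars <- strsplit(txt, "")[[1]]
  i <- 1L
  n <- length(chars)

  peek <- function() if (i <= n) chars[i] else ""
  fail <- function(msg) stop("newick parse error at position ", i, ": ", msg)

  read_name <- function() {
    if (peek() == "'") {
      j <- i + 1L
      out <- character(0)
      repeat {
        if (j > n) fail("unterminated quoted name")
        if (chars[j] == "'") {
          if (j + 1L <= n && chars[j + 1L] == "'") {
            out <- c(out, "'"); j <- j + 2L
          } else break
        } else {
          out <- c(out, chars[j]); j <- j + 1L
        }
      }
      i <<- j + 1L
      paste(out, collapse = "")
    } else {
      j <- i
      while (j <= n && grepl("[A-Za-z0-9_.#|-]", chars[j])) j <- j + 1L
      out <- paste(chars[i:(j - 1L)][seq_len(max(0, j - i))], collapse = "")
      i <<- j
      out
    }
  }

  read_comments <- function() {
    out <- character(0)
    while (peek() == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) fail("unterminated comment")
      out <- c(out, paste(chars[(i + 1L):(j - 1L)][seq_len(max(0, j - i - 1L))],
                          collapse = ""))
      i <<- j + 1L
    }
    out
  }

  skip_length <- function() {
    if (peek() == ":") {
      i <<- i + 1L
      while (grepl("[0-9.eE+-]", peek()) && peek() != "") i <<- i + 1L
    }
  }

  nodes <- list() # each: list(parent, muts, name, root_tokens)
  parse_node <- function(parent) {
    idx <- length(nodes) + 1L
    nodes[[idx]] <<- list(parent = parent, muts = character(0),
                          name = "", root_tokens = NULL)
    if (peek() == "(") {
      i <<- i + 1L
      repeat {
        parse_node(idx)
        if (peek() == ",") { i <<- i + 1L; next }
        if (peek() == ")") { i <<- i + 1L; break }
        fail("expected ',' or ')'")
      }
    }
    nm <- read_name()
    com <- read_comments()
    skip_length()
    com2 <- read_comments() # tolerate comments after the branch length
    com <- c(com, com2)
    muts <- character(0)
    root_tokens <- NULL
    for (cm in com) {
      if (grepl("^&m=", cm)) {
        body <- sub("^&m=", "", cm)
        muts <- c(muts, strsplit(trimws(body), " +")[[1]])
      } else if (grepl("^&root=", cm)) {
        root_tokens <- strsplit(trimws(sub("^&root=", "", cm)), " +")[[1]]
      }
    }
    nodes[[idx]]$muts <<- muts[muts != ""]
    nodes[[idx]]$name <<- nm
    nodes[[idx]]$root_tokens <<- root_tokens[root_tokens != ""]
    idx
  }

  parse_node(NA_integer_)
  if (peek() != ";") fail("expected ';'")

  parent <- vapply(nodes, function(x) x$parent, integer(1))
  has_kids <- seq_along(nodes) %in% parent[!is.na(parent)]
  tree <- structure(
    list(
      parent = parent,
      mutations = lapply(nodes, function(x) sort_variants(x$muts)),
      sample_id = ifelse(!has_kids & vapply(nodes, function(x) x$name, character(1)) != "",
                         vapply(nodes, function(x) x$name, character(1)),
                         NA_character_),
      label = ifelse(has_kids & vapply(nodes, function(x) x$name, character(1)) != "",
                     vapply(nodes, function(x) x$name, character(1)),
                     NA_character_),
      root_state = sort_variants(nodes[[1L]]$root_tokens %||% character(0))
    ),
    class = "mito_tree"
  )
  tree
}
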