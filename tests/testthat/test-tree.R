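test_that("worked parsimony examples place shared variants on internal nodes", {
  # three haplotypes sharing one variant: shared node carries it, score 3
  haps <- haplotype_table(c("A", "B", "C"),
                          list(c("73", "146"), c("73", "263"), "73"))
  tr <- build_parsimony_tree(haps)
  expect_equal(parsimony_score(tr), 3L)
  st <- node_states(tr)
  c_node <- tree_leaves(tr)[tr$sample_id[tree_leaves(tr)] == "C"]
  expect_identical(st[[c_node]], "73")
  expect_length(tr$mutations[[c_node]], 0L) # C sits at the shared node

  # a haplotype identical to the root state: zero-mutation leaf, score 0
  tr0 <- build_parsimony_tree(haplotype_table("A", list(character(0))))
  expect_equal(parsimony_score(tr0), 0L)

  # two identical haplotypes: one shared mutation, two zero-length leaves
  tr2 <- build_parsimony_tree(haplotype_table(c("A", "B"),
                                              list("5005", "5005")))
  expect_equal(parsimony_score(tr2), 1L)
  lv <- tree_leaves(tr2)
  expect_true(all(lengths(tr2$mutations[lv]) == 0L))
})

test_that("small instances reach the exhaustive parsimony minimum", {
  set.seed(23)
  for (i in 1:40) {
    n_leaves <- sample(2:5, 1)
    n_sites <- sample(1:6, 1)
    profiles <- lapply(seq_len(n_leaves),
                       function(.) which(runif(n_sites) < 0.45))
    haps <- haplotype_table(paste0("L", seq_len(n_leaves)),
                            lapply(profiles, function(p) as.character(p + 100)))
    tr <- build_parsimony_tree(haps)
    expect_equal(parsimony_score(tr), oracle_min_parsimony(profiles))
  }
})

test_that("replaying branch mutations reproduces every leaf profile", {
  set.seed(31)
  for (i in 1:15) {
    n <- sample(c(3, 8, 14), 1) # crosses the exact/greedy switch
    profiles <- lapply(seq_len(n), function(.) {
      as.character(2000 + which(runif(10) < 0.3))
    })
    haps <- haplotype_table(paste0("H", seq_len(n)), profiles)
    tr <- build_parsimony_tree(haps)
    st <- node_states(tr)
    for (leaf in tree_leaves(tr)) {
      want <- haps$variants[[match(tr$sample_id[leaf], haps$sample_id)]]
      expect_setequal(st[[leaf]], want)
    }
    # star-tree bound on the greedy/exact score
    expect_lte(parsimony_score(tr), sum(lengths(profiles)))
  }
})

test_that("duplicate sample ids are rejected and shuffled order is seeded", {
  haps <- haplotype_table(paste0("H", 1:8),
                          lapply(1:8, function(i) as.character(100 + (i %% 4))))
  dup <- haps
  dup$sample_id[2] <- "H1"
  expect_error(build_parsimony_tree(dup), "duplicate")
  a <- build_parsimony_tree(haps, seed = 5, shuffle = TRUE)
  b <- build_parsimony_tree(haps, seed = 5, shuffle = TRUE)
  expect_identical(a, b)
})

test_that("haplogroup labelling honours the two-haplotype and np 60 rules", {
  tr <- new_mito_tree()
  tr <- tree_add_node(tr, 1L, "1000")                      # eligible clade
  tr <- tree_add_node(tr, 2L, "1100", sample_id = "A")
  tr <- tree_add_node(tr, 2L, "1200", sample_id = "B")
  tr <- tree_add_node(tr, 1L, "2000")                      # single descendant
  tr <- tree_add_node(tr, 5L, "2100", sample_id = "C")
  tr <- tree_add_node(tr, 1L, "60")                        # np 60 only
  tr <- tree_add_node(tr, 7L, "3100", sample_id = "D")
  tr <- tree_add_node(tr, 7L, "3200", sample_id = "E")
  lab <- label_haplogroups(tr, prefix = "R0a")
  expect_identical(lab$label[1L], "R0a")
  expect_identical(lab$label[2L], "R0a1")   # >= 2 leaves, informative branch
  expect_true(is.na(lab$label[5L]))         # only one descendant haplotype
  expect_true(is.na(lab$label[7L]))         # only np 60 on the branch
})

test_that("nested labels extend their labelled ancestor's name", {
  tr <- new_mito_tree()
  tr <- tree_add_node(tr, 1L, "1000")
  tr <- tree_add_node(tr, 2L, "1100")
  tr <- tree_add_node(tr, 3L, "1110", sample_id = "A")
  tr <- tree_add_node(tr, 3L, "1120", sample_id = "B")
  tr <- tree_add_node(tr, 2L, "1300", sample_id = "C")
  lab <- label_haplogroups(tr, prefix = "R0a")
  expect_identical(lab$label[2L], "R0a1")
  expect_identical(lab$label[3L], "R0a1a")
})

test_that("motif classification returns the deepest full match", {
  motifs <- rbind(
    haplogroup_motif("R0a", c("16126", "16362")),
    haplogroup_motif("R0a1", c("16126", "16362", "58"), parent = "R0a"),
    haplogroup_motif("R0a1a", c("16126", "16362", "58", "64"), parent = "R0a1")
  )
  hit <- assign_haplogroup(c("16126", "16362", "73"), motifs)
  expect_identical(hit$label, "R0a")
  expect_equal(hit$score, 2L)
  deep <- assign_haplogroup(c("16126", "16362", "58", "64"), motifs)
  expect_identical(deep$label, "R0a1a")
  none <- assign_haplogroup("263", motifs)
  expect_true(is.na(none$label))
  expect_equal(none$score, 0L)
  expect_error(assign_haplogroup("263", motifs[0, ]), "empty motif")
})

test_that("annotated newick round-trips topology, mutations and labels", {
  haps <- haplotype_table(c("A", "B", "C", "D"),
                          list(c("73", "146"), c("73", "263"),
                               "73", c("5005", "537d")))
  tr <- build_parsimony_tree(haps)
  tr <- label_haplogroups(tr, prefix = "HGX")
  f <- withr::local_tempfile(fileext = ".nwk")
  write_tree(tr, f)
  back <- read_tree(f)
  expect_equal(parsimony_score(back), parsimony_score(tr))
  expect_setequal(back$sample_id[tree_leaves(back)],
                  tr$sample_id[tree_leaves(tr)])
  expect_setequal(back$label[!is.na(back$label)], tr$label[!is.na(tr$label)])
  sb <- node_states(back); sa <- node_states(tr)
  key <- function(t, s) sort(vapply(tree_leaves(t), function(i) {
    paste(t$sample_id[i], paste(s[[i]], collapse = " ")) }, character(1)))
  expect_identical(key(back, sb), key(tr, sa))
})

test_that("reversion flags and root states survive serialization", {
  tr <- new_mito_tree(root_state = c("73", "16126"))
  tr <- tree_add_node(tr, 1L, "@16126", sample_id = "X")
  tr <- tree_add_node(tr, 1L, "263", sample_id = "Y")
  f <- withr::local_tempfile(fileext = ".nwk")
  write_tree(tr, f)
  back <- read_tree(f)
  expect_identical(back$root_state, c("73", "16126"))
  xi <- which(back$sample_id == "X")
  expect_identical(back$mutations[[xi]], "@16126")
  expect_setequal(node_states(back)[[xi]], "73")
})

test_that("plain newick yields zero-mutation branches; malformed input errors", {
  tr <- read_tree("((A,B),C);")
  expect_equal(parsimony_score(tr), 0L)
  expect_length(tree_leaves(tr), 3L)
  expect_error(read_tree("((A,B),C)"), "missing terminal")
  expect_error(read_tree("((A,B,C);"), "parse error")
})

test_that("collapsing zero-mutation branches preserves leaves and score", {
  tr <- new_mito_tree()
  tr <- tree_add_node(tr, 1L, character(0))          # collapsible
  tr <- tree_add_node(tr, 2L, "100", sample_id = "A")
  tr <- tree_add_node(tr, 2L, character(0))          # collapsible chain
  tr <- tree_add_node(tr, 4L, "200", sample_id = "B")
  out <- collapse_zero_branches(tr)
  expect_equal(parsimony_score(out), 2L)
  expect_length(tree_leaves(out), 2L)
  expect_true(all(out$parent[tree_leaves(out)] == 1L))
})
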