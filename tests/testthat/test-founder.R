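demo_scenario <- function(...) {
  founder_scenario("demo", source = "Fertile Crescent",
                   sink = "Arabian Peninsula", ...)
}

test_that("scenario partitions honour region sets and the Palestinian switch", {
  demo <- f1f2_demo_dataset()
  haps <- demo$haplotypes
  haps$region[haps$sample_id == "S2"] <- "Europe"
  haps$population[haps$sample_id == "S1"] <- "Palestinian"

  part <- partition_leaves(demo$tree, haps, demo_scenario())
  cnt <- attr(part, "counts")
  expect_equal(unname(cnt[["excluded"]]), 2L) # Europe leaf + unassigned Palestinian
  expect_equal(unname(cnt[["sink"]]), 3L)

  with_ap <- partition_leaves(demo$tree, haps,
                              demo_scenario(palestinian_mode = "with_arabia"))
  s1 <- which(demo$tree$sample_id == "S1")
  expect_identical(with_ap[s1], "sink") # Arabia is the sink here
  with_fc <- partition_leaves(
    demo$tree, haps, demo_scenario(palestinian_mode = "with_fertile_crescent"))
  expect_identical(with_fc[s1], "source")

  # reciprocal scenario swaps the classes exactly
  rec <- founder_scenario("rec", source = "Arabian Peninsula",
                          sink = "Fertile Crescent")
  p1 <- partition_leaves(demo$tree, demo$haplotypes, demo_scenario())
  p2 <- partition_leaves(demo$tree, demo$haplotypes, rec)
  expect_identical(p1 == "source", p2 == "sink")
  expect_identical(p1 == "sink", p2 == "source")
})

test_that("iran and unknown-region handling are explicit", {
  demo <- f1f2_demo_dataset()
  haps <- demo$haplotypes
  haps$region[haps$sample_id == "S2"] <- "Iran"
  sc_with <- founder_scenario("w", source = c("Fertile Crescent", "Iran"),
                              sink = "Arabian Peninsula")
  sc_without <- founder_scenario("wo", source = c("Fertile Crescent", "Iran"),
                                 sink = "Arabian Peninsula",
                                 include_iran_in_source = FALSE)
  s2 <- which(demo$tree$sample_id == "S2")
  expect_identical(partition_leaves(demo$tree, haps, sc_with)[s2], "source")
  expect_identical(partition_leaves(demo$tree, haps, sc_without)[s2],
                   "excluded")
  bad <- haps
  bad$region[1] <- "unassigned"
  sc_strict <- founder_scenario("s", source = "Fertile Crescent",
                                sink = "Arabian Peninsula",
                                regions = c("Fertile Crescent",
                                            "Arabian Peninsula"))
  expect_error(partition_leaves(demo$tree, bad, sc_strict),
               "not in the configured label set")
})

test_that("f1 and f2 founders match the hand-traced six-leaf example", {
  demo <- f1f2_demo_dataset()
  ck <- mito_clock(tau = 42843)
  part <- partition_leaves(demo$tree, demo$haplotypes, demo_scenario())
  f1 <- identify_founders(demo$tree, part, "f1", ck)
  f2 <- identify_founders(demo$tree, part, "f2", ck)
  # f1: founder at F (node 3), whose single derived source branch is S1;
  # the zero-mutation source tip S3 does not count
  expect_equal(nrow(f1), 1L)
  expect_equal(f1$founder, 3L)
  expect_equal(f1$n_sink, 3L)
  expect_equal(f1$n_derived_source_branches, 1L)
  expect_false(f1$at_root)
  expect_equal(f1$rho_f, 1)
  expect_equal(f1$age_years, 2651)
  # f2: no qualifying ancestor, flagged at the root
  expect_equal(f2$founder, 1L)
  expect_true(f2$at_root)
  expect_equal(f2$n_sink, 3L)
})

test_that("an extra derived source branch at F upgrades it to an f2 founder", {
  demo <- f1f2_demo_dataset()
  tr <- tree_add_node(demo$tree, 3L, "160", sample_id = "S4")
  haps <- haplotype_table(
    sample_id = c(demo$haplotypes$sample_id, "S4"),
    variants = c(demo$haplotypes$variants, list(c("100", "160"))),
    population = c(demo$haplotypes$population, "SourcePop"),
    region = c(demo$haplotypes$region, "Fertile Crescent")
  )
  part <- partition_leaves(tr, haps, demo_scenario())
  f2 <- identify_founders(tr, part, "f2", mito_clock(tau = 42843))
  expect_equal(f2$founder, 3L)
  expect_false(f2$at_root)
  expect_equal(f2$n_derived_source_branches, 2L)
})

test_that("all-sink partitions collapse to a single flagged root cluster", {
  demo <- f1f2_demo_dataset()
  haps <- demo$haplotypes
  haps$region[] <- "Arabian Peninsula"
  part <- partition_leaves(demo$tree, haps, demo_scenario())
  cl <- identify_founders(demo$tree, part, "f1", mito_clock(tau = 42843))
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$founder, 1L)
  expect_true(cl$at_root)
  expect_equal(cl$n_sink, 6L)
})

test_that("founder clusters partition the sink leaves and nest across criteria", {
  ck <- mito_clock(tau = 42843)
  sc <- demo_scenario()
  for (seed in c(301, 302, 303, 304)) {
    sim <- simulate_genealogy(sim_config(seed = seed, n_source = 40L,
                                         n_sink = 25L, pulse_time = 12000))
    part <- partition_leaves(sim$tree, sim$haplotypes, sc)
    f1 <- identify_founders(sim$tree, part, "f1", ck)
    f2 <- identify_founders(sim$tree, part, "f2", ck)
    n_sink <- sum(part == "sink", na.rm = TRUE)
    expect_equal(sum(f1$n_sink), n_sink)
    expect_equal(sum(f2$n_sink), n_sink)
    expect_lte(nrow(f2), nrow(f1))
    # each leaf's f2 founder is an ancestor-or-equal of its f1 founder
    anc_or_equal <- function(tree, a, b) { # is a an ancestor-or-equal of b?
      v <- b
      while (!is.na(v)) { if (v == a) return(TRUE); v <- tree$parent[v] }
      FALSE
    }
    leaves <- which(!is.na(part) & part == "sink" &
                      !is.na(sim$tree$sample_id))
    per <- attr(part, "counts")
    for (leaf in leaves[seq_len(min(8, length(leaves)))]) {
      fo <- function(cl) {
        hit <- vapply(seq_len(nrow(cl)), function(i) {
          anc_or_equal(sim$tree, cl$founder[i], leaf)
        }, logical(1))
        # the leaf's own cluster founder: the nearest flagged one
        cand <- cl$founder[hit]
        cand[which.max(vapply(cand, function(f) {
          d <- 0L; v <- leaf
          while (!is.na(v) && v != f) { d <- d + 1L; v <- sim$tree$parent[v] }
          -d
        }, integer(1)))]
      }
      expect_true(anc_or_equal(sim$tree, fo(f2), fo(f1)))
    }
  }
})

test_that("migration scans conserve mass and place degenerate clusters", {
  ck <- mito_clock(tau = 42843)
  one <- tibble::tibble(founder = 2L, criterion = "f1", n_sink = 4L,
                        n_derived_source_branches = 1L, rho_f = 0, sigma_f = 0,
                        age_years = 0, sigma_years = 0, at_root = FALSE)
  scan <- scan_migrations(one)
  expect_equal(sum(scan$mass), 1)
  expect_equal(scan$mass[1], 1)  # all mass in [0, 200)

  two <- tibble::tibble(founder = c(2L, 5L), criterion = "f1",
                        n_sink = c(5L, 5L),
                        n_derived_source_branches = 1L,
                        rho_f = c(2, 10), sigma_f = c(0.2, 0.2),
                        age_years = c(5302, 26510),
                        sigma_years = c(530.2, 530.2), at_root = FALSE)
  scan2 <- scan_migrations(two)
  expect_equal(sum(scan2$mass), 1)
  peaks <- order(scan2$mass, decreasing = TRUE)[1:2]
  expect_setequal(findInterval(c(5302, 26510), scan2$bin_start), sort(peaks))
  # equal sink sizes: each peak region holds half the mass
  lower <- sum(scan2$mass[scan2$bin_mid < 15000])
  expect_equal(lower, 0.5, tolerance = 1e-6)
  expect_error(scan_migrations(two[0, ]), "no founder clusters")
})

test_that("shifting founder ages shifts the scan mode by the same amount", {
  set.seed(81)
  ck <- mito_clock(tau = 42843)
  cl <- tibble::tibble(founder = 1:3, criterion = "f2", n_sink = c(10L, 6L, 4L),
                       n_derived_source_branches = 2L,
                       rho_f = c(2, 3, 4), sigma_f = 0.4,
                       age_years = c(6000, 9000, 11000),
                       sigma_years = 0.4 * 2651, at_root = FALSE)
  base_mode <- scan_mode(scan_migrations(cl))
  shifted <- cl
  shifted$age_years <- cl$age_years + 4000
  expect_equal(scan_mode(scan_migrations(shifted)), base_mode + 4000,
               tolerance = 201 / base_mode)
})

test_that("scenario reports are deterministic and presets cover the seven designs", {
  presets <- scenario_presets()
  expect_identical(names(presets), LETTERS[1:7])
  expect_setequal(presets$A$sink, "Eastern Africa")
  expect_true("Iran" %in% presets$A$source)
  expect_setequal(presets$B$sink, c("Arabian Peninsula", "Eastern Africa"))
  expect_setequal(presets$C$source, c("Fertile Crescent", "Caucasus"))
  expect_setequal(presets$D$sink, c("Fertile Crescent", "Iran", "Caucasus"))
  expect_false("Iran" %in% presets$E$sink)
  expect_setequal(presets$F$sink, "South Asia")
  expect_setequal(presets$G$sink, "Europe")
  expect_error(founder_scenario("bad", source = "Iran", sink = "Iran"),
               "overlap")

  ck <- mito_clock(tau = 42843)
  sim <- simulate_genealogy(sim_config(seed = 11, n_source = 30L, n_sink = 15L))
  r1 <- run_scenario(sim$tree, sim$haplotypes, demo_scenario(), ck)
  r2 <- run_scenario(sim$tree, sim$haplotypes, demo_scenario(), ck)
  expect_identical(r1$clusters, r2$clusters)
  expect_identical(r1$scans$f2$mass, r2$scans$f2$mass)
})
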