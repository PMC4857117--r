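make_star <- function(dists) {
  tr <- new_mito_tree()
  for (i in seq_along(dists)) {
    tr <- tree_add_node(tr, 1L, as.character(1000 + seq_len(dists[i]) + 100 * i),
                        sample_id = paste0("L", i))
  }
  tr
}

test_that("rho equals the mean leaf distance on worked examples", {
  expect_equal(rho(make_star(c(1, 2, 3))), 2)
  single <- tree_add_node(new_mito_tree(), 1L, character(0), sample_id = "L1")
  expect_equal(rho(single), 0)
  nested <- new_mito_tree()
  nested <- tree_add_node(nested, 1L, "100")
  nested <- tree_add_node(nested, 2L, "200", sample_id = "L1")
  nested <- tree_add_node(nested, 2L, "300", sample_id = "L2")
  nested <- tree_add_node(nested, 1L, "400", sample_id = "L3")
  expect_equal(rho(nested), 5 / 3)
  expect_error(rho(nested, 99L), "not in tree")
})

test_that("the genealogical standard error matches its closed forms", {
  star4 <- make_star(c(1, 1, 1, 1))
  expect_equal(sigma_rho(star4), 0.5)
  zero <- make_star(c(0, 0, 0))
  expect_equal(sigma_rho(zero), 0)
  nested <- new_mito_tree()
  nested <- tree_add_node(nested, 1L, "100")
  nested <- tree_add_node(nested, 2L, "200", sample_id = "L1")
  nested <- tree_add_node(nested, 2L, "300", sample_id = "L2")
  expect_equal(sigma_rho(nested), sqrt(1.5))
})

test_that("rho agrees with explicit path summation on random trees", {
  set.seed(61)
  for (i in 1:100) {
    tr <- random_tree(sample(2:12, 1))
    expect_equal(rho(tr), rho_pathsum(tr))
    expect_equal(sigma_rho(tr), sigma_pathsum(tr))
    # recursion over children: rho(v) = sum (n_c/n) (rho(c) + m_c)
    kids <- mitofounder:::tree_children(tr)[[1L]]
    counts <- mitofounder:::leaf_counts(tr)
    if (counts[1L] > 0 && length(kids) > 0) {
      parts <- vapply(kids, function(cc) {
        if (counts[cc] == 0) return(0)
        counts[cc] * (rho(tr, cc) + length(tr$mutations[[cc]]))
      }, numeric(1))
      expect_equal(rho(tr), sum(parts) / counts[1L])
    }
  }
})

test_that("sigma matches the spread of rho under Poisson branch re-draws", {
  set.seed(71)
  for (i in 1:3) {
    tr <- random_tree(8, mean_muts = 2)
    counts <- mitofounder:::leaf_counts(tr)
    n <- counts[1L]
    b <- mitofounder:::branch_table(tr)
    draws <- replicate(4000, {
      sum(stats::rpois(nrow(b), b$m_b) * b$n_b) / n
    })
    expect_equal(sd(draws), sigma_rho(tr), tolerance = 0.08)
  }
})

test_that("the corrected clock is monotone, pinned at the origin and sandwiched", {
  ck <- mito_clock()
  expect_equal(clock_age(ck, 0), 0)
  d <- seq(0.05, 14, length.out = 60)
  ages <- clock_age(ck, d)
  expect_true(all(diff(ages) > 0))
  # linear bounds: 2562 d <= age(d) <= 3624 d
  expect_true(all(ages >= ck$rate_zero * d - 1e-6))
  expect_true(all(ages <= ck$rate_linear * d + 1e-6))
  # effective years-per-mutation grows with divergence
  expect_true(all(diff(ages / d) > 0))
  expect_error(clock_age(ck, -1), "non-negative")
})

test_that("age intervals transform the divergence interval and clip at zero", {
  ck <- mito_clock()
  out <- convert_age(0.22, 0.16, ck)
  expect_equal(out$ci_low_years, 0)
  expect_gt(out$ci_high_years, out$age_years)
  # degenerate zero divergence
  z <- convert_age(0, 0, ck)
  expect_equal(z$age_years, 0)
  expect_equal(z$ci_high_years, 0)
})

test_that("clade dating honours the minimum-size rule and its whitelist", {
  ck <- mito_clock()
  tr <- new_mito_tree()
  tr <- tree_add_node(tr, 1L, "1000")                    # clade of 2
  tr <- tree_add_node(tr, 2L, "1100", sample_id = "A")
  tr <- tree_add_node(tr, 2L, "1200", sample_id = "B")
  tr <- tree_add_node(tr, 1L, "2000")                    # clade of 3
  tr <- tree_add_node(tr, 5L, "2100", sample_id = "C")
  tr <- tree_add_node(tr, 5L, "2200", sample_id = "D")
  tr <- tree_add_node(tr, 5L, "2300", sample_id = "E")
  tr <- label_haplogroups(tr, prefix = "HG")
  tab <- date_clades(tr, ck)
  expect_setequal(tab$label, c("HG", "HG2"))
  tab2 <- date_clades(tr, ck, include = "HG1")
  expect_true("HG1" %in% tab2$label)
  # the small clade alone falls below the default minimum
  empty <- date_clades(tr, ck, min_n = 99L)
  expect_equal(nrow(empty), 0L)
  # consistency with the rho operator
  row <- tab[tab$label == "HG2", ]
  expect_equal(row$rho, rho(tr, row$node))
  expect_equal(row$age_ka * 1000, clock_age(ck, row$rho), tolerance = 1e-8)
})

test_that("regional rho contrasts average each region's leaves only", {
  haps <- haplotype_table(
    paste0("L", 1:4),
    list("100", c("200", "201"), c("300", "301"),
         c("400", "401", "402", "403")),
    region = c("Fertile Crescent", "Fertile Crescent",
               "Arabian Peninsula", "Arabian Peninsula")
  )
  tr <- new_mito_tree()
  for (i in 1:4) {
    tr <- tree_add_node(tr, 1L, haps$variants[[i]], sample_id = paste0("L", i))
  }
  # identical distance multisets give a unit ratio
  sym <- regional_rho_ratio(tr, haps, "Fertile Crescent", "Fertile Crescent")
  expect_equal(sym, 1)
  # A distances {1,2}, B distances {2,4}: ratio 0.5
  expect_equal(regional_rho_ratio(tr, haps, "Fertile Crescent",
                                  "Arabian Peninsula"), 0.5)
  expect_error(regional_rho_ratio(tr, haps, "Europe", "Fertile Crescent"),
               "no leaves")
})

test_that("mutation counters respect context and token classes", {
  tokens <- c("16519", "16182C", "522d", "73", "152Y")
  expect_equal(mutation_counter()(tokens), 5L)
  expect_equal(mutation_counter(context = "dating")(tokens), 3L)
  expect_equal(mutation_counter(count_indels = FALSE)(tokens), 4L)
  expect_equal(mutation_counter(count_heteroplasmies = FALSE)(tokens), 4L)
})
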