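test_that("DEG calling applies the adjusted-p and fold-change thresholds", {
  tab <- data.frame(
    gene_id = c("g1", "g2", "g3", "g4", "g5"),
    log2fc = c(2, -2, 0.5, 1.5, 2),
    p = c(0.001, 0.001, 0.001, 0.001, 0.2),
    p_adj = c(0.01, 0.01, 0.01, 0.2, 0.3))
  d <- call_degs(tab)
  expect_equal(d$direction, c("up", "down", "ns", "ns", "ns"))
  # lfc threshold is configurable
  d2 <- call_degs(tab, lfc_min = 0.4)
  expect_equal(d2$direction[3], "up")
})

test_that("DEG merging intersects, excludes conflicts, and is commutative", {
  mk <- function(ids, lfc) data.frame(gene_id = ids, log2fc = lfc,
                                      p = 0.001, p_adj = 0.001)
  a <- mk(c("g1", "g2", "g3", "g6"), c(2, 2, 2, -2))
  b <- mk(c("g2", "g3", "g5", "g6"), c(2, 2, 2, 2))
  m <- merge_degs(a, b)
  expect_equal(m$common_up, c("g2", "g3"))
  expect_equal(m$n_up, 2)
  expect_equal(m$conflicts, "g6")       # down in a, up in b
  m2 <- merge_degs(b, a)
  expect_equal(m2$common_up, m$common_up)
  expect_equal(m2$common_down, m$common_down)
  expect_equal(m2$conflicts, m$conflicts)
  expect_error(merge_degs(mk("x1", 1), mk("y1", 1)), "no genes")
})

test_that("merging recovers planted common DEG sets exactly", {
  sim <- simulate_deg_tables(500, n_common_up = 25, n_common_down = 10,
                             n_only_a = 15, n_only_b = 15, n_conflict = 5,
                             seed = 99)
  m <- merge_degs(call_degs(sim$a), call_degs(sim$b))
  expect_equal(m$common_up, sort(sim$truth$common_up))
  expect_equal(m$n_up, 25)
  expect_equal(m$common_down, sort(sim$truth$common_down))
  expect_equal(m$n_down, 10)
  expect_equal(m$conflicts, sort(sim$truth$conflict))
})

test_that("candidate profile enumeration matches the combinatorial count", {
  p1 <- stem_profiles(4, 1, 5)
  expect_equal(nrow(p1$candidates), 27)
  p2 <- stem_profiles(4, 2, 50)
  expect_equal(nrow(p2$candidates), 125)
  # all candidates start at 0 with bounded steps
  expect_true(all(p2$candidates[, 1] == 0))
  expect_true(all(abs(t(apply(p2$candidates, 1, diff))) <= 2))
  # selection is deterministic and excludes the flat profile
  p2b <- stem_profiles(4, 2, 50)
  expect_identical(p2$patterns, p2b$patterns)
  expect_false(any(rowSums(p2$patterns != 0) == 0))
  expect_error(stem_profiles(4, 1, 27), "non-flat")
})

test_that("greedy profile selection agrees with a second implementation", {
  p <- stem_profiles(4, 2, 10)
  # independent re-implementation of the max-min-distance greedy
  cand <- p$candidates
  cand <- cand[order(cand[, 1], cand[, 2], cand[, 3], cand[, 4]), ]
  nonflat <- cand[rowSums(cand != 0) > 0, , drop = FALSE]
  dmat <- matrix(1, nrow(nonflat), nrow(nonflat))
  for (i in seq_len(nrow(nonflat))) {
    for (j in seq_len(nrow(nonflat))) {
      dmat[i, j] <- 1 - suppressWarnings(
        stats::cor(nonflat[i, ], nonflat[j, ]))
    }
  }
  chosen <- 1L
  while (length(chosen) < 10) {
    rem <- setdiff(seq_len(nrow(nonflat)), chosen)
    mind <- vapply(rem, function(i) min(dmat[i, chosen]), numeric(1))
    chosen <- c(chosen, rem[which.max(mind)])
  }
  expect_equal(unname(p$patterns), unname(nonflat[chosen, ]))
})

test_that("genes are assigned to the best-correlated profile", {
  profs <- stem_profiles(4, 2, 50)
  rescue <- find_profile(profs, c(0, 0, 1, 0))
  expect_false(is.na(rescue))
  # counts whose group-mean log2 change is an exact pattern match; the
  # compensating gene keeps library sizes equal so CPM of the flat gene
  # is truly constant
  groups <- rep(c("Control", "Bacterium", "Calcium", "CalciumBacterium"),
                each = 2)
  counts <- matrix(0L, 3, 8,
                   dimnames = list(c("up", "comp", "flat"), paste0("s", 1:8)))
  counts["up", ] <- rep(c(100L, 100L, 400L, 100L), each = 2)
  counts["comp", ] <- rep(c(400L, 400L, 100L, 400L), each = 2)
  counts["flat", ] <- 100L
  fit <- assign_and_test_profiles(counts, groups, profs,
                                  group_order = unique(groups),
                                  baseline = "Control")
  expect_equal(unname(fit$assignments["up"]), rescue)
  expect_true(is.na(fit$assignments["flat"]))  # zero variance -> unassigned
})

test_that("the exact permutation null matches hand enumeration", {
  # two profiles, one gene with v = (0, 0, 2, 0): of the 24 permutations,
  # those placing the single large value at a given position split evenly;
  # hand enumeration over a tiny profile set verifies expected counts
  profs <- stem_profiles(4, 1, 4)
  counts <- matrix(0L, 2, 8, dimnames = list(c("g1", "g2"), paste0("s", 1:8)))
  counts[1, ] <- rep(c(100L, 100L, 400L, 100L), each = 2)
  counts[2, ] <- rep(c(300L, 200L, 100L, 250L), each = 2)
  groups <- rep(c("A", "B", "C", "D"), each = 2)
  fit <- assign_and_test_profiles(counts, groups, profs,
                                  group_order = c("A", "B", "C", "D"),
                                  baseline = "A")
  # hand enumeration with the same assignment rule, gene by gene
  vm <- group_log_means(counts, groups)
  vm <- vm - vm[, "A"]
  allperm <- expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4)
  allperm <- allperm[apply(allperm, 1, function(x) length(unique(x)) == 4), ]
  hand <- numeric(nrow(profs$patterns))
  for (g in 1:2) {
    for (k in seq_len(nrow(allperm))) {
      vp <- vm[g, as.integer(allperm[k, ])]
      if (stats::sd(vp) == 0) next
      rs <- apply(profs$patterns, 1, function(p) stats::cor(vp, p))
      hand[which.max(rs)] <- hand[which.max(rs)] + 1 / 24
    }
  }
  expect_equal(fit$table$expected, hand)
  # expected proportions over profiles + unassigned cover each gene once
  expect_lte(sum(fit$table$expected), nrow(counts) + 1e-12)
})

test_that("planted rescue-profile genes are detected as significant", {
  sim <- simulate_counts(
    2000, planted_profiles = list(list(pattern = c(0, 0, 1, 0), n = 200,
                                       effect = 2)),
    dispersion = 0.1, seed = 33)
  profs <- stem_profiles(4, 2, 50)
  fit <- assign_and_test_profiles(sim$counts, sim$groups, profs,
                                  group_order = sim$group_order,
                                  baseline = "Control")
  rescue <- find_profile(profs, c(0, 0, 1, 0))
  row <- fit$table[fit$table$profile_id == rescue, ]
  expect_true(row$significant)
  expect_gt(row$n_assigned, row$expected)
  planted <- sim$truth$planted_profile_gene_ids[["0,0,1,0"]]
  # most planted genes land on the rescue profile or a near neighbour
  assigned <- fit$assignments[planted]
  expect_gt(mean(assigned == rescue, na.rm = TRUE), 0.5)
  # oracle re-assignment loop agrees with the vectorized path
  s <- group_log_means(sim$counts, sim$groups, sim$group_order)
  v <- s - s[, "Control"]
  for (g in sample(rownames(v), 50)) {
    rs <- apply(profs$patterns, 1, function(p) stats::cor(v[g, ], p))
    want <- if (stats::sd(v[g, ]) == 0) NA_character_ else
      rownames(profs$patterns)[which.max(rs)]
    expect_equal(unname(fit$assignments[g]), want)
  }
})

test_that("pure-noise counts rarely flag the rescue profile", {
  profs <- stem_profiles(4, 2, 50)
  rescue <- find_profile(profs, c(0, 0, 1, 0))
  hits <- 0
  for (seed in 1:20) {
    sim <- simulate_counts(300, dispersion = 0.1, seed = seed)
    fit <- assign_and_test_profiles(sim$counts, sim$groups, profs,
                                    group_order = sim$group_order,
                                    baseline = "Control")
    if (fit$table$significant[fit$table$profile_id == rescue]) {
      hits <- hits + 1
    }
  }
  expect_lte(hits, 2)
})

test_that("ddCt fold changes match hand computation and invariances", {
  ct <- data.frame(
    sample = rep(c("c1", "c2", "t1", "t2"), each = 2),
    group = rep(c("Control", "Control", "Treat", "Treat"), each = 2),
    gene = rep(c("tgt", "ref"), 4),
    ct = c(20, 17, 20, 17, 22, 17, 19, 17))
  dd <- ddct_fold_change(ct, "tgt", "ref", "Control")
  expect_equal(dd$fold[dd$sample == "c1"], 1)       # at control mean
  expect_equal(dd$fold[dd$sample == "t1"], 0.25)    # ddCt = +2
  expect_equal(dd$fold[dd$sample == "t2"], 2)       # ddCt = -1
  # adding a constant to both target and reference leaves folds unchanged
  ct2 <- ct
  ct2$ct <- ct2$ct + 3
  expect_equal(ddct_fold_change(ct2, "tgt", "ref", "Control")$fold, dd$fold)
  # control-group folds multiply to 1 (geometric mean 1 by construction)
  expect_equal(prod(dd$fold[dd$group == "Control"]), 1)
  # samples without a reference Ct are dropped with a warning
  ct3 <- ct[-(6), ]
  expect_warning(dd3 <- ddct_fold_change(ct3, "tgt", "ref", "Control"),
                 "without reference")
  expect_false("t1" %in% dd3$sample)
  expect_error(ddct_fold_change(ct, "absent", "ref", "Control"), "no Ct rows")
})
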