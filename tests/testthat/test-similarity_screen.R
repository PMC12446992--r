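test_that("RSCU matrix rows equal per-gene RSCU and flag absent families", {
  gc <- standard_genetic_code()
  set.seed(7)
  counts <- t(vapply(1:50, function(i) random_gene_counts(150), numeric(64)))
  storage.mode(counts) <- "integer"
  rownames(counts) <- sprintf("g%02d", 1:50)
  m <- build_rscu_matrix(counts)
  expect_length(m$codon_order, 59)
  for (i in c(1, 25, 50)) {
    expect_equal(m$values[i, ], rscu(counts[i, ])[m$codon_order],
                 ignore_attr = TRUE)
  }
  # uniform usage -> row of 1s
  u <- matrix(5L, 1, 64, dimnames = list("u", gc$codons))
  u[1, gc$is_stop] <- 0L
  expect_equal(unname(build_rscu_matrix(u)$values[1, ]), rep(1, 59))
  # gene missing the Cys family -> TGT/TGC flagged, 57 usable codons
  nocys <- counts[1, , drop = FALSE]
  nocys[, c("TGT", "TGC")] <- 0L
  # rebuild with every other family guaranteed present
  full <- random_gene_counts(5000)
  full[c("TGT", "TGC")] <- 0
  fm <- matrix(full, 1, 64, dimnames = list("nc", gc$codons))
  r <- build_rscu_matrix(fm)
  expect_true(all(is.na(r$values[1, c("TGT", "TGC")])))
  expect_equal(sum(!is.na(r$values[1, ])), 57)
  expect_error(build_rscu_matrix(matrix(0L, 0, 64)), "nonempty")
})

test_that("screen selects exact matches and rejects anti-biased genes", {
  set.seed(9)
  profile_counts <- random_gene_counts(50000)
  prof <- organism_rscu(profile_counts)
  gc <- standard_genetic_code()
  # a gene whose RSCU equals the profile: counts proportional to profile
  g <- stats::setNames(numeric(64), gc$codons)
  for (a in names(gc$families)) {
    fam <- gc$families[[a]]
    g[fam] <- round(profile_counts[fam] / 10)
  }
  m1 <- matrix(g, 1, 64, dimnames = list("match", gc$codons))
  # reflect the profile about 1 within each family (anti-bias)
  ganti <- stats::setNames(numeric(64), gc$codons)
  for (a in names(gc$families)) {
    fam <- gc$families[[a]]
    tot <- sum(profile_counts[fam])
    anti_freq <- 2 / length(fam) - profile_counts[fam] / tot
    anti_freq <- pmax(anti_freq, 0)
    ganti[fam] <- round(anti_freq * 1000)
  }
  m2 <- matrix(ganti, 1, 64, dimnames = list("anti", gc$codons))
  res <- screen_genes(build_rscu_matrix(rbind(m1, m2)), prof)
  expect_gt(res$r[res$gene_id == "match"], 0.99)
  expect_true(res$selected[res$gene_id == "match"])
  expect_lt(res$r[res$gene_id == "anti"], 0)
  expect_false(res$selected[res$gene_id == "anti"])
  # output sorted by descending r
  expect_equal(res$gene_id, c("match", "anti"))
})

test_that("screen p-values are centred under the null and r near zero", {
  # genes simulated independently of the partner profile: the selection
  # rule (r >= 0.5 and p < 0.05) should fire essentially never, and the
  # r distribution should be centred on zero. (Exact p uniformity does
  # not hold: RSCU entries are linearly constrained within families, so
  # the t reference is mildly anticonservative — see the vignette.)
  own <- codon_model(401, gc3_bias = 0.5, preference_strength = 1e6)
  partner <- codon_model(402, gc3_bias = 0.5, preference_strength = 1e6)
  cds <- generate_cds_set(own, n_genes = 1000, seed = 403,
                          length_meanlog = log(200))
  counts <- count_codons(cds$sequences)
  partner_cds <- generate_cds_set(partner, n_genes = 300, seed = 404)
  prof <- organism_rscu(count_codons(partner_cds$sequences))
  res <- screen_genes(build_rscu_matrix(counts), prof)
  expect_lt(mean(res$selected), 0.01)
  expect_lt(abs(mean(res$r)), 0.05)
  # p and r are consistent: larger |r| gives smaller p
  ord <- order(abs(res$r))
  expect_gt(stats::cor(abs(res$r), -log10(res$p), method = "spearman"), 0.99)
})

test_that("sensitivity and specificity match an oracle rerun exactly", {
  own <- codon_model(21, gc3_bias = 0.35, preference_strength = 3)
  partner <- codon_model(22, gc3_bias = 0.6, preference_strength = 3)
  cds <- generate_cds_set(own, n_genes = 1000, partner_model = partner,
                          n_planted = 100, lambda = 0.9, seed = 23)
  counts <- count_codons(cds$sequences)
  partner_cds <- generate_cds_set(partner, n_genes = 500, seed = 24,
                                  id_prefix = "p")
  prof <- organism_rscu(count_codons(partner_cds$sequences))
  m <- build_rscu_matrix(counts)
  res <- screen_genes(m, prof)
  planted <- cds$truth$planted_similar_gene_ids
  sens <- mean(res$selected[match(planted, res$gene_id)])
  spec <- mean(!res$selected[!res$gene_id %in% planted])
  # oracle: independent correlation + t-test over all genes
  osel <- vapply(rownames(m$values), function(g) {
    o <- oracle_pearson(m$values[g, ], prof[m$codon_order])
    o[["n"]] >= 10 && o[["r"]] >= 0.5 && o[["p"]] < 0.05
  }, logical(1))
  expect_equal(sens, mean(osel[planted]))
  expect_equal(spec, mean(!osel[setdiff(names(osel), planted)]))
  expect_gt(sens, spec - 1)  # guard: both defined
})

test_that("planted-gene recovery is monotone in the mixing weight", {
  partner <- codon_model(62, gc3_bias = 0.62, preference_strength = 3)
  partner_cds <- generate_cds_set(partner, n_genes = 400, seed = 63,
                                  id_prefix = "p")
  prof <- organism_rscu(count_codons(partner_cds$sequences))
  sens <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(lam) {
    own <- codon_model(61, gc3_bias = 0.35, preference_strength = 3)
    cds <- generate_cds_set(own, n_genes = 300, partner_model = partner,
                            n_planted = 100, lambda = lam, seed = 64)
    res <- screen_genes(build_rscu_matrix(count_codons(cds$sequences)), prof)
    mean(res$selected[match(cds$truth$planted_similar_gene_ids,
                            res$gene_id)])
  }, numeric(1))
  expect_true(all(diff(sens) >= 0))
  expect_gt(sens[5], sens[1])
})

test_that("self-profile screening selects at least as many as a foreign one", {
  own <- codon_model(71, gc3_bias = 0.4, preference_strength = 2)
  other <- codon_model(72, gc3_bias = 0.65, preference_strength = 2)
  cds <- generate_cds_set(own, n_genes = 400, seed = 73)
  counts <- count_codons(cds$sequences)
  m <- build_rscu_matrix(counts)
  self_sel <- mean(screen_genes(m, organism_rscu(counts))$selected)
  other_cds <- generate_cds_set(other, n_genes = 400, seed = 74,
                                id_prefix = "o")
  other_sel <- mean(screen_genes(
    m, organism_rscu(count_codons(other_cds$sequences)))$selected)
  expect_gte(self_sel, other_sel)
})

test_that("best-gene mode reports the most correlated partner gene", {
  set.seed(81)
  counts <- t(vapply(1:5, function(i) random_gene_counts(200), numeric(64)))
  storage.mode(counts) <- "integer"
  rownames(counts) <- paste0("q", 1:5)
  pcounts <- counts
  rownames(pcounts) <- paste0("p", 1:5)
  qm <- build_rscu_matrix(counts)
  pm <- build_rscu_matrix(pcounts)
  res <- screen_genes(qm, pm, mode = "best-gene")
  # each query gene's best partner is its own copy, at r = 1
  expect_equal(res$partner_id[match(paste0("q", 1:5), res$gene_id)],
               paste0("p", 1:5))
  expect_true(all(res$r > 0.999))
})
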