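test_that("leaf depths count edges from the root", {
  tr <- read_tree(text = "((A,B),C);")
  expect_equal(leaf_depths(tr), c(A = 2L, B = 2L, C = 1L))
  # random trees agree with an independent root-to-leaf walking oracle
  set.seed(3)
  for (rep in 1:10) {
    tr <- random_tree(sprintf("t%02d", 1:50))
    expect_equal(leaf_depths(tr), oracle_leaf_depths(tr))
  }
})

test_that("viral clusters are the maximal viral-only clades", {
  rec <- records_for(c("v1", "v2", "m1", "m2"))
  # no viral leaves -> no clusters
  tr0 <- read_tree(text = "((m1,m2),(m1b,m2b));")
  expect_equal(nrow(find_viral_clusters(tr0, records_for(tr0$tip.label))), 0L)
  # forced single VC of two leaves at depth 1
  tr <- read_tree(text = "((v1,v2),(m1,m2));")
  vc <- find_viral_clusters(tr, rec)
  expect_equal(nrow(vc), 1L)
  expect_equal(vc$depth, 1L)
  expect_equal(vc$n_leaves, 2L)
  expect_setequal(vc$leaf_ids[[1L]], c("v1", "v2"))
  # a lone viral leaf with a non-viral sibling is a size-1 VC
  tr2 <- read_tree(text = "((v1,m1),(v2,(m2,v3)));")
  vc2 <- find_viral_clusters(tr2, rec2 <- records_for(tr2$tip.label))
  expect_equal(nrow(vc2), 3L)
  expect_true(all(vc2$n_leaves == 1L))
  # unresolvable leaf
  expect_error(find_viral_clusters(tr, rec[1:3, ]), "does not resolve")
})

test_that("VC enumeration matches the exhaustive per-node oracle with the
           partition and maximality invariants", {
  set.seed(17)
  for (rep in 1:200) {
    n <- sample(4:20, 1L)
    labels <- sprintf("%s%02d", sample(c("v", "m"), n, replace = TRUE,
                                       prob = c(0.35, 0.65)), 1:n)
    tr <- random_tree(labels)
    rec <- records_for(labels)
    vc <- find_viral_clusters(tr, rec)
    got <- vapply(vc$leaf_ids, function(x) paste(sort(x), collapse = ","), "")
    want <- vapply(oracle_viral_clusters(tr, rec), paste, "", collapse = ",")
    expect_setequal(got, want)
    # partition: disjoint cover of the viral leaves
    all_ids <- as.character(unlist(vc$leaf_ids))
    expect_equal(anyDuplicated(all_ids), 0L)
    expect_setequal(all_ids, grep("^v", labels, value = TRUE))
  }
})

test_that("normalized depths reproduce the 9/19 and 4/19 worked example", {
  tr <- caterpillar_tree(19L)
  expect_equal(max(leaf_depths(tr)), 19L)
  expect_equal(normalized_depth(tr, "L09"), 9 / 19)
  expect_equal(round(normalized_depth(tr, "L09"), 3), 0.474)
  expect_equal(normalized_depth(tr, "L04"), 4 / 19)
  expect_equal(round(normalized_depth(tr, "L04"), 3), 0.211)
  # the deepest leaf always normalizes to 1
  expect_equal(normalized_depth(tr, "L19a"), 1)
  # a VC that is a single leaf has that leaf's normalized depth
  labs <- sub("^L", "m", tr$tip.label)
  labs[labs == "m04"] <- "v04"
  rec <- records_for(labs)
  tr2 <- tr; tr2$tip.label <- labs
  vc <- find_viral_clusters(tr2, rec)
  expect_equal(nrow(vc), 1L)
  expect_equal(vc_depth(tr2, vc), normalized_depth(tr2, "v04"))
  # single-leaf-depth degenerate tree
  expect_error(normalized_depth(read_tree(text = "(A,B);"), "A"), NA)
  cherry <- read_tree(text = "(A,B);")
  expect_equal(normalized_depth(cherry, "A"), 1)
})

test_that("family classification applies the two-clause selection rule", {
  th <- selection_thresholds()
  # IL-6-like counts: 10 viral of 146 leaves, 2 VCs; fraction 0.068 > 0.05
  # and 10 > 2, so under the default thresholds the family is NOT selected
  labels <- c(sprintf("v%03d", 1:10), sprintf("m%03d", 1:136))
  set.seed(1)
  tr <- random_tree(sample(labels))
  rep1 <- classify_family(tr, records_for(labels), th, family_id = "PF00489")
  expect_equal(rep1$n_viral, 10L)
  expect_equal(rep1$viral_fraction, 10 / 146)
  expect_false(rep1$viral_fraction <= th$max_viral_fraction)
  expect_false(rep1$selected)
  expect_match(rep1$selection_reason, "not marginal")

  # 1 viral of 200, 1 VC -> selected by count override and simple clause
  labels2 <- c("v001", sprintf("m%03d", 1:199))
  tr2 <- random_tree(sample(labels2))
  rep2 <- classify_family(tr2, records_for(labels2), th)
  expect_equal(rep2$n_vc, 1L)
  expect_true(rep2$selected)

  # 12 viral of 1000 (fraction 0.012), 4 VCs, condensation 3 -> selected
  # via the condensed clause; built by grafting 4 viral triplets onto a
  # 988-leaf metazoan backbone
  met <- sprintf("m%03d", 1:988)
  s <- sprintf("(%s,%s)", met[987L], met[988L])
  for (i in rev(seq_len(986L))) s <- sprintf("(%s,%s)", met[i], s)
  for (g in 1:4) {
    anchor <- met[g * 200L]
    clade <- sprintf("(v%02d,(v%02d,v%02d))", 3 * g - 2, 3 * g - 1, 3 * g)
    s <- sub(anchor, sprintf("(%s,%s)", clade, anchor), s, fixed = TRUE)
  }
  tr3 <- read_tree(text = paste0(s, ";"))
  rep3 <- classify_family(tr3, records_for(tr3$tip.label), th)
  expect_equal(rep3$n_viral, 12L)
  expect_equal(rep3$n_vc, 4L)
  expect_true(rep3$condensation >= 3)
  expect_true(rep3$viral_fraction <= 0.05)
  expect_true(rep3$selected)
  expect_match(rep3$selection_reason, "condensed")

  # invariants of the report
  expect_true(all(rep3$normalized_viral_depths > 0 &
                    rep3$normalized_viral_depths <= 1))
  expect_true(rep3$condensation >= 1)
  expect_true(rep3$n_vc <= rep3$n_viral)
  # a family with no viral leaves is an error
  trm <- read_tree(text = "((m1,m2),m3);")
  expect_error(classify_family(trm, records_for(trm$tip.label), th),
               "no viral leaves")
})

test_that("planted-clustered cohorts separate viral depths more than random
           labelling (KS contrast)", {
  p <- cohort_params(n_families = 30L,
                     members_per_family = c(metazoa = 20, virus = 4),
                     tree_model = list(n_viral_clades = 1L, topology = "yule"),
                     seed = 31L)
  out <- generate_cohort(p, file.path(tempdir(), "depth_cohort"))
  mem <- read_membership_table(out$paths$members)
  set.seed(31)
  viral_d <- c(); all_d <- c(); viral_d_rand <- c()
  for (fam in family_ids(mem)) {
    tr <- read_tree(file.path(out$paths$trees, paste0(fam, ".nwk")))
    d <- leaf_depths(tr)
    mx <- max(d)
    cls <- mem$records$taxon_class[match(names(d), mem$records$protein_id)]
    viral_d <- c(viral_d, d[cls == "virus"] / mx)
    all_d <- c(all_d, d / mx)
    # random relabelling: same tree, same class counts, shuffled positions
    cls_r <- sample(cls)
    viral_d_rand <- c(viral_d_rand, d[cls_r == "virus"] / mx)
  }
  D_planted <- ks_two_sample(viral_d, all_d)$statistic
  D_random <- ks_two_sample(viral_d_rand, all_d)$statistic
  expect_gt(D_planted, D_random)
})
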