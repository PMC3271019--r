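mk_hits <- function(protein_id, start, end, score = NA_real_,
                    domain_id = sprintf("D%d", seq_along(start))) {
  data.frame(protein_id = protein_id, domain_id = domain_id,
             start = as.integer(start), end = as.integer(end),
             score = as.numeric(score), stringsAsFactors = FALSE)
}

test_that("overlap resolution keeps the greedy best-scoring compatible set", {
  # disjoint hits are all retained
  h <- mk_hits("P", c(10, 50), c(20, 80), c(5, 9))
  expect_equal(nrow(resolve_overlaps(h)), 2L)
  # the higher-scoring of two overlapping hits wins
  h2 <- mk_hits("P", c(10, 70), c(80, 120), c(50, 30))
  r2 <- resolve_overlaps(h2)
  expect_equal(nrow(r2), 1L)
  expect_equal(r2$start, 10L)
  # random hit sets match the exhaustive maximal-subset oracle
  set.seed(7)
  for (rep in 1:60) {
    n <- sample(2:8, 1L)
    start <- sample(1:150, n)
    h <- mk_hits("P", start, start + sample(5:60, n, replace = TRUE),
                 score = ifelse(runif(n) < 0.2, NA, round(runif(n, 1, 99))))
    got <- resolve_overlaps(h)
    want <- h[oracle_resolve_overlaps(h), , drop = FALSE]
    want <- want[order(want$start), , drop = FALSE]
    rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("decomposition splits tails, domains and linkers conservatively", {
  rec <- data.frame(protein_id = "P", length = 100L)
  # single full-length domain: zero tails, no IDOL
  d1 <- decompose_architecture(rec, mk_hits("P", 1, 100))
  expect_equal(d1$n_tail_len, 0L)
  expect_equal(d1$c_tail_len, 0L)
  expect_equal(d1$idol_lens, integer(0))
  expect_equal(tail_length(d1), 0)
  expect_true(is.na(idol_length(d1)))
  # two domains 21-40 and 61-90: tails 20/10, one IDOL of 20
  d2 <- decompose_architecture(rec, mk_hits("P", c(21, 61), c(40, 90)))
  expect_equal(d2$n_tail_len, 20L)
  expect_equal(d2$c_tail_len, 10L)
  expect_equal(d2$idol_lens, 20L)
  expect_equal(d2$n_tail_len + d2$c_tail_len + sum(d2$idol_lens) +
                 sum(d2$domain_segments$end - d2$domain_segments$start + 1L),
               100L)
  expect_equal(tail_length(d2), 15)
  expect_equal(idol_length(d2), 20)
  # a 701-aa protein with FYVE then a kinase domain has exactly one IDOL
  rec3 <- data.frame(protein_id = "Q5UR69", length = 701L)
  d3 <- decompose_architecture(rec3, mk_hits("Q5UR69", c(12, 420), c(80, 690),
                                             domain_id = c("FYVE",
                                                           "PI3_PI4_kinase")))
  expect_length(d3$idol_lens, 1L)
  expect_equal(architecture_string(d3), c("FYVE", "PI3_PI4_kinase"))
  # zero hits: decomposition undefined
  expect_error(decompose_architecture(rec, mk_hits("OTHER", 1, 10)),
               "no domain hits")
  # one-sided tail enters the mean
  d4 <- decompose_architecture(rec, mk_hits("P", 1, 60))
  expect_equal(tail_length(d4), 20)
  # multi-linker mean
  d5 <- decompose_architecture(
    data.frame(protein_id = "P", length = 300L),
    mk_hits("P", c(1, 61, 141, 212), c(50, 100, 180, 240)))
  expect_equal(d5$idol_lens, c(10L, 40L, 31L))
  expect_equal(idol_length(d5), mean(c(10, 40, 31)))
})

test_that("segment lengths always sum to protein length on generated proteins", {
  p <- cohort_params(n_families = 10L,
                     members_per_family = c(metazoa = 15, virus = 5),
                     seed = 13L)
  out <- generate_cohort(p, file.path(tempdir(), "conservation_unit"))
  mem <- read_membership_table(out$paths$members)
  hits <- read_domain_annotations(out$paths$domains)
  dec <- decompose_all(mem$records, hits)
  expect_equal(dec$n_without_hits, 0L)
  for (d in dec$decompositions) {
    expect_equal(d$n_tail_len + d$c_tail_len + sum(d$idol_lens) +
                   sum(d$domain_segments$end - d$domain_segments$start + 1L),
                 d$length)
  }
})

test_that("removing an internal domain shortens the protein, never the tails", {
  rec <- data.frame(protein_id = "P", length = 300L)
  h_full <- mk_hits("P", c(11, 101, 201), c(60, 150, 280),
                    domain_id = c("A", "B", "C"))
  full <- decompose_architecture(rec, h_full)
  # drop domain B and close the gap: the remainder shifts left by B's span
  shift <- (150 - 101 + 1) + full$idol_lens[2L]
  h_less <- mk_hits("P", c(11, 201 - shift), c(60, 280 - shift),
                    domain_id = c("A", "C"))
  rec_less <- data.frame(protein_id = "P", length = 300L - shift)
  less <- decompose_architecture(rec_less, h_less)
  expect_lt(less$length, full$length)
  expect_lt(nrow(less$domain_segments), nrow(full$domain_segments))
  expect_equal(less$n_tail_len, full$n_tail_len)
  expect_equal(less$c_tail_len, full$c_tail_len)
})

test_that("internal-domain loss is called only with preserved flanks", {
  # the kinase worked example and its anti-symmetry
  loss <- detect_internal_loss(c("FYVE", "PI3_PI4_kinase"),
                               c("FYVE", "PI3Ka", "PI3_PI4_kinase"))
  expect_equal(loss$domain_id, "PI3Ka")
  expect_equal(loss$host_position, 2L)
  expect_equal(nrow(detect_internal_loss(c("FYVE", "PI3Ka", "PI3_PI4_kinase"),
                                         c("FYVE", "PI3_PI4_kinase"))), 0L)
  # identical architectures: nothing lost
  expect_equal(nrow(detect_internal_loss(c("A", "B"), c("A", "B"))), 0L)
  # order not preserved: no call
  expect_equal(nrow(detect_internal_loss(c("A", "C"), c("C", "A", "B"))), 0L)
  # flank mismatch: no call
  expect_equal(nrow(detect_internal_loss(c("A", "B"), c("A", "B", "C"))), 0L)
  # multiple internal losses
  loss2 <- detect_internal_loss(c("A", "E"), c("A", "B", "C", "D", "E"))
  expect_equal(loss2$host_position, 2:4)
  # repeats: the viral copy count must be embeddable
  expect_equal(detect_internal_loss(c("A", "A"), c("A", "B", "A"))$domain_id,
               "B")
})

test_that("family summaries recover planted class contrasts", {
  # all-identical proteins give unit M/V ratios
  rec <- records_for(c("v1", "m1"), lengths = 200L)
  hits <- rbind(mk_hits("v1", c(21, 101), c(80, 180), domain_id = c("X", "Y")),
                mk_hits("m1", c(21, 101), c(80, 180), domain_id = c("X", "Y")))
  dec <- decompose_all(rec, hits)
  s <- summarize_family_architecture("F", c("v1", "m1"), rec,
                                     dec$decompositions)
  expect_equal(s$ratio_length_m_over_v, 1)
  expect_equal(s$ratio_distinct_domains_m_over_v, 1)
  expect_false(s$viral_shorter)

  # planted means 912 vs 503 aa at n = 200/class recover a ratio near 1.81
  set.seed(29)
  n <- 200L
  vlen <- pmax(60L, as.integer(round(rnorm(n, 503, 80))))
  mlen <- pmax(60L, as.integer(round(rnorm(n, 912, 120))))
  ids <- c(sprintf("v%03d", 1:n), sprintf("m%03d", 1:n))
  rec2 <- records_for(ids, lengths = c(vlen, mlen))
  hits2 <- do.call(rbind, lapply(seq_along(ids), function(i)
    mk_hits(ids[i], 11, rec2$length[i] - 10L, domain_id = "CORE")))
  dec2 <- decompose_all(rec2, hits2)
  s2 <- summarize_family_architecture("F2", ids, rec2, dec2$decompositions)
  expect_equal(s2$ratio_length_m_over_v, 912 / 503, tolerance = 0.05)
  expect_true(s2$viral_shorter)

  # single-domain viral vs 3-domain metazoan proteins: distinct-domain ratio 3
  rec3 <- records_for(c("v1", "v2", "m1", "m2"), lengths = 400L)
  hits3 <- rbind(
    mk_hits("v1", 51, 150, domain_id = "A"),
    mk_hits("v2", 51, 150, domain_id = "A"),
    mk_hits("m1", c(51, 161, 271), c(150, 260, 370),
            domain_id = c("A", "B", "C")),
    mk_hits("m2", c(51, 161, 271), c(150, 260, 370),
            domain_id = c("A", "B", "C")))
  dec3 <- decompose_all(rec3, hits3)
  s3 <- summarize_family_architecture("F3", rec3$protein_id, rec3,
                                      dec3$decompositions)
  expect_equal(s3$ratio_distinct_domains_m_over_v, 3)
  # members without hits are excluded but counted
  rec4 <- rbind(rec3, records_for("m9", 100L))
  s4 <- summarize_family_architecture("F4", rec4$protein_id, rec4,
                                      dec3$decompositions)
  expect_equal(s4$n_excluded_no_hits, 1L)
  # a class with zero members leaves its block and the ratios absent
  s5 <- summarize_family_architecture("F5", c("m1", "m2"), rec3,
                                      dec3$decompositions)
  expect_null(s5$virus)
  expect_true(is.na(s5$ratio_length_m_over_v))
})

test_that("short-IDOL excess of viral proteins emerges at planted paper scales", {
  p <- cohort_params(n_families = 40L,
                     members_per_family = c(metazoa = 8, virus = 5),
                     domain_loss_prob = 0,
                     seed = 37L)
  out <- generate_cohort(p, file.path(tempdir(), "idol_cohort"))
  mem <- read_membership_table(out$paths$members)
  hits <- read_domain_annotations(out$paths$domains)
  dec <- decompose_all(mem$records, hits)
  tab <- protein_architecture_table(mem$records, dec$decompositions)
  tab <- tab[!is.na(tab$idol_mean), , drop = FALSE]
  f_v <- mean(tab$idol_mean[tab$taxon_class == "virus"] < 40)
  f_m <- mean(tab$idol_mean[tab$taxon_class == "metazoa"] < 40)
  expect_gt(f_v, f_m)
})
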