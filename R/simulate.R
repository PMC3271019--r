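#' Parameters for a synthetic cross-taxa cohort
#'
#' Describes a cohort of cross-taxa protein families with planted effect
#' sizes: families dominated by multi-domain metazoan proteins with a small
#' viral fraction; viral members derived from the host architecture by
#' dropping internal domains and redrawing shorter linkers; family trees in
#' which the viral leaves form a planted number of clades.
#'
#' Defaults are the reported corpus scales: metazoan TAIL mean 85 aa vs
#' viral 14 aa, metazoan IDOL mean 67 aa vs viral 30 aa; host architectures
#' average 4.6 domains of ~120 aa, and an internal-domain loss probability
#' of 0.65 brings the viral average to ~2.9 domains. Linker lengths are
#' geometric by default (discrete, mode at short lengths, matching the
#' observed heavy-at-zero linker histograms); a discretized gamma is
#' offered as a smoother alternative.
#'
#' @param n_families Number of families.
#' @param members_per_family Named numeric vector `c(metazoa = , virus = )`
#'   of mean member counts per family.
#' @param viral_fraction_target Optional target viral fraction; when set it
#'   overrides the viral mean via `f/(1-f)` times the metazoan count.
#' @param n_cross_taxa Number of families given cross-taxa composition
#'   (both classes, size >= 2); the remainder are degenerate families
#'   (singletons or metazoan-only) that the filters should remove.
#'   `NULL` (default) makes every family cross-taxa.
#' @param host_architecture List: `n_domains_mean`, `domain_len_mean` (aa),
#'   `domain_len_sd` (aa).
#' @param linker_model List: `metazoan_tail_mean`, `viral_tail_mean`,
#'   `metazoan_idol_mean`, `viral_idol_mean` (aa) and `distribution`
#'   (`"geometric"` or `"gamma"`).
#' @param domain_loss_prob Probability that each internal domain of the
#'   host architecture is absent from a viral member (flanks always kept).
#' @param tree_model List: `n_viral_clades` (planted VC count per family),
#'   `topology` (`"yule"` or `"caterpillar"`).
#' @param with_sequences Emit random amino-acid sequences.
#' @param seed Integer seed; fixed seed implies byte-identical output.
#' @return A list of class `"cohort_params"`.
#' @export
cohort_params <- function(n_families = 20L,
                          members_per_family = c(metazoa = 15, virus = 3),
                          viral_fraction_target = NULL,
                          n_cross_taxa = NULL,
                          host_architecture = list(n_domains_mean = 4.6,
                                                   domain_len_mean = 120,
                                                   domain_len_sd = 30),
                          linker_model = list(metazoan_tail_mean = 85,
                                              viral_tail_mean = 14,
                                              metazoan_idol_mean = 67,
                                              viral_idol_mean = 30,
                                              distribution = "geometric"),
                          domain_loss_prob = 0.65,
                          tree_model = list(n_viral_clades = 2L,
                                            topology = "yule"),
                          with_sequences = FALSE,
                          seed = 1L) {
  stopifnot(n_families >= 0,
            all(members_per_family > 0),
            domain_loss_prob >= 0, domain_loss_prob <= 1,
            host_architecture$n_domains_mean > 0,
            host_architecture$domain_len_mean > 0,
            all(unlist(linker_model[c("metazoan_tail_mean", "viral_tail_mean",
                                      "metazoan_idol_mean",
                                      "viral_idol_mean")]) > 0),
            tree_model$n_viral_clades >= 1)
  linker_model$distribution <- match.arg(linker_model$distribution,
                                         c("geometric", "gamma"))
  tree_model$topology <- match.arg(tree_model$topology,
                                   c("yule", "caterpillar"))
  if (tree_model$n_viral_clades > members_per_family[["virus"]])
    stop("infeasible parameters: more planted viral clades than the mean ",
         "number of viral proteins per family", call. = FALSE)
  if (!is.null(n_cross_taxa) && n_cross_taxa > n_families)
    stop("n_cross_taxa cannot exceed n_families", call. = FALSE)
  structure(list(n_families = as.integer(n_families),
                 members_per_family = members_per_family,
                 viral_fraction_target = viral_fraction_target,
                 n_cross_taxa = if (is.null(n_cross_taxa)) as.integer(n_families)
                                else as.integer(n_cross_taxa),
                 host_architecture = host_architecture,
                 linker_model = linker_model,
                 domain_loss_prob = domain_loss_prob,
                 tree_model = tree_model,
                 with_sequences = with_sequences,
                 seed = as.integer(seed)),
            class = "cohort_params")
}

# one linker-length draw vectorized over n
.draw_linker <- function(n, mean, distribution) {
  if (n == 0L) return(integer(0))
  if (distribution == "geometric")
    stats::rgeom(n, prob = 1 / (mean + 1))
  else
    as.integer(round(stats::rgamma(n, shape = 2, scale = mean / 2)))
}

.rand_seq <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]], n, replace = TRUE),
        collapse = "")
}

# Yule topology over equal-width labels: start from the first label and
# repeatedly split a uniformly chosen placed leaf into a cherry.
.yule_newick <- function(labels) {
  n <- length(labels)
  if (n == 1L) return(labels)
  s <- sprintf("(%s,%s)", labels[1L], labels[2L])
  placed <- labels[1:2]
  for (i in seq_len(n - 2L) + 2L) {
    pick <- placed[sample.int(length(placed), 1L)]
    s <- sub(pick, sprintf("(%s,%s)", pick, labels[i]), s, fixed = TRUE)
    placed <- c(placed, labels[i])
  }
  s
}

.caterpillar_newick <- function(labels) {
  n <- length(labels)
  if (n == 1L) return(labels)
  s <- sprintf("(%s,%s)", labels[n - 1L], labels[n])
  for (i in rev(seq_len(n - 2L))) s <- sprintf("(%s,%s)", labels[i], s)
  s
}

#' Generate one synthetic cross-taxa family
#'
#' Draws a family architecture (ordered domains with fixed per-domain
#' lengths shared by both classes — domain lengths themselves are not
#' planted to differ), metazoan proteins realizing it with metazoan-model
#' linkers, and viral proteins derived by dropping each internal domain
#' with `domain_loss_prob` and redrawing all linkers from the viral model.
#' The family tree places the viral leaves in exactly
#' `tree_model$n_viral_clades` clades, each grafted as the sister of a
#' distinct metazoan leaf, so viral-cluster detection must recover the
#' planted count.
#'
#' Uses the current RNG state; seed once per cohort (see
#' [generate_cohort()]) or call `set.seed()` yourself for reproducibility.
#'
#' @param params A [cohort_params()].
#' @param family_index 1-based family number (used for ids).
#' @param cross_taxa Generate a proper cross-taxa family (default); when
#'   `FALSE` a degenerate family (singleton or metazoan-only) is produced.
#' @return List with `family_id`, `members` (data.frame rows for the
#'   membership table), `hits` (domain-hit data.frame), `newick` (tree
#'   string), `tree` ([ape::phylo]), and `truth` (planted ground truth:
#'   clade count, architecture, per-protein lost domains, linker means).
#' @export
generate_family <- function(params, family_index, cross_taxa = TRUE) {
  fam <- sprintf("FAM%04d", family_index)
  lm <- params$linker_model
  ha <- params$host_architecture

  if (!cross_taxa) {
    # degenerate families exercise the filter cascade: odd indices give a
    # singleton, even indices a metazoan-only pair
    n <- if (family_index %% 2L == 1L) 1L else 2L
    ids <- sprintf("%s_m%03d", fam, seq_len(n))
    len <- 100L + stats::rpois(n, 200)
    members <- data.frame(family_id = fam, protein_id = ids,
                          species = sprintf("metazoa_sp%02d", seq_len(n)),
                          taxon_class = "metazoa", length = len,
                          stringsAsFactors = FALSE)
    nwk <- if (n == 1L) sprintf("(%s);", ids) else
      sprintf("(%s,%s);", ids[1L], ids[2L])
    return(list(family_id = fam, members = members,
                hits = data.frame(protein_id = character(),
                                  domain_id = character(), start = integer(),
                                  end = integer(), score = numeric()),
                newick = nwk, tree = NULL,
                truth = list(family_id = fam, cross_taxa = FALSE,
                             n_metazoa = n, n_viral = 0L)))
  }

  k_clades <- params$tree_model$n_viral_clades
  mpf <- params$members_per_family
  vir_mean <- if (!is.null(params$viral_fraction_target)) {
    f <- params$viral_fraction_target
    max(1, f / (1 - f) * mpf[["metazoa"]])
  } else mpf[["virus"]]
  if (vir_mean < k_clades)
    stop("infeasible parameters: more planted viral clades than viral proteins",
         call. = FALSE)
  m0 <- max(2L, k_clades)
  n_met <- m0 + stats::rpois(1L, max(0, mpf[["metazoa"]] - m0))
  n_vir <- k_clades + stats::rpois(1L, max(0, vir_mean - k_clades))

  # family architecture: ordered distinct domains, lengths shared by classes
  k_dom <- 1L + stats::rpois(1L, max(0, ha$n_domains_mean - 1))
  dom_ids <- sprintf("DOM%05d", sample.int(99999L, k_dom))
  dom_len <- pmax(20L, as.integer(round(stats::rnorm(k_dom, ha$domain_len_mean,
                                                     ha$domain_len_sd))))

  build_protein <- function(id, species, class, keep) {
    kd <- sum(keep)
    tails <- .draw_linker(2L, if (class == "virus") lm$viral_tail_mean
                          else lm$metazoan_tail_mean, lm$distribution)
    idols <- .draw_linker(kd - 1L, if (class == "virus") lm$viral_idol_mean
                          else lm$metazoan_idol_mean, lm$distribution)
    lens <- dom_len[keep]
    starts <- integer(kd); ends <- integer(kd)
    pos <- tails[1L]
    for (j in seq_len(kd)) {
      starts[j] <- pos + 1L
      ends[j] <- pos + lens[j]
      pos <- ends[j] + if (j < kd) idols[j] else 0L
    }
    total <- pos + tails[2L]
    list(member = data.frame(family_id = fam, protein_id = id,
                             species = species, taxon_class = class,
                             length = total, stringsAsFactors = FALSE),
         hits = data.frame(protein_id = id, domain_id = dom_ids[keep],
                           start = starts, end = ends,
                           score = round(stats::runif(kd, 20, 200), 1),
                           stringsAsFactors = FALSE),
         lost = dom_ids[!keep])
  }

  m_ids <- sprintf("%s_m%03d", fam, seq_len(n_met))
  v_ids <- sprintf("%s_v%03d", fam, seq_len(n_vir))
  members <- list(); hits <- list(); lost <- stats::setNames(
    vector("list", n_vir), v_ids)
  for (i in seq_len(n_met)) {
    p <- build_protein(m_ids[i], sprintf("metazoa_sp%02d", i), "metazoa",
                       rep(TRUE, k_dom))
    members[[length(members) + 1L]] <- p$member
    hits[[length(hits) + 1L]] <- p$hits
  }
  for (i in seq_len(n_vir)) {
    keep <- rep(TRUE, k_dom)
    if (k_dom >= 3L)
      keep[2:(k_dom - 1L)] <- stats::runif(k_dom - 2L) >= params$domain_loss_prob
    p <- build_protein(v_ids[i], sprintf("virus_sp%02d", i), "virus", keep)
    members[[length(members) + 1L]] <- p$member
    hits[[length(hits) + 1L]] <- p$hits
    lost[[v_ids[i]]] <- p$lost
  }
  members <- do.call(rbind, members)
  hits <- do.call(rbind, hits)
  if (params$with_sequences)
    members$sequence <- vapply(members$length, .rand_seq, "")

  # tree: metazoan backbone, viral clades grafted at distinct metazoan leaves
  backbone <- if (params$tree_model$topology == "yule")
    .yule_newick(m_ids) else .caterpillar_newick(m_ids)
  groups <- split(v_ids, sort(rep_len(seq_len(k_clades), n_vir)))
  anchors <- m_ids[sample.int(n_met, k_clades)]
  for (g in seq_len(k_clades)) {
    clade <- .caterpillar_newick(groups[[g]])
    backbone <- sub(anchors[g],
                    sprintf("(%s,%s)", clade, anchors[g]),
                    backbone, fixed = TRUE)
  }
  nwk <- paste0(backbone, ";")
  tree <- ape::read.tree(text = nwk)

  list(family_id = fam, members = members, hits = hits,
       newick = nwk, tree = tree,
       truth = list(family_id = fam, cross_taxa = TRUE,
                    n_metazoa = n_met, n_viral = n_vir,
                    n_vc_planted = k_clades,
                    architecture = dom_ids,
                    domain_lengths = dom_len,
                    lost_domains = lost,
                    linker_means = lm[c("metazoan_tail_mean",
                                        "viral_tail_mean",
                                        "metazoan_idol_mean",
                                        "viral_idol_mean")]))
}

#' Generate a synthetic cohort on disk
#'
#' Writes `members.tsv`, `domains.tsv`, one Newick tree per cross-taxa
#' family under `trees/`, and `truth.json` holding the planted ground truth
#' (clade counts, architectures, lost domains, linker means) — kept in a
#' separate file so the pipeline under test cannot see it. Output is
#' deterministic: the same parameters and seed give byte-identical files.
#'
#' @param params A [cohort_params()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a list with the file `paths` and the `truth` list.
#' @export
generate_cohort <- function(params, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "trees"), showWarnings = FALSE)
  set.seed(params$seed)
  members <- list(); hits <- list(); truth <- list()
  for (i in seq_len(params$n_families)) {
    f <- generate_family(params, i, cross_taxa = i <= params$n_cross_taxa)
    members[[i]] <- f$members
    if (nrow(f$hits)) hits[[length(hits) + 1L]] <- f$hits
    truth[[f$family_id]] <- f$truth
    if (f$truth$cross_taxa)
      writeLines(f$newick, file.path(out_dir, "trees",
                                     paste0(f$family_id, ".nwk")))
  }
  members_path <- file.path(out_dir, "members.tsv")
  domains_path <- file.path(out_dir, "domains.tsv")
  truth_path <- file.path(out_dir, "truth.json")
  if (length(members)) {
    utils::write.table(do.call(rbind, members), members_path, sep = "\t",
                       quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  } else {
    writeLines(paste(c("family_id", "protein_id", "species", "taxon_class",
                       "length"), collapse = "\t"), members_path)
  }
  hdf <- if (length(hits)) do.call(rbind, hits) else
    data.frame(protein_id = character(), domain_id = character(),
               start = integer(), end = integer(), score = numeric())
  utils::write.table(hdf, domains_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(paths = list(members = members_path, domains = domains_path,
                              trees = file.path(out_dir, "trees"),
                              truth = truth_path),
                 truth = truth))
}
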