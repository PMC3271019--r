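#' Configuration for a full screening run
#'
#' @param members Path to the membership TSV.
#' @param domains Optional path to the domain-annotation TSV (without it the
#'   architecture stage is skipped).
#' @param trees_dir Optional directory of per-family Newick files named
#'   `<family_id>.nwk` (without it every family is UNCLASSIFIED for
#'   topology).
#' @param family_type `"cluster"` (sequence-cluster cascade) or `"domain"`
#'   (domain-family cascade).
#' @param filter A [filter_config()].
#' @param thresholds A [selection_thresholds()].
#' @param tests Character subset of `c("ks", "sign", "paired_t")`.
#' @param out_dir Output directory (created if absent).
#' @param seed Seed for any resampling done by the run.
#' @param quiet Suppress stderr progress logging.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(members, domains = NULL, trees_dir = NULL,
                       family_type = c("domain", "cluster"),
                       filter = filter_config(),
                       thresholds = selection_thresholds(),
                       tests = c("ks", "sign", "paired_t"),
                       out_dir = "virhijack_out", seed = 1L, quiet = FALSE) {
  family_type <- match.arg(family_type)
  if (!file.exists(members))
    stop(sprintf("members file '%s' does not exist", members), call. = FALSE)
  if (!is.null(domains) && !file.exists(domains))
    stop(sprintf("domains file '%s' does not exist", domains), call. = FALSE)
  if (!is.null(trees_dir) && !dir.exists(trees_dir))
    stop(sprintf("trees directory '%s' does not exist", trees_dir),
         call. = FALSE)
  tests <- match.arg(tests, several.ok = TRUE)
  structure(list(members = members, domains = domains, trees_dir = trees_dir,
                 family_type = family_type, filter = filter,
                 thresholds = thresholds, tests = tests, out_dir = out_dir,
                 seed = as.integer(seed), quiet = isTRUE(quiet)),
            class = "run_config")
}

.log <- function(config, fmt, ...) {
  if (!config$quiet)
    message(sprintf("[virhijack %s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...)))
}

.tests_row <- function(comparison, r) {
  data.frame(comparison = comparison, test = r$test_name,
             statistic = r$statistic, p_value = r$p_value,
             n_a = r$n_a, n_b = r$n_b, stringsAsFactors = FALSE)
}

#' Run the full screen
#'
#' Executes the stages in order: read inputs, filter families
#' (cluster or domain cascade), scan family trees for viral clusters and
#' apply the selection rule, compute architecture statistics on the
#' selected (plus topology-UNCLASSIFIED) families, and run the comparison
#' tests. Writes `filter_trace.tsv`, `topology_report.tsv`,
#' `per_protein.tsv`, `per_family.tsv`, `tests.tsv` and a machine-readable
#' `report.json` into the output directory, and returns the report.
#'
#' Any stage failure aborts with the stage name and offending family id.
#' Identical configuration and seed give an identical report.
#'
#' @param config A [run_config()].
#' @return Invisibly, the report list (also written as JSON): schema
#'   version, filtering funnel, per-stage counts, selection counts, the
#'   fraction of families whose viral mean length is below the metazoan
#'   mean, and the test results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()

  .log(config, "reading membership table %s", config$members)
  mem <- read_membership_table(config$members)
  records <- mem$records

  .log(config, "filtering %d families (%s cascade)",
       length(unique(mem$families$family_id)), config$family_type)
  flt <- if (config$family_type == "cluster")
    filter_clusters(mem$families, records, config$filter)
  else
    filter_domain_families(mem$families, records, config$filter)
  surviving <- flt$families
  write_filter_trace(flt$trace, file.path(config$out_dir, "filter_trace.tsv"))
  .log(config, "%d families survive filtering", length(surviving))

  reports <- list()
  unclassified <- character()
  for (fam in names(surviving)) {
    tree_path <- if (is.null(config$trees_dir)) "" else
      file.path(config$trees_dir, paste0(fam, ".nwk"))
    if (!nzchar(tree_path) || !file.exists(tree_path)) {
      unclassified <- c(unclassified, fam)
      next
    }
    tree <- tryCatch(read_tree(tree_path, "require_rooted"),
                     error = function(e)
                       stop(sprintf("tree-scan stage failed for family '%s': %s",
                                    fam, conditionMessage(e)), call. = FALSE))
    reports[[fam]] <- tryCatch(
      classify_family(tree, records, config$thresholds, family_id = fam),
      error = function(e)
        stop(sprintf("tree-scan stage failed for family '%s': %s",
                     fam, conditionMessage(e)), call. = FALSE))
  }
  selected <- names(reports)[vapply(reports, `[[`, TRUE, "selected")]
  .log(config, "topology: %d classified (%d selected), %d without trees",
       length(reports), length(selected), length(unclassified))
  if (length(reports))
    utils::write.table(topology_report_table(reports),
                       file.path(config$out_dir, "topology_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  arch_families <- c(selected, unclassified)
  tests_tab <- list()
  viral_shorter_fraction <- NA_real_
  n_arch <- 0L
  if (!is.null(config$domains) && length(arch_families)) {
    .log(config, "architecture statistics on %d families",
         length(arch_families))
    hits <- read_domain_annotations(config$domains)
    keep_ids <- unique(unlist(surviving[arch_families], use.names = FALSE))
    hits <- hits[hits$protein_id %in% keep_ids, , drop = FALSE]
    recs <- records[records$protein_id %in% keep_ids, , drop = FALSE]
    dec <- decompose_all(recs, hits)
    per_protein <- protein_architecture_table(recs, dec$decompositions)
    utils::write.table(per_protein,
                       file.path(config$out_dir, "per_protein.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summaries <- lapply(arch_families, function(fam)
      summarize_family_architecture(fam, surviving[[fam]], recs,
                                    dec$decompositions))
    fam_tab <- family_summary_table(summaries)
    n_arch <- nrow(fam_tab)
    utils::write.table(fam_tab, file.path(config$out_dir, "per_family.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    scored <- fam_tab[!is.na(fam_tab$viral_shorter), , drop = FALSE]
    if (nrow(scored))
      viral_shorter_fraction <- mean(scored$viral_shorter)

    v <- per_protein[per_protein$taxon_class == "virus", , drop = FALSE]
    m <- per_protein[per_protein$taxon_class == "metazoa", , drop = FALSE]
    if ("ks" %in% config$tests && nrow(v) && nrow(m)) {
      tests_tab[[length(tests_tab) + 1L]] <-
        .tests_row("length_virus_vs_metazoa", ks_two_sample(v$length, m$length))
      tests_tab[[length(tests_tab) + 1L]] <-
        .tests_row("tail_virus_vs_metazoa",
                   ks_two_sample(v$tail_mean, m$tail_mean))
      vi <- v$idol_mean[!is.na(v$idol_mean)]
      mi <- m$idol_mean[!is.na(m$idol_mean)]
      if (length(vi) && length(mi))
        tests_tab[[length(tests_tab) + 1L]] <-
          .tests_row("idol_virus_vs_metazoa", ks_two_sample(vi, mi))
    }
    if ("sign" %in% config$tests && nrow(scored))
      tests_tab[[length(tests_tab) + 1L]] <-
        .tests_row("families_viral_shorter",
                   sign_enrichment(nrow(scored), sum(scored$viral_shorter)))
    if ("paired_t" %in% config$tests) {
      paired <- fam_tab[!is.na(fam_tab$virus_mean_domain_occurrences) &
                          !is.na(fam_tab$metazoa_mean_domain_occurrences), ,
                        drop = FALSE]
      if (nrow(paired) >= 2L &&
          stats::sd(paired$metazoa_mean_domain_occurrences -
                      paired$virus_mean_domain_occurrences) > 0)
        tests_tab[[length(tests_tab) + 1L]] <-
          .tests_row("domain_occurrences_paired_by_family",
                     paired_t(paired$metazoa_mean_domain_occurrences,
                              paired$virus_mean_domain_occurrences))
    }
  }
  tests_df <- if (length(tests_tab)) do.call(rbind, tests_tab) else
    data.frame(comparison = character(), test = character(),
               statistic = numeric(), p_value = numeric(),
               n_a = integer(), n_b = integer())
  utils::write.table(tests_df, file.path(config$out_dir, "tests.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  report <- list(
    schema_version = "1.0",
    family_type = config$family_type,
    seed = config$seed,
    funnel = data.frame(stage = flt$trace$stage, n_in = flt$trace$n_in,
                        n_out = flt$trace$n_out),
    n_families_in = flt$trace$n_in[1L],
    n_families_surviving = length(surviving),
    n_families_classified = length(reports),
    n_families_selected = length(selected),
    n_families_unclassified = length(unclassified),
    unclassified_family_ids = unclassified,
    n_families_architecture = n_arch,
    viral_shorter_fraction = viral_shorter_fraction,
    tests = tests_df)
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       pretty = TRUE)
  .log(config, "done in %.1f s", as.numeric(Sys.time() - t0, units = "secs"))
  invisible(report)
}

#' Validate a pipeline report against the schema
#'
#' Checks that a report (as returned by [run_pipeline()] or re-read from
#' `report.json`) carries every schema-1.0 field and that its stage counts
#' reconcile: each funnel stage's output feeds the next stage's input, and
#' the classified/unclassified split covers the surviving families.
#'
#' @param report Report list or path to a `report.json`.
#' @return `TRUE` invisibly; otherwise an error describing the violation.
#' @export
validate_report <- function(report) {
  if (is.character(report)) report <- jsonlite::read_json(report,
                                                          simplifyVector = TRUE)
  need <- c("schema_version", "family_type", "funnel", "n_families_in",
            "n_families_surviving", "n_families_classified",
            "n_families_selected", "n_families_unclassified",
            "viral_shorter_fraction", "tests")
  miss <- setdiff(need, names(report))
  if (length(miss))
    stop(sprintf("report is missing field '%s'", miss[1L]), call. = FALSE)
  fn <- as.data.frame(report$funnel)
  if (nrow(fn) > 1L && any(fn$n_out[-nrow(fn)] != fn$n_in[-1L]))
    stop("funnel stages do not chain: some n_out != next n_in", call. = FALSE)
  if (fn$n_out[nrow(fn)] != report$n_families_surviving)
    stop("surviving count does not match final funnel stage", call. = FALSE)
  if (report$n_families_classified + report$n_families_unclassified !=
      report$n_families_surviving)
    stop("classified + unclassified != surviving", call. = FALSE)
  if (report$n_families_selected > report$n_families_classified)
    stop("selected exceeds classified", call. = FALSE)
  invisible(TRUE)
}
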