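#' Configuration for the family filtering cascades
#'
#' Holds the constants of the two filtering cascades that reduce raw
#' cross-taxa clusters or domain families to the analysis set: a minimal
#' cluster size of 2 proteins, the requirement for viral and metazoan
#' members (at least two metazoan proteins for domain families), the
#' removal of families that are >95% viral (structural elements such as
#' Env/Coat/Capsid), and an exclusion list for replication enzymes and
#' known contaminants.
#'
#' @param min_cluster_size Minimal family size (default 2).
#' @param require_viral Keep only families with at least one viral member.
#' @param require_metazoan Keep only families with at least one metazoan
#'   member (cluster cascade).
#' @param min_metazoan Minimal number of metazoan members for the
#'   domain-family cascade (default 2).
#' @param structural_viral_fraction Families whose viral member fraction
#'   exceeds this value are removed (default 0.95).
#' @param excluded_family_ids Character vector of family ids to drop
#'   outright.
#' @param excluded_name_patterns Character vector of case-insensitive
#'   regular expressions; a family whose id (or supplied name) matches any
#'   pattern is dropped. Defaults to the shipped replication-enzyme and
#'   contamination patterns, see [default_exclusion_patterns()].
#' @param structural_name_pattern Optional case-insensitive regex; when
#'   non-`NULL` the >95%-viral rule is applied only to families whose
#'   id/name matches it (e.g. `"env|coat|capsid"`). `NULL` (default)
#'   applies the rule to all families.
#' @return A list of class `"filter_config"`.
#' @export
filter_config <- function(min_cluster_size = 2L,
                          require_viral = TRUE,
                          require_metazoan = TRUE,
                          min_metazoan = 2L,
                          structural_viral_fraction = 0.95,
                          excluded_family_ids = character(),
                          excluded_name_patterns = default_exclusion_patterns(),
                          structural_name_pattern = NULL) {
  stopifnot(min_cluster_size >= 1L,
            structural_viral_fraction > 0, structural_viral_fraction <= 1,
            min_metazoan >= 0L)
  structure(list(min_cluster_size = as.integer(min_cluster_size),
                 require_viral = isTRUE(require_viral),
                 require_metazoan = isTRUE(require_metazoan),
                 min_metazoan = as.integer(min_metazoan),
                 structural_viral_fraction = structural_viral_fraction,
                 excluded_family_ids = as.character(excluded_family_ids),
                 excluded_name_patterns = as.character(excluded_name_patterns),
                 structural_name_pattern = structural_name_pattern),
            class = "filter_config")
}

#' Default family exclusion patterns
#'
#' Reads the shipped pattern list covering the excluded categories:
#' RNA/DNA polymerases, exo/endonucleases, helicases, tRNA synthetases,
#' primases, and the GFP contamination family (PF01353). The exact database
#' ids are release-dependent, so the exclusions are expressed as
#' case-insensitive name patterns that users can edit or replace.
#'
#' @param path Path to a two-column TSV (`pattern`, `category`); defaults to
#'   the file installed with the package.
#' @return Character vector of regular expressions, named by category.
#' @export
default_exclusion_patterns <- function(path = system.file("extdata",
                                                          "excluded_families.tsv",
                                                          package = "virhijack")) {
  df <- .read_tsv(path)
  stats::setNames(df$pattern, df$category)
}

.class_counts <- function(member_ids, records) {
  idx <- match(member_ids, records$protein_id)
  if (anyNA(idx))
    stop(sprintf("family member '%s' does not resolve to a protein record",
                 member_ids[is.na(idx)][1L]), call. = FALSE)
  cls <- records$taxon_class[idx]
  c(n = length(member_ids),
    virus = sum(cls == "virus"),
    metazoa = sum(cls == "metazoa"))
}

# Apply one named predicate stage to a family list, appending to the trace.
.apply_stage <- function(fams, keep, stage, trace) {
  removed <- names(fams)[!keep]
  trace[[length(trace) + 1L]] <- list(stage = stage,
                                      n_in = length(fams),
                                      n_out = sum(keep),
                                      removed = removed)
  list(fams = fams[keep], trace = trace)
}

.trace_df <- function(trace) {
  df <- data.frame(stage = vapply(trace, `[[`, "", "stage"),
                   n_in = vapply(trace, `[[`, 0L, "n_in"),
                   n_out = vapply(trace, `[[`, 0L, "n_out"),
                   stringsAsFactors = FALSE)
  df$n_removed <- df$n_in - df$n_out
  df$removed <- I(lapply(trace, `[[`, "removed"))
  class(df) <- c("filter_trace", class(df))
  df
}

.families_as_list <- function(families) {
  split(families$protein_id, factor(families$family_id,
                                    levels = unique(families$family_id)))
}

#' Filter cross-taxa sequence clusters
#'
#' The cluster cascade: (1) keep families of at least `min_cluster_size`
#' members; (2) keep families with at least one viral member; (3) keep
#' families with at least one metazoan member. Stages are applied in that
#' order and every stage is recorded in the returned trace.
#'
#' @param families data.frame (`family_id`, `protein_id`) or a named list of
#'   member-id vectors.
#' @param records data.frame of protein records.
#' @param config A [filter_config()].
#' @return List with `families` (surviving, same representation as a named
#'   list of member ids) and `trace` (a `filter_trace` data.frame with one
#'   row per stage; `n_in - n_out` equals the number of removed ids).
#' @export
filter_clusters <- function(families, records, config = filter_config()) {
  fams <- if (is.data.frame(families)) .families_as_list(families) else families
  counts <- t(vapply(fams, .class_counts, c(n = 0, virus = 0, metazoa = 0),
                     records = records))
  trace <- list()
  st <- .apply_stage(fams, counts[, "n"] >= config$min_cluster_size,
                     "min_size", trace)
  keep2 <- if (config$require_viral)
    counts[names(st$fams), "virus"] >= 1 else rep(TRUE, length(st$fams))
  st <- .apply_stage(st$fams, keep2, "has_viral", st$trace)
  keep3 <- if (config$require_metazoan)
    counts[names(st$fams), "metazoa"] >= 1 else rep(TRUE, length(st$fams))
  st <- .apply_stage(st$fams, keep3, "has_metazoan", st$trace)
  list(families = st$fams, trace = .trace_df(st$trace))
}

.matches_any <- function(ids, patterns) {
  if (!length(patterns)) return(rep(FALSE, length(ids)))
  hit <- rep(FALSE, length(ids))
  for (p in patterns) hit <- hit | grepl(p, ids, ignore.case = TRUE, perl = TRUE)
  hit
}

#' Filter cross-taxa domain families
#'
#' The domain-family cascade: (1) keep families with at least one viral
#' member and at least `min_metazoan` metazoan members; (2) remove families
#' whose viral member fraction exceeds `structural_viral_fraction` (viral
#' structural elements); (3) remove families on the exclusion list, by id or
#' by name pattern (replication enzymes and contaminants).
#'
#' @inheritParams filter_clusters
#' @param family_names Optional named character vector mapping family ids to
#'   human-readable names; patterns are matched against both.
#' @return As [filter_clusters()].
#' @export
filter_domain_families <- function(families, records,
                                   config = filter_config(),
                                   family_names = NULL) {
  fams <- if (is.data.frame(families)) .families_as_list(families) else families
  counts <- t(vapply(fams, .class_counts, c(n = 0, virus = 0, metazoa = 0),
                     records = records))
  trace <- list()
  st <- .apply_stage(fams,
                     counts[, "virus"] >= 1 &
                       counts[, "metazoa"] >= config$min_metazoan,
                     "cross_taxa", trace)

  ids <- names(st$fams)
  frac <- counts[ids, "virus"] / counts[ids, "n"]
  structural <- frac > config$structural_viral_fraction
  if (!is.null(config$structural_name_pattern)) {
    nm <- if (is.null(family_names)) ids else paste(ids, family_names[ids])
    structural <- structural &
      grepl(config$structural_name_pattern, nm, ignore.case = TRUE, perl = TRUE)
  }
  st <- .apply_stage(st$fams, !structural, "viral_structural", st$trace)

  ids <- names(st$fams)
  nm <- if (is.null(family_names)) ids else paste(ids, family_names[ids])
  excl <- ids %in% config$excluded_family_ids |
    .matches_any(nm, config$excluded_name_patterns)
  st <- .apply_stage(st$fams, !excl, "exclusion_list", st$trace)
  list(families = st$fams, trace = .trace_df(st$trace))
}

#' @export
print.filter_trace <- function(x, ...) {
  cat("filtering funnel:\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-16s %6d -> %6d (removed %d)\n",
                x$stage[i], x$n_in[i], x$n_out[i], x$n_removed[i]))
  invisible(x)
}

#' Write a filter trace as TSV
#' @param trace A `filter_trace` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_filter_trace <- function(trace, path) {
  out <- data.frame(stage = trace$stage, n_in = trace$n_in,
                    n_out = trace$n_out, n_removed = trace$n_removed,
                    removed = vapply(trace$removed, paste, "", collapse = ","))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
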