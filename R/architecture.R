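#' Resolve overlapping domain hits on one protein
#'
#' Greedy retention by descending score; ties are broken by the longer hit,
#' then by the smaller start. A candidate overlapping any already-retained
#' hit is dropped; nesting (one hit inside another) counts as overlap.
#' Missing scores rank below any numeric score.
#'
#' @param hits data.frame of domain hits for a single protein
#'   (`domain_id`, `start`, `end`, optional `score`).
#' @return The retained hits, pairwise non-overlapping, sorted by `start`.
#' @export
resolve_overlaps <- function(hits) {
  if (nrow(hits) <= 1L) return(hits[order(hits$start), , drop = FALSE])
  if (length(unique(hits$protein_id)) > 1L)
    stop("resolve_overlaps expects hits for a single protein", call. = FALSE)
  score <- if ("score" %in% names(hits)) hits$score else rep(NA_real_, nrow(hits))
  score[is.na(score)] <- -Inf
  len <- hits$end - hits$start + 1L
  ord <- order(-score, -len, hits$start)
  kept <- integer(0)
  for (i in ord) {
    clash <- any(hits$start[i] <= hits$end[kept] &
                   hits$end[i] >= hits$start[kept])
    if (!clash) kept <- c(kept, i)
  }
  out <- hits[sort(kept), , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Decompose a protein into tails, domains and inter-domain linkers
#'
#' Splits a protein of known length into: the N-terminal tail before the
#' first domain, the domain segments, the inter-domain linkers (IDOLs)
#' between consecutive domains, and the C-terminal tail after the last
#' domain. With 1-based inclusive domain coordinates:
#' `n_tail = start(first) - 1`, `c_tail = length - end(last)`,
#' `idol_i = start(i+1) - end(i) - 1`. The segment lengths always sum to
#' the protein length (asserted). A protein without any domain hit has no
#' decomposition.
#'
#' @param record One protein record (row with `protein_id`, `length`).
#' @param hits Non-overlapping domain hits for that protein.
#' @return A list of class `"architecture"` with `protein_id`,
#'   `length`, `n_tail_len`, `c_tail_len`, `domain_segments` (data.frame
#'   `domain_id`, `start`, `end`), `idol_lens` (integer vector, length
#'   one less than the number of domains).
#' @export
decompose_architecture <- function(record, hits) {
  if (is.data.frame(record)) record <- as.list(record[1L, ])
  h <- hits[hits$protein_id == record$protein_id, , drop = FALSE]
  if (nrow(h) == 0L)
    stop(sprintf("protein '%s' has no domain hits: decomposition undefined",
                 record$protein_id), call. = FALSE)
  h <- h[order(h$start), , drop = FALSE]
  if (nrow(h) > 1L && any(h$start[-1L] <= h$end[-nrow(h)]))
    stop(sprintf("overlapping domain hits on protein '%s'; resolve first",
                 record$protein_id), call. = FALSE)
  L <- as.integer(record$length)
  if (h$end[nrow(h)] > L)
    stop(sprintf("domain hit beyond protein '%s' length %d",
                 record$protein_id, L), call. = FALSE)
  n_tail <- h$start[1L] - 1L
  c_tail <- L - h$end[nrow(h)]
  idol <- if (nrow(h) > 1L) h$start[-1L] - h$end[-nrow(h)] - 1L else integer(0)
  dom_len <- sum(h$end - h$start + 1L)
  stopifnot(n_tail + c_tail + dom_len + sum(idol) == L)
  structure(list(protein_id = record$protein_id,
                 length = L,
                 n_tail_len = n_tail,
                 c_tail_len = c_tail,
                 domain_segments = data.frame(domain_id = h$domain_id,
                                              start = h$start, end = h$end,
                                              stringsAsFactors = FALSE),
                 idol_lens = as.integer(idol)),
            class = "architecture")
}

#' Per-protein TAIL length
#'
#' The mean of the two terminal segments outside the first and last domain
#' (zeros included): `(n_tail + c_tail) / 2`.
#'
#' @param d An `"architecture"` decomposition.
#' @return TAIL length in amino acids.
#' @export
tail_length <- function(d) (d$n_tail_len + d$c_tail_len) / 2

#' Per-protein IDOL length
#'
#' The mean length of the inter-domain linkers. A single-domain protein has
#' no inter-domain linker, so its IDOL length is `NA` — absence is a value
#' here, not an error.
#'
#' @param d An `"architecture"` decomposition.
#' @return Mean IDOL length in amino acids, or `NA_real_`.
#' @export
idol_length <- function(d) {
  if (length(d$idol_lens) == 0L) NA_real_ else mean(d$idol_lens)
}

#' Domain architecture as an ordered id list
#'
#' @param d An `"architecture"` decomposition.
#' @return Character vector of domain ids in N-to-C order, repeats kept.
#' @export
architecture_string <- function(d) d$domain_segments$domain_id

#' @export
print.architecture <- function(x, ...) {
  cat(sprintf("%s (%d aa): N-tail %d | %s | C-tail %d\n",
              x$protein_id, x$length, x$n_tail_len,
              paste(x$domain_segments$domain_id,
                    collapse = sprintf(" -%s- ", "idol")),
              x$c_tail_len))
  invisible(x)
}

#' Detect internal-domain loss between a viral and a host architecture
#'
#' Reports host domains missing from a viral protein when the viral domain
#' list is an ordered subsequence of the host list with both flanks intact:
#' the first viral domain must match the host's first domain and the last
#' viral domain the host's last, so that the flanking domains are preserved
#' in the same order and only internal domains are absent. When the viral
#' list is not such a subsequence the result is empty — no loss call is
#' made.
#'
#' @param viral_arch Character vector, viral domain ids N-to-C.
#' @param host_arch Character vector, host domain ids N-to-C.
#' @return data.frame with columns `domain_id` and `host_position`
#'   (1-based position in the host architecture); zero rows when no
#'   internal loss is detected.
#' @export
detect_internal_loss <- function(viral_arch, host_arch) {
  stopifnot(length(viral_arch) >= 1L, length(host_arch) >= 1L)
  empty <- data.frame(domain_id = character(), host_position = integer(),
                      stringsAsFactors = FALSE)
  k <- length(viral_arch); m <- length(host_arch)
  if (k > m) return(empty)
  if (viral_arch[1L] != host_arch[1L] || viral_arch[k] != host_arch[m])
    return(empty)
  if (k == 1L) return(empty)  # one domain cannot anchor both flanks (m > 1)
  # anchor the flanks, embed the middle greedily leftmost
  match_pos <- integer(k)
  match_pos[1L] <- 1L
  match_pos[k] <- m
  j <- 2L
  for (i in seq.int(2L, k - 1L, length.out = max(0L, k - 2L))) {
    while (j <= m - 1L && host_arch[j] != viral_arch[i]) j <- j + 1L
    if (j > m - 1L) return(empty)
    match_pos[i] <- j
    j <- j + 1L
  }
  lost <- setdiff(seq_len(m), match_pos)
  data.frame(domain_id = host_arch[lost], host_position = lost,
             stringsAsFactors = FALSE)
}

#' Decompose every protein with domain hits
#'
#' Convenience driver: resolves overlaps per protein and decomposes each
#' protein that has at least one hit. Proteins without hits are skipped and
#' counted — their architecture is undefined.
#'
#' @param records data.frame of protein records.
#' @param hits data.frame of domain hits (validated against `records`).
#' @return List with `decompositions` (named by protein id) and
#'   `n_without_hits` (count of records carrying no hit).
#' @export
decompose_all <- function(records, hits) {
  validate_domain_hits(hits, records)
  by_prot <- split(hits, hits$protein_id)
  ids <- names(by_prot)
  dec <- vector("list", length(ids))
  names(dec) <- ids
  for (id in ids) {
    rec <- records[records$protein_id == id, , drop = FALSE]
    dec[[id]] <- decompose_architecture(rec, resolve_overlaps(by_prot[[id]]))
  }
  list(decompositions = dec,
       n_without_hits = sum(!records$protein_id %in% ids))
}

#' Per-protein architecture table
#'
#' One row per decomposed protein with the quantities used throughout the
#' length/linker analyses.
#'
#' @param records data.frame of protein records.
#' @param decompositions Named list from [decompose_all()].
#' @return data.frame with columns `protein_id`, `taxon_class`, `length`,
#'   `n_domains` (occurrences, repeats counted), `n_distinct` (unique
#'   domain ids), `n_tail`, `c_tail`, `tail_mean`, `idol_mean` (`NA` for
#'   single-domain proteins).
#' @export
protein_architecture_table <- function(records, decompositions) {
  rows <- lapply(decompositions, function(d) {
    data.frame(protein_id = d$protein_id,
               n_domains = nrow(d$domain_segments),
               n_distinct = length(unique(d$domain_segments$domain_id)),
               n_tail = d$n_tail_len, c_tail = d$c_tail_len,
               tail_mean = tail_length(d), idol_mean = idol_length(d),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  idx <- match(tab$protein_id, records$protein_id)
  tab$taxon_class <- records$taxon_class[idx]
  tab$length <- records$length[idx]
  tab <- tab[, c("protein_id", "taxon_class", "length", "n_domains",
                 "n_distinct", "n_tail", "c_tail", "tail_mean", "idol_mean")]
  rownames(tab) <- NULL
  tab
}

.class_stats <- function(sub) {
  idol <- sub$idol_mean[!is.na(sub$idol_mean)]
  list(n_proteins = nrow(sub),
       mean_length = mean(sub$length),
       median_length = stats::median(sub$length),
       mean_domain_occurrences = mean(sub$n_domains),
       median_domain_occurrences = stats::median(sub$n_domains),
       mean_distinct_domains = mean(sub$n_distinct),
       mean_tail = mean(sub$tail_mean),
       mean_idol = if (length(idol)) mean(idol) else NA_real_)
}

#' Per-family architecture summary
#'
#' Class-wise (virus vs metazoa) means and medians of protein length,
#' domain occurrence and distinct-domain counts, TAIL and IDOL lengths for
#' one family, with metazoan/viral (M/V) ratios and a `viral_shorter` flag.
#' Statistics are computed per protein over the members that have at least
#' one domain hit; members without hits are excluded and counted. IDOL
#' means cover only proteins with at least two domains.
#'
#' @param family_id Family id (carried into the result).
#' @param member_ids Character vector of the family's protein ids.
#' @param records data.frame of protein records.
#' @param decompositions Named list from [decompose_all()] (may cover more
#'   proteins than this family).
#' @return A list of class `"family_architecture_summary"` with `family_id`,
#'   `virus` and `metazoa` stat blocks (`NULL` when the class is absent),
#'   `ratio_length_m_over_v`, `ratio_distinct_domains_m_over_v`,
#'   `viral_shorter`, `n_excluded_no_hits`.
#' @export
summarize_family_architecture <- function(family_id, member_ids, records,
                                          decompositions) {
  dec <- decompositions[intersect(member_ids, names(decompositions))]
  n_excluded <- length(member_ids) - length(dec)
  if (!length(dec))
    return(structure(list(family_id = family_id, virus = NULL, metazoa = NULL,
                          ratio_length_m_over_v = NA_real_,
                          ratio_distinct_domains_m_over_v = NA_real_,
                          viral_shorter = NA,
                          n_excluded_no_hits = n_excluded),
                     class = "family_architecture_summary"))
  tab <- protein_architecture_table(records, dec)
  v <- tab[tab$taxon_class == "virus", , drop = FALSE]
  m <- tab[tab$taxon_class == "metazoa", , drop = FALSE]
  vs <- if (nrow(v)) .class_stats(v) else NULL
  ms <- if (nrow(m)) .class_stats(m) else NULL
  both <- !is.null(vs) && !is.null(ms)
  structure(list(
    family_id = family_id, virus = vs, metazoa = ms,
    ratio_length_m_over_v = if (both && vs$mean_length > 0)
      ms$mean_length / vs$mean_length else NA_real_,
    ratio_distinct_domains_m_over_v = if (both && vs$mean_distinct_domains > 0)
      ms$mean_distinct_domains / vs$mean_distinct_domains else NA_real_,
    viral_shorter = if (both) vs$mean_length < ms$mean_length else NA,
    n_excluded_no_hits = n_excluded),
    class = "family_architecture_summary")
}

#' Flatten family architecture summaries to a table
#'
#' @param summaries List of `"family_architecture_summary"` objects.
#' @return data.frame, one row per family; absent class statistics are NA.
#' @export
family_summary_table <- function(summaries) {
  blk <- function(s, cls) {
    b <- s[[cls]]
    if (is.null(b))
      b <- list(n_proteins = 0L, mean_length = NA_real_,
                median_length = NA_real_, mean_domain_occurrences = NA_real_,
                median_domain_occurrences = NA_real_,
                mean_distinct_domains = NA_real_, mean_tail = NA_real_,
                mean_idol = NA_real_)
    stats::setNames(as.data.frame(b), paste0(cls, "_", names(b)))
  }
  rows <- lapply(summaries, function(s) {
    cbind(data.frame(family_id = s$family_id, stringsAsFactors = FALSE),
          blk(s, "virus"), blk(s, "metazoa"),
          data.frame(ratio_length_m_over_v = s$ratio_length_m_over_v,
                     ratio_distinct_domains_m_over_v =
                       s$ratio_distinct_domains_m_over_v,
                     viral_shorter = s$viral_shorter,
                     n_excluded_no_hits = s$n_excluded_no_hits))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
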