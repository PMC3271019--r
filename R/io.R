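#' @keywords internal
"_PACKAGE"

#' Recognised taxon classes
#'
#' Proteins are partitioned into five taxon classes. Only `virus` and
#' `metazoa` enter the core statistics; the remaining classes are carried
#' through so that cross-taxa filtering can see them.
#'
#' @format Character vector of the five class labels.
#' @export
TAXON_CLASSES <- c("virus", "metazoa", "other_eukaryote", "bacteria", "archaea")

.norm_taxon <- function(x, line = NULL) {
  v <- tolower(trimws(x))
  bad <- !(v %in% TAXON_CLASSES)
  if (any(bad)) {
    where <- if (is.null(line)) "" else sprintf(" (line %d)", line[bad][1L])
    stop(sprintf("unknown taxon_class '%s'%s; expected one of: %s",
                 x[bad][1L], where, paste(TAXON_CLASSES, collapse = ", ")),
         call. = FALSE)
  }
  v
}

.read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = "character", na.strings = NULL,
                    fileEncoding = "UTF-8")
}

.require_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s: missing required column '%s'", what, miss[1L]),
         call. = FALSE)
}

.as_count <- function(x, col, line, positive = TRUE) {
  v <- suppressWarnings(as.numeric(x))
  bad <- is.na(v) | v != floor(v) | (if (positive) v <= 0 else v < 0)
  if (any(bad))
    stop(sprintf("column '%s': invalid value '%s' at line %d (expected a %s integer)",
                 col, x[bad][1L], line[bad][1L],
                 if (positive) "positive" else "non-negative"),
         call. = FALSE)
  as.integer(v)
}

#' Read a family membership table
#'
#' Parses a tab-delimited membership table with mandatory header columns
#' `family_id`, `protein_id`, `species`, `taxon_class` and `length`
#' (amino acids), plus optional `sequence` and `fragment` columns.
#' One row is one (family, protein) membership; a protein may belong to
#' several families but must carry identical attributes in every row.
#'
#' @param path Path to a UTF-8 TSV file with a header row.
#' @return A list of class `"membership"` with elements
#'   \describe{
#'     \item{records}{data.frame of unique proteins: `protein_id`, `species`,
#'       `taxon_class`, `length`, and `sequence`/`fragment` when supplied.}
#'     \item{families}{data.frame of memberships: `family_id`, `protein_id`.}
#'   }
#' @seealso [write_membership_table()], [family_members()]
#' @export
read_membership_table <- function(path) {
  df <- .read_tsv(path)
  .require_cols(df, c("family_id", "protein_id", "species", "taxon_class",
                      "length"), "membership table")
  n <- nrow(df)
  if (n == 0L) {
    records <- data.frame(protein_id = character(), species = character(),
                          taxon_class = character(), length = integer(),
                          stringsAsFactors = FALSE)
    families <- data.frame(family_id = character(), protein_id = character(),
                           stringsAsFactors = FALSE)
    return(structure(list(records = records, families = families),
                     class = "membership"))
  }
  line <- seq_len(n) + 1L  # header is line 1
  if (any(!nzchar(df$protein_id)))
    stop(sprintf("empty protein_id at line %d", line[!nzchar(df$protein_id)][1L]),
         call. = FALSE)
  key <- paste(df$family_id, df$protein_id, sep = "\r")
  if (anyDuplicated(key))
    stop(sprintf("duplicate (family_id, protein_id) row at line %d",
                 line[duplicated(key)][1L]), call. = FALSE)
  df$taxon_class <- .norm_taxon(df$taxon_class, line)
  df$length <- .as_count(df$length, "length", line)
  if ("fragment" %in% names(df))
    df$fragment <- tolower(df$fragment) %in% c("true", "t", "1", "yes")

  rec_cols <- intersect(c("protein_id", "species", "taxon_class", "length",
                          "sequence", "fragment"), names(df))
  rec <- df[!duplicated(df$protein_id), rec_cols, drop = FALSE]
  # a protein repeated across families must be self-consistent
  chk <- df[, rec_cols, drop = FALSE]
  first <- rec[match(chk$protein_id, rec$protein_id), , drop = FALSE]
  same <- rowSums(chk != first, na.rm = TRUE) == 0L
  if (!all(same))
    stop(sprintf("protein '%s' has conflicting attributes at line %d",
                 chk$protein_id[!same][1L], line[!same][1L]), call. = FALSE)
  if ("sequence" %in% names(rec)) {
    has <- nzchar(rec$sequence)
    bad <- has & nchar(rec$sequence) != rec$length
    if (any(bad))
      stop(sprintf("protein '%s': sequence length %d does not match length %d",
                   rec$protein_id[bad][1L], nchar(rec$sequence[bad][1L]),
                   rec$length[bad][1L]), call. = FALSE)
  }
  rownames(rec) <- NULL
  families <- df[, c("family_id", "protein_id")]
  rownames(families) <- NULL
  structure(list(records = rec, families = families), class = "membership")
}

#' Write a family membership table
#'
#' Inverse of [read_membership_table()]: joins the per-protein records onto
#' the membership rows and writes a tab-delimited file that reads back to an
#' identical structure.
#'
#' @param membership A `"membership"` list (`records` + `families`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_membership_table <- function(membership, path) {
  fam <- membership$families
  rec <- membership$records
  idx <- match(fam$protein_id, rec$protein_id)
  if (anyNA(idx))
    stop("membership rows reference unknown protein ids", call. = FALSE)
  out <- cbind(family_id = fam$family_id,
               rec[idx, , drop = FALSE])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read per-protein domain annotations
#'
#' Parses a TSV of domain occurrences with header columns `protein_id`,
#' `domain_id`, `start`, `end` and optional `score` (bits). Coordinates are
#' 1-based inclusive amino-acid positions, as in Pfam/hmmscan output.
#' Hits are returned sorted by (`protein_id`, `start`). Protein ids are not
#' resolved at read time; use [validate_domain_hits()] against a record set.
#'
#' @param path Path to a UTF-8 TSV file with a header row.
#' @return data.frame with columns `protein_id`, `domain_id`, `start`,
#'   `end`, `score` (NA when absent).
#' @export
read_domain_annotations <- function(path) {
  df <- .read_tsv(path)
  .require_cols(df, c("protein_id", "domain_id", "start", "end"),
                "domain annotations")
  n <- nrow(df)
  line <- seq_len(n) + 1L
  start <- .as_count(df$start, "start", line)
  end <- .as_count(df$end, "end", line)
  rev <- start > end
  if (any(rev))
    stop(sprintf("start > end at line %d", line[rev][1L]), call. = FALSE)
  score <- if ("score" %in% names(df))
    suppressWarnings(as.numeric(df$score)) else rep(NA_real_, n)
  out <- data.frame(protein_id = df$protein_id, domain_id = df$domain_id,
                    start = start, end = end, score = score,
                    stringsAsFactors = FALSE)
  out <- out[order(out$protein_id, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write domain annotations
#'
#' @param hits data.frame as returned by [read_domain_annotations()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_domain_annotations <- function(hits, path) {
  out <- hits
  out$score <- ifelse(is.na(out$score), "", format(out$score, trim = TRUE))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Cross-validate domain hits against protein records
#'
#' Checks that every hit refers to a known protein and lies inside the
#' protein's bounds (`end <= length`).
#'
#' @param hits data.frame of domain hits.
#' @param records data.frame of protein records (`protein_id`, `length`).
#' @return `hits`, invisibly, when everything validates; otherwise an error
#'   naming the first offending hit.
#' @export
validate_domain_hits <- function(hits, records) {
  idx <- match(hits$protein_id, records$protein_id)
  if (anyNA(idx))
    stop(sprintf("domain hit references unknown protein '%s'",
                 hits$protein_id[is.na(idx)][1L]), call. = FALSE)
  len <- records$length[idx]
  bad <- hits$end > len
  if (any(bad))
    stop(sprintf("domain '%s' on protein '%s' ends at %d beyond protein length %d",
                 hits$domain_id[bad][1L], hits$protein_id[bad][1L],
                 hits$end[bad][1L], len[bad][1L]), call. = FALSE)
  invisible(hits)
}

#' Read a per-family tree from Newick
#'
#' Reads one Newick tree and enforces a rooting policy. Under
#' `"require_rooted"` the tree must already be rooted (a basal trifurcation
#' is an error). Under `"midpoint"` the tree is rooted at the midpoint of
#' its longest leaf-to-leaf path, which requires branch lengths.
#' Leaf labels must be unique; they are the protein ids.
#'
#' @param path Path to a Newick file (ignored when `text` is given).
#' @param root_policy `"require_rooted"` or `"midpoint"`.
#' @param text Optional Newick string, as in [ape::read.tree()].
#' @return An [ape::phylo] tree.
#' @export
read_tree <- function(path = NULL, root_policy = c("require_rooted", "midpoint"),
                      text = NULL) {
  root_policy <- match.arg(root_policy)
  tree <- if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text)
  if (is.null(tree)) stop("could not parse Newick input", call. = FALSE)
  if (inherits(tree, "multiPhylo")) tree <- tree[[1L]]
  if (anyDuplicated(tree$tip.label))
    stop(sprintf("duplicate leaf label '%s' in tree",
                 tree$tip.label[duplicated(tree$tip.label)][1L]), call. = FALSE)
  if (root_policy == "require_rooted") {
    if (!ape::is.rooted(tree))
      stop("tree is unrooted (basal multifurcation) but root_policy is 'require_rooted'",
           call. = FALSE)
  } else {
    if (is.null(tree$edge.length))
      stop("midpoint rooting requires branch lengths", call. = FALSE)
    tree <- phangorn::midpoint(tree)
  }
  tree
}

#' Write a tree to Newick
#'
#' @param tree An [ape::phylo] tree.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Members of one family
#'
#' @param membership A `"membership"` list.
#' @param family_id One family id.
#' @return Character vector of the family's protein ids.
#' @export
family_members <- function(membership, family_id) {
  membership$families$protein_id[membership$families$family_id == family_id]
}

#' All family ids in a membership table
#' @param membership A `"membership"` list.
#' @return Character vector of distinct family ids, in file order.
#' @export
family_ids <- function(membership) unique(membership$families$family_id)

#' @export
print.membership <- function(x, ...) {
  cat(sprintf("membership: %d proteins in %d families (%d rows)\n",
              nrow(x$records), length(unique(x$families$family_id)),
              nrow(x$families)))
  tab <- table(x$records$taxon_class)
  cat("  taxon classes:",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  invisible(x)
}
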