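#' Read a BLAST tabular (outfmt 6) hit table
#'
#' Standard 12-column tabular output: qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore. Alignment search itself
#' is out of scope; this module consumes hit tables and performs the
#' selection and collapse.
#'
#' @param path file path.
#' @return data.frame with the 12 standard columns.
#' @export
read_blast_tab <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  tab <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                      comment.char = "#", stringsAsFactors = FALSE),
    error = function(e) stop("failed to parse BLAST tabular file '", path,
                             "': ", conditionMessage(e)))
  if (ncol(tab) < 12L)
    stop("BLAST tabular file '", path, "' has ", ncol(tab),
         " columns; 12 expected (outfmt 6)")
  tab <- tab[, 1:12]
  names(tab) <- cols
  bad <- which(!is.finite(tab$evalue) | !is.finite(tab$bitscore))
  if (length(bad))
    stop("malformed BLAST rows (non-numeric evalue/bitscore) at line(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  tab
}

# strip transcript suffix like ".1" from subject identifiers
normalize_locus <- function(x) sub("\\.\\d+$", "", x)

#' Best-hit ortholog assignment
#'
#' Per query, selects the hit with the highest bit score, ties broken by
#' lowest E-value and then lexicographically smallest subject locus
#' (sort-before-select, so the result is independent of input row order).
#' Queries whose best hit exceeds \code{e_max}, or that have no hits at
#' all, are reported unassigned (\code{subject_locus = NA}).
#'
#' @param hits data.frame with columns \code{qseqid}, \code{sseqid},
#'   \code{evalue}, \code{bitscore} (e.g. from \code{\link{read_blast_tab}}).
#' @param e_max E-value acceptance threshold (default 1e-5).
#' @param query_ids optional full query universe; queries absent from
#'   \code{hits} are appended as unassigned.
#' @param normalize strip transcript suffixes (".1" etc.) from subject ids
#'   to locus form (default TRUE).
#' @return data.frame: \code{query_id}, \code{subject_locus} (NA when
#'   unassigned), \code{e_value}, \code{bit_score}.
#' @export
assign_best_hits <- function(hits, e_max = 1e-5, query_ids = NULL,
                             normalize = TRUE) {
  stopifnot(e_max > 0)
  h <- data.frame(query_id = as.character(hits$qseqid),
                  subject_locus = as.character(hits$sseqid),
                  e_value = as.numeric(hits$evalue),
                  bit_score = as.numeric(hits$bitscore),
                  stringsAsFactors = FALSE)
  if (any(h$e_value < 0)) stop("negative E-values in hit table")
  if (normalize) h$subject_locus <- normalize_locus(h$subject_locus)
  h <- h[order(h$query_id, -h$bit_score, h$e_value, h$subject_locus), ,
         drop = FALSE]
  best <- h[!duplicated(h$query_id), , drop = FALSE]
  best$subject_locus[best$e_value > e_max] <- NA_character_
  if (!is.null(query_ids)) {
    missing <- setdiff(query_ids, best$query_id)
    if (length(missing))
      best <- rbind(best, data.frame(query_id = missing,
                                     subject_locus = NA_character_,
                                     e_value = NA_real_, bit_score = NA_real_,
                                     stringsAsFactors = FALSE))
  }
  best <- best[order(best$query_id), , drop = FALSE]
  rownames(best) <- NULL
  best
}

#' Collapse ortholog assignments to target loci
#'
#' Many-to-one collapse: several queries (e.g. triplicated Brassica genes)
#' may indicate the same reference locus.
#'
#' @param assignments output of \code{\link{assign_best_hits}}.
#' @return list with \code{loci} (sorted distinct assigned subject loci),
#'   \code{many_to_one} (data.frame \code{subject_locus},
#'   \code{n_queries}, \code{query_ids} ";"-joined) and \code{unassigned}
#'   (query ids without an assignment).
#' @export
collapse_to_loci <- function(assignments) {
  asg <- assignments[!is.na(assignments$subject_locus), , drop = FALSE]
  tab <- tapply(asg$query_id, asg$subject_locus, function(q) sort(unique(q)),
                simplify = FALSE)
  loci <- sort(names(tab))
  many <- data.frame(subject_locus = loci,
                     n_queries = vapply(tab[loci], length, 1L),
                     query_ids = vapply(tab[loci], paste, "", collapse = ";"),
                     stringsAsFactors = FALSE)
  rownames(many) <- NULL
  list(loci = loci,
       many_to_one = many,
       unassigned = sort(assignments$query_id[is.na(assignments$subject_locus)]))
}
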