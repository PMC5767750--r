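#' Read / write a peptide evidence table
#'
#' The evidence dialect is a plain TSV with columns \code{dataset_id},
#' \code{tissue} (anther|meiocyte), \code{channel} (sample|control),
#' \code{replicate}, \code{protein_id}, \code{peptide_seq},
#' \code{identified} (0|1), \code{peak_area}, \code{mod_positions},
#' \code{mod_probs}.
#'
#' @param path file path.
#' @return data.frame of evidence rows.
#' @export
read_evidence <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                           comment.char = "", stringsAsFactors = FALSE)
  need <- c("dataset_id", "tissue", "channel", "replicate", "protein_id",
            "peptide_seq", "identified", "peak_area")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("evidence table lacks column(s): ", paste(miss, collapse = ", "))
  tab
}

#' @rdname read_evidence
#' @param evidence evidence data.frame.
#' @export
write_evidence <- function(evidence, path) {
  write_tsv(evidence, path)
}

# fixed-precision TSV writer: floats at 6 significant digits so reruns
# are byte-identical
write_tsv <- function(x, path) {
  for (j in seq_along(x)) {
    if (is.numeric(x[[j]]) && !is.integer(x[[j]]))
      x[[j]] <- signif(x[[j]], 6)
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  out <- as.character(aa)
  names(out) <- sub("\\s.*$", "", names(aa))
  out
}

#' Write protein sequences to FASTA
#'
#' @param sequences named character vector.
#' @param path output file.
#' @export
write_fasta <- function(sequences, path) {
  aa <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}
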