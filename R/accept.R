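#' Filter configuration for two-tier protein acceptance
#'
#' @param fc_min minimum fold-change for the quantitative tier (default 5).
#' @param p_max p-value ceiling for the quantitative tier (default 0.01).
#' @param min_unique_peptides minimum number of distinct peptide sequences
#'   (modifications stripped) required within a single dataset (default 2).
#' @return list of class \code{filter_config}.
#' @export
filter_config <- function(fc_min = 5, p_max = 0.01, min_unique_peptides = 2) {
  stopifnot(fc_min > 1, p_max > 0, p_max < 1, min_unique_peptides >= 1)
  structure(list(fc_min = fc_min, p_max = p_max,
                 min_unique_peptides = min_unique_peptides),
            class = "filter_config")
}

# strip modification annotations like "(S)" or "pS" markers from peptide
# strings; evidence tables store plain sequences, so this is a no-op guard
strip_mods <- function(x) gsub("[^A-Z]", "", toupper(x))

#' Two-tier acceptance of co-immunoprecipitated proteins
#'
#' A protein is accepted iff (a) it is identified (spectral ID) in at least
#' one sample-channel observation, (b) it is identified in zero
#' control-channel observations across all datasets, and (c) it carries at
#' least \code{min_unique_peptides} distinct peptide sequences in at least
#' one dataset. Accepted proteins that are additionally significant in the
#' moderated-t quantification of at least one dataset form the
#' \emph{quantitative} tier; the remainder form the less reliable
#' \emph{qualitative} (sample-specific) tier.
#'
#' Control exclusion keys on \emph{identification}, not on quantified area:
#' a protein may have an integrated control peak area (needed to form the
#' fold-change ratio) while never being spectrally identified in a control,
#' which is how the quantitative tier coexists with blanket control
#' exclusion.
#'
#' @param evidence peptide evidence data.frame (see
#'   \code{\link{simulate_coip}} for the dialect).
#' @param quant quantification results from \code{\link{quantify_all}} /
#'   \code{\link{test_dataset}}; may be \code{NULL} (everything accepted
#'   lands in the qualitative tier).
#' @param config a \code{\link{filter_config}}.
#' @return data.frame of class \code{accepted_proteins}: \code{protein_id},
#'   \code{tier} ("quantitative"/"qualitative"), \code{tissues}
#'   (";"-joined), \code{datasets_observed} (";"-joined),
#'   \code{max_unique_peptides_in_a_dataset}.
#' @export
accept_proteins <- function(evidence, quant = NULL, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  if (nrow(evidence) == 0L) {
    out <- data.frame(protein_id = character(), tier = character(),
                      tissues = character(), datasets_observed = character(),
                      max_unique_peptides_in_a_dataset = integer(),
                      stringsAsFactors = FALSE)
    class(out) <- c("accepted_proteins", class(out))
    return(out)
  }
  ev <- evidence
  ev$peptide_plain <- strip_mods(ev$peptide_seq)
  ided <- ev[ev$identified == 1L, , drop = FALSE]

  sample_id <- unique(ided$protein_id[ided$channel == "sample"])
  control_id <- unique(ided$protein_id[ided$channel == "control"])
  candidates <- setdiff(sample_id, control_id)
  if (length(candidates) == 0L)
    return(accept_proteins(evidence[0, , drop = FALSE], quant, config))

  samp <- ided[ided$channel == "sample" & ided$protein_id %in% candidates, ,
               drop = FALSE]
  # distinct stripped peptides per protein within each dataset
  key <- paste(samp$protein_id, samp$dataset_id, sep = "\r")
  pep_per_ds <- tapply(samp$peptide_plain, key,
                       function(p) length(unique(p)))
  prot_of_key <- vapply(strsplit(names(pep_per_ds), "\r"), `[`, "", 1L)
  max_pep <- tapply(as.integer(pep_per_ds), prot_of_key, max)

  keep <- names(max_pep)[max_pep >= config$min_unique_peptides]
  if (length(keep) == 0L)
    return(accept_proteins(evidence[0, , drop = FALSE], quant, config))

  sig_prot <- character()
  if (!is.null(quant) && nrow(quant) > 0L)
    sig_prot <- unique(quant$protein_id[quant$significant])

  rows <- lapply(sort(keep), function(p) {
    sub <- samp[samp$protein_id == p, , drop = FALSE]
    data.frame(protein_id = p,
               tier = if (p %in% sig_prot) "quantitative" else "qualitative",
               tissues = paste(sort(unique(sub$tissue)), collapse = ";"),
               datasets_observed = paste(sort(unique(sub$dataset_id)),
                                         collapse = ";"),
               max_unique_peptides_in_a_dataset =
                 as.integer(max_pep[[p]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("accepted_proteins", class(out))
  out
}

#' Tissue overlap of accepted proteins, at protein and locus level
#'
#' Counts proteins observed in both tissues, in anthers only and in
#' meiocytes only, and repeats the count at the collapsed ortholog-locus
#' level, where a locus inherits the union of its contributing proteins'
#' tissue sets.
#'
#' @param accepted output of \code{\link{accept_proteins}}.
#' @param assignments optional ortholog assignments
#'   (\code{\link{assign_best_hits}} output) covering the accepted ids;
#'   unassigned queries are allowed and excluded from the locus level.
#' @return list with \code{protein} and (if assignments given) \code{locus}
#'   components, each \code{c(both, anther_only, meiocyte_only, total)}.
#' @export
tissue_overlap <- function(accepted, assignments = NULL) {
  tis <- strsplit(accepted$tissues, ";", fixed = TRUE)
  names(tis) <- accepted$protein_id
  count_level <- function(tissue_sets) {
    both <- sum(vapply(tissue_sets, function(t)
      all(c("anther", "meiocyte") %in% t), TRUE))
    a <- sum(vapply(tissue_sets, function(t)
      "anther" %in% t && !("meiocyte" %in% t), TRUE))
    m <- sum(vapply(tissue_sets, function(t)
      "meiocyte" %in% t && !("anther" %in% t), TRUE))
    c(both = both, anther_only = a, meiocyte_only = m,
      total = length(tissue_sets))
  }
  out <- list(protein = count_level(tis))
  if (!is.null(assignments)) {
    asg <- assignments[!is.na(assignments$subject_locus) &
                         assignments$query_id %in% accepted$protein_id, ,
                       drop = FALSE]
    locus_sets <- tapply(asg$query_id, asg$subject_locus, function(q)
      sort(unique(unlist(tis[q]))), simplify = FALSE)
    out$locus <- count_level(locus_sets)
  }
  out
}
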