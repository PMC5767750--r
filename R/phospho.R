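#' Read a phosphopeptide table
#'
#' Parses the TSV dialect used for phosphopeptide observations (see the
#' packaged BoASY1/BoASY3 table under
#' \code{system.file("extdata", "boasy_phosphopeptides_tbl1.tsv",
#' package = "coipnet")}). Within the position/probability columns,
#' \code{";"} separates co-occurring sites of a multiply phosphorylated
#' peptide and \code{"|"} separates the two candidate positions of one
#' unresolved localization ambiguity.
#'
#' @param path TSV file with columns \code{protein_id},
#'   \code{protein_positions} (optional, may be absent when a full protein
#'   FASTA is supplied instead), \code{peptide_seq}, \code{pep_positions},
#'   \code{probs}, \code{tissues}.
#' @return data.frame, one row per observed peptide form.
#' @export
read_phosphopeptides <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                           comment.char = "#", stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("protein_id", "peptide_seq", "pep_positions", "probs", "tissues")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("phosphopeptide table lacks column(s): ", paste(miss, collapse = ", "))
  tab
}

#' Map peptide-local phosphosite positions to protein coordinates
#'
#' Locates \code{peptide_seq} as an exact substring of \code{protein_seq}.
#' The peptide must occur exactly once: zero occurrences is a mapping
#' error, more than one makes the site position unidentifiable (ambiguity
#' error). Protein position = occurrence offset + in-peptide position
#' (1-based at both ends).
#'
#' @param peptide_seq plain residue string (no modification marks).
#' @param pep_positions integer vector of 1-based in-peptide positions.
#' @param protein_seq full protein residue string.
#' @return integer vector of protein coordinates.
#' @export
map_peptide_sites <- function(peptide_seq, pep_positions, protein_seq) {
  stopifnot(nchar(peptide_seq) > 0, nchar(protein_seq) > 0)
  hits <- gregexpr(peptide_seq, protein_seq, fixed = TRUE)[[1]]
  if (hits[1] == -1L)
    stop("peptide '", peptide_seq, "' does not occur in the protein sequence")
  if (length(hits) > 1L)
    stop("peptide '", peptide_seq, "' occurs ", length(hits),
         " times in the protein sequence; site position cannot be inferred")
  pos <- as.integer(hits[1]) - 1L + as.integer(pep_positions)
  pep_res <- substring(peptide_seq, pep_positions, pep_positions)
  prot_res <- substring(protein_seq, pos, pos)
  if (!all(pep_res == prot_res))
    stop("residue mismatch between peptide and protein at mapped position(s)")
  pos
}

# split "253;260" / "442|443" tokens; returns list of integer vectors,
# one per phospho group (length 2 = unresolved ambiguity)
parse_position_groups <- function(x) {
  groups <- strsplit(x, ";", fixed = TRUE)[[1]]
  lapply(groups, function(g) as.integer(strsplit(g, "|", fixed = TRUE)[[1]]))
}

# expand a phosphopeptide table into one row per phospho group
# (= one site observation on one peptide), with protein coordinates taken
# from the table or computed from `proteins` (named character vector of
# full sequences)
phospho_observations <- function(peptides, proteins = NULL) {
  rows <- list()
  for (i in seq_len(nrow(peptides))) {
    r <- peptides[i, ]
    pep_groups <- parse_position_groups(r$pep_positions)
    prob_groups <- strsplit(strsplit(r$probs, ";", fixed = TRUE)[[1]], "|",
                            fixed = TRUE)
    if (!is.null(proteins) && r$protein_id %in% names(proteins)) {
      offset <- map_peptide_sites(r$peptide_seq, 1L,
                                  proteins[[r$protein_id]]) - 1L
      prot_groups <- lapply(pep_groups, function(g) g + offset)
    } else if ("protein_positions" %in% names(peptides) &&
               nzchar(r$protein_positions)) {
      prot_groups <- parse_position_groups(r$protein_positions)
    } else {
      stop("row ", i, ": no protein sequence and no protein_positions; ",
           "cannot place sites for '", r$protein_id, "'")
    }
    stopifnot(length(prot_groups) == length(pep_groups))
    for (k in seq_along(pep_groups)) {
      pp <- pep_groups[[k]]
      res <- substring(r$peptide_seq, pp, pp)
      if (!all(res %in% c("S", "T")))
        stop("row ", i, ": phosphosite residue must be S or T, got ",
             paste(res, collapse = ","))
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = r$protein_id,
        positions = paste(prot_groups[[k]], collapse = "|"),
        pep_positions = paste(pp, collapse = "|"),
        residues = paste(res, collapse = "|"),
        probs = paste(prob_groups[[min(k, length(prob_groups))]],
                      collapse = "|"),
        ambiguous = length(pp) == 2L,
        peptide_seq = r$peptide_seq,
        offset = prot_groups[[k]][1] - pp[1],
        tissues = r$tissues,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Collapse mapped phosphopeptide observations to distinct protein sites
#'
#' Observations sharing a resolved protein position merge into one site.
#' An unresolved two-position ambiguity ("X or Y") counts as \emph{one}
#' site, unless another peptide resolves one of its candidate positions, in
#' which case it merges into that resolved site. Multiply phosphorylated
#' peptides contribute each of their phospho groups independently. Tissues
#' and supporting peptides are unioned; a conflicting residue identity at a
#' shared position is a consistency error.
#'
#' @param observations data.frame from the internal expansion of a
#'   phosphopeptide table (one row per phospho group; see
#'   \code{\link{phospho_sites}} which calls this for you).
#' @return data.frame of distinct sites: \code{protein_id},
#'   \code{positions} ("294" or "442|443"), \code{residues},
#'   \code{ambiguous}, \code{n_peptides}, \code{supporting_peptides},
#'   \code{tissues}.
#' @export
collapse_sites <- function(observations) {
  out <- list()
  for (pid in sort(unique(observations$protein_id))) {
    obs <- observations[observations$protein_id == pid, , drop = FALSE]
    groups <- lapply(obs$positions, function(x)
      as.integer(strsplit(x, "|", fixed = TRUE)[[1]]))
    res_groups <- lapply(obs$residues, function(x)
      strsplit(x, "|", fixed = TRUE)[[1]])
    # residue identity bookkeeping
    res_at <- list()
    for (k in seq_along(groups)) {
      for (j in seq_along(groups[[k]])) {
        key <- as.character(groups[[k]][j])
        r <- res_groups[[k]][j]
        if (!is.null(res_at[[key]]) && res_at[[key]] != r)
          stop("conflicting residue identity at ", pid, " position ", key)
        res_at[[key]] <- r
      }
    }
    single <- lengths(groups) == 1L
    resolved <- sort(unique(unlist(groups[single])))
    # site key per observation group: resolved position or pair label
    site_of <- character(length(groups))
    for (k in seq_along(groups)) {
      g <- groups[[k]]
      if (length(g) == 1L) {
        site_of[k] <- as.character(g)
      } else {
        hit <- g[g %in% resolved]
        site_of[k] <- if (length(hit)) as.character(hit[1])
                      else paste(g, collapse = "|")
      }
    }
    for (key in unique(site_of)) {
      idx <- which(site_of == key)
      pos <- as.integer(strsplit(key, "|", fixed = TRUE)[[1]])
      tis <- sort(unique(unlist(strsplit(obs$tissues[idx], ";", fixed = TRUE))))
      peps <- sort(unique(obs$peptide_seq[idx]))
      out[[length(out) + 1L]] <- data.frame(
        protein_id = pid,
        positions = key,
        residues = paste(vapply(as.character(pos),
                                function(p) res_at[[p]], ""), collapse = "|"),
        ambiguous = length(pos) == 2L,
        n_peptides = length(peps),
        supporting_peptides = paste(peps, collapse = ";"),
        tissues = paste(tis, collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  sites <- do.call(rbind, out)
  first_pos <- vapply(strsplit(sites$positions, "|", fixed = TRUE),
                      function(x) as.integer(x[1]), 1L)
  sites <- sites[order(sites$protein_id, first_pos), , drop = FALSE]
  rownames(sites) <- NULL
  sites
}

#' Classify kinase consensus motifs at a phosphosite
#'
#' Labels, per candidate position (either candidate matching suffices for
#' an ambiguous site):
#' \itemize{
#'   \item \code{STQ}: glutamine at +1 (ATM/ATR family preference);
#'   \item \code{CDK1_minimal}: proline at +1 (S/T-P);
#'   \item \code{CDK1_full}: proline at +1 and K or R at +3 (S/T-P-X-K/R;
#'     implies \code{CDK1_minimal});
#'   \item \code{CK2}: acidic residue (D/E) at +1 or +3, where positions in
#'     \code{phospho_positions} (already-assigned phosphosites) also count
#'     as acidic.
#' }
#' When the needed context extends past the available sequence the affected
#' labels are omitted and \code{truncated} is set, never an error — this is
#' what permits peptide-local classification when no full-length protein
#' sequence is available.
#'
#' @param protein_seq residue string providing context; may be a bare
#'   peptide together with peptide-local \code{positions}.
#' @param positions integer vector: 1 (resolved) or 2 (ambiguous
#'   candidates) coordinates into \code{protein_seq}.
#' @param phospho_positions coordinates (same system) of other known
#'   phosphosites, counted as acidic for the CK2 rule.
#' @return list with \code{labels} (character subset of
#'   \code{STQ, CDK1_minimal, CDK1_full, CK2}) and \code{truncated}
#'   (logical).
#' @export
classify_site_motifs <- function(protein_seq, positions,
                                 phospho_positions = integer()) {
  n <- nchar(protein_seq)
  at <- function(p) if (p >= 1 && p <= n) substring(protein_seq, p, p)
                    else NA_character_
  labels <- character()
  truncated <- FALSE
  for (p in positions) {
    r1 <- at(p + 1); r3 <- at(p + 3)
    if (is.na(r1) || is.na(r3)) truncated <- TRUE
    if (!is.na(r1) && r1 == "Q") labels <- c(labels, "STQ")
    if (!is.na(r1) && r1 == "P") {
      labels <- c(labels, "CDK1_minimal")
      if (!is.na(r3) && r3 %in% c("K", "R")) labels <- c(labels, "CDK1_full")
    }
    acidic <- function(pp, r) (!is.na(r) && r %in% c("D", "E")) ||
      pp %in% phospho_positions
    if (acidic(p + 1, r1) || acidic(p + 3, r3)) labels <- c(labels, "CK2")
  }
  list(labels = intersect(c("STQ", "CDK1_minimal", "CDK1_full", "CK2"),
                          unique(labels)),
       truncated = truncated)
}

#' Build, collapse and motif-annotate the phosphosite inventory
#'
#' End-to-end phospho stage: expands a phosphopeptide table into site
#' observations (mapping to protein coordinates through \code{proteins}
#' when given, otherwise using the table's own \code{protein_positions}),
#' collapses them to distinct sites (\code{\link{collapse_sites}}) and
#' annotates each site with kinase consensus motifs
#' (\code{\link{classify_site_motifs}}); with a full-length sequence,
#' motif context comes from the protein, otherwise from the supporting
#' peptides (truncation flagged).
#'
#' @param peptides phosphopeptide table (\code{\link{read_phosphopeptides}}).
#' @param proteins optional named character vector of full protein
#'   sequences.
#' @return site data.frame as \code{\link{collapse_sites}} plus
#'   \code{motif_labels} (";"-joined) and \code{context_truncated}.
#' @export
phospho_sites <- function(peptides, proteins = NULL) {
  obs <- phospho_observations(peptides, proteins)
  sites <- collapse_sites(obs)
  sites$motif_labels <- ""
  sites$context_truncated <- FALSE
  for (i in seq_len(nrow(sites))) {
    pid <- sites$protein_id[i]
    pos <- as.integer(strsplit(sites$positions[i], "|", fixed = TRUE)[[1]])
    prior <- unlist(lapply(strsplit(
      sites$positions[sites$protein_id == pid], "|", fixed = TRUE),
      as.integer))
    if (!is.null(proteins) && pid %in% names(proteins)) {
      cl <- classify_site_motifs(proteins[[pid]], pos, prior)
    } else {
      # peptide-local context: evaluate on each supporting observation's
      # peptide, in protein coordinates via the peptide offset
      sup <- obs[obs$protein_id == pid, , drop = FALSE]
      labs <- character(); trunc <- TRUE
      for (k in seq_len(nrow(sup))) {
        g <- as.integer(strsplit(sup$positions[k], "|", fixed = TRUE)[[1]])
        if (!any(g %in% pos)) next
        off <- sup$offset[k]
        local_pos <- intersect(g, pos) - off
        cl_k <- classify_site_motifs(sup$peptide_seq[k], local_pos,
                                     prior - off)
        labs <- c(labs, cl_k$labels)
        trunc <- trunc && cl_k$truncated
      }
      cl <- list(labels = intersect(
        c("STQ", "CDK1_minimal", "CDK1_full", "CK2"), unique(labs)),
        truncated = trunc)
    }
    sites$motif_labels[i] <- paste(cl$labels, collapse = ";")
    sites$context_truncated[i] <- cl$truncated
  }
  sites
}

#' Per-protein phosphosite inventory summary
#'
#' @param sites output of \code{\link{phospho_sites}}.
#' @return data.frame per protein: \code{n_peptides} (distinct supporting
#'   peptide sequences), \code{n_sites}, \code{n_stq}, \code{n_cdk1}
#'   (minimal-or-full consensus), \code{n_cdk1_full}, \code{n_ck2}.
#' @export
phospho_summary <- function(sites) {
  has <- function(lab, x) vapply(strsplit(x, ";", fixed = TRUE),
                                 function(l) lab %in% l, TRUE)
  rows <- lapply(sort(unique(sites$protein_id)), function(pid) {
    s <- sites[sites$protein_id == pid, , drop = FALSE]
    peps <- unique(unlist(strsplit(s$supporting_peptides, ";", fixed = TRUE)))
    data.frame(protein_id = pid,
               n_peptides = length(peps),
               n_sites = nrow(s),
               n_stq = sum(has("STQ", s$motif_labels)),
               n_cdk1 = sum(has("CDK1_minimal", s$motif_labels)),
               n_cdk1_full = sum(has("CDK1_full", s$motif_labels)),
               n_ck2 = sum(has("CK2", s$motif_labels)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Configuration for S/TQ cluster-domain detection
#'
#' @param min_motifs minimum number of S/TQ motifs in a qualifying window
#'   (default 3).
#' @param max_span maximum first-to-last residue span of a qualifying
#'   window, inclusive (default 100): \code{last - first + 1 <= max_span}.
#' @return list of class \code{scd_config}.
#' @export
scd_config <- function(min_motifs = 3, max_span = 100) {
  stopifnot(min_motifs >= 2, max_span >= 2)
  structure(list(min_motifs = min_motifs, max_span = max_span),
            class = "scd_config")
}

#' S/TQ motif positions of a sequence
#'
#' @param protein_seq residue string.
#' @return 1-based positions of S or T immediately followed by Q.
#' @export
stq_positions <- function(protein_seq) {
  chars <- strsplit(protein_seq, "")[[1]]
  n <- length(chars)
  if (n < 2) return(integer())
  which(chars[-n] %in% c("S", "T") & chars[-1] == "Q")
}

#' Detect S/TQ cluster domains from motif positions
#'
#' A window of \code{min_motifs} or more motifs whose first-to-last span
#' (inclusive) does not exceed \code{max_span} qualifies as a cluster
#' domain; overlapping or chained qualifying windows merge into a single
#' region. Regions are disjoint and sorted.
#'
#' @param positions integer vector of S/TQ motif positions.
#' @param config an \code{\link{scd_config}}.
#' @return data.frame: \code{start}, \code{end} (coordinates of first/last
#'   member motif), \code{n_members}, \code{member_positions} (";"-joined).
#' @export
scd_from_positions <- function(positions, config = scd_config()) {
  empty <- data.frame(start = integer(), end = integer(),
                      n_members = integer(), member_positions = character(),
                      stringsAsFactors = FALSE)
  pos <- sort(unique(as.integer(positions)))
  m <- length(pos)
  if (m < config$min_motifs) return(empty)
  # qualifying windows as index intervals [i, j]
  wins <- list()
  for (i in seq_len(m)) {
    j <- i
    while (j < m && pos[j + 1] - pos[i] + 1 <= config$max_span) j <- j + 1
    if (j - i + 1 >= config$min_motifs)
      wins[[length(wins) + 1L]] <- c(as.integer(i), as.integer(j))
  }
  if (!length(wins)) return(empty)
  # merge index intervals that share a motif
  wins <- wins[order(vapply(wins, `[`, 1L, 1L))]
  merged <- list(wins[[1]])
  for (w in wins[-1]) {
    last <- merged[[length(merged)]]
    if (w[1] <= last[2]) merged[[length(merged)]] <- c(last[1], max(last[2], w[2]))
    else merged[[length(merged) + 1L]] <- w
  }
  rows <- lapply(merged, function(w) {
    members <- pos[w[1]:w[2]]
    data.frame(start = members[1], end = members[length(members)],
               n_members = length(members),
               member_positions = paste(members, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Detect S/TQ cluster domains in a protein sequence
#'
#' @inheritParams stq_positions
#' @inheritParams scd_from_positions
#' @return as \code{\link{scd_from_positions}}.
#' @export
detect_scd <- function(protein_seq, config = scd_config()) {
  scd_from_positions(stq_positions(protein_seq), config)
}

#' Cross-species site correspondence through a pairwise alignment
#'
#' Walks the columns of a global alignment and returns the position in the
#' other sequence that is aligned with a residue of the source sequence,
#' or \code{NA} when that column pairs the source residue with a gap.
#'
#' @param alignment an \code{alignment} object from
#'   \code{\link{global_align}}.
#' @param source_position 1-based position in the source sequence.
#' @param source which sequence the position refers to: \code{"a"}
#'   (default) or \code{"b"}.
#' @return integer target coordinate, or \code{NA_integer_} for a gap.
#' @export
site_correspondence <- function(alignment, source_position,
                                source = c("a", "b")) {
  source <- match.arg(source)
  src <- strsplit(if (source == "a") alignment$aligned_a else alignment$aligned_b,
                  "")[[1]]
  tgt <- strsplit(if (source == "a") alignment$aligned_b else alignment$aligned_a,
                  "")[[1]]
  src_len <- sum(src != "-")
  if (source_position < 1 || source_position > src_len)
    stop("source_position ", source_position, " outside sequence length ",
         src_len)
  si <- cumsum(src != "-")
  col <- match(source_position, si)
  if (tgt[col] == "-") return(NA_integer_)
  sum(tgt[seq_len(col)] != "-")
}
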