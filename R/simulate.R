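#' Configuration for the co-IP evidence simulator
#'
#' Defaults emulate the study design the pipeline targets: nine co-IP
#' datasets (five anther, four meiocyte), six of them with technical
#' triplicates of sample and control, matched IgG control channels,
#' spiked true-complex proteins, background binders identified in
#' controls, and a low-evidence sample-specific cohort.
#'
#' @param n_datasets number of co-IP datasets (default 9; the first
#'   \code{ceiling(5/9 * n)} are anther, the rest meiocyte).
#' @param triplicate_datasets indices of datasets with technical
#'   triplicates (default \code{c(1, 2, 3, 6, 7, 8)}); the remaining
#'   datasets have a single replicate per channel and contribute only
#'   qualitative evidence.
#' @param n_true_complex number of planted true-complex proteins
#'   (enriched in sample, never identified in controls).
#' @param n_background number of background binders (identified in
#'   control channels too).
#' @param n_sample_specific_low number of low-evidence sample-specific
#'   proteins (exactly 2 peptides, sample channels only).
#' @param log2_fc_true mean planted log2 enrichment of true-complex
#'   proteins (default 3, i.e. 8-fold, comfortably above the 5-fold
#'   acceptance threshold).
#' @param intensity_cv coefficient of variation of peak areas on the
#'   natural scale, in (0,1) (default 0.2, a typical technical-replicate
#'   CV for label-free peak areas).
#' @param missing_rate probability that a quantified observation is
#'   missing at random, in [0,1) (default 0.1). Missing means absent from
#'   the table, never zero.
#' @param min_peptides_true minimum number of distinct peptides per
#'   true-complex protein (>= 2; default 3).
#' @param seed integer seed; identical config + seed gives identical
#'   output.
#' @return list of class \code{coip_sim_config}.
#' @export
coip_sim_config <- function(n_datasets = 9,
                            triplicate_datasets = c(1, 2, 3, 6, 7, 8),
                            n_true_complex = 50,
                            n_background = 100,
                            n_sample_specific_low = 25,
                            log2_fc_true = 3,
                            intensity_cv = 0.2,
                            missing_rate = 0.1,
                            min_peptides_true = 3,
                            seed = 1L) {
  stopifnot(n_datasets >= 1,
            length(triplicate_datasets) >= 1,
            all(triplicate_datasets %in% seq_len(n_datasets)),
            n_true_complex >= 0, n_background >= 0,
            n_sample_specific_low >= 0,
            intensity_cv > 0, intensity_cv < 1,
            missing_rate >= 0, missing_rate < 1,
            min_peptides_true >= 2)
  structure(as.list(environment()), class = "coip_sim_config")
}

# tryptic-like peptide: internal residues without K/R, C-terminal K or R
random_peptide <- function(len) {
  internal <- c("A", "C", "D", "E", "F", "G", "H", "I", "L", "M", "N", "P",
                "Q", "S", "T", "V", "W", "Y")
  paste0(paste(sample(internal, len - 1, replace = TRUE), collapse = ""),
         sample(c("K", "R"), 1))
}

unique_peptides <- function(n, len_range = c(8, 14)) {
  peps <- character(0)
  while (length(peps) < n) {
    peps <- unique(c(peps, vapply(seq_len(n - length(peps)), function(i)
      random_peptide(sample(len_range[1]:len_range[2], 1)), "")))
  }
  peps
}

#' Simulate a co-IP peptide evidence table with known ground truth
#'
#' Generates the full peptide evidence table the quantification and
#' acceptance stages consume. Log2 peak areas are normal around a
#' protein/peptide baseline (log-normal areas) with standard deviation
#' derived from \code{intensity_cv}; true-complex proteins are enriched
#' by \code{log2_fc_true} in sample channels and, while their control
#' peak areas exist at the depressed baseline (peak integration without
#' spectral identification), they are never flagged \emph{identified} in
#' a control; background binders are identified in controls; the
#' low-evidence cohort appears only in sample channels with exactly two
#' peptides. Missing-at-random rows are deleted, not zeroed.
#'
#' @param config a \code{\link{coip_sim_config}}.
#' @return list with \code{evidence} (data.frame: \code{dataset_id},
#'   \code{tissue}, \code{channel}, \code{replicate}, \code{protein_id},
#'   \code{peptide_seq}, \code{identified}, \code{peak_area},
#'   \code{mod_positions}, \code{mod_probs}) and \code{truth} (list of id
#'   sets: \code{true_complex_ids}, \code{background_ids},
#'   \code{sample_specific_ids}).
#' @export
simulate_coip <- function(config = coip_sim_config()) {
  stopifnot(inherits(config, "coip_sim_config"))
  set.seed(config$seed)
  sigma <- sqrt(log(1 + config$intensity_cv^2)) / log(2)
  n_anther <- ceiling(config$n_datasets * 5 / 9)
  datasets <- data.frame(
    dataset_id = sprintf("DS%02d", seq_len(config$n_datasets)),
    tissue = c(rep("anther", n_anther),
               rep("meiocyte", config$n_datasets - n_anther)),
    n_rep = ifelse(seq_len(config$n_datasets) %in% config$triplicate_datasets,
                   3L, 1L),
    stringsAsFactors = FALSE)

  truth <- list(
    true_complex_ids = if (config$n_true_complex > 0)
      sprintf("TRUE%03d", seq_len(config$n_true_complex)) else character(),
    background_ids = if (config$n_background > 0)
      sprintf("BG%03d", seq_len(config$n_background)) else character(),
    sample_specific_ids = if (config$n_sample_specific_low > 0)
      sprintf("LOW%03d", seq_len(config$n_sample_specific_low))
      else character())

  rows <- list()
  emit <- function(ds, channel, rep_i, protein, peptides, log2_mu,
                   identified) {
    k <- length(peptides)
    rows[[length(rows) + 1L]] <<- data.frame(
      dataset_id = ds$dataset_id, tissue = ds$tissue, channel = channel,
      replicate = rep_i, protein_id = protein,
      peptide_seq = peptides,
      identified = as.integer(identified),
      peak_area = 2^(log2_mu + stats::rnorm(k, 0, sigma)),
      mod_positions = "", mod_probs = "",
      stringsAsFactors = FALSE)
  }

  for (pid in truth$true_complex_ids) {
    n_pep <- sample(config$min_peptides_true:(config$min_peptides_true + 3), 1)
    peps <- unique_peptides(n_pep)
    base <- stats::runif(1, 14, 20) + stats::rnorm(n_pep, 0, 0.8)
    for (d in seq_len(nrow(datasets))) {
      ds <- datasets[d, ]
      for (r in seq_len(ds$n_rep)) {
        emit(ds, "sample", r, pid, peps, base + config$log2_fc_true, TRUE)
        emit(ds, "control", r, pid, peps, base, FALSE)
      }
    }
  }
  for (pid in truth$background_ids) {
    n_pep <- sample(2:5, 1)
    peps <- unique_peptides(n_pep)
    base <- stats::runif(1, 14, 20) + stats::rnorm(n_pep, 0, 0.8)
    for (d in seq_len(nrow(datasets))) {
      ds <- datasets[d, ]
      for (r in seq_len(ds$n_rep)) {
        emit(ds, "sample", r, pid, peps, base, TRUE)
        emit(ds, "control", r, pid, peps, base, TRUE)
      }
    }
  }
  for (pid in truth$sample_specific_ids) {
    peps <- unique_peptides(2)
    base <- stats::runif(1, 12, 16) + stats::rnorm(2, 0, 0.8)
    in_ds <- sort(sample(seq_len(nrow(datasets)),
                         min(sample(1:2, 1), nrow(datasets))))
    for (d in in_ds) {
      ds <- datasets[d, ]
      for (r in seq_len(ds$n_rep)) {
        emit(ds, "sample", r, pid, peps, base, TRUE)
      }
    }
  }

  if (length(rows) == 0L) {
    evidence <- data.frame(dataset_id = character(), tissue = character(),
                           channel = character(), replicate = integer(),
                           protein_id = character(), peptide_seq = character(),
                           identified = integer(), peak_area = numeric(),
                           mod_positions = character(),
                           mod_probs = character(), stringsAsFactors = FALSE)
  } else {
    evidence <- do.call(rbind, rows)
    if (config$missing_rate > 0) {
      # missing-at-random suppresses the quantified peak area; the
      # spectral identification status of the observation is untouched
      # (peak integration and spectral ID are distinct events)
      drop <- stats::runif(nrow(evidence)) < config$missing_rate
      evidence$peak_area[drop] <- NA_real_
    }
    o <- order(evidence$dataset_id, evidence$channel, evidence$replicate,
               evidence$protein_id, evidence$peptide_seq)
    evidence <- evidence[o, , drop = FALSE]
    rownames(evidence) <- NULL
  }
  list(evidence = evidence, truth = truth, datasets = datasets)
}

#' Simulate a proteome with planted S/TQ cluster domains and kinase motifs
#'
#' Background sequence is drawn from an alphabet without Q, P, D and E, so
#' that no S/TQ, CDK1 or CK2 motif can arise by chance; planted features
#' are then written in with a 5-residue guard band between reservations.
#' Planted cluster domains contain three S/TQ dipeptides spanning at most
#' 100 residues; planted \code{CDK1_full} sites get P at +1 and K/R at
#' +3; \code{CDK1_minimal} sites get P at +1 and a neutral residue at +3;
#' \code{CK2} sites get D at +1; \code{STQ} sites get Q at +1.
#'
#' @param n_proteins number of proteins.
#' @param length_range integer min/max sequence length; max must be at
#'   least 120 when cluster domains are planted.
#' @param n_planted_scds number of planted S/TQ cluster domains.
#' @param n_planted_sites_per_class planted phosphosites per motif class
#'   (classes: STQ, CDK1_minimal, CDK1_full, CK2).
#' @param seed integer seed.
#' @return list with \code{sequences} (named character vector) and
#'   \code{truth} (\code{planted_scds}: data.frame protein_id/start/end;
#'   \code{planted_sites}: data.frame protein_id/position/motif_label).
#' @export
simulate_proteome <- function(n_proteins = 20, length_range = c(150, 400),
                              n_planted_scds = 2,
                              n_planted_sites_per_class = 2,
                              seed = 1L) {
  stopifnot(n_proteins >= 1, length_range[1] >= 30)
  if (n_planted_scds > 0 && length_range[2] < 120)
    stop("infeasible planting: max length must be >= 120 for cluster domains")
  set.seed(seed)
  scrubbed <- c("A", "C", "F", "G", "H", "I", "K", "L", "M", "N", "R",
                "S", "T", "V", "W", "Y")
  lens <- sample(length_range[1]:length_range[2], n_proteins, replace = TRUE)
  if (n_planted_scds > 0) lens[seq_len(min(n_planted_scds, n_proteins))] <-
    pmax(lens[seq_len(min(n_planted_scds, n_proteins))], 130L)
  seqs <- vapply(lens, function(L)
    paste(sample(scrubbed, L, replace = TRUE), collapse = ""), "")
  names(seqs) <- sprintf("PROT%03d", seq_len(n_proteins))
  reserved <- lapply(seq_len(n_proteins), function(i) cbind(lo = integer(),
                                                            hi = integer()))
  reserve <- function(i, lo, hi) {
    r <- reserved[[i]]
    if (any(pmax(r[, "lo"], lo - 5) <= pmin(r[, "hi"], hi + 5))) return(FALSE)
    reserved[[i]] <<- rbind(r, c(lo, hi))
    TRUE
  }
  put <- function(i, pos, what) {
    s <- seqs[[i]]
    seqs[[i]] <<- paste0(substring(s, 1, pos - 1), what,
                         substring(s, pos + nchar(what)))
  }
  scds <- list(); sites <- list()
  scd_prots <- character(); stq_prots <- character()
  target <- function(k) ((k - 1) %% n_proteins) + 1
  for (k in seq_len(n_planted_scds)) {
    placed <- FALSE
    for (try in 1:200) {
      i <- if (try == 1) target(k) else sample(n_proteins, 1)
      L <- nchar(seqs[[i]])
      if (L < 120) next
      start <- sample(5:(L - 100), 1)
      gaps <- sort(sample(seq(5, 95, by = 3), 2))
      p <- c(start, start + gaps)
      if (p[3] - p[1] + 1 > 100) next
      if (!reserve(i, p[1], p[3] + 1)) next
      for (pp in p) put(i, pp, paste0(sample(c("S", "T"), 1), "Q"))
      scds[[length(scds) + 1L]] <- data.frame(
        protein_id = names(seqs)[i], start = p[1], end = p[3],
        member_positions = paste(p, collapse = ";"),
        stringsAsFactors = FALSE)
      scd_prots <- union(scd_prots, names(seqs)[i])
      placed <- TRUE
      break
    }
    if (!placed) stop("infeasible planting: could not place cluster domain")
  }
  classes <- c("STQ", "CDK1_minimal", "CDK1_full", "CK2")
  neutral <- c("A", "G", "L", "V")
  for (cl in classes) {
    for (k in seq_len(n_planted_sites_per_class)) {
      placed <- FALSE
      for (try in 1:200) {
        # S/TQ motifs must not contaminate planted cluster-domain truth,
        # and no protein accumulates several loose S/TQ sites
        banned <- if (cl == "STQ") union(scd_prots, stq_prots) else scd_prots
        pool <- which(!(names(seqs) %in% banned))
        if (!length(pool))
          stop("infeasible planting: no protein left for ", cl, " site")
        i <- if (length(pool) == 1) pool else sample(pool, 1)
        L <- nchar(seqs[[i]])
        pos <- sample(8:(L - 8), 1)
        if (!reserve(i, pos, pos + 3)) next
        st <- sample(c("S", "T"), 1)
        motif <- switch(cl,
          STQ = paste0(st, "Q", sample(neutral, 1), sample(neutral, 1)),
          CDK1_minimal = paste0(st, "P", sample(neutral, 1),
                                sample(neutral, 1)),
          CDK1_full = paste0(st, "P", sample(neutral, 1),
                             sample(c("K", "R"), 1)),
          CK2 = paste0(st, "D", sample(neutral, 1), sample(neutral, 1)))
        put(i, pos, motif)
        sites[[length(sites) + 1L]] <- data.frame(
          protein_id = names(seqs)[i], position = pos, motif_label = cl,
          stringsAsFactors = FALSE)
        if (cl == "STQ") stq_prots <- union(stq_prots, names(seqs)[i])
        placed <- TRUE
        break
      }
      if (!placed) stop("infeasible planting: could not place ", cl, " site")
    }
  }
  list(sequences = seqs,
       truth = list(
         planted_scds = if (length(scds)) do.call(rbind, scds) else
           data.frame(protein_id = character(), start = integer(),
                      end = integer(), member_positions = character()),
         planted_sites = if (length(sites)) do.call(rbind, sites) else
           data.frame(protein_id = character(), position = integer(),
                      motif_label = character())))
}

#' Derive phosphopeptide observations from a simulated proteome
#'
#' Emits one phosphopeptide row per planted site: a 13-residue window
#' around the site (clipped at sequence ends and extended when the window
#' is not unique in the protein), a high localization probability, and —
#' when another S/T lies in the window — optionally an unresolved 50/50
#' two-candidate ambiguity.
#'
#' @param proteome output of \code{\link{simulate_proteome}}.
#' @param ambiguous_fraction fraction of sites emitted as unresolved
#'   two-candidate ambiguities when a partner S/T exists (default 0.2).
#' @param seed integer seed.
#' @return phosphopeptide data.frame in the
#'   \code{\link{read_phosphopeptides}} dialect.
#' @export
simulate_phosphopeptides <- function(proteome, ambiguous_fraction = 0.2,
                                     seed = 1L) {
  set.seed(seed)
  sites <- proteome$truth$planted_sites
  rows <- list()
  for (i in seq_len(nrow(sites))) {
    pid <- sites$protein_id[i]
    pos <- sites$position[i]
    s <- proteome$sequences[[pid]]
    half <- 6L
    repeat {
      lo <- max(1L, pos - half); hi <- min(nchar(s), pos + half)
      pep <- substring(s, lo, hi)
      if (length(gregexpr(pep, s, fixed = TRUE)[[1]]) == 1L) break
      half <- half + 3L
    }
    pep_pos <- pos - lo + 1L
    chars <- strsplit(pep, "")[[1]]
    partners <- setdiff(which(chars %in% c("S", "T")), pep_pos)
    if (length(partners) && stats::runif(1) < ambiguous_fraction) {
      q <- partners[which.min(abs(partners - pep_pos))]
      pp <- sort(c(pep_pos, q))
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = pid,
        protein_positions = paste(pp + lo - 1L, collapse = "|"),
        peptide_seq = pep,
        pep_positions = paste(pp, collapse = "|"),
        probs = "50.00|50.00",
        tissues = sample(c("anther", "meiocyte", "anther;meiocyte"), 1),
        stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = pid,
        protein_positions = as.character(pos),
        peptide_seq = pep,
        pep_positions = as.character(pep_pos),
        probs = sprintf("%.2f", stats::runif(1, 90, 100)),
        tissues = sample(c("anther", "meiocyte", "anther;meiocyte"), 1),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Simulate a BLAST-style ortholog hit table
#'
#' Emulates a lineage-specific whole-genome triplication: several query
#' proteins share the same best subject locus. Subjects carry transcript
#' suffixes (".1") to exercise locus normalization; per query 0-2 decoy
#' hits with lower bit scores are added; a chosen set of queries receives
#' only weak hits above any sensible acceptance threshold.
#'
#' @param query_ids character vector of query protein ids.
#' @param triplication_factor mean number of queries per subject locus
#'   (>= 1; default 1.2).
#' @param e_range min/max E-value of true best hits, within (0,1]
#'   (default \code{c(1e-180, 1e-20)}).
#' @param n_no_hit number of queries given only weak hits (E around
#'   1e-3), hence unassignable at the 1e-5 threshold (default 0).
#' @param seed integer seed.
#' @return data.frame in BLAST outfmt-6 column order.
#' @export
simulate_ortholog_hits <- function(query_ids, triplication_factor = 1.2,
                                   e_range = c(1e-180, 1e-20),
                                   n_no_hit = 0, seed = 1L) {
  stopifnot(triplication_factor >= 1,
            e_range[1] > 0, e_range[2] <= 1, e_range[1] <= e_range[2],
            n_no_hit >= 0, n_no_hit <= length(query_ids))
  set.seed(seed)
  n_q <- length(query_ids)
  no_hit <- if (n_no_hit > 0) sort(sample(query_ids, n_no_hit)) else character()
  assigned <- setdiff(query_ids, no_hit)
  n_subj <- max(1L, round(length(assigned) / triplication_factor))
  subjects <- sprintf("AT%dG%05d", sample(1:5, n_subj, replace = TRUE),
                      sample(seq(10, 99990, by = 10), n_subj))
  subjects <- make.unique(subjects, sep = "")
  # every subject used at least once; surplus queries collapse onto
  # already-used subjects (the triplication structure)
  perm <- sample(assigned)
  subj_of <- c(subjects[seq_len(min(n_subj, length(perm)))],
               sample(subjects, max(0L, length(perm) - n_subj),
                      replace = TRUE))
  names(subj_of) <- perm
  rows <- list()
  mk_row <- function(q, s, e, bits) data.frame(
    qseqid = q, sseqid = paste0(s, ".1"),
    pident = round(stats::runif(1, 60, 99), 1), length = sample(80:500, 1),
    mismatch = sample(0:40, 1), gapopen = sample(0:5, 1),
    qstart = 1L, qend = sample(80:500, 1), sstart = 1L,
    send = sample(80:500, 1), evalue = e, bitscore = bits,
    stringsAsFactors = FALSE)
  loge <- log10(e_range)
  for (q in assigned) {
    e_best <- 10^stats::runif(1, loge[1], loge[2])
    bits_best <- round(stats::runif(1, 200, 900), 1)
    rows[[length(rows) + 1L]] <- mk_row(q, subj_of[[q]], e_best, bits_best)
    for (k in seq_len(sample(0:2, 1))) {
      rows[[length(rows) + 1L]] <- mk_row(
        q, sample(subjects, 1), min(1, e_best * 10^sample(3:30, 1)),
        bits_best - stats::runif(1, 10, 150))
    }
  }
  for (q in no_hit) {
    rows[[length(rows) + 1L]] <- mk_row(
      q, sample(subjects, 1), 10^stats::runif(1, -4, -2),
      round(stats::runif(1, 30, 45), 1))
  }
  tab <- do.call(rbind, rows)
  tab[sample(nrow(tab)), , drop = FALSE]
}

#' Simulate an interaction network with one dominant component
#'
#' The main component is a random spanning tree plus extra edges over
#' \code{ceiling(main_fraction * n)} nodes; \code{n_orphans} nodes get no
#' edges at all; any remaining nodes are chained into small side
#' components of size >= 2. All edge scores lie above the default 0.4
#' retention threshold so that graph construction preserves the planted
#' component structure.
#'
#' @param node_ids character vector of node ids.
#' @param main_fraction fraction of nodes in the main component, in
#'   (0,1].
#' @param n_orphans number of edge-free nodes.
#' @param seed integer seed.
#' @return list with \code{edges} (data.frame node_a/node_b/score) and
#'   \code{truth} (\code{main_component_ids}, \code{orphan_ids},
#'   \code{side_ids}).
#' @export
simulate_network <- function(node_ids, main_fraction = 0.927, n_orphans = NULL,
                             seed = 1L) {
  stopifnot(main_fraction > 0, main_fraction <= 1)
  set.seed(seed)
  n <- length(node_ids)
  main_size <- ceiling(main_fraction * n)
  rest <- n - main_size
  if (is.null(n_orphans)) n_orphans <- rest
  if (n_orphans > rest)
    stop("infeasible sizes: n_orphans exceeds nodes outside the main component")
  leftover <- rest - n_orphans
  if (leftover == 1L)
    stop("infeasible sizes: a single leftover node cannot form a side ",
         "component of size >= 2")
  ids <- sample(node_ids)
  main <- ids[seq_len(main_size)]
  orphans <- if (n_orphans > 0) ids[main_size + seq_len(n_orphans)]
             else character()
  side <- if (leftover > 0) ids[(main_size + n_orphans) + seq_len(leftover)]
          else character()
  score <- function(k) round(stats::runif(k, 0.41, 0.99), 3)
  edges <- list()
  if (main_size >= 2) {
    to <- vapply(2:main_size, function(i) sample(i - 1, 1), 1L)
    edges[[1]] <- data.frame(node_a = main[2:main_size], node_b = main[to],
                             score = score(main_size - 1),
                             stringsAsFactors = FALSE)
    n_extra <- ceiling(main_size / 2)
    a <- sample(main, n_extra, replace = TRUE)
    b <- sample(main, n_extra, replace = TRUE)
    keep <- a != b
    if (any(keep))
      edges[[2]] <- data.frame(node_a = a[keep], node_b = b[keep],
                               score = score(sum(keep)),
                               stringsAsFactors = FALSE)
  }
  if (length(side) >= 2) {
    # chain side nodes into components of size 2-3
    i <- 1L
    while (i <= length(side)) {
      r <- length(side) - i + 1L
      # never strand a single node: it would read as an extra orphan
      k <- if (r <= 3L) r else if (r == 4L) 2L else sample(2:3, 1)
      grp <- side[i:(i + k - 1)]
      edges[[length(edges) + 1L]] <- data.frame(
        node_a = grp[-k], node_b = grp[-1], score = score(k - 1),
        stringsAsFactors = FALSE)
      i <- i + k
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(node_a = character(), node_b = character(),
               score = numeric(), stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  list(edges = edges,
       truth = list(main_component_ids = sort(main),
                    orphan_ids = sort(orphans),
                    side_ids = sort(side)))
}
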