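tbl1 <- read_phosphopeptides(system.file(
  "extdata", "boasy_phosphopeptides_tbl1.tsv", package = "coipnet"))

test_that("peptides map to protein coordinates by unique exact occurrence", {
  # context GNEMDK(S)PER placed so that peptide position 7 lands at 156
  prot <- paste0(paste(rep("A", 149), collapse = ""), "GNEMDKSPERWWWW")
  expect_equal(map_peptide_sites("GNEMDKSPER", 7L, prot), 156L)
  # identity mapping: peptide equals the protein
  expect_equal(map_peptide_sites("MSTK", 2L, "MSTK"), 2L)
  # absent peptide
  expect_error(map_peptide_sites("GNEMDKSPER", 7L, "AAAA"), "does not occur")
  # repeated peptide: position cannot be inferred
  rep_prot <- "AAASPERKGGGAAASPERK"
  expect_error(map_peptide_sites("AAASPERK", 4L, rep_prot), "cannot be inferred")
})

test_that("site collapse reproduces the BoASY1/BoASY3 inventories", {
  sites <- phospho_sites(tbl1)
  s1 <- sites[sites$protein_id == "BoASY1", ]
  s3 <- sites[sites$protein_id == "BoASY3", ]
  expect_equal(nrow(s1), 18)
  expect_equal(nrow(s3), 7)
  # distinct supporting peptide sequences
  expect_length(unique(unlist(strsplit(s1$supporting_peptides, ";"))), 13)
  expect_length(unique(unlist(strsplit(s3$supporting_peptides, ";"))), 6)
  # each unresolved two-position ambiguity is a single site
  expect_equal(sum(s1$ambiguous), 2)
  expect_equal(sum(s3$ambiguous), 2)
  # a site seen on several peptides merges (idempotent union)
  expect_gte(s1$n_peptides[s1$positions == "294"], 2)
})

test_that("collapse is order-independent and resolves ambiguity by merging", {
  perm <- tbl1[sample(nrow(tbl1)), ]
  expect_equal(phospho_sites(perm), phospho_sites(tbl1))
  # an ambiguous pair whose member is resolved elsewhere merges into it
  peps <- data.frame(
    protein_id = "PX",
    protein_positions = c("10", "10|12"),
    peptide_seq = c("AAASATAAAK", "AAASATAAAK"),
    pep_positions = c("4", "4|6"),
    probs = c("99.00", "50.00|50.00"),
    tissues = c("anther", "meiocyte"),
    stringsAsFactors = FALSE)
  sites <- collapse_sites(coipnet:::phospho_observations(peps))
  expect_equal(nrow(sites), 1)
  expect_equal(sites$positions, "10")
  expect_equal(sites$tissues, "anther;meiocyte")
})

test_that("motif classification covers S/TQ, CDK1 and CK2 rules", {
  # BoASY3 S156: context S-P-E-R, a full CDK1 motif
  cl <- classify_site_motifs("GNEMDKSPER", 7)
  expect_true(all(c("CDK1_minimal", "CDK1_full") %in% cl$labels))
  # BoASY1 T294 context T-Q: ATM/ATR S/TQ motif
  cl2 <- classify_site_motifs("EDNTQDPVESQQQLER", 4)
  expect_true("STQ" %in% cl2$labels)
  expect_false("CDK1_minimal" %in% cl2$labels)
  # minimal but not full: +3 not K/R
  cl3 <- classify_site_motifs("ASPEYNED", 2)
  expect_true("CDK1_minimal" %in% cl3$labels)
  expect_false("CDK1_full" %in% cl3$labels)
  # CK2: acidic at +1 or +3; assigned phosphosites count as acidic
  expect_true("CK2" %in% classify_site_motifs("XSDX", 2)$labels)
  expect_true("CK2" %in% classify_site_motifs("XSXXE", 2)$labels)
  expect_true("CK2" %in%
                classify_site_motifs("XSSXX", 2, phospho_positions = 3)$labels)
  expect_false("CK2" %in% classify_site_motifs("XSXXX", 2)$labels)
  # final residue: no +1 context, no labels, truncation flagged
  cl4 <- classify_site_motifs("AAAS", 4)
  expect_length(cl4$labels, 0)
  expect_true(cl4$truncated)
  # ambiguous: either candidate matching suffices
  cl5 <- classify_site_motifs("HHSDTIETDSESPEVATR", c(10, 12))
  expect_true("CDK1_minimal" %in% cl5$labels)
})

test_that("motif summary matches the published BoASY1/BoASY3 annotation", {
  rep <- phospho_report()
  s <- rep$summary
  expect_equal(s$n_stq[s$protein_id == "BoASY1"], 4)
  expect_equal(s$n_stq[s$protein_id == "BoASY3"], 1)
  expect_equal(s$n_cdk1[s$protein_id == "BoASY3"], 4)
  expect_equal(s$n_cdk1_full[s$protein_id == "BoASY3"], 1)
  expect_equal(s$n_cdk1[s$protein_id == "BoASY1"], 2)  # T493 and T536
  # the CK2 cluster S260/S262/S264 upstream of SCD1 is recovered
  sites <- rep$sites
  ck2 <- sites$positions[sites$protein_id == "BoASY1" &
                           grepl("CK2", sites$motif_labels)]
  expect_true(all(c("260", "262", "264") %in% ck2))
})

test_that("SCD detection matches layouts and handles span boundaries", {
  # span exactly 100: one region
  r <- scd_from_positions(c(10, 50, 109))
  expect_equal(nrow(r), 1)
  expect_equal(r$start, 10)
  expect_equal(r$end, 109)
  # span 102: none
  expect_equal(nrow(scd_from_positions(c(10, 50, 111))), 0)
  # the SCD1 layout: four members in one region
  r2 <- scd_from_positions(c(267, 272, 294, 300))
  expect_equal(nrow(r2), 1)
  expect_equal(r2$n_members, 4)
  expect_equal(r2$member_positions, "267;272;294;300")
  # motif scan on sequence
  seq <- paste0(paste(rep("A", 9), collapse = ""), "SQ",
                paste(rep("A", 38), collapse = ""), "TQ",
                paste(rep("A", 57), collapse = ""), "SQ")
  expect_equal(stq_positions(seq), c(10, 50, 109))
  expect_equal(detect_scd(seq)$start, 10)
  expect_equal(nrow(detect_scd("")), 0)
})

test_that("SCD scanner agrees with the brute-force oracle", {
  set.seed(42)
  for (i in 1:200) {
    n_mot <- sample(0:12, 1)
    pos <- sort(sample(1:500, n_mot))
    got <- scd_from_positions(pos)
    want <- oracle_scd(pos)
    expect_equal(nrow(got), length(want))
    if (length(want)) {
      want_str <- vapply(want, paste, "", collapse = ";")
      expect_setequal(got$member_positions, want_str)
    }
    # structural invariants: members are motif positions, regions disjoint
    if (nrow(got) > 1)
      expect_true(all(got$start[-1] > got$end[-nrow(got)]))
    expect_true(all(unlist(strsplit(got$member_positions, ";")) %in% pos))
  }
})

test_that("site correspondence walks alignment columns correctly", {
  al <- list(aligned_a = "MKT---LVNQ", aligned_b = "MKTAAALV-Q")
  expect_equal(site_correspondence(al, 1), 1)
  expect_equal(site_correspondence(al, 4), 7)   # L after the insertion
  expect_true(is.na(site_correspondence(al, 6)))  # N pairs with a gap
  expect_equal(site_correspondence(al, 8, source = "b"), 5)
  expect_error(site_correspondence(al, 99), "outside")
  # identity alignment maps every position to itself
  id <- list(aligned_a = "MKTLV", aligned_b = "MKTLV")
  expect_equal(vapply(1:5, function(p) site_correspondence(id, p), 1L), 1:5)
  # a 5-residue insertion before position 20 shifts by 5
  a <- paste(rep("A", 30), collapse = "")
  al2 <- list(aligned_a = paste0(substr(a, 1, 14), "KKKKK", substr(a, 15, 30)),
              aligned_b = paste0(substr(a, 1, 14), "-----", substr(a, 15, 30)))
  expect_equal(site_correspondence(al2, 25), 20)
})
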