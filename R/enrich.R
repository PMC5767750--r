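#' Hypergeometric term over-representation test
#'
#' For each annotation term, tests whether the study set contains more
#' term members than expected by drawing \code{n} genes from the
#' background: exact upper-tail hypergeometric \eqn{P(X \ge k)} with
#' \code{k} study hits, \code{K} background hits, background size
#' \code{N}, study size \code{n}. Fold enrichment is
#' \eqn{(k/n)/(K/N)}. Benjamini-Hochberg q-values are computed across all
#' tested terms. Terms with no study hit are reported with fold 0 and
#' p = 1.
#'
#' @param study character vector of study gene ids (must be a subset of
#'   \code{background}).
#' @param background character vector of background gene ids.
#' @param term_map data.frame with columns \code{term_id}, \code{gene_id};
#'   genes outside the background are clipped with a warning.
#' @return data.frame: \code{term_id}, \code{k}, \code{n}, \code{K},
#'   \code{N}, \code{fold_enrichment}, \code{p_value}, \code{q_value},
#'   sorted by p.
#' @export
hypergeometric_enrichment <- function(study, background, term_map) {
  study <- unique(as.character(study))
  background <- unique(as.character(background))
  if (length(study) == 0L || length(background) == 0L)
    stop("study and background sets must be non-empty")
  if (!all(study %in% background))
    stop("study set must be a subset of the background")
  tm <- term_map[, c("term_id", "gene_id")]
  out_bg <- !(tm$gene_id %in% background)
  if (any(out_bg)) {
    warning(sum(out_bg), " term-map gene(s) outside the background clipped")
    tm <- tm[!out_bg, , drop = FALSE]
  }
  N <- length(background)
  n <- length(study)
  terms <- sort(unique(tm$term_id))
  rows <- lapply(terms, function(t) {
    genes <- unique(tm$gene_id[tm$term_id == t])
    K <- length(genes)
    k <- sum(study %in% genes)
    p <- if (k == 0) 1 else stats::phyper(k - 1, K, N - K, n,
                                          lower.tail = FALSE)
    data.frame(term_id = t, k = k, n = n, K = K, N = N,
               fold_enrichment = (k / n) / (K / N),
               p_value = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q_value <- bh_adjust(res$p_value)
  res <- res[order(res$p_value, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment (via
#' \code{stats::p.adjust}), preserving input order.
#'
#' @param p_values numeric vector of p-values in [0,1].
#' @return q-values in input order.
#' @export
bh_adjust <- function(p_values) {
  if (any(!is.finite(p_values) | p_values < 0 | p_values > 1))
    stop("p-values must lie in [0,1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Yates-corrected chi-square test of a 2x2 table
#'
#' Continuity-corrected statistic
#' \eqn{\chi^2 = \sum (|O-E| - 0.5)^2 / E} with expected counts from the
#' margins, the correction floored at zero when \eqn{|O-E| < 0.5}
#' (otherwise tiny deviations would inflate the statistic), and a p-value
#' from the chi-square distribution with 1 df.
#'
#' @param table 2x2 numeric matrix of non-negative counts (rows =
#'   genotype, columns = aberrant/normal).
#' @return list: \code{chi2}, \code{p}, \code{df = 1}.
#' @export
chi2_yates <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == c(2, 2)),
            all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("chi-square test undefined: a table margin is zero")
  E <- outer(rowSums(table), colSums(table)) / sum(table)
  dev <- pmax(abs(table - E) - 0.5, 0)
  chi2 <- sum(dev^2 / E)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       df = 1)
}

#' Read a two-column term-to-gene annotation table
#'
#' @param path TSV with columns \code{term_id}, \code{gene_id} (header
#'   optional).
#' @return data.frame \code{term_id}, \code{gene_id}.
#' @export
read_term_map <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("term", first, ignore.case = TRUE)
  tab <- utils::read.table(path, sep = "\t", header = has_header,
                           quote = "", stringsAsFactors = FALSE)
  tab <- tab[, 1:2]
  names(tab) <- c("term_id", "gene_id")
  tab
}
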