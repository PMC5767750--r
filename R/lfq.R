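#' Aggregate peptide evidence to a protein intensity matrix
#'
#' Collapses peptide-level peak areas for one co-IP dataset into a
#' protein-by-replicate matrix, split by channel (sample vs control).
#' A cell is missing (\code{NA}) if and only if no quantified peptide
#' observation exists for that protein/channel/replicate; non-detection is
#' never coded as zero, since a zero would later be mistaken for a measured
#' (log-transformable) intensity.
#'
#' @param evidence data.frame of peptide evidence in the standard dialect
#'   (columns \code{dataset_id}, \code{channel}, \code{replicate},
#'   \code{protein_id}, \code{peptide_seq}, \code{peak_area}; see
#'   \code{\link{simulate_coip}}).
#' @param dataset_id dataset to aggregate; all evidence rows must belong
#'   to it.
#' @param rule aggregation rule for multiple peptides of one protein in the
#'   same replicate: \code{"sum"} (default) or \code{"mean"} of peak areas.
#' @return An object of class \code{protein_intensity_matrix}: a list with
#'   \code{dataset_id}, \code{sample} and \code{control} numeric matrices
#'   (proteins x replicates, \code{NA} = missing).
#' @export
aggregate_protein_intensity <- function(evidence, dataset_id,
                                        rule = c("sum", "mean")) {
  rule <- match.arg(rule)
  stopifnot(is.data.frame(evidence))
  ev <- evidence[evidence$dataset_id == dataset_id, , drop = FALSE]
  if (nrow(ev) != nrow(evidence) && nrow(ev) == 0L)
    stop("no evidence rows for dataset '", dataset_id, "'")
  ev <- ev[!is.na(ev$peak_area), , drop = FALSE]
  if (any(ev$peak_area < 0))
    stop("negative peak areas in dataset '", dataset_id, "'")
  proteins <- sort(unique(ev$protein_id))
  out <- list(dataset_id = dataset_id)
  for (ch in c("sample", "control")) {
    sub <- ev[ev$channel == ch, , drop = FALSE]
    reps <- sort(unique(ev$replicate[ev$channel == ch]))
    m <- matrix(NA_real_, nrow = length(proteins), ncol = length(reps),
                dimnames = list(proteins, as.character(reps)))
    if (nrow(sub) > 0L) {
      agg <- if (rule == "sum") {
        stats::aggregate(peak_area ~ protein_id + replicate, data = sub, FUN = sum)
      } else {
        stats::aggregate(peak_area ~ protein_id + replicate, data = sub, FUN = mean)
      }
      m[cbind(match(agg$protein_id, proteins),
              match(as.character(agg$replicate), colnames(m)))] <- agg$peak_area
    }
    out[[ch]] <- m
  }
  class(out) <- "protein_intensity_matrix"
  out
}

#' @export
print.protein_intensity_matrix <- function(x, ...) {
  cat("protein_intensity_matrix: dataset", x$dataset_id, "-",
      nrow(x$sample), "proteins;",
      ncol(x$sample), "sample and", ncol(x$control), "control replicates\n")
  invisible(x)
}

# Newton solve of trigamma(y) = x, vectorized; companion to the
# method-of-moments fit below.
trigamma_inverse <- function(x) {
  y <- 0.5 + 1 / x
  for (i in 1:75) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (max(abs(dif / y)) < 1e-10) break
  }
  y
}

#' Fit the empirical-Bayes variance prior for the moderated t-test
#'
#' Estimates the scaled inverse-chi-square prior on per-protein residual
#' variances by method of moments on the log variances: with
#' \eqn{z_g = \log s_g^2}, the mean and variance of
#' \eqn{e_g = z_g - \psi(d_g/2) + \log(d_g/2)} identify the prior scale
#' \eqn{s_0^2} and degrees of freedom \eqn{d_0} through the digamma/trigamma
#' moment equations. When the trigamma moment estimate is non-positive there
#' is no evidence of excess dispersion between proteins and the prior is
#' degenerate: \eqn{d_0 = \infty} with \eqn{s_0^2} the df-weighted mean of
#' the observed variances (the maximum-likelihood common variance).
#'
#' @param s_g_sq numeric vector of per-protein pooled residual variances
#'   (must be > 0 to contribute).
#' @param d_g residual degrees of freedom per protein (recycled if scalar).
#' @return An object of class \code{moderated_t_model}: list with \code{d0}
#'   (prior df, possibly \code{Inf}) and \code{s0_sq} (prior variance).
#' @export
fit_moderated_model <- function(s_g_sq, d_g) {
  if (length(d_g) == 1L) d_g <- rep(d_g, length(s_g_sq))
  stopifnot(length(d_g) == length(s_g_sq))
  keep <- is.finite(s_g_sq) & s_g_sq > 0 & d_g >= 1
  s2 <- s_g_sq[keep]
  df <- d_g[keep]
  if (length(s2) < 2L)
    stop("need at least 2 proteins with positive variance and df >= 1")
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  ebar <- mean(e)
  n <- length(e)
  # unbiased between-protein dispersion of e, minus the within term
  v <- mean((e - ebar)^2 * n / (n - 1) - trigamma(df / 2))
  if (v > 0) {
    d0 <- 2 * trigamma_inverse(v)
    s0_sq <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # no excess dispersion between proteins: degenerate prior; the
    # df-weighted mean is the ML estimate of the common variance
    d0 <- Inf
    s0_sq <- sum(df * s2) / sum(df)
  }
  structure(list(d0 = d0, s0_sq = s0_sq), class = "moderated_t_model")
}

#' @export
print.moderated_t_model <- function(x, ...) {
  cat("moderated_t_model: d0 =", format(x$d0), " s0_sq =", format(x$s0_sq), "\n")
  invisible(x)
}

#' Moderated t-test of sample vs control for one dataset
#'
#' For each protein with at least two observed log2 intensities per channel,
#' computes the log2 enrichment \eqn{\Delta} (sample minus control mean),
#' the pooled residual variance \eqn{s_g^2} on \eqn{d_g = n_1+n_2-2} df,
#' the posterior (shrunken) variance
#' \eqn{s^2_{post} = (d_0 s_0^2 + d_g s_g^2)/(d_0+d_g)},
#' the moderated statistic
#' \eqn{\tilde t = \Delta / (s_{post}\sqrt{1/n_1+1/n_2})} and its two-sided
#' p-value on \eqn{d_0+d_g} df (standard normal reference when
#' \eqn{d_0 = \infty}). Proteins lacking two observations in either channel
#' are reported \code{testable = FALSE} with \code{significant = FALSE}; no
#' imputation is performed, such proteins are candidates for the qualitative
#' acceptance tier instead.
#'
#' A protein is called \code{significant} when it is testable, its
#' fold-change (computed on the geometric/log2-mean scale,
#' \eqn{2^\Delta}) is at least \code{fc_min}, and \eqn{p <} \code{p_max}.
#' P-values are not multiplicity-adjusted by default, matching the
#' per-dataset decision rule the pipeline implements; see
#' \code{\link{bh_adjust}} for optional adjustment.
#'
#' @param mat a \code{protein_intensity_matrix} from
#'   \code{\link{aggregate_protein_intensity}}.
#' @param model a \code{moderated_t_model}; pass \code{NULL} to fit it on
#'   this dataset's variances. \code{d0 = 0} gives the shrinkage-free
#'   ordinary pooled t-test.
#' @param fc_min,p_max significance thresholds (defaults: fold-change >= 5,
#'   p < 0.01).
#' @return data.frame with one row per protein: \code{dataset_id},
#'   \code{protein_id}, \code{delta_log2}, \code{fold_change},
#'   \code{s_g_sq}, \code{d_g}, \code{t_moderated}, \code{p_value},
#'   \code{testable}, \code{significant}.
#' @export
test_dataset <- function(mat, model = NULL, fc_min = 5, p_max = 0.01) {
  stopifnot(inherits(mat, "protein_intensity_matrix"))
  proteins <- rownames(mat$sample)
  n <- length(proteins)
  ls <- log2(mat$sample)
  lc <- log2(mat$control)
  n1 <- rowSums(!is.na(ls))
  n2 <- rowSums(!is.na(lc))
  m1 <- rowMeans(ls, na.rm = TRUE)
  m2 <- rowMeans(lc, na.rm = TRUE)
  ss1 <- rowSums((ls - m1)^2, na.rm = TRUE)
  ss2 <- rowSums((lc - m2)^2, na.rm = TRUE)
  testable <- n1 >= 2 & n2 >= 2
  d_g <- ifelse(testable, n1 + n2 - 2, NA_real_)
  s_g_sq <- ifelse(testable, (ss1 + ss2) / d_g, NA_real_)
  delta <- ifelse(n1 >= 1 & n2 >= 1, m1 - m2, NA_real_)

  if (is.null(model)) {
    model <- fit_moderated_model(s_g_sq[testable], d_g[testable])
  }
  stopifnot(inherits(model, "moderated_t_model") ||
              (is.list(model) && !is.null(model$d0) && !is.null(model$s0_sq)))
  d0 <- model$d0
  s0 <- model$s0_sq

  s_post_sq <- ifelse(testable,
                      if (is.infinite(d0)) s0
                      else (d0 * s0 + d_g * s_g_sq) / (d0 + d_g),
                      NA_real_)
  se <- sqrt(s_post_sq * (1 / n1 + 1 / n2))
  t_mod <- ifelse(testable, delta / se, NA_real_)
  df_tot <- d0 + d_g
  p <- rep(NA_real_, n)
  idx <- which(testable)
  if (length(idx)) {
    p[idx] <- if (is.infinite(d0)) {
      2 * stats::pnorm(-abs(t_mod[idx]))
    } else {
      2 * stats::pt(-abs(t_mod[idx]), df = df_tot[idx])
    }
  }
  fc <- 2^delta
  # the >= comparison is tolerance-guarded: the fold-change is computed
  # through log2, so a ratio of exactly fc_min must not fail by rounding
  sig <- testable & !is.na(p) & (fc - fc_min >= -1e-9 * fc_min) & p < p_max
  data.frame(dataset_id = mat$dataset_id,
             protein_id = proteins,
             delta_log2 = unname(delta),
             fold_change = unname(fc),
             s_g_sq = unname(s_g_sq),
             d_g = unname(d_g),
             t_moderated = unname(t_mod),
             p_value = unname(p),
             testable = unname(testable),
             significant = unname(sig),
             stringsAsFactors = FALSE)
}

#' Quantify every dataset of an evidence table
#'
#' Convenience wrapper: aggregates and tests each dataset independently
#' (no cross-dataset normalization), fitting the variance prior per dataset.
#'
#' @inheritParams aggregate_protein_intensity
#' @inheritParams test_dataset
#' @return row-bound data.frame of \code{\link{test_dataset}} results for
#'   all datasets in \code{evidence}.
#' @export
quantify_all <- function(evidence, fc_min = 5, p_max = 0.01, rule = "sum") {
  res <- lapply(sort(unique(evidence$dataset_id)), function(d) {
    mat <- aggregate_protein_intensity(evidence, d, rule = rule)
    n_testable <- sum(rowSums(!is.na(mat$sample)) >= 2 &
                        rowSums(!is.na(mat$control)) >= 2)
    model <- if (n_testable >= 2) NULL
             else structure(list(d0 = Inf, s0_sq = 1), class = "moderated_t_model")
    test_dataset(mat, model, fc_min = fc_min, p_max = p_max)
  })
  do.call(rbind, res)
}
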