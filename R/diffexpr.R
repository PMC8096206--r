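# gene-wise two-group differential expression on log2 values

#' Differential expression between two phenotype groups
#'
#' Gene-wise linear model on log2 expression: `lfc = mean(alt) - mean(ref)`
#' with a pooled-variance t-test. By default gene variances are moderated
#' with an empirical-Bayes squeeze toward a method-of-moments prior:
#' assuming the gene variances follow a scaled F marginal
#' `s_g^2 ~ s0^2 F(d, d0)`, `d0` and `s0^2` are solved from the first two
#' moments of the observed `s_g^2`, the squeezed variance is
#' `(d0 s0^2 + d s_g^2) / (d0 + d)`, and the t statistic gains `d0` degrees
#' of freedom. With `moderated = FALSE` this reduces exactly to the
#' textbook pooled t-test.
#'
#' @param study An `expression_study`.
#' @param ref,alt Group labels (LFC is `alt - ref`).
#' @param moderated Apply empirical-Bayes variance moderation.
#' @param lfc_cut,p_cut Thresholds passed to [classify_calls()].
#' @param adjust Apply Benjamini-Hochberg to the p-values before calling
#'   (off by default: the per-gene p threshold is the classical unadjusted
#'   one).
#' @return data.frame(gene_id, lfc, t, p_value, call) with attribute
#'   `prior` = c(d0, s0_sq).
#' @export
differential_expression <- function(study, ref = "healthy", alt = "tumor",
                                    moderated = TRUE, lfc_cut = 0.5,
                                    p_cut = 0.05, adjust = FALSE) {
  ca <- names(study$groups)[study$groups == ref]
  cb <- names(study$groups)[study$groups == alt]
  if (length(ca) < 2 || length(cb) < 2)
    stopf("both groups need >= 2 samples (got %d '%s', %d '%s')",
          length(ca), ref, length(cb), alt)
  xa <- study$values[, ca, drop = FALSE]
  xb <- study$values[, cb, drop = FALSE]
  n1 <- length(ca); n2 <- length(cb)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  lfc <- mb - ma
  # pooled per-gene variance, d = n1 + n2 - 2 df
  ss <- rowSums((xa - ma)^2) + rowSums((xb - mb)^2)
  d <- n1 + n2 - 2
  s2 <- ss / d
  if (moderated) {
    pr <- mom_prior(s2, d)
    s2_used <- (pr["d0"] * pr["s0_sq"] + d * s2) / (pr["d0"] + d)
    if (!is.finite(pr["d0"])) s2_used <- rep(pr["s0_sq"], length(s2))
    df_used <- d + pr[["d0"]]  # pt() accepts df = Inf
  } else {
    pr <- c(d0 = 0, s0_sq = NA_real_)
    s2_used <- s2
    df_used <- d
  }
  tstat <- lfc / sqrt(s2_used * (1 / n1 + 1 / n2))
  p <- 2 * pt(-abs(tstat), df = df_used)
  if (adjust) p <- benjamini_hochberg(p)
  out <- data.frame(gene_id = study$gene_ids, lfc = lfc, t = tstat,
                    p_value = p,
                    call = classify_calls(lfc, p, lfc_cut, p_cut),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "prior") <- pr
  attr(out, "moderated") <- moderated
  out
}

# method-of-moments fit of the scaled-F prior: matches mean and variance of
# the observed pooled variances; d0 = Inf (pure pooling) when the observed
# spread is at or below what d residual df alone would produce
mom_prior <- function(s2, d) {
  M <- mean(s2)
  V <- var(s2)
  if (!is.finite(V) || V <= 0) return(c(d0 = Inf, s0_sq = M))
  R <- V / M^2  # squared coefficient of variation of F(d, d0)
  if (R * d <= 2) return(c(d0 = Inf, s0_sq = M))
  d0 <- (4 * R * d + 2 * d - 4) / (R * d - 2)
  if (!is.finite(d0) || d0 <= 2) return(c(d0 = Inf, s0_sq = M))
  c(d0 = d0, s0_sq = M * (d0 - 2) / d0)
}

#' Classify genes as over/under/unchanged
#'
#' `over` iff `lfc >= lfc_cut` and `p < p_cut`; `under` iff
#' `lfc <= -lfc_cut` and `p < p_cut`; otherwise `unchanged`. Boundary
#' semantics follow the thresholds' phrasing: |lfc| exactly at the cut
#' passes (>=), p exactly at the cut fails (<).
#'
#' @param lfc Log2 fold changes.
#' @param p p-values.
#' @param lfc_cut,p_cut Thresholds (defaults 0.5 and 0.05).
#' @return factor with levels over/under/unchanged.
#' @export
classify_calls <- function(lfc, p, lfc_cut = 0.5, p_cut = 0.05) {
  call <- rep("unchanged", length(lfc))
  call[lfc >= lfc_cut & p < p_cut] <- "over"
  call[lfc <= -lfc_cut & p < p_cut] <- "under"
  factor(call, levels = c("over", "under", "unchanged"))
}
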