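#' Differential-expression stand-in with fold-change-threshold semantics
#'
#' A clearly labeled stand-in for a full negative-binomial DE fit: per gene,
#' a Welch two-sample test on log2-CPM against the interval null
#' H0: |log2 fold change| <= `lfcThreshold`, so p-values refer to the
#' probability that the absolute change between the two groups exceeds the
#' baseline fold change (1.5 by default). The composite-null p-value is the
#' shifted-null two-sided construction
#' p = min(1, 2 min(P(T >= (d - theta)/se), P(T <= (d + theta)/se))),
#' which reduces exactly to the ordinary Welch test at `lfcThreshold = 0`
#' and is monotone in the threshold. P-values are Benjamini-Hochberg
#' adjusted across genes.
#'
#' This is not a reimplementation of a shrinkage-based NB GLM; externally
#' produced DE tables can be imported with [readDETable()] as a drop-in
#' replacement for real-data use.
#'
#' @param counts filtered count matrix (genes x samples) or
#'   [CasteExperiment-class].
#' @param samples sample metadata (ignored for a CasteExperiment).
#' @param groupA,groupB group labels to contrast; fold changes are B over A.
#' @param lfcThreshold interval-null half-width on the log2 scale (default
#'   log2(1.5)).
#' @param alpha significance level on the adjusted p-values (default 0.05).
#' @param pseudocount passed to [normalizeLogCPM()].
#' @return data.frame (gene, log2fc, pvalue, padj, significant) with
#'   attribute `label = "DE stand-in"`.
#' @export
deTest <- function(counts, samples = NULL, groupA = "control_worker",
                   groupB = "queen", lfcThreshold = log2(1.5),
                   alpha = 0.05, pseudocount = 1) {
  rc <- resolveCounts_(counts, samples)
  ia <- which(rc$samples$group == groupA)
  ib <- which(rc$samples$group == groupB)
  if (length(ia) < 2 || length(ib) < 2)
    stop("both groups need at least 2 samples (",
         groupA, ": ", length(ia), ", ", groupB, ": ", length(ib), ")")
  if (lfcThreshold < 0) stop("lfcThreshold must be nonnegative")
  expr <- normalizeLogCPM(rc$counts, pseudocount = pseudocount)
  A <- expr[, ia, drop = FALSE]; B <- expr[, ib, drop = FALSE]
  na <- length(ia); nb <- length(ib)
  ma <- rowMeans(A); mb <- rowMeans(B)
  va <- apply(A, 1, var); vb <- apply(B, 1, var)
  d <- mb - ma
  se <- sqrt(va / na + vb / nb)
  df <- (va / na + vb / nb)^2 /
    ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- numeric(length(d))
  degenerate <- se == 0 | !is.finite(df)
  tUp <- (d - lfcThreshold) / se
  tLo <- (d + lfcThreshold) / se
  pUp <- pt(tUp, df, lower.tail = FALSE)  # evidence lfc > +threshold
  pLo <- pt(tLo, df)                      # evidence lfc < -threshold
  p <- pmin(1, 2 * pmin(pUp, pLo))
  p[degenerate] <- ifelse(abs(d[degenerate]) > lfcThreshold, 0, 1)
  padj <- bhAdjust(p)
  out <- data.frame(gene = rownames(rc$counts), log2fc = unname(d),
                    pvalue = unname(p), padj = unname(padj),
                    significant = unname(padj < alpha),
                    stringsAsFactors = FALSE)
  attr(out, "label") <- "DE stand-in"
  attr(out, "lfcThreshold") <- lfcThreshold
  out
}

#' Write / import a DE results table
#'
#' The import path accepts any TSV with columns `gene`, `log2fc`, `padj`
#' (e.g. an externally produced shrinkage-GLM results table) so real-data
#' results can replace the stand-in.
#'
#' @param de DE results data.frame.
#' @param path TSV path.
#' @param alpha significance level applied on import when no `significant`
#'   column is present.
#' @export
writeDETable <- function(de, path) {
  writeTSV(de, path)
  invisible(path)
}

#' @rdname writeDETable
#' @export
readDETable <- function(path, alpha = 0.05) {
  tab <- readTSV(path)
  need <- c("gene", "log2fc", "padj")
  miss <- setdiff(need, colnames(tab))
  if (length(miss))
    stop("DE table missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(tab$significant)) tab$significant <- tab$padj < alpha
  tab
}
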