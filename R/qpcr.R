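# RT-qPCR relative quantification: Ct -> dCt (housekeeping) -> ddCt
# (reference sample) -> RQ = 2^-ddCt, with replicate-level propagation.

#' Read a Ct table from CSV
#'
#' Expects columns \code{sample, gene, replicate, Ct} (case-insensitive).
#'
#' @param path CSV file.
#' @return data.frame with those four columns.
#' @export
readCtTable <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(d) <- tolower(names(d))
  need <- c("sample", "gene", "replicate", "ct")
  if (!all(need %in% names(d)))
    stop("Ct table needs columns sample, gene, replicate, Ct", call. = FALSE)
  data.frame(sample = as.character(d$sample), gene = as.character(d$gene),
             replicate = d$replicate, Ct = as.numeric(d$ct))
}

#' Relative quantification by the delta-delta-Ct method
#'
#' Per sample and replicate, \eqn{\Delta Ct = Ct_{gene} - Ct_{housekeeping}};
#' per gene, \eqn{\Delta\Delta Ct = \Delta Ct - \overline{\Delta Ct}_{ref}}
#' (mean over the reference sample's replicates); \eqn{RQ =
#' 2^{-\Delta\Delta Ct}} with amplification efficiency fixed at 2.
#' Replicates are carried through to the end and summarized as mean and
#' SEM, with the summary RQ reported as \eqn{2^{-\overline{\Delta\Delta
#' Ct}}} so the reference sample's summary RQ is exactly 1; the SEM of
#' the per-replicate RQs is also emitted, labelled, since figures may
#' use either.
#'
#' @param ct data.frame with columns sample, gene, replicate, Ct
#'   (finite, > 0).
#' @param housekeeping housekeeping gene (default "GAPDH").
#' @param reference reference sample name.
#' @return list with \code{replicates} (sample, gene, replicate,
#'   delta_ct, delta_delta_ct, rq) and \code{summary} (sample, gene,
#'   n, mean_ddct, sem_ddct, rq = 2^-mean_ddct, mean_rq, sem_rq).
#' @examples
#' ct <- expand.grid(sample = c("CTRL", "KD"), gene = c("GAPDH", "GPC4"),
#'                   replicate = 1:3, stringsAsFactors = FALSE)
#' ct$Ct <- c(18, 18, 25, 26.3)[match(paste(ct$sample, ct$gene),
#'            c("CTRL GAPDH", "KD GAPDH", "CTRL GPC4", "KD GPC4"))]
#' computeRQ(ct, reference = "CTRL")$summary
#' @export
computeRQ <- function(ct, housekeeping = "GAPDH", reference) {
  need <- c("sample", "gene", "replicate", "Ct")
  if (!all(need %in% names(ct)))
    stop("Ct table needs columns sample, gene, replicate, Ct", call. = FALSE)
  if (anyNA(ct$Ct) || any(!is.finite(ct$Ct)) || any(ct$Ct <= 0))
    stop("all Ct values must be finite and > 0", call. = FALSE)
  if (!reference %in% ct$sample)
    stop(sprintf("reference sample '%s' not present", reference),
         call. = FALSE)
  hk <- ct[ct$gene == housekeeping, c("sample", "replicate", "Ct")]
  names(hk)[3L] <- "Ct_hk"
  noHk <- setdiff(unique(ct$sample), unique(hk$sample))
  if (length(noHk))
    stop(sprintf("missing housekeeping gene '%s' Ct for sample(s): %s",
                 housekeeping, paste(noHk, collapse = ", ")), call. = FALSE)
  g <- ct[ct$gene != housekeeping, , drop = FALSE]
  if (nrow(g) == 0L) stop("no target genes in the table", call. = FALSE)
  m <- merge(g, hk, by = c("sample", "replicate"))
  miss <- nrow(g) - nrow(m)
  if (miss > 0L)
    stop(sprintf(
      "%d target Ct value(s) lack a matching housekeeping replicate", miss),
      call. = FALSE)
  m$delta_ct <- m$Ct - m$Ct_hk

  refMean <- stats::aggregate(delta_ct ~ gene,
                              data = m[m$sample == reference, , drop = FALSE],
                              FUN = mean)
  names(refMean)[2L] <- "ref_mean_dct"
  noRef <- setdiff(unique(m$gene), refMean$gene)
  if (length(noRef))
    stop(sprintf("gene(s) %s have no Ct in reference sample '%s'",
                 paste(noRef, collapse = ", "), reference), call. = FALSE)
  m <- merge(m, refMean, by = "gene")
  m$delta_delta_ct <- m$delta_ct - m$ref_mean_dct
  m$rq <- 2^(-m$delta_delta_ct)
  reps <- m[order(m$sample, m$gene, m$replicate),
            c("sample", "gene", "replicate", "delta_ct", "delta_delta_ct",
              "rq")]
  rownames(reps) <- NULL

  sem <- function(x) if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else
    NA_real_
  spl <- split(reps, list(reps$sample, reps$gene), drop = TRUE)
  summ <- do.call(rbind, lapply(spl, function(d) data.frame(
    sample = d$sample[1L], gene = d$gene[1L], n = nrow(d),
    mean_ddct = mean(d$delta_delta_ct), sem_ddct = sem(d$delta_delta_ct),
    rq = 2^(-mean(d$delta_delta_ct)),
    mean_rq = mean(d$rq), sem_rq = sem(d$rq))))
  summ <- summ[order(summ$gene, summ$sample), , drop = FALSE]
  rownames(summ) <- NULL
  list(replicates = reps, summary = summ)
}
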