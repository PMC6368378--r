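#' Greedy removal of unreliable probes and samples
#'
#' Simplified greedy quality filter over a detection p-value matrix, in the
#' spirit of iterative matrix trimming: a measurement is unreliable when its
#' detection p-value exceeds `p_threshold`. While any row (probe) or column
#' (sample) carries an unreliable fraction above `stop_fraction`, the row or
#' column with the highest unreliable fraction is removed. Ties are broken
#' deterministically: probe before sample, then lexicographic id.
#'
#' @param dp Detection p-value matrix (probes x samples), values in `[0, 1]`.
#' @param p_threshold Detection p-value above which a measurement counts as
#'   unreliable (default 0.05).
#' @param stop_fraction Stop once every row and column has unreliable
#'   fraction at or below this (default 0.05).
#'
#' @return List with character vectors `probes` and `samples` removed. If
#'   everything is unreliable the whole matrix is consumed, with a warning.
#' @export
greedycut_like <- function(dp, p_threshold = 0.05, stop_fraction = 0.05) {
  stopifnot(is.matrix(dp))
  if (p_threshold <= 0 || p_threshold >= 1) stop2("p_threshold must be in (0, 1)")
  bad <- dp > p_threshold
  bad[is.na(bad)] <- TRUE
  removed_p <- character(0); removed_s <- character(0)

  repeat {
    if (nrow(bad) == 0L || ncol(bad) == 0L) {
      warning("greedycut_like removed every probe or sample", call. = FALSE)
      break
    }
    rf <- rowMeans(bad); cf <- colMeans(bad)
    worst <- max(max(rf), max(cf))
    if (worst <= stop_fraction) break
    if (max(rf) >= max(cf)) {          # probe before sample on ties
      cand <- names(rf)[rf == max(rf)]
      victim <- sort(cand)[1L]
      removed_p <- c(removed_p, victim)
      bad <- bad[setdiff(rownames(bad), victim), , drop = FALSE]
    } else {
      cand <- names(cf)[cf == max(cf)]
      victim <- sort(cand)[1L]
      removed_s <- c(removed_s, victim)
      bad <- bad[, setdiff(colnames(bad), victim), drop = FALSE]
    }
  }
  list(probes = removed_p, samples = removed_s)
}

#' Filter a beta matrix by probe identity, chromosome, and reliability
#'
#' Applies the standard methylation-array probe filters: probes whose id
#' starts with `"rs"` (SNP control probes) are removed, probes on the sex
#' chromosomes (X or Y) are removed, and — when a detection p-value matrix is
#' supplied — probes and samples flagged by [greedycut_like()] are removed.
#'
#' @param bm Beta matrix (probes x samples).
#' @param ann Probe annotation; used for chromosome lookup. Probes without
#'   an annotation row are retained by default (they carry no gene links and
#'   can never reach a gene list) or dropped when
#'   `drop_unannotated = TRUE`.
#' @param dp Optional detection p-value matrix aligned with `bm`.
#' @param drop_unannotated Drop probes lacking an annotation row (default
#'   `FALSE`).
#' @param p_threshold,stop_fraction Passed to [greedycut_like()].
#'
#' @return List with `beta` (the filtered matrix) and `report`, a list with
#'   `removed_probes` (`data.frame` of `probe_id`, `reason`),
#'   `removed_samples` (character), and `counts` per reason. The removal
#'   reasons reconcile: every input probe is either retained or listed once.
#' @export
filter_probes <- function(bm, ann, dp = NULL, drop_unannotated = FALSE,
                          p_threshold = 0.05, stop_fraction = 0.05) {
  probes <- rownames(bm)
  chr <- ann$chromosome[match(probes, ann$probe_id)]

  is_rs <- startsWith(probes, "rs")
  is_sex <- !is.na(chr) & chr %in% c("X", "Y")
  is_unann <- drop_unannotated & is.na(chr)

  unreliable_p <- character(0); removed_samples <- character(0)
  if (!is.null(dp)) {
    dp <- dp[intersect(rownames(dp), probes), , drop = FALSE]
    gc <- greedycut_like(dp, p_threshold = p_threshold, stop_fraction = stop_fraction)
    unreliable_p <- gc$probes
    removed_samples <- gc$samples
  }
  is_unrel <- probes %in% unreliable_p

  # first matching reason wins, in the order the filters are described
  reason <- rep(NA_character_, length(probes))
  reason[is_unrel] <- "unreliable"
  reason[is_sex] <- "sex_chromosome"
  reason[is_rs] <- "rs_identifier"
  reason[is_unann & is.na(reason)] <- "unannotated"

  drop <- !is.na(reason)
  keep_samples <- setdiff(colnames(bm), removed_samples)
  out <- bm[!drop, keep_samples, drop = FALSE]

  counts <- table(factor(reason[drop],
                         levels = c("rs_identifier", "sex_chromosome",
                                    "unreliable", "unannotated")))
  report <- list(
    removed_probes = data.frame(probe_id = probes[drop], reason = reason[drop],
                                stringsAsFactors = FALSE),
    removed_samples = removed_samples,
    counts = c(as.list(counts), n_removed_samples = length(removed_samples),
               n_retained = nrow(out)))
  list(beta = out, report = report)
}
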