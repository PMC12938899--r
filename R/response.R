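#' Percent change in tumor burden (%dSLD)
#'
#' Percent-wise change in the RECIST Sum of Longest Diameters between
#' baseline and follow-up imaging: `100 * (followup - baseline) / baseline`.
#' Negative values indicate tumor regression.
#'
#' @param baseline,followup SLD in mm; baseline must be positive.
#' @return percent change (vectorized).
#' @examples
#' pctDeltaSLD(100, 50)  # -50
#' @export
pctDeltaSLD <- function(baseline, followup) {
  if (any(!is.finite(baseline)) || any(baseline <= 0))
    dataError("baseline SLD must be positive and finite")
  100 * (followup - baseline) / baseline
}

#' Build the per-patient response table from paired NPX samples
#'
#' Joins per-patient baseline/follow-up SLD values to the within-patient
#' protein change computed from an [NpxExperiment-class]:
#' `delta_npx = NPX(PT_FU) - NPX(PT_BE)` per protein. Patients lacking
#' either timepoint or follow-up imaging are excluded.
#'
#' @param x an [NpxExperiment-class] with paired `PT_BE`/`PT_FU` samples.
#' @param sld data.frame with columns `subject_id`, `sld_baseline`,
#'   `sld_followup`.
#' @return list: `response` (data.frame `subject_id`, `sld_baseline`,
#'   `sld_followup`, `pct_delta_sld`) and `delta_npx` (patients x proteins
#'   matrix).
#' @export
responseTable <- function(x, sld) {
  stopifnot(all(c("subject_id", "sld_baseline", "sld_followup") %in%
                  names(sld)))
  grp <- sampleGroup(x); sid <- subjectId(x)
  be <- sid[grp == "PT_BE"]; fu <- sid[grp == "PT_FU"]
  subj <- intersect(intersect(be, fu), sld$subject_id)
  if (length(subj) == 0)
    dataError("no subject has both timepoints and SLD values")
  vals <- npx(x)
  beCols <- which(grp == "PT_BE")[match(subj, be)]
  fuCols <- which(grp == "PT_FU")[match(subj, fu)]
  d <- t(vals[, fuCols, drop = FALSE] - vals[, beCols, drop = FALSE])
  rownames(d) <- subj
  s <- sld[match(subj, sld$subject_id), ]
  resp <- data.frame(subject_id = subj,
                     sld_baseline = s$sld_baseline,
                     sld_followup = s$sld_followup,
                     pct_delta_sld = pctDeltaSLD(s$sld_baseline,
                                                 s$sld_followup))
  list(response = resp, delta_npx = d)
}

#' BH-corrected Spearman correlation of protein change with %dSLD
#'
#' Per protein, the Spearman correlation between within-patient NPX change
#' and percent change in tumor burden, with Benjamini-Hochberg adjustment
#' across proteins. Sign convention: rho < 0 means the protein level
#' increases with tumor regression; rho > 0 means it decreases with
#' regression. Proteins whose change vector is constant (all tied) have an
#' undefined correlation and are excluded with a warning. p-values follow
#' the standard treatment (exact for small untied samples, asymptotic
#' t-approximation otherwise).
#'
#' @param deltaNpx patients x proteins matrix of NPX changes.
#' @param pctDeltaSld per-patient percent change in SLD.
#' @param minPairs minimum paired observations per protein (default 5).
#' @return data.frame: `protein_id`, `rho`, `p_raw`, `q_bh`, `n`.
#' @export
spearmanBH <- function(deltaNpx, pctDeltaSld, minPairs = 5) {
  deltaNpx <- as.matrix(deltaNpx)
  if (nrow(deltaNpx) != length(pctDeltaSld))
    contractError("deltaNpx rows must match pctDeltaSld length")
  rows <- lapply(colnames(deltaNpx), function(pid) {
    d <- deltaNpx[, pid]
    ok <- !is.na(d) & !is.na(pctDeltaSld)
    if (sum(ok) < minPairs) return(NULL)
    if (length(unique(d[ok])) == 1) return(NA)
    ct <- suppressWarnings(
      cor.test(d[ok], pctDeltaSld[ok], method = "spearman"))
    data.frame(protein_id = pid, rho = unname(ct$estimate),
               p_raw = ct$p.value, n = sum(ok))
  })
  tied <- vapply(rows, function(r) !is.null(r) && !is.data.frame(r),
                 logical(1))
  if (any(tied))
    warning(sprintf("%d protein(s) with all-tied changes excluded",
                    sum(tied)))
  rows <- rows[!tied & !vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) dataError("no testable protein")
  out <- do.call(rbind, rows)
  out$q_bh <- adjustBH(out$p_raw)
  out
}

## Rank-based quartile assignment: subjects are ordered by delta-NPX (ties
## broken by subject id) and cut into four near-equal bins; the remainder
## goes to the lower quartiles first, so n = 27 gives sizes (7, 7, 7, 6).
assignQuartiles <- function(deltaNpx, subjectIds = names(deltaNpx)) {
  n <- length(deltaNpx)
  if (is.null(subjectIds)) subjectIds <- as.character(seq_len(n))
  sizes <- rep(n %/% 4, 4) + c(rep(1, n %% 4), rep(0, 4 - n %% 4))
  ord <- order(deltaNpx, subjectIds)
  q <- integer(n)
  q[ord] <- rep(1:4, times = sizes)
  factor(paste0("Q", q), levels = paste0("Q", 1:4))
}

#' Compare %dSLD between the extreme delta-NPX quartiles
#'
#' Subjects are ranked by a protein's NPX change and binned into four
#' near-equal quartiles (Q1 the most negative changes, Q4 the highest;
#' remainder assigned to the lower quartiles first). %dSLD in Q1 vs Q4 is
#' compared with a two-sample t-test when both quartiles pass the
#' [normalityGate()], otherwise with the Wilcoxon rank-sum test.
#'
#' @param deltaNpx per-subject NPX change for one protein (named by
#'   subject), or a patients x proteins matrix for the multi-protein screen
#'   (then p-values are BH-adjusted across proteins).
#' @param pctDeltaSld per-subject percent change in SLD.
#' @param alpha normality-gate level.
#' @return for a vector: list with `quartile` (per-subject assignment),
#'   `test_used`, `statistic`, `p`. For a matrix: data.frame with one row
#'   per protein plus `q_bh`.
#' @export
quartileCompare <- function(deltaNpx, pctDeltaSld, alpha = 0.05) {
  if (is.matrix(deltaNpx)) {
    rows <- lapply(colnames(deltaNpx), function(pid) {
      r <- quartileCompare(deltaNpx[, pid], pctDeltaSld, alpha)
      data.frame(protein_id = pid, test_used = r$test_used,
                 statistic = r$statistic, p_raw = r$p)
    })
    out <- do.call(rbind, rows)
    out$q_bh <- adjustBH(out$p_raw)
    return(out)
  }
  n <- length(deltaNpx)
  if (n < 8)
    dataError("quartile comparison requires >= 8 subjects, got %d", n)
  q <- assignQuartiles(deltaNpx)
  y1 <- pctDeltaSld[q == "Q1"]
  y4 <- pctDeltaSld[q == "Q4"]
  ## the KS gate needs >= 3 values; tiny extreme quartiles fall back to
  ## the rank-sum test
  gaussian <- length(y1) >= 3 && length(y4) >= 3 &&
    normalityGate(y1, alpha) && normalityGate(y4, alpha)
  ht <- if (gaussian) t.test(y1, y4) else
    suppressWarnings(wilcox.test(y1, y4, exact = FALSE))
  list(quartile = q, test_used = if (gaussian) "t" else "wilcoxon",
       statistic = unname(ht$statistic), p = ht$p.value)
}

#' Full treatment-response correlation analysis
#'
#' Combines [spearmanBH()] and the quartile screen ([quartileCompare()]) on
#' the same delta-NPX matrix.
#'
#' @inheritParams spearmanBH
#' @param alpha normality-gate level for the quartile tests.
#' @return data.frame joining the per-protein Spearman results (`rho`,
#'   `p_raw`, `q_bh`) with the Q1-vs-Q4 comparison (`q1q4_test`,
#'   `q1q4_statistic`, `q1q4_p`, `q1q4_q`).
#' @export
responseAnalysis <- function(deltaNpx, pctDeltaSld, minPairs = 5,
                             alpha = 0.05) {
  sp <- spearmanBH(deltaNpx, pctDeltaSld, minPairs = minPairs)
  qc <- quartileCompare(as.matrix(deltaNpx)[, sp$protein_id, drop = FALSE],
                        pctDeltaSld, alpha = alpha)
  data.frame(sp,
             q1q4_test = qc$test_used, q1q4_statistic = qc$statistic,
             q1q4_p = qc$p_raw, q1q4_q = qc$q_bh)
}
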