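# Differential expression from two-group replicated designs.
#
# Transcripts: per-gene Welch t-test on log2 ratios with Benjamini-Hochberg
# adjustment plus a fold-change gate on group means. Proteins: emPAI
# label-free quantification, per-replicate geometric-mean normalization,
# presence filtering, and a fold-change-only gate.

new_de_list <- function(entity, log2fc, p, padj, direction, unbounded,
                        line = NA_character_,
                        evidence = c("transcript", "protein")) {
  evidence <- match.arg(evidence)
  out <- data.frame(
    entity = as.character(entity),
    log2fc = as.numeric(log2fc),
    p = as.numeric(p),
    padj = as.numeric(padj),
    direction = as.character(direction),
    unbounded = as.logical(unbounded),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "line") <- line
  attr(out, "evidence") <- evidence
  class(out) <- c("kr_de_list", "data.frame")
  out
}

#' Differential transcripts between two replicated populations
#'
#' Calls differentially expressed transcripts between a high- and a
#' low-expression population of one cell line. Each matrix holds per-gene
#' log2 ratios (sample channel over common reference channel) with one
#' column per biological replicate. A gene is reported when the absolute
#' difference of group means is at least `log2(fold_threshold)` and the
#' Benjamini-Hochberg adjusted p-value of a two-sided Welch (unequal
#' variance) t-test is at most `alpha`.
#'
#' Genes with fewer than two finite values in either group are skipped with
#' a message; the test is undefined for them. Genes with zero variance in
#' both groups get p = 1 when the means agree and p = 0 otherwise.
#'
#' @param high,low Numeric matrices (genes x replicates) with identical row
#'   name universes; at least 2 replicate columns each.
#' @param fold_threshold Linear fold-change gate (default 2).
#' @param alpha Adjusted-p significance level (default 0.05).
#' @param line Optional cell-line label carried into the result.
#' @return A `kr_de_list` data frame with columns `entity`, `log2fc`
#'   (high minus low), `p`, `padj`, `direction` (`"up"` when the high
#'   population mean is larger), `unbounded` (always `FALSE` here).
#' @examples
#' set.seed(1)
#' high <- matrix(rnorm(30, 0, 0.2), 10, 3, dimnames = list(paste0("G", 1:10)))
#' low <- matrix(rnorm(30, 0, 0.2), 10, 3, dimnames = list(paste0("G", 1:10)))
#' high[1, ] <- high[1, ] + 3
#' de_transcripts(high, low)
#' @export
de_transcripts <- function(high, low, fold_threshold = 2, alpha = 0.05,
                           line = NA_character_) {
  if (!is.matrix(high) || !is.matrix(low)) {
    stop("`high` and `low` must be matrices of log2 ratios")
  }
  if (ncol(high) < 2L || ncol(low) < 2L) {
    stop("at least 2 replicates per population are required")
  }
  if (is.null(rownames(high)) || is.null(rownames(low))) {
    stop("matrices must carry gene identifiers as row names")
  }
  if (!setequal(rownames(high), rownames(low))) {
    stop("`high` and `low` must share the same entity universe")
  }
  low <- low[rownames(high), , drop = FALSE]

  fin_h <- is.finite(high)
  fin_l <- is.finite(low)
  n_h <- rowSums(fin_h)
  n_l <- rowSums(fin_l)
  testable <- n_h >= 2L & n_l >= 2L
  if (any(!testable)) {
    message(sum(!testable), " gene(s) skipped: fewer than 2 finite values ",
            "in one of the groups")
  }
  if (!any(testable)) {
    return(new_de_list(character(), numeric(), numeric(), numeric(),
                       character(), logical(), line, "transcript"))
  }

  h <- high[testable, , drop = FALSE]
  l <- low[testable, , drop = FALSE]
  fh <- fin_h[testable, , drop = FALSE]
  fl <- fin_l[testable, , drop = FALSE]
  nh <- n_h[testable]
  nl <- n_l[testable]
  h0 <- ifelse(fh, h, 0)
  l0 <- ifelse(fl, l, 0)
  mh <- rowSums(h0) / nh
  ml <- rowSums(l0) / nl
  vh <- rowSums(ifelse(fh, (h0 - mh)^2, 0)) / (nh - 1L)
  vl <- rowSums(ifelse(fl, (l0 - ml)^2, 0)) / (nl - 1L)

  diff <- mh - ml
  se2 <- vh / nh + vl / nl
  p <- numeric(length(diff))
  degen <- se2 == 0
  p[degen] <- ifelse(diff[degen] == 0, 1, 0)
  if (any(!degen)) {
    tt <- diff[!degen] / sqrt(se2[!degen])
    df <- se2[!degen]^2 /
      ((vh[!degen] / nh[!degen])^2 / (nh[!degen] - 1L) +
         (vl[!degen] / nl[!degen])^2 / (nl[!degen] - 1L))
    p[!degen] <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  }
  padj <- stats::p.adjust(p, method = "BH")

  keep <- abs(diff) >= log2(fold_threshold) & padj <= alpha
  new_de_list(
    entity = rownames(h)[keep],
    log2fc = diff[keep],
    p = p[keep],
    padj = padj[keep],
    direction = ifelse(diff[keep] > 0, "up", "down"),
    unbounded = rep(FALSE, sum(keep)),
    line = line, evidence = "transcript"
  )
}

#' Exponentially modified protein abundance index
#'
#' emPAI = 10^(observed / observable) - 1, where `observed` counts
#' significant peptide matches for a protein in one replicate and
#' `observable` counts its theoretically observable peptides.
#'
#' @param observed Non-negative integer vector of observed peptide matches.
#' @param observable Positive integer vector of observable peptides
#'   (recycled against `observed`).
#' @return Numeric vector of abundance indices (0 when nothing observed).
#' @examples
#' empai(3, 10)  # 10^0.3 - 1
#' @export
empai <- function(observed, observable) {
  if (any(observable < 1)) {
    stop("`observable` must be >= 1 for every protein record")
  }
  if (any(observed < 0)) stop("`observed` counts must be >= 0")
  10^(observed / observable) - 1
}

#' Build a peptide-count table
#'
#' @param observed Integer matrix, proteins x replicates, of significant
#'   peptide matches; row names are protein identifiers.
#' @param observable Positive integer vector, one value per protein.
#' @param line Optional cell-line label.
#' @param population Optional population label (`"high"` / `"low"`).
#' @return A `kr_peptides` object.
#' @export
peptide_table <- function(observed, observable, line = NA_character_,
                          population = NA_character_) {
  observed <- as.matrix(observed)
  if (is.null(rownames(observed))) stop("protein identifiers required")
  if (anyDuplicated(rownames(observed))) stop("duplicate protein identifiers")
  if (length(observable) != nrow(observed)) {
    stop("`observable` must have one entry per protein")
  }
  if (any(observable < 1)) stop("`observable` must be >= 1")
  if (any(observed < 0) || any(observed != round(observed))) {
    stop("observed counts must be non-negative integers")
  }
  structure(list(observed = observed, observable = as.numeric(observable),
                 line = line, population = population),
            class = "kr_peptides")
}

#' Normalized emPAI abundances
#'
#' Converts a peptide-count table to per-replicate emPAI values, each
#' divided by the geometric mean of observed significant peptide-match
#' counts over the proteins detected (observed >= 1) in that replicate.
#' Only the normalizer depends on the replicate; emPAI itself is computed
#' per protein cell.
#'
#' @param table A `kr_peptides` object from [peptide_table()].
#' @return A `kr_abundance` object: list with `abundance` (numeric matrix,
#'   proteins x replicates) and `detected` (logical matrix, observed >= 1).
#' @export
normalize_abundance <- function(table) {
  stopifnot(inherits(table, "kr_peptides"))
  obs <- table$observed
  emp <- empai(obs, table$observable)
  detected <- obs >= 1
  normalizer <- vapply(seq_len(ncol(obs)), function(j) {
    det <- detected[, j]
    if (!any(det)) {
      stop("replicate ", colnames(obs)[j] %||% j,
           " has no detected protein; normalizer undefined")
    }
    geometric_mean(obs[det, j])
  }, numeric(1))
  abundance <- sweep(emp, 2L, normalizer, "/")
  structure(list(abundance = abundance, detected = detected,
                 normalizer = normalizer, line = table$line,
                 population = table$population),
            class = "kr_abundance")
}

#' Differential proteins between two replicated populations
#'
#' Applies the label-free differential rule: a protein is treated as absent
#' from a population when it was detected (observed >= 1) in at most one of
#' the three biological replicates; for proteins present in both
#' populations the fold change is the ratio of across-replicate mean
#' normalized abundances, gated at `fold_threshold` (either direction);
#' proteins present in exactly one population are reported with the
#' direction of the present side and an unbounded fold change.
#'
#' With a replicate count other than 3 a warning is raised and the
#' generalized rule "present in >= 2 replicates" is applied.
#'
#' @param high,low `kr_abundance` objects (or `kr_peptides`, normalized on
#'   the fly) sharing the same protein universe.
#' @param fold_threshold Linear fold-change gate (default 2).
#' @param line Optional cell-line label.
#' @return A `kr_de_list` with `evidence = "protein"`; `log2fc` is
#'   `+Inf`/`-Inf` and `unbounded = TRUE` for one-sided presence.
#' @export
de_proteins <- function(high, low, fold_threshold = 2, line = NA_character_) {
  if (inherits(high, "kr_peptides")) high <- normalize_abundance(high)
  if (inherits(low, "kr_peptides")) low <- normalize_abundance(low)
  stopifnot(inherits(high, "kr_abundance"), inherits(low, "kr_abundance"))
  if (!setequal(rownames(high$abundance), rownames(low$abundance))) {
    stop("protein universes differ between populations")
  }
  ord <- rownames(high$abundance)
  ab_h <- high$abundance
  ab_l <- low$abundance[ord, , drop = FALSE]
  det_h <- high$detected
  det_l <- low$detected[ord, , drop = FALSE]
  if (ncol(ab_h) != 3L || ncol(ab_l) != 3L) {
    warning("replicate count != 3; applying generalized rule ",
            "'present in >= 2 replicates'")
  }

  present_h <- rowSums(det_h) >= 2L
  present_l <- rowSums(det_l) >= 2L
  mean_h <- rowMeans(ab_h)
  mean_l <- rowMeans(ab_l)

  entity <- character(0); l2fc <- numeric(0)
  dir <- character(0); unb <- logical(0)

  both <- present_h & present_l
  if (any(both)) {
    ratio <- mean_h[both] / mean_l[both]
    keep <- ratio >= fold_threshold | ratio <= 1 / fold_threshold
    entity <- c(entity, ord[both][keep])
    l2fc <- c(l2fc, log2(ratio[keep]))
    dir <- c(dir, ifelse(ratio[keep] > 1, "up", "down"))
    unb <- c(unb, rep(FALSE, sum(keep)))
  }
  only_h <- present_h & !present_l
  entity <- c(entity, ord[only_h])
  l2fc <- c(l2fc, rep(Inf, sum(only_h)))
  dir <- c(dir, rep("up", sum(only_h)))
  unb <- c(unb, rep(TRUE, sum(only_h)))

  only_l <- present_l & !present_h
  entity <- c(entity, ord[only_l])
  l2fc <- c(l2fc, rep(-Inf, sum(only_l)))
  dir <- c(dir, rep("down", sum(only_l)))
  unb <- c(unb, rep(TRUE, sum(only_l)))

  o <- order(entity)
  new_de_list(entity[o], l2fc[o], rep(NA_real_, length(o)),
              rep(NA_real_, length(o)), dir[o], unb[o],
              line = line, evidence = "protein")
}

#' Assemble the six per-line evidence lists
#'
#' Combines up- and down-regulated entries of each differential list and
#' returns the 3 cell lines x 2 evidence types = 6 lists that feed the
#' downstream transcription-factor and master-regulator searches. Each
#' evidence type is kept separate; lists may be empty.
#'
#' @param per_line Named list of exactly 3 cell lines, each a list with
#'   elements `transcript` and `protein` (both `kr_de_list`).
#' @return Named list of 6 `kr_de_list` objects, names
#'   `<line>.<evidence>`.
#' @export
build_six_lists <- function(per_line) {
  if (length(per_line) != 3L) stop("exactly 3 cell lines are required")
  if (is.null(names(per_line)) || anyDuplicated(names(per_line))) {
    stop("`per_line` must be uniquely named by cell line")
  }
  out <- list()
  for (ln in names(per_line)) {
    for (ev in c("transcript", "protein")) {
      dl <- per_line[[ln]][[ev]]
      if (is.null(dl)) stop("cell line ", ln, " is missing its ", ev, " list")
      dl <- dl[!duplicated(dl$entity), , drop = FALSE]
      attr(dl, "line") <- ln
      attr(dl, "evidence") <- ev
      class(dl) <- c("kr_de_list", "data.frame")
      out[[paste(ln, ev, sep = ".")]] <- dl
    }
  }
  out
}
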