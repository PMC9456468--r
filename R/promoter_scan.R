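# Promoter sets, both-strand PWM scanning, and yes-vs-no binding-site
# enrichment converting enriched matrices into TF candidate lists.

#' Construct a promoter set
#'
#' Promoters are expected to cover the window from 1000 bases upstream to
#' 100 bases downstream of the transcription start site (offsets -1000 to
#' +100 inclusive, 1101 bases when complete; the base at offset 0 is the
#' TSS). Shorter sequences are accepted and flagged with a message; their
#' window is assumed to end at +100 so that offsets stay anchored at the
#' TSS.
#'
#' @param sequences Named character vector of A/C/G/T/N sequences.
#' @param window_end Offset of the last base, inclusive (default +100).
#' @return A `kr_promoters` object (named character vector with window
#'   metadata).
#' @export
promoter_set <- function(sequences, window_end = 100L) {
  if (is.null(names(sequences)) || anyDuplicated(names(sequences))) {
    stop("promoters must be uniquely named by gene")
  }
  sequences <- toupper(sequences)
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad)) {
    stop("illegal characters in promoter record(s): ",
         paste(names(sequences)[bad], collapse = ", "))
  }
  short <- nchar(sequences) < 1101L
  if (any(short)) {
    message(sum(short), " promoter(s) shorter than the full 1101-base window")
  }
  structure(sequences, window_end = as.integer(window_end),
            class = "kr_promoters")
}

#' @export
`[.kr_promoters` <- function(x, i) {
  promoter_set(unclass(x)[i], window_end = attr(x, "window_end"))
}

# window start offset of each promoter (TSS-relative, leftmost base);
# window_end is the offset of the last base, inclusive
promoter_window_start <- function(promoters) {
  attr(promoters, "window_end") - nchar(promoters) + 1L
}

#' Scan promoters with a PWM library
#'
#' Scores every admissible start position on both strands of every
#' promoter and reports positions whose log-odds score reaches the
#' matrix's calibrated threshold. Overlapping hits are all reported; a
#' minus-strand hit is reported at the leftmost plus-strand base of the
#' window it covers. Offsets are TSS-relative (0-based, TSS at 0).
#'
#' @param library A calibrated `kr_pwm_library` (see
#'   [calibrate_library()]).
#' @param promoters A `kr_promoters` object.
#' @return Data frame of hits: `matrix_id`, `gene`, `strand`, `offset`,
#'   `score`.
#' @export
scan_set <- function(library, promoters) {
  stopifnot(inherits(library, "kr_pwm_library"))
  if (length(promoters) == 0L) {
    warning("empty promoter set: no hits")
    return(data.frame(matrix_id = character(), gene = character(),
                      strand = character(), offset = integer(),
                      score = numeric(), stringsAsFactors = FALSE))
  }
  thr <- vapply(library, function(p) p$threshold %||% NA_real_, numeric(1))
  if (anyNA(thr)) {
    stop("uncalibrated matrices in library: ",
         paste(names(library)[is.na(thr)], collapse = ", "))
  }
  genes <- names(promoters)
  lens <- nchar(promoters)
  win_start <- promoter_window_start(promoters)
  maxL <- max(vapply(library, pwm_length, integer(1)))

  # one concatenated code vector per strand; boundary sentinels (-Inf)
  # prevent windows from spanning two promoters
  pad <- rep(6L, maxL)
  codes <- lapply(promoters, encode_dna)
  concat <- unlist(lapply(codes, function(cc) c(cc, pad)), use.names = FALSE)
  starts <- cumsum(c(1L, lens + maxL))[seq_along(genes)]
  gene_at <- rep(seq_along(genes), lens + maxL)

  out <- vector("list", 2L * length(library))
  k <- 0L
  for (pwm in library) {
    L <- pwm_length(pwm)
    lom6 <- lom_ext(pwm)
    for (strand in c("+", "-")) {
      cc <- if (strand == "+") concat else {
        rev(c(4L, 3L, 2L, 1L, 5L, 6L)[concat])
      }
      sc <- score_positions(lom6, cc)
      hit <- which(sc >= pwm$threshold)
      if (!length(hit)) next
      if (strand == "-") {
        # map back: start in reversed coords j covers original
        # positions [n - j - L + 2, n - j + 1]
        hit_orig <- length(concat) - hit - L + 2L
        sc_hit <- sc[hit]
        hit <- hit_orig
      } else {
        sc_hit <- sc[hit]
      }
      gi <- gene_at[hit]
      pos_in_gene <- hit - starts[gi] + 1L
      keep <- pos_in_gene >= 1L & pos_in_gene + L - 1L <= lens[gi]
      if (!any(keep)) next
      k <- k + 1L
      out[[k]] <- data.frame(
        matrix_id = pwm$id,
        gene = genes[gi[keep]],
        strand = strand,
        offset = win_start[gi[keep]] + pos_in_gene[keep] - 1L,
        score = sc_hit[keep],
        stringsAsFactors = FALSE
      )
    }
  }
  if (k == 0L) {
    return(data.frame(matrix_id = character(), gene = character(),
                      strand = character(), offset = integer(),
                      score = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out[seq_len(k)])
  rownames(res) <- NULL
  res[order(res$matrix_id, res$gene, res$offset, res$strand), , drop = FALSE]
}

# positions scanned for a matrix of length L over a promoter set
# (both strands; overlapping starts all count)
scanned_positions <- function(promoters, L) {
  sum(pmax(0L, nchar(promoters) - L + 1L)) * 2
}

#' TF candidates by promoter binding-site enrichment
#'
#' For each matrix, compares the binding-site hit density (hits per
#' kilobase of scanned positions) in the promoters of a differential gene
#' list (the yes set) against background promoters (the no set) with a
#' one-sided binomial test (expected rate = no-set density), adjusted by
#' Benjamini-Hochberg across matrices. Matrices with adjusted p <= `alpha`
#' and fold enrichment >= `min_fold` contribute their annotated TF names to
#' the candidate list. When the no set has zero hits the fold enrichment is
#' computed with one pseudo-hit (the test itself uses the exact zero).
#'
#' @param yes Promoters of the differential genes (`kr_promoters`).
#' @param no Background promoters, disjoint from `yes`.
#' @param library A calibrated `kr_pwm_library`.
#' @param alpha BH-adjusted significance level (default 0.05).
#' @param min_fold Minimum fold enrichment (default 1.5).
#' @param min_yes Minimum yes-set size before a low-power warning
#'   (default 3).
#' @param hits Optional precomputed [scan_set()] result covering both sets
#'   (avoids rescanning, e.g. inside the pipeline).
#' @return List with `records` (per-matrix data frame: densities, fold,
#'   p, padj, enriched flag, TF names) and `candidates` (character vector
#'   of TF names of enriched matrices).
#' @export
tf_candidates <- function(yes, no, library, alpha = 0.05, min_fold = 1.5,
                          min_yes = 3L, hits = NULL) {
  stopifnot(inherits(library, "kr_pwm_library"))
  if (length(no) == 0L) stop("background (no) promoter set is empty")
  if (length(intersect(names(yes), names(no)))) {
    stop("yes and no promoter sets must be disjoint")
  }
  low_power <- length(yes) < min_yes
  if (low_power) {
    warning("yes set has fewer than ", min_yes, " genes; results are ",
            "low-power")
  }
  if (is.null(hits)) {
    hits <- rbind(scan_set(library, yes), scan_set(library, no))
  }
  ids <- names(library)
  Ls <- vapply(library, pwm_length, integer(1))
  n_yes <- vapply(Ls, function(L) scanned_positions(yes, L), numeric(1))
  n_no <- vapply(Ls, function(L) scanned_positions(no, L), numeric(1))
  in_yes <- hits$gene %in% names(yes)
  k_yes <- vapply(ids, function(id)
    sum(hits$matrix_id == id & in_yes), numeric(1))
  k_no <- vapply(ids, function(id)
    sum(hits$matrix_id == id & hits$gene %in% names(no)), numeric(1))

  p0 <- k_no / n_no
  p <- ifelse(
    k_yes == 0, 1,
    stats::pbinom(k_yes - 1, n_yes, pmin(1, p0), lower.tail = FALSE)
  )
  padj <- stats::p.adjust(p, method = "BH")
  dens_yes <- k_yes / n_yes * 1000
  dens_no <- k_no / n_no * 1000
  fold <- dens_yes / ((k_no + (k_no == 0)) / n_no * 1000)
  enriched <- padj <= alpha & fold >= min_fold & k_yes > 0
  records <- data.frame(
    matrix_id = ids,
    yes_hits = k_yes, no_hits = k_no,
    yes_density = dens_yes, no_density = dens_no,
    fold_enrichment = fold, p = p, padj = padj,
    enriched = enriched,
    tf = vapply(library, function(x) paste(x$tf, collapse = ","),
                character(1)),
    stringsAsFactors = FALSE
  )
  rownames(records) <- NULL
  candidates <- sort(unique(norm_id(unlist(
    lapply(library[enriched], function(x) x$tf)))))
  structure(list(records = records, candidates = candidates,
                 low_power = low_power),
            class = "kr_tf_result")
}
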