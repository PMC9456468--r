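# Positional weight matrices: construction, log-odds scoring, and
# minSUM-style threshold calibration by exact dynamic programming over the
# per-position score distributions.

DNA_BASES <- c("A", "C", "G", "T")

#' Construct a positional weight matrix
#'
#' Builds a PWM from a 4 x L count (or probability) matrix. Counts are
#' converted to probabilities with a background-weighted pseudocount:
#' p(b, j) = (n(b, j) + pseudocount * bg(b)) / (N(j) + pseudocount). A
#' probability matrix (columns summing to 1) is used as-is after mixing in
#' the pseudocount fraction so that every probability is strictly positive.
#'
#' @param mat 4 x L numeric matrix, rows in order A, C, G, T.
#' @param id Matrix identifier.
#' @param tf Character vector of annotated transcription-factor names.
#' @param background Background nucleotide frequencies (length 4, sums
#'   to 1); default uniform.
#' @param pseudocount Pseudocount mass (default 1).
#' @return A `kr_pwm` object with fields `id`, `tf`, `mat` (probabilities),
#'   `lom` (log2-odds against background), `background`, `pseudocount`,
#'   `threshold` (NULL until [calibrate_threshold()] is applied).
#' @export
new_pwm <- function(mat, id, tf = id, background = rep(0.25, 4),
                    pseudocount = 1) {
  mat <- as.matrix(mat)
  if (nrow(mat) != 4L) stop("PWM must have 4 rows (A, C, G, T)")
  if (ncol(mat) < 4L) stop("PWM must have length >= 4")
  if (any(mat < 0)) stop("negative PWM entries")
  if (length(background) != 4L || abs(sum(background) - 1) > 1e-9 ||
      any(background <= 0)) {
    stop("`background` must be 4 positive frequencies summing to 1")
  }
  totals <- colSums(mat)
  if (any(totals <= 0)) stop("PWM column with zero total in matrix ", id)
  if (all(abs(totals - 1) < 1e-9)) {
    # probability input: shrink toward background so all entries are > 0
    w <- pseudocount / (pseudocount + 100)
    prob <- (1 - w) * mat + w * background
  } else {
    prob <- sweep(mat, 2L, totals + pseudocount, "/") +
      background * pseudocount / rep(totals + pseudocount, each = 4L)
  }
  prob <- sweep(prob, 2L, colSums(prob), "/")
  rownames(prob) <- DNA_BASES
  structure(list(id = as.character(id), tf = norm_id(tf), mat = prob,
                 lom = log2(prob / background),
                 background = as.numeric(background),
                 pseudocount = pseudocount, threshold = NULL),
            class = "kr_pwm")
}

#' @export
print.kr_pwm <- function(x, ...) {
  cat("PWM", x$id, "(", paste(x$tf, collapse = ","), ") length",
      ncol(x$mat), "\n")
  if (!is.null(x$threshold)) cat("  calibrated threshold:", x$threshold, "\n")
  invisible(x)
}

pwm_length <- function(pwm) ncol(pwm$mat)

#' Bundle PWMs into a library
#' @param pwms List of `kr_pwm` objects.
#' @return A `kr_pwm_library` (named list).
#' @export
pwm_library <- function(pwms) {
  stopifnot(all(vapply(pwms, inherits, logical(1), "kr_pwm")))
  names(pwms) <- vapply(pwms, function(p) p$id, character(1))
  if (anyDuplicated(names(pwms))) stop("duplicate matrix identifiers")
  structure(pwms, class = "kr_pwm_library")
}

# integer base codes; 5 = N (scores 0), 6 = sequence boundary (-Inf)
encode_dna <- function(seq) {
  v <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  code <- match(v, DNA_BASES)
  code[is.na(code)] <- 5L
  code
}

revcomp_code <- function(code) {
  comp <- c(4L, 3L, 2L, 1L, 5L, 6L)
  rev(comp[code])
}

# log-odds rows extended with the N and boundary conventions
lom_ext <- function(pwm) rbind(pwm$lom, 0, -Inf)

# vectorized scores for every admissible start in a code vector (+ strand)
score_positions <- function(lom6, code) {
  L <- ncol(lom6)
  np <- length(code) - L + 1L
  if (np < 1L) return(numeric(0))
  s <- numeric(np)
  for (j in seq_len(L)) {
    s <- s + lom6[cbind(code[j:(j + np - 1L)], j)]
  }
  s
}

#' Log-odds score of one candidate binding site
#'
#' Scores the window of PWM length starting at `position` (1-based index
#' into the promoter sequence). The score is the sum over matrix columns of
#' log2(p(base) / background(base)); an N base contributes 0. On the minus
#' strand the reverse complement of the window is scored (the match still
#' covers the same plus-strand bases).
#'
#' @param pwm A `kr_pwm`.
#' @param sequence Promoter sequence (single character string, A/C/G/T/N).
#' @param position 1-based start of the window within `sequence`.
#' @param strand `"+"` or `"-"`.
#' @return Numeric log-odds score.
#' @export
score_site <- function(pwm, sequence, position, strand = "+") {
  stopifnot(inherits(pwm, "kr_pwm"))
  L <- pwm_length(pwm)
  n <- nchar(sequence)
  if (position < 1L || position + L - 1L > n) {
    stop("site [", position, ", ", position + L - 1L,
         "] out of bounds for sequence of length ", n)
  }
  code <- encode_dna(substr(sequence, position, position + L - 1L))
  if (identical(strand, "-")) code <- revcomp_code(code)
  sum(lom_ext(pwm)[cbind(code, seq_len(L))])
}

#' minSUM threshold calibration
#'
#' Computes the exact distribution of the log-odds score under the motif
#' model (bases drawn from the PWM columns) and under the background model
#' by dynamic programming over positions, then returns the achievable
#' cutoff minimizing false-negative rate + false-positive rate, where
#' FN(c) = P_motif(score < c) and FP(c) = P_background(score >= c). Ties
#' are broken toward the higher cutoff.
#'
#' Score values are merged on a grid of `granularity` during the DP; the
#' default 1e-9 keeps the support exact for motifs up to ~10 columns. For
#' longer matrices a coarser grid (1e-4) bounds memory.
#'
#' @param pwm A `kr_pwm`.
#' @param background Background frequencies (default: the PWM's own).
#' @param granularity Score merge tolerance (default automatic).
#' @return The cutoff, with attributes `fn`, `fp` (rates at the cutoff) and
#'   `distribution` (data frame of score support and both probability
#'   masses).
#' @export
calibrate_threshold <- function(pwm, background = pwm$background,
                                granularity = NULL) {
  stopifnot(inherits(pwm, "kr_pwm"))
  L <- pwm_length(pwm)
  if (is.null(granularity)) granularity <- if (L <= 10L) 1e-9 else 1e-4
  lom <- log2(pwm$mat / background)

  score <- 0; pm <- 1; pb <- 1
  for (j in seq_len(L)) {
    ns <- rep(score, each = 4L) + lom[, j]
    npm <- rep(pm, each = 4L) * pwm$mat[, j]
    npb <- rep(pb, each = 4L) * background
    key <- round(ns / granularity)
    agg <- rowsum(cbind(npm, npb, ns * npm), key)
    o <- order(as.numeric(rownames(agg)))
    agg <- agg[o, , drop = FALSE]
    pm <- agg[, 1L]
    pb <- agg[, 2L]
    # representative score: motif-mass-weighted mean of merged members
    # (all masses are strictly positive, so pm > 0 throughout)
    score <- agg[, 3L] / pm
  }
  o <- order(score)
  score <- unname(score[o]); pm <- unname(pm[o]); pb <- unname(pb[o])
  fn <- c(0, cumsum(pm))[seq_along(score)]          # P_m(score < c)
  fp <- rev(cumsum(rev(pb)))                        # P_b(score >= c)
  objective <- fn + fp
  best <- max(which(objective <= min(objective) + 1e-12))
  structure(score[best], fn = fn[best], fp = fp[best],
            distribution = data.frame(score = score, p_motif = pm,
                                      p_background = pb))
}

#' Calibrate every matrix in a library
#' @param library A `kr_pwm_library`.
#' @param ... Passed to [calibrate_threshold()].
#' @return The library with `threshold` filled in on every PWM.
#' @export
calibrate_library <- function(library, ...) {
  stopifnot(inherits(library, "kr_pwm_library"))
  for (i in seq_along(library)) {
    library[[i]]$threshold <- as.numeric(calibrate_threshold(library[[i]], ...))
  }
  library
}
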