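# Evidence-rank integration: one point per list membership across the six
# evidence lists of a category (TF or MR), singleton discard, and the
# TF-MR intersection ordered by total rank.

#' Membership ranks over evidence lists
#'
#' Assigns each entity one point for every list it appears in. Entities
#' are case-normalized; duplicates within a list count once.
#'
#' @param lists List of entity vectors (character vectors or `kr_de_list`
#'   objects), one per evidence list.
#' @param category `"TF"` or `"MR"`.
#' @param n_lists Required number of lists (default 6).
#' @return A `kr_rank_table` data frame: `entity`, `rank`, ordered by rank
#'   descending then entity.
#' @export
membership_ranks <- function(lists, category = c("TF", "MR"), n_lists = 6L) {
  category <- match.arg(category)
  if (length(lists) != n_lists) {
    stop("expected ", n_lists, " lists, got ", length(lists))
  }
  sets <- lapply(lists, function(x) {
    v <- if (inherits(x, "kr_de_list")) x$entity else x
    v <- norm_id(v)
    if (anyDuplicated(v)) {
      message("duplicate entities within one list counted once")
    }
    unique(v)
  })
  u <- unlist(sets, use.names = FALSE)
  if (length(u)) {
    tab <- table(u)
    out <- data.frame(entity = names(tab), rank = as.integer(tab),
                      stringsAsFactors = FALSE)
  } else {
    out <- data.frame(entity = character(0), rank = integer(0),
                      stringsAsFactors = FALSE)
  }
  out <- out[order(-out$rank, out$entity), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "category") <- category
  attr(out, "n_lists") <- as.integer(n_lists)
  class(out) <- c("kr_rank_table", "data.frame")
  out
}

#' Discard entities present in a single list
#'
#' @param table A `kr_rank_table`.
#' @return The table with every rank-1 entity removed; other ranks
#'   unchanged.
#' @export
discard_singletons <- function(table) {
  stopifnot(inherits(table, "kr_rank_table"))
  out <- table[table$rank >= 2L, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "category") <- attr(table, "category")
  attr(out, "n_lists") <- attr(table, "n_lists")
  class(out) <- class(table)
  out
}

#' Key regulators: TF-MR intersection with total ranks
#'
#' Intersects a (singleton-discarded) TF rank table with an MR rank table.
#' Each retained entity gets total rank = TF rank + MR rank, and the
#' result is ordered by total rank descending, TF rank descending, then
#' entity. With six lists per category the maximal total is 12.
#'
#' @param tf_table,mr_table `kr_rank_table` objects.
#' @return Data frame (`kr_key_regulators`): `entity`, `tf_rank`,
#'   `mr_rank`, `total_rank`.
#' @export
key_regulators <- function(tf_table, mr_table) {
  stopifnot(inherits(tf_table, "kr_rank_table"),
            inherits(mr_table, "kr_rank_table"))
  shared <- intersect(tf_table$entity, mr_table$entity)
  if (!length(shared)) warning("empty TF/MR intersection")
  tf_rank <- stats::setNames(tf_table$rank, tf_table$entity)[shared]
  mr_rank <- stats::setNames(mr_table$rank, mr_table$entity)[shared]
  out <- data.frame(entity = shared,
                    tf_rank = as.integer(tf_rank),
                    mr_rank = as.integer(mr_rank),
                    total_rank = as.integer(tf_rank + mr_rank),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$total_rank, -out$tf_rank, out$entity), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("kr_key_regulators", "data.frame")
  out
}

#' Key regulators from precomputed rank columns
#'
#' Ranks-only entry point: accepts ready-made per-entity TF and MR
#' membership ranks (for instance the published rank columns of a
#' key-regulator table) and reproduces the intersection and total-rank
#' arithmetic without rerunning the upstream searches.
#'
#' @param tf_ranks,mr_ranks Data frames with columns `entity` and `rank`.
#' @param n_lists Number of source lists per category (default 6).
#' @param discard Apply the singleton discard first (default TRUE).
#' @return A `kr_key_regulators` data frame.
#' @export
key_regulators_from_ranks <- function(tf_ranks, mr_ranks, n_lists = 6L,
                                      discard = TRUE) {
  as_table <- function(df, category) {
    out <- data.frame(entity = norm_id(df$entity),
                      rank = as.integer(df$rank), stringsAsFactors = FALSE)
    if (any(out$rank < 0L | out$rank > n_lists)) {
      stop("ranks must lie in 0..", n_lists)
    }
    out <- out[order(-out$rank, out$entity), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "category") <- category
    attr(out, "n_lists") <- as.integer(n_lists)
    class(out) <- c("kr_rank_table", "data.frame")
    out
  }
  tf <- as_table(tf_ranks, "TF")
  mr <- as_table(mr_ranks, "MR")
  if (discard) {
    tf <- discard_singletons(tf)
    mr <- discard_singletons(mr)
  }
  key_regulators(tf, mr)
}
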