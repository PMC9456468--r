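# Readers and writers for the plain-text interchange formats: TSV
# expression and peptide tables, FASTA promoters, JASPAR-PFM and
# TRANSFAC-text matrix libraries, SIF / two-column TSV networks.

read_tsv_checked <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

parse_numeric_block <- function(df, id_col, path) {
  ids <- as.character(df[[id_col]])
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate entity ids in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  }
  num_cols <- setdiff(colnames(df), id_col)
  vals <- matrix(NA_real_, nrow(df), length(num_cols),
                 dimnames = list(ids, num_cols))
  for (cn in num_cols) {
    raw <- df[[cn]]
    v <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(v) & !is.na(raw) & !toupper(trimws(raw)) %in%
                   c("NA", "NAN", ""))
    if (length(bad)) {
      stop("non-numeric cell in ", path, " at row '", ids[bad[1L]],
           "', column '", cn, "': '", raw[bad[1L]], "'")
    }
    vals[, cn] <- v
  }
  vals
}

split_populations <- function(vals, path) {
  pops <- sub("_[^_]+$", "", colnames(vals))
  if (!all(pops %in% c("high", "low"))) {
    stop("replicate columns in ", path,
         " must be named <population>_<replicate> with population ",
         "'high' or 'low'")
  }
  list(high = vals[, pops == "high", drop = FALSE],
       low = vals[, pops == "low", drop = FALSE])
}

#' Read a replicated expression matrix
#'
#' TSV with a header row: the first column holds gene identifiers, the
#' remaining columns per-replicate log2 ratios named
#' `<population>_<replicate>` with population `high` or `low`.
#'
#' @param path TSV file path.
#' @return List with matrices `high` and `low` (genes x replicates).
#' @export
read_expression <- function(path) {
  df <- read_tsv_checked(path)
  if (ncol(df) < 3L) stop("expression table needs id + replicate columns")
  split_populations(parse_numeric_block(df, colnames(df)[1L], path), path)
}

#' Write a replicated expression matrix
#' @param x List with matrices `high` and `low`.
#' @param path Output TSV path.
#' @export
write_expression <- function(x, path) {
  stopifnot(setequal(rownames(x$high), rownames(x$low)))
  low <- x$low[rownames(x$high), , drop = FALSE]
  df <- data.frame(gene = rownames(x$high),
                   stats::setNames(as.data.frame(x$high),
                                   paste0("high_", seq_len(ncol(x$high)))),
                   stats::setNames(as.data.frame(low),
                                   paste0("low_", seq_len(ncol(low)))),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a peptide-count table
#'
#' TSV with columns: protein identifier, `observable` (theoretically
#' observable peptides), then observed significant peptide-match counts
#' per replicate named `<population>_<replicate>`.
#'
#' @param path TSV file path.
#' @param line Optional cell-line label.
#' @return List with `kr_peptides` objects `high` and `low`.
#' @export
read_peptides <- function(path, line = NA_character_) {
  df <- read_tsv_checked(path)
  if (!"observable" %in% colnames(df)) {
    stop("peptide table must contain an 'observable' column")
  }
  vals <- parse_numeric_block(df, colnames(df)[1L], path)
  observable <- vals[, "observable"]
  counts <- vals[, setdiff(colnames(vals), "observable"), drop = FALSE]
  pops <- split_populations(counts, path)
  list(high = peptide_table(pops$high, observable, line, "high"),
       low = peptide_table(pops$low, observable, line, "low"))
}

#' Write a peptide-count table
#' @param x List with `kr_peptides` objects `high` and `low`.
#' @param path Output TSV path.
#' @export
write_peptides <- function(x, path) {
  stopifnot(identical(rownames(x$high$observed), rownames(x$low$observed)))
  df <- data.frame(protein = rownames(x$high$observed),
                   observable = x$high$observable,
                   stats::setNames(as.data.frame(x$high$observed),
                                   paste0("high_",
                                          seq_len(ncol(x$high$observed)))),
                   stats::setNames(as.data.frame(x$low$observed),
                                   paste0("low_",
                                          seq_len(ncol(x$low$observed)))),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read promoters from FASTA
#'
#' @param path FASTA file; records named by gene; letters A/C/G/T/N.
#' @param window_end TSS-relative offset one past the last base
#'   (default +100).
#' @return A `kr_promoters` object.
#' @export
read_promoters <- function(path, window_end = 100L) {
  # BStringSet keeps illegal letters intact so validation can name the
  # offending record (readDNAStringSet silently drops them)
  seqs <- Biostrings::readBStringSet(path)
  nm <- sub("\\s.*$", "", names(seqs))
  v <- stats::setNames(as.character(seqs), nm)
  promoter_set(v, window_end = window_end)
}

#' Write promoters to FASTA
#' @param promoters A `kr_promoters` object.
#' @param path Output FASTA path.
#' @export
write_promoters <- function(promoters, path) {
  x <- Biostrings::DNAStringSet(stats::setNames(unclass(promoters),
                                                names(promoters)))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

parse_jaspar <- function(lines, pseudocount, background) {
  heads <- grep("^>", lines)
  if (!length(heads)) stop("no JASPAR records found")
  bounds <- c(heads, length(lines) + 1L)
  pwms <- lapply(seq_along(heads), function(i) {
    hdr <- sub("^>\\s*", "", lines[heads[i]])
    toks <- strsplit(hdr, "\\s+")[[1L]]
    id <- toks[1L]
    tf <- if (length(toks) > 1L) toks[2L] else id
    body <- lines[(heads[i] + 1L):(bounds[i + 1L] - 1L)]
    body <- body[nzchar(trimws(body))]
    rows <- lapply(DNA_BASES, function(b) {
      ln <- body[grepl(paste0("^\\s*", b, "\\b"), body)]
      if (length(ln) != 1L) {
        stop("matrix ", id, ": expected exactly one '", b, "' row")
      }
      nums <- regmatches(ln, gregexpr("[0-9]+\\.?[0-9]*(?:[eE][-+]?[0-9]+)?",
                                      ln))[[1L]]
      as.numeric(nums)
    })
    lens <- lengths(rows)
    if (length(unique(lens)) != 1L) {
      stop("matrix ", id, ": base rows of unequal length")
    }
    new_pwm(do.call(rbind, rows), id = id, tf = tf,
            background = background, pseudocount = pseudocount)
  })
  pwm_library(pwms)
}

parse_transfac <- function(lines, pseudocount, background) {
  blocks <- split(lines, cumsum(grepl("^AC\\b", lines)))
  blocks <- blocks[names(blocks) != "0"]
  if (!length(blocks)) stop("no TRANSFAC records found")
  pwms <- lapply(blocks, function(bl) {
    id <- trimws(sub("^AC\\s*", "", bl[grepl("^AC\\b", bl)][1L]))
    idln <- bl[grepl("^ID\\b", bl)]
    tf <- if (length(idln)) trimws(sub("^ID\\s*", "", idln[1L])) else id
    p0 <- grep("^P0\\b|^PO\\b", bl)
    if (!length(p0)) stop("matrix ", id, ": missing P0 header")
    rows <- list()
    for (j in (p0[1L] + 1L):length(bl)) {
      if (grepl("^(//|XX)", bl[j]) || !grepl("^\\s*[0-9]", bl[j])) break
      toks <- strsplit(trimws(bl[j]), "\\s+")[[1L]]
      rows[[length(rows) + 1L]] <- as.numeric(toks[2:5])
    }
    if (!length(rows)) stop("matrix ", id, ": no count rows")
    counts <- t(do.call(rbind, rows))  # rows A C G T
    new_pwm(counts, id = id, tf = tf, background = background,
            pseudocount = pseudocount)
  })
  pwm_library(unname(pwms))
}

#' Read a PWM library
#'
#' Supports the JASPAR PFM dialect (`>ID NAME` header plus four base rows,
#' with or without brackets) and the TRANSFAC matrix text dialect
#' (`AC`/`ID`/`P0` blocks terminated by `//`). Counts are converted to
#' probabilities with a background-weighted pseudocount, so the same
#' counts encoded in either dialect yield identical PWMs.
#'
#' @param path Matrix file path.
#' @param dialect `"jaspar-pfm"` or `"transfac-text"`.
#' @param pseudocount,background Passed to [new_pwm()].
#' @return A `kr_pwm_library`.
#' @export
read_pwms <- function(path, dialect = c("jaspar-pfm", "transfac-text"),
                      pseudocount = 1, background = rep(0.25, 4)) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lib <- switch(dialect,
                "jaspar-pfm" = parse_jaspar(lines, pseudocount, background),
                "transfac-text" = parse_transfac(lines, pseudocount,
                                                 background))
  message("read ", length(lib), " matrices from ", path)
  lib
}

#' Read a directed regulatory network
#'
#' SIF lines are `source relation target [target2 ...]`; the edge-TSV
#' dialect holds two columns `from` and `to` (header optional). Self-loops
#' are dropped with a warning.
#'
#' @param path Network file path.
#' @param dialect `"sif"` or `"edge-tsv"`.
#' @return A `kr_network`.
#' @export
read_network <- function(path, dialect = c("sif", "edge-tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (dialect == "sif") {
    parts <- strsplit(trimws(lines), "\\s+")
    el <- do.call(rbind, lapply(parts, function(tk) {
      if (length(tk) < 3L) {
        stop("malformed SIF line (need source relation target): ",
             paste(tk, collapse = " "))
      }
      cbind(from = tk[1L], to = tk[-(1:2)])
    }))
  } else {
    parts <- strsplit(trimws(lines), "\t")
    if (identical(tolower(parts[[1L]][1:2]), c("from", "to"))) {
      parts <- parts[-1L]
    }
    el <- do.call(rbind, lapply(parts, function(tk) {
      if (length(tk) < 2L) stop("malformed edge line: ",
                                paste(tk, collapse = " "))
      cbind(from = tk[1L], to = tk[2L])
    }))
  }
  net <- regulatory_network(as.data.frame(el, stringsAsFactors = FALSE))
  message("read network with ", igraph::vcount(net$graph), " nodes and ",
          igraph::ecount(net$graph), " edges from ", path)
  net
}

#' Write a network as edge TSV
#' @param network A `kr_network`.
#' @param path Output path.
#' @export
write_network <- function(network, path) {
  el <- igraph::as_edgelist(network$graph)
  utils::write.table(data.frame(from = el[, 1L], to = el[, 2L]),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a differential list (or any pipeline table) as TSV
#' @param x Data frame.
#' @param path Output path.
#' @export
write_table_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
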