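# End-to-end driver: differential lists -> six evidence lists -> TF
# candidates (promoter enrichment) and master regulators (network search)
# per list -> membership ranks -> singleton discard -> key regulators.

#' Pipeline configuration
#'
#' Collects every threshold of the analysis in one place. Thresholds
#' default to the study design: fold change 2, significance 0.05, search
#' radius 10, coverage score 0.2, Z-score 1.0, FDR 0.05, six evidence
#' lists.
#'
#' @param fold_threshold,alpha Differential-expression gates.
#' @param radius,score_min,z_min,fdr_max Master-regulator cut-offs.
#' @param tf_alpha,tf_min_fold Promoter-enrichment cut-offs.
#' @param n_permutations Master-regulator permutation count.
#' @param n_background Background promoters sampled per enrichment test.
#' @param seed Seed for every stochastic stage.
#' @return A `kr_pipeline_config` list.
#' @export
pipeline_config <- function(fold_threshold = 2, alpha = 0.05, radius = 10,
                            score_min = 0.2, z_min = 1.0, fdr_max = 0.05,
                            tf_alpha = 0.05, tf_min_fold = 1.5,
                            n_permutations = 10000, n_background = 100L,
                            seed = 1L) {
  cfg <- list(fold_threshold = fold_threshold, alpha = alpha,
              radius = radius, score_min = score_min, z_min = z_min,
              fdr_max = fdr_max, tf_alpha = tf_alpha,
              tf_min_fold = tf_min_fold,
              n_permutations = as.integer(n_permutations),
              n_background = as.integer(n_background),
              seed = as.integer(seed))
  if (any(unlist(cfg[c("fold_threshold", "alpha", "radius", "score_min",
                       "z_min", "fdr_max", "tf_alpha", "tf_min_fold")]) <= 0)) {
    stop("all thresholds must be positive")
  }
  class(cfg) <- "kr_pipeline_config"
  cfg
}

#' Run the full key-regulator pipeline
#'
#' Takes a study bundle (as produced by [simulate_study()], or assembled
#' from files with the readers in this package) and executes: per-line
#' differential calling for transcripts and proteins, assembly of the six
#' evidence lists, promoter-enrichment TF candidates and network
#' master-regulator search per list, membership ranking over the six lists
#' of each category, singleton discard, and the TF/MR intersection with
#' total ranks. Promoters are scanned once and the hits reused across
#' lists. All randomness is derived from `config$seed`, so a rerun with
#' the same bundle and config is byte-identical.
#'
#' @param bundle List with `network`, `promoters`, `library`, `expression`
#'   (per line: `high`, `low` matrices), `peptides` (per line: `high`,
#'   `low` peptide tables).
#' @param config A `kr_pipeline_config`.
#' @param out_dir Optional directory: writes the key-regulator table, the
#'   per-list candidate tables, and a run log of every threshold and seed.
#' @return List: `key_regulators`, `tf_rank_table`, `mr_rank_table`,
#'   `tf_lists`, `mr_lists`, `six_lists`, `scan_hits`.
#' @export
run_pipeline <- function(bundle, config = pipeline_config(),
                         out_dir = NULL) {
  stopifnot(inherits(config, "kr_pipeline_config"))
  for (field in c("network", "promoters", "library", "expression",
                  "peptides")) {
    if (is.null(bundle[[field]])) {
      stop("pipeline stage 'inputs': bundle is missing '", field, "'")
    }
  }
  lines <- names(bundle$expression)
  if (length(lines) != 3L || !setequal(lines, names(bundle$peptides))) {
    stop("pipeline stage 'inputs': expression and peptide bundles must ",
         "cover the same 3 cell lines")
  }

  # -- stage 1: differential lists ------------------------------------
  per_line <- lapply(stats::setNames(lines, lines), function(ln) {
    ex <- bundle$expression[[ln]]
    pe <- bundle$peptides[[ln]]
    list(
      transcript = de_transcripts(ex$high, ex$low,
                                  fold_threshold = config$fold_threshold,
                                  alpha = config$alpha, line = ln),
      protein = de_proteins(pe$high, pe$low,
                            fold_threshold = config$fold_threshold,
                            line = ln)
    )
  })
  six <- build_six_lists(per_line)

  # -- stage 2: promoter scan (once) + per-list TF candidates ---------
  library <- bundle$library
  if (any(vapply(library, function(p) is.null(p$threshold), logical(1)))) {
    library <- calibrate_library(library)
  }
  all_hits <- scan_set(library, bundle$promoters)
  prom_genes <- names(bundle$promoters)
  # background promoters come from genes differential in NO list, so the
  # no set is not contaminated by genes regulated in another cell line
  de_union <- unique(unlist(lapply(six, function(x) x$entity)))
  tf_lists <- vector("list", length(six))
  names(tf_lists) <- names(six)
  tf_records <- tf_lists
  for (i in seq_along(six)) {
    yes_genes <- intersect(prom_genes, six[[i]]$entity)
    if (length(yes_genes) == 0L) {
      tf_lists[[i]] <- character(0)
      next
    }
    pool <- setdiff(prom_genes, de_union)
    set.seed(child_seed(config$seed, 10L + i))
    no_genes <- sample(pool, min(config$n_background, length(pool)))
    res <- suppressWarnings(tf_candidates(
      bundle$promoters[yes_genes], bundle$promoters[no_genes], library,
      alpha = config$tf_alpha, min_fold = config$tf_min_fold,
      hits = all_hits[all_hits$gene %in% c(yes_genes, no_genes), ,
                      drop = FALSE]
    ))
    tf_lists[[i]] <- res$candidates
    tf_records[[i]] <- res$records
  }

  # -- stage 3: per-list master regulators ----------------------------
  mr_results <- lapply(seq_along(six), function(i) {
    if (nrow(six[[i]]) == 0L) return(NULL)
    suppressWarnings(find_master_regulators(
      bundle$network, six[[i]], radius = config$radius,
      score_min = config$score_min, z_min = config$z_min,
      fdr_max = config$fdr_max, n_permutations = config$n_permutations,
      rng_seed = child_seed(config$seed, 30L + i)
    ))
  })
  names(mr_results) <- names(six)
  mr_lists <- lapply(mr_results, function(r) {
    if (is.null(r) || nrow(r) == 0L) character(0) else r$gene
  })

  # -- stage 4: rank integration --------------------------------------
  tf_table <- discard_singletons(membership_ranks(tf_lists, "TF"))
  mr_table <- discard_singletons(membership_ranks(mr_lists, "MR"))
  kr <- suppressWarnings(key_regulators(tf_table, mr_table))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_table_tsv(kr, file.path(out_dir, "key_regulators.tsv"))
    write_table_tsv(tf_table, file.path(out_dir, "tf_ranks.tsv"))
    write_table_tsv(mr_table, file.path(out_dir, "mr_ranks.tsv"))
    for (nm in names(six)) {
      write_table_tsv(six[[nm]],
                      file.path(out_dir, paste0("de_", nm, ".tsv")))
      write_table_tsv(
        data.frame(tf = tf_lists[[nm]] %||% character(0)),
        file.path(out_dir, paste0("tf_", nm, ".tsv")))
      write_table_tsv(
        data.frame(mr = mr_lists[[nm]] %||% character(0)),
        file.path(out_dir, paste0("mr_", nm, ".tsv")))
    }
    log_lines <- c(
      "keyreg run log",
      paste0(names(unclass(config)), "\t", unlist(unclass(config))),
      paste0("pwm_thresholds\t",
             paste(sprintf("%s=%.6f", names(library),
                           vapply(library, function(p) p$threshold,
                                  numeric(1))), collapse = ";"))
    )
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  }

  list(key_regulators = kr, tf_rank_table = tf_table,
       mr_rank_table = mr_table, tf_lists = tf_lists, mr_lists = mr_lists,
       tf_records = tf_records, mr_results = mr_results, six_lists = six,
       scan_hits = all_hits)
}
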